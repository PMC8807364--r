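test_that("CpG site detection matches a regex oracle", {
  expect_equal(find_cpg_sites("ACGTCG"), c(1L, 4L))
  expect_equal(find_cpg_sites("AATT"), integer())
  expect_error(find_cpg_sites("ACGN"), "non-ACGT")
  set.seed(61)
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    oracle <- as.integer(gregexpr("(?=CG)", s, perl = TRUE)[[1]]) - 1L
    oracle <- oracle[oracle >= 0]
    expect_equal(find_cpg_sites(s), oracle)
  }
})

test_that("bisulfite-aware alignment treats expected conversion as match", {
  ref <- "ACGTACCGTTAGCA"
  ident <- align_clone(ref, ref)
  expect_equal(ident$map, seq_len(nchar(ref)))
  expect_equal(ident$identity, 1)
  expect_false(ident$rejected)

  # fully converted clone (every C -> T) aligns with full score
  conv <- chartr("C", "T", ref)
  a <- align_clone(conv, ref)
  expect_equal(a$map, seq_len(nchar(ref)))
  expect_equal(a$score, nchar(ref))
  expect_equal(a$identity, 1)

  # a single-base deletion produces exactly one unmapped reference base
  del <- paste0(substr(ref, 1, 5), substr(ref, 7, nchar(ref)))
  ad <- align_clone(del, ref)
  expect_equal(sum(is.na(ad$map)), 1L)
  expect_false(ad$rejected)

  # garbage clone is rejected with a reason
  bad <- align_clone(paste(rep("A", 14), collapse = ""), "CGCGCGCGCGCGCG")
  expect_true(bad$rejected)
  expect_match(bad$reason, "identity")
})

# exhaustive enumeration of all global alignments with affine gap costs
# (first gap base -2, each further base -1); independent of the DP
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              go = -2, ge = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, last) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      s <- if (A[i] == B[j] || (A[i] == "C" && B[j] == "T")) match
           else mismatch
      recurse(i + 1, j + 1, score + s, "d")
    }
    if (i <= length(A))
      recurse(i + 1, j, score + if (last == "u") ge else go, "u")
    if (j <= length(B))
      recurse(i, j + 1, score + if (last == "l") ge else go, "l")
  }
  recurse(1, 1, 0, "d")
  best
}

test_that("alignment score equals the exhaustive-enumeration oracle", {
  set.seed(62)
  for (rep in 1:8) {
    n <- sample(4:6, 1); m <- sample(4:6, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    cln <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    got <- align_clone(cln, ref, min_identity = 0)$score
    expect_equal(got, brute_align_score(ref, cln),
                 info = paste(ref, cln))
  }
})

test_that("methylation calling reads C as methylated and T as unmethylated", {
  ref <- "ACGTCCGT"           # CpG sites at 1 and 5; non-CpG C at 4
  cs_meth <- clone_set(ref, data.frame(clone_id = "c1", sample_id = "s",
                                       sequence = "ACGTTCGT"))
  calls <- call_methylation(cs_meth)
  expect_true(all(calls$calls == "methylated"))
  expect_equal(calls$conversion_efficiency, 1)
  expect_true(calls$retained)

  cs_unmeth <- clone_set(ref, data.frame(clone_id = "c1", sample_id = "s",
                                         sequence = chartr("C", "T", ref)))
  calls2 <- call_methylation(cs_unmeth)
  expect_true(all(calls2$calls == "unmethylated"))

  # unconverted clone fails the conversion-efficiency QC
  cs_fail <- clone_set(ref, data.frame(clone_id = "c1", sample_id = "s",
                                       sequence = ref))
  calls3 <- call_methylation(cs_fail)
  expect_false(calls3$retained)
  expect_match(calls3$reason, "conversion")
})

test_that("simulate -> align -> call round trip is exact at full conversion", {
  cfg <- simulation_config(seed = 63, conversion_rate = 1)
  amp <- random_amplicon(200, 10, seed = 63)
  cs <- simulate_bisulfite_clones(amp, rep(0.5, 10), 20, cfg)
  calls <- call_methylation(cs)
  expect_true(all(calls$retained))
  expect_identical(calls$calls == "methylated", cs$truth)
})

test_that("clone generation follows the conversion rules", {
  cfg <- simulation_config(seed = 64, conversion_rate = 1)
  amp <- random_amplicon(120, 5, seed = 64)
  sites1 <- find_cpg_sites(amp) + 1
  # all sites methylated: clones differ from reference only at non-CpG Cs
  cs1 <- simulate_bisulfite_clones(amp, rep(1, 5), 5, cfg)
  for (sq in cs1$clones$sequence) {
    diffs <- which(strsplit(sq, "")[[1]] != strsplit(amp, "")[[1]])
    ref_chars <- strsplit(amp, "")[[1]]
    expect_true(all(ref_chars[diffs] == "C"))
    expect_true(all(!diffs %in% sites1))
    expect_true(all(strsplit(sq, "")[[1]][diffs] == "T"))
  }
  # all sites unmethylated: no C remains anywhere
  cs0 <- simulate_bisulfite_clones(amp, rep(0, 5), 5, cfg)
  expect_false(any(grepl("C", cs0$clones$sequence)))
})

test_that("conversion-efficiency estimate is unbiased", {
  cfg <- simulation_config(seed = 65, conversion_rate = 0.97)
  amp <- random_amplicon(200, 8, seed = 65)
  cs <- simulate_bisulfite_clones(amp, rep(0.5, 8), 100, cfg)
  calls <- call_methylation(cs, min_conversion = 0)
  n_nonCpG_C <- sum(strsplit(amp, "")[[1]] == "C") - 8
  se <- sqrt(0.97 * 0.03 / (100 * n_nonCpG_C))
  expect_lt(abs(mean(calls$conversion_efficiency) - 0.97), 2 * se + 0.005)
})

test_that("lollipop summary excludes ambiguous calls and rejected clones", {
  calls <- structure(list(
    calls = matrix(c("methylated", "methylated", "ambiguous",
                     "unmethylated", "methylated", "methylated"),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2", "c3"),
                                   c("cpg_1", "cpg_5"))),
    conversion_efficiency = c(1, 1, 0.5),
    retained = c(TRUE, TRUE, FALSE),
    reason = c(NA, NA, "conversion efficiency 0.5 below 0.95"),
    sample_id = c("s1", "s1", "s1"),
    cpg_sites = c(1L, 5L)), class = "clone_call_matrix")
  out <- lollipop_summary(calls)
  g <- out$s1
  expect_equal(nrow(g$grid), 2)                     # rejected clone dropped
  expect_equal(g$overall_fraction, 2 / 3)           # ambiguous excluded
  expect_equal(unname(g$site_fraction), c(1, 1/2))
  expect_equal(g$n_clones_retained, 2L)

  # all clones methylated everywhere -> fraction exactly 1
  calls$calls[] <- "methylated"; calls$retained <- rep(TRUE, 3)
  expect_equal(lollipop_summary(calls)$s1$overall_fraction, 1)
})

test_that("clone FASTA round-trips through write_clones/read_clones", {
  cfg <- simulation_config(seed = 66, conversion_rate = 1)
  amp <- random_amplicon(100, 4, seed = 66)
  cs <- simulate_bisulfite_clones(amp, rep(0.5, 4), 6, cfg,
                                  sample_id = "tumor")
  f <- tempfile(fileext = ".fa")
  write_clones(cs, f)
  back <- read_clones(f)
  expect_equal(back$reference, cs$reference)
  expect_equal(back$clones$sequence, cs$clones$sequence)
  expect_equal(back$clones$sample_id, cs$clones$sample_id)
  unlink(f)
})
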