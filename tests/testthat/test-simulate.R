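test_that("configuration validation names the offending field", {
  expect_error(simulation_config(seed = 1, planted_fraction = 0),
               "planted_fraction")
  expect_error(simulation_config(seed = 1, n_genes = 0), "n_genes")
  expect_error(simulation_config(seed = 1, conversion_rate = 0),
               "conversion_rate")
  expect_error(simulation_config(seed = 1, beta_noise_sd = -1),
               "beta_noise_sd")
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, n_genes = 5,
                                 planted_fraction = 0.01),
               "planted_fraction")
  err <- tryCatch(simulation_config(seed = 1, n_genes = -2),
                  condition = identity)
  expect_s3_class(err, "methylscreen_config_error")
})

test_that("generators are bit-identical under the same seed", {
  a <- tiny_inputs(9); b <- tiny_inputs(9)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth$planted, b$truth$planted)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$counts, b$counts)
  c2 <- tiny_inputs(10)
  expect_false(identical(a$intensities$M, c2$intensities$M))
})

test_that("annotation geometry keeps promoter windows in range", {
  cfg1 <- simulation_config(n_genes = 1, planted_fraction = 0.6, seed = 2)
  expect_equal(nrow(generate_annotation(cfg1)), 1L)
  # upstream windows never underflow, over many random configurations
  set.seed(81)
  for (rep in 1:200) {
    cfg <- simulation_config(n_genes = sample(1:20, 1),
                             planted_fraction = 0.9,
                             chrom_names = paste0("chr", 1:sample(1:3, 1)),
                             seed = sample.int(1e6, 1))
    ann <- generate_annotation(cfg)
    expect_true(all(ann$tss >= 1000))
    expect_true(all(ann$tss[ann$strand == "+"] - 500 >= 0))
    expect_true(all(ann$exonic_length >= 200))
    expect_false(anyDuplicated(ann$gene_id) > 0)
  }
})

test_that("manifest places promoter probes inside and background outside windows", {
  inp <- tiny_inputs(11)
  man <- inp$manifest; ann <- inp$annotation; cfg <- inp$config
  prom <- man[!is.na(man$gene_id), ]
  expect_equal(nrow(prom), cfg$probes_per_promoter * cfg$n_genes)
  expect_equal(sum(is.na(man$gene_id)), cfg$n_background_probes)
  expect_false(anyDuplicated(man$probe_id) > 0)

  asg <- assign_promoter_probes(man[c("probe_id", "chrom", "pos")], ann)
  # every promoter probe recovers exactly its intended gene
  expect_equal(nrow(asg), nrow(prom))
  m <- merge(prom, asg, by = "probe_id")
  expect_true(all(m$gene_id.x == m$gene_id.y))
  # background probes intersect no promoter window
  expect_false(any(asg$probe_id %in% man$probe_id[is.na(man$gene_id)]))

  expect_error(generate_probe_manifest(ann, tiny_config(11), upstream_bp = 2),
               "window too small|promoter window")
})

test_that("null methylation effect with zero noise gives identical conditions", {
  inp <- tiny_inputs(12, delta_beta_effect = 0, beta_noise_sd = 0)
  bm <- beta_matrix(inp$intensities)
  for (cc in setdiff(colnames(bm), "parental"))
    expect_equal(unname(bm[, cc]), unname(bm[, "parental"]))
})

test_that("planted methylation shift is recovered up to the offset attenuation", {
  # noiseless: delta-beta equals the effect scaled by S/(S+offset)
  inp <- tiny_inputs(13, n_genes = 100, beta_noise_sd = 0)
  bm <- beta_matrix(inp$intensities)
  asg <- assign_promoter_probes(
    inp$manifest[c("probe_id", "chrom", "pos")], inp$annotation)
  db <- delta_beta(bm, asg, "parental", paste0("deriv", 1:3))
  planted <- inp$truth$gene_id[inp$truth$planted]
  got <- db$delta_beta[db$gene_id %in% planted]
  expect_true(all(got > 0.35 & got <= 0.4))
  expect_true(all(abs(db$delta_beta[!db$gene_id %in% planted]) < 1e-12))

  # with noise, mean recovered effect sits within Monte-Carlo error of the
  # attenuated target 0.4 * E[S / (S + 100)]
  inp2 <- tiny_inputs(14, n_genes = 100, planted_fraction = 0.5,
                      beta_noise_sd = 0.05)
  bm2 <- beta_matrix(inp2$intensities)
  asg2 <- assign_promoter_probes(
    inp2$manifest[c("probe_id", "chrom", "pos")], inp2$annotation)
  db2 <- delta_beta(bm2, asg2, "parental", paste0("deriv", 1:3))
  planted2 <- inp2$truth$gene_id[inp2$truth$planted]
  got2 <- db2$delta_beta[db2$gene_id %in% planted2]
  set.seed(1)
  S <- pmax(200, rnorm(1e5, 2000, 200))
  target <- 0.4 * mean(S / (S + 100))
  se <- sd(got2) / sqrt(length(got2))
  expect_lt(abs(mean(got2) - target), 2 * se + 0.01)
})

test_that("expression counts realise the planted fold-change", {
  # dispersion 0, null effect: derivative/parental RPKM ratio ~ 1
  inp <- tiny_inputs(15, n_genes = 200, log2fc_effect = 0,
                     count_dispersion = 0)
  lens <- setNames(inp$annotation$exonic_length, inp$annotation$gene_id)
  rk <- rpkm_matrix(inp$counts, lens,
                    rep(inp$config$count_library_size, 4))
  ratio <- rk[, "deriv1"] / pmax(rk[, "parental"], 0.01)
  expect_equal(mean(ratio[rk[, "parental"] > 1]), 1, tolerance = 0.05)

  # planted genes: expected ratio 2^-2 = 0.25
  inp2 <- tiny_inputs(16, n_genes = 400, count_dispersion = 0)
  lens2 <- setNames(inp2$annotation$exonic_length, inp2$annotation$gene_id)
  rk2 <- rpkm_matrix(inp2$counts, lens2,
                     rep(inp2$config$count_library_size, 4))
  planted <- inp2$truth$planted
  obs <- rk2[planted, "deriv1"] / rk2[planted, "parental"]
  expect_equal(mean(obs), 0.25, tolerance = 0.03)

  # with dispersion 0.1, mean observed log2FC within 2 SE of -2
  inp3 <- tiny_inputs(17, n_genes = 400, count_dispersion = 0.1)
  rk3 <- rpkm_matrix(inp3$counts,
                     setNames(inp3$annotation$exonic_length,
                              inp3$annotation$gene_id),
                     rep(inp3$config$count_library_size, 4))
  pl <- inp3$truth$planted
  lfc <- log2_ratio(rk3[pl, "parental"],
                    rowMeans(rk3[pl, paste0("deriv", 1:3)]))
  expect_lt(abs(mean(lfc) - (-2)), 2 * sd(lfc) / sqrt(sum(pl)) + 0.1)
})

test_that("bisulfite clone draws respect the per-site probabilities", {
  cfg <- simulation_config(seed = 18, conversion_rate = 1)
  amp <- random_amplicon(200, 10, seed = 18)
  cs <- simulate_bisulfite_clones(amp, rep(0.8, 10), 100, cfg)
  frac <- mean(cs$truth)
  n <- length(cs$truth)
  ci <- 0.8 + c(-1.96, 1.96) * sqrt(0.8 * 0.2 / n)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
})

test_that("survival simulation honours censoring and grouping", {
  cfg <- simulation_config(seed = 19)
  tab <- simulate_survival(100, 1, censor_rate = 0, config = cfg)
  expect_true(all(tab$event == 1L))
  expect_true(all(tab$time > 0))
  expect_equal(tab$group, median_split(tab$marker))
  tab2 <- simulate_survival(400, 1, censor_rate = 0.3, config = cfg)
  expect_equal(mean(tab2$event == 0), 0.3, tolerance = 0.08)
  expect_error(simulate_survival(2, 1, 0, cfg), "n_subjects")
})
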