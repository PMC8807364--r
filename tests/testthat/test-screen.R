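make_dbeta <- function(gene_id, delta_beta, n_probes = 3L) {
  structure(data.frame(gene_id = gene_id, delta_beta = delta_beta,
                       max_abs_delta_beta = abs(delta_beta),
                       n_probes = n_probes, stringsAsFactors = FALSE),
            class = c("delta_beta_table", "data.frame"))
}

test_that("quadrant classification follows the sign pair and both gates", {
  expr <- data.frame(gene_id = c("gA", "gB", "gC", "gD", "gE"),
                     rpkm_parental = c(20, 20, 1, 20, 20),
                     rpkm_derivative = c(5, 5, 0.5, 80, 80),
                     log2_ratio = c(-2, -3, -1.5, 2, 2))
  db <- make_dbeta(c("gA", "gB", "gC", "gD", "gE"),
                   c(0.3, 0.05, 0.4, -0.3, 0.3))
  res <- integrate_screen(expr, db)
  q <- setNames(res$quadrant, res$gene_id)
  expect_equal(unname(q["gA"]), "hypermethylated_down")
  expect_true(res$candidate[res$gene_id == "gA"])
  expect_equal(unname(q["gB"]), "not_significant")  # |dbeta| <= 0.1
  expect_equal(unname(q["gC"]), "not_significant")  # fails RPKM gate
  expect_equal(unname(q["gD"]), "hypomethylated_up")
  expect_equal(unname(q["gE"]), "hypermethylated_up")
  expect_equal(sum(res$candidate), 1L)
  # candidate implies hypermethylated_down; others never flagged
  expect_true(all(res$quadrant[res$candidate] == "hypermethylated_down"))
})

test_that("genes with probes but no expression record are not significant", {
  expr <- data.frame(gene_id = "gA", rpkm_parental = 20,
                     rpkm_derivative = 5, log2_ratio = -2)
  db <- make_dbeta(c("gA", "gOrphan"), c(0.3, 0.5))
  expect_message(res <- integrate_screen(expr, db), "no expression")
  expect_equal(res$quadrant[res$gene_id == "gOrphan"], "not_significant")
})

test_that("screen equals a brute-force double-predicate comprehension", {
  set.seed(51)
  for (rep in 1:20) {
    n <- 50
    expr <- data.frame(gene_id = sprintf("g%02d", 1:n),
                       rpkm_parental = runif(n, 0, 12),
                       rpkm_derivative = runif(n, 0, 12))
    expr$log2_ratio <- log2_ratio(expr$rpkm_parental,
                                  expr$rpkm_derivative)
    db <- make_dbeta(expr$gene_id, runif(n, -0.5, 0.5))
    res <- integrate_screen(expr, db)
    oracle_cand <- expr$gene_id[sapply(1:n, function(i)
      (expr$rpkm_parental[i] > 3 || expr$rpkm_derivative[i] > 3) &&
        abs(expr$log2_ratio[i]) > 1 &&
        db$delta_beta[i] > 0.1 && expr$log2_ratio[i] < -1)]
    expect_setequal(res$gene_id[res$candidate], oracle_cand)
    oracle_sig <- expr$gene_id[sapply(1:n, function(i)
      (expr$rpkm_parental[i] > 3 || expr$rpkm_derivative[i] > 3) &&
        abs(expr$log2_ratio[i]) > 1 && abs(db$delta_beta[i]) > 0.1)]
    expect_setequal(res$gene_id[res$quadrant != "not_significant"],
                    oracle_sig)
    # every gene passing both gates lies in exactly one quadrant
    expect_true(all(res$quadrant[res$gene_id %in% oracle_sig] %in%
                      c("hypermethylated_down", "hypermethylated_up",
                        "hypomethylated_down", "hypomethylated_up")))
  }
})

test_that("results are ordered by descending delta-beta with deterministic ties", {
  expr <- data.frame(gene_id = c("gB", "gA", "gC"),
                     rpkm_parental = 20, rpkm_derivative = 5,
                     log2_ratio = c(-2, -2, -3))
  db <- make_dbeta(c("gB", "gA", "gC"), c(0.3, 0.3, 0.5))
  res <- integrate_screen(expr, db)
  expect_equal(res$gene_id, c("gC", "gA", "gB"))
})

test_that("raising the delta-beta threshold never grows the candidate set", {
  set.seed(52)
  expr <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     rpkm_parental = runif(200, 0, 30),
                     rpkm_derivative = runif(200, 0, 30))
  expr$log2_ratio <- log2_ratio(expr$rpkm_parental, expr$rpkm_derivative)
  db <- make_dbeta(expr$gene_id, runif(200, -0.6, 0.6))
  prev <- candidates(integrate_screen(expr, db, min_abs_delta_beta = 0.05))
  for (thr in c(0.1, 0.2, 0.4, 1.1)) {
    cur <- candidates(integrate_screen(expr, db,
                                       min_abs_delta_beta = thr))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_length(candidates(integrate_screen(expr, db,
                                            min_abs_delta_beta = 1.1)), 0)
})

test_that("candidate probe report is consistent with gene summaries", {
  inp <- tiny_inputs(7)
  scr <- methyl_screen(inp$intensities, inp$manifest, inp$annotation,
                       inp$counts, "parental")
  expect_s3_class(scr, "methyl_screen")
  rep_tab <- scr$report
  for (g in unique(rep_tab$gene_id)) {
    expect_equal(mean(rep_tab$delta_beta[rep_tab$gene_id == g]),
                 scr$screen$delta_beta[scr$screen$gene_id == g],
                 tolerance = 1e-12)
    expect_equal(sum(rep_tab$gene_id == g),
                 scr$screen$n_promoter_probes[scr$screen$gene_id == g])
  }
  # print and summary methods run cleanly
  expect_output(print(scr), "candidates")
  expect_output(print(summary(scr)), "Quadrant counts")
})

test_that("planted genes rank above all background genes by delta-beta", {
  hits <- 0L
  for (s in 1:10) {
    inp <- tiny_inputs(100 + s, n_genes = 100)
    scr <- methyl_screen(inp$intensities, inp$manifest, inp$annotation,
                         inp$counts, "parental")
    planted <- inp$truth$gene_id[inp$truth$planted]
    top <- scr$screen$gene_id[seq_along(planted)]
    if (setequal(top, planted)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
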