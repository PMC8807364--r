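#' Intersect the expression and methylation screens
#'
#' Genes that pass the expression gate and show a promoter methylation
#' change with \eqn{|\Delta\beta|} above threshold are classified by the
#' sign pair (\eqn{\mathrm{sgn}\,\Delta\beta},
#' \eqn{\mathrm{sgn}\,\log_2\mathrm{FC}}) into four quadrants; all other
#' genes are \code{not_significant}. Candidate silenced tumor-suppressor
#' genes are the hypermethylated-downregulated quadrant with
#' \eqn{\Delta\beta > } threshold and \eqn{\log_2\mathrm{FC} < -}
#' \code{min_abs_log2fc}. \eqn{\Delta\beta} is oriented derivative minus
#' parental, so hypermethylation in the derivative lines is positive.
#'
#' @param screen_input per-gene expression table (see
#'   [expression_screen_input()]).
#' @param dbeta a \code{delta_beta_table} from [delta_beta()].
#' @param min_rpkm,min_abs_log2fc expression gate thresholds (defaults 3
#'   and 1), strict inequalities.
#' @param min_abs_delta_beta methylation threshold (default 0.1), strict.
#' @return data.frame of class \code{screen_result}, sorted by descending
#'   \eqn{\Delta\beta}, then ascending log2 ratio, then gene id; columns
#'   \code{gene_id}, \code{log2_ratio}, \code{delta_beta},
#'   \code{max_abs_delta_beta}, \code{n_promoter_probes},
#'   \code{quadrant}, \code{candidate}.
#' @export
integrate_screen <- function(screen_input, dbeta,
                             min_rpkm = 3, min_abs_log2fc = 1,
                             min_abs_delta_beta = 0.1) {
  if (min_abs_delta_beta < 0)
    stop("min_abs_delta_beta must be nonnegative", call. = FALSE)
  expr_pass <- screen_expression(screen_input, min_rpkm, min_abs_log2fc)

  genes <- dbeta$gene_id
  no_expr <- setdiff(genes, screen_input$gene_id)
  if (length(no_expr))
    message(length(no_expr), " gene(s) with promoter probes but no ",
            "expression record classified not_significant")

  i <- match(genes, screen_input$gene_id)
  lfc <- screen_input$log2_ratio[i]
  db <- dbeta$delta_beta

  meth_pass <- abs(db) > min_abs_delta_beta
  both <- meth_pass & genes %in% expr_pass & !is.na(lfc)
  quadrant <- rep("not_significant", length(genes))
  quadrant[both] <- ifelse(db[both] > 0,
                           ifelse(lfc[both] < 0, "hypermethylated_down",
                                  "hypermethylated_up"),
                           ifelse(lfc[both] < 0, "hypomethylated_down",
                                  "hypomethylated_up"))
  candidate <- both & db > min_abs_delta_beta & lfc < -min_abs_log2fc

  out <- data.frame(gene_id = genes,
                    log2_ratio = lfc,
                    delta_beta = db,
                    max_abs_delta_beta = dbeta$max_abs_delta_beta,
                    n_promoter_probes = dbeta$n_probes,
                    quadrant = quadrant,
                    candidate = candidate,
                    stringsAsFactors = FALSE)
  ord <- order(-out$delta_beta, out$log2_ratio, out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            thresholds = c(min_rpkm = min_rpkm,
                           min_abs_log2fc = min_abs_log2fc,
                           min_abs_delta_beta = min_abs_delta_beta),
            class = c("screen_result", "data.frame"))
}

#' Probe-level report for candidate genes
#'
#' For every candidate gene, lists each of its promoter probes with the
#' per-condition beta-values and the per-probe delta-beta — the content of
#' a per-candidate promoter methylation heatmap, machine-readable.
#'
#' @param result a \code{screen_result}.
#' @param beta probe x condition \code{beta_matrix}.
#' @param assignment a \code{promoter_assignment}.
#' @param cond_a,cond_b condition labels as in [delta_beta()].
#' @return data.frame with \code{gene_id}, \code{probe_id}, one
#'   \code{beta_<condition>} column per condition, \code{delta_beta}.
#' @export
candidate_report <- function(result, beta, assignment, cond_a, cond_b) {
  cand <- result$gene_id[result$candidate]
  sel <- assignment[assignment$gene_id %in% cand, , drop = FALSE]
  bsub <- beta[sel$probe_id, , drop = FALSE]
  d <- rowMeans(bsub[, cond_b, drop = FALSE] -
                  bsub[, rep(cond_a, length(cond_b)), drop = FALSE])
  out <- data.frame(gene_id = sel$gene_id, probe_id = sel$probe_id,
                    stringsAsFactors = FALSE)
  for (cc in colnames(beta)) out[[paste0("beta_", cc)]] <- unname(bsub[, cc])
  out$delta_beta <- unname(d)
  out <- out[order(match(out$gene_id, result$gene_id), out$probe_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full integrative methylation-expression screen
#'
#' The central entry point: from raw probe intensities, a probe manifest,
#' a gene annotation and an expression count (or RPKM) matrix, computes
#' beta-values, assigns probes to promoters, contrasts each derivative
#' condition against the parental, applies the expression gate and the
#' methylation threshold, and returns a classed screen object.
#'
#' @param intensities long intensity table (\code{probe_id},
#'   \code{sample_id}, \code{M}, \code{U}).
#' @param manifest probe manifest (\code{probe_id}, \code{chrom},
#'   \code{pos}).
#' @param annotation gene annotation (\code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tss}, \code{exonic_length}).
#' @param counts gene x sample count matrix (conditions as columns; one
#'   RNA-seq sample per condition).
#' @param parental parental condition label.
#' @param grouping optional sample id -> condition map for the arrays;
#'   derived from \code{"_r<k>"} suffixes when NULL.
#' @param upstream_bp promoter window (default 500).
#' @param beta_offset beta-value denominator offset (default 100).
#' @param min_rpkm,min_abs_log2fc,min_abs_delta_beta screen thresholds
#'   (defaults 3, 1, 0.1).
#' @param rpkm_floor floor for fold-changes (default 0.01).
#' @param derivative_summary how per-derivative expression values are
#'   pooled for the gate: \code{"any"} (default; the derivative line with
#'   the strongest fold-change to the parental) or \code{"mean"}
#'   (arithmetic mean across derivative RPKMs). With a single RNA-seq
#'   replicate per condition, mean-pooling leaves enough fold-change
#'   noise that genuinely 4-fold-silenced genes regularly miss the
#'   two-fold gate; requiring any one line to show the change is the
#'   more sensitive screen at negligible cost in false candidates,
#'   because candidacy still requires the promoter methylation shift.
#' @param total_mapped per-sample library sizes; column sums when NULL.
#' @return object of class \code{methyl_screen}: list with \code{screen}
#'   (the \code{screen_result} table), \code{beta}, \code{rpkm},
#'   \code{dbeta}, \code{assignment}, \code{expr_input}, \code{report}
#'   (probe-level candidate report), \code{conditions}, \code{thresholds}.
#' @seealso [integrate_screen()], [candidate_report()], [run_screen()]
#' @export
methyl_screen <- function(intensities, manifest, annotation, counts,
                          parental, grouping = NULL,
                          upstream_bp = 500, beta_offset = 100,
                          min_rpkm = 3, min_abs_log2fc = 1,
                          min_abs_delta_beta = 0.1, rpkm_floor = 0.01,
                          derivative_summary = c("any", "mean"),
                          total_mapped = NULL) {
  derivative_summary <- match.arg(derivative_summary)
  beta <- beta_matrix(intensities, grouping, beta_offset)
  if (!parental %in% colnames(beta))
    stop("parental condition '", parental, "' not found among arrays",
         call. = FALSE)
  derivs <- setdiff(colnames(beta), parental)
  assignment <- assign_promoter_probes(manifest, annotation, upstream_bp)
  dbeta <- delta_beta(beta, assignment, parental, derivs)

  if (!is.matrix(counts)) counts <- as.matrix(counts)
  lens <- stats::setNames(annotation$exonic_length, annotation$gene_id)
  if (is.null(total_mapped)) total_mapped <- colSums(counts)
  rpkm <- rpkm_matrix(counts, lens, total_mapped)
  expr_derivs <- intersect(c(derivs, colnames(rpkm)), colnames(rpkm))
  expr_derivs <- setdiff(expr_derivs, parental)
  expr_input <- expression_screen_input(rpkm, parental, expr_derivs,
                                        derivative_summary, rpkm_floor)

  screen <- integrate_screen(expr_input, dbeta, min_rpkm, min_abs_log2fc,
                             min_abs_delta_beta)
  report <- candidate_report(screen, beta, assignment, parental, derivs)
  structure(list(screen = screen, beta = beta, rpkm = rpkm, dbeta = dbeta,
                 assignment = assignment, expr_input = expr_input,
                 report = report,
                 conditions = list(parental = parental,
                                   derivatives = derivs),
                 thresholds = attr(screen, "thresholds")),
            class = "methyl_screen")
}

#' @export
print.methyl_screen <- function(x, ...) {
  th <- x$thresholds
  cat("Integrative promoter methylation / expression screen\n")
  cat(sprintf("  conditions: %s vs %s\n", x$conditions$parental,
              paste(x$conditions$derivatives, collapse = ", ")))
  cat(sprintf("  genes screened: %d  (promoter probes assigned: %d)\n",
              nrow(x$screen), nrow(x$assignment)))
  cat(sprintf("  gates: RPKM > %g (either condition), |log2FC| > %g, |Δβ| > %g\n",
              th["min_rpkm"], th["min_abs_log2fc"], th["min_abs_delta_beta"]))
  cat(sprintf("  candidates (hypermethylated, silenced): %d\n",
              sum(x$screen$candidate)))
  if (any(x$screen$candidate)) {
    cat("  top candidates:\n")
    top <- utils::head(x$screen[x$screen$candidate, ], 5L)
    print(top[, c("gene_id", "delta_beta", "log2_ratio",
                  "n_promoter_probes")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.methyl_screen <- function(object, ...) {
  tab <- table(factor(object$screen$quadrant,
                      levels = c("hypermethylated_down", "hypermethylated_up",
                                 "hypomethylated_down", "hypomethylated_up",
                                 "not_significant")))
  structure(list(quadrants = tab,
                 n_candidates = sum(object$screen$candidate),
                 candidates = object$screen$gene_id[object$screen$candidate],
                 thresholds = object$thresholds),
            class = "summary.methyl_screen")
}

#' @export
print.summary.methyl_screen <- function(x, ...) {
  cat("Quadrant counts:\n")
  print(x$quadrants)
  cat("Candidates:", if (x$n_candidates) paste(x$candidates, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Extract candidate genes from a screen
#' @param x a \code{methyl_screen} or \code{screen_result}.
#' @return character vector of candidate gene ids, ranked by descending
#'   delta-beta.
#' @export
candidates <- function(x) {
  tab <- if (inherits(x, "methyl_screen")) x$screen else x
  tab$gene_id[tab$candidate]
}

#' Scatter of methylation change against expression change
#'
#' The screen's quadrant scatter: per-gene delta-beta on the x axis,
#' log2 expression ratio on the y axis, threshold guide lines, candidates
#' highlighted.
#'
#' @param x a \code{methyl_screen}.
#' @param ... passed to \code{plot}.
#' @export
plot.methyl_screen <- function(x, ...) {
  s <- x$screen
  th <- x$thresholds
  col <- ifelse(s$candidate, "firebrick",
                ifelse(s$quadrant == "not_significant", "grey60",
                       "steelblue"))
  graphics::plot(s$delta_beta, s$log2_ratio, col = col, pch = 16,
                 cex = 0.6, xlab = expression(Delta * beta ~
                   "(derivative - parental)"),
                 ylab = expression(log[2] ~ "RPKM ratio"), ...)
  graphics::abline(v = c(-1, 1) * th["min_abs_delta_beta"],
                   h = c(-1, 1) * th["min_abs_log2fc"],
                   col = "blue", lty = 2)
  invisible(x)
}
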