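#' Reads per kilobase of exon per million mapped reads
#'
#' \deqn{\mathrm{RPKM} = \frac{c \cdot 10^9}{L \cdot N}}
#' for \eqn{c} reads on a gene of total exonic length \eqn{L} bp in a
#' library of \eqn{N} mapped reads.
#'
#' @param count nonnegative read count(s).
#' @param exonic_length total exonic length in bp (> 0).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, exonic_length, total_mapped) {
  if (any(exonic_length <= 0))
    stop("exonic_length must be positive", call. = FALSE)
  if (any(total_mapped <= 0))
    stop("total_mapped must be positive", call. = FALSE)
  if (any(count < 0))
    stop("count must be nonnegative", call. = FALSE)
  count * 1e9 / (exonic_length * total_mapped)
}

#' RPKM matrix from a gene x sample count matrix
#'
#' @param counts nonnegative matrix, genes in rows, samples in columns.
#' @param exonic_length named (or row-aligned) vector of exonic lengths.
#' @param total_mapped per-sample totals; defaults to column sums.
#' @return RPKM matrix with the same dimnames as \code{counts}.
#' @export
rpkm_matrix <- function(counts, exonic_length,
                        total_mapped = colSums(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.null(names(exonic_length)) && !is.null(rownames(counts)))
    exonic_length <- exonic_length[rownames(counts)]
  if (length(exonic_length) != nrow(counts))
    stop("exonic_length does not cover every gene", call. = FALSE)
  if (anyNA(exonic_length))
    stop("missing exonic length for some genes", call. = FALSE)
  sweep(counts * 1e9 / exonic_length, 2L, total_mapped, "/")
}

#' Floored log2 expression ratio
#'
#' Both RPKM values are floored at a small positive constant before the
#' ratio is taken, so the fold-change is defined (and bounded) even when a
#' gene is fully silenced in one condition.
#'
#' @param rpkm_a denominator-condition RPKM (e.g. parental).
#' @param rpkm_b numerator-condition RPKM (e.g. derivative).
#' @param floor positive floor applied to both values (default 0.01).
#' @return \code{log2(max(rpkm_b, floor) / max(rpkm_a, floor))}.
#' @export
log2_ratio <- function(rpkm_a, rpkm_b, floor = 0.01) {
  if (!is.numeric(floor) || floor <= 0)
    stop("floor must be positive", call. = FALSE)
  log2(pmax(rpkm_b, floor) / pmax(rpkm_a, floor))
}

#' Row-wise z-scores with a population denominator
#'
#' Each gene row is centred and scaled by its population standard
#' deviation (denominator \eqn{n}), the usual convention for expression
#' heatmaps. Constant rows become all-zero and are flagged.
#'
#' @param rpkm numeric matrix, genes in rows, >= 2 samples.
#' @return matrix of z-scores; attribute \code{constant_rows} gives the
#'   row labels that had zero variance.
#' @export
zscore_rows <- function(rpkm) {
  if (!is.matrix(rpkm)) rpkm <- as.matrix(rpkm)
  if (ncol(rpkm) < 2L)
    stop("z-scores need at least 2 samples", call. = FALSE)
  mu <- rowMeans(rpkm)
  centred <- rpkm - mu
  sd_pop <- sqrt(rowMeans(centred^2))
  flat <- sd_pop == 0
  z <- centred / ifelse(flat, 1, sd_pop)
  z[flat, ] <- 0
  structure(z, constant_rows = rownames(rpkm)[flat])
}

#' Expression gate of the integrative screen
#'
#' A gene is retained iff it is expressed above \code{min_rpkm} in at least
#' one of the two conditions AND its absolute log2 ratio exceeds
#' \code{min_abs_log2fc}. Both inequalities are strict.
#'
#' @param screen_input data.frame with columns \code{gene_id},
#'   \code{rpkm_parental}, \code{rpkm_derivative}, \code{log2_ratio}.
#' @param min_rpkm expression threshold (default 3).
#' @param min_abs_log2fc fold-change threshold on the log2 scale
#'   (default 1, i.e. two-fold).
#' @return character vector of retained gene ids.
#' @export
screen_expression <- function(screen_input, min_rpkm = 3,
                              min_abs_log2fc = 1) {
  need <- c("gene_id", "rpkm_parental", "rpkm_derivative", "log2_ratio")
  stopifnot(all(need %in% names(screen_input)))
  if (min_rpkm < 0 || min_abs_log2fc < 0)
    stop("thresholds must be nonnegative", call. = FALSE)
  keep <- (screen_input$rpkm_parental > min_rpkm |
             screen_input$rpkm_derivative > min_rpkm) &
    abs(screen_input$log2_ratio) > min_abs_log2fc
  screen_input$gene_id[keep]
}

#' Per-gene expression summary for the parental-vs-derivative contrast
#'
#' Summarises an RPKM matrix into the screen's per-gene input: parental
#' RPKM, a derivative summary (mean across derivative conditions by
#' default, or the per-derivative extreme under \code{summary = "any"}),
#' and the floored log2 ratio derivative/parental.
#'
#' @param rpkm gene x condition RPKM matrix.
#' @param parental parental condition label.
#' @param derivatives derivative condition labels (default: all others).
#' @param summary \code{"mean"} pools derivatives by their mean;
#'   \code{"any"} takes, per gene, the derivative RPKM with the largest
#'   absolute log2 ratio to the parental.
#' @param floor passed to [log2_ratio()].
#' @return data.frame with \code{gene_id}, \code{rpkm_parental},
#'   \code{rpkm_derivative}, \code{log2_ratio}.
#' @export
expression_screen_input <- function(rpkm, parental,
                                    derivatives = setdiff(colnames(rpkm),
                                                          parental),
                                    summary = c("mean", "any"),
                                    floor = 0.01) {
  summary <- match.arg(summary)
  if (!parental %in% colnames(rpkm))
    stop("unknown parental condition: ", parental, call. = FALSE)
  if (!length(derivatives) || !all(derivatives %in% colnames(rpkm)))
    stop("invalid derivative condition labels", call. = FALSE)
  rp <- rpkm[, parental]
  dmat <- rpkm[, derivatives, drop = FALSE]
  if (summary == "mean") {
    rd <- rowMeans(dmat)
  } else {
    lr <- log2_ratio(rep(rp, ncol(dmat)), as.vector(dmat), floor)
    pick <- max.col(matrix(abs(lr), nrow(rpkm)), ties.method = "first")
    rd <- dmat[cbind(seq_len(nrow(dmat)), pick)]
  }
  data.frame(gene_id = rownames(rpkm),
             rpkm_parental = unname(rp),
             rpkm_derivative = unname(rd),
             log2_ratio = log2_ratio(unname(rp), unname(rd), floor),
             stringsAsFactors = FALSE)
}
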