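#' Assign array probes to strand-aware promoter windows
#'
#' A gene's promoter window is the \code{upstream_bp} bases immediately 5'
#' of its transcription start site (TSS), excluding the TSS base itself.
#' Coordinates are 0-based; windows are half-open. For a + strand gene with
#' TSS \eqn{t} the window is \eqn{[t - upstream\_bp, t)}; for a - strand
#' gene it is \eqn{[t + 1, t + upstream\_bp + 1)}. A probe is assigned to a
#' gene iff it lies on the same chromosome inside that window; one probe may
#' map to several genes.
#'
#' @param manifest data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{pos} (0-based CpG position).
#' @param annotation data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{tss}, and optionally
#'   \code{exonic_length}.
#' @param upstream_bp promoter window size in bp (default 500).
#' @return object of class \code{promoter_assignment}: a data.frame with
#'   columns \code{probe_id}, \code{gene_id}; attributes \code{upstream_bp}
#'   and \code{downstream_bp} (always 0).
#' @export
assign_promoter_probes <- function(manifest, annotation, upstream_bp = 500) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(manifest)),
            all(c("gene_id", "chrom", "strand", "tss") %in% names(annotation)))
  if (!all(annotation$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene", call. = FALSE)
  if (!is.numeric(upstream_bp) || upstream_bp < 0)
    stop("upstream_bp must be nonnegative", call. = FALSE)

  unknown <- setdiff(unique(manifest$chrom), unique(annotation$chrom))
  if (length(unknown))
    warning("probes on chromosomes absent from the annotation left ",
            "unassigned: ", paste(unknown, collapse = ", "), call. = FALSE)

  win_start <- ifelse(annotation$strand == "+",
                      annotation$tss - upstream_bp, annotation$tss + 1)
  win_end <- win_start + upstream_bp  # half-open [start, end)

  hits <- lapply(seq_len(nrow(annotation)), function(i) {
    on_chr <- manifest$chrom == annotation$chrom[i]
    inside <- on_chr & manifest$pos >= win_start[i] & manifest$pos < win_end[i]
    if (any(inside))
      data.frame(probe_id = manifest$probe_id[inside],
                 gene_id = annotation$gene_id[i],
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(probe_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, upstream_bp = upstream_bp, downstream_bp = 0,
            class = c("promoter_assignment", "data.frame"))
}

#' Per-gene methylation difference between two conditions
#'
#' Computes the per-probe beta-value difference
#' \eqn{\Delta\beta = \beta(\mathrm{cond_b}) - \beta(\mathrm{cond_a})} and
#' summarises it per gene as the arithmetic mean over the gene's promoter
#' probes; the maximum absolute per-probe difference is reported alongside
#' so either convention can be thresholded. Genes with no assigned probe are
#' absent from the result.
#'
#' @param beta probe x condition \code{beta_matrix}.
#' @param assignment a \code{promoter_assignment} (see
#'   [assign_promoter_probes()]).
#' @param cond_a reference condition label (e.g. the parental line).
#' @param cond_b comparison condition label (e.g. a derivative line), or a
#'   vector of labels whose per-derivative \eqn{\Delta\beta} values are
#'   averaged (the default screen pools derivatives this way).
#' @return data.frame (class \code{delta_beta_table}) with columns
#'   \code{gene_id}, \code{delta_beta} (mean over probes),
#'   \code{max_abs_delta_beta}, \code{n_probes}; attribute
#'   \code{probe_deltas} holds the per-(gene, probe) values.
#' @export
delta_beta <- function(beta, assignment, cond_a, cond_b) {
  conds <- colnames(beta)
  bad <- setdiff(c(cond_a, cond_b), conds)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  idx <- match(assignment$probe_id, rownames(beta))
  if (anyNA(idx))
    stop("assignment refers to probes absent from the beta matrix",
         call. = FALSE)
  # per-probe delta, averaged across derivative conditions if several given
  d_by_cond <- beta[idx, cond_b, drop = FALSE] -
    beta[idx, rep(cond_a, length(cond_b)), drop = FALSE]
  d <- rowMeans(d_by_cond)
  probe_tab <- data.frame(gene_id = assignment$gene_id,
                          probe_id = assignment$probe_id,
                          delta_beta = unname(d),
                          stringsAsFactors = FALSE)
  mean_d <- tapply(probe_tab$delta_beta, probe_tab$gene_id, mean)
  max_d <- tapply(abs(probe_tab$delta_beta), probe_tab$gene_id, max)
  n_p <- tapply(probe_tab$delta_beta, probe_tab$gene_id, length)
  genes <- names(mean_d)
  out <- data.frame(gene_id = genes,
                    delta_beta = unname(mean_d[genes]),
                    max_abs_delta_beta = unname(max_d[genes]),
                    n_probes = as.integer(n_p[genes]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, probe_deltas = probe_tab, cond_a = cond_a, cond_b = cond_b,
            class = c("delta_beta_table", "data.frame"))
}
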