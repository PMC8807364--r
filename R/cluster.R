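#' Hierarchically cluster probe methylation profiles chromosome by chromosome
#'
#' Within each chromosome, probes are clustered by average-linkage
#' agglomeration on the Euclidean distance between their per-condition
#' beta-value vectors, mirroring per-chromosome heatmap clustering of
#' methylation arrays. Chromosomes with a single probe yield a singleton
#' ordering. Ties in merge distance are resolved by input order (lower
#' index merges first), so the leaf ordering is reproducible.
#'
#' @param beta probe x condition \code{beta_matrix}.
#' @param manifest data.frame with columns \code{probe_id}, \code{chrom}.
#' @return named list, one element per chromosome: list with
#'   \code{order} (probe ids in leaf order) and \code{hclust} (the
#'   \code{stats::hclust} object, or NULL for singletons).
#' @export
cluster_by_chromosome <- function(beta, manifest) {
  stopifnot(all(c("probe_id", "chrom") %in% names(manifest)))
  chroms <- unique(manifest$chrom)
  out <- lapply(chroms, function(cc) {
    probes <- manifest$probe_id[manifest$chrom == cc]
    probes <- probes[probes %in% rownames(beta)]
    if (length(probes) < 2L)
      return(list(order = probes, hclust = NULL))
    hc <- stats::hclust(stats::dist(beta[probes, , drop = FALSE]),
                        method = "average")
    list(order = probes[hc$order], hclust = hc)
  })
  names(out) <- chroms
  out
}

#' Hierarchically cluster gene expression profiles
#'
#' Average-linkage agglomerative clustering of per-gene z-score (or RPKM)
#' rows using correlation distance \eqn{1 - r}. Rows with zero variance
#' (undefined correlation) are placed at maximal distance 2 from all other
#' rows and at 0 from each other.
#'
#' @param z numeric matrix, genes in rows, samples in columns (>= 2 rows).
#' @return list with \code{order} (row labels in leaf order) and
#'   \code{hclust}.
#' @export
cluster_expression <- function(z) {
  if (!is.matrix(z)) z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least 2 genes to cluster", call. = FALSE)
  r <- suppressWarnings(stats::cor(t(z)))
  d <- 1 - r
  # undefined correlations (constant rows): far from everything,
  # identical degenerate rows collapse together
  if (anyNA(d)) {
    d[is.na(d)] <- 2
    const <- which(apply(z, 1L, stats::sd) == 0)
    if (length(const) > 1L) d[const, const] <- 0
    diag(d) <- 0
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labs <- rownames(z)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(z)))
  list(order = labs[hc$order], hclust = hc)
}
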