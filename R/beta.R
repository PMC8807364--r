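#' Compute Infinium-style beta-values from probe intensities
#'
#' The methylation level of a CpG probe is estimated as
#' \deqn{\beta = M / (M + U + \mathrm{offset})}
#' where \code{M} and \code{U} are the intensities of the methylated and
#' unmethylated allele probes. The positive offset stabilises the ratio at
#' low total intensity and guarantees \eqn{\beta < 1} strictly.
#'
#' @param M numeric vector of methylated-allele intensities (>= 0).
#' @param U numeric vector of unmethylated-allele intensities (>= 0).
#' @param offset positive stabilising constant added to the denominator
#'   (default 100).
#' @return numeric vector of beta-values in \[0, 1).
#' @examples
#' compute_beta(100, 0)   # 0.5
#' compute_beta(900, 0)   # 0.9
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (!is.numeric(M) || !is.numeric(U))
    stop("M and U must be numeric", call. = FALSE)
  if (any(!is.finite(M)) || any(!is.finite(U)))
    stop("M and U must be finite", call. = FALSE)
  if (any(M < 0) || any(U < 0))
    stop("negative intensity: M and U must be >= 0", call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
    stop("offset must be a single positive number", call. = FALSE)
  M / (M + U + offset)
}

#' Average replicate beta-values within conditions
#'
#' Combines a probe x sample beta matrix into a probe x condition matrix by
#' taking the arithmetic mean over the replicate arrays of each condition.
#' Conditions with a single replicate pass through unchanged.
#'
#' @param beta_by_sample numeric matrix, probes in rows, samples in columns
#'   (column names are sample ids).
#' @param grouping named character vector mapping sample id to condition
#'   label; every column of \code{beta_by_sample} must be present.
#' @return a \code{beta_matrix}: probe x condition numeric matrix with
#'   attribute \code{replicate_count} (named integer vector per condition).
#' @export
average_replicates <- function(beta_by_sample, grouping) {
  if (!is.matrix(beta_by_sample))
    beta_by_sample <- as.matrix(beta_by_sample)
  samples <- colnames(beta_by_sample)
  if (is.null(samples))
    stop("beta_by_sample must have sample ids as column names", call. = FALSE)
  missing <- setdiff(samples, names(grouping))
  if (length(missing))
    stop("samples without a condition assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cond <- grouping[samples]
  conds <- unique(unname(cond))
  out <- vapply(conds, function(cc) {
    cols <- which(cond == cc)
    if (!length(cols)) stop("empty condition: ", cc, call. = FALSE)
    rowMeans(beta_by_sample[, cols, drop = FALSE])
  }, numeric(nrow(beta_by_sample)))
  if (is.null(dim(out)))  # single-probe edge case
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(beta_by_sample), conds))
  colnames(out) <- conds
  rownames(out) <- rownames(beta_by_sample)
  structure(out,
            replicate_count = vapply(conds, function(cc) sum(cond == cc),
                                     integer(1)),
            class = c("beta_matrix", class(out)))
}

#' Build a per-condition beta matrix from a long intensity table
#'
#' Convenience wrapper: computes beta-values for every (probe, sample)
#' record and averages replicates within conditions.
#'
#' @param intensities data.frame with columns \code{probe_id},
#'   \code{sample_id}, \code{M}, \code{U}; one row per probe per sample.
#' @param grouping named character vector sample id -> condition; if
#'   \code{NULL}, conditions are derived by stripping a trailing
#'   \code{"_r<k>"} replicate suffix from the sample ids.
#' @param offset passed to [compute_beta()].
#' @return probe x condition \code{beta_matrix} (see [average_replicates()]).
#' @export
beta_matrix <- function(intensities, grouping = NULL, offset = 100) {
  need <- c("probe_id", "sample_id", "M", "U")
  if (!all(need %in% names(intensities)))
    stop("intensity table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(intensities[c("probe_id", "sample_id")]))
    stop("duplicate (probe_id, sample_id) records", call. = FALSE)
  b <- compute_beta(intensities$M, intensities$U, offset)
  probes <- unique(intensities$probe_id)
  samples <- unique(intensities$sample_id)
  mat <- matrix(NA_real_, length(probes), length(samples),
                dimnames = list(probes, samples))
  mat[cbind(match(intensities$probe_id, probes),
            match(intensities$sample_id, samples))] <- b
  if (anyNA(mat))
    stop("intensity table is not complete over probes x samples",
         call. = FALSE)
  if (is.null(grouping)) grouping <- infer_conditions(samples)
  out <- average_replicates(mat, grouping)
  attr(out, "offset") <- offset
  out
}

# sample ids of the form "<condition>_r<k>" -> condition labels
infer_conditions <- function(sample_ids) {
  cond <- sub("_r[0-9]+$", "", sample_ids)
  stats::setNames(cond, sample_ids)
}
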