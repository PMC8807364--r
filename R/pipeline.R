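#' @title File-based pipeline orchestration
#' @description TSV/FASTA readers and writers for every pipeline input and
#'   output, plus end-to-end drivers: \code{run_simulation()} writes the
#'   full synthetic input set, \code{run_screen()} executes the
#'   intensity-to-candidate screen on files and writes all result tables
#'   and a reproducibility manifest.
#' @name pipeline
NULL

read_tsv_checked <- function(file, required, what) {
  if (!file.exists(file))
    data_error(what, ": file not found: ", file)
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    data_error(what, " (", file, "): missing column(s): ",
               paste(missing, collapse = ", "))
  for (cc in required) {
    bad <- which(is.na(df[[cc]]))
    if (length(bad))
      data_error(what, " (", file, "): missing value at line ",
                 bad[1L] + 1L, ", column ", cc)
  }
  df
}

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read pipeline input tables
#'
#' Schema-checked readers for the intensity, manifest, annotation,
#' counts and survival TSVs. Errors name the file and offending column.
#' The annotation reader also accepts BED-style input (chrom, start, end,
#' name, score, strand): the strand-aware TSS is taken from the interval
#' end on \code{-} strands.
#'
#' @param file path to a tab-separated file.
#' @return data.frame in the package's canonical schema.
#' @name readers
NULL

#' @rdname readers
#' @export
read_intensities <- function(file) {
  df <- read_tsv_checked(file, c("probe_id", "sample_id", "M", "U"),
                         "intensity table")
  if (any(df$M < 0) || any(df$U < 0))
    data_error("intensity table (", file, "): negative intensity")
  df
}

#' @rdname readers
#' @export
read_manifest <- function(file) {
  read_tsv_checked(file, c("probe_id", "chrom", "pos"), "probe manifest")
}

#' @rdname readers
#' @export
read_annotation <- function(file) {
  head1 <- utils::read.delim(file, nrows = 1, header = FALSE,
                             stringsAsFactors = FALSE)
  if (!is.na(suppressWarnings(as.numeric(head1[[2]])))) {
    # headerless BED3+: chrom start end name score strand
    df <- utils::read.delim(file, header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6)
      data_error("annotation (", file, "): BED input needs 6 columns ",
                 "(strand in column 6)")
    names(df)[1:6] <- c("chrom", "start", "end", "gene_id", "score",
                        "strand")
    df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
    df$exonic_length <- df$end - df$start
    return(df[c("gene_id", "chrom", "strand", "tss", "exonic_length")])
  }
  read_tsv_checked(file, c("gene_id", "chrom", "strand", "tss",
                           "exonic_length"), "annotation")
}

#' @rdname readers
#' @export
read_counts <- function(file) {
  df <- read_tsv_checked(file, c("gene_id", "sample_id", "count"),
                         "count table")
  genes <- unique(df$gene_id)
  samples <- unique(df$sample_id)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(df$gene_id, genes), match(df$sample_id, samples))] <-
    df$count
  if (anyNA(m))
    data_error("count table (", file, "): not complete over genes x ",
               "samples")
  m
}

#' @rdname readers
#' @export
read_survival <- function(file) {
  df <- read_tsv_checked(file, c("subject", "time", "event", "marker"),
                         "survival table")
  if (any(df$time <= 0))
    data_error("survival table (", file, "): nonpositive time")
  df
}

#' Write every synthetic input the screen consumes
#'
#' Generates and writes the complete input set with ground truth:
#' \code{annotation.tsv}, \code{manifest.tsv}, \code{intensities.tsv},
#' \code{counts.tsv}, \code{truth.tsv}, \code{survival.tsv} and
#' \code{clones.fa} (reference amplicon first, clone samples emulating an
#' unmethylated parental and a hypermethylated derivative).
#'
#' @param config a \code{simulation_config}.
#' @param outdir output directory (created if needed).
#' @param n_subjects,group_hazard_ratio,censor_rate survival-cohort
#'   settings (defaults 200, 2, 0.2).
#' @param n_clones_per_sample bisulfite clones per sample (default 10).
#' @return invisible list with the generated objects and file paths.
#' @export
run_simulation <- function(config, outdir,
                           n_subjects = 200, group_hazard_ratio = 2,
                           censor_rate = 0.2, n_clones_per_sample = 10) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config)
  man <- generate_probe_manifest(ann, config)
  truth <- generate_ground_truth(ann, config)
  intens <- simulate_methylation_intensities(man, truth, config)
  counts <- simulate_expression_counts(ann, truth, config)
  surv <- simulate_survival(n_subjects, group_hazard_ratio, censor_rate,
                            config)

  amp <- random_amplicon(200, 10, seed = config$seed)
  n_sites <- length(find_cpg_sites(amp))
  par_clones <- simulate_bisulfite_clones(amp, rep(0.1, n_sites),
                                          n_clones_per_sample, config,
                                          sample_id = "parental")
  der_clones <- simulate_bisulfite_clones(amp, rep(0.9, n_sites),
                                          n_clones_per_sample, config,
                                          sample_id = "deriv1")
  clones <- clone_set(amp, rbind(par_clones$clones, der_clones$clones))

  paths <- c(annotation = file.path(outdir, "annotation.tsv"),
             manifest = file.path(outdir, "manifest.tsv"),
             intensities = file.path(outdir, "intensities.tsv"),
             counts = file.path(outdir, "counts.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             survival = file.path(outdir, "survival.tsv"),
             clones = file.path(outdir, "clones.fa"))
  write_tsv(ann, paths["annotation"])
  write_tsv(man[c("probe_id", "chrom", "pos")], paths["manifest"])
  write_tsv(intens, paths["intensities"])
  counts_long <- data.frame(
    gene_id = rep(rownames(counts), ncol(counts)),
    sample_id = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts), stringsAsFactors = FALSE)
  write_tsv(counts_long, paths["counts"])
  write_tsv(truth, paths["truth"])
  write_tsv(surv[c("subject", "time", "event", "marker")],
            paths["survival"])
  write_clones(clones, paths["clones"])
  invisible(list(paths = paths, annotation = ann, manifest = man,
                 truth = truth, intensities = intens, counts = counts,
                 survival = surv, clones = clones))
}

#' Run the integrative screen on files and write all artifacts
#'
#' Reads the intensity, manifest, annotation and count tables, runs
#' [methyl_screen()], and writes: per-condition beta matrix, per-gene
#' delta-beta table, RPKM matrix, the screen table (gene, log2fc,
#' delta-beta, quadrant, candidate), the probe-level candidate report,
#' and a YAML run manifest (config hash, seed, package version, row
#' counts) sufficient to reproduce the run. Identical configs give
#' byte-identical outputs.
#'
#' @param config list (or path to a YAML file) with elements
#'   \code{paths} (\code{intensities}, \code{manifest},
#'   \code{annotation}, \code{counts}, \code{outdir}),
#'   \code{parental} (condition label, default \code{"parental"}),
#'   optional \code{thresholds} (\code{min_rpkm}, \code{min_abs_log2fc},
#'   \code{min_abs_delta_beta}, \code{upstream_bp}, \code{beta_offset},
#'   \code{rpkm_floor}) and \code{derivative_summary}.
#' @return the \code{methyl_screen} object, invisibly.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  p <- config$paths
  for (nm in c("intensities", "manifest", "annotation", "counts",
               "outdir"))
    if (is.null(p[[nm]]))
      config_error("paths$", nm, ": required path missing from run config")
  th <- utils::modifyList(
    list(min_rpkm = 3, min_abs_log2fc = 1, min_abs_delta_beta = 0.1,
         upstream_bp = 500, beta_offset = 100, rpkm_floor = 0.01),
    config$thresholds %||% list())
  if (any(unlist(th) < 0))
    config_error("thresholds: all thresholds must be nonnegative")

  scr <- methyl_screen(
    intensities = read_intensities(p$intensities),
    manifest = read_manifest(p$manifest),
    annotation = read_annotation(p$annotation),
    counts = read_counts(p$counts),
    parental = config$parental %||% "parental",
    upstream_bp = th$upstream_bp, beta_offset = th$beta_offset,
    min_rpkm = th$min_rpkm, min_abs_log2fc = th$min_abs_log2fc,
    min_abs_delta_beta = th$min_abs_delta_beta,
    rpkm_floor = th$rpkm_floor,
    derivative_summary = config$derivative_summary %||% "any")

  dir.create(p$outdir, recursive = TRUE, showWarnings = FALSE)
  beta_df <- data.frame(probe_id = rownames(scr$beta),
                        as.data.frame(unclass(scr$beta)[, , drop = FALSE]),
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(beta_df, file.path(p$outdir, "beta.tsv"))
  write_tsv(as.data.frame(scr$dbeta), file.path(p$outdir, "delta_beta.tsv"))
  rpkm_df <- data.frame(gene_id = rownames(scr$rpkm),
                        as.data.frame(scr$rpkm), check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_tsv(rpkm_df, file.path(p$outdir, "rpkm.tsv"))
  write_tsv(as.data.frame(scr$screen), file.path(p$outdir, "screen.tsv"))
  write_tsv(scr$report, file.path(p$outdir, "candidate_probes.tsv"))

  cfg_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_tmp)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    package_version = as.character(utils::packageVersion("methylscreen")),
    thresholds = th,
    n_probes = nrow(scr$beta), n_genes_screened = nrow(scr$screen),
    n_candidates = sum(scr$screen$candidate))
  unlink(cfg_tmp)
  yaml::write_yaml(manifest, file.path(p$outdir, "run_manifest.yaml"))
  invisible(scr)
}

#' Load a pipeline run configuration from YAML
#'
#' @param file YAML path.
#' @return the configuration list; the \code{simulation} block, if
#'   present, is converted to a [simulation_config()].
#' @export
load_run_config <- function(file) {
  if (!file.exists(file)) config_error("config file not found: ", file)
  cfg <- yaml::read_yaml(file)
  if (!is.null(cfg$simulation))
    cfg$simulation <- do.call(simulation_config, cfg$simulation)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
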