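#' @title Synthetic parental-vs-derivative epigenome simulation
#' @description Generators for every input the screen consumes, with known
#'   ground truth: a gene annotation, an array probe manifest, raw
#'   methylated/unmethylated probe intensities with planted promoter
#'   hypermethylation, expression counts with planted silencing, bisulfite
#'   clones at known per-CpG methylation probabilities, and survival times
#'   whose hazard depends on an expression group. All generators are pure
#'   functions of (inputs, seed).
#' @name synthetic-data
NULL

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("methylscreen_config_error",
                                             "error", "condition")))
}

data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("methylscreen_data_error",
                                             "error", "condition")))
}

# run expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration of the synthetic two-condition epigenome
#'
#' Defaults emulate the study design the pipeline targets: one parental
#' line, three derivative lines, duplicate methylation arrays per
#' condition and a single RNA-seq sample per condition. Effect sizes are
#' stand-ins for the (unreported) real distributions: a +0.4 beta shift
#' at planted promoters and 4-fold transcriptional silencing.
#'
#' @param n_genes number of genes (default 2000).
#' @param chrom_names chromosome labels (default chr1..chr8).
#' @param probes_per_promoter array probes per promoter window (default 3).
#' @param n_background_probes probes outside every promoter (default 1000).
#' @param n_derivative_conditions derivative lines (default 3).
#' @param n_array_replicates arrays per condition (default 2).
#' @param planted_fraction fraction of genes with planted
#'   hypermethylation + silencing (default 0.05).
#' @param delta_beta_effect planted beta shift in derivatives (default
#'   0.4).
#' @param log2fc_effect planted expression log2 fold-change, negative =
#'   silencing (default -2).
#' @param beta_noise_sd replicate noise sd on the raw beta scale
#'   (default 0.05).
#' @param intensity_scale mean total intensity M+U per probe (default
#'   2000).
#' @param count_library_size expected reads per RNA-seq sample (default
#'   2e7).
#' @param count_dispersion negative-binomial dispersion; 0 gives Poisson
#'   counts (default 0.1).
#' @param conversion_rate bisulfite conversion probability per
#'   unmethylated cytosine (default 0.99).
#' @param seed integer seed; mandatory, every generator is deterministic
#'   given it.
#' @return validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 2000,
                              chrom_names = paste0("chr", 1:8),
                              probes_per_promoter = 3,
                              n_background_probes = 1000,
                              n_derivative_conditions = 3,
                              n_array_replicates = 2,
                              planted_fraction = 0.05,
                              delta_beta_effect = 0.4,
                              log2fc_effect = -2,
                              beta_noise_sd = 0.05,
                              intensity_scale = 2000,
                              count_library_size = 2e7,
                              count_dispersion = 0.1,
                              conversion_rate = 0.99,
                              seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed) || seed != round(seed))
    config_error("seed: an integer seed is mandatory")
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != round(x))
      config_error(nm, ": must be an integer >= ", min)
  }
  chk_count(n_genes, "n_genes")
  if (!length(chrom_names) || anyDuplicated(chrom_names))
    config_error("chrom_names: nonempty unique labels required")
  chk_count(probes_per_promoter, "probes_per_promoter")
  chk_count(n_background_probes, "n_background_probes", min = 0)
  chk_count(n_derivative_conditions, "n_derivative_conditions")
  chk_count(n_array_replicates, "n_array_replicates")
  if (!is.numeric(planted_fraction) || planted_fraction <= 0 ||
      planted_fraction >= 1)
    config_error("planted_fraction: must lie in (0, 1)")
  if (round(planted_fraction * n_genes) < 1)
    config_error("planted_fraction: planted_fraction * n_genes must be >= 1")
  if (delta_beta_effect < 0 || delta_beta_effect > 1)
    config_error("delta_beta_effect: must lie in [0, 1]")
  if (beta_noise_sd < 0) config_error("beta_noise_sd: must be >= 0")
  if (intensity_scale <= 0) config_error("intensity_scale: must be > 0")
  chk_count(count_library_size, "count_library_size")
  if (count_dispersion < 0) config_error("count_dispersion: must be >= 0")
  if (conversion_rate <= 0 || conversion_rate > 1)
    config_error("conversion_rate: must lie in (0, 1]")
  structure(list(n_genes = as.integer(n_genes), chrom_names = chrom_names,
                 probes_per_promoter = as.integer(probes_per_promoter),
                 n_background_probes = as.integer(n_background_probes),
                 n_derivative_conditions = as.integer(n_derivative_conditions),
                 n_array_replicates = as.integer(n_array_replicates),
                 planted_fraction = planted_fraction,
                 delta_beta_effect = delta_beta_effect,
                 log2fc_effect = log2fc_effect,
                 beta_noise_sd = beta_noise_sd,
                 intensity_scale = intensity_scale,
                 count_library_size = as.integer(count_library_size),
                 count_dispersion = count_dispersion,
                 conversion_rate = conversion_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

condition_names <- function(config) {
  c("parental", paste0("deriv", seq_len(config$n_derivative_conditions)))
}

#' Generate a synthetic gene annotation
#'
#' Genes are laid out chromosome by chromosome on a 10 kb grid with
#' random jitter, so promoter windows never overlap; every TSS is at
#' least 1000 bp from the chromosome start so upstream windows never
#' underflow. Coordinates are 0-based.
#'
#' @param config a \code{simulation_config}.
#' @return data.frame with \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{tss}, \code{exonic_length}.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 101L, {
    n <- config$n_genes
    chrom <- rep(config$chrom_names, length.out = n)
    idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    tss <- 1000L + (idx_on_chrom - 1L) * 10000L +
      sample.int(4000L, n, replace = TRUE)
    data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
               chrom = chrom,
               strand = sample(c("+", "-"), n, replace = TRUE),
               tss = tss,
               exonic_length = 200L + stats::rnbinom(n, mu = 1500,
                                                     size = 3),
               stringsAsFactors = FALSE)
  })
}

#' Generate a probe manifest over the annotation
#'
#' Places \code{probes_per_promoter} probes inside each gene's
#' strand-aware 500-bp promoter window and
#' \code{n_background_probes} probes in intergenic space outside every
#' promoter window.
#'
#' @param annotation from [generate_annotation()].
#' @param config a \code{simulation_config}.
#' @param upstream_bp promoter window size (default 500).
#' @return data.frame with \code{probe_id}, \code{chrom}, \code{pos},
#'   and a \code{gene_id} column (\code{NA} for background probes) kept
#'   for ground-truth bookkeeping; only the first three columns form the
#'   on-disk manifest schema.
#' @export
generate_probe_manifest <- function(annotation, config, upstream_bp = 500) {
  stopifnot(inherits(config, "simulation_config"))
  if (!nrow(annotation)) config_error("annotation: empty")
  if (config$probes_per_promoter > upstream_bp)
    config_error("probes_per_promoter: promoter window too small for ",
                 config$probes_per_promoter, " distinct probes")
  with_seed(config$seed + 102L, {
    n <- nrow(annotation)
    # strand-aware half-open window [start, start + upstream_bp)
    win_start <- ifelse(annotation$strand == "+",
                        annotation$tss - upstream_bp, annotation$tss + 1L)
    offs <- matrix(vapply(seq_len(n), function(i)
      sort(sample.int(upstream_bp, config$probes_per_promoter)) - 1L,
      integer(config$probes_per_promoter)),
      nrow = n, byrow = TRUE)
    prom <- data.frame(
      probe_id = sprintf("cg%07d", seq_len(n * config$probes_per_promoter)),
      chrom = rep(annotation$chrom, each = config$probes_per_promoter),
      pos = as.integer(t(win_start + offs)),
      gene_id = rep(annotation$gene_id, each = config$probes_per_promoter),
      stringsAsFactors = FALSE)
    bg <- NULL
    if (config$n_background_probes > 0) {
      anchor <- sample.int(n, config$n_background_probes, replace = TRUE)
      bg <- data.frame(
        probe_id = sprintf("bg%07d", seq_len(config$n_background_probes)),
        chrom = annotation$chrom[anchor],
        pos = annotation$tss[anchor] + 2000L +
          sample.int(800L, config$n_background_probes, replace = TRUE),
        gene_id = NA_character_,
        stringsAsFactors = FALSE)
    }
    out <- rbind(prom, bg)
    rownames(out) <- NULL
    out
  })
}

#' Choose planted genes and record the simulation ground truth
#'
#' Planted genes — those given promoter hypermethylation plus
#' transcriptional silencing — are drawn only among genes whose baseline
#' expression is clearly above the screen's RPKM gate, mirroring that a
#' silencing screen can only detect genes expressed in the parental
#' line.
#'
#' @param annotation from [generate_annotation()].
#' @param config a \code{simulation_config}.
#' @return data.frame with \code{gene_id}, \code{planted},
#'   \code{true_delta_beta}, \code{true_log2fc}; attribute
#'   \code{baseline_rpkm} carries the per-gene parental expression level
#'   shared with [simulate_expression_counts()].
#' @export
generate_ground_truth <- function(annotation, config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- nrow(annotation)
  baseline <- with_seed(config$seed + 103L,
                        2^stats::rnorm(n, mean = 3, sd = 2))
  n_planted <- round(config$planted_fraction * n)
  eligible <- which(baseline >= 12)
  if (length(eligible) < n_planted)
    eligible <- order(baseline, decreasing = TRUE)[seq_len(n_planted)]
  planted_idx <- with_seed(config$seed + 104L,
                           sort(sample(eligible, n_planted)))
  planted <- seq_len(n) %in% planted_idx
  out <- data.frame(gene_id = annotation$gene_id,
                    planted = planted,
                    true_delta_beta = ifelse(planted,
                                             config$delta_beta_effect, 0),
                    true_log2fc = ifelse(planted, config$log2fc_effect, 0),
                    stringsAsFactors = FALSE)
  attr(out, "baseline_rpkm") <- stats::setNames(baseline,
                                                annotation$gene_id)
  out
}

#' Simulate raw methylation-array intensities
#'
#' Parental beta of each promoter probe is drawn Beta(0.5, 5)
#' (CpG-island-like, mostly unmethylated); background probes draw
#' Beta(5, 5). In the derivative conditions, probes of planted genes are
#' shifted by \code{delta_beta_effect}, clipped to \[0, 0.99\].
#' Per-replicate Gaussian noise is applied on the raw beta scale and
#' intensities are back-computed as \eqn{M = \beta S}, \eqn{U = (1 -
#' \beta) S} with a per-probe total intensity \eqn{S \sim N(\mu, 0.1\mu)}
#' truncated at 200. Because the downstream beta-value uses a +100
#' offset, observed beta is slightly below the intended value; this bias
#' is accepted and shared by all conditions.
#'
#' @param manifest from [generate_probe_manifest()] (needs its
#'   \code{gene_id} column).
#' @param truth from [generate_ground_truth()].
#' @param config a \code{simulation_config}.
#' @return long data.frame with \code{probe_id}, \code{sample_id},
#'   \code{M}, \code{U}; samples are named
#'   \code{<condition>_r<replicate>}.
#' @export
simulate_methylation_intensities <- function(manifest, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!"gene_id" %in% names(manifest))
    config_error("manifest: gene_id column required (as produced by ",
                 "generate_probe_manifest)")
  extra <- setdiff(stats::na.omit(unique(manifest$gene_id)), truth$gene_id)
  if (length(extra))
    config_error("manifest: genes absent from ground truth: ",
                 paste(utils::head(extra, 3), collapse = ", "))
  with_seed(config$seed + 105L, {
    np <- nrow(manifest)
    is_prom <- !is.na(manifest$gene_id)
    base <- ifelse(is_prom, stats::rbeta(np, 0.5, 5), stats::rbeta(np, 5, 5))
    planted_gene <- truth$gene_id[truth$planted]
    shifted <- is_prom & manifest$gene_id %in% planted_gene
    # per-probe characteristic total intensity, shared across samples
    S <- pmax(200, stats::rnorm(np, config$intensity_scale,
                                0.1 * config$intensity_scale))
    conds <- condition_names(config)
    recs <- lapply(conds, function(cc) {
      mu <- if (cc == "parental") base else
        pmin(0.99, pmax(0, base + shifted * config$delta_beta_effect))
      reps <- lapply(seq_len(config$n_array_replicates), function(r) {
        b <- pmin(0.99, pmax(0, mu + stats::rnorm(np, 0,
                                                  config$beta_noise_sd)))
        data.frame(probe_id = manifest$probe_id,
                   sample_id = paste0(cc, "_r", r),
                   M = b * S, U = (1 - b) * S,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, reps)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Simulate RNA-seq counts, one sample per condition
#'
#' Expected parental counts derive from the per-gene baseline RPKM shared
#' with [generate_ground_truth()]; planted genes' derivative means are
#' scaled by \eqn{2^{\mathrm{log2fc\_effect}}}. Counts are
#' negative-binomial with the configured dispersion (Poisson when 0).
#'
#' @param annotation,truth,config as elsewhere.
#' @return gene x condition integer count matrix.
#' @export
simulate_expression_counts <- function(annotation, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  baseline <- attr(truth, "baseline_rpkm")
  if (is.null(baseline))
    baseline <- attr(generate_ground_truth(annotation, config),
                     "baseline_rpkm")
  baseline <- baseline[annotation$gene_id]
  mu_par <- baseline * annotation$exonic_length *
    config$count_library_size / 1e9
  fc <- 2^ifelse(truth$planted[match(annotation$gene_id, truth$gene_id)],
                 config$log2fc_effect, 0)
  conds <- condition_names(config)
  with_seed(config$seed + 106L, {
    counts <- vapply(conds, function(cc) {
      mu <- if (cc == "parental") mu_par else mu_par * fc
      if (config$count_dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu,
                          size = 1 / config$count_dispersion)
    }, numeric(nrow(annotation)))
    rownames(counts) <- annotation$gene_id
    counts
  })
}

#' Simulate bisulfite-converted clone sequences
#'
#' Each clone draws an independent Bernoulli methylation state at every
#' CpG site of the reference amplicon. Unmethylated CpG cytosines and all
#' non-CpG cytosines are converted C -> T with probability
#' \code{conversion_rate} (failures remain C); methylated cytosines are
#' never converted. Only the top (converted) strand is modelled.
#'
#' @param region_sequence reference amplicon (must contain >= 1 CpG).
#' @param cpg_methylation_probs per-site methylation probabilities, one
#'   per CpG site of the reference.
#' @param n_clones clones to draw.
#' @param config a \code{simulation_config} (supplies
#'   \code{conversion_rate} and the seed).
#' @param sample_id label recorded on every clone (default
#'   \code{"sample1"}).
#' @return a \code{clone_set} with extra element \code{truth}: clone x
#'   site logical matrix of the simulated methylation states.
#' @export
simulate_bisulfite_clones <- function(region_sequence,
                                      cpg_methylation_probs, n_clones,
                                      config, sample_id = "sample1") {
  stopifnot(inherits(config, "simulation_config"))
  sites <- find_cpg_sites(region_sequence)
  if (!length(sites))
    config_error("region_sequence: no CpG dinucleotide present")
  if (length(cpg_methylation_probs) != length(sites))
    config_error("cpg_methylation_probs: length ",
                 length(cpg_methylation_probs), " but reference has ",
                 length(sites), " CpG sites")
  ref <- strsplit(toupper(region_sequence), "", fixed = TRUE)[[1]]
  c_pos <- which(ref == "C")
  site_pos <- sites + 1L
  with_seed(config$seed + 107L + sum(utf8ToInt(sample_id)), {
    truth <- matrix(stats::runif(n_clones * length(sites)) <
                      rep(cpg_methylation_probs, each = n_clones),
                    n_clones, length(sites))
    seqs <- vapply(seq_len(n_clones), function(k) {
      s <- ref
      unmeth_c <- c(setdiff(c_pos, site_pos), site_pos[!truth[k, ]])
      convert <- unmeth_c[stats::runif(length(unmeth_c)) <
                            config$conversion_rate]
      s[convert] <- "T"
      paste(s, collapse = "")
    }, character(1))
    cs <- clone_set(region_sequence,
                    data.frame(clone_id = sprintf("%s_clone%03d", sample_id,
                                                  seq_len(n_clones)),
                               sample_id = sample_id, sequence = seqs,
                               stringsAsFactors = FALSE))
    dimnames(truth) <- list(cs$clones$clone_id, paste0("cpg_", sites))
    cs$truth <- truth
    cs
  })
}

#' Random amplicon with a controlled number of CpG sites
#'
#' Utility for bisulfite simulations: a random sequence whose only CpG
#' dinucleotides are \code{n_cpg} evenly spaced planted sites; the
#' background retains non-CpG cytosines so conversion efficiency is
#' estimable.
#'
#' @param length sequence length in bp.
#' @param n_cpg number of CpG sites to plant.
#' @param seed integer seed.
#' @return DNA string.
#' @export
random_amplicon <- function(length = 200, n_cpg = 10, seed = 1) {
  stopifnot(length >= 4 * n_cpg + 10)
  with_seed(seed + 108L, {
    s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    cg <- which(s[-base::length(s)] == "C" & s[-1L] == "G")
    s[cg + 1L] <- "A"                  # break accidental CpGs
    at <- floor(seq(5, length - 5, length.out = n_cpg))
    s[at] <- "C"; s[at + 1L] <- "G"
    s[at + 2L] <- ifelse(s[at + 2L] == "G", "A", s[at + 2L])
    s[at - 1L] <- ifelse(s[at - 1L] == "C", "A", s[at - 1L])
    paste(s, collapse = "")
  })
}

#' Simulate a survival cohort with a marker-defined risk group
#'
#' Subjects receive a continuous expression marker; the median split of
#' that marker defines the high/low groups, and event times are
#' exponential with the high group's hazard multiplied by
#' \code{group_hazard_ratio}. Censoring is independent exponential,
#' calibrated so roughly \code{censor_rate} of subjects are censored at
#' hazard ratio 1 (exactly none when \code{censor_rate = 0}).
#'
#' @param n_subjects cohort size (>= 4).
#' @param group_hazard_ratio hazard multiplier for the high-marker group.
#' @param censor_rate target censored fraction in \[0, 1).
#' @param config a \code{simulation_config} (seed source).
#' @return data.frame with \code{subject}, \code{time}, \code{event},
#'   \code{marker}, \code{group} (ground-truth label from the median
#'   split).
#' @export
simulate_survival <- function(n_subjects, group_hazard_ratio = 1,
                              censor_rate = 0, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_subjects < 4) config_error("n_subjects: must be >= 4")
  if (group_hazard_ratio <= 0)
    config_error("group_hazard_ratio: must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    config_error("censor_rate: must lie in [0, 1)")
  base_hazard <- 0.1
  with_seed(config$seed + 109L, {
    marker <- stats::rnorm(n_subjects)
    grp <- median_split(marker)
    hz <- base_hazard * ifelse(grp == "high", group_hazard_ratio, 1)
    t_event <- stats::rexp(n_subjects, rate = hz)
    if (censor_rate > 0) {
      t_cens <- stats::rexp(n_subjects,
                            rate = base_hazard * censor_rate /
                              (1 - censor_rate))
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n_subjects)
      time <- t_event
    }
    data.frame(subject = sprintf("s%04d", seq_len(n_subjects)),
               time = time, event = event, marker = marker, group = grp,
               stringsAsFactors = FALSE)
  })
}
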