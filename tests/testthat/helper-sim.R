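# small, fast simulation configuration for unit tests
tiny_config <- function(seed, ...) {
  defaults <- list(n_genes = 40, chrom_names = c("chr1", "chr2"),
                   probes_per_promoter = 3, n_background_probes = 20,
                   planted_fraction = 0.1, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# full synthetic input set in memory
tiny_inputs <- function(seed, ...) {
  cfg <- tiny_config(seed, ...)
  ann <- generate_annotation(cfg)
  man <- generate_probe_manifest(ann, cfg)
  truth <- generate_ground_truth(ann, cfg)
  list(config = cfg, annotation = ann, manifest = man, truth = truth,
       intensities = simulate_methylation_intensities(man, truth, cfg),
       counts = simulate_expression_counts(ann, truth, cfg))
}
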