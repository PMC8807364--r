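# methylscreen

Integrative promoter-methylation / expression screening for silenced
candidate tumor-suppressor genes.

## The problem

Aggressive tumor subclones often silence growth-restraining genes
epigenetically rather than by mutation: the promoter CpGs gain DNA
methylation and transcription drops, with no change in the coding
sequence. Given a parental cell line and one or more derivative lines
(for example, lines re-isolated after in vivo selection), the screen
implemented here asks: *which genes became promoter-hypermethylated and
transcriptionally silenced in the derivatives?* Those genes are the
candidate tumor suppressors whose loss may drive the derived phenotype.

`methylscreen` is aimed at computational biologists who have
methylation-array intensities and RNA-seq abundance for such a
parental-vs-derivative design and want a reproducible, testable
implementation of the whole chain — plus a synthetic-data generator with
known ground truth to validate it end to end.

## The method

For each array probe with methylated intensity *M* and unmethylated
intensity *U*, the methylation level is the stabilised ratio

> β = M / (M + U + 100),

averaged over duplicate arrays per condition. Probes are assigned to the
500 bp immediately upstream of each annotated TSS (strand-aware,
half-open, 0-based), and per gene the promoter methylation change is

> Δβ = mean over promoter probes of β(derivative) − β(parental).

Expression is quantified as RPKM = c·10⁹ / (L·N) for *c* reads on *L* bp
of exon in a library of *N* mapped reads. A gene passes the expression
gate if RPKM > 3 in either condition and |log₂(RPKM_derivative /
RPKM_parental)| > 1; genes also showing |Δβ| > 0.1 are classified into
four quadrants by the signs of (Δβ, log₂FC). **Candidates** are the
hypermethylated-down quadrant: Δβ > 0.1 and log₂FC < −1, ranked by
descending Δβ.

Two companion analyses round out the workflow:

* **Clone bisulfite sequencing** — a bisulfite-aware global aligner
  (reference C aligned to clone T counts as a match) maps each cloned
  amplicon onto the reference; at every CpG the clone base calls the
  site methylated (C) or unmethylated (T), with per-clone conversion
  efficiency estimated from non-CpG cytosines as QC.
* **Median-split survival** — subjects are split at the median of an
  expression marker, per-group survival is estimated with the
  Kaplan–Meier product-limit estimator S(t) = Π (1 − dᵢ/nᵢ), and groups
  are compared with the two-group log-rank test, both implemented from
  first principles.

## Worked example

```r
library(methylscreen)

cfg   <- simulation_config(n_genes = 500, seed = 42)
ann   <- generate_annotation(cfg)
man   <- generate_probe_manifest(ann, cfg)
truth <- generate_ground_truth(ann, cfg)

scr <- methyl_screen(
  simulate_methylation_intensities(man, truth, cfg),
  man[c("probe_id", "chrom", "pos")], ann,
  simulate_expression_counts(ann, truth, cfg),
  parental = "parental")
scr
#> Integrative promoter methylation / expression screen
#>   conditions: parental vs deriv1, deriv2, deriv3
#>   genes screened: 500  (promoter probes assigned: 1500)
#>   gates: RPKM > 3 (either condition), |log2FC| > 1, |Δβ| > 0.1
#>   candidates (hypermethylated, silenced): 24
#>   top candidates:
#>    gene_id delta_beta log2_ratio n_promoter_probes
#>  gene00231  0.4063607  -1.575898                 3
#>  gene00380  0.4052251  -1.814865                 3
#>  gene00124  0.3959347  -2.489354                 3
#>  gene00500  0.3950093  -3.116902                 3
#>  gene00148  0.3937051  -1.679215                 3

all(candidates(scr) %in% truth$gene_id[truth$planted])
#> [1] TRUE
```

Every reported candidate is one of the 25 genes the simulation silenced
(24/25 recovered here; the Δβ column sits near the planted +0.4 shift,
slightly attenuated by the +100 offset in the β denominator, and the
log₂ ratios scatter around the planted −2). `plot(scr)` draws the
quadrant scatter with the threshold guide lines.

The survival comparison on a simulated cohort whose high-marker group
carries twice the hazard:

```r
surv <- simulate_survival(200, group_hazard_ratio = 2, censor_rate = 0.2,
                          config = cfg)
res <- survival_screen(surv[c("time", "event", "marker")])
res$test
#> Two-group log-rank test (chisq p-value)
#>  group observed expected
#>    low       84   120.26
#>   high       88    51.74
#> chi-square = 40.7135 (1 df), p = 1.763e-10
```

The high group suffers 88 events where 51.7 were expected under equal
hazards, and the log-rank test rejects decisively.

A file-based pipeline (`run_simulation()` / `run_screen()`, YAML
configuration) and a thin command-line front end
(`inst/cli/methylscreen` with `simulate`, `screen`, `bisulfite`,
`survival` and `all` subcommands) wrap the same functions.

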