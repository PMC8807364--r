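---
title: "Models and design choices behind the methylscreen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the methylscreen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscreen)
```

# Scope

`methylscreen` implements an integrative screen for promoter
hypermethylation coupled to transcriptional silencing between a parental
cell line and derivative lines, together with the two analyses that
typically accompany such a screen: clone bisulfite-sequencing
methylation calling and a median-split Kaplan–Meier / log-rank survival
comparison. This vignette records the models, the tunable parameters,
and the choices made where the design was genuinely open.

# The methylation model

## β-values

A probe's methylation level is estimated as

$$\beta = \frac{M}{M + U + 100}$$

with $M$, $U \ge 0$ the methylated- and unmethylated-allele intensities
and a fixed offset of 100 intensity units (configurable via
`beta_offset`) stabilising the ratio at low total intensity. Two
consequences are worth keeping in mind:

* $\beta < 1$ strictly, and $\beta = 0$ only when $M = 0$;
* $\beta$ underestimates the true methylated fraction by the factor
  $S/(S+100)$, where $S = M + U$ is the probe's total intensity. At
  $S \approx 2000$ this is a ~5 % multiplicative attenuation. Because
  the attenuation applies to every condition of the same probe, the
  *difference* Δβ is attenuated by the same factor but never inflated,
  so threshold-based screening is conservative, not anticonservative.

Inputs are assumed to be normalized intensities; color-bias correction
and interarray normalization belong upstream, and type-I/type-II probe
chemistry is not modelled.

## Replicates and promoter windows

Duplicate arrays per condition are combined by the arithmetic mean of
replicate β values — simple, order-invariant, and the natural choice
when each condition carries exactly two arrays. Single-replicate
conditions pass through unchanged.

The promoter is the 500 bp (configurable, `upstream_bp`) immediately 5′
of the TSS. All coordinates are 0-based and windows half-open: a
+ strand gene with TSS $t$ owns $[t-500, t)$; a − strand gene owns
$[t+1, t+501)$. The TSS base itself is excluded on both strands, one
probe may serve several genes, and probes on chromosomes absent from the
annotation are left unassigned with a warning.

## Gene-level Δβ

Per probe, $\Delta\beta = \beta(\text{derivative}) -
\beta(\text{parental})$, oriented so hypermethylation in the derivative
lines is positive. With several derivative lines the per-probe value is
first averaged across lines (the methylation shift of interest is
expected in every derived line, so averaging only reduces noise). The
gene summary is the mean across the gene's promoter probes; the maximum
absolute per-probe value is carried alongside so a "strongest probe"
convention can be screened without recomputation.

# The expression model

RPKM is $c \cdot 10^9 / (L \cdot N)$ for $c$ reads on $L$ bp of total
exon in a library of $N$ mapped reads. When per-sample totals are not
supplied, column sums of the count table stand in for $N$. Fold-changes
are $\log_2$ ratios after flooring both RPKM values at 0.01
(`rpkm_floor`): a fully silenced gene then shows a large, finite,
bounded fold-change instead of $-\infty$. Row z-scores (for heatmaps)
use the population standard deviation (denominator $n$); constant rows
become all-zero and are flagged rather than producing NaNs.

## The screen's gates

A gene is a **candidate** iff

1. RPKM > 3 in the parental or the derivative condition (strict),
2. $|\log_2 \text{FC}| > 1$ (strict), and
3. $\Delta\beta > 0.1$ with $\log_2\text{FC} < -1$ (the
   hypermethylated-down quadrant).

Genes meeting gates 1–2 with $|\Delta\beta| > 0.1$ in any direction are
classified into four quadrants by the sign pair; everything else is
`not_significant`. Candidates are ranked by descending Δβ, with ties
broken by ascending log₂FC and then gene id, so output order is fully
deterministic. No pathway-level prioritisation is applied.

## Pooling several derivative lines

This was the one genuinely open choice where implementation overturned
the first-draft design. Two modes exist:

* `"mean"` — the derivative RPKM is the arithmetic mean across lines;
* `"any"` (default) — the line with the strongest fold-change against
  the parental supplies the gene's RPKM and log₂FC.

With a single RNA-seq sample per condition (the design this package
targets) and negative-binomial dispersion around 0.1, the log₂ ratio of
mean-pooled derivatives to the parental has a standard deviation near
0.55 *even for highly expressed genes* — dominated by the lone parental
replicate. A genuinely 4-fold-silenced gene then lands above the
two-fold gate roughly 5–8 % of the time, which measurably caps the
screen's sensitivity. Under `"any"`, a planted gene is missed only when
*every* derivative line misses the gate simultaneously (about 1 % under
the same noise), while false candidates stay rare because candidacy
still requires the promoter methylation shift, which expression noise
cannot produce. Both modes are exposed; the methylation summary is
unaffected and always pools derivatives by mean.

# Hierarchical clustering

Probe clustering is performed within each chromosome (average linkage on
Euclidean distances between per-condition β vectors); expression
clustering uses correlation distance $1-r$ on z-scored rows, with
constant rows placed at the maximal distance 2 from everything and 0
from each other. Both delegate to `stats::hclust`, whose merge order is
deterministic for a fixed input order; with continuous data, exact
distance ties have probability zero, and the identical-profile case
merges at height 0 first by construction.

# Bisulfite clone calling

Only the top (converted) strand is modelled: PCR of bisulfite-converted
DNA is strand-specific, and the reference amplicon is treated as the
converted-strand template. Clones are aligned to the reference with a
global affine-gap aligner whose scoring treats a reference C aligned to
a clone T as a full match (conversion is *expected*): match +1, mismatch
−1, first base of a gap −2, each further base −1. Alignments with fewer
than 70 % match-equivalent columns (`min_identity`) are rejected with a
reason. Traceback ties prefer the diagonal, then consuming the
reference, so the position map is reproducible.

At each CpG the clone base at the reference C calls the site: C →
methylated, T → unmethylated, anything else or a gap → ambiguous; the G
of the CpG is not used, matching standard lollipop practice. Per-clone
conversion efficiency is the fraction of *non-CpG* reference cytosines
read as T; clones below 0.95 (`min_conversion`) are flagged and excluded
from the per-sample fractions, which are computed over unambiguous calls
only. Non-CpG methylation is not modelled.

# Survival comparison

The median split sends markers strictly above the median to "high" and
everything else — ties included — to "low", keeping group sizes as equal
as the data allow and fully deterministic. The Kaplan–Meier estimator is
the standard product-limit form; subjects censored exactly at an event
time count as at risk at that time. The log-rank statistic accumulates
observed-minus-expected events over distinct event times with the
hypergeometric variance, skipping the variance term of single-subject
strata, and refers $(\sum O - \sum E)^2 / \sum V$ to $\chi^2_1$. A
label-permutation p-value is available for small samples where the
chi-square approximation is doubtful.

# What the synthetic data do and do not emulate

The generator reproduces the *design*: one parental condition, three
derivative conditions, duplicate arrays per condition, one RNA-seq
sample per condition, promoter probes (3 per gene) plus background
probes, bisulfite clones (10 per sample by default), and a survival
cohort whose hazard depends on the median-split marker group. Defaults:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes on 8 chromosomes, 10 kb grid spacing |
| `planted_fraction` | 0.05 | genes given both planted effects |
| `delta_beta_effect` | +0.4 | promoter β shift in derivatives |
| `log2fc_effect` | −2 | expression change (4-fold silencing) |
| `beta_noise_sd` | 0.05 | per-replicate noise, raw-β scale |
| `intensity_scale` | 2000 | mean total intensity $S$ per probe |
| `count_library_size` | 2 × 10⁷ | reads per RNA-seq sample |
| `count_dispersion` | 0.1 | NB dispersion (variance $\mu + 0.1\mu^2$) |
| `conversion_rate` | 0.99 | bisulfite conversion probability |

Baseline promoter β is Beta(0.5, 5) (CpG-island-like, mostly
unmethylated) and background β is Beta(5, 5); neither distribution is an
estimate of any particular array, they simply make a +0.4 shift
detectable but nontrivial. Noise is applied on the raw β scale with
clipping to [0, 0.99]; intensities are back-computed as $M = \beta S$,
$U = (1-\beta)S$ with a per-probe $S \sim N(2000, 200)$ truncated at
200. $S$ is drawn once per probe and shared across samples — probes have
a characteristic brightness — so the offset attenuation cancels exactly
in null comparisons. Expression baselines are log-normal
($\log_2 \text{RPKM} \sim N(3, 2)$), shared between the ground-truth and
count generators. Planted genes are drawn only among genes with baseline
RPKM ≥ 12: a silencing screen can only detect genes expressed in the
parental line (a gene at RPKM ≤ 3 can never pass the "RPKM > 3 in either
condition" gate after 4-fold knockdown), so planting effects on silent
genes would test nothing but the gate's definition.

Not emulated: IDAT-level artifacts, probe cross-hybridization,
type-I/type-II chemistry differences, batch effects, copy-number
confounding, positional correlation of methylation along a promoter,
and any coupling between methylation noise and expression noise.
Passing the recovery tests therefore demonstrates that the pipeline's
logic is correct and its thresholds behave as specified under the
declared noise model — not that the thresholds are optimal for any
particular real data set.

Every generator is a pure function of its inputs and the configured
seed (each derives an independent stream with a fixed offset from
`seed`), so identical configurations give bit-identical outputs; the
file pipeline additionally writes a run manifest with an MD5 hash of the
configuration.

# Validation problem sizes

The shipped validation suite exercises: the default 2000-gene
configuration over 20 seeds for candidate-list sensitivity and
false-discovery proportion against ground truth; a 1000-gene null
configuration (all effects zero) over 20 seeds; 50 clones × 10 CpG sites
for the bisulfite round trip, with pooled-fraction checks against
binomial intervals; 1000 replicates of $n = 200$ cohorts for log-rank
type-I error and 200 replicates of $n = 500$ at hazard ratio 3 for
power; and 100 random tables each for the Kaplan–Meier/ECDF and
β-formula exactness checks. `scripts/acceptance.R` recomputes all of
these from a single `--seed`.

# Known limitations

* The screen has no per-gene test statistic or p-value — by design,
  since the targeted study layout has one RNA-seq sample per condition;
  the thresholds are descriptive gates, not hypothesis tests.
* Gene-level Δβ averages probes, so a single strongly shifted probe in
  a wide promoter can be diluted; the reported `max_abs_delta_beta`
  column is the escape hatch.
* The bisulfite aligner is quadratic in sequence length and intended
  for amplicon-scale references (hundreds of bp), not genome-scale
  mapping.
* The log-rank implementation handles exactly two groups; trend tests
  and Cox-style adjustment are out of scope.
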