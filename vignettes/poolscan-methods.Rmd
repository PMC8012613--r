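---
title: "Methods: the poolscan association and bioassay pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the poolscan association and bioassay pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The study design and the statistical model

`poolscan` analyses pool-seq data from a two-strain contrast: a resistant
colony (`R`) kept under periodic insecticide selection and a related
susceptible colony (`S`) released from selection, each sequenced as two
replicate pooled libraries of 22 diploid females. Read counts at a
biallelic site estimate the pool's allele frequency, so a 2×2 contingency
table of (ref, alt) counts by strain tests whether the strains'
frequencies differ at that site.

The per-site statistic is the Pearson χ² on that table with 1 degree of
freedom and no continuity correction. We deliberately avoid the Yates
correction: at the mandated minimum coverage of 22 reads per library the
expected cell counts are large, and the correction would only bias scores
downward. For genuinely small tables a Fisher-exact fallback can be
switched on (`filter_params(fisher_min_expected = ...)`), but it is off by
default. The association score is −log₁₀(p), with p floored at 1e−300 so
that scores remain finite for astronomically small p values.

Three filters precede any aggregation, in this order:

1. **Coverage.** A site must reach a total depth of `min_coverage` (default
   22, chosen to match the 22 diploid genomes per pool) in *every* library.
2. **Replicate consistency.** Within each strain, a Pearson χ² between the
   two replicate libraries' (ref, alt) counts; sites with replicate
   p < 0.10 in either strain are dropped (p exactly at the cutoff is
   kept). Under a calibrated null this filter intentionally sacrifices 19%
   of sites (2 × 10%, minus the overlap) to remove library artefacts.
3. **Strain test + BH.** The strain χ² is computed on counts summed over a
   strain's replicates, and the Benjamini–Hochberg step-up adjustment is
   applied across the passing sites' p values with cutoff 0.001. BH is
   applied at the site level because p values exist only per site; a gene
   is flagged BH-significant when at least one of its passing sites is.

Passing sites are assigned to genes by interval overlap (a site inside two
overlapping genes contributes to both — a conservative duplication that is
reported rather than resolved) and aggregated into the gene-wise score

$$ S_g = \frac{\sum_i w_i\,(-\log_{10} p_i)}{\sum_i w_i}, $$

with weights $w_i$ equal to the site's total cross-library depth. Depth is
the natural precision weight for a count-based statistic; uniform weights
are available (`weighting = "uniform"`) since the choice of weights in a
"weighted average" is a modelling decision, not a mathematical necessity.
Genes are called at $S_g \ge 15$ and ranked; genes with no passing site are
omitted and listed in a skipped-genes report. Pre-miRNA hairpin intervals
are scanned separately: every passing site inside a hairpin with score
strictly greater than 3.0 is reported, together with each hairpin's mean
depth and the fraction of bases covered at `min_coverage` in all libraries
("sufficient coverage" is defined as ≥ 80% of bases covered; the threshold
is configurable because no canonical value exists).

## The simulator: what it emulates and what it does not

`simulate_pool_readcounts()` generates data with the statistical structure
the scan assumes, plus known ground truth. Sampling is two-stage by
default:

* **pool stage** — each library's allele frequency is drawn
  $\mathrm{Bin}(2 \times 22, f_\text{strain})/44$, the sampling induced by
  pooling 22 individuals before library preparation;
* **read stage** — alt reads are drawn binomially at the realised pool
  frequency, with per-site, per-library depth from a negative binomial
  (`depth_mean`, dispersion `size = depth_dispersion`), matching
  capture-coverage heterogeneity without extra parameters.

Two-stage sampling matters because it makes read-level frequencies
overdispersed relative to binomial read sampling: the between-replicate χ²
is inflated by roughly $1 + \text{depth}/44$, so at depth 200 the replicate
filter keeps only about a quarter of sites, and the strain test is
similarly anti-conservative. Both effects are asserted as property tests.
Because of them, *calibration and recovery checks run in the simulator's
single-stage mode* (`sampling = "single_stage"`), where reads are drawn
directly from the strain frequency and the site test is exactly calibrated;
the two-stage mode documents the behaviour of the filters under realistic
pooling. The default fixture bundle written by `write_fixture_bundle()`
uses single-stage sampling for the same reason: it is the configuration in
which the planted structure (four signal genes and one hairpin SNP at
chr1:50888906, the mir-33 position) is recovered deterministically under
the bundle's fixed seed (20210331).

Selected sites take strain frequencies shifted symmetrically around the
ancestral value and re-anchored at the [0, 1] boundary, so the realised
difference is exactly `delta_f`. Defaults: 200 genes × 5 sites, depth mean
100× (dispersion 10), ancestral frequencies uniform on (0.05, 0.95), 20
selected sites with `delta_f = 0.5` — deep-coverage exome-capture scales at
desk size. The simulator does **not** emulate raw reads, alignment
artefacts, base-calling error, indels, or linkage between sites; passing
tests therefore demonstrate correctness of the statistics under the
two-stage sampling model, not robustness to upstream bioinformatic error.

## Bioassay and molecular-assay statistics

**Probit LC50.** `fit_probit_lc50()` fits death probability
$\Phi(\alpha + \beta \log_{10} d)$ by maximum likelihood; the LC50 is
$10^{-\alpha/\beta}$. The 95% CI is the delta method on
$\log_{10}\mathrm{LC50}$, exponentiated; Fieller's interval is available
(`ci_method = "fieller"`) and agrees to first order on well-behaved data.
The fit is declared non-identifiable (not an error) when every dose shows
complete mortality or survival, and non-converged when β ≤ 0. The
simulator's bioassay design mirrors the standard CDC bottle assay: 20
insects per bottle, 3 replicate bottles, five doses in a two-fold series
spanning the LC50, slope 3 per log₁₀ dose — a typical permethrin
dose-response steepness. Its noise-free mode rounds expected deaths half-up
so fixtures are deterministic and dose = LC50 yields exactly 50% mortality.
Monte-Carlo checks at both strain scales (≈2.4 and ≈25 µg per bottle) show
the nominal-95% intervals cover the truth in well over 90% of runs.

**Other tests.** Fisher's exact 2×2 p sums hypergeometric probabilities of
tables no more probable than observed (relative tie tolerance 1e−7, the
convention shared with `stats::fisher.test`, which is the cross-check, not
the implementation). One-way ANOVA uses the classical pooled-variance F;
knockdown comparisons apply it to replicate-level knockdown proportions at
the 60-minute endpoint (the end of the standard 1-hour time course; the
endpoint is a parameter). Genotype summaries report per-locus class
proportions, resistant-allele frequencies (hom + het/2), and composite
multi-locus classes over fully genotyped individuals, excluding (and
counting) individuals with missing calls.

**ΔΔCt.** Technical replicates are averaged per sample and gene; ΔCt is the
target Ct minus the arithmetic mean of the reference-gene Cts (ACTIN and
RPS7 in the bundled fixtures) — equivalent to a geometric mean of
quantities at equal efficiency; ΔΔCt subtracts the calibrator group's mean
ΔCt; RQ = 2^(−ΔΔCt). Group summaries exponentiate the group-mean ΔΔCt, so
the calibrator group's RQ is exactly 1 and the whole quantity is invariant
to adding a constant to every Ct.

## Enrichment

`enrich_categories()` computes the one-tailed cumulative hypergeometric
probability $P(X \ge k)$ of observing $k$ category members in a selected
set of size $n$ drawn from a background of $N$ genes containing $K$
members, via `phyper` (stable in log space at genome scale). The six
tested groups pool the curated oxidation/reduction and mitochondrial
labels into one Redox/MIT group; the significance threshold defaults to
0.007, kept as a stated constant rather than derived, because the implied
category count (0.05/7 ≈ 0.0071 vs 0.05/6 ≈ 0.0083) is ambiguous.
Percentage breakdowns are reported to one decimal and, after rounding, sum
to within [99, 101].

## Numerical and interface decisions

* Coordinates are 1-based inclusive everywhere internally; BED's 0-based
  half-open convention is converted only at the file boundary, so SNP
  positions match their 1-based names.
* Multiallelic sites keep the stated reference base plus the highest-count
  non-reference allele (pooled across libraries) and are flagged; the χ²
  model is 2×2 and orientation by the stated reference keeps scores
  invariant to allele labelling.
* Base qualities are treated as an upstream concern of the readcount
  producer; the parser does not re-filter on quality.
* `run_association()` requires exactly two replicate libraries per strain —
  the design the replicate filter is defined for.
* An allele absent from both strains gives χ² = 0, p = 1 by convention
  (no differentiation), never an error; a strain with zero reads is a
  coverage failure, not a test result.
* All simulators are seeded and bit-reproducible; `run_pipeline()` writes a
  provenance header (version, seed, config hash) into every output and
  produces byte-identical summaries for identical config + seed.

## Problem sizes used in the checks

The verification suite runs at desk scale, chosen so each property has
clear statistical resolution: oracle agreement on 1,000 random instances
per statistic; null calibration on a 10,000-site single-stage simulation at
depth 100 (rejection rate within 0.05 ± 0.007) and 20 seeds × 200 null
genes for gene-level specificity; planted-gene recovery (3 sites at
frequencies 0.1 vs 0.9, depth 200) over 20 seeds; and 200 Monte-Carlo
probit fits per strain scale for CI coverage.

## Known limitations

* The replicate-consistency filter is a hard cutoff, not a shrinkage
  estimator; under deep coverage of small pools it discards a substantial
  fraction of perfectly consistent sites (see above), which is faithful to
  the published procedure but statistically wasteful.
* Gene scores average site scores, not site evidence; long genes with many
  moderate sites can outrank short genes with one extreme site or vice
  versa depending on depth weights. Both weightings are provided.
* The simulator draws sites independently; linkage, selective sweeps'
  haplotype structure, and reference bias are out of scope.
* No natural-mortality (Abbott) correction is applied in the probit fit;
  control mortality is assumed negligible.
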