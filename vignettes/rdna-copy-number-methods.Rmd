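---
title: "Methods: rDNA copy number and methylation quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rDNA copy number and methylation quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocn)
```

# Scope and model

`ribocn` measures two per-sample quantities for the multicopy 47S rDNA
locus — copy number (CN) and mean CpG methylation — from
bisulfite-sequencing-derived inputs, and provides the statistics used
to relate them to body-mass phenotypes. This vignette records the
models, parameter choices and numerical decisions; it states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Reference engineering

Reads from a tandem array map poorly to a linear single-unit
reference in two ways: reads spanning the unit's end/start junction are
split (depressing coverage near the TSS, which sits close to the
junction), and rDNA-like pseudocopies scattered through the assembly
siphon off true rDNA reads. The package addresses both:

* **Looped unit.** The unit is rotated at a breakpoint inside the
  intergenic spacer so the junction moves away from the regulatory
  region. The breakpoint is configuration — by default derived as
  `(tss - 2120) mod unit_length`, i.e. 2120 bases upstream of the TSS,
  the midpoint of the IGS repetitive element nearest the unit's 3' end
  in the human unit annotation. The rotation is the bijection
  `looped = (native - breakpoint) mod L`; the package does not re-derive
  repeat annotations, it takes the offset (or an explicit breakpoint) as
  input. An annotated region that straddles the junction is represented
  as **two looped intervals** rather than wrapped coordinates, keeping
  downstream interval arithmetic simple; all depth and methylation
  functions accept split regions and average over their union.
* **Masking.** Pseudocopy intervals (BED, 0-based half-open) are
  hard-masked to `N` without changing contig lengths, and the looped
  unit is appended as one extra contig. For the rat, where the
  consensus covers only 18S-28S, the bare 18S subsequence (unit
  positions 1-1874, 1-based inclusive, i.e. `[0, 1874)` internally) is
  appended instead — there is no spacer to loop through.
* **Single-copy exome.** The depth denominator must itself be
  single-copy. Exons from sex chromosomes (dosage differs between
  sexes) and exons under 300 bases are removed; then, while any
  retained pair shares k-mers above a Jaccard threshold (default
  k = 31, threshold 0.5), the most similar offending pair loses its
  shorter member (ties: the lexicographically later identifier). The
  k-mer screen is this package's similarity primitive — it needs no
  external aligner binary, is configurable, and every removal is logged
  with its partner so the choice of which member to drop is auditable.
  Whether both members of a similar pair should instead be removed was
  an open design point; removing one retains more normalisation
  territory and the log preserves the evidence either way.

All coordinates are 0-based half-open internally; BED input is taken
as-is, bismark coverage positions and 1-based inclusive quotes are
converted at the boundary (`subseq_1based()`, `read_cpg_calls()`).

## Copy-number estimators

* **WGBS absolute:** `CN = 2 × d̄_18S / d̄_exome` with `d̄` the per-base
  arithmetic mean of unique-read depth over the region (pileup
  semantics, matching `samtools depth`), not a per-read count.
  "Unique" is operationalised as: not secondary (0x100), not
  supplementary (0x800), not unmapped (0x4), plus an optional mapping
  quality floor; for per-base depth-table input, uniqueness is assumed
  enforced upstream. The 18S interval is taken from the remapped
  looped annotation (both parts if split). Zero exome depth is an
  explicit error, never an infinite CN. All retained exons enter the
  denominator; no coverage trimming and no GC correction are applied
  (neither is part of the source procedure).
* **RRBS relative:** the rDNA alignment fraction
  `reads_rDNA / total_alignments`. This is a *relative* CN: the two
  estimators live in different units and are only ever compared by
  rank (`cross_validate()` reports Spearman primarily, Pearson
  alongside).
* **ddPCR:** `ploidy_ref × c_target / c_reference`; wells with Lambda
  (copies per partition) ≥ 1.6 violate the Poisson assumption of
  digital quantification and are excluded with a recorded reason.
* **Down-sampling stability:** reads are split into 10 equal
  partitions by seeded shuffle + round-robin (sizes differ by ≤ 1,
  partition exhaustive and disjoint — the equal-split semantics of
  `seqkit split` at desk scale); a fraction `f` estimate merges
  `round(10·f)` randomly chosen partitions. Identical seeds give
  identical partitions and estimates.

## Methylation aggregation

Per-CpG methylated/unmethylated counts (bismark coverage dialect,
destranded; the percent column is ignored in favour of counts) are
aggregated per region. Two weightings are offered: the default
**coverage weighting** `ΣM / Σ(M+U)` (the regional accounting used by
methylKit-style tools) and an unweighted per-CpG mean. On the rDNA
contig only CpGs covered by ≥ 50 reads are used — the multicopy locus
has hundreds-fold coverage, so this filters mapping artefacts without
losing CpGs; elsewhere every CpG is analysed (`min_coverage = 1`) and
feature-class coverage is the mean of `M+U` over contained CpGs. The
rDNA summary window is promoter (default 1000 bp upstream of the TSS,
upstream-only) plus the transcribed region; genome promoters are ±1 kb
of the TSS — the two windows are deliberately separate settings because
their definitions differ. A region where no CpG survives the filter
returns an explicit empty summary, never a silent 0.

**Active CN** is `CN × (1 − m̄)`. The exact adjustment formula behind
"adjusting for the silencing of the methylated copies" is not
published; the proportional discount is this package's explicit choice,
recorded in the output's `formula` field, and is the simplest rule with
the right limits (`m̄ = 0` leaves CN unchanged, `m̄ = 1` silences all
copies) and monotonicity in both arguments.

## Sample QC

The exclusion rules are qualitative in origin ("extremely high or low
uniquely mapped reads, poor mapping efficiency, poor bisulfite
conversion, extreme total-methylation outliers in RRBS"), so the
thresholds are explicit policy: read counts beyond median ± 3 MAD
(robust, because the rule targets outliers), mapping efficiency below
0.6, non-CpG methylation above 0.02 (a conversion-failure proxy), and
for RRBS total CpG methylation beyond mean ± 3 SD (classical moments,
mirroring the 3-SD language used for other pruning steps). Every
verdict lists all failed rules and the applied thresholds travel with
the output. Concordance with the source study's actual excluded-sample
lists cannot be checked without its supplementary files and is not
asserted.

## Cohort statistics

Rank statistics implement the average-rank tie convention and carry
**exact small-sample branches**: Spearman p by full enumeration of the
`n!` permutations for n ≤ 8, Mann-Whitney by enumeration of all group
assignments for combined n ≤ 12, Wilcoxon signed-rank by all `2^n` sign
flips for ≤ 12 informative pairs (zero differences dropped; all-zero
input is an explicit "no difference detectable" outcome, which the
twin analysis reports rather than fabricating a p-value). Above the
crossover the t-approximation (Spearman) or the tie-corrected normal
approximation with continuity correction (via `stats::wilcox.test`)
takes over; branch names are recorded in every result. The crossover
sizes are fixed constants — the original analyses used Prism/R
defaults, which are unstated, so fixed documented constants are the
reproducible choice.

Age adjustment is OLS residualisation (residuals of value ~ age, plus
the cohort mean); stratification was the alternative reading and
residualisation is labelled in the function contract. Twin pairs are
ordered heavier/leaner by BMI; within-pair tests are two-sided paired
Wilcoxon and the `|ΔCN|` contrasts vs age and BMI discordance are
Spearman.

The growth model is the exponential plateau
`W(t) = YM − (YM − Y0)·e^{−kt}` fitted by Levenberg-Marquardt least
squares (`minpack.lm::nlsLM`) over a deterministic multi-start grid
(`Y0` start at the first observation; `YM` at 1.1/1.5/2 × the maximum;
`k` in 0.05/0.2/0.5/1 per week), best SSE winning, ties to the smallest
`k` — deterministic without a seed. The fit is parameterised on
`(YM, span = YM − Y0, k)` with positivity constraints on `k` and
`span` only: `Y0` is the value extrapolated to `t = 0` and may
legitimately be negative when observations start at week 8. Per-week
growth correlations are reported raw (the primary scale in the source
material) with a Holm-adjusted column alongside.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated. Defaults are the study conditions where stated, and a single
realistic choice elsewhere:

| parameter | default | origin |
|---|---|---|
| true CN law | Uniform(150, 600) copies | stated cohort range |
| exome depth | 14× per base, Poisson | stated coverage |
| CN-methylation Spearman ρ | 0.74 at n = 63 | printed correlation, used as a generative setting |
| methylation marginal | Beta(mean 0.25, concentration 25) | typical rDNA promoter/unit methylation |
| RRBS allocation | Binomial(5×10⁶, CN × 1.2×10⁻⁵) | stated library size; rDNA fraction ~0.5% at CN 400 |
| BMI slope on CN | r = −0.18 (continuous) / 0.8 SD group shift at n = 31/32 | printed statistics |
| twins | 24 pairs, shared true CN, 3 kg/m² discordance, 3% CN measurement CV | stated design |
| growth | 44 animals, weeks 8-19, plateau rate k = 0.3/week, gain reduced 12 g per CN SD, residual gain SD 25 g, 3% observation noise | stated design; effect sized so the latent gain-CN correlation is near the printed −0.4 |

The CN-methylation coupling uses a Gaussian copula
(`ρ_z = 2 sin(πρ_s/6)`, exact for continuous marginals) with uniform
and Beta marginals; a target above 0.99 is rejected as infeasible.
Growth separates the week-8 weight (independent of CN) from the
window gain (CN-dependent), so the body-mass association is absent at
the first observation and emerges as gain accrues — the qualitative
late-emergence pattern; both are expressible as one exponential-plateau
curve per animal. Per-base depth is simulated as independent Poisson
rather than read-level; a separate read-record generator
(`simulate_reads()`) exists for the down-sampling analysis, where read
identity matters.

**Problem sizes.** Cohort depth simulations use a 50 kb exome stand-in
and the 1874-base 18S interval: at 14× this already puts the Monte
Carlo error of both depth means well under 1%, so the estimator's
behaviour is measured, not the stand-in's size. The read-level
generator uses a 600 kb exome with 100-base reads (~137,000 reads per
library), sized so that hypergeometric subsampling noise at the 10%
fraction stays a comfortable margin inside the 5% stability band.
Replicated power studies (200 replicates) reduce the per-replicate
exome to 4 kb and emit only the layers they read (`emit=` in
`sim_config()`), which leaves per-sample CN estimation error far below
every effect being measured.

**What passing tests do and do not show.** The generator draws
independent Poisson depths, destranded binomial CpG counts around a
per-sample Beta mean, and noise-free group labels. Real libraries have
GC- and fragment-length-dependent coverage, correlated errors along
reads, incomplete bisulfite conversion, mapping ambiguity that varies
along the unit, and batch structure — none of which are emulated. Tests
against this generator therefore validate the *estimators and
statistics* (formulas, filters, invariances, power at stated effect
sizes), not robustness to those real-data artefacts; the headline
numbers printed in the source material come from cohorts that are not
redistributable and are not reproduced here.

# Known limitations

* Absolute CN inherits any bias in the exome depth denominator;
  between-cohort absolute comparisons need consistent references.
* The RRBS estimator is relative by construction and is never
  calibrated to copies.
* The k-mer Jaccard similarity screen is blunter than an ungapped
  aligner for diverged duplicates; its threshold is exposed rather
  than tuned.
* `CN × (1 − m̄)` treats methylation as proportional silencing; any
  nonlinear silencing relationship would need a different adjustment.
* Haplotype-resolved CN and aligner/bisulfite-caller behaviour are out
  of scope: the package consumes alignment summaries and CpG calls, it
  does not produce them.
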