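---
title: "Integrated tumor-only panel profiling: models and methods"
author: "PanelProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated tumor-only panel profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PanelProfiler)
```

# Scope

PanelProfiler implements an integrated analysis for tumor-only targeted
sequencing panels of the kind used in head and neck squamous cell carcinoma
profiling: copy-number estimation from on-target coverage, allelic-imbalance
and copy-neutral LOH detection from heterozygous-SNP VAF deviations, somatic
variant filtering, gene-level synthesis into biallelic-inactivation and
actionability calls, and exact-test comparison of per-gene mutation
frequencies between cohorts.  Everything upstream of these stages — read
trimming, alignment, variant calling — is out of scope; the package consumes
variant tables and per-bin coverage.

A first-class synthetic-cohort simulator with known ground truth ships with
the package so that every stage can be validated against planted truth
rather than against another tool's output.

# The admixture model

All allele-fraction reasoning rests on one model.  A tumor sample is a
mixture of a fraction $p$ (purity) of neoplastic cells and $1-p$ diploid
normal cells.  At a locus inside a segment with total copy number $C_T$ in
tumor cells, of which $m$ copies carry the variant allele, and with $g \in
\{0, 1\}$ variant copies in the normal genome (0 somatic, 1 germline
heterozygous), the expected VAF is

$$E[\mathrm{VAF}] \;=\; \frac{p\,m + (1-p)\,g}{p\,C_T + (1-p)\,2},$$

implemented in `expectedVaf()`.  Its inversion,
$\hat m = \mathrm{VAF}\,(p\,C_T + 2(1-p))/p$ (`multiplicityEstimate()`),
supports the amplified-mutant-allele call.  The expected coverage ratio of
the same segment is $(p\,C_T + (1-p)2)/2$, whose $\log_2$ is the quantity
the CNV stage segments.

Two consequences shape the LOH stage.  A germline heterozygote on a segment
with minor copy number $M$ has $m \in \{M,\, C_T - M\}$ depending on
haplotype, so its VAF deviates from 0.5 symmetrically; for copy-neutral LOH
($C_T = 2, M = 0$) the expected deviation $|\mathrm{VAF} - 0.5|$ equals
$p/2$.  The 0.15 segment-deviation threshold therefore implies a detection
floor near $p = 0.3$: events in purer samples are detected almost surely,
events at $p \le 0.2$ almost never.  This threshold behavior is verified by
simulation in the test suite.

# Copy-number stage

`buildReference()` models panel-specific coverage bias as the per-bin median
of total-depth-normalized normal samples (spread as MAD).  Bins whose median
raw depth falls below 10 are flagged unreliable and excluded; no explicit
GC or mappability correction is applied, because the per-bin reference
median already absorbs stable target-level bias and the simulator plants
none.  `log2Ratios()` divides a normalized sample by the reference location,
takes $\log_2$, and median-centers, so global scaling cancels.

Segmentation is circular binary segmentation (`cbsSegment()`), re-implemented
in compiled code:

* the candidate split is the arc maximizing the pooled-variance two-sample
  t statistic against its complement, subject to every resulting piece
  holding at least `minBins = 3` elements;
* a split is accepted when its permutation p-value is below
  `alpha = 0.01`, with `nPerm = 1000` permutations and early termination
  once significance is impossible;
* ties break to the leftmost arc, and the permutation stream uses its own
  deterministic generator seeded from the `seed` argument, so results are
  reproducible and independent of R's RNG state;
* an arc that leaves both sides exactly constant (infinite t) is accepted
  without a permutation test.  Such arcs arise only in the noise-free
  limit, where the split is certain; skipping the permutation test there
  makes noise-free recovery deterministic instead of hostage to the
  discrete permutation null of short two-valued series.

Copy numbers come from inverting the expected ratio:
$\hat C = \mathrm{round}(2 \cdot 2^{\bar\ell})$ without purity, or
$\mathrm{round}((2 \cdot 2^{\bar\ell} - 2(1-p))/p)$ clipped at 0 with
purity, rounding exact halves away from zero (a stated, testable
convention).  States follow the clinical convention: 0 deep deletion, 1
shallow deletion, 2 neutral, 3–4 gain, ≥ 5 amplification (configurable via
`copyStateThresholds()`).  `recenterSegments(shift = "auto")` subtracts the
bin-weighted modal segment mean — segment means clustered within 0.05 log2
units, the heaviest cluster defining the mode — which restores a drifted
baseline and is idempotent.  Coverage ratios are floored at $\log_2$ ratio
−8 so homozygous deletions stay finite.

# Allelic imbalance and LOH

`selectInformative()` keeps variants with population allele frequency
strictly inside (0.0001, 0.95), depth strictly above 30, and observed VAF
strictly inside the homozygous-exclusion cutoffs (0.05, 0.95).  The
population-frequency window keeps common polymorphisms (informative
heterozygous markers) while discarding variants too rare to be reliably
germline; the depth floor bounds VAF noise.  The homozygosity cutoffs are a
symmetric, configurable surrogate for "exclusion of homozygous variants" —
no published value exists, so the default is chosen to be testable and is
exposed in configuration.

Deviations $|\mathrm{VAF} - 0.5|$ are segmented per chromosome **on the
variant index**, not genomic position: panel gaps of megabase scale would
otherwise dominate the arc statistics.  A segment is imbalanced when its
mean deviation reaches 0.15 (the median is available as a configuration
alternative; the mean is the default segment statistic).  With matched
normals, `pairedShift()` adds per-variant shifts $|v_T - v_N|$ over loci
heterozygous in the normal and marks segments whose mean shift reaches the
same 0.15 (no independent published value exists for the paired threshold,
so it mirrors the tumor-only one).  Paired mode only adds support flags; it
never changes imbalance calls.

`classifyLoh()` intersects imbalanced segments with copy-number segments
(bin-weighted majority on overlap): copy number 2 → copy-neutral LOH, ≤ 1 →
LOH through deletion, ≥ 3 → imbalanced gain.  At gene level
(`geneLohMechanism()`) the mechanism is re-derived from the gene's own
majority copy number, because a deviation segment can legitimately span a
CN-LOH gene and a deleted neighbor — their deviation signals are
indistinguishable, and only coverage separates them.

Sex chromosomes are excluded from the default panel: in a heavily male
cohort, hemizygous X produces constitutive apparent imbalance that the
model does not attempt to interpret.

# Variant filtering and integration

`filterCommon()` is a rule-based surrogate for manual curation: population
AF ≤ 0.001, depth ≥ 20, ≥ 4 alt reads, panel-of-normals occurrence ≤ 1
(all configurable; the published analyses name their databases but not
their cutoffs, so these are conventional targeted-panel defaults).  In
paired mode, variants present in the matched normal are removed — the
somatic definition.  `classifyPathogenicity()` applies a fixed precedence:
explicit predictor class if present; else truncating consequence in a tumor
suppressor → pathogenic; hotspot → pathogenic; silent → benign; otherwise
VUS.  Predictor scores themselves are consumed as an optional input label,
never recomputed.

`integrateGeneSample()` resolves each (gene, sample) to one mechanism label
by strict priority: deep deletion; ≥ 2 non-benign mutations; mutation +
(shallow deletion or deletion-LOH); mutation + CN-LOH; mutation with
estimated multiplicity ≥ 1.5 at copy number ≥ 3 (amplified mutant allele);
amplification without mutation; single mutation; none.  The first five
labels are biallelic.  The multiplicity threshold 1.5 is the midpoint
between one and two mutant copies — no published criterion exists for the
"putative amplification of the mutated allele", so the cutoff is explicit
and configurable, and when purity is unknown the estimate uses purity 1 and
the call is marked putative.  A mutation plus shallow deletion is accepted
as biallelic with either coverage evidence (copy state) or allelic evidence
(deletion-LOH); requiring both is stricter than the published description
supports.

# Actionability

`classifyActionable()` encodes a strict reporting policy: pathogenic or
hotspot mutations qualify; amplifications only from 5 total copies
(equivalently, at least 3 additional copies — the two published phrasings
are consistent and treated as one rule); deep deletions qualify; shallow
deletions without a second hit are eliminated, as are VUS-only records.
The gene→pathway map (`defaultPathwayMap()`) is editable configuration
seeded from the genes the analysis names; the published grouping is
narrative, not tabulated, so the map makes the grouping explicit.

# Cohort comparison

`compareCohorts()` performs the per-gene two-cohort mutation-frequency
comparison: the two-sided exact test by the probability-mass rule (sum of
hypergeometric probabilities of tables no more probable than the observed,
with the conventional $1 + 10^{-7}$ tie tolerance), the conditional
maximum-likelihood odds ratio (the $\psi$ with conditional expectation
equal to the observed cell, found by root-finding on the noncentral
hypergeometric mean), and the exact CI by inverting the one-sided tail
tests at $(1-\mathrm{level})/2$ each.  Zero cells give OR 0 (or $\infty$)
and CI endpoints 0/$\infty$, matching the reporting convention for genes
absent from one cohort.  A sample counts as mutated only through
small-scale mutations — copy-number-only labels never count, and CNV
frequency comparison is deliberately not attempted.  Per-gene denominators
may differ, accommodating genes unsequenced in part of a source cohort.
p-values are Benjamini–Hochberg adjusted.

# The simulator

`generateCohort()` emulates the study conditions the analysis assumes: 48
samples, 13 with matched normals, mean on-target depth 150, 400 bp coverage
bins, purity uniform on 0.6–0.9, per-bin Gaussian log2-ratio noise with SD
0.15, and negative-binomial depth overdispersion ($\phi = 0.05$, i.e.
variance $\mu + \phi\mu^2$ — typical capture-data overdispersion).  The
default panel places 24 recurrently altered head-and-neck genes on their
true chromosomes at synthetic coordinates, one 16 kb target each.  Germline
heterozygous SNPs arrive as a homogeneous Poisson process at 1.5/kb with
population AFs drawn from a mixture (80% common, 10% below $10^{-4}$, 10%
above 0.95) so the informativeness filter sees both passing and failing
variants.  Driver events per gene follow an editable probability table
(`defaultDriverTable()`): tumor suppressors receive truncating mutations
with deletion/CN-LOH second hits, oncogenes hotspot mutations and copy
gains.  The event probabilities are plausible fixtures, not estimates of
any real cohort's frequencies, and purity/ploidy are simulator controls —
the source study does not publish them.

With `log2NoiseSd = 0` and `depthDispersion = 0` the generator is fully
deterministic (depths and allele counts are rounded expectations): the
noise-free limit used for exact-recovery testing.  Two simulator behaviors
matter for interpretation:

* at purity 1, CN-LOH heterozygotes have VAF exactly 0 or 1, which the
  default homozygous-exclusion cutoffs would discard; exact noise-free
  recovery therefore disables the cutoffs (`homCutoffs = NULL`), while all
  noisy validation runs keep the defaults;
* no two variants may share a genomic position; colliding draws are nudged
  deterministically.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: GC and mappability bias, mapping artifacts,
subclonal mixtures beyond one clone fraction, mutational signatures,
FFPE damage, and germline CNVs.  `truthAlterations()` applies the
integration priority directly to planted truth, giving the matrix an ideal
analysis would recover; recovery scores compare pipeline output against it.

# Validation design and problem sizes

The test suite validates each kernel against an independent oracle:
segmentation against an exhaustive least-squares changepoint search (200
random noise-free series of length ≤ 50, exact agreement; 100 noisy
replicates with a planted 1.0 shift at σ = 0.1, breakpoint within ±1
index), the exact test against full hypergeometric enumeration over every
2×2 table with total ≤ 60 (agreement within $10^{-12}$), the conditional
MLE and CI against grid-search and bisection oracles (100 random tables,
$10^{-6}$), type-I error on 1000 null cohort comparisons (n = 67 vs 595,
rate 0.1), CN-LOH detection on 200 planted events per purity, and
end-to-end recovery on 48-sample cohorts (noise-free: cell-for-cell
equality; default noise: biallelic-flag accuracy ≥ 0.95 and copy-state
accuracy ≥ 0.9 over 1152 gene-sample pairs).  These sizes were chosen to
make the checks statistically meaningful while keeping a full run of suite
plus acceptance script in the minutes range on one CPU.

# Known limitations

* Tumor purity is consumed, never estimated; without it, deep deletions in
  impure samples are indistinguishable from shallow ones, and copy numbers
  are reported on the admixed scale.
* The LOH stage cannot separate CN-LOH from deletion-LOH by deviations
  alone; the distinction rests entirely on the coverage-derived copy
  number of the gene.
* The exact test conditions on both margins; its conservatism at these
  cohort sizes (observed type-I error ≈ 4%) is inherited, not corrected.
* Panel gaps make the variant-index segmentation blind to event boundaries
  between targets: an event edge is always reported at a covered variant.
* The X chromosome is excluded by default rather than modeled.

# Session info

```{r}
sessionInfo()
```
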