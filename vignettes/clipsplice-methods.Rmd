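---
title: "clipsplice: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clipsplice: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the generative
and inferential models, the assumptions behind each statistic, the tunable
parameters with their defaults, and the places where the design was
genuinely open and a choice had to be made.

## 1. Crosslink evidence from iCLIP reads

In iCLIP, reverse transcription usually terminates at the crosslinked
nucleotide, so the cDNA (and the aligned read) starts one nucleotide 3' of
the protein contact; a minority of reads instead read through the crosslink
and record it as a deletion. `call_crosslinks()` therefore emits, per read,
one **truncation** tag at the nucleotide immediately 5' of the read start,
plus one **deletion** tag per reference base deleted in the CIGAR. The two
evidence classes are tallied separately and never mixed: binding profiles
(`build_profile()`, Fig-6B-style line plots via `plot()`) use truncation
tags, while crosslink-nucleotide confirmation uses deletion evidence only.
Reads starting at reference position 0 have no upstream nucleotide; they are
dropped and counted, so tag conservation (tags + drops = reads) is exact and
testable. Antisense alignments are discarded with a reported count, since
the snRNA references are single-stranded sense targets.

**Deletion fraction.** For a position $d$, the estimator is
(reads deleting $d$) / (reads for which $d$ is *strictly interior* to the
aligned span). Anchoring is required on both sides because an alignment
cannot begin or end with a deletion — a read starting exactly at $d$ can
never show a deletion there, and including such reads in the denominator
would bias the estimate downward. With interior-anchored counting the
estimator is exactly binomial and unbiased; the simulator applies the same
eligibility rule, and the recovery tests exploit this (estimates fall within
3 binomial standard errors of the generative probability). Zero-coverage
positions are flagged undefined, never reported as 0. The across-sample
summary is the unweighted mean of per-sample fractions, matching how an
"average across all samples" is ordinarily quoted.

**Region proportions.** "Proportion of total hits" over a window (e.g. U6
nucleotides 25–47, which contain the ACAGA box) is computed per reference
and per sample: window tag count / reference tag count. Windows are 1-based
inclusive at every interface and converted once, centrally, to 0-based
half-open coordinates (`pos_to0()`/`interval_to0()`); SAM is 1-based, BED
0-based half-open, GTF 1-based inclusive, and all conversions go through the
same four helpers. Per-reference (rather than per-library) normalisation is
used because per-snRNA panels are the natural display unit; both raw counts
and the per-sample library size are retained so a library-scaled analysis
remains possible.

## 2. The maximum-entropy splice-site model

`fit_maxent()` estimates, from a set of aligned splice-site windows, the
distribution of maximum entropy subject to empirical marginal constraints.
The default constraint set is all single-position marginals plus all
adjacent-pair marginals. Window conventions follow the standard maxent
splice-site framework: donors are 9-mers (last 3 exonic + first 6 intronic
nt), acceptors 23-mers (last 20 intronic + 3 exonic nt).

* For enumerable windows (length ≤ 10) the fit runs **iterative
  proportional fitting** over the full $4^L$ table, converging when every
  constrained marginal matches its target within $10^{-6}$ (maximum
  absolute deviation) or after 500 sweeps. Because the adjacent-pair
  constraint set is decomposable, IPF converges in a single sweep in
  practice; the tests nevertheless verify the fit against an independent
  convex-optimization oracle (BFGS on the exponential-family dual) with
  KL divergence below $10^{-8}$.
* For 23-mers the same constraint set admits an **exact first-order Markov
  chain** representation,
  $\log p(x) = \log p_{12}(x_1,x_2) + \sum_{i\ge2} [\log p_{i,i+1}(x_i,x_{i+1}) - \log p_i(x_i)]$,
  which satisfies the pair marginals exactly with no iteration. Full
  MaxEntScan-style fragment decompositions with non-adjacent constraint
  subsets are deliberately not reproduced: scores here are used for
  *relative* stratification, and the chain model is exactly computable at
  desk scale. The model object records this in its `note` field.

**Smoothing.** Each highest-order constraint table receives a Laplace
pseudocount of 0.5 per cell (so unseen k-mers keep finite scores);
lower-order constraints use the margins implied by the smoothed tables
(pseudocount scaled by $4^{k_{max}-k}$), which makes the constraint system
exactly consistent — otherwise the single-position and pair targets would
disagree at the $O(1/n)$ level and IPF could never satisfy both to
$10^{-6}$.

**Scoring and stratification.** A window scores
$\log_2 p_{signal}/p_{background}$; the background is a maxent fit to a
decoy set when one is supplied, else uniform (the appropriate reference when
no decoy model is trusted). Swapping signal and background negates every
score exactly. Donor thresholds default to weak < 3 and strong > 8 with
boundary values intermediate; these are the conventional cut-points for
MaxEntScan-scaled donor scores, but since a retrained model's scale need not
match them they are arguments, not constants. `score_distribution()`
returns a kernel-density modality diagnostic (local maxima/minima) for
recognising biphasic score distributions; bandwidth is the standard
`stats::density` default and adjustable.

## 3. Differential binding

Fold changes are computed on CPM with a pseudocount of 0.5
(`log2_fold_change()`), implemented as a difference of logs so that
swapping case and control negates values *exactly* in floating point.
Direction calls use |log2FC| > 1 by default. Features with combined raw
coverage below 10 tags are excluded from fold-change reporting
(`stratified_fold_changes(min_total = 10)`): at lower counts the
pseudocounted ratio is dominated by noise and produces spurious extreme
fold changes.

**Kurtosis.** `excess_kurtosis()` uses population moments
($m_4/m_2^2 - 3$) without small-sample correction, because its intended
inputs are thousands of fold changes; a bias-corrected estimator is
available by flag. A 95% percentile bootstrap CI (default 1000 replicates,
seeded) accompanies the point estimate. Flatter fold-change distributions
with heavier shoulders — the retinal signature — give lower excess
kurtosis than sharply peaked ones.

**Region test.** `region_difference_test()` compares mean per-sample
window proportions between conditions. The null distribution permutes
tag-to-sample assignment: all tags are pooled and re-dealt keeping each
sample's total, which for the window statistic reduces to multivariate
hypergeometric draws of in-window counts — an exact, fast tag-level
permutation. The permutation unit is the tag rather than the sample label
because with 3 + 3 samples a sample-label permutation has only 20
assignments and a smallest attainable two-sided p of ~0.1; tag-level
exchangeability holds under the null of no condition effect on tag
placement and gives fine p resolution at any replicate count. p-values use
the add-one convention $(1 + \#\{|perm| \ge |obs|\})/(1 + n_{perm})$ and
are two-sided by absolute value. Calibration is verified by simulation:
the type-I error at $\alpha = 0.05$ over 500 null simulations falls within
the binomial 95% interval.

## 4. PSI variability and differential splicing

PSI is computed from junction counts only — mean(inclusion junctions) /
(mean(inclusion) + skipping) — with no effective-length normalisation
(junction counts already condition on informative reads; a length-normalised
variant would need transcript models the junction table does not carry).
Events with zero supporting counts are undefined and excluded downstream.

**Variability.** Per event, the variance ratio $F = s^2_{case}/s^2_{ctrl}$
is referred to the F distribution with $(n_1-1, n_2-1)$ df, two-sided. This
assumes approximate normality of per-sample PSI, reasonable at moderate
depth where the (beta-)binomial PSI is near-normal; the per-event p-values
pass a KS uniformity check under a matched null simulation. Events with
zero control variance are flagged and excluded (with a count) rather than
given p = 0. Globally, per-event PSI standard deviations of the two groups
are compared with an independent two-sample t test (Student by default,
Welch by flag) — the SD-shift statistic that summarises "more variable
splicing" in one number.

**Differential events.** The per-event group-difference test is a binomial
likelihood-ratio test of a common versus group-specific inclusion
proportion on pooled counts (df = 1), BH-adjusted, with the selection rule
p_adj < 0.05 **and** |ΔPSI| > 5%. The binomial LRT is exact to specify and
fast, but it ignores between-replicate overdispersion: under strong
beta-binomial dispersion it is anti-conservative, so its null validity is
asserted only at near-binomial dispersion and the double filter (effect
size plus significance) is what protects the final event list. This is a
known limitation relative to full beta-binomial or rMATS-style likelihood
models, which are out of scope here.

**Cryptic events.** A junction is cryptic iff its donor or acceptor
coordinate (strand-aware, genomic 1-based, terminal exonic base) is absent
from the annotated splice-site sets; an event is cryptic if any constituent
junction is. This is pure set membership — deterministic, permutation
invariant, and exact on planted ground truth (precision = recall = 1).

## 5. What the synthetic-data generator emulates — and what it does not

`simulation_truth()` fixes the full generative state: reference sequences,
a per-nucleotide crosslink probability profile (summing to 1, with zero
mass on the final nucleotide, where no read could start), designated
deletion-bearing nucleotides with a per-read deletion probability,
read geometry, the sample sheet, and per-event PSI means/dispersions. One
master seed is split hierarchically into per-sample seeds, so outputs are
byte-identical under a fixed seed and adding a sample never perturbs the
others.

* `simulate_clip_reads()` emits pre-aligned single-end SAM text (correct
  POS/CIGAR) — alignment itself is not the object of study and the
  references are short. Deletions are 1–2 nt CIGAR `D` operations at the
  designated nucleotides, the iCLIP deletion-evidence convention.
* `simulate_junction_counts()` draws inclusion counts from a beta-binomial
  parameterised by (mean, overdispersion $\rho \in (0,1)$), so
  $\mathrm{Var}(PSI) \approx \psi(1-\psi)\,[\rho + (1-\rho)/depth]$ —
  a single intuitive dispersion knob; totals per event always equal the
  requested depth.
* `simulate_splice_site_sets()` draws signal windows from a
  position-specific model hitting requested per-position information
  contents (0–2 bits; the consensus-base probability is solved from the
  entropy equation), decoys uniformly.
* `simulate_annotation()` builds a toy genome with canonical GT..AG
  introns, a valid GTF, and planted junctions guaranteed absent from the
  annotation.

Defaults mirror the emulated study where it states conditions: 2
replicates per condition (the study analysed "both replicates" per tissue;
its exact read depths are unpublished, so depths are arguments everywhere
and the recovery tests state theirs explicitly), deletion probability 4.3%
at U6 nucleotides 64–65, analysis windows U6 25–47 and U4 36–96, donor
thresholds 3/8, |log2FC| > 1, p_adj < 0.05 with |ΔPSI| > 5%.

Not emulated: sequencing errors beyond the crosslink deletion, PCR
duplicates and UMIs, non-uniform fragmentation, mappability, multi-locus
ambiguity, and expression-coupled coverage. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
generative model, not robustness to those artefacts in real libraries.

## 6. Numerical choices and degenerate inputs

* IPF tolerance $10^{-6}$ on marginal deviation, cap 500 sweeps; fitted
  distributions sum to 1 within $10^{-9}$.
* Scores are exact log-ratios of fitted probabilities; pseudocounts keep
  them finite for unseen k-mers.
* Boundary windows that would cross a contig end, or sit on introns
  shorter than 6 nt (donor) / 26 nt (acceptor), are skipped with warnings
  rather than silently truncated.
* Tags equidistant to two boundaries are assigned to both, with the
  multiply-assigned count reported.
* Permutation p-values can never be 0 (add-one convention); Fisher odds
  ratios use Haldane's 0.5 correction only when a cell is 0.
* Constant score vectors short-circuit the density machinery (a single
  maximum); constant inputs to the kurtosis estimator are an error, not a
  NaN.

Exact-test p-values (Fisher, and the permutation test at small $n_{perm}$)
are discrete and conservative; their null behaviour is asserted as
"stochastically no smaller than uniform" rather than strict uniformity,
which discreteness makes unattainable.

## 7. Problem sizes used by the test suite

The shipped tests run the full recovery suite at: 8 samples × 50,000 reads
for deletion-fraction recovery; 1000 training windows for the 9-mer maxent
marginal check; 500 events × 3v3 samples at depth 100 for the PSI
dispersion contrast (and 200 events for the F-test null); 50 genes × 5
exons with 20 planted cryptic junctions; 500 null simulations at
$n_{perm} = 199$ for permutation-test calibration; and 3v3 × 50,000 reads
for the planted 2-fold window enrichment. These sizes give each stochastic
assertion comfortable margins (3 standard errors or better) while keeping
the default suite in the minutes range on one core.

## 8. Known limitations

* The maxent constraint set is the adjacent-pair chain, not the full
  fragment decomposition; absolute scores need not match MaxEntScan
  digit-for-digit (stratification thresholds are configurable for this
  reason).
* The binomial LRT understates p-values under strong between-replicate
  overdispersion (see §4).
* The gene-level/site-level duality of enrichment inputs is resolved
  gene-level by default; BH adjustment is per direction × category
  stratum, matching how such panels are usually presented.
* The enrichment background is detectable boundaries (minimum-coverage
  filtered), not all annotated genes: enrichment statements condition on
  detectability.
* Intron retention is handled through its junction proxy only; no
  exonic-coverage quantification.
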