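---
title: "Biotin painting: models, parameters and design decisions"
author: "biotinpaint authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biotin painting: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biotinpaint)
```

## The scientific model

Covalent labelling of a protein side chain requires that the side chain
be solvent-accessible. In proximity-labelling proteomics the label is
biotin, delivered either enzymatically (BioID onto lysines, APEX2 onto
tyrosines) or chemically (NHS-biotin onto lysines). If accessibility
drives labelling, then residues inside intrinsically disordered regions
(IDRs) — which lack stable tertiary structure and are transiently or
permanently exposed — should accumulate more biotin marks than residues
of the same chemical type buried in folded domains. `biotinpaint`
implements the statistical workflow around that hypothesis: IDR calling,
composition-aware site enrichment, protein structural classes,
bias-corrected functional (GO) enrichment, and a labelling time course.

Everything operates in one coordinate frame: residue positions are
1-based, intervals inclusive on both ends, matching UniProt/PDB
convention. This is enforced at every boundary (site validation, track
expansion, interval calling) rather than converted back and forth.

## IDR calling

Per-residue disorder predictions arrive as dense tracks (scores in
[0, 1] or binary calls). `binarize_track()` calls residue *i* disordered
iff its value is at least the threshold (default 0.5, the conventional
disorder-probability cutoff; it only matters for score tracks — the
D2P2-style interval inputs are already binary). Maximal runs of
disordered residues become intervals. **No minimum IDR length is
applied**: a single-residue IDR is a legitimate call. This trades
specificity for sensitivity deliberately: short linkers and locally
mobile single residues are exactly the regions an accessibility probe
can reach.

Two combination policies are provided:

* `combine_union()` — a residue is disordered if either caller says so
  ("called by one or both predictors"); labels join with `_`
  (e.g. `VSL2b_IUPred-L`).
* `combine_consensus()` — a residue is disordered iff at least a quorum
  (default 75%) of the available callers agree. The comparison is
  inclusive (`>=`), so 75% of nine callers means at least 7 of 9
  (6.75 rounds up via the inclusive comparison). The denominator is the
  number of callers *with a track for that protein*, not a fixed nine:
  prediction resources do not cover every protein with every algorithm,
  and silently treating a missing predictor as "not disordered" would
  bias the consensus toward order.

Normalization merges overlapping *and adjacent* intervals. That choice
is cosmetic for any residue-level statistic (the mask is unchanged) but
makes interval counts and exports deterministic, and it gives the
round-trip law `binarize(mask(x)) == x` that the property tests rely on.

## Site enrichment

For one study, the trials are the study's **unique** biotin sites —
multiplicity of the same (accession, position) across replicates or
peptide forms counts once, because "number of sites" is the quantity
with structural meaning. A success is a site inside an IDR. The null
rate is composition-aware:

\[
p_0 \;=\; \frac{\#\{\text{target residues inside IDRs}\}}
               {\#\{\text{target residues total}\}}
\]

pooled over the **biotinome** — the proteins with at least one detected
site in that study. Pooling over the biotinome rather than the whole
proteome reflects that undetected proteins tell us nothing about where
labels land on detected ones; whole-proteome pooling is available
(`pool = "proteome"`) as a sensitivity mode. If \(p_0\) is exactly 0 or
1 the scope is flagged untestable (`$untestable`) instead of producing a
meaningless p-value.

The test itself is the exact binomial tail, computed by pmf summation in
log space — never a normal approximation, since study sizes range from
tens to tens of thousands of sites. The two-sided p-value is the sum of
probabilities of all outcomes no more likely than the observed one (the
"small-p" definition, with a `1 + 1e-7` relative tie tolerance); exact
two-sided binomial definitions differ between tools, so the choice is
stated here and pinned by tests against brute-force enumeration. The
default is two-sided, with the enrichment direction carried by the fold
`(k/n)/p0`; a one-sided `greater` alternative is available.

Endogenous PTMs go through the identical machinery with their own
eligible residues (phosphorylation S/T/Y; ubiquitination, acetylation
and sumoylation K); `ptm_idr_enrichment()` and `study_enrichment()` are
the same core function under two validations, and a test asserts their
bit-for-bit equivalence. Subset analyses (cytosolic vs mitochondrial
ribosomal proteins) restrict the same computation by name predicates on
the protein description.

## Structural classes

Proteins are classified by predicted disorder fraction: Folded below
10%, Partially folded from 10% to 30%, Unfolded above 30%. The printed
ranges leave the two boundary values ambiguous; both 0.10 and 0.30 are
assigned to P so that each stated range is honoured literally, and the
classes partition [0, 1].

Per-protein in-IDR biotin counts are compared across classes on
`log2(count + pseudo)` with pseudo-count 0.5: zero-count proteins then
sit strictly below the zero line, visually and numerically separated
from single-site proteins. Pairwise t-tests default to Welch — class
variances plainly differ in practice — with pooled-variance tests
behind a flag. The one-way ANOVA and Tukey HSD use `stats::aov` and
`stats::TukeyHSD`; base R's `ptukey` is a numerical quadrature of the
studentized-range distribution, and `TukeyHSD` applies the standard
Tukey–Kramer \(1/n_i + 1/n_j\) form for unbalanced classes. Degenerate
input (all values identical) returns F = 0 and p = 1 rather than NaN; a
class with fewer than two observations is skipped with a warning.

## GO enrichment with abundance-bias correction

Detection in a proximity experiment depends strongly on protein
abundance. If annotation categories correlate with abundance (they do:
ribosomal, glycolytic and cytoskeletal categories are systematically
abundant), an uncorrected Fisher test reports spurious enrichment. The
correction follows the goseq idea:

1. Fit a **probability weighting function** — a monotone non-decreasing
   map from the per-protein bias factor (expression) to the probability
   of biotinome membership. We use weighted isotonic regression
   (pool-adjacent-violators on the distinct bias values): it is
   parameter-free, order-preserving, pools tied bias values exactly,
   and its fit is testable against closed-form cases; a monotone spline
   would add smoothing parameters the data do not pin down. Fitted
   probabilities are floored at 1e-6 to keep weights positive.
2. Score each category with the **Wallenius noncentral hypergeometric**
   tail, the distribution of biased sampling without replacement. The
   odds for a category are the mean fitted weight of its members over
   the mean fitted weight of non-members (a two-group reduction: the
   full many-colour distribution adds nothing for a 2x2 margin).

The Wallenius tail is computed by the exact sequential-draw recursion
for populations up to 2000 (cost is quadratic in the sample size) and
by numerical integration of the integral representation
\(f(k) = \binom{m_1}{k}\binom{m_2}{n-k}\, D\int_0^1 (1-u^{\omega})^k
(1-u)^{n-k} u^{D-1}\,du\) above that, with the integrand evaluated on a
log scale and the integral split at its maximum (located numerically) so
large populations cannot underflow; the two methods agree to ~1e-9 on
overlapping ranges and both reduce to the central hypergeometric at
odds 1. Unannotated proteins are excluded from the population;
categories smaller than `min_category` (default 3) are not tested;
p-values are BH-adjusted across tested categories (the multiplicity
handling is recorded in the results object). Only over-representation is
tested by default, since that is the question the analysis asks;
`correct_bias = FALSE` gives the uncorrected Fisher tail for comparison.

## TMT time course

The labelling time course (triplicates at 10 s, 120 s, 300 s and a 1 h
carrier channel) is filtered to complete, biotinylated, ribosomal
peptides; the carrier is dropped from statistics. **No median
normalization is applied by default**: the fraction of biotinylated
peptide in the channel genuinely grows with labelling time, and
equalizing medians would erase the very signal under study (a
`normalize = TRUE` mode exists for sensitivity analysis). Missing values
are handled by complete-case row filtering, no imputation.

Testing is on log2 intensities — reporter noise is multiplicative, and
the shared-variance model below assumes it; a linear-scale mode exists
for sensitivity analysis. For each contrast (120 s vs 10 s, 300 s vs
10 s, fitted separately), the per-peptide pooled variance \(s^2_g\)
(4 df) is shrunk toward an empirical-Bayes prior \((d_0, s_0^2)\)
estimated across peptides by moment matching on log variances
(`limma::squeezeVar`, i.e. digamma/trigamma inversion; when the
trigamma equation has no positive solution the prior df are effectively
infinite and shrinkage is total). The moderated t is the mean log2
difference over \(s_{post}\sqrt{2/3}\) with \(d_0 + d_g\) degrees of
freedom, capped at the ensemble's pooled residual df. Forcing
\(d_0 = 0\) reproduces the ordinary two-sample t-test exactly;
\(d_0 = \infty\) uses the prior variance everywhere — both limits are
asserted in tests, and the default fit is cross-checked against a full
`limma::lmFit`/`eBayes` run.

Classification: a peptide is a **late** biotinylation event iff some
contrast shows an adjusted p strictly below 0.05 *and* a positive log
fold change — "significant increase" is directional, although the test
p-value itself is two-sided, keeping the test conventional while
honouring the direction of the question. Everything else is **early**
(the threshold is strict: adjusted p = 0.05 exactly is early). The
partition is exhaustive and exclusive.

## The synthetic world

Every input has a generator, and every generator is a pure function of
(config, seed): one global seed expands into per-component child seeds
by a fixed polynomial hash (`child_seed()`), so components can be
regenerated independently and reruns are byte-identical.

* **Proteome** — sequence lengths are negative-binomial (mean 400,
  dispersion 3, minimum 50, matching the scale of a mammalian
  proteome); residues i.i.d. with lysine at 6% and tyrosine at 3%
  (their approximate natural abundances — the two labelling targets are
  the frequencies that matter for power) and the remaining 18 letters
  uniform. Each protein draws its own disorder fraction from a Beta
  distribution with mean q (default 0.3) and concentration 8, so the
  proteome spans fully folded to fully disordered proteins — without
  this spread the F/P/U classes and the count-vs-disorder association
  are degenerate; `fraction_concentration = Inf` pins every protein at
  exactly q for calibration studies. The disordered budget is placed in
  Poisson-many non-overlapping blocks. Pseudo-predictors derive from
  the truth track by independent per-residue flips (rate 0.05),
  emulating disagreeing callers; flip rate 0 makes any consensus equal
  the truth.
* **Sites** — each of `n_sites` draws picks a target-residue position
  with weight rho inside IDRs and 1 outside, with replacement, then
  duplicates collapse (real studies report unique sites). The expected
  per-draw in-IDR fraction is \(\rho q_r / (\rho q_r + 1 - q_r)\) with
  \(q_r\) the fraction of target residues inside IDRs; for unique sites
  this holds as long as draws do not saturate the position pool, and
  the saturated regime follows the Poissonized form
  \(N_I(1-e^{-n\rho/W}) \,/\, [N_I(1-e^{-n\rho/W}) +
  N_O(1-e^{-n/W})]\), \(W = \rho N_I + N_O\), which the end-to-end test
  uses.
* **TMT** — log2 intensities are baseline + effect + Gaussian noise
  (sd 0.5); "late" peptides gain the effect at both 120 s and 300 s
  (a slowly labelled site keeps accumulating biotin), null peptides are
  flat; cells go missing and flags are contaminated at configurable
  rates; ground truth is recorded in `truth_late`.
* **GO** — per-protein bias factors are log-normal; biotinome
  membership is logistic in log bias (slope 1.5, intercept −1: low-
  abundance proteins are detected rarely, abundant ones usually);
  categories sample members weighted by bias^1, tying annotation to
  abundance — the regime the Wallenius correction exists for; one
  planted category can multiply membership odds.

What a green test does **not** establish: the generator reproduces the
statistical structure the analyses assume, not real sequence biology —
no homology, no real disorder-predictor error structure, no spectral or
digestion effects, no isotopic impurity. Power estimates transfer to
real data only to the extent those assumptions hold.

## Numerical choices and degenerate inputs

* Exact binomial and Wallenius tails are summed in log space; ties in
  the two-sided binomial use a `1 + 1e-7` relative tolerance.
* `p0` of exactly 0 or 1, empty residue sets, empty biotinomes, zero
  surviving peptides, or a predicate matching no protein all raise
  informative errors (or set the `untestable` flag) instead of
  returning boundary p-values.
* Residue-mismatched sites are dropped with a warning by default —
  isoform and sequence-version drift is expected in real tables — and
  abort in strict mode, which the synthetic fixtures use (there any
  mismatch is a bug). All drops are counted per reason in a validation
  report.
* In the pipeline, a study whose data are degenerate for one stage
  (e.g. a single structural class under an aggressive union caller) is
  skipped with a warning rather than failing the run; genuine errors
  abort with the stage name.
* Reports are written with 6-significant-digit formatting and fixed
  column order so reruns diff cleanly; end-to-end determinism under a
  fixed seed is asserted by hashing the output tree.

## Known limitations

* Disorder predictions are consumed, never computed: there is no
  re-implementation of VSL2b or IUPred, and no live queries to
  prediction services in tested code paths.
* GO terms are flat labels — no DAG propagation; annotation retrieval
  is out of scope.
* The PTM reference sets and the comparison proteome for the mean-PTM
  burden t-test are supplied by the user; the package deliberately does
  not embed a definition of "the" reference proteome.
* The time-course model fits contrasts separately and performs no
  protein-level rollup; peptide-level sites are the unit of inference.
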