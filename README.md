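# biotinpaint

Structural enrichment analysis of in vivo biotinylation sites.

## The problem

Proximity-labelling proteomics — BioID (a promiscuous biotin ligase that
acylates lysines), APEX2 (a peroxidase that activates biotin-phenol onto
tyrosines) and direct NHS-biotin chemistry — leaves covalent biotin marks
on proteins. Labelling requires solvent accessibility, so the *positions*
of those marks carry structural information: residues inside
intrinsically disordered regions (IDRs) are labelled more readily than
residues buried in folded domains. "Biotin painting" re-purposes
site-resolved proximity-labelling data as an in vivo probe of protein
plasticity, complementary to in vitro techniques such as HDX-MS.

`biotinpaint` is for computational proteomics researchers who have
peptide-level biotinylation (or PTM) site tables, protein sequences and
per-residue disorder predictions, and want the complete statistical
workflow around that idea — plus a synthetic-data generator that emulates
every input, so the whole pipeline is testable without downloads.

## The statistics

**IDR calling.** Per-residue disorder tracks (scores or binary calls, in
a dense TSV or a D2P2-style interval JSON) are binarized at a threshold
(default 0.5) into interval sets; no minimum IDR length is imposed, so a
single residue can be an IDR. Predictors can be combined by residue-level
union ("called by one or both") or by quorum consensus (a residue is
disordered iff at least, say, 75% of the available callers agree).

**Site enrichment.** For a study whose chemistry targets residue class
*R* (K for BirA/NHS-biotin, Y for APEX2), the null success rate is
composition-aware:

    p0 = (# R residues inside IDRs) / (# R residues total)

pooled over the study's biotinome (proteins with at least one detected
site). With *n* unique observed sites of which *k* fall inside IDRs, the
exact binomial test of *k* successes in *n* trials at rate `p0` gives the
p-value, and `(k/n)/p0` the fold enrichment. Endogenous PTMs run through
the same machinery with their own eligible-residue backgrounds
(phosphorylation: S/T/Y; ubiquitination, acetylation, sumoylation: K).

**Protein classes.** Proteins are classified by predicted disorder
fraction as Folded (< 10%), Partially folded (10–30%) or Unfolded
(> 30%), and per-protein `log2(in-IDR biotin count + 0.5)` values are
compared across classes by pairwise Welch t-tests, one-way ANOVA and
Tukey's HSD.

**GO enrichment.** Protein detection is abundance-biased, so categories
of abundant proteins look spuriously enriched under Fisher's exact test.
A monotone probability weighting function (isotonic regression of
biotinome membership on an expression bias factor) supplies odds for the
Wallenius noncentral hypergeometric test, which corrects for the bias.

**Time course.** TMT reporter intensities of a labelling time course
(triplicates at 10 s / 120 s / 300 s plus a 1 h carrier, deliberately not
median-normalised) are tested per peptide for increased labelling vs
10 s with empirical-Bayes moderated t-statistics; peptides with a
significant increase (BH-adjusted p < 0.05) are "late" biotinylation
events, the rest "early" — early sites mark the most accessible,
disordered surface.

## Worked example

```r
library(biotinpaint)

sim <- generate_proteome(n_proteins = 150, disorder_fraction = 0.3, seed = 42)
idrsets <- call_idrs(sim$tracks, caller = "VSL2b")
sites <- plant_sites(sim$proteome, idrsets, residues = "K", n_sites = 600,
                     rho = 3, study_id = "SpotBioID", seed = 42)
enr <- study_enrichment(sites, sim$proteome, idrsets, default_study_registry())
print(enr)
```

```
IDR enrichment [SpotBioID], caller VSL2b, null over biotinome (134 proteins)
  sites in IDRs: 329 / 549 (observed rate 0.5993)
  expected rate p0 = 0.3368 (residues K in IDRs / total)
  fold = 1.779, two.sided p = 5.33e-36 ***
```

The synthetic study planted 600 lysine-directed biotin sites with an IDR
enrichment factor rho = 3; after collapsing to 549 unique sites, 59.9% sit
inside IDRs against an expected 33.7% from lysine composition alone — a
1.78-fold enrichment the exact binomial test calls overwhelmingly
significant, close to the planting model's prediction
`rho·q/(rho·q + 1 − q) / q ≈ 1.9` at q ≈ 0.34.

Class comparison on the same world:

```r
cls <- biotin_class_analysis(sites, sim$proteome, idrsets)
print(cls$comparison)
```

```
Class comparison (Welch t-tests), n = F:5, P:56, U:73
 pair mean_diff statistic         df     p_value
  P-F 1.6831937  4.805973   5.939359 0.003065908
  U-F 2.0360904  5.869843   5.722782 0.001278842
  U-P 0.3528967  1.721689 122.517694 0.087649679
ANOVA: F(2, 131) = 7.883, p = 0.000585
```

Unfolded proteins carry about 2 log2 units (~4×) more in-IDR biotin
marks than folded ones.

## Pipeline and CLI

`simulate_inputs()` writes a complete synthetic input set (FASTA, site
TSV, disorder tracks, TMT matrix, GO annotations + bias factors);
`run_pipeline()` runs every stage in dependency order and writes
fixed-format TSV reports plus a manifest. A thin command-line wrapper
lives at `inst/cli/biotinpaint.R`:

```sh
Rscript inst/cli/biotinpaint.R simulate --out inputs --seed 1
Rscript inst/cli/biotinpaint.R run-all --config run_config.txt --out results
```

(`inst/extdata/run_config.example` is a template; flags override config
keys.)

## Acceptance script

`scripts/acceptance.R` exercises the installed package end to end: it
simulates the full input set under the given seed, runs every analysis
stage (IDR calling, biotin and PTM enrichment, disorder association,
structural classes, bias-corrected GO enrichment, TMT time course) and
writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

The synthetic generator reproduces the statistical structure the
analyses assume (block IDRs, residue composition, planted enrichment,
abundance bias, labelling kinetics), not real HEK293 sequences or true
predictor behaviour; see the methods vignette
(`vignettes/biotin-painting-methods.Rmd`) for the model, parameter
choices, numerical decisions and known limitations.
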