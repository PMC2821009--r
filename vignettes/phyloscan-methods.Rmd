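---
title: "Methods behind phyloscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind phyloscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phyloscan analyses resequenced candidate genes by treating the haplotype
network as the organising structure for three questions: which branch of the
network is associated with quantitative phenotypes, which phenotype drives a
joint association, and which amino-acid changes are physicochemically
radical.  This vignette documents the statistical models, the defaults, the
numerical decisions, and what the synthetic-data validation does and does
not establish.

## The haplotype network

Within a population sample of a short gene region, most haplotypes differ
from a common neighbour at a single site, and coalescent reasoning favours
these short connections over the long branches a phylogeny of divergent
species would need.  `build_network()` therefore connects haplotypes in
ascending order of pairwise difference, keeping all alternative connections
of equal length (loops) for explicit resolution, up to a parsimony
connection limit.

**Connection limit.**  The limit is the largest number of steps `j` at
which a connection can still be called parsimonious with 95% confidence.
We compute the parsimony probability from an explicit finite-sites model:
each of the `L` sites accumulates Poisson-distributed mutations along the
path joining two haplotypes, multiple hits follow a Jukes–Cantor chain, so
a site shows a difference with probability $\tfrac34(1 - e^{-4\theta/3})$
where $\theta$ is the expected number of hits per site.  $\theta$ is
estimated by maximum likelihood from the observed proportion $j/L$, and the
parsimony probability is the posterior probability that every differing
site experienced exactly one hit and every identical site none:

$$P_j \;=\;
\left(\frac{\theta e^{-\theta}}{\tfrac34(1-e^{-4\theta/3})}\right)^{\!j}
\left(\frac{e^{-\theta}}{1-\tfrac34(1-e^{-4\theta/3})}\right)^{\!L-j}.$$

Single steps are always parsimonious, the limit is non-decreasing in `L`,
and for a 1218-site alignment at 95% confidence the limit is 11 steps
(recomputed by `scripts/acceptance.R`).  The classical statistical-parsimony
literature derives this quantity with additional coalescent averaging; the
closed form above makes the same modelling assumptions explicit and is
independently re-implemented in the test suite as an oracle.

**Loop resolution.**  Coalescent theory gives qualitative guidance: rare
haplotypes are more likely tips, and connections between common, interior
haplotypes are more credible.  `resolve_loops()` breaks every cycle by a
fixed priority: remove longer (multi-step) connections first; then the edge
whose endpoints have the smallest summed frequency; then the edge incident
to the fewest interior (multi-degree) nodes; ties fall back to the
lexicographic edge id so runs are deterministic.  This is implemented as a
maximum-preference spanning tree, which breaks each independent cycle at
its least-preferred edge.  Specific breaks can be forced through
`break_edges` when a published resolution must be matched.

**Branches as markers.**  Each edge of the resolved tree bipartitions the
haplotypes.  The derived side is the side not containing the most frequent
haplotype, the usual ancestral proxy for within-population data; an
individual's genotype class at the branch is its number of derived-side
haplotypes (0/1/2).  This genotype-level definition makes the scan
invariant to how a singleton variant is phased onto its two candidate
backgrounds — the carrier lands in the heterozygote class either way — and
the suite checks bit-identical scan output under both phasings.

## The branch scan

Phenotypes are adjusted for covariates (default age, sex, BMI) by ordinary
least squares before testing; rows with missing phenotypes or covariates
are dropped per analysis.  For every branch, classes with fewer than
`min_class_count = 5` individuals are excluded (their individuals are
dropped for that branch only), and a branch with fewer than two surviving
classes is untestable and logged.  The default of 5 reflects the smallest
genotype class a one-way ANOVA can meaningfully use; it is configurable.

Significance is by permutation: phenotype rows are permuted (whole
phenotype vectors jointly, preserving inter-phenotype correlation) and the
one-way ANOVA F recomputed.  Nominal p-values use the add-one estimator
$(1 + \#\{F^* \ge F\})/(1 + B)$ so a p-value of zero is impossible; the
default is $B = 10{,}000$ permutations.

**Multiple-test correction.**  Branch tests are strongly correlated —
neighbouring branches share most of their carriers — so a plain Bonferroni
would be badly conservative.  The scan uses the step-down max-statistic
(Westfall–Young) procedure on a single permutation stream shared by all
branches: observed statistics are sorted descending, the corrected p of
rank $r$ counts permutations whose maximum statistic over ranks $r$ and
below exceeds the observed one, and monotonicity is enforced down the list.
Two branches inducing the same bipartition receive identical corrected and
nominal p-values (effectively one test), which the suite asserts.  The
statistics compared across branches are the F values themselves; branches
can differ slightly in degrees of freedom after class filtering, which we
accept for the transparency of the max-F construction.

**Second-round (conditional) scan.**  After a first-round hit, passing
`condition_on = <branch>` re-runs the scan with the hit's genotype class as
a blocking factor: branch effects are tested by the F statistic of the
branch factor after the conditioning factor in an additive two-factor
least-squares fit, and permutations are restricted within conditioning
strata.  A stratum that contains fewer than two classes of the tested
branch simply contributes no information.  Conditioning a branch on itself
leaves nothing to test (F = 0, p = 1).  An alternative second-round
semantics — subdividing the significant allele class — exists in the
treescanning literature; we implement and verify the stratified-conditioning
form, which matches the "conditioning on the first hit" description of the
analyses this package operationalises.

## MANOVA and partial Wilk's tests

Because lipid phenotypes are biologically coupled, each branch is also
tested jointly against the phenotype panel (default triglycerides, HDL,
VLDL, LDL; total cholesterol is excluded by default because the simulator —
like the assay panel it emulates — makes it a composite of the others).
With within- and between-class SSCP matrices $E$ and $H$,

$$\Lambda_p = \frac{\det E}{\det(E+H)},$$

and significance uses Rao's F transformation, which is exact for $p \le 2$
or $\nu_H \le 2$ — in particular for the three genotype classes of a
biallelic branch ($k = 3$, $\nu_H = 2$).  The implementation is checked
against `summary(manova(), test = "Wilks")` and against the Hotelling
$T^2$ closed form for two classes.

The contribution of a single phenotype $y_g$ given the others is the
partial Wilk's statistic $\Lambda_p / \Lambda_{p-1}$, where
$\Lambda_{p-1}$ excludes $y_g$; it transforms exactly to
$F_{\nu_H,\, \nu_E - p + 1} = \frac{1-\Lambda}{\Lambda}\cdot
\frac{\nu_E - p + 1}{\nu_H}$.  The suite verifies the ratio identity to
machine precision and the numerical identity of the partial F with the
class-factor F in an ANCOVA of $y_g$ on the remaining phenotypes.

Within the scan, the multivariate branch statistic is the Wilk's F; its
nominal permutation p and the step-down corrected p come from the same
shared permutation stream as the univariate tests, and the parametric p of
the F transformation is reported alongside (`p_parametric`).  Partial
Wilk's p-values are parametric (the exact F), not permutation-based:
permutation is reserved for branch-level inference.

**Numerical safeguards.**  Determinants are computed on the log scale with
sign checks; a reciprocal-condition estimate below $10^{-12}$ (condition
number above $10^{12}$) aborts with an explicit error rather than returning
an unreliable Λ.  Degenerate cases are defined, not patched: zero
within-class variance with equal means gives F = 0; an exactly collinear
phenotype set is reported as singular.

## Radical-substitution scoring

Substitution events are read off the haplotype tree after per-site
minimum-mutation ancestral reconstruction (Fitch/Sankoff dynamic programme
with unit costs, valid for multifurcating nodes, which star-like haplotype
trees have).  Ties on the downward pass prefer the parent's state, then the
alphabetically first state; for a variant seen in a single tip the event is
assigned to its pendant edge regardless of tie-breaks.  Maximum-likelihood
reconstruction is the classical choice here; on single-step haplotype trees
the two agree for pendant events — the only events such trees contain — and
parsimony removes an external-tool dependency.

For each physicochemical property, the expected distribution of change
magnitudes under completely random amino-acid replacement enumerates all
nonsynonymous replacements reachable by a single nucleotide change under
the standard genetic code, uniformly weighted, and bins $|v(\text{to}) -
v(\text{from})|$ into 8 equal-width categories spanning $[0, \max]$.
Observed events are binned the same way and each category gets a one-sided
z score $(O - nq)/\sqrt{nq(1-q)}$ against the expected proportion $q$, with
default threshold $z \ge 1.645$ ($\alpha = 0.05$); a category with $q = 0$
but observed events is flagged directly.  A site is flagged when one of its
events falls in a significant category, and called radical when that
category is 6–8.  Whether the expectation should instead condition on the
observed codon composition is a genuine modelling fork; the uniform-code
expectation is the default and the computation is isolated in
`expected_distribution()` so alternatives can be swapped.

The default 31-property table is drawn at runtime from the AAindex database
shipped with seqinr, chosen to cover the classical structural, energetic
and hydrophobicity indices used in radical-substitution work (accessions in
`phyloscan:::DEFAULT_PROPERTY_ACCESSIONS`).  Two classical properties
(compressibility, helical contact area) have no AAindex entry and are
replaced by related indices (helix–coil equilibrium constant, buried
residue volume).  Any table with the documented
property/amino_acid/value schema is accepted.

## Predictor evaluation

The packaged table of 27 missense variants records the phenotype-tail class
of each rare variant, the assay outcome, the PolyPhen score/prediction, and
the maximum radical-substitution category.  Six low-tail variants with
functional assay results plus two scan-associated common variants form the
known-positive column; the two high-tail assayed-nonfunctional variants are
excluded from every 2×2 table and counted separately; the remaining 17 are
negatives.  For each criterion the 2×2 table is tested with the two-tailed
Fisher exact test (point-probability tail rule) and summarised by the
conditional-MLE odds ratio with exact tail-inversion confidence interval —
the convention that goes with the exact test, and the only one consistent
with reporting an odds ratio of 9.130 for a table whose sample odds ratio
is 10.  Both are delegated to `stats::fisher.test`, which implements
exactly these conventions; the test suite checks the p-value against full
hypergeometric enumeration for every 2×2 table with total at most 30 and
the estimate against an independently coded root of the conditional score
equation.

## The cohort simulator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, not any particular cohort:

* **Haplotypes** — a frequency-weighted random attachment process: each new
  haplotype mutates one previously unused site off a parent drawn with
  probability proportional to frequency.  This reproduces the observed
  star-like, single-step topology directly; a full coalescent simulation
  would add realism (recombination, recurrent mutation, frequency/age
  correlations) the downstream tests do not depend on.
* **Frequencies** — the two common haplotypes default to 0.512 and 0.260,
  the remainder follows a power-law tail (exponent 1.2, chosen to give a
  handful of intermediate-frequency haplotypes and many rare ones);
  per-population spectra are high-concentration Dirichlet jitter around the
  overall spectrum.  Default population sizes are 1830/1045/601.
* **Diplotypes** — random union of gametes (Hardy–Weinberg) within each
  population; no mating structure is modelled.
* **Covariates** — age uniform on 18–65, sex Bernoulli(0.5), BMI
  normal(28, 5); arbitrary but documented, since only the residual
  structure matters after adjustment.
* **Phenotypes** — covariate term + additive branch effect (in SD units per
  derived-allele copy; default 0.5 SD on HDL, on the branch above
  haplotype `h3`, whose ~5% frequency mirrors a moderately common lipid
  variant) + multivariate normal noise with unit SDs and a lipid-like
  correlation matrix (tg–vldl 0.85, tg–hdl −0.40, hdl–vldl −0.40, weak LDL
  correlations).  Total cholesterol is ldl + hdl + vldl plus noise with
  SD 0.1, so excluding it from the MANOVA is structurally necessary, not
  just conventional.

One user seed expands into per-stage sub-seeds through a documented
splitting rule (`phyloscan:::derive_seed`), so every stage is individually
reproducible and identical configs give byte-identical cohorts.

**What passing tests show — and don't.**  The synthetic validation
establishes that the scan is calibrated under its own null (type-I error at
nominal 0.05 within 0.03–0.07 across 200 cohorts of 500 at 1000
permutations, uniform nominal p-values), that a 0.5 SD branch effect at
n = 3000 is recovered as the top corrected-significant branch and that the
effect phenotype has the smallest partial Wilk's Λ (50 replicates each),
and that every component matches an independent oracle on small instances.
It does not establish robustness to features real cohorts have and the
simulator lacks: genotyping and phasing error, non-normal phenotypes,
population stratification within a labelled population, relatedness,
recombination, or ascertainment.  Analyses of real data should treat those
as open questions for the data, not properties of the method.

## Validation problem sizes

The test-suite and acceptance-script simulations use cohorts of 500
(calibration, 200 replicates, one phenotype, 1000 permutations) and 3000
(effect recovery, 50 replicates, four phenotypes, 1000 permutations), with
the full 45-haplotype, 1218-site generator defaults.  These sizes give the
calibration estimate a standard error well under the width of the accepted
band while keeping the default check reproducible on a laptop; production
scans should keep the 10,000-permutation default, which bounds the smallest
achievable nominal p at ~1e-4.

## Known limitations

* Branch statistics with heterogeneous degrees of freedom enter the max-F
  correction on a common scale; a min-p style correction would equalise
  scales at roughly double the computation.
* The conditional scan implements stratified conditioning only; allele-class
  subdivision is not implemented.
* The parsimony connection limit uses the closed-form finite-sites model
  above rather than the original coalescent-averaged recursion; for the
  single-step networks this package targets, any limit ≥ 1 yields the same
  network.
* Haplotype phasing, model-based tree estimation and likelihood selection
  analyses (dN/dS) are out of scope; haplotypes and trees are inputs.
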