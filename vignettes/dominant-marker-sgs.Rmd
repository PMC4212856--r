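---
title: "Spatial genetic structure and inbreeding from dominant AFLP markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial genetic structure and inbreeding from dominant AFLP markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

AFLP and similar dominant fingerprinting methods score each locus as band
presence (1) or absence (0).  Band absence is the homozygous null genotype,
so heterozygotes are invisible: allele frequencies, diversity,
differentiation, kinship and inbreeding must all be *inferred* from binary
phenotypes under Hardy–Weinberg-style assumptions rather than counted.
`aflpsgs` implements a complete analysis chain for spatially sampled
dominant-marker data — the kind produced by patch-based field designs where
a "population" is a handful of individuals collected at a single point
(e.g. insects from one fungal sporocarp), with patches spread from metres
to hundreds of kilometres:

1. data model, TSV IO, locus filtering, great-circle distances;
2. Bayesian allele-frequency estimation with a moment-matched beta prior,
   diversity (PLP, Hj) and moment FST with its linearized form;
3. pairwise multilocus kinship for dominant phenotypes;
4. distance-class autocorrelograms with permutation envelopes and
   jackknife-over-loci errors, log-distance regression, the Sp index, and
   Mantel tests;
5. an FST-outlier neutrality scan against a simulated island-model null;
6. Bayesian estimation of individual inbreeding coefficients by
   Metropolis-within-Gibbs MCMC;
7. seeded synthetic-data generators with known truth, and a pipeline
   (`run_full_analysis()`) wiring the stages in the standard order
   (filter → diversity → outlier removal → FST/Mantel → kinship/SGS/Sp →
   inbreeding).

# Models and estimators

## Allele frequencies from dominant phenotypes

With null-allele frequency $q$, the band-absence phenotype frequency is
$x = q^2$ under Hardy–Weinberg.  Across loci, observed band-absence
proportions are fitted by a $\mathrm{Beta}(a,b)$ prior via method of
moments (`fit_phenotype_prior()`); given $n_0$ absences out of $n$
individuals the posterior of $x$ is $\mathrm{Beta}(a+n_0,\,b+n-n_0)$ and
the point estimate is the posterior mean of $\sqrt{x}$,

$$\hat q \;=\; \frac{B(a+n_0+\tfrac12,\; b+n-n_0)}{B(a+n_0,\; b+n-n_0)}.$$

The moment matching falls back to the uniform prior when the across-locus
variance is degenerate or incompatible with a beta law.  Per-locus gene
diversity uses the small-sample correction
$H_j = 2\hat q(1-\hat q)\cdot 2n/(2n-1)$; PLP applies the 5% criterion to
the minor *allele* frequency.

## FST

The moment estimator divides the across-population variance of $\hat q$
(population divisor $r$, so two completely fixed demes give $F_{ST} = 1$),
minus a sampling-variance correction, by $\bar w^2\,\bar q(1-\bar q)$,
summing numerators and denominators over loci before taking the ratio
(ratio-of-sums).  Because dominant-marker frequency estimates are noisier
than allele counting, the correction is not the binomial-allele
$\bar q(1-\bar q)/(2n)$ but the delta-method variance of the
posterior-mean-sqrt estimator, $w_i^2(1-\hat q_i^2)/(4 n_i)$ with shrink
factor $w_i = n_i/(n_i+a+b)$; the same shrink deflates the across-deme
spread, hence the $\bar w^2$ in the denominator.  Without the
dominant-specific correction, pseudo-populations cut from a single
panmictic pool show a spurious $F_{ST}$ of about $+0.01$ at $n = 30$.
Negative estimates are truncated at zero, and $F_{ST}/(1-F_{ST})$ is
provided for isolation-by-distance regressions.  Beyond this variance
correction the estimates are treated as observed frequencies; residual
uncertainty is not propagated further.

## Kinship from dominant phenotypes

For a pair of non-inbred individuals with kinship $\theta$, the
band-presence indicators at a locus with null frequency $q$ and presence
frequency $p = 1-q^2$ satisfy, to first order in $\theta$,
$\mathrm{corr}(Y_i, Y_j) = 4\theta q/(1+q)$.  This yields per-locus
components

$$c_\ell = (Y_{i\ell}-p_\ell)(Y_{j\ell}-p_\ell), \qquad
  w_\ell = \frac{4 q_\ell\, p_\ell (1-p_\ell)}{1+q_\ell},$$

and the multilocus estimate $\hat\theta_{ij} = \sum_\ell c_\ell / \sum_\ell
w_\ell$ over pairwise-complete, polymorphic loci.  Full enumeration of the
genotype configurations (tested in the suite) shows the estimator is
*exactly* unbiased for relationship classes without a double-IBD mode
(unrelated: 0; parent–offspring: 1/4) and biased upward where double IBD
occurs — $(1+3q)/(16q)$ per locus for full sibs, $(1+q)/(4q)$ for clones.
The bias is documented, asserted by the enumeration oracle, and left
uncorrected, matching standard dominant-marker practice.  Reference
frequencies are pooled over all individuals; an optional adjustment
replaces $p$ by $1-q^2-Fq(1-q)$ for a nonzero population inbreeding
coefficient.

## Autocorrelogram, Sp and Mantel test

Pairs are binned by great-circle distance into doubling classes
$\{0\}, (0,w], (w,2w], (2w,4w], \dots$ (defaults reproduce the
0/10/20/40/80/160/>160 km scheme; class 0 holds within-patch pairs).  Per
class the mean kinship is reported with

* a null envelope (2.5/97.5 percentiles) from random permutations of
  individual *locations* (joint row/column permutation of the distance
  matrix against the fixed kinship matrix; 9,999 permutations by default),
  and
* a jackknife-over-loci standard error, recomputing every pair's
  $\hat\theta$ from the stored per-locus components with one locus deleted
  at a time, $SE = \sqrt{\frac{L-1}{L}\sum_\ell (\bar f_{(-\ell)}-\bar
  f_{(\cdot)})^2}$.

The intensity of structure is summarized by the Sp index
$Sp = -b_1/(1-f_1)$, where $b_1$ is the OLS slope of pairwise kinship on
$\ln(\mathrm{km})$ over all positive-distance pairs and $f_1$ the mean
kinship of the first (within-patch) class; within-patch pairs enter $f_1$
but not the regression since $\ln 0$ is undefined.  Slope and Sp standard
errors come from the same leave-one-locus-out jackknife.  The package's
joint detection rule (`sgs_detected()`) requires first-class kinship above
the envelope *and* $b_1 < 0$ with $|b_1| > 2\,SE$.

The Mantel test correlates upper triangles of a genetic distance matrix
(typically $F_{ST}/(1-F_{ST})$) and log geographic distance, with
$p = (1 + \#\{r_{perm} \ge r\})/(1 + n_{perm})$, one-sided for positive
association (two-sided by flag).

## FST-outlier scan

The neutrality scan compares each locus' $(H_e, F_{ST})$ to a cloud of
loci simulated under a neutral island model: ancestral frequency from the
fitted prior (allele scale $q=\sqrt{x}$), per-deme frequencies from the
Balding–Nichols law $\mathrm{Beta}(q(1-F)/F, (1-q)(1-F)/F)$, dominant
phenotypes at the observed per-deme sample sizes, then the same estimator
stack as the data.  Because dominant data are intrinsically biallelic,
this biallelic draw plays the role that infinite-alleles simulators play
for codominant scans.  A locus' quantile is its FST rank among the
`k_neighbors` simulated loci nearest in $H_e$ (a bin-free conditional
quantile); loci above 0.99 are candidates for directional selection and
below 0.01 for stabilizing selection, and flagged loci are removed before
the SGS and inbreeding stages.

Two numerical choices matter at the small per-deme sizes typical of patch
sampling.  First, the same prior is used on the observed and simulated
sides, so both share the estimator's shrinkage.  Second, the per-locus
FST estimate is biased toward zero at small $n$ even after a delta-method
sampling correction and a de-shrunk denominator, so `simulate_null_cloud()`
first runs a pilot draw at the requested target, measures the residual
multiplicative bias of the true-FST → estimate map, and simulates the
final cloud at the inverted parameter.  The cloud's trimmed-mean FST is
thereby centred on the target — which is what the single-pass calibration
(target = trimmed mean of the central 70% of observed per-locus FST)
assumes.  Without this the 0.99-quantile false-positive rate on neutral
15-deme, n=9 data is roughly trebled.

## Inbreeding MCMC

The inbreeding model treats each individual's coefficient $F_i$ and each
locus' null frequency $q_\ell$ as unknowns with

$$P(Y_{i\ell} = 0) = q_\ell^2 + F_i\, q_\ell (1-q_\ell),$$

iid $\mathrm{Beta}(\alpha,\beta)$ priors on the $F_i$ and flat priors on
the $q_\ell$.  Sampling is Metropolis-within-Gibbs with random-walk
proposals on the logit scale, adaptively tuned to 20–45% acceptance during
burn-in and frozen afterwards; each sweep also performs a joint *ridge
move* — a common logit shift of all $F_i$ with deterministic per-locus
adjustment of $q_\ell$ preserving the population-mean absence probability,
accepted with the exact Jacobian.  Correctness is guarded by two oracles
in the test suite: with the likelihood silenced the sampled $F_i$ marginal
reproduces its beta prior (Kolmogorov–Smirnov), and on a 2×2 fixture the
posterior mean matches two-dimensional quadrature.

**Identifiability, and why the shapes can be estimated.**  For a single
population the likelihood is nearly flat along a ridge that trades the
*mean* of the $F_i$ against the $q_\ell$: any common shift of the
inbreeding coefficients can be almost exactly absorbed by per-locus
frequency adjustments (the package's profile-likelihood check finds ~2 log
units across mean F from 0.05 to 0.65 at 150 individuals × 80 loci).
Only the *differences* among individuals are well identified.  Two
consequences:

* Under a **fixed** beta prior the posterior of the average F simply
  reproduces the prior mean $\alpha/(\alpha+\beta)$ — the induced prior on
  the mean of 150 iid $F_i$ has a standard deviation of a few hundredths.
  The three-prior sensitivity harness (`prior_sensitivity()`, defaults
  $a=b\in\{0.1,1,5\}$, all with prior mean 0.5) therefore reports
  reassuringly consistent estimates *because of* the prior, not the data.
* With `estimate_shapes = TRUE` the shapes become parameters (random-walk
  Metropolis on the log scale under weak lognormal hyperpriors) and the
  supplied $(\alpha, \beta)$ act as initializations.  The posterior of the
  average F is then honestly *wide*, reflecting the ridge.  Even so, its
  location is driven by prior volume rather than data: simulation at
  150 × 80 shows credible intervals that need not cover a true mean F —
  average inbreeding is, for practical purposes, not recoverable from
  single-population dominant data of this size, and the package documents
  rather than hides this limit.  Per-individual $F_i$ contrasts remain
  meaningful.

Average F is recorded per kept sweep as the mean of the current $F_i$;
summaries (posterior mean, 95% credible interval, per-individual
summaries, mean/SD of the data log-likelihood, acceptance rates) use the
post-burn-in, thinned records.  Full-scale runs use 100,000 sweeps after
10,000 burn-in; the test suite uses 20,000-sweep chains so the recovery
study fits in a routine test run.

# Synthetic data: what it emulates and what it does not

All generators are seeded, return a truth record sufficient to recompute
every expectation asserted in the tests, and write round-trip-safe TSVs.

* `gen_unstructured()` — Hardy–Weinberg panmixia; patches of ~10
  individuals placed uniformly in a 300 km square (the null for
  permutation and type-I checks).
* `gen_island()` — Balding–Nichols island model at a known FST (ancestral
  $q \sim U(0.1, 0.9)$); calibration oracle for FST recovery and the
  outlier scan.
* `gen_related_pairs()` — founder genotypes plus Mendelian transmission
  for unrelated/parent–offspring/full-sib/self pairs (truth kinship 0,
  1/4, 1/4, 1/2); oracle for the kinship estimator.
* `gen_inbred()` — $F_i \sim$ Beta with chosen mean and concentration
  (default concentration 5, moderate heterogeneity); band absence with
  probability $q^2 + F_i q(1-q)$.
* `gen_ibd_landscape()` — forward-time drift–migration simulation on a
  square lattice (default 20×20 demes of 50 diploids, 200 generations,
  100 loci).  Dispersal follows a geometric random-walk kernel: a gene's
  parental deme is reached by a nearest-neighbour walk of length
  $K \sim \mathrm{Geometric}(1-m)$, i.e. migration matrix
  $(1-m)(I-mP)^{-1}$.  Small $m$ is classic stepping-stone migration and
  generates isolation by distance; $m = 1$ is the walk's stationary
  distribution, i.e. full mixing, so one parameter spans both controls
  continuously.  Sampled individuals are drawn from the post-migration
  parental pool (at $m=1$ exactly the global pool, so the panmictic
  control carries no residual within-deme family structure).  The default
  sampling layout (`patch_layout = "multiscale"`) picks 15 demes at
  roughly log-spaced distances from a random anchor, mirroring field
  designs that need pairs from within-patch to full-extent distances —
  with purely random patch placement almost no pairs fall inside the
  kinship decay range and the positive control has little power.  The
  truth record stores initial and final deme frequencies (full history
  under `store_history = TRUE`).

What passing tests on these data do *not* show: robustness to scoring
error and band homoplasy (phenotypes are generated error-free), linked
loci (all loci independent), non-equilibrium demography beyond the
simulated drift phase, and continuous-space dispersal (demes are
discrete).  Real AFLP data also carry locus-quality heterogeneity that
the frequency filter only partially removes.

# Numerical choices and degenerate inputs

* Missing scores (`?` on disk) are masked; all frequencies are computed
  over non-missing entries; kinship uses pairwise-complete loci and flags
  pairs with fewer than 10 usable loci.
* The locus filter keeps the open band $0.03 < f < 0.97$ on the
  band-presence frequency (strict at both edges); filtering is idempotent.
* Monomorphic loci ($q \in \{0,1\}$) are excluded from kinship sums as a
  signal, not an error; an all-loci-dropped filter result warns and
  returns an empty dataset.
* Distances use the haversine formula with mean Earth radius
  6371.0088 km; no projection, since spherical error is negligible at a
  ~300 km extent.  Same-patch pairs are exactly 0 km.
* Permutation p-values use the add-one convention
  $(1+\#)/(1+n_{perm})$, so $p \in (0, 1]$; envelopes use empirical
  2.5/97.5 percentiles of the permuted class means.
* MCMC proposals are clamped to $(10^{-12}, 1-10^{-12})$; non-finite
  initial likelihoods trigger re-initialization (up to 10 attempts).
* Chains, permutation tests and generators take explicit seeds; identical
  seed and settings reproduce results bit for bit.

# Problem sizes used by the test suite

Tests run at deliberately chosen sizes: 10,000 simulated pairs × 100 loci
for kinship means; 10 demes × 30 individuals × 200 loci for FST recovery;
1,000 null replicates for the Mantel type-I study; 200 replicates of
100 × 100 for envelope coverage; a 5,000-iteration cloud over 15 demes of
9 for the outlier false-positive rate; twenty 20,000-sweep chains at
150 × 80 for the inbreeding recovery study; and twenty positive plus
twenty panmictic 20×20-lattice landscapes for end-to-end detection.  These
sizes give Monte-Carlo noise comfortably below the asserted tolerances.

# Known limitations

* Mean inbreeding from single-population dominant data is essentially
  unidentified (see above); reported average-F posteriors are
  prior-driven under fixed shapes and honestly wide under estimated
  shapes.
* The kinship estimator's full-sib/clone bias is documented, not
  corrected; mean kinship over pair sets mixing relationship classes will
  be slightly inflated where double-IBD classes are common.
* FST treats estimated frequencies as observed; at per-patch sizes below
  ~10 the outlier-scan estimator (with its pilot calibration) should be
  used for per-locus work rather than the plain moment ratio.
* The Mantel test inherits the usual caveats of matrix permutation tests
  under spatial autocorrelation; the individual-based correlogram is the
  more sensitive instrument, which is precisely the comparison the
  pipeline enables.
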