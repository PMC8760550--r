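---
title: "Methods: normalization, archetypal stratification and matched models in plasmarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, archetypal stratification and matched models in plasmarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmarch)
```

`plasmarch` analyses plasma profiles from antibody suspension bead arrays
(SBA): positive median fluorescence intensities (MFI) for a few hundred to a
thousand antibodies measured across hundreds of samples laid out on 96-well
plates, in a 1:2 age- and site-matched case-control design with technical
replicate pairs, repeated-visit ("double") pairs and plasma-pool wells. This
vignette documents the statistical model behind each stage, the tunable
parameters and the reasoning behind defaults, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## The intensity model

All modelling happens on the log-MFI scale. The generator — and, implicitly,
the normalization and adjustment stages that undo its nuisance terms — treats
the log intensity of sample $i$ at antibody $j$ as

$$\log x_{ij} = b_j + \sum_a \alpha_{ia} Z_{aj} + u_{s(i),j}
  + \sum_c \beta_{cj}\,(w_{ic}-\bar w_c) + m_j\,\mathbf 1[\text{MHT ever}]
  + \pi_{p(i),j} + d_i + \varepsilon_{ij},$$

with antibody baseline $b_j$, archetype weights $\alpha_i$ on the probability
simplex and archetype effects $Z$, a per-subject biological deviation
$u_{s(i),j}$, linear covariate effects (BMI, age, entry date), an MHT-ever
signature $m_j$, a per-plate batch offset $\pi$, a per-sample log dilution
$d_i$, and residual noise $\varepsilon$. Technical replicate pairs share
everything except $d_i$ and $\varepsilon$; double pairs additionally differ
by a per-subject drift vector added to the second visit.

The subject term $u$ deserves a note: without it, an antibody whose archetype
loadings happen to be small has essentially no between-sample biological
variance, and its replicate-pair correlation collapses to zero even though
the assay is flawless — which would make reproducibility-based QC meaningless.
Plasma proteomes show strong inter-individual variation even in healthy
donors, so the generator includes it (default sd 0.3 log units) and defines
archetype separation relative to the within-archetype spread
$\sqrt{\sigma_\varepsilon^2 + \sigma_u^2}$.

## Normalization

**Abs-PQN** (within plate). Classical probabilistic quotient normalization
estimates one dilution factor per sample as the median quotient against a
reference profile. The antibody-specific variant computes, for each antibody
$j$, the factor from the `n_similar` antibodies most Spearman-correlated
with $j$ on the plate (including $j$), so antibodies responding to different
sample-level processes are normalized against their own kind. Defaults:
`n_similar = 50`; with `n_similar = p` the method reduces exactly to
classical PQN, which the tests assert against an independently coded oracle.
Ties in the correlation ranking break by antibody id; pools and buffer wells
are excluded from the reference but transformed with their own quotients.
Quotients are median-based, so the estimate is robust as long as fewer than
half of the similarity set carries a differential signal.

**MA normalization** (between plates). Per antibody, the global reference is
the median log intensity over all non-pool samples; per plate, $M$ is the
plate median minus the reference and $A$ their mean. A lowess fit of $M$ on
$A$ across antibodies (default span 0.3) estimates the intensity-dependent
plate offset, which is subtracted from all of the plate's samples. The fit
assumes plate effects are smooth in intensity and that most antibodies are
not differentially abundant between plates — reasonable when samples are
randomized across plates, as the matched-trio plate layout guarantees.
Because the smoother works against measured intensity, a planted effect that
is linear in the *latent* baseline is only fully removed when biological
variance is small relative to the baseline spread; the derived test uses
such a configuration.

## Antibody quality control

Three exclusion criteria, evaluated per antibody on normalized data:
replicate Spearman correlation below `rho_rep = 0.7` across duplicated
samples; Spearman correlation above `rho_igg = 0.5` with per-sample IgG
levels (an antibody tracking bulk immunoglobulin rather than its target);
and buffer-well MFI above `mean + 3 sd` of the study-sample MFI. Whether IgG
correlation is computed on raw or normalized values is configurable
(normalized by default — the statistic should reflect the data entering the
analysis). Among surviving antibodies sharing a target gene, the one with
the highest replicate correlation is kept (ties by antibody id):
reproducibility is the assay's primary QC axis, so it is also the natural
keep-rule. Replicate samples, pools and (per analysis stage, not globally)
samples with missing required covariates are dropped.

## Covariate adjustment

One joint OLS of log MFI on intercept + BMI + age + entry date per antibody;
two-sided t-tests per coefficient; residualization replaces each value by
the residual plus the fitted intercept, i.e. subtracts the estimated
covariate contributions. Coefficients come from study samples only and are
applied to held-out doubles/replicates, keeping the held-out samples
strictly out of the estimation. Residuals are exactly orthogonal to the
covariates, adjustment is idempotent, and entry date is encoded as integer
days since the earliest sample. Adjusted values stay on the log scale for
all downstream analysis.

A calibration caveat the tests make explicit: with latent low-rank structure
(archetypes) in the data, per-antibody p-values are strongly positively
dependent — a chance correlation between an archetype weight and a covariate
(or case status) lifts every antibody loading on that archetype. Uniformity
of the null p-value distribution therefore holds exactly only in
factor-free configurations, and rare correlated bursts of nominal findings
are expected otherwise. This mirrors real cohorts, where protein panels
share systemic drivers.

## Archetypal analysis

The decomposition $X \approx \alpha Z$, $Z = \beta X$, with rows of $\alpha$
($n \times k$) and $\beta$ ($k \times n$) on the simplex, frames each sample
as a convex mixture of $k$ extreme profiles lying in the convex hull of the
data. Fitting alternates two exact block solves: each $\alpha$ row is a
simplex-constrained least-squares projection onto the current archetypes,
and each $\beta$ row solves the same problem for the unconstrained optimal
archetypes $\tilde Z = (\alpha^\top\alpha)^{-1}\alpha^\top X$. The simplex
constraint is enforced by non-negative least squares on a penalty-augmented
system (weight $200\max|X|$ on the sum-to-one row — the classical device),
solved with a compiled active-set NNLS on the normal equations; rows are
renormalized to remove the $O(M^{-2})$ penalty slack. Initialization is
furthest-sum over data rows, best of `restarts = 5` seeded starts;
convergence at relative RSS decrease below `tol = 1e-6` or 200 iterations.
The two-step update is not strictly monotone in exact arithmetic, so the
fitter tracks the best state and stops at the first RSS increase beyond
relative `1e-9`, which makes the recorded RSS history non-increasing by
construction. An independent projected-gradient solver in the test suite
confirms the optima.

**Choosing k.** The RSS curve over `k_range` is scaled to the unit square on
both axes and the knee is the point of maximum perpendicular distance to the
chord joining its endpoints (unit-invariant by construction). Ties, and the
degenerate strictly-linear curve, resolve toward the smallest k (parsimony).
A non-monotone curve triggers one refit with doubled restarts, then an
error. Samples are assigned to their largest coefficient (ties toward the
lowest archetype index); held-out samples are projected onto the fixed
archetypes by the same constrained solve, leaving the archetypes untouched.

## Stability and concordance

Cluster stability is the mean Jaccard index over `B = 150` bootstrap
resamples: refit at the same k on each resample, and for each reference
cluster take the best-matching Jaccard overlap computed on the set of
distinct drawn samples (the resampling-convention used by standard
cluster-wise bootstrap stability assessments; computing instead on all
samples via prediction is a coherent alternative but changes the statistic's
meaning, so only the drawn-set convention is implemented). Values near 1
indicate clusters that re-form under perturbation; values below ~0.6
indicate arbitrary partitions — the tests calibrate both ends on separated
clouds and on a single Gaussian blob forced into k = 3.

Pair concordance compares how often replicate, double and random pairs land
in the same cluster, with two-sided Fisher exact tests on the 2x2
same/different-by-type tables (a permutation alternative would condition on
the pair sets; Fisher on the aggregated table is the simpler and adequate
choice at these counts). The planted-hierarchy experiment fixes technical
noise (0.05-0.07 log units) well below biological drift (1.8) well below
vertex separation (~10 across 60 antibodies), and uses a flatter archetype
weight distribution (`dirichlet_alpha = 1`) so that samples actually
populate the decision boundaries: with the default 0.3 nearly all samples
sit near vertices and almost no drift magnitude flips cluster membership,
which would leave the replicate-versus-double contrast untestable. Note that
in high dimensions only the drift component within the archetype subspace
moves assignments, so drift per antibody must be read against the simplex
geometry, not the noise sd.

## Cluster characterization

Continuous clinical variables use two-sided Wilcoxon rank-sum tests (cluster
vs rest and all cluster pairs; polygenic scores enter as absolute values),
categorical variables use Fisher's exact test with missing values excluded.
The r x c Fisher p-value uses the exact network algorithm where feasible and
seeded Monte Carlo with the conditional-probability ordering otherwise;
tests confirm the 2x2 path against a direct hypergeometric summation and
Monte Carlo convergence by doubling draws.

Differential abundance is a per-antibody Welch t-test (unequal variances —
the conservative reading of "two-tailed t-test") of the cluster against all
remaining samples on adjusted log values, BH-corrected across antibodies.
Shortlisting takes, within each direction, the union of the `m = 25`
lowest-p and `m` largest-|difference| antibodies (between m and 2m members).
Fold changes are signed ratios of linear-scale medians, computed on
normalized pre-adjustment MFI by default (the scale is configurable since
either convention is defensible): +2 means the cluster median doubles the
rest, -2 halves it. Trait association fits, per shortlisted protein, a
linear model of BMI- and age-adjusted dense area on the protein and a
binomial logistic model of MHT ever-use (before or current vs never; a
three-level multinomial coding is available behind `mht_coding =
"three_level"`), with complete-separation failures reported and skipped.

## Matched case-control models

For 1:M matched sets with one case each, the conditional likelihood
$\prod_s e^{\eta_{\text{case}}} / \sum_{l \in s} e^{\eta_l}$ eliminates the
per-set intercept. It is maximized by Newton-Raphson with step-halving from
$\beta = 0$, convergence at $|\Delta\ell| < 10^{-10}$, Wald tests per term.
Sets with any missing model covariate are dropped whole (the likelihood
stays well-formed; per-model sample counts then differ naturally), sets
without within-set exposure variation contribute a constant, and a fully
uninformative screen returns $\beta = 0$ by convention. Proteins are
z-scaled before fitting so screen coefficients are per-sd. The three
covariate models: (1) BMI + entry date; (2) + dense area, postmenopausal
status, MHT ever; (3) + smoking, alcohol, parity. Tests verify the 1:1
discordant-pair closed form, numerical agreement with the paired-difference
logistic identity and with `survival::clogit`, unbiased recovery of a
planted continuous effect, and permutation-null uniformity.

## What the generator does and does not emulate

Emulated: log-normal MFI with a floor at 1.0 (intensities are positive and
log-transformed downstream); per-sample dilution; per-plate (optionally
intensity-dependent) batch effects; matched trios, doubles, replicates and
pools co-located on 96-well plates (4 pool wells per plate); missingness
completely at random at the cohort's observed per-column rates; planted
archetype structure, covariate and MHT effects; duplicate-target antibodies
sharing biology; and the three defect classes, planted so the QC formulas
flag them by construction. Entry dates are uniform over a 600-day window
with second visits 325-605 days later; defaults for cohort composition
(183 cases, 366 controls, 30 doubles, 48 replicate pairs, ~1/3 duplicate
targets) match the study design the package addresses.

Not emulated: bead counts, saturation curves or any assay biochemistry
(effects are planted directly at the log-intensity level); drug-registry
detail beyond a three-level MHT/statin status; genotypes (the polygenic
score is a numeric covariate); and real correlation structure between
clinical covariates beyond age-menopause-MHT dependence. Passing tests
therefore demonstrate that the algorithms recover structure of the assumed
form at realistic sizes and noise — not that real cohorts satisfy those
assumptions. The MHT signature magnitude is a free parameter (default 0.5
log units on 10% of antibodies) since no literature value exists for it.

## Problem sizes and numerical conventions

The test and acceptance experiments use desk-scale cohorts chosen to make
each property measurable: archetype recovery at n = 500 study samples, 100
antibodies, k = 5, 20 seeds; stability calibration at B = 50; the screen
null at 60 matched sets and 200 antibodies over 20 cohort realizations; FDR
null over 100 label permutations. Degenerate inputs are contracts, not
accidents: empty similarity sets cannot occur (self-inclusion), plates need
3 samples for a median reference and 2 plates for MA, clusters need 3
members per side for a t-test, and zero-margin contingency tables raise
rather than return 1. All seeds flow through configuration objects or
function arguments; identical seeds give byte-identical outputs, and
per-stage pipeline seeds derive deterministically from the master seed so
stages can be rerun in isolation.

## Known limitations

The conditional-logistic screen fits proteins marginally, so latent factors
shared across proteins make screen p-values positively dependent;
Benjamini-Hochberg keeps the FDR controlled on average, but occasional
correlated bursts of nominal findings are expected and observed (in
synthetic and published cohorts alike). The MA smoother cannot distinguish
a plate effect from genuine plate-level biology if randomization is broken.
Archetypal analysis assumes convex mixture structure; for data with curved
or disconnected support the archetypes remain well-defined hull points but
the coefficient-based clusters lose interpretability, which is what the MJI
is there to flag. Soft ("in-between") memberships are deliberately not
propagated into downstream contrasts.
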