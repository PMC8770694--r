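---
title: "Methods: cranial shape analysis on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cranial shape analysis on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery it
implements, the assumptions behind it, and the design decisions taken where
the methodology left genuine choices open.

## Superimposition

Landmark configurations enter analysis as k × 3 matrices in scanner units
(mm).  `gpa()` performs full generalized Procrustes analysis: each
configuration is centred at the origin, scaled to unit centroid size
(CS = √Σ‖xᵢ − x̄‖², the standard geometric-morphometric size measure,
computed on the raw coordinates *before* scaling so that
`log_centroid_size` retains its mm scale), and rotated onto the running
consensus by rotation-only orthogonal Procrustes.  Reflections are
disallowed by construction: the SVD-based rotation enforces det = +1 by
flipping the sign of the singular vector associated with the smallest
singular value.  The consensus (per-landmark mean, re-normalised to unit
size) is updated until its summed squared displacement falls below 1e-10,
with a 100-iteration cap and a `converged` flag.

Aligned coordinates are treated directly as Euclidean (tangent-space)
coordinates; no separate orthogonal projection is applied.  This is the
convention of the major morphometric toolkits and is accurate when shape
variation is small relative to the curvature of shape space, as it is for
within-family cranial variation; it is a documented approximation, not an
exact identity.

Missing landmarks are estimated before superimposition by a 3D thin-plate
spline (`estimate_missing_tps()`), kernel U(r) = r with an affine part, fit
from a reference configuration's positions at the specimen's observed
landmarks to the observed positions and evaluated at the reference
positions of the missing ones.  TPS reproduces affine maps exactly and
requires at least four non-coplanar anchors.  When several references are
available their GPA consensus at their mean centroid size is used;
`estimate_missing_all()` prefers complete conspecific specimens and falls
back to the grand pool, the least biased reference available when the
reference choice is not otherwise specified.

## Permutation linear models (RRPP)

`rrpp_lm()` fits multivariate linear models to shape with sequential
(Type I) sums of squares, computed as differences in residual traces
between nested designs.  Significance uses residual randomization: for
each term, the residuals of its reduced (preceding) model are permuted and
added back to the reduced fitted values, and the term's pseudo-F is
recomputed; the observed arrangement is included in the reference set, so
the smallest attainable p-value is 1/(n_perm + 1).  The default 999
permutations is the convention of the permutation-ANOVA literature this
design follows; every fit records its seed and permutation schedule so
downstream pairwise tests reuse exactly the same draws.  Effect sizes Z
are standardized deviates of log F within the permutation distribution;
log F is used because the permutation distribution of F is strongly
right-skewed.

In `pgls` mode both the response and the design are pre-multiplied by
C^(−1/2), where C is the Brownian-motion covariance implied by the tree
(shared path lengths).  We use the *symmetric* inverse square root
EΛ^(−1/2)Eᵀ rather than Λ^(−1/2)Eᵀ: the two give identical sums of squares
and F for the observed data, but when C has repeated eigenvalues (the
star-tree limit) the eigenvector basis is arbitrary, and only the
symmetric root reduces to a scaled identity there — which is what makes
ordinary and phylogenetic fits coincide exactly, permutation distributions
included, on a star phylogeny.  Categorical predictors use treatment
contrasts with the default (alphabetical) reference level; reported group
comparisons are least-squares means, not raw coefficients, so the contrast
choice does not affect results.

Pairwise comparisons (`pairwise_groups()`) test either distances between
least-squares group means (covariates held at their mean) or, for
interaction models, differences between per-group slope vectors in length
and in angle.  The null model for means omits every term involving the
grouping factor; for slopes it omits only the grouping × covariate
interaction, so group mean differences are preserved under the null.  For
models where a grouping interacts with a covariate, the interaction is
fitted as the last sequential term.

Designs produced by the ecology joins (species duplicated across habitat
or productivity categories) carry a flag that makes `rrpp_lm()` refuse a
tree: duplicated species violate the one-tip-per-row assumption of pgls,
so those models are ordinary least squares by construction.

## Phylogenetic signal, disparity, rates

`physignal_K()` implements the multivariate generalization of Blomberg's
K: the observed ratio of summed squared deviations from the GLS
(phylogenetically weighted) mean to the C⁻¹-weighted sums of squares,
divided by its Brownian expectation (tr C − n/Σ(C⁻¹))/(n − 1), with the
quadratic forms summed over trait dimensions.  K ≈ 1 under Brownian
motion; the permutation test shuffles species across tips.  The test suite
verifies the calibration directly: over 100 replicate 10-dimensional BM
datasets on a 50-tip tree, mean K falls in [0.9, 1.1].

Disparity is the Procrustes variance — the mean squared shape distance of
group members from their group mean — with pairwise absolute differences
tested by permuting group labels.  Evolutionary rates (σ²mult) are mean
squared phylogenetically whitened tip deviations summed over dimensions,
partitioned by group; the max/min rate ratio is tested against Brownian
simulation with the pooled rate, *not* against tip permutation, because
permuting tips would destroy the tree–data covariance the statistic
depends on.

## Modularity

The covariance ratio (CR) for a module pair is the Frobenius norm of the
between-module covariance block over the geometric mean of the
within-module off-diagonal norms; multi-module CR averages the pairwise
values, and CR < 1 indicates modularity.  The null reassigns whole
landmarks — their three coordinates travel together, because coordinates
of one landmark are not exchangeable — to modules of the same sizes.  In
phylogenetic mode the covariance matrix is the uncentered cross-product of
independent contrasts divided by the number of contrasts (contrasts have
expectation zero; centering them would break the exact equality with the
ordinary covariance on a star tree).

Module discovery clusters the rows of a landmark association matrix
(congruence coefficients of consensus-centered coordinate blocks, or the
Euclidean distance matrix of the PIC block-covariance matrix) by k-means
with 25 restarts, choosing k by the gap statistic with 100 uniform
reference sets and the "smallest k with Gap(k) ≥ Gap(k+1) − SE(k+1)" rule.
Gap-statistic selections are iteration-dependent in principle; seeding
makes them reproducible.  Discovered schemes with modules of fewer than
two landmarks are flagged and rejected by the CR and likelihood machinery,
since one- or two-coordinate modules are not biologically meaningful and
break the CR denominator.

The likelihood comparison (`emmli_compare()`) models Fisher-z transformed
pairwise coefficients as normal around a shared block correlation with
variance 1/(n_eff − 3), n_eff being the number of landmarks; the block MLE
is the closed-form mean Fisher-z (verified against a grid-search oracle in
the tests).  Models — a single global rho, per-module within rhos with one
between rho, and fully separate blocks — are ranked by AICc with Akaike
weights.  Because likelihood rises with parameter count almost
mechanically in this family, the result object reports the correlation
between log-likelihood and parameter count across models; a high value is
a warning that the ranking may reflect parametrization rather than
biology.

The five named anatomical schemes ship as editable character vectors over
the 31-landmark one-sided subset (all midline plus right-side landmarks,
i.e. landmarks 23–44 of the 53-landmark template removed).  Anatomical
module definitions at landmark resolution are inherently a curation
choice; the defaults assign the template's landmarks by cranial region and
are data, not code.

## The synthetic-data generator

`simulate_landmark_dataset()` emulates the structure of a multi-specimen
cranial dataset: 96 species on a dated pure-birth tree (root age 20 Myr,
about the crown age of Bovidae), 141 specimens (1–3 per species), 53
landmarks on a bilaterally symmetric polyhedral cranium of realistic size
(~300 mm), two scan-type labels with some species scanned with both, and a
species table with tribes (monophyletic groups cut from the tree),
subfamilies (the two root clades), diets with a tribe-level bias,
hypsodonty for a 57-species subset, and body mass tied to size.

Shape evolves by Brownian motion in the 3k-dimensional tangent space of
the unit-size template.  The rate matrix is built block-wise from a module
assignment and two correlations (within/between), then projected onto the
template's shape tangent space — the orthogonal complement of the seven
similarity directions (translations, rotations, scaling).  The projection
matters: an unprojected compound-symmetric module block is dominated by
module-rigid translation factors, which superimposition silently absorbs
(we measured a planted within-module correlation of 0.7 collapsing to
~0.01 after GPA without the projection).  Since pose is handled separately
— each specimen is randomly rotated, translated and scaled to its
centroid size before being handed to the readers/GPA, so the
superimposition path is genuinely exercised — Brownian shape variation
belongs in the tangent space by construction.

Defaults: per-coordinate shape rate 1e-6 per Myr (giving a realistic total
Procrustes variance of ~0.003 at the tree depth), log-size rate 0.01 per
Myr (size SD ≈ 0.45 log units, dik-dik to buffalo), allometric strength
0.05 Procrustes units per log-size unit (size then explains ~8% of shape,
matching the magnitude reported for real bovid crania), intraspecific
per-coordinate noise SD 0.0015 (conspecific specimens cluster together in
UPGMA phenograms but subsetting still moves results slightly), and no
planted modularity (uniform correlation 0.2).  The allometric direction is
a fixed facial-elongation-with-flexion vector, also projected into the
tangent space.

What the generator does *not* emulate: realistic cranial anatomy (the
template is a labelled polyhedron), horn morphology, sexual dimorphism
beyond a metadata flag, measurement error structured by landmark type,
Ornstein–Uhlenbeck or rate-shift evolution, and any geographic structure
beyond a skewed-abundance occurrence grid.  Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under its
own assumptions — not that real bovid data satisfy those assumptions.

## Numerical and testing choices

* GPA convergence 1e-10 (squared consensus displacement), max 100
  iterations; alignments in practice converge in 2–3.
* Permutation p-values always include the observed arrangement; with
  n_perm = 999 the p floor is 0.001.
* The central/peripheral split at the median distance breaks ties by
  species name, so the equal partition is deterministic.
* Faunal-list cutoffs include all species tied with the last retained rank
  ("most commonly occurring" is ranked within habitat); with fraction 1.0
  the lists equal the raw pools.
* NPP bins are equal-count quantile bins computed from the data at hand;
  the published global bin edges (0/115/320/580/1100) are kept as a
  constant for reruns against the original extraction.
* Degenerate inputs error early and specifically: coincident landmarks,
  coplanar TPS anchors, rank-deficient designs (naming the aliased
  columns), singleton disparity groups, undersized modules, constant
  association matrices.
* Distance-from-mean is computed in the full shape space by default
  (invariant to the number of PCs retained); pass PC scores to work in a
  subspace.
* Test problem sizes: the calibration suite uses 50-tip trees with 100
  replicates (phylogenetic signal), 1000 null simulations at n = 50
  (type-I error of ols and pgls RRPP), 50 replicates at the study's
  96-species scale for planted-modularity and module-discovery recovery,
  and 8 replicates per strength for allometry recovery, where the
  direction check compares the replicate-averaged slope vector with the
  planted vector (single-draw slopes carry 15–30° of phylogenetic
  pseudo-replication noise at n = 96, so the averaged estimator is the
  meaningful test of direction recovery).

## Known limitations

* Tangent-space approximation (no projection step) — adequate for
  small-scale variation, untested for very disparate shapes.
* pgls assumes pure Brownian covariance; no Pagel's lambda or OU
  transformations are offered.
* The rate comparison reports a single σ²mult scalar per group, not
  per-group rate matrices.
* EMMLi-style likelihoods treat pairwise coefficients as independent
  observations, which they are not; the AICc ranking should be read with
  the reported likelihood–parameter correlation in hand.
* Whitening by C^(−1/2) amplifies non-phylogenetic (measurement or
  intraspecific) noise on short branches; with one randomly chosen
  specimen per species, ordinary least squares can outperform pgls as an
  estimator of the allometric direction even when the residuals are
  phylogenetically structured.
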