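# craniomorph

`craniomorph` is an R package for three-dimensional geometric morphometric
analysis of cranial landmark data in a phylogenetic comparative framework.
It was built around a concrete scientific question — what shaped the
diversity of the bovid (antelope and relative) cranium: environmental
selection (diet, habitat, productivity), or intrinsic factors such as a
deeply conserved size–shape allometry, phylogenetic inertia, and anatomical
modularity? — and provides the full toolchain such a study needs, from
landmark files to comparative inference, together with a seeded
synthetic-data generator so every stage can be exercised and calibrated
without access to specimen scans.

## What it computes

Given landmark configurations (k named 3D landmarks per specimen), a dated
phylogeny and per-species trait tables, the package provides:

* **Superimposition and shape traits** — generalized Procrustes analysis
  (GPA): iterative translation to the origin, scaling to unit centroid size
  CS = √Σᵢ‖xᵢ − x̄‖², and rotation-only orthogonal Procrustes alignment to
  the consensus; thin-plate-spline estimation of missing landmarks; facial
  length index; the one-sided symmetric landmark subset.
* **Ordination** — PCA of the Procrustes coordinates, BM ancestral states,
  phylomorphospace scores, distance from the morphospace mean with an
  equal central/peripheral split, UPGMA phenograms.
* **Permutation linear models (RRPP)** — multivariate shape regressions and
  ANOVA with sequential (Type I) sums of squares, significance by residual
  randomization (permuting reduced-model residuals), effect sizes Z as
  standardized deviates of log F in the permutation distribution; `ols`
  mode, or `pgls` mode in which response and design are pre-multiplied by
  C^(−1/2) for the Brownian covariance C implied by the tree.  Pairwise
  group comparisons of least-squares means and of allometric slope vectors
  (length and angle).
* **Phylogenetic signal, disparity, rates** — the multivariate
  generalization of Blomberg's K (K ≈ 1 under Brownian motion), Procrustes
  variance disparity with label-permutation tests, and multivariate
  Brownian rate (σ²mult) comparisons whose null comes from simulating BM on
  the tree.
* **Modularity** — landmark congruence-coefficient and PIC-based covariance
  matrices; k-means + gap-statistic module discovery; the covariance ratio
  CR (between-module over within-module covariation, CR < 1 = modular) with
  a landmark-reassignment null, optionally on independent contrasts
  ("phylogenetic" mode); EMMLi-style maximum-likelihood comparison of
  modularity models ranked by AICc; between-clade contrasts of CR effect
  sizes.
* **Ecology** — occurrence-grid filtering (≥ 4 species per 1×1° cell,
  > 40 cells per habitat), per-habitat faunal lists of the top 100/50/20%
  most common species, equal-count NPP bins, and joins that deliberately
  refuse pgls fits on species duplicated across categories.
* **Synthetic data** — pure-birth trees, correlated Brownian traits, and
  full landmark datasets on a 53-landmark bilaterally symmetric cranial
  template, with a shared allometric axis, optional planted modular
  covariance, intraspecific noise, scan-type labels and random specimen
  poses, plus gridded occurrence tables.

## Worked example

Simulate a study-sized dataset (141 specimens, 96 species on a dated
pure-birth tree), take one specimen per species, superimpose, and ask the
study's core questions:

```r
library(craniomorph)

spec <- simulation_spec(seed = 42)            # 141 specimens / 96 species
sim  <- simulate_landmark_dataset(spec)
sub  <- phylogenetic_subset(sim$configs, seed = 42)
fit  <- gpa(sub)
fit
#> <procrustes_fit> 96 specimens x 53 landmarks; 2 iteration(s), converged=TRUE

Y <- flatten_coords(fit); rownames(Y) <- names(sub)
shape_pca(Y)
#> <shape_pca> 96 specimens, 96 dimensions; PC1-3: 25.4/13.8/7.1% of variance

physignal_K(Y, sim$tree, n_perm = 999, seed = 42)
#> <signal_result> K = 0.489, P = 0.001 (999 permutations)

dat <- data.frame(size = fit$log_centroid_size, row.names = names(sub))
rrpp_lm(Y ~ size, data = dat, tree = sim$tree, n_perm = 999, seed = 42)
#> <rrpp_fit> pgls, n = 96, 999 permutations
#>  term Df     SS     R2     F       Z     P
#>  size  1 0.0027 0.0833 8.539 10.5567 0.001

Ysym <- flatten_coords(symmetric_subset(fit)); rownames(Ysym) <- names(sub)
covariance_ratio(Ysym, module_schemes()$element, n_perm = 999, seed = 42,
                 phylogenetic = TRUE, tree = sim$tree)
#> <cr_result> CR = 1.083, Z = 0.15, P = 0.566 (phylogenetic, 999 permutations)
```

Reading the output: the first three PCs carry ~25/14/7% of shape variance;
phylogenetic signal in shape is significant but below the Brownian
expectation of 1 (homoplasy); log centroid size explains ~8% of shape
(a real but partial allometric signal, matching the generator's default
allometry strength); and with no planted modular covariance the nine-module
"element" scheme shows no modular signal (CR ≈ 1).  `run_pipeline()` wires
these stages (plus disparity, rates, and the modularity table over all five
anatomical schemes) into one seeded, byte-reproducible run that writes
CSV/JSON/Newick outputs.

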