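test_that("module schemes validate sizes and the named schemes are sound", {
  schemes <- module_schemes()
  expect_named(schemes, c("mammalia2", "tripartite", "four", "element",
                          "mammalia6"))
  for (nm in names(schemes)) {
    expect_length(schemes[[nm]], 31L)
    sch <- module_scheme(nm, schemes[[nm]])      # strict: must pass
    expect_gte(min(table(sch$assignment)), 2L)
  }
  expect_equal(length(unique(schemes$element)), 9L)
  expect_equal(length(unique(schemes$mammalia2)), 2L)
  expect_error(module_scheme("bad", c("a", "a", "b")), "< 2")
  expect_error(module_scheme("one", rep("a", 5L)), ">= 2 modules")
})

test_that("congruence matrix is symmetric with unit diagonal and sane limits", {
  set.seed(101)
  n <- 50L; k <- 6L
  Y <- matrix(rnorm(n * 3L * k), n)
  colnames(Y) <- as.vector(t(outer(paste0("L", 1:k), c("x", "y", "z"),
                                   paste, sep = ".")))
  # duplicate landmark 2 into landmark 5
  Y[, 13:15] <- Y[, 4:6]
  M <- congruence_matrix(Y)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, k))
  expect_equal(M[2L, 5L], 1, tolerance = 1e-12)
  off <- M[upper.tri(M)][-which(combn(k, 2L)[1L, ] == 2L & combn(k, 2L)[2L, ] == 5L)]
  expect_lt(max(abs(off)), 0.5)           # independent blocks stay near 0
  expect_lt(median(abs(off)), 0.2)
})

test_that("PIC covariance distances reduce to raw covariance on a star tree", {
  star <- ape::stree(30L, "star")
  star$edge.length <- rep(1, 30L)
  star$tip.label <- paste0("t", 1:30)
  set.seed(102)
  Y <- matrix(rnorm(30L * 12L), 30L)
  rownames(Y) <- star$tip.label
  colnames(Y) <- as.vector(t(outer(paste0("L", 1:4), c("x", "y", "z"),
                                   paste, sep = ".")))
  D_phy <- pic_covariance_matrix(Y, star)
  D_raw <- pic_covariance_matrix(Y, tree = NULL)
  expect_equal(unclass(D_phy), unclass(D_raw), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(D_phy >= 0))
})

test_that("independent contrasts match the 3-tip hand computation", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  y <- c(A = 1, B = 3, C = 8)
  contrasts <- craniomorph:::pic_matrix(matrix(y, ncol = 1L,
                                               dimnames = list(names(y), "t")), tree)
  # hand: c1 = (1-3)/sqrt(2); ancestor value (1+3)/2 = 2 with branch
  # 1 + 1*1/(1+1) = 1.5; c2 = (2-8)/sqrt(1.5+2)
  expect_setequal(round(as.numeric(contrasts), 10L),
                  round(c(-2 / sqrt(2), -6 / sqrt(3.5)), 10L))
})

test_that("gap-statistic clustering recovers a planted 3-block partition", {
  set.seed(103)
  k <- 24L
  truth <- rep(c("m1", "m2", "m3"), each = 8L)
  mod3 <- rep(truth, each = 3L)
  R <- ifelse(outer(mod3, mod3, `==`), 0.7, 0)
  diag(R) <- 1
  Y <- matrix(rnorm(80L * 3L * k), 80L) %*% chol(R)
  colnames(Y) <- as.vector(t(outer(paste0("L", 1:k), c("x", "y", "z"),
                                   paste, sep = ".")))
  km <- kmeans_gap_modules(congruence_matrix(Y), k_max = 6L, B = 50L, seed = 1L)
  expect_equal(km$chosen_k, 3L)
  tab <- table(km$scheme$assignment, truth)
  expect_equal(sum(apply(tab, 1L, max)), k)      # exact recovery up to labels
  # W_k decreases with k
  expect_true(all(diff(km$gap$logW) <= 1e-8))
  expect_error(kmeans_gap_modules(matrix(1, 5L, 5L), k_max = 3L), "degenerate")
})

test_that("covariance ratio detects planted modularity and respects the null", {
  schemes <- module_schemes()
  spec_mod <- simulation_spec(n_species = 64L, n_specimens = 64L,
                              module_assignment = schemes$mammalia2,
                              within_module_corr = 0.7,
                              between_module_corr = 0.1, seed = 111L)
  sim <- simulate_landmark_dataset(spec_mod)
  Ysym <- flatten_coords(symmetric_subset(gpa(sim$configs)))
  cr <- covariance_ratio(Ysym, schemes$mammalia2, n_perm = 199L, seed = 4L)
  expect_lt(cr$CR, 1)
  expect_lt(cr$Z, -2)
  expect_lte(cr$P, 0.05)
  # null distribution brackets 1
  expect_gt(quantile(cr$CR_null, 0.95), min(1, max(cr$CR_null)))
  expect_lt(min(cr$CR_null), 1.05)
  # invariance to module relabeling and landmark order within modules
  relabeled <- c(facial = "B", neurocranial = "A")[schemes$mammalia2]
  cr2 <- covariance_ratio(Ysym, relabeled, n_perm = 99L, seed = 4L)
  expect_equal(cr2$CR, cr$CR, tolerance = 1e-12)
  expect_error(covariance_ratio(Ysym, c(rep("a", 30L), "b"), n_perm = 99L),
               "< 2 landmarks")
})

test_that("phylogenetic CR equals non-phylogenetic CR on a star phylogeny", {
  schemes <- module_schemes()
  star <- ape::stree(40L, "star")
  star$edge.length <- rep(1, 40L)
  star$tip.label <- paste0("t", 1:40)
  set.seed(112)
  Y <- matrix(rnorm(40L * 93L), 40L)
  rownames(Y) <- star$tip.label
  colnames(Y) <- as.vector(t(outer(paste0("L", 1:31), c("x", "y", "z"),
                                   paste, sep = ".")))
  cr_raw <- covariance_ratio(Y, schemes$mammalia2, n_perm = 99L, seed = 1L)
  cr_phy <- covariance_ratio(Y, schemes$mammalia2, n_perm = 99L, seed = 1L,
                             phylogenetic = TRUE, tree = star)
  expect_equal(cr_phy$CR, cr_raw$CR, tolerance = 1e-8)
})

test_that("EMMLi block likelihood is maximized at the mean Fisher z", {
  set.seed(113)
  k <- 10L
  R <- diag(k)
  R[upper.tri(R)] <- runif(sum(upper.tri(R)), -0.3, 0.8)
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  z <- atanh(R[upper.tri(R)])
  # grid-search oracle over a single shared rho
  sdz <- 1 / sqrt(k - 3)
  grid <- seq(-0.99, 0.99, by = 1e-4)
  ll <- vapply(grid, function(r) sum(dnorm(z, atanh(r), sdz, log = TRUE)), 0)
  rho_grid <- grid[which.max(ll)]
  res <- emmli_compare(R, schemes = list(half = rep(c("a", "b"), each = 5L)),
                       rho_models = "within_between")
  rho_single <- res$rho[["none.single"]][["rho"]]
  expect_equal(rho_single, rho_grid, tolerance = 1e-3)
  expect_equal(max(res$table$weight),
               res$table$weight[which.min(res$table$AICc)])
})

test_that("EMMLi model selection recovers generating rho structure", {
  make_corr <- function(within, between, k = 20L) {
    half <- rep(c("a", "b"), each = k / 2L)
    R <- ifelse(outer(half, half, `==`), within, between)
    diag(R) <- 1
    set.seed(114)
    X <- matrix(rnorm(400L * k), 400L) %*% chol(R)
    cor(X)
  }
  scheme <- rep(c("a", "b"), each = 10L)
  # uniform rho: the single-rho model wins
  R_uni <- make_corr(0.4, 0.4)
  res_uni <- emmli_compare(R_uni, list(half = scheme))
  expect_equal(res_uni$table$model[1L], "single")
  # planted 2-module rho: within/between model beats single-rho
  R_mod <- make_corr(0.7, 0.1)
  res_mod <- emmli_compare(R_mod, list(half = scheme))
  expect_true(res_mod$table$model[1L] %in% c("within_between", "separate"))
  best <- res_mod$rho[[paste0("half.", res_mod$table$model[1L])]]
  expect_gt(best[["within.a"]], 0.55)
  expect_lt(best[["between"]], 0.3)
  # a block of identical trajectories estimates rho ~ 1
  R_id <- matrix(1, 6L, 6L)
  res_id <- emmli_compare(R_id, list(all2 = rep(c("a", "b"), each = 3L)),
                          rho_models = "within_between")
  expect_gt(res_id$rho[["none.single"]][["rho"]], 0.99)
})

test_that("modularity contrasts are null for identical processes and detect planted ones", {
  schemes <- module_schemes()
  spec_mod <- simulation_spec(n_species = 40L, n_specimens = 40L,
                              module_assignment = schemes$mammalia2,
                              within_module_corr = 0.7,
                              between_module_corr = 0.1, seed = 121L)
  spec_flat <- simulation_spec(n_species = 40L, n_specimens = 40L, seed = 122L)
  Ymod <- flatten_coords(symmetric_subset(gpa(simulate_landmark_dataset(spec_mod)$configs)))
  Yflat <- flatten_coords(symmetric_subset(gpa(simulate_landmark_dataset(spec_flat)$configs)))
  Y <- rbind(Ymod, Yflat)
  groups <- rep(c("modular", "flat"), each = 40L)
  res <- modularity_contrast(Y, schemes$mammalia2, groups,
                             n_perm = 49L, n_perm_cr = 49L, seed = 5L)
  # groups are sorted: group1 = "flat", group2 = "modular"; the modular
  # group must carry the more negative effect size
  expect_lt(res$Z2[1L], res$Z1[1L])
  expect_lte(res$P[1L], 0.1)
  # the whole sample duplicated: no contrast
  Ydup <- rbind(Ymod, Ymod)
  res0 <- modularity_contrast(Ydup, schemes$mammalia2,
                              rep(c("g1", "g2"), each = 40L),
                              n_perm = 49L, n_perm_cr = 49L, seed = 6L)
  expect_lt(abs(res0$dZ[1L]), 1)
  expect_gt(res0$P[1L], 0.1)
})
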