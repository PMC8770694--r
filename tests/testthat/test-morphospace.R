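test_that("shape PCA is complete and matches a direct eigendecomposition", {
  set.seed(71)
  Y <- matrix(rnorm(45), 5L, 9L)
  pc <- shape_pca(Y)
  # oracle: eigenvalues of the sample covariance matrix
  ev <- eigen(cov(Y), symmetric = TRUE)$values
  expect_equal(pc$eigenvalues[1:4], ev[1:4], tolerance = 1e-8)
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  recon <- sweep(pc$scores %*% t(pc$loadings), 2L, pc$center, `+`)
  expect_lt(max(abs(recon - Y)), 1e-9)
  expect_equal(sum(apply(pc$scores, 2L, var)), sum(apply(Y, 2L, var)),
               tolerance = 1e-9)
})

test_that("rank-one data load entirely on PC1", {
  set.seed(72)
  v <- rnorm(6L)
  Y <- outer(rnorm(10L), v)
  pc <- shape_pca(Y)
  expect_equal(pc$variance_fraction[1L], 1, tolerance = 1e-9)
  expect_error(shape_pca(Y[1:2, ]), "at least 3")
})

test_that("ancestral states match a brute-force GLS solve", {
  # oracle: weighted squared-change parsimony normal equations, solved
  # directly for all internal nodes with tips fixed
  brute_anc <- function(tree, y) {
    n <- ape::Ntip(tree); m <- tree$Nnode
    A <- matrix(0, m, m); b <- rep(0, m)
    for (e in seq_len(nrow(tree$edge))) {
      u <- tree$edge[e, 1L] - n; v <- tree$edge[e, 2L]; w <- 1 / tree$edge.length[e]
      A[u, u] <- A[u, u] + w
      if (v <= n) b[u] <- b[u] + w * y[tree$tip.label[v]]
      else { vi <- v - n; A[u, vi] <- A[u, vi] - w; A[vi, vi] <- A[vi, vi] + w
             A[vi, u] <- A[vi, u] - w }
    }
    solve(A, b)
  }
  for (seed in 1:3) {
    tree <- simulate_tree(4L, seed = seed, depth = NULL)
    y <- setNames(rnorm(4L), tree$tip.label)
    est <- ancestral_states_bm(tree, y)
    expect_equal(as.numeric(est), brute_anc(tree, y), tolerance = 1e-6)
  }
  # 2 tips, equal lengths: root is the midpoint
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(as.numeric(ancestral_states_bm(t2, c(A = 0, B = 2))), 1)
  # constant tips propagate unchanged
  t5 <- simulate_tree(5L, seed = 2L)
  est <- ancestral_states_bm(t5, setNames(rep(3.3, 5L), t5$tip.label))
  expect_equal(as.numeric(est), rep(3.3, t5$Nnode), tolerance = 1e-9)
  expect_error(ancestral_states_bm(t5, c(bad = 1)), "tips")
})

test_that("the ancestral root equals the pgls phylogenetic mean", {
  fx <- small_gpa()
  y <- fx$Y[, 1L]
  est <- ancestral_states_bm(fx$tree, setNames(y, rownames(fx$Y)))
  C <- ape::vcv(fx$tree)
  Cin <- solve(C)
  gls_mean <- sum(Cin %*% y[rownames(C)]) / sum(Cin)
  expect_equal(unname(est[1L, 1L]), gls_mean, tolerance = 1e-6)
})

test_that("phylomorphospace projects ancestors onto tip-defined axes", {
  fx <- small_gpa()
  pc <- shape_pca(fx$Y)
  pm <- phylomorphospace_scores(pc, fx$tree, fx$Y)
  expect_equal(nrow(pm$node_scores), fx$tree$Nnode)
  expect_equal(pm$tip_scores, pc$scores[fx$tree$tip.label, ])
  # root should sit well inside the tip cloud on PC1 (a mean-ish shape)
  expect_gt(pm$root_score[1L], min(pc$scores[, 1L]))
  expect_lt(pm$root_score[1L], max(pc$scores[, 1L]))
})

test_that("distance from mean and the central/peripheral split behave", {
  Y <- rbind(c(0, 0), c(2, 0), c(-2, 0), c(0, 1), c(1, 1), c(3, 3))
  rownames(Y) <- paste0("s", 1:6)
  dm <- distance_from_mean(Y)
  ctr <- colMeans(Y)
  expect_equal(dm$distance, sqrt(rowSums(sweep(Y, 2L, ctr)^2)),
               ignore_attr = TRUE)
  expect_equal(sum(dm$centrality == "central"), 3L)
  # point at the mean has distance zero
  Y0 <- rbind(a = c(1, 1), b = c(0, 0), c = c(2, 2))
  expect_equal(distance_from_mean(Y0)$distance[1L], 0)
  # symmetric points are equidistant
  expect_equal(distance_from_mean(Y0)$distance[2L],
               distance_from_mean(Y0)$distance[3L])
  # 96 species split 48/48
  fx <- study_sim()
  sub <- phylogenetic_subset(fx$configs, seed = 2L)
  Yb <- flatten_coords(gpa(sub)); rownames(Yb) <- names(sub)
  split <- table(distance_from_mean(Yb)$centrality)
  expect_equal(unname(split["central"]), 48L)
  expect_equal(unname(split["peripheral"]), 48L)
})

test_that("UPGMA merge heights match a hand-computed example", {
  # 5 points: d(a,b)=2; d(c,d)=4; every a/b to c/d distance = 10; e is at
  # distance 20 from everyone.  Average-linkage merge heights: 2, 4, 10, 20.
  D <- matrix(20, 5L, 5L, dimnames = list(letters[1:5], letters[1:5]))
  diag(D) <- 0
  D["a", "b"] <- D["b", "a"] <- 2
  D["c", "d"] <- D["d", "c"] <- 4
  for (i in c("a", "b")) for (j in c("c", "d")) D[i, j] <- D[j, i] <- 10
  hc <- hclust(as.dist(D), method = "average")
  expect_equal(hc$height, c(2, 4, 10, 20))
  # the same structure via upgma_phenogram on coordinates whose Euclidean
  # distances approximate a two-cluster layout
  set.seed(81)
  Y <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0), c(50, 50))
  rownames(Y) <- letters[1:5]
  ph <- upgma_phenogram(Y)
  expect_s3_class(ph$phylo, "phylo")
  expect_true(ape::is.monophyletic(ph$phylo, c("a", "b")))
  expect_true(ape::is.monophyletic(ph$phylo, c("c", "d")))
})

test_that("conspecific specimens cluster together when noise is small", {
  sim <- small_sim()
  g <- gpa(sim$configs)
  ph <- upgma_phenogram(g)
  cl <- conspecific_clustering(ph, vapply(sim$configs, `[[`, "", "species"))
  expect_gt(mean(cl), 0.8)
})
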