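test_that("univariate RRPP F equals the classical ANOVA F", {
  # 3-group toy data; oracle = closed-form one-way ANOVA
  y <- c(1, 2, 3, 6, 7, 8, 11, 13, 15)
  g <- factor(rep(c("a", "b", "c"), each = 3L))
  grand <- mean(y)
  ss_b <- sum(3 * (tapply(y, g, mean) - grand)^2)
  ss_w <- sum((y - ave(y, g))^2)
  f_oracle <- (ss_b / 2) / (ss_w / 6)
  fit <- rrpp_lm(y ~ g, data = data.frame(g = g), n_perm = 199L, seed = 1L)
  expect_equal(fit$aov.table$F, f_oracle, tolerance = 1e-10)
  expect_equal(fit$aov.table$Df, 2L)
  expect_equal(fit$aov.table$SS, ss_b, tolerance = 1e-10)
  expect_equal(fit$aov.table$R2, ss_b / (ss_b + ss_w), tolerance = 1e-10)
})

test_that("sequential SS sums to total minus residual and R2 is bounded", {
  fx <- small_gpa()
  dat <- data.frame(size = fx$gpa$log_centroid_size,
                    tribe = fx$species_table$tribe[
                      match(rownames(fx$Y), fx$species_table$species)],
                    row.names = rownames(fx$Y))
  fit <- rrpp_lm(fx$Y ~ size + tribe, data = dat, n_perm = 99L, seed = 3L)
  expect_equal(sum(fit$aov.table$SS), fit$ss_total - fit$rss_full,
               tolerance = 1e-8)
  expect_lte(sum(fit$aov.table$R2), 1)
  expect_true(all(fit$aov.table$P >= 1 / 100))
})

test_that("collinear predictors raise a rank-deficiency error naming them", {
  d <- data.frame(x = 1:10, x2 = (1:10) * 2, y = rnorm(10))
  expect_error(rrpp_lm(y ~ x + x2, data = d), "aliased.*x2")
})

test_that("ols and pgls coincide on an equal-branch star phylogeny", {
  star <- ape::stree(15L, "star")
  star$edge.length <- rep(2, 15L)
  star$tip.label <- paste0("t", 1:15)
  set.seed(91)
  Y <- matrix(rnorm(45L), 15L, dimnames = list(star$tip.label, NULL))
  d <- data.frame(x = rnorm(15L), row.names = star$tip.label)
  f_ols <- rrpp_lm(Y ~ x, data = d, n_perm = 99L, seed = 7L)
  f_pgls <- rrpp_lm(Y ~ x, data = d, tree = star, n_perm = 99L, seed = 7L)
  expect_equal(f_ols$aov.table$F, f_pgls$aov.table$F, tolerance = 1e-10)
  expect_equal(f_ols$aov.table$SS / f_ols$ss_total,
               f_pgls$aov.table$SS / f_pgls$ss_total, tolerance = 1e-10)
  expect_equal(f_ols$aov.table$P, f_pgls$aov.table$P)
})

test_that("permutation p-values are reproducible and floored at 1/(n+1)", {
  set.seed(92)
  d <- data.frame(x = rnorm(30L))
  Y <- outer(d$x, rep(1, 4L)) + matrix(rnorm(120L, sd = 0.01), 30L)
  f1 <- rrpp_lm(Y ~ x, data = d, n_perm = 99L, seed = 5L)
  f2 <- rrpp_lm(Y ~ x, data = d, n_perm = 99L, seed = 5L)
  expect_identical(f1$aov.table, f2$aov.table)
  expect_equal(f1$aov.table$P, 1 / 100)  # overwhelming effect -> floor
  expect_gt(f1$aov.table$Z, 2)
})

test_that("Z and P are consistent within a fit across terms", {
  set.seed(93)
  n <- 40L
  d <- data.frame(a = rnorm(n), b = factor(sample(letters[1:2], n, TRUE)),
                  c = rnorm(n))
  Y <- outer(d$a, rep(1, 3L)) * 0.8 + matrix(rnorm(3L * n), n)
  fit <- rrpp_lm(Y ~ a + b + c, data = d, n_perm = 199L, seed = 8L)
  tab <- fit$aov.table
  expect_equal(order(tab$Z), order(-tab$P))
  expect_lt(tab$P[1L], 0.05)   # the planted term
  expect_gt(min(tab$P[2:3]), 0.05)
})

test_that("pairwise LS-mean distances find a planted group shift", {
  set.seed(94)
  n <- 60L
  g <- factor(rep(c("a", "b", "c"), each = 20L))
  Y <- matrix(rnorm(4L * n, sd = 1), n, 4L)
  Y[g == "c", ] <- Y[g == "c", ] + 2.5
  fit <- rrpp_lm(Y ~ g, data = data.frame(g = g), n_perm = 199L, seed = 9L)
  pw <- pairwise_groups(fit, "g")
  expect_equal(nrow(pw), 3L)
  shifted <- pw$group2 == "c"
  expect_true(all(pw$P[shifted] <= 0.05))
  expect_gt(pw$P[!shifted], 0.1)
  expect_true(all(pw$Z[shifted] > pw$Z[!shifted]))
})

test_that("pairwise slope comparisons recover equal and unequal slopes", {
  set.seed(95)
  n <- 80L
  g <- factor(rep(c("a", "b"), each = 40L))
  x <- rnorm(n)
  v <- c(1, 0, 0, 0)
  # identical slope vectors in both groups
  Y <- outer(x, v) + matrix(rnorm(4L * n, sd = 0.05), n)
  fit <- rrpp_lm(Y ~ x * g, data = data.frame(x = x, g = g),
                 n_perm = 199L, seed = 10L)
  pw <- pairwise_groups(fit, "g", statistic = "slopes", covariate = "x")
  expect_lt(pw$angle_deg, 10)
  expect_gt(pw$P_angle, 0.05)
  # orthogonal slope in group b
  Y2 <- Y
  Y2[g == "b", ] <- outer(x[g == "b"], c(0, 1, 0, 0)) +
    matrix(rnorm(4L * 40L, sd = 0.05), 40L)
  fit2 <- rrpp_lm(Y2 ~ x * g, data = data.frame(x = x, g = g),
                  n_perm = 199L, seed = 11L)
  pw2 <- pairwise_groups(fit2, "g", statistic = "slopes", covariate = "x")
  expect_gt(pw2$angle_deg, 60)
  expect_lte(pw2$P_angle, 0.05)
})

test_that("multivariate K is near 1 under BM and small for shuffled tips", {
  tree <- simulate_tree(40L, seed = 31L)
  Ks <- vapply(1:15, function(i) {
    Y <- simulate_bm_traits(tree, diag(6L), seed = 3000L + i)
    physignal_K(Y, tree, n_perm = 49L)$K
  }, 0)
  expect_gt(mean(Ks), 0.85)
  expect_lt(mean(Ks), 1.15)
  # destroying the phylogenetic structure drives K down and P up
  set.seed(32)
  Y <- simulate_bm_traits(tree, diag(6L), seed = 77L)
  Yshuf <- Y[sample(nrow(Y)), , drop = FALSE]
  rownames(Yshuf) <- rownames(Y)
  res_bm <- physignal_K(Y, tree, n_perm = 199L, seed = 1L)
  res_shuf <- physignal_K(Yshuf, tree, n_perm = 199L, seed = 1L)
  expect_lt(res_shuf$K, res_bm$K)
  expect_lte(res_bm$P, 0.05)
  expect_gt(res_shuf$P, 0.05)
})

test_that("disparity equals mean squared distance from the group mean", {
  Y <- rbind(c(0, 0), c(2, 0), c(0, 0), c(0, 4))
  g <- c("a", "a", "b", "b")
  res <- disparity_test(Y, g, n_perm = 99L, seed = 2L)
  expect_equal(unname(res$variances["a"]), (1 + 1) / 2)   # +-1 around mean (1,0)
  expect_equal(unname(res$variances["b"]), (4 + 4) / 2)
  # identical shapes have zero disparity
  Y0 <- rbind(c(1, 1), c(1, 1), c(0, 0), c(2, 2))
  res0 <- disparity_test(Y0, c("a", "a", "b", "b"), n_perm = 99L, seed = 2L)
  expect_equal(unname(res0$variances["a"]), 0)
  expect_warning(disparity_test(rbind(Y, c(9, 9)), c(g, "c"), n_perm = 99L),
                 "singleton")
})

test_that("disparity ratio tracks a planted noise-variance contrast", {
  set.seed(96)
  Ya <- matrix(rnorm(50L * 6L, sd = 1), 50L)
  Yb <- matrix(rnorm(50L * 6L, sd = 2), 50L)
  res <- disparity_test(rbind(Ya, Yb), rep(c("a", "b"), each = 50L),
                        n_perm = 199L, seed = 3L)
  ratio <- res$variances["b"] / res$variances["a"]
  expect_gt(ratio, 3.2); expect_lt(ratio, 4.8)
  expect_lte(res$pairwise$P, 0.05)
})

test_that("evolutionary rates are recovered and compared correctly", {
  tree <- simulate_tree(48L, seed = 41L, depth = 1)
  grp <- setNames(rep(c("g1", "g2"), 24L), tree$tip.label)
  p <- 4L
  # equal rates: ratio near 1, P not extreme
  Yeq <- simulate_bm_traits(tree, diag(p) * 2, seed = 42L)
  res_eq <- evol_rate_test(Yeq, tree, grp, n_sim = 199L, seed = 5L)
  expect_equal(unname(sum(res_eq$rates) / 2), 2 * p, tolerance = 0.5)
  expect_lt(res_eq$ratio, 1.7)
  expect_gt(res_eq$P, 0.05)
  # planted 4x rate in one group
  R <- diag(p)
  fast <- names(grp[grp == "g2"])
  Yfa <- Yeq
  Yfa[fast, ] <- Yfa[fast, ] * 2      # variance x4 for the fast tips
  res_fa <- evol_rate_test(Yfa, tree, grp, n_sim = 199L, seed = 5L)
  expect_gt(res_fa$ratio, 2)
  expect_lte(res_fa$P, 0.05)
  expect_gt(res_fa$Z, 2)
})

test_that("regression scores align with the generating covariate", {
  set.seed(97)
  n <- 60L
  x <- rnorm(n)
  v <- rnorm(10L)
  # noise variance along the signal direction = |v|^2 / 20 (high SNR)
  Y <- outer(x, v) + matrix(rnorm(10L * n, sd = sqrt(sum(v^2) / 20)), n)
  s <- regression_score(Y, x)
  expect_gt(cor(s, x), 0.95)
  # shuffling x decouples the score from x on average: single shuffles still
  # land the estimated slope near the dominant variance axis (+-v), but with
  # a random sign, so the signed association vanishes in expectation
  shuffle_cors <- vapply(1:50, function(r)
    cor(regression_score(Y, sample(x)), x), 0)
  expect_lt(abs(mean(shuffle_cors)), 0.25)
  # invariance to rotation of the coordinate basis
  Q <- qr.Q(qr(matrix(rnorm(100L), 10L)))
  expect_equal(regression_score(Y %*% Q, x), s, tolerance = 1e-8)
  expect_error(regression_score(Y, rep(1, n)), "zero variance")
})
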