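# Phylogenetic signal, disparity, evolutionary rates and regression scores.

# symmetric inverse square root of a covariance matrix
inv_sqrt_sym <- function(C) {
  ec <- eigen(C, symmetric = TRUE)
  if (min(ec$values) <= 0) stop("covariance matrix is singular")
  ec$vectors %*% diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
}

#' Multivariate phylogenetic signal (Blomberg's K)
#'
#' The multivariate generalization of Blomberg's K: the observed ratio of
#' the summed squared deviations from the phylogenetic (GLS) mean to the
#' phylogenetically corrected sums of squares, divided by its expectation
#' under Brownian motion on the supplied tree,
#' `(tr(C) - n / sum(C^-1)) / (n - 1)`.  Values near 1 are consistent with
#' Brownian evolution; values below 1 indicate homoplasy, above 1 strong
#' phylogenetic clustering.  Significance is assessed by permuting species
#' across the tips of the tree.
#'
#' @param Y Species x p trait matrix (a named vector is accepted), rows
#'   named by species.
#' @param tree `phylo` whose tips match the rows of `Y`.
#' @param n_perm Number of permutations (observed arrangement included in
#'   the reference set).
#' @param seed Optional integer seed.
#' @return Object of class `signal_result`: `K`, `P`, `n_perm`,
#'   `K_permuted`.
#' @export
physignal_K <- function(Y, tree, n_perm = 999L, seed = NULL) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L, dimnames = list(names(Y), "trait"))
  Y <- as.matrix(Y)
  if (is.null(rownames(Y)) || !all(sort(rownames(Y)) == sort(tree$tip.label)))
    stop("rows of Y must match the tree's tips one-to-one")
  Y <- Y[tree$tip.label, , drop = FALSE]
  n <- nrow(Y)
  C <- ape::vcv(tree)
  Cin <- solve(C)
  U <- chol(C)                       # C = U'U
  ones_w <- colSums(Cin)             # 1' C^-1
  denom_w <- sum(ones_w)
  expected <- (sum(diag(C)) - n / denom_w) / (n - 1)
  k_stat <- function(Ym) {
    a <- crossprod(ones_w, Ym) / denom_w
    Yc <- sweep(Ym, 2L, a)
    num <- sum(Yc^2)
    den <- sum(backsolve(U, Yc, transpose = TRUE)^2)
    (num / den) / expected
  }
  K_obs <- k_stat(Y)
  if (!is.null(seed)) set.seed(seed)
  K_perm <- vapply(seq_len(n_perm), function(m)
    k_stat(Y[sample.int(n), , drop = FALSE]), 0)
  P <- mean(c(K_obs, K_perm) >= K_obs - 1e-12)
  structure(list(K = K_obs, P = P, n_perm = n_perm, K_permuted = K_perm),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("<signal_result> K = %.3f, P = %.4g (%d permutations)\n",
              x$K, x$P, x$n_perm))
  invisible(x)
}

procrustes_variance <- function(Y) sum(scale(Y, scale = FALSE)^2) / nrow(Y)

#' Group disparity (Procrustes variance) with permutation tests
#'
#' Disparity of a group is its Procrustes variance: the mean squared
#' (Procrustes/Euclidean) distance of members from the group mean.
#' Pairwise absolute differences in disparity are tested by permuting
#' group labels.
#'
#' @param x `procrustes_fit` or n x p matrix.
#' @param groups Group labels, one per row (singleton groups are dropped
#'   with a warning).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return Object of class `disparity_result`: `variances` (named),
#'   `pairwise` data.frame (group1, group2, difference, P).
#' @export
disparity_test <- function(x, groups, n_perm = 999L, seed = NULL) {
  Y <- if (inherits(x, "procrustes_fit")) flatten_coords(x) else as.matrix(x)
  groups <- as.character(groups)
  tab <- table(groups)
  single <- names(tab[tab < 2L])
  if (length(single)) {
    warning("dropping singleton group(s): ", paste(single, collapse = ", "))
    keep <- !groups %in% single
    Y <- Y[keep, , drop = FALSE]; groups <- groups[keep]
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("disparity_test needs at least 2 groups of size >= 2")
  pv <- function(g) vapply(lev, function(l)
    procrustes_variance(Y[g == l, , drop = FALSE]), 0)
  obs <- pv(groups)
  pairs <- t(combn(lev, 2L))
  d_obs <- abs(obs[pairs[, 1L]] - obs[pairs[, 2L]])
  if (!is.null(seed)) set.seed(seed)
  d_perm <- t(vapply(seq_len(n_perm), function(m) {
    g <- sample(groups)
    v <- pv(g)
    abs(v[pairs[, 1L]] - v[pairs[, 2L]])
  }, numeric(nrow(pairs))))
  if (nrow(pairs) == 1L) d_perm <- t(d_perm)
  P <- vapply(seq_len(nrow(pairs)), function(r)
    mean(c(d_obs[r], d_perm[, r]) >= d_obs[r] - 1e-15), 0)
  structure(list(variances = obs,
                 pairwise = data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
                                       difference = unname(d_obs), P = P,
                                       stringsAsFactors = FALSE),
                 n_perm = n_perm),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("<disparity_result> Procrustes variances:\n")
  print(round(x$variances, 6L))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Compare multivariate Brownian rates of shape evolution between groups
#'
#' The net evolutionary rate of a group is the mean squared
#' phylogenetically transformed tip deviation per unit branch length,
#' summed over trait dimensions: rows of `C^(-1/2) (Y - 1a')` (with `a`
#' the GLS root estimate) are partitioned by group and averaged.  The test
#' statistic is the max/min rate ratio; its null distribution comes from
#' simulating Brownian motion with the common (pooled) rate on the tree,
#' because permuting tips would destroy the tree-data covariance the
#' statistic depends on.
#'
#' @param Y Species x p matrix, rows named by species.
#' @param tree `phylo`.
#' @param groups Named group labels (names = species) or a vector ordered
#'   as `rownames(Y)`; each group needs >= 2 species.
#' @param n_sim Number of Brownian simulations for the null.
#' @param seed Optional integer seed.
#' @return Object of class `rate_result`: `rates` (named sigma^2_mult per
#'   group), `ratio`, `P`, `Z`, `n_sim`.
#' @export
evol_rate_test <- function(Y, tree, groups, n_sim = 999L, seed = NULL) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y)) || !all(sort(rownames(Y)) == sort(tree$tip.label)))
    stop("rows of Y must match the tree's tips one-to-one")
  if (!is.null(names(groups))) groups <- groups[rownames(Y)]
  groups <- as.character(groups)
  names(groups) <- rownames(Y)
  Y <- Y[tree$tip.label, , drop = FALSE]
  groups <- groups[tree$tip.label]
  tab <- table(groups)
  if (any(tab < 2L)) stop("each group needs >= 2 species; offending: ",
                          paste(names(tab[tab < 2L]), collapse = ", "))
  n <- nrow(Y); p <- ncol(Y)
  C <- ape::vcv(tree)
  iC12 <- inv_sqrt_sym(C)
  Cin <- solve(C)
  ones_w <- colSums(Cin); denom_w <- sum(ones_w)
  rates_of <- function(Ym) {
    a <- crossprod(ones_w, Ym) / denom_w
    U <- iC12 %*% sweep(Ym, 2L, a)
    r <- rowSums(U^2)
    vapply(sort(unique(groups)), function(g) mean(r[groups == g]) , 0)
  }
  obs <- rates_of(Y)
  ratio_obs <- max(obs) / min(obs)
  pooled <- mean(rowSums((iC12 %*%
    sweep(Y, 2L, crossprod(ones_w, Y) / denom_w))^2))
  if (!is.null(seed)) set.seed(seed)
  LC <- chol_psd(C)
  ratio_sim <- vapply(seq_len(n_sim), function(s) {
    Ysim <- LC %*% matrix(rnorm(n * p, sd = sqrt(pooled / p)), n, p)
    rownames(Ysim) <- rownames(C)
    r <- rates_of(Ysim)
    max(r) / min(r)
  }, 0)
  all_r <- c(ratio_obs, ratio_sim)
  P <- mean(all_r >= ratio_obs - 1e-12)
  logr <- log(all_r)
  s <- sd(logr)
  Z <- if (s > 0) (logr[1L] - mean(logr)) / s else 0
  structure(list(rates = obs, ratio = ratio_obs, P = P, Z = Z, n_sim = n_sim),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> ratio = %.3f, P = %.4g, Z = %.2f\n",
              x$ratio, x$P, x$Z))
  print(round(x$rates, 6L))
  invisible(x)
}

#' Regression score of shape on a continuous variable
#'
#' Projects each (centered) row of `Y` onto the normalized multivariate
#' regression coefficient vector of `Y` on `x`: a univariate shape summary
#' maximally associated with `x` (the standard allometry/regression-score
#' construction).  Invariant to rotations of `Y`'s coordinate basis.
#'
#' @param Y n x p matrix.
#' @param x Numeric covariate of length n with positive variance.
#' @return Named numeric vector of scores, one per row of `Y`.
#' @export
regression_score <- function(Y, x) {
  Y <- as.matrix(Y)
  x <- as.numeric(x)
  if (length(x) != nrow(Y)) stop("length(x) must equal nrow(Y)")
  if (var(x) == 0) stop("regression_score: x has zero variance")
  xc <- x - mean(x)
  Yc <- scale(Y, scale = FALSE)
  b <- crossprod(Yc, xc) / sum(xc^2)   # p x 1 slope vector
  s <- as.numeric(Yc %*% b) / sqrt(sum(b^2))
  names(s) <- rownames(Y)
  s
}
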