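# Modularity: covariance constructions, module discovery, covariance ratio,
# likelihood model comparison, between-clade contrasts.

#' Construct a module scheme
#'
#' A named partition of landmark indices (over the one-sided symmetric
#' subset) into modules.  Schemes with any module of fewer than
#' `min_per_module` landmarks are rejected when `strict = TRUE` (modules of
#' one or two coordinates are not biologically meaningful and break the
#' covariance-ratio denominator).
#'
#' @param name Scheme name.
#' @param assignment Character/factor vector: module label per landmark.
#' @param strict Reject undersized modules (default TRUE).
#' @param min_per_module Minimum landmarks per module (default 2).
#' @return Object of class `module_scheme`.
#' @export
module_scheme <- function(name, assignment, strict = TRUE, min_per_module = 2L) {
  assignment <- as.character(assignment)
  if (anyNA(assignment)) stop("module assignment contains NA")
  tab <- table(assignment)
  if (strict && length(tab) < 2L) stop("a module scheme needs >= 2 modules")
  small <- names(tab[tab < min_per_module])
  if (strict && length(small))
    stop("scheme '", name, "' has module(s) with < ", min_per_module,
         " landmarks: ", paste(small, collapse = ", "))
  structure(list(name = name, assignment = assignment,
                 n_modules = length(tab),
                 small_modules = small),
            class = "module_scheme")
}

#' @export
print.module_scheme <- function(x, ...) {
  cat(sprintf("<module_scheme> '%s': %d modules over %d landmarks\n",
              x$name, x$n_modules, length(x$assignment)))
  print(table(x$assignment))
  invisible(x)
}

coords_matrix <- function(x) {
  if (inherits(x, "procrustes_fit")) flatten_coords(x) else as.matrix(x)
}

#' Landmark congruence-coefficient matrix
#'
#' For each landmark pair, the congruence coefficient of their (consensus
#' -centered) 3D coordinate blocks across specimens: the sum of
#' cross-products over the root of the two summed squares.  Coordinates
#' are centered per column (deviations from the mean shape) but not
#' variance-scaled, hence "unscaled".  The matrix is symmetric with unit
#' diagonal; duplicated landmarks give 1, independent landmarks values
#' near 0.
#'
#' @param x `procrustes_fit` (typically the symmetric subset) or an n x 3k
#'   matrix of aligned coordinates.
#' @return k x k numeric matrix.
#' @export
congruence_matrix <- function(x) {
  Y <- coords_matrix(x)
  if (anyNA(Y)) stop("congruence_matrix: missing data")
  k <- ncol(Y) / 3L
  Yc <- scale(Y, scale = FALSE)
  blocks <- lapply(seq_len(k), function(l) Yc[, 3L * (l - 1L) + 1:3, drop = FALSE])
  norms <- vapply(blocks, function(b) sum(b^2), 0)
  M <- diag(1, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    v <- sum(blocks[[i]] * blocks[[j]]) / sqrt(norms[i] * norms[j])
    M[i, j] <- M[j, i] <- v
  }
  lbl <- sub("\\.x$", "", colnames(Y)[seq(1L, ncol(Y), by = 3L)])
  dimnames(M) <- list(lbl, lbl)
  M
}

# phylogenetically independent contrasts, one column per coordinate
pic_matrix <- function(Y, tree) {
  if (is.null(rownames(Y)) || !all(sort(rownames(Y)) == sort(tree$tip.label)))
    stop("rows of Y must match the tree's tips one-to-one")
  Y <- Y[tree$tip.label, , drop = FALSE]
  tr <- tree
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr, random = FALSE)
  apply(Y, 2L, function(y) ape::pic(setNames(y, tr$tip.label), tr))
}

#' Phylogenetic landmark covariance distance matrix
#'
#' Computes phylogenetically independent contrasts of every Procrustes
#' coordinate, forms the landmark-block covariance matrix on the contrasts
#' (for a landmark pair, the coordinate-wise cross-covariances summed over
#' x, y, z), and returns the Euclidean distance matrix between its rows -
#' the input expected by [kmeans_gap_modules()].  On a star phylogeny the
#' contrasts are an orthonormal rotation of the centered data, so the
#' result equals the non-phylogenetic version.
#'
#' @param x `procrustes_fit` or n x 3k matrix, rows named by species.
#' @param tree Optional `phylo`; when `NULL`, covariances are computed on
#'   the raw (centered) data.
#' @return k x k distance matrix with the block covariance matrix attached
#'   as attribute `"cov"`.
#' @export
pic_covariance_matrix <- function(x, tree = NULL) {
  Y <- coords_matrix(x)
  k <- ncol(Y) / 3L
  # contrasts have expectation zero, so the BM rate estimator is the
  # uncentered cross-product; on a star tree this equals the ordinary
  # covariance of the tip data exactly
  S <- if (is.null(tree)) cov(Y) else {
    Z <- pic_matrix(Y, tree)
    crossprod(Z) / nrow(Z)
  }
  V <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    idx_i <- 3L * (i - 1L) + 1:3; idx_j <- 3L * (j - 1L) + 1:3
    V[i, j] <- V[j, i] <- sum(diag(S[idx_i, idx_j]))
  }
  lbl <- sub("\\.x$", "", colnames(Y)[seq(1L, ncol(Y), by = 3L)])
  dimnames(V) <- list(lbl, lbl)
  D <- as.matrix(dist(V))
  attr(D, "cov") <- V
  D
}

#' Discover modules by k-means and the gap statistic
#'
#' Applies k-means (multiple restarts) to the rows of a landmark
#' association/distance matrix for k = 1..`k_max` and selects the number
#' of clusters by the gap statistic with `B` uniform reference sets,
#' choosing the smallest k with `Gap(k) >= Gap(k+1) - SE(k+1)`.
#'
#' @param mat Square landmark matrix (association or distance); its rows
#'   are the clustering features.
#' @param k_max Largest k considered (< number of landmarks).
#' @param B Bootstrap reference sets for the gap statistic.
#' @param restarts k-means restarts per k.
#' @param seed Optional integer seed (k-means and the reference sets are
#'   seed-dependent; the selected k can vary between unseeded runs).
#' @return List with `scheme` ([module_scheme], built non-strictly: any
#'   undersized modules are flagged in `scheme$small_modules`),
#'   `chosen_k`, and `gap` (data.frame: k, logW, E_logW, gap, SE).
#' @export
kmeans_gap_modules <- function(mat, k_max = 10L, B = 100L, restarts = 25L,
                               seed = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("mat must be square (landmark x landmark)")
  if (k_max >= nrow(mat)) stop("k_max must be below the number of landmarks")
  if (sd(mat) == 0) stop("degenerate (constant) association matrix")
  if (!is.null(seed)) set.seed(seed)
  gs <- cluster::clusGap(mat, FUNcluster = function(x, k)
    kmeans(x, k, nstart = restarts, iter.max = 50L),
    K.max = k_max, B = B, verbose = FALSE)
  tab <- as.data.frame(gs$Tab)
  chosen_k <- cluster::maxSE(tab$gap, tab$SE.sim, method = "Tibs2001SEmax")
  cl <- if (chosen_k == 1L) rep(1L, nrow(mat)) else
    kmeans(mat, chosen_k, nstart = restarts, iter.max = 50L)$cluster
  assignment <- paste0("module", cl)
  names(assignment) <- rownames(mat)
  scheme <- module_scheme("clustering", assignment, strict = FALSE)
  list(scheme = scheme, chosen_k = chosen_k,
       gap = data.frame(k = seq_len(k_max), logW = tab$logW,
                        E_logW = tab$E.logW, gap = tab$gap, SE = tab$SE.sim))
}

# CR statistic from a coordinate covariance matrix and a per-landmark
# module assignment (3 coordinates per landmark travel together)
cr_statistic <- function(S, assignment) {
  mods <- sort(unique(assignment))
  cols_of <- lapply(mods, function(m) {
    lm_idx <- which(assignment == m)
    as.vector(vapply(lm_idx, function(l) 3L * (l - 1L) + 1:3, integer(3L)))
  })
  names(cols_of) <- mods
  within_norm <- vapply(mods, function(m) {
    Sw <- S[cols_of[[m]], cols_of[[m]], drop = FALSE]
    diag(Sw) <- 0
    sqrt(sum(Sw^2))
  }, 0)
  pairs <- t(combn(mods, 2L))
  crs <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    Sb <- S[cols_of[[a]], cols_of[[b]], drop = FALSE]
    sqrt(sum(Sb^2)) / sqrt(within_norm[a] * within_norm[b])
  }, 0)
  mean(crs)
}

#' Covariance ratio test of modularity
#'
#' The covariance ratio (CR) for a pair of modules is the Frobenius norm
#' of the between-module covariance block divided by the geometric mean of
#' the within-module off-diagonal norms; for more than two modules the
#' pairwise CRs are averaged.  CR < 1 indicates more modular structure
#' than an integrated one.  The null distribution reassigns whole
#' landmarks (their three coordinates together) at random to modules of
#' the same sizes; `Z` is the standardized observed CR within the null
#' (negative = more modular than chance) and `P` the fraction of the null
#' at or below the observed CR.  In phylogenetic mode the covariance
#' matrix is computed on independent contrasts, so the null model is
#' phylogenetically informed.
#'
#' @param x `procrustes_fit` (symmetric subset) or n x 3k matrix (rows
#'   named by species in phylogenetic mode).
#' @param scheme A [module_scheme] or an assignment vector over the k
#'   landmarks.
#' @param n_perm Number of random reassignments.
#' @param seed Optional integer seed.
#' @param phylogenetic Compute on independent contrasts?
#' @param tree Required when `phylogenetic = TRUE`.
#' @return Object of class `cr_result`: `CR`, `Z`, `P`, `n_perm`,
#'   `phylogenetic`, `CR_null`.
#' @export
covariance_ratio <- function(x, scheme, n_perm = 999L, seed = NULL,
                             phylogenetic = FALSE, tree = NULL) {
  assignment <- if (inherits(scheme, "module_scheme")) scheme$assignment
                else as.character(scheme)
  tab <- table(assignment)
  if (any(tab < 2L))
    stop("covariance_ratio: module(s) with < 2 landmarks: ",
         paste(names(tab[tab < 2L]), collapse = ", "))
  Y <- coords_matrix(x)
  if (ncol(Y) != 3L * length(assignment))
    stop("assignment length does not match the landmark count")
  if (phylogenetic) {
    if (is.null(tree)) stop("phylogenetic mode requires a tree")
    Z <- pic_matrix(Y, tree)
    S <- crossprod(Z) / nrow(Z)
  } else {
    S <- cov(Y)
  }
  cr_obs <- cr_statistic(S, assignment)
  if (!is.null(seed)) set.seed(seed)
  cr_null <- vapply(seq_len(n_perm), function(m)
    cr_statistic(S, sample(assignment)), 0)
  all_cr <- c(cr_obs, cr_null)
  P <- mean(all_cr <= cr_obs + 1e-12)
  s <- sd(all_cr)
  Zs <- if (s > 0) (cr_obs - mean(all_cr)) / s else 0
  structure(list(CR = cr_obs, Z = Zs, P = P, n_perm = n_perm,
                 phylogenetic = phylogenetic, CR_null = cr_null),
            class = "cr_result")
}

#' @export
print.cr_result <- function(x, ...) {
  cat(sprintf("<cr_result> CR = %.3f, Z = %.2f, P = %.4g (%s, %d permutations)\n",
              x$CR, x$Z, x$P,
              if (x$phylogenetic) "phylogenetic" else "non-phylogenetic",
              x$n_perm))
  invisible(x)
}

# ---- EMMLi-style likelihood comparison ----------------------------------

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

# block label per landmark pair under a scheme and rho model
emmli_blocks <- function(assignment, rho_model) {
  k <- length(assignment)
  pr <- t(combn(k, 2L))
  a <- assignment[pr[, 1L]]; b <- assignment[pr[, 2L]]
  same <- a == b
  blk <- switch(rho_model,
    single = rep("rho", nrow(pr)),
    within_between = ifelse(same, paste0("within.", a), "between"),
    separate = ifelse(same, paste0("within.", a),
                      paste0("between.", pmin(a, b), ".", pmax(a, b))))
  list(pairs = pr, block = blk)
}

emmli_fit_one <- function(z, blk, n_eff, n_pairs_total) {
  sdz <- 1 / sqrt(n_eff - 3)
  mus <- tapply(z, blk, mean)            # closed-form MLE per block
  ll <- sum(dnorm(z, mean = mus[blk], sd = sdz, log = TRUE))
  K <- length(mus)
  aicc <- -2 * ll + 2 * K + 2 * K * (K + 1) / max(n_pairs_total - K - 1, 1)
  list(logLik = ll, n_params = K, AICc = aicc, rho = tanh(mus))
}

#' Likelihood comparison of modularity models (EMMLi-style)
#'
#' Fits, for each module scheme and each rho model, the hypothesis that
#' every within/between block of the landmark correlation matrix shares a
#' single true correlation (rho): observed pairwise coefficients are
#' Fisher-z transformed and modelled as normal around the block rho with
#' variance `1/(n_eff - 3)`, with the effective sample size `n_eff` equal
#' to the number of landmarks.  The block MLE is the mean Fisher-z
#' (closed form).  Models are ranked by AICc with Akaike weights; a
#' single-rho "no modularity" model is always included.  The correlation
#' between log-likelihood and parameter count across models is reported as
#' a diagnostic of parametrization-driven ranking.
#'
#' @param assoc k x k correlation matrix (e.g. [congruence_matrix()]).
#' @param schemes Named list of [module_scheme] objects or assignment
#'   vectors of length k.
#' @param rho_models Subset of `c("single", "within_between", "separate")`
#'   fitted per scheme (the global single-rho model is fitted once).
#' @return Object of class `emmli_result`: `table` (scheme, model,
#'   logLik, n_params, AICc, dAICc, weight), `rho` (named list of block
#'   rho estimates for every fitted model), `lik_param_cor`.
#' @export
emmli_compare <- function(assoc, schemes,
                          rho_models = c("within_between", "separate")) {
  assoc <- as.matrix(assoc)
  k <- nrow(assoc)
  if (!length(schemes)) stop("emmli_compare needs at least one scheme")
  if (is.null(names(schemes))) names(schemes) <- paste0("scheme", seq_along(schemes))
  rho_models <- match.arg(rho_models, c("single", "within_between", "separate"),
                          several.ok = TRUE)
  pr <- t(combn(k, 2L))
  r <- assoc[pr]
  z <- fisher_z(r)
  n_pairs <- length(z)
  rows <- list(); rhos <- list()
  add <- function(scheme_name, model_name, assignment, rho_model) {
    eb <- emmli_blocks(assignment, rho_model)
    f <- emmli_fit_one(z, eb$block, n_eff = k, n_pairs_total = n_pairs)
    rows[[length(rows) + 1L]] <<- data.frame(
      scheme = scheme_name, model = model_name, logLik = f$logLik,
      n_params = f$n_params, AICc = f$AICc, stringsAsFactors = FALSE)
    rhos[[paste(scheme_name, model_name, sep = ".")]] <<- f$rho
  }
  add("none", "single", rep("all", k), "single")
  for (nm in names(schemes)) {
    sch <- schemes[[nm]]
    assignment <- if (inherits(sch, "module_scheme")) sch$assignment
                  else as.character(sch)
    if (length(assignment) != k)
      stop("scheme '", nm, "' length does not match the matrix")
    tab <- table(assignment)
    if (any(tab < 2L)) {
      warning("scheme '", nm, "' has undersized module(s); skipped")
      next
    }
    for (m in rho_models) add(nm, m, assignment, m)
  }
  tab <- do.call(rbind, rows)
  tab$dAICc <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$dAICc / 2)
  tab$weight <- w / sum(w)
  lik_cor <- if (nrow(tab) > 2L) cor(tab$logLik, tab$n_params) else NA_real_
  structure(list(table = tab[order(tab$AICc), ], rho = rhos,
                 lik_param_cor = lik_cor),
            class = "emmli_result")
}

#' @export
print.emmli_result <- function(x, digits = 3L, ...) {
  cat("<emmli_result>\n")
  tab <- x$table
  tab[, c("logLik", "AICc", "dAICc", "weight")] <-
    round(tab[, c("logLik", "AICc", "dAICc", "weight")], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("cor(logLik, n_params) = %.3f\n", x$lik_param_cor))
  invisible(x)
}

#' Compare covariance-ratio effect sizes between groups
#'
#' Computes the CR effect size (Z) per group under a common module scheme
#' and tests pairwise |Z| differences by permuting group membership.
#'
#' @param x n x 3k matrix or `procrustes_fit` (symmetric subset).
#' @param scheme [module_scheme] or assignment vector.
#' @param groups Group labels per row; groups smaller than
#'   `n_modules + 2` rows are dropped with a warning.
#' @param n_perm Outer permutations of group membership.
#' @param n_perm_cr Inner permutations for each CR effect size.
#' @param seed Optional integer seed.
#' @return data.frame: group1, group2, Z1, Z2, dZ, P.
#' @export
modularity_contrast <- function(x, scheme, groups, n_perm = 99L,
                                n_perm_cr = 99L, seed = NULL) {
  Y <- coords_matrix(x)
  assignment <- if (inherits(scheme, "module_scheme")) scheme$assignment
                else as.character(scheme)
  groups <- as.character(groups)
  min_n <- length(unique(assignment)) + 2L
  tab <- table(groups)
  small <- names(tab[tab < min_n])
  if (length(small)) {
    warning("dropping undersized group(s): ", paste(small, collapse = ", "))
    keep <- !groups %in% small
    Y <- Y[keep, , drop = FALSE]; groups <- groups[keep]
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("modularity_contrast needs >= 2 usable groups")
  if (!is.null(seed)) set.seed(seed)
  z_of <- function(g) vapply(lev, function(l) {
    covariance_ratio(Y[g == l, , drop = FALSE], assignment,
                     n_perm = n_perm_cr)$Z
  }, 0)
  z_obs <- z_of(groups)
  pairs <- t(combn(lev, 2L))
  d_obs <- abs(z_obs[pairs[, 1L]] - z_obs[pairs[, 2L]])
  d_perm <- t(vapply(seq_len(n_perm), function(m) {
    zz <- z_of(sample(groups))
    abs(zz[pairs[, 1L]] - zz[pairs[, 2L]])
  }, numeric(nrow(pairs))))
  if (nrow(pairs) == 1L) d_perm <- t(d_perm)
  P <- vapply(seq_len(nrow(pairs)), function(r)
    mean(c(d_obs[r], d_perm[, r]) >= d_obs[r] - 1e-12), 0)
  data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
             Z1 = unname(z_obs[pairs[, 1L]]), Z2 = unname(z_obs[pairs[, 2L]]),
             dZ = unname(d_obs), P = P, stringsAsFactors = FALSE)
}
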