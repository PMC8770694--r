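# Permutation linear models with residual randomization (RRPP), in ordinary
# or phylogenetic (Brownian) generalized least squares.

#' Fit a permutation linear model to multivariate shape data
#'
#' Sequential (Type I) sums of squares from multivariate least squares.  In
#' `pgls` mode (a tree is supplied) both response and design are first
#' transformed by the inverse square root of the Brownian-motion covariance
#' `C` (`P = diag(1/sqrt(lambda)) %*% t(E)` from `C = E diag(lambda) t(E)`),
#' which renders the errors exchangeable.  Significance uses residual
#' randomization: for each term, residuals of its reduced (previous) model
#' are permuted and added back to the reduced fitted values, and the term's
#' statistics are recomputed; the observed arrangement is included in the
#' reference set, so the smallest attainable p-value is
#' `1/(n_perm + 1)`.  Effect sizes `Z` are standardized deviates of log F
#' within each term's permutation distribution.
#'
#' @param formula Model formula.  The left-hand side is evaluated in
#'   `data` (then in the calling frame) and may be a matrix (rows =
#'   observations) or a numeric vector.
#' @param data A data.frame (or environment) holding the predictors.  When
#'   a tree is supplied, its row names (or the response's) must be species
#'   matching the tree's tips.
#' @param tree Optional `phylo`; supplying it switches to `pgls` mode.
#' @param n_perm Number of random permutations (>= 99; default 999).
#' @param seed Optional integer seed, recorded in the fit.
#' @return Object of class `rrpp_fit` with an `aov.table` data.frame
#'   (term, Df, SS, R2, F, Z, P), residual/total rows as attributes, and
#'   the internals needed by [pairwise_groups()].
#' @export
rrpp_lm <- function(formula, data = NULL, tree = NULL, n_perm = 999L,
                    seed = NULL) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  mode <- if (is.null(tree)) "ols" else "pgls"
  if (!is.null(tree) && isFALSE(attr(data, "pgls_ok")))
    stop("this design duplicates species across rows (habitat/NPP joins); ",
         "phylogenetic (pgls) fits are not valid on it - use ols")
  env <- environment(formula)
  Y <- eval(formula[[2L]], envir = if (is.data.frame(data)) data else env,
            enclos = env)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  rhs <- formula
  rhs[[2L]] <- NULL
  mf <- model.frame(rhs, data = data, na.action = stats::na.fail)
  if (nrow(mf) != n) stop("response and predictors have different lengths")
  trm <- attr(mf, "terms")
  X <- model.matrix(trm, mf)
  if (!attr(trm, "intercept")) stop("rrpp_lm requires an intercept")
  asgn <- attr(X, "assign")
  term_labels <- attr(trm, "term.labels")
  K <- length(term_labels)
  if (K < 1L) stop("no model terms to test")

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }

  if (mode == "pgls") {
    sp <- rownames(Y)
    if (is.null(sp)) sp <- rownames(mf)
    if (is.null(sp) || !all(sort(sp) == sort(tree$tip.label)))
      stop("pgls mode: row names must match the tree's tips one-to-one")
    ord <- match(tree$tip.label, sp)
    Y <- Y[ord, , drop = FALSE]
    X <- X[ord, , drop = FALSE]
    mf <- mf[ord, , drop = FALSE]
    C <- ape::vcv(tree)
    ec <- eigen(C, symmetric = TRUE)
    if (min(ec$values) <= 0)
      stop("phylogenetic covariance is singular (zero-length paths?)")
    # symmetric inverse square root: with equal eigenvalues (star tree)
    # this reduces to a scaled identity, so pgls coincides with ols exactly,
    # permutation distributions included
    Pmat <- ec$vectors %*% diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
    Yt <- Pmat %*% Y
    Xt <- Pmat %*% X
  } else {
    Pmat <- NULL
    Yt <- Y
    Xt <- X
  }

  # nested designs: qlist[[m]] holds terms with assign <= m - 1
  qlist <- lapply(0L:K, function(m) qr(Xt[, asgn <= m, drop = FALSE]))
  ranks <- vapply(qlist, `[[`, 0L, "rank")
  df_terms <- diff(ranks)
  df_res <- n - ranks[K + 1L]
  if (df_res < 1L) stop("no residual degrees of freedom")
  rss <- function(q, yy) sum(qr.resid(q, yy)^2)
  ss_total <- rss(qlist[[1L]], Yt)

  if (!is.null(seed)) set.seed(seed)
  perms <- t(replicate(n_perm, sample.int(n)))

  SS <- Fv <- Z <- Pv <- numeric(K)
  for (j in seq_len(K)) {
    q_red <- qlist[[j]]; q_full_j <- qlist[[j + 1L]]; q_full <- qlist[[K + 1L]]
    fit_red <- qr.fitted(q_red, Yt)
    res_red <- Yt - fit_red
    f_one <- function(idx) {
      Ystar <- fit_red + res_red[idx, , drop = FALSE]
      ss_j <- rss(q_red, Ystar) - rss(q_full_j, Ystar)
      c(ss_j, (ss_j / df_terms[j]) / (rss(q_full, Ystar) / df_res))
    }
    obs <- f_one(seq_len(n))
    perm_stats <- vapply(seq_len(n_perm), function(m) f_one(perms[m, ]),
                         numeric(2L))
    f_all <- c(obs[2L], perm_stats[2L, ])
    SS[j] <- obs[1L]
    Fv[j] <- obs[2L]
    Pv[j] <- mean(f_all >= obs[2L] - 1e-12)
    logf <- log(pmax(f_all, .Machine$double.eps))
    s <- sd(logf)
    Z[j] <- if (s > 0) (logf[1L] - mean(logf)) / s else 0
  }

  tab <- data.frame(term = term_labels, Df = df_terms, SS = SS,
                    R2 = SS / ss_total, F = Fv, Z = Z, P = Pv,
                    stringsAsFactors = FALSE)
  fit <- list(aov.table = tab, mode = mode, n = n, n_perm = n_perm,
              seed = seed, df_res = df_res,
              rss_full = rss(qlist[[K + 1L]], Yt), ss_total = ss_total,
              Y = Yt, X = Xt, Pmat = Pmat, mf = mf, terms = trm,
              assign = asgn, qlist = qlist, perms = perms, tree = tree,
              contrasts = attr(X, "contrasts"))
  class(fit) <- "rrpp_fit"
  fit
}

#' @export
print.rrpp_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("<rrpp_fit> %s, n = %d, %d permutations\n", x$mode, x$n, x$n_perm))
  tab <- x$aov.table
  tab[, -1L] <- round(tab[, -1L], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' ANOVA-style table of an RRPP fit
#' @param fit An `rrpp_fit`.
#' @return Its `aov.table` data.frame with the fit mode in a `Type` column.
#' @export
anova_table <- function(fit) {
  tab <- fit$aov.table
  tab$Type <- fit$mode
  tab
}

# design columns for the model excluding every term that involves any of
# the given variables
reduced_design_without <- function(fit, vars) {
  fac <- attr(fit$terms, "factors")
  labs <- attr(fit$terms, "term.labels")
  involves <- colSums(fac[rownames(fac) %in% vars, , drop = FALSE] > 0) > 0
  drop_terms <- which(involves)
  keep <- fit$assign %in% c(0L, setdiff(seq_along(labs), drop_terms))
  if (all(keep)) stop("no term involves: ", paste(vars, collapse = ", "))
  keep
}

# model matrix for new data using the fit's terms/contrasts/levels
predict_design <- function(fit, newdata) {
  trm <- delete.response(fit$terms)
  xlev <- lapply(fit$mf, function(v) if (is.factor(v)) levels(v) else NULL)
  xlev <- xlev[!vapply(xlev, is.null, TRUE)]
  mf_new <- model.frame(trm, newdata, xlev = xlev)
  model.matrix(trm, mf_new, contrasts.arg = fit$contrasts)
}

# one prediction row per level of `grouping`; continuous covariates at
# their mean, other factors at their reference level
ls_mean_grid <- function(fit, grouping, overrides = NULL) {
  mf <- fit$mf
  g <- mf[[grouping]]
  if (is.null(g)) stop("grouping '", grouping, "' is not in the model")
  g <- as.factor(g)
  grid <- data.frame(row.names = seq_along(levels(g)))
  for (v in names(mf)) {
    grid[[v]] <- if (v == grouping) factor(levels(g), levels = levels(g))
    else if (is.numeric(mf[[v]])) {
      if (!is.null(overrides) && v %in% names(overrides)) overrides[[v]]
      else mean(mf[[v]])
    } else factor(levels(as.factor(mf[[v]]))[1L],
                  levels = levels(as.factor(mf[[v]])))
  }
  grid
}

#' Pairwise group comparisons from an RRPP fit
#'
#' For `statistic = "mean_distance"`, compares least-squares group means
#' (continuous covariates held at their mean): the statistic per pair is
#' the Euclidean distance between predicted mean vectors.  For
#' `statistic = "slopes"` (models with a `covariate x grouping`
#' interaction), per-group slope vectors are compared in length and in
#' angle (degrees).  Null distributions come from residual randomization of
#' the reduced model that omits every term involving the grouping factor
#' (for means) or the grouping:covariate interaction (for slopes), using
#' the fit's stored permutations, so results are reproducible from the
#' fit's seed.
#'
#' @param fit An `rrpp_fit`.
#' @param grouping Name of the factor in the model to compare.
#' @param statistic `"mean_distance"` or `"slopes"`.
#' @param covariate For `"slopes"`: name of the continuous covariate whose
#'   group slopes are compared.
#' @return data.frame with one row per group pair: the statistic(s), `Z`
#'   and permutation `P`.
#' @export
pairwise_groups <- function(fit, grouping,
                            statistic = c("mean_distance", "slopes"),
                            covariate = NULL) {
  statistic <- match.arg(statistic)
  g <- as.factor(fit$mf[[grouping]])
  if (is.null(fit$mf[[grouping]])) stop("grouping '", grouping, "' not in model")
  lev <- levels(g)
  if (length(lev) < 2L) stop("grouping has fewer than 2 levels")
  q_full <- fit$qlist[[length(fit$qlist)]]
  pairs <- t(combn(lev, 2L))

  if (statistic == "mean_distance") {
    Xp <- predict_design(fit, ls_mean_grid(fit, grouping))
    keep <- reduced_design_without(fit, grouping)
    stat_fun <- function(beta) {
      pred <- Xp %*% beta
      as.numeric(dist(pred))
    }
  } else {
    if (is.null(covariate)) stop("statistic='slopes' needs a covariate name")
    if (is.null(fit$mf[[covariate]]) || !is.numeric(fit$mf[[covariate]]))
      stop("covariate '", covariate, "' is not a numeric model variable")
    X0 <- predict_design(fit, ls_mean_grid(fit, grouping,
                                           overrides = setNames(list(0), covariate)))
    X1 <- predict_design(fit, ls_mean_grid(fit, grouping,
                                           overrides = setNames(list(1), covariate)))
    Xd <- X1 - X0
    # reduced model: drop only terms containing BOTH grouping and covariate
    fac <- attr(fit$terms, "factors")
    both <- colSums(fac[rownames(fac) %in% c(grouping, covariate), , drop = FALSE] > 0) >= 2L
    if (!any(both)) stop("model has no ", grouping, ":", covariate, " interaction")
    keep <- fit$assign %in% c(0L, which(!both))
    stat_fun <- function(beta) {
      slopes <- Xd %*% beta            # one slope vector per level
      lens <- sqrt(rowSums(slopes^2))
      out <- matrix(NA_real_, nrow(pairs), 2L)
      for (r in seq_len(nrow(pairs))) {
        i <- match(pairs[r, 1L], lev); j <- match(pairs[r, 2L], lev)
        cosang <- sum(slopes[i, ] * slopes[j, ]) / (lens[i] * lens[j])
        out[r, ] <- c(abs(lens[i] - lens[j]),
                      acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
      }
      out
    }
  }

  q_red <- qr(fit$X[, keep, drop = FALSE])
  fit_red <- qr.fitted(q_red, fit$Y)
  res_red <- fit$Y - fit_red
  beta_for <- function(idx) {
    Ystar <- fit_red + res_red[idx, , drop = FALSE]
    qr.coef(q_full, Ystar)
  }
  obs <- stat_fun(beta_for(seq_len(fit$n)))
  perm_vals <- lapply(seq_len(fit$n_perm), function(m)
    stat_fun(beta_for(fit$perms[m, ])))

  summarize <- function(observed, draws) {
    all_v <- c(observed, draws)
    p <- mean(all_v >= observed - 1e-12)
    s <- sd(all_v)
    z <- if (s > 0) (observed - mean(all_v)) / s else 0
    c(Z = z, P = p)
  }

  if (statistic == "mean_distance") {
    res <- data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
                      distance = obs, stringsAsFactors = FALSE)
    pm <- do.call(rbind, perm_vals)  # n_perm x n_pairs
    zs <- t(vapply(seq_len(nrow(pairs)), function(r)
      summarize(obs[r], pm[, r]), numeric(2L)))
    res$Z <- zs[, 1L]; res$P <- zs[, 2L]
  } else {
    res <- data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
                      length_diff = obs[, 1L], angle_deg = obs[, 2L],
                      stringsAsFactors = FALSE)
    pm_len <- t(vapply(perm_vals, function(v) v[, 1L], numeric(nrow(pairs))))
    pm_ang <- t(vapply(perm_vals, function(v) v[, 2L], numeric(nrow(pairs))))
    if (nrow(pairs) == 1L) { pm_len <- t(pm_len); pm_ang <- t(pm_ang) }
    zl <- t(vapply(seq_len(nrow(pairs)), function(r)
      summarize(obs[r, 1L], pm_len[, r]), numeric(2L)))
    za <- t(vapply(seq_len(nrow(pairs)), function(r)
      summarize(obs[r, 2L], pm_ang[, r]), numeric(2L)))
    res$Z_length <- zl[, 1L]; res$P_length <- zl[, 2L]
    res$Z_angle <- za[, 1L]; res$P_angle <- za[, 2L]
  }
  res
}
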