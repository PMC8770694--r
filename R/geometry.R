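# Superimposition and shape-derived scalar traits.

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of the landmarks from their centroid.  Scales
#' linearly under uniform scaling of the configuration.
#'
#' @param x A [landmark_config] or a k x 3 numeric matrix without missing
#'   landmarks.
#' @return A single positive number (0, with a warning, for a degenerate
#'   configuration whose landmarks coincide).
#' @export
centroid_size <- function(x) {
  m <- if (inherits(x, "landmark_config")) {
    if (any(x$missing)) stop("centroid_size: configuration has missing landmarks; estimate them first")
    x$coords
  } else as.matrix(x)
  if (any(!is.finite(m))) stop("centroid_size: non-finite coordinates")
  cs <- sqrt(sum(scale(m, scale = FALSE)^2))
  if (cs == 0) warning("degenerate configuration: all landmarks coincide")
  cs
}

center_config <- function(m) scale(m, scale = FALSE)

# Orthogonal (rotation-only) Procrustes solution rotating A onto B.
# Both are assumed centered.  Reflections are disallowed: the sign of the
# smallest singular value's column is flipped when det < 0.
rotation_onto <- function(A, B) {
  sv <- svd(crossprod(A, B))
  U <- sv$u; V <- sv$v
  if (det(U %*% t(V)) < 0) U[, ncol(U)] <- -U[, ncol(U)]
  U %*% t(V)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: each configuration
#' is centred at the origin, scaled to unit centroid size, and rotated onto
#' the current consensus by rotation-only orthogonal Procrustes (det = +1
#' enforced); the consensus (per-landmark mean, re-normalised to unit
#' centroid size) is then updated, until its summed squared displacement
#' falls below `tol`.  Aligned coordinates are used directly as Euclidean
#' tangent coordinates (no separate orthogonal projection).
#'
#' @param x List of complete [landmark_config] objects (>= 2, equal k) or a
#'   k x 3 x n array.
#' @param tol Convergence tolerance on the summed squared consensus
#'   displacement between iterations.
#' @param max_iter Maximum number of update sweeps.
#' @return An object of class `procrustes_fit`: `coords` (k x 3 x n aligned,
#'   each centred with unit centroid size), `centroid_size` (mm),
#'   `log_centroid_size` (computed from the raw coordinates, before
#'   scaling), `consensus` (k x 3), `iterations`, `converged`, `specimens`,
#'   `species`.
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 100L) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "landmark_config"))) {
    if (any(vapply(x, function(cf) any(cf$missing), TRUE)))
      stop("gpa: configurations contain missing landmarks; estimate them first")
    arr <- as_landmark_array(x)
    species <- config_species(x)
  } else {
    arr <- x
    species <- dimnames(arr)[[3L]]
  }
  n <- dim(arr)[3L]
  if (n < 2L) stop("gpa needs at least 2 configurations")
  if (any(!is.finite(arr))) stop("gpa: non-finite coordinates")
  csize <- apply(arr, 3L, centroid_size)
  aligned <- array(NA_real_, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) aligned[, , i] <- center_config(arr[, , i]) / csize[i]
  consensus <- center_config(aligned[, , 1L])
  consensus <- consensus / sqrt(sum(consensus^2))
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (i in seq_len(n))
      aligned[, , i] <- aligned[, , i] %*% rotation_onto(aligned[, , i], consensus)
    new_cons <- apply(aligned, c(1L, 2L), mean)
    new_cons <- center_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sum((new_cons - consensus)^2)
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("gpa did not converge in ", max_iter, " iterations")
  structure(list(coords = aligned,
                 centroid_size = csize,
                 log_centroid_size = log(csize),
                 consensus = consensus,
                 iterations = iterations,
                 converged = converged,
                 specimens = dimnames(arr)[[3L]],
                 species = species),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("<procrustes_fit> %d specimens x %d landmarks; %d iteration(s), converged=%s\n",
              dim(x$coords)[3L], dim(x$coords)[1L], x$iterations, x$converged))
  invisible(x)
}

#' Flatten aligned coordinates to an n x 3k matrix
#'
#' Rows are specimens (named), columns are `label.x`, `label.y`, `label.z`
#' in landmark order.
#'
#' @param fit A `procrustes_fit`, or a k x 3 x n array.
#' @return Numeric matrix n x 3k.
#' @export
flatten_coords <- function(fit) {
  a <- if (inherits(fit, "procrustes_fit")) fit$coords else fit
  k <- dim(a)[1L]; n <- dim(a)[3L]
  m <- t(apply(a, 3L, function(cfg) as.vector(t(cfg))))
  dim(m) <- c(n, 3L * k)
  rownames(m) <- dimnames(a)[[3L]]
  lbl <- dimnames(a)[[1L]]
  if (is.null(lbl)) lbl <- paste0("L", seq_len(k))
  colnames(m) <- as.vector(t(outer(lbl, c("x", "y", "z"), paste, sep = ".")))
  m
}

#' Rebuild a k x 3 x n array from a flattened matrix
#' @param m n x 3k matrix as produced by [flatten_coords()].
#' @return k x 3 x n array.
#' @export
unflatten_coords <- function(m) {
  n <- nrow(m); k <- ncol(m) / 3L
  a <- array(NA_real_, c(k, 3L, n))
  for (i in seq_len(n)) a[, , i] <- matrix(m[i, ], k, 3L, byrow = TRUE)
  dimnames(a)[[3L]] <- rownames(m)
  a
}

#' Procrustes distance between two aligned shapes
#'
#' Euclidean norm of the coordinate difference between two configurations
#' superimposed in a common GPA.
#'
#' @param a,b k x 3 matrices (or flattened vectors) of aligned coordinates.
#' @return Non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("shape dimension mismatch")
  sqrt(sum((a - b)^2))
}

#' Symmetric (one-sided) landmark subset
#'
#' For the 53-landmark cranial template, drops the left-side lateral
#' landmarks 23-44, leaving the 31 midline + right-side landmarks; used by
#' the modularity analyses to avoid left/right redundancy.
#'
#' @param x A [landmark_config], a k x 3 x n array, or a `procrustes_fit`.
#' @param drop Landmark indices (1-based) to remove; default `23:44`.
#' @return Same type as the input, with the landmarks removed in place
#'   (retained landmark order preserved).
#' @export
symmetric_subset <- function(x, drop = 23:44) {
  if (inherits(x, "landmark_config")) {
    if (nrow(x$coords) != 53L)
      stop("symmetric_subset expects the 53-landmark configuration")
    keep <- setdiff(seq_len(53L), drop)
    return(landmark_config(x$specimen_id, x$species, x$coords[keep, , drop = FALSE],
                           x$landmark_labels[keep], x$missing[keep],
                           x$sex, x$scan_type))
  }
  if (inherits(x, "procrustes_fit")) {
    if (dim(x$coords)[1L] != 53L)
      stop("symmetric_subset expects 53 landmarks")
    keep <- setdiff(seq_len(53L), drop)
    out <- x
    out$coords <- x$coords[keep, , , drop = FALSE]
    out$consensus <- x$consensus[keep, , drop = FALSE]
    return(out)
  }
  if (dim(x)[1L] != 53L) stop("symmetric_subset expects 53 landmarks")
  x[setdiff(seq_len(53L), drop), , , drop = FALSE]
}

#' Facial length index
#'
#' Face length (orbit to anterior premaxilla) over ventral cranial length,
#' measured as interlandmark distances 5-13 and 5-52 on the raw,
#' untransformed coordinates.  Being a ratio it is scale-invariant.
#'
#' @param config A [landmark_config] with landmarks 5, 13 and 52 present.
#' @param i_orbit,i_premax,i_posterior 1-based landmark indices of the
#'   orbit, anterior premaxilla and posterior ventral cranium.
#' @return A single positive number.
#' @export
facial_length <- function(config, i_orbit = 5L, i_premax = 13L, i_posterior = 52L) {
  idx <- c(i_orbit, i_premax, i_posterior)
  if (any(idx > nrow(config$coords)))
    stop("facial_length: landmark index out of range")
  if (any(config$missing[idx]))
    stop("facial_length: required landmark(s) missing: ",
         paste(idx[config$missing[idx]], collapse = ", "))
  m <- config$coords
  face <- sqrt(sum((m[i_orbit, ] - m[i_premax, ])^2))
  base <- sqrt(sum((m[i_orbit, ] - m[i_posterior, ])^2))
  if (base == 0) stop("facial_length: zero ventral cranial length")
  face / base
}
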