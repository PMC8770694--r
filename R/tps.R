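# Thin-plate spline interpolation in 3D and missing-landmark estimation.

#' Fit a 3D thin-plate spline interpolant
#'
#' Solves the standard TPS system with radial kernel U(r) = r (the 3D
#' biharmonic fundamental solution) plus an affine part.  The returned
#' function maps arbitrary 3D points; it reproduces the anchors exactly and
#' reproduces any affine map exactly.
#'
#' @param src m x 3 matrix of source anchor positions (m >= 4, not
#'   coplanar).
#' @param dst m x 3 matrix of target anchor positions.
#' @return A function taking an n x 3 matrix and returning the warped
#'   n x 3 matrix.
#' @export
tps3d <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  m <- nrow(src)
  if (m < 4L) stop("tps3d needs at least 4 anchor landmarks")
  if (nrow(dst) != m) stop("src and dst must have the same number of rows")
  K <- as.matrix(dist(src))             # U(r) = r
  P <- cbind(1, src)
  if (qr(P)$rank < 4L)
    stop("tps3d: anchors are coplanar; the TPS system is singular")
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(dst, matrix(0, 4L, 3L))
  W <- tryCatch(solve(L, rhs),
                error = function(e) stop("tps3d: singular TPS system: ",
                                         conditionMessage(e)))
  w <- W[seq_len(m), , drop = FALSE]
  a <- W[m + 1:4, , drop = FALSE]
  function(pts) {
    pts <- matrix(as.numeric(pts), ncol = 3L)
    U <- sqrt(outer(rowSums(pts^2), rep(1, m)) +
              outer(rep(1, nrow(pts)), rowSums(src^2)) -
              2 * pts %*% t(src))
    U[U < 0 | !is.finite(U)] <- 0
    U %*% w + cbind(1, pts) %*% a
  }
}

#' Estimate missing landmarks by thin-plate spline
#'
#' A TPS interpolant is fit from the reference configuration's positions at
#' the target's observed landmarks to the target's observed positions, and
#' evaluated at the reference positions of the missing landmarks.  When
#' several references are supplied their GPA consensus (at their mean
#' centroid size) is used; in a pipeline the natural references are the
#' complete specimens of the same species when available, otherwise all
#' complete specimens.
#'
#' @param target A [landmark_config] with missing landmarks and at least 4
#'   non-coplanar observed landmarks.
#' @param references A single complete [landmark_config] or a list of them.
#' @return The completed [landmark_config]; the missing mask is cleared and
#'   the indices of estimated landmarks recorded in the `estimated`
#'   element.
#' @export
estimate_missing_tps <- function(target, references) {
  if (inherits(references, "landmark_config")) references <- list(references)
  if (!length(references)) stop("estimate_missing_tps: no reference configurations")
  if (any(vapply(references, function(cf) any(cf$missing), TRUE)))
    stop("estimate_missing_tps: references must be complete")
  if (!any(target$missing)) return(target)
  ref <- if (length(references) == 1L) {
    references[[1L]]$coords
  } else {
    al <- gpa(references)
    al$consensus * mean(al$centroid_size)
  }
  obs <- which(!target$missing)
  if (length(obs) < 4L)
    stop("estimate_missing_tps: fewer than 4 observed anchor landmarks")
  warp <- tps3d(ref[obs, , drop = FALSE], target$coords[obs, , drop = FALSE])
  out <- target$coords
  mis <- which(target$missing)
  out[mis, ] <- warp(ref[mis, , drop = FALSE])
  cfg <- landmark_config(target$specimen_id, target$species, out,
                         target$landmark_labels,
                         missing = rep(FALSE, nrow(out)),
                         sex = target$sex, scan_type = target$scan_type)
  cfg$estimated <- mis
  cfg
}

#' Complete a landmark dataset by TPS estimation
#'
#' Applies [estimate_missing_tps()] to every incomplete configuration,
#' preferring complete conspecific specimens as references and falling back
#' to all complete specimens.
#'
#' @param configs List of [landmark_config].
#' @return List of complete configurations.
#' @export
estimate_missing_all <- function(configs) {
  complete <- Filter(function(cf) !any(cf$missing), configs)
  if (!length(complete)) stop("no complete reference specimens available")
  sp <- config_species(complete)
  lapply(configs, function(cf) {
    if (!any(cf$missing)) return(cf)
    refs <- complete[sp == cf$species]
    if (!length(refs)) refs <- complete
    estimate_missing_tps(cf, refs)
  })
}
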