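# A bilaterally symmetric 53-landmark cranial template and the anatomical
# module schemes defined over its one-sided (31 landmark) subset.
#
# Layout: landmarks 1-22 right side, 23-44 left side (mirror of 1-22 in the
# same order), 45-53 midline.  Anterior is +x, dorsal +z, right +y; units mm
# (a ~300 mm adult bovid-sized cranium).  Landmark 5 sits on the anterior
# orbit, 13 on the anterior premaxilla and 52 on the posterior ventral
# midline, so the facial length index (5-13 over 5-52) is meaningful.
# The anatomical labels are placeholders a user can edit; they exist so that
# named module schemes resolve to concrete landmark indices.

template_right_side <- function() {
  # label, region, x, y, z
  df <- data.frame(
    label  = c("premaxilla_lateral_r", "premaxilla_canine_r", "maxilla_anterior_r",
               "maxilla_molar_r", "orbit_anterior_r", "orbit_posterior_r",
               "orbit_dorsal_r", "orbit_ventral_r", "lacrimal_r",
               "nasal_lateral_r", "nasofrontal_suture_r", "frontal_lateral_r",
               "premaxilla_anterior_r", "frontal_postorbital_r",
               "zygomatic_anterior_r", "zygomatic_arch_r", "temporal_fossa_r",
               "palatine_anterior_r", "palatine_posterior_r",
               "basioccipital_lateral_r", "occipital_condyle_r",
               "occipital_lateral_r"),
    region = c("premaxilla", "premaxilla", "maxilla", "maxilla", "orbit",
               "orbit", "orbit", "orbit", "maxilla", "nasal", "nasal",
               "frontal", "premaxilla", "frontal", "temporal", "temporal",
               "temporal", "palatine", "palatine", "basioccipital",
               "basioccipital", "occipital"),
    x = c(142, 126, 96, 58, 36, 2, 18, 20, 50, 84, 40, 12, 148, -8,
          44, -4, -30, 88, 36, -96, -128, -120),
    y = c(18, 25, 29, 33, 38, 41, 31, 45, 34, 22, 20, 26, 12, 34,
          48, 52, 40, 16, 18, 14, 20, 30),
    z = c(-12, -18, -22, -26, 14, 20, 36, -2, 8, 30, 40, 46, -6, 44,
          -14, 6, 30, -30, -28, -26, -20, 18),
    stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 22L)
  df
}

template_midline <- function() {
  df <- data.frame(
    label  = c("premaxilla_tip", "nasal_anterior", "nasal_posterior",
               "frontal_midline", "palatine_midline", "occipital_crest",
               "foramen_magnum_dorsal", "basioccipital_ventral", "opisthion"),
    region = c("premaxilla", "nasal", "nasal", "frontal", "palatine",
               "occipital", "occipital", "basioccipital", "occipital"),
    x = c(152, 110, 28, 0, 60, -132, -138, -110, -134),
    y = rep(0, 9L),
    z = c(-4, 34, 44, 50, -30, 34, 4, -24, -6),
    stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 9L)
  df
}

#' Synthetic 53-landmark cranial template
#'
#' A deterministic, bilaterally symmetric polyhedral "cranium": 22 right
#' lateral landmarks (1-22), their left mirrors (23-44) and 9 midline
#' landmarks (45-53), each carrying a placeholder anatomical label and a
#' cranial region used by the named module schemes.
#'
#' @return A list with `coords` (53 x 3, mm), `labels` (length 53),
#'   `regions` (length 53).
#' @export
cranium_template <- function() {
  r <- template_right_side()
  m <- template_midline()
  l <- r
  l$label <- sub("_r$", "_l", l$label)
  l$y <- -l$y
  all <- rbind(r, l, m)
  coords <- as.matrix(all[, c("x", "y", "z")])
  rownames(coords) <- all$label
  list(coords = coords, labels = all$label, regions = all$region)
}

#' Anatomical module schemes over the one-sided landmark subset
#'
#' Returns the named partitions of the 31 retained landmarks (right side +
#' midline, i.e. the 53-landmark template after [symmetric_subset()]) used
#' by the modularity analyses: a two-module facial/neurocranial scheme
#' (`mammalia2`), a `tripartite` braincase/orbital/anterior-facial scheme,
#' a `four`-module scheme, the nine-module per-bone `element` scheme, and a
#' six-module `mammalia6` scheme.  Assignments derive from the template's
#' region labels and are editable (they are plain character vectors).
#'
#' @return Named list of character vectors of length 31 (module label per
#'   retained landmark, in retained-landmark order).
#' @export
module_schemes <- function() {
  tpl <- cranium_template()
  keep <- setdiff(seq_len(53L), 23:44)
  region <- tpl$regions[keep]
  map <- function(lut) unname(lut[region])
  element <- region
  mammalia2 <- map(c(premaxilla = "facial", maxilla = "facial", nasal = "facial",
                     palatine = "facial", orbit = "facial",
                     frontal = "neurocranial", temporal = "neurocranial",
                     basioccipital = "neurocranial", occipital = "neurocranial"))
  tripartite <- map(c(premaxilla = "anterior_facial", maxilla = "anterior_facial",
                      nasal = "anterior_facial", palatine = "anterior_facial",
                      orbit = "orbital",
                      frontal = "braincase", temporal = "braincase",
                      basioccipital = "braincase", occipital = "braincase"))
  four <- map(c(frontal = "fronto_orbital", orbit = "fronto_orbital",
                maxilla = "oral", palatine = "oral",
                premaxilla = "snout", nasal = "snout",
                temporal = "temporal_occipital", basioccipital = "temporal_occipital",
                occipital = "temporal_occipital"))
  mammalia6 <- map(c(premaxilla = "anterior_oral_nasal", nasal = "anterior_oral_nasal",
                     basioccipital = "basicranium",
                     frontal = "cranial_vault", occipital = "cranial_vault",
                     maxilla = "molar", palatine = "molar",
                     orbit = "orbit", temporal = "zygomatic_pterygoid"))
  list(mammalia2 = mammalia2, tripartite = tripartite, four = four,
       element = element, mammalia6 = mammalia6)
}

#' Default allometric shape-change vector for the template
#'
#' A unit vector in the 159-dimensional tangent space of the unit-size
#' template describing facial elongation with dorsal flexion: anterior
#' landmarks displace anteriorly and ventrally with increasing size,
#' posterior landmarks compress.  Components along the similarity
#' directions (translations, rotations, scaling of the template) are
#' projected out so the planted effect survives Procrustes superimposition.
#'
#' @return Numeric vector of length 159 (53 landmarks x 3), unit norm.
#' @export
default_allometry_vector <- function() {
  tpl <- cranium_template()$coords
  tpl <- scale(tpl, scale = FALSE)
  tpl <- tpl / sqrt(sum(tpl^2))
  xs <- tpl[, 1L]
  v <- cbind(xs * 1.5,              # elongation along the facial axis
             0 * xs,
             -0.6 * xs * abs(xs))   # snout drops, braincase flexes
  v <- as.numeric(project_out_similarity(as.vector(t(v)), tpl))
  v / sqrt(sum(v^2))
}

# Symmetric projector onto the shape tangent space at configuration `ref`
# (k x 3, centered, unit size): the orthogonal complement of the 7
# similarity directions (3 translations, 3 infinitesimal rotations, 1
# scaling).
tangent_projector <- function(ref) {
  Q <- similarity_basis(ref)
  diag(3L * nrow(ref)) - Q %*% t(Q)
}

similarity_basis <- function(ref) {
  k <- nrow(ref)
  basis <- list()
  for (d in 1:3) {
    t_d <- matrix(0, k, 3L); t_d[, d] <- 1
    basis <- c(basis, list(as.vector(t(t_d))))
  }
  axes <- diag(3L)
  for (d in 1:3) {
    r_d <- t(apply(ref, 1L, function(p) crossprod_3(axes[d, ], p)))
    basis <- c(basis, list(as.vector(t(r_d))))
  }
  basis <- c(basis, list(as.vector(t(ref))))
  qr.Q(qr(do.call(cbind, basis)))
}

# Remove the components of a flattened displacement vector that lie in the
# similarity-transform tangent space at configuration `ref` (k x 3 centered,
# unit size): 3 translations, 3 infinitesimal rotations, 1 scaling.
project_out_similarity <- function(v, ref) {
  k <- nrow(ref)
  basis <- list()
  for (d in 1:3) {
    t_d <- matrix(0, k, 3L); t_d[, d] <- 1
    basis <- c(basis, list(as.vector(t(t_d))))
  }
  axes <- diag(3L)
  for (d in 1:3) {
    r_d <- t(apply(ref, 1L, function(p) crossprod_3(axes[d, ], p)))
    basis <- c(basis, list(as.vector(t(r_d))))
  }
  basis <- c(basis, list(as.vector(t(ref))))
  B <- do.call(cbind, basis)
  Q <- qr.Q(qr(B))
  v - Q %*% crossprod(Q, v)
}

crossprod_3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}
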