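# Seeded synthetic data: trees, Brownian traits, landmark datasets and
# occurrence grids with the statistical structure the analyses assume.

#' Simulate a dated pure-birth tree
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param seed Integer seed; the same seed reproduces the same tree.
#' @param depth Root age the tree is rescaled to, in Myr (default 20,
#'   roughly the crown age of Bovidae); `NULL` keeps the raw depth.
#' @return An ultrametric `phylo` with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1L, depth = 20) {
  if (n_tips < 2L) stop("simulate_tree needs n_tips >= 2")
  set.seed(seed)
  tree <- phytools::pbtree(b = birth_rate, n = n_tips, quiet = TRUE)
  if (!is.null(depth)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * depth / h
    # absorb floating-point drift into the terminal branches so tip depths
    # are exactly equal
    d <- ape::node.depth.edgelength(tree)
    tip_edges <- match(seq_len(n_tips), tree$edge[, 2L])
    tree$edge.length[tip_edges] <- tree$edge.length[tip_edges] +
      depth - d[seq_len(n_tips)]
  }
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Simulate correlated Brownian-motion traits on a tree
#'
#' Tip values are multivariate normal with covariance `C %x% R`, where `C`
#' is the shared-path-length (phylogenetic) covariance matrix and `R` the
#' among-trait rate matrix: `X = root + L_C Z L_R'` with Cholesky factors
#' of `C` and `R`.
#'
#' @param tree `phylo` with branch lengths.
#' @param R p x p symmetric positive semi-definite rate matrix (a scalar is
#'   promoted to `R * diag(p = 1)`).
#' @param root Root state, scalar or length-p vector.
#' @param seed Integer seed.
#' @return n_tips x p matrix, rows named by tip labels.
#' @export
simulate_bm_traits <- function(tree, R, root = 0, seed = 1L) {
  if (is.null(dim(R))) R <- diag(length(R)) * R
  R <- as.matrix(R)
  if (!isSymmetric(unname(R), tol = 1e-8)) stop("rate matrix R must be symmetric")
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("rate matrix R must be positive semi-definite")
  set.seed(seed)
  C <- ape::vcv(tree)
  n <- nrow(C); p <- nrow(R)
  LC <- chol_psd(C)
  LR <- chol_psd(R)
  root <- rep_len(root, p)
  X <- LC %*% matrix(rnorm(n * p), n, p) %*% t(LR)
  X <- sweep(X, 2L, root, `+`)
  rownames(X) <- rownames(C)
  X
}

# Lower-triangular factor tolerant of semi-definite matrices.
chol_psd <- function(M) {
  ch <- tryCatch(t(chol(M)), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ev <- eigen(M, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(vals), nrow = length(vals))
}

#' Specification for a synthetic landmark dataset
#'
#' Defaults emulate the structure of the study dataset this package is
#' built around: 141 specimens of 96 species (1-3 specimens per species),
#' 53 landmarks, Brownian-motion shape evolution on a dated tree with a
#' shared size-shape allometric axis, optional planted modular covariance,
#' intraspecific/measurement noise, and two scan-type labels.
#'
#' @param n_species Number of species.
#' @param n_specimens Total specimen count (extra specimens beyond one per
#'   species are spread over randomly chosen species, at most
#'   `max_per_species` each).
#' @param max_per_species Cap on specimens per species.
#' @param k_landmarks Landmark count; only 53 (the template) is supported.
#' @param bm_rate Per-coordinate Brownian rate of shape evolution, in
#'   squared shape units per Myr.
#' @param size_rate Brownian rate of log centroid size, per Myr.
#' @param allometry_vector Unit direction of allometric shape change
#'   (length 3k); default [default_allometry_vector()].
#' @param allometry_strength Shape displacement (Procrustes units) per unit
#'   log centroid size.
#' @param module_assignment Optional named module labels (length 31, over
#'   the one-sided subset, as in [module_schemes()]); mirrored to the left
#'   side.  `NULL` plants no modular structure.
#' @param within_module_corr,between_module_corr Coordinate correlations of
#'   the shape rate matrix within and between modules (`[0, 1]`, within >=
#'   between for planted modularity).  With no module assignment the
#'   `between_module_corr` applies to all coordinate pairs.
#' @param intraspecific_sd Per-coordinate intraspecific + measurement noise
#'   SD, in shape units.
#' @param scan_effect Magnitude of a planted CT-vs-surface shape offset
#'   (default 0 = no scanner bias).
#' @param seed Integer seed governing the whole dataset.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_species = 96L, n_specimens = 141L,
                            max_per_species = 3L, k_landmarks = 53L,
                            bm_rate = 1e-6, size_rate = 0.01,
                            allometry_vector = NULL, allometry_strength = 0.05,
                            module_assignment = NULL,
                            within_module_corr = 0.2, between_module_corr = 0.2,
                            intraspecific_sd = 0.0015,
                            scan_effect = 0, seed = 1L) {
  if (k_landmarks != 53L) stop("the synthetic template has 53 landmarks")
  stopifnot(within_module_corr >= 0, within_module_corr <= 1,
            between_module_corr >= 0, between_module_corr <= 1,
            n_specimens >= n_species,
            n_specimens <= n_species * max_per_species)
  if (!is.null(module_assignment)) {
    if (length(module_assignment) != 31L)
      stop("module_assignment must cover the 31 one-sided landmarks")
    if (within_module_corr < between_module_corr)
      stop("planted modularity requires within_module_corr >= between_module_corr")
  }
  if (is.null(allometry_vector)) allometry_vector <- default_allometry_vector()
  structure(list(n_species = as.integer(n_species),
                 n_specimens = as.integer(n_specimens),
                 max_per_species = as.integer(max_per_species),
                 k_landmarks = 53L, bm_rate = bm_rate, size_rate = size_rate,
                 allometry_vector = allometry_vector,
                 allometry_strength = allometry_strength,
                 module_assignment = module_assignment,
                 within_module_corr = within_module_corr,
                 between_module_corr = between_module_corr,
                 intraspecific_sd = intraspecific_sd,
                 scan_effect = scan_effect, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Expand a one-sided module assignment (31 labels) to all 53 landmarks:
# left-side landmark 22+i inherits the module of right-side landmark i.
expand_modules_full <- function(assignment31) {
  right <- assignment31[1:22]
  mid <- assignment31[23:31]
  c(right, right, mid)
}

# Correlation structure of the 3k-coordinate shape rate matrix.  The
# block-correlation matrix is projected onto the shape tangent space of the
# template (similarity-transform directions removed), because shape BM is
# simulated in that tangent space: variation along translations, rotations
# or scaling of the template is not shape variation and would be silently
# absorbed by the downstream superimposition.
shape_rate_matrix <- function(spec) {
  k <- spec$k_landmarks
  if (is.null(spec$module_assignment)) {
    mod <- rep("all", k)
    within <- spec$between_module_corr
  } else {
    mod <- expand_modules_full(spec$module_assignment)
    within <- spec$within_module_corr
  }
  mod3 <- rep(mod, each = 3L)
  same <- outer(mod3, mod3, `==`)
  R <- ifelse(same, within, spec$between_module_corr)
  diag(R) <- 1
  tpl <- cranium_template()$coords
  tpl <- scale(tpl, scale = FALSE)
  tpl <- tpl / sqrt(sum(tpl^2))
  Pt <- tangent_projector(tpl)
  Pt %*% R %*% Pt * spec$bm_rate
}

#' Simulate a full landmark dataset on a tree
#'
#' Per species, the flattened shape (in the tangent space of the unit-size
#' template) is `template + allometry_strength * allometry_vector *
#' (log CS - mean log CS) + BM deviation`, where the BM deviation evolves
#' with the block rate matrix implied by the module assignment and log
#' centroid size itself evolves by univariate BM.  Each specimen adds iid
#' per-coordinate intraspecific noise, is scaled to its centroid size in mm
#' and is then randomly rotated and translated, so downstream
#' superimposition is genuinely exercised.
#'
#' @param spec A [simulation_spec].
#' @param tree Optional `phylo` with `spec$n_species` tips; simulated by
#'   [simulate_tree()] from `spec$seed` when omitted.
#' @return List with `configs` (list of [landmark_config]),
#'   `species_table` (data.frame: species, tribe, subfamily, diet,
#'   hypsodonty, body_mass), `tree`, and `true` (the generating parameters:
#'   per-species log sizes, species shape matrix, allometry vector and
#'   strength, rate matrix details).
#' @export
simulate_landmark_dataset <- function(spec, tree = NULL) {
  if (is.null(tree)) tree <- simulate_tree(spec$n_species, seed = spec$seed)
  if (length(tree$tip.label) != spec$n_species)
    stop("tree tip count does not match spec$n_species")
  tpl <- cranium_template()
  tpl_c <- scale(tpl$coords, scale = FALSE)
  tpl_unit <- tpl_c / sqrt(sum(tpl_c^2))
  tpl_vec <- as.vector(t(tpl_unit))
  k <- spec$k_landmarks
  root_logcs <- log(sqrt(sum(tpl_c^2)))   # template centroid size, mm

  logcs <- simulate_bm_traits(tree, spec$size_rate, root = root_logcs,
                              seed = spec$seed + 11L)[, 1L]
  R <- shape_rate_matrix(spec)
  dev <- simulate_bm_traits(tree, R, root = 0, seed = spec$seed + 23L)
  allo <- spec$allometry_strength * outer(logcs - mean(logcs), spec$allometry_vector)
  shapes <- matrix(tpl_vec, spec$n_species, 3L * k, byrow = TRUE) + allo + dev
  rownames(shapes) <- tree$tip.label

  set.seed(spec$seed + 37L)
  # specimen allocation: everyone gets 1; extras spread with a per-species cap
  n_extra <- spec$n_specimens - spec$n_species
  counts <- rep(1L, spec$n_species)
  if (n_extra > 0L) {
    slots <- rep(seq_len(spec$n_species), spec$max_per_species - 1L)
    extra <- sample(slots)[seq_len(n_extra)]
    for (i in extra) counts[i] <- counts[i] + 1L
  }
  dual_scan <- counts > 1L & runif(spec$n_species) < 0.7

  configs <- vector("list", sum(counts))
  idx <- 0L
  scan_vec <- spec$scan_effect * default_allometry_vector()  # fixed offset direction
  for (s in seq_len(spec$n_species)) {
    sp <- tree$tip.label[s]
    for (j in seq_len(counts[s])) {
      idx <- idx + 1L
      scan <- if (dual_scan[s]) c("surface", "ct")[1L + (j %% 2L)] else
        sample(c("surface", "ct"), 1L, prob = c(0.7, 0.3))
      v <- shapes[s, ] + rnorm(3L * k, sd = spec$intraspecific_sd)
      if (scan == "ct") v <- v + scan_vec
      m <- matrix(v, k, 3L, byrow = TRUE)
      cs <- exp(logcs[s] + rnorm(1L, sd = 0.02))
      m <- scale(m, scale = FALSE)
      m <- m / sqrt(sum(m^2)) * cs
      m <- m %*% random_rotation() +
        matrix(runif(3L, -500, 500), k, 3L, byrow = TRUE)
      configs[[idx]] <- landmark_config(
        specimen_id = sprintf("%s_%d", sp, j), species = sp, coords = m,
        landmark_labels = tpl$labels,
        sex = sample(c("male", "female"), 1L, prob = c(0.9, 0.1)),
        scan_type = scan)
    }
  }
  species_table <- synth_species_table(tree, logcs, seed = spec$seed + 53L)
  list(configs = configs, species_table = species_table, tree = tree,
       true = list(log_centroid_size = logcs, species_shapes = shapes,
                   template = tpl_unit,
                   allometry_vector = spec$allometry_vector,
                   allometry_strength = spec$allometry_strength,
                   rate_matrix = R, counts = counts, dual_scan = dual_scan))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

tribe_name_pool <- c("Bovini", "Tragelaphini", "Boselaphini", "Cephalophini",
                     "Antilopini", "Neotragini", "Reduncini", "Alcelaphini",
                     "Hippotragini", "Caprini", "Aepycerotini", "Oreotragini",
                     "Peleini", "Ovibovini", "Saigini", "Rupicaprini")

# Tribes are monophyletic groups recovered by cutting the ultrametric tree;
# subfamilies are the two clades descending from the root.  Diet is drawn
# with a tribe-level bias; hypsodonty (available for a subset of species)
# rises with grazing; body mass follows size.
synth_species_table <- function(tree, logcs, n_tribes = 13L, n_hyps = 57L,
                                seed = 1L) {
  set.seed(seed)
  n <- length(tree$tip.label)
  n_tribes <- min(n_tribes, n)
  hc <- hclust(as.dist(ape::cophenetic.phylo(tree)), method = "average")
  tribe_id <- cutree(hc, k = n_tribes)
  tribes <- tribe_name_pool[seq_len(n_tribes)][tribe_id]
  names(tribes) <- hc$labels
  tribes <- tribes[tree$tip.label]

  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  clade1 <- if (kids[1L] <= n) tree$tip.label[kids[1L]] else
    ape::extract.clade(tree, kids[1L])$tip.label
  subfam <- ifelse(tree$tip.label %in% clade1, "Bovinae", "Antilopinae")

  diets <- c("browser", "grazer", "mixed", "frugivore")
  tribe_pref <- sample(diets, n_tribes, replace = TRUE, prob = c(0.35, 0.3, 0.3, 0.05))
  names(tribe_pref) <- tribe_name_pool[seq_len(n_tribes)]
  diet <- vapply(seq_len(n), function(i) {
    if (runif(1L) < 0.7) tribe_pref[[tribes[i]]] else
      sample(diets, 1L, prob = c(0.35, 0.3, 0.3, 0.05))
  }, "")

  hyp <- exp(rnorm(n, mean = 0.6, sd = 0.25)) *
    ifelse(diet == "grazer", 1.6, ifelse(diet == "mixed", 1.25, 1))
  keep_h <- sample.int(n, min(n_hyps, n))
  hypsodonty <- rep(NA_real_, n); hypsodonty[keep_h] <- hyp[keep_h]

  mass <- exp(3 * (logcs - mean(logcs)) + rnorm(n, sd = 0.3)) * 120
  data.frame(species = tree$tip.label, tribe = unname(tribes),
             subfamily = subfam, diet = diet, hypsodonty = hypsodonty,
             body_mass = mass, stringsAsFactors = FALSE)
}

#' Simulate a gridded occurrence table
#'
#' Emulates 1x1-degree occurrence extractions: each cell carries a habitat
#' class, a net-primary-productivity value and a species list.  Species
#' frequencies follow a Zipf-like skew so "top 20% most common" selection
#' is meaningful; NPP is drawn from a habitat-specific band of `npp_range`.
#'
#' @param n_cells Number of grid cells.
#' @param habitat_types Habitat class labels (default the five classes
#'   DXS, MGS, DBF, MBF, GSS).
#' @param npp_range Length-2 numeric range of NPP (trillions kg C per
#'   cell).
#' @param species_pool Character vector of species names (non-empty).
#' @param seed Integer seed.
#' @param min_richness Optional lower bound on per-cell species richness.
#' @return Long-format data.frame: `cell_id`, `lat`, `lon`, `habitat`,
#'   `npp`, `species` (one row per cell x species occurrence).
#' @export
simulate_occurrence_grid <- function(n_cells, habitat_types = c("DXS", "MGS", "DBF", "MBF", "GSS"),
                                     npp_range = c(0, 1100), species_pool,
                                     seed = 1L, min_richness = NULL) {
  if (!length(species_pool)) stop("species_pool is empty")
  set.seed(seed)
  nh <- length(habitat_types)
  hab <- sample(habitat_types, n_cells, replace = TRUE)
  # habitat-ordered NPP bands (deserts low, moist forests high), overlapping
  band <- match(hab, habitat_types)
  lo <- npp_range[1L] + (band - 1L) / nh * diff(npp_range) * 0.6
  hi <- lo + diff(npp_range) * 0.5
  npp <- pmin(runif(n_cells, lo, hi), npp_range[2L])
  w <- 1 / seq_along(species_pool)        # Zipf skew
  rich <- pmax(1L, rpois(n_cells, 5L))
  if (!is.null(min_richness)) rich <- pmax(rich, as.integer(min_richness))
  rich <- pmin(rich, length(species_pool))
  rows <- lapply(seq_len(n_cells), function(i) {
    spp <- sample(species_pool, rich[i], prob = w)
    data.frame(cell_id = sprintf("cell%04d", i),
               lat = round(runif(1L, -35, 55)), lon = round(runif(1L, -20, 140)),
               habitat = hab[i], npp = npp[i], species = spp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
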