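# Ordination and tree-aware morphospace statistics.

#' Principal components of shape
#'
#' Centered, unscaled PCA of flattened Procrustes shape coordinates.  The
#' decomposition is complete: `mean + scores %*% t(loadings)` reproduces
#' the input.
#'
#' @param x A `procrustes_fit` or an n x p numeric matrix (n >= 3).
#' @return Object of class `shape_pca`: `scores` (n x p), `loadings`,
#'   `eigenvalues` (variances, non-increasing), `variance_fraction`,
#'   `center`.
#' @export
shape_pca <- function(x) {
  Y <- if (inherits(x, "procrustes_fit")) flatten_coords(x) else as.matrix(x)
  if (nrow(Y) < 3L) stop("shape_pca needs at least 3 specimens")
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x, loadings = pc$rotation, eigenvalues = ev,
                 variance_fraction = ev / sum(ev), center = pc$center),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  vf <- round(100 * x$variance_fraction[1:min(3L, length(x$variance_fraction))], 1L)
  cat(sprintf("<shape_pca> %d specimens, %d dimensions; PC1-%d: %s%% of variance\n",
              nrow(x$scores), ncol(x$scores), length(vf),
              paste(vf, collapse = "/")))
  invisible(x)
}

#' Brownian-motion ancestral states
#'
#' Maximum-likelihood (equivalently, on an ultrametric tree, weighted
#' squared-change parsimony) estimates of internal-node values under BM,
#' one column per trait, via re-rooted ML (`phytools::fastAnc`).  The root
#' estimate equals the GLS phylogenetic mean.
#'
#' @param tree `phylo`.
#' @param tip_values Named vector or matrix (rows = species) matching the
#'   tree's tips.
#' @return Matrix of internal-node estimates (rows named by node number).
#' @export
ancestral_states_bm <- function(tree, tip_values) {
  if (is.null(dim(tip_values)))
    tip_values <- matrix(tip_values, ncol = 1L,
                         dimnames = list(names(tip_values), "trait"))
  if (!all(tree$tip.label %in% rownames(tip_values)))
    stop("tip_values rows do not cover the tree's tips")
  tip_values <- tip_values[tree$tip.label, , drop = FALSE]
  out <- apply(tip_values, 2L, function(y)
    phytools::fastAnc(tree, setNames(y, tree$tip.label)))
  out <- as.matrix(out)
  rownames(out) <- as.character(length(tree$tip.label) + seq_len(tree$Nnode))
  colnames(out) <- colnames(tip_values)
  out
}

#' Phylomorphospace scores
#'
#' Projects BM ancestral coordinate estimates onto the tip-defined PC axes
#' (ancestors do not influence the axes), giving tip and node scores for
#' plotting a phylomorphospace.
#'
#' @param pca A [shape_pca] whose rows are species matching `tree`.
#' @param tree `phylo`.
#' @param Y The species x coordinates matrix the PCA was computed from
#'   (rows named by species); defaults to reconstructing it from the PCA.
#' @return List with `tip_scores`, `node_scores` (both in PC space) and
#'   `root_score`.
#' @export
phylomorphospace_scores <- function(pca, tree, Y = NULL) {
  if (is.null(Y))
    Y <- sweep(pca$scores %*% t(pca$loadings), 2L, pca$center, `+`)
  anc <- ancestral_states_bm(tree, Y)
  node_scores <- sweep(anc, 2L, pca$center) %*% pca$loadings
  tips <- pca$scores[tree$tip.label, , drop = FALSE]
  list(tip_scores = tips, node_scores = node_scores,
       root_score = node_scores[1L, ])
}

#' Distance from the morphospace mean and central/peripheral split
#'
#' Euclidean distance of each species from the column-mean vector, computed
#' in the full shape space (invariant to how many PCs would be retained;
#' pass PC scores instead to work in a subspace).  Species are split into
#' equal-sized (within one) `central` and `peripheral` groups at the
#' median distance; ties are broken by species-name order so the split is
#' deterministic.
#'
#' @param x `procrustes_fit`, [shape_pca] (scores used) or numeric matrix
#'   with one row per species.
#' @return data.frame: `species`, `distance`, `centrality`.
#' @export
distance_from_mean <- function(x) {
  Y <- if (inherits(x, "procrustes_fit")) flatten_coords(x)
       else if (inherits(x, "shape_pca")) x$scores
       else as.matrix(x)
  ctr <- colMeans(Y)
  d <- sqrt(rowSums(sweep(Y, 2L, ctr)^2))
  sp <- rownames(Y)
  if (is.null(sp)) sp <- paste0("row", seq_len(nrow(Y)))
  ord <- order(d, sp)
  centrality <- character(length(d))
  n_central <- ceiling(length(d) / 2)
  centrality[ord[seq_len(n_central)]] <- "central"
  centrality[ord[-seq_len(n_central)]] <- "peripheral"
  data.frame(species = sp, distance = d, centrality = centrality,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' UPGMA phenogram of aligned specimens
#'
#' Average-linkage hierarchical clustering of the Euclidean distance matrix
#' of the Procrustes shape coordinates; used to check that conspecific
#' specimens cluster together (intraspecific variation smaller than
#' interspecific).
#'
#' @param x `procrustes_fit` or n x p matrix.
#' @return List with the `hclust` object and the equivalent `phylo`
#'   (exportable as Newick).
#' @export
upgma_phenogram <- function(x) {
  Y <- if (inherits(x, "procrustes_fit")) flatten_coords(x) else as.matrix(x)
  if (nrow(Y) < 2L) stop("upgma_phenogram needs at least 2 specimens")
  hc <- hclust(dist(Y), method = "average")
  list(hclust = hc, phylo = ape::as.phylo(hc))
}

#' Do conspecific specimens form exclusive clusters?
#'
#' For each multi-specimen species, checks whether its specimens form a
#' monophyletic group in the UPGMA phenogram.
#'
#' @param phenogram Result of [upgma_phenogram()].
#' @param species Character vector of species, parallel to the phenogram
#'   tips (specimen order of the clustered matrix).
#' @return Named logical vector over multi-specimen species.
#' @export
conspecific_clustering <- function(phenogram, species) {
  phy <- phenogram$phylo
  names(species) <- phenogram$hclust$labels
  tab <- table(species)
  multi <- names(tab[tab > 1L])
  vapply(multi, function(sp) {
    tips <- names(species)[species == sp]
    ape::is.monophyletic(phy, tips)
  }, TRUE)
}
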