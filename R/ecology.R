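# Discrete environmental covariates from gridded occurrence tables.

#' Reference NPP bin edges
#'
#' The net-primary-productivity category edges used with the original
#' global 1x1-degree extraction (trillions of kg C per cell):
#' 0-115, 115-320, 320-580, 580-1100.  Synthetic or re-extracted tables
#' should instead compute their own equal-count edges with [npp_bins()].
#' @export
npp_reference_edges <- c(0, 115, 320, 580, 1100)

check_occurrence <- function(table) {
  need <- c("cell_id", "habitat", "npp", "species")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("occurrence table lacks columns: ", paste(miss, collapse = ", "))
  if (any(table$npp < 0, na.rm = TRUE)) stop("npp must be >= 0")
  table
}

#' Filter occurrence cells and habitats
#'
#' Keeps only cells with at least `min_richness` species, then drops
#' habitat classes with `max_cells_cutoff` or fewer qualifying cells
#' (strictly more than the cutoff are required).
#'
#' @param table Long-format occurrence data.frame (`cell_id`, `habitat`,
#'   `npp`, `species`, one row per occurrence).
#' @param min_richness Minimum species per retained cell (default 4).
#' @param min_cells Cells per retained habitat must exceed this (default
#'   40).
#' @return The filtered table.
#' @export
filter_cells <- function(table, min_richness = 4L, min_cells = 40L) {
  check_occurrence(table)
  rich <- tapply(table$species, table$cell_id, function(s) length(unique(s)))
  ok_cells <- names(rich[rich >= min_richness])
  out <- table[table$cell_id %in% ok_cells, , drop = FALSE]
  cells_per_hab <- tapply(out$cell_id, out$habitat,
                          function(cc) length(unique(cc)))
  ok_hab <- names(cells_per_hab[cells_per_hab > min_cells])
  out <- out[out$habitat %in% ok_hab, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-habitat faunal lists of the most common species
#'
#' Within each habitat, species are ranked by the number of occupied
#' cells; the top `top_fraction` are retained.  The cutoff is
#' `ceiling(top_fraction * n_species)` ranks, and every species tied with
#' the species at the cutoff rank is included (inclusive tie rule), so the
#' result does not depend on input row order.  With `top_fraction = 1` the
#' lists equal the raw per-habitat species pools.
#'
#' @param table Filtered occurrence table.
#' @param top_fraction Fraction of most common species to keep (1, 0.5,
#'   0.2, ...).
#' @return Named list (habitat -> character vector of species, sorted by
#'   decreasing occurrence then name).
#' @export
habitat_faunal_lists <- function(table, top_fraction = 1) {
  check_occurrence(table)
  stopifnot(top_fraction > 0, top_fraction <= 1)
  habs <- sort(unique(table$habitat))
  out <- lapply(habs, function(h) {
    d <- table[table$habitat == h, , drop = FALSE]
    if (!nrow(d)) stop("empty habitat: ", h)
    counts <- tapply(d$cell_id, d$species, function(cc) length(unique(cc)))
    counts <- sort(counts, decreasing = TRUE)
    ord_names <- names(counts)[order(-counts, names(counts))]
    counts <- counts[ord_names]
    n_keep <- ceiling(top_fraction * length(counts))
    cutoff <- counts[n_keep]
    names(counts)[counts >= cutoff]
  })
  names(out) <- habs
  out
}

#' Equal-count NPP bins
#'
#' Divides the per-cell NPP range into `n_bins` categories with equal
#' numbers of cells (within one), by quantile edges.
#'
#' @param table Occurrence table (cell-level NPP is taken from the first
#'   row of each cell).
#' @param n_bins Number of bins (default 4).
#' @return List with `bins` (data.frame `cell_id`, `npp`, `bin`) and
#'   `edges` (length `n_bins + 1`, monotone).
#' @export
npp_bins <- function(table, n_bins = 4L) {
  check_occurrence(table)
  cells <- table[!duplicated(table$cell_id), c("cell_id", "npp")]
  if (nrow(cells) < n_bins) stop("fewer cells than bins")
  if (sd(cells$npp) == 0) stop("npp is constant; cannot bin")
  edges <- quantile(cells$npp, probs = seq(0, 1, length.out = n_bins + 1L),
                    type = 1L, names = FALSE)
  edges[1L] <- min(cells$npp); edges[n_bins + 1L] <- max(cells$npp)
  if (any(diff(edges) <= 0)) stop("npp bin edges are not strictly monotone (heavy ties)")
  bin <- cut(cells$npp, breaks = edges, include.lowest = TRUE,
             labels = paste0("npp", seq_len(n_bins)))
  list(bins = data.frame(cell_id = cells$cell_id, npp = cells$npp, bin = bin,
                         stringsAsFactors = FALSE),
       edges = edges)
}

#' Join ecological categories onto the species table
#'
#' Builds the long-format analysis table for habitat/NPP fits: one row per
#' species x category membership (a species commonly occurs under several
#' habitats or NPP bins, so rows duplicate species).  The result is
#' flagged `pgls_ok = FALSE`: [rrpp_lm()] refuses to fit a phylogenetic
#' model on it, because duplicated species violate the one-tip-per-row
#' assumption - use ordinary least squares.
#'
#' @param species_table data.frame with a `species` column.
#' @param faunal_lists Named list (category -> species), e.g. from
#'   [habitat_faunal_lists()], or from NPP bins via
#'   [npp_faunal_lists()].
#' @param category_name Name for the category column (default
#'   `"category"`).
#' @return data.frame of species rows joined with their categories, with
#'   attribute `pgls_ok = FALSE`.
#' @export
join_covariates <- function(species_table, faunal_lists,
                            category_name = "category") {
  if (!"species" %in% names(species_table))
    stop("species_table needs a 'species' column")
  all_listed <- unique(unlist(faunal_lists))
  missing_sp <- setdiff(all_listed, species_table$species)
  if (length(missing_sp))
    stop("species in faunal lists but not in species table: ",
         paste(missing_sp, collapse = ", "))
  rows <- lapply(names(faunal_lists), function(cat) {
    spp <- faunal_lists[[cat]]
    if (!length(spp)) return(NULL)
    d <- species_table[match(spp, species_table$species), , drop = FALSE]
    d[[category_name]] <- cat
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pgls_ok") <- FALSE
  out
}

#' Faunal lists per NPP bin
#'
#' Companion to [habitat_faunal_lists()] for NPP categories: species are
#' ranked by occupied cells within each bin, with the same inclusive tie
#' rule.
#'
#' @param table Occurrence table.
#' @param bins Result of [npp_bins()].
#' @param top_fraction Fraction of most common species to keep.
#' @return Named list (bin -> species).
#' @export
npp_faunal_lists <- function(table, bins, top_fraction = 1) {
  tab <- merge(table, bins$bins[, c("cell_id", "bin")], by = "cell_id")
  tab$habitat <- as.character(tab$bin)
  habitat_faunal_lists(tab, top_fraction)
}
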