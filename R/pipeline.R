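# Orchestration: subsetting, diagnostics, and the end-to-end analysis run.

#' Random one-specimen-per-species subset
#'
#' For species represented by several specimens, one is chosen uniformly
#' at random (seeded); species with a single specimen always contribute
#' it.  Repeating the analysis over different subsets propagates
#' intraspecific variation into the reported statistics.
#'
#' @param configs List of [landmark_config].
#' @param seed Optional integer seed.
#' @return List of configurations, one per species, named by species.
#' @export
phylogenetic_subset <- function(configs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- config_species(configs)
  idx <- vapply(split(seq_along(configs), sp), function(ii)
    if (length(ii) == 1L) ii else ii[sample.int(length(ii), 1L)], 0L)
  out <- configs[idx]
  names(out) <- names(idx)
  out
}

#' Repeat an analysis over random specimen subsets
#'
#' Runs `analysis` on `n_iter` independent one-per-species subsets and
#' summarizes the spread of each returned statistic.
#'
#' @param configs List of [landmark_config].
#' @param analysis Function taking a list of configurations (one per
#'   species) and returning a named numeric vector.
#' @param n_iter Number of subset iterations (default 20).
#' @param seed Integer seed; iteration i uses `seed + i`.
#' @return List with `values` (n_iter x k matrix) and `summary`
#'   (data.frame: statistic, min, median, max); iterations that fail are
#'   recorded in `errors` and excluded.
#' @export
iterate_analysis <- function(configs, analysis, n_iter = 20L, seed = 1L) {
  results <- vector("list", n_iter)
  errors <- character()
  for (i in seq_len(n_iter)) {
    sub <- phylogenetic_subset(configs, seed = seed + i)
    results[[i]] <- tryCatch(analysis(sub), error = function(e) {
      errors <<- c(errors, sprintf("iteration %d: %s", i, conditionMessage(e)))
      NULL
    })
  }
  ok <- !vapply(results, is.null, TRUE)
  if (!any(ok)) stop("all iterations failed: ", paste(errors, collapse = "; "))
  vals <- do.call(rbind, results[ok])
  summ <- data.frame(statistic = colnames(vals),
                     min = apply(vals, 2L, min),
                     median = apply(vals, 2L, median),
                     max = apply(vals, 2L, max), row.names = NULL,
                     stringsAsFactors = FALSE)
  list(values = vals, summary = summ, errors = errors)
}

#' Landmark rarefaction curves
#'
#' How much of the parent dataset's shape and size variation do reduced
#' landmark sets capture?  For each landmark count, random subsets are
#' drawn, re-superimposed, and compared with the parent: shape variation
#' captured is the correlation between the vectorized inter-specimen
#' Procrustes distance matrices (subset vs parent), size variation the
#' correlation between centroid sizes.  Curves plateauing before the full
#' landmark count indicate adequate sampling; the plateau is the first
#' count whose mean reaches 95% of the value at the full count.
#'
#' @param arr k x 3 x n array of raw coordinates (or list of complete
#'   [landmark_config]).
#' @param counts Landmark counts to evaluate (each >= 3).
#' @param replicates Random subsets per count.
#' @param seed Integer seed.
#' @return Object of class `rarefaction_curve`: `curve` (data.frame:
#'   count, shape_mean, shape_sd, size_mean, size_sd, replicates),
#'   `plateau_shape`, `plateau_size`.
#' @export
landmark_rarefaction <- function(arr, counts = NULL, replicates = 10L,
                                 seed = 1L) {
  if (is.list(arr)) arr <- as_landmark_array(arr)
  k <- dim(arr)[1L]
  if (is.null(counts)) counts <- unique(round(seq(5L, k, length.out = 8L)))
  if (any(counts < 3L)) stop("landmark counts below 3 are not superimposable")
  if (any(counts > k)) stop("counts exceed the available landmarks")
  parent <- gpa(arr)
  d_parent <- as.vector(dist(flatten_coords(parent)))
  cs_parent <- parent$centroid_size
  set.seed(seed)
  rows <- lapply(sort(counts), function(cnt) {
    reps <- vapply(seq_len(replicates), function(r) {
      keep <- if (cnt == k) seq_len(k) else sort(sample.int(k, cnt))
      sub <- gpa(arr[keep, , , drop = FALSE])
      c(shape = cor(as.vector(dist(flatten_coords(sub))), d_parent),
        size = cor(sub$centroid_size, cs_parent))
    }, numeric(2L))
    data.frame(count = cnt,
               shape_mean = mean(reps["shape", ]), shape_sd = sd(reps["shape", ]),
               size_mean = mean(reps["size", ]), size_sd = sd(reps["size", ]),
               replicates = replicates)
  })
  curve <- do.call(rbind, rows)
  plateau <- function(v) {
    target <- 0.95 * v[length(v)]
    curve$count[which(v >= target)[1L]]
  }
  structure(list(curve = curve,
                 plateau_shape = plateau(curve$shape_mean),
                 plateau_size = plateau(curve$size_mean)),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("<rarefaction_curve> shape plateau at %d landmarks, size at %d\n",
              x$plateau_shape, x$plateau_size))
  print(round(x$curve, 3L), row.names = FALSE)
  invisible(x)
}

#' Test for shape differences between scan types
#'
#' Restricts the data to specimens of species scanned with both scanner
#' types (so species identity cannot confound the contrast), superimposes
#' them, and fits an ordinary least squares permutation ANOVA of shape on
#' scan type.
#'
#' @param configs List of [landmark_config].
#' @param n_perm,seed Passed to [rrpp_lm()].
#' @return An `rrpp_fit`; the restricted specimen count is attached as
#'   attribute `"n_restricted"`.
#' @export
scan_type_test <- function(configs, n_perm = 999L, seed = NULL) {
  sp <- config_species(configs)
  st <- vapply(configs, `[[`, "", "scan_type")
  both <- names(Filter(function(v) length(v) > 1L, tapply(st, sp, unique)))
  keep <- sp %in% both
  if (!any(keep)) stop("no species was scanned with both scan types")
  sub <- configs[keep]
  fit_g <- gpa(sub)
  Y <- flatten_coords(fit_g)
  df <- data.frame(scan_type = factor(vapply(sub, `[[`, "", "scan_type")))
  out <- rrpp_lm(Y ~ scan_type, data = df, n_perm = n_perm, seed = seed)
  attr(out, "n_restricted") <- length(sub)
  out
}

#' Restrict species to tribes with more than a minimum size
#'
#' Tribe-level stages use only tribes with more than `min_species`
#' species.
#'
#' @param species_table data.frame with `species` and `tribe`.
#' @param min_species Minimum tribe size (strictly greater; default 3).
#' @return Filtered species table.
#' @export
tribe_subset <- function(species_table, min_species = 3L) {
  tab <- table(species_table$tribe)
  keep <- names(tab[tab > min_species])
  out <- species_table[species_table$tribe %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes, on either a simulated dataset or files read from disk:
#' one-per-species subsetting, GPA, PCA, distance-from-mean, the main
#' comparative fits (shape ~ tribe, shape ~ size, shape ~ tribe *
#' distance; phylogenetic signal), disparity and rates by subfamily, and
#' the modularity table over the named anatomical schemes.  Outputs are
#' written as CSV/JSON/Newick under `out_dir`.  All randomness derives
#' from `seed`, so reruns are byte-identical.
#'
#' @param config List with elements: `seed` (required); either `sim_spec`
#'   (a [simulation_spec]) or `landmark_file`/`tree_file`/`species_file`;
#'   optional `n_perm` (default 199), `out_dir` (default `tempdir()`),
#'   `stages` (subset of `c("gpa", "pca", "comparative", "modularity")`,
#'   default all).
#' @return Invisibly, a list with the computed objects and the summary
#'   (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("run_pipeline: config$seed is mandatory")
  seed <- as.integer(config$seed)
  n_perm <- if (is.null(config$n_perm)) 199L else as.integer(config$n_perm)
  out_dir <- if (is.null(config$out_dir)) tempdir() else config$out_dir
  stages <- if (is.null(config$stages)) c("gpa", "pca", "comparative", "modularity")
            else config$stages
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$sim_spec)) {
    sim <- simulate_landmark_dataset(config$sim_spec)
    configs <- sim$configs; tree <- sim$tree; sptab <- sim$species_table
  } else {
    configs <- read_landmarks(config$landmark_file)
    tree <- read_tree(config$tree_file)
    sptab <- read_species_table(config$species_file)
  }
  configs <- estimate_missing_all(configs)
  report <- validate_dataset(configs, sptab, tree)
  validation_report_json(report, file.path(out_dir, "validation.json"))

  sub <- phylogenetic_subset(configs, seed = seed)
  tree_sub <- prune_and_match(tree, names(sub))
  out <- list(validation = report)
  summary <- list(seed = seed, n_perm = n_perm,
                  n_specimens = length(configs), n_species = length(sub))

  if ("gpa" %in% stages) {
    fit_g <- gpa(sub)
    Y <- flatten_coords(fit_g)
    rownames(Y) <- names(sub)
    out$gpa <- fit_g
    write.csv(data.frame(species = names(sub),
                         centroid_size = fit_g$centroid_size,
                         log_centroid_size = fit_g$log_centroid_size),
              file.path(out_dir, "centroid_size.csv"), row.names = FALSE)
    write.csv(cbind(species = rownames(Y), as.data.frame(round(Y, 8L))),
              file.path(out_dir, "aligned_coords.csv"), row.names = FALSE)
    ape::write.tree(tree_sub, file.path(out_dir, "tree_subset.nwk"))
  } else return(invisible(out))

  if ("pca" %in% stages) {
    pc <- shape_pca(Y)
    out$pca <- pc
    write.csv(data.frame(species = rownames(pc$scores),
                         round(pc$scores[, seq_len(min(10L, ncol(pc$scores)))], 8L)),
              file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    summary$pc_variance_pct <- round(100 * pc$variance_fraction[1:3], 2L)
  }

  if ("comparative" %in% stages) {
    dfm <- distance_from_mean(Y)
    dat <- data.frame(sptab[match(rownames(Y), sptab$species), ],
                      distance = dfm$distance[match(rownames(Y), dfm$species)],
                      size = out$gpa$log_centroid_size,
                      row.names = rownames(Y))
    tdat <- tribe_subset(dat)
    fits <- list()
    fits[["shape~tribe"]] <- rrpp_lm(Y[tdat$species, ] ~ tribe, data = tdat,
                                     n_perm = n_perm, seed = seed + 101L)
    fits[["shape~size"]] <- rrpp_lm(Y ~ size, data = dat, tree = tree_sub,
                                    n_perm = n_perm, seed = seed + 102L)
    fits[["shape~tribe*distance"]] <- rrpp_lm(
      Y[tdat$species, ] ~ tribe * distance, data = tdat,
      n_perm = n_perm, seed = seed + 103L)
    tab1 <- do.call(rbind, lapply(names(fits), function(nm) {
      tt <- anova_table(fits[[nm]]); tt$model <- nm; tt
    }))
    write.csv(tab1, file.path(out_dir, "anova_table.csv"), row.names = FALSE)
    out$fits <- fits
    sig <- physignal_K(Y, tree_sub, n_perm = n_perm, seed = seed + 104L)
    out$signal <- sig
    summary$K_shape <- sig$K
    disp <- disparity_test(Y, dat$subfamily, n_perm = n_perm, seed = seed + 105L)
    rate <- evol_rate_test(Y, tree_sub, setNames(dat$subfamily, rownames(Y)),
                           n_sim = n_perm, seed = seed + 106L)
    out$disparity <- disp; out$rates <- rate
    summary$disparity_P <- disp$pairwise$P[1L]
    summary$rate_ratio <- rate$ratio
  }

  if ("modularity" %in% stages) {
    sym <- symmetric_subset(out$gpa)
    Ysym <- flatten_coords(sym)
    rownames(Ysym) <- names(sub)
    schemes <- module_schemes()
    tab2 <- do.call(rbind, lapply(names(schemes), function(nm) {
      cr <- covariance_ratio(Ysym, schemes[[nm]], n_perm = n_perm,
                             seed = seed + 200L, phylogenetic = TRUE,
                             tree = tree_sub)
      data.frame(Scheme = nm, n_modules = length(unique(schemes[[nm]])),
                 CR = cr$CR, Z = cr$Z, P = cr$P, stringsAsFactors = FALSE)
    }))
    tab2 <- tab2[order(tab2$Z), ]
    write.csv(tab2, file.path(out_dir, "modularity_table.csv"), row.names = FALSE)
    out$modularity <- tab2
    summary$best_scheme <- tab2$Scheme[1L]
  }

  js <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10L, pretty = TRUE)
  writeLines(js, file.path(out_dir, "summary.json"))
  out$summary <- summary
  invisible(out)
}
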