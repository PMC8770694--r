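# Landmark, tree and trait-table I/O with cross-validation.

#' Construct a landmark configuration
#'
#' A `landmark_config` holds one specimen's named 3D landmarks in scanner
#' units (mm), together with a missing-landmark mask and specimen metadata.
#' Rows flagged missing are stored as `NA` coordinates.
#'
#' @param specimen_id Specimen identifier (unique within a dataset).
#' @param species Species name the specimen belongs to.
#' @param coords Numeric matrix, k landmarks x 3 (x, y, z).
#' @param landmark_labels Character vector of length k; unique. Defaults to
#'   `L1..Lk`.
#' @param missing Logical vector of length k marking missing landmarks.
#'   Defaults to rows of `coords` containing any non-finite value.
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param scan_type One of `"surface"`, `"ct"` (surface scanner vs CT).
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, species, coords,
                            landmark_labels = NULL, missing = NULL,
                            sex = "unknown", scan_type = "surface") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  k <- nrow(coords)
  if (k < 3L) stop("a landmark configuration needs at least 3 landmarks")
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (is.null(landmark_labels)) landmark_labels <- paste0("L", seq_len(k))
  if (length(landmark_labels) != k) stop("landmark_labels length must equal nrow(coords)")
  if (anyDuplicated(landmark_labels)) stop("landmark_labels must be unique")
  if (is.null(missing)) missing <- !apply(is.finite(coords), 1L, all)
  missing <- as.logical(missing)
  if (length(missing) != k) stop("missing mask length must equal nrow(coords)")
  coords[missing, ] <- NA_real_
  sex <- match.arg(sex, c("male", "female", "unknown"))
  scan_type <- match.arg(scan_type, c("surface", "ct"))
  rownames(coords) <- landmark_labels
  colnames(coords) <- c("x", "y", "z")
  structure(list(specimen_id = as.character(specimen_id),
                 species = as.character(species),
                 coords = coords,
                 landmark_labels = as.character(landmark_labels),
                 missing = missing,
                 sex = sex, scan_type = scan_type),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s (%s): %d landmarks, %d missing, sex=%s, scan=%s\n",
              x$specimen_id, x$species, nrow(x$coords), sum(x$missing),
              x$sex, x$scan_type))
  invisible(x)
}

#' Read landmark configurations from a TPS or long-format CSV file
#'
#' The CSV dialect is long format with columns `specimen`, `landmark`,
#' `x`, `y`, `z` and optional `species`, `sex`, `scan_type`.  Blank (empty
#' or NA) coordinate cells mark missing landmarks.  The TPS dialect follows
#' the conventional `LM3=`/`ID=` block structure, with the `-9999 -9999
#' -9999` triple coding a missing landmark; an optional `SPECIES=` comment
#' line per block is honoured.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tps"`; guessed from the file extension when
#'   omitted.
#' @return A list of [landmark_config] objects, one per specimen, in file
#'   order.  All specimens must share the same landmark count.
#' @export
read_landmarks <- function(path, dialect = c("auto", "csv", "tps")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  configs <- if (dialect == "csv") read_landmarks_csv(path) else read_landmarks_tps(path)
  ids <- vapply(configs, `[[`, "", "specimen_id")
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ks <- vapply(configs, function(cf) nrow(cf$coords), 0L)
  if (length(unique(ks)) > 1L)
    stop("inconsistent landmark counts across specimens: ",
         paste(unique(ks), collapse = ", "))
  configs
}

read_landmarks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "landmark", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark csv lacks required columns: ", paste(miss, collapse = ", "))
  sp_ids <- unique(df$specimen)
  lapply(sp_ids, function(id) {
    d <- df[df$specimen == id, , drop = FALSE]
    if (anyDuplicated(d$landmark))
      stop("specimen ", id, " has duplicated landmark rows")
    xyz <- as.matrix(d[, c("x", "y", "z")])
    storage.mode(xyz) <- "double"
    landmark_config(
      specimen_id = id,
      species = if ("species" %in% names(d)) d$species[1L] else id,
      coords = xyz,
      landmark_labels = as.character(d$landmark),
      sex = if ("sex" %in% names(d)) d$sex[1L] else "unknown",
      scan_type = if ("scan_type" %in% names(d)) d$scan_type[1L] else "surface")
  })
}

read_landmarks_tps <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  starts <- grep("^LM3?=", lines)
  if (!length(starts)) stop("no LM=/LM3= blocks found in TPS file: ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    k <- as.integer(sub("^LM3?=", "", block[1L]))
    if (is.na(k) || k < 1L) stop("malformed LM3= line in TPS block ", b)
    coord_lines <- block[2L:(1L + k)]
    vals <- lapply(strsplit(coord_lines, "[[:space:]]+"), as.numeric)
    if (any(vapply(vals, length, 0L) != 3L))
      stop("TPS block ", b, ": expected 3 coordinates per landmark line")
    xyz <- do.call(rbind, vals)
    missing <- apply(xyz == -9999, 1L, all)
    xyz[missing, ] <- NA_real_
    rest <- block[-(1L:(1L + k))]
    get_field <- function(key) {
      ln <- grep(paste0("^", key, "="), rest, value = TRUE)
      if (length(ln)) sub(paste0("^", key, "="), "", ln[1L]) else NA_character_
    }
    id <- get_field("ID")
    if (is.na(id)) id <- paste0("specimen_", b)
    sp <- get_field("SPECIES")
    configs[[b]] <- landmark_config(
      specimen_id = id,
      species = if (is.na(sp)) id else sp,
      coords = xyz, missing = missing)
  }
  configs
}

#' Write landmark configurations to TPS or CSV
#'
#' Inverse of [read_landmarks()]: a write followed by a read reproduces
#' coordinates to 6 decimals and missing masks exactly.
#'
#' @param configs List of [landmark_config] objects.
#' @param path Output path.
#' @param dialect `"csv"` or `"tps"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(configs, path, dialect = c("csv", "tps")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    rows <- lapply(configs, function(cf) {
      data.frame(specimen = cf$specimen_id, species = cf$species,
                 landmark = cf$landmark_labels,
                 x = round(cf$coords[, 1L], 6L),
                 y = round(cf$coords[, 2L], 6L),
                 z = round(cf$coords[, 3L], 6L),
                 sex = cf$sex, scan_type = cf$scan_type,
                 stringsAsFactors = FALSE)
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (cf in configs) {
      xyz <- round(cf$coords, 6L)
      xyz[cf$missing, ] <- -9999
      writeLines(c(sprintf("LM3=%d", nrow(xyz)),
                   apply(xyz, 1L, paste, collapse = " "),
                   sprintf("ID=%s", cf$specimen_id),
                   sprintf("SPECIES=%s", cf$species)), con)
    }
  }
  invisible(path)
}

#' Read a species trait table
#'
#' Expects columns `species`, `tribe`, `subfamily` and optionally `diet`
#' (browser/grazer/mixed/frugivore), `hypsodonty` (lower m3 crown height /
#' crown width, unitless, >= 0; typically available for a subset of species
#' only) and `body_mass` (kg).
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_species_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_species_table(df)
}

validate_species_table <- function(df) {
  if (!"species" %in% names(df)) stop("species table needs a 'species' column")
  if (anyDuplicated(df$species))
    stop("species table has duplicated species: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  if ("diet" %in% names(df)) {
    bad <- setdiff(unique(df$diet[!is.na(df$diet)]),
                   c("browser", "grazer", "mixed", "frugivore"))
    if (length(bad)) stop("unknown diet categories: ", paste(bad, collapse = ", "))
  }
  if ("hypsodonty" %in% names(df) &&
      any(df$hypsodonty < 0, na.rm = TRUE)) stop("hypsodonty must be >= 0")
  df
}

#' Read a dated phylogeny from Newick
#'
#' @param path Newick file path.
#' @return An `ape` `phylo` object with branch lengths (Myr).  Trees
#'   without branch lengths are rejected; ultrametricity is not required
#'   here (operations that need it check it themselves).
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  check_branch_lengths(tree)
  tree
}

check_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("tree branch lengths must all be finite and >= 0")
  invisible(tree)
}

#' Prune a tree to a set of species
#'
#' Drops all other tips, summing branch lengths through removed degree-2
#' nodes so that patristic distances among retained tips are preserved.
#'
#' @param tree A `phylo` object.
#' @param species Character vector of tip labels to keep.
#' @return The pruned `phylo`.
#' @export
prune_and_match <- function(tree, species) {
  species <- as.character(species)
  absent <- setdiff(species, tree$tip.label)
  if (length(absent))
    stop("species absent from tree: ", paste(absent, collapse = ", "))
  if (length(species) == length(tree$tip.label)) {
    # identity prune; keep.tip would still reorder internally
    if (setequal(species, tree$tip.label)) return(tree)
  }
  ape::keep.tip(tree, species)
}

#' Cross-validate landmark data, species table, and tree
#'
#' Report-only consistency check: species present in one input but absent
#' from another, species represented by more than one specimen (candidates
#' for random one-per-species subsetting), and counts by sex and scan type.
#'
#' @param configs List of [landmark_config].
#' @param species_table Optional data.frame with a `species` column.
#' @param tree Optional `phylo`.
#' @return An object of class `validation_report`:
#'   `issues` (character), `multi_specimen` (named integer: extra specimens
#'   beyond the first, per species with > 1), `n_specimens`, `n_species`,
#'   `counts_sex`, `counts_scan_type`.
#' @export
validate_dataset <- function(configs, species_table = NULL, tree = NULL) {
  sp <- vapply(configs, `[[`, "", "species")
  issues <- character()
  if (!is.null(species_table)) {
    orphan <- setdiff(unique(sp), species_table$species)
    extra <- setdiff(species_table$species, unique(sp))
    if (length(orphan))
      issues <- c(issues, paste0("specimen species absent from species table: ",
                                 paste(orphan, collapse = ", ")))
    if (length(extra))
      issues <- c(issues, paste0("species-table species with no specimens: ",
                                 paste(extra, collapse = ", ")))
  }
  if (!is.null(tree)) {
    no_tip <- setdiff(unique(sp), tree$tip.label)
    if (length(no_tip))
      issues <- c(issues, paste0("specimen species absent from tree: ",
                                 paste(no_tip, collapse = ", ")))
  }
  tab <- table(sp)
  multi <- tab[tab > 1L] - 1L
  structure(list(
    issues = issues,
    multi_specimen = setNames(as.integer(multi), names(multi)),
    n_specimens = length(configs),
    n_species = length(tab),
    counts_sex = table(vapply(configs, `[[`, "", "sex")),
    counts_scan_type = table(vapply(configs, `[[`, "", "scan_type"))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d specimens / %d species; %d issue(s); %d extra specimens in %d multi-specimen species\n",
              x$n_specimens, x$n_species, length(x$issues),
              sum(x$multi_specimen), length(x$multi_specimen)))
  if (length(x$issues)) cat(paste0(" - ", x$issues, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
validation_report_json <- function(report, path = NULL) {
  obj <- list(issues = report$issues,
              multi_specimen = as.list(report$multi_specimen),
              n_specimens = report$n_specimens,
              n_species = report$n_species,
              counts_sex = as.list(report$counts_sex),
              counts_scan_type = as.list(report$counts_scan_type))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# --- shared small helpers -------------------------------------------------

#' Stack a list of configurations into a k x 3 x n array
#'
#' @param configs List of [landmark_config] with a common landmark count.
#' @return A `k x 3 x n` array with dimnames from landmark labels and
#'   specimen ids.
#' @export
as_landmark_array <- function(configs) {
  ks <- vapply(configs, function(cf) nrow(cf$coords), 0L)
  if (length(unique(ks)) != 1L) stop("landmark counts differ across configurations")
  k <- ks[1L]
  a <- array(NA_real_, c(k, 3L, length(configs)),
             dimnames = list(configs[[1L]]$landmark_labels, c("x", "y", "z"),
                             vapply(configs, `[[`, "", "specimen_id")))
  for (i in seq_along(configs)) a[, , i] <- configs[[i]]$coords
  a
}

config_species <- function(configs) vapply(configs, `[[`, "", "species")
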