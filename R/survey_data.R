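#' @title Observation tables: data model, validation and file I/O
#' @name survey_data
#' @description
#' An observation table holds one row per object in a survey campaign: a
#' verified detection of a target animal, a duplicate detection of an animal
#' already seen in the same survey, an object the detector falsely labelled
#' as the target species, or an animal known (from ground truthing) to have
#' been present but missed. Each row carries the covariates used by the
#' detection-probability models: ambient temperature (degrees C), wind speed
#' (km/h), distance to habitat edge (m, larger = nearer the forest core),
#' distance to the nearest other detection (m), time since the previous
#' detection (s), and perpendicular distance from the transect line (m, used
#' for distance binning).
NULL

# The four observation fates.
KLASS_LEVELS <- c("unique_detection", "duplicate", "false_positive", "missed")

# Columns that must be present (post schema mapping). lon/lat are optional.
OBS_REQUIRED <- c("object_id", "site", "date", "klass", "temperature",
                  "wind_speed", "dist_edge", "dist_nearest",
                  "time_since_prev", "perp_distance")

#' Column-name schema for observation files
#'
#' Maps the canonical column names used internally to the column names found
#' in a delimited file. Any canonical name not mentioned is assumed to match
#' the file verbatim.
#'
#' @param ... named character entries, e.g. `klass = "Class"`.
#' @param case_fold logical; if `TRUE` (default) the klass values are
#'   lower-cased and spaces/hyphens normalised to underscores before
#'   validation, so "Duplicate" and "false-positive" are accepted.
#' @return an object of class `obs_schema`.
#' @export
obs_schema <- function(..., case_fold = TRUE) {
  map <- list(...)
  if (length(map) && (is.null(names(map)) || any(names(map) == "")))
    stop("obs_schema() entries must be named")
  structure(list(map = map, case_fold = case_fold), class = "obs_schema")
}

normalize_klass <- function(x, case_fold = TRUE) {
  if (case_fold) x <- gsub("[ -]", "_", tolower(trimws(x)))
  x
}

#' Construct and validate an observation table
#'
#' Validates a data frame of per-object observation records and attaches the
#' `obs_table` class. `survey_id` is derived as `site_date` when absent.
#'
#' @param df data frame with the canonical columns (see [survey_data]).
#' @param provenance character source descriptor.
#' @param strip_halfwidth strip half-width in metres; perpendicular distances
#'   must lie in `[0, strip_halfwidth)`.
#' @return a validated `obs_table` (a data frame).
#' @export
observation_table <- function(df, provenance = "constructed",
                              strip_halfwidth = 75) {
  missing_cols <- setdiff(OBS_REQUIRED, names(df))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$klass <- normalize_klass(as.character(df$klass))
  bad <- which(!df$klass %in% KLASS_LEVELS)
  if (length(bad))
    stop(sprintf("invalid klass value %s at row(s) %s (line %s of file)",
                 paste(unique(df$klass[bad]), collapse = ", "),
                 paste(bad, collapse = ", "),
                 paste(bad + 1L, collapse = ", ")))
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable date (expected ISO-8601)")
  if (is.null(df$survey_id)) df$survey_id <- paste(df$site, df$date, sep = "_")
  if (anyDuplicated(df$object_id))
    stop("object_id values are not unique")
  sv <- unique(df[, c("survey_id", "site", "date")])
  if (anyDuplicated(sv$survey_id))
    stop("a survey_id maps to more than one (site, date)")
  for (col in c("temperature", "wind_speed", "dist_edge", "perp_distance")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      stop(sprintf("validation error: negative %s at row(s) %s", col,
                   paste(bad, collapse = ", ")))
  }
  bad <- which(!is.na(df$perp_distance) & df$perp_distance >= strip_halfwidth)
  if (length(bad))
    stop(sprintf("perp_distance >= strip half-width (%g m) at row(s) %s",
                 strip_halfwidth, paste(bad, collapse = ", ")))
  not_missed <- df$klass != "missed"
  for (col in c("dist_nearest", "time_since_prev")) {
    bad <- which(not_missed & is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("validation error: %s absent for detected object at row(s) %s",
                   col, paste(bad, collapse = ", ")))
  }
  attr(df, "provenance") <- provenance
  attr(df, "strip_halfwidth") <- strip_halfwidth
  class(df) <- unique(c("obs_table", class(df)))
  df
}

#' Composition of an observation table by fate
#'
#' Counts rows per fate (unique detection, duplicate, false positive,
#' missed). Reported for inspection; no fixed totals are enforced.
#'
#' @param table an `obs_table`.
#' @return named integer vector over the four fates plus `total`.
#' @export
klass_composition <- function(table) {
  n <- vapply(KLASS_LEVELS, function(k) sum(table$klass == k), integer(1))
  c(n, total = nrow(table))
}

#' Read an observation table from delimited text
#'
#' @param path CSV file with a header row.
#' @param schema an [obs_schema()] mapping canonical column names to file
#'   column names.
#' @param ... passed to [observation_table()].
#' @return a validated `obs_table`; row order preserved.
#' @export
read_observations <- function(path, schema = obs_schema(), ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (canon in names(schema$map)) {
    filecol <- schema$map[[canon]]
    if (!filecol %in% names(raw))
      stop("schema error: mapped column not in file: ", filecol)
    names(raw)[names(raw) == filecol] <- canon
  }
  if (!schema$case_fold && "klass" %in% names(raw)) {
    bad <- which(!raw$klass %in% KLASS_LEVELS)
    if (length(bad))
      stop(sprintf("invalid klass value at line(s) %s",
                   paste(bad + 1L, collapse = ", ")))
  }
  for (opt in c("lon", "lat"))
    if (!opt %in% names(raw)) raw[[opt]] <- rep(NA_real_, nrow(raw))
  observation_table(raw, provenance = path, ...)
}

#' Write an observation table to CSV
#'
#' Inverse of [read_observations()]: `read_observations(write_observations(t))`
#' recovers `t`. Dates are written ISO-8601; output is byte-stable for a
#' given table.
#'
#' @param table an `obs_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path) {
  df <- as.data.frame(table)
  df$date <- format(as.Date(df$date), "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split an observation table by survey date
#'
#' Partitions a table into training and testing tables with membership
#' determined solely by the survey date, emulating a temporal hold-out in
#' which the latest survey dates form the test set.
#'
#' @param table an `obs_table`.
#' @param test_dates dates (coercible via `as.Date`) whose surveys form the
#'   test set; must all be present in the table.
#' @return list with elements `train`, `test` (both `obs_table`) and
#'   `cutoff_dates`.
#' @export
split_by_date <- function(table, test_dates) {
  test_dates <- as.Date(test_dates)
  have <- unique(as.Date(table$date))
  unknown <- setdiff(as.character(test_dates), as.character(have))
  if (length(unknown))
    stop("test_dates not present in table: ", paste(unknown, collapse = ", "))
  in_test <- as.Date(table$date) %in% test_dates
  split_tab <- function(keep) {
    out <- table[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(train = split_tab(!in_test), test = split_tab(in_test),
       cutoff_dates = sort(test_dates))
}

#' Bin perpendicular distances into distance classes
#'
#' Tallies kept observations into half-open distance bins `[lo, hi)`, with
#' the final bin closed at the strip half-width, per survey. A perpendicular
#' distance of exactly 15 m with edges (0,15,30,...) falls in the second bin.
#'
#' @param table an `obs_table`.
#' @param bin_edges increasing numeric vector of bin edges starting at 0
#'   (default `c(0, 15, 30, 45, 60, 75)`).
#' @param keep character vector of fates to count (default the real-animal
#'   detections: unique detections and duplicates).
#' @return integer matrix, one row per survey_id, one column per bin, with
#'   `bin_edges` attached as an attribute.
#' @export
bin_counts <- function(table, bin_edges = c(0, 15, 30, 45, 60, 75),
                       keep = c("unique_detection", "duplicate")) {
  stopifnot(length(bin_edges) >= 2, bin_edges[1] == 0,
            all(diff(bin_edges) > 0))
  kept <- table[table$klass %in% keep, , drop = FALSE]
  if (anyNA(kept$perp_distance))
    stop("perp_distance missing on kept rows")
  over <- which(kept$perp_distance >= max(bin_edges))
  if (length(over))
    stop("perp_distance >= max bin edge for object(s): ",
         paste(kept$object_id[over], collapse = ", "))
  surveys <- unique(table$survey_id)
  nb <- length(bin_edges) - 1L
  out <- matrix(0L, nrow = length(surveys), ncol = nb,
                dimnames = list(surveys, paste0("bin", seq_len(nb))))
  if (nrow(kept)) {
    # half-open [lo, hi); right = FALSE; last bin effectively closed at the
    # top because distances >= max edge were rejected above
    idx <- findInterval(kept$perp_distance, bin_edges,
                        rightmost.closed = FALSE, left.open = FALSE)
    tab <- table(factor(kept$survey_id, levels = surveys),
                 factor(idx, levels = seq_len(nb)))
    out[] <- as.integer(tab)
  }
  attr(out, "bin_edges") <- bin_edges
  out
}

#' Construct a distance-binned transect count array
#'
#' Holds counts `y[transect, visit, bin]` for repeated strip-transect visits,
#' with per-transect land-cover covariates (percent forest/grass/road/water)
#' and per-visit weather covariates (temperature, wind speed).
#'
#' @param counts integer array `[transects, visits, bins]`, non-negative.
#' @param bin_edges increasing numeric bin edges starting at 0.
#' @param transect_covs data frame, one row per transect; percentage columns
#'   must lie in \[0, 100\].
#' @param visit_covs data frame, one row per visit (columns `temperature`,
#'   `wind_speed`).
#' @param site site label.
#' @return object of class `transect_counts`.
#' @export
transect_counts <- function(counts, bin_edges = c(0, 15, 30, 45, 60, 75),
                            transect_covs = NULL, visit_covs = NULL,
                            site = "site") {
  counts <- array(as.integer(counts), dim = dim(counts) %||%
                    c(length(counts), 1L, 1L))
  if (length(dim(counts)) != 3)
    stop("counts must be a transects x visits x bins array")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (dim(counts)[3] != length(bin_edges) - 1L)
    stop("third dimension must match number of distance bins")
  stopifnot(bin_edges[1] == 0, all(diff(bin_edges) > 0))
  if (!is.null(transect_covs)) {
    stopifnot(nrow(transect_covs) == dim(counts)[1])
    pct <- intersect(c("forest", "grass", "road", "water"),
                     names(transect_covs))
    for (col in pct)
      if (any(transect_covs[[col]] < 0 | transect_covs[[col]] > 100))
        stop("cover percentage outside [0, 100]: ", col)
  }
  if (!is.null(visit_covs)) stopifnot(nrow(visit_covs) == dim(counts)[2])
  structure(list(counts = counts, bin_edges = bin_edges,
                 transect_covs = transect_covs, visit_covs = visit_covs,
                 site = site),
            class = "transect_counts")
}

#' @export
print.transect_counts <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("transect_counts: %d transects x %d visits x %d bins (site %s)\n",
              d[1], d[2], d[3], x$site))
  cat("total count:", sum(x$counts), "\n")
  invisible(x)
}

#' Write a transect count array to CSV
#'
#' One row per transect x visit with columns `transect`, `visit`,
#' `bin1..binB`, the transect covariates, and the visit covariates.
#'
#' @param x a `transect_counts` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transect_counts <- function(x, path) {
  d <- dim(x$counts)
  rows <- expand.grid(visit = seq_len(d[2]), transect = seq_len(d[1]))
  rows <- rows[, c("transect", "visit")]
  bins <- t(apply(rows, 1, function(r) x$counts[r[1], r[2], ]))
  colnames(bins) <- paste0("bin", seq_len(d[3]))
  df <- cbind(rows, bins)
  if (!is.null(x$transect_covs))
    df <- cbind(df, x$transect_covs[rows$transect, , drop = FALSE])
  if (!is.null(x$visit_covs)) {
    vc <- x$visit_covs[rows$visit, , drop = FALSE]
    names(vc) <- paste0("visit_", names(vc))
    df <- cbind(df, vc)
  }
  df$site <- x$site
  df$edges <- paste(x$bin_edges, collapse = ";")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transect count array from CSV
#'
#' @param path file written by [write_transect_counts()].
#' @return a `transect_counts` object.
#' @export
read_transect_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bin_edges <- as.numeric(strsplit(df$edges[1], ";")[[1]])
  nb <- length(bin_edges) - 1L
  tr <- sort(unique(df$transect))
  vi <- sort(unique(df$visit))
  counts <- array(0L, dim = c(length(tr), length(vi), nb))
  for (i in seq_len(nrow(df)))
    counts[match(df$transect[i], tr), match(df$visit[i], vi), ] <-
      as.integer(df[i, paste0("bin", seq_len(nb))])
  tcols <- intersect(c("forest", "grass", "road", "water"), names(df))
  transect_covs <- if (length(tcols))
    df[match(tr, df$transect), tcols, drop = FALSE] else NULL
  if (!is.null(transect_covs)) rownames(transect_covs) <- NULL
  vcols <- grep("^visit_", names(df), value = TRUE)
  visit_covs <- if (length(vcols)) {
    vc <- df[match(vi, df$visit), vcols, drop = FALSE]
    names(vc) <- sub("^visit_", "", names(vc))
    rownames(vc) <- NULL
    vc
  } else NULL
  transect_counts(counts, bin_edges, transect_covs, visit_covs,
                  site = df$site[1])
}
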