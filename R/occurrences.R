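#' Occurrence sets
#'
#' An occurrence set couples a table of per-species point records with an
#' append-only log of the filters that produced it, so every downstream count
#' can be traced back to the raw input.
#'
#' @param records Data frame with columns `species`, `lon`, `lat`.
#' @param log List of filter-log entries (each a named list).
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(records, log = list()) {
  stopifnot(all(c("species", "lon", "lat") %in% names(records)))
  stopifnot(all(nzchar(records$species)),
            all(records$lat >= -90 & records$lat <= 90),
            all(records$lon >= -180 & records$lon < 180))
  rownames(records) <- NULL
  structure(list(records = records, log = log), class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d records, %d species, %d filter step(s)\n",
              nrow(x$records), length(unique(x$records$species)),
              length(x$log)))
  invisible(x)
}

log_step <- function(set, step, ...) {
  set$log[[length(set$log) + 1L]] <- c(list(step = step), list(...))
  set
}

#' Species record counts
#' @param set An `occurrence_set`.
#' @return Named integer vector of record counts per species.
#' @export
species_counts <- function(set) {
  tab <- table(set$records$species)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read occurrence records from delimited text
#'
#' Expects a header naming species, longitude and latitude columns (matched
#' case-insensitively against `species`/`lon`/`longitude`/`lat`/`latitude`).
#' Longitudes are normalized into `[-180, 180)`; rows with unparseable or
#' out-of-bounds coordinates or empty species ids are rejected and counted in
#' the filter log, never silently dropped.
#'
#' @param path CSV (or other single-character-delimited) file.
#' @param sep Field separator.
#' @return An `occurrence_set` whose log records the rejection count.
#' @export
read_occurrences <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) == 0) stop("empty occurrence file: ", path)
  nm <- tolower(names(raw))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("missing required column (", what, ") in ", path)
    i
  }
  sp <- as.character(raw[[pick(c("species", "species_id", "taxon"), "species")]])
  lon <- suppressWarnings(as.numeric(raw[[pick(c("lon", "longitude", "long", "x"),
                                               "longitude")]]))
  lat <- suppressWarnings(as.numeric(raw[[pick(c("lat", "latitude", "y"),
                                               "latitude")]]))
  lon <- ((lon + 180) %% 360) - 180  # wrap into [-180, 180)
  ok <- !is.na(lon) & !is.na(lat) & nzchar(sp) & !is.na(sp) &
    lat >= -90 & lat <= 90
  rec <- data.frame(species = sp[ok], lon = lon[ok], lat = lat[ok],
                    stringsAsFactors = FALSE)
  set <- occurrence_set(rec)
  log_step(set, "read", path = path, n_read = nrow(raw),
           n_kept = nrow(rec), n_rejected = sum(!ok))
}

#' Write an occurrence set to CSV (plus a JSON filter log)
#' @param set An `occurrence_set`.
#' @param path Output CSV path; the log goes to `<path>.log.json`.
#' @export
write_occurrences <- function(set, path) {
  utils::write.csv(set$records, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(set$log, paste0(path, ".log.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Exclude species with too few records
#'
#' Species below the record threshold are removed from the modelling set and
#' routed to the data-poor assessment path: their records are returned in
#' `$data_poor` and logged, never discarded. A species with exactly
#' `min_records` records is retained.
#'
#' @param set An `occurrence_set`.
#' @param min_records Minimum number of records to be modelled (default 4).
#' @return An `occurrence_set` (the retained species) with an extra element
#'   `data_poor`: the records of excluded species.
#' @export
filter_min_records <- function(set, min_records = 4) {
  stopifnot(min_records >= 1)
  counts <- species_counts(set)
  poor <- names(counts)[counts < min_records]
  keep <- !(set$records$species %in% poor)
  prior_poor <- set$data_poor
  out <- occurrence_set(set$records[keep, , drop = FALSE], set$log)
  out <- log_step(out, "min_records", min_records = min_records,
                  n_species_excluded = length(poor),
                  excluded = as.list(poor))
  new_poor <- set$records[!keep, , drop = FALSE]
  out$data_poor <- if (is.null(prior_poor)) new_poor else
    rbind(prior_poor, new_poor)
  rownames(out$data_poor) <- NULL
  out
}

#' Collapse records to one per species per grid cell
#'
#' Standard distribution-modelling hygiene: repeated records inside one grid
#' cell carry no extra information and pseudo-replicate the likelihood.
#' Applied after the minimum-record filter so that the record-count rule sees
#' raw records.
#'
#' @param set An `occurrence_set`.
#' @param grid An `nc_grid`.
#' @return An `occurrence_set` with at most one record per species per cell;
#'   records falling off the grid are dropped and logged.
#' @export
dedupe_to_cells <- function(set, grid) {
  rec <- set$records
  cells <- cell_index(grid, rec$lon, rec$lat)
  on_grid <- !is.na(cells)
  key <- paste(rec$species, cells)
  keep <- on_grid & !duplicated(key)
  out <- occurrence_set(rec[keep, , drop = FALSE], set$log)
  out <- log_step(out, "dedupe_to_cells",
                  n_in = nrow(rec), n_out = sum(keep),
                  n_off_grid = sum(!on_grid))
  out$data_poor <- set$data_poor
  out
}

#' Random train/validation split of record indices
#'
#' Training size is `round(train_fraction * n)` (round-half-to-even), then
#' adjusted so that at least one record lands in each part. Sampling is
#' uniform without replacement and reproducible under `seed`.
#'
#' @param n Number of records (>= 2), or a data frame of records.
#' @param train_fraction Fraction used for training, strictly in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`, plus `seed`.
#' @export
split_train_test <- function(n, train_fraction = 0.75, seed = 1) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 2) stop("need at least 2 records to split")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly in (0, 1)")
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)  # both parts nonempty
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train), seed = seed)
}
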