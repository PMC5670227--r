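# Plain-text file interfaces: logger CSVs, climatology JSON, point-score and
# roving CSVs, quadrat-map JSON, and the wide abundance CSV consumed by the
# statistics stage.

#' Read a temperature-logger CSV
#'
#' Expected columns: `timestamp` (ISO 8601, local clock) and
#' `temperature_c`; one file per site/habitat; header required.
#'
#' @param path CSV path.
#' @param site_id,habitat,nominal_interval Metadata for the series.
#' @return A [temperature_series()].
#' @export
read_logger_csv <- function(path, site_id, habitat = "unspecified",
                            nominal_interval = 15) {
  if (!file.exists(path)) stop_input("logger file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temperature_c") %in% names(df))) {
    stop_input(path, " must have columns 'timestamp' and 'temperature_c'")
  }
  # ISO 8601 with either "T" or space between date and time
  stamp <- as.POSIXct(sub("T", " ", df$timestamp, fixed = TRUE), tz = "UTC")
  if (anyNA(stamp)) {
    stop_input(path, ": unparseable timestamp at row ", which(is.na(stamp))[1])
  }
  temperature_series(stamp, df$temperature_c,
                     site_id = site_id, habitat = habitat,
                     nominal_interval = nominal_interval)
}

#' Write a temperature series to CSV
#'
#' @param series A [temperature_series()].
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(series, path) {
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S"),
    temperature_c = sprintf("%.4f", series$temperature_c))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a climatology configuration (JSON)
#'
#' JSON object mapping `site_id` to `{"mmm": <degC>, "source": <text>}`.
#'
#' @param path JSON path.
#' @return Named list of [climatology()] objects.
#' @export
read_climatology_json <- function(path) {
  if (!file.exists(path)) stop_input("climatology file not found: ", path)
  raw <- jsonlite::read_json(path)
  lapply(stats::setNames(names(raw), names(raw)), function(s) {
    climatology(s, raw[[s]]$mmm, raw[[s]]$source %||% "unspecified")
  })
}

#' Write / read point-score CSVs (the image-annotation export format)
#'
#' Columns: `quadrat_id, transect_id, site, time, point_index, category,
#' genus, morphology, health`.
#'
#' @param points Long point-record data frame (e.g. `gen_survey()$points`).
#' @param path CSV path.
#' @return `write_points_csv()`: `path` invisibly; `read_points_csv()`: the
#'   data frame.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) stop_input("points file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("quadrat_id", "transect_id", "site", "time", "point_index",
            "category", "genus", "morphology", "health")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input(path, " is missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(!df$category %in% SUBSTRATE_CATEGORIES)
  if (length(bad)) {
    stop_input(path, " row ", bad[1], ": unknown category '", df$category[bad[1]], "'")
  }
  bad <- which(df$category == "hard_coral" & !df$health %in% HEALTH_LEVELS)
  if (length(bad)) {
    stop_input(path, " row ", bad[1], ": hard_coral point with invalid health '",
               df$health[bad[1]], "'")
  }
  df
}

#' Write / read roving-survey CSVs
#'
#' Columns: `site, location, date, colony_id, genus, diameter_cm, health`.
#'
#' @param records Colony records (e.g. from [gen_roving()]).
#' @param path CSV path.
#' @return `write_roving_csv()`: `path` invisibly; `read_roving_csv()`: the
#'   data frame.
#' @export
write_roving_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_roving_csv
#' @export
read_roving_csv <- function(path) {
  if (!file.exists(path)) stop_input("roving file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!all(c("colony_id", "health") %in% names(df))) {
    stop_input(path, " must have at least columns 'colony_id' and 'health'")
  }
  bad <- which(!df$health %in% HEALTH_LEVELS)
  if (length(bad)) {
    stop_input(path, " row ", bad[1], ": unrecognised health code '",
               df$health[bad[1]], "'")
  }
  df
}

#' Write / read quadrat maps as JSON
#'
#' One JSON array of quadrat objects, each holding `quadrat_id`,
#' `transect_id` and a `regions` record list -- the same format the
#' synthetic generator emits.
#'
#' @param maps List of [quadrat_map()] objects.
#' @param path JSON path.
#' @return `write_quadrat_maps_json()`: `path` invisibly;
#'   `read_quadrat_maps_json()`: list of `quadrat_map`s.
#' @export
write_quadrat_maps_json <- function(maps, path) {
  payload <- lapply(maps, function(m) {
    list(quadrat_id = attr(m, "quadrat_id"),
         transect_id = attr(m, "transect_id"),
         regions = as.data.frame(m))
  })
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_quadrat_maps_json
#' @export
read_quadrat_maps_json <- function(path) {
  if (!file.exists(path)) stop_input("quadrat map file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    regions <- payload$regions[[i]]
    for (col in c("genus", "morphology", "health")) {
      if (!col %in% names(regions)) regions[[col]] <- NA_character_
    }
    quadrat_map(regions, quadrat_id = payload$quadrat_id[i],
                transect_id = payload$transect_id[i])
  })
}

#' Build a transect-level abundance matrix from point records
#'
#' Pools hard-coral points across the quadrats of each transect and converts
#' them to percent abundance per class (`genus_health` or `health`),
#' yielding the transects x classes matrix that feeds the multivariate
#' statistics. Points with `unknown` category or indeterminate health never
#' enter the denominator.
#'
#' @param points Long point records (see [read_points_csv()]), possibly
#'   covering several sites/times.
#' @param grouping `"genus_health"` (default) or `"health"`.
#' @return An [abundance_matrix()] (state `"raw"`) with meta columns `site`,
#'   `time`, `transect_id`.
#' @export
abundance_from_points <- function(points, grouping = c("genus_health", "health")) {
  grouping <- match.arg(grouping)
  hc <- points[points$category == "hard_coral" & !is.na(points$health), ,
               drop = FALSE]
  if (nrow(hc) == 0L) stop_input("no hard-coral points in input")
  hc$class <- if (grouping == "genus_health") {
    paste(hc$genus, hc$health, sep = "_")
  } else {
    hc$health
  }
  tr <- unique(hc[c("site", "time", "transect_id")])
  tr <- tr[order(tr$site, tr$time, tr$transect_id), , drop = FALSE]
  classes <- sort(unique(hc$class))
  mat <- matrix(0, nrow(tr), length(classes),
                dimnames = list(tr$transect_id, classes))
  for (i in seq_len(nrow(tr))) {
    sel <- hc$site == tr$site[i] & hc$time == tr$time[i] &
      hc$transect_id == tr$transect_id[i]
    tab <- table(hc$class[sel])
    mat[i, names(tab)] <- 100 * as.numeric(tab) / sum(tab)
  }
  rownames(tr) <- NULL
  abundance_matrix(mat, tr)
}

#' Write an abundance matrix as a wide CSV
#'
#' First columns `site, time, transect_id` (plus any further meta), then one
#' column per class.
#'
#' @param m An [abundance_matrix()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(m, path) {
  if (!inherits(m, "abundance_matrix")) stop_input("m must be an abundance_matrix")
  utils::write.csv(cbind(m$meta, as.data.frame(m$values)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide abundance CSV
#'
#' @param path CSV path.
#' @param meta_cols Names of the leading metadata columns.
#' @return An [abundance_matrix()] in state `"raw"`.
#' @export
read_abundance_csv <- function(path, meta_cols = c("site", "time", "transect_id")) {
  if (!file.exists(path)) stop_input("abundance file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(meta_cols, names(df))
  if (length(miss)) stop_input(path, " is missing meta column(s) ", paste(miss, collapse = ", "))
  abundance_matrix(as.matrix(df[setdiff(names(df), meta_cols)]),
                   df[meta_cols])
}
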