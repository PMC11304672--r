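#' Construct a telemetry dataset from a data frame
#'
#' Validates and normalises a table of GPS relocations into the tidy
#' telemetry format used throughout the package: one row per fix, columns
#' `animal_id`, `timestamp` (POSIXct, UTC), and either `x`/`y` (projected
#' metres) or `lon`/`lat` (decimal degrees). Rows are sorted by
#' `(animal_id, timestamp)`; duplicate `(animal_id, timestamp)` rows are
#' dropped (first kept) and rows with unparseable timestamps or non-finite
#' coordinates are dropped, each with a message reporting the count.
#'
#' @param df A data frame of relocations.
#' @param coordinate_mode `"projected"` (metres) or `"geographic"`
#'   (longitude/latitude degrees). Exactly one mode per dataset.
#' @param day_timezone Timezone used to split calendar days when daily
#'   tracks are formed (see [permute_datastream()]). Timestamps themselves
#'   are stored UTC-normalised. Default `"UTC"`.
#' @return A tibble of class `telemetry` with attributes `coordinate_mode`
#'   and `day_timezone`.
#' @examples
#' df <- data.frame(
#'   animal_id = c("A", "A", "B"),
#'   timestamp = as.POSIXct(c("2020-01-01 00:00", "2020-01-01 02:00",
#'                            "2020-01-01 00:01"), tz = "UTC"),
#'   x = c(0, 10, 5), y = c(0, 0, 5)
#' )
#' as_telemetry(df)
#' @export
as_telemetry <- function(df, coordinate_mode = c("projected", "geographic"),
                         day_timezone = "UTC") {
  coordinate_mode <- match.arg(coordinate_mode)
  coord_cols <- if (coordinate_mode == "projected") c("x", "y") else c("lon", "lat")
  needed <- c("animal_id", "timestamp", coord_cols)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("telemetry input is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "telesna_config_error")
  }
  out <- as_tibble(df)[needed]
  out$animal_id <- as.character(out$animal_id)
  if (!inherits(out$timestamp, "POSIXct")) {
    raw <- as.character(out$timestamp)
    parsed <- as.POSIXct(rep(NA_real_, length(raw)), origin = "1970-01-01", tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                  "%Y-%m-%d %H:%M", "%Y/%m/%d %H:%M:%OS")) {
      todo <- is.na(parsed)
      if (!any(todo)) break
      parsed[todo] <- as.POSIXct(raw[todo], tz = "UTC", format = fmt)
    }
    out$timestamp <- parsed
  }
  attr(out$timestamp, "tzone") <- "UTC"

  bad <- is.na(out$timestamp) | !is.finite(out[[coord_cols[1]]]) |
    !is.finite(out[[coord_cols[2]]]) | is.na(out$animal_id)
  if (any(bad)) {
    inform(sprintf("Dropped %d row(s) with unparseable timestamps or non-finite coordinates.",
                   sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out <- arrange(out, .data$animal_id, .data$timestamp)
  dup <- duplicated(out[c("animal_id", "timestamp")])
  if (any(dup)) {
    warn(sprintf("Dropped %d duplicate (animal_id, timestamp) row(s); first occurrence kept.",
                 sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  if (nrow(out) == 0) {
    abort("No valid relocations remain after validation.",
          class = "telesna_empty_error")
  }
  structure(out,
            coordinate_mode = coordinate_mode,
            day_timezone = day_timezone,
            class = c("telemetry", class(out)))
}

#' Read GPS relocations from a CSV file
#'
#' @param path Path to a CSV file with one row per GPS fix.
#' @param column_map Named character vector mapping the canonical names
#'   (`animal_id`, `timestamp`, and `x`/`y` or `lon`/`lat`) to the column
#'   names in the file. Defaults to identity.
#' @param coordinate_mode,day_timezone See [as_telemetry()].
#' @return A `telemetry` tibble.
#' @export
read_telemetry <- function(path, column_map = NULL,
                           coordinate_mode = c("projected", "geographic"),
                           day_timezone = "UTC") {
  coordinate_mode <- match.arg(coordinate_mode)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "telesna_config_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  canonical <- c("animal_id", "timestamp",
                 if (coordinate_mode == "projected") c("x", "y") else c("lon", "lat"))
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV is missing mapped column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "telesna_config_error")
  }
  df <- setNames(raw[unname(map)], names(map))
  as_telemetry(df, coordinate_mode = coordinate_mode, day_timezone = day_timezone)
}

#' Write a telemetry dataset to CSV
#'
#' Writes the normalised schema (`animal_id`, ISO-8601 UTC `timestamp`,
#' coordinates); [read_telemetry()] on the output round-trips the dataset.
#'
#' @param ds A `telemetry` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(ds, path) {
  out <- as_tibble(ds)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

coordinate_mode_of <- function(ds) {
  attr(ds, "coordinate_mode") %||%
    (if (all(c("x", "y") %in% names(ds))) "projected" else "geographic")
}

day_timezone_of <- function(ds) attr(ds, "day_timezone") %||% "UTC"

coord_matrix <- function(ds) {
  if (coordinate_mode_of(ds) == "projected") {
    cbind(ds$x, ds$y)
  } else {
    cbind(ds$lon, ds$lat)
  }
}

#' Distance between relocations
#'
#' Euclidean distance for projected coordinates; haversine great-circle
#' distance on a sphere of radius 6,371,000 m for geographic coordinates.
#' Vectorised over rows.
#'
#' @param p1,p2 Two-column matrices (or vectors of length 2): `x,y` metres
#'   in projected mode, `lon,lat` degrees in geographic mode.
#' @param coordinate_mode `"projected"` or `"geographic"`.
#' @return Distance(s) in metres.
#' @examples
#' pairwise_distance(c(0, 0), c(3, 4))  # 5
#' @export
pairwise_distance <- function(p1, p2, coordinate_mode = c("projected", "geographic")) {
  coordinate_mode <- match.arg(coordinate_mode)
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 2)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 2)
  if (coordinate_mode == "projected") {
    sqrt((p1[, 1] - p2[, 1])^2 + (p1[, 2] - p2[, 2])^2)
  } else {
    geosphere::distHaversine(p1, p2, r = 6371000)
  }
}

#' Summarise a telemetry dataset
#'
#' One row per animal (fix count, date span, median interval between
#' consecutive fixes) plus a totals row with `animal_id = "TOTAL"`.
#' Animals with a single fix get `NA` median interval.
#'
#' @param ds A `telemetry` tibble.
#' @return A tibble with columns `animal_id`, `n_fixes`, `first_fix`,
#'   `last_fix`, `median_interval_mins`.
#' @export
summarize_telemetry <- function(ds) {
  if (nrow(ds) == 0) abort("Empty telemetry dataset.", class = "telesna_empty_error")
  per <- as_tibble(ds) |>
    group_by(.data$animal_id) |>
    summarise(
      n_fixes = dplyr::n(),
      first_fix = min(.data$timestamp),
      last_fix = max(.data$timestamp),
      median_interval_mins = if (dplyr::n() > 1) {
        median(as.numeric(diff(sort(.data$timestamp)), units = "mins"))
      } else NA_real_,
      .groups = "drop"
    )
  total <- tibble(
    animal_id = "TOTAL",
    n_fixes = sum(per$n_fixes),
    first_fix = min(per$first_fix),
    last_fix = max(per$last_fix),
    median_interval_mins = median(per$median_interval_mins, na.rm = TRUE)
  )
  bind_rows(per, total)
}
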