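# Relocation data model: construction, validation, regularisation,
# grouping, and delimited-text I/O.

#' Create a track from columnar relocation data
#'
#' A track is a time-ordered set of relocations of one or more sampling
#' instances, stored as a tibble with columns `x`, `y` (metres, projected
#' CRS), `t` (POSIXct, stored UTC) and any retained extra columns (e.g.
#' `id`, `sex`, `hdop`). The EPSG code travels with the object.
#'
#' Fixes are sorted by time (within `id` when an `id` column is present);
#' duplicate timestamps are dropped keeping the first fix, with a warning.
#'
#' @param tbl a data frame of relocations.
#' @param x,y,t column names (bare or quoted) holding the planar
#'   coordinates and the timestamp. Timestamps may be POSIXct or ISO-8601
#'   strings; strings are parsed as UTC.
#' @param crs EPSG integer code of the coordinates. A geographic code
#'   (e.g. 4326) is accepted but flagged; estimators refuse geographic
#'   tracks.
#' @param ... additional named columns to retain, e.g. `id = id`,
#'   `hdop = HDOP`.
#' @return an `hr_track` tibble.
#' @examples
#' tbl <- data.frame(lon = c(0, 10), lat = c(0, 5),
#'                   time = c("2011-01-01 00:00:00", "2011-01-01 01:00:00"))
#' make_track(tbl, lon, lat, time, crs = 5070)
#' @export
make_track <- function(tbl, x, y, t, crs, ...) {
  x <- rlang::as_name(rlang::ensym(x))
  y <- rlang::as_name(rlang::ensym(y))
  t <- rlang::as_name(rlang::ensym(t))
  crs <- check_epsg(crs)
  extra <- rlang::enquos(...)
  need <- c(x, y, t)
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop_schema(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  }
  out <- tibble::tibble(
    x = as.numeric(tbl[[x]]),
    y = as.numeric(tbl[[y]]),
    t = parse_instants(tbl[[t]])
  )
  for (nm in names(extra)) {
    col <- rlang::eval_tidy(extra[[nm]], data = tbl)
    out[[nm]] <- col
  }
  new_track(out, crs = crs)
}

parse_instants <- function(v) {
  if (inherits(v, "POSIXct")) return(lubridate::with_tz(v, "UTC"))
  parsed <- suppressWarnings(lubridate::ymd_hms(as.character(v), tz = "UTC"))
  if (anyNA(parsed)) {
    # second attempt: date-only or alternative separators
    bad <- which(is.na(parsed))
    alt <- suppressWarnings(lubridate::parse_date_time(
      as.character(v)[bad], orders = c("ymd HMS", "ymd HM", "ymd"), tz = "UTC"
    ))
    parsed[bad] <- alt
    if (anyNA(parsed)) {
      stop_schema(sprintf(
        "Unparseable timestamp(s) at row(s): %s",
        paste(utils::head(which(is.na(parsed)), 5L), collapse = ", ")
      ))
    }
  }
  parsed
}

new_track <- function(df, crs) {
  crs <- check_epsg(crs)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop_schema("All coordinates must be finite.")
  }
  if ("hdop" %in% names(df)) {
    if (any(!is.na(df$hdop) & df$hdop <= 0)) {
      stop_schema("`hdop` values must be positive.")
    }
  }
  if ("id" %in% names(df)) {
    df <- df[order(df$id, df$t), , drop = FALSE]
    dup <- unlist(lapply(split(seq_len(nrow(df)), df$id), function(ix) {
      ix[duplicated(df$t[ix])]
    }), use.names = FALSE)
  } else {
    df <- df[order(df$t), , drop = FALSE]
    dup <- which(duplicated(df$t))
  }
  if (length(dup)) {
    rlang::warn(sprintf("Dropped %d fix(es) with duplicate timestamps (kept first).",
                        length(dup)))
    df <- df[-dup, , drop = FALSE]
  }
  structure(
    tibble::as_tibble(df),
    crs = crs,
    geographic = crs_is_geographic(crs),
    class = c("hr_track", class(tibble::tibble()))
  )
}

#' @export
print.hr_track <- function(x, ...) {
  cat(sprintf("<hr_track> %d fixes, EPSG:%d%s\n", nrow(x), attr(x, "crs"),
              if (isTRUE(attr(x, "geographic"))) " (geographic!)" else ""))
  NextMethod()
}

#' Get the EPSG code of a track or estimate
#' @param x an `hr_track` or home-range estimate.
#' @return an integer EPSG code.
#' @export
get_crs <- function(x) {
  if (inherits(x, "hr_track")) return(attr(x, "crs"))
  if (inherits(x, "hr_estimate")) return(x$crs)
  stop_unsupported("`get_crs()` expects a track or home-range estimate.")
}

is_track <- function(x) inherits(x, "hr_track")

check_track <- function(track, require_projected = TRUE) {
  if (!is_track(track)) stop_schema("Expected an `hr_track` object.")
  if (require_projected && isTRUE(attr(track, "geographic"))) {
    stop_domain(paste0(
      "Track is in a geographic CRS (EPSG:", attr(track, "crs"),
      "); reproject to a planar CRS before estimation."
    ))
  }
  invisible(track)
}

# preserve track class/attrs through row subsetting
track_subset <- function(track, idx) {
  out <- tibble::as_tibble(track)[idx, , drop = FALSE]
  structure(out, crs = attr(track, "crs"), geographic = attr(track, "geographic"),
            class = class(track))
}

#' Thin a track to (at most) one fix per regular interval
#'
#' Windows are anchored at the first fix's time floored to the interval;
#' each fix belongs to the window containing it, and the first fix at most
#' `tolerance` after the window anchor is retained. Gaps remain gaps: no
#' interpolation, every output fix exists in the input.
#'
#' @param track an `hr_track`.
#' @param interval window length; seconds, a `difftime` or a lubridate
#'   duration.
#' @param tolerance maximum delay after the window anchor for a fix to be
#'   retained; same units as `interval`.
#' @return the thinned `hr_track`.
#' @export
resample_track <- function(track, interval, tolerance = interval / 2) {
  check_track(track, require_projected = FALSE)
  interval <- as_seconds(interval)
  tolerance <- as_seconds(tolerance)
  if (interval <= 0) stop_domain("`interval` must be > 0.")
  if (tolerance < 0) stop_domain("`tolerance` must be >= 0.")
  if (nrow(track) == 0L) return(track)
  tt <- as.numeric(track$t)
  a0 <- floor(tt[1L] / interval) * interval
  win <- floor((tt - a0) / interval)
  offset <- tt - (a0 + win * interval)
  # first eligible fix per window (a window may contain none)
  keep <- tapply(seq_along(tt), win, function(ix) {
    cand <- ix[offset[ix] <= tolerance]
    if (length(cand)) cand[1L] else NA_integer_
  })
  track_subset(track, sort(keep[!is.na(keep)]))
}

as_seconds <- function(x) {
  if (inherits(x, "difftime")) return(as.numeric(x, units = "secs"))
  as.numeric(x)
}

#' Floor an instant to the start of its week
#'
#' @param t a POSIXct vector.
#' @param week_start day the week starts on, as in lubridate: 1 = Monday,
#'   7 = Sunday. Defaults to Monday.
#' @return POSIXct vector of week-boundary instants (00:00:00).
#' @export
floor_week <- function(t, week_start = 1) {
  lubridate::floor_date(t, unit = "week", week_start = week_start)
}

#' Split a relocation table into one track per group
#'
#' @param track an `hr_track` whose extra columns include the grouping
#'   variables.
#' @param by character vector of grouping column names (e.g. `"id"` or
#'   `c("id", "week")`).
#' @param min_n drop groups with fewer than `min_n` fixes (default keeps
#'   all).
#' @return an `hr_grouped_tracks` tibble: one row per group with the key
#'   columns, the group size `n`, and a `track` list-column.
#' @export
group_tracks <- function(track, by, min_n = 1L) {
  check_track(track, require_projected = FALSE)
  miss <- setdiff(by, names(track))
  if (length(miss)) {
    stop_schema(sprintf("Grouping column(s) not found: %s", paste(miss, collapse = ", ")))
  }
  df <- tibble::as_tibble(track)
  keys <- df[, by, drop = FALSE]
  key_id <- do.call(paste, c(lapply(keys, as.character), sep = "\r"))
  ord <- order(match(key_id, unique(key_id)))
  splits <- split(seq_len(nrow(df)), factor(key_id, levels = unique(key_id)))
  rows <- lapply(splits, function(ix) {
    g <- df[ix, , drop = FALSE]
    trk <- new_track(g[, setdiff(names(g), by), drop = FALSE], crs = attr(track, "crs"))
    key <- g[1L, by, drop = FALSE]
    key$n <- nrow(trk)
    key$track <- list(trk)
    key
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$n >= min_n, , drop = FALSE]
  structure(out, crs = attr(track, "crs"),
            keys = by,
            class = c("hr_grouped_tracks", class(tibble::tibble())))
}

#' @export
print.hr_grouped_tracks <- function(x, ...) {
  cat(sprintf("<hr_grouped_tracks> %d group(s) by %s, EPSG:%d\n",
              nrow(x), paste(attr(x, "keys"), collapse = ", "), attr(x, "crs")))
  NextMethod()
}

#' Read relocation data from a delimited text file
#'
#' Two dialects are supported. `generic_csv` expects columns `x`, `y`, `t`,
#' `id` and optionally `hdop`, with `x`/`y` already in a projected CRS
#' given by `crs`. `movebank_csv` expects `location-long`, `location-lat`,
#' `timestamp`, `individual-local-identifier` and optionally `gps:dop`;
#' coordinates are projected to the required target `crs`.
#'
#' @param path CSV file path.
#' @param dialect `"generic_csv"` or `"movebank_csv"`.
#' @param crs EPSG code: the CRS of the coordinates (generic) or the
#'   projection target (movebank, required).
#' @return an `hr_track` with an `id` column (and `hdop` when present).
#' @export
read_tracks <- function(path, dialect = c("generic_csv", "movebank_csv"), crs = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_schema(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "generic_csv") {
    if (is.null(crs)) stop_domain("`crs` is required for the generic CSV dialect.")
    need <- c("x", "y", "t", "id")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop_schema(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
    df <- tibble::tibble(x = as.numeric(raw$x), y = as.numeric(raw$y),
                         t = parse_instants(raw$t), id = as.character(raw$id))
    if ("hdop" %in% names(raw)) df$hdop <- as.numeric(raw$hdop)
    new_track(df, crs = crs)
  } else {
    if (is.null(crs)) {
      stop_domain("Movebank-dialect input is longitude/latitude; a target projection is required (supply `crs`, e.g. 5070).")
    }
    need <- c("location-long", "location-lat", "timestamp", "individual-local-identifier")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop_schema(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
    pr <- project_lonlat(as.numeric(raw[["location-long"]]),
                         as.numeric(raw[["location-lat"]]), crs)
    df <- tibble::tibble(x = pr$x, y = pr$y,
                         t = parse_instants(raw[["timestamp"]]),
                         id = as.character(raw[["individual-local-identifier"]]))
    if ("gps:dop" %in% names(raw)) df$hdop <- as.numeric(raw[["gps:dop"]])
    new_track(df, crs = crs)
  }
}

#' Write relocation data to a delimited text file
#'
#' @param track an `hr_track` (must carry an `id` column for the movebank
#'   dialect).
#' @param path output CSV path.
#' @param dialect `"generic_csv"` or `"movebank_csv"`. The movebank dialect
#'   writes longitude/latitude and requires the track CRS to support
#'   inverse projection (EPSG:5070).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(track, path, dialect = c("generic_csv", "movebank_csv")) {
  dialect <- match.arg(dialect)
  check_track(track, require_projected = FALSE)
  df <- tibble::as_tibble(track)
  if (!"id" %in% names(df)) df$id <- "A1"
  tstr <- format(df$t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  if (dialect == "generic_csv") {
    out <- tibble::tibble(x = df$x, y = df$y, t = tstr, id = df$id)
    if ("hdop" %in% names(df)) out$hdop <- df$hdop
  } else {
    ll <- project_to_lonlat(df$x, df$y, attr(track, "crs"))
    out <- tibble::tibble(
      `location-long` = ll$lon, `location-lat` = ll$lat,
      timestamp = tstr, `individual-local-identifier` = df$id
    )
    if ("hdop" %in% names(df)) out[["gps:dop"]] <- df$hdop
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a track as GeoJSON points
#'
#' Writes an RFC 7946 FeatureCollection of Point features with `id`, `t`
#' (ISO-8601) and `hdop` properties.
#'
#' @param track an `hr_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_geojson <- function(track, path) {
  check_track(track, require_projected = FALSE)
  df <- tibble::as_tibble(track)
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i])),
      properties = list(
        id = if ("id" %in% names(df)) df$id[i] else NULL,
        t = format(df$t[i], "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
        hdop = if ("hdop" %in% names(df)) df$hdop[i] else NULL
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
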