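# The common home-range estimator contract. Every estimate, geometric or
# probabilistic, is a named list with class `hr_estimate` carrying:
#   estimator  label ("mcp", "locoh", "kde", "akde", "akde_error")
#   levels     sorted isopleth levels in (0, 1]
#   crs        EPSG code inherited from the data
#   data       the source track (droppable with keep_data = FALSE)
#   isopleths  tibble(level, what, area, geometry) with multipolygon
#              geometry (list of rings, see geometry.R)
#   params     estimator-specific settings
# Probabilistic estimates add: trast, ud (hr_raster of cell probability
# masses), h (bandwidths), and for aKDE a movement-model fit and area CIs.

new_hr_estimate <- function(estimator, levels, crs, data, isopleths, params,
                            class2, extra = list()) {
  obj <- c(list(
    estimator = estimator, levels = levels, crs = crs, data = data,
    isopleths = isopleths, params = params
  ), extra)
  structure(obj, class = c(class2, "hr_estimate"))
}

is_probabilistic <- function(est) inherits(est, "hr_prob_estimate")

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("<hr_%s> levels: %s, EPSG:%d\n", x$estimator,
              paste(x$levels, collapse = ", "), x$crs))
  at <- hr_area(x)
  print(at)
  invisible(x)
}

#' Home-range area table
#'
#' Returns the long-format area table of an estimate: one row per level and
#' `what`, with `what` being `"estimate"` and, for aKDE, `"lci"`/`"uci"`
#' confidence bounds. Areas are planar areas in square metres.
#'
#' @param est a home-range estimate.
#' @return a tibble with columns `level`, `what`, `area`.
#' @export
hr_area <- function(est) {
  stopifnot(inherits(est, "hr_estimate"))
  iso <- est$isopleths
  out <- tibble::tibble(level = iso$level, what = iso$what, area = iso$area)
  out[order(out$level, match(out$what, c("lci", "estimate", "uci"))), ]
}

#' Home-range isopleth features
#'
#' One feature per level (and per confidence bound for aKDE) with
#' attributes `level`, `what`, `area` (m^2) and a `geometry` list-column of
#' multipolygons in the estimate's CRS. Feature areas agree with
#' [hr_area()] exactly (they are the same numbers).
#'
#' @param est a home-range estimate.
#' @return a tibble with columns `level`, `what`, `area`, `geometry`.
#' @export
hr_isopleths <- function(est) {
  stopifnot(inherits(est, "hr_estimate"))
  est$isopleths
}

#' Utilization distribution of a probabilistic estimate
#'
#' @param est a probabilistic home-range estimate (KDE or aKDE).
#' @return an `hr_raster` of per-cell probability masses summing to 1.
#' @export
hr_ud <- function(est) {
  if (!is_probabilistic(est)) {
    stop_unsupported("`hr_ud()` is only defined for probabilistic estimators.")
  }
  est$ud
}

#' Cumulative utilization distribution
#'
#' Cells are ranked by density; each cell is assigned the total probability
#' mass of all cells at least as dense as itself (tied densities share the
#' larger cumulative value). Thresholding this surface at a level yields
#' the smallest cell set holding that fraction of the mass.
#'
#' @param est a probabilistic home-range estimate.
#' @return an `hr_raster` with values in (0, 1].
#' @export
hr_cud <- function(est) {
  if (!is_probabilistic(est)) {
    stop_unsupported("`hr_cud()` is only defined for probabilistic estimators.")
  }
  r <- est$ud
  r$values <- cumulative_ud(r$values)
  r
}

# smallest cell set holding at least `level` of the total mass: cells are
# taken in decreasing density order (ties by cell index) until the running
# sum reaches the level
ud_level_mask <- function(m, level) {
  v <- as.vector(m)
  ord <- order(v, decreasing = TRUE)
  cs <- cumsum(v[ord])
  k <- which(cs >= level * sum(v) - 1e-12)[1L]
  if (is.na(k)) k <- length(v)
  mask <- logical(length(v))
  mask[ord[seq_len(k)]] <- TRUE
  matrix(mask, nrow = nrow(m))
}

cumulative_ud <- function(m) {
  v <- as.vector(m)
  ord <- order(v, decreasing = TRUE)
  cs <- cumsum(v[ord])
  # ties share the larger cumulative value
  cs <- stats::ave(cs, v[ord], FUN = max)
  out <- numeric(length(v))
  out[ord] <- cs
  matrix(out, nrow = nrow(m))
}

#' Export isopleths as GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection of MultiPolygon features with
#' properties `level`, `what` and `area_m2`.
#'
#' @param est a home-range estimate (or an isopleth tibble from
#'   [hr_isopleths()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isopleths_geojson <- function(est, path) {
  iso <- if (inherits(est, "hr_estimate")) hr_isopleths(est) else est
  feats <- lapply(seq_len(nrow(iso)), function(i) {
    polys <- assemble_polygons(iso$geometry[[i]])
    coords <- lapply(polys, function(p) lapply(p, ring_to_coords))
    list(
      type = "Feature",
      geometry = list(type = "MultiPolygon", coordinates = coords),
      properties = list(level = iso$level[i], what = iso$what[i],
                        area_m2 = iso$area[i])
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read isopleths back from GeoJSON
#'
#' @param path a GeoJSON file written by [write_isopleths_geojson()].
#' @return an isopleth tibble (`level`, `what`, `area`, `geometry`).
#' @export
read_isopleths_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(f) {
    rings <- list()
    for (poly in f$geometry$coordinates) {
      for (ring in poly) rings <- c(rings, list(coords_to_ring(ring)))
    }
    tibble::tibble(level = as.numeric(f$properties$level),
                   what = as.character(f$properties$what),
                   area = as.numeric(f$properties$area_m2),
                   geometry = list(rings))
  })
  dplyr::bind_rows(rows)
}
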