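#' Minimum convex polygon home range
#'
#' The classical hull-based estimator: for each level `a`, fixes are peeled
#' by distance from the arithmetic-mean centroid — only fixes whose
#' Euclidean distance to the centroid is at most the `a`-quantile of all
#' distances (linear-interpolation, R type-7 quantile) are retained — and
#' the home range is the convex hull of the retained fixes.
#'
#' @param track an `hr_track` in a projected CRS with at least 3
#'   non-collinear fixes.
#' @param levels isopleth levels, fractions in (0, 1].
#' @param keep_data keep the source track on the estimate?
#' @return an `hr_estimate` of subclass `hr_geom_estimate`.
#' @examples
#' sq <- make_track(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
#'                             t = as.POSIXct("2011-01-01", tz = "UTC") + 1:4),
#'                  x, y, t, crs = 5070)
#' hr_area(hr_mcp(sq, levels = 1))
#' @export
hr_mcp <- function(track, levels = 0.95, keep_data = TRUE) {
  check_track(track)
  levels <- check_levels(levels)
  if (nrow(track) < 3L) {
    stop_geometry("MCP needs at least 3 fixes.")
  }
  cx <- mean(track$x)
  cy <- mean(track$y)
  d <- sqrt((track$x - cx)^2 + (track$y - cy)^2)
  iso <- lapply(levels, function(a) {
    keep <- d <= stats::quantile(d, a, type = 7)
    ring <- convex_hull_ring(track$x[keep], track$y[keep])
    if (is.null(ring)) {
      stop_geometry(sprintf(
        "Degenerate geometry at level %g: fewer than 3 distinct non-collinear fixes retained.", a
      ))
    }
    geom <- list(ring)
    tibble::tibble(level = a, what = "estimate", area = poly_area(geom),
                   geometry = list(geom))
  })
  new_hr_estimate(
    estimator = "mcp", levels = levels, crs = get_crs(track),
    data = if (keep_data) track else NULL,
    isopleths = dplyr::bind_rows(iso),
    params = list(),
    class2 = "hr_geom_estimate"
  )
}
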