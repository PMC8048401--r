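# Isopleth extraction from the cumulative UD surface. Contours are drawn
# on the *cumulative* surface (marching squares via isoband, holes
# preserved) so that polygon areas match the mass interpretation directly:
# the region {cud <= level} is the smallest cell set holding `level` of
# the mass.

contour_isopleths <- function(trast, cud_vals, levels) {
  xs <- trast_xcenters(trast)
  # isoband orients rings for ascending axes; flip the north-up matrix
  ys <- rev(trast_ycenters(trast))
  cud_vals <- cud_vals[nrow(cud_vals):1, , drop = FALSE]
  rows <- lapply(levels, function(a) {
    if (min(cud_vals) > a) {
      rlang::warn(sprintf(
        "Level %g lies below the smallest cumulative mass (%.3g); empty isopleth.",
        a, min(cud_vals)
      ))
      return(tibble::tibble(level = a, what = "estimate", area = 0,
                            geometry = list(list())))
    }
    b <- isoband::isobands(xs, ys, cud_vals, levels_low = 0, levels_high = a)[[1]]
    rings <- split(data.frame(x = b$x, y = b$y), b$id)
    rings <- lapply(rings, function(d) list(x = d$x, y = d$y))
    names(rings) <- NULL
    tibble::tibble(level = a, what = "estimate", area = poly_area(rings),
                   geometry = list(rings))
  })
  dplyr::bind_rows(rows)
}

#' Extract isopleth polygons from a probabilistic estimate
#'
#' Contours the cumulative UD of a KDE/aKDE estimate at arbitrary levels
#' (not only the levels the estimate was built with).
#'
#' @param est a probabilistic home-range estimate.
#' @param levels fractions in (0, 1).
#' @return an isopleth tibble (`level`, `what`, `area`, `geometry`).
#' @export
ud_to_isopleths <- function(est, levels) {
  if (!is_probabilistic(est)) {
    stop_unsupported("`ud_to_isopleths()` needs a probabilistic estimate.")
  }
  levels <- check_levels(levels, allow_one = FALSE)
  contour_isopleths(est$trast, cumulative_ud(est$ud$values), levels)
}
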