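#' Template raster for utilization distributions
#'
#' The grid geometry (extent, resolution, CRS) on which UDs are evaluated.
#' The extent is the bounding box of the fixes expanded by `buffer` on every
#' side; `buffer = "auto"` uses half the larger bounding-box span. Cells are
#' square, sized so the extent has `ncol` columns; the number of rows is the
#' smallest count covering the (buffered) y-span, with the top edge pushed
#' out to keep cells square.
#'
#' @param track an `hr_track`.
#' @param buffer margin in metres, or `"auto"`.
#' @param ncol number of columns.
#' @return an `hr_trast`.
#' @export
make_trast <- function(track, buffer = "auto", ncol = 200) {
  check_track(track)
  if (nrow(track) == 0L) stop_domain("Cannot build a template raster from an empty track.")
  xr <- range(track$x); yr <- range(track$y)
  if (identical(buffer, "auto")) {
    buffer <- max(diff(xr), diff(yr)) / 2
  }
  if (!is_scalar_number(buffer) || buffer < 0) {
    stop_domain("`buffer` must be \"auto\" or a non-negative number.")
  }
  xmin <- xr[1] - buffer; xmax <- xr[2] + buffer
  ymin <- yr[1] - buffer; ymax <- yr[2] + buffer
  if (xmax - xmin <= 0 || ymax - ymin <= 0) {
    stop_domain("Degenerate raster extent (zero span); supply a positive `buffer`.")
  }
  ncol <- as.integer(ncol)
  if (ncol < 2L) stop_domain("`ncol` must be >= 2.")
  cs <- (xmax - xmin) / ncol
  nrow <- max(2L, as.integer(ceiling((ymax - ymin) / cs - 1e-9)))
  ymax <- ymin + nrow * cs
  structure(
    list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         ncol = ncol, nrow = nrow, crs = get_crs(track)),
    class = "hr_trast"
  )
}

#' @export
print.hr_trast <- function(x, ...) {
  cat(sprintf(
    "<hr_trast> %d x %d cells of %.6g m, extent [%.7g, %.7g] x [%.7g, %.7g], EPSG:%d\n",
    x$nrow, x$ncol, trast_cellsize(x), x$xmin, x$xmax, x$ymin, x$ymax, x$crs
  ))
  invisible(x)
}

trast_cellsize <- function(tr) (tr$xmax - tr$xmin) / tr$ncol

trast_xcenters <- function(tr) tr$xmin + (seq_len(tr$ncol) - 0.5) * trast_cellsize(tr)

# descending, matching north-up matrix storage (row 1 = top)
trast_ycenters <- function(tr) tr$ymax - (seq_len(tr$nrow) - 0.5) * trast_cellsize(tr)

trast_raster <- function(tr, values) {
  new_hr_raster(values, xmin = tr$xmin, xmax = tr$xmax, ymin = tr$ymin,
                ymax = tr$ymax, crs = tr$crs)
}

trast_contains <- function(tr, x, y) {
  all(x > tr$xmin & x < tr$xmax & y > tr$ymin & y < tr$ymax)
}
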