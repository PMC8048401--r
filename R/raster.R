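# Minimal in-memory single-band raster with square cells, plus ESRI ASCII
# grid (.asc) I/O — the plain-text raster format used for UD, cumulative UD
# and land-cover grids. Values are stored north-up: row 1 is the top
# (largest y) row, matching the on-disk ASCII grid layout.

new_hr_raster <- function(values, xmin, xmax, ymin, ymax, crs = NA_integer_) {
  stopifnot(is.matrix(values))
  csx <- (xmax - xmin) / ncol(values)
  csy <- (ymax - ymin) / nrow(values)
  if (abs(csx - csy) > 1e-9 * max(csx, csy)) {
    stop_domain("Raster cells must be square.")
  }
  structure(
    list(values = values, xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         crs = if (is.na(crs)) NA_integer_ else as.integer(crs)),
    class = "hr_raster"
  )
}

#' @export
print.hr_raster <- function(x, ...) {
  cat(sprintf(
    "<hr_raster> %d x %d cells, cell size %.6g m, extent [%.6g, %.6g] x [%.6g, %.6g], EPSG:%s\n",
    nrow(x$values), ncol(x$values), raster_cellsize(x),
    x$xmin, x$xmax, x$ymin, x$ymax, x$crs
  ))
  invisible(x)
}

raster_cellsize <- function(r) (r$xmax - r$xmin) / ncol(r$values)

# cell-centre coordinates; x ascending (columns), y descending (rows)
raster_xcenters <- function(r) {
  cs <- raster_cellsize(r)
  r$xmin + (seq_len(ncol(r$values)) - 0.5) * cs
}

raster_ycenters <- function(r) {
  cs <- raster_cellsize(r)
  r$ymax - (seq_len(nrow(r$values)) - 0.5) * cs
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r an `hr_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param digits significant digits written per cell.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, digits = 10) {
  stopifnot(inherits(r, "hr_raster"))
  cs <- raster_cellsize(r)
  hdr <- c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", cs),
    "NODATA_value -9999"
  )
  v <- r$values
  v[is.na(v)] <- -9999
  rows <- apply(v, 1L, function(z) paste(formatC(z, digits = digits, format = "g"),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path input file path.
#' @param crs EPSG code to tag the raster with (ASCII grids carry no CRS).
#' @return an `hr_raster`.
#' @export
read_asc <- function(path, crs = NA) {
  if (!file.exists(path)) stop_schema(sprintf("File not found: %s", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == nc * nr)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA
  new_hr_raster(m, xmin = hdr$xllcorner, xmax = hdr$xllcorner + nc * cs,
                ymin = hdr$yllcorner, ymax = hdr$yllcorner + nr * cs,
                crs = if (is.na(crs)) NA_integer_ else as.integer(crs))
}
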