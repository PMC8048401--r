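# Planar polygon helpers.
#
# Polygons are represented the way polyclip represents them: a *multipolygon*
# is a list of rings, each ring a list(x, y) of vertex coordinates (not
# closed; the last vertex is implicitly joined to the first). Outer rings are
# counter-clockwise (positive signed area), holes clockwise (negative), so
# the net area of a multipolygon is the sum of signed ring areas.

ring_signed_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  0.5 * sum(x * (y[c(2:n, 1L)]) - x[c(2:n, 1L)] * y)
}

poly_area <- function(rings) {
  if (length(rings) == 0L) return(0)
  sum(vapply(rings, function(r) ring_signed_area(r$x, r$y), numeric(1)))
}

# Convex hull as a single CCW ring; NULL when degenerate (<3 distinct
# non-collinear points).
convex_hull_ring <- function(x, y) {
  keep <- !duplicated(cbind(x, y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) return(NULL)
  idx <- grDevices::chull(x, y)
  if (length(idx) < 3L) return(NULL)
  r <- list(x = x[idx], y = y[idx])
  if (ring_signed_area(r$x, r$y) < 0) r <- list(x = rev(r$x), y = rev(r$y))
  if (abs(ring_signed_area(r$x, r$y)) <= 0) return(NULL)
  r
}

poly_op <- function(a, b, op) {
  out <- polyclip::polyclip(a, b, op = op,
                            fillA = "nonzero", fillB = "nonzero")
  out
}

poly_union <- function(a, b) poly_op(a, b, "union")
poly_intersection <- function(a, b) poly_op(a, b, "intersection")

# Boundary-inclusive point membership under even-odd filling across rings.
points_in_poly <- function(px, py, rings) {
  if (length(rings) == 0L) return(rep(FALSE, length(px)))
  inside <- rep(0L, length(px))
  boundary <- rep(FALSE, length(px))
  for (r in rings) {
    code <- sp::point.in.polygon(px, py, r$x, r$y)
    boundary <- boundary | code >= 2L
    inside <- inside + as.integer(code == 1L)
  }
  boundary | (inside %% 2L == 1L)
}

poly_translate <- function(rings, dx, dy) {
  lapply(rings, function(r) list(x = r$x + dx, y = r$y + dy))
}

poly_bbox <- function(rings) {
  xs <- unlist(lapply(rings, `[[`, "x"))
  ys <- unlist(lapply(rings, `[[`, "y"))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# Group loose rings into GeoJSON-style polygons: each outer (positive) ring
# carries the holes (negative rings) whose first vertex it contains.
assemble_polygons <- function(rings) {
  if (length(rings) == 0L) return(list())
  sa <- vapply(rings, function(r) ring_signed_area(r$x, r$y), numeric(1))
  outers <- rings[sa >= 0]
  holes <- rings[sa < 0]
  polys <- lapply(outers, function(o) list(o))
  for (h in holes) {
    placed <- FALSE
    for (i in seq_along(polys)) {
      o <- polys[[i]][[1L]]
      code <- sp::point.in.polygon(h$x[1L], h$y[1L], o$x, o$y)
      if (code > 0L) {
        polys[[i]] <- c(polys[[i]], list(h))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # orphan hole: keep as its own (negative-area) polygon so that net
      # area stays consistent
      polys <- c(polys, list(list(h)))
    }
  }
  polys
}

# Ring closure for GeoJSON (first vertex repeated at the end).
ring_to_coords <- function(r) {
  n <- length(r$x)
  m <- cbind(c(r$x, r$x[1L]), c(r$y, r$y[1L]))
  lapply(seq_len(n + 1L), function(i) c(m[i, 1L], m[i, 2L]))
}

coords_to_ring <- function(coords) {
  x <- vapply(coords, `[[`, numeric(1), 1L)
  y <- vapply(coords, `[[`, numeric(1), 2L)
  n <- length(x)
  if (n > 1L && x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  list(x = x, y = y)
}
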