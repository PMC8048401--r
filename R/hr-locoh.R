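#' Local convex hull (k-LoCoH) home range
#'
#' For every fix, the local hull of that fix together with its `n - 1`
#' Euclidean nearest neighbours (`n` points per hull, focal point included)
#' is formed. Hulls are sorted by area (ascending, ties broken by fix
#' index) and merged in order; the isopleth for level `a` is the first
#' running union that covers at least `ceiling(a * N)` of the `N` fixes,
#' dissolved to a multipolygon. Point coverage is boundary-inclusive.
#'
#' A common heuristic for the number of neighbours is the square root of
#' the number of fixes, `n = ceiling(sqrt(N))`, available as `n = "auto"`.
#'
#' @param track an `hr_track` in a projected CRS.
#' @param n number of points per local hull (>= 3), or `"auto"` for
#'   `ceiling(sqrt(N))`.
#' @param levels isopleth levels, fractions in (0, 1].
#' @param keep_data keep the source track on the estimate?
#' @return an `hr_estimate` of subclass `hr_geom_estimate`.
#' @export
hr_locoh <- function(track, n = "auto", levels = 0.95, keep_data = TRUE) {
  check_track(track)
  levels <- check_levels(levels)
  N <- nrow(track)
  if (identical(n, "auto")) n <- ceiling(sqrt(N))
  if (!is_scalar_number(n) || n < 3) stop_domain("`n` must be a single number >= 3.")
  n <- as.integer(n)
  if (n > N) stop_domain(sprintf("`n` (%d) exceeds the number of fixes (%d).", n, N))

  px <- track$x; py <- track$y
  hulls <- vector("list", N)
  areas <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    d2 <- (px - px[i])^2 + (py - py[i])^2
    nb <- c(i, setdiff(order(d2), i))[seq_len(n)]  # focal point always included
    ring <- convex_hull_ring(px[nb], py[nb])
    if (!is.null(ring)) {
      hulls[[i]] <- ring
      areas[i] <- ring_signed_area(ring$x, ring$y)
    }
  }
  ok <- which(!is.na(areas))
  if (!length(ok)) stop_geometry("All local hulls are degenerate.")
  if (length(ok) < N) {
    rlang::warn(sprintf("Skipped %d degenerate local hull(s).", N - length(ok)))
  }
  ord <- ok[order(areas[ok], ok)]

  thresholds <- ceiling(levels * N)
  covered <- rep(FALSE, N)
  acc <- list()
  iso <- vector("list", length(levels))
  li <- 1L
  for (i in ord) {
    hull <- list(hulls[[i]])
    acc <- if (length(acc) == 0L) hull else poly_union(acc, hull)
    newly <- !covered
    if (any(newly)) {
      covered[newly] <- points_in_poly(px[newly], py[newly], hull)
    }
    ncov <- sum(covered)
    while (li <= length(levels) && ncov >= thresholds[li]) {
      iso[[li]] <- acc
      li <- li + 1L
    }
    if (li > length(levels)) break
  }
  while (li <= length(levels)) {
    # not enough coverable fixes (degenerate hulls); fall back to the full union
    rlang::warn(sprintf(
      "Level %g: union of all local hulls covers only %d of %d fixes.",
      levels[li], sum(covered), N
    ))
    iso[[li]] <- acc
    li <- li + 1L
  }
  rows <- lapply(seq_along(levels), function(k) {
    tibble::tibble(level = levels[k], what = "estimate",
                   area = poly_area(iso[[k]]), geometry = list(iso[[k]]))
  })
  new_hr_estimate(
    estimator = "locoh", levels = levels, crs = get_crs(track),
    data = if (keep_data) track else NULL,
    isopleths = dplyr::bind_rows(rows),
    params = list(n = n),
    class2 = "hr_geom_estimate"
  )
}
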