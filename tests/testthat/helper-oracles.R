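# Independent oracles used across the suite. These deliberately avoid the
# code paths of the package: the hull oracle is gift wrapping + shoelace
# (package: grDevices::chull), the union-area oracle is dense grid point
# sampling (package: Clipper via polyclip), and the likelihood oracle is a
# dense multivariate-normal log-density (package: O(n) Kalman filtering).

# gift-wrapping (Jarvis march) convex hull, area by the shoelace formula
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3L) return(0)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p || r == q) next
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    p <- q
    if (p == start) break
    if (length(hull) > n) stop("gift wrapping failed to terminate")
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  m <- length(hx)
  abs(0.5 * sum(hx * hy[c(2:m, 1)] - hx[c(2:m, 1)] * hy))
}

# union area of a set of convex rings by dense grid sampling with
# boundary-inclusive point-in-polygon tests (independent of polyclip)
oracle_union_area_grid <- function(rings, n_grid = 1000) {
  xs <- unlist(lapply(rings, `[[`, "x"))
  ys <- unlist(lapply(rings, `[[`, "y"))
  gx <- seq(min(xs), max(xs), length.out = n_grid)
  gy <- seq(min(ys), max(ys), length.out = n_grid)
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  pts <- expand.grid(x = gx, y = gy)
  inside <- rep(FALSE, nrow(pts))
  for (r in rings) {
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- sp::point.in.polygon(pts$x[todo], pts$y[todo], r$x, r$y) > 0
  }
  sum(inside) * cell
}

# dense multivariate-normal log-likelihood built from position_acf()
oracle_dense_loglik <- function(trk, model, sigma2, tau_pos = NULL,
                                tau_vel = NULL, uere = NULL) {
  mu <- c(mean(trk$x), mean(trk$y))
  tt <- as.numeric(trk$t)
  n <- length(tt)
  fit <- list(model = model, sigma2 = sigma2, tau_pos = tau_pos, tau_vel = tau_vel)
  C <- outer(tt, tt, function(a, b) position_acf(fit, abs(a - b)))
  R <- if (is.null(uere)) {
    rep(0, n)
  } else {
    h <- if ("hdop" %in% names(trk)) trk$hdop else rep(1, n)
    (uere * h)^2 / 2
  }
  C <- C + diag(R, n)
  L <- chol(C)
  ll_ax <- function(yv, m) {
    z <- backsolve(L, yv - m, transpose = TRUE)
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
  }
  ll_ax(trk$x, mu[1]) + ll_ax(trk$y, mu[2])
}

# boundary-tolerant membership: inside by even-odd parity, or within `tol`
# of any polygon edge (clipper output can leave hairline gaps along shared
# edges of touching rings)
oracle_in_or_near <- function(px, py, rings, tol = 1e-6) {
  inside <- homerange:::points_in_poly(px, py, rings)
  for (k in which(!inside)) {
    d <- Inf
    for (r in rings) {
      n <- length(r$x)
      x1 <- r$x; y1 <- r$y
      x2 <- r$x[c(2:n, 1)]; y2 <- r$y[c(2:n, 1)]
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx^2 + dy^2
      tt <- pmin(pmax(((px[k] - x1) * dx + (py[k] - y1) * dy) / pmax(len2, 1e-300), 0), 1)
      d <- min(d, sqrt((x1 + tt * dx - px[k])^2 + (y1 + tt * dy - py[k])^2))
    }
    inside[k] <- d <= tol
  }
  inside
}

# small helper: a track from bare coordinates with evenly spaced times
toy_track <- function(x, y, crs = 5070, dt = 3600) {
  make_track(
    data.frame(x = x, y = y,
               t = as.POSIXct("2011-01-01", tz = "UTC") + dt * seq_along(x)),
    x, y, t, crs = crs
  )
}
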