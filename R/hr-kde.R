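# Kernel-based utilization distributions. The UD is stored as per-cell
# probability *masses* (summing to 1), evaluated from equally weighted
# product-Gaussian kernels at cell centres and renormalised. Kernels are
# truncated at 5 bandwidths; the neglected mass is < 1e-6.

# Gaussian kernel design matrix: rows = fixes, cols = grid centres.
# h may be per-fix (vector) to support fix-wise error inflation.
kernel_matrix <- function(centers, pos, h) {
  n <- length(pos)
  h <- rep_len(h, n)
  K <- matrix(0, nrow = n, ncol = length(centers))
  for (i in seq_len(n)) {
    z <- (centers - pos[i]) / h[i]
    v <- numeric(length(z))
    in5 <- abs(z) <= 5
    v[in5] <- exp(-0.5 * z[in5]^2)
    K[i, ] <- v / h[i]
  }
  K
}

ud_from_kernels <- function(track, trast, hx, hy) {
  Kx <- kernel_matrix(trast_xcenters(trast), track$x, hx)
  Ky <- kernel_matrix(trast_ycenters(trast), track$y, hy)
  D <- crossprod(Ky, Kx)  # nrow x ncol, north-up
  s <- sum(D)
  if (s <= 0) stop_domain("Utilization distribution is identically zero on the template raster; enlarge the extent or the bandwidth.")
  D / s
}

ref_bandwidth <- function(track) {
  n <- nrow(track)
  if (n < 5L) stop_domain("The reference bandwidth needs at least 5 fixes.")
  # ML (divisor n) standard deviations; bivariate normal reference rule
  sx <- sqrt(mean((track$x - mean(track$x))^2))
  sy <- sqrt(mean((track$y - mean(track$y))^2))
  if (sx <= 0 || sy <= 0) {
    stop_domain("Zero variance on an axis; supply an explicit bandwidth `h`.")
  }
  c(sx, sy) * n^(-1 / 6)
}

build_prob_estimate <- function(estimator, track, trast, ud_vals, h, levels,
                                keep_data, fit = NULL, params = list(),
                                debias = NULL) {
  ud <- trast_raster(trast, ud_vals)
  cud <- cumulative_ud(ud_vals)
  iso <- contour_isopleths(trast, cud, levels)
  if (!is.null(debias)) {
    # first-order correction of the kernel-induced variance inflation:
    # shrink isopleths about the UD centre so areas scale by `f`
    s <- sqrt(debias$f)
    iso$geometry <- lapply(iso$geometry, function(g) {
      lapply(g, function(r) list(x = debias$cx + (r$x - debias$cx) * s,
                                 y = debias$cy + (r$y - debias$cy) * s))
    })
    iso$area <- iso$area * debias$f
  }
  if (!is.null(fit)) {
    nu <- 2 * fit$dof_area
    lo <- nu / stats::qchisq(0.975, nu)
    hi <- nu / stats::qchisq(0.025, nu)
    rows <- lapply(seq_len(nrow(iso)), function(i) {
      a <- iso$area[i]
      g <- iso$geometry[[i]]
      tibble::tibble(
        level = iso$level[i],
        what = c("estimate", "lci", "uci"),
        area = c(a, a * lo, a * hi),
        geometry = list(g, scale_poly(g, sqrt(lo)), scale_poly(g, sqrt(hi)))
      )
    })
    iso <- dplyr::bind_rows(rows)
  }
  new_hr_estimate(
    estimator = estimator, levels = levels, crs = trast$crs,
    data = if (keep_data) track else NULL,
    isopleths = iso,
    params = params,
    class2 = "hr_prob_estimate",
    extra = list(trast = trast, ud = ud, h = h, fit = fit)
  )
}

# scale a multipolygon about its bbox centre (used to draw CI bounds whose
# polygon area matches the area bound)
scale_poly <- function(rings, f) {
  if (length(rings) == 0L) return(rings)
  bb <- poly_bbox(rings)
  cx <- mean(bb[c("xmin", "xmax")]); cy <- mean(bb[c("ymin", "ymax")])
  lapply(rings, function(r) list(x = cx + (r$x - cx) * f, y = cy + (r$y - cy) * f))
}

#' Kernel density estimate of the utilization distribution
#'
#' Classical KDE with the bivariate-normal reference ("ad hoc") bandwidth,
#' chosen to minimise the integrated mean squared error under the
#' assumption the data are normally distributed: per axis,
#' `h_i = sd_i * n^(-1/6)` (ML standard deviation). The UD is evaluated on
#' the template raster, normalised to total mass 1, and isopleths are
#' extracted by contouring the cumulative UD.
#'
#' @param track an `hr_track` in a projected CRS (n >= 5 for the reference
#'   bandwidth).
#' @param trast an `hr_trast`; defaults to [make_trast()] with an `"auto"`
#'   buffer.
#' @param h `"ref"` for the reference bandwidth, or a numeric bandwidth
#'   (length 1 or 2, metres per axis).
#' @param levels isopleth levels, fractions in (0, 1).
#' @param keep_data keep the source track on the estimate?
#' @return an `hr_estimate` of subclass `hr_prob_estimate`.
#' @export
hr_kde <- function(track, trast = NULL, h = "ref", levels = 0.95,
                   keep_data = TRUE) {
  check_track(track)
  levels <- check_levels(levels, allow_one = FALSE)
  if (is.null(trast)) trast <- make_trast(track)
  if (identical(h, "ref")) {
    h <- ref_bandwidth(track)
  } else {
    if (!is.numeric(h) || !length(h) %in% 1:2 || any(h <= 0)) {
      stop_domain("`h` must be \"ref\" or 1-2 positive numbers (m).")
    }
    h <- rep_len(as.numeric(h), 2L)
  }
  if (!trast_contains(trast, track$x, track$y)) {
    rlang::warn("Some fixes lie outside the template raster extent; mass will be truncated.")
  }
  ud_vals <- ud_from_kernels(track, trast, h[1], h[2])
  build_prob_estimate("kde", track, trast, ud_vals, h, levels, keep_data,
                      params = list(h = h))
}

#' Autocorrelated kernel density estimate (aKDE)
#'
#' KDE whose bandwidth uses the effective sample size implied by a fitted
#' continuous-time movement model: the reference rule with `n` replaced by
#' `dof_area`, `h^2 = sigma2_fit * dof_area^(-1/3)`, with the isotropic
#' model variance distributed across axes proportionally to the per-axis
#' sample (ML) variances so that an iid fit reduces exactly to [hr_kde()].
#' When the fit carries an error model (`uere`), the per-fix per-axis error
#' variance `(uere * hdop)^2 / 2` is added to the squared bandwidth
#' fix-wise.
#'
#' Because the kernel convolution inflates the UD variance by `h_i^2` per
#' axis, the reported isopleths carry a first-order area debias: polygons
#' are shrunk about the UD centre so areas scale by
#' `sqrt(prod_i s_i^2 / (s_i^2 + mean(h_i^2)))`, the standard
#' area-debiased aKDE correction. (Without it, areas at small effective
#' sample sizes are biased upward by roughly `1 + dof_area^(-1/3)`.)
#'
#' Per-level area confidence intervals come from a chi-squared sampling
#' model for the variance: `bound = area * nu / qchisq(q, nu)` with
#' `nu = 2 * dof_area` and `q = 0.975` (lci) / `0.025` (uci).
#'
#' @param track the `hr_track` the model was fitted to.
#' @param fit an `hr_ctmm` fit produced from the same track.
#' @param trast an `hr_trast`; defaults to [make_trast()].
#' @param levels isopleth levels, fractions in (0, 1).
#' @param keep_data keep the source track on the estimate?
#' @return an `hr_estimate` of subclass `hr_prob_estimate` with
#'   `what = "lci"/"uci"` rows in its area table.
#' @export
hr_akde <- function(track, fit, trast = NULL, levels = 0.95, keep_data = TRUE) {
  check_track(track)
  levels <- check_levels(levels, allow_one = FALSE)
  stopifnot(inherits(fit, "hr_ctmm"))
  if (fit$n != nrow(track)) {
    stop_domain("`fit` was produced from a track of different length.")
  }
  if (fit$dof_area <= 1) {
    stop_domain(paste0(
      "Effective sample size (", format(fit$dof_area, digits = 3),
      ") is too small for aKDE; collect more data or use a longer sampling window."
    ))
  }
  if (is.null(trast)) trast <- make_trast(track)
  sx2 <- mean((track$x - mean(track$x))^2)
  sy2 <- mean((track$y - mean(track$y))^2)
  if (sx2 <= 0 || sy2 <= 0) stop_domain("Zero variance on an axis.")
  sbar2 <- (sx2 + sy2) / 2
  base2 <- fit$dof_area^(-1 / 3) * fit$sigma2 / sbar2
  hx2 <- sx2 * base2
  hy2 <- sy2 * base2
  err <- obs_error_variance(track, fit$uere)
  hx <- sqrt(hx2 + err)
  hy <- sqrt(hy2 + err)
  ud_vals <- ud_from_kernels(track, trast, hx, hy)
  estimator <- if (is.null(fit$uere)) "akde" else "akde_error"
  debias <- list(
    f = sqrt((sx2 / (sx2 + mean(hx^2))) * (sy2 / (sy2 + mean(hy^2)))),
    cx = mean(track$x), cy = mean(track$y)
  )
  build_prob_estimate(estimator, track, trast, ud_vals, c(sqrt(hx2), sqrt(hy2)),
                      levels, keep_data, fit = fit,
                      params = list(model = fit$model, uere = fit$uere,
                                    debias = debias$f),
                      debias = debias)
}
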