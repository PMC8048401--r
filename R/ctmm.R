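# Continuous-time movement models for range-resident animals, fitted by
# exact maximum likelihood:
#   iid : uncorrelated bivariate normal positions
#   ou  : Ornstein-Uhlenbeck position process (range residency with
#         positional autocorrelation timescale tau_pos)
#   ouf : OU-with-foraging, adding a velocity autocorrelation timescale
#         tau_vel < tau_pos (CAR(2) state space)
# Axes are independent and share parameters (isotropic covariance). GPS
# error enters as independent per-fix noise with per-axis variance
# (uere * hdop)^2 / 2, so uere is the 2-D RMS error per unit HDOP.

CTMM_MODELS <- c("iid", "ou", "ouf")

new_hr_ctmm <- function(model, mu, sigma2, tau_pos = NA_real_, tau_vel = NA_real_,
                        uere = NULL, loglik, n, dt_median, converged = TRUE) {
  k <- switch(model, iid = 3, ou = 4, ouf = 5)
  aicc <- if (n - k - 1 > 0) {
    -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  } else Inf  # small-sample correction undefined; never selected by "auto"
  fit <- structure(list(
    model = model, mu = mu, sigma2 = sigma2,
    tau_pos = tau_pos, tau_vel = tau_vel, uere = uere,
    loglik = loglik, aicc = aicc, n_par = k, n = n,
    dt_median = dt_median, converged = converged
  ), class = "hr_ctmm")
  fit$dof_area <- ctmm_dof_area(fit)
  fit
}

#' @export
print.hr_ctmm <- function(x, ...) {
  cat(sprintf("<hr_ctmm> model: %s\n", x$model))
  cat(sprintf("  sigma2: %.6g m^2", x$sigma2))
  if (!is.na(x$tau_pos)) cat(sprintf(", tau_pos: %.6g s", x$tau_pos))
  if (!is.na(x$tau_vel)) cat(sprintf(", tau_vel: %.6g s", x$tau_vel))
  cat("\n")
  if (!is.null(x$uere)) cat(sprintf("  uere: %.4g m per HDOP unit\n", x$uere))
  cat(sprintf("  loglik: %.4f, AICc: %.4f, n: %d, effective n (area): %.2f\n",
              x$loglik, x$aicc, x$n, x$dof_area))
  invisible(x)
}

#' Stationary position autocovariance of a movement model
#'
#' Per-axis autocovariance (m^2) at time lag `lag` (seconds):
#' `sigma2 * I(lag == 0)` for iid, `sigma2 * exp(-lag/tau_pos)` for OU, and
#' `sigma2 * (tau_pos * exp(-lag/tau_pos) - tau_vel * exp(-lag/tau_vel)) /
#' (tau_pos - tau_vel)` for OUF.
#'
#' @param fit an `hr_ctmm` fit, or a list with fields `model`, `sigma2`,
#'   `tau_pos`, `tau_vel`.
#' @param lag numeric vector of non-negative lags in seconds.
#' @return numeric vector of autocovariances.
#' @export
position_acf <- function(fit, lag) {
  if (any(lag < 0)) stop_domain("`lag` must be >= 0.")
  switch(fit$model,
    iid = fit$sigma2 * as.numeric(lag == 0),
    ou = fit$sigma2 * exp(-lag / fit$tau_pos),
    ouf = {
      if (!is.na(fit$tau_vel) && fit$tau_vel >= fit$tau_pos) {
        stop_domain("OUF requires tau_vel < tau_pos (degenerate parameters).")
      }
      fit$sigma2 * (fit$tau_pos * exp(-lag / fit$tau_pos) -
                      fit$tau_vel * exp(-lag / fit$tau_vel)) /
        (fit$tau_pos - fit$tau_vel)
    },
    stop_domain(sprintf("Unknown model '%s'.", fit$model))
  )
}

obs_error_variance <- function(track, uere) {
  n <- nrow(track)
  if (is.null(uere) || uere == 0) return(rep(0, n))
  hdop <- if ("hdop" %in% names(track)) {
    h <- track$hdop
    h[is.na(h)] <- 1
    h
  } else rep(1, n)
  (uere * hdop)^2 / 2
}

#' Exact Gaussian log-likelihood of a track under a movement model
#'
#' Evaluates the log-density of the observed positions under the
#' stationary process plus independent per-fix measurement error, in O(n)
#' per axis by Kalman filtering (axes independent, shared parameters).
#'
#' @param track an `hr_track`.
#' @param model `"iid"`, `"ou"` or `"ouf"`.
#' @param mu length-2 stationary mean (m); defaults to the sample mean.
#' @param sigma2 stationary per-axis positional variance (m^2).
#' @param tau_pos positional autocorrelation timescale (s; OU/OUF).
#' @param tau_vel velocity autocorrelation timescale (s; OUF only,
#'   `tau_vel < tau_pos`).
#' @param uere optional error scale (m of 2-D RMS error per HDOP unit);
#'   fixes without HDOP get HDOP = 1.
#' @return the log-likelihood (scalar; `-Inf` for degenerate parameters).
#' @export
ctmm_loglik <- function(track, model, mu = NULL, sigma2, tau_pos = NULL,
                        tau_vel = NULL, uere = NULL) {
  check_track(track)
  model <- match.arg(model, CTMM_MODELS)
  if (is.null(mu)) mu <- c(mean(track$x), mean(track$y))
  if (!is_scalar_number(sigma2) || sigma2 <= 0) return(-Inf)
  R <- obs_error_variance(track, uere)
  tt <- as.numeric(track$t)
  dt <- diff(tt)
  ll_axis <- function(y, m) {
    switch(model,
      iid = sum(stats::dnorm(y, m, sqrt(sigma2 + R), log = TRUE)),
      ou = {
        if (!is_scalar_number(tau_pos) || tau_pos <= 0) return(-Inf)
        kalman_ou_loglik(y, dt, m, sigma2, tau_pos, R)
      },
      ouf = {
        if (!is_scalar_number(tau_pos) || tau_pos <= 0) return(-Inf)
        if (!is_scalar_number(tau_vel) || tau_vel <= 0) return(-Inf)
        if (tau_vel >= tau_pos) {
          stop_domain("OUF requires tau_vel < tau_pos (degenerate parameters).")
        }
        kalman_ouf_loglik(y, dt, m, sigma2, tau_pos, tau_vel, R)
      }
    )
  }
  ll <- ll_axis(track$x, mu[1]) + ll_axis(track$y, mu[2])
  if (!is.finite(ll)) return(-Inf)
  ll
}

#' Empirical semivariogram of a track
#'
#' Semivariance of positional displacement per lag bin, averaged over the
#' two axes; used to initialise movement-model fits (sill -> sigma2, lag
#' at 63% of the sill -> tau_pos).
#'
#' @param track an `hr_track` with at least 2 fixes.
#' @param n_lags number of equal-width lag bins spanning the observed lag
#'   range.
#' @param max_pairs cap on the number of fixes entering the all-pairs
#'   computation (larger tracks are thinned evenly first).
#' @param max_lag drop pairs further apart in time than this (s); `NULL`
#'   keeps the full observed lag range.
#' @return a tibble with columns `lag` (s, bin midpoint), `semivariance`
#'   (m^2) and `n_pairs`.
#' @export
empirical_variogram <- function(track, n_lags = 20, max_pairs = 1500,
                                max_lag = NULL) {
  check_track(track, require_projected = FALSE)
  n <- nrow(track)
  if (n < 2L) stop_domain("Variogram needs at least 2 fixes.")
  if (n > max_pairs) {
    track <- track_subset(track, unique(round(seq(1, n, length.out = max_pairs))))
    n <- nrow(track)
  }
  tt <- as.numeric(track$t)
  ij <- utils::combn(n, 2L)
  lag <- tt[ij[2L, ]] - tt[ij[1L, ]]
  sv <- 0.25 * ((track$x[ij[2L, ]] - track$x[ij[1L, ]])^2 +
                  (track$y[ij[2L, ]] - track$y[ij[1L, ]])^2)
  if (!is.null(max_lag)) {
    keep <- lag <= max_lag
    if (!any(keep)) stop_domain("`max_lag` excludes every pair of fixes.")
    lag <- lag[keep]
    sv <- sv[keep]
  }
  n_lags <- min(n_lags, length(unique(lag)))
  breaks <- seq(min(lag), max(lag), length.out = n_lags + 1L)
  bin <- findInterval(lag, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tibble::tibble(
    lag = tapply(lag, bin, mean),
    semivariance = tapply(sv, bin, mean),
    n_pairs = as.integer(table(bin))
  )
}

variogram_init <- function(track) {
  vg <- tryCatch(empirical_variogram(track), error = function(e) NULL)
  s2_fallback <- (stats::var(track$x) * (nrow(track) - 1) +
                    stats::var(track$y) * (nrow(track) - 1)) / (2 * nrow(track))
  dtm <- stats::median(diff(as.numeric(track$t)))
  if (is.null(vg) || nrow(vg) < 3L) {
    return(list(sigma2 = max(s2_fallback, 1e-12), tau = max(dtm * 5, 1)))
  }
  sill <- mean(utils::tail(vg$semivariance, max(2L, floor(nrow(vg) / 4))))
  sill <- max(sill, 1e-12)
  i63 <- which(vg$semivariance >= 0.632 * sill)[1L]
  tau <- if (is.na(i63)) dtm * 5 else max(vg$lag[i63], dtm / 2)
  list(sigma2 = sill, tau = tau)
}

ctmm_dof_area <- function(fit) {
  n <- fit$n
  if (fit$model == "iid") return(n)
  dt <- fit$dt_median
  rho <- position_acf(fit, (1:(n - 1)) * dt) / fit$sigma2
  keep <- rho >= 1e-3
  if (any(keep)) {
    kmax <- max(which(keep))
    k <- seq_len(kmax)
    denom <- 1 + 2 * sum((1 - k / n) * rho[k])
  } else {
    denom <- 1
  }
  max(min(n / denom, n), 1e-9)
}

fit_iid <- function(track, uere) {
  n <- nrow(track)
  mu <- c(mean(track$x), mean(track$y))
  R <- obs_error_variance(track, uere)
  if (all(R == 0)) {
    s2 <- (sum((track$x - mu[1])^2) + sum((track$y - mu[2])^2)) / (2 * n)
    ll <- ctmm_loglik(track, "iid", mu = mu, sigma2 = s2, uere = uere)
  } else {
    s2_0 <- (sum((track$x - mu[1])^2) + sum((track$y - mu[2])^2)) / (2 * n)
    opt <- stats::optimize(
      function(ls) -ctmm_loglik(track, "iid", mu = mu, sigma2 = exp(ls), uere = uere),
      interval = log(s2_0) + c(-10, 5)
    )
    s2 <- exp(opt$minimum)
    ll <- -opt$objective
  }
  new_hr_ctmm("iid", mu = mu, sigma2 = s2, uere = uere, loglik = ll, n = n,
              dt_median = stats::median(diff(as.numeric(track$t))))
}

fit_corr <- function(track, model, uere) {
  n <- nrow(track)
  mu <- c(mean(track$x), mean(track$y))
  init <- variogram_init(track)
  nll <- function(par) {
    s2 <- exp(par[1]); tp <- exp(par[2])
    tv <- if (model == "ouf") exp(par[3]) else NULL
    if (model == "ouf" && tv >= tp) return(1e10)
    ll <- tryCatch(
      ctmm_loglik(track, model, mu = mu, sigma2 = s2, tau_pos = tp,
                  tau_vel = tv, uere = uere),
      error = function(e) -Inf
    )
    if (!is.finite(ll)) 1e10 else -ll
  }
  base <- c(log(init$sigma2), log(init$tau))
  starts <- list(base, base + c(0, log(0.1)), base + c(0, log(10)))
  if (model == "ouf") {
    starts <- lapply(starts, function(s) c(s, s[2] + log(0.1)))
  }
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, nll, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-8))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$convergence != 0) {
    rlang::abort("Movement-model optimizer did not converge.",
                 class = "hr_error_convergence",
                 best_par = exp(best$par), best_nll = best$value)
  }
  p <- exp(best$par)
  new_hr_ctmm(model, mu = mu, sigma2 = p[1], tau_pos = p[2],
              tau_vel = if (model == "ouf") p[3] else NA_real_,
              uere = uere, loglik = -best$value, n = n,
              dt_median = stats::median(diff(as.numeric(track$t))))
}

#' Fit a continuous-time movement model by maximum likelihood
#'
#' Parameters are optimised on the log scale (Nelder-Mead, three starts
#' seeded from the empirical variogram and its timescale scaled by 0.1 and
#' 10). `model = "auto"` fits iid, OU and OUF and returns the fit with the
#' lowest AICc. The stationary mean is profiled as the sample mean.
#'
#' The effective sample size for area estimation, `dof_area`, is computed
#' from the standard autocorrelation-inflation formula
#' `n / (1 + 2 * sum_k (1 - k/n) * rho(k * dt))` with `rho` the fitted
#' normalised position ACF, `dt` the median sampling interval, and the sum
#' truncated where `rho < 1e-3`. For an iid fit it equals `n` exactly.
#'
#' @param track an `hr_track` (n >= 5 for `"auto"`).
#' @param model `"auto"`, `"iid"`, `"ou"` or `"ouf"`.
#' @param uere optional fixed GPS-error scale (m of 2-D RMS error per unit
#'   HDOP); never estimated.
#' @return an `hr_ctmm` fit.
#' @export
fit_ctmm <- function(track, model = "auto", uere = NULL) {
  check_track(track)
  model <- match.arg(model, c("auto", CTMM_MODELS))
  n <- nrow(track)
  if (model == "auto" && n < 5L) stop_domain("`model = \"auto\"` needs n >= 5.")
  if (model == "ou" && n < 2L) stop_domain("OU needs n >= 2.")
  if (model == "ouf" && n < 4L) stop_domain("OUF needs n >= 4.")
  if (!is.null(uere) && (!is_scalar_number(uere) || uere < 0)) {
    stop_domain("`uere` must be a single non-negative number.")
  }
  if (!is.null(uere) && uere == 0) uere <- NULL
  if (model != "auto") {
    return(if (model == "iid") fit_iid(track, uere) else fit_corr(track, model, uere))
  }
  fits <- list(fit_iid(track, uere))
  fits <- c(fits, list(fit_corr(track, "ou", uere)))
  if (n >= 7L) fits <- c(fits, list(fit_corr(track, "ouf", uere)))
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  fits[[which.min(aiccs)]]
}

#' Serialize a movement-model fit to JSON
#'
#' @param fit an `hr_ctmm` fit.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
ctmm_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "hr_ctmm"))
  obj <- list(
    model = fit$model,
    mu_m = fit$mu,
    sigma2_m2 = fit$sigma2,
    tau_pos_s = if (is.na(fit$tau_pos)) NULL else fit$tau_pos,
    tau_vel_s = if (is.na(fit$tau_vel)) NULL else fit$tau_vel,
    uere_m_per_hdop = fit$uere,
    loglik = fit$loglik,
    aicc = fit$aicc,
    dof_area = fit$dof_area,
    n = fit$n
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
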