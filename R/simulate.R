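# Simulators: exact stationary sampling of the three movement models,
# GPS-error injection, toy landscapes, and a no-download multi-animal
# fixture suite. All randomness flows through one seeded generator per
# call; the caller's RNG stream is left untouched.

#' Simulate a relocation track from a movement model
#'
#' Exact stationary sampling (no discretisation error): iid draws
#' independent bivariate normals; OU uses the exact AR(1) transition
#' `x[k+1] = mu + phi (x[k] - mu) + e`, `phi = exp(-dt/tau_pos)`,
#' `e ~ N(0, sigma2 (1 - phi^2))`, started from the stationary law; OUF
#' uses the exact discretisation of the position-velocity state space,
#' with position ACF matching [position_acf()]. Optional GPS error adds
#' per-axis `N(0, (uere * hdop)^2 / 2)` noise, with per-fix HDOP drawn
#' from `hdop_law`.
#'
#' @param model `"iid"`, `"ou"` or `"ouf"`.
#' @param n number of fixes.
#' @param dt sampling interval (s); scalar or length `n - 1`.
#' @param mu stationary mean, length 2 (m).
#' @param sigma2 stationary per-axis positional variance (m^2).
#' @param tau_pos,tau_vel autocorrelation timescales (s); `tau_vel` only
#'   for OUF and must be `< tau_pos`.
#' @param uere GPS-error scale (m of 2-D RMS error per unit HDOP); 0
#'   disables error injection entirely.
#' @param hdop_law `"constant"` (HDOP = `hdop_const`) or `"lognormal"`
#'   (meanlog `hdop_meanlog`, sdlog `hdop_sdlog`).
#' @param hdop_const,hdop_meanlog,hdop_sdlog HDOP-law parameters.
#' @param t0 timestamp of the first fix.
#' @param crs EPSG code to stamp on the track.
#' @param id id label column value.
#' @param seed RNG seed (required for reproducibility).
#' @return an `hr_track` with an `hdop` column when `uere > 0`.
#' @export
simulate_track <- function(model = c("ou", "iid", "ouf"), n, dt = 3600,
                           mu = c(0, 0), sigma2 = 1e6,
                           tau_pos = 3600, tau_vel = 360,
                           uere = 0, hdop_law = c("constant", "lognormal"),
                           hdop_const = 1, hdop_meanlog = log(2), hdop_sdlog = 0.5,
                           t0 = as.POSIXct("2011-01-01 00:00:00", tz = "UTC"),
                           crs = 5070, id = "S1", seed = 1) {
  model <- match.arg(model)
  hdop_law <- match.arg(hdop_law)
  if (!is_scalar_number(n) || n < 1) stop_domain("`n` must be a positive count.")
  n <- as.integer(n)
  if (!is_scalar_number(sigma2) || sigma2 <= 0) stop_domain("`sigma2` must be > 0.")
  if (model != "iid") {
    if (!is_scalar_number(tau_pos) || tau_pos <= 0) stop_domain("`tau_pos` must be > 0.")
  }
  if (model == "ouf" && !(is_scalar_number(tau_vel) && tau_vel > 0 && tau_vel < tau_pos)) {
    stop_domain("OUF requires 0 < tau_vel < tau_pos.")
  }
  dt <- rep_len(as.numeric(dt), max(n - 1L, 1L))
  if (any(dt <= 0)) stop_domain("`dt` must be positive.")

  with_seed(seed, {
    xy <- switch(model,
      iid = list(x = mu[1] + sqrt(sigma2) * stats::rnorm(n),
                 y = mu[2] + sqrt(sigma2) * stats::rnorm(n)),
      ou = list(x = sim_ou_axis(stats::rnorm(n), dt, mu[1], sigma2, tau_pos),
                y = sim_ou_axis(stats::rnorm(n), dt, mu[2], sigma2, tau_pos)),
      ouf = list(
        x = sim_ouf_axis(stats::rnorm(n), stats::rnorm(n), dt, mu[1], sigma2,
                         tau_pos, tau_vel),
        y = sim_ouf_axis(stats::rnorm(n), stats::rnorm(n), dt, mu[2], sigma2,
                         tau_pos, tau_vel)
      )
    )
    df <- tibble::tibble(
      x = xy$x, y = xy$y,
      t = t0 + c(0, cumsum(dt))[seq_len(n)],
      id = id
    )
    if (uere > 0) {
      hdop <- switch(hdop_law,
        constant = rep(hdop_const, n),
        lognormal = stats::rlnorm(n, hdop_meanlog, hdop_sdlog)
      )
      sd_ax <- uere * hdop / sqrt(2)
      df$x <- df$x + stats::rnorm(n, 0, sd_ax)
      df$y <- df$y + stats::rnorm(n, 0, sd_ax)
      df$hdop <- hdop
    }
    new_track(df, crs = crs)
  })
}

#' Generate a toy binary landscape
#'
#' A thresholded smoothed white-noise field: the threshold is the empirical
#' quantile of the smoothed field, so the realised forest fraction matches
#' the target up to ties.
#'
#' @param xmin,xmax,ymin,ymax extent (m).
#' @param ncol number of columns (square cells; rows follow from extent).
#' @param forest_fraction target fraction of 1-cells, in `[0, 1]`.
#' @param patch_scale smoothing radius in cells (larger = blobbier).
#' @param crs EPSG code.
#' @param seed RNG seed.
#' @return a binary `hr_raster` (values 0/1).
#' @export
make_toy_landscape <- function(xmin, xmax, ymin, ymax, ncol = 100,
                               forest_fraction = 0.5, patch_scale = 5,
                               crs = 5070, seed = 1) {
  if (forest_fraction < 0 || forest_fraction > 1) {
    stop_domain("`forest_fraction` must be in [0, 1].")
  }
  cs <- (xmax - xmin) / ncol
  nrow <- max(2L, as.integer(ceiling((ymax - ymin) / cs - 1e-9)))
  ymax <- ymin + nrow * cs
  with_seed(seed, {
    z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
    if (patch_scale > 0) {
      k <- stats::dnorm(seq(-3, 3, length.out = 2 * patch_scale + 1))
      k <- k / sum(k)
      z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
      z <- t(apply(z, 1, function(row) stats::filter(row, k, circular = TRUE)))
    }
    thr <- stats::quantile(z, 1 - forest_fraction, type = 7)
    vals <- matrix(as.numeric(z >= thr), nrow, ncol)
    if (forest_fraction == 1) vals[] <- 1
    if (forest_fraction == 0) vals[] <- 0
    new_hr_raster(vals, xmin, xmax, ymin, ymax, crs = crs)
  })
}

#' Write a complete no-download fixture suite
#'
#' Simulates a 6-animal, 2-sex population (per-animal OU parameters drawn
#' from a seeded log-normal), hourly fixes over 10 weeks with lognormal
#' HDOP and GPS error, and writes it in both CSV dialects together with a
#' toy binary landscape covering the population extent.
#'
#' @param out_dir writable output directory (created if missing).
#' @param n_animals number of animals (first half female `F*`, rest male
#'   `M*`).
#' @param weeks tracking duration in weeks (hourly fixes).
#' @param uere GPS-error scale used for error injection.
#' @param crs projected EPSG code (must support inverse projection for the
#'   movebank dialect; default 5070).
#' @param seed RNG seed.
#' @return invisibly, a list with the file paths and the simulated
#'   parameter table.
#' @export
make_fixture_suite <- function(out_dir, n_animals = 6, weeks = 10,
                               uere = 1.67, crs = 5070, seed = 42) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_animals <- as.integer(n_animals)
  nfix <- as.integer(weeks * 7 * 24)
  params <- with_seed(seed, {
    tibble::tibble(
      id = paste0(rep(c("F", "M"), c(ceiling(n_animals / 2), floor(n_animals / 2))),
                  c(seq_len(ceiling(n_animals / 2)), seq_len(floor(n_animals / 2)))),
      sigma2 = stats::rlnorm(n_animals, log(1e6), 0.4),
      tau_pos = stats::rlnorm(n_animals, log(6 * 3600), 0.3),
      mu_x = 1.78e6 + stats::runif(n_animals, -2e4, 2e4),
      mu_y = 2.40e6 + stats::runif(n_animals, -2e4, 2e4),
      seed = seed + seq_len(n_animals)
    )
  })
  tracks <- lapply(seq_len(n_animals), function(i) {
    simulate_track("ou", n = nfix, dt = 3600, mu = c(params$mu_x[i], params$mu_y[i]),
                   sigma2 = params$sigma2[i], tau_pos = params$tau_pos[i],
                   uere = uere, hdop_law = "lognormal",
                   crs = crs, id = params$id[i], seed = params$seed[i])
  })
  all_df <- dplyr::bind_rows(lapply(tracks, tibble::as_tibble))
  all_trk <- new_track(all_df, crs = crs)
  p_generic <- file.path(out_dir, "tracks_generic.csv")
  p_movebank <- file.path(out_dir, "tracks_movebank.csv")
  p_land <- file.path(out_dir, "landscape.asc")
  write_tracks(all_trk, p_generic, dialect = "generic_csv")
  write_tracks(all_trk, p_movebank, dialect = "movebank_csv")
  pad <- 5000
  land <- make_toy_landscape(min(all_df$x) - pad, max(all_df$x) + pad,
                             min(all_df$y) - pad, max(all_df$y) + pad,
                             ncol = 150, forest_fraction = 0.5,
                             patch_scale = 4, crs = crs, seed = seed + 1000)
  write_asc(land, p_land)
  invisible(list(generic_csv = p_generic, movebank_csv = p_movebank,
                 landscape = p_land, params = params))
}
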