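# Grouped, many-instance workflows: estimate home ranges per group for a
# set of estimators and flatten everything into one tidy long-format
# table. Group-level failures (degenerate geometry, non-convergence) are
# recorded as error rows so one bad group never aborts a batch.

ESTIMATOR_LABELS <- c("hr_mcp", "hr_kde", "hr_locoh", "hr_akde", "hr_akde_error")

#' Default estimator roster
#'
#' The five standard estimator specifications: MCP, KDE, k-LoCoH with
#' `n = ceiling(sqrt(group size))`, aKDE with automatic model selection,
#' and aKDE with a fixed GPS-error scale.
#'
#' @param uere error scale for the `hr_akde_error` entry (m per HDOP unit).
#' @return a named list of estimator specs for [batch_home_ranges()].
#' @export
default_estimators <- function(uere = 1.67) {
  list(
    hr_mcp = list(),
    hr_kde = list(),
    hr_locoh = list(n = "auto"),
    hr_akde = list(model = "auto"),
    hr_akde_error = list(model = "auto", uere = uere)
  )
}

apply_estimator <- function(label, spec, track, levels) {
  switch(label,
    hr_mcp = hr_mcp(track, levels = levels, keep_data = FALSE),
    hr_kde = hr_kde(track, levels = levels, keep_data = FALSE),
    hr_locoh = hr_locoh(track, n = spec$n %||% "auto", levels = levels,
                        keep_data = FALSE),
    hr_akde = {
      fit <- fit_ctmm(track, model = spec$model %||% "auto")
      hr_akde(track, fit, levels = levels, keep_data = FALSE)
    },
    hr_akde_error = {
      fit <- fit_ctmm(track, model = spec$model %||% "auto",
                      uere = spec$uere %||% 1.67)
      hr_akde(track, fit, levels = levels, keep_data = FALSE)
    },
    stop_domain(sprintf(
      "Unknown estimator label '%s' (known: %s).", label,
      paste(ESTIMATOR_LABELS, collapse = ", ")
    ))
  )
}

#' Home ranges for every group and estimator, as one long table
#'
#' @param groups an `hr_grouped_tracks` from [group_tracks()].
#' @param estimators a named list of estimator specs (names from
#'   `hr_mcp`, `hr_kde`, `hr_locoh`, `hr_akde`, `hr_akde_error`; values are
#'   parameter lists). See [default_estimators()].
#' @param levels isopleth levels.
#' @return a tibble with the group key columns plus `estimator`, `level`,
#'   `what`, `area` and `error` (failure message, `NA` on success). One row
#'   per (group, estimator, level, what); failed combinations yield a
#'   single error row.
#' @export
batch_home_ranges <- function(groups, estimators = default_estimators(),
                              levels = 0.95) {
  stopifnot(inherits(groups, "hr_grouped_tracks"))
  bad <- setdiff(names(estimators), ESTIMATOR_LABELS)
  if (length(bad)) {
    stop_domain(sprintf("Unknown estimator label(s): %s", paste(bad, collapse = ", ")))
  }
  keys <- attr(groups, "keys")
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    key <- tibble::as_tibble(groups)[g, keys, drop = FALSE]
    trk <- groups$track[[g]]
    for (label in names(estimators)) {
      res <- tryCatch({
        est <- apply_estimator(label, estimators[[label]], trk, levels)
        at <- hr_area(est)
        at$error <- NA_character_
        at
      }, error = function(e) {
        tibble::tibble(level = NA_real_, what = "error", area = NA_real_,
                       error = conditionMessage(e))
      })
      res <- dplyr::bind_cols(key[rep(1L, nrow(res)), , drop = FALSE], res)
      res$estimator <- label
      rows <- c(rows, list(res))
    }
  }
  out <- dplyr::bind_rows(rows)
  out[, c(keys, "estimator", "level", "what", "area", "error")]
}

#' Sex differences in mean log home-range size
#'
#' Averages natural-log home-range areas per sex and estimator, with
#' two-sided 95% t-intervals (n - 1 df), and the male-minus-female
#' difference with a Welch two-sample t interval.
#'
#' @param result a [batch_home_ranges()] table with an `id` key.
#' @param sex_of named character vector mapping animal id to `"f"`/`"m"`
#'   (case-insensitive); ignored if `result` already has a `sex` column.
#' @param level which isopleth level to summarise (default: the only one
#'   present).
#' @return a list with `by_sex` (tibble: estimator, sex, n, mean_log_area,
#'   lci, uci) and `difference` (tibble: estimator, diff m - f, lci, uci).
#' @export
sex_difference_summary <- function(result, sex_of = NULL, level = NULL) {
  df <- result[result$what == "estimate" & is.na(result$error), , drop = FALSE]
  n_err <- sum(result$what == "error")
  if (n_err > 0) {
    rlang::inform(sprintf("Skipping %d error row(s) in the summary.", n_err))
  }
  if (!"sex" %in% names(df)) {
    if (is.null(sex_of)) stop_schema("No `sex` column and no `sex_of` mapping supplied.")
    df$sex <- unname(sex_of[as.character(df$id)])
  }
  df$sex <- tolower(as.character(df$sex))
  if (is.null(level)) {
    level <- unique(df$level)
    if (length(level) > 1L) stop_domain("Multiple levels present; pick one with `level`.")
  }
  df <- df[df$level == level, , drop = FALSE]
  df$log_area <- log(df$area)
  by_sex <- dplyr::bind_rows(lapply(split(df, list(df$estimator, df$sex), drop = TRUE),
    function(d) {
      m <- mean(d$log_area)
      n <- nrow(d)
      if (n >= 2L) {
        half <- stats::qt(0.975, n - 1) * stats::sd(d$log_area) / sqrt(n)
        ci <- c(m - half, m + half)
        flag <- NA_character_
      } else {
        ci <- c(NA_real_, NA_real_)
        flag <- "fewer than 2 animals; CI undefined"
      }
      tibble::tibble(estimator = d$estimator[1L], sex = d$sex[1L], n = n,
                     mean_log_area = m, lci = ci[1L], uci = ci[2L], flag = flag)
    }))
  diffs <- dplyr::bind_rows(lapply(split(df, df$estimator), function(d) {
    dm <- d$log_area[d$sex == "m"]
    dfem <- d$log_area[d$sex == "f"]
    if (length(dm) >= 2L && length(dfem) >= 2L) {
      est <- mean(dm) - mean(dfem)
      # Welch CI; degenerate (zero-variance) samples give a point interval
      ci <- tryCatch(stats::t.test(dm, dfem)$conf.int,
                     error = function(e) c(est, est))
      tibble::tibble(estimator = d$estimator[1L],
                     diff_m_minus_f = est,
                     lci = ci[1L], uci = ci[2L],
                     flag = NA_character_)
    } else {
      tibble::tibble(estimator = d$estimator[1L],
                     diff_m_minus_f = NA_real_, lci = NA_real_, uci = NA_real_,
                     flag = "a sex has fewer than 2 animals")
    }
  }))
  list(by_sex = by_sex, difference = diffs)
}

#' Mean land-cover value inside home-range isopleths
#'
#' Averages raster values over cells whose centres fall inside any polygon
#' of the feature set (all polygons pooled). With a binary forest raster
#' this is the proportion of forest inside the home range.
#'
#' @param isopleths an isopleth tibble ([hr_isopleths()]) or a single
#'   multipolygon geometry.
#' @param landcover an `hr_raster`.
#' @return the mean cell value, or `NA` (with a warning) when no cell
#'   centre falls inside.
#' @export
zonal_proportion <- function(isopleths, landcover) {
  stopifnot(inherits(landcover, "hr_raster"))
  rings <- if (is.data.frame(isopleths)) {
    do.call(c, isopleths$geometry)
  } else isopleths
  if (length(rings) == 0L) {
    rlang::warn("Empty geometry; proportion undefined.")
    return(NA_real_)
  }
  bb <- poly_bbox(rings)
  xs <- raster_xcenters(landcover)
  ys <- raster_ycenters(landcover)
  ci <- which(xs >= bb["xmin"] & xs <= bb["xmax"])
  ri <- which(ys >= bb["ymin"] & ys <= bb["ymax"])
  if (!length(ci) || !length(ri)) {
    rlang::warn("No raster cell centre inside the isopleths; proportion undefined.")
    return(NA_real_)
  }
  grid <- expand.grid(r = ri, c = ci)
  inside <- points_in_poly(xs[grid$c], ys[grid$r], rings)
  if (!any(inside)) {
    rlang::warn("No raster cell centre inside the isopleths; proportion undefined.")
    return(NA_real_)
  }
  vals <- landcover$values[cbind(grid$r[inside], grid$c[inside])]
  mean(vals, na.rm = TRUE)
}

#' Weekly home ranges per animal
#'
#' Groups fixes by `(id, week)` with weeks floored to their start
#' ([floor_week()]), drops weeks with fewer than `min_n` fixes (the
#' default keeps weeks with strictly more than 10 observations), and runs
#' [batch_home_ranges()].
#'
#' @param track an `hr_track` with an `id` column.
#' @param estimators estimator specs, as in [batch_home_ranges()].
#' @param levels isopleth levels.
#' @param min_n minimum number of fixes per (id, week) group.
#' @param week_start day the week starts on (1 = Monday).
#' @return a long-format tibble keyed by `id` and `week`.
#' @export
weekly_home_ranges <- function(track, estimators = default_estimators(),
                               levels = 0.95, min_n = 11L, week_start = 1) {
  check_track(track, require_projected = FALSE)
  if (!"id" %in% names(track)) stop_schema("Track needs an `id` column.")
  df <- tibble::as_tibble(track)
  df$week <- floor_week(df$t, week_start = week_start)
  trk <- new_track(df, crs = attr(track, "crs"))
  groups <- group_tracks(trk, by = c("id", "week"), min_n = min_n)
  batch_home_ranges(groups, estimators = estimators, levels = levels)
}

#' Write a batch result table as CSV
#'
#' @param result a [batch_home_ranges()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_batch_csv <- function(result, path) {
  out <- result
  names(out)[names(out) == "area"] <- "area_m2"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
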