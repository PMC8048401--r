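# a small multi-animal population used by several blocks; module-level so
# it is simulated once
batch_pop <- local({
  ids <- c("F1", "F2", "F3", "M1", "M2", "M3")
  dfs <- lapply(seq_along(ids), function(i) {
    trk <- simulate_track("ou", n = 60, dt = 3600,
                          mu = c(i * 1e4, -i * 1e4), sigma2 = 1e6,
                          tau_pos = 2 * 3600, uere = 1.5,
                          hdop_law = "lognormal", id = ids[i], seed = 500 + i)
    tibble::as_tibble(trk)
  })
  df <- dplyr::bind_rows(dfs)
  homerange:::new_track(df, crs = 5070)
})

test_that("batch_home_ranges flattens groups x estimators to a long table", {
  groups <- group_tracks(batch_pop, by = "id")
  expect_equal(nrow(groups), 6L)
  res <- batch_home_ranges(groups, estimators = default_estimators(uere = 1.67),
                           levels = 0.95)
  expect_equal(sum(res$what == "estimate"), 30L)  # 6 animals x 5 estimators
  expect_setequal(unique(res$estimator), names(default_estimators()))
  expect_true(all(is.na(res$error)))
  # aKDE rows carry confidence bounds, geometric rows do not
  expect_equal(sum(res$what %in% c("lci", "uci")), 2L * 2L * 6L)
})

test_that("single group and single estimator reduce to hr_area", {
  groups <- group_tracks(batch_pop, by = "id")
  one <- groups[1, ]
  class(one) <- class(groups)
  attr(one, "keys") <- attr(groups, "keys")
  res <- batch_home_ranges(one, estimators = list(hr_mcp = list()), levels = 0.95)
  direct <- hr_area(hr_mcp(one$track[[1]], levels = 0.95))
  expect_equal(res$area, direct$area)
  expect_equal(res$level, direct$level)
})

test_that("a degenerate group becomes an error row, not an abort", {
  t0 <- as.POSIXct("2011-01-01", tz = "UTC")
  good <- as.data.frame(tibble::as_tibble(batch_pop))
  line <- data.frame(x = 1:3, y = 2 * (1:3), t = t0 + 1:3, id = "L0",
                     hdop = 1)
  df <- dplyr::bind_rows(good[, names(line)], line)
  trk <- homerange:::new_track(df, crs = 5070)
  res <- batch_home_ranges(group_tracks(trk, by = "id"),
                           estimators = list(hr_mcp = list()), levels = 0.95)
  expect_equal(sum(res$what == "error"), 1L)
  expect_equal(res$id[res$what == "error"], "L0")
  expect_match(res$error[res$what == "error"], "[Dd]egenerate")
  expect_equal(sum(res$what == "estimate"), 6L)
  expect_error(batch_home_ranges(group_tracks(trk, by = "id"),
                                 estimators = list(hr_voronoi = list())),
               class = "hr_error_domain")
})

test_that("batch results are invariant to group order (up to row order)", {
  groups <- group_tracks(batch_pop, by = "id")
  rev_track <- homerange:::new_track(
    dplyr::arrange(tibble::as_tibble(batch_pop), dplyr::desc(id)), crs = 5070
  )
  g2 <- group_tracks(rev_track, by = "id")
  r1 <- batch_home_ranges(groups, estimators = list(hr_mcp = list()))
  r2 <- batch_home_ranges(g2, estimators = list(hr_mcp = list()))
  r1s <- r1[order(r1$id), ]
  r2s <- r2[order(r2$id), ]
  expect_equal(r1s$area, r2s$area)
})

test_that("sex differences summarise log areas with t-based intervals", {
  res <- batch_home_ranges(group_tracks(batch_pop, by = "id"),
                           estimators = list(hr_mcp = list()), levels = 0.95)
  sx <- substr(res$id, 1, 1)
  names(sx) <- res$id
  s <- sex_difference_summary(res, sex_of = sx)
  expect_equal(nrow(s$by_sex), 2L)
  expect_true(all(s$by_sex$lci <= s$by_sex$mean_log_area &
                    s$by_sex$mean_log_area <= s$by_sex$uci))
  expect_true(s$difference$lci <= s$difference$diff_m_minus_f &
                s$difference$diff_m_minus_f <= s$difference$uci)

  # identical areas in both sexes: difference exactly 0, CI contains 0
  fake <- tibble::tibble(id = c("F1", "F2", "M1", "M2"), estimator = "hr_mcp",
                         level = 0.95, what = "estimate", area = 100,
                         error = NA_character_)
  s0 <- sex_difference_summary(fake, sex_of = c(F1 = "f", F2 = "f",
                                                M1 = "m", M2 = "m"))
  expect_equal(s0$difference$diff_m_minus_f, 0)
  expect_true(s0$difference$lci <= 0 && s0$difference$uci >= 0)

  # constructed effect: males e times larger on the log scale
  set.seed(99)
  ar <- exp(log(1e6) + rnorm(40, sd = 0.1))
  fake2 <- tibble::tibble(
    id = paste0(rep(c("F", "M"), each = 20), 1:20),
    estimator = "hr_mcp", level = 0.95, what = "estimate",
    area = ar * rep(c(1, exp(1)), each = 20), error = NA_character_
  )
  sx2 <- setNames(substr(fake2$id, 1, 1), fake2$id)
  s2 <- sex_difference_summary(fake2, sex_of = sx2)
  expect_true(s2$difference$lci <= 1 && 1 <= s2$difference$uci)
  expect_equal(s2$difference$diff_m_minus_f, 1, tolerance = 0.15)

  # single-sex input is flagged
  s3 <- sex_difference_summary(fake[1:2, ], sex_of = c(F1 = "f", F2 = "f"))
  expect_true(!is.na(s3$difference$flag))
})

test_that("zonal_proportion averages raster cells inside the isopleths", {
  # all-forest raster
  all1 <- homerange:::new_hr_raster(matrix(1, 50, 50), 0, 100, 0, 100, crs = 5070)
  rect <- list(list(x = c(10, 90, 90, 10), y = c(10, 10, 90, 90)))
  expect_equal(zonal_proportion(rect, all1), 1)
  # vertical half-forest stripe; rectangle spans both halves equally
  half <- matrix(0, 50, 50); half[, 26:50] <- 1
  r2 <- homerange:::new_hr_raster(half, 0, 100, 0, 100, crs = 5070)
  sym <- list(list(x = c(20, 80, 80, 20), y = c(20, 20, 80, 80)))
  expect_equal(zonal_proportion(sym, r2), 0.5, tolerance = 1 / 30)
  # polygon entirely outside the raster
  out <- list(list(x = c(200, 300, 300, 200), y = c(200, 200, 300, 300)))
  expect_warning(v <- zonal_proportion(out, r2), "undefined")
  expect_true(is.na(v))
  # isopleth-tibble input pools all polygons
  trk <- toy_track(runif(30, 20, 80), runif(30, 20, 80))
  iso <- hr_isopleths(hr_mcp(trk, levels = 0.95))
  v2 <- zonal_proportion(iso, all1)
  expect_equal(v2, 1)
})

test_that("weekly grouping floors weeks and drops sparse ones strictly", {
  t0 <- as.POSIXct("2011-01-03 00:00:00", tz = "UTC")  # a Monday
  # 4 weeks at 20 fixes/week, then one week with exactly 10 fixes
  times <- c(outer(seq(0, 6.9 * 86400, length.out = 20), (0:3) * 7 * 86400, "+"))
  times <- c(times, 4 * 7 * 86400 + seq(0, 86400, length.out = 10))
  set.seed(3)
  df <- data.frame(x = rnorm(length(times), sd = 50),
                   y = rnorm(length(times), sd = 50),
                   t = t0 + sort(times), id = "A1")
  trk <- make_track(df, x, y, t, crs = 5070, id = id)
  res <- weekly_home_ranges(trk, estimators = list(hr_mcp = list()),
                            levels = c(0.5, 0.95))
  wk <- unique(res$week)
  expect_equal(length(wk), 4L)  # the 10-fix week is dropped (strict > 10)
  expect_true(all(format(wk, "%u") == "1"))  # all Mondays
  # per-week nesting in level
  for (w in wk) {
    sub <- res[res$week == w & res$what == "estimate", ]
    expect_lte(sub$area[sub$level == 0.5], sub$area[sub$level == 0.95])
  }
  # csv writer emits the documented header
  p <- withr::local_tempfile(fileext = ".csv")
  write_batch_csv(res, p)
  expect_match(readLines(p, n = 1L), "id,week,estimator,level,what,area_m2")
})
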