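test_that("make_trast applies the buffer and square-cell rules", {
  trk <- toy_track(c(0, 100, 50), c(0, 50, 25))
  tr <- make_trast(trk, buffer = "auto", ncol = 200)
  expect_equal(c(tr$xmin, tr$xmax), c(-50, 150))
  expect_equal(tr$ymin, -50)
  expect_gte(tr$ymax, 100)
  cs <- homerange:::trast_cellsize(tr)
  expect_equal(cs, 1)  # 200 m span / 200 cols
  expect_equal(tr$ymax - tr$ymin, tr$nrow * cs)

  one <- toy_track(c(10, 10.0001), c(20, 20.0001))
  tr1 <- make_trast(one, buffer = 100, ncol = 10)
  expect_equal(tr1$xmax - tr1$xmin, 200.0001, tolerance = 1e-6)

  single <- toy_track(5, 5)
  expect_error(make_trast(single, buffer = 0), class = "hr_error_domain")
})

test_that("UD mass is normalized, nonnegative, and peaks at the data", {
  trk <- simulate_track("ou", n = 150, dt = 600, sigma2 = 1e6, tau_pos = 3600,
                        seed = 41)
  k <- hr_kde(trk, trast = make_trast(trk, ncol = 120), levels = c(0.5, 0.95))
  ud <- hr_ud(k)
  expect_equal(sum(ud$values), 1, tolerance = 1e-6)
  expect_true(all(ud$values >= 0))

  # one fix: the UD peaks in that fix's cell and shifts with it
  one <- toy_track(c(0, 1), c(0, 1))
  tr <- make_trast(one, buffer = 10, ncol = 50)
  k1 <- hr_kde(one, trast = tr, h = c(1, 1), levels = 0.5)
  peak <- which(k1$ud$values == max(k1$ud$values), arr.ind = TRUE)
  xc <- homerange:::raster_xcenters(k1$ud)[peak[1, "col"]]
  yc <- homerange:::raster_ycenters(k1$ud)[peak[1, "row"]]
  expect_lt(abs(xc - 0.5), 1)  # mean of the two kernels
  shifted <- toy_track(c(0, 1) + 5, c(0, 1) + 3)
  k2 <- hr_kde(shifted, trast = make_trast(shifted, buffer = 10, ncol = 50),
               h = c(1, 1), levels = 0.5)
  peak2 <- which(k2$ud$values == max(k2$ud$values), arr.ind = TRUE)
  xc2 <- homerange:::raster_xcenters(k2$ud)[peak2[1, "col"]]
  yc2 <- homerange:::raster_ycenters(k2$ud)[peak2[1, "row"]]
  expect_equal(xc2 - xc, 5, tolerance = homerange:::raster_cellsize(k1$ud))
  expect_equal(yc2 - yc, 3, tolerance = homerange:::raster_cellsize(k1$ud))
})

test_that("cumulative UD ranks cells by density with ties sharing mass", {
  m <- matrix(c(0.4, 0.3, 0.2, 0.05, 0.05), 1)
  cud <- homerange:::cumulative_ud(m)
  expect_equal(as.vector(cud), c(0.4, 0.7, 0.9, 1.0, 1.0))
  # max-density cell's value is its own mass; the minimum nonzero is 1
  expect_equal(cud[which.max(m)], max(m))
  expect_equal(max(cud), 1)
  # the level mask is the smallest cell set holding the target mass
  set.seed(6)
  m5 <- matrix(runif(25), 5)
  m5 <- m5 / sum(m5)
  mask <- homerange:::ud_level_mask(m5, 0.95)
  expect_gte(sum(m5[mask]), 0.95)
  # brute-force: no smaller cell count reaches 0.95
  srt <- sort(as.vector(m5), decreasing = TRUE)
  k_min <- which(cumsum(srt) >= 0.95)[1]
  expect_equal(sum(mask), k_min)
  # and the cud surface agrees with the mask up to the crossing cell
  cud5 <- homerange:::cumulative_ud(m5)
  expect_lte(sum(cud5 <= 0.95), k_min)
  expect_gte(sum(cud5 <= 0.95), k_min - 1L)
})

test_that("KDE bandwidth follows the normal-reference rule and scales area", {
  trk <- simulate_track("iid", n = 200, sigma2 = 1e6, seed = 55)
  k <- hr_kde(trk, levels = 0.95)
  sx <- sqrt(mean((trk$x - mean(trk$x))^2))
  expect_equal(k$params$h[1], sx * 200^(-1 / 6))
  # area strictly increases with the bandwidth
  tr <- make_trast(trk, ncol = 150)
  a1 <- hr_area(hr_kde(trk, trast = tr, h = k$params$h, levels = 0.95))$area
  a2 <- hr_area(hr_kde(trk, trast = tr, h = 2 * k$params$h, levels = 0.95))$area
  expect_gt(a2, a1)
  # degenerate inputs
  flat <- toy_track(1:10, rep(0, 10))
  expect_error(hr_kde(flat), class = "hr_error_domain")
  expect_error(hr_kde(toy_track(1:4, c(2, 4, 3, 1))), class = "hr_error_domain")
  expect_error(hr_kde(trk, levels = 1), class = "hr_error_domain")
})

test_that("KDE recovers the bivariate-normal closed-form area", {
  trk <- simulate_track("iid", n = 4000, sigma2 = 1e6, seed = 58)
  a <- hr_area(hr_kde(trk, levels = 0.95))$area
  expect_lt(abs(a / (-2 * pi * 1e6 * log(0.05)) - 1), 0.1)
})

test_that("aKDE with an iid fit reduces to the KDE up to the area debias", {
  n <- 150
  trk <- simulate_track("iid", n = n, sigma2 = 1e6, seed = 60)
  tr <- make_trast(trk, ncol = 150)
  f <- fit_ctmm(trk, "iid")
  a_kde <- hr_area(hr_kde(trk, trast = tr, levels = 0.95))$area
  ak <- hr_akde(trk, f, trast = tr, levels = 0.95)
  a_akde <- hr_area(ak)
  # same UD and bandwidth (dof_area = n); areas differ only by the
  # deterministic kernel-inflation correction 1/(1 + n^(-1/3))
  expect_equal(ak$h, hr_kde(trk, trast = tr, levels = 0.95)$params$h,
               tolerance = 1e-12)
  expect_equal(a_akde$area[a_akde$what == "estimate"],
               a_kde / (1 + n^(-1 / 3)), tolerance = 1e-6)
  expect_equal(ak$estimator, "akde")
})

test_that("aKDE inflates bandwidth under autocorrelation and reports CIs", {
  trk <- simulate_track("ou", n = 400, dt = 600, sigma2 = 1e6, tau_pos = 3600,
                        seed = 61)
  tr <- make_trast(trk, ncol = 150)
  f <- fit_ctmm(trk, "ou")
  ak <- hr_akde(trk, f, trast = tr, levels = 0.95)
  at <- hr_area(ak)
  expect_setequal(at$what, c("estimate", "lci", "uci"))
  est <- at$area[at$what == "estimate"]
  expect_true(at$area[at$what == "lci"] <= est && est <= at$area[at$what == "uci"])
  # the chi-squared CI construction
  nu <- 2 * f$dof_area
  expect_equal(at$area[at$what == "lci"], est * nu / qchisq(0.975, nu))
  expect_equal(at$area[at$what == "uci"], est * nu / qchisq(0.025, nu))
  # autocorrelation inflates the aKDE bandwidth beyond the KDE bandwidth
  expect_true(all(ak$h > hr_kde(trk, trast = tr, levels = 0.95)$params$h))
  # isopleth features agree with the area table
  iso <- hr_isopleths(ak)
  expect_equal(sort(iso$area), sort(at$area))
  # refusal cases
  f_bad <- f; f_bad$dof_area <- 0.5
  expect_error(hr_akde(trk, f_bad, trast = tr), class = "hr_error_domain")
  f_short <- f; f_short$n <- 10L
  expect_error(hr_akde(trk, f_short, trast = tr), class = "hr_error_domain")
})

test_that("isopleths nest, are near-circular for a Gaussian, and match cell counts", {
  trk <- simulate_track("iid", n = 2000, sigma2 = 1e6, seed = 62)
  k <- hr_kde(trk, levels = c(0.5, 0.95))
  iso <- hr_isopleths(k)
  expect_true(all(diff(iso$area[order(iso$level)]) >= 0))
  # inner isopleth vertices lie inside the outer isopleth
  g50 <- iso$geometry[[which(iso$level == 0.5)]]
  g95 <- iso$geometry[[which(iso$level == 0.95)]]
  v <- g50[[1]]
  expect_true(mean(homerange:::points_in_poly(v$x, v$y, g95)) > 0.99)
  # isoperimetric ratio of the 95% contour
  r <- g95[[which.max(vapply(g95, function(q) abs(homerange:::ring_signed_area(q$x, q$y)), numeric(1)))]]
  A <- abs(homerange:::ring_signed_area(r$x, r$y))
  P <- sum(sqrt(diff(c(r$x, r$x[1]))^2 + diff(c(r$y, r$y[1]))^2))
  expect_gt(4 * pi * A / P^2, 0.95)
  # polygon area vs counting cells under the level
  cud <- hr_cud(k)
  cell_area <- homerange:::raster_cellsize(cud)^2
  a_cells <- sum(cud$values <= 0.95) * cell_area
  expect_lt(abs(iso$area[iso$level == 0.95] / a_cells - 1), 0.05)
  # re-contouring at new levels via ud_to_isopleths
  extra <- ud_to_isopleths(k, c(0.3, 0.7))
  expect_equal(extra$level, c(0.3, 0.7))
  expect_true(all(diff(extra$area) > 0))
})

test_that("probabilistic accessors refuse geometric estimates and vice versa", {
  trk <- toy_track(runif(20), runif(20))
  m <- hr_mcp(trk, levels = 0.95)
  expect_error(hr_ud(m), class = "hr_error_unsupported")
  expect_error(hr_cud(m), class = "hr_error_unsupported")
  expect_error(ud_to_isopleths(m, 0.5), class = "hr_error_unsupported")
})

test_that("an unreachable level yields an empty isopleth with a warning", {
  one <- toy_track(c(0, 1), c(0, 1))
  k <- hr_kde(one, trast = make_trast(one, buffer = 5, ncol = 20), h = c(5, 5),
              levels = 0.5)
  cud_min <- min(hr_cud(k)$values)
  expect_warning(iso <- ud_to_isopleths(k, cud_min / 2), "empty")
  expect_equal(iso$area, 0)
})
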