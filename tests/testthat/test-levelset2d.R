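test_that("state initialisation builds a signed distance and banded density", {
  fx <- disk_fixture(n = 81L, R0 = 2.0)
  st <- init_state(fx$mask, fx$dom)
  centre <- which.min(abs(fx$ax - fx$center))
  # distance at the centre approximates -R within a pixel diagonal
  expect_lt(abs(st$phi[centre, centre] + 2.0), sqrt(2) * 0.1 + 1e-9)
  expect_setequal(unique(as.numeric(st$u)), c(0, 0.16, 0.5))
  # contour length close to the circumference (radius-20-pixel disk)
  b <- extract_boundary(st)
  per <- sum(sqrt(rowSums((b - b[c(2:nrow(b), 1), ])^2)))
  expect_lt(abs(per / (2 * pi * 2.0) - 1), 0.05)
  expect_error(init_state(matrix(FALSE, 81, 81), fx$dom), "empty")
})

test_that("signed distance gradient is unit-magnitude away from the interface", {
  fx <- disk_fixture(n = 81L, R0 = 2.0)
  st <- init_state(fx$mask, fx$dom)
  n <- 81
  gx <- (st$phi[3:n, 2:(n - 1)] - st$phi[1:(n - 2), 2:(n - 1)]) / 0.2
  gy <- (st$phi[2:(n - 1), 3:n] - st$phi[2:(n - 1), 1:(n - 2)]) / 0.2
  gmag <- sqrt(gx^2 + gy^2)
  outside_band <- abs(st$phi[2:(n - 1), 2:(n - 1)]) > 0.2
  expect_lt(median(abs(gmag[outside_band] - 1)), 0.05)
})

test_that("interface velocity matches the exponential-profile closed form", {
  fx <- disk_fixture(n = 81L, R0 = 1.0)
  st <- init_state(fx$mask, fx$dom)
  k <- 2  # 1/mm
  r <- sqrt(outer((fx$ax - fx$center)^2, (fx$ax - fx$center)^2, "+"))
  st$u <- matrix(pmin(1, st$ubar * exp(-k * (r - 1.0))), 81, 81)
  v <- interface_velocity(st, 400)
  expected <- um2h_to_mm2h(400) * k
  band <- abs(st$phi) < 0.15
  expect_lt(abs(mean(v[band]) / expected - 1), 0.10)
  # linearity in D
  v2 <- interface_velocity(st, 800)
  expect_equal(v2[band], 2 * v[band], tolerance = 1e-12)
  # uniform density at the interface value gives zero speed
  st$u <- matrix(st$ubar, 81, 81)
  expect_equal(max(abs(interface_velocity(st, 400))), 0, tolerance = 1e-12)
})

test_that("a prescribed constant normal speed grows the disk linearly", {
  fx <- disk_fixture(n = 81L, R0 = 1.0)
  st <- init_state(fx$mask, fx$dom)
  v0 <- 0.002  # mm/h
  res <- evolve(st, list(D = 400, rho = 0.02), fx$dom, t_end = st$time + 500,
                speed_hook = function(s) matrix(v0, 81, 81))
  Rfin <- sqrt(polygon_area(extract_boundary(res$state)) / pi)
  expect_lt(abs(Rfin / (1.0 + v0 * 500) - 1), 0.03)
})

test_that("a zero normal speed leaves the interface stationary", {
  fx <- disk_fixture(n = 81L, R0 = 1.0)
  st <- init_state(fx$mask, fx$dom)
  a0 <- polygon_area(extract_boundary(st))
  res <- evolve(st, list(D = 400, rho = 0.02), fx$dom, t_end = st$time + 600,
                speed_hook = function(s) matrix(0, 81, 81), max_dt = 6)
  a1 <- polygon_area(extract_boundary(res$state))
  expect_lt(abs(a1 / a0 - 1), 0.005)
})

test_that("the full Stefan problem matches the 1D radial reference", {
  # three parameter magnitudes representative of the 2D fitted range
  cases <- list(c(463.09, 0.027164), c(2955.1, 0.011975), c(11120, 0.007827))
  fx <- disk_fixture(n = 121L, R0 = 1.0)
  for (cs in cases) {
    ref <- radial_stefan_reference(cs[1], cs[2], 1.0, 336)
    st <- init_state(fx$mask, fx$dom, time = 0)
    res <- evolve(st, list(D = cs[1], rho = cs[2]), fx$dom, t_end = 336)
    Rn <- sqrt(polygon_area(extract_boundary(res$state)) / pi)
    expect_lt(abs(Rn / ref - 1), 0.02)
  }
})

test_that("boundary extraction is accurate and translation-equivariant", {
  n <- 61L
  dom <- planar_domain(c(n, n), c(0.1, 0.1), matrix(TRUE, n, n))
  # axis-aligned rectangle
  rect <- matrix(FALSE, n, n); rect[16:45, 21:40] <- TRUE
  st <- init_state(rect, dom)
  b <- extract_boundary(st)
  per <- sum(sqrt(rowSums((b - b[c(2:nrow(b), 1), ])^2)))
  expect_lt(abs(per / (2 * (3.0 + 2.0)) - 1), 0.05)
  # disk area by the shoelace formula
  fx <- disk_fixture(n = 81L, R0 = 1.5)
  bd <- extract_boundary(init_state(fx$mask, fx$dom))
  expect_lt(abs(polygon_area(bd) / (pi * 1.5^2) - 1), 0.02)
  # translating phi translates the vertices
  st2 <- init_state(rect, dom)
  st2$phi <- st$phi + 0  # copy
  sh <- st
  sh$phi <- rbind(st$phi[n, , drop = FALSE], st$phi[-n, ])  # shift +1 pixel in x
  b2 <- extract_boundary(sh)
  ord <- order(atan2(b[, 2] - mean(b[, 2]), b[, 1] - mean(b[, 1])))
  ord2 <- order(atan2(b2[, 2] - mean(b2[, 2]), b2[, 1] - mean(b2[, 1])))
  expect_equal(mean(b2[, 1]) - mean(b[, 1]), 0.1, tolerance = 1e-9)
  expect_equal(mean(b2[, 2]) - mean(b[, 2]), 0, tolerance = 1e-9)
})

test_that("axis-wise constant diffusivity reproduces the scalar path", {
  fx <- disk_fixture(n = 61L, R0 = 0.8)
  st <- init_state(fx$mask, fx$dom, time = 0)
  r1 <- evolve(st, list(D = 500, rho = 0.02), fx$dom, t_end = 100)
  Dmat <- matrix(500, 61, 61)
  r2 <- evolve(st, list(D = 500, rho = 0.02), fx$dom, t_end = 100,
               Dfield = list(Dx = Dmat, Dy = Dmat))
  expect_lt(max(abs(r1$state$phi - r2$state$phi)), 1e-10)
  expect_lt(max(abs(r1$state$u - r2$state$u)), 1e-10)
})

test_that("the tumor never enters the ventricles, including after updates", {
  n <- 61L
  brain <- matrix(TRUE, n, n)
  vent <- matrix(FALSE, n, n); vent[38:42, 28:34] <- TRUE
  vent2 <- matrix(FALSE, n, n); vent2[36:40, 28:34] <- TRUE  # drifted variant
  dom <- planar_domain(c(n, n), c(0.1, 0.1), brain, vent,
                       updates = list("15" = list(ventricles = vent2)))
  ax <- (seq_len(n) - 0.5) * 0.1
  mask <- sqrt(outer((ax - 2.4)^2, (ax - 3.05)^2, "+")) <= 0.6
  mask <- mask & !vent
  st <- init_state(mask, dom, time = day_to_hours(11))
  res <- evolve(st, list(D = 600, rho = 0.025), dom,
                t_end = day_to_hours(18),
                record_times = day_to_hours(c(15, 18)))
  for (s in res$history) {
    inside <- s$phi < 0
    if (s$time >= day_to_hours(15)) expect_false(any(inside & vent2))
  }
})

test_that("the 2D fit is exact at truth and recovers the wave speed", {
  fx <- disk_fixture(n = 81L, R0 = 0.8)
  truth <- list(D = 500, rho = 0.02)
  days <- c(11, 15, 18, 22, 25)
  st0 <- init_state(fx$mask, fx$dom, time = day_to_hours(11))
  res <- evolve(st0, truth, fx$dom, day_to_hours(25),
                record_times = day_to_hours(days[-1]))
  states <- lapply(days[-1], function(d) res$history[[sprintf("t%g", day_to_hours(d))]])
  masks <- c(list(fx$mask), lapply(states, function(s) s$phi < 0))
  bnds <- suppressMessages(lapply(states, extract_boundary))
  series2d <- list(days = days, masks = masks, boundaries = bnds)
  # objective at the truth is exactly zero (shared forward code path)
  cfg_truth <- fit_config(guess = params(truth$D, truth$rho), max_evals = 50)
  fit0 <- suppressMessages(fit_levelset(series2d, fx$dom, cfg_truth))
  expect_identical(fit0$E2, 0)
  expect_identical(fit0$z_d, 0)
  # recovery from an off-truth guess
  cfg <- fit_config(guess = params(1200, 0.008), max_evals = 50)
  fit1 <- suppressMessages(fit_levelset(series2d, fx$dom, cfg))
  c_true <- wave_speed(params(truth$D, truth$rho))
  expect_lt(abs(wave_speed(fit1$params) / c_true - 1), 0.10)
  expect_lte(fit1$E2, suppressMessages(fit_levelset(series2d, fx$dom,
    fit_config(guess = params(1200, 0.008), max_evals = 1)))$E2)
})

test_that("an isotropic fit cannot match an anisotropic-truth phantom exactly", {
  n <- 71L
  dom <- planar_domain(c(n, n), c(0.1, 0.1), matrix(TRUE, n, n))
  ax <- (seq_len(n) - 0.5) * 0.1
  mask <- sqrt(outer((ax - 3.55)^2, (ax - 3.55)^2, "+")) <= 0.7
  # strongly anisotropic truth: fast in x, slow in y
  Dx <- matrix(1200, n, n); Dy <- matrix(200, n, n)
  truth_rho <- 0.02
  days <- c(11, 15, 18, 22)
  st0 <- init_state(mask, dom, time = day_to_hours(11))
  res <- evolve(st0, list(D = NA, rho = truth_rho), dom, day_to_hours(22),
                Dfield = list(Dx = Dx, Dy = Dy),
                record_times = day_to_hours(days[-1]))
  states <- lapply(days[-1], function(d) res$history[[sprintf("t%g", day_to_hours(d))]])
  series2d <- list(days = days, masks = c(list(mask), lapply(states, function(s) s$phi < 0)),
                   boundaries = suppressMessages(lapply(states, extract_boundary)))
  # anisotropic-truth E2 is zero by construction; the best isotropic E2 is not
  iso <- suppressMessages(fit_levelset(series2d, dom,
                                       fit_config(guess = params(500, 0.02),
                                                  max_evals = 40)))
  expect_gt(iso$E2, 0.5)
})
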