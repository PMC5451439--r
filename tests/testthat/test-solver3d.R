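flat_geom <- function(shape = c(8, 8, 4), spacing = c(0.1, 0.1, 0.5)) {
  g <- grid3d(shape, spacing)
  brain_geometry(g, array(TRUE, dim = g$shape))
}

test_that("reaction-diffusion rate vanishes at the equilibria", {
  geom <- flat_geom()
  p <- params(413.77, 0.0188)
  f0 <- density_field(geom, array(0, dim = geom$grid$shape), 0)
  expect_true(all(reaction_diffusion_rhs(f0, p) == 0))
  f1 <- density_field(geom, array(1, dim = geom$grid$shape), 0)
  expect_equal(max(abs(reaction_diffusion_rhs(f1, p))), 0, tolerance = 1e-14)
})

test_that("flux-form divergence conserves mass exactly when rho = 0", {
  g <- grid3d(c(9, 7, 5), c(0.1, 0.2, 0.5))
  set.seed(3)
  brain <- array(runif(prod(g$shape)) > 0.25, dim = g$shape)
  brain[5, 4, 3] <- TRUE
  geom <- brain_geometry(g, brain)
  vals <- array(0, dim = g$shape)
  vals[geom$domain_mask] <- runif(sum(geom$domain_mask))
  f <- density_field(geom, vals, 0)
  rate <- reaction_diffusion_rhs(f, list(D = 700, rho = 0))
  total <- sum(rate) * voxel_volume(g)
  expect_lt(abs(total) / sum(abs(rate) * voxel_volume(g)), 1e-12)
})

test_that("rhs on a quasi-1D domain matches a dense-operator oracle", {
  n <- 24L
  g <- grid3d(c(n, 1, 1), c(0.1, 0.1, 0.1))
  geom <- brain_geometry(g, array(TRUE, dim = g$shape))
  D_um <- 500; Dmm <- um2h_to_mm2h(D_um); h <- 0.1
  # dense 1D no-flux Laplacian built explicitly
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) { L[i, i - 1] <- Dmm / h^2; L[i, i] <- L[i, i] - Dmm / h^2 }
    if (i < n) { L[i, i + 1] <- Dmm / h^2; L[i, i] <- L[i, i] - Dmm / h^2 }
  }
  u <- sin(seq(0, pi, length.out = n)) * 0.8
  vals <- array(u, dim = g$shape)
  f <- density_field(geom, vals, 0)
  rho <- 0.02
  expected <- as.numeric(L %*% u) + rho * u * (1 - u)
  got <- reaction_diffusion_rhs(f, list(D = D_um, rho = rho))[, 1, 1]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("integration reproduces the logistic closed form for uniform fields", {
  geom <- flat_geom()
  u0 <- 0.5; rho <- 0.02; t1 <- 150
  f <- density_field(geom, array(u0, dim = geom$grid$shape), 0)
  out <- integrate_density(f, list(D = 900, rho = rho), t1)[[1]]
  exact <- u0 * exp(rho * t1) / (1 + u0 * (exp(rho * t1) - 1))
  expect_lt(max(abs(out$values - exact)), 1e-4)
  expect_equal(out$time, t1)
})

test_that("pure diffusion conserves mass over 336 h and zero stays zero", {
  g <- grid3d(c(10, 10, 6), c(0.1, 0.1, 0.5))
  set.seed(5)
  brain <- array(runif(prod(g$shape)) > 0.2, dim = g$shape)
  brain[5, 5, 3] <- TRUE
  geom <- brain_geometry(g, brain)
  vals <- array(0, dim = g$shape)
  vals[geom$domain_mask] <- runif(sum(geom$domain_mask))
  f <- density_field(geom, vals, 0)
  out <- integrate_density(f, list(D = 413.77, rho = 0), 336)[[1]]
  expect_lt(abs(sum(out$values) - sum(vals)) / sum(vals), 1e-6)
  f0 <- density_field(geom, array(0, dim = g$shape), 0)
  out0 <- integrate_density(f0, params(413.77, 0.0188), 336)[[1]]
  expect_true(all(out0$values == 0))
})

test_that("integrator agrees with an independent adaptive RK45 (deSolve)", {
  g <- grid3d(c(10, 9, 4), c(0.1, 0.1, 0.5))
  set.seed(42)
  brain <- array(runif(prod(g$shape)) > 0.2, dim = g$shape)
  brain[5, 5, 2] <- TRUE
  geom <- brain_geometry(g, brain)
  st <- domain_stencil(geom)
  u0 <- array(0, dim = g$shape)
  u0[geom$domain_mask] <- runif(sum(geom$domain_mask), 0, 0.6)
  f <- density_field(geom, u0, 0)
  p <- list(D = 600, rho = 0.03)
  ours <- integrate_density(f, p, 96, solver_config(), st)[[1]]$values[st$idx]
  rhs_r <- function(t, y, parms) {
    a <- array(0, dim = g$shape); a[st$idx] <- y
    ff <- structure(list(geometry = geom, values = a, time = t),
                    class = "density_field")
    list(reaction_diffusion_rhs(ff, p, st)[st$idx])
  }
  ref <- deSolve::ode(y = u0[st$idx], times = c(0, 96), func = rhs_r,
                      parms = NULL, method = deSolve::rkMethod("rk45dp7"),
                      rtol = 1e-8, atol = 1e-10)
  expect_lt(max(abs(ours - ref[2, -1])), 1e-4)
})

test_that("thresholding is inclusive and restricted to the domain", {
  geom <- flat_geom()
  vals <- array(0, dim = geom$grid$shape)
  vals[2, 2, 2] <- 0.16       # exactly at threshold: included
  vals[3, 3, 3] <- 0.1599
  f <- density_field(geom, vals, 0)
  m <- threshold_to_mask(f, 0.16)
  expect_true(m[2, 2, 2]); expect_false(m[3, 3, 3])
  expect_equal(sum(m), 1L)
  f0 <- density_field(geom, array(0, dim = geom$grid$shape), 0)
  expect_equal(sum(threshold_to_mask(f0)), 0L)
  fu <- density_field(geom, array(0.5, dim = geom$grid$shape), 0)
  expect_identical(threshold_to_mask(fu, 0.16), geom$domain_mask)
  expect_error(threshold_to_mask(fu, 1.2), "\\(0, 1\\)")
})

test_that("integration rejects non-increasing output times", {
  geom <- flat_geom()
  f <- density_field(geom, array(0.2, dim = geom$grid$shape), 100)
  expect_error(integrate_density(f, params(400, 0.02), 50), "exceed")
})

test_that("measured front speed scales as 2 sqrt(D rho)", {
  r1 <- measure_front_speed(params(413.77, 0.0188))
  expect_lt(abs(r1$speed_umh / 5.5781 - 1), 0.05)
  r4 <- measure_front_speed(params(4 * 413.77, 0.0188), channel_length_mm = 38)
  expect_lt(abs(r4$speed_umh / r1$speed_umh - 2), 2 * 0.03)
})

test_that("without proliferation the threshold contour does not propagate", {
  # pure-diffusion control: seeded mass below the threshold-equilibrium level,
  # measured over the late window where the contour position has flattened
  r0 <- measure_front_speed(list(D = 413.77, rho = 0), channel_length_mm = 40,
                            t_end_h = 1.5e5, transient_frac = 0.4,
                            seed_length_mm = 5)
  expect_lt(abs(r0$speed_umh), 0.05)
})

test_that("halving the in-plane spacing barely changes the day-25 volume", {
  sp1 <- phantom_spec()
  v1 <- visible_volume(simulate_ground_truth(sp1)$series$masks[[5]], sp1$grid)
  sp2 <- phantom_spec(grid = grid3d(c(112, 112, 18), c(0.05, 0.05, 0.5)))
  v2 <- visible_volume(simulate_ground_truth(sp2)$series$masks[[5]], sp2$grid)
  expect_lt(abs(v2 / v1 - 1), 0.05)
})
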