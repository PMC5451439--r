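test_that("phantom brain volume matches the analytic ellipsoid volume", {
  sp <- phantom_spec(grid = grid3d(c(110, 170, 20)),
                     brain_center = c(5.5, 8.5, 5.0),
                     brain_semiaxes = c(5, 8, 4),
                     ventricles = list(), seed_center = c(5.5, 8.5, 5.0))
  geom <- make_brain_phantom(sp)
  expect_equal(sum(geom$ventricle_mask), 0L)
  expect_identical(geom$domain_mask, geom$brain_mask)
  v_analytic <- 4 / 3 * pi * 5 * 8 * 4
  v_voxel <- sum(geom$brain_mask) * voxel_volume(sp$grid)
  expect_lt(abs(v_voxel / v_analytic - 1), 0.03)
})

test_that("mirrored phantom specs produce x-reflected geometry", {
  g <- grid3d(c(40, 40, 12))
  extent <- g$shape * g$spacing
  mk <- function(cx_brain, cx_vent, cx_seed) {
    phantom_spec(grid = g, brain_center = c(cx_brain, 2.0, 3.0),
                 brain_semiaxes = c(1.5, 1.5, 2.5),
                 ventricles = list(list(center = c(cx_vent, 2.0, 3.0),
                                        semiaxes = c(0.2, 0.4, 0.8))),
                 seed_center = c(cx_seed, 2.0, 3.0), seed_radius = 0.4)
  }
  spL <- mk(1.7, 1.2, 2.2)
  spR <- mk(extent[1] - 1.7, extent[1] - 1.2, extent[1] - 2.2)
  gL <- make_brain_phantom(spL)
  gR <- make_brain_phantom(spR)
  flip <- function(m) m[rev(seq_len(dim(m)[1])), , ]
  expect_identical(gR$brain_mask, flip(gL$brain_mask))
  expect_identical(gR$ventricle_mask, flip(gL$ventricle_mask))
})

test_that("ventricles outside the brain are rejected", {
  g <- grid3d(c(40, 40, 12))
  sp <- phantom_spec(grid = g, brain_center = c(2, 2, 3),
                     brain_semiaxes = c(1.2, 1.2, 2),
                     ventricles = list(list(center = c(3.6, 2, 3),
                                            semiaxes = c(0.3, 0.3, 0.5))),
                     seed_center = c(2, 2, 3), seed_radius = 0.3)
  expect_error(make_brain_phantom(sp), "outside the brain")
})

test_that("initial field paints u0 inside the seed sphere only", {
  gt <- make_brain_phantom(phantom_spec())
  f <- make_initial_field(gt, c(2.8, 2.1, 4.5), 0.6, u0 = 0.5)
  expect_setequal(unique(as.numeric(f$values)), c(0, 0.5))
  expect_equal(f$time, day_to_hours(11))
  f0 <- make_initial_field(gt, c(2.8, 2.1, 4.5), 0.6, u0 = 0)
  expect_true(all(f0$values == 0))
  # sub-voxel radius centred on a voxel centre selects exactly one voxel
  g <- grid3d(c(11, 11, 5))
  geom <- brain_geometry(g, array(TRUE, dim = g$shape))
  center <- c((6 - 0.5) * 0.1, (6 - 0.5) * 0.1, (3 - 0.5) * 0.5)
  f1 <- make_initial_field(geom, center, radius = 0.04, u0 = 0.5)
  expect_equal(sum(f1$values > 0), 1L)
  expect_equal(f1$values[6, 6, 3], 0.5)
  expect_error(make_initial_field(geom, c(50, 50, 50), 0.1), "outside the domain")
})

test_that("ground-truth series is deterministic and grows monotonically", {
  sp <- small_phantom_spec(true_params = params(413.77, 0.0188))
  gt1 <- simulate_ground_truth(sp)
  gt2 <- simulate_ground_truth(sp)
  expect_identical(gt1$series$masks, gt2$series$masks)
  vols <- vapply(gt1$series$masks, sum, 0L)
  expect_true(vols[5] > vols[1])
  expect_true(all(diff(vols) > 0))
  # noiseless: masks equal the thresholded history fields
  for (k in seq_along(gt1$history)) {
    expect_identical(gt1$series$masks[[k]],
                     threshold_to_mask(gt1$history[[k]], sp$threshold))
  }
})

test_that("boundary noise only flips shell voxels, reproducibly", {
  sp <- small_phantom_spec(flip_prob = 0.3, rng_seed = 9L)
  noisy1 <- simulate_ground_truth(sp)
  noisy2 <- simulate_ground_truth(sp)
  expect_identical(noisy1$series$masks, noisy2$series$masks)
  clean <- simulate_ground_truth(small_phantom_spec())
  for (k in seq_along(clean$series$masks)) {
    diffvox <- which(noisy1$series$masks[[k]] != clean$series$masks[[k]])
    if (length(diffvox)) {
      shell <- gliomafit:::mask_boundary_shell(clean$series$masks[[k]],
                                               clean$geometry$domain_mask)
      expect_true(all(diffvox %in% which(shell)))
    }
  }
  # a different seed changes only the noise, not the underlying truth
  other <- simulate_ground_truth(small_phantom_spec(flip_prob = 0.3, rng_seed = 10L))
  expect_identical(lapply(noisy1$history, function(f) f$values),
                   lapply(other$history, function(f) f$values))
  expect_false(identical(noisy1$series$masks, other$series$masks))
})

test_that("ventricle drift shifts the centroid and is reversible", {
  # roomy fixture: one small central ventricle with space to drift
  g <- grid3d(c(60, 60, 16))
  sp <- phantom_spec(grid = g, brain_center = c(3, 3, 4),
                     brain_semiaxes = c(2.7, 2.7, 3.6),
                     ventricles = list(list(center = c(2.2, 3, 4),
                                            semiaxes = c(0.25, 0.4, 0.8))),
                     seed_center = c(3.8, 3, 4), seed_radius = 0.5)
  geom <- make_brain_phantom(sp)
  expect_identical(drift_ventricles(geom, c(0, 0, 0), 25), geom)
  drifted <- drift_ventricles(geom, c(0.1, 0, 0), 21)
  cen <- function(g) colMeans(which(g$ventricle_mask, arr.ind = TRUE)) * g$grid$spacing
  shift <- cen(drifted) - cen(geom)
  expect_lt(abs(shift[1] - 1.0), 0.05)   # +1.0 mm within half a voxel
  expect_lt(abs(shift[2]), 1e-9)
  back <- drift_ventricles(drifted, c(-0.1, 0, 0), 21)
  expect_identical(back$ventricle_mask, geom$ventricle_mask)
  expect_error(drift_ventricles(geom, c(2, 0, 0), 25), "outside")
})

test_that("anisotropic D field respects the half-plane intervals", {
  dom <- matrix(TRUE, 160, 160)
  spec <- dfield_spec(eta = 11120, rng_seed = 2L)
  f <- make_anisotropic_D_field(dom, spec, mode = "axis")
  nx <- nrow(dom)
  left <- f$Dx[seq_len(nx / 2), ]
  expect_true(all(left >= 0 & left <= 0.2 * 11120))
  right <- f$Dx[(nx / 2 + 1):nx, ]
  expect_true(all(right <= 0.05 * 11120))
  bottom <- f$Dy[, seq_len(nx / 2)]
  expect_true(all(bottom >= 0.3 * 11120 & bottom <= 0.5 * 11120))
  # law of large numbers: mean of the bottom half approaches 0.4 eta
  expect_gt(length(bottom), 1e4)
  expect_lt(abs(mean(bottom) / (0.4 * 11120) - 1), 0.02)
  # degenerate intervals give a constant field
  specc <- dfield_spec(eta = 1000, left = c(0.2, 0.2), right = c(0.2, 0.2),
                       top = c(0.2, 0.2), bottom = c(0.2, 0.2))
  fc <- make_anisotropic_D_field(dom, specc, mode = "quadrant")
  expect_true(all(fc == 200))
  # determinism given the seed
  expect_identical(f, make_anisotropic_D_field(dom, spec, mode = "axis"))
})

test_that("slices carry the correct in-plane spacing and re-stack", {
  g <- grid3d(c(12, 10, 6))
  set.seed(8)
  vol <- array(runif(prod(g$shape)) > 0.5, dim = g$shape)
  tr <- extract_slice(vol, g, "transverse", 3)
  expect_equal(tr$spacing, c(0.1, 0.1))
  expect_identical(tr$plane, vol[, , 3])
  sg <- extract_slice(vol, g, "sagittal", 5)
  expect_equal(sg$spacing, c(0.1, 0.5))
  expect_identical(sg$plane, vol[5, , ])
  co <- extract_slice(vol, g, "coronal", 2)
  expect_equal(co$spacing, c(0.1, 0.5))
  restacked <- simplify2array(lapply(seq_len(g$shape[3]), function(k)
    extract_slice(vol, g, "transverse", k)$plane))
  expect_identical(restacked, vol)
  expect_error(extract_slice(vol, g, "transverse", 7), "out of range")
})
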