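mask_from <- function(idx, n = 16) {
  m <- array(FALSE, dim = c(n, 1, 1)); m[idx, 1, 1] <- TRUE; m
}

test_that("jaccard distance matches its defining identities", {
  A <- mask_from(1:5); B <- mask_from(1:5)
  expect_equal(jaccard_distance(A, B), 0)                 # A = B
  expect_equal(jaccard_distance(mask_from(1:3), mask_from(7:9)), 1)  # disjoint
  expect_equal(jaccard_distance(mask_from(1:2), mask_from(2:4)), 0.75) # 1/4
  expect_message(d0 <- jaccard_distance(mask_from(integer(0)), mask_from(integer(0))),
                 "both masks empty")
  expect_equal(d0, 0)
  expect_equal(jaccard_distance(mask_from(1:2), mask_from(integer(0))), 1)
  expect_error(jaccard_distance(A, array(FALSE, dim = c(4, 1, 1))), "different grids")
})

test_that("jaccard distance is a metric on random small sets", {
  set.seed(101)
  jac <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0) 0 else 1 - length(intersect(a, b)) / length(u)
  }
  for (rep in 1:1000) {
    a <- sample(12, sample(1:6, 1)); b <- sample(12, sample(1:6, 1))
    cc <- sample(12, sample(1:6, 1))
    dab <- jac(a, b); dbc <- jac(b, cc); dac <- jac(a, cc)
    expect_equal(dab, jac(b, a))
    expect_lte(dac, dab + dbc + 1e-12)
  }
  # the array implementation agrees with the set-arithmetic oracle
  for (rep in 1:50) {
    a <- sample(12, sample(1:6, 1)); b <- sample(12, sample(1:6, 1))
    expect_equal(jaccard_distance(mask_from(a, 12), mask_from(b, 12)), jac(a, b))
  }
})

test_that("series error reproduces the reported per-interval arithmetic", {
  # Mouse 1 Hypothesis 2 per-interval errors and their printed aggregates
  d <- c(0.1196, 0.1191, 0.1029, 0.0949)
  expect_equal(error_report(d, "mean")$aggregate, 0.109125)
  expect_equal(error_report(d, "sum")$aggregate, 0.4365)
  expect_equal(error_report(d, "mean")$aggregate, error_report(d, "sum")$aggregate / 4)
  expect_equal(error_report(0.3, "mean")$aggregate, error_report(0.3, "sum")$aggregate)
})

test_that("series_error compares masks day by day, excluding the first day", {
  g <- grid3d(c(8, 1, 1), c(0.1, 0.1, 0.1))
  geom <- brain_geometry(g, array(TRUE, dim = g$shape))
  obs <- imaging_series(geom, c(11, 15, 18),
                        list(mask_from(1:2, 8), mask_from(1:3, 8), mask_from(1:4, 8)))
  sim <- list(mask_from(1:3, 8), mask_from(1:6, 8))
  er <- series_error(sim, obs, "mean")
  expect_equal(er$n, 2L)
  expect_equal(unname(er$per_day), c(0, 1 - 4 / 6))
  # identical masks give zero in both modes
  er0 <- series_error(obs$masks, obs, "sum")
  expect_equal(er0$aggregate, 0)
})

test_that("wave speed arithmetic matches the reported tables", {
  expect_equal(round(wave_speed(params(413.77, 0.0188)), 4), 5.5781)
  expect_equal(round(wave_speed(params(319.22, 0.0167)), 4), 4.6178)
  expect_equal(round(wave_speed(params(316.43, 0.0226)), 4), 5.3484)
  # monotone in each argument
  expect_true(wave_speed(500, 0.02) > wave_speed(400, 0.02))
  expect_true(wave_speed(500, 0.03) > wave_speed(500, 0.02))
})

test_that("velocity unit conversions reproduce the reported cm/yr figures", {
  expect_equal(round(umh_to_cmyr(3.1838), 3), 2.789)
  expect_equal(round(umh_to_cmyr(9.1280), 3), 7.996)
  expect_equal(umh_to_cmyr(0), 0)
  expect_equal(cmyr_to_umh(umh_to_cmyr(5.5781)), 5.5781, tolerance = 1e-12)
})

test_that("visible volume is voxel count times voxel volume", {
  g <- grid3d(c(20, 20, 20))
  m <- array(FALSE, dim = g$shape); m[seq_len(200)] <- TRUE
  expect_equal(visible_volume(m, g), 1.0)
  m2 <- array(FALSE, dim = g$shape); m2[seq_len(2468)] <- TRUE
  expect_equal(visible_volume(m2, g), 12.34)
  expect_equal(visible_volume(array(FALSE, dim = g$shape), g), 0)
})

test_that("relative invasiveness is the log ratio and scale-invariant", {
  expect_equal(relative_invasiveness(params(0.02, 0.02)), 0)
  expect_equal(round(relative_invasiveness(params(463.09, 0.027164)), 4), 4.2317)
  expect_equal(relative_invasiveness(params(463.09, 0.027164)),
               relative_invasiveness(params(4630.9, 0.27164)))
})

test_that("percent decrease reproduces the hypothesis comparison figures", {
  expect_equal(round(percent_decrease(0.4524, 0.4365), 1), 3.5)
  expect_equal(round(percent_decrease(0.4524, 0.3673), 1), 18.8)
  expect_equal(percent_decrease(0.7, 0.7), 0)
  expect_error(percent_decrease(0, 0.1), "positive")
})

test_that("boundary distance error matches a brute-force point-to-segment oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(boundary_distance_error(list(sq), list(sq)), 0)
  shifted <- sweep(sq, 2, c(0.3, 0), "+")
  # brute-force oracle over all vertex/segment pairs
  seg_dist <- function(p, a, b) {
    ab <- b - a; t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((p - a - t * ab)^2))
  }
  brute <- function(pts, poly) {
    m <- nrow(poly)
    sapply(seq_len(nrow(pts)), function(i)
      min(sapply(seq_len(m), function(s)
        seg_dist(pts[i, ], poly[s, ], poly[(s %% m) + 1, ]))))
  }
  d <- brute(shifted, sq)
  expect_equal(boundary_distance_error(list(shifted), list(sq)),
               sqrt(mean(d^2)))
  # vertices lying on the data polygon give zero even with unequal counts
  dense_sq <- cbind(c(0, 0.5, 1, 1, 1, 0.5, 0, 0), c(0, 0, 0, 0.5, 1, 1, 1, 0.5))
  expect_equal(boundary_distance_error(list(dense_sq), list(sq)), 0)
  # multi-day: sum of per-day RMS values
  expect_equal(boundary_distance_error(list(sq, shifted), list(sq, sq)),
               sqrt(mean(d^2)))
})

test_that("weighted total error combines z_d and the Jaccard sum", {
  expect_equal(total_error_E2(0, c(0, 0, 0, 0)), 0)
  expect_equal(total_error_E2(1.5, c(0.1, 0.2, 0.3, 0.4)), 11.5)
  j <- c(0.11, 0.07, 0.02)
  expect_equal(total_error_E2(2, 2 * j) - 2, 2 * (total_error_E2(2, j) - 2))
})
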