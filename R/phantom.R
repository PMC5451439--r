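# Synthetic phantom generator: mouse-scale brain with ventricle cavities,
# a spherical day-11 tumor seed, and forward-model-generated visible-tumor
# mask series at the imaging days, emulating registered segmented T2w data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Defines the synthetic study conditions: an ellipsoidal mouse-scale brain
#' with ellipsoidal ventricle cavities on the imaging grid, a spherical tumor
#' seed at day 11, the true model parameters driving the forward simulation,
#' and the imaging schedule. Defaults give a day-11 visible volume of about
#' 0.7 mm^3 (the observed day-11 range is roughly 0.6-1.0 mm^3) growing to the
#' tens of mm^3 by day 25.
#'
#' @param grid a `grid3d`; default 56 x 56 x 18 voxels at 0.1 x 0.1 x 0.5 mm,
#'   large enough to contain day-25 growth at the default parameters.
#' @param brain_center mm triple; default is the grid centre.
#' @param brain_semiaxes mm triple of brain ellipsoid semi-axes.
#' @param ventricles list of ellipsoids, each `list(center=, semiaxes=)` in mm.
#' @param seed_center mm triple, centre of the day-11 tumor seed sphere.
#' @param seed_radius mm, seed sphere radius.
#' @param u0 initial density inside the visible tumor (fraction of carrying
#'   capacity; default 0.5).
#' @param true_params `params` driving the ground-truth forward run.
#' @param days imaging days; default c(11, 15, 18, 22, 25).
#' @param threshold detection threshold (default 0.16).
#' @param flip_prob boundary-voxel flip probability in [0, 1) emulating
#'   segmentation noise (default 0: noiseless).
#' @param ventricle_drift mm/day triple of ventricle displacement (default 0).
#' @param rng_seed integer seed for all phantom randomness.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid = grid3d(c(56, 56, 18)),
                         brain_center = NULL,
                         brain_semiaxes = c(2.5, 2.5, 3.6),
                         ventricles = NULL,
                         seed_center = NULL,
                         seed_radius = 0.55,
                         u0 = 0.5,
                         true_params = params(413.77, 0.0188),
                         days = c(11L, 15L, 18L, 22L, 25L),
                         threshold = 0.16,
                         flip_prob = 0,
                         ventricle_drift = c(0, 0, 0),
                         rng_seed = 1L) {
  extent <- grid$shape * grid$spacing
  if (is.null(brain_center)) brain_center <- extent / 2
  if (is.null(ventricles)) {
    ventricles <- list(
      list(center = brain_center + c(-1.2, 0.7, 0), semiaxes = c(0.25, 0.5, 0.9)),
      list(center = brain_center + c( 1.2, 0.7, 0), semiaxes = c(0.25, 0.5, 0.9)))
  }
  if (is.null(seed_center)) seed_center <- brain_center + c(0, -0.7, 0)
  stopifnot(threshold > 0, threshold < 1, flip_prob >= 0, flip_prob < 1,
            u0 >= 0, u0 <= 1, seed_radius > 0)
  structure(list(grid = grid, brain_center = brain_center,
                 brain_semiaxes = brain_semiaxes, ventricles = ventricles,
                 seed_center = seed_center, seed_radius = seed_radius,
                 u0 = u0, true_params = true_params, days = as.integer(days),
                 threshold = threshold, flip_prob = flip_prob,
                 ventricle_drift = ventricle_drift,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Rasterise an ellipsoid on voxel centres: TRUE where
# sum(((x - c) / a)^2) <= 1.
rasterize_ellipsoid <- function(grid, center, semiaxes) {
  ax <- grid_axes(grid)
  qx <- ((ax$x - center[1]) / semiaxes[1])^2
  qy <- ((ax$y - center[2]) / semiaxes[2])^2
  qz <- ((ax$z - center[3]) / semiaxes[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

# Rasterise a sphere (physical mm radius) on voxel centres, inclusive.
rasterize_sphere <- function(grid, center, radius) {
  ax <- grid_axes(grid)
  qx <- (ax$x - center[1])^2
  qy <- (ax$y - center[2])^2
  qz <- (ax$z - center[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= radius^2
}

#' Build the phantom brain geometry
#'
#' Ellipsoidal brain mask minus ellipsoidal ventricle cavities, rasterised on
#' voxel centres.
#'
#' @param spec a `phantom_spec`.
#' @return a `brain_geometry`.
#' @export
make_brain_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  brain <- rasterize_ellipsoid(spec$grid, spec$brain_center, spec$brain_semiaxes)
  vent <- array(FALSE, dim = spec$grid$shape)
  for (v in spec$ventricles) {
    vm <- rasterize_ellipsoid(spec$grid, v$center, v$semiaxes)
    if (any(vm & !brain))
      stop("make_brain_phantom: ventricle extends outside the brain")
    vent <- vent | vm
  }
  brain_geometry(spec$grid, brain, vent)
}

#' Initial density field from a spherical seed
#'
#' Density u0 inside the seed sphere intersected with the domain, zero
#' elsewhere; the default time stamp is day 11 (264 h).
#'
#' @param geometry a `brain_geometry`.
#' @param center seed centre (mm).
#' @param radius seed radius (mm).
#' @param u0 density inside the seed (default 0.5).
#' @param time hours since implantation (default day 11).
#' @return a `density_field`.
#' @export
make_initial_field <- function(geometry, center, radius, u0 = 0.5,
                               time = day_to_hours(11)) {
  sphere <- rasterize_sphere(geometry$grid, center, radius)
  inside <- sphere & geometry$domain_mask
  if (!any(inside))
    stop("make_initial_field: seed sphere lies entirely outside the domain")
  vals <- array(0, dim = geometry$grid$shape)
  vals[inside] <- u0
  density_field(geometry, vals, time)
}

#' Initial density field painted onto an observed mask
#'
#' Used both by the phantom and by the fitting stages: every voxel of the
#' visible-tumor mask is set to density u0, all others to zero.
#'
#' @param geometry a `brain_geometry`.
#' @param mask logical array (subset of the domain).
#' @param u0 density inside the mask.
#' @param time hours since implantation.
#' @return a `density_field`.
#' @export
field_from_mask <- function(geometry, mask, u0, time) {
  vals <- array(0, dim = geometry$grid$shape)
  vals[mask & geometry$domain_mask] <- u0
  density_field(geometry, vals, time)
}

# One-voxel boundary shell of a mask: mask voxels with a 6-neighbour outside
# the mask, plus domain voxels outside the mask with a 6-neighbour inside.
mask_boundary_shell <- function(mask, domain) {
  sh <- dim(mask)
  shifted_any_diff <- array(FALSE, dim = sh)
  pad_shift <- function(m, ax, dir) {
    out <- array(FALSE, dim = sh)
    n <- sh[ax]
    idx_src <- if (dir > 0) seq_len(n - 1L) else 2:n
    idx_dst <- if (dir > 0) 2:n else seq_len(n - 1L)
    if (ax == 1) out[idx_dst, , ] <- m[idx_src, , ]
    if (ax == 2) out[, idx_dst, ] <- m[, idx_src, ]
    if (ax == 3) out[, , idx_dst] <- m[, , idx_src]
    out
  }
  nb_in <- array(FALSE, dim = sh)
  for (ax in 1:3) for (dir in c(-1L, 1L))
    nb_in <- nb_in | pad_shift(mask, ax, dir)
  nb_out <- array(FALSE, dim = sh)
  not_mask <- domain & !mask
  for (ax in 1:3) for (dir in c(-1L, 1L))
    nb_out <- nb_out | pad_shift(not_mask, ax, dir)
  (mask & nb_out) | (not_mask & nb_in)
}

#' Simulate the ground-truth imaging series of a phantom
#'
#' Runs the forward model from the day-11 seed and thresholds the density at
#' each imaging day. If `flip_prob > 0`, voxels in the one-voxel boundary
#' shell of each mask are flipped independently with that probability
#' (reproducibly from `rng_seed`), emulating segmentation uncertainty while
#' preserving topology. The noiseless density history is returned alongside.
#'
#' @param spec a `phantom_spec`.
#' @param config a `solver_config` (its threshold is overridden by the spec's).
#' @return list with `series` (an `imaging_series`, noisy if flip_prob > 0),
#'   `history` (list of noiseless `density_field`s, one per day including the
#'   initial one), `geometry`, and `truth` (the true `params`).
#' @export
simulate_ground_truth <- function(spec, config = solver_config()) {
  stopifnot(inherits(spec, "phantom_spec"))
  config$threshold <- spec$threshold
  geom <- make_brain_phantom(spec)
  f0 <- make_initial_field(geom, spec$seed_center, spec$seed_radius, spec$u0,
                           time = day_to_hours(spec$days[1]))
  later <- day_to_hours(spec$days[-1])
  fields <- c(list(f0), integrate_density(f0, spec$true_params, later, config))
  masks <- lapply(fields, threshold_to_mask, threshold = spec$threshold)
  if (spec$flip_prob > 0) {
    masks <- with_seed(spec$rng_seed, {
      lapply(masks, function(m) {
        shell <- which(mask_boundary_shell(m, geom$domain_mask))
        flip <- shell[stats::runif(length(shell)) < spec$flip_prob]
        m[flip] <- !m[flip]
        m
      })
    })
  }
  list(series = imaging_series(geom, spec$days, masks),
       history = fields, geometry = geom, truth = spec$true_params)
}

#' Translate the ventricles by a drift accumulated since day 11
#'
#' The ventricle mask is shifted by the nearest-voxel offset of
#' drift * (day - 11); the domain mask is recomputed. Emulates mass-effect
#' displacement so that time-updated geometry paths can be exercised.
#'
#' @param geometry a `brain_geometry`.
#' @param drift mm/day triple.
#' @param day target day (drift accumulates from day 11).
#' @return a new `brain_geometry`.
#' @export
drift_ventricles <- function(geometry, drift, day) {
  stopifnot(inherits(geometry, "brain_geometry"))
  off <- as.integer(round(drift * (day - 11) / geometry$grid$spacing))
  if (all(off == 0L)) return(geometry)
  sh <- geometry$grid$shape
  vm <- geometry$ventricle_mask
  idx <- which(vm)
  if (length(idx)) {
    ai <- arrayInd(idx, sh)
    ai <- sweep(ai, 2, off, "+")
    if (any(ai < 1L) || any(ai > matrix(sh, nrow(ai), 3, byrow = TRUE)))
      stop("drift_ventricles: ventricle pushed outside the grid")
    new_vm <- array(FALSE, dim = sh)
    new_vm[ai] <- TRUE
  } else {
    new_vm <- vm
  }
  if (any(new_vm & !geometry$brain_mask))
    stop("drift_ventricles: ventricle pushed outside the brain")
  brain_geometry(geometry$grid, geometry$brain_mask, new_vm)
}

#' Specification of a random 2D diffusion field
#'
#' Per-pixel diffusion coefficients drawn uniformly from half-plane-specific
#' intervals expressed as fractions of a base value eta. Two readings of the
#' half-plane rule are supported (see `make_anisotropic_D_field`).
#'
#' @param eta base diffusion value in um^2/h.
#' @param left,right horizontal-direction intervals (fractions of eta) for the
#'   left and right halves.
#' @param top,bottom vertical-direction intervals for the top and bottom
#'   halves ("top" = larger y index).
#' @param rng_seed integer seed.
#' @return a `dfield_spec` list.
#' @export
dfield_spec <- function(eta = 11120,
                        left = c(0, 0.2), right = c(0, 0.05),
                        top = c(0.1, 0.4), bottom = c(0.3, 0.5),
                        rng_seed = 1L) {
  for (iv in list(left, right, top, bottom))
    if (length(iv) != 2L || any(iv < 0) || iv[1] > iv[2])
      stop("dfield_spec: intervals must be 0 <= lo <= hi")
  stopifnot(eta > 0)
  structure(list(eta = eta, left = left, right = right, top = top,
                 bottom = bottom, rng_seed = as.integer(rng_seed)),
            class = "dfield_spec")
}

#' Draw a random anisotropic 2D diffusion field
#'
#' In `mode = "axis"` the horizontal-half intervals govern the x-direction
#' diffusivity and the vertical-half intervals the y-direction diffusivity:
#' the result is a list of two matrices `Dx`, `Dy` (um^2/h). In
#' `mode = "quadrant"` a single scalar field is drawn per pixel from the
#' quadrant interval formed by averaging the bounds of the two governing
#' half-plane intervals. Halves are split at the grid midline. Deterministic
#' given the spec's seed.
#'
#' @param domain2d logical matrix (TRUE inside the computational domain).
#' @param spec a `dfield_spec`.
#' @param mode "axis" or "quadrant".
#' @return matrix (quadrant mode) or list(Dx, Dy) (axis mode); 0 outside the
#'   domain.
#' @export
make_anisotropic_D_field <- function(domain2d, spec, mode = c("axis", "quadrant")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "dfield_spec"), is.matrix(domain2d))
  if (!any(domain2d)) stop("make_anisotropic_D_field: empty domain")
  nx <- nrow(domain2d); ny <- ncol(domain2d)
  leftH  <- outer(seq_len(nx) <= nx / 2, rep(TRUE, ny))
  bottomH <- outer(rep(TRUE, nx), seq_len(ny) <= ny / 2)
  draw <- function(lo, hi) {
    matrix(stats::runif(nx * ny, min = lo, max = hi), nx, ny)
  }
  with_seed(spec$rng_seed, {
    if (mode == "axis") {
      Dx <- ifelse(leftH, draw(spec$left[1], spec$left[2]),
                   draw(spec$right[1], spec$right[2])) * spec$eta
      Dy <- ifelse(bottomH, draw(spec$bottom[1], spec$bottom[2]),
                   draw(spec$top[1], spec$top[2])) * spec$eta
      Dx[!domain2d] <- 0; Dy[!domain2d] <- 0
      list(Dx = Dx, Dy = Dy)
    } else {
      avg <- function(a, b) (a + b) / 2
      lo <- ifelse(leftH,
                   ifelse(bottomH, avg(spec$left[1], spec$bottom[1]),
                          avg(spec$left[1], spec$top[1])),
                   ifelse(bottomH, avg(spec$right[1], spec$bottom[1]),
                          avg(spec$right[1], spec$top[1])))
      hi <- ifelse(leftH,
                   ifelse(bottomH, avg(spec$left[2], spec$bottom[2]),
                          avg(spec$left[2], spec$top[2])),
                   ifelse(bottomH, avg(spec$right[2], spec$bottom[2]),
                          avg(spec$right[2], spec$top[2])))
      D <- matrix(stats::runif(nx * ny), nx, ny)
      D <- (lo + D * (hi - lo)) * spec$eta
      D[!domain2d] <- 0
      D
    }
  })
}

#' Extract a 2D section from a 3D volume
#'
#' Sections follow the acquisition geometry: `transverse` planes are constant-z
#' (in-plane spacing hx x hy), `sagittal` constant-x (hy x hz), `coronal`
#' constant-y (hx x hz).
#'
#' @param volume 3D array (mask or density values).
#' @param grid a `grid3d`.
#' @param axis "transverse", "sagittal" or "coronal".
#' @param index slice index (1-based) along the fixed axis.
#' @return list with `plane` (matrix) and `spacing` (in-plane mm pair).
#' @export
extract_slice <- function(volume, grid, axis = c("transverse", "sagittal", "coronal"),
                          index) {
  axis <- match.arg(axis)
  stopifnot(all(dim(volume) == grid$shape))
  index <- as.integer(index)
  sp <- grid$spacing
  switch(axis,
    transverse = {
      if (index < 1L || index > grid$shape[3]) stop("extract_slice: index out of range")
      list(plane = volume[, , index], spacing = sp[c(1, 2)])
    },
    sagittal = {
      if (index < 1L || index > grid$shape[1]) stop("extract_slice: index out of range")
      list(plane = volume[index, , ], spacing = sp[c(2, 3)])
    },
    coronal = {
      if (index < 1L || index > grid$shape[2]) stop("extract_slice: index out of range")
      list(plane = volume[, index, ], spacing = sp[c(1, 3)])
    })
}
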