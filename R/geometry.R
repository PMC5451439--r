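#' Voxel grid specification
#'
#' A uniform 3D voxel grid with anisotropic spacing. Indexing is 0-based in the
#' (x, y, z) axis order with voxel-centred coordinates: voxel (i, j, k) sits at
#' world position ((i + 0.5) hx, (j + 0.5) hy, (k + 0.5) hz) mm.
#'
#' @param shape integer triple (nx, ny, nz), all >= 1.
#' @param spacing numeric triple of voxel spacings in mm, all > 0. The default
#'   matches the registered T2-weighted acquisitions: 0.1 x 0.1 x 0.5 mm.
#' @return an object of class `grid3d` with elements `shape` and `spacing`.
#' @export
grid3d <- function(shape, spacing = c(0.1, 0.1, 0.5)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("grid3d: shape must be three integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid3d: spacing must be three positive numbers (mm)")
  structure(list(shape = shape, spacing = spacing), class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid a `grid3d`.
#' @return scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' World coordinates of voxel centres along each axis
#' @param grid a `grid3d`.
#' @return list of numeric vectors `x`, `y`, `z` (mm, voxel centres).
#' @export
grid_axes <- function(grid) {
  list(x = (seq_len(grid$shape[1]) - 0.5) * grid$spacing[1],
       y = (seq_len(grid$shape[2]) - 0.5) * grid$spacing[2],
       z = (seq_len(grid$shape[3]) - 0.5) * grid$spacing[3])
}

check_mask_array <- function(mask, grid, what) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop(sprintf("%s must be a 3D array", what))
  if (!all(dim(mask) == grid$shape))
    stop(sprintf("%s shape %s does not match grid shape %s", what,
                 paste(dim(mask), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  storage.mode(mask) <- "logical"
  mask
}

#' Brain geometry: masks defining the computational domain
#'
#' The computational domain Omega is the brain with the ventricles segmented
#' out; no diffusion or growth occurs in the ventricular space or outside the
#' skull (no-flux boundaries at every domain face).
#'
#' @param grid a `grid3d`.
#' @param brain_mask logical 3D array, TRUE inside the brain.
#' @param ventricle_mask logical 3D array, TRUE inside the ventricles. Must be a
#'   subset of `brain_mask`.
#' @return an object of class `brain_geometry` with `grid`, `brain_mask`,
#'   `ventricle_mask` and the derived `domain_mask = brain & !ventricle`.
#' @export
brain_geometry <- function(grid, brain_mask, ventricle_mask = NULL) {
  stopifnot(inherits(grid, "grid3d"))
  brain_mask <- check_mask_array(brain_mask, grid, "brain_mask")
  if (is.null(ventricle_mask))
    ventricle_mask <- array(FALSE, dim = grid$shape)
  ventricle_mask <- check_mask_array(ventricle_mask, grid, "ventricle_mask")
  if (any(ventricle_mask & !brain_mask))
    stop("brain_geometry: ventricle_mask must be contained in brain_mask")
  domain_mask <- brain_mask & !ventricle_mask
  if (!any(domain_mask))
    stop("brain_geometry: computational domain is empty")
  structure(list(grid = grid, brain_mask = brain_mask,
                 ventricle_mask = ventricle_mask, domain_mask = domain_mask),
            class = "brain_geometry")
}

#' @export
print.brain_geometry <- function(x, ...) {
  cat(sprintf("brain_geometry: %d brain / %d ventricle / %d domain voxels\n",
              sum(x$brain_mask), sum(x$ventricle_mask), sum(x$domain_mask)))
  print(x$grid)
  invisible(x)
}

#' Normalised tumor cell density field
#'
#' Density is expressed as a fraction of the carrying capacity (which is 1), so
#' values lie in [0, 1]; the field is identically zero outside the computational
#' domain.
#'
#' @param geometry a `brain_geometry`.
#' @param values numeric 3D array of densities.
#' @param time time in hours since implantation.
#' @param tol slack allowed on the upper bound (numerical overshoot detection).
#' @return an object of class `density_field`.
#' @export
density_field <- function(geometry, values, time, tol = 1e-6) {
  stopifnot(inherits(geometry, "brain_geometry"))
  if (!all(dim(values) == geometry$grid$shape))
    stop("density_field: values shape does not match grid")
  if (any(values < -tol) || any(values > 1 + tol))
    stop("density_field: values outside [0, 1] beyond tolerance")
  if (any(values[!geometry$domain_mask] != 0))
    stop("density_field: nonzero values outside the computational domain")
  structure(list(geometry = geometry, values = values, time = as.numeric(time)),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("density_field at t = %g h (day %.2f): max u = %.4f, visible (>=0.16) voxels = %d\n",
              x$time, hours_to_day(x$time), max(x$values), sum(x$values >= 0.16)))
  invisible(x)
}

#' Imaging series of visible-tumor masks
#'
#' Ordered imaging sessions (days post-implantation) with one binary
#' visible-tumor mask per session, all registered to a common geometry. Masks
#' are restricted to the computational domain.
#'
#' @param geometry a `brain_geometry`.
#' @param days strictly increasing integer vector of imaging days. The study
#'   default is c(11, 15, 18, 22, 25).
#' @param masks list of logical 3D arrays, one per day, each a subset of the
#'   domain mask.
#' @return an object of class `imaging_series`.
#' @export
imaging_series <- function(geometry, days, masks) {
  stopifnot(inherits(geometry, "brain_geometry"))
  days <- as.integer(days)
  if (length(days) < 2L) stop("imaging_series: need at least two imaging days")
  if (any(diff(days) <= 0)) stop("imaging_series: days must be strictly increasing")
  if (length(masks) != length(days))
    stop("imaging_series: one mask per day required")
  masks <- lapply(masks, check_mask_array, grid = geometry$grid, what = "mask")
  for (k in seq_along(masks)) {
    if (any(masks[[k]] & !geometry$domain_mask))
      stop(sprintf("imaging_series: mask %d extends outside the domain; clip first (see load_series)", k))
  }
  names(masks) <- paste0("day", days)
  structure(list(geometry = geometry, days = days, masks = masks),
            class = "imaging_series")
}

#' @export
print.imaging_series <- function(x, ...) {
  vols <- vapply(x$masks, function(m) sum(m) * voxel_volume(x$geometry$grid), 0)
  cat("imaging_series:\n")
  for (k in seq_along(x$days))
    cat(sprintf("  day %2d: %7d voxels, %8.3f mm^3\n", x$days[k],
                sum(x$masks[[k]]), vols[k]))
  invisible(x)
}

#' Model parameters: diffusion and proliferation rates
#'
#' @param D diffusion coefficient in um^2/h (> 0).
#' @param rho proliferation (logistic growth) rate in 1/h (> 0).
#' @return an object of class `params`.
#' @export
params <- function(D, rho) {
  D <- as.numeric(D); rho <- as.numeric(rho)
  if (length(D) != 1L || !is.finite(D) || D <= 0)
    stop("params: D must be a positive scalar (um^2/h)")
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("params: rho must be a positive scalar (1/h)")
  structure(list(D = D, rho = rho), class = "params")
}

#' @export
print.params <- function(x, ...) {
  cat(sprintf("params: D = %g um^2/h, rho = %g 1/h (wave speed %g um/h)\n",
              x$D, x$rho, 2 * sqrt(x$D * x$rho)))
  invisible(x)
}
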