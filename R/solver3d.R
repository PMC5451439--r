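#' Solver configuration for the 3D forward model
#'
#' @param rtol relative tolerance of the adaptive integrator.
#' @param atol absolute tolerance.
#' @param max_step maximum internal step in hours (Inf = uncapped).
#' @param threshold detection threshold u_vis: densities at and above this
#'   fraction of carrying capacity are "visible tumor" on a synthetic scan.
#' @param clamp_check tolerance on the [0, 1] density bounds; violations beyond
#'   it abort the integration (instability is detected, never silently fixed).
#' @return a `solver_config` list.
#' @export
solver_config <- function(rtol = 1e-6, atol = 1e-9, max_step = Inf,
                          threshold = 0.16, clamp_check = 1e-6) {
  stopifnot(rtol > 0, atol > 0, max_step > 0,
            threshold > 0, threshold < 1, clamp_check > 0)
  structure(list(rtol = rtol, atol = atol, max_step = max_step,
                 threshold = threshold, clamp_check = clamp_check),
            class = "solver_config")
}

# Accept either a `params` object or a bare list/vector with D > 0, rho >= 0.
# (rho = 0 is a legitimate solver input: pure no-flux diffusion, used for the
# conservation checks; the `params` class itself requires rho > 0.)
as_solver_params <- function(p) {
  if (inherits(p, "params")) return(list(D = p$D, rho = p$rho))
  D <- p$D %||% p[["D"]]; rho <- p$rho %||% p[["rho"]]
  if (is.null(D) || is.null(rho) || !is.finite(D) || !is.finite(rho) ||
      D <= 0 || rho < 0)
    stop("solver params: need D > 0 (um^2/h) and rho >= 0 (1/h)")
  list(D = D, rho = rho)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precompute the masked-domain stencil for the flux-form discretisation
#'
#' Builds, once per geometry, the list of domain voxels and the 6-neighbour
#' index table used by the compiled solver. Faces adjoining non-domain voxels
#' (skull, ventricles) carry zero flux, which implements the no-flux boundary
#' condition and makes the discrete divergence exactly conservative.
#'
#' @param geometry a `brain_geometry`.
#' @return a `domain_stencil` list: `idx` (linear indices of domain voxels),
#'   `nbr` (n x 6 integer matrix, 0-based positions into the domain ordering,
#'   -1 for closed faces), `inv_h2` (1/h^2 per axis, 1/mm^2).
#' @export
domain_stencil <- function(geometry) {
  stopifnot(inherits(geometry, "brain_geometry"))
  dm <- geometry$domain_mask
  sh <- geometry$grid$shape
  idx <- which(dm)
  n <- length(idx)
  pos <- integer(prod(sh))          # full linear index -> domain position (1-based)
  pos[idx] <- seq_len(n)
  ai <- arrayInd(idx, sh)
  strides <- c(1L, sh[1], sh[1] * sh[2])
  nbr <- matrix(-1L, n, 6L)
  col <- 0L
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      col <- col + 1L
      ok <- if (dir < 0) ai[, ax] > 1L else ai[, ax] < sh[ax]
      j <- idx[ok] + dir * strides[ax]
      p <- pos[j]
      good <- p > 0L
      rows <- which(ok)[good]
      nbr[rows, col] <- p[good] - 1L
    }
  }
  structure(list(idx = idx, nbr = nbr, inv_h2 = 1 / geometry$grid$spacing^2,
                 shape = sh),
            class = "domain_stencil")
}

face_weights <- function(stencil, D_um2h) {
  D <- um2h_to_mm2h(D_um2h)
  rep(D * stencil$inv_h2, each = 2L)   # (x-, x+, y-, y+, z-, z+)
}

#' Reaction-diffusion right-hand side on the masked domain
#'
#' Evaluates du/dt = div(D grad u) + rho u (1 - u) with flux-form centred
#' differences and per-axis spacing; the rate is zero outside the domain and
#' fluxes across skull/ventricle faces are zero.
#'
#' @param field a `density_field`.
#' @param p a `params` (or list with D in um^2/h and rho >= 0 in 1/h).
#' @param stencil optional precomputed `domain_stencil` (built if missing).
#' @return 3D array of rates (1/h).
#' @export
reaction_diffusion_rhs <- function(field, p, stencil = NULL) {
  stopifnot(inherits(field, "density_field"))
  p <- as_solver_params(p)
  if (is.null(stencil)) stencil <- domain_stencil(field$geometry)
  u <- field$values[stencil$idx]
  du <- rd_rhs_cpp(u, stencil$nbr, face_weights(stencil, p$D), p$rho)
  out <- array(0, dim = stencil$shape)
  out[stencil$idx] <- du
  out
}

#' Advance a density field to later times
#'
#' Integrates the reaction-diffusion model with an adaptive explicit embedded
#' Runge-Kutta 4(5) (Dormand-Prince) scheme; the adaptive step is clipped so
#' that requested output times are hit exactly. Deterministic for fixed inputs
#' and tolerances. Bound violations beyond `config$clamp_check` abort.
#'
#' @param field a `density_field` (defines t0 via `field$time`).
#' @param p a `params` (or list, rho >= 0 allowed).
#' @param times output times in hours, strictly increasing, all > field$time.
#' @param config a `solver_config`.
#' @param stencil optional precomputed `domain_stencil`.
#' @return list of `density_field`s, one per output time.
#' @export
integrate_density <- function(field, p, times, config = solver_config(),
                              stencil = NULL) {
  stopifnot(inherits(field, "density_field"))
  p <- as_solver_params(p)
  times <- as.numeric(times)
  if (any(times <= field$time)) stop("integrate_density: times must exceed field$time")
  if (is.null(stencil)) stencil <- domain_stencil(field$geometry)
  u0 <- field$values[stencil$idx]
  hmax <- if (is.finite(config$max_step)) config$max_step else -1
  sol <- rd_integrate_cpp(u0, stencil$nbr, face_weights(stencil, p$D), p$rho,
                          field$time, times, config$rtol, config$atol, hmax,
                          config$clamp_check)
  lapply(seq_along(times), function(k) {
    vals <- array(0, dim = stencil$shape)
    vals[stencil$idx] <- sol[, k]   # unclamped; bounds were checked in-solver
    density_field(field$geometry, vals, times[k], tol = config$clamp_check)
  })
}

#' Threshold a density field to a visible-tumor mask
#'
#' The comparison is inclusive: voxels with u >= u_vis (and inside the domain)
#' are visible. The study phrases the threshold both as "greater than" and "at
#' and above" 0.16; this package standardises on inclusive.
#'
#' @param field a `density_field`.
#' @param threshold detection threshold in (0, 1); default 0.16.
#' @return logical 3D array.
#' @export
threshold_to_mask <- function(field, threshold = 0.16) {
  stopifnot(inherits(field, "density_field"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold_to_mask: threshold must lie in (0, 1)")
  field$values >= threshold & field$geometry$domain_mask
}

#' Measure the traveling-wave front speed in a quasi-1D channel
#'
#' Builds an n x 1 x 1 channel with no-flux ends, seeds one end, integrates the
#' reaction-diffusion model, tracks the position of the detection-threshold
#' contour (linear interpolation between voxel centres) and returns the
#' least-squares slope of position versus time over the post-transient window.
#' For a Fisher-KPP front this converges to c = 2 sqrt(D rho).
#'
#' @param p a `params` (or list; rho = 0 allowed, giving a non-propagating
#'   diffusive profile).
#' @param channel_length_mm length of the channel (mm); must be long enough for
#'   the front to travel at least 20 voxels after the transient.
#' @param config a `solver_config`; the default uses tighter integrator
#'   tolerances than the volumetric runs because the measurement integrates
#'   over thousands of hours and the slope is sensitive to the slowly damped
#'   numerical noise floor near the u = 1 equilibrium.
#' @param spacing_mm voxel size along the channel (mm); default matches the
#'   in-plane imaging resolution.
#' @param t_end_h total integration time (hours).
#' @param transient_frac fraction of the record discarded as transient.
#' @param n_samples number of sampling times.
#' @param seed_length_mm extent of the fully seeded (u = 1) channel end. For
#'   rho > 0 the choice is immaterial once the wave forms; for the rho = 0
#'   (pure diffusion) control it sets the conserved mass and must be large
#'   enough that the threshold contour persists through the measurement
#'   window.
#' @return list with `speed_umh` (slope in um/h), `positions_mm`, `times_h`.
#' @export
measure_front_speed <- function(p, channel_length_mm = 20,
                                config = solver_config(rtol = 1e-8, atol = 1e-11),
                                spacing_mm = 0.1, t_end_h = 3000,
                                transient_frac = 0.5, n_samples = 60,
                                seed_length_mm = 1) {
  p <- as_solver_params(p)
  nx <- max(40L, as.integer(round(channel_length_mm / spacing_mm)))
  g <- grid3d(c(nx, 1L, 1L), c(spacing_mm, spacing_mm, spacing_mm))
  geom <- brain_geometry(g, array(TRUE, dim = g$shape))
  seed_len <- max(5L, as.integer(round(seed_length_mm / spacing_mm)))
  u0 <- array(0, dim = g$shape)
  u0[seq_len(seed_len), 1, 1] <- 1
  field <- density_field(geom, u0, time = 0)
  times <- seq(t_end_h / n_samples, t_end_h, length.out = n_samples)
  fields <- integrate_density(field, p, times, config)
  x <- grid_axes(g)$x
  thr <- config$threshold
  pos <- vapply(fields, function(f) {
    u <- f$values[, 1, 1]
    above <- which(u >= thr)
    if (length(above) == 0L) return(NA_real_)
    i <- max(above)
    if (i >= nx) return(Inf)  # front reached the end of the channel
    # linear interpolation of the threshold crossing between voxels i, i+1
    x[i] + (thr - u[i]) / (u[i + 1L] - u[i]) * (x[i + 1L] - x[i])
  }, 0)
  if (any(is.infinite(pos)))
    stop("measure_front_speed: front reached the channel end; lengthen the channel or shorten t_end_h")
  keep <- which(times > transient_frac * t_end_h & !is.na(pos))
  if (length(keep) < 5L)
    stop("measure_front_speed: too few usable samples after the transient")
  travel_vox <- (max(pos[keep]) - min(pos[keep])) / spacing_mm
  if (p$rho > 0 && travel_vox < 20)
    stop("measure_front_speed: front travelled < 20 voxels post-transient; lengthen t_end_h")
  fit <- stats::lm.fit(cbind(1, times[keep]), pos[keep])
  slope_mmh <- fit$coefficients[2]
  list(speed_umh = unname(slope_mmh) * 1e3, positions_mm = pos, times_h = times)
}
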