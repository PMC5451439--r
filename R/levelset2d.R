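# 2D moving-boundary (Stefan) solver. The tumor region Omega1 = {phi < 0} is
# tracked implicitly by a signed-distance level-set function phi; the density
# u obeys the reaction-diffusion model inside Omega1 with Dirichlet u = ubar
# on the interface, and the interface moves with the Darcy/Stefan normal
# velocity v . n = -(D/ubar) grad(u) . n, extended off the interface along
# normals. The host region Omega2 (rest of the brain) imposes no-flux walls
# and can be swapped on scheduled days to emulate mass-effect displacement.

#' Planar computational domain for the 2D moving-boundary solver
#'
#' @param shape integer pair (nx, ny).
#' @param spacing in-plane spacing in mm (pair).
#' @param brain logical matrix, TRUE inside the brain section.
#' @param ventricles logical matrix (subset of brain) or NULL.
#' @param updates optional named list of geometry replacements applied at the
#'   start of the named day, e.g. `list("15" = list(brain=, ventricles=))`.
#' @return a `planar_domain`.
#' @export
planar_domain <- function(shape, spacing, brain, ventricles = NULL,
                          updates = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 3L),
            length(spacing) == 2L, all(spacing > 0),
            is.matrix(brain), all(dim(brain) == shape))
  if (is.null(ventricles)) ventricles <- matrix(FALSE, shape[1], shape[2])
  stopifnot(all(dim(ventricles) == shape))
  if (any(ventricles & !brain))
    stop("planar_domain: ventricles must lie inside the brain")
  if (!is.null(updates)) {
    d <- as.integer(names(updates))
    if (any(is.na(d)) || is.unsorted(d, strictly = TRUE))
      stop("planar_domain: update days must be named, sorted, unique")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 brain = brain, ventricles = ventricles,
                 domain = brain & !ventricles, updates = updates),
            class = "planar_domain")
}

# Pixel-centre axes of a planar domain (mm).
plane_axes <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2])
}

# Zero-level contour segments of a scalar field (marching squares with linear
# interpolation, via grDevices::contourLines). Returns list of data.frames
# with x, y in mm, or empty list.
zero_contours <- function(field, spacing, level = 0) {
  ax <- plane_axes(dim(field), spacing)
  grDevices::contourLines(ax$x, ax$y, field, levels = level)
}

# Signed distance (mm) to the zero contour of `field`; negative where
# field < 0. Falls back to large +/- values if there is no contour.
# When `keep_band` > 0 and `field` is already approximately a distance
# function near its interface, values with |field| < keep_band are kept
# unchanged so reinitialisation cannot displace the interface (the polygonal
# contour otherwise introduces a systematic curvature shrinkage).
signed_distance_to_zero <- function(field, spacing, keep_band = 0) {
  segs <- zero_contours(field, spacing)
  sh <- dim(field)
  if (length(segs) == 0L) {
    big <- sum(sh * spacing)
    return(matrix(ifelse(field < 0, -big, big), sh[1], sh[2]))
  }
  ax <- list()
  a_x <- c(); a_y <- c(); b_x <- c(); b_y <- c()
  for (s in segs) {
    n <- length(s$x)
    if (n < 2L) next
    a_x <- c(a_x, s$x[-n]); a_y <- c(a_y, s$y[-n])
    b_x <- c(b_x, s$x[-1]); b_y <- c(b_y, s$y[-1])
  }
  axes <- plane_axes(sh, spacing)
  px <- rep(axes$x, times = sh[2])
  py <- rep(axes$y, each = sh[1])
  d <- dist_to_segments_cpp(px, py, a_x, a_y, b_x, b_y)
  out <- matrix(ifelse(c(field) < 0, -d, d), sh[1], sh[2])
  if (keep_band > 0) {
    keep <- abs(field) < keep_band
    out[keep] <- field[keep]
  }
  out
}

# Signed distance to the boundary of a binary mask: distance to the 0.5-level
# contour of the smoothed indicator, negative inside the mask.
signed_distance_from_mask <- function(mask, spacing) {
  ind <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  signed_distance_to_zero(0.5 - ind, spacing)
}

shift2 <- function(m, dx, dy) {
  # shift with edge replication
  nx <- nrow(m); ny <- ncol(m)
  xi <- pmin(pmax(seq_len(nx) - dx, 1L), nx)
  yi <- pmin(pmax(seq_len(ny) - dy, 1L), ny)
  m[xi, yi]
}

# 4-neighbourhood dilation of a logical matrix.
dilate4 <- function(m) {
  m | shift2(m, 1, 0) | shift2(m, -1, 0) | shift2(m, 0, 1) | shift2(m, 0, -1)
}

#' Initialise the level-set state from a tumor mask
#'
#' phi is the signed Euclidean distance to the mask boundary (negative inside);
#' u is u0 on the tumor pixels, ubar on the one-pixel ghost band just outside
#' the interface, and 0 elsewhere.
#'
#' @param tumor_mask logical matrix, the initial visible tumor (subset of the
#'   domain, nonempty).
#' @param domain a `planar_domain`.
#' @param u0 interior density (default 0.5).
#' @param ubar interface density / detection threshold (default 0.16).
#' @param time hours since implantation (default day 11).
#' @return a `levelset_state`: list(phi, u, time, ubar, spacing).
#' @export
init_state <- function(tumor_mask, domain, u0 = 0.5, ubar = 0.16,
                       time = day_to_hours(11)) {
  stopifnot(inherits(domain, "planar_domain"))
  if (!any(tumor_mask)) stop("init_state: empty tumor mask")
  if (any(tumor_mask & !domain$domain))
    stop("init_state: tumor mask extends outside the domain")
  phi <- signed_distance_from_mask(tumor_mask, domain$spacing)
  inside <- phi < 0
  ghost <- !inside & dilate4(inside)
  u <- matrix(0, domain$shape[1], domain$shape[2])
  u[inside] <- u0
  u[ghost] <- ubar
  structure(list(phi = phi, u = u, time = time, ubar = ubar,
                 spacing = domain$spacing),
            class = "levelset_state")
}

#' @export
print.levelset_state <- function(x, ...) {
  area <- sum(x$phi < 0) * prod(x$spacing)
  cat(sprintf("levelset_state at t = %g h (day %.2f): tumor area %.3f mm^2\n",
              x$time, hours_to_day(x$time), area))
  invisible(x)
}

# Normalise a diffusion specification to per-axis mm^2/h matrices.
# D may be: scalar um^2/h; matrix um^2/h (isotropic per-pixel);
# list(Dx, Dy) um^2/h (axis-wise).
normalize_Dfield <- function(D, shape) {
  to_mat <- function(v) {
    if (is.matrix(v)) {
      stopifnot(all(dim(v) == shape))
      um2h_to_mm2h(v)
    } else matrix(um2h_to_mm2h(v), shape[1], shape[2])
  }
  if (is.list(D) && !is.null(D$Dx)) list(Dx = to_mat(D$Dx), Dy = to_mat(D$Dy))
  else list(Dx = to_mat(D), Dy = to_mat(D))
}

#' Stefan interface normal velocity with constant-normal extension
#'
#' Computes v = -(1/ubar) (Dx du/dx nx + Dy du/dy ny) with interior-biased
#' one-sided gradients of u and n = grad(phi)/|grad(phi)|, then extends the
#' value off the interface by sampling at each pixel's foot point
#' x - phi(x) n(x) (constant extrapolation along normals).
#'
#' @param state a `levelset_state`.
#' @param D scalar or matrix (um^2/h), or list(Dx, Dy) for axis-wise
#'   diffusivity. The cellular mobility of the Darcy closure is taken equal to
#'   D (no extra model parameter).
#' @return matrix of normal speeds (mm/h), positive = outward growth.
#' @export
interface_velocity <- function(state, D) {
  phi <- state$phi; u <- state$u
  h <- state$spacing
  Df <- normalize_Dfield(D, dim(phi))
  # unit normal from central differences of phi
  gx <- (shift2(phi, -1, 0) - shift2(phi, 1, 0)) / (2 * h[1])
  gy <- (shift2(phi, 0, -1) - shift2(phi, 0, 1)) / (2 * h[2])
  gn <- sqrt(gx^2 + gy^2)
  small <- gn < 1e-8
  gn[small] <- 1
  nx <- gx / gn; ny <- gy / gn
  nx[small] <- 0; ny[small] <- 0
  # normal derivative of u at the interface foot point of every pixel, by a
  # one-sided quadratic through u(x_I) = ubar and two interior probes along
  # the inward normal (sub-cell accurate in the interface position; constant
  # normal extension comes for free since every pixel uses its own foot point)
  delta <- 1.5 * min(h)
  ax <- plane_axes(dim(phi), h)
  X <- matrix(ax$x, nrow(phi), ncol(phi))
  Y <- matrix(ax$y, nrow(phi), ncol(phi), byrow = TRUE)
  fx <- X - phi * nx
  fy <- Y - phi * ny
  u1 <- bilinear_sample(u, fx - delta * nx, fy - delta * ny, h)
  u2 <- bilinear_sample(u, fx - 2 * delta * nx, fy - 2 * delta * ny, h)
  G <- (3 * state$ubar - 4 * u1 + u2) / (2 * delta)  # du/dn, outward
  Dn <- bilinear_sample(Df$Dx, fx, fy, h) * nx^2 +
    bilinear_sample(Df$Dy, fx, fy, h) * ny^2
  v <- -(Dn / state$ubar) * G
  v[small] <- 0
  return(v)
}

# legacy per-pixel formulation kept for reference/testing of the raw Stefan
# flux (not used by evolve)
interface_velocity_raw <- function(state, D) {
  phi <- state$phi; u <- state$u
  h <- state$spacing
  Df <- normalize_Dfield(D, dim(phi))
  gx <- (shift2(phi, -1, 0) - shift2(phi, 1, 0)) / (2 * h[1])
  gy <- (shift2(phi, 0, -1) - shift2(phi, 0, 1)) / (2 * h[2])
  gn <- sqrt(gx^2 + gy^2)
  small <- gn < 1e-8
  gn[small] <- 1
  nx <- gx / gn; ny <- gy / gn
  nx[small] <- 0; ny[small] <- 0
  # interior-biased one-sided u gradients: difference taken on the side the
  # tumor interior lies on (against the outward normal)
  dux_b <- (u - shift2(u, 1, 0)) / h[1]   # backward
  dux_f <- (shift2(u, -1, 0) - u) / h[1]  # forward
  duy_b <- (u - shift2(u, 0, 1)) / h[2]
  duy_f <- (shift2(u, 0, -1) - u) / h[2]
  dux <- ifelse(nx > 0, dux_b, dux_f)
  duy <- ifelse(ny > 0, duy_b, duy_f)
  v <- -(Df$Dx * dux * nx + Df$Dy * duy * ny) / state$ubar
  # constant-normal extension: sample v at the foot point x - phi n
  ax <- plane_axes(dim(phi), h)
  X <- matrix(ax$x, nrow(phi), ncol(phi))
  Y <- matrix(ax$y, nrow(phi), ncol(phi), byrow = TRUE)
  fx <- X - phi * nx
  fy <- Y - phi * ny
  bilinear_sample(v, fx, fy, h)
}

# Bilinear interpolation of matrix `m` (pixel-centred on spacing h) at points
# (fx, fy) in mm; clamped to the grid.
bilinear_sample <- function(m, fx, fy, h) {
  nx <- nrow(m); ny <- ncol(m)
  # continuous pixel coordinates (1-based at centres)
  cx <- pmin(pmax(fx / h[1] + 0.5, 1), nx)
  cy <- pmin(pmax(fy / h[2] + 0.5, 1), ny)
  i0 <- pmin(floor(cx), nx - 1); j0 <- pmin(floor(cy), ny - 1)
  tx <- cx - i0; ty <- cy - j0
  id <- function(i, j) (j - 1) * nx + i
  v00 <- m[id(i0, j0)]; v10 <- m[id(i0 + 1, j0)]
  v01 <- m[id(i0, j0 + 1)]; v11 <- m[id(i0 + 1, j0 + 1)]
  out <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  matrix(out, nx, ny)
}

# Reaction-diffusion substeps of u restricted to Omega1 = {phi < 0}.
# Dirichlet u = ubar is imposed at the sub-cell interface crossing via
# Gibou-Fedkiw cut-cell second differences (compiled kernel); host walls are
# no-flux. Afterwards the one-pixel ring just outside the interface is held at
# ubar (so pixels entering Omega1 as the front advances start from the
# interface density) and everything beyond the ring is zero.
update_u <- function(u, phi, domain, Df, rho, dt, nsub, ubar,
                     theta_min = 0.35) {
  h <- domain$spacing
  u <- ls_update_u_cpp(u, phi, !domain$domain, Df$Dx, Df$Dy, h[1], h[2],
                       rho, dt, as.integer(nsub), ubar, theta_min)
  inside <- phi < 0 & domain$domain
  ring <- !inside & dilate4(inside)
  u[ring] <- ubar
  u[!inside & !ring] <- 0
  u
}

# One first-order upwind (Godunov) advection step of phi under normal speed v.
advect_phi <- function(phi, v, dt, h) {
  a <- (phi - shift2(phi, 1, 0)) / h[1]    # backward x
  b <- (shift2(phi, -1, 0) - phi) / h[1]   # forward x
  cc <- (phi - shift2(phi, 0, 1)) / h[2]   # backward y
  d <- (shift2(phi, 0, -1) - phi) / h[2]   # forward y
  gpos <- sqrt(pmax(a, 0)^2 + pmin(b, 0)^2 + pmax(cc, 0)^2 + pmin(d, 0)^2)
  gneg <- sqrt(pmin(a, 0)^2 + pmax(b, 0)^2 + pmin(cc, 0)^2 + pmax(d, 0)^2)
  phi - dt * (pmax(v, 0) * gpos + pmin(v, 0) * gneg)
}

# Keep the tumor out of the ventricles: hard clip of phi.
clip_ventricles <- function(phi, domain) {
  hmin <- min(domain$spacing)
  phi[domain$ventricles] <- pmax(phi[domain$ventricles], hmin / 2)
  phi
}

#' Evolve the 2D moving-boundary problem
#'
#' Alternates (i) explicit reaction-diffusion substeps for u inside the tumor
#' region, imposing Dirichlet u = ubar at the sub-cell interface position via
#' cut-cell (Gibou-Fedkiw) stencils with no-flux walls,
#' (ii) first-order upwind advection of phi by the extension velocity under a
#' CFL bound dt <= cfl * min(h) / max|v|, and (iii) signed-distance
#' reinitialisation of phi every `reinit_every` advection steps. Scheduled
#' geometry updates are swapped in at the start of their day and the tumor is
#' clipped against the (possibly moved) ventricles.
#'
#' @param state a `levelset_state`.
#' @param p a `params` (or list with D um^2/h, rho 1/h). `p$D` is ignored if
#'   `Dfield` is given.
#' @param domain a `planar_domain`.
#' @param t_end final time (hours), > state$time.
#' @param Dfield optional spatially varying diffusivity: matrix (um^2/h) or
#'   list(Dx, Dy) for axis-wise values.
#' @param speed_hook optional function(state) returning a normal-speed matrix
#'   (mm/h), bypassing the Stefan velocity (used for verification against
#'   prescribed front motion).
#' @param record_times optional increasing vector of times (hours) at which
#'   intermediate states are stored.
#' @param cfl CFL number for the advection step (default 0.5).
#' @param max_dt cap on the advection step (hours), keeping the
#'   velocity-density coupling tight even when the front is slow.
#' @param reinit_every reinitialise phi after this many advection steps.
#' @return list with `state` (at t_end) and `history` (named list of states at
#'   `record_times`, including t_end if requested).
#' @export
evolve <- function(state, p, domain, t_end, Dfield = NULL, speed_hook = NULL,
                   record_times = NULL, cfl = 0.5, max_dt = 6,
                   reinit_every = 5) {
  stopifnot(inherits(state, "levelset_state"), inherits(domain, "planar_domain"))
  if (t_end <= state$time) stop("evolve: t_end must exceed state$time")
  p <- list(D = p$D, rho = p$rho)
  Df <- normalize_Dfield(if (is.null(Dfield)) p$D else Dfield, domain$shape)
  h <- domain$spacing
  # stability limit for the explicit interior diffusion update
  # stability of the cut-cell stencils is governed by the clamped minimum
  # interface distance theta_min = 0.35 (diagonal coefficient ~ 2D/(theta h)^2)
  Dmax <- max(Df$Dx, Df$Dy)
  dt_u <- if (Dmax > 0) {
    0.8 * 0.35^2 / (2 * Dmax * (1 / h[1]^2 + 1 / h[2]^2))
  } else max_dt
  record_times <- sort(unique(c(record_times, t_end)))
  history <- list()
  # geometry update days falling inside (state$time, t_end]
  upd_days <- if (is.null(domain$updates)) integer(0) else
    as.integer(names(domain$updates))
  phi <- clip_ventricles(state$phi, domain)
  u <- state$u
  t <- state$time
  steps <- 0L
  cur_domain <- domain
  pending_upd <- upd_days[day_to_hours(upd_days) > t]
  while (t < t_end - 1e-9) {
    # swap geometry at the start of an update day (day boundary inclusive)
    while (length(pending_upd) && t >= day_to_hours(pending_upd[1]) - 1e-9) {
      rep_geom <- domain$updates[[as.character(pending_upd[1])]]
      cur_domain <- planar_domain(domain$shape, domain$spacing,
                                  rep_geom$brain %||% cur_domain$brain,
                                  rep_geom$ventricles %||% cur_domain$ventricles)
      phi <- clip_ventricles(phi, cur_domain)
      pending_upd <- pending_upd[-1]
    }
    st <- structure(list(phi = phi, u = u, time = t, ubar = state$ubar,
                         spacing = h), class = "levelset_state")
    v <- if (is.null(speed_hook)) interface_velocity(st, Df_to_um(Df))
         else speed_hook(st)
    vmax <- max(abs(v))
    dt <- min(max_dt, t_end - t)
    if (length(pending_upd))
      dt <- min(dt, day_to_hours(pending_upd[1]) - t)
    if (vmax > 0) dt <- min(dt, cfl * min(h) / vmax)
    if (length(record_times)) {
      nxt <- record_times[record_times > t + 1e-9][1]
      if (!is.na(nxt)) dt <- min(dt, nxt - t)
    }
    # density substeps over dt (phi frozen inside the compiled kernel)
    n_sub <- max(1L, ceiling(dt / dt_u))
    u <- update_u(u, phi, cur_domain, Df, p$rho, dt / n_sub, n_sub, state$ubar)
    # interface advection
    phi <- advect_phi(phi, v, dt, h)
    phi <- clip_ventricles(phi, cur_domain)
    t <- t + dt
    steps <- steps + 1L
    if (steps %% reinit_every == 0L)
      phi <- signed_distance_to_zero(phi, h, keep_band = 1.5 * min(h))
    if (!any(phi < 0)) stop("evolve: tumor region vanished")
    if (any(abs(t - record_times) < 1e-6)) {
      phi_r <- signed_distance_to_zero(phi, h, keep_band = 1.5 * min(h))
      history[[sprintf("t%g", t)]] <-
        structure(list(phi = phi_r, u = u, time = t, ubar = state$ubar,
                       spacing = h), class = "levelset_state")
    }
  }
  final <- history[[sprintf("t%g", t_end)]]
  if (is.null(final)) {
    phi <- signed_distance_to_zero(phi, h, keep_band = 1.5 * min(h))
    final <- structure(list(phi = phi, u = u, time = t_end, ubar = state$ubar,
                            spacing = h), class = "levelset_state")
  }
  list(state = final, history = history)
}

# interface_velocity expects um^2/h inputs; convert a normalized mm^2/h field
# back (kept separate so the public function keeps a single unit convention).
Df_to_um <- function(Df) list(Dx = Df$Dx * 1e6, Dy = Df$Dy * 1e6)

#' Extract the tumor boundary as a closed polyline
#'
#' Marching-squares contour of phi = 0 with linear interpolation; the largest
#' connected contour (by vertex count) is returned, any others are reported in
#' a message.
#'
#' @param state a `levelset_state`.
#' @param day optional day label attached to the curve.
#' @return a `boundary_curve`: matrix with columns x, y (mm), first vertex not
#'   repeated; attribute "day".
#' @export
extract_boundary <- function(state, day = NULL) {
  segs <- zero_contours(state$phi, state$spacing)
  if (length(segs) == 0L) stop("extract_boundary: no zero contour")
  sizes <- vapply(segs, function(s) length(s$x), 0L)
  if (length(segs) > 1L)
    message(sprintf("extract_boundary: %d secondary contour(s) ignored",
                    length(segs) - 1L))
  s <- segs[[which.max(sizes)]]
  xy <- cbind(x = s$x, y = s$y)
  # contourLines may repeat the closing vertex on closed curves
  n <- nrow(xy)
  if (n > 1L && all(abs(xy[1, ] - xy[n, ]) < 1e-12)) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3L) stop("extract_boundary: degenerate contour")
  attr(xy, "day") <- day
  class(xy) <- c("boundary_curve", class(xy))
  xy
}

#' Polygon area by the shoelace formula
#' @param curve a `boundary_curve` or n x 2 matrix (closure implicit).
#' @return absolute enclosed area (mm^2).
#' @export
polygon_area <- function(curve) {
  x <- curve[, 1]; y <- curve[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Fit the 2D moving-boundary model to a per-day boundary series
#'
#' Nelder-Mead over (log D, log rho) minimizing the weighted total error
#' E2 = z_d + 10 sum_t d_J,t between the simulated and observed tumors over
#' the follow-up days. Observed data comprise per-day masks (for the Jaccard
#' term) and boundary polylines (for the z_d term; derived from the masks when
#' not supplied). Deterministic.
#'
#' @param series2d list with `days` (integer vector, >= 2 entries), `masks`
#'   (list of logical matrices, one per day) and optionally `boundaries`
#'   (list of polylines for the follow-up days).
#' @param domain a `planar_domain`.
#' @param cfg a `fit_config` (guess, tolerances, u0, threshold reused; the
#'   threshold doubles as the interface density ubar).
#' @return a `fit_result`-like list with `params`, `E2`, `z_d`, `jaccards`,
#'   `evals`, `converged`.
#' @export
fit_levelset <- function(series2d, domain, cfg = fit_config()) {
  days <- as.integer(series2d$days)
  stopifnot(length(days) >= 2L, length(series2d$masks) == length(days))
  follow <- seq_along(days)[-1]
  data_bnd <- series2d$boundaries
  if (is.null(data_bnd)) {
    data_bnd <- lapply(follow, function(k)
      mask_boundary_curve(series2d$masks[[k]], domain$spacing))
  }
  eval_E2 <- function(p) {
    st0 <- init_state(series2d$masks[[1]], domain, u0 = cfg$u0,
                      ubar = cfg$threshold, time = day_to_hours(days[1]))
    res <- tryCatch(
      evolve(st0, p, domain, day_to_hours(days[length(days)]),
             record_times = day_to_hours(days[-1])),
      error = function(e) NULL)
    if (is.null(res)) return(list(E2 = 1e6, z_d = NA, jac = rep(NA, length(follow))))
    sim_bnd <- list(); jac <- numeric(0)
    for (k in follow) {
      st <- res$history[[sprintf("t%g", day_to_hours(days[k]))]]
      sim_mask <- st$phi < 0
      jac <- c(jac, jaccard_distance(sim_mask, series2d$masks[[k]]))
      sim_bnd[[length(sim_bnd) + 1L]] <- extract_boundary(st)
    }
    z <- boundary_distance_error(sim_bnd, data_bnd)
    list(E2 = total_error_E2(z, jac), z_d = z, jac = jac)
  }
  opt <- minimize_logparams(function(p) eval_E2(p)$E2, cfg$guess, cfg)
  fin <- eval_E2(opt$par)
  list(params = opt$par, E2 = fin$E2, z_d = fin$z_d, jaccards = fin$jac,
       evals = opt$evals, converged = opt$converged,
       provenance = provenance(config = cfg))
}

#' Boundary polyline of a binary 2D mask
#' @param mask logical matrix.
#' @param spacing in-plane spacing (mm pair).
#' @return a `boundary_curve` (largest connected boundary).
#' @export
mask_boundary_curve <- function(mask, spacing) {
  ind <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  st <- structure(list(phi = 0.5 - ind, spacing = spacing),
                  class = "levelset_state")
  extract_boundary(st)
}
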