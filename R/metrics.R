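#' Jaccard distance between two masks
#'
#' d_J(A, B) = 1 - |A intersect B| / |A union B|. Identical sets give 0,
#' disjoint nonempty sets give 1. Two empty sets are defined to match perfectly
#' (d_J = 0): an empty prediction of an empty observation is not an error; the
#' 0/0 case is resolved that way and a message is logged when it occurs.
#'
#' @param A,B logical arrays over the same grid (same dimensions).
#' @return scalar in [0, 1].
#' @export
jaccard_distance <- function(A, B) {
  if (!all(dim(A) == dim(B)))
    stop("jaccard_distance: masks are on different grids")
  inter <- sum(A & B)
  union <- sum(A | B)
  if (union == 0L) {
    message("jaccard_distance: both masks empty; returning 0 by convention")
    return(0)
  }
  1 - inter / union
}

#' Per-day Jaccard errors and their aggregate
#'
#' Compares simulated visible-tumor masks with the observed series over the
#' follow-up days (the initialisation day is excluded from n). The aggregate is
#' either the time average of the per-day Jaccard distances (`mode = "mean"`,
#' used to report constant-parameter fits) or their plain sum (`mode = "sum"`,
#' used to summarise per-interval fits).
#'
#' @param sim_masks named or ordered list of logical arrays for the follow-up
#'   days (must align with `obs$days[-1]`, or with all of `obs$days` if a mask
#'   for the initialisation day is supplied too, in which case it is dropped).
#' @param obs an `imaging_series`.
#' @param mode "mean" or "sum".
#' @return an `error_report`: list with `per_day` (named numeric), `aggregate`,
#'   `mode`, `n`.
#' @export
series_error <- function(sim_masks, obs, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  follow <- obs$days[-1]
  if (length(sim_masks) == length(obs$days)) sim_masks <- sim_masks[-1]
  if (length(sim_masks) != length(follow))
    stop("series_error: day lists do not align")
  d <- vapply(seq_along(follow), function(k) {
    jaccard_distance(sim_masks[[k]], obs$masks[[k + 1L]])
  }, 0)
  names(d) <- paste0("day", follow)
  error_report(d, mode)
}

#' Assemble an error report from per-day Jaccard distances
#' @param per_day numeric vector of per-day Jaccard distances in [0, 1].
#' @param mode aggregation mode, "mean" or "sum".
#' @return an `error_report`.
#' @export
error_report <- function(per_day, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (any(per_day < 0 | per_day > 1)) stop("error_report: d_J outside [0, 1]")
  agg <- if (mode == "mean") mean(per_day) else sum(per_day)
  structure(list(per_day = per_day, aggregate = agg, mode = mode,
                 n = length(per_day)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report (%s over n = %d): %.4f  [%s]\n", x$mode, x$n,
              x$aggregate, paste(sprintf("%.4f", x$per_day), collapse = ", ")))
  invisible(x)
}

#' Traveling-wave front speed implied by the model parameters
#'
#' The Fisher-KPP front advances asymptotically at c = 2 sqrt(D rho).
#'
#' @param p a `params` (D in um^2/h, rho in 1/h), or a numeric D with `rho`
#'   given separately.
#' @param rho proliferation rate if `p` is numeric.
#' @return wave speed in um/h.
#' @export
wave_speed <- function(p, rho = NULL) {
  if (inherits(p, "params")) return(2 * sqrt(p$D * p$rho))
  2 * sqrt(p * rho)
}

#' Convert a speed from um/h to cm/yr
#'
#' 1 um/h = 8760 h/yr / 1e4 um/cm = 0.876 cm/yr.
#'
#' @param speed_umh speed in um/h (>= 0).
#' @return speed in cm/yr.
#' @export
umh_to_cmyr <- function(speed_umh) {
  if (any(speed_umh < 0)) stop("umh_to_cmyr: negative speed")
  speed_umh * 8760 / 1e4
}

#' Convert a speed from cm/yr to um/h
#' @param speed_cmyr speed in cm/yr (>= 0).
#' @return speed in um/h.
#' @export
cmyr_to_umh <- function(speed_cmyr) {
  if (any(speed_cmyr < 0)) stop("cmyr_to_umh: negative speed")
  speed_cmyr * 1e4 / 8760
}

#' Visible tumor volume of a mask
#' @param mask logical 3D array.
#' @param grid a `grid3d`.
#' @return volume in mm^3 (voxel count times voxel volume).
#' @export
visible_volume <- function(mask, grid) {
  mask <- check_mask_array(mask, grid, "mask")
  sum(mask) * voxel_volume(grid)
}

#' Relative invasiveness log10(D / rho)
#'
#' Small values correspond to nodular growth, large values to diffuse growth.
#' Dimensionally D/rho is a squared length (um^2); the conventional report uses
#' D in um^2/h and rho in 1/h.
#'
#' @param p a `params`.
#' @return log10(D / rho).
#' @export
relative_invasiveness <- function(p) {
  stopifnot(inherits(p, "params"))
  log10(p$D / p$rho)
}

#' Percent decrease of a value relative to a reference
#' @param reference positive baseline value.
#' @param value comparison value.
#' @return 100 * (reference - value) / reference.
#' @export
percent_decrease <- function(reference, value) {
  if (any(reference <= 0)) stop("percent_decrease: reference must be positive")
  100 * (reference - value) / reference
}

# Minimum distances from points to a closed polygon's segments.
# pts: n x 2 matrix; poly: m x 2 matrix of vertices (closure implicit).
point_to_polygon_distance <- function(pts, poly) {
  m <- nrow(poly)
  if (m < 3L) stop("polygon needs at least 3 vertices")
  a <- poly
  b <- poly[c(2:m, 1L), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(m)) {
    dx <- pts[, 1] - a[s, 1]; dy <- pts[, 2] - a[s, 2]
    if (len2[s] < 1e-300) {
      d2 <- dx^2 + dy^2
    } else {
      t <- pmin(1, pmax(0, (dx * ab[s, 1] + dy * ab[s, 2]) / len2[s]))
      d2 <- (dx - t * ab[s, 1])^2 + (dy - t * ab[s, 2])^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Boundary distance error z_d between simulated and data boundaries
#'
#' For each compared day the root mean square of the distances from every
#' simulated-boundary vertex to the nearest point of the data boundary (exact
#' point-to-segment distances over the closed data polygon) is computed; z_d is
#' the sum of these RMS values over days. The measure is one-directional by
#' construction (simulated vertices against the data polygon, not vice versa).
#'
#' @param sim_boundaries list of closed polylines (matrices n x 2, mm), one per
#'   compared day; each needs >= 3 vertices, first vertex not repeated.
#' @param data_boundaries list of closed polylines, aligned with
#'   `sim_boundaries` day for day.
#' @return z_d in mm.
#' @export
boundary_distance_error <- function(sim_boundaries, data_boundaries) {
  if (length(sim_boundaries) != length(data_boundaries))
    stop("boundary_distance_error: day lists do not match")
  if (length(sim_boundaries) == 0L) stop("boundary_distance_error: no days")
  z <- 0
  for (t in seq_along(sim_boundaries)) {
    sb <- as.matrix(sim_boundaries[[t]])
    db <- as.matrix(data_boundaries[[t]])
    if (nrow(sb) < 3L || nrow(db) < 3L)
      stop("boundary_distance_error: boundaries need >= 3 vertices")
    d <- point_to_polygon_distance(sb, db)
    z <- z + sqrt(mean(d^2))
  }
  z
}

#' Weighted total error E2 for the 2D moving-boundary fit
#'
#' E2 = z_d + 10 * sum_t d_J,t. The factor of 10 puts the boundary-position
#' term and the Jaccard term on comparable scales.
#'
#' @param z_d boundary distance error (mm).
#' @param jaccards numeric vector of per-day Jaccard distances.
#' @return E2.
#' @export
total_error_E2 <- function(z_d, jaccards) {
  stopifnot(is.finite(z_d), all(is.finite(jaccards)))
  z_d + 10 * sum(jaccards)
}
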