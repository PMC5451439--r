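#' Map the Jaccard error surface E(D, rho) over a parameter grid
#'
#' Evaluates the Hypothesis-1 objective at every node of a (D, rho) grid.
#' Because the model's observable dynamics are dominated by the front speed
#' c = 2 sqrt(D rho), the surface typically shows a low-error valley running
#' along curves of constant c — the practical-nonidentifiability structure.
#' Per-node solver failures are recorded as NA rather than aborting the map.
#'
#' @param series an `imaging_series`.
#' @param D_grid sorted positive diffusion values (um^2/h); the default spans
#'   the fitted murine range, log-spaced 50-2000 um^2/h.
#' @param rho_grid sorted positive proliferation values (1/h); default
#'   log-spaced 0.005-0.06 1/h.
#' @param cfg a `fit_config`.
#' @return an `error_surface`: list with `D`, `rho`, `E` (matrix
#'   length(D) x length(rho)), `meta`.
#' @export
compute_error_surface <- function(series,
                                  D_grid = exp(seq(log(50), log(2000), length.out = 25)),
                                  rho_grid = exp(seq(log(0.005), log(0.06), length.out = 25)),
                                  cfg = fit_config()) {
  stopifnot(all(D_grid > 0), all(rho_grid > 0),
            !is.unsorted(D_grid), !is.unsorted(rho_grid))
  stencil <- domain_stencil(series$geometry)
  E <- matrix(NA_real_, length(D_grid), length(rho_grid),
              dimnames = list(sprintf("D=%.4g", D_grid),
                              sprintf("rho=%.4g", rho_grid)))
  n <- length(series$days) - 1L
  for (i in seq_along(D_grid)) {
    for (j in seq_along(rho_grid)) {
      val <- objective_h1(params(D_grid[i], rho_grid[j]), series, cfg, stencil)
      E[i, j] <- if (val > 1) NA_real_ else val  # penalty => failed node
    }
  }
  structure(list(D = D_grid, rho = rho_grid, E = E,
                 meta = list(n = n, config_hash = config_hash(cfg))),
            class = "error_surface")
}

#' Constant-wave-speed arc rho(D) = c^2 / (4 D)
#'
#' The locus of (D, rho) pairs sharing front speed c; every sampled point
#' satisfies 2 sqrt(D rho(D)) = c to machine precision.
#'
#' @param c wave speed in um/h (> 0).
#' @param D_range positive interval of D (um^2/h) to sample.
#' @param n number of samples (log-spaced).
#' @return data.frame with columns D, rho.
#' @export
wavespeed_arc <- function(c, D_range, n = 100) {
  stopifnot(c > 0, length(D_range) == 2L, all(D_range > 0))
  D <- exp(seq(log(D_range[1]), log(D_range[2]), length.out = n))
  data.frame(D = D, rho = c^2 / (4 * D))
}

# Bilinear interpolation of the E matrix at (D, rho) points (log-space in the
# axes since the grids are typically log-spaced). Returns NA outside the hull.
interp_surface <- function(surface, D, rho) {
  lx <- log(surface$D); ly <- log(surface$rho)
  px <- log(D); py <- log(rho)
  out <- rep(NA_real_, length(px))
  ix <- findInterval(px, lx)
  iy <- findInterval(py, ly)
  ok <- ix >= 1 & ix < length(lx) & iy >= 1 & iy < length(ly)
  for (k in which(ok)) {
    x1 <- lx[ix[k]]; x2 <- lx[ix[k] + 1]
    y1 <- ly[iy[k]]; y2 <- ly[iy[k] + 1]
    tx <- (px[k] - x1) / (x2 - x1); ty <- (py[k] - y1) / (y2 - y1)
    z <- surface$E[ix[k]:(ix[k] + 1), iy[k]:(iy[k] + 1)]
    if (any(is.na(z))) next
    out[k] <- (1 - tx) * (1 - ty) * z[1, 1] + tx * (1 - ty) * z[2, 1] +
      (1 - tx) * ty * z[1, 2] + tx * ty * z[2, 2]
  }
  out
}

#' Quantify the flatness of the error surface along a constant-speed arc
#'
#' Samples E along the arc rho(D) = c^2/(4D) where it crosses the surface's
#' grid, and compares the spread of E along the arc with the spread over the
#' whole grid. A small ratio means many (D, rho) combinations along the arc
#' fit the data almost equally well: practical nonidentifiability.
#'
#' @param surface an `error_surface`.
#' @param c wave speed (um/h) defining the arc.
#' @param flat_ratio threshold on (arc range)/(overall range) below which the
#'   surface is flagged practically nonidentifiable (default 0.25; a package
#'   convention, configurable).
#' @return list with `arc_range`, `overall_range`, `ratio`,
#'   `nonidentifiable` (flag), `arc` (sampled points with E values).
#' @export
valley_flatness <- function(surface, c, flat_ratio = 0.25) {
  stopifnot(inherits(surface, "error_surface"), c > 0)
  arc <- wavespeed_arc(c, range(surface$D), n = 200)
  inside <- arc$rho >= min(surface$rho) & arc$rho <= max(surface$rho)
  arc <- arc[inside, , drop = FALSE]
  if (nrow(arc) < 2L)
    stop("valley_flatness: arc does not cross the surface grid")
  arc$E <- interp_surface(surface, arc$D, arc$rho)
  arcE <- arc$E[!is.na(arc$E)]
  if (length(arcE) < 2L)
    stop("valley_flatness: too few valid surface values along the arc")
  allE <- surface$E[!is.na(surface$E)]
  arc_range <- diff(range(arcE))
  overall_range <- diff(range(allE))
  if (overall_range == 0) {
    # perfectly flat surface: degenerate, trivially nonidentifiable
    return(list(arc_range = 0, overall_range = 0, ratio = 0,
                nonidentifiable = TRUE, arc = arc))
  }
  ratio <- arc_range / overall_range
  list(arc_range = arc_range, overall_range = overall_range, ratio = ratio,
       nonidentifiable = ratio < flat_ratio, arc = arc)
}
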