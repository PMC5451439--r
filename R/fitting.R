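#' Fit configuration
#'
#' @param guess initial `params` for the optimizer (default D = 500 um^2/h,
#'   rho = 0.02 1/h, central in the plausible murine range).
#' @param reltol relative convergence tolerance on the objective for the
#'   Nelder-Mead simplex.
#' @param max_evals maximum simplex iterations per fit.
#' @param u0 density painted onto observed masks when (re)building initial
#'   conditions (default 0.5).
#' @param threshold detection threshold for simulated visible tumor.
#' @param solver a `solver_config` used for every forward run.
#' @param h3_reset_mode how Hypothesis-3 resets rebuild the density inside the
#'   observed mask: "u0" paints the constant u0 (default, consistent with the
#'   day-11 initialisation); "carry" keeps the simulated densities inside the
#'   observed mask and zeroes the rest.
#' @return a `fit_config`.
#' @export
fit_config <- function(guess = params(500, 0.02), reltol = 1e-3,
                       max_evals = 300, u0 = 0.5, threshold = 0.16,
                       solver = solver_config(),
                       h3_reset_mode = c("u0", "carry")) {
  h3_reset_mode <- match.arg(h3_reset_mode)
  stopifnot(inherits(guess, "params"), reltol > 0, max_evals >= 1,
            u0 > 0, u0 < 1)
  solver$threshold <- threshold
  structure(list(guess = guess, reltol = reltol, max_evals = max_evals,
                 u0 = u0, threshold = threshold, solver = solver,
                 h3_reset_mode = h3_reset_mode),
            class = "fit_config")
}

# Forward-run a field to the given hours and return thresholded masks.
# Solver failures (instability at extreme trial parameters) yield NULL.
forward_masks <- function(field, p, times, cfg, stencil) {
  fields <- tryCatch(
    integrate_density(field, p, times, cfg$solver, stencil),
    error = function(e) {
      warning("forward solve failed (", conditionMessage(e),
              "); returning penalty", call. = FALSE)
      NULL
    })
  if (is.null(fields)) return(NULL)
  lapply(fields, threshold_to_mask, threshold = cfg$threshold)
}

#' Hypothesis-1 objective: mean Jaccard error of a constant-parameter run
#'
#' Builds the initial condition from the first observed mask (density u0
#' inside), integrates the model across all follow-up days with the given
#' constant parameters, and returns the time-averaged Jaccard distance between
#' simulated and observed visible tumor over those n days. Failed forward
#' solves return a large finite penalty (10 * n) so the simplex can continue.
#'
#' @param p a `params`.
#' @param series an `imaging_series` with >= 2 days.
#' @param cfg a `fit_config`.
#' @param stencil optional precomputed `domain_stencil`.
#' @return mean-mode error in [0, 1] (or the penalty on solver failure).
#' @export
objective_h1 <- function(p, series, cfg = fit_config(), stencil = NULL) {
  stopifnot(inherits(series, "imaging_series"))
  if (is.null(stencil)) stencil <- domain_stencil(series$geometry)
  f0 <- field_from_mask(series$geometry, series$masks[[1]], cfg$u0,
                        day_to_hours(series$days[1]))
  times <- day_to_hours(series$days[-1])
  masks <- forward_masks(f0, p, times, cfg, stencil)
  n <- length(times)
  if (is.null(masks)) return(10 * n)
  series_error(masks, series, mode = "mean")$aggregate
}

# Nelder-Mead over (log D, log rho); guarantees positivity of every evaluated
# point and returns the best point seen (never worse than the initial guess).
minimize_logparams <- function(fn, guess, cfg) {
  f0 <- fn(guess)
  res <- stats::optim(log(c(guess$D, guess$rho)),
                      function(lp) fn(params(exp(lp[1]), exp(lp[2]))),
                      method = "Nelder-Mead",
                      control = list(reltol = cfg$reltol,
                                     maxit = cfg$max_evals))
  best_p <- params(exp(res$par[1]), exp(res$par[2]))
  best_f <- res$value
  if (f0 <= best_f) {           # best-so-far contract
    best_p <- guess
    best_f <- f0
  }
  list(par = best_p, value = best_f, evals = res$counts[["function"]],
       converged = res$convergence == 0)
}

new_fit_result <- function(hypothesis, intervals, par_list, per_day, evals,
                           converged, cfg) {
  structure(list(
    hypothesis = hypothesis,
    intervals = intervals,
    params = par_list,
    errors_mean = error_report(per_day, "mean"),
    errors_sum = error_report(per_day, "sum"),
    evals = evals,
    converged = converged,
    provenance = provenance(config = cfg)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (Hypothesis %d), %s\n", x$hypothesis,
              if (x$converged) "converged" else "NOT converged"))
  for (k in seq_along(x$params)) {
    p <- x$params[[k]]
    cat(sprintf("  days %2d-%2d: D = %8.2f um^2/h, rho = %7.4f 1/h, c = %6.4f um/h\n",
                x$intervals[[k]][1], x$intervals[[k]][2], p$D, p$rho,
                wave_speed(p)))
  }
  cat(sprintf("  error: mean %.4f / sum %.4f over n = %d\n",
              x$errors_mean$aggregate, x$errors_sum$aggregate, x$errors_mean$n))
  invisible(x)
}

#' Fit Hypothesis 1: constant parameters over the whole series
#'
#' Nelder-Mead over (log D, log rho) minimizing the mean Jaccard error of the
#' full forward run; deterministic given inputs.
#'
#' @param series an `imaging_series`.
#' @param cfg a `fit_config`.
#' @return a `fit_result` with one parameter pair.
#' @export
fit_hypothesis1 <- function(series, cfg = fit_config()) {
  stencil <- domain_stencil(series$geometry)
  opt <- minimize_logparams(function(p) objective_h1(p, series, cfg, stencil),
                            cfg$guess, cfg)
  # recompute per-day errors at the optimum
  f0 <- field_from_mask(series$geometry, series$masks[[1]], cfg$u0,
                        day_to_hours(series$days[1]))
  masks <- forward_masks(f0, opt$par, day_to_hours(series$days[-1]), cfg, stencil)
  per_day <- series_error(masks, series, "mean")$per_day
  new_fit_result(1L, list(range(series$days)), list(opt$par), per_day,
                 opt$evals, opt$converged, cfg)
}

# Fit one inter-scan interval: single-day Jaccard between the forward run of
# `field0` and the observed mask at the interval end.
fit_interval <- function(field0, obs_mask, t_end, cfg, stencil) {
  fn <- function(p) {
    masks <- forward_masks(field0, p, t_end, cfg, stencil)
    if (is.null(masks)) return(10)
    jaccard_distance(masks[[1]], obs_mask)
  }
  minimize_logparams(fn, cfg$guess, cfg)
}

#' Fit Hypothesis 2: per-interval parameters, simulated state carried forward
#'
#' Parameters are re-optimized between successive imaging time points; the
#' continuous (unthresholded) simulated density at each interval end becomes
#' the next interval's initial condition. Per-interval error is the single-day
#' Jaccard distance; the headline aggregate is the sum over intervals.
#'
#' @param series an `imaging_series`.
#' @param cfg a `fit_config`.
#' @return a `fit_result` with one parameter pair per interval.
#' @export
fit_hypothesis2 <- function(series, cfg = fit_config()) {
  stencil <- domain_stencil(series$geometry)
  field <- field_from_mask(series$geometry, series$masks[[1]], cfg$u0,
                           day_to_hours(series$days[1]))
  n_int <- length(series$days) - 1L
  par_list <- vector("list", n_int)
  per_day <- numeric(n_int)
  evals <- 0L; converged <- TRUE
  intervals <- vector("list", n_int)
  for (k in seq_len(n_int)) {
    t_end <- day_to_hours(series$days[k + 1L])
    obs <- series$masks[[k + 1L]]
    opt <- fit_interval(field, obs, t_end, cfg, stencil)
    par_list[[k]] <- opt$par
    evals <- evals + opt$evals
    converged <- converged && opt$converged
    intervals[[k]] <- c(series$days[k], series$days[k + 1L])
    adv <- integrate_density(field, opt$par, t_end, cfg$solver, stencil)[[1]]
    per_day[k] <- jaccard_distance(threshold_to_mask(adv, cfg$threshold), obs)
    field <- adv
  }
  names(per_day) <- paste0("day", series$days[-1])
  new_fit_result(2L, intervals, par_list, per_day, evals, converged, cfg)
}

#' Fit Hypothesis 3: per-interval parameters with initial-condition resets
#'
#' Like Hypothesis 2, but at each imaging time point the state is rebuilt from
#' the observed mask (density u0 inside by default) before fitting the next
#' interval — a predictor-corrector scheme. Per-interval errors are those of
#' the predictions made before each reset.
#'
#' @param series an `imaging_series`.
#' @param cfg a `fit_config` (see `h3_reset_mode`).
#' @return a `fit_result`.
#' @export
fit_hypothesis3 <- function(series, cfg = fit_config()) {
  stencil <- domain_stencil(series$geometry)
  geom <- series$geometry
  field <- field_from_mask(geom, series$masks[[1]], cfg$u0,
                           day_to_hours(series$days[1]))
  n_int <- length(series$days) - 1L
  par_list <- vector("list", n_int)
  per_day <- numeric(n_int)
  evals <- 0L; converged <- TRUE
  intervals <- vector("list", n_int)
  for (k in seq_len(n_int)) {
    t_end <- day_to_hours(series$days[k + 1L])
    obs <- series$masks[[k + 1L]]
    opt <- fit_interval(field, obs, t_end, cfg, stencil)
    par_list[[k]] <- opt$par
    evals <- evals + opt$evals
    converged <- converged && opt$converged
    intervals[[k]] <- c(series$days[k], series$days[k + 1L])
    adv <- integrate_density(field, opt$par, t_end, cfg$solver, stencil)[[1]]
    per_day[k] <- jaccard_distance(threshold_to_mask(adv, cfg$threshold), obs)
    # reset from the observed mask for the next interval
    field <- if (cfg$h3_reset_mode == "u0") {
      field_from_mask(geom, obs, cfg$u0, t_end)
    } else {
      vals <- adv$values
      vals[!(obs & geom$domain_mask)] <- 0
      density_field(geom, vals, t_end, tol = cfg$solver$clamp_check)
    }
  }
  names(per_day) <- paste0("day", series$days[-1])
  new_fit_result(3L, intervals, par_list, per_day, evals, converged, cfg)
}

#' Sensitivity of the Hypothesis-1 fit to the assumed initial density
#'
#' Repeats the Hypothesis-1 fit with different densities painted onto the
#' initial visible-tumor mask and tabulates the fitted parameters and implied
#' wave speeds. The estimated D and rho trade off against each other, but the
#' wave speed 2 sqrt(D rho) is expected to be nearly invariant.
#'
#' @param series an `imaging_series`.
#' @param cfg a `fit_config` (its u0 is replaced per row).
#' @param densities vector of initial densities in (0, 1);
#'   default c(0.3, 0.5, 0.7).
#' @return data.frame with columns u0, D_um2_per_h, rho_per_h, speed_um_per_h,
#'   error_mean; the fits themselves are attached as attribute "fits".
#' @export
sensitivity_initial_density <- function(series, cfg = fit_config(),
                                        densities = c(0.3, 0.5, 0.7)) {
  stopifnot(all(densities > 0 & densities < 1))
  fits <- lapply(densities, function(d) {
    cfg_d <- cfg
    cfg_d$u0 <- d
    fit_hypothesis1(series, cfg_d)
  })
  tab <- data.frame(
    u0 = densities,
    D_um2_per_h = vapply(fits, function(f) f$params[[1]]$D, 0),
    rho_per_h = vapply(fits, function(f) f$params[[1]]$rho, 0),
    speed_um_per_h = vapply(fits, function(f) wave_speed(f$params[[1]]), 0),
    error_mean = vapply(fits, function(f) f$errors_mean$aggregate, 0))
  attr(tab, "fits") <- fits
  tab
}
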