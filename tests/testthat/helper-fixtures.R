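# Shared fixtures and independent reference implementations used across the
# test files. Everything here is generated in code at test time.

# A small, fast phantom for unit tests (coarser grid than the study default).
small_phantom_spec <- function(...) {
  phantom_spec(grid = grid3d(c(36, 36, 12), c(0.15, 0.15, 0.6)),
               brain_semiaxes = c(2.4, 2.4, 3.2),
               seed_radius = 0.6, ...)
}

# Cached default-phantom ground truth (noiseless) for tests that share it.
.default_gt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_ground_truth(phantom_spec())
    cache
  }
})

# Fixed 10-phantom recovery suite spanning the murine parameter range.
recovery_suite <- function() {
  Dseq <- exp(seq(log(100), log(1500), length.out = 10))
  rseq <- exp(seq(log(0.005), log(0.05), length.out = 10))
  perm <- c(5, 8, 2, 9, 4, 10, 1, 6, 3, 7)
  data.frame(D = Dseq, rho = rseq[perm])
}

# Independent 1D radial reference for the moving-boundary (Stefan) problem:
# front-fixing coordinate xi = r/R(t), explicit Euler on a fine radial grid.
# u_t = D (u_rr + u_r / r) + rho u (1 - u) inside r < R(t), u(R) = ubar,
# symmetric at r = 0, and R' = -(D/ubar) u_r(R).
radial_stefan_reference <- function(D_um2h, rho, R0_mm, t_hours,
                                    u0 = 0.5, ubar = 0.16, N = 250) {
  D <- D_um2h * 1e-6
  dxi <- 1 / N
  xi <- seq(0, 1, length.out = N + 1)
  u <- rep(u0, N + 1); u[N + 1] <- ubar
  R <- R0_mm; t <- 0
  t_hours <- sort(t_hours)
  out <- numeric(length(t_hours)); oi <- 1
  repeat {
    if (oi > length(t_hours)) break
    dt <- min(0.2 * dxi^2 * R^2 / D, t_hours[oi] - t)
    uxi1 <- (3 * u[N + 1] - 4 * u[N] + u[N - 1]) / (2 * dxi)
    Rp <- -(D / (ubar * R)) * uxi1
    i <- 2:N
    u_xx <- (u[i + 1] - 2 * u[i] + u[i - 1]) / dxi^2
    u_x <- (u[i + 1] - u[i - 1]) / (2 * dxi)
    du <- numeric(N + 1)
    du[i] <- D * (u_xx + u_x / xi[i]) / R^2 + (xi[i] * Rp / R) * u_x +
      rho * u[i] * (1 - u[i])
    du[1] <- D * 4 * (u[2] - u[1]) / dxi^2 / R^2 + rho * u[1] * (1 - u[1])
    u <- pmin(1, pmax(0, u + dt * du))
    u[N + 1] <- ubar
    R <- R + dt * Rp
    t <- t + dt
    if (abs(t - t_hours[oi]) < 1e-9) { out[oi] <- R; oi <- oi + 1 }
  }
  out
}

# All-brain planar disk domain with a centred disk tumor mask.
disk_fixture <- function(n = 81L, spacing = 0.1, R0 = 1.0) {
  dom <- planar_domain(c(n, n), c(spacing, spacing), matrix(TRUE, n, n))
  ax <- (seq_len(n) - 0.5) * spacing
  cc <- mean(range(ax))
  mask <- sqrt(outer((ax - cc)^2, (ax - cc)^2, "+")) <= R0
  list(dom = dom, mask = mask, ax = ax, center = cc)
}
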