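#' Integrate the model under constant drive
#'
#' Adaptive-step integration of the full nonlinear equations from
#' `(u0, w0)` with constant applied current `I`, using `deSolve`'s lsoda,
#' which switches automatically between non-stiff and stiff (BDF) methods
#' -- the relevant regime for `epsilon << 1`, where the limit cycle is a
#' relaxation oscillation with fast voltage jumps. The dense solution is
#' returned on a uniform grid of at least 2000 samples.
#'
#' @param model An `fhn_model` or preset name.
#' @param I Applied current, amperes.
#' @param u0,w0 Initial state (V, A).
#' @param t_end Integration horizon, seconds (> 0).
#' @param rel_tol,abs_tol Solver tolerances.
#' @param n_out Number of output samples (minimum 2000).
#' @return An object of class `fhn_trajectory`: a list with fields `t`
#'   (s), `u` (V), `w` (A), `drive_I` (A) and `params` (the model).
#' @examples
#' tr <- fhn_simulate("F", I = 0, u0 = 0.1, w0 = 0, t_end = 50)
#' @export
fhn_simulate <- function(model, I, u0, w0, t_end,
                         rel_tol = 1e-8, abs_tol = 1e-10, n_out = 2000L) {
  m <- as_fhn_model(model)
  stopifnot(is.finite(I), is.finite(u0), is.finite(w0))
  if (!(is.numeric(t_end) && length(t_end) == 1L && t_end > 0))
    stop("'t_end' must be positive", call. = FALSE)
  if (!(rel_tol > 0 && abs_tol > 0))
    stop("solver tolerances must be positive", call. = FALSE)
  n_out <- max(2000L, as.integer(n_out))
  C_m <- m$tau_m / m$R_I
  deriv <- function(t, y, parms) {
    du <- (I - (y[1]^3 / (3 * m$u_1^2) - y[1]) / m$R_I - y[2]) / C_m
    dw <- (y[1] / m$R_w - m$b * y[2]) / m$tau_k
    list(c(du, dw))
  }
  times <- seq(0, t_end, length.out = n_out)
  out <- deSolve::ode(y = c(u = u0, w = w0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rel_tol, atol = abs_tol)
  if (nrow(out) < n_out || any(!is.finite(out[, 2:3])))
    stop(sprintf("integration failed at t = %g s", out[nrow(out), 1]),
         call. = FALSE)
  structure(list(t = out[, 1], u = out[, 2], w = out[, 3],
                 drive_I = I, params = m),
            class = "fhn_trajectory")
}

#' @export
print.fhn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples over %g s at I = %g A; u in [%g, %g] V\n",
              length(x$t), max(x$t), x$drive_I, min(x$u), max(x$u)))
  invisible(x)
}

#' @export
as.data.frame.fhn_trajectory <- function(x, ...) {
  data.frame(t = x$t, u = x$u, w = x$w)
}

#' @export
plot.fhn_trajectory <- function(x, ...) {
  graphics::plot(x$t, x$u, type = "l", xlab = "t (s)", ylab = "u (V)", ...)
  invisible(x)
}

#' Response to a voltage step off a fixed point
#'
#' Locates the fixed point for drive `I` (when several exist, the one
#' nearest `u = 0` -- the middle branch the bistable and oscillatory
#' experiments are centered on), displaces the voltage by `delta_u` at
#' unchanged recovery current, and integrates. The default horizon is 200
#' times the slower of the two response times, covering on the order of a
#' hundred slow cycles (for an excitable membrane the slow time is
#' `tau_k`).
#'
#' @param model An `fhn_model` or preset name.
#' @param I Applied current, amperes.
#' @param delta_u Voltage perturbation, volts (default +1).
#' @param t_end Horizon, seconds; defaults to `200 * max(tau_k, tau_m)`.
#' @param n_out Output samples; the denser default resolves the fast
#'   voltage jumps of relaxation oscillations (>100 samples per slow
#'   cycle).
#' @param ... Passed to [fhn_simulate()].
#' @return An `fhn_trajectory`.
#' @export
perturbation_response <- function(model, I, delta_u = 1, t_end = NULL,
                                  n_out = 20000L, ...) {
  m <- as_fhn_model(model)
  fp <- fixed_points(I, m)
  i <- which.min(abs(fp$u))
  if (is.null(t_end)) t_end <- 200 * max(m$tau_k, m$tau_m)
  fhn_simulate(m, I, u0 = fp$u[i] + delta_u, w0 = fp$w[i], t_end = t_end,
               n_out = n_out, ...)
}

# Parabolic refinement of a discrete maximum at index i of series (t, y):
# returns c(t_peak, y_peak).
refine_peak <- function(t, y, i) {
  if (i <= 1L || i >= length(y)) return(c(t[i], y[i]))
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  den <- y0 - 2 * y1 + y2
  if (den == 0) return(c(t[i], y[i]))
  d <- 0.5 * (y0 - y2) / den
  d <- min(1, max(-1, d))
  dt <- t[i + 1] - t[i]
  c(t[i] + d * dt, y1 - 0.25 * (y0 - y2) * d)
}

#' Classify the long-time behavior of a trajectory
#'
#' Discards the first half of the record as transient and inspects the
#' voltage peaks (parabolically interpolated through the three samples
#' around each discrete maximum):
#' \describe{
#'   \item{sustained_oscillation}{at least 5 successive peaks whose period
#'     and amplitude both vary by less than 1% (coefficient of variation);
#'     reports `period` (s) and the peak-to-peak `amplitude_pp` (V).}
#'   \item{damped_oscillation}{at least 3 peaks with monotonically
#'     shrinking amplitude; reports `ring_frequency` (rad/s, from the mean
#'     inter-peak interval) and `decay_rate` (1/s, from a log-linear fit
#'     of the peak envelope).}
#'   \item{monotonic_decay}{no sign change of `du/dt` in the analysis
#'     window and a terminal state within 1e-4 V of a fixed point;
#'     reports `terminal_u`.}
#'   \item{jump_to_sink}{terminal fixed point different from the one
#'     nearest the initial condition; reports `terminal_u`.}
#' }
#' A trajectory matching none of the patterns raises an error suggesting
#' a longer horizon.
#'
#' @param traj An `fhn_trajectory` spanning at least `10 * tau_k`.
#' @return An object of class `fhn_oscillation`: a list with fields
#'   `kind` and the kind-specific metrics above.
#' @export
oscillation_metrics <- function(traj) {
  stopifnot(inherits(traj, "fhn_trajectory"))
  m <- traj$params
  if (max(traj$t) < 10 * m$tau_k)
    stop("trajectory too short: need at least 10 * tau_k", call. = FALSE)
  i0 <- floor(length(traj$t) / 2)
  t <- traj$t[i0:length(traj$t)]
  u <- traj$u[i0:length(traj$u)]
  n <- length(u)
  u_term <- u[n]
  fp <- fixed_points(traj$drive_I, m)
  j_term <- which.min(abs(fp$u - u_term))
  u_ref <- fp$u[j_term]  # envelope reference: the nearby equilibrium
  floor_amp <- max(1e-9, 1e-6 * (max(u) - min(u)))
  idx <- which(u[2:(n - 1)] >= u[1:(n - 2)] & u[2:(n - 1)] > u[3:n]) + 1L
  idx <- idx[u[idx] - u_ref > floor_amp]
  peaks <- t(vapply(idx, function(i) refine_peak(t, u, i), numeric(2)))
  res <- function(kind, ...) structure(list(kind = kind, ...),
                                       class = "fhn_oscillation")
  if (nrow(peaks) >= 5) {
    pt <- peaks[, 1]; ph <- peaks[, 2]
    periods <- diff(pt)
    cv <- function(x) stats::sd(x) / abs(mean(x))
    if (cv(periods) < 0.01 && cv(ph - min(u)) < 0.01) {
      return(res("sustained_oscillation",
                 period = mean(periods),
                 amplitude_pp = max(u) - min(u)))
    }
  }
  at_fp <- abs(fp$u[j_term] - u_term) < 1e-4
  j_init <- which.min(abs(fp$u - traj$u[1]))
  if (at_fp && j_init != j_term)
    return(res("jump_to_sink", terminal_u = fp$u[j_term]))
  if (nrow(peaks) >= 3) {
    ph <- peaks[, 2] - u_ref
    if (all(diff(ph) < 0)) {
      ivals <- diff(peaks[, 1])
      fit <- stats::lm.fit(cbind(1, peaks[, 1]), log(ph))
      return(res("damped_oscillation",
                 ring_frequency = 2 * pi / mean(ivals),
                 decay_rate = -fit$coefficients[[2]]))
    }
  }
  dudt <- fhn_rhs(u, traj$w[i0:length(traj$w)], traj$drive_I, m)$du_dt
  scale_du <- max(abs(traj$u)) / max(traj$t)
  s <- sign(dudt * (abs(dudt) > 1e-8 * max(1, scale_du)))
  s <- s[s != 0]
  monotone <- length(s) == 0 || all(s == s[1])
  if (at_fp && monotone)
    return(res("monotonic_decay", terminal_u = u_term))
  stop("inconclusive trajectory: no oscillation/decay pattern detected; ",
       "try a longer t_end", call. = FALSE)
}

#' @export
print.fhn_oscillation <- function(x, ...) {
  cat("Oscillation metrics:", x$kind, "\n")
  for (f in setdiff(names(x), "kind"))
    cat(sprintf("  %s = %g\n", f, x[[f]]))
  invisible(x)
}

#' Assemble a phase-plane portrait
#'
#' Bundles trajectories from a set of initial conditions with the sampled
#' nullclines and the classified fixed points, ready for plotting or
#' export.
#'
#' @param model An `fhn_model` or preset name.
#' @param I Applied current, amperes.
#' @param initial_conditions A list of `c(u, w)` pairs (or a two-column
#'   matrix/data frame).
#' @param t_end Horizon, seconds; defaults to `200 * tau_k`.
#' @param u_range Voltage range over which to sample the nullclines.
#' @param ... Passed to [fhn_simulate()].
#' @return An object of class `fhn_portrait`: a list with fields
#'   `trajectories` (list of `fhn_trajectory`), `nullclines` (data frame
#'   `u`, `w_nullcline`, `u_nullcline`) and `fixed_points` (data frame
#'   `u`, `w`, `class`).
#' @export
phase_portrait <- function(model, I, initial_conditions, t_end = NULL,
                           u_range = NULL, ...) {
  m <- as_fhn_model(model)
  if (is.matrix(initial_conditions) || is.data.frame(initial_conditions))
    initial_conditions <- asplit(as.matrix(initial_conditions), 1)
  if (!length(initial_conditions))
    stop("need at least one initial condition", call. = FALSE)
  if (is.null(t_end)) t_end <- 200 * m$tau_k
  trajs <- lapply(initial_conditions, function(s)
    fhn_simulate(m, I, u0 = s[[1]], w0 = s[[2]], t_end = t_end, ...))
  if (is.null(u_range)) {
    u_all <- unlist(lapply(trajs, `[[`, "u"))
    u_range <- range(c(u_all, -1.5 * m$u_1, 1.5 * m$u_1))
  }
  ug <- seq(u_range[1], u_range[2], length.out = 401L)
  nc <- nullclines(ug, m, I)
  fp <- fixed_points(I, m)
  fp$class <- vapply(fp$u, function(u) stability_report(u, m)$klass, "")
  structure(list(trajectories = trajs,
                 nullclines = data.frame(u = ug,
                                         w_nullcline = nc$w_nullcline,
                                         u_nullcline = nc$u_nullcline),
                 fixed_points = fp),
            class = "fhn_portrait")
}

#' @export
plot.fhn_portrait <- function(x, ...) {
  nc <- x$nullclines
  w_all <- c(unlist(lapply(x$trajectories, `[[`, "w")), x$fixed_points$w)
  graphics::plot(nc$u, nc$w_nullcline, type = "l", col = "forestgreen",
                 xlab = "u (V)", ylab = "w (A)",
                 ylim = range(c(w_all, nc$w_nullcline)), ...)
  graphics::lines(nc$u, nc$u_nullcline, col = "steelblue")
  for (tr in x$trajectories) graphics::lines(tr$u, tr$w, col = "grey30")
  graphics::points(x$fixed_points$u, x$fixed_points$w, pch = 19,
                   col = ifelse(grepl("^stable", x$fixed_points$class),
                                "black", "red"))
  invisible(x)
}
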