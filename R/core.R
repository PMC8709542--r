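#' Right-hand side of the model equations
#'
#' Instantaneous time derivatives of the state at voltage `u`, recovery
#' current `w` and constant applied current `I`:
#' `du/dt = (I - (u^3/(3 u_1^2) - u)/R_I - w) / C_m` and
#' `dw/dt = (u/R_w - b w) / tau_k`. The derivative in `u` is linear in the
#' drive with slope `1/C_m`.
#'
#' @param u Membrane voltage, volts (vectorized).
#' @param w Recovery current, amperes (vectorized, recycled against `u`).
#' @param I Applied current, amperes.
#' @param model An `fhn_model` or preset name.
#' @return A list with fields `du_dt` (V/s) and `dw_dt` (A/s).
#' @export
fhn_rhs <- function(u, w, I, model) {
  m <- as_fhn_model(model)
  if (!all(is.finite(u)) || !all(is.finite(w)) || !all(is.finite(I)))
    stop("state and drive must be finite", call. = FALSE)
  C_m <- m$tau_m / m$R_I
  list(du_dt = (I - (u^3 / (3 * m$u_1^2) - u) / m$R_I - w) / C_m,
       dw_dt = (u / m$R_w - m$b * w) / m$tau_k)
}

#' Stationary current-voltage relation
#'
#' The drive current that holds the membrane at steady state voltage `u`:
#' `I(u) = (u^3/(3 u_1^2) - u)/R_I + u/(b R_w)`. It is odd in `u`. The
#' curve is N-shaped (three-valued around I = 0) when `r/b < 1` and
#' single-valued when `r/b > 1`; its turning points (`dI/du = 0`) are the
#' saddle-node bifurcations, where the dc resistance diverges.
#'
#' @inheritParams fhn_rhs
#' @return Current in amperes, same length as `u`.
#' @export
stationary_current <- function(u, model) {
  m <- as_fhn_model(model)
  (u^3 / (3 * m$u_1^2) - u) / m$R_I + u / (m$b * m$R_w)
}

#' Nullclines of the phase plane
#'
#' Both nullcline branches evaluated at voltage `u`: the recovery nullcline
#' (`dw/dt = 0`) is the line `w = u/(b R_w)`; the voltage nullcline
#' (`du/dt = 0`) at drive `I` is the inverted cubic
#' `w = I - (u^3/(3 u_1^2) - u)/R_I`. Fixed points are their intersections.
#'
#' @inheritParams fhn_rhs
#' @param I Applied current for the voltage nullcline, amperes (default 0).
#' @return A list with fields `w_nullcline` and `u_nullcline`, amperes.
#' @export
nullclines <- function(u, model, I = 0) {
  m <- as_fhn_model(model)
  list(w_nullcline = u / (m$b * m$R_w),
       u_nullcline = I - (u^3 / (3 * m$u_1^2) - u) / m$R_I)
}

#' Fixed points at a constant drive
#'
#' All real steady states for applied current `I`: the real roots `u*` of
#' `stationary_current(u) = I`, each paired with `w* = u*/(b R_w)`. The
#' cubic is solved in closed form (Cardano / trigonometric branch of the
#' depressed cubic), each root is polished by one Newton step, and roots
#' closer than `1e-9 * u_1` are merged (saddle-node tangency). Between one
#' and three fixed points exist for any finite drive.
#'
#' @param I Applied current, amperes (scalar).
#' @param model An `fhn_model` or preset name.
#' @return A data frame with columns `u` (V) and `w` (A), sorted ascending
#'   in `u`.
#' @examples
#' fixed_points(0, "E")   # saddle at 0 flanked by two sinks at +/- 1 V
#' @export
fixed_points <- function(I, model) {
  m <- as_fhn_model(model)
  stopifnot(is.numeric(I), length(I) == 1L, is.finite(I))
  # a u^3 + c u = I with a = 1/(3 R_I u_1^2), c = 1/(b R_w) - 1/R_I
  a <- 1 / (3 * m$R_I * m$u_1^2)
  c0 <- 1 / (m$b * m$R_w) - 1 / m$R_I
  # depressed form t^3 + p t + q = 0 with t = u
  p <- c0 / a
  q <- -I / a
  roots <- solve_depressed_cubic(p, q)
  # one Newton polish per root on f(u) = I(u) - I
  f <- function(u) stationary_current(u, m) - I
  fp <- function(u) (u^2 / m$u_1^2 - 1) / m$R_I + 1 / (m$b * m$R_w)
  d1 <- fp(roots)
  ok <- abs(d1) > .Machine$double.eps
  roots[ok] <- roots[ok] - f(roots[ok])[ok] / d1[ok]
  roots <- sort(roots)
  # merge near-coincident roots (degenerate tangency)
  if (length(roots) > 1L) {
    keep <- c(TRUE, diff(roots) > 1e-9 * m$u_1)
    roots <- roots[keep]
  }
  data.frame(u = roots, w = roots / (m$b * m$R_w))
}

# Real roots of t^3 + p t + q = 0.
solve_depressed_cubic <- function(p, q) {
  disc <- -4 * p^3 - 27 * q^2
  if (disc > 0) {
    # three distinct real roots: trigonometric method (requires p < 0)
    mfac <- 2 * sqrt(-p / 3)
    arg <- 3 * q / (p * mfac)
    arg <- min(1, max(-1, arg))
    theta <- acos(arg) / 3
    mfac * cos(theta - 2 * pi * (0:2) / 3)
  } else {
    # one real root (Cardano), numerically stable branch
    if (p == 0 && q == 0) return(0)
    u3 <- -q / 2 + sqrt(max(q^2 / 4 + p^3 / 27, 0))
    if (abs(u3) < .Machine$double.eps) {
      tt <- -sign(q) * abs(p / 3)^(1 / 2) # degenerate; handled by Newton polish
      return(tt)
    }
    cr <- sign(u3) * abs(u3)^(1 / 3)
    cr - p / (3 * cr)
  }
}

#' Tabulate the stationary current-voltage curve
#'
#' @param model An `fhn_model` or preset name.
#' @param u_min,u_max Voltage range, volts.
#' @param n Number of grid points.
#' @return A data frame with columns `u` (V) and `I` (A), suitable for
#'   CSV export.
#' @export
steady_state_table <- function(model, u_min = -2, u_max = 2, n = 401L) {
  m <- as_fhn_model(model)
  stopifnot(u_max > u_min, n >= 2L)
  u <- seq(u_min, u_max, length.out = n)
  data.frame(u = u, I = stationary_current(u, m))
}
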