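#' Equivalent-circuit elements at a bias voltage
#'
#' The small-signal response of the model at bias `u` is exactly that of a
#' parallel combination of: the membrane capacitor `C_m = tau_m/R_I`, the
#' bias-dependent channel resistor `R_b` with conductance
#' `G_b = (u^2/u_1^2 - 1)/R_I` (negative differential resistance for
#' `|u| < u_1` -- the built-in firing mechanism), and a series
#' resistor-inductor branch `R_a = b R_w`, `L = tau_k R_w` contributed by
#' the slow recovery current (a kinetic, non-magnetic inductor). The dc
#' resistance is `R_dc = 1/(G_b + 1/R_a)`, which also equals `du/dI` on the
#' stationary curve; it diverges at the saddle-node bias and is negative on
#' the three-valued middle branch.
#'
#' @param u Bias voltage, volts (scalar).
#' @param model An `fhn_model` or preset name.
#' @return An object of class `fhn_ec`: a list with fields `C_m` (F),
#'   `G_b` (S, signed), `R_b` (ohm, signed; +/-Inf at `|u| = u_1`),
#'   `R_a` (ohm), `L` (H) and `R_dc` (ohm, signed, possibly infinite).
#' @examples
#' ec_elements(0, "E")   # negative R_b and negative R_dc at the saddle
#' @export
ec_elements <- function(u, model) {
  m <- as_fhn_model(model)
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u))
  C_m <- m$tau_m / m$R_I
  G_b <- (u^2 / m$u_1^2 - 1) / m$R_I
  R_a <- m$b * m$R_w
  L <- m$tau_k * m$R_w
  G_sum <- G_b + 1 / R_a
  R_dc <- if (G_sum == 0) Inf else 1 / G_sum
  structure(list(C_m = C_m, G_b = G_b, R_b = 1 / G_b, R_a = R_a, L = L,
                 R_dc = R_dc),
            class = "fhn_ec")
}

#' @export
print.fhn_ec <- function(x, ...) {
  cat("Equivalent-circuit elements:\n")
  cat(sprintf("  C_m = %g F, R_b = %g ohm (G_b = %g S)\n", x$C_m, x$R_b, x$G_b))
  cat(sprintf("  R_a = %g ohm, L = %g H, R_dc = %g ohm\n", x$R_a, x$L, x$R_dc))
  invisible(x)
}

#' Small-signal impedance at a bias voltage
#'
#' Complex impedance of the linearized model,
#' `Z(i omega) = 1 / (i omega C_m + G_b + 1/(R_a + i omega L))`.
#' `Z(0)` equals the dc resistance and `|Z| -> 1/(omega C_m)` as
#' `omega -> Inf` (no series resistance: every spectrum ends at the
#' origin). `Z` depends on the bias only through `u^2`.
#'
#' @param u Bias voltage, volts (scalar).
#' @param model An `fhn_model` or preset name.
#' @param omega Angular frequency, rad/s (vectorized, `>= 0`).
#' @return Complex impedance in ohms, same length as `omega`.
#' @export
impedance <- function(u, model, omega) {
  m <- as_fhn_model(model)
  if (any(omega < 0)) stop("'omega' must be >= 0", call. = FALSE)
  ec <- ec_elements(u, m)
  Z <- 1 / (1i * omega * ec$C_m + ec$G_b + 1 / (ec$R_a + 1i * omega * ec$L))
  if (any(omega == 0)) Z[omega == 0] <- complex(real = ec$R_dc)
  Z
}

#' Characteristic frequencies of the impedance (Nyquist criterion)
#'
#' The total admittance `Y(s) = 1/Z(s)` vanishes at the complex
#' frequencies `s` solving
#' `s^2 C_m L + s (C_m R_a + L G_b) + (R_a G_b + 1) = 0` (the numerator
#' quadratic of `Y`; equivalently the poles of `Z`). These roots are
#' algebraically identical to the eigenvalues of the Jacobian at the same
#' bias -- under current drive the free dynamics live where no external
#' current modulation is needed, `Y(s) du = dI = 0`. The stability of the
#' fixed point can therefore be read off the spectrum: a root in the right
#' half plane means an unstable point, and a purely imaginary pair (the
#' spectrum diverging at a real frequency, `|Z| -> Inf` at
#' `omega = sqrt(det J)`) marks the Hopf bifurcation.
#'
#' @inheritParams ec_elements
#' @return A complex vector of length 2, units 1/s (real roots sorted
#'   ascending).
#' @export
impedance_zeros <- function(u, model) {
  ec <- ec_elements(u, as_fhn_model(model))
  a <- ec$C_m * ec$L
  b <- ec$C_m * ec$R_a + ec$L * ec$G_b
  c0 <- ec$R_a * ec$G_b + 1
  disc <- as.complex(b^2 - 4 * a * c0)
  s <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  if (all(Im(s) == 0)) s <- s[order(Re(s))]
  s
}

default_omega_window <- function(m) {
  c(1e-3 / m$tau_k, 1e3 / m$tau_m)
}

#' Classify the impedance spectrum at a bias
#'
#' Assigns one of five spectral regimes:
#' \describe{
#'   \item{NEGATIVE_RDC}{`R_dc < 0`: the spectrum starts on the negative
#'     real axis (three-valued branch; the bias is not observable at
#'     steady state without a series resistor).}
#'   \item{HIDDEN_NDR}{positive `R_dc` but the spectrum crosses the real
#'     axis at a negative real value at finite frequency -- the hidden
#'     negative impedance of an unstable (spiking) fixed point.}
#'   \item{INDUCTIVE_LOOP}{positive `R_dc` and a real-axis crossing at a
#'     positive real value: a low-frequency inductive loop below the real
#'     axis in the Nyquist plot, on a stable bias.}
#'   \item{BENT_ARC}{no crossing, but the high-frequency tail bends at the
#'     real axis (tangency, or a negative-real excursion exceeding 1% of
#'     `R_dc`).}
#'   \item{RC_ARC}{a plain capacitive arc.}
#' }
#' The finite-frequency real-axis crossing (`Im Z = 0`) exists exactly when
#' `L > C_m R_a^2`, i.e. `epsilon < r/b^2` (for `b = 1` this is the loop
#' condition `epsilon < r/b` expressed through the branch time constants,
#' `tau_k > R_a C_m`), and the sign of `Re Z` at the crossing equals the
#' sign of `-trace(J)`: the crossing is detected numerically by a sign
#' change of `Im Z` on a 60-points-per-decade scan refined by bisection.
#'
#' @inheritParams ec_elements
#' @param points_per_decade Scan resolution for crossing detection.
#' @return A character scalar (the regime label) with attributes
#'   `crossing_omega` (rad/s, NA when no crossing) and `Re_at_crossing`
#'   (ohm, NA when no crossing).
#' @examples
#' classify_spectrum(0, "A")     # RC_ARC
#' classify_spectrum(0.5, "C")   # HIDDEN_NDR: the spiking regime
#' @export
classify_spectrum <- function(u, model, points_per_decade = 60) {
  m <- as_fhn_model(model)
  ec <- ec_elements(u, m)
  G_sum <- ec$G_b + 1 / ec$R_a
  lab <- function(x, w = NA_real_, rez = NA_real_)
    structure(x, crossing_omega = w, Re_at_crossing = rez)
  if (G_sum < 0) return(lab("NEGATIVE_RDC"))
  win <- default_omega_window(m)
  n <- max(16L, ceiling(log10(win[2] / win[1]) * points_per_decade))
  omega <- 10^seq(log10(win[1]), log10(win[2]), length.out = n)
  Z <- impedance(u, m, omega)
  im <- Im(Z)
  sc <- which(im[-n] > 0 & im[-1] <= 0)
  if (length(sc)) {
    i <- sc[length(sc)]  # descending crossing (loop closes onto the axis)
    w_x <- stats::uniroot(function(w) Im(impedance(u, m, w)),
                          c(omega[i], omega[i + 1]), tol = 1e-12)$root
    re_x <- Re(impedance(u, m, w_x))
    if (re_x < 0) return(lab("HIDDEN_NDR", w_x, re_x))
    return(lab("INDUCTIVE_LOOP", w_x, re_x))
  }
  # no crossing: tangency or a visible high-frequency bend at the axis
  R_ref <- if (is.finite(ec$R_dc)) abs(ec$R_dc) else max(abs(Z))
  if (max(im) >= -1e-9 * R_ref) return(lab("BENT_ARC"))
  if (max(-Re(Z)) / R_ref > 0.01) return(lab("BENT_ARC"))
  lab("RC_ARC")
}

#' Impedance spectrum over a log-spaced frequency grid
#'
#' Evaluates `Z(i omega)` on a log grid with an explicit `omega = 0` head
#' entry (where `Z = R_dc` exactly) and attaches the spectral regime from
#' [classify_spectrum()]. The default window `[1e-3/tau_k, 1e3/tau_m]`
#' spans both relaxation times with three decades of margin, so the dc and
#' capacitive asymptotes are both reached.
#'
#' @inheritParams ec_elements
#' @param omega_min,omega_max Window bounds, rad/s (`0 < omega_min <
#'   omega_max`).
#' @param points_per_decade Grid density.
#' @return An object of class `fhn_spectrum`: a list with fields `bias_u`
#'   (V), `bias_I` (A, the stationary drive at that bias), `omega` (rad/s,
#'   0 then ascending), `Z` (complex ohms) and `regime`.
#' @examples
#' sp <- impedance_spectrum(1.1, "D")
#' sp$regime
#' @export
impedance_spectrum <- function(u, model, omega_min = NULL, omega_max = NULL,
                               points_per_decade = 60) {
  m <- as_fhn_model(model)
  win <- default_omega_window(m)
  if (is.null(omega_min)) omega_min <- win[1]
  if (is.null(omega_max)) omega_max <- win[2]
  if (!(omega_min > 0 && omega_max > omega_min))
    stop("need 0 < omega_min < omega_max", call. = FALSE)
  n <- max(2L, ceiling(log10(omega_max / omega_min) * points_per_decade))
  omega <- c(0, 10^seq(log10(omega_min), log10(omega_max), length.out = n))
  structure(
    list(bias_u = u, bias_I = stationary_current(u, m),
         omega = omega, Z = impedance(u, m, omega),
         regime = as.character(classify_spectrum(u, m, points_per_decade))),
    class = "fhn_spectrum")
}

#' @export
print.fhn_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum at u = %g V (I = %g A): %s\n",
              x$bias_u, x$bias_I, x$regime))
  cat(sprintf("  %d frequencies, omega in [0, %g] rad/s, R_dc = %g ohm\n",
              length(x$omega), max(x$omega), Re(x$Z[1])))
  invisible(x)
}

#' @export
as.data.frame.fhn_spectrum <- function(x, ...) {
  data.frame(omega = x$omega, ReZ = Re(x$Z), ImZ = Im(x$Z))
}

#' Nyquist plot of a spectrum
#'
#' Complex-plane plot in the electrochemistry convention: `-Im Z` on the
#' vertical axis, so the fourth-quadrant inductive loop of the model
#' appears below the real axis. Internally `Z` is stored untransformed;
#' only this plot layer negates the imaginary part.
#'
#' @param x An `fhn_spectrum`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fhn_spectrum <- function(x, ...) {
  keep <- is.finite(Re(x$Z)) & is.finite(Im(x$Z))
  graphics::plot(Re(x$Z)[keep], -Im(x$Z)[keep], type = "l",
                 xlab = "Z' (ohm)", ylab = "-Z'' (ohm)",
                 main = sprintf("u = %g V: %s", x$bias_u, x$regime), ...)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}
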