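#' Construct a FitzHugh-Nagumo model parameter set
#'
#' The model is written in dimensional electrical form. Its state is the
#' membrane voltage `u` (V) and a slow recovery current `w` (A), driven by an
#' applied current `I` (A):
#'
#' \deqn{C_m \frac{du}{dt} = I - \frac{1}{R_I}\left(\frac{u^3}{3 u_1^2} - u\right) - w}
#' \deqn{\tau_k \frac{dw}{dt} = \frac{u}{R_w} - b\, w}
#'
#' with membrane capacitance \eqn{C_m = \tau_m / R_I}. Six independent
#' parameters define a model: the voltage response time `tau_m` (s), the
#' recovery response time `tau_k` (s), the channel resistor `R_I` (ohm), the
#' recovery resistor `R_w` (ohm), the dimensionless modulation constant `b`,
#' and the reference voltage `u_1` (V). For an excitable membrane the
#' recovery variable is slow, \eqn{\tau_k \gg \tau_m}.
#'
#' Instead of `tau_k` and `R_w` you may supply the dimensionless ratios
#' `epsilon = tau_m / tau_k` (time-scale ratio) and `r = R_I / R_w`
#' (resistance ratio); the six dimensional parameters remain canonical
#' internally and the round trip is exact.
#'
#' @param tau_m Membrane voltage response time, seconds (> 0).
#' @param tau_k Recovery response time, seconds (> 0). Mutually exclusive
#'   with `epsilon`.
#' @param R_I Channel resistor, ohms (> 0).
#' @param R_w Recovery resistor, ohms (> 0). Mutually exclusive with `r`.
#' @param b Modulation constant, dimensionless (> 0).
#' @param u_1 Reference voltage, volts (> 0). Defaults to 1 V; the cubic
#'   channel nonlinearity has negative differential resistance for
#'   `|u| < u_1`.
#' @param epsilon Optional time-scale ratio `tau_m / tau_k`.
#' @param r Optional resistance ratio `R_I / R_w`.
#'
#' @return An object of class `fhn_model`: a list with fields `tau_m`,
#'   `tau_k`, `R_I`, `R_w`, `b`, `u_1`.
#' @seealso [fhn_preset()] for built-in parameter sets, [derived_params()]
#'   for the derived quantities epsilon, r, C_m, L.
#' @examples
#' m <- fhn_model(tau_m = 0.01, R_I = 0.5, b = 0.8, u_1 = 1,
#'                epsilon = 0.1, r = 1)
#' derived_params(m)
#' @export
fhn_model <- function(tau_m, tau_k = NULL, R_I, R_w = NULL, b, u_1 = 1,
                      epsilon = NULL, r = NULL) {
  if (is.null(tau_k) && is.null(epsilon))
    stop("supply either 'tau_k' or 'epsilon'", call. = FALSE)
  if (!is.null(tau_k) && !is.null(epsilon))
    stop("'tau_k' and 'epsilon' are mutually exclusive", call. = FALSE)
  if (is.null(R_w) && is.null(r))
    stop("supply either 'R_w' or 'r'", call. = FALSE)
  if (!is.null(R_w) && !is.null(r))
    stop("'R_w' and 'r' are mutually exclusive", call. = FALSE)
  check_positive_scalar(tau_m, "tau_m")
  check_positive_scalar(R_I, "R_I")
  if (is.null(tau_k)) {
    check_positive_scalar(epsilon, "epsilon")
    tau_k <- tau_m / epsilon
  }
  if (is.null(R_w)) {
    check_positive_scalar(r, "r")
    R_w <- R_I / r
  }
  m <- structure(
    list(tau_m = tau_m, tau_k = tau_k, R_I = R_I, R_w = R_w, b = b, u_1 = u_1),
    class = "fhn_model")
  validate_fhn_model(m)
}

validate_fhn_model <- function(m) {
  stopifnot(inherits(m, "fhn_model"))
  for (f in c("tau_m", "tau_k", "R_I", "R_w", "b", "u_1"))
    check_positive_scalar(m[[f]], f)
  m
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}

as_fhn_model <- function(x) {
  if (inherits(x, "fhn_model")) return(x)
  if (is.character(x) && length(x) == 1L) return(fhn_preset(x))
  stop("expected an 'fhn_model' or a preset name", call. = FALSE)
}

#' Derived model quantities
#'
#' Pure functions of the six independent parameters: the time-scale ratio
#' `epsilon = tau_m/tau_k`, the resistance ratio `r = R_I/R_w`, the membrane
#' capacitance `C_m = tau_m/R_I` (F) and the kinetic inductance
#' `L = tau_k * R_w` (H). The inductor is not magnetic: it is the
#' small-signal signature of the slow relaxation of the recovery current.
#'
#' @param model An `fhn_model` or preset name.
#' @return A list with numeric fields `epsilon`, `r`, `C_m`, `L`.
#' @export
derived_params <- function(model) {
  m <- as_fhn_model(model)
  list(epsilon = m$tau_m / m$tau_k,
       r = m$R_I / m$R_w,
       C_m = m$tau_m / m$R_I,
       L = m$tau_k * m$R_w)
}

#' @export
print.fhn_model <- function(x, ...) {
  d <- derived_params(x)
  cat("FitzHugh-Nagumo model (dimensional form)\n")
  cat(sprintf("  tau_m = %g s, tau_k = %g s, R_I = %g ohm, R_w = %g ohm\n",
              x$tau_m, x$tau_k, x$R_I, x$R_w))
  cat(sprintf("  b = %g, u_1 = %g V\n", x$b, x$u_1))
  cat(sprintf("  derived: epsilon = %g, r = %g, C_m = %g F, L = %g H\n",
              d$epsilon, d$r, d$C_m, d$L))
  invisible(x)
}

# Built-in parameter sets. A-F share R_I = 0.5 ohm, tau_m = 1e-2 s and vary
# (b, r, epsilon); fig1a/fig1c are the two bistable/monostable illustration
# sets (R_I = 0.5, b = 0.8, epsilon = 0.1, r = 0.4 or 1).
.fhn_presets <- list(
  A     = list(b = 1,   r = 1.2, epsilon = 20),
  B     = list(b = 1,   r = 1.2, epsilon = 1.8),
  C     = list(b = 1,   r = 1.2, epsilon = 0.316),
  D     = list(b = 1,   r = 1.2, epsilon = 0.01),
  E     = list(b = 1.2, r = 0.8, epsilon = 0.01),
  F     = list(b = 1.1, r = 0.8, epsilon = 0.01),
  fig1a = list(b = 0.8, r = 0.4, epsilon = 0.1),
  fig1c = list(b = 0.8, r = 1,   epsilon = 0.1)
)

#' Built-in model presets
#'
#' Eight reference parameter sets spanning the spectral and dynamical
#' regimes of the model: `"A"`--`"F"` (all with `R_I` = 0.5 ohm and
#' `tau_m` = 0.01 s, varying `b`, `r` and `epsilon`) and `"fig1a"`/`"fig1c"`
#' (`b` = 0.8, `epsilon` = 0.1, with `r` = 0.4 and 1 respectively).
#' Models A and B have `epsilon` > 1 (fast recovery; outside the excitable
#' regime, kept for completeness), C and D are excitable with a Hopf
#' bifurcation, E is bistable around a saddle, and F oscillates
#' spontaneously at zero drive.
#'
#' @param name Preset name, one of `fhn_presets()`.
#' @return An `fhn_model`.
#' @examples
#' fhn_preset("C")
#' @export
fhn_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.fhn_presets))
    stop(sprintf("unknown preset %s; valid presets: %s",
                 deparse(substitute(name)),
                 paste(names(.fhn_presets), collapse = ", ")), call. = FALSE)
  p <- .fhn_presets[[name]]
  fhn_model(tau_m = 1e-2, R_I = 0.5, b = p$b, u_1 = 1,
            epsilon = p$epsilon, r = p$r)
}

#' @rdname fhn_preset
#' @export
fhn_presets <- function() names(.fhn_presets)
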