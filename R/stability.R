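#' Jacobian of the model at a bias voltage
#'
#' Linearization of the vector field about `(u, w = u/(b R_w))`. The matrix
#' (entries in 1/s) is
#' `[[(1 - u^2/u_1^2)/tau_m, -R_I/tau_m], [1/(R_w tau_k), -b/tau_k]]`.
#' Its trace and determinant in the dimensionless normalization used
#' throughout the package are `trace_norm = tr(J) * tau_m =
#' (1 - u^2/u_1^2) - epsilon*b` and `det_norm = det(J) * tau_m^2 =
#' epsilon * (b (u^2/u_1^2 - 1) + r)`.
#'
#' @param u Bias voltage, volts (scalar).
#' @param model An `fhn_model` or preset name.
#' @return A 2x2 numeric matrix, units 1/s.
#' @export
fhn_jacobian <- function(u, model) {
  m <- as_fhn_model(model)
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u))
  matrix(c((1 - u^2 / m$u_1^2) / m$tau_m, -m$R_I / m$tau_m,
           1 / (m$R_w * m$tau_k),         -m$b / m$tau_k),
         nrow = 2, byrow = TRUE)
}

trace_norm_at <- function(u, m) {
  (1 - u^2 / m$u_1^2) - (m$tau_m / m$tau_k) * m$b
}

det_norm_at <- function(u, m) {
  eps <- m$tau_m / m$tau_k
  r <- m$R_I / m$R_w
  eps * (m$b * (u^2 / m$u_1^2 - 1) + r)
}

# tolerances for the non-hyperbolic boundary flags
.tol_trace <- 1e-9
.tol_det <- 1e-12

#' Linear stability of a bias point
#'
#' Normal-mode analysis of the fixed point at voltage `u`. The eigenvalues
#' are the roots of `lambda^2 - tr(J) lambda + det(J) = 0`, reported in
#' absolute units (1/s) and, normalized by `tau_m`, as `eigenvalues_norm`.
#' The class follows the trace-determinant plane: a negative determinant is
#' a saddle (real eigenvalues of opposite sign); with positive determinant
#' the sign of the trace separates stable from unstable and the sign of
#' the discriminant `trace^2 - 4 det` separates nodes from spirals. Points
#' within `1e-9` of the Hopf boundary (trace = 0, det > 0) or `1e-12` of
#' the saddle-node boundary (det = 0) are flagged `non_hyperbolic`.
#'
#' @param u Bias voltage, volts.
#' @param model An `fhn_model` or preset name.
#' @param I_check Optional drive current, amperes. When supplied, `u` must
#'   be a fixed-point voltage for that drive (checked to 1e-8 A); omit it
#'   to analyze `u` as a hypothetical bias.
#' @return An object of class `fhn_stability`: a list with fields
#'   `fixed_point` (list `u`, `w`), `trace_norm`, `det_norm`,
#'   `discriminant` (dimensionless), `eigenvalues` (complex, 1/s),
#'   `eigenvalues_norm` and `klass`.
#' @examples
#' stability_report(0.9, "C")   # stable spiral: damped ring-down
#' @export
stability_report <- function(u, model, I_check = NULL) {
  m <- as_fhn_model(model)
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u))
  if (!is.null(I_check)) {
    resid <- abs(stationary_current(u, m) - I_check)
    if (resid >= 1e-8)
      stop(sprintf(
        "u = %g is not a fixed point for I = %g (|I(u) - I| = %g)",
        u, I_check, resid), call. = FALSE)
  }
  tr_n <- trace_norm_at(u, m)
  det_n <- det_norm_at(u, m)
  disc <- tr_n^2 - 4 * det_n
  # roots of lambda^2 - tr lambda + det = 0 in absolute units
  tr_a <- tr_n / m$tau_m
  det_a <- det_n / m$tau_m^2
  disc_a <- as.complex(tr_a^2 - 4 * det_a)
  lam <- (tr_a + c(1, -1) * sqrt(disc_a)) / 2
  if (all(Im(lam) == 0)) lam <- lam[order(Re(lam))]
  klass <-
    if (abs(det_n) < .tol_det) "non_hyperbolic"
    else if (det_n < 0) "saddle"
    else if (abs(tr_n) < .tol_trace) "non_hyperbolic"
    else if (tr_n < 0) { if (disc < 0) "stable_spiral" else "stable_node" }
    else { if (disc < 0) "unstable_spiral" else "unstable_node" }
  structure(
    list(fixed_point = list(u = u, w = u / (m$b * m$R_w)),
         trace_norm = tr_n, det_norm = det_n, discriminant = disc,
         eigenvalues = lam, eigenvalues_norm = lam * m$tau_m,
         klass = klass),
    class = "fhn_stability")
}

#' @export
print.fhn_stability <- function(x, ...) {
  cat(sprintf("Fixed point u = %g V, w = %g A: %s\n",
              x$fixed_point$u, x$fixed_point$w, x$klass))
  cat(sprintf("  trace_norm = %g, det_norm = %g, discriminant = %g\n",
              x$trace_norm, x$det_norm, x$discriminant))
  cat(sprintf("  eigenvalues (1/s): %s, %s\n",
              format(x$eigenvalues[1]), format(x$eigenvalues[2])))
  invisible(x)
}

#' Locate the bifurcations of a model
#'
#' The Hopf bifurcation is the bias where the Jacobian trace vanishes with
#' positive determinant; it exists when `1 - epsilon*b > 0` and is located
#' by a bracketed root solve of `trace_norm(u) = 0` on `(0, u_1)` (the
#' closed form is `u_H = u_1 sqrt(1 - epsilon*b)`). The saddle-node pair
#' sits where the stationary curve turns, `dI/du = 0`, which exists when
#' `r/b < 1`; it is located by a root solve of the dc conductance (closed
#' form `u_SN = u_1 sqrt(1 - r/b)`). The line `r = b` is a pitchfork:
#' the three fixed points at zero drive merge.
#'
#' @param model An `fhn_model` or preset name.
#' @return An object of class `fhn_bifurcations`: a list with fields
#'   `hopf_voltage` (+u_H, or NA when absent), `hopf_current` (amperes at
#'   +u_H), `saddle_node_voltages` (c(-u_SN, u_SN) or NULL) and `pitchfork`
#'   (logical, `|r - b| < 1e-12`). By odd symmetry the bifurcations come in
#'   +/- pairs; positive representatives are reported.
#' @examples
#' bifurcation_summary("fig1c")
#' @export
bifurcation_summary <- function(model) {
  m <- as_fhn_model(model)
  eps <- m$tau_m / m$tau_k
  r <- m$R_I / m$R_w
  hopf_u <- NA_real_
  hopf_I <- NA_real_
  if (1 - eps * m$b > 0) {
    # trace_norm is monotone decreasing in u^2: bracket on (0, u_1)
    f <- function(u) trace_norm_at(u, m)
    hopf_u <- stats::uniroot(f, c(0, m$u_1), tol = 1e-14)$root
    hopf_I <- stationary_current(hopf_u, m)
  }
  sn <- NULL
  if (r / m$b < 1) {
    # dI/du = 1/R_dc vanishes at the turning points
    g <- function(u) (u^2 / m$u_1^2 - 1) / m$R_I + 1 / (m$b * m$R_w)
    u_sn <- stats::uniroot(g, c(0, m$u_1), tol = 1e-14)$root
    sn <- c(-u_sn, u_sn)
  }
  structure(
    list(hopf_voltage = hopf_u, hopf_current = hopf_I,
         saddle_node_voltages = sn,
         pitchfork = abs(r - m$b) < 1e-12),
    class = "fhn_bifurcations")
}

#' @export
print.fhn_bifurcations <- function(x, ...) {
  cat("Bifurcations:\n")
  if (is.na(x$hopf_voltage)) {
    cat("  Hopf: none (epsilon * b >= 1)\n")
  } else {
    cat(sprintf("  Hopf: u_H = %.5f V, I_H = %.5f A (and the mirror pair)\n",
                x$hopf_voltage, x$hopf_current))
  }
  if (is.null(x$saddle_node_voltages)) {
    cat("  saddle-node: none (r/b >= 1)\n")
  } else {
    cat(sprintf("  saddle-node: u_SN = %.5f V\n", x$saddle_node_voltages[2]))
  }
  if (x$pitchfork) cat("  pitchfork: r = b\n")
  invisible(x)
}

#' Stability scan over a voltage grid
#'
#' Row-wise [stability_report()] over `u_grid` (treated as hypothetical
#' biases). Sign changes of `trace` bracket the Hopf voltages; sign changes
#' of `det` bracket the saddle-node voltages.
#'
#' @param model An `fhn_model` or preset name.
#' @param u_grid Ascending finite voltage grid, volts.
#' @return A data frame with columns `u`, `trace`, `det`, `disc`, `class`.
#' @export
stability_scan <- function(model, u_grid) {
  m <- as_fhn_model(model)
  if (!all(is.finite(u_grid)) || is.unsorted(u_grid, strictly = TRUE))
    stop("'u_grid' must be finite and strictly ascending", call. = FALSE)
  rows <- lapply(u_grid, function(u) {
    s <- stability_report(u, m)
    data.frame(u = u, trace = s$trace_norm, det = s$det_norm,
               disc = s$discriminant, class = s$klass)
  })
  do.call(rbind, rows)
}
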