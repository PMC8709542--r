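# Random model draws for property-style tests (log-uniform over the
# physically sensible ranges; u_1 fixed at 1 V as in all presets).
random_model <- function() {
  fhn_model(tau_m = 10^stats::runif(1, -3, -1),
            R_I = 10^stats::runif(1, -1, 0.3),
            b = 10^stats::runif(1, -0.5, 0.5),
            u_1 = 1,
            epsilon = 10^stats::runif(1, -2, 0.7),
            r = 10^stats::runif(1, -1, 0.7))
}

# Canonical ordering for complex pairs (real pairs by real part,
# conjugate pairs by imaginary part).
sort_c <- function(z) {
  if (all(Im(z) == 0)) z[order(Re(z))] else z[order(Im(z))]
}

# Brute-force fixed-point oracle: dense sign-change scan of I(u) - I.
scan_fixed_points <- function(I, m, n = 1e5) {
  u <- seq(-3 * m$u_1, 3 * m$u_1, length.out = n)
  f <- stationary_current(u, m) - I
  i <- which(f[-n] * f[-1] <= 0 & f[-n] != 0)
  vapply(i, function(j)
    stats::uniroot(function(x) stationary_current(x, m) - I,
                   c(u[j], u[j + 1]), tol = 1e-13)$root, numeric(1))
}
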