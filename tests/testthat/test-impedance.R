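test_that("equivalent-circuit elements match hand evaluation", {
  ec <- ec_elements(0, "E")
  expect_equal(ec$C_m, 0.02)
  expect_equal(ec$G_b, -2)
  expect_equal(ec$R_b, -0.5)
  expect_equal(ec$R_a, 0.75, tolerance = 1e-12)
  expect_equal(ec$L, 0.625, tolerance = 1e-12)
  expect_equal(ec$R_dc, -1.5, tolerance = 1e-12)
  # G_b vanishes at the reference voltage, so R_dc = R_a there
  ec1 <- ec_elements(1, "C")
  expect_equal(ec1$G_b, 0)
  expect_equal(ec1$R_dc, ec1$R_a)
  # divergent R_dc at the saddle-node bias
  ec_sn <- ec_elements(sqrt(1 / 3), "E")
  expect_lt(abs(1 / ec_sn$R_dc), 1e-12)
  # negative differential channel resistance exactly inside |u| < u_1
  set.seed(3)
  for (k in 1:30) {
    m <- random_model()
    u <- stats::runif(1, -2, 2)
    expect_identical(ec_elements(u, m)$G_b < 0, abs(u) < m$u_1)
  }
})

test_that("dc resistance is the reciprocal slope of the stationary curve", {
  h <- 1e-6
  for (nm in c("A", "B", "C", "D", "E", "F", "fig1a", "fig1c")) {
    m <- fhn_preset(nm)
    for (u in seq(-1.8, 1.8, length.out = 37)) {
      dIdu <- (stationary_current(u + h, m) - stationary_current(u - h, m)) /
        (2 * h)
      G_dc <- 1 / ec_elements(u, m)$R_dc
      expect_equal(G_dc, dIdu, tolerance = 1e-6)
      # sign of the determinant coincides with that of the total resistance
      d <- stability_report(u, m)$det_norm
      if (abs(G_dc) > 1e-9) expect_identical(sign(d), sign(G_dc))
    }
  }
})

test_that("impedance limits: Z(0) = R_dc and capacitive high-frequency asymptote", {
  for (nm in fhn_presets()) {
    for (u in c(0, 0.5, 1.1)) {
      expect_identical(impedance(u, nm, 0),
                       complex(real = ec_elements(u, fhn_preset(nm))$R_dc))
    }
  }
  expect_equal(Mod(impedance(0, "E", 1e6)), 1 / (1e6 * 0.02), tolerance = 0.01)
  # dc consistency at omega -> 0+
  for (nm in c("A", "C", "E")) {
    m <- fhn_preset(nm)
    z <- impedance(0.3, m, 1e-9 / m$tau_k)
    expect_equal(Re(z), ec_elements(0.3, m)$R_dc, tolerance = 1e-6)
  }
})

test_that("impedance depends on bias only through u^2", {
  omega <- 10^seq(-2, 5, length.out = 50)
  set.seed(17)
  for (k in 1:10) {
    m <- random_model()
    u <- stats::runif(1, 0, 2)
    expect_identical(impedance(u, m, omega), impedance(-u, m, omega))
  }
})

test_that("impedance zeros equal the Jacobian eigenvalues", {
  set.seed(23)
  for (k in 1:300) {
    m <- random_model()
    u <- stats::runif(1, -2, 2)
    z <- sort_c(impedance_zeros(u, m))
    lam <- sort_c(as.complex(eigen(fhn_jacobian(u, m),
                                   only.values = TRUE)$values))
    expect_lt(max(Mod(z - lam)) / max(Mod(lam)), 1e-9)
  }
})

test_that("the admittance vanishes at a real frequency exactly at the Hopf bias", {
  # the spectrum diverges (|Z| -> Inf, |1/Z| -> 0) at omega = sqrt(det J)
  for (nm in c("C", "D", "fig1c")) {
    u_h <- bifurcation_summary(nm)$hopf_voltage
    w_h <- sqrt(det(fhn_jacobian(u_h, nm)))
    expect_lt(1 / Mod(impedance(u_h, nm, w_h)), 1e-8)
    # purely imaginary admittance-zero pair at the Hopf bias
    z <- impedance_zeros(u_h, nm)
    expect_lt(max(abs(Re(z))), 1e-9 * max(Mod(z)))
    # off the Hopf bias the admittance is bounded away from zero
    for (du in c(-1e-3, 1e-3)) {
      wg <- seq(0.5 * w_h, 1.5 * w_h, length.out = 2000)
      expect_gt(min(1 / Mod(impedance(u_h + du, nm, wg))), 1e-8)
    }
  }
})

test_that("spectra carry a zero-frequency head entry equal to R_dc", {
  for (nm in fhn_presets()) {
    sp <- impedance_spectrum(0.25, nm)
    expect_identical(sp$omega[1], 0)
    expect_true(all(diff(sp$omega) > 0))
    expect_identical(Re(sp$Z[1]), ec_elements(0.25, fhn_preset(nm))$R_dc)
    expect_identical(Im(sp$Z[1]), 0)
    expect_equal(sp$bias_I, stationary_current(0.25, fhn_preset(nm)))
  }
  expect_error(impedance_spectrum(0, "C", omega_min = 10, omega_max = 1),
               "omega")
})

test_that("spectral regimes reproduce the preset taxonomy", {
  expect_identical(as.character(classify_spectrum(0, "A")), "RC_ARC")
  expect_identical(as.character(classify_spectrum(0, "B")), "BENT_ARC")
  expect_identical(as.character(classify_spectrum(0.5, "C")), "HIDDEN_NDR")
  expect_identical(as.character(classify_spectrum(1.1, "D")), "INDUCTIVE_LOOP")
  expect_identical(as.character(classify_spectrum(0, "E")), "NEGATIVE_RDC")
  expect_identical(as.character(classify_spectrum(0, "F")), "NEGATIVE_RDC")
  # the stable side of model C keeps its fully developed inductive loop
  expect_identical(as.character(classify_spectrum(0.9, "C")), "INDUCTIVE_LOOP")
})

test_that("the loop appears exactly when the recovery time beats the RC time", {
  # b = 1 branch: crossing condition tau_k > R_a C_m reads eps < r/b
  for (eps in c(0.05, 0.3, 1.5)) {
    for (r in c(0.5, 1.2, 3)) {
      m <- fhn_model(tau_m = 0.01, R_I = 0.5, b = 1, epsilon = eps, r = r)
      lab <- as.character(classify_spectrum(1.15, m))
      if (eps < r) expect_identical(lab, "INDUCTIVE_LOOP")
      else expect_true(lab %in% c("RC_ARC", "BENT_ARC"))
    }
  }
})
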