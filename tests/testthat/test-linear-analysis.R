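test_that("Jacobian matches hand evaluation", {
  J <- fhn_jacobian(0, "C")   # tau_k = 0.01/0.316, R_w = 5/12
  expect_equal(J[1, 1], 100)
  expect_equal(J[1, 2], -50)
  expect_equal(J[2, 1], 1 / ((5 / 12) * (0.01 / 0.316)), tolerance = 1e-12)
  expect_equal(J[2, 2], -0.316 / 0.01 * 1, tolerance = 1e-12)
  expect_equal(fhn_jacobian(1, "A")[1, 1], 0)
  # trace in units of 1/tau_m at u = 0, model A: 1 - eps*b = -19
  expect_equal(sum(diag(fhn_jacobian(0, "A"))) * 0.01, -19, tolerance = 1e-12)
})

test_that("eigenvalues from the quadratic agree with a matrix eigen-decomposition", {
  set.seed(5)
  for (k in 1:300) {
    m <- random_model()
    u <- stats::runif(1, -2, 2)
    lam <- stability_report(u, m)$eigenvalues
    ref <- eigen(fhn_jacobian(u, m), only.values = TRUE)$values
    ref <- as.complex(ref)
    if (all(Im(ref) == 0)) ref <- ref[order(Re(ref))] else
      ref <- ref[order(Im(ref))]
    got <- if (all(Im(lam) == 0)) lam[order(Re(lam))] else lam[order(Im(lam))]
    expect_lt(max(Mod(got - ref)) / max(Mod(ref)), 1e-10)
  }
})

test_that("fixed-point classes follow the trace-determinant plane", {
  s0 <- stability_report(0, "C")
  expect_equal(s0$trace_norm, 1 - 0.316, tolerance = 1e-12)
  expect_equal(s0$det_norm, 0.316 * (1.2 - 1), tolerance = 1e-12)
  expect_identical(s0$klass, "unstable_node")
  s9 <- stability_report(0.9, "C")
  expect_equal(s9$trace_norm, 0.19 - 0.316, tolerance = 1e-12)
  expect_identical(s9$klass, "stable_spiral")
  sE <- stability_report(0, "E")
  expect_equal(sE$det_norm, 0.01 * (0.8 - 1.2), tolerance = 1e-12)
  expect_identical(sE$klass, "saddle")
  # saddle <=> negative determinant, over random draws
  set.seed(13)
  for (k in 1:50) {
    m <- random_model()
    s <- stability_report(stats::runif(1, -2, 2), m)
    expect_identical(s$klass == "saddle",
                     s$det_norm < 0 && abs(s$det_norm) >= 1e-12)
    if (s$klass %in% c("stable_node", "stable_spiral")) {
      expect_true(s$det_norm > 0 && s$trace_norm < 0)
      expect_identical(s$klass == "stable_spiral", s$discriminant < 0)
    }
  }
})

test_that("I_check contract rejects non-fixed-point biases", {
  expect_error(stability_report(0.5, "C", I_check = 0), "not a fixed point")
  I5 <- stationary_current(0.5, fhn_preset("C"))
  expect_silent(stability_report(0.5, "C", I_check = I5))
})

test_that("bifurcation summary matches the closed forms", {
  # closed-form oracles: u_H = u_1 sqrt(1 - eps b), u_SN = u_1 sqrt(1 - r/b)
  set.seed(31)
  for (k in 1:40) {
    m <- random_model()
    d <- derived_params(m)
    bs <- bifurcation_summary(m)
    if (1 - d$epsilon * m$b > 0) {
      expect_equal(bs$hopf_voltage, m$u_1 * sqrt(1 - d$epsilon * m$b),
                   tolerance = 1e-9)
      expect_equal(bs$hopf_current, stationary_current(bs$hopf_voltage, m))
    } else {
      expect_true(is.na(bs$hopf_voltage))
    }
    if (d$r / m$b < 1) {
      expect_equal(bs$saddle_node_voltages[2],
                   m$u_1 * sqrt(1 - d$r / m$b), tolerance = 1e-9)
    } else {
      expect_null(bs$saddle_node_voltages)
    }
  }
  expect_true(is.na(bifurcation_summary("A")$hopf_voltage))
  bsE <- bifurcation_summary("E")
  expect_equal(bsE$hopf_voltage, 0.99398, tolerance = 1e-4)
  expect_equal(bsE$saddle_node_voltages[2], sqrt(1 / 3), tolerance = 1e-9)
  expect_true(bifurcation_summary(
    fhn_model(tau_m = 0.01, R_I = 0.5, b = 0.8, epsilon = 0.1, r = 0.8))$pitchfork)
})

test_that("stability flips from unstable inside the Hopf voltage to stable outside", {
  for (nm in c("C", "D", "fig1c")) {
    u_h <- bifurcation_summary(nm)$hopf_voltage
    expect_match(stability_report(u_h - 1e-3, nm)$klass, "^unstable")
    expect_match(stability_report(u_h + 1e-3, nm)$klass, "^stable")
  }
})

test_that("Hopf boundary is flagged non-hyperbolic", {
  u_h <- bifurcation_summary("C")$hopf_voltage
  expect_identical(stability_report(u_h, "C")$klass, "non_hyperbolic")
})

test_that("closed-form limits: u_H -> u_1 as eps -> 0, u_SN -> 0 as r/b -> 1", {
  m_small <- fhn_model(tau_m = 0.01, R_I = 0.5, b = 1, epsilon = 1e-8, r = 1.2)
  expect_equal(bifurcation_summary(m_small)$hopf_voltage, 1, tolerance = 1e-7)
  m_edge <- fhn_model(tau_m = 0.01, R_I = 0.5, b = 1, epsilon = 0.01,
                      r = 1 - 1e-10)
  expect_lt(bifurcation_summary(m_edge)$saddle_node_voltages[2], 2e-5)
})

test_that("stability scan brackets the bifurcations by sign changes", {
  sc <- stability_scan("C", c(0, 0.5, 0.82690, 0.9))
  expect_identical(names(sc), c("u", "trace", "det", "disc", "class"))
  expect_true(sc$trace[sc$u == 0.5] > 0 && sc$trace[sc$u == 0.9] < 0)
  expect_lt(abs(sc$trace[sc$u == 0.82690]), 1e-3)
  # model A is stable across (-1, 1)
  scA <- stability_scan("A", seq(-0.99, 0.99, length.out = 41))
  expect_true(all(scA$trace < 0))
  # at u = u_1 the trace is exactly -eps*b
  expect_equal(stability_scan("C", 1)$trace, -0.316, tolerance = 1e-12)
  expect_error(stability_scan("C", c(1, 0.5)), "ascending")
})
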