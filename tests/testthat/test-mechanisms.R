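sc <- spin_constants()

test_that("spin constants satisfy the isotope-ratio invariants", {
  expect_lt(abs(sc$gamma_H / sc$gamma_C - 3.976) / 3.976, 0.001)
  expect_lt(abs((sc$gamma_H / sc$gamma_D)^2 - 42.44) / 42.44, 0.001)
  expect_true(all(unlist(sc[c("gamma_H", "gamma_C", "gamma_D", "gamma_e",
                              "hbar", "k_B")]) > 0))
})

test_that("CSA rate law: value, zero field, quadratic scaling", {
  # hand evaluation of (2/15)(B ds 1e-6 gamma)^2 tau_c at 9.4 T
  expect_equal(r1_csa(9.4, 136.5, 7.3e-12), 7.25422858e-3, tolerance = 1e-8)
  expect_identical(r1_csa(0, 136.5, 7.3e-12), 0)
  for (B in c(1e-4, 0.03, 2.2)) {
    expect_equal(r1_csa(2 * B, 120, 5e-12) / r1_csa(B, 120, 5e-12), 4,
                 tolerance = 1e-12)
  }
  # log-log slope of 2 everywhere
  Bs <- 10^seq(-5, 0.9, length.out = 12)
  lr <- log(r1_csa(Bs, 136.5, 7.3e-12))
  expect_equal(diff(lr) / diff(log(Bs)), rep(2, 11), tolerance = 1e-10)
  expect_error(r1_csa(-1, 136.5, 7.3e-12), "B must be")
  expect_error(r1_csa(1, -5, 7.3e-12), "delta_sigma")
  expect_error(r1_csa(1, 136.5, -1e-12), "tau_c")
  expect_warning(r1_csa(9.4, 136.5, 1e-9), "extreme-narrowing")
})

test_that("PRE dispersion: zero-field amplitude, electron-driven midpoint, monotone", {
  expect_equal(r1_pre(0, amplitude = 0.0066, tau_c = 6.1e-12), 0.0066)
  # at B = 1/(gamma_e tau_c) the electron Lorentzian halves, nuclear ~1
  B_half <- 1 / (sc$gamma_e * 6.1e-12)
  expect_equal(B_half, 0.931, tolerance = 1e-3)
  expect_equal(r1_pre(B_half, amplitude = 0.0066, tau_c = 6.1e-12),
               0.65 * 0.0066, tolerance = 1e-5)
  Bs <- sort(c(0, 10^seq(-6, 2, length.out = 40)))
  r <- r1_pre(Bs, amplitude = 0.01, tau_c = 200e-12)
  expect_true(all(diff(r) <= 0))
  expect_lt(r1_pre(1e6, amplitude = 0.01, tau_c = 200e-12), 1e-8)
  # amplitude from concentration x relaxivity, and consistency enforcement
  expect_equal(r1_pre(0, tau_c = 6.1e-12, concentration = 150,
                      molar_relaxivity = 4.4e-5), 150 * 4.4e-5)
  expect_error(r1_pre(0, amplitude = 0.01, tau_c = 6.1e-12,
                      concentration = 150, molar_relaxivity = 4.4e-5),
               "inconsistent")
  expect_error(r1_pre(1, amplitude = -1, tau_c = 6.1e-12), "amplitude")
})

test_that("deuteration factor reproduces 15.9 and scales rates", {
  f <- deuteration_factor(sc)
  expect_equal(f, 15.9, tolerance = 0.005)      # within 0.5% of the printed value
  expect_equal(deuteration_factor(sc, I_Y = sc$I_H, gamma_Y = sc$gamma_H), 1)
  expect_equal(0.0095 / f, 5.97e-4, tolerance = 0.002)
})

test_that("exchange weighting is a convex combination", {
  expect_equal(exchange_weighted_rate(0.004, 0.015), 5.0e-3, tolerance = 1e-6)
  expect_identical(exchange_weighted_rate(0.004, 0.015, p_py = 1, p_pyh = 0), 0.004)
  expect_identical(exchange_weighted_rate(0.02, 0.02, p_py = 0.5, p_pyh = 0.5), 0.02)
  set.seed(11)
  for (i in 1:20) {
    r <- sort(runif(2, 0, 0.05)); p <- runif(1)
    out <- exchange_weighted_rate(r[1], r[2], p_py = p, p_pyh = 1 - p)
    expect_gte(out, r[1]); expect_lte(out, r[2])
  }
  expect_error(exchange_weighted_rate(1, 2, p_py = 0.6, p_pyh = 0.5), "sum to 1")
  expect_error(exchange_weighted_rate(1, 2, p_py = -0.1, p_pyh = 1.1), "\\[0, 1\\]")
})

test_that("thermal polarization: magnitude, zero field, gyromagnetic ratio limit", {
  expect_equal(thermal_polarization(sc$gamma_C, 1, 293), 8.77e-7, tolerance = 1e-4)
  expect_identical(thermal_polarization(sc$gamma_C, 0, 293), 0)
  expect_equal(thermal_polarization(sc$gamma_H, 1, 293) /
                 thermal_polarization(sc$gamma_C, 1, 293),
               sc$gamma_H / sc$gamma_C, tolerance = 1e-10)
  expect_error(thermal_polarization(sc$gamma_C, 1, -10), "temperature")
})

test_that("total rate matches the tabulated low-field anchors", {
  expect_equal(1 / total_r1(1e-3, sample_id = "#H"), 43.4, tolerance = 0.005)
  # most protected sample: background plateau alone, ~227 s, within 2% of 224.5
  t1_a <- 1 / total_r1(1e-3, sample_id = "#A")
  expect_equal(t1_a, 227.3, tolerance = 0.002)
  expect_lt(abs(t1_a - 224.5) / 224.5, 0.02)
  expect_error(total_r1(1e-3, sample_id = "#Z"), "unknown sample")
})

test_that("total rate is the sum of individual mechanism calls", {
  reg <- default_registry()
  f <- deuteration_factor(sc)
  bg_nd <- reg$background$rate - reg$intraDD$rate / f - reg$interDD$rate / f
  for (sid in c("#A", "#D", "#G", "#I")) {
    comp <- sample_compositions(sid)
    Bs <- c(1e-5, 1e-3, 0.05, 0.5, 2, 9.4)
    expected <- bg_nd +
      (if (comp$pyruvate_d4) reg$intraDD$rate / f else reg$intraDD$rate) +
      (if (comp$solvent_d2o) reg$interDD$rate / f else reg$interDD$rate) +
      (if (!comp$degassed)
        r1_pre(Bs, reg$pre_o2$amplitude, tau_c = reg$pre_o2$tau_c) else 0) +
      (if (!comp$has_tris && !comp$has_edta)
        r1_pre(Bs, if (comp$solvent_d2o) reg$pre_metal$amplitude_d2o
                   else reg$pre_metal$amplitude_h2o,
               tau_c = reg$pre_metal$tau_c) else 0) +
      (if (comp$has_radical && !comp$radical_filtered)
        r1_pre(Bs, reg$radical$amplitude, tau_c = reg$radical$tau_c) else 0) +
      r1_csa(Bs, reg$csa$delta_sigma, reg$csa$tau_c, warn_narrowing = FALSE)
    expect_equal(total_r1(Bs, comp), expected, tolerance = 1e-12)
  }
})

test_that("mechanism activation rules follow the composition flags", {
  act_g <- active_mechanisms(sample_compositions("#G"))
  expect_true(act_g[["radical"]]); expect_true(act_g[["pre_o2"]])
  expect_false(act_g[["pre_metal"]])  # Tris/EDTA present
  act_c <- active_mechanisms(sample_compositions("#C"))
  expect_false(act_c[["radical"]])    # filtered
  expect_false(act_c[["pre_o2"]])     # degassed
  act_i <- active_mechanisms(sample_compositions("#I"))
  expect_true(act_i[["pre_metal"]])
  expect_error(sample_compositions("#X"), "unknown sample")
})

test_that("temperature endpoint scaling and the fully deuterated ceiling", {
  expect_equal(scale_dipolar_temperature(0.0062, "inter", 353), 0.0062 / 2.6)
  expect_equal(scale_dipolar_temperature(0.0008, "intra", 293), 0.0008)
  expect_error(scale_dipolar_temperature(0.0062, "inter", 320), "endpoints")
  # simulation-derived dipolar rates, fully deuterated: ~39 min at 293 K
  expect_equal(deuterated_limit_t1() / 60, 39, tolerance = 0.02)
  expect_gt(deuterated_limit_t1(T_K = 353), deuterated_limit_t1(T_K = 293))
})
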