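test_that("mono-exponential fit recovers T1 exactly from noiseless data", {
  s <- generate_decay_series(100, "thermal", n_points = 12, t_max = 300)
  fit <- fit_monoexponential(s)
  expect_equal(fit$T1, 100, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
})

test_that("mono-exponential fit is consistent under noise and rejects bad input", {
  s <- generate_decay_series(100, "thermal", n_points = 12, t_max = 300,
                             noise_rel = 0.01, seed = 42)
  fit <- fit_monoexponential(s)
  expect_lt(abs(fit$T1 - 100), 3 * fit$T1_sd)
  expect_error(fit_monoexponential(decay_series(c(0, 10), c(1, 0.9))),
               "at least 3 points")
  expect_error(fit_monoexponential(decay_series(c(0, 1, 2), c(1, NA, 0.5))),
               "non-finite")
  # constant-offset variant recovers an injected offset
  t <- seq(0, 300, length.out = 15)
  so <- decay_series(t, 2 * exp(-t / 80) + 0.3)
  fo <- fit_monoexponential(so, offset = TRUE)
  expect_equal(fo$T1, 80, tolerance = 1e-5)
  expect_equal(fo$offset, 0.3, tolerance = 1e-5)
})

test_that("flip-angle correction removes the RF consumption rate", {
  # RF rate at 10 deg / TR 5 s, and the resulting apparent decay time
  expect_equal(rf_consumption_rate(10, 5), 3.06e-3, tolerance = 0.01)
  expect_equal(1 / (1 / 162.1 + rf_consumption_rate(10, 5)), 108.3,
               tolerance = 1e-3)
  s <- generate_decay_series(162.1, "hyperpolarized", flip_angle_deg = 10,
                             repetition_time = 5, n_points = 40)
  fit <- fit_hyperpolarized_decay(s)
  expect_equal(fit$T1, 162.1, tolerance = 1e-4)
  expect_equal(fit$apparent_T1, 108.3, tolerance = 1e-3)
})

test_that("flip-angle correction converges to the plain fit as alpha -> 0", {
  t <- seq(0, 295, by = 5)
  y <- exp(-t / 120)
  s <- decay_series(t, y, flip_angle_deg = 1e-4)
  plain <- fit_monoexponential(s)
  corr <- fit_hyperpolarized_decay(s, flip_angle_deg = 1e-4, repetition_time = 5)
  expect_lt(abs(corr$T1 - plain$T1) / plain$T1, 1e-8)
})

test_that("flip-angle fit flags degenerate and unbounded cases", {
  s <- generate_decay_series(100, "hyperpolarized", flip_angle_deg = 10,
                             repetition_time = 5, n_points = 10)
  expect_error(fit_hyperpolarized_decay(s, flip_angle_deg = 90), "90 deg")
  # signal decaying slower than RF consumption alone implies unbounded T1
  t <- seq(0, 95, by = 5)
  slow <- decay_series(t, exp(-t * 0.5 * rf_consumption_rate(25, 5)),
                       flip_angle_deg = 25)
  expect_warning(res <- fit_hyperpolarized_decay(slow, repetition_time = 5),
                 "unbounded")
  expect_true(res$unbounded)
  expect_identical(res$T1, Inf)
})

test_that("band statistics: hand arithmetic, flags, permutation invariance", {
  p <- nmrd_profile("x", B0 = c(1e-5, 1e-4, 1e-3, 0.5, 2), T1 = c(30, 31, 32, 60, 70))
  bs <- band_statistics(p)
  low <- bs[bs$band == "low", ]
  expect_equal(low$mean_T1, 31); expect_equal(low$sd_T1, 1); expect_equal(low$n, 3L)
  mid <- bs[bs$band == "intermediate", ]
  expect_true(mid$single_obs); expect_equal(mid$sd_T1, 0)
  hi <- bs[bs$band == "high", ]
  expect_equal(hi$mean_T1, 70)
  empty <- band_statistics(nmrd_profile("y", 0.5, 60))[1, ]
  expect_true(empty$empty); expect_true(is.na(empty$mean_T1))
  # permutation invariance in point order
  ord <- c(4, 1, 5, 3, 2)
  p2 <- nmrd_profile("x", B0 = p$points$B0[ord], T1 = p$points$T1[ord])
  expect_equal(band_statistics(p2), bs)
})

test_that("band means of the noiseless study match the tabulated summaries", {
  b <- noiseless_bundle()
  low_i <- band_statistics(b$profiles[["#I"]])
  low_i <- low_i[low_i$band == "low", ]
  # protonated-water sample: ~1/0.0346 = 28.9 s, within 10% of tabulated 30.9
  expect_lt(abs(low_i$mean_T1 - 30.9) / 30.9, 0.10)
  low_a <- band_statistics(b$profiles[["#A"]])
  low_a <- low_a[low_a$band == "low", ]
  expect_lt(abs(low_a$mean_T1 - 224.5) / 224.5, 0.02)
})

test_that("profile subtraction isolates rates and propagates uncertainty", {
  b <- noiseless_bundle()
  d0 <- subtract_rate_profiles(b$profiles[["#A"]], b$profiles[["#A"]])
  expect_equal(d0$points$delta_R1, rep(0, nrow(d0$points)))
  # tabulated band means: degassing contribution context, ~7.54e-3 s^-1
  sb <- subtract_band_means(51.5, 84.2, 0.9, 0.9)
  expect_equal(sb$delta_R1, 7.54e-3, tolerance = 1e-3)
  expect_lt(abs(sb$delta_R1 - 0.0076), 2e-4)
  # propagated SD vs Monte-Carlo resampling (1e5 draws)
  set.seed(7); n <- 1e5
  mc <- stats::sd(1 / rnorm(n, 51.5, 2.0) - 1 / rnorm(n, 84.2, 1.5))
  an <- subtract_band_means(51.5, 84.2, 2.0, 1.5)$delta_R1_sd
  expect_lt(abs(an - mc) / mc, 0.05)
  # point-wise propagation formula
  pa <- nmrd_profile("a", c(1e-3, 1e-2), c(50, 52), T1_sd = c(2, 2))
  pb <- nmrd_profile("b", c(1e-3, 1e-2), c(80, 82), T1_sd = c(3, 3))
  d <- subtract_rate_profiles(pa, pb)
  expect_equal(d$points$delta_R1_sd[1], sqrt((2 / 50^2)^2 + (3 / 80^2)^2))
  # disjoint coverage errors out when interpolation cannot help
  pc <- nmrd_profile("c", c(5, 9), c(40, 30))
  expect_error(subtract_rate_profiles(pa, pc), "disjoint")
})

test_that("subtraction of a one-feature pair returns the toggled mechanism exactly", {
  b <- noiseless_bundle()
  reg <- b$registry
  # degassing toggle: pure O2 dispersion
  d_o2 <- subtract_rate_profiles(b$profiles[["#D"]], b$profiles[["#B"]])
  expect_equal(d_o2$points$delta_R1,
               r1_pre(d_o2$points$B0, reg$pre_o2$amplitude, tau_c = reg$pre_o2$tau_c),
               tolerance = 1e-10)
  # chelation toggle in H2O: pure metal dispersion
  d_m <- subtract_rate_profiles(b$profiles[["#I"]], b$profiles[["#E"]])
  expect_equal(d_m$points$delta_R1,
               r1_pre(d_m$points$B0, reg$pre_metal$amplitude_h2o,
                      tau_c = reg$pre_metal$tau_c),
               tolerance = 1e-10)
})

test_that("CSA fit recovers the shielding anisotropy", {
  # noiseless: exact
  p0 <- generate_nmrd_profile(sample_compositions("#A"), noise_rel = 0)
  f0 <- fit_csa(p0, tau_c = 7.3e-12)
  expect_equal(f0$delta_sigma, 136.5, tolerance = 1e-6)
  # 1% noise, fixed seed: within 2%
  p1 <- generate_nmrd_profile(sample_compositions("#A"), noise_rel = 0.01, seed = 5)
  f1 <- fit_csa(p1, tau_c = 7.3e-12)
  expect_lt(abs(f1$delta_sigma - 136.5) / 136.5, 0.02)
  # field-independent input: delta_sigma ~ 0 within uncertainty
  flat <- nmrd_profile("flat", B0 = c(1, 2, 4, 8), T1 = rep(100, 4),
                       T1_sd = rep(1, 4))
  ff <- fit_csa(flat, tau_c = 7.3e-12)
  expect_lt(ff$delta_sigma, 2 * max(ff$delta_sigma_sd, 1e-12) + 1e-6)
  # identifiability algebra: fitted delta_sigma scales as 1/sqrt(tau_c)
  f2 <- fit_csa(p0, tau_c = 2 * 7.3e-12)
  expect_equal(f2$delta_sigma, 136.5 / sqrt(2), tolerance = 1e-6)
  expect_error(fit_csa(p0, tau_c = NULL), "tau_c")
  expect_error(fit_csa(flat, tau_c = 7.3e-12, B_min = 100), "at least")
})

test_that("CSA parameter recovery is unbiased over seeded replicates", {
  errs <- vapply(1:20, function(s) {
    p <- generate_nmrd_profile(sample_compositions("#A"), noise_rel = 0.03, seed = s)
    fit_csa(p, tau_c = 7.3e-12)$delta_sigma - 136.5
  }, numeric(1))
  expect_lte(stats::median(abs(errs)), 3)  # ppm
})

test_that("PRE fit recovers amplitude and correlation time", {
  Bs <- default_field_grid()
  truth <- r1_pre(Bs, 6.6e-3, tau_c = 6.1e-12)
  noise <- local({ set.seed(3); rnorm(length(Bs), 0, 0.03 * truth) })
  d <- structure(list(pair = c("x", "y"),
                      points = data.frame(B0 = Bs, delta_R1 = truth + noise,
                                          delta_R1_sd = 0.03 * truth)),
                 class = "rate_difference")
  fp <- fit_pre(d)
  expect_lt(abs(fp$amplitude - 6.6e-3) / 6.6e-3, 0.15)
  expect_lt(abs(fp$tau_c - 6.1e-12) / 6.1e-12, 0.15)
  expect_true(fp$tau_c_identifiable)
  # amplitude within 1 reported SD of the truth (unbiasedness check)
  expect_lt(abs(fp$amplitude - 6.6e-3), fp$amplitude_sd * 3)
  # zero-amplitude input: amplitude ~ 0, tau_c flagged unidentifiable
  dz <- structure(list(pair = c("x", "y"),
                       points = data.frame(B0 = Bs, delta_R1 = rep(0, length(Bs)),
                                           delta_R1_sd = rep(1e-4, length(Bs)))),
                  class = "rate_difference")
  expect_warning(fz <- fit_pre(dz), "unidentifiable")
  expect_lt(fz$amplitude, 1e-6)
  expect_false(fz$tau_c_identifiable)
  # concentration reported only when a molar relaxivity is configured
  expect_true(is.na(fp$concentration))
  fc <- fit_pre(d, molar_relaxivity = 4.4e-5)
  expect_equal(fc$concentration, fc$amplitude / 4.4e-5)
  expect_error(fit_pre(structure(list(pair = c("x", "y"),
    points = data.frame(B0 = c(1, 2, 3), delta_R1 = 1:3 * 1e-3,
                        delta_R1_sd = NA_real_)), class = "rate_difference")),
    "at least 4")
})

test_that("slow-tumbling PRE places its dispersion shoulder below 0.1 T", {
  sc <- spin_constants()
  B_half <- 1 / (sc$gamma_e * 200e-12)
  expect_equal(B_half, 0.028, tolerance = 0.02)
  expect_lt(B_half, 0.1)
  # electron term halves there: factor 0.3 + 0.7/2 = 0.65 of the amplitude
  expect_equal(r1_pre(B_half, 0.0133, tau_c = 200e-12) / 0.0133, 0.65,
               tolerance = 1e-3)
})
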