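test_that("noiseless profiles reproduce the additive-model anchors", {
  p_h <- generate_nmrd_profile(sample_compositions("#H"), noise_rel = 0,
                               fields = c(1e-3))
  expect_equal(p_h$points$T1, 43.4, tolerance = 0.005)
  expect_error(generate_nmrd_profile(sample_compositions("#H"), fields = c(-1)),
               "fields must be > 0")
})

test_that("generation is deterministic for a fixed seed", {
  p1 <- generate_nmrd_profile(sample_compositions("#I"), noise_rel = 0.03, seed = 9)
  p2 <- generate_nmrd_profile(sample_compositions("#I"), noise_rel = 0.03, seed = 9)
  expect_identical(p1, p2)
  p3 <- generate_nmrd_profile(sample_compositions("#I"), noise_rel = 0.03, seed = 10)
  expect_false(identical(p1$points$T1, p3$points$T1))
  b1 <- generate_study_bundle(seed = 4, noise_rel = 0.01)
  b2 <- generate_study_bundle(seed = 4, noise_rel = 0.01)
  expect_identical(b1$profiles, b2$profiles)
})

test_that("single-feature toggles move only the toggled mechanism", {
  b <- noiseless_bundle()
  # methyl deuteration: #A vs #B differ by the intraDD change at every field
  dr <- 1 / b$profiles[["#B"]]$points$T1 - 1 / b$profiles[["#A"]]$points$T1
  f <- deuteration_factor()
  expect_equal(dr, rep(b$registry$intraDD$rate * (1 - 1 / f), length(dr)),
               tolerance = 1e-10)
})

test_that("deuteration toggles scale the dipolar terms by exactly the factor", {
  f <- deuteration_factor()
  comp_h2o <- sample_compositions("#E")   # protonated solvent
  comp_d2o <- sample_compositions("#D")   # same composition, D2O
  c_h <- r1_components(1e-3, comp_h2o)
  c_d <- r1_components(1e-3, comp_d2o)
  expect_equal(unname(c_h[, "interDD"] / c_d[, "interDD"]), f, tolerance = 1e-12)
  # every non-dipolar channel identical between the pair
  same <- c("background", "intraDD", "pre_o2", "csa", "radical")
  expect_equal(c_h[, same], c_d[, same], tolerance = 1e-12)
})

test_that("decay generator round-trips through the fitters", {
  s <- generate_decay_series(120, "thermal", n_points = 10, t_max = 360)
  expect_equal(fit_monoexponential(s)$T1, 120, tolerance = 1e-8)
  h <- generate_decay_series(77.1, "hyperpolarized", flip_angle_deg = 10,
                             repetition_time = 5, n_points = 40)
  expect_equal(fit_hyperpolarized_decay(h)$T1, 77.1, tolerance = 1e-4)
  # injected noise shows up at the requested level
  hn <- generate_decay_series(100, "thermal", n_points = 200, t_max = 10,
                              noise_rel = 0.01, seed = 8)
  resid <- hn$signal - exp(-hn$time / 100)
  expect_equal(stats::sd(resid), 0.01, tolerance = 0.2)
  expect_error(generate_decay_series(-5, "thermal"), "T1 must be")
  expect_error(generate_decay_series(100, "hyperpolarized", flip_angle_deg = 95),
               "flip angle")
})

test_that("study bundle manifest records the activation rules", {
  b <- noiseless_bundle()
  m <- b$manifest
  expect_setequal(m$sample_id, sample_compositions()$sample_id)
  chelated <- sample_compositions()$has_tris | sample_compositions()$has_edta
  expect_true(all(!m$pre_metal[chelated]))
  expect_true(all(m$pre_metal[!chelated]))
  expect_true(all(m$seed >= 0))
})

test_that("registry round-trips through the shipped config file", {
  cfg <- system.file("extdata", "registry_default.yaml", package = "relaxcider")
  skip_if(cfg == "", "installed extdata not found")
  loaded <- read_registry(cfg)
  expect_equal(unclass(loaded$registry)[c("background", "intraDD", "csa")],
               unclass(default_registry())[c("background", "intraDD", "csa")],
               tolerance = 1e-12)
  expect_equal(loaded$registry$pre_metal$tau_c, 200e-12)
  # overrides merge on top of defaults
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("mechanisms:\n  background:\n    rate: 0.005", tmp)
  expect_equal(read_registry(tmp)$registry$background$rate, 0.005)
  expect_equal(read_registry(tmp)$registry$csa$delta_sigma, 136.5)
})
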