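#' Default field grid of the synthetic study
#'
#' 25 log-spaced fields from 7.8 uT to 9.4 T, emulating a field-cycling
#' relaxometry campaign that spans from the shielded low-field region to the
#' spectrometer field.
#'
#' @param n Number of fields (default 25).
#' @param B_min,B_max Range in tesla.
#' @return Numeric vector of fields, tesla.
#' @export
default_field_grid <- function(n = 25, B_min = 7.8e-6, B_max = 9.4) {
  if (B_min <= 0 || B_max <= B_min) stop("need 0 < B_min < B_max", call. = FALSE)
  10^seq(log10(B_min), log10(B_max), length.out = n)
}

#' Generate a synthetic NMRD profile
#'
#' Evaluates the additive model T1(B) = 1/[total_r1](B) for one composition
#' and perturbs it multiplicatively with Gaussian noise of relative standard
#' deviation \code{noise_rel}; the per-point \code{T1_sd} is set to
#' \code{noise_rel * T1} (the generator's truth, playing the role of the
#' mono-exponential fit uncertainty of a measured point). Reproducible for a
#' fixed seed.
#'
#' @param composition One row of [sample_compositions()] or equivalent flags
#'   (must include a \code{sample_id}).
#' @param registry A [default_registry()]-style registry.
#' @param fields Field grid, tesla (> 0).
#' @param noise_rel Relative noise level (>= 0; default 0.03).
#' @param seed Integer seed (default 20260521).
#' @param constants \code{spin_constants}.
#' @return An [nmrd_profile()].
#' @examples
#' p <- generate_nmrd_profile(sample_compositions("#H"), noise_rel = 0)
#' p$points$T1[1]  # ~43.4 s at the lowest field
#' @export
generate_nmrd_profile <- function(composition, registry = default_registry(),
                                  fields = default_field_grid(), noise_rel = 0.03,
                                  seed = 20260521, constants = spin_constants()) {
  if (any(fields <= 0)) stop("all fields must be > 0", call. = FALSE)
  if (noise_rel < 0) stop("noise_rel must be >= 0", call. = FALSE)
  t1_true <- 1 / total_r1(fields, composition, registry, constants)
  if (noise_rel > 0) {
    rng <- local({ set.seed(seed); stats::rnorm(length(fields), 0, noise_rel) })
    t1 <- t1_true * (1 + rng)
    t1 <- pmax(t1, 0.01 * t1_true)  # guard: noise cannot flip T1 negative
  } else {
    t1 <- t1_true
  }
  nmrd_profile(sample_id = as.list(composition)$sample_id, B0 = fields, T1 = t1,
               T1_sd = noise_rel * t1_true)
}

#' Generate a synthetic decay series
#'
#' Thermal mode emulates field-cycling relaxation-delay data:
#' \eqn{S(t) = e^{-t/T_1}} at the requested times. Hyperpolarized mode
#' emulates repeated small-flip-angle sampling of a hyperpolarized decay:
#' \eqn{S_n = \sin\alpha\,\cos^{\,n-1}\alpha\, e^{-t_n/T_1}} at
#' \eqn{t_n = (n-1)\,TR}. Additive Gaussian noise with standard deviation
#' \code{noise_rel} times the initial amplitude is applied.
#'
#' @param T1 True lifetime, s (> 0).
#' @param mode \code{"thermal"} or \code{"hyperpolarized"}.
#' @param flip_angle_deg Flip angle for hyperpolarized mode, degrees.
#' @param repetition_time TR for hyperpolarized mode, s.
#' @param n_points Number of points (>= 3).
#' @param t_max Last time point for thermal mode, s (default 3 * T1).
#' @param noise_rel Relative additive noise level (default 0).
#' @param seed Integer seed.
#' @return A [decay_series()].
#' @export
generate_decay_series <- function(T1, mode = c("thermal", "hyperpolarized"),
                                  flip_angle_deg = 10, repetition_time = 5,
                                  n_points = 12, t_max = 3 * T1, noise_rel = 0,
                                  seed = 20260521) {
  mode <- match.arg(mode)
  if (T1 <= 0) stop("T1 must be > 0", call. = FALSE)
  if (n_points < 3) stop("need at least 3 points", call. = FALSE)
  if (noise_rel < 0) stop("noise_rel must be >= 0", call. = FALSE)
  if (mode == "thermal") {
    t <- seq(0, t_max, length.out = n_points)
    s <- exp(-t / T1)
    alpha <- 90
  } else {
    if (flip_angle_deg <= 0 || flip_angle_deg >= 90)
      stop("hyperpolarized mode needs a flip angle in (0, 90) degrees", call. = FALSE)
    if (repetition_time <= 0) stop("repetition_time must be > 0", call. = FALSE)
    n <- seq_len(n_points)
    t <- (n - 1) * repetition_time
    a <- flip_angle_deg * pi / 180
    s <- sin(a) * cos(a)^(n - 1) * exp(-t / T1)
    alpha <- flip_angle_deg
  }
  if (noise_rel > 0) {
    eps <- local({ set.seed(seed); stats::rnorm(length(t), 0, noise_rel * max(abs(s))) })
    s <- s + eps
  }
  decay_series(t, s, flip_angle_deg = alpha)
}

#' Generate the nine-sample synthetic study bundle
#'
#' Builds an NMRD profile for each of the nine compositions of
#' [sample_compositions()] over a shared field grid, plus a manifest mapping
#' each sample to its active mechanisms and recording seed and registry
#' provenance.
#'
#' @param registry A [default_registry()]-style registry.
#' @param seed Integer seed; each sample's profile gets a distinct
#'   sub-seed derived from it.
#' @param fields Field grid (default [default_field_grid()]).
#' @param noise_rel Relative noise on T1 (default 0.03).
#' @param constants \code{spin_constants}.
#' @return Object of class \code{study_bundle}: list with \code{profiles}
#'   (named list of [nmrd_profile()]), \code{manifest} (data.frame of
#'   per-sample mechanism activity), \code{seed}, \code{noise_rel},
#'   \code{registry}.
#' @export
generate_study_bundle <- function(registry = default_registry(), seed = 20260521,
                                  fields = default_field_grid(), noise_rel = 0.03,
                                  constants = spin_constants()) {
  comps <- sample_compositions()
  profiles <- list()
  manifest <- NULL
  for (i in seq_len(nrow(comps))) {
    comp <- comps[i, , drop = FALSE]
    sub_seed <- (seed + i * 7919L) %% .Machine$integer.max
    profiles[[comp$sample_id]] <- generate_nmrd_profile(
      comp, registry, fields, noise_rel, seed = sub_seed, constants = constants)
    act <- active_mechanisms(comp)
    deut <- attr(act, "deuterated")
    manifest <- rbind(manifest, data.frame(
      sample_id = comp$sample_id, t(as.matrix(act)),
      intraDD_deuterated = deut[["intraDD"]], interDD_deuterated = deut[["interDD"]],
      seed = sub_seed, stringsAsFactors = FALSE))
  }
  structure(list(profiles = profiles, manifest = manifest, seed = seed,
                 noise_rel = noise_rel, registry = registry,
                 compositions = comps),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("Synthetic NMRD study: %d samples x %d fields, %.3g%% noise, seed %d\n",
              length(x$profiles), nrow(x$profiles[[1]]$points),
              100 * x$noise_rel, x$seed))
  invisible(x)
}
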