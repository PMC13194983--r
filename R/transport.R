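#' Construct a field-time trajectory
#'
#' A piecewise-linear magnetic field profile B(t) experienced by a sample in
#' transit (e.g. from the polarizer bore through the lab fringe field to the
#' spectrometer). Interpolation between samples is linear in time.
#'
#' @param time Sample times, s (strictly increasing, starting at 0 or later).
#' @param B Fields at those times, tesla (> 0 everywhere).
#' @return Object of class \code{field_time_profile} with a \code{B_of_t}
#'   interpolator.
#' @export
field_time_profile <- function(time, B) {
  if (length(time) != length(B)) stop("time and B lengths differ", call. = FALSE)
  if (length(time) < 2) stop("need at least two samples", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (any(!is.finite(B)) || any(B <= 0)) stop("B must be finite and > 0", call. = FALSE)
  fun <- stats::approxfun(time, B, rule = 2)
  structure(list(time = time, B = B, B_of_t = fun), class = "field_time_profile")
}

#' Constant-field trajectory shorthand
#' @param B Field, tesla.
#' @param duration Span, s.
#' @return A [field_time_profile()] holding \code{B} for \code{duration}.
#' @export
constant_field_profile <- function(B, duration) {
  field_time_profile(c(0, duration), c(B, B))
}

#' Built-in example transport trajectories
#'
#' Two synthetic example trajectories (the laboratory's true fringe-field map
#' is site-specific and not shipped): \code{"hold"}, a constant 1 mT hold,
#' and \code{"ramp"}, a piecewise ramp 1 mT -> 1 T -> 9.4 T emulating
#' transfer into a transfer magnet and then the spectrometer.
#'
#' @param which \code{"hold"} or \code{"ramp"}.
#' @param duration Total span, s (default 60).
#' @return A [field_time_profile()].
#' @export
example_transport_profile <- function(which = c("hold", "ramp"), duration = 60) {
  which <- match.arg(which)
  if (which == "hold") return(constant_field_profile(1e-3, duration))
  field_time_profile(time = c(0, 0.7, 0.95, 1) * duration,
                     B = c(1e-3, 1e-3, 1, 9.4))
}

#' T1(B) lookup model for transport integration
#'
#' Either wraps the additive mechanistic model (composition + registry) or a
#' tabulated T1(B) curve; tabulated curves are interpolated linearly in
#' log10(B) on the rate scale.
#'
#' @param composition Optional composition row (with \code{registry}) for the
#'   mechanistic model.
#' @param registry Registry used with \code{composition}.
#' @param profile Optional [nmrd_profile()] to tabulate from.
#' @param constants \code{spin_constants}.
#' @return Object of class \code{relaxation_map}: list with \code{T1_of_B}.
#' @export
relaxation_map <- function(composition = NULL, registry = default_registry(),
                           profile = NULL, constants = spin_constants()) {
  if (!is.null(composition)) {
    fun <- function(B) 1 / total_r1(B, composition, registry, constants)
  } else if (!is.null(profile)) {
    lx <- log10(profile$points$B0)
    rates <- 1 / profile$points$T1
    rfun <- stats::approxfun(lx, rates, rule = 2)
    fun <- function(B) 1 / rfun(log10(B))
    return(structure(list(T1_of_B = fun, B_knots = profile$points$B0),
                     class = "relaxation_map"))
  } else {
    stop("supply a composition (+registry) or a tabulated profile", call. = FALSE)
  }
  structure(list(T1_of_B = fun, B_knots = NULL), class = "relaxation_map")
}

#' Retained polarization along a field-time trajectory
#'
#' Fraction of longitudinal polarization surviving transport,
#' \deqn{P(t)/P(0) = \exp\left(-\int_0^{t} \frac{dt'}{T_1(B(t'))}\right),}
#' evaluated by adaptive quadrature (relative tolerance 1e-8) on each linear
#' segment of the trajectory so kinks in B(t) never straddle a quadrature
#' panel.
#'
#' @param map A [relaxation_map()] (or an [nmrd_profile()] /
#'   composition-like row, converted automatically).
#' @param profile A [field_time_profile()].
#' @param duration Integration span from the profile start, s (defaults to
#'   the full profile span; must not exceed it).
#' @param t_start Start time within the profile (default: first sample).
#' @return Retained fraction in (0, 1].
#' @examples
#' m <- relaxation_map(profile = nmrd_profile("x", c(1e-4, 1), c(46.6, 46.6)))
#' retained_polarization(m, constant_field_profile(1e-3, 19.5))  # ~0.658
#' @export
retained_polarization <- function(map, profile, duration = NULL, t_start = NULL) {
  if (inherits(map, "nmrd_profile")) map <- relaxation_map(profile = map)
  stopifnot(inherits(map, "relaxation_map"), inherits(profile, "field_time_profile"))
  t0 <- if (is.null(t_start)) profile$time[1] else t_start
  span <- profile$time[length(profile$time)] - t0
  if (is.null(duration)) duration <- span
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (duration > span + 1e-9)
    stop("duration exceeds the trajectory span (", signif(span, 6), " s)", call. = FALSE)
  if (duration == 0) return(1)
  t1_fun <- function(t) {
    t1 <- map$T1_of_B(profile$B_of_t(t))
    if (any(!is.finite(t1)) || any(t1 <= 0))
      stop("T1(B) must be finite and > 0 along the trajectory", call. = FALSE)
    t1
  }
  # integrate segment-wise between trajectory knots; for tabulated T1(B)
  # curves also split where B(t) crosses a tabulated field, so every
  # quadrature panel sees a smooth integrand
  knots <- sort(unique(c(t0, profile$time[profile$time > t0 & profile$time < t0 + duration],
                         t0 + duration)))
  if (!is.null(map$B_knots)) {
    tk <- profile$time; Bk <- profile$B
    cross <- unlist(lapply(seq_len(length(tk) - 1), function(i) {
      dB <- Bk[i + 1] - Bk[i]
      if (dB == 0) return(numeric(0))
      frac <- (map$B_knots - Bk[i]) / dB
      tk[i] + frac[frac > 0 & frac < 1] * (tk[i + 1] - tk[i])
    }))
    cross <- cross[cross > t0 & cross < t0 + duration]
    knots <- sort(unique(c(knots, cross)))
  }
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    seg <- stats::integrate(function(t) 1 / t1_fun(t), knots[i], knots[i + 1],
                            rel.tol = 1e-8, subdivisions = 2000L)
    total <- total + seg$value
  }
  exp(-total)
}

#' SNR gain from improved polarization retention
#'
#' Ratio of two retained polarization fractions: with matched acquisition,
#' signal (and hence SNR) scales linearly with the polarization available at
#' detection.
#'
#' @param p_optimized,p_reference Retained fractions in (0, 1].
#' @return The gain ratio.
#' @examples
#' snr_gain(0.704, 0.274)  # ~2.57
#' @export
snr_gain <- function(p_optimized, p_reference) {
  if (any(!is.finite(c(p_optimized, p_reference))) ||
      p_optimized <= 0 || p_optimized > 1 || p_reference <= 0 || p_reference > 1)
    stop("polarization fractions must lie in (0, 1]", call. = FALSE)
  p_optimized / p_reference
}

#' Absolute polarization from a thermal reference spectrum
#'
#' Converts the ratio of a hyperpolarized signal to a thermally polarized
#' reference of the same sample into absolute polarization:
#' \deqn{P = \frac{S_{hyper}}{S_{thermal}/n_{scans}}\;
#'       P_{thermal}(\gamma, B, T) \times 100\%.}
#'
#' @param S_hyper Integrated hyperpolarized signal.
#' @param S_thermal Integrated thermal reference signal (summed over
#'   \code{n_thermal_scans} scans; > 0).
#' @param n_thermal_scans Number of averaged scans in the reference
#'   (default 1).
#' @param gamma Gyromagnetic ratio (default 13C).
#' @param B Reference field, tesla (default 1).
#' @param T_K Temperature, K (default 293).
#' @param constants \code{spin_constants}.
#' @return Polarization in percent.
#' @examples
#' polarization_from_reference(4.06e5, 1)  # ~35.6 (%)
#' @export
polarization_from_reference <- function(S_hyper, S_thermal, n_thermal_scans = 1,
                                        gamma = spin_constants()$gamma_C,
                                        B = 1, T_K = 293,
                                        constants = spin_constants()) {
  if (!is.finite(S_thermal) || S_thermal <= 0)
    stop("thermal reference signal must be > 0", call. = FALSE)
  if (n_thermal_scans < 1) stop("n_thermal_scans must be >= 1", call. = FALSE)
  enh <- S_hyper / (S_thermal / n_thermal_scans)
  100 * enh * thermal_polarization(gamma, B, T_K, constants)
}
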