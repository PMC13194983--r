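#' Chemical-shift-anisotropy relaxation rate
#'
#' Longitudinal relaxation rate driven by chemical shift anisotropy in the
#' fast-motion (extreme-narrowing) regime,
#' \deqn{R_1^{CSA} = \frac{2}{15}\,(B_0\,\Delta\sigma\,\gamma)^2\,\tau_c,}
#' where \eqn{\Delta\sigma} is the shielding anisotropy (entered in ppm,
#' multiplied by 1e-6 inside) and \eqn{\tau_c} the rotational correlation
#' time. The rate grows quadratically with field and vanishes at zero field.
#' No Lorentzian factor is applied: with \eqn{\tau_c} of a few picoseconds,
#' \eqn{\omega\tau_c \approx 5\times 10^{-3}} even at 9.4 T.
#'
#' @param B Magnetic field(s), tesla (vectorized, >= 0).
#' @param delta_sigma Shielding anisotropy, ppm (>= 0).
#' @param tau_c Rotational correlation time, seconds (> 0).
#' @param gamma Nuclear gyromagnetic ratio, rad s^-1 T^-1
#'   (default: 13C).
#' @param warn_narrowing Warn if omega*tau_c >= 0.1 at the largest field
#'   (extreme-narrowing validity check). Default TRUE.
#' @return Rate(s) in s^-1.
#' @examples
#' r1_csa(9.4, delta_sigma = 136.5, tau_c = 7.3e-12)  # ~7.25e-3 s^-1
#' @export
r1_csa <- function(B, delta_sigma, tau_c, gamma = spin_constants()$gamma_C,
                   warn_narrowing = TRUE) {
  if (any(!is.finite(B)) || any(B < 0)) stop("B must be finite and >= 0", call. = FALSE)
  if (!is.finite(delta_sigma) || delta_sigma < 0)
    stop("delta_sigma must be finite and >= 0", call. = FALSE)
  if (!is.finite(tau_c) || tau_c <= 0) stop("tau_c must be finite and > 0", call. = FALSE)
  if (warn_narrowing && length(B) > 0 && max(B) * gamma * tau_c >= 0.1)
    warning("omega*tau_c >= 0.1 at the largest field: extreme-narrowing form questionable")
  (2 / 15) * (B * delta_sigma * 1e-6 * gamma)^2 * tau_c
}

#' Paramagnetic relaxation enhancement dispersion
#'
#' Simplified Solomon-Bloembergen dipolar dispersion for the nuclear rate
#' induced by a fast-relaxing electron spin,
#' \deqn{R_1^{PRE}(B) = A\,[\,0.3\,L(\gamma_I B) + 0.7\,L(\gamma_S B)\,],\quad
#'       L(\omega) = 1/(1+(\omega\tau_c)^2),}
#' with a single effective correlation time and fixed 3:7 weights on the
#' nuclear and electron Lorentzians. The dispersion is dominated by the
#' electron Larmor frequency; the amplitude \eqn{A} is the zero-field rate.
#' Monotonically non-increasing in field; tends to zero at infinite field.
#'
#' @param B Magnetic field(s), tesla (vectorized, >= 0).
#' @param amplitude Zero-field rate, s^-1 (>= 0). Alternatively supply
#'   \code{concentration} (micromolar) and \code{molar_relaxivity}
#'   (s^-1 per micromolar); if all three are given they must be consistent.
#' @param tau_c Effective electron-nucleus correlation time, s (> 0).
#' @param gamma_I Nuclear gyromagnetic ratio (default 13C).
#' @param gamma_S Electron gyromagnetic ratio magnitude (default free electron).
#' @param concentration,molar_relaxivity Optional; see \code{amplitude}.
#' @return Rate(s) in s^-1.
#' @examples
#' r1_pre(0, amplitude = 0.0066, tau_c = 6.1e-12)      # = amplitude
#' r1_pre(0.93, amplitude = 0.0066, tau_c = 6.1e-12)   # ~0.65 * amplitude
#' @export
r1_pre <- function(B, amplitude = NULL, tau_c,
                   gamma_I = spin_constants()$gamma_C,
                   gamma_S = spin_constants()$gamma_e,
                   concentration = NULL, molar_relaxivity = NULL) {
  if (any(!is.finite(B)) || any(B < 0)) stop("B must be finite and >= 0", call. = FALSE)
  if (!is.finite(tau_c) || tau_c <= 0) stop("tau_c must be finite and > 0", call. = FALSE)
  if (!is.null(concentration) && !is.null(molar_relaxivity)) {
    amp_cr <- concentration * molar_relaxivity
    if (is.null(amplitude)) {
      amplitude <- amp_cr
    } else if (abs(amplitude - amp_cr) > 1e-9) {
      stop("amplitude inconsistent with concentration * molar_relaxivity", call. = FALSE)
    }
  }
  if (is.null(amplitude))
    stop("supply amplitude, or concentration together with molar_relaxivity", call. = FALSE)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be finite and >= 0", call. = FALSE)
  lor <- function(omega) 1 / (1 + (omega * tau_c)^2)
  amplitude * (0.3 * lor(abs(gamma_I) * B) + 0.7 * lor(abs(gamma_S) * B))
}

#' Exchange-weighted observed relaxation rate
#'
#' The keto (Py) and hydrated gem-diol (PyH) forms of pyruvate exchange fast
#' compared with longitudinal relaxation, so the observed carboxylate 13C
#' rate is the population-weighted average
#' \eqn{R_1^{obs} = p_{Py} R_1^{Py} + p_{PyH} R_1^{PyH}}.
#' At neutral pH and room temperature the population ratio is about 10:1.
#'
#' @param r_py,r_pyh Rates of the two species, s^-1 (vectorized together).
#' @param p_py,p_pyh Population fractions; must sum to 1 within 1e-12.
#'   Defaults encode the 10:1 ratio.
#' @return Observed rate(s), s^-1; always between the two inputs.
#' @examples
#' exchange_weighted_rate(0.004, 0.015)  # (10*0.004 + 0.015)/11 = 5e-3
#' @export
exchange_weighted_rate <- function(r_py, r_pyh, p_py = 10 / 11, p_pyh = 1 / 11) {
  if (!is.finite(p_py) || !is.finite(p_pyh) ||
      p_py < 0 || p_py > 1 || p_pyh < 0 || p_pyh > 1)
    stop("populations must lie in [0, 1]", call. = FALSE)
  if (abs(p_py + p_pyh - 1) > 1e-12)
    stop("populations must sum to 1 (got ", p_py + p_pyh, ")", call. = FALSE)
  p_py * r_py + p_pyh * r_pyh
}

#' Thermal equilibrium polarization
#'
#' Spin-1/2 longitudinal polarization at thermal equilibrium,
#' \eqn{P = \tanh(\hbar\gamma B / (2 k_B T))}; about 8.8e-7 for 13C at
#' 1 T and 293 K. Used to convert hyperpolarized/thermal signal ratios into
#' absolute polarization.
#'
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param B Field, tesla (>= 0, vectorized).
#' @param T_K Temperature, kelvin (> 0).
#' @param constants \code{spin_constants} list.
#' @return Polarization fraction(s) in [0, 1).
#' @export
thermal_polarization <- function(gamma, B, T_K, constants = spin_constants()) {
  if (!is.finite(T_K) || T_K <= 0) stop("temperature must be > 0 K", call. = FALSE)
  if (any(!is.finite(B)) || any(B < 0)) stop("B must be finite and >= 0", call. = FALSE)
  tanh(constants$hbar * abs(gamma) * B / (2 * constants$k_B * T_K))
}

#' Per-mechanism rate contributions for a sample composition
#'
#' Evaluates every relaxation channel of the additive model at field(s)
#' \code{B} for one sample composition, applying the activation rules of
#' [active_mechanisms()]. Deuterated dipolar channels contribute their
#' protonated rate divided by [deuteration_factor()]. Because the registry's
#' \code{background} is the measured plateau of the fully deuterated,
#' degassed, chelated sample -- which already contains those deuterated
#' residuals -- the background channel contributes
#' \code{plateau - intraDD/f - interDD/f} and the residuals re-enter through
#' their own channels, so the fully protected sample sums back to the plateau
#' exactly.
#'
#' @param B Field(s), tesla.
#' @param composition One row of [sample_compositions()] or equivalent flags.
#' @param registry A [default_registry()]-style registry.
#' @param constants \code{spin_constants}.
#' @return A matrix with \code{length(B)} rows and one column per mechanism
#'   (\code{background, intraDD, interDD, pre_o2, pre_metal, csa, radical});
#'   inactive mechanisms are zero columns.
#' @export
r1_components <- function(B, composition, registry = default_registry(),
                          constants = spin_constants()) {
  validate_registry(registry)
  act <- active_mechanisms(composition)
  deut <- attr(act, "deuterated")
  f <- deuteration_factor(constants)
  cc <- as.list(composition)

  intra_full <- registry$intraDD$rate
  inter_full <- registry$interDD$rate
  bg_nondipolar <- registry$background$rate - intra_full / f - inter_full / f
  if (bg_nondipolar < 0)
    stop("registry inconsistent: background plateau smaller than deuterated dipolar residuals",
         call. = FALSE)

  out <- matrix(0, nrow = length(B), ncol = 7,
                dimnames = list(NULL, c("background", "intraDD", "interDD",
                                        "pre_o2", "pre_metal", "csa", "radical")))
  out[, "background"] <- bg_nondipolar
  out[, "intraDD"] <- if (deut[["intraDD"]]) intra_full / f else intra_full
  out[, "interDD"] <- if (deut[["interDD"]]) inter_full / f else inter_full
  if (act[["pre_o2"]])
    out[, "pre_o2"] <- r1_pre(B, amplitude = registry$pre_o2$amplitude,
                              tau_c = registry$pre_o2$tau_c,
                              gamma_I = constants$gamma_C, gamma_S = constants$gamma_e)
  if (act[["pre_metal"]]) {
    amp <- if (isTRUE(cc$solvent_d2o)) registry$pre_metal$amplitude_d2o
           else registry$pre_metal$amplitude_h2o
    out[, "pre_metal"] <- r1_pre(B, amplitude = amp, tau_c = registry$pre_metal$tau_c,
                                 gamma_I = constants$gamma_C, gamma_S = constants$gamma_e)
  }
  out[, "csa"] <- r1_csa(B, delta_sigma = registry$csa$delta_sigma,
                         tau_c = registry$csa$tau_c, gamma = constants$gamma_C,
                         warn_narrowing = FALSE)
  if (act[["radical"]])
    out[, "radical"] <- r1_pre(B, amplitude = registry$radical$amplitude,
                               tau_c = registry$radical$tau_c,
                               gamma_I = constants$gamma_C, gamma_S = constants$gamma_e)
  out
}

#' Total longitudinal relaxation rate of a composition
#'
#' Sum of the active mechanism contributions ([r1_components()]) at field(s)
#' \code{B}: the additive-rate model of the composition study.
#'
#' @inheritParams r1_components
#' @param sample_id Alternative to \code{composition}: a sample id known to
#'   [sample_compositions()].
#' @return Rate(s) in s^-1, same length as \code{B}.
#' @examples
#' 1 / total_r1(1e-3, sample_id = "#H")   # ~43.4 s
#' 1 / total_r1(1e-3, sample_id = "#A")   # ~227 s
#' @export
total_r1 <- function(B, composition = NULL, registry = default_registry(),
                     constants = spin_constants(), sample_id = NULL) {
  if (is.null(composition)) {
    if (is.null(sample_id))
      stop("supply a composition or a sample_id", call. = FALSE)
    composition <- sample_compositions(sample_id)
  }
  rowSums(r1_components(B, composition, registry, constants))
}

#' Temperature scaling of dipolar rates (293 K -> 353 K endpoints)
#'
#' Molecular-dynamics estimates predict that heating from 293 K to 353 K
#' reduces the intermolecular dipolar rate by a factor 2.6 and the
#' intramolecular one by 2.8. Only these two tabulated endpoints are applied;
#' no interpolation between temperatures is attempted.
#'
#' @param rate Dipolar rate(s) at 293 K, s^-1.
#' @param channel \code{"inter"} or \code{"intra"}.
#' @param T_K Target temperature: 293 (identity) or 353 K.
#' @return Scaled rate(s), s^-1.
#' @export
scale_dipolar_temperature <- function(rate, channel = c("inter", "intra"), T_K = 353) {
  channel <- match.arg(channel)
  if (any(rate < 0)) stop("rates must be >= 0", call. = FALSE)
  if (T_K == 293) return(rate)
  if (T_K != 353)
    stop("only the tabulated endpoints 293 K and 353 K are supported", call. = FALSE)
  rate / if (channel == "inter") 2.6 else 2.8
}

#' Dipole-dipole-only T1 ceiling of a fully deuterated system
#'
#' If every other relaxation source were eliminated and only the inter- and
#' intramolecular dipolar couplings remained, full deuteration would divide
#' their summed rate by [deuteration_factor()]. With the simulation-derived
#' population-weighted dipolar rates (0.0062 + 0.00068 s^-1 at 293 K) this
#' ceiling is about 39 minutes at 293 K.
#'
#' @param rate_inter,rate_intra Protonated dipolar rates at 293 K, s^-1.
#' @param T_K 293 or 353 K (endpoint scaling via
#'   [scale_dipolar_temperature()]).
#' @param constants \code{spin_constants}.
#' @return T1 ceiling in seconds.
#' @export
deuterated_limit_t1 <- function(rate_inter = 0.0062, rate_intra = 0.00068,
                                T_K = 293, constants = spin_constants()) {
  ri <- scale_dipolar_temperature(rate_inter, "inter", T_K)
  ra <- scale_dipolar_temperature(rate_intra, "intra", T_K)
  1 / ((ri + ra) / deuteration_factor(constants))
}
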