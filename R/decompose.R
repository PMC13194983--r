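#' Default pairing plan for mechanism isolation
#'
#' The subtraction ledger used to isolate each relaxation channel from the
#' nine-sample study, choosing for every mechanism the sample pair that
#' toggles it and nothing else:
#' \itemize{
#'   \item background: low-band mean rate of the most protected sample (#A:
#'     deuterated pyruvate, D2O, degassed, chelated);
#'   \item intraDD: #B - #A (only the methyl protonation toggles);
#'   \item interDD: #E - #D (only the solvent toggles; both pairs are
#'     chelated and aerated, so no paramagnetic channel changes). The
#'     alternative H2O-D2O pair #I - #H also toggles the metal-PRE
#'     amplitude and is therefore not used by default;
#'   \item PRE:O2: #D - #B (only degassing toggles);
#'   \item PRE:M+ in H2O: #I - #E; in D2O: #H - #D (only chelation toggles);
#'   \item CSA: high-field excess of the background sample;
#'   \item radical: residual of #G against the assembled non-radical model.
#' }
#'
#' @return List with \code{background_sample}, \code{csa_sample},
#'   \code{radical_sample}, and \code{pairs} (data.frame
#'   \code{minuend, subtrahend, mechanism_label}).
#' @export
default_pairing_plan <- function() {
  list(
    background_sample = "#A",
    csa_sample = "#A",
    radical_sample = "#G",
    pairs = data.frame(
      minuend         = c("#B", "#E", "#D", "#I", "#H"),
      subtrahend      = c("#A", "#D", "#B", "#E", "#D"),
      mechanism_label = c("intraDD", "interDD", "pre_o2",
                          "pre_metal_h2o", "pre_metal_d2o"),
      stringsAsFactors = FALSE)
  )
}

# Mechanism-activity signature of a composition: activity flags plus
# deuteration state of the dipolar channels. Tris and EDTA enter only through
# the single chelation-controlled metal channel, so a pair toggling both
# still counts as one mechanism difference.
mechanism_signature <- function(composition) {
  act <- active_mechanisms(composition)
  deut <- attr(act, "deuterated")
  c(act, intraDD_deut = unname(deut[["intraDD"]]), interDD_deut = unname(deut[["interDD"]]))
}

validate_pairing_plan <- function(plan, compositions, override = FALSE) {
  for (i in seq_len(nrow(plan$pairs))) {
    a <- plan$pairs$minuend[i]; b <- plan$pairs$subtrahend[i]
    sig_a <- mechanism_signature(compositions[compositions$sample_id == a, , drop = FALSE])
    sig_b <- mechanism_signature(compositions[compositions$sample_id == b, , drop = FALSE])
    ndiff <- sum(sig_a != sig_b)
    if (ndiff != 1 && !override)
      stop("plan pair (", a, ", ", b, ") toggles ", ndiff,
           " mechanisms; expected exactly 1 (set override_plan_check = TRUE to force)",
           call. = FALSE)
  }
  invisible(plan)
}

# Weighted mean rate difference of a pair over all shared fields (the
# field-independent mechanisms cancel everything that disperses).
pair_mean_delta <- function(profiles, minuend, subtrahend) {
  d <- subtract_rate_profiles(profiles[[minuend]], profiles[[subtrahend]])
  w <- wls_weights(d$points$delta_R1_sd)
  m <- stats::weighted.mean(d$points$delta_R1, w)
  list(value = m, sd = sqrt(1 / sum(w)) * (if (any(is.finite(d$points$delta_R1_sd) &
                                                  d$points$delta_R1_sd > 0)) 1 else NA_real_),
       difference = d)
}

#' Decompose a relaxation-dispersion study into mechanism parameters
#'
#' Executes the full subtraction-and-fit ledger on a set of NMRD profiles:
#' background plateau from the most protected sample's low band, the two
#' field-independent dipolar rates from single-toggle pair differences
#' (corrected for deuteration: a protonation toggle changes the rate by
#' \eqn{r\,(1 - 1/f)} with \eqn{f} the [deuteration_factor()], so the raw
#' difference is multiplied by \eqn{f/(f-1)} to recover the full protonated
#' rate), the O2 and metal PRE dispersions from [fit_pre()] on pair
#' differences, the shielding anisotropy from [fit_csa()] on the background
#' sample's high-field excess (baseline fixed at the fitted background), and
#' the unfiltered-radical PRE as the residual of its sample against the
#' assembled non-radical model. The assembled additive model is then compared
#' with every input profile.
#'
#' @param profiles Named list of [nmrd_profile()] (names = sample ids), e.g.
#'   the \code{profiles} element of [generate_study_bundle()].
#' @param plan A [default_pairing_plan()]-style plan.
#' @param compositions [sample_compositions()]-style table covering every
#'   sample referenced by the plan.
#' @param seeds Known fixed parameters: list with \code{csa_tau_c} (s; the
#'   simulation-derived rotational correlation time, required for the CSA
#'   fit) and optionally \code{molar_relaxivity_o2} (s^-1 per micromolar, to
#'   report an O2 concentration).
#' @param bands [field_bands()] used for the background low-band mean.
#' @param constants \code{spin_constants}.
#' @param override_plan_check Skip the one-mechanism-per-pair validation.
#' @return Object of class \code{decomposition_result}: list with
#'   \code{params} (per-mechanism estimates and 1-sigma uncertainties,
#'   including raw pair differences), \code{registry} (fitted
#'   \code{rate_registry} usable with [total_r1()]), \code{residuals}
#'   (per-profile, per-field observed vs model rates), \code{rms_rel_residual},
#'   \code{reduced_chisq}, \code{plan}.
#' @export
decompose_study <- function(profiles, plan = default_pairing_plan(),
                            compositions = sample_compositions(),
                            seeds = list(csa_tau_c = 7.3e-12),
                            bands = field_bands(),
                            constants = spin_constants(),
                            override_plan_check = FALSE) {
  referenced <- unique(c(plan$background_sample, plan$csa_sample,
                         plan$pairs$minuend, plan$pairs$subtrahend))
  missing_p <- setdiff(referenced, names(profiles))
  if (length(missing_p) > 0L)
    stop("plan references profiles not supplied: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  missing_c <- setdiff(referenced, compositions$sample_id)
  if (length(missing_c) > 0L)
    stop("compositions table lacks: ", paste(missing_c, collapse = ", "), call. = FALSE)
  if (is.null(seeds$csa_tau_c))
    stop("seeds$csa_tau_c (rotational correlation time) is required for the CSA fit",
         call. = FALSE)
  validate_pairing_plan(plan, compositions, override_plan_check)
  f <- deuteration_factor(constants)
  params <- list()

  # background: weighted mean low-band rate of the most protected sample
  bgp <- profiles[[plan$background_sample]]
  low <- bands[bands$name == "low", ]
  inb <- bgp$points$B0 >= low$B_min & bgp$points$B0 < low$B_max
  if (!any(inb)) stop("background sample has no points in the low band", call. = FALSE)
  r_bg <- 1 / bgp$points$T1[inb]
  sd_bg <- ifelse(is.na(bgp$points$T1_sd[inb]), NA_real_,
                  bgp$points$T1_sd[inb] / bgp$points$T1[inb]^2)
  w_bg <- wls_weights(sd_bg)
  params$background <- list(rate = stats::weighted.mean(r_bg, w_bg),
                            sd = if (any(is.finite(sd_bg) & sd_bg > 0))
                                   sqrt(1 / sum(w_bg)) else NA_real_,
                            n = sum(inb), sample = plan$background_sample)

  # field-independent dipolar channels from pair differences
  for (label in c("intraDD", "interDD")) {
    row <- plan$pairs[plan$pairs$mechanism_label == label, , drop = FALSE]
    if (nrow(row) == 0L) next
    pd <- pair_mean_delta(profiles, row$minuend, row$subtrahend)
    corr <- f / (f - 1)  # protonation toggle changes the rate by r * (1 - 1/f)
    params[[label]] <- list(rate = pd$value * corr,
                            sd = if (is.na(pd$sd)) NA_real_ else pd$sd * corr,
                            rate_raw_difference = pd$value,
                            pair = c(row$minuend, row$subtrahend))
  }

  # PRE dispersions
  fit_pre_pair <- function(label, relaxivity = NULL) {
    row <- plan$pairs[plan$pairs$mechanism_label == label, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    d <- subtract_rate_profiles(profiles[[row$minuend]], profiles[[row$subtrahend]])
    fp <- fit_pre(d, gamma_I = constants$gamma_C, gamma_S = constants$gamma_e,
                  molar_relaxivity = relaxivity)
    fp$pair <- c(row$minuend, row$subtrahend)
    fp
  }
  params$pre_o2 <- fit_pre_pair("pre_o2", seeds$molar_relaxivity_o2)
  params$pre_metal_h2o <- fit_pre_pair("pre_metal_h2o")
  params$pre_metal_d2o <- fit_pre_pair("pre_metal_d2o")

  # CSA from the high-field excess of the background sample
  params$csa <- fit_csa(bgp, tau_c = seeds$csa_tau_c, gamma = constants$gamma_C,
                        baseline = params$background$rate)
  params$csa$tau_c <- seeds$csa_tau_c
  params$csa$sample <- plan$csa_sample

  # assemble the fitted registry (additive-plateau convention)
  metal_tau <- if (!is.null(params$pre_metal_h2o)) params$pre_metal_h2o$tau_c
               else if (!is.null(params$pre_metal_d2o)) params$pre_metal_d2o$tau_c
               else default_registry()$pre_metal$tau_c
  fitted_reg <- default_registry()
  fitted_reg$background$rate <- params$background$rate
  fitted_reg$background$sd <- params$background$sd
  fitted_reg$background$provenance <- "fitted"
  if (!is.null(params$intraDD)) {
    fitted_reg$intraDD$rate <- params$intraDD$rate
    fitted_reg$intraDD$sd <- params$intraDD$sd
    fitted_reg$intraDD$provenance <- "fitted"
  }
  if (!is.null(params$interDD)) {
    fitted_reg$interDD$rate <- params$interDD$rate
    fitted_reg$interDD$sd <- params$interDD$sd
    fitted_reg$interDD$provenance <- "fitted"
  }
  if (!is.null(params$pre_o2)) {
    fitted_reg$pre_o2$amplitude <- params$pre_o2$amplitude
    fitted_reg$pre_o2$tau_c <- params$pre_o2$tau_c
    fitted_reg$pre_o2$provenance <- "fitted"
  }
  if (!is.null(params$pre_metal_h2o))
    fitted_reg$pre_metal$amplitude_h2o <- params$pre_metal_h2o$amplitude
  if (!is.null(params$pre_metal_d2o))
    fitted_reg$pre_metal$amplitude_d2o <- params$pre_metal_d2o$amplitude
  fitted_reg$pre_metal$tau_c <- metal_tau
  fitted_reg$pre_metal$provenance <- "fitted"
  fitted_reg$csa$delta_sigma <- params$csa$delta_sigma
  fitted_reg$csa$delta_sigma_sd <- params$csa$delta_sigma_sd
  fitted_reg$csa$tau_c <- seeds$csa_tau_c
  fitted_reg$csa$provenance <- "fitted"

  # radical channel as the residual of its sample vs the non-radical model
  rad_id <- plan$radical_sample
  if (!is.null(rad_id) && !is.na(rad_id) && rad_id %in% names(profiles) &&
      rad_id %in% compositions$sample_id) {
    comp_g <- compositions[compositions$sample_id == rad_id, , drop = FALSE]
    prof_g <- profiles[[rad_id]]
    comps_nr <- r1_components(prof_g$points$B0, comp_g, fitted_reg, constants)
    model_nr <- rowSums(comps_nr[, colnames(comps_nr) != "radical", drop = FALSE])
    resid_d <- structure(list(
      pair = c(rad_id, "model"),
      points = data.frame(B0 = prof_g$points$B0,
                          delta_R1 = 1 / prof_g$points$T1 - model_nr,
                          delta_R1_sd = ifelse(is.na(prof_g$points$T1_sd), NA_real_,
                                               prof_g$points$T1_sd / prof_g$points$T1^2))),
      class = "rate_difference")
    params$radical <- tryCatch(
      fit_pre(resid_d, gamma_I = constants$gamma_C, gamma_S = constants$gamma_e),
      error = function(e) list(amplitude = NA_real_, tau_c = NA_real_,
                               tau_c_identifiable = FALSE, error = conditionMessage(e)))
    if (is.finite(params$radical$amplitude)) {
      fitted_reg$radical$amplitude <- params$radical$amplitude
      fitted_reg$radical$tau_c <- if (isTRUE(params$radical$tau_c_identifiable))
        params$radical$tau_c else metal_tau
      fitted_reg$radical$provenance <- "fitted"
    }
  }

  # residuals of the assembled model against every input profile
  resid <- NULL
  for (sid in names(profiles)) {
    if (!sid %in% compositions$sample_id) next
    comp <- compositions[compositions$sample_id == sid, , drop = FALSE]
    prof <- profiles[[sid]]
    model <- total_r1(prof$points$B0, comp, fitted_reg, constants)
    obs <- 1 / prof$points$T1
    sdr <- ifelse(is.na(prof$points$T1_sd), NA_real_,
                  prof$points$T1_sd / prof$points$T1^2)
    resid <- rbind(resid, data.frame(
      sample_id = sid, B0 = prof$points$B0, observed_rate = obs, model_rate = model,
      residual = obs - model, rel_residual = (obs - model) / model,
      rate_sd = sdr, stringsAsFactors = FALSE))
  }
  n_par <- 9L  # bg, 2 dipolar, 3 PRE amplitudes, 2 PRE tau, delta_sigma
  w_all <- wls_weights(resid$rate_sd)
  out <- list(params = params, registry = fitted_reg, residuals = resid,
              rms_rel_residual = sqrt(mean(resid$rel_residual^2)),
              reduced_chisq = sum(w_all * resid$residual^2) /
                max(nrow(resid) - n_par, 1L),
              plan = plan)
  class(out) <- "decomposition_result"
  out
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("NMRD mechanism decomposition\n")
  cat(sprintf("  background  %.4g +/- %.2g s^-1 (sample %s)\n",
              x$params$background$rate, x$params$background$sd,
              x$params$background$sample))
  for (lab in c("intraDD", "interDD")) {
    if (is.null(x$params[[lab]])) next
    cat(sprintf("  %-10s  %.4g +/- %.2g s^-1 (pair %s - %s; raw diff %.4g)\n", lab,
                x$params[[lab]]$rate, x$params[[lab]]$sd,
                x$params[[lab]]$pair[1], x$params[[lab]]$pair[2],
                x$params[[lab]]$rate_raw_difference))
  }
  for (lab in c("pre_o2", "pre_metal_h2o", "pre_metal_d2o", "radical")) {
    p <- x$params[[lab]]
    if (is.null(p) || !is.finite(p$amplitude)) next
    cat(sprintf("  %-13s amp %.4g s^-1, tau_c %.3g ps%s\n", lab, p$amplitude,
                p$tau_c * 1e12,
                if (isTRUE(p$tau_c_identifiable)) "" else " (tau_c unidentifiable)"))
  }
  cat(sprintf("  CSA         delta_sigma %.4g +/- %.2g ppm (tau_c %.3g ps fixed)\n",
              x$params$csa$delta_sigma, x$params$csa$delta_sigma_sd,
              x$params$csa$tau_c * 1e12))
  cat(sprintf("  RMS relative residual over %d points: %.3g\n",
              nrow(x$residuals), x$rms_rel_residual))
  invisible(x)
}
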