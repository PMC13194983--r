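#' Construct an NMRD profile
#'
#' An NMRD (nuclear magnetic relaxation dispersion) profile is one sample's
#' T1 measured as a function of the static field B0. Points are stored sorted
#' by field; duplicate fields are rejected.
#'
#' @param sample_id Label (e.g. \code{"#A"}).
#' @param B0 Fields, tesla (> 0).
#' @param T1 Longitudinal relaxation times, s (> 0).
#' @param T1_sd Optional standard deviations of T1, s (NA allowed per point).
#' @param n_obs Optional observation counts per point (default 1).
#' @param temperature Kelvin (default 293).
#' @param pH Default 7.6.
#' @return An object of class \code{nmrd_profile}: list with \code{sample_id},
#'   \code{points} (data.frame \code{B0, T1, T1_sd, n_obs}), \code{temperature},
#'   \code{pH}.
#' @export
nmrd_profile <- function(sample_id, B0, T1, T1_sd = NULL, n_obs = NULL,
                         temperature = 293, pH = 7.6) {
  n <- length(B0)
  if (length(T1) != n) stop("B0 and T1 must have equal length", call. = FALSE)
  if (is.null(T1_sd)) T1_sd <- rep(NA_real_, n)
  if (is.null(n_obs)) n_obs <- rep(1L, n)
  if (any(!is.finite(B0)) || any(B0 <= 0)) stop("all B0 must be finite and > 0", call. = FALSE)
  if (any(!is.finite(T1)) || any(T1 <= 0)) stop("all T1 must be finite and > 0", call. = FALSE)
  if (any(T1_sd[!is.na(T1_sd)] < 0)) stop("T1_sd must be >= 0 where set", call. = FALSE)
  if (anyDuplicated(B0)) stop("duplicate B0 values in profile", call. = FALSE)
  ord <- order(B0)
  pts <- data.frame(B0 = B0[ord], T1 = T1[ord], T1_sd = T1_sd[ord],
                    n_obs = as.integer(n_obs[ord]))
  structure(list(sample_id = as.character(sample_id), points = pts,
                 temperature = temperature, pH = pH),
            class = "nmrd_profile")
}

#' @export
print.nmrd_profile <- function(x, ...) {
  cat(sprintf("NMRD profile %s: %d fields, %.2g-%.3g T, T1 %.3g-%.3g s (%g K, pH %g)\n",
              x$sample_id, nrow(x$points), min(x$points$B0), max(x$points$B0),
              min(x$points$T1), max(x$points$T1), x$temperature, x$pH))
  invisible(x)
}

#' @export
plot.nmrd_profile <- function(x, ...) {
  with(x$points, {
    graphics::plot(B0, T1, log = "xy", xlab = "B0 (T)", ylab = "T1 (s)",
                   main = paste("NMRD", x$sample_id), pch = 19, ...)
    has_sd <- !is.na(T1_sd) & T1_sd > 0
    if (any(has_sd))
      suppressWarnings(graphics::arrows(B0[has_sd], T1[has_sd] - T1_sd[has_sd],
                                        B0[has_sd], T1[has_sd] + T1_sd[has_sd],
                                        angle = 90, code = 3, length = 0.02))
  })
  invisible(x)
}

#' Default field bands
#'
#' Three half-open field ranges \code{[B_min, B_max)} used to summarize the
#' dispersion profiles: low (5 uT - 8 mT), intermediate (0.1 - 1 T) and high
#' (1 - 10 T). Points in the 8 mT - 0.1 T gap belong to no band. Boundaries
#' are configurable.
#'
#' @param low,intermediate,high Length-2 numeric \code{c(B_min, B_max)}, tesla.
#' @return A data.frame with columns \code{name, B_min, B_max}.
#' @export
field_bands <- function(low = c(5e-6, 8e-3), intermediate = c(0.1, 1),
                        high = c(1, 10)) {
  bands <- data.frame(name = c("low", "intermediate", "high"),
                      B_min = c(low[1], intermediate[1], high[1]),
                      B_max = c(low[2], intermediate[2], high[2]),
                      stringsAsFactors = FALSE)
  if (any(bands$B_min >= bands$B_max)) stop("each band needs B_min < B_max", call. = FALSE)
  ord <- order(bands$B_min)
  if (any(bands$B_max[ord][-nrow(bands)] > bands$B_min[ord][-1]))
    stop("bands must not overlap", call. = FALSE)
  bands
}

#' Per-band mean T1 of an NMRD profile
#'
#' Unweighted mean and sample standard deviation of T1 over the points falling
#' in each half-open band \code{[B_min, B_max)}. Empty bands are reported with
#' \code{n = 0} and NA statistics (flagged, not fatal); single-point bands get
#' \code{sd = 0} and \code{single_obs = TRUE}.
#'
#' @param profile An [nmrd_profile()].
#' @param bands A [field_bands()]-style data.frame.
#' @return data.frame with columns \code{sample_id, band, B_min, B_max,
#'   mean_T1, sd_T1, n, single_obs, empty}.
#' @export
band_statistics <- function(profile, bands = field_bands()) {
  stopifnot(inherits(profile, "nmrd_profile"))
  res <- lapply(seq_len(nrow(bands)), function(i) {
    inb <- profile$points$B0 >= bands$B_min[i] & profile$points$B0 < bands$B_max[i]
    t1 <- profile$points$T1[inb]
    n <- length(t1)
    data.frame(sample_id = profile$sample_id, band = bands$name[i],
               B_min = bands$B_min[i], B_max = bands$B_max[i],
               mean_T1 = if (n > 0) mean(t1) else NA_real_,
               sd_T1 = if (n > 1) stats::sd(t1) else if (n == 1) 0 else NA_real_,
               n = n, single_obs = n == 1L, empty = n == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Interpolate a profile's rate curve (1/T1) linearly in log10(B).
# Returns rates and propagated rate SDs at the requested fields.
interp_rates <- function(profile, B_target) {
  pts <- profile$points
  R <- 1 / pts$T1
  R_sd <- ifelse(is.na(pts$T1_sd), NA_real_, pts$T1_sd / pts$T1^2)
  lx <- log10(pts$B0)
  r_out <- stats::approx(lx, R, xout = log10(B_target))$y
  sd_out <- if (all(is.na(R_sd))) rep(NA_real_, length(B_target))
            else stats::approx(lx, ifelse(is.na(R_sd), stats::median(R_sd, na.rm = TRUE), R_sd),
                               xout = log10(B_target))$y
  list(rate = r_out, rate_sd = sd_out)
}

#' Subtract two NMRD profiles on the rate scale
#'
#' Forms the rate-difference curve
#' \eqn{\Delta R_1(B) = 1/T_{1,a}(B) - 1/T_{1,b}(B)} between two profiles.
#' When the two compositions differ in a single mechanism, the difference
#' isolates that mechanism's dispersion curve. Standard deviations propagate
#' as \eqn{\sigma_{\Delta R} = \sqrt{(\sigma_a/T_{1,a}^2)^2 +
#' (\sigma_b/T_{1,b}^2)^2}}. On unequal field grids, rates are interpolated
#' linearly in log10(B) onto the shared field range (disable with
#' \code{interpolate = FALSE}).
#'
#' @param a,b [nmrd_profile()] objects (minuend, subtrahend).
#' @param interpolate Allow interpolation onto common fields (default TRUE).
#' @return Object of class \code{rate_difference}: list with \code{pair}
#'   (c(a, b) ids) and \code{points} (data.frame \code{B0, delta_R1,
#'   delta_R1_sd}).
#' @export
subtract_rate_profiles <- function(a, b, interpolate = TRUE) {
  stopifnot(inherits(a, "nmrd_profile"), inherits(b, "nmrd_profile"))
  shared <- intersect(a$points$B0, b$points$B0)
  if (length(shared) == nrow(a$points) && length(shared) == nrow(b$points)) {
    B <- a$points$B0
    Ra <- 1 / a$points$T1
    Rb <- 1 / b$points$T1
    sa <- ifelse(is.na(a$points$T1_sd), NA_real_, a$points$T1_sd / a$points$T1^2)
    sb <- ifelse(is.na(b$points$T1_sd), NA_real_, b$points$T1_sd / b$points$T1^2)
  } else {
    if (!interpolate)
      stop("profiles ", a$sample_id, " and ", b$sample_id,
           " have different field grids and interpolation is disabled", call. = FALSE)
    lo <- max(min(a$points$B0), min(b$points$B0))
    hi <- min(max(a$points$B0), max(b$points$B0))
    if (lo >= hi)
      stop("profiles have disjoint field coverage; cannot pair", call. = FALSE)
    B <- sort(unique(c(a$points$B0[a$points$B0 >= lo & a$points$B0 <= hi],
                       b$points$B0[b$points$B0 >= lo & b$points$B0 <= hi])))
    ia <- interp_rates(a, B); ib <- interp_rates(b, B)
    Ra <- ia$rate; Rb <- ib$rate; sa <- ia$rate_sd; sb <- ib$rate_sd
  }
  sd_d <- sqrt(ifelse(is.na(sa), 0, sa)^2 + ifelse(is.na(sb), 0, sb)^2)
  sd_d[is.na(sa) & is.na(sb)] <- NA_real_
  structure(list(pair = c(a$sample_id, b$sample_id),
                 points = data.frame(B0 = B, delta_R1 = Ra - Rb, delta_R1_sd = sd_d)),
            class = "rate_difference")
}

#' @export
print.rate_difference <- function(x, ...) {
  cat(sprintf("Rate difference %s - %s: %d fields, delta_R1 %.3g to %.3g s^-1\n",
              x$pair[1], x$pair[2], nrow(x$points),
              min(x$points$delta_R1), max(x$points$delta_R1)))
  invisible(x)
}

#' Rate difference of two band means
#'
#' Same subtraction and error propagation as [subtract_rate_profiles()], but
#' applied to a pair of band-mean T1 values (e.g. low-field means of two
#' samples), as used for the field-independent dipolar contributions.
#'
#' @param T1_a,T1_b Band-mean T1 values, s.
#' @param sd_a,sd_b Their standard deviations, s (optional).
#' @return List with \code{delta_R1} and \code{delta_R1_sd} (s^-1).
#' @examples
#' subtract_band_means(51.5, 84.2)   # ~7.5e-3 s^-1 (O2 + metal difference context)
#' @export
subtract_band_means <- function(T1_a, T1_b, sd_a = NA_real_, sd_b = NA_real_) {
  if (T1_a <= 0 || T1_b <= 0) stop("T1 values must be > 0", call. = FALSE)
  sd <- sqrt(ifelse(is.na(sd_a), 0, sd_a / T1_a^2)^2 +
             ifelse(is.na(sd_b), 0, sd_b / T1_b^2)^2)
  list(delta_R1 = 1 / T1_a - 1 / T1_b,
       delta_R1_sd = if (is.na(sd_a) && is.na(sd_b)) NA_real_ else sd)
}
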