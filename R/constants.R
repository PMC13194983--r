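#' Nuclear and electron spin constants
#'
#' Returns the CODATA-grade physical constants used throughout the relaxation
#' rate laws: gyromagnetic ratios of 1H, 13C, 2H and the free electron (all in
#' rad s^-1 T^-1, electron by magnitude), the nuclear spin quantum numbers of
#' 1H and 2H, the reduced Planck constant and the Boltzmann constant.
#'
#' @return An object of class \code{spin_constants}: a named list with elements
#'   \code{gamma_H}, \code{gamma_C}, \code{gamma_D}, \code{gamma_e},
#'   \code{I_H}, \code{I_D}, \code{hbar}, \code{k_B}.
#' @examples
#' sc <- spin_constants()
#' sc$gamma_H / sc$gamma_C  # ~ 3.976
#' @export
spin_constants <- function() {
  sc <- list(
    gamma_H = 2.6752218744e8,   # rad s^-1 T^-1
    gamma_C = 6.728284e7,
    gamma_D = 4.10662919e7,
    gamma_e = 1.76085963023e11, # magnitude; sign irrelevant in |omega| Lorentzians
    I_H     = 0.5,
    I_D     = 1,
    hbar    = 1.054571817e-34,  # J s
    k_B     = 1.380649e-23      # J K^-1
  )
  class(sc) <- "spin_constants"
  validate_spin_constants(sc)
  sc
}

validate_spin_constants <- function(sc) {
  need <- c("gamma_H", "gamma_C", "gamma_D", "gamma_e", "I_H", "I_D", "hbar", "k_B")
  missing <- setdiff(need, names(sc))
  if (length(missing) > 0L)
    stop("spin_constants is missing: ", paste(missing, collapse = ", "), call. = FALSE)
  vals <- unlist(sc[need])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all spin constants must be finite and positive (magnitudes)", call. = FALSE)
  # plausibility guards against unit mistakes (ratios are isotope properties)
  if (abs(sc$gamma_H / sc$gamma_C - 3.976) / 3.976 > 0.001)
    stop("gamma_H/gamma_C inconsistent with 1H/13C (expected ~3.976)", call. = FALSE)
  if (abs((sc$gamma_H / sc$gamma_D)^2 - 42.44) / 42.44 > 0.001)
    stop("(gamma_H/gamma_D)^2 inconsistent with 1H/2H (expected ~42.44)", call. = FALSE)
  invisible(sc)
}

#' @export
print.spin_constants <- function(x, ...) {
  cat("Spin constants (SI units):\n")
  cat(sprintf("  gamma_H = %.9e rad/s/T   gamma_C = %.7e rad/s/T\n", x$gamma_H, x$gamma_C))
  cat(sprintf("  gamma_D = %.8e rad/s/T   |gamma_e| = %.10e rad/s/T\n", x$gamma_D, x$gamma_e))
  cat(sprintf("  I_H = %g, I_D = %g; hbar = %.9e J s, k_B = %.6e J/K\n",
              x$I_H, x$I_D, x$hbar, x$k_B))
  invisible(x)
}

#' Dipolar scaling factor for 1H -> 2H substitution
#'
#' Replacing a proton by a deuteron reduces the heteronuclear dipole-dipole
#' relaxation rate it drives by
#' \deqn{f = \frac{I_H(I_H+1)}{I_D(I_D+1)} \left(\frac{\gamma_H}{\gamma_D}\right)^2}
#' which evaluates to about 15.9 for standard constants. Dividing a
#' proton-driven rate by this factor gives the residual deuteron-driven rate.
#'
#' @param constants A \code{spin_constants} list (default \code{spin_constants()}).
#' @param I_X,I_Y Optional spin quantum numbers overriding \code{I_H}/\code{I_D}
#'   (to evaluate the factor for another isotope pair).
#' @param gamma_X,gamma_Y Optional gyromagnetic ratios overriding
#'   \code{gamma_H}/\code{gamma_D}.
#' @return The dimensionless scaling factor.
#' @examples
#' deuteration_factor()                     # ~ 15.91
#' 0.0095 / deuteration_factor()            # residual rate after solvent deuteration
#' @export
deuteration_factor <- function(constants = spin_constants(),
                               I_X = constants$I_H, I_Y = constants$I_D,
                               gamma_X = constants$gamma_H, gamma_Y = constants$gamma_D) {
  if (any(c(I_X, I_Y) <= 0) || any(c(gamma_X, gamma_Y) <= 0))
    stop("spin quantum numbers and gyromagnetic ratio magnitudes must be positive",
         call. = FALSE)
  (I_X * (I_X + 1)) / (I_Y * (I_Y + 1)) * (gamma_X / gamma_Y)^2
}
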