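NMRD_HEADER <- c("sample_id", "B0_T", "T1_s", "T1_sd_s", "n_obs")
DECAY_HEADER <- c("time_s", "signal", "flip_angle_deg")
PROFILE_HEADER <- c("time_s", "B_T")

#' Read NMRD profiles from CSV
#'
#' Expects the exact header \code{sample_id,B0_T,T1_s,T1_sd_s,n_obs}
#' (the SD and count columns may be empty). One [nmrd_profile()] is built per
#' distinct \code{sample_id}; rows are validated and sorted by field. Parse
#' errors name the offending data row.
#'
#' @param path CSV file path.
#' @return Named list of [nmrd_profile()].
#' @export
read_nmrd_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), NMRD_HEADER))
    stop("malformed NMRD header in ", path, ": expected '",
         paste(NMRD_HEADER, collapse = ","), "', got '",
         paste(names(df), collapse = ","), "'", call. = FALSE)
  bad <- which(!is.finite(df$B0_T) | df$B0_T <= 0 | !is.finite(df$T1_s) | df$T1_s <= 0)
  if (length(bad) > 0L)
    stop("non-positive or missing B0/T1 at data row ", bad[1],
         " (line ", bad[1] + 1L, " of ", path, ")", call. = FALSE)
  out <- lapply(split(df, df$sample_id), function(d) {
    nmrd_profile(d$sample_id[1], d$B0_T, d$T1_s,
                 T1_sd = suppressWarnings(as.numeric(d$T1_sd_s)),
                 n_obs = ifelse(is.na(d$n_obs), 1L, as.integer(d$n_obs)))
  })
  out[unique(df$sample_id)]
}

#' Write NMRD profiles to CSV
#'
#' Inverse of [read_nmrd_csv()]; finite values round-trip losslessly at 12
#' significant digits.
#'
#' @param profiles A single [nmrd_profile()] or a list of them.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_nmrd_csv <- function(profiles, path) {
  if (inherits(profiles, "nmrd_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id,
               B0_T = signif(p$points$B0, 12), T1_s = signif(p$points$T1, 12),
               T1_sd_s = signif(p$points$T1_sd, 12), n_obs = p$points$n_obs,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a decay series from CSV (\code{time_s,signal,flip_angle_deg})
#' @param path CSV file path.
#' @return A [decay_series()].
#' @export
read_decay_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), DECAY_HEADER))
    stop("malformed decay header in ", path, ": expected '",
         paste(DECAY_HEADER, collapse = ","), "'", call. = FALSE)
  decay_series(df$time_s, df$signal, flip_angle_deg = df$flip_angle_deg[1])
}

#' Write a decay series to CSV
#' @param series A [decay_series()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_decay_csv <- function(series, path) {
  df <- data.frame(time_s = signif(series$time, 12),
                   signal = signif(series$signal, 12),
                   flip_angle_deg = series$flip_angle_deg)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field-time trajectory from CSV (\code{time_s,B_T})
#' @param path CSV file path.
#' @return A [field_time_profile()].
#' @export
read_field_profile_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), PROFILE_HEADER))
    stop("malformed field-profile header in ", path, ": expected '",
         paste(PROFILE_HEADER, collapse = ","), "'", call. = FALSE)
  field_time_profile(df$time_s, df$B_T)
}
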