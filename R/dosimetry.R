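# ICNIRP (2004) actinic UV hazard table, 200-400 nm: 8-h exposure limits
# (mJ cm^-2) and relative spectral effectiveness S(lambda), anchored at
# S = 1, 3 mJ cm^-2 at 270 nm. Shipped as physical constants.
.icnirp <- tibble::tibble(
  wavelength_nm = c(200, 205, 210, 215, 220, 225, 230, 235, 240, 245, 250,
                    255, 260, 265, 270, 275, 280, 285, 290, 295, 300, 305,
                    310, 315, 320, 325, 330, 335, 340, 345, 350, 355, 360,
                    365, 370, 375, 380, 385, 390, 395, 400),
  limit_mJ_cm2 = c(100, 59, 40, 32, 25, 20, 16, 13, 10, 8.3, 7.0,
                   5.8, 4.6, 3.7, 3.0, 3.1, 3.4, 3.9, 4.7, 5.6, 10, 50,
                   200, 1000, 2900, 6000, 7300, 8800, 11000, 13000, 15000,
                   19000, 23000, 27000, 32000, 39000, 47000, 57000, 68000,
                   83000, 100000),
  S = c(0.03, 0.051, 0.075, 0.095, 0.12, 0.15, 0.19, 0.24, 0.30, 0.36, 0.43,
        0.52, 0.65, 0.81, 1.00, 0.96, 0.88, 0.77, 0.64, 0.54, 0.30, 0.060,
        0.015, 0.003, 0.0010, 0.00050, 0.00041, 0.00034, 0.00028, 0.00024,
        0.00020, 0.00016, 0.00013, 0.00011, 0.000093, 0.000077, 0.000064,
        0.000053, 0.000044, 0.000036, 0.000030)
)

#' ICNIRP actinic-hazard weighting
#'
#' The tabulated ICNIRP ultraviolet guidelines (Health Phys 87:171-186, 2004):
#' 8-hour exposure limits (mJ cm^-2) and relative spectral effectiveness
#' S(lambda) on 200-400 nm, with the S = 1 anchor at 270 nm where the limit
#' is 3 mJ cm^-2. Limits are interpolated linearly in wavelength (giving the
#' widely quoted 23 mJ cm^-2 at 222 nm from the 220 and 225 nm entries);
#' S is interpolated log-linearly, as is standard for actinic weighting.
#'
#' @return A tibble with columns `wavelength_nm`, `limit_mJ_cm2`, `S` and a
#'   `citation` attribute.
#' @export
icnirp_weighting <- function() {
  structure(.icnirp,
            citation = paste("ICNIRP (2004) Guidelines on limits of exposure",
                             "to ultraviolet radiation of wavelengths between",
                             "180 nm and 400 nm. Health Physics 87:171-186."))
}

# 222 nm susceptibility constants for the packaged pathogens. D90 is the
# radiant exposure (mJ cm^-2) per log10 reduction; k = ln(10)/D90. The
# SARS-CoV-2 surface entry is back-calculated from the reported 99.7%
# reduction at 3.0 mJ cm^-2 assuming first-order kinetics.
.pathogens <- tibble::tibble(
  id = c("hcov229e_aerosol", "hcov_oc43_aerosol", "sars_cov_2_surface"),
  pathogen = c("HCoV-229E", "HCoV-OC43", "SARS-CoV-2"),
  medium = c("aerosol", "aerosol", "surface"),
  k_cm2_mJ = c(4.1, 5.9, log(10) / (3.0 / log10(1 / 0.003))),
  source = c(
    paste("Buonanno et al. (2020) Far-UVC light (222 nm) efficiently and",
          "safely inactivates airborne human coronaviruses.",
          "Sci Rep 10:10285."),
    paste("Buonanno et al. (2020) Far-UVC light (222 nm) efficiently and",
          "safely inactivates airborne human coronaviruses.",
          "Sci Rep 10:10285."),
    paste("Kitagawa et al. (2021) Effectiveness of 222-nm ultraviolet light",
          "on disinfecting SARS-CoV-2 surface contamination.",
          "Am J Infect Control 49:299-301 (99.7% at 3.0 mJ cm^-2).")
  )
)
.pathogens$D90_mJ_cm2 <- log(10) / .pathogens$k_cm2_mJ

#' Packaged pathogen susceptibility constants
#'
#' First-order (single-exponential) 222 nm inactivation constants for the
#' coronaviruses discussed alongside far-UVC skin exposure work, with their
#' source citations. `D90_mJ_cm2` is the dose per 1-log (90%) reduction;
#' `k_cm2_mJ = ln(10)/D90`.
#'
#' @return A tibble, one row per pathogen/medium combination.
#' @export
uv_pathogens <- function() .pathogens

#' @rdname uv_pathogens
#' @param id One of `uv_pathogens()$id`.
#' @return For `inactivation_parameters()`, a one-row tibble.
#' @export
inactivation_parameters <- function(id) {
  row <- .pathogens[.pathogens$id == id, ]
  if (nrow(row) != 1) {
    stop("unknown pathogen id '", id, "'; see uv_pathogens()$id",
         call. = FALSE)
  }
  row
}

#' Radiant exposure from irradiance and time
#'
#' The exact product `irradiance * duration` (mW cm^-2 times s gives
#' mJ cm^-2). Display rounding is a separate concern: see
#' [display_exposure()].
#'
#' @param irradiance_mW_cm2 Irradiance, mW cm^-2, >= 0.
#' @param duration_s Exposure time, s, >= 0.
#' @return Radiant exposure in mJ cm^-2.
#' @export
radiant_exposure <- function(irradiance_mW_cm2, duration_s) {
  if (any(irradiance_mW_cm2 < 0) || any(duration_s < 0)) {
    stop("irradiance and duration must be non-negative", call. = FALSE)
  }
  irradiance_mW_cm2 * duration_s
}

#' Round an exposure for display at 2 significant figures
#'
#' Matches the convention of reporting radiant exposures such as 1500 and
#' 18 000 mJ cm^-2; exact values should be retained internally.
#'
#' @param x Radiant exposure(s), mJ cm^-2.
#' @return `x` rounded to 2 significant figures.
#' @export
display_exposure <- function(x) signif(x, 2)

#' Actinic-hazard effective irradiance
#'
#' Trapezoidal integral of `E(lambda) * S(lambda)` over the spectrum's grid,
#' with the relative spectral effectiveness S interpolated log-linearly
#' between table points. Requires an absolute spectrum.
#'
#' @param s An absolute `uvc_spectrum` (mW cm^-2 nm^-1).
#' @param w A weighting table as from [icnirp_weighting()].
#' @return Effective irradiance in mW cm^-2.
#' @export
effective_irradiance <- function(s, w = icnirp_weighting()) {
  validate_spectrum(s)
  if (!identical(unit_kind(s), "absolute")) {
    stop("effective irradiance needs an absolute spectrum; ",
         "use rescale_to_band_irradiance() first", call. = FALSE)
  }
  wl <- s$wavelength_nm
  if (min(wl) < min(w$wavelength_nm) || max(wl) > max(w$wavelength_nm)) {
    stop("weighting table does not cover the spectrum's support",
         call. = FALSE)
  }
  S <- exp(stats::approx(w$wavelength_nm, log(w$S), xout = wl)$y)
  band_integral(wl, s$value * S, min(wl), max(wl))
}

#' Monochromatic 8-hour exposure limit
#'
#' Linear interpolation of the tabulated 8-h limits between the bracketing
#' table wavelengths; at 222 nm this yields 23 mJ cm^-2 from the 220 nm
#' (25 mJ cm^-2) and 225 nm (20 mJ cm^-2) entries.
#'
#' @param wavelength_nm Wavelength within the limit table's span.
#' @param w A weighting table as from [icnirp_weighting()].
#' @return 8-h exposure limit in mJ cm^-2.
#' @export
monochromatic_limit <- function(wavelength_nm, w = icnirp_weighting()) {
  if (any(wavelength_nm < min(w$wavelength_nm)) ||
      any(wavelength_nm > max(w$wavelength_nm))) {
    stop("wavelength outside the limit table's span", call. = FALSE)
  }
  stats::approx(w$wavelength_nm, w$limit_mJ_cm2, xout = wavelength_nm)$y
}

#' Permissible exposure time at a given effective irradiance
#'
#' @param effective_irradiance_mW_cm2 Actinic-weighted irradiance, mW cm^-2.
#' @param limit_mJ_cm2 Exposure limit, mJ cm^-2.
#' @return Permissible time in seconds; `Inf` (with a warning) for zero
#'   irradiance.
#' @export
permissible_time <- function(effective_irradiance_mW_cm2, limit_mJ_cm2) {
  if (effective_irradiance_mW_cm2 < 0) {
    stop("irradiance must be non-negative", call. = FALSE)
  }
  if (effective_irradiance_mW_cm2 == 0) {
    warning("zero effective irradiance: permissible time is unbounded",
            call. = FALSE)
    return(Inf)
  }
  limit_mJ_cm2 / effective_irradiance_mW_cm2
}

#' Surviving fraction after a germicidal dose
#'
#' Single-exponential kinetics: `10^(-dose/D90)`.
#'
#' @param dose_mJ_cm2 Radiant exposure, mJ cm^-2, >= 0.
#' @param p A one-row pathogen tibble, see [inactivation_parameters()].
#' @return Surviving fraction in `(0, 1]`.
#' @export
survival_fraction <- function(dose_mJ_cm2, p) {
  if (any(dose_mJ_cm2 < 0)) stop("dose must be non-negative", call. = FALSE)
  10^(-dose_mJ_cm2 / p$D90_mJ_cm2)
}

#' Time to reach a target log reduction
#'
#' `n_logs * D90 / irradiance` seconds: the dose-reciprocity arithmetic of
#' first-order inactivation.
#'
#' @param n_logs Target log10 reduction, >= 0 (3 logs = 99.9%).
#' @param irradiance_mW_cm2 Delivered irradiance, mW cm^-2.
#' @param p A one-row pathogen tibble, see [inactivation_parameters()].
#' @return Time in seconds; `Inf` (with a warning) for zero irradiance.
#' @export
time_to_log_reduction <- function(n_logs, irradiance_mW_cm2, p) {
  if (any(n_logs < 0)) stop("n_logs must be non-negative", call. = FALSE)
  if (irradiance_mW_cm2 < 0) {
    stop("irradiance must be non-negative", call. = FALSE)
  }
  if (irradiance_mW_cm2 == 0) {
    warning("zero irradiance: inactivation never completes", call. = FALSE)
    return(ifelse(n_logs == 0, 0, Inf))
  }
  n_logs * p$D90_mJ_cm2 / irradiance_mW_cm2
}
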