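#' Synthetic KrCl lamp specification
#'
#' Parameters for a krypton-chloride excimer lamp emission model: a Gaussian
#' principal peak (default 222 nm, 2 nm FWHM), a set of weak long-wavelength
#' Gaussian lines, and a flat continuum confined to the 230-280 nm window
#' (with short raised-cosine ramps inside the window). Amplitudes are
#' relative to the principal peak and must not exceed 1.
#'
#' @param peak_nm Principal emission wavelength.
#' @param peak_fwhm_nm Full width at half maximum of the principal peak.
#' @param long_wavelength_lines Tibble with `center_nm`, `amplitude`,
#'   `fwhm_nm` for the low-power long-wavelength emissions.
#' @param continuum_amplitude Relative amplitude of the 230-280 nm continuum.
#' @param continuum_range_nm Window of the continuum emission.
#' @param pitch_nm Wavelength grid pitch of generated spectra.
#' @return A list of class `lamp_specification`.
#' @export
lamp_specification <- function(peak_nm = 222, peak_fwhm_nm = 2,
                               long_wavelength_lines = tibble::tibble(
                                 center_nm = c(237, 258, 270),
                                 amplitude = c(0.03, 0.05, 0.02),
                                 fwhm_nm = c(4, 8, 6)
                               ),
                               continuum_amplitude = 0.004,
                               continuum_range_nm = c(230, 280),
                               pitch_nm = 0.5) {
  long_wavelength_lines <- tibble::as_tibble(long_wavelength_lines)
  amps <- c(long_wavelength_lines$amplitude, continuum_amplitude)
  if (length(amps) && (any(amps < 0) || any(amps > 1))) {
    stop("relative amplitudes must lie in [0, 1]", call. = FALSE)
  }
  structure(list(peak_nm = peak_nm, peak_fwhm_nm = peak_fwhm_nm,
                 long_wavelength_lines = long_wavelength_lines,
                 continuum_amplitude = continuum_amplitude,
                 continuum_range_nm = continuum_range_nm,
                 pitch_nm = pitch_nm),
            class = "lamp_specification")
}

gaussian_line <- function(wl, center, amplitude, fwhm) {
  amplitude * exp(-4 * log(2) * ((wl - center) / fwhm)^2)
}

#' Generate a synthetic KrCl lamp spectrum
#'
#' Builds the 200-400 nm emission spectrum from a [lamp_specification()] and
#' applies the filtering stage: `"filtered"` multiplies all 230-280 nm
#' content by `suppression["filtered"]` (default 1e-2), `"additional"` by
#' `suppression["additional"]` (default 1e-4), emulating the progressively
#' filtered sources used in far-UVC skin work. The result is peak-normalized.
#'
#' @param spec A [lamp_specification()].
#' @param filtering `"unfiltered"`, `"filtered"` or `"additional"`.
#' @param suppression Named suppression factors for the 230-280 nm band.
#' @param noise_sd Multiplicative Gaussian noise (relative), default 0.
#' @param seed Seed used when `noise_sd > 0`.
#' @return A peak-normalized relative [spectral_distribution()].
#' @export
make_lamp_spectrum <- function(spec = lamp_specification(),
                               filtering = c("unfiltered", "filtered",
                                             "additional"),
                               suppression = c(filtered = 1e-2,
                                               additional = 1e-4),
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(spec, "lamp_specification"))
  filtering <- match.arg(filtering)
  wl <- seq(200, 400, by = spec$pitch_nm)
  v <- gaussian_line(wl, spec$peak_nm, 1, spec$peak_fwhm_nm)
  lines <- spec$long_wavelength_lines
  for (i in seq_len(nrow(lines))) {
    v <- v + gaussian_line(wl, lines$center_nm[i], lines$amplitude[i],
                           lines$fwhm_nm[i])
  }
  rng <- spec$continuum_range_nm
  ramp <- 4 # nm, raised-cosine edges inside the continuum window
  cont <- rep(0, length(wl))
  inside <- wl >= rng[1] & wl <= rng[2]
  cont[inside] <- spec$continuum_amplitude
  lo_edge <- inside & wl < rng[1] + ramp
  hi_edge <- inside & wl > rng[2] - ramp
  cont[lo_edge] <- cont[lo_edge] *
    (1 - cos(pi * (wl[lo_edge] - rng[1]) / ramp)) / 2
  cont[hi_edge] <- cont[hi_edge] *
    (1 - cos(pi * (rng[2] - wl[hi_edge]) / ramp)) / 2
  v <- v + cont
  if (filtering != "unfiltered") {
    f <- unname(suppression[[filtering]])
    band <- wl >= 230 & wl <= 280
    v[band] <- v[band] * f
  }
  if (noise_sd > 0) {
    v <- with_seed(seed, v * pmax(0, 1 + stats::rnorm(length(v), 0, noise_sd)))
  }
  normalize_to_peak(spectral_distribution(wl, v, "relative"))
}

#' Load a skin optical-property preset
#'
#' Reads a [skin_model()] from a YAML configuration holding every optical
#' constant. `"default"` is the shipped synthetic 5-layer preset (stratum
#' corneum 20 um, living epidermis 80 um, papillary dermis 150 um, reticular
#' dermis 1000 um, subcutis backstop) with markers at the top of the
#' epidermis (20 um), mid-epidermis (60 um) and basal layer (100 um).
#'
#' @param name A preset name (currently `"default"`) or a path to a YAML
#'   file written by [write_skin_config()].
#' @return A [skin_model()].
#' @export
make_skin_preset <- function(name = "default") {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", paste0("skin_", name, ".yaml"), package = "faruvc")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown skin preset '", name, "'", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  layers <- purrr::map_dfr(cfg$layers, tibble::as_tibble)
  # the config dialect spells the index 'refractive_index' (a bare 'n' is a
  # YAML 1.1 boolean)
  layers <- dplyr::rename(layers, n = "refractive_index")
  skin_model(layers, markers = unlist(cfg$markers),
             ambient_n = cfg$ambient_n,
             wl_range_nm = as.numeric(cfg$wl_range_nm),
             name = cfg$name)
}

#' @rdname make_skin_preset
#' @param model A [skin_model()].
#' @param path Output YAML path.
#' @export
write_skin_config <- function(model, path) {
  layers <- dplyr::rename(model$layers, refractive_index = "n")
  cfg <- list(
    name = model$name,
    ambient_n = model$ambient_n,
    wl_range_nm = model$wl_range_nm,
    markers = as.list(model$markers),
    layers = purrr::transpose(as.list(layers))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Yellowing-response kinetics
#'
#' Phenomenological model of the dose-dependent, stratum-corneum-confined
#' skin yellowing seen after large filtered far-UVC exposures: a yellow
#' chromophore (blue-band absorber) of amplitude
#' `A(dose) = A_max * max(0, 1 - exp(-(dose - threshold_dose)/D0))`
#' appearing immediately post-exposure and clearing as `exp(-t/tau_h)`.
#' Tape stripping removes the fraction `strip_factor` of the remaining
#' chromophore. No mechanism is claimed; every constant is configuration.
#'
#' @param A_max Maximal chromophore amplitude (absorbance-like units).
#' @param D0 Dose scale of the saturating response, mJ cm^-2.
#' @param tau_h Clearance time constant, hours. The default 6 h makes the
#'   6000 mJ cm^-2 response fall below the measurement noise floor by 24 h.
#' @param threshold_dose Dose below which no response occurs, mJ cm^-2.
#' @param strip_factor Fraction of chromophore removed by tape stripping.
#' @param noise_sd Gaussian reflectance measurement noise (per band).
#' @return A list of class `yellowing_kinetics`.
#' @export
yellowing_kinetics <- function(A_max = 0.06, D0 = 6000, tau_h = 6,
                               threshold_dose = 3000, strip_factor = 0.8,
                               noise_sd = 0.002) {
  stopifnot(A_max > 0, D0 > 0, tau_h > 0, threshold_dose >= 0,
            strip_factor >= 0, strip_factor <= 1, noise_sd >= 0)
  structure(list(A_max = A_max, D0 = D0, tau_h = tau_h,
                 threshold_dose = threshold_dose,
                 strip_factor = strip_factor, noise_sd = noise_sd),
            class = "yellowing_kinetics")
}

# Measurement grid and baseline of the synthetic reflectance instrument:
# 400-700 nm at 10 nm pitch, a smooth pale-skin-like curve rising from 0.3
# to 0.6. Documented constants; no external data.
reflectance_grid <- function() seq(400, 700, by = 10)

#' @rdname yellowing_kinetics
#' @param wavelength_nm Wavelengths, nm.
#' @export
baseline_reflectance <- function(wavelength_nm) {
  0.3 + 0.3 * (wavelength_nm - 400) / 300
}

# Spectral absorbance shape of the yellow chromophore: a blue-band Gaussian.
chromophore_absorbance <- function(wavelength_nm) {
  exp(-((wavelength_nm - 445) / 55)^2)
}

#' Chromophore dose-response amplitude
#'
#' @param dose_mJ_cm2 Radiant exposure, mJ cm^-2.
#' @param k A [yellowing_kinetics()].
#' @return Chromophore amplitude `A(dose)`.
#' @export
yellowing_amplitude <- function(dose_mJ_cm2, k) {
  k$A_max * pmax(0, 1 - exp(-(dose_mJ_cm2 - k$threshold_dose) / k$D0))
}

#' Map chromophore amplitude to the delta-b* it produces
#'
#' Applies the chromophore to the baseline reflectance on the instrument
#' grid and returns `b*(A) - b*(0)`. Monotone increasing in `A`; used both
#' by the generator and, inverted, for parameter recovery.
#'
#' @param A Chromophore amplitude(s).
#' @param weights Colorimetric weights, see [cie_weights()].
#' @return delta-b* value(s).
#' @export
yellowing_delta_b <- function(A, weights = cie_weights()) {
  wl <- reflectance_grid()
  r0 <- baseline_reflectance(wl)
  sig <- chromophore_absorbance(wl)
  b0 <- lab_one(wl, r0, weights)[["b_star"]]
  vapply(A, function(a) {
    lab_one(wl, r0 * 10^(-a * sig), weights)[["b_star"]] - b0
  }, numeric(1))
}

#' Generate a synthetic reflectance time series
#'
#' Baseline skin reflectance with a dose-dependent yellow chromophore that
#' appears immediately after exposure and decays exponentially, optional
#' tape-strip event, and per-band Gaussian measurement noise. The
#' `time_h == 0` row is the pre-irradiation baseline.
#'
#' @param dose_mJ_cm2 Radiant exposure, mJ cm^-2.
#' @param times_h Measurement times in hours; must include 0.
#' @param k A [yellowing_kinetics()].
#' @param tape_strip_at_h Optional time of a tape-strip event; measurements
#'   at `time_h >= tape_strip_at_h` see the stripped chromophore.
#' @param seed Seed for the measurement noise.
#' @param site Site label; defaults to the dose.
#' @return Long tibble: `site`, `time_h`, `wavelength_nm`, `reflectance`.
#' @export
make_reflectance_series <- function(dose_mJ_cm2,
                                    times_h = c(0, 1, 2, 3, 5, 8, 12, 24),
                                    k = yellowing_kinetics(),
                                    tape_strip_at_h = NULL, seed = NULL,
                                    site = sprintf("dose_%g", dose_mJ_cm2)) {
  if (dose_mJ_cm2 < 0) stop("dose must be non-negative", call. = FALSE)
  if (!0 %in% times_h) {
    stop("times_h must include the pre-irradiation baseline 0", call. = FALSE)
  }
  wl <- reflectance_grid()
  r0 <- baseline_reflectance(wl)
  sig <- chromophore_absorbance(wl)
  A0 <- yellowing_amplitude(dose_mJ_cm2, k)
  with_seed(seed, {
    purrr::map_dfr(sort(times_h), function(t) {
      A <- if (t == 0) 0 else A0 * exp(-t / k$tau_h)
      if (!is.null(tape_strip_at_h) && t >= tape_strip_at_h) {
        A <- A * (1 - k$strip_factor)
      }
      r <- r0 * 10^(-A * sig)
      if (k$noise_sd > 0) {
        r <- pmax(0, r + stats::rnorm(length(wl), 0, k$noise_sd))
      }
      tibble::tibble(site = site, time_h = t, wavelength_nm = wl,
                     reflectance = r)
    })
  })
}

#' Recover clearance and dose-response parameters from delta-b* series
#'
#' `fit_yellowing_tau()` inverts the monotone amplitude-to-delta-b* map at
#' each post-baseline time point (root finding to 1e-12) and fits
#' `log A(t) ~ t` by least squares, so that noise-free generated series
#' return `tau_h` to solver precision. `fit_dose_response()` then fits the
#' saturating dose-response `A0(dose) = A_max (1 - exp(-(dose - thr)/D0))`
#' across doses by nonlinear least squares.
#'
#' @param deltas Output of [delta_series()] for one site.
#' @param weights Colorimetric weights used for the series.
#' @return `fit_yellowing_tau()`: an object of class `yellowing_fit` with
#'   elements `tau_h`, `A0` (amplitude at t = 0+), `amplitudes` (per-time
#'   recovered amplitudes) and the underlying `lm` fit.
#' @export
fit_yellowing_tau <- function(deltas, weights = cie_weights()) {
  d <- deltas[deltas$time_h > 0, ]
  if (nrow(d) < 2) stop("need >= 2 post-baseline points", call. = FALSE)
  invert <- function(db) {
    if (db <= 0) return(NA_real_)
    stats::uniroot(function(a) yellowing_delta_b(a, weights) - db,
                   c(0, 1), extendInt = "upX", tol = 1e-12)$root
  }
  A <- vapply(d$delta_b, invert, numeric(1))
  if (anyNA(A) || any(A <= 0)) {
    stop("non-positive delta_b: cannot recover amplitudes", call. = FALSE)
  }
  fit <- stats::lm(log(A) ~ d$time_h)
  slope <- unname(stats::coef(fit)[2])
  structure(list(tau_h = -1 / slope,
                 A0 = exp(unname(stats::coef(fit)[1])),
                 amplitudes = tibble::tibble(time_h = d$time_h, A = A),
                 fit = fit),
            class = "yellowing_fit")
}

#' @rdname fit_yellowing_tau
#' @param amplitudes A tibble with columns `dose` and `A0` (amplitude at
#'   t = 0+), doses above the threshold.
#' @param threshold_dose Known response threshold, mJ cm^-2.
#' @return `fit_dose_response()`: a list with `D0`, `A_max` and the `nls`
#'   fit.
#' @export
fit_dose_response <- function(amplitudes, threshold_dose) {
  stopifnot(all(c("dose", "A0") %in% names(amplitudes)),
            nrow(amplitudes) >= 3)
  fit <- stats::nls(
    A0 ~ A_max * (1 - exp(-(dose - threshold_dose) / D0)),
    data = amplitudes,
    start = list(A_max = max(amplitudes$A0) * 1.2,
                 D0 = diff(range(amplitudes$dose)) / 2),
    # scaleOffset makes the convergence test well-defined for the
    # zero-residual (noise-free) case
    control = stats::nls.control(tol = 1e-10, maxiter = 500, scaleOffset = 1)
  )
  co <- stats::coef(fit)
  list(D0 = unname(co[["D0"]]), A_max = unname(co[["A_max"]]), fit = fit)
}

#' @export
print.yellowing_fit <- function(x, ...) {
  cat(sprintf("<yellowing_fit: tau_h = %.4g h, A0 = %.4g>\n", x$tau_h, x$A0))
  invisible(x)
}

#' @rdname fit_yellowing_tau
#' @param x A `yellowing_fit`.
#' @param ... Unused.
#' @export
tidy.yellowing_fit <- function(x, ...) {
  tibble::tibble(term = c("tau_h", "A0"), estimate = c(x$tau_h, x$A0))
}

#' @rdname fit_yellowing_tau
#' @export
glance.yellowing_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 n = nrow(x$amplitudes))
}
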