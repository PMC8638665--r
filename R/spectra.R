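#' Spectral distributions
#'
#' A spectral distribution is a tibble with columns `wavelength_nm` (strictly
#' ascending) and `value` (non-negative spectral magnitude per nm). Its
#' `unit_kind` attribute records whether values are `"relative"`
#' (dimensionless, typically peak-normalized) or `"absolute"`
#' (mW cm^-2 nm^-1).
#'
#' @param wavelength_nm Strictly ascending numeric wavelengths in nm.
#' @param value Non-negative spectral values, one per wavelength.
#' @param unit_kind `"relative"` or `"absolute"`.
#' @return A tibble of class `uvc_spectrum`.
#' @examples
#' s <- spectral_distribution(c(200, 222, 400), c(0, 1, 0))
#' unit_kind(s)
#' @export
spectral_distribution <- function(wavelength_nm, value,
                                  unit_kind = c("relative", "absolute")) {
  unit_kind <- match.arg(unit_kind)
  out <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                        value = as.numeric(value))
  out <- new_uvc_spectrum(out, unit_kind)
  validate_spectrum(out)
  out
}

new_uvc_spectrum <- function(df, unit_kind) {
  structure(df, unit_kind = unit_kind,
            class = c("uvc_spectrum", class(tibble::tibble())))
}

validate_spectrum <- function(s, what = "spectrum") {
  if (nrow(s) < 2) {
    stop(what, " must have at least 2 rows", call. = FALSE)
  }
  if (anyNA(s$wavelength_nm) || anyNA(s$value)) {
    stop(what, " contains missing values", call. = FALSE)
  }
  if (any(diff(s$wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing (input is not sorted; ",
         "refusing to sort silently)", call. = FALSE)
  }
  if (any(s$value < 0)) {
    stop("spectral values must be non-negative", call. = FALSE)
  }
  invisible(s)
}

#' @rdname spectral_distribution
#' @param s A `uvc_spectrum`.
#' @export
unit_kind <- function(s) attr(s, "unit_kind")

#' Read a two-column spectral file
#'
#' Accepts whitespace- or comma-delimited text with `#` comment lines, the
#' dialect common to spectroradiometer exports: column 1 wavelength (nm),
#' column 2 spectral value. Wavelengths must arrive strictly ascending; an
#' unsorted file is rejected rather than silently re-ordered.
#'
#' @param path Path to (or connection for) the file.
#' @param unit_kind Unit interpretation of column 2.
#' @return A [spectral_distribution()].
#' @export
read_spectrum <- function(path, unit_kind = c("relative", "absolute")) {
  unit_kind <- match.arg(unit_kind)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop("spectral file must contain at least 2 data rows", call. = FALSE)
  }
  parts <- strsplit(lines, "[,[:space:]]+")
  if (any(lengths(parts) != 2)) {
    stop("each data row must contain exactly two fields", call. = FALSE)
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  )
  if (anyNA(mat)) stop("non-numeric field in spectral file", call. = FALSE)
  spectral_distribution(mat[, 1], mat[, 2], unit_kind)
}

#' Write a spectral distribution as two-column text
#'
#' @param s A `uvc_spectrum`.
#' @param path Output path.
#' @param comment Optional comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, comment = NULL) {
  hdr <- c(sprintf("# unit_kind: %s", unit_kind(s)),
           if (!is.null(comment)) paste("#", comment))
  body <- sprintf("%.6f %.10g", s$wavelength_nm, s$value)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Peak-normalize a spectrum
#'
#' Divides by the maximum value so `max(value) == 1`; the result is marked
#' `"relative"`. Idempotent.
#'
#' @param s A `uvc_spectrum` with a positive maximum.
#' @return A peak-normalized relative `uvc_spectrum`.
#' @export
normalize_to_peak <- function(s) {
  validate_spectrum(s)
  m <- max(s$value)
  if (m <= 0) stop("cannot peak-normalize an all-zero spectrum", call. = FALSE)
  spectral_distribution(s$wavelength_nm, s$value / m, "relative")
}

#' Filter transmission curves
#'
#' A filter curve is a tibble with `wavelength_nm` (ascending) and
#' `transmission` (a fraction in `[0, 1]`).
#'
#' @param wavelength_nm Ascending wavelengths, nm.
#' @param transmission Transmission fraction in `[0, 1]`.
#' @return A tibble of class `uvc_filter`.
#' @export
filter_curve <- function(wavelength_nm, transmission) {
  out <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                        transmission = as.numeric(transmission))
  if (nrow(out) < 2) stop("filter curve needs at least 2 points", call. = FALSE)
  if (any(diff(out$wavelength_nm) <= 0)) {
    stop("filter wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(out$transmission < 0 | out$transmission > 1)) {
    stop("transmission must lie in [0, 1]", call. = FALSE)
  }
  structure(out, class = c("uvc_filter", class(tibble::tibble())))
}

#' Apply a transmission filter to a spectrum
#'
#' The filter is linearly interpolated onto the spectrum's wavelength grid and
#' multiplied pointwise. Wavelengths outside the filter's grid take the
#' nearest endpoint transmission (physical filters plateau); a warning is
#' issued when this extrapolation is used.
#'
#' @param s A `uvc_spectrum`.
#' @param f A [filter_curve()].
#' @return The filtered `uvc_spectrum`; `unit_kind` is preserved.
#' @export
apply_filter <- function(s, f) {
  validate_spectrum(s)
  wl <- s$wavelength_nm
  outside <- wl < min(f$wavelength_nm) | wl > max(f$wavelength_nm)
  if (any(outside)) {
    warning("spectrum extends beyond the filter grid; ",
            "using nearest-endpoint transmission for ",
            sum(outside), " wavelength(s)", call. = FALSE)
  }
  tr <- stats::approx(f$wavelength_nm, f$transmission, xout = wl,
                      rule = 2)$y
  spectral_distribution(wl, s$value * tr, unit_kind(s))
}

# Trapezoidal integral of (wl, val) over [lo, hi] with linear interpolation
# at the band edges. Band must lie inside the grid.
band_integral <- function(wl, val, lo, hi) {
  if (lo > hi) stop("band limits must satisfy lo <= hi", call. = FALSE)
  eps <- 1e-9
  if (lo < wl[1] - eps || hi > wl[length(wl)] + eps) {
    stop("integration band [", lo, ", ", hi, "] outside the wavelength grid",
         call. = FALSE)
  }
  if (hi == lo) return(0)
  inner <- wl > lo & wl < hi
  x <- c(lo, wl[inner], hi)
  y <- c(stats::approx(wl, val, xout = lo)$y, val[inner],
         stats::approx(wl, val, xout = hi)$y)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Band-integrated irradiance
#'
#' Trapezoidal integral of the spectrum over `[lo_nm, hi_nm]` on its native
#' grid, with partial-bin linear interpolation at the band edges. For an
#' absolute spectrum in mW cm^-2 nm^-1 the result is an irradiance in
#' mW cm^-2.
#'
#' @param s A `uvc_spectrum`.
#' @param lo_nm,hi_nm Band limits in nm, inside the spectrum's grid.
#' @return Scalar integral in units of `value * nm`.
#' @export
band_irradiance <- function(s, lo_nm, hi_nm) {
  validate_spectrum(s)
  band_integral(s$wavelength_nm, s$value, lo_nm, hi_nm)
}

#' Rescale a spectrum to a target band irradiance
#'
#' Scales the whole spectrum so that its trapezoidal integral over
#' `[lo_nm, hi_nm]` equals `target` (mW cm^-2); the result is marked
#' `"absolute"`. Used to pin a measured lamp spectrum to a radiometer
#' reading, e.g. 6.1 mW cm^-2 over 200-400 nm.
#'
#' @inheritParams band_irradiance
#' @param target Target band irradiance, mW cm^-2.
#' @return An absolute `uvc_spectrum` whose band integral equals `target`.
#' @export
rescale_to_band_irradiance <- function(s, target, lo_nm, hi_nm) {
  cur <- band_irradiance(s, lo_nm, hi_nm)
  if (target == 0) {
    return(spectral_distribution(s$wavelength_nm, 0 * s$value, "absolute"))
  }
  if (cur <= 0) {
    stop("band integral is zero; cannot rescale to a positive target",
         call. = FALSE)
  }
  spectral_distribution(s$wavelength_nm, s$value * target / cur, "absolute")
}

#' @export
print.uvc_spectrum <- function(x, ...) {
  cat(sprintf("<uvc_spectrum: %d points, %.5g-%.5g nm, unit_kind = %s>\n",
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
              unit_kind(x)))
  NextMethod()
}

#' Plot a spectral distribution
#'
#' @param object A `uvc_spectrum`.
#' @param log_y Plot the value axis on a log10 scale (the conventional way to
#'   show low-power long-wavelength lamp emissions).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uvc_spectrum <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$wavelength_nm, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = if (unit_kind(object) == "absolute") {
                    "spectral irradiance (mW cm⁻² nm⁻¹)"
                  } else "relative spectral value")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
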