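# CIE colorimetry tables, 400-700 nm at 10 nm pitch: the D65 relative
# spectral power distribution and the 1964 10-degree / 1931 2-degree
# standard-observer color-matching functions. All pipeline results are
# white-point-relative deltas, so the truncation to the visible
# reflectance-instrument range is immaterial.
.cie_wl <- seq(400, 700, by = 10)
.cie_d65 <- c(82.75, 91.49, 93.43, 86.68, 104.86, 117.01, 117.81, 114.86,
              115.92, 108.81, 109.35, 107.80, 104.79, 107.69, 104.41, 104.05,
              100.00, 96.33, 95.79, 88.69, 90.01, 89.60, 87.70, 83.29, 83.70,
              80.03, 80.21, 82.28, 78.28, 69.72, 71.61)
.cmf10 <- list(
  x = c(0.0191, 0.0847, 0.2045, 0.3147, 0.3837, 0.3707, 0.3023, 0.1956,
        0.0805, 0.0162, 0.0038, 0.0375, 0.1177, 0.2365, 0.3768, 0.5298,
        0.7052, 0.8787, 1.0142, 1.1185, 1.1240, 1.0305, 0.8563, 0.6475,
        0.4316, 0.2683, 0.1526, 0.0813, 0.0409, 0.0199, 0.0096),
  y = c(0.0020, 0.0088, 0.0214, 0.0387, 0.0621, 0.0895, 0.1282, 0.1852,
        0.2536, 0.3391, 0.4608, 0.6067, 0.7618, 0.8752, 0.9620, 0.9918,
        0.9973, 0.9556, 0.8689, 0.7774, 0.6583, 0.5280, 0.3981, 0.2835,
        0.1798, 0.1076, 0.0603, 0.0318, 0.0159, 0.0077, 0.0037),
  z = c(0.0860, 0.3894, 0.9725, 1.5535, 1.9673, 1.9948, 1.7454, 1.3176,
        0.7721, 0.4153, 0.2185, 0.1120, 0.0607, 0.0305, 0.0137, 0.0040,
        0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
)
.cmf2 <- list(
  x = c(0.0143, 0.0435, 0.1344, 0.2839, 0.3483, 0.3362, 0.2908, 0.1954,
        0.0956, 0.0320, 0.0049, 0.0093, 0.0633, 0.1655, 0.2904, 0.4334,
        0.5945, 0.7621, 0.9163, 1.0263, 1.0622, 1.0026, 0.8544, 0.6424,
        0.4479, 0.2835, 0.1649, 0.0874, 0.0468, 0.0227, 0.0114),
  y = c(0.0004, 0.0012, 0.0040, 0.0116, 0.0230, 0.0380, 0.0600, 0.0910,
        0.1390, 0.2080, 0.3230, 0.5030, 0.7100, 0.8620, 0.9540, 0.9950,
        0.9950, 0.9520, 0.8700, 0.7570, 0.6310, 0.5030, 0.3810, 0.2650,
        0.1750, 0.1070, 0.0610, 0.0320, 0.0170, 0.0082, 0.0041),
  z = c(0.0679, 0.2074, 0.6456, 1.3856, 1.7471, 1.7721, 1.6692, 1.2876,
        0.8130, 0.4652, 0.2720, 0.1582, 0.0782, 0.0422, 0.0203, 0.0087,
        0.0039, 0.0021, 0.0017, 0.0011, 0.0008, 0.0003, 0.0002, 0, 0, 0,
        0, 0, 0, 0, 0)
)

#' Illuminant-observer colorimetric weights
#'
#' Tabulated illuminant spectral power times standard-observer
#' color-matching functions on 400-700 nm at 10 nm pitch. The default D65
#' with the 1964 10-degree observer is typical for handheld sphere
#' spectrophotometers; all delta-based results in this package are
#' insensitive to the choice for neutral baselines.
#'
#' @param illuminant `"D65"` or `"E"` (equal energy).
#' @param observer `"10"` (1964 supplementary) or `"2"` (1931).
#' @return A tibble with columns `wavelength_nm`, `S` (illuminant power),
#'   `xbar`, `ybar`, `zbar`.
#' @export
cie_weights <- function(illuminant = c("D65", "E"), observer = c("10", "2")) {
  illuminant <- match.arg(illuminant)
  observer <- match.arg(observer)
  cmf <- if (observer == "10") .cmf10 else .cmf2
  tibble::tibble(
    wavelength_nm = .cie_wl,
    S = if (illuminant == "D65") .cie_d65 else rep(100, length(.cie_wl)),
    xbar = cmf$x, ybar = cmf$y, zbar = cmf$z
  )
}

# Tristimulus integration of one reflectance spectrum against the weights,
# reflectance linearly interpolated onto the weight grid with endpoint
# extension, then the CIELAB transform (cube root with the linear segment
# below (6/29)^3). Specular component treated as included: no gloss
# correction.
lab_one <- function(wavelength_nm, reflectance, weights) {
  r <- stats::approx(wavelength_nm, reflectance,
                     xout = weights$wavelength_nm, rule = 2)$y
  X <- sum(weights$S * weights$xbar * r)
  Y <- sum(weights$S * weights$ybar * r)
  Z <- sum(weights$S * weights$zbar * r)
  Xn <- sum(weights$S * weights$xbar)
  Yn <- sum(weights$S * weights$ybar)
  Zn <- sum(weights$S * weights$zbar)
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(X / Xn); fy <- f(Y / Yn); fz <- f(Z / Zn)
  c(L_star = 116 * fy - 16, a_star = 500 * (fx - fy), b_star = 200 * (fy - fz))
}

#' Convert reflectance spectra to CIELAB
#'
#' Takes a long tibble of reflectance spectra (`wavelength_nm`,
#' `reflectance`, optionally `site` and `time_h` identifying multiple
#' measurements) and returns one `L_star`/`a_star`/`b_star` row per
#' measurement. Reflectance is a fraction; values slightly above 1 (gloss)
#' are allowed, negatives are not.
#'
#' @param measurements A tibble with columns `wavelength_nm`, `reflectance`
#'   and any of the grouping columns `site`, `time_h`.
#' @param weights Colorimetric weights from [cie_weights()].
#' @return A tibble with the grouping columns plus `L_star`, `a_star`,
#'   `b_star`.
#' @export
reflectance_to_lab <- function(measurements, weights = cie_weights()) {
  stopifnot(all(c("wavelength_nm", "reflectance") %in% names(measurements)))
  if (any(measurements$reflectance < 0)) {
    stop("reflectance must be non-negative", call. = FALSE)
  }
  keys <- intersect(c("site", "time_h"), names(measurements))
  measurements |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$wavelength_nm, .by_group = TRUE) |>
    dplyr::group_modify(function(d, ...) {
      tibble::as_tibble_row(lab_one(d$wavelength_nm, d$reflectance, weights))
    }) |>
    dplyr::ungroup()
}

#' Color change relative to the pre-irradiation baseline
#'
#' Converts a time series of reflectance spectra to CIELAB and subtracts the
#' `time_h == 0` baseline per site: `delta_a > 0` is increased redness
#' (erythema proxy), `delta_b > 0` increased yellowness. By construction the
#' baseline row has all deltas exactly 0.
#'
#' @param measurements Long tibble with `site` (optional), `time_h`
#'   (including 0), `wavelength_nm`, `reflectance`.
#' @param weights Colorimetric weights from [cie_weights()].
#' @return A tibble with `site` (if present), `time_h`, `delta_L`,
#'   `delta_a`, `delta_b`, ordered by time within site.
#' @export
delta_series <- function(measurements, weights = cie_weights()) {
  stopifnot("time_h" %in% names(measurements))
  lab <- reflectance_to_lab(measurements, weights)
  keys <- intersect("site", names(lab))
  lab |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::group_modify(function(d, ...) {
      if (d$time_h[1] != 0) {
        stop("missing pre-irradiation baseline (time_h == 0)", call. = FALSE)
      }
      tibble::tibble(time_h = d$time_h,
                     delta_L = d$L_star - d$L_star[1],
                     delta_a = d$a_star - d$a_star[1],
                     delta_b = d$b_star - d$b_star[1])
    }) |>
    dplyr::ungroup()
}

#' Classify erythema and yellowing responses
#'
#' A response is called when the corresponding delta exceeds its threshold
#' for at least `min_consecutive` consecutive post-baseline time points
#' (a sustained change, not a single noisy excursion).
#'
#' @param deltas Output of [delta_series()] (needs >= 2 post-baseline time
#'   points per site).
#' @param delta_a_threshold,delta_b_threshold Thresholds in CIELAB units.
#' @param min_consecutive Number of consecutive exceeding points required.
#' @return A tibble with `site` (if present), `erythema`, `yellowing`
#'   (logical).
#' @export
classify_response <- function(deltas, delta_a_threshold = 1.0,
                              delta_b_threshold = 1.0, min_consecutive = 2) {
  keys <- intersect("site", names(deltas))
  sustained <- function(x, thr) {
    r <- rle(x > thr)
    any(r$values & r$lengths >= min_consecutive)
  }
  deltas |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::group_modify(function(d, ...) {
      post <- d[d$time_h > 0, ]
      if (nrow(post) < 2) {
        stop("need at least 2 post-baseline time points", call. = FALSE)
      }
      tibble::tibble(erythema = sustained(post$delta_a, delta_a_threshold),
                     yellowing = sustained(post$delta_b, delta_b_threshold))
    }) |>
    dplyr::ungroup()
}

#' Plot delta-b*/delta-a* time courses
#'
#' @param deltas Output of [delta_series()].
#' @param which `"delta_b"` (yellowness, default) or `"delta_a"` (redness).
#' @return A ggplot object mirroring the usual delta-b-vs-time presentation.
#' @export
plot_delta_series <- function(deltas, which = c("delta_b", "delta_a")) {
  which <- match.arg(which)
  aes <- if ("site" %in% names(deltas)) {
    ggplot2::aes(.data$time_h, .data[[which]], colour = .data$site)
  } else {
    ggplot2::aes(.data$time_h, .data[[which]])
  }
  ggplot2::ggplot(deltas, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time post-exposure (h)",
                  y = if (which == "delta_b") {
                    expression(Delta * b * "*")
                  } else expression(Delta * a * "*"))
}

#' Read and write reflectance time-series files
#'
#' Delimited text: a `# site:` header comment, then one row per time point
#' with `time_h` followed by one `R_<wavelength>` column per band.
#'
#' @param measurements Long tibble (`site`, `time_h`, `wavelength_nm`,
#'   `reflectance`).
#' @param path File path.
#' @return `read_reflectance_series()` returns the long tibble;
#'   `write_reflectance_series()` returns `path` invisibly.
#' @export
write_reflectance_series <- function(measurements, path) {
  site <- if ("site" %in% names(measurements)) {
    unique(measurements$site)
  } else "unlabelled"
  stopifnot(length(site) == 1)
  wide <- measurements |>
    dplyr::mutate(band = sprintf("R_%g", .data$wavelength_nm)) |>
    dplyr::select(dplyr::all_of(c("time_h", "band", "reflectance"))) |>
    tidyr::pivot_wider(names_from = "band", values_from = "reflectance") |>
    dplyr::arrange(.data$time_h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# site: %s", site), con)
  utils::write.table(wide, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reflectance_series
#' @export
read_reflectance_series <- function(path) {
  first <- readLines(path, n = 1)
  site <- sub("^#\\s*site:\\s*", "", first)
  wide <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE)
  tibble::as_tibble(wide) |>
    tidyr::pivot_longer(-"time_h", names_to = "band",
                        values_to = "reflectance") |>
    dplyr::mutate(site = site,
                  wavelength_nm = as.numeric(sub("^R_", "", .data$band))) |>
    dplyr::select(dplyr::all_of(c("site", "time_h", "wavelength_nm",
                                  "reflectance"))) |>
    dplyr::arrange(.data$time_h, .data$wavelength_nm)
}
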