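#' Layered skin model for UV radiative transfer
#'
#' Plane-parallel layers, surface first. Per-layer optical properties are
#' parametric in wavelength (all coefficients mm^-1):
#'
#' * `mu_a(l) = mua_const + mua_a1 exp(-(l-200)/mua_w1)
#'    + mua_a2 exp(-(l-200)/mua_w2) + mua_mel (l/400)^-3`
#'   (a protein/nucleic-acid-dominated double exponential below ~240 nm plus
#'   a melanin-like power-law term),
#' * `mu_s(l) = mus_const + mus_400 (l/400)^-mus_b` (power-law decay),
#' * anisotropy `g` and refractive index `n` constant per layer.
#'
#' @param layers A tibble with columns `name`, `thickness_um`, `n`, `g` and
#'   the coefficient columns above (missing coefficient columns default to 0).
#' @param markers Named numeric vector of depth markers in um from the
#'   surface; must be strictly increasing and within the total thickness.
#' @param ambient_n Refractive index above the surface.
#' @param wl_range_nm Wavelength validity range of the parametrization.
#' @param name Preset name, for provenance.
#' @return An object of class `skin_model`.
#' @seealso [make_skin_preset()] for the shipped 5-layer preset.
#' @export
skin_model <- function(layers,
                       markers = c(top_of_epidermis = NA_real_),
                       ambient_n = 1.0,
                       wl_range_nm = c(200, 400),
                       name = "custom") {
  coef_cols <- c("mua_const", "mua_a1", "mua_w1", "mua_a2", "mua_w2",
                 "mua_mel", "mus_const", "mus_400", "mus_b")
  layers <- tibble::as_tibble(layers)
  for (cc in coef_cols) if (is.null(layers[[cc]])) layers[[cc]] <- 0
  stopifnot(all(c("name", "thickness_um", "n", "g") %in% names(layers)))
  if (any(layers$thickness_um <= 0)) {
    stop("layer thicknesses must be positive", call. = FALSE)
  }
  if (any(abs(layers$g) >= 1)) {
    stop("anisotropy g must lie in (-1, 1)", call. = FALSE)
  }
  total <- sum(layers$thickness_um)
  markers <- markers[!is.na(markers)]
  if (length(markers)) {
    if (any(diff(markers) <= 0)) {
      stop("depth markers must be strictly increasing", call. = FALSE)
    }
    if (any(markers < 0) || any(markers > total)) {
      stop("depth markers must lie within the model thickness", call. = FALSE)
    }
  }
  structure(list(layers = layers, markers = markers, ambient_n = ambient_n,
                 wl_range_nm = wl_range_nm, name = name),
            class = "skin_model")
}

#' @export
print.skin_model <- function(x, ...) {
  cat(sprintf("<skin_model '%s': %d layers, %g um total, ambient n = %g>\n",
              x$name, nrow(x$layers), sum(x$layers$thickness_um), x$ambient_n))
  print(x$layers[, c("name", "thickness_um", "n", "g")])
  if (length(x$markers)) {
    cat("markers (um):",
        paste(names(x$markers), x$markers, sep = " = ", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Evaluate layer optical properties on a wavelength grid
#'
#' @param model A [skin_model()].
#' @param wavelengths_nm Wavelengths within the model's validity range.
#' @return A tibble with one row per layer x wavelength: `layer`,
#'   `wavelength_nm`, `mu_a`, `mu_s` (mm^-1) and `g`.
#' @export
skin_optical_properties <- function(model, wavelengths_nm) {
  if (any(wavelengths_nm < model$wl_range_nm[1]) ||
      any(wavelengths_nm > model$wl_range_nm[2])) {
    stop("wavelength outside the optical-property range [",
         model$wl_range_nm[1], ", ", model$wl_range_nm[2], "] nm",
         call. = FALSE)
  }
  ly <- model$layers
  purrr::map_dfr(seq_len(nrow(ly)), function(i) {
    l <- ly[i, ]
    wl <- wavelengths_nm
    e1 <- if (l$mua_a1 > 0) l$mua_a1 * exp(-(wl - 200) / l$mua_w1) else 0
    e2 <- if (l$mua_a2 > 0) l$mua_a2 * exp(-(wl - 200) / l$mua_w2) else 0
    mel <- l$mua_mel * (wl / 400)^(-3)
    tibble::tibble(layer = l$name, wavelength_nm = wl,
                   mu_a = l$mua_const + e1 + e2 + mel,
                   mu_s = l$mus_const + l$mus_400 * (wl / 400)^(-l$mus_b),
                   g = l$g)
  })
}

#' Exponential free-path sampling
#'
#' Inverse-CDF sample of the distance to the next interaction in a medium of
#' total attenuation `mu_t`: `-log(u)/mu_t` (mm).
#'
#' @param mu_t Total attenuation coefficient, mm^-1.
#' @param u Uniform deviate in (0, 1).
#' @return Step length in mm (`Inf` when `mu_t = 0`; the caller's boundary
#'   logic handles the non-interacting case).
#' @export
sample_free_path <- function(mu_t, u) {
  stopifnot(all(u > 0), all(u < 1))
  if (any(mu_t < 0)) stop("mu_t must be non-negative", call. = FALSE)
  n <- max(length(mu_t), length(u))
  ifelse(rep_len(mu_t, n) == 0, Inf, -log(rep_len(u, n)) / rep_len(mu_t, n))
}

#' Henyey-Greenstein scattering direction
#'
#' Draws the scattering cosine from the Henyey-Greenstein inverse CDF
#' (isotropic when `g = 0`), the azimuth uniformly, and rotates `direction`
#' accordingly. This is the reference R implementation of the same sampling
#' the compiled transport core uses.
#'
#' @param g Anisotropy, `|g| < 1`.
#' @param u1,u2 Uniform deviates in `[0, 1)` for cos(theta) and phi.
#' @param direction Incoming unit vector, default straight down.
#' @return New unit direction vector (length-3 numeric).
#' @export
sample_scatter <- function(g, u1, u2, direction = c(0, 0, 1)) {
  stopifnot(abs(g) < 1, length(direction) == 3)
  direction <- direction / sqrt(sum(direction^2))
  cost <- if (abs(g) < 1e-8) {
    2 * u1 - 1
  } else {
    tmp <- (1 - g^2) / (1 - g + 2 * g * u1)
    max(-1, min(1, (1 + g^2 - tmp^2) / (2 * g)))
  }
  sint <- sqrt(max(0, 1 - cost^2))
  phi <- 2 * pi * u2
  ux <- direction[1]; uy <- direction[2]; uz <- direction[3]
  if (abs(uz) > 0.99999) {
    out <- c(sint * cos(phi), sint * sin(phi), sign(uz) * cost)
  } else {
    tmp <- sqrt(1 - uz^2)
    out <- c(sint * (ux * uz * cos(phi) - uy * sin(phi)) / tmp + ux * cost,
             sint * (uy * uz * cos(phi) + ux * sin(phi)) / tmp + uy * cost,
             -sint * cos(phi) * tmp + uz * cost)
  }
  out / sqrt(sum(out^2))
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized reflectances at a planar boundary;
#' returns 1 beyond the critical angle (total internal reflection) and 0 for
#' matched indices.
#'
#' @param n1,n2 Refractive indices on the incident and far side.
#' @param cos_incident Cosine of the angle of incidence, in (0, 1].
#' @return Reflection probability in `[0, 1]`.
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  stopifnot(n1 > 0, n2 > 0, cos_incident > 0, cos_incident <= 1)
  if (abs(n1 - n2) < 1e-12) return(0)
  sini <- sqrt(max(0, 1 - cos_incident^2))
  sint <- n1 / n2 * sini
  if (sint >= 1) return(1)
  cost <- sqrt(1 - sint^2)
  rs <- (n1 * cos_incident - n2 * cost) / (n1 * cos_incident + n2 * cost)
  rp <- (n1 * cost - n2 * cos_incident) / (n1 * cost + n2 * cos_incident)
  (rs^2 + rp^2) / 2
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate depth- and wavelength-resolved fluence rates
#'
#' Independent single-wavelength Monte Carlo photon transport (collimated
#' normal incidence, laterally infinite layers, Henyey-Greenstein scattering,
#' implicit capture with Russian roulette) through a [skin_model()]. The
#' source spectrum is resampled by linear interpolation onto a regular
#' wavelength grid and enters only as a per-wavelength weight at tally time;
#' the transport itself is normalized per unit incident irradiance at each
#' wavelength.
#'
#' @param model A [skin_model()].
#' @param source A `uvc_spectrum` giving the relative (or absolute) source
#'   weighting per wavelength.
#' @param photons_per_wavelength Photon packets per wavelength, >= 1000.
#' @param bin_width_um Depth-bin width (half-open bins `[lo, hi)`), um.
#' @param wavelength_pitch_nm Pitch of the simulation wavelength grid, nm.
#' @param seed Integer seed; the same seed and inputs give an identical
#'   profile.
#' @return A `fluence_profile`: see [tidy.fluence_profile()] for the long
#'   table (`depth_lo_um`, `depth_hi_um`, `wavelength_nm`,
#'   `fluence_per_incident`, `se_per_incident`, `source_value`, `fluence`)
#'   and [glance.fluence_profile()] for the run summary. The `tallies`
#'   element carries the reflected/transmitted/absorbed weight fractions per
#'   wavelength, which sum to 1.
#' @export
simulate_fluence <- function(model, source, photons_per_wavelength = 10000,
                             bin_width_um = 5, wavelength_pitch_nm = 2,
                             seed = NULL) {
  stopifnot(inherits(model, "skin_model"))
  validate_spectrum(source, "source spectrum")
  if (photons_per_wavelength < 1000) {
    stop("photons_per_wavelength must be at least 1000", call. = FALSE)
  }
  lo <- max(model$wl_range_nm[1], min(source$wavelength_nm))
  hi <- min(model$wl_range_nm[2], max(source$wavelength_nm))
  if (hi <= lo) {
    stop("source spectrum does not overlap the model's wavelength range",
         call. = FALSE)
  }
  wl <- seq(lo, hi, by = wavelength_pitch_nm)
  src <- stats::approx(source$wavelength_nm, source$value, xout = wl)$y
  props <- skin_optical_properties(model, wl)
  bad <- props$mu_a + props$mu_s <= 0
  if (any(bad)) {
    stop("mu_a + mu_s must be positive in every layer at every wavelength",
         call. = FALSE)
  }
  thick_mm <- model$layers$thickness_um / 1000
  bounds_mm <- c(0, cumsum(thick_mm))
  bin_mm <- bin_width_um / 1000
  n_bins <- ceiling(sum(thick_mm) / bin_mm - 1e-9)
  n_layers <- nrow(model$layers)

  res <- with_seed(seed, {
    purrr::map(seq_along(wl), function(i) {
      p <- props[props$wavelength_nm == wl[i], ]
      stopifnot(nrow(p) == n_layers)
      mcrt_run(p$mu_a, p$mu_s, p$g, model$layers$n, bounds_mm,
               model$ambient_n, as.integer(photons_per_wavelength),
               bin_mm, as.integer(n_bins), 1e-4, 0.1)
    })
  })

  edges <- seq(0, by = bin_width_um, length.out = n_bins + 1)
  data <- purrr::map_dfr(seq_along(wl), function(i) {
    tibble::tibble(
      depth_lo_um = edges[-length(edges)],
      depth_hi_um = edges[-1],
      wavelength_nm = wl[i],
      fluence_per_incident = as.numeric(res[[i]]$fluence),
      se_per_incident = as.numeric(res[[i]]$se),
      source_value = src[i],
      fluence = as.numeric(res[[i]]$fluence) * src[i],
      fluence_se = as.numeric(res[[i]]$se) * src[i]
    )
  })
  tallies <- tibble::tibble(
    wavelength_nm = wl,
    reflected = purrr::map_dbl(res, "reflected"),
    transmitted = purrr::map_dbl(res, "transmitted"),
    absorbed = purrr::map_dbl(res, "absorbed")
  )
  structure(list(data = data, tallies = tallies, bin_edges_um = edges,
                 wavelengths_nm = wl, markers = model$markers,
                 n_photons = photons_per_wavelength, seed = seed,
                 model_name = model$name),
            class = "fluence_profile")
}

#' @export
print.fluence_profile <- function(x, ...) {
  cat(sprintf(paste0("<fluence_profile: %d depth bins x %d wavelengths ",
                     "(%g-%g nm), %d photons/wavelength, seed = %s>\n"),
              length(x$bin_edges_um) - 1, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm), x$n_photons,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' @rdname simulate_fluence
#' @param x,object A `fluence_profile`.
#' @param ... Unused.
#' @export
tidy.fluence_profile <- function(x, ...) x$data

#' @rdname simulate_fluence
#' @export
glance.fluence_profile <- function(x, ...) {
  closure <- with(x$tallies, abs(reflected + transmitted + absorbed - 1))
  tibble::tibble(
    n_wavelengths = length(x$wavelengths_nm),
    n_depth_bins = length(x$bin_edges_um) - 1,
    photons_per_wavelength = x$n_photons,
    max_ledger_error = max(closure),
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

# Resolve a depth marker (name or um) against a profile.
resolve_marker <- function(p, depth_marker) {
  if (is.character(depth_marker)) {
    if (!depth_marker %in% names(p$markers)) {
      stop("unknown depth marker '", depth_marker, "'", call. = FALSE)
    }
    depth_marker <- p$markers[[depth_marker]]
  }
  depth_marker
}

#' Band-integrated fluence at a depth marker
#'
#' Integrates the source-weighted spectral fluence rate over a wavelength
#' band at the depth bin containing the marker. The result carries the
#' propagated Monte Carlo standard error as attribute `"se"`.
#'
#' @param p A `fluence_profile`.
#' @param depth_marker A marker name (e.g. `"basal_layer"`) or a depth in um.
#' @param band Length-2 wavelength band in nm.
#' @return Scalar band-integrated fluence (source units x nm).
#' @export
fluence_at_depth <- function(p, depth_marker, band) {
  depth <- resolve_marker(p, depth_marker)
  edges <- p$bin_edges_um
  if (depth < edges[1] || depth > edges[length(edges)]) {
    stop("depth marker outside the profile's depth span", call. = FALSE)
  }
  # half-open [lo, hi) bins; the model's bottom edge falls in the last bin
  bin <- min(findInterval(depth, edges), length(edges) - 1)
  d <- p$data[p$data$depth_lo_um == edges[bin], ]
  val <- band_integral(d$wavelength_nm, d$fluence, band[1], band[2])
  if (band[1] == band[2]) return(structure(0, se = 0))
  wl <- d$wavelength_nm
  inner <- wl > band[1] & wl < band[2]
  x <- c(band[1], wl[inner], band[2])
  wts <- diff(x, lag = 1)
  trap_w <- c(wts / 2, 0) + c(0, wts / 2) # trapezoid weight per node
  se_nodes <- stats::approx(wl, d$fluence_se, xout = x)$y
  se <- sqrt(sum((trap_w * se_nodes)^2))
  structure(val, se = se)
}

#' Fold difference between two fluence profiles at a depth marker
#'
#' Ratio of band-integrated fluences (first over second) at the same depth
#' marker, with a propagated Monte Carlo uncertainty. The two profiles must
#' share depth and wavelength grids. Used for filtered-vs-unfiltered source
#' comparisons at the basal layer.
#'
#' @param p_unfiltered,p_filtered `fluence_profile` objects on matching
#'   grids (numerator, denominator).
#' @inheritParams fluence_at_depth
#' @return A one-row tibble: `depth_um`, `band_lo_nm`, `band_hi_nm`, `ratio`,
#'   `se`.
#' @export
fluence_ratio <- function(p_unfiltered, p_filtered, depth_marker, band) {
  if (!isTRUE(all.equal(p_unfiltered$bin_edges_um, p_filtered$bin_edges_um)) ||
      !isTRUE(all.equal(p_unfiltered$wavelengths_nm,
                        p_filtered$wavelengths_nm))) {
    stop("fluence profiles are on different depth or wavelength grids",
         call. = FALSE)
  }
  num <- fluence_at_depth(p_unfiltered, depth_marker, band)
  den <- fluence_at_depth(p_filtered, depth_marker, band)
  if (den == 0) {
    warning("zero denominator fluence: ratio is infinite", call. = FALSE)
    ratio <- Inf
    se <- NA_real_
  } else {
    ratio <- as.numeric(num) / as.numeric(den)
    se <- abs(ratio) * sqrt((attr(num, "se") / as.numeric(num))^2 +
                            (attr(den, "se") / as.numeric(den))^2)
  }
  tibble::tibble(depth_um = resolve_marker(p_unfiltered, depth_marker),
                 band_lo_nm = band[1], band_hi_nm = band[2],
                 ratio = ratio, se = se)
}

#' Plot spectral fluence rate at selected depths
#'
#' One curve per depth marker: relative spectral fluence rate against
#' wavelength, log scale, the conventional presentation for penetration-depth
#' results.
#'
#' @param object A `fluence_profile`.
#' @param depths Depth markers (names or um); defaults to the profile's
#'   markers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluence_profile <- function(object, depths = NULL, ...) {
  if (is.null(depths)) depths <- object$markers
  if (is.null(names(depths))) {
    names(depths) <- paste0(depths, " um")
  }
  edges <- object$bin_edges_um
  df <- purrr::map_dfr(names(depths), function(nm) {
    depth <- resolve_marker(object, unname(depths[[nm]]))
    bin <- min(findInterval(depth, edges), length(edges) - 1)
    d <- object$data[object$data$depth_lo_um == edges[bin], ]
    dplyr::mutate(d, depth_label = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$fluence,
                                   colour = .data$depth_label)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = "relative spectral fluence rate",
                  colour = "depth")
}
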