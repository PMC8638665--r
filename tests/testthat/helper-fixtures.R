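# Shared fixtures, built in code at test time.

# A homogeneous absorption-only slab with matched boundaries: the
# Beer-Lambert oracle geometry (no scattering, no Fresnel).
absorbing_slab <- function(mu_a = 1, thickness_um = 3000, n = 1.38) {
  skin_model(
    tibble::tibble(name = "slab", thickness_um = thickness_um, n = n,
                   g = 0, mua_const = mu_a),
    markers = c(mid = thickness_um / 2),
    ambient_n = n
  )
}

# A homogeneous absorbing-scattering slab (air above).
turbid_slab <- function(mu_a = 2, mu_s = 20, g = 0.9, thickness_um = 2000) {
  skin_model(
    tibble::tibble(name = "slab", thickness_um = thickness_um, n = 1.38,
                   g = g, mua_const = mu_a, mus_const = mu_s),
    markers = c(mid = thickness_um / 2),
    ambient_n = 1.0
  )
}

# Flat two-point source spanning the given wavelengths.
flat_source <- function(lo = 220, hi = 224) {
  spectral_distribution(c(lo, hi), c(1, 1))
}

# Expected bin-averaged Beer-Lambert fluence for unit incident irradiance.
beer_lambert_bins <- function(edges_um, mu_a_mm) {
  lo <- edges_um[-length(edges_um)] / 1000
  hi <- edges_um[-1] / 1000
  (exp(-mu_a_mm * lo) - exp(-mu_a_mm * hi)) / (mu_a_mm * (hi - lo))
}

write_temp_spectrum <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
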