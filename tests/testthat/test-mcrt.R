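test_that("free-path sampling inverts the exponential CDF", {
  expect_equal(sample_free_path(2, exp(-1)), 0.5)
  expect_identical(sample_free_path(0, 0.5), Inf)
  expect_lt(sample_free_path(1, 1 - 1e-12), 1e-9) # u -> 1 gives step -> 0
  set.seed(1)
  draws <- sample_free_path(2, runif(1e5))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("Henyey-Greenstein sampling has mean cosine g", {
  # g = 0 reduces to a uniform cosine
  u <- seq(0.01, 0.99, 0.01)
  expect_equal(vapply(u, mcrt_hg_cos, numeric(1), g = 0), 2 * u - 1)
  set.seed(2)
  for (g in c(0.5, 0.8, 0.9)) {
    cost <- vapply(runif(1e5), mcrt_hg_cos, numeric(1), g = g)
    se <- sd(cost) / sqrt(length(cost))
    expect_lt(abs(mean(cost) - g), 3 * se)
  }
})

test_that("R and compiled scattering/Fresnel primitives agree", {
  set.seed(3)
  for (i in 1:20) {
    g <- runif(1, -0.9, 0.95)
    u <- runif(1)
    dir <- sample_scatter(g, u, runif(1),
                          direction = stats::rnorm(3))
    expect_equal(sqrt(sum(dir^2)), 1, tolerance = 1e-9)
    # the polar cosine sampled in R matches the compiled inverse CDF
    r_cos <- if (abs(g) < 1e-8) 2 * u - 1 else mcrt_hg_cos(g, u)
    expect_equal(mcrt_hg_cos(g, u), r_cos)
    n1 <- runif(1, 1, 2); n2 <- runif(1, 1, 2); ci <- runif(1, 0.05, 1)
    expect_equal(fresnel_reflectance(n1, n2, ci), mcrt_fresnel(n1, n2, ci),
                 tolerance = 1e-12)
  }
})

test_that("Fresnel reflectance has the textbook limits", {
  expect_equal(fresnel_reflectance(1.0, 1.5, 1), ((1 - 1.5) / (1 + 1.5))^2)
  expect_equal(fresnel_reflectance(1.38, 1.38, 0.7), 0)
  # beyond the critical angle: total internal reflection
  expect_equal(fresnel_reflectance(1.38, 1.0, 0.1), 1)
  expect_true(fresnel_reflectance(1.38, 1.0, 0.999) < 1)
})

test_that("absorption-only transport reproduces Beer-Lambert decay", {
  m <- absorbing_slab(mu_a = 1)
  p <- simulate_fluence(m, flat_source(), photons_per_wavelength = 2e4,
                        bin_width_um = 100, seed = 21)
  d <- tidy(p)
  d1 <- d[d$wavelength_nm == 220, ]
  expected <- beer_lambert_bins(p$bin_edges_um, 1)
  dev <- abs(d1$fluence_per_incident - expected) /
    pmax(d1$se_per_incident, 1e-12)
  expect_lt(max(dev), 4)
  # surface bin is the maximum (monotone decay)
  expect_equal(which.max(d1$fluence_per_incident), 1L)
  # fluence-weighted mean depth matches the slab-truncated exponential mean
  zmid <- (d1$depth_lo_um + d1$depth_hi_um) / 2000
  mean_depth <- sum(zmid * d1$fluence_per_incident) /
    sum(d1$fluence_per_incident)
  z_max <- max(p$bin_edges_um) / 1000
  truncated_mean <- (1 - (1 + z_max) * exp(-z_max)) / (1 - exp(-z_max))
  expect_equal(mean_depth, truncated_mean, tolerance = 0.02)
})

test_that("the weight ledger closes at every wavelength", {
  m <- turbid_slab()
  p <- simulate_fluence(m, flat_source(220, 400),
                        photons_per_wavelength = 2000,
                        bin_width_um = 50, wavelength_pitch_nm = 60,
                        seed = 5)
  closure <- with(p$tallies, reflected + transmitted + absorbed)
  expect_true(all(abs(closure - 1) < 1e-6))
  expect_true(all(tidy(p)$fluence_per_incident >= 0))
})

test_that("the same seed reproduces a profile bit for bit", {
  m <- turbid_slab()
  p1 <- simulate_fluence(m, flat_source(), photons_per_wavelength = 1000,
                         bin_width_um = 100, seed = 9)
  p2 <- simulate_fluence(m, flat_source(), photons_per_wavelength = 1000,
                         bin_width_um = 100, seed = 9)
  expect_identical(tidy(p1), tidy(p2))
  expect_identical(p1$tallies, p2$tallies)
})

test_that("different seeds agree within the quoted MC uncertainty", {
  m <- turbid_slab()
  f1 <- fluence_at_depth(simulate_fluence(m, flat_source(),
                                          photons_per_wavelength = 5000,
                                          bin_width_um = 100, seed = 101),
                         "mid", c(220, 224))
  f2 <- fluence_at_depth(simulate_fluence(m, flat_source(),
                                          photons_per_wavelength = 5000,
                                          bin_width_um = 100, seed = 202),
                         "mid", c(220, 224))
  se <- sqrt(attr(f1, "se")^2 + attr(f2, "se")^2)
  expect_lt(abs(as.numeric(f1) - as.numeric(f2)), 4 * se)
})

test_that("halving the depth-bin width leaves band fluence within MC error", {
  # estimates over the same depth support must agree across bin refinements
  # (independent photon streams)
  m <- turbid_slab(mu_a = 1, mu_s = 10)
  coarse <- simulate_fluence(m, flat_source(), photons_per_wavelength = 5000,
                             bin_width_um = 100, seed = 31)
  fine <- simulate_fluence(m, flat_source(), photons_per_wavelength = 5000,
                           bin_width_um = 50, seed = 32)
  fc <- fluence_at_depth(coarse, 550, c(220, 224))
  f_lo <- fluence_at_depth(fine, 525, c(220, 224)) # bin [500, 550)
  f_hi <- fluence_at_depth(fine, 575, c(220, 224)) # bin [550, 600)
  combined <- (as.numeric(f_lo) + as.numeric(f_hi)) / 2
  se <- sqrt(attr(fc, "se")^2 +
               (attr(f_lo, "se")^2 + attr(f_hi, "se")^2) / 4)
  expect_lt(abs(as.numeric(fc) - combined), 3 * se)
})

test_that("fluence decays monotonically with depth in a homogeneous slab", {
  m <- turbid_slab(mu_a = 3, mu_s = 15)
  p <- simulate_fluence(m, flat_source(), photons_per_wavelength = 2e4,
                        bin_width_um = 100, seed = 13)
  d <- tidy(p)
  d1 <- d[d$wavelength_nm == 220 & d$depth_lo_um >= 100 &
            d$depth_lo_um < 1500, ]
  slack <- 3 * sqrt(d1$se_per_incident[-1]^2 +
                      d1$se_per_incident[-nrow(d1)]^2)
  expect_true(all(diff(d1$fluence_per_incident) <= slack))
})

test_that("fluence_at_depth integrates bands and validates markers", {
  m <- absorbing_slab(mu_a = 1)
  p <- simulate_fluence(m, flat_source(), photons_per_wavelength = 1000,
                        bin_width_um = 100, seed = 2)
  expect_equal(as.numeric(fluence_at_depth(p, "mid", c(222, 222))), 0)
  expect_error(fluence_at_depth(p, 99999, c(220, 224)), "outside")
  expect_error(fluence_at_depth(p, "no_such_marker", c(220, 224)), "unknown")
})

test_that("short UVC penetrates far less than UVB to the basal layer", {
  m <- make_skin_preset()
  # equal incident power at 222 and 302 nm: compare per-incident fluence
  src <- spectral_distribution(c(222, 302), c(1, 1))
  p <- simulate_fluence(m, src, photons_per_wavelength = 5000,
                        bin_width_um = 10, wavelength_pitch_nm = 80,
                        seed = 17)
  d <- tidy(p)
  basal <- d[d$depth_lo_um == 100, ]
  f222 <- basal$fluence_per_incident[basal$wavelength_nm == 222]
  f302 <- basal$fluence_per_incident[basal$wavelength_nm == 302]
  expect_lt(f222 * 100, f302)
})

test_that("fluence_ratio is 1 for identical runs and scale-invariant", {
  m <- turbid_slab()
  s <- flat_source()
  p1 <- simulate_fluence(m, s, photons_per_wavelength = 2000,
                         bin_width_um = 100, seed = 41)
  p2 <- simulate_fluence(m, s, photons_per_wavelength = 2000,
                         bin_width_um = 100, seed = 41)
  r <- fluence_ratio(p1, p2, "mid", c(220, 224))
  expect_equal(r$ratio, 1)
  # common rescaling of both sources cancels
  s10 <- spectral_distribution(s$wavelength_nm, 10 * s$value)
  p3 <- simulate_fluence(m, s10, photons_per_wavelength = 2000,
                         bin_width_um = 100, seed = 41)
  p4 <- simulate_fluence(m, s10, photons_per_wavelength = 2000,
                         bin_width_um = 100, seed = 41)
  expect_equal(fluence_ratio(p3, p4, "mid", c(220, 224))$ratio, r$ratio)
  pfine <- simulate_fluence(m, s, photons_per_wavelength = 2000,
                            bin_width_um = 50, seed = 41)
  expect_error(fluence_ratio(p1, pfine, "mid", c(220, 224)), "grids")
})

test_that("simulate_fluence validates its inputs", {
  m <- make_skin_preset()
  expect_error(simulate_fluence(m, flat_source(), 10), "at least 1000")
  off_grid <- spectral_distribution(c(500, 600), c(1, 1))
  expect_error(simulate_fluence(m, off_grid, 1000), "overlap")
  expect_error(skin_optical_properties(m, 150), "outside")
})
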