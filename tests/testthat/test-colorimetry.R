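grid_vis <- seq(400, 700, 10)

test_that("the perfect diffuser maps to the white point exactly", {
  for (obs in c("10", "2")) {
    w <- cie_weights(observer = obs)
    lab <- reflectance_to_lab(
      tibble::tibble(wavelength_nm = grid_vis, reflectance = 1), w)
    expect_equal(lab$L_star, 100, tolerance = 1e-9)
    expect_equal(lab$a_star, 0, tolerance = 1e-9)
    expect_equal(lab$b_star, 0, tolerance = 1e-9)
  }
})

test_that("neutral spectra stay neutral and order by lightness", {
  for (illum in c("D65", "E")) {
    w <- cie_weights(illuminant = illum)
    labs <- reflectance_to_lab(
      tidyr::crossing(site = c("a", "b", "c"), wavelength_nm = grid_vis) |>
        dplyr::mutate(reflectance = c(a = 0.05, b = 0.18, c = 0.9)[site]),
      w)
    expect_equal(labs$a_star, rep(0, 3), tolerance = 1e-9)
    expect_equal(labs$b_star, rep(0, 3), tolerance = 1e-9)
    # L* monotone in a uniform scaling of reflectance
    expect_true(all(diff(labs$L_star[order(labs$site)]) > 0))
    expect_true(all(labs$L_star > 0 & labs$L_star < 100))
  }
})

test_that("the Lab transform matches the grDevices oracle", {
  # independent route: relative XYZ rescaled to convertColor's D65 white
  w <- cie_weights()
  set.seed(8)
  for (i in 1:5) {
    refl <- runif(length(grid_vis), 0.05, 1)
    lab <- reflectance_to_lab(
      tibble::tibble(wavelength_nm = grid_vis, reflectance = refl), w)
    X <- sum(w$S * w$xbar * refl) / sum(w$S * w$ybar)
    Y <- sum(w$S * w$ybar * refl) / sum(w$S * w$ybar)
    Z <- sum(w$S * w$zbar * refl) / sum(w$S * w$ybar)
    Xn <- sum(w$S * w$xbar) / sum(w$S * w$ybar)
    Zn <- sum(w$S * w$zbar) / sum(w$S * w$ybar)
    # rescale to the D65 white grDevices uses (chromaticity 0.3137, 0.3291)
    Xn_cc <- 0.3137 / 0.3291
    Zn_cc <- (1 - 0.3137 - 0.3291) / 0.3291
    xyz_cc <- cbind(X / Xn * Xn_cc, Y, Z / Zn * Zn_cc)
    oracle <- grDevices::convertColor(xyz_cc, from = "XYZ", to = "Lab")
    expect_equal(unlist(lab[c("L_star", "a_star", "b_star")]),
                 c(oracle), tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("reducing blue-band reflectance raises b*", {
  base <- tibble::tibble(wavelength_nm = grid_vis,
                         reflectance = baseline_reflectance(grid_vis))
  yellowed <- dplyr::mutate(base, reflectance = ifelse(wavelength_nm <= 500,
                                                       reflectance * 0.8,
                                                       reflectance))
  b0 <- reflectance_to_lab(base)$b_star
  b1 <- reflectance_to_lab(yellowed)$b_star
  expect_gt(b1, b0)
})

test_that("delta_series is zero at baseline and needs a baseline", {
  s <- make_reflectance_series(12000, times_h = c(0, 1, 5), seed = 4)
  d <- delta_series(s)
  expect_identical(d$delta_a[d$time_h == 0], 0)
  expect_identical(d$delta_b[d$time_h == 0], 0)
  expect_identical(d$delta_L[d$time_h == 0], 0)
  no_base <- s[s$time_h > 0, ]
  expect_error(delta_series(no_base), "baseline")
  # identical spectra at every time point: deltas exactly zero
  flat <- tidyr::crossing(time_h = c(0, 1, 2), wavelength_nm = grid_vis) |>
    dplyr::mutate(reflectance = baseline_reflectance(wavelength_nm))
  expect_true(all(abs(as.matrix(
    delta_series(flat)[, c("delta_L", "delta_a", "delta_b")])) < 1e-12))
})

test_that("measurement noise propagates to a bounded delta-b", {
  k <- yellowing_kinetics() # default noise_sd
  # numeric gradient of b* wrt per-band reflectance at baseline
  wl <- grid_vis
  r0 <- baseline_reflectance(wl)
  b_of <- function(r) {
    reflectance_to_lab(tibble::tibble(wavelength_nm = wl,
                                      reflectance = r))$b_star
  }
  grad <- vapply(seq_along(wl), function(i) {
    h <- 1e-5
    rp <- r0; rp[i] <- rp[i] + h
    (b_of(rp) - b_of(r0)) / h
  }, numeric(1))
  # baseline and follow-up are both noisy
  sd_db <- sqrt(2 * sum(grad^2)) * k$noise_sd
  d <- delta_series(make_reflectance_series(0, times_h = 0:8, k = k,
                                            seed = 99))
  expect_lt(max(abs(d$delta_b[d$time_h > 0])), 4 * sd_db)
})

test_that("response classification follows sustained threshold crossings", {
  quiet <- tibble::tibble(time_h = 0:4, delta_L = 0, delta_a = 0, delta_b = 0)
  cls <- classify_response(quiet)
  expect_false(cls$erythema)
  expect_false(cls$yellowing)
  yellow <- dplyr::mutate(quiet, delta_b = c(0, 2.5, 2, 1.5, 0.5))
  cls <- classify_response(yellow)
  expect_false(cls$erythema)
  expect_true(cls$yellowing)
  red <- dplyr::mutate(quiet, delta_a = c(0, 1.8, 1.4, 0.9, 0.2))
  cls <- classify_response(red)
  expect_true(cls$erythema)
  expect_false(cls$yellowing)
  # one isolated spike is not a sustained response
  spike <- dplyr::mutate(quiet, delta_b = c(0, 3, 0, 0, 0))
  expect_false(classify_response(spike)$yellowing)
  expect_true(classify_response(spike, min_consecutive = 1)$yellowing)
  expect_error(classify_response(quiet[1:2, ]), "at least 2")
})

test_that("reflectance series files round-trip", {
  s <- make_reflectance_series(6000, times_h = c(0, 1, 24), seed = 7)
  p <- tempfile(fileext = ".tsv")
  write_reflectance_series(s, p)
  s2 <- read_reflectance_series(p)
  expect_equal(s2$reflectance, s$reflectance, tolerance = 1e-9)
  expect_equal(s2$wavelength_nm, s$wavelength_nm)
  expect_identical(unique(s2$site), "dose_6000")
})

test_that("plot builders return ggplot objects", {
  d <- delta_series(make_reflectance_series(12000, times_h = c(0, 1, 5),
                                            seed = 2))
  expect_s3_class(plot_delta_series(d), "ggplot")
  expect_s3_class(autoplot(make_lamp_spectrum(), log_y = TRUE), "ggplot")
  m <- absorbing_slab()
  p <- simulate_fluence(m, flat_source(), photons_per_wavelength = 1000,
                        bin_width_um = 200, seed = 1)
  expect_s3_class(autoplot(p), "ggplot")
})
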