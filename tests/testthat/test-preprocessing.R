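make_clean_map <- function(n = 6, axis = seq(500, 3500, by = 4)) {
  base <- eval_bands(axis, list(band_spec(1452, 25, 1),
                                band_spec(2850, 45, 2),
                                band_spec(2930, 45, 1.5)))
  spectral_map(axis, matrix(rep(base, n), ncol = n))
}

test_that("nearest-neighbour despiking restores spikes and nothing else", {
  map <- make_clean_map()
  clean <- map$intensities
  spiked <- clean
  spike_ch <- 120
  spiked[spike_ch, 3] <- spiked[spike_ch, 3] * 30
  out <- remove_cosmic_rays(spectral_map(map$wavenumber, spiked))
  expect_equal(out$intensities[spike_ch, 3], clean[spike_ch, 3],
               tolerance = 0.05)
  # untouched channels are bit-identical
  expect_identical(out$intensities[-spike_ch, ], spiked[-spike_ch, ])
  expect_identical(out$intensities[spike_ch, -3], spiked[spike_ch, -3])
  # spike-free map is a no-op
  expect_identical(remove_cosmic_rays(map)$intensities, clean)
})

test_that("spikes in different spectra are removed independently", {
  map <- make_clean_map()
  spiked <- map$intensities
  spiked[100, 1] <- spiked[100, 1] + 50
  spiked[300, 4] <- spiked[300, 4] + 80
  out <- remove_cosmic_rays(spectral_map(map$wavenumber, spiked))
  flagged <- attr(out, "flagged")
  expect_setequal(paste(flagged$spectrum, flagged$channel),
                  c("1 100", "4 300"))
  expect_equal(out$intensities[100, 1], map$intensities[100, 1],
               tolerance = 0.05)
  expect_equal(out$intensities[300, 4], map$intensities[300, 4],
               tolerance = 0.05)
})

test_that("single-spectrum maps are routed to the within-spectrum fallback", {
  map <- make_clean_map(n = 1)
  expect_error(remove_cosmic_rays(map), "despike_spectrum")
  sp <- map_spectrum(map, 1)
  spiked <- sp
  spiked$intensity[200] <- spiked$intensity[200] + 40
  fixed <- despike_spectrum(spiked)
  expect_equal(fixed$intensity[200], sp$intensity[200], tolerance = 0.1)
  expect_identical(fixed$intensity[-200], spiked$intensity[-200])
})

test_that("modified-polynomial baseline annihilates representable baselines", {
  axis <- seq(500, 3500, by = 4)
  u <- (axis - 2000) / 1500
  poly9 <- 5 + 3 * u - 2 * u^3 + u^5 + 0.5 * u^9
  sp <- raman_spectrum(axis, poly9)
  res <- subtract_baseline(sp, baseline_config("modified_poly"))
  expect_lt(max(abs(res$corrected$intensity)), 1e-6 * max(abs(poly9)))
  # all-zero spectrum stays all-zero
  z <- subtract_baseline(raman_spectrum(axis, rep(0, length(axis))),
                         baseline_config("modified_poly"))
  expect_equal(z$corrected$intensity, rep(0, length(axis)))
  expect_equal(z$baseline$intensity, rep(0, length(axis)))
})

test_that("baseline subtraction recovers band height on synthetic data", {
  axis <- seq(500, 3500, by = 2)
  u <- (axis - 2000) / 1500
  baseline <- 4 + 2 * u - u^2
  band <- eval_bands(axis, list(band_spec(2930, 45, 3)))
  sp <- raman_spectrum(axis, baseline + band)
  for (method in c("modified_poly", "spline")) {
    res <- subtract_baseline(sp, baseline_config(method))
    h <- peak_intensity(res$corrected, 2930)
    expect_equal(h, 3, tolerance = 0.05)
  }
})

test_that("too-short spectra are rejected for baseline fitting", {
  sp <- raman_spectrum(1:8, rnorm(8))
  expect_error(subtract_baseline(sp, baseline_config("modified_poly")),
               "too short")
})

test_that("SNV yields zero mean, unit sd, and affine invariance", {
  set.seed(4)
  sp <- raman_spectrum(1:100, rnorm(100, 5, 2))
  out <- snv_normalize(sp)
  expect_equal(mean(out$intensity), 0, tolerance = 1e-12)
  expect_equal(sd(out$intensity), 1, tolerance = 1e-12)
  shifted <- raman_spectrum(1:100, 3.7 * sp$intensity + 11)
  expect_equal(snv_normalize(shifted)$intensity, out$intensity,
               tolerance = 1e-10)
  expect_error(snv_normalize(raman_spectrum(1:10, rep(2, 10))),
               "constant spectrum")
})

test_that("area normalization gives unit integral and is idempotent", {
  # constant intensity 2 over a span of 1 cm^-1 -> constant 1
  sp <- raman_spectrum(c(100, 100.5, 101), rep(2, 3))
  out <- area_normalize(sp)
  expect_equal(out$intensity, rep(1, 3))
  cfg <- tiny_cohort_config(seed = 31)
  co <- simulate_cohorts(cfg)
  s <- map_spectrum(co, 5)
  a1 <- area_normalize(s)
  expect_equal(pracma::trapz(a1$wavenumber, a1$intensity), 1,
               tolerance = 1e-10)
  expect_equal(area_normalize(a1)$intensity, a1$intensity,
               tolerance = 1e-12)
  expect_error(area_normalize(raman_spectrum(1:10, rep(0, 10))),
               "area")
})

test_that("unit-grid resampling is exact on linear data and idempotent", {
  sp <- raman_spectrum(seq(1000, 1100, by = 1), seq(0, 100, by = 1))
  expect_identical(resample_unit_grid(sp)$wavenumber, sp$wavenumber)
  expect_equal(resample_unit_grid(sp)$intensity, sp$intensity)
  ramp <- raman_spectrum(c(500.4, 1000.3, 2000.7, 3499.6),
                         2 * c(500.4, 1000.3, 2000.7, 3499.6) + 1)
  out <- resample_unit_grid(ramp)
  expect_equal(out$wavenumber, 501:3499)
  expect_equal(out$intensity, 2 * (501:3499) + 1, tolerance = 1e-9)
  expect_error(resample_unit_grid(raman_spectrum(c(1, 1.5), c(0, 1))),
               "span")
})

test_that("region cropping keeps exactly the requested window", {
  axis <- seq(500, 3500, by = 2)
  sp <- raman_spectrum(axis, seq_along(axis))
  hw <- crop_region(sp, 2800, 3200)
  expect_true(all(hw$wavenumber >= 2800 & hw$wavenumber <= 3200))
  full <- crop_region(sp, 500, 3500)
  expect_identical(full$intensity, sp$intensity)
  expect_error(crop_region(sp, 4000, 5000), "fewer than 2")
  expect_error(crop_region(sp, 3000, 2000), "lo must be < hi")
})
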