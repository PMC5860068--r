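# dense synthetic window with one or more 2D Gaussian peaks on a grid
gaussian_window <- function(centers_dt, centers_mz, amps,
                            sigma_dt = 0.3, sigma_mz = 0.004,
                            dt_axis = seq(0.05, 50, by = 0.1),
                            mz_axis = seq(204.95, 205.25, by = 0.005),
                            noise = 0) {
  m <- matrix(0, length(dt_axis), length(mz_axis))
  for (k in seq_along(centers_dt)) {
    m <- m + amps[k] *
      outer(exp(-0.5 * ((dt_axis - centers_dt[k]) / sigma_dt)^2),
            exp(-0.5 * ((mz_axis - centers_mz[k]) / sigma_mz)^2))
  }
  if (noise > 0) m <- m + matrix(abs(rnorm(length(m), sd = noise)),
                                 nrow(m))
  intensity_map(mz_axis, dt_axis, m)
}

test_that("extract_window selects exactly the ppm band", {
  map <- gaussian_window(25, 205.0977, 100)
  w <- extract_window(map, 205.0977, 250)
  lo <- 205.0977 * (1 - 250e-6); hi <- 205.0977 * (1 + 250e-6)
  expect_equal(c(lo, hi), c(205.0464, 205.1490), tolerance = 1e-3)
  expect_true(all(w$mz_axis >= lo & w$mz_axis <= hi))
  expect_equal(length(w$dt_axis), length(map$dt_axis))
  # vanishing window degenerates to the single containing bin
  w0 <- extract_window(map, 205.10, 1e-4)
  expect_length(w0$mz_axis, 1L)
  expect_error(extract_window(map, 350.0, 250), "empty m/z window")
})

test_that("a single Gaussian peak is found at the true apex", {
  truth_dt <- 25.03; truth_mz <- 205.0977
  w <- gaussian_window(truth_dt, truth_mz, 100)
  peaks <- detect_peaks(w, field_index = 2L)
  expect_length(peaks, 1L)
  p <- peaks[[1]]
  expect_equal(p$field_index, 2L)
  expect_lt(abs(p$dtc - truth_dt), 0.1)     # within one dt bin
  expect_lt(abs(p$mzc - truth_mz), 0.005)   # within one m/z bin
  # FWHM of the smoothed peak: true width convolved with the kernel
  sigma_eff <- sqrt(0.3^2 + 0.1^2)
  expect_equal(p$dtw, 2.3548 * sigma_eff, tolerance = 0.1)
  expect_gte(p$summed_intensity, p$base_intensity)
  expect_true(p$mzl > 0.3 && p$mzl < 0.7)
  expect_true(p$dtl > 0.3 && p$dtl < 0.7)
})

test_that("an all-zero window yields no peaks", {
  z <- intensity_map(c(1, 2, 3), c(1, 2, 3), matrix(0, 3, 3))
  expect_equal(detect_peaks(z), list())
})

test_that("well-separated peaks are both found, ordered by intensity", {
  w <- gaussian_window(c(20.03, 35.06), c(205.052, 205.151), c(50, 120))
  peaks <- detect_peaks(w)
  expect_length(peaks, 2L)
  expect_gt(peaks[[1]]$summed_intensity, peaks[[2]]$summed_intensity)
  expect_lt(abs(peaks[[1]]$dtc - 35.06), 0.1)
  expect_lt(abs(peaks[[2]]$dtc - 20.03), 0.1)
})

test_that("detection is translation-equivariant in arrival time", {
  for (shift_bins in c(0, 7, 31)) {
    w <- gaussian_window(20.05 + shift_bins * 0.1, 205.0977, 80)
    p <- detect_peaks(w)[[1]]
    expect_equal(p$dtc, 20.05 + shift_bins * 0.1, tolerance = 1e-6)
  }
})

test_that("shape score separates Gaussian, flat and bimodal profiles", {
  t <- seq(-4, 4, by = 0.2)
  gauss <- list(arrival_time_ms = t, intensity = 1000 * dnorm(t))
  expect_gt(shape_score(gauss), 0.9)
  expect_equal(shape_score(gauss),
               oracle_jb_score(t, 1000 * dnorm(t)), tolerance = 1e-12)
  flat <- list(arrival_time_ms = seq_len(40), intensity = rep(7, 40))
  expect_lt(shape_score(flat), 0.4)
  expect_equal(shape_score(flat),
               oracle_jb_score(seq_len(40), rep(7, 40)), tolerance = 1e-12)
  tb <- seq(-8, 8, by = 0.05)
  bimodal_w <- dnorm(tb, -5, 0.5) + dnorm(tb, 5, 0.5)
  bim <- list(arrival_time_ms = tb, intensity = bimodal_w)
  expect_lt(shape_score(bim), 0.05)
  # scale invariance
  expect_equal(shape_score(gauss),
               shape_score(list(arrival_time_ms = t,
                                intensity = 123.4 * 1000 * dnorm(t))),
               tolerance = 1e-12)
  expect_error(
    shape_score(list(arrival_time_ms = 1:4, intensity = rep(1, 4))),
    "insufficient profile")
})

test_that("isotopic score follows the vector-angle formula", {
  expect_equal(isotopic_score(c(2, 1, 0.2), c(2, 1, 0.2)), 1)
  expect_equal(isotopic_score(c(10, 5, 1), c(2, 1, 0.2)), 1)  # scale-free
  expect_equal(isotopic_score(c(1, 0), c(0, 1)), 0)
  s <- isotopic_score(c(0.9, 0.1), c(0.8, 0.2))
  ct <- (0.9 * 0.8 + 0.1 * 0.2) /
    (sqrt(0.9^2 + 0.1^2) * sqrt(0.8^2 + 0.2^2))
  expect_equal(ct, 0.9909, tolerance = 1e-4)
  expect_equal(s, 1 - acos(ct) / (pi / 2), tolerance = 1e-12)
  expect_equal(s, 0.9142, tolerance = 1e-3)
  # symmetry under exchanging the vectors
  expect_equal(isotopic_score(c(0.8, 0.2), c(0.9, 0.1)), s)
  expect_error(isotopic_score(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(isotopic_score(1, 1), "length")
})

test_that("prefilter applies all three bounds conjunctively", {
  specs <- list(c(0.9, 0.9, 0.5), c(0.9, 0.3, 0.5), c(0.3, 0.9, 0.5),
                c(0.9, 0.9, 0.01), c(0.5, 0.5, 0.04), c(0.41, 0.41, 0.03))
  peaks <- lapply(specs, function(s) {
    fake_peak(shape = s[1], iso = s[2], rel = s[3])
  })
  kept <- prefilter(peaks)
  expect_length(kept, 3L)
  expect_equal(vapply(kept, `[[`, numeric(1), "shape_score"),
               c(0.9, 0.5, 0.41))
  expect_equal(prefilter(list()), list())
  expect_length(prefilter(peaks, 0, 0, 0), 6L)
  # monotone: raising any threshold never adds a peak
  for (args in list(list(min_shape = 0.6), list(min_isotopic = 0.6),
                    list(min_rel_intensity = 0.1))) {
    expect_lte(length(do.call(prefilter, c(list(peaks), args))),
               length(kept))
  }
})

test_that("observed envelope integrates isotopomer strips at the peak dt", {
  tgt <- make_target("C11H12N2O2", "[M+H]", n_isotopomers = 3L)
  off <- tgt$envelope$offsets_da
  q <- tgt$envelope$rel_intensities
  mz_axis <- seq(tgt$target_mz - 0.5, tgt$target_mz + 2.5, by = 0.001)
  dt_axis <- seq(0.05, 50, by = 0.1)
  m <- matrix(0, length(dt_axis), length(mz_axis))
  for (k in 1:3) {
    m <- m + 100 * q[k] *
      outer(exp(-0.5 * ((dt_axis - 25) / 0.3)^2),
            exp(-0.5 * ((mz_axis - tgt$target_mz - off[k]) / 0.0012)^2))
  }
  map <- intensity_map(mz_axis, dt_axis, m)
  pk <- fake_peak(dtc = 25, dtw = 0.7)
  obs <- observed_envelope(map, tgt, pk)
  expect_length(obs, 3L)
  # +/-15 ppm strips span about 2.5 sigma of each isotopomer, so the
  # captured fractions agree across isotopomers to a few percent
  expect_equal(obs / obs[1], q / q[1], tolerance = 0.05)
  expect_gt(isotopic_score(obs, tgt$envelope), 0.97)
})
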