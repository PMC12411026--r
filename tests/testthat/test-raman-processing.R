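clean_cfg <- function(group = "BN", seed = 1, noise_sd = 0, rate = 0) {
  raman_sim_config(group, noise_sd = noise_sd, cosmic_ray_rate = rate,
                   seed = seed)
}

test_that("despiking is a no-op on spike-free spectra", {
  s <- generate_raman_spectrum(clean_cfg(noise_sd = 8))
  out <- remove_cosmic_rays(s)
  expect_equal(out$intensities, s$intensities)
  expect_length(attr(out, "spikes_removed"), 0)
  # noiseless smooth background alone is also left untouched
  cfg0 <- raman_sim_config("BN", band_centers = numeric(0),
                           band_amplitudes = numeric(0),
                           band_widths = numeric(0), noise_sd = 0,
                           cosmic_ray_rate = 0, seed = 2)
  s0 <- generate_raman_spectrum(cfg0)
  expect_equal(remove_cosmic_rays(s0)$intensities, s0$intensities)
})

test_that("a 50-SD spike is restored to within 3 noise SDs of truth", {
  cfg <- clean_cfg(seed = 5, noise_sd = 8)
  s <- generate_raman_spectrum(cfg)
  truth <- s$intensities
  i <- 250
  s$intensities[i] <- s$intensities[i] + 50 * 8
  out <- remove_cosmic_rays(s)
  expect_true(i %in% attr(out, "spikes_removed"))
  expect_lt(abs(out$intensities[i] - truth[i]), 3 * 8)
  clean <- setdiff(seq_along(truth), attr(out, "spikes_removed"))
  expect_equal(out$intensities[clean], truth[clean])
})

test_that("boundary spikes are handled one-sidedly", {
  s <- generate_raman_spectrum(clean_cfg(seed = 7, noise_sd = 5))
  n <- length(s$intensities)
  truth_last <- s$intensities[n]
  s$intensities[n] <- s$intensities[n] + 4000
  out <- remove_cosmic_rays(s)
  expect_true(n %in% attr(out, "spikes_removed"))
  expect_lt(abs(out$intensities[n] - truth_last), 25)
})

test_that("smoothing reproduces polynomials and preserves constants", {
  w <- seq(800, 1000, by = 2)
  y_poly <- 3 + 0.5 * w - 1e-3 * w^2 + 2e-6 * w^3
  s <- raman_spectrum(w, y_poly)
  expect_equal(smooth_spectrum(s, 11, 3)$intensities, y_poly,
               tolerance = 1e-8)
  s_const <- raman_spectrum(w, rep(4, length(w)))
  expect_equal(smooth_spectrum(s_const)$intensities, rep(4, length(w)))
})

test_that("smoothing reduces white-noise variance", {
  set.seed(3)
  w <- seq(800, 1800, by = 2)
  y <- rnorm(length(w))
  sm <- smooth_spectrum(raman_spectrum(w, y))
  expect_lt(var(sm$intensities), var(y))
})

test_that("smoothing rejects bad windows", {
  s <- raman_spectrum(1:20, rnorm(20))
  expect_error(smooth_spectrum(s, window = 10), "odd")
  expect_error(smooth_spectrum(s, window = 3, order = 3), "odd")
  expect_error(smooth_spectrum(s, window = 21), "shorter")
})

test_that("fingerprint normalization: unit area, scale invariance, idempotence", {
  s <- generate_raman_spectrum(clean_cfg(seed = 2, noise_sd = 4))
  n1 <- normalize_fingerprint(s)
  w <- n1$wavenumbers
  idx <- which(w >= 800 & w <= 1800)
  area <- sum(diff(w[idx]) * (head(n1$intensities[idx], -1) +
                                tail(n1$intensities[idx], -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-12)
  s10 <- raman_spectrum(s$wavenumbers, s$intensities * 10)
  expect_equal(normalize_fingerprint(s10)$intensities, n1$intensities)
  expect_equal(normalize_fingerprint(n1)$intensities, n1$intensities)
  # fine-grid Riemann oracle for the integral (implied area = raw/normalized)
  f <- approxfun(s$wavenumbers, s$intensities)
  grid <- seq(800, 1800, length.out = 2e5)
  fg <- f(grid)
  fine_sum <- sum(diff(grid) * (head(fg, -1) + tail(fg, -1)) / 2)
  implied_area <- s$intensities[idx][5] / n1$intensities[idx][5]
  expect_equal(implied_area, fine_sum, tolerance = 1e-6)
  short <- raman_spectrum(seq(900, 1700, 2), rnorm(401))
  expect_error(normalize_fingerprint(short), "cover")
})

test_that("arPLS returns a gentle peak-free background as its own baseline", {
  # at the default noise the baseline must stay below noise scale from truth
  cfg <- raman_sim_config("BN", band_centers = numeric(0),
                          band_amplitudes = numeric(0),
                          band_widths = numeric(0), noise_sd = 8,
                          cosmic_ray_rate = 0, seed = 1)
  s <- generate_raman_spectrum(cfg)
  res <- suppressWarnings(arpls_baseline(s))
  truth <- attr(s, "true_background")
  expect_lt(max(abs(res$baseline - truth)), 8)  # background is ~1000s counts
  # corrected residual is noise plus baseline error: the expected maximum of
  # ~1000 N(0, sd) draws is ~3.5 sd, so 5 sd bounds it with margin
  expect_lt(max(abs(res$corrected$intensities)), 5 * 8)
})

test_that("arPLS beats the unweighted penalized fit against truth", {
  cfg <- clean_cfg("MM", seed = 4, noise_sd = 5)
  s <- generate_raman_spectrum(cfg)
  truth <- attr(s, "true_background")
  res <- suppressWarnings(arpls_baseline(s))
  rmse <- sqrt(mean((res$baseline - truth)^2))
  n <- length(truth)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  plain <- as.numeric(Matrix::solve(Matrix::Diagonal(n) +
                                      1e5 * Matrix::crossprod(D),
                                    s$intensities))
  rmse_plain <- sqrt(mean((plain - truth)^2))
  expect_lt(rmse, rmse_plain)
  expect_lt(rmse, 0.05 * mean(truth))
})

test_that("arPLS of the zero spectrum is zero", {
  s <- raman_spectrum(seq(800, 1000, 2), rep(0, 101))
  res <- arpls_baseline(s)
  expect_equal(res$baseline, rep(0, 101))
  expect_true(res$converged)
})

test_that("adding a peak barely moves the arPLS baseline under it", {
  s <- generate_raman_spectrum(clean_cfg(seed = 9, noise_sd = 3))
  b0 <- suppressWarnings(arpls_baseline(s))$baseline
  i <- which(s$wavenumbers == 1300)
  peak <- 500 * exp(-0.5 * ((s$wavenumbers - 1300) / 10)^2)
  s2 <- raman_spectrum(s$wavenumbers, s$intensities + peak)
  b1 <- suppressWarnings(arpls_baseline(s2))$baseline
  expect_lt(abs(b1[i] - b0[i]), 0.1 * 500)
})

test_that("full preprocessing chain preserves relative band heights", {
  cfg <- clean_cfg("BN", seed = 21, noise_sd = 2)
  s <- generate_raman_spectrum(cfg)
  proc <- suppressWarnings(
    arpls_baseline(smooth_spectrum(remove_cosmic_rays(s)))$corrected)
  centers <- cfg$band_centers
  idx <- match(centers, s$wavenumbers)
  recovered <- proc$intensities[idx]
  expect_gt(cor(recovered, cfg$band_amplitudes), 0.99)
  expect_identical(proc$processing_log[-1],
                   c("despike(z=8)", "smooth(window=11,order=3)",
                     "arpls(lambda=100000)"))
})

test_that("group statistics match the closed-form t interval", {
  set.seed(10)
  w <- seq(800, 1800, 10)
  sigma <- 4
  specs <- lapply(1:100, function(i)
    raman_spectrum(w, 100 + rnorm(length(w), 0, sigma)))
  gs <- group_statistics(specs, "BN")
  expected_hw <- qt(0.975, 99) * sigma / sqrt(100)
  expect_equal(mean(gs$ci_half_width), expected_hw, tolerance = 0.1)
  expect_length(gs$ci_points, 20)
  expect_true(all(gs$ci_half_width >= 0))
  # identical spectra: zero half-width; mean of two is the average
  twin <- list(specs[[1]], specs[[1]])
  gs0 <- group_statistics(twin, "BN")
  expect_equal(gs0$ci_half_width, rep(0, length(w)))
  pair <- group_statistics(specs[1:2], "BN")
  expect_equal(pair$mean,
               (specs[[1]]$intensities + specs[[2]]$intensities) / 2)
  expect_error(group_statistics(specs[1], "BN"), ">= 2")
})

test_that("difference spectra: self-zero, antisymmetry, Welch oracle", {
  set.seed(11)
  w <- seq(800, 1800, 10)
  mk <- function(n, mu, sd) lapply(seq_len(n), function(i)
    raman_spectrum(w, mu + rnorm(length(w), 0, sd)))
  a <- group_statistics(mk(8, 100, 5), "BN")
  b <- group_statistics(mk(13, 90, 9), "MM")
  expect_equal(difference_spectrum(a, a)$difference, rep(0, length(w)))
  d_ab <- difference_spectrum(a, b)
  d_ba <- difference_spectrum(b, a)
  expect_equal(d_ab$difference, -d_ba$difference, tolerance = 1e-12)
  expect_equal(d_ab$ci_half_width, d_ba$ci_half_width, tolerance = 1e-12)
  # direct per-channel Welch computation on the raw matrices
  ma <- do.call(rbind, lapply(mk(8, 100, 5), `[[`, "intensities"))
  set.seed(11)
  ma <- do.call(rbind, lapply(mk(8, 100, 5), `[[`, "intensities"))
  mb <- do.call(rbind, lapply(mk(13, 90, 9), `[[`, "intensities"))
  a2 <- group_statistics(apply(ma, 1, function(r) raman_spectrum(w, r),
                               simplify = FALSE), "BN")
  b2 <- group_statistics(apply(mb, 1, function(r) raman_spectrum(w, r),
                               simplify = FALSE), "MM")
  d2 <- difference_spectrum(a2, b2)
  oracle_hw <- vapply(seq_along(w), function(j) {
    tt <- t.test(ma[, j], mb[, j])
    diff(tt$conf.int) / 2
  }, numeric(1))
  expect_equal(d2$ci_half_width, oracle_hw, tolerance = 1e-9)
  short <- group_statistics(mk(3, 1, 1), "BN")
  short$wavenumbers <- short$wavenumbers + 1
  expect_error(difference_spectrum(a, short), "different axes")
})

test_that("regridding puts spectra on a common axis and logs it", {
  s1 <- raman_spectrum(seq(800, 1800, 2), rnorm(501))
  s2 <- raman_spectrum(seq(801, 1799, 2), rnorm(500))
  out <- regrid_spectra(list(s1, s2))
  expect_identical(out[[2]]$wavenumbers, s1$wavenumbers)
  expect_true("regrid" %in% out[[2]]$processing_log)
  expect_identical(out[[1]]$intensities, s1$intensities)
  expect_error(group_statistics(list(s1, s2), "BN"), "common axis")
})
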