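log_step <- function(s, step) {
  s$processing_log <- c(s$processing_log, step)
  s
}

#' Remove cosmic-ray spikes from a Raman spectrum
#'
#' Cosmic rays hit single CCD channels, so they stand out in the second
#' difference of the spectrum. Channels whose modified z-score of the second
#' difference (`0.6745 * |d - median(d)| / MAD(d)`) exceeds `z_threshold` are
#' replaced by linear interpolation between the nearest clean neighbors;
#' flagged channels at either end are filled from the nearest clean value.
#'
#' @param s a [raman_spectrum()] with at least 5 channels.
#' @param z_threshold modified z-score cutoff (default 8).
#' @return the despiked `raman_spectrum` (attribute `spikes_removed` holds
#'   the flagged channel indices).
#' @export
remove_cosmic_rays <- function(s, z_threshold = 8) {
  stopifnot(inherits(s, "raman_spectrum"))
  y <- s$intensities
  n <- length(y)
  if (n < 5L) stop_config("need >= 5 channels to despike")
  d2c <- diff(y, differences = 2)  # centered, aligned to channels 2..n-1
  # one-sided second differences so boundary-channel spikes are detectable
  d2 <- c(y[1] - 2 * y[2] + y[3], d2c, y[n] - 2 * y[n - 1] + y[n - 2])
  med <- median(d2)
  mad0 <- median(abs(d2 - med))
  flagged <- if (mad0 > 0) {
    which(0.6745 * abs(d2 - med) / mad0 > z_threshold)
  } else integer(0)
  if (length(flagged)) {
    clean <- setdiff(seq_len(n), flagged)
    if (length(clean) >= 2L) {
      y[flagged] <- approx(clean, y[clean], xout = flagged, rule = 2)$y
    }
  }
  out <- raman_spectrum(s$wavenumbers, y, s$processing_log)
  out <- log_step(out, sprintf("despike(z=%g)", z_threshold))
  attr(out, "spikes_removed") <- flagged
  out
}

# Savitzky-Golay projection: value at offset `at` of the degree-`order`
# polynomial least-squares fit over offsets -h..h.
.sg_row <- function(h, order, at = 0) {
  A <- outer(-h:h, 0:order, "^")
  drop(outer(at, 0:order, "^") %*% solve(crossprod(A), t(A)))
}

#' Savitzky-Golay smoothing of a Raman spectrum
#'
#' Moving-window polynomial least-squares smoothing. Interior channels use
#' the centered window; the first and last half-windows are filled by
#' evaluating the polynomial fitted to the first/last full window at their
#' positions, so polynomials up to `order` are reproduced exactly everywhere.
#'
#' @param s a [raman_spectrum()].
#' @param window odd window length in channels (default 11), `> order`.
#' @param order polynomial degree (default 3).
#' @return the smoothed `raman_spectrum`.
#' @export
smooth_spectrum <- function(s, window = 11L, order = 3L) {
  stopifnot(inherits(s, "raman_spectrum"))
  y <- s$intensities
  n <- length(y)
  if (window %% 2L != 1L || window <= order)
    stop_config("window must be odd and > order")
  if (window >= n) stop("window must be shorter than the spectrum",
                        call. = FALSE)
  h <- (window - 1L) %/% 2L
  cc <- .sg_row(h, order)
  out <- y
  core <- (h + 1L):(n - h)
  out[core] <- vapply(core, function(i) sum(cc * y[(i - h):(i + h)]),
                      numeric(1))
  for (d in seq_len(h)) {  # edges: evaluate the boundary-window fit
    out[d] <- sum(.sg_row(h, order, at = d - h - 1L) * y[1:window])
    out[n - h + d] <- sum(.sg_row(h, order, at = d) *
                            y[(n - window + 1L):n])
  }
  s2 <- raman_spectrum(s$wavenumbers, out, s$processing_log)
  log_step(s2, sprintf("smooth(window=%d,order=%d)", window, order))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Area-normalize a spectrum over the fingerprint region
#'
#' Divides the whole spectrum by the trapezoidal integral of intensity over
#' `[lo, hi]` (default 800-1800 1/cm), so the fingerprint-region area of the
#' result is exactly 1. Scale-invariant and idempotent.
#'
#' @param s a [raman_spectrum()] whose axis covers `[lo, hi]`.
#' @param lo,hi integration bounds, 1/cm.
#' @return the normalized `raman_spectrum`.
#' @export
normalize_fingerprint <- function(s, lo = 800, hi = 1800) {
  stopifnot(inherits(s, "raman_spectrum"))
  w <- s$wavenumbers
  if (w[1] > lo || w[length(w)] < hi)
    stop_config("axis does not cover the normalization region")
  idx <- which(w >= lo & w <= hi)
  if (length(idx) < 2L) stop_config("too few channels in region")
  area <- trapz(w[idx], s$intensities[idx])
  if (!is.finite(area) || area <= 0)
    stop("non-positive integral over the normalization region", call. = FALSE)
  s2 <- raman_spectrum(w, s$intensities / area, s$processing_log)
  log_step(s2, sprintf("normalize(%g-%g)", lo, hi))
}

#' arPLS autofluorescence baseline estimation
#'
#' Asymmetrically reweighted penalized least squares: iteratively solves the
#' weighted Whittaker system `(W + lambda D'D) z = W y` with a
#' second-difference penalty `D`, then reweights channels by the arPLS
#' logistic rule `w = 1 / (1 + exp(2 (d - (2 s_d - m_d)) / s_d))`, where `d =
#' y - z` and `m_d`, `s_d` are the mean and SD of the negative residuals.
#' Channels well above the running baseline (Raman peaks) are driven toward
#' zero weight, so the baseline relaxes under them instead of following them.
#'
#' @param s a [raman_spectrum()].
#' @param lambda smoothness penalty (default 1e5 for channel grids of a few
#'   hundred to a thousand points).
#' @param ratio_tol convergence tolerance on the relative weight change
#'   (default 1e-6).
#' @param max_iter iteration cap (default 50); hitting it returns the last
#'   iterate with a warning.
#' @return list with `baseline` (numeric vector), `corrected` (the
#'   baseline-subtracted `raman_spectrum`), `iterations`, `converged`.
#' @export
arpls_baseline <- function(s, lambda = 1e5, ratio_tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (lambda <= 0 || ratio_tol <= 0 || max_iter < 1L)
    stop_config("invalid arPLS configuration")
  y <- s$intensities
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  H <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + H, w * y))
    d <- y - z
    dn <- d[d < 0]
    if (length(dn) < 2L) { converged <- TRUE; break }  # nothing above baseline
    m <- mean(dn)
    sdev <- sd(dn)
    if (!is.finite(sdev) || sdev == 0) { converged <- TRUE; break }
    expo <- pmin(pmax(2 * (d - (2 * sdev - m)) / sdev, -500), 500)
    wt <- 1 / (1 + exp(expo))
    if (sqrt(sum((w - wt)^2)) / sqrt(sum(w^2)) < ratio_tol) {
      converged <- TRUE
      w <- wt
      break
    }
    w <- wt
  }
  if (!converged) warning("arPLS did not converge within max_iter")
  corrected <- raman_spectrum(s$wavenumbers, y - z, s$processing_log)
  corrected <- log_step(corrected, sprintf("arpls(lambda=%g)", lambda))
  list(baseline = z, corrected = corrected, iterations = iter,
       converged = converged)
}

#' Interpolate spectra onto a common wavenumber axis
#'
#' @param spectra list of `raman_spectrum`.
#' @param axis target axis; default: the first spectrum's axis.
#' @return list of `raman_spectrum` on `axis` (re-grid logged).
#' @export
regrid_spectra <- function(spectra, axis = spectra[[1]]$wavenumbers) {
  lapply(spectra, function(s) {
    if (identical(s$wavenumbers, axis)) return(s)
    y <- approx(s$wavenumbers, s$intensities, xout = axis, rule = 2)$y
    log_step(raman_spectrum(axis, y, s$processing_log), "regrid")
  })
}

#' Group mean spectrum with pointwise confidence intervals
#'
#' Pointwise mean and Student-t confidence half-width
#' `t(1-(1-conf)/2, n-1) * sd / sqrt(n)` per channel, plus a subsample of
#' `n_ci_points` equally spaced channels for uncluttered CI display.
#'
#' @param spectra list of >= 2 `raman_spectrum` on a common axis.
#' @param group group label, `"BN"` or `"MM"`.
#' @param confidence confidence level (default 0.95).
#' @param n_ci_points number of display CI positions (default 20).
#' @return object of class `group_spectra`: list with `group`, `wavenumbers`,
#'   `mean`, `sd`, `n`, `ci_half_width`, `ci_points` (channel indices).
#' @export
group_statistics <- function(spectra, group = c("BN", "MM"),
                             confidence = 0.95, n_ci_points = 20L) {
  group <- match.arg(group)
  if (length(spectra) < 2L)
    stop("confidence intervals need >= 2 spectra", call. = FALSE)
  axis <- spectra[[1]]$wavenumbers
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wavenumbers, axis)))
      stop("spectra are not on a common axis; regrid_spectra() first",
           call. = FALSE)
  }
  m <- do.call(rbind, lapply(spectra, `[[`, "intensities"))
  n <- nrow(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  hw <- qt(1 - (1 - confidence) / 2, df = n - 1) * sdv / sqrt(n)
  structure(list(group = group, wavenumbers = axis, mean = mu, sd = sdv,
                 n = n, ci_half_width = hw,
                 ci_points = unique(round(seq(1, length(axis),
                                              length.out = n_ci_points))),
                 confidence = confidence),
            class = "group_spectra")
}

#' Difference of two group mean spectra with Welch confidence intervals
#'
#' `difference = mean_a - mean_b` per channel; the half-width uses the
#' unpooled (Welch) two-sample t interval with Welch-Satterthwaite degrees
#' of freedom per channel.
#'
#' @param a,b `group_spectra` on the same axis.
#' @param confidence confidence level (default 0.95).
#' @return list with `wavenumbers`, `difference`, `ci_half_width`, `groups`.
#' @export
difference_spectrum <- function(a, b, confidence = 0.95) {
  stopifnot(inherits(a, "group_spectra"), inherits(b, "group_spectra"))
  if (!isTRUE(all.equal(a$wavenumbers, b$wavenumbers)))
    stop("group spectra are on different axes", call. = FALSE)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  df[!is.finite(df)] <- a$n + b$n - 2  # both variances zero
  hw <- qt(1 - (1 - confidence) / 2, df) * sqrt(va + vb)
  list(wavenumbers = a$wavenumbers, difference = a$mean - b$mean,
       ci_half_width = hw, groups = c(a$group, b$group))
}
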