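#' Locate the tissue surface in an A-scan
#'
#' The surface is taken as the global intensity maximum (the bright air-tissue
#' interface); ties are broken toward the shallowest pixel. The exponential
#' decay fit starts from this index.
#'
#' @param ascan an [oct_ascan()] or numeric vector.
#' @return integer surface index (1-based pixels).
#' @export
detect_surface <- function(ascan) {
  y <- if (inherits(ascan, "oct_ascan")) ascan$intensities else as.numeric(ascan)
  if (length(y) == 0L) stop_config("empty A-scan")
  if (all(y == y[1])) stop("no surface: flat A-scan signal", call. = FALSE)
  which.max(y)  # first maximum == shallowest tie
}

# Profile SSE of I(z) = a exp(-2 b z): for fixed b the optimal amplitude is
# a(b) = <y, u>/<u, u> with u = exp(-2 b z), reducing the problem to a 1-D
# minimization in b.
.profile_sse <- function(b, y, z) {
  u <- exp(-2 * b * z)
  uu <- sum(u * u)
  a <- if (uu > 0) sum(y * u) / uu else 0
  sum((y - a * u)^2)
}

.profile_a <- function(b, y, z) {
  u <- exp(-2 * b * z)
  uu <- sum(u * u)
  if (uu > 0) sum(y * u) / uu else 0
}

#' Fit the two-way Lambert-Beer decay to one A-scan
#'
#' Least-squares fit of `I(z) = a * exp(-2 * b * z)` on linear intensities
#' over the window starting at the surface, where `b` is the effective
#' attenuation coefficient (attenuation times refractive index). By default
#' `z` is physical depth below the surface in mm (`pixels * pixel_spacing`),
#' so `b` is an effective 1/mm value; `per_pixel = TRUE` measures `z` in
#' pixels instead (the two coincide when `pixel_spacing = 1`).
#'
#' The fit profiles the amplitude out analytically and minimizes over `b`
#' with Brent's method, started and bracketed by an ordinary regression on
#' the log intensities (floor-subtracted). Whichever of the two candidates
#' has the smaller SSE is returned, so the nonlinear SSE never exceeds the
#' log-linear fallback's.
#'
#' @param ascan an [oct_ascan()].
#' @param surface_index fit origin in pixels; default [detect_surface()].
#' @param fit_depth fit window length in pixels (default 150); the window is
#'   `[surface_index, min(surface_index + fit_depth - 1, end)]`.
#' @param per_pixel if `TRUE`, measure depth in pixels rather than mm.
#' @return a one-row `data.frame` (class `oct_fit`) with columns
#'   `column_index`, `amplitude_a`, `attenuation_b`, `r_squared`, `rmse`,
#'   `max_intensity`, `surface_index`, `converged`. `r_squared` is
#'   `1 - SS_res/SS_tot` over the window (defined as 1 when both sums vanish,
#'   0 when only `SS_tot` does); `rmse = sqrt(SS_res / n_window)`;
#'   `max_intensity` is the observed intensity at the surface index.
#' @export
fit_attenuation <- function(ascan, surface_index = detect_surface(ascan),
                            fit_depth = 150L, per_pixel = FALSE) {
  stopifnot(inherits(ascan, "oct_ascan"))
  y_all <- ascan$intensities
  n <- length(y_all)
  if (surface_index < 1L || surface_index > n)
    stop_config("surface_index outside the A-scan")
  hi <- min(surface_index + fit_depth - 1L, n)
  win <- surface_index:hi
  if (length(win) < 3L) stop("fit window shorter than 3 points", call. = FALSE)
  y <- y_all[win]
  dz <- if (per_pixel) 1 else ascan$pixel_spacing
  z <- (seq_along(win) - 1) * dz

  # log-linear initialization on floor-subtracted intensities; restricted to
  # the leading stretch still well above zero so a fully decayed tail cannot
  # drag the slope toward zero
  floor_est <- if (surface_index > 5L) {
    median(y_all[seq_len(surface_index - 1L)])
  } else 0
  ypos <- y - floor_est
  lead <- which(ypos < max(ypos) * 1e-3)
  lead <- if (length(lead)) max(lead[1] - 1L, 5L) else length(y)
  lead <- min(lead, length(y))
  eps <- max(max(y), 1) * 1e-9
  zl <- z[seq_len(lead)]
  ll <- lm.fit(cbind(1, zl), log(pmax(ypos[seq_len(lead)], eps)))
  b0 <- max(-ll$coefficients[[2]] / 2, 0)
  sse_ll <- .profile_sse(b0, y, z)

  # upper bracket: 8x the log-linear slope, or full extinction over the
  # window — keeps Brent off the flat large-b plateau
  b_hi <- max(8 * b0, 10 / z[length(z)])
  opt <- tryCatch(optimize(.profile_sse, c(0, b_hi), y = y, z = z,
                           tol = 1e-10),
                  error = function(e) NULL)
  converged <- !is.null(opt) && is.finite(opt$objective)
  if (converged && opt$objective <= sse_ll) {
    b <- opt$minimum
    sse <- opt$objective
  } else {
    b <- b0
    sse <- sse_ll
  }
  a <- .profile_a(b, y, z)

  m <- length(y)
  sstot <- sum((y - mean(y))^2)
  tol0 <- 1e-13 * m * max(1, max(abs(y)))^2
  r2 <- if (sstot <= tol0) {
    if (sse <= tol0) 1 else 0
  } else 1 - sse / sstot
  structure(data.frame(
    column_index = ascan$column_index, amplitude_a = a, attenuation_b = b,
    r_squared = r2, rmse = sqrt(sse / m),
    max_intensity = y_all[surface_index],
    surface_index = as.integer(surface_index), converged = converged
  ), class = c("oct_fit", "data.frame"))
}

#' Fit every A-scan of a B-scan region of interest
#'
#' Applies [detect_surface()] and [fit_attenuation()] to each column in
#' `roi`, never aborting the scan: a column whose fit fails is returned as a
#' flagged row (`converged = FALSE`, `NA` estimates) and counted in the
#' `n_failed` attribute.
#'
#' @param bscan an `oct_bscan`.
#' @param roi integer vector of column indices (default: all columns); in the
#'   clinical workflow this selects the ~1000 lesion-area A-scans.
#' @param fit_depth,per_pixel passed to [fit_attenuation()].
#' @return an `oct_fit` data frame with one row per ROI column, in ROI order.
#' @export
fit_bscan <- function(bscan, roi = seq_len(ncol(bscan)), fit_depth = 150L,
                      per_pixel = FALSE) {
  stopifnot(inherits(bscan, "oct_bscan"))
  roi <- as.integer(roi)
  if (any(roi < 1L) || any(roi > ncol(bscan)))
    stop_config("roi outside B-scan width")
  rows <- vector("list", length(roi))
  n_failed <- 0L
  for (k in seq_along(roi)) {
    j <- roi[k]
    rows[[k]] <- tryCatch(
      fit_attenuation(bscan_column(bscan, j), fit_depth = fit_depth,
                      per_pixel = per_pixel),
      error = function(e) {
        n_failed <<- n_failed + 1L
        data.frame(column_index = j, amplitude_a = NA_real_,
                   attenuation_b = NA_real_, r_squared = NA_real_,
                   rmse = NA_real_, max_intensity = NA_real_,
                   surface_index = NA_integer_, converged = FALSE)
      })
  }
  out <- do.call(rbind, rows)
  if (n_failed > 0L)
    message(n_failed, " of ", length(roi), " A-scan fits failed and were flagged")
  structure(out, class = c("oct_fit", "data.frame"),
            sample_id = attr(bscan, "sample_id"),
            sample_label = attr(bscan, "sample_label"), n_failed = n_failed)
}

#' Attenuation-coefficient map of a fitted B-scan
#'
#' The per-column fitted attenuation coefficients in acquisition order, i.e.
#' the 1-D profile rendered as a heatmap row in lesion assessment.
#'
#' @param fits an `oct_fit` data frame from [fit_bscan()].
#' @param sample_id identifier; defaults to the one carried by `fits`.
#' @return an `attenuation_map`: numeric vector of `attenuation_b` with
#'   attribute `sample_id`.
#' @export
attenuation_map <- function(fits, sample_id = attr(fits, "sample_id")) {
  if (NROW(fits) == 0L) stop_config("no fits supplied")
  structure(fits$attenuation_b, class = "attenuation_map",
            sample_id = if (is.null(sample_id)) "" else sample_id,
            column_index = fits$column_index)
}

#' Write an attenuation map as delimited text
#'
#' @param map an [attenuation_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attenuation_map <- function(map, path) {
  df <- data.frame(column_index = attr(map, "column_index"),
                   attenuation_b = as.numeric(map))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
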