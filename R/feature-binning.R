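.feature_cols <- c("mean_b", "sd_b", "mean_r2", "sd_r2",
                   "mean_rmse", "sd_rmse", "mean_maxI", "sd_maxI")

#' Bin per-A-scan fit results into feature vectors
#'
#' Consecutive non-overlapping bins of `bin_size` fitted A-scans are reduced
#' to the arithmetic mean and sample standard deviation (n-1 denominator) of
#' the four fit quantities — attenuation coefficient, R-squared, RMSE and
#' maximum intensity — giving the 8-feature representation used for
#' classification. Binning damps per-A-scan observational error.
#'
#' Non-converged fits are dropped first and bins are formed on the surviving
#' sequence; a trailing incomplete bin is discarded so all bins share the
#' same size, hence `n_bins = floor(n_usable / bin_size)`.
#'
#' @param fits an `oct_fit` data frame ([fit_bscan()]).
#' @param bin_size A-scans per bin (default 5).
#' @param label class label `"BN"` or `"MM"`; defaults to the label carried
#'   by `fits`.
#' @param sample_id sample identifier; defaults to the one carried by `fits`.
#' @return a `data.frame` (class `binned_features`) with the 8 feature
#'   columns in fixed order, then `label`, `sample_id`, `bin_index`.
#' @export
bin_features <- function(fits, bin_size = 5L,
                         label = attr(fits, "sample_label"),
                         sample_id = attr(fits, "sample_id")) {
  if (NROW(fits) == 0L) stop_config("no fits supplied")
  if (bin_size < 2L) stop_config("bin_size must be >= 2")
  if (is.null(label)) stop_config("label required")
  label <- match.arg(label, c("BN", "MM"))
  if (is.null(sample_id)) sample_id <- ""
  ok <- fits[fits$converged & is.finite(fits$attenuation_b), , drop = FALSE]
  n_bins <- nrow(ok) %/% bin_size
  if (n_bins == 0L) {
    warning("fewer than bin_size converged fits; empty feature set")
    out <- data.frame(matrix(numeric(0), 0, 8,
                             dimnames = list(NULL, .feature_cols)))
    out$label <- character(0); out$sample_id <- character(0)
    out$bin_index <- integer(0)
    class(out) <- c("binned_features", "data.frame")
    return(out)
  }
  idx <- rep(seq_len(n_bins), each = bin_size)
  used <- ok[seq_along(idx), , drop = FALSE]
  agg <- function(v, f) as.numeric(tapply(v, idx, f))
  out <- data.frame(
    mean_b    = agg(used$attenuation_b, mean),
    sd_b      = agg(used$attenuation_b, sd),
    mean_r2   = agg(used$r_squared, mean),
    sd_r2     = agg(used$r_squared, sd),
    mean_rmse = agg(used$rmse, mean),
    sd_rmse   = agg(used$rmse, sd),
    mean_maxI = agg(used$max_intensity, mean),
    sd_maxI   = agg(used$max_intensity, sd),
    label = label, sample_id = sample_id, bin_index = seq_len(n_bins)
  )
  class(out) <- c("binned_features", "data.frame")
  out
}

#' Assemble binned features from several samples into one dataset
#'
#' Row-wise concatenation preserving `sample_id` (needed for the per-sample
#' majority report) with the 8 feature columns in their fixed order.
#'
#' @param ... `binned_features` data frames, or a single list of them.
#' @return a `binned_features` data frame.
#' @export
assemble_dataset <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) parts <- parts[[1]]
  parts <- Filter(function(p) NROW(p) > 0L, parts)
  if (length(parts) == 0L) stop_config("no feature rows to assemble")
  for (p in parts) {
    if (!all(c(.feature_cols, "label", "sample_id") %in% names(p)))
      stop_config("input is not a binned feature table")
  }
  out <- do.call(rbind, lapply(parts, function(p)
    p[, c(.feature_cols, "label", "sample_id", "bin_index")]))
  rownames(out) <- NULL
  class(out) <- c("binned_features", "data.frame")
  out
}
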