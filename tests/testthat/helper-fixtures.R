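# Shared fixture builders. Everything is generated in code at test time;
# no data files.

# Noise-free decaying A-scan with unit pixel spacing, so depth in pixels
# equals depth in the fit's z units.
noiseless_ascan <- function(a = 2, b = 0.5, n = 120, spacing = 1) {
  z <- (seq_len(n) - 1) * spacing
  oct_ascan(a * exp(-2 * b * z), pixel_spacing = spacing)
}

quiet_fit_bscan <- function(...) suppressMessages(fit_bscan(...))

# Small fitted-and-binned dataset: `n_per_class` B-scans per class at
# `n_ascans` columns each. Deliberately scaled down from the 6 x 1000
# clinical design to keep unit tests fast.
small_dataset <- function(n_per_class = 1, n_ascans = 200, seed = 42,
                          fit_depth = 150) {
  parts <- list()
  for (cls in c("BN", "MM")) {
    for (i in seq_len(n_per_class)) {
      cfg <- oct_sim_config(cls, n_ascans = n_ascans,
                            seed = seed + 17 * i + (cls == "MM") * 1009)
      sid <- sprintf("%02d_%s", i + (cls == "MM") * n_per_class,
                     if (cls == "BN") "Nevus" else "Melanoma")
      bs <- generate_bscan(cfg, sample_id = sid)
      parts[[sid]] <- bin_features(quiet_fit_bscan(bs, fit_depth = fit_depth))
    }
  }
  assemble_dataset(parts)
}

# Gaussian feature matrix with two classes separated by `delta` SDs on every
# column; returns a binned_features-shaped data frame usable by
# cross_validate().
gaussian_features <- function(n_per_class = 600, p = 8, delta = 4,
                              seed = 1, informative = rep(TRUE, p)) {
  set.seed(seed)
  shift <- ifelse(informative, delta, 0)
  x_bn <- matrix(rnorm(n_per_class * p), n_per_class, p)
  x_mm <- matrix(rnorm(n_per_class * p), n_per_class, p)
  x_mm <- sweep(x_mm, 2, shift, "+")
  x <- rbind(x_bn, x_mm)
  colnames(x) <- attenuskin:::.feature_cols[seq_len(p)]
  df <- as.data.frame(x)
  df$label <- rep(c("BN", "MM"), each = n_per_class)
  df$sample_id <- rep(c("s_bn", "s_mm"), each = n_per_class)
  df$bin_index <- rep(seq_len(n_per_class), 2)
  df
}

# Mann-Whitney AUC of scores: probability that a positive outranks a
# negative, ties counted half. Independent oracle for the ROC-trapezoid AUC.
rank_sum_auc <- function(scores, is_pos) {
  r <- rank(scores)
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
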