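#' Default end-to-end run configuration
#'
#' Describes a seeded demonstration run mirroring the clinical design: three
#' benign-nevus and three melanoma B-scans of 1000 lesion A-scans each
#' (giving 6 x 200 = 1200 binned instances), plus a Raman branch with
#' `n_raman` spectra per group.
#'
#' @param seed global seed; per-stage seeds derive from it via
#'   [stage_seed()].
#' @param out_dir output directory.
#' @param n_samples_per_class B-scans per class (default 3).
#' @param n_ascans A-scans per B-scan (default 1000).
#' @param n_raman Raman spectra per group (default 30).
#' @param bin_size A-scans per feature bin (default 5).
#' @param fit_depth fit window, pixels (default 150).
#' @param arpls_lambda arPLS penalty (default 1e5).
#' @return a named list (class `run_config`).
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("attenuskin_run_"),
                       n_samples_per_class = 3L, n_ascans = 1000L,
                       n_raman = 30L, bin_size = 5L, fit_depth = 150L,
                       arpls_lambda = 1e5) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_samples_per_class = as.integer(n_samples_per_class),
                 n_ascans = as.integer(n_ascans), n_raman = as.integer(n_raman),
                 bin_size = as.integer(bin_size),
                 fit_depth = as.integer(fit_depth),
                 arpls_lambda = arpls_lambda),
            class = "run_config")
}

#' Read a JSON run configuration
#'
#' @param path JSON file with any subset of [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  known <- setdiff(names(cfg), "")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop_config("unknown config keys: ",
                               paste(bad, collapse = ", "))
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full dual-modal analysis pipeline
#'
#' Simulate (or reuse) OCT B-scans and Raman spectra, fit attenuation, bin
#' features, cross-validate the linear SVM (all 8 features and the
#' attenuation-only pair), and run the Raman branch
#' (despike, smooth, normalize, group CIs, arPLS, difference spectrum).
#' All intermediates are written under `cfg$out_dir` along with
#' `report.json`, `raman_report.json` and `manifest.json`. Outputs are a
#' pure function of the configuration (seeds included), so reruns are
#' byte-identical except for the manifest timestamp.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly: list with the config snapshot, output
#'   file MD5 digests, package version and timestamp.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- OCT branch ------------------------------------------------------
  binned <- list()
  oct_seed <- stage_seed(cfg$seed, "simulate_oct")
  for (cls in c("BN", "MM")) {
    for (i in seq_len(cfg$n_samples_per_class)) {
      sid <- sprintf("%02d_%s", (cls == "MM") * cfg$n_samples_per_class + i,
                     if (cls == "BN") "Nevus" else "Melanoma")
      ocfg <- oct_sim_config(class_label = cls, n_ascans = cfg$n_ascans,
                             seed = (oct_seed + 131L * length(binned)) %%
                               2147483647L)
      bs <- generate_bscan(ocfg, sample_id = sid)
      write_bscan(bs, file.path(cfg$out_dir, paste0(sid, "_bscan.csv")))
      fits <- fit_bscan(bs, fit_depth = cfg$fit_depth)
      write_fits(fits, file.path(cfg$out_dir, paste0(sid, "_fits.csv")))
      write_attenuation_map(attenuation_map(fits),
                            file.path(cfg$out_dir, paste0(sid, "_map.csv")))
      binned[[sid]] <- bin_features(fits, bin_size = cfg$bin_size)
    }
  }
  dataset <- assemble_dataset(binned)
  write.table(dataset, file.path(cfg$out_dir, "features.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)

  cls_seed <- stage_seed(cfg$seed, "classify")
  rep_all <- cross_validate(dataset, cv_config(seed = cls_seed))
  rep_atten <- cross_validate(dataset,
                              cv_config(feature_subset = c("mean_b", "sd_b"),
                                        seed = cls_seed))
  report <- list(
    all_features = cv_report_json(rep_all),
    attenuation_only = cv_report_json(rep_atten)
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(data.frame(fpr = rep_all$mean_roc$fpr_grid,
                         mean_tpr = rep_all$mean_roc$mean_tpr,
                         sd_tpr = rep_all$mean_roc$sd_tpr),
              file.path(cfg$out_dir, "roc_grid.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)

  # --- Raman branch ----------------------------------------------------
  raman_seed <- stage_seed(cfg$seed, "simulate_raman")
  groups <- list()
  for (grp in c("BN", "MM")) {
    specs <- lapply(seq_len(cfg$n_raman), function(i) {
      rcfg <- raman_sim_config(group = grp,
                               seed = (raman_seed + 977L * i +
                                         (grp == "MM") * 499L) %% 2147483647L)
      generate_raman_spectrum(rcfg)
    })
    proc <- lapply(specs, function(s)
      normalize_fingerprint(smooth_spectrum(remove_cosmic_rays(s))))
    corrected <- lapply(proc, function(s)
      arpls_baseline(s, lambda = cfg$arpls_lambda)$corrected)
    groups[[grp]] <- list(
      raw_stats = group_statistics(proc, grp),
      corrected_stats = group_statistics(corrected, grp)
    )
  }
  diff_spec <- difference_spectrum(groups$BN$corrected_stats,
                                   groups$MM$corrected_stats)
  for (grp in c("BN", "MM")) {
    gs <- groups[[grp]]$corrected_stats
    write.table(data.frame(wavenumber = gs$wavenumbers, mean = gs$mean,
                           ci_half_width = gs$ci_half_width),
                file.path(cfg$out_dir, paste0("raman_mean_", grp, ".csv")),
                sep = ",", row.names = FALSE, quote = FALSE)
  }
  write.table(data.frame(wavenumber = diff_spec$wavenumbers,
                         difference = diff_spec$difference,
                         ci_half_width = diff_spec$ci_half_width),
              file.path(cfg$out_dir, "raman_difference.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  raman_report <- list(
    n_per_group = cfg$n_raman,
    ci_points = groups$BN$raw_stats$ci_points,
    mean_background_gap = mean(groups$MM$raw_stats$mean -
                                 groups$BN$raw_stats$mean)
  )
  jsonlite::write_json(raman_report,
                       file.path(cfg$out_dir, "raman_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "manifest.json"]
  manifest <- list(
    config = unclass(cfg),
    outputs = as.list(tools::md5sum(sort(outputs))),
    package_version = as.character(utils::packageVersion("attenuskin")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# JSON-friendly view of a cv_report (deterministic fields only).
cv_report_json <- function(r) {
  list(
    features = r$feature_names,
    fold_accuracies = r$fold_accuracies,
    overall_accuracy = r$overall_accuracy,
    n_correct = r$n_correct, n_total = r$n_total,
    confusion_matrix = as.vector(r$confusion_matrix),
    fold_aucs = r$fold_aucs, mean_auc = r$mean_auc, auc_sd = r$auc_sd,
    weights = as.list(r$weights), bias = r$bias,
    per_sample = r$per_sample
  )
}
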