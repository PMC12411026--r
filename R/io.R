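#' Write a B-scan as delimited text with a metadata header
#'
#' Format: one `#`-prefixed header line of `key=value` pairs
#' (`pixel_spacing`, `label`, `sample_id`), then a comma-separated numeric
#' matrix, rows = depth pixels, columns = A-scans, full float precision.
#'
#' @param bscan an `oct_bscan`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(bscan, path) {
  stopifnot(inherits(bscan, "oct_bscan"))
  header <- sprintf("# pixel_spacing=%s label=%s sample_id=%s",
                    format(attr(bscan, "pixel_spacing"), digits = 17),
                    attr(bscan, "sample_label"), attr(bscan, "sample_id"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(unclass(bscan), 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ",")), con)
  invisible(path)
}

#' Read a B-scan written by [write_bscan()]
#'
#' Malformed input is rejected with the offending line number: ragged rows,
#' non-numeric cells, or a header missing `pixel_spacing`.
#'
#' @param path input file.
#' @return an `oct_bscan`.
#' @export
read_bscan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#"))
    stop("parse error: missing metadata header line", call. = FALSE)
  kv <- strsplit(strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  if (!"pixel_spacing" %in% names(meta))
    stop("parse error: header lacks pixel_spacing", call. = FALSE)
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("parse error: ragged row at line ", bad + 1L, call. = FALSE)
  }
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, function(v) anyNA(v), logical(1)))
  if (length(bad))
    stop("parse error: non-numeric cell at line ", bad[1] + 1L, call. = FALSE)
  m <- do.call(rbind, vals)
  label <- if ("label" %in% names(meta)) meta[["label"]] else "BN"
  structure(m, class = c("oct_bscan", "matrix"),
            pixel_spacing = as.numeric(meta[["pixel_spacing"]]),
            sample_label = label,
            sample_id = if ("sample_id" %in% names(meta))
              meta[["sample_id"]] else "")
}

#' Write a Raman spectrum as two-column delimited text
#'
#' @param s a `raman_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wavenumber_cm-1\tintensity", con)
  writeLines(paste(format(s$wavenumbers, digits = 17, trim = TRUE),
                   format(s$intensities, digits = 17, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a two-column Raman spectrum file
#'
#' Whitespace- or tab-delimited, `#` comment lines tolerated. A descending
#' axis is sorted ascending with a warning; duplicate wavenumbers are an
#' error.
#'
#' @param path input file.
#' @return a `raman_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("wavenumber", "intensity"))
  w <- df$wavenumber
  if (anyDuplicated(w)) stop("duplicate wavenumbers in ", path, call. = FALSE)
  if (is.unsorted(w)) {
    warning("wavenumber axis not ascending; sorting")
    o <- order(w)
    df <- df[o, ]
    w <- df$wavenumber
  }
  raman_spectrum(w, df$intensity, processing_log = paste0("read(", basename(path), ")"))
}

#' Write fit results as CSV
#'
#' @param fits an `oct_fit` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  write.table(as.data.frame(fits), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read fit results written by [write_fits()]
#'
#' @param path input file.
#' @param sample_label,sample_id metadata to attach (optional).
#' @return an `oct_fit` data frame.
#' @export
read_fits <- function(path, sample_label = NULL, sample_id = NULL) {
  df <- read.table(path, header = TRUE, sep = ",")
  structure(df, class = c("oct_fit", "data.frame"),
            sample_label = sample_label, sample_id = sample_id)
}
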