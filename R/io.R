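# Plain-text interchange: long-form spectra CSV + sample metadata, peak
# definitions, peak matrices and report tables (with a config-hash header).

#' Write spectra to long-form CSV
#'
#' One row per grid point: `sample_id`, `tier`, `mz`, `intensity`; sample
#' metadata (`sample_id`, `group`, `age`) goes to a companion file.
#'
#' @param x A `seldi_cohort` or list of `seldi_spectrum`.
#' @param spectra_file,metadata_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_spectra_csv <- function(x, spectra_file, metadata_file) {
  sl <- spectra_list(x)
  long <- do.call(rbind, lapply(sl, function(sp)
    data.frame(sample_id = sp$sample_id, tier = sp$tier, mz = sp$mz,
               intensity = sp$intensity, stringsAsFactors = FALSE)))
  write.csv(long, spectra_file, row.names = FALSE)
  meta <- unique(do.call(rbind, lapply(sl, function(sp)
    data.frame(sample_id = sp$sample_id, group = sp$group, age = sp$age,
               stringsAsFactors = FALSE))))
  write.csv(meta, metadata_file, row.names = FALSE)
  invisible(c(spectra_file, metadata_file))
}

#' Read spectra from long-form CSV
#'
#' Inverse of [write_spectra_csv()].
#'
#' @param spectra_file,metadata_file Paths written by [write_spectra_csv()].
#' @return List of `seldi_spectrum` objects.
#' @export
read_spectra_csv <- function(spectra_file, metadata_file) {
  long <- read.csv(spectra_file, stringsAsFactors = FALSE)
  meta <- read.csv(metadata_file, stringsAsFactors = FALSE)
  need <- c("sample_id", "tier", "mz", "intensity")
  if (!all(need %in% names(long)))
    stop("spectra file must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (key in unique(paste(long$sample_id, long$tier, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sel <- long$sample_id == parts[1L] & long$tier == parts[2L]
    mrow <- meta[match(parts[1L], meta$sample_id), ]
    ord <- order(long$mz[sel])
    out[[length(out) + 1L]] <- new_spectrum(
      long$mz[sel][ord], long$intensity[sel][ord], parts[1L],
      mrow$group, mrow$age, parts[2L])
  }
  out
}

#' Write a peak matrix (and its definitions) to CSV
#'
#' @param pm A `peak_matrix`.
#' @param matrix_file Peaks x samples intensity CSV (first column `peak_id`).
#' @param peaks_file Optional peak-definition CSV.
#' @return Invisibly, the paths written.
#' @export
write_peak_matrix_csv <- function(pm, matrix_file, peaks_file = NULL) {
  df <- data.frame(peak_id = rownames(pm$intensity), pm$intensity,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, matrix_file, row.names = FALSE)
  if (!is.null(peaks_file)) write.csv(pm$peaks, peaks_file, row.names = FALSE)
  invisible(c(matrix_file, peaks_file))
}

#' Read a pre-quantified peak matrix from CSV
#'
#' Accepts a peaks x samples table (first column `peak_id`, remaining columns
#' sample intensities) plus a metadata table, for analyses starting from
#' vendor-exported peak intensities rather than raw spectra.
#'
#' @param matrix_file Intensity CSV.
#' @param metadata_file Metadata CSV (`sample_id`, `group`, `age`).
#' @param peaks_file Optional peak-definition CSV (else minimal definitions
#'   are reconstructed from numeric peak ids).
#' @return A `peak_matrix`.
#' @export
read_peak_matrix_csv <- function(matrix_file, metadata_file, peaks_file = NULL) {
  df <- read.csv(matrix_file, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.csv(metadata_file, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$peak_id
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  peaks <- if (!is.null(peaks_file)) read.csv(peaks_file, stringsAsFactors = FALSE)
  else {
    mz <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", df$peak_id)))
    data.frame(peak_id = df$peak_id, tier = NA_character_, mz = mz,
               lo = mz * 0.997, hi = mz * 1.003, snr = NA_real_,
               stringsAsFactors = FALSE)
  }
  structure(list(intensity = mat, peaks = peaks, samples = meta,
                 missing = which(is.na(mat), arr.ind = TRUE)),
            class = "peak_matrix")
}

# Write a data frame as CSV preceded by '#' header lines (config fingerprint).
write_table_stamped <- function(df, file, header_lines) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  write.csv(df, con, row.names = FALSE)
  invisible(file)
}
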