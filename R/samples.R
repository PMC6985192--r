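#' @keywords internal
luc_bands <- function() c("ndvi", "evi", "nir", "mir")

#' @keywords internal
luc_n_steps <- function() 23L

# Band columns in fixed band-major order: ndvi_1..ndvi_23, evi_1.., nir_1..,
# mir_1..23. This order defines the 92-dimensional feature space.
#' @keywords internal
band_columns <- function() {
  as.vector(vapply(
    luc_bands(),
    function(b) paste(b, seq_len(luc_n_steps()), sep = "_"),
    character(luc_n_steps())
  ))
}

#' @keywords internal
sample_columns <- function() {
  c("longitude", "latitude", "start_date", "end_date", "label", band_columns())
}

#' Validate a tibble of labelled time-series samples
#'
#' A sample is one labelled pixel-year: location, the agricultural-year date
#' span, a training-class label and four 23-step vegetation-index /
#' reflectance series (NDVI, EVI, NIR, MIR) on the physical scale.
#' Validation enforces: all 92 band columns present and finite, NDVI and EVI
#' within \[-1, 1\], and labels drawn from the nine training classes.
#'
#' @param samples A data frame with columns `longitude`, `latitude`,
#'   `start_date`, `end_date`, `label` and `ndvi_1`..`mir_23`.
#' @return The samples as a tibble, invisibly validated; errors name the
#'   first offending row.
#' @export
validate_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  missing <- setdiff(sample_columns(), names(samples))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_label <- !(samples$label %in% training_classes())
  if (any(bad_label)) {
    row <- which(bad_label)[1]
    stop(sprintf("row %d: unknown label '%s'", row, samples$label[row]),
         call. = FALSE)
  }
  vals <- as.matrix(samples[, band_columns()])
  if (nrow(samples) > 0 && !is.numeric(vals)) {
    stop("band columns must be numeric", call. = FALSE)
  }
  nf <- !is.finite(vals)
  if (any(nf)) {
    row <- which(rowSums(nf) > 0)[1]
    stop(sprintf("row %d: non-finite band value", row), call. = FALSE)
  }
  idx_cols <- c(paste0("ndvi_", 1:23), paste0("evi_", 1:23))
  idx <- as.matrix(samples[, idx_cols])
  out_of_range <- abs(idx) > 1
  if (any(out_of_range)) {
    row <- which(rowSums(out_of_range) > 0)[1]
    stop(sprintf("row %d: NDVI/EVI value outside [-1, 1]", row), call. = FALSE)
  }
  samples
}

#' Read and write sample CSV files
#'
#' The CSV dialect is comma-separated UTF-8 with dot decimals and columns
#' `longitude`, `latitude`, `start_date` (ISO-8601), `end_date`, `label`,
#' then `ndvi_1`..`ndvi_23`, `evi_1`.., `nir_1`.., `mir_1`..`mir_23`.
#'
#' @param path File path.
#' @param samples A valid sample tibble (see [validate_samples()]); extra
#'   columns beyond the canonical schema are dropped on write.
#' @return `read_samples_csv()` returns a validated tibble of samples;
#'   `write_samples_csv()` returns `path` invisibly.
#' @export
read_samples_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw$start_date <- as.Date(raw$start_date)
  raw$end_date <- as.Date(raw$end_date)
  validate_samples(raw)
}

#' @rdname read_samples_csv
#' @export
write_samples_csv <- function(samples, path) {
  samples <- validate_samples(samples)
  readr::write_csv(samples[, sample_columns()], path, progress = FALSE)
  invisible(path)
}

#' Build the 92-dimensional feature matrix
#'
#' Each sample's four 23-step series are concatenated band-major
#' (NDVI 1..23, EVI 1..23, NIR 1..23, MIR 1..23) into one 92-dimensional
#' feature vector, the representation used by both the SOM quality control
#' and the SVM classifier. No rescaling or standardization is applied: values
#' stay on the physical index/reflectance scale, which is what makes the RBF
#' width default gamma = 1/92 meaningful.
#'
#' @param samples A valid sample tibble.
#' @return A numeric matrix with one row per sample and 92 columns.
#' @export
sample_features <- function(samples) {
  samples <- validate_samples(samples)
  m <- as.matrix(samples[, band_columns()])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

#' @rdname sample_features
#' @param sample A single sample (one-row data frame).
#' @return `build_feature_vector()` returns a numeric vector of length 92.
#' @export
build_feature_vector <- function(sample) {
  if (nrow(sample) != 1) stop("expected exactly one sample row", call. = FALSE)
  unname(drop(sample_features(sample)))
}
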