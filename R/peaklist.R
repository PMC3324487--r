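#' Construct a peak-list sample
#'
#' A `peak_sample` holds one urine sample's deconvoluted CE-MS feature list.
#' Each feature is characterised by its molecular mass (Da), CE migration
#' time (min) and signal intensity (arbitrary units). Charge-state
#' deconvolution is upstream of this package; inputs are already single-mass
#' peak lists.
#'
#' @param sample_id character scalar identifying the sample.
#' @param features data.frame with columns `mass_da`, `time_min`,
#'   `intensity`. Masses and times must be positive, intensities
#'   non-negative, and no two features may share an identical
#'   (mass, time) pair.
#' @param calibrated logical; whether mass/time/intensity calibration has
#'   been applied. Matching refuses uncalibrated samples.
#' @return an object of class `peak_sample`.
#' @export
peak_sample <- function(sample_id, features, calibrated = FALSE) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  features <- as.data.frame(features)
  req <- c("mass_da", "time_min", "intensity")
  if (!all(req %in% names(features))) {
    stop("features must have columns mass_da, time_min, intensity")
  }
  features <- features[, req]
  if (nrow(features) > 0) {
    if (any(features$mass_da <= 0)) stop("masses must be > 0")
    if (any(features$time_min <= 0)) stop("times must be > 0")
    if (any(features$intensity < 0)) stop("intensities must be >= 0")
    if (anyDuplicated(features[, c("mass_da", "time_min")])) {
      stop("duplicate (mass, time) pairs in sample ", sample_id)
    }
  }
  structure(
    list(sample_id = sample_id, features = features,
         calibrated = isTRUE(calibrated)),
    class = "peak_sample"
  )
}

#' @export
print.peak_sample <- function(x, ...) {
  cat(sprintf("<peak_sample> %s: %d features (%scalibrated)\n",
              x$sample_id, nrow(x$features),
              if (x$calibrated) "" else "un"))
  invisible(x)
}

#' Read / write a peak list as tab-separated text
#'
#' The on-disk format is a TSV with header `mass_da  time_min  intensity`,
#' one row per feature. The sample id defaults to the file name without
#' extension.
#'
#' @param path file path.
#' @param sample_id optional sample id override.
#' @param calibrated whether the stored list is calibrated.
#' @return `read_peak_list` returns a [peak_sample()].
#' @export
read_peak_list <- function(path, sample_id = NULL, calibrated = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#")
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  peak_sample(sample_id, df, calibrated = calibrated)
}

#' @param sample a [peak_sample()].
#' @rdname read_peak_list
#' @export
write_peak_list <- function(sample, path) {
  stopifnot(inherits(sample, "peak_sample"))
  utils::write.table(sample$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort design table
#'
#' The design table links samples to animals, compound, dose (mg/kg),
#' collection day and group label, one row per sample.
#'
#' @param path CSV file path.
#' @return `read_design` returns a data.frame with columns `sample_id`,
#'   `animal_id`, `compound`, `dose_mg_kg`, `day`, `group`.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "animal_id", "compound", "dose_mg_kg", "day", "group")
  if (!all(req %in% names(df))) {
    stop("design table must have columns ", paste(req, collapse = ", "))
  }
  df
}

#' @param design a design data.frame.
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
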