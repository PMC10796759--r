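#' Read a CT volume from NIfTI or a DICOM series
#'
#' NIfTI-1 files are read through RNifti; only axis-aligned orientations (a
#' diagonal, positive xform) are supported — oblique orientations raise an
#' error. DICOM input is a directory containing a single uncompressed
#' explicit-VR little-endian series, one slice per file; slices are sorted by
#' their along-axis position, uniform slice gaps are enforced, and the rescale
#' slope/intercept is applied so values are HU.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or a DICOM series directory.
#' @param format `"nifti"` or `"dicom_series"`; guessed from `path` when
#'   `"auto"` (directory implies DICOM).
#' @return A [ct_volume()].
#' @seealso [write_ct_volume()]
#' @export
read_ct_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (!file.exists(path))
    rlang::abort(sprintf("path does not exist: %s", path))
  if (format == "dicom_series") return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (attr(xf, "code") == 0) {
    spacing <- RNifti::pixdim(img)
    origin <- c(0, 0, 0)
  } else {
    if (max(abs(rot - diag(diag(rot)))) > 1e-6 || any(diag(rot) <= 0))
      rlang::abort("oblique or flipped NIfTI orientation is not supported")
    spacing <- diag(rot)
    origin <- xf[1:3, 4]
  }
  ct_volume(img[, , , drop = FALSE], spacing = spacing, origin = origin)
}

#' Write a CT volume
#'
#' NIfTI output stores the array as float64 with a diagonal sform/qform built
#' from spacing and origin, so a write/read roundtrip is bit-exact. DICOM
#' output writes one uncompressed int16 slice per file (values are rounded to
#' the nearest HU before applying the inverse rescale).
#'
#' @param volume A [ct_volume()].
#' @param path Output `.nii` file, or directory for `format = "dicom_series"`.
#' @param format `"nifti"` (default) or `"dicom_series"`.
#' @param rescale_intercept,rescale_slope DICOM rescale tags (stored value
#'   `v` maps to HU as `slope * v + intercept`).
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path, format = c("nifti", "dicom_series"),
                            rescale_intercept = -1024, rescale_slope = 1) {
  stopifnot(inherits(volume, "ct_volume"))
  format <- match.arg(format)
  if (format == "dicom_series")
    return(write_dicom_series(volume, path, rescale_intercept, rescale_slope))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a drilling force trace
#'
#' Reads a CSV with columns `time_s` and `force_N`. The time grid must be
#' strictly increasing and uniform; the sampling rate is taken from the grid
#' (or validated against `sample_rate` if supplied).
#'
#' @param path CSV file path.
#' @param sample_rate Expected sampling rate in Hz, or `NULL` to infer.
#' @param feed_velocity Constant feed velocity of the drill in mm/s
#'   (default 2).
#' @return A `force_trace`: tibble with columns `time_s`, `force_N` and
#'   attributes `sample_rate` (Hz) and `feed_velocity` (mm/s).
#' @export
read_force_trace <- function(path, sample_rate = NULL, feed_velocity = 2) {
  if (!file.exists(path))
    rlang::abort(sprintf("path does not exist: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("time_s", "force_N") %in% names(df)))
    rlang::abort("force trace CSV must have columns time_s and force_N")
  force_trace(df$time_s, df$force_N, sample_rate = sample_rate,
              feed_velocity = feed_velocity)
}

#' Construct a force trace
#'
#' @param time_s Sample times in seconds (uniform, strictly increasing).
#' @param force_N Axial force in Newton.
#' @param sample_rate Hz; inferred from `time_s` when `NULL`.
#' @param feed_velocity mm/s.
#' @return A `force_trace` tibble.
#' @export
force_trace <- function(time_s, force_N, sample_rate = NULL,
                        feed_velocity = 2) {
  if (length(time_s) < 2L || length(time_s) != length(force_N))
    rlang::abort("a force trace needs >= 2 samples of equal length")
  if (any(!is.finite(time_s)) || any(!is.finite(force_N)))
    rlang::abort("force trace values must be finite")
  dt <- diff(time_s)
  if (any(dt <= 0))
    rlang::abort("non-uniform sampling: time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    rlang::abort("non-uniform sampling: time grid is not uniform")
  rate <- 1 / stats::median(dt)
  if (!is.null(sample_rate) && abs(rate - sample_rate) > 1e-6 * sample_rate)
    rlang::abort(sprintf("time grid implies %.6g Hz, not the declared %g Hz",
                         rate, sample_rate))
  if (feed_velocity <= 0) rlang::abort("`feed_velocity` must be > 0")
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        force_N = as.numeric(force_N))
  attr(out, "sample_rate") <- rate
  attr(out, "feed_velocity") <- feed_velocity
  class(out) <- c("force_trace", class(out))
  out
}

#' Write a force trace to CSV
#'
#' Values are written with 17 significant digits so a read/write roundtrip
#' preserves the force to full double precision.
#'
#' @param trace A [force_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_force_trace <- function(trace, path) {
  df <- data.frame(time_s = sprintf("%.17g", trace$time_s),
                   force_N = sprintf("%.17g", trace$force_N))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specimen metadata
#'
#' @param individual Donor label (e.g. `"A"`).
#' @param region Vertebral region, `"T"` (thoracic) or `"L"` (lumbar).
#' @param level Vertebral level label (e.g. `"T11"`, `"L5"`); its prefix must
#'   match `region`.
#' @return A named list of class `specimen_meta`.
#' @export
specimen_meta <- function(individual, region, level) {
  region <- match.arg(region, c("T", "L"))
  if (!startsWith(level, region))
    rlang::abort(sprintf("level '%s' inconsistent with region '%s'",
                         level, region))
  structure(list(individual = individual, region = region, level = level),
            class = "specimen_meta")
}

#' Write a correlation results table
#'
#' Writes the grouped correlation table (one row per specimen or pooled group)
#' as CSV and/or JSON. JSON is written with full numeric precision so it parses
#' back to identical values.
#'
#' @param results Tibble of correlation results, e.g. from
#'   [grouped_correlations()].
#' @param csv,json Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, csv = NULL, json = NULL) {
  if (!is.data.frame(results) || nrow(results) == 0)
    rlang::abort("`results` must be a non-empty data frame")
  if (is.null(csv) && is.null(json))
    rlang::abort("supply at least one of `csv`, `json`")
  if (!is.null(csv))
    utils::write.csv(as.data.frame(results), csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(results, json, dataframe = "rows", digits = NA,
                         na = "null")
  invisible(c(csv = csv, json = json))
}

#' Read back a correlation results table written as JSON
#'
#' @param path JSON path written by [write_results()].
#' @return Tibble of correlation results.
#' @export
read_results <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}
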