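# B-scan containers and file I/O: multi-page TIFF + JSON sidecar for image
# series, CSV for time courses, PNG for SV-structure overlays.

#' Construct a single B-scan
#'
#' A B-scan is a 2-D cross-sectional OCT intensity image with rows indexing
#' depth (z, increasing downward) and columns indexing the transverse
#' direction (x). Intensities are normalized to `[0, 1]`.
#'
#' @param intensity numeric matrix `[z, x]` with finite values in `[0, 1]`.
#' @param pixel_dz_um,pixel_dx_um axial / transverse pixel pitch in microns.
#' @param timestamp_s acquisition time in seconds relative to drug
#'   application (negative = pre-application).
#' @return An object of class `bscan`.
#' @export
bscan <- function(intensity, pixel_dz_um, pixel_dx_um, timestamp_s = 0) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("'intensity' must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(intensity))) stop("intensity contains non-finite values", call. = FALSE)
  stopifnot_scalar(pixel_dz_um, "pixel_dz_um")
  stopifnot_scalar(pixel_dx_um, "pixel_dx_um")
  structure(
    list(intensity = intensity, pixel_dz_um = pixel_dz_um,
         pixel_dx_um = pixel_dx_um, timestamp_s = timestamp_s),
    class = "bscan"
  )
}

#' Construct a B-scan series
#'
#' An ordered stack of equally shaped B-scans with strictly increasing
#' timestamps and a designated reference frame (the frame acquired at drug
#' application, timestamp 0 within one frame interval).
#'
#' @param frames list of numeric matrices `[z, x]`, all the same shape.
#' @param pixel_dz_um,pixel_dx_um pixel pitch in microns.
#' @param timestamps_s numeric vector, seconds relative to drug application.
#' @param reference_index 1-based index of the reference frame.
#' @param metadata named list of free-form provenance (preset, seed, ...).
#' @return An object of class `bscan_series`.
#' @export
bscan_series <- function(frames, pixel_dz_um, pixel_dx_um, timestamps_s,
                         reference_index, metadata = list()) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("'frames' must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims)) {
      stop("all frames must be matrices of identical shape", call. = FALSE)
    }
  }
  if (length(timestamps_s) != length(frames)) {
    stop("one timestamp per frame required", call. = FALSE)
  }
  if (any(diff(timestamps_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(frames)) {
    stop("'reference_index' out of range", call. = FALSE)
  }
  dt <- if (length(timestamps_s) > 1L) stats::median(diff(timestamps_s)) else Inf
  if (abs(timestamps_s[reference_index]) > dt + 1e-9) {
    stop("reference frame must sit at t = 0 within one frame interval", call. = FALSE)
  }
  structure(
    list(frames = frames, pixel_dz_um = pixel_dz_um, pixel_dx_um = pixel_dx_um,
         timestamps_s = as.numeric(timestamps_s),
         reference_index = reference_index, metadata = metadata),
    class = "bscan_series"
  )
}

#' @export
print.bscan_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<bscan_series> %d frames of %d x %d px (%.3g x %.3g um), t = [%.3g, %.3g] s, reference #%d\n",
    length(x$frames), d[1], d[2], x$pixel_dz_um, x$pixel_dx_um,
    min(x$timestamps_s), max(x$timestamps_s), x$reference_index))
  invisible(x)
}

#' Number of frames in a series
#' @param series a `bscan_series`.
#' @return integer frame count.
#' @export
n_frames <- function(series) length(series$frames)

#' Extract one frame as a `bscan`
#' @param series a `bscan_series`.
#' @param i frame index.
#' @return a `bscan`.
#' @export
get_bscan <- function(series, i) {
  bscan(series$frames[[i]], series$pixel_dz_um, series$pixel_dx_um,
        series$timestamps_s[i])
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a B-scan series to multi-page TIFF with a JSON sidecar
#'
#' Intensities are quantized to 16 bit over the stated dynamic-range window
#' (default `[0, 1]`); the sidecar records pixel spacings, timestamps, the
#' reference index, the window and any metadata so reading back is exact up
#' to quantization.
#'
#' @param series a `bscan_series`.
#' @param path output TIFF path (sidecar takes the same stem + `.json`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "bscan_series")) stop("not a bscan_series", call. = FALSE)
  if (length(series$frames) == 0L) stop("empty series", call. = FALSE)
  window <- c(0, 1)
  pages <- lapply(series$frames, function(f) {
    q <- (f - window[1]) / diff(window)
    pmin(pmax(q, 0), 1)
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) stop("could not write TIFF at ", path, call. = FALSE)
  side <- list(
    pixel_dz_um = series$pixel_dz_um,
    pixel_dx_um = series$pixel_dx_um,
    timestamps_s = series$timestamps_s,
    reference_index = series$reference_index,
    window = window,
    metadata = series$metadata
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a B-scan series written by [write_series()]
#'
#' @param path TIFF path; the JSON sidecar with the same stem must exist.
#' @return a `bscan_series` with intensities rescaled to `[0, 1]` by the
#'   sidecar's dynamic-range window.
#' @export
read_series <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("missing metadata: sidecar ", sp, " not found", call. = FALSE)
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- dim(pages[[1]])
  for (p in pages) {
    if (!identical(dim(p), dims)) stop("shape mismatch between TIFF pages", call. = FALSE)
  }
  window <- as.numeric(side$window)
  frames <- lapply(pages, function(p) {
    pmin(pmax(p * diff(window) + window[1], 0), 1)
  })
  meta <- side$metadata
  if (is.null(meta)) meta <- list()
  bscan_series(frames, side$pixel_dz_um, side$pixel_dx_um,
               as.numeric(side$timestamps_s), side$reference_index, meta)
}

#' Write a diffusion time course to CSV
#'
#' One row per (time, region) with columns `time_s, region_label,
#' mean_sv_sum, sd_sv_sum, com_depth_um`. Undefined center-of-mass entries
#' (frames with zero total SV) are written as empty cells.
#'
#' @param tc a `time_course` (see [roi_timecourse()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  if (!inherits(tc, "time_course")) stop("not a time_course", call. = FALSE)
  df <- tc$summary
  df$com_depth_um <- tc$com_depth_um[match(df$time_s, tc$times_s)]
  df <- df[, c("time_s", "region_label", "mean_sv_sum", "sd_sv_sum", "com_depth_um")]
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double",
                     na = "")
  invisible(path)
}

#' Merge structure and speckle variance into an overlay PNG
#'
#' Structural intensity is rendered in gray scale; suprathreshold SV is
#' alpha-blended on top in a red scale, the convention used for SV-OCT
#' display.
#'
#' @param bscan a `bscan` or numeric matrix (structure).
#' @param sv an `sv_image` or numeric matrix (same shape).
#' @param path output PNG path.
#' @param sv_scale SV value mapped to full red; defaults to `max(sv)`.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(bscan, sv, path, sv_scale = NULL) {
  gray <- if (inherits(bscan, "bscan")) bscan$intensity else bscan
  svm <- if (inherits(sv, "sv_image")) sv$sv else sv
  if (!identical(dim(gray), dim(svm))) stop("shape mismatch", call. = FALSE)
  if (is.null(sv_scale)) sv_scale <- max(svm)
  w <- if (sv_scale > 0) pmin(svm / sv_scale, 1) else svm * 0
  gray <- pmin(pmax(gray, 0), 1)
  rgb <- array(0, dim = c(nrow(gray), ncol(gray), 3))
  rgb[, , 1] <- gray * (1 - w) + w
  rgb[, , 2] <- gray * (1 - w)
  rgb[, , 3] <- gray * (1 - w)
  png::writePNG(rgb, path)
  invisible(path)
}
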