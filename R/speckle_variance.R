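# Reference-frame speckle variance (SV), depth-cumulative shadow
# correction, noise-floor thresholding, and the per-series SV stack.
#
# SV is computed between the reference frame (acquired at drug application)
# and each later frame on normalized linear intensity: for pixel values
# a and b with m = (a + b) / 2,
#   SV = sqrt( ((a - m)^2 + (b - m)^2) / 2 ) = |a - b| / 2.
# The shadow-corrected variant multiplies SV by
# exp(sign * (1/gamma) * cumulative column sum of SV down to the pixel).

new_sv_image <- function(sv, stage, timestamp_s = NA_real_,
                         reference_timestamp_s = NA_real_, gamma = NA_real_,
                         exponent_sign = NA_real_, threshold = NA_real_) {
  structure(list(sv = sv, stage = stage, timestamp_s = timestamp_s,
                 reference_timestamp_s = reference_timestamp_s,
                 gamma = gamma, exponent_sign = exponent_sign,
                 threshold = threshold),
            class = "sv_image")
}

#' @export
print.sv_image <- function(x, ...) {
  cat(sprintf("<sv_image> %d x %d px, stage = %s, t = %.3g s (ref %.3g s)\n",
              nrow(x$sv), ncol(x$sv), x$stage, x$timestamp_s,
              x$reference_timestamp_s))
  if (!is.na(x$gamma)) cat(sprintf("  gamma = %.4g, sign = %+d\n", x$gamma,
                                   as.integer(x$exponent_sign)))
  if (!is.na(x$threshold)) cat(sprintf("  threshold = %.4g\n", x$threshold))
  invisible(x)
}

#' Shadow-correction parameters
#'
#' @param gamma attenuation coefficient (> 0) of the depth-cumulative
#'   exponent, or `"auto"` to derive it per frame as
#'   `auto_scale` x the median (over columns) depth-integrated raw SV.
#' @param exponent_sign `+1` (amplifying, as typeset in the SV revision) or
#'   `-1` (attenuating).
#' @param cap maximum amplification factor applied to any pixel (>= 1).
#' @param auto_scale multiplier for the automatic gamma.
#' @return An object of class `shadow_params`.
#' @export
shadow_params <- function(gamma = "auto", exponent_sign = +1,
                          cap = exp(3), auto_scale = 10) {
  if (!identical(gamma, "auto")) {
    stopifnot_scalar(gamma, "gamma")
  }
  if (!exponent_sign %in% c(-1, 1)) stop("exponent_sign must be +1 or -1",
                                         call. = FALSE)
  if (cap < 1) stop("cap must be >= 1", call. = FALSE)
  structure(list(gamma = gamma, exponent_sign = exponent_sign, cap = cap,
                 auto_scale = auto_scale),
            class = "shadow_params")
}

#' Compute a raw SV image against the reference frame
#'
#' @param reference,frame `bscan` objects or matrices of identical shape,
#'   surface-realigned, intensities in `[0, 1]`.
#' @return An `sv_image` with `stage = "raw"`.
#' @export
compute_sv <- function(reference, frame) {
  a <- as_intensity(reference)
  b <- as_intensity(frame)
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  sv <- abs(a - b) / 2
  new_sv_image(sv, "raw",
               timestamp_s = if (inherits(frame, "bscan")) frame$timestamp_s else NA_real_,
               reference_timestamp_s = if (inherits(reference, "bscan"))
                 reference$timestamp_s else NA_real_)
}

resolve_gamma <- function(sv, params) {
  if (!identical(params$gamma, "auto")) return(params$gamma)
  colsum <- colSums(sv)
  g <- params$auto_scale * stats::median(colsum)
  if (!is.finite(g) || g <= 0) g <- 1
  g
}

#' Apply the depth-cumulative shadow correction
#'
#' `SVR(x, z) = SV(x, z) * exp(sign * (1/gamma) * sum_{i<=z} SV(x, i))`,
#' with the cumulative sum taken down each column inclusive of the pixel's
#' own row; the multiplicative factor is capped at `params$cap`.
#'
#' @param sv a raw `sv_image`.
#' @param params a [shadow_params()].
#' @return An `sv_image` with `stage = "shadow_corrected"` recording the
#'   gamma and sign used.
#' @export
shadow_correct <- function(sv, params = shadow_params()) {
  if (!inherits(sv, "sv_image") || sv$stage != "raw") {
    stop("shadow_correct expects a raw sv_image", call. = FALSE)
  }
  g <- resolve_gamma(sv$sv, params)
  if (g <= 0) stop("gamma must be > 0", call. = FALSE)
  cum <- apply(sv$sv, 2, cumsum)
  fac <- exp(params$exponent_sign * cum / g)
  fac <- pmin(fac, params$cap)
  out <- new_sv_image(sv$sv * fac, "shadow_corrected",
                      timestamp_s = sv$timestamp_s,
                      reference_timestamp_s = sv$reference_timestamp_s,
                      gamma = g, exponent_sign = params$exponent_sign)
  out
}

#' Estimate the SV noise-floor threshold from pre-application frames
#'
#' The speckle-noise floor is estimated from the SV of frames acquired
#' before the drug application against the reference frame. Policy
#' `"paper_fixed"` uses the fixed value 0.05 on normalized intensity;
#' `"percentile"` returns the chosen percentile of the pooled raw
#' pre-application SV values.
#'
#' @param pre_series a `bscan_series` (its pre-application frames, t < 0,
#'   are used; the reference frame is the comparison target).
#' @param policy `"paper_fixed"` or `"percentile"`.
#' @param probs percentile for the `"percentile"` policy.
#' @param mask optional `nail_mask`; restricts the pooled pixels.
#' @param shadow optional [shadow_params()]; when given, the pre-application
#'   SV is shadow-corrected before pooling, so the threshold is estimated on
#'   the same quantity it is later applied to.
#' @return scalar threshold.
#' @export
estimate_noise_threshold <- function(pre_series,
                                     policy = c("paper_fixed", "percentile"),
                                     probs = 0.99, mask = NULL, shadow = NULL) {
  policy <- match.arg(policy)
  if (policy == "paper_fixed") return(0.05)
  pre_idx <- which(pre_series$timestamps_s < 0)
  if (length(pre_idx) < 2L) {
    stop("percentile policy needs >= 2 pre-application frames", call. = FALSE)
  }
  ref <- get_bscan(pre_series, pre_series$reference_index)
  pool <- unlist(lapply(pre_idx, function(i) {
    sv <- compute_sv(ref, get_bscan(pre_series, i))
    if (!is.null(shadow)) sv <- shadow_correct(sv, shadow)
    if (!is.null(mask)) sv$sv[mask$plate] else as.numeric(sv$sv)
  }))
  as.numeric(stats::quantile(pool, probs, names = FALSE))
}

#' Threshold an SV image and restrict it to the nail structure
#'
#' SV is set to zero where it falls below the noise-floor threshold or
#' outside the nail-plate mask (only SV inside the nail structure is
#' reported; sub-bed blood-flow signal is excluded by the mask).
#'
#' @param sv an `sv_image`.
#' @param threshold scalar >= 0.
#' @param mask a `nail_mask`, or `NULL` for no spatial restriction.
#' @return An `sv_image` with `stage = "thresholded"`.
#' @export
apply_threshold <- function(sv, threshold, mask = NULL) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  m <- sv$sv
  if (!is.null(mask)) {
    if (!identical(dim(mask$plate), dim(m))) stop("mask shape mismatch", call. = FALSE)
    m[!mask$plate] <- 0
  }
  m[m < threshold] <- 0
  out <- new_sv_image(m, "thresholded", timestamp_s = sv$timestamp_s,
                      reference_timestamp_s = sv$reference_timestamp_s,
                      gamma = sv$gamma, exponent_sign = sv$exponent_sign,
                      threshold = threshold)
  out
}

#' Compute the SV stack for a realigned series
#'
#' For each selected frame: raw SV against the reference, shadow
#' correction, then noise-floor thresholding within the mask.
#' Post-application frames (t > 0, excluding the reference itself) are
#' processed by default; `frames = "pre"` processes the pre-application
#' frames instead (used for baselines).
#'
#' @param series a realigned `bscan_series`.
#' @param params a [shadow_params()].
#' @param mask a `nail_mask` or `NULL`.
#' @param threshold scalar noise floor (see [estimate_noise_threshold()]).
#' @param frames `"post"` or `"pre"`.
#' @return list of `sv_image` (stage `"thresholded"`), one per frame.
#' @export
sv_series <- function(series, params = shadow_params(), mask = NULL,
                      threshold = 0.05, frames = c("post", "pre")) {
  frames <- match.arg(frames)
  idx <- if (frames == "post") {
    which(series$timestamps_s > 0 & seq_along(series$frames) != series$reference_index)
  } else {
    which(series$timestamps_s < 0)
  }
  ref <- get_bscan(series, series$reference_index)
  lapply(idx, function(i) {
    sv <- compute_sv(ref, get_bscan(series, i))
    sv <- shadow_correct(sv, params)
    apply_threshold(sv, threshold, mask)
  })
}
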