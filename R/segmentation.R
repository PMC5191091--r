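# Nail-surface detection per A-scan, axial realignment of a time series to
# the reference surface, nail-bed delimitation, plate/MAZ masking, and
# averaged A-scan profiles.

as_intensity <- function(x) {
  if (inherits(x, "bscan")) x$intensity else if (is.matrix(x)) x else
    stop("expected a bscan or a matrix", call. = FALSE)
}

#' Detect the nail surface on a B-scan
#'
#' Per column, the surface is the first row where the axially smoothed
#' A-scan exceeds an adaptive threshold (a fraction of the Otsu threshold of
#' the whole frame), refined to the strongest local intensity rise and
#' required to have gradient prominence at least `min_prominence`. Columns
#' with no qualifying crossing are interpolated from their neighbours and
#' flagged invalid. The profile is median-filtered across columns.
#'
#' The defaults (no axial smoothing, a low fraction of the Otsu threshold)
#' exploit the near-zero background above the air/nail interface: the first
#' suprathreshold pixel of the raw A-scan locates the surface to within one
#' pixel even under fully developed speckle, and the cross-column median
#' removes isolated dark-speckle misses.
#'
#' @param x a `bscan` or numeric matrix, intensities in `[0, 1]`.
#' @param min_prominence minimum axial intensity rise at the surface.
#' @param smooth_window cross-column median window (odd, default 7).
#' @param axial_smooth axial moving-average window (pixels; 1 = none).
#' @param threshold_frac fraction of the frame's Otsu threshold used for the
#'   first-crossing test.
#' @return A `surface_profile`: integer `row` per column and a logical
#'   `valid` flag per column.
#' @export
detect_surface <- function(x, min_prominence = 0.005, smooth_window = 7,
                           axial_smooth = 1, threshold_frac = 0.1) {
  img <- as_intensity(x)
  nz <- nrow(img); nx <- ncol(img)
  if (max(img) <= 0) stop("no surface found: image is empty", call. = FALSE)
  thr <- EBImage::otsu(img, range = c(0, 1)) * threshold_frac
  rows <- rep(NA_real_, nx)
  for (j in seq_len(nx)) {
    prof <- if (axial_smooth > 1L) running_mean(img[, j], axial_smooth) else img[, j]
    idx <- which(prof >= thr)
    if (length(idx) == 0L) next
    cand <- idx[1]
    rise <- prof[cand] - if (cand > 1L) prof[cand - 1L] else 0
    if (rise < min_prominence) next
    rows[j] <- cand
  }
  valid <- !is.na(rows)
  if (!any(valid)) stop("no surface found", call. = FALSE)
  if (any(!valid)) {
    rows[!valid] <- round(stats::approx(which(valid), rows[valid],
                                        xout = which(!valid), rule = 2)$y)
  }
  rows <- round(median_smooth(rows, smooth_window))
  rows <- pmin(pmax(rows, 1L), nz)
  structure(list(row = as.integer(rows), valid = valid),
            class = "surface_profile")
}

#' Realign a series to the reference nail surface
#'
#' Shifts each frame axially by integer pixels (per column, or one global
#' shift) so its detected surface coincides with the reference surface.
#' This removes the redundant optical path introduced by the drug film and
#' bulk axial motion. Vacated pixels are zero-filled. Frames requiring a
#' shift beyond `max_shift_frac` of the image depth are flagged
#' motion-corrupted (shift capped).
#'
#' @param series a `bscan_series`.
#' @param reference_surface a `surface_profile` for the reference frame;
#'   detected from the reference frame when `NULL`.
#' @param mode `"per_column"` or `"global"` (median shift across columns).
#' @param max_shift_frac cap on |shift| as a fraction of image depth.
#' @param shift_smooth_window cross-column median window applied to the
#'   per-column shift field; suppresses isolated surface-detection misses
#'   (a wrongly shifted column would decorrelate its whole A-scan).
#' @param ... passed to [detect_surface()].
#' @return A `bscan_series`; `metadata$motion_corrupted` flags frames whose
#'   required shift exceeded the cap, `metadata$applied_shift_px` records
#'   the per-frame median shift.
#' @export
realign_series <- function(series, reference_surface = NULL,
                           mode = c("per_column", "global"),
                           max_shift_frac = 0.25, shift_smooth_window = 9,
                           ...) {
  mode <- match.arg(mode)
  nz <- nrow(series$frames[[1]])
  cap <- floor(nz * max_shift_frac)
  if (is.null(reference_surface)) {
    reference_surface <- detect_surface(series$frames[[series$reference_index]], ...)
  }
  ref_row <- reference_surface$row
  flagged <- logical(n_frames(series))
  applied <- integer(n_frames(series))
  frames <- series$frames
  for (i in seq_len(n_frames(series))) {
    surf <- detect_surface(frames[[i]], ...)
    d <- ref_row - surf$row                    # positive = shift frame down
    if (mode == "global") {
      d <- rep(as.integer(round(stats::median(d))), length(d))
    } else {
      # crater (MAZ aperture) columns give unreliable surface fixes; the
      # nail moves rigidly, so take their shifts from the intact flanks
      bad <- bridge_surface(ref_row)$crater | bridge_surface(surf$row)$crater
      if (any(bad) && any(!bad)) {
        d[bad] <- round(stats::approx(which(!bad), d[!bad], xout = which(bad),
                                      rule = 2)$y)
      }
      d <- as.integer(round(median_smooth(d, shift_smooth_window)))
    }
    if (max(abs(d)) > cap) {
      flagged[i] <- TRUE
      d <- pmin(pmax(d, -cap), cap)
    }
    applied[i] <- as.integer(round(stats::median(d)))
    if (any(d != 0L)) {
      f <- frames[[i]]
      for (j in which(d != 0L)) f[, j] <- shift_vec(f[, j], d[j])
      frames[[i]] <- f
    }
  }
  meta <- series$metadata
  meta$motion_corrupted <- flagged
  meta$applied_shift_px <- applied
  bscan_series(frames, series$pixel_dz_um, series$pixel_dx_um,
               series$timestamps_s, series$reference_index, meta)
}

#' Detect the nail-bed boundary
#'
#' The plate/bed boundary is placed at the strongest negative axial
#' intensity gradient within `expected_thickness_um +/- tolerance_um` below
#' the surface. Deep speckle fluctuations rival the layer step in a single
#' A-scan, so the search proceeds in two stages: the cross-column median
#' depth profile (surface-referenced) fixes the global boundary depth, and
#' each column is then refined within a few pixels of it, median-filtered
#' across columns. Columns with no negative gradient near the global
#' boundary fall back to it and are flagged.
#'
#' @param x a `bscan` or matrix.
#' @param surface a `surface_profile`.
#' @param expected_thickness_um prior nail-plate thickness.
#' @param tolerance_um half-width of the search window.
#' @param pixel_dz_um axial pitch (taken from `x` when it is a `bscan`).
#' @param smooth_window cross-column median window.
#' @param transverse_smooth columns averaged before the gradient search;
#'   single-column speckle gradients otherwise swamp the layer step.
#' @return list with integer `row` per column and logical `fallback` flags.
#' @export
detect_nail_bed <- function(x, surface, expected_thickness_um = 600,
                            tolerance_um = 150, pixel_dz_um = NULL,
                            smooth_window = 7, transverse_smooth = 7) {
  img <- as_intensity(x)
  if (is.null(pixel_dz_um)) {
    if (!inherits(x, "bscan")) stop("pixel_dz_um required for plain matrices",
                                    call. = FALSE)
    pixel_dz_um <- x$pixel_dz_um
  }
  nz <- nrow(img); nx <- ncol(img)
  exp_px <- round(expected_thickness_um / pixel_dz_um)
  tol_px <- round(tolerance_um / pixel_dz_um)
  if (all(surface$row + exp_px - tol_px > nz)) {
    stop("expected nail-bed window lies outside the image", call. = FALSE)
  }
  if (transverse_smooth > 1L) {
    img <- t(apply(img, 1, running_mean, k = transverse_smooth))
  }

  # stage 1: global boundary depth from the surface-referenced median profile
  d_lo <- max(exp_px - tol_px, 2L); d_hi <- exp_px + tol_px
  depth_profile <- vapply(seq_len(d_hi + 2L), function(d) {
    rr <- surface$row + d - 1L
    ok <- rr >= 1L & rr <= nz
    if (!any(ok)) return(NA_real_)
    stats::median(img[cbind(rr[ok], which(ok))])
  }, numeric(1))
  dp <- ifelse(is.finite(depth_profile), depth_profile, 0)
  dg <- diff(dp)
  cand <- d_lo:min(d_hi, length(dg))
  if (all(!is.finite(dg[cand])) || min(dg[cand], na.rm = TRUE) >= 0) {
    d_star <- exp_px
  } else {
    d_star <- cand[which.min(dg[cand])] + 1L   # first bed depth offset
  }

  # stage 2: per-column refinement around the global boundary
  rows <- integer(nx); fallback <- logical(nx)
  for (j in seq_len(nx)) {
    lo <- max(surface$row[j] + d_star - 3L, 2L)
    hi <- min(surface$row[j] + d_star, nz - 1L)
    if (lo > hi) { rows[j] <- min(surface$row[j] + d_star, nz); fallback[j] <- TRUE; next }
    prof <- running_mean(img[, j], 3L)
    g <- prof[(lo:hi) + 1L] - prof[lo:hi]      # forward gradient at row r
    k <- which.min(g)
    if (length(k) == 0L || g[k] >= 0) {
      rows[j] <- min(surface$row[j] + d_star, nz); fallback[j] <- TRUE
    } else {
      rows[j] <- (lo:hi)[k] + 1L               # first bed row
    }
  }
  rows <- as.integer(round(median_smooth(rows, smooth_window)))
  list(row = pmin(pmax(rows, 1L), nz), fallback = fallback)
}

#' Build the nail-plate mask
#'
#' The plate mask spans surface to nail-bed boundary per column. MAZ
#' interiors are removed under `policy = "exclude_maz"` (liquid experiment,
#' where ablated voids stay empty) and retained under `"include_maz"`
#' (cream experiment, where the MAZs are filled with drug).
#'
#' @param surface a `surface_profile`.
#' @param bed_boundary per-column first bed row (vector or the list from
#'   [detect_nail_bed()]).
#' @param maz_mask logical matrix of MAZ interiors (or `NULL` for none).
#' @param policy `"exclude_maz"` or `"include_maz"`.
#' @param dim image dimensions `c(nz, nx)` (required when `maz_mask` is
#'   `NULL`).
#' @return A `nail_mask`: logical `plate`, logical `maz`, and the policy.
#' @export
build_mask <- function(surface, bed_boundary, maz_mask = NULL,
                       policy = c("exclude_maz", "include_maz"), dim = NULL) {
  policy <- match.arg(policy)
  bed <- if (is.list(bed_boundary)) bed_boundary$row else bed_boundary
  if (is.null(dim)) {
    if (is.null(maz_mask)) stop("'dim' required when no maz_mask given", call. = FALSE)
    dim <- base::dim(maz_mask)
  }
  nz <- dim[1]; nx <- dim[2]
  rows <- matrix(seq_len(nz), nz, nx)
  surfm <- matrix(surface$row, nz, nx, byrow = TRUE)
  bedm <- matrix(bed, nz, nx, byrow = TRUE)
  plate <- rows >= surfm & rows < bedm
  if (is.null(maz_mask)) maz_mask <- matrix(FALSE, nz, nx)
  if (policy == "exclude_maz") plate <- plate & !maz_mask
  structure(list(plate = plate, maz = maz_mask, policy = policy),
            class = "nail_mask")
}

#' Averaged A-scan profile
#'
#' Mean backscatter-vs-depth profile over `n_adjacent` columns centred at
#' `x_center` (11 columns span ~50 um at 5 um transverse pitch, the
#' convention used for A-scan averaging).
#'
#' @param x a `bscan` or matrix.
#' @param x_center centre column (1-based).
#' @param n_adjacent number of columns averaged (odd).
#' @return Numeric vector of length `nrow(x)`.
#' @export
averaged_ascan_profile <- function(x, x_center, n_adjacent = 11) {
  img <- as_intensity(x)
  half <- (n_adjacent - 1L) %/% 2L
  lo <- x_center - half; hi <- x_center + (n_adjacent - 1L - half)
  if (lo < 1L || hi > ncol(img)) stop("A-scan window out of bounds", call. = FALSE)
  rowMeans(img[, lo:hi, drop = FALSE])
}
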