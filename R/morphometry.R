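# Detection and measurement of microthermal ablation zones (MAZs) in
# cross-sectional B-scans: low-backscatter voids open to the nail surface,
# measured as axial penetration depth (surface to apex) and transverse
# aperture diameter at the surface.

run_min <- function(v, k) {
  half <- (k - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i)
    min(v[max(1L, i - half):min(n, i + half)]), numeric(1))
}

run_max <- function(v, k) {
  half <- (k - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i)
    max(v[max(1L, i - half):min(n, i + half)]), numeric(1))
}

# Bridge crater dips in a detected surface. A grayscale opening (running
# min then running max) of the per-column surface rows removes dips
# narrower than `trend_window` while following tilt; columns dropping well
# below that trend are aperture columns and are re-interpolated from the
# flanking intact surface. `trend_window` must exceed the widest aperture.
bridge_surface <- function(surface_row, drop_px = 0L, trend_window = 51L) {
  trend <- run_max(run_min(surface_row, trend_window), trend_window)
  crater <- surface_row > trend + drop_px
  out <- surface_row
  if (any(crater) && any(!crater)) {
    out[crater] <- round(stats::approx(which(!crater), surface_row[!crater],
                                       xout = which(crater), rule = 2)$y)
  }
  list(row = as.integer(out), crater = crater)
}

#' Detect MAZ candidates in a B-scan
#'
#' The frame is median-filtered to suppress speckle and then flattened by
#' the intact-plate depth profile (the median intensity at each depth below
#' the crater-bridged surface, over non-aperture columns), which removes
#' depth attenuation and layer contrast. Candidates are connected regions
#' whose flattened intensity falls below `k_otsu` times the Otsu threshold
#' of the flattened image — i.e. regions dark relative to tissue at the
#' same depth — that open onto the nail-surface aperture. Touching
#' candidates closer than `min_width_um` are merged and flagged. The
#' relative threshold makes detection invariant to a global intensity
#' rescale.
#'
#' @param x a `bscan` (pixel pitches are taken from it) or matrix (then
#'   `pixel_dz_um`/`pixel_dx_um` must be given).
#' @param surface a `surface_profile` detected on the same frame.
#' @param min_depth_um,min_width_um minimum candidate size.
#' @param max_depth_um search depth below the surface; caps the candidate
#'   mask so the attenuated sub-bed tissue (also dark) cannot connect to a
#'   void. Defaults to a typical nail-plate thickness.
#' @param k_otsu threshold fraction.
#' @param pixel_dz_um,pixel_dx_um pitches for plain matrices.
#' @param median_radius speckle-suppression median filter radius (pixels).
#' @return list of candidates, each `list(mask, aperture_cols, apex_row,
#'   apex_col, merged)`; empty list when none.
#' @export
detect_mazs <- function(x, surface, min_depth_um = 50, min_width_um = 30,
                        max_depth_um = 600, k_otsu = 0.5,
                        pixel_dz_um = NULL, pixel_dx_um = NULL,
                        median_radius = 2L) {
  img <- as_intensity(x)
  if (inherits(x, "bscan")) {
    pixel_dz_um <- x$pixel_dz_um; pixel_dx_um <- x$pixel_dx_um
  }
  if (is.null(pixel_dz_um) || is.null(pixel_dx_um)) {
    stop("pixel pitches required", call. = FALSE)
  }
  nz <- nrow(img); nx <- ncol(img)
  br <- bridge_surface(surface$row)
  smoothed <- if (median_radius > 0L) {
    EBImage::medianFilter(pmin(pmax(img, 0), 1), median_radius)
  } else img
  rows <- matrix(seq_len(nz), nz, nx)
  surfm <- matrix(br$row, nz, nx, byrow = TRUE)
  max_depth_px <- round(max_depth_um / pixel_dz_um)

  # intact-plate depth profile: median intensity at each depth below the
  # bridged surface over non-crater columns
  intact <- if (any(!br$crater)) which(!br$crater) else seq_len(nx)
  profile <- vapply(seq_len(max_depth_px), function(d) {
    rr <- br$row[intact] + d - 1L
    ok <- rr <= nz
    if (!any(ok)) return(NA_real_)
    stats::median(smoothed[cbind(rr[ok], intact[ok])])
  }, numeric(1))
  profile[!is.finite(profile) | profile <= 0] <- max(profile, na.rm = TRUE)
  expected <- matrix(1, nz, nx)
  d_below <- rows - surfm + 1L
  in_band <- d_below >= 1L & d_below <= max_depth_px
  expected[in_band] <- profile[d_below[in_band]]
  flat <- pmin(smoothed / expected, 2) / 2     # ratio image on [0, 1]
  thr <- k_otsu * EBImage::otsu(flat, range = c(0, 1)) * 2

  # skip the top 2 rows: the median filter's boundary window mixes in air
  # and darkens the surface row along the whole width
  dark <- smoothed / expected < thr & rows >= surfm + 2L & rows < surfm + max_depth_px
  lab <- EBImage::bwlabel(dark)
  n <- max(lab)
  if (n == 0L) return(list())
  min_depth_px <- round(min_depth_um / pixel_dz_um)
  min_width_px <- round(min_width_um / pixel_dx_um)
  cands <- list()
  for (k in seq_len(n)) {
    mk <- lab == k
    # must open onto the surface aperture
    top_rows <- apply(mk, 2, function(col) if (any(col)) which(col)[1] else NA_integer_)
    open_cols <- which(!is.na(top_rows) & top_rows <= br$row + 4L)
    if (length(open_cols) == 0L) next
    depth_px <- max(rows[mk]) - stats::median(br$row[open_cols])
    width_px <- length(open_cols)
    if (depth_px < min_depth_px || width_px < min_width_px) next
    cands[[length(cands) + 1L]] <- list(
      mask = mk, aperture_cols = open_cols,
      apex_row = max(rows[mk]),
      apex_col = round(stats::median(which(colSums(mk & rows == max(rows[mk])) > 0))),
      merged = FALSE)
  }
  # The median filter erodes the void by 1-3 px at the apex and aperture
  # edges; refine both on the unfiltered ratio image.
  flat_raw <- img / expected
  refine <- function(cand) {
    ac <- cand$apex_col
    zmax <- min(nz, br$row[ac] + max_depth_px - 1L)
    z <- cand$apex_row
    while (z + 1L <= zmax && flat_raw[z + 1L, ac] < thr) {
      z <- z + 1L
      cand$mask[z, ac] <- TRUE
    }
    cand$apex_row <- z
    srow <- br$row[ac]
    band <- function(col) flat_raw[srow, col]
    lo <- min(cand$aperture_cols); hi <- max(cand$aperture_cols)
    while (lo - 1L >= 1L && band(lo - 1L) < thr) lo <- lo - 1L
    while (hi + 1L <= nx && band(hi + 1L) < thr) hi <- hi + 1L
    cand$aperture_cols <- lo:hi
    cand
  }
  cands <- lapply(cands, refine)
  if (length(cands) < 2L) return(cands)
  # merge candidates whose apertures are closer than min_width
  ord <- order(vapply(cands, function(c) min(c$aperture_cols), numeric(1)))
  cands <- cands[ord]
  merged <- list(cands[[1]])
  for (k in 2:length(cands)) {
    prev <- merged[[length(merged)]]
    cur <- cands[[k]]
    gap <- min(cur$aperture_cols) - max(prev$aperture_cols)
    if (gap < min_width_px) {
      prev$mask <- prev$mask | cur$mask
      prev$aperture_cols <- sort(union(prev$aperture_cols, cur$aperture_cols))
      if (cur$apex_row > prev$apex_row) {
        prev$apex_row <- cur$apex_row; prev$apex_col <- cur$apex_col
      }
      prev$merged <- TRUE
      merged[[length(merged)]] <- prev
    } else {
      merged[[length(merged) + 1L]] <- cur
    }
  }
  merged
}

#' Measure one MAZ candidate
#'
#' Penetration depth is the axial distance from the local (crater-bridged)
#' surface to the deepest candidate pixel; diameter is the aperture extent
#' at the surface. Both are reported in microns.
#'
#' @param x a `bscan` or matrix.
#' @param surface a `surface_profile`.
#' @param candidate one element of the [detect_mazs()] result.
#' @param pixel_dz_um,pixel_dx_um pitches for plain matrices.
#' @param energy_mJ optional exposure-energy label.
#' @return An object of class `maz_measurement` (also a one-row data frame)
#'   with `apex_x`, `apex_z`, `penetration_depth_um`, `diameter_um`,
#'   `energy_mJ`, `merged`.
#' @export
measure_maz <- function(x, surface, candidate, pixel_dz_um = NULL,
                        pixel_dx_um = NULL, energy_mJ = NA_real_) {
  if (inherits(x, "bscan")) {
    pixel_dz_um <- x$pixel_dz_um; pixel_dx_um <- x$pixel_dx_um
  }
  if (is.null(pixel_dz_um) || is.null(pixel_dx_um)) {
    stop("pixel pitches required", call. = FALSE)
  }
  if (length(candidate$aperture_cols) == 0L) {
    stop("candidate detached from surface", call. = FALSE)
  }
  br <- bridge_surface(surface$row)
  local_surf <- stats::median(br$row[candidate$aperture_cols])
  depth_px <- candidate$apex_row - local_surf
  if (depth_px < 0) stop("candidate apex above surface", call. = FALSE)
  width_px <- max(candidate$aperture_cols) - min(candidate$aperture_cols) + 1L
  out <- data.frame(
    apex_x = candidate$apex_col, apex_z = candidate$apex_row,
    penetration_depth_um = max(depth_px, 1) * pixel_dz_um,
    diameter_um = width_px * pixel_dx_um,
    energy_mJ = energy_mJ, merged = isTRUE(candidate$merged))
  class(out) <- c("maz_measurement", class(out))
  out
}

#' Summarize MAZ measurements by exposure energy
#'
#' @param measurements data frame of [measure_maz()] rows with an
#'   `energy_mJ` column.
#' @return data frame sorted by energy with per-energy `n`, mean and sd of
#'   depth and diameter (sd 0 for a single measurement).
#' @export
summarize_by_energy <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0L) {
    return(data.frame(energy_mJ = numeric(), n = integer(),
                      mean_depth_um = numeric(), sd_depth_um = numeric(),
                      mean_diameter_um = numeric(), sd_diameter_um = numeric()))
  }
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  sp <- split(measurements, measurements$energy_mJ)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(energy_mJ = g$energy_mJ[1], n = nrow(g),
               mean_depth_um = mean(g$penetration_depth_um),
               sd_depth_um = sd0(g$penetration_depth_um),
               mean_diameter_um = mean(g$diameter_um),
               sd_diameter_um = sd0(g$diameter_um))
  }))
  out <- out[order(out$energy_mJ), , drop = FALSE]
  rownames(out) <- NULL
  out
}
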