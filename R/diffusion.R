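# ROI diffusion time courses, onset/saturation times, SV center-of-mass
# depth trajectories, and liquid-vs-cream formulation comparison.

#' Place the three analysis regions
#'
#' Region I: squares centred at the MAZ apices (tip regions). Region II:
#' squares in the upper nail, at a shallow depth below the surface and away
#' from the apertures. Region III: squares midway between adjacent MAZ
#' pairs at mid-plate depth. Three squares per region; with fewer than
#' three natural positions the remaining squares are offset transversely
#' from existing ones. All squares are clipped to the image.
#'
#' @param mask a `nail_mask` (provides surface/bed extent per column).
#' @param maz_geometry data frame with `x_px`, `apex_row`, `surface_row`
#'   and `width_px` per MAZ (ground truth or measured).
#' @param square_size_px square side in pixels.
#' @return An object of class `roi_set`: data frame with `region_label`,
#'   `x0`, `x1`, `z0`, `z1`.
#' @export
place_rois <- function(mask, maz_geometry, square_size_px = 10) {
  nz <- nrow(mask$plate); nx <- ncol(mask$plate)
  if (nrow(maz_geometry) < 1L) stop("at least one MAZ required", call. = FALSE)
  surf <- apply(mask$plate | mask$maz, 2, function(col)
    if (any(col)) which(col)[1] else NA_integer_)
  surf[is.na(surf)] <- round(stats::median(surf, na.rm = TRUE))
  bed <- apply(mask$plate | mask$maz, 2, function(col)
    if (any(col)) which(col)[length(which(col))] else NA_integer_)
  bed[is.na(bed)] <- round(stats::median(bed, na.rm = TRUE))
  thick <- stats::median(bed - surf)
  half <- square_size_px %/% 2L
  sq <- function(region_label, cz, cx) {
    data.frame(region_label = region_label,
               x0 = max(1L, round(cx) - half),
               x1 = min(nx, round(cx) - half + square_size_px - 1L),
               z0 = max(1L, round(cz) - half),
               z1 = min(nz, round(cz) - half + square_size_px - 1L))
  }
  g <- maz_geometry[order(maz_geometry$x_px), , drop = FALSE]

  # Region I: MAZ tips
  roi1 <- do.call(rbind, lapply(seq_len(nrow(g)), function(k)
    sq("I", g$apex_row[k], g$x_px[k])))

  # candidate transverse positions away from apertures: flanks + midpoints
  ap_half <- g$width_px / 2
  flank_l <- max(1 + half, min(g$x_px - ap_half) - square_size_px)
  flank_r <- min(nx - half, max(g$x_px + ap_half) + square_size_px)
  mids <- if (nrow(g) >= 2L) (g$x_px[-nrow(g)] + g$x_px[-1]) / 2 else numeric()

  z2 <- stats::median(surf) + max(round(0.15 * thick), half + 1L)
  xs2 <- c(flank_l, if (length(mids)) mids[ceiling(length(mids) / 2)] else
    mean(c(flank_l, flank_r)), flank_r)
  roi2 <- do.call(rbind, lapply(xs2, function(x) sq("II", z2, x)))

  roi3 <- NULL
  if (nrow(g) >= 2L) {
    z3 <- stats::median(surf) + round(0.5 * thick)
    # pad to 3 squares by stacking extra squares axially at the existing
    # midpoints (keeps them between the MAZs, off the apertures)
    pos <- data.frame(x = mids, z = z3)
    off <- square_size_px + 2L
    k <- 1L
    while (nrow(pos) < 3L) {
      pos <- rbind(pos, data.frame(x = mids[(k - 1L) %% length(mids) + 1L],
                                   z = z3 - off * ((k - 1L) %/% length(mids) + 1L)))
      k <- k + 1L
    }
    pos <- pos[1:3, ]
    roi3 <- do.call(rbind, lapply(seq_len(3L), function(i)
      sq("III", pos$z[i], pos$x[i])))
  } else {
    warning("fewer than 2 MAZs: Region III omitted")
  }
  out <- rbind(roi1, roi2, roi3)
  rownames(out) <- NULL
  class(out) <- c("roi_set", class(out))
  out
}

roi_sums <- function(svm, rois) {
  vapply(seq_len(nrow(rois)), function(k) {
    sum(svm[rois$z0[k]:rois$z1[k], rois$x0[k]:rois$x1[k]])
  }, numeric(1))
}

#' ROI time course of summed SV
#'
#' Per time point and region, the SV values inside each of the region's
#' squares are summed, and the three square sums are averaged; their
#' standard deviation quantifies within-region spread.
#'
#' @param sv_list list of (thresholded) `sv_image`, e.g. from [sv_series()].
#' @param rois a `roi_set`.
#' @return An object of class `time_course`: `times_s`, a `summary` data
#'   frame (`time_s`, `region_label`, `mean_sv_sum`, `sd_sv_sum`), and a
#'   `com_depth_um` slot (NA until filled by [sv_center_of_mass()]).
#' @export
roi_timecourse <- function(sv_list, rois) {
  if (length(sv_list) == 0L) stop("empty SV series", call. = FALSE)
  d <- dim(sv_list[[1]]$sv)
  if (any(rois$x1 > d[2]) || any(rois$z1 > d[1])) {
    stop("ROI outside image", call. = FALSE)
  }
  times <- vapply(sv_list, function(s) s$timestamp_s, numeric(1))
  labs <- unique(rois$region_label)
  rows <- list()
  for (i in seq_along(sv_list)) {
    s <- roi_sums(sv_list[[i]]$sv, rois)
    for (lb in labs) {
      v <- s[rois$region_label == lb]
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = times[i], region_label = lb,
        mean_sv_sum = mean(v),
        sd_sv_sum = if (length(v) > 1L) stats::sd(v) else 0)
    }
  }
  structure(list(times_s = times, summary = do.call(rbind, rows),
                 com_depth_um = rep(NA_real_, length(times)),
                 rois = rois,
                 onset_s = stats::setNames(rep(NA_real_, length(labs)), labs),
                 saturation_s = stats::setNames(rep(NA_real_, length(labs)), labs),
                 baseline = NULL),
            class = "time_course")
}

#' Extract one region's curve from a time course
#' @param tc a `time_course`.
#' @param region region label.
#' @return data frame `time_s`, `mean_sv_sum`.
#' @export
region_curve <- function(tc, region) {
  s <- tc$summary[tc$summary$region_label == region, , drop = FALSE]
  s[order(s$time_s), c("time_s", "mean_sv_sum")]
}

#' Onset time of a diffusion curve
#'
#' First time the curve exceeds `baseline_mean + 3 * baseline_sd` for at
#' least two consecutive samples; `NA` when it never does.
#'
#' @param curve numeric vector of region means over time.
#' @param times_s matching time vector (seconds).
#' @param baseline_mean,baseline_sd noise baseline from pre-application
#'   frames.
#' @return onset time in seconds, or `NA_real_`.
#' @export
onset_time <- function(curve, times_s, baseline_mean = 0, baseline_sd = 0) {
  if (length(curve) < 2L) stop("curve shorter than 2 samples", call. = FALSE)
  thr <- baseline_mean + 3 * baseline_sd
  above <- curve > thr
  run2 <- above[-length(above)] & above[-1]
  k <- which(run2)
  if (length(k) == 0L) return(NA_real_)
  times_s[k[1]]
}

#' Saturation time of a diffusion curve
#'
#' The plateau is the mean of the final 10% of samples; saturation is the
#' first time the curve reaches 95% of the plateau and stays at or above
#' 90% of it thereafter. `NA` when the plateau does not rise above the
#' baseline.
#'
#' @param curve numeric vector.
#' @param times_s matching times (seconds).
#' @param baseline baseline level the plateau must exceed.
#' @return saturation time in seconds, or `NA_real_`.
#' @export
saturation_time <- function(curve, times_s, baseline = 0) {
  n <- length(curve)
  if (n < 10L) stop("curve too short for saturation estimation", call. = FALSE)
  tail_n <- max(1L, ceiling(0.1 * n))
  plateau <- mean(curve[(n - tail_n + 1L):n])
  if (plateau <= baseline) return(NA_real_)
  ge95 <- curve >= 0.95 * plateau
  ge90 <- curve >= 0.90 * plateau
  stays <- rev(cumprod(rev(ge90))) == 1
  k <- which(ge95 & stays)
  if (length(k) == 0L) return(NA_real_)
  times_s[k[1]]
}

#' SV center-of-mass depth trajectory
#'
#' Per frame, the SV-weighted mean depth below the local nail surface,
#' `sum((z - surface[x]) * SV) / sum(SV) * pixel_dz`, over masked pixels.
#' Referencing depths to the surface keeps bulk position out of the
#' trajectory. Frames with zero total SV yield `NA`.
#'
#' @param sv_list list of `sv_image`.
#' @param mask a `nail_mask`.
#' @param surface a `surface_profile` (reference frame).
#' @param pixel_dz_um axial pitch in microns.
#' @return numeric vector of COM depths (um), one per frame.
#' @export
sv_center_of_mass <- function(sv_list, mask, surface, pixel_dz_um) {
  nz <- nrow(mask$plate); nx <- ncol(mask$plate)
  depth <- (matrix(seq_len(nz), nz, nx) -
              matrix(surface$row, nz, nx, byrow = TRUE))
  vapply(sv_list, function(s) {
    svm <- s$sv
    svm[!mask$plate] <- 0
    tot <- sum(svm)
    if (tot <= 0) return(NA_real_)
    sum(depth * svm) / tot * pixel_dz_um
  }, numeric(1))
}

com_descent_rate <- function(times_s, com_um, after_s = NULL) {
  ok <- is.finite(com_um)
  if (!is.null(after_s) && is.finite(after_s)) ok <- ok & times_s >= after_s
  if (sum(ok) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(com_um[ok] ~ times_s[ok]))[2])
}

#' Compare two formulations' time courses
#'
#' Per region: onset and saturation differences (a minus b). Globally: the
#' ratio of the SV center-of-mass descent rates (least-squares slope of COM
#' depth vs time over the post-onset window), a over b — a proxy for the
#' relative diffusion velocity of the two preparations.
#'
#' @param tc_a,tc_b `time_course` objects with populated onset/saturation
#'   and COM slots (see [quantify_diffusion()]); time grids must overlap.
#' @return list with `by_region` (data frame of differences) and
#'   `com_rate_ratio`, `com_rate_a`, `com_rate_b`.
#' @export
compare_formulations <- function(tc_a, tc_b) {
  if (max(tc_a$times_s) < min(tc_b$times_s) ||
      max(tc_b$times_s) < min(tc_a$times_s)) {
    stop("no overlap in time", call. = FALSE)
  }
  regions <- intersect(names(tc_a$onset_s), names(tc_b$onset_s))
  by_region <- do.call(rbind, lapply(regions, function(r) {
    data.frame(region_label = r,
               onset_a_s = tc_a$onset_s[[r]], onset_b_s = tc_b$onset_s[[r]],
               onset_diff_s = tc_a$onset_s[[r]] - tc_b$onset_s[[r]],
               saturation_a_s = tc_a$saturation_s[[r]],
               saturation_b_s = tc_b$saturation_s[[r]],
               saturation_diff_s = tc_a$saturation_s[[r]] - tc_b$saturation_s[[r]])
  }))
  onset_a <- suppressWarnings(min(unlist(tc_a$onset_s), na.rm = TRUE))
  onset_b <- suppressWarnings(min(unlist(tc_b$onset_s), na.rm = TRUE))
  rate_a <- com_descent_rate(tc_a$times_s, tc_a$com_depth_um,
                             if (is.finite(onset_a)) onset_a else NULL)
  rate_b <- com_descent_rate(tc_b$times_s, tc_b$com_depth_um,
                             if (is.finite(onset_b)) onset_b else NULL)
  list(by_region = by_region,
       com_rate_a = rate_a, com_rate_b = rate_b,
       com_rate_ratio = if (is.finite(rate_a) && is.finite(rate_b) && rate_b != 0)
         rate_a / rate_b else NA_real_)
}

#' Quantify diffusion for a thresholded SV series
#'
#' Convenience wrapper: ROI time course, per-region onset (against the
#' pre-application baseline) and saturation times, and the SV
#' center-of-mass trajectory, assembled into one `time_course`.
#'
#' @param sv_post,sv_pre thresholded SV lists for post-/pre-application
#'   frames (see [sv_series()]).
#' @param rois a `roi_set`.
#' @param mask a `nail_mask`.
#' @param surface reference `surface_profile`.
#' @param pixel_dz_um axial pitch.
#' @return a populated `time_course`.
#' @export
quantify_diffusion <- function(sv_post, sv_pre, rois, mask, surface,
                               pixel_dz_um) {
  tc <- roi_timecourse(sv_post, rois)
  tc$com_depth_um <- sv_center_of_mass(sv_post, mask, surface, pixel_dz_um)
  base_tc <- if (length(sv_pre) > 0L) roi_timecourse(sv_pre, rois) else NULL
  for (r in names(tc$onset_s)) {
    cur <- region_curve(tc, r)
    bmean <- 0; bsd <- 0
    if (!is.null(base_tc)) {
      b <- region_curve(base_tc, r)$mean_sv_sum
      bmean <- mean(b); bsd <- stats::sd(b)
      if (!is.finite(bsd)) bsd <- 0
    }
    tc$onset_s[[r]] <- onset_time(cur$mean_sv_sum, cur$time_s, bmean, bsd)
    tc$saturation_s[[r]] <- if (nrow(cur) >= 10L) {
      saturation_time(cur$mean_sv_sum, cur$time_s, baseline = bmean)
    } else NA_real_
    tc$baseline[[r]] <- c(mean = bmean, sd = bsd)
  }
  tc
}
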