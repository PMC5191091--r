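three_maz_mask <- function() {
  cfg <- phantom_config(maz_list = list(
    list(x_px = 40, depth_um = 372, top_width_um = 203),
    list(x_px = 100, depth_um = 372, top_width_um = 203),
    list(x_px = 160, depth_um = 372, top_width_um = 203)))
  tr <- build_static_phantom(cfg)
  surf <- structure(list(row = tr$surface_row, valid = rep(TRUE, cfg$grid_nx)),
                    class = "surface_profile")
  list(cfg = cfg, truth = tr, surf = surf,
       mask = build_mask(surf, tr$bed_row, tr$maz_mask, "exclude_maz"))
}

test_that("ROI placement yields three squares per region inside the plate", {
  x <- three_maz_mask()
  rois <- place_rois(x$mask, x$truth$maz_geometry, square_size_px = 10)
  expect_equal(as.vector(table(rois$region_label)[c("I", "II", "III")]),
               c(3L, 3L, 3L))
  # every square pixel lies between surface and bed
  band <- x$mask$plate | x$mask$maz
  for (k in seq_len(nrow(rois))) {
    expect_true(all(band[rois$z0[k]:rois$z1[k], rois$x0[k]:rois$x1[k]]))
  }
  # Region I squares sit at the MAZ apices
  r1 <- rois[rois$region_label == "I", ]
  expect_equal(sort(round((r1$x0 + r1$x1) / 2)), c(40, 100, 160))
})

test_that("a single MAZ omits Region III with a warning", {
  cfg <- phantom_config(maz_list = list(
    list(x_px = 100, depth_um = 372, top_width_um = 203)))
  tr <- build_static_phantom(cfg)
  surf <- structure(list(row = tr$surface_row, valid = rep(TRUE, cfg$grid_nx)),
                    class = "surface_profile")
  mask <- build_mask(surf, tr$bed_row, tr$maz_mask, "exclude_maz")
  expect_warning(rois <- place_rois(mask, tr$maz_geometry), "Region III")
  expect_setequal(unique(rois$region_label), c("I", "II"))
})

test_that("ROI time courses have closed-form values on constant SV", {
  x <- three_maz_mask()
  rois <- place_rois(x$mask, x$truth$maz_geometry, square_size_px = 10)
  zero <- nailsv:::new_sv_image(matrix(0, x$cfg$grid_nz, x$cfg$grid_nx),
                                "thresholded", timestamp_s = 0.2)
  tc0 <- roi_timecourse(list(zero), rois)
  expect_true(all(tc0$summary$mean_sv_sum == 0))

  const <- nailsv:::new_sv_image(matrix(0.3, x$cfg$grid_nz, x$cfg$grid_nx),
                                 "thresholded", timestamp_s = 0.2)
  tc1 <- roi_timecourse(list(const), rois)
  expect_equal(tc1$summary$mean_sv_sum, rep(0.3 * 100, 3))  # c * area
  expect_equal(tc1$summary$sd_sv_sum, rep(0, 3))

  # scaling SV scales summations linearly
  tc2 <- roi_timecourse(list(nailsv:::new_sv_image(const$sv * 2, "thresholded",
                                                   timestamp_s = 0.2)), rois)
  expect_equal(tc2$summary$mean_sv_sum, 2 * tc1$summary$mean_sv_sum)

  bad <- rois; bad$x1[1] <- 10000
  expect_error(roi_timecourse(list(const), bad), "outside image")
})

test_that("onset detection needs a sustained 3-sigma exceedance", {
  times <- seq(0.2, 4, by = 0.2)
  expect_true(is.na(onset_time(rep(0.5, 20), times, 0.5, 0.1)))
  step <- c(rep(0, 9), rep(10, 11))
  expect_equal(onset_time(step, times, 0, 0.5), times[10])
  # one-sample blips do not trigger
  blip <- rep(0, 20); blip[5] <- 10
  expect_true(is.na(onset_time(blip, times, 0, 0.5)))
  expect_error(onset_time(1, 0.2), "shorter")
})

test_that("saturation time matches the analytic 95% crossing", {
  times <- seq(0.2, 15, by = 0.2)
  tau <- 3
  curve <- 1 - exp(-times / tau)
  got <- saturation_time(curve, times)
  # plateau ~ mean of final 10% ~= 0.992; 95% of it crossed near -tau*log(0.05)
  analytic <- -tau * log(1 - 0.95 * mean(tail(curve, ceiling(0.1 * length(curve)))))
  expect_lte(abs(got - analytic), 0.2 + 1e-9)  # within one sample
  expect_lte(abs(got - 3 * tau), 0.5)

  expect_true(is.na(saturation_time(rep(0, 30), times[1:30])))
  step <- ifelse(times >= 2, 1, 0)
  expect_equal(saturation_time(step, times), 2)
  expect_error(saturation_time(1:5, times[1:5]), "too short")
})

test_that("SV center of mass is the SV-weighted depth below the surface", {
  nz <- 60; nx <- 40
  mask <- structure(list(plate = matrix(TRUE, nz, nx),
                         maz = matrix(FALSE, nz, nx), policy = "include_maz"),
                    class = "nail_mask")
  surf <- structure(list(row = rep(5L, nx), valid = rep(TRUE, nx)),
                    class = "surface_profile")
  one <- matrix(0, nz, nx); one[15, 20] <- 0.4      # depth 10 px below surface
  two <- matrix(0, nz, nx); two[15, 20] <- 0.2; two[25, 20] <- 0.2
  svl <- list(nailsv:::new_sv_image(one, "thresholded", timestamp_s = 0.2),
              nailsv:::new_sv_image(two, "thresholded", timestamp_s = 0.4),
              nailsv:::new_sv_image(matrix(0, nz, nx), "thresholded",
                                    timestamp_s = 0.6))
  com <- sv_center_of_mass(svl, mask, surf, pixel_dz_um = 7)
  expect_equal(com[1], 10 * 7)
  expect_equal(com[2], 15 * 7)                      # symmetric pair
  expect_true(is.na(com[3]))                        # zero total SV
  # scale invariance
  com2 <- sv_center_of_mass(list(nailsv:::new_sv_image(one * 5, "thresholded",
                                                       timestamp_s = 0.2)),
                            mask, surf, 7)
  expect_equal(com2[1], com[1])
})

test_that("formulation comparison reports onset shifts and COM rate ratios", {
  mk_tc <- function(shift = 0, rate = 10) {
    times <- seq(0.2, 10, by = 0.2)
    structure(list(
      times_s = times,
      summary = NULL,
      com_depth_um = 100 + rate * times,
      onset_s = c(I = 0.4 + shift, II = 1 + shift, III = 2 + shift),
      saturation_s = c(I = 5 + shift, II = 6 + shift, III = 7 + shift)),
      class = "time_course")
  }
  a <- mk_tc()
  same <- compare_formulations(a, mk_tc())
  expect_true(all(same$by_region$onset_diff_s == 0))
  expect_true(all(same$by_region$saturation_diff_s == 0))
  expect_equal(same$com_rate_ratio, 1)

  shifted <- compare_formulations(mk_tc(shift = 1), a)
  expect_equal(shifted$by_region$onset_diff_s, rep(1, 3))

  faster <- compare_formulations(mk_tc(rate = 20), mk_tc(rate = 10))
  expect_equal(faster$com_rate_ratio, 2)

  late <- mk_tc(); late$times_s <- late$times_s + 100
  expect_error(compare_formulations(a, late), "overlap")
})
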