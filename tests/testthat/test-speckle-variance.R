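test_that("speckle variance reduces to |a - b| / 2 and matches the full form", {
  a <- matrix(c(1.0, 0.8, 0.3, 0.3), 2, 2)
  b <- matrix(c(0.0, 0.2, 0.3, 0.7), 2, 2)
  sv <- compute_sv(a, b)
  expect_equal(sv$sv, matrix(c(0.5, 0.3, 0, 0.2), 2, 2))
  expect_equal(sv$stage, "raw")
  expect_true(all(compute_sv(a, a)$sv == 0))
  expect_equal(compute_sv(a, b)$sv, compute_sv(b, a)$sv)  # symmetric

  set.seed(99)
  x <- matrix(runif(64), 8, 8)
  y <- matrix(runif(64), 8, 8)
  expect_lt(max(abs(compute_sv(x, y)$sv - oracle_sv(x, y))), 1e-12)
  expect_error(compute_sv(x, matrix(0, 4, 4)), "shape mismatch")
})

test_that("shadow correction follows the cumulative-sum closed form", {
  col <- matrix(c(0.1, 0.2, 0.3), 3, 1)
  sv <- nailsv:::new_sv_image(col, "raw")
  out <- shadow_correct(sv, shadow_params(gamma = 1, exponent_sign = +1))
  want <- c(0.1 * exp(0.1), 0.2 * exp(0.3), 0.3 * exp(0.6))
  # verify the hand case by direct summation before relying on it
  direct <- col[, 1] * exp(cumsum(col[, 1]) / 1)
  expect_equal(want, direct)
  expect_equal(out$sv[, 1], want)
  expect_equal(out$stage, "shadow_corrected")
  expect_equal(out$gamma, 1)

  # zero SV stays zero; infinite gamma recovers the raw image
  z <- nailsv:::new_sv_image(matrix(0, 4, 4), "raw")
  expect_true(all(shadow_correct(z, shadow_params(gamma = 1))$sv == 0))
  set.seed(7)
  r <- nailsv:::new_sv_image(matrix(runif(100, 0, 0.3), 10, 10), "raw")
  lim <- shadow_correct(r, shadow_params(gamma = 1e12))
  expect_lt(max(abs(lim$sv - r$sv) / pmax(r$sv, 1e-30)), 1e-9)

  # sign determines whether the correction amplifies or attenuates
  up <- shadow_correct(r, shadow_params(gamma = 0.5, exponent_sign = +1))
  dn <- shadow_correct(r, shadow_params(gamma = 0.5, exponent_sign = -1))
  expect_true(all(up$sv >= r$sv))
  expect_true(all(dn$sv <= r$sv))
  # amplification never exceeds the cap
  expect_true(all(up$sv <= exp(3) * r$sv + 1e-12))
  expect_error(shadow_params(gamma = -1), "> 0")
})

test_that("noise-floor threshold policies behave as specified", {
  cfg <- small_config(n_pre_frames = 4, seed = 17)
  tr <- build_static_phantom(cfg)
  conc <- replicate(cfg$n_post_frames, matrix(0, cfg$grid_nz, cfg$grid_nx),
                    simplify = FALSE)
  se <- render_series(tr, conc, cfg)
  expect_equal(estimate_noise_threshold(se, "paper_fixed"), 0.05)

  # identical pre-frames give a zero percentile threshold
  frozen <- small_config(decorrelation_gain = 0, bulk_motion_sd_px = 0,
                         sensor_noise_sd = 0, n_pre_frames = 3, seed = 2)
  trf <- build_static_phantom(frozen)
  sef <- render_series(trf, conc, frozen)
  expect_equal(estimate_noise_threshold(sef, "percentile"), 0)

  # percentile reproduces an independently recomputed empirical quantile
  got <- estimate_noise_threshold(se, "percentile")
  ref <- se$frames[[se$reference_index]]
  pool <- unlist(lapply(which(se$timestamps_s < 0),
                        function(i) abs(ref - se$frames[[i]]) / 2))
  expect_identical(got, as.numeric(quantile(pool, 0.99, names = FALSE)))

  short <- small_config(n_pre_frames = 1, seed = 17)
  ses <- render_series(build_static_phantom(short), conc, short)
  expect_error(estimate_noise_threshold(ses, "percentile"), "pre-application")
})

test_that("thresholding zeroes sub-floor and out-of-mask SV", {
  set.seed(5)
  svm <- matrix(runif(400, 0, 0.2), 20, 20)
  sv <- nailsv:::new_sv_image(svm, "raw")
  expect_equal(apply_threshold(sv, 0)$sv, svm)          # no-op
  expect_true(all(apply_threshold(sv, 0.3)$sv == 0))    # above max
  counts <- vapply(seq(0, 0.2, length.out = 10), function(th)
    sum(apply_threshold(sv, th)$sv > 0), numeric(1))
  expect_true(all(diff(counts) <= 0))                   # nonincreasing

  mask <- structure(list(plate = matrix(FALSE, 20, 20),
                         maz = matrix(FALSE, 20, 20), policy = "exclude_maz"),
                    class = "nail_mask")
  expect_true(all(apply_threshold(sv, 0, mask)$sv == 0))
  bad <- mask; bad$plate <- matrix(TRUE, 5, 5)
  expect_error(apply_threshold(sv, 0, bad), "mask shape")
})

test_that("sv_series bookkeeping excludes the reference and pre frames", {
  set.seed(3)
  n_post <- 5
  frames <- replicate(n_post, matrix(runif(100), 10, 10), simplify = FALSE)
  s <- bscan_series(frames, 7, 5, timestamps_s = (0:(n_post - 1)) * 0.2,
                    reference_index = 1)
  out <- sv_series(s, shadow_params(gamma = 1), threshold = 0)
  expect_length(out, n_post - 1)               # reference not compared to itself
  expect_true(all(vapply(out, function(x) x$stage == "thresholded", logical(1))))
})

test_that("null and active simulations separate cleanly in thresholded SV", {
  st <- make_fixture("static", seed = 6, n_post_frames = 8, n_pre_frames = 4)
  ra <- realign_series(st$series)
  surf <- detect_surface(get_bscan(ra, ra$reference_index))
  surf$row <- nailsv:::bridge_surface(surf$row)$row
  mask <- build_mask(surf, surf$row + round(600 / 7), st$truth$maz_mask,
                     "exclude_maz")
  out <- sv_series(ra, shadow_params(), mask, threshold = 0.05)
  supra <- vapply(out, function(x) mean(x$sv[mask$plate] > 0), numeric(1))
  expect_true(all(supra < 0.01))               # static preset: below noise floor

  lq <- make_fixture("liquid_like", seed = 6, n_post_frames = 5, n_pre_frames = 4)
  ra2 <- realign_series(lq$series)
  surf2 <- detect_surface(get_bscan(ra2, ra2$reference_index))
  surf2$row <- nailsv:::bridge_surface(surf2$row)$row
  mask2 <- build_mask(surf2, surf2$row + round(600 / 7), lq$truth$maz_mask,
                      "exclude_maz")
  out2 <- sv_series(ra2, shadow_params(), mask2, threshold = 0.05)
  # suprathreshold SV appears next to a MAZ wall within the first second
  wall <- EBImage::dilate(lq$truth$maz_mask,
                          EBImage::makeBrush(5, "box")) & !lq$truth$maz_mask
  early <- Reduce(`+`, lapply(out2[1:5], function(x) x$sv))
  expect_gt(sum(early[wall & mask2$plate] > 0), 0)
})
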