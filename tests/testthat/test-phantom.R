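test_that("static phantom geometry matches the configured presets", {
  # no MAZs: plate mask is the full band between surface and bed
  cfg <- small_config()
  tr <- build_static_phantom(cfg)
  thick_px <- round(cfg$plate_thickness_um / cfg$pixel_dz_um)
  rows <- matrix(seq_len(cfg$grid_nz), cfg$grid_nz, cfg$grid_nx)
  expected <- rows >= cfg$surface_row & rows < cfg$surface_row + thick_px
  expect_identical(tr$plate_mask, expected)
  expect_false(any(tr$maz_mask))

  # single MAZ with the deepest energy preset: apex and aperture arithmetic
  cfg2 <- phantom_config(maz_list = list(
    list(x_px = 100, depth_um = 372, top_width_um = 203)))
  tr2 <- build_static_phantom(cfg2)
  g <- tr2$maz_geometry
  expect_equal(g$apex_row - g$surface_row, round(372 / 7))  # 53 px
  aperture <- sum(tr2$maz_mask[g$surface_row, ])
  expect_equal(aperture, round(203 / 5))                    # 41 columns
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_config(grid_nz = 50, surface_row = 20,
                              plate_thickness_um = 600),
               "fit inside the grid")
  expect_error(phantom_config(maz_list = list(
    list(x_px = 100, depth_um = 700, top_width_um = 100))),
    "exceeds plate thickness")
  cfg <- phantom_config(maz_list = list(
    list(x_px = 100, depth_um = 300, top_width_um = 203),
    list(x_px = 110, depth_um = 300, top_width_um = 203)))
  expect_error(build_static_phantom(cfg), "overlap")
  cfg2 <- phantom_config(maz_list = list(
    list(x_px = 5, depth_um = 300, top_width_um = 203)))
  expect_error(build_static_phantom(cfg2), "wider than grid")
})

test_that("concentration dynamics: zero-diffusivity and mass growth", {
  cfg <- small_config(maz_list = list(
    list(x_px = 30, depth_um = 200, top_width_um = 100)),
    diffusion_coefficient_um2_per_s = 0, source_strength = 1)
  tr <- build_static_phantom(cfg)
  conc <- simulate_concentration(tr, cfg, times = c(-0.5, 0, 0.5, 1))
  expect_true(all(conc[[1]] == 0))             # pre-application
  expect_true(all(conc[[2]] == 0))             # at application
  src <- nailsv:::source_mask_for(tr)
  expect_true(all(conc[[4]][src] == 1))
  expect_true(all(conc[[4]][!src] == 0))       # D = 0: sources only

  cfg$diffusion_coefficient_um2_per_s <- 200
  conc2 <- simulate_concentration(tr, cfg, times = seq(0.2, 2, by = 0.2))
  masses <- vapply(conc2, sum, numeric(1))
  expect_true(all(diff(masses) > -1e-10))      # nondecreasing while source on
  expect_true(all(vapply(conc2, function(C) all(C >= 0), logical(1))))
})

test_that("diffusion solver matches a brute-force stencil oracle", {
  set.seed(42)
  nz <- 20; nx <- 20
  domain <- matrix(TRUE, nz, nx)
  domain[1:2, ] <- FALSE                       # a little structure
  src <- matrix(FALSE, nz, nx); src[3, 8:12] <- TRUE
  absorb <- matrix(FALSE, nz, nx); absorb[nz, ] <- TRUE
  C0 <- matrix(runif(nz * nx), nz, nx)
  D <- 150; dx <- 5; dz <- 7
  for (steps in c(1, 5)) {
    got <- diffuse_field(C0, domain, D, steps * 0.05, dx, dz,
                         source_mask = src, source_value = 0.7,
                         absorb_below = absorb)
    want <- oracle_diffuse(C0, domain, D, steps * 0.05, dx, dz,
                           src = src, sval = 0.7, absorb = absorb)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("diffusion conserves mass with sources off and boundaries closed", {
  set.seed(1)
  domain <- matrix(TRUE, 30, 25)
  C0 <- matrix(runif(30 * 25), 30, 25)
  out <- diffuse_field(C0, domain, D = 300, dt_total = 2, dx = 5, dz = 7)
  expect_lt(abs(sum(out) - sum(C0)), 1e-10)
})

test_that("rendering is deterministic and respects degenerate settings", {
  cfg <- small_config(seed = 11)
  tr <- build_static_phantom(cfg)
  conc <- replicate(cfg$n_post_frames, matrix(0, cfg$grid_nz, cfg$grid_nx),
                    simplify = FALSE)
  s1 <- render_series(tr, conc, cfg)
  s2 <- render_series(tr, conc, cfg)
  expect_identical(s1$frames, s2$frames)       # bit-identical under same seed

  # frozen speckle: no decorrelation, no motion, no sensor noise
  cfg0 <- small_config(decorrelation_gain = 0, bulk_motion_sd_px = 0,
                       sensor_noise_sd = 0, seed = 3)
  tr0 <- build_static_phantom(cfg0)
  s0 <- render_series(tr0, conc, cfg0)
  for (i in seq_len(n_frames(s0))) {
    expect_identical(s0$frames[[i]], s0$frames[[1]])
  }
})

test_that("MAZ voids render darker than adjacent plate at equal depth", {
  cfg <- small_config(maz_list = list(
    list(x_px = 30, depth_um = 250, top_width_um = 150)), seed = 5)
  tr <- build_static_phantom(cfg)
  conc <- replicate(cfg$n_post_frames, matrix(0, cfg$grid_nz, cfg$grid_nx),
                    simplify = FALSE)
  se <- render_series(tr, conc, cfg)
  fr <- se$frames[[se$reference_index]]
  band <- (cfg$surface_row + 5):(cfg$surface_row + 20)
  void <- tr$maz_mask[band, ]
  plate <- tr$plate_mask[band, ] & !tr$maz_mask[band, ]
  expect_lt(mean(fr[band, ][void]), mean(fr[band, ][plate]))
})

test_that("concentration-driven decorrelation raises |I_t - I_ref| locally", {
  cfg <- small_config(n_post_frames = 30, seed = 9, decorrelation_gain = 2.5)
  tr <- build_static_phantom(cfg)
  # concentration confined to a block on the left side of the plate
  C <- matrix(0, cfg$grid_nz, cfg$grid_nx)
  C[20:40, 5:20] <- 1
  conc <- replicate(cfg$n_post_frames, C, simplify = FALSE)
  se <- render_series(tr, conc, cfg)
  ref <- se$frames[[se$reference_index]]
  post <- se$frames[(se$reference_index + 1):n_frames(se)]
  dev <- Reduce(`+`, lapply(post, function(f) abs(f - ref))) / length(post)
  inside <- mean(dev[20:40, 5:20])
  far <- mean(dev[20:40, 40:55])
  expect_gt(inside, 2 * far)
})

test_that("frame-to-frame intensity correlation follows exp(-gain*C*dt)", {
  cfg <- phantom_config(grid_nz = 120, grid_nx = 150, surface_row = 10,
                        plate_thickness_um = 700, n_pre_frames = 0,
                        n_post_frames = 30, bulk_motion_sd_px = 0,
                        sensor_noise_sd = 0, decorrelation_gain = 2.5,
                        shadow_gain = 0, seed = 21)
  tr <- build_static_phantom(cfg)
  Cval <- 0.2
  C <- matrix(Cval, cfg$grid_nz, cfg$grid_nx)
  conc <- replicate(cfg$n_post_frames, C, simplify = FALSE)
  se <- render_series(tr, conc, cfg)
  rho_want <- exp(-cfg$decorrelation_gain * Cval * cfg$frame_interval_s)
  # lag-1 Pearson correlation across columns within single rows (constant
  # mean intensity per row), averaged over rows and frame pairs; avoids the
  # O(1/T) bias of per-pixel time-series demeaning
  rows_use <- seq(cfg$surface_row + 5, cfg$surface_row + 90, by = 3)
  ests <- c()
  for (t in 2:(n_frames(se) - 1)) {
    f1 <- se$frames[[t]]; f2 <- se$frames[[t + 1]]
    ests <- c(ests, vapply(rows_use, function(r) cor(f1[r, ], f2[r, ]),
                           numeric(1)))
  }
  expect_lt(abs(mean(ests) - rho_want), 0.03)
})

test_that("fixture presets encode the study conditions", {
  st <- make_fixture("static", seed = 2, n_post_frames = 4, n_pre_frames = 2)
  expect_true(all(vapply(st$concentrations, function(C) all(C == 0), logical(1))))
  expect_equal(st$config$diffusion_coefficient_um2_per_s, 0)

  lq <- make_fixture("liquid_like", seed = 2, n_post_frames = 2, n_pre_frames = 2)
  cr <- make_fixture("cream_like", seed = 2, n_post_frames = 2, n_pre_frames = 2)
  expect_gt(lq$config$diffusion_coefficient_um2_per_s,
            cr$config$diffusion_coefficient_um2_per_s)

  fe <- make_fixture("four_energies", seed = 2)
  expect_length(fe, 4)
  expect_equal(vapply(fe, function(s) s$truth$maz_geometry$depth_um, numeric(1)),
               c(372, 321, 290, 255))
  expect_equal(vapply(fe, function(s) s$truth$maz_geometry$top_width_um, numeric(1)),
               c(203, 183, 171, 137))
  expect_error(make_fixture("unknown_preset"))
})
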