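# Synthetic dynamic-speckle OCT phantom: a layered nail plate over a nail
# bed, inverted-pyramid microthermal ablation zones (MAZs), a diffusing
# drug-concentration field that drives frame-to-frame speckle decorrelation
# and shadowing, depth attenuation, and small bulk axial motion. Ground
# truth (geometry, concentration, applied shifts) is retained so every
# downstream stage can be checked against it.

#' Phantom configuration
#'
#' Defines the geometry, optics and dynamics of the synthetic nail phantom.
#' Defaults mirror an OCT system with ~7 um axial and ~5 um transverse
#' resolution sampled at one pixel per resolution element, a ~600 um nail
#' plate, and a 0.2 s frame interval covering 10 s after drug application.
#'
#' @param grid_nz,grid_nx image size in pixels (depth x transverse).
#' @param pixel_dz_um,pixel_dx_um pixel pitch in microns.
#' @param surface_row row of the nail surface at the first column (1-based).
#' @param surface_slope_px_per_col surface tilt, rows per column.
#' @param plate_thickness_um nail-plate thickness in microns.
#' @param layer_reflectivities mean backscatter of the dorsal, intermediate,
#'   ventral and bed layers (named numeric of length 4).
#' @param layer_fractions dorsal/intermediate/ventral thickness fractions.
#' @param maz_reflectivity residual backscatter inside an ablated void.
#' @param attenuation_mu_per_um exponential depth-attenuation coefficient.
#' @param maz_list list of MAZs, each `list(x_px, depth_um, top_width_um)`:
#'   apex column, axial penetration depth and surface aperture width.
#' @param diffusion_coefficient_um2_per_s scalar diffusivity D of the drug
#'   concentration field.
#' @param source_strength constant concentration held at MAZ walls and the
#'   exposed surface (arbitrary concentration units).
#' @param decorrelation_gain maps local concentration to speckle
#'   decorrelation: frame-to-frame intensity correlation
#'   `rho = exp(-gain * C * dt)`.
#' @param shadow_gain attenuation applied below high-concentration voxels,
#'   per unit concentration per voxel.
#' @param bulk_motion_sd_px standard deviation of the per-frame integer
#'   axial jitter.
#' @param sensor_noise_sd additive Gaussian sensor noise (pre-normalization
#'   intensity units).
#' @param psf_sigma_z_px,psf_sigma_x_px Gaussian sigma of the speckle
#'   spatial low-pass, in pixels.
#' @param frame_interval_s seconds between frames.
#' @param n_pre_frames,n_post_frames frames before / after the reference
#'   frame (the reference is acquired at drug application, t = 0).
#' @param speckle logical; `FALSE` renders the noise-free deterministic
#'   intensity (useful for geometry tests).
#' @param seed RNG seed; identical config + seed gives bit-identical series.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_nz = 140, grid_nx = 200,
                           pixel_dz_um = 7, pixel_dx_um = 5,
                           surface_row = 20, surface_slope_px_per_col = 0,
                           plate_thickness_um = 600,
                           layer_reflectivities = c(dorsal = 0.90, intermediate = 0.60,
                                                    ventral = 0.75, bed = 0.35),
                           layer_fractions = c(0.15, 0.70, 0.15),
                           maz_reflectivity = 0.02,
                           attenuation_mu_per_um = 0.0015,
                           maz_list = list(),
                           diffusion_coefficient_um2_per_s = 0,
                           source_strength = 1,
                           decorrelation_gain = 2.5,
                           shadow_gain = 0.02,
                           bulk_motion_sd_px = 0.4,
                           sensor_noise_sd = 0.005,
                           psf_sigma_z_px = 0.7, psf_sigma_x_px = 0.7,
                           frame_interval_s = 0.2,
                           n_pre_frames = 10, n_post_frames = 50,
                           speckle = TRUE,
                           seed = 1) {
  cfg <- list(
    grid_nz = as.integer(grid_nz), grid_nx = as.integer(grid_nx),
    pixel_dz_um = pixel_dz_um, pixel_dx_um = pixel_dx_um,
    surface_row = surface_row,
    surface_slope_px_per_col = surface_slope_px_per_col,
    plate_thickness_um = plate_thickness_um,
    layer_reflectivities = layer_reflectivities,
    layer_fractions = layer_fractions,
    maz_reflectivity = maz_reflectivity,
    attenuation_mu_per_um = attenuation_mu_per_um,
    maz_list = maz_list,
    diffusion_coefficient_um2_per_s = diffusion_coefficient_um2_per_s,
    source_strength = source_strength,
    decorrelation_gain = decorrelation_gain,
    shadow_gain = shadow_gain,
    bulk_motion_sd_px = bulk_motion_sd_px,
    sensor_noise_sd = sensor_noise_sd,
    psf_sigma_z_px = psf_sigma_z_px, psf_sigma_x_px = psf_sigma_x_px,
    frame_interval_s = frame_interval_s,
    n_pre_frames = as.integer(n_pre_frames),
    n_post_frames = as.integer(n_post_frames),
    speckle = isTRUE(speckle),
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  for (nm in c("grid_nz", "grid_nx", "pixel_dz_um", "pixel_dx_um",
               "plate_thickness_um", "frame_interval_s")) {
    stopifnot_scalar(cfg[[nm]], nm)
  }
  for (nm in c("diffusion_coefficient_um2_per_s", "decorrelation_gain",
               "shadow_gain", "bulk_motion_sd_px", "sensor_noise_sd",
               "attenuation_mu_per_um")) {
    stopifnot_scalar(cfg[[nm]], nm, positive = FALSE)
    if (cfg[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  thick_px <- round(cfg$plate_thickness_um / cfg$pixel_dz_um)
  if (cfg$surface_row + thick_px >= cfg$grid_nz) {
    stop("surface_row + plate thickness must fit inside the grid", call. = FALSE)
  }
  if (length(cfg$layer_reflectivities) != 4L) {
    stop("'layer_reflectivities' needs dorsal/intermediate/ventral/bed entries",
         call. = FALSE)
  }
  for (m in cfg$maz_list) {
    if (is.null(m$x_px) || is.null(m$depth_um) || is.null(m$top_width_um)) {
      stop("each MAZ needs x_px, depth_um, top_width_um", call. = FALSE)
    }
    if (m$depth_um > cfg$plate_thickness_um) {
      stop("MAZ depth exceeds plate thickness", call. = FALSE)
    }
  }
  invisible(cfg)
}

# Columns covered by the inverted-pyramid cross-section at depth offset d
# (0 = surface row); `cx` is the real-valued aperture center.
maz_cols_at <- function(cx, width_px, depth_px, d) {
  hw <- ((width_px - 1) / 2) * (1 - d / depth_px)
  lo <- ceiling(cx - hw - 0.5 - 1e-9)
  hi <- floor(cx + hw + 0.5 + 1e-9)
  seq.int(lo, hi)
}

#' Build the static phantom geometry and reflectivity map
#'
#' Lays out the layered nail plate (dorsal/intermediate/ventral) over the
#' nail bed, carves the configured inverted-pyramid MAZ voids below the
#' surface, and returns the reflectivity map together with the ground-truth
#' masks and geometry.
#'
#' @param config a [phantom_config()].
#' @return An object of class `ground_truth`: `reflectivity` matrix,
#'   `surface_row` and `bed_row` per-column vectors, logical `plate_mask`
#'   and `maz_mask`, a `maz_geometry` data frame, and the config.
#' @export
build_static_phantom <- function(config) {
  validate_phantom_config(config)
  nz <- config$grid_nz; nx <- config$grid_nx
  surf <- round(config$surface_row + config$surface_slope_px_per_col * (seq_len(nx) - 1))
  if (any(surf < 1L) || any(surf > nz)) stop("surface leaves the grid", call. = FALSE)
  thick_px <- round(config$plate_thickness_um / config$pixel_dz_um)
  bed <- surf + thick_px                       # first nail-bed row per column
  if (any(bed > nz)) stop("nail bed leaves the grid", call. = FALSE)

  rows <- matrix(seq_len(nz), nz, nx)
  surfm <- matrix(surf, nz, nx, byrow = TRUE)
  bedm <- matrix(bed, nz, nx, byrow = TRUE)
  plate <- rows >= surfm & rows < bedm

  refl <- matrix(0, nz, nx)
  lr <- config$layer_reflectivities
  fr <- config$layer_fractions / sum(config$layer_fractions)
  d_below <- rows - surfm                       # 0 at surface row
  cut1 <- round(fr[1] * thick_px); cut2 <- round((fr[1] + fr[2]) * thick_px)
  refl[plate & d_below < cut1] <- lr[[1]]
  refl[plate & d_below >= cut1 & d_below < cut2] <- lr[[2]]
  refl[plate & d_below >= cut2] <- lr[[3]]
  refl[rows >= bedm] <- lr[[4]]

  maz <- matrix(FALSE, nz, nx)
  geom <- list()
  for (m in config$maz_list) {
    depth_px <- round(m$depth_um / config$pixel_dz_um)
    width_px <- round(m$top_width_um / config$pixel_dx_um)
    cx <- m$x_px
    top_cols <- maz_cols_at(cx, width_px, depth_px, 0)
    if (min(top_cols) < 1L || max(top_cols) > nx) {
      stop("MAZ aperture wider than grid", call. = FALSE)
    }
    s0 <- surf[round(cx)]
    this <- matrix(FALSE, nz, nx)
    for (d in 0:depth_px) {
      cols <- maz_cols_at(cx, width_px, depth_px, d)
      cols <- cols[cols >= 1L & cols <= nx]
      this[s0 + d, cols] <- TRUE
    }
    if (any(this & maz)) stop("overlapping MAZs", call. = FALSE)
    maz <- maz | this
    geom[[length(geom) + 1L]] <- data.frame(
      x_px = cx, depth_um = m$depth_um, top_width_um = m$top_width_um,
      depth_px = depth_px, width_px = width_px,
      apex_row = s0 + depth_px, surface_row = s0,
      energy_mJ = if (is.null(m$energy_mJ)) NA_real_ else m$energy_mJ)
  }
  refl[maz] <- config$maz_reflectivity

  structure(
    list(reflectivity = refl, surface_row = surf, bed_row = bed,
         plate_mask = plate, maz_mask = maz,
         maz_geometry = if (length(geom)) do.call(rbind, geom) else
           data.frame(x_px = numeric(), depth_um = numeric(),
                      top_width_um = numeric(), depth_px = numeric(),
                      width_px = numeric(), apex_row = numeric(),
                      surface_row = numeric(), energy_mJ = numeric()),
         config = config),
    class = "ground_truth")
}

#' Explicit finite-difference diffusion step(s)
#'
#' Marches `dC/dt = D * laplacian(C)` on an arbitrary domain with no-flux
#' (mirror) conditions at domain edges, optional Dirichlet source cells held
#' at a constant value, and optional absorbing cells (ghost value 0) below
#' the domain. Sub-steps internally to satisfy the CFL stability bound
#' `D * dt * (1/dx^2 + 1/dz^2) <= 1/4`.
#'
#' @param C initial concentration matrix (same shape as `domain`).
#' @param domain logical matrix of diffusing cells.
#' @param D diffusivity (um^2/s).
#' @param dt_total time to advance (s).
#' @param dx,dz pixel pitch (um).
#' @param source_mask logical matrix of Dirichlet cells (held at
#'   `source_value`), or `NULL`.
#' @param source_value Dirichlet value.
#' @param absorb_below logical matrix: domain cells whose lower neighbour is
#'   an absorbing boundary (ghost concentration 0), or `NULL`.
#' @return The advanced concentration matrix.
#' @export
diffuse_field <- function(C, domain, D, dt_total, dx, dz,
                          source_mask = NULL, source_value = 1,
                          absorb_below = NULL) {
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (dt_total <= 0 || D == 0) {
    if (!is.null(source_mask)) C[source_mask] <- source_value
    C[!domain] <- 0
    return(C)
  }
  nz <- nrow(C); nx <- ncol(C)
  cfl <- 0.25 / (D * (1 / dx^2 + 1 / dz^2))
  nsub <- max(1L, ceiling(dt_total / cfl))
  dt <- dt_total / nsub

  up_in <- rbind(domain[1, , drop = FALSE], domain[-nz, , drop = FALSE])
  dn_in <- rbind(domain[-1, , drop = FALSE], domain[nz, , drop = FALSE])
  lf_in <- cbind(domain[, 1, drop = FALSE], domain[, -nx, drop = FALSE])
  rt_in <- cbind(domain[, -1, drop = FALSE], domain[, nx, drop = FALSE])
  # neighbour-on-edge rows/cols of the grid itself are mirrored (no-flux)
  up_in[1, ] <- FALSE; dn_in[nz, ] <- FALSE
  lf_in[, 1] <- FALSE; rt_in[, nx] <- FALSE
  absorb <- if (is.null(absorb_below)) matrix(FALSE, nz, nx) else absorb_below

  if (!is.null(source_mask)) C[source_mask] <- source_value
  C[!domain] <- 0
  for (k in seq_len(nsub)) {
    Cu <- rbind(C[1, , drop = FALSE], C[-nz, , drop = FALSE])
    Cd <- rbind(C[-1, , drop = FALSE], C[nz, , drop = FALSE])
    Cl <- cbind(C[, 1, drop = FALSE], C[, -nx, drop = FALSE])
    Cr <- cbind(C[, -1, drop = FALSE], C[, nx, drop = FALSE])
    Cu[!up_in] <- C[!up_in]
    Cd[!dn_in] <- C[!dn_in]
    Cd[absorb] <- 0
    Cl[!lf_in] <- C[!lf_in]
    Cr[!rt_in] <- C[!rt_in]
    lap <- (Cu + Cd - 2 * C) / dz^2 + (Cl + Cr - 2 * C) / dx^2
    C <- C + D * dt * lap
    if (!is.null(source_mask)) C[source_mask] <- source_value
    C[!domain] <- 0
  }
  C
}

# Dirichlet source cells: plate cells adjacent to a MAZ interior plus the
# exposed surface (topmost plate cell of every column).
source_mask_for <- function(truth) {
  domain <- truth$plate_mask & !truth$maz_mask
  nz <- nrow(domain); nx <- ncol(domain)
  m <- truth$maz_mask
  near_maz <- rbind(m[-1, , drop = FALSE], m[nz, , drop = FALSE]) |
    rbind(m[1, , drop = FALSE], m[-nz, , drop = FALSE]) |
    cbind(m[, -1, drop = FALSE], m[, nx, drop = FALSE]) |
    cbind(m[, 1, drop = FALSE], m[, -nx, drop = FALSE])
  rows <- matrix(seq_len(nz), nz, nx)
  surfm <- matrix(truth$surface_row, nz, nx, byrow = TRUE)
  src <- (near_maz & domain) | (domain & rows == surfm)
  src
}

#' Simulate the drug-concentration field
#'
#' Solves the diffusion equation on the nail plate with a constant
#' concentration source on the MAZ walls and the exposed surface, no-flux
#' lateral edges and an absorbing nail-bed boundary. Concentration is zero
#' for all times at or before drug application (t <= 0).
#'
#' @param truth a `ground_truth` from [build_static_phantom()].
#' @param config the phantom config (supplies D, source strength, pitches).
#' @param times nondecreasing vector of seconds relative to drug application.
#' @return A list of concentration matrices, one per requested time.
#' @export
simulate_concentration <- function(truth, config, times) {
  if (any(diff(times) < 0)) stop("times must be nondecreasing", call. = FALSE)
  nz <- config$grid_nz; nx <- config$grid_nx
  domain <- truth$plate_mask & !truth$maz_mask
  src <- source_mask_for(truth)
  rows <- matrix(seq_len(nz), nz, nx)
  bedm <- matrix(truth$bed_row, nz, nx, byrow = TRUE)
  absorb <- domain & (rows + 1L >= bedm) &
    !rbind(domain[-1, , drop = FALSE], domain[nz, , drop = FALSE])
  D <- config$diffusion_coefficient_um2_per_s
  S <- config$source_strength

  out <- vector("list", length(times))
  C <- matrix(0, nz, nx)
  t_cur <- 0
  for (i in seq_along(times)) {
    ti <- times[i]
    if (ti <= 0) {
      out[[i]] <- matrix(0, nz, nx)
      next
    }
    if (t_cur == 0) { C[src] <- S }            # source switches on at t = 0+
    if (ti > t_cur) {
      C <- diffuse_field(C, domain, D, ti - t_cur, config$pixel_dx_um,
                         config$pixel_dz_um, source_mask = src,
                         source_value = S, absorb_below = absorb)
      t_cur <- ti
    }
    out[[i]] <- C
  }
  out
}

#' Render a speckled B-scan series from phantom ground truth
#'
#' Per frame, intensity = reflectivity x exponential depth attenuation x a
#' cumulative shadow factor from the concentration above x fully developed
#' speckle. Speckle is the intensity of a spatially low-pass-filtered
#' complex-Gaussian field (exponential marginal); the field is blended
#' AR(1)-style between frames so the frame-to-frame intensity correlation is
#' `exp(-decorrelation_gain * C * dt)` per pixel. Each non-reference frame
#' receives an integer bulk axial shift and additive sensor noise; the whole
#' series is normalized to `[0, 1]`.
#'
#' @param truth a `ground_truth`.
#' @param concentrations list of concentration matrices for the
#'   post-application frames (length `n_post_frames`), or `NULL` for none.
#' @param config the phantom config.
#' @return A `bscan_series`; ground-truth bulk shifts are stored in
#'   `metadata$bulk_shift_px`.
#' @export
render_series <- function(truth, concentrations, config) {
  nz <- config$grid_nz; nx <- config$grid_nx
  n_pre <- config$n_pre_frames; n_post <- config$n_post_frames
  n_tot <- n_pre + 1L + n_post
  dt <- config$frame_interval_s
  times <- (seq_len(n_tot) - n_pre - 1L) * dt
  if (!is.null(concentrations) && length(concentrations) != n_post) {
    stop("need one concentration field per post-application frame", call. = FALSE)
  }

  rows <- matrix(seq_len(nz), nz, nx)
  surfm <- matrix(truth$surface_row, nz, nx, byrow = TRUE)
  depth_um <- pmax(rows - surfm, 0) * config$pixel_dz_um
  M <- truth$reflectivity * exp(-config$attenuation_mu_per_um * depth_um)

  zeroC <- matrix(0, nz, nx)
  conc_at <- function(i) {
    j <- i - n_pre - 1L
    if (j >= 1L && !is.null(concentrations)) concentrations[[j]] else zeroC
  }

  with_seed(config$seed, {
    kern <- if (config$speckle) {
      speckle_kernel_fft(nz, nx, config$psf_sigma_z_px, config$psf_sigma_x_px)
    } else NULL
    new_field <- function() fft_filter(matrix(stats::rnorm(nz * nx), nz, nx), kern)
    re <- NULL; im <- NULL
    frames <- vector("list", n_tot)
    shifts <- integer(n_tot)
    for (i in seq_len(n_tot)) {
      Ck <- conc_at(i)
      if (config$speckle) {
        if (i == 1L) {
          re <- new_field(); im <- new_field()
        } else {
          a <- exp(-config$decorrelation_gain * Ck * dt / 2)  # field AR coeff
          if (any(a < 1)) {
            b <- sqrt(pmax(1 - a^2, 0))
            re <- a * re + b * new_field()
            im <- a * im + b * new_field()
          }
        }
        speck <- (re^2 + im^2) / 2
      } else {
        speck <- 1
      }
      cs <- apply(Ck, 2, cumsum)
      shadow <- exp(-config$shadow_gain *
                      rbind(rep(0, nx), cs[-nz, , drop = FALSE]))
      I <- M * shadow * speck
      s <- if (i == n_pre + 1L || config$bulk_motion_sd_px == 0) 0L else
        as.integer(round(stats::rnorm(1, 0, config$bulk_motion_sd_px)))
      shifts[i] <- s
      if (s != 0L) I <- shift_mat_rows(I, s)
      if (config$sensor_noise_sd > 0) {
        I <- I + matrix(stats::rnorm(nz * nx, 0, config$sensor_noise_sd), nz, nx)
      }
      frames[[i]] <- pmax(I, 0)
    }
    # display window: clip at a high percentile so the exponential speckle
    # tail does not compress the usable dynamic range
    hi <- if (config$speckle) {
      stats::quantile(unlist(lapply(frames, as.numeric)), 0.995, names = FALSE)
    } else {
      max(vapply(frames, max, numeric(1)))
    }
    if (!is.finite(hi) || hi <= 0) hi <- 1
    frames <- lapply(frames, function(f) pmin(f / hi, 1))
    bscan_series(frames, config$pixel_dz_um, config$pixel_dx_um, times,
                 reference_index = n_pre + 1L,
                 metadata = list(seed = config$seed,
                                 bulk_shift_px = shifts,
                                 intensity_window_raw = c(0, hi)))
  })
}

#' Built-in phantom presets
#'
#' `liquid_like` and `cream_like` share geometry (three 50 mJ-scale MAZs)
#' and differ in diffusivity (liquid diffuses faster, emulating its earlier
#' observed onset); `static` has the same geometry but no drug (null
#' control); `four_energies` renders four single-MAZ scans with the
#' penetration depth / aperture presets 372/321/290/255 um and
#' 203/183/171/137 um labelled 50/40/30/20 mJ.
#'
#' @param preset one of `"liquid_like"`, `"cream_like"`, `"static"`,
#'   `"four_energies"`.
#' @param seed RNG seed.
#' @param speckle render speckle (`FALSE` gives the noise-free intensity).
#' @param n_post_frames,n_pre_frames override the preset frame counts.
#' @return For the time-series presets, `list(series, truth, config)`; for
#'   `four_energies`, a list of four such lists (one per energy).
#' @export
make_fixture <- function(preset = c("liquid_like", "cream_like", "static",
                                    "four_energies"),
                         seed = 1, speckle = TRUE,
                         n_post_frames = 50, n_pre_frames = 10) {
  preset <- match.arg(preset)
  three_mazs <- list(
    list(x_px = 40, depth_um = 372, top_width_um = 203, energy_mJ = 50),
    list(x_px = 100, depth_um = 372, top_width_um = 203, energy_mJ = 50),
    list(x_px = 160, depth_um = 372, top_width_um = 203, energy_mJ = 50))
  base <- function(...) {
    phantom_config(maz_list = three_mazs, seed = seed, speckle = speckle,
                   n_post_frames = n_post_frames, n_pre_frames = n_pre_frames,
                   ...)
  }
  if (preset == "four_energies") {
    depths <- c(372, 321, 290, 255)
    widths <- c(203, 183, 171, 137)
    energies <- c(50, 40, 30, 20)
    out <- vector("list", 4L)
    for (k in 1:4) {
      cfg <- phantom_config(
        grid_nx = 120,
        maz_list = list(list(x_px = 60, depth_um = depths[k],
                             top_width_um = widths[k], energy_mJ = energies[k])),
        seed = seed + k - 1L, speckle = speckle,
        n_pre_frames = 0L, n_post_frames = 1L)
      truth <- build_static_phantom(cfg)
      series <- render_series(truth, list(matrix(0, cfg$grid_nz, cfg$grid_nx)), cfg)
      out[[k]] <- list(series = series, truth = truth, config = cfg,
                       energy_mJ = energies[k])
    }
    return(out)
  }
  cfg <- switch(preset,
    liquid_like = base(diffusion_coefficient_um2_per_s = 300, source_strength = 1),
    cream_like  = base(diffusion_coefficient_um2_per_s = 60, source_strength = 1),
    static      = base(diffusion_coefficient_um2_per_s = 0, source_strength = 0))
  truth <- build_static_phantom(cfg)
  conc <- if (preset == "static") {
    replicate(cfg$n_post_frames, matrix(0, cfg$grid_nz, cfg$grid_nx),
              simplify = FALSE)
  } else {
    post_times <- seq_len(cfg$n_post_frames) * cfg$frame_interval_s
    simulate_concentration(truth, cfg, post_times)
  }
  series <- render_series(truth, conc, cfg)
  list(series = series, truth = truth, config = cfg, concentrations = conc)
}
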