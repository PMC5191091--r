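# End-to-end driver: phantom/reader -> segmentation -> speckle variance ->
# morphometry -> diffusion quantification, with a provenance manifest.
# The numbered scripts under analysis/ are thin narrative wrappers over
# this function and the module functions it calls.

#' Run the full trans-nail SV-OCT pipeline
#'
#' Wires the modules together for one input: load or simulate a B-scan
#' series, segment and realign it to the reference nail surface, detect and
#' measure MAZs, compute the thresholded shadow-corrected SV stack, place
#' the three analysis regions, and quantify diffusion. Writes CSV reports
#' and a JSON provenance manifest (config + seed) to `outdir`; outputs are
#' byte-identical across runs with the same configuration and seed.
#'
#' @param preset phantom preset name (see [make_fixture()]), or `NULL` when
#'   `input_path` is given.
#' @param input_path path to a series TIFF (with sidecar) instead of a
#'   preset.
#' @param policy MAZ-interior mask policy: `"exclude_maz"` (liquid) or
#'   `"include_maz"` (cream).
#' @param gamma shadow-correction gamma (`"auto"` or a positive scalar).
#' @param exponent_sign shadow-correction exponent sign, `+1` or `-1`.
#' @param threshold_policy `"paper_fixed"` (0.05) or `"percentile"`.
#' @param square_size_px ROI square side.
#' @param expected_thickness_um,tolerance_um nail-bed search window.
#' @param seed RNG seed for simulated inputs.
#' @param outdir output directory (created); `NULL` to skip writing.
#' @param morphometry_only stop after the MAZ energy summary.
#' @param write_overlays also write SV-OCT overlay PNGs for a few frames.
#' @return Invisibly, a list with the intermediate and final results
#'   (`series`, `surface`, `mask`, `maz_measurements`, `threshold`,
#'   `sv_post`, `timecourse`, ...).
#' @export
run_pipeline <- function(preset = "liquid_like", input_path = NULL,
                         policy = c("exclude_maz", "include_maz"),
                         gamma = "auto", exponent_sign = +1,
                         threshold_policy = c("paper_fixed", "percentile"),
                         square_size_px = 10,
                         expected_thickness_um = 600, tolerance_um = 150,
                         seed = 1, outdir = NULL,
                         morphometry_only = FALSE, write_overlays = FALSE) {
  policy <- match.arg(policy)
  threshold_policy <- match.arg(threshold_policy)
  if (!is.null(preset) && !is.null(input_path)) {
    stop("give exactly one input source (preset or input_path)", call. = FALSE)
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(outdir)) {
      utils::write.table(df, file.path(outdir, name), sep = ",",
                         row.names = FALSE, qmethod = "double", na = "")
    }
  }
  provenance <- list(preset = preset, input_path = input_path, policy = policy,
                     gamma = gamma, exponent_sign = exponent_sign,
                     threshold_policy = threshold_policy,
                     square_size_px = square_size_px, seed = seed,
                     package_version = as.character(utils::packageVersion("nailsv")))

  if (identical(preset, "four_energies")) {
    scans <- make_fixture("four_energies", seed = seed)
    meas <- do.call(rbind, lapply(scans, function(sc) {
      fr <- get_bscan(sc$series, n_frames(sc$series))
      surf <- detect_surface(fr)
      cands <- detect_mazs(fr, surf)
      if (length(cands) == 0L) return(NULL)
      do.call(rbind, lapply(cands, function(cd)
        measure_maz(fr, surf, cd, energy_mJ = sc$energy_mJ)))
    }))
    summary <- summarize_by_energy(meas)
    emit(meas, "maz_measurements.csv")
    emit(summary, "maz_by_energy.csv")
    if (!is.null(outdir)) {
      jsonlite::write_json(provenance, file.path(outdir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    return(invisible(list(maz_measurements = meas, maz_by_energy = summary,
                          scans = scans, provenance = provenance)))
  }

  fixture <- NULL
  if (!is.null(input_path)) {
    series <- read_series(input_path)
  } else {
    fixture <- make_fixture(preset, seed = seed)
    series <- fixture$series
  }

  ref_frame <- get_bscan(series, series$reference_index)
  surface <- detect_surface(ref_frame)
  realigned <- realign_series(series, surface)
  # intact (crater-bridged) surface for thickness-referenced steps
  surface_b <- surface
  surface_b$row <- bridge_surface(surface$row)$row
  bed <- detect_nail_bed(ref_frame, surface_b, expected_thickness_um, tolerance_um)

  cands <- detect_mazs(ref_frame, surface)
  maz_mask <- matrix(FALSE, nrow(ref_frame$intensity), ncol(ref_frame$intensity))
  for (cd in cands) maz_mask <- maz_mask | cd$mask
  maz_measurements <- if (length(cands)) {
    do.call(rbind, lapply(cands, function(cd) measure_maz(ref_frame, surface, cd)))
  } else NULL
  mask <- build_mask(surface_b, bed, maz_mask, policy)

  params <- shadow_params(gamma = gamma, exponent_sign = exponent_sign)
  threshold <- estimate_noise_threshold(realigned, threshold_policy,
                                        mask = mask, shadow = params)
  sv_post <- sv_series(realigned, params, mask, threshold, frames = "post")
  sv_pre <- sv_series(realigned, params, mask, threshold, frames = "pre")

  maz_geom <- if (!is.null(fixture)) fixture$truth$maz_geometry else {
    if (is.null(maz_measurements) || nrow(maz_measurements) == 0L) {
      stop("no MAZs detected: cannot place analysis regions", call. = FALSE)
    }
    data.frame(x_px = maz_measurements$apex_x,
               apex_row = maz_measurements$apex_z,
               surface_row = surface$row[pmin(pmax(maz_measurements$apex_x, 1),
                                              length(surface$row))],
               width_px = maz_measurements$diameter_um / series$pixel_dx_um)
  }
  rois <- place_rois(mask, maz_geom, square_size_px)
  tc <- quantify_diffusion(sv_post, sv_pre, rois, mask, surface_b,
                           series$pixel_dz_um)

  if (!is.null(outdir)) {
    write_timecourse_csv(tc, file.path(outdir, "timecourse.csv"))
    emit(data.frame(region_label = names(tc$onset_s),
                    onset_s = unlist(tc$onset_s),
                    saturation_s = unlist(tc$saturation_s)),
         "onset_saturation.csv")
    if (!is.null(maz_measurements)) emit(maz_measurements, "maz_measurements.csv")
    emit(as.data.frame(rois), "rois.csv")
    prov <- c(provenance, list(threshold = threshold,
                               n_frames = n_frames(series),
                               motion_corrupted = sum(realigned$metadata$motion_corrupted)))
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    if (write_overlays && length(sv_post) > 0L) {
      pick <- unique(round(seq(1, length(sv_post), length.out = 4)))
      for (i in pick) {
        write_overlay(get_bscan(realigned, realigned$reference_index),
                      sv_post[[i]],
                      file.path(outdir, sprintf("overlay_t%04.1fs.png",
                                                sv_post[[i]]$timestamp_s)))
      }
    }
  }
  invisible(list(series = series, realigned = realigned, surface = surface,
                 bed = bed, mask = mask, maz_measurements = maz_measurements,
                 threshold = threshold, sv_post = sv_post, sv_pre = sv_pre,
                 rois = rois, timecourse = tc, fixture = fixture,
                 provenance = provenance))
}
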