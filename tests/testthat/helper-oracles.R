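# Independent oracles and small shared fixtures, kept free of the package's
# own code paths wherever they serve as a cross-check.

# Compact phantom used by fast unit tests (no MAZs unless added).
small_config <- function(...) {
  args <- utils::modifyList(
    list(grid_nz = 80, grid_nx = 60, surface_row = 10,
         plate_thickness_um = 350, n_pre_frames = 2, n_post_frames = 3,
         bulk_motion_sd_px = 0),
    list(...))
  do.call(phantom_config, args)
}

# Brute-force explicit diffusion stencil: scalar loops over cells and
# sub-steps, mirroring neighbours outside the domain and an absorbing ghost
# below flagged cells. Sub-step count must match the solver's CFL rule.
oracle_diffuse <- function(C, domain, D, dt_total, dx, dz,
                           src = NULL, sval = 1, absorb = NULL) {
  nz <- nrow(C); nx <- ncol(C)
  if (is.null(absorb)) absorb <- matrix(FALSE, nz, nx)
  cfl <- 0.25 / (D * (1 / dx^2 + 1 / dz^2))
  nsub <- max(1L, ceiling(dt_total / cfl))
  dt <- dt_total / nsub
  if (!is.null(src)) C[src] <- sval
  C[!domain] <- 0
  for (step in seq_len(nsub)) {
    out <- C
    for (i in seq_len(nz)) {
      for (j in seq_len(nx)) {
        if (!domain[i, j]) { out[i, j] <- 0; next }
        up <- if (i > 1 && domain[i - 1, j]) C[i - 1, j] else C[i, j]
        dn <- if (absorb[i, j]) 0 else
          if (i < nz && domain[i + 1, j]) C[i + 1, j] else C[i, j]
        lf <- if (j > 1 && domain[i, j - 1]) C[i, j - 1] else C[i, j]
        rt <- if (j < nx && domain[i, j + 1]) C[i, j + 1] else C[i, j]
        lap <- (up + dn - 2 * C[i, j]) / dz^2 + (lf + rt - 2 * C[i, j]) / dx^2
        out[i, j] <- C[i, j] + D * dt * lap
      }
    }
    C <- out
    if (!is.null(src)) C[src] <- sval
    C[!domain] <- 0
  }
  C
}

# Unsimplified two-sample speckle-variance expression: the RMS deviation of
# the two intensities from their mean.
oracle_sv <- function(a, b) {
  m <- (a + b) / 2
  sqrt(((a - m)^2 + (b - m)^2) / 2)
}
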