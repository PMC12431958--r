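#' Inverse chirp Z-transform onto a zoomed time grid
#'
#' Evaluates the band-limited inverse transform of frequency-domain spectra
#' on an arbitrary uniform time window, independent of the frequency
#' sampling:
#' `x(t_k) = df * sum_n S(f_n) exp(+i 2 pi f_n t_k)`.
#' This is the chirp-Z contour evaluation of the inverse DFT; it is computed
#' as a single complex matrix product over all paths at once. With the
#' degenerate parameters `f_min = df`, `t0 = 0`, `t1 = 1/df` and
#' `n_time = n_freq` it reduces (up to the constant `df`) to the inverse DFT
#' of the spectrum.
#'
#' @param S Complex matrix (paths x frequencies) or a complex vector.
#' @param sweep The [freq_sweep()] the spectra were sampled on.
#' @param t0_ns,t1_ns Time-window edges in ns (samples at `t0`, spacing
#'   `(t1 - t0)/n_time`, excluding `t1`).
#' @param n_time Number of time samples.
#' @return List with `t_ns` (time grid) and complex `signal` matrix
#'   (paths x time).
#' @export
iczt <- function(S, sweep, t0_ns = 0, t1_ns = 3, n_time = 1024L) {
  stopifnot(t1_ns > t0_ns, n_time >= 8)
  if (is.vector(S)) S <- matrix(S, nrow = 1L)
  stopifnot(ncol(S) == sweep$n_points)
  dt <- (t1_ns - t0_ns) / n_time
  t_ns <- t0_ns + (seq_len(n_time) - 1L) * dt
  df <- sweep$freq_ghz[2L] - sweep$freq_ghz[1L]
  E <- exp(2i * pi * outer(sweep$freq_ghz, t_ns))
  list(t_ns = t_ns, signal = (S %*% E) * df)
}

#' Transform one path spectrum to a time-domain envelope signal
#'
#' The band occupies positive frequencies only, so the inverse transform is
#' an analytic-type signal whose magnitude is the pulse envelope used for
#' arrival-time picking. If the global envelope peak falls on the first or
#' last time sample the physical delay likely lies outside the window; this
#' is flagged rather than silently accepted.
#'
#' @param spectrum Complex vector over the sweep.
#' @inheritParams iczt
#' @return An object of class `time_signal`: `t_ns`, real `amplitude`
#'   (envelope), and `peak_at_edge` flag.
#' @export
to_time_domain <- function(spectrum, sweep, t0_ns = 0, t1_ns = 3,
                           n_time = 1024L) {
  z <- iczt(spectrum, sweep, t0_ns, t1_ns, n_time)
  amp <- as.numeric(Mod(z$signal[1L, ]))
  ip <- which.max(amp)
  structure(
    list(t_ns = z$t_ns, amplitude = amp,
         peak_at_edge = any(amp > 0) && (ip == 1L || ip == n_time)),
    class = "time_signal"
  )
}

# Arrival times for a batch of envelope rows: global maximum refined by
# 3-point parabolic interpolation (exact for a locally quadratic envelope).
peak_times <- function(amp, t_ns) {
  if (is.vector(amp)) amp <- matrix(amp, nrow = 1L)
  dt <- t_ns[2L] - t_ns[1L]
  ip <- max.col(amp, ties.method = "first")
  tp <- t_ns[ip]
  n <- ncol(amp)
  interior <- which(ip > 1L & ip < n)
  if (length(interior)) {
    i <- ip[interior]
    rows <- cbind(interior, i)
    y0 <- amp[cbind(interior, i - 1L)]
    y1 <- amp[rows]
    y2 <- amp[cbind(interior, i + 1L)]
    den <- y0 - 2 * y1 + y2
    delta <- ifelse(abs(den) > 0, 0.5 * (y0 - y2) / den, 0)
    tp[interior] <- tp[interior] + pmax(pmin(delta, 0.5), -0.5) * dt
  }
  tp
}

#' Estimate the arrival time of a time-domain signal
#'
#' Time of the global envelope maximum, refined by three-point parabolic
#' interpolation around the discrete peak.
#'
#' @param signal A [to_time_domain()] result (or a list with `t_ns` and
#'   `amplitude`).
#' @return Peak time in ns.
#' @export
estimate_arrival_time <- function(signal) {
  amp <- signal$amplitude
  if (all(amp == 0)) stop("no peak: signal is identically zero")
  peak_times(amp, signal$t_ns)
}

#' Invert an arrival-time difference to a path-average permittivity
#'
#' With propagation speed `c/sqrt(eps_r)` over path length `L`, the delay
#' relative to the equal-length air reference is
#' `dt = L (sqrt(eps_r) - 1)/c`, inverted as `eps_r = (1 + c dt / L)^2`.
#' Negative differences (noise) are clamped to `eps_r = 1`.
#'
#' @param dt_ns Arrival-time difference(s) vs. reference, ns.
#' @param L_mm Path length(s) `sqrt(d^2 + offset^2)`, mm.
#' @return Relative permittivity estimate(s), with attribute `clamped`
#'   giving the number of negative differences clamped.
#' @export
estimate_path_permittivity <- function(dt_ns, L_mm) {
  stopifnot(all(L_mm > 0))
  clamped <- sum(dt_ns < 0)
  eps <- (1 + C_MM_NS * pmax(dt_ns, 0) / L_mm)^2
  attr(eps, "clamped") <- clamped
  eps
}

# Precompute, per path, the linear pixel indices of its disk footprint on the
# grid (pixel centers within footprint_radius of the path midpoint). Reused
# across scans sharing one geometry/grid.
footprint_index <- function(paths, grid, footprint_radius_mm = 6) {
  r <- footprint_radius_mm
  px <- grid$pixel_mm
  lapply(seq_len(nrow(paths)), function(p) {
    cx <- paths$mid_x[p]
    cy <- paths$mid_y[p]
    ix_lo <- max(1L, as.integer(ceiling((cx - r) / px)))
    ix_hi <- min(grid$nx, as.integer(ceiling((cx + r) / px)))
    iy_lo <- max(1L, as.integer(ceiling((cy - r) / px)))
    iy_hi <- min(grid$ny, as.integer(ceiling((cy + r) / px)))
    if (ix_hi < ix_lo || iy_hi < iy_lo) return(integer(0))
    ix <- ix_lo:ix_hi
    iy <- iy_lo:iy_hi
    xc <- (ix - 0.5) * px
    yc <- (iy - 0.5) * px
    inside <- outer(yc - cy, xc - cx, function(a, b) a^2 + b^2) <= r^2
    (rep(ix, each = length(iy))[inside] - 1L) * grid$ny +
      rep(iy, times = length(ix))[inside]
  })
}

#' Map per-path permittivity estimates to the mid-plane image
#'
#' Each path's scalar estimate is painted on a disk footprint centered at the
#' path's mid-plane midpoint; overlapping footprints are resolved by the
#' unweighted mean. Pixels no footprint covers are set to the air baseline
#' 1.0 with coverage 0. Footprints falling entirely outside the grid are
#' skipped with a warning.
#'
#' @param estimates Data frame with `mid_x`, `mid_y` (mm) and `eps` columns;
#'   typically the path table augmented with estimates.
#' @param grid A [grid_spec()].
#' @param footprint_radius_mm Footprint disk radius (mm).
#' @param footprints Optional precomputed [footprint_index()] list.
#' @param meta Optional named list stored as scan metadata.
#' @return An object of class `recon_image`: `grid`, `epsilon_map`,
#'   `coverage` (per-pixel path counts) and `meta`.
#' @export
map_paths_to_image <- function(estimates, grid, footprint_radius_mm = 6,
                               footprints = NULL, meta = list()) {
  stopifnot(nrow(estimates) >= 1L)
  if (is.null(footprints))
    footprints <- footprint_index(estimates, grid, footprint_radius_mm)
  len <- lengths(footprints)
  if (any(len == 0L))
    warning(sum(len == 0L), " footprint(s) fall outside the grid; skipped")
  idx <- unlist(footprints, use.names = FALSE)
  w <- rep(estimates$eps, len)
  npix <- grid$ny * grid$nx
  counts <- tabulate(idx, nbins = npix)
  sums <- numeric(npix)
  agg <- rowsum(w, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  eps <- ifelse(counts > 0L, sums / pmax(counts, 1L), 1.0)
  structure(
    list(grid = grid,
         epsilon_map = matrix(eps, grid$ny, grid$nx),
         coverage = matrix(counts, grid$ny, grid$nx),
         meta = meta),
    class = "recon_image"
  )
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf(
    "<recon_image> %d x %d px, coverage %d-%d, eps range [%.2f, %.2f]\n",
    x$grid$ny, x$grid$nx, min(x$coverage), max(x$coverage),
    min(x$epsilon_map), max(x$epsilon_map)
  ))
  invisible(x)
}

#' Reconstruct one scan from measured and reference spectra
#'
#' The full image-formation chain: both spectrum sets are transformed to the
#' time domain with the inverse chirp Z-transform, envelope peaks give
#' per-path arrival times, measurement-minus-reference differences are
#' inverted to path-average permittivities, and the estimates are mapped to
#' footprints on the mid-plane grid.
#'
#' @param spectra Complex matrix (paths x frequencies) of measurements.
#' @param references Complex matrix of equal-geometry air references.
#' @param paths Path table from [enumerate_paths()].
#' @param grid Output [grid_spec()].
#' @param sweep The [freq_sweep()] used.
#' @param t0_ns,t1_ns,n_time Time-window parameters for [iczt()].
#' @param footprint_radius_mm Footprint disk radius (mm).
#' @param footprints Optional precomputed [footprint_index()].
#' @param meta Scan metadata stored on the image.
#' @return A `recon_image`; `meta` additionally records the number of
#'   clamped (negative-difference) paths and of window-edge peaks.
#' @export
reconstruct_scan <- function(spectra, references, paths, grid,
                             sweep = freq_sweep(), t0_ns = 0, t1_ns = 3,
                             n_time = 1024L, footprint_radius_mm = 6,
                             footprints = NULL, meta = list()) {
  if (is.null(references)) stop("missing reference spectra for this scan")
  stopifnot(nrow(spectra) == nrow(paths), nrow(references) == nrow(paths))
  zm <- iczt(spectra, sweep, t0_ns, t1_ns, n_time)
  zr <- iczt(references, sweep, t0_ns, t1_ns, n_time)
  am <- Mod(zm$signal)
  ar <- Mod(zr$signal)
  t_meas <- peak_times(am, zm$t_ns)
  t_ref <- peak_times(ar, zr$t_ns)
  edge <- max.col(am, ties.method = "first")
  meta$n_edge_peaks <- sum(edge == 1L | edge == n_time)
  eps <- estimate_path_permittivity(t_meas - t_ref, paths$L_mm)
  meta$n_clamped <- attr(eps, "clamped")
  est <- paths
  est$eps <- as.numeric(eps)
  map_paths_to_image(est, grid, footprint_radius_mm, footprints, meta)
}

#' Forward-simulate and reconstruct a phantom in one call
#'
#' Convenience wrapper running [simulate_scan_spectra()],
#' [simulate_reference_spectra()] and [reconstruct_scan()] with consistent
#' geometry. Noise seeds for measurement and reference are derived from
#' `seed`.
#'
#' @param phantom Phantom to image.
#' @param geom Optional [build_array()] geometry (defaults to the standard
#'   array at the phantom's separation).
#' @param paths Optional path table (enumerated from `geom` if missing).
#' @param sweep A [freq_sweep()].
#' @param snr_db Measurement SNR in dB (`Inf` = noiseless).
#' @param seed Noise seed.
#' @param grid Output grid (defaults to the phantom grid).
#' @param ... Passed to [reconstruct_scan()].
#' @return A `recon_image` with view/density/separation metadata.
#' @export
simulate_and_reconstruct <- function(phantom, geom = NULL, paths = NULL,
                                     sweep = freq_sweep(), snr_db = Inf,
                                     seed = 1L, grid = NULL, ...) {
  if (is.null(grid)) grid <- phantom$grid
  if (is.null(geom)) geom <- build_array(grid, d = phantom$separation_mm)
  if (is.null(paths)) paths <- enumerate_paths(geom)
  spectra <- simulate_scan_spectra(phantom, paths, sweep, snr_db,
                                   derive_seed(seed, 1L))
  refs <- simulate_reference_spectra(paths$L_mm, sweep, snr_db,
                                     derive_seed(seed, 2L))
  reconstruct_scan(spectra, refs, paths, grid, sweep,
                   meta = list(view = phantom$view, density = phantom$density,
                               separation_mm = phantom$separation_mm),
                   ...)
}
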