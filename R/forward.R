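#' Speed of light in vacuum, mm/ns
#' @export
C_MM_NS <- 299.792458

#' Frequency sweep specification
#'
#' Ultra-wideband sweep over which per-path transmission is simulated and
#' measured; defaults span 0.1 to 8 GHz.
#'
#' @param f_min_ghz,f_max_ghz Band edges in GHz.
#' @param n_points Number of frequency samples.
#' @return An object of class `freq_sweep` with a `freq_ghz` vector.
#' @export
freq_sweep <- function(f_min_ghz = 0.1, f_max_ghz = 8, n_points = 161L) {
  stopifnot(f_min_ghz > 0, f_max_ghz > f_min_ghz, n_points >= 2)
  structure(
    list(f_min_ghz = f_min_ghz, f_max_ghz = f_max_ghz,
         n_points = as.integer(n_points),
         freq_ghz = seq(f_min_ghz, f_max_ghz, length.out = n_points)),
    class = "freq_sweep"
  )
}

#' Build the planar transmit/receive array geometry
#'
#' The transmitting plate carries 247 antennas on a 19 x 13 lattice and the
#' receiving plate 240 antennas on a 20 x 12 lattice, both spanning the full
#' system extent. Only the counts and the extent are fixed by the hardware
#' description; the lattice layout is this package's choice.
#'
#' @param grid A [grid_spec()] giving the system extent.
#' @param d Plate separation in mm.
#' @param tx_dims,rx_dims Lattice dimensions (nx, ny) per plate.
#' @param pairing_radius_mm Maximum lateral transmitter-receiver offset for a
#'   measured path.
#' @return An object of class `array_geometry` with `tx` and `rx` position
#'   matrices (columns x, y in mm), `d` and `pairing_radius_mm`.
#' @export
build_array <- function(grid, d = 60, tx_dims = c(19L, 13L),
                        rx_dims = c(20L, 12L), pairing_radius_mm = 25) {
  stopifnot(inherits(grid, "grid_spec"), d > 0, pairing_radius_mm > 0)
  lattice <- function(dims) {
    as.matrix(expand.grid(
      x = seq(0, grid$width_mm, length.out = dims[1L]),
      y = seq(0, grid$height_mm, length.out = dims[2L])
    ))
  }
  structure(
    list(tx = lattice(tx_dims), rx = lattice(rx_dims), d = d,
         pairing_radius_mm = pairing_radius_mm, grid = grid),
    class = "array_geometry"
  )
}

#' Enumerate measured transmitter-receiver paths
#'
#' Each transmitter is paired with every receiver within the lateral pairing
#' radius on the opposite plate. Ordering is transmitter-major, then receiver
#' index. The 3D path length accounts for the lateral offset:
#' `L = sqrt(d^2 + offset^2)`.
#'
#' @param geom An [build_array()] geometry.
#' @return A data frame with one row per path: `tx`, `rx` indices, lateral
#'   `dx`, `dy`, `offset_mm`, midpoint `mid_x`, `mid_y` (mm, on the
#'   mid-plane) and path length `L_mm`.
#' @export
enumerate_paths <- function(geom) {
  stopifnot(inherits(geom, "array_geometry"))
  r <- geom$pairing_radius_mm
  ntx <- nrow(geom$tx)
  nrx <- nrow(geom$rx)
  dx <- outer(geom$tx[, 1L], geom$rx[, 1L], "-")
  dy <- outer(geom$tx[, 2L], geom$rx[, 2L], "-")
  off <- sqrt(dx^2 + dy^2)
  keep <- which(t(off) <= r)  # transpose -> tx-major ordering
  rx_i <- (keep - 1L) %% nrx + 1L
  tx_i <- (keep - 1L) %/% nrx + 1L
  if (length(keep) == 0L || length(unique(tx_i)) < ntx)
    warning("some transmitters have no receiver within the pairing radius")
  offset <- off[cbind(tx_i, rx_i)]
  data.frame(
    tx = tx_i, rx = rx_i,
    dx = dx[cbind(tx_i, rx_i)], dy = dy[cbind(tx_i, rx_i)],
    offset_mm = offset,
    mid_x = (geom$tx[tx_i, 1L] + geom$rx[rx_i, 1L]) / 2,
    mid_y = (geom$tx[tx_i, 2L] + geom$rx[rx_i, 2L]) / 2,
    L_mm = sqrt(geom$d^2 + offset^2)
  )
}

#' Straight-ray propagation delays through a phantom
#'
#' Computes the time of flight along each straight transmitter-receiver
#' segment: `tau = (1/c) * integral of sqrt(eps_r) ds` over the 3D segment,
#' with the permittivity read from the 2D mid-plane map along the segment's
#' lateral projection (through-thickness homogeneity). The integral is a
#' midpoint rule with sample spacing at most half a pixel along the
#' projection; for laterally aligned paths it is exact.
#'
#' @param phantom A [generate_breast_phantom()] result (or any object with
#'   `grid` and `epsilon_map`).
#' @param paths Data frame from [enumerate_paths()] (or any frame with
#'   `mid_x`, `mid_y`, `dx`, `dy`, `offset_mm`, `L_mm`).
#' @return Numeric vector of delays in ns, one per path.
#' @export
path_delays <- function(phantom, paths) {
  grid <- phantom$grid
  sqrt_eps <- sqrt(phantom$epsilon_map)
  max_off <- max(paths$offset_mm, 0)
  n_s <- max(2L, as.integer(ceiling(max_off / (grid$pixel_mm / 2))))
  frac <- (seq_len(n_s) - 0.5) / n_s - 0.5   # centered fractions of the segment
  acc <- numeric(nrow(paths))
  for (fr in frac) {
    idx <- grid_linear_index(grid, paths$mid_x + fr * (-paths$dx),
                             paths$mid_y + fr * (-paths$dy))
    acc <- acc + sqrt_eps[idx]
  }
  paths$L_mm * (acc / n_s) / C_MM_NS
}

#' Single-path delay
#'
#' Convenience scalar wrapper around [path_delays()].
#' @param phantom Phantom as in [path_delays()].
#' @param pair One-row data frame describing the path.
#' @return Delay in ns.
#' @export
path_delay <- function(phantom, pair) {
  path_delays(phantom, pair[1L, , drop = FALSE])[1L]
}

# Raised-cosine (Hann) band-shaping amplitude over the sweep; identical for
# measurement and reference so peak alignment is unbiased.
band_window <- function(sweep) {
  u <- (sweep$freq_ghz - sweep$f_min_ghz) / (sweep$f_max_ghz - sweep$f_min_ghz)
  0.5 - 0.5 * cos(2 * pi * u)
}

# Complex spectra for a vector of delays: S(f) = A(f) exp(-i 2 pi f tau),
# plus complex white Gaussian noise at snr_db relative to mean band power.
spectra_from_delays <- function(tau, sweep, snr_db = Inf, seed = 1L) {
  A <- band_window(sweep)
  S <- exp(-2i * pi * outer(tau, sweep$freq_ghz)) *
    matrix(A, length(tau), sweep$n_points, byrow = TRUE)
  if (is.finite(snr_db)) {
    sigma <- sqrt(mean(A^2) / 10^(snr_db / 10))
    S <- S + withr::with_seed(seed, {
      n <- length(S)
      matrix(complex(real = rnorm(n, 0, sigma / sqrt(2)),
                     imaginary = rnorm(n, 0, sigma / sqrt(2))),
             nrow(S), ncol(S))
    })
  }
  S
}

#' Simulate transmission spectra for every path through a phantom
#'
#' Frequency-domain forward model: each path's spectrum is a band-shaped
#' pure delay, `S(f) = A(f) exp(-i 2 pi f tau)`, with `tau` from
#' [path_delays()] and additive complex white Gaussian noise at the stated
#' SNR (defined against mean spectral power of the noiseless signal).
#'
#' @param phantom Phantom to propagate through.
#' @param paths Path table from [enumerate_paths()].
#' @param sweep A [freq_sweep()].
#' @param snr_db Signal-to-noise ratio in dB; `Inf` for noiseless.
#' @param seed Noise seed.
#' @return Complex matrix, paths x frequencies.
#' @export
simulate_scan_spectra <- function(phantom, paths, sweep = freq_sweep(),
                                  snr_db = Inf, seed = 1L) {
  spectra_from_delays(path_delays(phantom, paths), sweep, snr_db, seed)
}

#' Simulate air-reference spectra
#'
#' Reference signals traverse the same geometry with air (`eps_r = 1`)
#' between the plates, so each path's reference delay is `L/c`.
#'
#' @param L_mm Path lengths in mm (vector; use `paths$L_mm` for per-path
#'   references, or a plate separation `d` for an aligned reference).
#' @inheritParams simulate_scan_spectra
#' @return Complex matrix, paths x frequencies.
#' @export
simulate_reference_spectra <- function(L_mm, sweep = freq_sweep(),
                                       snr_db = Inf, seed = 1L) {
  spectra_from_delays(L_mm / C_MM_NS, sweep, snr_db, seed)
}

#' Single-path spectrum
#'
#' @inheritParams simulate_scan_spectra
#' @param pair One-row path table.
#' @return Complex vector over the sweep.
#' @export
simulate_path_spectrum <- function(phantom, pair, sweep = freq_sweep(),
                                   snr_db = Inf, seed = 1L) {
  drop(simulate_scan_spectra(phantom, pair[1L, , drop = FALSE], sweep,
                             snr_db, seed))
}
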