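# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Scan contexts on the 4 mm (fast) and 2 mm (default) grids, noiseless.
ctx4 <- function() fixture("ctx4", function() {
  scan_context(grid_spec(pixel_mm = 4), snr_db = Inf)
})
ctx2 <- function() fixture("ctx2", function() {
  scan_context(grid_spec(pixel_mm = 2), snr_db = Inf)
})

with_snr <- function(ctx, snr_db) {
  ctx$snr_db <- snr_db
  ctx
}

# A phantom-shaped object with a uniform permittivity map covering the whole
# grid (a homogeneous slab between the plates).
uniform_phantom <- function(eps, grid, d = 60) {
  structure(
    list(grid = grid, epsilon_map = matrix(eps, grid$ny, grid$nx),
         breast_mask_true = matrix(TRUE, grid$ny, grid$nx),
         view = "LCC", density = "B", separation_mm = d, tumor = NULL,
         glandular_fraction = 0, semi_axes_mm = c(0, 0), seed = 0L),
    class = "breast_phantom"
  )
}

# A recon_image wrapped around an explicit matrix.
toy_image <- function(mat, pixel_mm = 2, meta = list()) {
  grid <- grid_spec(ncol(mat) * pixel_mm, nrow(mat) * pixel_mm, pixel_mm)
  structure(
    list(grid = grid, epsilon_map = mat,
         coverage = matrix(1L, nrow(mat), ncol(mat)), meta = meta),
    class = "recon_image"
  )
}

# Exhaustive minimum within-cluster-variance bipartition of a numeric vector
# (oracle for the 2-means operations; feasible for n <= 12).
exhaustive_bipartition <- function(values) {
  n <- length(values)
  best <- list(wcss = Inf, labels = NULL)
  for (code in seq_len(2^n - 2L)) {
    lab <- as.integer(intToBits(code)[seq_len(n)]) + 1L
    wcss <- sum(tapply(values, lab, function(v) sum((v - mean(v))^2)))
    if (wcss < best$wcss) best <- list(wcss = wcss, labels = lab)
  }
  # Normalize label identity: 1 = lower-mean cluster.
  m <- tapply(values, best$labels, mean)
  if (m[1L] > m[2L]) best$labels <- 3L - best$labels
  best
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

band_window_test <- function(sweep) mwbreast:::band_window(sweep)

# Tumor-side over contralateral-side CC breast-average ratio.
side_ratio <- function(eps_tumor_side, eps_other) eps_tumor_side / eps_other
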