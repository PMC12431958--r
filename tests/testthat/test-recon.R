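test_that("inverse chirp-Z basics: zero in, zero out; delays peak in place", {
  sweep <- freq_sweep()
  z <- iczt(complex(real = rep(0, sweep$n_points)), sweep)
  expect_true(all(Mod(z$signal) == 0))
  tau <- 0.5
  S <- mwbreast:::spectra_from_delays(tau, sweep)
  sig <- to_time_domain(drop(S), sweep)
  dt <- sig$t_ns[2] - sig$t_ns[1]
  expect_lt(abs(sig$t_ns[which.max(sig$amplitude)] - tau), dt + 1e-12)
  expect_false(sig$peak_at_edge)
  # Window that excludes the physical delay flags the edge peak.
  clipped <- to_time_domain(drop(S), sweep, t0_ns = 0, t1_ns = 0.15,
                            n_time = 64L)
  expect_true(clipped$peak_at_edge)
})

test_that("degenerate chirp-Z parameters reproduce the inverse DFT", {
  df <- 0.05
  n <- 16L
  sweep <- freq_sweep(f_min_ghz = df, f_max_ghz = n * df, n_points = n)
  set.seed(1)
  S <- complex(real = rnorm(n), imaginary = rnorm(n))
  # Uniform full-band grid: times k / ((n+1) df), k = 0..n.
  z <- iczt(S, sweep, t0_ns = 0, t1_ns = 1 / df, n_time = n + 1L)
  oracle <- df * fft(c(0 + 0i, S), inverse = TRUE)  # zero-padded at DC
  expect_lt(max(Mod(drop(z$signal) - oracle)) / max(Mod(oracle)), 1e-9)
})

test_that("parabolic refinement locates off-grid peaks", {
  sweep <- freq_sweep()
  tau <- 0.5123457  # deliberately between time samples
  S <- mwbreast:::spectra_from_delays(tau, sweep)
  sig <- to_time_domain(drop(S), sweep)
  dt <- sig$t_ns[2] - sig$t_ns[1]
  t_hat <- estimate_arrival_time(sig)
  # Fine-grid oracle: brute-force argmax on a ~150x oversampled local window.
  ip <- which.max(sig$amplitude)
  fine <- iczt(S, sweep, t0_ns = sig$t_ns[ip] - 2 * dt,
               t1_ns = sig$t_ns[ip] + 2 * dt, n_time = 600L)
  t_fine <- fine$t_ns[which.max(Mod(fine$signal[1, ]))]
  expect_lt(abs(t_hat - t_fine), 0.2 * dt)
  expect_lt(abs(t_hat - tau), 0.5 * dt)
  # Two pulses: the stronger one wins the global-maximum rule.
  S2 <- 1.0 * mwbreast:::spectra_from_delays(0.6, sweep) +
    0.5 * mwbreast:::spectra_from_delays(1.4, sweep)
  sig2 <- to_time_domain(drop(S2), sweep)
  expect_lt(abs(estimate_arrival_time(sig2) - 0.6), 2 * dt)
  zero <- sig
  zero$amplitude[] <- 0
  expect_error(estimate_arrival_time(zero), "no peak")
})

test_that("arrival-time differences invert to permittivity", {
  expect_equal(as.numeric(estimate_path_permittivity(0, 50)), 1)
  expect_equal(as.numeric(estimate_path_permittivity(100 / C_MM_NS, 50)), 9)
  expect_equal(as.numeric(estimate_path_permittivity(60 / C_MM_NS, 60)), 4)
  neg <- estimate_path_permittivity(c(-0.01, 0.1), c(50, 50))
  expect_equal(as.numeric(neg[1]), 1)
  expect_equal(attr(neg, "clamped"), 1L)
})

test_that("footprint mapping paints disks and averages overlaps", {
  g <- grid_spec(60, 60, 2)
  one <- data.frame(mid_x = 30, mid_y = 30, eps = 9)
  img <- map_paths_to_image(one, g, footprint_radius_mm = 6)
  # Brute-force disk membership over every pixel center.
  inside <- outer(g$y - 30, g$x - 30, function(a, b) a^2 + b^2) <= 36
  expect_equal(img$coverage > 0, inside)
  expect_true(all(img$epsilon_map[inside] == 9))
  expect_true(all(img$epsilon_map[!inside] == 1))
  expect_true(all(img$coverage[inside] == 1L))
  two <- data.frame(mid_x = c(28, 32), mid_y = c(30, 30), eps = c(4, 16))
  img2 <- map_paths_to_image(two, g, footprint_radius_mm = 6)
  overlap <- img2$coverage == 2L
  expect_true(any(overlap))
  expect_true(all(img2$epsilon_map[overlap] == 10))
  outside <- data.frame(mid_x = c(-50, 30), mid_y = c(-50, 30), eps = c(5, 9))
  expect_warning(map_paths_to_image(outside, g, footprint_radius_mm = 6),
                 "outside the grid")
})

test_that("the full chain recovers homogeneous slabs and air", {
  ctx <- ctx4()
  slab <- uniform_phantom(9, ctx$grid, d = 60)
  img <- image_phantom(slab, ctx, seed = 1L)
  cov <- img$coverage > 0
  expect_lt(max(abs(img$epsilon_map[cov] - 9) / 9), 0.02)
  air <- uniform_phantom(1, ctx$grid, d = 60)
  img_air <- image_phantom(air, ctx, seed = 1L)
  expect_equal(max(abs(img_air$epsilon_map - 1)), 0, tolerance = 1e-6)
})

test_that("a high-permittivity inclusion brightens its own footprint", {
  ctx <- ctx4()
  g <- ctx$grid
  ph <- uniform_phantom(5, g, d = 60)
  incl <- outer(g$y - 80, g$x - 60, function(a, b) a^2 + b^2) <= 20^2
  ph$epsilon_map[incl] <- 15
  img <- image_phantom(ph, ctx, seed = 1L)
  far <- outer(g$y - 80, g$x - 160, function(a, b) a^2 + b^2) <= 20^2
  expect_gt(mean(img$epsilon_map[incl]), mean(img$epsilon_map[far]))
})

test_that("reconstruction is order-independent and monotone in the phantom", {
  ctx <- ctx4()
  ph <- generate_breast_phantom(ctx$grid, density = "B", seed = 17L)
  paths <- mwbreast:::paths_at_separation(ctx, 60)[1:400, ]
  sweep <- ctx$sweep
  S <- simulate_scan_spectra(ph, paths, sweep)
  R <- simulate_reference_spectra(paths$L_mm, sweep)
  img <- reconstruct_scan(S, R, paths, ctx$grid, sweep)
  perm <- sample(nrow(paths))
  img_p <- reconstruct_scan(S[perm, ], R[perm, ], paths[perm, ], ctx$grid,
                            sweep)
  expect_equal(img_p$epsilon_map, img$epsilon_map)
  expect_equal(img_p$coverage, img$coverage)
  raised <- ph
  raised$epsilon_map[ph$breast_mask_true] <-
    ph$epsilon_map[ph$breast_mask_true] + 2
  S2 <- simulate_scan_spectra(raised, paths, sweep)
  img2 <- reconstruct_scan(S2, R, paths, ctx$grid, sweep)
  cov <- img$coverage > 0
  expect_true(all(img2$epsilon_map[cov] >= img$epsilon_map[cov] - 1e-9))
  expect_error(reconstruct_scan(S, NULL, paths, ctx$grid, sweep),
               "missing reference")
})
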