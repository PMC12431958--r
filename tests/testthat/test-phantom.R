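test_that("phantom generation is a pure function of seed and parameters", {
  g <- grid_spec(pixel_mm = 4)
  p1 <- generate_breast_phantom(g, density = "B", seed = 7L)
  p2 <- generate_breast_phantom(g, density = "B", seed = 7L)
  expect_identical(p1$epsilon_map, p2$epsilon_map)
  expect_identical(p1$breast_mask_true, p2$breast_mask_true)
  p3 <- generate_breast_phantom(g, density = "B", seed = 8L)
  expect_false(identical(p1$epsilon_map, p3$epsilon_map))
})

test_that("permittivity is 1 outside the breast and >= 1 everywhere", {
  g <- grid_spec(pixel_mm = 4)
  for (dens in c("A", "B", "C", "D")) {
    p <- generate_breast_phantom(g, density = dens, seed = 11L)
    expect_true(all(p$epsilon_map[!p$breast_mask_true] == 1))
    expect_true(all(p$epsilon_map >= 1))
  }
})

test_that("breast-average permittivity increases with density category", {
  g <- grid_spec(pixel_mm = 4)
  seeds <- 1:20
  means <- sapply(c("A", "B", "C", "D"), function(dens) {
    mean(sapply(seeds, function(s) {
      true_breast_average(generate_breast_phantom(
        g, density = dens, seed = s, semi_axes_mm = c(85, 65)))
    }))
  })
  expect_true(all(diff(means) > 0))
  # A vs D at matched seed and geometry: D always denser.
  for (s in seeds) {
    ea <- true_breast_average(generate_breast_phantom(
      g, density = "A", seed = s, semi_axes_mm = c(85, 65)))
    ed <- true_breast_average(generate_breast_phantom(
      g, density = "D", seed = s, semi_axes_mm = c(85, 65)))
    expect_gt(ed, ea)
  }
})

test_that("a tumor above the glandular band strictly raises the breast average", {
  g <- grid_spec(pixel_mm = 4)
  base <- generate_breast_phantom(g, density = "B", seed = 3L,
                                  semi_axes_mm = c(85, 65))
  tu <- tumor_spec(c(40, 80), c(10, 10), 25)
  with_tu <- generate_breast_phantom(g, density = "B", seed = 3L,
                                     semi_axes_mm = c(85, 65), tumor = tu)
  expect_gt(true_breast_average(with_tu), true_breast_average(base))
  # Relative (multiplicative) inclusion likewise; identity at zero contrast.
  rel <- tumor_spec(c(40, 80), c(10, 10), 1.2, relative = TRUE)
  expect_gt(true_breast_average(generate_breast_phantom(
    g, density = "B", seed = 3L, semi_axes_mm = c(85, 65), tumor = rel)),
    true_breast_average(base))
  null_tu <- tumor_spec(c(40, 80), c(10, 10), 1, relative = TRUE)
  expect_identical(generate_breast_phantom(
    g, density = "B", seed = 3L, semi_axes_mm = c(85, 65),
    tumor = null_tu)$epsilon_map, base$epsilon_map)
})

test_that("invalid phantom inputs are rejected", {
  g <- grid_spec(pixel_mm = 4)
  expect_error(generate_breast_phantom(g, glandular_fraction = 1.2),
               "glandular_fraction")
  expect_error(generate_breast_phantom(
    g, seed = 3L, semi_axes_mm = c(60, 50),
    tumor = tumor_spec(c(200, 150), c(5, 5), 25)),
    "tumor not inside breast")
  expect_error(tumor_spec(c(0, 0), c(-1, 5), 20), "semi-axes")
})

test_that("true_breast_average matches a brute-force masked mean", {
  g <- grid_spec(60, 40, 10)
  p <- uniform_phantom(10, g)
  expect_equal(true_breast_average(p), 10)
  half <- p
  half$epsilon_map[, 1:3] <- 5
  half$epsilon_map[, 4:6] <- 15
  expect_equal(true_breast_average(half), 10)
  rp <- generate_breast_phantom(grid_spec(pixel_mm = 4), density = "C",
                                seed = 21L)
  acc <- 0; cnt <- 0
  for (i in seq_len(nrow(rp$epsilon_map))) {
    for (j in seq_len(ncol(rp$epsilon_map))) {
      if (rp$breast_mask_true[i, j]) {
        acc <- acc + rp$epsilon_map[i, j]
        cnt <- cnt + 1
      }
    }
  }
  expect_equal(true_breast_average(rp), acc / cnt)
  empty <- p
  empty$breast_mask_true[] <- FALSE
  expect_error(true_breast_average(empty), "empty")
})

test_that("zero asymmetry gives near-equal sides; asymmetry scales the gap", {
  g <- grid_spec(pixel_mm = 2)
  s0 <- generate_subject("S1", "healthy", density = "B", grid = g,
                         seed = 5L, asymmetry_scale = 0)
  d0 <- abs(normalized_difference(s0$true_averages[["LCC"]],
                                  s0$true_averages[["RCC"]]))
  expect_lt(d0, 0.04)  # residual texture noise only
  # Median healthy |delta| stays within the ~10% clinical envelope.
  g4 <- grid_spec(pixel_mm = 4)
  subs <- generate_cohort(cohort_spec(20, 0, seed = 31L, grid = g4))
  deltas <- sapply(subs, function(s) {
    abs(normalized_difference(s$true_averages[["LCC"]],
                              s$true_averages[["RCC"]]))
  })
  expect_lte(median(deltas), 0.10)
})

test_that("subject construction follows the scan protocol", {
  g <- grid_spec(pixel_mm = 4)
  s <- generate_subject("P1", "cancer", density = "C", grid = g, seed = 9L,
                        tumor_contrast = 0.5)
  expect_equal(s$d2, s$d1 - 5)
  expect_setequal(names(s$phantoms), c("LCC", "RCC", "LMLO", "RMLO"))
  has_tumor <- vapply(s$phantoms, function(p) !is.null(p$tumor), logical(1))
  expect_equal(sum(has_tumor), 2L)
  expect_true(all(substr(names(which(has_tumor)), 1, 1) == s$tumor_side))
  # MLO re-realization covers a smaller area than CC.
  expect_lt(sum(s$phantoms$LMLO$breast_mask_true),
            sum(s$phantoms$LCC$breast_mask_true))
  # Single-view visibility.
  s_cc <- generate_subject("P2", "cancer", density = "C", grid = g,
                           seed = 9L, tumor_contrast = 0.5,
                           tumor_visibility = "CC-only")
  expect_equal(sum(vapply(s_cc$phantoms, function(p) !is.null(p$tumor),
                          logical(1))), 1L)
  h <- generate_subject("H1", "healthy", density = "C", grid = g, seed = 9L)
  expect_true(all(vapply(h$phantoms, function(p) is.null(p$tumor),
                         logical(1))))
})

test_that("cohort generation is reproducible and counts add up", {
  g <- grid_spec(pixel_mm = 8)
  spec <- cohort_spec(20, 14, seed = 42L, grid = g)
  co <- generate_cohort(spec)
  expect_length(co, 34L)
  expect_equal(sum(vapply(co, function(s) length(s$phantoms), 0L)), 136L)
  co2 <- generate_cohort(spec)
  expect_identical(co[[5]]$phantoms$LMLO$epsilon_map,
                   co2[[5]]$phantoms$LMLO$epsilon_map)
  expect_identical(co[[30]]$true_averages, co2[[30]]$true_averages)
  one <- generate_cohort(cohort_spec(0, 1, seed = 2L, grid = g))
  expect_length(one, 1L)
  expect_equal(one[[1]]$group, "cancer")
  expect_error(cohort_spec(density_probs = c(A = 0.5, B = 0.4)), "sum to 1")
})
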