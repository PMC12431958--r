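test_that("breast averages and bilateral statistics compute as defined", {
  img <- toy_image(matrix(12, 4, 4))
  expect_equal(breast_average(img, matrix(TRUE, 4, 4)), 12)
  mix <- toy_image(matrix(c(10, 14, 10, 14), 2))
  expect_equal(breast_average(mix, matrix(TRUE, 2, 2)), 12)
  expect_error(breast_average(img, matrix(FALSE, 4, 4)), "empty mask")

  expect_equal(normalized_difference(10, 10), 0)
  expect_equal(normalized_difference(11, 9), 0.2)
  expect_error(normalized_difference(-1, 5), "positive")
  expect_equal(contralateral_ratio(10, 10), 1)
  expect_equal(contralateral_ratio(11.5, 10), 1.15)
  expect_error(contralateral_ratio(0, 5), "positive")

  set.seed(2)
  a <- runif(50, 1, 30)
  b <- runif(50, 1, 30)
  expect_equal(normalized_difference(a, b), -normalized_difference(b, a))
  expect_equal(contralateral_ratio(a, b), contralateral_ratio(b, a))
  rho <- contralateral_ratio(a, b)
  expect_true(all(rho >= 1))
  # |delta| and rho are algebraically linked: |delta| = 2(rho-1)/(rho+1).
  expect_equal(abs(normalized_difference(a, b)), 2 * (rho - 1) / (rho + 1))
  expect_equal(contralateral_ratio(7, 7), 1)
})

test_that("one-way ANOVA matches hand computation and the t^2 identity", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$value, 0)
  r <- one_way_anova(list(c(1, 2), c(3, 4)))
  expect_equal(r$value, 8)          # SSB = 4 over MSW = 0.5
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 2)
  set.seed(8)
  x <- rnorm(12)
  y <- rnorm(15, 0.5)
  f <- one_way_anova(list(x, y))
  t <- two_sample_t(x, y)
  expect_equal(f$value, t$value^2, tolerance = 1e-9)
  expect_equal(f$p_value, t$p_value, tolerance = 1e-9)
  deg <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$value, Inf)
  expect_equal(deg$p_value, 0)
})

test_that("pooled t-test reproduces the worked example and p monotonicity", {
  same <- rnorm(5)
  r0 <- two_sample_t(same, same)
  expect_equal(r0$value, 0)
  expect_equal(r0$p_value, 1)
  r <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$value, -sqrt(1.5), tolerance = 1e-9)  # -1.2247 at df 4
  expect_equal(r$df1, 4)
  # At fixed df, p decreases as |t| grows.
  p_small <- two_sample_t(c(1, 2, 3), c(1.5, 2.5, 3.5))$p_value
  p_large <- two_sample_t(c(1, 2, 3), c(4, 5, 6))$p_value
  expect_gt(p_small, p_large)
  expect_true(two_sample_t(c(1, 1, 1), c(2, 2, 2))$degenerate)
})

test_that("two-way Type-II table matches the RSS-decomposition oracle", {
  set.seed(21)
  d <- expand.grid(group = c("healthy", "cancer"),
                   view = c("LCC", "RCC", "LMLO", "RMLO"),
                   rep = 1:3)
  d$y <- rnorm(nrow(d)) + 2 * (d$group == "cancer") + 0.5 * (d$view == "LCC")
  tab <- two_way_anova(d, "y")
  rss <- function(formula) sum(stats::residuals(stats::lm(formula, d))^2)
  ss_a <- rss(y ~ view) - rss(y ~ group + view)
  ss_b <- rss(y ~ group) - rss(y ~ group + view)
  ss_ab <- rss(y ~ group + view) - rss(y ~ group * view)
  expect_equal(tab$sum_sq, c(ss_a, ss_b, ss_ab), tolerance = 1e-9)
  # Pure group effect with near-zero noise: group F dominates.
  d2 <- d
  d2$y <- 3 * (d2$group == "cancer") + rnorm(nrow(d2), sd = 1e-3)
  tab2 <- two_way_anova(d2, "y")
  expect_gt(tab2$F_value[1], 1e4)
  expect_lt(tab2$p_value[1], 1e-10)
  expect_gt(tab2$p_value[3], 0.01)
  # Row order is invariant to record permutation.
  perm <- d[sample(nrow(d)), ]
  expect_equal(two_way_anova(perm, "y"), tab)
  # Empty design cells are reported by name.
  d3 <- d[!(d$group == "cancer" & d$view == "RMLO"), ]
  expect_error(two_way_anova(d3, "y"), "empty design cell.*RMLO")
})

test_that("cohort report aggregates ratios and skips infeasible tests", {
  mk_scans <- function(ids, group, eps) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(subject_id = ids[i], group = group[i], density = "B",
                 view = c("LCC", "RCC", "LMLO", "RMLO"),
                 side = c("L", "R", "L", "R"),
                 view_type = c("CC", "CC", "MLO", "MLO"),
                 eps_bar = eps[[i]], d_mm = 55, area_ratio = 0.25)
    }))
  }
  # Every subject bilaterally equal: group-mean rho is exactly 1.
  scans <- mk_scans(c("H1", "H2", "C1", "C2"),
                    c("healthy", "healthy", "cancer", "cancer"),
                    rep(list(c(9, 9, 8, 8)), 4))
  rep1 <- cohort_report(list(scans = scans,
                             summary = mwbreast:::summarize_scans(scans)))
  expect_true(all(rep1$group_view_ratios$mean_rho == 1))
  # Group means equal the brute-force average of per-subject ratios.
  eps <- list(c(10, 9, 8, 8), c(11, 10, 9, 9.5), c(12, 9, 8, 8.8),
              c(9, 9.9, 8.1, 8))
  scans2 <- mk_scans(c("H1", "H2", "C1", "C2"),
                     c("healthy", "healthy", "cancer", "cancer"), eps)
  rep2 <- cohort_report(list(scans = scans2,
                             summary = mwbreast:::summarize_scans(scans2)))
  manual_h_cc <- mean(c(10 / 9, 11 / 10))
  got <- rep2$group_view_ratios
  expect_equal(got$mean_rho[got$group == "healthy" & got$view_type == "CC"],
               manual_h_cc)
  expect_true(all(c("t_rho_healthy_vs_cancer_CC",
                    "two_way_group_x_view_eps_bar") %in% rep2$tests$test))
  # Single-subject cohort: tables still render, tests are skipped with reason.
  solo <- mk_scans("H1", "healthy", list(c(9, 9, 8, 8)))
  rep3 <- cohort_report(list(scans = solo,
                             summary = mwbreast:::summarize_scans(solo)))
  expect_equal(nrow(rep3$subject_table), 4L)
  expect_true(all(is.na(rep3$tests$value)))
  expect_true(all(nzchar(rep3$tests$note)))
})
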