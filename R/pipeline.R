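#' Precompute the shared per-scan context
#'
#' The array's lateral layout, path table and footprint pixel lists depend
#' only on the grid and pairing/footprint radii, not on the plate
#' separation, so they are computed once and reused across scans; only the
#' 3D path lengths are updated per separation.
#'
#' @param grid A [grid_spec()].
#' @param sweep A [freq_sweep()].
#' @param pairing_radius_mm,footprint_radius_mm Path-pairing and footprint
#'   radii (mm).
#' @param t0_ns,t1_ns,n_time Inverse-transform window parameters.
#' @param snr_db Measurement SNR (dB).
#' @param seg_config A [segmentation_config()].
#' @return An object of class `scan_context`.
#' @export
scan_context <- function(grid = grid_spec(), sweep = freq_sweep(),
                         pairing_radius_mm = 25, footprint_radius_mm = 6,
                         t0_ns = 0, t1_ns = 3, n_time = 1024L, snr_db = 30,
                         seg_config = segmentation_config()) {
  geom <- build_array(grid, d = 60, pairing_radius_mm = pairing_radius_mm)
  paths <- enumerate_paths(geom)
  structure(
    list(grid = grid, sweep = sweep, geom = geom, paths = paths,
         footprints = footprint_index(paths, grid, footprint_radius_mm),
         footprint_radius_mm = footprint_radius_mm,
         t0_ns = t0_ns, t1_ns = t1_ns, n_time = as.integer(n_time),
         snr_db = snr_db, seg_config = seg_config),
    class = "scan_context"
  )
}

# Path table with 3D lengths for a given plate separation.
paths_at_separation <- function(ctx, d) {
  p <- ctx$paths
  p$L_mm <- sqrt(d^2 + p$offset_mm^2)
  p
}

#' Image one phantom within a scan context
#'
#' @param phantom Phantom to image.
#' @param ctx A [scan_context()].
#' @param seed Noise seed for this scan.
#' @return A `recon_image`.
#' @export
image_phantom <- function(phantom, ctx, seed = 1L) {
  paths <- paths_at_separation(ctx, phantom$separation_mm)
  spectra <- simulate_scan_spectra(phantom, paths, ctx$sweep, ctx$snr_db,
                                   derive_seed(seed, 1L))
  refs <- simulate_reference_spectra(paths$L_mm, ctx$sweep, ctx$snr_db,
                                     derive_seed(seed, 2L))
  reconstruct_scan(spectra, refs, paths, ctx$grid, ctx$sweep,
                   t0_ns = ctx$t0_ns, t1_ns = ctx$t1_ns, n_time = ctx$n_time,
                   footprint_radius_mm = ctx$footprint_radius_mm,
                   footprints = ctx$footprints,
                   meta = list(view = phantom$view, density = phantom$density,
                               separation_mm = phantom$separation_mm))
}

#' Image and segment the four scans of a subject
#'
#' Runs the measurement, reconstruction and segmentation chain on all four
#' views and assembles the per-scan summaries used by the cohort statistics:
#' breast-average permittivity, separation distance and breast-area ratio
#' per view/side, plus per-view contralateral ratios and normalized
#' differences (reconstructed and ground truth).
#'
#' @param subject A [generate_subject()] result.
#' @param ctx A [scan_context()].
#' @param seed Scan-noise seed for this subject.
#' @param keep_images Return the reconstructed images as well.
#' @return List with data frames `scans` (one row per view/side) and
#'   `summary` (one row per view type: CC, MLO), and optionally `images`.
#' @export
analyze_subject <- function(subject, ctx, seed = 1L, keep_images = FALSE) {
  stopifnot(inherits(subject, "subject_scans"), inherits(ctx, "scan_context"))
  views <- names(subject$phantoms)
  images <- list()
  rows <- vector("list", length(views))
  for (k in seq_along(views)) {
    v <- views[k]
    ph <- subject$phantoms[[v]]
    img <- image_phantom(ph, ctx, derive_seed(seed, k))
    seg <- segment_image(img, ctx$seg_config)
    rows[[k]] <- data.frame(
      subject_id = subject$subject_id, group = subject$group,
      density = subject$density, view = v,
      side = substr(v, 1L, 1L),
      view_type = if (grepl("MLO$", v)) "MLO" else "CC",
      eps_bar = seg$breast_mean,
      d_mm = ph$separation_mm,
      area_ratio = seg$breast_area_ratio,
      true_eps = subject$true_averages[[v]]
    )
    if (keep_images) images[[v]] <- img
  }
  scans <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(c("CC", "MLO"), function(vt) {
    sub <- scans[scans$view_type == vt, ]
    eL <- sub$eps_bar[sub$side == "L"]
    eR <- sub$eps_bar[sub$side == "R"]
    tL <- sub$true_eps[sub$side == "L"]
    tR <- sub$true_eps[sub$side == "R"]
    data.frame(
      subject_id = subject$subject_id, group = subject$group,
      density = subject$density, view_type = vt,
      rho = contralateral_ratio(eL, eR),
      delta = normalized_difference(eL, eR),
      true_rho = contralateral_ratio(tL, tR),
      true_delta = normalized_difference(tL, tR)
    )
  }))
  out <- list(scans = scans, summary = summary)
  if (keep_images) out$images <- images
  out
}

#' Analyze a whole cohort
#'
#' @param subjects List of `subject_scans` (from [generate_cohort()]).
#' @param ctx A [scan_context()].
#' @param seed Master scan-noise seed; per-subject seeds are derived.
#' @param progress Print one line per subject.
#' @return List of data frames: `scans` (subject x view/side rows) and
#'   `summary` (subject x view-type rows with contralateral statistics).
#' @export
analyze_cohort <- function(subjects, ctx, seed = 1L, progress = FALSE) {
  stopifnot(length(subjects) >= 1L)
  res <- lapply(seq_along(subjects), function(i) {
    if (progress)
      message(sprintf("analyzing subject %s (%d/%d)",
                      subjects[[i]]$subject_id, i, length(subjects)))
    analyze_subject(subjects[[i]], ctx, derive_seed(seed, i))
  })
  list(scans = do.call(rbind, lapply(res, `[[`, "scans")),
       summary = do.call(rbind, lapply(res, `[[`, "summary")))
}

skip_row <- function(test, reason) {
  data.frame(test = test, statistic = NA_character_, value = NA_real_,
             df1 = NA_real_, df2 = NA_real_, p_value = NA_real_,
             note = reason)
}

test_row <- function(test, sr) {
  data.frame(test = test, statistic = sr$statistic, value = sr$value,
             df1 = as.numeric(sr$df1), df2 = as.numeric(sr$df2),
             p_value = sr$p_value,
             note = if (sr$degenerate) "degenerate" else "")
}

#' Cohort summary tables and test battery
#'
#' Produces the study's summary and inference tables: per-group, per-view
#' mean contralateral ratios; the per-subject panel (breast averages,
#' separations, area ratios); one-way ANOVA of breast averages across the
#' four views within each group; two-way (group x view, Type-II) ANOVA of
#' breast average, separation and area ratio; and pooled two-sample t-tests
#' comparing contralateral ratios between views within each group and
#' between groups within each view. Tests whose design cannot be formed
#' (e.g. a single-subject cohort) are reported as skipped with a reason.
#'
#' @param cohort Result of [analyze_cohort()].
#' @return List of data frames: `group_view_ratios`, `subject_table`,
#'   `tests`.
#' @export
cohort_report <- function(cohort) {
  scans <- cohort$scans
  summ <- cohort$summary
  stopifnot(nrow(summ) >= 1L)

  agg <- stats::aggregate(rho ~ group + view_type, data = summ, FUN = mean)
  names(agg)[names(agg) == "rho"] <- "mean_rho"
  agg$n <- stats::aggregate(rho ~ group + view_type, data = summ,
                            FUN = length)$rho

  tests <- list()
  for (g in unique(scans$group)) {
    sub <- scans[scans$group == g, ]
    groups <- split(sub$eps_bar, sub$view)
    nm <- sprintf("one_way_eps_by_view_%s", g)
    tests[[nm]] <- if (length(unique(sub$subject_id)) < 2L) {
      skip_row(nm, "needs >= 2 subjects")
    } else test_row(nm, one_way_anova(groups))
  }
  for (resp in c("eps_bar", "d_mm", "area_ratio")) {
    nm <- sprintf("two_way_group_x_view_%s", resp)
    tests[[nm]] <- if (length(unique(scans$group)) < 2L ||
                       length(unique(scans$subject_id)) < 3L) {
      skip_row(nm, "needs both groups and >= 3 subjects")
    } else {
      tryCatch({
        tw <- two_way_anova(scans, resp)
        data.frame(test = nm, statistic = "F", value = tw$F_value,
                   df1 = tw$df, df2 = NA_real_, p_value = tw$p_value,
                   note = tw$term)
      }, error = function(e) skip_row(nm, paste("not testable:",
                                                conditionMessage(e))))
    }
  }
  for (g in unique(summ$group)) {
    nm <- sprintf("t_rho_CC_vs_MLO_%s", g)
    cc <- summ$rho[summ$group == g & summ$view_type == "CC"]
    ml <- summ$rho[summ$group == g & summ$view_type == "MLO"]
    tests[[nm]] <- if (length(cc) < 2L || length(ml) < 2L) {
      skip_row(nm, "needs >= 2 subjects")
    } else test_row(nm, two_sample_t(cc, ml))
  }
  for (vt in c("CC", "MLO")) {
    nm <- sprintf("t_rho_healthy_vs_cancer_%s", vt)
    h <- summ$rho[summ$group == "healthy" & summ$view_type == vt]
    cn <- summ$rho[summ$group == "cancer" & summ$view_type == vt]
    tests[[nm]] <- if (length(h) < 2L || length(cn) < 2L) {
      skip_row(nm, "needs >= 2 subjects per group")
    } else test_row(nm, two_sample_t(h, cn))
  }

  list(group_view_ratios = agg,
       subject_table = scans,
       tests = do.call(rbind, c(tests, make.row.names = FALSE)))
}
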