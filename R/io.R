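#' Default run configuration
#'
#' Nested list of all pipeline parameters with their defaults; any subset
#' can be overridden from a YAML/JSON file via [load_config()]. Matrices on
#' disk are plain CSV with rows indexing y (row 1 = the y = 0 edge) and
#' columns indexing x, chosen for diffability over binary containers.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    grid = list(width_mm = 210, height_mm = 160, pixel_mm = 2),
    array = list(tx_dims = c(19L, 13L), rx_dims = c(20L, 12L),
                 pairing_radius_mm = 25),
    sweep = list(f_min_ghz = 0.1, f_max_ghz = 8, n_points = 161L),
    transform = list(t0_ns = 0, t1_ns = 3, n_time = 1024L),
    footprint_radius_mm = 6,
    noise = list(snr_db = 30),
    segmentation = list(thresholds = c(8, 13, 18), seed = 1L, nstart = 10L,
                        max_iter = 100L, tol = 1e-8),
    cohort = list(n_healthy = 20L, n_cancer = 14L,
                  density_probs = c(A = 0.1, B = 0.4, C = 0.4, D = 0.1),
                  asymmetry_scale = 0.2, tumor_contrast = 0.10)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(config) {
  th <- config$segmentation$thresholds
  if (!(0 < th[1] && th[1] < th[2] && th[2] < th[3]))
    stop("segmentation thresholds must satisfy 0 < T1 < T2 < T3")
  stopifnot(config$grid$pixel_mm > 0, config$sweep$n_points >= 2,
            config$transform$t1_ns > config$transform$t0_ns,
            config$cohort$n_healthy >= 0, config$cohort$n_cancer >= 0)
  if (abs(sum(config$cohort$density_probs) - 1) > 1e-8)
    stop("cohort density_probs must sum to 1")
  if (is.null(config$seed)) stop("a master seed is required")
  config
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file, overlays it on
#' [default_config()], rejects unknown keys and validates the result.
#'
#' @param path File path; a minimal file may set only `seed`.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.null(user$cohort$density_probs))
    user$cohort$density_probs <- unlist(user$cohort$density_probs)
  validate_config(merge_config(default_config(), user))
}

#' Save a run configuration
#'
#' @param config Configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (!is.null(config$cohort$density_probs))
    config$cohort$density_probs <- as.list(config$cohort$density_probs)
  yaml::write_yaml(config, path)
  invisible(path)
}

# Build the heavyweight objects a configuration describes.
config_objects <- function(config) {
  grid <- grid_spec(config$grid$width_mm, config$grid$height_mm,
                    config$grid$pixel_mm)
  sweep <- freq_sweep(config$sweep$f_min_ghz, config$sweep$f_max_ghz,
                      config$sweep$n_points)
  seg <- segmentation_config(config$segmentation$thresholds,
                             config$segmentation$seed,
                             config$segmentation$nstart,
                             config$segmentation$max_iter,
                             config$segmentation$tol)
  ctx <- scan_context(grid, sweep,
                      pairing_radius_mm = config$array$pairing_radius_mm,
                      footprint_radius_mm = config$footprint_radius_mm,
                      t0_ns = config$transform$t0_ns,
                      t1_ns = config$transform$t1_ns,
                      n_time = config$transform$n_time,
                      snr_db = config$noise$snr_db, seg_config = seg)
  list(grid = grid, sweep = sweep, seg = seg, ctx = ctx)
}

write_matrix_csv <- function(mat, path) {
  utils::write.table(mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write / read a reconstructed image
#'
#' The image is stored as `<stem>.csv` (permittivity matrix),
#' `<stem>_coverage.csv` (per-pixel path counts) and a `<stem>.json`
#' sidecar carrying the grid specification and scan metadata.
#'
#' @param image A `recon_image`.
#' @param stem Path stem (no extension).
#' @return `write_image` returns the stem invisibly; `read_image` returns
#'   the `recon_image`.
#' @export
write_image <- function(image, stem) {
  write_matrix_csv(image$epsilon_map, paste0(stem, ".csv"))
  write_matrix_csv(image$coverage, paste0(stem, "_coverage.csv"))
  sidecar <- list(
    grid = image$grid[c("width_mm", "height_mm", "pixel_mm", "nx", "ny")],
    meta = image$meta
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_image
#' @export
read_image <- function(stem) {
  json_path <- paste0(stem, ".json")
  if (!file.exists(json_path)) stop("missing sidecar: ", json_path)
  sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  grid <- grid_spec(sc$grid$width_mm, sc$grid$height_mm, sc$grid$pixel_mm)
  eps <- unname(read_matrix_csv(paste0(stem, ".csv")))
  cov <- unname(read_matrix_csv(paste0(stem, "_coverage.csv")))
  if (!all(dim(eps) == c(grid$ny, grid$nx)))
    stop("image dimensions do not match sidecar grid")
  structure(list(grid = grid, epsilon_map = eps, coverage = cov,
                 meta = as.list(sc$meta)),
            class = "recon_image")
}

#' Write / read a phantom
#'
#' Stored as `<stem>.csv` (permittivity matrix), `<stem>_mask.csv` (0/1
#' breast mask) and a JSON sidecar with view/density/separation/tumor/seed
#' metadata.
#'
#' @param phantom A `breast_phantom`.
#' @param stem Path stem.
#' @export
write_phantom <- function(phantom, stem) {
  write_matrix_csv(phantom$epsilon_map, paste0(stem, ".csv"))
  write_matrix_csv(phantom$breast_mask_true * 1L, paste0(stem, "_mask.csv"))
  sidecar <- list(
    grid = phantom$grid[c("width_mm", "height_mm", "pixel_mm")],
    view = phantom$view, density = phantom$density,
    separation_mm = phantom$separation_mm,
    glandular_fraction = phantom$glandular_fraction,
    semi_axes_mm = phantom$semi_axes_mm, seed = phantom$seed,
    tumor = if (is.null(phantom$tumor)) NULL else unclass(phantom$tumor)
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(stem) {
  json_path <- paste0(stem, ".json")
  if (!file.exists(json_path)) stop("missing sidecar: ", json_path)
  sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  grid <- grid_spec(sc$grid$width_mm, sc$grid$height_mm, sc$grid$pixel_mm)
  eps <- unname(read_matrix_csv(paste0(stem, ".csv")))
  if (!all(dim(eps) == c(grid$ny, grid$nx)))
    stop("phantom dimensions do not match sidecar grid")
  mask <- unname(read_matrix_csv(paste0(stem, "_mask.csv"))) > 0
  tumor <- if (is.null(sc$tumor)) NULL else
    tumor_spec(sc$tumor$center_mm, sc$tumor$semi_axes_mm,
               sc$tumor$permittivity)
  structure(
    list(grid = grid, epsilon_map = eps, breast_mask_true = mask,
         view = sc$view, density = sc$density,
         separation_mm = sc$separation_mm,
         tumor = tumor, glandular_fraction = sc$glandular_fraction,
         semi_axes_mm = sc$semi_axes_mm, seed = sc$seed),
    class = "breast_phantom"
  )
}

write_report <- function(report, dir) {
  paths <- character(0)
  for (nm in names(report)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}

#' Run the full simulation and analysis pipeline
#'
#' Generates the configured cohort, images and segments every scan, writes
#' all per-stage artifacts (phantoms, reconstructed images, segmentation
#' summaries, cohort tables) under `out_dir`, and records a run manifest.
#' Fully deterministic given the configuration's master seed.
#'
#' @param config Configuration list (see [default_config()] /
#'   [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @param write_phantoms,write_images Write per-scan grids (disable to save
#'   space on large cohorts).
#' @return The manifest (also written to `manifest.json`): configuration,
#'   per-stage file inventory and counts.
#' @export
run_pipeline <- function(config, out_dir, write_phantoms = TRUE,
                         write_images = TRUE) {
  config <- validate_config(merge_config(default_config(), config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- config_objects(config)

  co <- config$cohort
  subjects <- generate_cohort(cohort_spec(
    n_healthy = co$n_healthy, n_cancer = co$n_cancer,
    density_probs = co$density_probs, asymmetry_scale = co$asymmetry_scale,
    tumor_contrast = co$tumor_contrast,
    seed = derive_seed(config$seed, 1L), grid = obj$grid))

  files <- character(0)
  seg_rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    for (k in seq_along(s$phantoms)) {
      v <- names(s$phantoms)[k]
      ph <- s$phantoms[[v]]
      stem_base <- sprintf("%s_%s", s$subject_id, v)
      if (write_phantoms) {
        stem <- file.path(out_dir, paste0("phantom_", stem_base))
        write_phantom(ph, stem)
        files <- c(files, paste0(stem, c(".csv", "_mask.csv", ".json")))
      }
      img <- image_phantom(ph, obj$ctx,
                           derive_seed(derive_seed(config$seed, 2L + i), k))
      if (write_images) {
        stem <- file.path(out_dir, paste0("image_", stem_base))
        write_image(img, stem)
        files <- c(files, paste0(stem, c(".csv", "_coverage.csv", ".json")))
      }
      seg <- segment_image(img, obj$seg)
      seg_rows[[stem_base]] <- data.frame(
        subject_id = s$subject_id, group = s$group, density = s$density,
        view = v, side = substr(v, 1L, 1L),
        view_type = if (grepl("MLO$", v)) "MLO" else "CC",
        eps_bar = seg$breast_mean, d_mm = ph$separation_mm,
        area_ratio = seg$breast_area_ratio,
        eps_low = unname(seg$tissue$means["low"]),
        eps_high = unname(seg$tissue$means["high"]),
        fR1 = unname(seg$region_fractions["R1"]),
        fR2 = unname(seg$region_fractions["R2"]),
        fR3 = unname(seg$region_fractions["R3"]),
        fR4 = unname(seg$region_fractions["R4"]),
        true_eps = s$true_averages[[v]]
      )
    }
  }
  scans <- do.call(rbind, c(seg_rows, make.row.names = FALSE))
  summary <- summarize_scans(scans)
  report <- cohort_report(list(scans = scans, summary = summary))
  seg_path <- file.path(out_dir, "segmentation.csv")
  utils::write.csv(scans, seg_path, row.names = FALSE)
  files <- c(files, seg_path, write_report(report, out_dir))

  manifest <- list(
    config = config,
    n_subjects = length(subjects),
    n_phantoms = sum(vapply(subjects, function(s) length(s$phantoms), 0L)),
    files = basename(files),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  missing <- !file.exists(file.path(out_dir, manifest$files))
  if (any(missing))
    stop("manifest lists missing files: ",
         paste(manifest$files[missing], collapse = ", "))
  invisible(manifest)
}

# Per-subject per-view-type contralateral summaries from a scans table.
summarize_scans <- function(scans) {
  out <- list()
  for (id in unique(scans$subject_id)) {
    for (vt in unique(scans$view_type[scans$subject_id == id])) {
      sub <- scans[scans$subject_id == id & scans$view_type == vt, ]
      eL <- sub$eps_bar[sub$side == "L"]
      eR <- sub$eps_bar[sub$side == "R"]
      row <- data.frame(
        subject_id = id, group = sub$group[1L], density = sub$density[1L],
        view_type = vt,
        rho = contralateral_ratio(eL, eR),
        delta = normalized_difference(eL, eR)
      )
      if ("true_eps" %in% names(sub)) {
        tL <- sub$true_eps[sub$side == "L"]
        tR <- sub$true_eps[sub$side == "R"]
        row$true_rho <- contralateral_ratio(tL, tR)
        row$true_delta <- normalized_difference(tL, tR)
      }
      out[[paste(id, vt)]] <- row
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Re-analyze previously written images
#'
#' Stage-isolation entry point: reads every `image_*` artifact under a
#' pipeline output directory, re-runs segmentation and the cohort
#' statistics, and rewrites the summary tables, without touching the
#' simulation or reconstruction stages.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param config Configuration (defaults to the manifest's).
#' @return The cohort report, invisibly.
#' @export
analyze_image_dir <- function(out_dir, config = NULL) {
  if (is.null(config)) {
    mf <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                              simplifyVector = TRUE)
    config <- mf$config
    config$cohort$density_probs <- unlist(config$cohort$density_probs)
  }
  config <- validate_config(merge_config(default_config(), config))
  seg_cfg <- segmentation_config(config$segmentation$thresholds,
                                 config$segmentation$seed,
                                 config$segmentation$nstart,
                                 config$segmentation$max_iter,
                                 config$segmentation$tol)
  stems <- sub("\\.json$", "",
               list.files(out_dir, pattern = "^image_.*[0-9A-Za-z]\\.json$",
                          full.names = TRUE))
  stems <- stems[!grepl("_coverage$", stems)]
  if (!length(stems)) stop("no images found under ", out_dir)
  rows <- lapply(stems, function(stem) {
    img <- read_image(stem)
    seg <- segment_image(img, seg_cfg)
    parts <- strsplit(basename(stem), "_")[[1L]]
    v <- parts[length(parts)]
    data.frame(
      subject_id = paste(parts[-c(1L, length(parts))], collapse = "_"),
      group = if (grepl("^image_H", basename(stem))) "healthy" else "cancer",
      density = as.character(img$meta$density), view = v,
      side = substr(v, 1L, 1L),
      view_type = if (grepl("MLO$", v)) "MLO" else "CC",
      eps_bar = seg$breast_mean, d_mm = img$meta$separation_mm,
      area_ratio = seg$breast_area_ratio
    )
  })
  scans <- do.call(rbind, rows)
  scans <- scans[order(scans$subject_id, scans$view), ]
  rownames(scans) <- NULL
  report <- cohort_report(list(scans = scans,
                               summary = summarize_scans(scans)))
  write_report(report, out_dir)
  invisible(report)
}
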