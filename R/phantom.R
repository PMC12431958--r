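#' @importFrom stats rnorm runif quantile dnorm sd setNames
NULL

# Default glandular area fraction by mammographic density category. Chosen so
# that, combined with the per-category permittivity bands below, category B
# images are dominated by the 8-13 band, C by 13-18 and D by >18.
DENSITY_GLANDULAR <- c(A = 0.15, B = 0.35, C = 0.55, D = 0.75)

# Glandular relative-permittivity bands per density category; fat occupies
# the lowest threshold band.
DEFAULT_GLAND_BANDS <- list(
  A = c(8, 11), B = c(10, 14), C = c(13, 18), D = c(17, 23)
)
DEFAULT_FAT_BAND <- c(4, 7)

VIEWS <- c("LCC", "RCC", "LMLO", "RMLO")

# Deterministic per-item seed derived from a master seed (kept below 2^31).
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 2147483629 * 48271 + k * 16807) %% 2147483629)
}

# Separable Gaussian smoothing with replicate edge padding.
gauss_smooth <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  hw <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- dnorm(seq(-hw, hw), sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1L], hw), v, rep(v[n], hw))
    out <- numeric(n)
    for (j in seq_along(k)) out <- out + k[j] * vp[j:(j + n - 1L)]
    out
  }
  sm <- apply(mat, 2L, conv1)
  t(apply(sm, 1L, conv1))
}

#' Tumor inclusion specification
#'
#' An elliptical inclusion that overwrites the underlying tissue permittivity
#' wherever it intersects the breast region. Tumor extents in the clinical
#' motivation are centimeter-scale in three axes; here the in-plane ellipse
#' carries the model.
#'
#' @param center_mm Length-2 numeric, ellipse center (x, y) in mm.
#' @param semi_axes_mm Length-2 numeric, ellipse semi-axes in mm.
#' @param permittivity With `relative = FALSE`, the relative permittivity
#'   assigned inside the ellipse; with `relative = TRUE`, a multiplier
#'   applied to the underlying tissue values (`1 + contrast`), so a
#'   multiplier of 1 leaves the phantom unchanged.
#' @param relative Whether `permittivity` is a multiplicative contrast.
#' @return An object of class `tumor_spec`.
#' @export
tumor_spec <- function(center_mm, semi_axes_mm, permittivity,
                       relative = FALSE) {
  stopifnot(length(center_mm) == 2L, length(semi_axes_mm) == 2L)
  if (any(semi_axes_mm <= 0)) stop("tumor semi-axes must be positive")
  if (permittivity <= 0) stop("tumor permittivity must be positive")
  structure(
    list(center_mm = as.numeric(center_mm),
         semi_axes_mm = as.numeric(semi_axes_mm),
         permittivity = as.numeric(permittivity),
         relative = isTRUE(relative)),
    class = "tumor_spec"
  )
}

ellipse_mask <- function(grid, center, semi_axes) {
  X <- matrix(grid$x, grid$ny, grid$nx, byrow = TRUE)
  Y <- matrix(grid$y, grid$ny, grid$nx)
  ((X - center[1L]) / semi_axes[1L])^2 + ((Y - center[2L]) / semi_axes[2L])^2 <= 1
}

#' Generate a single-breast permittivity phantom
#'
#' Builds a 2D relative-permittivity map for one breast in one view. The
#' breast is a semi-ellipse abutting the x = 0 (chest-wall) edge of the grid.
#' Fat pixels are drawn uniformly from `fat_band`; glandular tissue is laid
#' out by thresholding a Gaussian-smoothed white-noise field so that a target
#' area fraction of the breast is glandular, with values drawn from the
#' density category's band. Outside the breast the map is exactly 1 (air).
#' Through-thickness homogeneity is assumed: the mid-plane map fully
#' determines propagation delays.
#'
#' @param grid A [grid_spec()].
#' @param density Density category, one of `"A"`, `"B"`, `"C"`, `"D"`
#'   (fatty to extremely dense).
#' @param glandular_fraction Target glandular area fraction in `[0, 1]`;
#'   defaults to a per-category value.
#' @param view One of `"LCC"`, `"RCC"`, `"LMLO"`, `"RMLO"`.
#' @param d Plate separation in mm (carried as scan metadata).
#' @param tumor Optional [tumor_spec()]; must intersect the breast region.
#' @param seed Integer seed; the phantom is a pure function of its arguments.
#' @param semi_axes_mm Optional length-2 breast semi-axes (x, y) in mm. If
#'   `NULL`, drawn uniformly from 70-100 (x) and 55-75 (y) mm, and scaled by
#'   `sqrt(mlo_area_scale)` for MLO views (a smaller portion of the breast
#'   sits between the plates in the tilted view).
#' @param center_y_mm Breast center along y; defaults to mid-height.
#' @param fat_band,gland_bands Permittivity ranges for fat and per-category
#'   glandular tissue.
#' @param smooth_mm Correlation length of the glandular texture field (mm).
#' @param mlo_area_scale Breast-area scale factor applied in MLO views when
#'   semi-axes are drawn internally.
#' @return An object of class `breast_phantom` with fields `grid`,
#'   `epsilon_map` (ny x nx), `breast_mask_true`, `view`, `density`,
#'   `separation_mm`, `tumor`, `glandular_fraction`, `semi_axes_mm`, `seed`.
#' @export
generate_breast_phantom <- function(grid, density = "B",
                                    glandular_fraction = NULL,
                                    view = "LCC", d = 60, tumor = NULL,
                                    seed = 1L,
                                    semi_axes_mm = NULL, center_y_mm = NULL,
                                    fat_band = DEFAULT_FAT_BAND,
                                    gland_bands = DEFAULT_GLAND_BANDS,
                                    smooth_mm = 15, mlo_area_scale = 0.8) {
  density <- match.arg(density, c("A", "B", "C", "D"))
  view <- match.arg(view, VIEWS)
  stopifnot(inherits(grid, "grid_spec"), d > 0)
  if (is.null(glandular_fraction)) glandular_fraction <- DENSITY_GLANDULAR[[density]]
  if (glandular_fraction < 0 || glandular_fraction > 1)
    stop("glandular_fraction must be in [0, 1]")
  if (is.null(center_y_mm)) center_y_mm <- grid$height_mm / 2

  withr::with_seed(seed, {
    if (is.null(semi_axes_mm)) {
      semi_axes_mm <- c(runif(1, 70, 100), runif(1, 55, 75))
      if (grepl("MLO$", view)) semi_axes_mm <- semi_axes_mm * sqrt(mlo_area_scale)
    }
    X <- matrix(grid$x, grid$ny, grid$nx, byrow = TRUE)
    Y <- matrix(grid$y, grid$ny, grid$nx)
    mask <- (X / semi_axes_mm[1L])^2 +
      ((Y - center_y_mm) / semi_axes_mm[2L])^2 <= 1
    if (!any(mask)) stop("breast region is empty on this grid")

    eps <- matrix(1, grid$ny, grid$nx)
    n_in <- sum(mask)
    eps[mask] <- runif(n_in, fat_band[1L], fat_band[2L])

    field <- gauss_smooth(matrix(rnorm(grid$ny * grid$nx), grid$ny, grid$nx),
                          smooth_mm / grid$pixel_mm)
    gland <- mask & FALSE
    if (glandular_fraction >= 1) {
      gland <- mask
    } else if (glandular_fraction > 0) {
      thr <- quantile(field[mask], 1 - glandular_fraction, names = FALSE)
      gland <- mask & (field > thr)
    }
    band <- gland_bands[[density]]
    eps[gland] <- runif(sum(gland), band[1L], band[2L])

    if (!is.null(tumor)) {
      stopifnot(inherits(tumor, "tumor_spec"))
      tmask <- ellipse_mask(grid, tumor$center_mm, tumor$semi_axes_mm) & mask
      if (!any(tmask)) stop("tumor not inside breast")
      eps[tmask] <- if (isTRUE(tumor$relative))
        eps[tmask] * tumor$permittivity else tumor$permittivity
    }

    structure(
      list(grid = grid, epsilon_map = eps, breast_mask_true = mask,
           view = view, density = density, separation_mm = d, tumor = tumor,
           glandular_fraction = glandular_fraction,
           semi_axes_mm = semi_axes_mm, seed = seed),
      class = "breast_phantom"
    )
  })
}

#' @export
print.breast_phantom <- function(x, ...) {
  cat(sprintf(
    "<breast_phantom> view %s, density %s, d = %g mm, %stumor; mean eps = %.3f\n",
    x$view, x$density, x$separation_mm,
    if (is.null(x$tumor)) "no " else "", true_breast_average(x)
  ))
  invisible(x)
}

#' Ground-truth breast-average permittivity
#'
#' Mean of the phantom permittivity map over the true breast mask. Serves as
#' the ground-truth oracle against which reconstructed breast averages are
#' compared.
#'
#' @param phantom A [generate_breast_phantom()] result.
#' @return Scalar mean relative permittivity.
#' @export
true_breast_average <- function(phantom) {
  stopifnot(inherits(phantom, "breast_phantom"))
  if (!any(phantom$breast_mask_true)) stop("empty breast mask")
  mean(phantom$epsilon_map[phantom$breast_mask_true])
}

#' Generate the four scans of one subject
#'
#' Produces the LCC/RCC/LMLO/RMLO phantoms of a bilateral subject. Left and
#' right breasts share geometry and base composition; a signed asymmetry draw
#' `a ~ N(0, asymmetry_scale)` offsets the two glandular fractions to
#' `g * (1 +/- a/2)`, emulating the small healthy left-right differences seen
#' clinically (typically within ~10% in average properties). MLO phantoms are
#' independent spatial re-realizations of the same subject parameters with a
#' reduced in-system breast area. Plates are brought to a first separation D1
#' and then lowered by a 5 mm target to D2; phantoms carry D2, the separation
#' used for imaging.
#'
#' Cancer subjects receive a single elliptical tumor on one side, present in
#' both views of that side by default (`tumor_visibility = "both"`), or in
#' only one view to emulate lesions evident on a single view. The tumor is a
#' multiplicative inclusion: tissue values inside the ellipse are scaled by
#' `1 + tumor_contrast`, so zero contrast leaves the phantom identical to a
#' healthy one (the clinically motivated default is a contrast of ~10% over
#' the surrounding tissue; cohort calibration adjusts it).
#'
#' @param subject_id Identifier stored in the output.
#' @param group `"healthy"` or `"cancer"`.
#' @param density Density category A-D.
#' @param grid A [grid_spec()].
#' @param seed Integer seed (subject-level; per-phantom seeds are derived).
#' @param asymmetry_scale Standard deviation of the signed glandular-fraction
#'   asymmetry draw.
#' @param tumor_contrast Fractional permittivity contrast of the tumor
#'   region over the underlying tissue (`>= 0`).
#' @param tumor_semi_axes_mm In-plane tumor semi-axes (mm).
#' @param tumor_side `"L"`, `"R"`, or `NULL` to draw at random.
#' @param tumor_visibility `"both"`, `"CC-only"` or `"MLO-only"`.
#' @param d1_range Range (mm) from which the first plate separation is drawn.
#' @param sep_decrement_mm Target decrease from D1 to D2 (mm).
#' @param glandular_fraction Optional base glandular fraction; defaults to
#'   the per-category value plus a small uniform jitter.
#' @param mlo_area_scale MLO breast-area scale factor.
#' @param ... Passed on to [generate_breast_phantom()] (e.g. bands,
#'   `smooth_mm`).
#' @return An object of class `subject_scans`: phantoms (named list over
#'   views), separations `d1`/`d2`, the asymmetry draw, per-side glandular
#'   fractions, tumor metadata and per-view ground-truth breast averages.
#' @export
generate_subject <- function(subject_id, group = c("healthy", "cancer"),
                             density = "B", grid = grid_spec(), seed = 1L,
                             asymmetry_scale = 0.2,
                             tumor_contrast = 0.10,
                             tumor_semi_axes_mm = c(20, 15),
                             tumor_side = NULL,
                             tumor_visibility = c("both", "CC-only", "MLO-only"),
                             d1_range = c(50, 70), sep_decrement_mm = 5,
                             glandular_fraction = NULL,
                             mlo_area_scale = 0.8,
                             gland_bands = DEFAULT_GLAND_BANDS, ...) {
  group <- match.arg(group)
  tumor_visibility <- match.arg(tumor_visibility)
  density <- match.arg(density, c("A", "B", "C", "D"))
  stopifnot(asymmetry_scale >= 0)

  draws <- withr::with_seed(seed, {
    g <- if (is.null(glandular_fraction)) {
      min(max(DENSITY_GLANDULAR[[density]] + runif(1, -0.05, 0.05), 0.02), 0.95)
    } else glandular_fraction
    list(
      g = g,
      a = rnorm(1, 0, asymmetry_scale),
      cc_axes = c(runif(1, 70, 100), runif(1, 55, 75)),
      d1 = runif(1, d1_range[1L], d1_range[2L]),
      side = if (is.null(tumor_side)) sample(c("L", "R"), 1L) else tumor_side,
      tu = runif(1), tphi = runif(1, -pi / 2, pi / 2)
    )
  })
  g_L <- min(max(draws$g * (1 + draws$a / 2), 0), 1)
  g_R <- min(max(draws$g * (1 - draws$a / 2), 0), 1)
  d2 <- draws$d1 - sep_decrement_mm
  mlo_axes <- draws$cc_axes * sqrt(mlo_area_scale)

  tumor_for <- function(view, side, axes) {
    if (group != "cancer" || side != draws$side) return(NULL)
    is_mlo <- grepl("MLO$", view)
    if (tumor_visibility == "CC-only" && is_mlo) return(NULL)
    if (tumor_visibility == "MLO-only" && !is_mlo) return(NULL)
    u <- sqrt(draws$tu) * 0.55
    center <- c(axes[1L] * u * cos(draws$tphi),
                grid$height_mm / 2 + axes[2L] * u * sin(draws$tphi))
    if (tumor_contrast <= 0) return(NULL)
    tumor_spec(center, tumor_semi_axes_mm, 1 + tumor_contrast,
               relative = TRUE)
  }

  phantoms <- setNames(vector("list", 4L), VIEWS)
  for (k in seq_along(VIEWS)) {
    view <- VIEWS[k]
    side <- substr(view, 1L, 1L)
    axes <- if (grepl("MLO$", view)) mlo_axes else draws$cc_axes
    phantoms[[view]] <- generate_breast_phantom(
      grid = grid, density = density,
      glandular_fraction = if (side == "L") g_L else g_R,
      view = view, d = d2,
      tumor = tumor_for(view, side, axes),
      seed = derive_seed(seed, k),
      semi_axes_mm = axes, gland_bands = gland_bands, ...
    )
  }

  structure(
    list(subject_id = subject_id, group = group, density = density,
         phantoms = phantoms, d1 = draws$d1, d2 = d2,
         asymmetry = draws$a,
         glandular = c(L = g_L, R = g_R),
         tumor_side = if (group == "cancer") draws$side else NA_character_,
         true_averages = vapply(phantoms, true_breast_average, numeric(1)),
         seed = seed),
    class = "subject_scans"
  )
}

#' Cohort specification
#'
#' @param n_healthy,n_cancer Subject counts (defaults match the clinical
#'   study scale: 20 healthy, 14 cancer).
#' @param density_probs Named probabilities over density categories A-D
#'   (must sum to 1).
#' @param asymmetry_scale,tumor_contrast Passed to [generate_subject()].
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @param grid A [grid_spec()].
#' @param ... Further arguments forwarded to [generate_subject()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 20, n_cancer = 14,
                        density_probs = c(A = 0.1, B = 0.4, C = 0.4, D = 0.1),
                        asymmetry_scale = 0.2, tumor_contrast = 0.10,
                        seed = 1L, grid = grid_spec(), ...) {
  stopifnot(n_healthy >= 0, n_cancer >= 0)
  if (abs(sum(density_probs) - 1) > 1e-8) stop("density_probs must sum to 1")
  if (!all(names(density_probs) %in% c("A", "B", "C", "D")))
    stop("density_probs must be named with categories A-D")
  structure(
    list(n_healthy = n_healthy, n_cancer = n_cancer,
         density_probs = density_probs, asymmetry_scale = asymmetry_scale,
         tumor_contrast = tumor_contrast, seed = seed, grid = grid,
         extra = list(...)),
    class = "cohort_spec"
  )
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return List of `subject_scans`, healthy subjects first; reproducible
#'   given the master seed.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_healthy + spec$n_cancer
  if (n == 0L) return(list())
  densities <- withr::with_seed(derive_seed(spec$seed, 0L), {
    sample(names(spec$density_probs), n, replace = TRUE,
           prob = spec$density_probs)
  })
  groups <- c(rep("healthy", spec$n_healthy), rep("cancer", spec$n_cancer))
  ids <- c(sprintf("H%02d", seq_len(spec$n_healthy)),
           sprintf("C%02d", seq_len(spec$n_cancer)))
  lapply(seq_len(n), function(i) {
    do.call(generate_subject, c(
      list(subject_id = ids[i], group = groups[i], density = densities[i],
           grid = spec$grid, seed = derive_seed(spec$seed, i),
           asymmetry_scale = spec$asymmetry_scale,
           tumor_contrast = spec$tumor_contrast),
      spec$extra
    ))
  })
}
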