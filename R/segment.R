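#' Segmentation configuration
#'
#' Fixed thresholds split the permittivity range into four tissue regions,
#' closed on the upper side: R1 = (0, 8], R2 = (8, 13], R3 = (13, 18],
#' R4 = (18, Inf).
#'
#' @param thresholds Increasing length-3 numeric, the R1/R2, R2/R3 and R3/R4
#'   boundaries.
#' @param seed Seed for k-means initialization.
#' @param nstart Number of k-means restarts.
#' @param max_iter,tol Lloyd iteration cap and convergence tolerance.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(thresholds = c(8, 13, 18), seed = 1L,
                                nstart = 10L, max_iter = 100L, tol = 1e-8) {
  stopifnot(length(thresholds) == 3L)
  if (!(0 < thresholds[1L] && thresholds[1L] < thresholds[2L] &&
        thresholds[2L] < thresholds[3L]))
    stop("thresholds must satisfy 0 < T1 < T2 < T3")
  structure(
    list(thresholds = thresholds, seed = seed, nstart = as.integer(nstart),
         max_iter = as.integer(max_iter), tol = tol),
    class = "segmentation_config"
  )
}

# Scalar 2-means via Lloyd's algorithm with seeded random restarts; returns
# integer labels (1 = lower-mean cluster, 2 = higher-mean cluster).
kmeans2_scalar <- function(values, config) {
  if (length(unique(values)) < 2L)
    stop("need at least 2 distinct values for a 2-cluster split")
  km <- withr::with_seed(config$seed, {
    stats::kmeans(values, centers = 2L, nstart = config$nstart,
                  iter.max = config$max_iter, algorithm = "Lloyd")
  })
  ord <- order(km$centers[, 1L])
  labels <- match(km$cluster, ord)
  list(labels = labels, centers = unname(km$centers[ord, 1L]))
}

#' Identify the breast area of a reconstructed image
#'
#' Two-cluster k-means separates tissue from the air/plate background; the
#' higher-mean cluster is taken as tissue and its largest connected
#' component (4-connectivity) as the breast. Clustering runs on
#' log-permittivity: permittivity contrasts are multiplicative and the log
#' scale keeps the air-tissue split dominant over the fat-gland split for
#' dense breasts.
#'
#' @param image A `recon_image`.
#' @param config A [segmentation_config()].
#' @return Logical breast-mask matrix.
#' @export
segment_breast_mask <- function(image, config = segmentation_config()) {
  v <- as.vector(image$epsilon_map)
  if (any(!is.finite(v))) stop("image contains non-finite values")
  if (length(unique(v)) < 2L) stop("no breast detected: image is constant")
  ks <- kmeans2_scalar(log(pmax(v, .Machine$double.eps)), config)
  mask <- matrix(ks$labels == 2L, image$grid$ny, image$grid$nx)
  labs <- EBImage::bwlabel(mask * 1)
  if (max(labs) > 1L) {
    sizes <- tabulate(labs[labs > 0])
    mask <- labs == which.max(sizes)
  }
  mask
}

#' Two-cluster tissue split within the breast
#'
#' Scalar k-means (k = 2) on the permittivity values inside the mask,
#' splitting lower-permittivity (fat-like) from higher-permittivity
#' (gland-like) tissue.
#'
#' @param image A `recon_image`.
#' @param mask Logical breast mask.
#' @param config A [segmentation_config()].
#' @return List with `labels` (integer matrix, NA outside mask, 1 = low,
#'   2 = high) and `means` (named ascending cluster means).
#' @export
kmeans_tissue_split <- function(image, mask, config = segmentation_config()) {
  if (!any(mask)) stop("empty mask")
  v <- image$epsilon_map[mask]
  ks <- kmeans2_scalar(v, config)
  labels <- matrix(NA_integer_, image$grid$ny, image$grid$nx)
  labels[mask] <- ks$labels
  list(labels = labels,
       means = c(low = ks$centers[1L], high = ks$centers[2L]))
}

#' Four-region threshold segmentation
#'
#' Assigns each masked pixel to one of the fixed permittivity bands
#' (upper-closed: a value exactly on a boundary belongs to the lower region)
#' and returns each region's area as a fraction of the breast area.
#'
#' @param image A `recon_image`.
#' @param mask Logical breast mask.
#' @param config A [segmentation_config()].
#' @return Named numeric `c(R1, R2, R3, R4)` summing to 1.
#' @export
threshold_regions <- function(image, mask, config = segmentation_config()) {
  if (!any(mask)) stop("empty mask")
  v <- image$epsilon_map[mask]
  br <- c(-Inf, config$thresholds, Inf)
  counts <- table(cut(v, breaks = br, right = TRUE,
                      labels = c("R1", "R2", "R3", "R4")))
  stats::setNames(as.numeric(counts) / length(v), c("R1", "R2", "R3", "R4"))
}

#' Breast-area-to-system-area ratio
#'
#' @param mask Logical breast mask.
#' @return Fraction of image pixels inside the mask.
#' @export
breast_area_ratio <- function(mask) {
  if (length(mask) == 0L) stop("empty grid")
  mean(mask)
}

#' Segment a reconstructed image end to end
#'
#' Runs breast-mask identification, the two-cluster tissue split, the
#' four-region threshold segmentation and the area summaries.
#'
#' @param image A `recon_image`.
#' @param config A [segmentation_config()].
#' @return An object of class `segmentation_result`: `mask`, `tissue`
#'   (labels + means), `region_fractions`, `breast_area_ratio` and the
#'   breast-average permittivity `breast_mean`.
#' @export
segment_image <- function(image, config = segmentation_config()) {
  mask <- segment_breast_mask(image, config)
  structure(
    list(mask = mask,
         tissue = kmeans_tissue_split(image, mask, config),
         region_fractions = threshold_regions(image, mask, config),
         breast_area_ratio = breast_area_ratio(mask),
         breast_mean = breast_average(image, mask)),
    class = "segmentation_result"
  )
}
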