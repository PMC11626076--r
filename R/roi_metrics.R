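#' Circular region of interest
#'
#' @param center_x,center_y centre in 0-based pixel coordinates (need not be
#'   integer).
#' @param radius radius in pixels (> 0).
#' @param tissue_label one of `"trachea"`, `"liver"`, `"air"`.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(center_x, center_y, radius,
                         tissue_label = c("trachea", "liver", "air")) {
  tissue_label <- match.arg(tissue_label)
  stopifnot(is.finite(center_x), is.finite(center_y), is.finite(radius),
            radius > 0)
  structure(list(center_x = center_x, center_y = center_y, radius = radius,
                 tissue_label = tissue_label),
            class = "circular_roi")
}

# 0-based (x, y) of pixels whose centres are strictly inside the circle
roi_pixel_coords <- function(roi) {
  r <- roi$radius
  xs <- seq.int(ceiling(roi$center_x - r), floor(roi$center_x + r))
  ys <- seq.int(ceiling(roi$center_y - r), floor(roi$center_y + r))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - roi$center_x)^2 + (g$y - roi$center_y)^2 < r^2
  g[keep, , drop = FALSE]
}

#' ROI statistics: mean HU and noise
#'
#' Mean and population standard deviation of HU over all pixels whose centres
#' lie strictly inside the circle; the SD of the air ROI is the image-noise
#' estimate used by [snr()] and [cnr()]. The ROI must lie fully inside the
#' image and enclose at least `min_pixels` pixels (default 5000 — at 512^2
#' resolution a radius of 40 px is the smallest accepted circle).
#'
#' @param image a [ct_image].
#' @param roi a [circular_roi].
#' @param min_pixels minimum enclosed pixel count; default 5000.
#' @return An object of class `roi_stats`: list with `mean_hu`, `sd_hu`
#'   (population SD, >= 0), `n_pixels`, `tissue_label`.
#' @examples
#' img <- ct_image(matrix(-1000, 120, 120), 0.7)
#' roi_stats(img, circular_roi(60, 60, 45, "air"))
#' @export
roi_stats <- function(image, roi, min_pixels = 5000L) {
  stopifnot(inherits(image, "ct_image"), inherits(roi, "circular_roi"))
  px <- roi_pixel_coords(roi)
  if (nrow(px) < min_pixels)
    stop(sprintf("ROI encloses %d pixels, below the minimum of %d",
                 nrow(px), min_pixels), call. = FALSE)
  if (!all(in_bounds(image, px$x, px$y)))
    stop("ROI extends outside the image", call. = FALSE)
  hu <- pixel_at(image, px$x, px$y)
  m <- mean(hu)
  structure(list(mean_hu = m,
                 sd_hu = sqrt(mean((hu - m)^2)),
                 n_pixels = nrow(px),
                 tissue_label = roi$tissue_label),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> %s: mean %.1f HU, SD %.2f HU, n=%d px\n",
              x$tissue_label, x$mean_hu, x$sd_hu, x$n_pixels))
  invisible(x)
}

#' Average repeated ROI measurements
#'
#' Repeated placements in the same tissue are combined by the arithmetic mean
#' of the ROI means and of the ROI SDs; pixel counts are summed for
#' reporting.
#'
#' @param stats list of [roi_stats] for one tissue (same `tissue_label`).
#' @return A combined `roi_stats`.
#' @export
average_repeats <- function(stats) {
  stopifnot(is.list(stats), length(stats) >= 1L,
            all(vapply(stats, inherits, TRUE, "roi_stats")))
  labels <- unique(vapply(stats, `[[`, "", "tissue_label"))
  if (length(labels) != 1L)
    stop("cannot average ROI repeats across tissue labels: ",
         paste(labels, collapse = ", "), call. = FALSE)
  structure(list(mean_hu = mean(vapply(stats, `[[`, 0, "mean_hu")),
                 sd_hu = mean(vapply(stats, `[[`, 0, "sd_hu")),
                 n_pixels = sum(vapply(stats, `[[`, 0L, "n_pixels")),
                 tissue_label = labels),
            class = "roi_stats")
}

#' Signal-to-noise ratio
#'
#' `SNR = |mean tissue| / SD air`, where the tissue mean is taken as the
#' average of the liver and trachea ROI means (the compound-mean convention;
#' see the package vignette) and the noise estimate is the air ROI's SD.
#' Reported as a magnitude since the tissue mean may be negative.
#'
#' @param mean_tissue mean tissue HU (average of liver and trachea means).
#' @param sd_air air ROI standard deviation, HU (> 0).
#' @return SNR (dimensionless, >= 0).
#' @examples
#' snr(20, 2)    # 10
#' snr(-40, 4)   # 10, magnitude convention
#' @export
snr <- function(mean_tissue, sd_air) {
  if (!is.finite(sd_air) || sd_air <= 0)
    stop("SNR undefined: air SD must be > 0", call. = FALSE)
  abs(mean_tissue) / sd_air
}

#' Contrast-to-noise ratio
#'
#' `CNR = |mean(liver mean, trachea mean) - mean air| / SD air`, reported as
#' a magnitude.
#'
#' @param mean_liver,mean_trachea,mean_air ROI mean HU values.
#' @param sd_air air ROI standard deviation, HU (> 0).
#' @return CNR (dimensionless, >= 0).
#' @examples
#' cnr(60, -980, -1000, 4)   # 135
#' @export
cnr <- function(mean_liver, mean_trachea, mean_air, sd_air) {
  if (!is.finite(sd_air) || sd_air <= 0)
    stop("CNR undefined: air SD must be > 0", call. = FALSE)
  abs((mean_liver + mean_trachea) / 2 - mean_air) / sd_air
}

#' SNR and CNR from averaged ROI statistics
#'
#' Convenience wrapper: given the (repeat-averaged) trachea, liver and air
#' [roi_stats], computes both ratios with the package's conventions.
#'
#' @param trachea,liver,air `roi_stats` objects with matching labels.
#' @return Named list with `snr` and `cnr`.
#' @export
scan_noise_metrics <- function(trachea, liver, air) {
  stopifnot(trachea$tissue_label == "trachea", liver$tissue_label == "liver",
            air$tissue_label == "air")
  mean_tissue <- (liver$mean_hu + trachea$mean_hu) / 2
  list(snr = snr(mean_tissue, air$sd_hu),
       cnr = cnr(liver$mean_hu, trachea$mean_hu, air$mean_hu, air$sd_hu))
}

#' Read ROI definitions from CSV
#'
#' Columns: `center_x`, `center_y`, `radius`, `tissue_label`.
#'
#' @param path CSV file path.
#' @return List of [circular_roi] objects.
#' @export
read_roi_config <- function(path) {
  tb <- data.table::fread(path)
  need <- c("center_x", "center_y", "radius", "tissue_label")
  if (!all(need %in% names(tb)))
    stop("ROI CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(tb)), function(i)
    circular_roi(tb$center_x[i], tb$center_y[i], tb$radius[i],
                 tb$tissue_label[i]))
}
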