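#' CT image container
#'
#' A `ct_image` holds a single HU-calibrated axial CT slice: a numeric pixel
#' matrix plus the physical pixel spacing needed to express measurements in
#' millimetres. All downstream measurements (line profiles, ROI statistics)
#' operate on this container.
#'
#' Coordinate convention: 0-based integer pixel indices, `x` = column,
#' `y` = row, so `I(x, y)` addresses `pixels[y + 1, x + 1]`. Distances are
#' physical (mm), computed per axis from `spacing_x` / `spacing_y`.
#'
#' @param pixels numeric matrix of Hounsfield Units (rows = y, columns = x).
#' @param spacing_x,spacing_y pixel spacing in mm along x (columns) and y
#'   (rows); strictly positive and finite.
#' @param metadata optional named list of free-form acquisition tags
#'   (kVp, mA, slice thickness, window settings, ...).
#'
#' @return An object of class `ct_image` with elements `pixels`,
#'   `spacing_x`, `spacing_y`, `metadata`.
#' @examples
#' img <- ct_image(matrix(-1000, 8, 8), spacing_x = 0.7, spacing_y = 0.7)
#' dim(img$pixels)
#' @export
ct_image <- function(pixels, spacing_x, spacing_y = spacing_x, metadata = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) == 0L))
    stop("'pixels' must be a non-empty numeric matrix", call. = FALSE)
  for (s in c(spacing_x = spacing_x, spacing_y = spacing_y)) {
    if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
      stop("pixel spacing must be a single strictly positive finite number",
           call. = FALSE)
  }
  stopifnot(is.list(metadata))
  structure(
    list(pixels = pixels, spacing_x = as.numeric(spacing_x),
         spacing_y = as.numeric(spacing_y), metadata = metadata),
    class = "ct_image"
  )
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %d x %d px, spacing %.4g x %.4g mm, HU range [%g, %g]\n",
              ncol(x$pixels), nrow(x$pixels), x$spacing_x, x$spacing_y,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ct_image <- function(x) dim(x$pixels)

# TRUE when 0-based (x, y) lies on the pixel grid of `image`
in_bounds <- function(image, x, y) {
  x >= 0 & y >= 0 & x <= ncol(image$pixels) - 1L & y <= nrow(image$pixels) - 1L
}

# HU value at 0-based (x, y); vectorized
pixel_at <- function(image, x, y) {
  image$pixels[cbind(y + 1L, x + 1L)]
}

#' Read / write CT images as plain text
#'
#' Interchange format used by the package: a headerless CSV pixel matrix
#' (`<path>.csv`, rows = y) with a JSON sidecar (`<path>.json`) carrying the
#' pixel spacing and metadata. DICOM / NIfTI readers are not bundled; export
#' from those formats to this interchange format is expected upstream.
#'
#' @param image a [ct_image].
#' @param path file stem; `.csv` and `.json` are appended.
#' @return `write_ct_image` returns `path` invisibly; `read_ct_image` returns
#'   a [ct_image].
#' @examples
#' p <- file.path(tempdir(), "slice")
#' write_ct_image(ct_image(matrix(0, 4, 4), 0.7), p)
#' img <- read_ct_image(p)
#' img$spacing_x
#' @export
write_ct_image <- function(image, path) {
  stopifnot(inherits(image, "ct_image"))
  data.table::fwrite(data.table::as.data.table(image$pixels),
                     paste0(path, ".csv"), col.names = FALSE)
  side <- list(spacing_x = image$spacing_x, spacing_y = image$spacing_y,
               metadata = image$metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ct_image
#' @export
read_ct_image <- function(path) {
  m <- as.matrix(data.table::fread(paste0(path, ".csv"), header = FALSE))
  dimnames(m) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  md <- side$metadata
  if (is.null(md)) md <- list()
  ct_image(m, side$spacing_x, side$spacing_y, as.list(md))
}
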