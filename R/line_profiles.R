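#' Measurement line across a tissue interface
#'
#' A `profile_line` is a straight measurement line in pixel coordinates,
#' labelled by anatomical level (apical / mid / basal), side (left / right),
#' location (anterior / lateral / posterior) and a replicate index. Grids of
#' such lines drive [measure_scan()].
#'
#' @param x_begin,y_begin,x_end,y_end integer 0-based pixel coordinates of the
#'   line endpoints; start must differ from end.
#' @param level,side,location,replicate optional labels carried through to the
#'   measurement output.
#' @return An object of class `profile_line`.
#' @examples
#' profile_line(10, 20, 30, 20, level = "mid", side = "left",
#'              location = "lateral", replicate = 1)
#' @export
profile_line <- function(x_begin, y_begin, x_end, y_end,
                         level = NA_character_, side = NA_character_,
                         location = NA_character_, replicate = NA_integer_) {
  co <- c(x_begin, y_begin, x_end, y_end)
  if (any(!is.finite(co)) || any(co != round(co)))
    stop("line endpoints must be finite integer pixel coordinates", call. = FALSE)
  if (x_begin == x_end && y_begin == y_end)
    stop("line start and end coincide", call. = FALSE)
  structure(
    list(x_begin = as.integer(x_begin), y_begin = as.integer(y_begin),
         x_end = as.integer(x_end), y_end = as.integer(y_end),
         level = level, side = side, location = location,
         replicate = as.integer(replicate)),
    class = "profile_line"
  )
}

#' Rasterize a line with Bresenham's algorithm
#'
#' Returns every pixel on the 8-connected Bresenham raster from `start` to
#' `end`, endpoints included. The classic integer-error formulation is used,
#' which rounds toward the end point at exact half-steps; the raster has
#' exactly `max(|dx|, |dy|) + 1` pixels and consecutive pixels differ by at
#' most 1 in each coordinate.
#'
#' @param start,end integer 0-based `c(x, y)` pixel coordinates. A degenerate
#'   call with `start == end` returns that single pixel.
#' @return Integer matrix with columns `x`, `y`, one row per raster pixel,
#'   first row `start`, last row `end`.
#' @examples
#' rasterize_line(c(0, 0), c(5, 0))
#' rasterize_line(c(0, 0), c(3, 1))
#' @export
rasterize_line <- function(start, end) {
  stopifnot(length(start) == 2L, length(end) == 2L)
  if (any(!is.finite(c(start, end))) || any(c(start, end) != round(c(start, end))))
    stop("endpoints must be finite integer coordinates", call. = FALSE)
  x <- as.integer(start[1L]); y <- as.integer(start[2L])
  x1 <- as.integer(end[1L]); y1 <- as.integer(end[2L])
  dx <- abs(x1 - x); sx <- if (x < x1) 1L else -1L
  dy <- -abs(y1 - y); sy <- if (y < y1) 1L else -1L
  n <- max(dx, -dy) + 1L
  out <- matrix(NA_integer_, n, 2L, dimnames = list(NULL, c("x", "y")))
  err <- dx + dy
  for (i in seq_len(n)) {
    out[i, 1L] <- x; out[i, 2L] <- y
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  out
}

#' Extract an HU line density profile
#'
#' Walks the Bresenham raster of `line` through `image` and records, for each
#' raster pixel, the Euclidean distance (mm) of its centre from the start
#' pixel's centre — using the per-axis pixel spacing — together with its HU
#' value. No sub-pixel interpolation is performed: the profile samples pixel
#' values only.
#'
#' @param image a [ct_image].
#' @param line a [profile_line]; both endpoints must lie inside the image.
#' @return An object of class `line_profile`: list with `distance_mm`
#'   (strictly increasing from 0 along the ideal line direction), `hu`, and
#'   `line` (the source [profile_line]).
#' @examples
#' img <- ct_image(matrix(seq(-1000, 40, length.out = 64), 8, 8), 0.5)
#' pr <- extract_profile(img, profile_line(0, 3, 7, 3))
#' pr$distance_mm
#' @export
extract_profile <- function(image, line) {
  stopifnot(inherits(image, "ct_image"), inherits(line, "profile_line"))
  for (pt in list(c(line$x_begin, line$y_begin), c(line$x_end, line$y_end))) {
    if (!in_bounds(image, pt[1L], pt[2L]))
      stop(sprintf("line endpoint (%d, %d) is outside the %d x %d image",
                   pt[1L], pt[2L], ncol(image$pixels), nrow(image$pixels)),
           call. = FALSE)
  }
  px <- rasterize_line(c(line$x_begin, line$y_begin), c(line$x_end, line$y_end))
  d <- sqrt(((px[, "x"] - px[1L, "x"]) * image$spacing_x)^2 +
            ((px[, "y"] - px[1L, "y"]) * image$spacing_y)^2)
  structure(
    list(distance_mm = d, hu = pixel_at(image, px[, "x"], px[, "y"]),
         line = line),
    class = "line_profile"
  )
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.3g mm, HU range [%g, %g]\n",
              length(x$hu), max(x$distance_mm), min(x$hu), max(x$hu)))
  invisible(x)
}

#' Read a measurement grid from CSV
#'
#' One row per measurement line with columns `x_begin`, `y_begin`, `x_end`,
#' `y_end` and optional `level`, `side`, `location`, `replicate`.
#'
#' @param path CSV file path.
#' @return List of [profile_line] objects.
#' @seealso [default_profile_grid()] for the built-in 39-interface grid.
#' @export
read_profile_grid <- function(path) {
  tb <- data.table::fread(path)
  need <- c("x_begin", "y_begin", "x_end", "y_end")
  if (!all(need %in% names(tb)))
    stop("grid CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  opt <- function(col, default) if (col %in% names(tb)) tb[[col]] else
    rep(default, nrow(tb))
  lapply(seq_len(nrow(tb)), function(i)
    profile_line(tb$x_begin[i], tb$y_begin[i], tb$x_end[i], tb$y_end[i],
                 level = as.character(opt("level", NA_character_)[i]),
                 side = as.character(opt("side", NA_character_)[i]),
                 location = as.character(opt("location", NA_character_)[i]),
                 replicate = as.integer(opt("replicate", NA_integer_)[i])))
}

#' Write a measurement grid to CSV
#'
#' @param grid list of [profile_line] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_grid <- function(grid, path) {
  tb <- data.table::rbindlist(lapply(grid, function(g)
    data.table::data.table(x_begin = g$x_begin, y_begin = g$y_begin,
                           x_end = g$x_end, y_end = g$y_end, level = g$level,
                           side = g$side, location = g$location,
                           replicate = g$replicate)))
  data.table::fwrite(tb, path)
  invisible(path)
}
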