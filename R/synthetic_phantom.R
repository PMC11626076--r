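#' Synthetic chest-phantom specification
#'
#' Describes the stated world of the synthetic generator: a single axial
#' chest slice with an air background (-1000 HU), a soft-tissue body ellipse
#' (+40 HU), two lung ellipses (-800 HU), an air-filled trachea (-1000 HU)
#' and a liver disc (+60 HU); later compartments overwrite earlier ones
#' (z-order). Edges are softened by a fixed detector/optics Gaussian blur
#' plus a dose-dependent reconstruction blur, and seeded Gaussian noise is
#' added with SD proportional to `1 / sqrt(mAs)`.
#'
#' Defaults: noise SD 27 HU at the reference 14 mAs (the air-ROI noise
#' implied by the reference dose series' printed SNR at its highest dose),
#' detector blur 0.6 px, reconstruction blur 0.43 px at 14 mAs growing as
#' `sqrt(reference_mas / mas)` — the denoising-smoothing trade-off of
#' low-dose reconstruction, without which additive noise alone would bias
#' fitted steepness upward at low dose (see the package vignette).
#'
#' @param size image size in pixels (square); default 512.
#' @param spacing pixel spacing, mm; default 0.7 (36 cm field of view at
#'   512). Use ~0.35 mm when edges steeper than ~1200 HU/mm must be
#'   resolvable.
#' @param compartments named list of compartment definitions; each is a list
#'   with `shape` (`"background"`, `"ellipse"`, `"circle"`), `hu`, and — as
#'   fractions of `size` — `cx`, `cy`, plus `a`, `b` (ellipse semi-axes) or
#'   `r` (circle radius). Defaults as above.
#' @param edge_blur_sigma fixed detector blur, px (>= 0).
#' @param recon_blur_ref reconstruction blur at `reference_mas`, px (>= 0).
#' @param noise_sd_ref additive noise SD at `reference_mas`, HU (>= 0).
#' @param reference_mas reference tube current-time product, mAs.
#' @param kvp_noise_mult optional named numeric vector of per-kVp noise
#'   multipliers (names = kVp values); unlisted kVp values use 1.
#' @param seed integer seed driving all randomness; `NULL` leaves the global
#'   RNG untouched.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 512L, spacing = 0.7,
                         compartments = default_compartments(),
                         edge_blur_sigma = 0.6, recon_blur_ref = 0.43,
                         noise_sd_ref = 27, reference_mas = 14,
                         kvp_noise_mult = NULL, seed = 1L) {
  stopifnot(size >= 16L, spacing > 0, edge_blur_sigma >= 0,
            recon_blur_ref >= 0, noise_sd_ref >= 0, reference_mas > 0)
  hus <- vapply(compartments, `[[`, 0, "hu")
  if (any(hus < -1100 | hus > 3100))
    stop("compartment HU values must lie in [-1100, 3100]", call. = FALSE)
  structure(list(size = as.integer(size), spacing = spacing,
                 compartments = compartments,
                 edge_blur_sigma = edge_blur_sigma,
                 recon_blur_ref = recon_blur_ref,
                 noise_sd_ref = noise_sd_ref, reference_mas = reference_mas,
                 kvp_noise_mult = kvp_noise_mult, seed = seed),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_compartments <- function() {
  list(
    background = list(shape = "background", hu = -1000),
    body       = list(shape = "ellipse", hu = 40,  cx = 0.500, cy = 0.547,
                      a = 0.391, b = 0.320),
    lung_left  = list(shape = "ellipse", hu = -800, cx = 0.283, cy = 0.555,
                      a = 0.141, b = 0.205),
    lung_right = list(shape = "ellipse", hu = -800, cx = 0.717, cy = 0.555,
                      a = 0.141, b = 0.205),
    trachea    = list(shape = "circle", hu = -1000, cx = 0.500, cy = 0.410,
                      r = 0.094),
    liver      = list(shape = "circle", hu = 60,  cx = 0.500, cy = 0.742,
                      r = 0.090)
  )
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# noiseless compartment rendering (z-order: later compartments win)
render_compartments <- function(spec) {
  s <- spec$size
  x <- matrix(rep(0:(s - 1L), each = s), s, s)   # column index = x
  y <- matrix(rep(0:(s - 1L), times = s), s, s)  # row index = y
  img <- matrix(NA_real_, s, s)
  for (cp in spec$compartments) {
    if (cp$shape == "background") {
      img[] <- cp$hu
    } else if (cp$shape == "ellipse") {
      inside <- ((x - cp$cx * s) / (cp$a * s))^2 +
                ((y - cp$cy * s) / (cp$b * s))^2 <= 1
      img[inside] <- cp$hu
    } else if (cp$shape == "circle") {
      inside <- (x - cp$cx * s)^2 + (y - cp$cy * s)^2 <= (cp$r * s)^2
      img[inside] <- cp$hu
    } else stop("unknown compartment shape: ", cp$shape, call. = FALSE)
  }
  img
}

# separable Gaussian blur with edge replication; sigma in pixels
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) out <- out + k[j] * m[, clamp(seq_len(nc) + j - r - 1L, nc)]
  m2 <- out
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) out <- out + k[j] * m2[clamp(seq_len(nr) + j - r - 1L, nr), ]
  out
}

# noise SD (HU) at a dose level: 1/sqrt(mAs) law with optional kVp multiplier
noise_sd_at <- function(spec, mas, kvp = NULL) {
  mult <- 1
  if (!is.null(kvp) && !is.null(spec$kvp_noise_mult)) {
    nm <- as.character(kvp)
    if (nm %in% names(spec$kvp_noise_mult)) mult <- spec$kvp_noise_mult[[nm]]
  }
  spec$noise_sd_ref * sqrt(spec$reference_mas / mas) * mult
}

# total edge blur (px) at a dose level: detector + reconstruction smoothing,
# the latter scaling with the relative noise level
blur_sigma_at <- function(spec, mas, kvp = NULL) {
  rel <- if (spec$noise_sd_ref > 0) noise_sd_at(spec, mas, kvp) / spec$noise_sd_ref
         else sqrt(spec$reference_mas / mas)
  spec$edge_blur_sigma + spec$recon_blur_ref * rel
}

#' Generate a pure logistic edge image
#'
#' An image whose HU varies along one axis exactly as [logistic_model()]
#' (no blur — the profile *is* the model), plus seeded Gaussian noise of SD
#' `spec$noise_sd_ref`. With a `"vertical"` edge the transition runs along x;
#' `"horizontal"` along y. Ground truth records the generating steepness
#' `|theta1 * (theta_end - theta_begin) / 4|`.
#'
#' @param spec a [phantom_spec] (its `size`, `spacing`, `noise_sd_ref` and
#'   `seed` are used).
#' @param theta0 edge location, mm from the image origin.
#' @param theta1 logistic slope, 1/mm.
#' @param theta_begin,theta_end asymptotic HU levels (defaults: lung -800,
#'   soft tissue +40).
#' @param orientation `"vertical"` (transition along x) or `"horizontal"`.
#' @return List with `image` (a [ct_image]) and `truth` (list with
#'   `steepness`, `theta`, `noise_sd`).
#' @examples
#' e <- generate_edge_image(phantom_spec(size = 64, noise_sd_ref = 0),
#'                          theta0 = 20, theta1 = 1)
#' e$truth$steepness  # 210 HU/mm
#' @export
generate_edge_image <- function(spec, theta0, theta1, theta_begin = -800,
                                theta_end = 40,
                                orientation = c("vertical", "horizontal")) {
  stopifnot(inherits(spec, "phantom_spec"))
  orientation <- match.arg(orientation)
  s <- spec$size
  l <- (0:(s - 1L)) * spec$spacing
  prof <- logistic_model(l, theta0, theta1, theta_begin, theta_end)
  img <- if (orientation == "vertical") matrix(prof, s, s, byrow = TRUE)
         else matrix(prof, s, s)
  img <- img + with_seed(spec$seed, matrix(stats::rnorm(s * s, 0, spec$noise_sd_ref), s, s))
  list(image = ct_image(img, spec$spacing, spec$spacing,
                        metadata = list(kind = "synthetic_edge",
                                        orientation = orientation)),
       truth = list(steepness = abs(theta1 * (theta_end - theta_begin) / 4),
                    theta = c(theta0 = theta0, theta1 = theta1,
                              theta_begin = theta_begin, theta_end = theta_end),
                    noise_sd = spec$noise_sd_ref))
}

#' Generate one synthetic phantom slice
#'
#' Renders the compartments, applies the total Gaussian edge blur for the
#' dose level, and adds seeded noise. Ground truth carries the compartment
#' HU values, the injected noise SD and blur sigma; when `grid` is supplied,
#' also the per-edge true steepness, obtained by fitting the logistic model
#' to each grid profile of the *noiseless* blurred image (exact under any
#' compartment geometry, unlike a closed form).
#'
#' @param spec a [phantom_spec].
#' @param mas dose level, mAs; default the reference.
#' @param kvp optional kVp for the per-kVp noise multiplier.
#' @param grid optional list of [profile_line] for edge ground truth.
#' @param seed_offset integer added to `spec$seed` so slices and dose levels
#'   get distinct, reproducible noise.
#' @return List with `image` (a [ct_image]) and `truth` (list with
#'   `compartments`, `noise_sd`, `blur_sigma_px`, `seed`, and — with `grid` —
#'   `edge_steepness` vector and `median_steepness`).
#' @export
generate_phantom_slice <- function(spec, mas = spec$reference_mas, kvp = NULL,
                                   grid = NULL, seed_offset = 0L) {
  st <- generate_phantom_stack(spec, n_slices = 1L, mas = mas, kvp = kvp,
                               grid = grid, seed_offset = seed_offset)
  list(image = st$images[[1L]], truth = st$truth)
}

#' Generate a slice stack (apical / mid / basal)
#'
#' Identical geometry per slice with independent, reproducible noise; the
#' default measurement grid maps its level labels onto the three slices.
#'
#' @inheritParams generate_phantom_slice
#' @param n_slices number of slices; default 3.
#' @return List with `images` (list of [ct_image]) and `truth`
#'   (geometry-shared across the stack).
#' @export
generate_phantom_stack <- function(spec, n_slices = 3L,
                                   mas = spec$reference_mas, kvp = NULL,
                                   grid = NULL, seed_offset = 0L) {
  stopifnot(inherits(spec, "phantom_spec"), mas > 0, n_slices >= 1L)
  sigma <- blur_sigma_at(spec, mas, kvp)
  sd <- noise_sd_at(spec, mas, kvp)
  clean <- gaussian_blur(render_compartments(spec), sigma)
  md <- list(kind = "synthetic_phantom", mas = mas, kvp = kvp)
  images <- lapply(seq_len(n_slices), function(i) {
    seed <- if (is.null(spec$seed)) NULL
            else spec$seed + as.integer(seed_offset) + i - 1L
    noisy <- clean +
      with_seed(seed, matrix(stats::rnorm(length(clean), 0, sd),
                             nrow(clean), ncol(clean)))
    ct_image(noisy, spec$spacing, spec$spacing, md)
  })
  truth <- list(compartments = vapply(spec$compartments, `[[`, 0, "hu"),
                noise_sd = sd, blur_sigma_px = sigma,
                seed = if (is.null(spec$seed)) NULL
                       else spec$seed + as.integer(seed_offset))
  if (!is.null(grid)) {
    clean_img <- ct_image(clean, spec$spacing, spec$spacing, md)
    st <- vapply(grid, function(line) {
      fit <- fit_logistic(extract_profile(clean_img, line))
      if (fit$converged) steepness_from_fit(fit) else NA_real_
    }, 0)
    truth$edge_steepness <- st
    truth$median_steepness <- stats::median(st, na.rm = TRUE)
  }
  list(images = images, truth = truth)
}

#' Generate a synthetic dose series
#'
#' One phantom slice per acquisition setting, with injected noise SD
#' `noise_sd_ref * sqrt(reference_mas / mas)` (times any per-kVp multiplier)
#' and the dose-dependent reconstruction blur of [phantom_spec()]. Seed
#' offsets are fixed per level, so reruns with the same spec are
#' bit-identical.
#'
#' @param spec a [phantom_spec].
#' @param settings list of [scan_record] (>= 2 levels).
#' @param grid optional measurement grid for per-level edge ground truth.
#' @param n_slices noise realizations (slices) per level; default 1.
#' @return List of per-level entries: `image` (first slice), `images` (all
#'   slices), `truth`, `record`.
#' @seealso [default_dose_levels()] for the packaged 13-level kVp/mA grid.
#' @export
generate_dose_series <- function(spec, settings, grid = NULL, n_slices = 1L) {
  stopifnot(is.list(settings), length(settings) >= 2L,
            all(vapply(settings, inherits, TRUE, "scan_record")))
  lapply(seq_along(settings), function(i) {
    rec <- settings[[i]]
    st <- generate_phantom_stack(spec, n_slices = n_slices,
                                 mas = compute_mas(rec$ma, rec$rotation_time),
                                 kvp = rec$kvp, grid = grid,
                                 seed_offset = 1000L * i)
    list(image = st$images[[1L]], images = st$images, truth = st$truth,
         record = rec)
  })
}

#' The packaged 13-level dose series settings
#'
#' Scan records for the reference acquisition protocol: 13 kVp/mA levels
#' from 70 kVp / 10 mA to 140 kVp / 50 mA at 0.28 s rotation, with the
#' reference CTDIvol values, read from the packaged reference scan table.
#'
#' @param phantom `"adult"`, `"paediatric"` or `"neonate"`.
#' @return List of 13 [scan_record] objects (highest to lowest dose).
#' @export
default_dose_levels <- function(phantom = c("adult", "paediatric", "neonate")) {
  ph <- match.arg(phantom)
  tb <- data.table::fread(system.file("extdata", "reference_scan_table.csv",
                                      package = "lungqc", mustWork = TRUE))
  tb <- tb[tolower(tb$phantom) == ph, ]
  geo <- data.table::fread(system.file("extdata", "phantom_geometry_synthetic.csv",
                                       package = "lungqc", mustWork = TRUE))
  geo <- geo[tolower(geo$phantom) == ph, ]
  lapply(seq_len(nrow(tb)), function(i)
    scan_record(kvp = tb$kvp[i], ma = tb$ma[i], rotation_time = 0.28,
                ctdi_vol = tb$ctdi_vol[i], scan_length = geo$scan_length_cm,
                ap_diameter = geo$ap_cm, ml_diameter = geo$ml_cm,
                id = tb$id[i], phantom = ph))
}

#' Default 39-interface measurement grid
#'
#' 13 lung-to-pleura interfaces per level (7 on the left lung, 6 on the
#' right, angles rotated slightly between levels) x 3 levels (apical, mid,
#' basal) x 12 replicate placements (parallel lines offset by 1-6 px along
#' the interface tangent on each side) = 468 measurement lines. Each line
#' runs from inside the lung, across the pleural interface, into the chest
#' wall along the local outward ellipse normal.
#'
#' @param spec a [phantom_spec] (geometry scales with `spec$size`).
#' @param replicates replicate placements per interface; default 12.
#' @param half_length half line length, px; default 10 (20 px lines).
#' @return List of `replicates x 39` [profile_line] objects.
#' @export
default_profile_grid <- function(spec, replicates = 12L, half_length = 10L) {
  stopifnot(inherits(spec, "phantom_spec"), replicates >= 1L)
  s <- spec$size
  lungs <- spec$compartments[c("lung_left", "lung_right")]
  levels3 <- c("apical", "mid", "basal")
  offsets <- rep(c(-1, 1), length.out = replicates) *
    ceiling(seq_len(replicates) / 2)  # +-1, +-2, ... px along the tangent

  grid <- list()
  for (lv in seq_along(levels3)) {
    rot <- (lv - 1L) * 5  # degrees; distinct interfaces per level
    for (side in names(lungs)) {
      cp <- lungs[[side]]
      angles <- if (side == "lung_left") seq(80, 280, length.out = 7) + rot
                else seq(-100, 100, length.out = 6) + rot
      for (phi_deg in angles) {
        phi <- phi_deg * pi / 180
        a <- cp$a * s; b <- cp$b * s
        px <- cp$cx * s + a * cos(phi)
        py <- cp$cy * s + b * sin(phi)
        nrm <- c(cos(phi) / a, sin(phi) / b)
        nrm <- nrm / sqrt(sum(nrm^2))
        tng <- c(-nrm[2L], nrm[1L])
        loc <- if (sin(phi) > 0.34) "posterior" else if (sin(phi) < -0.34)
          "anterior" else "lateral"
        for (ri in seq_len(replicates)) {
          o <- offsets[ri] * tng
          p0 <- round(c(px, py) + o - half_length * nrm)
          p1 <- round(c(px, py) + o + half_length * nrm)
          grid[[length(grid) + 1L]] <- profile_line(
            p0[1L], p0[2L], p1[1L], p1[2L], level = levels3[lv],
            side = sub("lung_", "", side), location = loc, replicate = ri)
        }
      }
    }
  }
  grid
}

#' Default ROI placements for the synthetic phantom
#'
#' Circular ROIs in the trachea, the liver, and the air anterior to the
#' chest, sized to enclose just over 5000 pixels at the default 512 px
#' resolution.
#'
#' @param spec a [phantom_spec].
#' @return Named list of three [circular_roi] objects
#'   (`trachea`, `liver`, `air`).
#' @export
default_rois <- function(spec) {
  s <- spec$size
  r <- 41 / 512 * s
  list(trachea = circular_roi(0.500 * s, 0.410 * s, r, "trachea"),
       liver   = circular_roi(0.500 * s, 0.742 * s, r, "liver"),
       air     = circular_roi(0.500 * s, 0.117 * s, r, "air"))
}
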