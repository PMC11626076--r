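#' Four-parameter logistic transition model
#'
#' Models the HU transition along a line density profile crossing a tissue
#' interface:
#' \deqn{\hat h(l) = \theta_{begin} + \frac{\theta_{end} - \theta_{begin}}
#'   {1 + e^{-\theta_1 (l - \theta_0)}}}
#' `theta0` (mm) locates the inflection point, `theta1` (1/mm) controls the
#' slope, and `theta_begin` / `theta_end` are the asymptotic HU levels before
#' and after the interface. The evaluation is numerically guarded: for large
#' `|theta1 * (l - theta0)|` it saturates to the appropriate asymptote.
#'
#' @param l distance from the line start, mm (vectorized).
#' @param theta0 location parameter, mm.
#' @param theta1 slope parameter, 1/mm (negative for falling profiles).
#' @param theta_begin,theta_end asymptotic HU levels.
#' @return HU value(s) of the modelled transition at `l`.
#' @examples
#' logistic_model(5, 5, 2, -800, 40)   # inflection point: midpoint HU
#' @export
logistic_model <- function(l, theta0, theta1, theta_begin, theta_end) {
  # plogis is overflow-safe: exp never evaluated beyond its linear range
  theta_begin + (theta_end - theta_begin) * stats::plogis(theta1 * (l - theta0))
}

#' Fit the logistic transition model to a line profile
#'
#' Nonlinear least squares for the four parameters of [logistic_model()],
#' minimizing the sum of squared HU residuals by bounded quasi-Newton
#' (`L-BFGS-B`) with an analytic gradient. Bounds keep the fit physical:
#' `|theta1| <= theta1_max` and asymptotes within `hu_bounds`.
#'
#' Initialization: `theta_begin` / `theta_end` from the means of the first /
#' last three samples, `theta0` at the sample closest to their midpoint, and
#' `theta1 = sign(theta_end - theta_begin) * 4 / profile length` — robust for
#' both rising and falling edges.
#'
#' Optimizer failure or non-finite estimates are reported via
#' `converged = FALSE`, never as an error, so grid runs can apply an
#' exclusion policy downstream.
#'
#' @param profile a profile from [extract_profile()], or any list with numeric `distance_mm`
#'   and `hu` of equal length (>= 5 samples spanning a nonzero distance).
#' @param init optional numeric vector
#'   `c(theta0, theta1, theta_begin, theta_end)` overriding the default
#'   initialization.
#' @param theta1_max bound on `|theta1|` (1/mm); default 100.
#' @param hu_bounds length-2 bounds for the asymptote parameters (HU);
#'   default `c(-1100, 3100)`.
#' @return An object of class `logistic_fit`: list with `theta0`, `theta1`,
#'   `theta_begin`, `theta_end`, `converged`, `residual_norm` (sum of squared
#'   residuals, HU^2) and `n_samples`.
#' @examples
#' l <- seq(0, 10, length.out = 21)
#' pr <- list(distance_mm = l, hu = logistic_model(l, 5, 2, -800, 40))
#' fit <- fit_logistic(pr)
#' steepness_from_fit(fit)  # ~ 420 HU/mm
#' @export
fit_logistic <- function(profile, init = NULL, theta1_max = 100,
                         hu_bounds = c(-1100, 3100)) {
  l <- profile$distance_mm
  h <- profile$hu
  n <- length(l)
  if (n < 5L || length(h) != n)
    stop("profile must have at least 5 (distance, HU) samples", call. = FALSE)
  span <- max(l) - min(l)
  if (!is.finite(span) || span <= 0)
    stop("profile must span a nonzero distance", call. = FALSE)

  if (is.null(init)) {
    b0 <- mean(h[1:3])
    e0 <- mean(h[(n - 2L):n])
    t0 <- l[which.min(abs(h - (b0 + e0) / 2))]
    sgn <- sign(e0 - b0)
    if (sgn == 0) sgn <- 1
    init <- c(t0, sgn * 4 / span, b0, e0)
  }
  init[2L] <- min(max(init[2L], -theta1_max), theta1_max)
  init[3L] <- min(max(init[3L], hu_bounds[1L]), hu_bounds[2L])
  init[4L] <- min(max(init[4L], hu_bounds[1L]), hu_bounds[2L])

  sse <- function(p) {
    r <- logistic_model(l, p[1L], p[2L], p[3L], p[4L]) - h
    sum(r * r)
  }
  sse_grad <- function(p) {
    s <- stats::plogis(p[2L] * (l - p[1L]))
    d <- p[4L] - p[3L]
    r <- p[3L] + d * s - h
    w <- s * (1 - s)
    2 * c(sum(r * d * w * (-p[2L])),
          sum(r * d * w * (l - p[1L])),
          sum(r * (1 - s)),
          sum(r * s))
  }

  lower <- c(-Inf, -theta1_max, hu_bounds[1L], hu_bounds[1L])
  upper <- c(Inf, theta1_max, hu_bounds[2L], hu_bounds[2L])
  opt <- tryCatch(
    stats::optim(init, sse, sse_grad, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 500L, factr = 1e4)),
    error = function(e) NULL
  )
  ok <- !is.null(opt) && opt$convergence == 0L && all(is.finite(opt$par))
  par <- if (is.null(opt)) rep(NA_real_, 4L) else opt$par
  structure(
    list(theta0 = par[1L], theta1 = par[2L], theta_begin = par[3L],
         theta_end = par[4L], converged = ok,
         residual_norm = if (is.null(opt)) NA_real_ else opt$value,
         n_samples = n),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(paste0("<logistic_fit> theta0=%.4g mm, theta1=%.4g /mm, ",
                     "asymptotes [%.4g, %.4g] HU, converged=%s\n"),
              x$theta0, x$theta1, x$theta_begin, x$theta_end, x$converged))
  invisible(x)
}

#' Edge steepness of a fitted transition
#'
#' The sharpness metric: the magnitude of the logistic model's derivative at
#' its inflection point,
#' \deqn{|\theta_1 (\theta_{end} - \theta_{begin}) / 4|}
#' in HU/mm. The absolute value is taken because `theta1` is negative for
#' falling density profiles.
#'
#' @param fit a converged [fit_logistic()] result.
#' @return Steepness in HU/mm (>= 0).
#' @examples
#' steepness_from_fit(list(theta1 = -4, theta_begin = 0, theta_end = 100,
#'                         converged = TRUE))  # 100
#' @export
steepness_from_fit <- function(fit) {
  if (!isTRUE(fit$converged))
    stop("steepness is undefined for a non-converged fit", call. = FALSE)
  abs(fit$theta1 * (fit$theta_end - fit$theta_begin) / 4)
}

#' Measure per-scan sharpness over a grid of lines
#'
#' Extracts and fits every line in the measurement grid, applies the
#' exclusion policy (non-converged fits; fits with estimated HU contrast
#' `|theta_end - theta_begin|` below `min_contrast`), and reports the pooled
#' median steepness over all included measurements — no per-interface
#' averaging first.
#'
#' Lines carry a `level` label; with a multi-slice stack, apical / mid /
#' basal map to slices 1 / 2 / 3 (a single image is used for every line).
#'
#' @param images a [ct_image] or list of them (the slice stack).
#' @param grid non-empty list of [profile_line] objects.
#' @param min_contrast minimum fitted `|theta_end - theta_begin|` (HU) for a
#'   measurement to enter the median; default 50.
#' @param ... passed to [fit_logistic()].
#' @return An object of class `scan_sharpness`: list with `measurements` (a
#'   `data.table`, one row per line: labels, fitted parameters, steepness,
#'   `converged`, `excluded`, `exclude_reason`), `median_steepness` (HU/mm;
#'   `NA` and `all_excluded = TRUE` when nothing survives), `n_total`,
#'   `n_converged`, `n_included`.
#' @examples
#' spec <- phantom_spec(size = 128, noise_sd_ref = 0)
#' edge <- generate_edge_image(spec, theta0 = 20, theta1 = 0.5)
#' line <- profile_line(20, 64, 100, 64)
#' measure_scan(edge$image, list(line))$median_steepness
#' @export
measure_scan <- function(images, grid, min_contrast = 50, ...) {
  if (inherits(images, "ct_image")) images <- list(images)
  stopifnot(length(images) >= 1L, all(vapply(images, inherits, TRUE, "ct_image")))
  if (!is.list(grid) || length(grid) == 0L)
    stop("measurement grid is empty", call. = FALSE)
  levels3 <- c(apical = 1L, mid = 2L, basal = 3L)

  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    line <- grid[[i]]
    slice <- 1L
    if (length(images) > 1L && !is.na(line$level) && line$level %in% names(levels3))
      slice <- min(levels3[[line$level]], length(images))
    fit <- fit_logistic(extract_profile(images[[slice]], line), ...)
    contrast <- abs(fit$theta_end - fit$theta_begin)
    excluded <- FALSE
    reason <- ""
    if (!fit$converged) {
      excluded <- TRUE; reason <- "fit did not converge"
    } else if (contrast < min_contrast) {
      excluded <- TRUE
      reason <- sprintf("HU contrast %.1f below minimum %.1f", contrast, min_contrast)
    }
    rows[[i]] <- data.table::data.table(
      level = line$level, side = line$side, location = line$location,
      replicate = line$replicate,
      theta0 = fit$theta0, theta1 = fit$theta1,
      theta_begin = fit$theta_begin, theta_end = fit$theta_end,
      steepness = if (fit$converged) steepness_from_fit(fit) else NA_real_,
      converged = fit$converged, excluded = excluded, exclude_reason = reason)
  }
  meas <- data.table::rbindlist(rows)
  incl <- meas$steepness[!meas$excluded]
  structure(
    list(measurements = meas,
         median_steepness = if (length(incl)) stats::median(incl) else NA_real_,
         all_excluded = length(incl) == 0L,
         n_total = nrow(meas),
         n_converged = sum(meas$converged),
         n_included = length(incl)),
    class = "scan_sharpness"
  )
}

#' @export
print.scan_sharpness <- function(x, ...) {
  cat(sprintf("<scan_sharpness> median %.1f HU/mm over %d/%d included (%d converged)\n",
              x$median_steepness, x$n_included, x$n_total, x$n_converged))
  invisible(x)
}

#' Write per-scan sharpness measurements to CSV
#'
#' One row per measurement (labels, fitted parameters, steepness, exclusion
#' flags) followed by a summary row holding the pooled median and counts.
#'
#' @param scan a [measure_scan()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sharpness_csv <- function(scan, path) {
  tb <- data.table::copy(scan$measurements)
  summary_row <- tb[NA_integer_]
  summary_row$level <- "summary"
  summary_row$steepness <- scan$median_steepness
  summary_row$exclude_reason <- sprintf("median of %d included / %d total",
                                        scan$n_included, scan$n_total)
  data.table::fwrite(rbind(tb, summary_row), path)
  invisible(path)
}
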