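#' Likert rating table
#'
#' Reader ratings on 4-point Likert scales: an overall image-quality score
#' plus five subjective items (streak artefacts, noise, pleura sharpness,
#' structure sharpness, small-structure visibility) per scan and reader.
#' Stored long: one row per (scan, reader, item) with a score in 1..4.
#'
#' @param scores data.frame with columns `scan_id`, `reader_id`, `item`,
#'   `score` (integers 1..4). Items must come from [rating_items()] plus
#'   `"overall"`.
#' @return A `data.table` of class `rating_table`.
#' @export
rating_table <- function(scores) {
  tb <- data.table::as.data.table(scores)
  need <- c("scan_id", "reader_id", "item", "score")
  if (!all(need %in% names(tb)))
    stop("ratings must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tb$score %in% 1:4))
    stop("all Likert scores must be integers in 1..4", call. = FALSE)
  bad <- setdiff(unique(tb$item), c("overall", rating_items()))
  if (length(bad))
    stop("unknown rating items: ", paste(bad, collapse = ", "), call. = FALSE)
  data.table::setattr(tb, "class", c("rating_table", class(tb)))
  tb
}

#' @rdname rating_table
#' @param path CSV file with the long-format columns above.
#' @export
read_rating_table <- function(path) rating_table(data.table::fread(path))

#' The five subjective image-quality items
#'
#' The items whose per-reader sum feeds the diagnostic decision; the
#' `overall` score is rated separately and never enters the sum.
#'
#' @return Character vector of the five item names.
#' @export
rating_items <- function() {
  c("streak_artefacts", "noise", "pleura_sharpness",
    "structure_sharpness", "small_structure_visibility")
}

#' Diagnostic-quality decision for one scan
#'
#' A scan is diagnostic when (a) the across-reader mean of the five-item
#' score sum exceeds `sum_threshold` (strictly; a mean of exactly 14 is not
#' diagnostic) and (b) every reader rated the overall quality at least
#' `overall_min`.
#'
#' @param ratings a [rating_table].
#' @param scan scan identifier present in `ratings`.
#' @param sum_threshold strict lower bound on the mean five-item sum;
#'   default 14.
#' @param overall_min minimum overall score required of every reader;
#'   default 3 ("adequate").
#' @return List of class `diagnostic_decision` with `scan_id`,
#'   `mean_item_sum`, `all_readers_overall_ok`, `diagnostic`.
#' @examples
#' r <- expand.grid(scan_id = "s1", reader_id = c("A", "B", "C"),
#'                  item = c("overall", rating_items()))
#' r$score <- 3L
#' diagnostic_decision(rating_table(r), "s1")$diagnostic  # sum 15 > 14: TRUE
#' @export
diagnostic_decision <- function(ratings, scan, sum_threshold = 14,
                                overall_min = 3) {
  stopifnot(inherits(ratings, "rating_table"))
  tb <- ratings[ratings$scan_id == scan, ]
  if (nrow(tb) == 0L)
    stop("scan '", scan, "' not present in the rating table", call. = FALSE)
  readers <- unique(ratings$reader_id)
  expected <- data.table::CJ(reader_id = readers,
                             item = c("overall", rating_items()))
  have <- tb[, c("reader_id", "item")]
  missing <- expected[!have, on = c("reader_id", "item")]
  if (nrow(missing))
    stop("scan '", scan, "' is missing ratings: ",
         paste(sprintf("%s/%s", missing$reader_id, missing$item),
               collapse = ", "), call. = FALSE)

  items <- tb[tb$item %in% rating_items(), ]
  sums <- tapply(items$score, items$reader_id, sum)
  overall <- tb$score[tb$item == "overall"]
  mean_sum <- mean(sums)
  ok <- all(overall >= overall_min)
  structure(list(scan_id = scan, mean_item_sum = mean_sum,
                 all_readers_overall_ok = ok,
                 diagnostic = mean_sum > sum_threshold && ok),
            class = "diagnostic_decision")
}

#' Intraclass correlation ICC(3,k)
#'
#' Two-way mixed-effects, consistency, average-measures intraclass
#' correlation for a scans x readers score matrix:
#' `ICC(3,k) = (MSR - MSE) / MSR`, with `MSR` the between-scan mean square
#' and `MSE` the residual mean square of the two-way (scan + reader) layout.
#' Being a consistency coefficient, it is invariant to reader-specific
#' additive shifts.
#'
#' Values are labelled with the conventional interpretation bands:
#' below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, above 0.9 excellent.
#'
#' @param scores numeric matrix, rows = scans (>= 2), columns = readers
#'   (>= 2), no missing cells.
#' @param conf_level confidence level for the F-based interval; default 0.95.
#' @return List of class `icc` with `value`, `label`, `conf_int`
#'   (lower/upper), `msr`, `mse`, `df1`, `df2`.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5))  # perfect consistency
#' icc_3k(m)$value  # 1
#' @export
icc_3k <- function(scores, conf_level = 0.95) {
  m <- as.matrix(scores)
  if (anyNA(m))
    stop("ICC(3,k) requires a complete scans x readers matrix", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("ICC(3,k) needs at least 2 scans and 2 readers", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0)
    stop("ICC(3,k) undefined: no between-scan variance (MSR = 0)", call. = FALSE)
  value <- (msr - mse) / msr

  # Shrout-Fleiss F interval for the average-measures consistency ICC
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  ci <- c(NA_real_, NA_real_)
  if (mse > 0) {
    f <- msr / mse
    fl <- f / stats::qf(1 - (1 - conf_level) / 2, df1, df2)
    fu <- f * stats::qf(1 - (1 - conf_level) / 2, df2, df1)
    ci <- c(1 - 1 / fl, 1 - 1 / fu)
  } else ci <- c(value, value)

  bands <- c(poor = 0.5, moderate = 0.75, good = 0.9)
  label <- if (value < bands[1L]) "poor" else if (value < bands[2L])
    "moderate" else if (value <= bands[3L]) "good" else "excellent"
  structure(list(value = value, label = label, conf_int = ci,
                 msr = msr, mse = mse, df1 = df1, df2 = df2),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(3,k) = %.3f (%s agreement), 95%% CI [%.3f, %.3f]\n",
              x$value, x$label, x$conf_int[1L], x$conf_int[2L]))
  invisible(x)
}

#' Reader-score matrix for one item (or the five-item sum)
#'
#' Pivots a long [rating_table] into the scans x readers matrix consumed by
#' [icc_3k()].
#'
#' @param ratings a [rating_table].
#' @param item one item name, or `"sum"` for the five-item per-reader sum.
#' @return Numeric matrix, rows = scans, columns = readers.
#' @export
score_matrix <- function(ratings, item = "sum") {
  stopifnot(inherits(ratings, "rating_table"))
  wanted <- item  # distinct name: 'item' is also a column of the table
  tb <- if (identical(wanted, "sum")) {
    it <- ratings[ratings$item %in% rating_items(), ]
    it[, list(score = sum(score)), by = c("scan_id", "reader_id")]
  } else ratings[ratings$item == wanted, ]
  m <- data.table::dcast(data.table::as.data.table(tb),
                         scan_id ~ reader_id, value.var = "score")
  out <- as.matrix(m[, -1])
  rownames(out) <- as.character(m$scan_id)
  out
}

#' Polynomial dose-response fit
#'
#' Ordinary least-squares fit of a degree-2 (quadratic) or degree-3 (cubic)
#' polynomial of a quality response (median steepness, SNR, CNR) on a dose
#' predictor (CTDIvol or SSDE), with R^2 and an optional pointwise
#' confidence band for plotting.
#'
#' @param doses numeric predictor values (distinct; length >= degree + 2).
#' @param responses numeric response values, same length.
#' @param degree polynomial degree, 2 or 3.
#' @param predictor,response names recorded in the result.
#' @return List of class `dose_response_fit` with `coefficients` (intercept
#'   first), `r_squared`, `degree`, `model` (the underlying `lm`), and
#'   `predict(newdoses, interval = "confidence")` available via the model.
#' @export
fit_dose_response <- function(doses, responses, degree = 3,
                              predictor = "dose", response = "response") {
  stopifnot(degree %in% c(2, 3), length(doses) == length(responses))
  if (length(unique(doses)) < degree + 1)
    stop("dose-response fit is rank-deficient: need more distinct dose values",
         call. = FALSE)
  if (length(doses) < degree + 2)
    stop("need at least degree + 2 points", call. = FALSE)
  df <- data.frame(dose = doses, y = responses)
  model <- stats::lm(y ~ poly(dose, degree, raw = TRUE), data = df)
  ss_res <- sum(stats::residuals(model)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  structure(list(coefficients = unname(stats::coef(model)),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 degree = degree, predictor = predictor, response = response,
                 model = model),
            class = "dose_response_fit")
}

#' Confidence band of a dose-response fit
#'
#' @param fit a [fit_dose_response()] result.
#' @param doses predictor values at which to evaluate the band.
#' @param level confidence level; default 0.95.
#' @return data.frame with `dose`, `fit`, `lwr`, `upr`.
#' @export
dose_response_band <- function(fit, doses, level = 0.95) {
  p <- stats::predict(fit$model, newdata = data.frame(dose = doses),
                      interval = "confidence", level = level)
  data.frame(dose = doses, fit = p[, "fit"], lwr = p[, "lwr"], upr = p[, "upr"])
}

#' Lowest diagnostic dose level and sharpness cut-off
#'
#' Among scans rated diagnostic, selects the one with minimal effective dose
#' (ties broken by minimal CTDIvol, then minimal mAs) and returns its scan
#' record together with its median steepness, which becomes the sharpness
#' cut-off for adequate image quality. The result does not depend on input
#' order.
#'
#' @param scans list of entries, each a list with elements `record`
#'   (a [scan_record]), `sharpness` (a [measure_scan()] result or a number),
#'   `decision` (a [diagnostic_decision] or logical), and optionally
#'   `effective_dose` (mSv; otherwise taken from
#'   `dose_estimates(record, table)`).
#' @param table optional conversion table used when `effective_dose` is
#'   absent from an entry.
#' @return List of class `threshold_analysis` with `found`, `record`,
#'   `sharpness_cutoff` (HU/mm), `effective_dose`; `found = FALSE` (and `NA`
#'   fields) when no scan is diagnostic.
#' @export
threshold_analysis <- function(scans, table = NULL) {
  stopifnot(is.list(scans), length(scans) >= 1L)
  get_num <- function(x) {
    if (is.numeric(x)) x else if (inherits(x, "scan_sharpness"))
      x$median_steepness else stop("bad sharpness entry", call. = FALSE)
  }
  get_diag <- function(x) {
    if (is.logical(x)) x else if (inherits(x, "diagnostic_decision"))
      x$diagnostic else stop("bad decision entry", call. = FALSE)
  }
  get_ed <- function(e) {
    if (!is.null(e$effective_dose)) return(e$effective_dose)
    dose_estimates(e$record, table)$effective_dose
  }
  diag <- vapply(scans, function(e) isTRUE(get_diag(e$decision)), TRUE)
  if (!any(diag))
    return(structure(list(found = FALSE, record = NULL,
                          sharpness_cutoff = NA_real_,
                          effective_dose = NA_real_),
                     class = "threshold_analysis"))
  cand <- scans[diag]
  ed <- vapply(cand, get_ed, 0)
  ctdi <- vapply(cand, function(e) e$record$ctdi_vol, 0)
  mas <- vapply(cand, function(e) compute_mas(e$record$ma, e$record$rotation_time), 0)
  best <- order(ed, ctdi, mas)[1L]
  structure(list(found = TRUE, record = cand[[best]]$record,
                 sharpness_cutoff = get_num(cand[[best]]$sharpness),
                 effective_dose = ed[best]),
            class = "threshold_analysis")
}

#' @export
print.threshold_analysis <- function(x, ...) {
  if (!x$found) {
    cat("<threshold_analysis> no diagnostic scan\n")
  } else {
    cat(sprintf(paste0("<threshold_analysis> lowest diagnostic dose: %g kVp / %g mA",
                       " (ED %.3g mSv); sharpness cut-off %.1f HU/mm\n"),
                x$record$kvp, x$record$ma, x$effective_dose, x$sharpness_cutoff))
  }
  invisible(x)
}
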