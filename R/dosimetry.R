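#' Acquisition settings for one scan
#'
#' @param kvp peak tube voltage, kV.
#' @param ma tube current, mA.
#' @param rotation_time gantry rotation / exposure time, s.
#' @param ctdi_vol volume CT dose index (32 cm reference phantom), mGy.
#' @param scan_length scan range, cm.
#' @param ap_diameter,ml_diameter optional anteroposterior / mediolateral
#'   chest diameters, cm (needed for SSDE and effective dose).
#' @param id,phantom optional identifiers carried through to reports.
#' @return An object of class `scan_record`.
#' @export
scan_record <- function(kvp, ma, rotation_time = 0.28, ctdi_vol = NA_real_,
                        scan_length = NA_real_, ap_diameter = NA_real_,
                        ml_diameter = NA_real_, id = NA, phantom = NA_character_) {
  for (v in list(kvp = kvp, ma = ma, rotation_time = rotation_time)) {
    if (!is.finite(v) || v <= 0)
      stop("kvp, ma and rotation_time must be strictly positive", call. = FALSE)
  }
  for (v in list(ctdi_vol, scan_length, ap_diameter, ml_diameter)) {
    if (!is.na(v) && (!is.finite(v) || v <= 0))
      stop("physical scan quantities must be strictly positive", call. = FALSE)
  }
  structure(list(kvp = kvp, ma = ma, rotation_time = rotation_time,
                 ctdi_vol = ctdi_vol, scan_length = scan_length,
                 ap_diameter = ap_diameter, ml_diameter = ml_diameter,
                 id = id, phantom = phantom),
            class = "scan_record")
}

#' Tube current-time product
#'
#' @param ma tube current, mA (> 0).
#' @param exposure_time exposure / rotation time, s (> 0).
#' @return mAs.
#' @examples
#' compute_mas(50, 0.28)  # 14
#' @export
compute_mas <- function(ma, exposure_time) {
  stopifnot(all(ma > 0), all(exposure_time > 0))
  ma * exposure_time
}

#' Dose-length product
#'
#' `DLP = CTDIvol x scan length`.
#'
#' @param ctdi_vol mGy (> 0).
#' @param scan_length cm (> 0).
#' @return DLP in mGy*cm.
#' @examples
#' compute_dlp(0.14, 36)  # 5.04
#' @export
compute_dlp <- function(ctdi_vol, scan_length) {
  stopifnot(all(ctdi_vol > 0), all(scan_length > 0))
  ctdi_vol * scan_length
}

#' Effective chest diameter
#'
#' The geometric mean of the anteroposterior and mediolateral chest
#' diameters, `sqrt(AP x ML)`, rounded half-up to full centimetres — the
#' single-size surrogate keying the SSDE / effective-dose conversion tables.
#'
#' @param ap,ml chest diameters, cm (> 0).
#' @return Integer effective diameter, cm.
#' @examples
#' effective_diameter(25, 36)  # 30
#' effective_diameter(20, 30)  # sqrt(600) = 24.49 -> 24
#' @export
effective_diameter <- function(ap, ml) {
  stopifnot(all(ap > 0), all(ml > 0))
  as.integer(floor(sqrt(ap * ml) + 0.5))  # half-up, not banker's rounding
}

#' Load a size-dependent conversion-factor table
#'
#' CSV with columns `effective_diameter` (integer cm, unique),
#' `ssde_factor` (dimensionless, > 0) and `ed_factor` (mSv per mGy*cm, > 0).
#' The package ships a synthetic example table
#' (`system.file("extdata", "conversion_factors_synthetic.csv",
#' package = "lungqc")`) whose curves are anchored to published
#' (CTDIvol, SSDE, ED) value pairs; substitute the published AAPM /
#' Romanyukha tables for real dosimetry.
#'
#' @param path CSV file path.
#' @return A `data.table` of class `conversion_table`, sorted by diameter.
#' @export
read_conversion_table <- function(path) {
  tb <- data.table::fread(path)
  need <- c("effective_diameter", "ssde_factor", "ed_factor")
  if (!all(need %in% names(tb)))
    stop("conversion table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tb$effective_diameter))
    stop("conversion table diameters must be unique", call. = FALSE)
  if (any(tb$ssde_factor <= 0) || any(tb$ed_factor <= 0))
    stop("conversion factors must be strictly positive", call. = FALSE)
  data.table::setorder(tb, effective_diameter)
  data.table::setattr(tb, "class", c("conversion_table", class(tb)))
  tb
}

# factor lookup with linear interpolation; refuses extrapolation
lookup_factor <- function(table, diameter, column) {
  rng <- range(table$effective_diameter)
  if (diameter < rng[1L] || diameter > rng[2L])
    stop(sprintf("effective diameter %s cm outside table range [%d, %d] cm",
                 format(diameter), rng[1L], rng[2L]), call. = FALSE)
  stats::approx(table$effective_diameter, table[[column]], xout = diameter)$y
}

#' Size-specific dose estimate
#'
#' `SSDE = CTDIvol x f(effective diameter)`, with the size-dependent factor
#' looked up (linearly interpolated) in the conversion table. Diameters
#' outside the table range are refused rather than extrapolated.
#'
#' @param ctdi_vol mGy (> 0).
#' @param diameter effective diameter, cm.
#' @param table a [read_conversion_table()] result.
#' @return SSDE in mGy.
#' @export
compute_ssde <- function(ctdi_vol, diameter, table) {
  stopifnot(ctdi_vol > 0)
  ctdi_vol * lookup_factor(table, diameter, "ssde_factor")
}

#' Effective dose
#'
#' `ED = DLP x k(effective diameter)` with the diameter-specific conversion
#' factor in mSv per mGy*cm.
#'
#' @param dlp dose-length product, mGy*cm (> 0).
#' @param diameter effective diameter, cm.
#' @param table a [read_conversion_table()] result.
#' @return Effective dose in mSv.
#' @export
compute_effective_dose <- function(dlp, diameter, table) {
  stopifnot(dlp > 0)
  dlp * lookup_factor(table, diameter, "ed_factor")
}

#' All dose estimates for one scan
#'
#' Derives mAs and DLP from the acquisition settings; when chest diameters
#' and a conversion table are supplied, also the effective diameter, SSDE and
#' effective dose.
#'
#' @param record a [scan_record].
#' @param table optional [read_conversion_table()] result.
#' @return List of class `dose_estimates` with `mas`, `dlp`,
#'   `effective_diameter`, `ssde`, `effective_dose` (the latter three `NA`
#'   without diameters + table).
#' @export
dose_estimates <- function(record, table = NULL) {
  stopifnot(inherits(record, "scan_record"))
  mas <- compute_mas(record$ma, record$rotation_time)
  dlp <- if (is.na(record$ctdi_vol) || is.na(record$scan_length)) NA_real_
         else compute_dlp(record$ctdi_vol, record$scan_length)
  eff <- ssde <- ed <- NA_real_
  if (!is.null(table) && !is.na(record$ap_diameter) && !is.na(record$ml_diameter)) {
    eff <- effective_diameter(record$ap_diameter, record$ml_diameter)
    if (!is.na(record$ctdi_vol)) ssde <- compute_ssde(record$ctdi_vol, eff, table)
    if (!is.na(dlp)) ed <- compute_effective_dose(dlp, eff, table)
  }
  structure(list(mas = mas, dlp = dlp, effective_diameter = eff,
                 ssde = ssde, effective_dose = ed),
            class = "dose_estimates")
}

#' Read a scan-settings table from CSV
#'
#' Expects (a superset of) columns `kvp`, `ma` and optionally
#' `rotation_time`, `ctdi_vol`, `scan_length`, `ap_diameter`, `ml_diameter`,
#' `id`, `phantom`. The packaged reference dose series is available via
#' `system.file("extdata", "reference_scan_table.csv", package = "lungqc")`.
#'
#' @param path CSV file path.
#' @param rotation_time default rotation time (s) for rows lacking the column.
#' @return List of [scan_record] objects.
#' @export
read_scan_table <- function(path, rotation_time = 0.28) {
  tb <- data.table::fread(path)
  if (!all(c("kvp", "ma") %in% names(tb)))
    stop("scan table must have columns kvp, ma", call. = FALSE)
  col <- function(nm, default) if (nm %in% names(tb)) tb[[nm]] else
    rep(default, nrow(tb))
  lapply(seq_len(nrow(tb)), function(i)
    scan_record(kvp = tb$kvp[i], ma = tb$ma[i],
                rotation_time = col("rotation_time", rotation_time)[i],
                ctdi_vol = col("ctdi_vol", NA_real_)[i],
                scan_length = col("scan_length", NA_real_)[i],
                ap_diameter = col("ap_diameter", NA_real_)[i],
                ml_diameter = col("ml_diameter", NA_real_)[i],
                id = col("id", NA)[i],
                phantom = as.character(col("phantom", NA_character_)[i])))
}
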