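## Per-plate technical validation: calibrator / kit-QC accuracy rules,
## blank ceilings, internal-standard intensity windows, and the
## plate-specific limit of detection derived from zero-sample wells.

#' Technical validation rule set
#'
#' Acceptance rules applied per plate.  Tolerances are inclusive: a
#' calibrator at exactly +/-30\% of its target is valid.  Blank ceilings
#' and internal-standard bounds are kit-defined configuration, not
#' constants.
#'
#' @param calibrator_tolerance relative accuracy window for calibration
#'   standards (default 0.30, i.e. +/-30\%)
#' @param calibrator_min_valid minimum fraction of valid calibrator
#'   injections per analyte (default 0.75)
#' @param qc_tolerance relative accuracy window for kit QC injections
#'   (default 0.45)
#' @param qc_min_valid_overall minimum overall fraction of valid QC
#'   injections per analyte (default 2/3, the "67%" rule: 6 of 9
#'   injections must pass)
#' @param qc_min_valid_per_level minimum fraction of valid injections
#'   within each QC level (default 0.50)
#' @param blank_max named numeric vector of per-analyte (or per-standard)
#'   blank signal ceilings, or a single ceiling applied to all
#' @param istd_bounds named list of `c(min, max)` intensity windows per
#'   internal standard
#' @return object of class `validation_rule`
#' @export
validation_rule <- function(calibrator_tolerance = 0.30,
                            calibrator_min_valid = 0.75,
                            qc_tolerance = 0.45,
                            qc_min_valid_overall = 2 / 3,
                            qc_min_valid_per_level = 0.50,
                            blank_max = NULL,
                            istd_bounds = NULL) {
  tol <- c(calibrator_tolerance, qc_tolerance)
  if (any(tol <= 0 | tol >= 1)) stop2("tolerances must lie in (0, 1)")
  fr <- c(calibrator_min_valid, qc_min_valid_overall, qc_min_valid_per_level)
  if (any(fr <= 0 | fr > 1)) stop2("min-valid fractions must lie in (0, 1]")
  structure(list(calibrator_tolerance = calibrator_tolerance,
                 calibrator_min_valid = calibrator_min_valid,
                 qc_tolerance = qc_tolerance,
                 qc_min_valid_overall = qc_min_valid_overall,
                 qc_min_valid_per_level = qc_min_valid_per_level,
                 blank_max = blank_max,
                 istd_bounds = istd_bounds),
            class = "validation_rule")
}

#' Plate-specific limit of detection from zero-sample wells
#'
#' The LOD of each analyte on a plate is three times the mean signal level
#' of the zero-sample (internal-standard-only) wells.  A zero mean yields
#' LOD 0, i.e. the analyte is never censored on that plate.
#'
#' @param zero_well_values named list (or single-column data source) of
#'   per-analyte replicate concentrations from the plate's zero wells, or a
#'   replicate x analyte numeric matrix with analyte column names
#' @return named numeric vector analyte_id -> LOD (uM)
#' @export
compute_plate_lod <- function(zero_well_values) {
  if (is.matrix(zero_well_values) || is.data.frame(zero_well_values)) {
    zero_well_values <- as.list(as.data.frame(zero_well_values))
  }
  if (!length(zero_well_values)) stop2("no zero-well values supplied")
  vapply(zero_well_values, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) stop2("analyte with no zero-well value")
    if (any(v < 0)) stop2("negative zero-well value")
    3 * mean(v)
  }, numeric(1))
}


## inclusive accuracy window with a float-safe boundary: a measurement at
## exactly target*(1 +/- tol) is valid
within_tol <- function(measured, target, tol) {
  abs(measured / target - 1) <= tol + 1e-9
}

check_targets <- function(measured, targets, what) {
  need <- c("analyte_id", "level")
  if (!all(c(need, "measured") %in% names(measured)))
    stop2(what, ": measured table needs analyte_id, level, measured")
  if (!all(c(need, "target") %in% names(targets)))
    stop2(what, ": target table needs analyte_id, level, target")
  if (any(!is.finite(targets$target) | targets$target <= 0))
    stop2(what, ": target concentrations must be > 0")
  key <- function(d) paste(d$analyte_id, d$level)
  m <- merge(measured, targets[c("analyte_id", "level", "target")],
             by = c("analyte_id", "level"), all.x = TRUE)
  if (anyNA(m$target))
    stop2(what, ": no target for ",
          paste(unique(key(m[is.na(m$target), ])), collapse = ", "))
  m
}

#' Validate calibration standards for one plate
#'
#' A calibrator injection is valid iff its measured concentration lies
#' within the rule's accuracy window of the nominal target
#' (`|measured/target - 1| <= calibrator_tolerance`, inclusive); an analyte
#' passes iff its valid fraction is at least `calibrator_min_valid`.
#'
#' @param measured data.frame of calibrator injections with columns
#'   `analyte_id`, `level` (calibration level), `measured`
#' @param targets data.frame with columns `analyte_id`, `level`, `target`
#' @param rule a [validation_rule()]
#' @return data.frame per analyte: `analyte_id`, `n`, `n_valid`,
#'   `frac_valid`, `pass`; the per-injection table is attached as
#'   attribute `injections`.
#' @export
validate_calibrators <- function(measured, targets, rule = validation_rule()) {
  m <- check_targets(measured, targets, "calibrators")
  m$valid <- within_tol(m$measured, m$target, rule$calibrator_tolerance)
  agg <- stats::aggregate(valid ~ analyte_id, data = m,
                          FUN = function(v) c(n = length(v), ok = sum(v)))
  out <- data.frame(analyte_id = agg$analyte_id,
                    n = agg$valid[, "n"], n_valid = agg$valid[, "ok"],
                    stringsAsFactors = FALSE)
  out$frac_valid <- out$n_valid / out$n
  out$pass <- out$frac_valid >= rule$calibrator_min_valid
  attr(out, "injections") <- m
  out
}

#' Validate kit QC samples for one plate
#'
#' Kit QC injections at three concentration levels; an injection is valid
#' iff within the QC accuracy window of its nominal target.  An analyte
#' passes iff its overall valid fraction is at least
#' `qc_min_valid_overall` *and* every level's valid fraction is at least
#' `qc_min_valid_per_level`.
#'
#' @inheritParams validate_calibrators
#' @param measured data.frame with columns `analyte_id`, `level` (one of
#'   three QC levels), `measured`; every analyte must appear at all three
#'   levels
#' @return per-analyte data.frame with `pass`, overall and per-level valid
#'   fractions; per-injection table attached as attribute `injections`.
#' @export
validate_kit_qcs <- function(measured, targets, rule = validation_rule()) {
  m <- check_targets(measured, targets, "kit QCs")
  lv <- sort(unique(m$level))
  if (length(lv) != 3) stop2("kit QCs: expected exactly three QC levels, got ",
                             length(lv))
  per_an <- split(m, m$analyte_id)
  res <- lapply(per_an, function(d) {
    if (length(setdiff(lv, d$level)))
      stop2("kit QCs: analyte ", d$analyte_id[1], " missing QC level(s): ",
            paste(setdiff(lv, d$level), collapse = ", "))
    valid <- within_tol(d$measured, d$target, rule$qc_tolerance)
    overall <- mean(valid)
    per_level <- tapply(valid, d$level, mean)
    data.frame(analyte_id = d$analyte_id[1], n = length(valid),
               n_valid = sum(valid), frac_valid = overall,
               min_level_frac = min(per_level),
               pass = overall >= rule$qc_min_valid_overall &&
                 all(per_level >= rule$qc_min_valid_per_level),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  m$valid <- within_tol(m$measured, m$target, rule$qc_tolerance)
  attr(out, "injections") <- m
  out
}

#' Validate blank signals and internal-standard intensities
#'
#' Blank signals must stay below the kit-defined ceiling; internal-standard
#' intensities must fall inside their kit-defined windows.  Every observed
#' standard must have a configured bound.
#'
#' @param blank_signals named numeric vector of blank-well signals per
#'   analyte (or standard)
#' @param istd_intensities named numeric vector of internal-standard
#'   intensities
#' @param rule a [validation_rule()] carrying `blank_max` and `istd_bounds`
#' @return data.frame of failures (`rule`, `id`, `observed`, `bound`);
#'   zero rows when everything passes.
#' @export
validate_blank_and_istd <- function(blank_signals, istd_intensities,
                                    rule = validation_rule()) {
  failures <- list()
  if (length(blank_signals)) {
    bm <- rule$blank_max
    if (is.null(bm)) stop2("rule has no blank_max ceiling")
    ceilings <- if (length(bm) == 1 && is.null(names(bm)))
      rep(bm, length(blank_signals))
    else {
      if (!all(names(blank_signals) %in% names(bm)))
        stop2("blank ceiling missing for: ",
              paste(setdiff(names(blank_signals), names(bm)), collapse = ", "))
      unname(bm[names(blank_signals)])
    }
    bad <- which(!(blank_signals < ceilings))
    for (i in bad)
      failures[[length(failures) + 1L]] <-
        data.frame(rule = "blank_max", id = names(blank_signals)[i],
                   observed = unname(blank_signals[i]), bound = ceilings[i],
                   stringsAsFactors = FALSE)
  }
  if (length(istd_intensities)) {
    ib <- rule$istd_bounds
    if (is.null(ib)) stop2("rule has no istd_bounds")
    missing_b <- setdiff(names(istd_intensities), names(ib))
    if (length(missing_b))
      stop2("ISTD bounds missing for: ", paste(missing_b, collapse = ", "))
    for (nm in names(istd_intensities)) {
      b <- ib[[nm]]
      x <- istd_intensities[[nm]]
      if (x < b[1] || x > b[2])
        failures[[length(failures) + 1L]] <-
          data.frame(rule = "istd_bounds", id = nm, observed = x,
                     bound = paste0("[", b[1], ", ", b[2], "]"),
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(failures))
    return(data.frame(rule = character(), id = character(),
                      observed = numeric(), bound = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(failures, make.row.names = FALSE))
}

#' Full technical verdict for one plate
#'
#' Combines calibrator, kit-QC, blank and internal-standard checks into a
#' single pass/fail verdict with an itemized failure list (`pass` is TRUE
#' iff the failure list is empty).
#'
#' @param plate_id plate identifier
#' @param calibrators,calibrator_targets injection and target tables for
#'   [validate_calibrators()] (NULL to skip, e.g. flow-injection panels
#'   without a calibration curve)
#' @param kit_qcs,kit_qc_targets injection and target tables for
#'   [validate_kit_qcs()]
#' @param blank_signals,istd_intensities inputs for
#'   [validate_blank_and_istd()] (NULL to skip)
#' @param rule a [validation_rule()]
#' @return object of class `plate_verdict`: list with `plate_id`, `pass`,
#'   `failures` data.frame
#' @export
validate_plate <- function(plate_id,
                           calibrators = NULL, calibrator_targets = NULL,
                           kit_qcs = NULL, kit_qc_targets = NULL,
                           blank_signals = NULL, istd_intensities = NULL,
                           rule = validation_rule()) {
  fails <- list()
  add_fail <- function(rule_name, ids, obs, bound) {
    if (!length(ids)) return()
    fails[[length(fails) + 1L]] <<-
      data.frame(rule = rule_name, id = ids, observed = obs,
                 bound = as.character(bound), stringsAsFactors = FALSE)
  }
  if (!is.null(calibrators)) {
    cal <- validate_calibrators(calibrators, calibrator_targets, rule)
    bad <- cal[!cal$pass, ]
    add_fail("calibrator_min_valid", bad$analyte_id, bad$frac_valid,
             rule$calibrator_min_valid)
  }
  if (!is.null(kit_qcs)) {
    qc <- validate_kit_qcs(kit_qcs, kit_qc_targets, rule)
    bad <- qc[!qc$pass, ]
    add_fail("qc_min_valid", bad$analyte_id,
             pmin(bad$frac_valid, bad$min_level_frac),
             paste0(rule$qc_min_valid_overall, "/",
                    rule$qc_min_valid_per_level))
  }
  if (!is.null(blank_signals) || !is.null(istd_intensities)) {
    bi <- validate_blank_and_istd(blank_signals %||% numeric(),
                                  istd_intensities %||% numeric(), rule)
    if (nrow(bi)) fails[[length(fails) + 1L]] <- bi
  }
  failures <- if (length(fails))
    do.call(rbind, c(fails, make.row.names = FALSE))
  else data.frame(rule = character(), id = character(),
                  observed = numeric(), bound = character(),
                  stringsAsFactors = FALSE)
  structure(list(plate_id = plate_id, pass = nrow(failures) == 0L,
                 failures = failures),
            class = "plate_verdict")
}

#' @export
print.plate_verdict <- function(x, ...) {
  cat(sprintf("plate %s: %s\n", x$plate_id,
              if (x$pass) "PASS" else sprintf("FAIL (%d violations)",
                                              nrow(x$failures))))
  if (!x$pass) print(x$failures)
  invisible(x)
}
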