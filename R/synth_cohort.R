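## Seeded generator of synthetic Level-0 plate data, clinical tables and
## free-text medication records with known ground truth, so that every
## pipeline stage is testable without access-restricted cohort data.

#' Simulation configuration
#'
#' Defaults describe the emulated cohort: 11 plates of 76 study wells
#' carrying 831 study samples including 20 blinded duplicate pairs, a 182
#' analyte panel, multiplicative plate batch effects, ~5\% technical CV,
#' 44 analytes planted to fail quality filters, 2 score-space outlier
#' subjects, 69 non-fasting / 2 missing-BMI / 1 missing-medication-record
#' subjects and 4 thaw-excluded samples.
#'
#' @param n_plates number of plates
#' @param study_wells_per_plate study wells available per plate
#' @param n_study_samples study samples injected (subjects =
#'   `n_study_samples - n_duplicate_pairs`)
#' @param n_duplicate_pairs blinded analytical duplicate pairs
#' @param n_analytes panel size
#' @param conc_log10_range log10 range of analyte mean concentrations (uM)
#' @param biological_cv between-subject coefficient of variation
#' @param technical_cv within-subject (injection) coefficient of variation
#'   for clean analytes
#' @param high_cv_value technical CV planted on `high_cv` defect analytes
#' @param plate_effect_sd log-scale sd of multiplicative plate batch
#'   effects
#' @param censor_q_clean target censoring fraction of clean analytes (the
#'   plate LOD is set at this quantile; 0 means LOD 0, never censored)
#' @param censor_q_high target censoring fraction planted on
#'   `high_censoring` defect analytes
#' @param planted_bad named counts of defect analytes:
#'   `c(high_cv=, low_icc=, high_censoring=)`
#' @param n_outlier_subjects planted score-space outlier subjects
#' @param outlier_magnitude total score-space displacement in sd units
#'   (spread over all analytes)
#' @param n_non_fasting,n_missing_bmi,n_missing_meds clinical flag counts
#'   (disjoint subjects)
#' @param n_thawed samples excluded at Level 1 (thawed during shipment)
#' @param n_meds_max maximum medications per subject
#' @param typo_rate probability that a drug name is misspelled (adjacent
#'   transposition)
#' @param n_calibrator_levels calibration-curve levels (UPLC analytes)
#' @param seed mandatory RNG seed
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_plates = 11L,
                              study_wells_per_plate = 76L,
                              n_study_samples = 831L,
                              n_duplicate_pairs = 20L,
                              n_analytes = 182L,
                              conc_log10_range = c(-1, 2),
                              biological_cv = 0.30,
                              technical_cv = 0.05,
                              high_cv_value = 0.40,
                              plate_effect_sd = 0.10,
                              censor_q_clean = 0.02,
                              censor_q_high = 0.60,
                              planted_bad = c(high_cv = 15L, low_icc = 15L,
                                              high_censoring = 14L),
                              n_outlier_subjects = 2L,
                              outlier_magnitude = 30,
                              n_non_fasting = 69L,
                              n_missing_bmi = 2L,
                              n_missing_meds = 1L,
                              n_thawed = 4L,
                              n_meds_max = 3L,
                              typo_rate = 0.10,
                              n_calibrator_levels = 7L,
                              seed) {
  if (missing(seed) || is.null(seed)) stop2("seed is mandatory")
  planted_bad <- unlist(planted_bad)
  planted_bad <- planted_bad[c("high_cv", "low_icc", "high_censoring")]
  planted_bad[is.na(planted_bad)] <- 0L
  names(planted_bad) <- c("high_cv", "low_icc", "high_censoring")
  cfg <- list(n_plates = as.integer(n_plates),
              study_wells_per_plate = as.integer(study_wells_per_plate),
              n_study_samples = as.integer(n_study_samples),
              n_duplicate_pairs = as.integer(n_duplicate_pairs),
              n_analytes = as.integer(n_analytes),
              conc_log10_range = conc_log10_range,
              biological_cv = biological_cv,
              technical_cv = technical_cv,
              high_cv_value = high_cv_value,
              plate_effect_sd = plate_effect_sd,
              censor_q_clean = censor_q_clean,
              censor_q_high = censor_q_high,
              planted_bad = planted_bad,
              n_outlier_subjects = as.integer(n_outlier_subjects),
              outlier_magnitude = outlier_magnitude,
              n_non_fasting = as.integer(n_non_fasting),
              n_missing_bmi = as.integer(n_missing_bmi),
              n_missing_meds = as.integer(n_missing_meds),
              n_thawed = as.integer(n_thawed),
              n_meds_max = as.integer(n_meds_max),
              typo_rate = typo_rate,
              n_calibrator_levels = as.integer(n_calibrator_levels),
              seed = as.integer(seed))
  counts <- c(cfg$n_plates, cfg$study_wells_per_plate, cfg$n_study_samples,
              cfg$n_analytes)
  if (any(counts <= 0)) stop2("plate/sample/analyte counts must be positive")
  if (cfg$n_study_samples > cfg$n_plates * cfg$study_wells_per_plate)
    stop2("study samples exceed plate capacity")
  if (2L * cfg$n_duplicate_pairs > cfg$n_study_samples)
    stop2("duplicate pairs exceed sample count")
  if (sum(cfg$planted_bad) > cfg$n_analytes)
    stop2("planted defect analytes exceed panel size")
  n_subjects <- cfg$n_study_samples - cfg$n_duplicate_pairs
  reserved <- cfg$n_duplicate_pairs + cfg$n_non_fasting + cfg$n_missing_bmi +
    cfg$n_missing_meds + cfg$n_outlier_subjects + cfg$n_thawed
  if (reserved > n_subjects)
    stop2("duplicates + flags + outliers + thawed exceed subject count")
  structure(cfg, class = "simulation_config")
}

## analyte panel with class / platform / quantitation assignments
make_panel <- function(A) {
  classes <- c("acylcarnitine", "amino acid", "biogenic amine",
               "glycerophospholipid", "sphingolipid", "hexose")
  prefix <- c(acylcarnitine = "AC", `amino acid` = "AA",
              `biogenic amine` = "BA", glycerophospholipid = "GPL",
              sphingolipid = "SM", hexose = "H")
  ## proportions loosely mirroring the p180 panel composition
  prop <- c(0.22, 0.115, 0.115, 0.46, 0.08, 0.01)
  n <- pmax(1L, as.integer(round(prop * A)))
  while (sum(n) > A) n[which.max(n)] <- n[which.max(n)] - 1L
  while (sum(n) < A) n[4] <- n[4] + 1L
  cls <- rep(classes, n)
  ids <- unlist(lapply(seq_along(classes), function(i)
    sprintf("%s.%02d", prefix[classes[i]], seq_len(n[i]))))
  platform <- ifelse(cls %in% c("amino acid", "biogenic amine"),
                     "UPLC", "FIA")
  data.frame(analyte_id = ids, analyte_class = cls, platform = platform,
             quantitation = ifelse(platform == "UPLC", "fully-quantitative",
                                   "semi-quantitative"),
             stringsAsFactors = FALSE)
}

## per-plate injection layout mirroring the bracketed analysis order
plate_layout <- function(n_study, n_cal) {
  cal <- sprintf("calibrator_%d", seq_len(n_cal))
  qcs <- c("kit_QC1", "kit_QC2", "kit_QC3")
  first <- max(1L, ceiling(n_study / 2))
  c("blank", "zero", "zero", "zero", cal, qcs, "SPQC", "NIST",
    "reference_serum", rep("study", first), qcs, "NIST", "reference_serum",
    rep("study", n_study - first), cal, qcs, "SPQC", "NIST",
    "reference_serum")
}

swap_typo <- function(word) {
  ## adjacent transposition that changes the string; "" if impossible
  n <- nchar(word)
  if (n < 2) return("")
  pos <- sample.int(n - 1L, n - 1L)  # try positions in random order
  ch <- strsplit(word, "")[[1]]
  for (p in pos) {
    if (ch[p] != ch[p + 1L]) {
      out <- ch
      out[c(p, p + 1L)] <- out[c(p + 1L, p)]
      return(paste(out, collapse = ""))
    }
  }
  ""
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Subject abundances are lognormal per analyte; an observed value is
#' `truth x plate_effect x (1 + technical noise)` truncated at zero; the
#' study-pool QC shares one fixed pooled truth across plates; censoring
#' applies the plate-specific LOD (placed at the configured censoring
#' quantile, with zero wells written at exactly LOD/3 so the LOD rule
#' recovers it); blinded duplicates are independent redraws of the
#' technical noise; planted defect analytes get inflated technical CV,
#' zero between-subject variance, or heavy censoring; planted outlier
#' subjects are displaced by the configured score-space magnitude.  All
#' randomness derives from the configuration seed.
#'
#' @param config a [simulation_config()]
#' @param dir optional directory: when given, all Level-0 files are also
#'   written there via [write_cohort()]
#' @return list of class `synthetic_cohort`: `level0` (list `matrix`,
#'   `plates` as from [read_level0()]), `clinical`, `meds`, `review`,
#'   `targets`, `istd`, `blank_signals`, `rule`, `panel`, `truth`
#'   (ground-truth manifest), `config`
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  A <- config$n_analytes
  panel <- make_panel(A)
  an <- panel$analyte_id

  ## ---- analyte parameters and defect labels -----------------------------
  defect <- rep("none", A)
  n_bad <- sum(config$planted_bad)
  if (n_bad > 0) {
    idx <- sample.int(A, n_bad)
    defect[idx] <- rep(c("high_cv", "low_icc", "high_censoring"),
                       times = config$planted_bad)
  }
  meanlog <- log(10^stats::runif(A, config$conc_log10_range[1],
                                 config$conc_log10_range[2]))
  sdlog_bio <- rep(sqrt(log(1 + config$biological_cv^2)), A)
  sdlog_bio[defect == "low_icc"] <- 0
  tech_cv <- rep(config$technical_cv, A)
  tech_cv[defect == "high_cv"] <- config$high_cv_value
  censor_q <- rep(config$censor_q_clean, A)
  censor_q[defect == "high_censoring"] <- config$censor_q_high

  ## ---- subjects, roles, plate assignment --------------------------------
  n_sub <- config$n_study_samples - config$n_duplicate_pairs
  subjects <- sprintf("S%04d", seq_len(n_sub))
  pool <- sample(subjects)                      # shuffled role assignment
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]
                        out }
  dup_subjects <- if (config$n_duplicate_pairs) take(config$n_duplicate_pairs)
                  else character()
  nf_subjects <- if (config$n_non_fasting) take(config$n_non_fasting)
                 else character()
  bmi_subjects <- if (config$n_missing_bmi) take(config$n_missing_bmi)
                  else character()
  med_subjects <- if (config$n_missing_meds) take(config$n_missing_meds)
                  else character()
  out_subjects <- if (config$n_outlier_subjects)
                    take(config$n_outlier_subjects) else character()
  thaw_subjects <- if (config$n_thawed) take(config$n_thawed) else character()

  ## subject truth matrix
  truth_mat <- exp(matrix(meanlog, n_sub, A, byrow = TRUE) +
                   matrix(stats::rnorm(n_sub * A), n_sub, A) *
                   matrix(sdlog_bio, n_sub, A, byrow = TRUE))
  dimnames(truth_mat) <- list(subjects, an)
  if (length(out_subjects)) {
    mu <- colMeans(truth_mat)
    sds <- apply(truth_mat, 2, stats::sd)
    shift <- config$outlier_magnitude / sqrt(A)
    for (s in out_subjects)
      truth_mat[s, ] <- mu + shift * sds
  }

  ## study sample list: one aliquot per subject plus duplicate re-aliquots
  samp_subject <- c(subjects, dup_subjects)
  samp_id <- sprintf("X%05d", seq_along(samp_subject))
  ord <- sample(length(samp_subject))           # scatter across plates
  samp_subject <- samp_subject[ord]
  samp_id <- samp_id[ord]
  thawed_samples <- samp_id[match(thaw_subjects, samp_subject)]

  plate_ids <- sprintf("P%02d", seq_len(config$n_plates))
  b <- exp(stats::rnorm(config$n_plates, 0, config$plate_effect_sd))
  names(b) <- plate_ids
  ## per-plate LOD (scales with the plate's sensitivity)
  sdlog_marg <- sqrt(sdlog_bio^2 + log(1 + tech_cv^2))
  lod_base <- ifelse(censor_q > 0,
                     stats::qlnorm(censor_q, meanlog, sdlog_marg), 0)
  lod <- outer(b, lod_base)                     # plates x analytes
  dimnames(lod) <- list(plate_ids, an)

  ## assign study samples to plates in order
  per_plate <- pmin(config$study_wells_per_plate,
                    config$n_study_samples -
                      config$study_wells_per_plate *
                      (seq_len(config$n_plates) - 1L))
  per_plate <- pmax(per_plate, 0L)
  plate_of <- rep(plate_ids, per_plate)

  noise <- function(n, cv) pmax(0, 1 + stats::rnorm(n) * cv)

  ## ---- build rows plate by plate -----------------------------------------
  spqc_truth <- exp(meanlog)
  nist_truth <- 0.8 * spqc_truth
  ref_truth <- 1.2 * spqc_truth
  cal_targets <- do.call(rbind, lapply(seq_len(config$n_calibrator_levels),
    function(l) data.frame(analyte_id = an[panel$platform == "UPLC"],
                           kind = "calibrator", level = l,
                           target = spqc_truth[panel$platform == "UPLC"] *
                             2^(l - 4), stringsAsFactors = FALSE)))
  qc_mult <- c(0.25, 1, 4)
  qc_targets <- do.call(rbind, lapply(1:3, function(l)
    data.frame(analyte_id = an, kind = "kit_QC", level = l,
               target = spqc_truth * qc_mult[l], stringsAsFactors = FALSE)))
  targets <- rbind(cal_targets, qc_targets)

  rows_samples <- list(); rows_values <- list(); rows_status <- list()
  plates <- list()
  taken <- 0L
  for (pi in seq_along(plate_ids)) {
    p <- plate_ids[pi]
    ns <- per_plate[pi]
    if (ns == 0L) next
    layout <- plate_layout(ns, config$n_calibrator_levels)
    nw <- length(layout)
    sid <- character(nw); sub <- character(nw)
    vals <- matrix(NA_real_, nw, A, dimnames = list(NULL, an))
    stat <- matrix("missing", nw, A)
    study_slots <- which(layout == "study")
    these <- taken + seq_len(ns)
    sid[study_slots] <- samp_id[these]
    sub[study_slots] <- samp_subject[these]
    taken <- taken + ns
    counters <- new.env(parent = emptyenv())
    for (w in seq_len(nw)) {
      role <- layout[w]
      if (role == "study") {
        vals[w, ] <- truth_mat[sub[w], ] * b[p] * noise(A, tech_cv)
        stat[w, ] <- "valid"
        next
      }
      k <- (get0(role, counters, ifnotfound = 0L)) + 1L
      assign(role, k, counters)
      sid[w] <- sprintf("%s_%s_%d", p, role, k)
      sub[w] <- sid[w]
      if (role == "SPQC") {
        vals[w, ] <- spqc_truth * b[p] * noise(A, tech_cv)
        stat[w, ] <- "valid"
      } else if (role == "NIST") {
        vals[w, ] <- nist_truth * b[p] * noise(A, tech_cv)
        stat[w, ] <- "valid"
      } else if (role == "reference_serum") {
        vals[w, ] <- ref_truth * b[p] * noise(A, tech_cv)
        stat[w, ] <- "valid"
      } else if (role == "zero") {
        vals[w, ] <- lod[p, ] / 3
        stat[w, ] <- "valid"
      } else if (role == "blank") {
        vals[w, ] <- lod[p, ] / 6
        stat[w, ] <- "valid"
      } else if (startsWith(role, "calibrator_")) {
        l <- as.integer(sub("calibrator_", "", role))
        up <- panel$platform == "UPLC"
        vals[w, up] <- spqc_truth[up] * 2^(l - 4) * noise(sum(up), 0.03)
        stat[w, up] <- "valid"
      } else if (startsWith(role, "kit_QC")) {
        l <- as.integer(sub("kit_QC", "", role))
        vals[w, ] <- spqc_truth * qc_mult[l] * noise(A, 0.05)
        stat[w, ] <- "valid"
      }
    }
    ## censoring against the plate LOD (measured cohort/pool wells only)
    cens_roles <- layout %in% c("study", "SPQC", "NIST", "reference_serum")
    lodm <- matrix(lod[p, ], nw, A, byrow = TRUE)
    cens <- cens_roles & !is.na(vals) & vals < lodm
    vals[cens] <- NA_real_
    stat[cens] <- "below_LOD"
    smp <- data.frame(sample_id = sid, subject_id = sub, plate_id = p,
                      well_id = sprintf("W%03d", seq_len(nw)), role = layout,
                      stringsAsFactors = FALSE)
    rows_samples[[p]] <- smp
    rows_values[[p]] <- vals
    rows_status[[p]] <- stat
    wells <- smp[c("well_id", "role", "sample_id", "subject_id")]
    wells$injection_position <- seq_len(nw)
    plates[[p]] <- plate_run(p, wells, stats::setNames(lod[p, ], an))
  }
  samples <- do.call(rbind, rows_samples)
  rownames(samples) <- NULL
  values <- do.call(rbind, rows_values)
  status <- do.call(rbind, rows_status)
  samples$duplicate_group <- ifelse(
    samples$role == "study" & samples$subject_id %in% dup_subjects,
    samples$subject_id, NA_character_)
  mm <- measurement_matrix(samples, values, status)

  ## ---- clinical -----------------------------------------------------------
  clinical <- data.frame(subject_id = subjects,
                         fasting = !(subjects %in% nf_subjects),
                         bmi = round(pmax(15, stats::rnorm(n_sub, 27, 4)), 1),
                         has_baseline_med_record =
                           !(subjects %in% med_subjects),
                         stringsAsFactors = FALSE)
  clinical$bmi[clinical$subject_id %in% bmi_subjects] <- NA_real_
  flag_block <- function(subs, why)
    data.frame(subject_id = subs, reason = rep(why, length(subs)),
               stringsAsFactors = FALSE)
  flagged <- rbind(flag_block(nf_subjects, "non-fasting"),
                   flag_block(bmi_subjects, "missing-BMI"),
                   flag_block(med_subjects, "missing-med-record"))
  flagged$sample_id <- samp_id[match(flagged$subject_id, samp_subject)]

  ## ---- medications --------------------------------------------------------
  lex <- read_lexicon()
  drug_names <- names(lex$drugs)
  dose_vocab <- c("10mg", "25 mg", "50mg QD", "100 mg BID", "5mg daily",
                  "500mg", "20 mg qhs", "1 tab PO QD", "")
  med_rows <- list(); review_map <- list()
  med_drugs <- stats::setNames(vector("list", n_sub), subjects)
  for (s in subjects) {
    if (s %in% med_subjects) next  # no baseline record
    k <- sample.int(config$n_meds_max + 1L, 1L) - 1L
    if (k == 0L) next
    drugs <- sample(drug_names, k)
    med_drugs[[s]] <- drugs
    for (d in drugs) {
      shown <- d
      if (stats::runif(1) < config$typo_rate) {
        ty <- swap_typo(d)
        if (nzchar(ty)) {
          cand <- match_term(ty, lex)[1, ]
          if (cand$status == "needs_review") {
            shown <- ty
            review_map[[ty]] <- d
          } else if (cand$status == "auto_accepted" &&
                     identical(sort(unlist(lex$drugs[[cand$candidate]])),
                               sort(unlist(lex$drugs[[d]])))) {
            shown <- ty  # close enough to auto-resolve correctly
          }                     # else: keep the clean spelling
        }
      }
      dose <- dose_vocab[sample.int(length(dose_vocab), 1L)]
      med_rows[[length(med_rows) + 1L]] <-
        data.frame(subject_id = s, visit = "baseline",
                   raw_text = trimws(paste(shown, dose)),
                   stringsAsFactors = FALSE)
    }
  }
  meds <- if (length(med_rows))
    do.call(rbind, c(med_rows, make.row.names = FALSE))
  else data.frame(subject_id = character(), visit = character(),
                  raw_text = character(), stringsAsFactors = FALSE)
  review <- if (length(review_map))
    data.frame(query = names(review_map), decision = "accept_as",
               target = unlist(review_map), stringsAsFactors = FALSE,
               row.names = NULL)
  else data.frame(query = character(), decision = character(),
                  target = character(), stringsAsFactors = FALSE)
  ## ground-truth class matrix over subjects appearing in the meds table
  med_subjects_present <- unique(meds$subject_id)
  class_list <- default_drug_classes()$class
  med_truth <- matrix(FALSE, length(med_subjects_present),
                      length(class_list),
                      dimnames = list(med_subjects_present, class_list))
  for (s in med_subjects_present) {
    for (d in med_drugs[[s]]) {
      cls <- unique(unlist(lapply(lex$drugs[[d]], function(ing)
        vapply(lex$ingredients[[ing]], `[[`, "", "class"))))
      med_truth[s, intersect(cls, class_list)] <- TRUE
    }
  }
  med_truth_df <- data.frame(subject_id = med_subjects_present,
                             stringsAsFactors = FALSE, check.names = FALSE)
  med_truth_df <- cbind(med_truth_df,
                        as.data.frame(med_truth, check.names = FALSE))
  rownames(med_truth_df) <- NULL

  ## ---- kit-validation side tables ----------------------------------------
  istd_ids <- sprintf("ISTD%02d", 1:10)
  istd <- do.call(rbind, lapply(plate_ids[per_plate > 0], function(p)
    data.frame(plate_id = p, standard_id = istd_ids,
               intensity = stats::runif(length(istd_ids), 3e5, 6e5),
               stringsAsFactors = FALSE)))
  blank_signals <- do.call(rbind, lapply(plate_ids[per_plate > 0],
    function(p) data.frame(plate_id = p, analyte_id = an,
                           signal = stats::runif(A, 5, 20),
                           stringsAsFactors = FALSE)))
  rule <- validation_rule(
    blank_max = 50,
    istd_bounds = stats::setNames(rep(list(c(2e5, 8e5)), length(istd_ids)),
                                  istd_ids))

  truth <- list(
    plate_effects = b,
    analyte_defects = data.frame(analyte_id = an, defect = defect,
                                 meanlog = meanlog, sdlog_bio = sdlog_bio,
                                 technical_cv = tech_cv,
                                 censor_target = censor_q,
                                 stringsAsFactors = FALSE),
    expected_dropped_analytes = an[defect != "none"],
    outlier_subjects = sort(out_subjects),
    duplicate_subjects = sort(dup_subjects),
    flagged_samples = flagged,
    excluded_samples = thawed_samples,
    subject_truth = truth_mat,
    lod = lod,
    med_truth = med_truth_df)

  sim <- structure(list(level0 = list(matrix = mm, plates = plates),
                        clinical = clinical, meds = meds, review = review,
                        targets = targets, istd = istd,
                        blank_signals = blank_signals, rule = rule,
                        panel = panel, truth = truth, config = config),
                   class = "synthetic_cohort")
  if (!is.null(dir)) sim$files <- write_cohort(sim, dir)
  sim
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d plates, %d study samples ",
                     "(%d subjects, %d duplicate pairs), %d analytes ",
                     "(%d planted defects)\n"),
              x$config$n_plates, x$config$n_study_samples,
              x$config$n_study_samples - x$config$n_duplicate_pairs,
              x$config$n_duplicate_pairs, x$config$n_analytes,
              length(x$truth$expected_dropped_analytes)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the Level-0 file formats
#'
#' Emits exactly the files [read_level0()] and friends read: one plate
#' export CSV per plate under `plates/`, `manifest.csv`, `lod.csv`,
#' `clinical.csv`, `meds.csv`, `review.csv`, `targets.csv`, `istd.csv`,
#' `blank_signals.csv` and the ground-truth manifest
#' `ground_truth.json`.
#'
#' @param sim a [simulate_cohort()] result
#' @param dir output directory (created)
#' @return named list of file paths
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(file.path(dir, "plates"), recursive = TRUE,
             showWarnings = FALSE)
  mm <- sim$level0$matrix
  wcsv <- function(d, path) {
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    utils::write.csv(d, con, row.names = FALSE, quote = TRUE, eol = "\n")
    path
  }
  plate_files <- character()
  for (p in names(sim$level0$plates)) {
    idx <- mm$samples$plate_id == p
    cells <- encode_cells(mm$values[idx, , drop = FALSE],
                          mm$status[idx, , drop = FALSE])
    colnames(cells) <- colnames(mm$values)
    tab <- cbind(data.frame(plate_id = p,
                            well_id = mm$samples$well_id[idx],
                            stringsAsFactors = FALSE),
                 as.data.frame(cells, stringsAsFactors = FALSE,
                               check.names = FALSE))
    plate_files[p] <- wcsv(tab, file.path(dir, "plates",
                                          paste0(p, ".csv")))
  }
  manifest <- do.call(rbind, lapply(sim$level0$plates, function(pr)
    cbind(data.frame(plate_id = pr$plate_id, stringsAsFactors = FALSE),
          pr$wells)))
  rownames(manifest) <- NULL
  lod <- do.call(rbind, lapply(sim$level0$plates, function(pr)
    data.frame(plate_id = pr$plate_id, analyte_id = names(pr$lod),
               lod = fmt_num(unname(pr$lod)), stringsAsFactors = FALSE)))
  rownames(lod) <- NULL
  files <- list(
    plates = plate_files,
    manifest = wcsv(manifest, file.path(dir, "manifest.csv")),
    lod = wcsv(lod, file.path(dir, "lod.csv")),
    clinical = wcsv(sim$clinical, file.path(dir, "clinical.csv")),
    meds = wcsv(sim$meds, file.path(dir, "meds.csv")),
    review = wcsv(sim$review, file.path(dir, "review.csv")),
    targets = wcsv(sim$targets, file.path(dir, "targets.csv")),
    istd = wcsv(sim$istd, file.path(dir, "istd.csv")),
    blank_signals = wcsv(sim$blank_signals,
                         file.path(dir, "blank_signals.csv")))
  gt <- sim$truth
  gt$subject_truth <- NULL   # large matrix: kept in memory only
  gt$lod <- NULL
  writeLines(as.character(canonical_json(gt)),
             file.path(dir, "ground_truth.json"))
  files$ground_truth <- file.path(dir, "ground_truth.json")
  writeLines(as.character(canonical_json(unclass(sim$rule))),
             file.path(dir, "rules.json"))
  files$rules <- file.path(dir, "rules.json")
  files
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Reassembles the Level-0 data, plate runs, clinical/medication tables,
#' validation targets and rule file from disk.
#'
#' @param dir directory produced by [write_cohort()] (or hand-assembled in
#'   the same layout)
#' @return list with `level0`, `clinical`, `meds`, `review`, `targets`,
#'   `istd`, `blank_signals`, `rule`
#' @export
read_cohort <- function(dir) {
  pf <- sort(list.files(file.path(dir, "plates"), full.names = TRUE,
                        pattern = "\\.csv$"))
  if (!length(pf)) stop2("no plate files under ", file.path(dir, "plates"))
  level0 <- read_level0(pf, file.path(dir, "manifest.csv"),
                        lod = file.path(dir, "lod.csv"))
  num_csv <- function(name, cols) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    x <- read_csv_strict(p)
    for (cc in cols) x[[cc]] <- as.numeric(x[[cc]])
    x
  }
  opt <- function(name, reader) {
    p <- file.path(dir, name)
    if (file.exists(p)) reader(p) else NULL
  }
  rule <- NULL
  rp <- file.path(dir, "rules.json")
  if (file.exists(rp)) {
    rl <- jsonlite::read_json(rp)
    rule <- validation_rule(
      calibrator_tolerance = rl$calibrator_tolerance,
      calibrator_min_valid = rl$calibrator_min_valid,
      qc_tolerance = rl$qc_tolerance,
      qc_min_valid_overall = rl$qc_min_valid_overall,
      qc_min_valid_per_level = rl$qc_min_valid_per_level,
      blank_max = if (!is.null(rl$blank_max)) unlist(rl$blank_max),
      istd_bounds = lapply(rl$istd_bounds, unlist))
  }
  targets <- num_csv("targets.csv", c("level", "target"))
  if (!is.null(targets)) targets$level <- as.integer(targets$level)
  list(level0 = level0,
       clinical = opt("clinical.csv", read_clinical),
       meds = opt("meds.csv", read_csv_strict),
       review = opt("review.csv", read_csv_strict),
       targets = targets,
       istd = num_csv("istd.csv", "intensity"),
       blank_signals = num_csv("blank_signals.csv", "signal"),
       rule = rule)
}

#' Validate every plate of a synthetic cohort
#'
#' Extracts calibrator and kit-QC injections from the cohort's measurement
#' matrix, joins the nominal targets, adds the blank/internal-standard
#' tables, and returns one [validate_plate()] verdict per plate.
#'
#' @param sim a [simulate_cohort()] result
#' @param rule a [validation_rule()]; defaults to the cohort's bundled rule
#' @return named list of `plate_verdict`
#' @export
validate_cohort_plates <- function(sim, rule = sim$rule) {
  mm <- sim$level0$matrix
  out <- list()
  for (p in names(sim$level0$plates)) {
    s <- mm$samples
    idx_cal <- which(s$plate_id == p & grepl("^calibrator_", s$role))
    cal <- NULL
    if (length(idx_cal)) {
      lv <- as.integer(sub("calibrator_", "", s$role[idx_cal]))
      v <- mm$values[idx_cal, , drop = FALSE]
      cal <- data.frame(analyte_id = rep(colnames(v), each = length(idx_cal)),
                        level = rep(lv, times = ncol(v)),
                        measured = as.vector(v), stringsAsFactors = FALSE)
      cal <- cal[!is.na(cal$measured), , drop = FALSE]
    }
    idx_qc <- which(s$plate_id == p & grepl("^kit_QC", s$role))
    qc <- NULL
    if (length(idx_qc)) {
      lv <- as.integer(sub("kit_QC", "", s$role[idx_qc]))
      v <- mm$values[idx_qc, , drop = FALSE]
      qc <- data.frame(analyte_id = rep(colnames(v), each = length(idx_qc)),
                       level = rep(lv, times = ncol(v)),
                       measured = as.vector(v), stringsAsFactors = FALSE)
      qc <- qc[!is.na(qc$measured), , drop = FALSE]
    }
    bl <- sim$blank_signals[sim$blank_signals$plate_id == p, ]
    it <- sim$istd[sim$istd$plate_id == p, ]
    out[[p]] <- validate_plate(
      p,
      calibrators = cal,
      calibrator_targets = sim$targets[sim$targets$kind == "calibrator", ],
      kit_qcs = qc,
      kit_qc_targets = sim$targets[sim$targets$kind == "kit_QC", ],
      blank_signals = stats::setNames(bl$signal, bl$analyte_id),
      istd_intensities = stats::setNames(it$intensity, it$standard_id),
      rule = rule)
  }
  out
}

#' Deterministic reference fixture
#'
#' A small, fully deterministic cohort (3 plates, 40 analytes, 6 duplicate
#' pairs, 2 planted defects per type, 1 planted outlier, fixed internal
#' seed) plus three crafted medication entries — one exact brand name, one
#' misspelling resolved by the bundled review file, one unknown drug —
#' used throughout the test and acceptance suites.
#'
#' @param dir optional directory to also write the Level-0 files to
#' @return a `synthetic_cohort` (see [simulate_cohort()])
#' @export
make_reference_fixture <- function(dir = NULL) {
  cfg <- simulation_config(
    n_plates = 3L, study_wells_per_plate = 40L, n_study_samples = 120L,
    n_duplicate_pairs = 6L, n_analytes = 40L,
    planted_bad = c(high_cv = 2L, low_icc = 2L, high_censoring = 2L),
    n_outlier_subjects = 1L, outlier_magnitude = 30,
    n_non_fasting = 3L, n_missing_bmi = 1L, n_missing_meds = 1L,
    n_thawed = 2L, seed = 104729L)
  sim <- simulate_cohort(cfg)
  ## crafted medication entries with known resolutions
  plain <- setdiff(sim$clinical$subject_id,
                   c(sim$truth$duplicate_subjects,
                     sim$truth$flagged_samples$subject_id,
                     sim$truth$outlier_subjects,
                     unique(sim$meds$subject_id)))
  who <- utils::head(sort(plain), 3)
  extra <- data.frame(subject_id = who, visit = "baseline",
                      raw_text = c("Aricept 10mg QD", "metfromin 500 mg",
                                   "Qzzxorbinol 5mg"),
                      stringsAsFactors = FALSE)
  sim$meds <- rbind(sim$meds, extra)
  if (!"metfromin" %in% sim$review$query)
    sim$review <- rbind(sim$review,
                        data.frame(query = "metfromin",
                                   decision = "accept_as",
                                   target = "metformin",
                                   stringsAsFactors = FALSE))
  lex <- read_lexicon()
  class_list <- default_drug_classes()$class
  add_truth <- function(df, subject, drug) {
    cls <- if (is.na(drug)) character()
           else unique(unlist(lapply(lex$drugs[[drug]], function(ing)
             vapply(lex$ingredients[[ing]], `[[`, "", "class"))))
    row <- df[1, , drop = FALSE]
    row$subject_id <- subject
    row[, -1] <- FALSE
    row[, intersect(cls, class_list)] <- TRUE
    rbind(df, row)
  }
  mt <- sim$truth$med_truth
  if (!nrow(mt)) {
    mt <- data.frame(subject_id = character(), stringsAsFactors = FALSE,
                     check.names = FALSE)
    for (cl in class_list) mt[[cl]] <- logical()
  }
  mt <- add_truth(mt, who[1], "aricept")
  mt <- add_truth(mt, who[2], "metformin")
  mt <- add_truth(mt, who[3], NA)
  rownames(mt) <- NULL
  sim$truth$med_truth <- mt
  sim$truth$crafted_meds <- data.frame(
    subject_id = who,
    kind = c("exact", "misspelled", "unknown"),
    raw_text = extra$raw_text, stringsAsFactors = FALSE)
  if (!is.null(dir)) sim$files <- write_cohort(sim, dir)
  sim
}
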