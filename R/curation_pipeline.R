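## Orchestration of the staged curation workflow (Levels 1..5) with a
## full audit trail, producing one curated subject x analyte matrix.

#' Pipeline configuration
#'
#' Thresholds default to the curation workflow's canonical values: CV
#' < 20\%, ICC > 0.65, at most 40\% censored measurements, >90\%
#' cumulative PCA variance, 7-sd outlier distance, and log2 transformation
#' when the omnibus normality p-value is below 0.05 with skewness above 2.
#'
#' @param cv_max duplicate CV retention threshold in percent
#' @param icc_min ICC retention threshold
#' @param lod_pct_max censoring retention threshold in percent
#' @param var_cum cumulative variance target for outlier PCA
#' @param k_sd outlier distance threshold in sds
#' @param dagostino_alpha omnibus normality significance level
#' @param skew_min skewness threshold for log2 transformation
#' @param exclusion_lists data.frame (`sample_id`, `reason`) or character
#'   vector of sample ids dropped at Level 1 (pre-analytical exclusions,
#'   e.g. thawed during shipment)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(cv_max = 20, icc_min = 0.65, lod_pct_max = 40,
                            var_cum = 0.90, k_sd = 7,
                            dagostino_alpha = 0.05, skew_min = 2,
                            exclusion_lists = NULL) {
  thr <- c(cv_max, icc_min, lod_pct_max, var_cum, k_sd, dagostino_alpha,
           skew_min)
  if (any(!is.finite(thr) | thr <= 0)) stop2("thresholds must be positive")
  if (is.character(exclusion_lists))
    exclusion_lists <- data.frame(sample_id = exclusion_lists,
                                  reason = "pre-analytical exclusion",
                                  stringsAsFactors = FALSE)
  structure(list(cv_max = cv_max, icc_min = icc_min,
                 lod_pct_max = lod_pct_max, var_cum = var_cum, k_sd = k_sd,
                 dagostino_alpha = dagostino_alpha, skew_min = skew_min,
                 exclusion_lists = exclusion_lists),
            class = "pipeline_config")
}

audit_entry <- function(samples_before, samples_after,
                        analytes_before, analytes_after,
                        removed_samples = NULL, removed_analytes = NULL,
                        extra = list()) {
  c(list(samples_before = samples_before, samples_after = samples_after,
         samples_removed = samples_before - samples_after,
         analytes_before = analytes_before, analytes_after = analytes_after,
         analytes_removed = analytes_before - analytes_after,
         removed_samples = removed_samples,
         removed_analytes = removed_analytes),
    extra)
}

n_study <- function(mm) sum(mm$samples$role == "study")

#' Level 1: pre-analytical sample exclusion
#'
#' Removes samples listed in the configuration's exclusion list (reason
#' recorded per sample).  Listed ids that are absent produce a warning,
#' not a failure; listed ids that refer to QC wells are rejected.
#'
#' @param matrix Level-0 [measurement_matrix()]
#' @param config a [pipeline_config()]
#' @return list(`matrix`, `audit`)
#' @export
level1_exclude <- function(matrix, config = pipeline_config()) {
  excl <- config$exclusion_lists
  s <- matrix$samples
  nb <- n_study(matrix); ab <- ncol(matrix$values)
  removed <- NULL
  if (!is.null(excl) && nrow(excl)) {
    hit <- excl$sample_id %in% s$sample_id
    if (any(!hit))
      warning("exclusion list id(s) not present: ",
              paste(excl$sample_id[!hit], collapse = ", "), call. = FALSE)
    excl <- excl[hit, , drop = FALSE]
    role <- s$role[match(excl$sample_id, s$sample_id)]
    if (any(role != "study"))
      stop2("exclusion list refers to non-study well(s): ",
            paste(excl$sample_id[role != "study"], collapse = ", "))
    keep <- !(s$sample_id %in% excl$sample_id)
    matrix <- matrix[keep, ]
    removed <- excl
  }
  list(matrix = matrix,
       audit = audit_entry(nb, n_study(matrix), ab, ncol(matrix$values),
                           removed_samples = removed))
}

#' Level 2: cross-plate SPQC scaling
#'
#' Computes and applies the study-pool-QC scaling factors; the full
#' factor table is recorded in the audit.
#'
#' @inheritParams level1_exclude
#' @return list(`matrix`, `factors`, `audit`)
#' @export
level2_scale <- function(matrix, config = pipeline_config()) {
  factors <- compute_scaling_factors(matrix)
  out <- apply_scaling(matrix, factors)
  nb <- n_study(matrix)
  list(matrix = out, factors = factors,
       audit = audit_entry(nb, nb, ncol(matrix$values), ncol(out$values),
                           extra = list(factors = as.data.frame(factors))))
}

#' Level 3: analyte quality filtering
#'
#' Computes duplicate CV, ICC and the censoring percentage on the scaled
#' matrix and removes analyte columns failing the retention verdict; the
#' audit lists each dropped analyte with its metrics and first-failing
#' rule.
#'
#' @inheritParams level1_exclude
#' @param duplicate_groups optional named list of sample-id pairs (default:
#'   derived from the samples table)
#' @return list(`matrix`, `metrics`, `audit`)
#' @export
level3_filter <- function(matrix, duplicate_groups = NULL,
                          config = pipeline_config()) {
  grp <- duplicate_groups %||% duplicate_group_list(matrix)
  if (!length(grp)) stop2("no duplicate groups available for analyte QC")
  cv <- duplicate_cv(matrix, grp)
  icc <- duplicate_icc(matrix, grp)
  pct <- pct_below_lod(matrix)
  metrics <- analyte_verdicts(cv, icc, pct, cv_max = config$cv_max,
                              icc_min = config$icc_min,
                              lod_pct_max = config$lod_pct_max)
  keep <- metrics$analyte_id[metrics$verdict == "retain"]
  out <- matrix[, colnames(matrix$values) %in% keep]
  dropped <- metrics[metrics$verdict != "retain", , drop = FALSE]
  list(matrix = out, metrics = metrics,
       audit = audit_entry(n_study(matrix), n_study(out),
                           ncol(matrix$values), ncol(out$values),
                           removed_analytes = dropped))
}

#' Level 4: LOD/2 imputation and pre-analytical flagging
#'
#' Every remaining `below_LOD` study cell is set to half the limit of
#' detection of the plate the sample ran on (status becomes `imputed`).
#' Samples are flagged for removal when their subject is non-fasting,
#' lacks a BMI value, or has no baseline medication record; flagged rows
#' are retained until Level 5.
#'
#' @inheritParams level1_exclude
#' @param clinical clinical table (see [read_clinical()])
#' @param lod_tables data.frame (`plate_id`, `analyte_id`, `lod`) or a
#'   list of [plate_run()] objects carrying LODs
#' @return list(`matrix`, `audit`)
#' @export
level4_impute_and_flag <- function(matrix, clinical, lod_tables,
                                   config = pipeline_config()) {
  if (inherits(lod_tables, "plate_run")) lod_tables <- list(lod_tables)
  if (is.list(lod_tables) && !is.data.frame(lod_tables))
    lod_tables <- do.call(rbind, lapply(lod_tables, function(p)
      data.frame(plate_id = rep(p$plate_id, length(p$lod)),
                 analyte_id = names(p$lod) %||% character(),
                 lod = unname(p$lod), stringsAsFactors = FALSE)))
  s <- matrix$samples
  v <- matrix$values
  st <- matrix$status
  plates <- unique(s$plate_id)
  an <- colnames(v)
  lm <- matrix(NA_real_, length(plates), length(an),
               dimnames = list(plates, an))
  keep <- lod_tables$plate_id %in% plates & lod_tables$analyte_id %in% an
  lm[cbind(lod_tables$plate_id[keep], lod_tables$analyte_id[keep])] <-
    lod_tables$lod[keep]
  is_study <- s$role == "study"
  cens <- st == "below_LOD" & is_study
  lod_cells <- lm[s$plate_id, , drop = FALSE][cens]
  if (anyNA(lod_cells))
    stop2("below_LOD cell(s) with no plate LOD entry: ",
          sum(is.na(lod_cells)), " cell(s)")
  v[cens] <- lod_cells / 2
  st[cens] <- "imputed"
  ## pre-analytical flags (recorded, rows kept until Level 5)
  cl <- clinical[match(s$subject_id, clinical$subject_id), , drop = FALSE]
  if (any(is_study & is.na(cl$subject_id)))
    stop2("study sample(s) with subject missing from clinical table: ",
          paste(utils::head(s$sample_id[is_study & is.na(cl$subject_id)], 5),
                collapse = ", "))
  reasons <- character(nrow(s))
  add_reason <- function(cond, label) {
    cond <- is_study & !is.na(cond) & cond
    ifelse(cond, ifelse(reasons == "", label,
                        paste(reasons, label, sep = ";")), reasons)
  }
  reasons <- add_reason(!cl$fasting, "non-fasting")
  reasons <- add_reason(is.na(cl$bmi) & is_study, "missing-BMI")
  reasons <- add_reason(!cl$has_baseline_med_record, "missing-med-record")
  s$flag <- reasons
  out <- measurement_matrix(s, v, st)
  flagged <- s[s$flag != "", c("sample_id", "subject_id", "flag")]
  list(matrix = out,
       audit = audit_entry(n_study(matrix), n_study(out), length(an),
                           length(an),
                           extra = list(n_imputed = sum(cens),
                                        flagged_samples = flagged)))
}

#' Level 5: finalization to one row per subject
#'
#' Fixed order of operations: (1) drop the samples flagged at Level 4
#' (and all QC wells); (2) average blinded duplicate pairs to a single row
#' per subject; (3) flag and drop score-space outliers via
#' [pca_outliers()]; (4) log2-transform analytes selected by
#' [normality_decision()].
#'
#' @inheritParams level1_exclude
#' @return list(`matrix`, `outliers` (an `outlier_report`),
#'   `log2_analytes`, `audit`)
#' @export
level5_finalize <- function(matrix, config = pipeline_config()) {
  s <- matrix$samples
  nb <- n_study(matrix); ab <- ncol(matrix$values)
  keep <- s$role == "study" & s$flag == ""
  dropped_flagged <- s[s$role == "study" & s$flag != "",
                       c("sample_id", "subject_id", "flag")]
  m1 <- matrix[keep, ]
  if (anyNA(m1$values))
    stop2("Level 5 requires a complete matrix (",
          sum(is.na(m1$values)), " missing cells remain)")
  ## average duplicate pairs -> one row per subject
  sub <- m1$samples$subject_id
  uniq <- unique(sub)
  v <- rowsum(m1$values, group = sub, reorder = FALSE) /
    as.vector(table(factor(sub, levels = unique(sub))))
  st <- matrix("valid", nrow(v), ncol(v), dimnames = dimnames(v))
  for (stat in c("imputed", "below_LLOQ", "semi_quant")) {
    hit <- rowsum((m1$status == stat) + 0, group = sub, reorder = FALSE) > 0
    st[hit & st == "valid"] <- stat
  }
  samples <- data.frame(sample_id = uniq, subject_id = uniq,
                        plate_id = "", well_id = "", role = "study",
                        duplicate_group = NA_character_, flag = "",
                        stringsAsFactors = FALSE)
  m2 <- measurement_matrix(samples, v, st)
  ## score-space outliers
  rep_out <- pca_outliers(m2$values, var_cum = config$var_cum,
                          k_sd = config$k_sd)
  m3 <- m2[!(m2$samples$subject_id %in% rep_out$flagged), ]
  ## conditional log2
  log2_analytes <- character()
  vals <- m3$values
  for (a in colnames(vals)) {
    if (isTRUE(as.logical(suppressWarnings(
      normality_decision(vals[, a], alpha = config$dagostino_alpha,
                         skew_min = config$skew_min))))) {
      if (any(vals[, a] <= 0))
        stop2("analyte ", a, " selected for log2 has non-positive values")
      vals[, a] <- log2(vals[, a])
      log2_analytes <- c(log2_analytes, a)
    }
  }
  m4 <- measurement_matrix(m3$samples, vals, m3$status)
  list(matrix = m4, outliers = rep_out, log2_analytes = log2_analytes,
       audit = audit_entry(nb, nrow(m4$values), ab, ncol(m4$values),
                           extra = list(
                             flagged_dropped = dropped_flagged,
                             n_subjects = nrow(m4$values),
                             outlier_subjects = rep_out$flagged,
                             log2_analytes = log2_analytes)))
}

#' Run the full Level 0 -> Level 5 curation pipeline
#'
#' Deterministic end to end: identical inputs and configuration give
#' bit-identical outputs.  When `outdir` is given, every intermediate
#' level file, the audit, the analyte QC metrics and the scaling-factor
#' table are written there.
#'
#' @param level0 list with `matrix` (a [measurement_matrix()]) and
#'   `plates` (list of [plate_run()]), as returned by [read_level0()] or
#'   [simulate_cohort()]
#' @param clinical clinical table (see [read_clinical()])
#' @param config a [pipeline_config()]
#' @param outdir optional output directory (created if needed)
#' @return object of class `curation_result`: list with `matrix` (Level 5),
#'   `audit` (class `curation_audit`), `levels` (matrices 1..5), `metrics`,
#'   `factors`, `outliers`, `log2_analytes`
#' @export
run_pipeline <- function(level0, clinical, config = pipeline_config(),
                         outdir = NULL) {
  stopifnot(inherits(level0$matrix, "measurement_matrix"))
  l1 <- level1_exclude(level0$matrix, config)
  l2 <- level2_scale(l1$matrix, config)
  l3 <- level3_filter(l2$matrix, config = config)
  l4 <- level4_impute_and_flag(l3$matrix, clinical, level0$plates, config)
  l5 <- level5_finalize(l4$matrix, config)
  audit <- structure(list(levels = list(level1 = l1$audit, level2 = l2$audit,
                                        level3 = l3$audit, level4 = l4$audit,
                                        level5 = l5$audit),
                          config_hash = config_hash(config)),
                     class = "curation_audit")
  res <- structure(list(matrix = l5$matrix, audit = audit,
                        levels = list(level1 = l1$matrix, level2 = l2$matrix,
                                      level3 = l3$matrix, level4 = l4$matrix,
                                      level5 = l5$matrix),
                        metrics = l3$metrics, factors = l2$factors,
                        outliers = l5$outliers,
                        log2_analytes = l5$log2_analytes),
                   class = "curation_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in 1:5)
      write_level(res$levels[[i]], i,
                  file.path(outdir, sprintf("LEVEL%d.csv", i)),
                  config = config,
                  log2_analytes = if (i == 5) res$log2_analytes
                                  else character())
    utils::write.csv(res$metrics, file.path(outdir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$factors),
                     file.path(outdir, "scaling_factors.csv"),
                     row.names = FALSE)
    writeLines(as.character(audit_json(audit)),
               file.path(outdir, "audit.json"))
  }
  res
}

#' Serialize a curation audit to canonical JSON
#' @param audit a `curation_audit`
#' @return JSON string
#' @export
audit_json <- function(audit) {
  canonical_json(unclass(audit))
}

#' @export
print.curation_audit <- function(x, ...) {
  cat("curation_audit\n")
  for (nm in names(x$levels)) {
    a <- x$levels[[nm]]
    cat(sprintf("  %s: samples %d -> %d, analytes %d -> %d\n", nm,
                a$samples_before, a$samples_after,
                a$analytes_before, a$analytes_after))
  }
  invisible(x)
}

#' @export
print.curation_result <- function(x, ...) {
  cat("curation_result\n")
  print(x$audit)
  cat(sprintf("  final: %d subjects x %d analytes; %d log2-transformed\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              length(x$log2_analytes)))
  invisible(x)
}
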