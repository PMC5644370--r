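test_that("pre-analytical exclusion removes listed study samples only", {
  sim <- simulate_cohort(small_cfg(401, n_thawed = 4L))
  mm <- sim$level0$matrix
  # empty exclusion list -> identity
  ident <- level1_exclude(mm, pipeline_config())
  expect_identical(ident$matrix$values, mm$values)
  # the 4 listed thawed samples are removed with a reason
  cfg <- pipeline_config(exclusion_lists = sim$truth$excluded_samples)
  out <- level1_exclude(mm, cfg)
  expect_equal(out$audit$samples_before - out$audit$samples_after, 4L)
  expect_false(any(sim$truth$excluded_samples %in%
                     out$matrix$samples$sample_id))
  expect_identical(out$audit$removed_samples$reason,
                   rep("pre-analytical exclusion", 4))
  # absent id -> warning, not failure
  expect_warning(level1_exclude(mm, pipeline_config(
    exclusion_lists = "NOT_A_SAMPLE")), "not present")
  # excluding an SPQC well is rejected
  spqc_id <- mm$samples$sample_id[mm$samples$role == "SPQC"][1]
  expect_error(level1_exclude(mm, pipeline_config(
    exclusion_lists = spqc_id)), "non-study")
})

test_that("level 2 scaling removes planted batch effects and logs factors", {
  sim <- simulate_cohort(small_cfg(402, plate_effect_sd = 0.3,
                                   technical_cv = 0, censor_q_clean = 0))
  l2 <- level2_scale(sim$level0$matrix)
  # noiseless SPQC: recovered factors proportional to 1/b exactly
  b <- sim$truth$plate_effects
  f <- l2$factors
  expect_equal(f$factor, unname(mean(b) / b[f$plate_id]), tolerance = 1e-12)
  # factor logged for every (plate, analyte)
  expect_equal(nrow(l2$audit$factors),
               length(b) * ncol(sim$level0$matrix$values))
  # post-scaling SPQC means equal across plates
  s <- l2$matrix$samples
  spqc <- s$role == "SPQC"
  for (a in analyte_ids(l2$matrix)) {
    means <- tapply(l2$matrix$values[spqc, a], s$plate_id[spqc], mean)
    expect_lt(diff(range(means)) / mean(means), 1e-9)
  }
  # single-plate input is an identity
  one <- simulate_cohort(small_cfg(403, n_plates = 1L,
                                   study_wells_per_plate = 30L,
                                   n_study_samples = 30L,
                                   n_duplicate_pairs = 3L))
  l2one <- level2_scale(one$level0$matrix)
  expect_equal(l2one$matrix$values, one$level0$matrix$values,
               tolerance = 1e-12)
})

test_that("level 3 drops exactly the planted defect analytes", {
  cfg <- small_cfg(404, n_plates = 6L, n_study_samples = 120L,
                   n_duplicate_pairs = 20L, n_analytes = 20L,
                   planted_bad = c(high_cv = 2L, low_icc = 2L,
                                   high_censoring = 2L))
  sim <- simulate_cohort(cfg)
  l2 <- suppressWarnings(level2_scale(sim$level0$matrix))
  l3 <- suppressWarnings(level3_filter(l2$matrix))
  dropped <- l3$audit$removed_analytes$analyte_id
  expect_setequal(dropped, sim$truth$expected_dropped_analytes)
  expect_equal(ncol(l3$matrix$values), 20L - 6L)
  # audit records metrics and the first-failing rule for each removal
  expect_true(all(c("cv", "icc", "pct_below_lod", "verdict") %in%
                    names(l3$audit$removed_analytes)))
  # all-clean panel: nothing removed
  clean <- simulate_cohort(small_cfg(405, n_duplicate_pairs = 10L,
                                     n_study_samples = 60L))
  l3c <- suppressWarnings(level3_filter(
    level2_scale(clean$level0$matrix)$matrix))
  expect_identical(nrow(l3c$audit$removed_analytes), 0L)
})

test_that("level 4 imputes plate LOD/2 and flags pre-analytical samples", {
  fx <- get_fixture()
  cfg <- pipeline_config(exclusion_lists = fx$truth$excluded_samples)
  l1 <- level1_exclude(fx$level0$matrix, cfg)
  l2 <- suppressWarnings(level2_scale(l1$matrix))
  l3 <- suppressWarnings(level3_filter(l2$matrix))
  l4 <- level4_impute_and_flag(l3$matrix, fx$clinical, fx$level0$plates)
  m3 <- l3$matrix; m4 <- l4$matrix
  was_lod <- m3$status == "below_LOD" & m3$samples$role == "study"
  expect_gt(sum(was_lod), 0)
  # exhaustive: every below_LOD study cell equals its plate LOD/2
  lods <- do.call(rbind, lapply(fx$level0$plates, function(p)
    data.frame(plate_id = p$plate_id, analyte_id = names(p$lod),
               lod = unname(p$lod))))
  for (i in which(rowSums(was_lod) > 0)) {
    for (a in colnames(m4$values)[was_lod[i, ]]) {
      want <- lods$lod[lods$plate_id == m4$samples$plate_id[i] &
                         lods$analyte_id == a] / 2
      expect_identical(unname(m4$values[i, a]), want)
      expect_identical(unname(m4$status[i, a]), "imputed")
    }
  }
  # 3 non-fasting + 1 missing-BMI + 1 missing-meds -> 5 flagged samples
  expect_identical(nrow(l4$audit$flagged_samples), 5L)
  expect_setequal(l4$audit$flagged_samples$subject_id,
                  fx$truth$flagged_samples$subject_id)
  # rows are retained until Level 5
  expect_equal(nrow(m4$values), nrow(m3$values))
  # clean covariates -> zero flags
  clinical_ok <- fx$clinical
  clinical_ok$fasting <- TRUE
  clinical_ok$bmi[is.na(clinical_ok$bmi)] <- 25
  clinical_ok$has_baseline_med_record <- TRUE
  l4ok <- level4_impute_and_flag(l3$matrix, clinical_ok, fx$level0$plates)
  expect_identical(nrow(l4ok$audit$flagged_samples), 0L)
  # a below_LOD cell without a plate LOD entry aborts
  nolod <- lapply(fx$level0$plates, function(p) { p$lod <- numeric(); p })
  expect_error(level4_impute_and_flag(l3$matrix, fx$clinical, nolod),
               "no plate LOD")
})

test_that("level 5 averages duplicates, drops flags/outliers, then log2", {
  # duplicate pair 10 & 14 -> subject value 12; flagged sample dropped
  v <- matrix(c(10, 14, 20, 30, 40, 5), 6, 1, dimnames = list(NULL, "A01"))
  mm <- mk_mm(v, subjects = c("S1", "S1", "S2", "S3", "S4", "S5"),
              dup = c("S1", "S1", NA, NA, NA, NA))
  mm$samples$flag <- c("", "", "", "", "", "non-fasting")
  l5 <- level5_finalize(mm)
  expect_equal(unname(l5$matrix$values["S1", "A01"]), 12)
  expect_false("S5" %in% l5$matrix$samples$subject_id)
  expect_equal(nrow(l5$matrix$values), 4L)
  expect_identical(l5$log2_analytes, character())
})

test_that("the full pipeline is deterministic and conserves counts", {
  fx <- get_fixture()
  cfg <- pipeline_config(exclusion_lists = fx$truth$excluded_samples)
  r1 <- suppressWarnings(run_pipeline(fx$level0, fx$clinical, cfg))
  r2 <- suppressWarnings(run_pipeline(fx$level0, fx$clinical, cfg))
  expect_identical(r1$matrix$values, r2$matrix$values)
  expect_identical(audit_json(r1$audit), audit_json(r2$audit))
  # conservation at every level
  for (a in r1$audit$levels) {
    expect_identical(a$samples_before - a$samples_removed, a$samples_after)
    expect_identical(a$analytes_before - a$analytes_removed,
                     a$analytes_after)
  }
  # the audit reproduces every removal with a reason
  expect_equal(r1$audit$levels$level1$samples_removed,
               nrow(r1$audit$levels$level1$removed_samples))
  expect_equal(r1$audit$levels$level3$analytes_removed,
               nrow(r1$audit$levels$level3$removed_analytes))
  # loosening the ICC threshold only ever retains more analytes
  loose <- suppressWarnings(run_pipeline(
    fx$level0, fx$clinical,
    pipeline_config(icc_min = 1e-6,
                    exclusion_lists = fx$truth$excluded_samples)))
  expect_true(all(analyte_ids(r1$matrix) %in% analyte_ids(loose$matrix)))
  expect_gt(ncol(loose$matrix$values), ncol(r1$matrix$values))
})

test_that("a defect-free cohort passes through losslessly", {
  sim <- simulate_cohort(small_cfg(406, n_duplicate_pairs = 10L,
                                   censor_q_clean = 0))
  res <- suppressWarnings(run_pipeline(sim$level0, sim$clinical,
                                       pipeline_config()))
  expect_identical(res$audit$levels$level3$analytes_removed, 0L)
  expect_identical(res$outliers$flagged, character())
  expect_identical(nrow(res$audit$levels$level4$flagged_samples), 0L)
  # one row per subject, none lost beyond duplicate collapsing
  n_subj <- sim$config$n_study_samples - sim$config$n_duplicate_pairs
  expect_equal(nrow(res$matrix$values), n_subj)
})
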