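# shared builders; fixture and cohort results are memoized per test run

.cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.cache$fx)) .cache$fx <- make_reference_fixture()
  .cache$fx
}

get_fixture_result <- function() {
  if (is.null(.cache$fx_res)) {
    fx <- get_fixture()
    .cache$fx_res <- suppressWarnings(run_pipeline(
      fx$level0, fx$clinical,
      pipeline_config(exclusion_lists = fx$truth$excluded_samples)))
  }
  .cache$fx_res
}

# small cohort configuration for fast pipeline tests
small_cfg <- function(seed, ...) {
  args <- list(n_plates = 3L, study_wells_per_plate = 20L,
               n_study_samples = 60L, n_duplicate_pairs = 6L,
               n_analytes = 12L,
               planted_bad = c(high_cv = 0L, low_icc = 0L,
                               high_censoring = 0L),
               n_outlier_subjects = 0L, n_non_fasting = 0L,
               n_missing_bmi = 0L, n_missing_meds = 0L, n_thawed = 0L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# hand-built measurement matrix: one plate unless plate given per row
mk_mm <- function(values, roles = NULL, plates = NULL, subjects = NULL,
                  status = NULL, dup = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("A%02d", seq_len(ncol(values)))
  roles <- roles %||% rep("study", n)
  plates <- plates %||% rep("P01", n)
  ids <- sprintf("R%03d", seq_len(n))
  subjects <- subjects %||% ids
  samples <- data.frame(sample_id = ids, subject_id = subjects,
                        plate_id = plates,
                        well_id = sprintf("W%03d", seq_len(n)),
                        role = roles,
                        duplicate_group = dup %||% rep(NA_character_, n),
                        stringsAsFactors = FALSE)
  measurement_matrix(samples, values, status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
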