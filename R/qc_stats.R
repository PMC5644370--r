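## Statistical primitives of the curation pipeline: SPQC scaling factors,
## duplicate CV, one-way ICC, censoring fraction, analyte verdicts,
## PCA outlier distances, and the conditional-log2 normality decision.

spqc_rows <- function(matrix) which(matrix$samples$role == "SPQC")

#' Cross-plate scaling factors from study-pool QC wells
#'
#' For each analyte the correction factor of a plate is the analyte's
#' global SPQC average divided by its SPQC average within that plate, so
#' that multiplying a plate's values by its factor equalizes per-plate
#' SPQC means to the global mean.  Plates whose SPQC mean is zero or
#' all-missing for an analyte get factor 1 with a warning.
#'
#' @param matrix a [measurement_matrix()] containing SPQC wells
#' @return data.frame (`plate_id`, `analyte_id`, `factor`) of class
#'   `scaling_factors`, with the per-analyte global SPQC means attached as
#'   attribute `global_means`
#' @export
compute_scaling_factors <- function(matrix) {
  idx <- spqc_rows(matrix)
  if (!length(idx)) stop2("matrix contains no SPQC wells")
  v <- matrix$values[idx, , drop = FALSE]
  plate <- matrix$samples$plate_id[idx]
  plates <- unique(matrix$samples$plate_id)
  an <- colnames(v)
  global <- colMeans(v, na.rm = TRUE)           # mean over all SPQC wells
  out <- expand.grid(plate_id = plates, analyte_id = an,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$factor <- 1
  n_undef <- 0L
  for (p in plates) {
    pv <- v[plate == p, , drop = FALSE]
    if (!nrow(pv)) { n_undef <- n_undef + length(an); next }
    pm <- colMeans(pv, na.rm = TRUE)
    f <- global / pm
    undef <- !is.finite(f) | pm == 0 | !is.finite(global)
    n_undef <- n_undef + sum(undef)
    f[undef] <- 1
    out$factor[out$plate_id == p] <- f[match(out$analyte_id[out$plate_id == p],
                                             an)]
  }
  if (n_undef > 0)
    warning(sprintf(paste0("scaling factor undefined (zero or all-missing ",
                           "plate SPQC mean) for %d (plate, analyte) pairs; ",
                           "factor 1 used"), n_undef), call. = FALSE)
  structure(out, class = c("scaling_factors", "data.frame"),
            global_means = global)
}

#' Apply cross-plate scaling factors
#'
#' Multiplies every numeric cell by its plate/analyte factor.  Status
#' flags are unchanged; `below_LOD` cells stay non-numeric.
#'
#' @param matrix a [measurement_matrix()]
#' @param factors a [compute_scaling_factors()] table covering every
#'   (plate, analyte) pair present in `matrix`
#' @return the scaled [measurement_matrix()]
#' @export
apply_scaling <- function(matrix, factors) {
  plates <- unique(matrix$samples$plate_id)
  an <- colnames(matrix$values)
  fm <- matrix(NA_real_, length(plates), length(an),
               dimnames = list(plates, an))
  keep <- factors$plate_id %in% plates & factors$analyte_id %in% an
  fm[cbind(factors$plate_id[keep], factors$analyte_id[keep])] <-
    factors$factor[keep]
  if (anyNA(fm))
    stop2("missing scaling factor for ",
          sum(is.na(fm)), " (plate, analyte) pair(s)")
  v <- matrix$values * fm[matrix$samples$plate_id, , drop = FALSE]
  measurement_matrix(matrix$samples, v, matrix$status)
}

#' Extract duplicate pairs for one analyte
#' @keywords internal
pair_values <- function(matrix, groups, analyte) {
  s <- matrix$samples
  v <- matrix$values[, analyte]
  out <- t(vapply(groups, function(ids) v[match(ids, s$sample_id)],
                  numeric(2)))
  rownames(out) <- names(groups)
  out
}

duplicate_group_list <- function(matrix) {
  s <- matrix$samples
  dg <- s$duplicate_group
  grp <- split(s$sample_id[!is.na(dg)], dg[!is.na(dg)])
  bad <- vapply(grp, length, integer(1)) != 2L
  if (any(bad))
    stop2("duplicate group(s) without exactly two samples: ",
          paste(names(grp)[bad], collapse = ", "))
  grp
}

## unbiasing constant for a Gaussian sd estimated from n = 2: E[s] = c4 sigma
c4_n2 <- sqrt(2 / pi)

#' Duplicate coefficient of variation per analyte
#'
#' For each blinded duplicate pair the CV is the pair standard deviation
#' divided by the pair mean (in percent); the analyte CV is the arithmetic
#' mean over usable pairs.  By default each pair sd is divided by the
#' n = 2 Gaussian unbiasing constant `c4 = sqrt(2/pi)` so that the
#' estimator is unbiased for the true technical CV (the raw two-point sd
#' underestimates sigma by ~20\%).  Pairs with a missing member are
#' skipped for that analyte; pairs with non-positive mean are skipped with
#' a warning; analytes with no usable pair get `NA` (and fail the filter
#' downstream).
#'
#' @param matrix a [measurement_matrix()] (typically Level-2 scaled)
#' @param duplicate_groups optional named list of sample-id pairs; by
#'   default derived from the samples table's `duplicate_group` column
#' @param bias_correct divide pair sds by `c4(2) = sqrt(2/pi)` (default
#'   TRUE); FALSE gives the raw two-point sd/mean
#' @return named numeric vector of CV percent per analyte
#' @export
duplicate_cv <- function(matrix, duplicate_groups = NULL,
                         bias_correct = TRUE) {
  grp <- duplicate_groups %||% duplicate_group_list(matrix)
  an <- colnames(matrix$values)
  n_nonpos <- 0L
  out <- vapply(an, function(a) {
    pv <- pair_values(matrix, grp, a)
    ok <- stats::complete.cases(pv)
    pv <- pv[ok, , drop = FALSE]
    if (!nrow(pv)) return(NA_real_)
    m <- rowMeans(pv)
    usable <- m > 0
    n_nonpos <<- n_nonpos + sum(!usable)
    pv <- pv[usable, , drop = FALSE]
    m <- m[usable]
    if (!length(m)) return(NA_real_)
    s <- abs(pv[, 1] - pv[, 2]) / sqrt(2)
    if (bias_correct) s <- s / c4_n2
    mean(s / m * 100)
  }, numeric(1))
  if (n_nonpos > 0)
    warning(sprintf("%d duplicate pair(s) with non-positive mean skipped",
                    n_nonpos), call. = FALSE)
  out
}

#' One-way intraclass correlation from duplicate pairs
#'
#' ICC(1,1) from the one-way random-effects ANOVA decomposition,
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` with `k = 2` measurements per
#' subject; estimates may be negative.  Analytes with fewer than
#' `min_pairs` complete pairs get `NA` (and fail the filter downstream).
#'
#' @inheritParams duplicate_cv
#' @param min_pairs minimum number of complete pairs (default 3)
#' @return named numeric vector of ICC per analyte
#' @export
duplicate_icc <- function(matrix, duplicate_groups = NULL, min_pairs = 3L) {
  grp <- duplicate_groups %||% duplicate_group_list(matrix)
  an <- colnames(matrix$values)
  vapply(an, function(a) {
    pv <- pair_values(matrix, grp, a)
    pv <- pv[stats::complete.cases(pv), , drop = FALSE]
    if (nrow(pv) < min_pairs) return(NA_real_)
    icc_oneway(pv)
  }, numeric(1))
}

#' @keywords internal
icc_oneway <- function(pairs) {
  n <- nrow(pairs); k <- ncol(pairs)
  mi <- rowMeans(pairs)
  g <- mean(pairs)
  msb <- k * sum((mi - g)^2) / (n - 1)
  msw <- sum((pairs - mi)^2) / (n * (k - 1))
  if (msb + (k - 1) * msw == 0) return(NA_real_)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Percent of study measurements below the limit of detection
#'
#' `100 * (#below_LOD study cells) / (#study cells)` per analyte; wells
#' with QC, calibrator or reference roles are excluded from both counts
#' (missingness of controls is not a property of the cohort).
#'
#' @param matrix a [measurement_matrix()]
#' @return named numeric vector, percent in `[0, 100]`
#' @export
pct_below_lod <- function(matrix) {
  idx <- matrix$samples$role == "study"
  if (!any(idx)) stop2("matrix contains no study samples")
  st <- matrix$status[idx, , drop = FALSE]
  100 * colSums(st == "below_LOD") / nrow(st)
}

#' Analyte retention verdicts
#'
#' An analyte is retained iff its duplicate CV is strictly below `cv_max`,
#' its ICC strictly above `icc_min`, and its censoring percentage at most
#' `lod_pct_max`.  The verdict records the first failing rule in the fixed
#' order CV, ICC, LOD; an undefined (NA) CV or ICC fails its own rule
#' (stringent-by-default policy).
#'
#' @param cv,icc,pct_lod named numeric vectors over the same analytes
#' @param cv_max CV threshold in percent (default 20, strict `<` to retain)
#' @param icc_min ICC threshold (default 0.65, strict `>` to retain)
#' @param lod_pct_max censoring threshold in percent (default 40,
#'   inclusive `<=` to retain)
#' @return data.frame (`analyte_id`, `pct_below_lod`, `cv`, `icc`,
#'   `verdict`) with verdict in `retain`, `drop_cv`, `drop_icc`, `drop_lod`
#' @export
analyte_verdicts <- function(cv, icc, pct_lod,
                             cv_max = 20, icc_min = 0.65, lod_pct_max = 40) {
  an <- names(cv)
  stopifnot(identical(an, names(icc)), identical(an, names(pct_lod)))
  verdict <- rep("retain", length(an))
  fail_cv <- is.na(cv) | cv >= cv_max
  fail_icc <- is.na(icc) | icc <= icc_min
  fail_lod <- pct_lod > lod_pct_max
  verdict[fail_lod] <- "drop_lod"
  verdict[fail_icc] <- "drop_icc"
  verdict[fail_cv] <- "drop_cv"      # first rule wins: applied last
  data.frame(analyte_id = an, pct_below_lod = unname(pct_lod),
             cv = unname(cv), icc = unname(icc), verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Principal-component outlier flagging
#'
#' Analytes are standardized to zero mean / unit variance, subjects are
#' projected onto the smallest number K of principal components whose
#' cumulative explained variance exceeds `var_cum`, and each subject's
#' Euclidean distance from the score-space centroid is computed.  Subjects
#' farther than `mean(d) + k_sd * sd(d)` are flagged.
#'
#' @param x complete numeric matrix, subjects x analytes (rownames are
#'   subject ids)
#' @param var_cum cumulative explained-variance target (default 0.90)
#' @param k_sd distance threshold in standard deviations (default 7)
#' @return object of class `outlier_report`: `n_components`, `explained`
#'   (cumulative fraction at K), `distances` (named), `threshold`,
#'   `flagged` (subject ids)
#' @export
pca_outliers <- function(x, var_cum = 0.90, k_sd = 7) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop2("outlier detection requires a complete matrix")
  if (nrow(x) < 3) stop2("need at least 3 subjects")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance analyte(s) dropped from PCA",
                    sum(sds == 0)), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  subjects <- rownames(x) %||% as.character(seq_len(nrow(x)))
  if (ncol(x) == 0) {
    d <- stats::setNames(rep(0, nrow(x)), subjects)
    return(structure(list(n_components = 0L, explained = 1,
                          distances = d, threshold = 0,
                          flagged = character()),
                     class = "outlier_report"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  vexp <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  K <- which(vexp > var_cum)[1]
  if (is.na(K)) K <- length(vexp)
  sc <- pc$x[, seq_len(K), drop = FALSE]
  centroid <- colMeans(sc)
  d <- sqrt(rowSums(sweep(sc, 2, centroid)^2))
  names(d) <- subjects
  thr <- mean(d) + k_sd * stats::sd(d)
  if (is.na(thr)) thr <- Inf
  structure(list(n_components = as.integer(K), explained = vexp[K],
                 distances = d, threshold = thr,
                 flagged = subjects[d > thr]),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(paste0("outlier_report: K = %d components (%.1f%% variance), ",
                     "threshold %.3f, %d flagged\n"),
              x$n_components, 100 * x$explained, x$threshold,
              length(x$flagged)))
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = ", "),
                             "\n")
  invisible(x)
}

## ---- D'Agostino-Pearson omnibus normality test ---------------------------

#' Fisher-Pearson skewness coefficient g1
#' @param x numeric vector (NAs dropped)
#' @return g1 = m3 / m2^(3/2)
#' @export
skewness_g1 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m3 / m2^1.5
}

## D'Agostino (1970) transformed skewness z
dagostino_z_skew <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop2("skewness test needs n >= 8")
  g1 <- skewness_g1(x)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
}

## Anscombe-Glynn (1983) transformed kurtosis z
dagostino_z_kurt <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 5) stop2("kurtosis test needs n >= 5")
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m4 <- sum((x - m)^4) / n
  b2 <- m4 / m2^2
  e <- 3 * (n - 1) / (n + 1)
  v <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - e) / sqrt(v)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  ((1 - 2 / (9 * a)) -
     ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness and kurtosis z-scores into
#' `K2 = z1^2 + z2^2`, chi-squared with 2 df under normality (the test
#' behind scipy's `normaltest`).
#'
#' @param x numeric vector with at least 20 non-missing values
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`
#' @export
dagostino_test <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 20) stop2("omnibus test needs n >= 20")
  z1 <- dagostino_z_skew(x)
  z2 <- dagostino_z_kurt(x)
  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Decide whether an analyte should be log2-transformed
#'
#' TRUE iff the D'Agostino-Pearson omnibus p-value is below `alpha` *and*
#' the Fisher-Pearson skewness g1 exceeds `skew_min` (both conditions
#' required: only significantly non-normal *and* strongly right-skewed
#' analytes are transformed).  Below the validity floor of `min_n`
#' non-missing values the decision is FALSE with a warning.
#'
#' @param values one analyte's subject values
#' @param alpha omnibus significance level (default 0.05)
#' @param skew_min skewness threshold (default 2)
#' @param min_n test validity floor (default 20)
#' @return logical flag with attributes `p.value` and `skewness`
#' @export
normality_decision <- function(values, alpha = 0.05, skew_min = 2,
                               min_n = 20L) {
  v <- values[!is.na(values)]
  if (length(v) < min_n) {
    warning(sprintf("only %d values (< %d): no transform", length(v), min_n),
            call. = FALSE)
    return(structure(FALSE, p.value = NA_real_, skewness = NA_real_))
  }
  g1 <- skewness_g1(v)
  tst <- dagostino_test(v)
  structure(tst$p.value < alpha && g1 > skew_min,
            p.value = tst$p.value, skewness = g1)
}
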