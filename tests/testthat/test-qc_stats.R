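# independent ICC oracle: one-way ANOVA via stats::aov mean squares
aov_icc <- function(pairs) {
  d <- data.frame(y = as.vector(t(pairs)),
                  g = factor(rep(seq_len(nrow(pairs)), each = 2)))
  ms <- summary(stats::aov(y ~ g, data = d))[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}

test_that("SPQC scaling factors equal global mean / plate mean", {
  # hand arithmetic: plate means 11 and 19, global mean 15
  mm <- mk_mm(matrix(c(10, 12, 18, 20), 4, 1),
              roles = rep("SPQC", 4),
              plates = c("PA", "PA", "PB", "PB"))
  f <- compute_scaling_factors(mm)
  expect_equal(f$factor[f$plate_id == "PA"], 15 / 11, tolerance = 1e-12)
  expect_equal(f$factor[f$plate_id == "PB"], 15 / 19, tolerance = 1e-12)
  # single plate: global mean = plate mean -> all factors 1
  one <- compute_scaling_factors(mk_mm(matrix(c(3, 5), 2, 2),
                                       roles = c("SPQC", "SPQC")))
  expect_true(all(one$factor == 1))
  # zero / all-missing plate SPQC mean -> factor 1 with a warning
  bad <- mk_mm(matrix(c(0, 0, 4, 6), 4, 1), roles = rep("SPQC", 4),
               plates = c("PA", "PA", "PB", "PB"))
  expect_warning(fb <- compute_scaling_factors(bad), "undefined")
  expect_equal(fb$factor[fb$plate_id == "PA"], 1)
})

test_that("applying factors rescales values and equalizes SPQC plate means", {
  v <- matrix(c(2, 4, 10, 12, 18, 20), 6, 1, dimnames = list(NULL, "A01"))
  mm <- mk_mm(v, roles = c("study", "study", "SPQC", "SPQC", "SPQC", "SPQC"),
              plates = c("PA", "PB", "PA", "PA", "PB", "PB"))
  f <- compute_scaling_factors(mm)
  out <- apply_scaling(mm, f)
  # value x factor, flags unchanged
  expect_equal(unname(out$values[1, 1]), 2 * 15 / 11, tolerance = 1e-12)
  expect_identical(out$status, mm$status)
  spqc <- out$samples$role == "SPQC"
  means <- tapply(out$values[spqc, 1], out$samples$plate_id[spqc], mean)
  expect_equal(unname(diff(range(means))) / mean(means), 0,
               tolerance = 1e-9)
  # identity when all factors are 1
  f1 <- f; f1$factor[] <- 1
  expect_identical(apply_scaling(mm, f1)$values, mm$values)
  # value 2.0 with factor 1.5 -> 3.0
  f15 <- f; f15$factor[] <- 1.5
  expect_equal(unname(apply_scaling(mm, f15)$values[1, 1]), 3.0)
  # missing factor is rejected
  expect_error(apply_scaling(mm, f[f$plate_id == "PA", ]),
               "missing scaling factor")
})

test_that("below-LOD cells survive scaling as non-numeric flagged cells", {
  v <- matrix(c(NA, 2, 10, 12), 4, 1, dimnames = list(NULL, "A01"))
  st <- matrix(c("below_LOD", "valid", "valid", "valid"), 4, 1,
               dimnames = dimnames(v))
  mm <- mk_mm(v, roles = c("study", "study", "SPQC", "SPQC"), status = st)
  out <- apply_scaling(mm, compute_scaling_factors(mm))
  expect_true(is.na(out$values[1, 1]))
  expect_identical(unname(out$status[1, 1]), "below_LOD")
})

test_that("duplicate CV matches hand arithmetic with and without c4 correction", {
  v <- matrix(c(10, 12, 20, 20), 4, 1)
  mm <- mk_mm(v, subjects = c("S1", "S1", "S2", "S2"),
              dup = c("S1", "S1", "S2", "S2"))
  # uncorrected: mean(sd(10,12)/11, 0) * 100 = 6.4282...%
  raw_expect <- mean(c(stats::sd(c(10, 12)) / 11, 0)) * 100
  expect_equal(unname(duplicate_cv(mm, bias_correct = FALSE)), raw_expect,
               tolerance = 1e-12)
  expect_equal(raw_expect, 6.428243, tolerance = 1e-6)
  # default: each pair sd divided by c4(2) = sqrt(2/pi)
  expect_equal(unname(duplicate_cv(mm)), raw_expect / sqrt(2 / pi),
               tolerance = 1e-12)
  # identical pairs -> 0
  same <- mk_mm(matrix(c(5, 5, 7, 7), 4, 1),
                subjects = c("S1", "S1", "S2", "S2"),
                dup = c("S1", "S1", "S2", "S2"))
  expect_equal(unname(duplicate_cv(same)), 0)
  # non-positive pair mean: pair skipped with a warning
  neg <- mk_mm(matrix(c(-2, 2, 10, 12), 4, 1),
               subjects = c("S1", "S1", "S2", "S2"),
               dup = c("S1", "S1", "S2", "S2"))
  expect_warning(cv <- duplicate_cv(neg), "non-positive")
  expect_equal(unname(cv), stats::sd(c(10, 12)) / sqrt(2 / pi) / 11 * 100,
               tolerance = 1e-12)
})

test_that("the default CV estimator recovers a known technical CV", {
  # 5% true CV, 20 pairs, many replicates: mean estimate within 5 +/- 1
  set.seed(91)
  est <- replicate(200, {
    mu <- 50
    pairs <- matrix(mu * (1 + rnorm(40) * 0.05), 20, 2)
    mm <- mk_mm(matrix(as.vector(t(pairs)), 40, 1),
                subjects = rep(sprintf("S%02d", 1:20), each = 2),
                dup = rep(sprintf("S%02d", 1:20), each = 2))
    duplicate_cv(mm)
  })
  expect_lt(abs(mean(est) - 5), 1)
})

test_that("ICC equals the one-way ANOVA oracle", {
  # worked example: MSB 213.5, MSW 8.5/3 -> 0.9738
  pairs <- rbind(c(10, 12), c(20, 18), c(30, 33))
  mm <- mk_mm(matrix(as.vector(t(pairs)), 6, 1),
              subjects = rep(c("S1", "S2", "S3"), each = 2),
              dup = rep(c("S1", "S2", "S3"), each = 2))
  icc <- unname(duplicate_icc(mm))
  expect_equal(icc, (213.5 - 8.5 / 3) / (213.5 + 8.5 / 3), tolerance = 1e-12)
  expect_equal(icc, 0.9738, tolerance = 1e-4)
  expect_equal(icc, aov_icc(pairs), tolerance = 1e-12)
  # property: estimator == brute-force oracle on random instances
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    p <- matrix(rnorm(2 * n, 10, 2), n, 2) + rnorm(n, 0, 3)
    mm <- mk_mm(matrix(as.vector(t(p)), 2 * n, 1),
                subjects = rep(sprintf("S%02d", 1:n), each = 2),
                dup = rep(sprintf("S%02d", 1:n), each = 2))
    expect_equal(unname(duplicate_icc(mm)), aov_icc(p), tolerance = 1e-10)
  }
  # exactly equal members across distinct subjects -> ICC 1
  eq <- mk_mm(matrix(c(1, 1, 5, 5, 9, 9), 6, 1),
              subjects = rep(c("S1", "S2", "S3"), each = 2),
              dup = rep(c("S1", "S2", "S3"), each = 2))
  expect_equal(unname(duplicate_icc(eq)), 1)
  # fewer than 3 complete pairs -> undefined
  two <- mk_mm(matrix(c(1, 2, 5, 6), 4, 1),
               subjects = c("S1", "S1", "S2", "S2"),
               dup = c("S1", "S1", "S2", "S2"))
  expect_true(is.na(duplicate_icc(two)))
})

test_that("ICC is near zero when members are independent resamples", {
  set.seed(41)
  est <- replicate(300, {
    p <- matrix(rnorm(40, 100, 10), 20, 2)  # no subject effect
    icc_vals <- p180curate:::icc_oneway(p)
  })
  expect_lt(abs(mean(est)), 0.05)
})

test_that("censoring percentage counts study wells only, boundary at 40%", {
  st <- matrix("valid", 12, 1, dimnames = list(NULL, "A01"))
  st[1:4, 1] <- "below_LOD"      # 4 of 10 study cells
  st[11, 1] <- "below_LOD"       # an SPQC cell: excluded from both counts
  v <- matrix(1, 12, 1); v[st == "below_LOD"] <- NA
  mm <- mk_mm(v, roles = c(rep("study", 10), "SPQC", "SPQC"), status = st)
  expect_equal(unname(pct_below_lod(mm)), 40)
  # the rule is strict >40%: exactly 40% is retained
  verdict <- analyte_verdicts(c(A01 = 5), c(A01 = 0.9), pct_below_lod(mm))
  expect_identical(verdict$verdict, "retain")
  clean <- mk_mm(matrix(1, 5, 1))
  expect_equal(unname(pct_below_lod(clean)), 0)
  verdict41 <- analyte_verdicts(c(A01 = 5), c(A01 = 0.9), c(A01 = 41))
  expect_identical(verdict41$verdict, "drop_lod")
})

test_that("analyte verdicts reproduce the printed borderline examples", {
  cv <- c(histamine = 5.4, methionine = 8.1, clean = 5)
  icc <- c(histamine = 0.09, methionine = 0.65, clean = 0.9)
  pct <- c(histamine = 17.2, methionine = 0, clean = 10)
  v <- analyte_verdicts(cv, icc, pct)
  # both printed examples are excluded; 0.65 proves strict ICC > 0.65
  expect_identical(v$verdict, c("drop_icc", "drop_icc", "retain"))
  # undefined metric fails its own rule; first failing rule is reported
  v2 <- analyte_verdicts(c(a = NA, b = 25), c(a = 0.9, b = 0.2),
                         c(a = 0, b = 50))
  expect_identical(v2$verdict, c("drop_cv", "drop_cv"))
})

test_that("verdicts are monotone in each metric", {
  set.seed(51)
  for (i in 1:100) {
    cv <- runif(1, 0, 40); icc <- runif(1, -0.2, 1); pct <- runif(1, 0, 80)
    base <- analyte_verdicts(c(a = cv), c(a = icc), c(a = pct))$verdict
    better <- analyte_verdicts(c(a = cv * 0.5), c(a = min(1, icc + 0.2)),
                               c(a = pct * 0.5))$verdict
    if (base == "retain") expect_identical(better, "retain")
  }
})

test_that("PCA outlier flagging finds planted points and nothing else", {
  set.seed(61)
  x <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(sprintf("S%03d", 1:200), NULL))
  x[17, 1] <- 50   # planted subject at 50 units on analyte 1
  rep <- pca_outliers(x)
  expect_identical(rep$flagged, "S017")
  expect_true(all(rep$distances >= 0))
  expect_gt(rep$explained, 0.90)
  # K is minimal: dropping one component falls at or below the target
  pc <- prcomp(x, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  expect_true(rep$n_components == 1 || cum[rep$n_components - 1] <= 0.90)
  # flags invariant to sign flips of the input axes
  rep2 <- pca_outliers(-x)
  expect_identical(rep2$flagged, rep$flagged)
  # all-identical subjects: zero variance everywhere, nobody flagged
  const <- matrix(3, 10, 4, dimnames = list(sprintf("S%02d", 1:10), NULL))
  expect_warning(rep3 <- pca_outliers(const), "zero-variance")
  expect_identical(rep3$flagged, character())
})

test_that("omnibus normality test matches frozen scipy reference values", {
  set.seed(42)
  x <- rlnorm(100, 0, 1.5)
  t1 <- dagostino_test(x)
  expect_equal(t1$statistic, 107.9001057, tolerance = 1e-8)
  expect_equal(t1$p.value, 3.713554136e-24, tolerance = 1e-6)
  expect_equal(skewness_g1(x), 3.655665557, tolerance = 1e-8)
  y <- c(10.002460306714966, 10.59749107501694, 9.451724289275564,
         8.218816322485452, 9.0906584296565551, 8.0167068900070753,
         10.120287205194877, 12.680430491109068, 9.0155869628973413,
         8.7590502003601198, 10.979684100370397, 10.713774016320121,
         10.210828497995797, 8.1390639105835909, 9.9414963550734523,
         11.390606388916575, 7.3115709054298357, 9.0847684779195639,
         6.1975545203983113, 7.4209245204300478, 6.3165299244165354,
         9.529817737850637, 7.4651070371125936, 10.542528717643403,
         10.31350217324845)
  t2 <- dagostino_test(y)
  expect_equal(t2$statistic, 0.1138382357, tolerance = 1e-8)
  expect_equal(t2$p.value, 0.9446704733, tolerance = 1e-8)
  expect_equal(skewness_g1(y), -0.1306377217, tolerance = 1e-8)
})

test_that("the log2 decision requires both significance and strong skew", {
  set.seed(71)
  sym <- rnorm(500)                       # symmetric: skewness ~ 0
  expect_false(as.logical(normality_decision(sym)))
  ln <- rlnorm(500, 0, 1.5)               # heavy right skew
  expect_true(as.logical(normality_decision(ln)))
  expect_false(as.logical(normality_decision(-ln)))  # mirrored: g1 < 0
  expect_warning(flag <- normality_decision(rnorm(10)), "no transform")
  expect_false(as.logical(flag))
})
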