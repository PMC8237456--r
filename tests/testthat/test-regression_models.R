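test_that("all four families agree with the normal-equations oracle", {
  set.seed(10)
  for (trial in 1:5) {
    n <- sample(8:20, 1)
    X <- data.frame(a = runif(n), b = runif(n, 1, 3))
    y <- rnorm(n, 2 + X$a - 0.5 * X$b, 0.3)
    m <- fit_linear_multi(X, y)
    o <- normal_eq(X, y)
    expect_equal(m$coefficients, o$coefficients, tolerance = 1e-8)
    expect_equal(m$r_squared, o$r_squared, tolerance = 1e-8)

    x <- runif(n, 0.05, 0.3)
    ys <- exp(rnorm(n, 6 - 0.02 / x, 0.1))
    ms <- fit_s_type(x, ys)
    os <- normal_eq(data.frame(ix = 1 / x), log(ys))
    expect_equal(ms$coefficients, os$coefficients, tolerance = 1e-8)
    expect_equal(ms$r_squared, os$r_squared, tolerance = 1e-8)

    yi <- rnorm(n, 30 + 20 / x, 1)
    mi <- fit_inverse(x, yi)
    oi <- normal_eq(data.frame(ix = 1 / x), yi)
    expect_equal(mi$coefficients, oi$coefficients, tolerance = 1e-8)

    xc <- runif(n, 0, 1)
    yc <- rnorm(n, 1 + xc - xc^2 + 0.5 * xc^3, 0.1)
    mc <- fit_cubic(xc, yc)
    oc <- normal_eq(data.frame(xc, xc^2, xc^3), yc)
    expect_equal(mc$coefficients, oc$coefficients, tolerance = 1e-8)
  }
})

test_that("noiseless generate-and-refit recovers coefficients exactly", {
  x <- seq(0.01, 0.24, length.out = 50)
  suppressWarnings({
    m1 <- fit_s_type(x, exp(8.11 - 0.024 / x))
    m2 <- fit_s_type(x, exp(7.677 - 0.017 / x))
  })
  expect_equal(m1$coefficients, c(8.11, -0.024), tolerance = 1e-9)
  expect_equal(m2$coefficients, c(7.677, -0.017), tolerance = 1e-9)
  suppressWarnings({
    X <- data.frame(u = runif(12), v = runif(12))
    ml <- fit_linear_multi(X, 3 + 2 * X$u - X$v)
    expect_equal(ml$coefficients, c(3, 2, -1), tolerance = 1e-9)
    expect_equal(ml$r_squared, 1, tolerance = 1e-12)
    mi <- fit_inverse(x, 1 + 2 / x)
    expect_equal(mi$coefficients, c(1, 2), tolerance = 1e-9)
    # quadratic data fitted by the cubic family leaves b3 at zero
    xq <- seq(0.1, 1, length.out = 12)
    mq <- fit_cubic(xq, 2 + xq - 3 * xq^2)
    expect_equal(mq$coefficients[4], 0, tolerance = 1e-8)
  })
})

test_that("degenerate designs raise informative errors", {
  expect_error(fit_s_type(c(0.1, -0.2, 0.3), c(1, 2, 3)), "offending rows")
  expect_error(fit_s_type(c(0.1, 0.2, 0.3), c(1, -2, 3)), "offending rows")
  expect_error(fit_inverse(c(0, 1, 2), c(1, 2, 3)), "x = 0")
  expect_error(fit_cubic(c(1, 1, 2, 2, 3), rnorm(5)), "distinct")
  X <- data.frame(a = rep(1, 8), b = runif(8))  # constant column
  expect_error(fit_linear_multi(X, rnorm(8)), "rank-deficient")
  expect_error(fit_linear_multi(data.frame(a = runif(3), b = runif(3),
                                           c = runif(3), d = runif(3)),
                                rnorm(3)), "underdetermined")
  suppressWarnings({
    yconst <- fit_s_type(c(0.1, 0.2, 0.4, 0.5), rep(3, 4))
    expect_equal(yconst$coefficients, c(log(3), 0), tolerance = 1e-9)
  })
})

test_that("spearman matches mid-rank oracles and handles ties", {
  u <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  expect_equal(spearman(u, u^3)$r, 1)
  expect_equal(spearman(u, -u)$r, -1)
  # invariance under strictly monotone transforms
  set.seed(2)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(spearman(a, b)$r, spearman(exp(a), b)$r, tolerance = 1e-12)
  expect_equal(spearman(a, b)$r, spearman(a, rank(b))$r, tolerance = 1e-12)
  # tied vector: equals Pearson correlation of explicitly averaged ranks
  ut <- c(1, 2, 2, 3, 5, 5, 5, 7)
  vt <- c(3, 1, 4, 4, 6, 2, 8, 8)
  midrank <- function(x) {
    sapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2)
  }
  expect_equal(spearman(ut, vt)$r, cor(midrank(ut), midrank(vt)),
               tolerance = 1e-12)
  # agreement with the reference implementation
  expect_equal(spearman(a, b)$r,
               suppressWarnings(cor.test(a, b, method = "spearman")$estimate),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(spearman(rep(1, 5), 1:5), "zero variance")
  # small-sample p comes from the permutation null
  small <- spearman(1:5, c(2, 1, 4, 3, 5))
  expect_gt(small$p_value, 0)
  expect_lte(small$p_value, 1)
})

test_that("goodness and correlation bands reproduce the reported pairings", {
  expect_equal(classify_fit(c(0.811, 0.692, 0.455)),
               c("high", "moderate", "poor"))
  expect_equal(classify_fit(c(0.7, 0.5, 0.4999999)),
               c("high", "moderate", "poor"))
  expect_error(classify_fit(1.2), "0, 1")
  expect_equal(classify_corr(c(0.85, 0.7, 0.5)),
               c("high", "moderate", "below_moderate"))
  expect_equal(classify_corr(c(0.8, 0.6, -1)),
               c("high", "moderate", "below_moderate"))
  expect_error(classify_corr(1.5), "-1, 1")
})

test_that("catalog prediction evaluates the stored equations", {
  cat_b <- bundled_catalog()
  set.seed(4)
  for (k in 1:5) {
    f <- list(overlap_ratio_heart_ln_to_ln = runif(1, 0.01, 0.24))
    expect_equal(
      catalog_predict(cat_b, "heart_d30", "physical", "C&S", f),
      exp(8.11 - 0.024 / f$overlap_ratio_heart_ln_to_ln), tolerance = 1e-12)
    expect_equal(
      catalog_predict(cat_b, "heart_mean", "physical", "C&SIB", f),
      exp(7.656 - 0.017 / f$overlap_ratio_heart_ln_to_ln), tolerance = 1e-12)
  }
  lin <- hybridplan:::new_regression_model(
    "linear_multi", c("a", "b"), "resp", c(4, 0, 0), 1, 0.01,
    domain = "physical", regime = "C&S")
  expect_equal(predict_model(lin, list(a = 9, b = -2)), 4)
  expect_error(predict_model(lin, list(a = 1)), "missing feature")
  sm <- catalog_get(cat_b, "heart_d30", "physical", "C&S")
  expect_error(predict_model(sm, list(overlap_ratio_heart_ln_to_ln = 0)),
               "<= 0")
  # entries published without coefficients refuse to predict
  expect_error(catalog_predict(cat_b, "ptv_ln_ci60", "physical", "C&S",
                               list(vol_pt = 30, vol_ln = 100,
                                    min_dist_pt_ln = 4)), "no coefficients")
  # JSON round trip preserves the catalog
  path <- tempfile(fileext = ".json")
  write_catalog(cat_b, path)
  cat2 <- read_catalog(path)
  m1 <- catalog_get(cat_b, "heart_d30", "physical", "C&S")
  m2 <- catalog_get(cat2, "heart_d30", "physical", "C&S")
  expect_equal(m2$coefficients, m1$coefficients)
  expect_equal(m2$units, m1$units)
  expect_equal(length(cat2$entries), length(cat_b$entries))
})

test_that("cohort fitting collects per-row failures without aborting", {
  cohort <- sample_feature_cohort(3, synthetic_reference_catalog(), 0, seed = 2)
  spec <- default_model_spec()
  fitted <- suppressWarnings(fit_cohort(cohort, spec))
  fails <- attr(fitted, "failures")
  expect_gt(length(fails), 0)  # 4-predictor models cannot fit on n = 3
  expect_true(any(grepl("underdetermined", unlist(fails))))
})

test_that("noisy cohorts recover generating coefficients within sampling error", {
  gen <- synthetic_reference_catalog()
  hits <- 0; total <- 0
  for (seed in 1:10) {
    cohort <- sample_feature_cohort(40, gen, noise_sd = 0.05, seed = seed)
    fitted <- suppressWarnings(fit_cohort(cohort))
    m <- catalog_get(fitted, "heart_d30", "physical", "C&S")
    fitlm <- lm(log(value) ~ I(1 / x), data = data.frame(
      value = cohort$parameters$value[cohort$parameters$response == "heart_d30" &
                                        cohort$parameters$domain == "physical" &
                                        cohort$parameters$regime == "C&S"],
      x = cohort$features$overlap_ratio_heart_ln_to_ln))
    se <- summary(fitlm)$coefficients[, 2]
    total <- total + 2
    hits <- hits + (abs(m$coefficients[1] - 8.11) <= 3 * se[1]) +
      (abs(m$coefficients[2] + 0.024) <= 3 * se[2])
  }
  expect_gte(hits / total, 0.95)
})
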