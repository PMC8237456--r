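# Regression families linking plan parameters to anatomy, the SPSS-style
# curve-estimation conventions: multi-linear OLS, S-type y = exp(b0 + b1/x)
# (OLS of ln y on 1/x), inverse y = b0 + b1/x, and cubic.  R^2 for the
# transformed families is reported on the link scale (what the fit
# minimizes).  Goodness-of-fit and correlation bands follow the analysis
# thresholds: R^2 >= 0.7 high, [0.5, 0.7) moderate, < 0.5 poor;
# r >= 0.8 high, [0.6, 0.8) moderate.

new_regression_model <- function(form, predictors, response, coefficients,
                                 r_squared, p_value, units = "Gy",
                                 domain = NA_character_, regime = NA_character_,
                                 provenance = "user-fitted", n = NA_integer_) {
  structure(list(form = form, predictors = predictors, response = response,
                 coefficients = coefficients, r_squared = r_squared,
                 p_value = p_value, units = units, domain = domain,
                 regime = regime, provenance = provenance, n = n),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model> %s [%s, %s]: %s(%s), R^2 = %s, p = %s (%s)\n",
              x$response, x$domain, x$regime, x$form,
              paste(x$predictors, collapse = ", "),
              ifelse(is.na(x$r_squared), "?", signif(x$r_squared, 3)),
              ifelse(is.na(x$p_value), "?", format.pval(x$p_value, digits = 3)),
              x$provenance))
  if (!is.null(x$coefficients))
    cat("  coefficients:", paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

lm_summary_stats <- function(fit) {
  s <- summary(fit)
  fstat <- s$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  list(r2 = s$r.squared, p = p)
}

# p-value on the slope for two-parameter families
slope_p <- function(fit) {
  ct <- summary(fit)$coefficients
  if (nrow(ct) < 2) NA_real_ else unname(ct[2, 4])
}

check_design <- function(X, y, min_extra = 1) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) <= ncol(X) + min_extra)
    stop(sprintf("underdetermined fit: n = %d rows for %d predictor(s)",
                 nrow(X), ncol(X)))
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < ncol(X) + 1)
    stop("rank-deficient design (constant or collinear predictor)")
  X
}

#' Multi-linear OLS fit
#'
#' @param X data.frame/matrix of predictor columns (named).
#' @param y numeric response.
#' @return A `regression_model` with coefficients `(intercept, b1, ...)`,
#'   plain R^2 and the overall-F p-value.
#' @export
fit_linear_multi <- function(X, y) {
  X <- check_design(X, y)
  fit <- lm(y ~ ., data = cbind(X, y = y))
  st <- lm_summary_stats(fit)
  new_regression_model("linear_multi", names(X), NA_character_,
                       unname(coef(fit)), st$r2, st$p, n = length(y))
}

#' S-type fit: y = exp(b0 + b1/x)
#'
#' OLS of `ln(y)` on `1/x`; R^2 and p (t-test on the slope) are reported on
#' the log scale.
#'
#' @param x positive predictor.
#' @param y positive response.
#' @return A `regression_model` with coefficients `(b0, b1)`.
#' @export
fit_s_type <- function(x, y) {
  bad <- which(!(x > 0) | !(y > 0))
  if (length(bad))
    stop("S-type fit needs x > 0 and y > 0; offending rows: ",
         paste(head(bad, 10), collapse = ", "))
  if (length(x) < 3) stop("need at least 3 points")
  inv_x <- 1 / x
  fit <- lm(log(y) ~ inv_x)
  new_regression_model("s_type", NA_character_, NA_character_,
                       unname(coef(fit)), summary(fit)$r.squared,
                       slope_p(fit), n = length(y))
}

#' Inverse fit: y = b0 + b1/x
#' @param x positive predictor (zero values are an error).
#' @param y numeric response.
#' @return A `regression_model` with coefficients `(b0, b1)`.
#' @export
fit_inverse <- function(x, y) {
  bad <- which(x == 0)
  if (length(bad))
    stop("inverse fit undefined at x = 0; offending rows: ",
         paste(head(bad, 10), collapse = ", "))
  if (length(x) < 3) stop("need at least 3 points")
  inv_x <- 1 / x
  fit <- lm(y ~ inv_x)
  new_regression_model("inverse", NA_character_, NA_character_,
                       unname(coef(fit)), summary(fit)$r.squared,
                       slope_p(fit), n = length(y))
}

#' Cubic fit: y = b0 + b1 x + b2 x^2 + b3 x^3
#' @param x predictor with at least 4 distinct values.
#' @param y numeric response.
#' @return A `regression_model` with coefficients `(b0, b1, b2, b3)`.
#' @export
fit_cubic <- function(x, y) {
  if (length(unique(x)) < 4) stop("cubic fit needs >= 4 distinct x values")
  if (length(x) <= 4) stop("need n > 4 points")
  X <- data.frame(x = x, x2 = x^2, x3 = x^3)
  m <- fit_linear_multi(X, y)
  m$form <- "cubic"
  m$predictors <- NA_character_
  m
}

# Pearson correlation of mid-ranks with p-value: t approximation for
# n >= 10, permutation null below that (exact enumeration up to n = 6).
#' Spearman rank correlation
#'
#' Implemented as the Pearson correlation of mid-ranks (average ranks on
#' ties).  The p-value uses the t approximation for n >= 10 and a
#' permutation null for smaller samples (exhaustive for n <= 6, 20000
#' Monte-Carlo permutations otherwise; the Monte-Carlo draw uses a local,
#' fixed RNG state and does not disturb the global seed).
#'
#' @param u,v numeric vectors, length >= 3.
#' @param label optional pair label carried into the result.
#' @return An object of class `correlation_result` with `r`, `p_value`,
#'   `n`, `label`.
#' @export
spearman <- function(u, v, label = NULL) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  n <- length(u)
  if (n < 3) stop("need at least 3 observations")
  ru <- rank(u); rv <- rank(v)
  if (stats::sd(ru) == 0 || stats::sd(rv) == 0)
    stop("zero variance in ranks; correlation undefined")
  r <- stats::cor(ru, rv)
  r_null <- function(perm) stats::cor(ru, rv[perm])
  if (n >= 10) {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  } else if (n <= 6) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, r_null)
    p <- mean(abs(rs) >= abs(r) - 1e-12)
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(20210627)
    rs <- replicate(20000, r_null(sample.int(n)))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
  }
  structure(list(r = r, p_value = unname(p), n = n, label = label),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %sr = %.3f, p = %s (n = %d)\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$r, format.pval(x$p_value, digits = 3), x$n))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1
    }
  }
  out
}

#' Classify goodness of fit from R^2
#'
#' `"high"` when R^2 >= 0.7, `"moderate"` when 0.5 <= R^2 < 0.7, `"poor"`
#' below 0.5.
#'
#' @param r_squared value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @export
classify_fit <- function(r_squared) {
  if (any(r_squared < 0 | r_squared > 1, na.rm = TRUE))
    stop("R^2 must be in [0, 1]")
  ifelse(is.na(r_squared), NA_character_,
         ifelse(r_squared >= 0.7, "high",
                ifelse(r_squared >= 0.5, "moderate", "poor")))
}

#' Classify a correlation coefficient
#'
#' `"high"` when r >= 0.8, `"moderate"` when 0.6 <= r < 0.8,
#' `"below_moderate"` otherwise.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return Character vector of labels.
#' @export
classify_corr <- function(r) {
  if (any(r < -1 | r > 1, na.rm = TRUE)) stop("r must be in [-1, 1]")
  ifelse(is.na(r), NA_character_,
         ifelse(r >= 0.8, "high",
                ifelse(r >= 0.6, "moderate", "below_moderate")))
}

#' Evaluate a regression model at feature values
#'
#' @param model a `regression_model` with coefficients.
#' @param features a named list / one-row data.frame of geometry features,
#'   or a numeric vector of predictor values in model order.
#' @return Predicted response in the model's declared units.
#' @export
predict_model <- function(model, features) {
  stopifnot(inherits(model, "regression_model"))
  if (is.null(model$coefficients))
    stop(sprintf("model for '%s' has no coefficients (provenance %s); refit on a cohort",
                 model$response, model$provenance))
  xs <- if (is.numeric(features) && is.null(names(features))) features
  else {
    missing <- setdiff(model$predictors, names(features))
    if (length(missing))
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    as.numeric(features[model$predictors])
  }
  if (any(is.na(xs))) stop("missing predictor value")
  b <- model$coefficients
  switch(model$form,
    linear_multi = b[1] + sum(b[-1] * xs),
    s_type = {
      if (xs[1] <= 0) stop("S-type model undefined for predictor <= 0")
      exp(b[1] + b[2] / xs[1])
    },
    inverse = {
      if (xs[1] == 0) stop("inverse model undefined at predictor 0")
      b[1] + b[2] / xs[1]
    },
    cubic = b[1] + b[2] * xs[1] + b[3] * xs[1]^2 + b[4] * xs[1]^3,
    stop("unknown model form: ", model$form))
}
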