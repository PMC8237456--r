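# Feature-cohort sampler: draws anatomy feature vectors uniformly over the
# cohort ranges and generates plan parameters by evaluating a model
# catalog at the drawn features (plus optional noise on each model's link
# scale).  With zero noise the parameters lie exactly on the generating
# models, which is what makes coefficient-recovery tests exact.

#' Cohort feature ranges
#'
#' The observed (min, max) range of each geometry feature in the emulated
#' 20-patient cohort; features are sampled uniformly within them.  Ranges
#' not reported for the cohort (lung volumes and the derived
#' primary-to-lung ratios, neck-node volume fraction) use physiologically
#' conventional values: total lung 2500-4500 cc, ipsilateral fraction
#' 0.45-0.55, neck fraction of the nodal target 0-0.3.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
cohort_feature_ranges <- function() {
  list(
    vol_pt = c(10.9, 100.1),
    vol_ln = c(24.8, 452.3),
    min_dist_pt_ln = c(1.2, 7.1),
    overlap_thickness_pt_ln = c(-4.5, 6.1),
    vol_ratio_ln_total_lung = c(0.01, 0.14),
    vol_ratio_ln_ipsi_lung = c(0.02, 0.30),
    min_dist_pt_eso = c(0.89, 10.47),
    overlap_ratio_eso_ln_to_eso = c(0.00, 0.87),
    min_dist_pt_heart = c(1.11, 7.58),
    overlap_ratio_heart_ln_to_heart = c(0.00, 0.05),
    overlap_ratio_heart_ln_to_ln = c(0.01, 0.24),
    lung_total_cc = c(2500, 4500),
    ipsi_fraction = c(0.45, 0.55),
    neck_fraction = c(0, 0.3)
  )
}

#' Sample a synthetic feature/parameter cohort
#'
#' Draws `n` anatomy feature vectors uniformly within
#' [cohort_feature_ranges()] (derived ratios computed consistently: the
#' corrected nodal ratios scale the uncorrected ones by one minus the drawn
#' neck fraction, and the primary-to-lung ratios divide the drawn primary
#' volume by the drawn lung volumes) and evaluates every
#' coefficient-carrying catalog entry at each feature vector.  Gaussian
#' noise of s.d. `noise_sd` is added on each model's link scale (log scale
#' for S-type models); `noise_sd = 0` reproduces the catalog predictions
#' exactly.
#'
#' @param n number of phantoms/patients (>= 3).
#' @param catalog a [model_catalog()] whose entries all carry coefficients,
#'   e.g. [synthetic_reference_catalog()].
#' @param noise_sd link-scale noise s.d. (response units; log units for
#'   S-type rows).
#' @param seed integer seed.
#' @return An object of class `plan_cohort`: `features` (one row per
#'   phantom) and `parameters` (long table: `phantom_id`, `response`,
#'   `domain`, `regime`, `value`, `units`).
#' @export
sample_feature_cohort <- function(n, catalog = synthetic_reference_catalog(),
                                  noise_sd = 0, seed = 1L) {
  if (n < 3) stop("need n >= 3")
  stopifnot(inherits(catalog, "model_catalog"))
  rng <- local_rng(seed)
  rg <- cohort_feature_ranges()
  draw <- function(nm) rng$runif(n, rg[[nm]][1], rg[[nm]][2])
  feats <- data.frame(phantom_id = seq_len(n))
  for (nm in c("vol_pt", "vol_ln", "min_dist_pt_ln", "overlap_thickness_pt_ln",
               "vol_ratio_ln_total_lung", "vol_ratio_ln_ipsi_lung",
               "min_dist_pt_eso", "overlap_ratio_eso_ln_to_eso",
               "min_dist_pt_heart", "overlap_ratio_heart_ln_to_heart",
               "overlap_ratio_heart_ln_to_ln"))
    feats[[nm]] <- draw(nm)
  neck <- draw("neck_fraction")
  lung_cc <- draw("lung_total_cc")
  ipsi <- draw("ipsi_fraction")
  feats$vol_ln_corrected <- feats$vol_ln * (1 - neck)
  feats$corr_vol_ratio_ln_total_lung <- feats$vol_ratio_ln_total_lung * (1 - neck)
  feats$corr_vol_ratio_ln_ipsi_lung <- feats$vol_ratio_ln_ipsi_lung * (1 - neck)
  feats$vol_ratio_pt_total_lung <- feats$vol_pt / lung_cc
  feats$vol_ratio_pt_ipsi_lung <- feats$vol_pt / (ipsi * lung_cc)

  rows <- list()
  for (m in catalog$entries) {
    if (is.null(m$coefficients)) next
    missing <- setdiff(m$predictors, names(feats))
    if (length(missing))
      stop(sprintf("catalog model '%s' references undrawn feature(s): %s",
                   m$response, paste(missing, collapse = ", ")))
    link <- vapply(seq_len(n), function(i) {
      x <- as.numeric(feats[i, m$predictors, drop = TRUE])
      b <- m$coefficients
      switch(m$form,
        linear_multi = b[1] + sum(b[-1] * x),
        cubic = b[1] + b[2] * x + b[3] * x^2 + b[4] * x^3,
        inverse = b[1] + b[2] / x,
        s_type = b[1] + b[2] / x)  # log scale
    }, numeric(1))
    if (noise_sd > 0) link <- link + rng$rnorm(n, 0, noise_sd)
    value <- if (m$form == "s_type") exp(link) else link
    rows[[length(rows) + 1]] <- data.frame(
      phantom_id = seq_len(n), response = m$response, domain = m$domain,
      regime = m$regime, value = value, units = m$units,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("catalog has no coefficient-carrying entries")
  parameters <- do.call(rbind, rows)
  rownames(parameters) <- NULL
  structure(list(features = feats, parameters = parameters,
                 noise_sd = noise_sd, seed = seed),
            class = "plan_cohort")
}

#' @export
print.plan_cohort <- function(x, ...) {
  cat(sprintf("<plan_cohort> %d phantoms, %d parameter rows (noise_sd = %g)\n",
              nrow(x$features), nrow(x$parameters), x$noise_sd))
  invisible(x)
}

#' Fit the model-specification table on a cohort
#'
#' For every row of `spec` (see [default_model_spec()]), subsets the
#' cohort's parameter table to that (response, domain, regime), joins the
#' features, and fits the stated family.  Rows whose predictors violate a
#' family's domain (x <= 0 for S-type, x = 0 for inverse, or y <= 0 for
#' S-type) are dropped from that fit — overlap-free anatomies fall outside
#' the S-type models' support.  Per-row failures are collected, not fatal.
#'
#' @param cohort a `plan_cohort` (or a list with `features` and long
#'   `parameters` in the same layout).
#' @param spec model-specification `data.frame`; default
#'   [default_model_spec()].
#' @return A [model_catalog()] of fitted entries; failed rows appear with
#'   an `error` field instead of coefficients in the `failures` attribute.
#' @export
fit_cohort <- function(cohort, spec = default_model_spec()) {
  feats <- cohort$features
  pars <- cohort$parameters
  entries <- list()
  failures <- list()
  for (i in seq_len(nrow(spec))) {
    response <- spec$response[i]; domain <- spec$domain[i]
    regime <- spec$regime[i]; form <- spec$form[i]
    predictors <- spec$predictors[[i]]
    res <- tryCatch({
      sub <- pars[pars$response == response & pars$domain == domain &
                    pars$regime == regime, ]
      if (!nrow(sub)) stop("no cohort rows for this model")
      df <- merge(sub, feats, by = "phantom_id")
      y <- df$value
      if (form == "s_type") {
        x <- df[[predictors]]
        keep <- x > 0 & y > 0
        m <- fit_s_type(x[keep], y[keep])
      } else if (form == "inverse") {
        x <- df[[predictors]]
        keep <- x != 0
        m <- fit_inverse(x[keep], y[keep])
      } else if (form == "cubic") {
        m <- fit_cubic(df[[predictors]], y)
      } else {
        m <- fit_linear_multi(df[predictors], y)
      }
      m$response <- response; m$domain <- domain; m$regime <- regime
      m$predictors <- predictors
      m$units <- sub$units[1]
      m$provenance <- "user-fitted"
      m
    }, error = function(e) e)
    key <- catalog_key(response, domain, regime)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
    } else {
      entries[[length(entries) + 1]] <- res
    }
  }
  out <- model_catalog(entries)
  attr(out, "failures") <- failures
  out
}
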