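# End-to-end orchestration: cohort generation -> geometry features ->
# dose/EQD2 -> plan parameters -> physical-vs-EQD2 Spearman concordance ->
# per-model fits with goodness classification -> holdout prediction and
# regime comparison.  Two cohort sources: "model" evaluates a generating
# catalog at sampled features (fast, exact, used for parameter-recovery
# studies); "phantom" runs the full voxel pipeline on synthetic phantoms.

#' Configure a pipeline run
#'
#' @param n_phantoms cohort size.
#' @param n_holdout phantoms held out of fitting and predicted via the
#'   fitted catalog (the last `n_holdout` ids).
#' @param cohort_source `"model"` (catalog-generated parameters) or
#'   `"phantom"` (voxel pipeline on synthetic phantoms).
#' @param noise_sd link-scale noise for the model source.
#' @param seed master seed; every stage derives its stream from it.
#' @param regimes subset of `c("C&S", "C&SIB")`.
#' @param catalog generating catalog for the model source.
#' @param model_spec model-specification table for fitting.
#' @param ab_map [alpha_beta_map()] for the phantom source.
#' @param phantom_shape,phantom_spacing lattice of phantom-source runs.
#' @param dose_args list of extra arguments passed to [dose_model_spec()]
#'   for every regime (phantom source).
#' @param out_dir if non-`NULL`, report tables are written there as CSV.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_phantoms = 12, n_holdout = 2,
                       cohort_source = c("model", "phantom"),
                       noise_sd = 0, seed = 1L, regimes = REGIMES,
                       catalog = synthetic_reference_catalog(),
                       model_spec = default_model_spec(),
                       ab_map = alpha_beta_map(),
                       phantom_shape = c(72, 46, 60),
                       phantom_spacing = c(4.5, 4.5, 4.5),
                       dose_args = list(), out_dir = NULL) {
  cohort_source <- match.arg(cohort_source)
  if (!length(regimes) || !all(regimes %in% REGIMES))
    stop("regimes must be a nonempty subset of C&S / C&SIB")
  if (n_phantoms - n_holdout < 3)
    stop(sprintf("cohort of %d too small for %d holdouts plus fitting",
                 n_phantoms, n_holdout))
  structure(list(n_phantoms = n_phantoms, n_holdout = n_holdout,
                 cohort_source = cohort_source, noise_sd = noise_sd,
                 seed = as.integer(seed), regimes = regimes,
                 catalog = catalog, model_spec = model_spec, ab_map = ab_map,
                 phantom_shape = phantom_shape,
                 phantom_spacing = phantom_spacing,
                 dose_args = dose_args, out_dir = out_dir),
            class = "run_config")
}

# phantom-source cohort: voxel pipeline per phantom x regime
phantom_cohort <- function(config) {
  rng <- local_rng(config$seed)
  rg <- cohort_feature_ranges()
  feats_rows <- list(); par_rows <- list(); failures <- list()
  for (i in seq_len(config$n_phantoms)) {
    draw <- rng$runif(5)
    spec <- phantom_spec(
      shape = config$phantom_shape, spacing = config$phantom_spacing,
      pt_volume_cc = rg$vol_pt[1] + draw[1] * diff(rg$vol_pt),
      ln_volume_cc = 80 + draw[2] * 220,
      pt_ln_gap_cm = 2 + draw[3] * 4,
      pt_ln_overlap_cm = -1 + draw[4] * 4,
      neck_node_cc = if (draw[5] < 0.3) 25 else 0,
      jitter_mm = 3, seed = config$seed + 1000L + i)
    res <- tryCatch({
      st <- make_phantom(spec)
      f <- extract_features(st)
      f$phantom_id <- i
      prows <- list()
      for (regime in config$regimes) {
        ds <- do.call(dose_model_spec, c(list(regime = regime), config$dose_args))
        comp <- make_dose(st, ds)
        hyb <- hybrid_plan_dose(comp$cfrt, comp$boost, comp$cfrt_scheme,
                                comp$boost_scheme, config$ab_map, st)
        for (domain in c("physical", "EQD2")) {
          pp <- plan_parameters(hyb, st, domain)
          long <- data.frame(phantom_id = i, regime = regime,
                             domain = domain,
                             response = setdiff(names(pp), "domain"),
                             value = as.numeric(unlist(pp[setdiff(names(pp), "domain")])),
                             units = "Gy", stringsAsFactors = FALSE)
          prows[[length(prows) + 1]] <- long
        }
      }
      list(features = f, parameters = do.call(rbind, prows))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(i)]] <- conditionMessage(res)
    } else {
      feats_rows[[length(feats_rows) + 1]] <- res$features
      par_rows[[length(par_rows) + 1]] <- res$parameters
    }
  }
  if (!length(feats_rows)) stop("no phantom succeeded; cohort empty")
  cohort <- structure(list(features = do.call(rbind, feats_rows),
                           parameters = do.call(rbind, par_rows),
                           noise_sd = 0, seed = config$seed),
                      class = "plan_cohort")
  attr(cohort, "failures") <- failures
  cohort
}

# Spearman physical-vs-EQD2 per (response, regime)
spearman_table <- function(parameters) {
  rows <- list()
  for (regime in unique(parameters$regime)) {
    sub <- parameters[parameters$regime == regime, ]
    responses <- intersect(unique(sub$response[sub$domain == "physical"]),
                           unique(sub$response[sub$domain == "EQD2"]))
    for (resp in responses) {
      u <- sub$value[sub$domain == "physical" & sub$response == resp]
      v <- sub$value[sub$domain == "EQD2" & sub$response == resp]
      ord_u <- order(sub$phantom_id[sub$domain == "physical" & sub$response == resp])
      ord_v <- order(sub$phantom_id[sub$domain == "EQD2" & sub$response == resp])
      if (anyNA(u) || anyNA(v)) next
      res <- tryCatch(spearman(u[ord_u], v[ord_v]), error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- data.frame(
        response = resp, regime = regime, r = res$r, p_value = res$p_value,
        corr_class = classify_corr(res$r), n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

holdout_table <- function(fitted, cohort, holdout_ids, spec) {
  rows <- list()
  feats <- cohort$features
  pars <- cohort$parameters
  for (id in holdout_ids) {
    f <- feats[feats$phantom_id == id, ]
    for (i in seq_len(nrow(spec))) {
      key <- c(spec$response[i], spec$domain[i], spec$regime[i])
      obs <- pars$value[pars$phantom_id == id & pars$response == key[1] &
                          pars$domain == key[2] & pars$regime == key[3]]
      if (!length(obs)) next
      pred <- tryCatch(
        catalog_predict(fitted, key[1], key[2], key[3], f),
        error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        phantom_id = id, response = key[1], domain = key[2], regime = key[3],
        observed = obs[1], predicted = pred, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Generates a cohort (from the model catalog or from voxel phantoms),
#' computes the physical-vs-EQD2 Spearman concordance per parameter and
#' regime, fits every model-specification row on the non-holdout phantoms
#' with goodness classification, predicts the holdout phantoms from the
#' fitted catalog, and compares regimes on the holdouts.  Deterministic
#' under a fixed `seed`.  If `config$out_dir` is set, the tables are
#' written there as CSV (`features.csv`, `parameters.csv`, `fits.csv`,
#' `spearman.csv`, `holdout.csv`, `regime_comparison.csv`).
#'
#' @param config a [run_config()].
#' @return An object of class `run_report` with elements `features`,
#'   `parameters`, `fitted_catalog`, `fit_table`, `spearman`, `holdout`,
#'   `regime_comparison`, `failures`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$model_spec
  spec <- spec[vapply(spec$regime, function(g) g %in% config$regimes, logical(1)), ]
  cohort <- if (config$cohort_source == "model") {
    cat_entries <- config$catalog$entries
    keep <- vapply(cat_entries, function(m)
      m$regime %in% config$regimes && !is.null(m$coefficients), logical(1))
    sample_feature_cohort(config$n_phantoms, model_catalog(unname(cat_entries[keep])),
                          config$noise_sd, config$seed)
  } else {
    phantom_cohort(config)
  }
  ids <- sort(unique(cohort$features$phantom_id))
  holdout_ids <- if (config$n_holdout > 0) utils::tail(ids, config$n_holdout)
  else integer(0)
  train_ids <- setdiff(ids, holdout_ids)
  train <- structure(list(
    features = cohort$features[cohort$features$phantom_id %in% train_ids, ],
    parameters = cohort$parameters[cohort$parameters$phantom_id %in% train_ids, ]),
    class = "plan_cohort")
  fitted <- fit_cohort(train, spec)
  fit_table <- catalog_table(fitted)
  sp_table <- spearman_table(cohort$parameters)
  hold <- if (length(holdout_ids)) holdout_table(fitted, cohort, holdout_ids, spec)
  else NULL
  report <- structure(list(
    features = cohort$features, parameters = cohort$parameters,
    fitted_catalog = fitted, fit_table = fit_table, spearman = sp_table,
    holdout = hold, regime_comparison = NULL,
    failures = c(attr(cohort, "failures"), attr(fitted, "failures")),
    config = config), class = "run_report")
  if (length(config$regimes) == 2 && !is.null(hold))
    report$regime_comparison <- compare_regimes(report)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) if (!is.null(df))
      write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
    wr(report$features, "features.csv")
    wr(report$parameters, "parameters.csv")
    wr(report$fit_table, "fits.csv")
    wr(report$spearman, "spearman.csv")
    wr(report$holdout, "holdout.csv")
    wr(report$regime_comparison, "regime_comparison.csv")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d phantoms, %d parameter rows, %d fitted models, %d failure(s)\n",
              length(unique(x$features$phantom_id)), nrow(x$parameters),
              length(x$fitted_catalog$entries), length(x$failures)))
  invisible(x)
}

#' Compare regimes on the holdout phantoms
#'
#' For each holdout phantom, parameter and domain present in both regimes,
#' records which regime's observed and predicted values are larger and
#' whether the prediction ordered the regimes correctly (ties count as
#' agreement only with an observed tie).
#'
#' @param report a `run_report` from a two-regime run with holdouts.
#' @return A `data.frame` with columns `phantom_id`, `response`, `domain`,
#'   `higher_observed`, `higher_predicted`, `ordering_correct`.
#' @export
compare_regimes <- function(report) {
  hold <- report$holdout
  if (is.null(hold)) stop("report has no holdout table")
  if (length(unique(hold$regime)) < 2)
    stop("regime comparison needs both regimes in the report")
  rows <- list()
  keys <- unique(hold[c("phantom_id", "response", "domain")])
  for (i in seq_len(nrow(keys))) {
    sub <- merge(keys[i, ], hold)
    if (nrow(sub) != 2 || any(is.na(sub$predicted))) next
    pick <- function(v) if (v[1] == v[2]) "tie" else sub$regime[which.max(v)]
    ho <- pick(sub$observed); hp <- pick(sub$predicted)
    rows[[length(rows) + 1]] <- data.frame(
      keys[i, ], higher_observed = ho, higher_predicted = hp,
      ordering_correct = identical(ho, hp), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
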