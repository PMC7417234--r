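#' @title Coverage assessment and estimator-comparison experiments
#' @name evaluation
#' @description
#' Tools to score abundance estimators against known truth: per-survey
#' interval-coverage reports (the proportion of surveys whose confidence
#' interval contains the true count), and seeded simulation experiments
#' comparing the raw detector count, the modified Horvitz-Thompson
#' estimator, and the N-mixture total on bias, RMSE and coverage.
NULL

#' Drop ground-truth-only rows from an observation table
#'
#' Abundance estimation operates on detector output only; animals known to
#' be present but missed by the detector are used in model fitting, never in
#' estimation. Returns the table without `missed` rows.
#'
#' @param table an `obs_table`.
#' @return the filtered `obs_table`.
#' @export
filter_detected <- function(table) {
  out <- table[table$klass != "missed", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assess confidence-interval coverage against known truth
#'
#' Marks each survey covered when `lower <= truth <= upper` (boundary
#' equality counts as covered) and reports the proportion covered.
#'
#' @param estimates data frame from [estimate_surveys()] (columns
#'   `survey_id`, `estimate`, `lower`, `upper`).
#' @param truths data frame with columns `survey_id` and `truth` (or
#'   `true_N`), one row per estimated survey.
#' @return object of class `coverage_report`: `per_survey` data frame,
#'   `n_covered`, `n_surveys`, `proportion`.
#' @export
assess_coverage <- function(estimates, truths) {
  if (!is.null(truths$true_N) && is.null(truths$truth))
    truths$truth <- truths$true_N
  m <- match(estimates$survey_id, truths$survey_id)
  if (anyNA(m))
    stop("no truth for survey_id: ",
         paste(estimates$survey_id[is.na(m)], collapse = ", "))
  per <- data.frame(survey_id = estimates$survey_id,
                    truth = truths$truth[m],
                    estimate = estimates$estimate,
                    lower = estimates$lower, upper = estimates$upper,
                    stringsAsFactors = FALSE)
  per$covered <- per$lower <= per$truth & per$truth <= per$upper
  structure(list(per_survey = per, n_covered = sum(per$covered),
                 n_surveys = nrow(per),
                 proportion = sum(per$covered) / nrow(per)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  print(x$per_survey, digits = 4)
  cat(sprintf("coverage: %d / %d surveys (%.1f%%)\n", x$n_covered,
              x$n_surveys, 100 * x$proportion))
  invisible(x)
}

# Hold out the latest n_test survey dates (the temporal hold-out used for
# estimator testing).
latest_test_dates <- function(table, n_test = 4) {
  dates <- sort(unique(as.Date(table$date)))
  utils::tail(dates, n_test)
}

#' One full modified-H-T pipeline pass over a simulated campaign
#'
#' Simulates a campaign, holds out the latest `n_test` survey dates, fits
#' the three detection models on the training dates by stepwise selection,
#' estimates abundance for each test survey, and scores coverage against the
#' generator's truth.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param n_test number of latest survey dates held out for estimation.
#' @param stepwise use [stepwise_select()] (default); otherwise fit the
#'   generating covariate sets directly.
#' @param level nominal interval coverage.
#' @return list with `estimates`, `coverage` (a `coverage_report`), `fits`
#'   and `truth`.
#' @export
ht_pipeline <- function(config = sim_config(), seed = config$seed,
                        n_test = 4, stepwise = TRUE, level = 0.95) {
  sim <- simulate_observations(config, seed = seed)
  split <- split_by_date(sim$table, latest_test_dates(sim$table, n_test))
  fits <- fit_roles(split$train, stepwise = stepwise)
  est <- estimate_surveys(filter_detected(split$test),
                          fits$detection, fits$false, fits$duplicate,
                          level = level)
  truth <- sim$truth$per_survey
  cov <- assess_coverage(est, data.frame(survey_id = truth$survey_id,
                                         truth = truth$true_N))
  list(estimates = est, coverage = cov, fits = fits, truth = sim$truth)
}

# Constant-probability fit for a degenerate response (e.g. a campaign with
# no misses at all): predicts mean(y) with zero uncertainty.
constant_fit <- function(role, p) {
  p <- min(max(p, 1e-12), 1 - 1e-12)
  structure(list(role = role, covariate_names = character(0),
                 coefficients = c(`(Intercept)` = stats::qlogis(p)),
                 se = 0, vcov = matrix(0, 1, 1), smooth = FALSE,
                 model = NULL, p_values = numeric(0), n_par = 1L),
            class = "detection_fit")
}

# Fit the three probability models on a training table. A role whose
# response has only one outcome class gets a constant-probability fit.
fit_roles <- function(train, stepwise = TRUE, alpha = 0.05) {
  fit_one <- function(role, covs = NULL) {
    br <- build_response(train, role)
    if (sum(br$y) == 0 || sum(br$y) == length(br$y)) {
      ua_log("INFO", "fit_roles",
             sprintf("role %s: degenerate response, constant fit at %.3g",
                     role, mean(br$y)))
      return(constant_fit(role, mean(br$y)))
    }
    if (stepwise) stepwise_select(train, role, alpha)$selected
    else fit_logistic(br$y, br$X[, covs, drop = FALSE], role)
  }
  list(detection = fit_one("detection", c("temperature", "dist_edge")),
       false = fit_one("false", "dist_edge"),
       duplicate = fit_one("duplicate", "dist_nearest"))
}

#' Simulation experiment comparing abundance estimators
#'
#' For each replicate (with a per-replicate seed derived from the master
#' seed by counter) a survey campaign is simulated; the test surveys are
#' estimated with the selected estimators and scored against truth. Metrics
#' per estimator: mean bias, RMSE, and (where an interval exists) coverage.
#' The raw detector count has no interval; the N-mixture estimator is run on
#' a transect-count dataset simulated under the same replicate seed and
#' scored against its own latent truth `sum(M_t)`.
#'
#' @param config a [sim_config()].
#' @param replicates number of replicates (>= 1).
#' @param estimators subset of `c("raw", "ht", "nmixture")`.
#' @param seed master seed.
#' @param n_test latest survey dates held out per replicate.
#' @param stepwise passed to [ht_pipeline()].
#' @return object of class `comparison_summary`: `summary` data frame (one
#'   row per estimator), `per_survey` records, `attempted`, `completed`.
#' @export
run_comparison <- function(config = sim_config(), replicates = 10,
                           estimators = c("raw", "ht"),
                           seed = config$seed, n_test = 4,
                           stepwise = FALSE) {
  stopifnot(replicates >= 1)
  estimators <- match.arg(estimators, c("raw", "ht", "nmixture"),
                          several.ok = TRUE)
  recs <- list()
  completed <- 0L
  for (r in seq_len(replicates)) {
    rseed <- seed + r
    res <- tryCatch({
      rows <- list()
      if (any(c("raw", "ht") %in% estimators)) {
        pl <- ht_pipeline(config, seed = rseed, n_test = n_test,
                          stepwise = stepwise)
        per <- pl$coverage$per_survey
        if ("ht" %in% estimators)
          rows$ht <- data.frame(replicate = r, estimator = "ht",
                                survey_id = per$survey_id,
                                truth = per$truth, estimate = per$estimate,
                                covered = per$covered,
                                stringsAsFactors = FALSE)
        if ("raw" %in% estimators) {
          est <- pl$estimates
          rows$raw <- data.frame(replicate = r, estimator = "raw",
                                 survey_id = est$survey_id,
                                 truth = per$truth, estimate = est$raw_count,
                                 covered = NA, stringsAsFactors = FALSE)
        }
      }
      if ("nmixture" %in% estimators) {
        simc <- simulate_transect_counts(config, seed = rseed)
        sp <- nmixture_spec(config$keyfun,
                            dispersion = is.finite(config$nb_dispersion))
        fit <- fit_nmixture(simc$counts, sp)
        rows$nmixture <- data.frame(replicate = r, estimator = "nmixture",
                                    survey_id = "transect_total",
                                    truth = sum(simc$truth$M),
                                    estimate = total_abundance(fit),
                                    covered = NA, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }, error = function(e) {
      ua_log("WARN", "run_comparison",
             sprintf("replicate %d skipped: %s", r, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      completed <- completed + 1L
      recs[[r]] <- res
    }
  }
  per <- do.call(rbind, recs)
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, per$estimator), function(d) {
    data.frame(estimator = d$estimator[1], n = nrow(d),
               mean_bias = mean(d$estimate - d$truth),
               rmse = sqrt(mean((d$estimate - d$truth)^2)),
               coverage = if (all(is.na(d$covered))) NA_real_
                 else mean(d$covered, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, per_survey = per,
                 attempted = replicates, completed = completed,
                 seed = seed),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("estimator comparison: %d/%d replicates completed (seed %d)\n",
              x$completed, x$attempted, x$seed))
  print(x$summary, digits = 4)
  invisible(x)
}
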