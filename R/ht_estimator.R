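#' @title Modified Horvitz-Thompson abundance estimator
#' @name ht_estimator
#' @description
#' A design-based abundance estimator for automated-detector output. Every
#' object the detector flags contributes one inverse-probability term,
#' down-weighted by its estimated probability of being a duplicate or a
#' false detection:
#' \deqn{\hat N = \sum_{i=1}^{C} \frac{1 - \hat d_i - \hat f_i}{\hat p_i}}
#' where C is the raw count of detector-identified objects, \eqn{\hat p_i}
#' the fitted probability of detection, \eqn{\hat f_i} the fitted probability
#' the object is false, and \eqn{\hat d_i} the fitted probability it is a
#' duplicate. Confidence limits substitute the per-object 95% limits of the
#' three probabilities: the lower limits of p, f and d give the upper limit
#' of N (few animals missed being equivalent to low p, and a low chance of
#' spurious detections inflating the numerator), and vice versa.
NULL

#' Modified Horvitz-Thompson point estimate
#'
#' Evaluates the estimator above. Each per-object numerator is clamped below
#' at 0 (an object judged almost surely false *and* duplicate cannot
#' subtract animals) and each \eqn{\hat p_i} is clamped below at
#' `p_floor` so no single object's contribution explodes; the number of
#' clamped objects is reported so truncation is never silent.
#'
#' @param p_hat,f_hat,d_hat equal-length vectors of per-object fitted
#'   probabilities; `p_hat` must be positive.
#' @param p_floor lower clamp for `p_hat` (default 1e-3).
#' @return list with `estimate` (raw), `estimate_rounded` (nearest integer,
#'   as reported), and `clamped_objects`.
#' @export
modified_ht_point <- function(p_hat, f_hat, d_hat, p_floor = 1e-3) {
  n <- length(p_hat)
  if (length(f_hat) != n || length(d_hat) != n)
    stop("p_hat, f_hat and d_hat must have equal length")
  if (any(p_hat <= 0)) stop("p_hat must be positive for every object")
  stopifnot(all(f_hat >= 0 & f_hat <= 1), all(d_hat >= 0 & d_hat <= 1),
            all(p_hat <= 1))
  num <- 1 - d_hat - f_hat
  clamped <- sum(num < 0) + sum(p_hat < p_floor)
  num <- pmax(num, 0)
  p <- pmax(p_hat, p_floor)
  est <- sum(num / p)
  list(estimate = est, estimate_rounded = round(est),
       clamped_objects = as.integer(clamped))
}

#' Abundance estimate with plug-in confidence limits
#'
#' Builds one survey's abundance estimate from the per-object predictions
#' (with limits) of the three probability models. The upper limit of N uses
#' the lower limits of p, f and d; the lower limit of N uses their upper
#' limits; the ordering `lower <= estimate <= upper` is asserted.
#'
#' @param pred_p,pred_f,pred_d data frames from [predict_with_ci()] with
#'   columns `fit`, `lower`, `upper`, aligned over the same objects.
#' @param survey_id survey label.
#' @param level nominal coverage recorded on the estimate.
#' @return one-row data frame of class `abundance_estimate` with columns
#'   `survey_id`, `raw_count`, `estimate`, `lower`, `upper`, `level`,
#'   `clamped_objects`.
#' @export
modified_ht_interval <- function(pred_p, pred_f, pred_d,
                                 survey_id = "survey", level = 0.95) {
  n <- nrow(pred_p)
  if (nrow(pred_f) != n || nrow(pred_d) != n)
    stop("prediction tables must cover the same objects")
  point <- modified_ht_point(pred_p$fit, pred_f$fit, pred_d$fit)
  upper <- modified_ht_point(pred_p$lower, pred_f$lower, pred_d$lower)
  lower <- modified_ht_point(pred_p$upper, pred_f$upper, pred_d$upper)
  est <- data.frame(survey_id = survey_id, raw_count = n,
                    estimate = point$estimate_rounded,
                    lower = lower$estimate_rounded,
                    upper = upper$estimate_rounded,
                    estimate_raw = point$estimate,
                    lower_raw = lower$estimate, upper_raw = upper$estimate,
                    level = level,
                    clamped_objects = point$clamped_objects,
                    stringsAsFactors = FALSE)
  stopifnot(est$lower_raw <= est$estimate_raw + 1e-9,
            est$estimate_raw <= est$upper_raw + 1e-9)
  class(est) <- c("abundance_estimate", class(est))
  est
}

#' Per-survey abundance estimates for a testing table
#'
#' For each survey in the table: the raw count C is the number of
#' detector-identified objects; p and f are predicted from each object's
#' temperature, wind speed and habitat-edge distance per the fitted models;
#' d from its nearest-detection distance and detection timing; the modified
#' Horvitz-Thompson estimate and limits follow. The table must contain only
#' detector output: ground-truthed misses are never part of estimation and
#' raise an error.
#'
#' @param test an `obs_table` of detector-identified objects (no `missed`
#'   rows).
#' @param fit_p,fit_f,fit_d `detection_fit` objects for detection, false
#'   detection and duplicate detection.
#' @param level nominal coverage; the limits use
#'   `z = qnorm(1 - (1-level)/2)`.
#' @return data frame with one `abundance_estimate` row per survey.
#' @export
estimate_surveys <- function(test, fit_p, fit_f, fit_d, level = 0.95) {
  if (any(test$klass == "missed"))
    stop("testing table must contain only detector-identified objects; ",
         "remove rows with klass = missed")
  z <- stats::qnorm(1 - (1 - level) / 2)
  # logistic predictions are positive by construction; guard the rare
  # response-scale underflow to 0 so it is handled by the estimator's clamp
  # instead of tripping its positivity check
  floor_p <- function(pr) {
    pr$fit <- pmax(pr$fit, 1e-12)
    pr$lower <- pmax(pr$lower, 1e-12)
    pr$upper <- pmax(pr$upper, 1e-12)
    pr
  }
  out <- lapply(unique(test$survey_id), function(sid) {
    rows <- test[test$survey_id == sid, , drop = FALSE]
    modified_ht_interval(floor_p(predict_with_ci(fit_p, rows, z)),
                         predict_with_ci(fit_f, rows, z),
                         predict_with_ci(fit_d, rows, z),
                         survey_id = sid, level = level)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
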