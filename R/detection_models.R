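#' @title Bernoulli models of detection, false detection and duplicate
#'   detection
#' @name detection_models
#' @description
#' Three logistic-regression models drive the modified Horvitz-Thompson
#' estimator:
#' \describe{
#'   \item{detection}{probability an animal present is detected; fitted on
#'     verified detections vs. ground-truthed misses (duplicates and false
#'     positives excluded); candidate covariates: ambient temperature, wind
#'     speed, distance to habitat edge.}
#'   \item{false}{probability a detected object is not actually the target
#'     species; fitted on all detector output (misses excluded); same
#'     candidates.}
#'   \item{duplicate}{probability a verified detection is a repeat of an
#'     already-detected animal; fitted on unique vs. duplicate detections;
#'     candidates: distance to nearest detection, time since previous
#'     detection.}
#' }
#' Selection is stepwise: univariate fits ranked with the null model by
#' p-value, deviance reduction and AIC; significant covariates combined into
#' multivariate fits; finally a penalized-spline additive (GAM) version of
#' the best linear model is adopted only if it lowers AIC by more than 2.
NULL

ROLE_COVARIATES <- list(
  detection = c("temperature", "wind_speed", "dist_edge"),
  false = c("temperature", "wind_speed", "dist_edge"),
  duplicate = c("dist_nearest", "time_since_prev"))

ROLE_RESPONSE <- list(
  detection = list(keep = c("unique_detection", "missed"),
                   positive = "unique_detection"),
  false = list(keep = c("unique_detection", "duplicate", "false_positive"),
               positive = "false_positive"),
  duplicate = list(keep = c("unique_detection", "duplicate"),
                   positive = "duplicate"))

#' Build the binary response and design rows for one model role
#'
#' Subsets an observation table to the rows relevant for a role and derives
#' the 0/1 response: detection keeps unique detections (1) vs misses (0);
#' false keeps all detector output (false positive = 1, real detection = 0)
#' and drops misses; duplicate keeps verified koala detections (duplicate =
#' 1, first unique detection = 0).
#'
#' @param table an `obs_table`.
#' @param role one of `"detection"`, `"false"`, `"duplicate"`.
#' @return list with `y` (integer 0/1), `X` (data frame of the role's
#'   candidate covariates) and `rows` (the subset of the table used).
#' @export
build_response <- function(table, role = c("detection", "false", "duplicate")) {
  role <- match.arg(role)
  rr <- ROLE_RESPONSE[[role]]
  rows <- table[table$klass %in% rr$keep, , drop = FALSE]
  covs <- ROLE_COVARIATES[[role]]
  for (cv in covs) {
    if (is.null(rows[[cv]]) || all(is.na(rows[[cv]])))
      stop(sprintf("covariate %s required for role %s is absent", cv, role))
  }
  y <- as.integer(rows$klass == rr$positive)
  X <- rows[, covs, drop = FALSE]
  rownames(X) <- NULL
  list(y = y, X = X, rows = rows, role = role)
}

# Diagnose (quasi-)perfect separation: a single covariate whose value ranges
# for y=0 and y=1 do not overlap.
find_separating_covariate <- function(y, X) {
  for (nm in names(X)) {
    x0 <- X[[nm]][y == 0]; x1 <- X[[nm]][y == 1]
    if (!length(x0) || !length(x1)) next
    if (max(x0) < min(x1) || max(x1) < min(x0)) return(nm)
  }
  NA_character_
}

new_model_fit <- function(model, role, covariates, smooth = FALSE,
                          basis = NULL) {
  ll <- as.numeric(stats::logLik(model))
  null_dev <- model$null.deviance
  null_ll <- ll + (model$deviance - null_dev) / 2
  co <- summary(model)
  if (smooth) {
    pvals <- if (length(covariates)) co$s.table[, "p-value"] else numeric(0)
    npar <- sum(model$edf) # effective dof, counted toward AIC
  } else {
    ct <- co$coefficients
    pvals <- if (length(covariates)) ct[-1, "Pr(>|z|)"] else numeric(0)
    npar <- length(stats::coef(model))
  }
  structure(list(
    role = role, covariate_names = covariates,
    coefficients = stats::coef(model),
    se = sqrt(diag(stats::vcov(model))),
    vcov = stats::vcov(model),
    loglik = ll, null_loglik = null_ll,
    aic = stats::AIC(model),
    null_deviance = null_dev, residual_deviance = model$deviance,
    p_values = pvals, n = length(model$y),
    n_par = npar, smooth = smooth, basis = basis,
    model = model), class = "detection_fit")
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("%s model (%s): %s\n", x$role,
              if (x$smooth) "GAM" else "GLM",
              if (length(x$covariate_names))
                paste(x$covariate_names, collapse = " + ") else "null"))
  cat(sprintf("  n = %d, logLik = %.3f, AIC = %.2f, deviance %.2f -> %.2f\n",
              x$n, x$loglik, x$aic, x$null_deviance, x$residual_deviance))
  cat(sprintf("  McFadden pseudo-R2 = %.4f\n", mcfadden_r2(x)))
  invisible(x)
}

#' Fit a logistic (Bernoulli, logit-link) regression
#'
#' Maximum-likelihood fit of `y ~ X` with standard errors from the inverse
#' observed information. Perfect separation and rank-deficient designs are
#' errors (downstream estimation divides by fitted probabilities, so huge
#' coefficients must not pass silently).
#'
#' @param y binary 0/1 vector with at least one success and one failure.
#' @param X data frame of covariates; zero columns gives the intercept-only
#'   (null) model.
#' @param role model role label stored on the fit.
#' @return a `detection_fit`.
#' @export
fit_logistic <- function(y, X = NULL, role = "detection") {
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one success and one failure")
  if (is.null(X)) X <- data.frame(row.names = seq_along(y))
  covs <- names(X)
  dat <- cbind(data.frame(.y = y), X)
  form <- stats::as.formula(paste(".y ~",
    if (length(covs)) paste(covs, collapse = " + ") else "1"))
  if (length(covs)) {
    mm <- stats::model.matrix(form, dat)
    if (qr(mm)$rank < ncol(mm))
      stop("rank-deficient design: collinear covariates")
  }
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <- find_separating_covariate(y, X)
        stop("perfect separation detected",
             if (!is.na(sep)) paste0(" (covariate: ", sep, ")") else "",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (length(covs) && max(abs(stats::coef(fit)[-1] * vapply(X, stats::sd, 1))) > 30) {
    sep <- find_separating_covariate(y, X)
    stop("perfect separation detected",
         if (!is.na(sep)) paste0(" (covariate: ", sep, ")") else "")
  }
  new_model_fit(fit, role, covs, smooth = FALSE)
}

#' Fit an additive (penalized-spline GAM, logit-link) model
#'
#' Each covariate enters through a thin-plate spline smooth of the given
#' basis size; smoothing parameters are chosen by generalized
#' cross-validation, and the effective degrees of freedom enter the AIC.
#'
#' @param y binary 0/1 response.
#' @param X data frame of covariates (at least one column).
#' @param basis_size spline basis dimension per smooth (>= 3).
#' @param role model role label.
#' @return a `detection_fit` with `smooth = TRUE`.
#' @export
fit_additive <- function(y, X, basis_size = 10, role = "detection") {
  if (basis_size < 3) stop("basis_size must be >= 3")
  y <- as.integer(y)
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one success and one failure")
  covs <- names(X)
  if (!length(covs)) stop("additive model needs at least one covariate")
  k <- vapply(X, function(x) min(basis_size, length(unique(x)) - 1L), 1)
  if (any(k < 3)) stop("too few unique covariate values for a smooth")
  dat <- cbind(data.frame(.y = y), X)
  form <- stats::as.formula(paste(".y ~",
    paste(sprintf("s(%s, k = %d)", covs, k), collapse = " + ")))
  fit <- mgcv::gam(form, family = stats::binomial(), data = dat,
                   method = "GCV.Cp")
  if (any(abs(fit$fitted.values - 0.5) > 0.5 - 1e-10) &&
      !is.na(find_separating_covariate(y, X)))
    stop("perfect separation detected (covariate: ",
         find_separating_covariate(y, X), ")")
  new_model_fit(fit, role, covs, smooth = TRUE,
                basis = sprintf("tp spline, k = %s", paste(k, collapse = ",")))
}

#' McFadden pseudo R-squared
#'
#' `1 - logLik(model)/logLik(null)`: the proportional reduction in deviance
#' relative to the intercept-only model; 0 for the null model itself,
#' approaching 1 for perfect prediction.
#'
#' @param fit a `detection_fit`.
#' @return a proportion in \[0, 1).
#' @export
mcfadden_r2 <- function(fit) {
  stopifnot(fit$null_loglik < 0)
  max(0, 1 - fit$loglik / fit$null_loglik)
}

#' Stepwise model selection for one detection role
#'
#' Stage 1 fits the null model and every univariate GLM, ranking them by
#' AIC (p-value and residual-deviance reduction are reported alongside);
#' covariates with Wald p < `alpha` advance. Stage 2 fits all combinations
#' of advanced covariates. Stage 3 fits the additive (GAM) version of the
#' best linear model and selects it only when it beats that model's AIC by
#' more than 2 points. The final selection is the lowest-AIC model subject
#' to that rule, ties broken toward fewer parameters; if nothing beats the
#' null model on AIC the null model is selected.
#'
#' @param table an `obs_table` (training data).
#' @param role `"detection"`, `"false"` or `"duplicate"`.
#' @param alpha significance threshold for stage-1 advancement.
#' @param basis_size GAM basis size for stage 3.
#' @return object of class `ranking_table`: a list with `ranking` (data
#'   frame sorted by AIC), `selected` (a `detection_fit`) and
#'   `selected_label`.
#' @export
stepwise_select <- function(table, role = c("detection", "false", "duplicate"),
                            alpha = 0.05, basis_size = 10) {
  role <- match.arg(role)
  br <- build_response(table, role)
  fits <- list()
  fits[["null"]] <- fit_logistic(br$y, NULL, role)
  covs <- sort(names(br$X)) # canonical order: selection must not depend on
                            # column order
  for (cv in covs)
    fits[[cv]] <- fit_logistic(br$y, br$X[, cv, drop = FALSE], role)
  uni_p <- vapply(covs, function(cv) unname(fits[[cv]]$p_values[1]), 1)
  advanced <- covs[!is.na(uni_p) & uni_p < alpha]
  if (length(advanced) > 1) {
    for (m in 2:length(advanced)) {
      for (set in utils::combn(advanced, m, simplify = FALSE)) {
        lbl <- paste(set, collapse = "+")
        fits[[lbl]] <- fit_logistic(br$y, br$X[, set, drop = FALSE], role)
      }
    }
  }
  aics <- vapply(fits, function(f) f$aic, 1)
  npar <- vapply(fits, function(f) f$n_par, 1)
  best_lin <- names(fits)[order(aics, npar)][1]
  gam_lbl <- NA_character_
  if (best_lin != "null") {
    set <- strsplit(best_lin, "+", fixed = TRUE)[[1]]
    gam_lbl <- paste0("GAM:", best_lin)
    gfit <- tryCatch(fit_additive(br$y, br$X[, set, drop = FALSE],
                                  basis_size, role), error = function(e) NULL)
    if (!is.null(gfit)) fits[[gam_lbl]] <- gfit else gam_lbl <- NA_character_
  }
  aics <- vapply(fits, function(f) f$aic, 1)
  npar <- vapply(fits, function(f) f$n_par, 1)
  # GAM adopted only under the delta-2 rule
  selected_label <- best_lin
  if (!is.na(gam_lbl) && aics[gam_lbl] < aics[best_lin] - 2)
    selected_label <- gam_lbl
  ranking <- data.frame(
    model = names(fits),
    type = ifelse(grepl("^GAM:", names(fits)), "GAM",
                  ifelse(names(fits) == "null", "null", "GLM")),
    n_par = npar,
    null_deviance = vapply(fits, function(f) f$null_deviance, 1),
    residual_deviance = vapply(fits, function(f) f$residual_deviance, 1),
    deviance_reduction = vapply(fits, function(f)
      f$null_deviance - f$residual_deviance, 1),
    p_value = vapply(fits, function(f)
      if (length(f$p_values)) min(f$p_values) else NA_real_, 1),
    aic = aics, row.names = NULL, stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$aic, ranking$n_par), ]
  rownames(ranking) <- NULL
  ranking$selected <- ranking$model == selected_label
  structure(list(ranking = ranking, selected = fits[[selected_label]],
                 selected_label = selected_label, alpha = alpha,
                 advanced = advanced, role = role),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("Stepwise selection, role = %s (alpha = %g)\n", x$role, x$alpha))
  print(x$ranking[, c("model", "type", "n_par", "residual_deviance",
                      "p_value", "aic", "selected")], digits = 5)
  invisible(x)
}

#' Predict fitted probabilities with 95% limits on the response scale
#'
#' Computes the linear predictor and its standard error for each new row,
#' forms `eta +/- z * SE(eta)` on the link (logit) scale, and maps fitted
#' value and both limits back through the inverse link, guaranteeing limits
#' inside \[0, 1\] and `lower <= fit <= upper`.
#'
#' @param fit a `detection_fit` (GLM or GAM) or a deserialized fit from
#'   [read_fit()].
#' @param newdata data frame covering the fit's covariates.
#' @param z normal quantile for the limits (default 1.96, i.e. 95%).
#' @return data frame with columns `fit`, `lower`, `upper`.
#' @export
predict_with_ci <- function(fit, newdata, z = 1.96) {
  miss <- setdiff(fit$covariate_names, names(newdata))
  if (length(miss))
    stop("covariate missing in newdata: ", paste(miss, collapse = ", "))
  if (!is.null(fit$model)) {
    pr <- stats::predict(fit$model, newdata = newdata, type = "link",
                         se.fit = TRUE)
    eta <- as.numeric(pr$fit); se <- as.numeric(pr$se.fit)
  } else {
    # serialized linear fit: eta = X beta, var = diag(X V X')
    mm <- cbind(`(Intercept)` = 1,
                as.matrix(newdata[, fit$covariate_names, drop = FALSE]))
    eta <- as.numeric(mm %*% fit$coefficients)
    se <- sqrt(rowSums((mm %*% fit$vcov) * mm))
  }
  data.frame(fit = inv_logit(eta),
             lower = inv_logit(eta - z * se),
             upper = inv_logit(eta + z * se))
}

#' Serialize a linear detection fit to a key-value text file
#'
#' Stores role, covariates, coefficients, standard errors, covariance
#' matrix, log-likelihoods and AIC so that [predict_with_ci()] and the
#' abundance estimator can run from the saved fit. Additive (GAM) fits are
#' not serializable to this flat format.
#'
#' @param fit a linear `detection_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  if (isTRUE(fit$smooth))
    stop("additive (GAM) fits cannot be serialized to the key-value format")
  obj <- list(role = fit$role,
              covariates = as.list(fit$covariate_names),
              coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              vcov = lapply(seq_len(nrow(fit$vcov)),
                            function(i) as.numeric(fit$vcov[i, ])),
              loglik = fit$loglik, null_loglik = fit$null_loglik,
              aic = fit$aic, null_deviance = fit$null_deviance,
              residual_deviance = fit$residual_deviance, n = fit$n,
              n_par = fit$n_par)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a serialized detection fit
#'
#' @param path file written by [write_fit()].
#' @return a `detection_fit` usable with [predict_with_ci()] and
#'   [estimate_surveys()] (the underlying `glm` object is not restored).
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stop("fit file not found: ", path)
  obj <- yaml::read_yaml(path)
  cf <- unlist(obj$coefficients)
  vc <- do.call(rbind, obj$vcov)
  dimnames(vc) <- list(names(cf), names(cf))
  structure(list(role = obj$role,
                 covariate_names = as.character(unlist(obj$covariates)),
                 coefficients = cf, se = unlist(obj$se), vcov = vc,
                 loglik = obj$loglik, null_loglik = obj$null_loglik,
                 aic = obj$aic, null_deviance = obj$null_deviance,
                 residual_deviance = obj$residual_deviance,
                 p_values = numeric(0), n = obj$n, n_par = obj$n_par,
                 smooth = FALSE, basis = NULL, model = NULL),
            class = "detection_fit")
}
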