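test_that("build_response encodes each role's observations correctly", {
  tab <- observation_table(make_obs_df(
    klass = c("unique_detection", "missed", "duplicate", "false_positive")))
  det <- build_response(tab, "detection")
  expect_equal(det$y, c(1L, 0L))
  expect_equal(names(det$X), c("temperature", "wind_speed", "dist_edge"))
  fls <- build_response(tab, "false")
  expect_equal(sort(fls$rows$klass),
               c("duplicate", "false_positive", "unique_detection"))
  expect_equal(fls$y[fls$rows$klass == "false_positive"], 1L)
  dup <- build_response(tab, "duplicate")
  expect_equal(dup$y, c(0L, 1L))
  expect_equal(names(dup$X), c("dist_nearest", "time_since_prev"))
  # role-required covariate entirely absent -> error
  broken <- tab
  broken$dist_nearest <- NA_real_
  class(broken) <- class(tab)
  expect_error(build_response(broken, "duplicate"), "dist_nearest")
})

test_that("an intercept-only fit on balanced data gives logit 0.5", {
  fit <- fit_logistic(c(1, 0, 1, 0))
  expect_equal(unname(coef(fit$model)), 0, tolerance = 1e-8)
  expect_equal(mcfadden_r2(fit), 0, tolerance = 1e-10)
})

test_that("fit_logistic matches direct likelihood maximization", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(12:30, 1)
    p_cov <- sample(1:2, 1)
    X <- as.data.frame(matrix(rnorm(n * p_cov), n,
                              dimnames = list(NULL, paste0("x", 1:p_cov))))
    y <- rbinom(n, 1, inv_logit(0.3 + as.matrix(X) %*% rep(0.8, p_cov)))
    fit <- tryCatch(fit_logistic(y, X), error = function(e) NULL)
    if (is.null(fit)) next # separated draw; equivalence needs a valid fit
    oracle <- direct_logistic_mle(y, X)
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-4)
    expect_equal(fit$loglik,
                 -logistic_negloglik(oracle, y, as.matrix(X)),
                 tolerance = 1e-6)
  }
})

test_that("large-sample estimates recover the generating coefficients", {
  set.seed(3)
  n <- 5000
  x <- runif(n, -2, 2)
  y <- rbinom(n, 1, inv_logit(-1 + 0.5 * x))
  fit <- fit_logistic(y, data.frame(x = x))
  expect_lt(abs(fit$coefficients["(Intercept)"] + 1), 3 * fit$se[1])
  expect_lt(abs(fit$coefficients["x"] - 0.5), 3 * fit$se[2])
  # the fitted point beats every point of a grid around truth
  grid <- expand.grid(b0 = seq(-1.2, -0.8, length.out = 21),
                      b1 = seq(0.3, 0.7, length.out = 21))
  grid_ll <- -apply(grid, 1, function(b) logistic_negloglik(b, y, cbind(x)))
  expect_gte(fit$loglik, max(grid_ll))
})

test_that("separation and rank deficiency are errors, not silent fits", {
  y <- c(rep(0, 10), rep(1, 10))
  X <- data.frame(x = c(seq(0, 1, length.out = 10),
                        seq(2, 3, length.out = 10)))
  expect_error(fit_logistic(y, X), "separation.*x")
  set.seed(1)
  X2 <- data.frame(a = rnorm(20))
  X2$b <- 2 * X2$a
  expect_error(fit_logistic(rbinom(20, 1, 0.5), X2), "rank-deficient")
  expect_error(fit_logistic(rep(1, 5)), "success and.*failure")
})

test_that("pseudo R-squared approaches 1 for near-perfect prediction", {
  set.seed(21)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, inv_logit(8 * x)) # steep but not separated
  fit <- tryCatch(fit_logistic(y, data.frame(x = x)),
                  error = function(e) NULL)
  if (!is.null(fit)) expect_gt(mcfadden_r2(fit), 0.5)
  # null fit pins the other end
  expect_equal(mcfadden_r2(fit_logistic(rbinom(50, 1, 0.5))), 0)
})

test_that("response-scale limits follow the closed-form inverse logit", {
  # hand-built fit: eta = 0 with unit variance
  fit <- structure(list(role = "detection", covariate_names = character(0),
                        coefficients = c(`(Intercept)` = 0),
                        vcov = matrix(1, 1, 1), smooth = FALSE,
                        model = NULL),
                   class = "detection_fit")
  pr <- predict_with_ci(fit, data.frame(x = 1), z = 1.96)
  expect_equal(unlist(pr, use.names = FALSE),
               plogis(c(0, -1.96, 1.96)), tolerance = 1e-12)
  # zero SE collapses the limits onto the fit
  fit$vcov <- matrix(0, 1, 1)
  pr0 <- predict_with_ci(fit, data.frame(x = 1))
  expect_equal(pr0$lower, pr0$fit)
  expect_equal(pr0$upper, pr0$fit)
})

test_that("predicted limits are ordered and inside [0,1] for a real fit", {
  sim <- simulate_observations(sim_config(), seed = 19)
  br <- build_response(sim$table, "detection")
  fit <- fit_logistic(br$y, br$X[, c("temperature", "dist_edge")])
  pr <- predict_with_ci(fit, br$X)
  expect_true(all(pr$lower >= 0 & pr$upper <= 1))
  expect_true(all(pr$lower <= pr$fit & pr$fit <= pr$upper))
  expect_error(predict_with_ci(fit, data.frame(temperature = 1)),
               "dist_edge")
})

test_that("an additive fit of a linear signal stays near the GLM's AIC", {
  # GCV occasionally undersmooths a binary fit, so characterize the typical
  # behaviour over several datasets rather than a single draw
  n <- 500
  within2 <- sapply(1:6, function(s) {
    set.seed(s)
    x <- runif(n, 0, 10)
    y <- rbinom(n, 1, inv_logit(-1 + 0.3 * x))
    lin <- fit_logistic(y, data.frame(x = x))
    add <- suppressWarnings(fit_additive(y, data.frame(x = x)))
    abs(add$aic - lin$aic) < 2
  })
  expect_gte(sum(within2), 5)
  expect_error(fit_additive(rbinom(20, 1, 0.5),
                            data.frame(x = rnorm(20)), basis_size = 2),
               ">= 3")
})

test_that("stepwise selection keeps the null model under pure noise", {
  set.seed(101)
  n <- 400
  df <- make_obs_df(klass = sample(c("unique_detection", "missed"), n,
                                   replace = TRUE))
  df$object_id <- paste0("o", 1:n)
  df$temperature <- runif(n, 5, 25)
  df$wind_speed <- runif(n, 0, 20)
  df$dist_edge <- runif(n, 0, 200)
  df$dist_nearest <- ifelse(df$klass == "missed", NA, runif(n, 5, 100))
  df$time_since_prev <- ifelse(df$klass == "missed", NA, runif(n, 10, 500))
  tab <- observation_table(df)
  sel <- stepwise_select(tab, "detection")
  expect_equal(sel$selected_label, "null")
  expect_equal(sel$ranking$aic, sort(sel$ranking$aic))
})

test_that("stepwise selection recovers the generating structure", {
  sim <- simulate_observations(sim_config(), seed = 55)
  sel_p <- stepwise_select(sim$table, "detection")
  expect_true(all(c("temperature", "dist_edge") %in% sel_p$advanced))
  sel_f <- stepwise_select(sim$table, "false")
  expect_true("dist_edge" %in% sel_f$advanced)
  sel_d <- stepwise_select(sim$table, "duplicate")
  expect_true(grepl("dist_nearest", sel_d$selected_label))
})

test_that("stepwise selection is invariant to covariate column order", {
  sim <- simulate_observations(quick_config(), seed = 71)
  tab <- sim$table
  perm <- tab[, c("object_id", "survey_id", "site", "date", "klass",
                  "dist_edge", "wind_speed", "temperature", "dist_nearest",
                  "time_since_prev", "perp_distance", "lon", "lat")]
  class(perm) <- class(tab)
  a <- stepwise_select(tab, "detection")
  b <- stepwise_select(perm, "detection")
  expect_equal(a$selected_label, b$selected_label)
  expect_equal(a$selected$aic, b$selected$aic)
})

test_that("Wald intervals for the slopes attain near-nominal coverage", {
  set.seed(202)
  hits <- 0L
  runs <- 200L
  for (r in seq_len(runs)) {
    x <- runif(300, 0, 200)
    y <- rbinom(300, 1, inv_logit(1 - 0.02 * x))
    fit <- fit_logistic(y, data.frame(x = x))
    ci <- fit$coefficients["x"] + c(-1.96, 1.96) * fit$se["x"]
    if (ci[1] <= -0.02 && -0.02 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / runs, 0.90)
})

test_that("serialized linear fits reproduce predictions exactly", {
  sim <- simulate_observations(quick_config(), seed = 12)
  br <- build_response(sim$table, "false")
  fit <- fit_logistic(br$y, br$X[, "dist_edge", drop = FALSE], role = "false")
  path <- withr::local_tempfile(fileext = ".yml")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-10)
  nd <- data.frame(dist_edge = c(0, 50, 180))
  expect_equal(predict_with_ci(back, nd), predict_with_ci(fit, nd),
               tolerance = 1e-7)
  gam_fit <- fit_additive(br$y, br$X[, "dist_edge", drop = FALSE])
  expect_error(write_fit(gam_fit, path), "cannot be serialized")
})
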