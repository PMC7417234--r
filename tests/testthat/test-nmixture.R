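edges5 <- c(0, 15, 30, 45, 60, 75)

test_that("distance cell probabilities follow the key functions", {
  expect_equal(distance_cell_probabilities("uniform", bin_edges = edges5),
               rep(0.2, 5))
  # sigma -> Inf approaches the uniform vector
  expect_equal(distance_cell_probabilities("halfnormal", 1e7, edges5),
               rep(0.2, 5), tolerance = 1e-8)
  # quadrature oracle: fine midpoint rule on the half-normal
  sigma <- 30
  xs <- seq(0.0005, 15 - 0.0005, by = 0.001)
  quad <- sum(exp(-xs^2 / (2 * sigma^2))) * 0.001 / 75
  pi1 <- distance_cell_probabilities("halfnormal", sigma, edges5)[1]
  expect_equal(pi1, quad, tolerance = 1e-6)
  expect_error(distance_cell_probabilities("halfnormal", NULL, edges5),
               "sigma")
})

test_that("the marginal likelihood equals exhaustive latent enumeration", {
  set.seed(61)
  for (i in 1:12) {
    Tn <- sample(1:2, 1); V <- sample(1:2, 1); K <- 6
    nb <- sample(2:3, 1)
    edges <- c(0, sort(runif(nb - 1, 10, 70)), 75)
    y <- array(rpois(Tn * V * nb, 0.7), dim = c(Tn, V, nb))
    y[y > 2] <- 2 # keep within the K = 6 envelope
    tc <- transect_counts(y, edges)
    keyfun <- sample(c("uniform", "halfnormal"), 1)
    disp <- sample(c(TRUE, FALSE), 1)
    spec <- nmixture_spec(keyfun, dispersion = disp)
    lambda <- runif(1, 0.5, 2.5)
    phi <- runif(1, 0.3, 0.9)
    sigma <- runif(1, 20, 60)
    alpha <- if (disp) runif(1, 1, 6) else Inf
    params <- c(log(lambda), logit(phi),
                if (keyfun == "halfnormal") log(sigma),
                if (disp) log(alpha))
    pi <- distance_cell_probabilities(keyfun, sigma, edges)
    expect_equal(
      nmixture_loglik(params, tc, spec, K),
      brute_nmix_loglik(y, edges, rep(lambda, Tn), rep(phi, V), pi, alpha, K),
      tolerance = 1e-8)
  }
})

test_that("likelihood limiting cases behave", {
  y0 <- array(0L, dim = c(2, 2, 5))
  tc <- transect_counts(y0, edges5)
  spec <- nmixture_spec("uniform", dispersion = FALSE)
  # no animals, vanishing abundance: probability 1
  expect_equal(nmixture_loglik(c(log(1e-9), logit(0.5)), tc, spec, 10), 0,
               tolerance = 1e-6)
  expect_error(nmixture_loglik(c(NA, 0), tc, spec, 10), "non-finite")
  y <- array(rpois(20, 2), dim = c(2, 2, 5))
  tc2 <- transect_counts(y, edges5)
  expect_error(nmixture_loglik(c(log(2), 0), tc2, spec,
                               K = max(apply(y, c(1, 2), sum)) - 1),
               "K must be")
  # exchangeability over transects
  perm <- transect_counts(y[2:1, , , drop = FALSE], edges5)
  p <- c(log(2), logit(0.6))
  expect_equal(nmixture_loglik(p, tc2, spec, 50),
               nmixture_loglik(p, perm, spec, 50))
})

test_that("doubling K beyond the default leaves the likelihood unchanged", {
  sim <- simulate_transect_counts(sim_config(), seed = 41)
  spec <- nmixture_spec("halfnormal")
  fit <- fit_nmixture(sim$counts, spec)
  ll2 <- nmixture_loglik(fit$params, sim$counts, spec, K = 2 * fit$K)
  expect_lt(abs(ll2 - fit$loglik), 1e-6)
})

test_that("fitting recovers generating parameters on a large design", {
  cfg <- sim_config(n_transects = 200, n_visits = 4,
                    lambda_coefs = c(intercept = log(3)),
                    phi_coefs = c(intercept = logit(0.6)),
                    keyfun = "halfnormal", sigma = 40, nb_dispersion = 5)
  sim <- simulate_transect_counts(cfg, seed = 99)
  fit <- fit_nmixture(sim$counts, nmixture_spec("halfnormal"))
  expect_true(fit$se_available)
  truth <- c(log(3), logit(0.6), log(40), log(5))
  for (k in seq_along(truth))
    expect_lt(abs(fit$params[k] - truth[k]), 3 * fit$estimates$se[k])
  # fitted totals track the realized latent population
  expect_lt(abs(total_abundance(fit, round = FALSE) - sum(sim$truth$M)) /
              sum(sim$truth$M), 0.25)
})

test_that("a useless abundance covariate costs about two AIC points", {
  cfg <- sim_config(n_transects = 150, n_visits = 4,
                    lambda_coefs = c(intercept = log(3)),
                    keyfun = "uniform", nb_dispersion = Inf)
  sim <- simulate_transect_counts(cfg, seed = 7)
  f0 <- fit_nmixture(sim$counts, nmixture_spec("uniform", dispersion = FALSE))
  f1 <- fit_nmixture(sim$counts,
                     nmixture_spec("uniform", lambda_covs = "grass",
                                   dispersion = FALSE))
  expect_lt(abs((f1$aic - f0$aic) - 2), 2.5)
})

test_that("model ranking prefers the generating structure", {
  # single candidate is trivially selected
  sim <- simulate_transect_counts(sim_config(), seed = 13)
  only <- rank_nmixture_models(sim$counts,
                               list(nmixture_spec("uniform")))
  expect_equal(nrow(only$ranking), 1)
  expect_equal(only$selected$spec$label, only$ranking$model[1])
  # a real grass effect is picked up over the null
  cfg <- sim_config(n_transects = 60, n_visits = 4,
                    lambda_coefs = c(intercept = log(8), grass = -0.06),
                    keyfun = "uniform", nb_dispersion = Inf)
  simg <- simulate_transect_counts(cfg, seed = 29)
  rk <- rank_nmixture_models(simg$counts, list(
    nmixture_spec("uniform", dispersion = FALSE, label = "null"),
    nmixture_spec("uniform", lambda_covs = "grass", dispersion = FALSE,
                  label = "grass")))
  expect_equal(rk$ranking$model[1], "grass")
  expect_equal(rk$ranking$aic, sort(rk$ranking$aic))
})

test_that("total abundance sums fitted expected abundance", {
  mock <- structure(list(lambda_hat = rep(3, 9)), class = "nmixture_fit")
  expect_equal(total_abundance(mock), 27)
})

test_that("a perfectly fitting model gives T = 0 and p = 1", {
  counts <- array(1L, dim = c(2, 3, 5))
  tc <- transect_counts(counts, edges5)
  mock <- structure(list(
    lambda_hat = rep(5, 2), phi_hat = rep(1, 3),
    pi = matrix(0.2, 2, 5), alpha_hat = Inf, data = tc,
    spec = nmixture_spec("uniform", dispersion = FALSE)),
    class = "nmixture_fit")
  gof <- freeman_tukey_gof(mock, n_sim = 30, seed = 5)
  expect_equal(gof$statistic, 0)
  expect_equal(gof$p_value, 1)
  expect_error(freeman_tukey_gof(mock, n_sim = 0), "n_sim")
})

test_that("the bootstrap p-value is unexceptional under the fitted model", {
  sim <- simulate_transect_counts(sim_config(), seed = 3)
  fit <- fit_nmixture(sim$counts, nmixture_spec("halfnormal"))
  gof <- freeman_tukey_gof(fit, n_sim = 200, seed = 11)
  expect_gte(gof$p_value, 0.01)
  expect_lte(gof$p_value, 0.99)
  # seeded determinism
  gof2 <- freeman_tukey_gof(fit, n_sim = 200, seed = 11)
  expect_identical(gof$t_star, gof2$t_star)
})
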