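# Independent oracles and small fixture builders shared across tests.

# A minimal valid observation data frame, one row per fate by default.
make_obs_df <- function(klass = c("unique_detection", "duplicate",
                                  "false_positive", "missed"),
                        site = "north", date = "2018-02-01") {
  n <- length(klass)
  missed <- klass == "missed"
  data.frame(
    object_id = paste0("obj", seq_len(n)),
    site = site, date = date, klass = klass,
    temperature = seq(10, 20, length.out = n),
    wind_speed = seq(2, 8, length.out = n),
    dist_edge = seq(20, 120, length.out = n),
    dist_nearest = ifelse(missed, NA, 25 + 5 * seq_len(n)),
    time_since_prev = ifelse(missed, NA, 40 * seq_len(n)),
    perp_distance = seq(5, 70, length.out = n),
    stringsAsFactors = FALSE)
}

# Bernoulli log-likelihood written out directly; used to maximize the
# likelihood numerically, independent of glm's IRLS path.
logistic_negloglik <- function(beta, y, X) {
  eta <- as.numeric(cbind(1, X) %*% beta)
  -sum(y * eta - log(1 + exp(eta)))
}

direct_logistic_mle <- function(y, X) {
  X <- as.matrix(X)
  opt <- stats::optim(rep(0, ncol(X) + 1), logistic_negloglik, y = y, X = X,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

# Exhaustive latent-variable enumeration of the generalized N-mixture
# likelihood in linear space: joint sum over M and per-visit N using
# dmultinom with an explicit remainder cell.
brute_nmix_loglik <- function(counts, bin_edges, lambda, phi, pi, alpha, K) {
  Tn <- dim(counts)[1]; V <- dim(counts)[2]
  ll <- 0
  for (t in seq_len(Tn)) {
    Lt <- 0
    for (M in 0:K) {
      fM <- if (is.finite(alpha)) dnbinom(M, mu = lambda[t], size = alpha)
            else dpois(M, lambda[t])
      pr <- 1
      for (v in seq_len(V)) {
        yv <- counts[t, v, ]
        s <- 0
        if (M >= sum(yv)) {
          for (N in sum(yv):M) {
            s <- s + dbinom(N, M, phi[v]) *
              dmultinom(c(yv, N - sum(yv)), prob = c(pi, 1 - sum(pi)))
          }
        }
        pr <- pr * s
      }
      Lt <- Lt + fM * pr
    }
    ll <- ll + log(Lt)
  }
  ll
}

# Quick constant-probability prediction table for estimator tests.
const_pred <- function(n, fit, lower = fit, upper = fit) {
  data.frame(fit = rep(fit, n), lower = rep(lower, n), upper = rep(upper, n))
}

# Small simulation config used where speed matters more than realism.
quick_config <- function(...) {
  args <- list(surveys_per_site = c(2, 2), true_N_per_survey = 15,
               f_rate = 8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
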