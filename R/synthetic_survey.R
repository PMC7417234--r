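#' Configuration for the synthetic survey generator
#'
#' Bundles every generating parameter for the two synthetic data products:
#' per-object observation tables (detections, duplicates, false positives,
#' misses, with covariates) and distance-binned repeated transect counts.
#' Defaults emulate a small two-site drone thermal-imaging campaign: 11
#' surveys across two sites producing roughly 250 observation rows over the
#' training dates, and a 9-transect, 5-visit count design with five 15-m
#' distance bins out to a 75-m strip half-width.
#'
#' Detection, false-detection and duplicate-detection are Bernoulli processes
#' on the logit scale: detection depends on ambient temperature and distance
#' to habitat edge (animals deep in the forest core and in warm conditions
#' are harder to see in thermal imagery); false positives are placed
#' preferentially near habitat edges; duplicates arise from field-of-view
#' overlap, so their probability decays with distance to the nearest other
#' detection.
#'
#' @param n_sites number of survey sites.
#' @param surveys_per_site integer vector (recycled) of surveys per site.
#' @param n_transects transects for the repeated-count design.
#' @param n_visits visits per transect.
#' @param strip_halfwidth strip half-width W in metres.
#' @param bin_edges distance bin edges (metres), starting at 0, ending at W.
#' @param true_N_per_survey true animals present per survey: a scalar/vector
#'   of integers, or `list(mean =, dispersion =)` for a negative-binomial
#'   draw.
#' @param p_coefs logit-scale detection coefficients, named
#'   `(intercept, temperature, dist_edge)`.
#' @param f_rate expected false positives per survey (Poisson mean).
#' @param f_coefs logit-scale false-profile coefficients
#'   `(intercept, dist_edge)` governing where false positives sit relative to
#'   the habitat edge.
#' @param d_coefs logit-scale duplicate coefficients
#'   `(intercept, dist_nearest)`.
#' @param covariate_dists list of ranges for `temperature` (deg C),
#'   `wind_speed` (km/h) and `dist_edge` (m).
#' @param dup_jitter max positional jitter (m) for a duplicate relative to
#'   its parent detection.
#' @param site_dim site extent (m), used for positions and nearest-neighbour
#'   distances.
#' @param lambda_coefs log-scale abundance coefficients for the count design:
#'   `intercept` plus optional named slopes over transect covariates
#'   (`forest`, `grass`, `road`, `water`).
#' @param phi_coefs logit-scale availability coefficients: `intercept` plus
#'   optional named slopes over visit covariates (`temperature`,
#'   `wind_speed`).
#' @param keyfun distance key function, `"uniform"` or `"halfnormal"`.
#' @param sigma half-normal scale (m); ignored for the uniform key.
#' @param nb_dispersion negative-binomial dispersion alpha for latent
#'   abundance (variance lambda + lambda^2/alpha); `Inf` gives Poisson.
#' @param seed default RNG seed used by the simulators.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2,
                       surveys_per_site = c(5, 6),
                       n_transects = 9,
                       n_visits = 5,
                       strip_halfwidth = 75,
                       bin_edges = c(0, 15, 30, 45, 60, 75),
                       true_N_per_survey = 18,
                       p_coefs = c(intercept = 7.0, temperature = -0.188,
                                   dist_edge = -0.0233),
                       f_rate = 11,
                       f_coefs = c(intercept = 0, dist_edge = -0.0324),
                       d_coefs = c(intercept = -0.15, dist_nearest = -0.0228),
                       covariate_dists = list(temperature = c(5, 25),
                                              wind_speed = c(0, 20),
                                              dist_edge = c(0, 200)),
                       dup_jitter = 30,
                       site_dim = c(500, 300),
                       lambda_coefs = c(intercept = log(4)),
                       phi_coefs = c(intercept = logit(0.7)),
                       keyfun = c("halfnormal", "uniform"),
                       sigma = 40,
                       nb_dispersion = 5,
                       seed = 1L) {
  keyfun <- match.arg(keyfun)
  cfg <- list(n_sites = n_sites, surveys_per_site = surveys_per_site,
              n_transects = n_transects, n_visits = n_visits,
              strip_halfwidth = strip_halfwidth, bin_edges = bin_edges,
              true_N_per_survey = true_N_per_survey, p_coefs = p_coefs,
              f_rate = f_rate, f_coefs = f_coefs, d_coefs = d_coefs,
              covariate_dists = covariate_dists, dup_jitter = dup_jitter,
              site_dim = site_dim, lambda_coefs = lambda_coefs,
              phi_coefs = phi_coefs, keyfun = keyfun, sigma = sigma,
              nb_dispersion = nb_dispersion, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_sites >= 1, all(cfg$surveys_per_site >= 1),
            cfg$n_transects >= 1, cfg$n_visits >= 1,
            cfg$strip_halfwidth > 0, cfg$f_rate >= 0,
            max(cfg$bin_edges) == cfg$strip_halfwidth)
  if (any(is.nan(c(cfg$p_coefs, cfg$f_coefs, cfg$d_coefs))))
    stop("non-finite (NaN) coefficients in config")
  # detection probability must not be 0 everywhere over the covariate box
  corners <- expand.grid(temperature = cfg$covariate_dists$temperature,
                         dist_edge = cfg$covariate_dists$dist_edge)
  p <- inv_logit(cfg$p_coefs[1] + cfg$p_coefs[2] * corners$temperature +
                   cfg$p_coefs[3] * corners$dist_edge)
  if (all(p <= 1e-12))
    stop("degenerate config: detection probability is 0 over the whole covariate range")
  invisible(cfg)
}

# Draw the true number of animals present for one survey.
draw_true_N <- function(spec, k) {
  if (is.list(spec)) {
    if (is.finite(spec$dispersion))
      stats::rnbinom(1, mu = spec$mean, size = spec$dispersion)
    else stats::rpois(1, spec$mean)
  } else {
    n <- rep_len(spec, k)[k]
    as.integer(n)
  }
}

# Nearest-neighbour distance for each row of an n x 2 position matrix.
# Singletons get the site diagonal (no neighbour closer than the site).
nearest_dist <- function(pos, site_dim) {
  n <- nrow(pos)
  if (n <= 1) return(rep(sqrt(sum(site_dim^2)), n))
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  apply(d, 1, min)
}

# Rejection-sample m dist_edge values with density proportional to
# inv_logit(f0 + f1 * e) on [range].
sample_false_edges <- function(m, f_coefs, range) {
  if (m == 0) return(numeric(0))
  wfun <- function(e) inv_logit(f_coefs[1] + f_coefs[2] * e)
  wmax <- max(wfun(range))
  if (wmax <= 0) return(stats::runif(m, range[1], range[2]))
  out <- numeric(0)
  for (it in 1:200) {
    prop <- stats::runif(2 * m + 10, range[1], range[2])
    acc <- prop[stats::runif(length(prop)) < wfun(prop) / wmax]
    out <- c(out, acc)
    if (length(out) >= m) return(out[seq_len(m)])
  }
  out[seq_len(min(m, length(out)))]
}

#' Simulate an observation table with known truth
#'
#' Generates, survey by survey: true animals placed uniformly in the site;
#' each animal detected with probability `inv_logit(p_coefs %*% (1, temp,
#' dist_edge))`; a Poisson number of false positives with habitat-edge-biased
#' placement; and, for each detected animal, a possible duplicate record
#' (field-of-view overlap) with probability `inv_logit(d_coefs %*% (1,
#' dist_nearest))`, its position jittered locally. `dist_nearest` and
#' detection times are recomputed post hoc over all detected objects in the
#' survey (true, false and duplicate), mirroring how they would be derived
#' from real detector output. Missed animals are recorded with fate
#' `missed`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`. Identical seeds give
#'   identical output.
#' @return list with `table` (a validated `obs_table`) and `truth` (list with
#'   per-survey data frame `per_survey` and the generating coefficients).
#' @export
simulate_observations <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  cd <- config$covariate_dists
  W <- config$strip_halfwidth
  sites <- if (config$n_sites == 2) c("north", "south") else
    paste0("site", seq_len(config$n_sites))
  nsurv <- rep_len(config$surveys_per_site, config$n_sites)
  all_rows <- list()
  truth_rows <- list()
  surv_k <- 0L
  for (s in seq_along(sites)) {
    dates <- seq(as.Date("2018-02-01"), by = "3 weeks",
                 length.out = nsurv[s]) + (s - 1L) * 7L
    for (v in seq_len(nsurv[s])) {
      surv_k <- surv_k + 1L
      site <- sites[s]
      date <- dates[v]
      sid <- paste(site, date, sep = "_")
      temp <- stats::runif(1, cd$temperature[1], cd$temperature[2])
      wind <- stats::runif(1, cd$wind_speed[1], cd$wind_speed[2])
      N <- draw_true_N(config$true_N_per_survey, surv_k)
      pos <- cbind(stats::runif(N, 0, config$site_dim[1]),
                   stats::runif(N, 0, config$site_dim[2]))
      edge <- stats::runif(N, cd$dist_edge[1], cd$dist_edge[2])
      perp <- stats::runif(N, 0, W)
      p <- inv_logit(config$p_coefs[1] + config$p_coefs[2] * temp +
                       config$p_coefs[3] * edge)
      det <- stats::rbinom(N, 1, p) == 1
      nF <- stats::rpois(1, config$f_rate)
      f_pos <- cbind(stats::runif(nF, 0, config$site_dim[1]),
                     stats::runif(nF, 0, config$site_dim[2]))
      f_edge <- sample_false_edges(nF, config$f_coefs, cd$dist_edge)
      nF <- length(f_edge)
      f_pos <- f_pos[seq_len(nF), , drop = FALSE]
      f_perp <- stats::runif(nF, 0, W)

      # provisional nearest-neighbour distances drive duplicate spawning
      det_pos <- rbind(pos[det, , drop = FALSE], f_pos)
      nn_prov <- nearest_dist(det_pos, config$site_dim)
      nn_animals <- nn_prov[seq_len(sum(det))]
      d_prob <- inv_logit(config$d_coefs[1] + config$d_coefs[2] * nn_animals)
      d_prob[is.na(d_prob)] <- 0
      spawn <- stats::rbinom(sum(det), 1, d_prob) == 1
      parent_idx <- which(det)[spawn]
      nD <- length(parent_idx)
      jit <- function(x, lo, hi) pmin(pmax(x + stats::runif(length(x),
        -config$dup_jitter, config$dup_jitter), lo), hi)
      dup_pos <- cbind(jit(pos[parent_idx, 1], 0, config$site_dim[1]),
                       jit(pos[parent_idx, 2], 0, config$site_dim[2]))
      dup_perp <- pmin(pmax(perp[parent_idx] +
        stats::runif(nD, -config$dup_jitter, config$dup_jitter), 0),
        W - 1e-9)

      klass <- c(rep("unique_detection", sum(det)),
                 rep("false_positive", nF),
                 rep("duplicate", nD),
                 rep("missed", sum(!det)))
      obj_pos <- rbind(pos[det, , drop = FALSE], f_pos, dup_pos,
                       pos[!det, , drop = FALSE])
      obj_edge <- c(edge[det], f_edge, edge[parent_idx], edge[!det])
      obj_perp <- c(perp[det], f_perp, dup_perp, perp[!det])
      n_obj <- length(klass)
      detected <- klass != "missed"

      # final nearest-neighbour distances and detection times over every
      # detected object, in flight order along the long site axis
      nn <- rep(NA_real_, n_obj)
      nn[detected] <- nearest_dist(obj_pos[detected, , drop = FALSE],
                                   config$site_dim)
      tsp <- rep(NA_real_, n_obj)
      if (any(detected)) {
        ord <- order(obj_pos[detected, 1])
        times <- sort(stats::runif(sum(detected), 0, 3600))
        t_obj <- numeric(sum(detected))
        t_obj[ord] <- times
        prev <- c(0, times[-length(times)])
        gaps <- numeric(sum(detected))
        gaps[ord] <- times - prev
        tsp[detected] <- gaps
      }
      df <- data.frame(
        object_id = sprintf("%s_obj%03d", sid, seq_len(n_obj)),
        site = site, date = as.character(date), klass = klass,
        temperature = temp, wind_speed = wind, dist_edge = obj_edge,
        dist_nearest = nn, time_since_prev = tsp, perp_distance = obj_perp,
        lon = obj_pos[, 1], lat = obj_pos[, 2],
        stringsAsFactors = FALSE)
      all_rows[[sid]] <- df
      truth_rows[[sid]] <- data.frame(
        survey_id = sid, site = site, date = as.character(date),
        true_N = N, n_unique = sum(det), n_missed = sum(!det),
        n_false = nF, n_duplicate = nD, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, c(all_rows, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  list(table = observation_table(tab, provenance = "simulated",
                                 strip_halfwidth = W),
       truth = list(per_survey = truth,
                    coefs = config[c("p_coefs", "f_coefs", "d_coefs",
                                     "f_rate", "true_N_per_survey")]))
}

# Linear predictor from a named coefficient vector ("intercept" + slopes
# matching columns of covs).
named_linpred <- function(coefs, covs) {
  eta <- rep(unname(coefs["intercept"]), nrow(covs))
  for (nm in setdiff(names(coefs), "intercept")) {
    if (!nm %in% names(covs))
      stop("coefficient names a covariate not present: ", nm)
    eta <- eta + coefs[[nm]] * covs[[nm]]
  }
  eta
}

#' Simulate distance-binned repeated transect counts with known truth
#'
#' The generating process is the generalized N-mixture model itself: latent
#' abundance `M_t ~ NB(lambda_t, alpha)` with
#' `log lambda_t = lambda_coefs %*% transect covariates`; available animals
#' `N_tv ~ Binomial(M_t, phi_v)` with availability on the logit scale of the
#' visit covariates; each available animal assigned a uniform perpendicular
#' distance on `[0, W)` and detected with the key-function probability at
#' that distance; detected animals tallied into the distance bins.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with `counts` (a `transect_counts`) and `truth` (latent
#'   abundances `M`, availability `phi`, and generating parameters).
#' @export
simulate_transect_counts <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  Tn <- config$n_transects
  V <- config$n_visits
  W <- config$strip_halfwidth
  edges <- config$bin_edges
  nb <- length(edges) - 1L
  cd <- config$covariate_dists
  transect_covs <- data.frame(forest = stats::runif(Tn, 40, 90),
                              grass = stats::runif(Tn, 5, 40),
                              road = stats::runif(Tn, 0, 15),
                              water = stats::runif(Tn, 0, 10))
  visit_covs <- data.frame(
    temperature = stats::runif(V, cd$temperature[1], cd$temperature[2]),
    wind_speed = stats::runif(V, cd$wind_speed[1], cd$wind_speed[2]))
  lambda <- exp(named_linpred(config$lambda_coefs, transect_covs))
  phi <- inv_logit(named_linpred(config$phi_coefs, visit_covs))
  alpha <- config$nb_dispersion
  M <- if (is.finite(alpha)) stats::rnbinom(Tn, mu = lambda, size = alpha)
       else stats::rpois(Tn, lambda)
  gfun <- if (config$keyfun == "uniform") function(x) rep(1, length(x))
          else function(x) exp(-x^2 / (2 * config$sigma^2))
  counts <- array(0L, dim = c(Tn, V, nb))
  for (t in seq_len(Tn)) {
    for (v in seq_len(V)) {
      Nav <- stats::rbinom(1, M[t], phi[v])
      if (Nav == 0) next
      x <- stats::runif(Nav, 0, W)
      det <- stats::rbinom(Nav, 1, gfun(x)) == 1
      if (!any(det)) next
      idx <- findInterval(x[det], edges, rightmost.closed = TRUE)
      counts[t, v, ] <- counts[t, v, ] +
        tabulate(idx, nbins = nb)
    }
  }
  tc <- transect_counts(counts, edges, transect_covs, visit_covs,
                        site = "north")
  list(counts = tc,
       truth = list(M = M, lambda = lambda, phi = phi,
                    params = config[c("lambda_coefs", "phi_coefs", "keyfun",
                                      "sigma", "nb_dispersion")]))
}
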