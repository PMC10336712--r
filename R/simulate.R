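#' Configuration for the synthetic trial-effect generator
#'
#' Describes the generative model used to simulate historical-trial tables:
#' disease-area mean effects are exchangeable, `mu_A ~ N(M, eta^2)`;
#' between-study variances are exchangeable, `tau2_A ~ pi(kappa, nu)` for
#' one of three families; study effects are `theta_i ~ N(mu_A + B*X_i,
#' tau2_A)` and observed estimates `y_i ~ N(theta_i, se_i^2)` with known
#' standard errors drawn log-uniformly.
#'
#' @param M_true Overall mean effect across disease areas (log scale).
#' @param eta_true Between-area standard deviation (>= 0).
#' @param variance_family One of `"lognormal"` (log tau2 ~ N(kappa, nu^2)),
#'   `"gamma"` (tau2 ~ Gamma(shape = kappa, scale = nu)) or `"halfnormal"`
#'   (tau2 ~ N(kappa, nu^2) truncated to non-negative values).
#' @param family_params Numeric length-2 vector `c(kappa, nu)`.
#' @param B_true Comparison-type covariate coefficient (added to the mean
#'   for active-vs-active records, X = 1).
#' @param area_sizes Named (or unnamed) positive integer vector of record
#'   counts per disease area; unnamed areas are labelled `area_01`, ...
#' @param prop_active Per-area probability that a record is
#'   active-vs-active; recycled to the number of areas.
#' @param se_range Range of the log-uniform law for the known standard
#'   errors `se_i` (drawn independently of the effects).
#' @param seed Integer seed; the single seed fans out to per-area
#'   substreams so each area's records are reproducible on their own.
#' @return A `generator_config` list.
#' @export
generator_config <- function(M_true = -0.1, eta_true = 0.2,
                             variance_family = c("gamma", "lognormal", "halfnormal"),
                             family_params = c(2, 0.05),
                             B_true = 0,
                             area_sizes = rep(30L, 9L),
                             prop_active = 0.5,
                             se_range = c(0.05, 0.5),
                             seed = 1L) {
  variance_family <- match.arg(variance_family)
  stopifnot(is.numeric(family_params), length(family_params) == 2L,
            eta_true >= 0, all(area_sizes >= 1L),
            all(prop_active >= 0 & prop_active <= 1),
            length(se_range) == 2L, se_range[1] > 0,
            se_range[2] >= se_range[1])
  area_sizes <- stats::setNames(as.integer(area_sizes), names(area_sizes))
  if (is.null(names(area_sizes)))
    names(area_sizes) <- sprintf("area_%02d", seq_along(area_sizes))
  structure(list(M_true = M_true, eta_true = eta_true,
                 variance_family = variance_family,
                 family_params = as.numeric(family_params),
                 B_true = B_true, area_sizes = area_sizes,
                 prop_active = rep_len(prop_active, length(area_sizes)),
                 se_range = as.numeric(se_range),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# One draw of tau2 per area from the chosen family; the half-normal and
# gamma families have non-negative support by construction, no silent
# clamping is ever applied.
draw_tau2 <- function(n, family, kappa, nu) {
  switch(family,
    lognormal = exp(stats::rnorm(n, kappa, nu)),
    gamma = if (kappa == 0 || nu == 0) rep(0, n)
            else stats::rgamma(n, shape = kappa, scale = nu),
    halfnormal = rtruncnorm0(n, kappa, nu),
    stop("unknown variance family: ", family))
}

# Normal(mean, sd) truncated to [0, Inf) by inverse-CDF sampling.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  p0 <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate a historical-trial table from the hierarchical model
#'
#' Draws per-area means and between-study variances from the hyper-model in
#' `config`, then per-record true effects and observed estimates, and
#' returns the dataset together with the latent truth (for
#' parameter-recovery studies).
#'
#' @param config A [generator_config()].
#' @return List with `data` (a [trial_dataset()]) and `truth` (list of
#'   `M`, `eta`, `kappa`, `nu`, `B`, per-area `mu`, `tau2`, and per-record
#'   `theta`).
#' @export
simulate_trial_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_area <- length(config$area_sizes)
  set.seed(config$seed)
  # area-level draws plus per-area substream seeds from the root seed
  area_seeds <- sample.int(.Machine$integer.max - 1L, n_area)
  mu <- stats::rnorm(n_area, config$M_true, config$eta_true)
  tau2 <- draw_tau2(n_area, config$variance_family,
                    config$family_params[1], config$family_params[2])
  recs <- vector("list", n_area)
  theta_all <- vector("list", n_area)
  for (a in seq_len(n_area)) {
    set.seed(area_seeds[a])
    n_a <- config$area_sizes[a]
    x <- stats::rbinom(n_a, 1L, config$prop_active[a])
    se <- exp(stats::runif(n_a, log(config$se_range[1]), log(config$se_range[2])))
    theta <- stats::rnorm(n_a, mu[a] + config$B_true * x, sqrt(tau2[a]))
    y <- stats::rnorm(n_a, theta, se)
    recs[[a]] <- data.frame(
      study_id = sprintf("%s_%04d", names(config$area_sizes)[a], seq_len(n_a)),
      y = y, se = se,
      disease_area = names(config$area_sizes)[a],
      comparison_type = ifelse(x == 1L, "active_vs_active", "active_vs_inactive"),
      outcome_type = NA_character_, year = NA_integer_,
      stringsAsFactors = FALSE)
    theta_all[[a]] <- theta
  }
  data <- trial_dataset(do.call(rbind, recs))
  truth <- list(M = config$M_true, eta = config$eta_true,
                kappa = config$family_params[1], nu = config$family_params[2],
                B = config$B_true,
                mu = stats::setNames(mu, names(config$area_sizes)),
                tau2 = stats::setNames(tau2, names(config$area_sizes)),
                theta = unlist(theta_all, use.names = FALSE))
  list(data = data, truth = truth)
}

#' Named fixture suite for testing the pipeline
#'
#' Generates a reproducible collection of (config, dataset) pairs covering
#' the shapes the downstream stages must handle: a composition like the
#' motivating dataset (nine areas, one dominant area holding roughly 87%
#' of records, two comparator types), a balanced small fixture, and a
#' single-area fixture.
#'
#' @param root_seed Integer seed controlling the whole suite.
#' @return Named list; each element has `config`, `data` and `truth`.
#' @export
make_fixture_suite <- function(root_seed = 1L) {
  # 725 of 828 records in the dominant area ~ 87.6%; scaled by 1/5 while
  # keeping the dominant-area share (145/166 = 87.3%)
  table1_sizes <- c(oncology = 145L, circulatory = 4L, digestive = 1L,
                    musculoskeletal = 2L, nervous = 4L, health_services = 2L,
                    injury = 1L, mental_health = 3L, obstetrics = 3L)
  suite <- list(
    table1_shape = generator_config(M_true = -0.1, eta_true = 0.2,
                                    variance_family = "gamma",
                                    family_params = c(2, 0.05),
                                    B_true = 0.035,
                                    area_sizes = table1_sizes,
                                    prop_active = 0.84,
                                    seed = root_seed),
    balanced_small = generator_config(M_true = -0.1, eta_true = 0.15,
                                      variance_family = "gamma",
                                      family_params = c(2, 0.05),
                                      area_sizes = rep(10L, 4L),
                                      seed = root_seed + 1L),
    single_area = generator_config(M_true = -0.2, eta_true = 0,
                                   variance_family = "gamma",
                                   family_params = c(2, 0.02),
                                   area_sizes = c(solo = 20L),
                                   seed = root_seed + 2L))
  lapply(suite, function(cfg) c(list(config = cfg), simulate_trial_dataset(cfg)))
}
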