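#' Model specification for the hierarchical synthesis
#'
#' The base model ("model1") is a three-level normal hierarchy on the
#' observed log-scale effects: `y_i ~ N(theta_i, se_i^2)` with known
#' standard errors, `theta_i ~ N(mu_A, tau2_A)` within disease area,
#' exchangeable area means `mu_A ~ N(M, eta^2)`, and exchangeable
#' between-study variances `tau2_A ~ pi(kappa, nu)` for one of three
#' families.  "model2" adds a shared comparison-type coefficient:
#' `theta_i ~ N(mu_A + B * X_i, tau2_A)` with `X_i = 1` for
#' active-vs-active comparisons.
#'
#' Hyperpriors are vague: `M ~ N(0, 1000^2)`, `eta ~ Unif(0, 5)`,
#' `B ~ N(0, 1000^2)`; the log-normal family takes
#' `kappa ~ N(0, 1000^2)`, `nu ~ Unif(0, 5)` for the mean and sd of
#' `log(tau2)`; the gamma family `kappa ~ Unif(0, 50)` (shape) and
#' `nu ~ Unif(0, 50)` (scale); the half-normal family
#' `kappa ~ half-N(0, 1000^2)` truncated to `[0, 100]` (location) and
#' `nu ~ Unif(0, 5)` (sd), with `tau2 ~ N(kappa, nu^2)` truncated to
#' non-negative values.
#'
#' @param model `"model1"` or `"model2"` (comparison-type covariate).
#' @param variance_family `"lognormal"`, `"gamma"` or `"halfnormal"`.
#' @param fixed Optional named list pinning hyperparameters instead of
#'   assigning them priors.  Recognised names: `M`, `eta`, `B`, `kappa`,
#'   `nu`, and `tau2` (scalar or per-area vector; pinning `tau2` removes
#'   the variance family from the model).  Used mainly for oracle checks
#'   and degenerate-case studies.
#' @return An `rte_model_spec`.
#' @export
model_spec <- function(model = c("model1", "model2"),
                       variance_family = c("gamma", "lognormal", "halfnormal"),
                       fixed = list()) {
  model <- match.arg(model)
  variance_family <- match.arg(variance_family)
  known <- c("M", "eta", "B", "kappa", "nu", "tau2")
  if (length(fixed) > 0L) {
    if (is.null(names(fixed)) || any(!names(fixed) %in% known))
      stop("fixed must be a named list with names among: ",
           paste(known, collapse = ", "), call. = FALSE)
    if (!is.null(fixed$eta) && fixed$eta < 0) stop("fixed eta must be >= 0")
    if (!is.null(fixed$tau2) && any(fixed$tau2 < 0)) stop("fixed tau2 must be >= 0")
  }
  structure(list(model = model, variance_family = variance_family,
                 fixed = fixed),
            class = "rte_model_spec")
}

#' MCMC run settings
#'
#' @param profile `"paper"` (3 chains, 150,000 retained iterations per
#'   chain after 50,000 burn-in — the full-scale settings used for
#'   reported results) or `"test"` (3 chains, 5,000 after 2,000 — for
#'   development and simulation studies).
#' @param n_chains Number of chains (>= 2 so convergence can be assessed).
#' @param n_burnin Burn-in iterations per chain.
#' @param n_samples Retained iterations per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain c uses RNG seed `seed + c`.
#' @param rhat_threshold Convergence is flagged when any monitored
#'   parameter's split-chain R-hat exceeds this (default 1.05).
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(profile = c("paper", "test"),
                          n_chains = NULL, n_burnin = NULL,
                          n_samples = NULL, thin = 1L, seed = 1L,
                          rhat_threshold = 1.05) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") list(3L, 50000L, 150000L)
         else list(3L, 2000L, 5000L)
  n_chains <- if (is.null(n_chains)) def[[1]] else as.integer(n_chains)
  n_burnin <- if (is.null(n_burnin)) def[[2]] else as.integer(n_burnin)
  n_samples <- if (is.null(n_samples)) def[[3]] else as.integer(n_samples)
  stopifnot(n_chains >= 2L, n_burnin >= 0L, n_samples > 0L, thin >= 1L)
  structure(list(n_chains = n_chains, n_burnin = n_burnin,
                 n_samples = n_samples, thin = as.integer(thin),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold),
            class = "mcmc_settings")
}

# Assemble the JAGS model string for a spec.  Pinned hyperparameters are
# passed in as data, so they simply do not appear as stochastic nodes.
jags_model_string <- function(spec, n_area) {
  fx <- spec$fixed
  pin <- function(p) !is.null(fx[[p]])
  lines <- c("model {",
             "  for (i in 1:N) {",
             "    y[i] ~ dnorm(theta[i], prec_y[i])")
  mean_i <- if (spec$model == "model2") "mu[area[i]] + B * x[i]" else "mu[area[i]]"
  lines <- c(lines,
             sprintf("    theta[i] ~ dnorm(%s, prec_area[area[i]])", mean_i),
             "  }",
             "  for (a in 1:A) {",
             "    mu[a] ~ dnorm(M, prec_eta)",
             "    prec_area[a] <- 1 / tau2[a]")
  if (!pin("tau2")) {
    fam <- switch(spec$variance_family,
      lognormal = "    tau2[a] <- exp(log_tau2[a])\n    log_tau2[a] ~ dnorm(kappa, prec_nu)",
      gamma = "    tau2[a] ~ dgamma(kappa, rate_nu)",
      halfnormal = "    tau2[a] ~ dnorm(kappa, prec_nu) T(0,)")
    lines <- c(lines, fam)
  }
  lines <- c(lines, "  }")
  if (!pin("M")) lines <- c(lines, "  M ~ dnorm(0, 1.0E-6)")
  if (!pin("eta")) lines <- c(lines, "  eta ~ dunif(0, 5)")
  lines <- c(lines, "  prec_eta <- 1 / (eta * eta)")
  if (spec$model == "model2" && !pin("B"))
    lines <- c(lines, "  B ~ dnorm(0, 1.0E-6)")
  if (!pin("tau2")) {
    hyp <- switch(spec$variance_family,
      lognormal = c(if (!pin("kappa")) "  kappa ~ dnorm(0, 1.0E-6)",
                    if (!pin("nu")) "  nu ~ dunif(0, 5)",
                    "  prec_nu <- 1 / (nu * nu)"),
      gamma = c(if (!pin("kappa")) "  kappa ~ dunif(0, 50)",
                if (!pin("nu")) "  nu ~ dunif(0, 50)",
                "  rate_nu <- 1 / nu"),
      halfnormal = c(if (!pin("kappa")) "  kappa ~ dnorm(0, 1.0E-6) T(0, 100)",
                     if (!pin("nu")) "  nu ~ dunif(0, 5)",
                     "  prec_nu <- 1 / (nu * nu)"))
    lines <- c(lines, hyp)
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Fit the hierarchical relative-effect model
#'
#' Fits the synthesis model described in [model_spec()] to a
#' [trial_dataset()] by Markov chain Monte Carlo (JAGS backend), monitors
#' all model parameters, and computes convergence and fit diagnostics
#' (split-chain R-hat, posterior mean residual deviance, effective number
#' of parameters and DIC).  The fit is fully seeded: identical data,
#' spec and settings reproduce identical draws.
#'
#' @param data A [trial_dataset()] that has passed [filter_for_analysis()]
#'   (no missing disease areas).
#' @param model,variance_family,fixed Passed to [model_spec()]; ignored if
#'   `spec` is supplied.
#' @param spec An [model_spec()] object (overrides the previous three).
#' @param settings An [mcmc_settings()] object.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `rte_hier` with components `draws` (named
#'   list of arrays, `chains x draws` for scalars and
#'   `chains x draws x dim` for `mu`, `tau2`, `theta`), `diagnostics`
#'   (class `rte_diagnostics`: `rhat`, `Dbar`, `pD`, `DIC`, `converged`),
#'   `spec`, `settings`, `data` and `area_index`.
#' @examples
#' \donttest{
#' sim <- simulate_trial_dataset(generator_config(area_sizes = rep(15L, 3L)))
#' fit <- rte_hier(sim$data, settings = mcmc_settings("test", seed = 7))
#' summary(fit)
#' }
#' @export
rte_hier <- function(data, model = "model1", variance_family = "gamma",
                     fixed = list(), spec = NULL,
                     settings = mcmc_settings(), quiet = TRUE) {
  stopifnot(inherits(data, "trial_dataset"), inherits(settings, "mcmc_settings"))
  if (is.null(spec)) spec <- model_spec(model, variance_family, fixed)
  stopifnot(inherits(spec, "rte_model_spec"))
  if (any(is.na(data$disease_area)))
    stop("data contain records with missing disease area; ",
         "run filter_for_analysis() first", call. = FALSE)
  idx <- area_index(data)
  n_area <- length(idx)
  fx <- spec$fixed
  if (n_area < 2L && is.null(fx$eta) && is.null(fx$tau2))
    stop("hierarchical sharing across disease areas is undefined with ",
         "fewer than 2 areas; either provide more areas or pin the ",
         "area-level hyperparameters via fixed = list(eta = ..., tau2 = ...)",
         call. = FALSE)
  if (spec$model == "model2" && any(is.na(data$comparison_type)))
    stop("model2 requires comparison_type on every record", call. = FALSE)

  if (!is.null(fx$eta) && fx$eta <= 0)
    stop("pinned eta must be > 0 for fitting (use a small positive value ",
         "for near-degenerate studies)", call. = FALSE)
  if (!is.null(fx$tau2) && any(fx$tau2 <= 0))
    stop("pinned tau2 must be > 0 for fitting", call. = FALSE)

  jd <- list(N = nrow(data), A = n_area,
             y = data$y, prec_y = 1 / data$se^2,
             area = unname(idx[data$disease_area]))
  if (spec$model == "model2")
    jd$x <- as.integer(data$comparison_type == "active_vs_active")
  for (p in c("M", "eta"))
    if (!is.null(fx[[p]])) jd[[p]] <- fx[[p]]
  if (spec$model == "model2" && !is.null(fx$B)) jd$B <- fx$B
  if (is.null(fx$tau2)) {
    for (p in c("kappa", "nu"))
      if (!is.null(fx[[p]])) jd[[p]] <- fx[[p]]
  } else {
    jd$tau2 <- rep_len(fx$tau2, n_area)
  }

  # mildly dispersed, deterministic starting values per chain
  area_means <- tapply(data$y, data$disease_area, mean)[names(idx)]
  make_inits <- function(chain) {
    ini <- list(theta = data$y,
                mu = unname(area_means) + 0.1 * (chain - 2),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = settings$seed + chain)
    if (is.null(fx$M)) ini$M <- mean(data$y) + 0.1 * (chain - 2)
    if (is.null(fx$eta)) ini$eta <- 0.3 + 0.2 * chain
    if (is.null(fx$B) && spec$model == "model2") ini$B <- 0.05 * (chain - 2)
    if (is.null(fx$tau2)) {
      ini$tau2 <- rep(0.05, n_area)
      if (spec$variance_family == "lognormal") {
        ini$log_tau2 <- rep(log(0.05), n_area)
        ini$tau2 <- NULL
        if (is.null(fx$kappa)) ini$kappa <- log(0.05)
        if (is.null(fx$nu)) ini$nu <- 0.3 + 0.2 * chain
      } else if (spec$variance_family == "gamma") {
        if (is.null(fx$kappa)) ini$kappa <- 1.5 + 0.5 * chain
        if (is.null(fx$nu)) ini$nu <- 0.05 * chain
      } else {
        if (is.null(fx$kappa)) ini$kappa <- 0.02 * chain
        if (is.null(fx$nu)) ini$nu <- 0.3 + 0.2 * chain
      }
    }
    ini
  }
  inits <- lapply(seq_len(settings$n_chains), make_inits)

  monitors <- c(if (is.null(fx$M)) "M", if (is.null(fx$eta)) "eta",
                if (is.null(fx$tau2) && is.null(fx$kappa)) "kappa",
                if (is.null(fx$tau2) && is.null(fx$nu)) "nu",
                if (spec$model == "model2" && is.null(fx$B)) "B",
                "mu", if (is.null(fx$tau2)) "tau2", "theta")

  model_str <- jags_model_string(spec, n_area)
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = jd,
                            inits = inits, n.chains = settings$n_chains,
                            n.adapt = 1000L, quiet = TRUE)
    if (settings$n_burnin > 0L)
      stats::update(jm, settings$n_burnin, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = settings$n_samples,
                        thin = settings$thin, progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  draws <- coda_to_arrays(samp, idx, nrow(data))
  # pinned values are still exposed as (constant) draws for downstream code
  n_kept <- dim(draws$theta)[2]
  const <- function(v) matrix(v, settings$n_chains, n_kept)
  for (p in c("M", "eta", "B", "kappa", "nu"))
    if (!is.null(fx[[p]])) draws[[p]] <- const(fx[[p]])
  if (!is.null(fx$tau2)) {
    t2 <- rep_len(fx$tau2, n_area)
    draws$tau2 <- array(rep(t2, each = settings$n_chains * n_kept),
                        dim = c(settings$n_chains, n_kept, n_area),
                        dimnames = list(NULL, NULL, names(idx)))
  }

  fit <- structure(list(draws = draws, spec = spec, settings = settings,
                        data = data, area_index = idx),
                   class = "rte_hier")
  fit$diagnostics <- compute_diagnostics(fit, monitors)
  fit
}

# Reshape a coda::mcmc.list into chains x draws (x dim) arrays.
coda_to_arrays <- function(samp, idx, n_rec) {
  n_chain <- length(samp)
  vn <- coda::varnames(samp)
  n_kept <- nrow(samp[[1]])
  get <- function(cols) {
    a <- array(NA_real_, dim = c(n_chain, n_kept, length(cols)))
    for (ch in seq_len(n_chain))
      a[ch, , ] <- as.matrix(samp[[ch]][, cols, drop = FALSE])
    a
  }
  out <- list()
  for (p in c("M", "eta", "kappa", "nu", "B"))
    if (p %in% vn) out[[p]] <- get(p)[, , 1]
  vec_par <- function(p, dim_names) {
    # JAGS drops the index on length-1 vector nodes
    cols <- if (length(dim_names) == 1L && p %in% vn) p
            else sprintf("%s[%d]", p, seq_along(dim_names))
    if (!all(cols %in% vn)) return(NULL)
    a <- get(cols)
    dimnames(a) <- list(NULL, NULL, dim_names)
    a
  }
  out$mu <- vec_par("mu", names(idx))
  t2 <- vec_par("tau2", names(idx))
  if (!is.null(t2)) out$tau2 <- t2
  out$theta <- vec_par("theta", as.character(seq_len(n_rec)))
  out
}

compute_diagnostics <- function(fit, monitors) {
  d <- fit$draws
  rhats <- c()
  add_rhat <- function(name, mat) {
    r <- tryCatch(gelman_rubin_matrix(mat), warning = function(w) NA_real_)
    stats::setNames(r, name)
  }
  for (p in c("M", "eta", "kappa", "nu", "B"))
    if (p %in% monitors && !is.null(d[[p]]))
      rhats <- c(rhats, add_rhat(p, t(d[[p]])))
  for (p in c("mu", "tau2", "theta")) {
    if (!p %in% monitors || is.null(d[[p]])) next
    for (k in seq_len(dim(d[[p]])[3]))
      rhats <- c(rhats, add_rhat(sprintf("%s[%s]", p, dimnames(d[[p]])[[3]][k]),
                                 t(d[[p]][, , k])))
  }
  dic <- compute_dic(fit)
  structure(list(rhat = rhats, Dbar = dic$Dbar, pD = dic$pD, DIC = dic$DIC,
                 rhat_threshold = fit$settings$rhat_threshold,
                 converged = all(is.na(rhats) | rhats <= fit$settings$rhat_threshold)),
            class = "rte_diagnostics")
}

#' @export
print.rte_diagnostics <- function(x, ...) {
  cat("Fit diagnostics\n")
  cat(sprintf("  Dbar (posterior mean residual deviance): %.2f\n", x$Dbar))
  cat(sprintf("  pD (effective parameters):               %.2f\n", x$pD))
  cat(sprintf("  DIC:                                     %.2f\n", x$DIC))
  worst <- if (all(is.na(x$rhat))) NA_real_ else max(x$rhat, na.rm = TRUE)
  cat(sprintf("  max split R-hat: %.4f (threshold %.2f) -> %s\n", worst,
              x$rhat_threshold,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.rte_hier <- function(x, ...) {
  cat("Hierarchical relative-effect model fit (", x$spec$model, ", ",
      x$spec$variance_family, " variance family)\n", sep = "")
  cat("  ", nrow(x$data), " comparisons in ", length(x$area_index),
      " disease area(s)\n", sep = "")
  cat("  ", x$settings$n_chains, " chains x ", dim(x$draws$theta)[2],
      " retained draws\n", sep = "")
  cm <- coef(x)
  hyper <- cm[names(cm) %in% c("M", "eta", "kappa", "nu", "B")]
  cat("  posterior means: ",
      paste(sprintf("%s = %.3f", names(hyper), hyper), collapse = ", "),
      "\n", sep = "")
  if (!isTRUE(x$diagnostics$converged))
    cat("  WARNING: convergence flag raised (max R-hat above threshold)\n")
  invisible(x)
}

#' @export
summary.rte_hier <- function(object, ...) {
  d <- object$draws
  smry <- function(v) c(mean = mean(v), sd = stats::sd(v),
                        `2.5%` = unname(stats::quantile(v, 0.025)),
                        `97.5%` = unname(stats::quantile(v, 0.975)))
  rows <- list()
  for (p in c("M", "eta", "kappa", "nu", "B"))
    if (!is.null(d[[p]])) rows[[p]] <- smry(d[[p]])
  for (p in c("mu", "tau2"))
    if (!is.null(d[[p]]))
      for (k in seq_len(dim(d[[p]])[3]))
        rows[[sprintf("%s[%s]", p, dimnames(d[[p]])[[3]][k])]] <-
          smry(d[[p]][, , k])
  tab <- do.call(rbind, rows)
  out <- list(table = tab, diagnostics = object$diagnostics,
              spec = object$spec)
  class(out) <- "summary.rte_hier"
  out
}

#' @export
print.summary.rte_hier <- function(x, ...) {
  cat("Posterior summary (", x$spec$model, ", ", x$spec$variance_family,
      " family)\n", sep = "")
  print(round(x$table, 4))
  print(x$diagnostics)
  invisible(x)
}

#' @export
coef.rte_hier <- function(object, ...) {
  d <- object$draws
  out <- c()
  for (p in c("M", "eta", "kappa", "nu", "B"))
    if (!is.null(d[[p]])) out[p] <- mean(d[[p]])
  for (p in c("mu", "tau2"))
    if (!is.null(d[[p]])) {
      m <- apply(d[[p]], 3, mean)
      out[sprintf("%s[%s]", p, names(m))] <- unname(m)
    }
  out
}

#' @export
residuals.rte_hier <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  theta_hat <- apply(object$draws$theta, 3, mean)
  r <- object$data$y - theta_hat
  if (type == "standardized") r <- r / object$data$se
  r
}

#' Flatten posterior draws across chains
#'
#' @param fit An `rte_hier` fit.
#' @param par Parameter name (`"M"`, `"eta"`, `"kappa"`, `"nu"`, `"B"`,
#'   `"mu"`, `"tau2"`, `"theta"`).
#' @return For scalar parameters a numeric vector (one value per retained
#'   draw, chains concatenated); for vector parameters a matrix with one
#'   column per component.
#' @export
posterior_matrix <- function(fit, par) {
  stopifnot(inherits(fit, "rte_hier"))
  d <- fit$draws[[par]]
  if (is.null(d)) stop("parameter not monitored/present: ", par, call. = FALSE)
  if (length(dim(d)) == 2L) return(as.vector(d))
  out <- matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3])
  colnames(out) <- dimnames(d)[[3]]
  out
}
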