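#' Log joint posterior density (up to a constant)
#'
#' Evaluates the log of the joint density of data and parameters for the
#' hierarchical model in [model_spec()] at a full parameter point.  Points
#' outside the support (non-positive variances, uniform hyperparameters
#' out of range) return `-Inf`.  Hyperparameters pinned in
#' `spec$fixed` contribute no prior term and their pinned values override
#' whatever `point` carries.
#'
#' @param spec An [model_spec()].
#' @param data A [trial_dataset()] with no missing disease areas (and no
#'   missing comparison types for model2).
#' @param point Named list with `theta` (length = records), `mu`, `tau2`
#'   (length = areas), `M`, `eta`, and the family parameters `kappa`,
#'   `nu`; `B` for model2.
#' @return Log density (scalar; `-Inf` outside the support).
#' @export
log_posterior <- function(spec, data, point) {
  stopifnot(inherits(spec, "rte_model_spec"), inherits(data, "trial_dataset"))
  idx <- area_index(data)
  n_area <- length(idx)
  fx <- spec$fixed
  val <- function(p) if (!is.null(fx[[p]])) fx[[p]] else point[[p]]
  free <- function(p) is.null(fx[[p]])

  theta <- point$theta
  mu <- val("mu")  # mu/theta are never pinned, but keep the accessor uniform
  tau2 <- if (!is.null(fx$tau2)) rep_len(fx$tau2, n_area) else point$tau2
  M <- val("M"); eta <- val("eta")
  if (length(theta) != nrow(data) || length(mu) != n_area ||
      length(tau2) != n_area)
    stop("parameter dimensions do not match the data (",
         nrow(data), " records, ", n_area, " areas)", call. = FALSE)

  # support checks
  if (any(tau2 < 0) || eta < 0 || eta > 5) return(-Inf)
  kappa <- NULL; nu <- NULL
  if (is.null(fx$tau2)) {
    kappa <- val("kappa"); nu <- val("nu")
    ok <- switch(spec$variance_family,
      lognormal = nu >= 0 && nu <= 5 && all(tau2 > 0),
      gamma = kappa >= 0 && kappa <= 50 && nu >= 0 && nu <= 50 && all(tau2 > 0),
      halfnormal = kappa >= 0 && kappa <= 100 && nu >= 0 && nu <= 5)
    if (!ok) return(-Inf)
  }

  a_of <- unname(idx[data$disease_area])
  mean_theta <- mu[a_of]
  B <- NULL
  if (spec$model == "model2") {
    if (any(is.na(data$comparison_type)))
      stop("model2 requires comparison_type on every record", call. = FALSE)
    B <- val("B")
    mean_theta <- mean_theta + B * (data$comparison_type == "active_vs_active")
  }

  lp <- sum(stats::dnorm(data$y, theta, data$se, log = TRUE)) +
    sum(stats::dnorm(theta, mean_theta, sqrt(tau2[a_of]), log = TRUE)) +
    sum(stats::dnorm(mu, M, eta, log = TRUE))

  if (is.null(fx$tau2)) {
    lp <- lp + switch(spec$variance_family,
      lognormal = sum(stats::dlnorm(tau2, kappa, nu, log = TRUE)),
      gamma = sum(stats::dgamma(tau2, shape = kappa, scale = nu, log = TRUE)),
      halfnormal = sum(stats::dnorm(tau2, kappa, nu, log = TRUE) -
                         stats::pnorm(0, kappa, nu, lower.tail = FALSE,
                                      log.p = TRUE)))
    # family hyperpriors
    if (free("kappa"))
      lp <- lp + switch(spec$variance_family,
        lognormal = stats::dnorm(kappa, 0, 1000, log = TRUE),
        gamma = stats::dunif(kappa, 0, 50, log = TRUE),
        halfnormal = stats::dnorm(kappa, 0, 1000, log = TRUE))  # flat trunc. const. absorbed
    if (free("nu"))
      lp <- lp + switch(spec$variance_family,
        lognormal = stats::dunif(nu, 0, 5, log = TRUE),
        gamma = stats::dunif(nu, 0, 50, log = TRUE),
        halfnormal = stats::dunif(nu, 0, 5, log = TRUE))
  }
  if (free("M")) lp <- lp + stats::dnorm(M, 0, 1000, log = TRUE)
  if (free("eta")) lp <- lp + stats::dunif(eta, 0, 5, log = TRUE)
  if (spec$model == "model2" && free("B"))
    lp <- lp + stats::dnorm(B, 0, 1000, log = TRUE)
  if (!is.finite(lp)) return(-Inf)
  lp
}
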