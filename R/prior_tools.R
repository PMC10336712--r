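#' Normal prior on a log relative-effect scale
#'
#' @param mean,sd Normal parameters (`sd > 0`).
#' @param scale Scale tag (e.g. `"log-hr"`, `"log-or"`, `"log"`); priors
#'   can only be combined when their tags agree.
#' @return A `normal_prior`.
#' @export
normal_prior <- function(mean, sd, scale = "log") {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  structure(list(mean = mean, sd = sd, scale = scale),
            class = "normal_prior")
}

#' @export
print.normal_prior <- function(x, ...) {
  cat(sprintf("Normal prior on %s scale: N(%.4g, %.4g^2)\n",
              x$scale, x$mean, x$sd))
  invisible(x)
}

#' Gamma prior (shape/rate) for an event rate
#'
#' @param shape,rate Positive gamma parameters.
#' @return A `gamma_prior`.
#' @export
gamma_prior <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  structure(list(shape = shape, rate = rate), class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("Gamma prior: shape %.4g, rate %.4g (mean %.4g)\n",
              x$shape, x$rate, x$shape / x$rate))
  invisible(x)
}

#' Apply a log-scale effect prior to a baseline probability
#'
#' Induces the distribution of the treated-arm annual recurrence (or
#' event) parameter implied by a normal prior on the log relative effect.
#' Two conventions are supported: `"multiply_probability"` scales the
#' baseline probability directly, `p_new = p0 * exp(theta)`; while
#' `"multiply_rate"` treats the effect as a log hazard ratio acting on the
#' baseline rate, `r_new = -log(1 - p0) * exp(theta)` with
#' `p_new = 1 - exp(-r_new)`.  Medians and intervals come from closed-form
#' log-normal quantiles (both transforms are monotone in `theta`);
#' samples are returned for downstream distribution fitting.
#'
#' @param prior A [normal_prior()] on the log relative-effect scale.
#' @param baseline_prob Baseline (control-arm) annual event probability,
#'   in (0, 1).
#' @param convention `"multiply_probability"` (default; matches the
#'   reported case-study summaries) or `"multiply_rate"`.
#' @param n_samples Number of representative samples to draw.
#' @param seed Seed for the samples.
#' @param level Interval level(s).
#' @return An `induced_distribution`: list with `median`, `intervals`
#'   (probability scale), `rate_median` and rate-scale samples
#'   (`rate_samples`), probability samples (`prob_samples`), the
#'   convention and baseline, and a `truncated` flag/count under
#'   `multiply_probability` when induced probabilities exceeded 1.
#' @export
apply_log_effect_prior <- function(prior, baseline_prob,
                                   convention = c("multiply_probability",
                                                  "multiply_rate"),
                                   n_samples = 10000L, seed = 1L,
                                   level = 0.95) {
  stopifnot(inherits(prior, "normal_prior"),
            baseline_prob > 0, baseline_prob < 1)
  convention <- match.arg(convention)
  q_theta <- function(p) stats::qnorm(p, prior$mean, prior$sd)
  qs <- c(0.5, (1 - level) / 2, 1 - (1 - level) / 2)
  set.seed(seed)
  theta <- stats::rnorm(n_samples, prior$mean, prior$sd)
  n_trunc <- 0L
  if (convention == "multiply_probability") {
    p_q <- baseline_prob * exp(q_theta(qs))
    prob_samples <- baseline_prob * exp(theta)
    over <- prob_samples >= 1
    n_trunc <- sum(over)
    if (stats::pnorm(log(1 / baseline_prob), prior$mean, prior$sd,
                     lower.tail = FALSE) > 0.001) {
      warning("induced probability >= 1 in more than 0.1% of the prior ",
              "mass; samples truncated just below 1", call. = FALSE)
    }
    prob_samples[over] <- 1 - 1e-12
    p_q <- pmin(p_q, 1 - 1e-12)
    rate_samples <- -log(1 - prob_samples)
  } else {
    r0 <- -log(1 - baseline_prob)
    r_q <- r0 * exp(q_theta(qs))
    rate_samples <- r0 * exp(theta)
    prob_samples <- 1 - exp(-rate_samples)
    p_q <- 1 - exp(-r_q)
  }
  structure(list(baseline_prob = baseline_prob, convention = convention,
                 median = p_q[1],
                 intervals = data.frame(level = level,
                                        lo = p_q[2], hi = p_q[3]),
                 rate_median = -log(1 - p_q[1]),
                 prob_samples = prob_samples, rate_samples = rate_samples,
                 n_truncated = n_trunc, prior = prior),
            class = "induced_distribution")
}

#' @export
print.induced_distribution <- function(x, ...) {
  cat("Induced event-parameter distribution (", x$convention, ")\n", sep = "")
  cat(sprintf("  baseline probability: %.3f\n", x$baseline_prob))
  cat(sprintf("  median probability:   %.3f (%.0f%%)\n", x$median,
              100 * x$median))
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  %g%% interval: (%.3f, %.3f)\n", 100 * x$intervals$level[i],
                x$intervals$lo[i], x$intervals$hi[i]))
  if (x$n_truncated > 0L)
    cat("  (", x$n_truncated, " sample(s) truncated at probability 1)\n",
        sep = "")
  invisible(x)
}

#' Moment-matched gamma parameters
#'
#' `shape = mean^2 / variance`, `rate = mean / variance`.
#'
#' @param mean,variance Positive moments.
#' @return A [gamma_prior()].
#' @export
fit_gamma_moments <- function(mean, variance) {
  stopifnot(mean > 0, variance > 0)
  gamma_prior(shape = mean^2 / variance, rate = mean / variance)
}

#' Fit a gamma distribution to an induced rate distribution
#'
#' Fits a gamma to the rate-scale samples of an
#' [apply_log_effect_prior()] result, by moment matching (default) or
#' maximum likelihood.
#'
#' @param induced An `induced_distribution`.
#' @param method `"moments"` or `"mle"` (requires the MASS package).
#' @return A [gamma_prior()].
#' @export
fit_gamma_to_induced <- function(induced, method = c("moments", "mle")) {
  stopifnot(inherits(induced, "induced_distribution"))
  method <- match.arg(method)
  r <- induced$rate_samples
  if (method == "moments")
    return(fit_gamma_moments(mean(r), stats::var(r)))
  if (!requireNamespace("MASS", quietly = TRUE))
    stop("the mle method requires the MASS package", call. = FALSE)
  est <- MASS::fitdistr(r, "gamma")$estimate
  gamma_prior(shape = unname(est["shape"]), rate = unname(est["rate"]))
}

#' Combine two normal priors by Bayesian updating
#'
#' Treats the two priors as independent normal information sources:
#' precisions add and the combined mean is the precision-weighted average.
#' The combined sd never exceeds either component's.
#'
#' @param a,b [normal_prior()] objects with matching scale tags.
#' @return A [normal_prior()].
#' @export
bayes_combine_normals <- function(a, b) {
  stopifnot(inherits(a, "normal_prior"), inherits(b, "normal_prior"))
  if (!identical(a$scale, b$scale))
    stop("cannot combine priors on different scales: '", a$scale,
         "' vs '", b$scale, "'", call. = FALSE)
  pa <- 1 / a$sd^2
  pb <- 1 / b$sd^2
  normal_prior((pa * a$mean + pb * b$mean) / (pa + pb),
               sqrt(1 / (pa + pb)), scale = a$scale)
}

#' Linear opinion pool of normal priors
#'
#' Forms the weighted mixture of the component priors (weights normalized
#' internally).  The pooled density integrates to 1 and the pooled
#' variance is the weighted mean of component variances plus the
#' between-component mean dispersion, so pooling never manufactures
#' precision.
#'
#' @param priors List of [normal_prior()] objects on a common scale.
#' @param weights Non-negative weights, sum > 0 (default equal).
#' @return A `pooled_prior`: list with `components`, `weights`, pooled
#'   `mean` and `sd`, a density function `density(x)` and a sampler
#'   `sample(n, seed)`.
#' @export
linear_pool <- function(priors, weights = NULL) {
  if (length(priors) == 0L) stop("empty prior list", call. = FALSE)
  stopifnot(all(vapply(priors, inherits, TRUE, "normal_prior")))
  scales <- unique(vapply(priors, `[[`, "", "scale"))
  if (length(scales) > 1L)
    stop("all pooled priors must share one scale tag; got: ",
         paste(scales, collapse = ", "), call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(priors))
  stopifnot(length(weights) == length(priors), all(weights >= 0),
            sum(weights) > 0)
  w <- weights / sum(weights)
  mu <- vapply(priors, `[[`, 0, "mean")
  sd_ <- vapply(priors, `[[`, 0, "sd")
  pooled_mean <- sum(w * mu)
  pooled_var <- sum(w * (sd_^2 + mu^2)) - pooled_mean^2
  dens <- function(x)
    rowSums(vapply(seq_along(w),
                   function(k) w[k] * stats::dnorm(x, mu[k], sd_[k]),
                   numeric(length(x))))
  sampler <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    k <- sample.int(length(w), n, replace = TRUE, prob = w)
    stats::rnorm(n, mu[k], sd_[k])
  }
  structure(list(components = priors, weights = w, scale = scales,
                 mean = pooled_mean, sd = sqrt(pooled_var),
                 density = dens, sample = sampler),
            class = "pooled_prior")
}

#' @export
print.pooled_prior <- function(x, ...) {
  cat("Linear opinion pool of", length(x$components), "normal priors on",
      x$scale, "scale\n")
  cat(sprintf("  weights: %s\n", paste(round(x$weights, 3), collapse = ", ")))
  cat(sprintf("  pooled moments: mean %.4g, sd %.4g\n", x$mean, x$sd))
  invisible(x)
}

#' Serialize a prior as a small JSON document
#'
#' @param x A `normal_prior` or `gamma_prior`.
#' @param path Optional output path.
#' @param provenance Optional provenance string stored alongside.
#' @return JSON string (invisibly when written to a file).
#' @export
prior_json <- function(x, path = NULL, provenance = NULL) {
  doc <- if (inherits(x, "normal_prior"))
    list(type = "normal", mean = x$mean, sd = x$sd, scale = x$scale)
  else if (inherits(x, "gamma_prior"))
    list(type = "gamma", shape = x$shape, rate = x$rate)
  else stop("unsupported prior class", call. = FALSE)
  if (!is.null(provenance)) doc$provenance <- provenance
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
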