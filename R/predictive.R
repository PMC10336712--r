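#' Predictive samples and priors for a future trial
#'
#' Turns a fitted hierarchy into the predictive distribution of the true
#' effect `theta_pred` in a new randomized trial.  For a disease area
#' represented in the data, one `theta_pred ~ N(mu_A, tau2_A)` is drawn
#' per retained posterior draw (plus the comparison-type shift `B` for
#' active-vs-active comparisons under model2).  For an unrepresented
#' ("new") area, three levels of prediction are used per posterior draw:
#' `mu_pred ~ N(M, eta^2)`, `tau2_pred ~ pi(kappa, nu)`, then
#' `theta_pred ~ N(mu_pred, tau2_pred)`.
#'
#' With `type = "samples"` the raw vector of predictive draws is
#' returned; `type = "prior"` moment-matches them to a normal summary and
#' returns a [predictive_prior()].  The same underlying standard-normal
#' deviates are used for every comparison type at a given seed, so at
#' matched seeds the active-vs-active and active-vs-inactive sample
#' vectors differ by exactly the posterior draws of `B`.
#'
#' @param object An `rte_hier` fit.
#' @param area Disease-area label present in the fit, or `"new"` for an
#'   area not represented in the data.
#' @param comparison `"any"` (model1 fits), `"active_vs_inactive"` or
#'   `"active_vs_active"` (model2 fits).
#' @param type `"prior"` (normal summary) or `"samples"`.
#' @param level Interval level(s) for the returned prior.
#' @param seed Integer seed for the predictive draws.
#' @param ... Unused.
#' @return A numeric vector (`type = "samples"`) or a
#'   [predictive_prior()].
#' @export
predict.rte_hier <- function(object, area = "new",
                             comparison = c("any", "active_vs_inactive",
                                            "active_vs_active"),
                             type = c("prior", "samples"),
                             level = 0.95, seed = 1L, ...) {
  comparison <- match.arg(comparison)
  type <- match.arg(type)
  samples <- predictive_samples(object, area, comparison, seed)
  if (type == "samples") return(samples)
  ms <- summarize_to_normal(samples)
  predictive_prior(label = if (identical(area, "new")) "other/unknown" else area,
                   comparison = comparison, mean = ms[["mean"]],
                   sd = ms[["sd"]], level = level,
                   model = paste0(object$spec$model, "/",
                                  object$spec$variance_family))
}

#' Raw predictive samples of a future trial effect
#'
#' One `theta_pred` per retained posterior draw; see
#' [predict.rte_hier()] for the sampling scheme.
#'
#' @param fit An `rte_hier` fit.
#' @param area Disease-area label or `"new"`.
#' @param comparison Comparison type (see [predict.rte_hier()]).
#' @param seed Integer seed.
#' @return Numeric vector with one value per retained posterior draw.
#' @export
predictive_samples <- function(fit, area, comparison = "any", seed = 1L) {
  stopifnot(inherits(fit, "rte_hier"))
  is_model2 <- fit$spec$model == "model2"
  if (comparison != "any" && !is_model2)
    stop("comparison-specific prediction requires a model2 fit", call. = FALSE)
  if (comparison == "any" && is_model2)
    stop("a model2 fit predicts per comparison type; choose ",
         "'active_vs_inactive' or 'active_vs_active'", call. = FALSE)
  new_area <- identical(area, "new") || identical(area, "other/unknown")
  if (!new_area && !area %in% names(fit$area_index))
    stop("unknown disease area '", area, "'; known areas: ",
         paste(names(fit$area_index), collapse = ", "),
         " (or 'new' for an unrepresented area)", call. = FALSE)

  shift <- if (is_model2 && comparison == "active_vs_active")
    posterior_matrix(fit, "B") else 0
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  if (new_area) {
    M <- posterior_matrix(fit, "M")
    eta <- posterior_matrix(fit, "eta")
    n <- length(M)
    mu_pred <- stats::rnorm(n, M, eta)
    tau2_pred <- if (!is.null(fit$spec$fixed$tau2)) {
      rep_len(fit$spec$fixed$tau2, n)
    } else {
      kappa <- posterior_matrix(fit, "kappa")
      nu <- posterior_matrix(fit, "nu")
      draw_tau2_vec(fit$spec$variance_family, kappa, nu)
    }
    z <- stats::rnorm(n)
    mu_pred + shift + sqrt(tau2_pred) * z
  } else {
    mu <- posterior_matrix(fit, "mu")[, area]
    tau2 <- posterior_matrix(fit, "tau2")[, area]
    z <- stats::rnorm(length(mu))
    mu + shift + sqrt(tau2) * z
  }
}

# Vectorized family draw with per-draw parameters (used for new-area
# prediction: one tau2_pred per posterior draw of (kappa, nu)).
draw_tau2_vec <- function(family, kappa, nu) {
  n <- length(kappa)
  switch(family,
    lognormal = exp(stats::rnorm(n, kappa, nu)),
    gamma = ifelse(kappa == 0 | nu == 0, 0,
                   stats::rgamma(n, shape = pmax(kappa, 1e-12), scale = pmax(nu, 1e-12))),
    halfnormal = {
      p0 <- stats::pnorm(0, kappa, nu)
      u <- stats::runif(n, p0, 1)
      out <- stats::qnorm(u, kappa, nu)
      out[nu == 0] <- pmax(kappa[nu == 0], 0)
      out
    },
    stop("unknown variance family: ", family))
}

#' Moment-match a sample vector to a normal summary
#'
#' @param samples Numeric vector (>= 2 values).
#' @return Named vector `c(mean, sd)`; the sd uses the `n - 1`
#'   denominator.  Constant samples give sd 0 with a warning.
#' @export
summarize_to_normal <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  s <- stats::sd(samples)
  if (s == 0) warning("samples have zero variance; sd = 0", call. = FALSE)
  c(mean = mean(samples), sd = s)
}

#' Central normal interval
#'
#' Returns `mean +/- z * sd`.  At the conventional 95% level the reporting
#' convention `z = 1.96` is used; other levels use exact normal quantiles.
#'
#' @param mean,sd Normal parameters (`sd >= 0`).
#' @param level Interval level in (0, 1).
#' @return Named vector `c(lo, hi)`.
#' @export
normal_interval <- function(mean, sd, level = 0.95) {
  stopifnot(sd >= 0, level > 0, level < 1)
  z <- if (isTRUE(all.equal(level, 0.95))) 1.96 else stats::qnorm((1 + level) / 2)
  c(lo = mean - z * sd, hi = mean + z * sd)
}

#' A normal predictive prior on the log relative-effect scale
#'
#' @param label Disease-area name or `"other/unknown"`.
#' @param comparison `"any"`, `"active_vs_inactive"` or
#'   `"active_vs_active"`.
#' @param mean,sd Normal summary on the log odds/hazard-ratio scale
#'   (`sd > 0`).
#' @param level Interval level(s) to precompute.
#' @param model Optional tag recording which model produced the prior.
#' @return A `predictive_prior` list with `label`, `comparison`, `mean`,
#'   `sd`, `intervals` (data frame `level`, `lo`, `hi`) and `model`.
#' @export
predictive_prior <- function(label, comparison = "any", mean, sd,
                             level = 0.95, model = NA_character_) {
  stopifnot(sd > 0)
  iv <- t(vapply(level, function(l) normal_interval(mean, sd, l), c(lo = 0, hi = 0)))
  structure(list(label = label, comparison = comparison,
                 mean = mean, sd = sd,
                 intervals = data.frame(level = level, lo = iv[, "lo"],
                                        hi = iv[, "hi"]),
                 model = model),
            class = "predictive_prior")
}

#' @export
print.predictive_prior <- function(x, ...) {
  cat("Predictive prior for a future trial effect (log scale)\n")
  cat(sprintf("  %s [%s]%s: N(mean = %.3f, sd = %.3f)\n", x$label,
              x$comparison,
              if (!is.na(x$model)) paste0(" (", x$model, ")") else "",
              x$mean, x$sd))
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  %g%% predictive interval: (%.3f, %.3f)\n",
                100 * x$intervals$level[i], x$intervals$lo[i],
                x$intervals$hi[i]))
  r <- to_ratio_scale(x)
  cat(sprintf("  odds/hazard-ratio scale: median %.3f (%.3f, %.3f)\n",
              r$median_ratio, r$lo[1], r$hi[1]))
  invisible(x)
}

#' Transform a log-scale prior to the odds/hazard-ratio scale
#'
#' Exponentiates the normal summary (a log-normal on the ratio scale):
#' the median ratio is `exp(mean)` and interval endpoints map
#' monotonically.
#'
#' @param prior A [predictive_prior()].
#' @return List with `median_ratio`, `lo`, `hi` (per interval level).
#' @export
to_ratio_scale <- function(prior) {
  stopifnot(inherits(prior, "predictive_prior"))
  list(median_ratio = exp(prior$mean),
       level = prior$intervals$level,
       lo = exp(prior$intervals$lo), hi = exp(prior$intervals$hi))
}

#' Export a table of predictive priors
#'
#' Builds one predictive prior per represented disease area, plus an
#' `"other/unknown"` row from the three-level new-area prediction.  For
#' model2 fits each requested comparison type gets its own row per area.
#'
#' @param fit An `rte_hier` fit.
#' @param areas Area labels to include (default: all represented areas).
#' @param include_new Add the `"other/unknown"` new-area row.
#' @param level Interval level for the `lo`/`hi` columns.
#' @param seed Seed for the predictive draws.
#' @return A `prior_table` data frame with columns `label`, `comparison`,
#'   `model`, `mean_log`, `sd_log`, `lo95`, `hi95`, `median_ratio`.
#' @export
prior_table <- function(fit, areas = NULL, include_new = TRUE,
                        level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "rte_hier"))
  if (is.null(areas)) areas <- names(fit$area_index)
  comparisons <- if (fit$spec$model == "model2")
    c("active_vs_inactive", "active_vs_active") else "any"
  targets <- expand.grid(label = c(areas, if (include_new) "new"),
                         comparison = comparisons,
                         stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    pr <- predict(fit, area = targets$label[i],
                  comparison = targets$comparison[i],
                  type = "prior", level = level, seed = seed + i)
    data.frame(label = pr$label, comparison = pr$comparison,
               model = pr$model, mean_log = pr$mean, sd_log = pr$sd,
               lo95 = pr$intervals$lo[1], hi95 = pr$intervals$hi[1],
               median_ratio = exp(pr$mean), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("prior_table", "data.frame")
  out
}

#' Write a prior table to CSV and/or JSON
#'
#' @param x A [prior_table()].
#' @param csv,json Optional output paths.
#' @return `x`, invisibly.
#' @export
write_prior_table <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "prior_table"))
  if (!is.null(csv)) utils::write.csv(as.data.frame(x), csv, row.names = FALSE)
  if (!is.null(json))
    writeLines(jsonlite::toJSON(as.data.frame(x), dataframe = "rows",
                                auto_unbox = TRUE, digits = NA), json)
  invisible(x)
}

#' @export
print.prior_table <- function(x, ...) {
  cat("Predictive priors for a future trial (log scale; ",
      100 * attr(x, "level"), "% intervals)\n", sep = "")
  print.data.frame(cbind(x[, c("label", "comparison", "model")],
                         round(x[, c("mean_log", "sd_log", "lo95", "hi95",
                                     "median_ratio")], 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Interval plot of a prior table on the ratio scale
#'
#' @param x A [prior_table()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.prior_table <- function(x, ...) {
  n <- nrow(x)
  med <- x$median_ratio
  lo <- exp(x$lo95)
  hi <- exp(x$hi95)
  labs <- ifelse(x$comparison == "any", x$label,
                 paste0(x$label, " (", x$comparison, ")"))
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(med, rev(seq_len(n)), xlim = range(c(lo, hi, 1)),
                 ylim = c(0.5, n + 0.5), yaxt = "n", log = "x",
                 xlab = "odds/hazard ratio (log axis)", ylab = "",
                 pch = 19, ...)
  graphics::segments(lo, rev(seq_len(n)), hi, rev(seq_len(n)))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = rev(seq_len(n)), labels = labs, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}
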