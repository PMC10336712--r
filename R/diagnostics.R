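#' Residual deviance of study-level effects
#'
#' Under the normal approximation with known standard errors the residual
#' deviance at study-effect values `theta` is
#' `sum_i (y_i - theta_i)^2 / se_i^2`.  The additive `log(2*pi*se^2)`
#' constant is omitted: it cancels in model comparison.
#'
#' @param data A [trial_dataset()].
#' @param theta Numeric vector of per-record effects (same length/order as
#'   the records).
#' @return The residual deviance (non-negative scalar).
#' @export
residual_deviance <- function(data, theta) {
  stopifnot(inherits(data, "trial_dataset"))
  if (length(theta) != nrow(data))
    stop("theta must have one value per record (", nrow(data), "), got ",
         length(theta), call. = FALSE)
  sum(((data$y - theta) / data$se)^2)
}

#' Deviance information criterion of a fit
#'
#' Computes `Dbar` (posterior mean residual deviance over the retained
#' draws of the study effects), the effective number of parameters
#' `pD = Dbar - D(theta_hat)` evaluated at the posterior-mean study
#' effects (deviance focus at the study-effect level), and
#' `DIC = Dbar + pD`.
#'
#' @param fit An `rte_hier` fit (or any list with `draws$theta` and
#'   `data`).
#' @return List with `Dbar`, `pD`, `DIC`.
#' @export
compute_dic <- function(fit) {
  th <- fit$draws$theta
  if (is.null(th)) stop("fit does not carry theta draws", call. = FALSE)
  n_draw <- dim(th)[1] * dim(th)[2]
  mat <- matrix(th, nrow = n_draw, ncol = dim(th)[3])
  y <- fit$data$y
  se <- fit$data$se
  dev <- colSums(((t(mat) - y) / se)^2)
  Dbar <- mean(dev)
  Dhat <- sum(((y - colMeans(mat)) / se)^2)
  pD <- Dbar - Dhat
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

# Split-chain potential scale reduction factor on a draws x chains matrix.
# Each chain is split in half, giving 2*n_chains sequences of length
# floor(n/2); R-hat = sqrt(((n-1)/n * W + B/n) / W).
gelman_rubin_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (m < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (n < 10L) stop("at least 10 draws per chain are required", call. = FALSE)
  half <- n %/% 2L
  splits <- vector("list", 2L * m)
  for (j in seq_len(m)) {
    splits[[2L * j - 1L]] <- x[seq_len(half), j]
    splits[[2L * j]] <- x[(n - half + 1L):n, j]
  }
  means <- vapply(splits, mean, 0)
  vars <- vapply(splits, stats::var, 0)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) {
    warning("R-hat undefined: chains have zero within-sequence variance",
            call. = FALSE)
    return(NA_real_)
  }
  B <- half * stats::var(means)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Gelman-Rubin convergence diagnostic for one parameter
#'
#' Split-chain potential scale reduction factor: each chain is split in
#' half and the usual between/within variance ratio is computed on the
#' resulting sequences.  Values near 1 indicate the chains agree.
#'
#' @param fit An `rte_hier` fit.
#' @param parameter Parameter name, e.g. `"M"`, `"mu[area_01]"`,
#'   `"theta[3]"`.
#' @return The R-hat value, or `NA` (with a warning) when the chains are
#'   constant and the statistic is undefined.
#' @export
gelman_rubin <- function(fit, parameter) {
  stopifnot(inherits(fit, "rte_hier"))
  base <- sub("\\[.*\\]$", "", parameter)
  comp <- sub("^.*\\[(.*)\\]$", "\\1", parameter)
  d <- fit$draws[[base]]
  if (is.null(d)) stop("unknown parameter: ", parameter, call. = FALSE)
  if (length(dim(d)) == 2L) return(gelman_rubin_matrix(t(d)))
  labs <- dimnames(d)[[3]]
  k <- if (comp %in% labs) match(comp, labs) else suppressWarnings(as.integer(comp))
  if (is.na(k) || k < 1L || k > dim(d)[3])
    stop("unknown component '", comp, "' of parameter ", base, call. = FALSE)
  gelman_rubin_matrix(t(d[, , k]))
}
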