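#' Inputs for the bladder-cancer Markov decision model
#'
#' Bundles the decision-model and trial parameters for the three-state
#' (recurrence-free / recurrence / dead) cohort model used in the
#' value-of-information case study.  Defaults reproduce the published
#' input table: control-arm 1-year failure-free survival 0.75 under an
#' exponential model (so the control recurrence rate is `-log(0.75)` per
#' year and is treated as known), 5-year disease-specific survival after
#' failure 79%, annual surveillance cost $5,585 (se 1,117), annual
#' recurrent-state cost $17,727 (se 3,545), an added experimental-arm cost
#' of $147.18 per year, utilities 0.997 (se 0.05) failure-free and 0.96
#' (se 0.192) recurrent, willingness-to-pay $150,000/QALY, cohort age 68,
#' and a 3% annual discount rate.  The cycle length is 1 year and the
#' horizon runs to age 100; background (non-disease) mortality is not
#' modelled.
#'
#' @param control_ffs_1y Control-arm 1-year failure-free survival.
#' @param surv_5y_post_failure 5-year disease-specific survival after
#'   failure.
#' @param cost_surveillance,cost_recurrent Length-2 vectors `c(mean, se)`
#'   in $/year.
#' @param added_cost_trt Added cost of the experimental arm, $/year while
#'   failure-free.
#' @param utility_ff,utility_recurrent Length-2 vectors `c(mean, se)`.
#' @param wtp Willingness-to-pay, $ per QALY.
#' @param age,max_age Cohort age at entry and horizon cap.
#' @param cycle_length Markov cycle length in years.
#' @param discount Annual discount rate for costs and QALYs.
#' @return A `decision_inputs` list (includes the derived
#'   `control_rate = -log(control_ffs_1y)` and post-failure mortality rate
#'   `-log(surv_5y_post_failure)/5`, both per year).
#' @export
decision_inputs <- function(control_ffs_1y = 0.75,
                            surv_5y_post_failure = 0.79,
                            cost_surveillance = c(mean = 5585, se = 1117),
                            cost_recurrent = c(mean = 17727, se = 3545),
                            added_cost_trt = 147.18,
                            utility_ff = c(mean = 0.997, se = 0.05),
                            utility_recurrent = c(mean = 0.96, se = 0.192),
                            wtp = 150000, age = 68, max_age = 100,
                            cycle_length = 1, discount = 0.03) {
  stopifnot(control_ffs_1y > 0, control_ffs_1y < 1,
            surv_5y_post_failure > 0, surv_5y_post_failure < 1,
            all(cost_surveillance >= 0), all(cost_recurrent >= 0),
            added_cost_trt >= 0, wtp > 0, max_age > age,
            cycle_length > 0, discount >= 0)
  structure(list(control_ffs_1y = control_ffs_1y,
                 control_rate = -log(control_ffs_1y),
                 surv_5y_post_failure = surv_5y_post_failure,
                 mortality_rate = -log(surv_5y_post_failure) / 5,
                 cost_surveillance = cost_surveillance,
                 cost_recurrent = cost_recurrent,
                 added_cost_trt = added_cost_trt,
                 utility_ff = utility_ff,
                 utility_recurrent = utility_recurrent,
                 wtp = wtp, age = age, max_age = max_age,
                 cycle_length = cycle_length, discount = discount,
                 n_cycles = as.integer(floor((max_age - age) / cycle_length))),
            class = "decision_inputs")
}

#' Proposed trial design
#'
#' @param n Total sample size (both arms).
#' @param accrual_years,followup_years Accrual period and mean follow-up
#'   (years); only follow-up enters the expected exposure.
#' @param allocation Fraction of patients allocated to the experimental
#'   arm (default 1:1).
#' @return A `trial_design` list; `person_years` is the expected
#'   experimental-arm exposure `n * allocation * followup_years`.
#' @export
trial_design <- function(n = 616, accrual_years = 3, followup_years = 2.5,
                         allocation = 0.5) {
  stopifnot(n >= 0, followup_years >= 0, allocation > 0, allocation < 1)
  structure(list(n = n, accrual_years = accrual_years,
                 followup_years = followup_years, allocation = allocation,
                 person_years = n * allocation * followup_years),
            class = "trial_design")
}

#' Population projection inputs
#'
#' @param patients_per_year Incident patients per year affected by the
#'   decision.
#' @param horizon_years Years over which trial results inform treatment.
#' @param discount Annual discount rate for the population stream.
#' @return A `population_inputs` list.
#' @export
population_inputs <- function(patients_per_year = 25900,
                              horizon_years = 10, discount = 0.03) {
  stopifnot(patients_per_year > 0, horizon_years >= 1, discount >= 0)
  structure(list(patients_per_year = patients_per_year,
                 horizon_years = horizon_years, discount = discount),
            class = "population_inputs")
}

#' Probabilistic-sensitivity draws of the decision-model parameters
#'
#' Costs are drawn from gamma distributions and utilities from beta
#' distributions, each moment-matched to the published mean and standard
#' error; a parameter with se = 0 is passed through as its mean.  When a
#' utility's (mean, se) admits no beta parameterization the draw falls
#' back to a normal truncated to [0, 1] with a warning.
#'
#' @param inputs A [decision_inputs()].
#' @param n Number of draws.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so nested simulations stay reproducible from one outer seed).
#' @return A data frame with `n` rows and columns `c_surv`, `c_rec`,
#'   `u_ff`, `u_rec`.
#' @export
draw_psa_parameters <- function(inputs, n = 1L, seed = NULL) {
  stopifnot(inherits(inputs, "decision_inputs"))
  if (!is.null(seed)) set.seed(seed)
  draw_gamma <- function(ms) {
    m <- ms[[1]]; s <- ms[[2]]
    if (s == 0) return(rep(m, n))
    stats::rgamma(n, shape = m^2 / s^2, rate = m / s^2)
  }
  draw_beta <- function(ms) {
    m <- ms[[1]]; s <- ms[[2]]
    if (s == 0) return(rep(m, n))
    common <- m * (1 - m) / s^2 - 1
    if (common <= 0) {
      warning("utility (mean, se) admits no beta distribution; ",
              "using a [0, 1]-truncated normal", call. = FALSE)
      lo <- stats::pnorm(0, m, s); hi <- stats::pnorm(1, m, s)
      return(stats::qnorm(stats::runif(n, lo, hi), m, s))
    }
    stats::rbeta(n, common * m, common * (1 - m))
  }
  data.frame(c_surv = draw_gamma(inputs$cost_surveillance),
             c_rec = draw_gamma(inputs$cost_recurrent),
             u_ff = draw_beta(inputs$utility_ff),
             u_rec = draw_beta(inputs$utility_recurrent))
}

#' State-occupancy trace of the three-state cohort model
#'
#' The cohort starts recurrence-free.  Per cycle, the probability of
#' recurrence is `1 - exp(-rate * cycle)`; patients with recurrence die at
#' the post-failure disease-specific mortality rate (derived from 5-year
#' survival); the dead state is absorbing and there is no other exit from
#' the recurrence-free state.
#'
#' @param rate Annual recurrence (failure) rate, >= 0.
#' @param inputs A [decision_inputs()].
#' @param horizon_years Optional horizon override (default: to `max_age`).
#' @param mortality_rate Optional post-failure mortality-rate override.
#' @return Matrix with one row per cycle start (including time 0) and
#'   columns `recurrence_free`, `recurrence`, `dead`; every row sums to 1.
#' @export
markov_trace <- function(rate, inputs, horizon_years = NULL,
                         mortality_rate = NULL) {
  stopifnot(inherits(inputs, "decision_inputs"), rate >= 0)
  cyc <- inputs$cycle_length
  H <- if (is.null(horizon_years)) inputs$n_cycles
       else as.integer(floor(horizon_years / cyc))
  if (H < 1L) stop("horizon shorter than one cycle", call. = FALSE)
  mu <- if (is.null(mortality_rate)) inputs$mortality_rate else mortality_rate
  p_fail <- 1 - exp(-rate * cyc)
  p_die <- 1 - exp(-mu * cyc)
  tr <- matrix(0, H + 1L, 3L,
               dimnames = list(NULL, c("recurrence_free", "recurrence", "dead")))
  tr[1L, ] <- c(1, 0, 0)
  for (k in seq_len(H)) {
    ff <- tr[k, 1L]; fl <- tr[k, 2L]; dd <- tr[k, 3L]
    tr[k + 1L, 1L] <- ff * (1 - p_fail)
    tr[k + 1L, 2L] <- fl * (1 - p_die) + ff * p_fail
    tr[k + 1L, 3L] <- dd + fl * p_die
  }
  tr
}

# Discounted state-years (recurrence-free, recurrence) for a vector of
# annual failure rates -- the vectorized core of the EVSI engine.  State
# membership is counted at cycle starts, no half-cycle correction.
disc_state_years <- function(rate, inputs) {
  cyc <- inputs$cycle_length
  H <- inputs$n_cycles
  s <- exp(-rate * cyc)                 # stay recurrence-free
  q <- exp(-inputs$mortality_rate * cyc)  # survive the recurrence state
  v <- (1 + inputs$discount)^(-cyc)
  ff <- rep(1, length(rate))
  fl <- numeric(length(rate))
  t_ff <- numeric(length(rate))
  t_fl <- numeric(length(rate))
  disc <- 1
  for (k in seq_len(H)) {
    t_ff <- t_ff + disc * ff
    t_fl <- t_fl + disc * fl
    fl <- fl * q + ff * (1 - s)
    ff <- ff * s
    disc <- disc * v
  }
  list(ff = t_ff * cyc, fl = t_fl * cyc)
}

#' Expected discounted cost and QALYs of a trace
#'
#' Accumulates annual surveillance / recurrent-state costs and utilities
#' over the state occupancy (counted at cycle starts), discounting each
#' cycle at the annual rate; the experimental arm additionally accrues
#' the added treatment cost while failure-free.
#'
#' @param trace A [markov_trace()] matrix.
#' @param params One row of [draw_psa_parameters()] (or a list with
#'   `c_surv`, `c_rec`, `u_ff`, `u_rec`).
#' @param inputs A [decision_inputs()].
#' @param arm `"control"` or `"treatment"`.
#' @param discount Annual discount rate (default from `inputs`).
#' @return Named vector `c(cost, qaly)`.
#' @export
expected_outcomes <- function(trace, params, inputs,
                              arm = c("control", "treatment"),
                              discount = NULL) {
  arm <- match.arg(arm)
  if (is.null(discount)) discount <- inputs$discount
  cyc <- inputs$cycle_length
  H <- nrow(trace) - 1L
  disc <- (1 + discount)^(-cyc * (seq_len(H) - 1L))
  ff <- trace[seq_len(H), 1L]
  fl <- trace[seq_len(H), 2L]
  t_ff <- sum(disc * ff) * cyc
  t_fl <- sum(disc * fl) * cyc
  added <- if (arm == "treatment") inputs$added_cost_trt else 0
  cost <- (params$c_surv + added) * t_ff + params$c_rec * t_fl
  qaly <- params$u_ff * t_ff + params$u_rec * t_fl
  c(cost = cost, qaly = qaly)
}

#' Net monetary benefit
#'
#' @param cost,qaly Discounted totals.
#' @param wtp Willingness-to-pay per QALY.
#' @return `wtp * qaly - cost`.
#' @export
net_benefit <- function(cost, qaly, wtp) wtp * qaly - cost

# Mean net benefit of an arm over paired draws of the failure rate and
# PSA parameters (vectors recycle against each other).
arm_expected_nb <- function(rate, psa, inputs, arm) {
  sy <- disc_state_years(rate, inputs)
  added <- if (arm == "treatment") inputs$added_cost_trt else 0
  cost <- (psa$c_surv + added) * sy$ff + psa$c_rec * sy$fl
  qaly <- psa$u_ff * sy$ff + psa$u_rec * sy$fl
  mean(net_benefit(cost, qaly, inputs$wtp))
}

#' Simulate trial event counts
#'
#' Expected experimental-arm exposure is `n * allocation * followup`
#' person-years; observed events are Poisson with mean
#' `rate * person_years`.
#'
#' @param true_rate True annual recurrence rate in the experimental arm.
#' @param design A [trial_design()].
#' @param seed Optional seed (`NULL`: current RNG stream).
#' @return List with `events` and `person_years`.
#' @export
simulate_trial <- function(true_rate, design, seed = NULL) {
  stopifnot(inherits(design, "trial_design"), true_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  py <- design$person_years
  list(events = stats::rpois(1L, true_rate * py), person_years = py)
}

#' Conjugate Poisson-gamma posterior update
#'
#' @param prior A [gamma_prior()] on the event rate.
#' @param events Observed event count (>= 0).
#' @param person_years Observed exposure (>= 0).
#' @return The posterior [gamma_prior()]
#'   `(shape + events, rate + person_years)`.
#' @export
posterior_update <- function(prior, events, person_years) {
  stopifnot(inherits(prior, "gamma_prior"), events >= 0, person_years >= 0)
  gamma_prior(prior$shape + events, prior$rate + person_years)
}

#' Expected value of perfect information (per person)
#'
#' Simulates joint draws of the experimental-arm rate and the PSA
#' parameters, and returns `E[max-arm NB] - max-arm E[NB]`, holding the
#' PSA parameters common across arms within a draw.
#'
#' @param prior A [gamma_prior()] on the experimental-arm rate.
#' @param inputs A [decision_inputs()].
#' @param n_sims Number of simulations (>= 100).
#' @param seed Integer seed.
#' @return EVPI in $ per person (non-negative up to Monte-Carlo error).
#' @export
evpi <- function(prior, inputs, n_sims = 10000L, seed = 1L) {
  stopifnot(inherits(prior, "gamma_prior"), n_sims >= 100L)
  set.seed(seed)
  lam <- stats::rgamma(n_sims, prior$shape, prior$rate)
  psa <- draw_psa_parameters(inputs, n_sims)
  sy_t <- disc_state_years(lam, inputs)
  sy_c <- disc_state_years(inputs$control_rate, inputs)
  nb_t <- net_benefit((psa$c_surv + inputs$added_cost_trt) * sy_t$ff +
                        psa$c_rec * sy_t$fl,
                      psa$u_ff * sy_t$ff + psa$u_rec * sy_t$fl, inputs$wtp)
  nb_c <- net_benefit(psa$c_surv * sy_c$ff + psa$c_rec * sy_c$fl,
                      psa$u_ff * sy_c$ff + psa$u_rec * sy_c$fl, inputs$wtp)
  mean(pmax(nb_t, nb_c)) - max(mean(nb_t), mean(nb_c))
}

#' Expected value of sample information by nested Monte Carlo
#'
#' Outer loop: draw a true experimental-arm recurrence rate from the
#' prior, simulate the proposed trial's event count, and update the prior
#' by Poisson-gamma conjugacy (no sampling in the update).  Inner loop:
#' probabilistic draws of the decision-model parameters and of the
#' posterior rate give each arm's expected net benefit at the
#' willingness-to-pay threshold.  EVSI per person is the mean over outer
#' draws of the best posterior expected net benefit, minus the best prior
#' expected net benefit; the prior term uses `100 * n_inner` draws.
#'
#' @param prior A [gamma_prior()] on the experimental-arm rate.
#' @param inputs A [decision_inputs()].
#' @param design A [trial_design()].
#' @param population Optional [population_inputs()]; when supplied the
#'   result also carries the population-scaled EVSI.
#' @param n_outer,n_inner Nested simulation sizes (>= 10 each).
#' @param seed Integer seed covering every random draw.
#' @return An `evsi_result`: `evsi_per_person`, `mc_se` (outer-loop
#'   standard error), `evsi_population` and `effective_population` (if
#'   `population` given), the prior/posterior settings and seeds.
#' @export
evsi_nested <- function(prior, inputs, design, population = NULL,
                        n_outer = 1000L, n_inner = 1000L, seed = 1L) {
  stopifnot(inherits(prior, "gamma_prior"), inherits(inputs, "decision_inputs"),
            inherits(design, "trial_design"),
            n_outer >= 10L, n_inner >= 10L)
  set.seed(seed)
  # prior (current-information) expected net benefit per arm; a larger
  # sample here since this single baseline enters every EVSI estimate
  n0 <- 100L * n_inner
  lam0 <- stats::rgamma(n0, prior$shape, prior$rate)
  psa0 <- draw_psa_parameters(inputs, n0)
  enb0_t <- arm_expected_nb(lam0, psa0, inputs, "treatment")
  enb0_c <- arm_expected_nb(inputs$control_rate, psa0, inputs, "control")
  base <- max(enb0_t, enb0_c)

  lam_true <- stats::rgamma(n_outer, prior$shape, prior$rate)
  events <- stats::rpois(n_outer, lam_true * design$person_years)
  vmax <- numeric(n_outer)
  for (o in seq_len(n_outer)) {
    post <- posterior_update(prior, events[o], design$person_years)
    lam_post <- stats::rgamma(n_inner, post$shape, post$rate)
    psa <- draw_psa_parameters(inputs, n_inner)
    enb_t <- arm_expected_nb(lam_post, psa, inputs, "treatment")
    enb_c <- arm_expected_nb(inputs$control_rate, psa, inputs, "control")
    if (!is.finite(enb_t) || !is.finite(enb_c))
      stop("non-finite expected net benefit in inner simulation ", o,
           call. = FALSE)
    vmax[o] <- max(enb_t, enb_c)
  }
  evsi_pp <- mean(vmax) - base
  res <- list(evsi_per_person = evsi_pp,
              mc_se = stats::sd(vmax) / sqrt(n_outer),
              prior_enb = c(treatment = enb0_t, control = enb0_c),
              prior = prior, design = design, inputs = inputs,
              n_outer = n_outer, n_inner = n_inner, seed = seed)
  if (!is.null(population)) {
    stopifnot(inherits(population, "population_inputs"))
    scaled <- population_scale(max(evsi_pp, 0), population)
    res$evsi_population <- as.numeric(scaled)
    res$effective_population <- attr(scaled, "effective_population")
    res$population <- population
  }
  structure(res, class = "evsi_result")
}

#' @export
print.evsi_result <- function(x, ...) {
  cat("Expected value of sample information (nested Monte Carlo)\n")
  cat(sprintf("  prior: gamma(shape %.4g, rate %.4g); trial n = %d\n",
              x$prior$shape, x$prior$rate, x$design$n))
  cat(sprintf("  %d outer x %d inner simulations, seed %d\n",
              x$n_outer, x$n_inner, x$seed))
  cat(sprintf("  EVSI per person: $%s  (outer MC se $%s)\n",
              format(round(x$evsi_per_person), big.mark = ","),
              format(round(x$mc_se), big.mark = ",")))
  if (!is.null(x$evsi_population))
    cat(sprintf("  population EVSI: $%s  (effective population %s)\n",
                format(round(x$evsi_population), big.mark = ","),
                format(round(x$effective_population), big.mark = ",")))
  invisible(x)
}

#' Scale a per-person value to the affected population
#'
#' The effective population is the discounted stream of incident patients
#' over the information horizon:
#' `sum_{t=0}^{horizon-1} patients_per_year / (1 + discount)^t`.
#'
#' @param per_person $ per person (>= 0).
#' @param population A [population_inputs()].
#' @return Population total ($), with the effective population attached as
#'   an attribute.
#' @export
population_scale <- function(per_person, population) {
  stopifnot(per_person >= 0, inherits(population, "population_inputs"))
  t <- seq_len(population$horizon_years) - 1L
  eff <- sum(population$patients_per_year / (1 + population$discount)^t)
  structure(per_person * eff, effective_population = eff)
}

#' Serialize an EVSI result as JSON
#'
#' @param x An `evsi_result`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
evsi_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "evsi_result"))
  doc <- list(evsi_per_person = x$evsi_per_person, mc_se = x$mc_se,
              evsi_population = x$evsi_population,
              effective_population = x$effective_population,
              prior = list(shape = x$prior$shape, rate = x$prior$rate),
              trial_n = x$design$n, person_years = x$design$person_years,
              n_outer = x$n_outer, n_inner = x$n_inner, seed = x$seed)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
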