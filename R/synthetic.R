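#' Simulate a three-arm trial with binomial response
#'
#' Emulates the structure of the source randomized trial: per-arm
#' binomial counts of clinically significant responders at given true
#' rates, with Wilson score 95\% confidence intervals. The resulting
#' response proportions can be fed back into a model configuration with
#' [apply_trial()] to produce a runnable perturbed model.
#'
#' @param n_per_arm Named integer vector of arm sizes (all > 0). Default
#'   splits 203 participants approximately evenly across HE/TM/PE.
#' @param true_rates Named vector of true response probabilities in
#'   \[0, 1\], same names as `n_per_arm`.
#' @param seed Optional integer seed.
#' @return Object of class `synthetic_trial`: a data frame with columns
#'   `arm`, `n_randomized`, `n_responders`, `p_hat`, `ci_low`, `ci_high`.
#' @export
simulate_trial <- function(n_per_arm = c(HE = 68L, TM = 68L, PE = 67L),
                           true_rates = c(HE = 0.32, TM = 0.61, PE = 0.42),
                           seed = NULL) {
  if (any(n_per_arm <= 0)) stop("all arm sizes must be > 0")
  if (any(true_rates < 0 | true_rates > 1))
    stop("true rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  arms <- names(n_per_arm)
  k <- stats::rbinom(length(arms), n_per_arm, true_rates[arms])
  ci <- t(vapply(seq_along(arms), function(i) {
    # Wilson score interval (no continuity correction)
    suppressWarnings(
      stats::prop.test(k[i], n_per_arm[i], correct = FALSE)$conf.int)
  }, numeric(2)))
  out <- data.frame(arm = arms,
                    n_randomized = as.integer(n_per_arm),
                    n_responders = as.integer(k),
                    p_hat = k / as.numeric(n_per_arm),
                    ci_low = ci[, 1L], ci_high = ci[, 2L])
  rownames(out) <- NULL
  class(out) <- c("synthetic_trial", "data.frame")
  out
}

#' Feed simulated trial proportions into a model configuration
#'
#' Replaces each arm's response probability base with the trial's observed
#' proportion and its low/high range with the Wilson interval.
#'
#' @param config A [model_config()] whose arm names appear in the trial.
#' @param trial A [simulate_trial()] result.
#' @return A perturbed [model_config()].
#' @export
apply_trial <- function(config, trial) {
  for (i in seq_len(nrow(trial))) {
    nm <- trial$arm[i]
    if (!nm %in% names(config$arms)) next
    config$arms[[nm]]$p_respond$base <- trial$p_hat[i]
    config$arms[[nm]]$p_respond$low <- trial$ci_low[i]
    config$arms[[nm]]$p_respond$high <- trial$ci_high[i]
  }
  config
}

#' Independent expectation oracle for the cohort engine
#'
#' Recomputes an arm's total discounted cost and QALYs by explicit
#' per-cycle matrix-vector expectation, written independently of
#' [run_cohort()] (its own rate conversion, matrix composition, discount
#' schedule and reward accumulation). Used as the engine's correctness
#' oracle: agreement to 1e-9 relative is asserted in the test suite.
#'
#' @param arm Arm name present in `config$arms`.
#' @param config A [model_config()].
#' @return Named numeric vector `c(total_cost, total_qalys)`.
#' @export
expectation_oracle <- function(arm, config) {
  sh <- config$shared
  pol <- config$policy
  cv <- config$conventions
  len <- pol$cycle_length_years
  n <- pol$n_cycles

  # per-cycle probabilities via the hazard form 1 - exp(len * log(1 - p))
  cyc <- function(p) if (p >= 1) 1 else 1 - exp(len * log1p(-p))
  qrel <- cyc(sh$relapse_annual$base)
  qrem <- cyc(sh$remission_annual$base)
  dci <- cyc(sh$mortality_improved_annual$base)
  dni <- cyc(sh$mortality_not_improved_annual$base)

  if (cv$transition_order == "death-first") {
    M <- rbind(c((1 - dci) * (1 - qrel), (1 - dci) * qrel, dci),
               c(qrem * (1 - dni), (1 - qrem) * (1 - dni), dni),
               c(0, 0, 1))
  } else {
    M <- rbind(c((1 - qrel) * (1 - dci), qrel * (1 - dni),
                 (1 - qrel) * dci + qrel * dni),
               c(qrem * (1 - dci), (1 - qrem) * (1 - dni),
                 qrem * dci + (1 - qrem) * dni),
               c(0, 0, 1))
  }

  p <- config$arms[[arm]]$p_respond$base
  v <- c(p, 1 - p, 0)
  if (cv$mortality_start_cycle == 1L)
    v <- c(v[1] * (1 - dci), v[2] * (1 - dni), v[1] * dci + v[2] * dni)

  # occupancy at the start of cycles 1 .. n+1
  states <- vector("list", n + 1L)
  states[[1L]] <- v
  for (k in seq_len(n)) states[[k + 1L]] <- as.vector(states[[k]] %*% M)

  r <- pol$annual_discount_rate
  disc <- vapply(seq_len(n), function(k) {
    past <- k - (pol$discount_start_cycle - 1L)
    if (past <= 0) return(1)
    yrs <- if (cv$discount_method == "stepwise") ceiling(past * len) else past * len
    (1 + r)^(-yrs)
  }, numeric(1))

  u <- c(sh$utility_improved$base, sh$utility_not_improved$base, 0)
  h <- c(sh$hc_cost_improved_annual$base, sh$hc_cost_not_improved_annual$base, 0)
  qal <- cost <- 0
  for (k in seq_len(n)) {
    w <- if (cv$half_cycle) (states[[k]] + states[[k + 1L]]) / 2 else states[[k]]
    qal <- qal + sum(w * u) * len * disc[k]
    if (k >= cv$cost_start_cycle)
      cost <- cost + sum(w * h) * len * disc[k]
  }
  c(total_cost = config$arms[[arm]]$intervention_cost$base + cost,
    total_qalys = qal)
}

#' Individual-level microsimulation oracle
#'
#' Walks `n_individuals` through the state process with per-cycle
#' categorical draws, accruing discounted rewards under the same
#' conventions as the cohort model. The mean cost and QALYs are unbiased
#' estimators of the cohort values; standard errors shrink as 1/sqrt(n).
#' Each individual consumes one dedicated row of a pre-drawn uniform
#' matrix derived from the master seed, so trajectories are reproducible
#' and independent of evaluation order.
#'
#' @param arm Arm name present in `config$arms`.
#' @param config A [model_config()].
#' @param n_individuals Number of simulated patients (>= 1).
#' @param seed Integer master seed.
#' @return Object of class `microsim_result`: list with `n_individuals`,
#'   `seed`, `mean_cost`, `mean_qalys`, `se_cost`, `se_qalys`.
#' @export
microsimulate <- function(arm, config, n_individuals, seed = 1L) {
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  pol <- config$policy
  cv <- config$conventions
  n <- pol$n_cycles
  len <- pol$cycle_length_years
  P <- build_transition_matrix(config)
  cum <- t(apply(P, 1L, cumsum))

  set.seed(seed)
  U <- matrix(stats::runif(n_individuals * (n + 2L)), n_individuals, n + 2L)

  p <- config$arms[[arm]]$p_respond$base
  state <- ifelse(U[, 1L] < p, 1L, 2L)  # 1 improved, 2 not improved, 3 dead
  if (cv$mortality_start_cycle == 1L) {
    d <- c(annual_prob_to_cycle(config$shared$mortality_improved_annual$base, len),
           annual_prob_to_cycle(config$shared$mortality_not_improved_annual$base, len))
    state[U[, 2L] < d[state]] <- 3L
  }

  util <- c(config$shared$utility_improved$base,
            config$shared$utility_not_improved$base, 0)
  hc <- c(config$shared$hc_cost_improved_annual$base,
          config$shared$hc_cost_not_improved_annual$base, 0)
  df <- discount_factor(seq_len(n), pol, cv$discount_method)

  qal <- cost <- numeric(n_individuals)
  for (k in seq_len(n)) {
    u_k <- U[, k + 2L]
    nxt <- ifelse(state == 3L, 3L,
                  ifelse(u_k < cum[state, 1L], 1L,
                         ifelse(u_k < cum[state, 2L], 2L, 3L)))
    w_u <- if (cv$half_cycle) (util[state] + util[nxt]) / 2 else util[state]
    w_h <- if (cv$half_cycle) (hc[state] + hc[nxt]) / 2 else hc[state]
    qal <- qal + w_u * len * df[k]
    if (k >= cv$cost_start_cycle) cost <- cost + w_h * len * df[k]
    state <- nxt
  }
  cost <- cost + config$arms[[arm]]$intervention_cost$base

  structure(
    list(n_individuals = as.integer(n_individuals), seed = as.integer(seed),
         mean_cost = mean(cost), mean_qalys = mean(qal),
         se_cost = stats::sd(cost) / sqrt(n_individuals),
         se_qalys = stats::sd(qal) / sqrt(n_individuals)),
    class = "microsim_result"
  )
}

#' Draw a random, valid model configuration
#'
#' Perturbs the bundled base-case configuration with random response
#' probabilities, rates, utilities, costs and convention flags. Used for
#' property-style verification of the cohort engine against
#' [expectation_oracle()].
#'
#' @param base A [model_config()] template.
#' @return A valid random [model_config()] (uses the global random
#'   stream; seed with [set.seed()]).
#' @export
random_config <- function(base = table1_default_config()) {
  cfg <- base
  for (nm in names(cfg$arms)) {
    cfg$arms[[nm]]$p_respond$base <- stats::runif(1, 0.05, 0.95)
    cfg$arms[[nm]]$intervention_cost$base <- stats::runif(1, 100, 5000)
  }
  cfg$shared$relapse_annual$base <- stats::runif(1, 0, 0.5)
  cfg$shared$remission_annual$base <- stats::runif(1, 0, 0.5)
  cfg$shared$mortality_improved_annual$base <- stats::runif(1, 0, 0.05)
  cfg$shared$mortality_not_improved_annual$base <- stats::runif(1, 0, 0.05)
  u_ni <- stats::runif(1, 0.2, 0.8)
  cfg$shared$utility_not_improved$base <- u_ni
  cfg$shared$utility_improved$base <- stats::runif(1, u_ni, 1)
  cfg$shared$hc_cost_improved_annual$base <- stats::runif(1, 1000, 20000)
  cfg$shared$hc_cost_not_improved_annual$base <- stats::runif(1, 1000, 20000)
  # clear ranges so the perturbed bases cannot violate ordering invariants
  for (nm in names(cfg$shared)) {
    cfg$shared[[nm]]$low <- NA_real_
    cfg$shared[[nm]]$high <- NA_real_
    cfg$shared[[nm]]$distribution <- "fixed"
  }
  for (nm in names(cfg$arms)) {
    for (f in c("p_respond", "intervention_cost")) {
      cfg$arms[[nm]][[f]]$low <- NA_real_
      cfg$arms[[nm]][[f]]$high <- NA_real_
      cfg$arms[[nm]][[f]]$distribution <- "fixed"
    }
  }
  cfg$conventions <- model_conventions(
    transition_order = sample(c("death-first", "transition-first"), 1L),
    mortality_start_cycle = sample(1:2, 1L),
    half_cycle = sample(c(TRUE, FALSE), 1L),
    discount_method = sample(c("stepwise", "per-cycle"), 1L),
    cost_start_cycle = sample(1:2, 1L)
  )
  cfg$policy$annual_discount_rate <- stats::runif(1, 0, 0.1)
  cfg
}
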