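#' Health states of the cohort model
#'
#' The model tracks three states: clinically improved, not clinically
#' improved, and dead (absorbing). Order is fixed and used throughout for
#' occupancy vectors and transition matrices.
#' @export
HEALTH_STATES <- c("improved", "not_improved", "dead")

#' Convert an annual probability to a per-cycle probability
#'
#' Uses the constant-hazard assumption: the per-cycle probability is
#' `1 - (1 - p_annual)^cycle_length_years`, so that composing
#' `1 / cycle_length_years` cycles recovers the annual probability.
#'
#' @param p_annual Annual probability in \[0, 1\] (vectorized).
#' @param cycle_length_years Cycle length in years (> 0).
#' @return Per-cycle probability.
#' @examples
#' annual_prob_to_cycle(0.06, 0.25)  # 0.015350
#' @export
annual_prob_to_cycle <- function(p_annual, cycle_length_years) {
  if (any(p_annual < 0 | p_annual > 1))
    stop("p_annual must lie in [0, 1]")
  if (cycle_length_years <= 0) stop("cycle_length_years must be > 0")
  1 - (1 - p_annual)^cycle_length_years
}

#' Build the per-cycle transition matrix
#'
#' Rows are origin states, columns destinations, in [HEALTH_STATES] order.
#' Relapse (improved to not improved), remission (not improved to
#' improved) and state-specific background mortality are first converted to
#' per-cycle probabilities, then composed as competing risks according to
#' the configuration's `transition_order` convention:
#' `"death-first"` applies mortality and splits the survivors by
#' relapse/remission; `"transition-first"` assigns the relapse/remission
#' split first and then applies the destination-appropriate mortality.
#' The dead row is absorbing.
#'
#' @param config A [model_config()].
#' @return 3 x 3 matrix; each row sums to 1.
#' @export
build_transition_matrix <- function(config) {
  sh <- config$shared
  len <- config$policy$cycle_length_years
  q_rel <- annual_prob_to_cycle(sh$relapse_annual$base, len)
  q_rem <- annual_prob_to_cycle(sh$remission_annual$base, len)
  d_ci <- annual_prob_to_cycle(sh$mortality_improved_annual$base, len)
  d_ni <- annual_prob_to_cycle(sh$mortality_not_improved_annual$base, len)
  P <- matrix(0, 3, 3, dimnames = list(HEALTH_STATES, HEALTH_STATES))
  if (config$conventions$transition_order == "death-first") {
    P["improved", ] <- c((1 - d_ci) * (1 - q_rel), (1 - d_ci) * q_rel, d_ci)
    P["not_improved", ] <- c((1 - d_ni) * q_rem, (1 - d_ni) * (1 - q_rem), d_ni)
  } else {
    # survivors-of-destination: mortality follows the state occupied after
    # the relapse/remission assignment
    P["improved", ] <- c((1 - q_rel) * (1 - d_ci), q_rel * (1 - d_ni),
                         (1 - q_rel) * d_ci + q_rel * d_ni)
    P["not_improved", ] <- c(q_rem * (1 - d_ci), (1 - q_rem) * (1 - d_ni),
                             q_rem * d_ci + (1 - q_rem) * d_ni)
  }
  P["dead", ] <- c(0, 0, 1)
  if (any(P < 0 | P > 1))
    stop("transition matrix entries outside [0, 1]")
  P
}

#' Discount factor for a model cycle
#'
#' Accruals in cycles before `discount_start_cycle` are undiscounted.
#' Under the default `"stepwise"` convention the factor then steps down
#' once per model year: `(1 + r)^-k` where `k` is the (ceiling) number of
#' whole discounting years reached by the cycle. The `"per-cycle"`
#' alternative compounds continuously,
#' `(1 + r)^-(elapsed years past the undiscounted period)`.
#'
#' @param cycle_index Cycle number(s), 1-based (vectorized).
#' @param policy A [policy_settings()].
#' @param method `"stepwise"` or `"per-cycle"`.
#' @return Discount factor(s) in (0, 1\]; non-increasing in `cycle_index`.
#' @examples
#' discount_factor(5, policy_settings())   # 1/1.03
#' discount_factor(20, policy_settings())  # 1/1.03^4
#' @export
discount_factor <- function(cycle_index, policy,
                            method = c("stepwise", "per-cycle")) {
  method <- match.arg(method)
  if (any(cycle_index < 1L | cycle_index > policy$n_cycles))
    stop("cycle_index out of range")
  r <- policy$annual_discount_rate
  len <- policy$cycle_length_years
  start <- policy$discount_start_cycle
  k <- pmax(0, cycle_index - (start - 1L))      # cycles into discounting
  if (method == "stepwise") {
    (1 + r)^(-ceiling(k * len))
  } else {
    (1 + r)^(-k * len)
  }
}

#' Propagate one treatment arm's cohort through the Markov process
#'
#' The cohort enters split by the trial-observed 12-week response
#' (`p_respond` improved, the rest not improved); subsequent cycles follow
#' the transition matrix. Per-cycle QALY increments are
#' occupancy x utility x cycle length x discount factor; health-care cost
#' increments are occupancy x annual state cost x cycle length x discount
#' factor, accruing from the configuration's `cost_start_cycle`. The
#' one-time intervention cost enters undiscounted at time zero. The dead
#' state carries utility 0 and cost 0.
#'
#' @param arm An [arm_parameters()] object, or the name of an arm in
#'   `config$arms`.
#' @param config A [model_config()]; must pass [validate_config()].
#' @return Object of class `arm_result`: a list with `arm_name`,
#'   `p_respond`, `intervention_cost`, `healthcare_cost` (discounted),
#'   `total_cost`, `total_qalys`, `total_qalys_undiscounted`,
#'   `total_cost_undiscounted` and `trace` (a per-cycle data frame with
#'   occupancies, discount factor and cost/QALY increments).
#' @examples
#' res <- run_cohort("TM", table1_default_config())
#' round(res$total_qalys, 2)
#' @export
run_cohort <- function(arm, config) {
  if (is.character(arm)) {
    if (!arm %in% names(config$arms))
      stop(sprintf("unknown arm '%s'; arms: %s", arm,
                   paste(names(config$arms), collapse = ", ")))
    arm <- config$arms[[arm]]
  }
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))

  pol <- config$policy
  cv <- config$conventions
  n <- pol$n_cycles
  len <- pol$cycle_length_years
  P <- build_transition_matrix(config)

  p <- arm$p_respond$base
  occ <- matrix(0, n + 1L, 3L, dimnames = list(NULL, HEALTH_STATES))
  start <- c(p, 1 - p, 0)
  if (cv$mortality_start_cycle == 1L) {
    d_ci <- annual_prob_to_cycle(config$shared$mortality_improved_annual$base, len)
    d_ni <- annual_prob_to_cycle(config$shared$mortality_not_improved_annual$base, len)
    start <- c(p * (1 - d_ci), (1 - p) * (1 - d_ni),
               p * d_ci + (1 - p) * d_ni)
  }
  occ[1L, ] <- start
  for (c in 2:(n + 1L)) occ[c, ] <- occ[c - 1L, ] %*% P

  util <- c(config$shared$utility_improved$base,
            config$shared$utility_not_improved$base, 0)
  hc <- c(config$shared$hc_cost_improved_annual$base,
          config$shared$hc_cost_not_improved_annual$base, 0)
  df <- discount_factor(seq_len(n), pol, cv$discount_method)

  reward_occ <- if (cv$half_cycle) {
    (occ[seq_len(n), , drop = FALSE] + occ[seq_len(n) + 1L, , drop = FALSE]) / 2
  } else {
    occ[seq_len(n), , drop = FALSE]
  }
  qaly_inc <- as.vector(reward_occ %*% util) * len
  cost_inc <- as.vector(reward_occ %*% hc) * len
  cost_inc[seq_len(min(cv$cost_start_cycle - 1L, n))] <- 0

  trace <- data.frame(
    cycle = seq_len(n),
    improved = occ[seq_len(n), "improved"],
    not_improved = occ[seq_len(n), "not_improved"],
    dead = occ[seq_len(n), "dead"],
    discount = df,
    cost = cost_inc,
    cost_discounted = cost_inc * df,
    qaly = qaly_inc,
    qaly_discounted = qaly_inc * df
  )

  ic <- arm$intervention_cost$base
  structure(
    list(arm_name = arm$arm_name,
         p_respond = p,
         intervention_cost = ic,
         healthcare_cost = sum(trace$cost_discounted),
         total_cost = ic + sum(trace$cost_discounted),
         total_qalys = sum(trace$qaly_discounted),
         total_cost_undiscounted = ic + sum(trace$cost),
         total_qalys_undiscounted = sum(trace$qaly),
         trace = trace),
    class = "arm_result"
  )
}

#' Run every arm of a configuration
#'
#' @param config A [model_config()].
#' @return Named list of [run_cohort()] results, one per arm.
#' @export
run_model <- function(config) {
  lapply(config$arms, run_cohort, config = config)
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm %s: %.4f QALYs, $%.2f total cost ($%.2f intervention + $%.2f health care)\n",
              x$arm_name, x$total_qalys, x$total_cost,
              x$intervention_cost, x$healthcare_cost))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle: state occupancies, discount factor, and undiscounted
#' and discounted cost and QALY increments.
#'
#' @param result An `arm_result` from [run_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
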