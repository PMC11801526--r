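#' Incremental cost-effectiveness of one arm against a reference
#'
#' Computes unrounded incremental cost, QALYs and response, the dominance
#' verdict, the ICER (only when the signs of the cost and effect
#' differences agree), the incremental cost per additional responder, and
#' the net monetary benefit `NMB = wtp * delta_qalys - delta_cost`.
#'
#' Verdicts: `"dominant"` (cheaper and more effective), `"dominated"`
#' (costlier and less effective), `"icer"` (signs agree, a ratio is
#' meaningful), `"cost-only"` (no QALY difference but a cost difference;
#' no ratio reported) or `"tie"` (no difference at all).
#'
#' @param intervention,reference `arm_result` objects from [run_cohort()]
#'   produced under the same configuration.
#' @param wtp Willingness to pay per QALY (USD).
#' @return Object of class `incremental_result`.
#' @examples
#' cfg <- table1_default_config()
#' incremental_analysis(run_cohort("TM", cfg), run_cohort("PE", cfg), 50000)
#' @export
incremental_analysis <- function(intervention, reference, wtp) {
  dC <- intervention$total_cost - reference$total_cost
  dE <- intervention$total_qalys - reference$total_qalys
  dR <- intervention$p_respond - reference$p_respond
  nmb <- wtp * dE - dC
  verdict <- if (dC < 0 && dE > 0) "dominant"
  else if (dC > 0 && dE < 0) "dominated"
  else if (dE == 0 && dC == 0) "tie"
  else if (dE == 0) "cost-only"
  else "icer"
  icer <- if (verdict == "icer") dC / dE else NA_real_
  icer_resp <- if (verdict == "icer" && dR != 0) dC / dR else NA_real_
  structure(
    list(intervention = intervention$arm_name,
         reference = reference$arm_name,
         delta_cost = dC, delta_qalys = dE, delta_response = dR,
         verdict = verdict,
         icer_per_qaly = icer, icer_per_responder = icer_resp,
         wtp = wtp, nmb = nmb,
         note = if (verdict == "cost-only") "cost-only difference" else NA_character_),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost $%.0f, dQALYs %.4f, %s", x$intervention,
              x$reference, x$delta_cost, x$delta_qalys, x$verdict))
  if (x$verdict == "icer")
    cat(sprintf(" ($%.0f/QALY)", x$icer_per_qaly))
  cat(sprintf(", NMB $%.0f at WTP $%.0f/QALY\n", x$nmb, x$wtp))
  invisible(x)
}

#' Intervention cost per clinically improved participant
#'
#' Divides the per-participant intervention cost by the response rate,
#' rounded to whole dollars for reporting.
#'
#' @param intervention_cost One-time intervention cost (USD).
#' @param p_respond Response probability (> 0).
#' @return Cost per responder, in whole USD.
#' @examples
#' cost_per_responder(2822, 0.42)  # 6719
#' @export
cost_per_responder <- function(intervention_cost, p_respond) {
  if (p_respond <= 0) stop("no responders: p_respond must be > 0")
  round(intervention_cost / p_respond)
}

# Shared optimality rule: highest NMB, ties broken by lowest cost then
# lexicographic arm name. Used by optimal_strategy, run_psa and ceac so the
# CEAC reproduces the PSA tally exactly.
.pick_optimal <- function(arm_names, costs, qalys, wtp) {
  nmb <- wtp * qalys - costs
  ord <- order(-nmb, costs, arm_names)
  best <- ord[1L]
  tie <- sum(nmb == nmb[best]) > 1L
  structure(arm_names[best], tie = tie)
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' Returns the arm maximizing net monetary benefit
#' `wtp * total_qalys - total_cost`. Ties are broken by lowest total cost,
#' then lexicographic arm name; a tie is flagged in the `"tie"` attribute.
#'
#' @param results List of `arm_result` objects (>= 2).
#' @param wtp Willingness to pay per QALY (USD).
#' @return Arm name (character scalar) with logical attribute `"tie"`.
#' @export
optimal_strategy <- function(results, wtp) {
  if (length(results) < 2L) stop("need at least two arms")
  .pick_optimal(vapply(results, `[[`, character(1), "arm_name"),
                vapply(results, `[[`, numeric(1), "total_cost"),
                vapply(results, `[[`, numeric(1), "total_qalys"),
                wtp)
}

#' Scale per-person savings to a treated population
#'
#' Linear budget-impact projection for reporting: per-person incremental
#' savings times the number of patients treated.
#'
#' @param delta_cost_per_person Per-person cost difference (USD).
#' @param n_patients Number of patients (>= 0).
#' @return Total USD.
#' @export
scale_savings <- function(delta_cost_per_person, n_patients) {
  if (n_patients < 0) stop("n_patients must be >= 0")
  delta_cost_per_person * n_patients
}

#' Cost-effectiveness efficiency frontier
#'
#' Orders arms by effectiveness and removes strictly dominated arms
#' (costlier and no more effective than another) and extendedly dominated
#' arms (ICER against the previous frontier arm exceeding that of the next).
#'
#' @param results List of `arm_result` objects.
#' @return Data frame of frontier arms with incremental ICERs (`NA` for the
#'   least effective frontier arm).
#' @export
efficiency_frontier <- function(results) {
  d <- data.frame(
    arm = vapply(results, `[[`, character(1), "arm_name"),
    cost = vapply(results, `[[`, numeric(1), "total_cost"),
    qalys = vapply(results, `[[`, numeric(1), "total_qalys")
  )
  d <- d[order(d$qalys, d$cost), ]
  # strict dominance: drop any arm with a cheaper, at-least-as-effective rival
  keep <- vapply(seq_len(nrow(d)), function(i)
    !any(d$qalys >= d$qalys[i] & d$cost < d$cost[i]), logical(1))
  d <- d[keep, , drop = FALSE]
  # extended dominance: enforce increasing ICERs along the frontier
  repeat {
    if (nrow(d) < 3L) break
    icer <- c(NA, diff(d$cost) / diff(d$qalys))
    drop <- which(diff(icer[-1]) < 0)  # ICER decreases at the next step
    if (!length(drop)) break
    d <- d[-(drop[1L] + 1L), , drop = FALSE]
  }
  d$icer <- c(NA, diff(d$cost) / diff(d$qalys))
  rownames(d) <- NULL
  d
}
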