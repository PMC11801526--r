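# Enumerate every samplable parameter of a config with set/get accessors,
# in a fixed deterministic order (arms in config order: response then
# intervention cost; then the shared block).
.param_table <- function(config) {
  out <- list()
  for (nm in names(config$arms)) {
    out[[paste0("p_respond_", nm)]] <- list(
      spec = config$arms[[nm]]$p_respond,
      set = local({
        nm <- nm
        function(cfg, v) { cfg$arms[[nm]]$p_respond$base <- v; cfg }
      }))
    out[[paste0("intervention_cost_", nm)]] <- list(
      spec = config$arms[[nm]]$intervention_cost,
      set = local({
        nm <- nm
        function(cfg, v) { cfg$arms[[nm]]$intervention_cost$base <- v; cfg }
      }))
  }
  for (nm in names(config$shared)) {
    out[[nm]] <- list(
      spec = config$shared[[nm]],
      set = local({
        nm <- nm
        function(cfg, v) { cfg$shared[[nm]]$base <- v; cfg }
      }))
  }
  out
}

# Strip ranges/distributions so per-draw configs with sampled bases (which
# may legitimately fall outside the printed 95% ranges) stay valid.
.neutralize_ranges <- function(config) {
  for (nm in names(config$shared)) {
    config$shared[[nm]]$low <- NA_real_
    config$shared[[nm]]$high <- NA_real_
    config$shared[[nm]]$distribution <- "fixed"
  }
  for (a in names(config$arms)) {
    for (f in c("p_respond", "intervention_cost")) {
      config$arms[[a]][[f]]$low <- NA_real_
      config$arms[[a]][[f]]$high <- NA_real_
      config$arms[[a]][[f]]$distribution <- "fixed"
    }
  }
  config
}

.pair_nmb <- function(config, pair, wtp) {
  a <- run_cohort(pair[1L], config)
  b <- run_cohort(pair[2L], config)
  wtp * (a$total_qalys - b$total_qalys) - (a$total_cost - b$total_cost)
}

#' One-way tornado sensitivity analysis of incremental NMB
#'
#' For each parameter with a low/high range, reruns the full model with
#' that parameter at its low and at its high value (all others at base) and
#' records the incremental net monetary benefit of the arm pair. Parameters
#' without a range (fixed) are skipped with a warning.
#'
#' @param config A [model_config()].
#' @param pair Character pair `c(intervention, reference)`; default TM vs
#'   PE.
#' @param wtp Willingness to pay per QALY; defaults to the policy value.
#' @return Data frame of class `tornado_result` with columns `parameter`,
#'   `nmb_at_low`, `nmb_at_high`, `bar_width`, sorted by decreasing
#'   `bar_width` (ties broken by parameter name).
#' @export
one_way_tornado <- function(config, pair = c("TM", "PE"),
                            wtp = config$policy$wtp_per_qaly) {
  params <- .param_table(config)
  has_range <- vapply(params, function(p)
    !is.na(p$spec$low) && !is.na(p$spec$high), logical(1))
  if (any(!has_range))
    warning("skipping parameter(s) without a range: ",
            paste(names(params)[!has_range], collapse = ", "))
  params <- params[has_range]
  rows <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    data.frame(parameter = nm,
               nmb_at_low = .pair_nmb(p$set(config, p$spec$low), pair, wtp),
               nmb_at_high = .pair_nmb(p$set(config, p$spec$high), pair, wtp))
  })
  out <- do.call(rbind, rows)
  out$bar_width <- abs(out$nmb_at_high - out$nmb_at_low)
  out <- out[order(-out$bar_width, out$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Fit a sampling distribution to a parameter spec
#'
#' Beta and gamma samplers are moment-matched so draws have mean equal to
#' the base value and standard deviation `(high - low) / 3.92` (the range
#' read as a central 95\% interval). Triangular samplers use
#' (min = low, mode = base, max = high). Fixed samplers always return the
#' base value.
#'
#' @param spec A [parameter_spec()] with a valid range for its
#'   distribution.
#' @return Object of class `distribution_sampler` with elements `name`,
#'   `family`, fitted `constants`, and `draw(n)`, a function returning `n`
#'   random draws using R's global random stream.
#' @export
fit_sampler <- function(spec) {
  fam <- spec$distribution
  constants <- switch(fam,
    fixed = list(base = spec$base),
    beta = {
      if (spec$base <= 0 || spec$base >= 1)
        stop(sprintf("%s: beta distribution requires base in (0, 1)", spec$name))
      m <- spec$base
      s <- (spec$high - spec$low) / 3.92
      k <- m * (1 - m) / s^2 - 1
      if (k <= 0)
        stop(sprintf("%s: range too wide for a beta fit at this mean", spec$name))
      list(shape1 = m * k, shape2 = (1 - m) * k)
    },
    gamma = {
      m <- spec$base
      s <- (spec$high - spec$low) / 3.92
      list(shape = m^2 / s^2, rate = m / s^2)
    },
    triangular = list(min = spec$low, mode = spec$base, max = spec$high)
  )
  draw <- switch(fam,
    fixed = function(n) rep(constants$base, n),
    beta = function(n) stats::rbeta(n, constants$shape1, constants$shape2),
    gamma = function(n) stats::rgamma(n, constants$shape, constants$rate),
    triangular = function(n) {
      a <- constants$min; b <- constants$max; m <- constants$mode
      if (a == b) return(rep(a, n))
      u <- stats::runif(n)
      fc <- (m - a) / (b - a)
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (m - a)),
             b - sqrt((1 - u) * (b - a) * (b - m)))
    }
  )
  structure(list(name = spec$name, family = fam, constants = constants,
                 draw = draw),
            class = "distribution_sampler")
}

#' Probabilistic sensitivity analysis
#'
#' Samples every non-fixed parameter once per draw from its fitted
#' distribution (parameters are shared across arms within a draw:
#' utilities, costs and rates are population quantities), reruns every arm,
#' and records per-draw costs, QALYs, pairwise dominance and the
#' NMB-optimal arm. Sampled probabilities or utilities falling outside
#' \[0, 1\] are redrawn and counted (impossible for beta/triangular by
#' construction; the guard covers degenerate fits).
#'
#' @param config A [model_config()].
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed; the result is fully reproducible given the
#'   seed (default 20250101).
#' @param wtp Willingness to pay per QALY; defaults to the policy value.
#' @return Object of class `psa_result`: `n_draws`, `seed`, `wtp`,
#'   `params` (matrix of sampled values, one column per parameter),
#'   `arms` (list per arm with `cost` and `qalys` vectors), `optimal`
#'   (per-draw optimal arm name), `tallies` (see [psa_tallies()]) and
#'   `n_redraws`.
#' @export
run_psa <- function(config, n_draws = 1000L, seed = 20250101L,
                    wtp = config$policy$wtp_per_qaly) {
  if (n_draws < 1L) stop("n_draws must be >= 1")
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  set.seed(seed)

  params <- .param_table(config)
  n_redraws <- 0L
  draws <- matrix(NA_real_, n_draws, length(params),
                  dimnames = list(NULL, names(params)))
  for (j in seq_along(params)) {
    sampler <- fit_sampler(params[[j]]$spec)
    x <- sampler$draw(n_draws)
    if (params[[j]]$spec$role %in% c("probability", "utility", "annual_rate")) {
      bad <- which(x < 0 | x > 1)
      guard <- 0L
      while (length(bad) && guard < 100L) {
        n_redraws <- n_redraws + length(bad)
        x[bad] <- sampler$draw(length(bad))
        bad <- which(x < 0 | x > 1)
        guard <- guard + 1L
      }
    }
    draws[, j] <- x
  }

  arm_names <- names(config$arms)
  template <- .neutralize_ranges(config)
  costs <- qalys <- matrix(NA_real_, n_draws, length(arm_names),
                           dimnames = list(NULL, arm_names))
  for (i in seq_len(n_draws)) {
    cfg_i <- template
    for (j in seq_along(params))
      cfg_i <- params[[j]]$set(cfg_i, draws[i, j])
    for (a in arm_names) {
      r <- run_cohort(a, cfg_i)
      costs[i, a] <- r$total_cost
      qalys[i, a] <- r$total_qalys
    }
  }
  optimal <- vapply(seq_len(n_draws), function(i)
    as.character(.pick_optimal(arm_names, costs[i, ], qalys[i, ], wtp)),
    character(1))

  psa <- structure(
    list(n_draws = as.integer(n_draws), seed = as.integer(seed), wtp = wtp,
         params = draws,
         arms = lapply(arm_names, function(a)
           list(cost = costs[, a], qalys = qalys[, a])),
         optimal = optimal,
         n_redraws = n_redraws),
    class = "psa_result"
  )
  names(psa$arms) <- arm_names
  psa$tallies <- lapply(config$policy$reference_arm_pairs, function(pair) {
    if (all(pair %in% arm_names)) psa_tallies(psa, pair) else NULL
  })
  names(psa$tallies) <- vapply(config$policy$reference_arm_pairs,
                               paste, character(1), collapse = "_vs_")
  psa
}

#' Summary tallies for an arm pair from a PSA
#'
#' @param psa A [run_psa()] result.
#' @param pair Character pair `c(intervention, reference)`.
#' @return List with `dominant` (fraction of draws where the intervention
#'   is cheaper and more effective than the reference),
#'   `reference_more_effective_not_ce` (reference more effective but its
#'   NMB below the intervention's, i.e. its extra cost not worth the QALY
#'   gain at the analysis WTP), `optimal` (fraction of draws in which the
#'   intervention is NMB-optimal among all arms) and `n_draws`.
#' @export
psa_tallies <- function(psa, pair) {
  a <- psa$arms[[pair[1L]]]
  b <- psa$arms[[pair[2L]]]
  nmb_a <- psa$wtp * a$qalys - a$cost
  nmb_b <- psa$wtp * b$qalys - b$cost
  list(intervention = pair[1L], reference = pair[2L],
       dominant = mean(a$cost < b$cost & a$qalys > b$qalys),
       reference_more_effective_not_ce = mean(b$qalys > a$qalys & nmb_b < nmb_a),
       optimal = mean(psa$optimal == pair[1L]),
       n_draws = psa$n_draws)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay point, the probability (fraction of PSA
#' draws) that each arm is NMB-optimal, using the same tie-break rule as
#' [optimal_strategy()]. Probabilities sum to 1 across arms at every
#' point; the curve at the analysis WTP reproduces the PSA optimality
#' tally exactly.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Non-empty numeric vector of WTP values (USD/QALY).
#' @return Data frame: `wtp` plus one probability column per arm.
#' @export
ceac <- function(psa, wtp_grid) {
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty")
  arm_names <- names(psa$arms)
  costs <- sapply(psa$arms, `[[`, "cost")
  qalys <- sapply(psa$arms, `[[`, "qalys")
  if (length(arm_names) == 1L) {
    costs <- matrix(costs, ncol = 1L, dimnames = list(NULL, arm_names))
    qalys <- matrix(qalys, ncol = 1L, dimnames = list(NULL, arm_names))
  }
  out <- lapply(wtp_grid, function(w) {
    best <- vapply(seq_len(psa$n_draws), function(i)
      as.character(.pick_optimal(arm_names, costs[i, ], qalys[i, ], w)),
      character(1))
    p <- vapply(arm_names, function(a) mean(best == a), numeric(1))
    c(wtp = w, p)
  })
  as.data.frame(do.call(rbind, out))
}
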