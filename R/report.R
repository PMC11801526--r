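#' Published benchmark results for calibration
#'
#' The printed per-arm deterministic results of the source analysis:
#' cumulative discounted QALYs per person and total five-year cost per
#' person (intervention plus discounted health care) for the HE, TM and PE
#' arms. Used as the calibration target when grid-searching the
#' within-cycle convention flags ([calibrate_conventions()]), never as a
#' substitute for model output.
#'
#' @return Data frame with columns `arm`, `qalys`, `total_cost`.
#' @export
table2_reference <- function() {
  data.frame(arm = c("HE", "TM", "PE"),
             qalys = c(2.66, 2.75, 2.69),
             total_cost = c(45679, 42982, 46730))
}

#' Grid-search convention flags against the published benchmark
#'
#' Runs the deterministic model under every combination of the five
#' within-cycle convention flags (transition order, mortality start cycle,
#' half-cycle correction, discount stepping, cost accrual start: 32
#' combinations) and ranks them by the maximum absolute relative error
#' against the published per-arm QALYs and total costs.
#'
#' @param config A [model_config()]; its convention block is overridden by
#'   the grid.
#' @param reference Benchmark data frame as from [table2_reference()].
#' @return List with `grid` (all combinations with residuals, sorted
#'   best-first) and `best` (the winning [model_conventions()]).
#' @export
calibrate_conventions <- function(config, reference = table2_reference()) {
  grid <- expand.grid(
    transition_order = c("death-first", "transition-first"),
    mortality_start_cycle = 1:2,
    half_cycle = c(FALSE, TRUE),
    discount_method = c("stepwise", "per-cycle"),
    cost_start_cycle = 1:2,
    stringsAsFactors = FALSE
  )
  maxerr <- vapply(seq_len(nrow(grid)), function(i) {
    config$conventions <- model_conventions(
      transition_order = grid$transition_order[i],
      mortality_start_cycle = grid$mortality_start_cycle[i],
      half_cycle = grid$half_cycle[i],
      discount_method = grid$discount_method[i],
      cost_start_cycle = grid$cost_start_cycle[i]
    )
    res <- run_model(config)
    err <- vapply(seq_len(nrow(reference)), function(k) {
      r <- res[[reference$arm[k]]]
      max(abs(r$total_qalys / reference$qalys[k] - 1),
          abs(r$total_cost / reference$total_cost[k] - 1))
    }, numeric(1))
    max(err)
  }, numeric(1))
  grid$max_rel_error <- maxerr
  grid <- grid[order(grid$max_rel_error), ]
  rownames(grid) <- NULL
  best <- model_conventions(
    transition_order = grid$transition_order[1L],
    mortality_start_cycle = grid$mortality_start_cycle[1L],
    half_cycle = grid$half_cycle[1L],
    discount_method = grid$discount_method[1L],
    cost_start_cycle = grid$cost_start_cycle[1L]
  )
  list(grid = grid, best = best)
}

#' Full incremental cost-effectiveness report
#'
#' Runs every arm and assembles the per-arm block (response rate, QALYs,
#' intervention / health-care / total costs) and one incremental comparison
#' per reference pair (delta cost, delta QALYs, delta response,
#' ICER-or-dominance verdict, cost per additional responder, NMB), all at
#' full precision.
#'
#' @param config A [model_config()].
#' @param wtp Willingness to pay per QALY; defaults to the policy value.
#' @return Object of class `cea_report`: list with `arms` and `pairs` data
#'   frames, plus `wtp` and `optimal` (the NMB-optimal arm).
#' @export
cea_report <- function(config, wtp = config$policy$wtp_per_qaly) {
  results <- run_model(config)
  arms <- do.call(rbind, lapply(results, function(r)
    data.frame(arm = r$arm_name, p_respond = r$p_respond,
               qalys = r$total_qalys,
               intervention_cost = r$intervention_cost,
               healthcare_cost = r$healthcare_cost,
               total_cost = r$total_cost,
               cost_per_responder = cost_per_responder(r$intervention_cost,
                                                       r$p_respond))))
  rownames(arms) <- NULL
  pairs <- do.call(rbind, lapply(config$policy$reference_arm_pairs, function(pr) {
    inc <- incremental_analysis(results[[pr[1L]]], results[[pr[2L]]], wtp)
    data.frame(intervention = inc$intervention, reference = inc$reference,
               delta_cost = inc$delta_cost, delta_qalys = inc$delta_qalys,
               delta_response = inc$delta_response, verdict = inc$verdict,
               icer_per_qaly = inc$icer_per_qaly,
               icer_per_responder = inc$icer_per_responder, nmb = inc$nmb)
  }))
  structure(list(arms = arms, pairs = pairs, wtp = wtp,
                 optimal = as.character(optimal_strategy(results, wtp))),
            class = "cea_report")
}

#' @export
print.cea_report <- function(x, ...) {
  cat("Per-arm results (5-year horizon):\n")
  a <- x$arms
  a$qalys <- round(a$qalys, 2)
  for (col in c("intervention_cost", "healthcare_cost", "total_cost"))
    a[[col]] <- round(a[[col]])
  print(a, row.names = FALSE)
  cat(sprintf("\nIncremental comparisons (WTP $%s/QALY):\n",
              format(x$wtp, big.mark = ",")))
  p <- x$pairs
  p$delta_qalys <- round(p$delta_qalys, 2)
  for (col in c("delta_cost", "icer_per_qaly", "icer_per_responder", "nmb"))
    p[[col]] <- round(p[[col]])
  print(p, row.names = FALSE)
  cat(sprintf("\nOptimal strategy: %s\n", x$optimal))
  invisible(x)
}

#' Write a CEA report as CSV and JSON
#'
#' Writes `arms.csv`, `comparisons.csv` and `report.json` (full precision)
#' under `dir`.
#'
#' @param report A [cea_report()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cea_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$arms, file.path(dir, "arms.csv"), row.names = FALSE)
  utils::write.csv(report$pairs, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(wtp = report$wtp, optimal = report$optimal,
         arms = report$arms, pairs = report$pairs),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}

#' Write tornado entries as CSV
#'
#' @param tornado A [one_way_tornado()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(tornado, path) {
  utils::write.csv(as.data.frame(tornado), path, row.names = FALSE)
  invisible(path)
}

#' Write PSA outputs: scatter CSV, tallies JSON and CEAC CSV
#'
#' The scatter file holds the per-draw incremental cost and QALYs of the
#' requested pair (cost-effectiveness plane coordinates); tallies are the
#' pairwise dominance/optimality fractions; the CEAC file holds per-arm
#' acceptability curves over `wtp_grid`.
#'
#' @param psa A [run_psa()] result.
#' @param pair Character pair `c(intervention, reference)` for the scatter.
#' @param dir Output directory (created if needed).
#' @param wtp_grid WTP grid for the CEAC (default $0 to $150,000 by
#'   $5,000).
#' @return `dir`, invisibly.
#' @export
write_psa_outputs <- function(psa, pair = c("TM", "PE"), dir,
                              wtp_grid = seq(0, 150000, by = 5000)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- psa$arms[[pair[1L]]]
  b <- psa$arms[[pair[2L]]]
  scatter <- data.frame(draw = seq_len(psa$n_draws),
                        delta_cost = a$cost - b$cost,
                        delta_qalys = a$qalys - b$qalys)
  utils::write.csv(scatter, file.path(dir, "psa_scatter.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(list(n_draws = psa$n_draws, seed = psa$seed, wtp = psa$wtp,
           n_redraws = psa$n_redraws),
      psa$tallies),
    file.path(dir, "psa_tallies.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(ceac(psa, wtp_grid), file.path(dir, "ceac.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to reproduce a run byte-for-byte: config
#' path and MD5 hash, convention flags, seed, package version and
#' timestamp.
#'
#' @param config_path Path to the configuration file used.
#' @param conventions A [model_conventions()] object.
#' @param seed Integer seed used (or `NA`).
#' @return Object of class `run_manifest` (a list).
#' @export
run_manifest <- function(config_path, conventions, seed = NA_integer_) {
  structure(
    list(config_path = config_path,
         config_md5 = unname(tools::md5sum(config_path)),
         conventions = unclass(conventions),
         seed = seed,
         package_version = as.character(utils::packageVersion("ptsdcea")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}
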