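#' Define a single model input parameter
#'
#' A parameter spec carries the base-case value used in the deterministic
#' model together with the low/high range and sampling distribution used by
#' the one-way and probabilistic sensitivity analyses.
#'
#' @param name Identifier, e.g. `"utility_improved"`.
#' @param base Base-case value (units depend on `role`).
#' @param low,high Range endpoints for sensitivity analyses. Read as a
#'   central 95\% interval when fitting beta/gamma samplers, and as hard
#'   bounds for triangular sampling. Omit (or `NA`) for fixed parameters.
#' @param distribution Sampling family: `"beta"`, `"triangular"`, `"gamma"`
#'   or `"fixed"`.
#' @param role What the number means: `"probability"`, `"annual_rate"`,
#'   `"utility"`, `"cost_one_time"` or `"cost_annual"`. Probabilities and
#'   utilities are confined to \[0, 1\]; costs must be non-negative.
#' @return An object of class `parameter_spec`.
#' @seealso [validate_config()] which checks the range/role invariants.
#' @export
parameter_spec <- function(name, base, low = NA_real_, high = NA_real_,
                           distribution = c("fixed", "beta", "triangular", "gamma"),
                           role = c("probability", "annual_rate", "utility",
                                    "cost_one_time", "cost_annual")) {
  distribution <- match.arg(distribution)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(base), length(base) == 1L)
  structure(
    list(name = name, base = as.numeric(base),
         low = as.numeric(low), high = as.numeric(high),
         distribution = distribution, role = role),
    class = "parameter_spec"
  )
}

#' Per-arm parameters: response probability and intervention cost
#'
#' @param arm_name Arm label (e.g. `"TM"`, `"PE"`, `"HE"`).
#' @param p_respond [parameter_spec()] for the probability of clinically
#'   significant improvement at the first (12-week) assessment.
#' @param intervention_cost [parameter_spec()] for the one-time cost of
#'   delivering the intervention (2023 USD).
#' @return An object of class `arm_parameters`.
#' @export
arm_parameters <- function(arm_name, p_respond, intervention_cost) {
  stopifnot(inherits(p_respond, "parameter_spec"),
            inherits(intervention_cost, "parameter_spec"))
  structure(list(arm_name = arm_name, p_respond = p_respond,
                 intervention_cost = intervention_cost),
            class = "arm_parameters")
}

#' Policy settings: horizon, discounting and willingness to pay
#'
#' @param cycle_length_years Cycle length in years (default 0.25, i.e.
#'   three months, matching the trial's assessment interval).
#' @param n_cycles Number of cycles (default 20, a five-year horizon).
#' @param annual_discount_rate Annual discount rate applied to costs and
#'   QALYs (default 0.03).
#' @param discount_start_cycle First cycle whose accruals are discounted
#'   (default 5: the first model year is undiscounted).
#' @param wtp_per_qaly Willingness to pay per QALY in USD (default 50000).
#' @param reference_arm_pairs Ordered list of `c(intervention, reference)`
#'   arm-name pairs reported in the incremental analysis.
#' @return An object of class `policy_settings`.
#' @export
policy_settings <- function(cycle_length_years = 0.25,
                            n_cycles = 20L,
                            annual_discount_rate = 0.03,
                            discount_start_cycle = 5L,
                            wtp_per_qaly = 50000,
                            reference_arm_pairs = list(c("TM", "HE"),
                                                       c("TM", "PE"),
                                                       c("PE", "HE"))) {
  structure(
    list(cycle_length_years = cycle_length_years,
         n_cycles = as.integer(n_cycles),
         annual_discount_rate = annual_discount_rate,
         discount_start_cycle = as.integer(discount_start_cycle),
         wtp_per_qaly = wtp_per_qaly,
         reference_arm_pairs = reference_arm_pairs),
    class = "policy_settings"
  )
}

#' Within-cycle modelling conventions
#'
#' The published deterministic results were produced with commercial
#' decision-tree software whose within-cycle conventions are not part of the
#' printed input table. Each convention that could plausibly differ is
#' exposed as a flag; [calibrate_conventions()] grid-searches all
#' combinations against the printed benchmark results. The defaults are the
#' calibrated best-fitting set.
#'
#' @param transition_order Within a cycle, apply state-specific death before
#'   the relapse/remission split (`"death-first"`, default) or after
#'   (`"transition-first"`).
#' @param mortality_start_cycle 1 (default) applies background mortality to
#'   the initial response split; 2 lets deaths enter only at the first
#'   transition.
#' @param half_cycle Use a trapezoidal half-cycle correction for rewards
#'   (default `FALSE`).
#' @param discount_method `"stepwise"` (default) holds the discount factor
#'   constant within each model year; `"per-cycle"` compounds continuously
#'   every cycle.
#' @param cost_start_cycle First cycle in which state health-care costs
#'   accrue (default 2: care during the 12-week treatment cycle is treated
#'   as subsumed in the intervention cost). QALYs always accrue from
#'   cycle 1.
#' @return An object of class `model_conventions`.
#' @export
model_conventions <- function(transition_order = c("death-first", "transition-first"),
                              mortality_start_cycle = 1L,
                              half_cycle = FALSE,
                              discount_method = c("stepwise", "per-cycle"),
                              cost_start_cycle = 2L) {
  transition_order <- match.arg(transition_order)
  discount_method <- match.arg(discount_method)
  stopifnot(mortality_start_cycle %in% c(1L, 2L),
            is.logical(half_cycle), length(half_cycle) == 1L,
            cost_start_cycle >= 1L)
  structure(
    list(transition_order = transition_order,
         mortality_start_cycle = as.integer(mortality_start_cycle),
         half_cycle = half_cycle,
         discount_method = discount_method,
         cost_start_cycle = as.integer(cost_start_cycle)),
    class = "model_conventions"
  )
}

# The eight shared (non-arm-specific) parameters every config must define.
SHARED_PARAM_NAMES <- c(
  "relapse_annual", "remission_annual",
  "mortality_improved_annual", "mortality_not_improved_annual",
  "utility_improved", "utility_not_improved",
  "hc_cost_improved_annual", "hc_cost_not_improved_annual"
)

.shared_roles <- c(
  relapse_annual = "annual_rate", remission_annual = "annual_rate",
  mortality_improved_annual = "annual_rate",
  mortality_not_improved_annual = "annual_rate",
  utility_improved = "utility", utility_not_improved = "utility",
  hc_cost_improved_annual = "cost_annual",
  hc_cost_not_improved_annual = "cost_annual"
)

#' Assemble a full model configuration
#'
#' @param arms List of [arm_parameters()] objects (at least two, unique
#'   names).
#' @param shared Named list of [parameter_spec()] objects covering all of
#'   `relapse_annual`, `remission_annual`, `mortality_improved_annual`,
#'   `mortality_not_improved_annual`, `utility_improved`,
#'   `utility_not_improved`, `hc_cost_improved_annual`,
#'   `hc_cost_not_improved_annual`.
#' @param policy A [policy_settings()] object.
#' @param conventions A [model_conventions()] object.
#' @return An object of class `model_config`.
#' @export
model_config <- function(arms, shared, policy = policy_settings(),
                         conventions = model_conventions()) {
  names(arms) <- vapply(arms, function(a) a$arm_name, character(1))
  structure(list(arms = arms, shared = shared, policy = policy,
                 conventions = conventions),
            class = "model_config")
}

#' The published base-case configuration
#'
#' Bundles every input of the published PTSD treatment model: per-arm
#' response probabilities and intervention costs for Health Education (HE),
#' Transcendental Meditation (TM) and Prolonged Exposure (PE), shared
#' clinical rates, utilities and annual health-care costs, with the
#' distributions and low/high sensitivity ranges of the source input table,
#' and the five-year / 3-month-cycle / 3\%-discount / $50,000-per-QALY
#' policy.
#'
#' @return A [model_config()] that passes [validate_config()] with no
#'   violations.
#' @examples
#' cfg <- table1_default_config()
#' cfg$arms$TM$p_respond$base  # 0.61
#' @export
table1_default_config <- function() {
  ps <- parameter_spec
  arms <- list(
    arm_parameters("HE",
      ps("p_respond_HE", 0.32, 0.256, 0.384, "beta", "probability"),
      ps("intervention_cost_HE", 492, 394, 590, "triangular", "cost_one_time")),
    arm_parameters("TM",
      ps("p_respond_TM", 0.61, 0.490, 0.730, "beta", "probability"),
      ps("intervention_cost_TM", 1504, 1203, 1805, "triangular", "cost_one_time")),
    arm_parameters("PE",
      ps("p_respond_PE", 0.42, 0.336, 0.504, "beta", "probability"),
      ps("intervention_cost_PE", 2822, 1605, 3386, "triangular", "cost_one_time"))
  )
  shared <- list(
    relapse_annual = ps("relapse_annual", 0.06, role = "annual_rate"),
    remission_annual = ps("remission_annual", 0.10, role = "annual_rate"),
    mortality_improved_annual =
      ps("mortality_improved_annual", 0.0045, 0.0036, 0.0054, "beta", "annual_rate"),
    mortality_not_improved_annual =
      ps("mortality_not_improved_annual", 0.0059, 0.0047, 0.0071, "beta", "annual_rate"),
    utility_improved = ps("utility_improved", 0.63, 0.50, 0.76, "beta", "utility"),
    utility_not_improved = ps("utility_not_improved", 0.54, 0.43, 0.65, "beta", "utility"),
    hc_cost_improved_annual =
      ps("hc_cost_improved_annual", 7855, 6284, 9426, "gamma", "cost_annual"),
    hc_cost_not_improved_annual =
      ps("hc_cost_not_improved_annual", 12154, 9723, 14585, "gamma", "cost_annual")
  )
  model_config(arms, shared)
}

.validate_spec <- function(spec) {
  v <- character(0)
  n <- spec$name
  has_range <- !is.na(spec$low) && !is.na(spec$high)
  if (spec$distribution != "fixed") {
    if (!has_range) {
      v <- c(v, sprintf("%s: distribution '%s' requires low and high",
                        n, spec$distribution))
    } else if (!(spec$low <= spec$base && spec$base <= spec$high)) {
      v <- c(v, sprintf("%s: ordering rule low <= base <= high violated (%g, %g, %g)",
                        n, spec$low, spec$base, spec$high))
    }
  } else if (has_range && !(spec$low == spec$base && spec$high == spec$base)) {
    v <- c(v, sprintf("%s: fixed distribution requires low/high absent or equal to base", n))
  }
  bounds <- c(spec$base, spec$low, spec$high)
  bounds <- bounds[!is.na(bounds)]
  if (spec$role %in% c("probability", "utility", "annual_rate")) {
    if (any(bounds < 0 | bounds > 1))
      v <- c(v, sprintf("%s: %s values must lie in [0, 1]", n, spec$role))
  }
  if (spec$role %in% c("cost_one_time", "cost_annual") && any(bounds < 0))
    v <- c(v, sprintf("%s: cost values must be >= 0", n))
  v
}

#' Validate a model configuration
#'
#' Checks every structural and range invariant; violations are returned as
#' messages rather than raised, so a configuration can be audited in full.
#'
#' @param config A [model_config()].
#' @return Character vector of violation messages; `character(0)` when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  if (!inherits(config, "model_config"))
    return("not a model_config object")
  missing <- setdiff(SHARED_PARAM_NAMES, names(config$shared))
  if (length(missing))
    v <- c(v, sprintf("missing shared parameter: %s", missing))
  for (nm in intersect(SHARED_PARAM_NAMES, names(config$shared)))
    v <- c(v, .validate_spec(config$shared[[nm]]))
  if (length(config$arms) < 2L)
    v <- c(v, "at least two arms required")
  arm_names <- vapply(config$arms, function(a) a$arm_name, character(1))
  if (anyDuplicated(arm_names))
    v <- c(v, "arm names must be unique")
  for (arm in config$arms) {
    v <- c(v, .validate_spec(arm$p_respond), .validate_spec(arm$intervention_cost))
    if (!(arm$p_respond$base > 0 && arm$p_respond$base < 1))
      v <- c(v, sprintf("%s: p_respond base must be in (0, 1)", arm$arm_name))
    if (!(arm$intervention_cost$base > 0))
      v <- c(v, sprintf("%s: intervention cost base must be > 0", arm$arm_name))
  }
  pol <- config$policy
  if (pol$n_cycles < 1L) v <- c(v, "policy: n_cycles must be >= 1")
  if (pol$annual_discount_rate < 0 || pol$annual_discount_rate >= 1)
    v <- c(v, "policy: annual_discount_rate must be in [0, 1)")
  if (pol$discount_start_cycle < 1L || pol$discount_start_cycle > pol$n_cycles + 1L)
    v <- c(v, "policy: discount_start_cycle must be in 1..n_cycles+1")
  v
}

# ---- serialization -------------------------------------------------------

.spec_to_list <- function(spec) {
  out <- list(base = spec$base, dist = spec$distribution, role = spec$role)
  if (!is.na(spec$low)) out$low <- spec$low
  if (!is.na(spec$high)) out$high <- spec$high
  out
}

.spec_from_list <- function(name, x) {
  allowed <- c("beta", "triangular", "gamma", "fixed")
  if (is.null(x$base))
    stop(sprintf("parameter '%s' is missing its base value", name))
  dist <- if (is.null(x$dist)) "fixed" else x$dist
  if (!dist %in% allowed)
    stop(sprintf("parameter '%s': unknown distribution '%s'; allowed: %s",
                 name, dist, paste(allowed, collapse = ", ")))
  role <- if (is.null(x$role)) .shared_roles[[name]] else x$role
  parameter_spec(name, x$base,
                 low = if (is.null(x$low)) NA_real_ else x$low,
                 high = if (is.null(x$high)) NA_real_ else x$high,
                 distribution = dist, role = role)
}

#' Save a model configuration to YAML or JSON
#'
#' The on-disk schema is a flat audit-friendly form: one named block per
#' parameter with `base`, `low`, `high`, `dist` and `role`, plus `policy`
#' and `conventions` blocks. Format is chosen by file extension
#' (`.yaml`/`.yml` vs `.json`).
#'
#' @param config A [model_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  doc <- list(
    arms = lapply(config$arms, function(a)
      list(p_respond = .spec_to_list(a$p_respond),
           intervention_cost = .spec_to_list(a$intervention_cost))),
    shared = lapply(config$shared, .spec_to_list),
    policy = unclass(config$policy),
    conventions = unclass(config$conventions)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path, precision = 15)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Load a model configuration from YAML or JSON
#'
#' @param path File written by [save_config()] (or hand-authored in the
#'   same schema). Missing parameters and unknown distribution names are
#'   reported by name.
#' @return A [model_config()]; `load_config(save_config(x, f))` reproduces
#'   `x` field for field.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  missing <- setdiff(SHARED_PARAM_NAMES, names(doc$shared))
  if (length(missing))
    stop(sprintf("config is missing shared parameter(s): %s",
                 paste(missing, collapse = ", ")))
  shared <- lapply(SHARED_PARAM_NAMES, function(nm)
    .spec_from_list(nm, doc$shared[[nm]]))
  names(shared) <- SHARED_PARAM_NAMES
  arms <- lapply(names(doc$arms), function(nm) {
    a <- doc$arms[[nm]]
    if (is.null(a$p_respond) || is.null(a$intervention_cost))
      stop(sprintf("arm '%s' must define p_respond and intervention_cost", nm))
    arm_parameters(nm,
                   .spec_from_list(paste0("p_respond_", nm), a$p_respond),
                   .spec_from_list(paste0("intervention_cost_", nm),
                                   a$intervention_cost))
  })
  pol <- doc$policy
  # JSON readers may simplify the list of pairs to a character matrix
  if (is.matrix(pol$reference_arm_pairs))
    pol$reference_arm_pairs <- lapply(asplit(pol$reference_arm_pairs, 1L),
                                      as.vector)
  policy <- policy_settings(
    cycle_length_years = pol$cycle_length_years,
    n_cycles = pol$n_cycles,
    annual_discount_rate = pol$annual_discount_rate,
    discount_start_cycle = pol$discount_start_cycle,
    wtp_per_qaly = pol$wtp_per_qaly,
    reference_arm_pairs = lapply(pol$reference_arm_pairs, unlist)
  )
  cv <- doc$conventions
  conventions <- model_conventions(
    transition_order = cv$transition_order,
    mortality_start_cycle = cv$mortality_start_cycle,
    half_cycle = cv$half_cycle,
    discount_method = cv$discount_method,
    cost_start_cycle = cv$cost_start_cycle
  )
  model_config(arms, shared, policy, conventions)
}

#' Audit build-up of the meditation intervention cost
#'
#' The delivered meditation course was billed as an inclusive external
#' instructor fee, plus in-house administrative scheduling time to which
#' facility overhead applies. Overhead is applied only to the personnel
#' component, not to the instructor fee.
#'
#' @param instructor_fee Inclusive external instructor fee (USD).
#' @param admin_hours Administrative support time per participant (hours).
#' @param wage Administrative hourly wage (USD/hour).
#' @param overhead_fraction Overhead fraction applied to personnel costs.
#' @return Total cost in USD:
#'   `instructor_fee + admin_hours * wage * (1 + overhead_fraction)`.
#'   Note the published input table's rounded intervention cost, not this
#'   audit arithmetic, feeds the model.
#' @export
tm_cost_buildup <- function(instructor_fee, admin_hours, wage, overhead_fraction) {
  args <- c(instructor_fee, admin_hours, wage, overhead_fraction)
  if (any(args < 0)) stop("all cost build-up inputs must be >= 0")
  instructor_fee + admin_hours * wage * (1 + overhead_fraction)
}
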