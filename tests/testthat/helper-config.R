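# Shared fixtures for the suite: all built in code.

base_config <- function() table1_default_config()

# A degenerate config useful for closed-form checks: no deaths, no
# discounting, mortality applied only from cycle 2.
clean_config <- function() {
  cfg <- table1_default_config()
  cfg$shared$mortality_improved_annual <-
    parameter_spec("mortality_improved_annual", 0, role = "annual_rate")
  cfg$shared$mortality_not_improved_annual <-
    parameter_spec("mortality_not_improved_annual", 0, role = "annual_rate")
  cfg$policy$annual_discount_rate <- 0
  cfg$conventions$mortality_start_cycle <- 2L
  cfg
}

set_shared <- function(cfg, name, value) {
  cfg$shared[[name]]$base <- value
  cfg$shared[[name]]$low <- NA_real_
  cfg$shared[[name]]$high <- NA_real_
  cfg$shared[[name]]$distribution <- "fixed"
  cfg
}

# Replace every sampled distribution by a point mass at base.
all_fixed_config <- function() {
  cfg <- table1_default_config()
  for (nm in names(cfg$shared)) cfg <- set_shared(cfg, nm, cfg$shared[[nm]]$base)
  for (a in names(cfg$arms)) {
    for (f in c("p_respond", "intervention_cost")) {
      cfg$arms[[a]][[f]]$low <- NA_real_
      cfg$arms[[a]][[f]]$high <- NA_real_
      cfg$arms[[a]][[f]]$distribution <- "fixed"
    }
  }
  cfg
}
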