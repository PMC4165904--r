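# Shared fixtures: the bundled base case is read once per test run.
base_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_inputs()
    cache
  }
})

# A deathless world: flat zero-mortality life table, useful for isolating
# the recurrence process from background mortality.
no_mortality_inputs <- function(inputs = base_inputs()) {
  inputs$life_table <- synthetic_life_table("flat", q = 0, max_age = 120)
  inputs
}

# Builds one subgroup trace from the input bundle's own group parameters.
subgroup_trace_for_test <- function(inputs, label, treated) {
  g <- inputs$groups[inputs$groups$label == label, ]
  p <- annual_prob_from_cumulative(
    chemo_adjusted_risk(g$baseline_risk_10y, g$rrr_chemo, treated), 10)
  run_subgroup_cohort(
    subgroup_spec(label, treated, p, Inf, inputs$settings$start_age),
    as.numeric(treated), inputs)
}

# Rewrites the bundled config with one field replaced, returns the temp path.
config_with <- function(edit) {
  cfg <- yaml::read_yaml(system.file("extdata", "config_default.yaml",
                                     package = "assaycea"))
  cfg <- edit(cfg)
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  cfg$life_table <- system.file("extdata",
                                "lifetable_jp_female_synthetic.csv",
                                package = "assaycea")
  yaml::write_yaml(cfg, path)
  path
}
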