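#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise
#'   ungroup left_join pull across desc
NULL

#' Health states of the cohort model
#'
#' Order matters: transition rows and trace columns follow this order.
#' @keywords internal
cea_states <- c("recurrence_free", "distant_recurrence", "dead_bc", "dead_other")

risk_group_labels <- c("low", "intermediate", "high")

cost_items <- c("assay", "chemo_drugs", "adverse_events", "time_transport",
                "surveillance_annual", "recurrence_annual")
utility_items <- c("u_recurrence_free", "u_progression", "chemo_qaly_tariff")

# ---- constructors ----------------------------------------------------------

new_cea_inputs <- function(groups, risk_sources, costs, utilities, settings,
                           life_table, life_table_path = NA_character_,
                           config_path = NA_character_) {
  structure(
    list(groups = groups, risk_sources = risk_sources, costs = costs,
         utilities = utilities, settings = settings, life_table = life_table,
         life_table_path = life_table_path, config_path = config_path),
    class = "cea_inputs"
  )
}

#' Read a model configuration
#'
#' Loads the full input bundle (risk groups, costs, utilities, settings and
#' the life table referenced by the config) from a YAML configuration file
#' and validates every invariant.  The bundled default configuration
#' reproduces the published base case.
#'
#' @param path Path to a YAML configuration file.
#' @param risk_source Optional override of the config's `risk_source`
#'   (`"japan"` or `"us_uk"`): selects which set of baseline 10-year distant
#'   recurrence risks is active.
#' @return A `cea_inputs` object: a list with tibbles `groups` (one row per
#'   recurrence-risk stratum), `costs`, `utilities` (each `item`, `base`,
#'   `low`, `high`), `risk_sources` (baseline risks for both validation-study
#'   sources), a `settings` list, and the `life_table` tibble
#'   (`age`, `q_annual`).
#' @examples
#' inp <- default_inputs()
#' inp$groups
#' @export
read_inputs <- function(path, risk_source = NULL) {
  if (!file.exists(path)) {
    abort(paste0("configuration file not found: ", path),
          class = "cea_config_error")
  }
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("risk_source", "life_table", "groups", "costs",
                    "utilities", "settings"), "top level")
  if (!is.null(risk_source)) cfg$risk_source <- risk_source
  cfg$risk_source <- match.arg(cfg$risk_source, c("japan", "us_uk"))

  check_keys(cfg$groups, risk_group_labels, "groups")
  grp_rows <- purrr::map(risk_group_labels, function(lab) {
    g <- cfg$groups[[lab]]
    check_keys(g, c("n_patients", "n_chemo_pre", "n_chemo_post",
                    "baseline_risk_10y", "rrr_chemo"),
               paste0("groups.", lab))
    check_keys(g$baseline_risk_10y, c("japan", "us_uk"),
               paste0("groups.", lab, ".baseline_risk_10y"))
    tibble(
      label = lab,
      n_patients = num(g$n_patients),
      n_chemo_pre = num(g$n_chemo_pre),
      n_chemo_post = num(g$n_chemo_post),
      rrr_chemo = num(g$rrr_chemo$base),
      rrr_low = num(g$rrr_chemo$low),
      rrr_high = num(g$rrr_chemo$high)
    )
  })
  groups <- bind_rows(grp_rows)
  n_total <- sum(groups$n_patients)
  groups <- mutate(groups,
                   cohort_share = .data$n_patients / n_total,
                   chemo_rate_pre = .data$n_chemo_pre / .data$n_patients,
                   chemo_rate_post = .data$n_chemo_post / .data$n_patients)

  risk_sources <- purrr::map_dfr(risk_group_labels, function(lab) {
    purrr::map_dfr(c("japan", "us_uk"), function(src) {
      b <- cfg$groups[[lab]]$baseline_risk_10y[[src]]
      check_keys(b, c("base", "low", "high"),
                 paste0("groups.", lab, ".baseline_risk_10y.", src))
      tibble(label = lab, source = src, base = num(b$base),
             low = num(b$low), high = num(b$high))
    })
  })
  groups <- apply_risk_source(groups, risk_sources, cfg$risk_source)

  costs <- bounded_table(cfg$costs, cost_items, "costs")
  utilities <- bounded_table(cfg$utilities, utility_items, "utilities")

  s <- cfg$settings
  check_keys(s, c("start_age", "discount_rate", "cycle_length", "max_age",
                  "post_recurrence_mortality", "fatal_toxicity_risk",
                  "recurrence_hazard_mode", "half_cycle_correction"),
             "settings")
  settings <- list(
    start_age = num(s$start_age$base),
    start_age_low = num(s$start_age$low),
    start_age_high = num(s$start_age$high),
    discount_rate = num(s$discount_rate$base),
    discount_low = num(s$discount_rate$low),
    discount_high = num(s$discount_rate$high),
    cycle_length = num(s$cycle_length),
    max_age = num(s$max_age),
    post_recurrence_mortality = num(s$post_recurrence_mortality$base),
    post_recurrence_mortality_low = num(s$post_recurrence_mortality$low),
    post_recurrence_mortality_high = num(s$post_recurrence_mortality$high),
    fatal_toxicity_risk = num(s$fatal_toxicity_risk$base),
    fatal_toxicity_low = num(s$fatal_toxicity_risk$low),
    fatal_toxicity_high = num(s$fatal_toxicity_risk$high),
    recurrence_hazard_mode = match.arg(s$recurrence_hazard_mode,
                                       c("lifetime", "first_10_years")),
    half_cycle_correction = isTRUE(s$half_cycle_correction),
    risk_source = cfg$risk_source
  )

  lt_path <- cfg$life_table
  if (!file.exists(lt_path)) {
    lt_path <- file.path(dirname(path), cfg$life_table)
  }
  life_table <- read_life_table(lt_path)

  inp <- new_cea_inputs(groups, risk_sources, costs, utilities, settings,
                        life_table, life_table_path = normalizePath(lt_path),
                        config_path = normalizePath(path))
  validate_inputs(inp)
}

#' Base-case inputs
#'
#' The bundled base case: 104-patient decision-impact counts, 2013 JPY costs,
#' published utilities, and the synthetic Japanese female life table.
#'
#' @inheritParams read_inputs
#' @export
default_inputs <- function(risk_source = "japan") {
  read_inputs(system.file("extdata", "config_default.yaml",
                          package = "assaycea", mustWork = TRUE),
              risk_source = risk_source)
}

#' Switch the baseline-recurrence-risk source
#'
#' Swaps the three active baseline 10-year distant recurrence risks (and
#' their sensitivity bounds) between the Japanese validation study and the
#' US/UK validation studies.  Everything else is unchanged.
#'
#' @param inputs A `cea_inputs` object.
#' @param source `"japan"` or `"us_uk"`.
#' @export
set_risk_source <- function(inputs, source) {
  source <- match.arg(source, c("japan", "us_uk"))
  inputs$groups <- apply_risk_source(inputs$groups, inputs$risk_sources, source)
  inputs$settings$risk_source <- source
  inputs
}

apply_risk_source <- function(groups, risk_sources, source) {
  act <- filter(risk_sources, .data$source == !!source)
  groups$baseline_risk_10y <- act$base[match(groups$label, act$label)]
  groups$risk_low <- act$low[match(groups$label, act$label)]
  groups$risk_high <- act$high[match(groups$label, act$label)]
  groups
}

# ---- small parsing helpers -------------------------------------------------

num <- function(x) {
  if (is.null(x) || length(x) != 1 || is.na(suppressWarnings(as.numeric(x)))) {
    abort(paste0("expected a single number, got: ", deparse(x)),
          class = "cea_config_error")
  }
  as.numeric(x)
}

check_keys <- function(x, expected, where) {
  if (!is.list(x)) {
    abort(paste0("configuration section '", where, "' is not a mapping"),
          class = "cea_config_error")
  }
  missing <- setdiff(expected, names(x))
  extra <- setdiff(names(x), expected)
  if (length(missing)) {
    abort(paste0("missing key(s) in ", where, ": ",
                 paste(missing, collapse = ", ")),
          class = "cea_config_error")
  }
  if (length(extra)) {
    abort(paste0("unknown key(s) in ", where, ": ",
                 paste(extra, collapse = ", ")),
          class = "cea_config_error")
  }
  invisible(x)
}

bounded_table <- function(section, items, where) {
  check_keys(section, items, where)
  purrr::map_dfr(items, function(it) {
    b <- section[[it]]
    check_keys(b, c("base", "low", "high"), paste0(where, ".", it))
    tibble(item = it, base = num(b$base), low = num(b$low), high = num(b$high))
  })
}

# ---- life table ------------------------------------------------------------

#' Read a life table
#'
#' @param path CSV with header `age,q_annual`: one row per integer age with
#'   the annual probability of death from causes other than breast cancer.
#' @return A tibble with `age` and `q_annual`, validated (ages strictly
#'   increasing, probabilities in \[0, 1\]).
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("life-table file not found: ", path),
          class = "cea_config_error")
  }
  lt <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_double(), q_annual = readr::col_double()))
  validate_life_table(lt)
}

validate_life_table <- function(lt) {
  if (!all(c("age", "q_annual") %in% names(lt))) {
    abort("life table must have columns 'age' and 'q_annual'",
          class = "cea_validation_error")
  }
  if (any(diff(lt$age) <= 0)) {
    abort("life-table ages must be strictly increasing",
          class = "cea_validation_error")
  }
  check_prob(lt$q_annual, "life_table.q_annual")
  as_tibble(lt[, c("age", "q_annual")])
}

#' Annual other-cause death probability at a given age
#'
#' Looks up the life-table row for `floor(age)`; ages beyond the last record
#' fall back to the last record's value, ages below the first to the first.
#'
#' @param life_table A life-table tibble (`age`, `q_annual`).
#' @param age Attained age in years (vectorised).
#' @export
life_table_q <- function(life_table, age) {
  idx <- findInterval(floor(age), life_table$age)
  idx[idx < 1] <- 1
  life_table$q_annual[idx]
}

# ---- validation ------------------------------------------------------------

check_prob <- function(x, field) {
  bad <- which(!is.finite(x) | x < 0 | x > 1)
  if (length(bad)) {
    abort(sprintf("field '%s' must lie in [0, 1]; got %s", field,
                  paste(format(x[bad[1]]), collapse = ", ")),
          class = "cea_validation_error")
  }
  invisible(x)
}

check_bounds <- function(tbl, where) {
  bad <- which(!(tbl$low <= tbl$base & tbl$base <= tbl$high))
  if (length(bad)) {
    abort(sprintf(
      "bounds for '%s.%s' do not bracket the base value (low %s, base %s, high %s)",
      where, tbl$item[bad[1]], tbl$low[bad[1]], tbl$base[bad[1]],
      tbl$high[bad[1]]), class = "cea_validation_error")
  }
  invisible(tbl)
}

#' Validate a cea_inputs bundle
#'
#' Checks every structural invariant: proportions in \[0, 1\], sensitivity
#' bounds bracketing base values, cohort shares summing to one, non-negative
#' costs, a valid life table and settings.  Returns the bundle invisibly so
#' it can be used in a pipe; aborts with a `cea_validation_error` naming the
#' offending field otherwise.
#'
#' @param inputs A `cea_inputs` object.
#' @export
validate_inputs <- function(inputs) {
  g <- inputs$groups
  for (f in c("cohort_share", "chemo_rate_pre", "chemo_rate_post",
              "baseline_risk_10y", "risk_low", "risk_high",
              "rrr_chemo", "rrr_low", "rrr_high")) {
    check_prob(g[[f]], paste0("groups.", f))
  }
  if (abs(sum(g$cohort_share) - 1) > 1e-9) {
    abort(sprintf("cohort shares sum to %.12f, not 1", sum(g$cohort_share)),
          class = "cea_validation_error")
  }
  check_bounds(tibble(item = g$label, low = g$risk_low,
                      base = g$baseline_risk_10y, high = g$risk_high),
               "baseline_risk_10y")
  check_bounds(tibble(item = g$label, low = g$rrr_low, base = g$rrr_chemo,
                      high = g$rrr_high), "rrr_chemo")

  if (any(inputs$costs$low < 0)) {
    abort("costs must be non-negative", class = "cea_validation_error")
  }
  check_bounds(inputs$costs, "costs")
  check_bounds(inputs$utilities, "utilities")
  check_prob(inputs$utilities$base[inputs$utilities$item != "chemo_qaly_tariff"],
             "utilities")
  if (inputs$utilities$base[inputs$utilities$item == "chemo_qaly_tariff"] < 0) {
    abort("chemo_qaly_tariff must be non-negative",
          class = "cea_validation_error")
  }

  s <- inputs$settings
  if (!(s$discount_rate >= 0 && s$discount_rate < 1)) {
    abort(sprintf("settings.discount_rate must lie in [0, 1); got %s",
                  s$discount_rate), class = "cea_validation_error")
  }
  if (!(s$start_age < s$max_age)) {
    abort(sprintf("settings.start_age (%s) must be below max_age (%s)",
                  s$start_age, s$max_age), class = "cea_validation_error")
  }
  check_prob(s$post_recurrence_mortality, "settings.post_recurrence_mortality")
  check_prob(s$fatal_toxicity_risk, "settings.fatal_toxicity_risk")
  if (s$cycle_length != 1) {
    abort("settings.cycle_length is fixed at 1 year",
          class = "cea_validation_error")
  }
  validate_life_table(inputs$life_table)
  invisible(inputs)
}

# ---- serialisation ---------------------------------------------------------

fmt_num <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  exact <- as.numeric(s) == x
  s[!exact] <- sprintf("%.17g", x[!exact])
  s
}

bounded_list <- function(base, low, high) {
  list(base = fmt_num(base), low = fmt_num(low), high = fmt_num(high))
}

#' Write a model configuration
#'
#' Serialises a `cea_inputs` bundle back to YAML.  Numbers are written with
#' enough digits that a write-then-read round trip reproduces every value
#' bit-exactly.  The life table is referenced by the path it was loaded from
#' (or written beside the config when that path is unknown).
#'
#' @param inputs A `cea_inputs` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_inputs <- function(inputs, path) {
  g <- inputs$groups
  rs <- inputs$risk_sources
  groups_cfg <- stats::setNames(purrr::map(seq_len(nrow(g)), function(i) {
    lab <- g$label[i]
    risks <- stats::setNames(purrr::map(c("japan", "us_uk"), function(src) {
      r <- filter(rs, .data$label == lab, .data$source == src)
      bounded_list(r$base, r$low, r$high)
    }), c("japan", "us_uk"))
    list(n_patients = g$n_patients[i],
         n_chemo_pre = g$n_chemo_pre[i],
         n_chemo_post = g$n_chemo_post[i],
         baseline_risk_10y = risks,
         rrr_chemo = bounded_list(g$rrr_chemo[i], g$rrr_low[i], g$rrr_high[i]))
  }), g$label)

  tbl_cfg <- function(tbl) {
    stats::setNames(purrr::map(seq_len(nrow(tbl)), function(i) {
      bounded_list(tbl$base[i], tbl$low[i], tbl$high[i])
    }), tbl$item)
  }
  s <- inputs$settings
  lt_path <- inputs$life_table_path
  if (is.na(lt_path)) {
    lt_path <- file.path(dirname(path), "life_table.csv")
    readr::write_csv(inputs$life_table, lt_path)
  }
  cfg <- list(
    risk_source = s$risk_source,
    life_table = lt_path,
    groups = groups_cfg,
    costs = tbl_cfg(inputs$costs),
    utilities = tbl_cfg(inputs$utilities),
    settings = list(
      start_age = bounded_list(s$start_age, s$start_age_low, s$start_age_high),
      discount_rate = bounded_list(s$discount_rate, s$discount_low,
                                   s$discount_high),
      cycle_length = s$cycle_length,
      max_age = fmt_num(s$max_age),
      post_recurrence_mortality = bounded_list(
        s$post_recurrence_mortality, s$post_recurrence_mortality_low,
        s$post_recurrence_mortality_high),
      fatal_toxicity_risk = bounded_list(
        s$fatal_toxicity_risk, s$fatal_toxicity_low, s$fatal_toxicity_high),
      recurrence_hazard_mode = s$recurrence_hazard_mode,
      half_cycle_correction = s$half_cycle_correction
    )
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# ---- strategy arms ---------------------------------------------------------

#' Strategy arms of the decision problem
#'
#' Builds the two strategy arms from the risk-group table: `without_assay`
#' applies the pre-assay chemotherapy recommendation rates (usual clinical
#' practice), `with_assay` the post-assay rates plus the one-time assay cost.
#'
#' @param groups The `groups` tibble of a `cea_inputs` object, or the object
#'   itself.
#' @return A tibble with one row per arm and risk group: `arm`,
#'   `assay_cost_applied`, `label`, `cohort_share`, `chemo_rate`.
#' @examples
#' strategy_arms(default_inputs())
#' @export
strategy_arms <- function(groups) {
  if (inherits(groups, "cea_inputs")) groups <- groups$groups
  bind_rows(
    tibble(arm = "without_assay", assay_cost_applied = FALSE,
           label = groups$label, cohort_share = groups$cohort_share,
           chemo_rate = groups$chemo_rate_pre),
    tibble(arm = "with_assay", assay_cost_applied = TRUE,
           label = groups$label, cohort_share = groups$cohort_share,
           chemo_rate = groups$chemo_rate_post)
  )
}

#' Cohort-level chemotherapy proportion of an arm
#'
#' Share-weighted mean of the per-group chemotherapy recommendation rates.
#'
#' @param arms Output of [strategy_arms()], optionally filtered to one arm.
#' @return A tibble with `arm` and `chemo_proportion`.
#' @export
overall_chemo_proportion <- function(arms) {
  arms |>
    group_by(.data$arm) |>
    summarise(chemo_proportion = sum(.data$cohort_share * .data$chemo_rate),
              .groups = "drop")
}

# ---- sensitivity parameter registry ---------------------------------------

#' Parameters varied in the one-way sensitivity analysis
#'
#' Every scalar input that carries (low, high) sensitivity bounds: the three
#' baseline recurrence risks of the active source, the three relative risk
#' reductions, the six costs, the three utilities, starting age, discount
#' rate, post-recurrence mortality and fatal chemotherapy toxicity.
#'
#' @param inputs A `cea_inputs` object.
#' @return A tibble `id`, `base`, `low`, `high`; `id` is a dotted path
#'   accepted by [set_parameter()].
#' @export
sensitivity_parameters <- function(inputs) {
  g <- inputs$groups
  s <- inputs$settings
  bind_rows(
    tibble(id = paste0("risk.", g$label), base = g$baseline_risk_10y,
           low = g$risk_low, high = g$risk_high),
    tibble(id = paste0("rrr.", g$label), base = g$rrr_chemo,
           low = g$rrr_low, high = g$rrr_high),
    tibble(id = paste0("cost.", inputs$costs$item), base = inputs$costs$base,
           low = inputs$costs$low, high = inputs$costs$high),
    tibble(id = paste0("utility.", inputs$utilities$item),
           base = inputs$utilities$base, low = inputs$utilities$low,
           high = inputs$utilities$high),
    tibble(id = c("settings.start_age", "settings.discount_rate",
                  "settings.post_recurrence_mortality",
                  "settings.fatal_toxicity_risk"),
           base = c(s$start_age, s$discount_rate,
                    s$post_recurrence_mortality, s$fatal_toxicity_risk),
           low = c(s$start_age_low, s$discount_low,
                   s$post_recurrence_mortality_low, s$fatal_toxicity_low),
           high = c(s$start_age_high, s$discount_high,
                    s$post_recurrence_mortality_high, s$fatal_toxicity_high))
  )
}

#' Set one scalar input by its dotted id
#'
#' @param inputs A `cea_inputs` object.
#' @param id A dotted path as listed by [sensitivity_parameters()], e.g.
#'   `"cost.chemo_drugs"`, `"risk.high"`, `"settings.discount_rate"`.
#' @param value New value, in the parameter's native units.
#' @return The modified (and re-validated) `cea_inputs` object.
#' @export
set_parameter <- function(inputs, id, value) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    abort(paste0("unknown parameter id: ", id), class = "cea_config_error")
  }
  section <- parts[1]
  key <- parts[2]
  hit <- FALSE
  if (section == "risk" && key %in% inputs$groups$label) {
    i <- match(key, inputs$groups$label)
    inputs$groups$baseline_risk_10y[i] <- value
    inputs$groups$risk_low[i] <- min(inputs$groups$risk_low[i], value)
    inputs$groups$risk_high[i] <- max(inputs$groups$risk_high[i], value)
    j <- which(inputs$risk_sources$label == key &
                 inputs$risk_sources$source == inputs$settings$risk_source)
    inputs$risk_sources$base[j] <- value
    inputs$risk_sources$low[j] <- min(inputs$risk_sources$low[j], value)
    inputs$risk_sources$high[j] <- max(inputs$risk_sources$high[j], value)
    hit <- TRUE
  } else if (section == "rrr" && key %in% inputs$groups$label) {
    i <- match(key, inputs$groups$label)
    inputs$groups$rrr_chemo[i] <- value
    inputs$groups$rrr_low[i] <- min(inputs$groups$rrr_low[i], value)
    inputs$groups$rrr_high[i] <- max(inputs$groups$rrr_high[i], value)
    hit <- TRUE
  } else if (section == "cost" && key %in% inputs$costs$item) {
    i <- match(key, inputs$costs$item)
    inputs$costs$base[i] <- value
    inputs$costs$low[i] <- min(inputs$costs$low[i], value)
    inputs$costs$high[i] <- max(inputs$costs$high[i], value)
    hit <- TRUE
  } else if (section == "utility" && key %in% inputs$utilities$item) {
    i <- match(key, inputs$utilities$item)
    inputs$utilities$base[i] <- value
    inputs$utilities$low[i] <- min(inputs$utilities$low[i], value)
    inputs$utilities$high[i] <- max(inputs$utilities$high[i], value)
    hit <- TRUE
  } else if (section == "settings") {
    setting_keys <- c("start_age", "discount_rate",
                      "post_recurrence_mortality", "fatal_toxicity_risk")
    if (key %in% setting_keys) {
      inputs$settings[[key]] <- value
      bound_keys <- list(
        start_age = c("start_age_low", "start_age_high"),
        discount_rate = c("discount_low", "discount_high"),
        post_recurrence_mortality = c("post_recurrence_mortality_low",
                                      "post_recurrence_mortality_high"),
        fatal_toxicity_risk = c("fatal_toxicity_low", "fatal_toxicity_high")
      )[[key]]
      inputs$settings[[bound_keys[1]]] <-
        min(inputs$settings[[bound_keys[1]]], value)
      inputs$settings[[bound_keys[2]]] <-
        max(inputs$settings[[bound_keys[2]]], value)
      hit <- TRUE
    }
  }
  if (!hit) {
    abort(paste0("unknown parameter id: ", id), class = "cea_config_error")
  }
  validate_inputs(inputs)
  inputs
}

#' Get one scalar input by its dotted id
#'
#' @inheritParams set_parameter
#' @export
get_parameter <- function(inputs, id) {
  p <- sensitivity_parameters(inputs)
  i <- match(id, p$id)
  if (is.na(i)) {
    abort(paste0("unknown parameter id: ", id), class = "cea_config_error")
  }
  p$base[i]
}

#' @export
print.cea_inputs <- function(x, ...) {
  cat("<cea_inputs>  risk source:", x$settings$risk_source,
      " start age:", x$settings$start_age,
      " discount:", x$settings$discount_rate, "\n")
  print(x$groups[, c("label", "cohort_share", "chemo_rate_pre",
                     "chemo_rate_post", "baseline_risk_10y", "rrr_chemo")])
  invisible(x)
}
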