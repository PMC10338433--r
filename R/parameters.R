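# Model inputs: base-case values, sensitivity ranges and distribution kinds
# for every quantity the model consumes, in one validated container.

# Canonical parameter table. `dist` is the distribution used in probabilistic
# sensitivity analysis (beta for probabilities/utilities, gamma for costs and
# positive ratios); `origin` records whether the range was published or assumed
# as +/-5% of the base value (capped at 1 for probabilities).
.param_table <- function() {
  tab <- rbind.data.frame(
    # name, base, low, high, dist, origin
    list("prev_ec_pmb",             0.09,   0.08,    0.11,    "beta",  "published"),
    list("prev_pmb_ec",             0.91,   0.87,    0.93,    "beta",  "published"),
    list("ec_incidence_pop",        53.5,   50.825,  56.175,  "gamma", "assumed_pm5pct"),
    list("prog_stage_1_2",          0.30,   0.285,   0.315,   "beta",  "assumed_pm5pct"),
    list("prog_stage_2_3",          0.40,   0.38,    0.42,    "beta",  "assumed_pm5pct"),
    list("prog_stage_3_4",          0.55,   0.52,    0.578,   "beta",  "assumed_pm5pct"),
    list("stage_dist_1",            0.705,  0.66975, 0.74025, "beta",  "assumed_pm5pct"),
    list("stage_dist_2",            0.062,  0.0589,  0.0651,  "beta",  "assumed_pm5pct"),
    list("stage_dist_3",            0.149,  0.14155, 0.15645, "beta",  "assumed_pm5pct"),
    list("stage_dist_4",            0.084,  0.0798,  0.0882,  "beta",  "assumed_pm5pct"),
    list("sens_hysteroscopy",       0.864,  0.821,   0.907,   "beta",  "assumed_pm5pct"),
    list("spec_hysteroscopy",       0.992,  0.942,   1.0,     "beta",  "assumed_pm5pct"),
    list("sens_pipelle",            0.94,   0.84,    0.99,    "beta",  "published"),
    list("spec_pipelle",            0.99,   0.98,    1.0,     "beta",  "published"),
    list("sens_tvu",                0.906,  0.861,   0.951,   "beta",  "assumed_pm5pct"),
    list("spec_tvu",                0.235,  0.223,   0.247,   "beta",  "assumed_pm5pct"),
    list("sens_molecular_pap",      0.78,   0.75,    0.85,    "beta",  "published"),
    list("spec_molecular_pap",      0.97,   0.83,    1.0,     "beta",  "published"),
    list("sens_molecular_pipelle",  0.96,   0.92,    0.98,    "beta",  "published"),
    list("spec_molecular_pipelle",  0.94,   0.79,    0.99,    "beta",  "published"),
    list("obesity_proportion",      0.213,  0.20235, 0.22365, "beta",  "assumed_pm5pct"),
    list("obesity_hr",              3.0,    2.5,     4.0,     "gamma", "published"),
    list("p_bleeding_recurrence",   0.80,   0.76,    0.84,    "beta",  "assumed_pm5pct"),
    list("p_pipelle_insertion",     0.92,   0.89,    0.94,    "beta",  "published"),
    list("p_pipelle_tissue",        0.87,   0.86,    0.90,    "beta",  "published"),
    list("recurrence_stage_1",      0.065,  0.061,   0.067,   "beta",  "assumed_pm5pct"),
    list("recurrence_stage_2",      0.20,   0.19,    0.21,    "beta",  "assumed_pm5pct"),
    list("recurrence_stage_3",      0.375,  0.356,   0.394,   "beta",  "assumed_pm5pct"),
    list("recurrence_stage_4",      0.667,  0.634,   0.70,    "beta",  "assumed_pm5pct"),
    list("surv5_stage_1",           0.957,  0.90915, 1.0,     "beta",  "assumed_pm5pct"),
    list("surv5_stage_2",           0.707,  0.67165, 0.74235, "beta",  "assumed_pm5pct"),
    list("surv5_stage_3",           0.707,  0.67165, 0.74235, "beta",  "assumed_pm5pct"),
    list("surv5_stage_4",           0.171,  0.16245, 0.17955, "beta",  "assumed_pm5pct"),
    list("p_death_other",           0.017,  0.01615, 0.01785, "beta",  "assumed_pm5pct"),
    list("u_bleeding",              0.95,   0.903,   0.998,   "beta",  "assumed_pm5pct"),
    list("u_benign_hysterectomy",   0.70,   0.665,   0.735,   "beta",  "assumed_pm5pct"),
    list("u_detected_stage_1",      0.68,   0.646,   0.714,   "beta",  "assumed_pm5pct"),
    list("u_detected_stage_2",      0.56,   0.532,   0.588,   "beta",  "assumed_pm5pct"),
    list("u_detected_stage_3",      0.56,   0.532,   0.588,   "beta",  "assumed_pm5pct"),
    list("u_detected_stage_4",      0.48,   0.456,   0.504,   "beta",  "assumed_pm5pct"),
    list("u_undetected",            0.68,   0.646,   0.714,   "beta",  "assumed_pm5pct"),
    list("u_survivor_stage_1",      0.88,   0.834,   0.922,   "beta",  "assumed_pm5pct"),
    list("u_survivor_stage_2",      0.72,   0.687,   0.760,   "beta",  "assumed_pm5pct"),
    list("u_survivor_stage_3",      0.72,   0.687,   0.760,   "beta",  "assumed_pm5pct"),
    list("u_survivor_stage_4",      0.62,   0.589,   0.651,   "beta",  "assumed_pm5pct"),
    list("cost_initial_visit",      148,    140.6,   155.4,   "gamma", "assumed_pm5pct"),
    list("cost_successive_visit",   69,     65.5,    72.5,    "gamma", "assumed_pm5pct"),
    list("cost_telephone_visit",    41,     38.9,    43.1,    "gamma", "assumed_pm5pct"),
    list("cost_pap_smear",          49,     46.6,    51.5,    "gamma", "assumed_pm5pct"),
    list("cost_tvu",                31,     29.5,    32.6,    "gamma", "assumed_pm5pct"),
    list("cost_pipelle",            105,    99.8,    110.3,   "gamma", "assumed_pm5pct"),
    list("cost_molecular_test",     310,    294.5,   325.5,   "gamma", "assumed_pm5pct"),
    list("cost_hysteroscopy",       134,    127.3,   140.7,   "gamma", "assumed_pm5pct"),
    list("cost_hysterectomy_early", 5367,   3817,    6917,    "gamma", "published"),
    list("cost_hysterectomy_late",  10607,  10077,   11137,   "gamma", "assumed_pm5pct"),
    list("cost_adjuvant",           4326,   3743,    8653,    "gamma", "published")
  )
  names(tab) <- c("name", "base", "low", "high", "dist", "origin")
  tab$name <- as.character(tab$name)
  tab$dist <- as.character(tab$dist)
  tab$origin <- as.character(tab$origin)
  tab
}

# Structural scalars: fixed analysis settings without sensitivity ranges.
.structural_defaults <- function() {
  list(
    discount_rate = 0.03,
    n_cycles = 35L,
    start_age = 50L,
    wtp_threshold_low = 22000,
    wtp_threshold_high = 25000,
    survivor_followup_cost = 0
  )
}

# Model-structure switches (documented alternatives for paper-silent choices).
.setting_defaults <- function() {
  list(
    recurrence_rate_mode = "cumulative_5yr",  # or "annual"
    benign_hyst_utility_mode = "temporary",   # or "permanent"
    recurrence_cost_mode = "adjuvant",        # or "full"
    half_cycle_correction = FALSE,
    cycle_order = c("death_other", "death_ec", "progression",
                    "incidence", "workup")
  )
}

.setting_choices <- list(
  recurrence_rate_mode = c("cumulative_5yr", "annual"),
  benign_hyst_utility_mode = c("temporary", "permanent"),
  recurrence_cost_mode = c("adjuvant", "full")
)

.prob_params <- function(tab) tab$name[tab$dist == "beta"]
.cost_params <- function(tab) tab$name[startsWith(tab$name, "cost_")]

#' Default model parameters
#'
#' Returns the complete base-case parameter set: test characteristics,
#' procedure success probabilities, epidemiology, FIGO stage vectors,
#' utilities and unit costs (2020 euros), together with the per-parameter
#' sensitivity ranges and distribution assignments (beta for probabilities
#' and utilities, gamma for costs) and the structural analysis settings
#' (3% annual discounting, 35 one-year cycles from age 50, willingness-to-pay
#' threshold 22,000-25,000 euro/QALY).
#'
#' @return An object of class `pmb_parameters`: a list with elements
#'   `values` (named numeric vector of all scalar inputs), `ranges`
#'   (data frame `name`, `base`, `low`, `high`, `dist`, `origin`),
#'   `settings` (model-structure switches) and `age_tables` (optional
#'   per-age overrides, empty by default).
#' @seealso [load_parameters()], [validate_parameters()], [perturb()]
#' @export
#' @examples
#' ps <- default_parameters()
#' ps$values[["cost_molecular_test"]]
default_parameters <- function() {
  tab <- .param_table()
  values <- stats::setNames(tab$base, tab$name)
  values <- c(values, unlist(.structural_defaults()))
  ps <- structure(
    list(values = values, ranges = tab,
         settings = .setting_defaults(), age_tables = list()),
    class = "pmb_parameters")
  ps
}

#' @export
print.pmb_parameters <- function(x, ...) {
  cat("<pmb_parameters> ", length(x$values), " scalar inputs, ",
      nrow(x$ranges), " with sensitivity ranges\n", sep = "")
  cat("  cycles:", x$values[["n_cycles"]],
      " start age:", x$values[["start_age"]],
      " discount:", x$values[["discount_rate"]], "\n")
  if (length(x$age_tables))
    cat("  age tables:", paste(names(x$age_tables), collapse = ", "), "\n")
  invisible(x)
}

#' Look up one scalar parameter
#'
#' @param ps A `pmb_parameters` object.
#' @param name Parameter name.
#' @return The scalar value.
#' @export
param <- function(ps, name) {
  if (!name %in% names(ps$values))
    stop("unknown parameter: ", name, call. = FALSE)
  unname(ps$values[[name]])
}

# Stage-indexed helper: param_stages(ps, "surv5_stage") -> length-4 vector.
param_stages <- function(ps, prefix) {
  vapply(1:4, function(s) param(ps, paste0(prefix, "_", s)), numeric(1))
}

# Age-dependent lookup: a per-age table (data.frame age, value) in
# ps$age_tables overrides the scalar at the attained age; the scalar is the
# cycle-constant default.
param_at_age <- function(ps, name, age) {
  tab <- ps$age_tables[[name]]
  if (is.null(tab)) return(param(ps, name))
  idx <- findInterval(age, tab$age)
  if (idx < 1) idx <- 1
  tab$value[idx]
}

#' Validate a parameter set
#'
#' Checks every type invariant: probabilities and utilities in \[0,1\],
#' costs non-negative, the FIGO stage distribution summing to 1 (tolerance
#' 1e-9), hazard ratio positive, each sensitivity range ordered
#' `low <= base <= high`, and settings drawn from their documented choices.
#' Violations are returned, not raised.
#'
#' @param ps A `pmb_parameters` object.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_parameters <- function(ps) {
  v <- character(0)
  tab <- ps$ranges
  probs <- .prob_params(tab)
  for (nm in probs) {
    x <- param(ps, nm)
    if (!is.finite(x) || x < 0 || x > 1)
      v <- c(v, sprintf("%s = %g outside [0, 1]", nm, x))
  }
  for (nm in .cost_params(tab)) {
    x <- param(ps, nm)
    if (!is.finite(x) || x < 0)
      v <- c(v, sprintf("%s = %g is negative", nm, x))
  }
  if (param(ps, "obesity_hr") <= 0)
    v <- c(v, "obesity_hr must be positive")
  if (param(ps, "ec_incidence_pop") < 0)
    v <- c(v, "ec_incidence_pop must be non-negative")
  sd <- param_stages(ps, "stage_dist")
  if (any(sd < 0) || abs(sum(sd) - 1) > 1e-9)
    v <- c(v, sprintf("stage distribution must be non-negative and sum to 1 (sum = %.12f)",
                      sum(sd)))
  if (param(ps, "discount_rate") < 0)
    v <- c(v, "discount_rate must be non-negative")
  if (param(ps, "n_cycles") < 1)
    v <- c(v, "n_cycles must be at least 1")
  for (i in seq_len(nrow(tab))) {
    base <- param(ps, tab$name[i])
    if (tab$low[i] > tab$high[i] ||
        base < tab$low[i] - 1e-12 || base > tab$high[i] + 1e-12)
      v <- c(v, sprintf("range for %s does not bracket the base value (%g not in [%g, %g])",
                        tab$name[i], base, tab$low[i], tab$high[i]))
  }
  for (nm in names(.setting_choices)) {
    if (!ps$settings[[nm]] %in% .setting_choices[[nm]])
      v <- c(v, sprintf("setting %s = '%s' not one of: %s", nm,
                        ps$settings[[nm]],
                        paste(.setting_choices[[nm]], collapse = ", ")))
  }
  if (!setequal(ps$settings$cycle_order,
                c("death_other", "death_ec", "progression", "incidence", "workup")))
    v <- c(v, "cycle_order must be a permutation of the five within-cycle events")
  v
}

.assert_valid <- function(ps) {
  v <- validate_parameters(ps)
  if (length(v))
    stop("invalid parameter set:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  invisible(ps)
}

#' Perturb one parameter
#'
#' Returns a new parameter set differing from `ps` only in the named scalar;
#' the original is untouched. The stored sensitivity range is expanded if
#' needed so the new base value still passes validation (one-way sensitivity
#' analysis sets values at range bounds; scenario analyses may go beyond).
#'
#' @param ps A `pmb_parameters` object.
#' @param name Name of a known scalar parameter.
#' @param value New value.
#' @return A new `pmb_parameters` object.
#' @export
#' @examples
#' ps <- perturb(default_parameters(), "spec_molecular_pap", 0.83)
perturb <- function(ps, name, value) {
  if (!name %in% names(ps$values))
    stop("unknown parameter: ", name, call. = FALSE)
  ps$values[[name]] <- value
  i <- match(name, ps$ranges$name)
  if (!is.na(i)) {
    ps$ranges$low[i] <- min(ps$ranges$low[i], value)
    ps$ranges$high[i] <- max(ps$ranges$high[i], value)
  }
  ps
}

#' Annual death probability from a 5-year survival rate
#'
#' Constant-hazard (exponential) conversion: the annual probability of death
#' is `1 - s5^(1/5)`, so that surviving five consecutive years reproduces the
#' 5-year survival exactly.
#'
#' @param s5 Five-year survival probability, in \[0,1\]. Vectorised.
#' @return Annual death probability.
#' @export
#' @examples
#' annual_prob_from_5yr_survival(0.957)  # FIGO stage I
annual_prob_from_5yr_survival <- function(s5) {
  if (any(!is.finite(s5)) || any(s5 < 0) || any(s5 > 1))
    stop("s5 must be in [0, 1]", call. = FALSE)
  1 - s5^(1 / 5)
}

# Annualised recurrence probability for survivors, honouring the configured
# interpretation of the published recurrence rates.
annual_recurrence <- function(ps) {
  r <- param_stages(ps, "recurrence_stage")
  if (ps$settings$recurrence_rate_mode == "cumulative_5yr")
    1 - (1 - r)^(1 / 5)
  else r
}

#' The full parameter table
#'
#' @param ps A `pmb_parameters` object (default: the base case).
#' @return Data frame with columns `name`, `base` (current value), `low`,
#'   `high`, `dist`, `origin`.
#' @export
parameter_table <- function(ps = default_parameters()) {
  tab <- ps$ranges
  tab$base <- unname(ps$values[tab$name])
  tab
}

#' Export / import the parameter table as CSV
#'
#' @param ps A `pmb_parameters` object.
#' @param path File path.
#' @return `export_parameter_table` returns `path` invisibly;
#'   `import_parameter_table` returns a `pmb_parameters` object with bases
#'   and ranges taken from the CSV (settings keep their defaults).
#' @export
export_parameter_table <- function(ps, path) {
  utils::write.csv(parameter_table(ps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_parameter_table
#' @export
import_parameter_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "base", "low", "high", "dist", "origin")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ps <- default_parameters()
  unknown <- setdiff(tab$name, ps$ranges$name)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    ps$values[[tab$name[i]]] <- tab$base[i]
    j <- match(tab$name[i], ps$ranges$name)
    ps$ranges$low[j] <- tab$low[i]
    ps$ranges$high[j] <- tab$high[i]
  }
  .assert_valid(ps)
  ps
}

# Flat config representation used by the YAML/JSON interface.
as_config_list <- function(ps) {
  out <- list(values = as.list(ps$values), settings = ps$settings)
  if (length(ps$age_tables))
    out$age_tables <- lapply(ps$age_tables, function(t)
      list(age = t$age, value = t$value))
  rng <- ps$ranges
  def <- .param_table()
  changed <- rng$low != def$low | rng$high != def$high
  if (any(changed))
    out$ranges <- lapply(which(changed), function(i)
      list(name = rng$name[i], low = rng$low[i], high = rng$high[i]))
  out
}

#' Write a parameter set to a YAML (or JSON) config file
#'
#' @param ps A `pmb_parameters` object.
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  cfg <- as_config_list(ps)
  if (grepl("\\.json$", path))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load a parameter set from a config source
#'
#' Accepts a YAML or JSON file path, or a list, overriding any subset of the
#' defaults. The config may be flat (`name: value` pairs for scalar inputs)
#' or structured with `values`, `settings`, `ranges` and `age_tables`
#' sections, as written by [write_parameters()]. Unspecified fields fall
#' back to [default_parameters()]. Unknown keys and invariant violations
#' raise errors naming the offending field.
#'
#' @param config `NULL` (defaults), a file path, or a list of overrides.
#' @return A validated `pmb_parameters` object.
#' @export
#' @examples
#' load_parameters(list(cost_molecular_test = 620))
load_parameters <- function(config = NULL) {
  ps <- default_parameters()
  if (is.null(config)) return(ps)
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  structured <- any(c("values", "settings", "ranges", "age_tables") %in% names(config))
  vals <- if (structured) config$values else
    config[setdiff(names(config), c("settings", "age_tables", "ranges"))]
  sets <- config$settings
  if (!structured) sets <- c(sets, config[intersect(names(config), names(.setting_defaults()))])
  if (!structured) vals <- vals[setdiff(names(vals), names(.setting_defaults()))]
  if (length(vals)) {
    unknown <- setdiff(names(vals), names(ps$values))
    if (length(unknown))
      stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (nm in names(vals)) ps <- perturb(ps, nm, as.numeric(vals[[nm]]))
  }
  if (length(sets)) {
    unknown <- setdiff(names(sets), names(ps$settings))
    if (length(unknown))
      stop("unknown setting(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    for (nm in names(sets)) {
      val <- sets[[nm]]
      if (nm == "cycle_order") val <- as.character(unlist(val))
      if (nm == "half_cycle_correction") val <- as.logical(val)
      ps$settings[[nm]] <- val
    }
  }
  for (rg in config$ranges) {
    i <- match(rg$name, ps$ranges$name)
    if (is.na(i)) stop("unknown parameter in ranges: ", rg$name, call. = FALSE)
    ps$ranges$low[i] <- as.numeric(rg$low)
    ps$ranges$high[i] <- as.numeric(rg$high)
  }
  for (nm in names(config$age_tables)) {
    if (!nm %in% names(ps$values))
      stop("unknown parameter in age_tables: ", nm, call. = FALSE)
    t <- config$age_tables[[nm]]
    ps$age_tables[[nm]] <- data.frame(age = as.numeric(unlist(t$age)),
                                      value = as.numeric(unlist(t$value)))
  }
  v <- validate_parameters(ps)
  if (length(v))
    stop("invalid configuration:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  ps
}
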