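# Scenario and fixture generation: parameter sets with the statistical
# structure the analysis assumes, plus degenerate fixtures with known
# closed-form outcomes, so every stage is testable without external data.

new_scenario <- function(name, description, overrides, tag) {
  structure(list(name = name, description = description,
                 overrides = overrides, tag = tag),
            class = "pmb_scenario")
}

#' @export
print.pmb_scenario <- function(x, ...) {
  cat("<pmb_scenario> ", x$name, ": ", x$description, "\n", sep = "")
  invisible(x)
}

#' Degenerate test scenarios with closed-form outcomes
#'
#' Named fixtures that pin down limiting behaviour: perfect tests (every
#' cancer detected at first presentation), zero prevalence and incidence
#' (no EC states ever occupied), an immortal cohort (no deaths), a free
#' molecular test, and undiscounted accounting.
#'
#' @return Named list of `pmb_scenario` objects.
#' @export
degenerate_scenarios <- function() {
  perfect <- as.list(stats::setNames(rep(1, 12), c(
    "sens_tvu", "spec_tvu", "sens_pipelle", "spec_pipelle",
    "sens_hysteroscopy", "spec_hysteroscopy",
    "sens_molecular_pap", "spec_molecular_pap",
    "sens_molecular_pipelle", "spec_molecular_pipelle",
    "p_pipelle_insertion", "p_pipelle_tissue")))
  immortal <- c(as.list(stats::setNames(rep(1, 4), paste0("surv5_stage_", 1:4))),
                list(p_death_other = 0))
  list(
    perfect_tests = new_scenario(
      "perfect_tests",
      "all sensitivities, specificities and procedural successes equal 1",
      perfect, "detection_certain"),
    zero_prevalence = new_scenario(
      "zero_prevalence",
      "no prevalent or incident endometrial cancer",
      list(prev_ec_pmb = 0, ec_incidence_pop = 0), "no_ec_states"),
    immortal = new_scenario(
      "immortal",
      "no death from any cause (5-year survivals 1, other-cause mortality 0)",
      immortal, "no_deaths"),
    free_molecular = new_scenario(
      "free_molecular", "molecular test at zero unit cost",
      list(cost_molecular_test = 0), "cheaper_molecular"),
    no_discounting = new_scenario(
      "no_discounting", "zero annual discount rate",
      list(discount_rate = 0), "discounted_equals_undiscounted")
  )
}

#' Apply a scenario's overrides to a parameter set
#'
#' @param ps A `pmb_parameters` object.
#' @param scenario A `pmb_scenario` (or its name in [degenerate_scenarios()]).
#' @return A validated `pmb_parameters` object.
#' @export
apply_scenario <- function(ps, scenario) {
  if (is.character(scenario)) {
    sc <- degenerate_scenarios()[[scenario]]
    if (is.null(sc)) stop("unknown scenario: ", scenario, call. = FALSE)
    scenario <- sc
  }
  for (nm in names(scenario$overrides))
    ps <- perturb(ps, nm, scenario$overrides[[nm]])
  .assert_valid(ps)
  ps
}

#' Random but internally consistent parameter set
#'
#' Generates a parameter set for property-based testing: probabilities and
#' utilities uniform within their sensitivity ranges (`"table"` profile) or
#' within \[0.001, 0.999\] (`"wide"` profile); costs log-uniform within
#' 0.5-2 times base. The FIGO stage distribution is renormalised to sum
#' to 1, and the result always passes [validate_parameters()]. The global
#' RNG state is preserved.
#'
#' @param seed Integer seed.
#' @param profile `"table"` or `"wide"`.
#' @return A validated `pmb_parameters` object.
#' @export
random_parameter_set <- function(seed, profile = c("table", "wide")) {
  profile <- match.arg(profile)
  ps <- default_parameters()
  tab <- ps$ranges
  with_preserved_seed(seed, {
    for (i in seq_len(nrow(tab))) {
      nm <- tab$name[i]
      base <- tab$base[i]
      val <- if (nm %in% .cost_params(tab) || tab$dist[i] == "gamma") {
        exp(stats::runif(1, log(pmax(base, 1e-6) * 0.5), log(pmax(base, 1e-6) * 2)))
      } else if (profile == "wide") {
        stats::runif(1, 0.001, 0.999)
      } else {
        stats::runif(1, tab$low[i], tab$high[i])
      }
      ps <- perturb(ps, nm, val)
    }
  })
  ps <- .renormalised(ps, "stage_dist_1")
  .assert_valid(ps)
  ps
}

#' Base case with machine-checkable direction expectations
#'
#' Returns the default parameter set together with named expectation flags
#' for the qualitative direction of the strategy comparison: the molecular
#' strategy should dominate (cheaper and more effective), perform fewer
#' total and fewer benign hysterectomies, and leave fewer cancers
#' undetected. Use [check_directions()] to evaluate the flags on a fitted
#' comparison.
#'
#' @return List with `parameters` (a `pmb_parameters`) and `expectations`
#'   (named character descriptions).
#' @export
base_case_directions <- function() {
  list(
    parameters = default_parameters(),
    expectations = c(
      dominant = "delta_cost < 0 and delta_qaly > 0",
      fewer_hysterectomies = "molecular total hysterectomies < usual",
      fewer_benign_hysterectomies = "molecular benign hysterectomies < usual",
      fewer_undetected = "molecular undetected cancers < usual"))
}

#' @rdname base_case_directions
#' @param comparison A `pmb_comparison` from [compare_strategies()].
#' @return `check_directions` returns a named logical vector over the same
#'   expectation names.
#' @export
check_directions <- function(comparison) {
  inc <- comparison$incremental
  c(dominant = inc$delta_cost < 0 && inc$delta_qaly > 0,
    fewer_hysterectomies =
      comparison$molecular$hysterectomies_total <
      comparison$usual$hysterectomies_total,
    fewer_benign_hysterectomies =
      comparison$molecular$hysterectomies_benign <
      comparison$usual$hysterectomies_benign,
    fewer_undetected =
      comparison$molecular$undetected_cases < comparison$usual$undetected_cases)
}
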