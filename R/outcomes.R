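# Economic outcomes: discounted QALYs, life-years, costs, event counts and
# the incremental comparison of two strategies.

#' Present value of a per-cycle stream
#'
#' `sum(values[t] / (1 + rate)^t)` for `t = 0, 1, ...`; the cycle-0 value is
#' undiscounted.
#'
#' @param values Numeric vector, one value per cycle starting at cycle 0.
#' @param rate Annual discount rate, non-negative.
#' @return The present value.
#' @export
#' @examples
#' discount_stream(c(0, 103), 0.03)  # 100
discount_stream <- function(values, rate) {
  if (!is.finite(rate) || rate < 0) stop("rate must be non-negative", call. = FALSE)
  sum(values / (1 + rate)^(seq_along(values) - 1))
}

# State utility vector in health_states() order.
.state_utilities <- function(ps) {
  u <- stats::setNames(numeric(16), .STATE_NAMES)
  u[.S_PMB] <- param(ps, "u_bleeding")
  u[.S_BEN] <- if (ps$settings$benign_hyst_utility_mode == "permanent")
    param(ps, "u_benign_hysterectomy") else param(ps, "u_bleeding")
  u[.S_UND] <- param(ps, "u_undetected")
  u[.S_DET] <- param_stages(ps, "u_detected_stage")
  u[.S_SUR] <- param_stages(ps, "u_survivor_stage")
  u
}

#' Accumulate economic outcomes over a cohort trace
#'
#' Per cycle, utility accrual is occupancy times state utility (with the
#' temporary surgery-cycle decrement for new benign hysterectomies under the
#' default utility mode), and cost accrual combines work-up costs for every
#' bleeding episode (priced by true disease status from the strategy's
#' work-up outcome), treatment costs on detection (stage I hysterectomy
#' tariff for stage I; stage II-IV tariff plus adjuvant treatment otherwise),
#' the stage-I hysterectomy tariff for benign (false-positive) surgery, and
#' the configured re-treatment tariff for survivor recurrences. Undetected
#' EC accrues work-up costs only. Streams are reported discounted and
#' undiscounted.
#'
#' @param trace A `pmb_cohort_trace` from [run_cohort()].
#' @param ps The matching `pmb_parameters`.
#' @param tree The strategy's `pmb_decision_tree` (prices the work-up).
#' @return A `pmb_outcomes` list: `qalys_*`, `life_years_*`, `cost_*`
#'   (each `_discounted`/`_undiscounted`), hysterectomy/detection/death
#'   counts, undetected-EC person-years, undetected and total cancer cases.
#' @export
accumulate_outcomes <- function(trace, ps, tree) {
  if (is.null(trace$events))
    stop("trace has no event tallies (microsimulation traces price nothing)",
         call. = FALSE)
  .assert_valid(ps)
  wk <- workup_outcome(tree)
  n_cycles <- as.integer(param(ps, "n_cycles"))
  occ <- trace$occupancy[seq_len(n_cycles), , drop = FALSE]  # cycle starts 0..n-1
  occ_end <- trace$occupancy[seq_len(n_cycles) + 1, , drop = FALSE]
  ev <- trace$events
  u <- .state_utilities(ps)

  occ_u <- occ
  if (isTRUE(ps$settings$half_cycle_correction)) occ_u <- (occ + occ_end) / 2
  qaly <- as.vector(occ_u %*% u)
  if (ps$settings$benign_hyst_utility_mode == "temporary")
    qaly <- qaly + ev$benign_hysterectomies *
      (param(ps, "u_benign_hysterectomy") - param(ps, "u_bleeding"))
  ly <- rowSums(occ_u[, .S_ALIVE, drop = FALSE])

  detections <- sapply(1:4, function(s) ev[[paste0("detections_", s)]])
  recurrences <- sapply(1:4, function(s) ev[[paste0("recurrences_", s)]])
  incident <- sapply(1:4, function(s) ev[[paste0("incident_", s)]])
  c_early <- param(ps, "cost_hysterectomy_early")
  c_late <- param(ps, "cost_hysterectomy_late")
  c_adj <- param(ps, "cost_adjuvant")
  treat_by_stage <- c(c_early, rep(c_late + c_adj, 3))
  recur_by_stage <- if (ps$settings$recurrence_cost_mode == "full")
    treat_by_stage else rep(c_adj, 4)

  cost <- ev$episodes_pmb * wk$expected_cost_given_no_ec +
    ev$episodes_undetected * wk$expected_cost_given_ec +
    as.vector(detections %*% treat_by_stage) +
    ev$benign_hysterectomies * c_early +
    as.vector(recurrences %*% recur_by_stage) +
    rowSums(occ[, .S_SUR, drop = FALSE]) * param(ps, "survivor_followup_cost")

  rate <- param(ps, "discount_rate")
  det_tot <- colSums(detections)
  undetected_cases <- .undetected_cases(trace, ps)
  total_cancers <- param(ps, "prev_ec_pmb") + sum(incident)
  structure(list(
    strategy = trace$strategy,
    qalys_discounted = discount_stream(qaly, rate),
    qalys_undiscounted = sum(qaly),
    life_years_discounted = discount_stream(ly, rate),
    life_years_undiscounted = sum(ly),
    cost_discounted = discount_stream(cost, rate),
    cost_undiscounted = sum(cost),
    hysterectomies_benign = sum(ev$benign_hysterectomies),
    hysterectomies_cancer = sum(det_tot),
    hysterectomies_cancer_by_stage = stats::setNames(det_tot, paste0("stage_", 1:4)),
    hysterectomies_total = sum(ev$benign_hysterectomies) + sum(det_tot),
    cancers_detected = sum(det_tot),
    recurrences = sum(recurrences),
    ec_deaths = sum(ev$ec_deaths),
    other_deaths = sum(ev$other_deaths),
    undetected_person_years = sum(occ[, .S_UND]),
    undetected_cases = undetected_cases,
    total_cancers = total_cancers),
    class = "pmb_outcomes")
}

# Cancers never detected over the horizon: EC or other-cause deaths occurring
# while undetected, plus cases still undetected at the end of the horizon.
# Identity: detections + undetected_cases = prevalent + incident cases.
.undetected_cases <- function(trace, ps) {
  n_cycles <- as.integer(param(ps, "n_cycles"))
  incident <- sum(sapply(1:4, function(s) sum(trace$events[[paste0("incident_", s)]])))
  detections <- sum(sapply(1:4, function(s) sum(trace$events[[paste0("detections_", s)]])))
  param(ps, "prev_ec_pmb") + incident - detections
}

#' @export
print.pmb_outcomes <- function(x, ...) {
  cat("<pmb_outcomes> strategy '", x$strategy, "'\n", sep = "")
  cat(sprintf("  QALYs (disc.): %.4f   life-years (disc.): %.4f   cost (disc.): %.2f\n",
              x$qalys_discounted, x$life_years_discounted, x$cost_discounted))
  cat(sprintf("  hysterectomies: %.5f (benign %.5f, cancer %.5f)\n",
              x$hysterectomies_total, x$hysterectomies_benign, x$hysterectomies_cancer))
  cat(sprintf("  cancers: %.5f total, %.5f never detected\n",
              x$total_cancers, x$undetected_cases))
  invisible(x)
}

#' @export
as.data.frame.pmb_outcomes <- function(x, ...) {
  flat <- x[!vapply(x, is.character, logical(1))]
  flat$hysterectomies_cancer_by_stage <- NULL
  out <- data.frame(strategy = x$strategy, flat, check.names = FALSE)
  for (s in 1:4)
    out[[paste0("hysterectomies_cancer_stage_", s)]] <-
      x$hysterectomies_cancer_by_stage[[s]]
  out
}

#' Incremental cost-effectiveness ratio
#'
#' Compares a comparator strategy against a reference:
#' `delta = comparator - reference` for discounted cost and QALYs, with
#' `icer = delta_cost / delta_qaly` when the QALY difference is non-zero.
#' A comparator that is cheaper and more effective is dominant; costlier and
#' less effective, dominated; otherwise the ICER is judged against the
#' willingness-to-pay threshold band (the upper bound decides the label).
#'
#' @param reference,comparator `pmb_outcomes` from [accumulate_outcomes()].
#' @param thresholds Willingness-to-pay band in euro/QALY (length 2).
#' @return A `pmb_icer` list: `delta_cost`, `delta_qaly`, `icer`,
#'   `classification` (one of `dominant`, `dominated`,
#'   `ICER_below_threshold`, `ICER_above_threshold`, `equal_effect`),
#'   `thresholds`.
#' @export
icer <- function(reference, comparator, thresholds = c(22000, 25000)) {
  dc <- comparator$cost_discounted - reference$cost_discounted
  dq <- comparator$qalys_discounted - reference$qalys_discounted
  if (dq == 0) {
    cls <- "equal_effect"; ic <- NA_real_
  } else {
    ic <- dc / dq
    cls <- if (dq > 0 && dc < 0) "dominant"
      else if (dq < 0 && dc > 0) "dominated"
      else if (ic <= max(thresholds)) "ICER_below_threshold"
      else "ICER_above_threshold"
  }
  structure(list(reference = reference$strategy, comparator = comparator$strategy,
                 delta_cost = dc, delta_qaly = dq, icer = ic,
                 classification = cls, thresholds = thresholds),
            class = "pmb_icer")
}

#' @export
print.pmb_icer <- function(x, ...) {
  cat("<pmb_icer> ", x$comparator, " vs ", x$reference, "\n", sep = "")
  cat(sprintf("  delta cost: %.2f   delta QALY: %.6f\n", x$delta_cost, x$delta_qaly))
  if (is.na(x$icer)) cat("  equal effect; cost difference only\n")
  else cat(sprintf("  ICER: %.0f euro/QALY (%s)\n", x$icer, x$classification))
  invisible(x)
}

#' Run both strategies end-to-end and compare them
#'
#' Builds the usual-care and molecular work-up trees, runs the cohort model
#' under each, accumulates economic outcomes, and computes the incremental
#' comparison (molecular vs usual care).
#'
#' @param ps A validated `pmb_parameters` object.
#' @return A `pmb_comparison` list with `usual`, `molecular`
#'   (`pmb_outcomes`), `incremental` (`pmb_icer`) and the two traces.
#' @export
compare_strategies <- function(ps) {
  tr_u <- build_current_strategy(ps)
  tr_m <- build_molecular_strategy(ps)
  trace_u <- run_cohort(build_transition_model(ps, tr_u), ps)
  trace_m <- run_cohort(build_transition_model(ps, tr_m), ps)
  out_u <- accumulate_outcomes(trace_u, ps, tr_u)
  out_m <- accumulate_outcomes(trace_m, ps, tr_m)
  structure(list(
    usual = out_u, molecular = out_m,
    incremental = icer(out_u, out_m,
                       c(param(ps, "wtp_threshold_low"),
                         param(ps, "wtp_threshold_high"))),
    trace_usual = trace_u, trace_molecular = trace_m),
    class = "pmb_comparison")
}

#' @export
print.pmb_comparison <- function(x, ...) {
  print(x$usual); print(x$molecular); print(x$incremental)
  invisible(x)
}
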