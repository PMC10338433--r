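# Annual-cycle Markov cohort engine.
#
# A closed cohort of 50-year-old women with postmenopausal bleeding (PMB) is
# propagated to age 85. The six conceptual health states (PMB, undetected EC,
# detected EC, EC survivor, death from EC, death from other causes) are
# expanded into 16 implementation substates: PMB splits into the bleeding
# state and the post-benign-hysterectomy state (women who underwent surgery
# for a false-positive work-up exit the bleeding loop), and each EC state is
# expanded by FIGO stage I-IV.
#
# Each annual cycle applies five events in a documented, configurable order
# (default: other-cause death, EC death, stage progression of undetected
# disease, new EC incidence, bleeding episode/work-up). Every substep is a
# stochastic matrix, so cohort mass is conserved exactly.

.STATE_NAMES <- c("pmb", "post_benign_hyst",
                  paste0("undetected_", 1:4),
                  paste0("detected_", 1:4),
                  paste0("survivor_", 1:4),
                  "death_ec", "death_other")
.S_PMB <- 1L; .S_BEN <- 2L; .S_UND <- 3:6; .S_DET <- 7:10; .S_SUR <- 11:14
.S_DEC <- 15L; .S_DOTH <- 16L
.S_ALIVE <- 1:14

#' Health-state labels of the cohort engine
#'
#' @return Character vector of the 16 implementation substates.
#' @export
health_states <- function() .STATE_NAMES

.identity_matrix <- function() {
  m <- diag(16)
  dimnames(m) <- list(.STATE_NAMES, .STATE_NAMES)
  m
}

m_death_other <- function(p) {
  m <- .identity_matrix()
  for (j in .S_ALIVE) { m[j, j] <- 1 - p; m[j, .S_DOTH] <- p }
  m
}

m_death_ec <- function(mu) {
  m <- .identity_matrix()
  for (s in 1:4) {
    for (j in c(.S_UND[s], .S_DET[s], .S_SUR[s])) {
      m[j, j] <- 1 - mu[s]; m[j, .S_DEC] <- mu[s]
    }
  }
  m
}

m_progression <- function(prog) {
  m <- .identity_matrix()
  for (s in 1:3) {
    m[.S_UND[s], .S_UND[s]] <- 1 - prog[s]
    m[.S_UND[s], .S_UND[s + 1]] <- prog[s]
  }
  m
}

m_incidence <- function(r, stage_dist) {
  m <- .identity_matrix()
  m[.S_PMB, .S_PMB] <- 1 - r
  m[.S_PMB, .S_UND] <- r * stage_dist
  m
}

m_workup <- function(b, p_det, p_fp, rec) {
  m <- .identity_matrix()
  m[.S_PMB, .S_PMB] <- 1 - b * p_fp
  m[.S_PMB, .S_BEN] <- b * p_fp
  for (s in 1:4) {
    m[.S_UND[s], .S_UND[s]] <- 1 - b * p_det
    m[.S_UND[s], .S_DET[s]] <- b * p_det
    m[.S_DET[s], .S_DET[s]] <- 0
    m[.S_DET[s], .S_SUR[s]] <- 1        # one cycle in detected EC, then survivor
    m[.S_SUR[s], .S_SUR[s]] <- 1 - rec[s]
    m[.S_SUR[s], .S_DET[s]] <- rec[s]   # recurrence re-enters detected EC
  }
  m
}

#' Build the transition model for one diagnostic strategy
#'
#' Combines the parameter set with the strategy's work-up outcome (the
#' probability that a bleeding episode ends in hysterectomy, given true
#' disease status) into the per-cycle transition structure. EC mortality is
#' the constant-hazard annualisation of the stage-specific 5-year survival
#' rates and applies to undetected, detected and survivor EC states alike;
#' survivor recurrence uses the annualised recurrence rates. New EC incidence
#' among bleeding non-EC women is the population rate partitioned across
#' obesity strata so the weighted average reproduces the population rate.
#'
#' @param ps A validated `pmb_parameters` object.
#' @param tree A `pmb_decision_tree` (see [build_current_strategy()]).
#' @return A `pmb_transition_model`.
#' @export
build_transition_model <- function(ps, tree) {
  .assert_valid(ps)
  wk <- workup_outcome(tree)
  structure(list(
    strategy = tree$name,
    workup = wk,
    order = ps$settings$cycle_order,
    stage_dist = param_stages(ps, "stage_dist"),
    prog = c(param(ps, "prog_stage_1_2"), param(ps, "prog_stage_2_3"),
             param(ps, "prog_stage_3_4")),
    rec = annual_recurrence(ps)),
    class = "pmb_transition_model")
}

#' @export
print.pmb_transition_model <- function(x, ...) {
  cat("<pmb_transition_model> strategy '", x$strategy, "', event order: ",
      paste(x$order, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# Obesity-stratum incidence partition: the weighted average of the two
# stratum rates equals the population rate, with the obese rate HR-fold the
# non-obese rate.
.stratum_incidence <- function(rate_pop, p_ob, hr) {
  r_non <- rate_pop / (1 + p_ob * (hr - 1))
  c(nonobese = r_non, obese = hr * r_non)
}

# Per-cycle, per-stratum substep matrices (age-dependent inputs resolved at
# the attained age), in the configured order.
.cycle_matrices <- function(tm, ps, age, stratum, b) {
  p_do <- param_at_age(ps, "p_death_other", age)
  mu <- annual_prob_from_5yr_survival(
    vapply(1:4, function(s) param_at_age(ps, paste0("surv5_stage_", s), age),
           numeric(1)))
  rate_pop <- param_at_age(ps, "ec_incidence_pop", age) / 1e5
  p_ob <- param_at_age(ps, "obesity_proportion", age)
  r <- .stratum_incidence(rate_pop, p_ob, param(ps, "obesity_hr"))[[stratum]]
  mats <- list(
    death_other = m_death_other(p_do),
    death_ec = m_death_ec(mu),
    progression = m_progression(tm$prog),
    incidence = m_incidence(r, tm$stage_dist),
    workup = m_workup(b, tm$workup$p_hysterectomy_given_ec,
                      tm$workup$p_hysterectomy_given_no_ec, tm$rec))
  mats[tm$order]
}

.has_age_tables <- function(ps) length(ps$age_tables) > 0

#' Initial cohort distribution
#'
#' At model entry every woman presents with postmenopausal bleeding:
#' a fraction `prev_ec_pmb` harbours undetected EC, split across FIGO
#' stages by the stage distribution; the rest are bleeding without EC.
#'
#' @param ps A validated `pmb_parameters` object.
#' @return Named occupancy vector over [health_states()], summing to 1.
#' @export
initial_distribution <- function(ps) {
  .assert_valid(ps)
  occ <- stats::setNames(numeric(16), .STATE_NAMES)
  prev <- param(ps, "prev_ec_pmb")
  occ[.S_PMB] <- 1 - prev
  occ[.S_UND] <- prev * param_stages(ps, "stage_dist")
  occ
}

.empty_events <- function(n_cycles, start_age) {
  ev <- data.frame(cycle = 0:(n_cycles - 1), age = start_age + 0:(n_cycles - 1))
  for (nm in c("benign_hysterectomies",
               paste0("detections_", 1:4), paste0("recurrences_", 1:4),
               paste0("incident_", 1:4), "ec_deaths", "other_deaths",
               "episodes_pmb", "episodes_undetected"))
    ev[[nm]] <- 0
  ev
}

# Deterministic propagation for one obesity stratum, with event tallies
# accumulated from transition flows.
.run_stratum <- function(tm, ps, stratum) {
  n_cycles <- as.integer(param(ps, "n_cycles"))
  start_age <- param(ps, "start_age")
  occ <- matrix(0, n_cycles + 1, 16, dimnames = list(NULL, .STATE_NAMES))
  occ[1, ] <- initial_distribution(ps)
  ev <- .empty_events(n_cycles, start_age)
  p_bleed <- param(ps, "p_bleeding_recurrence")
  cache <- NULL
  for (t in 0:(n_cycles - 1)) {
    b <- if (t == 0) 1 else p_bleed
    age <- start_age + t
    if (is.null(cache) || .has_age_tables(ps) || t <= 1) {
      mats <- .cycle_matrices(tm, ps, age, stratum, b)
      if (t >= 1) cache <- mats
    } else mats <- cache
    row <- occ[t + 1, ]
    i <- t + 1
    for (step in names(mats)) {
      m <- mats[[step]]
      if (step == "death_other") {
        ev$other_deaths[i] <- ev$other_deaths[i] + sum(row * m[, .S_DOTH]) - row[.S_DOTH]
      } else if (step == "death_ec") {
        ev$ec_deaths[i] <- ev$ec_deaths[i] + sum(row * m[, .S_DEC]) - row[.S_DEC]
      } else if (step == "incidence") {
        flow <- row[.S_PMB] * m[.S_PMB, .S_UND]
        for (s in 1:4) ev[[paste0("incident_", s)]][i] <- flow[s]
      } else if (step == "workup") {
        ev$episodes_pmb[i] <- row[.S_PMB] * b
        ev$episodes_undetected[i] <- sum(row[.S_UND]) * b
        ev$benign_hysterectomies[i] <- row[.S_PMB] * m[.S_PMB, .S_BEN]
        for (s in 1:4) {
          ev[[paste0("detections_", s)]][i] <- row[.S_UND[s]] * m[.S_UND[s], .S_DET[s]]
          ev[[paste0("recurrences_", s)]][i] <- row[.S_SUR[s]] * m[.S_SUR[s], .S_DET[s]]
        }
      }
      row <- as.vector(row %*% m)
    }
    occ[t + 2, ] <- row
  }
  list(occupancy = occ, events = ev)
}

#' Run the deterministic cohort model
#'
#' Propagates the initial distribution through `n_cycles` annual cycles,
#' separately for the obese and non-obese strata (which differ only in EC
#' incidence), and returns the stratum-weighted state-occupancy trace plus
#' per-cycle event tallies (benign and cancer hysterectomies, detections and
#' recurrences by stage, incident cancers, deaths, work-up episodes).
#'
#' @param tm A `pmb_transition_model`.
#' @param ps The `pmb_parameters` used to build it.
#' @return A `pmb_cohort_trace` with elements `occupancy`
#'   (`n_cycles + 1` rows over [health_states()], each summing to 1) and
#'   `events` (one row per cycle).
#' @export
run_cohort <- function(tm, ps) {
  .assert_valid(ps)
  w_ob <- param(ps, "obesity_proportion")
  res_non <- .run_stratum(tm, ps, "nonobese")
  res_ob <- if (w_ob > 0) .run_stratum(tm, ps, "obese") else res_non
  occ <- (1 - w_ob) * res_non$occupancy + w_ob * res_ob$occupancy
  ev <- res_non$events
  num <- setdiff(names(ev), c("cycle", "age"))
  ev[num] <- (1 - w_ob) * res_non$events[num] + w_ob * res_ob$events[num]
  structure(list(strategy = tm$strategy, occupancy = occ, events = ev,
                 n_individuals = NULL),
            class = "pmb_cohort_trace")
}

#' @export
print.pmb_cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  cat("<pmb_cohort_trace> strategy '", x$strategy, "', ", n, " cycles",
      if (!is.null(x$n_individuals))
        paste0(" (microsimulation, n = ", x$n_individuals, ")"), "\n", sep = "")
  alive <- sum(x$occupancy[n + 1, .S_ALIVE])
  cat(sprintf("  alive at end of horizon: %.4f of cohort\n", alive))
  invisible(x)
}

#' @export
as.data.frame.pmb_cohort_trace <- function(x, ...) {
  occ <- as.data.frame(x$occupancy)
  occ$cycle <- 0:(nrow(occ) - 1)
  if (!is.null(x$events)) {
    out <- merge(occ, x$events, by = "cycle", all.x = TRUE, sort = TRUE)
  } else {
    out <- occ
  }
  out[order(out$cycle), , drop = FALSE]
}

#' Run the individual-level microsimulation
#'
#' Independent stochastic oracle for [run_cohort()]: individual women are
#' assigned an obesity stratum and sampled through the same per-cycle
#' transition structure (transitions drawn per individual; equivalently,
#' multinomial sampling of each state's occupants). As `n_individuals`
#' grows, the aggregated occupancy converges to the deterministic trace at
#' the binomial Monte-Carlo rate.
#'
#' @param tm A `pmb_transition_model`.
#' @param ps The matching `pmb_parameters`.
#' @param n_individuals Number of simulated women.
#' @param seed Integer seed; fixes the random stream (the global RNG state
#'   is preserved).
#' @return A `pmb_cohort_trace` with occupancy proportions and
#'   `n_individuals` set; no event tallies.
#' @export
run_microsimulation <- function(tm, ps, n_individuals, seed) {
  .assert_valid(ps)
  stopifnot(n_individuals >= 1)
  n_cycles <- as.integer(param(ps, "n_cycles"))
  start_age <- param(ps, "start_age")
  p_bleed <- param(ps, "p_bleeding_recurrence")
  occ_total <- matrix(0, n_cycles + 1, 16, dimnames = list(NULL, .STATE_NAMES))
  with_preserved_seed(seed, {
    w_ob <- param(ps, "obesity_proportion")
    n_ob <- stats::rbinom(1, n_individuals, w_ob)
    ns <- c(nonobese = n_individuals - n_ob, obese = n_ob)
    init <- initial_distribution(ps)
    for (stratum in names(ns)) {
      n <- ns[[stratum]]
      if (n == 0) next
      counts <- as.vector(stats::rmultinom(1, n, init))
      occ <- matrix(0, n_cycles + 1, 16)
      occ[1, ] <- counts
      cache <- NULL
      for (t in 0:(n_cycles - 1)) {
        b <- if (t == 0) 1 else p_bleed
        if (is.null(cache) || .has_age_tables(ps) || t <= 1) {
          mats <- .cycle_matrices(tm, ps, start_age + t, stratum, b)
          p_cycle <- Reduce(`%*%`, mats)
          if (t >= 1) cache <- p_cycle
        } else p_cycle <- cache
        nxt <- numeric(16)
        for (j in which(counts > 0))
          nxt <- nxt + as.vector(stats::rmultinom(1, counts[j], p_cycle[j, ]))
        counts <- nxt
        occ[t + 2, ] <- counts
      }
      occ_total <- occ_total + occ
    }
  })
  structure(list(strategy = tm$strategy,
                 occupancy = occ_total / n_individuals, events = NULL,
                 n_individuals = n_individuals),
            class = "pmb_cohort_trace")
}
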