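test_that("discounting follows the annuity convention with cycle 0 undiscounted", {
  expect_equal(discount_stream(c(3, 4, 5), 0), 12)
  expect_equal(discount_stream(c(0, 103), 0.03), 100)
  # constant unit stream over 36 cycles: annuity-due closed form
  expect_equal(discount_stream(rep(1, 36), 0.03),
               (1 - 1.03^(-36)) / 0.03 * 1.03, tolerance = 1e-12)
  expect_error(discount_stream(1:3, -0.01), "non-negative")
})

# Minimal hand-built trace: full occupancy in one state at cycle 0, everyone
# in a death state afterwards, no events.
single_state_trace <- function(state, ps) {
  n <- as.integer(param(ps, "n_cycles"))
  occ <- matrix(0, n + 1, 16, dimnames = list(NULL, health_states()))
  occ[1, state] <- 1
  occ[2:(n + 1), "death_other"] <- 1
  structure(list(strategy = "current", occupancy = occ,
                 events = pmbcea:::.empty_events(n, param(ps, "start_age"))),
            class = "pmb_cohort_trace")
}

test_that("state utilities weight occupancy time, death accrues nothing", {
  ps <- perturb(default_parameters(), "discount_rate", 0)
  tree <- build_current_strategy(ps)
  # one undiscounted year in detected stage IV is worth its stage utility
  out <- accumulate_outcomes(single_state_trace("detected_4", ps), ps, tree)
  expect_equal(out$qalys_undiscounted, 0.48, tolerance = 1e-12)
  expect_equal(out$life_years_undiscounted, 1, tolerance = 1e-12)
  expect_equal(out$cost_undiscounted, 0)
  # a trace entirely in death states yields nothing
  dead <- single_state_trace("detected_4", ps)
  dead$occupancy[1, ] <- c(rep(0, 14), 1, 0)
  out0 <- accumulate_outcomes(dead, ps, tree)
  expect_equal(out0$qalys_undiscounted, 0)
  expect_equal(out0$life_years_undiscounted, 0)
  expect_equal(out0$cost_undiscounted, 0)
})

test_that("unit utilities make QALYs equal life-years", {
  ps <- default_parameters()
  for (nm in grep("^u_", names(ps$values), value = TRUE)) ps <- perturb(ps, nm, 1)
  tree <- build_molecular_strategy(ps)
  trace <- run_cohort(build_transition_model(ps, tree), ps)
  out <- accumulate_outcomes(trace, ps, tree)
  expect_equal(out$qalys_discounted, out$life_years_discounted, tolerance = 1e-12)
  expect_equal(out$qalys_undiscounted, out$life_years_undiscounted, tolerance = 1e-12)
})

test_that("discounted streams never exceed undiscounted ones", {
  for (ps in list(default_parameters(), random_parameter_set(21))) {
    cmp <- compare_strategies(ps)
    for (out in list(cmp$usual, cmp$molecular)) {
      expect_lte(out$qalys_discounted, out$qalys_undiscounted)
      expect_lte(out$life_years_discounted, out$life_years_undiscounted)
      expect_lte(out$cost_discounted, out$cost_undiscounted)
      expect_lte(out$qalys_discounted, out$life_years_discounted)
    }
  }
})

test_that("zero discounting collapses discounted and undiscounted totals", {
  ps <- apply_scenario(default_parameters(), "no_discounting")
  cmp <- compare_strategies(ps)
  for (out in list(cmp$usual, cmp$molecular)) {
    expect_equal(out$qalys_discounted, out$qalys_undiscounted, tolerance = 1e-12)
    expect_equal(out$cost_discounted, out$cost_undiscounted, tolerance = 1e-12)
  }
})

test_that("the ICER classifies the four quadrants and the threshold band", {
  mk <- function(cost, qaly) {
    structure(list(strategy = "x", cost_discounted = cost,
                   qalys_discounted = qaly), class = "pmb_outcomes")
  }
  ref <- mk(10000, 10)
  dom <- icer(ref, mk(9900, 10.01))
  expect_equal(dom$icer, -10000)
  expect_equal(dom$classification, "dominant")
  below <- icer(ref, mk(11000, 10.05))
  expect_equal(below$icer, 20000)
  expect_equal(below$classification, "ICER_below_threshold")
  above <- icer(ref, mk(11000, 10.01))
  expect_equal(above$classification, "ICER_above_threshold")
  expect_equal(icer(ref, mk(11000, 9.9))$classification, "dominated")
  eq <- icer(ref, mk(10500, 10))
  expect_equal(eq$classification, "equal_effect")
  expect_true(is.na(eq$icer))
  # antisymmetry: swapping arms negates the deltas and preserves the ratio
  a <- icer(ref, mk(11000, 10.05)); b <- icer(mk(11000, 10.05), ref)
  expect_equal(b$delta_cost, -a$delta_cost)
  expect_equal(b$delta_qaly, -a$delta_qaly)
  expect_equal(b$icer, a$icer)
})

test_that("identical strategies compare as equal effect at zero cost difference", {
  ps <- default_parameters()
  tree <- build_current_strategy(ps)
  trace <- run_cohort(build_transition_model(ps, tree), ps)
  out <- accumulate_outcomes(trace, ps, tree)
  inc <- icer(out, out)
  expect_equal(inc$classification, "equal_effect")
  expect_equal(inc$delta_cost, 0)
})

test_that("the molecular test price moves costs but never effectiveness", {
  ps <- default_parameters()
  dear <- perturb(ps, "cost_molecular_test", 620)
  cheap <- compare_strategies(ps)
  costly <- compare_strategies(dear)
  expect_gt(costly$molecular$cost_discounted, cheap$molecular$cost_discounted)
  expect_equal(costly$molecular$qalys_discounted, cheap$molecular$qalys_discounted,
               tolerance = 1e-12)
  expect_equal(costly$usual$cost_discounted, cheap$usual$cost_discounted,
               tolerance = 1e-12)
})

test_that("the permanent benign-hysterectomy utility mode lowers QALYs", {
  ps <- default_parameters()
  ps2 <- ps
  ps2$settings$benign_hyst_utility_mode <- "permanent"
  q_tmp <- compare_strategies(ps)$usual$qalys_discounted
  q_perm <- compare_strategies(ps2)$usual$qalys_discounted
  expect_lt(q_perm, q_tmp)
})
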