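test_that("initial distribution splits prevalent cancer across stages", {
  ps <- default_parameters()
  occ <- initial_distribution(ps)
  expect_equal(sum(occ), 1, tolerance = 1e-12)
  expect_equal(unname(occ["undetected_1"]), 0.09 * 0.705, tolerance = 1e-12)
  expect_equal(unname(occ["pmb"]), 0.91, tolerance = 1e-12)
  occ0 <- initial_distribution(perturb(ps, "prev_ec_pmb", 0))
  expect_equal(unname(occ0["pmb"]), 1)
  expect_true(all(occ0[names(occ0) != "pmb"] == 0))
})

test_that("cohort mass is conserved and death states are absorbing", {
  ps <- default_parameters()
  for (build in list(build_current_strategy, build_molecular_strategy)) {
    tm <- build_transition_model(ps, build(ps))
    trace <- run_cohort(tm, ps)
    expect_equal(nrow(trace$occupancy), 36)
    expect_lt(max(abs(rowSums(trace$occupancy) - 1)), 1e-9)
    expect_true(all(trace$occupancy >= 0))
    expect_true(all(diff(trace$occupancy[, "death_ec"]) >= -1e-15))
    expect_true(all(diff(trace$occupancy[, "death_other"]) >= -1e-15))
  }
})

test_that("zero prevalence and incidence keep the cohort out of EC states", {
  ps <- apply_scenario(default_parameters(), "zero_prevalence")
  tm <- build_transition_model(ps, build_current_strategy(ps))
  trace <- run_cohort(tm, ps)
  ec_states <- grep("undetected|detected|survivor|death_ec",
                    colnames(trace$occupancy))
  expect_equal(max(abs(trace$occupancy[, ec_states])), 0)
  expect_equal(sum(trace$events$ec_deaths), 0)
})

test_that("without death or detection all prevalent cancer progresses to stage IV", {
  ps <- default_parameters()
  ps <- perturb(ps, "p_death_other", 0)
  for (s in 1:4) ps <- perturb(ps, paste0("surv5_stage_", s), 1)
  for (nm in grep("^sens_", names(ps$values), value = TRUE)) ps <- perturb(ps, nm, 0)
  ps <- perturb(ps, "ec_incidence_pop", 0)
  tm <- build_transition_model(ps, build_current_strategy(ps))
  trace <- run_cohort(tm, ps)
  final <- trace$occupancy[36, ]
  # oracle: hand propagation of the undetected stage chain (no exits)
  stages <- 0.09 * c(0.705, 0.062, 0.149, 0.084)
  prog <- c(0.30, 0.40, 0.55)
  for (t in 1:35) {
    flow <- stages[1:3] * prog
    stages <- stages + c(-flow, 0) + c(0, flow)
  }
  expect_equal(unname(final[paste0("undetected_", 1:4)]), stages,
               tolerance = 1e-12)
  expect_lt(sum(stages[1:3]), 1e-4)          # chain has essentially drained
  expect_equal(sum(final[c("death_ec", "death_other")]), 0)
  expect_equal(max(abs(final[grep("^(detected|survivor)", names(final))])), 0)
  # remaining mass sits in the two PMB substates
  expect_equal(unname(final["pmb"] + final["post_benign_hyst"]), 0.91,
               tolerance = 1e-12)
})

test_that("perfect tests with certain bleeding leave no case undetected after entry", {
  ps <- apply_scenario(default_parameters(), "perfect_tests")
  ps <- perturb(ps, "p_bleeding_recurrence", 1)
  tm <- build_transition_model(ps, build_molecular_strategy(ps))
  trace <- run_cohort(tm, ps)
  und <- trace$occupancy[2:36, grep("^undetected", colnames(trace$occupancy))]
  expect_equal(max(abs(und)), 0)
})

test_that("the better-detecting strategy accrues fewer undetected person-years", {
  for (seed in c(NA, 7, 8)) {
    ps <- if (is.na(seed)) default_parameters() else random_parameter_set(seed)
    wk_u <- workup_outcome(build_current_strategy(ps))
    wk_m <- workup_outcome(build_molecular_strategy(ps))
    tr_u <- run_cohort(build_transition_model(ps, build_current_strategy(ps)), ps)
    tr_m <- run_cohort(build_transition_model(ps, build_molecular_strategy(ps)), ps)
    py_u <- sum(tr_u$occupancy[1:35, grep("^undetected", colnames(tr_u$occupancy))])
    py_m <- sum(tr_m$occupancy[1:35, grep("^undetected", colnames(tr_m$occupancy))])
    if (wk_m$p_hysterectomy_given_ec >= wk_u$p_hysterectomy_given_ec)
      expect_lte(py_m, py_u + 1e-12)
    else
      expect_gte(py_m, py_u - 1e-12)
  }
})

test_that("event tallies close the bookkeeping identities", {
  ps <- default_parameters()
  tm <- build_transition_model(ps, build_molecular_strategy(ps))
  trace <- run_cohort(tm, ps)
  ev <- trace$events
  # cumulative deaths from flows equal terminal death-state occupancy
  expect_equal(sum(ev$ec_deaths), unname(trace$occupancy[36, "death_ec"]),
               tolerance = 1e-12)
  expect_equal(sum(ev$other_deaths), unname(trace$occupancy[36, "death_other"]),
               tolerance = 1e-12)
  expect_equal(sum(ev$ec_deaths) + sum(ev$other_deaths),
               1 - sum(trace$occupancy[36, 1:14]), tolerance = 1e-12)
  # never-detected cases: independent oracle summing deaths that occur while
  # still in the undetected pool (deaths precede work-up in the default
  # order, incident cases enter after the death steps) plus the residual pool
  mu <- 1 - sapply(1:4, function(s) param(ps, paste0("surv5_stage_", s)))^(1 / 5)
  p_do <- param(ps, "p_death_other")
  occ_u <- trace$occupancy[1:35, paste0("undetected_", 1:4)]
  deaths_in_pool <- sum(sweep(occ_u, 2, p_do + (1 - p_do) * mu, "*"))
  final_undetected <- sum(trace$occupancy[36, paste0("undetected_", 1:4)])
  out <- accumulate_outcomes(trace, ps, build_molecular_strategy(ps))
  expect_equal(out$undetected_cases, deaths_in_pool + final_undetected,
               tolerance = 1e-9)
  expect_lt(out$undetected_cases, out$total_cancers)
})

test_that("microsimulation is seed-reproducible and converges to the cohort trace", {
  ps <- default_parameters()
  tm <- build_transition_model(ps, build_current_strategy(ps))
  a <- run_microsimulation(tm, ps, 5000, seed = 42)
  b <- run_microsimulation(tm, ps, 5000, seed = 42)
  expect_identical(a$occupancy, b$occupancy)
  big <- run_microsimulation(tm, ps, 200000, seed = 9)
  cohort <- run_cohort(tm, ps)
  expect_lt(max(abs(big$occupancy - cohort$occupancy)), 0.01)
  expect_lt(max(abs(rowSums(big$occupancy) - 1)), 1e-12)
})

test_that("a fully deterministic model makes microsimulation exact", {
  ps <- apply_scenario(default_parameters(), "zero_prevalence")
  ps <- apply_scenario(ps, "perfect_tests")   # specificity 1: no false positives
  ps <- perturb(ps, "p_death_other", 0)
  ps <- perturb(ps, "obesity_proportion", 0)
  tm <- build_transition_model(ps, build_current_strategy(ps))
  ms <- run_microsimulation(tm, ps, 500, seed = 3)
  co <- run_cohort(tm, ps)
  expect_equal(ms$occupancy, co$occupancy, tolerance = 1e-15)
})

test_that("the within-cycle event order is configurable and changes the trace", {
  ps <- default_parameters()
  ps2 <- ps
  ps2$settings$cycle_order <- c("workup", "death_other", "death_ec",
                                "progression", "incidence")
  tm1 <- build_transition_model(ps, build_current_strategy(ps))
  tm2 <- build_transition_model(ps2, build_current_strategy(ps2))
  t1 <- run_cohort(tm1, ps)
  t2 <- run_cohort(tm2, ps2)
  expect_lt(max(abs(rowSums(t2$occupancy) - 1)), 1e-9)
  expect_gt(max(abs(t1$occupancy - t2$occupancy)), 1e-6)
  # first-cycle deaths cannot precede the first work-up under workup-first order
  expect_gt(sum(t1$events$ec_deaths), sum(t2$events$ec_deaths))
})

test_that("age tables make inputs age-dependent", {
  ps <- load_parameters(list(
    age_tables = list(p_death_other = list(age = c(50, 70),
                                           value = c(0.005, 0.10)))))
  tm <- build_transition_model(ps, build_current_strategy(ps))
  trace <- run_cohort(tm, ps)
  deaths <- trace$events$other_deaths
  alive <- rowSums(trace$occupancy[1:35, 1:14])
  hazard <- deaths / alive
  expect_lt(max(abs(hazard[trace$events$age < 70] - 0.005)), 2e-3)
  expect_gt(mean(hazard[trace$events$age >= 70]), 0.05)
})
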