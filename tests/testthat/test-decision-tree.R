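test_that("usual-care work-up reproduces the hand-enumerated pathway arithmetic", {
  ps <- default_parameters()
  tr <- build_current_strategy(ps)
  succ <- 0.92 * 0.87  # insertion then adequate tissue
  # oracle: explicit path enumeration of the Fig-style usual-care algorithm
  p_ec <- 0.906 * (succ * 0.94 + (1 - succ) * 0.864)
  p_no <- (1 - 0.235) * (succ * (1 - 0.99) + (1 - succ) * (1 - 0.992))
  cost_no <- 148 + 31 + (1 - 0.235) * (succ * 105 + (1 - succ) * 134)
  ec <- evaluate_tree(tr, "EC")
  no <- evaluate_tree(tr, "no_EC")
  expect_equal(ec$p_hysterectomy, p_ec, tolerance = 1e-12)
  expect_equal(no$p_hysterectomy, p_no, tolerance = 1e-12)
  expect_equal(no$expected_cost, cost_no, tolerance = 1e-12)
  expect_equal(nrow(enumerate_paths(tr, "EC")), 7)
  # TVU executes once per episode; pipelle morphology only after success
  expect_equal(unname(ec$procedure_counts["tvu"]), 1)
  expect_equal(unname(ec$procedure_counts["pipelle_morphology"]), 0.906 * succ,
               tolerance = 1e-12)
})

test_that("molecular work-up reproduces the hand-enumerated pathway arithmetic", {
  ps <- default_parameters()
  tr <- build_molecular_strategy(ps)
  # oracle: explicit enumeration; molecular positives confirmed by hysteroscopy
  pap_ec <- 0.78 * 0.864
  pip_ec <- 0.96 * 0.864
  p_ec <- 0.094 * pap_ec +
    0.906 * (0.08 * pap_ec +
             0.92 * (0.13 * pip_ec + 0.87 * (0.94 + 0.06 * pip_ec)))
  pap_no <- (1 - 0.97) * (1 - 0.992)
  pip_no <- (1 - 0.94) * (1 - 0.992)
  p_no <- 0.235 * pap_no +
    0.765 * (0.08 * pap_no +
             0.92 * (0.13 * pip_no + 0.87 * ((1 - 0.99) + 0.99 * pip_no)))
  ec <- evaluate_tree(tr, "EC")
  no <- evaluate_tree(tr, "no_EC")
  expect_equal(ec$p_hysterectomy, p_ec, tolerance = 1e-12)
  expect_equal(no$p_hysterectomy, p_no, tolerance = 1e-12)
  expect_equal(ec$p_hysterectomy, 0.9198, tolerance = 1e-4)
  expect_equal(no$p_hysterectomy, 0.00653, tolerance = 1e-3)
})

test_that("perfect tests detect every cancer and no healthy woman", {
  ps <- default_parameters()
  for (nm in grep("^(sens|spec)_", names(ps$values), value = TRUE))
    ps <- perturb(ps, nm, 1)
  ps <- perturb(perturb(ps, "p_pipelle_insertion", 1), "p_pipelle_tissue", 1)
  for (build in list(build_current_strategy, build_molecular_strategy)) {
    tr <- build(ps)
    expect_equal(evaluate_tree(tr, "EC")$p_hysterectomy, 1)
    expect_equal(evaluate_tree(tr, "no_EC")$p_hysterectomy, 0)
  }
})

test_that("a dead molecular test cannot detect more than usual care", {
  ps <- perturb(perturb(default_parameters(), "sens_molecular_pap", 0),
                "sens_molecular_pipelle", 0)
  p_mol <- evaluate_tree(build_molecular_strategy(ps), "EC")$p_hysterectomy
  p_cur <- evaluate_tree(build_current_strategy(ps), "EC")$p_hysterectomy
  expect_lte(p_mol, p_cur)
})

test_that("path probabilities are conserved and aggregate to the evaluator", {
  sets <- c(list(default_parameters()),
            lapply(1:4, function(s) random_parameter_set(100 + s, "wide")))
  for (ps in sets) {
    for (build in list(build_current_strategy, build_molecular_strategy)) {
      tr <- build(ps)
      for (status in c("EC", "no_EC")) {
        paths <- enumerate_paths(tr, status)
        expect_equal(sum(paths$probability), 1, tolerance = 1e-9)
        agg <- aggregate_paths(tr, status)
        ev <- evaluate_tree(tr, status)
        expect_equal(ev$p_hysterectomy, agg$p_hysterectomy, tolerance = 1e-15)
        expect_equal(ev$expected_cost, agg$expected_cost, tolerance = 1e-15)
        expect_true(ev$p_hysterectomy >= 0 && ev$p_hysterectomy <= 1)
      }
    }
  }
})

test_that("evaluator equals the path-enumeration oracle on randomized trees", {
  for (seed in 1:25) {
    tr <- random_workup_tree(seed)
    for (status in c("EC", "no_EC")) {
      agg <- aggregate_paths(tr, status)
      ev <- evaluate_tree(tr, status)
      expect_equal(ev$p_hysterectomy, agg$p_hysterectomy, tolerance = 1e-15)
      expect_equal(ev$expected_cost, agg$expected_cost, tolerance = 1e-15)
      expect_equal(sum(enumerate_paths(tr, status)$probability), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("detection improves with sensitivity, false positives fall with specificity", {
  ps <- default_parameters()
  sens <- grep("^sens_", ps$ranges$name, value = TRUE)
  spec <- grep("^spec_", ps$ranges$name, value = TRUE)
  for (build in list(build_current_strategy, build_molecular_strategy)) {
    base_ec <- evaluate_tree(build(ps), "EC")$p_hysterectomy
    base_no <- evaluate_tree(build(ps), "no_EC")$p_hysterectomy
    for (nm in sens) {
      up <- perturb(ps, nm, min(1, param(ps, nm) + 0.05))
      expect_gte(evaluate_tree(build(up), "EC")$p_hysterectomy, base_ec - 1e-12)
    }
    for (nm in spec) {
      up <- perturb(ps, nm, min(1, param(ps, nm) + 0.005))
      expect_lte(evaluate_tree(build(up), "no_EC")$p_hysterectomy, base_no + 1e-12)
    }
  }
})

test_that("a single perfect-test tree yields certain detection at the node cost", {
  tr <- structure(list(name = "single", root = tree_test(
    "only", 1, 1, 42, tree_terminal("hysterectomy"), tree_terminal("no_action"))),
    class = "pmb_decision_tree")
  ec <- evaluate_tree(tr, "EC")
  expect_equal(ec$p_hysterectomy, 1)
  expect_equal(ec$expected_cost, 42)
  expect_equal(evaluate_tree(tr, "no_EC")$p_hysterectomy, 0)
})

test_that("malformed trees raise structural errors", {
  bad <- structure(list(name = "bad", root = tree_test(
    "t", 0.5, 0.5, 1, tree_terminal("no_action"), "not a node")),
    class = "pmb_decision_tree")
  expect_error(evaluate_tree(bad, "EC"), "dangling")
  expect_error(evaluate_tree(bad, "sick"), "disease_status")
})

test_that("trees serialise to YAML and back without changing behaviour", {
  ps <- default_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  for (build in list(build_current_strategy, build_molecular_strategy)) {
    tr <- build(ps)
    write_tree(tr, path)
    back <- read_tree(path)
    for (status in c("EC", "no_EC"))
      expect_equal(evaluate_tree(back, status), evaluate_tree(tr, status))
  }
})
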