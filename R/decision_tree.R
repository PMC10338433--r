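# Diagnostic work-up pathways as declarative trees over imperfect tests.
#
# A tree is evaluated separately for the two true disease statuses: branch
# probabilities at a test node use the test's sensitivity when the woman has
# endometrial cancer and the specificity complement when she does not, while
# procedural success splits (pipelle insertion, tissue adequacy) are
# independent of disease status. Successive tests are conditionally
# independent given disease status.

#' Decision-tree node constructors
#'
#' `tree_test()` is a diagnostic test with a sensitivity/specificity operating
#' point and a cost charged whenever the node executes. `tree_chance()` is a
#' disease-independent success split (e.g. pipelle insertion). `tree_terminal()`
#' ends a pathway with a clinical action.
#'
#' @param name Node label; expected procedure counts are reported per label.
#' @param sens,spec Test sensitivity and specificity, in \[0,1\].
#' @param cost Cost in euros charged when the node executes.
#' @param on_positive,on_negative,on_success,on_failure Child nodes.
#' @param p_success Probability of the success branch.
#' @param action One of `"hysterectomy"`, `"no_action"`.
#' @return A `pmb_tree_node` list.
#' @export
tree_test <- function(name, sens, spec, cost, on_positive, on_negative) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1, cost >= 0)
  structure(list(type = "test", name = name, sens = sens, spec = spec,
                 cost = cost, on_positive = on_positive,
                 on_negative = on_negative),
            class = "pmb_tree_node")
}

#' @rdname tree_test
#' @export
tree_chance <- function(name, p_success, cost, on_success, on_failure) {
  stopifnot(p_success >= 0, p_success <= 1, cost >= 0)
  structure(list(type = "chance", name = name, p_success = p_success,
                 cost = cost, on_success = on_success,
                 on_failure = on_failure),
            class = "pmb_tree_node")
}

#' @rdname tree_test
#' @export
tree_terminal <- function(action = c("no_action", "hysterectomy")) {
  action <- match.arg(action)
  structure(list(type = "terminal", action = action),
            class = "pmb_tree_node")
}

new_tree <- function(name, root) {
  structure(list(name = name, root = root), class = "pmb_decision_tree")
}

#' @export
print.pmb_decision_tree <- function(x, ...) {
  paths <- enumerate_paths(x, "EC")
  cat("<pmb_decision_tree> '", x$name, "': ", nrow(paths),
      " root-to-leaf paths\n", sep = "")
  invisible(x)
}

#' Build the usual-care diagnostic strategy
#'
#' Transvaginal ultrasound (TVU) at the first gynaecological visit (charged
#' with the initial visit); a negative TVU ends the work-up. On increased
#' endometrial thickness a pipelle biopsy is attempted: insertion failure or
#' an inadequate tissue sample routes to hysteroscopy, an adequate sample to
#' morphological assessment. A positive biopsy result (pipelle morphology or
#' hysteroscopy) leads to hysterectomy; a negative result ends the work-up.
#'
#' @param ps A validated `pmb_parameters` object.
#' @return A `pmb_decision_tree`.
#' @export
build_current_strategy <- function(ps) {
  .assert_valid(ps)
  hyst <- tree_terminal("hysterectomy")
  none <- tree_terminal("no_action")
  hscope <- tree_test("hysteroscopy",
                      param(ps, "sens_hysteroscopy"), param(ps, "spec_hysteroscopy"),
                      param(ps, "cost_hysteroscopy"), hyst, none)
  morph <- tree_test("pipelle_morphology",
                     param(ps, "sens_pipelle"), param(ps, "spec_pipelle"),
                     param(ps, "cost_pipelle"), hyst, none)
  tissue <- tree_chance("pipelle_tissue", param(ps, "p_pipelle_tissue"), 0,
                        morph, hscope)
  insertion <- tree_chance("pipelle_insertion", param(ps, "p_pipelle_insertion"), 0,
                           tissue, hscope)
  tvu <- tree_test("tvu", param(ps, "sens_tvu"), param(ps, "spec_tvu"),
                   param(ps, "cost_initial_visit") + param(ps, "cost_tvu"),
                   insertion, none)
  new_tree("current", tvu)
}

#' Build the molecular-test-augmented diagnostic strategy
#'
#' Extends the usual work-up with molecular testing on minimally invasive
#' samples: a cervicovaginal Pap-brush molecular test when the TVU is
#' negative or pipelle insertion fails, and a molecular test on the
#' endometrial sample when pipelle morphology is negative or the tissue
#' amount is insufficient. Any molecular-positive result is confirmed by
#' hysteroscopy before hysterectomy (the conservative reading that keeps the
#' existing diagnostic steps); a positive pipelle morphology still leads
#' directly to hysterectomy.
#'
#' @param ps A validated `pmb_parameters` object.
#' @return A `pmb_decision_tree`.
#' @export
build_molecular_strategy <- function(ps) {
  .assert_valid(ps)
  hyst <- tree_terminal("hysterectomy")
  none <- tree_terminal("no_action")
  confirm <- tree_test("hysteroscopy",
                       param(ps, "sens_hysteroscopy"), param(ps, "spec_hysteroscopy"),
                       param(ps, "cost_hysteroscopy"), hyst, none)
  pap_mol <- tree_test("molecular_pap",
                       param(ps, "sens_molecular_pap"), param(ps, "spec_molecular_pap"),
                       param(ps, "cost_pap_smear") + param(ps, "cost_molecular_test"),
                       confirm, none)
  pip_mol <- tree_test("molecular_pipelle",
                       param(ps, "sens_molecular_pipelle"),
                       param(ps, "spec_molecular_pipelle"),
                       param(ps, "cost_molecular_test"), confirm, none)
  morph <- tree_test("pipelle_morphology",
                     param(ps, "sens_pipelle"), param(ps, "spec_pipelle"),
                     param(ps, "cost_pipelle"), hyst, pip_mol)
  tissue <- tree_chance("pipelle_tissue", param(ps, "p_pipelle_tissue"), 0,
                        morph, pip_mol)
  insertion <- tree_chance("pipelle_insertion", param(ps, "p_pipelle_insertion"), 0,
                           tissue, pap_mol)
  tvu <- tree_test("tvu", param(ps, "sens_tvu"), param(ps, "spec_tvu"),
                   param(ps, "cost_initial_visit") + param(ps, "cost_tvu"),
                   insertion, pap_mol)
  new_tree("molecular", tvu)
}

.check_status <- function(disease_status) {
  if (!disease_status %in% c("EC", "no_EC"))
    stop('disease_status must be "EC" or "no_EC"', call. = FALSE)
  disease_status
}

#' Enumerate all root-to-leaf paths of a work-up tree
#'
#' Exhaustive, order-stable enumeration; aggregating the result reproduces
#' [evaluate_tree()] exactly. Serves as the path-probability oracle for the
#' aggregate evaluator.
#'
#' @param tree A `pmb_decision_tree` (or a bare `pmb_tree_node`).
#' @param disease_status `"EC"` or `"no_EC"`.
#' @param max_depth Structural guard against cyclic node references.
#' @return Data frame with one row per path: `path` (slash-separated branch
#'   labels), `probability`, `cost`, `action`.
#' @export
enumerate_paths <- function(tree, disease_status, max_depth = 64) {
  .check_status(disease_status)
  root <- if (inherits(tree, "pmb_decision_tree")) tree$root else tree
  ec <- identical(disease_status, "EC")
  out <- list()
  walk <- function(node, label, prob, cost, depth) {
    if (depth > max_depth)
      stop("malformed tree: depth exceeds ", max_depth,
           " (cyclic node reference?)", call. = FALSE)
    if (!inherits(node, "pmb_tree_node"))
      stop("malformed tree: dangling branch (not a pmb_tree_node)", call. = FALSE)
    if (node$type == "terminal") {
      out[[length(out) + 1]] <<- data.frame(
        path = paste(label, collapse = "/"), probability = prob,
        cost = cost, action = node$action, stringsAsFactors = FALSE)
      return(invisible())
    }
    cost <- cost + node$cost
    if (node$type == "test") {
      p_pos <- if (ec) node$sens else 1 - node$spec
      walk(node$on_positive, c(label, paste0(node$name, "+")),
           prob * p_pos, cost, depth + 1)
      walk(node$on_negative, c(label, paste0(node$name, "-")),
           prob * (1 - p_pos), cost, depth + 1)
    } else if (node$type == "chance") {
      walk(node$on_success, c(label, paste0(node$name, ":ok")),
           prob * node$p_success, cost, depth + 1)
      walk(node$on_failure, c(label, paste0(node$name, ":fail")),
           prob * (1 - node$p_success), cost, depth + 1)
    } else stop("malformed tree: unknown node type ", node$type, call. = FALSE)
  }
  walk(root, character(0), 1, 0, 1)
  do.call(rbind, out)
}

#' Evaluate a work-up tree for one true disease status
#'
#' Sums over all root-to-leaf paths: the probability that the work-up ends in
#' hysterectomy, the expected work-up cost, and the expected number of
#' executions of each named node.
#'
#' @inheritParams enumerate_paths
#' @return List with `p_hysterectomy`, `expected_cost` and
#'   `procedure_counts` (named numeric).
#' @export
evaluate_tree <- function(tree, disease_status) {
  .check_status(disease_status)
  root <- if (inherits(tree, "pmb_decision_tree")) tree$root else tree
  ec <- identical(disease_status, "EC")
  p_hyst <- 0; e_cost <- 0
  counts <- new.env(parent = emptyenv())
  walk <- function(node, prob, depth) {
    if (depth > 64) stop("malformed tree: cyclic node reference?", call. = FALSE)
    if (!inherits(node, "pmb_tree_node"))
      stop("malformed tree: dangling branch", call. = FALSE)
    if (node$type == "terminal") {
      if (node$action == "hysterectomy") p_hyst <<- p_hyst + prob
      return(invisible())
    }
    e_cost <<- e_cost + prob * node$cost
    prev <- mget(node$name, envir = counts, ifnotfound = 0)[[1]]
    assign(node$name, prev + prob, envir = counts)
    if (node$type == "test") {
      p_pos <- if (ec) node$sens else 1 - node$spec
      walk(node$on_positive, prob * p_pos, depth + 1)
      walk(node$on_negative, prob * (1 - p_pos), depth + 1)
    } else {
      walk(node$on_success, prob * node$p_success, depth + 1)
      walk(node$on_failure, prob * (1 - node$p_success), depth + 1)
    }
  }
  walk(root, 1, 1)
  list(p_hysterectomy = p_hyst, expected_cost = e_cost,
       procedure_counts = unlist(as.list(counts)))
}

#' Work-up outcome of a strategy, by true disease status
#'
#' @param tree A `pmb_decision_tree`.
#' @return A `pmb_workup_outcome`: hysterectomy probabilities, expected
#'   work-up costs and expected procedure counts given EC and given no EC.
#' @export
workup_outcome <- function(tree) {
  ec <- evaluate_tree(tree, "EC")
  no <- evaluate_tree(tree, "no_EC")
  structure(list(
    strategy = tree$name,
    p_hysterectomy_given_ec = ec$p_hysterectomy,
    p_hysterectomy_given_no_ec = no$p_hysterectomy,
    expected_cost_given_ec = ec$expected_cost,
    expected_cost_given_no_ec = no$expected_cost,
    procedure_counts_ec = ec$procedure_counts,
    procedure_counts_no_ec = no$procedure_counts),
    class = "pmb_workup_outcome")
}

#' @export
print.pmb_workup_outcome <- function(x, ...) {
  cat("<pmb_workup_outcome> strategy '", x$strategy, "'\n", sep = "")
  cat(sprintf("  P(hysterectomy | EC)    = %.4f   E[cost | EC]    = %8.2f\n",
              x$p_hysterectomy_given_ec, x$expected_cost_given_ec))
  cat(sprintf("  P(hysterectomy | no EC) = %.4f   E[cost | no EC] = %8.2f\n",
              x$p_hysterectomy_given_no_ec, x$expected_cost_given_no_ec))
  invisible(x)
}

# Serialisation: trees as plain nested lists for the YAML config dialect, so
# alternative branch topologies can be explored without code changes.
tree_node_to_list <- function(node) {
  if (node$type == "terminal") return(list(type = "terminal", action = node$action))
  base <- list(type = node$type, name = node$name, cost = node$cost)
  if (node$type == "test") {
    c(base, list(sens = node$sens, spec = node$spec,
                 on_positive = tree_node_to_list(node$on_positive),
                 on_negative = tree_node_to_list(node$on_negative)))
  } else {
    c(base, list(p_success = node$p_success,
                 on_success = tree_node_to_list(node$on_success),
                 on_failure = tree_node_to_list(node$on_failure)))
  }
}

tree_node_from_list <- function(x) {
  switch(x$type,
    terminal = tree_terminal(x$action),
    test = tree_test(x$name, x$sens, x$spec, x$cost,
                     tree_node_from_list(x$on_positive),
                     tree_node_from_list(x$on_negative)),
    chance = tree_chance(x$name, x$p_success, x$cost,
                         tree_node_from_list(x$on_success),
                         tree_node_from_list(x$on_failure)),
    stop("unknown node type in tree definition: ", x$type, call. = FALSE))
}

#' Write / read a decision tree as a YAML document
#'
#' @param tree A `pmb_decision_tree`.
#' @param path File path.
#' @return `write_tree` returns `path` invisibly; `read_tree` the tree.
#' @export
write_tree <- function(tree, path) {
  yaml::write_yaml(list(name = tree$name,
                        root = tree_node_to_list(tree$root)), path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  x <- yaml::read_yaml(path)
  new_tree(x$name, tree_node_from_list(x$root))
}
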