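# Shared fixtures, built in code.

# Parameter set whose sensitivity ranges are all collapsed to the base value,
# so probabilistic draws are degenerate.
zero_variance_parameters <- function(ps = default_parameters()) {
  ps$ranges$low <- ps$ranges$base <- unname(ps$values[ps$ranges$name])
  ps$ranges$high <- ps$ranges$low
  ps
}

# Random well-formed work-up tree for oracle-equivalence properties: a few
# levels of randomly chosen test/chance nodes over random operating points.
random_workup_tree <- function(seed, max_depth = 4) {
  grow <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.35)
      return(tree_terminal(sample(c("hysterectomy", "no_action"), 1)))
    if (stats::runif(1) < 0.6)
      tree_test(paste0("test_d", depth, "_", sample.int(1000, 1)),
                stats::runif(1), stats::runif(1), stats::runif(1, 0, 500),
                grow(depth + 1), grow(depth + 1))
    else
      tree_chance(paste0("chance_d", depth, "_", sample.int(1000, 1)),
                  stats::runif(1), stats::runif(1, 0, 100),
                  grow(depth + 1), grow(depth + 1))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  structure(list(name = paste0("random_", seed), root = grow(1)),
            class = "pmb_decision_tree")
}

# Independent aggregation of enumerate_paths(), used as the oracle for
# evaluate_tree().
aggregate_paths <- function(tree, status) {
  p <- enumerate_paths(tree, status)
  list(p_hysterectomy = sum(p$probability[p$action == "hysterectomy"]),
       expected_cost = sum(p$probability * p$cost))
}
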