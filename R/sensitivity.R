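# Deterministic and probabilistic sensitivity analyses.

#' One-way deterministic sensitivity analysis
#'
#' For each parameter, rebuilds both strategies and the full model at the
#' low and the high bound of its sensitivity range, holding all other
#' parameters fixed, and records the resulting incremental comparison.
#'
#' @param ps A validated `pmb_parameters` object.
#' @param parameters Character vector of parameter names (default: every
#'   parameter with a sensitivity range).
#' @return A `pmb_tornado` data frame: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `delta_cost_low/high`, `delta_qaly_low/high`,
#'   `icer_base`, `classification_low/high`, `span`, sorted by decreasing
#'   ICER span.
#' @export
one_way_dsa <- function(ps, parameters = NULL) {
  .assert_valid(ps)
  tab <- ps$ranges
  if (is.null(parameters)) parameters <- tab$name
  missing <- setdiff(parameters, tab$name)
  if (length(missing))
    stop("no sensitivity range for parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  base <- compare_strategies(ps)$incremental
  one <- function(nm, value) {
    inc <- compare_strategies(.renormalised(perturb(ps, nm, value), nm))$incremental
    c(icer = inc$icer, dc = inc$delta_cost, dq = inc$delta_qaly,
      cls = inc$classification)
  }
  rows <- lapply(parameters, function(nm) {
    i <- match(nm, tab$name)
    lo <- one(nm, tab$low[i]); hi <- one(nm, tab$high[i])
    data.frame(parameter = nm, low = tab$low[i], high = tab$high[i],
               icer_low = as.numeric(lo[["icer"]]),
               icer_high = as.numeric(hi[["icer"]]),
               delta_cost_low = as.numeric(lo[["dc"]]),
               delta_cost_high = as.numeric(hi[["dc"]]),
               delta_qaly_low = as.numeric(lo[["dq"]]),
               delta_qaly_high = as.numeric(hi[["dq"]]),
               classification_low = lo[["cls"]], classification_high = hi[["cls"]],
               icer_base = base$icer, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$span <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  class(out) <- c("pmb_tornado", "data.frame")
  out
}

# Stage-distribution entries must keep summing to 1 after a single-entry
# perturbation or a joint redraw.
.renormalised <- function(ps, touched) {
  if (!any(startsWith(touched, "stage_dist_"))) return(ps)
  sd <- param_stages(ps, "stage_dist")
  sd <- sd / sum(sd)
  for (s in 1:4) ps <- perturb(ps, paste0("stage_dist_", s), sd[s])
  ps
}

#' Draw parameter values for probabilistic sensitivity analysis
#'
#' Moment-matched draws: the distribution mean equals the base value and the
#' standard deviation is `(high - low) / (2 * 1.96)`, treating the
#' sensitivity range as a 95% interval. Probabilities and utilities use a
#' beta distribution, costs and positive ratios a gamma distribution
#' (`shape = mean^2/var`, `rate = mean/var`). A degenerate `sd = 0` returns
#' the base value exactly.
#'
#' @param base Base value (distribution mean).
#' @param low,high Range bounds; define the standard deviation.
#' @param kind `"beta"` or `"gamma"`.
#' @param n Number of draws.
#' @param sd Standard deviation override (defaults to the range-derived sd).
#' @return Numeric vector of `n` draws.
#' @export
draw_parameter <- function(base, low, high, kind = c("beta", "gamma"), n = 1,
                           sd = (high - low) / (2 * 1.96)) {
  kind <- match.arg(kind)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (sd == 0) return(rep(base, n))
  v <- sd^2
  if (kind == "beta") {
    if (base <= 0 || base >= 1)
      stop("beta draws need a base value strictly inside (0, 1); got ", base,
           call. = FALSE)
    if (v >= base * (1 - base))
      stop("beta variance too large for mean ", base, call. = FALSE)
    k <- base * (1 - base) / v - 1
    stats::rbeta(n, base * k, (1 - base) * k)
  } else {
    if (base <= 0)
      stop("gamma draws need a positive base value; got ", base, call. = FALSE)
    stats::rgamma(n, shape = base^2 / v, rate = base / v)
  }
}

#' Redraw every uncertain parameter of a set
#'
#' Draws each ranged parameter per [draw_parameter()] (independently; no
#' correlation structure is imposed), renormalises the FIGO stage
#' distribution to sum to 1, and returns the perturbed set.
#'
#' @param ps A validated `pmb_parameters` object.
#' @param fixed Names excluded from drawing (kept at their current values).
#' @return A `pmb_parameters` object.
#' @export
draw_parameter_set <- function(ps, fixed = character(0)) {
  tab <- ps$ranges
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    if (nm %in% fixed) next
    val <- draw_parameter(param(ps, nm), tab$low[i], tab$high[i], tab$dist[i])
    ps <- perturb(ps, nm, val)
  }
  .renormalised(ps, "stage_dist_1")
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo evaluation of decision uncertainty: per draw, every uncertain
#' parameter is redrawn from its beta/gamma distribution, both strategies are
#' evaluated end-to-end, and the incremental cost and QALYs are recorded.
#' A draw is cost-effective when its incremental net monetary benefit
#' `delta_qaly * wtp - delta_cost` is positive at the stated
#' willingness-to-pay (dominant draws therefore count as cost-effective).
#'
#' @param ps A validated `pmb_parameters` object.
#' @param n_draws Number of Monte-Carlo iterations.
#' @param seed Integer seed fixing the stream (global RNG state preserved).
#' @param wtp Willingness-to-pay for the headline cost-effective fraction
#'   (default: the upper threshold in `ps`).
#' @param fixed Parameter names held at their current values.
#' @return A `pmb_psa` data frame (one row per draw: `draw`, `delta_cost`,
#'   `delta_qaly`, `nmb`, `cost_effective`) with attributes `wtp`, `seed`,
#'   `fraction_cost_effective` and `fraction_cost_effective_low` (at the
#'   lower threshold).
#' @export
psa <- function(ps, n_draws = 1000, seed = 1, wtp = NULL, fixed = character(0)) {
  .assert_valid(ps)
  stopifnot(n_draws >= 1)
  if (is.null(wtp)) wtp <- param(ps, "wtp_threshold_high")
  wtp_low <- param(ps, "wtp_threshold_low")
  dc <- dq <- numeric(n_draws)
  with_preserved_seed(seed, {
    for (i in seq_len(n_draws)) {
      drawn <- draw_parameter_set(ps, fixed = fixed)
      inc <- compare_strategies(drawn)$incremental
      dc[i] <- inc$delta_cost; dq[i] <- inc$delta_qaly
    }
  })
  out <- data.frame(draw = seq_len(n_draws), delta_cost = dc, delta_qaly = dq,
                    nmb = dq * wtp - dc)
  out$cost_effective <- out$nmb > 0
  attr(out, "wtp") <- wtp
  attr(out, "seed") <- seed
  attr(out, "fraction_cost_effective") <- mean(out$cost_effective)
  attr(out, "fraction_cost_effective_low") <- mean(dq * wtp_low - dc > 0)
  class(out) <- c("pmb_psa", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Per willingness-to-pay value, the fraction of PSA draws with positive
#' incremental net monetary benefit.
#'
#' @param samples A `pmb_psa` data frame (or any data frame with
#'   `delta_cost` and `delta_qaly`).
#' @param wtp_grid Numeric grid of willingness-to-pay values (euro/QALY).
#' @return Data frame `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 50000, by = 1000)) {
  if (NROW(samples) == 0) stop("no PSA samples supplied", call. = FALSE)
  prob <- vapply(wtp_grid, function(w)
    mean(samples$delta_qaly * w - samples$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' Molecular-test-cost sweep
#'
#' Reruns the PSA across a grid of molecular test unit costs (the cost under
#' study is held fixed within each PSA, all other uncertain parameters are
#' redrawn) and reports the fraction of cost-effective draws per grid point.
#' The same seed is used at every grid point, so the fraction is
#' non-increasing in the test cost by construction.
#'
#' @param ps A validated `pmb_parameters` object.
#' @param cost_grid Non-negative molecular test costs to evaluate.
#' @param n_draws,seed,wtp As in [psa()].
#' @return Data frame `molecular_test_cost`, `fraction_cost_effective`.
#' @export
test_cost_sweep <- function(ps, cost_grid = seq(0, 1000, by = 100),
                            n_draws = 1000, seed = 1, wtp = NULL) {
  stopifnot(all(cost_grid >= 0))
  rows <- lapply(cost_grid, function(cost) {
    ps2 <- perturb(ps, "cost_molecular_test", cost)
    res <- psa(ps2, n_draws = n_draws, seed = seed, wtp = wtp,
               fixed = "cost_molecular_test")
    data.frame(molecular_test_cost = cost,
               fraction_cost_effective = attr(res, "fraction_cost_effective"))
  })
  do.call(rbind, rows)
}

#' Multivariate probabilistic sensitivity analysis
#'
#' Jointly redraws a named subset of influential parameters with standard
#' deviation equal to a stated fraction of each base value (all other
#' parameters fixed) and reports the fraction of draws below the
#' cost-effectiveness threshold (positive incremental net monetary benefit).
#'
#' @param ps A validated `pmb_parameters` object.
#' @param parameters Subset to vary; the default is the set with the
#'   greatest one-way impact: TVU sensitivity, hysteroscopy specificity,
#'   and the stage I EC, stage IV EC and bleeding (PMB) utilities.
#' @param deviation_fraction Standard deviation as a fraction of the base
#'   value (e.g. `1/10`, `1/6`).
#' @param n_draws,seed,wtp As in [psa()].
#' @return A `pmb_psa` data frame (see [psa()]).
#' @export
multivariate_psa <- function(ps,
                             parameters = c("sens_tvu", "spec_hysteroscopy",
                                            "u_detected_stage_1",
                                            "u_detected_stage_4", "u_bleeding"),
                             deviation_fraction = 1 / 10,
                             n_draws = 1000, seed = 1, wtp = NULL) {
  .assert_valid(ps)
  stopifnot(deviation_fraction > 0, n_draws >= 1)
  missing <- setdiff(parameters, ps$ranges$name)
  if (length(missing))
    stop("unknown parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(wtp)) wtp <- param(ps, "wtp_threshold_high")
  tab <- ps$ranges
  dc <- dq <- numeric(n_draws)
  with_preserved_seed(seed, {
    for (i in seq_len(n_draws)) {
      drawn <- ps
      for (nm in parameters) {
        j <- match(nm, tab$name)
        base <- param(ps, nm)
        sd <- base * deviation_fraction
        # probabilities so close to 1 that the requested deviation exceeds
        # what a beta can represent are drawn at the widest feasible sd
        if (tab$dist[j] == "beta")
          sd <- min(sd, 0.95 * sqrt(base * (1 - base)))
        val <- draw_parameter(base, tab$low[j], tab$high[j], tab$dist[j],
                              sd = sd)
        drawn <- perturb(drawn, nm, val)
      }
      drawn <- .renormalised(drawn, parameters)
      inc <- compare_strategies(drawn)$incremental
      dc[i] <- inc$delta_cost; dq[i] <- inc$delta_qaly
    }
  })
  out <- data.frame(draw = seq_len(n_draws), delta_cost = dc, delta_qaly = dq,
                    nmb = dq * wtp - dc)
  out$cost_effective <- out$nmb > 0
  attr(out, "wtp") <- wtp
  attr(out, "seed") <- seed
  attr(out, "deviation_fraction") <- deviation_fraction
  attr(out, "fraction_cost_effective") <- mean(out$cost_effective)
  class(out) <- c("pmb_psa", "data.frame")
  out
}
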