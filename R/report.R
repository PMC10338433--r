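# Structured result export with run provenance: every command writes tidy
# CSV/JSON outputs plus a run manifest naming the config hash, seed(s),
# package version and output files, so deterministic runs are reproducible
# bit-for-bit from the manifest.

.out_path <- function(out_dir, name) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  file.path(out_dir, name)
}

.config_hash <- function(ps) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_parameters(ps, tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(out_dir, command, ps, seed, files, extra = list()) {
  manifest <- c(list(
    command = command,
    package = "pmbcea",
    version = as.character(utils::packageVersion("pmbcea")),
    config_md5 = .config_hash(ps),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(files)), extra)
  path <- .out_path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.load_config <- function(config) {
  if (inherits(config, "pmb_parameters")) return(.assert_valid(config))
  load_parameters(config)
}

#' Base-case analysis command
#'
#' Runs both strategies end-to-end and writes per-strategy outcome summaries
#' (CSV), the incremental comparison (JSON), the two cohort traces (CSV) and
#' a run manifest.
#'
#' @param config `NULL` (defaults), a YAML/JSON config path, a list of
#'   overrides, or a `pmb_parameters` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `pmb_comparison`.
#' @export
cmd_base_case <- function(config = NULL, out_dir = ".") {
  ps <- .load_config(config)
  cmp <- compare_strategies(ps)
  f1 <- .out_path(out_dir, "outcomes.csv")
  utils::write.csv(rbind(as.data.frame(cmp$usual), as.data.frame(cmp$molecular)),
                   f1, row.names = FALSE)
  f2 <- .out_path(out_dir, "icer.json")
  inc <- cmp$incremental
  jsonlite::write_json(
    list(reference = inc$reference, comparator = inc$comparator,
         delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
         icer = inc$icer, classification = inc$classification,
         thresholds = inc$thresholds),
    f2, auto_unbox = TRUE, digits = NA, null = "null")
  f3 <- .out_path(out_dir, "trace_usual.csv")
  utils::write.csv(as.data.frame(cmp$trace_usual), f3, row.names = FALSE)
  f4 <- .out_path(out_dir, "trace_molecular.csv")
  utils::write.csv(as.data.frame(cmp$trace_molecular), f4, row.names = FALSE)
  .write_manifest(out_dir, "base_case", ps, NULL, c(f1, f2, f3, f4))
  invisible(cmp)
}

#' One-way deterministic sensitivity analysis command
#'
#' Writes the tornado table (CSV, sorted by decreasing ICER span) and a run
#' manifest.
#'
#' @inheritParams cmd_base_case
#' @param parameters Passed to [one_way_dsa()].
#' @return Invisibly, the `pmb_tornado` data frame.
#' @export
cmd_dsa <- function(config = NULL, out_dir = ".", parameters = NULL) {
  ps <- .load_config(config)
  torn <- one_way_dsa(ps, parameters)
  f1 <- .out_path(out_dir, "tornado.csv")
  utils::write.csv(torn, f1, row.names = FALSE)
  .write_manifest(out_dir, "dsa", ps, NULL, f1,
                  list(n_parameters = nrow(torn)))
  invisible(torn)
}

#' Probabilistic sensitivity analysis command
#'
#' Writes the cost-effectiveness plane (one row per draw), the
#' acceptability curve, a summary JSON (fractions cost-effective at both
#' thresholds, with the willingness-to-pay and seed used) and a run
#' manifest.
#'
#' @inheritParams cmd_base_case
#' @param n Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @return Invisibly, the `pmb_psa` data frame.
#' @export
cmd_psa <- function(config = NULL, n = 1000, seed = 1, out_dir = ".",
                    wtp_grid = seq(0, 50000, by = 1000)) {
  ps <- .load_config(config)
  res <- psa(ps, n_draws = n, seed = seed)
  f1 <- .out_path(out_dir, "ce_plane.csv")
  utils::write.csv(as.data.frame(res), f1, row.names = FALSE)
  f2 <- .out_path(out_dir, "ceac.csv")
  utils::write.csv(ceac(res, wtp_grid), f2, row.names = FALSE)
  f3 <- .out_path(out_dir, "psa_summary.json")
  jsonlite::write_json(
    list(n_draws = n, seed = seed, wtp = attr(res, "wtp"),
         fraction_cost_effective = attr(res, "fraction_cost_effective"),
         fraction_cost_effective_low_threshold =
           attr(res, "fraction_cost_effective_low")),
    f3, auto_unbox = TRUE, digits = NA)
  .write_manifest(out_dir, "psa", ps, seed, c(f1, f2, f3))
  invisible(res)
}

#' Molecular-test-cost sweep command
#'
#' Writes the sweep table (fraction of cost-effective draws per molecular
#' test cost) and a run manifest.
#'
#' @inheritParams cmd_psa
#' @param grid Molecular test costs to evaluate.
#' @return Invisibly, the sweep data frame.
#' @export
cmd_sweep <- function(config = NULL, grid = seq(0, 1000, by = 100),
                      n = 1000, seed = 1, out_dir = ".") {
  ps <- .load_config(config)
  sw <- test_cost_sweep(ps, grid, n_draws = n, seed = seed)
  f1 <- .out_path(out_dir, "cost_sweep.csv")
  utils::write.csv(sw, f1, row.names = FALSE)
  .write_manifest(out_dir, "sweep", ps, seed, f1)
  invisible(sw)
}

#' Multivariate PSA command
#'
#' Writes the cost-effectiveness plane for the jointly varied influential
#' parameters and a summary JSON, plus a run manifest.
#'
#' @inheritParams cmd_psa
#' @param deviation_fraction Standard deviation as a fraction of base values.
#' @param parameters Passed to [multivariate_psa()].
#' @return Invisibly, the `pmb_psa` data frame.
#' @export
cmd_multivariate_psa <- function(config = NULL, deviation_fraction = 1 / 10,
                                 n = 1000, seed = 1, out_dir = ".",
                                 parameters = NULL) {
  ps <- .load_config(config)
  args <- list(ps = ps, deviation_fraction = deviation_fraction,
               n_draws = n, seed = seed)
  if (!is.null(parameters)) args$parameters <- parameters
  res <- do.call(multivariate_psa, args)
  f1 <- .out_path(out_dir, "multivariate_ce_plane.csv")
  utils::write.csv(as.data.frame(res), f1, row.names = FALSE)
  f2 <- .out_path(out_dir, "multivariate_summary.json")
  jsonlite::write_json(
    list(n_draws = n, seed = seed, wtp = attr(res, "wtp"),
         deviation_fraction = deviation_fraction,
         fraction_cost_effective = attr(res, "fraction_cost_effective")),
    f2, auto_unbox = TRUE, digits = NA)
  .write_manifest(out_dir, "multivariate_psa", ps, seed, c(f1, f2),
                  list(deviation_fraction = deviation_fraction))
  invisible(res)
}
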