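write_run_config <- function(out_dir, config, extra = list()) {
  yaml::write_yaml(c(unclass(config), extra),
                   file.path(out_dir, "run_config.yaml"))
}

#' Run the prediction pipeline on files and write all artifacts
#'
#' Thin orchestration over [read_expression()], [read_pkn()],
#' [predict_determinants()] and the writers: reads the two inputs, runs the
#' pipeline, and writes `predictions.tsv`, `tf_ranking.tsv`,
#' `nrd_table.tsv`, `stage_counts.tsv` and the resolved `run_config.yaml`
#' into `out_dir`. Stage counts are also logged as `key=value` messages.
#'
#' @param expr_path Path to the expression TSV.
#' @param pkn_path Path to the PKN TSV.
#' @param out_dir Output directory (created if needed).
#' @param config A [seesaw_config()].
#' @return The `seesaw_fit`, invisibly.
#' @export
run_predict <- function(expr_path, pkn_path, out_dir,
                        config = seesaw_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expr <- read_expression(expr_path)
  pkn <- read_pkn(pkn_path)
  fit <- predict_determinants(expr, pkn, config, verbose = TRUE)
  write_predictions(fit$report, file.path(out_dir, "predictions.tsv"))
  readr::write_tsv(fit$tf_ranking, file.path(out_dir, "tf_ranking.tsv"), progress = FALSE)
  if (!is.null(fit$nrd_table)) {
    readr::write_tsv(fit$nrd_table, file.path(out_dir, "nrd_table.tsv"), progress = FALSE)
  }
  readr::write_tsv(fit$stage_counts, file.path(out_dir, "stage_counts.tsv"), progress = FALSE)
  write_run_config(out_dir, config,
                   list(expr_path = expr_path, pkn_path = pkn_path))
  if (fit$status != "ok") inform(paste0("status=", fit$status))
  invisible(fit)
}

#' Aggregate ranked TF lists from files by reciprocal rank fusion
#'
#' @param ranking_paths At least two ranking files (see [read_rankings()]).
#' @param out_path Output TSV for the aggregate ranking.
#' @param k RRF constant.
#' @param top_n Number of TFs kept.
#' @return The aggregate ranking tibble, invisibly.
#' @export
run_aggregate <- function(ranking_paths, out_path, k = 10, top_n = 8) {
  if (length(ranking_paths) < 2) abort("aggregation needs at least 2 ranking files")
  rankings <- read_rankings(ranking_paths)
  for (m in unique(rankings$method)) {
    inform(sprintf("method=%s n_tfs=%d", m, sum(rankings$method == m)))
  }
  agg <- aggregate_rankings(rankings, k = k, top_n = top_n)
  readr::write_tsv(agg, out_path, progress = FALSE)
  invisible(agg)
}

#' Run the PKN-perturbation sensitivity analysis on files
#'
#' Writes the per-trial table (`sensitivity.tsv`) and the median/quartile
#' summary (`sensitivity_summary.tsv`) into `out_dir`.
#'
#' @inheritParams run_predict
#' @inheritParams sensitivity_sweep
#' @return The `seesaw_sensitivity` object, invisibly.
#' @export
run_sensitivity <- function(expr_path, pkn_path, out_dir,
                            config = seesaw_config(),
                            fractions = seq(0.05, 0.25, by = 0.05),
                            modes = c("remove", "add"),
                            n_trials = 10L, top_n = 10L,
                            base_seed = config$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expr <- read_expression(expr_path)
  pkn <- read_pkn(pkn_path)
  sens <- sensitivity_sweep(expr, pkn, config, fractions = fractions,
                            modes = modes, n_trials = n_trials,
                            top_n = top_n, base_seed = base_seed)
  readr::write_tsv(sens$detail, file.path(out_dir, "sensitivity.tsv"), progress = FALSE)
  readr::write_tsv(sens$summary, file.path(out_dir, "sensitivity_summary.tsv"), progress = FALSE)
  write_run_config(out_dir, config,
                   list(expr_path = expr_path, pkn_path = pkn_path,
                        fractions = fractions, modes = modes,
                        n_trials = n_trials, top_n = top_n,
                        base_seed = base_seed))
  invisible(sens)
}

#' Write a synthetic seesaw dataset to a directory
#'
#' Writes `expression.tsv`, `pkn.tsv` and `truth.tsv` (the planted pairs)
#' generated from a [synthetic_spec()].
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [synthetic_spec()].
#' @return Invisibly, the generated dataset list.
#' @export
run_simulate <- function(out_dir, spec = synthetic_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  synth <- generate_dataset(spec)
  write_expression(synth$expression, file.path(out_dir, "expression.tsv"))
  write_pkn(synth$pkn, file.path(out_dir, "pkn.tsv"))
  readr::write_tsv(synth$truth$pairs, file.path(out_dir, "truth.tsv"), progress = FALSE)
  yaml::write_yaml(unclass(spec), file.path(out_dir, "synthetic_spec.yaml"))
  invisible(synth)
}
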