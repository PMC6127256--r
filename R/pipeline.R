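empty_report <- function() {
  tibble(tf_a = character(), tf_b = character(),
         frac_scc_cooccur = double(), frac_scc_direct = double(),
         min_outdegree = integer(), score = double(), rank = integer())
}

new_seesaw_fit <- function(..., status) {
  structure(c(list(...), list(status = status)), class = "seesaw_fit")
}

stage_count <- function(counts, stage, n) {
  dplyr::bind_rows(counts, tibble(stage = stage, n = as.integer(n)))
}

#' Predict cell-fate determinant TF pairs
#'
#' Runs the full seesaw pipeline: aggregate replicates, call TFs
#' differentially expressed between the daughters, compute the NRD table,
#' retain candidate pairs by the three criteria, subset the PKN to the
#' retained TFs, apply the iterative out-degree filter, sample
#' Boolean-consistent GRN solutions, detect strongly connected components,
#' and score and rank the pairs. The run is a pure function of
#' `(expr, pkn, config)`; rerunning with an identical configuration gives
#' identical output.
#'
#' An empty candidate set at any stage is a legal outcome, not an error:
#' the returned fit has an empty report and a `status` describing the stage
#' that emptied.
#'
#' @param expr Long-form expression tibble (see [read_expression()]).
#' @param pkn PKN tibble (see [read_pkn()]).
#' @param config A [seesaw_config()].
#' @param verbose Emit machine-parseable `key=value` stage-count messages.
#' @return A `seesaw_fit` object with elements `report` (ranked pair
#'   tibble), `tf_ranking`, `calls`, `nrd_table`, `candidate_pairs`,
#'   `filtered_pkn`, `solutions`, `sccs`, `stage_counts`, `config`,
#'   `status`. Use [tidy()], [glance()] and [autoplot()] on it.
#' @examples
#' synth <- generate_dataset(synthetic_spec(seed = 7))
#' fit <- predict_determinants(synth$expression, synth$pkn,
#'                             seesaw_config(n_solutions = 50, seed = 7))
#' tidy(fit)
#' @export
predict_determinants <- function(expr, pkn, config = seesaw_config(),
                                 verbose = FALSE) {
  validate_expression(expr)
  validate_pkn(pkn)
  stopifnot(inherits(config, "seesaw_config"))
  log_stage <- function(stage, n) {
    if (verbose) inform(sprintf("stage=%s n=%d", stage, n))
  }
  counts <- tibble(stage = character(), n = integer())
  note <- function(stage, n) {
    log_stage(stage, n)
    counts <<- stage_count(counts, stage, n)
  }

  genes <- unique(expr$gene)
  note("expression_genes", length(genes))
  universe <- intersect(pkn_nodes(pkn), genes)
  note("tf_universe", length(universe))
  if (length(universe) == 0) abort("no TFs shared between expression data and PKN")

  profile <- aggregate_replicates(expr)
  calls <- call_differential_tfs(expr, universe, config)
  note("differential_tfs", nrow(calls))

  done <- function(status, ...) {
    new_seesaw_fit(
      report = empty_report(), tf_ranking = tf_level_ranking(empty_report()),
      calls = calls, profile = profile,
      stage_counts = counts, config = config, ...,
      status = status
    )
  }
  if (nrow(calls) < 2) {
    return(done("no_candidate_pairs: fewer than 2 differential TFs"))
  }

  nrd_table <- build_nrd_table(profile, calls$gene, config, expr = expr)
  note("nrd_ordered_pairs", nrow(nrd_table))
  pairs <- select_candidate_pairs(nrd_table, calls, config)
  note("candidate_pairs", nrow(pairs))
  if (nrow(pairs) == 0) {
    return(done("no_candidate_pairs: no pair passed the retention criteria",
                nrd_table = nrd_table))
  }

  retained_tfs <- union(pairs$tf_a, pairs$tf_b)
  sub <- subset_pkn(pkn, retained_tfs)
  note("subset_nodes", length(pkn_nodes(sub)))
  note("subset_edges", nrow(sub))
  filtered <- withCallingHandlers(
    filter_by_out_degree(sub, config$min_out_degree_exclusive),
    message = function(m) if (!verbose) invokeRestart("muffleMessage")
  )
  filt_nodes <- pkn_nodes(filtered)
  note("filtered_nodes", length(filt_nodes))
  note("filtered_edges", nrow(filtered))

  pairs_kept <- dplyr::filter(pairs, .data$tf_a %in% filt_nodes,
                              .data$tf_b %in% filt_nodes)
  note("scored_pairs", nrow(pairs_kept))
  if (nrow(pairs_kept) == 0) {
    return(done("no_candidate_pairs: no pair survived the out-degree filter",
                nrd_table = nrd_table, candidate_pairs = pairs,
                filtered_pkn = filtered))
  }

  directions <- calls |>
    dplyr::filter(.data$gene %in% filt_nodes) |>
    dplyr::select("gene", "direction")
  solutions <- sample_grn_solutions(filtered, directions, config)
  note("grn_solutions", config$n_solutions)
  sccs <- scc_by_solution(solutions)

  report <- score_pairs(pairs_kept, solutions, sccs, filtered) |>
    rank_pairs()
  tf_ranking <- tf_level_ranking(report)

  new_seesaw_fit(
    report = report, tf_ranking = tf_ranking, calls = calls,
    profile = profile, nrd_table = nrd_table, candidate_pairs = pairs,
    filtered_pkn = filtered, directions = directions,
    solutions = solutions, sccs = sccs,
    stage_counts = counts, config = config,
    status = "ok"
  )
}

#' @export
print.seesaw_fit <- function(x, n = 5, ...) {
  cat("<seesaw_fit>  status:", x$status, "\n")
  print(x$stage_counts, n = Inf)
  if (nrow(x$report) > 0) {
    cat("Top pairs:\n")
    print(utils::head(x$report, n))
  }
  invisible(x)
}

#' Tidy a seesaw fit into its ranked pair report
#'
#' @param x A `seesaw_fit`.
#' @param ... Unused.
#' @return The ranked pair-score tibble.
#' @export
tidy.seesaw_fit <- function(x, ...) {
  x$report
}

#' One-row summary of a seesaw fit
#'
#' @param x A `seesaw_fit`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts plus the fit status.
#' @export
glance.seesaw_fit <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$stage_counts, names_from = "stage", values_from = "n")
  dplyr::mutate(wide, status = x$status)
}

#' Plot the top-ranked TF pairs of a fit
#'
#' Bar chart of pair scores for the highest-ranked pairs, annotated with the
#' SCC co-occurrence fraction.
#'
#' @param object A `seesaw_fit`.
#' @param top_n Number of pairs to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seesaw_fit <- function(object, top_n = 10, ...) {
  df <- utils::head(object$report, top_n) |>
    dplyr::mutate(pair = paste(.data$tf_a, .data$tf_b, sep = "__"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$pair, -.data$rank),
    y = .data$score, fill = .data$frac_scc_cooccur
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "SCC co-occurrence") +
    ggplot2::labs(x = NULL, y = "pair score") +
    ggplot2::theme_minimal()
}
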