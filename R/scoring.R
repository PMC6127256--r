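#' Score candidate TF pairs across GRN solutions
#'
#' The score of an unordered TF pair is the product of three factors:
#' \describe{
#'   \item{`frac_scc_cooccur`}{fraction of GRN solutions in which some
#'     strongly connected component contains both TFs;}
#'   \item{`frac_scc_direct`}{fraction of solutions in which they co-occur
#'     in a component *and* the solution contains an edge between them in
#'     either direction;}
#'   \item{`min_outdegree`}{the smaller of the two TFs' out-degrees in the
#'     degree-filtered subset PKN (stable across solutions).}
#' }
#' By construction `frac_scc_direct <= frac_scc_cooccur`.
#'
#' @param pairs Tibble of unordered pairs with columns `tf_a`, `tf_b`
#'   (e.g. from [select_candidate_pairs()]); order within a row is
#'   normalized lexicographically.
#' @param solutions GRN solutions from [sample_grn_solutions()].
#' @param sccs Per-solution components from [scc_by_solution()].
#' @param degree_pkn The degree-filtered subset PKN used for out-degrees;
#'   every pair member must be one of its nodes.
#' @param n_solutions Number of solutions (defaults to the attribute on
#'   `solutions`).
#' @return Tibble with columns `tf_a`, `tf_b`, `frac_scc_cooccur`,
#'   `frac_scc_direct`, `min_outdegree`, `score`.
#' @export
score_pairs <- function(pairs, solutions, sccs, degree_pkn,
                        n_solutions = NULL) {
  n <- n_solutions %||% attr(solutions, "n_solutions")
  if (is.null(n)) abort("number of solutions unknown; pass `n_solutions`")
  nodes <- pkn_nodes(degree_pkn)
  pr <- tibble(tf_a = pmin(pairs$tf_a, pairs$tf_b),
               tf_b = pmax(pairs$tf_a, pairs$tf_b))
  absent <- setdiff(unique(c(pr$tf_a, pr$tf_b)), nodes)
  if (length(absent) > 0) {
    abort(sprintf("pair member(s) absent from the degree-source network: %s",
                  paste(absent, collapse = ", ")))
  }
  od <- pkn_out_degrees(degree_pkn, nodes)

  co <- dplyr::inner_join(sccs, sccs, by = c("solution_id", "component"),
                          relationship = "many-to-many") |>
    dplyr::filter(.data$gene.x < .data$gene.y) |>
    dplyr::distinct(.data$solution_id, tf_a = .data$gene.x, tf_b = .data$gene.y)
  direct_edges <- solutions |>
    dplyr::transmute(.data$solution_id,
                     tf_a = pmin(.data$source, .data$target),
                     tf_b = pmax(.data$source, .data$target)) |>
    dplyr::distinct()
  direct <- dplyr::inner_join(co, direct_edges,
                              by = c("solution_id", "tf_a", "tf_b"))

  co_n <- dplyr::count(co, .data$tf_a, .data$tf_b, name = "n_co")
  direct_n <- dplyr::count(direct, .data$tf_a, .data$tf_b, name = "n_direct")

  pr |>
    dplyr::left_join(co_n, by = c("tf_a", "tf_b")) |>
    dplyr::left_join(direct_n, by = c("tf_a", "tf_b")) |>
    dplyr::mutate(
      frac_scc_cooccur = dplyr::coalesce(.data$n_co, 0L) / n,
      frac_scc_direct = dplyr::coalesce(.data$n_direct, 0L) / n,
      min_outdegree = unname(pmin(od[.data$tf_a], od[.data$tf_b])),
      score = .data$frac_scc_cooccur * .data$frac_scc_direct * .data$min_outdegree
    ) |>
    dplyr::select("tf_a", "tf_b", "frac_scc_cooccur", "frac_scc_direct",
                  "min_outdegree", "score")
}

#' Rank scored TF pairs
#'
#' Sorts descending by score with deterministic lexicographic tie-breaking
#' on `(tf_a, tf_b)` and assigns contiguous 1-based ranks.
#'
#' @param scores Tibble from [score_pairs()].
#' @return The same tibble with a `rank` column, sorted by rank.
#' @export
rank_pairs <- function(scores) {
  scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$tf_a, .data$tf_b) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' TF-level ranking from a pair report
#'
#' Orders individual TFs by the best (lowest) rank of any pair containing
#' them, ties broken lexicographically; each TF appears once. This is the
#' representation used to compare against single-TF predictors and for the
#' sensitivity analysis.
#'
#' @param report Ranked pair report from [rank_pairs()].
#' @return Tibble with columns `rank`, `tf`, `best_pair_rank`.
#' @export
tf_level_ranking <- function(report) {
  if (nrow(report) == 0) {
    return(tibble(rank = integer(), tf = character(), best_pair_rank = integer()))
  }
  report |>
    dplyr::select("rank", "tf_a", "tf_b") |>
    tidyr::pivot_longer(c("tf_a", "tf_b"), values_to = "tf") |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(best_pair_rank = min(.data$rank), .groups = "drop") |>
    dplyr::arrange(.data$best_pair_rank, .data$tf) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "tf", "best_pair_rank")
}
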