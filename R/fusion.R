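#' Normalize rankings input
#'
#' Accepts either a tibble with columns `method`, `tf` (rows in rank order
#' within each method; an explicit `rank` column is respected if present) or
#' a named list of character vectors, one ordered TF list per method.
#'
#' @param rankings Rankings in either representation.
#' @return Tibble with columns `method`, `rank`, `tf`.
#' @export
as_rankings <- function(rankings) {
  if (is.list(rankings) && !is.data.frame(rankings)) {
    if (is.null(names(rankings))) abort("list rankings must be named by method")
    rankings <- purrr::imap(rankings, function(tfs, nm) {
      tibble(method = nm, rank = seq_along(tfs), tf = tfs)
    }) |>
      purrr::list_rbind()
  }
  if (!all(c("method", "tf") %in% colnames(rankings))) {
    abort("rankings must have columns method and tf")
  }
  out <- as_tibble(rankings)
  if (!"rank" %in% colnames(out)) {
    out <- out |>
      dplyr::group_by(.data$method) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  dup <- out |>
    dplyr::count(.data$method, .data$tf) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate TF(s) within a ranking: %s",
                  paste(unique(dup$tf), collapse = ", ")))
  }
  out[, c("method", "rank", "tf")]
}

#' Reciprocal rank fusion score of one TF
#'
#' Sums `1 / (k + rank)` over every ranking that contains the TF; rankings
#' lacking it contribute nothing. `k` dampens the influence of top ranks and
#' is fixed a priori (default 10).
#'
#' @param tf TF symbol; must appear in at least one ranking.
#' @param rankings Rankings (see [as_rankings()]).
#' @param k Positive RRF constant (default 10).
#' @return The RRF score (a single number).
#' @examples
#' r <- list(m1 = c("GATA1", "SPI1"), m2 = c("GATA1", "KLF1"))
#' rrf_score("GATA1", r) # 2/11
#' @export
rrf_score <- function(tf, rankings, k = 10) {
  if (k <= 0) abort("`k` must be positive")
  rk <- as_rankings(rankings)
  hits <- rk$rank[rk$tf == tf]
  if (length(hits) == 0) abort(sprintf("TF '%s' absent from all rankings", tf))
  sum(1 / (k + hits))
}

#' Aggregate ranked TF lists by reciprocal rank fusion
#'
#' Scores the union of all ranked TFs with [rrf_score()], sorts descending
#' with lexicographic tie-breaking and truncates to `top_n`. At least two
#' rankings are required: aggregating a single list is the identity and is
#' rejected to avoid silent misuse.
#'
#' @param rankings Rankings (see [as_rankings()]) from at least two methods.
#' @param k Positive RRF constant (default 10).
#' @param top_n Number of TFs to keep (default 8, matching the convention of
#'   trimming predictions to at most eight TFs).
#' @return Tibble with columns `method` (`"Aggregate"`), `rank`, `tf`,
#'   `rrf_score`.
#' @export
aggregate_rankings <- function(rankings, k = 10, top_n = 8) {
  if (k <= 0) abort("`k` must be positive")
  if (top_n < 1) abort("`top_n` must be >= 1")
  rk <- as_rankings(rankings)
  if (dplyr::n_distinct(rk$method) < 2) {
    abort("aggregation needs at least 2 rankings")
  }
  rk |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(rrf_score = sum(1 / (k + .data$rank)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$rrf_score), .data$tf) |>
    utils::head(top_n) |>
    dplyr::mutate(method = "Aggregate", rank = dplyr::row_number()) |>
    dplyr::select("method", "rank", "tf", "rrf_score")
}
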