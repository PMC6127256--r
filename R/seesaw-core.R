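#' Aggregate replicates into per-cell-type mean profiles
#'
#' Summarizes replicate expression by the arithmetic mean within each of the
#' three cell-type groups. The mean is the natural summary for linear-scale
#' data feeding a ratio statistic.
#'
#' @param expr Long-form expression tibble (see [read_expression()]).
#' @return A tibble with columns `gene`, `mean_P`, `mean_D1`, `mean_D2`,
#'   one row per gene in input order.
#' @export
aggregate_replicates <- function(expr) {
  validate_expression(expr)
  gene_order <- unique(expr$gene)
  expr |>
    dplyr::group_by(.data$gene, .data$cell_type) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(cell_type = dplyr::recode(.data$cell_type,
      Progenitor = "mean_P", Daughter1 = "mean_D1", Daughter2 = "mean_D2"
    )) |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "mean") |>
    dplyr::select("gene", "mean_P", "mean_D1", "mean_D2") |>
    dplyr::arrange(match(.data$gene, gene_order))
}

# Vectorized Welch two-sample p-value from group summaries. Zero pooled
# standard error (e.g. noise-free data) degenerates to an exact 0/1 call.
welch_p <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero <- !is.na(se2) & se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  p
}

#' Call TFs differentially expressed between the two daughter cell types
#'
#' Applies a Welch two-sample test on `log2(value + pseudocount)` between
#' Daughter1 and Daughter2 replicates, Benjamini-Hochberg adjusted over the
#' TF universe, combined with an absolute log2 fold-change floor. With a
#' single replicate in either daughter the test is undefined and the filter
#' degenerates to fold change alone (reported via a message).
#'
#' @param expr Long-form expression tibble.
#' @param tf_universe Character vector of TF symbols to test; normally the
#'   PKN node set intersected with the expression genes.
#' @param config A [seesaw_config()].
#' @return A tibble of *called* TFs with columns `gene`, `direction`
#'   (`up_in_D1` iff the log2 fold change D1 vs D2 is positive), `log2fc`,
#'   `p_value`, `p_adj`.
#' @export
call_differential_tfs <- function(expr, tf_universe, config = seesaw_config()) {
  validate_expression(expr)
  universe <- intersect(tf_universe, unique(expr$gene))
  if (length(universe) == 0) {
    abort("no TFs shared between expression data and PKN")
  }

  stats_tbl <- expr |>
    dplyr::filter(.data$gene %in% universe, .data$cell_type != "Progenitor") |>
    dplyr::mutate(log2v = log2(.data$value + config$pseudocount)) |>
    dplyr::group_by(.data$gene, .data$cell_type) |>
    dplyr::summarise(
      m = mean(.data$log2v), v = stats::var(.data$log2v), n = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = c("m", "v", "n"))

  degenerate <- any(stats_tbl$n_Daughter1 < 2) || any(stats_tbl$n_Daughter2 < 2)
  out <- stats_tbl |>
    dplyr::mutate(
      log2fc = .data$m_Daughter1 - .data$m_Daughter2,
      p_value = if (degenerate) NA_real_ else
        welch_p(.data$m_Daughter1, .data$v_Daughter1, .data$n_Daughter1,
                .data$m_Daughter2, .data$v_Daughter2, .data$n_Daughter2),
      p_adj = p.adjust(.data$p_value, method = "BH")
    )
  if (degenerate) {
    inform("single replicate in a daughter cell type: differential filter degenerates to fold change only")
  }

  out |>
    dplyr::filter(
      (is.na(.data$p_adj) | .data$p_adj < config$de_alpha),
      abs(.data$log2fc) >= config$de_min_abs_log2fc
    ) |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up_in_D1", "up_in_D2")) |>
    dplyr::select("gene", "direction", "log2fc", "p_value", "p_adj")
}

#' Normalized ratio difference (NRD)
#'
#' The NRD for a TF pair (i, j) compares its expression ratio in the
#' progenitor with the ratio in a daughter cell type, normalized by the
#' progenitor ratio:
#' `NRD = ((ci_p / cj_p) - (ci_d / cj_d)) / (ci_p / cj_p)`.
#' It is 0 when the ratio is preserved, approaches 1 when TF i collapses
#' relative to TF j in the daughter, and is strongly negative in the
#' opposite case. All arguments are recycled and must be strictly positive
#' (apply the pseudocount first).
#'
#' @param ci_p,cj_p Progenitor expression of TF i and TF j.
#' @param ci_d,cj_d Daughter expression of TF i and TF j.
#' @return Numeric vector of NRD values.
#' @examples
#' nrd(4, 2, 1, 2) # 0.75
#' @export
nrd <- function(ci_p, cj_p, ci_d, cj_d) {
  if (any(c(ci_p, cj_p, ci_d, cj_d) <= 0)) {
    abort("nrd() requires strictly positive expression values (apply the pseudocount first)")
  }
  rp <- ci_p / cj_p
  rd <- ci_d / cj_d
  (rp - rd) / rp
}

#' NRD table over all ordered candidate TF pairs
#'
#' Computes the NRD in both daughter cell types for every ordered pair of
#' candidate TFs, plus a per-pair significance level. The default test
#' (`nrd_test = "ratio_t"`) asks, per daughter, whether the per-replicate
#' log2 expression ratio of the pair differs between progenitor and daughter
#' replicates (Welch test); the pair p-value is the larger of the two
#' daughters' p-values, so both daughters must deviate, and is BH-adjusted
#' across pairs. `"empirical"` instead ranks each pair's
#' `min(|nrd_d1|, |nrd_d2|)` against the pooled distribution of all computed
#' |NRD| values. `"none"` (or missing replicate data) leaves `p_adj` as `NA`,
#' which downstream filtering treats as a pass.
#'
#' @param profile Per-cell-type mean profile from [aggregate_replicates()].
#' @param candidates Character vector of candidate TF symbols (at least 2,
#'   all present in `profile`).
#' @param config A [seesaw_config()].
#' @param expr Optional long-form expression tibble; required for the
#'   `"ratio_t"` test.
#' @return Tibble with columns `tf_i`, `tf_j`, `nrd_d1`, `nrd_d2`,
#'   `p_value`, `p_adj`; one row per ordered pair. Fewer than two candidates
#'   yields an empty table with a warning.
#' @export
build_nrd_table <- function(profile, candidates, config = seesaw_config(),
                            expr = NULL) {
  if (!all(candidates %in% profile$gene)) {
    abort("all candidates must be present in the profile")
  }
  empty <- tibble(tf_i = character(), tf_j = character(),
                  nrd_d1 = double(), nrd_d2 = double(),
                  p_value = double(), p_adj = double())
  if (length(candidates) < 2) {
    warn("fewer than 2 candidate TFs: NRD table is empty and no pairs can be predicted")
    return(empty)
  }

  prof <- profile[match(candidates, profile$gene), ]
  pc <- config$pseudocount
  mP <- prof$mean_P + pc
  mD1 <- prof$mean_D1 + pc
  mD2 <- prof$mean_D2 + pc

  pairs <- tidyr::expand_grid(i = seq_along(candidates), j = seq_along(candidates)) |>
    dplyr::filter(.data$i != .data$j)
  tab <- tibble(
    tf_i = candidates[pairs$i],
    tf_j = candidates[pairs$j],
    nrd_d1 = nrd(mP[pairs$i], mP[pairs$j], mD1[pairs$i], mD1[pairs$j]),
    nrd_d2 = nrd(mP[pairs$i], mP[pairs$j], mD2[pairs$i], mD2[pairs$j])
  )

  test <- config$nrd_test
  if (test == "ratio_t" && is.null(expr)) {
    inform("no replicate-level data supplied: NRD significance not computed")
    test <- "none"
  }
  if (test == "ratio_t") {
    p <- nrd_ratio_t(expr, candidates, pairs$i, pairs$j, pc)
    if (is.null(p)) {
      inform("fewer than 2 replicates in a cell type: NRD significance not computed")
      test <- "none"
    } else {
      tab$p_value <- p
    }
  }
  if (test == "empirical") {
    pool <- abs(c(tab$nrd_d1, tab$nrd_d2))
    stat <- pmin(abs(tab$nrd_d1), abs(tab$nrd_d2))
    tab$p_value <- vapply(stat, function(s) mean(pool > s), numeric(1))
  }
  if (test == "none") tab$p_value <- NA_real_
  tab$p_adj <- p.adjust(tab$p_value, method = "BH")
  tab
}

# Welch test on per-replicate log2 ratios of each candidate pair, progenitor
# vs each daughter; returns max of the two daughters' p-values per pair, or
# NULL when any cell type has fewer than two replicates.
nrd_ratio_t <- function(expr, candidates, idx_i, idx_j, pseudocount) {
  sub <- expr |>
    dplyr::filter(.data$gene %in% candidates) |>
    dplyr::mutate(log2v = log2(.data$value + pseudocount))
  group_stats <- function(ct) {
    wide <- sub |>
      dplyr::filter(.data$cell_type == ct) |>
      tidyr::pivot_wider(id_cols = "gene", names_from = "replicate",
                         values_from = "log2v")
    L <- as.matrix(wide[, -1])[match(candidates, wide$gene), , drop = FALSE]
    if (ncol(L) < 2) return(NULL)
    list(m = rowMeans(L), C = stats::cov(t(L)), n = ncol(L))
  }
  gp <- group_stats("Progenitor")
  g1 <- group_stats("Daughter1")
  g2 <- group_stats("Daughter2")
  if (is.null(gp) || is.null(g1) || is.null(g2)) return(NULL)

  pair_p <- function(g) {
    m <- g$m[idx_i] - g$m[idx_j]
    v <- diag(g$C)[idx_i] + diag(g$C)[idx_j] -
      2 * g$C[cbind(idx_i, idx_j)]
    v <- pmax(v, 0) # guard tiny negative values from floating-point cancellation
    mp <- gp$m[idx_i] - gp$m[idx_j]
    vp <- diag(gp$C)[idx_i] + diag(gp$C)[idx_j] - 2 * gp$C[cbind(idx_i, idx_j)]
    vp <- pmax(vp, 0)
    welch_p(mp, vp, gp$n, m, v, g$n)
  }
  pmax(pair_p(g1), pair_p(g2))
}

#' Select candidate TF pairs by the three retention criteria
#'
#' An unordered pair \{i, j\} is retained iff (a) both TFs are
#' differentially expressed between the daughters, (b) its NRD is
#' significant (`p_adj < nrd_alpha`; skipped when no test was computed) and
#' (c) its absolute NRD exceeds `nrd_abs_threshold` in *both* daughter cell
#' types. Because the NRD is orientation-dependent, each unordered pair is
#' evaluated in the orientation maximizing `min(|nrd_d1|, |nrd_d2|)`.
#'
#' @param nrd_table Ordered-pair NRD table from [build_nrd_table()].
#' @param calls Differential calls from [call_differential_tfs()].
#' @param config A [seesaw_config()].
#' @return Tibble of retained pairs with columns `tf_a`, `tf_b` (sorted
#'   lexicographically), `nrd_d1`, `nrd_d2`, `p_adj` (values of the chosen
#'   orientation). May be empty.
#' @export
select_candidate_pairs <- function(nrd_table, calls, config = seesaw_config()) {
  empty <- tibble(tf_a = character(), tf_b = character(),
                  nrd_d1 = double(), nrd_d2 = double(), p_adj = double())
  if (nrow(nrd_table) == 0) return(empty)

  oriented <- nrd_table |>
    dplyr::mutate(
      tf_a = pmin(.data$tf_i, .data$tf_j),
      tf_b = pmax(.data$tf_i, .data$tf_j),
      stat = pmin(abs(.data$nrd_d1), abs(.data$nrd_d2)),
      forward = .data$tf_i <= .data$tf_j
    ) |>
    dplyr::arrange(.data$tf_a, .data$tf_b, dplyr::desc(.data$stat),
                   dplyr::desc(.data$forward)) |>
    dplyr::distinct(.data$tf_a, .data$tf_b, .keep_all = TRUE)

  called <- calls$gene
  if (all(is.na(oriented$p_adj))) {
    inform("no NRD significance test computed: significance criterion skipped")
  }
  oriented |>
    dplyr::filter(
      .data$tf_a %in% called, .data$tf_b %in% called,
      is.na(.data$p_adj) | .data$p_adj < config$nrd_alpha,
      abs(.data$nrd_d1) > config$nrd_abs_threshold,
      abs(.data$nrd_d2) > config$nrd_abs_threshold
    ) |>
    dplyr::select("tf_a", "tf_b", "nrd_d1", "nrd_d2", "p_adj")
}
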