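#' Specification for a synthetic seesaw dataset
#'
#' Describes a synthetic binary-differentiation experiment with planted
#' seesaw motifs. Each planted pair (X, Y) mutually inhibits itself
#' (`X -| Y`, `Y -| X`), is balanced in the progenitor at
#' `baseline_expression`, and separates by `fold_separation` in opposite
#' directions in the two daughters (X up in Daughter1, Y up in Daughter2).
#' To let planted TFs survive the out-degree filter, each planted TF also
#' activates `hub_out_degree` lineage-responsive TFs of its own direction;
#' each direction hosts `hub_out_degree + 2` responsive TFs that form a
#' dense same-direction activation clique (so the high-out-degree core is
#' not destroyed by a single lost edge). Responsive TFs separate by a
#' moderate, nearly uniform fold (log2 fold ~ Normal(2, 0.05)), mirrored
#' across daughters. The remaining TFs are weak background: their
#' daughter-vs-daughter log2 fold change is drawn from Normal(0, 0.2), so
#' the differential filter has realistic rejections, and they are wired by
#' `n_background_edges` random edges of mixed sign (including
#' `Unspecified`). Replicate noise is multiplicative log-normal.
#'
#' @param n_tfs Total number of TFs (must host the planted pairs plus two
#'   responsive groups).
#' @param n_background_edges Random edges among weak background TFs.
#' @param n_replicates Replicates per cell type.
#' @param planted_pairs Number of planted seesaw pairs.
#' @param baseline_expression Balanced progenitor expression level.
#' @param fold_separation Daughter fold separation of planted TFs (> 1).
#' @param noise_sd Standard deviation of the log-normal replicate noise on
#'   the natural-log scale; 0 gives noise-free replicates.
#' @param hub_out_degree Activation out-degree of each planted TF towards
#'   responsive TFs; must exceed the out-degree cutoff of 6.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `seesaw_synth_spec` object (named list).
#' @export
synthetic_spec <- function(n_tfs = 60L,
                           n_background_edges = 120L,
                           n_replicates = 3L,
                           planted_pairs = 1L,
                           baseline_expression = 100,
                           fold_separation = 10,
                           noise_sd = 0.1,
                           hub_out_degree = 8L,
                           seed = 1L) {
  if (hub_out_degree <= 6) abort("`hub_out_degree` must exceed the out-degree cutoff of 6")
  if (fold_separation <= 1) abort("`fold_separation` must be > 1")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  if (planted_pairs < 1) abort("`planted_pairs` must be >= 1")
  group <- hub_out_degree + 2L
  n_min <- 2L * planted_pairs + 2L * group
  if (n_tfs < n_min) {
    abort(sprintf("`n_tfs` too small to host planted pairs and hubs: need at least %d", n_min))
  }
  structure(
    list(
      n_tfs = as.integer(n_tfs),
      n_background_edges = as.integer(n_background_edges),
      n_replicates = as.integer(n_replicates),
      planted_pairs = as.integer(planted_pairs),
      baseline_expression = baseline_expression,
      fold_separation = fold_separation,
      noise_sd = noise_sd,
      hub_out_degree = as.integer(hub_out_degree),
      responsive_group_size = group,
      seed = as.integer(seed)
    ),
    class = "seesaw_synth_spec"
  )
}

complete_digraph <- function(nodes, sign) {
  pairs <- tidyr::expand_grid(source = nodes, target = nodes) |>
    dplyr::filter(.data$source != .data$target)
  tibble(source = pairs$source, sign = sign, target = pairs$target)
}

#' Generate a synthetic seesaw dataset
#'
#' Builds the expression matrix, the PKN and the ground truth described by a
#' [synthetic_spec()]. With `noise_sd = 0`, the NRD of a planted pair in the
#' orientation (Y, X) equals `1 - 1/fold_separation^2` in Daughter1 by
#' closed form (0.99 at the default fold of 10).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `expression` (long-form tibble), `pkn`
#'   (edge-list tibble) and `truth` (list with `pairs` — planted pairs,
#'   lexicographically ordered — and `directions` — the planted and
#'   responsive TF direction map).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "seesaw_synth_spec"))
  withr::with_seed(spec$seed, {
    g <- spec$responsive_group_size
    np <- spec$planted_pairs
    planted_a <- sprintf("PTF%02dA", seq_len(np)) # up in Daughter1
    planted_b <- sprintf("PTF%02dB", seq_len(np)) # up in Daughter2
    resp1 <- sprintf("RTFA%02d", seq_len(g))      # up in Daughter1
    resp2 <- sprintf("RTFB%02d", seq_len(g))      # up in Daughter2
    n_weak <- spec$n_tfs - 2L * np - 2L * g
    weak <- if (n_weak > 0) sprintf("BTF%03d", seq_len(n_weak)) else character()

    base <- spec$baseline_expression
    f <- spec$fold_separation
    f_resp1 <- 2^rnorm(g, mean = 2, sd = 0.05)
    f_resp2 <- 2^rnorm(g, mean = 2, sd = 0.05)
    lfc_weak <- rnorm(n_weak, mean = 0, sd = 0.2)

    means <- dplyr::bind_rows(
      tibble(gene = planted_a, mean_P = base, mean_D1 = base * f, mean_D2 = base / f),
      tibble(gene = planted_b, mean_P = base, mean_D1 = base / f, mean_D2 = base * f),
      tibble(gene = resp1, mean_P = base, mean_D1 = base * f_resp1, mean_D2 = base / f_resp1),
      tibble(gene = resp2, mean_P = base, mean_D1 = base / f_resp2, mean_D2 = base * f_resp2),
      tibble(gene = weak, mean_P = base,
             mean_D1 = base * 2^(lfc_weak / 2), mean_D2 = base * 2^(-lfc_weak / 2))
    )

    reps <- spec$n_replicates
    long <- means |>
      tidyr::pivot_longer(dplyr::starts_with("mean_"),
                          names_to = "cell_type", values_to = "mu") |>
      dplyr::mutate(cell_type = dplyr::recode(.data$cell_type,
        mean_P = "Progenitor", mean_D1 = "Daughter1", mean_D2 = "Daughter2"
      )) |>
      tidyr::expand_grid(rep = seq_len(reps)) |>
      dplyr::mutate(
        replicate = sprintf("%s_%d", .data$cell_type, .data$rep),
        value = .data$mu * exp(rnorm(dplyr::n(), 0, spec$noise_sd))
      ) |>
      dplyr::select("gene", "replicate", "cell_type", "value")

    hub_edges <- purrr::map2(
      c(planted_a, planted_b),
      c(replicate(np, sample(resp1, spec$hub_out_degree), simplify = FALSE),
        replicate(np, sample(resp2, spec$hub_out_degree), simplify = FALSE)),
      function(src, targets) tibble(source = src, sign = "Activation", target = targets)
    ) |>
      purrr::list_rbind()

    background <- if (n_weak >= 2 && spec$n_background_edges > 0) {
      random_edges(weak, spec$n_background_edges,
                   signs = INTERACTION_SIGNS, prob = c(0.45, 0.35, 0.20))
    } else {
      tibble(source = character(), sign = character(), target = character())
    }

    pkn <- dplyr::bind_rows(
      tibble(source = planted_a, sign = "Inhibition", target = planted_b),
      tibble(source = planted_b, sign = "Inhibition", target = planted_a),
      hub_edges,
      complete_digraph(resp1, "Activation"),
      complete_digraph(resp2, "Activation"),
      background
    ) |>
      dplyr::distinct()

    truth <- list(
      pairs = tibble(tf_a = pmin(planted_a, planted_b),
                     tf_b = pmax(planted_a, planted_b)),
      directions = tibble(
        gene = c(planted_a, planted_b, resp1, resp2),
        direction = c(rep("up_in_D1", np), rep("up_in_D2", np),
                      rep("up_in_D1", g), rep("up_in_D2", g))
      )
    )
    list(expression = long, pkn = pkn, truth = truth)
  })
}

# Draw n distinct random (source, sign, target) triples among `nodes`,
# rejecting duplicates of `existing` triples. Self-loops allowed.
random_edges <- function(nodes, n, signs, prob = NULL,
                         existing = NULL) {
  drawn <- tibble(source = character(), sign = character(), target = character())
  tries <- 0L
  while (nrow(drawn) < n) {
    tries <- tries + 1L
    if (tries > 100L) abort("cannot draw the requested number of distinct edges")
    k <- 2L * (n - nrow(drawn)) + 4L
    batch <- tibble(
      source = sample(nodes, k, replace = TRUE),
      sign = sample(signs, k, replace = TRUE, prob = prob),
      target = sample(nodes, k, replace = TRUE)
    )
    drawn <- dplyr::bind_rows(drawn, batch) |> dplyr::distinct()
    if (!is.null(existing)) {
      drawn <- dplyr::anti_join(drawn, existing, by = c("source", "sign", "target"))
    }
  }
  drawn[seq_len(n), ]
}

#' Generate a uniformly random signed PKN
#'
#' Draws `n_edges` distinct directed edges uniformly over all
#' `n_nodes^2` ordered node pairs (self-loops permitted), each with a sign
#' drawn from `sign_mix`.
#'
#' @param n_nodes Number of nodes (labelled `G01`, `G02`, ...).
#' @param n_edges Number of edges; at most `n_nodes^2`.
#' @param sign_mix Length-3 vector of proportions for Activation,
#'   Inhibition, Unspecified.
#' @param seed Integer seed.
#' @return A PKN tibble.
#' @export
generate_random_pkn <- function(n_nodes, n_edges, sign_mix = c(1, 1, 1) / 3,
                                seed = 1L) {
  if (n_edges > n_nodes^2) abort("`n_edges` exceeds the number of possible ordered pairs")
  if (length(sign_mix) != 3 || any(sign_mix < 0) || sum(sign_mix) == 0) {
    abort("`sign_mix` must be 3 non-negative proportions")
  }
  nodes <- sprintf("G%02d", seq_len(n_nodes))
  withr::with_seed(seed, {
    idx <- sample.int(n_nodes^2, n_edges)
    tibble(
      source = nodes[(idx - 1L) %/% n_nodes + 1L],
      sign = sample(INTERACTION_SIGNS, n_edges, replace = TRUE, prob = sign_mix),
      target = nodes[(idx - 1L) %% n_nodes + 1L]
    )
  })
}
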