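#' Perturb a PKN by random edge removal or addition
#'
#' `mode = "remove"` deletes a uniformly sampled set of
#' `round(fraction * n_edges)` edges. `mode = "add"` inserts that many new
#' edges between *existing* nodes (the TF universe stays fixed so perturbed
#' and original predictions remain comparable), each with uniformly random
#' source, target and sign in Activation/Inhibition, rejecting duplicates
#' of existing triples. The random draw is seeded deterministically from
#' `(base_seed, mode, fraction, trial)` so an entire sweep reproduces from
#' one base seed. `fraction = 0` is allowed as a degenerate case for
#' testing and returns the network unchanged.
#'
#' @param pkn PKN tibble.
#' @param mode `"remove"` or `"add"`.
#' @param fraction Fraction of the edge count to perturb, in `[0, 1)`.
#' @param trial Trial index (part of the seed derivation).
#' @param base_seed Integer base seed.
#' @return The perturbed PKN tibble.
#' @export
perturb_pkn <- function(pkn, mode = c("remove", "add"), fraction,
                        trial = 1L, base_seed = 1L) {
  mode <- match.arg(mode)
  validate_pkn(pkn)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    abort("`fraction` must be in [0, 1)")
  }
  n_change <- round(fraction * nrow(pkn))
  if (n_change == 0) return(pkn)
  seed <- as.integer(base_seed) + as.integer(trial) +
    1000L * as.integer(round(100 * fraction)) +
    500000L * (mode == "add")
  withr::with_seed(seed, {
    if (mode == "remove") {
      pkn[-sample.int(nrow(pkn), n_change), , drop = FALSE]
    } else {
      added <- random_edges(pkn_nodes(pkn), n_change,
                            signs = c("Activation", "Inhibition"),
                            existing = pkn)
      dplyr::bind_rows(pkn, added)
    }
  })
}

#' Fraction of original top predictions recovered after perturbation
#'
#' The identity fraction is `|top_original intersect top_perturbed| /
#' |top_original|`: the proportion of the original run's top TFs that are
#' still predicted from the perturbed network.
#'
#' @param top_original Non-empty character vector of originally predicted
#'   TFs.
#' @param top_perturbed Character vector of TFs predicted after
#'   perturbation (may be empty).
#' @return A number in `[0, 1]`.
#' @examples
#' identity_fraction(LETTERS[1:10], c(LETTERS[1:5], letters[1:5])) # 0.5
#' @export
identity_fraction <- function(top_original, top_perturbed) {
  top_original <- unique(top_original)
  if (length(top_original) == 0) {
    abort("`top_original` must be non-empty: the metric is undefined")
  }
  length(intersect(top_original, unique(top_perturbed))) / length(top_original)
}

#' Sensitivity of predictions to PKN perturbation
#'
#' Runs the full prediction pipeline on the unperturbed PKN, then for every
#' combination of mode, perturbation fraction and trial, reruns it on a
#' perturbed PKN (same configuration and seed, for comparability) and
#' records the identity fraction of the top-`top_n` TF-level rankings.
#'
#' @param expr Long-form expression tibble.
#' @param pkn PKN tibble.
#' @param config A [seesaw_config()].
#' @param fractions Perturbation fraction grid (default 5% to 25% in 5%
#'   steps).
#' @param modes Perturbation modes to sweep.
#' @param n_trials Independent perturbed networks per (mode, fraction).
#' @param top_n Number of top TFs compared (default 10).
#' @param base_seed Base seed for the perturbation draws (defaults to
#'   `config$seed`).
#' @return A `seesaw_sensitivity` object with elements `detail` (one row
#'   per mode/fraction/trial with `identity_fraction`), `summary` (median
#'   and quartiles per mode/fraction) and `baseline_top`. Use [tidy()],
#'   [glance()] and [autoplot()] on it.
#' @export
sensitivity_sweep <- function(expr, pkn, config = seesaw_config(),
                              fractions = seq(0.05, 0.25, by = 0.05),
                              modes = c("remove", "add"),
                              n_trials = 10L, top_n = 10L,
                              base_seed = config$seed) {
  baseline <- predict_determinants(expr, pkn, config)
  top0 <- utils::head(baseline$tf_ranking$tf, top_n)
  if (length(top0) == 0) {
    abort("baseline run produced no predictions: identity fraction undefined")
  }

  grid <- tidyr::expand_grid(mode = modes, fraction = fractions,
                             trial = seq_len(n_trials))
  detail <- purrr::pmap(grid, function(mode, fraction, trial) {
    perturbed <- perturb_pkn(pkn, mode, fraction, trial, base_seed)
    fit <- predict_determinants(expr, perturbed, config)
    tibble(
      mode = mode, fraction = fraction, trial = trial,
      identity_fraction = identity_fraction(
        top0, utils::head(fit$tf_ranking$tf, top_n)
      )
    )
  }) |>
    purrr::list_rbind()

  summary <- detail |>
    dplyr::group_by(.data$mode, .data$fraction) |>
    dplyr::summarise(
      median = median(.data$identity_fraction),
      q1 = unname(quantile(.data$identity_fraction, 0.25)),
      q3 = unname(quantile(.data$identity_fraction, 0.75)),
      .groups = "drop"
    )

  structure(
    list(detail = detail, summary = summary, baseline_top = top0,
         top_n = top_n, config = config),
    class = "seesaw_sensitivity"
  )
}

#' @export
print.seesaw_sensitivity <- function(x, ...) {
  cat("<seesaw_sensitivity>  top", x$top_n, "TFs,",
      nrow(x$detail), "perturbed runs\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy a sensitivity sweep into its per-trial table
#'
#' @param x A `seesaw_sensitivity`.
#' @param ... Unused.
#' @return Tibble with one row per (mode, fraction, trial).
#' @export
tidy.seesaw_sensitivity <- function(x, ...) {
  x$detail
}

#' One-row summary of a sensitivity sweep
#'
#' @param x A `seesaw_sensitivity`.
#' @param ... Unused.
#' @return A one-row tibble: number of runs, fraction range, and the
#'   overall median identity fraction per mode.
#' @export
glance.seesaw_sensitivity <- function(x, ...) {
  per_mode <- x$detail |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(m = median(.data$identity_fraction), .groups = "drop")
  out <- tibble(
    n_runs = nrow(x$detail),
    min_fraction = min(x$detail$fraction),
    max_fraction = max(x$detail$fraction)
  )
  for (i in seq_len(nrow(per_mode))) {
    out[[paste0("median_", per_mode$mode[i])]] <- per_mode$m[i]
  }
  out
}

#' Box plot of identity fractions across perturbation levels
#'
#' @param object A `seesaw_sensitivity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seesaw_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$detail, ggplot2::aes(
    x = factor(.data$fraction), y = .data$identity_fraction
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "perturbed fraction of edges",
                  y = "fraction of identical top predictions") +
    ggplot2::theme_minimal()
}
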