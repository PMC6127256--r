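#' Analysis configuration for the seesaw pipeline
#'
#' Collects every tunable parameter of the prediction pipeline in one object
#' so that a run is a pure function of `(expression, pkn, config)`.
#'
#' @param pseudocount Small positive value added to every expression mean
#'   before any ratio is formed, guarding against zero expression.
#' @param de_alpha Adjusted-p threshold for calling a TF differentially
#'   expressed between the two daughter cell types.
#' @param de_min_abs_log2fc Minimum absolute log2 fold change (Daughter1 vs
#'   Daughter2) required in addition to `de_alpha`.
#' @param nrd_alpha Adjusted-p threshold for the NRD significance test.
#' @param nrd_abs_threshold Absolute NRD a pair must exceed in *both*
#'   daughter cell types. The method's reference value is 0.5.
#' @param min_out_degree_exclusive Out-degree cutoff for the network filter:
#'   nodes are kept only while their out-degree exceeds this value. The
#'   method's reference value is 6.
#' @param n_solutions Number of GRN solutions to sample; capped at 10000.
#' @param retention_probability Probability that a consistent edge is kept
#'   in any one GRN solution.
#' @param nrd_test Which NRD significance test to use: `"ratio_t"` (Welch
#'   test on per-replicate log expression ratios, the default; requires at
#'   least two replicates per cell type), `"empirical"` (pooled empirical
#'   null over all computed |NRD| values) or `"none"`.
#' @param seed Integer seed; all randomness in the pipeline derives from it.
#'
#' @return A `seesaw_config` object (a named list).
#' @examples
#' cfg <- seesaw_config(n_solutions = 100, seed = 42)
#' cfg$nrd_abs_threshold
#' @export
seesaw_config <- function(pseudocount = 1e-6,
                          de_alpha = 0.05,
                          de_min_abs_log2fc = 1,
                          nrd_alpha = 0.05,
                          nrd_abs_threshold = 0.5,
                          min_out_degree_exclusive = 6L,
                          n_solutions = 200L,
                          retention_probability = 0.8,
                          nrd_test = c("ratio_t", "empirical", "none"),
                          seed = 1L) {
  nrd_test <- match.arg(nrd_test)
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be a positive number.")
  }
  if (!is.numeric(n_solutions) || length(n_solutions) != 1 ||
      n_solutions < 1 || n_solutions > 10000) {
    abort("`n_solutions` must be between 1 and the cap of 10000 networks.")
  }
  if (!is.numeric(retention_probability) ||
      retention_probability <= 0 || retention_probability > 1) {
    abort("`retention_probability` must be in (0, 1].")
  }
  if (min_out_degree_exclusive < 0) {
    abort("`min_out_degree_exclusive` must be >= 0.")
  }
  structure(
    list(
      pseudocount = pseudocount,
      de_alpha = de_alpha,
      de_min_abs_log2fc = de_min_abs_log2fc,
      nrd_alpha = nrd_alpha,
      nrd_abs_threshold = nrd_abs_threshold,
      min_out_degree_exclusive = as.integer(min_out_degree_exclusive),
      n_solutions = as.integer(n_solutions),
      retention_probability = retention_probability,
      nrd_test = nrd_test,
      seed = as.integer(seed)
    ),
    class = "seesaw_config"
  )
}

#' @export
print.seesaw_config <- function(x, ...) {
  cat("<seesaw_config>\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}
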