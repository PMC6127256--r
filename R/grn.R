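#' Subset a PKN to a TF set
#'
#' Returns the induced subnetwork: only interactions whose source *and*
#' target are both in `tfs` are kept.
#'
#' @param pkn PKN tibble (`source`, `sign`, `target`).
#' @param tfs Character vector of TF symbols.
#' @return The induced PKN tibble (possibly empty).
#' @export
subset_pkn <- function(pkn, tfs) {
  validate_pkn(pkn)
  dplyr::filter(pkn, .data$source %in% tfs, .data$target %in% tfs)
}

pkn_out_degrees <- function(pkn, nodes = pkn_nodes(pkn)) {
  counts <- table(factor(pkn$source, levels = nodes))
  setNames(as.integer(counts), nodes)
}

#' Iteratively remove low-out-degree nodes from a PKN
#'
#' Removes every node whose out-degree (number of outgoing interaction
#' records) is `<= min_exclusive`, recomputes degrees on the reduced
#' network, and repeats until a fixed point: every surviving node has
#' out-degree strictly greater than the cutoff *within the returned
#' network*. A single pass would leave nodes whose out-degree only fell
#' below the cutoff because their targets were removed.
#'
#' @param pkn PKN tibble.
#' @param min_exclusive Exclusive out-degree cutoff (default 6: keep nodes
#'   with out-degree larger than six).
#' @return The induced PKN on the surviving nodes (possibly empty). The
#'   number of removal iterations is reported via a message.
#' @export
filter_by_out_degree <- function(pkn, min_exclusive = 6L) {
  validate_pkn(pkn)
  if (min_exclusive < 0) abort("`min_exclusive` must be >= 0")
  nodes <- pkn_nodes(pkn)
  edges <- pkn
  iter <- 0L
  repeat {
    od <- pkn_out_degrees(edges, nodes)
    drop <- nodes[od <= min_exclusive]
    if (length(drop) == 0 || length(nodes) == 0) break
    iter <- iter + 1L
    nodes <- setdiff(nodes, drop)
    edges <- dplyr::filter(edges, .data$source %in% nodes, .data$target %in% nodes)
  }
  inform(sprintf("out-degree filter converged in %d iteration(s); %d node(s), %d edge(s) kept",
                 iter, length(nodes), nrow(edges)))
  edges
}

dir_lookup <- function(directions) {
  if (is.data.frame(directions)) {
    if (!all(c("gene", "direction") %in% colnames(directions))) {
      abort("directions must have columns gene and direction")
    }
    setNames(directions$direction, directions$gene)
  } else {
    directions
  }
}

#' Edge consistency with daughter differential-expression directions
#'
#' An `Activation` edge is consistent iff source and target change in the
#' same direction between the two daughter cell types; an `Inhibition` edge
#' iff they change in opposite directions (the toggle-switch pattern).
#' `Unspecified` signs must be resolved before calling.
#'
#' @param edges Tibble with columns `source`, `sign`, `target` (signs
#'   `Activation`/`Inhibition` only).
#' @param directions Either a tibble with columns `gene`, `direction` or a
#'   named character vector mapping gene to `up_in_D1`/`up_in_D2`. Every
#'   edge endpoint must be present.
#' @return Logical vector, one element per edge.
#' @export
edge_consistent <- function(edges, directions) {
  dir <- dir_lookup(directions)
  if (any(edges$sign == "Unspecified")) {
    abort("edge_consistent() requires resolved signs (no Unspecified)")
  }
  ds <- dir[edges$source]
  dt <- dir[edges$target]
  if (anyNA(ds) || anyNA(dt)) {
    missing <- unique(c(edges$source[is.na(ds)], edges$target[is.na(dt)]))
    abort(sprintf("edge endpoint(s) missing from direction map: %s",
                  paste(missing, collapse = ", ")))
  }
  ifelse(edges$sign == "Activation", ds == dt, ds != dt)
}

#' Sample Boolean-consistent GRN solutions from a filtered PKN
#'
#' Each solution is generated independently with seed `config$seed +
#' solution_id` by (i) assigning every `Unspecified` edge a sign uniformly
#' at random, (ii) dropping edges inconsistent with the daughter
#' differential-expression directions ([edge_consistent()]) and
#' (iii) keeping each remaining edge independently with probability
#' `config$retention_probability`. The same inputs and seed always yield a
#' bit-identical solution set; duplicate edge sets across solutions are
#' allowed.
#'
#' @param pkn Filtered PKN tibble whose nodes all have a direction.
#' @param directions Direction map (see [edge_consistent()]).
#' @param config A [seesaw_config()]; uses `n_solutions`,
#'   `retention_probability` and `seed`.
#' @return Tibble with columns `solution_id`, `source`, `sign`, `target`,
#'   `seed_used`; solutions with no surviving edges contribute no rows. The
#'   number of solutions is recorded in the `n_solutions` attribute.
#' @export
sample_grn_solutions <- function(pkn, directions, config = seesaw_config()) {
  validate_pkn(pkn)
  dir <- dir_lookup(directions)
  nodes <- pkn_nodes(pkn)
  if (!all(nodes %in% names(dir))) {
    abort("every node of the filtered PKN needs a direction")
  }
  n_edges <- nrow(pkn)
  unspecified <- pkn$sign == "Unspecified"

  sols <- purrr::map(seq_len(config$n_solutions), function(id) {
    seed_used <- config$seed + id
    withr::with_seed(seed_used, {
      sign <- pkn$sign
      if (any(unspecified)) {
        sign[unspecified] <- sample(c("Activation", "Inhibition"),
                                    sum(unspecified), replace = TRUE)
      }
      resolved <- tibble(source = pkn$source, sign = sign, target = pkn$target)
      keep <- edge_consistent(resolved, dir) &
        runif(n_edges) <= config$retention_probability
      # conflicting duplicate edges can collapse after sign resolution
      dplyr::distinct(resolved[keep, ]) |>
        dplyr::mutate(solution_id = id, seed_used = seed_used, .before = 1)
    })
  }) |>
    purrr::list_rbind()
  attr(sols, "n_solutions") <- config$n_solutions
  sols
}

#' Strongly connected components of one edge set
#'
#' Detects all maximal strongly connected components of size at least two
#' (interaction signs are ignored, direction is respected). Size-1
#' components, including self-loops, are excluded: a TF pair can only
#' co-reside in a component with two or more members. Components are
#' numbered in lexicographic order of their smallest member and genes are
#' sorted within each component, so the output order is deterministic.
#'
#' @param edges Tibble with columns `source`, `target` (extra columns
#'   ignored).
#' @return Tibble with columns `component` (integer) and `gene`.
#' @export
strongly_connected_components <- function(edges) {
  empty <- tibble(component = integer(), gene = character())
  if (nrow(edges) == 0) return(empty)
  g <- igraph::graph_from_data_frame(
    dplyr::distinct(edges[, c("source", "target")]), directed = TRUE
  )
  comp <- igraph::components(g, mode = "strong")
  keep <- which(comp$csize >= 2)
  if (length(keep) == 0) return(empty)
  members <- lapply(keep, function(k) {
    sort(igraph::V(g)$name[comp$membership == k])
  })
  members <- members[order(vapply(members, `[`, character(1), 1))]
  tibble(
    component = rep(seq_along(members), lengths(members)),
    gene = unlist(members)
  )
}

#' Strongly connected components of every GRN solution
#'
#' @param solutions Solution tibble from [sample_grn_solutions()].
#' @return Tibble with columns `solution_id`, `component`, `gene`; the
#'   `n_solutions` attribute is carried over.
#' @export
scc_by_solution <- function(solutions) {
  out <- solutions |>
    dplyr::group_by(.data$solution_id) |>
    dplyr::group_map(function(ed, key) {
      dplyr::mutate(strongly_connected_components(ed),
                    solution_id = key$solution_id, .before = 1)
    }) |>
    purrr::list_rbind()
  if (nrow(out) == 0) {
    out <- tibble(solution_id = integer(), component = integer(), gene = character())
  }
  attr(out, "n_solutions") <- attr(solutions, "n_solutions")
  out
}
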