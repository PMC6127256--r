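# Build a long-form expression tibble from per-cell-type value matrices
# (vectors are recycled as genes x 1 matrices). Rows are gene-major with
# replicates in column order, matching read_expression().
expr_tbl <- function(genes, P, D1, D2) {
  mats <- list(Progenitor = matrix(P, nrow = length(genes)),
               Daughter1 = matrix(D1, nrow = length(genes)),
               Daughter2 = matrix(D2, nrow = length(genes)))
  reps <- unlist(lapply(names(mats), function(ct) {
    sprintf("%s_%d", ct, seq_len(ncol(mats[[ct]])))
  }), use.names = FALSE)
  cts <- rep(names(mats), vapply(mats, ncol, 1L))
  V <- do.call(cbind, mats)
  tibble::tibble(
    gene = rep(genes, each = length(reps)),
    replicate = rep(reps, times = length(genes)),
    cell_type = rep(cts, times = length(genes)),
    value = as.vector(t(V))
  )
}

# PKN tibble from flat (source, sign, target) triples.
pkn_tbl <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  tibble::tibble(source = m[, 1], sign = m[, 2], target = m[, 3])
}

# Brute-force SCC oracle: Warshall transitive closure + mutual reachability.
# Same output contract as strongly_connected_components().
scc_oracle <- function(edges) {
  nodes <- sort(unique(c(edges$source, edges$target)))
  n <- length(nodes)
  if (n == 0) return(tibble::tibble(component = integer(), gene = character()))
  R <- diag(n) > 0
  R[cbind(match(edges$source, nodes), match(edges$target, nodes))] <- TRUE
  for (k in seq_len(n)) R <- R | outer(R[, k], R[k, ], "&")
  mutual <- R & t(R)
  membership <- match(
    apply(mutual, 1, paste, collapse = ""),
    unique(apply(mutual, 1, paste, collapse = ""))
  )
  comps <- split(nodes, membership)
  comps <- comps[lengths(comps) >= 2]
  comps <- lapply(comps, sort)
  if (length(comps) == 0) return(tibble::tibble(component = integer(), gene = character()))
  comps <- comps[order(vapply(comps, `[`, character(1), 1))]
  tibble::tibble(
    component = rep(seq_along(comps), lengths(comps)),
    gene = unlist(comps, use.names = FALSE)
  )
}

# Exhaustive reciprocal-rank-fusion oracle.
rrf_oracle <- function(tf, ranking_list, k) {
  total <- 0
  for (tfs in ranking_list) {
    pos <- which(tfs == tf)
    if (length(pos) == 1) total <- total + 1 / (k + pos)
  }
  total
}
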