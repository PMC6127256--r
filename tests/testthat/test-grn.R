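test_that("PKN subsetting keeps only edges with both endpoints in the TF set", {
  pkn <- pkn_tbl("A", "Activation", "B", "B", "Activation", "C", "C", "Activation", "A")
  expect_equal(nrow(subset_pkn(pkn, c("A", "B"))), 1)
  expect_equal(subset_pkn(pkn, c("A", "B"))$source, "A")
  expect_equal(subset_pkn(pkn, pkn_nodes(pkn)), pkn)
  expect_equal(nrow(subset_pkn(pkn, character())), 0)
})

test_that("out-degree filtering iterates to a fixed point", {
  # hub with 7 sink targets: the sinks fall first, then the hub cascades out
  hub <- pkn_tbl(
    "H", "Activation", "T1", "H", "Activation", "T2", "H", "Activation", "T3",
    "H", "Activation", "T4", "H", "Activation", "T5", "H", "Activation", "T6",
    "H", "Activation", "T7"
  )
  expect_message(out <- filter_by_out_degree(hub, 6L), "2 iteration")
  expect_equal(nrow(out), 0)

  # complete digraph on 8 nodes: out-degree 7 everywhere, untouched
  nodes <- paste0("N", 1:8)
  complete <- tidyr::expand_grid(source = nodes, target = nodes) |>
    dplyr::filter(source != target) |>
    dplyr::mutate(sign = "Activation", .after = "source")
  suppressMessages(expect_equal(filter_by_out_degree(complete, 6L), complete))

  # cutoff 0 removes sink nodes iteratively
  chain <- pkn_tbl("A", "Activation", "B", "B", "Activation", "C")
  suppressMessages(expect_equal(nrow(filter_by_out_degree(chain, 0L)), 0))
})

test_that("filtered networks are a fixed point on random instances", {
  for (s in 1:20) {
    pkn <- generate_random_pkn(12, 60, seed = s)
    suppressMessages(out <- filter_by_out_degree(pkn, 3L))
    if (nrow(out) > 0) {
      od <- table(factor(out$source, levels = pkn_nodes(out)))
      expect_true(all(od > 3))
    }
  }
})

test_that("edge consistency encodes co-regulation vs mutual antagonism", {
  dirs <- tibble::tibble(gene = c("A", "B"), direction = c("up_in_D1", "up_in_D1"))
  expect_true(edge_consistent(pkn_tbl("A", "Activation", "B"), dirs))
  expect_false(edge_consistent(pkn_tbl("A", "Inhibition", "B"), dirs))
  toggle_dirs <- c(A = "up_in_D1", B = "up_in_D2")
  expect_true(edge_consistent(pkn_tbl("A", "Inhibition", "B"), toggle_dirs))
  expect_error(edge_consistent(pkn_tbl("A", "Activation", "C"), dirs), "missing")
  expect_error(edge_consistent(pkn_tbl("A", "Unspecified", "B"), dirs), "Unspecified")
})

test_that("with only consistent signed edges and full retention every solution is the core", {
  pkn <- pkn_tbl("A", "Inhibition", "B", "B", "Inhibition", "A", "A", "Activation", "C")
  dirs <- c(A = "up_in_D1", B = "up_in_D2", C = "up_in_D1")
  sols <- sample_grn_solutions(pkn, dirs, seesaw_config(n_solutions = 5, retention_probability = 1))
  expect_equal(attr(sols, "n_solutions"), 5L)
  for (id in 1:5) {
    sol <- sols[sols$solution_id == id, c("source", "sign", "target")]
    expect_equal(dplyr::arrange(sol, source), dplyr::arrange(pkn, source),
                 ignore_attr = TRUE)
  }
})

test_that("solution sampling is deterministic in the seed and respects the config contract", {
  pkn <- generate_random_pkn(8, 30, seed = 4)
  dirs <- withr::with_seed(4, setNames(sample(c("up_in_D1", "up_in_D2"), 8, TRUE),
                                       sprintf("G%02d", 1:8)))
  cfg <- seesaw_config(n_solutions = 10, seed = 99)
  expect_identical(sample_grn_solutions(pkn, dirs, cfg),
                   sample_grn_solutions(pkn, dirs, cfg))
  expect_error(seesaw_config(n_solutions = 10001), "10000")
})

test_that("sampled solutions only contain consistent edges from the input network", {
  for (s in 1:10) {
    pkn <- generate_random_pkn(10, 40, seed = s)
    nodes <- pkn_nodes(pkn)
    dirs <- withr::with_seed(s, setNames(sample(c("up_in_D1", "up_in_D2"),
                                                length(nodes), TRUE), nodes))
    sols <- sample_grn_solutions(pkn, dirs, seesaw_config(n_solutions = 5, seed = s))
    if (nrow(sols) == 0) next
    expect_true(all(edge_consistent(sols, dirs)))
    expect_true(all(paste(sols$source, sols$target) %in% paste(pkn$source, pkn$target)))
  }
})

test_that("an Unspecified edge between equal-direction endpoints survives half the time", {
  pkn <- pkn_tbl("A", "Unspecified", "B")
  dirs <- c(A = "up_in_D1", B = "up_in_D1")
  sols <- sample_grn_solutions(pkn, dirs,
                               seesaw_config(n_solutions = 1000, retention_probability = 1, seed = 3))
  freq <- nrow(sols) / 1000
  expect_gt(freq, 0.45)
  expect_lt(freq, 0.55)
  expect_true(all(sols$sign == "Activation"))
})

test_that("SCC detection handles the canonical small cases", {
  toggle <- pkn_tbl("A", "Inhibition", "B", "B", "Inhibition", "A")
  comp <- strongly_connected_components(toggle)
  expect_equal(comp$component, c(1L, 1L))
  expect_equal(comp$gene, c("A", "B"))

  dag <- pkn_tbl("A", "Activation", "B", "B", "Activation", "C", "A", "Activation", "C")
  expect_equal(nrow(strongly_connected_components(dag)), 0)

  # self-loops never form a reportable (size >= 2) component
  loop <- pkn_tbl("A", "Activation", "A")
  expect_equal(nrow(strongly_connected_components(loop)), 0)
})

test_that("SCC detection matches the brute-force reachability oracle on random digraphs", {
  for (s in 1:50) {
    withr::with_seed(s, {
      n <- sample(3:12, 1)
      pkn <- generate_random_pkn(n, sample.int(min(3 * n, n^2), 1), seed = s)
    })
    expect_equal(strongly_connected_components(pkn), scc_oracle(pkn),
                 info = paste("seed", s))
  }
})
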