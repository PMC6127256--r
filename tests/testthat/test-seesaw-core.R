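test_that("replicate aggregation takes arithmetic group means and ignores column order", {
  expr <- expr_tbl("TF1", P = cbind(1, 3), D1 = cbind(2, 4), D2 = cbind(10, 20))
  prof <- aggregate_replicates(expr)
  expect_equal(prof$mean_P, 2)
  expect_equal(prof$mean_D1, 3)
  expect_equal(prof$mean_D2, 15)

  single <- expr_tbl(c("A", "B"), P = c(1, 2), D1 = c(3, 4), D2 = c(5, 6))
  prof1 <- aggregate_replicates(single)
  expect_equal(prof1$mean_D2, c(5, 6))

  shuffled <- expr[sample.int(nrow(expr)), ]
  expect_equal(aggregate_replicates(shuffled), prof)
})

test_that("nrd matches direct substitution and rejects non-positive input", {
  expect_equal(nrd(2, 1, 2, 1), 0)
  expect_equal(nrd(4, 2, 1, 2), 0.75)
  expect_error(nrd(0, 1, 1, 1), "positive")
  expect_error(nrd(1, 1, -1, 1), "positive")
})

test_that("nrd algebraic identity and scale invariance hold on random positive inputs", {
  withr::with_seed(11, {
    for (i in 1:500) {
      q <- exp(stats::rnorm(4, sd = 2))
      x <- nrd(q[1], q[2], q[3], q[4])
      y <- nrd(q[2], q[1], q[4], q[3])
      expect_lt(abs((1 - x) * (1 - y) - 1), 1e-9)
      s <- exp(stats::rnorm(1))
      expect_equal(nrd(s * q[1], s * q[2], s * q[3], s * q[4]), x, tolerance = 1e-12)
    }
  })
})

test_that("the vectorized Welch p-value agrees with stats::t.test", {
  withr::with_seed(5, {
    for (i in 1:25) {
      x <- stats::rnorm(4, mean = i %% 3)
      y <- stats::rnorm(6, sd = 2)
      got <- seesawtf:::welch_p(mean(x), stats::var(x), length(x),
                                mean(y), stats::var(y), length(y))
      expect_equal(got, stats::t.test(x, y)$p.value, tolerance = 1e-12)
    }
  })
})

test_that("differential calls require both significance and fold change, with directions", {
  expr <- expr_tbl(
    c("SEP", "FLAT", "WEAK"),
    P = cbind(c(50, 50, 50), c(55, 50, 52)),
    D1 = cbind(c(100, 20, 50), c(110, 20, 55)),
    D2 = cbind(c(1, 20, 45), c(1.2, 20, 50))
  )
  calls <- call_differential_tfs(expr, c("SEP", "FLAT", "WEAK"), seesaw_config())
  expect_equal(calls$gene, "SEP")
  expect_equal(calls$direction, "up_in_D1")
  expect_error(call_differential_tfs(expr, "NOT_PRESENT"), "no TFs shared")
})

test_that("single-replicate daughters degenerate to fold-change-only filtering", {
  expr <- expr_tbl(c("A", "B"), P = c(10, 10), D1 = c(40, 11), D2 = c(10, 10))
  expect_message(
    calls <- call_differential_tfs(expr, c("A", "B"), seesaw_config()),
    "fold change only"
  )
  expect_equal(calls$gene, "A")
  expect_true(is.na(calls$p_value))
})

test_that("planted anti-correlated pairs are both called, in opposite directions, across seeds", {
  hits <- 0L
  for (s in 1:100) {
    ok <- withr::with_seed(s, {
      noise <- function(mu) mu * exp(stats::rnorm(3, 0, 0.1))
      expr <- expr_tbl(
        c("X", "Y"),
        P = rbind(noise(100), noise(100)),
        D1 = rbind(noise(1000), noise(10)),
        D2 = rbind(noise(10), noise(1000))
      )
      calls <- call_differential_tfs(expr, c("X", "Y"), seesaw_config())
      nrow(calls) == 2 &&
        calls$direction[calls$gene == "X"] == "up_in_D1" &&
        calls$direction[calls$gene == "Y"] == "up_in_D2"
    })
    hits <- hits + ok
  }
  expect_gte(hits, 95)
})

test_that("the NRD table enumerates ordered pairs and survives zero means via the pseudocount", {
  expr <- expr_tbl(
    c("A", "B"),
    P = cbind(c(0, 5), c(0, 6)),
    D1 = cbind(c(10, 5), c(12, 6)),
    D2 = cbind(c(1, 5), c(2, 4))
  )
  prof <- aggregate_replicates(expr)
  tab <- build_nrd_table(prof, c("A", "B"), seesaw_config(), expr = expr)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$nrd_d1)) && all(is.finite(tab$nrd_d2)))

  expect_warning(
    empty <- build_nrd_table(prof, "A", seesaw_config(), expr = expr),
    "fewer than 2"
  )
  expect_equal(nrow(empty), 0)
})

test_that("ratio significance test matches an explicit per-pair t.test computation", {
  withr::with_seed(21, {
    genes <- paste0("G", 1:4)
    vals <- function(n) matrix(exp(stats::rnorm(4 * n, log(50), 0.5)), nrow = 4)
    expr <- expr_tbl(genes, P = vals(3), D1 = vals(4), D2 = vals(3))
    prof <- aggregate_replicates(expr)
    tab <- build_nrd_table(prof, genes, seesaw_config(), expr = expr)

    pc <- seesaw_config()$pseudocount
    lr <- function(i, j, ct) {
      sub <- expr[expr$cell_type == ct, ]
      wide <- tidyr::pivot_wider(sub, id_cols = "gene",
                                 names_from = "replicate", values_from = "value")
      m <- log2(as.matrix(wide[, -1]) + pc)
      m[match(i, wide$gene), ] - m[match(j, wide$gene), ]
    }
    for (r in sample.int(nrow(tab), 5)) {
      i <- tab$tf_i[r]; j <- tab$tf_j[r]
      p1 <- stats::t.test(lr(i, j, "Progenitor"), lr(i, j, "Daughter1"))$p.value
      p2 <- stats::t.test(lr(i, j, "Progenitor"), lr(i, j, "Daughter2"))$p.value
      expect_equal(tab$p_value[r], max(p1, p2), tolerance = 1e-9)
    }
  })
})

test_that("pair selection applies the three criteria conjunctively", {
  calls <- tibble::tibble(gene = c("A", "B", "C"),
                          direction = c("up_in_D1", "up_in_D2", "up_in_D1"),
                          log2fc = c(2, -2, 2), p_value = 0.001, p_adj = 0.001)
  tab <- tibble::tibble(
    tf_i = c("A", "B", "A", "C"),
    tf_j = c("B", "A", "C", "A"),
    nrd_d1 = c(0.9, -9, 0.9, -2),
    nrd_d2 = c(-0.8, 0.9, 0.3, 0.2),
    p_value = 0.001, p_adj = 0.001
  )
  kept <- select_candidate_pairs(tab, calls, seesaw_config())
  expect_equal(nrow(kept), 1)
  expect_equal(kept$tf_a, "A")
  expect_equal(kept$tf_b, "B")
  # the retained orientation maximizes min(|nrd_d1|, |nrd_d2|):
  # (B, A) with min(9, 0.9) = 0.9 beats (A, B) with min(0.9, 0.8) = 0.8
  expect_equal(kept$nrd_d1, -9)
  expect_equal(kept$nrd_d2, 0.9)

  # a TF without a differential call disqualifies its pairs
  no_b <- calls[calls$gene != "B", ]
  expect_equal(nrow(select_candidate_pairs(tab, no_b, seesaw_config())), 0)
})

test_that("on a 10-TF fixture selection agrees with a brute-force evaluation of the criteria", {
  withr::with_seed(33, {
    genes <- sprintf("T%02d", 1:10)
    # two strong opposite TFs, four moderate same-direction, four flat
    folds <- c(10, 1 / 10, 4, 4.2, 1 / 4, 1 / 4.1, 1, 1, 1, 1)
    noise <- function(mu) mu * exp(stats::rnorm(3, 0, 0.05))
    P <- t(sapply(rep(100, 10), noise))
    D1 <- t(sapply(100 * folds, noise))
    D2 <- t(sapply(100 / folds, noise))
    expr <- expr_tbl(genes, P, D1, D2)
    cfg <- seesaw_config()

    prof <- aggregate_replicates(expr)
    calls <- call_differential_tfs(expr, genes, cfg)
    tab <- build_nrd_table(prof, calls$gene, cfg, expr = expr)
    kept <- select_candidate_pairs(tab, calls, cfg)

    # independent oracle: loop over all unordered pairs and re-apply the criteria
    expected <- character()
    for (a in genes) {
      for (b in genes) {
        if (a >= b) next
        rows <- tab[(tab$tf_i == a & tab$tf_j == b) | (tab$tf_i == b & tab$tf_j == a), ]
        if (nrow(rows) == 0) next
        best <- rows[which.max(pmin(abs(rows$nrd_d1), abs(rows$nrd_d2))), ]
        ok <- a %in% calls$gene && b %in% calls$gene &&
          best$p_adj < cfg$nrd_alpha &&
          abs(best$nrd_d1) > cfg$nrd_abs_threshold &&
          abs(best$nrd_d2) > cfg$nrd_abs_threshold
        if (ok) expected <- c(expected, paste(a, b))
      }
    }
    expect_setequal(paste(kept$tf_a, kept$tf_b), expected)
    expect_true(paste("T01", "T02") %in% expected)
  })
})

test_that("raising the |NRD| threshold never adds a pair", {
  withr::with_seed(8, {
    genes <- sprintf("T%d", 1:6)
    folds <- exp(stats::rnorm(6, 0, 1.5))
    expr <- expr_tbl(genes,
                     P = t(sapply(rep(100, 6), function(m) m * exp(stats::rnorm(3, 0, 0.1)))),
                     D1 = t(sapply(100 * folds, function(m) m * exp(stats::rnorm(3, 0, 0.1)))),
                     D2 = t(sapply(100 / folds, function(m) m * exp(stats::rnorm(3, 0, 0.1)))))
    prof <- aggregate_replicates(expr)
    calls <- call_differential_tfs(expr, genes, seesaw_config())
    expect_gte(nrow(calls), 2)
    tab <- build_nrd_table(prof, calls$gene, seesaw_config(), expr = expr)
    prev <- NULL
    for (thr in c(0.3, 0.5, 0.8, 1.5)) {
      kept <- select_candidate_pairs(tab, calls, seesaw_config(nrd_abs_threshold = thr))
      keys <- paste(kept$tf_a, kept$tf_b)
      if (!is.null(prev)) expect_true(all(keys %in% prev))
      prev <- keys
    }
  })
})
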