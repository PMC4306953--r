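test_that("a labeled 4-carbon chain resolves into two acetate-sized units", {
  g <- make_chain_graph(4)
  best <- tile(g, calls = list(acetate_1_13C = c("1", "3")))[[1]]
  expect_length(best$units, 2L)
  expect_equal(best$tokens, c("acetyl_starter", "malonyl"))
  expect_equal(best$concordance, 1)
  expect_equal(best$n_anomalous, 0L)
  # the anchor consistent with the calls is the methyl end at node 4
  expect_equal(best$backbone, as.character(4:1))
})

test_that("the lorneic worked example yields the published tiling uniquely", {
  g <- read_carbon_graph(fixture("lorneic_acid_a_graph.txt"))
  tilings <- tile(g, lorneic_graph_calls())
  expect_equal(attr(tilings, "n_top_ties"), 1L)
  best <- tilings[[1]]
  expect_length(best$units, 8L)
  expect_equal(best$concordance, 1)
  expect_equal(best$n_anomalous, 0L)
  # single methylmalonate, fifth unit of the chain (C-8/C-7 + C-17 methyl)
  expect_equal(which(extender_sequence(best) == "methylmalonyl"), 5L)
  expect_equal(best$units[[5]]$c2, "8")
  expect_equal(best$units[[5]]$c1, "7")
  expect_equal(best$units[[5]]$side, "17")
  # chain runs from the C-16/C-15 acetate to the C-1 carboxyl
  expect_equal(best$backbone[1:2], c("16", "15"))
  expect_equal(best$backbone[16], "1")
})

test_that("the akaeolide tiling flags exactly the ring-closing bond", {
  g <- read_carbon_graph(fixture("akaeolide_graph.txt"))
  tilings <- tile(g, akaeolide_graph_calls())
  best <- tilings[[1]]
  expect_length(best$units, 8L)  # 1 starter + 7 extenders
  expect_equal(best$concordance, 1)
  side_sizes <- vapply(best$units, function(u) length(u$side), integer(1))
  expect_equal(side_sizes[-1], c(1L, 1L, 0L, 1L, 0L, 3L, 0L))
  expect_equal(best$n_anomalous, 1L)
  expect_equal(sort(unlist(best$anomalous_bonds[1, ])), c("16", "17"),
               ignore_attr = TRUE)
  # all other bonds are explained by head-to-tail extension
  expect_setequal(setdiff(best$bond_classes$class, "anomalous"),
                  c("intra_unit", "inter_unit", "side_attachment"))
})

test_that("tile agrees with the exhaustive oracle on small graphs", {
  set.seed(11)
  checked <- 0L
  seed <- 0L
  while (checked < 10L) {
    seed <- seed + 1L
    r <- run_pipeline(seed, n_modules = sample(2:4, 1),
                      inject = seed %% 2L == 0L)
    if (is.null(r) || length(r$lab$graph$nodes) > 12L) next
    checked <- checked + 1L
    calls <- lapply(r$lab$tables, function(t) classify_enriched(compute_enrichment(t)))
    a <- tile(r$lab$graph, calls)
    b <- brute_force_tile(r$lab$graph, calls)
    expect_identical(tiling_keys(a), tiling_keys(b))
    expect_identical(a[[1]]$key, b[[1]]$key)
    expect_equal(a[[1]]$concordance, b[[1]]$concordance)
  }
  # the truncated lorneic chain (first 10 carbons from the methyl end)
  sub <- carbon_graph(data.frame(a = as.character(16:8), b = as.character(15:7)),
                      terminal_hint = "16")
  calls <- list(acetate_1_13C = c("15", "13", "11", "9"), propionate_1_13C = "7")
  expect_identical(tiling_keys(tile(sub, calls)),
                   tiling_keys(brute_force_tile(sub, calls)))
})

test_that("the oracle refuses oversized graphs", {
  expect_error(brute_force_tile(make_chain_graph(16)), class = "pks_tiling_error")
})

test_that("every tiling partitions the nodes into its units", {
  graphs <- list(read_carbon_graph(fixture("akaeolide_graph.txt")),
                 read_carbon_graph(fixture("lorneic_acid_a_graph.txt")),
                 make_chain_graph(6))
  for (g in graphs) {
    for (t in tile(g)) {
      covered <- unlist(lapply(t$units, function(u) c(u$c2, u$c1, u$side)))
      expect_equal(sort_ids(covered), g$nodes)
      expect_false(anyDuplicated(covered) > 0L)
    }
  }
})

test_that("empty calls rank all size-compatible tilings equally", {
  tilings <- tile(make_chain_graph(6))
  conc <- vapply(tilings, `[[`, numeric(1), "concordance")
  expect_true(all(conc == 1))
  expect_length(tilings[[1]]$units, 3L)
})

test_that("tiling inputs are validated", {
  g <- make_chain_graph(4)
  expect_error(tile(g, calls = list(acetate_1_13C = "99")),
               class = "pks_validation_error")
  expect_error(carbon_graph(data.frame(a = c("1", "3"), b = c("2", "4"))),
               class = "pks_validation_error")  # disconnected
  expect_error(carbon_graph(data.frame(a = "1", b = "1")),
               class = "pks_validation_error")  # self loop
  # a graph whose every carbon is buried in a cycle has no starter candidate
  ring <- carbon_graph(data.frame(a = as.character(1:4),
                                  b = as.character(c(2:4, 1))))
  expect_error(tile(ring), class = "pks_tiling_error")
})

test_that("an injected alpha-alpha bond is flagged exactly", {
  found <- 0L
  seed <- 500L
  while (found < 10L) {
    seed <- seed + 1L
    r <- run_pipeline(seed, inject = TRUE)
    if (is.null(r)) next
    found <- found + 1L
    expect_equal(r$best$n_anomalous, 1L)
    expect_equal(sort(unlist(r$best$anomalous_bonds[1, ], use.names = FALSE)),
                 sort(r$truth$injected_bond))
  }
})
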