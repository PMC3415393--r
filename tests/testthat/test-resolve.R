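# mismatch graph, cycle/chain detection, plate transforms, attribution

scored_state <- function(ch) {
  train <- if (sum(ch$map$trusted) >= 3) ch$map[ch$map$trusted, ] else ch$map
  pairs <- scan_cis_associations(ch$expr, ch$geno, train)
  set <- fit_densities(pairs, ch$expr, ch$geno, train)
  P <- predict_matrix(set, ch$expr)
  O <- ch$geno$values[set$pairs$snp_id, , drop = FALSE]
  sc <- badger_scores(P, O)
  list(scores = sc, ranks = rank_matrix(sc),
       deltas = delta_statistic(sc))
}

test_that("a planted neighbour swap appears as an alternating 4-node cycle", {
  cfg <- cohort_config(seed = 70, error_spec = list(
                         list(type = "swap", platform = "genotype")))
  ch <- simulate_cohort(cfg)
  st <- scored_state(ch)
  g <- build_mismatch_graph(st$ranks, ch$map, scores = st$scores)
  expect_length(g$expr_nodes, 2)
  expect_length(g$geno_nodes, 2)
  # two evidence edges + the two (non-rank-1) intended pairings define the
  # 4-node cycle; the rank-1 evidence crosses the intended mapping
  ev <- g$edges[g$edges$rank == 1, ]
  expect_equal(nrow(ev), 2)
  expect_false(any(ev$intended))

  cc <- find_cycles_and_chains(g, ch$map,
                               zsep = separation_z(st$scores$B))
  expect_length(cc$cycles, 1)
  expect_equal(cc$cycles[[1]]$type, "swap")
  expect_setequal(cc$cycles[[1]]$samples, ch$truth[[1]]$samples)
})

test_that("an error-free cohort yields an empty graph and no hypotheses", {
  ch <- small_cohort(seed = 71)
  st <- scored_state(ch)
  g <- build_mismatch_graph(st$ranks, ch$map, scores = st$scores)
  expect_length(g$expr_nodes, 0)
  expect_equal(nrow(g$edges), 0)
  hyp <- enumerate_plate_transforms(ch$map, st$ranks)
  expect_length(hyp, 0)
})

test_that("an alien sample leaves an isolated high-scoring expression node", {
  cfg <- cohort_config(seed = 72, error_spec = list(
                         list(type = "alien", platform = "genotype",
                              sample = "S020")))
  ch <- simulate_cohort(cfg)
  st <- scored_state(ch)
  g <- build_mismatch_graph(st$ranks, ch$map, scores = st$scores)
  expect_true("ES020" %in% g$expr_nodes)
  expect_false(any(g$edges$expr == "ES020" & g$edges$rank == 1))
  cc <- find_cycles_and_chains(g, ch$map,
                               zsep = separation_z(st$scores$B))
  expect_length(cc$orphans, 1)
  expect_equal(cc$orphans[[1]]$samples, "S020")
})

test_that("a reversed 4-array block is reported whole, not as its middle swap", {
  # reversal of consecutive genotype wells = outer swap + inner swap
  cfg <- cohort_config(seed = 73, error_spec = list(
                         list(type = "swap", platform = "genotype",
                              samples = c("S009", "S012")),
                         list(type = "swap", platform = "genotype",
                              samples = c("S010", "S011"))))
  ch <- simulate_cohort(cfg)
  st <- scored_state(ch)
  g <- build_mismatch_graph(st$ranks, ch$map, scores = st$scores)
  cc <- find_cycles_and_chains(g, ch$map,
                               zsep = separation_z(st$scores$B))
  expect_length(cc$cycles, 1)
  expect_setequal(cc$cycles[[1]]$samples,
                  c("S009", "S010", "S011", "S012"))
})

test_that("planted slippage emits a chain with orphan arrays at both ends", {
  cfg <- cohort_config(seed = 74, error_spec = list(
                         list(type = "slippage", platform = "genotype",
                              start = 5, length = 6)))
  ch <- simulate_cohort(cfg)
  st <- scored_state(ch)
  g <- build_mismatch_graph(st$ranks, ch$map, scores = st$scores)
  cc <- find_cycles_and_chains(g, ch$map,
                               zsep = separation_z(st$scores$B))
  expect_length(cc$chains, 1)
  expect_setequal(cc$chains[[1]]$samples, ch$truth[[1]]$samples)
  res <- attribute_and_apply(cc$chains, ch$map)
  expect_equal(res$applied[[1]]$platform, "genotype")
  expect_true(maps_agree(res$map, ch$true_map))
})

test_that("a planted plate transform is recovered by the systematic search", {
  # densities trained on a trusted pilot: with the whole plate rotated no
  # intended pairing can be believed
  cfg <- cohort_config(n_samples = 96L, n_pilot = 48L, seed = 75,
                       error_spec = list(
    list(type = "plate_rotation", platform = "genotype",
         plate_id = "DNAP1")))
  ch <- simulate_cohort(cfg)
  st <- scored_state(ch)
  hyp <- enumerate_plate_transforms(ch$map, st$ranks)
  expect_gt(length(hyp), 0)
  best <- hyp[[1]]
  expect_equal(best$transform, "rotate180")
  expect_equal(best$platform, "genotype")
  res <- attribute_and_apply(list(best), ch$map)
  expect_true(maps_agree(res$map, ch$true_map))
})

test_that("attribution follows processing neighbourhood", {
  map <- toy_map()
  # samples A and C: expression neighbours? positions 1 and 3 - no;
  # use A and B: expression positions 1,2 (contiguous), genotype plates
  # differ entirely -> the error happened on the expression chip
  swap_ab <- list(type = "swap", samples = c("A", "B"),
                  pairing = data.frame(
                    sample_id = c("A", "B"),
                    expr_array = c("E1", "E2"),
                    matched_geno = c("G2", "G1"),
                    stringsAsFactors = FALSE))
  res <- attribute_and_apply(list(swap_ab), map)
  expect_equal(res$applied[[1]]$platform, "expression")
  # applied on the expression side: the owner of G2 (sample B) is on E1
  na <- res$applied[[1]]$new_assignment
  expect_setequal(na$platform, "expression")
  expect_equal(na$array[na$sample_id == "B"], "E1")

  # neighbours on both platforms: undetermined
  map2 <- toy_map()
  prov <- attr(map2, "provenance")
  prov$position[prov$platform == "genotype"] <- 1:4
  prov$plate_id[prov$platform == "genotype"] <- "DNAP1"
  attr(map2, "provenance") <- prov
  res2 <- attribute_and_apply(list(swap_ab), map2)
  expect_equal(res2$applied[[1]]$platform, "undetermined")
})

test_that("overlapping corrections conflict and none of them is applied", {
  map <- toy_map()
  swap1 <- list(type = "swap", samples = c("A", "B"),
                pairing = data.frame(sample_id = c("A", "B"),
                                     expr_array = c("E1", "E2"),
                                     matched_geno = c("G2", "G1"),
                                     stringsAsFactors = FALSE))
  swap2 <- list(type = "swap", samples = c("B", "C"),
                pairing = data.frame(sample_id = c("B", "C"),
                                     expr_array = c("E2", "E3"),
                                     matched_geno = c("G3", "G2"),
                                     stringsAsFactors = FALSE))
  expect_warning(res <- attribute_and_apply(list(swap1, swap2), map),
                 "conflict")
  expect_length(res$conflicts, 1)
  # disjoint double swap: both applied
  swap3 <- list(type = "swap", samples = c("C", "D"),
                pairing = data.frame(sample_id = c("C", "D"),
                                     expr_array = c("E3", "E4"),
                                     matched_geno = c("G4", "G3"),
                                     stringsAsFactors = FALSE))
  res2 <- attribute_and_apply(list(swap1, swap3), map)
  expect_length(res2$applied, 2)
  expect_length(res2$conflicts, 0)
})

test_that("single-mechanism planted errors are restored exactly across seeds", {
  mechanisms <- list(
    list(list(type = "swap", platform = "expression")),
    list(list(type = "swap", platform = "genotype")),
    list(list(type = "cycle", platform = "genotype", k = 3)),
    list(list(type = "slippage", platform = "genotype", length = 4)),
    list(list(type = "plate_rotation", platform = "genotype",
              plate_id = "DNAP1")))
  fails <- 0L
  for (m in seq_along(mechanisms)) {
    for (seed in 1:6) {
      # a whole-plate rotation leaves no believable intended pairings, so
      # that mechanism gets a trusted pilot to train on
      np <- if (m == 5) 48L else 0L
      cfg <- cohort_config(n_pilot = np, seed = 200 + 10 * m + seed,
                           error_spec = mechanisms[[m]])
      ch <- simulate_cohort(cfg)
      r <- suppressMessages(run_badger(ch$expr, ch$geno, ch$map))
      fails <- fails + !maps_agree(r$map, ch$true_map)
    }
  }
  expect_equal(fails, 0L)
})

test_that("DOT export writes a parseable graph description", {
  cfg <- cohort_config(seed = 76, error_spec = list(
                         list(type = "swap", platform = "genotype")))
  ch <- simulate_cohort(cfg)
  st <- scored_state(ch)
  g <- build_mismatch_graph(st$ranks, ch$map, scores = st$scores)
  f <- tempfile(fileext = ".dot")
  write_dot(g, f)
  lines <- readLines(f)
  expect_equal(lines[1], "graph mismatches {")
  expect_equal(tail(lines, 1), "}")
  expect_true(any(grepl("--", lines, fixed = TRUE)))
})
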