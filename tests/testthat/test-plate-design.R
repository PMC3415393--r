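# sex-based plate layout design and its combinatorics

test_that("an 8x12 plate has exactly 172 orthogonal neighbour pairs", {
  expect_equal(nrow(neighbour_index_pairs()), 172)
  all_male <- plate_layout(sex = matrix("male", 8, 12))
  expect_equal(count_same_sex_pairs(all_male), 172)
})

test_that("the blocked 1-2-2-2-1 pattern leaves 36 same-sex pairs, 3 per column", {
  lay <- generate_pattern("blocked_12221")
  expect_equal(count_same_sex_pairs(lay), 36)
  # per column: vertical same-sex pairs only, three in each
  per_col <- vapply(1:12, function(c)
    sum(lay$sex[1:7, c] == lay$sex[2:8, c]), numeric(1))
  expect_true(all(per_col == 3))
  # balanced
  expect_equal(sum(lay$sex == "male"), 48)
})

test_that("the chequerboard attains the minimum of zero same-sex pairs", {
  expect_equal(count_same_sex_pairs(generate_pattern("chequerboard")), 0)
})

test_that("random layouts are balanced and differ between seeds", {
  a <- generate_pattern("random", seed = 1)
  b <- generate_pattern("random", seed = 2)
  expect_equal(sum(a$sex == "male"), 48)
  expect_equal(sum(b$sex == "male"), 48)
  expect_false(identical(a$sex, b$sex))
  expect_true(count_same_sex_pairs(a) >= 0 &&
                count_same_sex_pairs(a) <= 172)
})

test_that("permuted-column designs are balanced and configurable", {
  lay <- generate_pattern("permuted_columns")
  expect_equal(sum(lay$sex == "male"), 48)
  lay2 <- generate_pattern("permuted_columns",
                           permutation = rep(c(1, 2), 6))
  expect_equal(sum(lay2$sex == "male"), 48)
  expect_false(identical(lay$sex, lay2$sex))
})

test_that("rotational symmetry and confusable pairs are detected", {
  cheq <- generate_pattern("chequerboard")
  flags <- check_rotational_distinctness(list(cheq))
  expect_true(any(grepl("self-symmetric", flags$relation)))

  blocked <- generate_pattern("blocked_12221")
  flags2 <- check_rotational_distinctness(list(blocked))
  expect_false(any(grepl("self-symmetric", flags2$relation)))
  # but its sex-inverse is its rotation, so the pair is confusable
  expect_true(any(grepl("inverse identical", flags2$relation)))

  rot <- blocked
  rot$sex <- rot$sex[8:1, 12:1]
  rot$plate_id <- "rotated"
  flags3 <- check_rotational_distinctness(list(blocked, rot))
  expect_true(any(grepl("rotation of each other", flags3$relation)))
})

test_that("random-layout simulation matches the analytic same-sex mean", {
  st <- simulate_random_layout_stats(n_plates = 50, n_reps = 20, seed = 90)
  analytic <- 172 * 2 * 48 * 47 / (96 * 95)        # 85.09
  se <- st$sd_same_sex / sqrt(st$n_layouts)
  expect_lt(abs(st$mean_same_sex - analytic), 3 * se + 0.2)
  # two plates: per-well mismatch probability is 1/2, so about 48 wells
  st2 <- simulate_random_layout_stats(n_plates = 2, n_reps = 400, seed = 91)
  expect_lt(abs(mean(st2$min_diff) - 48), 1.5)
})

test_that("a switch changes the well difference by at most two", {
  # lower bound d/2: one simple switch alters two wells at most; and d/2
  # switches suffice because mismatches pair off in a balanced layout
  set.seed(92)
  base <- sample(rep(0:1, 8))                       # 4x4 balanced plate
  other <- sample(rep(0:1, 8))
  d <- sum(base != other)
  for (i in 1:50) {
    sw <- sample(16, 2)
    pert <- base
    pert[sw] <- pert[rev(sw)]
    expect_lte(abs(sum(pert != other) - d), 2)
  }
  # constructive: pairing opposite-direction mismatches reaches the target
  # in exactly d/2 switches
  cur <- base; n_sw <- 0
  while (any(cur != other)) {
    i <- which(cur == 1 & other == 0)[1]
    j <- which(cur == 0 & other == 1)[1]
    cur[c(i, j)] <- cur[c(j, i)]
    n_sw <- n_sw + 1
  }
  expect_equal(n_sw, d / 2)
})

test_that("sex-check diagnostics identify transforms and tolerate same-sex swaps", {
  lay <- generate_pattern("blocked_12221")
  res <- sex_check_diagnostic(lay, lay$sex)
  expect_equal(res$best, "identity")
  expect_length(res$mismatches, 0)

  rot <- lay$sex[8:1, 12:1]
  res2 <- sex_check_diagnostic(lay, rot)
  expect_equal(res2$best, "rotate180")
  expect_length(res2$mismatches, 0)

  # a same-sex neighbour swap is invisible to the sex check by design
  swapped <- lay$sex
  hit <- which(swapped[1:7, 1] == swapped[2:8, 1])[1]
  swapped[c(hit, hit + 1), 1] <- swapped[c(hit + 1, hit), 1]
  res3 <- sex_check_diagnostic(lay, swapped)
  expect_equal(res3$best, "identity")
  expect_length(res3$mismatches, 0)

  # use of another plate is recognised
  alt <- generate_pattern("random", seed = 9, plate_id = "alt")
  res4 <- sex_check_diagnostic(lay, alt$sex, alternates = list(alt = alt))
  expect_equal(res4$best, "plate:alt")
})
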