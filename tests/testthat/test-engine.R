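# genotype prediction, score/rank matrices, gap statistic, discrepancy and
# refinement with fast rescoring

# build grid densities from closed-form Gaussians (independent of the KDE
# fitting path)
gauss_density <- function(mu, sd, from = -3, to = 5, n = 2048) {
  x <- seq(from, to, length.out = n)
  list(x = x, y = dnorm(x, mu, sd), bw = sd, n = 1L)
}

test_that("posterior prediction agrees with a brute-force density ratio", {
  set.seed(40)
  for (rep in 1:100) {
    mus <- sort(runif(3, -1, 3))
    sds <- runif(3, 0.1, 0.6)
    dens <- list(AA = gauss_density(mus[1], sds[1]),
                 AB = gauss_density(mus[2], sds[2]),
                 BB = gauss_density(mus[3], sds[3]))
    e <- runif(1, -1, 3)
    got <- predict_b_allele(dens, e)
    # brute force: interpolate each stored grid by hand and normalise
    f <- vapply(dens, function(d) {
      i <- findInterval(e, d$x)
      w <- (e - d$x[i]) / (d$x[i + 1] - d$x[i])
      (1 - w) * d$y[i] + w * d$y[i + 1]
    }, numeric(1))
    post <- f / sum(f)
    expect_equal(unname(got$posterior[1, ]), unname(post), tolerance = 1e-10)
    expect_equal(got$predicted, sum(post * 0:2), tolerance = 1e-10)
  }
})

test_that("prediction handles uninformative, decisive and two-class cases", {
  flat <- list(AA = gauss_density(1, 100), AB = gauss_density(1, 100),
               BB = gauss_density(1, 100))
  expect_equal(predict_b_allele(flat, 1)$predicted, 1, tolerance = 1e-6)

  sharp <- list(AA = gauss_density(0, 0.2), AB = gauss_density(1, 0.2),
                BB = gauss_density(2, 0.2))
  expect_lt(predict_b_allele(sharp, 0)$predicted, 0.01)

  two <- list(AA = gauss_density(0, 0.2), AB = NULL,
              BB = gauss_density(2, 0.2))
  expect_equal(predict_b_allele(two, 1)$predicted, 1, tolerance = 1e-8)

  expect_true(is.na(predict_b_allele(sharp, NA)$predicted))
})

test_that("scores follow the missing-rescaled sum of squared differences", {
  P <- matrix(c(0.1, 1.9), 2, 1, dimnames = list(NULL, "e1"))
  O <- matrix(c(0L, 2L), 2, 1, dimnames = list(NULL, "g1"))
  expect_equal(unname(badger_scores(P, O)$B[1, 1]), 0.02)

  # a perfectly matching column scores zero
  P2 <- cbind(e1 = c(0.5, 1.5, 1.0))
  O2 <- cbind(g1 = c(0.5, 1.5, 1.0), g2 = c(NA, NA, NA))
  B <- badger_scores(P2, O2)
  expect_equal(unname(B$B[1, "g1"]), 0)
  expect_true(is.na(B$B[1, "g2"]))   # all-missing column excluded

  # missing rescaling: one missing of three terms scales by 3/2
  P3 <- cbind(e1 = c(1, NA, 0))
  O3 <- cbind(g1 = c(0L, 1L, 1L))
  expect_equal(unname(badger_scores(P3, O3)$B[1, 1]), 3 / 2 * (1 + 1))
})

test_that("column permutations permute scores identically", {
  ch <- small_cohort(seed = 41)
  pairs <- scan_cis_associations(ch$expr, ch$geno, ch$map)
  set <- fit_densities(pairs, ch$expr, ch$geno, ch$map)
  P <- predict_matrix(set, ch$expr)
  O <- ch$geno$values[set$pairs$snp_id, , drop = FALSE]
  B1 <- badger_scores(P, O)$B
  perm <- sample(ncol(O))
  B2 <- badger_scores(P, O[, perm])$B
  expect_identical(B1[, perm], B2)
})

test_that("ranks are per-row, ties share the minimum rank", {
  B <- rbind(e1 = c(g1 = 0.5, g2 = 0.1, g3 = 0.9))
  expect_equal(unname(rank_matrix(B)[1, ]), c(2L, 1L, 3L))
  B2 <- rbind(e1 = c(g1 = 0.1, g2 = 0.1, g3 = 0.9))
  expect_equal(unname(rank_matrix(B2)[1, ]), c(1L, 1L, 3L))
})

test_that("the gap statistic respects the replicate parameter", {
  B <- rbind(e1 = c(0.1, 5.0, 6.0))
  colnames(B) <- paste0("g", 1:3)
  d1 <- delta_statistic(B, g = 1)
  expect_equal(d1$gap, 4.9)
  expect_equal(d1$min_score, 0.1)
  # a duplicated genotype array: measure to the third order statistic
  B2 <- rbind(e1 = c(0.1, 0.12, 6.0))
  colnames(B2) <- paste0("g", 1:3)
  expect_equal(delta_statistic(B2, g = 2)$gap, 5.9)
  expect_error(delta_statistic(B2, g = 3), "more genotype arrays")
})

test_that("an expression array without its genotype array is an outlier", {
  cfg <- cohort_config(n_samples = 48L, n_snps = 120L, n_probes = 100L,
                       seed = 42, error_spec = list(
                         list(type = "alien", platform = "genotype",
                              sample = "S010")))
  ch <- simulate_cohort(cfg)
  pairs <- scan_cis_associations(ch$expr, ch$geno, ch$map)
  set <- fit_densities(pairs, ch$expr, ch$geno, ch$map)
  P <- predict_matrix(set, ch$expr)
  O <- ch$geno$values[set$pairs$snp_id, , drop = FALSE]
  dl <- delta_statistic(badger_scores(P, O))
  orphan <- dl$min_score[dl$expression_array == "ES010"]
  others <- dl$min_score[dl$expression_array != "ES010"]
  expect_gt(orphan, quantile(others, 0.99))
})

test_that("discrepancy equals the mean squared prediction error", {
  # constant heterozygote prediction vs balanced genotypes: 1/4*1+1/2*0+1/4*1
  P <- matrix(1, 1, 4, dimnames = list(NULL, paste0("e", 1:4)))
  O <- matrix(c(0L, 1L, 1L, 2L), 1, 4,
              dimnames = list(NULL, paste0("g", 1:4)))
  sc <- badger_scores(P, O)
  matched <- data.frame(expression_array = paste0("e", 1:4),
                        genotype_array = paste0("g", 1:4))
  expect_equal(unname(eqtl_discrepancy(sc, matched)), 0.5)

  # perfect prediction: zero discrepancy
  sc2 <- badger_scores(matrix(as.numeric(O), 1, 4,
                              dimnames = dimnames(P)), O)
  expect_equal(unname(eqtl_discrepancy(sc2, matched)), 0)
})

test_that("null pairs show larger discrepancies than true eQTLs", {
  worse <- 0
  for (seed in 1:10) {
    cfg <- cohort_config(n_samples = 48L, n_snps = 150L, n_probes = 120L,
                         fraction_cis_eqtl = 0.25, fraction_intergenic = 0,
                         seed = 50 + seed)
    ch <- simulate_cohort(cfg)
    truth <- ch$eqtl_truth[, c("probe_id", "snp_id")]
    nulls <- data.frame(
      probe_id = setdiff(ch$expr$probe_annotation$probe_id,
                         truth$probe_id)[seq_len(nrow(truth))],
      snp_id = truth$snp_id)
    allp <- rbind(truth, nulls)
    set <- fit_densities(allp, ch$expr, ch$geno, ch$map)
    P <- predict_matrix(set, ch$expr)
    O <- ch$geno$values[set$pairs$snp_id, , drop = FALSE]
    d <- eqtl_discrepancy(badger_scores(P, O), ch$map)
    is_true <- seq_len(nrow(truth))
    worse <- worse + (median(d[-is_true]) > median(d[is_true]))
  }
  expect_gte(worse, 10 * 0.95)
})

test_that("refinement removes high-discrepancy pairs and rescoring is exact", {
  ch <- small_cohort(seed = 43)
  truth <- ch$eqtl_truth[, c("probe_id", "snp_id")]
  nulls <- data.frame(
    probe_id = setdiff(ch$expr$probe_annotation$probe_id,
                       truth$probe_id)[seq_len(nrow(truth))],
    snp_id = truth$snp_id)
  allp <- rbind(truth, nulls)
  set <- fit_densities(allp, ch$expr, ch$geno, ch$map)
  P <- predict_matrix(set, ch$expr)
  O <- ch$geno$values[set$pairs$snp_id, , drop = FALSE]
  sc <- badger_scores(P, O)
  d <- eqtl_discrepancy(sc, ch$map)

  # T = Inf keeps everything
  ref_inf <- refine_eqtl_set(set, d, cutoff = Inf)
  expect_true(all(ref_inf$keep))

  ref <- refine_eqtl_set(set, d)
  expect_true(is.finite(ref$cutoff))
  is_null <- c(rep(FALSE, nrow(truth)), rep(TRUE, nrow(nulls)))
  expect_gte(sum(!ref$keep & is_null) / sum(is_null), 0.9)
  expect_lte(sum(!ref$keep & !is_null) / sum(!is_null), 0.1)

  # rescoring equals scoring the retained set directly, exactly
  expect_identical(rescore(sc, ref$keep)$B,
                   badger_scores(P[ref$keep, ], O[ref$keep, ])$B)
  # removing one pair from a two-pair score matches direct recomputation
  sc2 <- badger_scores(P[1:2, ], O[1:2, ])
  expect_identical(rescore(sc2, 2)$B, badger_scores(P[2, , drop = FALSE],
                                                    O[2, , drop = FALSE])$B)
})

test_that("a mismatched pairing never scores better than the true pairing", {
  bad <- 0L; total <- 0L
  for (seed in 1:10) {
    ch <- simulate_cohort(cohort_config(
      n_samples = 48L, n_snps = 200L, n_probes = 200L,
      fraction_cis_eqtl = 0.3, seed = 60 + seed))
    pairs <- scan_cis_associations(ch$expr, ch$geno, ch$map)
    set <- fit_densities(pairs, ch$expr, ch$geno, ch$map)
    P <- predict_matrix(set, ch$expr)
    O <- ch$geno$values[set$pairs$snp_id, , drop = FALSE]
    B <- badger_scores(P, O)$B
    ip <- ch$map
    own <- B[cbind(ip$expression_array, ip$genotype_array)]
    for (j in seq_len(nrow(ip))) {
      others <- B[ip$expression_array[j],
                  setdiff(colnames(B), ip$genotype_array[j])]
      total <- total + sum(!is.na(others))
      bad <- bad + sum(others < own[j], na.rm = TRUE)
    }
  }
  expect_identical(bad, 0L)
})
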