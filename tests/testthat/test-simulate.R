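# the synthetic cohort generator: population structure, expression model,
# tumour distortion, planted errors and reproducibility

test_that("single undrifted group is Hardy-Weinberg at the ancestral MAF", {
  cfg <- cohort_config(n_samples = 400L, n_snps = 200L, n_probes = 20L,
                       maf_range = c(0.3, 0.3), seed = 10)
  pop <- simulate_population(cfg)
  freq <- rowMeans(pop$genotypes$values) / 2
  expect_lt(abs(mean(freq) - 0.3), 0.01)
  het <- rowMeans(pop$genotypes$values == 1L)
  expect_lt(abs(mean(het) - 2 * 0.3 * 0.7), 0.01)
})

test_that("group drift matches the Balding-Nichols Beta variance", {
  ps <- data.frame(group = c("g1", "g2"), proportion = c(0.5, 0.5),
                   divergence_f = 0.2, eqtl_active = TRUE,
                   stringsAsFactors = FALSE)
  cfg <- cohort_config(n_samples = 96L, n_snps = 4000L, n_probes = 20L,
                       maf_range = c(0.3, 0.3), population_spec = ps,
                       seed = 11)
  pop <- simulate_population(cfg)
  v <- mean((pop$group_freq - pop$ancestral_maf)^2)
  expect_lt(abs(v - 0.3 * 0.7 * 0.2), 0.005)   # p(1-p)F = 0.042
})

test_that("trio children obey Mendelian transmission", {
  cfg <- cohort_config(n_samples = 24L, n_snps = 150L, n_probes = 20L,
                       relatives_spec = list(n_trios = 2L), seed = 12)
  pop <- simulate_population(cfg)
  g <- pop$genotypes$values
  for (child in c(24L, 21L)) {
    fa <- g[, child - 2L]; mo <- g[, child - 1L]; kid <- g[, child]
    # child allele count bounded by what the parents can transmit
    lo <- (fa == 2) + (mo == 2)
    hi <- 2 - ((fa == 0) + (mo == 0))
    expect_true(all(kid >= lo & kid <= hi))
    # opposing homozygote parents force a heterozygous child
    forced <- (fa == 0 & mo == 2) | (fa == 2 & mo == 0)
    expect_true(all(kid[forced] == 1L))
  }
})

test_that("noiseless expression equals baseline plus the allele-count effect", {
  cfg <- cohort_config(n_samples = 24L, n_snps = 60L, n_probes = 40L,
                       noise_sd = 1e-12, effect_size = 1, seed = 13)
  pop <- simulate_population(cfg)
  ex <- simulate_expression(pop, cfg)
  p1 <- ex$eqtl_truth$probe_id[1]; s1 <- ex$eqtl_truth$snp_id[1]
  e <- ex$expression$values[p1, ]
  b <- pop$genotypes$values[s1, ]
  expect_equal(unname(e - min(e[b == 0])), unname(as.numeric(b)),
               tolerance = 1e-6)
})

test_that("groups with inactive eQTLs show no genotype effect", {
  ps <- data.frame(group = c("act", "nul"), proportion = c(0.5, 0.5),
                   divergence_f = 0, eqtl_active = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  cfg <- cohort_config(n_samples = 200L, n_snps = 60L, n_probes = 40L,
                       population_spec = ps, seed = 14)
  pop <- simulate_population(cfg)
  ex <- simulate_expression(pop, cfg)
  p1 <- ex$eqtl_truth$probe_id[1]; s1 <- ex$eqtl_truth$snp_id[1]
  sl <- function(idx) coef(lm(ex$expression$values[p1, idx] ~
                                pop$genotypes$values[s1, idx]))[2]
  expect_lt(abs(sl(pop$groups == "nul")), 0.2)
  expect_gt(sl(pop$groups == "act"), 0.8)
})

test_that("least squares recovers the simulated effect size", {
  cfg <- cohort_config(n_samples = 96L, seed = 15)
  pop <- simulate_population(cfg)
  ex <- simulate_expression(pop, cfg)
  slopes <- vapply(seq_len(nrow(ex$eqtl_truth)), function(i) {
    fit <- lm(ex$expression$values[ex$eqtl_truth$probe_id[i], ] ~
                pop$genotypes$values[ex$eqtl_truth$snp_id[i], ])
    coef(fit)[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.05)
  expect_lt(max(abs(slopes - 1)), 3 * 0.3 / sqrt(96 * 0.3))  # ~3 s.e.
})

test_that("tumour distortion collapses heterozygotes at loh_rate x cellularity", {
  cfg <- cohort_config(seed = 16, n_probes = 20L)
  pop <- simulate_population(cfg)
  g <- pop$genotypes$values

  expect_identical(apply_tumour_distortion(g, 0, 0.8), g)

  full <- apply_tumour_distortion(g, 1, 1)
  expect_equal(sum(full == 1L, na.rm = TRUE), 0)
  expect_identical(full[g != 1L], g[g != 1L])

  set.seed(99)
  part <- apply_tumour_distortion(g, 0.5, 0.6)
  het <- sum(g == 1L)
  collapsed <- sum(g == 1L & part != 1L)
  expect_lt(abs(collapsed / het - 0.30), 3 * sqrt(0.3 * 0.7 / het))
})

test_that("planted swap and empty error specs behave as documented", {
  ch0 <- small_cohort(seed = 17)
  inj <- inject_errors(ch0$map, list())
  expect_length(inj$truth, 0)
  expect_true(maps_agree(inj$map, ch0$map))

  inj <- inject_errors(ch0$map, list(list(type = "swap",
                                          platform = "genotype")))
  expect_length(inj$truth, 1)
  tr <- inj$truth[[1]]
  expect_equal(tr$type, "swap")
  expect_length(tr$samples, 2)
  # the inverse correction restores a consistent one-to-one assignment
  fixed <- apply_corrections(inj$map, inj$truth)
  ta <- inj$true_assignment
  for (i in seq_len(nrow(fixed))) {
    g <- fixed$genotype_array[i]
    if (is.na(g)) next
    expect_equal(ta$sample_id[ta$platform == "genotype" & ta$array_id == g],
                 fixed$sample_id[i])
  }
})

test_that("slippage produces shifted matches and orphans at both ends", {
  cfg <- cohort_config(n_samples = 48L, n_snps = 200L, n_probes = 200L,
                       fraction_cis_eqtl = 0.3,
                       seed = 18, error_spec = list(
                         list(type = "slippage", platform = "genotype",
                              start = 10, length = 6)))
  ch <- simulate_cohort(cfg)
  tr <- ch$truth[[1]]
  expect_equal(tr$type, "chain/slippage")
  expect_length(tr$samples, 6)
  # first array holds an alien individual; last sample was never genotyped
  expect_length(tr$alien_arrays, 1)
  na_row <- tr$new_assignment[is.na(tr$new_assignment$array), ]
  expect_equal(na_row$sample_id, tr$samples[6])
  ta <- ch$true_assignment
  alien <- ta$sample_id[ta$array_id == tr$alien_arrays]
  expect_match(alien, "^X")
  # remaining samples shifted by exactly one position
  shifted <- tr$new_assignment[!is.na(tr$new_assignment$array), ]
  expect_equal(shifted$array, tr$arrays[2:6])
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- small_cohort(seed = 19)
  b <- small_cohort(seed = 19)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$geno$values, b$geno$values)
  expect_identical(as.data.frame(a$map), as.data.frame(b$map))
  c2 <- small_cohort(seed = 20)
  expect_false(identical(a$expr$values, c2$expr$values))
})
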