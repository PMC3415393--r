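# Synthetic cohort generator: matched expression/genotype data with the
# statistical structure the scoring engine assumes, plus planted plating
# errors, tumour genotype distortion, population structure and trios.

#' Configuration for the synthetic cohort simulator
#'
#' Defaults describe a 96-sample study (one full 8 x 12 genotyping plate,
#' eight 12-array expression BeadChips) with strong cis-eQTLs: an additive
#' shift of one log2 unit per B allele over residual noise of 0.3 log2 units,
#' and common variants (MAF 0.2--0.5).
#'
#' @param n_samples study samples (each intended on one expression and one
#'   genotype array).
#' @param n_pilot additional trusted samples (an error-free internal pilot)
#'   used to train eQTL densities; 0 disables the pilot.
#' @param n_snps,n_probes numbers of SNPs and expression probes.
#' @param fraction_cis_eqtl proportion of probes carrying a true cis-eQTL.
#' @param effect_size mean expression shift per B allele (log2 units).
#' @param noise_sd residual log2-expression standard deviation.
#' @param maf_range range of ancestral minor-allele frequencies.
#' @param fraction_snp_under_probe fraction of true-eQTL probes annotated
#'   with SNPs under the probe sequence (cis-eQTL artefact analogues).
#' @param population_spec data.frame with columns `group`, `proportion`,
#'   `divergence_f` (Balding-Nichols drift parameter) and `eqtl_active`
#'   (logical; FALSE makes all eQTL effects zero within that group,
#'   emulating population-specific eQTL nulls).
#' @param tumour_spec list with `loh_rate` (per-SNP probability scale for
#'   heterozygous calls collapsing to homozygous on a tumour genotype array)
#'   and `cellularity_shape` (Beta shape parameters for per-sample tumour
#'   cellularity).
#' @param relatives_spec list with `n_trios` parent-parent-child trios placed
#'   at the end of the study samples.
#' @param error_spec list of planted plating errors; see [inject_errors()].
#' @param baseline_range range of per-probe baseline log2 intensities for
#'   expressed probes.
#' @param intergenic_baseline baseline for intergenic (expected-silent) probes.
#' @param fraction_intergenic fraction of probes annotated intergenic.
#' @param seed integer seed; mandatory, all generation flows from it.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 96L,
                          n_pilot = 0L,
                          n_snps = 300L,
                          n_probes = 240L,
                          fraction_cis_eqtl = 0.25,
                          effect_size = 1.0,
                          noise_sd = 0.3,
                          maf_range = c(0.2, 0.5),
                          fraction_snp_under_probe = 0.5,
                          population_spec = data.frame(
                            group = "pop1", proportion = 1,
                            divergence_f = 0, eqtl_active = TRUE,
                            stringsAsFactors = FALSE),
                          tumour_spec = list(loh_rate = 0.3,
                                             cellularity_shape = c(5, 2)),
                          relatives_spec = list(n_trios = 0L),
                          error_spec = list(),
                          baseline_range = c(7, 10),
                          intergenic_baseline = 5.5,
                          fraction_intergenic = 0.15,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (abs(sum(population_spec$proportion) - 1) > 1e-8)
    stop("population proportions must sum to 1")
  rates <- c(fraction_cis_eqtl, fraction_snp_under_probe, fraction_intergenic,
             tumour_spec$loh_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  n_eqtl <- round(fraction_cis_eqtl * n_probes)
  if (n_eqtl > n_snps) stop("need at least one SNP per true eQTL probe")
  structure(list(
    n_samples = as.integer(n_samples), n_pilot = as.integer(n_pilot),
    n_snps = as.integer(n_snps), n_probes = as.integer(n_probes),
    fraction_cis_eqtl = fraction_cis_eqtl, effect_size = effect_size,
    noise_sd = noise_sd, maf_range = maf_range,
    fraction_snp_under_probe = fraction_snp_under_probe,
    population_spec = population_spec, tumour_spec = tumour_spec,
    relatives_spec = relatives_spec, error_spec = error_spec,
    baseline_range = baseline_range,
    intergenic_baseline = intergenic_baseline,
    fraction_intergenic = fraction_intergenic,
    seed = as.integer(seed)), class = "cohort_config")
}

n_individuals <- function(config) {
  config$n_samples + config$n_pilot
}

#' Simulate individual-level genotypes with population structure
#'
#' Ancestral minor-allele frequencies are drawn uniformly from `maf_range`;
#' each population group's frequencies drift from the ancestral value under a
#' Balding-Nichols Beta model with drift parameter F, i.e.
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean p, variance p(1-p)F).  Genotypes are
#' Hardy-Weinberg within group.  Trios obey Mendelian transmission: the last
#' `3 * n_trios` study individuals form father/mother/child triples.
#'
#' Sets the RNG state from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param n_extra number of additional (alien) individuals to simulate beyond
#'   study + pilot; used internally to materialise planted alien samples.
#' @return list with `genotypes` (a [genotype_matrix()] whose columns are
#'   individuals, not arrays), `groups` (character vector per individual),
#'   `ancestral_maf` and `group_freq` (SNP x group matrix).
#' @export
simulate_population <- function(config, n_extra = 0L) {
  set.seed(config$seed)
  ps <- config$population_spec
  n_ind <- n_individuals(config) + n_extra
  n_snps <- config$n_snps

  counts <- floor(ps$proportion * n_ind)
  rem <- n_ind - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  groups <- sample(rep(ps$group, counts))

  p <- stats::runif(n_snps, config$maf_range[1], config$maf_range[2])
  group_freq <- sapply(seq_len(nrow(ps)), function(g) {
    f <- ps$divergence_f[g]
    if (f <= 0) p
    else stats::rbeta(n_snps, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  })
  colnames(group_freq) <- ps$group

  gmat <- matrix(NA_integer_, n_snps, n_ind)
  for (g in ps$group) {
    idx <- which(groups == g)
    if (!length(idx)) next
    gmat[, idx] <- stats::rbinom(n_snps * length(idx), 2L,
                                 rep(group_freq[, g], length(idx)))
  }

  # trios occupy the tail of the study samples: father, mother, child
  n_trios <- config$relatives_spec$n_trios %||% 0L
  if (n_trios > 0) {
    if (3L * n_trios > config$n_samples)
      stop("too many trios for n_samples")
    for (t in seq_len(n_trios)) {
      child <- config$n_samples - 3L * (t - 1L)
      fa <- child - 2L; mo <- child - 1L
      pass <- function(par) stats::rbinom(n_snps, 1L, gmat[, par] / 2)
      gmat[, child] <- pass(fa) + pass(mo)
    }
  }

  ids <- c(sprintf("S%03d", seq_len(config$n_samples)),
           if (config$n_pilot > 0) sprintf("P%03d", seq_len(config$n_pilot)),
           if (n_extra > 0) sprintf("X%03d", seq_len(n_extra)))
  colnames(gmat) <- ids
  snp_ann <- data.frame(
    snp_id = sprintf("rs%04d", seq_len(n_snps)),
    chromosome = "1",
    position = 2e6 * seq_len(n_snps) + 1000,
    stringsAsFactors = FALSE)
  rownames(gmat) <- snp_ann$snp_id
  list(genotypes = genotype_matrix(gmat, snp_ann), groups = groups,
       ancestral_maf = p, group_freq = group_freq)
}

#' Simulate individual-level expression driven by cis-eQTLs
#'
#' The first `round(fraction_cis_eqtl * n_probes)` probes each carry a true
#' eQTL on the SNP sharing their genomic locus (the paired SNP sits 1 kb from
#' the probe; unrelated loci are 2 Mb apart, outside the scan window).  For
#' these probes `e = baseline + effect_size * B + N(0, noise_sd)`, with the
#' effect zeroed in groups whose `eqtl_active` flag is FALSE.  All other
#' probes are pure noise around their baseline; probes annotated intergenic
#' sit at a low background baseline.
#'
#' Uses the current RNG state offset from `config$seed` (seed + 1).
#'
#' @param pop result of [simulate_population()].
#' @param config a [cohort_config()].
#' @return list with `expression` (an [expression_matrix()] whose columns are
#'   individuals) and `eqtl_truth` (data.frame of true probe/SNP pairs).
#' @export
simulate_expression <- function(pop, config) {
  set.seed(config$seed + 1L)
  gmat <- pop$genotypes$values
  n_ind <- ncol(gmat)
  n_probes <- config$n_probes
  n_eqtl <- round(config$fraction_cis_eqtl * n_probes)
  n_inter <- round(config$fraction_intergenic * n_probes)
  if (n_eqtl + n_inter > n_probes)
    stop("fraction_cis_eqtl + fraction_intergenic exceed 1")

  tier <- rep("perfect", n_probes)
  if (n_inter > 0)
    tier[(n_probes - n_inter + 1L):n_probes] <- "intergenic"
  # sprinkle a few 'good'/'other' probes among the non-eQTL expressed ones
  mid <- setdiff(which(tier == "perfect"), seq_len(n_eqtl))
  if (length(mid) >= 4) {
    tier[mid[seq_len(min(4, length(mid)))]] <- rep(c("good", "other"), 2)
  }

  n_under <- integer(n_probes)
  if (n_eqtl > 0) {
    with_snp <- which(stats::runif(n_eqtl) < config$fraction_snp_under_probe)
    n_under[with_snp] <- sample(1:3, length(with_snp), replace = TRUE)
  }

  baseline <- stats::runif(n_probes, config$baseline_range[1],
                           config$baseline_range[2])
  baseline[tier == "intergenic"] <- config$intergenic_baseline

  active <- stats::setNames(config$population_spec$eqtl_active,
                            config$population_spec$group)
  eff <- config$effect_size * as.numeric(active[pop$groups])  # per individual

  emat <- matrix(stats::rnorm(n_probes * n_ind, 0, config$noise_sd),
                 n_probes, n_ind) + baseline
  if (n_eqtl > 0) {
    b <- gmat[seq_len(n_eqtl), , drop = FALSE]        # eQTL i pairs SNP i
    b[is.na(b)] <- 1L
    emat[seq_len(n_eqtl), ] <- emat[seq_len(n_eqtl), ] +
      b * rep(eff, each = n_eqtl)
  }
  colnames(emat) <- colnames(gmat)
  probe_ann <- data.frame(
    probe_id = sprintf("ILMN_%04d", seq_len(n_probes)),
    chromosome = "1",
    position = 2e6 * seq_len(n_probes),
    quality_tier = tier,
    n_snps_under_probe = n_under,
    stringsAsFactors = FALSE)
  rownames(emat) <- probe_ann$probe_id
  eqtl_truth <- data.frame(
    probe_id = probe_ann$probe_id[seq_len(n_eqtl)],
    snp_id = pop$genotypes$snp_annotation$snp_id[seq_len(n_eqtl)],
    effect = config$effect_size,
    stringsAsFactors = FALSE)
  list(expression = expression_matrix(emat, probe_ann),
       eqtl_truth = eqtl_truth)
}

#' Collapse heterozygous calls as in a tumour genotype array
#'
#' Each heterozygous call collapses to 0 or 2 (equally likely) with
#' probability `loh_rate * cellularity`: a pure tumour (cellularity 1)
#' expresses its loss-of-heterozygosity fully, while stromal contamination
#' (low cellularity) rescues heterozygous calls.  Homozygous and missing
#' calls are unchanged.
#'
#' @param geno a [genotype_matrix()] (or plain matrix) of diploid germline
#'   calls; columns are arrays/individuals.
#' @param loh_rate per-SNP probability scale in `[0, 1]`.
#' @param cellularity scalar or per-column vector of tumour cell fractions
#'   in `[0, 1]`.
#' @return object of the same shape with collapsed calls.
#' @export
apply_tumour_distortion <- function(geno, loh_rate, cellularity) {
  is_gm <- inherits(geno, "genotype_matrix")
  vals <- if (is_gm) geno$values else as.matrix(geno)
  if (loh_rate < 0 || loh_rate > 1 || any(cellularity < 0 | cellularity > 1))
    stop("loh_rate and cellularity must lie in [0, 1]")
  cellularity <- rep_len(cellularity, ncol(vals))
  het <- which(!is.na(vals) & vals == 1L)
  if (length(het)) {
    colv <- ((het - 1L) %/% nrow(vals)) + 1L
    p <- loh_rate * cellularity[colv]
    hit <- stats::runif(length(het)) < p
    vals[het[hit]] <- 2L * stats::rbinom(sum(hit), 1L, 0.5)
  }
  if (is_gm) genotype_matrix(vals, geno$snp_annotation) else vals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- layout / provenance construction --------------------------------------

# a random processing order for the expression platform under the
# constraint that no two consecutive samples are also neighbours in the
# genotype plate order (consecutive wells, or the same row of adjacent
# columns): diverging the two layouts is what makes a plating error
# attributable to one platform
scatter_order <- function(n) {
  if (n < 5) return(seq_len(n))
  for (attempt in 1:5000) {
    ord <- sample.int(n)
    dd <- abs(diff(ord))
    if (!any(dd == 1L | dd == 8L)) return(ord)
  }
  stop("could not scatter the expression order")
}

# genotype plates are filled column-major (A1, B1, ... H1, A2, ...);
# expression BeadChips hold 12 arrays each, filled in a scattered order
build_provenance <- function(map, n_study, n_pilot) {
  n <- n_study
  ord <- scatter_order(n)                   # ord[t] = sample index at position t
  gpos <- seq_len(n)
  epos_of_sample <- order(ord)

  prov_one <- function(sample_ids, platform, pos, plate_size, plate_prefix,
                       well_fun, offset_plate = 0L) {
    plate <- (pos - 1L) %/% plate_size + 1L + offset_plate
    within <- (pos - 1L) %% plate_size + 1L
    data.frame(sample_id = sample_ids, platform = platform,
               stage = "hybridization", stage_index = 1L,
               plate_id = paste0(plate_prefix, plate),
               well = well_fun(within), position = pos,
               stringsAsFactors = FALSE)
  }
  geno_well <- function(w) rc_to_well((w - 1L) %% 8L + 1L, (w - 1L) %/% 8L + 1L)
  expr_well <- function(w) paste0("A", w)

  study <- map$sample_id[seq_len(n)]
  prov <- rbind(
    prov_one(study, "genotype", gpos, 96L, "DNAP", geno_well),
    prov_one(study[order(epos_of_sample)], "expression", sort(epos_of_sample),
             12L, "RNAC", function(w) expr_well((w - 1L) %% 12L + 1L)))
  # BeadChip position within chip: recompute well from within-chip index
  ei <- prov$platform == "expression"
  within_chip <- (prov$position[ei] - 1L) %% 12L + 1L
  prov$well[ei] <- expr_well(within_chip)

  if (n_pilot > 0) {
    pil <- map$sample_id[n + seq_len(n_pilot)]
    n_gplates <- ceiling(n / 96)
    n_echips <- ceiling(n / 12)
    prov <- rbind(prov,
      prov_one(pil, "genotype", seq_len(n_pilot), 96L, "DNAP", geno_well,
               offset_plate = n_gplates),
      prov_one(pil, "expression", seq_len(n_pilot), 12L, "RNAC",
               function(w) expr_well((w - 1L) %% 12L + 1L),
               offset_plate = n_echips))
    # pilot positions continue the platform sequences
    pi_g <- prov$platform == "genotype" & prov$sample_id %in% pil
    prov$position[pi_g] <- prov$position[pi_g] + n
    pi_e <- prov$platform == "expression" & prov$sample_id %in% pil
    prov$position[pi_e] <- prov$position[pi_e] + n
  }
  prov
}

# plate_layout objects for the genotype plates (sex pattern included)
cohort_layouts <- function(map) {
  prov <- attr(map, "provenance")
  gp <- prov[prov$platform == "genotype", , drop = FALSE]
  sex_of <- stats::setNames(map$sex, map$sample_id)
  lapply(split(gp, gp$plate_id), function(d) {
    lay <- plate_layout(plate_id = d$plate_id[1])
    rc <- well_to_rc(d$well)
    lay$samples[cbind(rc[, 1], rc[, 2])] <- d$sample_id
    lay$sex[cbind(rc[, 1], rc[, 2])] <- sex_of[d$sample_id]
    lay
  })
}

# ---- planted errors --------------------------------------------------------

#' Plant plating errors into a sample map
#'
#' Takes the intended (recorded) map and an error specification and returns
#' the *true* array-to-sample assignment implied by the planted errors,
#' together with the exact inverse corrections (the ground truth).  The
#' recorded map itself is what the laboratory believes and is returned
#' unchanged (except that planted replicate arrays add recorded rows).
#'
#' Supported error types (each a list with a `type` field):
#' \describe{
#'   \item{swap}{`platform`, and either `samples` (two ids) or nothing, in
#'     which case a random pair of processing neighbours is chosen.}
#'   \item{cycle}{`platform`, `k`: contents of `k` consecutive arrays in the
#'     platform sequence rotate by one.}
#'   \item{slippage}{`platform`, `start` (position in the platform sequence),
#'     `length`: the sample sequence slips by one position over the run, as
#'     when a row of tubes is offset by one.  The first array receives an
#'     alien sample (one never meant to be run) and the last sample in the
#'     run is never assayed on that platform.}
#'   \item{plate_rotation}{`platform`, `plate_id`: the plate was rotated 180
#'     degrees when loaded.}
#'   \item{plate_swap}{`platform`, `plates` (two ids): the two plates'
#'     contents are exchanged well-for-well.}
#'   \item{duplicate}{`sample`: an extra genotype array replicating that
#'     sample (a recorded replicate, not an error; it feeds the replicate
#'     parameter g of the gap statistic).}
#'   \item{alien}{`platform`, `sample`: the array recorded for `sample`
#'     actually carries an alien individual.}
#'   \item{empty}{`platform`, `sample`: the array recorded for `sample` is
#'     physically empty.}
#' }
#'
#' Sample-level errors must touch disjoint samples; plate-level transforms
#' must not overlap sample-level errors on the same platform.
#'
#' @param map a [sample_map()] with provenance.
#' @param error_spec list of error descriptors.
#' @param alien_pool character vector of individual ids available to play
#'   alien samples.
#' @return list with `map` (recorded map, possibly with added replicate
#'   rows), `true_assignment` (data.frame `platform`, `array_id`,
#'   `sample_id`; `NA` sample = empty array), and `truth` (list of inverse
#'   corrections in the same shape produced by the resolver).
#' @export
inject_errors <- function(map, error_spec, alien_pool = character()) {
  prov <- attr(map, "provenance")
  if (is.null(prov) && length(error_spec))
    stop("error injection requires plate provenance")
  arr_col <- c(expression = "expression_array", genotype = "genotype_array")
  array_of <- function(s, platform)
    map[[arr_col[[platform]]]][match(s, map$sample_id)]

  # true_of[[platform]][array] = sample actually on the array
  true_of <- list()
  for (pf in c("expression", "genotype")) {
    a <- map[[arr_col[[pf]]]]
    keep <- !is.na(a)
    true_of[[pf]] <- stats::setNames(map$sample_id[keep], a[keep])
  }

  # sample-level errors claim samples across both platforms so composed
  # errors stay attributable; plate-level transforms only exclude other
  # errors on their own platform
  touched <- character()
  touched_pf <- list(expression = character(), genotype = character())
  plate_touched <- list(expression = character(), genotype = character())
  claim <- function(platform, samples) {
    if (any(samples %in% touched))
      stop("planted errors overlap")
    touched <<- c(touched, samples)
    touched_pf[[platform]] <<- c(touched_pf[[platform]], samples)
  }

  seq_of <- function(platform) {
    d <- prov[prov$platform == platform & !prov$sample_id %in%
                map$sample_id[map$trusted], , drop = FALSE]
    d[order(d$position), , drop = FALSE]
  }
  neighbour_pairs <- function(platform) {
    d <- seq_of(platform)
    out <- list()
    for (i in seq_len(nrow(d) - 1L)) {
      if (d$plate_id[i] != d$plate_id[i + 1L]) next
      if (platform == "genotype") {
        rc <- well_to_rc(c(d$well[i], d$well[i + 1L]))
        if (sum(abs(rc[1, ] - rc[2, ])) != 1L) next
      }
      out[[length(out) + 1L]] <- c(d$sample_id[i], d$sample_id[i + 1L])
    }
    out
  }

  truth <- list()
  extra_rows <- NULL
  aliens_used <- 0L
  next_alien <- function() {
    aliens_used <<- aliens_used + 1L
    if (aliens_used > length(alien_pool))
      stop("alien_pool too small for the requested errors")
    alien_pool[aliens_used]
  }

  for (err in error_spec) {
    type <- err$type
    pf <- err$platform %||% "genotype"
    if (type == "swap") {
      if (!is.null(err$samples)) ss <- err$samples
      else {
        cand <- Filter(function(p) !any(p %in% touched),
                       neighbour_pairs(pf))
        if (!length(cand)) stop("no free neighbour pair left for a swap")
        ss <- cand[[sample.int(length(cand), 1L)]]
      }
      claim(pf, ss)
      a <- array_of(ss, pf)
      true_of[[pf]][a] <- rev(ss)
      truth[[length(truth) + 1L]] <- list(
        type = "swap", platform = pf, samples = ss, arrays = a,
        new_assignment = data.frame(sample_id = ss, platform = pf,
                                    array = rev(a), stringsAsFactors = FALSE),
        alien_arrays = character())
    } else if (type == "cycle") {
      k <- err$k
      d <- seq_of(pf)
      free <- !(d$sample_id %in% touched)
      runs <- rle(free)
      start <- NULL
      at <- cumsum(c(0L, runs$lengths))
      for (r in seq_along(runs$lengths))
        if (runs$values[r] && runs$lengths[r] >= k) { start <- at[r] + 1L; break }
      if (is.null(start)) stop("no free run long enough for the cycle")
      ss <- d$sample_id[start:(start + k - 1L)]
      claim(pf, ss)
      a <- array_of(ss, pf)
      # content rotates: array of sample t+1 holds sample t
      true_of[[pf]][a] <- ss[c(k, seq_len(k - 1L))]
      truth[[length(truth) + 1L]] <- list(
        type = "cycle", platform = pf, samples = ss, arrays = a,
        new_assignment = data.frame(
          sample_id = ss, platform = pf,
          array = a[c(2:k, 1L)], stringsAsFactors = FALSE),
        alien_arrays = character())
    } else if (type == "slippage") {
      d <- seq_of(pf)
      L <- err$length
      start <- err$start %||% NA
      if (is.na(start)) {
        free <- !(d$sample_id %in% touched)
        runs <- rle(free); at <- cumsum(c(0L, runs$lengths)); start <- NULL
        for (r in seq_along(runs$lengths))
          if (runs$values[r] && runs$lengths[r] >= L) { start <- at[r] + 1L; break }
        if (is.null(start)) stop("no free run long enough for slippage")
      }
      ss <- d$sample_id[start:(start + L - 1L)]
      claim(pf, ss)
      a <- array_of(ss, pf)
      alien <- next_alien()
      true_of[[pf]][a] <- c(alien, ss[seq_len(L - 1L)])
      truth[[length(truth) + 1L]] <- list(
        type = "chain/slippage", platform = pf, samples = ss, arrays = a,
        new_assignment = data.frame(
          sample_id = ss, platform = pf,
          array = c(a[-1L], NA_character_), stringsAsFactors = FALSE),
        alien_arrays = a[1L])
    } else if (type %in% c("plate_rotation", "plate_swap")) {
      pd <- prov[prov$platform == pf, , drop = FALSE]
      if (type == "plate_rotation") {
        plates <- err$plate_id
        d <- pd[pd$plate_id == plates, , drop = FALSE]
        if (any(d$sample_id %in% touched_pf[[pf]]))
          stop("plate transform overlaps sample-level errors")
        plate_touched <- c(plate_touched, plates)
        rc <- well_to_rc(d$well)
        # 180-degree rotation of the full 8 x 12 grid
        rot <- rc_to_well(PLATE_NROW + 1L - rc[, 1], PLATE_NCOL + 1L - rc[, 2])
        partner <- d$sample_id[match(rot, d$well)]
        if (anyNA(partner))
          stop("plate rotation needs rotation-symmetric occupancy")
        a <- array_of(d$sample_id, pf)
        true_of[[pf]][a] <- partner
        truth[[length(truth) + 1L]] <- list(
          type = "plate_transform", platform = pf, transform = "rotate180",
          plate_id = plates, samples = d$sample_id, arrays = a,
          new_assignment = data.frame(
            sample_id = d$sample_id, platform = pf,
            array = array_of(partner, pf), stringsAsFactors = FALSE),
          alien_arrays = character())
      } else {
        pl <- err$plates
        d1 <- pd[pd$plate_id == pl[1], , drop = FALSE]
        d2 <- pd[pd$plate_id == pl[2], , drop = FALSE]
        if (any(c(d1$sample_id, d2$sample_id) %in% touched_pf[[pf]]))
          stop("plate transform overlaps sample-level errors")
        plate_touched <- c(plate_touched, pl)
        m2 <- match(d1$well, d2$well)
        if (anyNA(m2) || nrow(d1) != nrow(d2))
          stop("plate swap needs identical occupancy patterns")
        s1 <- d1$sample_id; s2 <- d2$sample_id[m2]
        a1 <- array_of(s1, pf); a2 <- array_of(s2, pf)
        true_of[[pf]][a1] <- s2; true_of[[pf]][a2] <- s1
        truth[[length(truth) + 1L]] <- list(
          type = "plate_transform", platform = pf, transform = "plate_swap",
          plate_id = pl, samples = c(s1, s2), arrays = c(a1, a2),
          new_assignment = data.frame(
            sample_id = c(s1, s2), platform = pf, array = c(a2, a1),
            stringsAsFactors = FALSE),
          alien_arrays = character())
      }
    } else if (type == "derangement") {
      # switch a large fraction of samples at once: n samples are paired off
      # at random and each pair's arrays exchanged (disjoint transpositions,
      # a fixed-point-free permutation), the stress analogue of simulating
      # many simultaneous sample switches
      d <- seq_of(pf)
      free <- d$sample_id[!(d$sample_id %in% touched)]
      n2 <- 2L * (err$n %/% 2L)
      if (length(free) < n2) stop("not enough free samples to derange")
      ss <- sample(free, n2)
      claim(pf, ss)
      for (j in seq_len(n2 / 2L)) {
        pr2 <- ss[c(2L * j - 1L, 2L * j)]
        a <- array_of(pr2, pf)
        true_of[[pf]][a] <- rev(pr2)
        truth[[length(truth) + 1L]] <- list(
          type = "swap", platform = pf, samples = pr2, arrays = a,
          new_assignment = data.frame(sample_id = pr2, platform = pf,
                                      array = rev(a),
                                      stringsAsFactors = FALSE),
          alien_arrays = character())
      }
    } else if (type == "duplicate") {
      s <- err$sample
      new_id <- paste0(array_of(s, "genotype"), "dup")
      row <- map[match(s, map$sample_id), , drop = FALSE]
      row$genotype_array <- new_id
      row$expression_array <- NA_character_
      extra_rows <- rbind(extra_rows, row)
      true_of$genotype[new_id] <- s
    } else if (type == "alien") {
      s <- err$sample
      claim(pf, s)
      a <- array_of(s, pf)
      alien <- next_alien()
      true_of[[pf]][a] <- alien
      truth[[length(truth) + 1L]] <- list(
        type = "alien", platform = pf, samples = s, arrays = a,
        new_assignment = data.frame(sample_id = s, platform = pf,
                                    array = NA_character_,
                                    stringsAsFactors = FALSE),
        alien_arrays = a)
    } else if (type == "empty") {
      s <- err$sample
      claim(pf, s)
      a <- array_of(s, pf)
      true_of[[pf]][a] <- NA_character_
      truth[[length(truth) + 1L]] <- list(
        type = "empty", platform = pf, samples = s, arrays = a,
        new_assignment = data.frame(sample_id = s, platform = pf,
                                    array = NA_character_,
                                    stringsAsFactors = FALSE),
        alien_arrays = character())
    } else stop("unknown error type: ", type)
  }

  out_map <- map
  if (!is.null(extra_rows)) {
    out_map <- sample_map(rbind(as.data.frame(map), extra_rows),
                          provenance = prov)
  }
  ta <- rbind(
    data.frame(platform = "expression", array_id = names(true_of$expression),
               sample_id = unname(true_of$expression),
               stringsAsFactors = FALSE),
    data.frame(platform = "genotype", array_id = names(true_of$genotype),
               sample_id = unname(true_of$genotype),
               stringsAsFactors = FALSE))
  list(map = out_map, true_assignment = ta, truth = truth)
}

#' Apply a list of corrections to a sample map
#'
#' Each correction carries a `new_assignment` data.frame (`sample_id`,
#' `platform`, `array`); rows overwrite the map's array columns.  Arrays
#' listed in `alien_arrays` end up assigned to no sample.
#'
#' @param map a [sample_map()].
#' @param corrections list of correction records (see [inject_errors()] and
#'   [attribute_and_apply()]).
#' @return corrected [sample_map()].
#' @export
apply_corrections <- function(map, corrections) {
  arr_col <- c(expression = "expression_array", genotype = "genotype_array")
  for (cr in corrections) {
    na <- cr$new_assignment
    if (is.null(na)) next
    for (i in seq_len(nrow(na))) {
      col <- arr_col[[na$platform[i]]]
      map[[col]][map$sample_id == na$sample_id[i]] <- na$array[i]
    }
  }
  map
}

#' Compare two sample maps on their array assignments
#'
#' @param a,b [sample_map()] objects over the same samples.
#' @return TRUE iff every sample has identical expression and genotype array
#'   assignments in both maps (`NA` matches `NA`).
#' @export
maps_agree <- function(a, b) {
  ids <- union(a$sample_id, b$sample_id)
  same <- function(x, y) (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y)
  ia <- match(ids, a$sample_id); ib <- match(ids, b$sample_id)
  all(same(a$expression_array[ia], b$expression_array[ib])) &&
    all(same(a$genotype_array[ia], b$genotype_array[ib]))
}

# ---- full cohort -----------------------------------------------------------

#' Simulate a full matched cohort with planted errors
#'
#' Generates individual-level genotypes and expression, lays samples out on
#' genotyping plates (column-major) and expression BeadChips (in a strided
#' order, so that platform neighbourhoods differ and plating errors are
#' attributable), plants the configured errors, and materialises per-array
#' data from the *true* array contents.  Pilot samples (if any) are trusted,
#' error-free, and occupy their own plates.
#'
#' @param config a [cohort_config()].
#' @return list of class `"badger_cohort"`: `expr`, `geno` (array-level
#'   matrices), `map` (the recorded map), `truth` (ground-truth corrections),
#'   `true_assignment`, `true_map` (the map after applying the truth),
#'   `groups`, `eqtl_truth`, `layouts`, `config`.
#' @export
simulate_cohort <- function(config) {
  n_slip_alien <- sum(vapply(config$error_spec, function(e)
    e$type %in% c("slippage", "alien"), logical(1)))
  pop <- simulate_population(config, n_extra = n_slip_alien)
  ex <- simulate_expression(pop, config)

  set.seed(config$seed + 2L)
  n <- config$n_samples; n_pilot <- config$n_pilot
  study_ids <- sprintf("S%03d", seq_len(n))
  pilot_ids <- if (n_pilot > 0) sprintf("P%03d", seq_len(n_pilot)) else character()
  alien_ids <- if (n_slip_alien > 0) sprintf("X%03d", seq_len(n_slip_alien)) else character()
  ids <- c(study_ids, pilot_ids)

  sexes <- sample(rep(c("male", "female"), length.out = length(ids)))
  records <- data.frame(
    sample_id = ids,
    expression_array = paste0("E", ids),
    genotype_array = paste0("G", ids),
    tissue = "normal",
    trusted = ids %in% pilot_ids,
    sex = sexes,
    stringsAsFactors = FALSE)
  prov <- build_provenance(records, n, n_pilot)
  map <- sample_map(records, provenance = prov)

  inj <- inject_errors(map, config$error_spec, alien_pool = alien_ids)
  map <- inj$map

  # materialise array-level matrices from the true contents
  ta <- inj$true_assignment
  mk <- function(platform, source) {
    d <- ta[ta$platform == platform, , drop = FALSE]
    out <- matrix(if (platform == "genotype") NA_integer_ else NA_real_,
                  nrow(source), nrow(d),
                  dimnames = list(rownames(source), d$array_id))
    have <- !is.na(d$sample_id)
    out[, have] <- source[, d$sample_id[have]]
    if (platform == "expression" && any(!have)) {
      # an empty expression array still reports background; intergenic probes
      # carry slightly more stray signal than designed probes, inverting the
      # usual rank ordering
      for (j in which(!have)) {
        bg <- stats::rnorm(nrow(source), config$intergenic_baseline - 1, 0.25)
        inter <- ex$expression$probe_annotation$quality_tier == "intergenic"
        bg[inter] <- bg[inter] + 0.5
        out[, j] <- bg
      }
    }
    out
  }
  emat <- mk("expression", ex$expression$values)
  gmat <- mk("genotype", pop$genotypes$values)

  true_map <- apply_corrections(map, inj$truth)

  structure(list(
    expr = expression_matrix(emat, ex$expression$probe_annotation),
    geno = genotype_matrix(gmat, pop$genotypes$snp_annotation),
    map = map, truth = inj$truth, true_assignment = ta,
    true_map = true_map,
    groups = stats::setNames(pop$groups[seq_along(ids)], ids),
    eqtl_truth = ex$eqtl_truth,
    layouts = cohort_layouts(map),
    config = config), class = "badger_cohort")
}

#' Add matched tumour genotype arrays to a simulated cohort
#'
#' For every (non-pilot) sample, appends a genotype array carrying the
#' sample's germline calls after tumour distortion ([apply_tumour_distortion()]
#' with per-sample cellularity drawn from the configured Beta distribution).
#' Expression remains germline-driven: the cis(-artefact) associations used
#' for identity depend on the probe's germline sequence, while the tumour
#' array's *calls* are corrupted by loss of heterozygosity.
#'
#' @param cohort a `"badger_cohort"` from [simulate_cohort()].
#' @return the cohort with extra genotype columns (ids prefixed `"T"`) and a
#'   `tumour_arrays` data.frame (`sample_id`, `normal_array`, `tumour_array`,
#'   `cellularity`).
#' @export
add_tumour_genotype_arrays <- function(cohort) {
  cfg <- cohort$config
  set.seed(cfg$seed + 5L)
  map <- cohort$map
  idx <- which(!map$trusted & !is.na(map$genotype_array) &
                 !duplicated(map$sample_id))
  sh <- cfg$tumour_spec$cellularity_shape
  cel <- stats::rbeta(length(idx), sh[1], sh[2])
  germ <- cohort$geno$values[, map$genotype_array[idx], drop = FALSE]
  tum <- apply_tumour_distortion(germ, cfg$tumour_spec$loh_rate, cel)
  tids <- paste0("T", map$sample_id[idx])
  colnames(tum) <- tids
  vals <- cbind(cohort$geno$values, tum)
  cohort$geno <- genotype_matrix(vals, cohort$geno$snp_annotation)
  cohort$tumour_arrays <- data.frame(
    sample_id = map$sample_id[idx],
    normal_array = map$genotype_array[idx],
    tumour_array = tids, cellularity = cel, stringsAsFactors = FALSE)
  cohort
}
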