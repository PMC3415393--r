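# The scoring engine: B-allele prediction from expression, the score and
# rank matrices, the gap statistic, per-eQTL discrepancies, refinement with
# fast rescoring, and the iterative correction loop.

#' Posterior B-allele prediction for one eQTL pair
#'
#' With equal prior probability on the three genotypes, the posterior of
#' genotype g given expression level e is `f_g(e) / sum_g' f_g'(e)`,
#' evaluated over the *available* classes (an unavailable class contributes
#' zero mass and the posterior renormalises over the rest).  The predicted
#' B-allele count is the posterior expectation `0 P(AA) + 1 P(AB) + 2 P(BB)`.
#' When every available density evaluates to zero at e (far outside all
#' training supports) the posterior falls back to uniform over available
#' classes, so an uninformative expression level predicts the heterozygote.
#'
#' @param densities list with components `AA`, `AB`, `BB` (each `NULL` or a
#'   density grid as fitted by [fit_densities()]).
#' @param e numeric vector of log2-expression levels (`NA` gives `NA`).
#' @return list with `predicted` (vector in `[0, 2]`) and `posterior`
#'   (length(e) x 3 matrix).
#' @export
predict_b_allele <- function(densities, e) {
  avail <- !vapply(densities, is.null, logical(1))
  if (!any(avail)) stop("no available genotype class density")
  f <- sapply(1:3, function(g) eval_density(densities[[g]], e))
  f <- matrix(f, ncol = 3)
  f[, !avail] <- 0
  tot <- rowSums(f)
  post <- f / ifelse(tot > 0, tot, 1)
  flat <- tot <= 0
  if (any(flat))
    post[flat, ] <- rep(avail / sum(avail), each = sum(flat))
  p <- as.numeric(post %*% (0:2))
  p[is.na(e)] <- NA_real_
  post[is.na(e), ] <- NA_real_
  list(predicted = p, posterior = post)
}

#' Predicted B-allele counts for every eQTL and expression array
#'
#' @param set an `"eqtl_set"` from [fit_densities()].
#' @param expr an [expression_matrix()].
#' @return I x l numeric matrix of predicted counts (rows: eQTL pairs,
#'   columns: expression arrays); unusable pairs give `NA` rows.
#' @export
predict_matrix <- function(set, expr) {
  I <- nrow(set$pairs)
  E <- expr$values[set$pairs$probe_id, , drop = FALSE]
  P <- matrix(NA_real_, I, ncol(E),
              dimnames = list(NULL, colnames(E)))
  for (i in seq_len(I)) {
    if (!set$pairs$usable[i]) next
    P[i, ] <- predict_b_allele(set$densities[[i]], E[i, ])$predicted
  }
  P
}

#' Score matrix between predicted and observed B-allele counts
#'
#' The score for expression array j against genotype array k is the sum over
#' eQTLs of the squared difference between predicted and observed counts.
#' Under missing data the sum is rescaled to the full eQTL count,
#' `B_jk = (I / I_jk) * sum_i (p_ij - o_ik)^2` over the `I_jk` eQTLs with
#' both values present, which reduces to the plain sum when nothing is
#' missing.  Cells with no usable eQTL are `NA` and excluded from ranking.
#'
#' The predicted and observed matrices are cached inside the returned object
#' so that refinement can rescore cheaply without refitting densities.
#'
#' @param P I x l matrix of predicted counts ([predict_matrix()]).
#' @param O I x m matrix of observed counts (rows aligned with `P`).
#' @return object of class `"score_matrix"`: list with `B` (l x m), `counts`
#'   (non-missing eQTLs per cell), `n_eqtls`, and the cached `P`, `O`.
#' @export
badger_scores <- function(P, O) {
  P <- as.matrix(P); O <- as.matrix(O)
  if (nrow(P) != nrow(O)) stop("P and O must share the eQTL index")
  storage.mode(O) <- "double"
  Pm <- !is.na(P); Om <- !is.na(O)
  P0 <- ifelse(Pm, P, 0); O0 <- ifelse(Om, O, 0)
  S <- crossprod(P0^2, Om) + crossprod(Pm, O0^2) - 2 * crossprod(P0, O0)
  cnt <- crossprod(Pm, Om)
  B <- ifelse(cnt > 0, nrow(P) * S / cnt, NA_real_)
  dimnames(B) <- dimnames(cnt) <- list(colnames(P), colnames(O))
  structure(list(B = B, counts = cnt, n_eqtls = nrow(P), P = P, O = O),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d expression x %d genotype arrays, %d eQTLs\n",
              nrow(x$B), ncol(x$B), x$n_eqtls))
  invisible(x)
}

#' Rescore after dropping eQTL pairs
#'
#' Recomputes the scores from the cached predicted/observed matrices
#' restricted to the retained eQTLs -- equivalent to subtracting the removed
#' per-cell terms, and exactly equal to a full recomputation on the reduced
#' set -- then reapplies the missing-data rescaling.  Density fitting and
#' prediction (the expensive steps) are not repeated.
#'
#' @param scores a `"score_matrix"`.
#' @param keep logical or integer index over the eQTLs to retain.
#' @return a `"score_matrix"` over the retained eQTLs.
#' @export
rescore <- function(scores, keep) {
  badger_scores(scores$P[keep, , drop = FALSE],
                scores$O[keep, , drop = FALSE])
}

#' Per-row ranks of the score matrix
#'
#' Rank 1 marks the best (smallest) score for each expression array.  Ties
#' take the minimum rank, so exact-duplicate genotype arrays are all rank 1.
#' Missing scores get `NA` rank.
#'
#' @param scores a `"score_matrix"` (or plain matrix).
#' @return integer matrix of ranks with the same dimnames.
#' @export
rank_matrix <- function(scores) {
  B <- if (inherits(scores, "score_matrix")) scores$B else as.matrix(scores)
  R <- t(apply(B, 1, function(x) {
    r <- rep(NA_integer_, length(x))
    ok <- !is.na(x)
    r[ok] <- as.integer(rank(x[ok], ties.method = "min"))
    r
  }))
  dimnames(R) <- dimnames(B)
  R
}

#' Gap statistic for each expression array
#'
#' Sorting an expression array's scores into order statistics
#' `B_(1) <= ... <= B_(m)`, the gap is `B_(g+1) - B_(1)`, where `g` is the
#' largest number of replicate genotype arrays expected in the data set
#' (replicates of the true sample would occupy the first g order statistics,
#' so the gap to the (g+1)-th is the meaningful separation).  A large gap
#' marks a confident match; a large minimum score marks an array whose
#' sample appears on no genotype array.
#'
#' @param scores a `"score_matrix"` (or plain matrix).
#' @param g replicate parameter, `>= 1`; the number of genotype arrays must
#'   exceed `g`.
#' @return data.frame with `expression_array`, `min_score`, `gap`; the full
#'   per-array order statistics are attached as attribute `"order_stats"`.
#' @export
delta_statistic <- function(scores, g = 1L) {
  B <- if (inherits(scores, "score_matrix")) scores$B else as.matrix(scores)
  if (g < 1) stop("g must be >= 1")
  os <- apply(B, 1, function(x) sort(x[!is.na(x)]), simplify = FALSE)
  if (any(vapply(os, length, integer(1)) <= g))
    stop("need more genotype arrays than the replicate parameter g")
  out <- data.frame(
    expression_array = rownames(B),
    min_score = vapply(os, `[`, numeric(1), 1L),
    gap = vapply(os, function(x) x[g + 1L] - x[1L], numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "order_stats") <- os
  attr(out, "g") <- g
  out
}

#' Per-eQTL discrepancy over well-matched pairs
#'
#' `d_i` is the mean over well-matched expression/genotype array pairs of the
#' squared difference between predicted and observed B-allele counts; it
#' ranges over [0, 4] and measures how poorly eQTL i predicts genotypes even
#' when the pairing is right.
#'
#' @param scores a `"score_matrix"` (its cached `P`/`O` are used).
#' @param matched data.frame with columns `expression_array`,
#'   `genotype_array` of pairs believed well matched.
#' @return numeric vector `d` (one per eQTL); `NA` when an eQTL has no
#'   usable pair.
#' @export
eqtl_discrepancy <- function(scores, matched) {
  if (nrow(matched) < 1) stop("need at least one well-matched pair")
  Pj <- scores$P[, matched$expression_array, drop = FALSE]
  Ok <- scores$O[, matched$genotype_array, drop = FALSE]
  rowMeans((Pj - Ok)^2, na.rm = TRUE)
}

#' Automatic discrepancy cutoff from the largest histogram gap
#'
#' Sorts the `d_i` and places the cutoff in the middle of the largest gap
#' between consecutive values, searching only above the lower quartile so a
#' stray gap among the well-behaved pairs cannot discard the bulk of the
#' set.  If no gap clearly dominates (largest gap under 4 times the median
#' positive gap) the distribution is judged unimodal and `Inf` is returned
#' (no pruning).
#'
#' @param d numeric vector of per-eQTL discrepancies.
#' @return cutoff value T; pairs with `d > T` are discarded.
#' @export
choose_cutoff <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) < 4) return(Inf)
  s <- sort(d)
  gaps <- diff(s)
  lo <- max(2L, ceiling(0.25 * length(s)))
  cand <- seq(from = lo, to = length(gaps))
  i <- cand[which.max(gaps[cand])]
  pos <- gaps[gaps > 0]
  if (!length(pos) || gaps[i] < 4 * stats::median(pos)) return(Inf)
  (s[i] + s[i + 1L]) / 2
}

#' Refine an eQTL set by its discrepancies
#'
#' Discards all pairs whose discrepancy exceeds the cutoff (chosen
#' automatically from the distribution's largest gap when not supplied).
#'
#' @param set an `"eqtl_set"`.
#' @param d per-pair discrepancies ([eqtl_discrepancy()]).
#' @param cutoff manual override for the cutoff T.
#' @return list with `set` (reduced, `d` recorded in `pairs$d`), `keep`
#'   (logical), `cutoff`.
#' @export
refine_eqtl_set <- function(set, d, cutoff = NULL) {
  if (length(d) != nrow(set$pairs))
    stop("one discrepancy per eQTL pair required")
  if (is.null(cutoff)) cutoff <- choose_cutoff(d)
  set$pairs$d <- d
  keep <- is.na(d) | d <= cutoff
  keep[is.na(d)] <- FALSE                     # no usable pair: drop
  if (!any(keep)) stop("refinement would empty the eQTL set")
  list(set = subset_eqtl_set(set, keep), keep = keep, cutoff = cutoff)
}

# ---- the iterative loop ----------------------------------------------------

#' Configuration for the iterative correction loop
#'
#' @param window_bp,log10p_threshold cis scan parameters (see
#'   [scan_cis_associations()]).
#' @param min_class_count,bw_floor density-fit parameters.
#' @param refine whether to prune high-discrepancy eQTLs within iterations.
#' @param cutoff manual discrepancy cutoff (default: automatic).
#' @param g replicate parameter of the gap statistic.
#' @param rank_threshold evidence edges require a rank below this.
#' @param accept_z a correction is auto-accepted only when every affected
#'   expression array attains rank 1 afterwards and its robust separation --
#'   (median - minimum) / mad of the array's scores -- reaches this value,
#'   i.e. the proposed match is a clear low outlier against the array's own
#'   null scores.
#' @param orphan_z an expression array counts as an orphan (its sample on no
#'   genotype array, or foreign content) when its robust separation falls
#'   below this value: no genotype array matches it better than the bulk.
#' @param max_iter iteration cap.
#' @param max_cycle_len cycles longer than this surface as unresolved.
#' @param eqtl_pairs optional externally defined eQTL set (data.frame with
#'   `probe_id`, `snp_id`); skips the cis scan, densities are still fitted
#'   from the study's own training pairs each iteration.
#' @return list of class `"badger_config"`.
#' @export
badger_config <- function(window_bp = 1e6, log10p_threshold = 15,
                          min_class_count = 3L, bw_floor = 0.05,
                          refine = TRUE, cutoff = NULL, g = 1L,
                          rank_threshold = 3L, accept_z = 4,
                          orphan_z = 3.5, max_iter = 10L,
                          max_cycle_len = Inf, eqtl_pairs = NULL) {
  structure(as.list(environment()), class = "badger_config")
}

# intended matched pairs of a map (one row per pair, duplicates dropped)
intended_pairs <- function(map) {
  d <- map[!is.na(map$expression_array) & !is.na(map$genotype_array), ,
           drop = FALSE]
  d[!duplicated(paste(d$expression_array, d$genotype_array)), , drop = FALSE]
}

#' Run the full iterative mix-up detection and correction loop
#'
#' Each iteration: fit eQTL densities on the currently trusted matches
#' (the trusted subset when one exists, otherwise all intended matches),
#' predict B-allele counts for every expression array, score and rank
#' against every genotype array, optionally refine the eQTL set by
#' discrepancy over the current reciprocal rank-1 matches (scores are then
#' cheaply rescored), propose corrections from the rank evidence (plate
#' transforms, cycles/swaps, chains/slippage), auto-accept those meeting the
#' confidence policy, apply them, and repeat with the full eQTL set
#' reinstated.  The loop ends with a confirming iteration that proposes no
#' changes, or stops early if the same correction set recurs (oscillation).
#'
#' @param expr an [expression_matrix()].
#' @param geno a [genotype_matrix()].
#' @param map the recorded (intended) [sample_map()].
#' @param config a [badger_config()].
#' @return list of class `"badger_run"`: `map` (corrected), `report` (a
#'   `"mixup_report"`), `iterations` (per-iteration log), `converged`,
#'   `productive_iterations`, and the final `scores`, `ranks`, `deltas`,
#'   `eqtl_set`.
#' @export
run_badger <- function(expr, geno, map, config = badger_config()) {
  issues <- validate_inputs(expr, geno, map)
  real_issues <- grep("replicate", issues, value = TRUE, invert = TRUE)
  if (length(real_issues))
    stop("invalid inputs:\n", paste(real_issues, collapse = "\n"))

  trusted <- map[map$trusted & !is.na(map$expression_array) &
                   !is.na(map$genotype_array), , drop = FALSE]
  has_pilot <- nrow(trusted) >= 3
  current <- map
  pairs <- NULL
  trust_ids <- NULL      # sample ids of currently-trusted matches (no pilot)
  all_corrections <- list()
  iter_log <- list()
  seen <- character()
  converged <- FALSE
  productive <- 0L

  for (iter in seq_len(config$max_iter)) {
    # densities are fitted on the currently-trusted matches: the designated
    # pilot when one exists, otherwise the reciprocal rank-1 pairs carried
    # over from the previous iteration (all intended pairs at first, when no
    # ranks exist yet)
    train <- if (has_pilot) trusted
             else if (!is.null(trust_ids) && length(trust_ids) >= 10)
               current[current$sample_id %in% trust_ids, , drop = FALSE]
             else current
    # returning to the beginning: the full eQTL set is reinstated and, when
    # training on the evolving trusted set, rediscovered from it (with a
    # fixed pilot the scan result is constant and computed once)
    if (!is.null(config$eqtl_pairs)) {
      pairs <- config$eqtl_pairs
    } else if (is.null(pairs) || !has_pilot) {
      pairs <- scan_cis_associations(expr, geno, train,
                                     window_bp = config$window_bp,
                                     log10p_threshold = config$log10p_threshold)
      if (nrow(pairs) < 2)
        stop("cis scan retained fewer than 2 eQTL pairs; cannot score")
    }
    set <- fit_densities(pairs, expr, geno, train,
                         min_class_count = config$min_class_count,
                         bw_floor = config$bw_floor)
    P <- predict_matrix(set, expr)
    O <- geno$values[set$pairs$snp_id, , drop = FALSE]
    scores <- badger_scores(P, O)
    ranks <- rank_matrix(scores)

    ip <- intended_pairs(current)
    rk <- ranks[cbind(match(ip$expression_array, rownames(ranks)),
                      match(ip$genotype_array, colnames(ranks)))]
    n_used <- nrow(set$pairs)
    if (config$refine) {
      recip <- !is.na(rk) & rk == 1L
      matched <- ip[recip, , drop = FALSE]
      if (nrow(matched) >= 3) {
        d <- eqtl_discrepancy(scores, matched)
        ref <- refine_eqtl_set(set, d, cutoff = config$cutoff)
        if (!all(ref$keep)) {
          set <- ref$set
          scores <- rescore(scores, ref$keep)
          ranks <- rank_matrix(scores)
          rk <- ranks[cbind(match(ip$expression_array, rownames(ranks)),
                            match(ip$genotype_array, colnames(ranks)))]
          n_used <- nrow(set$pairs)
        }
      }
    }
    deltas <- delta_statistic(scores, g = config$g)

    props <- propose_corrections(scores, ranks, deltas, current, config)
    res <- attribute_and_apply(props$accepted, current)
    n_prop <- length(props$proposed)
    n_acc <- length(res$applied)
    iter_log[[iter]] <- data.frame(
      iteration = iter, eqtls_used = n_used,
      proposed = n_prop, accepted = n_acc,
      mismatched_pairs = sum(rk != 1L, na.rm = TRUE) + sum(is.na(rk)))
    message(sprintf(
      "iteration %d: %d eQTLs, %d mismatched pairs, %d corrections proposed, %d accepted",
      iter, n_used, sum(rk != 1L, na.rm = TRUE), n_prop, n_acc))

    if (n_acc > 0L) {
      key <- paste(sort(vapply(res$applied, correction_key, character(1))),
                   collapse = ";")
      if (key %in% seen) {
        warning("the same correction set recurred; stopping with unresolved arrays")
        break
      }
      seen <- c(seen, key)
      productive <- productive + 1L
      res$applied <- lapply(res$applied, function(cr) { cr$iteration <- iter; cr })
      all_corrections <- c(all_corrections, res$applied)
      current <- res$map
    }
    if (!has_pilot) {
      # reciprocal rank-1 intended pairs of the (possibly corrected) map
      # become the trusted matches of the next iteration
      ip2 <- intended_pairs(current)
      keep <- !is.na(ip2$expression_array) & !is.na(ip2$genotype_array)
      ip2 <- ip2[keep, , drop = FALSE]
      ok_r <- ranks[cbind(match(ip2$expression_array, rownames(ranks)),
                          match(ip2$genotype_array, colnames(ranks)))] == 1L
      colmin <- apply(scores$B, 2, function(x) min(x, na.rm = TRUE))
      ok_c <- scores$B[cbind(match(ip2$expression_array, rownames(scores$B)),
                             match(ip2$genotype_array, colnames(scores$B)))] <=
        colmin[match(ip2$genotype_array, colnames(scores$B))]
      new_trust <- sort(ip2$sample_id[!is.na(ok_r) & ok_r & ok_c])
      if (n_acc == 0L && identical(new_trust, trust_ids)) {
        converged <- TRUE; break
      }
      trust_ids <- new_trust
    } else if (n_acc == 0L) { converged <- TRUE; break }
  }

  # final state for the report
  ip <- intended_pairs(current)
  rk <- ranks[cbind(match(ip$expression_array, rownames(ranks)),
                    match(ip$genotype_array, colnames(ranks)))]
  unresolved <- ip[is.na(rk) | rk != 1L, , drop = FALSE]
  report <- structure(list(
    corrections = all_corrections,
    deferred = if (converged) list() else NULL,
    unresolved = unresolved,
    orphans = propose_corrections(scores, ranks, deltas, current,
                                  config)$orphans,
    converged = converged,
    productive_iterations = productive), class = "mixup_report")

  structure(list(map = current, report = report,
                 iterations = do.call(rbind, iter_log),
                 converged = converged,
                 productive_iterations = productive,
                 scores = scores, ranks = ranks, deltas = deltas,
                 eqtl_set = set), class = "badger_run")
}

correction_key <- function(cr) {
  paste(cr$type, paste(sort(unlist(cr$samples)), collapse = ","), sep = ":")
}

#' @export
print.badger_run <- function(x, ...) {
  cat(sprintf("badger_run: %s after %d productive iteration(s); %d correction(s), %d unresolved pair(s)\n",
              if (x$converged) "converged" else "stopped",
              x$productive_iterations,
              length(x$report$corrections), nrow(x$report$unresolved)))
  invisible(x)
}

#' @export
print.mixup_report <- function(x, ...) {
  cat(sprintf("mixup_report: %d correction(s), %d unresolved pair(s), converged: %s\n",
              length(x$corrections), nrow(x$unresolved), x$converged))
  for (cr in x$corrections)
    cat(sprintf("  [%s/%s] samples: %s\n", cr$type,
                cr$platform %||% "?", paste(cr$samples, collapse = ", ")))
  invisible(x)
}
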