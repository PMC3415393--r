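# cis-eQTL discovery on a trusted training subset, and per-genotype kernel
# density estimation of expression for each retained probe/SNP pair.

#' Scan for cis associations between expression probes and SNPs
#'
#' For every (probe, SNP) pair on the same chromosome within `window_bp`
#' (probe anchor position to SNP position, point to point), expression is
#' regressed on the B-allele count over the supplied training pairs and the
#' 1-d.f. trend F-test computed.  Pairs with `-log10(p)` above the threshold
#' are retained.  Only probes with `quality_tier == "perfect"` are scanned:
#' these include the probes whose sequence covers SNPs, whose apparent eQTL
#' behaviour (a hybridisation artefact) is an especially robust identity
#' signal.
#'
#' @param expr an [expression_matrix()].
#' @param geno a [genotype_matrix()].
#' @param map a [sample_map()] restricted to trusted matched pairs (rows with
#'   both arrays present are used).
#' @param window_bp maximum probe-SNP distance (default 1 Mb).
#' @param log10p_threshold retention threshold on `-log10(p)` (default 15).
#' @return data.frame with columns `probe_id`, `snp_id`, `association_log10p`
#'   and `n_train`, ordered by decreasing association strength.
#' @export
scan_cis_associations <- function(expr, geno, map, window_bp = 1e6,
                                  log10p_threshold = 15) {
  pairs <- map[!is.na(map$expression_array) & !is.na(map$genotype_array), ,
               drop = FALSE]
  pairs <- pairs[!duplicated(pairs$sample_id), , drop = FALSE]
  if (nrow(pairs) < 3)
    stop("need at least 3 matched training pairs")
  E <- expr$values[, pairs$expression_array, drop = FALSE]
  G <- geno$values[, pairs$genotype_array, drop = FALSE]
  pa <- expr$probe_annotation
  sa <- geno$snp_annotation

  keep_probe <- which(pa$quality_tier == "perfect")
  out <- vector("list", length(keep_probe))
  for (ii in seq_along(keep_probe)) {
    p <- keep_probe[ii]
    cand <- which(sa$chromosome == pa$chromosome[p] &
                    abs(sa$position - pa$position[p]) <= window_bp)
    if (!length(cand)) next
    e <- E[p, ]
    res <- lapply(cand, function(s) {
      o <- G[s, ]
      ok <- !is.na(e) & !is.na(o)
      n <- sum(ok)
      if (n < 3 || stats::var(o[ok]) == 0 || stats::var(e[ok]) == 0)
        return(NULL)
      r2 <- stats::cor(e[ok], o[ok])^2
      r2 <- min(r2, 1 - 1e-15)
      f <- (n - 2) * r2 / (1 - r2)
      l10p <- -stats::pf(f, 1, n - 2, lower.tail = FALSE, log.p = TRUE) / log(10)
      data.frame(probe_id = pa$probe_id[p], snp_id = sa$snp_id[s],
                 association_log10p = l10p, n_train = n,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (!is.null(res))
      out[[ii]] <- res[res$association_log10p > log10p_threshold, , drop = FALSE]
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(probe_id = character(), snp_id = character(),
                      association_log10p = numeric(), n_train = integer(),
                      stringsAsFactors = FALSE)
  out <- out[order(-out$association_log10p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gaussian KDE for one genotype class, stored as a grid for serialisability.
# Bandwidth: Silverman's rule floored at bw_floor so a degenerate class
# (all values equal) still yields a finite density.
fit_class_density <- function(v, bw_floor = 0.05, grid_n = 256L) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NULL)
  # all-equal training values defeat Silverman's rule (its zero-spread
  # fallback scales with the data magnitude); pin such classes to the floor
  bw <- if (length(unique(v)) < 2) bw_floor
        else tryCatch(stats::bw.nrd0(v), error = function(e) bw_floor)
  if (!is.finite(bw) || bw < bw_floor) bw <- bw_floor
  d <- stats::density(v, bw = bw, from = min(v) - 4 * bw,
                      to = max(v) + 4 * bw, n = grid_n)
  list(x = d$x, y = d$y, bw = bw, n = length(v))
}

# evaluate a stored class density at arbitrary points (0 outside its grid)
eval_density <- function(dens, e) {
  if (is.null(dens)) return(rep(0, length(e)))
  y <- stats::approx(dens$x, dens$y, xout = e, yleft = 0, yright = 0)$y
  y[is.na(y)] <- 0
  pmax(y, 0)
}

#' Fit per-genotype expression densities for a set of eQTL pairs
#'
#' For each pair, training expression values are split by the observed
#' B-allele count on the intended matching genotype array and a Gaussian
#' kernel density is fitted per genotype class.  Classes with fewer than
#' `min_class_count` training arrays are marked unavailable; a pair with no
#' available class is flagged unusable.
#'
#' @param pairs data.frame from [scan_cis_associations()] (columns `probe_id`,
#'   `snp_id`; other columns carried through).
#' @param expr an [expression_matrix()].
#' @param geno a [genotype_matrix()].
#' @param map a [sample_map()] of trusted matched training pairs.
#' @param min_class_count minimum training arrays per class (default 3).
#' @param bw_floor lower bound on the kernel bandwidth, log2 units.
#' @return object of class `"eqtl_set"`: list with `pairs` (data.frame, plus
#'   `usable` flag and `d` discrepancy placeholder), `densities` (per pair, a
#'   list with components `AA`, `AB`, `BB`, each `NULL` or a density grid)
#'   and `class_counts` (pairs x 3 matrix).
#' @export
fit_densities <- function(pairs, expr, geno, map, min_class_count = 3L,
                          bw_floor = 0.05) {
  tr <- map[!is.na(map$expression_array) & !is.na(map$genotype_array), ,
            drop = FALSE]
  tr <- tr[!duplicated(tr$sample_id), , drop = FALSE]
  if (nrow(pairs) == 0)
    return(structure(list(pairs = cbind(pairs, usable = logical(),
                                        d = numeric()),
                          densities = list(),
                          class_counts = matrix(0L, 0, 3)),
                     class = "eqtl_set"))
  E <- expr$values[pairs$probe_id, tr$expression_array, drop = FALSE]
  G <- geno$values[pairs$snp_id, tr$genotype_array, drop = FALSE]
  I <- nrow(pairs)
  densities <- vector("list", I)
  class_counts <- matrix(0L, I, 3, dimnames = list(NULL, c("AA", "AB", "BB")))
  for (i in seq_len(I)) {
    e <- E[i, ]; o <- G[i, ]
    dl <- list(AA = NULL, AB = NULL, BB = NULL)
    for (g in 0:2) {
      v <- e[!is.na(o) & o == g & !is.na(e)]
      class_counts[i, g + 1L] <- length(v)
      if (length(v) >= min_class_count)
        dl[[g + 1L]] <- fit_class_density(v, bw_floor = bw_floor)
    }
    densities[[i]] <- dl
  }
  pairs$usable <- vapply(densities, function(dl)
    any(!vapply(dl, is.null, logical(1))), logical(1))
  if (any(!pairs$usable))
    warning(sum(!pairs$usable), " eQTL pair(s) unusable: no genotype class ",
            "reached the minimum training count")
  pairs$d <- NA_real_
  structure(list(pairs = pairs, densities = densities,
                 class_counts = class_counts),
            class = "eqtl_set")
}

#' @export
print.eqtl_set <- function(x, ...) {
  cat(sprintf("eqtl_set: %d pairs (%d usable)\n",
              nrow(x$pairs), sum(x$pairs$usable)))
  invisible(x)
}

#' Drop eQTL pairs from a fitted set
#'
#' @param set an `"eqtl_set"`.
#' @param keep logical or integer index of pairs to retain.
#' @return the reduced `"eqtl_set"`.
#' @export
subset_eqtl_set <- function(set, keep) {
  set$pairs <- set$pairs[keep, , drop = FALSE]
  set$densities <- set$densities[keep]
  set$class_counts <- set$class_counts[keep, , drop = FALSE]
  set
}
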