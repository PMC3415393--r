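# Turning rank evidence into concrete, attributed plating-error hypotheses:
# bipartite mismatch graph, cycle/chain detection, systematic plate
# transforms, and platform attribution via plate provenance.

#' Bipartite mismatch graph from rank evidence
#'
#' Nodes are the unresolved expression arrays and unresolved genotype arrays
#' (those whose intended partner is not rank 1, plus arrays with no intended
#' partner).  An evidence edge joins expression array j to genotype array k
#' when the rank of their score is below `rank_threshold`; intended-mapping
#' edges are marked.  Swaps appear as short alternating cycles, slippage as
#' chains terminated by orphans.
#'
#' @param ranks rank matrix from [rank_matrix()].
#' @param map the current [sample_map()].
#' @param rank_threshold evidence edges require rank strictly below this.
#' @param scores optional `"score_matrix"`; stores per-node minimum scores.
#' @return object of class `"mismatch_graph"`: list with `expr_nodes`,
#'   `geno_nodes`, `edges` (data.frame `expr`, `geno`, `rank`, `score`,
#'   `intended`), `best_geno` (rank-1 target per unresolved expression
#'   array, over all genotype arrays) and `min_score`.
#' @export
build_mismatch_graph <- function(ranks, map, rank_threshold = 3L,
                                 scores = NULL) {
  B <- if (!is.null(scores)) scores$B else NULL
  ip <- intended_pairs(map)
  rk <- ranks[cbind(match(ip$expression_array, rownames(ranks)),
                    match(ip$genotype_array, colnames(ranks)))]
  bad <- is.na(rk) | rk != 1L
  expr_nodes <- ip$expression_array[bad]
  geno_nodes <- ip$genotype_array[bad]
  # arrays with no intended partner are unresolved by definition
  solo_e <- map$expression_array[!is.na(map$expression_array) &
                                   is.na(map$genotype_array)]
  solo_g <- map$genotype_array[is.na(map$expression_array) &
                                 !is.na(map$genotype_array)]
  expr_nodes <- unique(c(expr_nodes, solo_e))
  geno_nodes <- unique(c(geno_nodes, solo_g))

  edges <- NULL
  if (length(expr_nodes) && length(geno_nodes)) {
    sub <- ranks[expr_nodes, geno_nodes, drop = FALSE]
    hit <- which(!is.na(sub) & sub < rank_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      edges <- data.frame(
        expr = expr_nodes[hit[, 1]], geno = geno_nodes[hit[, 2]],
        rank = sub[hit],
        score = if (!is.null(B)) B[cbind(match(expr_nodes[hit[, 1]], rownames(B)),
                                         match(geno_nodes[hit[, 2]], colnames(B)))]
                else NA_real_,
        stringsAsFactors = FALSE)
      key <- paste(ip$expression_array, ip$genotype_array)
      edges$intended <- paste(edges$expr, edges$geno) %in% key
    }
  }
  if (is.null(edges))
    edges <- data.frame(expr = character(), geno = character(),
                        rank = integer(), score = numeric(),
                        intended = logical(), stringsAsFactors = FALSE)

  best <- character(0)
  if (length(expr_nodes)) {
    best <- vapply(expr_nodes, function(e) {
      r <- ranks[e, ]
      w <- which(!is.na(r) & r == 1L)
      if (length(w)) colnames(ranks)[w[1]] else NA_character_
    }, character(1))
  }
  min_score <- NULL
  if (!is.null(B) && length(expr_nodes))
    min_score <- apply(B[expr_nodes, , drop = FALSE], 1,
                       function(x) min(x, na.rm = TRUE))
  structure(list(expr_nodes = expr_nodes, geno_nodes = geno_nodes,
                 edges = edges, best_geno = best, min_score = min_score),
            class = "mismatch_graph")
}

#' @export
print.mismatch_graph <- function(x, ...) {
  cat(sprintf("mismatch_graph: %d expression + %d genotype unresolved arrays, %d evidence edges\n",
              length(x$expr_nodes), length(x$geno_nodes), nrow(x$edges)))
  invisible(x)
}

#' Export the mismatch graph in DOT format
#'
#' Rearrangements that are hard to enumerate are often obvious to the eye
#' once the graph is drawn; solid edges are rank evidence, dashed edges the
#' intended mapping.
#'
#' @param graph a `"mismatch_graph"`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dot <- function(graph, path) {
  lines <- c("graph mismatches {", "  rankdir=LR;")
  for (e in graph$expr_nodes)
    lines <- c(lines, sprintf('  "%s" [shape=circle];', e))
  for (g in graph$geno_nodes)
    lines <- c(lines, sprintf('  "%s" [shape=box];', g))
  if (nrow(graph$edges))
    lines <- c(lines, sprintf('  "%s" -- "%s" [style=%s,label="%d"];',
                              graph$edges$expr, graph$edges$geno,
                              ifelse(graph$edges$intended, "dashed", "solid"),
                              graph$edges$rank))
  writeLines(c(lines, "}"), path)
  invisible(path)
}

# owner sample of each array on a platform (first record)
owner_of <- function(map, platform) {
  col <- if (platform == "expression") "expression_array" else "genotype_array"
  keep <- !is.na(map[[col]])
  stats::setNames(map$sample_id[keep], map[[col]][keep])
}

#' Candidate corrections from cycles and chains in the mismatch graph
#'
#' The rank-1 evidence defines a functional mapping on unresolved samples:
#' sample s points to the sample whose intended genotype array best matches
#' s's expression array.  Cycles of this mapping are cyclic relabelings
#' (2-cycles are simple swaps); maximal paths whose terminal node is an
#' orphan (minimum score above `orphan_threshold`) are slippage hypotheses
#' with the characteristic orphan arrays at both ends.  Disjoint 2-cycles
#' whose union is a contiguous segment reversed end-to-end are merged into a
#' single reversal correction, so that the entire error is reported rather
#' than just its middle.
#'
#' @param graph a `"mismatch_graph"` built with scores.
#' @param map the current [sample_map()].
#' @param zsep optional named vector of per-expression-array robust
#'   separations ((median - min) / mad of the array's scores); computed from
#'   the graph's scores when absent.
#' @param orphan_z an expression array whose separation falls below this is
#'   an orphan: none of its scores is an outlier, so its sample appears on
#'   no genotype array (or its own content is foreign).
#' @param max_cycle_len cycles longer than this are left unresolved.
#' @return list with `cycles`, `chains`, `duplicates`, `orphans` (each a
#'   list of correction hypotheses).
#' @export
find_cycles_and_chains <- function(graph, map, zsep = NULL, orphan_z = 3.5,
                                   max_cycle_len = Inf) {
  e_owner <- owner_of(map, "expression")
  g_owner <- owner_of(map, "genotype")
  exprs <- graph$expr_nodes
  samples <- unname(e_owner[exprs])
  ok <- !is.na(samples)
  exprs <- exprs[ok]; samples <- samples[ok]

  orphan <- rep(FALSE, length(exprs))
  if (!is.null(zsep)) orphan <- zsep[exprs] < orphan_z

  sigma <- rep(NA_character_, length(exprs))
  names(sigma) <- samples
  duplicates <- list()
  for (i in seq_along(exprs)) {
    if (orphan[i]) next
    tgt <- graph$best_geno[[exprs[i]]]
    if (is.na(tgt)) next
    u <- g_owner[tgt]
    if (is.na(u)) next
    if (!u %in% samples) {
      # best match is an already-resolved genotype array: the expression
      # array looks like an accidental duplicate of that sample's content
      duplicates[[length(duplicates) + 1L]] <- list(
        type = "duplicate", platform = "undetermined",
        samples = c(samples[i], unname(u)),
        arrays = c(exprs[i], tgt),
        note = "expression array duplicates the content matching an already-resolved genotype array")
      next
    }
    sigma[samples[i]] <- unname(u)
  }
  best_g_of <- stats::setNames(graph$best_geno[exprs], samples)
  expr_of <- stats::setNames(exprs, samples)
  min_score_of <- if (!is.null(graph$min_score))
    stats::setNames(graph$min_score[exprs], samples) else NULL

  cycles <- list()
  state <- stats::setNames(rep(0L, length(samples)), samples)  # 0 new, 1 done
  for (s0 in samples) {
    if (state[s0] != 0L) next
    path <- s0; cur <- s0
    repeat {
      nxt <- sigma[[cur]]
      if (is.na(nxt) || !(nxt %in% samples) || state[nxt] == 1L) break
      if (nxt %in% path) {
        cyc <- path[which(path == nxt):length(path)]
        if (length(cyc) >= 2 && length(cyc) <= max_cycle_len)
          cycles[[length(cycles) + 1L]] <- list(
            type = if (length(cyc) == 2L) "swap" else "cycle",
            samples = cyc,
            pairing = data.frame(
              sample_id = cyc,
              expr_array = unname(expr_of[cyc]),
              matched_geno = unname(best_g_of[cyc]),
              stringsAsFactors = FALSE))
        break
      }
      path <- c(path, nxt); cur <- nxt
    }
    state[path] <- 1L
  }
  cycles <- merge_reversals(cycles, map)

  # chains: start at samples with no sigma-preimage, walk to the end of the
  # path; the terminal is orphan-like when its scores single out no genotype
  # array, or when its only lead points outside the unresolved set (an alien
  # sample's accidental best match)
  chains <- list()
  in_cycle <- unlist(lapply(cycles, `[[`, "samples"))
  image <- stats::na.omit(unname(sigma))
  starts <- setdiff(samples[!(samples %in% image)], in_cycle)
  for (s0 in starts) {
    path <- s0; cur <- s0
    while (!is.na(sigma[[cur]]) && sigma[[cur]] %in% samples &&
           !(sigma[[cur]] %in% path)) {
      cur <- sigma[[cur]]; path <- c(path, cur)
    }
    term_orphan <- isTRUE(orphan[match(cur, samples)]) ||
      is.na(sigma[[cur]]) || !(sigma[[cur]] %in% samples)
    if (length(path) >= 2 && term_orphan) {
      chains[[length(chains) + 1L]] <- list(
        type = "chain/slippage", samples = path,
        edges = data.frame(from = path[-length(path)], to = path[-1],
                           stringsAsFactors = FALSE),
        pairing = data.frame(
          sample_id = path[-length(path)],
          expr_array = unname(expr_of[path[-length(path)]]),
          matched_geno = unname(best_g_of[path[-length(path)]]),
          stringsAsFactors = FALSE))
    }
  }

  orphans <- list()
  lone <- setdiff(samples[orphan], unlist(lapply(chains, `[[`, "samples")))
  for (s in lone)
    orphans[[length(orphans) + 1L]] <- list(
      type = "alien", platform = "undetermined", samples = s,
      arrays = unname(expr_of[s]),
      min_score = if (!is.null(min_score_of)) unname(min_score_of[s]) else NA,
      note = "expression array matches no genotype array; its sample (or its intended genotype array's content) is foreign to the study")

  list(cycles = cycles, chains = chains, duplicates = duplicates,
       orphans = orphans)
}

# merge disjoint 2-cycles that jointly reverse a contiguous run of positions
# on one platform into a single correction (so the outer arrays of a
# reversed block are not orphaned by reporting only the middle swap)
merge_reversals <- function(cycles, map) {
  prov <- attr(map, "provenance")
  if (is.null(prov)) return(cycles)
  is_swap <- vapply(cycles, function(cc) cc$type == "swap", logical(1))
  if (sum(is_swap) < 2) return(cycles)
  for (pf in c("expression", "genotype")) {
    pd <- prov[prov$platform == pf, , drop = FALSE]
    pos <- stats::setNames(pd$position, pd$sample_id)
    sw <- which(vapply(cycles, function(cc)
      cc$type == "swap" && all(cc$samples %in% names(pos)), logical(1)))
    if (length(sw) < 2) next
    ctr <- vapply(sw, function(i) mean(pos[cycles[[i]]$samples]), numeric(1))
    # swaps of one reversed block share the block's centre position
    for (c0 in unique(ctr)) {
      grp <- sw[ctr == c0]
      if (length(grp) < 2) next
      ss <- unlist(lapply(cycles[grp], `[[`, "samples"))
      p <- sort(pos[ss])
      if (!all(diff(p) == 1)) next
      merged <- list(type = "cycle", samples = names(p),
                     pairing = do.call(rbind,
                                       lapply(cycles[grp], `[[`, "pairing")),
                     note = sprintf("contiguous %d-array block reversed on the %s platform",
                                    length(p), pf))
      cycles <- c(cycles[-grp], list(merged))
      return(merge_reversals(cycles, map))
    }
  }
  cycles
}

#' Systematic plate-transform hypotheses
#'
#' For each plate (or BeadChip strip) on each platform, tests the identity
#' against 180-degree rotation, row-order reversal, column-order reversal
#' (strip reversal for chips), a +/-1 slip of the plate's sample sequence,
#' and content exchange with every other same-platform plate of identical
#' occupancy.  A hypothesis is reported whenever it strictly increases the
#' number of intended pairs at rank 1, with the count gained.
#'
#' @param map the current [sample_map()] (with provenance).
#' @param ranks rank matrix from [rank_matrix()].
#' @return list of hypotheses, each with `type = "plate_transform"`,
#'   `transform`, `platform`, `plate_id`, `gain`, `samples` and a ready
#'   `new_assignment`; sorted by decreasing gain.
#' @export
enumerate_plate_transforms <- function(map, ranks) {
  prov <- attr(map, "provenance")
  if (is.null(prov)) {
    warning("no provenance available; plate-transform search skipped")
    return(list())
  }
  e_of <- stats::setNames(map$expression_array, map$sample_id)
  g_of <- stats::setNames(map$genotype_array, map$sample_id)
  arr_of <- function(s, pf) if (pf == "expression") e_of[s] else g_of[s]

  rank1 <- function(pf, s, proposed) {
    # is the intended pair of sample s at rank 1 under the proposed array?
    e <- if (pf == "expression") proposed else unname(e_of[s])
    g <- if (pf == "expression") unname(g_of[s]) else proposed
    ok <- !is.na(e) & !is.na(g) & e %in% rownames(ranks) & g %in% colnames(ranks)
    out <- rep(FALSE, length(s))
    out[ok] <- !is.na(ranks[cbind(e[ok], g[ok])]) &
      ranks[cbind(e[ok], g[ok])] == 1L
    out
  }

  hyps <- list()
  for (pf in c("expression", "genotype")) {
    pd <- prov[prov$platform == pf, , drop = FALSE]
    plates <- split(pd, pd$plate_id)
    for (pl in names(plates)) {
      d <- plates[[pl]]
      d <- d[order(d$position), , drop = FALSE]
      s <- d$sample_id
      base_ok <- rank1(pf, s, unname(arr_of(s, pf)))
      base <- sum(base_ok)
      rc <- well_to_rc(d$well)

      try_wells <- function(name, r2, c2) {
        partner <- s[match(rc_to_well(r2, c2), d$well)]
        if (anyNA(partner)) return(NULL)
        prop <- unname(arr_of(partner, pf))
        new_ok <- rank1(pf, s, prop)
        gain <- sum(new_ok) - base
        if (gain <= 0) return(NULL)
        list(type = "plate_transform", transform = name, platform = pf,
             plate_id = pl, gain = gain, losses = sum(base_ok & !new_ok),
             samples = s,
             new_assignment = data.frame(sample_id = s, platform = pf,
                                         array = prop,
                                         stringsAsFactors = FALSE),
             alien_arrays = character())
      }
      hyps <- c(hyps, Filter(Negate(is.null), list(
        try_wells("rotate180", PLATE_NROW + 1L - rc[, 1],
                  PLATE_NCOL + 1L - rc[, 2]),
        try_wells("row_reversal", PLATE_NROW + 1L - rc[, 1], rc[, 2]),
        try_wells("column_reversal", rc[, 1], PLATE_NCOL + 1L - rc[, 2]))))

      for (dir in c(1L, -1L)) {
        k <- length(s)
        # slip: content shifted by one, so sample t sits on array t + dir
        idx <- seq_len(k) + dir
        prop <- ifelse(idx >= 1L & idx <= k, unname(arr_of(s, pf))[pmin(pmax(idx, 1L), k)],
                       NA_character_)
        new_ok <- rank1(pf, s, prop)
        gain <- sum(new_ok) - base
        if (gain > 0) {
          alien <- unname(arr_of(if (dir == 1L) s[1L] else s[k], pf))
          hyps[[length(hyps) + 1L]] <- list(
            type = "plate_transform",
            transform = sprintf("slip%+d", dir), platform = pf,
            plate_id = pl, gain = gain, losses = sum(base_ok & !new_ok),
            samples = s,
            new_assignment = data.frame(sample_id = s, platform = pf,
                                        array = prop,
                                        stringsAsFactors = FALSE),
            alien_arrays = alien)
        }
      }
      for (pl2 in names(plates)) {
        if (pl2 <= pl) next
        d2 <- plates[[pl2]]
        m2 <- match(d$well, d2$well)
        if (anyNA(m2) || nrow(d2) != nrow(d)) next
        s2 <- d2$sample_id[m2]
        prop <- c(unname(arr_of(s2, pf)), unname(arr_of(s, pf)))
        both <- c(s, s2)
        base2_ok <- rank1(pf, both, unname(arr_of(both, pf)))
        new2_ok <- rank1(pf, both, prop)
        gain <- sum(new2_ok) - sum(base2_ok)
        if (gain > 0)
          hyps[[length(hyps) + 1L]] <- list(
            type = "plate_transform", transform = "plate_swap",
            platform = pf, plate_id = c(pl, pl2), gain = gain,
            losses = sum(base2_ok & !new2_ok), samples = both,
            new_assignment = data.frame(sample_id = both, platform = pf,
                                        array = prop,
                                        stringsAsFactors = FALSE),
            alien_arrays = character())
      }
    }
  }
  hyps[order(-vapply(hyps, `[[`, numeric(1), "gain"))]
}

# contiguity of a sample set in a platform's processing sequence (the
# sequence runs across plate boundaries: a slip in the source plate can
# spill over the array-to-chip boundary)
contiguous_on <- function(map, samples, platform) {
  prov <- attr(map, "provenance")
  if (is.null(prov)) return(FALSE)
  pd <- prov[prov$platform == platform & prov$sample_id %in% samples, ,
             drop = FALSE]
  if (nrow(pd) != length(samples)) return(FALSE)
  p <- sort(pd$position)
  all(diff(p) == 1L)
}

#' Attribute corrections to a platform and apply them to the map
#'
#' The platform carrying the error is the one on which the affected samples
#' were processing neighbours (a contiguous run of the platform's sample
#' sequence) at some stage.  When the samples are neighbours on both
#' platforms -- or on neither -- the source cannot be identified and the
#' attribution is `"undetermined"`; the pairing is still corrected, applied
#' by convention on the genotype side (consistent with matching from the
#' expression array towards a deduplicated set of genotype arrays).
#' Corrections touching a common array conflict and none of them is applied.
#'
#' @param corrections list of hypotheses from [find_cycles_and_chains()] /
#'   [enumerate_plate_transforms()] (or ground-truth records).
#' @param map the current [sample_map()].
#' @return list with `map` (corrected), `applied` (corrections completed
#'   with `platform` and `new_assignment`), `conflicts`.
#' @export
attribute_and_apply <- function(corrections, map) {
  e_of <- stats::setNames(map$expression_array, map$sample_id)
  g_of <- stats::setNames(map$genotype_array, map$sample_id)
  g_owner <- owner_of(map, "genotype")

  completed <- list()
  for (cr in corrections) {
    if (is.null(cr$new_assignment)) {
      on_e <- contiguous_on(map, cr$samples, "expression")
      on_g <- contiguous_on(map, cr$samples, "genotype")
      platform <- if (on_e && !on_g) "expression"
                  else if (on_g && !on_e) "genotype"
                  else "undetermined"
      apply_side <- if (platform == "expression") "expression" else "genotype"
      if (cr$type %in% c("swap", "cycle")) {
        pr <- cr$pairing
        if (apply_side == "genotype") {
          cr$new_assignment <- data.frame(
            sample_id = pr$sample_id, platform = "genotype",
            array = pr$matched_geno, stringsAsFactors = FALSE)
        } else {
          # the matched genotype array's owner is the sample actually on
          # this expression array
          cr$new_assignment <- data.frame(
            sample_id = unname(g_owner[pr$matched_geno]),
            platform = "expression",
            array = pr$expr_array, stringsAsFactors = FALSE)
        }
        cr$alien_arrays <- character()
      } else if (cr$type == "chain/slippage") {
        ed <- cr$edges
        if (apply_side == "genotype") {
          # edge from -> to: from's content matches to's intended genotype
          term <- cr$samples[length(cr$samples)]
          cr$new_assignment <- rbind(
            data.frame(sample_id = ed$from, platform = "genotype",
                       array = unname(g_of[ed$to]), stringsAsFactors = FALSE),
            data.frame(sample_id = term, platform = "genotype",
                       array = NA_character_, stringsAsFactors = FALSE))
          cr$alien_arrays <- unname(g_of[cr$samples[1L]])
        } else {
          head_s <- cr$samples[1L]
          term <- cr$samples[length(cr$samples)]
          cr$new_assignment <- rbind(
            data.frame(sample_id = ed$to, platform = "expression",
                       array = unname(e_of[ed$from]), stringsAsFactors = FALSE),
            data.frame(sample_id = head_s, platform = "expression",
                       array = NA_character_, stringsAsFactors = FALSE))
          cr$alien_arrays <- unname(e_of[term])
        }
      } else {
        next  # report-only hypotheses (orphans, duplicates)
      }
      cr$platform <- platform
    }
    completed[[length(completed) + 1L]] <- cr
  }

  # conflict check: no array or (sample, platform) may be assigned twice
  keys_arr <- character(); keys_sp <- character(); conflicts <- list()
  ok_list <- list()
  for (cr in completed) {
    na <- cr$new_assignment
    ka <- stats::na.omit(paste(na$platform, na$array))
    ks <- paste(na$platform, na$sample_id)
    if (any(ka %in% keys_arr) || any(ks %in% keys_sp)) {
      conflicts[[length(conflicts) + 1L]] <- cr
    } else {
      keys_arr <- c(keys_arr, ka); keys_sp <- c(keys_sp, ks)
      ok_list[[length(ok_list) + 1L]] <- cr
    }
  }
  if (length(conflicts)) {
    warning(length(conflicts), " overlapping correction(s) conflicted and were not applied")
  }
  new_map <- apply_corrections(map, ok_list)
  list(map = new_map, applied = ok_list, conflicts = conflicts)
}

# robust per-row separation of the best score from the bulk of (almost all
# non-matching) scores; self-calibrating against density contamination,
# which inflates matched scores and compresses gaps globally
separation_z <- function(B) {
  apply(B, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 4) return(NA_real_)
    s <- stats::mad(x)
    (stats::median(x) - min(x)) / max(s, 1e-8)
  })
}

# orchestrates one iteration's proposals and the acceptance policy
propose_corrections <- function(scores, ranks, deltas, map, config) {
  zsep <- separation_z(scores$B)

  transforms <- enumerate_plate_transforms(map, ranks)
  graph <- build_mismatch_graph(ranks, map,
                                rank_threshold = config$rank_threshold,
                                scores = scores)
  cc <- find_cycles_and_chains(graph, map, zsep = zsep,
                               orphan_z = config$orphan_z,
                               max_cycle_len = config$max_cycle_len)

  e_of <- stats::setNames(map$expression_array, map$sample_id)

  passes <- function(cr) {
    if (cr$type == "plate_transform") {
      loss <- cr$losses %||% 0
      # slips must explain every pair they touch (partial runs belong to the
      # chain mechanism); other transforms may break a rank-1 pair only when
      # a composed error leaves one intact by coincidence, so demand
      # overwhelming net evidence in that case
      if (startsWith(cr$transform, "slip")) return(cr$gain > 0 && loss == 0)
      return(cr$gain > 0 && (loss == 0 || cr$gain >= 5 * loss))
    }
    if (cr$type %in% c("swap", "cycle")) {
      pr <- cr$pairing
      r1 <- ranks[cbind(pr$expr_array, pr$matched_geno)]
      all(!is.na(r1) & r1 == 1L) &&
        all(zsep[pr$expr_array] >= config$accept_z, na.rm = TRUE)
    } else if (cr$type == "chain/slippage") {
      # a 2-node chain is indistinguishable from a swap with one noisy
      # member; slippage proper involves at least two shifted samples plus
      # the orphan, so only longer chains are applied unattended -- and only
      # when the affected samples form a contiguous run of exactly one
      # platform's processing sequence (the structural signature of a slip)
      if (length(cr$samples) < 3) return(FALSE)
      on_e <- contiguous_on(map, cr$samples, "expression")
      on_g <- contiguous_on(map, cr$samples, "genotype")
      if (on_e == on_g) return(FALSE)
      pr <- cr$pairing
      r1 <- ranks[cbind(pr$expr_array, pr$matched_geno)]
      all(!is.na(r1) & r1 == 1L) &&
        all(zsep[pr$expr_array] >= config$accept_z, na.rm = TRUE)
    } else FALSE
  }

  proposed <- c(transforms, cc$cycles, cc$chains)
  claimed <- character()
  arrays_of <- function(cr) {
    if (!is.null(cr$new_assignment))
      c(stats::na.omit(cr$new_assignment$array),
        unname(stats::na.omit(e_of[cr$samples])))
    else unique(c(unlist(cr$pairing[c("expr_array", "matched_geno")]),
                  cr$arrays))
  }
  g_of <- stats::setNames(map$genotype_array, map$sample_id)
  accepted <- list()
  for (cr in proposed) {
    a <- c(arrays_of(cr),
           unname(stats::na.omit(e_of[cr$samples])),
           unname(stats::na.omit(g_of[cr$samples])))
    if (any(a %in% claimed)) next
    if (!passes(cr)) next
    claimed <- c(claimed, a)
    accepted[[length(accepted) + 1L]] <- cr
  }
  # chains orphan an array, which is irreversible within the loop; only act
  # on them once no other correction is pending, i.e. after the eQTL set has
  # been re-learnt from the already-corrected map and scores are at full
  # strength
  is_chain <- vapply(accepted, function(cr)
    cr$type == "chain/slippage", logical(1))
  if (any(is_chain) && !all(is_chain)) accepted <- accepted[!is_chain]
  list(proposed = proposed, accepted = accepted,
       orphans = c(cc$orphans, cc$duplicates))
}
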