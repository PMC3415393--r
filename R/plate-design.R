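# Sex-based plate-layout design: patterns, the neighbour-pair combinatorics
# of an 8 x 12 plate, rotational distinctness, and random-layout simulations.

#' Generate a sex pattern for an 8 x 12 plate
#'
#' Patterns for laying out equal numbers of male and female samples so that
#' inferred sexes diagnose use of the wrong plate or orientation:
#' \describe{
#'   \item{blocked_12221}{rows form blocks of sizes 1,2,2,2,1 with the sex
#'     phase alternating between blocks, and adjacent columns complementary.
#'     The unequal end blocks break the 180-degree rotational symmetry that a
#'     2-2-2-2 blocking would have.}
#'   \item{permuted_columns}{a permutation (default `rep(1:4, 3)`) of four
#'     basic column patterns; supply `permutation` (length 12) and optionally
#'     `columns` (list of four 8-vectors of 0/1) to pick a design.}
#'   \item{chequerboard}{alternation in both directions; minimises same-sex
#'     neighbour pairs but is symmetric under rotation.}
#'   \item{random}{uniform balanced (48/48) permutation.}
#' }
#'
#' @param kind one of `"blocked_12221"`, `"permuted_columns"`,
#'   `"chequerboard"`, `"random"`.
#' @param seed RNG seed (used by `"random"`).
#' @param permutation,columns see `permuted_columns`.
#' @param plate_id identifier for the returned layout.
#' @return a [plate_layout()] with the sex grid filled (samples empty).
#' @export
generate_pattern <- function(kind = c("blocked_12221", "permuted_columns",
                                      "chequerboard", "random"),
                             seed = NULL, permutation = rep(1:4, 3),
                             columns = NULL, plate_id = kind) {
  kind <- match.arg(kind)
  sexes <- c("male", "female")
  grid <- matrix(0L, PLATE_NROW, PLATE_NCOL)
  if (kind == "blocked_12221") {
    phase <- rep(c(0L, 1L, 0L, 1L, 0L), times = c(1, 2, 2, 2, 1))
    grid <- outer(phase, (seq_len(PLATE_NCOL) - 1L) %% 2L, function(a, b)
      (a + b) %% 2L)
  } else if (kind == "chequerboard") {
    grid <- outer(seq_len(PLATE_NROW), seq_len(PLATE_NCOL), function(r, c)
      (r + c) %% 2L)
  } else if (kind == "permuted_columns") {
    if (is.null(columns)) {
      phase <- rep(c(0L, 1L, 0L, 1L, 0L), times = c(1, 2, 2, 2, 1))
      shifted <- rep(c(1L, 0L, 1L, 0L, 1L), times = c(2, 2, 2, 1, 1))
      columns <- list(phase, 1L - phase, shifted, 1L - shifted)
    }
    if (length(permutation) != PLATE_NCOL)
      stop("permutation must have length 12")
    grid <- sapply(permutation, function(k) columns[[k]])
  } else {
    if (!is.null(seed)) set.seed(seed)
    grid <- matrix(sample(rep(0:1, each = 48)), PLATE_NROW, PLATE_NCOL)
  }
  if (sum(grid) != 48L)
    stop("pattern is not balanced 48/48")
  plate_layout(sex = matrix(sexes[grid + 1L], PLATE_NROW, PLATE_NCOL),
               plate_id = plate_id)
}

# the 172 orthogonal neighbour pairs of an 8 x 12 grid, as index pairs into
# the column-major well vector (88 horizontal + 84 vertical)
neighbour_index_pairs <- function() {
  idx <- matrix(seq_len(PLATE_NROW * PLATE_NCOL), PLATE_NROW, PLATE_NCOL)
  horiz <- cbind(as.vector(idx[, -PLATE_NCOL]), as.vector(idx[, -1]))
  vert <- cbind(as.vector(idx[-PLATE_NROW, ]), as.vector(idx[-1, ]))
  rbind(horiz, vert)
}

#' Count orthogonally adjacent same-sex well pairs
#'
#' An 8 x 12 plate has 172 orthogonal neighbour pairs (88 horizontal, 84
#' vertical, diagonals ignored); a simple switch of two neighbouring
#' same-sex samples is invisible to a sex check, so this count is the number
#' of undetectable simple switches for the layout.
#'
#' @param layout a [plate_layout()] (or an 8 x 12 sex matrix).
#' @return integer in `[0, 172]`.
#' @export
count_same_sex_pairs <- function(layout) {
  sex <- if (inherits(layout, "plate_layout")) layout$sex else as.matrix(layout)
  v <- as.vector(sex)
  np <- neighbour_index_pairs()
  sum(v[np[, 1]] == v[np[, 2]])
}

rotate180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]

#' Flag layouts confusable under 180-degree rotation
#'
#' A layout is flagged when it equals the 180-degree rotation of itself, of
#' another supplied layout, or of any layout's sex-inverse (the inverse of a
#' design can be identical to the original under rotation, in which case
#' using both on different plates invites confusion).
#'
#' @param layouts list of [plate_layout()] objects (or sex matrices).
#' @return data.frame with columns `layout_a`, `layout_b`, `relation`; zero
#'   rows when all layouts are rotationally distinct.
#' @export
check_rotational_distinctness <- function(layouts) {
  if (!is.list(layouts)) layouts <- list(layouts)
  sexes <- lapply(layouts, function(l)
    unname(if (inherits(l, "plate_layout")) l$sex else as.matrix(l)))
  ids <- vapply(seq_along(layouts), function(i) {
    l <- layouts[[i]]
    if (inherits(l, "plate_layout")) l$plate_id else as.character(i)
  }, character(1))
  inv <- function(m) ifelse(m == "male", "female",
                            ifelse(m == "female", "male", m))
  out <- NULL
  add <- function(i, j, rel) {
    out <<- rbind(out, data.frame(layout_a = ids[i], layout_b = ids[j],
                                  relation = rel, stringsAsFactors = FALSE))
  }
  for (i in seq_along(sexes)) {
    if (identical(sexes[[i]], rotate180(sexes[[i]])))
      add(i, i, "self-symmetric under 180-degree rotation")
    if (identical(inv(sexes[[i]]), rotate180(sexes[[i]])))
      add(i, i, "inverse identical under 180-degree rotation")
    if (i < length(sexes)) for (j in (i + 1):length(sexes)) {
      if (identical(sexes[[i]], rotate180(sexes[[j]])))
        add(i, j, "rotation of each other")
      if (identical(sexes[[i]], sexes[[j]]))
        add(i, j, "identical")
    }
  }
  if (is.null(out))
    out <- data.frame(layout_a = character(), layout_b = character(),
                      relation = character(), stringsAsFactors = FALSE)
  out
}

#' Simulate the behaviour of random balanced sex layouts
#'
#' Per replicate, `n_plates` independent uniformly random balanced (48/48)
#' layouts are drawn; the same-sex neighbour-pair count of every plate and
#' the minimum over all plate pairs of the number of differing wells are
#' recorded.  Two balanced layouts differing in d wells can be explained by
#' a minimum of d/2 simple switches (each switch changes two wells).
#'
#' @param n_plates plates per replicate (`>= 2`).
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @return list with `mean_same_sex` (over all simulated plates),
#'   `sd_same_sex`, `n_layouts`, `min_diff` (per-replicate minima, wells),
#'   `min_diff_median` (central estimate), `min_diff_ci` (2.5/97.5
#'   percentiles), `min_swaps_median` (= median difference / 2).
#' @export
simulate_random_layout_stats <- function(n_plates = 100L, n_reps = 200L,
                                         seed = 1L) {
  if (n_plates < 2) stop("need at least 2 plates")
  set.seed(seed)
  np <- neighbour_index_pairs()
  n_wells <- PLATE_NROW * PLATE_NCOL
  base <- rep(c(1, 0), each = n_wells / 2)
  same_sex <- numeric(0)
  min_diff <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    X <- t(vapply(seq_len(n_plates), function(i) sample(base),
                  numeric(n_wells)))
    same_sex <- c(same_sex, rowSums(X[, np[, 1]] == X[, np[, 2]]))
    M <- tcrossprod(X, 1 - X)       # wells where a has 1, b has 0
    D <- M + t(M)
    min_diff[r] <- min(D[upper.tri(D)])
  }
  list(mean_same_sex = mean(same_sex),
       sd_same_sex = stats::sd(same_sex),
       n_layouts = length(same_sex),
       min_diff = min_diff,
       min_diff_median = stats::median(min_diff),
       min_diff_ci = stats::quantile(min_diff, c(0.025, 0.975)),
       min_swaps_median = stats::median(min_diff) / 2)
}

#' Diagnose a plate from inferred sample sexes
#'
#' Compares the sexes inferred for each well (supplied externally, e.g. from
#' genotype heterozygosity) against the expected layout and any alternate
#' plates' layouts, under the identity and 180-degree rotation, and reports
#' the explanation with fewest mismatching wells.
#'
#' @param expected a [plate_layout()] (or sex matrix) for the intended plate.
#' @param inferred 8 x 12 matrix of inferred sexes (`"unknown"` ignored).
#' @param alternates optional named list of other plates' layouts.
#' @return list with `best` (label of best explanation), `mismatches`
#'   (wells disagreeing under the best explanation) and `table` (mismatch
#'   count per candidate explanation).
#' @export
sex_check_diagnostic <- function(expected, inferred, alternates = list()) {
  get_sex <- function(l) if (inherits(l, "plate_layout")) l$sex else as.matrix(l)
  inferred <- as.matrix(inferred)
  if (!all(dim(inferred) == c(PLATE_NROW, PLATE_NCOL)))
    stop("inferred sexes must form an 8 x 12 grid")
  cands <- list(identity = get_sex(expected),
                rotate180 = rotate180(get_sex(expected)))
  for (nm in names(alternates)) {
    cands[[paste0("plate:", nm)]] <- get_sex(alternates[[nm]])
    cands[[paste0("plate:", nm, ":rotate180")]] <-
      rotate180(get_sex(alternates[[nm]]))
  }
  usable <- inferred != "unknown"
  counts <- vapply(cands, function(m) sum(m[usable] != inferred[usable]),
                   numeric(1))
  best <- names(counts)[which.min(counts)]
  mm <- which(cands[[best]] != inferred & usable, arr.ind = TRUE)
  list(best = best,
       mismatches = if (nrow(mm)) rc_to_well(mm[, 1], mm[, 2]) else character(),
       table = counts)
}
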