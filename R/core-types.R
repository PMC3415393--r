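#' @keywords internal
"_PACKAGE"

# ---- shared constants -------------------------------------------------------

PLATE_NROW <- 8L
PLATE_NCOL <- 12L
PLATE_ROWS <- LETTERS[1:8]
QUALITY_TIERS <- c("perfect", "good", "other", "intergenic")

#' Construct an expression matrix with probe annotation
#'
#' Container for log2-intensity values, rows indexed by expression probes and
#' columns by expression arrays.  The probe annotation carries the genomic
#' anchor of each probe, its design-quality tier and the number of known SNPs
#' under the probe sequence (the driver of cis-eQTL artefacts, which are
#' exploited as identity signals).
#'
#' @param values numeric matrix (probes x arrays) of log2 intensities; `NA`
#'   encodes missing.
#' @param probe_annotation data.frame with columns `probe_id`, `chromosome`,
#'   `position` (1-based bp), `quality_tier` (one of `"perfect"`, `"good"`,
#'   `"other"`, `"intergenic"`) and `n_snps_under_probe` (non-negative
#'   integer).  Row order must match `rownames(values)`.
#' @return object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, probe_annotation) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate expression array ids")
  probe_annotation <- as.data.frame(probe_annotation,
                                    stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "position", "quality_tier",
            "n_snps_under_probe")
  if (!all(need %in% names(probe_annotation)))
    stop("probe_annotation must have columns: ", paste(need, collapse = ", "))
  probe_annotation <- probe_annotation[
    match(rownames(values), probe_annotation$probe_id), , drop = FALSE]
  if (anyNA(probe_annotation$probe_id))
    stop("probe_annotation is missing some probes present in values")
  if (any(probe_annotation$n_snps_under_probe < 0, na.rm = TRUE))
    stop("n_snps_under_probe must be non-negative")
  bad <- setdiff(unique(probe_annotation$quality_tier), QUALITY_TIERS)
  if (length(bad))
    stop("unknown quality tier(s): ", paste(bad, collapse = ", "))
  rownames(probe_annotation) <- NULL
  structure(list(values = values, probe_annotation = probe_annotation),
            class = "expression_matrix")
}

#' Construct a genotype matrix of B-allele counts
#'
#' Rows are biallelic SNPs, columns genotype arrays.  Entries are B-allele
#' counts under a diploid model: 0 (AA), 1 (AB), 2 (BB) or `NA` (no call).
#' Which allele is "B" is the caller's convention and must be applied
#' consistently; a flipped SNP only mirrors its residuals (0 and 2 exchange).
#'
#' @param values matrix of values in `{0, 1, 2, NA}` (SNPs x arrays).
#' @param snp_annotation data.frame with columns `snp_id`, `chromosome`,
#'   `position` (1-based bp).
#' @return object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(values, snp_annotation) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate snp ids")
  if (anyDuplicated(colnames(values))) stop("duplicate genotype array ids")
  ok <- is.na(values) | values %in% 0:2
  if (!all(ok))
    stop("genotype values must be 0, 1, 2 or NA")
  snp_annotation <- as.data.frame(snp_annotation, stringsAsFactors = FALSE)
  need <- c("snp_id", "chromosome", "position")
  if (!all(need %in% names(snp_annotation)))
    stop("snp_annotation must have columns: ", paste(need, collapse = ", "))
  snp_annotation <- snp_annotation[
    match(rownames(values), snp_annotation$snp_id), , drop = FALSE]
  if (anyNA(snp_annotation$snp_id))
    stop("snp_annotation is missing some SNPs present in values")
  rownames(snp_annotation) <- NULL
  structure(list(values = values, snp_annotation = snp_annotation),
            class = "genotype_matrix")
}

#' Construct a sample map
#'
#' Records the intended association between samples and the arrays they were
#' (supposedly) run on, together with per-stage plate/well provenance used to
#' attribute plating errors to a platform.  A sample may lack an array on
#' either platform (`NA`), and duplicate genotype arrays for one sample are
#' representable as repeated rows (they set the replicate parameter `g` of the
#' gap statistic).
#'
#' @param records data.frame with columns `sample_id`, `expression_array`,
#'   `genotype_array` (both possibly `NA`), `tissue` (`"tumour"` or
#'   `"normal"`), and optionally `trusted` (logical; arrays whose pairing is
#'   known to be correct, e.g. a pilot subset).
#' @param provenance data.frame with columns `sample_id`, `platform`
#'   (`"expression"` or `"genotype"`), `stage`, `stage_index`, `plate_id`,
#'   `well` (e.g. `"A1"`; expression BeadChip positions use wells `"A1"` ..
#'   `"A12"` of a 1 x 12 strip), `position` (ordinal within the platform's
#'   processing sequence, used for slippage hypotheses).
#' @return object of class `"sample_map"` (a data.frame with a `provenance`
#'   attribute).
#' @export
sample_map <- function(records, provenance = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("sample_id", "expression_array", "genotype_array", "tissue")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (!"trusted" %in% names(records)) records$trusted <- FALSE
  if (!is.null(provenance)) {
    provenance <- as.data.frame(provenance, stringsAsFactors = FALSE)
    pneed <- c("sample_id", "platform", "stage", "stage_index", "plate_id",
               "well", "position")
    if (!all(pneed %in% names(provenance)))
      stop("provenance must have columns: ", paste(pneed, collapse = ", "))
    badw <- !grepl("^[A-H](1[0-2]|[1-9])$", provenance$well)
    if (any(badw))
      stop("syntactically invalid wells: ",
           paste(unique(provenance$well[badw]), collapse = ", "))
  }
  structure(records, provenance = provenance,
            class = c("sample_map", "data.frame"))
}

#' @export
print.sample_map <- function(x, ...) {
  cat(sprintf("sample_map: %d records, %d expression arrays, %d genotype arrays, %d intended pairs\n",
              nrow(x), sum(!is.na(x$expression_array)),
              sum(!is.na(x$genotype_array)),
              sum(!is.na(x$expression_array) & !is.na(x$genotype_array))))
  NextMethod()
}

#' Numbers of arrays and intended pairs in a sample map
#'
#' @param map a [sample_map()].
#' @return list with `l` (expression arrays), `m` (genotype arrays) and `n`
#'   (intended matched pairs); always `n <= min(l, m)`.
#' @export
map_counts <- function(map) {
  l <- length(unique(stats::na.omit(map$expression_array)))
  m <- length(unique(stats::na.omit(map$genotype_array)))
  n <- sum(!is.na(map$expression_array) & !is.na(map$genotype_array))
  list(l = l, m = m, n = n)
}

#' Construct an 8 x 12 plate layout
#'
#' @param samples 8 x 12 character matrix of sample ids (`NA` = empty well);
#'   row 1 is plate row A, column 1 is plate column 1, A1 top-left.
#' @param sex 8 x 12 character matrix with entries `"male"`, `"female"` or
#'   `"unknown"`.
#' @param plate_id scalar identifier.
#' @return object of class `"plate_layout"`.
#' @export
plate_layout <- function(samples = matrix(NA_character_, PLATE_NROW, PLATE_NCOL),
                         sex = matrix("unknown", PLATE_NROW, PLATE_NCOL),
                         plate_id = "plate-1") {
  samples <- as.matrix(samples); sex <- as.matrix(sex)
  if (!all(dim(samples) == c(PLATE_NROW, PLATE_NCOL)) ||
      !all(dim(sex) == c(PLATE_NROW, PLATE_NCOL)))
    stop("plate layouts are exactly 8 rows (A-H) x 12 columns (1-12)")
  if (!all(sex %in% c("male", "female", "unknown")))
    stop("sex entries must be male/female/unknown")
  dimnames(samples) <- dimnames(sex) <- list(PLATE_ROWS, as.character(1:PLATE_NCOL))
  structure(list(plate_id = plate_id, samples = samples, sex = sex),
            class = "plate_layout")
}

# well string <-> (row, column) indices; A1 is (1, 1)
well_to_rc <- function(well) {
  r <- match(substr(well, 1, 1), PLATE_ROWS)
  c <- as.integer(substring(well, 2))
  cbind(row = r, col = c)
}

rc_to_well <- function(row, col) paste0(PLATE_ROWS[row], col)

#' Validate an expression/genotype/sample-map triple
#'
#' Checks cross-references and invariants without raising: every array id in
#' the map must exist in the corresponding matrix, genotype values must lie in
#' the B-allele-count domain, and duplicate arrays are flagged (informational,
#' since replicate genotype arrays are legitimate and feed the gap statistic's
#' replicate parameter).
#'
#' @param expr an [expression_matrix()].
#' @param geno a [genotype_matrix()].
#' @param map a [sample_map()].
#' @return character vector of issues; empty when everything is consistent.
#' @export
validate_inputs <- function(expr, geno, map) {
  issues <- character()
  ea <- stats::na.omit(map$expression_array)
  ga <- stats::na.omit(map$genotype_array)
  miss_e <- setdiff(ea, colnames(expr$values))
  if (length(miss_e))
    issues <- c(issues, paste0("expression array not in matrix: ", miss_e))
  miss_g <- setdiff(ga, colnames(geno$values))
  if (length(miss_g))
    issues <- c(issues, paste0("genotype array not in matrix: ", miss_g))
  bad <- !(is.na(geno$values) | geno$values %in% 0:2)
  if (any(bad))
    issues <- c(issues, sprintf(
      "genotype matrix holds %d value(s) outside {0,1,2,NA}", sum(bad)))
  if (any(!is.finite(expr$values) & !is.na(expr$values)))
    issues <- c(issues, "expression matrix holds non-finite values")
  dup_g <- unique(ga[duplicated(ga)])
  if (length(dup_g))
    issues <- c(issues, paste0("genotype array mapped more than once: ", dup_g))
  dup_s <- map$sample_id[duplicated(map$sample_id)]
  if (length(dup_s))
    issues <- c(issues, paste0(
      "sample with multiple records (replicate arrays): ", unique(dup_s)))
  cts <- map_counts(map)
  if (cts$n > min(cts$l, cts$m))
    issues <- c(issues, "more intended pairs than arrays on a platform")
  issues
}
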