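# Readers and writers: TSV matrices (first column = feature id, header =
# array ids), CSV sample maps and plate layouts, JSON eQTL sets and mix-up
# reports, and VCF import of genotypes.

#' @name badger-io
#' @title File formats
#' @description
#' Native formats round-trip losslessly: expression and genotype matrices as
#' TSV with an annotation sidecar, sample maps and plate layouts as CSV,
#' eQTL sets and mix-up reports as JSON.  Genotypes may also be imported
#' from VCF (`GT` converted to B-allele counts; multi-allelic sites skipped
#' with a warning).  Matrix readers are gzip-transparent.
NULL

#' @rdname badger-io
#' @param expr an [expression_matrix()].
#' @param path main output/input file.
#' @param annotation_path sidecar annotation file (defaults to
#'   `<path>.annotation.tsv`).
#' @export
write_expression_matrix <- function(expr, path,
                                    annotation_path = paste0(path, ".annotation.tsv")) {
  df <- data.frame(probe_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$probe_annotation, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname badger-io
#' @export
read_expression_matrix <- function(path,
                                   annotation_path = paste0(path, ".annotation.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = c(probe_id = "character",
                                          chromosome = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, ann)
}

#' @rdname badger-io
#' @param geno a [genotype_matrix()].
#' @export
write_genotype_matrix <- function(geno, path,
                                  annotation_path = paste0(path, ".annotation.tsv")) {
  df <- data.frame(snp_id = rownames(geno$values), geno$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(geno$snp_annotation, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname badger-io
#' @export
read_genotype_matrix <- function(path,
                                 annotation_path = paste0(path, ".annotation.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = c(snp_id = "character",
                                          chromosome = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(is.na(m) | m %in% 0:2), arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid genotype value(s) at data line(s) ",
         paste(unique(bad[, 1] + 1L), collapse = ", "), " of ", path)
  rownames(m) <- df[[1]]
  genotype_matrix(m, ann)
}

#' Import genotypes from a VCF file as B-allele counts
#'
#' The `GT` field is converted to the count of ALT ("B") alleles: `0/0` -> 0,
#' `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> missing (phased separators
#' equivalent).  Multi-allelic sites are skipped with a warning naming the
#' count skipped.
#'
#' @param path a VCF file (plain or gzipped).
#' @return a [genotype_matrix()] whose columns are the VCF sample columns.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt_core <- gsub("\\|", "/", gt)
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  counts[] <- lut[gt_core]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  rownames(counts) <- ids
  genotype_matrix(counts, data.frame(
    snp_id = ids, chromosome = as.character(fix[, "CHROM"]),
    position = as.integer(fix[, "POS"]), stringsAsFactors = FALSE))
}

#' @rdname badger-io
#' @param map a [sample_map()].
#' @param provenance_path sidecar CSV for provenance (defaults to
#'   `<path>.provenance.csv`).
#' @export
write_sample_map <- function(map, path,
                             provenance_path = paste0(path, ".provenance.csv")) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, na = "")
  prov <- attr(map, "provenance")
  if (!is.null(prov))
    utils::write.csv(prov, provenance_path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname badger-io
#' @export
read_sample_map <- function(path,
                            provenance_path = paste0(path, ".provenance.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$trusted <- as.logical(df$trusted)
  prov <- if (file.exists(provenance_path))
    utils::read.csv(provenance_path, stringsAsFactors = FALSE, na.strings = "")
  else NULL
  sample_map(df, provenance = prov)
}

#' @rdname badger-io
#' @param layout a [plate_layout()].
#' @export
write_plate_layout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("plate_id,", layout$plate_id), con)
  emit <- function(m, label) {
    writeLines(paste0(label, ",", paste(1:PLATE_NCOL, collapse = ",")), con)
    for (r in seq_len(PLATE_NROW)) {
      v <- m[r, ]; v[is.na(v)] <- ""
      writeLines(paste(c(PLATE_ROWS[r], v), collapse = ","), con)
    }
  }
  emit(layout$samples, "samples")
  emit(layout$sex, "sex")
  invisible(path)
}

#' @rdname badger-io
#' @export
read_plate_layout <- function(path) {
  lines <- readLines(path)
  plate_id <- sub("^plate_id,", "", lines[1])
  grab <- function(label) {
    at <- which(lines == paste0(label, ",", paste(1:PLATE_NCOL, collapse = ",")))
    if (length(at) != 1)
      stop("malformed plate layout at line ", at, ": missing ", label, " block")
    block <- lines[(at + 1):(at + PLATE_NROW)]
    m <- do.call(rbind, strsplit(block, ",", fixed = TRUE))
    rows <- m[, 1]
    if (!identical(rows, PLATE_ROWS))
      stop("malformed plate rows near line ", at + 1)
    vals <- m[, -1, drop = FALSE]
    vals <- cbind(vals, matrix("", nrow = PLATE_NROW,
                               ncol = PLATE_NCOL - ncol(vals)))
    vals[vals == ""] <- NA
    vals
  }
  samples <- grab("samples")
  sex <- grab("sex")
  sex[is.na(sex)] <- "unknown"
  plate_layout(samples = samples, sex = sex, plate_id = plate_id)
}

#' @rdname badger-io
#' @param set an `"eqtl_set"`.
#' @export
write_eqtl_set <- function(set, path) {
  obj <- list(pairs = set$pairs,
              class_counts = as.data.frame(set$class_counts),
              densities = lapply(set$densities, function(dl)
                lapply(dl, function(d) if (is.null(d)) NULL else
                  list(x = d$x, y = d$y, bw = d$bw, n = d$n))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname badger-io
#' @export
read_eqtl_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cell <- function(v) if (is.null(v)) NA else v
  pairs <- do.call(rbind, lapply(obj$pairs, function(r)
    as.data.frame(lapply(r, cell), stringsAsFactors = FALSE)))
  cc <- do.call(rbind, lapply(obj$class_counts, function(r)
    vapply(r[c("AA", "AB", "BB")], function(v) as.integer(cell(v)),
           integer(1))))
  densities <- lapply(obj$densities, function(dl) {
    out <- lapply(c("AA", "AB", "BB"), function(g) {
      d <- dl[[g]]
      if (is.null(d) || is.null(d$x)) NULL
      else list(x = as.numeric(unlist(d$x)), y = as.numeric(unlist(d$y)),
                bw = as.numeric(d$bw), n = as.integer(d$n))
    })
    names(out) <- c("AA", "AB", "BB")
    out
  })
  structure(list(pairs = pairs, densities = densities, class_counts = cc),
            class = "eqtl_set")
}

#' @rdname badger-io
#' @param report a `"mixup_report"`.
#' @export
write_mixup_report <- function(report, path) {
  ser <- list(
    converged = report$converged,
    productive_iterations = report$productive_iterations,
    corrections = lapply(report$corrections, function(cr)
      list(type = cr$type, platform = cr$platform %||% "undetermined",
           samples = cr$samples,
           arrays = cr$arrays %||% NULL,
           transform = cr$transform %||% NULL,
           gain = cr$gain %||% NULL,
           new_assignment = cr$new_assignment,
           alien_arrays = cr$alien_arrays %||% character(),
           iteration = cr$iteration %||% NULL)),
    unresolved = report$unresolved[, c("sample_id", "expression_array",
                                       "genotype_array")],
    orphans = lapply(report$orphans, function(o)
      list(type = o$type, samples = o$samples, arrays = o$arrays,
           note = o$note %||% NULL)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
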