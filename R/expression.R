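#' Expression matrix container
#'
#' A light genes-by-samples matrix with a scale tag: `"counts"` for raw
#' (non-negative) counts, `"log"` for log2 intensities or log2-CPM. Gene and
#' sample identifiers live in the dimnames and must be unique.
#'
#' @param values Numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param scale `"counts"` or `"log"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale = c("log", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop2("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop2("'values' needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop2("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop2("duplicate sample ids")
  if (anyNA(values)) stop2("missing values in expression matrix")
  if (scale == "counts" && any(values < 0)) {
    stop2("counts-scale matrix must be non-negative")
  }
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @method print expression_matrix
#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", x$scale, " scale)\n", sep = "")
  invisible(x)
}

#' @method dim expression_matrix
#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Load an expression matrix from TSV or MatrixMarket
#'
#' TSV layout: header row of sample ids, first column of gene ids. MTX input
#' expects sidecar id files `<path>.rows` and `<path>.cols` (one id per line).
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`; default guessed from the extension.
#' @param scale Declared scale of the values (`"log"` or `"counts"`).
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, format = c("auto", "tsv", "mtx"),
                            scale = c("log", "counts")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop2("expression file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes)) stop2("duplicate gene ids in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  } else {
    rows_f <- paste0(path, ".rows")
    cols_f <- paste0(path, ".cols")
    if (!file.exists(rows_f) || !file.exists(cols_f)) {
      stop2("mtx input needs sidecar id files ", rows_f, " and ", cols_f)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(rows_f, warn = FALSE)
    samples <- readLines(cols_f, warn = FALSE)
    if (nrow(m) != length(genes) || ncol(m) != length(samples)) {
      stop2("mtx dimensions do not match sidecar id files")
    }
    dimnames(m) <- list(genes, samples)
  }
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix as TSV (gene_id column + sample columns)
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Required columns: `sample_id`, `compound`, `dose_multiple` (in multiples
#' of the clinical C_max), `group` (`treatment`/`control`), `donor`.
#'
#' @param path CSV file path, or a data.frame to validate in place.
#' @param m Optional [expression_matrix()]; when given, every sample_id must
#'   be a column of the matrix.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path, m = NULL) {
  design <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "compound", "dose_multiple", "group", "donor")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop2("sample sheet lacks column(s): ",
                          paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  if (anyDuplicated(design$sample_id)) stop2("duplicate sample_id in sample sheet")
  if (!all(design$group %in% c("treatment", "control"))) {
    stop2("'group' must be 'treatment' or 'control'")
  }
  design$dose_multiple <- as.numeric(design$dose_multiple)
  if (anyNA(design$dose_multiple) || any(design$dose_multiple < 0)) {
    stop2("'dose_multiple' must be numeric and >= 0")
  }
  if (!is.null(m)) {
    missing_s <- setdiff(design$sample_id, colnames(m$values))
    if (length(missing_s)) {
      stop2("sample(s) absent from expression matrix: ",
            paste(missing_s, collapse = ", "))
    }
  }
  design
}

#' Collapse probe-level rows to gene level
#'
#' For each gene, keeps verbatim the row of the probe with the highest mean
#' intensity across all samples; ties keep the probe appearing first in
#' input order. Unmapped probes are dropped (count reported via message).
#'
#' @param m Log-scale [expression_matrix()] with probe-level rownames.
#' @param probe_to_gene Data.frame with columns `source_id` (probe) and
#'   `target_id` (gene); a probe must map to exactly one gene.
#' @return Gene-level [expression_matrix()].
#' @export
collapse_probes <- function(m, probe_to_gene) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log") stop2("collapse_probes expects a log-scale matrix")
  map <- validate_mapping(probe_to_gene)
  if (anyDuplicated(map$source_id)) {
    stop2("a probe maps to more than one gene; resolve the mapping first")
  }
  probes <- rownames(m$values)
  map <- map[map$source_id %in% probes, , drop = FALSE]
  if (nrow(map) == 0L) stop2("no probe in the matrix is present in the mapping")
  n_unmapped <- sum(!probes %in% map$source_id)
  if (n_unmapped > 0L) message(n_unmapped, " unmapped probe(s) dropped")
  means <- rowMeans(m$values)
  # stable: first probe in input order wins ties via order() stability
  ord <- order(match(map$source_id, probes))
  map <- map[ord, , drop = FALSE]
  keep <- character(0)
  best <- tapply(seq_len(nrow(map)), map$target_id, function(idx) {
    pm <- means[map$source_id[idx]]
    idx[which.max(pm)]  # which.max returns the first maximum
  })
  sel <- map$source_id[unlist(best)]
  genes <- map$target_id[unlist(best)]
  out <- m$values[sel, , drop = FALSE]
  rownames(out) <- genes
  # restore input row order of selected probes
  o <- order(match(sel, probes))
  expression_matrix(out[o, , drop = FALSE], scale = "log")
}

#' Map gene identifiers across species (one-to-one orthologs only)
#'
#' Genes mapping to zero or to multiple targets, and targets hit by multiple
#' sources, are dropped (counts reported via message); nothing is aggregated.
#'
#' @param m An [expression_matrix()] with source-species gene ids.
#' @param orthologs Data.frame with columns `source_id`, `target_id`.
#' @return An [expression_matrix()] with target ids.
#' @export
map_orthologs <- function(m, orthologs) {
  stopifnot(inherits(m, "expression_matrix"))
  map <- validate_mapping(orthologs)
  map <- map[map$source_id %in% rownames(m$values), , drop = FALSE]
  multi_src <- unique(map$source_id[duplicated(map$source_id)])
  multi_tgt <- unique(map$target_id[duplicated(map$target_id)])
  drop <- map$source_id %in% multi_src | map$target_id %in% multi_tgt
  n_amb <- length(unique(map$source_id[drop]))
  map <- map[!drop, , drop = FALSE]
  if (nrow(map) == 0L) stop2("ortholog mapping empty after one-to-one filtering")
  n_unmapped <- sum(!rownames(m$values) %in% map$source_id) - n_amb
  if (n_amb > 0L) message(n_amb, " ambiguously mapped gene(s) dropped")
  if (n_unmapped > 0L) message(n_unmapped, " unmapped gene(s) dropped")
  out <- m$values[map$source_id, , drop = FALSE]
  rownames(out) <- map$target_id
  expression_matrix(out, scale = m$scale)
}

validate_mapping <- function(map) {
  need <- c("source_id", "target_id")
  if (!all(need %in% names(map))) {
    stop2("mapping table needs columns source_id and target_id")
  }
  map$source_id <- trimws(as.character(map$source_id))
  map$target_id <- trimws(as.character(map$target_id))
  if (anyDuplicated(map[need])) stop2("duplicate (source, target) pairs in mapping")
  map
}

#' Transform counts to log2 counts-per-million
#'
#' `log2((count + prior) / (lib + 2 * prior) * 1e6)` per cell, where `lib` is
#' the column sum of raw counts. The fixed prior keeps the transform exactly
#' scale-invariant at `prior_count = 0`.
#'
#' @param m Counts-scale [expression_matrix()].
#' @param prior_count Pseudo-count added to each value (default 0.5).
#' @return Log-scale [expression_matrix()].
#' @export
log_cpm <- function(m, prior_count = 0.5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "counts") stop2("log_cpm expects a counts-scale matrix")
  lib <- colSums(m$values)
  if (any(lib <= 0)) stop2("zero library size in sample(s): ",
                           paste(colnames(m$values)[lib <= 0], collapse = ", "))
  v <- log2(sweep(m$values + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
  expression_matrix(v, scale = "log")
}
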