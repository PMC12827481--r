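#' Gene signatures: transcription-factor regulons plus their combined set
#'
#' A `gene_signature` is a named list of gene sets: one set per transcription
#' factor (TF) regulon and, when built with [build_signature()], a combined
#' set named `"AEGIS_combined"` equal to the deduplicated union of the per-TF
#' sets. Gene identity is a case-sensitive symbol match after whitespace
#' trimming; no alias resolution is attempted.
#'
#' @param sets Named list of character vectors; every set must be non-empty
#'   and free of within-set duplicates.
#' @param provenance Free-text provenance string.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(sets, provenance = "") {
  if (!is.list(sets) || length(sets) == 0L || is.null(names(sets)) ||
      any(!nzchar(names(sets)))) {
    stop2("'sets' must be a non-empty named list of gene vectors")
  }
  if (anyDuplicated(names(sets))) stop2("duplicate set names in signature")
  sets <- lapply(sets, function(g) trimws(as.character(g)))
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (length(g) == 0L) stop2("set '", nm, "' is empty")
    if (anyDuplicated(g)) stop2("set '", nm, "' contains duplicated genes")
    if (any(!nzchar(g))) stop2("set '", nm, "' contains blank gene symbols")
  }
  structure(list(sets = sets, provenance = as.character(provenance)),
            class = "gene_signature")
}

#' @method print gene_signature
#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature with", length(x$sets), "set(s)\n")
  for (nm in names(x$sets)) cat("  ", nm, ": ", length(x$sets[[nm]]),
                                " genes\n", sep = "")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Name of the combined (union) set in built signatures
#' @export
AEGIS_COMBINED <- "AEGIS_combined"

evidence_levels <- c("A", "B", "C", "D", "E")

#' Read a regulon table
#'
#' Expects a TSV with header and columns `tf`, `target`, `evidence` and
#' optionally `mode` (+1/-1). Evidence levels are the letters A-E, ordered
#' A < B < C < D < E (A strongest). Duplicate (tf, target) pairs are an error.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with columns tf, target, evidence (and mode if given).
#' @export
read_regulons <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_regulons(df)
}

#' @rdname read_regulons
#' @param regulons A data.frame to validate in place of a file.
#' @export
validate_regulons <- function(regulons) {
  need <- c("tf", "target", "evidence")
  miss <- setdiff(need, names(regulons))
  if (length(miss)) stop2("regulon table lacks column(s): ",
                          paste(miss, collapse = ", "))
  regulons$tf <- trimws(as.character(regulons$tf))
  regulons$target <- trimws(as.character(regulons$target))
  regulons$evidence <- trimws(as.character(regulons$evidence))
  bad <- !regulons$evidence %in% evidence_levels
  if (any(bad)) stop2("invalid evidence level(s): ",
                      paste(unique(regulons$evidence[bad]), collapse = ", "))
  if (anyDuplicated(regulons[c("tf", "target")])) {
    stop2("duplicate (tf, target) pairs in regulon table")
  }
  regulons
}

#' Build a TF-regulon gene signature
#'
#' Selects the requested TFs that are expressed above `tpm_threshold` in the
#' expression reference, keeps for each selected TF the targets whose
#' regulatory evidence is at least as strong as `max_evidence`
#' (A < B < C < D < E, so `"C"` keeps levels A-C), and adds the combined set
#' `"AEGIS_combined"` equal to the union of the per-TF sets. A `mode` column,
#' if present, is read but ignored: the downstream score is sign-agnostic at
#' the set level.
#'
#' @param regulons Regulon table (see [read_regulons()]).
#' @param tf_list Character vector of TF symbols to consider.
#' @param max_evidence Weakest evidence level to keep (default `"C"`).
#' @param reference Data.frame with columns `gene` and `abundance` (TPM);
#'   the liver-expression filter operand. `NULL` disables the filter.
#' @param tpm_threshold Keep TFs with reference abundance strictly above this
#'   value (default 1 TPM).
#' @return A [gene_signature()].
#' @export
build_signature <- function(regulons, tf_list, max_evidence = "C",
                            reference = NULL, tpm_threshold = 1) {
  regulons <- validate_regulons(regulons)
  tf_list <- trimws(as.character(tf_list))
  if (length(tf_list) == 0L) stop2("'tf_list' must be non-empty")
  if (!max_evidence %in% evidence_levels) {
    stop2("'max_evidence' must be one of ", paste(evidence_levels, collapse = ", "))
  }
  if (!is.null(reference)) {
    if (!all(c("gene", "abundance") %in% names(reference))) {
      stop2("'reference' needs columns gene and abundance")
    }
    if (any(reference$abundance < 0)) stop2("reference abundance must be >= 0")
    ref_ab <- stats::setNames(as.numeric(reference$abundance),
                              trimws(as.character(reference$gene)))
    absent <- setdiff(tf_list, names(ref_ab))
    if (length(absent)) {
      warning("TF(s) absent from expression reference, excluded: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    tf_list <- tf_list[tf_list %in% names(ref_ab) &
                         ref_ab[tf_list] > tpm_threshold]
  }
  keep_lv <- evidence_levels[seq_len(match(max_evidence, evidence_levels))]
  sets <- list()
  for (tf in tf_list) {
    tg <- regulons$target[regulons$tf == tf & regulons$evidence %in% keep_lv]
    tg <- unique(tg)
    if (length(tg)) sets[[tf]] <- tg
  }
  if (length(sets) == 0L) {
    stop2("empty signature: no TF passed the expression/evidence filters")
  }
  sets[[AEGIS_COMBINED]] <- unique(unlist(sets, use.names = FALSE))
  gene_signature(sets, provenance = sprintf(
    "build_signature: %d TF(s), evidence <= %s, TPM > %g",
    length(sets) - 1L, max_evidence, tpm_threshold))
}

#' Read a gene signature from GMT or two-column TSV
#'
#' GMT: one line per set, `set<TAB>description<TAB>gene...`. TSV: header plus
#' one `(set, gene)` row per membership. Duplicate genes within a set are
#' dropped with a warning.
#'
#' @param path File path.
#' @param format `"gmt"` or `"tsv"`; default guessed from the extension.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (!file.exists(path)) stop2("signature file not found: ", path)
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (i in seq_along(lines)) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) {
        stop2("malformed GMT line ", i, ": expected at least 3 tab-separated fields")
      }
      genes <- trimws(f[-(1:2)])
      genes <- genes[nzchar(genes)]
      if (anyDuplicated(genes)) {
        warning("duplicate gene(s) in GMT set '", f[1],
                "' (line ", i, "); deduplicated", call. = FALSE)
        genes <- unique(genes)
      }
      if (length(genes) == 0L) stop2("malformed GMT line ", i, ": set has no genes")
      sets[[trimws(f[1])]] <- genes
    }
    gene_signature(sets, provenance = paste0("read_signature: ", basename(path)))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop2("malformed TSV signature: need columns (set, gene)")
    names(df)[1:2] <- c("set", "gene")
    df$set <- trimws(as.character(df$set))
    df$gene <- trimws(as.character(df$gene))
    sets <- split(df$gene, factor(df$set, levels = unique(df$set)))
    sets <- lapply(sets, function(g) {
      if (anyDuplicated(g)) {
        warning("duplicate gene membership in TSV signature; deduplicated",
                call. = FALSE)
        g <- unique(g)
      }
      g
    })
    gene_signature(as.list(sets),
                   provenance = paste0("read_signature: ", basename(path)))
  }
}

#' Write a gene signature
#'
#' Writes GMT (set, description, genes per line) or two-column TSV
#' (`set`, `gene`, one row per membership, with header). Round-trips with
#' [read_signature()] byte-stably for canonical ordering.
#'
#' @param sig A [gene_signature()].
#' @param path Output path.
#' @param format `"gmt"` or `"tsv"`; default guessed from the extension.
#' @export
write_signature <- function(sig, path, format = c("auto", "gmt", "tsv")) {
  stopifnot(inherits(sig, "gene_signature"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (any(lengths(sig$sets) == 0L)) stop2("refusing to write an empty set")
  if (format == "gmt") {
    lines <- vapply(names(sig$sets), function(nm) {
      paste(c(nm, "na", sig$sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
  } else {
    df <- data.frame(
      set = rep(names(sig$sets), lengths(sig$sets)),
      gene = unlist(sig$sets, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Per-TF sets of a built signature (drops the combined set if present).
tf_sets <- function(sig) {
  sig$sets[setdiff(names(sig$sets), AEGIS_COMBINED)]
}
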