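#' Score every treatment of an experiment
#'
#' Splits the sample sheet into treatments (one per compound x dose_multiple
#' x donor combination with `group == "treatment"`), pairs each with the
#' control samples of the same donor, and computes the DILI score for each
#' contrast. Noise-injection confidence uses gene-level SDs computed across
#' ALL samples of the experiment.
#'
#' @param m Log-scale [expression_matrix()] for the whole experiment.
#' @param design Sample sheet covering all samples (see
#'   [read_sample_sheet()]).
#' @param sig A [gene_signature()].
#' @param rot_cfg A [rotation_config()].
#' @param score_cfg A [scoring_config()].
#' @param noise Run the noise-injection iterations (default TRUE). With
#'   FALSE, `score_mean`/`score_sd` repeat the no-noise score and 0.
#' @return Data.frame, one row per treatment: compound, dose_multiple,
#'   donor, n_genes, prop_up, prop_down, fdr_mixed, raw, normalized,
#'   score_mean, score_sd. Per-treatment [score_with_confidence()] objects
#'   are attached as `attr(, "distributions")` when `noise` is TRUE.
#' @export
aegis_score <- function(m, design, sig, rot_cfg = rotation_config(),
                        score_cfg = scoring_config(), noise = TRUE) {
  stopifnot(inherits(m, "expression_matrix"))
  design <- read_sample_sheet(design, m)
  trt <- design[design$group == "treatment", , drop = FALSE]
  if (nrow(trt) == 0L) stop2("no treatment samples in the design")
  key <- interaction(trt$compound, trt$dose_multiple, trt$donor, drop = TRUE)
  sigma <- apply(m$values, 1, stats::sd)
  rows <- list()
  dists <- list()
  k <- 0L
  for (lev in levels(key)) {
    k <- k + 1L
    sub_t <- trt[key == lev, , drop = FALSE]
    donor <- sub_t$donor[1]
    ctrl <- design[design$group == "control" & design$donor == donor, , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      stop2("no control samples for donor '", donor, "' (treatment ",
            sub_t$compound[1], " @ ", sub_t$dose_multiple[1], "x)")
    }
    sub <- rbind(sub_t, ctrl)
    mi <- m
    mi$values <- m$values[, sub$sample_id, drop = FALSE]
    sc_cfg <- score_cfg
    sc_cfg$seed <- derive_seed(score_cfg$seed, k)
    if (noise) {
      dist <- score_with_confidence(mi, sub, sig, rot_cfg, sc_cfg, sigma = sigma)
      row0 <- dist$row
      rows[[lev]] <- data.frame(
        compound = sub_t$compound[1], dose_multiple = sub_t$dose_multiple[1],
        donor = donor, n_genes = row0$n_genes,
        prop_up = row0$prop_up, prop_down = row0$prop_down,
        fdr_mixed = row0$fdr_mixed,
        raw = dist$base_raw, normalized = dist$base,
        score_mean = dist$mean, score_sd = dist$sd,
        stringsAsFactors = FALSE
      )
      dists[[lev]] <- dist
    } else {
      base <- score_once(mi, sub, sig, rot_cfg, sc_cfg,
                         rot_seed = derive_seed(sc_cfg$seed, 0))
      rows[[lev]] <- data.frame(
        compound = sub_t$compound[1], dose_multiple = sub_t$dose_multiple[1],
        donor = donor, n_genes = base$row$n_genes,
        prop_up = base$row$prop_up, prop_down = base$row$prop_down,
        fdr_mixed = base$row$fdr_mixed,
        raw = base$raw, normalized = base$normalized,
        score_mean = base$normalized, score_sd = 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$compound, out$dose_multiple, out$donor), , drop = FALSE]
  rownames(out) <- NULL
  if (noise) attr(out, "distributions") <- dists
  out
}

#' Write a scores table as TSV
#' @param scores An [aegis_score()] result.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
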