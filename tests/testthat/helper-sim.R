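# Shared builders for small fixtures constructed in code.

two_group_design <- function(n_per_group = 3, donor = "d1") {
  n <- 2 * n_per_group
  data.frame(
    sample_id = paste0("s", seq_len(n)),
    compound = "cmpd",
    dose_multiple = rep(c(0, 1), each = n_per_group),
    group = rep(c("control", "treatment"), each = n_per_group),
    donor = donor,
    stringsAsFactors = FALSE
  )
}

# Gaussian null matrix (no treatment effect) with named dims.
null_matrix <- function(n_genes, n_samples, sd = 1, mean = 0) {
  matrix(stats::rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

# Two-group log-scale experiment with the first `n_shift` genes shifted by
# `delta` in the treatment samples.
shifted_experiment <- function(n_genes = 200, n_per_group = 3, n_shift = 0,
                               delta = 0, sd = 1) {
  design <- two_group_design(n_per_group)
  Y <- null_matrix(n_genes, nrow(design), sd = sd)
  if (n_shift > 0) {
    Y[seq_len(n_shift), design$group == "treatment"] <-
      Y[seq_len(n_shift), design$group == "treatment"] + delta
  }
  list(m = expression_matrix(Y, "log"), design = design,
       genes = rownames(Y))
}

first_genes_signature <- function(n, name = "S") {
  gene_signature(stats::setNames(list(sprintf("g%04d", seq_len(n))), name))
}

toy_regulons <- function() {
  data.frame(
    tf = c("T1", "T1", "T2", "T2"),
    target = c("g1", "g2", "g3", "g1"),
    evidence = c("A", "D", "B", "B"),
    stringsAsFactors = FALSE
  )
}
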