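#' Configuration of a synthetic treatment-vs-control experiment
#'
#' The generator emulates the structure the score assumes: log-scale
#' expression with per-gene baselines, an optional shared latent factor
#' inducing inter-gene correlation, and a dose-scaled log2 shift applied to
#' a fraction of the signature genes in treated samples. The shift follows
#' the log-logistic factor `1 / (1 + exp(hill_b * (ln dose - ln hill_e)))`,
#' so a negative `hill_b` makes the perturbation grow with dose.
#'
#' Defaults mirror a realistic hepatocyte screen: a 241-gene signature over
#' 8 TF regulons inside a 2000-gene background, 3 replicates per group,
#' doses 0.1/1/10 x C_max, Hill slope -0.7 with midpoint at 1 x C_max,
#' log2 effect size 1 on half the signature genes (half up, half down) and
#' residual SD 0.5 on the log2 scale.
#'
#' @param n_genes Total genes.
#' @param n_signature Signature genes (`<= n_genes`).
#' @param n_tf_sets Number of per-TF regulon sets the signature is split into.
#' @param n_per_group Replicates per treatment group and per control group.
#' @param baseline_mean,baseline_sd Mean/SD of per-gene baseline log2 expression.
#' @param effect_size Maximal log2 shift of a perturbed gene.
#' @param frac_perturbed Fraction of signature genes shifted.
#' @param direction_mix Fraction of perturbed genes shifted up (rest down).
#' @param dose_levels Dose multiples (> 0) of the treated groups.
#' @param hill_b,hill_e Hill slope and midpoint of the dose scaling.
#' @param gene_correlation Loading of the shared standard-normal latent
#'   factor (0 = independent genes).
#' @param noise_sd Residual SD of log2 expression.
#' @param compound Compound label used in the sample sheet.
#' @param donor Donor label.
#' @param seed Seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_signature = 241, n_tf_sets = 8,
                              n_per_group = 3, baseline_mean = 6,
                              baseline_sd = 1.5, effect_size = 1,
                              frac_perturbed = 0.5, direction_mix = 0.5,
                              dose_levels = c(0.1, 1, 10), hill_b = -0.7,
                              hill_e = 1, gene_correlation = 0,
                              noise_sd = 0.5, compound = "cmpd",
                              donor = "d1", seed = 1) {
  if (n_signature > n_genes) stop2("'n_signature' cannot exceed 'n_genes'")
  if (frac_perturbed < 0 || frac_perturbed > 1) stop2("'frac_perturbed' in [0,1]")
  if (direction_mix < 0 || direction_mix > 1) stop2("'direction_mix' in [0,1]")
  if (any(dose_levels <= 0)) stop2("'dose_levels' must be > 0")
  if (n_per_group < 2) stop2("need >= 2 replicates per group")
  structure(as.list(environment()), class = "simulation_config")
}

hill_factor <- function(dose, b, e) 1 / (1 + exp(b * (log(dose) - log(e))))

#' Simulate a treatment-vs-control experiment with known truth
#'
#' Generates `Y[g, s] = mu_g + rho * F_s + delta_g(dose_s) * treated_s +
#' eps`, with `F_s ~ N(0, 1)` shared across genes, `eps ~ N(0, noise_sd^2)`,
#' and `delta_g(dose) = sign_g * effect_size * hill(dose)` for the perturbed
#' signature genes. One control group plus one treated group per dose level.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `simulated_experiment`: `matrix`
#'   ([expression_matrix()], log scale), `design` (sample sheet), `signature`
#'   ([gene_signature()]), `truth` (perturbed genes, signs, per-dose realised
#'   shift).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    sig_genes <- genes[seq_len(cfg$n_signature)]
    # split signature genes into regulons (near-equal, disjoint)
    tf_names <- if (cfg$n_tf_sets == 8) {
      c("ATF3", "E2F3", "FOXA1", "FOXO3", "JUN", "PPARG", "REST", "TFAP4")
    } else paste0("TF", seq_len(cfg$n_tf_sets))
    grp_id <- rep(seq_len(cfg$n_tf_sets), length.out = cfg$n_signature)
    sets <- split(sig_genes, tf_names[grp_id])
    sets <- sets[order(match(names(sets), tf_names))]
    sets[[AEGIS_COMBINED]] <- sig_genes
    sig <- gene_signature(sets, provenance = "simulate_experiment")

    n_pert <- round(cfg$frac_perturbed * cfg$n_signature)
    pert <- sample(sig_genes, n_pert)
    n_up <- round(cfg$direction_mix * n_pert)
    signs <- stats::setNames(
      c(rep(1, n_up), rep(-1, n_pert - n_up))[sample.int(max(n_pert, 1))][seq_len(n_pert)],
      pert)

    groups <- c(list(data.frame(group = "control", dose_multiple = 0)),
                lapply(cfg$dose_levels, function(dm)
                  data.frame(group = "treatment", dose_multiple = dm)))
    design <- do.call(rbind, lapply(groups, function(g)
      g[rep(1, cfg$n_per_group), , drop = FALSE]))
    design$compound <- ifelse(design$group == "control", "control", cfg$compound)
    design$donor <- cfg$donor
    design$replicate <- stats::ave(seq_len(nrow(design)),
                                   design$group, design$dose_multiple,
                                   FUN = seq_along)
    design$sample_id <- sprintf("s%02d_%s_%g", seq_len(nrow(design)),
                                substr(design$group, 1, 1), design$dose_multiple)
    design <- design[c("sample_id", "compound", "dose_multiple", "group",
                       "donor", "replicate")]

    n_s <- nrow(design)
    mu <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    FF <- stats::rnorm(n_s)
    Y <- matrix(stats::rnorm(cfg$n_genes * n_s, sd = cfg$noise_sd),
                cfg$n_genes, n_s) + mu +
      cfg$gene_correlation * matrix(FF, cfg$n_genes, n_s, byrow = TRUE)
    delta_by_dose <- stats::setNames(
      cfg$effect_size * hill_factor(cfg$dose_levels, cfg$hill_b, cfg$hill_e),
      as.character(cfg$dose_levels))
    if (n_pert > 0) {
      gi <- match(pert, genes)
      for (j in seq_len(n_s)) {
        if (design$group[j] == "treatment") {
          Y[gi, j] <- Y[gi, j] +
            signs * delta_by_dose[[as.character(design$dose_multiple[j])]]
        }
      }
    }
    dimnames(Y) <- list(genes, design$sample_id)
    structure(list(
      matrix = expression_matrix(Y, scale = "log"),
      design = design,
      signature = sig,
      truth = list(perturbed = pert, signs = signs,
                   delta_by_dose = delta_by_dose,
                   frac_perturbed = cfg$frac_perturbed,
                   direction_mix = cfg$direction_mix)
    ), class = "simulated_experiment")
  })
}

#' @method print simulated_experiment
#' @export
print.simulated_experiment <- function(x, ...) {
  cat("simulated_experiment: ", nrow(x$matrix$values), " genes x ",
      ncol(x$matrix$values), " samples, ",
      length(x$truth$perturbed), " perturbed signature genes\n", sep = "")
  invisible(x)
}

#' Simulate a labelled compound panel
#'
#' Positives are generated with the configured effect size, negatives with
#' effect size 0; each compound gets an independent substream of the master
#' seed, so panels are reproducible and order-independent.
#'
#' @param cfg A [simulation_config()] used as template.
#' @param n_positive,n_negative Number of DILI-positive / negative compounds.
#' @return List of class `compound_panel`: `experiments` (named list of
#'   [simulate_experiment()] outputs) and `labels` (named logical, TRUE =
#'   positive).
#' @export
simulate_compound_panel <- function(cfg, n_positive, n_negative) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (n_positive + n_negative < 1) stop2("empty panel")
  labels <- c(rep(TRUE, n_positive), rep(FALSE, n_negative))
  names(labels) <- c(sprintf("pos%02d", seq_len(n_positive)),
                     sprintf("neg%02d", seq_len(n_negative)))
  experiments <- lapply(seq_along(labels), function(i) {
    ci <- cfg
    ci$compound <- names(labels)[i]
    ci$effect_size <- if (labels[i]) cfg$effect_size else 0
    ci$seed <- derive_seed(cfg$seed, i)
    simulate_experiment(ci)
  })
  names(experiments) <- names(labels)
  structure(list(experiments = experiments, labels = labels),
            class = "compound_panel")
}

#' Write a simulated experiment as public file formats
#'
#' Emits the expression TSV (`matrix.tsv`), sample sheet (`samples.csv`),
#' signature (`signature.gmt`) and a truth manifest (`truth.json`) into a
#' directory, so downstream tools consume only standard formats.
#'
#' @param exp_ A [simulate_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulated_experiment <- function(exp_, dir) {
  stopifnot(inherits(exp_, "simulated_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(exp_$matrix, file.path(dir, "matrix.tsv"))
  utils::write.csv(exp_$design, file.path(dir, "samples.csv"), row.names = FALSE)
  write_signature(exp_$signature, file.path(dir, "signature.gmt"))
  jsonlite::write_json(
    list(perturbed = exp_$truth$perturbed,
         signs = as.list(exp_$truth$signs),
         delta_by_dose = as.list(exp_$truth$delta_by_dose)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
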