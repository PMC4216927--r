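# Synthetic cohorts with the statistical structure the pipeline assumes:
# a low-rank bilinear expression signal D W P' plus Gaussian noise,
# subtype-shifted protein profiles, activity-driven drug responses, and
# activity-driven exponential survival with independent censoring.

.subtype_names <- function(n) {
  if (n == 4) c("Basal", "HER2", "LumA", "LumB") else paste0("ST", seq_len(n))
}

#' Generate a synthetic tumor cohort
#'
#' Draws a binary motif-hit matrix `D ~ Bernoulli(motif_density)`, protein
#' profiles `P` as subtype mean shifts (scale `effect_sd`) plus unit Gaussian
#' noise (column-centered), a low-rank Gaussian interaction matrix `W_true`,
#' and expression `Y = D W_true P' + noise`, where the noise standard
#' deviation is `noise_sd` times the elementwise standard deviation of the
#' signal. `W_true` carries a global scale chosen so that the per-gene
#' standard deviations of the signal straddle the 0.65 log-scale filter, and
#' gene-level baselines are added so `Y` is returned uncentered. Optionally,
#' `n_effect_tfs` TFs receive an additive subtype-specific activity shift of
#' `tf_effect_size` standard deviations (these planted TF effects break the
#' exact bilinear identity but keep `Y = D %*% tf_activity_true`).
#'
#' @param n_genes,n_samples,n_tfs,n_proteins Cohort dimensions (all >= 2).
#' @param motif_density Bernoulli hit probability in (0, 1).
#' @param rank Rank of `W_true`.
#' @param noise_sd Noise level relative to the signal sd (0 = noise-free).
#' @param n_subtypes Number of balanced subtype groups.
#' @param effect_sd Scale of the per-subtype protein mean shifts.
#' @param n_effect_tfs Number of TFs with planted subtype-specific activity.
#' @param tf_effect_size Planted shift in units of the TF's activity sd.
#' @param seed Integer seed; outputs are bit-identical for equal seeds.
#' @return List with `Y` (genes x samples, uncentered), `D` (genes x TFs),
#'   `P` (samples x proteins, centered), `labels` (named), and `truth`
#'   (list with `W_true`, `tf_activity_true`, `protein_activity_true`,
#'   `planted_tfs`, `signal_sd`, `seed`).
#' @export
generate_cohort <- function(n_genes = 500, n_samples = 64, n_tfs = 40,
                            n_proteins = 20, motif_density = 0.1, rank = 5,
                            noise_sd = 0.1, n_subtypes = 4, effect_sd = 1,
                            n_effect_tfs = 0, tf_effect_size = 2, seed = 1) {
  if (min(n_genes, n_samples, n_tfs, n_proteins) < 2) {
    stop("all cohort dimensions must be >= 2", call. = FALSE)
  }
  if (motif_density <= 0 || motif_density >= 1) {
    stop("motif_density must lie in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  proteins <- sprintf("PR%02d", seq_len(n_proteins))
  labels <- setNames(rep_len(.subtype_names(n_subtypes), n_samples), samples)

  shift <- matrix(rnorm(n_subtypes * n_proteins, 0, effect_sd), n_subtypes)
  p <- shift[match(labels, .subtype_names(n_subtypes)), ] +
    matrix(rnorm(n_samples * n_proteins), n_samples)
  p <- p - rep(colMeans(p), each = n_samples)
  dimnames(p) <- list(samples, proteins)
  attr(p, "centered") <- TRUE

  d <- matrix(rbinom(n_genes * n_tfs, 1, motif_density), n_genes,
              dimnames = list(genes, tfs))
  for (j in which(colSums(d) == 0)) d[sample(n_genes, 1), j] <- 1L

  w <- (matrix(rnorm(n_tfs * rank), n_tfs) %*%
          t(matrix(rnorm(n_proteins * rank), n_proteins))) / sqrt(rank)
  tf_act <- w %*% t(p)
  sig <- d %*% tf_act
  row_sds <- apply(sig, 1L, sd)
  scale_c <- as.numeric(0.65 / max(quantile(row_sds[row_sds > 0], 0.3), 1e-12))
  w <- w * scale_c
  tf_act <- tf_act * scale_c
  dimnames(w) <- list(tfs, proteins)
  dimnames(tf_act) <- list(tfs, samples)

  planted <- data.frame(tf = character(0), subtype = character(0),
                        shift = numeric(0), stringsAsFactors = FALSE)
  if (n_effect_tfs > 0) {
    idx <- sample(n_tfs, n_effect_tfs)
    sts <- rep_len(unique(labels), n_effect_tfs)
    for (i in seq_len(n_effect_tfs)) {
      delta <- tf_effect_size * sd(tf_act[idx[i], ])
      tf_act[idx[i], labels == sts[i]] <- tf_act[idx[i], labels == sts[i]] + delta
      planted <- rbind(planted, data.frame(tf = tfs[idx[i]], subtype = sts[i],
                                           shift = delta, stringsAsFactors = FALSE))
    }
  }
  sig <- d %*% tf_act
  sig_sd <- sd(as.vector(sig))
  noise <- if (noise_sd > 0) {
    matrix(rnorm(n_genes * n_samples, 0, noise_sd * sig_sd), n_genes)
  } else 0
  baseline <- rnorm(n_genes, 8, 1)
  y <- baseline + sig + noise
  dimnames(y) <- list(genes, samples)
  attr(y, "centered") <- FALSE

  list(Y = y, D = d, P = p, labels = labels,
       truth = list(W_true = w,
                    tf_activity_true = tf_act,
                    protein_activity_true = t(p),
                    planted_tfs = planted,
                    labels = labels,
                    signal_sd = sig_sd,
                    noise_sd = noise_sd,
                    seed = seed))
}

#' Generate a synthetic drug response table
#'
#' The first `n_target_drugs` drugs respond to a planted target protein:
#' `response = effect * activity + noise`, with noise sd equal to `noise_sd`
#' times the activity sd. The remaining drugs are pure noise with per-drug
#' sds drawn uniformly in `[0.2, 1.2]` (so the 0.5 variability filter is
#' exercised). Entries are masked missing at `missing_fraction`.
#'
#' @param truth The `truth` element of [generate_cohort()] (or a cohort).
#' @param n_drugs Total drugs.
#' @param n_target_drugs Drugs driven by a planted protein
#'   (<= `n_drugs`).
#' @param effect Linear effect size of the target activity.
#' @param noise_sd Relative noise level for target drugs.
#' @param missing_fraction Probability an entry is missing.
#' @param seed Integer seed.
#' @return List with `values` (cell lines x drugs, log-GI50 scale, `NA` for
#'   missing) and `drug_targets` (named character vector for target drugs).
#' @export
generate_drug_table <- function(truth, n_drugs = 20, n_target_drugs = 5,
                                effect = 1, noise_sd = 0.5,
                                missing_fraction = 0.1, seed = 1) {
  if (!is.null(truth$truth)) truth <- truth$truth
  if (n_target_drugs > n_drugs) {
    stop("n_target_drugs exceeds n_drugs", call. = FALSE)
  }
  act <- truth$protein_activity_true
  m <- ncol(act)
  set.seed(seed)
  drugs <- sprintf("Drug%02d", seq_len(n_drugs))
  targets <- sample(rownames(act), n_target_drugs)
  values <- matrix(NA_real_, m, n_drugs, dimnames = list(colnames(act), drugs))
  for (i in seq_len(n_target_drugs)) {
    av <- act[targets[i], ]
    values[, i] <- effect * av + rnorm(m, 0, noise_sd * sd(av))
  }
  for (i in seq(n_target_drugs + 1, length.out = n_drugs - n_target_drugs)) {
    values[, i] <- rnorm(m, 0, runif(1, 0.2, 1.2))
  }
  if (missing_fraction > 0) {
    values[matrix(rbinom(length(values), 1, missing_fraction) == 1,
                  nrow(values))] <- NA_real_
  }
  list(values = values,
       drug_targets = setNames(targets, drugs[seq_len(n_target_drugs)]),
       seed = seed)
}

#' Generate synthetic survival follow-up
#'
#' Event times are exponential with log-hazard equal to the linear predictor
#' over planted protein activities; censoring times are independent
#' exponentials calibrated so that roughly `censor_rate` of patients are
#' censored under a null predictor. A fraction of events is attributed to an
#' unrelated cause (`cause = "other"`).
#'
#' @param truth The `truth` element of [generate_cohort()] (or a cohort).
#' @param baseline_hazard Baseline exponential rate.
#' @param coefficients Named log-hazard coefficients over protein ids
#'   (default: all zero).
#' @param censor_rate Target censoring fraction in `[0, 1]`; `>= 1` censors
#'   everyone.
#' @param other_cause_fraction Fraction of events labeled `"other"`.
#' @param seed Integer seed.
#' @return Data frame with `sample_id`, `time`, `event`, `cause`.
#' @export
generate_survival <- function(truth, baseline_hazard = 0.05,
                              coefficients = NULL, censor_rate = 0.3,
                              other_cause_fraction = 0.1, seed = 1) {
  if (!is.null(truth$truth)) truth <- truth$truth
  act <- truth$protein_activity_true
  m <- ncol(act)
  set.seed(seed)
  lp <- rep(0, m)
  if (!is.null(coefficients)) {
    missing <- setdiff(names(coefficients), rownames(act))
    if (length(missing) > 0) {
      stop(sprintf("unknown protein(s) in coefficients: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    lp <- as.numeric(coefficients %*% act[names(coefficients), , drop = FALSE])
  }
  if (censor_rate >= 1) {
    return(data.frame(sample_id = colnames(act),
                      time = rexp(m, baseline_hazard),
                      event = 0L, cause = NA_character_,
                      stringsAsFactors = FALSE))
  }
  t_event <- rexp(m, rate = baseline_hazard * exp(lp))
  c_rate <- baseline_hazard * censor_rate / max(1 - censor_rate, 1e-9)
  t_cens <- if (censor_rate > 0) rexp(m, rate = c_rate) else rep(Inf, m)
  event <- as.integer(t_event <= t_cens)
  cause <- rep(NA_character_, m)
  ev <- which(event == 1)
  if (length(ev) > 0 && other_cause_fraction > 0) {
    other <- ev[runif(length(ev)) < other_cause_fraction]
    cause[ev] <- "disease"
    cause[other] <- "other"
  } else if (length(ev) > 0) {
    cause[ev] <- "disease"
  }
  data.frame(sample_id = colnames(act), time = pmin(t_event, t_cens),
             event = event, cause = cause, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Writes the expression matrix, protein matrix, and subtype labels as TSV,
#' the motif-hit matrix as GMT, and (when given) the drug table as CSV and
#' the survival table as CSV.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param drug_table Optional output of [generate_drug_table()].
#' @param survival_table Optional output of [generate_survival()].
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, drug_table = NULL, survival_table = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(cohort$Y, file.path(dir, "expression.tsv"))
  write_protein_tsv(cohort$P, file.path(dir, "rppa.tsv"))
  write_gmt(cohort$D, file.path(dir, "tf_targets.gmt"))
  write.table(data.frame(sample_id = names(cohort$labels),
                         label = unname(cohort$labels)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(drug_table)) {
    df <- data.frame(cell_id = rownames(drug_table$values), drug_table$values,
                     check.names = FALSE)
    write.table(df, file.path(dir, "gi50.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(survival_table)) {
    write.table(survival_table, file.path(dir, "survival.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  }
  saveRDS(cohort$truth, file.path(dir, "truth.rds"))
  invisible(dir)
}
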