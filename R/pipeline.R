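# Configuration-driven orchestration: prepare -> fit -> evaluate ->
# associate -> drugs -> survive, with optional simulation of the inputs,
# per-stage manifests (parameter values and input/output checksums), and a
# single seed controlling every stochastic step.

#' Read a drug response table from CSV
#'
#' Cell lines in rows (first column = cell id), drugs in columns; empty
#' fields are missing.
#'
#' @param path Path to a CSV file.
#' @return Cell lines x drugs numeric matrix with `NA` for missing entries.
#' @export
read_drug_csv <- function(path) {
  raw <- read.delim(path, sep = ",", check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate cell ids in drug table", call. = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  m
}

#' Read a survival table from CSV
#'
#' Columns `sample_id`, `time`, `event`, and optionally `cause`.
#'
#' @param path Path to a CSV file.
#' @return Survival data frame.
#' @export
read_survival_csv <- function(path) {
  s <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  s$time <- as.numeric(s$time)
  s$event <- as.integer(s$event)
  .check_survival_table(s)
}

.default_config <- function() {
  list(seed = 17,
       stages = c("prepare", "fit", "evaluate"),
       sd_threshold = 0.65, jaccard = 0.8,
       variance_fraction = 0.99, lambda = "auto", folds = 6,
       inner_folds = 3, control = FALSE,
       assoc_kind = "tf", n_perm = 1000, fdr = 0.10,
       gi50_sd_threshold = 0.5, alpha_min = 0.001, alpha_max = 0.2,
       iters = 100, min_count = 10,
       cox_p = 0.001, repeats = 100, keep_fraction = 0.5, tails = 0.40,
       simulate = list())
}

.manifest <- function(run_dir, stage, params, inputs, outputs) {
  man <- list(stage = stage,
              package_version = as.character(packageVersion("affreg")),
              parameters = params,
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(man, file.path(run_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order inside `out_dir`. The
#' configuration is a flat named list (or the path of a YAML file holding
#' one) with input paths (`expr`, `rppa`, `gmt`, `labels`, optionally `gi50`,
#' `surv`, `validate_expr`, `validate_surv`), the stage list, one `seed`, and
#' per-stage parameters; unset parameters take the defaults (sd filter 0.65,
#' 6 folds, 1000 permutations, FDR 0.10, GI50 sd 0.5, alpha in
#' `[0.001, 0.2]`, 100 iterations, minimum count 10, Cox p 0.001, 100
#' stepwise repeats, 40/40 risk tails). Before any stage runs, every input
#' path referenced by the requested stages must exist. Each stage writes its
#' outputs plus a JSON manifest with the parameters and the MD5 checksums of
#' its inputs and outputs; a rerun with an identical configuration is
#' bit-identical.
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The run directory, invisibly; stage results are written to disk.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_config(), config)
  run_dir <- out_dir %||% cfg$out_dir
  if (is.null(run_dir)) stop("config error: out_dir is required", call. = FALSE)
  stages <- cfg$stages
  known <- c("simulate", "prepare", "fit", "evaluate", "associate", "drugs",
             "survive")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop(sprintf("config error: unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  stages <- known[known %in% stages]   # dependency order
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

  if ("simulate" %in% stages) {
    sim <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
    cohort <- do.call(generate_cohort, sim[intersect(names(sim),
      names(formals(generate_cohort)))])
    dt <- if (any(c("drugs") %in% stages)) {
      generate_drug_table(cohort$truth, seed = cfg$seed + 1)
    }
    sv <- if ("survive" %in% stages) {
      cf <- setNames(rep(1, 2), rownames(cohort$truth$protein_activity_true)[1:2])
      generate_survival(cohort$truth, coefficients = cf, seed = cfg$seed + 2)
    }
    sim_dir <- file.path(run_dir, "simulated")
    write_cohort(cohort, sim_dir, drug_table = dt, survival_table = sv)
    cfg$expr <- file.path(sim_dir, "expression.tsv")
    cfg$rppa <- file.path(sim_dir, "rppa.tsv")
    cfg$gmt <- file.path(sim_dir, "tf_targets.gmt")
    cfg$labels <- file.path(sim_dir, "labels.tsv")
    if (!is.null(dt)) cfg$gi50 <- file.path(sim_dir, "gi50.csv")
    if (!is.null(sv)) cfg$surv <- file.path(sim_dir, "survival.csv")
    .manifest(run_dir, "simulate", sim, character(0),
              list.files(sim_dir, full.names = TRUE))
  }

  # pre-flight: every input needed by the requested stages must exist
  need <- c(expr = "prepare", rppa = "prepare", gmt = "prepare",
            gi50 = "drugs", surv = "survive")
  for (key in names(need)) {
    if (need[[key]] %in% stages) {
      if (is.null(cfg[[key]])) {
        stop(sprintf("config error: stage '%s' requires input '%s'",
                     need[[key]], key), call. = FALSE)
      }
      if (!file.exists(cfg[[key]])) {
        stop(sprintf("config error: input file not found: %s", cfg[[key]]),
             call. = FALSE)
      }
    }
  }

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  env <- new.env(parent = emptyenv())
  downstream <- c("fit", "evaluate", "associate", "drugs", "survive")
  if (!"prepare" %in% stages && any(downstream %in% stages)) {
    prep_path <- file.path(run_dir, "prep.rds")
    if (!file.exists(prep_path)) {
      stop("config error: downstream stages need 'prepare' (no prep.rds found)",
           call. = FALSE)
    }
    prep <- readRDS(prep_path)
    for (nm in names(prep)) assign(nm, prep[[nm]], envir = env)
  }
  if (!"fit" %in% stages && any(c("associate", "drugs", "survive") %in% stages)) {
    model_path <- file.path(run_dir, "model.rds")
    if (!file.exists(model_path)) {
      stop("config error: this stage set needs 'fit' (no model.rds found)",
           call. = FALSE)
    }
    env$model <- load_model(model_path)
  }
  if ("prepare" %in% stages) run_stage("prepare", function() {
    y <- read_expression_tsv(cfg$expr)
    p <- read_protein_tsv(cfg$rppa)
    labels <- if (!is.null(cfg$labels)) read_labels_tsv(cfg$labels)
    sets <- read_gmt(cfg$gmt)
    y <- filter_genes_by_sd(y, cfg$sd_threshold)
    d <- build_motif_matrix(sets, rownames(y))
    d <- remove_redundant_motifs(d, cfg$jaccard)
    al <- align_cohort(y, d, p, labels)
    env$y_raw <- al$y
    env$d <- al$d
    env$p_raw <- al$p
    env$labels <- al$labels
    env$y <- mean_center(al$y, "gene")
    env$p <- mean_center(al$p, "protein")
    prep_path <- file.path(run_dir, "prep.rds")
    saveRDS(list(y = env$y, d = env$d, p = env$p, labels = env$labels,
                 y_raw = env$y_raw, p_raw = env$p_raw), prep_path)
    .manifest(run_dir, "prepare",
              cfg[c("sd_threshold", "jaccard")],
              unlist(cfg[c("expr", "rppa", "gmt", "labels")]), prep_path)
  })

  if ("fit" %in% stages) run_stage("fit", function() {
    lam <- cfg$lambda
    if (identical(lam, "auto")) {
      lam <- as.numeric(select_lambda(env$y, env$d, env$p,
                                      k_folds = cfg$inner_folds + 2,
                                      seed = cfg$seed,
                                      variance_fraction = cfg$variance_fraction))
    }
    env$model <- affreg_fit(env$y, env$d, env$p, lambda = lam,
                            variance_fraction = cfg$variance_fraction)
    model_path <- file.path(run_dir, "model.rds")
    w_path <- file.path(run_dir, "W.tsv")
    save_model(env$model, model_path)
    .write_id_matrix(env$model$W, w_path, "tf_id")
    .manifest(run_dir, "fit",
              list(lambda = lam, variance_fraction = cfg$variance_fraction),
              file.path(run_dir, "prep.rds"), c(model_path, w_path))
  })

  if ("evaluate" %in% stages) run_stage("evaluate", function() {
    cv <- cross_validate(env$y_raw, env$d, env$p_raw, k = cfg$folds,
                         labels = env$labels, seed = cfg$seed,
                         inner_folds = cfg$inner_folds,
                         variance_fraction = cfg$variance_fraction)
    tab <- cv$samples
    if (isTRUE(cfg$control)) {
      ctrl <- randomization_control(env$y_raw, env$d, env$p_raw,
                                    k = cfg$folds, seed = cfg$seed,
                                    inner_folds = cfg$inner_folds,
                                    variance_fraction = cfg$variance_fraction)
      tab$rho_control <- ctrl$samples$rho_model[
        match(tab$sample_id, ctrl$samples$sample_id)]
    }
    cv_path <- file.path(run_dir, "cv.tsv")
    write.table(tab, cv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    .manifest(run_dir, "evaluate",
              cfg[c("folds", "seed", "control")],
              file.path(run_dir, "prep.rds"), cv_path)
  })

  if ("associate" %in% stages) run_stage("associate", function() {
    if (is.null(env$labels)) stop("associate requires subtype labels")
    assoc <- subtype_associations(env$model, env$labels, kind = cfg$assoc_kind,
                                  p = env$p, y = env$y, d = env$d,
                                  n_perm = cfg$n_perm, fdr = cfg$fdr,
                                  seed = cfg$seed)
    assoc_path <- file.path(run_dir, "assoc.tsv")
    write.table(assoc, assoc_path, sep = "\t", quote = FALSE, row.names = FALSE)
    .manifest(run_dir, "associate", cfg[c("assoc_kind", "n_perm", "fdr", "seed")],
              file.path(run_dir, "model.rds"), assoc_path)
  })

  if ("drugs" %in% stages) run_stage("drugs", function() {
    gi50 <- filter_variable_drugs(read_drug_csv(cfg$gi50), cfg$gi50_sd_threshold)
    act <- infer_protein_activities(env$model, env$y, env$d)
    cors <- protein_drug_correlation(act, gi50)
    .write_id_matrix(cors, file.path(run_dir, "drug_correlations.tsv"), "protein_id")
    sig_rows <- lapply(colnames(gi50), function(dg) {
      sig <- tryCatch(
        fit_drug_signature(act, gi50[, dg],
                           alpha_range = c(cfg$alpha_min, cfg$alpha_max),
                           n_iter = cfg$iters, min_count = cfg$min_count,
                           seed = cfg$seed),
        error = function(e) NULL)
      if (is.null(sig) || nrow(sig$features) == 0) return(NULL)
      cbind(drug = dg, sig$features, alpha = sig$alpha, cv_mse = sig$cv_mse)
    })
    sig_tab <- do.call(rbind, sig_rows) %||%
      data.frame(drug = character(0), protein = character(0))
    sig_path <- file.path(run_dir, "drug_signatures.tsv")
    write.table(sig_tab, sig_path, sep = "\t", quote = FALSE, row.names = FALSE)
    .manifest(run_dir, "drugs",
              cfg[c("gi50_sd_threshold", "alpha_min", "alpha_max", "iters",
                    "min_count", "seed")],
              c(cfg$gi50, file.path(run_dir, "model.rds")),
              c(file.path(run_dir, "drug_correlations.tsv"), sig_path))
  })

  if ("survive" %in% stages) run_stage("survive", function() {
    s <- filter_other_cause(read_survival_csv(cfg$surv))
    act <- infer_protein_activities(env$model, env$y, env$d)
    screened <- univariate_screen(act, s, p_threshold = cfg$cox_p)
    rm_out <- if (nrow(screened) > 0) {
      stepwise_multivariate(act, s, covariates = screened$protein,
                            n_repeats = cfg$repeats,
                            keep_fraction = cfg$keep_fraction, seed = cfg$seed)
    }
    outputs <- file.path(run_dir, c("surv_screen.tsv", "surv_groups.tsv",
                                    "surv_logrank.tsv", "surv_km.tsv"))
    write.table(screened, outputs[1], sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rm_out) && length(rm_out$coefficients) > 0) {
      a_val <- if (!is.null(cfg$validate_expr)) {
        yv <- mean_center(read_expression_tsv(cfg$validate_expr), "gene")
        yv <- yv[rownames(env$d), , drop = FALSE]
        infer_protein_activities(env$model, yv, env$d)
      } else act
      s_val <- if (!is.null(cfg$validate_surv)) {
        filter_other_cause(read_survival_csv(cfg$validate_surv))
      } else s
      grp <- stratify_risk(rm_out, a_val, top = cfg$tails, bottom = cfg$tails)
      lr <- logrank_test(grp, s_val)
      write.table(data.frame(sample_id = names(grp), group = unname(grp)),
                  outputs[2], sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(chisq = lr$chisq, p = lr$p), outputs[3],
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(km_curve(grp, s_val), outputs[4], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    .manifest(run_dir, "survive",
              cfg[c("cox_p", "repeats", "keep_fraction", "tails", "seed")],
              c(cfg$surv, cfg$validate_surv %||% character(0),
                file.path(run_dir, "model.rds")), outputs)
  })

  invisible(run_dir)
}
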