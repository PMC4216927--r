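# Survival analysis from inferred protein activities: other-cause removal,
# univariate Cox screen, repeated stepwise AIC multivariate selection with a
# selection-frequency consensus, 40/40 risk stratification, and the log-rank
# comparison of the resulting Kaplan-Meier curves.

.check_survival_table <- function(s) {
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(s))) {
    stop("survival table needs columns sample_id, time, event", call. = FALSE)
  }
  if (any(s$time < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(s$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  invisible(s)
}

#' Remove deaths from other causes
#'
#' Drops samples whose event is attributed to a cause other than the disease
#' under study (column `cause` equal to `"other"`).
#'
#' @param s Survival data frame with columns `sample_id`, `time`, `event`,
#'   and optionally `cause`.
#' @return The filtered survival table.
#' @export
filter_other_cause <- function(s) {
  .check_survival_table(s)
  if (!"cause" %in% colnames(s)) return(s)
  drop <- s$event == 1 & !is.na(s$cause) & s$cause == "other"
  s[!drop, , drop = FALSE]
}

.surv_frame <- function(a, s) {
  ids <- intersect(colnames(a), s$sample_id)
  if (length(ids) == 0) stop("no shared samples between activities and survival table",
                             call. = FALSE)
  s <- s[match(ids, s$sample_id), , drop = FALSE]
  list(x = t(unclass(a)[, ids, drop = FALSE]), s = s)
}

#' Univariate Cox screen over protein activities
#'
#' Fits one proportional-hazards model per protein and returns those whose
#' Wald p-value falls below `p_threshold`. Proteins whose fit fails to
#' converge are skipped with a warning.
#'
#' @param a Proteins x samples activity matrix.
#' @param s Survival table (`sample_id`, `time`, `event`, optional `cause`;
#'   other-cause deaths should be removed first, see
#'   [filter_other_cause()]).
#' @param p_threshold Wald p-value cutoff (default 0.001).
#' @return Data frame of `protein`, `coefficient`, `p` sorted by p, with the
#'   unfiltered table attached as attribute `"all"`.
#' @export
univariate_screen <- function(a, s, p_threshold = 0.001) {
  dat <- .surv_frame(a, s)
  if (sum(dat$s$event) < 10) stop("fewer than 10 events", call. = FALSE)
  rows <- lapply(rownames(a), function(pr) {
    df <- data.frame(time = dat$s$time, event = dat$s$event, x = dat$x[, pr])
    fit <- tryCatch(survival::coxph(survival::Surv(time, event) ~ x, data = df),
                    warning = function(w) w, error = function(e) e)
    if (inherits(fit, "condition")) {
      warning(sprintf("univariate Cox fit skipped for %s: %s", pr,
                      conditionMessage(fit)))
      return(NULL)
    }
    sm <- summary(fit)$coefficients
    data.frame(protein = pr, coefficient = sm[1, "coef"],
               p = sm[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  all_tab <- do.call(rbind, rows)
  all_tab <- all_tab[order(all_tab$p), , drop = FALSE]
  rownames(all_tab) <- NULL
  out <- all_tab[all_tab$p < p_threshold, , drop = FALSE]
  attr(out, "all") <- all_tab
  out
}

#' Repeated stepwise multivariate Cox selection
#'
#' Each repeat draws a random subsample of patients and runs bidirectional
#' stepwise AIC selection from the empty Cox model over the candidate
#' covariates. The final risk model refits, on the full data, the covariates
#' selected in at least `keep_fraction` of the repeats. Repeated subsampling
#' stabilizes selection among highly correlated activities.
#'
#' @param a Proteins x samples activity matrix.
#' @param s Survival table.
#' @param covariates Candidate protein ids (default: all rows of `a`;
#'   typically the univariate-significant set).
#' @param n_repeats Number of stepwise repeats (default 100).
#' @param subsample Fraction of patients per repeat (default 0.8).
#' @param keep_fraction Consensus threshold on selection frequency
#'   (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `risk_model`: `covariates`, `coefficients`,
#'   `selection_frequency` (all candidates), `fit` (the full-data `coxph`
#'   fit or `NULL`), and `meta`.
#' @export
stepwise_multivariate <- function(a, s, covariates = NULL, n_repeats = 100,
                                  subsample = 0.8, keep_fraction = 0.5,
                                  seed = 1) {
  covariates <- covariates %||% rownames(a)
  if (length(covariates) == 0) {
    stop("no candidate covariates for stepwise selection", call. = FALSE)
  }
  dat <- .surv_frame(a[covariates, , drop = FALSE], s)
  safe <- paste0("v", seq_along(covariates))
  df <- data.frame(time = dat$s$time, event = dat$s$event, dat$x)
  colnames(df) <- c("time", "event", safe)
  n <- nrow(df)
  counts <- setNames(integer(length(covariates)), safe)
  set.seed(seed)
  for (r in seq_len(n_repeats)) {
    idx <- sample(n, max(2, floor(subsample * n)))
    sub <- df[idx, , drop = FALSE]
    sel <- tryCatch({
      fit0 <- survival::coxph(survival::Surv(time, event) ~ 1, data = sub)
      st <- MASS::stepAIC(fit0, scope = list(lower = ~1, upper = reformulate(safe)),
                          direction = "both", trace = 0)
      names(coef(st))
    }, error = function(e) character(0))
    counts[sel] <- counts[sel] + 1L
  }
  freq <- counts / n_repeats
  keep <- safe[freq >= keep_fraction]
  fit <- NULL
  coefs <- numeric(0)
  if (length(keep) == 0) {
    warning("no covariate reached the consensus threshold; empty risk model")
  } else {
    fit <- survival::coxph(
      stats::as.formula(paste("survival::Surv(time, event) ~",
                              paste(keep, collapse = " + "))), data = df)
    coefs <- setNames(coef(fit), covariates[match(keep, safe)])
  }
  structure(list(covariates = covariates[match(keep, safe)],
                 coefficients = coefs,
                 selection_frequency = setNames(freq, covariates),
                 fit = fit,
                 meta = list(seed = seed, n_repeats = n_repeats,
                             subsample = subsample,
                             keep_fraction = keep_fraction)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Cox risk model: %d covariate(s) from %d stepwise repeats\n",
              length(x$covariates), x$meta$n_repeats))
  if (length(x$coefficients) > 0) print(round(x$coefficients, 4))
  invisible(x)
}

#' Stratify patients into high- and low-risk groups
#'
#' Computes each patient's linear predictor under the risk model, ranks
#' patients by decreasing risk, and labels the top fraction `"high"`, the
#' bottom fraction `"low"`, and the middle `"excluded"` (tail sizes rounded
#' down). Ties spanning a boundary are resolved by stable sample order with a
#' message.
#'
#' @param model A `risk_model` (or a named coefficient vector).
#' @param a_validation Proteins x samples activity matrix for the cohort to
#'   stratify.
#' @param top,bottom Tail fractions (default 0.40 each).
#' @return Named character vector of `"high"`, `"low"`, `"excluded"` with the
#'   risk scores attached as attribute `"risk"`.
#' @export
stratify_risk <- function(model, a_validation, top = 0.40, bottom = 0.40) {
  coefs <- if (inherits(model, "risk_model")) model$coefficients else model
  if (length(coefs) == 0) stop("empty risk model", call. = FALSE)
  missing <- setdiff(names(coefs), rownames(a_validation))
  if (length(missing) > 0) {
    stop(sprintf("validation activities lack covariate(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  risk <- as.numeric(t(unclass(a_validation)[names(coefs), , drop = FALSE]) %*% coefs)
  names(risk) <- colnames(a_validation)
  n <- length(risk)
  n_high <- floor(n * top)
  n_low <- floor(n * bottom)
  if (n_high + n_low > n) stop("top + bottom fractions exceed 1", call. = FALSE)
  ord <- order(-risk, seq_len(n))   # stable: ties resolved by sample order
  ranked <- names(risk)[ord]
  grp <- setNames(rep("excluded", n), names(risk))
  grp[ranked[seq_len(n_high)]] <- "high"
  grp[ranked[seq(n - n_low + 1, n)]] <- "low"
  sorted_risk <- risk[ord]
  boundary_tie <- (n_high > 0 && n_high < n && sorted_risk[n_high] == sorted_risk[n_high + 1]) ||
    (n_low > 0 && n_low < n && sorted_risk[n - n_low + 1] == sorted_risk[n - n_low])
  if (boundary_tie) message("stratify_risk: ties at a group boundary resolved by sample order")
  attr(grp, "risk") <- risk
  grp
}

#' Two-group log-rank test
#'
#' Compares the Kaplan-Meier survival experience of the high- and low-risk
#' groups (samples labeled `"excluded"` are dropped).
#'
#' @param groups Named group labels from [stratify_risk()] (or any two-level
#'   labeling).
#' @param s Survival table.
#' @return List with `chisq` and `p` (1 df).
#' @export
logrank_test <- function(groups, s) {
  .check_survival_table(s)
  groups <- groups[groups != "excluded"]
  ids <- intersect(names(groups), s$sample_id)
  s <- s[match(ids, s$sample_id), , drop = FALSE]
  g <- factor(groups[ids])
  if (nlevels(g) != 2) stop("need exactly two non-empty groups", call. = FALSE)
  if (any(tapply(s$event, g, sum) == 0)) {
    warning("a group has zero events; the log-rank statistic may be degenerate")
  }
  sd <- survival::survdiff(survival::Surv(s$time, s$event) ~ g)
  chisq <- sd$chisq
  list(chisq = chisq, p = 1 - pchisq(chisq, df = 1))
}

#' Kaplan-Meier curve data per group
#'
#' Thin wrapper around [survival::survfit()] returning plot-ready step data.
#'
#' @param groups Named group labels.
#' @param s Survival table.
#' @return Data frame with `group`, `time`, `surv`.
#' @export
km_curve <- function(groups, s) {
  .check_survival_table(s)
  groups <- groups[groups != "excluded"]
  ids <- intersect(names(groups), s$sample_id)
  s <- s[match(ids, s$sample_id), , drop = FALSE]
  g <- factor(groups[ids])
  fit <- survival::survfit(survival::Surv(s$time, s$event) ~ g)
  grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  data.frame(group = grp, time = fit$time, surv = fit$surv,
             stringsAsFactors = FALSE)
}
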