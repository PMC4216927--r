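# Subtype association testing for inferred TF / protein activities:
# Mann-Whitney statistics per entity, empirical null distributions obtained
# by randomizing the trained interaction matrix, Benjamini-Hochberg FDR
# control, and a sign-consistency filter on subtype assignments.

#' Mann-Whitney U test between two groups
#'
#' Ties are mid-ranked. For small untied samples the exact null distribution
#' is used; otherwise the normal approximation with tie correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return List with `U` (statistic for group `a`) and two-sided `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(a, b))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Canonical subtype group comparisons
#'
#' When the labels are the four transcriptomic breast-cancer subtypes
#' (Basal, HER2, LumA, LumB, matched case-insensitively with a "basal-like"
#' synonym), returns the four standard contrasts: basal vs. rest, HER2 vs.
#' luminal, HER2 vs. basal, and LumA vs. LumB. Otherwise each level is
#' compared against all others.
#'
#' @param labels Character vector (or factor) of subtype labels.
#' @return Named list of comparisons, each a list with `group_a` and
#'   `group_b` label sets.
#' @export
subtype_comparisons <- function(labels) {
  lv <- unique(as.character(labels))
  canon <- tolower(lv)
  find <- function(x) lv[canon %in% x]
  basal <- find(c("basal", "basal-like"))
  her2 <- find("her2")
  luma <- find(c("luma", "luminal a"))
  lumb <- find(c("lumb", "luminal b"))
  if (length(basal) == 1 && length(her2) == 1 && length(luma) == 1 &&
      length(lumb) == 1) {
    return(list(
      basal_vs_rest = list(group_a = basal, group_b = c(her2, luma, lumb)),
      her2_vs_luminal = list(group_a = her2, group_b = c(luma, lumb)),
      her2_vs_basal = list(group_a = her2, group_b = basal),
      luma_vs_lumb = list(group_a = luma, group_b = lumb)))
  }
  out <- lapply(lv, function(l) list(group_a = l, group_b = setdiff(lv, l)))
  names(out) <- paste0(lv, "_vs_rest")
  out
}

#' Permutation-based empirical p-values for activity-subtype associations
#'
#' For each permutation the trained interaction matrix is randomized (by
#' default a row permutation that reassigns TF identities while preserving
#' the weight distribution; `null = "entrywise"` shuffles all entries),
#' activities are recomputed through the model, and each entity's centered
#' Mann-Whitney statistic for the group contrast is recorded. The empirical
#' p-value uses the add-one estimator
#' `p = (1 + #(|null| >= |observed|)) / (1 + n_perm)`, so it is never zero.
#'
#' @param model A fitted `affreg_model`.
#' @param labels Named subtype labels covering the profiled samples.
#' @param comparison List with `group_a` and `group_b` label sets.
#' @param kind `"tf"` (activities `W P'`, requires `p`) or `"protein"`
#'   (activities `Y'DW`, requires `y` and `d`).
#' @param p Centered samples x proteins matrix (for `kind = "tf"`).
#' @param y,d Centered expression and motif matrices (for `kind = "protein"`).
#' @param n_perm Number of randomized interaction matrices (>= 1).
#' @param seed Integer seed.
#' @param null `"rows"` or `"entrywise"` randomization of `W`.
#' @return Data frame with one row per entity: `entity`, `U`, `effect`
#'   (U centered at its null mean), and `p_emp`.
#' @export
permutation_null <- function(model, labels, comparison,
                             kind = c("tf", "protein"),
                             p = NULL, y = NULL, d = NULL,
                             n_perm = 1000, seed = 1,
                             null = c("rows", "entrywise")) {
  kind <- match.arg(kind)
  null <- match.arg(null)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (kind == "tf") {
    if (is.null(p)) stop("kind = 'tf' requires the protein matrix p", call. = FALSE)
    act <- infer_tf_activities(model, p)
    right <- t(p[, model$protein_ids, drop = FALSE])   # activities = W %*% right
  } else {
    if (is.null(y) || is.null(d)) {
      stop("kind = 'protein' requires y and d", call. = FALSE)
    }
    act <- infer_protein_activities(model, y, d)
    left <- crossprod(y, d)                            # activities = t(left %*% W)
  }
  labels <- labels[colnames(act)]
  ia <- which(labels %in% comparison$group_a)
  ib <- which(labels %in% comparison$group_b)
  if (length(ia) == 0 || length(ib) == 0) {
    stop("a comparison group has no samples", call. = FALSE)
  }
  obs <- .u_effects(unclass(act), ia, ib)
  set.seed(seed)
  q <- nrow(model$W)
  exceed <- integer(nrow(act))
  for (b in seq_len(n_perm)) {
    wb <- switch(null,
                 rows = model$W[sample(q), , drop = FALSE],
                 entrywise = matrix(sample(model$W), nrow = q))
    ab <- if (kind == "tf") wb %*% right else t(left %*% wb)
    eff_b <- .u_effects(ab, ia, ib)
    exceed <- exceed + (abs(eff_b) >= abs(obs))
  }
  na <- length(ia)
  data.frame(entity = rownames(act),
             U = obs + na * length(ib) / 2,
             effect = obs,
             p_emp = (1 + exceed) / (1 + n_perm),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery control
#'
#' Standard step-up procedure on a vector of p-values.
#'
#' @param pvals P-values in (0, 1].
#' @param q FDR threshold (default 0.10).
#' @return List with `rejected` (indices with adjusted value <= `q`) and
#'   `adjusted` (monotone BH-adjusted values).
#' @export
bh_fdr <- function(pvals, q = 0.10) {
  if (any(pvals <= 0 | pvals > 1 | is.na(pvals))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  adjusted <- p.adjust(pvals, method = "BH")
  list(rejected = which(adjusted <= q), adjusted = adjusted)
}

#' Filter subtype assignments by activity sign consistency
#'
#' An entity assigned to a subtype through a significant group contrast is
#' kept only when the subtype's own mean activity shares the sign of the
#' contrast; a zero mean is dropped (strict sign match).
#'
#' @param assignments Data frame with columns `entity`, `subtype`, and
#'   `contrast_sign` (+1 / -1, the sign of mean(group A) - mean(group B)).
#' @param activities Entities x samples activity matrix.
#' @param labels Named subtype labels for the activity columns.
#' @return The rows of `assignments` that pass the filter.
#' @export
sign_consistency_filter <- function(assignments, activities, labels) {
  if (nrow(assignments) == 0) return(assignments)
  labels <- labels[colnames(activities)]
  keep <- vapply(seq_len(nrow(assignments)), function(i) {
    ent <- assignments$entity[i]
    st <- assignments$subtype[i]
    mu <- mean(activities[ent, labels == st])
    sign(mu) == assignments$contrast_sign[i] && mu != 0
  }, TRUE)
  assignments[keep, , drop = FALSE]
}

#' Subtype association testing for inferred activities
#'
#' Runs the full association pipeline for every comparison: observed
#' Mann-Whitney statistics per entity, an empirical null from randomized
#' interaction matrices, BH correction of the empirical p-values across
#' entities, and sign-consistent subtype assignment.
#'
#' @inheritParams permutation_null
#' @param comparisons List of comparisons (default [subtype_comparisons()]).
#' @param fdr FDR threshold for assignment (default 0.10).
#' @return Data frame with columns `entity`, `comparison`, `U`, `p_emp`, `q`,
#'   `mean_diff`, `assigned`; the sign-filtered per-subtype assignments are
#'   attached as the `"subtype_assignments"` attribute.
#' @export
subtype_associations <- function(model, labels, kind = c("tf", "protein"),
                                 p = NULL, y = NULL, d = NULL,
                                 comparisons = NULL, n_perm = 1000,
                                 fdr = 0.10, seed = 1,
                                 null = c("rows", "entrywise")) {
  kind <- match.arg(kind)
  null <- match.arg(null)
  act <- if (kind == "tf") infer_tf_activities(model, p) else
    infer_protein_activities(model, y, d)
  labels <- labels[colnames(act)]
  comparisons <- comparisons %||% subtype_comparisons(labels)
  out <- list()
  assign_rows <- list()
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    cmp_name <- names(comparisons)[ci]
    pn <- permutation_null(model, labels, cmp, kind = kind, p = p, y = y,
                           d = d, n_perm = n_perm, seed = seed + ci,
                           null = null)
    bh <- bh_fdr(pn$p_emp, q = fdr)
    ia <- labels %in% cmp$group_a
    ib <- labels %in% cmp$group_b
    mean_diff <- rowMeans(act[, ia, drop = FALSE]) -
      rowMeans(act[, ib, drop = FALSE])
    tab <- data.frame(entity = pn$entity, comparison = cmp_name,
                      U = pn$U, p_emp = pn$p_emp, q = bh$adjusted,
                      mean_diff = mean_diff[pn$entity],
                      assigned = FALSE, stringsAsFactors = FALSE)
    if (length(bh$rejected) > 0) {
      cand <- expand.grid(entity = pn$entity[bh$rejected],
                          subtype = cmp$group_a,
                          stringsAsFactors = FALSE)
      cand$comparison <- cmp_name
      cand$contrast_sign <- sign(mean_diff[cand$entity])
      kept <- sign_consistency_filter(cand, act, labels)
      assign_rows[[cmp_name]] <- kept
      tab$assigned <- tab$entity %in% kept$entity
    }
    out[[cmp_name]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "subtype_assignments") <-
    if (length(assign_rows) > 0) do.call(rbind, assign_rows) else
      data.frame(entity = character(0), subtype = character(0),
                 comparison = character(0), contrast_sign = numeric(0))
  res
}
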