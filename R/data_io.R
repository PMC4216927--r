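# Reading the standard tabular formats and the preprocessing steps applied
# before model training: per-gene variance filtering on the log scale,
# mean-centering, motif-hit matrix construction from gene sets, redundancy
# removal among TFs with near-identical target sets, and universe alignment.

.read_id_table <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) {
    stop(sprintf("malformed header in %s: need an id column plus data columns",
                 path), call. = FALSE)
  }
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s id(s) in %s: %s", what, path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  bad <- which(is.na(num) & !is.na(body) & !(body %in% c("NA", "NaN", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s': '%s'",
                 path, ids[bad[1, 1]], colnames(body)[bad[1, 2]],
                 body[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  num[body %in% c("", "NA", "NaN")] <- NA_real_
  num
}

#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids, with a
#' numeric body on the log2 scale. Gene rows containing any missing value are
#' dropped (the count is reported via a message), so the returned matrix is
#' complete.
#'
#' @param path Path to a tab-separated file.
#' @return A genes x samples numeric matrix with a `centered = FALSE`
#'   attribute.
#' @export
read_expression_tsv <- function(path) {
  m <- .read_id_table(path, "gene")
  drop <- which(rowSums(is.na(m)) > 0)
  if (length(drop) > 0) {
    message(sprintf("read_expression_tsv: dropped %d gene row(s) with missing values",
                    length(drop)))
    m <- m[-drop, , drop = FALSE]
  }
  attr(m, "centered") <- FALSE
  m
}

#' Read a protein (RPPA) matrix from TSV
#'
#' Samples in rows (first column = sample id), proteins in columns. Protein
#' columns containing any missing value are dropped with a message.
#'
#' @param path Path to a tab-separated file.
#' @return A samples x proteins numeric matrix with a `centered = FALSE`
#'   attribute.
#' @export
read_protein_tsv <- function(path) {
  m <- .read_id_table(path, "sample")
  drop <- which(colSums(is.na(m)) > 0)
  if (length(drop) > 0) {
    message(sprintf("read_protein_tsv: dropped %d protein column(s) with missing values",
                    length(drop)))
    m <- m[, -drop, drop = FALSE]
  }
  attr(m, "centered") <- FALSE
  m
}

#' Read sample subtype labels from TSV
#'
#' Two columns: sample id and label.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A named character vector of labels keyed by sample id.
#' @export
read_labels_tsv <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) stop("label table needs at least two columns", call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) stop("duplicate sample ids in label table", call. = FALSE)
  setNames(raw[[2]], ids)
}

#' Filter genes by expression standard deviation
#'
#' Removes genes whose standard deviation across samples (denominator n - 1)
#' is strictly below `threshold`; genes exactly at the threshold are kept.
#' Applied to log-scale values before centering.
#'
#' @param y Genes x samples expression matrix, not yet centered.
#' @param threshold Non-negative sd cutoff (default 0.65 on the log2 scale).
#' @return The filtered matrix, row order preserved.
#' @export
filter_genes_by_sd <- function(y, threshold = 0.65) {
  .check_numeric_matrix(y, "y")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  if (isTRUE(attr(y, "centered"))) {
    stop("filter_genes_by_sd expects uncentered log-scale values", call. = FALSE)
  }
  sds <- apply(y, 1L, sd)
  out <- y[sds >= threshold, , drop = FALSE]
  attr(out, "centered") <- FALSE
  out
}

#' Mean-center an expression or protein matrix
#'
#' Subtracts each gene's mean across samples (`margin = "gene"`, rows) or
#' each protein's mean across samples (`margin = "protein"`, columns).
#'
#' @param x Numeric matrix.
#' @param margin `"gene"` for genes-in-rows expression data, `"protein"` for
#'   samples-in-rows protein data.
#' @return The centered matrix with a `centered = TRUE` attribute.
#' @export
mean_center <- function(x, margin = c("gene", "protein")) {
  margin <- match.arg(margin)
  .check_numeric_matrix(x, "x")
  if (length(x) == 0) stop("cannot center an empty matrix", call. = FALSE)
  out <- if (margin == "gene") x - rowMeans(x) else sweep(x, 2L, colMeans(x))
  attr(out, "centered") <- TRUE
  out
}

#' Read TF target-gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines with fewer than three
#' fields, duplicate set names, and empty member lists are rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list mapping TF/set name to a character vector of genes.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate GMT set name: %s", nm[duplicated(nm)][1]), call. = FALSE)
  }
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  empty <- which(vapply(sets, length, 1L) == 0L)
  if (length(empty) > 0) {
    stop(sprintf("GMT set '%s' has an empty member list", names(sets)[empty[1]]),
         call. = FALSE)
  }
  sets
}

#' Build a binary motif-hit matrix over a gene universe
#'
#' `D[i, j] = 1` iff gene i is a target of TF j. TF columns with zero hits in
#' the universe are dropped with a message.
#'
#' @param targets Named list mapping TF id to a character vector of target
#'   genes (e.g. from [read_gmt()]).
#' @param gene_universe Ordered character vector of gene ids.
#' @return Genes x TFs binary matrix.
#' @export
build_motif_matrix <- function(targets, gene_universe) {
  if (length(gene_universe) == 0) stop("gene universe is empty", call. = FALSE)
  if (anyDuplicated(gene_universe)) stop("duplicate ids in gene universe", call. = FALSE)
  d <- vapply(targets, function(g) as.integer(gene_universe %in% g),
              integer(length(gene_universe)))
  d <- matrix(d, nrow = length(gene_universe),
              dimnames = list(gene_universe, names(targets)))
  empty <- which(colSums(d) == 0)
  if (length(empty) > 0) {
    message(sprintf("build_motif_matrix: dropped %d TF(s) with no hits in the universe: %s",
                    length(empty), paste(colnames(d)[empty], collapse = ", ")))
    d <- d[, -empty, drop = FALSE]
  }
  d
}

#' Remove TFs with redundant target sets
#'
#' Greedy pass in lexicographic TF-id order: a TF is dropped when the Jaccard
#' similarity of its target set with any already-retained TF is at least
#' `jaccard_threshold`. The (dropped, representative) pairs are attached as
#' the `"dropped"` attribute.
#'
#' @param d Genes x TFs binary motif-hit matrix.
#' @param jaccard_threshold Similarity cutoff in (0, 1]; default 0.8.
#' @return The motif matrix restricted to retained TFs (original column
#'   order preserved).
#' @export
remove_redundant_motifs <- function(d, jaccard_threshold = 0.8) {
  .check_numeric_matrix(d, "d")
  if (!is.numeric(jaccard_threshold) || length(jaccard_threshold) != 1 ||
      jaccard_threshold <= 0 || jaccard_threshold > 1) {
    stop("jaccard_threshold must be in (0, 1]", call. = FALSE)
  }
  ord <- order(colnames(d))
  kept <- character(0)
  log <- list()
  for (tf in colnames(d)[ord]) {
    col <- d[, tf] > 0
    redundant <- NA_character_
    for (k in kept) {
      ref <- d[, k] > 0
      jac <- sum(col & ref) / sum(col | ref)
      if (jac >= jaccard_threshold) {
        redundant <- k
        break
      }
    }
    if (is.na(redundant)) {
      kept <- c(kept, tf)
    } else {
      log[[length(log) + 1L]] <- data.frame(dropped = tf, representative = redundant,
                                            stringsAsFactors = FALSE)
    }
  }
  out <- d[, colnames(d) %in% kept, drop = FALSE]
  attr(out, "dropped") <- if (length(log) > 0) do.call(rbind, log) else
    data.frame(dropped = character(0), representative = character(0))
  out
}

#' Align expression, motif, and protein matrices on shared universes
#'
#' Restricts `y` and `d` to their shared genes (in `y`'s order) and `y`, `p`,
#' and optional labels to their shared samples, ordering every object
#' identically. Idempotent.
#'
#' @param y Genes x samples expression matrix.
#' @param d Genes x TFs motif-hit matrix.
#' @param p Samples x proteins matrix.
#' @param labels Optional named label vector keyed by sample id.
#' @return List with elements `y`, `d`, `p`, and (when given) `labels`.
#' @export
align_cohort <- function(y, d, p, labels = NULL) {
  genes <- intersect(rownames(y), rownames(d))
  if (length(genes) == 0) stop("gene universes of y and d are disjoint", call. = FALSE)
  samples <- intersect(colnames(y), rownames(p))
  if (!is.null(labels)) samples <- intersect(samples, names(labels))
  if (length(samples) == 0) stop("sample universes are disjoint", call. = FALSE)
  out <- list(y = y[genes, samples, drop = FALSE],
              d = d[genes, , drop = FALSE],
              p = p[samples, , drop = FALSE])
  attr(out$y, "centered") <- attr(y, "centered")
  attr(out$p, "centered") <- attr(p, "centered")
  zero <- which(colSums(out$d) == 0)
  if (length(zero) > 0) {
    message(sprintf("align_cohort: dropped %d TF(s) with no hits after alignment",
                    length(zero)))
    out$d <- out$d[, -zero, drop = FALSE]
  }
  if (!is.null(labels)) out$labels <- labels[samples]
  out
}

# writers used by the simulator and pipeline stages -------------------------

.write_id_matrix <- function(m, path, id_name) {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write an expression matrix as TSV (genes in rows)
#' @param y Genes x samples matrix.
#' @param path Output path.
#' @export
write_expression_tsv <- function(y, path) .write_id_matrix(y, path, "gene_id")

#' Write a protein matrix as TSV (samples in rows)
#' @param p Samples x proteins matrix.
#' @param path Output path.
#' @export
write_protein_tsv <- function(p, path) .write_id_matrix(p, path, "sample_id")

#' Write a motif-hit matrix as a GMT file
#' @param d Genes x TFs binary matrix.
#' @param path Output path.
#' @param description Second GMT field, recycled across sets.
#' @export
write_gmt <- function(d, path, description = "synthetic") {
  lines <- vapply(colnames(d), function(tf) {
    paste(c(tf, description, rownames(d)[d[, tf] > 0]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}
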