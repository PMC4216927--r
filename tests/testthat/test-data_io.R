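write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("expression TSV parsing declares ids and drops incomplete genes", {
  f <- write_tsv_lines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"))
  y <- read_expression_tsv(f)
  expect_identical(dim(y), c(3L, 2L))
  expect_identical(rownames(y), c("g1", "g2", "g3"))
  expect_false(attr(y, "centered"))

  f2 <- write_tsv_lines(c("gene\ts1\ts2", "g1\t1\t2", "g2\tNA\t4", "g3\t5\t6"))
  expect_message(y2 <- read_expression_tsv(f2), "dropped 1 gene")
  expect_identical(dim(y2), c(2L, 2L))

  fdup <- write_tsv_lines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"))
  expect_error(read_expression_tsv(fdup), "duplicate gene id.*g1")

  fbad <- write_tsv_lines(c("gene\ts1\ts2", "g1\t1\tx", "g2\t3\t4"))
  expect_error(read_expression_tsv(fbad), "non-numeric.*g1.*s2")
})

test_that("protein TSV parsing drops columns with missing values", {
  f <- write_tsv_lines(c("sample\tp1\tp2\tp3",
                         "s1\t1\t2\t3", "s2\t4\t\t6", "s3\t7\t8\t9"))
  expect_message(p <- read_protein_tsv(f), "dropped 1 protein")
  expect_identical(colnames(p), c("p1", "p3"))
  expect_identical(rownames(p), c("s1", "s2", "s3"))
})

test_that("sd filter removes only strictly sub-threshold genes", {
  # two-sample rows with sd exactly 0.5, 0.65, 0.9
  y <- rbind(g1 = c(0, 0.50 * sqrt(2)),
             g2 = c(0, 0.65 * sqrt(2)),
             g3 = c(0, 0.90 * sqrt(2)))
  colnames(y) <- c("s1", "s2")
  expect_identical(rownames(filter_genes_by_sd(y, 0.65)), c("g2", "g3"))
  expect_equal(filter_genes_by_sd(y, 0), y, ignore_attr = TRUE)
  yc <- rbind(y, g4 = c(1, 1))
  expect_identical(rownames(filter_genes_by_sd(yc, 0.1)), c("g1", "g2", "g3"))
  expect_error(filter_genes_by_sd(y, -1), "non-negative")
  ycen <- mean_center(y, "gene")
  expect_error(filter_genes_by_sd(ycen, 0.1), "uncentered")
})

test_that("mean centering per gene and per protein, idempotently", {
  y <- matrix(c(1, 2, 3, 4, 4, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  yc <- mean_center(y, "gene")
  expect_equal(yc["g1", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_equal(yc["g2", ], c(s1 = 0, s2 = 0, s3 = 0))
  expect_true(attr(yc, "centered"))
  expect_equal(mean_center(yc, "gene"), yc, tolerance = 1e-12)

  p <- matrix(c(4, 4), ncol = 1, dimnames = list(c("s1", "s2"), "p1"))
  expect_equal(as.numeric(mean_center(p, "protein")), c(0, 0))
  expect_error(mean_center(matrix(numeric(0), 0, 0)), "empty")
})

test_that("GMT parsing validates structure and recovers memberships", {
  f <- write_tsv_lines(c("TFA\tdesc\tg1\tg2", "TFB\tdesc\tg3"))
  sets <- read_gmt(f)
  expect_length(sets, 2)
  expect_setequal(sets$TFA, c("g1", "g2"))

  fdup <- write_tsv_lines(c("TFA\tdesc\tg1", "TFA\tdesc\tg2"))
  expect_error(read_gmt(fdup), "duplicate GMT set name")
  fshort <- write_tsv_lines(c("TFA\tdesc\tg1", "TFB\tdesc"))
  expect_error(read_gmt(fshort), "line 2")
})

test_that("motif matrix construction over a universe", {
  targets <- list(A = c("g1", "g3"), B = c("g9"), C = c("g2"))
  expect_message(d <- build_motif_matrix(targets, c("g1", "g2", "g3")),
                 "dropped 1 TF")
  expect_equal(unname(d[, "A"]), c(1L, 0L, 1L))
  expect_identical(colnames(d), c("A", "C"))
  expect_equal(sum(d[, "A"] * d[, "C"]), 0L)  # disjoint targets
})

test_that("motif matrix is invariant to set order up to column permutation", {
  targets <- list(A = c("g1", "g3"), B = c("g2", "g3"))
  d1 <- build_motif_matrix(targets, paste0("g", 1:3))
  d2 <- build_motif_matrix(rev(targets), paste0("g", 1:3))
  expect_identical(d1, d2[, colnames(d1)])
})

test_that("redundant motif removal is greedy on lexicographic order", {
  d <- cbind(TFb = c(1L, 1L, 0L, 0L), TFa = c(1L, 1L, 0L, 0L),
             TFc = c(0L, 0L, 1L, 1L))
  rownames(d) <- paste0("g", 1:4)
  out <- remove_redundant_motifs(d, 0.8)
  expect_identical(colnames(out), c("TFa", "TFc"))   # Jaccard 1: keep first lexicographic
  expect_identical(attr(out, "dropped")$dropped, "TFb")
  expect_identical(attr(out, "dropped")$representative, "TFa")

  # Jaccard |{g2,g3}| / |{g1,g2,g3,g4}| = 0.5 < 0.8: both kept
  d2 <- cbind(TFa = c(1L, 1L, 1L, 0L), TFb = c(0L, 1L, 1L, 1L))
  rownames(d2) <- paste0("g", 1:4)
  expect_identical(colnames(remove_redundant_motifs(d2, 0.8)), c("TFa", "TFb"))
  # disjoint: both kept even at the lowest threshold
  d3 <- cbind(TFa = c(1L, 0L), TFb = c(0L, 1L))
  rownames(d3) <- paste0("g", 1:2)
  expect_identical(ncol(remove_redundant_motifs(d3, 0.1)), 2L)
  expect_error(remove_redundant_motifs(d, 0), "jaccard")
  expect_error(remove_redundant_motifs(d, 1.2), "jaccard")
})

test_that("alignment intersects universes, errors on disjoint, and is idempotent", {
  y <- matrix(rnorm(6), 3, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  d <- matrix(1L, 3, 1, dimnames = list(c("b", "c", "d"), "TFa"))
  p <- matrix(rnorm(4), 2, dimnames = list(c("s2", "s1"), c("p1", "p2")))
  al <- align_cohort(y, d, p)
  expect_identical(rownames(al$y), c("b", "c"))
  expect_identical(rownames(al$d), c("b", "c"))
  expect_identical(rownames(al$p), colnames(al$y))
  al2 <- align_cohort(al$y, al$d, al$p)
  expect_identical(al2[c("y", "d", "p")], al[c("y", "d", "p")])

  p_bad <- matrix(rnorm(4), 2, dimnames = list(c("s8", "s9"), c("p1", "p2")))
  expect_error(align_cohort(y, d, p_bad), "disjoint")
})

test_that("the filter-then-center pipeline leaves gene rows centered", {
  co <- small_cohort(seed = 3)
  y <- mean_center(filter_genes_by_sd(co$Y, 0.65), "gene")
  expect_lt(max(abs(rowMeans(y))), 1e-9)
})

test_that("cohort writers round-trip through the readers", {
  co <- small_cohort(seed = 9)
  dir <- tempfile()
  write_cohort(co, dir,
               drug_table = generate_drug_table(co$truth, n_drugs = 5,
                                                n_target_drugs = 2, seed = 9),
               survival_table = generate_survival(co$truth, seed = 9))
  y <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(unname(y), unname(co$Y), tolerance = 1e-12, ignore_attr = TRUE)
  p <- read_protein_tsv(file.path(dir, "rppa.tsv"))
  expect_equal(unname(p), unname(co$P), tolerance = 1e-12, ignore_attr = TRUE)
  sets <- read_gmt(file.path(dir, "tf_targets.gmt"))
  d <- build_motif_matrix(sets, rownames(co$Y))
  expect_equal(d[, colnames(co$D)], co$D)
  s <- read_survival_csv(file.path(dir, "survival.csv"))
  expect_identical(s$sample_id, names(co$labels))
})
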