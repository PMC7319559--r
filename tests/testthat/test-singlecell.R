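tiny_matrix <- function(counts, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(counts)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(counts)))
  cell_matrix(genes, cells, counts)
}

test_that("read_mtx maps triplets, sums duplicates and checks dimensions", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 3", "1 2 4", "2 1 2", "2 1 3"), mtx)
  writeLines(c("gA", "gB"), file.path(dir, "genes.txt"))
  writeLines(c("cA", "cB"), file.path(dir, "cells.txt"))
  m <- read_mtx(mtx, file.path(dir, "genes.txt"), file.path(dir, "cells.txt"))
  expect_equal(as.matrix(m$counts),
               matrix(c(0, 5, 4, 0), 2, dimnames = list(c("gA", "gB"), c("cA", "cB"))))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "genes.txt"))
  expect_error(read_mtx(mtx, file.path(dir, "genes.txt"),
                        file.path(dir, "cells.txt")), "id files")
})

test_that("dense counts round-trip through the reader", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.tsv")
  writeLines(c("gene\tc1\tc2", "gA\t0\t3", "gB\t2\t0"), path)
  m <- read_dense_counts(path)
  expect_equal(unname(as.matrix(m$counts)), rbind(c(0, 3), c(2, 0)))
})

test_that("filter_cells drops empty-droplet and doublet candidates", {
  counts <- cbind(rep(1, 10),               # 10 genes detected
                  c(rep(1, 9), 0),          # 9 genes
                  rep(0, 10))               # empty
  m <- tiny_matrix(counts)
  f <- filter_cells(m, min_genes = 10, max_count_mads = Inf)
  expect_identical(f$cells, "c01")
  expect_setequal(attr(f, "dropped"), c("c02", "c03"))
  # mads = Inf performs no doublet filtering at all
  f2 <- filter_cells(m, min_genes = 0, max_count_mads = Inf)
  expect_length(f2$cells, 3L)
  expect_error(filter_cells(m, min_genes = 100), "all cells")
})

test_that("a planted double-count doublet is the only cell removed", {
  set.seed(13)
  counts <- matrix(rpois(50 * 30, 2) + 1, nrow = 50)
  counts[, 30] <- counts[, 30] * 2  # doublet proxy: twice the library size
  m <- tiny_matrix(counts)
  f <- filter_cells(m, min_genes = 0, max_count_mads = 3)
  expect_identical(attr(f, "dropped"), "c30")
})

test_that("normalization is log scaled-counts-per-total and scale invariant", {
  counts <- matrix(0, nrow = 3, ncol = 2)
  counts[1, 1] <- 5
  counts[, 2] <- c(1, 2, 3)
  m <- normalize_cells(tiny_matrix(counts), scale = 1e4)
  expect_equal(m$normalized[1, 1], log(1 + 1e4))
  expect_equal(m$normalized[2, 1], 0)
  doubled <- counts; doubled[, 2] <- doubled[, 2] * 2
  m2 <- normalize_cells(tiny_matrix(doubled), scale = 1e4)
  expect_equal(m2$normalized[, 2], m$normalized[, 2], tolerance = 1e-12)
  zero <- tiny_matrix(cbind(c(1, 0, 0), 0))
  expect_error(normalize_cells(zero), "zero-total")
})

test_that("expressed_set supports nonzero and deterministic top_k modes", {
  counts <- cbind(c(2, 0, 1, 0), c(1, 1, 1, 1))
  m <- tiny_matrix(counts, genes = c("A", "B", "C", "D"))
  expect_setequal(expressed_set(m, "c01"), c("A", "C"))
  m <- normalize_cells(m)
  expect_identical(expressed_set(m, "c02", "top_k", k = 2), c("A", "B"))
  expect_identical(expressed_set(m, "c02", "top_k", k = 4), c("A", "B", "C", "D"))
  expect_error(expressed_set(m, "c02", "top_k", k = 5), "exceeds")
  expect_error(expressed_set(m, "nope"), "unknown cell")
})

test_that("per-cell enrichment finds a cell's matching category", {
  genes <- sprintf("g%02d", 1:50)
  coll <- gene_set_collection("c", list(P = genes[1:10], Q = genes[21:30]),
                              universe = genes)
  counts <- matrix(0, 50, 3)
  counts[1:10, 1] <- 1          # cell 1 expresses exactly P
  counts[c(1:5, 21:25), 2] <- 1 # cell 2 mixed
  counts[31:50, 3] <- 1         # cell 3 disjoint from both categories
  m <- tiny_matrix(counts)
  pc <- percell_enrichment(m, coll)
  expect_equal(colnames(pc$p_raw), c("P", "Q"))
  expect_lt(pc$p_raw["c01", "P"], pc$p_raw["c01", "Q"])
  expect_equal(pc$p_raw["c01", "P"], ora(genes[1:10], genes[1:10], genes)$p_raw)
  expect_equal(pc$p_raw["c03", "P"], 1)   # k = 0 => p = 1
  expect_false(any(pc$enriched["c03", ]))
  pc0 <- percell_enrichment(m, coll, alpha = 0)
  expect_false(any(pc0$enriched))
})

test_that("a cell's enrichment depends only on its own expressed set", {
  set.seed(23)
  genes <- sprintf("g%02d", 1:40)
  coll <- gene_set_collection("c", list(P = genes[1:8], Q = genes[9:20]),
                              universe = genes)
  counts <- matrix(rbinom(40 * 6, 1, 0.3), 40, 6)
  counts[, 1] <- c(rep(1, 8), rep(0, 32))
  m <- tiny_matrix(counts)
  p1 <- percell_enrichment(m, coll)$p_raw["c01", ]
  shuf <- counts[, c(1, 6, 4, 5, 3, 2)]  # permute the *other* cells
  p2 <- percell_enrichment(tiny_matrix(shuf), coll)$p_raw["c01", ]
  expect_equal(p1, p2)
})

test_that("group characterization flags the planted pathway and conserves counts", {
  fx <- make_singlecell_fixture(group_sizes = c(A = 60, B = 60), n_genes = 300,
                                n_categories = 6, category_size = 25, seed = 19)
  m <- normalize_cells(filter_cells(fx$matrix, min_genes = 5,
                                    max_count_mads = Inf))
  pc <- percell_enrichment(m, fx$collection)
  ch <- suppressWarnings(
    characterize_groups(pc, fx$annotation, "age_group"))
  # contingency conservation: a+b+c+d = number of cells for every category
  expect_true(all(ch$a + ch$b + ch$c + ch$d == length(m$cells)))
  expect_true(all(ch$a + ch$b == 60))
  actA <- ch[ch$group == "A" & ch$call == "predominantly_active", ]
  expect_identical(actA$category_id[1L], fx$truth$A)
  # the planted category of B is depleted in A
  bInA <- ch[ch$group == "A" & ch$category_id == fx$truth$B, ]
  expect_identical(bInA$call, "predominantly_inactive")
})

test_that("identical enrichment rates across groups give chi2 = 0 and ns", {
  enriched <- matrix(FALSE, 20, 2, dimnames = list(sprintf("c%02d", 1:20),
                                                   c("P", "Q")))
  enriched[c(1:5, 11:15), 1] <- TRUE  # 50% in both halves
  ann <- data.frame(cell_id = sprintf("c%02d", 1:20),
                    grp = rep(c("x", "y"), each = 10))
  ch <- suppressWarnings(characterize_groups(enriched, ann, "grp"))
  px <- ch[ch$group == "x" & ch$category_id == "P", ]
  expect_equal(px$chi2, 0)
  expect_identical(px$call, "ns")
  # degenerate table (Q never enriched) recorded as ns with p = 1
  qx <- ch[ch$group == "x" & ch$category_id == "Q", ]
  expect_equal(qx$p_raw, 1)
  expect_identical(qx$call, "ns")
})

test_that("characterization chi2 agrees with the closed-form 2x2 statistic", {
  enriched <- matrix(FALSE, 100, 1, dimnames = list(sprintf("c%03d", 1:100), "P"))
  enriched[1:10, 1] <- TRUE        # a = 10, b = 20 in group g1 (30 cells)
  enriched[31:60, 1] <- TRUE       # c = 30, d = 40 outside
  ann <- data.frame(cell_id = sprintf("c%03d", 1:100),
                    grp = rep(c("g1", "g2"), c(30, 70)))
  ch <- characterize_groups(enriched, ann, "grp")
  ref <- chi_square_2x2(10, 20, 30, 40)
  row <- ch[ch$group == "g1", ]
  expect_equal(row$chi2, ref$statistic, tolerance = 1e-12)
  expect_equal(row$p_raw, ref$p, tolerance = 1e-12)
})
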