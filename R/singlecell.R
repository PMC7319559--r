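#' Single-cell enrichment workflow
#'
#' Filters artifact cells from a scRNA-seq count matrix, normalizes to
#' log counts-per-scale, runs an over-representation analysis per cell on
#' the set of genes expressed in that cell (against the global gene
#' universe), and characterizes annotated cell groups by testing, for
#' every pathway, whether the group's cells are enriched for it more or
#' less often than all other cells (chi-square 2x2 test).
#'
#' @name singlecell
NULL

#' Construct a cell matrix
#'
#' @param genes,cells character vectors of unique ids.
#' @param counts genes x cells matrix of non-negative counts; coerced to
#'   a sparse `dgCMatrix`.
#' @return a `CellMatrix` (list with `genes`, `cells`, `counts`,
#'   `normalized`).
#' @export
cell_matrix <- function(genes, cells, counts) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (anyDuplicated(genes) || anyDuplicated(cells)) {
    stop("gene and cell ids must be unique")
  }
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells)) {
    stop("counts must be genes x cells")
  }
  if (any(counts@x < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(genes, cells)
  structure(list(genes = as.character(genes), cells = as.character(cells),
                 counts = counts, normalized = NULL),
            class = "CellMatrix")
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells, %.1f%% nonzero%s\n",
              length(x$genes), length(x$cells),
              100 * length(x$counts@x) /
                (length(x$genes) * length(x$cells)),
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' Read a MatrixMarket sparse count matrix
#'
#' Reads a coordinate-format MTX triplet plus one-id-per-line gene and
#' cell files (genes as MTX rows, cells as columns). Duplicate `(i, j)`
#' entries are summed.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param genes_path,cells_path paths to the row/column id files.
#' @return a [cell_matrix()].
#' @export
read_mtx <- function(matrix_path, genes_path, cells_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path, warn = FALSE)
  cells <- readLines(cells_path, warn = FALSE)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop(sprintf("MTX header is %d x %d but id files list %d genes and %d cells",
                 nrow(m), ncol(m), length(genes), length(cells)))
  }
  # Csparse conversion sums duplicate triplet entries
  cell_matrix(genes, cells, m)
}

#' Read a dense count matrix
#'
#' White-space separated genes x cells table: header row of cell ids,
#' first column gene ids.
#'
#' @param path path to the table.
#' @return a [cell_matrix()].
#' @export
read_dense_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cell_matrix(df[[1L]], colnames(df)[-1L], as.matrix(df[, -1L, drop = FALSE]))
}

#' Read a cell-annotation table
#'
#' TSV with a `cell_id` column plus arbitrary annotation columns (age
#' group, tissue, precomputed cluster labels from external tools, ...).
#'
#' @param path path to the TSV.
#' @return data.frame keyed by `cell_id`.
#' @export
read_cell_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!"cell_id" %in% names(df)) stop("annotation needs a cell_id column")
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in annotation")
  df
}

#' Remove artifact cells
#'
#' Cells detecting fewer than `min_genes` genes are dropped as
#' empty-droplet candidates; cells whose total count exceeds
#' `median + max_count_mads * MAD` of the per-cell totals are dropped as
#' doublet candidates (MAD on the usual 1.4826 normal-consistency scale).
#'
#' @param m a `CellMatrix`.
#' @param min_genes minimum number of detected genes (default 200).
#' @param max_count_mads MAD multiplier for the upper total-count cutoff
#'   (default 3; `Inf` disables doublet filtering).
#' @return the filtered `CellMatrix`, with attribute `dropped` listing the
#'   removed cell ids.
#' @export
filter_cells <- function(m, min_genes = 200L, max_count_mads = 3) {
  stopifnot(inherits(m, "CellMatrix"), min_genes >= 0)
  detected <- Matrix::colSums(m$counts > 0)
  totals <- Matrix::colSums(m$counts)
  cutoff <- stats::median(totals) + max_count_mads * stats::mad(totals)
  keep <- detected >= min_genes & (is.infinite(max_count_mads) | totals <= cutoff)
  if (!any(keep)) stop("all cells removed by filtering")
  dropped <- m$cells[!keep]
  out <- cell_matrix(m$genes, m$cells[keep], m$counts[, keep, drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Normalize counts to log scaled counts
#'
#' `normalized[g, c] = log(1 + counts[g, c] * scale / total_c)` with
#' `total_c` the cell's total count — log counts-per-10k for the default
#' scale. Scale-invariant per cell: doubling all of a cell's counts
#' leaves its normalized profile unchanged.
#'
#' @param m a `CellMatrix`; every cell must have a positive total (filter
#'   first).
#' @param scale library-size scale factor (default `1e4`).
#' @return the `CellMatrix` with the `normalized` slot filled.
#' @export
normalize_cells <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "CellMatrix"), scale > 0)
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) {
    stop("zero-total cell(s): ",
         paste(utils::head(m$cells[totals == 0], 5L), collapse = ", "),
         "; run filter_cells first")
  }
  norm <- m$counts %*% Matrix::Diagonal(x = scale / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m$counts)
  m$normalized <- norm
  m
}

#' Genes expressed in one cell
#'
#' `nonzero` mode returns every gene with a positive count in the cell;
#' `top_k` returns the `k` genes with the highest normalized values, ties
#' broken lexicographically by gene id.
#'
#' @param m a `CellMatrix` (normalized, for `top_k`).
#' @param cell a cell id.
#' @param mode `"nonzero"` (default) or `"top_k"`.
#' @param k number of genes for `top_k`.
#' @return character vector of gene ids.
#' @export
expressed_set <- function(m, cell, mode = c("nonzero", "top_k"), k = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "CellMatrix"))
  j <- match(cell, m$cells)
  if (is.na(j)) stop("unknown cell: ", cell)
  if (mode == "nonzero") {
    return(m$genes[m$counts[, j] > 0])
  }
  if (is.null(k)) stop("top_k mode needs k")
  if (k > length(m$genes)) stop("k exceeds the number of genes")
  v <- if (!is.null(m$normalized)) m$normalized[, j] else m$counts[, j]
  ord <- order(-v, m$genes)
  sort(m$genes[ord[seq_len(k)]])
}

#' Per-cell over-representation analysis
#'
#' For each cell, ORA of the cell's expressed gene set against every
#' category, with the full gene universe of the matrix as background;
#' p-values adjusted per cell across categories; a cell is called
#' "enriched" for a category when its adjusted p-value is at most
#' `alpha`.
#'
#' @param m a `CellMatrix`.
#' @param coll a [gene_set_collection()]; harmonized to the matrix genes
#'   internally.
#' @param mode,k expressed-set criterion, see [expressed_set()].
#' @param correction per-cell correction method (default `"bh"`).
#' @param alpha adjusted-p threshold for the enriched call (default 0.05).
#' @return a `PerCellEnrichment`: list with matrices `p_raw`,
#'   `p_adjusted` and logical `enriched` (cells x categories), plus
#'   `alpha`, `correction` and the `universe` used.
#' @export
percell_enrichment <- function(m, coll, mode = c("nonzero", "top_k"), k = NULL,
                               correction = "bh", alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "CellMatrix"), inherits(coll, "GeneSetCollection"))
  coll <- suppressWarnings(harmonize(coll, m$genes))
  if (length(coll$sets) == 0L) stop("no categories left after harmonization")
  N <- length(m$genes)
  ncat <- length(coll$sets)
  memb <- Matrix::sparseMatrix(
    i = match(unlist(coll$sets, use.names = FALSE), m$genes),
    j = rep(seq_len(ncat), lengths(coll$sets)),
    x = 1, dims = c(N, ncat))
  if (mode == "nonzero") {
    expr <- Matrix::drop0(m$counts)
    expr@x[] <- 1
  } else {
    if (is.null(k)) stop("top_k mode needs k")
    sets <- lapply(m$cells, function(cl) expressed_set(m, cl, "top_k", k))
    expr <- Matrix::sparseMatrix(
      i = match(unlist(sets), m$genes),
      j = rep(seq_along(sets), lengths(sets)),
      x = 1, dims = c(N, length(m$cells)))
  }
  n_per_cell <- Matrix::colSums(expr)            # n: expressed genes per cell
  if (any(n_per_cell == 0)) {
    stop("cell(s) with empty expressed set: ",
         paste(utils::head(m$cells[n_per_cell == 0], 5L), collapse = ", "),
         "; run filter_cells first")
  }
  K <- lengths(coll$sets)                        # K per category
  kmat <- as.matrix(Matrix::t(expr) %*% memb)    # cells x categories overlap
  Km <- matrix(K, nrow = length(m$cells), ncol = ncat, byrow = TRUE)
  nm <- matrix(n_per_cell, nrow = length(m$cells), ncol = ncat)
  p_raw <- matrix(
    stats::phyper(kmat - 1, Km, N - Km, nm, lower.tail = FALSE),
    nrow = length(m$cells),
    dimnames = list(m$cells, coll$ids))
  p_adj <- t(apply(p_raw, 1L, adjust_pvalues, method = correction))
  dimnames(p_adj) <- dimnames(p_raw)
  structure(
    list(p_raw = p_raw, p_adjusted = p_adj, enriched = p_adj <= alpha,
         alpha = alpha, correction = correction, universe = m$genes),
    class = "PerCellEnrichment")
}

#' @export
print.PerCellEnrichment <- function(x, ...) {
  cat(sprintf("PerCellEnrichment: %d cells x %d categories; %.1f%% enriched calls at alpha = %g\n",
              nrow(x$enriched), ncol(x$enriched),
              100 * mean(x$enriched), x$alpha))
  invisible(x)
}

#' Chi-square characterization of cell groups
#'
#' For every value of one annotation column and every category, fills the
#' 2x2 table (a = enriched cells in the group, b = not-enriched in the
#' group, c = enriched outside, d = not-enriched outside) and applies the
#' chi-square test without continuity correction; p-values adjusted
#' across categories within each group. A category is called
#' `predominantly_active` in a group when significant with an odds
#' ratio above 1, `predominantly_inactive` when significant with an
#' odds ratio below 1, and `ns` otherwise. Degenerate tables (a zero margin, e.g. a category
#' enriched in no cell at all) are recorded as `ns` with p = 1 and a
#' warning.
#'
#' @param calls a `PerCellEnrichment` (or its logical `enriched` matrix,
#'   cells x categories).
#' @param ann annotation data.frame from [read_cell_annotation()]; must
#'   annotate every cell of `calls`.
#' @param annotation_name name of the grouping column.
#' @param correction method for [adjust_pvalues()].
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return data.frame with one row per (group, category): `group`,
#'   `category_id`, `a`, `b`, `c`, `d`, `chi2`, `p_raw`, `p_adjusted`,
#'   `odds_ratio`, `call`; within each group sorted by `p_raw`.
#' @export
characterize_groups <- function(calls, ann, annotation_name,
                                correction = "bh", alpha = 0.05) {
  enriched <- if (inherits(calls, "PerCellEnrichment")) calls$enriched else calls
  cells <- rownames(enriched)
  if (!annotation_name %in% names(ann)) {
    stop("annotation column not found: ", annotation_name)
  }
  lab <- ann[[annotation_name]][match(cells, ann$cell_id)]
  if (anyNA(lab)) {
    stop("cells without ", annotation_name, " annotation: ",
         paste(utils::head(cells[is.na(lab)], 5L), collapse = ", "))
  }
  groups <- sort(unique(as.character(lab)))
  cats <- colnames(enriched)
  out <- list()
  for (g in groups) {
    ing <- lab == g
    if (!any(ing)) stop("group with 0 cells: ", g)
    a <- colSums(enriched[ing, , drop = FALSE])
    b <- sum(ing) - a
    cc <- colSums(enriched[!ing, , drop = FALSE])
    d <- sum(!ing) - cc
    chi2 <- p <- or <- numeric(length(cats))
    degen <- logical(length(cats))
    for (i in seq_along(cats)) {
      res <- tryCatch(chi_square_2x2(a[i], b[i], cc[i], d[i]),
                      error = function(e) NULL)
      if (is.null(res)) {
        degen[i] <- TRUE
        chi2[i] <- 0; p[i] <- 1; or[i] <- NA_real_
      } else {
        chi2[i] <- res$statistic; p[i] <- res$p; or[i] <- res$odds_ratio
      }
    }
    if (any(degen)) {
      warning(sum(degen), " degenerate table(s) in group ", g,
              " recorded as ns with p = 1")
    }
    padj <- adjust_pvalues(p, correction)
    call <- rep("ns", length(cats))
    sig <- !degen & padj <= alpha
    call[sig & or > 1] <- "predominantly_active"
    call[sig & or < 1] <- "predominantly_inactive"
    df <- data.frame(group = g, category_id = cats,
                     a = as.integer(a), b = as.integer(b),
                     c = as.integer(cc), d = as.integer(d),
                     chi2 = chi2, p_raw = p, p_adjusted = padj,
                     odds_ratio = or, call = call,
                     stringsAsFactors = FALSE, row.names = NULL)
    out[[g]] <- df[order(df$p_raw, df$category_id), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scatter of cells colored by a per-cell p-value
#'
#' Smoke-test visualization: plots precomputed 2D coordinates (e.g. a
#' UMAP embedding carried in the annotation table) colored by
#' `-log10(p_adjusted)` of one category.
#'
#' @param embedding data.frame/matrix with two coordinate columns, rows
#'   matching the cells of `calls`.
#' @param calls a `PerCellEnrichment`.
#' @param category_id category to display.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the color vector used.
#' @export
plot_cell_pvalues <- function(embedding, calls, category_id, ...) {
  stopifnot(inherits(calls, "PerCellEnrichment"))
  p <- calls$p_adjusted[, category_id]
  score <- -log10(pmax(p, 1e-300))
  pal <- grDevices::colorRampPalette(c("grey80", "darkblue"))(100)
  col <- pal[pmin(100L, 1L + floor(99 * score / max(score, 1e-12)))]
  graphics::plot(embedding[, 1L], embedding[, 2L], col = col, pch = 16,
                 xlab = colnames(embedding)[1L], ylab = colnames(embedding)[2L],
                 main = paste0(category_id, " (-log10 adj. p)"), ...)
  invisible(col)
}
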