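#' Time-series clustering workflow
#'
#' Filters a time-resolved expression matrix for genes with appreciable
#' change over time, groups the remaining expression curves with a
#' two-stage hierarchical clustering (strict clusters first, then
#' "super-clusters" of similar cluster mean curves), orders the
#' super-clusters by their most active point in time, and runs
#' over-representation analyses for every cluster and super-cluster.
#'
#' @name timeseries
NULL

#' Construct / read a time-resolved expression series
#'
#' The on-disk format is a white-space separated matrix: a header row of
#' numeric time labels (hours) and one row per gene, first column the
#' gene id.
#'
#' @param genes character vector of gene ids.
#' @param timepoints strictly increasing numeric vector (>= 3 values).
#' @param values numeric matrix, genes x timepoints, no missing values.
#' @return an `ExpressionSeries` (list with `genes`, `timepoints`,
#'   `values`).
#' @export
expression_series <- function(genes, timepoints, values) {
  values <- as.matrix(values)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 3L) stop("need at least 3 timepoints")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (nrow(values) != length(genes) || ncol(values) != length(timepoints)) {
    stop("values must be genes x timepoints")
  }
  if (anyNA(values)) stop("missing values are not supported")
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  dimnames(values) <- list(genes, as.character(timepoints))
  structure(list(genes = as.character(genes), timepoints = timepoints,
                 values = values),
            class = "ExpressionSeries")
}

#' @rdname expression_series
#' @param path path to the matrix file.
#' @export
read_expression_series <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  tp <- suppressWarnings(as.numeric(colnames(df)[-1L]))
  if (anyNA(tp)) stop("header must contain numeric time labels")
  expression_series(df[[1L]], tp, as.matrix(df[, -1L, drop = FALSE]))
}

#' @export
print.ExpressionSeries <- function(x, ...) {
  cat(sprintf("ExpressionSeries: %d genes x %d timepoints (t = %s ... %s)\n",
              length(x$genes), length(x$timepoints),
              format(min(x$timepoints)), format(max(x$timepoints))))
  invisible(x)
}

#' Write an expression series
#' @param series an `ExpressionSeries`.
#' @param path output path.
#' @export
write_expression_series <- function(series, path) {
  df <- data.frame(gene = series$genes, series$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", format(series$timepoints, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove genes with limited expression change over time
#'
#' The per-gene change statistic is the range (max - min) across
#' timepoints; genes below `min_range` are removed. On log-scale data the
#' default of 1.0 corresponds to a two-fold change for log2 values.
#'
#' @param series an `ExpressionSeries`.
#' @param min_range non-negative threshold on the per-gene range.
#' @return the filtered series, gene order preserved.
#' @export
filter_low_change <- function(series, min_range = 1.0) {
  stopifnot(inherits(series, "ExpressionSeries"), min_range >= 0)
  rng <- apply(series$values, 1L, function(v) max(v) - min(v))
  keep <- rng >= min_range
  if (!any(keep)) {
    stop("min_range = ", min_range,
         " removed every gene; lower the threshold")
  }
  expression_series(series$genes[keep], series$timepoints,
                    series$values[keep, , drop = FALSE])
}

#' Euclidean distance of expression gradients
#'
#' The gradient of a curve between consecutive timepoints is
#' `g_i = (v[i+1] - v[i]) / (t[i+1] - t[i])`; the distance between two
#' curves is the Euclidean norm of the difference of their gradient
#' vectors. It is invariant to additive offsets, so curves with the same
#' shape but different baseline expression are close.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param timepoints matching numeric vector of times.
#' @return the gradient distance, a non-negative number.
#' @export
gradient_distance <- function(x, y, timepoints) {
  stopifnot(length(x) == length(y), length(x) == length(timepoints),
            length(x) >= 2L)
  dt <- diff(timepoints)
  if (any(dt == 0)) stop("duplicate timepoints")
  gx <- diff(x) / dt
  gy <- diff(y) / dt
  sqrt(sum((gx - gy)^2))
}

# gradient matrix (genes x (T-1)) of a series
.gradients <- function(values, timepoints) {
  dt <- diff(timepoints)
  if (any(dt == 0)) stop("duplicate timepoints")
  t(apply(values, 1L, diff)) / rep(dt, each = nrow(values))
}

# dist object for a series under a named distance measure
.series_dist <- function(values, timepoints, distance) {
  d <- switch(distance,
    gradient_euclidean = stats::dist(.gradients(values, timepoints)),
    euclidean = stats::dist(values),
    one_minus_pearson = stats::as.dist(1 - stats::cor(t(values))),
    stop("unknown distance: ", distance))
  if (any(!is.finite(d))) stop("non-finite distances (constant rows under correlation?)")
  d
}

#' Hierarchical clustering of expression curves
#'
#' Agglomerative clustering under one of three distances
#' (`gradient_euclidean`, plain `euclidean`, `one_minus_pearson`) and
#' complete or average linkage; flat clusters are obtained by cutting the
#' dendrogram at height `cut`. Genes are ordered lexicographically before
#' clustering so equal-height merges resolve deterministically.
#'
#' @param series an `ExpressionSeries` with >= 2 genes.
#' @param distance distance measure (default `gradient_euclidean`).
#' @param linkage `"complete"` (default) or `"average"`.
#' @param cut positive dendrogram cut height.
#' @return named list cluster-id (`"C1"`, `"C2"`, ...) -> gene ids;
#'   cluster ids are assigned in decreasing cluster size (ties by first
#'   member).
#' @export
hier_cluster <- function(series,
                         distance = c("gradient_euclidean", "euclidean",
                                      "one_minus_pearson"),
                         linkage = c("complete", "average"), cut) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(inherits(series, "ExpressionSeries"), cut > 0)
  if (length(series$genes) < 2L) stop("need at least 2 genes")
  ord <- order(series$genes)
  vals <- series$values[ord, , drop = FALSE]
  d <- .series_dist(vals, series$timepoints, distance)
  hc <- stats::hclust(d, method = linkage)
  memb <- stats::cutree(hc, h = cut)
  cl <- split(series$genes[ord], memb)
  cl <- cl[order(-lengths(cl), vapply(cl, `[[`, "", 1L))]
  names(cl) <- paste0("C", seq_along(cl))
  cl
}

#' Dendrogram merge-height summary
#'
#' Cut heights are data-scale dependent; this helper reports the sorted
#' merge heights of the dendrogram so users can pick strict and
#' super-cluster cuts from the gaps.
#'
#' @inheritParams hier_cluster
#' @return numeric vector of merge heights, ascending.
#' @export
suggest_cut_heights <- function(series,
                                distance = c("gradient_euclidean", "euclidean",
                                             "one_minus_pearson"),
                                linkage = c("complete", "average")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  d <- .series_dist(series$values, series$timepoints, distance)
  sort(stats::hclust(d, method = linkage)$height)
}

#' Two-stage clustering into clusters and super-clusters
#'
#' Stage 1 cuts the dendrogram at the strict height, producing small
#' clusters whose members are all highly similar; clusters smaller than
#' `min_cluster_size` are discarded (their genes reported as unassigned).
#' Stage 2 clusters the mean curves of the surviving clusters at the
#' (larger) super height, combining similar clusters into super-clusters.
#'
#' @inheritParams hier_cluster
#' @param strict_cut stage-1 cut height; must be smaller than `super_cut`.
#' @param super_cut stage-2 cut height on cluster mean curves.
#' @param min_cluster_size smallest stage-1 cluster kept (default 5).
#' @return a `ClusterTree`: list with `clusters` (id -> genes),
#'   `super_clusters` (id -> cluster ids), `mean_curves` (list `cluster`
#'   and `super` of matrices), `discarded` (gene ids), `genes` (all
#'   post-filter genes), `timepoints`.
#' @export
two_stage <- function(series, strict_cut, super_cut, min_cluster_size = 5L,
                      distance = c("gradient_euclidean", "euclidean",
                                   "one_minus_pearson"),
                      linkage = c("complete", "average")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (!(strict_cut < super_cut)) stop("strict_cut must be < super_cut")
  stage1 <- hier_cluster(series, distance, linkage, cut = strict_cut)
  small <- lengths(stage1) < min_cluster_size
  discarded <- sort(unlist(stage1[small], use.names = FALSE))
  clusters <- stage1[!small]
  if (length(clusters) < 2L) {
    stop("fewer than 2 clusters of size >= ", min_cluster_size,
         " survive the strict cut")
  }
  names(clusters) <- paste0("C", seq_along(clusters))
  cmeans <- t(vapply(clusters, function(g) {
    colMeans(series$values[match(g, series$genes), , drop = FALSE])
  }, numeric(length(series$timepoints))))
  mean_series <- expression_series(names(clusters), series$timepoints, cmeans)
  stage2 <- hier_cluster(mean_series, distance, linkage, cut = super_cut)
  names(stage2) <- paste0("SC", seq_along(stage2))
  smeans <- t(vapply(stage2, function(cids) {
    g <- unlist(clusters[cids], use.names = FALSE)
    colMeans(series$values[match(g, series$genes), , drop = FALSE])
  }, numeric(length(series$timepoints))))
  structure(
    list(clusters = clusters, super_clusters = stage2,
         mean_curves = list(cluster = cmeans, super = smeans),
         discarded = discarded, genes = series$genes,
         timepoints = series$timepoints),
    class = "ClusterTree")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat(sprintf("ClusterTree: %d clusters in %d super-clusters (%d genes, %d unassigned)\n",
              length(x$clusters), length(x$super_clusters),
              length(x$genes), length(x$discarded)))
  invisible(x)
}

#' Super-cluster membership of every gene
#'
#' @param tree a `ClusterTree`.
#' @return data.frame `gene`, `cluster`, `super_cluster`; discarded genes
#'   appear with `NA` labels.
#' @export
cluster_membership <- function(tree) {
  stopifnot(inherits(tree, "ClusterTree"))
  cl <- rep(names(tree$clusters), lengths(tree$clusters))
  genes <- unlist(tree$clusters, use.names = FALSE)
  c2sc <- rep(names(tree$super_clusters), lengths(tree$super_clusters))
  names(c2sc) <- unlist(tree$super_clusters, use.names = FALSE)
  df <- data.frame(gene = c(genes, tree$discarded),
                   cluster = c(cl, rep(NA_character_, length(tree$discarded))),
                   stringsAsFactors = FALSE)
  df$super_cluster <- unname(c2sc[df$cluster])
  df[order(df$gene), , drop = FALSE]
}

#' Order super-clusters by most active point in time
#'
#' Each super-cluster's mean curve is z-scored (so amplitude differences
#' do not dominate) and its peak time is the timepoint of the maximum;
#' super-clusters are sorted by ascending peak time, so the earliest
#' responding groups come first. Ties are broken by larger membership
#' first, then id.
#'
#' @param tree a `ClusterTree`.
#' @param timepoints defaults to the tree's timepoints.
#' @return character vector of super-cluster ids in activity order.
#' @export
order_superclusters <- function(tree, timepoints = tree$timepoints) {
  stopifnot(inherits(tree, "ClusterTree"))
  sm <- tree$mean_curves$super
  peak <- apply(sm, 1L, function(v) {
    s <- stats::sd(v)
    z <- if (s > 0) (v - mean(v)) / s else v * 0
    timepoints[which.max(z)]
  })
  sizes <- vapply(tree$super_clusters, function(cids) {
    sum(lengths(tree$clusters[cids]))
  }, 0L)
  ids <- names(tree$super_clusters)
  ids[order(peak, -sizes, ids)]
}

#' Enrichment of every cluster and super-cluster
#'
#' Over-representation analysis for each stage-1 cluster and each
#' super-cluster against the collection, with all post-filter genes as
#' the universe; p-values adjusted within each (level, id) across
#' categories. Discarded genes are part of the universe but never form a
#' test set.
#'
#' @param tree a `ClusterTree`.
#' @param coll a [gene_set_collection()]; harmonized to the post-filter
#'   universe internally.
#' @param correction method for [adjust_pvalues()].
#' @return named list with keys like `"cluster:C1"` and `"super:SC2"`,
#'   each an enrichment data.frame.
#' @export
enrich_clusters <- function(tree, coll, correction = "bh") {
  stopifnot(inherits(tree, "ClusterTree"))
  coll <- suppressWarnings(harmonize(coll, tree$genes))
  out <- list()
  for (id in names(tree$clusters)) {
    out[[paste0("cluster:", id)]] <-
      enrich_collection(tree$clusters[[id]], coll, "over", correction)
  }
  for (id in names(tree$super_clusters)) {
    g <- unlist(tree$clusters[tree$super_clusters[[id]]], use.names = FALSE)
    out[[paste0("super:", id)]] <-
      enrich_collection(g, coll, "over", correction)
  }
  out
}
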