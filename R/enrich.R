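#' Over-representation analysis (hypergeometric test)
#'
#' Tests whether a gene category overlaps a test set more (or less) than
#' expected when drawing `n = |test_set|` genes without replacement from a
#' universe of `N` genes containing `K` category members. With `k` the
#' observed overlap, the one-sided over-representation p-value is
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`, the under-representation
#' p-value is `P(X <= k)`, and the two-sided p-value is the doubled smaller
#' tail, capped at 1.
#'
#' @param test_set character vector of gene ids, a subset of `universe`.
#' @param category character vector of gene ids (harmonized to `universe`;
#'   members outside the universe are ignored).
#' @param universe character vector defining the background.
#' @param direction one of `"over"`, `"under"`, `"two_sided"`.
#' @param category_id label carried into the result.
#' @return an `EnrichmentRecord`: a list with `category_id`, the counts
#'   `n_universe` (N), `n_category` (K), `n_test` (n), `n_overlap` (k), the
#'   test `statistic` (here k), `p_raw`, `p_adjusted` (NA until adjusted),
#'   `direction` and the sorted `hits`.
#' @examples
#' u <- paste0("g", 1:10)
#' ora(u[1:5], u[1:4], u)$p_raw   # 11/42
#' @export
ora <- function(test_set, category, universe,
                direction = c("over", "under", "two_sided"),
                category_id = "category") {
  direction <- match.arg(direction)
  universe <- unique(as.character(universe))
  test_set <- unique(as.character(test_set))
  if (length(universe) < 1L) stop("universe must be nonempty")
  if (length(test_set) == 0L) stop("test set is empty")
  outside <- setdiff(test_set, universe)
  if (length(outside)) {
    stop("test set not contained in universe; first offender: ", outside[1L])
  }
  category <- intersect(unique(as.character(category)), universe)
  N <- length(universe)
  K <- length(category)
  n <- length(test_set)
  hits <- sort(intersect(test_set, category))
  k <- length(hits)
  p <- .hyper_p(k, K, n, N, direction)
  structure(
    list(category_id = category_id, n_universe = N, n_category = K,
         n_test = n, n_overlap = k, statistic = as.numeric(k),
         p_raw = p, p_adjusted = NA_real_, direction = direction,
         hits = hits),
    class = "EnrichmentRecord")
}

# vectorized hypergeometric tails; k, K, n may be vectors recycled against N
.hyper_p <- function(k, K, n, N, direction) {
  over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  under <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  switch(direction,
         over = over,
         under = under,
         two_sided = pmin(1, 2 * pmin(over, under)))
}

#' @export
print.EnrichmentRecord <- function(x, ...) {
  cat(sprintf(
    "EnrichmentRecord %s [%s]: N=%d K=%d n=%d k=%d p=%.4g adj=%s\n",
    x$category_id, x$direction, x$n_universe, x$n_category, x$n_test,
    x$n_overlap, x$p_raw,
    if (is.na(x$p_adjusted)) "NA" else sprintf("%.4g", x$p_adjusted)))
  invisible(x)
}

#' ORA of one test set against every category of a collection
#'
#' Runs [ora()] for each category against the collection's universe and
#' adjusts the p-values across categories.
#'
#' @param test_set character vector of gene ids.
#' @param coll a [gene_set_collection()] whose universe contains `test_set`.
#' @inheritParams ora
#' @param correction correction method passed to [adjust_pvalues()].
#' @return a data.frame with one row per category: `category_id`, `name`,
#'   `N`, `K`, `n`, `k`, `statistic`, `p_raw`, `p_adjusted`, `direction`
#'   and `hits` (semicolon-joined), sorted by `p_raw`.
#' @export
enrich_collection <- function(test_set, coll,
                              direction = c("over", "under", "two_sided"),
                              correction = "bh") {
  direction <- match.arg(direction)
  stopifnot(inherits(coll, "GeneSetCollection"))
  test_set <- unique(as.character(test_set))
  if (length(test_set) == 0L) stop("test set is empty")
  outside <- setdiff(test_set, coll$universe)
  if (length(outside)) {
    stop("test set not contained in collection universe; first offender: ",
         outside[1L])
  }
  if (length(coll$sets) == 0L) return(.empty_enrichment_df())
  N <- length(coll$universe)
  n <- length(test_set)
  K <- vapply(coll$sets, length, 0L)  # collection assumed harmonized
  hit_list <- lapply(coll$sets, function(s) sort(intersect(test_set, s)))
  k <- lengths(hit_list)
  p <- .hyper_p(k, K, n, N, direction)
  res <- data.frame(
    category_id = coll$ids,
    name = unname(coll$set_names),
    N = N, K = as.integer(K), n = n, k = as.integer(k),
    statistic = as.numeric(k),
    p_raw = p,
    p_adjusted = adjust_pvalues(p, correction),
    direction = direction,
    hits = vapply(hit_list, paste, "", collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p_raw, res$category_id), , drop = FALSE]
}

.empty_enrichment_df <- function() {
  data.frame(category_id = character(), name = character(),
             N = integer(), K = integer(), n = integer(), k = integer(),
             statistic = numeric(), p_raw = numeric(),
             p_adjusted = numeric(), direction = character(),
             hits = character(), stringsAsFactors = FALSE)
}

#' Running-sum (GSEA-style) enrichment score
#'
#' Walks a ranked gene list from top to bottom keeping a running sum that
#' increases by `1/K` at each category hit and decreases by `1/(N-K)` at
#' each miss (the unweighted Kolmogorov-Smirnov-like statistic). The
#' enrichment score ES is the signed maximum deviation of this sum from
#' zero; ES near +1 means the category concentrates at the top of the
#' ranking, near -1 at the bottom.
#'
#' @param ranked_genes character vector, a ranking without duplicates.
#' @param category character vector of gene ids; must share at least one
#'   gene with the list but not cover it entirely.
#' @return the enrichment score, a number in `[-1, 1]`, with attribute
#'   `leading_edge`: the category hits at or before the extremum (after it
#'   for a negative ES).
#' @export
running_sum_es <- function(ranked_genes, category) {
  ranked_genes <- as.character(ranked_genes)
  if (anyDuplicated(ranked_genes)) stop("ranked list contains duplicates")
  is_hit <- ranked_genes %in% category
  N <- length(ranked_genes)
  K <- sum(is_hit)
  if (K == 0L) stop("category is disjoint from the ranked list")
  if (K == N) stop("category covers the whole ranked list; statistic undefined")
  steps <- ifelse(is_hit, 1 / K, -1 / (N - K))
  rs <- cumsum(steps)
  i_max <- which.max(rs)
  i_min <- which.min(rs)
  # when the two deviations tie, the positive one wins by convention
  if (rs[i_max] >= -rs[i_min]) {
    es <- rs[i_max]
    le <- ranked_genes[seq_len(i_max)][is_hit[seq_len(i_max)]]
  } else {
    es <- rs[i_min]
    idx <- seq.int(i_min + 1L, N)
    le <- ranked_genes[idx][is_hit[idx]]
  }
  structure(es, leading_edge = le, rs_max = rs[i_max], rs_min = rs[i_min])
}

#' Permutation p-value for the running-sum statistic
#'
#' The null distribution is obtained by permuting gene labels (shuffling
#' the ranked list) and recomputing the enrichment score; the two-sided
#' p-value uses the add-one estimator
#' `(1 + #\{|ES*| >= |ES|\}) / (1 + n_permutations)`, so it is never zero
#' and is reproducible for a fixed seed.
#'
#' @inheritParams running_sum_es
#' @param n_permutations number of label permutations, at least 100.
#' @param seed integer seed; required so that results are reproducible.
#' @return a `RunningSumResult`: list with `category_id`, `es`, `p_raw`,
#'   `n_permutations` and `leading_edge`.
#' @export
running_sum_pvalue <- function(ranked_genes, category, n_permutations = 1000L,
                               seed, category_id = "category") {
  if (missing(seed)) stop("a seed is required for the permutation test")
  if (n_permutations < 100L) stop("need at least 100 permutations")
  es <- running_sum_es(ranked_genes, category)
  le <- attr(es, "leading_edge")
  es <- as.numeric(es)
  is_hit <- ranked_genes %in% category
  N <- length(ranked_genes)
  K <- sum(is_hit)
  # permuting hit positions is equivalent to permuting gene labels
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  exceed <- 0L
  thr <- abs(es)
  for (b in seq_len(n_permutations)) {
    pos <- logical(N)
    pos[sample.int(N, K)] <- TRUE
    steps <- ifelse(pos, 1 / K, -1 / (N - K))
    rs <- cumsum(steps)
    if (max(rs[which.max(rs)], -rs[which.min(rs)]) >= thr) exceed <- exceed + 1L
  }
  structure(
    list(category_id = category_id, es = es,
         p_raw = (1 + exceed) / (1 + n_permutations),
         n_permutations = as.integer(n_permutations),
         leading_edge = le),
    class = "RunningSumResult")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.RunningSumResult <- function(x, ...) {
  cat(sprintf("RunningSumResult %s: ES=%.4f p=%.4g (%d permutations, %d leading-edge genes)\n",
              x$category_id, x$es, x$p_raw, x$n_permutations,
              length(x$leading_edge)))
  invisible(x)
}

#' Multiple-testing correction
#'
#' Adjusts a vector of raw p-values by Bonferroni, Holm, Benjamini-Hochberg
#' (FDR) or Benjamini-Yekutieli; input order is preserved and outputs are
#' clipped to at most 1.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @param method `"bonferroni"`, `"holm"`, `"bh"` or `"by"`.
#' @return adjusted p-values, same length and order as the input.
#' @export
adjust_pvalues <- function(p_values, method = c("bh", "holm", "bonferroni", "by")) {
  method <- match.arg(tolower(method), c("bh", "holm", "bonferroni", "by"))
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values,
                  method = c(bh = "BH", holm = "holm",
                             bonferroni = "bonferroni", by = "BY")[[method]])
}

#' Chi-square test for a 2x2 contingency table
#'
#' Pearson's chi-square statistic without continuity correction,
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with `N = a+b+c+d`,
#' compared against the chi-square distribution with one degree of
#' freedom. The odds ratio is `ad / (bc)`; when any cell is zero the
#' Haldane correction adds 0.5 to every cell for the odds ratio only.
#'
#' @param a,b,c,d non-negative cell counts of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `statistic`, `p` and `odds_ratio`.
#' @examples
#' chi_square_2x2(10, 20, 30, 40)$statistic  # ~0.7937
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) stop("counts must be non-negative")
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) stop("degenerate table")
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  if (any(cells == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       odds_ratio = or)
}

#' Serialize enrichment results
#'
#' Writes the data.frame produced by [enrich_collection()] (or the
#' workflow-level wrappers) as TSV with a fixed column order and
#' 6-significant-digit p-values, so identical runs give identical files.
#'
#' @param df enrichment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(df, path) {
  out <- df
  for (col in c("p_raw", "p_adjusted", "statistic")) {
    if (col %in% names(out)) out[[col]] <- signif(out[[col]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
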