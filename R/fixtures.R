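#' Synthetic fixtures with known ground truth
#'
#' Deterministic generators that produce inputs for every workflow along
#' with the planted structure (chromatin states, cluster labels, active
#' pathways per group), so the whole toolkit can be built and tested
#' without any external data. All randomness flows from one seed through
#' named substreams, so adding an output does not shift the others and a
#' fixed seed reproduces files byte for byte.
#'
#' @name fixtures
NULL

# stable 32-bit substream seed from (seed, stream name)
.substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647)
}

.with_stream <- function(seed, name, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream_seed(seed, name))
  expr
}

#' Epigenome fixture: gene model, mark tracks and planted states
#'
#' Samples a target chromatin state per gene and sample group, then
#' places histone-mark peaks in the promoter/body regions exactly as the
#' default rule table requires for that state: active genes get promoter
#' H3K4me3 plus promoter H3K27ac or body H3K36me3; poised genes promoter
#' H3K4me3 plus promoter H3K27me3; repressed genes promoter H3K27me3 or
#' H3K9me3 (without H3K4me3); no_signal genes get no peak. By
#' construction [assign_states()] recovers the planted state of every
#' gene.
#'
#' @param n_genes number of genes (>= 1).
#' @param groups character vector of sample-group names (default two).
#' @param state_probs sampling probabilities of the four states.
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, writes `genes.tsv`, one
#'   `<group>_<mark>.bed` per (group, mark) with peaks, and `truth.json`.
#' @param promoter_up,promoter_down promoter window used for placement.
#' @return list with `genes` (gene model data.frame), `tracks` (list of
#'   mark tracks per group), `truth` (data.frame `gene_id`, `sample_group`,
#'   `state`) and `files` (paths written, if any).
#' @export
make_epigenome_fixture <- function(n_genes = 200L,
                                   groups = c("group1", "group2"),
                                   state_probs = c(active = 0.3, poised = 0.2,
                                                   repressed = 0.3,
                                                   no_signal = 0.2),
                                   seed = 1L, out_dir = NULL,
                                   promoter_up = 2000L, promoter_down = 500L) {
  stopifnot(n_genes >= 1L, length(groups) >= 1L)
  ids <- sprintf("G%05d", seq_len(n_genes))
  tss <- (seq_len(n_genes) - 1L) * 10000L + 5000L
  strand <- rep(c("+", "-"), length.out = n_genes)
  genes <- data.frame(gene_id = ids, chrom = "chr1", strand = strand,
                      tss = tss,
                      tes = ifelse(strand == "+", tss + 3000L, tss - 3000L),
                      stringsAsFactors = FALSE)
  genes$enhancers <- replicate(n_genes,
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE), simplify = FALSE)
  truth <- list(); tracks <- list(); files <- character()
  for (grp in groups) {
    st <- .with_stream(seed, paste0("epi_states_", grp), {
      sample(names(state_probs), n_genes, replace = TRUE, prob = state_probs)
    })
    alt <- .with_stream(seed, paste0("epi_alt_", grp), {
      stats::runif(n_genes)  # which alternative mark realizes the state
    })
    truth[[grp]] <- data.frame(gene_id = ids, sample_group = grp, state = st,
                               stringsAsFactors = FALSE)
    iv <- list()  # mark -> data.frame of intervals
    add <- function(mark, region_df, i) {
      d <- data.frame(chrom = region_df$chrom[i],
                      start = region_df$start[i] + 200L,
                      end = region_df$start[i] + 600L,
                      stringsAsFactors = FALSE)
      iv[[mark]] <<- rbind(iv[[mark]], d)
    }
    plus <- genes$strand == "+"
    prom <- data.frame(
      chrom = genes$chrom,
      start = as.integer(pmax(0, ifelse(plus, genes$tss - promoter_up,
                                        genes$tss - promoter_down))),
      stringsAsFactors = FALSE)
    body <- data.frame(chrom = genes$chrom,
                       start = as.integer(pmin(genes$tss, genes$tes)),
                       stringsAsFactors = FALSE)
    add("H3K4me3", prom, which(st %in% c("active", "poised")))
    add("H3K27me3", prom, which(st == "poised"))
    add("H3K27ac", prom, which(st == "active" & alt < 0.5))
    add("H3K36me3", body, which(st == "active" & alt >= 0.5))
    add("H3K27me3", prom, which(st == "repressed" & alt < 0.5))
    add("H3K9me3", prom, which(st == "repressed" & alt >= 0.5))
    tracks[[grp]] <- lapply(names(iv), function(mk) {
      d <- iv[[mk]]
      d <- d[order(d$chrom, d$start), , drop = FALSE]
      rownames(d) <- NULL
      d$end <- as.integer(d$end)
      list(mark_name = mk, sample_group = grp, intervals = d)
    })
    names(tracks[[grp]]) <- names(iv)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(genes = genes, tracks = tracks, truth = truth,
              files = character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gpath <- file.path(out_dir, "genes.tsv")
    gm <- genes
    gm$enhancers <- ""
    utils::write.table(gm, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- gpath
    for (grp in groups) {
      for (mk in names(tracks[[grp]])) {
        p <- file.path(out_dir, paste0(grp, "_", mk, ".bed"))
        d <- tracks[[grp]][[mk]]$intervals
        writeLines(sprintf("%s\t%d\t%d", d$chrom, d$start, d$end), p)
        files <- c(files, p)
      }
    }
    tp <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, tp, digits = NA)
    out$files <- c(files, tp)
  }
  out
}

# time-series template: dominant Gaussian bump at `peak` plus a
# super-group-specific oscillation whose crest coincides with the bump,
# optionally time-shifted (for sub-cluster variants)
.ts_template <- function(t, peak, freq, amplitude, shift = 0) {
  tt <- t - shift
  span <- max(t) - min(t)
  amplitude * exp(-(tt - peak)^2 / 8) +
    (amplitude / 2) * (1 + sin(2 * pi * freq * (tt - (peak - span / (4 * freq))) / span))
}

#' Time-series fixture: expression matrix with planted cluster structure
#'
#' Each super-group has a template expression curve with a distinct peak
#' time (a dominant bump) and a distinct oscillation frequency, so
#' super-group templates are strongly separated in gradient space.
#' Sub-cluster templates are small time shifts of their super-group
#' template, calibrated so adjacent sub-templates are `0.5 * amplitude`
#' apart in gradient distance. Gene rows add i.i.d. Gaussian noise.
#'
#' The default grid is 13 timepoints at 2 h intervals over 24 h. The
#' returned `suggested_cuts` are computed from the template geometry and
#' the noise level: the strict cut sits above the expected noise diameter
#' of a cluster (and above half the sub-template separation), the super
#' cut halfway between the largest within-super and the smallest
#' between-super template distance.
#'
#' @param k_super number of super-groups (>= 2).
#' @param subclusters_per_super sub-clusters per super-group.
#' @param genes_per_cluster genes per sub-cluster.
#' @param timepoints numeric grid (default `seq(0, 24, 2)`).
#' @param amplitude template amplitude (default 2; log-scale units).
#' @param noise_sd Gaussian noise sd (default `0.1 * amplitude`).
#' @param seed integer master seed.
#' @param out_dir optional directory; writes `matrix.tsv` and `truth.json`.
#' @return list with `series` (an `ExpressionSeries`), `truth` (data.frame
#'   `gene`, `subcluster`, `supercluster`), `templates`, `peak_times`
#'   (planted per-super peak of the z-scored template),
#'   `suggested_cuts` (named `strict`/`super`) and `files`.
#' @export
make_timeseries_fixture <- function(k_super = 3L, subclusters_per_super = 2L,
                                    genes_per_cluster = 30L,
                                    timepoints = seq(0, 24, 2),
                                    amplitude = 2, noise_sd = 0.1 * amplitude,
                                    seed = 1L, out_dir = NULL) {
  stopifnot(k_super >= 2L, subclusters_per_super >= 1L, noise_sd >= 0)
  t <- as.numeric(timepoints)
  span <- max(t) - min(t)
  peaks <- min(t) + span * (2 * seq_len(k_super) - 1) / (2 * k_super)
  freqs <- seq_len(k_super) + 1.5
  sep_target <- 0.5 * amplitude
  gd <- function(x, y) gradient_distance(x, y, t)
  templates <- list(); sub_of <- integer(); sup_of <- integer()
  for (s in seq_len(k_super)) {
    base <- function(shift) .ts_template(t, peaks[s], freqs[s], amplitude, shift)
    if (subclusters_per_super > 1L) {
      delta <- stats::uniroot(function(d) gd(base(-d / 2), base(d / 2)) - sep_target,
                              c(1e-3, span / 4))$root
    } else delta <- 0
    offs <- (seq_len(subclusters_per_super) -
               (subclusters_per_super + 1) / 2) * delta
    for (j in seq_len(subclusters_per_super)) {
      templates[[length(templates) + 1L]] <- base(offs[j])
      sub_of <- c(sub_of, j); sup_of <- c(sup_of, s)
    }
  }
  tm <- do.call(rbind, templates)
  D <- as.matrix(stats::dist(t(apply(tm, 1L, diff)) / rep(diff(t), each = nrow(tm))))
  same <- outer(sup_of, sup_of, "==")
  S <- if (any(same & D > 0)) max(D[same & D > 0]) else sep_target
  B <- min(D[!same])
  noise_diam <- 2 * noise_sd * sqrt(2 * (length(t) - 1)) / mean(diff(t))
  cuts <- c(strict = max(0.5 * sep_target, 1.4 * noise_diam),
            super = (S + B) / 2)
  n <- nrow(tm) * genes_per_cluster
  gene_ids <- sprintf("TG%04d", seq_len(n))
  noise <- .with_stream(seed, "ts_noise", {
    matrix(stats::rnorm(n * length(t), 0, noise_sd), nrow = n)
  })
  values <- tm[rep(seq_len(nrow(tm)), each = genes_per_cluster), , drop = FALSE] + noise
  truth <- data.frame(
    gene = gene_ids,
    subcluster = rep(paste0("S", sup_of, ".", sub_of), each = genes_per_cluster),
    supercluster = rep(paste0("S", sup_of), each = genes_per_cluster),
    stringsAsFactors = FALSE)
  series <- expression_series(gene_ids, t, values)
  peak_times <- vapply(seq_len(k_super), function(s) {
    mc <- colMeans(tm[sup_of == s, , drop = FALSE])
    t[which.max((mc - mean(mc)) / stats::sd(mc))]
  }, 0)
  out <- list(series = series, truth = truth, templates = tm,
              peak_times = stats::setNames(peak_times, paste0("S", seq_len(k_super))),
              suggested_cuts = cuts, files = character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mp <- file.path(out_dir, "matrix.tsv")
    write_expression_series(series, mp)
    tp <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(labels = truth, peak_times = as.list(out$peak_times),
           suggested_cuts = as.list(cuts)),
      tp, auto_unbox = TRUE, digits = NA)
    out$files <- c(mp, tp)
  }
  out
}

#' Single-cell fixture: counts with planted group-specific pathway activity
#'
#' Generates a sparse count matrix over annotated cell groups (default:
#' the three age groups of an aging-mouse microglia atlas, 2219 + 1998 +
#' 4113 = 8330 cells), a GMT of disjoint categories, and an annotation
#' table. For each cell, genes of a category are expressed with
#' probability `effect_fraction` when the cell's group is planted-active
#' for that category and `baseline_fraction` otherwise; background genes
#' are expressed at `background_rate`. Counts of expressed genes are
#' 1 + Poisson(1).
#'
#' @param group_sizes named integer vector of cells per group.
#' @param n_genes total number of genes.
#' @param n_categories number of (disjoint) categories in the GMT.
#' @param category_size genes per category.
#' @param active_map named character vector group -> planted-active
#'   category id; defaults to category `i` for group `i` (recycled).
#' @param effect_fraction,baseline_fraction expression probabilities for
#'   category genes in active / inactive groups (defaults 0.9 / 0.1).
#' @param background_rate expression probability of non-category genes.
#' @param seed integer master seed.
#' @param out_dir optional directory; writes `matrix.mtx`, `genes.txt`,
#'   `cells.txt`, `annotation.tsv`, `sets.gmt`, `truth.json`.
#' @return list with `matrix` (a `CellMatrix`), `annotation` (data.frame
#'   `cell_id`, `age_group`), `collection` (the GMT as a
#'   `GeneSetCollection`), `truth` (the active map) and `files`.
#' @export
make_singlecell_fixture <- function(group_sizes = c(month_03 = 2219L,
                                                    month_18 = 1998L,
                                                    month_24 = 4113L),
                                    n_genes = 1000L, n_categories = 10L,
                                    category_size = 40L,
                                    active_map = NULL,
                                    effect_fraction = 0.9,
                                    baseline_fraction = 0.1,
                                    background_rate = 0.1,
                                    seed = 1L, out_dir = NULL) {
  stopifnot(effect_fraction > baseline_fraction,
            effect_fraction <= 1, baseline_fraction >= 0,
            n_categories * category_size <= n_genes)
  groups <- names(group_sizes)
  if (is.null(groups)) stop("group_sizes must be named")
  genes <- sprintf("SG%04d", seq_len(n_genes))
  cat_ids <- sprintf("CAT%02d", seq_len(n_categories))
  sets <- lapply(seq_len(n_categories), function(i) {
    genes[((i - 1L) * category_size + 1L):(i * category_size)]
  })
  names(sets) <- cat_ids
  coll <- gene_set_collection("synthetic", sets, universe = genes)
  if (is.null(active_map)) {
    active_map <- stats::setNames(
      cat_ids[(seq_along(groups) - 1L) %% n_categories + 1L], groups)
  }
  gene_rate <- matrix(background_rate, nrow = n_genes, ncol = length(groups),
                      dimnames = list(genes, groups))
  for (g in groups) {
    for (ci in cat_ids) {
      r <- if (identical(active_map[[g]], ci)) effect_fraction else baseline_fraction
      gene_rate[sets[[ci]], g] <- r
    }
  }
  cells <- sprintf("CELL%05d", seq_len(sum(group_sizes)))
  grp_of <- rep(groups, group_sizes)
  tri_i <- list(); tri_j <- list(); tri_x <- list()
  offset <- 0L
  for (g in groups) {
    ncell <- group_sizes[[g]]
    dat <- .with_stream(seed, paste0("sc_counts_", g), {
      expressed <- matrix(stats::runif(n_genes * ncell), nrow = n_genes) <
        gene_rate[, g]
      nz <- which(expressed)
      list(nz = nz, cnt = 1L + stats::rpois(length(nz), 1))
    })
    tri_i[[g]] <- (dat$nz - 1L) %% n_genes + 1L
    tri_j[[g]] <- (dat$nz - 1L) %/% n_genes + 1L + offset
    tri_x[[g]] <- dat$cnt
    offset <- offset + ncell
  }
  counts <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                                 x = as.numeric(unlist(tri_x)),
                                 dims = c(n_genes, length(cells)))
  m <- cell_matrix(genes, cells, counts)
  ann <- data.frame(cell_id = cells, age_group = grp_of,
                    stringsAsFactors = FALSE)
  out <- list(matrix = m, annotation = ann, collection = coll,
              truth = as.list(active_map), files = character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mp <- file.path(out_dir, "matrix.mtx")
    Matrix::writeMM(m$counts, mp)
    writeLines(genes, file.path(out_dir, "genes.txt"))
    writeLines(cells, file.path(out_dir, "cells.txt"))
    ap <- file.path(out_dir, "annotation.tsv")
    utils::write.table(ann, ap, sep = "\t", quote = FALSE, row.names = FALSE)
    gp <- file.path(out_dir, "sets.gmt")
    write_gmt(coll, gp)
    tp <- file.path(out_dir, "truth.json")
    jsonlite::write_json(out$truth, tp, auto_unbox = TRUE)
    out$files <- c(mp, file.path(out_dir, c("genes.txt", "cells.txt")),
                   ap, gp, tp)
  }
  out
}
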