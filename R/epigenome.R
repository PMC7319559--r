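#' Chromatin-state workflow
#'
#' Assigns a discrete chromatin state (active, poised, repressed or
#' no_signal) to every gene of a gene model from histone-mark peak tracks,
#' separately per sample group; compares two groups to build a
#' state-transition graph whose edge weights are the number of genes in
#' each transition group; and runs over-representation analyses on every
#' transition group.
#'
#' @name epigenome
NULL

# histone marks understood by the default rule table
.default_marks <- c("H3K4me3", "H3K9me3", "H3K27ac", "H3K27me3", "H3K36me3")

.chromatin_states <- c("active", "poised", "repressed", "no_signal")

#' Read genomic intervals from a BED file
#'
#' Parses the first three BED columns (chrom, start, end; 0-based
#' half-open), ignores any extra columns, and merges overlapping or
#' bookended intervals within the track. Chromosome names are not checked
#' against a reference.
#'
#' @param path path to a BED file.
#' @return a data.frame with columns `chrom`, `start`, `end`, sorted, with
#'   overlapping intervals merged.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("BED line %d: fewer than 3 columns", lineno[which(nf < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("BED line %d: invalid interval (need 0 <= start < end)",
                 lineno[bad[1L]]))
  }
  merge_intervals(data.frame(chrom = chrom, start = start, end = end,
                             stringsAsFactors = FALSE))
}

# sorted merge of half-open intervals, per chromosome, via IRanges
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  pieces <- lapply(split(df, df$chrom), function(d) {
    # half-open [start, end) -> closed IRanges [start, end - 1]
    r <- IRanges::reduce(IRanges::IRanges(start = d$start, end = d$end - 1L))
    data.frame(chrom = d$chrom[1L], start = IRanges::start(r),
               end = IRanges::end(r) + 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene model table
#'
#' Expects a 6-column TSV with header: `gene_id`, `chrom`, `strand`,
#' `tss`, `tes`, `enhancers`, where `tss`/`tes` are 0-based coordinates
#' and `enhancers` is an optional semicolon-separated list of
#' `chrom:start-end` half-open intervals (empty for none).
#'
#' @param path path to the TSV.
#' @return a data.frame with an `enhancers` list-column of interval
#'   data.frames.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene model lacks columns: ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$tss == df$tes)) stop("tss must differ from tes")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene model")
  enh <- if ("enhancers" %in% names(df)) df$enhancers else rep("", nrow(df))
  df$enhancers <- lapply(enh, .parse_enhancers)
  df[need[1:5]] <- df[need[1:5]]
  df
}

.parse_enhancers <- function(txt) {
  txt <- trimws(if (is.na(txt)) "" else txt)
  if (!nzchar(txt)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
  if (any(lengths(m) != 4L)) stop("malformed enhancer interval: ", txt)
  out <- data.frame(chrom = vapply(m, `[[`, "", 2L),
                    start = as.integer(vapply(m, `[[`, "", 3L)),
                    end = as.integer(vapply(m, `[[`, "", 4L)),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("malformed enhancer interval: ", txt)
  out
}

#' Regulatory regions of a gene
#'
#' Derives promoter, gene-body and (optional) enhancer intervals from a
#' single gene-model row. The promoter spans `promoter_up` bp upstream to
#' `promoter_down` bp downstream of the TSS in the direction of
#' transcription, clipped at coordinate 0; the body spans TSS to TES.
#' All intervals are 0-based half-open.
#'
#' @param gene one-row data.frame (or list) with `chrom`, `strand`, `tss`,
#'   `tes` and optionally `enhancers`.
#' @param promoter_up,promoter_down promoter window in bp (defaults
#'   2000/500).
#' @return a named list of interval data.frames: `promoter`, `body` and,
#'   when enhancers are supplied, `enhancer`.
#' @export
gene_regions <- function(gene, promoter_up = 2000L, promoter_down = 500L) {
  stopifnot(promoter_up >= 0, promoter_down >= 0)
  tss <- as.numeric(gene$tss); tes <- as.numeric(gene$tes)
  if (gene$strand == "+") {
    pstart <- max(0, tss - promoter_up); pend <- tss + promoter_down
  } else {
    pstart <- max(0, tss - promoter_down); pend <- tss + promoter_up
  }
  out <- list(
    promoter = data.frame(chrom = gene$chrom, start = pstart, end = pend,
                          stringsAsFactors = FALSE),
    body = data.frame(chrom = gene$chrom, start = min(tss, tes),
                      end = max(tss, tes), stringsAsFactors = FALSE))
  enh <- gene$enhancers
  if (is.list(enh) && !is.data.frame(enh)) enh <- enh[[1L]]
  if (is.data.frame(enh) && nrow(enh) > 0L) out$enhancer <- enh
  out
}

#' Default chromatin-state rule table
#'
#' An ordered rule list (first match wins) encoding the canonical
#' bivalent/active/repressed logic of the five histone marks H3K4me3,
#' H3K9me3, H3K27ac, H3K27me3 and H3K36me3:
#' \enumerate{
#'   \item promoter H3K4me3 and promoter H3K27me3 -> poised (bivalent);
#'   \item promoter H3K4me3 and (promoter H3K27ac, or body H3K36me3, or —
#'     when enhancers are supplied — enhancer H3K27ac) -> active;
#'   \item promoter H3K4me3 alone -> active;
#'   \item H3K27me3 or H3K9me3 in promoter or body -> repressed;
#'   \item otherwise -> no_signal.
#' }
#' Each rule is a list with a `state` and a `predicate(has)` where
#' `has(region, mark)` returns a logical vector over genes; users may pass
#' their own table of the same shape to [assign_states()].
#'
#' @return the ordered rule list.
#' @export
default_rule_table <- function() {
  list(
    list(state = "poised",
         predicate = function(has) has("promoter", "H3K4me3") & has("promoter", "H3K27me3")),
    list(state = "active",
         predicate = function(has) {
           has("promoter", "H3K4me3") &
             (has("promoter", "H3K27ac") | has("body", "H3K36me3") |
                has("enhancer", "H3K27ac"))
         }),
    list(state = "active",
         predicate = function(has) has("promoter", "H3K4me3")),
    list(state = "repressed",
         predicate = function(has) {
           has("promoter", "H3K27me3") | has("body", "H3K27me3") |
             has("promoter", "H3K9me3") | has("body", "H3K9me3")
         }),
    list(state = "no_signal", predicate = function(has) rep(TRUE, length(has("promoter", "H3K4me3"))))
  )
}

# presence of each (region, mark) per gene: overlap of >= 1 bp with any
# track interval. Returns a named list "region|mark" -> logical over genes.
.mark_presence <- function(genes, tracks, promoter_up, promoter_down) {
  plus <- genes$strand == "+"
  prom <- data.frame(
    chrom = genes$chrom,
    start = pmax(0, ifelse(plus, genes$tss - promoter_up,
                           genes$tss - promoter_down)),
    end = ifelse(plus, genes$tss + promoter_down, genes$tss + promoter_up),
    gene = seq_len(nrow(genes)), stringsAsFactors = FALSE)
  body <- data.frame(chrom = genes$chrom,
                     start = pmin(genes$tss, genes$tes),
                     end = pmax(genes$tss, genes$tes),
                     gene = seq_len(nrow(genes)), stringsAsFactors = FALSE)
  enh <- NULL
  if (!is.null(genes$enhancers)) {
    nn <- vapply(genes$enhancers, NROW, 0L)
    if (any(nn > 0L)) {
      enh <- do.call(rbind, genes$enhancers[nn > 0L])
      enh$gene <- rep(which(nn > 0L), nn[nn > 0L])
    }
  }
  region_iv <- list(promoter = prom, body = body, enhancer = enh)
  pres <- list()
  for (tr in tracks) {
    iv <- tr$intervals
    for (rn in names(region_iv)) {
      rows <- region_iv[[rn]]
      col <- paste(rn, tr$mark_name, sep = "|")
      hit <- rep(FALSE, nrow(genes))
      if (!is.null(rows) && nrow(rows) > 0L && nrow(iv) > 0L) {
        for (chr in intersect(unique(rows$chrom), unique(iv$chrom))) {
          q <- rows[rows$chrom == chr, ]
          s <- iv[iv$chrom == chr, ]
          ov <- IRanges::findOverlaps(
            IRanges::IRanges(q$start, q$end - 1L),
            IRanges::IRanges(s$start, s$end - 1L))
          hit[q$gene[unique(S4Vectors::queryHits(ov))]] <- TRUE
        }
      }
      pres[[col]] <- if (is.null(pres[[col]])) hit else (pres[[col]] | hit)
    }
  }
  pres
}

#' Assign chromatin states to genes
#'
#' A mark is "present" in a region iff any of its peak intervals overlaps
#' the region by at least one bp; the state of a gene is decided by the
#' first matching rule of the (ordered) rule table. Every gene receives
#' exactly one state.
#'
#' @param genes gene model data.frame from [read_gene_model()].
#' @param tracks list of mark tracks, each a list with `mark_name`,
#'   `sample_group` and `intervals` (a data.frame as from [read_bed()]).
#'   All tracks must share the same sample group.
#' @param rules rule table, default [default_rule_table()].
#' @param promoter_up,promoter_down promoter window in bp.
#' @param mark_vocabulary allowed mark names; unknown marks are an error.
#' @return a data.frame of `ChromatinCall`s: `gene_id`, `sample_group`,
#'   `state`, plus an `evidence` attribute (named list gene ->
#'   region -> marks present).
#' @export
assign_states <- function(genes, tracks, rules = default_rule_table(),
                          promoter_up = 2000L, promoter_down = 500L,
                          mark_vocabulary = .default_marks) {
  stopifnot(is.data.frame(genes), length(tracks) >= 1L)
  marks <- vapply(tracks, `[[`, "", "mark_name")
  unknown <- setdiff(marks, mark_vocabulary)
  if (length(unknown)) stop("unknown mark name: ", paste(unknown, collapse = ", "))
  grp <- unique(vapply(tracks, `[[`, "", "sample_group"))
  if (length(grp) != 1L) stop("all tracks must share one sample_group")
  pres <- .mark_presence(genes, tracks, promoter_up, promoter_down)
  ngene <- nrow(genes)
  has <- function(region, mark) {
    v <- pres[[paste(region, mark, sep = "|")]]
    if (is.null(v)) rep(FALSE, ngene) else v
  }
  state <- rep(NA_character_, ngene)
  for (rule in rules) {
    m <- rule$predicate(has) & is.na(state)
    state[m] <- rule$state
  }
  if (anyNA(state)) stop("rule table is not total: some genes got no state")
  evidence <- lapply(seq_len(ngene), function(i) {
    got <- names(pres)[vapply(pres, `[[`, FALSE, i)]
    sp <- strsplit(got, "|", fixed = TRUE)
    ev <- split(vapply(sp, `[[`, "", 2L), vapply(sp, `[[`, "", 1L))
    lapply(ev, unname)
  })
  names(evidence) <- genes$gene_id
  structure(
    data.frame(gene_id = genes$gene_id, sample_group = grp, state = state,
               stringsAsFactors = FALSE),
    evidence = evidence)
}

#' Assign the chromatin state of a single gene
#'
#' Convenience wrapper around [assign_states()] for one gene-model row.
#'
#' @inheritParams assign_states
#' @param gene one-row gene-model data.frame.
#' @return one `ChromatinCall` row.
#' @export
assign_state <- function(gene, tracks, rules = default_rule_table(),
                         promoter_up = 2000L, promoter_down = 500L,
                         mark_vocabulary = .default_marks) {
  assign_states(gene, tracks, rules, promoter_up, promoter_down,
                mark_vocabulary)
}

#' Build the state-transition graph between two sample groups
#'
#' Genes with the same pair of states (state in group 1, state in group 2)
#' form a state transition group, e.g. `poised -> active`; each such group
#' is an edge whose weight is its number of member genes. Vertices carry
#' per-group state counts.
#'
#' @param calls_g1,calls_g2 call data.frames from [assign_states()],
#'   covering the same gene universe.
#' @return a `TransitionGraph`: list with `groups`, `vertices` (data.frame
#'   `sample_group`, `state`, `count`), `edges` (data.frame `from`, `to`,
#'   `weight`), `members` (named list `"from->to"` -> gene ids) and
#'   `universe`.
#' @export
transitions <- function(calls_g1, calls_g2) {
  sym_diff <- c(setdiff(calls_g1$gene_id, calls_g2$gene_id),
                setdiff(calls_g2$gene_id, calls_g1$gene_id))
  if (length(sym_diff)) {
    stop("gene universes differ between groups; asymmetric genes: ",
         paste(utils::head(sort(sym_diff), 10L), collapse = ", "))
  }
  g1 <- calls_g1$sample_group[1L]; g2 <- calls_g2$sample_group[1L]
  s2 <- calls_g2$state[match(calls_g1$gene_id, calls_g2$gene_id)]
  key <- paste(calls_g1$state, s2, sep = "->")
  members <- split(calls_g1$gene_id, key)
  members <- lapply(members, sort)
  st <- factor(c(calls_g1$state, s2), levels = .chromatin_states)
  vertices <- data.frame(
    sample_group = rep(c(g1, g2), each = length(.chromatin_states)),
    state = rep(.chromatin_states, 2L),
    count = c(as.integer(table(factor(calls_g1$state, .chromatin_states))),
              as.integer(table(factor(s2, .chromatin_states)))),
    stringsAsFactors = FALSE)
  fp <- strsplit(names(members), "->", fixed = TRUE)
  edges <- data.frame(from = vapply(fp, `[[`, "", 1L),
                      to = vapply(fp, `[[`, "", 2L),
                      weight = lengths(members),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(groups = c(g1, g2), vertices = vertices, edges = edges,
                 members = members, universe = sort(calls_g1$gene_id)),
            class = "TransitionGraph")
}

#' @export
print.TransitionGraph <- function(x, ...) {
  cat(sprintf("TransitionGraph %s -> %s: %d genes, %d transition groups\n",
              x$groups[1L], x$groups[2L], length(x$universe), nrow(x$edges)))
  e <- x$edges[order(-x$edges$weight), ]
  for (i in seq_len(min(nrow(e), 8L))) {
    cat(sprintf("  %-10s -> %-10s %6d genes\n", e$from[i], e$to[i], e$weight[i]))
  }
  invisible(x)
}

#' Enrichment of every state-transition group
#'
#' Runs an over-representation analysis of each edge's member genes
#' against every category, with the full call universe (all genes with
#' states in both groups) as background; p-values are adjusted within
#' each edge across categories. Edges with fewer than `min_edge_size`
#' members are skipped with a warning.
#'
#' @param graph a [transitions()] result.
#' @param coll a [gene_set_collection()]; harmonized to the graph universe
#'   internally.
#' @param correction method for [adjust_pvalues()].
#' @param min_edge_size smallest edge analyzed (default 2).
#' @return named list `"from->to"` -> enrichment data.frame.
#' @export
enrich_transitions <- function(graph, coll, correction = "bh",
                               min_edge_size = 2L) {
  stopifnot(inherits(graph, "TransitionGraph"))
  coll <- suppressWarnings(harmonize(coll, graph$universe))
  out <- list()
  for (edge in names(graph$members)) {
    mem <- graph$members[[edge]]
    if (length(mem) < min_edge_size) {
      warning("skipping transition group ", edge, " with ", length(mem),
              " member(s)")
      next
    }
    out[[edge]] <- enrich_collection(mem, coll, direction = "over",
                                     correction = correction)
  }
  out
}

#' Write chromatin calls / transition graph
#'
#' `write_calls_tsv` writes the per-gene state table; `write_graph_json`
#' serializes the full transition graph (vertices with counts, edges with
#' members) as JSON.
#'
#' @param calls call data.frame from [assign_states()].
#' @param graph a `TransitionGraph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(groups = graph$groups, vertices = graph$vertices,
         edges = cbind(graph$edges,
                       members = I(unname(graph$members)))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
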