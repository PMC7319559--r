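# Independent oracles and small fixture builders shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force ORA oracle: enumerate every n-subset of a universe of size N
# whose first K elements form the category, and count draws with overlap
# >= k (over) or <= k (under). Feasible for N <= 12.
ora_oracle <- function(N, K, n, k, direction = "over") {
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  if (direction == "over") mean(overlaps >= k) else mean(overlaps <= k)
}

# step-up / step-down correction oracles written directly from the
# definitions (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in seq(m, 1L)) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(run, 1)
  }
  adj
}

write_tiny_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# one-gene gene model row for state-assignment tests
one_gene <- function(strand = "+", tss = 10000, tes = 13000) {
  data.frame(gene_id = "G1", chrom = "chr1", strand = strand,
             tss = tss, tes = tes, stringsAsFactors = FALSE)
}

track <- function(mark, intervals, group = "g") {
  list(mark_name = mark, sample_group = group, intervals = intervals)
}

iv <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}
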