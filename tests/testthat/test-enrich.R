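test_that("ora reproduces the hypergeometric tail on worked examples", {
  u <- paste0("g", 1:10)
  # N=10, K=4, n=5, k=3: 66 of the 252 equally likely draws have >= 3 hits
  r <- ora(c(u[1:3], u[5:6]), u[1:4], u)
  expect_equal(r$p_raw, 11 / 42, tolerance = 1e-12)
  expect_identical(r$hits, sort(u[1:3]))
  expect_identical(c(r$n_universe, r$n_category, r$n_test, r$n_overlap),
                   c(10L, 4L, 5L, 3L))
  # test set = universe: overlap is certain
  expect_equal(ora(u, u[1:4], u)$p_raw, 1)
  # no overlap: P(X >= 0) = 1
  expect_equal(ora(u[5:10], u[1:4], u)$p_raw, 1)
})

test_that("ora validates its inputs", {
  u <- paste0("g", 1:10)
  expect_error(ora(c("zz"), u[1:4], u), "not contained")
  expect_error(ora(character(), u[1:4], u), "empty")
})

test_that("ora matches a brute-force subset-enumeration oracle", {
  for (N in c(5L, 8L)) {
    u <- paste0("g", seq_len(N))
    for (K in 1:(N - 1)) {
      for (n in 1:N) {
        for (k in max(0, n + K - N):min(K, n)) {
          test_set <- c(u[seq_len(k)],
                        if (n > k) u[K + seq_len(n - k)])
          r <- ora(test_set, u[seq_len(K)], u)
          expect_equal(r$p_raw, ora_oracle(N, K, n, k, "over"),
                       tolerance = 1e-12)
          r2 <- ora(test_set, u[seq_len(K)], u, direction = "under")
          expect_equal(r2$p_raw, ora_oracle(N, K, n, k, "under"),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("over-representation p is non-increasing in the overlap", {
  u <- paste0("g", 1:12)
  K <- 5L; n <- 6L
  ps <- vapply(0:5, function(k) {
    test_set <- c(u[seq_len(k)], if (n > k) u[K + seq_len(n - k)])
    ora(test_set, u[1:K], u)$p_raw
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("two-sided ora doubles the smaller tail, capped at 1", {
  u <- paste0("g", 1:10)
  t3 <- c(u[1:3], u[5:6])
  over <- ora(t3, u[1:4], u, "over")$p_raw
  under <- ora(t3, u[1:4], u, "under")$p_raw
  expect_equal(ora(t3, u[1:4], u, "two_sided")$p_raw,
               min(1, 2 * min(over, under)))
})

test_that("running sum walks the list with 1/K and -1/(N-K) increments", {
  g <- paste0("g", 1:4)
  expect_equal(as.numeric(running_sum_es(g, g[1:2])), 1)
  expect_equal(as.numeric(running_sum_es(g, g[3:4])), -1)
  # N=6, K=2, hits at ranks 1 and 4: running sum 1/2,1/4,0,1/2,1/4,0
  g6 <- paste0("g", 1:6)
  es <- running_sum_es(g6, g6[c(1, 4)])
  expect_equal(as.numeric(es), 0.5)
  expect_identical(attr(es, "leading_edge"), "g1")
})

test_that("running sum is antisymmetric under list reversal", {
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(5:40, 1)
    g <- paste0("x", seq_len(N))
    K <- sample(seq_len(N - 1), 1)
    cat_genes <- sample(g, K)
    es <- running_sum_es(g, cat_genes)
    # when the positive and negative deviations tie exactly, the sign is a
    # convention and antisymmetry does not apply
    if (abs(abs(attr(es, "rs_max")) - abs(attr(es, "rs_min"))) < 1e-9) next
    expect_equal(as.numeric(running_sum_es(rev(g), cat_genes)),
                 -as.numeric(es), tolerance = 1e-9)
  }
})

test_that("running sum rejects degenerate categories", {
  g <- paste0("g", 1:4)
  expect_error(running_sum_es(g, c("a", "b")), "disjoint")
  expect_error(running_sum_es(g, g), "whole")
  expect_error(running_sum_es(c(g, g[1]), g[1:2]), "duplicates")
})

test_that("permutation p-values are bounded, significant for top hits, and seeded", {
  g <- paste0("g", 1:100)
  r <- running_sum_pvalue(g, g[1:5], n_permutations = 1000, seed = 7)
  expect_gte(r$p_raw, 1 / 1001)
  expect_lte(r$p_raw, 0.05)
  r2 <- running_sum_pvalue(g, g[1:5], n_permutations = 1000, seed = 7)
  expect_identical(r$p_raw, r2$p_raw)
  expect_error(running_sum_pvalue(g, g[1:5], n_permutations = 50, seed = 1),
               "100")
  expect_error(running_sum_pvalue(g, g[1:5], n_permutations = 1000),
               "seed")
})

test_that("adjust matches hand-evaluated step rules and preserves order", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.5, "bonferroni"), 0.5)
  expect_equal(adjust_pvalues(0.37, "by"), 0.37)
  p <- c(0.04, 0.001, 0.9, 0.02)
  expect_equal(adjust_pvalues(p, "bh"), bh_oracle(p))
  expect_equal(adjust_pvalues(p, "holm"), holm_oracle(p))
  expect_error(adjust_pvalues(c(0.1, 0)), "0, 1")
  expect_error(adjust_pvalues(c(0.1, 1.2)), "0, 1")
})

test_that("corrections are ordered: bonferroni >= holm >= raw, all capped at 1", {
  set.seed(5)
  for (rep in 1:50) {
    p <- runif(sample(1:30, 1), min = 1e-6)
    bonf <- adjust_pvalues(p, "bonferroni")
    holm <- adjust_pvalues(p, "holm")
    bh <- adjust_pvalues(p, "bh")
    by <- adjust_pvalues(p, "by")
    expect_true(all(bonf >= holm - 1e-12))
    expect_true(all(holm >= p - 1e-12))
    expect_true(all(bh >= p - 1e-12))
    expect_true(all(by >= bh - 1e-12))
    expect_true(all(c(bonf, holm, bh, by) <= 1))
    expect_equal(bh, bh_oracle(p), tolerance = 1e-12)
    expect_equal(holm, holm_oracle(p), tolerance = 1e-12)
  }
})

test_that("chi-square 2x2 evaluates the closed form without continuity correction", {
  r <- chi_square_2x2(10, 20, 30, 40)
  expect_equal(r$statistic, 100 * (400 - 600)^2 / (30 * 70 * 40 * 60),
               tolerance = 1e-12)
  expect_equal(r$statistic, 4e6 / 5.04e6, tolerance = 1e-9)
  flat <- chi_square_2x2(5, 5, 5, 5)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_equal(flat$odds_ratio, 1)
  # perfect association: Haldane 0.5 correction kicks in for the OR
  perf <- chi_square_2x2(7, 0, 0, 7)
  expect_equal(perf$odds_ratio, (7.5 * 7.5) / (0.5 * 0.5))
  expect_lt(perf$p, 1e-3)
  expect_error(chi_square_2x2(0, 0, 3, 4), "degenerate")
})

test_that("chi-square matches stats::chisq.test and is swap-invariant", {
  set.seed(9)
  for (rep in 1:100) {
    tb <- matrix(rpois(4, 20) + 1, 2)
    r <- chi_square_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
    # simultaneous row and column swap leaves the table equivalent
    sw <- chi_square_2x2(tb[2, 2], tb[2, 1], tb[1, 2], tb[1, 1])
    expect_equal(sw$statistic, r$statistic, tolerance = 1e-12)
    expect_equal(sw$odds_ratio, r$odds_ratio, tolerance = 1e-12)
  }
})

test_that("enrich_collection adjusts across categories and serializes", {
  u <- paste0("g", 1:50)
  coll <- gene_set_collection("c", list(A = u[1:10], B = u[11:20],
                                        C = u[21:30]), universe = u)
  res <- enrich_collection(u[1:10], coll)
  expect_identical(res$category_id[1L], "A")
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(res, path)
  back <- read.delim(path)
  expect_identical(back$category_id, res$category_id)
})
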