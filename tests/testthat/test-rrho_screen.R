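test_that("overlap p-value matches hand-derived values", {
  expect_equal(overlap_pvalue(10, 5, 5, 4), 26 / 252, tolerance = 1e-12)
  expect_identical(overlap_pvalue(10, 5, 5, 0), 1)
  expect_identical(overlap_pvalue(6, 6, 6, 6), 1)
  expect_error(overlap_pvalue(10, 5, 5, 6), "inconsistent")
  expect_error(overlap_pvalue(10, 11, 5, 2), "inconsistent")
})

test_that("gene SNR reproduces the hand example and its invariances", {
  m <- mk_matrix(c(3, 1, 1, -1), "g", paste0("s", 1:4))
  expect_equal(gene_snr("g", c("s1", "s2"), m), 1.0, tolerance = 1e-12)
  expect_error(gene_snr("g", character(0), m))
  expect_error(gene_snr("g", paste0("s", 1:4), m))

  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(12)
    mm <- mk_matrix(x, "g", paste0("s", 1:12))
    p <- sample(colnames(mm), sample(2:10, 1))
    base <- gene_snr("g", p, mm)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(gene_snr("g", p, mk_matrix(a * x + b, "g", colnames(mm))),
                 base, tolerance = 1e-9)
    # absolute-value convention: complement + sign flip leaves SNR unchanged
    expect_equal(gene_snr("g", setdiff(colnames(mm), p),
                          mk_matrix(-x, "g", colnames(mm))),
                 base, tolerance = 1e-9)
    # signed variant flips sign on the complement
    expect_equal(gene_snr("g", setdiff(colnames(mm), p), mm, signed = TRUE),
                 -gene_snr("g", p, mm, signed = TRUE), tolerance = 1e-9)
  }
})

test_that("identical in/out distributions give zero SNR and constant genes stay finite", {
  m <- mk_matrix(c(0, 2, 2, 0), "g", paste0("s", 1:4))
  expect_equal(gene_snr("g", c("s1", "s2"), m), 0)
  const <- mk_matrix(rep(1, 6), "g", paste0("s", 1:6))
  expect_true(is.finite(gene_snr("g", c("s1", "s2"), const)))
})

test_that("set SNR is the gene mean and permutation-symmetric", {
  m <- mk_matrix(c(3, 1, 1, -1,
                   0, 2, 2, 0), c("g1", "g2"), paste0("s", 1:4))
  p <- c("s1", "s2")
  expect_equal(set_snr("g1", p, m), gene_snr("g1", p, m))
  expect_equal(set_snr(c("g1", "g2"), p, m), 0.5, tolerance = 1e-12)
  expect_equal(set_snr(c("g2", "g1"), p, m), set_snr(c("g1", "g2"), p, m))
})

test_that("rrho_edge agrees with a brute-force grid scan on 8 samples", {
  set.seed(11)
  samples <- paste0("s", 1:8)
  for (rep in 1:6) {
    x1 <- rnorm(8); x2 <- rnorm(8)
    m <- mk_matrix(c(x1, x2), c("g1", "g2"), samples)
    for (bt in c(FALSE, TRUE)) {
      cfg <- screen_config(both_tails = bt)
      ev <- rrho_edge("g1", "g2", m, cfg)
      ref <- brute_rrho(x1, x2, both_tails = bt)
      expect_equal(log(ev$p_min), ref$logp, tolerance = 1e-9)
      expect_identical(ev$samples[[1]], samples[ref$set])
    }
  }
})

test_that("rrho_edge on identical genes picks a diagonal prefix with full overlap", {
  set.seed(2)
  x <- rnorm(8)
  m <- mk_matrix(c(x, x), c("g1", "g2"), paste0("s", 1:8))
  ev <- rrho_edge("g1", "g2", m)
  ref <- brute_rrho(x, x)
  expect_equal(log(ev$p_min), ref$logp, tolerance = 1e-9)
  # overlap set is a prefix of the common descending ranking
  o <- order(-x, seq_along(x))
  k <- length(ev$samples[[1]])
  expect_setequal(ev$samples[[1]], paste0("s", o[1:k]))
})

test_that("rrho_edge is symmetric in its gene arguments", {
  set.seed(13)
  for (rep in 1:5) {
    m <- mk_matrix(rnorm(24), c("g1", "g2"), paste0("s", 1:12))
    a <- rrho_edge("g1", "g2", m)
    b <- rrho_edge("g2", "g1", m)
    expect_equal(a$p_min, b$p_min, tolerance = 1e-12)
    expect_identical(a$samples[[1]], b$samples[[1]])
  }
})

test_that("anticorrelated genes lose the concordant-high signal of identical ones", {
  set.seed(4)
  x <- rnorm(8)
  m <- mk_matrix(c(x, -x), c("g1", "g2"), paste0("s", 1:8))
  ev_hi <- rrho_edge("g1", "g2", m, screen_config(both_tails = FALSE))
  ident <- rrho_edge("g1", "g1b", mk_matrix(c(x, x), c("g1", "g1b"),
                                            paste0("s", 1:8)))
  expect_gt(ev_hi$p_min, ident$p_min)
  expect_equal(log(ev_hi$p_min), brute_rrho(x, -x)$logp, tolerance = 1e-9)
})

test_that("correlated gene pairs score lower RRHO p than independent ones", {
  set.seed(21)
  n <- 60
  p_dep <- p_ind <- numeric(20)
  for (r in 1:20) {
    base <- rnorm(n)
    m <- mk_matrix(c(base, base + rnorm(n, sd = 0.3), rnorm(n)),
                   c("g1", "g2", "g3"), paste0("s", 1:n))
    p_dep[r] <- rrho_edge("g1", "g2", m)$p_min
    p_ind[r] <- rrho_edge("g1", "g3", m)$p_min
  }
  expect_lt(median(log(p_dep)), median(log(p_ind)))
})

test_that("preliminary SNR threshold is half the mean branch SNR and positive on planted data", {
  m <- mk_planted(n_genes = 6, n_samples = 24, n_mod = 4, n_in = 8, effect = 5)
  net1 <- igraph::graph_from_edgelist(cbind("g01", "g02"), directed = FALSE)
  thr1 <- preliminary_snr_threshold(m, net1)
  parts <- bipartition_samples(c("g01", "g02"), m)
  ok <- Filter(function(p) length(p) < 0.55 * ncol(m), parts)
  sel <- which.max(vapply(ok, function(p) set_snr(c("g01", "g02"), p, m, signed = TRUE), 0))
  expect_equal(thr1, set_snr(c("g01", "g02"), ok[[sel]], m) / 2, tolerance = 1e-12)

  net2 <- igraph::graph_from_edgelist(cbind(c("g01", "g03"), c("g02", "g04")),
                                      directed = FALSE)
  thr2 <- preliminary_snr_threshold(m, net2)
  expect_gt(thr2, 0)
  expect_lt(thr2, set_snr(paste0("g0", 1:4), paste0("s", sprintf("%02d", 1:8)), m))
})

test_that("screening keeps planted edges, honours vacuous thresholds, and errors when nothing survives", {
  m <- normalize_per_gene(mk_planted(n_genes = 8, n_samples = 40, n_mod = 4,
                                     n_in = 12, effect = 5))
  el <- cbind(c("g01", "g03", "g05", "g07"), c("g02", "g04", "g06", "g08"))
  net <- igraph::graph_from_edgelist(el, directed = FALSE)

  suppressMessages(ev <- screen_network_edges(m, net, screen_config()))
  kept <- paste(ev$gene_a, ev$gene_b)
  expect_setequal(kept, c("g01 g02", "g03 g04"))
  thr <- attr(ev, "snr_threshold")
  expect_true(all(ev$p_min <= 0.01 & ev$snr > thr))
  # evidence SNR is recomputable from the matrix
  for (e in seq_len(nrow(ev))) {
    expect_equal(ev$snr[e],
                 (gene_snr(ev$gene_a[e], ev$samples[[e]], m) +
                  gene_snr(ev$gene_b[e], ev$samples[[e]], m)) / 2,
                 tolerance = 1e-12)
  }

  suppressMessages(suppressWarnings(
    ev_all <- screen_network_edges(m, net, screen_config(p_threshold = 1,
                                                         snr_threshold = 0))))
  expect_identical(nrow(ev_all), 4L)

  expect_error(suppressMessages(suppressWarnings(
    screen_network_edges(m, net, screen_config(p_threshold = 1e-30,
                                               snr_threshold = 0)))),
    "no edges survive")
})
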