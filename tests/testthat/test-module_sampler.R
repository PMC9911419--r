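test_that("membership matrix places ones at each edge's samples and validates input", {
  ev <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                   p_min = c(1e-4, 1e-4), direction = "concordant-high",
                   snr = c(1, 1), stringsAsFactors = FALSE)
  ev$samples <- list(c("s1", "s3"), c("s1", "s3"))
  x <- build_membership_matrix(ev, c("s1", "s2", "s3"))
  expect_identical(unname(x[1, ]), c(1L, 0L, 1L))
  expect_identical(x[1, ], x[2, ])
  expect_identical(attr(x, "gene_a"), c("A", "B"))

  ev_bad <- ev; ev_bad$samples <- list(c("s1", "sX"), "s1")
  expect_error(build_membership_matrix(ev_bad, c("s1", "s2", "s3")), "unknown sample")
  ev_empty <- ev; ev_empty$samples <- list(character(0), "s1")
  expect_error(build_membership_matrix(ev_empty, c("s1", "s2", "s3")), "empty")
})

test_that("collapsed conditional weights match the hand-evaluated example", {
  # 2 edges, 2 samples, x = [[1,0],[1,0]], edge 1 in component 1,
  # alpha = 1, beta_total = 2, K = 2, updating edge 2:
  # w1 = (2/3)*(1.5/2)*(1.5/2) = 0.375, w2 = (1/3)*(0.5/1)*(0.5/1) = 1/12
  x <- matrix(c(1L, 0L, 1L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("s1", "s2")))
  cfg <- gibbs_config(K = 2, alpha = 1, beta_over_k = 1)
  w <- conditional_weights(2, x, c(1L, 1L), cfg)
  w_abs <- w / max(w) * 0.375   # weights are returned max-normalized
  expect_equal(w_abs, c(0.375, 1 / 12), tolerance = 1e-12)
  expect_equal(w[1] / sum(w), 0.375 / (0.375 + 1 / 12), tolerance = 1e-12)
  expect_equal(w[1] / sum(w), 0.8181818, tolerance = 1e-6)
})

test_that("empty components take the closed-form pseudo-count weight", {
  # edge 1 (row (1,0)) sits in component 1; edge 2 has row (0,0);
  # alpha = 0.5, beta_over_k = 1, K = 3 (beta_total = 3):
  #   w1 = (1+1)/(1+3) * [(0.25+0)/1.5] * [(0.25+1)/1.5] = 0.069444...
  #   w_empty = (1)/(1+3) * (1/2) * (1/2) = 0.0625   (each factor (a/2)/a)
  x <- matrix(c(1L, 0L, 0L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("s1", "s2")))
  cfg <- gibbs_config(K = 3, alpha = 0.5, beta_over_k = 1)
  w <- conditional_weights(2, x, c(1L, 1L), cfg)
  expect_equal(w[2], w[3], tolerance = 1e-12)
  expect_equal(w[2] / w[1], 0.0625 / (0.5 * (0.25 * 1.25) / 2.25),
               tolerance = 1e-9)
})

test_that("single-component sampling is forced and deterministic", {
  x <- matrix(rbinom(12, 1, 0.5), 4, 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  attr(x, "gene_a") <- paste0("a", 1:4); attr(x, "gene_b") <- paste0("b", 1:4)
  s <- run_gibbs(x, gibbs_config(K = 1, n_sweeps = 10, n_burnin = 5, seed = 9))
  expect_identical(as.integer(s), rep(1L, 4))
})

test_that("gibbs runs are bit-reproducible for a fixed seed", {
  set.seed(77)
  x <- matrix(rbinom(60, 1, 0.4), 10, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  x[1, ] <- 1L  # guarantee no empty rows matter
  cfg <- gibbs_config(K = 3, n_sweeps = 50, n_burnin = 10, seed = 123)
  s1 <- run_gibbs(x, cfg)
  s2 <- run_gibbs(x, cfg)
  expect_identical(s1, s2)
  expect_identical(attr(s1, "counts"), attr(s2, "counts"))
})

test_that("well-separated edge groups land in different components", {
  block <- function(on, len) { v <- rep(0L, len); v[on] <- 1L; v }
  x <- rbind(matrix(rep(block(1:4, 8), 10), 10, 8, byrow = TRUE),
             matrix(rep(block(5:8, 8), 10), 10, 8, byrow = TRUE))
  colnames(x) <- paste0("s", 1:8)
  hits <- 0L
  for (seed in 1:20) {
    s <- run_gibbs(x, gibbs_config(K = 2, n_sweeps = 200, n_burnin = 100,
                                   seed = seed))
    g1 <- s[1:10]; g2 <- s[11:20]
    if (length(unique(g1)) == 1L && length(unique(g2)) == 1L &&
        g1[1] != g2[1]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("permuting sample columns does not change the assignment distribution", {
  x <- rbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L))
  colnames(x) <- paste0("s", 1:4)
  perm <- c(3L, 1L, 4L, 2L)
  xp <- x[, perm]
  freq_same <- function(xx) {
    mean(vapply(1:30, function(seed) {
      s <- run_gibbs(xx, gibbs_config(K = 2, n_sweeps = 60, n_burnin = 20,
                                      seed = seed))
      s[1] == s[2]
    }, TRUE))
  }
  expect_equal(freq_same(x), freq_same(xp), tolerance = 0.15)
})

test_that("modules are extracted as endpoint unions with majority-rate samples", {
  # two edges sharing gene B with identical sample sets -> 3 genes, that set
  ev <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                   p_min = 1e-5, direction = "concordant-high", snr = 1,
                   stringsAsFactors = FALSE)
  ev$samples <- list(c("s1", "s2"), c("s1", "s2"))
  sam <- paste0("s", 1:4)
  x <- build_membership_matrix(ev, sam)
  m <- mk_planted(n_genes = 3, n_samples = 4, n_mod = 3, n_in = 2, effect = 5)
  rownames(m) <- c("A", "B", "C"); colnames(m) <- sam
  mods <- extract_modules(c(1L, 1L), x, m)
  expect_length(mods, 1L)
  expect_setequal(mods[[1]]$genes, c("A", "B", "C"))
  expect_setequal(mods[[1]]$samples, c("s1", "s2"))
  expect_equal(mods[[1]]$avg_snr, set_snr(c("A", "B", "C"), c("s1", "s2"), m),
               tolerance = 1e-12)

  # disjoint sample sets: rates (1 + 0.25) / (2 + 0.5) = 0.5, not > 0.5
  ev2 <- ev; ev2$samples <- list(c("s1", "s2"), c("s3", "s4"))
  x2 <- build_membership_matrix(ev2, sam)
  expect_warning(mods2 <- extract_modules(c(1L, 1L), x2, m, alpha = 0.5),
                 "degenerate")
  expect_length(mods2, 0L)
})
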