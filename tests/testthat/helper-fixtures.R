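# Shared fixture builders. Everything is generated in code; no files.

# small matrix with named dims
mk_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

# planted two-group matrix: `n_mod` genes shifted by `effect` on the first
# `n_in` samples, remaining genes pure noise
mk_planted <- function(n_genes = 20, n_samples = 40, n_mod = 6, n_in = 12,
                       effect = 5, seed = 7) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:n_samples)))
  m[seq_len(n_mod), seq_len(n_in)] <- m[seq_len(n_mod), seq_len(n_in)] + effect
  m
}

# independent enumeration oracle for the upper-tail hypergeometric
# probability, summing binomial coefficients directly
enum_hyper_upper <- function(n_total, size_a, size_b, overlap) {
  lo <- max(overlap, size_a + size_b - n_total)
  hi <- min(size_a, size_b)
  if (overlap <= max(0, size_a + size_b - n_total)) return(1)
  sum(choose(size_a, lo:hi) * choose(n_total - size_a, size_b - (lo:hi))) /
    choose(n_total, size_b)
}

# independent enumeration oracle for the two-sided Fisher p-value of a
# 2x2 table (margins fixed): sum of probabilities of tables at most as
# probable as the observed one
enum_fisher_two_sided <- function(n11, n12, n21, n22) {
  ra <- n11 + n12; rb <- n21 + n22; ca <- n11 + n21
  support <- max(0, ca - rb):min(ra, ca)
  probs <- choose(ra, support) * choose(rb, ca - support) / choose(ra + rb, ca)
  p_obs <- probs[support == n11]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force RRHO: scan the full threshold grid in plain R
brute_rrho <- function(x1, x2, imin = 2, both_tails = FALSE) {
  n <- length(x1)
  imax <- n - 2
  best <- list(logp = Inf)
  tails <- if (both_tails) c("hi", "lo") else "hi"
  for (tail in tails) {
    o1 <- if (tail == "hi") order(-x1, seq_len(n)) else order(x1, seq_len(n))
    o2 <- if (tail == "hi") order(-x2, seq_len(n)) else order(x2, seq_len(n))
    for (i in imin:imax) {
      for (j in imin:imax) {
        o <- length(intersect(o1[1:i], o2[1:j]))
        lp <- phyper(o - 1, i, n - i, j, lower.tail = FALSE, log.p = TRUE)
        better <- lp < best$logp ||
          (lp == best$logp && (i + j < best$i + best$j ||
            (i + j == best$i + best$j && tail == "hi" && best$tail == "lo")))
        if (better) best <- list(logp = lp, i = i, j = j, o = o, tail = tail,
                                 set = sort(intersect(o1[1:i], o2[1:j])))
      }
    }
  }
  best
}

# exact collapsed posterior over all K^E label vectors of the Bernoulli
# mixture (theta ~ Beta(a2, a2) per component x sample, weights ~
# symmetric Dirichlet beta_total/K)
enum_collapsed_posterior <- function(x, K, alpha, beta_total) {
  E <- nrow(x); S <- ncol(x)
  a2 <- alpha / 2
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), E)))
  logp <- apply(grid, 1, function(s) {
    lp <- 0
    for (k in seq_len(K)) {
      mem <- which(s == k)
      nk <- length(mem)
      lp <- lp + lgamma(nk + beta_total / K) - lgamma(beta_total / K)
      if (nk > 0) {
        c1 <- colSums(x[mem, , drop = FALSE])
        lp <- lp + sum(lbeta(a2 + c1, a2 + nk - c1) - lbeta(a2, a2))
      }
    }
    lp
  })
  p <- exp(logp - max(logp))
  list(states = grid, prob = p / sum(p))
}
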