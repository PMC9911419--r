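#' Gibbs sampler configuration
#'
#' @param K Number of mixture components. `NULL` lets the pipeline derive
#'   it from the retained-edge network (number of connected components).
#' @param alpha Beta pseudo-count parameter of the per-component Bernoulli
#'   rates, `theta ~ Beta(alpha/2, alpha/2)`. Default 0.5, the calibrated
#'   value.
#' @param beta_over_k Per-component Dirichlet concentration; the total
#'   concentration passed to the sampler is `beta_over_k * K`. Default
#'   1.0, the calibrated value.
#' @param n_sweeps Total Gibbs sweeps (default 500).
#' @param n_burnin Burn-in sweeps discarded before summarising
#'   (default 250, must be < `n_sweeps`).
#' @param seed Integer RNG seed.
#' @return A list of class `gibbs_config`.
#' @export
gibbs_config <- function(K = NULL, alpha = 0.5, beta_over_k = 1.0,
                         n_sweeps = 500L, n_burnin = 250L, seed = 1L) {
  stopifnot(alpha > 0, beta_over_k > 0, n_sweeps >= 1L,
            n_burnin >= 0L, n_burnin < n_sweeps)
  if (!is.null(K)) stopifnot(K >= 1L)
  structure(list(K = K, alpha = alpha, beta_over_k = beta_over_k,
                 n_sweeps = as.integer(n_sweeps),
                 n_burnin = as.integer(n_burnin), seed = as.integer(seed)),
            class = "gibbs_config")
}

#' Build the binary edge-by-sample membership matrix
#'
#' Row `j` has ones exactly at the samples of edge `j`'s RRHO-optimal set.
#'
#' @param evidence An `edge_evidence` data frame (see
#'   [screen_network_edges()]).
#' @param sample_ids Ordered sample identifiers (the matrix columns).
#' @return Integer 0/1 matrix with attributes `gene_a` / `gene_b` carrying
#'   the edge endpoints.
#' @export
build_membership_matrix <- function(evidence, sample_ids) {
  stopifnot(nrow(evidence) >= 1L)
  x <- matrix(0L, nrow(evidence), length(sample_ids),
              dimnames = list(NULL, sample_ids))
  for (j in seq_len(nrow(evidence))) {
    s <- evidence$samples[[j]]
    if (length(s) == 0L) stop("edge ", j, " has an empty sample set")
    idx <- match(s, sample_ids)
    if (anyNA(idx)) {
      stop("edge ", j, " references unknown sample(s): ",
           paste(s[is.na(idx)], collapse = ", "))
    }
    x[j, idx] <- 1L
  }
  attr(x, "gene_a") <- evidence$gene_a
  attr(x, "gene_b") <- evidence$gene_b
  x
}

#' Collapsed conditional label weights for one edge
#'
#' Reference implementation of the collapsed Gibbs conditional
#' `P(s_j = k | X, s_-j; alpha, beta)`, proportional to
#' `(n_k + beta/K) / (n - 1 + beta) *
#'  prod_{i: x_ji=1} (alpha/2 + c1_ki) / (alpha + n_k) *
#'  prod_{i: x_ji=0} (alpha/2 + c0_ki) / (alpha + n_k)`,
#' where all counts exclude edge `j`. Computed in log space; the
#' compiled sampler uses an algebraically identical incremental form.
#'
#' @param j Edge index to update.
#' @param x Binary membership matrix.
#' @param s Integer assignments (1..K) for all edges; entry `j` ignored.
#' @param cfg A [gibbs_config()] with a numeric `K`.
#' @return Numeric vector of K unnormalized weights (exponentiated after
#'   max subtraction, so the maximum is 1).
#' @export
conditional_weights <- function(j, x, s, cfg) {
  K <- cfg$K
  stopifnot(!is.null(K), length(s) == nrow(x))
  a2 <- cfg$alpha / 2
  beta_total <- cfg$beta_over_k * K
  idx <- setdiff(seq_len(nrow(x)), j)
  lw <- numeric(K)
  for (k in seq_len(K)) {
    mem <- idx[s[idx] == k]
    nk <- length(mem)
    c1 <- if (nk > 0L) colSums(x[mem, , drop = FALSE]) else numeric(ncol(x))
    c0 <- nk - c1
    ones <- x[j, ] == 1L
    lw[k] <- log(nk + beta_total / K) - log(nrow(x) - 1 + beta_total) +
      sum(log(a2 + c1[ones])) + sum(log(a2 + c0[!ones])) -
      ncol(x) * log(cfg$alpha + nk)
  }
  if (any(!is.finite(lw))) stop("non-finite conditional weight")
  exp(lw - max(lw))
}

#' Run the collapsed Gibbs sampler over edge labels
#'
#' Sequential sweeps in fixed edge order; each edge is resampled from its
#' normalized collapsed conditional. After burn-in, each edge's modal
#' component over the retained sweeps is reported (marginal mode, which
#' is more stable across seeds than the last sample). Deterministic for a
#' fixed seed.
#'
#' @param x Binary membership matrix from [build_membership_matrix()].
#' @param cfg A [gibbs_config()]; `K` must be set.
#' @param keep_history Keep the full post-burn-in label history (matrix
#'   edges x kept sweeps) as attribute `history` — intended for small
#'   instances and diagnostics.
#' @return Integer vector of modal assignments (1..K), with attributes
#'   `counts` (edges x K post-burn-in occupancy) and optionally `history`.
#' @export
run_gibbs <- function(x, cfg, keep_history = FALSE) {
  stopifnot(!is.null(cfg$K))
  K <- as.integer(cfg$K)
  set.seed(cfg$seed)
  s0 <- sample.int(K, nrow(x), replace = TRUE)
  res <- gibbs_sweeps_cpp(x, K, cfg$alpha, cfg$beta_over_k * K,
                          cfg$n_sweeps, cfg$n_burnin, s0, keep_history)
  counts <- res$counts
  assign <- max.col(counts, ties.method = "first")
  structure(assign, counts = counts,
            history = if (keep_history) res$history else NULL)
}

#' Convert edge-label components into biclusters
#'
#' Per non-empty component: the gene set is the union of the endpoint
#' genes of its edges; the sample set holds the samples whose posterior
#' Bernoulli membership mean `(c1_ki + alpha/2) / (n_k + alpha)` exceeds
#' 0.5; the average SNR is recomputed from the expression matrix.
#' Components whose sample set comes out empty are dropped with a warning.
#'
#' With a non-`NULL` `gene_alpha`, genes that are not significantly
#' differential on the component's consensus sample set (Welch t-test of
#' in-set vs out-set expression, p > `gene_alpha`) are pruned from the
#' union: an edge between a module gene and an unrelated gene can join a
#' component on the strength of the module gene alone, and the per-gene
#' test removes such hitchhikers. Genuinely differential genes sit many
#' orders of magnitude below any reasonable level, so the choice of
#' `gene_alpha` is uncritical; the pipeline passes its screening
#' significance level. The default `NULL` keeps the plain endpoint union.
#'
#' @param s Assignments from [run_gibbs()].
#' @param x Membership matrix (with endpoint attributes).
#' @param m Expression matrix.
#' @param alpha Beta pseudo-count used for the posterior rate (default
#'   0.5, matching the sampler).
#' @param gene_alpha Significance level of the per-gene differential
#'   test (default `NULL`: no pruning).
#' @return List of biclusters sorted by descending `avg_snr`.
#' @export
extract_modules <- function(s, x, m, alpha = 0.5, gene_alpha = NULL) {
  ga <- attr(x, "gene_a"); gb <- attr(x, "gene_b")
  stopifnot(!is.null(ga), !is.null(gb), length(s) == nrow(x))
  out <- list()
  for (k in sort(unique(s))) {
    mem <- which(s == k)
    nk <- length(mem)
    c1 <- colSums(x[mem, , drop = FALSE])
    rate <- (c1 + alpha / 2) / (nk + alpha)
    samp <- colnames(x)[rate > 0.5]
    genes <- sort(unique(c(ga[mem], gb[mem])))
    if (length(samp) == 0L || length(samp) == ncol(x)) {
      warning("component ", k, " has a degenerate consensus sample set (",
              length(samp), " of ", ncol(x), " samples); dropped")
      next
    }
    if (!is.null(gene_alpha)) {
      keep <- vapply(genes, gene_differential_p, 0, p_set = samp, m = m) <=
        gene_alpha
      if (!any(keep)) {
        warning("component ", k, " has no differential gene; dropped")
        next
      }
      genes <- genes[keep]
    }
    out[[length(out) + 1L]] <- new_bicluster(genes, samp,
                                             set_snr(genes, samp, m))
  }
  out[order(-vapply(out, function(b) b$avg_snr, 0))]
}

# Welch t-test p-value for one gene's expression, in-set vs out-set;
# degenerate (constant) splits count as non-differential.
gene_differential_p <- function(g, p_set, m) {
  x <- m[g, ]
  inn <- colnames(m) %in% p_set
  tryCatch(stats::t.test(x[inn], x[!inn])$p.value, error = function(e) 1)
}
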