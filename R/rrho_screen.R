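#' Screening configuration
#'
#' @param p_threshold Significance level applied to each edge's minimal
#'   RRHO overlap p-value. The method was calibrated over \{0.01, 0.05\};
#'   other values are allowed with a warning. Default 0.01.
#' @param rank_step Step of the rank-threshold grid (default 1: every
#'   prefix length from 2 to n-2 is scanned).
#' @param snr_threshold Numeric SNR cutoff, or `"auto"` to derive it from
#'   preliminary hierarchical clustering (half the mean preliminary-set
#'   SNR over all edges; see [preliminary_snr_threshold()]).
#' @param both_tails Search both the concordant-high (top-vs-top) and
#'   concordant-low (bottom-vs-bottom) corners of the rank-rank grid
#'   (default `TRUE`, so down-co-expressed sets are detectable). Set
#'   `FALSE` to restrict screening to the concordant-high corner; for
#'   modules spanning about half the samples the two corners describe
#'   the same split from opposite sides, and the high-only restriction
#'   removes that ambiguity at the cost of missing down-co-expressed
#'   sets.
#' @param bh_correct Apply Benjamini-Hochberg correction across edges
#'   before the p cut. Off by default: the raw per-edge cut is the
#'   calibrated behaviour.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(p_threshold = 0.01, rank_step = 1L,
                          snr_threshold = "auto", both_tails = TRUE,
                          bh_correct = FALSE) {
  stopifnot(p_threshold > 0, p_threshold <= 1, rank_step >= 1L)
  if (!p_threshold %in% c(0.01, 0.05)) {
    warning("p_threshold ", p_threshold,
            " is outside the calibrated set {0.01, 0.05}")
  }
  structure(list(p_threshold = p_threshold, rank_step = as.integer(rank_step),
                 snr_threshold = snr_threshold, both_tails = both_tails,
                 bh_correct = bh_correct),
            class = "screen_config")
}

#' Signal-to-noise ratio of one gene over a sample split
#'
#' `SNR(g, P') = |mean_in - mean_out| / (sd_in + sd_out)` where `in` is the
#' sample set `p_set` and `out` its complement, with population standard
#' deviations. The default absolute value makes the score direction-free,
#' so a set and its complement score identically; `signed = TRUE` keeps
#' the sign of the mean difference, which distinguishes the up-expressed
#' side of a split from its complement (used for branch selection). A
#' degenerate denominator (< 1e-12) is guarded by adding
#' `1e-12 * (1 + |mean difference|)`.
#'
#' @param g Gene identifier (row of `m`).
#' @param p_set Character vector of sample identifiers, a proper non-empty
#'   subset of `colnames(m)`.
#' @param m Expression matrix.
#' @param signed Keep the sign of the mean difference (default `FALSE`).
#' @return Finite scalar; non-negative unless `signed = TRUE`.
#' @export
gene_snr <- function(g, p_set, m, signed = FALSE) {
  x <- m[g, ]
  inn <- colnames(m) %in% p_set
  k <- sum(inn)
  if (k == 0L || k == ncol(m)) {
    stop("p_set must be a non-empty proper subset of the samples")
  }
  xi <- x[inn]; xo <- x[!inn]
  num <- mean(xi) - mean(xo)
  if (!signed) num <- abs(num)
  den <- sqrt(mean((xi - mean(xi))^2)) + sqrt(mean((xo - mean(xo))^2))
  if (den < 1e-12) den <- den + 1e-12 * (1 + abs(num))
  num / den
}

#' Average SNR of a gene set over a sample split
#'
#' Arithmetic mean of [gene_snr()] over the genes.
#'
#' @inheritParams gene_snr
#' @param genes Non-empty character vector of gene identifiers.
#' @export
set_snr <- function(genes, p_set, m, signed = FALSE) {
  stopifnot(length(genes) >= 1L)
  mean(vapply(genes, gene_snr, 0, p_set = p_set, m = m, signed = signed))
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `overlap` shared items when `size_b`
#' items are drawn from a universe of `n_total` containing `size_a` marked
#' items: `P[X >= overlap]`.
#'
#' @param n_total Universe size.
#' @param size_a,size_b Set sizes, each at most `n_total`.
#' @param overlap Observed intersection size.
#' @return p-value in (0, 1].
#' @export
overlap_pvalue <- function(n_total, size_a, size_b, overlap) {
  if (size_a > n_total || size_b > n_total || overlap > min(size_a, size_b) ||
      overlap < 0 || overlap < size_a + size_b - n_total) {
    stop("inconsistent hypergeometric counts")
  }
  phyper(overlap - 1, size_a, n_total - size_a, size_b, lower.tail = FALSE)
}

# Stable sample orderings for a gene: descending expression for the
# concordant-high tail, ascending for concordant-low; ties broken by
# sample index.
.rank_orders <- function(x) {
  list(hi = order(-x, seq_along(x)), lo = order(x, seq_along(x)))
}

#' RRHO evidence for one gene pair
#'
#' Ranks the samples by each gene's expression and scans every rank
#' threshold pair `(i, j)` with `i, j` in `{2, ..., n-2}` (grid step
#' `cfg$rank_step`), scoring the overlap of the two prefixes with the
#' upper-tail hypergeometric probability. Both the concordant-high
#' (top-vs-top) and concordant-low (bottom-vs-bottom) corners are scanned
#' unless `cfg$both_tails` is `FALSE`. The returned evidence carries the
#' prefix intersection at the minimising grid cell, its p-value, the tail
#' it came from, and the average SNR of the two genes on that set.
#' Ties in p are broken towards the smaller `i + j`, then concordant-high.
#'
#' @param g1,g2 Gene identifiers.
#' @param m Expression matrix with at least 4 samples.
#' @param cfg A [screen_config()].
#' @return A one-row data frame with columns `gene_a`, `gene_b`, `p_min`,
#'   `direction`, `snr` and a list column `samples`.
#' @export
rrho_edge <- function(g1, g2, m, cfg = screen_config()) {
  stopifnot(ncol(m) >= 4L)
  res <- .rrho_scan_edges(matrix(c(g1, g2), ncol = 2L, byrow = TRUE), m, cfg)
  res
}

# Vectorised scan over many edges; edges is a 2-column character matrix.
# Gene pairs are canonicalised (lexicographic order) before scanning so
# that the grid tie-break cannot depend on argument order; evidence is
# reported in the caller's order.
.rrho_scan_edges <- function(edges, m, cfg) {
  n <- ncol(m)
  n_edges <- nrow(edges)
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L), drop = FALSE]
  ord <- lapply(rownames(m), function(g) .rank_orders(m[g, ]))
  names(ord) <- rownames(m)
  # pos[k, e] = rank in g2's ordering of the sample ranked k by g1
  pos_hi <- matrix(0L, n, n_edges)
  pos_lo <- matrix(0L, n, n_edges)
  for (e in seq_len(n_edges)) {
    o1 <- ord[[edges[e, 1L]]]; o2 <- ord[[edges[e, 2L]]]
    r2h <- integer(n); r2h[o2$hi] <- seq_len(n)
    r2l <- integer(n); r2l[o2$lo] <- seq_len(n)
    pos_hi[, e] <- r2h[o1$hi]
    pos_lo[, e] <- r2l[o1$lo]
  }
  best <- rrho_scan_cpp(pos_hi, pos_lo, 2L, n - 2L, cfg$rank_step,
                        isTRUE(cfg$both_tails))
  samples <- vector("list", n_edges)
  snr <- numeric(n_edges)
  dir <- ifelse(best$tail == 1L, "concordant-high", "concordant-low")
  for (e in seq_len(n_edges)) {
    o1 <- ord[[edges[e, 1L]]]; o2 <- ord[[edges[e, 2L]]]
    if (best$tail[e] == 1L) {
      s <- intersect(o1$hi[seq_len(best$i[e])], o2$hi[seq_len(best$j[e])])
    } else {
      s <- intersect(o1$lo[seq_len(best$i[e])], o2$lo[seq_len(best$j[e])])
    }
    samples[[e]] <- colnames(m)[sort(s)]
    # a best cell with zero overlap (possible for strongly anticorrelated
    # pairs under a high-tail-only scan) carries no differential set
    snr[e] <- if (length(s) == 0L || length(s) == n) 0 else
      (gene_snr(edges[e, 1L], samples[[e]], m) +
       gene_snr(edges[e, 2L], samples[[e]], m)) / 2
  }
  ga <- ifelse(flip, edges[, 2L], edges[, 1L])
  gb <- ifelse(flip, edges[, 1L], edges[, 2L])
  out <- data.frame(gene_a = ga, gene_b = gb,
                    p_min = best$p, direction = dir, snr = snr,
                    stringsAsFactors = FALSE)
  out$samples <- samples
  class(out) <- c("edge_evidence", "data.frame")
  out
}

#' Data-driven preliminary SNR threshold
#'
#' For every network edge the samples are hierarchically bipartitioned on
#' the two genes' expression (see [bipartition_samples()]); the branch
#' with the higher two-gene SNR among branches holding fewer than 55% of
#' the samples is that edge's preliminary set. The threshold is half the
#' mean preliminary-set SNR over all edges.
#'
#' @param m Expression matrix.
#' @param net Pruned gene network (non-empty).
#' @return Positive scalar threshold.
#' @export
preliminary_snr_threshold <- function(m, net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) stop("empty network")
  cap <- 0.55 * ncol(m)
  snrs <- vapply(seq_len(nrow(el)), function(e) {
    genes <- el[e, ]
    parts <- bipartition_samples(genes, m)
    ok <- Filter(function(p) length(p) < cap, parts)
    sel <- which.max(vapply(ok, function(p) set_snr(genes, p, m, signed = TRUE), 0))
    set_snr(genes, ok[[sel]], m)
  }, 0)
  mean(snrs) / 2
}

#' Screen all network edges by RRHO overlap and SNR
#'
#' Computes [rrho_edge()] evidence for every edge of `net` and retains
#' edges with `p_min <= cfg$p_threshold` and `snr > snr_threshold`
#' (`"auto"` resolves to [preliminary_snr_threshold()]). Discarded edges
#' are removed from the working network and genes left isolated dropped.
#'
#' @param m Expression matrix (normalized, complete).
#' @param net Gene network already pruned against `m`.
#' @param cfg A [screen_config()].
#' @return An `edge_evidence` data frame of the surviving edges, with
#'   attributes `network` (the retained-edge igraph), `snr_threshold`
#'   (the resolved numeric threshold) and `n_scanned`.
#' @export
screen_network_edges <- function(m, net, cfg = screen_config()) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) stop("empty network: nothing to screen")
  thr <- cfg$snr_threshold
  if (identical(thr, "auto")) thr <- preliminary_snr_threshold(m, net)
  ev <- .rrho_scan_edges(el, m, cfg)
  p_eff <- if (isTRUE(cfg$bh_correct)) stats::p.adjust(ev$p_min, "BH") else ev$p_min
  keep <- p_eff <= cfg$p_threshold & ev$snr > thr & lengths(ev$samples) > 0L
  if (!any(keep)) {
    stop("no edges survive screening (p <= ", cfg$p_threshold, ", SNR > ",
         signif(thr, 4), "); consider relaxing the thresholds")
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  g <- igraph::graph_from_edgelist(cbind(ev$gene_a, ev$gene_b), directed = FALSE)
  message(sprintf("screening: %d / %d edges retained (SNR threshold %.4f)",
                  nrow(ev), nrow(el), thr))
  structure(ev, network = g, snr_threshold = thr, n_scanned = nrow(el),
            class = c("edge_evidence", "data.frame"))
}

#' Write edge evidence as TSV
#' @param ev An `edge_evidence` data frame.
#' @param path Output path.
#' @export
write_edge_evidence <- function(ev, path) {
  df <- data.frame(gene_a = ev$gene_a, gene_b = ev$gene_b, p_min = ev$p_min,
                   direction = ev$direction, snr = ev$snr,
                   samples = vapply(ev$samples, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
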