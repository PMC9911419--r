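#' Construct a bicluster
#'
#' A bicluster is a gene set co-behaving on a sample set, scored by the
#' average per-gene SNR over that sample split.
#'
#' @param genes Non-empty character vector of gene IDs.
#' @param samples Non-empty character vector of sample IDs.
#' @param avg_snr Average SNR (recomputable via [set_snr()]).
#' @return A list of class `bicluster`.
#' @export
new_bicluster <- function(genes, samples, avg_snr = NA_real_) {
  stopifnot(length(genes) >= 1L, length(samples) >= 1L)
  structure(list(genes = as.character(genes),
                 samples = as.character(samples),
                 avg_snr = as.numeric(avg_snr)),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("<bicluster: %d genes x %d samples, avg SNR %.4f>\n",
              length(x$genes), length(x$samples), x$avg_snr))
  invisible(x)
}

#' Fisher exact test on the sample overlap of two biclusters
#'
#' Two-sided Fisher exact p-value of the 2x2 table cross-classifying the
#' sample universe by membership in `a` and in `b`. Small p means the two
#' sample sets differ significantly (association far from independence);
#' the merge criterion requires a *non*-significant p. Degenerate tables
#' (a set empty or covering the whole universe) return p = 1 with a
#' warning.
#'
#' @param a,b Biclusters.
#' @param all_samples Character vector, the sample universe.
#' @param alternative `"two.sided"` (default) tests any departure from
#'   independence; `"greater"` tests positive association (overlap larger
#'   than chance), the direction the merge gate uses.
#' @return p-value in (0, 1].
#' @export
fisher_overlap_test <- function(a, b, all_samples,
                                alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ina <- all_samples %in% a$samples
  inb <- all_samples %in% b$samples
  if (!any(ina) || all(ina) || !any(inb) || all(inb)) {
    warning("degenerate sample membership table; returning p = 1")
    return(1)
  }
  tab <- table(factor(ina, c(TRUE, FALSE)), factor(inb, c(TRUE, FALSE)))
  fisher.test(tab, alternative = alternative)$p.value
}

#' Hierarchically bipartition the samples on a gene set
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance) of the
#' sample columns restricted to the given gene rows, cut at two clusters.
#' Deterministic; ties in the dendrogram are resolved by `hclust`'s
#' stable ordering of the input, so permuting sample columns gives the
#' same partition as sets.
#'
#' @param genes Gene IDs (rows of `m`).
#' @param m Expression matrix with at least 4 samples.
#' @return List of two disjoint non-empty character vectors covering all
#'   samples.
#' @export
bipartition_samples <- function(genes, m) {
  stopifnot(length(genes) >= 1L, ncol(m) >= 4L)
  sub <- m[genes, , drop = FALSE]
  d <- dist(t(sub))
  if (all(d < 1e-12)) stop("all sample profiles identical; no bipartition")
  cl <- cutree(hclust(d, method = "ward.D2"), k = 2L)
  list(colnames(m)[cl == 1L], colnames(m)[cl == 2L])
}

#' Attempt to merge two biclusters
#'
#' Merges when (1) the Fisher test finds the two sample sets
#' significantly positively associated — they share more samples than
#' chance would give, i.e. they are not different draws
#' (one-sided p `<= fisher_alpha`); (2) the union gene set,
#' re-bipartitioned over the samples, yields a branch (the one with the
#' higher *signed* set SNR among branches under the 55% cap — the side on
#' which the genes are up-expressed, which matters when both branches
#' clear the cap and |SNR| alone cannot tell a set from its complement)
#' that (3) holds fewer
#' than 55% of all samples and (4) has set SNR above `snr_threshold`.
#' Rejection is a value naming the failed criterion, not an error.
#'
#' @param a,b Distinct biclusters.
#' @param m Expression matrix.
#' @param snr_threshold Minimal SNR of the merged cluster.
#' @param fisher_alpha Significance level for the difference test
#'   (default 0.05).
#' @return The merged `bicluster`, or a rejection object (class
#'   `merge_rejection`) whose `reason` field is one of `"fisher"`,
#'   `"sample_cap"`, `"snr"`.
#' @export
try_merge <- function(a, b, m, snr_threshold, fisher_alpha = 0.05) {
  p <- fisher_overlap_test(a, b, colnames(m), alternative = "greater")
  reject <- function(reason) {
    structure(list(reason = reason, fisher_p = p), class = "merge_rejection")
  }
  if (p > fisher_alpha) return(reject("fisher"))
  genes <- sort(unique(c(a$genes, b$genes)))
  parts <- bipartition_samples(genes, m)
  cap <- 0.55 * ncol(m)
  ok <- Filter(function(s) length(s) < cap, parts)
  if (length(ok) == 0L) return(reject("sample_cap"))
  sel <- which.max(vapply(ok, function(s) set_snr(genes, s, m, signed = TRUE), 0))
  cand <- ok[[sel]]
  snr <- set_snr(genes, cand, m)
  if (snr <= snr_threshold) return(reject("snr"))
  new_bicluster(genes, sort(cand), snr)
}

#' Iteratively merge biclusters until convergence
#'
#' Repeated passes over all unordered pairs, ordered by ascending Fisher
#' p within each pass (most-similar-first, which makes the greedy
#' procedure deterministic). An accepted merge replaces its two inputs
#' immediately; a pass in which nothing merges terminates the loop.
#' Rejected pairs are re-evaluated on later passes since earlier merges
#' change the landscape.
#'
#' The number of pairwise tests grows quadratically with the cluster
#' count, so by default `fisher_alpha` is Bonferroni-adjusted by the
#' number of pairs in each pass: fragments of one true module overlap
#' far beyond chance (p many orders below any cut) and still merge,
#' while chance-high overlaps between unrelated clusters no longer do.
#' Set `correct = "none"` for the raw per-pair level.
#'
#' @param clusters Non-empty list of biclusters.
#' @param m Expression matrix.
#' @param snr_threshold Minimal merged-cluster SNR.
#' @param fisher_alpha Fisher significance level (default 0.05).
#' @param correct Multiplicity handling across the pairs of a pass:
#'   `"bonferroni"` (default) or `"none"`.
#' @return List of biclusters ordered by descending `avg_snr`, with
#'   attribute `merge_log` (data frame: pass, cluster indices, Fisher p,
#'   decision).
#' @export
iterative_merge <- function(clusters, m, snr_threshold, fisher_alpha = 0.05,
                            correct = c("bonferroni", "none")) {
  correct <- match.arg(correct)
  stopifnot(length(clusters) >= 1L)
  log_rows <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (length(clusters) < 2L) break
    pairs <- utils::combn(length(clusters), 2L)
    pvals <- apply(pairs, 2L, function(ij) {
      suppressWarnings(
        fisher_overlap_test(clusters[[ij[1L]]], clusters[[ij[2L]]],
                            colnames(m), alternative = "greater"))
    })
    alpha_eff <- if (correct == "bonferroni") fisher_alpha / ncol(pairs) else
      fisher_alpha
    ord <- order(pvals, pairs[1L, ], pairs[2L, ])
    merged_any <- FALSE
    consumed <- rep(FALSE, length(clusters))
    accepted <- list()
    for (c_idx in ord) {
      i <- pairs[1L, c_idx]; j <- pairs[2L, c_idx]
      if (consumed[i] || consumed[j]) next
      res <- suppressWarnings(
        try_merge(clusters[[i]], clusters[[j]], m, snr_threshold, alpha_eff))
      ok <- inherits(res, "bicluster")
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(pass = pass, a = i, b = j, fisher_p = pvals[c_idx],
                   decision = if (ok) "merged" else res$reason,
                   stringsAsFactors = FALSE)
      if (ok) {
        consumed[i] <- consumed[j] <- TRUE
        accepted[[length(accepted) + 1L]] <- res
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
    clusters <- c(clusters[!consumed], accepted)
  }
  clusters <- clusters[order(-vapply(clusters, function(b) b$avg_snr, 0))]
  attr(clusters, "merge_log") <-
    if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(pass = integer(), a = integer(), b = integer(),
                 fisher_p = numeric(), decision = character())
  clusters
}
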