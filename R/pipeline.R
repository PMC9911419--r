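#' Run the full biclustering pipeline on an expression matrix and network
#'
#' Composes the method end to end: KNN imputation of missing values,
#' per-gene z-scoring, network/matrix reconciliation, RRHO + SNR edge
#' screening, collapsed Gibbs grouping of the retained edges, conversion
#' of edge modules to biclusters, and iterative Fisher-test merging.
#' Genes that are not significantly differential on their cluster's
#' sample set (Welch t-test at the screening significance level) are
#' pruned at extraction and again after merging, and final outputs are
#' filtered to the structural constraints (sample set under 55% of
#' samples, recomputed average SNR above the screening threshold).
#'
#' @param m Expression matrix (genes x samples; may contain `NA`s).
#' @param net Gene network ([igraph::graph] with gene-ID vertex names).
#' @param screen A [screen_config()].
#' @param gibbs A [gibbs_config()]; a `NULL` `K` is resolved to the number
#'   of connected components of the retained-edge network.
#' @param fisher_alpha Significance level of the merge difference test.
#' @param knn_k Neighbours for imputation.
#' @param seed Global seed; stage seeds are derived from it.
#' @param normalize Set `FALSE` if `m` is already per-gene z-scored.
#' @return List of class `cobinet_result`: `biclusters`, `evidence`,
#'   `assignments`, `merge_log`, `snr_threshold`, `K`, `config`.
#' @export
run_pipeline <- function(m, net, screen = screen_config(),
                         gibbs = gibbs_config(), fisher_alpha = 0.05,
                         knn_k = 10L, seed = 1L, normalize = TRUE) {
  if (anyNA(m)) m <- knn_impute(m, knn_k)
  if (normalize) m <- normalize_per_gene(m)
  pruned <- prune_isolated_genes(net, m)
  m <- pruned$matrix
  ev <- screen_network_edges(m, pruned$network, screen)
  thr <- attr(ev, "snr_threshold")
  retained_net <- attr(ev, "network")
  K <- gibbs$K
  if (is.null(K)) {
    K <- igraph::count_components(retained_net)
  }
  gcfg <- gibbs_config(K = K, alpha = gibbs$alpha,
                       beta_over_k = gibbs$beta_over_k,
                       n_sweeps = gibbs$n_sweeps, n_burnin = gibbs$n_burnin,
                       seed = derive_seed(seed, "gibbs"))
  x <- build_membership_matrix(ev, colnames(m))
  s <- run_gibbs(x, gcfg)
  modules <- extract_modules(s, x, m, alpha = gibbs$alpha,
                             gene_alpha = screen$p_threshold)
  if (length(modules) == 0L) stop("no modules extracted from the sampler")
  merged <- iterative_merge(modules, m, thr, fisher_alpha)
  merge_log <- attr(merged, "merge_log")
  cap <- 0.55 * ncol(m)
  # merging unions gene sets, so re-apply the per-gene differential test
  # before the structural checks
  merged <- lapply(merged, function(b) {
    p <- vapply(b$genes, gene_differential_p, 0, p_set = b$samples, m = m)
    keep <- p <= screen$p_threshold
    if (!any(keep)) return(NULL)
    new_bicluster(b$genes[keep], b$samples,
                  set_snr(b$genes[keep], b$samples, m))
  })
  merged <- Filter(Negate(is.null), merged)
  final <- Filter(function(b) {
    length(b$samples) < cap && set_snr(b$genes, b$samples, m) > thr
  }, merged)
  message(sprintf("pipeline: %d retained edges, K = %d, %d sampler modules, %d after merge, %d final",
                  nrow(ev), K, length(modules), length(merged), length(final)))
  structure(list(biclusters = final, evidence = ev, assignments = s,
                 merge_log = merge_log, snr_threshold = thr, K = K,
                 config = list(screen = screen, gibbs = gcfg,
                               fisher_alpha = fisher_alpha, knn_k = knn_k,
                               seed = seed)),
            class = "cobinet_result")
}

#' @export
print.cobinet_result <- function(x, ...) {
  cat(sprintf("<cobinet result: %d biclusters (SNR threshold %.4f, K = %d)>\n",
              length(x$biclusters), x$snr_threshold, x$K))
  for (b in head(x$biclusters, 10L)) print(b)
  if (length(x$biclusters) > 10L) cat("...\n")
  invisible(x)
}

#' Simulate, analyse and score one benchmark cell
#'
#' Generates a planted-module dataset and its matched network, runs the
#' pipeline at the calibrated defaults, and scores recovery against the
#' planted truth.
#'
#' @param spec A [simulation_spec()].
#' @param screen,gibbs,fisher_alpha Pipeline settings.
#' @return List with `result` (the `cobinet_result`), `report`
#'   (the [recovery_score()] report) and `truth`.
#' @export
run_benchmark_cell <- function(spec, screen = screen_config(),
                               gibbs = gibbs_config(), fisher_alpha = 0.05) {
  ds <- generate_dataset(spec)
  net <- generate_network(ds$modules, spec)
  res <- run_pipeline(ds$matrix, net, screen = screen, gibbs = gibbs,
                      fisher_alpha = fisher_alpha, seed = spec$seed)
  report <- recovery_score(res$biclusters, ds$modules)
  list(result = res, report = report, truth = ds$modules)
}

#' Benchmark a grid of planted module sizes
#'
#' For every `(samples_per_module, genes_per_module)` configuration and
#' every replicate: simulate with a derived seed, run the pipeline, and
#' score mean best-match cell Jaccard against the planted modules.
#'
#' @param sizes Two-column matrix or data frame: samples per module,
#'   genes per module.
#' @param replicates Replicate datasets per configuration (default 5).
#' @param seed Base seed; each replicate derives its own.
#' @param n_genes,n_samples,n_modules Matrix dimensions / module count.
#' @param in_mean In-module mean (default 2).
#' @param screen,gibbs,fisher_alpha Pipeline settings.
#' @return Data frame: one row per configuration with mean and SD of
#'   recovery over replicates, plus the per-replicate scores as a list
#'   column. Failed cells are recorded with `NA` scores and the benchmark
#'   continues.
#' @export
benchmark_grid <- function(sizes, replicates = 5L, seed = 1L,
                           n_genes = 2000L, n_samples = 200L, n_modules = 20L,
                           in_mean = 2, screen = screen_config(),
                           gibbs = gibbs_config(), fisher_alpha = 0.05) {
  sizes <- as.matrix(sizes)
  rows <- vector("list", nrow(sizes))
  for (r in seq_len(nrow(sizes))) {
    ns <- sizes[r, 1L]; ng <- sizes[r, 2L]
    scores <- rep(NA_real_, replicates)
    for (rep_i in seq_len(replicates)) {
      spec <- simulation_spec(
        n_genes = n_genes, n_samples = n_samples, n_modules = n_modules,
        in_mean = in_mean, fixed_module_size = c(ns, ng),
        seed = derive_seed(seed, sprintf("bench_%d_%d_%d", ns, ng, rep_i)))
      out <- tryCatch(
        run_benchmark_cell(spec, screen, gibbs, fisher_alpha),
        error = function(e) {
          warning(sprintf("benchmark cell (%d,%d) replicate %d failed: %s",
                          ns, ng, rep_i, conditionMessage(e)))
          NULL
        })
      if (!is.null(out)) scores[rep_i] <- out$report$recovery
    }
    rows[[r]] <- data.frame(samples_per_module = ns, genes_per_module = ng,
                            mean_recovery = mean(scores, na.rm = TRUE),
                            sd_recovery = stats::sd(scores[!is.na(scores)]),
                            n_ok = sum(!is.na(scores)))
    rows[[r]]$scores <- I(list(scores))
  }
  do.call(rbind, rows)
}
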