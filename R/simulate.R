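#' Specification for the planted-module benchmark generator
#'
#' Defaults reproduce the benchmark conditions: a 2000-gene by 200-sample
#' matrix with 20 planted modules whose gene counts are drawn from
#' \{100, 50, 20, 10, 5\} and sample counts from \{100, 50, 20, 10\};
#' in-module cells ~ N(2, 1), background ~ N(0, 1); modules may overlap.
#'
#' @param n_genes,n_samples Matrix dimensions (defaults 2000, 200).
#' @param n_modules Number of planted modules (default 20).
#' @param gene_size_pool,sample_size_pool Pools the per-module gene /
#'   sample counts are drawn from (uniformly, with replacement across
#'   modules).
#' @param in_mean,in_sd In-module cell distribution (defaults 2, 1).
#' @param bg_mean,bg_sd Background cell distribution (defaults 0, 1).
#' @param fixed_module_size Optional `c(n_samples_per_module,
#'   n_genes_per_module)` override giving every module the same size —
#'   the benchmark-table style configuration (samples, genes).
#' @param module_degree Target mean within-module degree of the
#'   companion network (default 3).
#' @param background_degree Target mean degree contributed by random
#'   background edges (default 1).
#' @param seed Integer RNG seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000L, n_samples = 200L,
                            n_modules = 20L,
                            gene_size_pool = c(100L, 50L, 20L, 10L, 5L),
                            sample_size_pool = c(100L, 50L, 20L, 10L),
                            in_mean = 2, in_sd = 1, bg_mean = 0, bg_sd = 1,
                            fixed_module_size = NULL,
                            module_degree = 3, background_degree = 1,
                            seed = 1L) {
  stopifnot(n_genes >= 2L, n_samples >= 4L, n_modules >= 1L,
            length(gene_size_pool) >= 1L, length(sample_size_pool) >= 1L,
            in_sd > 0, bg_sd > 0)
  if (!is.null(fixed_module_size)) {
    stopifnot(length(fixed_module_size) == 2L,
              fixed_module_size[1L] <= n_samples,
              fixed_module_size[2L] <= n_genes)
  }
  if (is.null(fixed_module_size) &&
      (max(gene_size_pool) > n_genes || max(sample_size_pool) > n_samples)) {
    stop("module size pool exceeds matrix dimensions")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_modules = as.integer(n_modules),
                 gene_size_pool = as.integer(gene_size_pool),
                 sample_size_pool = as.integer(sample_size_pool),
                 in_mean = in_mean, in_sd = in_sd,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 fixed_module_size = fixed_module_size,
                 module_degree = module_degree,
                 background_degree = background_degree,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a planted-module expression matrix
#'
#' Background cells are drawn from `N(bg_mean, bg_sd^2)`. For each module,
#' gene and sample counts are drawn from the pools (or fixed by
#' `fixed_module_size`), the member genes and samples uniformly without
#' replacement, and the member cells overwritten with draws from
#' `N(in_mean, in_sd^2)`. Where modules overlap, the last-generated
#' module's draw stands. Deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with `matrix` (genes x samples, dimnames `g0001...` /
#'   `s001...`) and `modules` (list of `genes` / `samples` ID sets).
#' @export
generate_dataset <- function(spec) {
  set.seed(derive_seed(spec$seed, "dataset"))
  gid <- sprintf("g%04d", seq_len(spec$n_genes))
  sid <- sprintf("s%03d", seq_len(spec$n_samples))
  m <- matrix(rnorm(spec$n_genes * spec$n_samples, spec$bg_mean, spec$bg_sd),
              spec$n_genes, spec$n_samples, dimnames = list(gid, sid))
  modules <- vector("list", spec$n_modules)
  for (k in seq_len(spec$n_modules)) {
    if (is.null(spec$fixed_module_size)) {
      ng <- sample(spec$gene_size_pool, 1L)
      ns <- sample(spec$sample_size_pool, 1L)
    } else {
      ns <- spec$fixed_module_size[1L]
      ng <- spec$fixed_module_size[2L]
    }
    genes <- sort(sample(spec$n_genes, ng))
    samples <- sort(sample(spec$n_samples, ns))
    m[genes, samples] <- rnorm(ng * ns, spec$in_mean, spec$in_sd)
    modules[[k]] <- list(genes = gid[genes], samples = sid[samples])
  }
  list(matrix = m, modules = modules)
}

# uniform random spanning tree over ids via a random Pruefer sequence
.random_tree_edges <- function(ids) {
  n <- length(ids)
  if (n == 1L) return(matrix(character(0), 0L, 2L))
  if (n == 2L) return(matrix(ids, 1L, 2L))
  pruefer <- sample.int(n, n - 2L, replace = TRUE)
  degree <- rep(1L, n)
  for (v in pruefer) degree[v] <- degree[v] + 1L
  edges <- matrix("", n - 1L, 2L)
  ptr <- 1L
  for (i in seq_len(n - 2L)) {
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(ids[leaf], ids[pruefer[i]])
    degree[leaf] <- 0L
    degree[pruefer[i]] <- degree[pruefer[i]] - 1L
    ptr <- ptr + 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- ids[last]
  edges
}

#' Generate a gene network matched to planted modules
#'
#' Each module's genes are wired into a uniform random spanning tree
#' (guaranteeing a connected induced subgraph) and topped up with random
#' in-module edges until the module's mean degree reaches
#' `spec$module_degree`. Random background edges between arbitrary gene
#' pairs are added at a rate giving mean background degree
#' `spec$background_degree`. The result is a simple undirected graph with
#' no isolated module genes.
#'
#' @param modules Planted modules from [generate_dataset()].
#' @param spec The [simulation_spec()] used to generate them.
#' @return An undirected [igraph::graph] on all gene IDs that carry at
#'   least one edge.
#' @export
generate_network <- function(modules, spec) {
  set.seed(derive_seed(spec$seed, "network"))
  gid <- sprintf("g%04d", seq_len(spec$n_genes))
  edges <- list()
  for (mod in modules) {
    ids <- mod$genes
    n <- length(ids)
    edges[[length(edges) + 1L]] <- .random_tree_edges(ids)
    extra <- max(0L, round(n * spec$module_degree / 2) - (n - 1L))
    if (extra > 0L && n >= 3L) {
      a <- sample(ids, 2L * extra, replace = TRUE)
      b <- sample(ids, 2L * extra, replace = TRUE)
      keep <- a != b
      edges[[length(edges) + 1L]] <- cbind(a[keep], b[keep])[seq_len(
        min(extra, sum(keep))), , drop = FALSE]
    }
  }
  n_bg <- round(spec$n_genes * spec$background_degree / 2)
  if (n_bg > 0L) {
    a <- sample(gid, 2L * n_bg, replace = TRUE)
    b <- sample(gid, 2L * n_bg, replace = TRUE)
    keep <- a != b
    edges[[length(edges) + 1L]] <-
      cbind(a[keep], b[keep])[seq_len(min(n_bg, sum(keep))), , drop = FALSE]
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Write a simulated dataset as a reusable fixture
#'
#' Writes `expression.tsv`, `network.tsv`, `truth.json` (module ->
#' genes/samples) and `spec.yaml` (the generator settings and seed, from
#' which the fixture can be regenerated bit-identically).
#'
#' @param dir Output directory (created if missing).
#' @param dataset Result of [generate_dataset()].
#' @param network Result of [generate_network()].
#' @param spec The [simulation_spec()] used.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, dataset, network, spec) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(dataset$matrix, file.path(dir, "expression.tsv"))
  write_edge_list(network, file.path(dir, "network.tsv"))
  jsonlite::write_json(dataset$modules, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  if (requireNamespace("yaml", quietly = TRUE)) {
    sp <- unclass(spec)
    sp$fixed_module_size <- if (is.null(sp$fixed_module_size)) "none" else
      as.integer(sp$fixed_module_size)
    yaml::write_yaml(sp, file.path(dir, "spec.yaml"))
  }
  invisible(dir)
}

#' Read the ground-truth modules of a fixture
#' @param path Path to `truth.json`.
#' @return List of planted modules (`genes`, `samples`).
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(mod) list(genes = unlist(mod$genes),
                                 samples = unlist(mod$samples)))
}
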