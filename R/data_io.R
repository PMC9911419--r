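#' Read a delimited expression table
#'
#' Reads a genes-by-samples expression matrix from TSV/CSV. The first
#' column holds gene identifiers and the header row sample identifiers.
#' Empty cells, `NA` and `NaN` are treated as missing.
#'
#' @param path Path to the file.
#' @param sep Field separator. `NULL` (default) picks `","` for `.csv`
#'   files and tab otherwise.
#' @param transpose If `TRUE` the file is samples-by-genes and is
#'   transposed after reading.
#' @return A numeric matrix (genes in rows) with unique dimnames; missing
#'   entries are `NA`.
#' @export
read_expression_table <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nf <- count.fields(path, sep = sep, quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L) stop("expression file has no data rows: ", path)
  bad <- which(nf != nf[1L])
  if (length(bad) > 0L) {
    stop("ragged expression table: line ", bad[1L], " has ", nf[bad[1L]],
         " fields, expected ", nf[1L])
  }
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   na.strings = c("", "NA", "NaN"), comment.char = "",
                   colClasses = c("character", rep("numeric", nf[1L] - 1L)))
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate row identifiers in expression table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    stop("duplicate column identifiers in expression table")
  }
  if (transpose) m <- t(m)
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]; round-trips bit-identically for
#' matrices written with full precision.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the identifier column in the header.
#' @export
write_expression_table <- function(m, path, id_col = "gene_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute missing values by k-nearest-neighbour averaging
#'
#' Each missing entry of a gene is replaced by the mean of the same
#' sample's values over the `k` genes nearest in Euclidean distance.
#' Distances are computed over co-observed samples and scaled by the
#' fraction observed (nan-Euclidean), so partially observed genes remain
#' comparable.
#'
#' @param m Numeric genes-by-samples matrix, possibly with `NA`s.
#' @param k Number of neighbours (default 10).
#' @return The matrix with no missing entries; observed cells unchanged.
#' @export
knn_impute <- function(m, k = 10L) {
  stopifnot(is.matrix(m), k >= 1L)
  if (!anyNA(m)) return(m)
  obs <- !is.na(m)
  all_missing <- rowSums(obs) == 0L
  if (any(all_missing)) {
    stop("gene(s) missing in all samples, cannot impute: ",
         paste(head(rownames(m)[all_missing], 5L), collapse = ", "))
  }
  need <- which(rowSums(!obs) > 0L)
  n_samp <- ncol(m)
  out <- m
  for (g in need) {
    # nan-Euclidean distance from gene g to all others
    co <- obs & rep(obs[g, ], each = nrow(m))  # co-observed indicator
    diffs <- sweep(m, 2L, m[g, ], "-")
    diffs[!co] <- 0
    n_co <- rowSums(co)
    d2 <- rowSums(diffs^2)
    d <- sqrt(n_samp / pmax(n_co, 1L) * d2)
    d[n_co == 0L] <- Inf
    d[g] <- Inf
    for (s in which(!obs[g, ])) {
      cand <- which(obs[, s] & is.finite(d))
      if (length(cand) < k) {
        stop("fewer than k=", k, " genes observed in sample '",
             colnames(m)[s], "' to impute gene '", rownames(m)[g], "'")
      }
      nb <- cand[order(d[cand], cand)[seq_len(k)]]
      out[g, s] <- mean(m[nb, s])
    }
  }
  out
}

#' Z-score each gene across samples
#'
#' Centres and scales every row to mean 0, SD 1, using the population
#' standard deviation (divisor `n`). Constant rows map to all zeros: such
#' genes carry no differential signal and can never pass SNR screening.
#'
#' @param m Complete numeric matrix (no `NA`s).
#' @return Matrix of the same shape.
#' @export
normalize_per_gene <- function(m) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("normalize_per_gene requires a complete matrix; impute first")
  mu <- rowMeans(m)
  cen <- m - mu
  s <- sqrt(rowMeans(cen^2))
  keep <- s > 0
  cen[keep, ] <- cen[keep, , drop = FALSE] / s[keep]
  cen[!keep, ] <- 0
  cen
}

#' Read a two-column edge list into an undirected gene network
#'
#' Accepts whitespace- or tab-separated files; extra columns (e.g. STRING
#' confidence scores) are ignored. Self-loops are dropped with a warning
#' and duplicate edges (in either orientation) collapsed.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::graph] with gene IDs as vertex
#'   names.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("empty edge list: ", path)
    return(igraph::make_empty_graph(directed = FALSE))
  }
  parts <- strsplit(lines, "[\t ]+")
  short <- which(lengths(parts) < 2L)
  if (length(short) > 0L) {
    stop("malformed edge list: line ", short[1L], " has fewer than two fields")
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  loops <- a == b
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s) from edge list")
    a <- a[!loops]; b <- b[!loops]
  }
  if (length(a) == 0L) {
    warning("edge list contains only self-loops: ", path)
    return(igraph::make_empty_graph(directed = FALSE))
  }
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a two-column TSV edge list
#' @param net An igraph network with named vertices.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reconcile a gene network with an expression matrix
#'
#' Restricts the network to genes present in the matrix, drops
#' isolated vertices, and subsets the matrix to the genes that remain
#' connected. Genes absent from either side are silently intersected;
#' counts are reported via `message()`.
#'
#' @param net Undirected igraph network.
#' @param m Expression matrix (genes in rows).
#' @return List with elements `network` and `matrix`, mutually consistent.
#' @export
prune_isolated_genes <- function(net, m) {
  common <- intersect(igraph::V(net)$name, rownames(m))
  g <- igraph::induced_subgraph(net, common)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  if (igraph::ecount(g) == 0L) {
    stop("no network edges remain after intersecting with the expression matrix; nothing to screen")
  }
  keep <- igraph::V(g)$name
  message(sprintf("network/matrix reconciliation: %d genes retained (%d network-only, %d matrix-only or isolated dropped)",
                  length(keep), igraph::vcount(net) - length(common),
                  nrow(m) - length(keep)))
  list(network = g, matrix = m[keep, , drop = FALSE])
}

#' Write biclusters as TSV (and optionally JSON)
#'
#' One row per bicluster: `cluster_id`, `avg_snr`, `n_genes`, `n_samples`,
#' `gene_ids` and `sample_ids` (semicolon-joined).
#'
#' @param clusters List of biclusters (see [new_bicluster()]).
#' @param path Output TSV path.
#' @param json_path Optional path for a JSON variant.
#' @export
write_biclusters <- function(clusters, path, json_path = NULL) {
  df <- data.frame(
    cluster_id = seq_along(clusters),
    avg_snr = vapply(clusters, function(b) b$avg_snr, 0),
    n_genes = vapply(clusters, function(b) length(b$genes), 0L),
    n_samples = vapply(clusters, function(b) length(b$samples), 0L),
    gene_ids = vapply(clusters, function(b) paste(b$genes, collapse = ";"), ""),
    sample_ids = vapply(clusters, function(b) paste(b$samples, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      lapply(seq_along(clusters), function(i) {
        b <- clusters[[i]]
        list(cluster_id = i, avg_snr = b$avg_snr,
             genes = b$genes, samples = b$samples)
      }),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read biclusters written by [write_biclusters()]
#' @param path TSV path.
#' @param m Optional expression matrix used to recompute `avg_snr`.
#' @return List of biclusters.
#' @export
read_biclusters <- function(path, m = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("integer", "numeric", "integer", "integer",
                                  "character", "character"))
  lapply(seq_len(nrow(df)), function(i) {
    genes <- strsplit(df$gene_ids[i], ";", fixed = TRUE)[[1L]]
    samples <- strsplit(df$sample_ids[i], ";", fixed = TRUE)[[1L]]
    snr <- if (!is.null(m)) set_snr(genes, samples, m) else df$avg_snr[i]
    new_bicluster(genes, samples, snr)
  })
}
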