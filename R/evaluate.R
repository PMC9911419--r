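#' Cell-level Jaccard similarity of two biclusters
#'
#' Jaccard coefficient of the (gene, sample) cell sets:
#' `|cells(a) n cells(b)| / |cells(a) u cells(b)|` with
#' `cells(X) = genes(X) x samples(X)`. Scoring cells rather than genes
#' alone makes sample accuracy count.
#'
#' @param a,b Biclusters or planted modules (lists with `genes` and
#'   `samples`).
#' @return Value in [0, 1].
#' @export
cell_jaccard <- function(a, b) {
  na <- length(a$genes) * length(a$samples)
  nb <- length(b$genes) * length(b$samples)
  if (na + nb == 0L) stop("both cell sets empty")
  ig <- length(intersect(a$genes, b$genes))
  is <- length(intersect(a$samples, b$samples))
  inter <- ig * is
  inter / (na + nb - inter)
}

#' Score recovered biclusters against planted ground truth
#'
#' For each true module the best cell-level Jaccard over the found
#' clusters is taken; *recovery* is the mean of these best matches (the
#' headline score), *relevance* the dual mean over found clusters of
#' their best match to truth. Per-size-group means (grouped by the true
#' module's gene count) support size-stratified summaries.
#'
#' @param found List of biclusters (may be empty: all scores 0).
#' @param truth Non-empty list of planted modules.
#' @return A list of class `evaluation_report` with elements
#'   `per_module` (best Jaccard per true module), `recovery`,
#'   `relevance`, `group_means` (named by gene count).
#' @export
recovery_score <- function(found, truth) {
  stopifnot(length(truth) >= 1L)
  per_module <- vapply(truth, function(tm) {
    if (length(found) == 0L) return(0)
    max(vapply(found, cell_jaccard, 0, b = tm))
  }, 0)
  relevance <- if (length(found) == 0L) 0 else
    mean(vapply(found, function(f) {
      max(vapply(truth, cell_jaccard, 0, b = f))
    }, 0))
  sizes <- vapply(truth, function(tm) length(tm$genes), 0L)
  group_means <- tapply(per_module, sizes, mean)
  structure(list(per_module = per_module,
                 recovery = mean(per_module),
                 relevance = relevance,
                 group_means = group_means),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation: recovery %.4f, relevance %.4f over %d true modules>\n",
              x$recovery, x$relevance, length(x$per_module)))
  invisible(x)
}

#' Import biclusters produced by an external tool
#'
#' Supported formats: `"bicluster-tsv"` (this package's own TSV layout,
#' see [write_biclusters()]) and `"triplet-list"` (rows of
#' `cluster_id <TAB> gene_id <TAB> sample_id`). When `universe` is given,
#' unknown gene or sample IDs raise an error listing the offenders;
#' when `m` is given, `avg_snr` is recomputed, otherwise it is 0 for
#' triplet input.
#'
#' @param path Input file.
#' @param format `"bicluster-tsv"` or `"triplet-list"`.
#' @param universe Optional list with `genes` and `samples` vectors.
#' @param m Optional expression matrix for SNR recomputation.
#' @return List of biclusters.
#' @export
import_external_result <- function(path, format = c("bicluster-tsv", "triplet-list"),
                                   universe = NULL, m = NULL) {
  format <- match.arg(format)
  if (file.size(path) == 0L) {
    warning("empty result file: ", path)
    return(list())
  }
  clusters <- if (format == "bicluster-tsv") {
    read_biclusters(path, m)
  } else {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("cluster_id", "gene_id", "sample_id"),
                     stringsAsFactors = FALSE)
    lapply(split(df, df$cluster_id), function(d) {
      genes <- sort(unique(d$gene_id))
      samples <- sort(unique(d$sample_id))
      snr <- if (!is.null(m)) set_snr(genes, samples, m) else 0
      new_bicluster(genes, samples, snr)
    })
  }
  if (!is.null(universe)) {
    for (b in clusters) {
      badg <- setdiff(b$genes, universe$genes)
      bads <- setdiff(b$samples, universe$samples)
      if (length(badg) || length(bads)) {
        stop("imported cluster references unknown IDs: ",
             paste(c(badg, bads), collapse = ", "))
      }
    }
  }
  unname(clusters)
}

#' Write an evaluation report as JSON and TSV
#' @param report An `evaluation_report`.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @export
write_evaluation_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(recovery = report$recovery,
                              relevance = report$relevance,
                              per_module = report$per_module,
                              group_means = as.list(report$group_means)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(module = seq_along(report$per_module),
                     best_jaccard = report$per_module)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
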