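# Localization index against the cytoplasmic reference and temporal clustering.

#' Localization index
#'
#' `LI_g = log2(efficiency_compartment_g / efficiency_cytoplasm_g)` where
#' efficiency is `edit_count / read_count` per gene. Positive values mean
#' enrichment in the target compartment relative to the cytoplasm.
#'
#' @param compartment,cytoplasm Per-gene profiles ([gene_edit_counts()]),
#'   matched by `gene_id`.
#' @param policy Zero-edit handling: `"exclude"` (default; genes with zero
#'   edits in either sample are excluded and reported) or `"pseudocount"`
#'   (adds `pseudocount` to both edit counts).
#' @param pseudocount Pseudocount for the `"pseudocount"` policy (default 0.5).
#' @return data.frame with columns `gene_id`, `efficiency_compartment`,
#'   `efficiency_cytoplasm`, `li`. Excluded genes are reported in the
#'   `excluded` attribute as a data.frame of `gene_id` and `reason`
#'   (`"zero_reads"` or `"zero_edits"`).
#' @export
localization_index <- function(compartment, cytoplasm,
                               policy = c("exclude", "pseudocount"),
                               pseudocount = 0.5) {
  policy <- match.arg(policy)
  m <- merge(compartment[, c("gene_id", "edit_count", "read_count")],
             cytoplasm[, c("gene_id", "edit_count", "read_count")],
             by = "gene_id", suffixes = c("_c", "_cyt"))
  excluded <- data.frame(gene_id = character(0), reason = character(0))
  zero_reads <- m$read_count_c == 0 | m$read_count_cyt == 0
  if (any(zero_reads)) {
    excluded <- rbind(excluded, data.frame(gene_id = m$gene_id[zero_reads],
                                           reason = "zero_reads"))
    m <- m[!zero_reads, , drop = FALSE]
  }
  if (policy == "pseudocount") {
    m$edit_count_c <- m$edit_count_c + pseudocount
    m$edit_count_cyt <- m$edit_count_cyt + pseudocount
  } else {
    zero_edits <- m$edit_count_c == 0 | m$edit_count_cyt == 0
    if (any(zero_edits)) {
      excluded <- rbind(excluded, data.frame(gene_id = m$gene_id[zero_edits],
                                             reason = "zero_edits"))
      m <- m[!zero_edits, , drop = FALSE]
    }
  }
  out <- data.frame(gene_id = m$gene_id,
                    efficiency_compartment = m$edit_count_c / m$read_count_c,
                    efficiency_cytoplasm = m$edit_count_cyt / m$read_count_cyt)
  out$li <- log2(out$efficiency_compartment / out$efficiency_cytoplasm)
  attr(out, "excluded") <- excluded
  out
}

#' Row-wise z-score standardization
#'
#' Centers and scales each row to mean 0 and SD 1 (n-1 denominator). Constant
#' rows have no defined z-score and are excluded.
#'
#' @param m Numeric matrix (genes x timepoints), at least 2 columns.
#' @return The standardized matrix; excluded row names are reported in the
#'   `excluded` attribute.
#' @export
zscore_rows <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2)
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  out <- m[!constant, , drop = FALSE]
  out <- (out - rowMeans(out)) / apply(out, 1, stats::sd)
  attr(out, "excluded") <- rownames(m)[constant]
  out
}

#' UPGMA clustering on correlation distance
#'
#' Computes pairwise distances `d = 1 - r` between rows (Pearson by default),
#' merges by average linkage (UPGMA) and cuts the tree into `k` flat clusters.
#'
#' @param m Numeric matrix (genes x timepoints), no constant rows.
#' @param k Number of flat clusters.
#' @param cor_method Correlation for the distance (default `"pearson"`).
#' @return A list of class `upgma_clust` with components `hclust`, `labels`
#'   (named cluster assignment), `k` and `dist`.
#' @export
upgma_cluster <- function(m, k, cor_method = "pearson") {
  stopifnot(is.matrix(m), nrow(m) >= 2, k >= 1, k <= nrow(m))
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    fail("constant rows have no correlation distance: %s",
         paste(rownames(m)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(m), method = cor_method))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, labels = stats::cutree(hc, k = k), k = k,
                 dist = d),
            class = "upgma_clust")
}

#' @export
print.upgma_clust <- function(x, ...) {
  cat(sprintf("UPGMA clustering: %d leaves cut into %d clusters (sizes: %s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Leaf names are the row names of the clustered matrix; branch lengths are
#' merge-height differences.
#'
#' @param x An `upgma_clust` object.
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(x, path) {
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
}

#' Per-cluster mean trajectories
#'
#' @param m Standardized matrix (genes x timepoints).
#' @param labels Cluster labels covering all rows (named or positional).
#' @return data.frame with columns `cluster`, `timepoint`, `mean`, `sd`, `n`.
#' @export
cluster_trajectories <- function(m, labels) {
  if (!is.null(names(labels))) labels <- labels[rownames(m)]
  if (length(labels) != nrow(m) || anyNA(labels)) {
    fail("labels must cover every row of the matrix")
  }
  tp <- colnames(m)
  if (is.null(tp)) tp <- as.character(seq_len(ncol(m)))
  pieces <- lapply(sort(unique(labels)), function(cl) {
    sub <- m[labels == cl, , drop = FALSE]
    data.frame(cluster = cl, timepoint = tp,
               mean = colMeans(sub),
               sd = apply(sub, 2, stats::sd),
               n = nrow(sub))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
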