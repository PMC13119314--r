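# Detained-intron quantification: intron coverage over flanking exon coverage.

#' Per-cell detained-intron ratio
#'
#' For intron k of a gene's designated transcript, the ratio of the intron's
#' mean per-base coverage to the average of the mean coverages of the
#' immediately upstream and downstream exons (exons k and k+1 in transcript
#' order). The ratio is scale-invariant per cell, so per-cell sequencing depth
#' cancels.
#'
#' @param cov Feature-coverage data.frame with columns `cell_id`, `gene_id`,
#'   `feature` (`"intron_k"`/`"exon_k"`), `mean_coverage`.
#' @param gene_id Gene to quantify.
#' @param intron_index Intron k (1-based, transcript order).
#' @param models Optional `transcript_models`; when supplied, `intron_index`
#'   is validated against the gene's designated transcript.
#' @return data.frame with columns `cell_id`, `ratio`, `defined`. Cells whose
#'   flanking exons both have zero coverage get `defined = FALSE` and an `NA`
#'   ratio.
#' @export
intron_ratio <- function(cov, gene_id, intron_index, models = NULL) {
  stopifnot(intron_index >= 1)
  if (!is.null(models)) {
    tr <- models$transcripts
    tx <- tr$transcript_id[tr$gene_id == gene_id & tr$designated]
    if (!length(tx)) fail("unknown gene_id: %s", gene_id)
    n_introns <- tr$n_exons[tr$transcript_id == tx] - 1
    if (intron_index > n_introns) {
      fail("intron index %d out of range for %s (%d introns)",
           intron_index, gene_id, n_introns)
    }
  }
  cov <- cov[cov$gene_id == gene_id, , drop = FALSE]
  feats <- c(paste0("intron_", intron_index),
             paste0("exon_", intron_index),
             paste0("exon_", intron_index + 1))
  cells <- unique(cov$cell_id)
  get <- function(cell, feat) {
    v <- cov$mean_coverage[cov$cell_id == cell & cov$feature == feat]
    if (!length(v)) fail("missing feature %s for cell %s", feat, cell)
    if (v < 0) fail("negative coverage for %s in cell %s", feat, cell)
    v[1]
  }
  out <- data.frame(cell_id = cells, ratio = NA_real_, defined = FALSE)
  for (i in seq_along(cells)) {
    intron <- get(cells[i], feats[1])
    up <- get(cells[i], feats[2])
    dn <- get(cells[i], feats[3])
    flank <- (up + dn) / 2
    if (flank > 0) {
      out$ratio[i] <- intron / flank
      out$defined[i] <- TRUE
    }
  }
  out
}

# Mann-Whitney U from midranks: number of (a, b) pairs with a > b, ties 1/2.
rank_sum_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Compare intron ratios between two cell groups
#'
#' Two-sided Mann-Whitney U test on per-cell ratios, plus the fold change of
#' group medians. For small samples the p-value is the exact permutation tail
#' of `|U - n1 n2 / 2|` over all group reassignments (correct under ties);
#' larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param ratios Numeric per-cell ratios (undefined cells already removed).
#' @param labels Two-level factor/character grouping of the same length.
#' @param min_n Minimum defined ratios per group (default 3).
#' @param exact_max Use exact permutation when `choose(n, n1)` is at most this
#'   (default 2e5).
#' @param median_pseudocount Added to both medians when either is 0 before the
#'   fold change; `NULL` (default) uses half the smallest positive ratio.
#' @return list with `statistic` (U for the first group level), `p.value`,
#'   `method`, `medians`, `fold_change` (first level over second) and
#'   `pseudocount` (0 when unused).
#' @export
compare_groups <- function(ratios, labels, min_n = 3, exact_max = 2e5,
                           median_pseudocount = NULL) {
  ok <- is.finite(ratios)
  ratios <- ratios[ok]
  labels <- as.character(labels[ok])
  lv <- unique(labels)
  if (length(lv) != 2) fail("labels must have exactly two groups")
  x <- ratios[labels == lv[1]]
  y <- ratios[labels == lv[2]]
  if (length(x) < min_n || length(y) < min_n) {
    fail("need at least %d defined ratios per group (got %d and %d)",
         min_n, length(x), length(y))
  }
  n1 <- length(x); n2 <- length(y)
  u <- rank_sum_u(x, y)
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= exact_max) {
    pool <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(i) rank_sum_u(pool[i], pool[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    method <- "normal approximation"
  }
  med <- c(stats::median(x), stats::median(y))
  eps <- 0
  if (any(med == 0)) {
    eps <- if (!is.null(median_pseudocount)) median_pseudocount else {
      pos <- ratios[ratios > 0]
      if (length(pos)) min(pos) / 2 else 1
    }
  }
  list(statistic = u, p.value = p, method = method,
       medians = stats::setNames(med, lv),
       fold_change = (med[1] + eps) / (med[2] + eps),
       pseudocount = eps)
}
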