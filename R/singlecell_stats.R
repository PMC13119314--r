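# Single-cell QC, detection-rate heterogeneity and the expression-matched
# shuffling null with chi-square goodness-of-fit.

#' Paired single-cell edit and expression matrices
#'
#' @param edits Cell x gene matrix of nonnegative integer edit counts.
#' @param expr Cell x gene TPM matrix with identical dimnames; row sums must
#'   be 1e6 within 1 percent.
#' @param reads Optional cell x gene unique-read-count matrix (used for the
#'   gene-retention step of [qc_filter_cells()]).
#' @param phase Optional per-cell phase labels (`G1`/`S`/`G2M`).
#' @param editing_ratio Optional per-cell chemistry-consistency fraction
#'   (fraction of candidate SNVs matching the reporter chemistry), used by the
#'   NES-mode QC fences.
#' @param validate Check invariants (default TRUE).
#' @return A list of class `cell_matrices`.
#' @export
cell_matrices <- function(edits, expr, reads = NULL, phase = NULL,
                          editing_ratio = NULL, validate = TRUE) {
  if (validate) {
    stopifnot(is.matrix(edits), is.matrix(expr),
              all(dim(edits) == dim(expr)))
    if (!identical(dimnames(edits), dimnames(expr))) {
      fail("edits and expr must share dimnames (cells x genes)")
    }
    if (any(edits < 0) || any(edits != round(edits))) {
      fail("edit counts must be nonnegative integers")
    }
    rs <- rowSums(expr)
    if (any(abs(rs - 1e6) > 1e4)) {
      fail("TPM rows must sum to 1e6 within 1%%; worst cell: %s",
           rownames(expr)[which.max(abs(rs - 1e6))])
    }
    if (!is.null(reads)) stopifnot(all(dim(reads) == dim(edits)))
    if (!is.null(phase)) stopifnot(length(phase) == nrow(edits))
    if (!is.null(editing_ratio)) stopifnot(length(editing_ratio) == nrow(edits))
  }
  structure(list(edits = edits, expr = expr, reads = reads, phase = phase,
                 editing_ratio = editing_ratio),
            class = "cell_matrices")
}

#' @export
print.cell_matrices <- function(x, ...) {
  cat(sprintf("cell_matrices: %d cells x %d genes%s%s\n",
              nrow(x$edits), ncol(x$edits),
              if (!is.null(x$reads)) ", with read support" else "",
              if (!is.null(x$phase)) ", with phase labels" else ""))
  invisible(x)
}

subset_cells <- function(m, keep_cells, keep_genes = NULL) {
  if (is.null(keep_genes)) keep_genes <- rep(TRUE, ncol(m$edits))
  cell_matrices(m$edits[keep_cells, keep_genes, drop = FALSE],
                m$expr[keep_cells, keep_genes, drop = FALSE],
                reads = if (!is.null(m$reads))
                  m$reads[keep_cells, keep_genes, drop = FALSE],
                phase = if (!is.null(m$phase)) m$phase[keep_cells],
                editing_ratio = if (!is.null(m$editing_ratio))
                  m$editing_ratio[keep_cells],
                validate = FALSE)
}

tukey_fences <- function(x, k) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(low = q[1] - k * iqr, high = q[2] + k * iqr)
}

#' Single-cell quality control
#'
#' Applies, in order: (1) gene retention — genes supported by at least
#' `min_gene_reads` unique reads in at least `min_gene_cells` cells are kept
#' (requires the `reads` matrix; skipped with a message otherwise, on the
#' assumption the gene set is pre-filtered); (2) removal of cells expressing
#' fewer than `min_genes` genes (a gene is "expressed" when TPM > 0); (3)
#' editing-activity outlier removal. In `"NES"` mode a cell is removed when
#' its chemistry-consistency ratio or its edited-gene count falls outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`; in `"ERM"` mode when its edited-gene count
#' is below `erm_floor` or above `Q3 + 3 IQR`. Quartiles use linear
#' interpolation (type 7).
#'
#' @param m A [cell_matrices()] object.
#' @param mode `"NES"` (cytoplasmic reporter) or `"ERM"`.
#' @param min_genes Detected-gene floor per cell (default 9000).
#' @param min_gene_reads,min_gene_cells Gene-retention support thresholds
#'   (defaults 5 reads in 2 cells).
#' @param edited_min_edits A gene counts as edited in a cell when it carries
#'   at least this many edits (default 3).
#' @param nes_k,erm_k IQR multipliers (1.5 and 3).
#' @param erm_floor Minimum edited genes per cell in ERM mode (default 200).
#' @return list with `matrices` (passing cells, retained genes) and `qc`
#'   (one row per input cell: `cell_id`, `detected_genes`, `edited_genes`,
#'   `total_edits`, `editing_ratio`, `pass`, `reason`).
#' @export
qc_filter_cells <- function(m, mode = c("NES", "ERM"), min_genes = 9000,
                            min_gene_reads = 5, min_gene_cells = 2,
                            edited_min_edits = 3, nes_k = 1.5, erm_k = 3,
                            erm_floor = 200) {
  mode <- match.arg(mode)
  if (!is.null(m$reads)) {
    keep_genes <- colSums(m$reads >= min_gene_reads) >= min_gene_cells
    m <- subset_cells(m, rep(TRUE, nrow(m$edits)), keep_genes)
  } else {
    message("no read-support matrix: gene retention step skipped")
  }
  qc <- data.frame(cell_id = rownames(m$edits),
                   detected_genes = rowSums(m$expr > 0),
                   edited_genes = rowSums(m$edits >= edited_min_edits),
                   total_edits = rowSums(m$edits),
                   editing_ratio = if (!is.null(m$editing_ratio))
                     m$editing_ratio else NA_real_,
                   pass = TRUE, reason = "", stringsAsFactors = FALSE)

  qc$pass[qc$detected_genes < min_genes] <- FALSE
  qc$reason[!qc$pass] <- "min_genes"

  surv <- which(qc$pass)
  if (length(surv) < 4) fail("fewer than 4 cells reach the IQR step; quartiles unstable")
  if (mode == "NES") {
    eg <- tukey_fences(qc$edited_genes[surv], nes_k)
    out_eg <- qc$edited_genes[surv] < eg["low"] | qc$edited_genes[surv] > eg["high"]
    out_er <- rep(FALSE, length(surv))
    if (!anyNA(qc$editing_ratio[surv])) {
      er <- tukey_fences(qc$editing_ratio[surv], nes_k)
      out_er <- qc$editing_ratio[surv] < er["low"] |
        qc$editing_ratio[surv] > er["high"]
    }
    qc$pass[surv][out_er & !out_eg] <- FALSE
    qc$reason[surv][out_er & !out_eg] <- "ratio_iqr"
    qc$pass[surv][out_eg] <- FALSE
    qc$reason[surv][out_eg] <- "edited_genes_iqr"
  } else {
    low <- qc$edited_genes[surv] < erm_floor
    fence <- tukey_fences(qc$edited_genes[surv], erm_k)["high"]
    high <- qc$edited_genes[surv] > fence
    qc$pass[surv][low] <- FALSE
    qc$reason[surv][low] <- "min_edited_genes"
    qc$pass[surv][high & !low] <- FALSE
    qc$reason[surv][high & !low] <- "edited_genes_iqr_high"
  }
  list(matrices = subset_cells(m, qc$pass), qc = qc)
}

#' Per-gene detection rates
#'
#' Fraction of (passing) cells in which a gene carries at least `min_edits`
#' editing events.
#'
#' @param m A [cell_matrices()] object (passing cells only).
#' @param min_edits Edit threshold (default 3).
#' @return Named numeric vector of rates in `[0, 1]`, one per gene.
#' @export
detection_rates <- function(m, min_edits = 3) {
  colMeans(m$edits >= min_edits)
}

#' Bin detection rates into 10 percent intervals
#'
#' Bins are `[0, 0.1), [0.1, 0.2), ..., [0.9, 1.0]` (top bin closed). Genes
#' with rate exactly 0 are excluded from the histogram and reported in the
#' `zero_rate_genes` attribute, keeping the observed and shuffled supports
#' comparable.
#'
#' @param rates Named rates from [detection_rates()].
#' @param width Bin width (default 0.1).
#' @return data.frame with columns `bin_start`, `bin_end`, `count`;
#'   attribute `zero_rate_genes`.
#' @export
bin_rates <- function(rates, width = 0.1) {
  stopifnot(all(rates >= 0 & rates <= 1))
  breaks <- seq(0, 1, by = width)
  nb <- length(breaks) - 1
  zero <- rates == 0
  idx <- findInterval(rates[!zero], breaks, rightmost.closed = TRUE)
  out <- data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
                    count = tabulate(idx, nbins = nb))
  attr(out, "zero_rate_genes") <- names(rates)[zero]
  out
}

#' Expression-matched shuffling null for detection rates
#'
#' For each shuffle and each cell, the cell's observed edit total is randomly
#' reassigned across genes by a multinomial draw with probabilities
#' proportional to that cell's TPM. Genes accumulating at least `min_edits`
#' simulated edits in at least one cell are retained; detection rates are
#' computed and binned as for the observed data. Per-bin mean and SD are
#' summarized over shuffles.
#'
#' @param m A [cell_matrices()] object.
#' @param n_shuffles Number of independent shuffles (default 3).
#' @param min_edits Edit threshold (default 3).
#' @param seed Seed; each shuffle uses a deterministic substream.
#' @param width Bin width (default 0.1).
#' @return list with `bins` (data.frame `bin_start`, `bin_end`,
#'   `shuffled_mean`, `shuffled_sd`), `per_shuffle` (bins x shuffles count
#'   matrix) and `n_shuffles`.
#' @export
shuffle_null <- function(m, n_shuffles = 3, min_edits = 3, seed = 1,
                         width = 0.1) {
  totals <- rowSums(m$edits)
  rs <- rowSums(m$expr)
  if (any(rs <= 0)) {
    fail("cell with zero total TPM: %s", rownames(m$expr)[which(rs <= 0)[1]])
  }
  n_cells <- nrow(m$edits)
  per_shuffle <- vapply(seq_len(n_shuffles), function(s) {
    with_stream(seed, paste0("shuffle", s), {
      sim <- vapply(seq_len(n_cells), function(c) {
        as.numeric(stats::rmultinom(1, totals[c], m$expr[c, ] / rs[c]))
      }, numeric(ncol(m$edits)))
      sim <- t(sim)  # cells x genes
      keep <- colSums(sim >= min_edits) >= 1
      r <- colMeans(sim[, keep, drop = FALSE] >= min_edits)
      names(r) <- colnames(m$edits)[keep]
      bin_rates(r, width = width)$count
    })
  }, numeric(round(1 / width)))
  bins <- bin_rates(stats::setNames(numeric(0), character(0)), width = width)
  bins$count <- NULL
  bins$shuffled_mean <- rowMeans(per_shuffle)
  bins$shuffled_sd <- apply(per_shuffle, 1, stats::sd)
  list(bins = bins, per_shuffle = per_shuffle, n_shuffles = n_shuffles)
}

#' Chi-square goodness-of-fit between observed and expected histograms
#'
#' Expected counts are rescaled so their total matches the observed total;
#' bins with expected count below 5 are merged into their right neighbor
#' (the last bin merges leftward) until the validity condition holds.
#'
#' @param observed,expected Numeric count vectors of equal length.
#' @param min_expected Merge threshold (default 5).
#' @return list with `statistic` (`sum((O-E)^2/E)`), `df`
#'   (`bins used - 1`), `p.value`, and the merged `observed`/`expected`
#'   vectors plus `n_merged`.
#' @export
chisq_gof <- function(observed, expected, min_expected = 5) {
  stopifnot(length(observed) == length(expected), sum(observed) > 0,
            sum(expected) > 0, all(observed >= 0), all(expected >= 0))
  expected <- expected / sum(expected) * sum(observed)
  n_merged <- 0L
  while (length(expected) > 1 && any(expected < min_expected)) {
    i <- which(expected < min_expected)[1]
    j <- if (i < length(expected)) i + 1L else i - 1L
    expected[j] <- expected[j] + expected[i]
    observed[j] <- observed[j] + observed[i]
    expected <- expected[-i]
    observed <- observed[-i]
    n_merged <- n_merged + 1L
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- if (df >= 1) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  list(statistic = stat, df = df, p.value = p,
       observed = observed, expected = expected, n_merged = n_merged)
}

#' Detection-rate heterogeneity test
#'
#' Convenience wrapper combining [detection_rates()], [bin_rates()],
#' [shuffle_null()] and [chisq_gof()] into one result.
#'
#' @inheritParams shuffle_null
#' @return list of class `detection_rate_result` with components `rates`,
#'   `bins` (observed counts plus shuffled mean/SD) and `chisq`.
#' @export
detection_rate_test <- function(m, n_shuffles = 3, min_edits = 3, seed = 1,
                                width = 0.1) {
  rates <- detection_rates(m, min_edits = min_edits)
  obs <- bin_rates(rates[rates > 0], width = width)
  null <- shuffle_null(m, n_shuffles = n_shuffles, min_edits = min_edits,
                       seed = seed, width = width)
  bins <- cbind(obs, null$bins[, c("shuffled_mean", "shuffled_sd")])
  chisq <- chisq_gof(bins$count, bins$shuffled_mean)
  structure(list(rates = rates, bins = bins, chisq = chisq,
                 n_shuffles = n_shuffles),
            class = "detection_rate_result")
}

#' @export
print.detection_rate_result <- function(x, ...) {
  cat(sprintf(
    "detection-rate heterogeneity: %d genes with rate > 0, %d shuffles\n",
    sum(x$bins$count), x$n_shuffles))
  cat(sprintf("chi-square = %.3f, df = %d, p = %.3g\n",
              x$chisq$statistic, x$chisq$df, x$chisq$p.value))
  invisible(x)
}

#' Per-bin overlap with a bulk-detected gene set
#'
#' For each detection-rate bin, the fraction of its genes present in the
#' bulk-detected set.
#'
#' @param rates Named detection rates (zero-rate genes are ignored).
#' @param bulk_gene_set Character vector of bulk-detected gene ids.
#' @param width Bin width (default 0.1).
#' @return data.frame with columns `bin_start`, `bin_end`, `n`,
#'   `overlap_fraction` (`NA` for empty bins).
#' @export
occurrence_overlap <- function(rates, bulk_gene_set, width = 0.1) {
  rates <- rates[rates > 0]
  breaks <- seq(0, 1, by = width)
  nb <- length(breaks) - 1
  idx <- findInterval(rates, breaks, rightmost.closed = TRUE)
  out <- data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1])
  out$n <- tabulate(idx, nbins = nb)
  out$overlap_fraction <- vapply(seq_len(nb), function(b) {
    g <- names(rates)[idx == b]
    if (!length(g)) NA_real_ else mean(g %in% bulk_gene_set)
  }, numeric(1))
  out
}
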