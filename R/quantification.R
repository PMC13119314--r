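# Gene-level editing quantification: EPM, ECPM, efficiency, metagene density
# and expression-binned summaries.

#' Per-gene editing profiles
#'
#' Sums editing occurrences per gene (multiple edits on one read counted
#' individually, so the per-event `alt_count` is the unit) and joins mapped
#' read counts. Genes present in the read table but without events get an
#' `edit_count` of 0.
#'
#' @param events Events as returned by [call_events()] (needs `gene_id` and
#'   `alt_count`).
#' @param per_gene_reads data.frame with columns `gene_id` and `read_count`.
#' @param sample_id Sample label stored in the profiles.
#' @return data.frame with columns `gene_id`, `sample_id`, `edit_count`,
#'   `read_count`, `efficiency` (`edit_count / read_count`, `NA` when
#'   `read_count` is 0). Pass the result to [ecpm()] to fill `ecpm`.
#' @export
gene_edit_counts <- function(events, per_gene_reads, sample_id = "sample") {
  if (!all(c("gene_id", "read_count") %in% names(per_gene_reads))) {
    fail("per_gene_reads must have columns gene_id, read_count")
  }
  missing <- setdiff(unique(events$gene_id), per_gene_reads$gene_id)
  if (length(missing)) {
    fail("events reference genes absent from the read table: %s",
         paste(missing, collapse = ", "))
  }
  ec <- tapply(events$alt_count, events$gene_id, sum)
  out <- data.frame(gene_id = per_gene_reads$gene_id,
                    sample_id = sample_id,
                    edit_count = as.numeric(ec[per_gene_reads$gene_id]),
                    read_count = per_gene_reads$read_count)
  out$edit_count[is.na(out$edit_count)] <- 0
  out$efficiency <- ifelse(out$read_count > 0,
                           out$edit_count / out$read_count, NA_real_)
  out
}

#' Editing counts per million (ECPM)
#'
#' `ecpm_g = edit_count_g / sum_i(edit_count_i) * 1e6` within one sample.
#' Gene length is deliberately not normalized: edit counts are
#' length-independent for a 3'-anchored reporter.
#'
#' @param profiles Profiles for a single sample ([gene_edit_counts()]).
#' @return The profiles with an `ecpm` column; `sum(ecpm)` is 1e6.
#' @export
ecpm <- function(profiles) {
  if (length(unique(profiles$sample_id)) > 1) {
    fail("ecpm() normalizes within one sample; got multiple sample_id values")
  }
  total <- sum(profiles$edit_count)
  if (total <= 0) fail("no edits in sample")
  profiles$ecpm <- profiles$edit_count / total * 1e6
  profiles
}

#' Editing sites per million mapped reads (EPM)
#'
#' Sample-level editing activity: distinct editing sites per million mapped
#' reads.
#'
#' @param total_edit_sites Number of distinct editing sites.
#' @param mapped_reads Total mapped reads in the sample.
#' @return EPM value.
#' @export
epm <- function(total_edit_sites, mapped_reads) {
  stopifnot(total_edit_sites >= 0)
  if (mapped_reads <= 0) fail("mapped_reads must be positive")
  total_edit_sites / mapped_reads * 1e6
}

#' Metagene edit density upstream of poly(A) sites
#'
#' Bins each event's distance from its transcript's poly(A) site toward the 5'
#' end (transcript coordinates, so strand is already resolved) and normalizes
#' the in-window histogram to sum 1. Events farther than `window` are counted
#' separately in the `n_beyond_window` attribute.
#'
#' @param events Events with `transcript_id` and `position`.
#' @param models A `transcript_models` object.
#' @param window Window size in nt upstream of the poly(A) site (default 1000).
#' @param bin Bin width in nt (default 50).
#' @return data.frame with columns `bin_start`, `bin_end`, `count`, `density`;
#'   attributes `n_beyond_window` and `n_total`.
#' @export
metagene_polyA_density <- function(events, models, window = 1000, bin = 50) {
  stopifnot(window > 0, bin > 0, window %% bin == 0)
  d <- rep(NA_real_, nrow(events))
  for (tx in unique(events$transcript_id)) {
    i <- events$transcript_id == tx
    L <- models$transcripts$tx_length[models$transcripts$transcript_id == tx]
    if (!length(L)) fail("unknown transcript_id: %s", tx)
    txpos <- tx_position(models, tx, events$position[i])
    if (anyNA(txpos)) fail("event outside the exons of transcript %s", tx)
    d[i] <- L - 1 - txpos
  }
  breaks <- seq(0, window, by = bin)
  inside <- d < window
  idx <- findInterval(d[inside], breaks)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  dens <- if (sum(counts) > 0) counts / sum(counts) else rep(0, length(counts))
  out <- data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
                    count = counts, density = dens)
  attr(out, "n_beyond_window") <- sum(!inside)
  attr(out, "n_total") <- length(d)
  out
}

#' Expression-binned summary of editing abundance
#'
#' Stratifies genes into `n_bins` equal-width bins along the log2 expression
#' axis and reports the per-bin mean and standard error of log2 editing
#' abundance. Genes at or below `min_log2_expr` (default 0, i.e. linear
#' expression of at most 1) are excluded first.
#'
#' @param x Per-gene log2 expression (e.g. log2 RPKM).
#' @param y Per-gene log2 editing abundance (e.g. log2 ECPM), same length.
#' @param n_bins Number of equal-width bins (default 10).
#' @param min_log2_expr Exclusion threshold on `x`; `NULL` disables it.
#' @return data.frame with columns `bin`, `x_lo`, `x_hi`, `n`, `mean`, `se`
#'   (`se` is sample SD with n-1 denominator over `sqrt(n)`). Empty bins are
#'   reported with `n = 0` and `NA` summaries.
#' @export
binned_expression_summary <- function(x, y, n_bins = 10, min_log2_expr = 0) {
  stopifnot(length(x) == length(y), n_bins >= 1)
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(min_log2_expr)) ok <- ok & x > min_log2_expr
  x <- x[ok]; y <- y[ok]
  if (!length(x)) fail("no genes left after expression filtering")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  out <- data.frame(bin = seq_len(n_bins),
                    x_lo = breaks[-length(breaks)], x_hi = breaks[-1])
  out$n <- vapply(seq_len(n_bins), function(b) sum(idx == b), integer(1))
  out$mean <- vapply(seq_len(n_bins), function(b) {
    if (out$n[b] > 0) mean(y[idx == b]) else NA_real_
  }, numeric(1))
  out$se <- vapply(seq_len(n_bins), function(b) {
    if (out$n[b] > 1) stats::sd(y[idx == b]) / sqrt(out$n[b])
    else if (out$n[b] == 1) 0 else NA_real_
  }, numeric(1))
  out
}
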