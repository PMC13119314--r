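# Strand-aware sequence contexts around editing sites and motif diagnostics.

#' Extract sequence contexts around editing sites
#'
#' Slices the `2*flank + 1`-mer centered on each edited base. Minus-strand
#' events are reverse-complemented so every context reads 5' to 3' in
#' transcript orientation; position 0 is the edited base, upstream positions
#' are negative. Events within `flank` of a contig end are excluded and
#' reported.
#'
#' @param genome A `Biostrings::DNAStringSet` (or path to a FASTA file).
#' @param events Events with columns `contig`, `position`, `strand`.
#' @param flank Nucleotides on each side (default 10).
#' @return A list of class `context_set` with components `flank`, `sequences`
#'   (character vector) and `freq` (position x base frequency matrix from
#'   [frequency_matrix()]); excluded event indices are in the `excluded`
#'   attribute.
#' @export
extract_context <- function(genome, events, flank = 10) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  bad <- setdiff(unique(events$contig), names(genome))
  if (length(bad)) fail("contig not in genome: %s", paste(bad, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(events$position >= lens[events$contig] | events$position < 0)) {
    fail("event position beyond contig length")
  }
  ok <- events$position - flank >= 0 &
    events$position + flank < lens[events$contig]
  ev <- events[ok, , drop = FALSE]
  seqs <- character(nrow(ev))
  for (ctg in unique(ev$contig)) {
    i <- ev$contig == ctg
    chr <- as.character(genome[[ctg]])
    seqs[i] <- substring(chr, ev$position[i] - flank + 1,
                         ev$position[i] + flank + 1)
  }
  minus <- ev$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  structure(list(flank = flank, sequences = seqs,
                 freq = frequency_matrix(seqs, flank = flank)),
            class = "context_set",
            excluded = unname(which(!ok)))
}

#' @export
print.context_set <- function(x, ...) {
  cat(sprintf("context_set: %d sequences of width %d (flank %d)\n",
              length(x$sequences), 2 * x$flank + 1, x$flank))
  invisible(x)
}

#' Position-specific nucleotide frequency matrix
#'
#' Columns of the underlying alignment (positions) each sum to 1. With a
#' background composition, per-position log2 enrichment is attached.
#'
#' @param contexts A `context_set` or character vector of equal-length
#'   sequences.
#' @param background Optional background: a named frequency vector over
#'   `A`,`C`,`G`,`T` (e.g. 3'-UTR composition) or `"uniform"`.
#' @param flank Used to label positions `-flank..flank`; inferred from a
#'   `context_set`.
#' @return Matrix (positions x `A`,`C`,`G`,`T`) of frequencies, rownames the
#'   center-relative positions. When `background` is given, the
#'   `enrichment` attribute holds `log2(freq / background)`.
#' @export
frequency_matrix <- function(contexts, background = NULL, flank = NULL) {
  if (inherits(contexts, "context_set")) {
    if (is.null(flank)) flank <- contexts$flank
    contexts <- contexts$sequences
  }
  if (!length(contexts)) fail("empty context set")
  w <- unique(nchar(contexts))
  if (length(w) != 1) fail("contexts must have equal length")
  if (is.null(flank)) flank <- (w - 1) %/% 2
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(contexts))
  counts <- matrix(0, nrow = w, ncol = 4, dimnames = list(NULL, BASES))
  for (b in intersect(rownames(cm), BASES)) counts[, b] <- cm[b, ]
  freq <- counts / rowSums(counts)
  rownames(freq) <- as.character(seq_len(w) - flank - 1)
  if (!is.null(background)) {
    if (identical(background, "uniform")) {
      background <- stats::setNames(rep(0.25, 4), BASES)
    }
    stopifnot(all(BASES %in% names(background)))
    attr(freq, "enrichment") <-
      log2(sweep(freq, 2, unlist(background[BASES]), "/"))
  }
  freq
}

#' Per-sequence adenosine content
#'
#' Fraction of A among non-N bases of each sequence, with an optional
#' two-group Mann-Whitney comparison (the statistic used to show that
#' poly(A)-binding reporters capture A-rich sequence).
#'
#' @param sequences Character vector over `A`,`C`,`G`,`T`,`N`.
#' @param groups Optional two-level grouping of the same length.
#' @return Numeric vector of fractions in `[0, 1]`. With `groups`, the
#'   `test` attribute holds the [stats::wilcox.test()] result.
#' @export
adenosine_content <- function(sequences, groups = NULL) {
  frac <- vapply(sequences, function(s) {
    b <- strsplit(toupper(s), "")[[1]]
    b <- b[b %in% BASES]
    if (!length(b)) return(NA_real_)
    mean(b == "A")
  }, numeric(1), USE.NAMES = FALSE)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(sequences))
    g <- factor(groups)
    if (nlevels(g) != 2) fail("groups must have exactly two levels")
    attr(frac, "test") <- stats::wilcox.test(frac[g == levels(g)[1]],
                                             frac[g == levels(g)[2]],
                                             exact = FALSE)
  }
  frac
}
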