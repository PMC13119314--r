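# Transcript models, coordinate conventions and flat-file IO.
#
# All internal coordinates are 0-based half-open. GTF is converted on read and
# write; BED output is emitted 0-based half-open as the format requires.

#' Construct a set of transcript models
#'
#' A `transcript_models` object anchors every positional computation in the
#' package. It holds one row per transcript plus an exon table in 0-based
#' half-open genomic coordinates.
#'
#' @param transcripts data.frame with columns `gene_id`, `transcript_id`,
#'   `contig`, `strand` (`"+"`/`"-"`), `biotype`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @param mito_contigs Contig names treated as mitochondrial; genes on them get
#'   biotype `"mito"` (a reporting category only).
#' @return An object of class `transcript_models` with components
#'   `transcripts` (including derived `polyA_site`, `tx_length`, `n_exons` and
#'   a logical `designated` marking the longest transcript per gene) and
#'   `exons` (sorted, with `exon_rank` in genomic order).
#' @details The poly(A) site is the transcript's 3'-terminal base: the last
#'   exon end minus one on the plus strand, the first exon start on the minus
#'   strand. Positional analyses use one designated transcript per gene,
#'   chosen as the longest; use [designate_transcripts()] to override.
#' @export
transcript_models <- function(transcripts, exons,
                              mito_contigs = c("chrM", "MT")) {
  req <- c("gene_id", "transcript_id", "contig", "strand", "biotype")
  if (!all(req %in% names(transcripts))) {
    fail("transcripts table must have columns: %s", paste(req, collapse = ", "))
  }
  if (!all(c("transcript_id", "start", "end") %in% names(exons))) {
    fail("exons table must have columns transcript_id, start, end")
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    dup <- unique(transcripts$transcript_id[duplicated(transcripts$transcript_id)])
    fail("duplicate transcript_id: %s", paste(dup, collapse = ", "))
  }
  if (!all(transcripts$strand %in% c("+", "-"))) fail("strand must be '+' or '-'")
  missing_ex <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(missing_ex)) {
    fail("transcript with zero exons: %s", paste(missing_ex, collapse = ", "))
  }
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), c("transcript_id", "start", "end")]
  if (any(exons$end <= exons$start)) fail("exon with end <= start")
  by_tx <- split(exons, exons$transcript_id)
  for (tx in names(by_tx)) {
    e <- by_tx[[tx]]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      fail("overlapping exons in transcript %s", tx)
    }
  }
  exons$exon_rank <- unlist(lapply(by_tx[unique(exons$transcript_id)],
                                   function(e) seq_len(nrow(e))),
                            use.names = FALSE)
  lens <- vapply(by_tx, function(e) sum(e$end - e$start), numeric(1))
  firsts <- vapply(by_tx, function(e) min(e$start), numeric(1))
  lasts <- vapply(by_tx, function(e) max(e$end), numeric(1))
  tr <- transcripts
  tr$tx_length <- lens[tr$transcript_id]
  tr$n_exons <- vapply(by_tx, nrow, integer(1))[tr$transcript_id]
  tr$polyA_site <- ifelse(tr$strand == "+", lasts[tr$transcript_id] - 1,
                          firsts[tr$transcript_id])
  tr$biotype <- ifelse(tr$contig %in% mito_contigs, "mito", tr$biotype)
  obj <- structure(list(transcripts = tr, exons = exons), class = "transcript_models")
  designate_transcripts(obj)
}

#' Mark one designated transcript per gene
#'
#' @param models A `transcript_models` object.
#' @param rule `"longest"` (default) or a named character vector
#'   `gene_id -> transcript_id` selecting transcripts explicitly.
#' @return The models with an updated `designated` column.
#' @export
designate_transcripts <- function(models, rule = "longest") {
  tr <- models$transcripts
  if (is.character(rule) && length(rule) == 1 && rule == "longest") {
    ord <- order(tr$gene_id, -tr$tx_length, tr$transcript_id)
    chosen <- tr$transcript_id[ord][!duplicated(tr$gene_id[ord])]
  } else {
    chosen <- unname(rule[tr$gene_id])
  }
  tr$designated <- tr$transcript_id %in% chosen
  models$transcripts <- tr
  models
}

#' @export
print.transcript_models <- function(x, ...) {
  tr <- x$transcripts
  cat(sprintf("transcript_models: %d transcripts, %d genes, %d exons\n",
              nrow(tr), length(unique(tr$gene_id)), nrow(x$exons)))
  invisible(x)
}

#' Derive introns of a transcript
#'
#' Introns are the gaps between consecutive exons, 0-based half-open, indexed
#' in transcript (5' to 3') order: intron k separates exon k and exon k+1.
#'
#' @param models A `transcript_models` object.
#' @param transcript_id Transcript to query.
#' @return data.frame with columns `intron_index`, `start`, `end`.
#' @export
transcript_introns <- function(models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, ]
  if (!nrow(e)) fail("unknown transcript_id: %s", transcript_id)
  strand <- models$transcripts$strand[
    models$transcripts$transcript_id == transcript_id]
  n <- nrow(e)
  if (n < 2) {
    return(data.frame(intron_index = integer(0), start = numeric(0),
                      end = numeric(0)))
  }
  gaps <- data.frame(start = e$end[-n], end = e$start[-1])
  idx <- if (strand == "+") seq_len(n - 1) else rev(seq_len(n - 1))
  out <- data.frame(intron_index = idx, gaps)
  out[order(out$intron_index), ]
}

# Map genomic positions (0-based) to transcript coordinates (0-based from the
# 5' end) for a single transcript. Positions outside exons return NA.
tx_position <- function(models, transcript_id, pos) {
  e <- models$exons[models$exons$transcript_id == transcript_id, ]
  if (!nrow(e)) fail("unknown transcript_id: %s", transcript_id)
  strand <- models$transcripts$strand[
    models$transcripts$transcript_id == transcript_id]
  cum <- cumsum(c(0, e$end - e$start))
  L <- cum[length(cum)]
  idx <- findInterval(pos, e$start)
  inside <- idx >= 1 & pos < e$end[pmax(idx, 1)]
  plus <- ifelse(inside, cum[pmax(idx, 1)] + pos - e$start[pmax(idx, 1)], NA_real_)
  if (strand == "+") plus else L - 1 - plus
}

# Inverse of tx_position: transcript coordinate -> genomic position.
genomic_position <- function(models, transcript_id, txpos) {
  e <- models$exons[models$exons$transcript_id == transcript_id, ]
  strand <- models$transcripts$strand[
    models$transcripts$transcript_id == transcript_id]
  cum <- cumsum(c(0, e$end - e$start))
  L <- cum[length(cum)]
  p <- if (strand == "+") txpos else L - 1 - txpos
  if (any(p < 0 | p >= L, na.rm = TRUE)) fail("transcript coordinate out of range")
  idx <- findInterval(p, cum[-length(cum)], rightmost.closed = FALSE)
  e$start[idx] + (p - cum[idx])
}

# Spliced transcript sequence in transcript orientation (5'->3').
transcript_seq <- function(genome, models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, ]
  tr <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  chr <- as.character(genome[[tr$contig]])
  s <- paste(substring(chr, e$start + 1, e$end), collapse = "")
  if (tr$strand == "-") reverse_complement(s) else s
}

map_biotype <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[x %in% "protein_coding"] <- "protein_coding"
  out[x %in% c("lncrna", "lincrna")] <- "lncRNA"
  out[grepl("pseudogene", x)] <- "pseudogene"
  out
}

#' Read transcript models from a GTF file
#'
#' Parses exon features from a GTF (1-based inclusive) into 0-based half-open
#' internal coordinates. Biotype is read from the `gene_type`/`gene_biotype`
#' attribute when present and mapped to
#' `{protein_coding, lncRNA, pseudogene, mito, other}`.
#'
#' @param path Path to a GTF file.
#' @param mito_contigs Passed to [transcript_models()].
#' @return A `transcript_models` object.
#' @export
read_gtf <- function(path, mito_contigs = c("chrM", "MT")) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    fail("malformed GTF line %d in %s (expected 9 tab-separated fields)", bad, path)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) fail("no exon features in %s", path)
  mc <- as.data.frame(gr)
  if (is.null(mc$gene_id) || is.null(mc$transcript_id) ||
      anyNA(mc$gene_id) || anyNA(mc$transcript_id)) {
    fail("exon features must carry gene_id and transcript_id attributes")
  }
  bt <- mc$gene_type
  if (is.null(bt)) bt <- mc$gene_biotype
  if (is.null(bt)) bt <- rep("other", nrow(mc))
  ex <- data.frame(transcript_id = mc$transcript_id,
                   start = mc$start - 1, end = mc$end)
  key <- paste(mc$transcript_id, mc$gene_id, mc$seqnames, mc$strand)
  per_tx <- tapply(key, mc$transcript_id, function(k) length(unique(k)))
  if (any(per_tx > 1)) {
    fail("duplicate transcript_id used across genes/contigs/strands: %s",
         paste(names(per_tx)[per_tx > 1], collapse = ", "))
  }
  first <- !duplicated(mc$transcript_id)
  tr <- data.frame(gene_id = mc$gene_id[first],
                   transcript_id = mc$transcript_id[first],
                   contig = as.character(mc$seqnames)[first],
                   strand = as.character(mc$strand)[first],
                   biotype = map_biotype(bt[first]))
  dup_ex <- duplicated(ex)
  if (any(dup_ex)) {
    fail("duplicate transcript_id (repeated exon rows) for: %s",
         paste(unique(ex$transcript_id[dup_ex]), collapse = ", "))
  }
  transcript_models(tr, ex, mito_contigs = mito_contigs)
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` feature per exon, converting back to GTF's 1-based
#' inclusive coordinates. Round-trips with [read_gtf()].
#'
#' @param models A `transcript_models` object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  tr <- models$transcripts
  e <- merge(models$exons, tr, by = "transcript_id", sort = FALSE)
  e <- e[order(match(e$transcript_id, tr$transcript_id), e$start), ]
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
                   e$gene_id, e$transcript_id, e$biotype)
  lines <- paste(e$contig, "rlptools", "exon", e$start + 1, e$end, ".",
                 e$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
}

#' Read a per-site base-count table
#'
#' The contractual caller input: a TSV with header columns `contig`,
#' `position` (0-based), `ref`, `A`, `C`, `G`, `T`. Depth is computed as the
#' row sum of the four base columns.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the input columns plus `depth`.
#' @export
read_site_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("contig", "position", "ref", BASES)
  if (!all(req %in% names(x))) {
    fail("site-count table must have columns: %s", paste(req, collapse = ", "))
  }
  x <- x[, req]
  if (!nrow(x)) {
    x$depth <- integer(0)
    return(x)
  }
  if (!all(x$ref %in% BASES)) {
    fail("unknown ref base: %s", paste(unique(setdiff(x$ref, BASES)), collapse = ", "))
  }
  cnt <- as.matrix(x[, BASES])
  if (any(cnt < 0)) fail("negative base count in %s", path)
  x$depth <- as.integer(rowSums(cnt))
  x
}

#' Write a per-site base-count table
#'
#' @param sites data.frame as returned by [read_site_counts()] (the `depth`
#'   column, if present, is dropped: it is derived on read).
#' @param path Output path.
#' @export
write_site_counts <- function(sites, path) {
  cols <- c("contig", "position", "ref", BASES)
  utils::write.table(sites[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write editing events as BED6
#'
#' Intervals are 0-based half-open; `name` is `gene_id:conversion` and `score`
#' is `round(1000 * editing_ratio)`.
#'
#' @param events Events as returned by [call_events()].
#' @param path Output path.
#' @export
write_events_bed <- function(events, path) {
  lines <- paste(events$contig, events$position, events$position + 1,
                 paste0(events$gene_id, ":", events$conversion),
                 round(1000 * events$editing_ratio), events$strand, sep = "\t")
  writeLines(lines, path)
}

#' Read/write a cell-by-gene matrix as TSV
#'
#' Rows are cells, columns are genes; the first column holds cell identifiers.
#'
#' @param path File path.
#' @return A numeric matrix with cell rownames and gene colnames.
#' @export
read_cell_matrix <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_cell_matrix
#' @param m Matrix to write (cells x genes).
#' @export
write_cell_matrix <- function(m, path) {
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
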