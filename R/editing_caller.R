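# Edit-event calling from induced vs uninduced-control site counts.

#' Caller thresholds
#'
#' Bundles the thresholds of the four-filter event caller.
#'
#' @param min_alt Minimum reads supporting the edit at a site (default 3).
#' @param min_events_per_transcript Minimum qualifying events a transcript
#'   needs for its events to be retained (default 3).
#' @param min_event_ratio Each counted event must have
#'   `editing_ratio > min_event_ratio` (default 0.01).
#' @param control_max_alt Maximum alt reads tolerated at the site in every
#'   control sample ("absent from controls"; default 0, the strictest reading).
#' @param purity_min_fraction Minimum fraction of non-reference reads carried
#'   by the chemistry's alt base (single-SNV-type rule; default 0.9).
#' @param min_depth Minimum site depth (default 1).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_alt = 3, min_events_per_transcript = 3,
                          min_event_ratio = 0.01, control_max_alt = 0,
                          purity_min_fraction = 0.9, min_depth = 1) {
  stopifnot(min_alt >= 0, min_events_per_transcript >= 0, min_depth >= 0,
            control_max_alt >= 0,
            min_event_ratio >= 0, min_event_ratio <= 1,
            purity_min_fraction >= 0, purity_min_fraction <= 1)
  structure(list(min_alt = min_alt,
                 min_events_per_transcript = min_events_per_transcript,
                 min_event_ratio = min_event_ratio,
                 control_max_alt = control_max_alt,
                 purity_min_fraction = purity_min_fraction,
                 min_depth = min_depth),
            class = "caller_params")
}

# Assign sites to the designated transcript whose exons contain them.
# Returns sites with gene_id/transcript_id/strand columns; unassigned rows
# are dropped (they can never satisfy the per-transcript filter).
assign_sites <- function(sites, models) {
  tr <- models$transcripts[models$transcripts$designated, ]
  ex <- merge(models$exons, tr[, c("transcript_id", "gene_id", "contig", "strand")],
              by = "transcript_id", sort = FALSE)
  out <- vector("list", nrow(tr))
  pieces <- list()
  for (ctg in unique(sites$contig)) {
    s <- sites[sites$contig == ctg, , drop = FALSE]
    e <- ex[ex$contig == ctg, , drop = FALSE]
    if (!nrow(e) || !nrow(s)) next
    e <- e[order(e$start), ]
    idx <- findInterval(s$position, e$start)
    hit <- idx >= 1 & s$position < e$end[pmax(idx, 1)]
    if (!any(hit)) next
    s <- s[hit, , drop = FALSE]
    idx <- idx[hit]
    s$gene_id <- e$gene_id[idx]
    s$transcript_id <- e$transcript_id[idx]
    s$strand <- e$strand[idx]
    pieces[[ctg]] <- s
  }
  if (!length(pieces)) {
    sites$gene_id <- character(0)
    return(sites[0, ])
  }
  do.call(rbind, pieces)
}

#' Call reporter-induced editing events
#'
#' Compares induced against uninduced-control per-site base counts and applies
#' four filters: (1) the site is absent from every control
#' (`alt_count <= control_max_alt` in each); (2) only one SNV type — the
#' chemistry's alt base carries at least `purity_min_fraction` of the
#' non-reference reads and no other alt base reaches `min_alt`; (3) the edit
#' is supported by at least `min_alt` reads; (4) only transcripts with at
#' least `min_events_per_transcript` events, each with
#' `editing_ratio > min_event_ratio`, retain their events.
#'
#' Strand orientation is applied before classifying the conversion: a genomic
#' T>C change on a minus-strand transcript is an A>G event in transcript
#' orientation.
#'
#' @param induced Site-count data.frame (see [read_site_counts()]).
#' @param controls List of control site-count data.frames.
#' @param models A `transcript_models` object; sites are assigned to the
#'   designated transcript per gene.
#' @param params A [caller_params()] object.
#' @param chemistry `"A>G"` (TadA-style) or `"C>T"` (APOBEC1-style),
#'   in transcript orientation.
#' @param missing_control Policy for sites absent from all controls:
#'   `"reject"` (default; rejected sites are counted in the
#'   `missing_control_sites` attribute and a warning is raised) or `"keep"`.
#' @return data.frame of class `edit_events` with columns `gene_id`,
#'   `transcript_id`, `contig`, `position`, `strand`, `conversion`,
#'   `ref`, `alt` (genomic bases), `alt_count`, `depth`, `editing_ratio`.
#' @export
call_events <- function(induced, controls, models, params = caller_params(),
                        chemistry = c("A>G", "C>T"),
                        missing_control = c("reject", "keep")) {
  chemistry <- match.arg(chemistry)
  missing_control <- match.arg(missing_control)
  if (!is.list(controls) || is.data.frame(controls)) controls <- list(controls)

  ref_tx <- substr(chemistry, 1, 1)
  alt_tx <- substr(chemistry, 3, 3)

  s <- assign_sites(induced, models)
  empty <- data.frame(gene_id = character(0), transcript_id = character(0),
                      contig = character(0), position = numeric(0),
                      strand = character(0), conversion = character(0),
                      ref = character(0), alt = character(0),
                      alt_count = numeric(0), depth = numeric(0),
                      editing_ratio = numeric(0))
  class(empty) <- c("edit_events", "data.frame")
  if (!nrow(s)) return(empty)

  # genomic ref/alt expected under the chemistry, given transcript strand
  g_ref <- ifelse(s$strand == "+", ref_tx, unname(COMPLEMENT[ref_tx]))
  g_alt <- ifelse(s$strand == "+", alt_tx, unname(COMPLEMENT[alt_tx]))

  keep <- s$ref == g_ref & s$depth > 0 & s$depth >= params$min_depth
  s <- s[keep, , drop = FALSE]
  g_ref <- g_ref[keep]; g_alt <- g_alt[keep]
  if (!nrow(s)) return(empty)

  cnt <- as.matrix(s[, BASES])
  alt_count <- cnt[cbind(seq_len(nrow(s)), match(g_alt, BASES))]
  ref_count <- cnt[cbind(seq_len(nrow(s)), match(g_ref, BASES))]
  nonref <- s$depth - ref_count
  other_max <- vapply(seq_len(nrow(s)), function(i) {
    max(cnt[i, setdiff(BASES, c(g_ref[i], g_alt[i]))])
  }, numeric(1))

  purity_ok <- nonref > 0 &
    alt_count / pmax(nonref, 1) >= params$purity_min_fraction &
    other_max < params$min_alt
  support_ok <- alt_count >= params$min_alt

  # control absence
  ctl_alt_max <- rep(-Inf, nrow(s))  # -Inf = seen in no control
  key <- paste(s$contig, s$position)
  for (ctl in controls) {
    ck <- paste(ctl$contig, ctl$position)
    m <- match(key, ck)
    seen <- !is.na(m)
    if (!any(seen)) next
    ccnt <- as.matrix(ctl[m[seen], BASES])
    calt <- ccnt[cbind(seq_len(sum(seen)), match(g_alt[seen], BASES))]
    ctl_alt_max[seen] <- pmax(ctl_alt_max[seen], calt)
  }
  unseen <- is.infinite(ctl_alt_max)
  control_ok <- !unseen & ctl_alt_max <= params$control_max_alt
  if (any(unseen) && missing_control == "keep") control_ok[unseen] <- TRUE
  n_missing <- sum(unseen & purity_ok & support_ok)
  if (missing_control == "reject" && n_missing > 0) {
    warning(sprintf("%d candidate site(s) absent from all controls were rejected",
                    n_missing), call. = FALSE)
  }

  pass <- control_ok & purity_ok & support_ok
  s <- s[pass, , drop = FALSE]
  if (!nrow(s)) return(empty)
  ev <- data.frame(gene_id = s$gene_id, transcript_id = s$transcript_id,
                   contig = s$contig, position = s$position, strand = s$strand,
                   conversion = chemistry,
                   ref = g_ref[pass], alt = g_alt[pass],
                   alt_count = alt_count[pass], depth = s$depth,
                   editing_ratio = alt_count[pass] / s$depth)

  # filter (4): per-transcript floor on qualifying events
  qual <- ev$editing_ratio > params$min_event_ratio
  n_qual <- table(ev$transcript_id[qual])
  ok_tx <- names(n_qual)[n_qual >= params$min_events_per_transcript]
  ev <- ev[qual & ev$transcript_id %in% ok_tx, , drop = FALSE]
  ev <- ev[order(ev$contig, ev$position), ]
  rownames(ev) <- NULL
  attr(ev, "missing_control_sites") <- n_missing
  class(ev) <- c("edit_events", "data.frame")
  ev
}

#' Mutation spectrum of candidate SNVs
#'
#' Tabulates candidate single-nucleotide variants over the 12 conversion
#' classes. Used as a specificity diagnostic: a clean reporter run is
#' dominated (>98 percent in well-behaved data) by its chemistry's class.
#'
#' @param snvs data.frame with columns `ref` and `alt`, or a single
#'   `conversion` column of `"X>Y"` strings.
#' @return data.frame with columns `conversion`, `count`, `fraction`
#'   covering all 12 classes; fractions sum to 1.
#' @export
mutation_spectrum <- function(snvs) {
  if (!nrow(snvs)) fail("empty candidate set")
  if (!is.null(snvs$conversion)) {
    conv <- snvs$conversion
  } else if (!is.null(snvs$ref) && !is.null(snvs$alt)) {
    conv <- paste0(snvs$ref, ">", snvs$alt)
  } else {
    fail("snvs must have a conversion column or ref and alt columns")
  }
  classes <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, ">", b)))
  classes <- classes[substr(classes, 1, 1) != substr(classes, 3, 3)]
  classes <- sort(classes)
  bad <- setdiff(unique(conv), classes)
  if (length(bad)) fail("invalid conversion class: %s", paste(bad, collapse = ", "))
  n <- table(factor(conv, levels = classes))
  data.frame(conversion = classes, count = as.integer(n),
             fraction = as.numeric(n) / sum(n))
}
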