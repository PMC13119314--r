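# Independent brute-force oracles and small fixture builders shared across
# test files. The oracles are literal transcriptions of the contracts,
# deliberately written without reference to the package's implementation.

# ---- fixtures ---------------------------------------------------------------

# A minimal hand-built gene: one transcript, explicit exons.
toy_models <- function(strand = "+", exons = data.frame(start = 100, end = 600),
                       gene_id = "G1", transcript_id = "T1",
                       contig = "chr1", biotype = "protein_coding") {
  transcript_models(
    data.frame(gene_id = gene_id, transcript_id = transcript_id,
               contig = contig, strand = strand, biotype = biotype),
    cbind(transcript_id = transcript_id, exons))
}

# One site-count row in caller input layout.
site_row <- function(contig, position, ref, A = 0, C = 0, G = 0, T = 0) {
  data.frame(contig = contig, position = position, ref = ref,
             A = A, C = C, G = G, T = T, depth = A + C + G + T)
}

# Random site table over the exons of `models` plus controls, for the
# caller-vs-oracle equivalence checks. Positions may fall in introns or
# intergenic space; refs and counts are noisy on purpose.
random_site_tables <- function(models, n_sites, n_controls = 2) {
  tr <- models$transcripts
  contig <- tr$contig[1]
  span <- range(c(models$exons$start, models$exons$end))
  pos <- sort(sample(seq(span[1], span[2] - 1), n_sites))
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  mk_counts <- function() {
    t(vapply(seq_len(n_sites), function(i) {
      depth <- sample(0:60, 1)
      main <- sample(c("A", "C", "G", "T"), 1)
      out <- c(A = 0, C = 0, G = 0, T = 0)
      alt_n <- min(depth, sample(0:8, 1))
      second <- min(depth - alt_n, sample(0:3, 1))
      out[main] <- depth - alt_n - second
      alt_b <- sample(setdiff(names(out), main), 2)
      out[alt_b[1]] <- out[alt_b[1]] + alt_n
      out[alt_b[2]] <- out[alt_b[2]] + second
      out
    }, numeric(4)))
  }
  induced_counts <- mk_counts()
  # bias induced refs toward the actual major base so filters get exercised
  major <- colnames(induced_counts)[max.col(induced_counts + 1e-3)]
  use_major <- runif(n_sites) < 0.8
  ref[use_major] <- major[use_major]
  induced <- data.frame(contig = contig, position = pos, ref = ref,
                        induced_counts)
  induced$depth <- rowSums(induced_counts)
  controls <- lapply(seq_len(n_controls), function(k) {
    keep <- runif(n_sites) < 0.9  # some sites missing from this control
    cc <- t(vapply(seq_len(n_sites), function(i) {
      depth <- sample(0:60, 1)
      out <- c(A = 0, C = 0, G = 0, T = 0)
      noise_b <- sample(c("A", "C", "G", "T"), 1)
      noise_n <- min(depth, sample(0:2, 1))
      out[ref[i]] <- depth - noise_n
      out[noise_b] <- out[noise_b] + noise_n
      out
    }, numeric(4)))
    ctl <- data.frame(contig = contig, position = pos, ref = ref, cc)
    ctl$depth <- rowSums(cc)
    ctl[keep, ]
  })
  list(induced = induced, controls = controls)
}

# ---- caller oracle ----------------------------------------------------------

comp <- c(A = "T", C = "G", G = "C", T = "A")

# Literal four-filter caller: loop over sites, loop over transcripts.
oracle_call_events <- function(induced, controls, models, params, chemistry,
                               missing_control = "reject") {
  ref_tx <- substr(chemistry, 1, 1)
  alt_tx <- substr(chemistry, 3, 3)
  tr <- models$transcripts[models$transcripts$designated, ]
  candidates <- list()
  for (i in seq_len(nrow(induced))) {
    row <- induced[i, ]
    hit_tx <- NULL
    for (j in seq_len(nrow(tr))) {
      if (tr$contig[j] != row$contig) next
      ex <- models$exons[models$exons$transcript_id == tr$transcript_id[j], ]
      if (any(row$position >= ex$start & row$position < ex$end)) {
        hit_tx <- tr[j, ]
        break
      }
    }
    if (is.null(hit_tx)) next
    g_ref <- if (hit_tx$strand == "+") ref_tx else comp[[ref_tx]]
    g_alt <- if (hit_tx$strand == "+") alt_tx else comp[[alt_tx]]
    if (row$ref != g_ref) next
    depth <- row$A + row$C + row$G + row$T
    if (depth <= 0 || depth < params$min_depth) next
    alt <- row[[g_alt]]
    others <- unlist(row[setdiff(c("A", "C", "G", "T"), c(g_ref, g_alt))])
    nonref <- depth - row[[g_ref]]
    if (alt < params$min_alt) next
    if (nonref <= 0) next
    if (alt / nonref < params$purity_min_fraction) next
    if (any(others >= params$min_alt)) next
    seen <- FALSE
    ok <- TRUE
    for (ctl in controls) {
      hit <- ctl$contig == row$contig & ctl$position == row$position
      if (any(hit)) {
        seen <- TRUE
        if (ctl[[g_alt]][hit][1] > params$control_max_alt) ok <- FALSE
      }
    }
    if (!seen) ok <- missing_control == "keep"
    if (!ok) next
    candidates[[length(candidates) + 1]] <-
      data.frame(transcript_id = hit_tx$transcript_id, position = row$position,
                 alt_count = alt, depth = depth, ratio = alt / depth)
  }
  if (!length(candidates)) {
    return(data.frame(transcript_id = character(0), position = numeric(0),
                      alt_count = numeric(0)))
  }
  cand <- do.call(rbind, candidates)
  out <- list()
  for (tx in unique(cand$transcript_id)) {
    sub <- cand[cand$transcript_id == tx, ]
    qual <- sub[sub$ratio > params$min_event_ratio, ]
    if (nrow(qual) >= params$min_events_per_transcript) {
      out[[tx]] <- qual
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), position = numeric(0),
                      alt_count = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position), c("transcript_id", "position", "alt_count")]
  rownames(res) <- NULL
  res
}

event_key <- function(ev) {
  if (!nrow(ev)) return(character(0))
  sort(paste(ev$transcript_id, ev$position, ev$alt_count))
}

# ---- UPGMA oracle -----------------------------------------------------------

# Textbook UPGMA on a distance matrix: repeatedly merge the closest pair
# (lowest indices on ties), average linkage weighted by cluster size.
# Returns the sorted merge heights.
oracle_upgma_heights <- function(D) {
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    bestd <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        d <- D[active[a], active[b]]
        if (d < bestd - 1e-12) {
          bestd <- d
          best <- c(a, b)
        }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights <- c(heights, bestd)
    for (k in active) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# ---- QC oracle --------------------------------------------------------------

# Brute-force reimplementation of the cell QC contract with type-7 quantiles.
oracle_qc_pass <- function(detected, edited, ratio, mode,
                           min_genes = 9000, nes_k = 1.5, erm_k = 3,
                           erm_floor = 200) {
  pass <- detected >= min_genes
  surv <- which(pass)
  q <- function(x, p) as.numeric(quantile(x, p, type = 7))
  if (mode == "NES") {
    lo_e <- q(edited[surv], 0.25) - nes_k * (q(edited[surv], 0.75) - q(edited[surv], 0.25))
    hi_e <- q(edited[surv], 0.75) + nes_k * (q(edited[surv], 0.75) - q(edited[surv], 0.25))
    lo_r <- q(ratio[surv], 0.25) - nes_k * (q(ratio[surv], 0.75) - q(ratio[surv], 0.25))
    hi_r <- q(ratio[surv], 0.75) + nes_k * (q(ratio[surv], 0.75) - q(ratio[surv], 0.25))
    for (i in surv) {
      if (edited[i] < lo_e || edited[i] > hi_e ||
          ratio[i] < lo_r || ratio[i] > hi_r) pass[i] <- FALSE
    }
  } else {
    hi <- q(edited[surv], 0.75) + erm_k * (q(edited[surv], 0.75) - q(edited[surv], 0.25))
    for (i in surv) {
      if (edited[i] < erm_floor || edited[i] > hi) pass[i] <- FALSE
    }
  }
  pass
}

# Build a cell_matrices object directly from an edit matrix (uniform TPM
# unless given), for unit tests that do not need realistic expression.
quick_cells <- function(edits, expr = NULL, ...) {
  if (is.null(dimnames(edits))) {
    dimnames(edits) <- list(sprintf("c%d", seq_len(nrow(edits))),
                            sprintf("g%d", seq_len(ncol(edits))))
  }
  if (is.null(expr)) {
    expr <- matrix(1e6 / ncol(edits), nrow(edits), ncol(edits),
                   dimnames = dimnames(edits))
  }
  cell_matrices(edits, expr, ...)
}
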