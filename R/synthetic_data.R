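# Ground-truth simulators for every input the pipeline consumes.
#
# One master seed fans out into named substreams (substream_seed), so each
# generator is deterministic on its own and adding a generator never perturbs
# the output of another.

#' Simulation ground truth
#'
#' Draws and freezes the per-gene attributes and model parameters every
#' simulator consumes. Gene identifiers follow the same `G%04d` scheme as
#' [make_transcriptome()], so a truth object and a transcriptome built from
#' the same `n_genes` align by construction.
#'
#' @param n_genes Number of genes.
#' @param seed Master seed.
#' @param chemistry Reporter chemistry, `"A>G"` (TadA-style; TA dinucleotide
#'   motif) or `"C>T"` (APOBEC1-style; AC motif).
#' @param membership_props Proportions of compartment membership classes
#'   `compartment_enriched`, `background`, `cytoplasm_only`, `unexpressed`.
#' @param edit_rate Per-read editing probability at a planted site in the
#'   compartment sample for enriched genes (default 0.2, a typical strong
#'   reporter ratio).
#' @param enrichment Efficiency ratio of enriched over background genes
#'   (default 4, so the planted localization index is 2).
#' @param depth_per_gene Mean mapped reads per average-expression gene in bulk
#'   samples (default 100).
#' @param sites_per_gene Editing sites planted per edited gene (default 5).
#' @param site_cov Fraction of a gene's reads covering each 3'-proximal site
#'   (default 0.7).
#' @param control_error Per-read error rate in uninduced controls
#'   (default 1e-3).
#' @param motif_fidelity Fraction of planted edits at the chemistry's
#'   dinucleotide motif (default 0.9).
#' @param positional_law Edit-placement law over distance upstream of the
#'   poly(A) site: mass `hot_mass` uniform on `[hot_lo, hot_hi)`, remainder
#'   uniform on the rest of `[0, window)`.
#' @param core_frac,rare_frac Fractions of genes edited in a large
#'   (`core_member_p`) or small (`rare_member_p`) random cell subset; the
#'   remainder are null genes whose edits follow expression.
#' @param core_member_p,rare_member_p Cell-subset membership probabilities.
#' @param planted_mult Planted genes receive Poisson edits with mean
#'   `planted_mult * N_c / n_genes` in member cells (default 2.5, i.e. mean
#'   ~8 at the default edit load, well above the 3-edit detection floor).
#' @param edits_per_gene Mean single-cell edit load per gene; a cell's total
#'   is Poisson with mean `edits_per_gene * n_genes` (default 3.33, matching
#'   roughly half of detected genes carrying 3 or more edits).
#' @param expr_sdlog,cell_noise_sd Lognormal SDs of gene mean expression and
#'   of per-cell expression noise.
#' @param phase_props Cell-cycle phase proportions.
#' @param temporal_props Proportions of `rising`, `peaked`, `flat` temporal
#'   classes.
#' @param timecourse_noise_sd Gaussian noise SD on standardized localization
#'   trajectories (default 0.3).
#' @param intron_retention Named per-phase intron retention levels
#'   (default S = 0.5, G2M = 0.05: a 10-fold detained-intron contrast).
#' @param intron_noise_sd Lognormal noise SD on intron coverage.
#' @return A list of class `simulation_truth`; `genes` holds the per-gene
#'   table (`gene_id`, `expr_level`, `biotype`, `membership`, `sc_class`,
#'   `temporal_class`).
#' @export
simulation_truth <- function(n_genes = 300, seed = 1,
                             chemistry = c("A>G", "C>T"),
                             membership_props = c(compartment_enriched = 0.3,
                                                  background = 0.4,
                                                  cytoplasm_only = 0.2,
                                                  unexpressed = 0.1),
                             edit_rate = 0.2, enrichment = 4,
                             depth_per_gene = 100, sites_per_gene = 5,
                             site_cov = 0.7, control_error = 1e-3,
                             motif_fidelity = 0.9,
                             positional_law = list(window = 1000, hot_lo = 50,
                                                   hot_hi = 250,
                                                   hot_mass = 0.95),
                             core_frac = 0.2, rare_frac = 0.3,
                             core_member_p = 0.95, rare_member_p = 0.05,
                             planted_mult = 2.5, edits_per_gene = 3.33,
                             expr_sdlog = 1.5, cell_noise_sd = 0.3,
                             phase_props = c(G1 = 0.5, S = 0.25, G2M = 0.25),
                             temporal_props = c(rising = 0.4, peaked = 0.4,
                                                flat = 0.2),
                             timecourse_noise_sd = 0.3,
                             intron_retention = c(S = 0.5, G2M = 0.05),
                             intron_noise_sd = 0.25) {
  chemistry <- match.arg(chemistry)
  stopifnot(n_genes >= 1, core_frac + rare_frac <= 1,
            abs(sum(membership_props) - 1) < 1e-8)
  genes <- with_stream(seed, "truth", {
    data.frame(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      expr_level = stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1),
      biotype = sample(c("protein_coding", "lncRNA", "pseudogene"), n_genes,
                       replace = TRUE, prob = c(0.9, 0.07, 0.03)),
      membership = sample(names(membership_props), n_genes, replace = TRUE,
                          prob = membership_props),
      sc_class = sample(c("core", "rare", "null"), n_genes, replace = TRUE,
                        prob = c(core_frac, rare_frac,
                                 1 - core_frac - rare_frac)),
      temporal_class = sample(names(temporal_props), n_genes, replace = TRUE,
                              prob = temporal_props),
      stringsAsFactors = FALSE)
  })
  motif <- if (chemistry == "A>G") "TA" else "AC"
  structure(list(seed = seed, n_genes = n_genes, chemistry = chemistry,
                 motif = motif, genes = genes,
                 edit_rate = edit_rate, enrichment = enrichment,
                 depth_per_gene = depth_per_gene,
                 sites_per_gene = sites_per_gene, site_cov = site_cov,
                 control_error = control_error,
                 motif_fidelity = motif_fidelity,
                 positional_law = positional_law,
                 core_member_p = core_member_p,
                 rare_member_p = rare_member_p,
                 planted_mult = planted_mult,
                 edits_per_gene = edits_per_gene,
                 expr_sdlog = expr_sdlog, cell_noise_sd = cell_noise_sd,
                 phase_props = phase_props,
                 temporal_props = temporal_props,
                 timecourse_noise_sd = timecourse_noise_sd,
                 intron_retention = intron_retention,
                 intron_noise_sd = intron_noise_sd),
            class = "simulation_truth")
}

#' Serialize simulation truth to JSON
#'
#' @param truth A `simulation_truth` object.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

# Remove all occurrences of a 2-mer motif from a base vector (in place
# orientation), then plant it at approximately `density` of positions.
control_motif <- function(bases, motif, density) {
  m1 <- substr(motif, 1, 1); m2 <- substr(motif, 2, 2)
  n <- length(bases)
  if (n >= 2) {
    repeat {
      hit <- which(bases[-n] == m1 & bases[-1] == m2)
      if (!length(hit)) break
      for (i in hit) {
        avoid <- m2
        if (i + 2 <= n && bases[i + 2] == m2) avoid <- c(avoid, m1)
        bases[i + 1] <- sample(setdiff(BASES, avoid), 1)
      }
    }
  }
  n_plant <- round(density * n)
  if (n_plant > 0 && n >= 3) {
    pos <- sort(sample_int(n - 2, min(n_plant, floor((n - 2) / 2))) + 1)
    pos <- pos[c(TRUE, diff(pos) > 1)]  # avoid overlapping plants
    bases[pos - 1] <- m1
    bases[pos] <- m2
  }
  bases
}

#' Generate a synthetic transcriptome
#'
#' Builds a random genome on one contig with `n_genes` genes of 1-5 exons on
#' both strands, with a controlled density of the chemistry's target
#' dinucleotide in exons (transcript orientation). Byte-identical under a
#' fixed seed.
#'
#' @param n_genes Number of genes.
#' @param seed Master seed (substream `"transcriptome"`).
#' @param motif Two-base edit motif planted in exons (default `"TA"`, the
#'   TadA preference; use `"AC"` for APOBEC1-style chemistry).
#' @param motif_density Target fraction of exon positions carrying the motif
#'   (0 removes it entirely).
#' @param exon_length,intron_length,intergenic Length ranges (nt).
#' @param max_exons Maximum exons per transcript (uniform on 1..max).
#' @param contig Contig name.
#' @return list with `models` (a [transcript_models()] object, one transcript
#'   per gene) and `genome` (a `Biostrings::DNAStringSet`).
#' @export
make_transcriptome <- function(n_genes = 50, seed = 1, motif = "TA",
                               motif_density = 0.05,
                               exon_length = c(200, 800),
                               intron_length = c(100, 500),
                               intergenic = c(200, 1000),
                               max_exons = 5, contig = "chrS1") {
  stopifnot(n_genes >= 1, nchar(motif) == 2, motif_density >= 0,
            motif_density <= 0.5)
  with_stream(seed, "transcriptome", {
    cursor <- 0
    chunks <- character(0)
    tr <- vector("list", n_genes)
    ex <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gap <- sample(seq(intergenic[1], intergenic[2]), 1)
      chunks <- c(chunks, paste(sample(BASES, gap, replace = TRUE),
                                collapse = ""))
      cursor <- cursor + gap
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample.int(max_exons, 1)
      ex_len <- sample(seq(exon_length[1], exon_length[2]), n_ex,
                       replace = TRUE)
      in_len <- if (n_ex > 1) {
        sample(seq(intron_length[1], intron_length[2]), n_ex - 1,
               replace = TRUE)
      } else integer(0)
      # exon sequences in transcript orientation, motif-controlled
      tx_exons <- lapply(ex_len, function(L) {
        control_motif(sample(BASES, L, replace = TRUE), motif, motif_density)
      })
      # genomic order: reverse exon order (and complement) on minus strand
      genomic_exons <- if (strand == "+") {
        vapply(tx_exons, paste, character(1), collapse = "")
      } else {
        rev(vapply(tx_exons, function(b) {
          reverse_complement(paste(b, collapse = ""))
        }, character(1)))
      }
      starts <- numeric(n_ex)
      for (i in seq_len(n_ex)) {
        starts[i] <- cursor
        chunks <- c(chunks, genomic_exons[i])
        cursor <- cursor + nchar(genomic_exons[i])
        if (i < n_ex) {
          chunks <- c(chunks, paste(sample(BASES, in_len[i], replace = TRUE),
                                    collapse = ""))
          cursor <- cursor + in_len[i]
        }
      }
      gid <- sprintf("G%04d", g)
      tr[[g]] <- data.frame(gene_id = gid,
                            transcript_id = paste0("T", substring(gid, 2)),
                            contig = contig, strand = strand,
                            biotype = "protein_coding")
      ex[[g]] <- data.frame(transcript_id = tr[[g]]$transcript_id,
                            start = starts,
                            end = starts + nchar(genomic_exons))
    }
    genome <- Biostrings::DNAStringSet(paste(chunks, collapse = ""))
    names(genome) <- contig
    list(models = transcript_models(do.call(rbind, tr), do.call(rbind, ex)),
         genome = genome)
  })
}

# Draw site positions under the positional law: each site is "hot" (inside
# [hot_lo, hot_hi) upstream of the poly(A) site) with probability hot_mass,
# then placed uniformly over the candidate positions of its stratum; when a
# stratum runs out of candidates the remainder falls back to the other one.
draw_positions <- function(candidates, d, law, n) {
  hot <- candidates[d[candidates] >= law$hot_lo & d[candidates] < law$hot_hi]
  cold <- candidates[d[candidates] < law$window &
                       !(d[candidates] >= law$hot_lo &
                           d[candidates] < law$hot_hi)]
  n_hot <- stats::rbinom(1, n, law$hot_mass)
  take <- function(pool, k) {
    if (k <= 0 || !length(pool)) integer(0)
    else pool[sample_int(length(pool), min(k, length(pool)))]
  }
  h <- take(hot, n_hot)
  c_ <- take(cold, n - length(h))
  c(h, c_, take(setdiff(hot, h), n - length(h) - length(c_)))
}

#' Simulate bulk site-count tables with planted edits
#'
#' Draws per-gene read counts from expression, plants editing sites at
#' chemistry-consistent motif positions under the 3'-biased positional law,
#' and emits one induced table plus uninduced controls carrying only
#' error-rate noise.
#'
#' In the `"compartment"` sample, enriched genes are edited at
#' `truth$edit_rate` per covering read, background genes at
#' `edit_rate / enrichment`, and cytoplasm-only genes not at all; in the
#' `"cytoplasm"` sample every expressed gene is edited at the background
#' rate.
#'
#' @param truth A [simulation_truth()] object.
#' @param models,genome From [make_transcriptome()] with the same `n_genes`.
#' @param sample Which reporter sample to emulate.
#' @param n_controls Number of uninduced control tables (default 2).
#' @param seed Master seed (default the truth's; substream
#'   `"bulk_<sample>"`).
#' @return list with `induced` (site-count data.frame), `controls` (list of
#'   site-count data.frames), `per_gene_reads`, and `sites` (the planted
#'   ground truth: gene, transcript, genomic position, strand, transcript
#'   distance from the poly(A) site, and rate).
#' @export
simulate_bulk <- function(truth, models, genome,
                          sample = c("compartment", "cytoplasm"),
                          n_controls = 2, seed = truth$seed) {
  sample <- match.arg(sample)
  tr <- models$transcripts[models$transcripts$designated, ]
  genes <- merge(truth$genes, tr, by = "gene_id", sort = FALSE)
  if (nrow(genes) != truth$n_genes) {
    fail("truth and models disagree on gene ids")
  }
  genes <- genes[order(genes$gene_id), ]
  ref_tx <- substr(truth$chemistry, 1, 1)
  base_rate <- truth$edit_rate / truth$enrichment
  with_stream(seed, paste0("bulk_", sample), {
    reads <- ifelse(genes$membership == "unexpressed", 0,
                    stats::rpois(nrow(genes),
                                 genes$expr_level / mean(genes$expr_level) *
                                   truth$depth_per_gene))
    rate <- if (sample == "cytoplasm") {
      ifelse(genes$membership == "unexpressed", 0, base_rate)
    } else {
      ifelse(genes$membership == "compartment_enriched", truth$edit_rate,
             ifelse(genes$membership == "background", base_rate, 0))
    }
    site_rows <- list()
    truth_rows <- list()
    for (i in seq_len(nrow(genes))) {
      if (reads[i] == 0) next
      tx <- genes$transcript_id[i]
      L <- genes$tx_length[i]
      s <- strsplit(transcript_seq(genome, models, tx), "")[[1]]
      is_motif <- c(FALSE, s[-L] == substr(truth$motif, 1, 1) &
                      s[-1] == substr(truth$motif, 2, 2))
      is_ref <- s == ref_tx
      d <- (L - 1) - (seq_len(L) - 1)
      n_motif <- stats::rbinom(1, truth$sites_per_gene, truth$motif_fidelity)
      at_motif <- draw_positions(which(is_motif), d, truth$positional_law,
                                 n_motif)
      off_motif <- draw_positions(which(is_ref & !is_motif), d,
                                  truth$positional_law,
                                  truth$sites_per_gene - n_motif)
      pos_tx <- unique(c(at_motif, off_motif)) - 1
      if (!length(pos_tx)) next
      gpos <- genomic_position(models, tx, pos_tx)
      strand <- genes$strand[i]
      g_ref <- if (strand == "+") ref_tx else unname(COMPLEMENT[ref_tx])
      alt_tx <- substr(truth$chemistry, 3, 3)
      g_alt <- if (strand == "+") alt_tx else unname(COMPLEMENT[alt_tx])
      depth <- stats::rbinom(length(gpos), reads[i], truth$site_cov)
      alt <- stats::rbinom(length(gpos), depth, rate[i])
      cnt <- matrix(0, length(gpos), 4, dimnames = list(NULL, BASES))
      cnt[cbind(seq_along(gpos), match(g_ref, BASES))] <- depth - alt
      cnt[cbind(seq_along(gpos), match(g_alt, BASES))] <- alt
      row <- cbind(data.frame(contig = genes$contig[i], position = gpos,
                              ref = g_ref), as.data.frame(cnt))
      site_rows[[tx]] <- row
      truth_rows[[tx]] <- data.frame(gene_id = genes$gene_id[i],
                                     transcript_id = tx,
                                     contig = genes$contig[i],
                                     position = gpos, strand = strand,
                                     tx_distance = (L - 1) - pos_tx,
                                     rate = rate[i], depth = depth,
                                     alt_count = alt)
    }
    induced <- do.call(rbind, site_rows)
    sites <- do.call(rbind, truth_rows)
    if (is.null(induced)) fail("no expressed genes; nothing to simulate")
    rownames(induced) <- rownames(sites) <- NULL
    induced$depth <- rowSums(induced[, BASES])
    controls <- lapply(seq_len(n_controls), function(k) {
      ctl <- induced
      gene_reads <- reads[match(sites$gene_id, genes$gene_id)]
      depth <- stats::rbinom(nrow(ctl), gene_reads, truth$site_cov)
      alt <- stats::rbinom(nrow(ctl), depth, truth$control_error)
      g_alt <- ifelse(sites$strand == "+",
                      substr(truth$chemistry, 3, 3),
                      unname(COMPLEMENT[substr(truth$chemistry, 3, 3)]))
      cnt <- matrix(0, nrow(ctl), 4, dimnames = list(NULL, BASES))
      cnt[cbind(seq_len(nrow(ctl)), match(ctl$ref, BASES))] <- depth - alt
      cnt[cbind(seq_len(nrow(ctl)), match(g_alt, BASES))] <-
        cnt[cbind(seq_len(nrow(ctl)), match(g_alt, BASES))] + alt
      ctl[, BASES] <- cnt
      ctl$depth <- rowSums(cnt)
      ctl
    })
    list(induced = induced, controls = controls,
         per_gene_reads = data.frame(gene_id = genes$gene_id,
                                     read_count = reads),
         sites = sites)
  })
}

#' Simulate single-cell edit and expression matrices
#'
#' Expression is lognormal around gene means and renormalized to TPM per
#' cell. Each cell's edit total is Poisson with mean
#' `edits_per_gene * n_genes`. Null genes receive edits by a multinomial draw
#' proportional to the cell's TPM (exactly the shuffle null); core and rare
#' genes instead receive Poisson edits with mean
#' `planted_mult * N_c / n_genes`, but only inside their random member-cell
#' subset (probability `core_member_p` / `rare_member_p` per cell).
#'
#' @param truth A [simulation_truth()] object.
#' @param n_cells Number of cells.
#' @param seed Master seed (default the truth's; substream `"cells"`).
#' @param with_reads Also generate a unique-read-support matrix
#'   (for the QC gene-retention step).
#' @param reads_per_cell Mean total reads per cell for the support matrix.
#' @return list with `matrices` (a [cell_matrices()] object, with phase
#'   labels and per-cell chemistry-consistency ratios) and `truth_cells`
#'   (`member` logical cell x gene matrix and the per-gene `sc_class`).
#' @export
simulate_cells <- function(truth, n_cells = 100, seed = truth$seed,
                           with_reads = TRUE, reads_per_cell = 5e5) {
  n_genes <- truth$n_genes
  gid <- truth$genes$gene_id
  cls <- truth$genes$sc_class
  with_stream(seed, "cells", {
    gene_mu <- stats::rlnorm(n_genes, meanlog = log(50),
                             sdlog = truth$expr_sdlog)
    expr <- t(vapply(seq_len(n_cells), function(c) {
      e <- gene_mu * stats::rlnorm(n_genes, 0, truth$cell_noise_sd)
      e / sum(e) * 1e6
    }, numeric(n_genes)))
    member <- matrix(FALSE, n_cells, n_genes)
    for (g in which(cls == "core")) {
      member[, g] <- stats::runif(n_cells) < truth$core_member_p
    }
    for (g in which(cls == "rare")) {
      member[, g] <- stats::runif(n_cells) < truth$rare_member_p
    }
    planted <- cls != "null"
    edits <- matrix(0, n_cells, n_genes)
    for (c in seq_len(n_cells)) {
      N_c <- stats::rpois(1, truth$edits_per_gene * n_genes)
      p <- expr[c, ] / sum(expr[c, ])
      if (any(!planted)) {
        edits[c, !planted] <- stats::rmultinom(1, N_c,
                                               p[!planted] / sum(p[!planted]))
      }
      hit <- planted & member[c, ]
      if (any(hit)) {
        edits[c, hit] <- stats::rpois(sum(hit),
                                      truth$planted_mult * N_c / n_genes)
      }
    }
    cell_id <- sprintf("C%04d", seq_len(n_cells))
    dimnames(edits) <- dimnames(expr) <- list(cell_id, gid)
    reads <- NULL
    if (with_reads) {
      reads <- matrix(stats::rpois(n_cells * n_genes,
                                   as.vector(expr) / 1e6 * reads_per_cell),
                      n_cells, n_genes, dimnames = dimnames(expr))
    }
    phase <- sample(names(truth$phase_props), n_cells, replace = TRUE,
                    prob = truth$phase_props)
    ratio <- stats::rbeta(n_cells, 90, 10)
    m <- cell_matrices(edits, expr, reads = reads, phase = phase,
                       editing_ratio = ratio)
    list(matrices = m,
         truth_cells = list(member = member,
                            sc_class = stats::setNames(cls, gid)))
  })
}

#' Simulate a localization-index time course
#'
#' Gene trajectories follow the planted temporal class: `rising` increases
#' linearly across timepoints, `peaked` is unimodal with its maximum at the
#' middle timepoint, `flat` is constant; Gaussian noise of SD
#' `timecourse_noise_sd` is added. Edit/read profiles realizing the same
#' efficiencies are returned alongside the LI matrix.
#'
#' @param truth A [simulation_truth()] object.
#' @param timepoints Number of timepoints (default 7).
#' @param seed Master seed (substream `"timecourse"`).
#' @param amplitude Half-range of the noise-free trajectories (default 1.2).
#' @param reads Per-gene read count used to realize counts (default 1e4).
#' @param base_efficiency Cytoplasmic reference efficiency (default 0.1).
#' @return list with `li` (gene x timepoint matrix), `classes` (named planted
#'   classes), `edit_counts` and `read_counts` matrices.
#' @export
simulate_timecourse <- function(truth, timepoints = 7, seed = truth$seed,
                                amplitude = 1.2, reads = 1e4,
                                base_efficiency = 0.1) {
  stopifnot(timepoints >= 2)
  cls <- stats::setNames(truth$genes$temporal_class, truth$genes$gene_id)
  shapes <- list(
    rising = seq(-amplitude, amplitude, length.out = timepoints),
    peaked = {
      x <- seq(-2, 2, length.out = timepoints)
      y <- exp(-x^2)
      (y - min(y)) / (max(y) - min(y)) * 2 * amplitude - amplitude
    },
    flat = rep(0, timepoints))
  with_stream(seed, "timecourse", {
    li <- t(vapply(cls, function(k) {
      shapes[[k]] + stats::rnorm(timepoints, 0, truth$timecourse_noise_sd)
    }, numeric(timepoints)))
    colnames(li) <- paste0("t", seq_len(timepoints))
    eff <- base_efficiency * 2^li
    edit_counts <- round(eff * reads)
    read_counts <- matrix(reads, nrow(li), ncol(li), dimnames = dimnames(li))
    list(li = li, classes = cls, edit_counts = edit_counts,
         read_counts = read_counts)
  })
}

#' Simulate per-cell intron/exon coverage with a phase contrast
#'
#' Flanking exon coverages are lognormal around `flank_mean`; intron coverage
#' is the flank mean times the phase's retention level times lognormal noise.
#'
#' @param truth A [simulation_truth()] object (uses `intron_retention` and
#'   `intron_noise_sd`).
#' @param n_cells_per_phase Cells per phase (default 50).
#' @param gene_id,intron_index Feature naming for the emitted table.
#' @param flank_mean Mean flanking-exon coverage (default 20).
#' @param flank_sdlog Lognormal SD of exon coverage (default 0.4).
#' @param seed Master seed (substream `"introns"`).
#' @return list with `coverage` (a feature-coverage data.frame usable by
#'   [intron_ratio()]) and `phases` (data.frame `cell_id`, `phase`).
#' @export
simulate_intron_coverage <- function(truth, n_cells_per_phase = 50,
                                     gene_id = "G0001", intron_index = 1,
                                     flank_mean = 20, flank_sdlog = 0.4,
                                     seed = truth$seed) {
  phases <- names(truth$intron_retention)
  with_stream(seed, "introns", {
    rows <- list()
    ph <- list()
    for (p in phases) {
      for (i in seq_len(n_cells_per_phase)) {
        cell <- sprintf("%s_%03d", p, i)
        up <- stats::rlnorm(1, log(flank_mean), flank_sdlog)
        dn <- stats::rlnorm(1, log(flank_mean), flank_sdlog)
        noise <- if (truth$intron_noise_sd > 0) {
          stats::rlnorm(1, 0, truth$intron_noise_sd)
        } else 1
        intron <- (up + dn) / 2 * truth$intron_retention[[p]] * noise
        rows[[cell]] <- data.frame(
          cell_id = cell, gene_id = gene_id,
          feature = c(paste0("exon_", intron_index),
                      paste0("intron_", intron_index),
                      paste0("exon_", intron_index + 1)),
          mean_coverage = c(up, intron, dn))
        ph[[cell]] <- data.frame(cell_id = cell, phase = p)
      }
    }
    cov <- do.call(rbind, rows)
    rownames(cov) <- NULL
    list(coverage = cov, phases = do.call(rbind, c(ph, make.row.names = FALSE)))
  })
}
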