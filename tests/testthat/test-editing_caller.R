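# Four-filter event calling and the mutation spectrum.

params3 <- caller_params()  # defaults: min_alt 3, >=3 events/transcript, etc.

test_that("a clean transcript with three qualifying sites yields three events", {
  m <- toy_models()
  induced <- rbind(site_row("chr1", 110, "A", A = 47, G = 5),
                   site_row("chr1", 150, "A", A = 40, G = 4),
                   site_row("chr1", 190, "A", A = 30, G = 3))
  ctl <- rbind(site_row("chr1", 110, "A", A = 50),
               site_row("chr1", 150, "A", A = 44),
               site_row("chr1", 190, "A", A = 33))
  ev <- call_events(induced, list(ctl, ctl), m, params3, "A>G")
  expect_equal(nrow(ev), 3)
  expect_equal(ev$editing_ratio, c(5 / 52, 4 / 44, 3 / 33))
  expect_equal(unique(ev$conversion), "A>G")
  expect_equal(ev$gene_id, rep("G1", 3))
})

test_that("control signal, impure sites and sparse transcripts are rejected", {
  m <- toy_models()
  pos4 <- c(110, 150, 190, 230)
  four_ok <- do.call(rbind, lapply(pos4, function(p)
    site_row("chr1", p, "A", A = 40, G = 4)))
  clean_ctl <- function(pos) {
    do.call(rbind, lapply(pos, function(p) site_row("chr1", p, "A", A = 50)))
  }
  # one control carries a single alt read at one site -> that site is lost
  dirty <- clean_ctl(pos4)
  dirty$G[1] <- 1
  dirty$A[1] <- 49
  ev <- call_events(four_ok, list(clean_ctl(pos4), dirty), m, params3, "A>G")
  expect_equal(nrow(ev), 3)
  expect_false(110 %in% ev$position)

  # two SNV types at a site -> purity filter rejects it
  impure <- four_ok
  impure[1, c("A", "G", "C")] <- c(40, 4, 4)
  ev <- call_events(impure, list(clean_ctl(pos4)), m, params3, "A>G")
  expect_equal(nrow(ev), 3)
  expect_false(110 %in% ev$position)

  # exactly two qualifying sites -> the per-transcript floor drops both
  ev <- call_events(four_ok[1:2, ], list(clean_ctl(pos4[1:2])), m, params3,
                    "A>G")
  expect_equal(nrow(ev), 0)

  # sites absent from every control are rejected (with a warning) by default
  expect_warning(
    ev <- call_events(four_ok, list(clean_ctl(pos4[1:3])), m, params3, "A>G"),
    "absent from all controls")
  expect_equal(nrow(ev), 3)
  ev <- call_events(four_ok, list(clean_ctl(pos4[1:3])), m, params3, "A>G",
                    missing_control = "keep")
  expect_equal(nrow(ev), 4)
})

test_that("minus-strand genomic T>C sites are reported as A>G in transcript orientation", {
  plus <- toy_models(strand = "+")
  minus <- toy_models(strand = "-")
  # genomic mirror of an A>G site on the minus strand is T>C
  ind_plus <- rbind(site_row("chr1", 110, "A", A = 47, G = 5),
                    site_row("chr1", 150, "A", A = 40, G = 4),
                    site_row("chr1", 190, "A", A = 30, G = 3))
  ind_minus <- rbind(site_row("chr1", 110, "T", T = 47, C = 5),
                     site_row("chr1", 150, "T", T = 40, C = 4),
                     site_row("chr1", 190, "T", T = 30, C = 3))
  ctl_plus <- do.call(rbind, lapply(c(110, 150, 190), function(p)
    site_row("chr1", p, "A", A = 50)))
  ctl_minus <- do.call(rbind, lapply(c(110, 150, 190), function(p)
    site_row("chr1", p, "T", T = 50)))
  ev_p <- call_events(ind_plus, list(ctl_plus), plus, params3, "A>G")
  ev_m <- call_events(ind_minus, list(ctl_minus), minus, params3, "A>G")
  expect_equal(ev_m$conversion, ev_p$conversion)
  expect_equal(ev_m$alt_count, ev_p$alt_count)
  expect_equal(ev_m$ref, c("T", "T", "T"))
  expect_equal(ev_m$alt, c("C", "C", "C"))
})

test_that("caller matches the brute-force four-filter oracle on random tables", {
  tx <- make_transcriptome(n_genes = 10, seed = 21)
  grid <- expand.grid(min_alt = c(2, 3), control_max_alt = c(0, 1),
                      min_event_ratio = c(0.01, 0.05),
                      chem = c("A>G", "C>T"), stringsAsFactors = FALSE)
  set.seed(404)
  for (rep in 1:20) {
    tabs <- random_site_tables(tx$models, n_sites = sample(50:150, 1))
    g <- grid[sample.int(nrow(grid), 1), ]
    p <- caller_params(min_alt = g$min_alt, control_max_alt = g$control_max_alt,
                       min_event_ratio = g$min_event_ratio)
    got <- suppressWarnings(
      call_events(tabs$induced, tabs$controls, tx$models, p, g$chem))
    want <- oracle_call_events(tabs$induced, tabs$controls, tx$models, p, g$chem)
    expect_identical(event_key(got), event_key(want))
  }
})

test_that("tightening thresholds never enlarges the event set", {
  tx <- make_transcriptome(n_genes = 10, seed = 22)
  set.seed(77)
  tabs <- random_site_tables(tx$models, n_sites = 150)
  base <- suppressWarnings(call_events(tabs$induced, tabs$controls, tx$models,
                                       caller_params(min_alt = 2), "A>G"))
  for (p in list(caller_params(min_alt = 4),
                 caller_params(min_alt = 2, min_event_ratio = 0.1),
                 caller_params(min_alt = 2, min_events_per_transcript = 5))) {
    tighter <- suppressWarnings(
      call_events(tabs$induced, tabs$controls, tx$models, p, "A>G"))
    expect_true(all(event_key(tighter) %in% event_key(base)))
  }
})

test_that("planted edits are recovered exactly when controls are clean", {
  tx <- make_transcriptome(n_genes = 15, seed = 5)
  truth <- simulation_truth(n_genes = 15, seed = 5, edit_rate = 0.5,
                            control_error = 0,
                            membership_props = c(compartment_enriched = 1,
                                                 background = 0,
                                                 cytoplasm_only = 0,
                                                 unexpressed = 0))
  b <- simulate_bulk(truth, tx$models, tx$genome)
  ev <- call_events(b$induced, b$controls, tx$models, params3, "A>G")
  # precision: every event is a planted site
  key_ev <- paste(ev$contig, ev$position)
  key_truth <- paste(b$sites$contig, b$sites$position)
  expect_true(all(key_ev %in% key_truth))
  # recall: every planted site meeting the thresholds, on a transcript with
  # >=3 such sites, is called
  s <- b$sites
  s$ratio <- ifelse(s$depth > 0, s$alt_count / s$depth, 0)
  qual <- s[s$alt_count >= 3 & s$ratio > 0.01, ]
  n_qual <- table(qual$transcript_id)
  expected <- qual[qual$transcript_id %in% names(n_qual)[n_qual >= 3], ]
  expect_setequal(key_ev, paste(expected$contig, expected$position))
})

test_that("mutation spectrum covers the 12 classes and sums to one", {
  snvs <- data.frame(ref = c(rep("A", 9), "C"), alt = c(rep("G", 9), "T"))
  sp <- mutation_spectrum(snvs)
  expect_equal(nrow(sp), 12)
  expect_equal(sum(sp$fraction), 1)
  expect_equal(sp$fraction[sp$conversion == "A>G"], 0.9)
  expect_equal(sp$fraction[sp$conversion == "C>T"], 0.1)

  one <- mutation_spectrum(data.frame(conversion = rep("C>T", 5)))
  expect_equal(one$fraction[one$conversion == "C>T"], 1)
  expect_equal(sum(one$fraction), 1)

  expect_error(mutation_spectrum(data.frame(ref = character(0),
                                            alt = character(0))),
               "empty")
})
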