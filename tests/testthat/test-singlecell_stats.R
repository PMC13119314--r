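# Single-cell QC, detection rates, shuffle null and chi-square GOF.

test_that("cell matrices enforce their invariants", {
  e <- matrix(0L, 2, 3, dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  x <- matrix(1e6 / 3, 2, 3, dimnames = dimnames(e))
  expect_s3_class(cell_matrices(e, x), "cell_matrices")
  bad <- x; bad[1, ] <- bad[1, ] * 2
  expect_error(cell_matrices(e, bad), "1%")
  neg <- e; neg[1, 1] <- -1
  expect_error(cell_matrices(neg, x), "nonnegative")
})

test_that("QC boundary cells fall exactly where the contract says", {
  # 6 cells: detected genes straddle the 9,000 floor; edited genes include a
  # value exactly on the upper fence (kept) and an extreme outlier (removed)
  detected <- c(8999, 9000, 12000, 12000, 12000, 12000)
  edited <- c(500, 100, 200, 300, 400, 5000)
  n_genes <- 13000
  expr <- t(vapply(detected, function(d) {
    v <- c(rep(1, d), rep(0, n_genes - d))
    v / sum(v) * 1e6
  }, numeric(n_genes)))
  edits <- t(vapply(edited, function(k) {
    c(rep(3L, k), rep(0L, n_genes - k))
  }, integer(n_genes)))
  dimnames(expr) <- dimnames(edits) <-
    list(paste0("c", 1:6), paste0("g", seq_len(n_genes)))
  m <- cell_matrices(edits, expr)

  res <- qc_filter_cells(m, mode = "NES")
  qc <- res$qc
  expect_false(qc$pass[1])
  expect_equal(qc$reason[1], "min_genes")
  # among survivors {100,200,300,400,5000}: Q1=200, Q3=400, fences [-100, 700]
  expect_true(all(qc$pass[2:5]))
  expect_false(qc$pass[6])
  expect_equal(qc$reason[6], "edited_genes_iqr")
  expect_equal(rownames(res$matrices$edits), paste0("c", 2:5))

  # ERM mode: the 200-gene floor is a strict < comparison
  res_erm <- qc_filter_cells(m, mode = "ERM")
  expect_false(res_erm$qc$pass[2])  # cell c2: 100 edited genes < 200
  expect_equal(res_erm$qc$reason[2], "min_edited_genes")
  expect_true(res_erm$qc$pass[3])       # exactly 200 is kept
})

test_that("QC matches a brute-force reimplementation on random cell tables", {
  set.seed(515)
  for (rep in 1:30) {
    n_cells <- sample(8:30, 1)
    n_genes <- 11000
    detected <- sample(8500:10500, n_cells, replace = TRUE)
    edited <- sample(0:1200, n_cells, replace = TRUE)
    ratio <- runif(n_cells, 0.5, 1)
    expr <- t(vapply(detected, function(d) {
      v <- c(rep(1, d), rep(0, n_genes - d)); v / sum(v) * 1e6
    }, numeric(n_genes)))
    edits <- t(vapply(edited, function(k) {
      c(rep(3L, k), rep(0L, n_genes - k))
    }, integer(n_genes)))
    dimnames(expr) <- dimnames(edits) <-
      list(sprintf("c%02d", seq_len(n_cells)), paste0("g", seq_len(n_genes)))
    m <- cell_matrices(edits, expr, editing_ratio = ratio)
    mode <- sample(c("NES", "ERM"), 1)
    got <- tryCatch(qc_filter_cells(m, mode = mode)$qc$pass,
                    error = function(e) "error")
    if (identical(got, "error")) {
      expect_lt(sum(detected >= 9000), 4)
      next
    }
    want <- oracle_qc_pass(detected, edited, ratio, mode)
    expect_identical(got, want)
  }
})

test_that("detection rates count cells with at least three edits", {
  edits <- rbind(matrix(3L, 4, 3), matrix(0L, 6, 3))
  edits[, 2] <- 2L
  edits[, 3] <- 5L
  m <- quick_cells(edits)
  r <- detection_rates(m)
  expect_equal(unname(r), c(0.4, 0, 1))
})

test_that("rate binning uses left-closed decile bins with a closed top", {
  r <- c(a = 0.05, b = 0.05, c = 0.95, d = 0.1, e = 1.0, f = 0)
  b <- bin_rates(r)
  expect_equal(b$count[1], 2)
  expect_equal(b$count[2], 1)   # 0.1 goes to [0.1, 0.2)
  expect_equal(b$count[10], 2)  # 0.95 and the closed-top 1.0
  expect_equal(attr(b, "zero_rate_genes"), "f")
  expect_equal(sum(b$count), sum(r > 0))
})

test_that("shuffling conserves per-cell totals and applies the retention rule", {
  set.seed(66)
  n_cells <- 6; n_genes <- 40
  expr <- matrix(rlnorm(n_cells * n_genes), n_cells, n_genes)
  expr <- expr / rowSums(expr) * 1e6
  edits <- matrix(rpois(n_cells * n_genes, 1.5), n_cells, n_genes)
  dimnames(expr) <- dimnames(edits) <-
    list(paste0("c", 1:n_cells), paste0("g", 1:n_genes))
  m <- cell_matrices(edits, expr)

  # reproduce one shuffle by hand from the same substream and check totals
  # and the >=3-in-at-least-one-cell retention, brute force
  totals <- rowSums(edits)
  sim <- withr::with_seed(substream_seed(99, "shuffle1"), {
    t(vapply(seq_len(n_cells), function(c) {
      as.numeric(rmultinom(1, totals[c], expr[c, ] / sum(expr[c, ])))
    }, numeric(n_genes)))
  })
  expect_equal(rowSums(sim), totals, ignore_attr = TRUE)
  retained <- which(apply(sim, 2, function(g) any(g >= 3)))
  rates <- colMeans(sim[, retained, drop = FALSE] >= 3)
  want <- tabulate(findInterval(rates, seq(0, 1, 0.1), rightmost.closed = TRUE),
                   10)
  got <- shuffle_null(m, n_shuffles = 1, seed = 99)
  expect_equal(got$per_shuffle[, 1], want)

  # a cell expressing a single gene puts all its edits there
  e1 <- matrix(c(5L, 0L), 1, 2, dimnames = list("c1", c("g1", "g2")))
  x1 <- matrix(c(1e6, 0), 1, 2, dimnames = dimnames(e1))
  got1 <- shuffle_null(cell_matrices(e1, x1), n_shuffles = 2, seed = 4)
  expect_equal(got1$bins$shuffled_mean[10], 1)  # g1 at rate 1.0 every shuffle
  expect_equal(sum(got1$bins$shuffled_mean), 1)

  # zero-TPM cell is an error naming the cell
  x0 <- x1; x0[1, ] <- 0
  expect_error(shuffle_null(cell_matrices(e1, x0, validate = FALSE)), "c1")
})

test_that("simulated multinomial edits match binomial moments under uniform TPM", {
  set.seed(202)
  G <- 20; N <- 60; n_cells <- 1000
  expr <- matrix(1e6 / G, n_cells, G,
                 dimnames = list(paste0("c", 1:n_cells), paste0("g", 1:G)))
  edits <- matrix(0L, n_cells, G, dimnames = dimnames(expr))
  for (c in seq_len(n_cells)) edits[c, ] <- rmultinom(1, N, rep(1 / G, G))
  # per-gene counts are Binomial(N, 1/G): mean 3, var 3*(1-1/G)
  mu <- N / G; v <- N * (1 / G) * (1 - 1 / G)
  expect_lt(abs(mean(edits[, 1]) - mu), 3 * sqrt(v / n_cells))
  expect_lt(abs(var(edits[, 1]) - v), 3 * v * sqrt(2 / (n_cells - 1)))
})

test_that("chi-square GOF matches hand computation and merges sparse bins", {
  ident <- chisq_gof(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)

  hand <- chisq_gof(c(8, 2), c(5, 5))
  expect_equal(hand$statistic, 3.6)
  expect_equal(hand$df, 1)
  expect_equal(hand$p.value, pchisq(3.6, 1, lower.tail = FALSE))

  # a zero-expected zero-observed bin merges away and df drops
  merged <- chisq_gof(c(8, 2, 0), c(5, 5, 0))
  expect_equal(merged$df, 1)
  expect_equal(merged$statistic, 3.6)
  expect_gte(merged$n_merged, 1)

  # expected rescaled to the observed total before comparison
  scaled <- chisq_gof(c(16, 4), c(50, 50))
  expect_equal(scaled$statistic, 7.2)
})

test_that("occurrence overlap reports per-bin bulk fractions", {
  rates <- c(a = 0.05, b = 0.15, c = 0.18, d = 0.95)
  all_in <- occurrence_overlap(rates, c("a", "b", "c", "d"))
  expect_equal(all_in$overlap_fraction[!is.na(all_in$overlap_fraction)],
               c(1, 1, 1))
  none <- occurrence_overlap(rates, "zz")
  expect_equal(none$overlap_fraction[!is.na(none$overlap_fraction)], c(0, 0, 0))
  some <- occurrence_overlap(rates, c("b", "d"))
  expect_equal(some$overlap_fraction[2], 0.5)
  expect_equal(some$overlap_fraction[10], 1)
})

test_that("core genes are detected in most cells and null data passes the test", {
  truth <- simulation_truth(n_genes = 300, seed = 303)
  sc <- simulate_cells(truth, n_cells = 200, with_reads = FALSE)
  rates <- detection_rates(sc$matrices)
  core <- rates[sc$truth_cells$sc_class == "core"]
  expect_gte(mean(core), 0.9)
  rare <- rates[sc$truth_cells$sc_class == "rare"]
  expect_lt(mean(rare), 0.1)

  null_truth <- simulation_truth(n_genes = 300, seed = 304, core_frac = 0,
                                 rare_frac = 0)
  scn <- simulate_cells(null_truth, n_cells = 50, with_reads = FALSE)
  res <- detection_rate_test(scn$matrices, seed = 7)
  expect_gt(res$chisq$p.value, 0.05)
})
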