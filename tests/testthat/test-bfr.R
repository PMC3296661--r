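test_that("informative base frequency is count over column depth", {
  col <- pileup_row("u1", 1, "C", C = 9, G = 1)
  expect_equal(informative_base_frequency(col, "G"), 0.1)
  expect_equal(informative_base_frequency(col, "A"), 0)
  expect_equal(informative_base_frequency(pileup_row("u1", 2, "T", T = 7),
                                          "T"), 1)
  # the default denominator includes non-substitution symbols
  col <- pileup_row("u1", 3, "C", C = 8, G = 1, n_other = 1)
  expect_equal(informative_base_frequency(col, "G"), 0.1)
  expect_equal(informative_base_frequency(col, "G", denominator = "acgt"),
               1 / 9)
  # zero depth has no defined frequency
  expect_true(is.na(informative_base_frequency(pileup_row("u1", 4, "C"),
                                               "G")))
})

test_that("BFR orientation follows the informative base's parent of origin", {
  # high-parent marker: enrichment shows as f_high over f_low
  expect_equal(bulk_frequency_ratio(0.397, 0.017, origin = "B"),
               0.397 / 0.017)
  # low-parent marker with empty denominator: divide-by-zero exclusion
  expect_true(is.na(bulk_frequency_ratio(0, 0.4, origin = "A")))
  # both zero: excluded
  expect_true(is.na(bulk_frequency_ratio(0, 0, origin = "A")))
  expect_true(is.na(bulk_frequency_ratio(0, 0, origin = "B")))
  # no enrichment in either orientation
  expect_equal(bulk_frequency_ratio(0.25, 0.25, origin = "A"), 1)
  expect_equal(bulk_frequency_ratio(0.25, 0.25, origin = "B"), 1)
  # swapping the bulks and the origin label leaves the ratio unchanged
  set.seed(5)
  fh <- runif(50); fl <- runif(50)
  org <- sample(c("A", "B"), 50, replace = TRUE)
  swapped <- ifelse(org == "A", "B", "A")
  expect_equal(bulk_frequency_ratio(fh, fl, org),
               bulk_frequency_ratio(fl, fh, swapped))
})

make_screen_fixture <- function() {
  snps <- data.frame(
    unigene_id = c("u1", "u1", "u2", "u3"), pos = c(10L, 40L, 5L, 8L),
    snp_type = c("hemi", "hemi", "simple", "hemi"),
    genotype_a = c("S", "Y", "T", "C"), genotype_b = c("C", "C", "G", "M"),
    informative_base = c("G", "T", "T", "A"), origin = c("A", "A", "A", "B"),
    shared_base = c("C", "C", NA, "C"), depth_a = 20L, depth_b = 20L,
    stringsAsFactors = FALSE)
  high <- pileup_table(
    pileup_row("u1", 10, "C", C = 18, G = 2),        # f(G) = 0.1
    pileup_row("u1", 40, "C", C = 12, T = 4),        # f(T) = 0.25
    pileup_row("u2", 5, "T", G = 10))                # f(T) = 0
  low <- pileup_table(
    pileup_row("u1", 10, "C", C = 10, G = 10),       # f(G) = 0.5
    pileup_row("u1", 40, "C", C = 9, T = 3),         # f(T) = 0.25
    pileup_row("u2", 5, "T", T = 9, G = 3))          # f(T) = 0.75
  list(snps = snps, high = high, low = low)
}

test_that("bsa_screen computes oriented ratios with depth and zero flags", {
  fx <- make_screen_fixture()
  rec <- bsa_screen(fx$snps, fx$high, fx$low, min_depth = 8, threshold = 3)
  expect_equal(nrow(rec), 4L)

  r1 <- rec[rec$unigene_id == "u1" & rec$pos == 10, ]
  expect_equal(r1$bfr, 0.5 / 0.1)   # origin A: low over high
  expect_true(r1$passes_depth)
  expect_true(r1$passes_threshold)

  r2 <- rec[rec$unigene_id == "u1" & rec$pos == 40, ]
  expect_equal(r2$bfr, 1)
  expect_false(r2$passes_threshold)

  # informative base absent from the denominator bulk: excluded, not ranked
  r3 <- rec[rec$unigene_id == "u2", ]
  expect_true(is.na(r3$bfr))
  expect_true(r3$excluded)
  expect_false(r3$passes_threshold)

  # SNP absent from both bulk pileups: no coverage, fails depth
  r4 <- rec[rec$unigene_id == "u3", ]
  expect_false(r4$passes_depth)
  expect_equal(r4$depth_high, 0L)
  expect_true(is.na(r4$excluded))
})

test_that("every screened BFR equals a brute-force recount from pileups", {
  set.seed(21)
  sim <- simulate_bsa_experiment(sim_config(n_unigenes = 10,
                                            length_mean = 600, seed = 33))
  rec <- bsa_screen(sim$truth$snps, sim$pileups$high, sim$pileups$low)
  expect_gt(nrow(rec), 3)
  for (i in seq_len(nrow(rec))) {
    oracle <- brute_force_bfr(rec[i, ], sim$pileups$high, sim$pileups$low)
    if (is.na(oracle)) expect_true(is.na(rec$bfr[i]))
    else expect_equal(rec$bfr[i], oracle)
  }
})

test_that("one SNP per unigene selects the best-covered, earliest position", {
  fx <- make_screen_fixture()
  rec <- bsa_screen(fx$snps, fx$high, fx$low, one_per_unigene = TRUE)
  expect_equal(nrow(rec), 3L)
  # u1: min depth is 20 at pos 10 vs 12 at pos 40
  expect_equal(rec$pos[rec$unigene_id == "u1"], 10L)

  # tie on coverage: smallest position wins
  high <- pileup_table(pileup_row("u9", 3, "C", C = 10, G = 2),
                       pileup_row("u9", 6, "C", C = 10, G = 2))
  low <- pileup_table(pileup_row("u9", 3, "C", C = 6, G = 6),
                      pileup_row("u9", 6, "C", C = 6, G = 6))
  snps <- data.frame(unigene_id = "u9", pos = c(6L, 3L), snp_type = "hemi",
                     genotype_a = "S", genotype_b = "C",
                     informative_base = "G", origin = "A",
                     shared_base = "C", depth_a = 20L, depth_b = 20L,
                     stringsAsFactors = FALSE)
  rec <- bsa_screen(snps, high, low, one_per_unigene = TRUE)
  expect_equal(rec$pos, 3L)
})

test_that("raising min_depth never increases depth-passing records", {
  sim <- simulate_bsa_experiment(sim_config(n_unigenes = 15,
                                            length_mean = 500,
                                            mean_depth = 14, seed = 9))
  counts <- vapply(c(8, 12, 16), function(d) {
    rec <- bsa_screen(sim$truth$snps, sim$pileups$high, sim$pileups$low,
                      min_depth = d)
    sum(rec$passes_depth)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold summary counts inclusively among ranked records", {
  rec <- data.frame(
    unigene_id = paste0("u", 1:5), pos = 1:5, snp_type = "hemi",
    origin = "A", informative_base = "G", f_high = 0.1, f_low = 0.3,
    depth_high = 20L, depth_low = 20L, bfr = c(1, 2, 3, 4, 5),
    excluded = FALSE, passes_depth = TRUE, passes_threshold = NA,
    stringsAsFactors = FALSE)
  s <- threshold_summary(rec, thresholds = c(2, 3))
  expect_equal(s$n_snps, c(4L, 3L))
  expect_equal(s$pct, c(80, 60))

  # a record at exactly the cutoff is counted
  one <- rec[3, ]
  expect_equal(threshold_summary(one, 3)$n_snps, 1L)

  # excluded and depth-failing records are outside the denominator
  rec$excluded[1:2] <- TRUE
  rec$passes_depth[5] <- FALSE
  s <- threshold_summary(rec, c(2, 3))
  expect_equal(s$n_snps, c(2L, 2L))
  expect_equal(s$pct, c(100, 100))

  # all excluded: zero counts, zero percentages
  rec$excluded <- TRUE
  s <- threshold_summary(rec, c(2, 3))
  expect_equal(s$n_snps, c(0L, 0L))
  expect_equal(s$pct, c(0, 0))
})
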