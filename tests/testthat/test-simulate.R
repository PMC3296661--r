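test_that("homoeologue pairs diverge at the configured identity", {
  # perfect identity: no IHPs, identical copies
  pair <- simulate_homoeologue_pair(500, 1.0, seed = 4)
  expect_equal(length(pair$ihp_pos), 0L)
  expect_equal(pair$seq_a, pair$seq_b)
  expect_equal(nchar(pair$seq_a), 500L)

  # divergent count inside the central 99% binomial interval
  pair <- simulate_homoeologue_pair(10000, 0.97, seed = 4)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.03)
  expect_gte(length(pair$ihp_pos), bounds[1])
  expect_lte(length(pair$ihp_pos), bounds[2])
  # divergent positions really differ, others do not
  a <- strsplit(pair$seq_a, "")[[1]]; b <- strsplit(pair$seq_b, "")[[1]]
  expect_equal(which(a != b), pair$ihp_pos)

  # determinism under an explicit seed
  expect_identical(simulate_homoeologue_pair(800, 0.97, seed = 12),
                   simulate_homoeologue_pair(800, 0.97, seed = 12))
})

test_that("bulks are pure for the target locus and mixed away from it", {
  cfg <- sim_config(interval_cM = 12.2, target_locus_cM = 6.1, seed = 3)
  lines <- simulate_cross(cfg, seed = 3)
  expect_equal(sum(lines$bulk == "high"), 14L)
  expect_equal(sum(lines$bulk == "low"), 15L)
  expect_true(all(lines$breakpoint_cM >= 0 & lines$breakpoint_cM <= 12.2))

  g_target <- cross_genotype(lines, 6.1)[, 1]
  expect_true(all(g_target[lines$bulk == "high"]))
  expect_false(any(g_target[lines$bulk == "low"]))

  # a marker exactly at the target has identical allele dosage
  expect_equal(cross_genotype(lines, 6.1), cross_genotype(lines, 6.1))

  # the wrong-bulk donor dosage at distance d matches direct enumeration
  # over breakpoints and grows linearly in d under uniform breakpoints
  set.seed(31)
  dists <- c(0.5, 2, 5)
  wrong <- sapply(dists, function(d) {
    mean(replicate(300, {
      ln <- simulate_cross(cfg)
      g <- cross_genotype(ln, 6.1 - d)[, 1]
      # donor alleles leaking into the low bulk: lines whose breakpoint
      # falls between marker and target
      mean(g[ln$bulk == "low"])
    }))
  })
  expect_lt(max(abs(wrong - dists / 12.2)), 0.02)
  expect_true(all(diff(wrong) > 0))
})

test_that("zero-error parent pileups contain only planted bases", {
  cfg <- sim_config(n_unigenes = 8, length_mean = 500, error_rate = 0,
                    expression_sdlog = 0, mean_depth = 30, seed = 6)
  sim <- simulate_bsa_experiment(cfg)
  hap <- sim$haplotypes
  for (s in c("parent_a", "parent_b")) {
    p <- sim$pileups[[s]]
    key <- paste(p$unigene_id, p$pos)
    hk <- paste(sim$unigenes$unigene_id[hap$uidx], hap$pos)
    idx <- match(key, hk)
    h1 <- hap[[if (s == "parent_a") "a1" else "b1"]][idx]
    h2 <- hap[[if (s == "parent_a") "a2" else "b2"]][idx]
    m <- as.matrix(p[, c("A", "C", "G", "T")])
    allowed <- matrix(FALSE, nrow(p), 4)
    allowed[cbind(seq_len(nrow(p)), h1)] <- TRUE
    ok <- !is.na(h2)
    allowed[cbind(which(ok), h2[ok])] <- TRUE
    expect_equal(sum(m[!allowed]), 0L)
    expect_equal(p$n_other, rep(0L, nrow(p)))
  }
})

test_that("hemi-SNP informative base tends to half under balanced expression", {
  cfg <- sim_config(n_unigenes = 6, length_mean = 800, error_rate = 0,
                    expression_sdlog = 0, mean_depth = 200,
                    p_single_copy = 0, seed = 16)
  sim <- simulate_bsa_experiment(cfg)
  hemi <- sim$truth$snps[sim$truth$snps$snp_type == "hemi", ]
  expect_gt(nrow(hemi), 5)
  carrier <- ifelse(hemi$planted_parent == "A", "parent_a", "parent_b")
  f <- mapply(function(u, pos, base, smp) {
    p <- sim$pileups[[smp]]
    row <- p[p$unigene_id == u & p$pos == pos, ]
    row[[base]] / row$depth
  }, hemi$unigene_id, hemi$pos, hemi$informative_base, carrier)
  expect_lt(abs(mean(f) - 0.5), 0.05)
})

test_that("mpileup rendering round-trips with exact count agreement", {
  sim <- simulate_bsa_experiment(sim_config(n_unigenes = 4,
                                            length_mean = 400, seed = 10))
  p <- sim$pileups$high
  lines <- write_mpileup(p)
  back <- read_pileup(text = lines)
  rownames(p) <- NULL
  expect_equal(back, p)
})

test_that("the same seed reproduces the experiment byte for byte", {
  cfg <- sim_config(n_unigenes = 5, length_mean = 400, seed = 77)
  s1 <- simulate_bsa_experiment(cfg)
  s2 <- simulate_bsa_experiment(cfg)
  expect_identical(s1$pileups, s2$pileups)
  expect_identical(s1$truth$snps, s2$truth$snps)
  expect_identical(s1$reference, s2$reference)

  d1 <- tempfile(); d2 <- tempfile()
  write_sim(s1, d1); write_sim(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("a planted collapsed paralogue is removed by the density filter", {
  cfg <- sim_config(n_unigenes = 12, length_mean = 1000, error_rate = 0,
                    expression_sdlog = 0, n_collapsed_paralogues = 2,
                    paralogue_divergence_per_kb = 12, seed = 23)
  sim <- simulate_bsa_experiment(cfg)
  paralogues <- sim$unigenes$unigene_id[sim$unigenes$collapsed_paralogue]
  expect_equal(length(paralogues), 2L)

  lengths <- sim$unigenes[, c("unigene_id", "length_bp")]
  res <- snp_density_filter(sim$truth$snps, lengths, max_density = 5)
  # realised planted density on these unigenes is far above the cutoff
  rep <- res$report[res$report$unigene_id %in% paralogues, ]
  expect_true(all(!rep$retained))
  expect_false(any(res$snps$unigene_id %in% paralogues))
})

test_that("regenerated sample pileups honour overrides and seeds", {
  sim <- simulate_bsa_experiment(sim_config(n_unigenes = 3,
                                            length_mean = 300, seed = 2))
  a <- simulate_pileup(sim, "high", seed = 5)
  b <- simulate_pileup(sim, "high", seed = 5)
  expect_identical(a, b)
  deep <- simulate_pileup(sim, "high", mean_depth = 200, seed = 5)
  expect_gt(mean(deep$pileup$depth), 2 * mean(a$pileup$depth))
})
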