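# Seeded simulator for a tetraploid transcriptome BSA experiment.
#
# The generated world: unigenes are consensus transcripts onto which both
# homoeologous gene copies co-map. Most unigenes carry a homoeologue pair
# diverged at ~3% of sites (inter-homoeologue polymorphisms, IHPs); a
# fraction express a single copy. Varietal SNPs distinguish the two parents:
# on a duplicated unigene the variant sits on one homoeologue of one parent
# (a hemi-SNP), on a single-copy unigene the parents carry different bases
# (a simple SNP). A panel of homozygous recombinant lines, each with a
# single crossover at a uniform position in the mapped interval, is bulked
# by phenotype at a target locus; reads are multinomial draws from each
# sample's allele mixture with a uniform per-base error, at Poisson depth
# scaled by a log-normal per-unigene expression weight.

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale analogue of a fine-mapping experiment in
#' tetraploid wheat: ~97% homoeologue identity, 2 varietal SNPs/kb in
#' polymorphic unigenes, a 12.2 cM interval with bulks of 14 (high) and 15
#' (low) recombinant lines, balanced homoeologue expression, moderate
#' log-normal expression dispersion.
#'
#' @param n_unigenes Number of unigenes.
#' @param length_mean,length_sdlog Log-normal unigene length parameters
#'   (bp); lengths are floored at 300 bp.
#' @param homoeologue_identity Sequence identity between homoeologues.
#' @param p_single_copy Fraction of unigenes expressing one homoeologue
#'   only (their varietal SNPs are simple SNPs).
#' @param prop_linked Fraction of unigenes whose locus lies inside the
#'   mapped interval.
#' @param varietal_snp_rate Varietal SNPs per kb in polymorphic unigenes.
#' @param interval_cM Genetic length of the mapped interval.
#' @param target_locus_cM Position of the selected locus (default:
#'   interval midpoint).
#' @param n_lines_high,n_lines_low Bulk sizes (recombinant lines).
#' @param line_weights_high,line_weights_low Per-line RNA weights in each
#'   bulk (default equal; doubling a line emulates unequal pooling).
#' @param homoeologue_ratio Expression share of the first homoeologue
#'   (0.5 = parity).
#' @param expression_sdlog Log-normal sd of per-unigene expression weights
#'   (0 disables dispersion).
#' @param mean_depth Mean per-position read depth at expression weight 1.
#' @param error_rate Per-base sequencing error (uniform to other bases).
#' @param read_sampling `"binomial"` draws each column's base counts
#'   multinomially from the sample's allele mixture (the realistic model);
#'   `"expected"` apportions the column depth deterministically in
#'   proportion to the mixture (largest-remainder rounding), defining the
#'   noise-free limit in which consensus calls recover planted genotypes
#'   exactly at every covered position.
#' @param n_collapsed_paralogues Unigenes planted as collapsed paralogues:
#'   apparent varietal SNPs at `paralogue_divergence_per_kb`, for testing
#'   the SNP-density filter.
#' @param paralogue_divergence_per_kb Apparent SNP rate in collapsed
#'   paralogues.
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_unigenes = 50, length_mean = 2000,
                       length_sdlog = 0.25, homoeologue_identity = 0.97,
                       p_single_copy = 0.2, prop_linked = 0.3,
                       varietal_snp_rate = 2, interval_cM = 12.2,
                       target_locus_cM = interval_cM / 2,
                       n_lines_high = 14, n_lines_low = 15,
                       line_weights_high = rep(1, n_lines_high),
                       line_weights_low = rep(1, n_lines_low),
                       homoeologue_ratio = 0.5, expression_sdlog = 0.5,
                       mean_depth = 50, error_rate = 0.005,
                       read_sampling = c("binomial", "expected"),
                       n_collapsed_paralogues = 0,
                       paralogue_divergence_per_kb = 8, seed = 1) {
  read_sampling <- match.arg(read_sampling)
  stopifnot(n_unigenes >= 1, length_mean > 0,
            homoeologue_identity > 0, homoeologue_identity <= 1,
            p_single_copy >= 0, p_single_copy <= 1,
            prop_linked >= 0, prop_linked <= 1,
            varietal_snp_rate >= 0, interval_cM > 0,
            target_locus_cM >= 0, target_locus_cM <= interval_cM,
            n_lines_high >= 1, n_lines_low >= 1,
            length(line_weights_high) == n_lines_high,
            length(line_weights_low) == n_lines_low,
            homoeologue_ratio > 0, homoeologue_ratio < 1,
            expression_sdlog >= 0, mean_depth > 0,
            error_rate >= 0, error_rate < 1,
            n_collapsed_paralogues >= 0,
            n_collapsed_paralogues <= n_unigenes)
  structure(as.list(environment()), class = "sim_config")
}

.rand_dna_idx <- function(n) sample.int(4L, n, replace = TRUE)

#' Simulate one homoeologous transcript pair
#'
#' The second copy diverges from the first at each site independently with
#' probability `1 - identity`, substitutions uniform over the three
#' alternative bases.
#'
#' @param length Transcript length in bp.
#' @param identity Sequence identity in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return List with `seq_a`, `seq_b` (character strings) and `ihp_pos`
#'   (1-based divergent positions).
#' @export
simulate_homoeologue_pair <- function(length, identity, seed = NULL) {
  stopifnot(length > 0, identity > 0, identity <= 1)
  .with_seed(seed, {
    a <- .rand_dna_idx(length)
    b <- a
    mut <- which(stats::runif(length) < 1 - identity)
    if (length(mut))
      b[mut] <- ((b[mut] - 1L + sample.int(3L, length(mut),
                                           replace = TRUE)) %% 4L) + 1L
    list(seq_a = paste(.BASES[a], collapse = ""),
         seq_b = paste(.BASES[b], collapse = ""),
         ihp_pos = mut)
  })
}

#' Simulate a recombinant-line cross and its phenotype bulks
#'
#' Each line is homozygous with exactly one crossover, at a uniform position
#' in the interval; one flank carries the donor (parent B) segment, the
#' other the recurrent (parent A) segment, so the line's genotype at the
#' target locus determines its phenotype and hence its bulk.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return Data.frame of lines: `line_id`, `bulk`, `weight`,
#'   `breakpoint_cM`, `left_donor` (is the left flank the donor segment).
#' @export
simulate_cross <- function(config, seed = NULL) {
  L <- config$interval_cM; t <- config$target_locus_cM
  draw <- function(n, donor_at_target) {
    # left-donor lines are donor at t iff breakpoint > t; sampling the
    # orientation with its conditional probability keeps breakpoints
    # uniform on the whole interval
    p_left <- if (donor_at_target) (L - t) / L else t / L
    left <- stats::runif(n) < p_left
    bp <- numeric(n)
    hi <- if (donor_at_target) left else !left
    bp[hi] <- stats::runif(sum(hi), t, L)
    bp[!hi] <- stats::runif(sum(!hi), 0, t)
    data.frame(bulk = if (donor_at_target) "high" else "low",
               breakpoint_cM = bp, left_donor = left,
               stringsAsFactors = FALSE)
  }
  .with_seed(seed, {
    lines <- rbind(draw(config$n_lines_high, TRUE),
                   draw(config$n_lines_low, FALSE))
    lines$weight <- c(config$line_weights_high, config$line_weights_low)
    lines$line_id <- sprintf("RSL%02d", seq_len(nrow(lines)))
    lines[, c("line_id", "bulk", "weight", "breakpoint_cM", "left_donor")]
  })
}

#' Genotypes of recombinant lines at mapped positions
#'
#' @param lines Line table from [simulate_cross()].
#' @param map_cM Vector of map positions inside the interval.
#' @return Logical matrix (lines x positions): `TRUE` where the line
#'   carries the donor (parent B) allele.
#' @export
cross_genotype <- function(lines, map_cM) {
  left_of_bp <- outer(lines$breakpoint_cM, map_cM, `>`)
  donor <- left_of_bp == lines$left_donor   # recycles by row
  dimnames(donor) <- list(lines$line_id, NULL)
  donor
}

# weighted donor dosage of each bulk at given map positions
.bulk_dosage_linked <- function(lines, map_cM) {
  g <- cross_genotype(lines, map_cM)
  dose <- function(b) {
    w <- lines$weight[lines$bulk == b]
    colSums(g[lines$bulk == b, , drop = FALSE] * w) / sum(w)
  }
  list(high = dose("high"), low = dose("low"))
}

#' Simulate a complete bulked-segregant experiment
#'
#' Generates the reference, parental haplotypes, recombinant lines, bulks
#' and all four sample pileups, together with complete ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `bsa_sim`: `config`, `unigenes` (with length,
#'   duplication/linkage status, map position, expression weight, bulk
#'   dosages), `lines`, `truth` (planted varietal SNPs in scan-output
#'   layout plus provenance columns, and IHP positions), `pileups`
#'   (data.frames for `parent_a`, `parent_b`, `high`, `low`), `counts`
#'   (mapped read-equivalents per unigene per sample) and `reference`
#'   (named character vector of unigene sequences).
#' @export
simulate_bsa_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  n <- cfg$n_unigenes
  len <- pmax(300L, as.integer(round(stats::rlnorm(
    n, log(cfg$length_mean), cfg$length_sdlog))))
  ids <- sprintf("UG%04d", seq_len(n))
  duplicated_ug <- stats::runif(n) >= cfg$p_single_copy
  n_linked <- round(cfg$prop_linked * n)
  linked <- seq_len(n) %in% sample.int(n, n_linked)
  map_cM <- ifelse(linked, stats::runif(n, 0, cfg$interval_cM), NA_real_)
  is_paralogue <- seq_len(n) %in%
    utils::head(which(!linked), cfg$n_collapsed_paralogues)
  snp_rate <- ifelse(is_paralogue, cfg$paralogue_divergence_per_kb,
                     cfg$varietal_snp_rate)
  expr_w <- if (cfg$expression_sdlog > 0)
    stats::rlnorm(n, 0, cfg$expression_sdlog) else rep(1, n)

  # haplotype layer: per position, base index of each homoeologue copy for
  # each parent (hom2 NA on single-copy unigenes)
  uidx <- rep.int(seq_len(n), len)
  npos <- length(uidx)
  pos <- sequence(len)
  base1 <- .rand_dna_idx(npos)
  base2 <- base1
  mut <- stats::runif(npos) < (1 - cfg$homoeologue_identity) &
    duplicated_ug[uidx]
  base2[mut] <- ((base2[mut] - 1L +
                    sample.int(3L, sum(mut), replace = TRUE)) %% 4L) + 1L
  base2[!duplicated_ug[uidx]] <- NA_integer_
  ihp <- which(!is.na(base2) & base2 != base1)

  a1 <- base1; a2 <- base2; b1 <- base1; b2 <- base2

  # plant varietal SNPs at non-IHP positions
  eligible <- rep(TRUE, npos)
  eligible[ihp] <- FALSE
  n_snp <- stats::rpois(n, snp_rate * len / 1000)
  snp_rows <- integer(0)
  off <- c(0L, cumsum(len))
  for (u in seq_len(n)) {
    if (n_snp[u] == 0L) next
    cand <- off[u] + which(eligible[(off[u] + 1L):(off[u + 1L])])
    k <- min(n_snp[u], length(cand))
    if (k > 0L)
      snp_rows <- c(snp_rows, cand[sample.int(length(cand), k)])
  }
  snp_rows <- sort(snp_rows)
  ns <- length(snp_rows)
  planted_parent <- sample(c("A", "B"), ns, replace = TRUE)
  hom <- ifelse(duplicated_ug[uidx[snp_rows]],
                sample.int(2L, ns, replace = TRUE), 1L)
  orig <- base1[snp_rows]
  variant <- ((orig - 1L + sample.int(3L, ns, replace = TRUE)) %% 4L) + 1L
  for (k in seq_len(ns)) {
    i <- snp_rows[k]
    if (planted_parent[k] == "A") {
      if (hom[k] == 1L) a1[i] <- variant[k] else a2[i] <- variant[k]
    } else {
      if (hom[k] == 1L) b1[i] <- variant[k] else b2[i] <- variant[k]
    }
  }

  snp_truth <- .snp_truth_table(ids, uidx, pos, snp_rows, duplicated_ug,
                                planted_parent, orig, variant, map_cM,
                                linked)

  # recombinant lines, bulk dosages (donor = parent B)
  lines <- simulate_cross(cfg)
  dosage_high <- dosage_low <- numeric(n)
  if (any(linked)) {
    d <- .bulk_dosage_linked(lines, map_cM[linked])
    dosage_high[linked] <- d$high
    dosage_low[linked] <- d$low
  }
  if (any(!linked)) {
    # free recombination off the interval: independent Bernoulli(1/2)
    nl <- sum(!linked)
    g <- matrix(stats::runif(nrow(lines) * nl) < 0.5, nrow(lines), nl)
    for (b in c("high", "low")) {
      sel <- lines$bulk == b
      w <- lines$weight[sel]
      dd <- colSums(g[sel, , drop = FALSE] * w) / sum(w)
      if (b == "high") dosage_high[!linked] <- dd
      else dosage_low[!linked] <- dd
    }
    unlinked_genotypes <- g
  } else unlinked_genotypes <- NULL

  unigenes <- data.frame(unigene_id = ids, length_bp = len,
                         duplicated = duplicated_ug, linked = linked,
                         collapsed_paralogue = is_paralogue,
                         map_cM = map_cM, expr_weight = expr_w,
                         dosage_high = dosage_high,
                         dosage_low = dosage_low, stringsAsFactors = FALSE)

  hap <- list(uidx = uidx, pos = pos, ref = base1,
              a1 = a1, a2 = a2, b1 = b1, b2 = b2)
  sim <- list(config = cfg, unigenes = unigenes, lines = lines,
              truth = list(
                snps = snp_truth,
                ihp = data.frame(unigene_id = ids[uidx[ihp]],
                                 pos = pos[ihp],
                                 base_1 = .BASES[base1[ihp]],
                                 base_2 = .BASES[base2[ihp]],
                                 stringsAsFactors = FALSE),
                unlinked_genotypes = unlinked_genotypes),
              haplotypes = hap,
              reference = .collapse_sequences(ids, uidx, base1))
  class(sim) <- "bsa_sim"

  sim$pileups <- list()
  sim$counts <- list()
  for (s in c("parent_a", "parent_b", "high", "low")) {
    smp <- .sample_pileup(sim, s, cfg$mean_depth, cfg$error_rate)
    sim$pileups[[s]] <- smp$pileup
    sim$counts[[s]] <- smp$counts
  }
  sim
}

.collapse_sequences <- function(ids, uidx, base_idx) {
  seqs <- vapply(split(.BASES[base_idx], uidx),
                 paste, character(1), collapse = "")
  names(seqs) <- ids
  seqs
}

.snp_truth_table <- function(ids, uidx, pos, snp_rows, duplicated_ug,
                             planted_parent, orig, variant, map_cM,
                             linked) {
  u <- uidx[snp_rows]
  dup <- duplicated_ug[u]
  type <- ifelse(dup, "hemi", "simple")
  code_pair <- function(x, y)
    unname(.KEY_CODE[bitwOr(2L^(x - 1L), 2L^(y - 1L))])
  gen_carrier <- ifelse(dup, code_pair(orig, variant), .BASES[variant])
  gen_other <- .BASES[orig]
  genotype_a <- ifelse(planted_parent == "A", gen_carrier, gen_other)
  genotype_b <- ifelse(planted_parent == "B", gen_carrier, gen_other)
  # classifier conventions: hemi records the private pair member and its
  # parent; simple records parent A's base with origin A
  informative <- ifelse(dup, .BASES[variant],
                        ifelse(planted_parent == "A",
                               .BASES[variant], .BASES[orig]))
  origin <- ifelse(dup, planted_parent, "A")
  data.frame(unigene_id = ids[u], pos = pos[snp_rows], snp_type = type,
             genotype_a = genotype_a, genotype_b = genotype_b,
             informative_base = informative, origin = origin,
             shared_base = ifelse(dup, .BASES[orig], NA_character_),
             planted_parent = planted_parent,
             map_cM = map_cM[u], linked = linked[u],
             stringsAsFactors = FALSE)
}

# allele mixture matrix (positions x 4) for one sample
.sample_mixture <- function(sim, sample) {
  hap <- sim$haplotypes
  cfg <- sim$config
  npos <- length(hap$uidx)
  mix_parent <- function(h1, h2) {
    w2 <- ifelse(is.na(h2), 0, 1 - cfg$homoeologue_ratio)
    w1 <- 1 - w2
    P <- matrix(0, npos, 4L)
    iseq <- seq_len(npos)
    P[cbind(iseq, h1)] <- P[cbind(iseq, h1)] + w1
    ok <- !is.na(h2)
    P[cbind(iseq[ok], h2[ok])] <- P[cbind(iseq[ok], h2[ok])] + w2[ok]
    P
  }
  if (sample == "parent_a") return(mix_parent(hap$a1, hap$a2))
  if (sample == "parent_b") return(mix_parent(hap$b1, hap$b2))
  d_col <- if (sample == "high") "dosage_high" else "dosage_low"
  d <- sim$unigenes[[d_col]][hap$uidx]
  d * mix_parent(hap$b1, hap$b2) + (1 - d) * mix_parent(hap$a1, hap$a2)
}

# counts at each position from the effective mixture (base error folded
# in): multinomial via a vectorised binomial cascade, or a deterministic
# largest-remainder apportionment for the noise-free limit
.sample_counts <- function(depth, P, error_rate,
                           read_sampling = "binomial") {
  Pe <- P * (1 - error_rate) + (1 - P) * error_rate / 3
  if (read_sampling == "expected") return(.apportion_counts(depth, Pe))
  npos <- length(depth)
  counts <- matrix(0L, npos, 4L, dimnames = list(NULL, .BASES))
  rem <- depth
  ptot <- rep(1, npos)
  for (j in 1:3) {
    pj <- ifelse(ptot > 0, pmin(1, pmax(0, Pe[, j] / ptot)), 0)
    counts[, j] <- stats::rbinom(npos, rem, pj)
    rem <- rem - counts[, j]
    ptot <- ptot - Pe[, j]
  }
  counts[, 4L] <- rem
  counts
}

.apportion_counts <- function(depth, Pe) {
  exp_counts <- depth * Pe
  counts <- floor(exp_counts)
  frac <- exp_counts - counts
  rem <- depth - rowSums(counts)
  for (k in 1:3) {       # at most 3 leftover reads per column
    idx <- max.col(frac, ties.method = "first")
    take <- rem >= k
    counts[cbind(which(take), idx[take])] <-
      counts[cbind(which(take), idx[take])] + 1
    frac[cbind(seq_along(idx), idx)] <- -1
  }
  mode(counts) <- "integer"
  colnames(counts) <- .BASES
  counts
}

.sample_pileup <- function(sim, sample, mean_depth, error_rate) {
  hap <- sim$haplotypes
  w <- sim$unigenes$expr_weight[hap$uidx]
  depth <- stats::rpois(length(hap$uidx), mean_depth * w)
  P <- .sample_mixture(sim, sample)
  counts <- .sample_counts(depth, P, error_rate,
                           sim$config$read_sampling)
  keep <- depth > 0L
  pile <- data.frame(unigene_id = sim$unigenes$unigene_id[hap$uidx[keep]],
                     pos = hap$pos[keep],
                     ref_base = .BASES[hap$ref[keep]],
                     depth = depth[keep],
                     A = counts[keep, "A"], C = counts[keep, "C"],
                     G = counts[keep, "G"], T = counts[keep, "T"],
                     n_other = 0L, stringsAsFactors = FALSE)
  rownames(pile) <- NULL
  reads <- vapply(split(depth, hap$uidx), sum, numeric(1))
  cnt <- data.frame(unigene_id = sim$unigenes$unigene_id,
                    mapped_reads = as.numeric(reads),
                    stringsAsFactors = FALSE)
  list(pileup = pile, counts = cnt)
}

#' Regenerate one sample's pileup from simulated truth
#'
#' Draws a fresh read layer (depth, base sampling, error) over the fixed
#' haplotypes, lines and expression weights of an existing simulation.
#'
#' @param sim A `bsa_sim` object from [simulate_bsa_experiment()].
#' @param sample One of `"parent_a"`, `"parent_b"`, `"high"`, `"low"`.
#' @param mean_depth,error_rate Overrides; default to the simulation's
#'   configuration.
#' @param seed Optional seed for the read layer.
#' @return List with `pileup` (data.frame) and `counts` (mapped
#'   read-equivalents per unigene).
#' @export
simulate_pileup <- function(sim, sample = c("parent_a", "parent_b",
                                            "high", "low"),
                            mean_depth = NULL, error_rate = NULL,
                            seed = NULL) {
  sample <- match.arg(sample)
  stopifnot(inherits(sim, "bsa_sim"))
  if (is.null(mean_depth)) mean_depth <- sim$config$mean_depth
  if (is.null(error_rate)) error_rate <- sim$config$error_rate
  .with_seed(seed, .sample_pileup(sim, sample, mean_depth, error_rate))
}

#' Render a pileup table as samtools-mpileup text
#'
#' Reads matching the reference base are written as `.`, others as their
#' upper-case base. The output round-trips through [read_pileup()] with
#' exact count agreement.
#'
#' @param pileup Pileup data.frame (with `ref_base`).
#' @param path Optional output path; if `NULL` the lines are returned.
#' @return Character vector of mpileup lines (invisibly when written).
#' @export
write_mpileup <- function(pileup, path = NULL) {
  m <- as.matrix(pileup[, .BASES, drop = FALSE])
  refmatch <- outer(pileup$ref_base, .BASES, `==`)
  chunks <- vapply(1:4, function(j)
    strrep(ifelse(refmatch[, j], ".", .BASES[j]), m[, j]),
    character(nrow(pileup)))
  if (nrow(pileup) == 1L) chunks <- matrix(chunks, nrow = 1L)
  bases <- apply(chunks, 1L, paste, collapse = "")
  lines <- paste(pileup$unigene_id, pileup$pos, pileup$ref_base,
                 pileup$depth, bases, sep = "\t")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Write a simulated experiment to disk
#'
#' Emits `reference.fasta`, one mpileup file and one counts TSV per sample,
#' the truth tables and the effective configuration, all as plain text.
#'
#' @param sim A `bsa_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- Biostrings::DNAStringSet(sim$reference)
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))
  for (s in names(sim$pileups)) {
    write_mpileup(sim$pileups[[s]], file.path(dir, paste0(s, ".pileup")))
    utils::write.table(sim$counts[[s]],
                       file.path(dir, paste0("counts_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sim$truth$snps, file.path(dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$ihp, file.path(dir, "truth_ihp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$lines, file.path(dir, "truth_lines.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$unigenes, file.path(dir, "truth_unigenes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  writeLines(yaml::as.yaml(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
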