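# End-to-end orchestration: genotype -> classify -> density filter -> BSA
# -> summary, with per-stage counts for auditing.

#' Pipeline configuration
#'
#' @param parent_a,parent_b,bulk_high,bulk_low Pileup inputs: file paths
#'   (mpileup text) or pileup data.frames. Parent A is the declared
#'   low-phenotype parent.
#' @param reference Unigene FASTA path or a lengths data.frame
#'   (`unigene_id`, `length_bp`).
#' @param min_depth Minimum depth for genotype calls and bulk screening
#'   (8, 12 or 16 are the usual operating points).
#' @param min_allele_reads,min_allele_fraction Consensus-call thresholds,
#'   see [call_genotypes()].
#' @param max_density SNP-density cutoff (SNPs/kb), see
#'   [snp_density_filter()].
#' @param bfr_threshold BFR enrichment cutoff (inclusive).
#' @param one_per_unigene Evaluate a single SNP per unigene in the screen.
#' @param low_parent Label of the low-phenotype parent (`"A"` or `"B"`).
#' @param denominator Frequency denominator (`"total"` or `"acgt"`).
#' @param thresholds Cutoffs for the BFR summary table.
#' @param out_dir Optional directory for TSV outputs.
#' @return A list of class `bsa_run_config`.
#' @export
bsa_config <- function(parent_a, parent_b, bulk_high, bulk_low,
                       reference, min_depth = 8, min_allele_reads = 2,
                       min_allele_fraction = 0.2, max_density = 5,
                       bfr_threshold = 3, one_per_unigene = FALSE,
                       low_parent = "A", denominator = "total",
                       thresholds = 2:10, out_dir = NULL) {
  stopifnot(min_depth >= 1, bfr_threshold > 0, low_parent %in% c("A", "B"))
  structure(as.list(environment()), class = "bsa_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [bsa_config()].
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @export
read_bsa_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(bsa_config, vals)
}

.as_pileup <- function(x) {
  if (is.data.frame(x)) x else read_pileup(x)
}

.as_lengths <- function(x) {
  if (is.data.frame(x)) x else read_unigene_lengths(x)
}

#' Run the full SNP-discovery and BSA pipeline
#'
#' Stages: per-parent consensus genotyping, varietal SNP classification
#' (symmetric difference of the two call sets), SNP-density paralogue
#' filter, bulk screening with the oriented BFR, and a threshold summary.
#'
#' @param config A [bsa_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `bsa_run` with elements `snps`, `complex`,
#'   `density`, `bfr`, `thresholds`, `summary` (named stage counts) and
#'   `config`. If `config$out_dir` is set, `snps.tsv`, `density.tsv`,
#'   `bfr.tsv` and `summary.yaml` are written there.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "bsa_run_config"))
  say <- function(...) if (!quiet) message("[polyBSA] ", ...)

  lengths <- .as_lengths(config$reference)
  pa <- .as_pileup(config$parent_a); pb <- .as_pileup(config$parent_b)
  say("genotype: calling consensus in both parents")
  calls_a <- call_genotypes(pa, config$min_depth, config$min_allele_reads,
                            config$min_allele_fraction)
  calls_b <- call_genotypes(pb, config$min_depth, config$min_allele_reads,
                            config$min_allele_fraction)
  say("  parent A: ", nrow(calls_a), " calls; parent B: ",
      nrow(calls_b), " calls")

  say("classify: varietal SNPs from the parental call sets")
  snps <- varietal_snp_scan(calls_a, calls_b)
  complex <- attr(snps, "complex")
  n_ihp <- attr(snps, "n_ihp")
  say("  candidates: ", attr(snps, "n_candidates"), " differing; ",
      nrow(snps), " varietal (", sum(snps$snp_type == "hemi"), " hemi, ",
      sum(snps$snp_type == "simple"), " simple); ",
      nrow(complex), " complex; IHP-like positions excluded upstream: ",
      n_ihp)

  say("density-filter: removing unigenes > ", config$max_density,
      " SNPs/kb")
  filt <- snp_density_filter(snps, lengths, config$max_density)
  n_removed <- nrow(snps) - nrow(filt$snps)
  say("  removed ", n_removed, " SNPs in ",
      sum(!filt$report$retained), " unigenes")

  say("bsa: screening ", nrow(filt$snps), " SNPs against the bulks")
  bfr <- bsa_screen(filt$snps, .as_pileup(config$bulk_high),
                    .as_pileup(config$bulk_low),
                    min_depth = config$min_depth,
                    threshold = config$bfr_threshold,
                    one_per_unigene = config$one_per_unigene,
                    low_parent = config$low_parent,
                    denominator = config$denominator)
  thr <- threshold_summary(bfr, config$thresholds)
  say("  evaluated ", nrow(bfr), "; depth-passing ",
      sum(bfr$passes_depth), "; excluded ",
      sum(bfr$excluded, na.rm = TRUE), "; >= ", config$bfr_threshold,
      ": ", sum(bfr$passes_threshold))

  summary <- list(
    n_calls_a = nrow(calls_a), n_calls_b = nrow(calls_b),
    n_candidates = attr(snps, "n_candidates"),
    n_ihp_excluded = n_ihp,
    n_varietal = nrow(snps),
    n_hemi = sum(snps$snp_type == "hemi"),
    n_simple = sum(snps$snp_type == "simple"),
    n_complex = nrow(complex),
    n_density_removed_snps = n_removed,
    n_density_removed_unigenes = sum(!filt$report$retained),
    n_screened = nrow(filt$snps),
    n_evaluated = nrow(bfr),
    n_depth_passing = sum(bfr$passes_depth),
    n_excluded = sum(bfr$excluded, na.rm = TRUE),
    n_threshold_passing = sum(bfr$passes_threshold))

  run <- structure(list(snps = filt$snps, complex = complex,
                        density = filt$report, bfr = bfr,
                        thresholds = thr, summary = summary,
                        config = config), class = "bsa_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_snp_table(filt$snps, file.path(config$out_dir, "snps.tsv"))
    write_snp_table(filt$report, file.path(config$out_dir, "density.tsv"))
    write_snp_table(bfr, file.path(config$out_dir, "bfr.tsv"))
    cfg <- config; class(cfg) <- NULL
    cfg$out_dir <- NULL
    cfg <- cfg[!vapply(cfg, is.data.frame, logical(1))]
    writeLines(yaml::as.yaml(c(summary, list(config = cfg))),
               file.path(config$out_dir, "summary.yaml"))
  }
  run
}

#' @export
print.bsa_run <- function(x, ...) {
  s <- x$summary
  cat("polyBSA run\n")
  cat(sprintf("  parental calls:   A %d / B %d\n", s$n_calls_a, s$n_calls_b))
  cat(sprintf("  varietal SNPs:    %d (%d hemi, %d simple); %d complex\n",
              s$n_varietal, s$n_hemi, s$n_simple, s$n_complex))
  cat(sprintf("  density filter:   removed %d SNPs in %d unigenes\n",
              s$n_density_removed_snps, s$n_density_removed_unigenes))
  cat(sprintf("  bulk screen:      %d evaluated, %d depth-passing, %d excluded, %d with BFR >= %s\n",
              s$n_evaluated, s$n_depth_passing, s$n_excluded,
              s$n_threshold_passing, format(x$config$bfr_threshold)))
  invisible(x)
}

#' Percentage as printed in study reports
#'
#' Rounds `100 * n / total` to a fixed number of digits, the way recovery
#' and validation rates are quoted (e.g. 1619 of 3427 SNPs -> 47.2).
#'
#' @param n Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal digits (default 1).
#' @return Numeric percentage.
#' @export
percent_of <- function(n, total, digits = 1) {
  if (any(total <= 0)) stop("total must be positive")
  round(100 * n / total, digits)
}
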