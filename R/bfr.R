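# Bulked segregant analysis via the bulk frequency ratio (BFR).
#
# At a varietal SNP the informative base is the allele private to one parent.
# Its read frequency is measured in each phenotype bulk; the BFR divides the
# frequency in the bulk that should be enriched for that parent's allele by
# the frequency in the opposite bulk, so linkage to the selected locus shows
# up as BFR >> 1 regardless of which parent carries the marker. In a
# tetraploid with both homoeologues expressed the enriched-bulk frequency
# tops out near 0.5, not 1, because the non-informative homoeologue's base is
# always present.

#' Frequency of a base in a pileup column
#'
#' @param column One-row pileup data.frame (or a row of [read_pileup()]
#'   output).
#' @param base One of A, C, G, T.
#' @param denominator `"total"` divides by the full column depth (including
#'   indel/N/other symbols); `"acgt"` divides by the four-base count only.
#' @return Proportion in `[0, 1]`, or `NA` when the denominator is 0.
#' @export
informative_base_frequency <- function(column, base,
                                       denominator = c("total", "acgt")) {
  denominator <- match.arg(denominator)
  base <- toupper(base)
  stopifnot(base %in% .BASES)
  den <- if (denominator == "total") column$depth
         else column$A + column$C + column$G + column$T
  ifelse(den > 0, column[[base]] / den, NA_real_)
}

#' Oriented bulk frequency ratio
#'
#' For markers whose informative base originates in the low-phenotype parent
#' the ratio is `f_low / f_high`; for the high-phenotype parent it is
#' reversed. Divide-by-zero cases (denominator frequency 0, or an undefined
#' frequency) are excluded: the ratio is `NA` there, a value the screen
#' flags rather than drops.
#'
#' @param f_high,f_low Informative-base frequencies in the high and low
#'   bulks.
#' @param origin Parent of origin of the informative base, `"A"` or `"B"`.
#' @param low_parent Which parent label is the low-phenotype parent
#'   (default `"A"`).
#' @return Numeric vector of ratios, `NA` where excluded.
#' @examples
#' bulk_frequency_ratio(0.397, 0.017, origin = "B")  # 23.35
#' @export
bulk_frequency_ratio <- function(f_high, f_low, origin, low_parent = "A") {
  stopifnot(all(origin %in% c("A", "B")), low_parent %in% c("A", "B"))
  num <- ifelse(origin == low_parent, f_low, f_high)
  den <- ifelse(origin == low_parent, f_high, f_low)
  ifelse(!is.na(den) & den > 0 & !is.na(num), num / den, NA_real_)
}

#' Screen varietal SNPs against two phenotype bulks
#'
#' Looks up each candidate SNP in the high- and low-bulk pileups, computes
#' informative-base frequencies and the oriented BFR, and flags depth and
#' threshold passes. SNPs absent from a bulk's pileup get depth 0 and fail
#' the depth screen but are still reported.
#'
#' @param snps Varietal SNP table ([varietal_snp_scan()], possibly
#'   density-filtered).
#' @param pileup_high,pileup_low Bulk pileup tables ([read_pileup()]).
#' @param min_depth Minimum per-bulk depth for `passes_depth` (default 8).
#' @param threshold BFR cutoff for `passes_threshold` (default 3; inclusive).
#' @param one_per_unigene If `TRUE`, evaluate a single SNP per unigene: the
#'   one with the largest `min(depth_high, depth_low)`, ties broken by
#'   smallest position.
#' @param low_parent Label of the low-phenotype parent (default `"A"`).
#' @param denominator Frequency denominator, see
#'   [informative_base_frequency()].
#' @return Data.frame of BFR records: `unigene_id`, `pos`, `snp_type`,
#'   `origin`, `informative_base`, `f_high`, `f_low`, `depth_high`,
#'   `depth_low`, `bfr`, `excluded`, `passes_depth`, `passes_threshold`.
#'   `excluded` is `TRUE` exactly when the orientation's denominator
#'   frequency is 0, `NA` when a bulk has no coverage at all.
#' @export
bsa_screen <- function(snps, pileup_high, pileup_low, min_depth = 8,
                       threshold = 3, one_per_unigene = FALSE,
                       low_parent = "A",
                       denominator = c("total", "acgt")) {
  denominator <- match.arg(denominator)
  cols <- c("unigene_id", "pos", "snp_type", "origin", "informative_base")
  rec <- snps[, cols, drop = FALSE]

  lookup <- function(pileup, suffix) {
    keep <- c("unigene_id", "pos", "depth", .BASES)
    p <- pileup[, keep, drop = FALSE]
    names(p)[3:7] <- paste0(names(p)[3:7], suffix)
    p
  }
  rec <- merge(rec, lookup(pileup_high, "_h"),
               by = c("unigene_id", "pos"), all.x = TRUE)
  rec <- merge(rec, lookup(pileup_low, "_l"),
               by = c("unigene_id", "pos"), all.x = TRUE)
  for (nm in grep("_[hl]$", names(rec), value = TRUE))
    rec[[nm]][is.na(rec[[nm]])] <- 0L

  if (one_per_unigene && nrow(rec) > 0L) {
    score <- pmin(rec$depth_h, rec$depth_l)
    ord <- order(rec$unigene_id, -score, rec$pos)
    rec <- rec[ord, , drop = FALSE]
    rec <- rec[!duplicated(rec$unigene_id), , drop = FALSE]
  }
  rec <- rec[order(rec$unigene_id, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL

  count_of <- function(m, base) m[cbind(seq_along(base), match(base, .BASES))]
  mh <- as.matrix(rec[, paste0(.BASES, "_h"), drop = FALSE])
  ml <- as.matrix(rec[, paste0(.BASES, "_l"), drop = FALSE])
  den_h <- if (denominator == "total") rec$depth_h else rowSums(mh)
  den_l <- if (denominator == "total") rec$depth_l else rowSums(ml)
  f_high <- ifelse(den_h > 0,
                   count_of(mh, rec$informative_base) / den_h, NA_real_)
  f_low <- ifelse(den_l > 0,
                  count_of(ml, rec$informative_base) / den_l, NA_real_)

  den_f <- ifelse(rec$origin == low_parent, f_high, f_low)
  excluded <- ifelse(is.na(den_f), NA, den_f == 0)
  bfr <- bulk_frequency_ratio(f_high, f_low, rec$origin, low_parent)
  passes_depth <- rec$depth_h >= min_depth & rec$depth_l >= min_depth
  passes_threshold <- passes_depth & !is.na(bfr) & bfr >= threshold

  out <- data.frame(unigene_id = rec$unigene_id, pos = rec$pos,
                    snp_type = rec$snp_type, origin = rec$origin,
                    informative_base = rec$informative_base,
                    f_high = f_high, f_low = f_low,
                    depth_high = rec$depth_h, depth_low = rec$depth_l,
                    bfr = bfr, excluded = excluded,
                    passes_depth = passes_depth,
                    passes_threshold = passes_threshold,
                    stringsAsFactors = FALSE)
  if (nrow(out)) rownames(out) <- NULL
  out
}

#' Tabulate SNP counts above BFR cutoffs
#'
#' Among depth-passing, non-excluded records, counts how many reach each
#' cutoff and what percentage of that pool they represent.
#'
#' @param records BFR table from [bsa_screen()].
#' @param thresholds Numeric cutoffs (default `2:10`); comparison is `>=`.
#' @return Data.frame with `threshold`, `n_snps`, `pct` (percentage of the
#'   depth-passing, non-excluded records; 0 when the pool is empty).
#' @export
threshold_summary <- function(records, thresholds = 2:10) {
  pool <- records[!is.na(records$excluded) & !records$excluded &
                    records$passes_depth, , drop = FALSE]
  n_pool <- nrow(pool)
  n <- vapply(thresholds, function(th) sum(pool$bfr >= th), integer(1))
  data.frame(threshold = as.numeric(thresholds), n_snps = n,
             pct = if (n_pool > 0) 100 * n / n_pool else rep(0, length(n)))
}
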