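# RPKM expression profiling for non-normalised RNA-seq libraries.

#' Reads per kilobase per million mapped reads
#'
#' @param mapped_reads Reads mapped to the unigene.
#' @param length_bp Unigene length in bases (> 0).
#' @param total_mapped_reads Library size: total mapped reads (> 0).
#' @return `mapped_reads * 1e9 / (length_bp * total_mapped_reads)`.
#' @examples
#' rpkm(10, 1000, 1e6)   # 10
#' @export
rpkm <- function(mapped_reads, length_bp, total_mapped_reads) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(total_mapped_reads <= 0))
    stop("total_mapped_reads must be positive")
  mapped_reads * 1e9 / (length_bp * total_mapped_reads)
}

#' Expression profile of a counts table
#'
#' @param counts Data.frame with `unigene_id` and `mapped_reads`.
#' @param lengths Unigene lengths ([read_unigene_lengths()]).
#' @return Data.frame `unigene_id`, `mapped_reads`, `length_bp`, `rpkm`,
#'   plus the ranking columns of [cumulative_mapped_fraction()].
#' @export
expression_profile <- function(counts, lengths) {
  x <- merge(counts[, c("unigene_id", "mapped_reads")], lengths,
             by = "unigene_id")
  x$rpkm <- rpkm(x$mapped_reads, x$length_bp, sum(x$mapped_reads))
  cumulative_mapped_fraction(x)
}

#' Cumulative mapped-read fraction by expression rank
#'
#' Ranks unigenes by RPKM (descending, ties broken by identifier) and
#' accumulates the fraction of all mapped reads. In a non-normalised
#' library the curve rises steeply: a handful of highly expressed
#' transcripts can soak up half the reads.
#'
#' @param records Data.frame with `unigene_id`, `mapped_reads` and either
#'   `rpkm` or (`length_bp` to derive it).
#' @return The records ranked, with `rank` and `cumulative_fraction`
#'   columns; the final cumulative fraction is exactly 1.
#' @export
cumulative_mapped_fraction <- function(records) {
  total <- sum(records$mapped_reads)
  if (total <= 0) stop("no mapped reads")
  if (is.null(records$rpkm))
    records$rpkm <- rpkm(records$mapped_reads, records$length_bp, total)
  ord <- order(-records$rpkm, records$unigene_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$cumulative_fraction <- cumsum(out$mapped_reads) / total
  out$cumulative_fraction[nrow(out)] <- 1
  rownames(out) <- NULL
  out
}

#' Smallest expression rank reaching a cumulative read fraction
#'
#' @param curve Output of [cumulative_mapped_fraction()].
#' @param fraction Target cumulative fraction (default 0.5: how many top
#'   unigenes hold half the reads).
#' @return Integer rank.
#' @export
rank_at_fraction <- function(curve, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  which(curve$cumulative_fraction >= fraction)[1]
}

#' Cross-sample agreement of log10 RPKM
#'
#' Squared Pearson correlation of log10 RPKM over unigenes expressed
#' (rpkm > 0) in both samples.
#'
#' @param records_a,records_b Data.frames with `unigene_id` and `rpkm`.
#' @return Coefficient of determination in `[0, 1]`.
#' @export
log_rpkm_r2 <- function(records_a, records_b) {
  m <- merge(records_a[, c("unigene_id", "rpkm")],
             records_b[, c("unigene_id", "rpkm")],
             by = "unigene_id", suffixes = c("_a", "_b"))
  m <- m[m$rpkm_a > 0 & m$rpkm_b > 0, , drop = FALSE]
  if (nrow(m) < 2L)
    stop("need at least 2 unigenes expressed in both samples")
  stats::cor(log10(m$rpkm_a), log10(m$rpkm_b))^2
}
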