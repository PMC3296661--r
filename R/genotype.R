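# In a tetraploid aligned to a collapsed unigene reference, a two-base IUPAC
# code at a position usually means co-expression of both homoeologues, not
# heterozygosity: inbred material is homozygous within each genome.

#' Encode an allele set as an IUPAC character
#'
#' @param alleles Character vector of 1 or 2 distinct bases from A,C,G,T.
#' @return Single IUPAC character: the base itself for singletons;
#'   M, R, W, S, Y or K for pairs.
#' @examples
#' iupac_code(c("C", "T"))  # "Y"
#' iupac_code(c("C", "G"))  # "S"
#' @export
iupac_code <- function(alleles) {
  alleles <- sort(unique(toupper(alleles)))
  if (!all(alleles %in% .BASES))
    stop("alleles must be drawn from A, C, G, T")
  if (length(alleles) < 1L || length(alleles) > 2L)
    stop("allele set must contain 1 or 2 bases, got ", length(alleles))
  if (length(alleles) == 1L) alleles
  else unname(.IUPAC_PAIRS[paste(alleles, collapse = "")])
}

#' Decode an IUPAC character back to its allele set
#'
#' Inverse of [iupac_code()]; defined for the 4 bases and the 6 two-base
#' ambiguity codes.
#'
#' @param code Single IUPAC character.
#' @return Character vector of 1 or 2 bases, sorted.
#' @export
iupac_alleles <- function(code) {
  code <- toupper(code)
  if (code %in% .BASES) return(code)
  hit <- names(.IUPAC_PAIRS)[.IUPAC_PAIRS == code]
  if (length(hit) != 1L)
    stop("not a 1- or 2-base IUPAC code: '", code, "'")
  strsplit(hit, "")[[1]]
}

#' Call consensus genotypes from pileup columns
#'
#' Emulates the role of an alignment consensus caller with an explicit,
#' count-based rule: a base is an allele when it is seen in at least
#' `min_allele_reads` reads and in at least `min_allele_fraction` of the
#' column depth (ties inclusive). Positions below `min_depth`, with no
#' qualifying base, or with three or more qualifying bases (possible
#' paralogue collapse) are no-calls and are omitted from the result.
#'
#' @param pileup Pileup data.frame as returned by [read_pileup()].
#' @param min_depth Minimum column depth to attempt a call (default 8; the
#'   12- and 16-fold settings trade sensitivity for validation rate).
#' @param min_allele_reads Minimum reads supporting an allele (default 2).
#' @param min_allele_fraction Minimum fraction of depth supporting an allele
#'   (default 0.2).
#' @return Data.frame of calls: `unigene_id`, `pos`, `code` (IUPAC), `depth`,
#'   and `A`, `C`, `G`, `T` counts. One- or two-base codes only.
#' @export
call_genotypes <- function(pileup, min_depth = 8, min_allele_reads = 2,
                           min_allele_fraction = 0.2) {
  stopifnot(min_depth >= 1, min_allele_reads >= 1,
            min_allele_fraction >= 0, min_allele_fraction <= 1)
  if (nrow(pileup) == 0L)
    return(data.frame(unigene_id = character(), pos = integer(),
                      code = character(), depth = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), stringsAsFactors = FALSE))
  m <- as.matrix(pileup[, .BASES])
  depth <- pileup$depth
  qual <- m >= min_allele_reads & m >= min_allele_fraction * depth
  nq <- rowSums(qual)
  key <- as.integer(qual %*% c(1L, 2L, 4L, 8L))
  keep <- depth >= min_depth & nq >= 1L & nq <= 2L
  out <- data.frame(unigene_id = pileup$unigene_id[keep],
                    pos = pileup$pos[keep],
                    code = .KEY_CODE[key[keep]],
                    depth = depth[keep],
                    A = m[keep, "A"], C = m[keep, "C"],
                    G = m[keep, "G"], T = m[keep, "T"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call the consensus genotype of a single pileup column
#'
#' @param column One-row pileup data.frame (see [parse_pileup_line()]).
#' @inheritParams call_genotypes
#' @return A list with `unigene_id`, `pos`, `alleles`, `code`, `depth` and
#'   `allele_counts`, or `NULL` for a no-call.
#' @export
call_genotype <- function(column, min_depth = 8, min_allele_reads = 2,
                          min_allele_fraction = 0.2) {
  calls <- call_genotypes(column, min_depth, min_allele_reads,
                          min_allele_fraction)
  if (nrow(calls) == 0L) return(NULL)
  counts <- c(A = calls$A[1], C = calls$C[1], G = calls$G[1], T = calls$T[1])
  alleles <- iupac_alleles(calls$code[1])
  list(unigene_id = calls$unigene_id[1], pos = calls$pos[1],
       alleles = alleles, code = calls$code[1], depth = calls$depth[1],
       allele_counts = counts[alleles])
}
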