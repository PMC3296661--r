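# Small programmatic fixtures shared across tests.

# one pileup row from explicit base counts
pileup_row <- function(unigene_id, pos, ref, A = 0, C = 0, G = 0, T = 0,
                       n_other = 0) {
  data.frame(unigene_id = unigene_id, pos = as.integer(pos), ref_base = ref,
             depth = as.integer(A + C + G + T + n_other),
             A = as.integer(A), C = as.integer(C), G = as.integer(G),
             T = as.integer(T), n_other = as.integer(n_other),
             stringsAsFactors = FALSE)
}

pileup_table <- function(...) do.call(rbind, list(...))

# one consensus-call row (alleles given as an IUPAC code)
call_row <- function(unigene_id, pos, code, depth = 20) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  al <- polyBSA::iupac_alleles(code)
  counts[al] <- as.integer(round(depth / length(al)))
  data.frame(unigene_id = unigene_id, pos = as.integer(pos), code = code,
             depth = as.integer(sum(counts)), A = counts[["A"]],
             C = counts[["C"]], G = counts[["G"]], T = counts[["T"]],
             stringsAsFactors = FALSE)
}

call_table <- function(...) do.call(rbind, list(...))

# generate a random, valid mpileup base string symbol by symbol, returning
# the line and independently tallied expected counts
random_pileup_line <- function(unigene_id = "u1", pos = 1L) {
  ref <- sample(c("A", "C", "G", "T"), 1)
  n_reads <- sample(0:12, 1)
  expected <- c(A = 0L, C = 0L, G = 0L, T = 0L, n_other = 0L)
  syms <- character(0)
  for (i in seq_len(n_reads)) {
    start <- sample(c(TRUE, FALSE), 1, prob = c(0.2, 0.8))
    kind <- sample(c("ref", "alt", "other"), 1, prob = c(0.6, 0.3, 0.1))
    if (kind == "ref") {
      s <- sample(c(".", ","), 1)
      expected[ref] <- expected[ref] + 1L
    } else if (kind == "alt") {
      b <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      s <- sample(c(b, tolower(b)), 1)
      expected[b] <- expected[b] + 1L
    } else {
      s <- sample(c("*", "N", "n"), 1)
      expected[["n_other"]] <- expected[["n_other"]] + 1L
    }
    if (start) s <- paste0("^", rawToChar(as.raw(sample(33:126, 1))), s)
    if (!start && runif(1) < 0.15) {
      ins <- sample(1:3, 1)
      s <- paste0(s, sample(c("+", "-"), 1), ins,
                  paste(sample(c("A", "C", "G", "T"), ins, replace = TRUE),
                        collapse = ""))
    }
    if (runif(1) < 0.1) s <- paste0(s, "$")
    syms <- c(syms, s)
  }
  line <- paste(unigene_id, pos, ref, n_reads,
                paste(syms, collapse = ""), sep = "\t")
  list(line = line, ref = ref, depth = n_reads, expected = expected)
}

# independent per-record BFR recount straight from pileup columns
brute_force_bfr <- function(record, pileup_high, pileup_low,
                            low_parent = "A") {
  pick <- function(p) p[p$unigene_id == record$unigene_id &
                          p$pos == record$pos, , drop = FALSE]
  h <- pick(pileup_high); l <- pick(pileup_low)
  freq <- function(x) {
    if (nrow(x) == 0 || x$depth == 0) return(NA_real_)
    x[[record$informative_base]] / x$depth
  }
  fh <- freq(h); fl <- freq(l)
  num <- if (record$origin == low_parent) fl else fh
  den <- if (record$origin == low_parent) fh else fl
  if (is.na(den) || den == 0 || is.na(num)) NA_real_ else num / den
}
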