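#' Parse one samtools-mpileup text line
#'
#' Resolves a single mpileup line into per-base substitution counts.
#' `.`/`,` count towards the reference base; upper/lower case letters towards
#' that base; `^` consumes the following mapping-quality character; `$` is
#' consumed; `+n`/`-n` indel blocks are consumed without counting (insertions
#' do not contribute to column depth); `*`, `N`, `<` and `>` consume depth and
#' are tallied in `n_other`. Base qualities (column 6), if present, are
#' ignored: quality handling is assumed to live in the upstream aligner.
#'
#' @param line A single mpileup text line (>= 5 tab-separated fields:
#'   name, position, reference base, depth, base string and optionally
#'   a quality string).
#' @param line_number Line number used in error messages.
#' @return A one-row data.frame with columns `unigene_id`, `pos`, `ref_base`,
#'   `depth`, `A`, `C`, `G`, `T`, `n_other`. `sum(A,C,G,T) + n_other == depth`
#'   always holds.
#' @examples
#' parse_pileup_line("u1\t5\tC\t4\t.,TT")
#' @export
parse_pileup_line <- function(line, line_number = 1L) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 5L && !(length(fields) >= 4L && fields[4] == "0"))
    stop("pileup parse error at line ", line_number,
         ": expected >= 5 tab-separated fields, got ", length(fields))
  pos <- suppressWarnings(as.integer(fields[2]))
  depth <- suppressWarnings(as.integer(fields[4]))
  if (is.na(pos) || pos < 1L)
    stop("pileup parse error at line ", line_number,
         ": malformed position field '", fields[2], "'")
  if (is.na(depth) || depth < 0L)
    stop("pileup parse error at line ", line_number,
         ": malformed depth field '", fields[4], "'")
  ref <- toupper(fields[3])
  bases <- if (length(fields) >= 5L) fields[5] else ""
  counts <- if (depth == 0L) c(A = 0L, C = 0L, G = 0L, T = 0L, n_other = 0L)
            else .parse_base_string(bases, ref, line_number)
  total <- sum(counts)
  if (total != depth)
    stop("pileup parse error at line ", line_number, ": base string resolves ",
         total, " reads but depth field says ", depth)
  data.frame(unigene_id = fields[1], pos = pos, ref_base = ref, depth = depth,
             A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
             T = counts[["T"]], n_other = counts[["n_other"]],
             stringsAsFactors = FALSE)
}

# single-line scanner: handles ^/$ markers and indel blocks
.parse_base_string <- function(s, ref, line_number = NA) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, n_other = 0L)
  i <- 1L
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L                       # '^' + one mapping-quality char
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= n && ch[j] >= "0" && ch[j] <= "9") j <- j + 1L
      len <- suppressWarnings(as.integer(paste(ch[(i + 1L):(j - 1L)],
                                               collapse = "")))
      if (is.na(len))
        stop("pileup parse error at line ", line_number,
             ": malformed indel block in base string")
      i <- j + len                      # skip inserted/deleted sequence
    } else {
      if (c0 == "." || c0 == ",") {
        counts[ref] <- counts[ref] + 1L
      } else {
        up <- toupper(c0)
        if (up %in% .BASES) counts[up] <- counts[up] + 1L
        else counts[["n_other"]] <- counts[["n_other"]] + 1L
      }
      i <- i + 1L
    }
  }
  counts
}

# vectorised fast path for base strings free of ^ $ + - markers
.count_simple_strings <- function(bases, ref) {
  ntot <- nchar(bases)
  drop_n <- function(pat) ntot - nchar(gsub(pat, "", bases))
  ndot <- drop_n("[.,]")
  m <- cbind(A = drop_n("[Aa]"), C = drop_n("[Cc]"),
             G = drop_n("[Gg]"), T = drop_n("[Tt]"))
  n_other <- ntot - ndot - rowSums(m)
  ok <- ref %in% .BASES
  idx <- match(ref[ok], .BASES)
  m[cbind(which(ok), idx)] <- m[cbind(which(ok), idx)] + ndot[ok]
  if (any(!ok)) n_other[!ok] <- n_other[!ok] + ndot[!ok]
  cbind(m, n_other = n_other)
}

#' Read a samtools-mpileup text file into a pileup table
#'
#' @param path Path to an mpileup text file (or a character vector of lines
#'   via `text =`).
#' @param text Optional character vector of mpileup lines, used instead of
#'   `path`.
#' @return A data.frame with one row per reference position:
#'   `unigene_id`, `pos`, `ref_base`, `depth`, `A`, `C`, `G`, `T`, `n_other`.
#' @seealso [parse_pileup_line()] for the per-line symbol resolution rules.
#' @export
read_pileup <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(unigene_id = character(), pos = integer(),
                      ref_base = character(), depth = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), n_other = integer(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5L)) {
    bad <- which(nf < 5L)
    short_ok <- vapply(parts[bad], function(p)
      length(p) >= 4L && p[4] == "0", logical(1))
    if (!all(short_ok))
      stop("pileup parse error at line ", bad[!short_ok][1],
           ": expected >= 5 tab-separated fields")
  }
  field <- function(k) vapply(parts, function(p)
    if (length(p) >= k) p[k] else "", character(1))
  id <- field(1); pos <- suppressWarnings(as.integer(field(2)))
  ref <- toupper(field(3))
  depth <- suppressWarnings(as.integer(field(4)))
  if (anyNA(pos) || any(pos < 1L, na.rm = TRUE))
    stop("pileup parse error at line ",
         which(is.na(pos) | pos < 1L)[1], ": malformed position field")
  if (anyNA(depth) || any(depth < 0L))
    stop("pileup parse error at line ",
         which(is.na(depth) | depth < 0L)[1], ": malformed depth field")
  bases <- field(5)
  cnt <- matrix(0L, nrow = length(lines), ncol = 5L,
                dimnames = list(NULL, c(.BASES, "n_other")))
  nz <- depth > 0L
  if (any(nz)) {
    simple <- nz & !grepl("[$^+-]", bases)
    if (any(simple))
      cnt[simple, ] <- .count_simple_strings(bases[simple], ref[simple])
    hard <- which(nz & !simple)
    for (i in hard)
      cnt[i, ] <- .parse_base_string(bases[i], ref[i], i)
  }
  total <- rowSums(cnt)
  if (any(total != depth)) {
    i <- which(total != depth)[1]
    stop("pileup parse error at line ", i, ": base string resolves ",
         total[i], " reads but depth field says ", depth[i])
  }
  data.frame(unigene_id = id, pos = pos, ref_base = ref, depth = depth,
             A = cnt[, "A"], C = cnt[, "C"], G = cnt[, "G"], T = cnt[, "T"],
             n_other = cnt[, "n_other"], stringsAsFactors = FALSE)
}

#' Read unigene lengths from a FASTA reference
#'
#' @param path Path to a FASTA file of unigene (consensus transcript)
#'   sequences.
#' @return A data.frame with columns `unigene_id` and `length_bp`, one row
#'   per sequence in input order.
#' @export
read_unigene_lengths <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate unigene identifier(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(unigene_id = ids, length_bp = Biostrings::width(seqs),
             stringsAsFactors = FALSE)
}

# canonical column sets (and classes) for the pipeline's tabular outputs
.TABLE_SCHEMAS <- list(
  snps = c(unigene_id = "character", pos = "integer", snp_type = "character",
           genotype_a = "character", genotype_b = "character",
           informative_base = "character", origin = "character",
           shared_base = "character", depth_a = "integer",
           depth_b = "integer"),
  bfr = c(unigene_id = "character", pos = "integer", snp_type = "character",
          origin = "character", informative_base = "character",
          f_high = "numeric", f_low = "numeric", depth_high = "integer",
          depth_low = "integer", bfr = "numeric", excluded = "logical",
          passes_depth = "logical", passes_threshold = "logical"),
  density = c(unigene_id = "character", n_snps = "integer",
              length_bp = "integer", density = "numeric",
              retained = "logical"),
  calls = c(unigene_id = "character", pos = "integer", code = "character",
            depth = "integer", A = "integer", C = "integer", G = "integer",
            T = "integer"),
  expression = c(unigene_id = "character", mapped_reads = "numeric",
                 length_bp = "integer", rpkm = "numeric", rank = "integer",
                 cumulative_fraction = "numeric")
)

#' Write a pipeline table as tab-separated text
#'
#' @param x Data.frame of records (SNPs, BFR records, density reports, ...).
#' @param path Output path; a header row names the columns.
#' @export
write_snp_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a pipeline table written by [write_snp_table()]
#'
#' Columns are addressed by name, so column order in the file is free.
#' Unknown headers are an error.
#'
#' @param path Path to a TSV with a header row.
#' @param kind One of `"snps"`, `"bfr"`, `"density"`, `"calls"`,
#'   `"expression"`; selects the expected column set.
#' @return Data.frame with the canonical column order and types for `kind`.
#' @export
read_snp_table <- function(path, kind = c("snps", "bfr", "density",
                                          "calls", "expression")) {
  kind <- match.arg(kind)
  schema <- .TABLE_SCHEMAS[[kind]]
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = "NA")
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown))
    stop("unknown column(s) in ", kind, " table: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(names(schema), names(x))
  if (length(missing))
    stop("missing column(s) in ", kind, " table: ",
         paste(missing, collapse = ", "))
  x <- x[names(schema)]
  for (nm in names(schema)) {
    x[[nm]] <- switch(schema[[nm]],
                      character = as.character(x[[nm]]),
                      integer = as.integer(x[[nm]]),
                      numeric = as.numeric(x[[nm]]),
                      logical = as.logical(x[[nm]]))
  }
  x
}
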