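# Varietal SNP classification between two parental consensus call sets.
#
# A position with the same ambiguity code in both parents is an
# inter-homoeologue polymorphism (IHP): a fixed difference between the
# ancestral genomes, useless as a varietal marker. A two-base code in only
# one parent whose partner base matches the other parent's singleton is a
# hemi-SNP; two distinct singletons are a simple SNP. Everything else
# (pair vs non-member singleton, two different pairs) is "complex" and kept
# out of the marker set.

.code_key <- function(code) {
  al <- lapply(code, iupac_alleles)
  vapply(al, function(a) sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[a]),
         integer(1))
}

# vectorised classification on bitmask keys; returns list of vectors
.classify_keys <- function(ka, kb) {
  n <- length(ka)
  type <- rep("complex", n)
  informative <- shared <- rep(NA_character_, n)
  origin <- rep(NA_character_, n)
  na <- .POPCNT[ka]; nb <- .POPCNT[kb]

  type[ka == kb] <- "IHP"

  hemi_a <- ka != kb & na == 2L & nb == 1L & bitwAnd(ka, kb) == kb
  type[hemi_a] <- "hemi"
  informative[hemi_a] <- .KEY_BASE[bitwAnd(ka[hemi_a],
                                           bitwNot(kb[hemi_a]) %% 16L)]
  shared[hemi_a] <- .KEY_BASE[kb[hemi_a]]
  origin[hemi_a] <- "A"

  hemi_b <- ka != kb & nb == 2L & na == 1L & bitwAnd(ka, kb) == ka
  type[hemi_b] <- "hemi"
  informative[hemi_b] <- .KEY_BASE[bitwAnd(kb[hemi_b],
                                           bitwNot(ka[hemi_b]) %% 16L)]
  shared[hemi_b] <- .KEY_BASE[ka[hemi_b]]
  origin[hemi_b] <- "B"

  simple <- ka != kb & na == 1L & nb == 1L
  type[simple] <- "simple"
  # each parent's base is informative for its own bulk; records store the
  # parent-A base (origin A) and the BSA stage treats simple SNPs
  # symmetrically through the orientation rule
  informative[simple] <- .KEY_BASE[ka[simple]]
  origin[simple] <- "A"

  list(type = type, informative_base = informative, origin = origin,
       shared_base = shared)
}

#' Classify one position called in both parents
#'
#' @param call_a,call_b Per-parent calls at the same unigene and position:
#'   lists with at least `alleles` (or `code`), as returned by
#'   [call_genotype()], or bare IUPAC code strings.
#' @return A list with `type` (one of `"IHP"`, `"hemi"`, `"simple"`,
#'   `"complex"`), and for varietal types `informative_base`, `origin`
#'   (`"A"` or `"B"`) and `shared_base` (hemi only).
#' @examples
#' classify_pair("Y", "Y")  # IHP: same homoeologous polymorphism in both
#' classify_pair("S", "C")  # hemi-SNP, informative base G, origin A
#' @export
classify_pair <- function(call_a, call_b) {
  code_of <- function(x) {
    if (is.character(x) && length(x) == 1L) x
    else if (!is.null(x$code)) x$code
    else iupac_code(x$alleles)
  }
  a <- code_of(call_a); b <- code_of(call_b)
  if (is.list(call_a) && is.list(call_b) &&
      !is.null(call_a$pos) && !is.null(call_b$pos)) {
    if (!identical(call_a$pos, call_b$pos) ||
        !identical(call_a$unigene_id, call_b$unigene_id))
      stop("calls are not at the same unigene and position")
  }
  res <- .classify_keys(.code_key(a), .code_key(b))
  lapply(res, `[[`, 1L)
}

#' Scan two parental call sets for varietal SNPs
#'
#' Takes the positions called in both parents with differing genotypes (the
#' symmetric difference of the two call sets, restricted to double-covered
#' positions) and classifies each one. Only hemi- and simple SNPs are
#' emitted; IHP and complex positions are excluded, as are positions called
#' in a single parent (no cross-parent evidence). The complex positions are
#' attached as attribute `"complex"` for auditing.
#'
#' @param calls_a,calls_b Call tables from [call_genotypes()] for parent A
#'   (declared low-phenotype parent) and parent B.
#' @return Data.frame of varietal SNPs ordered by (unigene, position):
#'   `unigene_id`, `pos`, `snp_type`, `genotype_a`, `genotype_b`,
#'   `informative_base`, `origin`, `shared_base`, `depth_a`, `depth_b`.
#' @export
varietal_snp_scan <- function(calls_a, calls_b) {
  merged <- merge(calls_a[, c("unigene_id", "pos", "code", "depth")],
                  calls_b[, c("unigene_id", "pos", "code", "depth")],
                  by = c("unigene_id", "pos"), suffixes = c("_a", "_b"))
  # positions with the same two-base code in both parents are IHPs
  n_ihp <- sum(merged$code_a == merged$code_b &
                 merged$code_a %in% .IUPAC_PAIRS)
  merged <- merged[merged$code_a != merged$code_b, , drop = FALSE]
  n_candidates <- nrow(merged)
  empty <- data.frame(unigene_id = character(), pos = integer(),
                      snp_type = character(), genotype_a = character(),
                      genotype_b = character(),
                      informative_base = character(), origin = character(),
                      shared_base = character(), depth_a = integer(),
                      depth_b = integer(), stringsAsFactors = FALSE)
  if (nrow(merged) == 0L) {
    attr(empty, "complex") <- empty
    attr(empty, "n_ihp") <- n_ihp
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  cls <- .classify_keys(.code_key(merged$code_a), .code_key(merged$code_b))
  out <- data.frame(unigene_id = merged$unigene_id, pos = merged$pos,
                    snp_type = cls$type, genotype_a = merged$code_a,
                    genotype_b = merged$code_b,
                    informative_base = cls$informative_base,
                    origin = cls$origin, shared_base = cls$shared_base,
                    depth_a = merged$depth_a, depth_b = merged$depth_b,
                    stringsAsFactors = FALSE)
  out <- out[order(out$unigene_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  complex <- out[out$snp_type == "complex", , drop = FALSE]
  out <- out[out$snp_type %in% c("hemi", "simple"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "complex") <- complex
  attr(out, "n_ihp") <- n_ihp
  attr(out, "n_candidates") <- n_candidates
  out
}

#' Remove unigenes with implausibly high SNP density
#'
#' Collapsed paralogues or pseudogenes mapped onto one unigene masquerade as
#' dense runs of varietal SNPs. Any unigene whose density (SNPs per kb)
#' strictly exceeds `max_density` is dropped wholesale; equality is
#' retained.
#'
#' @param snps Varietal SNP table from [varietal_snp_scan()].
#' @param lengths Unigene lengths from [read_unigene_lengths()].
#' @param max_density Maximum tolerated SNPs per kb (default 5).
#' @return A list with `snps` (retained records) and `report`, a data.frame
#'   per polymorphic unigene: `unigene_id`, `n_snps`, `length_bp`,
#'   `density`, `retained`.
#' @export
snp_density_filter <- function(snps, lengths, max_density = 5) {
  if (nrow(snps) == 0L) {
    report <- data.frame(unigene_id = character(), n_snps = integer(),
                         length_bp = integer(), density = numeric(),
                         retained = logical(), stringsAsFactors = FALSE)
    return(list(snps = snps, report = report))
  }
  tab <- table(snps$unigene_id)
  ids <- names(tab)
  len <- lengths$length_bp[match(ids, lengths$unigene_id)]
  if (anyNA(len))
    stop("no length record for unigene(s): ",
         paste(ids[is.na(len)], collapse = ", "))
  density <- as.integer(tab) * 1000 / len
  report <- data.frame(unigene_id = ids, n_snps = as.integer(tab),
                       length_bp = len, density = density,
                       retained = density <= max_density,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  keep_ids <- report$unigene_id[report$retained]
  kept <- snps[snps$unigene_id %in% keep_ids, , drop = FALSE]
  rownames(kept) <- NULL
  list(snps = kept, report = report)
}
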