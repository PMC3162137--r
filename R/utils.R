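#' @import data.table
#' @importFrom stats rnorm runif rbinom setNames
#' @importFrom utils head tail write.table
#' @importFrom methods is
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomness in the package flows through this helper so
# that identical seeds give bit-identical outputs.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying
# within 32-bit integer range.
derive_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + s) %% 2147483647)
}

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

# Coerce a genome given as named character vector / DNAStringSet into a
# named character vector (internal working representation: plain strings,
# 0-based half-open coordinates at all interfaces).
as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    return(genome)
  }
  stop("genome must be a named character vector or DNAStringSet")
}

genome_as_dnastringset <- function(genome) {
  g <- as_genome(genome)
  Biostrings::DNAStringSet(setNames(unname(g), names(g)))
}

# substring with 0-based half-open coordinates
subseq0 <- function(s, start0, end0) substring(s, start0 + 1L, end0)

#' Left-normalize a variant (VCF-style)
#'
#' Shifts an indel to its leftmost equivalent representation and trims
#' shared flanking bases, so that truth records and calls match by
#' coordinate regardless of where inside a repeat run the event was
#' originally placed. SBS records pass through unchanged.
#'
#' @param chrom_seq reference chromosome sequence (single string).
#' @param pos0 0-based position of the first base of `ref`.
#' @param ref,alt reference and alternate alleles (anchor-base convention
#'   for indels, as in VCF).
#' @return list with elements `pos0`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom_seq, pos0, ref, alt) {
  stopifnot(nchar(ref) >= 1L, nchar(alt) >= 1L)
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(list(pos0 = as.integer(pos0), ref = ref, alt = alt))
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  p <- as.integer(pos0)
  repeat {
    if (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    } else if (length(r) == 0 || length(a) == 0) {
      if (p == 0L) break
      prev <- substring(chrom_seq, p, p)  # base at 0-based p-1
      r <- c(prev, r)
      a <- c(prev, a)
      p <- p - 1L
    } else break
  }
  # trim common leading bases, keep one anchor base for indels
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    p <- p + 1L
  }
  list(pos0 = p, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

variant_type <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1L && la == 1L) "SBS" else if (la > lr) "insertion" else "deletion"
}

empty_alignments <- function() {
  data.table(
    qname = character(), chrom = character(), pos = integer(),
    strand = character(), mapq = integer(), unique = logical(),
    cigar = character(), seq = character(),
    mate_chrom = character(), mate_pos = integer(),
    mate_strand = character(), first_of_pair = logical()
  )
}

reflen_from_cigar <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}
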