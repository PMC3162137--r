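#' Generate a random reference genome
#'
#' Draws i.i.d. bases at the configured GC fraction, then guarantees that
#' every chromosome carries at least one homopolymer run (>= 6 identical
#' bases) and one polydinucleotide run (>= 4 tandem copies of a 2-base
#' unit) per 100 kb, so that slippage-prone indel contexts are always
#' available for planting.
#'
#' @param config a [sim_config()].
#' @return named character vector of chromosome sequences ("chr1", ...).
#'   Coordinates everywhere in this package are 0-based half-open.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  gc <- config$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(derive_seed(config$seed, "genome"), {
    chroms <- vapply(seq_len(config$n_chromosomes), function(i) {
      s <- paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = "")
      plant_repeat_runs(s, probs)
    }, character(1))
    names(chroms) <- paste0("chr", seq_len(config$n_chromosomes))
    chroms
  })
}

# Overwrite short windows with a 6-base homopolymer and an 8-base (4-unit)
# dinucleotide run, one of each per started 100 kb. Run bases are drawn
# from the same base distribution as the genome so degenerate GC settings
# stay degenerate; a 14-base overwrite per 100 kb does not disturb the GC
# fraction beyond sampling noise.
plant_repeat_runs <- function(seq, probs) {
  L <- nchar(seq)
  n_runs <- max(1L, ceiling(L / 100000L))
  min_span <- 20L
  if (L < 2L * n_runs * min_span + 40L) n_runs <- 1L
  if (L < 60L) return(seq)  # too short to bother
  avail <- BASES[probs > 0]
  for (i in seq_len(n_runs)) {
    lo <- floor((i - 1) * L / n_runs)
    hi <- floor(i * L / n_runs)
    p1 <- sample((lo + 1):(hi - 30L), 1L)
    b <- sample(BASES, 1L, prob = probs)
    substr(seq, p1, p1 + 5L) <- strrep(b, 6L)
    p2 <- p1 + 15L
    unit <- if (length(avail) >= 2L)
      paste(sample(avail, 2L, replace = FALSE), collapse = "")
    else strrep(avail[1], 2L)
    substr(seq, p2, p2 + 7L) <- strrep(unit, 4L)
  }
  seq
}

#' Locate homopolymer runs in a sequence
#'
#' @param seq chromosome sequence (single string).
#' @param min_run minimum run length.
#' @return data.table with 0-based half-open `start0`/`end0`, `base`,
#'   `length`.
#' @export
find_homopolymer_runs <- function(seq, min_run = 3L) {
  ch <- strsplit(seq, "")[[1]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_run & r$values %in% BASES
  data.table(start0 = starts[keep], end0 = ends[keep],
             base = r$values[keep], length = r$lengths[keep])
}

#' Locate polydinucleotide runs (tandem repeats of a 2-base unit with two
#' distinct bases)
#'
#' @param seq chromosome sequence.
#' @param min_units minimum number of tandem unit copies.
#' @return data.table with `start0`, `end0`, `unit`, `units`.
#' @export
find_dinucleotide_runs <- function(seq, min_units = 2L) {
  pat <- sprintf("(([ACGT])(?!\\2)[ACGT])\\1{%d,}", max(0L, min_units - 1L))
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.table(start0 = integer(), end0 = integer(),
                      unit = character(), units = integer()))
  }
  len <- attr(m, "match.length")
  data.table(start0 = as.integer(m) - 1L,
             end0 = as.integer(m) - 1L + len,
             unit = substring(seq, m, m + 1L),
             units = len %/% 2L)
}

#' Observed GC fraction of a genome
#' @param genome named character vector or DNAStringSet.
#' @return fraction of G/C bases.
#' @export
gc_fraction <- function(genome) {
  g <- as_genome(genome)
  counts <- Biostrings::letterFrequency(genome_as_dnastringset(g), c("GC"))
  sum(counts) / sum(nchar(g))
}
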