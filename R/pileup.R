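#' Apply the read-level filters
#'
#' Retains reads with Phred-scaled mapping quality at or above
#' `min_mapq` (reads with mapq below 20 are excluded by default) and,
#' when `require_unique`, only uniquely mapped reads. Order is
#' preserved; the operation is idempotent.
#'
#' @param records alignment record data.table.
#' @param min_mapq minimum mapping quality (kept when `mapq >= min_mapq`).
#' @param require_unique drop non-uniquely mapped reads.
#' @return filtered data.table.
#' @export
filter_reads <- function(records, min_mapq = 20L, require_unique = TRUE) {
  records <- as.data.table(records)
  if (nrow(records) == 0L) return(records)
  keep <- records$mapq >= min_mapq
  if (require_unique) keep <- keep & records$unique
  records[keep]
}

base_to_idx <- function(chars_int) {
  # A=65 C=67 G=71 T=84 -> 1..4, anything else 5 (N)
  idx <- rep.int(5L, length(chars_int))
  idx[chars_int == 65L] <- 1L
  idx[chars_int == 67L] <- 2L
  idx[chars_int == 71L] <- 3L
  idx[chars_int == 84L] <- 4L
  idx
}

#' Build per-position pileups from filtered reads
#'
#' Read bases are assigned to reference positions via the CIGAR.
#' Insertions are recorded as an allele (`+SEQ`) anchored at the
#' preceding reference position, deletions as an allele (`-SEQ`)
#' likewise anchored; a read carrying an indel contributes the indel
#' allele at the anchor column instead of its matched anchor base, so
#' allele counts at a column always sum to the number of reads
#' represented there. Reads overhanging the chromosome end are rejected
#' with a warning.
#'
#' @param records filtered alignment record data.table.
#' @param genome reference genome.
#' @return object of class `pileup`: per chromosome a 5 x L base-count
#'   matrix (rows A,C,G,T,N) plus an indel-allele table.
#' @export
build_pileup <- function(records, genome) {
  g <- as_genome(genome)
  records <- as.data.table(records)
  out <- list()
  for (cn in names(g)) {
    L <- nchar(g[[cn]])
    recs <- records[chrom == cn]
    counts_idx <- integer(0)
    indel_list <- list()
    if (nrow(recs) > 0L) {
      reflen <- reflen_from_cigar(recs$cigar)
      bad <- recs$pos < 0L | recs$pos + reflen > L
      if (any(bad)) {
        warning(sum(bad), " read(s) overhang the end of ", cn,
                "; rejected")
        recs <- recs[!bad]
        reflen <- reflen[!bad]
      }
      simple <- !grepl("[IDNSHP]", recs$cigar)
      # fast path: all-M reads
      if (any(simple)) {
        sr <- recs[simple]
        w <- nchar(sr$seq)
        posv <- rep(sr$pos, w) + (sequence(w) - 1L)
        basev <- base_to_idx(utf8ToInt(paste(sr$seq, collapse = "")))
        counts_idx <- posv * 5L + basev
      }
      # slow path: cigar walk
      if (any(!simple)) {
        cr <- recs[!simple]
        ops <- GenomicAlignments::explodeCigarOps(cr$cigar)
        lens <- GenomicAlignments::explodeCigarOpLengths(cr$cigar)
        for (i in seq_len(nrow(cr))) {
          contrib <- walk_cigar(cr$pos[i], cr$seq[i], ops[[i]], lens[[i]])
          if (length(contrib$posv) > 0L)
            counts_idx <- c(counts_idx, contrib$posv * 5L + contrib$basev)
          if (length(contrib$indels) > 0L)
            indel_list <- c(indel_list, contrib$indels)
        }
      }
    }
    counts <- matrix(tabulate(counts_idx, nbins = 5L * L), nrow = 5L,
                     dimnames = list(c(BASES, "N"), NULL))
    indels <- if (length(indel_list) > 0L) {
      rbindlist(indel_list)[, .(count = .N), by = .(pos0, allele)]
    } else data.table(pos0 = integer(), allele = character(),
                      count = integer())
    out[[cn]] <- list(counts = counts, indels = indels)
  }
  structure(list(columns = out, genome = g), class = "pileup")
}

# One read's pileup contributions: matched-base positions (minus anchor
# bases reassigned to indel alleles) and indel allele records.
walk_cigar <- function(pos, seq, ops, lens) {
  rpos <- pos           # 0-based reference cursor
  qpos <- 1L            # 1-based read cursor
  posv <- integer(0)
  basev <- integer(0)
  indels <- list()
  for (k in seq_along(ops)) {
    op <- ops[k]; w <- lens[k]
    if (op %in% c("M", "=", "X")) {
      chars <- utf8ToInt(substring(seq, qpos, qpos + w - 1L))
      posv <- c(posv, rpos + 0:(w - 1L))
      basev <- c(basev, base_to_idx(chars))
      rpos <- rpos + w
      qpos <- qpos + w
    } else if (op == "I") {
      ins <- substring(seq, qpos, qpos + w - 1L)
      anchor <- rpos - 1L
      if (anchor >= 0L) {
        drop <- which(posv == anchor)
        if (length(drop) > 0L) {
          keep <- seq_along(posv) != drop[length(drop)]
          posv <- posv[keep]; basev <- basev[keep]
        }
        indels[[length(indels) + 1L]] <-
          data.table(pos0 = anchor, allele = paste0("+", ins))
      }
      qpos <- qpos + w
    } else if (op == "D") {
      anchor <- rpos - 1L
      if (anchor >= 0L) {
        drop <- which(posv == anchor)
        if (length(drop) > 0L) {
          keep <- seq_along(posv) != drop[length(drop)]
          posv <- posv[keep]; basev <- basev[keep]
        }
        indels[[length(indels) + 1L]] <-
          data.table(pos0 = anchor, allele = paste0("-", w))
      }
      rpos <- rpos + w
    } else if (op %in% c("S")) {
      qpos <- qpos + w
    } else if (op %in% c("N")) {
      rpos <- rpos + w
    } # H, P consume nothing
  }
  list(posv = posv, basev = basev, indels = indels)
}

#' Extract one pileup column
#'
#' @param pile a `pileup`.
#' @param chrom chromosome name.
#' @param pos0 0-based position.
#' @return list with `chrom`, `pos0`, `ref_base`, `depth` and named
#'   `allele_counts` (bases and indel alleles); depth equals the sum of
#'   the allele counts.
#' @export
pileup_column <- function(pile, chrom, pos0) {
  stopifnot(inherits(pile, "pileup"))
  col <- pile$columns[[chrom]]
  if (is.null(col)) stop("no pileup for chromosome ", chrom)
  bases <- col$counts[, pos0 + 1L]
  sel <- col$indels$pos0 == pos0   # evaluated outside [] to avoid
  ind <- col$indels[sel]           # capture by the column of same name
  ac <- c(bases[bases > 0L],
          if (nrow(ind) > 0L) setNames(ind$count, ind$allele))
  list(chrom = chrom, pos0 = pos0,
       ref_base = subseq0(pile$genome[[chrom]], pos0, pos0 + 1L),
       depth = sum(ac), allele_counts = ac)
}

#' Build per-position coverage tracks
#'
#' Depth at a position is the number of filtered reads whose aligned
#' reference span (M/D/N operations) covers it.
#'
#' @param records filtered alignment record data.table.
#' @param genome reference genome.
#' @return object of class `coverage_track`: named list of integer
#'   vectors, one per chromosome, length = chromosome length.
#' @export
coverage_track <- function(records, genome) {
  g <- as_genome(genome)
  records <- as.data.table(records)
  out <- lapply(names(g), function(cn) {
    L <- nchar(g[[cn]])
    recs <- records[chrom == cn]
    if (nrow(recs) == 0L) return(integer(L))
    reflen <- reflen_from_cigar(recs$cigar)
    keep <- recs$pos >= 0L & recs$pos + reflen <= L
    recs <- recs[keep]; reflen <- reflen[keep]
    cov <- IRanges::coverage(IRanges::IRanges(start = recs$pos + 1L,
                                              width = reflen), width = L)
    as.integer(cov)
  })
  names(out) <- names(g)
  structure(out, class = "coverage_track")
}

#' Covered genome size
#'
#' The number of reference positions with filtered-read depth at or
#' above `min_depth`, summed over chromosomes: the denominator *s* of
#' the per-site mutation frequency ("unique reads covered" genome size).
#'
#' @param track a `coverage_track` (or plain list of depth vectors).
#' @param min_depth minimum depth.
#' @return base count (numeric scalar).
#' @export
covered_genome_size <- function(track, min_depth = 1L) {
  sum(vapply(track, function(v) sum(v >= min_depth), numeric(1)))
}

#' Mean depth over covered positions
#'
#' Genome-wide average depth over the covered (depth >= 1) mask, used to
#' normalize per-element transposon coverage.
#'
#' @param track a `coverage_track`.
#' @param masked average over covered positions only (TRUE) or the whole
#'   genome (FALSE).
#' @return mean depth.
#' @export
mean_depth <- function(track, masked = TRUE) {
  tot <- sum(vapply(track, function(v) sum(as.numeric(v)), numeric(1)))
  den <- if (masked) covered_genome_size(track, 1L)
         else sum(vapply(track, length, numeric(1)))
  if (den == 0) return(0)
  tot / den
}
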