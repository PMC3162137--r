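#' Extract distant read pairs
#'
#' Retains pairs whose mates map strictly more than `min_distance` bases
#' apart on the same chromosome (leftmost-to-leftmost), plus all
#' interchromosomal pairs — the discordant-pair signature of large
#' insertions, inversions and translocations. Pairs with an unmapped
#' mate are skipped and tallied.
#'
#' @param records filtered alignment record data.table (both mates
#'   present as rows).
#' @param min_distance separation threshold in bases (strict
#'   inequality).
#' @return object of class `distant_pairs`: data.table with one row per
#'   pair (locus 1 is the lexicographically smaller), columns qname,
#'   chrom1/start1/end1/strand1, chrom2/start2/end2/strand2,
#'   `interchrom`, `orientation` (convergent / divergent / same-strand),
#'   plus attribute `n_unmapped_mate`.
#' @export
extract_distant_pairs <- function(records, min_distance = 750L) {
  records <- as.data.table(records)
  empty <- data.table(qname = character(), chrom1 = character(),
                      start1 = integer(), end1 = integer(),
                      strand1 = character(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      strand2 = character(), interchrom = logical(),
                      orientation = character())
  if (nrow(records) == 0L) {
    setattr(empty, "class", c("distant_pairs", class(empty)))
    setattr(empty, "n_unmapped_mate", 0L)
    return(empty)
  }
  unmapped <- is.na(records$mate_pos) | is.na(records$mate_chrom)
  n_unmapped <- sum(unmapped) %/% 2L + sum(unmapped) %% 2L
  recs <- records[!unmapped]
  distant <- recs$chrom != recs$mate_chrom |
    abs(recs$pos - recs$mate_pos) > min_distance
  recs <- recs[distant]
  if (nrow(recs) == 0L) {
    setattr(empty, "class", c("distant_pairs", class(empty)))
    setattr(empty, "n_unmapped_mate", n_unmapped)
    return(empty)
  }
  recs$reflen <- reflen_from_cigar(recs$cigar)
  r1 <- recs[first_of_pair == TRUE]
  r2 <- recs[first_of_pair == FALSE]
  pairs <- merge(
    r1[, .(qname, chrom_a = chrom, start_a = pos, end_a = pos + reflen,
           strand_a = strand)],
    r2[, .(qname, chrom_b = chrom, start_b = pos, end_b = pos + reflen,
           strand_b = strand)],
    by = "qname")
  # put the lexicographically smaller locus first
  swap <- pairs$chrom_b < pairs$chrom_a |
    (pairs$chrom_b == pairs$chrom_a & pairs$start_b < pairs$start_a)
  out <- data.table(
    qname = pairs$qname,
    chrom1 = ifelse(swap, pairs$chrom_b, pairs$chrom_a),
    start1 = ifelse(swap, pairs$start_b, pairs$start_a),
    end1 = ifelse(swap, pairs$end_b, pairs$end_a),
    strand1 = ifelse(swap, pairs$strand_b, pairs$strand_a),
    chrom2 = ifelse(swap, pairs$chrom_a, pairs$chrom_b),
    start2 = ifelse(swap, pairs$start_a, pairs$start_b),
    end2 = ifelse(swap, pairs$end_a, pairs$end_b),
    strand2 = ifelse(swap, pairs$strand_a, pairs$strand_b)
  )
  out$interchrom <- out$chrom1 != out$chrom2
  out$orientation <- ifelse(
    out$strand1 == out$strand2, "same-strand",
    ifelse(out$strand1 == "+", "convergent", "divergent"))
  setorder(out, chrom1, start1, qname)
  setattr(out, "class", c("distant_pairs", class(out)))
  setattr(out, "n_unmapped_mate", n_unmapped)
  out
}

#' Cluster distant pairs into candidate regions
#'
#' Merges overlapping distant-pair read footprints per chromosome and
#' keeps regions where the distant-pair read depth reaches
#' `min_support` at some position (coverage is computed from
#' distant-pair reads only, as the candidate lists are built from the
#' distant-pair subset). The partner locus aggregates the mate
#' footprints of the cluster's reads; clusters overlapping configured
#' exclusion intervals (e.g. centromeres/telomeres) are flagged.
#'
#' @param pairs a `distant_pairs` table.
#' @param min_support minimum distant-pair read depth.
#' @param exclude optional data.table of intervals (chrom, start0, end0)
#'   to flag.
#' @return data.table of clusters: chrom, start0, end0, n_pairs,
#'   max_depth, partner_chrom, partner_start0, partner_end0,
#'   same_strand_frac, dominant_orientation, excluded.
#' @export
cluster_pairs <- function(pairs, min_support = 5L, exclude = NULL) {
  empty <- data.table(chrom = character(), start0 = integer(),
                      end0 = integer(), n_pairs = integer(),
                      max_depth = integer(), partner_chrom = character(),
                      partner_start0 = integer(), partner_end0 = integer(),
                      same_strand_frac = numeric(),
                      dominant_orientation = character(),
                      excluded = logical())
  if (nrow(pairs) == 0L) return(empty)
  # one footprint per read; partner = the other read of the pair
  fp <- rbind(
    data.table(chrom = pairs$chrom1, start0 = pairs$start1,
               end0 = pairs$end1, mate_chrom = pairs$chrom2,
               mate_start0 = pairs$start2, mate_end0 = pairs$end2,
               orientation = pairs$orientation, qname = pairs$qname),
    data.table(chrom = pairs$chrom2, start0 = pairs$start2,
               end0 = pairs$end2, mate_chrom = pairs$chrom1,
               mate_start0 = pairs$start1, mate_end0 = pairs$end1,
               orientation = pairs$orientation, qname = pairs$qname)
  )
  out <- list()
  for (cn in unique(fp$chrom)) {
    f <- fp[chrom == cn]
    ir <- IRanges::IRanges(start = f$start0 + 1L, end = f$end0)
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, red)
    cov <- IRanges::coverage(ir)
    for (j in seq_along(red)) {
      members <- f[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == j]]
      maxd <- IRanges::viewMaxs(
        IRanges::Views(cov, IRanges::start(red)[j], IRanges::end(red)[j]))
      if (maxd < min_support) next
      mate_tab <- sort(table(members$mate_chrom), decreasing = TRUE)
      pch <- names(mate_tab)[1]
      mates <- members[mate_chrom == pch]
      ssf <- mean(members$orientation == "same-strand")
      orient_tab <- sort(table(members$orientation), decreasing = TRUE)
      out[[length(out) + 1L]] <- data.table(
        chrom = cn, start0 = IRanges::start(red)[j] - 1L,
        end0 = IRanges::end(red)[j],
        n_pairs = length(unique(members$qname)),
        max_depth = as.integer(maxd),
        partner_chrom = pch,
        partner_start0 = min(mates$mate_start0),
        partner_end0 = max(mates$mate_end0),
        same_strand_frac = ssf,
        dominant_orientation = names(orient_tab)[1],
        excluded = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- rbindlist(out)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    for (i in seq_len(nrow(res))) {
      ov <- exclude$chrom == res$chrom[i] &
        exclude$start0 < res$end0[i] & exclude$end0 > res$start0[i]
      if (any(ov)) set(res, i, "excluded", TRUE)
    }
  }
  setorder(res, chrom, start0)
  res[]
}

#' Type clustered candidates
#'
#' Orientation/partner rules replace the visual inspection step of the
#' original analysis: an interchromosomal partner makes a translocation
#' candidate; a dominant same-strand orientation an inversion; remaining
#' same-chromosome convergent clusters (bridging a distant donor locus)
#' a large insertion; divergent clusters are reported "ambiguous".
#'
#' @param clusters data.table from [cluster_pairs()].
#' @return data.table of candidates with a `type` column (class
#'   `sv_candidates`).
#' @export
type_candidates <- function(clusters) {
  clusters <- as.data.table(clusters)
  if (nrow(clusters) == 0L) {
    out <- copy(clusters)
    out$type <- character(0)
    return(out)
  }
  type <- ifelse(clusters$partner_chrom != clusters$chrom, "translocation",
          ifelse(clusters$same_strand_frac >= 0.5, "inversion",
          ifelse(clusters$dominant_orientation == "convergent",
                 "large_insertion", "ambiguous")))
  out <- copy(clusters)
  out$type <- type
  setcolorder(out, c("type"))
  out[]
}

#' Subtract progenitor-shared structural candidates
#'
#' A regenerant candidate is marked shared when a progenitor candidate
#' of the same type overlaps its primary locus with at least
#' `reciprocal_overlap` in both directions; only unshared candidates
#' are regenerant events.
#'
#' @param r1_candidates,p1_candidates typed candidate tables.
#' @param reciprocal_overlap minimum reciprocal overlap fraction.
#' @return r1 candidates with a `shared_with_progenitor` column; the
#'   attribute `"novel"` is the unshared subset.
#' @export
subtract_shared <- function(r1_candidates, p1_candidates,
                            reciprocal_overlap = 0.5) {
  r1 <- copy(as.data.table(r1_candidates))
  p1 <- as.data.table(p1_candidates)
  if (nrow(r1) == 0L) {
    r1$shared_with_progenitor <- logical(0)
    return(r1)
  }
  shared <- logical(nrow(r1))
  for (i in seq_len(nrow(r1))) {
    if (nrow(p1) == 0L) break
    cand <- p1[type == r1$type[i] & chrom == r1$chrom[i]]
    if (nrow(cand) == 0L) next
    ov_lo <- pmax(cand$start0, r1$start0[i])
    ov_hi <- pmin(cand$end0, r1$end0[i])
    ov <- pmax(0L, ov_hi - ov_lo)
    w1 <- r1$end0[i] - r1$start0[i]
    w2 <- cand$end0 - cand$start0
    shared[i] <- any(ov >= reciprocal_overlap * w1 &
                       ov >= reciprocal_overlap * w2)
  }
  r1$shared_with_progenitor <- shared
  r1
}

#' Regenerant structural variants (full chain)
#'
#' extract -> cluster -> type -> subtract shared, for one regenerant
#' sample against the progenitor.
#'
#' @param r1_records,p1_records filtered alignment tables.
#' @param min_distance distant-pair threshold (bases, strict).
#' @param min_support minimum distant-pair depth per cluster.
#' @param reciprocal_overlap sharing threshold.
#' @param exclude optional exclusion intervals.
#' @return list: `candidates` (typed R1 candidates with sharing flag),
#'   `novel` (unshared, non-excluded, unambiguous candidates),
#'   `p1_candidates`.
#' @export
detect_svs <- function(r1_records, p1_records, min_distance = 750L,
                       min_support = 5L, reciprocal_overlap = 0.5,
                       exclude = NULL) {
  r1c <- type_candidates(cluster_pairs(
    extract_distant_pairs(r1_records, min_distance), min_support, exclude))
  p1c <- type_candidates(cluster_pairs(
    extract_distant_pairs(p1_records, min_distance), min_support, exclude))
  r1c <- subtract_shared(r1c, p1c, reciprocal_overlap)
  novel <- r1c[shared_with_progenitor == FALSE & excluded == FALSE &
                 type != "ambiguous"]
  list(candidates = r1c, novel = novel, p1_candidates = p1c)
}
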