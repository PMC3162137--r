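# Piecewise-linear maps between reference coordinates and "donor"
# (rearranged haplotype) coordinates. A donor chromosome is an ordered
# list of segments, each a contiguous reference interval carried over
# intact on the + or - strand. Large structural events (inversions,
# translocations, duplicative insertions, large deletions) edit the
# segment list; small variants (SBS, 1-2 bp indels) never enter the map
# and are instead applied on the fly when read sequences are built.
#
# Segments are data.tables with columns ref_chrom, ref_start, ref_end
# (0-based half-open on the reference) and strand ("+"/"-"), in donor
# order. All constructors below assume planted events do not overlap,
# which plant_mutations() enforces.

identity_segments <- function(genome) {
  g <- as_genome(genome)
  out <- lapply(names(g), function(cn) {
    data.table(ref_chrom = cn, ref_start = 0L,
               ref_end = nchar(g[[cn]]), strand = "+")
  })
  names(out) <- names(g)
  out
}

# Split the (+-strand, untouched) segment of `segs` that contains
# reference position p on chromosome `chrom`, so that p becomes a segment
# boundary. No-op if p already is one.
seg_split_ref <- function(segs, chrom, p) {
  hit <- which(segs$ref_chrom == chrom & segs$strand == "+" &
                 segs$ref_start < p & p < segs$ref_end)
  if (length(hit) == 0L) return(segs)
  i <- hit[1]
  top <- segs[i]
  a <- copy(top); a$ref_end <- as.integer(p)
  b <- copy(top); b$ref_start <- as.integer(p)
  rbindlist(list(if (i > 1L) segs[seq_len(i - 1L)], a, b,
                 if (i < nrow(segs)) segs[(i + 1L):nrow(segs)]))
}

seg_range_idx <- function(segs, chrom, s, e) {
  which(segs$ref_chrom == chrom & segs$ref_start >= s & segs$ref_end <= e &
          segs$strand == "+")
}

# Remove reference interval [s, e) from the segment list; returns the
# modified list and the excised piece (in original orientation).
seg_excise <- function(segs, chrom, s, e) {
  segs <- seg_split_ref(segs, chrom, s)
  segs <- seg_split_ref(segs, chrom, e)
  idx <- seg_range_idx(segs, chrom, s, e)
  if (length(idx) == 0L || any(diff(idx) != 1L))
    stop("structural event at ", chrom, ":", s, "-", e,
         " overlaps a previously planted event")
  list(segs = segs[-idx], piece = segs[idx])
}

# Invert reference interval [s, e) in place.
seg_invert <- function(segs, chrom, s, e) {
  segs <- seg_split_ref(segs, chrom, s)
  segs <- seg_split_ref(segs, chrom, e)
  idx <- seg_range_idx(segs, chrom, s, e)
  if (length(idx) == 0L || any(diff(idx) != 1L))
    stop("inversion at ", chrom, ":", s, "-", e, " overlaps another event")
  mid <- segs[rev(idx)]
  mid$strand <- ifelse(mid$strand == "+", "-", "+")
  rbindlist(list(segs[seq_len(min(idx) - 1L)], mid,
                 if (max(idx) < nrow(segs)) segs[(max(idx) + 1L):nrow(segs)]))
}

# Map a reference position to a donor offset on one donor chromosome
# (must fall in a +-strand segment).
seg_ref_to_donor <- function(segs, chrom, p) {
  don <- cumsum(c(0L, segs$ref_end - segs$ref_start))
  hit <- which(segs$ref_chrom == chrom & segs$strand == "+" &
                 segs$ref_start <= p & p <= segs$ref_end)
  if (length(hit) == 0L)
    stop("reference position ", chrom, ":", p,
         " does not map to an intact donor location")
  i <- hit[1]
  don[i] + (p - segs$ref_start[i])
}

# Splice `piece` into the segment list at donor offset d.
seg_insert_at_donor <- function(segs, d, piece) {
  don <- cumsum(c(0L, segs$ref_end - segs$ref_start))
  i <- findInterval(d, don, rightmost.closed = FALSE)
  if (d == don[i]) {  # boundary: insert before segment i
    return(rbindlist(list(if (i > 1L) segs[seq_len(i - 1L)], piece,
                          segs[i:nrow(segs)])))
  }
  # split segment i at internal offset
  off <- d - don[i]
  top <- segs[i]
  a <- copy(top); b <- copy(top)
  if (top$strand == "+") {
    a$ref_end <- top$ref_start + as.integer(off)
    b$ref_start <- a$ref_end
  } else {
    a$ref_start <- top$ref_end - as.integer(off)
    b$ref_end <- a$ref_start
  }
  rbindlist(list(if (i > 1L) segs[seq_len(i - 1L)], a, piece, b,
                 if (i < nrow(segs)) segs[(i + 1L):nrow(segs)]))
}

seg_donor_length <- function(segs) sum(segs$ref_end - segs$ref_start)

# Materialize the donor sequence of one chromosome from the reference.
seg_materialize <- function(segs, genome) {
  g <- as_genome(genome)
  parts <- vapply(seq_len(nrow(segs)), function(i) {
    s <- subseq0(g[[segs$ref_chrom[i]]], segs$ref_start[i], segs$ref_end[i])
    if (segs$strand[i] == "-") revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

# Map a donor interval [d0, d1) to its reference placement. Returns NULL
# when the interval spans a segment boundary (breakpoint-crossing reads
# are dropped by the simulator, mimicking clipped/unmapped reads), else
# list(ref_chrom, ref_start, ref_end, flip).
seg_map_span <- function(segs, donor_starts, d0, d1) {
  i <- findInterval(d0, donor_starts)
  if (i < 1L || i > nrow(segs)) return(NULL)
  seg_end <- donor_starts[i] + (segs$ref_end[i] - segs$ref_start[i])
  if (d1 > seg_end) return(NULL)
  off0 <- d0 - donor_starts[i]
  w <- d1 - d0
  if (segs$strand[i] == "+") {
    rs <- segs$ref_start[i] + off0
    list(ref_chrom = segs$ref_chrom[i], ref_start = rs, ref_end = rs + w,
         flip = FALSE)
  } else {
    re <- segs$ref_end[i] - off0
    list(ref_chrom = segs$ref_chrom[i], ref_start = re - w, ref_end = re,
         flip = TRUE)
  }
}

# Apply a table of structural events to an identity map. `svs` columns:
# type in {large_insertion, large_deletion, inversion, translocation,
# te_amplification}; chrom/start0/end0 = source interval (for inversions
# and deletions the affected interval); target_chrom/target_pos0 =
# insertion point for insertions/translocations/te_amplification.
apply_svs <- function(genome, svs) {
  segmap <- identity_segments(genome)
  if (is.null(svs) || nrow(svs) == 0L) return(segmap)
  svs <- copy(as.data.table(svs))
  pending_insert <- list()
  cut_types <- c("large_deletion", "inversion", "translocation")
  cuts <- svs[type %in% cut_types][order(chrom, -start0)]
  for (i in seq_len(nrow(cuts))) {
    ev <- cuts[i]
    if (ev$type == "inversion") {
      segmap[[ev$chrom]] <- seg_invert(segmap[[ev$chrom]], ev$chrom,
                                       ev$start0, ev$end0)
    } else {
      res <- seg_excise(segmap[[ev$chrom]], ev$chrom, ev$start0, ev$end0)
      segmap[[ev$chrom]] <- res$segs
      if (ev$type == "translocation")
        pending_insert[[length(pending_insert) + 1L]] <-
          list(target_chrom = ev$target_chrom, target_pos0 = ev$target_pos0,
               piece = res$piece)
    }
  }
  dups <- svs[type %in% c("large_insertion", "te_amplification")]
  for (i in seq_len(nrow(dups))) {
    ev <- dups[i]
    pending_insert[[length(pending_insert) + 1L]] <-
      list(target_chrom = ev$target_chrom, target_pos0 = ev$target_pos0,
           piece = data.table(ref_chrom = ev$chrom,
                              ref_start = as.integer(ev$start0),
                              ref_end = as.integer(ev$end0), strand = "+"))
  }
  # insert at descending target position per chromosome so earlier splices
  # do not shift later targets
  if (length(pending_insert) > 0L) {
    ord <- order(vapply(pending_insert, function(x) x$target_chrom, character(1)),
                 -vapply(pending_insert, function(x) x$target_pos0, numeric(1)))
    for (ins in pending_insert[ord]) {
      segs <- segmap[[ins$target_chrom]]
      d <- seg_ref_to_donor(segs, ins$target_chrom, ins$target_pos0)
      segmap[[ins$target_chrom]] <- seg_insert_at_donor(segs, d, ins$piece)
    }
  }
  segmap
}
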