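# Build one read of `read_len` bases starting at 0-based reference
# position rs, carrying the haplotype's small variants (VCF-style rows
# pos0/ref/alt, sorted, restricted to a window around the read). Returns
# list(seq, cigar, ref_end) or NULL when the read would overhang the
# chromosome. Variants are applied with the anchor-base convention:
# insertions appear after their anchor base, deletions skip reference
# bases after the anchor. Leading indels (anchor before the first emitted
# base) degrade gracefully: the read simply starts beyond them, as an
# aligner would place it.
build_read <- function(chrom_seq, vars, rs, read_len) {
  L <- nchar(chrom_seq)
  out_seq <- character(0)
  ops <- character(0)
  opw <- integer(0)
  emit <- function(op, w) {
    n <- length(ops)
    if (n > 0L && ops[n] == op) opw[n] <<- opw[n] + w
    else { ops[n + 1L] <<- op; opw[n + 1L] <<- w }
  }
  r <- rs
  filled <- 0L
  vi <- 1L
  nv <- if (is.null(vars)) 0L else nrow(vars)
  while (filled < read_len) {
    # next relevant variant
    v <- NULL
    while (vi <= nv) {
      cand <- vars[vi]
      vend <- cand$pos0 + nchar(cand$ref)
      if (vend <= r) { vi <- vi + 1L; next }
      v <- cand
      break
    }
    if (is.null(v) || v$pos0 >= rs + 4L * read_len) {
      need <- read_len - filled
      if (r + need > L) return(NULL)
      out_seq <- c(out_seq, subseq0(chrom_seq, r, r + need))
      emit("M", need)
      r <- r + need
      filled <- read_len
      break
    }
    if (v$pos0 < r) {
      # read starts inside a deletion: begin after it
      r <- v$pos0 + nchar(v$ref)
      vi <- vi + 1L
      next
    }
    lr <- nchar(v$ref); la <- nchar(v$alt)
    # emit reference bases up to and including the variant anchor base
    lead <- min(read_len - filled, v$pos0 + 1L - r)
    if (lead > 0L) {
      if (r + lead > L) return(NULL)
      out_seq <- c(out_seq, subseq0(chrom_seq, r, r + lead))
      emit("M", lead)
      filled <- filled + lead
      r <- r + lead
    }
    if (filled >= read_len) break
    if (r <= v$pos0) break  # couldn't even reach the variant (read full)
    if (lr == 1L && la == 1L) {
      # SBS: the emitted anchor base IS the variant base; replace it
      out_seq[length(out_seq)] <-
        paste0(substring(out_seq[length(out_seq)], 1L, lead - 1L), v$alt)
    } else if (la > lr) {
      ins <- substring(v$alt, 2L)
      take <- min(nchar(ins), read_len - filled)
      if (take > 0L) {
        out_seq <- c(out_seq, substring(ins, 1L, take))
        emit("I", take)
        filled <- filled + take
      }
    } else {
      k <- lr - 1L
      emit("D", k)
      r <- r + k
    }
    vi <- vi + 1L
  }
  if (filled < read_len) return(NULL)
  # drop a trailing D (cannot end a read on a deletion)
  n <- length(ops)
  if (ops[n] == "D") { r <- r - opw[n]; ops <- ops[-n]; opw <- opw[-n] }
  list(seq = paste(out_seq, collapse = ""),
       cigar = paste0(opw, ops, collapse = ""),
       ref_end = r)
}

#' Simulate aligned paired-end read pairs from a diploid sample
#'
#' Fragments are drawn uniformly along each haplotype at the configured
#' depth (half from each haplotype), with Gaussian fragment lengths.
#' Alignment is by construction: each record carries its true mapping
#' position on the reference, mapping quality 60 and uniqueness flag
#' TRUE. Reads spanning a structural breakpoint are dropped (a real
#' aligner would clip or fail to map them); pairs whose mates fall in
#' different rearranged blocks produce the discordant coordinates and
#' orientations characteristic of the planted event. Substitution
#' sequencing errors are injected at `base_error_rate`.
#'
#' @param sample a `sim_sample` from [plant_mutations()] (or a bare
#'   genome, treated as a variant-free homozygous sample).
#' @param config a [sim_config()].
#' @return data.table of alignment records sorted by (chrom, pos):
#'   columns qname, chrom, pos (0-based), strand, mapq, unique, cigar,
#'   seq, mate_chrom, mate_pos, mate_strand, first_of_pair.
#' @export
simulate_read_pairs <- function(sample, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(sample, "sim_sample")) {
    g <- as_genome(sample)
    sample <- structure(list(reference = g,
                             variants = list(A = data.table(chrom = character(),
                                                            pos0 = integer(),
                                                            ref = character(),
                                                            alt = character()),
                                             B = data.table(chrom = character(),
                                                            pos0 = integer(),
                                                            ref = character(),
                                                            alt = character())),
                             segmap = list(A = identity_segments(g),
                                           B = identity_segments(g)),
                             truth = empty_truth()),
                        class = "sim_sample")
  }
  if (config$depth == 0) {
    warning("depth 0: returning an empty record set")
    return(empty_alignments())
  }
  rl <- config$read_length
  recs <- with_seed(derive_seed(config$seed, "reads"), {
    out <- list()
    for (hap in c("A", "B")) {
      segmap <- sample$segmap[[hap]]
      vars <- sample$variants[[hap]]
      setorder(vars, chrom, pos0)
      donor_len <- vapply(segmap, seg_donor_length, numeric(1))
      total <- sum(donor_len)
      n_frag <- round(config$depth * total / (2 * rl) / 2)
      if (n_frag == 0L) next
      frag_chrom <- sample(names(segmap), n_frag, replace = TRUE,
                           prob = donor_len)
      frag_len <- pmax(rl, round(rnorm(n_frag, config$fragment_mean,
                                       config$fragment_sd)))
      for (cn in names(segmap)) {
        idx <- which(frag_chrom == cn)
        if (length(idx) == 0L) next
        segs <- segmap[[cn]]
        dstarts <- cumsum(c(0L, head(segs$ref_end - segs$ref_start, -1L)))
        clen <- donor_len[[cn]]
        fl <- pmin(frag_len[idx], clen)
        fs <- as.integer(floor(runif(length(idx), 0, clen - fl + 1)))
        out[[length(out) + 1L]] <-
          emit_pairs(sample, segs, dstarts, cn, hap, fs, fl, rl)
      }
    }
    recs <- rbindlist(out)
    if (nrow(recs) > 0L) recs <- inject_errors(recs, config$base_error_rate)
    recs
  })
  if (nrow(recs) == 0L) return(empty_alignments())
  setorder(recs, chrom, pos, qname)
  recs[]
}

# Map both reads of each fragment and build their sequences. A read
# whose span crosses a segment boundary is unmappable (a real aligner
# would clip or reject it); its mate, if mappable, is kept with
# unmapped-mate fields. The all-M no-variant case is fully vectorized.
emit_pairs <- function(sample, segs, dstarts, cn, hap, fs, fl, rl) {
  g <- sample$reference
  vars <- sample$variants[[hap]]
  n <- length(fs)
  seg_w <- segs$ref_end - segs$ref_start
  map_vec <- function(d0) {
    i <- findInterval(d0, dstarts)
    ok <- i >= 1L & i <= nrow(segs) & (d0 + rl) <= dstarts[i] + seg_w[i]
    i[!ok] <- NA_integer_
    off <- d0 - dstarts[i]
    minus <- !is.na(i) & segs$strand[i] == "-"
    rs <- ifelse(minus, segs$ref_end[i] - off - rl, segs$ref_start[i] + off)
    list(seg = i, rs = as.integer(rs), flip = minus,
         chrom = segs$ref_chrom[i])
  }
  m1 <- map_vec(fs)
  m2 <- map_vec(fs + fl - rl)
  s1 <- ifelse(m1$flip, "-", "+")
  s2 <- ifelse(m2$flip, "+", "-")
  ok1 <- !is.na(m1$seg)
  ok2 <- !is.na(m2$seg)
  keep <- ok1 | ok2
  if (!any(keep)) return(empty_alignments())
  qn <- sprintf("frag_%s_%s_%07d", hap, cn, seq_len(n))
  make_rows <- function(m, strand, mm, mstrand, mok, first) {
    idx <- which(!is.na(m$seg))
    if (length(idx) == 0L) return(NULL)
    chrom <- m$chrom[idx]
    rs <- m$rs[idx]
    seqs <- character(length(idx))
    cigars <- rep(paste0(rl, "M"), length(idx))
    valid <- rep(TRUE, length(idx))
    for (cnm in unique(chrom)) {
      sel <- which(chrom == cnm)
      refseq <- g[[cnm]]
      L <- nchar(refseq)
      inb <- rs[sel] >= 0L & rs[sel] + rl <= L
      valid[sel][!inb] <- FALSE
      sel <- sel[inb]
      if (length(sel) == 0L) next
      vc <- vars[vars$chrom == cnm]
      if (nrow(vc) > 0L) {
        vpos <- vc$pos0
        nhit <- findInterval(rs[sel] + rl + 9L, vpos) -
          findInterval(rs[sel] - 10L, vpos)
        fast <- nhit == 0L
      } else fast <- rep(TRUE, length(sel))
      fsel <- sel[fast]
      if (length(fsel) > 0L)
        seqs[fsel] <- substring(refseq, rs[fsel] + 1L, rs[fsel] + rl)
      for (j in sel[!fast]) {
        r <- build_read(refseq, vc, rs[j], rl)
        if (is.null(r)) { valid[j] <- FALSE; next }
        seqs[j] <- r$seq
        cigars[j] <- r$cigar
      }
    }
    mate_missing <- !mok[idx]
    data.table(
      qname = qn[idx], chrom = chrom, pos = rs, strand = strand[idx],
      mapq = 60L, unique = TRUE, cigar = cigars, seq = seqs,
      mate_chrom = ifelse(mate_missing, NA_character_, mm$chrom[idx]),
      mate_pos = ifelse(mate_missing, NA_integer_, mm$rs[idx]),
      mate_strand = ifelse(mate_missing, NA_character_, mstrand[idx]),
      first_of_pair = first)[valid]
  }
  rbindlist(list(make_rows(m1, s1, m2, s2, ok2, TRUE),
                 make_rows(m2, s2, m1, s1, ok1, FALSE)),
            use.names = TRUE)
}

# Fast path: no small variant near the read -> plain substring, all-M cigar.
realize_read <- function(g, vars, chrom, rs, rl) {
  seq <- g[[chrom]]
  L <- nchar(seq)
  if (rs < 0L || rs + rl > L) return(NULL)
  sel <- vars$chrom == chrom & vars$pos0 > rs - 10L & vars$pos0 < rs + rl + 10L
  w <- vars[sel]
  if (nrow(w) == 0L) {
    return(list(seq = subseq0(seq, rs, rs + rl),
                cigar = paste0(rl, "M"), ref_end = rs + rl))
  }
  build_read(seq, w, rs, rl)
}

# Vectorized substitution-error injection; CIGARs are unaffected
# (mismatches stay M).
inject_errors <- function(recs, rate) {
  if (rate <= 0) return(recs)
  widths <- nchar(recs$seq)
  total <- sum(widths)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(recs)
  flat <- sort(sample.int(total, n_err))
  ends <- cumsum(widths)
  read_idx <- findInterval(flat - 1L, ends) + 1L
  offset <- flat - c(0L, ends)[read_idx]
  for (j in seq_len(n_err)) {
    i <- read_idx[j]
    o <- offset[j]
    orig <- substring(recs$seq[i], o, o)
    if (!orig %in% BASES) next
    repl <- sample(setdiff(BASES, orig), 1L)
    s <- recs$seq[i]
    substr(s, o, o) <- repl
    set(recs, i, "seq", s)
  }
  recs
}
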