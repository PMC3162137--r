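#' Call homozygous variants from a pileup
#'
#' Emits a call at columns where the filtered depth reaches `min_depth`
#' and a single non-reference allele accounts for at least
#' `min_alt_fraction` of the reads. Heterozygous-looking columns (two
#' alleles each below the fraction) yield no call by design: the
#' pipeline detects homozygous mutations only. Indel alleles compete
#' with base alleles at their anchor column. Calls are left-normalized.
#'
#' @param pile a `pileup` built from filtered reads.
#' @param min_depth minimum column depth.
#' @param min_alt_fraction minimum fraction of reads supporting the
#'   single alternate allele.
#' @param sample_id sample label carried on the calls.
#' @return data.table of calls: chrom, pos0, ref, alt, type, depth,
#'   alt_fraction, sample.
#' @export
call_homozygous <- function(pile, min_depth = 5L, min_alt_fraction = 0.9,
                            sample_id = "sample") {
  stopifnot(inherits(pile, "pileup"))
  calls <- list()
  for (cn in names(pile$columns)) {
    col <- pile$columns[[cn]]
    seq <- pile$genome[[cn]]
    L <- nchar(seq)
    base_depth <- colSums(col$counts)
    depth <- base_depth
    ind <- col$indels
    ind_tot <- integer(0)
    if (nrow(ind) > 0L) {
      agg <- ind[, .(tot = sum(count)), by = pos0]
      depth[agg$pos0 + 1L] <- depth[agg$pos0 + 1L] + agg$tot
    }
    ridx <- base_to_idx(utf8ToInt(seq))
    # best non-reference base allele per position
    cnr <- col$counts
    cnr[cbind(ridx, seq_len(L))] <- 0L
    cnr[5L, ] <- 0L                     # N is never an alternate allele
    cand_pos <- which(depth >= min_depth)
    if (length(cand_pos) == 0L) next
    sub <- cnr[, cand_pos, drop = FALSE]
    best_idx <- max.col(t(sub), ties.method = "first")
    best_cnt <- sub[cbind(best_idx, seq_along(cand_pos))]
    # SBS candidates
    ok <- best_cnt >= min_alt_fraction * depth[cand_pos] & best_cnt > 0L &
      ridx[cand_pos] != 5L
    if (any(ok)) {
      p0 <- cand_pos[ok] - 1L
      calls[[length(calls) + 1L]] <- data.table(
        chrom = cn, pos0 = p0,
        ref = substring(seq, p0 + 1L, p0 + 1L),
        alt = BASES[best_idx[ok]],
        type = "SBS",
        depth = as.integer(depth[cand_pos[ok]]),
        alt_fraction = best_cnt[ok] / depth[cand_pos[ok]],
        sample = sample_id)
    }
    # indel candidates
    if (nrow(ind) > 0L) {
      top <- ind[order(pos0, -count), .SD[1L], by = pos0]
      top <- top[depth[pos0 + 1L] >= min_depth &
                   count >= min_alt_fraction * depth[pos0 + 1L]]
      if (nrow(top) > 0L) {
        rows <- lapply(seq_len(nrow(top)), function(i) {
          p <- top$pos0[i]
          a <- top$allele[i]
          anchor <- substring(seq, p + 1L, p + 1L)
          if (startsWith(a, "+")) {
            ref <- anchor; alt <- paste0(anchor, substring(a, 2L))
            ty <- "insertion"
          } else {
            k <- as.integer(substring(a, 2L))
            ref <- paste0(anchor, subseq0(seq, p + 1L, p + 1L + k))
            alt <- anchor
            ty <- "deletion"
          }
          nv <- normalize_variant(seq, p, ref, alt)
          data.table(chrom = cn, pos0 = nv$pos0, ref = nv$ref, alt = nv$alt,
                     type = ty, depth = as.integer(depth[p + 1L]),
                     alt_fraction = top$count[i] / depth[p + 1L],
                     sample = sample_id)
        })
        calls[[length(calls) + 1L]] <- rbindlist(rows)
      }
    }
  }
  if (length(calls) == 0L) {
    return(data.table(chrom = character(), pos0 = integer(),
                      ref = character(), alt = character(),
                      type = character(), depth = integer(),
                      alt_fraction = numeric(), sample = character()))
  }
  out <- rbindlist(calls)
  out <- unique(out, by = c("chrom", "pos0", "ref", "alt"))
  setorder(out, chrom, pos0)
  out[]
}

# Progenitor evidence at a call site: depth at the anchor column and
# support for the call's alternate allele.
p1_evidence <- function(call, p1_pile) {
  chrom_cols <- p1_pile$columns[[call$chrom]]
  if (is.null(chrom_cols)) return(list(depth = 0L, alt_count = 0L))
  col <- pileup_column(p1_pile, call$chrom, call$pos0)
  if (call$type == "SBS") {
    cnt <- col$allele_counts[call$alt]
    return(list(depth = col$depth,
                alt_count = if (is.na(cnt)) 0L else as.integer(cnt)))
  }
  # indels: normalize every P1 indel allele in a window around the call
  # and count those matching the call's normalized representation
  seq <- p1_pile$genome[[call$chrom]]
  ind <- chrom_cols$indels
  win <- ind[pos0 >= call$pos0 - 25L & pos0 <= call$pos0 + 25L]
  alt_count <- 0L
  if (nrow(win) > 0L) {
    for (i in seq_len(nrow(win))) {
      p <- win$pos0[i]; a <- win$allele[i]
      anchor <- substring(seq, p + 1L, p + 1L)
      if (startsWith(a, "+")) {
        nv <- normalize_variant(seq, p, anchor,
                                paste0(anchor, substring(a, 2L)))
      } else {
        k <- as.integer(substring(a, 2L))
        nv <- normalize_variant(seq, p,
                                paste0(anchor, subseq0(seq, p + 1L, p + 1L + k)),
                                anchor)
      }
      if (nv$pos0 == call$pos0 && nv$ref == call$ref && nv$alt == call$alt)
        alt_count <- alt_count + win$count[i]
    }
  }
  list(depth = col$depth, alt_count = alt_count)
}

#' Subtract the progenitor: keep only novel regenerant mutations
#'
#' A regenerant (R1) call is novel only when the progenitor (P1) sample
#' is adequately covered at the site (depth >= `min_p1_depth`) and shows
#' at most `max_p1_alt_fraction` support for the same alternate allele.
#' Sites undercovered in P1 are set aside as "unresolvable" rather than
#' silently called novel; calls with substantial P1 support are
#' "inherited". Because novelty is defined against P1 evidence rather
#' than against the reference assembly, apparent errors in the reference
#' cancel out.
#'
#' @param r1_calls calls from [call_homozygous()].
#' @param p1_pile the progenitor `pileup` (built from filtered reads).
#' @param min_p1_depth minimum progenitor depth to resolve a site.
#' @param max_p1_alt_fraction maximum progenitor support for the
#'   alternate allele.
#' @return list with data.tables `novel` (calls plus p1_depth,
#'   p1_alt_fraction), `inherited` and `unresolvable`.
#' @export
subtract_progenitor <- function(r1_calls, p1_pile, min_p1_depth = 5L,
                                max_p1_alt_fraction = 0.1) {
  r1_calls <- as.data.table(r1_calls)
  if (is.null(p1_pile)) {
    message("no progenitor pileup supplied: all calls unresolvable")
    return(list(novel = r1_calls[0],
                inherited = r1_calls[0],
                unresolvable = copy(r1_calls)))
  }
  stopifnot(inherits(p1_pile, "pileup"))
  n <- nrow(r1_calls)
  p1_depth <- integer(n)
  p1_af <- numeric(n)
  status <- character(n)
  for (i in seq_len(n)) {
    ev <- p1_evidence(r1_calls[i], p1_pile)
    p1_depth[i] <- ev$depth
    p1_af[i] <- if (ev$depth > 0L) ev$alt_count / ev$depth else 0
    status[i] <- if (ev$depth < min_p1_depth) "unresolvable"
    else if (p1_af[i] > max_p1_alt_fraction) "inherited"
    else "novel"
  }
  res <- copy(r1_calls)
  res$p1_depth <- p1_depth
  res$p1_alt_fraction <- p1_af
  list(novel = res[status == "novel"],
       inherited = res[status == "inherited"],
       unresolvable = res[status == "unresolvable"])
}

#' Compare novel calls with the planted truth
#'
#' The in-silico analogue of capillary-sequencing validation: matches
#' calls and truth records by chromosome, left-normalized position and
#' alleles. Sensitivity is computed against homozygous truth events
#' (the caller is homozygous-only by contract); calls matching planted
#' heterozygous events are tallied separately.
#'
#' @param novel data.table of novel calls.
#' @param truth a `truth_set`.
#' @param genome reference genome (for normalizing truth records).
#' @return list: `sensitivity`, `precision` (NA when undefined), `tp`,
#'   `fp`, `n_truth_hom`, `het_called`, `misses` (truth rows not
#'   recovered), `false_positives` (call rows with no truth match),
#'   `per_class` breakdown.
#' @export
recover_truth <- function(novel, truth, genome) {
  stopifnot(inherits(truth, "truth_set"))
  g <- as_genome(genome)
  novel <- as.data.table(novel)
  tr <- rbind(
    if (nrow(truth$sbs) > 0L)
      truth$sbs[, .(chrom, pos0, ref, alt, zygosity, class = "SBS")],
    if (nrow(truth$indels) > 0L)
      truth$indels[, .(chrom, pos0, ref, alt, zygosity, class = type)]
  )
  if (is.null(tr)) tr <- data.table(chrom = character(), pos0 = integer(),
                                    ref = character(), alt = character(),
                                    zygosity = character(), class = character())
  if (nrow(tr) > 0L) {
    for (i in seq_len(nrow(tr))) {
      nv <- normalize_variant(g[[tr$chrom[i]]], tr$pos0[i], tr$ref[i],
                              tr$alt[i])
      set(tr, i, "pos0", nv$pos0)
      set(tr, i, "ref", nv$ref)
      set(tr, i, "alt", nv$alt)
    }
  }
  key <- function(d) paste(d$chrom, d$pos0, d$ref, d$alt)
  tr_hom <- tr[zygosity == "hom"]
  tr_het <- tr[zygosity == "het"]
  ck <- key(novel)
  tp <- sum(key(tr_hom) %in% ck)
  het_called <- sum(key(tr_het) %in% ck)
  fp_rows <- novel[!ck %in% key(tr)]
  misses <- tr_hom[!key(tr_hom) %in% ck]
  n_hom <- nrow(tr_hom)
  sens <- if (n_hom > 0L) tp / n_hom else NA_real_
  prec <- if (nrow(novel) > 0L) tp / nrow(novel) else NA_real_
  per_class <- if (nrow(tr_hom) > 0L) {
    tr_hom[, .(n_truth = .N, recovered = sum(key(.SD) %in% ck)), by = class]
  } else data.table(class = character(), n_truth = integer(),
                    recovered = integer())
  list(sensitivity = sens, precision = prec, tp = tp,
       fp = nrow(fp_rows), n_truth_hom = n_hom, het_called = het_called,
       misses = misses, false_positives = fp_rows, per_class = per_class)
}
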