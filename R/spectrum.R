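#' Classify a base substitution (pyrimidine-strand collapsed)
#'
#' Purine-strand changes are reported on the pyrimidine strand (G>A is
#' reported as C>T), giving six classes: C>T and T>C are transitions,
#' C>A, C>G, T>A and T>G are transversions.
#'
#' @param ref,alt single distinct bases in A/C/G/T.
#' @return list with `class` (e.g. "C>T"), `kind` ("transition" or
#'   "transversion") and `raw` (the uncollapsed "ref>alt").
#' @export
classify_substitution <- function(ref, alt) {
  if (!ref %in% BASES || !alt %in% BASES)
    stop("classify_substitution: ref and alt must be one of A/C/G/T")
  if (ref == alt)
    stop("classify_substitution: ref and alt must differ")
  raw <- paste0(ref, ">", alt)
  if (ref %in% c("G", "A")) {
    ref2 <- complement_base(ref)
    alt2 <- complement_base(alt)
  } else {
    ref2 <- ref; alt2 <- alt
  }
  cls <- paste0(ref2, ">", alt2)
  kind <- if (cls %in% c("C>T", "T>C")) "transition" else "transversion"
  list(class = cls, kind = kind, raw = raw)
}

#' Classify substitutions in a call table
#' @param calls data.table with ref/alt columns (SBS rows only are used).
#' @return the SBS rows with `class`, `kind` and `raw_class` columns added.
#' @export
classify_substitutions <- function(calls) {
  calls <- as.data.table(calls)
  sbs <- calls[nchar(ref) == 1L & nchar(alt) == 1L & ref != alt]
  if (nrow(sbs) == 0L) {
    sbs$class <- character(0); sbs$kind <- character(0)
    sbs$raw_class <- character(0)
    return(sbs)
  }
  res <- lapply(seq_len(nrow(sbs)),
                function(i) classify_substitution(sbs$ref[i], sbs$alt[i]))
  sbs$class <- vapply(res, `[[`, character(1), "class")
  sbs$kind <- vapply(res, `[[`, character(1), "kind")
  sbs$raw_class <- vapply(res, `[[`, character(1), "raw")
  sbs
}

#' Transition:transversion ratio
#'
#' @param mutations data.table of SBS calls (ref/alt columns), or a
#'   table already carrying a `kind` column.
#' @return transitions divided by transversions; NA (with a message)
#'   when there are no transversions.
#' @export
ts_tv_ratio <- function(mutations) {
  mutations <- as.data.table(mutations)
  if (!"kind" %in% names(mutations)) mutations <- classify_substitutions(mutations)
  ts <- sum(mutations$kind == "transition")
  tv <- sum(mutations$kind == "transversion")
  if (tv == 0L) {
    message("ts_tv_ratio: no transversions; ratio undefined")
    return(NA_real_)
  }
  ts / tv
}

#' Classify the sequence context of a small indel
#'
#' Replication-slippage hotspots: an indel whose inserted/deleted unit
#' extends or shortens a reference run of at least `min_run` identical
#' bases is "homopolymer"; one matching a tandem dinucleotide repeat of
#' at least `min_units` copies is "polydinucleotide"; anything else is
#' "other". The indel must be left-normalized (anchor-base convention).
#'
#' @param genome reference genome.
#' @param chrom chromosome name.
#' @param pos0 0-based anchor position.
#' @param ref,alt normalized alleles.
#' @param min_run minimum homopolymer run length (reference, counting
#'   the affected site).
#' @param min_units minimum tandem dinucleotide copies.
#' @return list with `context`, `run_length`, `unit`.
#' @export
classify_indel_context <- function(genome, chrom, pos0, ref, alt,
                                   min_run = 3L, min_units = 2L) {
  g <- as_genome(genome)
  seq <- g[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  L <- nchar(seq)
  if (pos0 < 0L || pos0 + nchar(ref) > L)
    stop("indel out of genome bounds: ", chrom, ":", pos0)
  unit <- if (nchar(alt) > nchar(ref)) substring(alt, nchar(ref) + 1L)
          else substring(ref, nchar(alt) + 1L)
  k <- nchar(unit)
  chars <- strsplit(unit, "")[[1]]
  # homopolymer: all unit bases identical, reference run >= min_run
  if (length(unique(chars)) == 1L) {
    b <- chars[1]
    left <- pos0       # count identical bases at pos0, pos0-1, ... (anchor side)
    nleft <- 0L
    while (left >= 0L && substring(seq, left + 1L, left + 1L) == b) {
      nleft <- nleft + 1L
      left <- left - 1L
    }
    right <- pos0 + 1L # and forward from the first affected base
    nright <- 0L
    while (right < L && substring(seq, right + 1L, right + 1L) == b) {
      nright <- nright + 1L
      right <- right + 1L
    }
    run <- nleft + nright
    if (run >= min_run)
      return(list(context = "homopolymer", run_length = run, unit = b))
  }
  if (k == 2L && chars[1] != chars[2]) {
    n_units <- 0L
    p <- pos0 + 1L     # copies forward of the anchor
    while (p + 2L <= L && subseq0(seq, p, p + 2L) == unit) {
      n_units <- n_units + 1L
      p <- p + 2L
    }
    p <- pos0 - 1L     # copies ending at the anchor
    while (p >= 0L && subseq0(seq, p, p + 2L) == unit) {
      n_units <- n_units + 1L
      p <- p - 2L
    }
    if (n_units >= min_units)
      return(list(context = "polydinucleotide", run_length = n_units,
                  unit = unit))
  }
  list(context = "other", run_length = 0L, unit = unit)
}

#' Summarize the mutation spectrum
#'
#' Pools novel mutations into the summary tables of the analysis:
#' per-sample detected counts (SBS/indel split) with the x4 theoretical
#' count, substitution classes (6-class collapsed and 12-class raw),
#' transition:transversion ratio, indel contexts, per-chromosome counts
#' and (when an annotation is supplied) genomic-location categories.
#'
#' @param novel data.table of novel mutations (chrom, pos0, ref, alt,
#'   type, sample).
#' @param genome reference genome.
#' @param annotation optional annotation object from [read_annotation()].
#' @param min_run,min_units indel-context thresholds.
#' @return list of data.tables, class `spectrum_summary`.
#' @export
spectrum_summary <- function(novel, genome, annotation = NULL,
                             min_run = 3L, min_units = 2L) {
  novel <- as.data.table(novel)
  if (!"type" %in% names(novel) && nrow(novel) > 0L)
    novel$type <- mapply(variant_type, novel$ref, novel$alt)
  if (!"sample" %in% names(novel)) novel$sample <- "sample"
  per_sample <- if (nrow(novel) > 0L) {
    novel[, .(n_sbs = sum(type == "SBS"),
              n_indel = sum(type != "SBS"),
              n_total = .N, theoretical = 4L * .N), by = sample]
  } else data.table(sample = character(), n_sbs = integer(),
                    n_indel = integer(), n_total = integer(),
                    theoretical = integer())
  sbs <- classify_substitutions(novel)
  class6_levels <- c("C>T", "T>C", "C>A", "C>G", "T>A", "T>G")
  class6 <- data.table(class = class6_levels,
                       n = vapply(class6_levels,
                                  function(cl) sum(sbs$class == cl),
                                  integer(1)))
  class12 <- if (nrow(sbs) > 0L) sbs[, .(n = .N), by = raw_class] else
    data.table(raw_class = character(), n = integer())
  indels <- novel[type != "SBS"]
  ctx <- if (nrow(indels) > 0L) {
    cc <- vapply(seq_len(nrow(indels)), function(i) {
      classify_indel_context(genome, indels$chrom[i], indels$pos0[i],
                             indels$ref[i], indels$alt[i],
                             min_run = min_run, min_units = min_units)$context
    }, character(1))
    data.table(context = c("homopolymer", "polydinucleotide", "other"),
               n = vapply(c("homopolymer", "polydinucleotide", "other"),
                          function(x) sum(cc == x), integer(1)))
  } else data.table(context = c("homopolymer", "polydinucleotide", "other"),
                    n = 0L)
  by_chrom <- if (nrow(novel) > 0L) novel[, .(n = .N), by = chrom] else
    data.table(chrom = character(), n = integer())
  location <- NULL
  if (!is.null(annotation) && nrow(novel) > 0L) {
    ann_res <- annotate_locations(novel, annotation, genome)
    location <- ann_res[, .(n = .N), by = category]
  }
  structure(list(per_sample = per_sample, class6 = class6,
                 class12 = class12, ts_tv = ts_tv_ratio(sbs),
                 indel_context = ctx, by_chrom = by_chrom,
                 location = location),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Mutation spectrum summary\n")
  cat("  per-sample counts:\n")
  print(x$per_sample)
  cat("  substitution classes (pyrimidine-collapsed):\n")
  print(x$class6)
  cat("  Ts:Tv =", if (is.na(x$ts_tv)) "undefined" else
    formatC(x$ts_tv, format = "f", digits = 2), "\n")
  cat("  indel contexts:\n")
  print(x$indel_context)
  if (!is.null(x$location)) {
    cat("  genomic locations:\n")
    print(x$location)
  }
  invisible(x)
}
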