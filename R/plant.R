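#' Describe a batch of mutations to plant
#'
#' Builds one row of a planting specification for [plant_mutations()].
#' Rows are combined with `rbind()`.
#'
#' @param n number of events.
#' @param type "SBS", "insertion" or "deletion".
#' @param zygosity "hom" (both haplotypes) or "het" (haplotype A only).
#' @param context for indels: "homopolymer", "polydinucleotide", "other"
#'   or "any"; ignored for SBS.
#' @param class optional pyrimidine-collapsed substitution class to force,
#'   e.g. "C>T" (SBS only); NA picks ref/alt at random.
#' @param size indel length in bases (1 or 2; polydinucleotide context
#'   forces 2).
#' @return one-row data.table.
#' @export
mutation_spec <- function(n, type = "SBS", zygosity = "hom",
                          context = "any", class = NA_character_, size = 1L) {
  stopifnot(type %in% c("SBS", "insertion", "deletion"),
            zygosity %in% c("hom", "het"),
            context %in% c("any", "homopolymer", "polydinucleotide", "other"))
  data.table(n = as.integer(n), type = type, zygosity = zygosity,
             context = context, class = as.character(class),
             size = as.integer(size))
}

empty_truth <- function() {
  structure(list(
    sbs = data.table(chrom = character(), pos0 = integer(), ref = character(),
                     alt = character(), zygosity = character()),
    indels = data.table(chrom = character(), pos0 = integer(),
                        ref = character(), alt = character(),
                        type = character(), context_class = character(),
                        zygosity = character()),
    svs = data.table(type = character(), chrom = character(),
                     start0 = integer(), end0 = integer(),
                     target_chrom = character(), target_pos0 = integer()),
    te_amplifications = data.table(element_id = character(),
                                   chrom = character(), start0 = integer(),
                                   end0 = integer(), target_chrom = character(),
                                   target_pos0 = integer(),
                                   multiplier = integer())
  ), class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$sbs), "SBS,", nrow(x$indels), "indels,",
      nrow(x$svs), "SVs,", nrow(x$te_amplifications), "TE amplifications\n")
  invisible(x)
}

#' Plant mutations, structural variants and TE amplifications
#'
#' Derives a diploid sample from a reference genome. Homozygous small
#' variants alter both haplotypes, heterozygous ones haplotype A only.
#' Indels requested with homopolymer context are placed inside reference
#' runs of >= 3 identical bases (replication-slippage hotspots);
#' polydinucleotide indels inside tandem 2-mer repeats. Structural events
#' and TE amplifications are applied to both haplotypes. No two planted
#' events overlap; truth records are left-normalized 0-based reference
#' coordinates.
#'
#' @param genome reference genome (named character vector or DNAStringSet).
#' @param spec data.table of [mutation_spec()] rows (may be NULL).
#' @param svs optional data.table of structural events with columns
#'   `type` (large_insertion, large_deletion, inversion, translocation),
#'   `chrom`, `start0`, `end0`, and for insertion-like types
#'   `target_chrom`, `target_pos0`.
#' @param te_amplifications optional data.table with columns `element_id`,
#'   `chrom`, `start0`, `end0`, `target_chrom`, `target_pos0` describing
#'   duplicative transpositions (the element sequence is copied to the
#'   target site, doubling its copy number).
#' @param seed integer seed.
#' @param margin minimum distance between planted small variants and from
#'   chromosome ends.
#' @return object of class `sim_sample`: list with `reference`,
#'   `variants` (per-haplotype small-variant tables), `segmap`
#'   (per-haplotype structural maps), `truth` (a `truth_set`).
#' @export
plant_mutations <- function(genome, spec = NULL, svs = NULL,
                            te_amplifications = NULL, seed, margin = 150L) {
  if (missing(seed)) stop("plant_mutations: `seed` is mandatory")
  g <- as_genome(genome)
  truth <- empty_truth()

  with_seed(derive_seed(seed, "plant"), {
    occupied <- data.table(chrom = character(), start0 = integer(),
                           end0 = integer())
    reserve <- function(chrom, s, e) {
      occupied <<- rbind(occupied,
                         data.table(chrom = chrom, start0 = as.integer(s),
                                    end0 = as.integer(e)))
    }
    is_free <- function(chrom, s, e) {
      !any(occupied$chrom == chrom & occupied$start0 < e + margin &
             occupied$end0 > s - margin)
    }

    # --- structural events first (they occupy large intervals) ---
    if (!is.null(svs) && nrow(svs) > 0L) {
      svs <- copy(as.data.table(svs))
      if (!"target_chrom" %in% names(svs)) svs$target_chrom <- NA_character_
      if (!"target_pos0" %in% names(svs)) svs$target_pos0 <- NA_integer_
      for (i in seq_len(nrow(svs))) {
        ev <- svs[i]
        if (!is_free(ev$chrom, ev$start0, ev$end0))
          stop("planted SV overlaps a previous event: ", ev$type)
        reserve(ev$chrom, ev$start0, ev$end0)
        if (!is.na(ev$target_pos0))
          reserve(ev$target_chrom, ev$target_pos0, ev$target_pos0 + 1L)
      }
      truth$svs <- svs[, .(type, chrom, start0 = as.integer(start0),
                           end0 = as.integer(end0), target_chrom,
                           target_pos0 = as.integer(target_pos0))]
    }
    if (!is.null(te_amplifications) && nrow(te_amplifications) > 0L) {
      tea <- copy(as.data.table(te_amplifications))
      if (!"multiplier" %in% names(tea)) tea$multiplier <- 2L
      for (i in seq_len(nrow(tea))) {
        ev <- tea[i]
        reserve(ev$target_chrom, ev$target_pos0, ev$target_pos0 + 1L)
      }
      truth$te_amplifications <- tea[, .(element_id, chrom,
                                         start0 = as.integer(start0),
                                         end0 = as.integer(end0), target_chrom,
                                         target_pos0 = as.integer(target_pos0),
                                         multiplier = as.integer(multiplier))]
    }

    # --- small variants ---
    sbs_rows <- list()
    indel_rows <- list()
    if (!is.null(spec) && nrow(spec) > 0L) {
      spec <- as.data.table(spec)
      for (i in seq_len(nrow(spec))) {
        row <- spec[i]
        for (k in seq_len(row$n)) {
          if (row$type == "SBS") {
            v <- place_sbs(g, row, is_free)
            reserve(v$chrom, v$pos0, v$pos0 + 1L)
            sbs_rows[[length(sbs_rows) + 1L]] <-
              data.table(chrom = v$chrom, pos0 = v$pos0, ref = v$ref,
                         alt = v$alt, zygosity = row$zygosity)
          } else {
            v <- place_indel(g, row, is_free)
            reserve(v$chrom, v$pos0, v$pos0 + nchar(v$ref))
            indel_rows[[length(indel_rows) + 1L]] <-
              data.table(chrom = v$chrom, pos0 = v$pos0, ref = v$ref,
                         alt = v$alt, type = row$type,
                         context_class = v$context, zygosity = row$zygosity)
          }
        }
      }
    }
    if (length(sbs_rows) > 0L) truth$sbs <- rbindlist(sbs_rows)
    if (length(indel_rows) > 0L) truth$indels <- rbindlist(indel_rows)
  })

  setorder(truth$sbs, chrom, pos0)
  setorder(truth$indels, chrom, pos0)

  small <- rbind(
    truth$sbs[, .(chrom, pos0, ref, alt, zygosity)],
    truth$indels[, .(chrom, pos0, ref, alt, zygosity)]
  )
  setorder(small, chrom, pos0)
  variants <- list(A = small[, .(chrom, pos0, ref, alt)],
                   B = small[zygosity == "hom", .(chrom, pos0, ref, alt)])

  sv_all <- truth$svs
  if (nrow(truth$te_amplifications) > 0L) {
    sv_all <- rbind(sv_all,
                    truth$te_amplifications[, .(type = "te_amplification",
                                                chrom, start0, end0,
                                                target_chrom, target_pos0)])
  }
  segmap <- apply_svs(g, sv_all)

  structure(list(reference = g,
                 variants = variants,
                 segmap = list(A = segmap, B = segmap),
                 truth = truth),
            class = "sim_sample")
}

#' @export
print.sim_sample <- function(x, ...) {
  cat("sim_sample over", length(x$reference), "chromosome(s) (",
      sum(nchar(x$reference)), "bp )\n")
  print(x$truth)
  invisible(x)
}

place_sbs <- function(g, row, is_free) {
  for (attempt in 1:5000) {
    chrom <- sample(names(g), 1L, prob = nchar(g))
    L <- nchar(g[[chrom]])
    p <- sample.int(L - 300L, 1L) + 150L - 1L   # 0-based, away from ends
    ref <- subseq0(g[[chrom]], p, p + 1L)
    if (!ref %in% BASES) next
    if (!is.free_ok(is_free, chrom, p, p + 1L)) next
    if (!is.na(row$class) && nzchar(row$class) && row$class != "NA") {
      cl <- strsplit(row$class, ">")[[1]]
      if (ref == cl[1]) alt <- cl[2]
      else if (ref == complement_base(cl[1])) alt <- complement_base(cl[2])
      else next
    } else {
      alt <- sample(setdiff(BASES, ref), 1L)
    }
    return(list(chrom = chrom, pos0 = p, ref = ref, alt = alt))
  }
  stop("could not place SBS (class ", row$class, "): no free site found")
}

is.free_ok <- function(is_free, chrom, s, e) isTRUE(is_free(chrom, s, e))

place_indel <- function(g, row, is_free) {
  size <- row$size
  ctx <- row$context
  if (ctx == "polydinucleotide") size <- 2L
  for (attempt in 1:5000) {
    chrom <- sample(names(g), 1L, prob = nchar(g))
    seq <- g[[chrom]]
    L <- nchar(seq)
    if (ctx == "homopolymer") {
      runs <- find_homopolymer_runs(seq, min_run = 3L)
      runs <- runs[start0 > 150L & end0 < L - 150L]
      if (nrow(runs) == 0L) next
      r <- runs[sample.int(nrow(runs), 1L)]
      anchor <- r$start0 - 1L            # base before the run
      unit <- strrep(r$base, size)
      achar <- subseq0(seq, anchor, anchor + 1L)
      if (row$type == "deletion") {
        if (r$length < size + 1L) next   # keep a shortened run recognizable
        ref <- paste0(achar, unit); alt <- achar
      } else {
        ref <- achar; alt <- paste0(achar, unit)
      }
      pos0 <- anchor
      context <- "homopolymer"
    } else if (ctx == "polydinucleotide") {
      runs <- find_dinucleotide_runs(seq, min_units = 2L)
      runs <- runs[start0 > 150L & end0 < L - 150L & units >= 3L]
      if (nrow(runs) == 0L) next
      r <- runs[sample.int(nrow(runs), 1L)]
      anchor <- r$start0 - 1L
      achar <- subseq0(seq, anchor, anchor + 1L)
      if (row$type == "deletion") {
        ref <- paste0(achar, r$unit); alt <- achar
      } else {
        ref <- achar; alt <- paste0(achar, r$unit)
      }
      pos0 <- anchor
      context <- "polydinucleotide"
    } else {
      p <- sample.int(L - 300L, 1L) + 150L - 1L
      achar <- subseq0(seq, p, p + 1L)
      if (!achar %in% BASES) next
      if (row$type == "deletion") {
        unit <- subseq0(seq, p + 1L, p + 1L + size)
        if (grepl("N", unit)) next
        ref <- paste0(achar, unit); alt <- achar
      } else {
        unit <- paste(sample(BASES, size, replace = TRUE), collapse = "")
        ref <- achar; alt <- paste0(achar, unit)
      }
      pos0 <- p
      ctx_chk <- classify_indel_context(g, chrom, pos0, ref, alt)
      if (ctx == "other" && ctx_chk$context != "other") next
      context <- ctx_chk$context
    }
    nv <- normalize_variant(seq, pos0, ref, alt)
    span <- nchar(nv$ref) + 2L
    if (!is.free_ok(is_free, chrom, nv$pos0 - 6L, nv$pos0 + span + 6L)) next
    # reject placements whose normalized form collides with an N
    if (grepl("N", paste0(nv$ref, nv$alt))) next
    return(list(chrom = chrom, pos0 = nv$pos0, ref = nv$ref, alt = nv$alt,
                context = context))
  }
  stop("could not place ", row$type, " with context '", ctx,
       "': no free site found")
}

#' Materialize a haplotype sequence
#'
#' Applies the sample's structural events and then its small variants to
#' the reference, yielding the full haplotype sequence (mainly useful for
#' inspection and FASTA export; the read simulator never needs it).
#'
#' @param sample a `sim_sample`.
#' @param hap "A" or "B".
#' @return named character vector of donor chromosome sequences.
#' @export
haplotype_sequence <- function(sample, hap = "A") {
  stopifnot(inherits(sample, "sim_sample"), hap %in% c("A", "B"))
  segmap <- sample$segmap[[hap]]
  vars <- sample$variants[[hap]]
  out <- vapply(names(segmap), function(cn) {
    segs <- segmap[[cn]]
    donor <- seg_materialize(segs, sample$reference)
    # lift small variants on +-strand segments into donor coordinates
    don <- cumsum(c(0L, segs$ref_end - segs$ref_start))
    vc <- vars[chrom %in% segs$ref_chrom]
    if (nrow(vc) == 0L) return(donor)
    at <- integer(0); repl <- character(0); width <- integer(0)
    for (i in seq_len(nrow(vc))) {
      v <- vc[i]
      hit <- which(segs$ref_chrom == v$chrom & segs$strand == "+" &
                     segs$ref_start <= v$pos0 &
                     v$pos0 + nchar(v$ref) <= segs$ref_end)
      for (h in hit) {
        d <- don[h] + (v$pos0 - segs$ref_start[h])
        at <- c(at, d + 1L)
        width <- c(width, nchar(v$ref))
        repl <- c(repl, v$alt)
      }
    }
    if (length(at) == 0L) return(donor)
    x <- Biostrings::DNAString(donor)
    ord <- order(at)
    ir <- IRanges::IRanges(start = at[ord], width = width[ord])
    as.character(Biostrings::replaceAt(x, ir,
                                       Biostrings::DNAStringSet(repl[ord])))
  }, character(1))
  names(out) <- names(segmap)
  out
}
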