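#' Read a GFF3 gene annotation
#'
#' Imports gene / mRNA / exon / CDS / UTR features with rtracklayer and
#' organizes CDS features per transcript for codon-effect annotation.
#' CDS features with a malformed phase are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return annotation object (list of GRanges, class `gene_annotation`).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  cds <- gr[ty == "CDS"]
  if (length(cds) > 0L) {
    ph <- cds$phase
    bad <- is.na(ph) | !ph %in% c(0L, 1L, 2L)
    if (any(bad)) {
      warning(sum(bad), " CDS feature(s) with malformed phase skipped")
      cds <- cds[!bad]
    }
  }
  parent_of <- function(x) {
    p <- x$Parent
    if (is.null(p)) return(rep(NA_character_, length(x)))
    vapply(as.list(p), function(v) if (length(v) > 0) v[[1]] else NA_character_,
           character(1))
  }
  cds$tx <- parent_of(cds)
  cds$tx[is.na(cds$tx)] <- if (!is.null(cds$ID)) cds$ID[is.na(cds$tx)] else
    paste0("tx", seq_len(sum(is.na(cds$tx))))
  structure(list(
    gene = gr[ty %in% c("gene")],
    tx = gr[ty %in% c("mRNA", "transcript")],
    exon = gr[ty == "exon"],
    cds = cds,
    utr = gr[ty %in% c("five_prime_UTR", "three_prime_UTR", "UTR")]
  ), class = "gene_annotation")
}

gene_id_of <- function(gr, idx) {
  if (length(idx) == 0L) return(NA_character_)
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (is.null(ids)) return(NA_character_)
  ids[idx[1]]
}

# Spliced CDS model for one transcript: ordered pieces, cumulative
# offsets, strand, first-piece phase, spliced sequence.
cds_model <- function(ann, tx, genome) {
  g <- as_genome(genome)
  pieces <- ann$cds[ann$cds$tx == tx]
  minus <- as.character(BiocGenerics::strand(pieces)[1]) == "-"
  ord <- order(BiocGenerics::start(pieces), decreasing = minus)
  pieces <- pieces[ord]
  seqs <- vapply(seq_along(pieces), function(i) {
    cn <- as.character(GenomeInfoDb::seqnames(pieces)[i])
    s <- subseq0(g[[cn]], BiocGenerics::start(pieces)[i] - 1L,
                 BiocGenerics::end(pieces)[i])
    if (minus) revcomp(s) else s
  }, character(1))
  widths <- BiocGenerics::width(pieces)
  list(pieces = pieces, minus = minus,
       offsets = cumsum(c(0L, head(widths, -1L))),
       phase = pieces$phase[1],
       seq = paste(seqs, collapse = ""))
}

translate_codon <- function(codon) {
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

# Coding effect of an SBS at 0-based reference position pos0 with
# alternate base alt, for one transcript model.
codon_effect <- function(model, chrom, pos0, alt) {
  pieces <- model$pieces
  hit <- which(as.character(GenomeInfoDb::seqnames(pieces)) == chrom &
                 BiocGenerics::start(pieces) - 1L <= pos0 &
                 pos0 < BiocGenerics::end(pieces))
  if (length(hit) == 0L) return(NULL)
  i <- hit[1]
  local <- if (model$minus) {
    model$offsets[i] + (BiocGenerics::end(pieces)[i] - 1L - pos0)
  } else {
    model$offsets[i] + (pos0 - (BiocGenerics::start(pieces)[i] - 1L))
  }
  frame_local <- local - model$phase
  if (frame_local < 0L) return(list(effect = "unknown", aa_change = NA_character_))
  codon_idx <- frame_local %/% 3L
  codon_pos <- frame_local %% 3L
  cds_start <- model$phase + codon_idx * 3L
  if (cds_start + 3L > nchar(model$seq))
    return(list(effect = "unknown", aa_change = NA_character_))
  ref_codon <- substring(model$seq, cds_start + 1L, cds_start + 3L)
  alt_cds <- if (model$minus) complement_base(alt) else alt
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos + 1L, codon_pos + 1L) <- alt_cds
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt))
    return(list(effect = "unknown", aa_change = NA_character_))
  list(effect = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous",
       truncating = (aa_alt == "*" && aa_ref != "*"),
       aa_change = paste0(aa_ref, codon_idx + 1L, aa_alt))
}

#' Annotate the genomic location and coding effect of one mutation
#'
#' Overlap priority is CDS > UTR > intron > intergenic. For an SBS in a
#' CDS the reference and mutated codons are translated (honoring strand
#' and phase): the category is `CDS_synonymous` or `CDS_nonsynonymous`,
#' and a stop-gain is additionally flagged protein-truncating. Indels in
#' CDS disrupt the reading frame and are reported `CDS_nonsynonymous`.
#' Without explicit UTR features, non-CDS exonic overlap is labelled
#' `UTR_or_noncoding_exon`.
#'
#' @param mut list or one-row data.table with chrom, pos0, ref, alt.
#' @param ann a `gene_annotation`.
#' @param genome reference genome.
#' @return list: `category`, `gene`, `effect`, `aa_change`, `truncating`.
#' @export
annotate_location <- function(mut, ann, genome) {
  stopifnot(inherits(ann, "gene_annotation"))
  pos1 <- mut$pos0 + 1L
  site <- GenomicRanges::GRanges(mut$chrom,
                                 IRanges::IRanges(pos1, pos1))
  ov <- function(gr) {
    if (length(gr) == 0L) return(integer(0))
    S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, site))
  }
  cds_hit <- ov(ann$cds)
  is_sbs <- nchar(mut$ref) == 1L && nchar(mut$alt) == 1L
  if (length(cds_hit) > 0L) {
    tx <- ann$cds$tx[cds_hit[1]]
    gene <- sub("\\.t?[0-9]+$", "", tx)
    if (is_sbs) {
      model <- cds_model(ann, tx, genome)
      eff <- codon_effect(model, mut$chrom, mut$pos0, mut$alt)
      if (is.null(eff) || identical(eff$effect, "unknown"))
        return(list(category = "CDS_unknown", gene = gene,
                    effect = "unknown", aa_change = NA_character_,
                    truncating = FALSE))
      return(list(category = paste0("CDS_", eff$effect), gene = gene,
                  effect = eff$effect, aa_change = eff$aa_change,
                  truncating = isTRUE(eff$truncating)))
    }
    return(list(category = "CDS_nonsynonymous", gene = gene,
                effect = "frameshift_or_inframe_indel",
                aa_change = NA_character_, truncating = FALSE))
  }
  utr_hit <- ov(ann$utr)
  if (length(utr_hit) > 0L)
    return(list(category = "UTR", gene = gene_id_of(ann$utr, utr_hit),
                effect = NA_character_, aa_change = NA_character_,
                truncating = FALSE))
  exon_hit <- ov(ann$exon)
  if (length(exon_hit) > 0L)
    return(list(category = "UTR_or_noncoding_exon",
                gene = gene_id_of(ann$exon, exon_hit),
                effect = NA_character_, aa_change = NA_character_,
                truncating = FALSE))
  gene_hit <- ov(ann$gene)
  if (length(gene_hit) == 0L) gene_hit <- ov(ann$tx)
  if (length(gene_hit) > 0L)
    return(list(category = "intron", gene = gene_id_of(ann$gene, gene_hit),
                effect = NA_character_, aa_change = NA_character_,
                truncating = FALSE))
  list(category = "intergenic", gene = NA_character_,
       effect = NA_character_, aa_change = NA_character_,
       truncating = FALSE)
}

#' Annotate a table of mutations
#' @param muts data.table with chrom, pos0, ref, alt.
#' @param ann a `gene_annotation`.
#' @param genome reference genome.
#' @return the input with category/gene/effect/aa_change/truncating added.
#' @export
annotate_locations <- function(muts, ann, genome) {
  muts <- copy(as.data.table(muts))
  res <- lapply(seq_len(nrow(muts)),
                function(i) annotate_location(muts[i], ann, genome))
  muts$category <- vapply(res, `[[`, character(1), "category")
  muts$gene <- vapply(res, function(x) as.character(x$gene)[1], character(1))
  muts$effect <- vapply(res, function(x) as.character(x$effect)[1], character(1))
  muts$aa_change <- vapply(res, function(x) as.character(x$aa_change)[1],
                           character(1))
  muts$truncating <- vapply(res, `[[`, logical(1), "truncating")
  muts
}
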