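# Shared fixtures, built once per test run and cached. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    builder <- get(paste0("build_fixture_", name), mode = "function")
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Main diploid resequencing fixture: progenitor + one regenerant with
# planted homozygous SBSs and 1-2 bp indels (plus heterozygous SBSs
# that must never be called), noiseless reads at 25x over 100 kb.
build_fixture_base <- function() {
  cfg <- sim_config(genome_length = 100000L, seed = 101L,
                    base_error_rate = 0)
  genome <- generate_genome(cfg)
  spec <- rbind(
    mutation_spec(20, "SBS", "hom"),
    mutation_spec(3, "SBS", "het"),
    mutation_spec(3, "deletion", "hom", context = "homopolymer"),
    mutation_spec(2, "insertion", "hom", context = "homopolymer"),
    mutation_spec(2, "deletion", "hom", context = "polydinucleotide"),
    mutation_spec(1, "deletion", "hom", context = "other"),
    mutation_spec(1, "insertion", "hom", context = "other", size = 2L)
  )
  r1 <- plant_mutations(genome, spec, seed = 202L)
  p1 <- plant_mutations(genome, NULL, seed = 303L)
  r1_recs <- filter_reads(simulate_read_pairs(r1, cfg))
  p1_recs <- filter_reads(simulate_read_pairs(p1, cfg))
  list(cfg = cfg, genome = genome, r1 = r1, p1 = p1,
       r1_recs = r1_recs, p1_recs = p1_recs,
       r1_pile = build_pileup(r1_recs, genome),
       p1_pile = build_pileup(p1_recs, genome),
       r1_track = coverage_track(r1_recs, genome),
       p1_track = coverage_track(p1_recs, genome))
}

# Structural-variant fixture: inversion, same-chromosome duplicative
# insertion, and interchromosomal translocation, one each.
build_fixture_sv <- function() {
  cfg <- sim_config(genome_length = 60000L, n_chromosomes = 2L,
                    seed = 404L, base_error_rate = 0)
  genome <- generate_genome(cfg)
  svs <- data.table::data.table(
    type = c("inversion", "large_insertion", "translocation"),
    chrom = c("chr1", "chr1", "chr2"),
    start0 = c(10000L, 30000L, 20000L),
    end0 = c(12000L, 32000L, 22000L),
    target_chrom = c(NA, "chr1", "chr1"),
    target_pos0 = c(NA_integer_, 50000L, 45000L))
  r1 <- plant_mutations(genome, NULL, svs = svs, seed = 505L)
  r1_recs <- filter_reads(simulate_read_pairs(r1, cfg))
  p1_recs <- filter_reads(simulate_read_pairs(genome, cfg))
  list(cfg = cfg, genome = genome, r1 = r1,
       r1_recs = r1_recs, p1_recs = p1_recs)
}

# TE-amplification fixture: one 4 kb element (LTR-retrotransposon
# sized) duplicated into a new site, one untouched element.
build_fixture_te <- function() {
  cfg <- sim_config(genome_length = 100000L, seed = 606L,
                    base_error_rate = 0)
  genome <- generate_genome(cfg)
  elements <- data.table::data.table(
    element_id = c("TE_amp", "TE_quiet"),
    family = c("COPIA", "CACTA"),
    chrom = "chr1",
    start0 = c(40000L, 70000L), end0 = c(44000L, 72000L),
    length = c(4000L, 2000L))
  tea <- data.table::data.table(
    element_id = "TE_amp", chrom = "chr1", start0 = 40000L, end0 = 44000L,
    target_chrom = "chr1", target_pos0 = 15000L)
  r1 <- plant_mutations(genome, NULL, te_amplifications = tea, seed = 707L)
  r1_recs <- filter_reads(simulate_read_pairs(r1, cfg))
  p1_recs <- filter_reads(simulate_read_pairs(genome, cfg))
  list(cfg = cfg, genome = genome, elements = elements, r1 = r1,
       r1_recs = r1_recs, p1_recs = p1_recs,
       r1_track = coverage_track(r1_recs, genome),
       p1_track = coverage_track(p1_recs, genome))
}

empty_alignments_for_test <- function() regenmut:::empty_alignments()

complement_for_test <- function(x) chartr("ACGT", "TGCA", x)

revcomp_for_test <- function(x)
  paste(rev(strsplit(complement_for_test(x), "")[[1]]), collapse = "")

# Hand-built alignment record (defaults give a simple all-M read).
make_record <- function(chrom = "chr1", pos = 0L, seq = "ACGT",
                        cigar = paste0(nchar(seq), "M"), strand = "+",
                        mapq = 60L, unique = TRUE, qname = "r1",
                        mate_chrom = chrom, mate_pos = pos + 200L,
                        mate_strand = "-", first_of_pair = TRUE) {
  data.table::data.table(qname = qname, chrom = chrom, pos = as.integer(pos),
                         strand = strand, mapq = as.integer(mapq),
                         unique = unique, cigar = cigar, seq = seq,
                         mate_chrom = mate_chrom,
                         mate_pos = as.integer(mate_pos),
                         mate_strand = mate_strand,
                         first_of_pair = first_of_pair)
}

# Brute-force pileup depth oracle: count reads whose aligned reference
# span (M/D ops) covers the position.
brute_force_depth <- function(records, chrom, pos0) {
  records <- records[records$chrom == chrom, ]
  if (nrow(records) == 0L) return(0L)
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(records$cigar)
  sum(records$pos <= pos0 & pos0 < records$pos + w)
}

# Toy single-gene GFF3 written to a temp file; CDS spans [cds_start,
# cds_end] 1-based on the given strand.
write_toy_gff <- function(path, chrom = "chr1", gene_start = 101L,
                          gene_end = 400L, cds_start = 131L,
                          cds_end = 370L, strand = "+") {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=gene1", chrom, gene_start,
            gene_end, strand),
    sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=tx1;Parent=gene1", chrom,
            gene_start, gene_end, strand),
    sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tParent=tx1", chrom, gene_start,
            gene_end, strand),
    sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tParent=tx1", chrom, cds_start,
            cds_end, strand))
  writeLines(lines, path)
  path
}
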