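test_that("substitution classes collapse to the pyrimidine strand", {
  r <- classify_substitution("G", "A")
  expect_identical(r$class, "C>T")
  expect_identical(r$kind, "transition")
  r2 <- classify_substitution("C", "G")
  expect_identical(r2$class, "C>G")
  expect_identical(r2$kind, "transversion")
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("N", "A"), "A/C/G/T")
})

test_that("strand-collapse involution holds for all 12 ordered base pairs", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ref in c("A", "C", "G", "T")) {
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a <- classify_substitution(ref, alt)
      b <- classify_substitution(comp[[ref]], comp[[alt]])
      expect_identical(a$class, b$class,
                       info = paste(ref, ">", alt))
      expect_identical(a$kind, b$kind)
      # transitions are exactly the purine<->purine / pyr<->pyr changes
      same_family <- (ref %in% c("A", "G")) == (alt %in% c("A", "G"))
      expect_identical(a$kind,
                       if (same_family) "transition" else "transversion")
    }
  }
})

test_that("ts_tv_ratio reproduces worked values and degenerate cases", {
  mk <- function(n_ts, n_tv) {
    data.table::data.table(
      ref = c(rep("C", n_ts), rep("C", n_tv)),
      alt = c(rep("T", n_ts), rep("A", n_tv)))
  }
  # 63/68 = 0.926...; the published summary prints 0.92 (truncated) --
  # assert the true arithmetic and agreement at the printed precision
  expect_equal(ts_tv_ratio(mk(63L, 68L)), 63 / 68)
  expect_lt(abs(ts_tv_ratio(mk(63L, 68L)) - 0.92), 0.01)
  expect_equal(ts_tv_ratio(mk(10L, 10L)), 1.0)
  expect_equal(ts_tv_ratio(mk(0L, 5L)), 0.0)
  expect_message(r <- ts_tv_ratio(mk(5L, 0L)), "undefined")
  expect_true(is.na(r))
})

test_that("indel context classification follows the run rules", {
  g <- c(chr1 = "ACGTAAAAACGTACACACGTTTGCA")
  #         0-based: A0 C1 G2 T3 A4-A8 run(5) C9 G10 T11 A12 C13 A14 C15 A16 C17 G18 T19 T20 T21 G22 C23 A24
  # deletion of one A inside AAAAA (normalized anchor T at 3)
  r <- classify_indel_context(g, "chr1", 3L, "TA", "T")
  expect_identical(r$context, "homopolymer")
  expect_equal(r$run_length, 5L)
  expect_identical(r$unit, "A")

  # deletion of AC inside ACACAC (3 tandem units, anchor T at 11)
  r2 <- classify_indel_context(g, "chr1", 11L, "TAC", "T")
  expect_identical(r2$context, "polydinucleotide")
  expect_equal(r2$run_length, 3L)
  expect_identical(r2$unit, "AC")

  # insertion extending a run
  r3 <- classify_indel_context(g, "chr1", 3L, "T", "TA")
  expect_identical(r3$context, "homopolymer")

  # deletion of G in mixed sequence -> other
  r4 <- classify_indel_context(g, "chr1", 1L, "CG", "C")
  expect_identical(r4$context, "other")

  expect_error(classify_indel_context(g, "chr1", 100L, "TA", "T"), "bounds")
})

test_that("annotate_location agrees with brute-force translation over an exhaustive CDS scan", {
  # 10-codon toy CDS on the forward strand; every possible single-base
  # change inside the CDS is compared against full-CDS translation
  set.seed(99)
  flank1 <- paste(sample(c("A", "C", "G", "T"), 130L, replace = TRUE),
                  collapse = "")
  cds <- "ATGGCTAAAGGGTTTCAACCCGATTACTGTAAA"  # hand-made; length 33 -> use 30
  cds <- substr(cds, 1L, 30L)
  flank2 <- paste(sample(c("A", "C", "G", "T"), 140L, replace = TRUE),
                  collapse = "")
  g <- c(chr1 = paste0(flank1, cds, flank2))
  gff <- write_toy_gff(tempfile(fileext = ".gff3"), gene_start = 101L,
                       gene_end = 290L, cds_start = 131L, cds_end = 160L)
  ann <- read_annotation(gff)
  translate_str <- function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  p_ref <- translate_str(cds)
  for (off in 0:29) {
    pos0 <- 130L + off
    ref <- substring(g[["chr1"]], pos0 + 1L, pos0 + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      res <- annotate_location(list(chrom = "chr1", pos0 = pos0, ref = ref,
                                    alt = alt), ann, g)
      mut_cds <- cds
      substr(mut_cds, off + 1L, off + 1L) <- alt
      brute <- if (translate_str(mut_cds) == p_ref) "synonymous"
               else "nonsynonymous"
      expect_identical(res$effect, brute,
                       info = paste0("pos ", pos0, " ", ref, ">", alt))
      expect_identical(res$category, paste0("CDS_", brute))
    }
  }
})

test_that("stop-gain SBS is nonsynonymous and flagged truncating", {
  flank <- strrep("T", 100L)
  g <- c(chr1 = paste0(flank, "ATGGAAGCTTAG", flank))  # M E A *
  gff <- write_toy_gff(tempfile(fileext = ".gff3"), gene_start = 95L,
                       gene_end = 120L, cds_start = 101L, cds_end = 112L)
  ann <- read_annotation(gff)
  # GAA -> TAA at codon 2 first position (0-based 103)
  res <- annotate_location(list(chrom = "chr1", pos0 = 103L, ref = "G",
                                alt = "T"), ann, g)
  expect_identical(res$category, "CDS_nonsynonymous")
  expect_true(res$truncating)
  expect_identical(res$aa_change, "E2*")
  # third-position synonymous change: GCT -> GCC (codon 3, 0-based 108)
  res2 <- annotate_location(list(chrom = "chr1", pos0 = 108L, ref = "T",
                                 alt = "C"), ann, g)
  expect_identical(res2$category, "CDS_synonymous")
})

test_that("minus-strand CDS effects honor strand and phase", {
  # reverse-complement gene: CDS on - strand, protein M K F *
  cds_fwd <- "ATGAAATTTTGA"
  g <- c(chr1 = paste0(strrep("C", 100L), revcomp_for_test(cds_fwd),
                       strrep("C", 100L)))
  gff <- write_toy_gff(tempfile(fileext = ".gff3"), gene_start = 95L,
                       gene_end = 118L, cds_start = 101L, cds_end = 112L,
                       strand = "-")
  ann <- read_annotation(gff)
  # mutate codon 2 AAA->AGA (K2R): plus-strand position of the middle A
  # of codon 2: CDS local index 4 -> genomic pos0 = 101+12-1-1-4 = 107
  res <- annotate_location(list(chrom = "chr1", pos0 = 107L,
                                ref = substring(g[[1]], 108L, 108L),
                                alt = complement_for_test("G")), ann, g)
  expect_identical(res$effect, "nonsynonymous")
  expect_identical(res$aa_change, "K2R")
})

test_that("location priority is CDS > UTR > intron > intergenic", {
  g <- c(chr1 = strrep("ACGT", 200L))
  gff <- write_toy_gff(tempfile(fileext = ".gff3"))
  ann <- read_annotation(gff)
  expect_identical(annotate_location(list(chrom = "chr1", pos0 = 700L,
                                          ref = "A", alt = "C"),
                                     ann, g)$category, "intergenic")
  expect_identical(annotate_location(list(chrom = "chr1", pos0 = 110L,
                                          ref = "A", alt = "C"),
                                     ann, g)$category,
                   "UTR_or_noncoding_exon")
})

test_that("spectrum_summary partitions counts and reports 4n", {
  fx <- fixture("base")
  calls <- call_homozygous(fx$r1_pile, sample_id = "R1")
  novel <- subtract_progenitor(calls, fx$p1_pile)$novel
  s <- spectrum_summary(novel, fx$genome)
  expect_equal(s$per_sample$n_total, nrow(novel))
  expect_equal(s$per_sample$theoretical, 4L * nrow(novel))
  expect_equal(s$per_sample$n_sbs + s$per_sample$n_indel,
               s$per_sample$n_total)
  # class counts sum to total SBS count
  expect_equal(sum(s$class6$n), s$per_sample$n_sbs)
  expect_equal(sum(s$class12$n), s$per_sample$n_sbs)
  # context counts partition the indels
  expect_equal(sum(s$indel_context$n), s$per_sample$n_indel)
  # chromosome counts partition everything
  expect_equal(sum(s$by_chrom$n), nrow(novel))

  empty <- spectrum_summary(novel[0], fx$genome)
  expect_equal(sum(empty$class6$n), 0L)
  expect_equal(nrow(empty$per_sample), 0L)
})

test_that("a single planted class dominates the class table", {
  cfg <- sim_config(genome_length = 30000L, seed = 77L, base_error_rate = 0)
  g <- generate_genome(cfg)
  s <- plant_mutations(g, mutation_spec(10, "SBS", "hom", class = "C>T"),
                       seed = 78L)
  sbs <- classify_substitutions(s$truth$sbs)
  expect_true(all(sbs$class == "C>T"))
})
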