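test_that("generate_genome is deterministic, respects GC and plants repeat runs", {
  cfg <- sim_config(genome_length = 1000L, gc_content = 0.5, seed = 7L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1[["chr1"]]), 1000L)

  gc_only <- generate_genome(sim_config(genome_length = 500L,
                                        gc_content = 1.0, seed = 1L))
  expect_true(grepl("^[GC]+$", gc_only[["chr1"]]))

  # observed GC within binomial bounds on 100 kb at 0.36
  big <- fixture("base")$genome
  expect_lt(abs(gc_fraction(big) - 0.36), 0.02)

  # at least one homopolymer (>=6) and one polydinucleotide (>=4 units)
  # run per 100 kb
  expect_gte(nrow(find_homopolymer_runs(big[["chr1"]], 6L)), 1L)
  expect_gte(nrow(find_dinucleotide_runs(big[["chr1"]], 4L)), 1L)

  expect_error(sim_config(genome_length = 0L, seed = 1L), "positive")
  expect_error(sim_config(genome_length = 10L, seed = 1L,
                          read_length = 76L, fragment_mean = 50L),
               "read_length")
  expect_error(sim_config(genome_length = 10L), "seed")
})

test_that("plant_mutations alters exactly the planted sites with correct zygosity", {
  fx <- fixture("base")
  s <- fx$r1
  truth <- s$truth
  expect_equal(nrow(truth$sbs), 23L)  # 20 hom + 3 het
  expect_equal(nrow(truth$indels), 9L)

  hapA <- haplotype_sequence(s, "A")[["chr1"]]
  hapB <- haplotype_sequence(s, "B")[["chr1"]]
  ref <- fx$genome[["chr1"]]

  # independent oracle: apply variants right-to-left by string surgery
  apply_vars <- function(seq, vars) {
    vars <- vars[order(-pos0)]
    for (i in seq_len(nrow(vars))) {
      v <- vars[i]
      seq <- paste0(substring(seq, 1L, v$pos0),
                    v$alt,
                    substring(seq, v$pos0 + nchar(v$ref) + 1L))
    }
    seq
  }
  all_vars <- rbind(truth$sbs[, .(pos0, ref, alt, zygosity)],
                    truth$indels[, .(pos0, ref, alt, zygosity)])
  expect_identical(hapA, apply_vars(ref, all_vars))
  expect_identical(hapB, apply_vars(ref, all_vars[zygosity == "hom"]))
  # heterozygous sites: A carries the alt, B the reference
  expect_false(identical(hapA, hapB))

  # homopolymer indels lie inside runs of >= 3 identical reference bases
  hp <- truth$indels[context_class == "homopolymer"]
  expect_gte(nrow(hp), 5L)
  runs <- find_homopolymer_runs(ref, 3L)
  for (i in seq_len(nrow(hp))) {
    v <- hp[i]
    site <- v$pos0 + 1L  # first affected base (0-based)
    expect_true(any(runs$start0 <= site & site < runs$end0),
                info = paste("indel at", v$pos0, "not inside a run"))
  }

  # impossible requests fail loudly, naming the class
  tiny <- c(chr1 = strrep("ACGT", 100L))
  expect_error(
    plant_mutations(tiny, mutation_spec(5, "deletion", "hom",
                                        context = "homopolymer"),
                    seed = 1L),
    "homopolymer")
})

test_that("plant_mutations truth events never overlap and stay in bounds", {
  fx <- fixture("base")
  truth <- fx$r1$truth
  ev <- rbind(truth$sbs[, .(chrom, start0 = pos0, end0 = pos0 + nchar(ref))],
              truth$indels[, .(chrom, start0 = pos0,
                               end0 = pos0 + nchar(ref))])
  setorder(ev, chrom, start0)
  expect_true(all(ev$start0 >= 0L))
  expect_true(all(ev$end0 <= nchar(fx$genome[ev$chrom])))
  overlaps <- ev[, any(start0[-1L] < head(end0, -1L)), by = chrom]$V1
  expect_false(any(overlaps))
  expect_true(all(c(truth$sbs$zygosity, truth$indels$zygosity) %in%
                    c("het", "hom")))
})

test_that("simulate_read_pairs hits the configured depth and geometry", {
  cfg <- sim_config(genome_length = 1000L, depth = 20, seed = 9L,
                    base_error_rate = 0, fragment_mean = 300L,
                    fragment_sd = 10)
  g <- generate_genome(cfg)
  recs <- simulate_read_pairs(g, cfg)
  aligned <- sum(GenomicAlignments::cigarWidthAlongQuerySpace(recs$cigar))
  expect_lt(abs(aligned / 1000 - 20), 2)

  # noiseless, variant-free: every read base matches the reference
  for (i in seq_len(min(nrow(recs), 200L))) {
    expect_identical(recs$seq[i],
                     substring(g[["chr1"]], recs$pos[i] + 1L,
                               recs$pos[i] + nchar(recs$seq[i])))
  }
  expect_true(all(recs$mapq == 60L))
  expect_true(all(recs$unique))

  expect_warning(
    empty <- simulate_read_pairs(g, sim_config(genome_length = 1000L,
                                               depth = 0, seed = 2L)),
    "depth 0")
  expect_equal(nrow(empty), 0L)
})

test_that("mean pileup depth matches configured depth within 10% on 100 kb", {
  fx <- fixture("base")
  md <- mean_depth(fx$r1_track, masked = FALSE)
  expect_lt(abs(md - fx$cfg$depth) / fx$cfg$depth, 0.10)
})

test_that("every planted event is observable in simulated reads at 25x", {
  fx <- fixture("base")
  truth <- fx$r1$truth
  track <- fx$r1_track
  ev <- rbind(truth$sbs[, .(chrom, pos0)], truth$indels[, .(chrom, pos0)])
  for (i in seq_len(nrow(ev)))
    expect_gte(track[[ev$chrom[i]]][ev$pos0[i] + 1L], 1L)
})

test_that("inversion breakpoints force same-strand mates", {
  fx <- fixture("sv")
  inv <- fx$r1$truth$svs[type == "inversion"]
  recs <- fx$r1_recs
  near <- recs[chrom == inv$chrom & mate_chrom == inv$chrom &
                 !is.na(mate_pos) &
                 pos < inv$start0 & pos > inv$start0 - 400L]
  expect_gt(sum(near$strand == near$mate_strand), 0L)
})

test_that("fixtures are byte-identical under an identical config", {
  cfg <- sim_config(genome_length = 5000L, seed = 42L)
  g <- generate_genome(cfg)
  s <- plant_mutations(g, mutation_spec(3, "SBS", "hom"), seed = 8L)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture("S", simulate_read_pairs(s, cfg), s$truth, d1, g)
  write_fixture("S", simulate_read_pairs(s, cfg), s$truth, d2, g)
  expect_identical(readLines(file.path(d1, "S.sam")),
                   readLines(file.path(d2, "S.sam")))
  expect_identical(readLines(file.path(d1, "S.truth.json")),
                   readLines(file.path(d2, "S.truth.json")))
})

test_that("write_fixture round-trips records and truth losslessly", {
  fx <- fixture("base")
  recs <- fx$r1_recs[1:100]
  dir <- tempfile()
  paths <- write_fixture("RT", recs, fx$r1$truth, dir, fx$genome)
  back <- read_alignments(paths[["sam"]])
  cols <- c("qname", "chrom", "pos", "strand", "mapq", "unique", "cigar",
            "seq", "mate_chrom", "mate_pos", "mate_strand", "first_of_pair")
  expect_equal(as.data.frame(recs[order(chrom, pos, qname), ..cols]),
               as.data.frame(back[, ..cols]))
  tr <- read_truth(paths[["truth"]])
  expect_equal(as.data.frame(tr$sbs), as.data.frame(fx$r1$truth$sbs))
  expect_equal(as.data.frame(tr$indels), as.data.frame(fx$r1$truth$indels))

  # empty record set -> valid header-only file
  p2 <- write_fixture("E", empty_alignments_for_test(), NULL, dir, fx$genome)
  expect_equal(nrow(read_alignments(p2[["sam"]])), 0L)
})

test_that("fastq export flips minus-strand mates back to sequencing orientation", {
  cfg <- sim_config(genome_length = 2000L, seed = 3L, base_error_rate = 0)
  g <- generate_genome(cfg)
  recs <- simulate_read_pairs(g, cfg)
  prefix <- tempfile()
  paths <- write_fastq(recs, prefix)
  l1 <- readLines(paths[1])
  expect_equal(length(l1) %% 4L, 0L)
  expect_true(startsWith(l1[1], "@"))
})
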