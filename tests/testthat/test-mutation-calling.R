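test_that("call_homozygous applies depth and fraction thresholds", {
  g <- c(chr1 = strrep("C", 40L))
  # 10 unanimous T reads at one site
  recs <- data.table::rbindlist(lapply(1:10, function(i)
    make_record(qname = paste0("r", i), pos = 10L, seq = "CCCCCTCCCC")))
  recs[, seq := "CCCCCTCCCC"]
  pile <- build_pileup(recs, g)
  calls <- call_homozygous(pile)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos0, 15L)
  expect_identical(calls$ref, "C")
  expect_identical(calls$alt, "T")
  expect_equal(calls$alt_fraction, 1.0)
  expect_equal(calls$depth, 10L)

  # heterozygous pattern (5 ref / 5 alt) yields no call
  het <- data.table::rbindlist(c(
    lapply(1:5, function(i) make_record(qname = paste0("a", i), pos = 10L,
                                        seq = "CCCCCTCCCC")),
    lapply(1:5, function(i) make_record(qname = paste0("b", i), pos = 10L,
                                        seq = "CCCCCCCCCC"))))
  expect_equal(nrow(call_homozygous(build_pileup(het, g))), 0L)

  # depth 4 below min_depth 5 yields no call
  thin <- data.table::rbindlist(lapply(1:4, function(i)
    make_record(qname = paste0("r", i), pos = 10L, seq = "CCCCCTCCCC")))
  expect_equal(nrow(call_homozygous(build_pileup(thin, g))), 0L)

  # two non-ref alleles each below 0.9 yield no call (multi-allelic)
  multi <- data.table::rbindlist(c(
    lapply(1:5, function(i) make_record(qname = paste0("a", i), pos = 10L,
                                        seq = "CCCCCTCCCC")),
    lapply(1:5, function(i) make_record(qname = paste0("b", i), pos = 10L,
                                        seq = "CCCCCGCCCC"))))
  expect_equal(nrow(call_homozygous(build_pileup(multi, g))), 0L)
})

test_that("indel alleles are called and left-normalized", {
  g <- c(chr1 = "ACGTACGAAAAACGTACGTACGT")
  # 8 reads carrying a 1-base deletion inside the A-run (anchor varies by
  # read placement; normalization must converge on the leftmost form)
  recs <- data.table::rbindlist(lapply(1:8, function(i)
    make_record(qname = paste0("d", i), pos = 3L, seq = "TACGAAAACGTAC",
                cigar = "8M1D5M")))
  calls <- call_homozygous(build_pileup(recs, g))
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$type, "deletion")
  # leftmost representation: anchor G before the run
  expect_equal(calls$pos0, 6L)
  expect_identical(calls$ref, "GA")
  expect_identical(calls$alt, "G")
})

test_that("subtract_progenitor separates novel, inherited and unresolvable", {
  g <- c(chr1 = strrep("C", 40L))
  r1_calls <- data.table::data.table(
    chrom = "chr1", pos0 = 15L, ref = "C", alt = "T", type = "SBS",
    depth = 10L, alt_fraction = 1.0, sample = "R1")

  deep_ref <- data.table::rbindlist(lapply(1:20, function(i)
    make_record(qname = paste0("p", i), pos = 10L, seq = "CCCCCCCCCC")))
  res <- subtract_progenitor(r1_calls, build_pileup(deep_ref, g))
  expect_equal(nrow(res$novel), 1L)
  expect_equal(res$novel$p1_depth, 20L)
  expect_equal(res$novel$p1_alt_fraction, 0)

  deep_alt <- data.table::rbindlist(lapply(1:20, function(i)
    make_record(qname = paste0("p", i), pos = 10L, seq = "CCCCCTCCCC")))
  res2 <- subtract_progenitor(r1_calls, build_pileup(deep_alt, g))
  expect_equal(nrow(res2$novel), 0L)
  expect_equal(nrow(res2$inherited), 1L)

  thin <- data.table::rbindlist(lapply(1:2, function(i)
    make_record(qname = paste0("p", i), pos = 10L, seq = "CCCCCCCCCC")))
  res3 <- subtract_progenitor(r1_calls, build_pileup(thin, g))
  expect_equal(nrow(res3$novel), 0L)
  expect_equal(nrow(res3$unresolvable), 1L)

  expect_message(res4 <- subtract_progenitor(r1_calls, NULL), "unresolvable")
  expect_equal(nrow(res4$unresolvable), 1L)
})

test_that("full chain recovers planted homozygous mutations perfectly at 25x", {
  fx <- fixture("base")
  calls <- call_homozygous(fx$r1_pile, sample_id = "R1")
  sub <- subtract_progenitor(calls, fx$p1_pile)
  rec <- recover_truth(sub$novel, fx$r1$truth, fx$genome)
  expect_equal(rec$sensitivity, 1.0)
  expect_equal(rec$precision, 1.0)
  expect_equal(rec$fp, 0L)
  expect_equal(rec$n_truth_hom, 29L)
  # per-class breakdown covers SBS, insertion, deletion
  expect_setequal(rec$per_class$class, c("SBS", "insertion", "deletion"))
  expect_equal(rec$per_class$recovered, rec$per_class$n_truth)
})

test_that("planted heterozygous mutations are never called", {
  fx <- fixture("base")
  calls <- call_homozygous(fx$r1_pile, sample_id = "R1")
  sub <- subtract_progenitor(calls, fx$p1_pile)
  rec <- recover_truth(sub$novel, fx$r1$truth, fx$genome)
  expect_equal(rec$het_called, 0L)
})

test_that("no call survives where the progenitor carries the same allele", {
  fx <- fixture("base")
  calls <- call_homozygous(fx$r1_pile, sample_id = "R1")
  sub <- subtract_progenitor(calls, fx$p1_pile)
  expect_true(all(sub$novel$p1_alt_fraction <= 0.1))
  expect_true(all(sub$novel$p1_depth >= 5L))
})

test_that("mutation-free fixture yields zero novel calls", {
  fx <- fixture("base")
  calls <- call_homozygous(fx$p1_pile, sample_id = "P1b")
  sub <- subtract_progenitor(calls, fx$p1_pile)
  expect_equal(nrow(sub$novel), 0L)
})

test_that("calls are invariant to read input order", {
  fx <- fixture("base")
  recs <- fx$r1_recs
  set.seed(42)
  shuffled <- recs[sample(nrow(recs))]
  c1 <- call_homozygous(build_pileup(recs, fx$genome))
  c2 <- call_homozygous(build_pileup(shuffled, fx$genome))
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("recover_truth handles the degenerate empty case", {
  fx <- fixture("base")
  empty_calls <- call_homozygous(build_pileup(fx$p1_recs[0], fx$genome))
  rec <- recover_truth(empty_calls, regenmut:::empty_truth(), fx$genome)
  expect_true(is.na(rec$sensitivity))
  expect_true(is.na(rec$precision))
})
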