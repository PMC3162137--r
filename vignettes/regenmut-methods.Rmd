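---
title: "Methods: detecting regenerant mutations by progenitor subtraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting regenerant mutations by progenitor subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Plants regenerated from tissue culture ("somaclones") show heritable
phenotypic variation even though all regenerants descend from a single
clonal progenitor. One genetic explanation is a genome-wide elevation of
the DNA mutation rate during callus growth and regeneration. Testing it
requires comparing resequenced regenerant genomes (R1: selfed progeny of
a regenerated R0 plant) against the progenitor plant (P1) at single-base
resolution, and asking four separate questions:

1. Which single-base substitutions (SBSs) and short indels are present
   in an R1 plant but absent from P1?
2. What is the molecular spectrum of those mutations — substitution
   classes, transition:transversion ratio, indel sequence context,
   coding consequences?
3. What per-site mutation frequency do they imply, and how does it
   compare with the spontaneous rate of sexually propagated plants?
4. Did anything larger happen — large insertions, inversions,
   translocations, or transposon amplification?

`regenmut` implements this analysis as a reusable pipeline, together
with a read simulator that plants known mutations so that every stage
can be validated against ground truth without access to the original
sequencing data.

## The calling model

**Read filters.** Only uniquely mapped reads with Phred-scaled mapping
quality ≥ 20 are used, at every stage (`filter_reads()`). No
base-quality filter is applied — the method's stated filters are
mapping quality and uniqueness only; a hook exists but defaults off.

**Homozygous-only calling.** A de novo mutation in the regenerated R0
plant is heterozygous when it arises. After one round of
self-pollination a heterozygous locus segregates 1/4 homozygous mutant
: 1/2 heterozygous : 1/4 homozygous wild type, so an R1 plant is
homozygous for roughly a quarter of its parent's mutations. The caller
exploits this deliberately: it emits a call only where the filtered
depth is at least `min_depth = 5` and a *single* non-reference allele
carries at least `min_alt_fraction = 0.9` of the reads. Heterozygous
patterns (two alleles near 0.5) and multi-allelic columns yield no
call. This trades sensitivity (×4 undercounting, corrected later) for
a very low false-positive rate. The original analysis used an early
SAMtools plus a filtering scheme whose full decision tree is not
public; the thresholds here are documented reconstructions, all
configurable.

**Progenitor subtraction.** A call is *novel* only when P1 is itself
well covered at the site (depth ≥ `min_p1_depth = 5`) and shows at most
`max_p1_alt_fraction = 0.1` support for the same allele. Sites
undercovered in P1 go to an explicit "unresolvable" list — they are
never silently promoted to novel. Defining novelty against P1 evidence
rather than against the reference assembly makes assembly errors cancel:
a position where the reference is simply wrong looks identical in P1
and R1 and is subtracted.

**Normalization.** Indels are left-aligned and trimmed to the VCF
anchor-base convention (`normalize_variant()`) before any comparison, so
that a deletion called anywhere inside a homopolymer run matches the
planted truth record placed anywhere else in the same run. 1-based
coordinates appear only in the VCF writer; everything internal is
0-based half-open.

## Spectrum and rate

Substitution classes are collapsed to the pyrimidine strand (G→A is
reported as C→T), giving six classes of which C→T and T→C are
transitions. A 12-class uncollapsed table is also emitted, since the
published figure's convention is not determinable from its text.

Indel context asks whether the inserted/deleted unit extends or
shortens a homopolymer run (≥ `min_run = 3` identical reference bases)
or a tandem dinucleotide repeat (≥ `min_units = 2` copies); these
cutoffs are free choices documented here — the source analysis shows
the contexts but defines no thresholds.

Coding effects translate the affected codon with strand and phase from
the GFF3 (stop-gains are additionally flagged protein-truncating);
in-CDS indels are counted as protein-altering. Without explicit UTR
features, non-CDS exonic overlap is labelled `UTR_or_noncoding_exon`
rather than guessed.

The per-site mutation frequency for an R0 plant is

> m = 4n / s

where `n` is the number of detected homozygous R1 mutations (the factor
4 undoes the 25% homozygosity expectation above) and `s` is the number
of reference positions covered by at least one filtered read
(`covered_genome_size()`), never silently the full reference length.
The fold change divides `m` by the spontaneous per-site per-generation
rate of sexually propagated Arabidopsis, 7×10⁻⁹ by default.
`selfing_homozygosity()` exposes the genotype Markov chain itself (exact
by matrix iteration, optionally Monte-Carlo over independent loci) —
after g selfings the homozygous-mutant fraction is (1 − 2⁻ᵍ)/2.

## Distant pairs and transposons

Large events are found from read pairs whose mates map strictly more
than 750 bp apart (leftmost-to-leftmost; the measuring convention is a
documented choice) or to different chromosomes. Footprints of such
reads are merged per chromosome, and regions where the distant-pair
read depth reaches 5 become clusters. An ambiguity in the source
method — whether the ≥5-read rule counts distant-pair reads or all
reads — is resolved in favour of distant-pair reads, since the
candidate lists are built from the distant-pair files.

Typing replaces the original visual inspection with orientation rules:
interchromosomal partner → translocation; dominant same-strand
orientation → inversion; same-chromosome convergent pairs bridging a
distant partner → large insertion; divergent clusters are reported
"ambiguous" (the tandem-duplication/deletion signature, which the
source method's candidate list does not name). Two geometric
consequences are worth knowing: a duplicative insertion whose donor is
on *another* chromosome necessarily types as translocation under these
rules, and the excision side of a translocation leaves a convergent
deletion-like signature at the gap. Candidates sharing ≥ 50% reciprocal
overlap with a progenitor candidate of the same type are subtracted as
pre-existing; clusters in configured exclusion intervals (centromeres,
telomeres) are flagged, never hard-coded.

Transposon amplification is scanned by read depth: per catalogued
element, mean coverage is divided by the sample's genome-wide average
depth (mean over positions with depth ≥ 1 — the masked mean, since
that is the depth regime element coverages are drawn from; the exact
statistic in the source is unstated and the choice is configurable),
and the log2 of the normalized sample/control ratio is taken. A single
duplicative transposition is expected to score 1; elements above 0.75
are flagged. Elements with zero control coverage are reported
"no-data" rather than ratio 0: after unique-read filtering, highly
repetitive elements can legitimately have no usable coverage, and a
silent 0 would hide false negatives. Flagged elements are corroborated
by the second, independent signature: distant-pair clusters whose
partner footprint lies in a catalogued element and whose target locus
is new relative to the progenitor.

## The simulator: what it emulates, what it does not

`sim_config()` defaults *are* the stated experimental world: 76 bp
paired-end reads from ~350 bp fragments, 25× mean coverage (midpoint
of the reported 22–30×), GC fraction 0.36 (Arabidopsis-like). Choices
the source leaves open, fixed here once: fragment-length SD 30 bp
(truncated below at the read length); substitution sequencing errors at
0.001 per base by default (noiseless fixtures set 0); mandatory seeds
with no hidden global randomness — identical configs give
byte-identical fixtures.

Diploidy is two haplotypes per sample; reads are drawn from each with
equal probability; heterozygous events alter haplotype A only.
Structural events are represented as a piecewise segment map from
rearranged coordinates to the reference, so every simulated read knows
its true mapping position by construction — no aligner runs. Reads
spanning a structural breakpoint are dropped (an aligner would clip or
reject them); the mate, if intact, is kept with unmapped-mate fields.
Pairs with mates in different segments acquire exactly the discordant
coordinates and orientations the detector looks for.

The simulator does **not** model: realistic Illumina error profiles or
quality scores, PCR duplicates, indel sequencing errors, multi-mapping
reads, or centromeric/telomeric repeat structure (the source analysis
excludes those regions anyway). A green test therefore establishes
that the *logic* of each detector is correct on reads with known truth
— it does not establish robustness to alignment artefacts in real
repetitive sequence, which is exactly the gap the original authors
covered by capillary-sequencing validation.

## Numerical notes

- The worked rate example n = 20, s = 115.62 Mb gives
  m = 4·20/115.62×10⁶ = 6.9×10⁻⁷ (2 significant figures), and rates are
  displayed at 2 significant figures while full precision is kept
  internally.
- 63 transitions against 68 transversions is 0.9264…; the published
  summary prints 0.92. `ts_tv_ratio()` returns the exact ratio; the
  tests assert agreement with the printed value at its own precision.
  A spectrum with zero transversions reports the ratio as undefined
  (NA), not infinity.
- On toy coverage tracks an amplified element perturbs its own
  genome-wide normalizer (a 4 kb element is a negligible fraction of a
  real 120 Mb genome but not of a 20 kb toy track), so
  `te_log2_ratios()` accepts explicit average depths to reproduce the
  large-genome regime exactly; the default computes the masked mean
  from the tracks, and the simulated-read tests use the default.
- The TE test fixture uses a 4 kb element — the size of a typical LTR
  retrotransposon — which keeps the coverage erosion at copy junctions
  (reads spanning a junction are unmappable) to a few percent of the
  element.
- Ties in the caller (two alleles at exactly equal count) are broken by
  base order A,C,G,T; with `min_alt_fraction = 0.9` a tie can never
  produce a call, so the tie-break only affects diagnostic output.

## Known limitations

Pileups hold a 5×L count matrix per chromosome, sized for the
megabase-scale fixtures of the test-suite; a full 120 Mb genome would
need chunked processing. Heterozygous calling, genotype likelihoods,
joint calling and breakpoint base-resolution refinement are explicit
non-goals. The ×4 scaling assumes one R1 plant sampled per lineage and
every R0 mutation heterozygous; detection of the same mutation in
sibling R1 plants is not modelled.
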