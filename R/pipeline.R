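#' Pipeline configuration
#'
#' Collects all file paths and stage thresholds. Every threshold
#' defaults to the method constant of the analysis it reimplements:
#' mapping quality 20, calling depth 5 with alternate fraction 0.9,
#' progenitor depth 5 with maximum alternate fraction 0.1, distant-pair
#' distance 750 bp with support 5, TE flag threshold 0.75, spontaneous
#' baseline rate 7e-9 per site per generation.
#'
#' @param reference path to the reference FASTA.
#' @param p1 path to the progenitor SAM/BAM.
#' @param r1 named character vector of regenerant SAM/BAM paths.
#' @param gff optional GFF3 annotation path.
#' @param te_catalog optional TE catalog TSV path.
#' @param exclude_bed optional BED of excluded (centromere/telomere)
#'   intervals.
#' @param outdir output directory.
#' @param min_mapq,min_depth,min_alt_fraction,min_p1_depth,
#'   max_p1_alt_fraction,sv_min_distance,sv_min_support,
#'   sv_reciprocal_overlap,te_threshold,baseline stage thresholds.
#' @param seed integer seed (only consulted by simulation helpers).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, p1, r1, gff = NULL,
                            te_catalog = NULL, exclude_bed = NULL,
                            outdir = tempfile("regenmut_out_"),
                            min_mapq = 20L, min_depth = 5L,
                            min_alt_fraction = 0.9, min_p1_depth = 5L,
                            max_p1_alt_fraction = 0.1,
                            sv_min_distance = 750L, sv_min_support = 5L,
                            sv_reciprocal_overlap = 0.5,
                            te_threshold = 0.75, baseline = 7e-9,
                            seed = 1L) {
  if (is.null(names(r1))) names(r1) <- paste0("R1_", seq_along(r1))
  structure(as.list(environment()), class = "pipeline_config")
}

read_exclude_bed <- function(path) {
  if (is.null(path)) return(NULL)
  dt <- fread(path, header = FALSE)
  setnames(dt, seq_len(3L), c("chrom", "start0", "end0"))
  dt[, .(chrom = as.character(chrom), start0 = as.integer(start0),
         end0 = as.integer(end0))]
}

#' Run the full pipeline
#'
#' For each regenerant sample: filter -> pileup -> homozygous calls ->
#' progenitor subtraction -> spectrum -> rate -> distant-pair SVs ->
#' (optional) TE coverage scan. Writes per-sample VCF/TSV/BED artifacts
#' and a deterministic combined JSON report (no timestamps or
#' hostnames) into `config$outdir`.
#'
#' @param config a [pipeline_config()].
#' @return the report (list), invisibly also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$reference, config$p1, unname(config$r1),
              config$gff, config$te_catalog, config$exclude_bed)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input: ", p)
  }
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  genome <- read_fasta(config$reference)
  ann <- if (!is.null(config$gff)) read_annotation(config$gff) else NULL
  te_cat <- if (!is.null(config$te_catalog)) read_te_catalog(config$te_catalog)
            else NULL
  exclude <- read_exclude_bed(config$exclude_bed)

  message("filtering progenitor reads (min_mapq=", config$min_mapq,
          ", require_unique=TRUE)")
  p1_recs <- filter_reads(read_alignments(config$p1),
                          min_mapq = config$min_mapq)
  p1_pile <- build_pileup(p1_recs, genome)
  p1_track <- coverage_track(p1_recs, genome)
  p1_pairs <- extract_distant_pairs(p1_recs, config$sv_min_distance)

  report <- list(
    parameters = config[setdiff(names(config),
                                c("reference", "p1", "r1", "gff",
                                  "te_catalog", "exclude_bed", "outdir"))],
    samples = list()
  )
  for (sn in names(config$r1)) {
    message("sample ", sn)
    res <- tryCatch(
      analyze_sample(sn, config$r1[[sn]], genome, p1_pile, p1_track,
                     p1_pairs, ann, te_cat, exclude, config),
      error = function(e) list(status = "failed", error = conditionMessage(e)))
    report$samples[[sn]] <- res
  }
  report_path <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  writeLines(report_text(report), file.path(config$outdir, "report.txt"))
  invisible(report)
}

analyze_sample <- function(sn, path, genome, p1_pile, p1_track, p1_pairs,
                           ann, te_cat, exclude, config) {
  recs <- filter_reads(read_alignments(path), min_mapq = config$min_mapq)
  pile <- build_pileup(recs, genome)
  track <- coverage_track(recs, genome)
  calls <- call_homozygous(pile, min_depth = config$min_depth,
                           min_alt_fraction = config$min_alt_fraction,
                           sample_id = sn)
  sub <- subtract_progenitor(calls, p1_pile,
                             min_p1_depth = config$min_p1_depth,
                             max_p1_alt_fraction = config$max_p1_alt_fraction)
  novel <- sub$novel
  s <- covered_genome_size(track, min_depth = 1L)
  rate <- estimate_rate(nrow(novel), s)
  spec <- spectrum_summary(novel, genome, annotation = ann)
  # reuse precomputed progenitor distant pairs for SV + TE subtraction
  p1_clusters <- type_candidates(cluster_pairs(p1_pairs,
                                               config$sv_min_support,
                                               exclude))
  r1_pairs <- extract_distant_pairs(recs, config$sv_min_distance)
  r1_clusters <- type_candidates(cluster_pairs(r1_pairs,
                                               config$sv_min_support,
                                               exclude))
  r1_clusters <- subtract_shared(r1_clusters, p1_clusters,
                                 config$sv_reciprocal_overlap)
  sv_novel <- r1_clusters[shared_with_progenitor == FALSE &
                            excluded == FALSE & type != "ambiguous"]
  te <- NULL
  te_novel_ins <- NULL
  if (!is.null(te_cat)) {
    te <- te_log2_ratios(track, p1_track, te_cat,
                         threshold = config$te_threshold)
    te_novel_ins <- detect_te_insertions(r1_pairs, p1_pairs, te_cat,
                                         min_support = config$sv_min_support)
  }
  # artifacts
  out <- config$outdir
  write_vcf(calls, file.path(out, paste0(sn, ".calls.vcf")), genome)
  write_vcf(novel, file.path(out, paste0(sn, ".novel.vcf")), genome)
  if (nrow(sub$unresolvable) > 0L)
    fwrite(sub$unresolvable, file.path(out, paste0(sn, ".unresolvable.tsv")),
           sep = "\t")
  if (nrow(r1_clusters) > 0L)
    fwrite(r1_clusters, file.path(out, paste0(sn, ".sv_clusters.tsv")),
           sep = "\t")
  if (!is.null(te))
    fwrite(te, file.path(out, paste0(sn, ".te_log2.tsv")), sep = "\t")
  covered <- covered_regions(track)
  write_bed(covered, file.path(out, paste0(sn, ".covered.bed")))

  list(status = "ok",
       n_detected = nrow(novel),
       n_sbs = sum(novel$type == "SBS"),
       n_indel = sum(novel$type != "SBS"),
       theoretical = rate$theoretical,
       s = s, m = rate$m,
       fold_change = fold_change(rate$m, config$baseline),
       ts_tv = spec$ts_tv,
       class6 = as.data.frame(spec$class6),
       indel_context = as.data.frame(spec$indel_context),
       location = if (!is.null(spec$location)) as.data.frame(spec$location),
       by_chrom = as.data.frame(spec$by_chrom),
       n_unresolvable = nrow(sub$unresolvable),
       n_inherited = nrow(sub$inherited),
       sv_candidates = as.data.frame(sv_novel),
       te_flagged = if (!is.null(te)) te[flagged == TRUE, element_id],
       te_novel_insertions = if (!is.null(te_novel_ins))
         as.data.frame(te_novel_ins))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

covered_regions <- function(track, min_depth = 1L) {
  out <- list()
  for (cn in names(track)) {
    r <- rle(track[[cn]] >= min_depth)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[length(out) + 1L]] <- data.table(chrom = cn,
                                            start0 = starts[keep],
                                            end0 = ends[keep])
  }
  if (length(out) == 0L)
    return(data.table(chrom = character(), start0 = integer(),
                      end0 = integer()))
  rbindlist(out)
}

report_text <- function(report) {
  lines <- c("regenerant mutation analysis report", "")
  for (sn in names(report$samples)) {
    s <- report$samples[[sn]]
    if (!identical(s$status, "ok")) {
      lines <- c(lines, sprintf("%s: FAILED (%s)", sn, s$error))
      next
    }
    lines <- c(lines,
               sprintf("%s: detected %d (SBS %d, indel %d); theoretical %d",
                       sn, s$n_detected, s$n_sbs, s$n_indel, s$theoretical),
               sprintf("  s = %s bp; m = %s per site; fold change vs baseline = %.1f",
                       format(s$s, big.mark = ","),
                       format(signif(s$m, 2), scientific = TRUE),
                       s$fold_change),
               sprintf("  Ts:Tv = %s",
                       if (is.null(s$ts_tv) || is.na(s$ts_tv)) "undefined"
                       else formatC(s$ts_tv, format = "f", digits = 2)),
               sprintf("  SV candidates: %d; TE flagged: %d",
                       NROW(s$sv_candidates),
                       length(s$te_flagged %||% character(0))))
  }
  lines
}
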