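#' Read a transposable-element catalog
#'
#' TSV with columns `element_id`, `family`, `chrom`, `start`, `end`
#' (1-based inclusive, converted to the internal 0-based half-open
#' convention).
#'
#' @param path TSV file.
#' @return data.table with element_id, family, chrom, start0, end0,
#'   length.
#' @export
read_te_catalog <- function(path) {
  dt <- fread(path)
  need <- c("element_id", "family", "chrom", "start", "end")
  if (!all(need %in% names(dt)))
    stop("TE catalog must have columns: ", paste(need, collapse = ", "))
  out <- dt[, .(element_id = as.character(element_id),
                family = as.character(family), chrom = as.character(chrom),
                start0 = as.integer(start) - 1L, end0 = as.integer(end))]
  out$length <- out$end0 - out$start0
  if (any(out$length <= 0L)) stop("TE catalog contains zero-length elements")
  out[]
}

#' Mean filtered depth over one element
#'
#' Sums the coverage at each position within the element and divides by
#' its length.
#'
#' @param track a `coverage_track`.
#' @param element one-row data.table or list with chrom, start0, end0.
#' @return mean depth (numeric).
#' @export
element_mean_coverage <- function(track, element) {
  if (element$end0 <= element$start0)
    stop("element_mean_coverage: zero-length element")
  v <- track[[element$chrom]]
  if (is.null(v)) stop("no coverage track for chromosome ", element$chrom)
  mean(v[(element$start0 + 1L):element$end0])
}

#' Per-element log2 coverage ratios between a sample and a control
#'
#' For each catalogued element the mean depth is normalized by the
#' sample's own genome-wide average depth (computed over the covered
#' mask), and the log2 of the normalized sample/control ratio is taken.
#' A duplicative transposition (one extra copy) is expected to score
#' log2 = 1; elements are flagged when the score exceeds `threshold`
#' (strictly). Elements with zero normalized control coverage carry
#' status "no-data" rather than a ratio — unique-read filtering can
#' legitimately blank out highly repetitive elements, and reporting
#' those as 0 would hide false negatives.
#'
#' @param sample_track,control_track `coverage_track`s built from
#'   filtered reads of the sample and control.
#' @param elements TE catalog data.table (from [read_te_catalog()] or
#'   equivalent).
#' @param threshold flag threshold on the log2 ratio.
#' @param masked_mean normalize by mean depth over covered positions
#'   (TRUE, default) or over the whole genome.
#' @param sample_avg,control_avg optional explicit genome-wide average
#'   depths; by default they are computed from the tracks. On a real
#'   genome the elements are a negligible fraction of the sequence, so
#'   supplying the known averages reproduces that regime exactly on toy
#'   tracks where an amplified element would otherwise perturb its own
#'   normalizer.
#' @return data.table: element_id, family, mean_coverage,
#'   control_coverage, normalized_coverage, control_normalized,
#'   log2_ratio, status, flagged.
#' @export
te_log2_ratios <- function(sample_track, control_track, elements,
                           threshold = 0.75, masked_mean = TRUE,
                           sample_avg = NULL, control_avg = NULL) {
  elements <- as.data.table(elements)
  if (nrow(elements) == 0L) stop("te_log2_ratios: empty TE catalog")
  avg_s <- sample_avg %||% mean_depth(sample_track, masked = masked_mean)
  avg_c <- control_avg %||% mean_depth(control_track, masked = masked_mean)
  if (avg_c == 0) stop("te_log2_ratios: control average depth is zero")
  if (avg_s == 0) stop("te_log2_ratios: sample average depth is zero")
  mc_s <- vapply(seq_len(nrow(elements)), function(i)
    element_mean_coverage(sample_track, elements[i]), numeric(1))
  mc_c <- vapply(seq_len(nrow(elements)), function(i)
    element_mean_coverage(control_track, elements[i]), numeric(1))
  norm_s <- mc_s / avg_s
  norm_c <- mc_c / avg_c
  log2_ratio <- ifelse(norm_c > 0, log2(norm_s / norm_c), NA_real_)
  status <- ifelse(norm_c > 0, "ok", "no-data")
  flagged <- !is.na(log2_ratio) & log2_ratio > threshold
  data.table(element_id = elements$element_id,
             family = if ("family" %in% names(elements)) elements$family
                      else NA_character_,
             mean_coverage = mc_s, control_coverage = mc_c,
             normalized_coverage = norm_s, control_normalized = norm_c,
             log2_ratio = log2_ratio, status = status, flagged = flagged)
}

#' Detect novel TE insertions from distant-pair signatures
#'
#' A novel insertion of a catalogued element produces distant pairs with
#' one read flanking the new target site and the mate inside the
#' element's reference location. Regenerant distant-pair clusters whose
#' partner footprint overlaps a catalogued element, whose own locus lies
#' outside that element, and which are absent from the progenitor are
#' reported with target site and donor element.
#'
#' @param r1_pairs,p1_pairs `distant_pairs` tables (from
#'   [extract_distant_pairs()]).
#' @param elements TE catalog data.table.
#' @param min_support minimum distant-pair depth per cluster.
#' @param reciprocal_overlap sharing threshold against progenitor
#'   clusters.
#' @return data.table of candidates: target_chrom, target_start0,
#'   target_end0, element_id, family, n_pairs.
#' @export
detect_te_insertions <- function(r1_pairs, p1_pairs, elements,
                                 min_support = 5L,
                                 reciprocal_overlap = 0.5) {
  elements <- as.data.table(elements)
  if (nrow(elements) == 0L) stop("detect_te_insertions: empty TE catalog")
  empty <- data.table(target_chrom = character(), target_start0 = integer(),
                      target_end0 = integer(), element_id = character(),
                      family = character(), n_pairs = integer())
  te_hits <- function(clusters) {
    if (nrow(clusters) == 0L) return(empty)
    rows <- list()
    for (i in seq_len(nrow(clusters))) {
      cl <- clusters[i]
      ov <- elements$chrom == cl$partner_chrom &
        elements$start0 < cl$partner_end0 & elements$end0 > cl$partner_start0
      if (!any(ov)) next
      el <- elements[which(ov)[1]]
      inside <- cl$chrom == el$chrom & cl$start0 < el$end0 &
        cl$end0 > el$start0
      if (inside) next
      rows[[length(rows) + 1L]] <- data.table(
        target_chrom = cl$chrom, target_start0 = cl$start0,
        target_end0 = cl$end0, element_id = el$element_id,
        family = el$family, n_pairs = cl$n_pairs)
    }
    if (length(rows) == 0L) return(empty) else rbindlist(rows)
  }
  r1_cand <- te_hits(cluster_pairs(r1_pairs, min_support))
  p1_cand <- te_hits(cluster_pairs(p1_pairs, min_support))
  if (nrow(r1_cand) == 0L) return(r1_cand)
  keep <- rep(TRUE, nrow(r1_cand))
  for (i in seq_len(nrow(r1_cand))) {
    if (nrow(p1_cand) == 0L) break
    same <- p1_cand[element_id == r1_cand$element_id[i] &
                      target_chrom == r1_cand$target_chrom[i]]
    if (nrow(same) == 0L) next
    ov <- pmax(0L, pmin(same$target_end0, r1_cand$target_end0[i]) -
                 pmax(same$target_start0, r1_cand$target_start0[i]))
    w1 <- r1_cand$target_end0[i] - r1_cand$target_start0[i]
    w2 <- same$target_end0 - same$target_start0
    if (any(ov >= reciprocal_overlap * w1 & ov >= reciprocal_overlap * w2))
      keep[i] <- FALSE
  }
  r1_cand[keep]
}
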