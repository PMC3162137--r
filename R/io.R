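#' Write a simulated sample to disk as a fixture
#'
#' Emits a coordinate-sorted SAM file and a truth JSON next to it. The
#' pair round-trips losslessly through [read_alignments()] and
#' [read_truth()].
#'
#' @param sample_name sample label, used as the file stem.
#' @param records alignment record data.table (as from
#'   [simulate_read_pairs()]); sorted before writing if needed.
#' @param truth a `truth_set` (optional).
#' @param dir output directory (created if missing).
#' @param genome reference genome (named character vector), used for the
#'   SAM header `@SQ` lines.
#' @return invisibly, named vector of written paths.
#' @export
write_fixture <- function(sample_name, records, truth = NULL, dir, genome) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sam_path <- file.path(dir, paste0(sample_name, ".sam"))
  write_sam(records, sam_path, genome)
  paths <- c(sam = sam_path)
  if (!is.null(truth)) {
    truth_path <- file.path(dir, paste0(sample_name, ".truth.json"))
    write_truth(truth, truth_path)
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}

#' Write alignment records as SAM
#'
#' @param records alignment record data.table.
#' @param path output path (plain-text SAM).
#' @param genome named character vector (for header contig lengths).
#' @export
write_sam <- function(records, path, genome) {
  g <- as_genome(genome)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(g), nchar(g)))
  records <- as.data.table(records)
  if (nrow(records) > 0L) {
    records <- records[order(chrom, pos, qname)]
    mate_unmapped <- is.na(records$mate_pos) | is.na(records$mate_chrom)
    flag <- 1L +                                   # paired
      ifelse(records$strand == "-", 16L, 0L) +
      ifelse(!mate_unmapped & records$mate_strand == "-", 32L, 0L) +
      ifelse(mate_unmapped, 8L, 0L) +
      ifelse(records$first_of_pair, 64L, 128L)
    tlen <- ifelse(!mate_unmapped & records$chrom == records$mate_chrom,
                   records$mate_pos - records$pos, 0L)
    body <- paste(records$qname, flag, records$chrom, records$pos + 1L,
                  records$mapq, records$cigar,
                  ifelse(mate_unmapped, "*", records$mate_chrom),
                  ifelse(mate_unmapped, 0L, records$mate_pos + 1L), tlen,
                  records$seq,
                  strrep("I", nchar(records$seq)),
                  ifelse(records$unique, "XU:i:1", "XU:i:0"),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted with Rsamtools and parsed with standard flag
#' semantics. The uniqueness flag is taken from the simulator's `XU` tag
#' when present; otherwise a read is "unique" when it is neither
#' secondary nor supplementary and has mapping quality > 0 (the exact
#' uniqueness criterion of the original analysis is not operational;
#' this flag-based rule is the documented choice).
#'
#' @param path SAM or BAM file.
#' @return alignment record data.table (0-based positions).
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand",
            "mrnm", "mpos", "seq")
  p <- Rsamtools::ScanBamParam(what = what, tag = "XU")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  if (n == 0L) return(empty_alignments())
  flag <- res$flag
  xu <- res$tag$XU
  unique_flag <- if (!is.null(xu) && length(xu) == n) {
    xu == 1L
  } else {
    bitwAnd(flag, 0x100) == 0L & bitwAnd(flag, 0x800) == 0L & res$mapq > 0L
  }
  mate_unmapped <- bitwAnd(flag, 0x8) > 0L
  dt <- data.table(
    qname = res$qname,
    chrom = as.character(res$rname),
    pos = res$pos - 1L,
    strand = ifelse(bitwAnd(flag, 0x10) > 0L, "-", "+"),
    mapq = as.integer(res$mapq),
    unique = unique_flag,
    cigar = res$cigar,
    seq = as.character(res$seq),
    mate_chrom = ifelse(mate_unmapped, NA_character_,
                        as.character(res$mrnm)),
    mate_pos = ifelse(mate_unmapped, NA_integer_, res$mpos - 1L),
    mate_strand = ifelse(mate_unmapped, NA_character_,
                         ifelse(bitwAnd(flag, 0x20) > 0L, "-", "+")),
    first_of_pair = bitwAnd(flag, 0x40) > 0L
  )
  dt[!is.na(pos)][order(chrom, pos, qname)]
}

#' Write a truth set as JSON
#' @param truth a `truth_set`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(lapply(unclass(truth), as.data.frame), path,
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a truth set written by [write_truth()]
#' @param path truth JSON path.
#' @return a `truth_set`.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- empty_truth()
  for (nm in names(out)) {
    if (!is.null(raw[[nm]]) && length(raw[[nm]]) > 0 && NROW(raw[[nm]]) > 0) {
      dt <- as.data.table(raw[[nm]])
      for (col in names(out[[nm]])) {
        if (!col %in% names(dt)) dt[[col]] <- out[[nm]][[col]][NA_integer_]
        mode_wanted <- class(out[[nm]][[col]])[1]
        if (mode_wanted == "integer") dt[[col]] <- as.integer(dt[[col]])
        if (mode_wanted == "character") dt[[col]] <- as.character(dt[[col]])
      }
      out[[nm]] <- dt[, names(out[[nm]]), with = FALSE]
    }
  }
  out
}

#' Write a genome as FASTA
#' @param genome named character vector or DNAStringSet.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome_as_dnastringset(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

#' Export simulated records as FASTQ (optional, for running a real
#' aligner outside the pipeline)
#'
#' @param records alignment record data.table.
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`. Mate-2 sequences are reverse-complemented back
#'   to sequencing orientation.
#' @export
write_fastq <- function(records, prefix) {
  records <- as.data.table(records)
  for (mate in 1:2) {
    rows <- records[first_of_pair == (mate == 1L)][order(qname)]
    seqs <- rows$seq
    flipme <- rows$strand == "-"
    if (any(flipme)) seqs[flipme] <- revcomp(seqs[flipme])
    path <- paste0(prefix, "_", mate, ".fastq")
    lines <- as.vector(rbind(paste0("@", rows$qname, "/", mate), seqs,
                             "+", strrep("I", nchar(seqs))))
    writeLines(lines, path)
  }
  invisible(paste0(prefix, "_", 1:2, ".fastq"))
}

#' Write variant calls as VCF 4.2
#'
#' Positions are converted to 1-based; alleles are the left-normalized
#' anchor-base representation used internally.
#'
#' @param calls data.table with chrom, pos0, ref, alt, and optionally
#'   depth, alt_fraction, sample, p1_depth, p1_alt_fraction.
#' @param path output path.
#' @param genome named character vector (contig header lines).
#' @export
write_vcf <- function(calls, path, genome) {
  g <- as_genome(genome)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(g), nchar(g)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Filtered read depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
           "##INFO=<ID=P1DP,Number=1,Type=Integer,Description=\"Progenitor depth\">",
           "##INFO=<ID=P1AF,Number=1,Type=Float,Description=\"Progenitor alt fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  calls <- as.data.table(calls)
  if (nrow(calls) > 0L) {
    info <- rep("", nrow(calls))
    addinfo <- function(info, key, val, fmt = "%s") {
      piece <- sprintf(paste0(key, "=", fmt), val)
      ifelse(nzchar(info), paste0(info, ";", piece), piece)
    }
    if ("depth" %in% names(calls)) info <- addinfo(info, "DP", calls$depth, "%d")
    if ("alt_fraction" %in% names(calls))
      info <- addinfo(info, "AF", calls$alt_fraction, "%.4f")
    if ("sample" %in% names(calls)) info <- addinfo(info, "SAMPLE", calls$sample)
    if ("p1_depth" %in% names(calls))
      info <- addinfo(info, "P1DP", calls$p1_depth, "%d")
    if ("p1_alt_fraction" %in% names(calls))
      info <- addinfo(info, "P1AF", calls$p1_alt_fraction, "%.4f")
    info[!nzchar(info)] <- "."
    body <- paste(calls$chrom, calls$pos0 + 1L, ".", calls$ref, calls$alt,
                  ".", "PASS", info, sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write intervals as BED (0-based half-open, matching the internal
#' convention)
#' @param dt data.table with chrom, start0, end0 and optionally name/score.
#' @param path output path.
#' @export
write_bed <- function(dt, path) {
  dt <- as.data.table(dt)
  cols <- list(dt$chrom, dt$start0, dt$end0)
  if ("name" %in% names(dt)) cols <- c(cols, list(dt$name))
  if ("score" %in% names(dt)) cols <- c(cols, list(dt$score))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
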