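#' Simulation configuration
#'
#' Bundles all parameters of the synthetic sequencing experiment. Defaults
#' describe the stated world of the pipeline: an Arabidopsis-like genome
#' (GC fraction 0.36) resequenced with 76 bp paired-end reads drawn from
#' ~350 bp fragments at 25-fold mean coverage.
#'
#' @param genome_length bases per chromosome.
#' @param n_chromosomes number of chromosomes.
#' @param gc_content GC fraction in (0, 1).
#' @param read_length read length in bases.
#' @param fragment_mean,fragment_sd Gaussian fragment-length parameters
#'   (bases); fragments are truncated below at `read_length`.
#' @param depth mean fold-coverage over both haplotypes.
#' @param base_error_rate per-base probability of a substitution
#'   sequencing error.
#' @param seed integer seed; mandatory, there is no hidden global
#'   randomness. Identical configs give bit-identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L,
                       n_chromosomes = 1L,
                       gc_content = 0.36,
                       read_length = 76L,
                       fragment_mean = 350L,
                       fragment_sd = 30,
                       depth = 25,
                       base_error_rate = 0.001,
                       seed) {
  if (missing(seed)) stop("sim_config: `seed` is mandatory")
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    gc_content = gc_content,
    read_length = as.integer(read_length),
    fragment_mean = as.integer(fragment_mean),
    fragment_sd = fragment_sd,
    depth = depth,
    base_error_rate = base_error_rate,
    seed = as.integer(seed)
  )
  if (cfg$genome_length <= 0L) stop("sim_config: genome_length must be positive")
  if (cfg$n_chromosomes <= 0L) stop("sim_config: n_chromosomes must be positive")
  if (cfg$gc_content < 0 || cfg$gc_content > 1)
    stop("sim_config: gc_content must lie in [0, 1]")
  if (cfg$read_length > cfg$fragment_mean)
    stop("sim_config: read_length must not exceed fragment_mean")
  if (cfg$depth < 0) stop("sim_config: depth must be >= 0")
  if (cfg$base_error_rate < 0 || cfg$base_error_rate > 1)
    stop("sim_config: base_error_rate must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_chromosomes, "chromosome(s) x", x$genome_length, "bp,",
      "GC", x$gc_content, "\n  ",
      x$read_length, "bp paired-end reads, fragments ~N(",
      x$fragment_mean, ",", x$fragment_sd, "), depth", x$depth,
      ", error rate", x$base_error_rate, ", seed", x$seed, "\n")
  invisible(x)
}
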