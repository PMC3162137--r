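#' Per-site mutation frequency with heterozygote scaling
#'
#' If n homozygous mutations are detected in an R1 plant, the expected
#' number of (originally heterozygous) mutations in the source R0 plant
#' is 4n, because a heterozygous mutation has a 1/4 chance of being
#' homozygous after one selfing generation. The per-site mutation
#' frequency is m = 4n/s, where s is the uniquely-covered genome size.
#'
#' @param n detected homozygous mutation count.
#' @param s covered genome size in bases (from
#'   [covered_genome_size()]; never silently the full reference length).
#' @return object of class `rate_estimate`: list(n, s, theoretical, m).
#' @export
estimate_rate <- function(n, s) {
  if (n < 0) stop("estimate_rate: n must be >= 0")
  if (s <= 0) stop("estimate_rate: s must be > 0")
  structure(list(n = n, s = s, theoretical = 4 * n, m = 4 * n / s),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("rate_estimate: n =", x$n, ", s =", format(x$s, big.mark = ","),
      "bp; theoretical 4n =", x$theoretical, "; m =",
      format(signif(x$m, 2), scientific = TRUE), "per site\n")
  invisible(x)
}

#' Fold change over the spontaneous baseline rate
#'
#' @param m per-site mutation frequency (number or `rate_estimate`).
#' @param baseline spontaneous per-site per-generation rate (default
#'   7e-9, the rate observed in sexually propagated Arabidopsis).
#' @return m / baseline.
#' @export
fold_change <- function(m, baseline = 7e-9) {
  if (inherits(m, "rate_estimate")) m <- m$m
  if (baseline <= 0) stop("fold_change: baseline must be > 0")
  m / baseline
}

#' Homozygous-mutant fraction after selfing generations
#'
#' A locus heterozygous for a new mutation segregates 1/4 homozygous
#' mutant : 1/2 heterozygous : 1/4 homozygous wild-type at each selfing.
#' The exact expectation is obtained by iterating this genotype Markov
#' chain; optionally a Monte-Carlo estimate over independent loci is
#' returned alongside.
#'
#' @param generations number of selfing generations (0 = still the R0
#'   heterozygote).
#' @param replicates Monte-Carlo replicate loci (0 disables simulation).
#' @param seed seed for the Monte-Carlo draw (required when
#'   `replicates > 0`).
#' @return list with `exact` (fraction homozygous mutant), `mc`
#'   (Monte-Carlo estimate or NA), `mc_se` (binomial standard error or
#'   NA), `replicates`.
#' @export
selfing_homozygosity <- function(generations, replicates = 0L, seed = NULL) {
  stopifnot(generations >= 0L)
  # states: hom-mut, het, hom-wt; selfing transition for the het state
  trans <- matrix(c(1, 0, 0,
                    0.25, 0.5, 0.25,
                    0, 0, 1), nrow = 3L, byrow = TRUE)
  state <- c(0, 1, 0)
  g <- generations
  while (g > 0L) {
    state <- as.numeric(state %*% trans)
    g <- g - 1L
  }
  exact <- state[1]
  mc <- NA_real_
  se <- NA_real_
  if (replicates > 0L) {
    if (is.null(seed)) stop("selfing_homozygosity: seed required for Monte-Carlo")
    mc <- with_seed(derive_seed(seed, "selfing"), {
      geno <- rep.int(1L, replicates)  # 1 = het; 0 = hom-mut; 2 = hom-wt
      for (gen in seq_len(generations)) {
        het <- geno == 1L
        if (!any(het)) break
        draw <- sample(c(0L, 1L, 2L), sum(het), replace = TRUE,
                       prob = c(0.25, 0.5, 0.25))
        geno[het] <- draw
      }
      mean(geno == 0L)
    })
    se <- sqrt(max(mc * (1 - mc), .Machine$double.eps) / replicates)
  }
  list(exact = exact, mc = mc, mc_se = se, replicates = replicates)
}
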