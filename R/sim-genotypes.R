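#' Map expansion for sib-mated recombinant inbred lines
#'
#' In an RI panel produced by repeated sib-mating, the chance that two loci
#' carry alleles from different founders is inflated relative to a single
#' meiosis.  The Haldane-Waddington expansion for sib-mating is
#' `R = 4r / (1 + 6r)`, where `r` is the per-meiosis recombination fraction.
#'
#' @param r per-meiosis recombination fraction, in `[0, 0.5]` (vectorised).
#' @return expanded RI recombination fraction `R`, also in `[0, 0.5]`.
#' @examples
#' expand_rf(0.1)  # 0.25
#' @export
expand_rf <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.5))
    stop("recombination fraction must lie in [0, 0.5]")
  4 * r / (1 + 6 * r)
}

#' Haldane map function
#'
#' Converts a map distance in cM to a single-meiosis recombination fraction
#' under no interference: `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param d_cM map distance in centimorgans (vectorised, non-negative).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane_rf <- function(d_cM) {
  if (any(!is.finite(d_cM)) || any(d_cM < 0))
    stop("map distance must be finite and non-negative")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Simulate RI-panel genotypes
#'
#' Each line's genome on each chromosome is a two-state Markov chain over the
#' marker grid: the first marker is B or D with probability 1/2, and the
#' allele switches between adjacent markers with probability
#' `expand_rf(haldane_rf(delta_cM))`.  Higher-order interference is ignored;
#' lines are fully inbred, so no heterozygous calls are produced.
#'
#' @param map a [genetic_map()].
#' @param n_lines number of RI lines (default 32).
#' @param seed integer seed; the result is fully determined by it.
#' @return integer matrix, lines x markers, coded B = 0, D = 1; row names are
#'   line ids (`BXD1`, ...), column names the marker names.
#' @export
simulate_ri_genotypes <- function(map, n_lines = 32, seed = 1) {
  stopifnot(inherits(map, "genetic_map"), nrow(map) >= 1, n_lines >= 1)
  withr::with_seed(as.integer(seed), {
    G <- matrix(NA_integer_, nrow = n_lines, ncol = nrow(map),
                dimnames = list(paste0("BXD", seq_len(n_lines)), map$marker))
    for (cc in unique(map$chr)) {
      idx <- which(map$chr == cc)
      g <- stats::rbinom(n_lines, 1, 0.5)
      G[, idx[1]] <- g
      if (length(idx) > 1) {
        R <- expand_rf(haldane_rf(diff(map$cM[idx])))
        for (j in seq_along(R)) {
          flip <- stats::rbinom(n_lines, 1, R[j])
          g <- ifelse(flip == 1L, 1L - g, g)
          G[, idx[j + 1]] <- g
        }
      }
    }
    G
  })
}
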