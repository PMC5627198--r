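#' Peak-marker effect size and allele direction
#'
#' Least-squares regression of line means on the 0/1 genotype code of a
#' single marker: the coefficient of determination R-squared is the
#' fraction of line-mean variance the marker explains, and the allele
#' increasing the trait is `"D2"` for a positive D-coefficient, `"B6"` for
#' a negative one (`"indeterminate"` if exactly zero).
#'
#' @param y line means (named vector or `line_trait`).
#' @param calls named 0/1 marker calls for the same lines.
#' @return list with `R2`, `allele_increasing`, `slope`, `n`.
#' @export
peak_r2 <- function(y, calls) {
  yv <- line_values(y)
  shared <- intersect(names(yv), names(calls))
  ok <- shared[!is.na(yv[shared]) & !is.na(calls[shared])]
  yv <- yv[ok]; x <- calls[ok]
  if (length(unique(x)) < 2) stop("monomorphic marker: R2 undefined")
  sxx <- sum((x - mean(x))^2)
  syy <- sum((yv - mean(yv))^2)
  b <- sum((x - mean(x)) * (yv - mean(yv))) / sxx
  r2 <- if (syy == 0) 0 else b^2 * sxx / syy
  allele <- if (b > 0) "D2" else if (b < 0) "B6" else "indeterminate"
  list(R2 = unname(r2), allele_increasing = allele, slope = unname(b),
       n = length(ok))
}

#' Phenotypic correlation between two line-mean traits
#'
#' Pearson product-moment correlation over the lines present in both
#' vectors, with the two-sided p-value from the t transform; used to check
#' that directly and indirectly affected traits at a locus covary at the
#' phenotypic level.
#'
#' @param x,y line means (named vectors or `line_trait`s).
#' @return list with `r`, `p`, `n`.
#' @export
trait_correlation <- function(x, y) {
  xv <- line_values(x); yv <- line_values(y)
  shared <- intersect(names(xv), names(yv))
  shared <- shared[!is.na(xv[shared]) & !is.na(yv[shared])]
  if (length(shared) < 3) stop("need at least 3 shared lines")
  ct <- stats::cor.test(xv[shared], yv[shared], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Broad-sense heritability from a one-way ANOVA on lines
#'
#' One-way ANOVA of replicate-level adjusted residuals with line as the
#' factor; broad-sense heritability is estimated as eta-squared,
#' `H2 = SS_between / SS_total`, with the F statistic and its p-value.
#' Requires at least two lines with two or more replicates each (an ANOVA
#' on single-replicate lines is degenerate).
#'
#' @param adj replicate-level residuals: an `adjusted_trait` (or any data
#'   frame with `line_id` and `residual` columns).
#' @return list with `H2`, `F`, `p`, `n_lines`, `n_obs`.
#' @export
heritability_anova <- function(adj) {
  if (!all(c("line_id", "residual") %in% names(adj)))
    stop("need columns line_id and residual")
  dat <- data.frame(line = factor(adj$line_id), y = adj$residual)
  dat <- dat[!is.na(dat$y), , drop = FALSE]
  reps <- table(dat$line)
  if (sum(reps >= 2) < 2)
    stop("need at least 2 lines with >= 2 replicates for the line ANOVA")
  fit <- stats::aov(y ~ line, data = dat)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  h2 <- ss[1] / sum(ss)
  sm <- summary(fit)[[1]]
  list(H2 = h2, F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
       n_lines = nlevels(droplevels(dat$line)), n_obs = nrow(dat))
}
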