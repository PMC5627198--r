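#' Convert a likelihood ratio statistic to a LOD score
#'
#' `LOD = LRS / divisor`.  The default divisor 4.61 is the GeneNetwork
#' convention; the exact-theory value `2 * ln 10` (about 4.6052) is selected
#' with `divisor = "exact"`.
#'
#' @param lrs non-negative LRS value(s).
#' @param divisor numeric divisor, or `"exact"` for `2 * log(10)`.
#' @examples
#' lrs_to_lod(19.517)  # 4.234
#' @export
lrs_to_lod <- function(lrs, divisor = 4.61) {
  if (any(!is.finite(lrs)) || any(lrs < 0)) stop("LRS must be non-negative")
  if (identical(divisor, "exact")) divisor <- 2 * log(10)
  lrs / divisor
}

# scan grid: marker positions plus pseudomarkers every step_cM (0 = markers
# only); Mb interpolated from the marker (cM, Mb) pairs
scan_grid <- function(map, step_cM = 0) {
  pieces <- lapply(unique(map$chr), function(cc) {
    m <- map[map$chr == cc, , drop = FALSE]
    cm <- m$cM
    if (step_cM > 0 && nrow(m) > 1)
      cm <- sort(unique(c(cm, seq(min(cm), max(cm), by = step_cM))))
    at_marker <- match(cm, m$cM)
    data.frame(chr = cc, cM = cm, Mb = interpolate_mb(map, cc, cm),
               marker = ifelse(is.na(at_marker), NA_character_,
                               m$marker[at_marker]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Conditional genotype probability at a map position
#'
#' Probability that a line carries the D allele at an arbitrary position,
#' given its observed flanking marker calls, under the two-state Markov
#' model of the RI genome with step probabilities
#' `expand_rf(haldane_rf(distance))`.  At a typed marker this returns the
#' call itself; with only one informative flank it conditions on that flank
#' alone; with no informative marker on the chromosome it returns `NA` (the
#' line is then dropped from the regression at that position).
#'
#' @param G genotype matrix (lines x markers, 0/1/NA).
#' @param map the [genetic_map()].
#' @param line line id (row of `G`).
#' @param chr chromosome of the query position.
#' @param pos_cM query position in cM.
#' @return P(D) in `[0, 1]`, or `NA`.
#' @export
genotype_prob <- function(G, map, line, chr, pos_cM) {
  m <- map[map$chr == as.character(chr), , drop = FALSE]
  if (!nrow(m)) stop("no markers on chromosome ", chr)
  calls <- G[line, m$marker]
  typed <- which(!is.na(calls))
  if (!length(typed)) return(NA_real_)
  prob_from_flanks(pos_cM, m$cM[typed], calls[typed])
}

# core flanking-marker computation shared by genotype_prob and the matrix
# builder; typed_cM sorted ascending, calls in {0,1}
prob_from_flanks <- function(pos, typed_cM, calls) {
  hit <- which(abs(typed_cM - pos) < 1e-9)
  if (length(hit)) return(as.numeric(calls[hit[1]]))
  left <- which(typed_cM < pos)
  right <- which(typed_cM > pos)
  step <- function(g, d) {          # P(D at query | call g at distance d)
    R <- expand_rf(haldane_rf(d))
    if (g == 1) 1 - R else R
  }
  if (length(left) && length(right)) {
    iL <- left[length(left)]; iR <- right[1]
    pL <- step(calls[iL], pos - typed_cM[iL])       # P(D | left)
    R_r <- expand_rf(haldane_rf(typed_cM[iR] - pos))
    lik_r <- function(g) if (g == calls[iR]) 1 - R_r else R_r  # P(right | g)
    num <- pL * lik_r(1)
    den <- num + (1 - pL) * lik_r(0)
    num / den
  } else if (length(left)) {
    iL <- left[length(left)]
    step(calls[iL], pos - typed_cM[iL])
  } else {
    iR <- right[1]
    step(calls[iR], typed_cM[iR] - pos)
  }
}

# lines x grid matrix of P(D); grid from scan_grid()
genotype_prob_matrix <- function(G, map, grid) {
  P <- matrix(NA_real_, nrow = nrow(G), ncol = nrow(grid),
              dimnames = list(rownames(G), NULL))
  for (cc in unique(grid$chr)) {
    m <- map[map$chr == cc, , drop = FALSE]
    gj <- which(grid$chr == cc)
    calls_chr <- G[, m$marker, drop = FALSE]
    for (i in seq_len(nrow(G))) {
      typed <- which(!is.na(calls_chr[i, ]))
      if (!length(typed)) next
      P[i, gj] <- vapply(grid$cM[gj], prob_from_flanks,
                         numeric(1), m$cM[typed], calls_chr[i, typed])
    }
  }
  P
}

# LRS for one position: n * ln(RSS0/RSS1) of the Haley-Knott regression of
# y on P(D); complete cases only; ratio capped at LRS_CAP_RATIO
LRS_CAP_RATIO <- 1e12

lrs_at <- function(y, x) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(c(lrs = NA_real_, n = n))
  y <- y[ok]; x <- x[ok]
  rss0 <- sum((y - mean(y))^2)
  if (rss0 == 0) return(c(lrs = 0, n = n))
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(c(lrs = 0, n = n))
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss1 <- rss0 - b^2 * sxx
  ratio <- rss0 / max(rss1, rss0 / LRS_CAP_RATIO)
  c(lrs = n * log(ratio), n = n)
}

#' Genome scan of line means by Haley-Knott regression
#'
#' At every grid position (markers plus pseudomarkers every `step_cM`; 0 =
#' markers only) the line-mean trait is regressed on the conditional
#' probability of the D allele, and the likelihood ratio statistic is
#' `LRS = n * ln(RSS0 / RSS1)` with `RSS0` from the intercept-only model.
#' Lines missing a genotype probability at a position are excluded
#' position-wise, with `n` the per-position complete-case count.  A perfect
#' fit (`RSS1 = 0`) is capped at `n * ln(1e12)` with a warning; a trait with
#' zero variance yields an all-zero profile with a warning.  The peak is the
#' profile maximum, ties broken towards the first chromosome and smallest
#' Mb, and the support interval is the 1.5-LOD drop around it.
#'
#' @param y line means: a `line_trait` from [line_means()] or a named
#'   numeric vector.
#' @param G genotype matrix (lines x markers, 0/1/NA).
#' @param map the [genetic_map()].
#' @param step_cM pseudomarker spacing (default 0: typed markers only).
#' @param lod_divisor see [lrs_to_lod()].
#' @param drop LOD-drop defining the support interval (default 1.5).
#' @param trait,effect_class,day optional labels carried into the result.
#' @return A `qtl_scan` object: the grid with per-position `lrs`, `lod` and
#'   `n`, the peak, `max_lrs`/`max_lod`, and the Mb support interval.
#'   Permutation significance is attached by [permutation_null()].
#' @export
qtl_scan <- function(y, G, map, step_cM = 0, lod_divisor = 4.61, drop = 1.5,
                     trait = NULL, effect_class = NULL, day = NULL) {
  yv <- line_values(y)
  shared <- intersect(names(yv), rownames(G))
  if (length(shared) < 8)
    stop("need at least 8 lines with both phenotype and genotype, have ",
         length(shared))
  yv <- yv[shared]
  grid <- scan_grid(map, step_cM)
  P <- genotype_prob_matrix(G[shared, , drop = FALSE], map, grid)

  if (stats::var(yv) == 0) {
    warning("zero phenotypic variance; LRS profile is identically 0")
    res <- matrix(c(0, length(yv)), nrow = nrow(grid), ncol = 2, byrow = TRUE)
  } else {
    res <- t(vapply(seq_len(nrow(grid)),
                    function(j) lrs_at(yv, P[, j]), numeric(2)))
    if (any(res[, 1] >= max(res[, 2]) * log(LRS_CAP_RATIO) - 1e-6, na.rm = TRUE))
      warning("perfect fit at one or more positions; LRS capped")
  }
  grid$lrs <- res[, 1]
  grid$n <- as.integer(res[, 2])
  grid$lod <- lrs_to_lod(pmax(grid$lrs, 0), lod_divisor)

  peak_i <- which(grid$lrs == max(grid$lrs, na.rm = TRUE))[1]
  sr <- structure(list(trait = trait, effect_class = effect_class, day = day,
                       grid = grid, prob = P, y = yv,
                       peak_index = peak_i, peak_chr = grid$chr[peak_i],
                       peak_cM = grid$cM[peak_i], peak_Mb = grid$Mb[peak_i],
                       peak_marker = grid$marker[peak_i],
                       max_lrs = grid$lrs[peak_i], max_lod = grid$lod[peak_i],
                       lod_divisor = lod_divisor,
                       n_lines = length(yv),
                       threshold = NA_real_, genomewide_p = NA_real_),
                  class = "qtl_scan")
  sr$ci_Mb <- lod_drop_interval(sr, drop = drop)
  sr
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("Genome scan", if (!is.null(x$trait)) paste0("of ", x$trait), "on",
      x$n_lines, "lines\n")
  cat(sprintf("  peak: chr %s @ %.3f Mb, LRS %.3f (LOD %.3f)\n",
              x$peak_chr, x$peak_Mb, x$max_lrs, x$max_lod))
  cat(sprintf("  1.5-LOD interval: %.3f-%.3f Mb\n",
              x$ci_Mb[1], x$ci_Mb[2]))
  if (!is.na(x$genomewide_p))
    cat(sprintf("  genome-wide p = %.4g (threshold LRS %.3f)\n",
                x$genomewide_p, x$threshold))
  invisible(x)
}

#' LOD-drop support interval
#'
#' Walks outward from the scan peak along its chromosome to the first grid
#' positions where the LOD falls below `max_LOD - drop`; the interval
#' endpoints are the Mb positions of the last grid points still within
#' `drop` LOD of the peak, clamped at the chromosome ends.
#'
#' @param sr a `qtl_scan`.
#' @param drop LOD units (default 1.5).
#' @return `c(low, high)` in Mb.
#' @export
lod_drop_interval <- function(sr, drop = 1.5) {
  g <- sr$grid[sr$grid$chr == sr$peak_chr, , drop = FALSE]
  pk <- which(g$cM == sr$peak_cM)[1]
  thr <- sr$max_lod - drop
  ok <- !is.na(g$lod) & g$lod >= thr
  lo <- pk
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- pk
  while (hi < nrow(g) && ok[hi + 1]) hi <- hi + 1
  c(g$Mb[lo], g$Mb[hi])
}

#' Permutation null distribution of the genome-wide maximum LRS
#'
#' Permutes the line labels of the phenotype (genotypes fixed), rescans the
#' genome, and records the maximum LRS of each permuted scan.  The
#' genome-wide significance threshold is the empirical `(1 - alpha)`
#' quantile of these maxima, and the genome-wide p of an observed peak is
#' `(1 + #\{perm max >= observed\}) / (n_perm + 1)` (the add-one estimator;
#' `method = "raw"` gives `#\{>=\} / n_perm`).  Fully deterministic given
#' `seed`.
#'
#' @param y line means (as in [qtl_scan()]).
#' @param G,map,step_cM as in [qtl_scan()].
#' @param n_perm number of permutations (default 5000; fewer than 100 gives
#'   an unstable tail and a warning).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer seed.
#' @param observed optional observed max LRS for which to report a p-value.
#' @param method `"add_one"` (default) or `"raw"`.
#' @return A `permutation_null`: the vector of null maxima, the threshold,
#'   and (if `observed` given) `genomewide_p`.
#' @export
permutation_null <- function(y, G, map, n_perm = 5000, alpha = 0.05,
                             seed = 1, step_cM = 0, observed = NULL,
                             method = c("add_one", "raw")) {
  method <- match.arg(method)
  if (n_perm < 100) warning("fewer than 100 permutations: unstable null tail")
  yv <- line_values(y)
  shared <- intersect(names(yv), rownames(G))
  yv <- yv[shared]
  n <- length(yv)
  grid <- scan_grid(map, step_cM)
  P <- genotype_prob_matrix(G[shared, , drop = FALSE], map, grid)

  null_max <- withr::with_seed(as.integer(seed), {
    perms <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    if (!anyNA(P) && stats::var(yv) > 0) {
      # complete data: one standardized cross-product gives every
      # permutation's whole profile at once
      Xs <- scale(P)
      Xs[, attr(Xs, "scaled:scale") == 0 | is.na(attr(Xs, "scaled:scale"))] <- 0
      Xs[is.na(Xs)] <- 0
      ys <- as.numeric(scale(yv))
      Y <- matrix(ys[perms], nrow = n)
      r2 <- (crossprod(Xs, Y) / (n - 1))^2
      lrs <- -n * log(pmax(1 - r2, 1 / LRS_CAP_RATIO))
      apply(lrs, 2, max)
    } else {
      vapply(seq_len(n_perm), function(k) {
        yp <- stats::setNames(yv[perms[, k]], names(yv))
        max(vapply(seq_len(nrow(grid)),
                   function(j) lrs_at(yp, P[, j])[1], numeric(1)), na.rm = TRUE)
      }, numeric(1))
    }
  })

  out <- structure(list(null_max = null_max, n_perm = n_perm, alpha = alpha,
                        seed = as.integer(seed),
                        threshold = unname(stats::quantile(null_max, 1 - alpha)),
                        method = method),
                   class = "permutation_null")
  if (!is.null(observed))
    out$genomewide_p <- genomewide_p(out, observed)
  out
}

#' @rdname permutation_null
#' @param pn a `permutation_null`.
#' @export
genomewide_p <- function(pn, observed, method = pn$method) {
  k <- sum(pn$null_max >= observed)
  if (identical(method, "raw")) k / pn$n_perm else (1 + k) / (pn$n_perm + 1)
}

#' Point-wise single-marker test
#'
#' Partial F-test p-value for the regression of line means on the 0/1 calls
#' of a single marker (equivalent to the two-group comparison); this is the
#' per-trait p entering the protected FDR step at an established locus.
#'
#' @param y line means (named vector or `line_trait`).
#' @param calls named 0/1 marker calls.
#' @return list with `F`, `p`, `n`; monomorphic markers are flagged with
#'   `p = NA` and a warning.
#' @export
pointwise_p <- function(y, calls) {
  yv <- line_values(y)
  cv <- if (is.null(names(calls))) {
    if (length(calls) != length(yv)) stop("unnamed calls of wrong length")
    stats::setNames(calls, names(yv))
  } else calls
  shared <- intersect(names(yv), names(cv))
  ok <- shared[!is.na(yv[shared]) & !is.na(cv[shared])]
  yv <- yv[ok]; x <- cv[ok]
  n <- length(ok)
  if (length(unique(x)) < 2) {
    warning("monomorphic marker: point-wise test undefined")
    return(list(F = NA_real_, p = NA_real_, n = n))
  }
  if (n < 3) stop("need at least 3 informative lines")
  rss0 <- sum((yv - mean(yv))^2)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (yv - mean(yv))) / sxx
  rss1 <- rss0 - b^2 * sxx
  if (rss0 == 0) return(list(F = 0, p = 1, n = n))
  Fstat <- (rss0 - rss1) / (rss1 / (n - 2))
  if (!is.finite(Fstat)) Fstat <- Inf
  list(F = Fstat, p = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE), n = n)
}

#' Plot a genome scan profile
#'
#' Manhattan-style LRS (or LOD) profile over the whole genome with
#' chromosomes laid end to end; the permutation threshold, if attached, is
#' drawn as a horizontal line.
#'
#' @param x a `qtl_scan`.
#' @param stat `"lrs"` or `"lod"`.
#' @param ... passed to [plot()].
#' @export
plot.qtl_scan <- function(x, stat = c("lrs", "lod"), ...) {
  stat <- match.arg(stat)
  g <- x$grid
  off <- 0; xs <- numeric(nrow(g)); bounds <- numeric(0)
  for (cc in unique(g$chr)) {
    i <- g$chr == cc
    xs[i] <- g$cM[i] + off
    off <- off + max(g$cM[i]) + 10
    bounds <- c(bounds, off - 5)
  }
  plot(xs, g[[stat]], type = "l", xlab = "genome position (cM, chromosomes concatenated)",
       ylab = toupper(stat), ...)
  graphics::abline(v = bounds, col = "grey80", lty = 3)
  if (!is.na(x$threshold)) {
    thr <- if (stat == "lod") lrs_to_lod(x$threshold, x$lod_divisor) else x$threshold
    graphics::abline(h = thr, col = "red", lty = 2)
  }
  invisible(x)
}
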