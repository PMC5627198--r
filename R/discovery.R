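#' Benjamini-Hochberg step-up selection
#'
#' Sorts the p-values ascending and selects all hypotheses with rank at
#' most `k* = max{k : p(k) <= k q / m}`; controls the FDR at `q` under
#' independence or positive dependence.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return Sorted indices (into `pvals`) of the selected hypotheses.
#' @examples
#' bh_select(c(0.001, 0.01, 0.02, 0.8))  # 1 2 3
#' @export
bh_select <- function(pvals, q = 0.05) {
  step_up(pvals, q, cm = 1)
}

#' Benjamini-Yekutieli step-up selection
#'
#' As [bh_select()] but with the harmonic correction
#' `c(m) = sum(1/i, i = 1..m)`, valid under arbitrary dependence; used for
#' the protected follow-up tests at an established locus (default
#' `q = 0.10`).
#'
#' @inheritParams bh_select
#' @export
by_protected <- function(pvals, q = 0.10) {
  m <- length(pvals)
  if (!m) return(integer(0))
  step_up(pvals, q, cm = sum(1 / seq_len(m)))
}

step_up <- function(pvals, q, cm) {
  m <- length(pvals)
  if (!m) return(integer(0))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  o <- order(pvals)
  ok <- pvals[o] <= seq_len(m) * q / (m * cm)
  if (!any(ok)) return(integer(0))
  sort(o[seq_len(max(which(ok)))])
}

#' Group co-located effects into named loci
#'
#' Significant effects on the same chromosome whose Mb confidence intervals
#' mutually overlap (closed intervals: they overlap iff
#' `max(lows) <= min(highs)`, so touching endpoints count) are grouped into
#' one locus.  For one-dimensional intervals, pairwise overlap implies a
#' common point, so the grouping is computed by a sweep that maintains the
#' running intersection of the current group.  Groups containing at least
#' one direct effect become loci named `SocInt<chr>` (a second locus on the
#' same chromosome gets a `.2` suffix, ordered by position); groups with
#' only indirect members are reported separately and are not loci.
#'
#' @param members data frame with one row per significant effect: columns
#'   `role`, `trait`, `day`, `effect_class`, `chr`, `peak_Mb`, `ci_low`,
#'   `ci_high`, `max_lrs`, `max_lod`, `p`, `p_type` (and optionally
#'   validation columns).
#' @return list with `loci` (list of locus reports: `name`, `chr`,
#'   `members`) and `indirect_only` (the same structure for groups without
#'   a direct member).
#' @export
co_locate <- function(members) {
  empty <- list(loci = list(), indirect_only = list())
  if (is.null(members) || !nrow(members)) return(empty)
  need <- c("role", "trait", "day", "effect_class", "chr", "peak_Mb",
            "ci_low", "ci_high")
  miss <- setdiff(need, names(members))
  if (length(miss)) stop("members lack column(s): ", paste(miss, collapse = ", "))

  groups <- list()
  for (cc in unique(members$chr[order(chr_index(members$chr))])) {
    mm <- members[members$chr == cc, , drop = FALSE]
    mm <- mm[order(mm$ci_low, mm$ci_high, mm$peak_Mb), , drop = FALSE]
    cur <- 1L; int_hi <- mm$ci_high[1]
    idx <- list()
    for (i in seq_len(nrow(mm))[-1]) {
      if (mm$ci_low[i] <= int_hi) {        # still intersects the whole group
        cur <- c(cur, i)
        int_hi <- min(int_hi, mm$ci_high[i])
      } else {
        idx[[length(idx) + 1]] <- cur
        cur <- i; int_hi <- mm$ci_high[i]
      }
    }
    idx[[length(idx) + 1]] <- cur
    for (g in idx) groups[[length(groups) + 1]] <- mm[g, , drop = FALSE]
  }

  loci <- list(); indirect_only <- list()
  per_chr_count <- list()
  for (g in groups) {
    g <- g[order(g$effect_class != "direct", g$day,
                 match(g$role, ROLES), g$trait), , drop = FALSE]
    rownames(g) <- NULL
    cc <- g$chr[1]
    if (any(g$effect_class == "direct")) {
      k <- (per_chr_count[[cc]] %||% 0) + 1
      per_chr_count[[cc]] <- k
      name <- if (k == 1) paste0("SocInt", cc) else paste0("SocInt", cc, ".", k)
      loci[[length(loci) + 1]] <- list(name = name, chr = cc, members = g)
    } else {
      indirect_only[[length(indirect_only) + 1]] <-
        list(name = NA_character_, chr = cc, members = g)
    }
  }
  list(loci = loci, indirect_only = indirect_only)
}

#' Assemble the final locus table
#'
#' Merges mapping statistics with the per-member validation statistics
#' (peak-marker R-squared and the allele increasing the trait) into the
#' report layout: loci ordered by chromosome then peak position, members
#' direct-first.
#'
#' @param reports `loci` element from [co_locate()].
#' @param validation data frame keyed by `(role, trait, day, effect_class)`
#'   with columns `R2` and `allele_increasing`.
#' @return data frame with the columns of [write_locus_table()].
#' @export
assemble_locus_table <- function(reports, validation = NULL) {
  if (!length(reports)) return(locus_members_df(list()))
  if (!is.null(validation)) {
    reports <- lapply(reports, function(rep) {
      m <- merge(rep$members, validation,
                 by = c("role", "trait", "day", "effect_class"),
                 all.x = TRUE, sort = FALSE)
      if (any(is.na(m$R2)))
        stop("locus ", rep$name, " has member(s) lacking validation stats")
      rep$members <- m
      rep
    })
  }
  ord <- order(vapply(reports, function(r) chr_index(r$chr), numeric(1)),
               vapply(reports, function(r) min(r$members$peak_Mb), numeric(1)))
  locus_members_df(reports[ord])
}
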