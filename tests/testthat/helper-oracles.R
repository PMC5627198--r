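# Shared fixtures and independent oracles used across test files.

# tiny single-chromosome map
tiny_map <- function(cM = c(0, 10, 20, 30), chr = "1", mb_per_cM = 2) {
  genetic_map(sprintf("t%s_%02d", chr, seq_along(cM)), chr = rep(chr, length(cM)),
              cM = cM, Mb = cM * mb_per_cM)
}

# independent per-marker LRS oracle via lm(): n * ln(RSS0 / RSS1)
lrs_oracle <- function(y, x) {
  ok <- !is.na(x) & !is.na(y)
  y <- y[ok]; x <- x[ok]
  rss0 <- deviance(lm(y ~ 1))
  rss1 <- deviance(lm(y ~ x))
  length(y) * log(rss0 / rss1)
}

# brute-force step-up selection: largest k with p_(k) <= k*q/(m*cm),
# checked by explicit enumeration over all ranks
step_up_oracle <- function(p, q, cm = 1) {
  m <- length(p)
  if (!m) return(integer(0))
  o <- order(p)
  kstar <- 0
  for (k in seq_len(m)) if (p[o][k] <= k * q / (m * cm)) kstar <- k
  if (kstar == 0) integer(0) else sort(o[seq_len(kstar)])
}

# direct sum-of-squares decomposition for one-way ANOVA eta-squared
eta_sq_oracle <- function(values, groups) {
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  sst <- sum((values - gm)^2)
  ssb / sst
}

# exhaustive enumeration of P(D at query | flanking calls) over the
# two-state RI chain: sum over the hidden state g in {B = 0, D = 1}
genotype_prob_oracle <- function(gL, gR, dL_cM, dR_cM) {
  trans <- function(a, b, d) {
    R <- expand_rf(haldane_rf(d))
    if (a == b) 1 - R else R
  }
  w <- vapply(0:1, function(g) 0.5 * trans(gL, g, dL_cM) * trans(g, gR, dR_cM),
              numeric(1))
  w[2] / sum(w)
}

# a family table for one (role, day) stratum with chosen covariate signal
make_stratum <- function(seed, n = 96, value = NULL, trait = "sucking",
                         role = "BXD_offspring", day = 6) {
  withr::with_seed(seed, {
    tbl <- data.frame(
      family_id = paste0("f", seq_len(n)),
      line_id = paste0("L", rep_len(seq_len(32), n)),
      day = day, role = role, trait = trait,
      value = 0,
      maternal_bodyweight = rnorm(n, 32, 3),
      avg_B6_pup_weight = rnorm(n, 6, 0.8),
      B6_litter_size = sample(3:6, n, TRUE),
      avg_BXD_pup_weight = rnorm(n, 6, 0.8),
      BXD_litter_size = sample(3:6, n, TRUE),
      batch = paste0("b", sample(1:4, n, TRUE)),
      stringsAsFactors = FALSE)
    tbl$value <- if (is.null(value)) rnorm(n) else value(tbl)
    tbl
  })
}

# minimal valid locus report for io tests
fake_report <- function(name = "SocInt4", chr = "4",
                        classes = c("direct", "indirect")) {
  members <- data.frame(
    role = ifelse(classes == "direct", "BXD_offspring", "mother"),
    trait = ifelse(classes == "direct", "sucking", "suckling"),
    day = 6, effect_class = classes, chr = chr,
    peak_Mb = 11.3, ci_low = 10.8, ci_high = 13.0,
    max_lrs = c(19.7, 19.5)[seq_along(classes)],
    max_lod = c(4.28, 4.23)[seq_along(classes)],
    p = c(0.044, 0.045)[seq_along(classes)],
    p_type = "genomewide",
    allele_increasing = "B6", R2 = 0.6, stringsAsFactors = FALSE)
  list(name = name, chr = chr, members = members)
}
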