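#' Full direct/indirect QTL discovery pipeline
#'
#' Runs the four analysis stages over a family table and an RI genotype
#' panel:
#'
#' 1. **Covariate adjustment** — per role-trait-day stratum, a Gaussian GLM
#'    on the six litter/maternal covariates with backward elimination at
#'    `alpha_covar`, then residuals averaged per BXD line.
#' 2. **Interval mapping** — a Haley-Knott genome scan of each of the 24
#'    line-mean trait vectors, with genome-wide significance from
#'    permutations of line labels and 1.5-LOD support intervals.
#' 3. **Discovery** — Benjamini-Hochberg selection of genome-wide
#'    permutation p-values across the 24-scan family at `q_genome`; at the
#'    peak marker of each selected scan, protected point-wise tests of the
#'    not-yet-selected indirect traits of the same day, Benjamini-Yekutieli
#'    controlled at `q_protected`; then co-location of all significant
#'    effects into named `SocInt` loci by confidence-interval overlap.
#' 4. **Validation** — per member, peak-marker R-squared and allele
#'    direction at the locus peak; phenotypic correlations between direct
#'    and indirect members; ANOVA broad-sense heritability per stratum.
#'
#' @param pheno a family table ([read_pheno()] / [simulate_families()]).
#' @param G genotype matrix (lines x markers, 0/1/NA).
#' @param map the [genetic_map()].
#' @param n_perm permutations per scan (5000 for production; smaller values
#'   speed up exploratory runs at the cost of threshold stability).
#' @param alpha genome-wide significance level for permutation thresholds.
#' @param q_genome FDR level of the BH step across the scan family.
#' @param q_protected FDR level of the protected BY tests.
#' @param alpha_covar retention threshold of the covariate elimination.
#' @param step_cM pseudomarker spacing for the scans.
#' @param lod_divisor see [lrs_to_lod()].
#' @param seed integer seed; per-scan permutation seeds are derived from it.
#' @return list with `scans` (24 `qtl_scan`s with permutation results),
#'   `scan_summary` (one row per scan), `members` (significant effects),
#'   `loci`/`indirect_only` (from [co_locate()]), `locus_table` (the final
#'   report), `correlations`, `heritability`, and `models` (the covariate
#'   fits).
#' @export
map_social_qtl <- function(pheno, G, map, n_perm = 5000, alpha = 0.05,
                           q_genome = 0.05, q_protected = 0.10,
                           alpha_covar = 0.05, step_cM = 0,
                           lod_divisor = 4.61, seed = 1) {
  pheno <- validate_family_table(as.data.frame(pheno))
  defs <- enumerate_scans(intersect(DAYS, unique(pheno$day)))

  scans <- vector("list", nrow(defs))
  models <- vector("list", nrow(defs))
  lm_list <- vector("list", nrow(defs))
  herit <- vector("list", nrow(defs))
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    sub <- pheno[pheno$role == d$role & pheno$day == d$day &
                   pheno$trait == d$trait, , drop = FALSE]
    mod <- backward_eliminate(sub, trait = d$trait, alpha = alpha_covar)
    adj <- residualize(sub, mod)
    y <- line_means(adj)
    sr <- qtl_scan(y, G, map, step_cM = step_cM, lod_divisor = lod_divisor,
                   trait = d$trait, effect_class = d$effect_class, day = d$day)
    pn <- permutation_null(y, G, map, n_perm = n_perm, alpha = alpha,
                           seed = as.integer(seed) + i, step_cM = step_cM,
                           observed = sr$max_lrs)
    sr$threshold <- pn$threshold
    sr$genomewide_p <- pn$genomewide_p
    sr$role <- d$role
    scans[[i]] <- sr
    models[[i]] <- mod
    lm_list[[i]] <- y
    herit[[i]] <- tryCatch(
      c(heritability_anova(adj)[c("H2", "F", "p", "n_lines")],
        list(role = d$role, trait = d$trait, day = d$day)),
      error = function(e) NULL)
  }

  scan_summary <- data.frame(
    role = defs$role, trait = defs$trait, day = defs$day,
    effect_class = defs$effect_class,
    chr = vapply(scans, function(s) s$peak_chr, character(1)),
    peak_Mb = vapply(scans, function(s) s$peak_Mb, numeric(1)),
    peak_marker = vapply(scans, function(s) s$peak_marker %||% NA_character_,
                         character(1)),
    ci_low = vapply(scans, function(s) s$ci_Mb[1], numeric(1)),
    ci_high = vapply(scans, function(s) s$ci_Mb[2], numeric(1)),
    max_lrs = vapply(scans, function(s) s$max_lrs, numeric(1)),
    max_lod = vapply(scans, function(s) s$max_lod, numeric(1)),
    genomewide_p = vapply(scans, function(s) s$genomewide_p, numeric(1)),
    stringsAsFactors = FALSE)

  # stage 3: BH across the scan family
  selected <- bh_select(scan_summary$genomewide_p, q = q_genome)
  members <- scan_summary[selected, , drop = FALSE]
  if (nrow(members)) {
    members$p <- members$genomewide_p
    members$p_type <- "genomewide"
  }

  # protected BY tests at the peak markers of selected scans
  protected <- list()
  for (si in selected) {
    pk_marker <- scans[[si]]$peak_marker
    if (is.na(pk_marker)) {  # pseudomarker peak: use nearest typed marker
      g <- scans[[si]]$grid
      on_chr <- which(g$chr == scans[[si]]$peak_chr & !is.na(g$marker))
      pk_marker <- g$marker[on_chr[which.min(abs(g$cM[on_chr] - scans[[si]]$peak_cM))]]
    }
    cand <- setdiff(which(defs$effect_class == "indirect" &
                            defs$day == defs$day[si]), selected)
    if (!length(cand)) next
    pvec <- vapply(cand, function(ci) {
      pointwise_p(lm_list[[ci]], G[, pk_marker])$p
    }, numeric(1))
    keep <- !is.na(pvec)
    hits <- cand[keep][by_protected(pvec[keep], q = q_protected)]
    for (hi in hits) {
      sr <- scans[[hi]]
      # locus-conditional statistics: profile restricted to the chromosome
      # of the selecting locus
      cc <- scans[[si]]$peak_chr
      g <- sr$grid[sr$grid$chr == cc, , drop = FALSE]
      pk <- which.max(g$lrs)
      loc <- list(grid = sr$grid, max_lod = g$lod[pk],
                  peak_chr = cc, peak_cM = g$cM[pk])
      ci_mb <- lod_drop_interval(loc, drop = 1.5)
      protected[[length(protected) + 1]] <- data.frame(
        role = defs$role[hi], trait = defs$trait[hi], day = defs$day[hi],
        effect_class = defs$effect_class[hi], chr = cc,
        peak_Mb = g$Mb[pk], peak_marker = g$marker[pk],
        ci_low = ci_mb[1], ci_high = ci_mb[2],
        max_lrs = g$lrs[pk], max_lod = g$lod[pk],
        genomewide_p = sr$genomewide_p,
        p = pvec[match(hi, cand)], p_type = "protected",
        stringsAsFactors = FALSE)
    }
  }
  if (length(protected)) {
    prot <- do.call(rbind, protected)
    # a trait can be picked up from several selected peaks: keep best p
    prot <- prot[order(prot$p), ]
    key <- paste(prot$role, prot$trait, prot$day, prot$chr)
    prot <- prot[!duplicated(key), ]
    members <- rbind(members, prot)
  }

  grouped <- co_locate(members)

  # stage 4: validation stats at each locus's peak marker
  val_rows <- list()
  cors <- list()
  for (rep in grouped$loci) {
    m <- rep$members
    dir_i <- which(m$effect_class == "direct")
    pk_marker <- m$peak_marker[dir_i[which.max(m$max_lrs[dir_i])]]
    calls <- G[, pk_marker]
    for (j in seq_len(nrow(m))) {
      yj <- lm_list[[scan_def_index(defs, m[j, ])]]
      pr <- peak_r2(yj, calls)
      val_rows[[length(val_rows) + 1]] <- data.frame(
        locus = rep$name, role = m$role[j], trait = m$trait[j],
        day = m$day[j], effect_class = m$effect_class[j],
        R2 = pr$R2, allele_increasing = pr$allele_increasing,
        stringsAsFactors = FALSE)
    }
    ind_i <- which(m$effect_class == "indirect")
    for (a in dir_i) for (b in ind_i) if (m$day[a] == m$day[b]) {
      tc <- trait_correlation(lm_list[[scan_def_index(defs, m[a, ])]],
                              lm_list[[scan_def_index(defs, m[b, ])]])
      cors[[length(cors) + 1]] <- data.frame(
        locus = rep$name, day = m$day[a],
        direct_trait = phenotype_label(m$role[a], m$trait[a]),
        indirect_trait = phenotype_label(m$role[b], m$trait[b]),
        r = tc$r, p = tc$p, n = tc$n, stringsAsFactors = FALSE)
    }
  }
  validation <- if (length(val_rows)) do.call(rbind, val_rows) else NULL
  if (!is.null(validation)) {
    grouped$loci <- lapply(grouped$loci, function(rep) {
      rep$members <- merge(rep$members,
                           validation[validation$locus == rep$name,
                                      c("role", "trait", "day", "effect_class",
                                        "R2", "allele_increasing")],
                           by = c("role", "trait", "day", "effect_class"),
                           sort = FALSE)
      rep
    })
  }
  locus_table <- assemble_locus_table(grouped$loci)

  list(scans = scans, scan_summary = scan_summary,
       selected = selected, members = members,
       loci = grouped$loci, indirect_only = grouped$indirect_only,
       locus_table = locus_table,
       correlations = if (length(cors)) do.call(rbind, cors) else NULL,
       heritability = do.call(rbind, lapply(herit, function(h)
         if (is.null(h)) NULL else as.data.frame(h))),
       models = models, line_means = lm_list, defs = defs)
}

scan_def_index <- function(defs, row) {
  which(defs$role == row$role & defs$trait == row$trait & defs$day == row$day)
}
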