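#' Simulate cross-fostered family phenotypes
#'
#' Generates one row per family x day x role x trait.  Each family consists
#' of a B6 foster mother rearing a half-litter of B6 pups and a half-litter
#' of pups from one BXD line.  Trait values follow an additive model:
#' baseline + planted direct effects (BXD rows, own genotype) + planted
#' indirect effects (B6 sibling and mother rows, genotype of the fostered
#' BXD half-litter) + covariate effects + a line-level environmental deviate
#' shared by the replicate families of a line + within-family noise.
#' Genotype is coded 0 for the B and 1 for the D allele at the named marker.
#'
#' @param G genotype matrix from [simulate_ri_genotypes()] (lines x markers,
#'   0/1).
#' @param map the [genetic_map()] the genotypes were simulated on.
#' @param scen a [sim_scenario()].
#' @return A validated family table (see [read_pheno()] for the schema).
#' @export
simulate_families <- function(G, map, scen) {
  validate_scenario(scen, map)
  lines <- rownames(G)[seq_len(min(scen$n_lines, nrow(G)))]
  if (length(lines) < scen$n_lines)
    stop("genotype matrix has fewer lines than the scenario requests")

  withr::with_seed(scen$seed, {
    # replicate families per line; the first always succeeds, later ones
    # fail independently with dropout_prob (breeding failure)
    fam <- do.call(rbind, lapply(lines, function(ln) {
      keep <- c(TRUE, stats::runif(scen$replicates_per_line - 1) >= scen$dropout_prob)
      data.frame(line_id = ln, rep = which(keep), stringsAsFactors = FALSE)
    }))
    fam$family_id <- paste0(fam$line_id, "_f", fam$rep)

    cd <- scen$covariate_dists
    nf <- nrow(fam)
    fam$maternal_bodyweight <- stats::rnorm(nf, cd$maternal_bodyweight["mean"],
                                            cd$maternal_bodyweight["sd"])
    fam$avg_B6_pup_weight <- stats::rnorm(nf, cd$avg_B6_pup_weight["mean"],
                                          cd$avg_B6_pup_weight["sd"])
    fam$avg_BXD_pup_weight <- stats::rnorm(nf, cd$avg_BXD_pup_weight["mean"],
                                           cd$avg_BXD_pup_weight["sd"])
    fam$B6_litter_size <- sample(cd$B6_litter_size, nf, replace = TRUE)
    fam$BXD_litter_size <- sample(cd$BXD_litter_size, nf, replace = TRUE)
    fam$batch <- paste0("b", sample(seq_len(cd$n_batches), nf, replace = TRUE))

    rt <- role_traits()
    cells <- merge(merge(fam, data.frame(day = scen$days), by = NULL),
                   rt, by = NULL)

    # line-level environmental deviate, shared across replicate families of a
    # line but independent per (role, trait, day)
    env_key <- unique(cells[, c("line_id", "role", "trait", "day")])
    env_key$line_env <- stats::rnorm(nrow(env_key), 0, scen$line_env_sd)
    cells <- merge(cells, env_key, by = c("line_id", "role", "trait", "day"))

    value <- unname(scen$trait_baselines[cells$trait]) + cells$line_env
    ce <- scen$covariate_effects
    for (cv in setdiff(COVARIATES, "batch"))
      value <- value + (ce[[cv]] %||% 0) * cells[[cv]]
    if (!is.null(ce$batch)) {
      lev <- as.integer(sub("^b", "", cells$batch))
      value <- value + ce$batch[lev]
    }

    q <- scen$qtl_effects
    if (nrow(q)) for (i in seq_len(nrow(q))) {
      g <- G[cells$line_id, q$marker[i]]
      hit <- cells$role == q$role[i] & cells$trait == q$trait[i] &
        cells$day == q$day[i]
      value <- value + ifelse(hit, q$effect[i] * g, 0)
    }

    value <- value + stats::rnorm(nrow(cells), 0, scen$noise_sd_within_family)
    cells$value <- value

    out <- cells[, c("family_id", "line_id", "day", "role", "trait", "value",
                     "maternal_bodyweight", "avg_B6_pup_weight",
                     "B6_litter_size", "avg_BXD_pup_weight",
                     "BXD_litter_size", "batch")]
    out <- out[order(out$family_id, out$day, match(out$role, ROLES), out$trait), ]
    rownames(out) <- NULL
    class(out) <- c("family_table", "data.frame")
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a self-contained synthetic fixture to disk
#'
#' Simulates genotypes and family phenotypes under a scenario and writes
#' four files into `out_dir`: `genotypes.geno` (GeneNetwork-style dialect),
#' `phenotypes.csv` (the family table), `truth.json` (the planted QTL
#' effects, for recovery checks) and `scenario.yaml`.  Byte-identical across
#' runs with the same scenario.
#'
#' @param scen a [sim_scenario()].
#' @param out_dir output directory (created if needed).
#' @param map marker map; defaults to [default_map()].
#' @return Invisibly, a named list of the four file paths.
#' @export
generate_fixture <- function(scen = sim_scenario(), out_dir, map = default_map()) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  validate_scenario(scen, map)
  G <- simulate_ri_genotypes(map, scen$n_lines, seed = scen$seed)
  tbl <- simulate_families(G, map, scen)
  paths <- list(geno = file.path(out_dir, "genotypes.geno"),
                pheno = file.path(out_dir, "phenotypes.csv"),
                truth = file.path(out_dir, "truth.json"),
                scenario = file.path(out_dir, "scenario.yaml"))
  write_geno(map, G, paths$geno)
  write_pheno(tbl, paths$pheno)
  truth <- if (nrow(scen$qtl_effects)) scen$qtl_effects else list()
  jsonlite::write_json(truth, paths$truth, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  scen_plain <- unclass(scen)
  scen_plain$qtl_effects <- as.list(as.data.frame(scen$qtl_effects))
  yaml::write_yaml(scen_plain, paths$scenario)
  invisible(paths)
}
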