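# Role/trait vocabulary of the split-litter design.  Each family holds one
# B6 foster mother, a B6 half-litter and a BXD half-litter; offspring traits
# are litter-half averages, maternal traits are per-mother.
ROLES <- c("BXD_offspring", "B6_offspring", "mother")
OFFSPRING_TRAITS <- c("solicitation", "sucking", "activity")
MOTHER_TRAITS <- c("suckling", "activity")
DAYS <- c(6, 10, 14)
COVARIATES <- c("maternal_bodyweight", "avg_B6_pup_weight", "B6_litter_size",
                "avg_BXD_pup_weight", "BXD_litter_size", "batch")

role_traits <- function() {
  rbind(
    data.frame(role = "BXD_offspring", trait = OFFSPRING_TRAITS),
    data.frame(role = "B6_offspring", trait = OFFSPRING_TRAITS),
    data.frame(role = "mother", trait = MOTHER_TRAITS)
  )
}

#' Enumerate the scan family of the design
#'
#' One genome scan per role-trait-day combination: three offspring traits
#' measured on each half-litter plus two maternal traits, over the
#' observation days.  Scans of BXD offspring traits test direct genetic
#' effects (own genotype); scans of B6 offspring or maternal traits test
#' indirect effects of the fostered BXD genotype on its social partners.
#' With the default three observation days this is the 24-test family over
#' which genome-wide discoveries are FDR-controlled.
#'
#' @param days observation days (default postpartum days 6, 10, 14).
#' @return data frame with columns `role`, `trait`, `day`, `effect_class`.
#' @examples
#' nrow(enumerate_scans())  # 24
#' @export
enumerate_scans <- function(days = DAYS) {
  rt <- role_traits()
  out <- merge(rt, data.frame(day = days), by = NULL)
  out$effect_class <- ifelse(out$role == "BXD_offspring", "direct", "indirect")
  out <- out[order(out$day, match(out$role, ROLES), match(out$trait, c(OFFSPRING_TRAITS, "suckling"))), ]
  rownames(out) <- NULL
  out
}

#' Define a simulation scenario for the cross-fostered family design
#'
#' Bundles every knob of the synthetic-data generator: panel and replication
#' size, planted QTL effects, covariate distributions and slopes, and noise
#' components.  Defaults emulate the study design the generator is meant to
#' stand in for: 32 BXD lines, three replicate families per line (with a
#' small dropout probability for failed breedings), four behavioural traits
#' over three observation days, and one pleiotropic locus with a direct
#' effect on BXD sucking and indirect effects on B6 sibling and maternal
#' behaviour at day 6.  With the default noise settings
#' (`line_env_sd = 0.29`, `noise_sd_within_family = 0.5`, three replicates)
#' a planted additive effect of 1 trait unit explains about 60% of the
#' line-mean variance, matching the effect sizes the pipeline is expected to
#' recover.
#'
#' @param n_lines number of BXD lines (default 32).
#' @param replicates_per_line replicate families set up per line (default 3).
#' @param dropout_prob probability that a replicate family beyond the first
#'   fails (breeding failure); the first family of each line always succeeds.
#' @param days observation days.
#' @param qtl_effects data frame with columns `marker`, `role`, `trait`,
#'   `day`, `effect_class` ("direct"/"indirect") and `effect` (additive
#'   effect of the D allele in trait units).  Direct effects may only target
#'   BXD offspring traits; indirect effects only B6 offspring or maternal
#'   traits.
#' @param covariate_effects named list of slopes for the continuous
#'   covariates plus `batch`, a vector of per-level effects.
#' @param covariate_dists named list: `c(mean, sd)` for the continuous
#'   covariates, an integer range for the litter sizes, and `n_batches`.
#' @param trait_baselines named numeric: intercept per trait.
#' @param line_env_sd SD of the line-level environmental deviate (shared by
#'   the replicate families of a line, drawn independently per
#'   role-trait-day).
#' @param noise_sd_within_family SD of the residual per-observation noise.
#' @param seed integer seed stored with the scenario.
#' @return A `sim_scenario` object (a named list).
#' @export
sim_scenario <- function(n_lines = 32,
                         replicates_per_line = 3,
                         dropout_prob = 0.1,
                         days = DAYS,
                         qtl_effects = default_qtl_effects(),
                         covariate_effects = list(
                           maternal_bodyweight = 0.03,
                           avg_B6_pup_weight = 0.10,
                           B6_litter_size = 0,
                           avg_BXD_pup_weight = 0.10,
                           BXD_litter_size = 0,
                           batch = c(0, 0.25, -0.25, 0.1)
                         ),
                         covariate_dists = list(
                           maternal_bodyweight = c(mean = 32, sd = 3),
                           avg_B6_pup_weight = c(mean = 6, sd = 0.8),
                           avg_BXD_pup_weight = c(mean = 6, sd = 0.8),
                           B6_litter_size = 3:6,
                           BXD_litter_size = 3:6,
                           n_batches = 4
                         ),
                         trait_baselines = c(solicitation = 4, sucking = 6,
                                             activity = 3, suckling = 7),
                         line_env_sd = 0.29,
                         noise_sd_within_family = 0.5,
                         seed = 1) {
  scen <- list(n_lines = n_lines, replicates_per_line = replicates_per_line,
               dropout_prob = dropout_prob, days = days,
               qtl_effects = qtl_effects,
               covariate_effects = covariate_effects,
               covariate_dists = covariate_dists,
               trait_baselines = trait_baselines,
               line_env_sd = line_env_sd,
               noise_sd_within_family = noise_sd_within_family,
               seed = as.integer(seed))
  class(scen) <- "sim_scenario"
  validate_scenario(scen)
  scen
}

#' @rdname sim_scenario
#' @export
default_qtl_effects <- function() {
  data.frame(
    marker = "m4_040",
    role = c("BXD_offspring", "B6_offspring", "B6_offspring", "mother"),
    trait = c("sucking", "sucking", "activity", "suckling"),
    day = 6,
    effect_class = c("direct", "indirect", "indirect", "indirect"),
    effect = 1.0,
    stringsAsFactors = FALSE
  )
}

validate_scenario <- function(scen, map = NULL) {
  stopifnot(inherits(scen, "sim_scenario"))
  if (scen$n_lines < 1 || scen$replicates_per_line < 1)
    stop("n_lines and replicates_per_line must be >= 1")
  if (scen$dropout_prob < 0 || scen$dropout_prob > 1)
    stop("dropout_prob must be a probability")
  if (scen$line_env_sd < 0 || scen$noise_sd_within_family < 0)
    stop("standard deviations must be non-negative")
  q <- scen$qtl_effects
  if (nrow(q)) {
    bad_class <- !(q$effect_class %in% c("direct", "indirect"))
    if (any(bad_class)) stop("unknown effect class: ", q$effect_class[bad_class][1])
    if (any(q$effect_class == "direct" & q$role != "BXD_offspring"))
      stop("direct effects may only target BXD_offspring traits")
    if (any(q$effect_class == "indirect" & !(q$role %in% c("B6_offspring", "mother"))))
      stop("indirect effects may only target B6_offspring or mother traits")
    ok_trait <- ifelse(q$role == "mother", q$trait %in% MOTHER_TRAITS,
                       q$trait %in% OFFSPRING_TRAITS)
    if (any(!ok_trait))
      stop("invalid role/trait combination in qtl_effects: ",
           paste(q$role[!ok_trait], q$trait[!ok_trait], collapse = "; "))
    if (any(!(q$day %in% scen$days)))
      stop("qtl_effects reference days outside the scenario's days")
    if (!is.null(map) && any(!(q$marker %in% map$marker)))
      stop("qtl_effects name markers absent from the map: ",
           paste(setdiff(q$marker, map$marker), collapse = ", "))
  }
  invisible(scen)
}
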