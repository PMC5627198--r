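#' Backward elimination of litter and maternal covariates
#'
#' Fits a Gaussian least-squares linear model of one trait on the litter and
#' maternal covariates and removes non-significant terms one at a time: at
#' each step every remaining term is tested by a partial F-test
#' (`drop1`; for continuous covariates this is equivalent to the t-test,
#' and `batch` enters and leaves as a whole factor), the single term with
#' the largest p-value above `alpha` is dropped, and the model is refitted.
#' Elimination stops when every remaining term is significant or no terms
#' remain.  Ties in p are broken by removing the term that appears later in
#' the declared covariate order, so the procedure is deterministic.
#'
#' @param tbl a family table, already restricted to one (role, day) stratum;
#'   if `trait` is given, rows are further filtered to that trait.
#' @param trait optional trait name to filter on.
#' @param covariates candidate covariates, a subset of the six design
#'   covariates (default all six).
#' @param alpha retention threshold on the per-term p-value (default 0.05).
#' @return An object of class `covar_model`: the final fit, the retained
#'   terms, an ordered removal log, per-term summaries, and the row indices
#'   used (rows with missing covariates are excluded and recorded).
#' @export
backward_eliminate <- function(tbl, trait = NULL, covariates = COVARIATES,
                               alpha = 0.05) {
  bad <- setdiff(covariates, COVARIATES)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  dat <- as.data.frame(tbl)
  if (!is.null(trait)) dat <- dat[dat$trait == trait, , drop = FALSE]
  if ("batch" %in% covariates) dat$batch <- factor(dat$batch)

  cc <- stats::complete.cases(dat[, c("value", covariates), drop = FALSE])
  excluded <- which(!cc)
  dat <- dat[cc, , drop = FALSE]

  # degrees of freedom guard: batch contributes (levels - 1) terms
  n_terms <- sum(covariates != "batch") +
    if ("batch" %in% covariates) max(nlevels(dat$batch) - 1, 0) else 0
  if (nrow(dat) < n_terms + 3)
    stop("too few rows (", nrow(dat), ") for ", n_terms, " model terms")

  terms_now <- covariates
  log_steps <- list()
  repeat {
    fit <- fit_covar_lm(dat, terms_now)
    if (length(terms_now) && any(is.na(stats::coef(fit)))) {
      alias_terms <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design; collinear term(s): ",
           paste(unique(alias_terms), collapse = ", "))
    }
    pvals <- term_pvalues(fit, terms_now)
    drop_cand <- terms_now[!is.na(pvals) & pvals > alpha]
    if (!length(drop_cand)) break
    pmax_val <- max(pvals[terms_now %in% drop_cand])
    at_max <- terms_now[!is.na(pvals) & pvals >= pmax_val - 1e-15 &
                          terms_now %in% drop_cand]
    # tie-break: later term in the declared covariate order goes first
    victim <- at_max[which.max(match(at_max, covariates))]
    log_steps[[length(log_steps) + 1]] <-
      data.frame(step = length(log_steps) + 1, term = victim,
                 p = unname(pvals[victim]), stringsAsFactors = FALSE)
    terms_now <- setdiff(terms_now, victim)
  }

  final_p <- term_pvalues(fit, terms_now)
  coefs <- stats::coef(fit)
  structure(list(trait = trait, retained = terms_now,
                 removed = if (length(log_steps)) do.call(rbind, log_steps)
                           else data.frame(step = integer(), term = character(),
                                           p = numeric()),
                 coefficients = coefs, term_p = final_p, alpha = alpha,
                 covariate_order = covariates, fit = fit,
                 rows_used = which(cc), rows_excluded = excluded),
            class = "covar_model")
}

fit_covar_lm <- function(dat, terms_now) {
  fml <- if (length(terms_now))
    stats::reformulate(terms_now, response = "value")
  else value ~ 1
  stats::lm(fml, data = dat)
}

# per-term p-values by partial F (drop1); factors tested as a whole
term_pvalues <- function(fit, terms_now) {
  if (!length(terms_now)) return(stats::setNames(numeric(0), character(0)))
  d1 <- stats::drop1(fit, test = "F")
  p <- d1[["Pr(>F)"]]
  names(p) <- rownames(d1)
  p <- p[terms_now]
  names(p) <- terms_now
  # a term that explains nothing testable (e.g. zero residual variance)
  # carries no evidence for retention
  p[is.na(p)] <- 1
  p
}

#' Residualize a trait on its retained covariates
#'
#' Scores the final model from [backward_eliminate()] on the same rows:
#' `residual = observed - fitted`.  If no covariate survived elimination the
#' residual is the trait centred on its grand mean.  Rows with missing
#' covariate values are excluded and reported via the `rows_excluded`
#' attribute.
#'
#' @param tbl the family table the model was built on (same filtering rules).
#' @param model a `covar_model`.
#' @return the filtered rows with an added `residual` column, class
#'   `adjusted_trait`; attributes `retained` and `rows_excluded`.
#' @export
residualize <- function(tbl, model) {
  stopifnot(inherits(model, "covar_model"))
  dat <- as.data.frame(tbl)
  if (!is.null(model$trait)) dat <- dat[dat$trait == model$trait, , drop = FALSE]
  if ("batch" %in% model$covariate_order) dat$batch <- factor(dat$batch)
  cc <- stats::complete.cases(dat[, c("value", model$covariate_order), drop = FALSE])
  dat <- dat[cc, , drop = FALSE]
  dat$residual <- if (length(model$retained))
    dat$value - as.numeric(stats::fitted(model$fit))
  else dat$value - mean(dat$value)
  structure(dat, class = c("adjusted_trait", "data.frame"),
            retained = model$retained, rows_excluded = which(!cc))
}

#' Average adjusted residuals per line
#'
#' The mapping unit is the BXD line: residuals of the replicate families
#' fostering a given line are averaged, for BXD traits (direct scans) and
#' for B6 sibling / maternal traits (indirect scans) alike, since each
#' family carries exactly one BXD line.
#'
#' @param adj an `adjusted_trait` (or any data frame with `line_id` and
#'   `residual` columns).
#' @return data frame `line_id`, `value` (mean residual), `n` (replicates),
#'   class `line_trait`.
#' @export
line_means <- function(adj) {
  if (!all(c("line_id", "residual") %in% names(adj)))
    stop("need columns line_id and residual")
  ok <- !is.na(adj$residual)
  if (!all(ok)) warning(sum(!ok), " rows with missing residuals omitted")
  adj <- adj[ok, , drop = FALSE]
  sp <- split(adj$residual, adj$line_id)
  sp <- sp[lengths(sp) > 0]
  out <- data.frame(line_id = names(sp),
                    value = vapply(sp, mean, numeric(1)),
                    n = lengths(sp), stringsAsFactors = FALSE)
  out <- out[order(out$line_id), ]
  rownames(out) <- NULL
  class(out) <- c("line_trait", "data.frame")
  out
}

# named numeric vector view of a line_trait (or pass-through)
line_values <- function(y) {
  if (is.data.frame(y)) stats::setNames(y$value, y$line_id)
  else if (!is.null(names(y))) y
  else stop("line trait values must carry line ids as names")
}
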