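#' Fit models across all replicate datasets
#'
#' Runs each requested model on every (dataset, tree) pair of a replicate set,
#' computing the tree's covariance matrix and (when needed) node counts per
#' replicate. Every fit gets its own deterministically derived seed; failures
#' are recorded per replicate rather than aborting the run.
#'
#' @param replicates a `replicate_set` from [build_replicates()], or any list
#'   of `list(data =, tree =)` pairs.
#' @param models character vector of model names (see [pglmm_model()]).
#' @param priors,control shared [pglmm_priors()] / [mcmc_control()]; the
#'   control's seed acts as the master seed for all fits.
#' @param rescale_cov passed to [phylo_cov()].
#' @return an object of class `pglmm_runs`: per model, a list of per-replicate
#'   records (each either a `summary.pglmm_fit` or an error message), plus
#'   per-replicate species ages and counts used by [aggregate_fits()].
#' @export
run_models <- function(replicates, models = "M1", priors = pglmm_priors(),
                       control = mcmc_control(), rescale_cov = TRUE) {
  if (length(replicates) == 0L) stop("no replicates supplied")
  meta <- lapply(replicates, function(r) {
    list(
      counts = table(r$data$species),
      age_q95 = tapply(r$data$age_ma, r$data$species, stats::quantile,
                       probs = 0.95, names = FALSE),
      age_mean = tapply(r$data$age_ma, r$data$species, mean)
    )
  })
  out <- list()
  for (mi in seq_along(models)) {
    mname <- models[mi]
    model <- pglmm_model(mname)
    fits <- vector("list", length(replicates))
    for (k in seq_along(replicates)) {
      rep_k <- replicates[[k]]
      seed_k <- replicate_seed(control$seed * 131L + mi, k)
      ctl <- control
      ctl$seed <- seed_k
      fits[[k]] <- tryCatch({
        cv <- phylo_cov(rep_k$tree, rescale = rescale_cov)
        nc <- if ("log10_nc" %in% model$fixed) node_counts(rep_k$tree) else NULL
        s <- summary(fit_pglmm(rep_k$data, cv, model = model, priors = priors,
                               control = ctl, node_counts = nc))
        s$ok <- TRUE
        s
      }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    }
    out[[mname]] <- fits
  }
  structure(list(models = out, meta = meta, control = control,
                 priors = priors),
            class = "pglmm_runs")
}

#' @export
print.pglmm_runs <- function(x, ...) {
  for (m in names(x$models)) {
    ok <- sum(vapply(x$models[[m]], `[[`, TRUE, "ok"))
    cat("Model ", m, ": ", ok, "/", length(x$models[[m]]),
        " replicate fits succeeded\n", sep = "")
  }
  invisible(x)
}

#' Replicate-wise significance rule
#'
#' An effect is declared significant when its pMCMC value is at or below
#' `alpha` in at least `proportion` of the replicate analyses; the boundary is
#' inclusive on both comparisons (a fraction exactly equal to `proportion`
#' counts as significant).
#'
#' @param pmcmc_values numeric vector of per-replicate pMCMC values for one
#'   term (failed replicates excluded by the caller).
#' @param alpha per-replicate significance level (default 0.05).
#' @param proportion required fraction of replicates (default 0.95).
#' @return a list with `fraction` (share of replicates passing `alpha`) and
#'   `significant` (logical call).
#' @export
significance_call <- function(pmcmc_values, alpha = 0.05, proportion = 0.95) {
  if (length(pmcmc_values) == 0L) stop("no replicate pMCMC values")
  fraction <- mean(pmcmc_values <= alpha)
  list(fraction = fraction, significant = fraction >= proportion)
}

#' Correlation between species slopes and species age
#'
#' Pearson correlation between the per-species within-time slope (by default
#' its magnitude, i.e. the rate of increase toward the present) and a
#' representative species age. With `direction = "time"` the age axis is
#' negated so that a pattern of faster within-species increase in more recent
#' species yields a positive correlation; `direction = "age"` correlates with
#' age in Ma directly.
#'
#' @param slopes named numeric vector of per-species slopes (age-axis sign).
#' @param ages named numeric vector of representative ages in Ma (same
#'   species).
#' @param exclude optional species name(s) to drop before computing r.
#' @param magnitude use `abs(slope)` (default TRUE).
#' @param direction `"time"` (default; positive r = acceleration toward the
#'   present) or `"age"`.
#' @return the Pearson correlation coefficient.
#' @export
slope_age_correlation <- function(slopes, ages, exclude = NULL,
                                  magnitude = TRUE,
                                  direction = c("time", "age")) {
  direction <- match.arg(direction)
  common <- intersect(names(slopes), names(ages))
  common <- setdiff(common, exclude)
  if (length(common) < 3L) stop("need at least 3 species after exclusion")
  s <- slopes[common]
  a <- ages[common]
  if (magnitude) s <- abs(s)
  if (direction == "time") a <- -a
  if (stats::sd(s) == 0 || stats::sd(a) == 0)
    stop("zero variance in slopes or ages")
  stats::cor(s, a)
}

#' Aggregate replicate fits
#'
#' Applies the replicate-wise significance rule to every fixed term, averages
#' the model-level statistics (heritability, marginal/conditional R2, DIC)
#' across replicates, summarizes the per-species within-time slopes
#' (across-replicate mean and 95% quantile band), and computes the
#' slope-age correlation over well-sampled species.
#'
#' @param runs a `pglmm_runs` from [run_models()].
#' @param model which fitted model to aggregate (default: the first).
#' @param alpha,proportion the significance rule (see [significance_call()]).
#' @param min_specimens species with a mean replicate sample size at or below
#'   this value are excluded from the slope-age correlation (default 10);
#'   they still contribute to every fit.
#' @param age_stat representative species age: `"q95"` (the 95% quantile of
#'   the sampled specimen ages, averaged over replicates; default) or
#'   `"mean"`.
#' @param exclude_species optional species excluded from a second slope-age
#'   correlation, reported alongside the full one.
#' @param magnitude,direction passed to [slope_age_correlation()].
#' @return an object of class `pglmm_aggregate` with elements `terms` (per
#'   fixed term: significance fraction and call), `h2`, `r2_marginal`,
#'   `r2_conditional`, `dic` (grand means), `slopes` (per-species summary),
#'   `slope_age_r`, `slope_age_r_excluded`, `n_ok`, `n_failed`.
#' @export
aggregate_fits <- function(runs, model = NULL, alpha = 0.05,
                           proportion = 0.95, min_specimens = 10,
                           age_stat = c("q95", "mean"),
                           exclude_species = NULL, magnitude = TRUE,
                           direction = "time") {
  stopifnot(inherits(runs, "pglmm_runs"))
  age_stat <- match.arg(age_stat)
  model <- model %||% names(runs$models)[1]
  fits <- runs$models[[model]]
  if (is.null(fits)) stop("model not present in runs: ", model)
  ok <- vapply(fits, `[[`, TRUE, "ok")
  if (!any(ok)) stop("all replicate fits failed for model ", model)
  if (mean(!ok) > 0.05)
    warning(sprintf("%.0f%% of replicate fits failed", 100 * mean(!ok)))
  good <- fits[ok]

  terms <- good[[1]]$fixed$term
  pm <- vapply(good, function(s) s$fixed$pmcmc[match(terms, s$fixed$term)],
               numeric(length(terms)))
  pm <- matrix(pm, nrow = length(terms),
               dimnames = list(terms, NULL))
  calls <- lapply(terms, function(tr)
    significance_call(pm[tr, ], alpha = alpha, proportion = proportion))
  term_tab <- data.frame(
    term = terms,
    fraction = vapply(calls, `[[`, 0, "fraction"),
    significant = vapply(calls, `[[`, TRUE, "significant"),
    mean_estimate = rowMeans(vapply(good, function(s)
      s$fixed$mean[match(terms, s$fixed$term)], numeric(length(terms)))),
    stringsAsFactors = FALSE
  )

  grand <- function(field) mean(vapply(good, `[[`, 0, field))

  slopes_tab <- NULL
  r_full <- r_excl <- NA_real_
  if (!is.null(good[[1]]$slopes)) {
    # species can drop out of single replicates under taxonomic randomization
    sp <- sort(unique(unlist(lapply(good, function(s) s$slopes$species))))
    sl <- vapply(good, function(s)
      s$slopes$slope[match(sp, s$slopes$species)], numeric(length(sp)))
    sl <- matrix(sl, nrow = length(sp), dimnames = list(sp, NULL))
    slopes_tab <- data.frame(
      species = sp,
      mean = rowMeans(sl, na.rm = TRUE),
      q025 = apply(sl, 1, stats::quantile, 0.025, na.rm = TRUE),
      q975 = apply(sl, 1, stats::quantile, 0.975, na.rm = TRUE),
      n_replicates = rowSums(!is.na(sl)),
      stringsAsFactors = FALSE
    )
    meta_ok <- runs$meta[ok]
    ages <- rowMeans(vapply(meta_ok, function(m) {
      v <- if (age_stat == "q95") m$age_q95 else m$age_mean
      as.numeric(v[sp])
    }, numeric(length(sp))), na.rm = TRUE)
    names(ages) <- sp
    counts <- rowMeans(vapply(meta_ok, function(m)
      as.numeric(m$counts[sp]), numeric(length(sp))), na.rm = TRUE)
    use <- sp[!is.na(counts) & counts > min_specimens]
    slopes_use <- stats::setNames(slopes_tab$mean, sp)[use]
    if (length(use) >= 3L) {
      r_full <- tryCatch(
        slope_age_correlation(slopes_use, ages[use], magnitude = magnitude,
                              direction = direction),
        error = function(e) NA_real_)
      if (!is.null(exclude_species))
        r_excl <- tryCatch(
          slope_age_correlation(slopes_use, ages[use],
                                exclude = exclude_species,
                                magnitude = magnitude, direction = direction),
          error = function(e) NA_real_)
    }
  }

  structure(list(
    model = model, terms = term_tab, h2 = grand("h2"),
    r2_marginal = grand("r2_marginal"),
    r2_conditional = grand("r2_conditional"), dic = grand("dic"),
    slopes = slopes_tab, slope_age_r = r_full, slope_age_r_excluded = r_excl,
    n_ok = sum(ok), n_failed = sum(!ok), alpha = alpha,
    proportion = proportion
  ), class = "pglmm_aggregate")
}

#' @export
print.pglmm_aggregate <- function(x, digits = 3, ...) {
  cat("Aggregate over ", x$n_ok, " replicate fits of model ", x$model,
      if (x$n_failed) sprintf(" (%d failed)", x$n_failed), "\n\n", sep = "")
  tab <- x$terms
  tab$fraction <- round(tab$fraction, digits)
  tab$mean_estimate <- round(tab$mean_estimate, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\ngrand means: h2 = %.3f, marginal R2 = %.3f, conditional R2 = %.3f, DIC = %.2f\n",
              x$h2, x$r2_marginal, x$r2_conditional, x$dic))
  if (!is.na(x$slope_age_r))
    cat(sprintf("slope-age Pearson r = %.3f%s\n", x$slope_age_r,
                if (!is.na(x$slope_age_r_excluded))
                  sprintf(" (excluding: %.3f)", x$slope_age_r_excluded)
                else ""))
  invisible(x)
}

#' Write an aggregate report to JSON and CSV
#'
#' @param agg a `pglmm_aggregate`.
#' @param path_prefix files `<prefix>.json` and `<prefix>_terms.csv` (plus
#'   `<prefix>_slopes.csv` when slopes are present) are written.
#' @return the JSON path, invisibly.
#' @export
write_aggregate <- function(agg, path_prefix) {
  stopifnot(inherits(agg, "pglmm_aggregate"))
  utils::write.csv(agg$terms, paste0(path_prefix, "_terms.csv"),
                   row.names = FALSE)
  if (!is.null(agg$slopes))
    utils::write.csv(agg$slopes, paste0(path_prefix, "_slopes.csv"),
                     row.names = FALSE)
  out <- agg[c("model", "h2", "r2_marginal", "r2_conditional", "dic",
               "slope_age_r", "slope_age_r_excluded", "n_ok", "n_failed")]
  json <- paste0(path_prefix, ".json")
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA)
  invisible(json)
}
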