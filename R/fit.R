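#' Fit a within-group-centered Bayesian phylogenetic mixed model
#'
#' Fits a Gaussian mixed model for log10 cranial capacity with
#' within-group-centered predictors and a phylogenetically structured species
#' effect, by a blocked conjugate Gibbs sampler: each iteration draws all
#' location effects (fixed plus random) jointly from the mixed-model-equations
#' full conditional given the current variances, then each variance component
#' (including the residual) from its inverse-gamma full conditional. The
#' phylogenetic block uses the inverse of the shared-path covariance `A`
#' (rescaled to mean tip depth 1 by [phylo_cov()]); species
#' intercept/slope blocks have independent diagonal variances.
#'
#' @param data replicate data.frame (`species`, `age_ma`, `log10_cc`,
#'   `log10_bm`), e.g. one element of [build_replicates()].
#' @param cov a `phylo_cov` from [phylo_cov()].
#' @param model a `pglmm_model` or a preset name such as `"M1"`.
#' @param priors a `pglmm_priors`.
#' @param control an `mcmc_control`; its `seed` fully determines the chain.
#' @param node_counts [node_counts()] output; required for node-count models.
#' @param update_variances set FALSE to hold the variance components fixed at
#'   `start_variances` and sample only the location effects (useful for
#'   validating against the closed-form GLS estimator).
#' @param start_variances optional named list/vector of starting values: one
#'   per random term plus `"residual"`.
#' @return an object of class `pglmm_fit` with posterior draws of the fixed
#'   effects (`$beta`), random effects (`$re`, one matrix per block), variance
#'   components (`$sigma2`), and the per-draw conditional deviance, plus the
#'   design bookkeeping. Use [summary.pglmm_fit()], [pmcmc()], [dic()],
#'   [heritability()], [r2_components()], [species_within_slopes()].
#' @examples
#' \donttest{
#' sc <- scenario_config(n_species = 6, n_specimens = 60, seed = 2)
#' sim <- simulate_dataset(sc)
#' cv <- phylo_cov(sim$tree)
#' fit <- fit_pglmm(sim$data_model, cv, model = "M1",
#'                  control = mcmc_control(iterations = 4000, burn_in = 1000,
#'                                         thinning = 5, seed = 1))
#' summary(fit)
#' }
#' @export
fit_pglmm <- function(data, cov, model = "M1", priors = pglmm_priors(),
                      control = mcmc_control(), node_counts = NULL,
                      update_variances = TRUE, start_variances = NULL) {
  if (is.character(model)) model <- pglmm_model(model)
  stopifnot(inherits(priors, "pglmm_priors"), inherits(control, "mcmc_control"))
  des <- build_design(data, cov, model, node_counts = node_counts)

  B <- length(des$blocks)
  phylo_block <- match("phylo", names(des$blocks), nomatch = 0L)
  Ainv <- diag(1)
  jitter_used <- FALSE
  if (phylo_block > 0L) {
    Ainv <- tryCatch(chol2inv(chol(des$A)), error = function(e) NULL)
    if (is.null(Ainv)) {            # singular covariance: jitter the diagonal
      jitter_used <- TRUE
      Ainv <- chol2inv(chol(des$A + diag(1e-10 * mean(diag(des$A)),
                                         nrow(des$A))))
    }
  }

  vy <- stats::var(des$y)
  s2_start <- rep(vy / (B + 1), B)
  resid_start <- vy / (B + 1)
  if (!is.null(start_variances)) {
    sv <- unlist(start_variances)
    for (i in seq_len(B)) {
      nm <- names(des$blocks)[i]
      if (nm %in% names(sv)) s2_start[i] <- sv[[nm]]
    }
    if ("residual" %in% names(sv)) resid_start <- sv[["residual"]]
  }

  set.seed(control$seed)
  t0 <- proc.time()[["elapsed"]]
  raw <- gibbs_mixed_cpp(
    y = des$y, W = des$W, p_fixed = ncol(des$X),
    block_start = vapply(des$blocks, `[[`, 1L, "start"),
    block_size = vapply(des$blocks, `[[`, 1L, "size"),
    phylo_block = phylo_block, Ainv = Ainv,
    fixed_prec = 1 / priors$fixed_variance,
    pr_shape = priors$variance_shape, pr_scale = priors$variance_scale,
    iterations = control$iterations, burn_in = control$burn_in,
    thin = control$thinning, update_variances = update_variances,
    var_start = if (B > 0) s2_start else numeric(0),
    resid_start = resid_start
  )
  elapsed <- proc.time()[["elapsed"]] - t0

  p <- ncol(des$X)
  beta <- raw$theta[, seq_len(p), drop = FALSE]
  colnames(beta) <- colnames(des$X)
  re <- list()
  for (nm in names(des$blocks)) {
    b <- des$blocks[[nm]]
    re[[nm]] <- raw$theta[, b$start:(b$start + b$size - 1L), drop = FALSE]
    colnames(re[[nm]]) <- b$labels
  }
  sigma2 <- raw$sigma2
  colnames(sigma2) <- c(names(des$blocks), "residual")

  structure(list(
    beta = beta, re = re, sigma2 = sigma2, deviance = raw$deviance,
    design = des, model = des$model, priors = priors, control = control,
    update_variances = update_variances, jitter_used = jitter_used,
    elapsed = elapsed, call = match.call()
  ), class = "pglmm_fit")
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat("Bayesian phylogenetic mixed model (", x$model$name, "), ",
      nrow(x$beta), " retained draws, n = ", x$design$n, ", ",
      length(x$design$species), " species\n", sep = "")
  cat("Posterior mean fixed effects:\n")
  print(round(colMeans(x$beta), 4))
  cat("Posterior mean variance components:\n")
  print(round(colMeans(x$sigma2), 5))
  invisible(x)
}

#' @export
coef.pglmm_fit <- function(object, ...) colMeans(object$beta)

#' @export
fitted.pglmm_fit <- function(object, ...) {
  theta <- c(colMeans(object$beta),
             unlist(lapply(object$re, colMeans), use.names = FALSE))
  drop(object$design$W %*% theta)
}

#' @export
residuals.pglmm_fit <- function(object, ...) {
  object$design$y - fitted(object)
}

#' Predicted values from a fitted model
#'
#' @param object a `pglmm_fit`.
#' @param level `"conditional"` (fixed + random effects at their posterior
#'   means) or `"marginal"` (fixed effects only).
#' @param ... unused.
#' @return numeric vector of predictions, one per specimen.
#' @export
predict.pglmm_fit <- function(object, level = c("conditional", "marginal"),
                              ...) {
  level <- match.arg(level)
  if (level == "conditional") return(fitted(object))
  drop(object$design$X %*% colMeans(object$beta))
}

#' Posterior-predictive simulation
#'
#' Draws new response vectors from the posterior predictive distribution:
#' for each simulation one retained draw is selected and
#' `y* = W theta + N(0, sigma2_e)` is generated at that draw.
#'
#' @param object a `pglmm_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return a data.frame with `nsim` columns, one row per specimen.
#' @export
simulate.pglmm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nkeep <- nrow(object$beta)
  idx <- sample.int(nkeep, nsim, replace = TRUE)
  p <- ncol(object$beta)
  out <- vapply(idx, function(d) {
    theta <- c(object$beta[d, ], unlist(lapply(object$re, function(m) m[d, ]),
                                        use.names = FALSE))
    mu <- drop(object$design$W %*% theta)
    mu + stats::rnorm(length(mu), 0,
                      sqrt(object$sigma2[d, "residual"]))
  }, numeric(object$design$n))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Trace plots of a fitted model
#'
#' @param x a `pglmm_fit`.
#' @param which `"fixed"` or `"variances"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pglmm_fit <- function(x, which = c("fixed", "variances"), ...) {
  which <- match.arg(which)
  m <- if (which == "fixed") x$beta else x$sigma2
  old <- graphics::par(mfrow = c(ceiling(ncol(m) / 2), 2),
                       mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (j in seq_len(ncol(m)))
    graphics::plot(m[, j], type = "l", xlab = "", ylab = colnames(m)[j], ...)
  invisible(x)
}

#' Summarize a fitted model
#'
#' Produces the per-term posterior summary (mean, 95\% HPD interval, pMCMC,
#' effective sample size) together with the model-level statistics:
#' phylogenetic heritability, marginal and conditional R2, and DIC. Fits in
#' which any fixed-effect ESS falls below `ess_warn` are flagged.
#'
#' @param object a `pglmm_fit`.
#' @param prob HPD probability (default 0.95).
#' @param ess_warn flag threshold for effective sample sizes (default 200).
#' @param ... unused.
#' @return an object of class `summary.pglmm_fit` (a list with elements
#'   `fixed` - a data.frame - plus `h2`, `r2_marginal`, `r2_conditional`,
#'   `dic`, `slopes`, `low_ess`).
#' @export
summary.pglmm_fit <- function(object, prob = 0.95, ess_warn = 200, ...) {
  beta <- object$beta
  fixed <- data.frame(
    term = colnames(beta),
    mean = colMeans(beta),
    lower = apply(beta, 2, function(v) hpd_interval(v, prob)[1]),
    upper = apply(beta, 2, function(v) hpd_interval(v, prob)[2]),
    pmcmc = apply(beta, 2, pmcmc),
    ess = apply(beta, 2, ess),
    row.names = NULL, stringsAsFactors = FALSE
  )
  h2 <- if ("phylo" %in% names(object$re)) heritability(object)$mean else NA_real_
  r2 <- r2_components(object)
  slopes <- if ("species_time_slope" %in% names(object$re))
    species_within_slopes(object) else NULL
  structure(list(
    model = object$model$name, n = object$design$n,
    n_species = length(object$design$species), draws = nrow(beta),
    fixed = fixed, h2 = h2, r2_marginal = r2$marginal,
    r2_conditional = r2$conditional, dic = dic(object), slopes = slopes,
    variances = colMeans(object$sigma2),
    low_ess = any(fixed$ess < ess_warn), elapsed = object$elapsed
  ), class = "summary.pglmm_fit")
}

#' @export
print.summary.pglmm_fit <- function(x, digits = 4, ...) {
  cat("Model ", x$model, ": n = ", x$n, ", ", x$n_species, " species, ",
      x$draws, " draws\n\nFixed effects:\n", sep = "")
  tab <- x$fixed
  tab[, -1] <- lapply(tab[, -1], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nh2 = %.3f   marginal R2 = %.3f   conditional R2 = %.3f   DIC = %.2f\n",
              x$h2, x$r2_marginal, x$r2_conditional, x$dic))
  if (x$low_ess)
    cat("warning: some effective sample sizes are low; lengthen the chain\n")
  invisible(x)
}
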