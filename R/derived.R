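#' MCMC significance value of a coefficient
#'
#' Twice the smaller of the posterior probabilities that the coefficient is
#' positive or negative, the MCMC analogue of a two-sided p-value. Draws
#' exactly equal to zero are split evenly between the two sides, and the
#' result is floored at `2/N` (with N retained draws a chain can never
#' demonstrate a probability below `1/N`), so pMCMC is never exactly zero.
#'
#' @param x either a numeric vector of posterior draws or a `pglmm_fit` (then
#'   `term` selects the coefficient).
#' @param term fixed-effect name when `x` is a fit.
#' @return the pMCMC value in `[2/N, 1]`.
#' @examples
#' pmcmc(c(-1, 1, -2, 2))      # symmetric: 1
#' pmcmc(rep(1, 1000))         # one-sided floor: 0.002
#' @export
pmcmc <- function(x, term = NULL) {
  if (inherits(x, "pglmm_fit")) {
    if (is.null(term)) stop("supply a term name")
    if (!term %in% colnames(x$beta)) stop("unknown term: ", term)
    x <- x$beta[, term]
  }
  n <- length(x)
  if (n == 0L) stop("empty chain")
  zero_half <- mean(x == 0) / 2
  p_pos <- mean(x > 0) + zero_half
  p_neg <- mean(x < 0) + zero_half
  max(2 * min(p_pos, p_neg), 2 / n)
}

#' Deviance information criterion
#'
#' Spiegelhalter's DIC with the Gaussian likelihood conditional on the
#' location effects: `DIC = 2 * mean(D) - D(posterior means)`, where the
#' plug-in deviance is evaluated at the posterior means of all location
#' effects and of the residual variance. For a single retained draw this
#' collapses to that draw's deviance.
#'
#' @param fit a `pglmm_fit`.
#' @return the DIC value.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "pglmm_fit"))
  dbar <- mean(fit$deviance)
  theta <- c(colMeans(fit$beta),
             unlist(lapply(fit$re, colMeans), use.names = FALSE))
  s2e <- mean(fit$sigma2[, "residual"])
  e <- fit$design$y - drop(fit$design$W %*% theta)
  dhat <- fit$design$n * log(2 * pi * s2e) + sum(e^2) / s2e
  2 * dbar - dhat
}

#' Phylogenetic heritability
#'
#' The fraction of variance attributable to the phylogenetically structured
#' species effect, per retained draw:
#' `h2 = sigma2_phylo / (sigma2_phylo + sigma2_species_intercept + sigma2_e)`.
#' Random-slope variances do not enter because they contribute nothing at the
#' reference covariate value zero (the species mean, after centering). The
#' quantity is Lynch's heritability adapted to the mixed model; it is well
#' defined for non-ultrametric trees because [phylo_cov()] rescales the
#' shared-path matrix to mean tip depth 1, putting `sigma2_phylo` on the same
#' scale as the other components.
#'
#' @param fit a `pglmm_fit` whose model includes the phylogenetic effect.
#' @return a list with per-draw values (`draws`) and the posterior `mean`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "pglmm_fit"))
  if (!"phylo" %in% colnames(fit$sigma2))
    stop("model has no phylogenetic random effect")
  s2a <- fit$sigma2[, "phylo"]
  s2b <- if ("species_intercept" %in% colnames(fit$sigma2))
    fit$sigma2[, "species_intercept"] else 0
  s2e <- fit$sigma2[, "residual"]
  tot <- s2a + s2b + s2e
  draws <- ifelse(tot > 0, s2a / tot, 0)
  list(draws = draws, mean = mean(draws))
}

#' Marginal and conditional R-squared
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed plus
#' random effects (conditional), in the Nakagawa-Schielzeth sense, computed
#' per retained draw and averaged. The fixed-effect variance is the sample
#' variance of the linear predictor `X beta` at that draw; each random
#' block contributes its variance times a design weight (1 for intercept-like
#' blocks, the mean squared within-species covariate for slope blocks, the
#' mean diagonal of the phylogenetic covariance over specimens for the
#' phylogenetic block).
#'
#' @param fit a `pglmm_fit`.
#' @return a list with `marginal`, `conditional` (posterior means) and the
#'   per-draw vectors `marginal_draws`, `conditional_draws`.
#' @export
r2_components <- function(fit) {
  stopifnot(inherits(fit, "pglmm_fit"))
  Xb <- fit$design$X %*% t(fit$beta)             # n x draws
  var_fixed <- apply(Xb, 2, stats::var)
  w <- vapply(fit$design$blocks, `[[`, 0, "r2_weight")
  var_rand <- if (length(w))
    as.vector(fit$sigma2[, names(w), drop = FALSE] %*% w) else 0
  s2e <- fit$sigma2[, "residual"]
  tot <- var_fixed + var_rand + s2e
  if (any(tot <= 0)) stop("zero total variance")
  marg <- var_fixed / tot
  cond <- (var_fixed + var_rand) / tot
  list(marginal = mean(marg), conditional = mean(cond),
       marginal_draws = marg, conditional_draws = cond)
}

#' Per-species within-time slopes
#'
#' Posterior mean of the species-level slope of log10 cranial capacity on
#' within-species time: the fixed within-time coefficient plus each species'
#' random slope deviation. Slopes are in log10-units per Myr on the age (Ma)
#' axis, so a species whose cranial capacity grows toward the present has a
#' negative slope; `flip_sign = TRUE` reports the slope "through time"
#' (positive = increase toward the present) for display.
#'
#' @param fit a `pglmm_fit` whose model includes the species time-slope
#'   random effect.
#' @param flip_sign report positive-through-time slopes (default FALSE).
#' @return a data.frame with columns `species` and `slope`.
#' @export
species_within_slopes <- function(fit, flip_sign = FALSE) {
  stopifnot(inherits(fit, "pglmm_fit"))
  if (!"species_time_slope" %in% names(fit$re))
    stop("model has no species time-slope random effect")
  fixed <- fit$beta[, "time_within"]
  dev <- fit$re[["species_time_slope"]]
  slope <- colMeans(fixed + dev)                  # recycles fixed per column
  if (flip_sign) slope <- -slope
  data.frame(species = colnames(dev), slope = unname(slope),
             stringsAsFactors = FALSE)
}

#' Shortest (highest posterior density) credible interval
#'
#' @param x numeric vector of posterior draws.
#' @param prob interval probability (default 0.95).
#' @return length-2 numeric vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  n <- length(x)
  if (n < 2L) return(c(x[1], x[1]))
  xs <- sort(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(xs[1], xs[n]))
  width <- xs[(m + 1):n] - xs[seq_len(n - m)]
  i <- which.min(width)
  c(xs[i], xs[i + m])
}

#' Effective sample size of a chain
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence
#' estimator: autocorrelations are summed in adjacent pairs until a pair sum
#' turns negative.
#'
#' @param x numeric vector of posterior draws.
#' @return effective sample size (at most `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE,
                   demean = TRUE)$acf[-1]
  s <- 0
  k <- 1L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  min(n, max(1, n / (1 + 2 * s)))
}
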