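FIXED_TERMS <- c("bm_between", "bm_within", "time_between", "time_within",
                 "time_between:time_within", "log10_nc", "log10_bm", "age_ma")
RANDOM_TERMS <- c("phylo", "species_intercept", "species_time_slope",
                  "species_bm_slope")

#' Model specifications for the within/between analysis
#'
#' The response is always log10 cranial capacity. The canonical models are:
#' \describe{
#'   \item{M1}{four centered main effects (between/within body mass and time),
#'     phylogenetic species effect, and species-specific random slopes for
#'     within-species time.}
#'   \item{M2}{M1 plus species-specific random slopes for within-species body
#'     mass.}
#'   \item{M3}{M1 plus the log10 root-to-tip node count, a speciation-rate
#'     proxy contrasting cladogenetic with anagenetic change.}
#'   \item{M3-notime}{node-count model without the time effects (body-mass
#'     terms + log10 node count; phylogenetic effect), used to check that node
#'     count stays non-significant when it does not compete with the time
#'     terms.}
#'   \item{M4}{the four main effects plus the between x within time
#'     interaction (accelerating-trend test); phylogenetic effect only.}
#'   \item{PGLS-naive}{the conflated model: uncentered specimen-level log10
#'     body mass and age with a phylogenetic effect - the standard PGLS-style
#'     regression that mixes within- and between-species effects, provided for
#'     contrast.}
#' }
#'
#' @param name one of `"M1"`, `"M2"`, `"M3"`, `"M3-notime"`, `"M4"`,
#'   `"PGLS-naive"`, or `"custom"` (then supply `fixed`/`random`).
#' @param fixed,random character vectors of term labels for custom models.
#'   Fixed terms among `bm_between`, `bm_within`, `time_between`,
#'   `time_within`, `time_between:time_within`, `log10_nc` (centered models)
#'   or `log10_bm`, `age_ma` (uncentered); the intercept is always included.
#'   Random terms among `phylo`, `species_intercept`, `species_time_slope`,
#'   `species_bm_slope`.
#' @param species_intercept add an iid species random intercept alongside the
#'   phylogenetic intercept (default FALSE: the phylogenetic effect is the
#'   species-level intercept, and at fossil-clade sample sizes a second,
#'   unstructured species intercept is only weakly identified against it and
#'   soaks up phylogenetic variance; see the methods vignette).
#' @return an object of class `pglmm_model`.
#' @export
pglmm_model <- function(name = c("M1", "M2", "M3", "M3-notime", "M4",
                                 "PGLS-naive", "custom"),
                        fixed = NULL, random = NULL,
                        species_intercept = FALSE) {
  name <- match.arg(name)
  main4 <- c("bm_between", "bm_within", "time_between", "time_within")
  spec <- switch(name,
    "M1" = list(fixed = main4,
                random = c("phylo", "species_intercept", "species_time_slope"),
                centered = TRUE),
    "M2" = list(fixed = main4,
                random = c("phylo", "species_intercept", "species_time_slope",
                           "species_bm_slope"),
                centered = TRUE),
    "M3" = list(fixed = c(main4, "log10_nc"),
                random = c("phylo", "species_intercept", "species_time_slope"),
                centered = TRUE),
    "M3-notime" = list(fixed = c("bm_between", "bm_within", "log10_nc"),
                       random = c("phylo", "species_intercept"),
                       centered = TRUE),
    "M4" = list(fixed = c(main4, "time_between:time_within"),
                random = "phylo", centered = TRUE),
    "PGLS-naive" = list(fixed = c("log10_bm", "age_ma"),
                        random = "phylo", centered = FALSE),
    "custom" = list(fixed = fixed, random = random, centered = TRUE)
  )
  if (!species_intercept)
    spec$random <- setdiff(spec$random, "species_intercept")
  if (is.null(spec$fixed)) stop("custom model needs fixed terms")
  bad <- setdiff(spec$fixed, FIXED_TERMS)
  if (length(bad)) stop("unknown fixed term(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(spec$random, RANDOM_TERMS)
  if (length(bad)) stop("unknown random term(s): ", paste(bad, collapse = ", "))
  if ("time_between:time_within" %in% spec$fixed &&
      !all(c("time_between", "time_within") %in% spec$fixed))
    stop("the interaction requires both time main effects")
  structure(c(spec, list(name = name)), class = "pglmm_model")
}

#' @export
print.pglmm_model <- function(x, ...) {
  cat("Model", x$name, "\n  fixed : (Intercept) +",
      paste(x$fixed, collapse = " + "),
      "\n  random:", paste(x$random, collapse = " + "),
      if (!x$centered) "\n  (uncentered specimen-level predictors)", "\n")
  invisible(x)
}

#' Prior specification for the Bayesian mixed model
#'
#' Diffuse normal priors on the fixed effects and inverse-gamma priors on
#' every variance component including the residual.
#'
#' @param fixed_mean,fixed_variance normal prior for each fixed effect
#'   (defaults 0 and 1e8).
#' @param variance_shape,variance_scale inverse-gamma shape and scale for each
#'   variance component (defaults 0.01, 0.01).
#' @return a list of class `pglmm_priors`.
#' @export
pglmm_priors <- function(fixed_mean = 0, fixed_variance = 1e8,
                         variance_shape = 0.01, variance_scale = 0.01) {
  stopifnot(fixed_variance > 0, variance_shape > 0, variance_scale > 0)
  if (fixed_mean != 0)
    stop("only zero-centred fixed-effect priors are supported")
  structure(list(fixed_mean = fixed_mean, fixed_variance = fixed_variance,
                 variance_shape = variance_shape,
                 variance_scale = variance_scale),
            class = "pglmm_priors")
}

#' MCMC settings
#'
#' The `"paper"` preset (1,000,000 iterations, 10,000 burn-in, thinning 500)
#' matches full-scale runs; the `"desk"` preset (50,000 / 5,000 / 10) is sized
#' for interactive work and testing. Retained draw count is
#' `floor((iterations - burn_in) / thinning)`.
#'
#' @param preset `"desk"` or `"paper"`; individual values override the preset.
#' @param iterations,burn_in,thinning,seed MCMC controls.
#' @return a list of class `mcmc_control`.
#' @export
mcmc_control <- function(preset = c("desk", "paper"), iterations = NULL,
                         burn_in = NULL, thinning = NULL, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") c(1e6, 1e4, 500) else c(5e4, 5e3, 10)
  iterations <- as.integer(iterations %||% def[1])
  burn_in <- as.integer(burn_in %||% def[2])
  thinning <- as.integer(thinning %||% def[3])
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thinning < 1L) stop("thinning must be >= 1")
  structure(list(iterations = iterations, burn_in = burn_in,
                 thinning = thinning, seed = as.integer(seed)),
            class = "mcmc_control")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build design matrices for a replicate dataset
#'
#' Assembles the response (log10 cranial capacity), the fixed-effect matrix
#' from within-group-centered predictors (or raw predictors for the
#' uncentered model), and the random-effect incidence matrices: the
#' phylogenetic effect maps each specimen to its species' tip, and random
#' slopes multiply the incidence by the within-species covariate. Species
#' means are computed from the replicate at hand, so centering reflects that
#' replicate's resampled ages.
#'
#' @param data a replicate data.frame with columns `species`, `age_ma`,
#'   `log10_cc`, `log10_bm`.
#' @param cov a `phylo_cov` whose labels include every species in `data`.
#' @param model a `pglmm_model`.
#' @param node_counts data.frame from [node_counts()]; required when the model
#'   includes `log10_nc`.
#' @return a list with `y`, `X`, the stacked design `W`, block descriptors,
#'   and bookkeeping used by the derived statistics.
#' @export
build_design <- function(data, cov, model, node_counts = NULL) {
  stopifnot(inherits(cov, "phylo_cov"), inherits(model, "pglmm_model"))
  need <- c("species", "age_ma", "log10_cc", "log10_bm")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(unique(data$species), cov$labels)
  if (length(absent))
    stop("species missing from covariance: ", paste(absent, collapse = ", "))
  if (!all(is.finite(data$log10_cc)) || !all(is.finite(data$log10_bm)))
    stop("non-finite trait values")

  sp_levels <- cov$labels[cov$labels %in% unique(data$species)]
  A <- cov$V[sp_levels, sp_levels, drop = FALSE]
  spf <- factor(data$species, levels = sp_levels)
  n <- nrow(data)

  bm <- within_group_center(data$log10_bm, data$species)
  tm <- within_group_center(data$age_ma, data$species)
  cols <- list(
    "bm_between" = bm$between, "bm_within" = bm$within,
    "time_between" = tm$between, "time_within" = tm$within,
    "time_between:time_within" = tm$between * tm$within,
    "log10_bm" = data$log10_bm, "age_ma" = data$age_ma
  )
  if ("log10_nc" %in% model$fixed) {
    if (is.null(node_counts)) stop("model needs node_counts")
    idx <- match(data$species, node_counts$species)
    if (anyNA(idx)) stop("node counts missing for some species")
    cols$log10_nc <- node_counts$log10_count[idx]
  }
  X <- do.call(cbind, c(list(rep(1, n)), cols[model$fixed]))
  colnames(X) <- c("(Intercept)", model$fixed)
  if (qr(X)$rank < ncol(X)) warning("fixed-effect matrix is rank deficient")

  inc <- stats::model.matrix(~ 0 + spf)
  colnames(inc) <- sp_levels
  blocks <- list()
  for (term in model$random) {
    Z <- switch(term,
      "phylo" = inc,
      "species_intercept" = inc,
      "species_time_slope" = inc * tm$within,
      "species_bm_slope" = inc * bm$within
    )
    # r2 weight: per-row variance multiplier of this block at the current draw
    w <- switch(term,
      "phylo" = mean(diag(A)[as.integer(spf)]),
      "species_intercept" = 1,
      "species_time_slope" = mean(tm$within^2),
      "species_bm_slope" = mean(bm$within^2)
    )
    blocks[[term]] <- list(term = term, Z = Z, size = ncol(Z),
                           type = if (term == "phylo") "phylo" else "iid",
                           r2_weight = w, labels = sp_levels)
  }
  W <- do.call(cbind, c(list(X), lapply(blocks, `[[`, "Z")))
  start <- ncol(X) + c(0, cumsum(vapply(blocks, `[[`, 0, "size")))
  for (i in seq_along(blocks)) blocks[[i]]$start <- as.integer(start[i] + 1L)

  list(y = data$log10_cc, X = X, W = W, blocks = blocks, A = A,
       species = sp_levels, species_index = as.integer(spf),
       model = model, data = data, n = n)
}
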