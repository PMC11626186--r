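make_small_sim <- function(seed, n_species = 6, n = 60, ...) {
  sim <- simulate_dataset(scenario_config(n_species = n_species,
                                          n_specimens = n, seed = seed, ...))
  list(sim = sim, cov = phylo_cov(sim$tree))
}

test_that("design matrices follow the model definitions", {
  s <- make_small_sim(1)
  d1 <- build_design(s$sim$data_model, s$cov, pglmm_model("M1"))
  expect_equal(colnames(d1$X),
               c("(Intercept)", "bm_between", "bm_within",
                 "time_between", "time_within"))
  expect_equal(names(d1$blocks), c("phylo", "species_time_slope"))

  d4 <- build_design(s$sim$data_model, s$cov, pglmm_model("M4"))
  expect_equal(ncol(d4$X), 6)
  expect_equal(d4$X[, "time_between:time_within"],
               d4$X[, "time_between"] * d4$X[, "time_within"])
  expect_equal(names(d4$blocks), "phylo")

  nc <- node_counts(s$sim$tree)
  d3 <- build_design(s$sim$data_model, s$cov, pglmm_model("M3"),
                     node_counts = nc)
  expect_true("log10_nc" %in% colnames(d3$X))
  expect_error(build_design(s$sim$data_model, s$cov, pglmm_model("M3")),
               "node_counts")

  bad <- s$sim$data_model
  bad$species[1] <- "not_a_tip"
  expect_error(build_design(bad, s$cov, pglmm_model("M1")), "missing")
  expect_error(pglmm_model("custom", fixed = "time_between:time_within"),
               "interaction")
})

test_that("retention arithmetic and seeding are exact", {
  s <- make_small_sim(2)
  ctl <- mcmc_control(iterations = 5030, burn_in = 1000, thinning = 7,
                      seed = 4)
  f1 <- fit_pglmm(s$sim$data_model, s$cov, "M1", control = ctl)
  expect_equal(nrow(f1$beta), floor((5030 - 1000) / 7))
  f2 <- fit_pglmm(s$sim$data_model, s$cov, "M1", control = ctl)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2, f2$sigma2)
  f3 <- fit_pglmm(s$sim$data_model, s$cov, "M1",
                  control = mcmc_control(iterations = 5030, burn_in = 1000,
                                         thinning = 7, seed = 5))
  expect_false(identical(f1$beta, f3$beta))
})

test_that("the intercept-only posterior matches the conjugate closed form", {
  set.seed(12)
  n <- 100
  sigma2 <- 0.04
  y <- rnorm(n, 2.7, sqrt(sigma2))
  tr <- simulate_tree(4, 5, seed = 1)
  d <- data.frame(specimen_id = as.character(1:n),
                  species = rep(tr$tip.label, length.out = n),
                  age_ma = 0, log10_cc = y, log10_bm = 0, bm_imputed = FALSE)
  m <- pglmm_model("custom", fixed = character(0), random = character(0))
  f <- fit_pglmm(d, phylo_cov(tr), m, update_variances = FALSE,
                 start_variances = list(residual = sigma2),
                 control = quick_ctl(3, iterations = 30000, burn_in = 1000,
                                     thinning = 2))
  # mu | y ~ N(m*, v*) with prior N(0, 1e8)
  v_star <- 1 / (n / sigma2 + 1e-8)
  m_star <- v_star * sum(y) / sigma2
  draws <- f$beta[, 1]
  mcse <- sd(draws) / sqrt(ess(draws))
  expect_lt(abs(mean(draws) - m_star), 3 * mcse)
  expect_equal(sd(draws), sqrt(v_star), tolerance = 0.05)
})

test_that("with variances fixed the Gibbs means match the GLS closed form", {
  # per design, the root-mean-square standardized discrepancy across
  # coefficients must sit within 2 Monte-Carlo standard errors
  rms_max <- 0
  for (seed in 1:5) {
    s <- make_small_sim(seed + 20)
    des <- build_design(s$sim$data_model, s$cov, pglmm_model("M1"))
    sv <- list(phylo = 0.0225, species_time_slope = 1.2e-3,
               residual = 2.5e-3)
    f <- fit_pglmm(s$sim$data_model, s$cov, "M1", update_variances = FALSE,
                   start_variances = sv,
                   control = quick_ctl(seed, iterations = 96000,
                                       burn_in = 2000, thinning = 4))
    V <- sv$phylo * des$blocks$phylo$Z %*% des$A %*% t(des$blocks$phylo$Z) +
      sv$species_time_slope * tcrossprod(des$blocks$species_time_slope$Z) +
      sv$residual * diag(des$n)
    Vi <- solve(V)
    bhat <- drop(solve(t(des$X) %*% Vi %*% des$X, t(des$X) %*% Vi %*% des$y))
    mcse <- apply(f$beta, 2, function(v) sd(v) / sqrt(ess(v)))
    z <- (colMeans(f$beta) - bhat) / mcse
    rms_max <- max(rms_max, sqrt(mean(z^2)))
  }
  expect_lt(rms_max, 2)
})

test_that("pMCMC follows its definition including the floor", {
  expect_equal(pmcmc(c(-1, 1, -2, 2)), 1)
  expect_equal(pmcmc(rep(1, 1000)), 0.002)
  expect_equal(pmcmc(c(rep(1, 975), rep(-1, 25))), 0.05)
  expect_equal(pmcmc(c(0, 0, 1, -1)), 1)      # zeros split evenly
  expect_equal(pmcmc(c(rep(1, 9), 0)), 0.2)   # floor 2/N dominates 2*0.05
  expect_error(pmcmc(numeric(0)), "empty")
  s <- make_small_sim(3)
  f <- fit_pglmm(s$sim$data_model, s$cov, "M1", control = quick_ctl(1))
  expect_equal(pmcmc(f, "time_within"), pmcmc(f$beta[, "time_within"]))
  expect_error(pmcmc(f, "nope"), "unknown")
})

test_that("DIC collapses for a single draw and is seed-stable", {
  s <- make_small_sim(4)
  f1 <- fit_pglmm(s$sim$data_model, s$cov, "M1",
                  control = mcmc_control(iterations = 501, burn_in = 500,
                                         thinning = 1, seed = 1))
  expect_equal(nrow(f1$beta), 1)
  expect_equal(dic(f1), f1$deviance[1], tolerance = 1e-10)

  fa <- fit_pglmm(s$sim$data_model, s$cov, "M1",
                  control = quick_ctl(11, iterations = 20000, burn_in = 4000))
  fb <- fit_pglmm(s$sim$data_model, s$cov, "M1",
                  control = quick_ctl(12, iterations = 20000, burn_in = 4000))
  expect_lt(abs(dic(fa) - dic(fb)), 2)
})

test_that("DIC prefers the model containing the true covariate", {
  # strong within-time trend; null model omits the time terms entirely
  wins <- 0
  for (i in 1:20) {
    sim <- simulate_dataset(scenario_config(time_scenario = "B",
                                            n_species = 6, n_specimens = 60,
                                            bm_missing = 0, seed = 400 + i))
    cv <- phylo_cov(sim$tree)
    full <- fit_pglmm(sim$data_model, cv,
                      pglmm_model("custom",
                                  fixed = c("bm_between", "time_within"),
                                  random = "phylo"),
                      control = quick_ctl(i, iterations = 4000))
    null <- fit_pglmm(sim$data_model, cv,
                      pglmm_model("custom", fixed = "bm_between",
                                  random = "phylo"),
                      control = quick_ctl(i, iterations = 4000))
    wins <- wins + (dic(full) < dic(null))
  }
  expect_gte(wins, 19)
})

test_that("heritability draws hit the boundary cases", {
  fake <- structure(list(sigma2 = cbind(phylo = c(1, 0),
                                        species_time_slope = c(0, 2),
                                        residual = c(0, 0))),
                    class = "pglmm_fit")
  h <- heritability(fake)
  expect_equal(h$draws, c(1, 0))   # slope variance never enters
  fake2 <- structure(list(sigma2 = cbind(phylo = 1, species_intercept = 1,
                                         residual = 2)),
                     class = "pglmm_fit")
  expect_equal(heritability(fake2)$mean, 0.25)
  fake3 <- structure(list(sigma2 = cbind(residual = 1)), class = "pglmm_fit")
  expect_error(heritability(fake3), "phylogenetic")
})

test_that("R2 components respect their limiting cases", {
  s <- make_small_sim(5)
  # no random effects: conditional equals marginal
  m0 <- pglmm_model("custom", fixed = c("bm_between", "time_within"),
                    random = character(0))
  f0 <- fit_pglmm(s$sim$data_model, s$cov, m0, control = quick_ctl(2))
  r0 <- r2_components(f0)
  expect_equal(r0$marginal, r0$conditional)
  # intercept-only fixed part: marginal ~ 0
  mi <- pglmm_model("custom", fixed = character(0), random = "phylo")
  fi <- fit_pglmm(s$sim$data_model, s$cov, mi, control = quick_ctl(2))
  expect_lt(r2_components(fi)$marginal, 1e-10)
  expect_gt(r2_components(fi)$conditional, 0)
  # full model: marginal <= conditional <= 1
  f1 <- fit_pglmm(s$sim$data_model, s$cov, "M1", control = quick_ctl(2))
  r1 <- r2_components(f1)
  expect_lte(r1$marginal, r1$conditional)
  expect_lte(r1$conditional, 1)
})

test_that("species slopes combine fixed and random parts", {
  s <- make_small_sim(6)
  f <- fit_pglmm(s$sim$data_model, s$cov, "M1", control = quick_ctl(3))
  sl <- species_within_slopes(f)
  expect_setequal(sl$species, s$cov$labels)
  manual <- mean(f$beta[, "time_within"]) +
    colMeans(f$re$species_time_slope)[sl$species]
  expect_equal(sl$slope, unname(manual))
  expect_equal(species_within_slopes(f, flip_sign = TRUE)$slope, -sl$slope)

  f4 <- fit_pglmm(s$sim$data_model, s$cov, "M4", control = quick_ctl(3))
  expect_error(species_within_slopes(f4), "random")

  # zero slope variance: all species slopes equal the fixed coefficient
  fake <- structure(list(
    beta = cbind("(Intercept)" = rnorm(50), time_within = rnorm(50, -0.1)),
    re = list(species_time_slope = matrix(0, 50, 3,
                                          dimnames = list(NULL, c("a", "b", "c"))))
  ), class = "pglmm_fit")
  sf <- species_within_slopes(fake)
  expect_true(all(sf$slope == mean(fake$beta[, "time_within"])))
})

test_that("HPD intervals are shortest and contain the posterior mean", {
  set.seed(13)
  x <- rexp(4000)                  # skewed: shortest interval hugs zero
  h <- hpd_interval(x, 0.95)
  expect_lt(h[1], 0.05)
  q <- quantile(x, c(0.025, 0.975))
  expect_lt(h[2] - h[1], unname(q[2] - q[1]))
  expect_true(h[1] <= mean(x) && mean(x) <= h[2])
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.95 - 1e-9)
})

test_that("h2 and R2 are invariant to rescaling the time axis", {
  s <- make_small_sim(7, n_species = 8, n = 80)
  ctl <- quick_ctl(5, iterations = 20000, burn_in = 4000)
  f1 <- fit_pglmm(s$sim$data_model, s$cov, "M1", control = ctl)
  d2 <- s$sim$data_model
  d2$age_ma <- d2$age_ma * 0.5
  f2 <- fit_pglmm(d2, s$cov, "M1", control = ctl)
  expect_equal(heritability(f1)$mean, heritability(f2)$mean, tolerance = 0.05)
  r1 <- r2_components(f1); r2 <- r2_components(f2)
  expect_equal(r1$marginal, r2$marginal, tolerance = 0.05)
  expect_equal(r1$conditional, r2$conditional, tolerance = 0.05)
  # slopes rescale by the inverse factor (approximately: the inverse-gamma
  # prior sets an absolute variance scale, so the correspondence is not exact)
  expect_equal(mean(f1$beta[, "time_within"]),
               0.5 * mean(f2$beta[, "time_within"]), tolerance = 0.1)
})

test_that("the conflated (uncentered) model mixes within and between effects", {
  # opposing trends: cc rises within species but falls between species; the
  # centered model recovers both levels, while the conflated model's single
  # time coefficient cannot represent the between-species trend at all
  sim <- simulate_dataset(scenario_config(
    n_species = 8, n_specimens = 120, bm_missing = 0,
    beta_time_between = 0.3, beta_time_within = -0.12,
    sigma2_slope = 0, seed = 9))
  cv <- phylo_cov(sim$tree)
  ctl <- quick_ctl(4, iterations = 20000, burn_in = 4000)
  cen <- fit_pglmm(sim$data_model, cv, "M1", control = ctl)
  con <- fit_pglmm(sim$data_model, cv, "PGLS-naive", control = ctl)
  tw <- mean(cen$beta[, "time_within"])
  tb <- mean(cen$beta[, "time_between"])
  conflated <- mean(con$beta[, "age_ma"])
  expect_lt(abs(tw - (-0.12)), 0.04)           # centered model is faithful
  expect_lt(abs(tb - 0.3), 0.15)
  expect_gt(abs(conflated - tb), 0.2)          # the single coefficient misses
  expect_true(sign(conflated) != sign(tb))     # the between-species trend

  # identical within and between slopes: the two models agree
  sim2 <- simulate_dataset(scenario_config(
    n_species = 8, n_specimens = 120, bm_missing = 0, h2 = 0,
    beta_time_between = -0.12, beta_time_within = -0.12,
    sigma2_slope = 0, seed = 10))
  cv2 <- phylo_cov(sim2$tree)
  cen2 <- fit_pglmm(sim2$data_model, cv2, "M1", control = ctl)
  con2 <- fit_pglmm(sim2$data_model, cv2, "PGLS-naive", control = ctl)
  expect_equal(mean(con2$beta[, "age_ma"]),
               mean(cen2$beta[, "time_within"]), tolerance = 0.03)

  # intercept-only: centered and uncentered machinery coincide
  mi <- pglmm_model("custom", fixed = character(0), random = "phylo")
  fa <- fit_pglmm(sim$data_model, cv, mi, control = quick_ctl(6))
  expect_equal(colnames(fa$beta), "(Intercept)")
})

test_that("summary and methods expose a coherent fit object", {
  s <- make_small_sim(8)
  f <- fit_pglmm(s$sim$data_model, s$cov, "M1", control = quick_ctl(7))
  sm <- summary(f)
  expect_s3_class(sm, "summary.pglmm_fit")
  expect_true(all(c("term", "mean", "lower", "upper", "pmcmc", "ess") %in%
                    names(sm$fixed)))
  expect_true(all(sm$fixed$lower <= sm$fixed$mean &
                    sm$fixed$mean <= sm$fixed$upper))
  expect_true(sm$h2 >= 0 && sm$h2 <= 1)
  expect_lte(sm$r2_marginal, sm$r2_conditional)
  expect_equal(coef(f), colMeans(f$beta))
  expect_equal(residuals(f), s$sim$data_model$log10_cc - fitted(f))
  expect_length(predict(f, "marginal"), nrow(s$sim$data_model))
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(s$sim$data_model), 2))
  expect_output(print(f), "phylogenetic mixed model")
  expect_output(print(sm), "Fixed effects")
})
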