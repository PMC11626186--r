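test_that("age sampling respects bounds and the uniform law", {
  expect_equal(sample_age(1.8, 1.8), 1.8)
  set.seed(1)
  draws <- sample_age(0.5, 0.7, n = 1000)
  expect_true(all(draws >= 0.5 & draws <= 0.7))
  draws <- sample_age(1, 3, n = 10000)
  se <- sqrt((3 - 1)^2 / 12 / 10000)
  expect_lt(abs(mean(draws) - 2), 3 * se)
  expect_error(sample_age(2, 1.5), "inverted")
})

test_that("species assignment is uniform over candidates", {
  expect_equal(assign_species("only"), "only")
  set.seed(2)
  draws <- replicate(10000, assign_species(c("X", "Y")))
  p <- mean(draws == "X")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(assign_species(character(0)), "candidate")
})

test_that("small-pool imputation draws uniformly from the observed range", {
  pool <- data.frame(bm_kg = 50, rock_unit = "Calabrian", realm = "Afrotropical")
  attr(pool, "n") <- 1
  out <- impute_body_mass(pool)
  expect_equal(out$bm_kg, 50)
  expect_true(out$imputed)

  pool2 <- data.frame(bm_kg = c(30, 60), rock_unit = NA, realm = NA)
  attr(pool2, "n") <- 2
  set.seed(3)
  draws <- replicate(10000, impute_body_mass(pool2)$bm_kg)
  expect_true(all(draws >= 30 & draws <= 60))
  ks <- stats::ks.test(draws, "punif", 30, 60)
  expect_gt(ks$p.value, 0.001)
  # resample mode returns observed values only
  set.seed(4)
  rs <- replicate(200, impute_body_mass(pool2, mode = "resample")$bm_kg)
  expect_true(all(rs %in% c(30, 60)))
})

test_that("large-pool imputation stratifies by rock unit and realm", {
  set.seed(5)
  pool <- data.frame(
    bm_kg = 1:30,
    rock_unit = rep(c("Calabrian", "Gelasian", "Chibanian"), each = 10),
    realm = rep(c("Afrotropical", "Palearctic"), 15)
  )
  attr(pool, "n") <- 30
  target <- which(pool$rock_unit == "Calabrian" & pool$realm == "Afrotropical")
  draws <- replicate(1000, {
    o <- impute_body_mass(pool, rock_unit = "Calabrian", realm = "Afrotropical")
    expect_equal(o$fallback, 0)
    o$bm_kg
  })
  expect_true(all(draws %in% pool$bm_kg[target]))

  # ladder: empty exact stratum -> same unit any realm -> same realm -> pool
  o <- impute_body_mass(pool, rock_unit = "Calabrian", realm = "Indomalayan")
  expect_equal(o$fallback, 1)
  expect_true(o$bm_kg %in% pool$bm_kg[pool$rock_unit == "Calabrian"])
  o <- impute_body_mass(pool, rock_unit = "Zanclean", realm = "Palearctic")
  expect_equal(o$fallback, 2)
  expect_true(o$bm_kg %in% pool$bm_kg[pool$realm == "Palearctic"])
  o <- impute_body_mass(pool, rock_unit = "Zanclean", realm = "Indomalayan")
  expect_equal(o$fallback, 3)
  expect_error(impute_body_mass(pool[0, ]), "empty")
})

test_that("ages map onto the stage table at the boundaries", {
  tab <- default_rock_units()
  expect_equal(age_to_rock_unit(c(0.001, 0.5, 1.0, 2.0, 3.0)),
               c("Holocene", "Chibanian", "Calabrian", "Gelasian", "Piacenzian"))
  expect_equal(age_to_rock_unit(0.774), "Calabrian")  # boundary goes old side
  expect_true(is.na(age_to_rock_unit(99)))
})

test_that("replicate building is deterministic, complete, and flagged", {
  sim <- simulate_dataset(scenario_config(n_species = 8, n_specimens = 60,
                                          taxonomic_uncertainty = 0.1,
                                          seed = 6))
  trees <- lapply(1:5, function(i) jitter_tree(sim$tree, seed = 600 + i))
  r1 <- build_replicates(sim$data, trees, 5, master_seed = 99)
  r2 <- build_replicates(sim$data, trees, 5, master_seed = 99)
  expect_identical(lapply(r1, `[[`, "data"), lapply(r2, `[[`, "data"))

  ids <- lapply(r1, function(r) r$data$specimen_id)
  expect_true(all(vapply(ids, identical, TRUE, ids[[1]])))
  cc_rows <- !is.na(sim$data$cc_cm3)
  expect_equal(nrow(r1[[1]]$data), sum(cc_rows))

  for (r in r1) {
    expect_true(all(r$data$age_ma >= sim$data$age_min_ma[cc_rows] &
                      r$data$age_ma <= sim$data$age_max_ma[cc_rows]))
    expect_equal(r$data$bm_imputed, is.na(sim$data$bm_kg)[cc_rows])
    expect_true(all(is.finite(r$data$log10_cc)))
    expect_true(all(is.finite(r$data$log10_bm)))
    expect_true(all(mapply(function(s, cand) s %in% cand,
                           r$data$species, sim$data$candidates[cc_rows])))
  }
  expect_error(build_replicates(sim$data, trees, 10, master_seed = 1),
               "exceeds")
})

test_that("taxonomic randomization varies across replicates", {
  sim <- simulate_dataset(scenario_config(n_specimens = 150,
                                          taxonomic_uncertainty = 0.3,
                                          seed = 7))
  amb <- which(lengths(sim$data$candidates) > 1)
  expect_gt(length(amb), 0)
  trees <- lapply(1:100, function(i) sim$tree)
  reps <- build_replicates(sim$data, trees, 100, master_seed = 3)
  labels <- vapply(reps, function(r) r$data$species[amb[1]], character(1))
  expect_setequal(unique(labels), sim$data$candidates[[amb[1]]])
})

test_that("replicate sets export as one long CSV", {
  sim <- simulate_dataset(scenario_config(n_species = 6, n_specimens = 30,
                                          seed = 8))
  reps <- build_replicates(sim$data, list(sim$tree, sim$tree), 2,
                           master_seed = 5)
  f <- tempfile(fileext = ".csv")
  write_replicates(reps, f)
  long <- utils::read.csv(f)
  expect_equal(nrow(long), 2 * nrow(reps[[1]]$data))
  expect_equal(unique(long$replicate), c(1, 2))
})
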