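#' Simulate a time-calibrated species tree
#'
#' Generates a rooted birth-death tree rescaled to a requested root depth.
#' With `fossil_tips = TRUE` the terminal branches are shortened by random
#' fractions so that tips terminate before the present at different times,
#' emulating the non-ultrametric trees of an extinct clade.
#'
#' @param n_species number of tips (>= 2); labelled `sp01`, `sp02`, ...
#' @param depth_ma root-to-deepest-tip depth in Myr (default 7, the span of
#'   the hominin fossil record).
#' @param fossil_tips shorten terminal branches to make the tree
#'   non-ultrametric (default TRUE).
#' @param birth,death birth-death rates before rescaling.
#' @param seed optional seed; when NULL the current R random stream is used.
#' @return a rooted `phylo` object.
#' @export
simulate_tree <- function(n_species, depth_ma = 7, fossil_tips = TRUE,
                          birth = 0.5, death = 0.2, seed = NULL) {
  if (n_species < 2L) stop("need at least 2 species")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth, death = death)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  depths <- ape::node.depth.edgelength(tr)[seq_len(n_species)]
  tr$edge.length <- tr$edge.length * depth_ma / max(depths)
  if (fossil_tips) {
    term <- which(tr$edge[, 2] <= n_species)
    # keep the deepest tip at the full depth so the clade spans depth_ma
    depths <- ape::node.depth.edgelength(tr)[seq_len(n_species)]
    anchor <- which.max(depths)
    for (e in term) {
      if (tr$edge[e, 2] == anchor) next
      tr$edge.length[e] <- tr$edge.length[e] *
        (1 - stats::runif(1, 0, 0.8))
    }
  }
  tr
}

#' Jitter a tree's branch lengths
#'
#' Emulates draws from a posterior sample of time-calibrated trees: each
#' branch length is multiplied by an independent log-normal factor, so
#' replicate trees share the topology of the base tree but differ in node
#' ages and tip depths, as successive posterior samples do.
#'
#' @param tree a `phylo` object.
#' @param sd standard deviation of the log-normal edge factors (default
#'   0.15).
#' @param seed optional seed.
#' @return a `phylo` with perturbed branch lengths.
#' @export
jitter_tree <- function(tree, sd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree$edge.length <- tree$edge.length *
    exp(stats::rnorm(length(tree$edge.length), 0, sd))
  tree
}

#' Scenario configuration for the synthetic-data generator
#'
#' Encodes the canonical grid of within- versus between-species evolutionary
#' scenarios. Time scenarios (`A`-`E`) control the between-species time trend,
#' the common within-species trend, and the heterogeneity of within-species
#' slopes; body-mass scenarios (`F`-`J`) are the analogous grid for the
#' allometric predictor:
#'
#' \describe{
#'   \item{A}{between-species trend only (`beta_time_between < 0`, no within
#'     trend).}
#'   \item{B}{a common within-species trend only.}
#'   \item{C}{both trends.}
#'   \item{D}{heterogeneous within-species trends (species-specific slopes
#'     around a common mean) with no between-species time effect; the apparent
#'     between-species pattern arises from the phylogenetic effect and the
#'     body-mass allometry. This is the geometry inferred for the hominin
#'     data.}
#'   \item{E}{heterogeneous within-species slopes around zero, no trends.}
#'   \item{F}{between-species body-mass allometry only (default).}
#'   \item{G}{within-species body-mass effect only.}
#'   \item{H}{both body-mass effects.}
#'   \item{I}{between-species allometry plus heterogeneous within-species
#'     body-mass slopes.}
#'   \item{J}{heterogeneous within-species body-mass slopes only.}
#' }
#'
#' Time slopes are on the age (Ma) axis, so negative values mean increase
#' toward the present. All defaults can be overridden individually. The
#' phylogenetic variance is derived from the target heritability `h2` as
#' `sigma2_phylo = h2 / (1 - h2) * (sigma2_species_intercept + sigma2_residual)`.
#'
#' @param time_scenario,bm_scenario scenario letters (defaults `"D"`, `"F"`).
#' @param n_species,n_specimens clade and sample size (defaults 18 species,
#'   285 specimens, the shape of the hominin compilation).
#' @param specimens_per_species optional integer vector of per-species counts
#'   (overrides the skewed random allocation of `n_specimens`).
#' @param tree_depth_ma root depth of the simulated tree (Myr).
#' @param beta0 intercept on the log10 cranial-capacity scale.
#' @param beta_time_between,beta_time_within,beta_bm_between,beta_bm_within,beta_interaction
#'   fixed-effect values; NULL means "resolved from the scenario letters".
#' @param sigma2_slope,sigma2_bm_slope random-slope variances (NULL =
#'   scenario-resolved).
#' @param h2 target phylogenetic heritability (default 0.9).
#' @param sigma2_species_intercept,sigma2_residual remaining variance
#'   components (log10 units squared).
#' @param age_halfwidth half-width of the recorded chronometric range around
#'   each specimen's true age (Ma).
#' @param bm_missing fraction of specimens whose body mass is deleted
#'   (default 0.65, cf. 184 of 285 in the hominin compilation).
#' @param taxonomic_uncertainty fraction of specimens given a second candidate
#'   species label.
#' @param seed integer seed driving the whole simulation.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(time_scenario = c("D", "A", "B", "C", "E"),
                            bm_scenario = c("F", "G", "H", "I", "J"),
                            n_species = 18, n_specimens = 285,
                            specimens_per_species = NULL,
                            tree_depth_ma = 7, beta0 = 1.3,
                            beta_time_between = NULL,
                            beta_time_within = NULL,
                            beta_bm_between = NULL, beta_bm_within = NULL,
                            beta_interaction = 0,
                            sigma2_slope = NULL, sigma2_bm_slope = NULL,
                            h2 = 0.9, sigma2_species_intercept = 0,
                            sigma2_residual = 2.5e-3,
                            age_halfwidth = 0.15, bm_missing = 0.65,
                            taxonomic_uncertainty = 0, seed = 1L) {
  time_scenario <- match.arg(time_scenario)
  bm_scenario <- match.arg(bm_scenario)
  tdef <- switch(time_scenario,
    A = list(tb = -0.12, tw = 0,     s2 = 0),
    B = list(tb = 0,     tw = -0.12, s2 = 0),
    C = list(tb = -0.12, tw = -0.12, s2 = 0),
    D = list(tb = 0,     tw = -0.12, s2 = 1.2e-3),
    E = list(tb = 0,     tw = 0,     s2 = 1.2e-3))
  bdef <- switch(bm_scenario,
    F = list(bb = 1.0, bw = 0,   s2 = 0),
    G = list(bb = 0,   bw = 0.5, s2 = 0),
    H = list(bb = 1.0, bw = 0.5, s2 = 0),
    I = list(bb = 1.0, bw = 0,   s2 = 0.01),
    J = list(bb = 0,   bw = 0,   s2 = 0.01))
  stopifnot(h2 >= 0, h2 < 1, bm_missing >= 0, bm_missing <= 1,
            sigma2_species_intercept >= 0, sigma2_residual >= 0)
  cfg <- list(
    time_scenario = time_scenario, bm_scenario = bm_scenario,
    n_species = as.integer(n_species), n_specimens = as.integer(n_specimens),
    specimens_per_species = specimens_per_species,
    tree_depth_ma = tree_depth_ma, beta0 = beta0,
    beta_time_between = beta_time_between %||% tdef$tb,
    beta_time_within = beta_time_within %||% tdef$tw,
    beta_bm_between = beta_bm_between %||% bdef$bb,
    beta_bm_within = beta_bm_within %||% bdef$bw,
    beta_interaction = beta_interaction,
    sigma2_slope = sigma2_slope %||% tdef$s2,
    sigma2_bm_slope = sigma2_bm_slope %||% bdef$s2,
    h2 = h2,
    sigma2_phylo = if (h2 > 0)
      h2 / (1 - h2) * (sigma2_species_intercept + sigma2_residual) else 0,
    sigma2_species_intercept = sigma2_species_intercept,
    sigma2_residual = sigma2_residual,
    age_halfwidth = age_halfwidth, bm_missing = bm_missing,
    taxonomic_uncertainty = taxonomic_uncertainty, seed = as.integer(seed)
  )
  stopifnot(cfg$sigma2_slope >= 0, cfg$sigma2_bm_slope >= 0)
  structure(cfg, class = "scenario_config")
}

# skewed per-species specimen counts summing exactly to n (counts >= 1)
allocate_counts <- function(n, n_species) {
  w <- stats::rgamma(n_species, shape = 0.6)
  raw <- n * w / sum(w)
  counts <- pmax(1L, floor(raw))
  delta <- n - sum(counts)
  ord <- order(raw - floor(raw), decreasing = TRUE)
  i <- 1L
  while (delta != 0L) {
    j <- ord[(i - 1L) %% n_species + 1L]
    if (delta > 0L) {
      counts[j] <- counts[j] + 1L
      delta <- delta - 1L
    } else if (counts[j] > 1L) {
      counts[j] <- counts[j] - 1L
      delta <- delta + 1L
    }
    i <- i + 1L
  }
  counts
}

#' Simulate a specimen dataset under a scenario
#'
#' Runs the fitted model forward under the configured scenario: species mean
#' ages are tiled along the tree depth (tips terminating deeper in the past
#' get older temporal ranges), specimen true ages are uniform within each
#' species' range, species-specific within-time slopes are drawn around the
#' common within-time effect, phylogenetic species effects are drawn from
#' `N(0, sigma2_phylo * A)` with `A` the rescaled shared-path covariance, and
#' log10 cranial capacity is assembled from the between/within decomposition
#' of the realized predictors plus species and residual noise. Species mean
#' body mass increases toward the present (recent species are larger),
#' so under scenario D the apparent between-species increase in cranial
#' capacity is carried by the allometry, not by a between-species time effect.
#'
#' Body masses are deleted at the configured missingness rate and recorded
#' chronometric ranges are the true age plus/minus `age_halfwidth`, so the
#' output exercises the full uncertainty-propagation machinery.
#'
#' @param scenario a [scenario_config()].
#' @param tree optional `phylo`; simulated from the scenario when NULL.
#' @return a list with elements `data` (a `specimen_table` as read by
#'   [read_specimens()]), `tree`, `truth` (all generative parameters and
#'   draws, including per-species slopes, the realized heritability of the
#'   simulated species effects, and the per-species specimen counts), and
#'   `data_model` (the noise-free bookkeeping dataset with true ages, true
#'   species and complete log10 traits, ready for [fit_pglmm()] directly).
#' @export
simulate_dataset <- function(scenario, tree = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(scenario$seed)
  if (is.null(tree))
    tree <- simulate_tree(scenario$n_species, scenario$tree_depth_ma)
  S <- length(tree$tip.label)
  sp <- tree$tip.label
  A <- phylo_cov(tree, rescale = TRUE)$V

  counts <- scenario$specimens_per_species %||%
    allocate_counts(scenario$n_specimens, S)
  if (length(counts) != S) stop("specimens_per_species length must equal tips")
  n <- sum(counts)
  species <- rep(sp, counts)

  depths <- ape::node.depth.edgelength(tree)[seq_len(S)]
  tip_age <- max(depths) - depths               # Ma before present
  range_myr <- stats::runif(S, 0.6, 1.8)
  age_true <- stats::runif(n, rep(tip_age, counts),
                           rep(tip_age + range_myr, counts))

  # recent species are larger: allometric between-species structure
  recency <- if (max(tip_age) > 0) 1 - tip_age / max(tip_age) else rep(0.5, S)
  # recency trend plus substantial independent species-level size scatter
  # (contemporaneous hominins differ widely in body size)
  bm_bar <- 1.45 + 0.4 * recency + stats::rnorm(S, 0, 0.15)
  lbm <- rep(bm_bar, counts) + stats::rnorm(n, 0, 0.05)

  a <- drop(crossprod(chol(A), stats::rnorm(S))) *
    sqrt(scenario$sigma2_phylo)
  b <- stats::rnorm(S, 0, sqrt(scenario$sigma2_species_intercept))
  slope <- stats::rnorm(S, scenario$beta_time_within,
                        sqrt(scenario$sigma2_slope))
  bm_slope <- stats::rnorm(S, scenario$beta_bm_within,
                           sqrt(scenario$sigma2_bm_slope))
  eps <- stats::rnorm(n, 0, sqrt(scenario$sigma2_residual))

  t_bar <- stats::ave(age_true, species)
  t_dev <- age_true - t_bar
  b_bar <- stats::ave(lbm, species)
  b_dev <- lbm - b_bar
  si <- match(species, sp)

  y <- scenario$beta0 +
    scenario$beta_bm_between * b_bar + bm_slope[si] * b_dev +
    scenario$beta_time_between * t_bar + slope[si] * t_dev +
    scenario$beta_interaction * t_bar * t_dev +
    a[si] + b[si] + eps

  miss <- stats::runif(n) < scenario$bm_missing
  # every species keeps at least one observed mass so imputation pools exist
  for (s in sp) {
    rows <- which(species == s)
    if (all(miss[rows])) miss[rows[1]] <- FALSE
  }
  realm_pool <- c("Afrotropical", "Palearctic", "Indomalayan")
  realm_sp <- realm_pool[(seq_len(S) - 1L) %% length(realm_pool) + 1L]

  cand <- species
  if (scenario$taxonomic_uncertainty > 0 && S > 1L) {
    amb <- which(stats::runif(n) < scenario$taxonomic_uncertainty)
    # ambiguous specimens are confused with close relatives of similar age
    # and size (species are mistaken for each other because they are related
    # and look alike), not with arbitrary members of the clade
    z_age <- tip_age / max(stats::sd(tip_age), 1e-8)
    z_bm <- bm_bar / max(stats::sd(bm_bar), 1e-8)
    C <- stats::cov2cor(A)
    for (i in amb) {
      others <- match(setdiff(sp, species[i]), sp)
      d2 <- (z_age[others] - z_age[si[i]])^2 +
        (z_bm[others] - z_bm[si[i]])^2 +
        4 * (1 - C[si[i], others])^2
      # a specimen is only controversial when a plausible alternative exists
      if (min(d2) <= 1)
        cand[i] <- paste(species[i], sp[others[which.min(d2)]], sep = ";")
    }
  }

  df <- data.frame(
    specimen_id = sprintf("spec%04d", seq_len(n)),
    species = cand,
    cc_cm3 = 10^y,
    bm_kg = ifelse(miss, NA_real_, 10^lbm),
    age_min_ma = pmax(0, age_true - scenario$age_halfwidth),
    age_max_ma = age_true + scenario$age_halfwidth,
    rock_unit = age_to_rock_unit(age_true),
    realm = realm_sp[si],
    flags = "",
    stringsAsFactors = FALSE
  )

  # realized variance of the phylogenetic effects in the A-metric (the naive
  # sample variance is biased downward when effects are correlated)
  var_a <- if (scenario$sigma2_phylo > 0)
    drop(crossprod(backsolve(chol(A), a, transpose = TRUE))) / S else 0
  var_b <- if (scenario$sigma2_species_intercept > 0) stats::var(b) else 0
  var_e <- if (scenario$sigma2_residual > 0) stats::var(eps) else 0
  den <- var_a + var_b + var_e
  realized_h2 <- if (den > 0) var_a / den else 0

  list(
    data = as_specimen_table(df, species = sp),
    tree = tree,
    truth = list(
      scenario = unclass(scenario), species = sp, counts = counts,
      tip_age = stats::setNames(tip_age, sp),
      slopes = stats::setNames(slope, sp),
      bm_slopes = stats::setNames(bm_slope, sp),
      phylo_effects = stats::setNames(a, sp),
      species_intercepts = stats::setNames(b, sp),
      bm_bar = stats::setNames(bm_bar, sp),
      realized_h2 = realized_h2
    ),
    data_model = data.frame(
      specimen_id = df$specimen_id, species = species, age_ma = age_true,
      log10_cc = y, log10_bm = lbm, bm_imputed = FALSE,
      stringsAsFactors = FALSE
    )
  )
}

#' Write the deterministic fixture suite
#'
#' Writes one fixture per time scenario (A-E, each with the between-species
#' body-mass geometry) at a small size, plus a "study-shaped" fixture
#' matching the hominin compilation's shape: 18 species, 285 specimens, 65%
#' body-mass missingness, a share of two-candidate specimens, and 25 trees
#' for replicate building. Each fixture comprises a specimen CSV, a
#' multi-tree Newick file, and a truth JSON holding the generative
#' parameters, so tests never re-derive them. All output is a deterministic
#' function of `seed`.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed master seed (default 1).
#' @return a data.frame catalogue: fixture name, file paths, record count.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  catalogue <- list()
  write_fixture <- function(name, sim, trees) {
    csv <- file.path(out_dir, paste0(name, "_specimens.csv"))
    nwk <- file.path(out_dir, paste0(name, "_trees.nwk"))
    tjs <- file.path(out_dir, paste0(name, "_truth.json"))
    write_specimens(sim$data, csv)
    ape::write.tree(trees, nwk)
    truth <- sim$truth
    truth$slopes <- as.list(truth$slopes)
    jsonlite::write_json(truth, tjs, auto_unbox = TRUE, digits = NA)
    data.frame(name = name, specimens = csv, trees = nwk, truth = tjs,
               n_records = nrow(sim$data), stringsAsFactors = FALSE)
  }
  for (ts in c("A", "B", "C", "D", "E")) {
    sc <- scenario_config(time_scenario = ts, bm_scenario = "F",
                          n_species = 8, n_specimens = 120,
                          seed = seed + match(ts, LETTERS))
    sim <- simulate_dataset(sc)
    catalogue[[ts]] <- write_fixture(paste0("scenario_", ts), sim,
                                     c(sim$tree))
  }
  sc <- scenario_config(time_scenario = "D", bm_scenario = "F",
                        n_species = 18, n_specimens = 285,
                        bm_missing = 0.65, taxonomic_uncertainty = 0.05,
                        seed = seed + 100L)
  sim <- simulate_dataset(sc)
  trees <- c(list(sim$tree), lapply(seq_len(24), function(i)
    jitter_tree(sim$tree, seed = seed + 200L + i)))
  class(trees) <- "multiPhylo"
  catalogue$study <- write_fixture("study_shaped", sim, trees)
  do.call(rbind, catalogue)
}
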