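#' Default geological-age to rock-unit lookup table
#'
#' Standard ICS stage boundaries for the Quaternary and late Neogene, spanning
#' the fossil hominin record (0 to ~11.6 Ma). A specimen's sampled age maps to
#' the stage whose interval contains it; the table is user-overridable via the
#' `rock_units` argument of [build_replicates()] for analyses that used a
#' different stratigraphic scheme.
#'
#' @return a data.frame with columns `unit`, `min_ma`, `max_ma` (intervals are
#'   closed on the young side, open on the old side except the last).
#' @export
default_rock_units <- function() {
  data.frame(
    unit = c("Holocene", "Late Pleistocene", "Chibanian", "Calabrian",
             "Gelasian", "Piacenzian", "Zanclean", "Messinian", "Tortonian"),
    min_ma = c(0, 0.0117, 0.129, 0.774, 1.80, 2.58, 3.60, 5.333, 7.246),
    max_ma = c(0.0117, 0.129, 0.774, 1.80, 2.58, 3.60, 5.333, 7.246, 11.63),
    stringsAsFactors = FALSE
  )
}

#' Map a geological age to a rock-unit label
#'
#' @param age_ma numeric vector of ages in Ma.
#' @param table lookup table as produced by [default_rock_units()].
#' @return character vector of unit labels (`NA` for ages outside the table).
#' @export
age_to_rock_unit <- function(age_ma, table = default_rock_units()) {
  idx <- findInterval(age_ma, c(table$min_ma, table$max_ma[nrow(table)]),
                      rightmost.closed = TRUE)
  out <- rep(NA_character_, length(age_ma))
  ok <- idx >= 1L & idx <= nrow(table)
  out[ok] <- table$unit[idx[ok]]
  out
}

#' Sample a specimen age from its chronometric range
#'
#' Draws uniformly on `[age_min_ma, age_max_ma]`; a degenerate range returns
#' its single value. Uses the current R random number stream.
#'
#' @param age_min_ma,age_max_ma chronometric bounds in Ma (vectors recycle).
#' @param n number of draws per bound pair when bounds are scalars.
#' @return sampled age(s) in Ma.
#' @export
sample_age <- function(age_min_ma, age_max_ma, n = max(length(age_min_ma), 1L)) {
  if (any(age_min_ma > age_max_ma)) stop("inverted age bounds")
  stats::runif(n, age_min_ma, age_max_ma)
}

#' Randomly assign a specimen to one of its candidate species
#'
#' Controversial specimens carry several candidate labels; each replicate
#' dataset classifies them as one candidate chosen uniformly at random.
#' Single-candidate specimens are deterministic.
#'
#' @param candidates character vector of candidate species labels.
#' @return one species label.
#' @export
assign_species <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidate species")
  if (length(candidates) == 1L) return(candidates)
  candidates[sample.int(length(candidates), 1L)]
}

#' Impute a missing body mass from a species pool
#'
#' Observed body masses are never altered; this is only called for specimens
#' lacking one. For species with fewer than 20 pooled estimates the mass is
#' drawn uniformly from the observed range (or resampled from the observed
#' values with `mode = "resample"`). For larger pools the draw is taken
#' uniformly among pool entries matching the specimen's rock unit (derived
#' from its sampled age) and biogeographic realm, relaxing the stratification
#' in a fixed ladder when the stratum is empty: same rock unit with any realm,
#' then same realm with any rock unit, then the whole species pool.
#'
#' @param pool one element of [species_pools()] (data.frame with `n` attr).
#' @param rock_unit,realm stratum labels of the specimen (may be `NA`).
#' @param mode `"range_uniform"` (continuous uniform on \[min, max\]) or
#'   `"resample"` for the small-pool rule.
#' @return a list with `bm_kg` (the drawn mass), `imputed = TRUE` and
#'   `fallback` (0 = exact stratum, 1-3 = ladder level used, NA for small
#'   pools).
#' @export
impute_body_mass <- function(pool, rock_unit = NA, realm = NA,
                             mode = c("range_uniform", "resample")) {
  mode <- match.arg(mode)
  if (is.null(pool) || nrow(pool) == 0L) stop("empty body-mass pool")
  n <- attr(pool, "n")
  if (is.null(n)) n <- nrow(pool)
  if (n < 20L) {
    bm <- if (mode == "range_uniform") {
      stats::runif(1, min(pool$bm_kg), max(pool$bm_kg))
    } else {
      pool$bm_kg[sample.int(nrow(pool), 1L)]
    }
    return(list(bm_kg = bm, imputed = TRUE, fallback = NA_integer_))
  }
  match_unit <- !is.na(rock_unit) & !is.na(pool$rock_unit) &
    pool$rock_unit == rock_unit
  match_realm <- !is.na(realm) & !is.na(pool$realm) & pool$realm == realm
  strata <- list(which(match_unit & match_realm), which(match_unit),
                 which(match_realm), seq_len(nrow(pool)))
  level <- which(lengths(strata) > 0L)[1L]
  idx <- strata[[level]]
  list(bm_kg = pool$bm_kg[idx[sample.int(length(idx), 1L)]],
       imputed = TRUE, fallback = level - 1L)
}

replicate_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) * 69069 + as.numeric(k) * 104729) %%
               2147483629)
}

#' Build uncertainty-propagating replicate datasets
#'
#' Realizes `n_replicates` datasets from the specimen table, one per posterior
#' tree: every cranial-capacity-bearing specimen gets a species label drawn
#' uniformly among its candidates, an age drawn uniformly from its
#' chronometric range, and - where body mass is missing - a mass imputed from
#' the species pool ([impute_body_mass()]). Traits are log10-transformed.
#' Replicate `k` is paired with tree `k`, so the set propagates phylogenetic,
#' chronometric, taxonomic and body-mass uncertainty jointly.
#'
#' Each replicate uses a seed derived deterministically from `master_seed` and
#' the replicate index, so the whole set is exactly reproducible.
#'
#' @param records a `specimen_table` ([read_specimens()]).
#' @param trees a list/`multiPhylo` of rooted trees, at least `n_replicates`
#'   long; every candidate species must be a tip of every tree used.
#' @param n_replicates number of replicate datasets.
#' @param master_seed integer master seed.
#' @param pools body-mass pools; computed from `records` when NULL.
#' @param impute_mode passed to [impute_body_mass()].
#' @param rock_units age-to-unit lookup table ([default_rock_units()]).
#' @return an object of class `replicate_set`: a list of `n_replicates`
#'   elements, each with `data` (one row per cc-bearing specimen: columns
#'   `specimen_id`, `species`, `age_ma`, `log10_cc`, `log10_bm`,
#'   `bm_imputed`), `tree`, and `seed`.
#' @export
build_replicates <- function(records, trees, n_replicates, master_seed,
                             pools = NULL,
                             impute_mode = c("range_uniform", "resample"),
                             rock_units = default_rock_units()) {
  stopifnot(inherits(records, "specimen_table"))
  impute_mode <- match.arg(impute_mode)
  if (n_replicates > length(trees))
    stop("n_replicates exceeds the number of trees supplied")
  if (is.null(pools)) pools <- species_pools(records)
  cc_rows <- which(!is.na(records$cc_cm3))
  if (length(cc_rows) == 0L) stop("no specimens with cranial capacity")

  out <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    seed_k <- replicate_seed(master_seed, k)
    set.seed(seed_k)
    tree <- trees[[k]]
    sp <- vapply(records$candidates[cc_rows], assign_species, character(1))
    absent <- setdiff(unique(sp), tree$tip.label)
    if (length(absent))
      stop("species missing from tree ", k, ": ", paste(absent, collapse = ", "))
    age <- sample_age(records$age_min_ma[cc_rows], records$age_max_ma[cc_rows])
    bm <- records$bm_kg[cc_rows]
    imputed <- is.na(bm)
    for (i in which(imputed)) {
      pool <- pools[[sp[i]]]
      if (is.null(pool))
        stop("no body-mass pool for species: ", sp[i])
      unit <- age_to_rock_unit(age[i], rock_units)
      realm <- records$realm[cc_rows][i]
      bm[i] <- impute_body_mass(pool, rock_unit = unit, realm = realm,
                                mode = impute_mode)$bm_kg
    }
    out[[k]] <- list(
      data = data.frame(
        specimen_id = records$specimen_id[cc_rows],
        species = sp,
        age_ma = age,
        log10_cc = log10(records$cc_cm3[cc_rows]),
        log10_bm = log10(bm),
        bm_imputed = imputed,
        stringsAsFactors = FALSE
      ),
      tree = tree,
      seed = seed_k
    )
  }
  structure(out, class = "replicate_set", master_seed = master_seed)
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("Replicate set:", length(x), "datasets of", nrow(x[[1]]$data),
      "specimens (master seed", attr(x, "master_seed"), ")\n")
  invisible(x)
}

#' Write a replicate set as one long-format CSV
#'
#' @param replicates a `replicate_set`.
#' @param path output CSV path; a `replicate` id column distinguishes
#'   datasets.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(replicates, path) {
  stopifnot(inherits(replicates, "replicate_set"))
  long <- do.call(rbind, lapply(seq_along(replicates), function(k) {
    cbind(replicate = k, replicates[[k]]$data)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
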