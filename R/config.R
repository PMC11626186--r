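#' Read a structured run configuration
#'
#' Loads a YAML run configuration describing input files and data-treatment
#' variants. Recognized keys (all optional):
#'
#' \describe{
#'   \item{trees, specimens}{input file paths.}
#'   \item{keep}{species keep-list; candidate labels outside it are dropped.}
#'   \item{exclude}{species to remove from every candidate list.}
#'   \item{lump}{named mapping `new_label: [old labels]` merging species
#'     (e.g. lumping two sister taxa into one).}
#'   \item{drop_flags}{records carrying any of these flags are removed.}
#'   \item{impute_mode}{`range_uniform` or `resample`.}
#'   \item{n_replicates, master_seed, alpha, proportion, min_specimens}{run
#'     parameters.}
#' }
#'
#' @param path YAML file path.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Apply a run configuration's data treatments to a specimen table
#'
#' Applies, in order: flag-based record filtering, species lumping, species
#' exclusion, and the keep-list. Records left without any candidate species
#' are dropped, and the table is re-validated.
#'
#' @param records a `specimen_table`.
#' @param config a `run_config` (or plain list with the same keys).
#' @param species optional tree tip labels for re-validation.
#' @return the filtered and relabelled `specimen_table`.
#' @export
apply_run_config <- function(records, config, species = NULL) {
  stopifnot(inherits(records, "specimen_table"))
  df <- as.data.frame(records)

  if (!is.null(config$drop_flags)) {
    hit <- vapply(df$flag_list, function(f)
      any(f %in% config$drop_flags), logical(1))
    df <- df[!hit, , drop = FALSE]
  }
  cands <- df$candidates
  if (!is.null(config$lump)) {
    for (new in names(config$lump)) {
      old <- config$lump[[new]]
      cands <- lapply(cands, function(x) unique(ifelse(x %in% old, new, x)))
    }
  }
  if (!is.null(config$exclude))
    cands <- lapply(cands, setdiff, y = config$exclude)
  if (!is.null(config$keep))
    cands <- lapply(cands, intersect, y = config$keep)
  df$species <- vapply(cands, paste, character(1), collapse = ";")
  df <- df[lengths(cands) > 0L, , drop = FALSE]
  if (nrow(df) == 0L) stop("configuration removed every record")
  keep <- setdiff(names(df), c("candidates", "flag_list"))
  as_specimen_table(df[, keep], species = species)
}
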