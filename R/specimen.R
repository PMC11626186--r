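#' Read and validate a specimen-level trait table
#'
#' Reads a CSV of fossil specimens carrying cranial capacity, optional body
#' mass, a chronometric age range and one or more candidate species labels.
#' The expected columns are:
#'
#' \describe{
#'   \item{specimen_id}{unique specimen identifier}
#'   \item{species}{candidate species label(s), semicolon-separated when the
#'     taxonomic assignment is controversial}
#'   \item{cc_cm3}{cranial capacity in cm^3 (may be empty for body-mass-only
#'     specimens that feed the imputation pools)}
#'   \item{bm_kg}{body mass in kg (may be empty)}
#'   \item{age_min_ma, age_max_ma}{chronometric bounds in Ma, min <= max}
#'   \item{rock_unit}{stratigraphic unit label (optional)}
#'   \item{realm}{biogeographic realm label (optional)}
#'   \item{flags}{semicolon-separated flags such as `adult_projected`,
#'     `cranial_bm_estimate` (optional)}
#' }
#'
#' Rows violating hard invariants (inverted age bounds, non-positive traits,
#' empty species field, candidate species absent from `species`) raise an
#' error naming the offending specimens. Soft issues (missing rock unit or
#' realm) are collected into a validation report attached as the
#' `"validation"` attribute.
#'
#' @param path CSV file path (UTF-8, decimal point).
#' @param species optional character vector of valid species labels (normally
#'   the tree tip labels); when given, every candidate label must be present.
#' @return a data.frame of class `specimen_table`, one row per input row, with
#'   a `candidates` list-column of parsed species labels and a `flag_list`
#'   list-column of parsed flags.
#' @seealso [species_pools()], [build_replicates()]
#' @export
read_specimens <- function(path, species = NULL) {
  required <- c("specimen_id", "species", "cc_cm3", "bm_kg",
                "age_min_ma", "age_max_ma")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (opt in c("rock_unit", "realm", "flags"))
    if (is.null(df[[opt]])) df[[opt]] <- NA_character_
  as_specimen_table(df, species = species)
}

as_specimen_table <- function(df, species = NULL) {
  df$specimen_id <- trimws(as.character(df$specimen_id))
  df$species <- trimws(as.character(df$species))
  df$candidates <- lapply(strsplit(df$species, ";", fixed = TRUE),
                          function(x) trimws(x[nzchar(trimws(x))]))
  df$flag_list <- lapply(strsplit(ifelse(is.na(df$flags), "", df$flags), ";"),
                         function(x) trimws(x[nzchar(trimws(x))]))
  for (col in c("cc_cm3", "bm_kg", "age_min_ma", "age_max_ma"))
    df[[col]] <- as.numeric(df[[col]])

  bad <- function(cond) df$specimen_id[which(cond)]
  errs <- character(0)
  inv <- bad(df$age_min_ma > df$age_max_ma)
  if (length(inv)) errs <- c(errs, paste0("inverted age bounds: ",
                                          paste(inv, collapse = ", ")))
  nocc <- bad(!is.na(df$cc_cm3) & df$cc_cm3 <= 0)
  if (length(nocc)) errs <- c(errs, paste0("non-positive cranial capacity: ",
                                           paste(nocc, collapse = ", ")))
  nobm <- bad(!is.na(df$bm_kg) & df$bm_kg <= 0)
  if (length(nobm)) errs <- c(errs, paste0("non-positive body mass: ",
                                           paste(nobm, collapse = ", ")))
  empty <- bad(lengths(df$candidates) == 0L)
  if (length(empty)) errs <- c(errs, paste0("empty species field: ",
                                            paste(empty, collapse = ", ")))
  if (!is.null(species)) {
    species <- trimws(species)
    unknown <- setdiff(unique(unlist(df$candidates)), species)
    if (length(unknown))
      errs <- c(errs, paste0("species label(s) absent from tree tips: ",
                             paste(unknown, collapse = ", ")))
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))

  report <- c(
    sprintf("%d records (%d with cranial capacity, %d with body mass)",
            nrow(df), sum(!is.na(df$cc_cm3)), sum(!is.na(df$bm_kg))),
    sprintf("%d cc-bearing records lack body mass",
            sum(!is.na(df$cc_cm3) & is.na(df$bm_kg))),
    if (any(is.na(df$rock_unit) | !nzchar(df$rock_unit)))
      sprintf("%d records without rock_unit",
              sum(is.na(df$rock_unit) | !nzchar(df$rock_unit))),
    if (any(is.na(df$realm) | !nzchar(df$realm)))
      sprintf("%d records without realm",
              sum(is.na(df$realm) | !nzchar(df$realm)))
  )
  structure(df, class = c("specimen_table", "data.frame"),
            validation = report)
}

#' Write a specimen table back to CSV
#'
#' Inverse of [read_specimens()]: the parsed list-columns are dropped and the
#' original column layout is written, so a write/read round trip reproduces
#' identical records.
#'
#' @param records a `specimen_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(records, path) {
  stopifnot(inherits(records, "specimen_table"))
  keep <- c("specimen_id", "species", "cc_cm3", "bm_kg",
            "age_min_ma", "age_max_ma", "rock_unit", "realm", "flags")
  utils::write.csv(as.data.frame(records)[, keep], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-species body-mass imputation pools
#'
#' Collects all observed body-mass estimates, tagged with rock unit and
#' biogeographic realm, into one pool per species. Specimens with body mass
#' but no cranial capacity contribute to the pools even though they never
#' enter the regression; a specimen with several candidate species contributes
#' to the pool of each candidate (it could be any of them).
#'
#' @param records a `specimen_table`.
#' @return a named list (one element per species) of data.frames with columns
#'   `bm_kg`, `rock_unit`, `realm`; the `n` attribute of each element is the
#'   pool size used for the n < 20 vs n >= 20 imputation rule.
#' @export
species_pools <- function(records) {
  stopifnot(inherits(records, "specimen_table"))
  has_bm <- which(!is.na(records$bm_kg))
  rows <- do.call(rbind, lapply(has_bm, function(i) {
    data.frame(species = records$candidates[[i]],
               bm_kg = records$bm_kg[i],
               rock_unit = as.character(records$rock_unit[i]),
               realm = as.character(records$realm[i]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) return(structure(list(), class = "species_pools"))
  pools <- split(rows[, c("bm_kg", "rock_unit", "realm")], rows$species)
  pools <- lapply(pools, function(p) { attr(p, "n") <- nrow(p); p })
  structure(pools, class = "species_pools")
}

#' @export
print.specimen_table <- function(x, ...) {
  cat("Specimen table:", nrow(x), "records\n")
  for (line in attr(x, "validation")) cat(" -", line, "\n")
  NextMethod()
}
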