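#' Within-group centering of a predictor
#'
#' Decomposes a specimen-level predictor into a between-species component (the
#' species mean, constant within each species) and a within-species component
#' (the deviation of each specimen from its own species mean). Fitting both
#' components as separate regressors lets a mixed model estimate the
#' between-species (cross-sectional) and within-species (anagenetic) effects
#' of the same variable on different coefficients instead of conflating them.
#'
#' The two components reconstruct the input (`between + within == values`),
#' within-species deviations sum to zero inside every species, and centering
#' the within component again by the same groups leaves it unchanged.
#'
#' @param values numeric vector (finite), one entry per specimen.
#' @param groups species label per specimen, same length as `values`.
#' @return a list of class `centered_predictor` with numeric elements
#'   `between` and `within`, each aligned with the input rows.
#' @examples
#' within_group_center(c(1, 3, 5, 7), c("g1", "g1", "g2", "g2"))
#' @export
within_group_center <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  if (length(values) == 0L) stop("empty input")
  if (!all(is.finite(values))) stop("values must be finite")
  between <- stats::ave(values, groups)
  structure(list(between = between, within = values - between),
            class = "centered_predictor")
}
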