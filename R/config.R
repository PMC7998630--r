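#' Validated pipeline configuration
#'
#' Bundles the settings of every stage; defaults reproduce the common
#' high-resolution search configuration (trypsin with proline block, up to 2
#' missed cleavages, fixed carbamidomethyl-C, variable oxidation-M, 10 ppm
#' precursor tolerance, peptide length 6-50). Every field is validated
#' before any stage runs.
#'
#' @param rule \code{\link{cleavage_rule}}.
#' @param scheme \code{\link{modification_scheme}}.
#' @param min_length,max_length Peptide length window.
#' @param options \code{\link{uniqueness_options}}.
#' @param tolerance_ppm Precursor match window (must be > 0).
#' @param consensus Replicate consensus for detection (>= 1).
#' @param min_peptides,min_proteins Species-calling rule.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(rule = cleavage_rule(),
                            scheme = modification_scheme(),
                            min_length = 6L, max_length = 50L,
                            options = uniqueness_options(),
                            tolerance_ppm = 10,
                            consensus = 1L,
                            min_peptides = 1L, min_proteins = 1L) {
  stopifnot(inherits(rule, "cleavage_rule"),
            inherits(scheme, "modification_scheme"),
            inherits(options, "uniqueness_options"))
  min_length <- as.integer(min_length); max_length <- as.integer(max_length)
  if (min_length < 1L || max_length < min_length) {
    stop("invalid peptide length window [", min_length, ", ", max_length,
         "]", call. = FALSE)
  }
  if (!is.numeric(tolerance_ppm) || length(tolerance_ppm) != 1L ||
      !is.finite(tolerance_ppm) || tolerance_ppm <= 0) {
    stop("tolerance_ppm must be a positive number", call. = FALSE)
  }
  consensus <- as.integer(consensus)
  if (consensus < 1L) stop("consensus must be >= 1", call. = FALSE)
  min_peptides <- as.integer(min_peptides)
  min_proteins <- as.integer(min_proteins)
  if (min_peptides < 1L || min_proteins < 1L) {
    stop("min_peptides and min_proteins must be >= 1", call. = FALSE)
  }
  structure(list(rule = rule, scheme = scheme, min_length = min_length,
                 max_length = max_length, options = options,
                 tolerance_ppm = tolerance_ppm, consensus = consensus,
                 min_peptides = min_peptides, min_proteins = min_proteins),
            class = "pipeline_config")
}
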