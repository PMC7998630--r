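# Bridges from the transcribed study tables to pipeline objects, so the
# detection/authentication stages can run on the published data directly.

#' Marker panel built from the study fixture
#'
#' Builds a validated \code{marker_panel} from the published marker peptides:
#' the 40 hemp peptides, the meat attributions, and optionally the sunflower
#' seed-storage peptides. Masses are the fixed-modification base states (no
#' variable-modification expansion); missed cleavages come from
#' \code{\link{is_tryptic}}.
#'
#' @param fixture Output of \code{\link{load_paper_fixture}}.
#' @param include_meat,include_sunflower Include the meat / sunflower marker
#'   sets (defaults \code{TRUE} / \code{FALSE}).
#' @param scheme \code{\link{modification_scheme}} for masses.
#' @param expand_modifications Expand variable-modification states (default
#'   \code{FALSE} for the fixture panel).
#' @return A \code{marker_panel} data.frame.
#' @export
fixture_panel <- function(fixture = load_paper_fixture(),
                          include_meat = TRUE, include_sunflower = FALSE,
                          scheme = modification_scheme(),
                          expand_modifications = FALSE) {
  hemp <- data.frame(
    peptide = fixture$hemp_matrix$peptide,
    species = "Cannabis sativa",
    protein = fixture$hemp_matrix$protein,
    accession = fixture$hemp_matrix$accession,
    stringsAsFactors = FALSE)
  parts <- list(hemp)
  if (include_meat) {
    meat <- unique(fixture$meat_attributions[
      , c("peptide", "species", "protein", "accession")])
    parts <- c(parts, list(meat))
  }
  if (include_sunflower) {
    sun <- fixture$sunflower_peptides
    sun$accession <- sun$protein
    parts <- c(parts, list(sun[, c("peptide", "species", "protein",
                                   "accession")]))
  }
  cand <- do.call(rbind, parts)
  cand$unique <- TRUE   # published markers are species-unique by selection
  build_panel(cand, scheme, expand_modifications = expand_modifications,
              provenance = "published marker tables")
}

#' Detection matrix encoding the fixture presence/absence tables
#'
#' Converts the published presence/absence data into a
#' \code{detection_matrix}: the hemp peptide matrix over samples M1-M4 and
#' HC and, optionally, the meat attributions (detected in their reported
#' sample: M4 for guinea fowl, rabbit, and pig; P12 for chicken). Detected
#' cells are given full replicate support (the publication reports
#' triplicate consensus only); intensities are zero because the tables print
#' protein-level, not peptide-level, intensities.
#'
#' @param fixture Output of \code{\link{load_paper_fixture}}.
#' @param include_meat Add the meat peptide rows and the P12 sample.
#' @return A \code{detection_matrix}.
#' @export
fixture_detection_matrix <- function(fixture = load_paper_fixture(),
                                     include_meat = TRUE) {
  hm <- fixture$hemp_matrix
  samples <- c("M1", "M2", "M3", "M4", "HC")
  peptides <- data.frame(peptide = hm$peptide, species = "Cannabis sativa",
                         protein = hm$protein, accession = hm$accession,
                         stringsAsFactors = FALSE)
  detected <- as.matrix(hm[, samples])
  if (include_meat) {
    ma <- fixture$meat_attributions
    samples <- c(samples, "P12")
    detected <- cbind(detected, P12 = rep(FALSE, nrow(detected)))
    meat_det <- matrix(FALSE, nrow(ma), length(samples),
                       dimnames = list(NULL, samples))
    meat_det[cbind(seq_len(nrow(ma)), match(ma$sample_id, samples))] <- TRUE
    peptides <- rbind(peptides,
                      data.frame(peptide = ma$peptide, species = ma$species,
                                 protein = ma$protein,
                                 accession = ma$accession,
                                 stringsAsFactors = FALSE))
    detected <- rbind(detected, meat_det)
  }
  dimnames(detected) <- list(peptides$peptide, samples)
  replicate_count <- 3L
  structure(list(peptides = peptides, samples = samples,
                 detected = detected,
                 support = detected * replicate_count,
                 intensity = matrix(0, nrow(detected), ncol(detected),
                                    dimnames = dimnames(detected)),
                 consensus = 1L),
            class = "detection_matrix")
}

#' Dilution-series concentrations of the fixture
#'
#' Named vector sample id -> hemp-cake spike concentration (% w/w) for the
#' meatball dilution series M1-M4 (0.9, 2.6, 4.2, 7.4), excluding the
#' unspiked control and the pure hemp-cake sample.
#'
#' @param fixture Output of \code{\link{load_paper_fixture}}.
#' @return Named numeric vector.
#' @export
fixture_series_concentrations <- function(fixture = load_paper_fixture()) {
  d <- fixture$designs
  sel <- d$spike_concentration > 0 & d$spike_concentration < 100
  stats::setNames(d$spike_concentration[sel], d$sample_id[sel])
}
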