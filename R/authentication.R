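#' Call species from a detection matrix
#'
#' A species is called in a sample when at least \code{min_proteins} of its
#' panel proteins each have at least \code{min_peptides} detected unique
#' peptides. The defaults (1 and 1) reflect that a single species-unique
#' peptide is already species-level evidence; stricter two-peptide
#' confirmation is available through the rule parameters.
#'
#' @param matrix A \code{detection_matrix} whose rows carry \code{species}
#'   and \code{protein} metadata.
#' @param min_peptides Minimum detected unique peptides per protein.
#' @param min_proteins Minimum qualifying proteins per species.
#' @return data.frame: \code{sample_id}, \code{species},
#'   \code{n_proteins} (qualifying), \code{n_peptides} (total detected),
#'   \code{called}; per-protein evidence in attribute \code{"evidence"}.
#' @export
call_species <- function(matrix, min_peptides = 1L, min_proteins = 1L) {
  stopifnot(inherits(matrix, "detection_matrix"))
  pep <- matrix$peptides
  stopifnot(all(c("species", "protein") %in% names(pep)))
  evidence <- list(); calls <- list()
  for (s in matrix$samples) {
    det <- matrix$detected[, s]
    counts <- stats::aggregate(det,
                               by = list(species = pep$species,
                                         protein = pep$protein),
                               FUN = sum)
    names(counts)[3L] <- "n_detected_peptides"
    counts$sample_id <- s
    evidence[[s]] <- counts
    for (sp in unique(counts$species)) {
      sub <- counts[counts$species == sp, ]
      qualifying <- sum(sub$n_detected_peptides >= min_peptides)
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = s, species = sp,
        n_proteins = qualifying,
        n_peptides = sum(sub$n_detected_peptides),
        called = qualifying >= min_proteins,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  attr(out, "evidence") <- do.call(rbind, evidence)
  out
}

#' Heat-stable markers across processing variants
#'
#' Returns the peptides detected in every listed sample (per-sample
#' intersection): the markers that survive all processing variants.
#'
#' @param matrix A \code{detection_matrix}, or a list of single-/multi-sample
#'   detection matrices (intersected across all their samples).
#' @param samples Samples to intersect over (default: all samples of the
#'   matrix).
#' @return Character vector of peptide sequences.
#' @export
stable_markers <- function(matrix, samples = NULL) {
  if (inherits(matrix, "detection_matrix")) matrix <- list(matrix)
  stopifnot(length(matrix) >= 1L,
            all(vapply(matrix, inherits, logical(1), "detection_matrix")))
  sets <- list()
  for (m in matrix) {
    use <- if (is.null(samples)) m$samples else intersect(samples, m$samples)
    for (s in use) {
      sets[[length(sets) + 1L]] <- m$peptides$peptide[m$detected[, s]]
    }
  }
  if (!length(sets)) return(character(0))
  Reduce(intersect, sets)
}

#' Estimate protein-level limits of detection from a dilution series
#'
#' The LOD of a protein is the smallest tested spike concentration at which
#' at least \code{min_peptides} of its unique peptides are detected;
#' \code{NA} if it is never detected. Reported on the tested grid only (no
#' interpolation). If detection is lost again at a higher concentration the
#' result is flagged non-monotone.
#'
#' @param matrix A \code{detection_matrix} with \code{protein} row metadata.
#' @param concentrations Named numeric vector: sample id -> spike
#'   concentration (% w/w). Names must be samples of the matrix; duplicate
#'   concentration values are an error.
#' @param proteins Proteins to report (default: all in the matrix).
#' @param min_peptides Detected-peptide rule for "protein detected"
#'   (default 1).
#' @return data.frame of class \code{lod_result}: \code{protein},
#'   \code{species}, \code{lod}, \code{n_supporting},
#'   \code{supporting_peptides} (semicolon-joined, at the LOD
#'   concentration), \code{non_monotone}.
#' @export
estimate_lod <- function(matrix, concentrations, proteins = NULL,
                         min_peptides = 1L) {
  stopifnot(inherits(matrix, "detection_matrix"))
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
    stop("concentrations must be named by sample id", call. = FALSE)
  }
  if (length(concentrations) < 2L) {
    stop("need at least two tested concentrations", call. = FALSE)
  }
  if (anyDuplicated(concentrations)) {
    stop("duplicate concentration values in the series", call. = FALSE)
  }
  missing <- setdiff(names(concentrations), matrix$samples)
  if (length(missing)) {
    stop("concentration sample(s) not in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  conc <- sort(concentrations)
  pep <- matrix$peptides
  stopifnot("protein" %in% names(pep))
  if (is.null(proteins)) proteins <- unique(pep$protein)
  rows <- list()
  for (pr in proteins) {
    sel <- pep$protein == pr
    if (!any(sel)) stop("protein not in matrix: ", pr, call. = FALSE)
    detected_at <- vapply(names(conc), function(s)
      sum(matrix$detected[sel, s]) >= min_peptides, logical(1))
    lod <- NA_real_; supporting <- character(0); non_mono <- FALSE
    if (any(detected_at)) {
      first <- which(detected_at)[1L]
      lod <- unname(conc[first])
      supporting <- pep$peptide[sel][matrix$detected[sel, names(conc)[first]]]
      non_mono <- any(!detected_at[first:length(conc)])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protein = pr,
      species = if ("species" %in% names(pep))
        pep$species[sel][1L] else NA_character_,
      lod = lod,
      n_supporting = length(supporting),
      supporting_peptides = paste(supporting, collapse = ";"),
      non_monotone = non_mono,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lod_result", "data.frame")
  out
}

#' Linear intensity-versus-concentration trend
#'
#' Ordinary least-squares fit of protein total intensity on spike
#' concentration; the coefficient of determination is the squared Pearson
#' correlation. An all-constant response is reported with
#' \code{r_squared = 0}. A zero point (no spike, zero intensity) is included
#' by default, mirroring a calibration line through the blank; disable it
#' when a measured blank intensity is available.
#'
#' @param concentrations Numeric vector of spike concentrations (% w/w).
#' @param intensities Numeric vector of total intensities (same length).
#' @param include_zero Prepend the point (0, 0) (default \code{TRUE}).
#' @param log_intensity Fit on log10 intensity instead of raw intensity
#'   (default \code{FALSE}; zero intensities are then not allowed and the
#'   zero point is dropped).
#' @return List of class \code{trend_fit}: \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{n}, \code{x}, \code{y}, \code{log_intensity}.
#' @examples
#' intensity_trend(c(1, 2, 3), c(3, 5, 7), include_zero = FALSE)  # R^2 = 1
#' @export
intensity_trend <- function(concentrations, intensities,
                            include_zero = TRUE, log_intensity = FALSE) {
  stopifnot(length(concentrations) == length(intensities))
  x <- as.numeric(concentrations); y <- as.numeric(intensities)
  if (include_zero && !log_intensity) {
    x <- c(0, x); y <- c(0, y)
  }
  if (log_intensity) {
    if (any(y <= 0)) stop("log fit requires positive intensities",
                          call. = FALSE)
    y <- log10(y)
  }
  if (length(x) < 3L) stop("need at least 3 points for a trend fit",
                           call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in concentration", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n = length(x), x = x, y = y,
                 log_intensity = log_intensity),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend fit (n = %d%s): intensity = %.4g + %.4g * conc, R^2 = %.4f\n",
              x$n, if (x$log_intensity) ", log10 intensity" else "",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}
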