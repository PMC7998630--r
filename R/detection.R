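#' Match observed features to a marker panel at ppm tolerance
#'
#' Peptide-centric matching on neutral monoisotopic mass: a feature matches a
#' panel state when |observed - theoretical| / theoretical * 1e6 is at most
#' \code{tolerance_ppm}. A feature matching several states is assigned once,
#' to the state with minimal absolute ppm error; ties go to the lower
#' theoretical mass, then the lexicographically smaller sequence.
#'
#' @param features Feature data.frame (\code{\link{read_features}} columns).
#' @param panel Marker panel with computed \code{neutral_mass}.
#' @param tolerance_ppm Match window in parts per million (default 10).
#' @return data.frame of detection events: feature columns plus
#'   \code{panel_row}, \code{peptide}, \code{modification}, \code{species},
#'   \code{protein}, \code{theoretical_mass}, \code{mass_error_ppm}.
#' @export
match_features <- function(features, panel, tolerance_ppm = 10) {
  if (!is.numeric(tolerance_ppm) || length(tolerance_ppm) != 1L ||
      !is.finite(tolerance_ppm) || tolerance_ppm <= 0) {
    stop("tolerance_ppm must be a positive number", call. = FALSE)
  }
  stopifnot(all(c("neutral_mass") %in% names(panel)))
  n <- nrow(features)
  empty <- cbind(features[0, , drop = FALSE],
                 data.frame(panel_row = integer(0), peptide = character(0),
                            modification = character(0),
                            species = character(0), protein = character(0),
                            theoretical_mass = numeric(0),
                            mass_error_ppm = numeric(0)))
  if (!n || !nrow(panel)) return(empty)
  pm <- panel$neutral_mass
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    obs <- features$neutral_mass[i]
    err_all <- (obs - pm) / pm * 1e6
    keep <- abs(err_all) <= tolerance_ppm
    if (!any(keep)) next
    cand <- which(keep); err <- err_all[keep]
    pick <- order(abs(err), panel$neutral_mass[cand],
                  panel$peptide[cand])[1L]
    rows[[i]] <- data.frame(
      features[i, , drop = FALSE],
      panel_row = cand[pick],
      peptide = panel$peptide[cand[pick]],
      modification = panel$modification[cand[pick]],
      species = panel$species[cand[pick]],
      protein = panel$protein[cand[pick]],
      theoretical_mass = panel$neutral_mass[cand[pick]],
      mass_error_ppm = err[pick],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a replicate-consensus detection matrix
#'
#' A panel peptide is detected in a sample when it has at least one matching
#' feature in at least \code{consensus} replicates of that sample. Cell
#' intensity is the per-replicate summed matched-feature intensity averaged
#' over the sample's replicate count.
#'
#' @param events Output of \code{\link{match_features}}.
#' @param panel Marker panel (defines the matrix rows: unique bare peptides).
#' @param designs Sample design table (\code{sample_id},
#'   \code{replicate_count}).
#' @param consensus Required number of supporting replicates (default 1;
#'   the published table does not publish replicate-level detail).
#' @return An object of class \code{detection_matrix}: list with
#'   \code{peptides} (row metadata), \code{samples}, logical matrix
#'   \code{detected}, integer matrix \code{support}, numeric matrix
#'   \code{intensity}, and \code{consensus}.
#' @export
build_detection_matrix <- function(events, panel, designs, consensus = 1L) {
  consensus <- as.integer(consensus)
  if (consensus < 1L) stop("consensus must be >= 1", call. = FALSE)
  if (any(designs$replicate_count < consensus)) {
    stop("consensus exceeds replicate_count for sample(s): ",
         paste(designs$sample_id[designs$replicate_count < consensus],
               collapse = ", "), call. = FALSE)
  }
  if (nrow(events)) {
    unknown <- setdiff(unique(events$sample_id), designs$sample_id)
    if (length(unknown)) {
      stop("event references unknown sample(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  meta_cols <- intersect(c("peptide", "species", "protein", "accession"),
                         names(panel))
  peptides <- unique(as.data.frame(panel)[, meta_cols, drop = FALSE])
  rownames(peptides) <- NULL
  samples <- designs$sample_id
  np <- nrow(peptides); ns <- length(samples)
  support <- matrix(0L, np, ns, dimnames = list(peptides$peptide, samples))
  intensity <- matrix(0, np, ns, dimnames = list(peptides$peptide, samples))
  if (nrow(events)) {
    key <- paste(events$peptide, events$species, sep = "\r")
    pkey <- paste(peptides$peptide, peptides$species, sep = "\r")
    ridx <- match(key, pkey)
    cidx <- match(events$sample_id, samples)
    ok <- !is.na(ridx)
    for (e in which(ok)) {
      intensity[ridx[e], cidx[e]] <- intensity[ridx[e], cidx[e]] +
        events$intensity[e]
    }
    # supporting replicates: distinct replicates with >= 1 event
    rep_key <- paste(ridx, cidx, events$replicate, sep = "\r")[ok]
    first <- !duplicated(rep_key)
    idx <- cbind(ridx[ok][first], cidx[ok][first])
    for (j in seq_len(nrow(idx))) {
      support[idx[j, 1L], idx[j, 2L]] <- support[idx[j, 1L], idx[j, 2L]] + 1L
    }
  }
  intensity <- sweep(intensity, 2L, designs$replicate_count, "/")
  structure(list(peptides = peptides, samples = samples,
                 detected = support >= consensus, support = support,
                 intensity = intensity, consensus = consensus),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("detection matrix: %d peptides x %d samples (consensus >= %d)\n",
              nrow(x$peptides), length(x$samples), x$consensus))
  tab <- x$peptides
  for (s in x$samples) tab[[s]] <- ifelse(x$detected[, s], "+", ".")
  print(utils::head(tab, 20L), ...)
  if (nrow(tab) > 20L) cat("...", nrow(tab) - 20L, "more rows\n")
  invisible(x)
}

# union length of 0-based half-open intervals
interval_union_length <- function(start, end) {
  if (!length(start)) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0L; cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  total + (cur_e - cur_s)
}

#' Protein-level rollup of a detection matrix
#'
#' Per (protein, sample): number of detected panel peptides, summed cell
#' intensity, and — when parent sequences are supplied — sequence coverage as
#' the residue-interval union of all detected peptides' occurrences divided
#' by parent length (percent). Coverage without a parent sequence is
#' \code{NA}, not an error.
#'
#' @param matrix A \code{detection_matrix}.
#' @param panel Marker panel (maps peptides to proteins).
#' @param parents Optional protein records providing parent sequences
#'   (matched by \code{accession}/\code{identifier}).
#' @return data.frame: \code{protein}, \code{accession}, \code{species},
#'   \code{sample_id}, \code{n_matched_peptides}, \code{sequence_coverage},
#'   \code{total_intensity}.
#' @export
protein_rollup <- function(matrix, panel, parents = NULL) {
  stopifnot(inherits(matrix, "detection_matrix"))
  pep <- matrix$peptides
  if (!"protein" %in% names(pep)) {
    pep$protein <- panel$protein[match(pep$peptide, panel$peptide)]
  }
  groups <- unique(pep[, intersect(c("protein", "accession", "species"),
                                   names(pep)), drop = FALSE])
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- pep$protein == groups$protein[g] &
      (!"species" %in% names(groups) | pep$species == groups$species[g])
    parent_seq <- NULL
    if (!is.null(parents) && "accession" %in% names(groups)) {
      hit <- match(groups$accession[g], parents$identifier)
      if (!is.na(hit)) parent_seq <- parents$sequence[hit]
    }
    for (s in matrix$samples) {
      det <- matrix$detected[sel, s]
      dpep <- pep$peptide[sel][det]
      coverage <- NA_real_
      if (!is.null(parent_seq)) {
        spans <- lapply(unique(dpep), function(p) {
          m <- gregexpr(p, parent_seq, fixed = TRUE)[[1L]]
          if (m[1L] == -1L) return(NULL)
          cbind(m - 1L, m - 1L + nchar(p))
        })
        spans <- do.call(rbind, spans)
        coverage <- if (is.null(spans)) 0 else
          100 * interval_union_length(spans[, 1L], spans[, 2L]) /
            nchar(parent_seq)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein = groups$protein[g],
        accession = if ("accession" %in% names(groups))
          groups$accession[g] else NA_character_,
        species = if ("species" %in% names(groups))
          groups$species[g] else NA_character_,
        sample_id = s,
        n_matched_peptides = sum(det),
        sequence_coverage = coverage,
        total_intensity = sum(matrix$intensity[sel, s]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
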