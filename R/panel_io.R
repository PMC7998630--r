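# TSV readers/writers for the pipeline's tabular artifacts. All files are
# tab-separated with a fixed header line, decimal point, no thousands
# separators, so round-trips are bit-stable in tests.

PANEL_COLUMNS <- c("species", "protein", "accession", "peptide",
                   "modification", "neutral_mass", "missed_cleavages")

#' Validate a marker panel
#'
#' Checks column presence, canonical peptide sequences, duplicate
#' (species, peptide, modification) entries, and agreement of the stored
#' neutral mass with the mass recomputed from sequence and modification
#' state.
#'
#' @param panel A marker panel data.frame (see \code{\link{build_panel}}).
#' @param scheme \code{\link{modification_scheme}} used to recompute masses.
#' @param tol Maximum tolerated |stored - recomputed| mass discrepancy (Da).
#' @return The panel, invisibly; errors describe the first violation.
#' @export
validate_panel <- function(panel, scheme = modification_scheme(),
                           tol = 1e-4) {
  missing <- setdiff(PANEL_COLUMNS, names(panel))
  if (length(missing)) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is_canonical_sequence(panel$peptide))) {
    stop("panel contains non-canonical peptide sequences", call. = FALSE)
  }
  key <- paste(panel$species, panel$peptide, panel$modification, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (species, peptide, modification) panel rows: ",
         panel$peptide[duplicated(key)][1L], call. = FALSE)
  }
  if (!nrow(panel)) return(invisible(panel))
  recomputed <- mapply(function(p, mod) {
    sites <- parse_mod_sites(mod)
    monoisotopic_mass(p, scheme, sites)
  }, panel$peptide, panel$modification)
  off <- abs(recomputed - panel$neutral_mass) > tol
  if (any(off)) {
    i <- which(off)[1L]
    stop(sprintf("panel mass for %s (mod '%s') disagrees with recomputed mass by %.3g Da",
                 panel$peptide[i], panel$modification[i],
                 abs(recomputed[i] - panel$neutral_mass[i])), call. = FALSE)
  }
  invisible(panel)
}

parse_mod_sites <- function(mod) {
  if (is.na(mod) || !nzchar(mod)) return(integer(0))
  as.integer(strsplit(mod, ",", fixed = TRUE)[[1L]])
}

#' Write / read a marker panel as TSV
#'
#' One peptide modification state per row; \code{read_panel(write_panel(x))}
#' is the identity for a valid panel. Reading validates the stored masses
#' against recomputation and rejects duplicate rows.
#'
#' @param panel Marker panel data.frame.
#' @param path File path.
#' @param scheme \code{\link{modification_scheme}} for mass validation.
#' @return \code{write_panel}: the path, invisibly. \code{read_panel}: the
#'   panel data.frame with class \code{marker_panel}.
#' @export
write_panel <- function(panel, path, scheme = modification_scheme()) {
  validate_panel(panel, scheme)
  out <- as.data.frame(panel)[, PANEL_COLUMNS]
  out$neutral_mass <- sprintf("%.6f", out$neutral_mass)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, scheme = modification_scheme()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing)) {
    stop("panel file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df)) {
    df$neutral_mass <- as.numeric(df$neutral_mass)
    df$missed_cleavages <- as.integer(df$missed_cleavages)
    df$modification[is.na(df$modification)] <- ""
  } else {
    df$neutral_mass <- numeric(0)
    df$missed_cleavages <- integer(0)
  }
  validate_panel(df, scheme)
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' Write / read observed LC-MS feature tables
#'
#' Columns: \code{sample_id}, \code{replicate}, \code{neutral_mass} (Da),
#' \code{intensity}, optional \code{retention_time} (minutes).
#'
#' @param features Feature data.frame.
#' @param path File path.
#' @return \code{write_features}: the path, invisibly; \code{read_features}:
#'   the validated data.frame.
#' @export
write_features <- function(features, path) {
  cols <- c("sample_id", "replicate", "neutral_mass", "intensity")
  stopifnot(all(cols %in% names(features)))
  if (!"retention_time" %in% names(features)) {
    features$retention_time <- NA_real_
  }
  out <- features[, c(cols, "retention_time")]
  out$neutral_mass <- sprintf("%.6f", out$neutral_mass)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  cols <- c("sample_id", "replicate", "neutral_mass", "intensity")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("feature file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"retention_time" %in% names(df)) df$retention_time <- NA_real_
  if (nrow(df)) {
    if (any(!is.finite(df$neutral_mass)) || any(df$neutral_mass <= 0)) {
      stop("neutral_mass must be positive and finite", call. = FALSE)
    }
    if (any(df$intensity < 0, na.rm = TRUE)) {
      stop("intensity must be non-negative", call. = FALSE)
    }
  }
  df$sample_id <- as.character(df$sample_id)
  df$replicate <- as.integer(df$replicate)
  df
}

#' Write / read dilution-series design tables
#'
#' Columns: \code{sample_id}, \code{spike_concentration} (% w/w),
#' \code{replicate_count}, \code{is_processed}. Nested compositions are not
#' serialized.
#'
#' @param designs Design data.frame (see \code{\link{load_paper_fixture}}).
#' @param path File path.
#' @return path / data.frame as for the other readers.
#' @export
write_designs <- function(designs, path) {
  cols <- c("sample_id", "spike_concentration", "replicate_count",
            "is_processed")
  stopifnot(all(cols %in% names(designs)))
  utils::write.table(as.data.frame(designs)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_designs
#' @export
read_designs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  cols <- c("sample_id", "spike_concentration", "replicate_count",
            "is_processed")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("design file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$spike_concentration < 0, na.rm = TRUE)) {
    stop("spike_concentration must be non-negative", call. = FALSE)
  }
  if (any(df$replicate_count < 1L)) {
    stop("replicate_count must be positive", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$replicate_count <- as.integer(df$replicate_count)
  df
}

#' Write a detection matrix as TSV
#'
#' One row per panel peptide: metadata columns then one \code{+}/\code{-}
#' presence column per sample (published-table layout), followed by
#' \code{<sample>_intensity} columns.
#'
#' @param x A \code{detection_matrix}.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_detection_matrix <- function(x, path) {
  stopifnot(inherits(x, "detection_matrix"))
  out <- x$peptides
  for (s in x$samples) out[[s]] <- ifelse(x$detected[, s], "+", "-")
  for (s in x$samples) {
    out[[paste0(s, "_intensity")]] <- sprintf("%.6g", x$intensity[, s])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
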