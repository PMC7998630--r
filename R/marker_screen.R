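#' Options controlling uniqueness screening
#'
#' @param collapse_IL Treat isoleucine and leucine as indistinguishable
#'   (isobaric in MS). Default \code{FALSE}: published markers are reported
#'   as distinct sequences, but note MS cannot tell I from L.
#' @param match_mode \code{"sequence-substring"} (default): a candidate is
#'   disqualified if its sequence occurs anywhere in a foreign protein, even
#'   where trypsin would not release it; \code{"digest-product"}: uniqueness
#'   is judged only against the tryptic products of foreign proteins.
#' @param rule \code{\link{cleavage_rule}} used for \code{"digest-product"}
#'   mode.
#' @return An object of class \code{uniqueness_options}.
#' @export
uniqueness_options <- function(collapse_IL = FALSE,
                               match_mode = c("sequence-substring",
                                              "digest-product"),
                               rule = cleavage_rule()) {
  match_mode <- match.arg(match_mode)
  structure(list(collapse_IL = isTRUE(collapse_IL), match_mode = match_mode,
                 rule = rule),
            class = "uniqueness_options")
}

collapse_il <- function(x) chartr("I", "L", x)

#' Screen candidate peptides for species uniqueness
#'
#' A candidate is species-unique when its sequence (under the chosen I/L
#' equivalence and match mode) occurs in no protein of any other species in
#' the taxon-tagged database. Same-species paralog occurrences are recorded
#' but do not break species-level uniqueness.
#'
#' @param candidates data.frame with at least columns \code{peptide} and
#'   \code{species} (e.g. output of \code{\link{cleave}} joined with its
#'   parent record, or a panel of published sequences).
#' @param database data.frame of protein records (\code{\link{read_fasta}}).
#' @param options \code{\link{uniqueness_options}}.
#' @return The candidate data.frame with added columns \code{unique}
#'   (logical), \code{n_foreign_hits}, \code{n_paralog_hits}; foreign and
#'   same-species occurrences are attached as a data.frame in attribute
#'   \code{"hits"} (columns: \code{candidate} row index, \code{hit_species},
#'   \code{hit_protein}, \code{foreign}).
#' @export
screen_uniqueness <- function(candidates, database,
                              options = uniqueness_options()) {
  stopifnot(all(c("peptide", "species") %in% names(candidates)))
  if (!nrow(database)) stop("database is empty", call. = FALSE)
  absent <- setdiff(unique(candidates$species), unique(database$species))
  if (length(absent)) {
    stop("candidate species absent from database: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  targets <- database$sequence
  if (options$match_mode == "digest-product") {
    targets <- vapply(database$sequence, function(s) {
      peps <- cleave(s, options$rule, min_length = 1L,
                     max_length = nchar(s))$peptide
      # spacer keeps substring search from matching across product borders
      paste(peps, collapse = "-")
    }, character(1), USE.NAMES = FALSE)
  }
  query <- candidates$peptide
  if (options$collapse_IL) {
    targets <- collapse_il(targets)
    query <- collapse_il(query)
  }
  hits <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    pat <- if (options$match_mode == "digest-product") {
      # whole-product match within the spacer-joined digest string
      sprintf("(^|-)%s(-|$)", query[i])
    } else query[i]
    hit <- if (options$match_mode == "digest-product") {
      grepl(pat, targets)
    } else grepl(pat, targets, fixed = TRUE)
    # every hit record; self-parent hits count as paralog evidence too
    if (any(hit)) {
      hits[[i]] <- data.frame(
        candidate = i,
        hit_species = database$species[hit],
        hit_protein = database$identifier[hit],
        foreign = database$species[hit] != candidates$species[i],
        stringsAsFactors = FALSE
      )
    }
  }
  hitdf <- if (length(h <- Filter(Negate(is.null), hits))) {
    do.call(rbind, h)
  } else {
    data.frame(candidate = integer(0), hit_species = character(0),
               hit_protein = character(0), foreign = logical(0))
  }
  n_foreign <- tabulate(hitdf$candidate[hitdf$foreign], nrow(candidates))
  n_paralog <- tabulate(hitdf$candidate[!hitdf$foreign], nrow(candidates))
  out <- candidates
  out$unique <- n_foreign == 0L
  out$n_foreign_hits <- n_foreign
  out$n_paralog_hits <- n_paralog
  attr(out, "hits") <- hitdf
  attr(out, "options") <- options
  out
}

#' Nearest same-length homolog windows of a candidate peptide
#'
#' For each foreign species, scans every same-length ungapped window of every
#' protein and reports the window with minimal Hamming distance to the
#' candidate, with per-position agreement marks (\code{*} conserved,
#' \code{.} different). Distance 0 occurs exactly when the candidate is
#' non-unique under the same options.
#'
#' @param peptide Candidate peptide sequence.
#' @param species Candidate's own species (its proteins are skipped).
#' @param database data.frame of protein records.
#' @param options \code{\link{uniqueness_options}} (only \code{collapse_IL}
#'   is honoured; the scan is always windowed).
#' @return data.frame with one row per foreign species: \code{species},
#'   \code{protein}, \code{window}, \code{distance}, \code{marks}; empty for
#'   an empty foreign database.
#' @export
nearest_homolog_report <- function(peptide, species, database,
                                   options = uniqueness_options()) {
  q <- split_residues(peptide, "peptide")
  if (options$collapse_IL) q <- chartr("I", "L", q)
  k <- length(q)
  foreign <- database[database$species != species, , drop = FALSE]
  rows <- list()
  for (sp in unique(foreign$species)) {
    sub <- foreign[foreign$species == sp, , drop = FALSE]
    best <- NULL
    for (j in seq_len(nrow(sub))) {
      chars <- strsplit(sub$sequence[j], "", fixed = TRUE)[[1L]]
      if (options$collapse_IL) chars <- chartr("I", "L", chars)
      n <- length(chars)
      if (n < k) next
      for (s in seq_len(n - k + 1L)) {
        w <- chars[s:(s + k - 1L)]
        d <- sum(w != q)
        if (is.null(best) || d < best$distance) {
          best <- list(protein = sub$identifier[j],
                       window = paste(substring(sub$sequence[j], s,
                                                s + k - 1L), collapse = ""),
                       distance = d,
                       marks = paste(ifelse(w == q, "*", "."), collapse = ""))
          if (d == 0L) break
        }
      }
      if (!is.null(best) && best$distance == 0L) break
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, protein = best$protein, window = best$window,
        distance = best$distance, marks = best$marks,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(species = character(0), protein = character(0),
                      window = character(0), distance = integer(0),
                      marks = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Assemble a marker panel from screened candidates
#'
#' Keeps species-unique candidates, expands variable-modification states
#' (\code{\link{enumerate_mod_states}}), groups rows by (species, protein),
#' and validates against duplicate entries. Uniqueness is a property of the
#' bare sequence; modification states inherit it.
#'
#' @param screened Output of \code{\link{screen_uniqueness}} (columns
#'   \code{peptide}, \code{species}, \code{unique}; optional \code{protein},
#'   \code{accession}, \code{missed_cleavages}).
#' @param scheme \code{\link{modification_scheme}} for state expansion.
#' @param expand_modifications Expand variable-modification states (default
#'   \code{TRUE}); if \code{FALSE} only the fixed-modification base state is
#'   kept.
#' @param provenance Free-text database name/version recorded on the panel.
#' @return A \code{marker_panel} data.frame (columns \code{species},
#'   \code{protein}, \code{accession}, \code{peptide}, \code{modification},
#'   \code{n_variable}, \code{neutral_mass}, \code{missed_cleavages}), with
#'   attribute \code{"provenance"}.
#' @export
build_panel <- function(screened, scheme = modification_scheme(),
                        expand_modifications = TRUE, provenance = "") {
  stopifnot(all(c("peptide", "species", "unique") %in% names(screened)))
  keep <- screened[screened$unique, , drop = FALSE]
  if (!"protein" %in% names(keep)) keep$protein <- NA_character_
  if (!"accession" %in% names(keep)) keep$accession <- keep$protein
  if (!"missed_cleavages" %in% names(keep)) {
    keep$missed_cleavages <- vapply(keep$peptide, function(p)
      is_tryptic(p)$missed_cleavages, integer(1), USE.NAMES = FALSE)
  }
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    states <- enumerate_mod_states(keep$peptide[i], scheme)
    if (!expand_modifications) states <- states[states$n_variable == 0L, ]
    data.frame(species = keep$species[i], protein = keep$protein[i],
               accession = keep$accession[i], peptide = states$peptide,
               modification = states$modification,
               n_variable = states$n_variable,
               neutral_mass = states$neutral_mass,
               missed_cleavages = keep$missed_cleavages[i],
               stringsAsFactors = FALSE)
  })
  panel <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), protein = character(0),
               accession = character(0), peptide = character(0),
               modification = character(0), n_variable = integer(0),
               neutral_mass = numeric(0), missed_cleavages = integer(0),
               stringsAsFactors = FALSE)
  key <- paste(panel$species, panel$peptide, panel$modification, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate panel entry: ", panel$peptide[duplicated(key)][1L],
         call. = FALSE)
  }
  panel <- panel[order(panel$species, panel$protein, panel$peptide,
                       panel$n_variable, panel$modification), ]
  rownames(panel) <- NULL
  attr(panel, "provenance") <- provenance
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Number of (species, protein) groups in a panel
#' @param panel A marker panel.
#' @return Integer count of distinct (species, protein) groups.
#' @export
panel_groups <- function(panel) {
  nrow(unique(as.data.frame(panel)[, c("species", "protein")]))
}
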