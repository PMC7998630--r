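#' Trypsin-style cleavage rule
#'
#' Describes a site-specific protease: cleavage occurs C-terminal to any
#' residue in \code{residues_after} unless the next residue is in
#' \code{blocked_next} (the Keil proline block for trypsin), with up to
#' \code{max_missed} internal sites left uncut.
#'
#' @param residues_after Residues after which the enzyme cuts (default K, R).
#' @param blocked_next Residues that suppress cleavage when they follow a site
#'   (default P; set to \code{character()} to disable the proline block).
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @return An object of class \code{cleavage_rule}.
#' @examples
#' cleavage_rule()                        # trypsin, Keil rule, <= 2 missed
#' cleavage_rule(blocked_next = character())  # trypsin without proline block
#' @export
cleavage_rule <- function(residues_after = c("K", "R"),
                          blocked_next = "P",
                          max_missed = 2L) {
  residues_after <- toupper(as.character(residues_after))
  blocked_next <- toupper(as.character(blocked_next))
  if (!all(residues_after %in% CANONICAL_RESIDUES)) {
    stop("residues_after must be canonical residue letters", call. = FALSE)
  }
  if (length(blocked_next) && !all(blocked_next %in% CANONICAL_RESIDUES)) {
    stop("blocked_next must be canonical residue letters", call. = FALSE)
  }
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) {
    stop("max_missed must be a non-negative integer", call. = FALSE)
  }
  structure(list(residues_after = residues_after,
                 blocked_next = blocked_next,
                 max_missed = max_missed),
            class = "cleavage_rule")
}

#' Fixed and variable modification scheme
#'
#' Maps residues to mass deltas. Fixed modifications apply to every eligible
#' residue; variable modifications are enumerated per peptide up to
#' \code{max_variable} sites. Defaults reproduce the common search setting of
#' fixed cysteine carbamidomethylation and variable methionine oxidation.
#'
#' @param fixed Named numeric vector, residue -> mass delta (Da).
#' @param variable Named numeric vector, residue -> mass delta (Da).
#' @param max_variable Maximum number of variable-modified sites per peptide.
#' @return An object of class \code{modification_scheme}.
#' @export
modification_scheme <- function(fixed = c(C = MASS_CARBAMIDOMETHYL),
                                variable = c(M = MASS_OXIDATION),
                                max_variable = 2L) {
  fixed <- unlist(fixed); variable <- unlist(variable)
  if (length(fixed) && (is.null(names(fixed)) || any(!nzchar(names(fixed))))) {
    stop("fixed modifications must be named by residue", call. = FALSE)
  }
  if (length(variable) &&
      (is.null(names(variable)) || any(!nzchar(names(variable))))) {
    stop("variable modifications must be named by residue", call. = FALSE)
  }
  if (any(!is.finite(c(fixed, variable)))) {
    stop("modification deltas must be finite", call. = FALSE)
  }
  overlap <- intersect(names(fixed), names(variable))
  if (length(overlap)) {
    stop("residue(s) ", paste(overlap, collapse = ", "),
         " carry both a fixed and a variable modification", call. = FALSE)
  }
  max_variable <- as.integer(max_variable)
  if (is.na(max_variable) || max_variable < 0L) {
    stop("max_variable must be a non-negative integer", call. = FALSE)
  }
  structure(list(fixed = fixed, variable = variable,
                 max_variable = max_variable),
            class = "modification_scheme")
}

# 1-based positions i such that cutting between residue i and i+1 is allowed.
cleavage_sites <- function(chars, rule) {
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% rule$residues_after)
  if (length(rule$blocked_next) && length(idx)) {
    idx <- idx[!chars[idx + 1L] %in% rule$blocked_next]
  }
  idx
}

#' In silico proteolytic digestion
#'
#' Enumerates every peptide bounded by cleavage sites of \code{rule}, for all
#' missed-cleavage counts from 0 to \code{rule$max_missed}, filtered to a
#' length window. Protein termini always count as peptide boundaries.
#'
#' @param protein Either a single sequence string or a one-row data.frame with
#'   columns \code{identifier}, \code{species}, \code{sequence} (a
#'   \code{\link{read_fasta}} record).
#' @param rule A \code{\link{cleavage_rule}}.
#' @param min_length,max_length Peptide length bounds (defaults 6 and 50;
#'   published food-marker peptides span roughly 8-27 residues).
#' @return data.frame with columns \code{protein}, \code{species},
#'   \code{start}, \code{end} (0-based half-open residue coordinates),
#'   \code{peptide}, \code{missed_cleavages}, \code{neutral_mass} (unmodified,
#'   fixed modifications not applied here).
#' @examples
#' cleave("MKAR", cleavage_rule(max_missed = 1), min_length = 1)
#' @export
cleave <- function(protein, rule = cleavage_rule(),
                   min_length = 6L, max_length = 50L) {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    id <- protein$identifier; sp <- protein$species
    sequence <- protein$sequence
  } else {
    id <- NA_character_; sp <- NA_character_
    sequence <- protein
  }
  min_length <- as.integer(min_length); max_length <- as.integer(max_length)
  if (min_length < 1L) stop("min_length must be >= 1", call. = FALSE)
  chars <- split_residues(sequence, "protein sequence")
  n <- length(chars)
  sites <- cleavage_sites(chars, rule)
  bounds <- c(0L, sites, n)          # cut points in 0-based coordinates
  nb <- length(bounds)
  out <- list(); k <- 0L
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + rule$max_missed)
    for (j in (i + 1L):jmax) {
      start <- bounds[i]; end <- bounds[j]
      len <- end - start
      if (len < min_length || len > max_length) next
      k <- k + 1L
      out[[k]] <- list(start = start, end = end,
                       missed = j - i - 1L)
    }
  }
  if (!k) {
    return(data.frame(protein = character(0), species = character(0),
                      start = integer(0), end = integer(0),
                      peptide = character(0), missed_cleavages = integer(0),
                      neutral_mass = numeric(0), stringsAsFactors = FALSE))
  }
  start <- vapply(out, `[[`, integer(1), "start")
  end <- vapply(out, `[[`, integer(1), "end")
  pep <- substring(paste(chars, collapse = ""), start + 1L, end)
  data.frame(
    protein = rep(id, k), species = rep(sp, k),
    start = start, end = end, peptide = pep,
    missed_cleavages = vapply(out, `[[`, integer(1), "missed"),
    neutral_mass = vapply(pep, function(p) sum(RESIDUE_MONO_MASS[
      strsplit(p, "", fixed = TRUE)[[1L]]]) + MASS_WATER, numeric(1),
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Check a peptide for consistency with a cleavage rule
#'
#' A peptide is tryptic-consistent when its C-terminal residue is a cleavage
#' residue (or the peptide is declared protein C-terminal) and, if the residue
#' preceding the peptide in its parent is known, that residue is a valid
#' cleavage context. Missed cleavages are internal cleavage residues not
#' followed by a blocking residue, the C-terminal one excluded.
#'
#' @param peptide Peptide sequence string.
#' @param preceding Optional residue letter immediately preceding the peptide
#'   in its parent (\code{NA} = unknown or protein N-terminus).
#' @param rule A \code{\link{cleavage_rule}}.
#' @param protein_terminal Set \code{TRUE} if the peptide ends at the parent's
#'   C-terminus (end of chain counts as a boundary).
#' @return List with elements \code{consistent} (logical) and
#'   \code{missed_cleavages} (integer).
#' @examples
#' is_tryptic("ISTVNSYNLPILR")          # consistent, 0 missed
#' is_tryptic("SQQCSETEIQRPVSQCQR")     # internal R before P: still 0 missed
#' @export
is_tryptic <- function(peptide, preceding = NA, rule = cleavage_rule(),
                       protein_terminal = FALSE) {
  chars <- split_residues(peptide, "peptide")
  n <- length(chars)
  cterm_ok <- chars[n] %in% rule$residues_after || isTRUE(protein_terminal)
  context_ok <- TRUE
  if (!is.na(preceding)) {
    preceding <- toupper(preceding)
    if (!preceding %in% CANONICAL_RESIDUES) {
      stop("preceding residue must be canonical", call. = FALSE)
    }
    context_ok <- preceding %in% rule$residues_after &&
      !(length(rule$blocked_next) && chars[1L] %in% rule$blocked_next)
  }
  missed <- length(cleavage_sites(chars, rule))
  list(consistent = cterm_ok && context_ok, missed_cleavages = missed)
}

#' Neutral monoisotopic peptide mass
#'
#' Residue monoisotopic masses plus one water, plus fixed-modification deltas
#' for every eligible residue and variable-modification deltas at the given
#' sites.
#'
#' @param peptide Peptide sequence string.
#' @param scheme A \code{\link{modification_scheme}}; \code{NULL} for the bare
#'   (unmodified) mass.
#' @param variable_sites Integer vector of 1-based positions carrying a
#'   variable modification; each must point at a residue with a variable
#'   entry in \code{scheme}.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("G", scheme = NULL)              # 75.03203
#' monoisotopic_mass("VQVVNHMGQK", variable_sites = 7)  # oxidised Met
#' @export
monoisotopic_mass <- function(peptide, scheme = modification_scheme(),
                              variable_sites = integer(0)) {
  chars <- split_residues(peptide, "peptide")
  m <- sum(RESIDUE_MONO_MASS[chars]) + MASS_WATER
  if (is.null(scheme)) {
    if (length(variable_sites)) {
      stop("variable_sites given without a modification scheme", call. = FALSE)
    }
    return(m)
  }
  stopifnot(inherits(scheme, "modification_scheme"))
  for (res in names(scheme$fixed)) {
    m <- m + scheme$fixed[[res]] * sum(chars == res)
  }
  variable_sites <- as.integer(variable_sites)
  if (length(variable_sites)) {
    if (anyDuplicated(variable_sites)) {
      stop("duplicate variable modification sites", call. = FALSE)
    }
    if (any(variable_sites < 1L | variable_sites > length(chars))) {
      stop("variable site out of range", call. = FALSE)
    }
    eligible <- chars[variable_sites] %in% names(scheme$variable)
    if (!all(eligible)) {
      bad <- variable_sites[!eligible][1L]
      stop(sprintf("variable modification at position %d targets residue '%s' with no variable entry",
                   bad, chars[bad]), call. = FALSE)
    }
    m <- m + sum(unlist(scheme$variable)[chars[variable_sites]])
  }
  m
}

#' Enumerate variable-modification states of a peptide
#'
#' One state per subset of variable-eligible sites of size at most
#' \code{scheme$max_variable}; fixed modifications are always applied.
#'
#' @param peptide Peptide sequence string.
#' @param scheme A \code{\link{modification_scheme}}.
#' @return data.frame with columns \code{peptide}, \code{modification}
#'   (comma-separated 1-based variable sites, \code{""} for none),
#'   \code{n_variable}, \code{neutral_mass}.
#' @examples
#' enumerate_mod_states("VQVVNHMGQK")  # one Met: 2 states
#' @export
enumerate_mod_states <- function(peptide, scheme = modification_scheme()) {
  chars <- split_residues(peptide, "peptide")
  sites <- which(chars %in% names(scheme$variable))
  base <- monoisotopic_mass(peptide, scheme)
  subsets <- list(integer(0))
  for (k in seq_len(min(length(sites), scheme$max_variable))) {
    # index-based combn: a length-1 `sites` must not be read as seq_len(n)
    combs <- utils::combn(seq_along(sites), k, simplify = FALSE)
    subsets <- c(subsets, lapply(combs, function(j) sites[j]))
  }
  data.frame(
    peptide = peptide,
    modification = vapply(subsets, function(s)
      paste(s, collapse = ","), character(1)),
    n_variable = vapply(subsets, length, integer(1)),
    neutral_mass = vapply(subsets, function(s)
      if (length(s)) base + sum(unlist(scheme$variable)[chars[s]]) else base,
      numeric(1)),
    stringsAsFactors = FALSE
  )
}
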