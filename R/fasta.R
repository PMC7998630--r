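#' Read a taxon-tagged protein FASTA
#'
#' Headers must carry an identifier (first whitespace-delimited token) and a
#' species tag: either a \code{species=<binomial>} key anywhere in the
#' description, or a bracketed binomial at the end of the header
#' (\code{[Genus species]}). Sequences are uppercased and validated against
#' the 20 canonical residues.
#'
#' @param path Path to a FASTA file.
#' @param strict If \code{TRUE} (default) a non-canonical residue or an
#'   unresolvable species is an error naming the record and position; if
#'   \code{FALSE}, offending records are flagged, excluded from the returned
#'   set, and reported via warning.
#' @return data.frame with columns \code{identifier}, \code{species},
#'   \code{description}, \code{sequence}, in file order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (!length(seqs)) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(data.frame(identifier = character(0), species = character(0),
                      description = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  headers <- names(seqs)
  if (is.null(headers) || any(!nzchar(headers))) {
    stop("malformed header: FASTA entry without a header line in ", path,
         call. = FALSE)
  }
  recs <- lapply(seq_along(seqs), function(i) {
    header <- headers[i]
    identifier <- sub("\\s.*$", "", header)
    description <- strip_species_tag(sub("^\\S+\\s*", "", header))
    species <- parse_species_tag(header)
    sequence <- toupper(as.character(seqs[[i]]))
    ok <- TRUE
    if (is.na(species)) {
      if (strict) {
        stop(sprintf("malformed header for record %d ('%s'): no species tag",
                     i, identifier), call. = FALSE)
      }
      ok <- FALSE
    }
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% CANONICAL_RESIDUES)
    if (length(bad)) {
      if (strict) {
        stop(sprintf("non-canonical residue '%s' at position %d of record '%s'",
                     chars[bad[1L]], bad[1L], identifier), call. = FALSE)
      }
      ok <- FALSE
    }
    if (!nzchar(sequence)) {
      if (strict) stop("empty sequence for record '", identifier, "'",
                       call. = FALSE)
      ok <- FALSE
    }
    list(identifier = identifier, species = species,
         description = description, sequence = sequence, ok = ok)
  })
  ok <- vapply(recs, `[[`, logical(1), "ok")
  if (any(!ok)) {
    warning(sum(!ok), " record(s) flagged and excluded (non-canonical ",
            "residues or missing species tag)", call. = FALSE)
    recs <- recs[ok]
  }
  out <- data.frame(
    identifier = vapply(recs, `[[`, character(1), "identifier"),
    species = vapply(recs, `[[`, character(1), "species"),
    description = vapply(recs, `[[`, character(1), "description"),
    sequence = vapply(recs, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out[, c("identifier", "species")])
  if (any(dup)) {
    stop("duplicate (identifier, species) records: ",
         paste(out$identifier[dup], collapse = ", "), call. = FALSE)
  }
  out
}

# species=<binomial> key wins (last field of the header; value runs to the
# end of the line); fallback to a trailing bracketed binomial [Genus species].
parse_species_tag <- function(header) {
  if (grepl("(^|\\s)species=", header)) {
    sp <- trimws(sub("^.*(^|\\s)species=", "", header))
    if (nzchar(sp)) return(sp)
    return(NA_character_)
  }
  m <- regmatches(header, regexpr("\\[([^][]+)\\]\\s*$", header))
  if (length(m)) {
    sp <- trimws(gsub("^\\[|\\]\\s*$", "", m[1L]))
    if (nzchar(sp)) return(sp)
  }
  NA_character_
}

# Strip the species tag / trailing bracket from a description string.
strip_species_tag <- function(description) {
  description <- sub("(^|\\s)species=.*$", "", description)
  description <- sub("\\[([^][]+)\\]\\s*$", "", description)
  trimws(description)
}

#' Write protein records to FASTA
#'
#' Inverse of \code{\link{read_fasta}}: headers are written as
#' \code{identifier description species=<species>} (the species tag is the
#' last header field by convention, since a binomial contains whitespace).
#'
#' @param records data.frame as returned by \code{\link{read_fasta}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("identifier", "species", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  desc <- ifelse(is.na(desc) | !nzchar(desc), "", paste0(" ", desc))
  headers <- sprintf("%s%s species=%s", records$identifier, desc,
                     records$species)
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
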