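# Monoisotopic mass constants (Da). Residue masses are for the residue as it
# appears in a peptide chain (amino acid minus water); peptide neutral mass is
# the residue sum plus one water.

#' Canonical amino-acid residue letters
#'
#' The twenty canonical one-letter residue codes accepted throughout the
#' package. Ambiguity/rare codes (B, J, O, U, X, Z) are rejected by the strict
#' FASTA reader and by all mass computations.
#'
#' @format Character vector of length 20.
#' @export
CANONICAL_RESIDUES <- c(
  "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Residue monoisotopic masses, 6 decimal places.
RESIDUE_MONO_MASS <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Monoisotopic mass of water (Da)
#' @export
MASS_WATER <- 18.010565

#' Carbamidomethylation mass delta (Da)
#'
#' Fixed cysteine modification introduced by iodoacetamide alkylation.
#' @export
MASS_CARBAMIDOMETHYL <- 57.021464

#' Methionine oxidation mass delta (Da)
#' @export
MASS_OXIDATION <- 15.994915

# Split a sequence string into residue letters, validating canonicity.
# Returns the character vector or stops naming the offending position.
split_residues <- function(sequence, context = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop(context, " must be a non-empty character string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% CANONICAL_RESIDUES)
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], context), call. = FALSE)
  }
  chars
}

is_canonical_sequence <- function(sequence) {
  grepl(sprintf("^[%s]+$", paste(CANONICAL_RESIDUES, collapse = "")),
        toupper(sequence))
}
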