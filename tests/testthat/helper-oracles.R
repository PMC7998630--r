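# Independent oracles used across the suite. These deliberately share no
# code with the package: masses come from element compositions and atomic
# masses, digestion from exhaustive substring enumeration, and least squares
# from the closed-form normal equations.

# Atomic monoisotopic masses (CODATA / IUPAC values).
ORACLE_ATOM <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
                 O = 15.9949146196, S = 31.97207100)

# Residue elemental compositions (residue = amino acid minus water), H C N O S
ORACLE_FORMULA <- list(
  G = c(3, 2, 1, 1, 0),  A = c(5, 3, 1, 1, 0),  S = c(5, 3, 1, 2, 0),
  P = c(7, 5, 1, 1, 0),  V = c(9, 5, 1, 1, 0),  T = c(7, 4, 1, 2, 0),
  C = c(5, 3, 1, 1, 1),  L = c(11, 6, 1, 1, 0), I = c(11, 6, 1, 1, 0),
  N = c(6, 4, 2, 2, 0),  D = c(5, 4, 1, 3, 0),  Q = c(8, 5, 2, 2, 0),
  K = c(12, 6, 2, 1, 0), E = c(7, 5, 1, 3, 0),  M = c(9, 5, 1, 1, 1),
  H = c(7, 6, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(12, 6, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(10, 11, 2, 1, 0)
)

# Neutral monoisotopic mass from element counts: residues + water, plus
# carbamidomethyl (C2H3NO) per cysteine if fixed_cam, plus one O per
# oxidised site.
oracle_mass <- function(peptide, fixed_cam = TRUE, n_ox = 0L) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  counts <- Reduce(`+`, ORACLE_FORMULA[chars])  # H C N O S
  counts <- counts + c(2, 0, 0, 1, 0)           # water
  if (fixed_cam) counts <- counts + sum(chars == "C") * c(3, 2, 1, 1, 0)
  counts[4] <- counts[4] + n_ox
  sum(counts * ORACLE_ATOM[c("H", "C", "N", "O", "S")])
}

# Brute-force digestion: every substring whose ends are valid cleavage
# boundaries and whose internal missed-cleavage count is within bounds.
oracle_cleave <- function(sequence, residues_after = c("K", "R"),
                          blocked_next = "P", max_missed = 2L,
                          min_length = 1L, max_length = nchar(sequence)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  is_site <- function(i) {            # cut allowed after residue i
    i >= 1L && i < n && chars[i] %in% residues_after &&
      !(length(blocked_next) && chars[i + 1L] %in% blocked_next)
  }
  rows <- list()
  for (a in 0:(n - 1L)) {
    if (!(a == 0L || is_site(a))) next
    for (b in (a + 1L):n) {
      if (!(b == n || is_site(b))) next
      len <- b - a
      if (len < min_length || len > max_length) next
      internal <- if (b - a >= 2L) sum(vapply((a + 1L):(b - 1L), is_site,
                                              logical(1))) else 0L
      if (internal > max_missed) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = a, end = b,
        peptide = paste(chars[(a + 1L):b], collapse = ""),
        missed_cleavages = internal, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      peptide = character(0), missed_cleavages = integer(0)))
  }
  do.call(rbind, rows)
}

# Closed-form ordinary least squares and squared Pearson correlation.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = if (syy == 0) 0 else sxy^2 / (sxx * syy))
}

random_protein <- function(n) {
  paste(sample(pepmarker::CANONICAL_RESIDUES, n, replace = TRUE),
        collapse = "")
}

# Canonical digest comparison key, order-independent
digest_key <- function(df) {
  sort(paste(df$start, df$end, df$peptide, df$missed_cleavages, sep = ":"))
}

# Two-protein, one-peptide-each toy panel for simulation tests
two_protein_panel <- function() {
  cand <- data.frame(peptide = c("AVLDTGSK", "GFPLDTIR"),
                     species = "SpA", protein = c("high", "low"),
                     unique = TRUE, stringsAsFactors = FALSE)
  pepmarker::build_panel(cand, expand_modifications = FALSE)
}

series_designs <- function(conc = c(0, 0.9, 2.6, 4.2, 7.4), nrep = 3L) {
  data.frame(sample_id = paste0("S", seq_along(conc)),
             spike_concentration = conc, replicate_count = nrep,
             is_processed = TRUE, stringsAsFactors = FALSE)
}

# All published marker peptides (hemp matrix + meat + sunflower)
all_fixture_peptides <- function() {
  fix <- pepmarker::load_paper_fixture()
  unique(c(fix$hemp_matrix$peptide, fix$meat_attributions$peptide,
           fix$sunflower_peptides$peptide))
}
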