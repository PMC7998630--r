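toy_panel <- function(masses, peptides = NULL) {
  n <- length(masses)
  if (is.null(peptides)) peptides <- paste0(strrep("A", 3), seq_len(n), "K")
  structure(data.frame(
    species = "SpA", protein = "p1", accession = "p1",
    peptide = peptides, modification = "", n_variable = 0L,
    neutral_mass = masses, missed_cleavages = 0L,
    stringsAsFactors = FALSE), class = c("marker_panel", "data.frame"))
}

feature_row <- function(mass, sample = "S1", rep = 1L, intensity = 1e6) {
  data.frame(sample_id = sample, replicate = rep, neutral_mass = mass,
             intensity = intensity, retention_time = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("ppm matching applies the tolerance window symmetrically", {
  panel <- toy_panel(1000)
  ev <- match_features(feature_row(1000.005), panel, 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mass_error_ppm, 5, tolerance = 1e-9)
  expect_equal(nrow(match_features(feature_row(1000.0101), panel, 10)), 0L)
  expect_equal(match_features(feature_row(999.995), panel, 10)$mass_error_ppm,
               -5, tolerance = 1e-9)
  expect_error(match_features(feature_row(1000), panel, 0), "positive")
})

test_that("a feature is assigned once, to the minimal |ppm| state", {
  panel <- toy_panel(c(999.99800, 1000.00100), c("AAK", "CCK"))
  ev <- match_features(feature_row(1000.00000), panel, 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$theoretical_mass, 1000.00100)  # |1 ppm| beats |2 ppm|
  # isobaric states (I/L swap) tie on |ppm| and mass: lexicographic order
  m <- monoisotopic_mass("AALK")
  panel2 <- toy_panel(c(m, m), c("AALK", "AAIK"))
  ev2 <- match_features(feature_row(m), panel2, 10)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$peptide, "AAIK")
})

test_that("shrinking the tolerance never adds events", {
  set.seed(3)
  panel <- toy_panel(sort(runif(20, 800, 2500)))
  feats <- do.call(rbind, lapply(runif(100, 800, 2500), feature_row))
  tols <- c(50, 20, 10, 5, 1)
  counts <- vapply(tols, function(t)
    nrow(match_features(feats, panel, t)), integer(1))
  expect_true(all(diff(counts) <= 0L))
  # self-audit: every reported event is inside its tolerance
  ev <- match_features(feats, panel, 10)
  if (nrow(ev)) {
    recomputed <- (ev$neutral_mass - ev$theoretical_mass) /
      ev$theoretical_mass * 1e6
    expect_equal(recomputed, ev$mass_error_ppm, tolerance = 1e-12)
    expect_true(all(abs(recomputed) <= 10))
  }
})

test_that("detection matrix enforces the replicate consensus", {
  panel <- toy_panel(1000)
  designs <- data.frame(sample_id = "S1", spike_concentration = 1,
                        replicate_count = 3L, is_processed = TRUE)
  ev1 <- match_features(feature_row(1000, rep = 1L), panel, 10)
  dm1 <- build_detection_matrix(ev1, panel, designs, consensus = 2L)
  expect_false(any(dm1$detected))       # 1 of 3 replicates < consensus 2
  ev2 <- rbind(ev1, match_features(feature_row(1000.001, rep = 2L),
                                   panel, 10))
  dm2 <- build_detection_matrix(ev2, panel, designs, consensus = 2L)
  expect_true(all(dm2$detected))
  expect_equal(unname(dm2$support[1, 1]), 2L)
  # intensity: per-replicate sums averaged over the replicate count
  expect_equal(unname(dm2$intensity[1, 1]), 2e6 / 3)
  # no events: all cells absent
  dm0 <- build_detection_matrix(ev1[0, ], panel, designs)
  expect_false(any(dm0$detected))
  expect_error(build_detection_matrix(
    match_features(feature_row(1000, sample = "??"), panel, 10),
    panel, designs), "unknown sample")
  expect_error(build_detection_matrix(ev1, panel, designs, consensus = 4L),
               "consensus")
})

test_that("protein rollup computes interval-union coverage", {
  # parent of length 20; detected peptides MK and AAAAAAAK cover [0,10)
  parent <- data.frame(identifier = "p1", species = "SpA", description = "",
                       sequence = "MKAAAAAAAKGGGGGRTTTR",
                       stringsAsFactors = FALSE)
  panel <- structure(data.frame(
    species = "SpA", protein = "p1", accession = "p1",
    peptide = c("MK", "AAAAAAAK"), modification = "", n_variable = 0L,
    neutral_mass = c(monoisotopic_mass("MK"),
                     monoisotopic_mass("AAAAAAAK")),
    missed_cleavages = 0L, stringsAsFactors = FALSE),
    class = c("marker_panel", "data.frame"))
  designs <- data.frame(sample_id = "S1", spike_concentration = 1,
                        replicate_count = 1L, is_processed = TRUE)
  ev <- match_features(rbind(feature_row(monoisotopic_mass("MK")),
                             feature_row(monoisotopic_mass("AAAAAAAK"))),
                       panel, 10)
  dm <- build_detection_matrix(ev, panel, designs)
  ru <- protein_rollup(dm, panel, parent)
  expect_equal(ru$n_matched_peptides, 2L)
  expect_equal(ru$sequence_coverage, 100 * 10 / 20)  # residues 0-9 of 20
  # coverage undefined without a parent sequence, not an error
  ru2 <- protein_rollup(dm, panel)
  expect_true(is.na(ru2$sequence_coverage))
  expect_equal(ru2$n_matched_peptides, 2L)
})

test_that("overlapping peptides are unioned, not summed", {
  parent <- data.frame(identifier = "p1", species = "SpA", description = "",
                       sequence = "AAAAKAAAAGGGGGRTTTTT",  # length 20
                       stringsAsFactors = FALSE)
  panel <- structure(data.frame(
    species = "SpA", protein = "p1", accession = "p1",
    peptide = c("AAAAK", "AAAAKAAAAGGGGGR"), modification = "",
    n_variable = 0L,
    neutral_mass = c(monoisotopic_mass("AAAAK"),
                     monoisotopic_mass("AAAAKAAAAGGGGGR")),
    missed_cleavages = c(0L, 1L), stringsAsFactors = FALSE),
    class = c("marker_panel", "data.frame"))
  designs <- data.frame(sample_id = "S1", spike_concentration = 1,
                        replicate_count = 1L, is_processed = TRUE)
  ev <- match_features(rbind(
    feature_row(monoisotopic_mass("AAAAK")),
    feature_row(monoisotopic_mass("AAAAKAAAAGGGGGR"))), panel, 10)
  dm <- build_detection_matrix(ev, panel, designs)
  ru <- protein_rollup(dm, panel, parent)
  # spans [0,5) and [0,15): union 15 of 20 residues
  expect_equal(ru$sequence_coverage, 75)
})

test_that("rollup counts equal a brute-force recount of the matrix", {
  fix <- load_paper_fixture()
  dm <- fixture_detection_matrix(fix, include_meat = FALSE)
  panel <- fixture_panel(fix, include_meat = FALSE)
  ru <- protein_rollup(dm, panel)
  for (i in seq_len(nrow(ru))) {
    sel <- dm$peptides$protein == ru$protein[i]
    expect_equal(ru$n_matched_peptides[i],
                 sum(dm$detected[sel, ru$sample_id[i]]))
  }
  # published pattern: edestin 1 detected in M1, 7S vicilin-like is not
  e1 <- subset(ru, protein == "edestin 1" & sample_id == "M1")
  v7 <- subset(ru, protein == "7S vicilin-like protein" & sample_id == "M1")
  expect_gte(e1$n_matched_peptides, 1L)
  expect_equal(v7$n_matched_peptides, 0L)
})
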