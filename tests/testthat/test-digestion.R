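test_that("cleave enumerates tryptic peptides with missed cleavages", {
  out <- cleave("MKAR", cleavage_rule(max_missed = 1L), min_length = 1L)
  expect_setequal(out$peptide, c("MK", "AR", "MKAR"))
  expect_equal(out$missed_cleavages[match(c("MK", "AR", "MKAR"),
                                          out$peptide)], c(0L, 0L, 1L))
  # K before P is not a cleavage site
  out <- cleave("MKPAR", cleavage_rule(), min_length = 1L)
  expect_equal(out$peptide, "MKPAR")
  expect_equal(out$missed_cleavages, 0L)
  # no duplicate coordinates; coordinates slice the parent
  out <- cleave("MKARKKTR", cleavage_rule(), min_length = 1L)
  expect_false(anyDuplicated(out[, c("start", "end")]) > 0L)
  expect_equal(substring("MKARKKTR", out$start + 1L, out$end), out$peptide)
})

test_that("cleave matches brute-force enumeration on random sequences", {
  set.seed(42)
  for (i in 1:60) {
    seq <- random_protein(sample(5:40, 1L))
    for (mm in 0:2) {
      for (block in list("P", character(0))) {
        got <- cleave(seq, cleavage_rule(blocked_next = block,
                                         max_missed = mm),
                      min_length = 1L, max_length = nchar(seq))
        want <- oracle_cleave(seq, blocked_next = block, max_missed = mm)
        expect_identical(digest_key(got), digest_key(want),
                         info = sprintf("%s mm=%d block=%d", seq, mm,
                                        length(block)))
      }
    }
  }
})

test_that("cleave honours the peptide length window", {
  seq <- "MKARKKTRGGGGGGK"
  got <- cleave(seq, cleavage_rule(), min_length = 6L, max_length = 8L)
  expect_true(all(nchar(got$peptide) >= 6L & nchar(got$peptide) <= 8L))
  want <- oracle_cleave(seq, min_length = 6L, max_length = 8L)
  expect_identical(digest_key(got), digest_key(want))
})

test_that("is_tryptic validates published marker sequences", {
  r <- is_tryptic("ISTVNSYNLPILR")
  expect_true(r$consistent); expect_equal(r$missed_cleavages, 0L)
  # internal R precedes P: masked by the proline block
  r <- is_tryptic("SQQCSETEIQRPVSQCQR")
  expect_true(r$consistent); expect_equal(r$missed_cleavages, 0L)
  r <- is_tryptic("SQQCSETEIQRPVSQCQR",
                  rule = cleavage_rule(blocked_next = character()))
  expect_true(r$consistent); expect_equal(r$missed_cleavages, 1L)
  # no tryptic C-terminus
  expect_false(is_tryptic("AAAA")$consistent)
  expect_true(is_tryptic("AAAA", protein_terminal = TRUE)$consistent)
  # preceding-residue context
  expect_true(is_tryptic("AK", preceding = "R")$consistent)
  expect_false(is_tryptic("AK", preceding = "G")$consistent)
  expect_false(is_tryptic("PK", preceding = "R")$consistent)
  expect_error(is_tryptic("AB2K"), "non-canonical")
})

test_that("every published marker peptide is tryptic with <= 2 missed cleavages", {
  for (p in all_fixture_peptides()) {
    r <- is_tryptic(p)
    expect_true(r$consistent, info = p)
    expect_lte(r$missed_cleavages, 2L)
  }
})

test_that("monoisotopic mass agrees with the element-composition oracle", {
  expect_equal(monoisotopic_mass("G", scheme = NULL), 75.03203,
               tolerance = 1e-4)
  # fixed carbamidomethyl adds one delta per cysteine
  with_cam <- monoisotopic_mass("CPALEMEIQK")
  without <- monoisotopic_mass("CPALEMEIQK", scheme = NULL)
  expect_equal(with_cam - without, 57.02146, tolerance = 1e-5)
  # variable oxidation adds one delta at a Met site
  ox <- monoisotopic_mass("VQVVNHMGQK", variable_sites = 7L)
  expect_equal(ox - monoisotopic_mass("VQVVNHMGQK"), 15.99491,
               tolerance = 1e-5)
  for (p in c("VQVVNHMGQK", "CPALEMEIQK", "GQFGGQEMDIAR",
              "SQQCSETEIQRPVSQCQR", "LSADTEVVCGAPAIYLDFAR")) {
    expect_equal(monoisotopic_mass(p), oracle_mass(p), tolerance = 1e-4,
                 info = p)
  }
})

test_that("mass is additive and permutation-invariant", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_protein(sample(3:15, 1L))
    b <- random_protein(sample(3:15, 1L))
    expect_equal(monoisotopic_mass(paste0(a, b), scheme = NULL),
                 monoisotopic_mass(a, scheme = NULL) +
                   monoisotopic_mass(b, scheme = NULL) - MASS_WATER,
                 tolerance = 1e-9)
    perm <- paste(sample(strsplit(a, "")[[1L]]), collapse = "")
    expect_equal(monoisotopic_mass(perm, scheme = NULL),
                 monoisotopic_mass(a, scheme = NULL), tolerance = 1e-12)
  }
})

test_that("mass computation rejects invalid modification sites", {
  expect_error(monoisotopic_mass("GAK", variable_sites = 2L),
               "no variable entry")
  expect_error(monoisotopic_mass("GAK", variable_sites = 9L), "out of range")
  expect_error(monoisotopic_mass("GAXK"), "non-canonical")
  expect_error(modification_scheme(fixed = c(M = 1), variable = c(M = 2)),
               "both a fixed and a variable")
})

test_that("modification state enumeration counts subsets up to the cap", {
  expect_equal(nrow(enumerate_mod_states("GAK")), 1L)   # no Met
  # a single Met gives exactly two states at its own position
  one_met <- enumerate_mod_states("VQVVNHMGQK")
  expect_equal(nrow(one_met), 2L)
  expect_setequal(one_met$modification, c("", "7"))
  two_met <- enumerate_mod_states("MGMK",
                                  modification_scheme(max_variable = 2L))
  expect_equal(nrow(two_met), 4L)                        # {} {1} {3} {1,3}
  capped <- enumerate_mod_states("NGMMAPHFNLDSHSVIYVTR",
                                 modification_scheme(max_variable = 1L))
  expect_equal(nrow(capped), 3L)
  deltas <- sort(capped$neutral_mass - min(capped$neutral_mass))
  expect_equal(deltas, c(0, 15.994915, 15.994915), tolerance = 1e-6)
  expect_equal(capped$neutral_mass[capped$modification == ""],
               oracle_mass("NGMMAPHFNLDSHSVIYVTR"), tolerance = 1e-4)
})
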