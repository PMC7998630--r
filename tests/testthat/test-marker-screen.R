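make_db <- function(...) {
  recs <- list(...)
  data.frame(
    identifier = vapply(recs, `[[`, character(1), 1L),
    species = vapply(recs, `[[`, character(1), 2L),
    description = "",
    sequence = vapply(recs, `[[`, character(1), 3L),
    stringsAsFactors = FALSE)
}

test_that("screen_uniqueness flags cross-species occurrences", {
  db <- make_db(list("a1", "SpA", "GGGAAAKGGG"),
                list("b1", "SpB", "TTTAAAKTTT"))
  cand <- data.frame(peptide = "AAAK", species = "SpA",
                     stringsAsFactors = FALSE)
  res <- screen_uniqueness(cand, db)
  expect_false(res$unique)
  expect_equal(res$n_foreign_hits, 1L)
  hits <- attr(res, "hits")
  expect_equal(hits$hit_species[hits$foreign], "SpB")
  # same-species paralogs do not break species uniqueness
  db2 <- make_db(list("a1", "SpA", "GGGAAAKGGG"),
                 list("a2", "SpA", "CCCAAAKCCC"),
                 list("b1", "SpB", "TTTTTT"))
  res2 <- screen_uniqueness(cand, db2)
  expect_true(res2$unique)
  expect_gte(res2$n_paralog_hits, 1L)
  expect_error(screen_uniqueness(
    data.frame(peptide = "AAAK", species = "SpZ"), db), "absent")
})

test_that("I/L collapse and digest-product mode change uniqueness", {
  db <- make_db(list("a1", "SpA", "GGILKGG"),
                list("b1", "SpB", "GGLIKGG"))
  cand <- data.frame(peptide = "ILK", species = "SpA",
                     stringsAsFactors = FALSE)
  expect_true(screen_uniqueness(cand, db,
                                uniqueness_options(collapse_IL = FALSE))$unique)
  expect_false(screen_uniqueness(cand, db,
                                 uniqueness_options(collapse_IL = TRUE))$unique)
  # peptide embedded in a foreign protein where trypsin cannot release it:
  # disqualified by substring mode, allowed by digest-product mode
  db3 <- make_db(list("a1", "SpA", "GGGAAKGG"),
                 list("b1", "SpB", "TTAAKPTT"))  # K followed by P
  cand3 <- data.frame(peptide = "AAK", species = "SpA",
                      stringsAsFactors = FALSE)
  expect_false(screen_uniqueness(
    cand3, db3, uniqueness_options(match_mode = "sequence-substring"))$unique)
  expect_true(screen_uniqueness(
    cand3, db3, uniqueness_options(match_mode = "digest-product"))$unique)
})

test_that("uniqueness is sound and monotone on random databases", {
  set.seed(11)
  for (rep in 1:20) {
    nprot <- sample(5:20, 1L)
    db <- data.frame(
      identifier = paste0("p", seq_len(nprot)),
      species = sample(c("SpA", "SpB", "SpC"), nprot, replace = TRUE),
      description = "",
      sequence = vapply(seq_len(nprot), function(i)
        random_protein(sample(30:120, 1L)), character(1)),
      stringsAsFactors = FALSE)
    db$species[1L] <- "SpA"
    cands <- cleave(db[1L, ], cleavage_rule(), min_length = 4L,
                    max_length = 20L)
    if (!nrow(cands)) next
    cands <- cands[sample(nrow(cands), min(5L, nrow(cands))), ]
    res <- screen_uniqueness(cands, db)
    for (i in seq_len(nrow(res))) {
      foreign <- db[db$species != "SpA", , drop = FALSE]
      brute <- any(vapply(foreign$sequence, grepl,
                          logical(1), pattern = res$peptide[i],
                          fixed = TRUE, USE.NAMES = FALSE))
      expect_equal(res$unique[i], !brute)
    }
    # adding a protein can only flip unique -> not unique
    extra <- rbind(db, data.frame(identifier = "new", species = "SpB",
                                  description = "",
                                  sequence = random_protein(80)))
    res2 <- screen_uniqueness(cands, extra)
    expect_true(all(res$unique | !res2$unique | !res$unique))
    expect_true(all(res2$unique <= res$unique))
  }
})

test_that("nearest homolog report scans same-length windows", {
  db <- make_db(list("a1", "SpA", "AAAGGGKCCC"),
                list("b1", "SpB", "TTTGGAKTTT"))  # GGAK vs GGGK: 1 mismatch
  rep1 <- nearest_homolog_report("GGGK", "SpA", db)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$distance, 1L)
  expect_equal(rep1$window, "GGAK")
  expect_equal(rep1$marks, "**.*")
  # identical foreign window: distance 0 and screening must agree
  db0 <- make_db(list("a1", "SpA", "AAAGGGKCCC"),
                 list("b1", "SpB", "TTGGGKTT"))
  rep0 <- nearest_homolog_report("GGGK", "SpA", db0)
  expect_equal(rep0$distance, 0L)
  scr <- screen_uniqueness(data.frame(peptide = "GGGK", species = "SpA"),
                           db0)
  expect_false(scr$unique)
  # foreign protein differing at exactly two positions
  db2 <- make_db(list("a1", "SpA", "GAGAK"), list("b1", "SpB", "GTGTK"))
  rep2 <- nearest_homolog_report("GAGAK", "SpA", db2)
  expect_equal(rep2$distance, 2L)
  expect_equal(sum(strsplit(rep2$marks, "")[[1L]] == "."), 2L)
  # empty foreign database
  solo <- make_db(list("a1", "SpA", "AAAGGGKCCC"))
  expect_equal(nrow(nearest_homolog_report("GGGK", "SpA", solo)), 0L)
})

test_that("nearest-homolog distance is zero exactly when non-unique", {
  set.seed(23)
  for (rep in 1:10) {
    db <- data.frame(
      identifier = paste0("p", 1:6),
      species = rep(c("SpA", "SpB"), each = 3L),
      description = "",
      sequence = vapply(1:6, function(i) random_protein(60), character(1)),
      stringsAsFactors = FALSE)
    cands <- cleave(db[1L, ], cleavage_rule(), min_length = 4L,
                    max_length = 15L)
    if (!nrow(cands)) next
    res <- screen_uniqueness(cands, db)
    for (i in seq_len(min(nrow(res), 4L))) {
      rep_i <- nearest_homolog_report(res$peptide[i], "SpA", db)
      if (!nrow(rep_i)) next
      expect_equal(min(rep_i$distance) == 0L, !res$unique[i])
      if (res$unique[i]) expect_gte(min(rep_i$distance), 1L)
    }
  }
})

test_that("build_panel keeps unique candidates and groups by protein", {
  screened <- data.frame(
    peptide = c("AAAK", "CCCK", "DDDR", "EEEK", "FFFR"),
    species = "SpA",
    protein = c("p1", "p1", "p2", "p2", "p2"),
    unique = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  panel <- build_panel(screened, expand_modifications = FALSE)
  expect_equal(nrow(panel), 3L)
  expect_equal(panel_groups(panel), 2L)
  # modification expansion multiplies Met-containing rows
  met <- data.frame(peptide = "MAMK", species = "SpA", protein = "p1",
                    unique = TRUE, stringsAsFactors = FALSE)
  expanded <- build_panel(met, modification_scheme(max_variable = 2L))
  expect_equal(nrow(expanded), 4L)
  expect_error(build_panel(rbind(screened[1, ], screened[1, ])),
               "duplicate")
})

test_that("fixture panels have the published protein-group structure", {
  fix <- load_paper_fixture()
  hemp <- fixture_panel(fix, include_meat = FALSE)
  expect_equal(panel_groups(hemp), 5L)
  # sunflower peptides span three proteins
  sun <- data.frame(peptide = fix$sunflower_peptides$peptide,
                    species = fix$sunflower_peptides$species,
                    protein = fix$sunflower_peptides$protein,
                    unique = TRUE, stringsAsFactors = FALSE)
  expect_equal(panel_groups(build_panel(sun)), 3L)
  # hemp marker unique within the combined synthetic proteome
  db <- rbind(synthetic_hemp_proteome(), synthetic_meat_proteome())
  res <- screen_uniqueness(
    data.frame(peptide = "VQVVNHMGQK", species = "Cannabis sativa"), db)
  expect_true(res$unique)
})
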