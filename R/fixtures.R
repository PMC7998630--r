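# Verbatim in-memory encodings of the published hemp-meatball study tables:
# sample compositions and dilution design, the hemp peptide presence/absence
# matrix, per-protein identification statistics (opaque metadata from the
# vendor search engine: never recomputed here), meat peptide attributions,
# and the sunflower seed-storage peptides.

HEMP_PROTEINS <- data.frame(
  protein = c("edestin 1", "edestin 2", "edestin 3", "albumin",
              "7S vicilin-like protein"),
  accession = c("CDP79023.1", "CDP79028.1", "SNQ45160.1", "SNQ45151.1",
                "SNQ45153.2"),
  stringsAsFactors = FALSE
)

# peptide, protein, then presence flags for M1, M2, M3, M4, HC
HEMP_MATRIX_ROWS <- list(
  list("NAIYTPHWNVNAHSVMYVLR",        "edestin 1", 1,1,1,1,1),
  list("YLEEAFNVDSETVK",              "edestin 1", 1,1,1,1,1),
  list("YTIQQNGLHLPSYTNTPQLVYIVK",    "edestin 1", 1,1,1,1,1),
  list("ISTVNSYNLPILR",               "edestin 1", 1,1,1,1,1),
  list("VEAEAGLIESWNPNHNQFQCAGVAVVR", "edestin 1", 0,0,1,1,1),
  list("GILGVTFPGCPETFEESQR",         "edestin 1", 0,1,1,1,1),
  list("GQGQGQSQGSQPDR",              "edestin 1", 0,0,1,1,1),
  list("QASSDGFEWVSFK",               "edestin 1", 1,1,1,1,1),
  list("VQVVNHMGQK",                  "edestin 1", 1,1,1,1,1),
  list("EETVLLTSSTSSR",               "edestin 1", 0,1,1,1,1),
  list("LQGQNDDR",                    "edestin 1", 0,0,0,1,1),
  list("GTLDLVSPLR",                  "edestin 1", 0,1,1,1,1),
  list("QQNQCQIDR",                   "edestin 1", 0,1,1,1,1),
  list("ILAESFNVDTELAHK",             "edestin 2", 1,1,1,1,1),
  list("AMPDDVLANAFQISR",             "edestin 2", 1,1,1,1,1),
  list("NGMMAPHFNLDSHSVIYVTR",        "edestin 2", 1,1,1,1,1),
  list("GLLLPSFLNAPMMFYVIQGR",        "edestin 2", 1,1,1,1,1),
  list("ASAQGFEWIAVK",                "edestin 2", 0,0,1,1,1),
  list("SEGASSDEQHQK",                "edestin 2", 0,0,0,1,1),
  list("LNTLNNYNLPILR",               "edestin 2", 1,1,1,1,1),
  list("DEISVFSPSSQQTR",              "edestin 2", 0,1,0,1,0),
  list("WQSQCQFQR",                   "edestin 2", 0,0,1,1,1),
  list("LQVVDDNGR",                   "edestin 2", 1,1,1,1,1),
  list("GEDLQIIAPSR",                 "edestin 2", 1,0,1,1,1),
  list("VECEGGMIESWNPNHEQFQCAGVALLR", "edestin 3", 0,0,0,1,1),
  list("FYIAGNPHEDFPQSR",             "edestin 3", 1,1,1,1,1),
  list("AMPEDVIANSYQISR",             "edestin 3", 0,1,1,1,1),
  list("GFSVNLIQEAFNVDSETAR",         "edestin 3", 1,1,1,1,1),
  list("LTIQPNGLHLPSYTNGPQLIHVIR",    "edestin 3", 1,1,1,1,1),
  list("TAVYGDQNECQLNR",              "edestin 3", 0,0,1,1,1),
  list("GVLGTLFPGCAETFEEAQVSVGGGR",   "edestin 3", 0,0,1,1,1),
  list("NAMYAPHYNINAHSIIYAIR",        "edestin 3", 0,0,0,1,1),
  list("LEACEPDHR",                   "edestin 3", 0,0,0,0,1),
  list("QGQALTVPQNFAVVK",             "edestin 3", 1,1,1,1,1),
  list("FYIAGNPHQEFPQSMMTQQGR",       "edestin 3", 0,0,0,0,1),
  list("CPALEMEIQK",                  "albumin",   0,0,1,1,1),
  list("NIPSMCGMQPR",                 "albumin",   1,1,1,1,1),
  list("GPELAAAFGLSLER",          "7S vicilin-like protein", 0,0,1,1,1),
  list("EILSSQQEGPIVYIPDSR",      "7S vicilin-like protein", 0,0,0,0,1),
  list("NNYGWSIALDEFSYSPLR",      "7S vicilin-like protein", 0,0,0,0,1)
)

# protein, sample, coverage %, matched peptides, unique score, total intensity
PROTEIN_STATS_ROWS <- list(
  list("edestin 1", "M1", 65.9, 28, 411.49, 4.08e7),
  list("edestin 1", "M2", 65.7, 27, 415.23, 6.11e7),
  list("edestin 1", "M3", 69.8, 32, 551.19, 2.94e8),
  list("edestin 1", "M4", 74.9, 37, 627.60, 4.29e8),
  list("edestin 1", "HC", 78.4, 45, 787.00, 2.43e9),
  list("edestin 2", "M1", 57.4, 23, 344.04, 4.70e7),
  list("edestin 2", "M2", 57.4, 23, 359.00, 7.42e7),
  list("edestin 2", "M3", 68.8, 28, 503.93, 3.77e8),
  list("edestin 2", "M4", 72.9, 36, 637.90, 3.98e8),
  list("edestin 2", "HC", 66.8, 42, 775.24, 1.89e9),
  list("edestin 3", "M1", 59.4, 23, 321.57, 2.84e7),
  list("edestin 3", "M2", 48.4, 21, 320.60, 3.74e7),
  list("edestin 3", "M3", 69.4, 27, 457.01, 2.45e8),
  list("edestin 3", "M4", 72.3, 31, 517.93, 6.24e8),
  list("edestin 3", "HC", 82.6, 41, 731.50, 2.99e9),
  list("albumin",   "M1", 19.0,  3,  32.14, 1.17e6),
  list("albumin",   "M2", 23.9,  4,  52.36, 4.90e6),
  list("albumin",   "M3", 34.5,  6,  78.89, 1.70e7),
  list("albumin",   "M4", 34.5,  6,  90.47, 3.84e7),
  list("albumin",   "HC", 41.5,  9, 142.84, 1.53e8),
  list("7S vicilin-like protein", "M3",  7.5,  3,  34.37, 5.66e5),
  list("7S vicilin-like protein", "M4", 25.7, 10, 138.97, 2.19e6),
  list("7S vicilin-like protein", "HC", 45.6, 23, 386.04, 6.87e7)
)

# species, protein, accession, peptide, sample where detected
MEAT_ATTRIBUTION_ROWS <- list(
  list("Numida meleagris", "triosephosphate isomerase", "XP_021251610.1",
       "LSADTEVVCGAPAIYLDFAR", "M4"),
  list("Numida meleagris", "phosphoglycerate mutase 1", "XP_021255837.1",
       "HLESMSEEAIMELNLPTGIPIVYELDK", "M4"),
  list("Oryctolagus cuniculus", "myosin heavy chain", "NP_001103286.1",
       "TLAFLFTGTAAAEAEGGGK", "M4"),
  list("Oryctolagus cuniculus", "myosin heavy chain, skeletal muscle",
       "XP_008268944.1", "TLAFLFSGAQTGEEGGGGGK", "M4"),
  list("Oryctolagus cuniculus", "fructose-bisphosphate aldolase A",
       "NP_001075707.1", "PHSHPALTPEQK", "M4"),
  list("Oryctolagus cuniculus",
       "ATP-dependent 6-phosphofructokinase, muscle type", "XP_002723486.1",
       "ALVFQPVTELQNQTDFEHR", "M4"),
  list("Oryctolagus cuniculus", "beta globin", "AAA02985.1",
       "FFESFGDLSSAHAVMSNPK", "M4"),
  list("Oryctolagus cuniculus", "beta globin", "AAA02985.1",
       "VLAAFSEGLNHLDNLK", "M4"),
  list("Sus scrofa", "myosin-1", "NP_001098421.1",
       "TLAFLFTGAAGADAEAGGGK", "M4"),
  list("Sus scrofa", "myosin-2 isoform X1", "XP_020921875.1",
       "TLAFLFSGAQTGEAEAGGTK", "M4"),
  list("Sus scrofa", "myosin-4", "NP_001116613.1", "TLAFLFAER", "M4"),
  list("Sus scrofa", "myosin-7", "NP_999020.2", "LLSNLFANYAGADTPVEK", "M4"),
  list("Sus scrofa", "albumin, partial", "CAA30970.1", "TVLGNFAAFVQK", "M4"),
  list("Sus scrofa", "carbonic anhydrase 3", "NP_001008688.1",
       "HDPSLLPWTASYDPGSAK", "M4"),
  list("Sus scrofa", "hemoglobin (beta subunit)", "pdb|1QPW|B",
       "FFESFGDLSNADAVMGNPK", "M4"),
  list("Sus scrofa", "glyceraldehyde-3-phosphate dehydrogenase",
       "NP_001193288.1", "WGDAGATYVVESTGVFTTMEK", "M4"),
  list("Gallus gallus", "myosin binding protein C", "NP_001038124.1",
       "TSDVDSVFFIR", "P12"),
  list("Gallus gallus", "myosin binding protein C", "NP_001038124.1",
       "LDVPISGEPAPTVTWK", "P12"),
  list("Gallus gallus", "myosin binding protein C", "NP_001038124.1",
       "VAGAALPCAPAVK", "P12"),
  list("Gallus gallus", "pyruvate kinase", "NP_990800.1",
       "EPADAMAAGAVEASFK", "P12"),
  list("Gallus gallus", "beta-enolase", "NP_990450.1",
       "LAMQEFMVLPVGAASFHDAMR", "P12"),
  list("Gallus gallus",
       "sarcoplasmic/endoplasmic reticulum calcium ATPase 1", "NP_990850.1",
       "IGIFTEDEEVSGR", "P12")
)

SUNFLOWER_PEPTIDE_ROWS <- list(
  list("2S seed storage albumin 2 precursor", "GQFGGQEMDIAR"),
  list("2S seed storage albumin 2 precursor", "AQILPNVCNLQSR"),
  list("2S seed storage albumin 2 precursor", "SQQCSETEIQRPVSQCQR"),
  list("2S seed storage albumin 2 precursor", "ECQCEAVQEVAR"),
  list("putative 11-S seed storage protein",  "SPFGGQEELTR"),
  list("2S seed storage albumin 1",           "GQFGGQEMETAR")
)

#' Load the hemp-meatball study fixture
#'
#' Returns in-memory transcriptions of the published study tables: the sample
#' design (five meatball variants M0-M4 with hemp-cake spike concentrations
#' 0, 0.9, 2.6, 4.2, 7.4 % w/w, plus pure hemp cake HC), the 40-peptide
#' hemp presence/absence matrix over M1-M4 and HC, per-protein identification
#' statistics (coverage, matched-peptide count, vendor "unique score", total
#' intensity; opaque metadata), the meat peptide-to-species attributions, and
#' the sunflower seed-storage marker peptides.
#'
#' @return List of class \code{paper_fixture} with elements \code{designs},
#'   \code{hemp_matrix} (data.frame: peptide, protein, accession, then logical
#'   columns M1, M2, M3, M4, HC), \code{protein_stats},
#'   \code{meat_attributions}, \code{sunflower_peptides}.
#' @examples
#' fix <- load_paper_fixture()
#' subset(fix$hemp_matrix, peptide == "VQVVNHMGQK")
#' @export
load_paper_fixture <- function() {
  designs <- data.frame(
    sample_id = c("M0", "M1", "M2", "M3", "M4", "HC"),
    spike_concentration = c(0, 0.9, 2.6, 4.2, 7.4, 100),
    replicate_count = 3L,
    is_processed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  designs$composition <- list(
    data.frame(ingredient = c("pork", "rabbit meat", "guinea fowl meat",
                              "water", "bread crumbs", "salt", "pepper",
                              "garlic"),
               percent = c(66, 10.9, 7.3, 8.9, 5.3, 1.3, 0.2, 0.1)),
    data.frame(ingredient = c("pork", "rabbit meat", "guinea fowl meat",
                              "hemp cake", "water", "bread crumbs", "salt",
                              "pepper", "garlic"),
               percent = c(65.4, 10.8, 7.2, 0.9, 8.8, 5.3, 1.3, 0.2, 0.1)),
    data.frame(ingredient = c("pork", "rabbit meat", "guinea fowl meat",
                              "hemp cake", "water", "bread crumbs", "salt",
                              "pepper", "garlic"),
               percent = c(64.3, 10.6, 7.1, 2.6, 8.6, 5.2, 1.3, 0.2, 0.1)),
    data.frame(ingredient = c("pork", "rabbit meat", "guinea fowl meat",
                              "hemp cake", "water", "bread crumbs", "salt",
                              "pepper", "garlic"),
               percent = c(63.2, 10.4, 7, 4.2, 8.5, 5.1, 1.3, 0.2, 0.1)),
    data.frame(ingredient = c("pork", "rabbit meat", "guinea fowl meat",
                              "hemp cake", "water", "bread crumbs", "salt",
                              "pepper", "garlic"),
               percent = c(61.1, 10.1, 6.7, 7.4, 8.2, 4.9, 1.2, 0.2, 0.1)),
    data.frame(ingredient = "hemp cake", percent = 100)
  )

  hemp <- do.call(rbind, lapply(HEMP_MATRIX_ROWS, function(r) {
    data.frame(peptide = r[[1L]], protein = r[[2L]],
               M1 = as.logical(r[[3L]]), M2 = as.logical(r[[4L]]),
               M3 = as.logical(r[[5L]]), M4 = as.logical(r[[6L]]),
               HC = as.logical(r[[7L]]), stringsAsFactors = FALSE)
  }))
  hemp$accession <- HEMP_PROTEINS$accession[
    match(hemp$protein, HEMP_PROTEINS$protein)]
  hemp <- hemp[, c("peptide", "protein", "accession",
                   "M1", "M2", "M3", "M4", "HC")]

  stats <- do.call(rbind, lapply(PROTEIN_STATS_ROWS, function(r) {
    data.frame(protein = r[[1L]], sample_id = r[[2L]], coverage = r[[3L]],
               matched_peptides = r[[4L]], unique_score = r[[5L]],
               total_intensity = r[[6L]], stringsAsFactors = FALSE)
  }))
  stats$accession <- HEMP_PROTEINS$accession[
    match(stats$protein, HEMP_PROTEINS$protein)]

  meat <- do.call(rbind, lapply(MEAT_ATTRIBUTION_ROWS, function(r) {
    data.frame(species = r[[1L]], protein = r[[2L]], accession = r[[3L]],
               peptide = r[[4L]], sample_id = r[[5L]],
               stringsAsFactors = FALSE)
  }))

  sunflower <- do.call(rbind, lapply(SUNFLOWER_PEPTIDE_ROWS, function(r) {
    data.frame(species = "Helianthus annuus", protein = r[[1L]],
               peptide = r[[2L]], stringsAsFactors = FALSE)
  }))

  structure(list(designs = designs, hemp_matrix = hemp,
                 protein_stats = stats, meat_attributions = meat,
                 sunflower_peptides = sunflower),
            class = "paper_fixture")
}

#' Synthetic hemp parent proteins
#'
#' Builds one synthetic protein record per hemp marker protein by
#' concatenating its published marker peptides in table order. The real
#' database sequences are not shipped; these stand-ins release exactly the
#' printed peptides under tryptic digestion (every marker ends in K/R and
#' none begins with proline), which is all the screening, coverage, and
#' simulation code requires.
#'
#' @return data.frame of protein records (see \code{\link{read_fasta}}).
#' @export
synthetic_hemp_proteome <- function() {
  fix <- load_paper_fixture()
  seqs <- vapply(split(fix$hemp_matrix$peptide, fix$hemp_matrix$protein),
                 paste, character(1), collapse = "")
  prot <- HEMP_PROTEINS
  data.frame(
    identifier = prot$accession,
    species = "Cannabis sativa",
    description = paste0(prot$protein, " (synthetic concatenation)"),
    sequence = unname(seqs[prot$protein]),
    stringsAsFactors = FALSE
  )
}

#' Synthetic meat parent proteins
#'
#' Same construction as \code{\link{synthetic_hemp_proteome}} for the meat
#' marker proteins: each record concatenates the published species-specific
#' peptides of one protein.
#'
#' @return data.frame of protein records.
#' @export
synthetic_meat_proteome <- function() {
  fix <- load_paper_fixture()
  key <- paste(fix$meat_attributions$species, fix$meat_attributions$accession,
               sep = "\r")
  first <- !duplicated(key)
  seqs <- vapply(split(fix$meat_attributions$peptide, key), paste,
                 character(1), collapse = "")
  data.frame(
    identifier = fix$meat_attributions$accession[first],
    species = fix$meat_attributions$species[first],
    description = paste0(fix$meat_attributions$protein[first],
                         " (synthetic concatenation)"),
    sequence = unname(seqs[key[first]]),
    stringsAsFactors = FALSE
  )
}
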