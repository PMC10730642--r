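# Family motif rules, GnRH lineage split and active-peptide extraction

test_that("the documented examples classify as stated", {
  expect_equal(classify_family("APGW", TRUE)$family, "APGWamide")
  expect_equal(classify_family("QLNFSPGW", TRUE)$family, "RPCH/AKH1")
  expect_equal(classify_family("GLRW", TRUE)$family, "LWamide")
  expect_equal(classify_family("QTFQYSRGWTNG", TRUE)$family, "CRZ")
  expect_error(classify_family("", TRUE), "empty")
})

test_that("every canonical family template classifies to its own family", {
  for (fam in names(FAMILY_TEMPLATES)) {
    call <- classify_family(FAMILY_TEMPLATES[[fam]], amidated = TRUE)
    want <- if (startsWith(fam, "GnRH")) "GnRH" else fam
    expect_equal(call$family, want, label = fam)
  }
})

test_that("amidation is required by every family rule", {
  for (fam in names(FAMILY_TEMPLATES))
    expect_equal(classify_family(FAMILY_TEMPLATES[[fam]], FALSE)$family,
                 "unclassified", label = fam)
})

test_that("the AKH supergroup splits on the residue after tryptophan", {
  expect_equal(classify_family("QLNFSPGWG", TRUE)$family, "AKH2")
  expect_equal(classify_family("QLNFSPGWQ", TRUE)$family, "AKH3")
  # tryptophan away from position 8 -> the AKH4 residual
  expect_equal(classify_family("QLNFSTWGA", TRUE)$family, "AKH4")
  # decapeptide with W8 + G9 -> ACP, two extra residues -> crustacean type
  acp <- classify_family("QLNFSPGWGT", TRUE)
  expect_equal(acp$family, "ACP")
  expect_true("insect_type" %in% acp$matched_features)
  acp2 <- classify_family("QLNFSPGWGTSA", TRUE)
  expect_equal(acp2$family, "ACP")
  expect_true("crustacean_type" %in% acp2$matched_features)
})

test_that("a crustacean lineage resolves the merged RPCH/AKH1 call", {
  lin <- c(phylum = "Arthropoda", class = "Malacostraca")
  expect_equal(classify_family("QLNFSPGW", TRUE, lin)$family, "RPCH")
  lin2 <- c(phylum = "Arthropoda", class = "Insecta")
  expect_equal(classify_family("QLNFSPGW", TRUE, lin2)$family, "RPCH/AKH1")
})

test_that("GnRH lineage rule follows length and anchor residues", {
  expect_equal(classify_gnrh_lineage("GAQPSTNWYPGG"), "protostome")
  expect_equal(classify_gnrh_lineage("GAQPHTNWYP"), "deuterostome")
  expect_equal(classify_gnrh_lineage("GAQPSTNGS"), "ambiguous")   # no W
  expect_equal(classify_gnrh_lineage("AAQPSTNWYPGG"), "ambiguous")
})

test_that("classification is deterministic", {
  set.seed(9)
  peps <- replicate(40, paste0(sample(AA_STANDARD, sample(3:14, 1),
                                      replace = TRUE), collapse = ""))
  c1 <- vapply(peps, function(p) classify_family(p, TRUE)$family,
               character(1))
  c2 <- vapply(peps, function(p) classify_family(p, TRUE)$family,
               character(1))
  expect_identical(c1, c2)
})

test_that("active peptides are excised between productive sites", {
  sig <- paste0("M", strrep("L", 7), strrep("S", 7))
  rec <- precursor_records("r", paste0(sig, "APGWGKR", "APGWGKR",
                                       strrep("T", 20)))
  ann <- structural_screen(rec)
  peps <- ann$peptides
  expect_equal(peps$seq, c("APGW", "APGW"))
  expect_equal(peps$copy_index, c(1L, 2L))
  expect_true(all(peps$amidated))
  # spans are 0-based half-open and exclude the amide-donor G
  expect_equal(peps$start, c(15L, 22L))
  expect_equal(peps$end, c(19L, 26L))
})

test_that("spacers and unprocessed segments are dropped", {
  sig <- paste0("M", strrep("L", 7), strrep("S", 7))
  # "AG" between two sites is a spacer (< 3 aa after trimming)
  rec <- precursor_records("r", paste0(sig, "APGWGKR", "AGKR",
                                       strrep("T", 20)))
  ann <- structural_screen(rec)
  expect_equal(ann$peptides$seq, "APGW")
  # no productive sites -> no peptides
  rec2 <- precursor_records("r2", paste0(sig, "APGWG", strrep("T", 25)))
  ann2 <- structural_screen(rec2)
  expect_equal(nrow(ann2$peptides), 0L)
})

test_that("extracted peptides honor the no-dyad and amidation invariants", {
  g <- generate_precursors(synthetic_config(n_records = 60, p_valid = 1,
                                            seed = 13))
  res <- run_purge(g$records)
  for (ann in res$annotations) {
    peps <- ann$peptides
    if (is.null(peps) || nrow(peps) == 0L) next
    for (i in seq_len(nrow(peps))) {
      expect_equal(nrow(find_cleavage_sites(peps$seq[i])), 0L)
      if (peps$amidated[i]) {
        after <- substr(ann$aa_seq, peps$end[i] + 1L, peps$end[i] + 3L)
        expect_equal(substr(after, 1L, 1L), "G")
        expect_true(substr(after, 2L, 3L) %in% c("KR", "RK", "RR", "KK"))
      }
    }
  }
})

test_that("classifier accuracy is 100% at mutation 0 and degrades with rate", {
  acc_at_rate <- function(rate) {
    g <- generate_precursors(synthetic_config(n_records = 120, p_valid = 1,
                                              mutation_rate = rate,
                                              seed = 31))
    res <- run_purge(g$records)
    hits <- 0L; total <- 0L
    for (i in seq_len(nrow(g$truth))) {
      id <- g$truth$record_id[i]
      want <- expected_call(g$truth$family[i])
      ann <- res$annotations[[id]]
      peps <- ann$peptides
      k <- if (is.null(peps)) 0L else nrow(peps)
      total <- total + g$truth$copy_count[i]
      if (k == 0L) next
      calls <- vapply(seq_len(k), function(j)
        classify_family(peps$seq[j], peps$amidated[j])$family, character(1))
      hits <- hits + sum(calls == want)
    }
    hits / total
  }
  a0 <- acc_at_rate(0)
  a_mid <- acc_at_rate(0.3)
  a_hi <- acc_at_rate(1)
  expect_equal(a0, 1)
  expect_true(a0 >= a_mid)
  expect_true(a_mid >= a_hi)
})

test_that("the rule set exports as JSON with the fixed order", {
  js <- jsonlite::fromJSON(export_family_rules())
  expect_equal(js$order[1], "RPCH/AKH1")
  expect_equal(js$order[length(js$order)], "LWamide")
  expect_true(all(names(FAMILY_TEMPLATES) %in% names(js$templates)))
})
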