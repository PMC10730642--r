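# Dibasic scanning, convertase scoring, signal-peptide heuristic and the
# three-stage purge

test_that("cleavage-site scan reports every dyad, including overlaps", {
  s <- find_cleavage_sites("MAAPGWGKRAPGWGKR")
  expect_equal(s$pos, c(7L, 14L))
  expect_equal(s$motif, c("KR", "KR"))

  expect_equal(nrow(find_cleavage_sites("ACDEFGHILM")), 0L)

  s2 <- find_cleavage_sites("AKKRA")
  expect_equal(s2$pos, c(1L, 2L))
  expect_equal(s2$motif, c("KK", "KR"))

  expect_equal(nrow(find_cleavage_sites("")), 0L)
  expect_equal(nrow(find_cleavage_sites("K")), 0L)
})

test_that("cleavage-site scan agrees with the naive all-substrings oracle", {
  set.seed(101)
  for (i in 1:60) {
    s <- paste0(sample(c(AA_STANDARD, "X"), sample(2:120, 1),
                       replace = TRUE), collapse = "")
    got <- find_cleavage_sites(s)
    want <- oracle_dyad_scan(s)
    expect_equal(got$pos, want$pos)
    expect_equal(got$motif, want$motif)
  }
})

test_that("convertase rule table scores as stated", {
  expect_equal(score_convertase_site("AGKRA", 2), 1.0)   # KR
  expect_equal(score_convertase_site("AAKKA", 2), 0.5)   # KK, no P
  expect_equal(score_convertase_site("AKRPA", 1), 0.0)   # proline blocks
  expect_equal(score_convertase_site("ARKA", 1), 0.5)    # RK
  expect_equal(score_convertase_site("AKR", 1), 1.0)     # dyad at terminus
  expect_error(score_convertase_site("AAAA", 1), "dyad")
})

test_that("signal-peptide heuristic fires on hydrophobic cores only", {
  s <- paste0("M", strrep("L", 12), strrep("A", 6), strrep("D", 20))
  expect_equal(detect_signal_peptide(s), c(0L, 15L))
  expect_null(detect_signal_peptide(paste0("A", strrep("L", 30))))
  expect_null(detect_signal_peptide(paste0("M", strrep("D", 30))))
  # late window pushes the cleavage point past 15: first qualifying
  # window is [14, 21] (2 x D + 6 x L), so c = 21 + 5 = 26
  s2 <- paste0("M", strrep("D", 14), strrep("L", 8), strrep("S", 20))
  expect_equal(detect_signal_peptide(s2), c(0L, 26L))
  # window ending at residue 30 gives the cap c = 35
  s3 <- paste0("M", strrep("D", 23), strrep("L", 7), strrep("S", 20))
  expect_equal(detect_signal_peptide(s3), c(0L, 35L))
})

test_that("structural screen requires signal, dyad and length gate", {
  sig <- paste0("M", strrep("L", 7), strrep("S", 7))
  good <- precursor_records("ok", paste0(sig, "APGWGKR", strrep("T", 20)))
  expect_true(structural_screen(good)$passed_structural)

  frag <- precursor_records("frag", paste0(sig, "GKR"))  # 20 aa
  expect_false(structural_screen(frag)$passed_structural)

  nosig <- precursor_records("nosig",
                             paste0(strrep("D", 15), "APGWGKR",
                                    strrep("T", 20)))
  expect_false(structural_screen(nosig)$passed_structural)

  nodyad <- precursor_records("nodyad", paste0(sig, "APGWG", strrep("T", 20)))
  expect_false(structural_screen(nodyad)$passed_structural)
})

test_that("purge retains exactly the constructed-valid records", {
  g <- generate_precursors(synthetic_config(n_records = 100, p_valid = 0.4,
                                            seed = 7))
  res <- run_purge(g$records)
  truth_valid <- g$truth$record_id[g$truth$is_valid]
  expect_equal(res$counts$n_convertase, 40L)
  expect_setequal(res$retained, truth_valid)
})

test_that("purge of empty input gives all-zero counts", {
  res <- run_purge(precursor_records(character(0), character(0)))
  expect_equal(res$counts$n_input, 0L)
  expect_equal(res$counts$n_final, 0L)
})

test_that("records without Gly before any dyad die at the dibasic stage", {
  sig <- paste0("M", strrep("L", 7), strrep("S", 7))
  recs <- precursor_records(c("a", "b"),
                            c(paste0(sig, "APGWTKR", strrep("T", 20)),
                              paste0(sig, "QLNFKRT", strrep("S", 20))))
  res <- run_purge(recs)
  expect_equal(res$counts$n_structural, 2L)
  expect_equal(res$counts$n_dibasic, 0L)
  expect_equal(res$counts$n_convertase, 0L)
})

test_that("stage counts are monotone non-increasing on random batches", {
  for (seed in c(3, 17, 29)) {
    set.seed(seed)
    n <- 40
    seqs <- vapply(seq_len(n), function(i)
      paste0(sample(AA_STANDARD, sample(10:120, 1), replace = TRUE),
             collapse = ""), character(1))
    res <- run_purge(precursor_records(sprintf("r%03d", 1:n), seqs))
    cc <- res$counts
    expect_true(cc$n_input >= cc$n_structural)
    expect_true(cc$n_structural >= cc$n_dibasic)
    expect_true(cc$n_dibasic >= cc$n_convertase)
  }
})

test_that("purge annotations are deterministic for identical input", {
  g <- generate_precursors(synthetic_config(n_records = 30, seed = 5))
  a <- run_purge(g$records)
  b <- run_purge(g$records)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$counts, b$counts)
})

test_that("deny and allow lists adjust the retained set after stage 3", {
  g <- generate_precursors(synthetic_config(n_records = 20, p_valid = 0.5,
                                            seed = 2))
  base <- run_purge(g$records)
  drop <- base$retained[1L]
  res <- run_purge(g$records, denylist = drop)
  expect_false(drop %in% res$retained)
  bad <- setdiff(g$records$record_id, base$retained)[1L]
  res2 <- run_purge(g$records, allowlist = bad)
  expect_true(bad %in% res2$retained)
})

test_that("pipeline_counts enforces monotonicity and named additions", {
  expect_error(pipeline_counts(10, 12, 5, 3), "monotone")
  expect_error(pipeline_counts(10, 8, 5, 3, additions = c(5)), "named")
  expect_error(pipeline_counts(10, 8, 5, 3, additions = c(ACP = -1)),
               "non-negative")
  cc <- pipeline_counts(10, 8, 5, 3, additions = c(ACP = 2, NPP = 1))
  expect_equal(cc$n_final, 6L)
})
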