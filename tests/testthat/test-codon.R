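# Codon back-mapping, conserved-block detection and NPP fusion

make_codon_aln <- function(aln, cds) codon_backmap(aln, cds)

test_that("codon back-mapping turns aa columns into codon columns", {
  ca <- make_codon_aln(c(r1 = "AP-GW", r2 = "APQGW"),
                       c(r1 = "GCTCCAGGTTGG", r2 = "GCTCCACAAGGTTGG"))
  expect_equal(unname(ca$codons["r1", ]),
               c("GCT", "CCA", "---", "GGT", "TGG"))
  expect_equal(unname(ca$codons["r2", ]),
               c("GCT", "CCA", "CAA", "GGT", "TGG"))
  # provenance offsets restore cds coordinates
  expect_equal(unname(ca$provenance["r1", ]), c(0L, 3L, NA, 6L, 9L))
})

test_that("back-translation round-trips: gap-stripped rows equal the cds", {
  g <- generate_precursors(synthetic_config(n_records = 6, p_valid = 1,
                                            seed = 19))
  seqs <- setNames(g$records$aa_seq, g$records$record_id)
  aln <- progressive_align(seqs, align_params("dnalm"))
  cds <- setNames(g$records$cds_seq, g$records$record_id)
  ca <- codon_backmap(aln, cds)
  for (r in ca$rows) {
    joined <- paste0(ca$codons[r, ca$codons[r, ] != "---"], collapse = "")
    expect_equal(joined, unname(cds[r]))
  }
})

test_that("cds of the wrong length is rejected naming the row", {
  expect_error(codon_backmap(c(r1 = "APGW"), c(r1 = "GCTCCAGGT")), "r1")
})

test_that("an all-gap column is preserved through back-mapping", {
  ca <- make_codon_aln(c(r1 = "A-W", r2 = "A-W"),
                       c(r1 = "GCTTGG", r2 = "GCATGG"))
  expect_equal(unname(ca$codons[, 2]), c("---", "---"))
})

test_that("two identical rows give one full-width block of identity 1", {
  ca <- make_codon_aln(c(r1 = "APGW", r2 = "APGW"),
                       c(r1 = "GCTCCAGGTTGG", r2 = "GCTCCAGGTTGG"))
  b <- find_conserved_blocks(ca, min_len = 2, min_ident = 0.9)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(0L, 4L))
  expect_equal(b$mean_identity, 1)
})

test_that("conserved and divergent regions split into the right blocks", {
  # columns 0-3 and 8-11 identical; 4-7 maximally divergent
  left <- "GCTCCAGGTTGG"; right <- "CAACATAATGAA"
  mid1 <- "TTTTTTTTTTTT"; mid2 <- "AAAAAAAAAAAA"
  aa1 <- translate_cds(paste0(left, mid1, right))
  aa2 <- translate_cds(paste0(left, mid2, right))
  ca <- make_codon_aln(setNames(c(aa1, aa2), c("r1", "r2")),
                       c(r1 = paste0(left, mid1, right),
                         r2 = paste0(left, mid2, right)))
  b <- find_conserved_blocks(ca, min_len = 4, min_ident = 0.9)
  expect_equal(nrow(b), 2L)
  expect_equal(b$start, c(0L, 8L))
  expect_equal(b$end, c(4L, 12L))
  # direct column-identity verification
  for (j in 1:4) expect_equal(mean(strsplit(ca$codons[1, j], "")[[1]] ==
                                   strsplit(ca$codons[2, j], "")[[1]]), 1)
  for (j in 5:8) expect_equal(mean(strsplit(ca$codons[1, j], "")[[1]] ==
                                   strsplit(ca$codons[2, j], "")[[1]]), 0)
})

test_that("min_len larger than the alignment yields no blocks", {
  ca <- make_codon_aln(c(r1 = "APGW", r2 = "APGW"),
                       c(r1 = "GCTCCAGGTTGG", r2 = "GCTCCAGGTTGG"))
  expect_equal(nrow(find_conserved_blocks(ca, min_len = 10)), 0L)
})

test_that("raising min_ident never increases block coverage", {
  set.seed(37)
  for (rep in 1:4) {
    n <- 3
    aa <- random_aa(30)
    cds <- vapply(1:n, function(i) {
      # synonymous re-encoding: rows agree in aa but diverge in codons
      ct <- sapply(strsplit(aa, "")[[1]], function(r) {
        cods <- names(which(Biostrings::GENETIC_CODE == r))
        cods[sample.int(length(cods), 1)]
      })
      paste0(ct, collapse = "")
    }, character(1))
    ca <- codon_backmap(setNames(rep(aa, n), paste0("r", 1:n)),
                        setNames(cds, paste0("r", 1:n)))
    cov <- function(mi) {
      b <- find_conserved_blocks(ca, min_len = 2, min_ident = mi)
      if (nrow(b) == 0) 0L else sum(b$end - b$start)
    }
    cv <- vapply(c(0.5, 0.7, 0.9, 1), cov, integer(1))
    expect_true(all(diff(cv) <= 0))
  }
})

test_that("fusion concatenates consensus codons in template order", {
  ca <- make_codon_aln(c(r1 = "APGW", r2 = "APGW"),
                       c(r1 = "GCTCCAGGTTGG", r2 = "GCTCCAGGTTGG"))
  b <- find_conserved_blocks(ca, min_len = 4, min_ident = 0.9)
  npp <- fuse_blocks(b, ca, template = "r1")
  expect_equal(npp$aa, "APGW")
  expect_equal(nchar(npp$cds), 3L * nchar(npp$aa))
  # provenance tiles the fused cds without overlap
  expect_equal(npp$provenance$fused_start[1], 0L)
  expect_equal(npp$provenance$fused_end[nrow(npp$provenance)],
               nchar(npp$cds))

  # blocks given out of order come back in coordinate order
  ca2 <- make_codon_aln(
    c(r1 = "APGWAPGW", r2 = "APGWAPGW"),
    c(r1 = strrep("GCTCCAGGTTGG", 2), r2 = strrep("GCTCCAGGTTGG", 2)))
  b2 <- find_conserved_blocks(ca2, min_len = 4, min_ident = 0.9)
  expect_equal(nrow(b2), 1L)  # one maximal run; split it manually
  halves <- data.frame(start = c(4L, 0L), end = c(8L, 4L),
                       mean_identity = 1,
                       consensus = c("GCTCCAGGTTGG", "GCTCCAGGTTGG"))
  npp2 <- fuse_blocks(halves, ca2, template = "r1")
  expect_equal(npp2$provenance$col_start, c(0L, 4L))
  expect_error(fuse_blocks(b2[0, ], ca2), "no blocks")
})

test_that("consensus uses plurality with lexicographic tie-break", {
  ca <- make_codon_aln(c(r1 = "L", r2 = "L"),
                       c(r1 = "CTT", r2 = "CTA"))
  b <- find_conserved_blocks(ca, min_len = 1, min_ident = 0.6)
  expect_equal(b$consensus, "CTA")  # tie CTA/CTT -> lexicographic
})

test_that("the rotifer-style precursor lays out as 3 APGW + 1 AKH-type", {
  sig <- paste0("M", strrep("L", 7), strrep("S", 7))
  fix <- paste0(sig, strrep("APGWGKR", 3), "QLNFSPGWGT", "GKR",
                strrep("T", 12))
  lay <- validate_npp_layout(fix)
  expect_equal(unname(lay["APGWamide"]), 3L)
  akh_group <- c("RPCH/AKH1", "RPCH", "AKH2", "AKH3", "AKH4", "ACP")
  expect_equal(sum(lay[names(lay) %in% akh_group]), 1L)

  fix2 <- paste0(sig, strrep("APGWGKR", 2), "QLNFSPGWGT", "GKR",
                 strrep("T", 12))
  expect_equal(unname(validate_npp_layout(fix2)["APGWamide"]), 2L)

  expect_length(validate_npp_layout(paste0(sig, strrep("T", 30))), 0L)
})

test_that("ORF scanning finds ATG..stop frames", {
  set.seed(5)
  aa <- paste0(sample(setdiff(AA_STANDARD, "M"), 100, replace = TRUE),
               collapse = "")
  orf_cds <- paste0("ATG", paste0(vapply(strsplit(aa, "")[[1]], function(r)
    names(which(Biostrings::GENETIC_CODE == r))[1], character(1)),
    collapse = ""), "TAA")
  cdna <- paste0("acgtacg", orf_cds, "ttgtt")
  o <- find_orfs(cdna)
  expect_equal(o$length_bp[1], 306L)  # 102 codons including the stop
  expect_equal(o$aa[1], paste0("M", aa))
})
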