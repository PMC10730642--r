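# Independent oracles used across the test suite.

# Exhaustive alignment-score oracle: enumerates every global alignment of
# a and b (all monotone gap placements) with incremental scoring under the
# run-based rules: a matched column adds substitution + bonus; a maximal
# gap run costs open + extend*(len-1) unless it touches the first or last
# alignment column, in which case it costs terminal per residue. Exponential
# in sequence length; intended for sequences of length <= 8.
oracle_align_score <- function(a, b, params) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  sub <- nppcur::BLOSUM62
  open <- params$gap_open; ext <- params$gap_extend
  term <- params$terminal_gap; bon <- params$bonus
  best <- -Inf

  # cost of closing an open run that does NOT reach the final column;
  # from_col1: the run started at alignment column 1 (leading => terminal)
  close_run <- function(len, from_col1) {
    if (len == 0L) return(0)
    if (from_col1) -term * len else -(open + ext * (len - 1L))
  }
  # run_b: open gap run in row b (a residues vs gaps); run_a: in row a.
  # At most one of the two is nonzero (each column has one gap at most,
  # and a column of the other kind closes the run).
  rec <- function(i, j, score, run_b, b_from1, run_a, a_from1) {
    if (i == n && j == m) {
      s <- score
      if (run_b > 0L) s <- s - term * run_b    # reaches final column
      if (run_a > 0L) s <- s - term * run_a
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < n && j < m)                         # match column
      rec(i + 1L, j + 1L,
          score + close_run(run_b, b_from1) + close_run(run_a, a_from1) +
            sub[ca[i + 1L], cb[j + 1L]] + bon,
          0L, FALSE, 0L, FALSE)
    if (i < n)                                  # gap column in row b
      rec(i + 1L, j,
          score + close_run(run_a, a_from1),
          run_b + 1L, if (run_b > 0L) b_from1 else (i + j == 0L),
          0L, FALSE)
    if (j < m)                                  # gap column in row a
      rec(i, j + 1L,
          score + close_run(run_b, b_from1),
          0L, FALSE,
          run_a + 1L, if (run_a > 0L) a_from1 else (i + j == 0L))
    invisible()
  }
  rec(0L, 0L, 0, 0L, FALSE, 0L, FALSE)
  best
}

# Naive all-substrings dibasic scan (oracle for find_cleavage_sites)
oracle_dyad_scan <- function(aa) {
  n <- nchar(aa)
  pos <- integer(0); motif <- character(0)
  if (n >= 2) for (p in 1:(n - 1)) {
    dy <- substr(aa, p, p + 1)
    if (dy %in% c("KR", "RK", "RR", "KK")) {
      pos <- c(pos, p - 1L)
      motif <- c(motif, dy)
    }
  }
  data.frame(pos = pos, motif = motif, stringsAsFactors = FALSE)
}

# Robinson-Foulds by independent split enumeration (ape::prop.part clade
# enumeration, canonicalized by membership of the alphabetically first
# leaf) — shares no code with nppcur::splits.
oracle_rf <- function(t1, t2) {
  enum_splits <- function(tr) {
    tr <- ape::unroot(tr)
    tips <- sort(tr$tip.label)
    n <- length(tips)
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    keys <- character(0)
    for (p in parts) {
      side <- sort(labs[p])
      if (length(side) < 2 || length(side) > n - 2) next
      if (!tips[1] %in% side) side <- sort(setdiff(tips, side))
      keys <- c(keys, paste(side, collapse = "|"))
    }
    unique(keys)
  }
  s1 <- enum_splits(t1); s2 <- enum_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

random_aa <- function(len) {
  paste0(sample(nppcur::AA_STANDARD, len, replace = TRUE), collapse = "")
}

# expected classifier call for a generator truth family
expected_call <- function(truth_family, with_lineage = FALSE) {
  if (startsWith(truth_family, "GnRH")) return("GnRH")
  if (truth_family == "RPCH/AKH1" && with_lineage) return("RPCH")
  truth_family
}
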