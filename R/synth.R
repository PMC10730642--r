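# Deterministic synthetic-data generators: labeled precursor batches with
# the canonical precursor anatomy (signal peptide, active peptides flanked
# by Gly + dibasic motifs, related-peptide filler), and tree pairs at a
# controlled topological distance.

# residue pools used by the generator; K/R excluded everywhere outside the
# deliberate cleavage sites so no spurious dyads arise
SYN_HYDROPHILIC <- c("S", "T", "N", "Q", "D", "E", "H", "Y")

CORRUPTION_MODES <- c("drop_signal", "drop_dyad", "drop_amide_G", "truncate")

#' Synthetic-batch configuration
#'
#' @param n_records number of records to generate.
#' @param p_valid fraction of records with a correct precursor structure.
#'   Validity is assigned by stratification (`round(n * p_valid)` records
#'   are valid, exactly) unless `bernoulli = TRUE`.
#' @param family_mix named weights over the family templates of
#'   [FAMILY_TEMPLATES] (default: uniform).
#' @param n_copies integer range of active-peptide copy numbers per valid
#'   precursor (default 1:3).
#' @param mutation_rate per-residue substitution probability applied to
#'   the finished amino-acid sequence (default 0).
#' @param invalid_modes weights over the corruption modes
#'   `drop_signal`, `drop_dyad`, `drop_amide_G`, `truncate` (default
#'   uniform). Each invalid record receives exactly one corruption.
#' @param bernoulli use per-record Bernoulli validity instead of exact
#'   stratification.
#' @param seed integer seed; fully determines the output
#'   (Mersenne-Twister).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records = 100L, p_valid = 0.5,
                             family_mix = NULL, n_copies = 1:3,
                             mutation_rate = 0, invalid_modes = NULL,
                             bernoulli = FALSE, seed = 1L) {
  stopifnot(n_records >= 0L, p_valid >= 0, p_valid <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  if (is.null(family_mix))
    family_mix <- setNames(rep(1, length(FAMILY_TEMPLATES)),
                           names(FAMILY_TEMPLATES))
  stopifnot(all(names(family_mix) %in% names(FAMILY_TEMPLATES)),
            all(family_mix >= 0), sum(family_mix) > 0)
  if (is.null(invalid_modes))
    invalid_modes <- setNames(rep(1, length(CORRUPTION_MODES)),
                              CORRUPTION_MODES)
  stopifnot(all(names(invalid_modes) %in% CORRUPTION_MODES),
            sum(invalid_modes) > 0)
  structure(list(n_records = as.integer(n_records), p_valid = p_valid,
                 family_mix = family_mix / sum(family_mix),
                 n_copies = as.integer(n_copies),
                 mutation_rate = mutation_rate,
                 invalid_modes = invalid_modes / sum(invalid_modes),
                 bernoulli = isTRUE(bernoulli),
                 seed = as.integer(seed),
                 rng = "Mersenne-Twister"),
            class = "synthetic_config")
}

# signal peptide whose detected cleavage point equals its length (15):
# M + 7 hydrophobic + 7 hydrophilic
.syn_signal <- function() {
  paste0("M",
         paste0(sample(setdiff(AA_HYDROPHOBIC, "M"), 7, replace = TRUE),
                collapse = ""),
         paste0(sample(SYN_HYDROPHILIC, 7, replace = TRUE), collapse = ""))
}

.syn_filler <- function(len) {
  paste0(sample(SYN_HYDROPHILIC, len, replace = TRUE), collapse = "")
}

# reverse-translate an aa string with uniform synonymous codon choice
.syn_reverse_translate <- function(aa) {
  ct <- .codon_table()
  ch <- .chars(aa)
  paste0(vapply(ch, function(r) {
    cods <- ct[[r]]
    if (is.null(cods)) "NNN" else cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# one structurally valid precursor around a family template
.syn_valid_aa <- function(template, k) {
  body <- paste0(rep(paste0(template, "G", "KR"), k), collapse = "")
  paste0(.syn_signal(), body, .syn_filler(sample(18:30, 1L)))
}

#' Generate a labeled batch of synthetic precursors
#'
#' Valid records follow the canonical precursor anatomy: a signal peptide
#' whose heuristic cleavage point equals its true length, `k` copies of
#' (family peptide + amide-donor G + KR dyad), and hydrophilic
#' related-peptide filler free of basic residues. Invalid records are
#' valid records with exactly one corruption applied (signal removed,
#' dyads removed, amide-donor glycines removed, or truncation below the
#' length gate). Coding sequences are produced by reverse translation with
#' uniform synonymous codon choice. Fully deterministic under the seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (a `precursor_records` data.frame with
#'   `cds_seq`), `truth` (data.frame `record_id`, `is_valid`, `family`,
#'   `copy_count`, `corruption`), and `annotation` (taxonomy table usable
#'   with [summarize_taxonomy()]).
#' @export
generate_precursors <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- RNGkind("Mersenne-Twister", "Inversion")
  on.exit(RNGkind(old[1L], old[2L]), add = TRUE)
  set.seed(config$seed)
  n <- config$n_records

  if (n == 0L) {
    return(list(records = precursor_records(character(0), character(0)),
                truth = data.frame(record_id = character(0),
                                   is_valid = logical(0),
                                   family = character(0),
                                   copy_count = integer(0),
                                   corruption = character(0),
                                   stringsAsFactors = FALSE),
                annotation = data.frame(record_id = character(0))))
  }

  if (config$bernoulli) {
    valid <- runif(n) < config$p_valid
  } else {
    n_valid <- round(n * config$p_valid)
    valid <- rep(FALSE, n)
    if (n_valid > 0L) valid[sample.int(n, n_valid)] <- TRUE
  }

  fams <- sample(names(config$family_mix), n, replace = TRUE,
                 prob = config$family_mix)
  ks <- sample(config$n_copies, n, replace = TRUE)
  modes <- sample(names(config$invalid_modes), n, replace = TRUE,
                  prob = config$invalid_modes)

  ids <- sprintf("SYN%04d", seq_len(n))
  aa <- character(n)
  corr <- rep("none", n)
  for (i in seq_len(n)) {
    template <- FAMILY_TEMPLATES[[fams[i]]]
    s <- .syn_valid_aa(template, ks[i])
    if (!valid[i]) {
      corr[i] <- modes[i]
      s <- switch(modes[i],
        drop_signal = paste0("D", substr(s, 2L, nchar(s))),
        drop_dyad = gsub("KR", "ST", s, fixed = TRUE),
        drop_amide_G = gsub("G+KR", "KR", s),  # strip all Gs before dyads
        truncate = substr(s, 1L, 30L))
    }
    if (config$mutation_rate > 0)
      s <- .mutate_aa(s, config$mutation_rate)
    aa[i] <- s
  }
  cds <- vapply(aa, .syn_reverse_translate, character(1), USE.NAMES = FALSE)

  taxa <- .syn_taxonomy(n, fams)
  records <- precursor_records(ids, aa, cds, species = taxa$species,
                               family_claim = fams)
  truth <- data.frame(record_id = ids, is_valid = valid, family = fams,
                      copy_count = ifelse(valid, ks, 0L),
                      corruption = corr, stringsAsFactors = FALSE)
  annotation <- data.frame(record_id = ids, taxa, family_claim = fams,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(records = records, truth = truth, annotation = annotation)
}

# small fake taxonomy pool; crustacean lineages are attached to RPCH-family
# records so the taxonomy-deferred RPCH call is exercised
.syn_taxonomy <- function(n, fams) {
  pool <- data.frame(
    phylum = c("Arthropoda", "Arthropoda", "Mollusca", "Rotifera",
               "Cnidaria", "Chordata"),
    class = c("Malacostraca", "Insecta", "Gastropoda", "Monogononta",
              "Hydrozoa", "Actinopteri"),
    order = c("Decapoda", "Orthoptera", "Hygrophila", "Ploima",
              "Anthoathecata", "Salmoniformes"),
    family = c("Portunidae", "Acrididae", "Lymnaeidae", "Brachionidae",
               "Hydridae", "Salmonidae"),
    genus = c("Callinectes", "Schistocerca", "Lymnaea", "Brachionus",
              "Hydra", "Salmo"),
    species = c("Callinectes toxotes", "Schistocerca gregaria",
                "Lymnaea stagnalis", "Brachionus plicatilis",
                "Hydra vulgaris", "Salmo salar"),
    stringsAsFactors = FALSE)
  idx <- sample.int(nrow(pool), n, replace = TRUE)
  idx[fams %in% c("RPCH/AKH1")] <- 1L  # crustacean lineage for RPCH group
  pool[idx, , drop = FALSE]
}

# per-residue substitution, uniform among the other 19 standard residues
.mutate_aa <- function(aa, rate) {
  ch <- .chars(aa)
  hit <- runif(length(ch)) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(r)
      sample(setdiff(AA_STANDARD, r), 1L), character(1))
  paste0(ch, collapse = "")
}

#' Mutate one precursor record
#'
#' Per-residue substitution at the given rate, replacement drawn uniformly
#' among the other 19 standard residues. When a coding sequence is
#' present, mutated residues are re-encoded with a random synonymous
#' codon so cds and aa stay consistent.
#'
#' @param record one-row `precursor_records` data.frame.
#' @param rate substitution probability per residue, in \[0, 1\].
#' @param seed integer seed.
#' @return one-row `precursor_records` data.frame.
#' @export
mutate_precursor <- function(record, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  old <- RNGkind("Mersenne-Twister", "Inversion")
  on.exit(RNGkind(old[1L], old[2L]), add = TRUE)
  set.seed(seed)
  aa_old <- .chars(record$aa_seq[1L])
  aa_new <- .chars(.mutate_aa(record$aa_seq[1L], rate))
  cds <- record$cds_seq[1L]
  if (!is.na(cds)) {
    cdn <- .codons(cds)
    ct <- .codon_table()
    changed <- which(aa_new != aa_old)
    for (i in changed) {
      cods <- ct[[aa_new[i]]]
      cdn[i] <- cods[sample.int(length(cods), 1L)]
    }
    cds <- paste0(cdn, collapse = "")
  }
  precursor_records(record$record_id[1L], paste0(aa_new, collapse = ""),
                    cds, record$species[1L], record$family_claim[1L])
}

#' Generate a pair of trees at controlled topological distance
#'
#' `t1` is a random binary tree with leaves `L1..Ln`; `t2` is `t1` after
#' `k` random nearest-neighbor-interchange moves. Each NNI changes at most
#' one split, so `RF(t1, t2) <= 2k`.
#'
#' @param n_leaves number of leaves (>= 4).
#' @param k_nni number of NNI moves (>= 0).
#' @param seed integer seed.
#' @return list with trees `t1`, `t2`.
#' @export
generate_tree_pair <- function(n_leaves, k_nni, seed = 1L) {
  stopifnot(n_leaves >= 4L, k_nni >= 0L)
  old <- RNGkind("Mersenne-Twister", "Inversion")
  on.exit(RNGkind(old[1L], old[2L]), add = TRUE)
  set.seed(seed)
  t1 <- ape::rtree(n_leaves, tip.label = paste0("L", seq_len(n_leaves)))
  t2 <- t1
  if (k_nni > 0L)
    for (i in seq_len(k_nni)) t2 <- phangorn::rNNI(t2, moves = 1L)
  list(t1 = t1, t2 = t2)
}
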