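# Motif-based classification of mature active peptides into the LWamide,
# APGWamide, RPCH/AKH, ACP, CRZ and GnRH families, and extraction of mature
# peptides from annotated precursors.

#' Neuropeptide family names recognized by the classifier
#' @export
NP_FAMILIES <- c("RPCH/AKH1", "RPCH", "AKH2", "AKH3", "AKH4", "ACP", "CRZ",
                 "GnRH", "APGWamide", "LWamide")

# families forming the AKH supergroup (octapeptide-derived hormones)
AKH_SUPERGROUP <- c("RPCH/AKH1", "RPCH", "AKH2", "AKH3", "AKH4", "ACP")

#' Canonical rule-satisfying peptide templates, one per family
#'
#' Used by the synthetic-data generator and as documentation of the rule
#' set: each template classifies to its own family at mutation rate 0.
#' @export
FAMILY_TEMPLATES <- c(
  "LWamide"            = "GLRW",
  "APGWamide"          = "APGW",
  "RPCH/AKH1"          = "QLNFSPGW",
  "AKH2"               = "QLNFSPGWG",
  "AKH3"               = "QLNFSPGWQ",
  "AKH4"               = "QLNFSTWGA",
  "ACP"                = "QLNFSPGWGT",
  "CRZ"                = "QTFQYSRGWTNG",
  "GnRH-protostome"    = "GAQPSTNWYPGG",
  "GnRH-deuterostome"  = "GAQPHTNWYP")

.res_at <- function(ch, i) if (length(ch) >= i) ch[i] else ""

#' Classify a mature peptide into a neuropeptide family
#'
#' Ordered rule cascade; the first matching rule wins, with the most
#' specific multi-feature families tested first so the generic C-terminal
#' APGW/LW rules cannot shadow them. Positions are 1-based from the mature
#' N-terminus (e.g. "phenylalanine in the fourth position"). An N-terminal
#' Q is treated as equivalent to pyro-Gln; no sequence edit is made.
#'
#' Rules (all families require C-terminal amidation):
#' \itemize{
#'   \item RPCH/AKH1: octapeptide, F at 4, W at 8. With a crustacean
#'     lineage the merged call resolves to RPCH (RPCH is exclusively
#'     crustacean); otherwise the merged "RPCH/AKH1" is returned.
#'   \item AKH2: 9-mer, F4, W8, glycine after the tryptophan.
#'   \item AKH3: 9-mer, F4, W8, glutamine after the tryptophan.
#'   \item AKH4: 9-12 residues, F4, tryptophan present but not at
#'     position 8 (a different organization around the tryptophan);
#'     called only by exclusion within the AKH supergroup.
#'   \item ACP: 10-12 residues, F4, W8 then glycine; crustacean-type
#'     length variants (two additional residues) are noted in
#'     `matched_features`.
#'   \item CRZ: Gln-Tyr repeat between the phenylalanine and serine
#'     (contiguous FQYS), tryptophan downstream; the Thr-Asn-Gly tail
#'     motif is noted when present.
#'   \item GnRH: glycine at position 1, tryptophan present, 8-13 residues.
#'   \item APGWamide: ends in P-G-W, leucine absent.
#'   \item LWamide: C-terminal tryptophan with a leucine in the peptide.
#' }
#'
#' @param peptide mature amino-acid string (no dibasic dyads).
#' @param amidated logical; is the C-terminus amidated (glycine donor
#'   followed by a dyad in the precursor)?
#' @param lineage optional named character vector of taxonomy ranks for the
#'   source record (used only to resolve RPCH vs AKH1).
#' @return list of class `family_call` with `family` (or "unclassified")
#'   and `matched_features`.
#' @export
classify_family <- function(peptide, amidated, lineage = NULL) {
  if (!nzchar(peptide)) stop("empty peptide")
  ch <- .chars(peptide)
  n <- length(ch)
  feats <- character(0)
  fam <- "unclassified"

  f4 <- .res_at(ch, 4L) == "F"
  w8 <- .res_at(ch, 8L) == "W"
  has_w <- "W" %in% ch

  if (amidated) {
    if (n == 8L && f4 && w8) {
      fam <- "RPCH/AKH1"
      feats <- c("len8", "F4", "W8", "amide")
      if (.is_crustacean(lineage)) {
        fam <- "RPCH"
        feats <- c(feats, "crustacean_lineage")
      }
    } else if (n == 9L && f4 && w8 && ch[9L] == "G") {
      fam <- "AKH2"; feats <- c("len9", "F4", "W8", "G_after_W", "amide")
    } else if (n == 9L && f4 && w8 && ch[9L] == "Q") {
      fam <- "AKH3"; feats <- c("len9", "F4", "W8", "Q_after_W", "amide")
    } else if (n >= 9L && n <= 12L && f4 && has_w && !w8) {
      fam <- "AKH4"
      feats <- c("len9_12", "F4", "W_shifted", "amide")
    } else if (n >= 10L && n <= 12L && f4 && w8 && .res_at(ch, 9L) == "G") {
      fam <- "ACP"
      feats <- c("len10_12", "F4", "W8", "G_after_W", "amide")
      feats <- c(feats, if (n >= 12L) "crustacean_type" else "insect_type")
    } else if (grepl("FQYS", peptide, fixed = TRUE) &&
               regexpr("FQYS", peptide, fixed = TRUE)[1L] + 3L <
                 max(which(ch == "W"), 0L)) {
      fam <- "CRZ"
      feats <- c("FQYS", "W_downstream", "amide")
      if (grepl("TNG", peptide, fixed = TRUE)) feats <- c(feats, "TNG_tail")
    } else if (ch[1L] == "G" && has_w && n >= 8L && n <= 13L) {
      fam <- "GnRH"
      feats <- c("G1", "W_present", "amide")
    } else if (n >= 3L && endsWith(peptide, "PGW") && !"L" %in% ch) {
      fam <- "APGWamide"
      feats <- c("PGW_terminus", "no_L", "amide")
    } else if (ch[n] == "W" && "L" %in% ch) {
      fam <- "LWamide"
      feats <- c("W_terminus", "L_present", "amide")
    }
  }
  structure(list(family = fam, matched_features = feats),
            class = "family_call")
}

.is_crustacean <- function(lineage) {
  if (is.null(lineage)) return(FALSE)
  any(tolower(lineage) %in% c("crustacea", "malacostraca", "branchiopoda"))
}

#' Assign a GnRH peptide to the protostome or deuterostome lineage
#'
#' Length-relative rule anchored on the family tryptophan: relative to the
#' 12-residue protostome anchor form, equal-length peptides sharing the
#' glycine at position 1 and serine at position 5 are protostome-type;
#' forms two residues shorter sharing glycine, tryptophan and a proline are
#' deuterostome-type; everything else (including peptides lacking
#' tryptophan) is ambiguous.
#'
#' @param peptide mature GnRH peptide string.
#' @return one of "protostome", "deuterostome", "ambiguous".
#' @export
classify_gnrh_lineage <- function(peptide) {
  ch <- .chars(peptide)
  n <- length(ch)
  if (!"W" %in% ch) return("ambiguous")
  if (n == 12L && .res_at(ch, 1L) == "G" && .res_at(ch, 5L) == "S")
    return("protostome")
  if (n == 10L && .res_at(ch, 1L) == "G" && "P" %in% ch)
    return("deuterostome")
  "ambiguous"
}

#' Extract mature active peptides from an annotated precursor
#'
#' Segments are taken between productive cleavage sites (rule score >=
#' 0.5), plus the leading segment between the signal-peptide end and the
#' first productive site (where the first peptide copy of the canonical
#' precursor layout sits). Each segment is trimmed of the amide-donor
#' glycine when present; segments shorter than 3 residues are discarded as
#' spacers, and segments still containing a dibasic dyad are discarded as
#' unprocessed. Copy indices are assigned left to right.
#'
#' @param annotation a `precursor_annotation` from [structural_screen()].
#' @return data.frame with columns `seq`, `start`, `end` (0-based,
#'   half-open), `amidated`, `copy_index`.
#' @export
extract_active_peptides <- function(annotation) {
  empty <- data.frame(seq = character(0), start = integer(0),
                      end = integer(0), amidated = logical(0),
                      copy_index = integer(0), stringsAsFactors = FALSE)
  aa <- annotation$aa_seq
  sites <- annotation$sites
  prod <- sites[sites$score >= CONVERTASE_TAU, , drop = FALSE]
  if (nrow(prod) == 0L) return(empty)

  sig_end <- if (!is.null(annotation$signal_span))
    annotation$signal_span[2L] else 0L
  # segment i runs from the end of site i-1 (or the signal) to site i
  starts <- c(sig_end, head(prod$pos, -1L) + 2L)
  ends <- prod$pos                        # 0-based, exclusive

  out <- empty
  k <- 0L
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (e - s < 1L) next
    seg <- substr(aa, s + 1L, e)
    amid <- FALSE
    if (endsWith(seg, "G")) {
      # glycine immediately before the downstream dyad donates the amide
      seg <- substr(seg, 1L, nchar(seg) - 1L)
      e <- e - 1L
      amid <- TRUE
    }
    if (nchar(seg) < 3L) next                       # spacer
    if (nrow(find_cleavage_sites(seg)) > 0L) next   # unprocessed remnant
    k <- k + 1L
    out <- rbind(out, data.frame(seq = seg, start = s, end = e,
                                 amidated = amid, copy_index = k,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Export the classifier rule set as JSON
#'
#' Freezes the rule order, per-family feature predicates and the canonical
#' templates so tests and external tools can pin the rule set.
#'
#' @param path optional path to write to; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
export_family_rules <- function(path = NULL) {
  rules <- list(
    order = c("RPCH/AKH1", "AKH2", "AKH3", "AKH4", "ACP", "CRZ", "GnRH",
              "APGWamide", "LWamide"),
    requires_amidation = TRUE,
    templates = as.list(FAMILY_TEMPLATES),
    features = list(
      "RPCH/AKH1" = c("len==8", "F@4", "W@8"),
      "AKH2" = c("len==9", "F@4", "W@8", "G@9"),
      "AKH3" = c("len==9", "F@4", "W@8", "Q@9"),
      "AKH4" = c("len in 9..12", "F@4", "W present, not @8"),
      "ACP" = c("len in 10..12", "F@4", "W@8", "G@9"),
      "CRZ" = c("contains FQYS", "W downstream of FQYS"),
      "GnRH" = c("G@1", "W present", "len in 8..13"),
      "APGWamide" = c("ends PGW", "no L"),
      "LWamide" = c("ends W", "contains L")))
  js <- jsonlite::toJSON(rules, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @export
print.family_call <- function(x, ...) {
  cat("family_call: ", x$family, sep = "")
  if (length(x$matched_features))
    cat(" [", paste(x$matched_features, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}
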