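---
title: "Curation, classification and DNA-loss-model phylogenetics of neuropeptide precursors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation, classification and DNA-loss-model phylogenetics of neuropeptide precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nppcur)
```

## The problem

Public sequence databases contain many entries labelled "neuropeptide
precursor" that lack the structure such a protein must have to function: a
signal peptide for entry into the rough endoplasmic reticulum, one or more
active peptides, related (spacer) peptides, and dibasic excision motifs
recognized by pro-protein convertases. Downstream evolutionary analyses are
only as good as this annotation, so the first half of this package is a
reproducible, rule-based purification of candidate precursors.

The second half concerns the *DNA loss model* (DNA-LM): the hypothesis that
new neuropeptide genes — the RPCH/AKH octapeptide hormones in particular —
arose by loss and fusion of conserved codon blocks from ancestral
multi-copy precursors such as APGWamide. Under this model one can assemble
a *virtual* precursor (an "NPP", Neuropeptide Precursor Predictive) by
fusing the conserved codon blocks of related families, and one can ask
whether phylogenies built under the DNA-LM alignment penalties group
families differently than phylogenies built under default penalties. The
package implements both constructions and quantifies the contrast with the
Robinson-Foulds metric.

## The purge: three ordered screens

`run_purge()` applies three screens in a fixed order; each stage only sees
survivors of the previous one, so the stage counts are monotone
non-increasing by construction.

1. **Structural screen.** A candidate must (a) carry a detectable signal
   peptide, (b) contain at least one dibasic dyad (KR, RK, RR or KK), and
   (c) be 40–2000 residues long. The length floor removes fragments
   (the shortest real precursors, e.g. AKH, exceed 40 aa); the ceiling
   removes obvious polyproteins and database chimeras.
2. **Dibasic screen.** At least one dyad must be immediately preceded by
   glycine — the amide-donor pattern `...X-G-[dyad]` that C-terminally
   amidated neuropeptides require.
3. **Convertase screen.** At least one site must score at or above the
   productive threshold τ = 0.5 under the convertase rule score.

**Convertase rule score.** Rather than a neural-network predictor, the
package uses a stated, deterministic rule so that every decision is
reproducible and auditable: base 0.5 for any dibasic dyad, +0.5 when the
dyad is KR (the canonical PC1/PC2 substrate, and the site type highlighted
in curated precursors), and 0 whenever the residue after the dyad is
proline, which sterically blocks convertase cleavage. The score is clamped
to [0, 1] and τ = 0.5 marks a productive site. The rule is monotone —
KR-containing, proline-free sites always win — which is all the pipeline
needs from it.

**Signal-peptide heuristic.** A sequence must start with methionine and
contain, within its first 30 residues, a window of 8 consecutive residues
with at least 6 from the hydrophobic set {A, I, L, M, F, V, W, C} (the
classical h-region). The cleavage point is the end of the first such
window plus 5 residues, clamped to [15, 35] — the empirical length range
of secretory signal peptides. This is deliberately a structural heuristic,
not a trained predictor: the pipeline uses the *presence* of the canonical
architecture, not a calibrated cleavage probability.

Manual curation is represented explicitly: optional allow/deny lists
applied after stage 3. An allowed record is marked verified at all three
stages (so counts stay coherent); a denied record is marked failed at
stage 3. Records contributed by family-specific external searches enter as
an `additions` count map, and the final database size is
`n_convertase + sum(additions)` — e.g. the published 636 + 45 + 38 = 719.

## Peptide extraction and family rules

`extract_active_peptides()` cuts the precursor between productive cleavage
sites, plus the leading segment between the signal-peptide end and the
first site, where the first peptide copy sits in the canonical layout
(signal — peptide — G — dyad — peptide — G — dyad — ... — related
peptide). The amide-donor glycine is trimmed and sets `amidated = TRUE`.
Segments shorter than 3 residues are spacers; segments still containing a
dyad are unprocessed remnants; both are dropped.

`classify_family()` is an ordered rule cascade (most specific first, so
the generic C-terminal APGW/LW rules cannot shadow the octapeptide
families). All rules require amidation; positions are 1-based from the
mature N-terminus; an N-terminal Gln is treated as pyro-Gln without
editing the sequence.

| order | family | rule |
|---|---|---|
| 1 | RPCH/AKH1 | length 8, F at 4, W at 8 |
| 2 | AKH2 | length 9, F4, W8, Gly after the Trp |
| 3 | AKH3 | length 9, F4, W8, Gln after the Trp |
| 4 | AKH4 | length 9–12, F4, Trp present but *not* at 8 |
| 5 | ACP | length 10–12, F4, W8 then Gly (12-mers flagged crustacean-type) |
| 6 | CRZ | contiguous Phe-Gln-Tyr-Ser, Trp downstream (Thr-Asn-Gly tail noted) |
| 7 | GnRH | Gly at 1, Trp present, length 8–13 |
| 8 | APGWamide | ends Pro-Gly-Trp, leucine absent |
| 9 | LWamide | C-terminal Trp with a leucine present |

Two design points deserve comment. RPCH and AKH1 are not separable on
sequence features alone; the classifier returns the merged call
"RPCH/AKH1" and resolves it to RPCH only when a crustacean lineage is
supplied, since RPCH is exclusively crustacean. AKH4 is defined by
*exclusion* within the AKH supergroup — its diagnostic is precisely a
different organization around the tryptophan — so its rule requires the
Trp to sit away from position 8; this keeps the W8 decapeptides reachable
by the later ACP rule despite AKH4's earlier position in the cascade.
`classify_gnrh_lineage()` then splits GnRH calls by a length-relative rule
anchored on the Trp: 12-mers with Gly-1 and Ser-5 are protostome-type,
10-mers (two residues shorter) with Gly-1 and a Pro are deuterostome-type,
anything else — including Trp-less peptides — is ambiguous.

The full rule set (order, predicates, canonical templates) can be frozen
to JSON with `export_family_rules()`.

## The alignment engine

`pairwise_affine_align()` is a global affine-gap aligner over BLOSUM62
(embedded as a frozen table so scores never drift with dependency
versions) with one non-standard feature that the DNA-LM regime requires: a
*separate terminal-gap rate*. Internal gap runs cost
`gap_open + gap_extend * (len - 1)`; runs touching the first or last
column of the alignment cost `terminal_gap` per residue instead. The
`bonus` parameter adds a constant per matched column (0 in both presets,
hence a no-op, but carried for completeness). Two presets are defined:

* `"dnalm"` — open 9, extend 0.2, terminal 0.45, bonus 0: the
  DNA-loss-model regime, which makes end gaps nearly free and internal
  gaps expensive, so short hormones align *into* the conserved cores of
  long multi-copy precursors rather than being smeared across them;
* `"default"` — open 11, extend 0.85, terminal 0.45, bonus 0: the
  package's default regime for the contrast, chosen to match commonly
  used protein-alignment penalties.

The dynamic program carries three states (match, insertion in either
sequence) with dedicated boundary handling so that a run charged at the
terminal rate is never part-charged at the internal rate; correctness is
guaranteed against the scoring *definition* (`score_alignment()`) by an
exhaustive enumeration oracle in the test suite, over all global
alignments of random pairs up to length 8, including a deliberately
adversarial parameter set where terminal gaps are *more* expensive than
internal ones. Ties are broken deterministically: match over insertion in
the first sequence over insertion in the second.

`progressive_align()` builds a UPGMA guide tree from 3-mer cosine
distances (fast, deterministic, adequate for family-scale sets) and merges
profiles with the same machinery, scoring a column pair as the mean
BLOSUM62 score over ungapped residue pairs. Sequence ids are sorted before
guide-tree construction, so the alignment is invariant to input order.

## Codon blocks and NPP fusion

`codon_backmap()` projects a protein alignment onto codons (one codon
column per residue column, `---` at gaps; stripping gaps restores each
coding sequence exactly). `find_conserved_blocks()` marks maximal runs of
columns whose mean pairwise nucleotide identity (gaps excluded) reaches
`min_ident`, keeping runs of at least `min_len` columns. The defaults —
`min_len = 4` codons, `min_ident = 0.8` — encode the DNA-LM's unit of
conservation: the four-codon runs (the first four and the last four
residues of the octapeptide hormones) that the model traces into the
APGWamide copies. `fuse_blocks()` concatenates the consensus codon of each
block (column-wise plurality, lexicographic tie-break) in template-row
coordinate order and translates the fusion: the virtual NPP.
`validate_npp_layout()` closes the loop by running the purge annotation
and the classifier on any precursor and tabulating copies per family —
the rotifer-style fixture (three APGWamide copies plus one AKH-type
decapeptide, each followed by G + KR) yields exactly
`{APGWamide: 3, AKH-group: 1}`.

## Trees and the regime contrast

Tree inference is deliberately simple: neighbor joining on p-distances
from each alignment regime. Maximum-likelihood inference with model
selection and bootstrap support is out of scope here — the deliverable is
the *contrast between regimes*, which only requires that both trees be
built by the same deterministic method from the two alignments.
`robinson_foulds()` is the symmetric difference of the two trees'
nontrivial bipartition sets, computed on unrooted topologies with
canonical (smaller-side) split keys; `normalized_rf()` divides by the
total number of splits, giving [0, 1] regardless of resolution.
Single-number RF summaries reported for such regime contrasts are often
non-integer — an averaged or normalized variant whose exact definition is
rarely stated — so the package always reports both the raw integer
distance and its own explicitly defined normalization, and treats
externally reported single values as non-reproducible.
"Association" between families on a tree is likewise given a concrete
operational definition in `clade_association_counts()`: a leaf is
associated with a reference family when its sibling subtree contains at
least one reference leaf.

## The synthetic generator

`generate_precursors()` emulates exactly the structure the screens test:
a signal peptide built so that its *detected* cleavage point equals its
true length (Met + 7 hydrophobic + 7 hydrophilic residues), k copies of a
family template followed by the amide-donor glycine and a KR dyad, and a
basic-residue-free hydrophilic tail. Invalid records receive exactly one
corruption — signal removed, dyads removed, amide-donor glycines removed,
or truncation below the length gate — each engineered to defeat exactly
one screen. Validity is stratified (`round(n * p_valid)` valid records,
exactly) so count assertions are sharp; a Bernoulli mode exists for
statistical tests. Coding sequences come from reverse translation with
uniform synonymous codon choice, and `mutate_precursor()` keeps cds and
protein consistent when mutating. All generators fix the RNG kind
(Mersenne-Twister) so output is byte-identical across platforms under a
given seed.

What the generator does *not* emulate — and hence what green tests do not
show about real data: genuine signal-peptide diversity (real h-regions are
not clean 8-mers), monobasic and non-canonical cleavage sites, sequence
families with internal homology between copies, database noise such as
frameshifted translations, and any indel evolution along trees.
`generate_tree_pair()` produces topological fixtures (a random binary tree
and a k-NNI neighbor), not simulated alignments.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open internally; printed reports are
  1-based.
* Non-standard residues (B, Z, U, O) are mapped to X on input with a
  warning; motif rules are defined only on the standard alphabet.
* Floating-point score comparisons in the aligner traceback use a 1e-9
  tolerance; the retention percentage is truncated, not rounded, at two
  decimals (719/13,778 → 5.21).
* Consensus and guide-tree ties break lexicographically; NJ input labels
  are sorted first.
* The test and acceptance workloads use batches of 1000 synthetic records
  (10 seeds × 3 validity fractions), 200 aligner-oracle pairs of length
  ≤ 8, 200–500 oracle comparisons for splits and dyad scans, and
  40-record end-to-end runs with 24 sequences per alignment — sizes chosen
  so the whole suite exercises every property at comfortable desk scale.

## Known limitations

The purge rules are declared stand-ins for the tool chain they replace
(structure screen, dibasic screen, convertase prediction): they are
deterministic and tested, but they are not calibrated against
experimentally verified cleavage data. The family rules encode the
features that separate the seven families on curated examples; peptides
from families with no stated motif (cerebral peptide, PTSP) are reported
as unclassified by design. The aligner is quadratic-time R code intended
for family-scale sets (tens of sequences, hundreds of residues), not
genome-scale alignment. NJ trees carry no support values; conclusions
about any *particular* clade should be re-checked with a full ML pipeline.
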