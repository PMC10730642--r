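# Neighbor-joining trees, split sets, the Robinson-Foulds metric, and
# clade-association counts between neuropeptide families.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}), with labels
#' sorted first so ties are broken deterministically by label order.
#'
#' @param d symmetric numeric matrix with zero diagonal and matching
#'   dimnames, or a named `dist`.
#' @param labels optional character vector of leaf labels overriding the
#'   dimnames.
#' @return an \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d))) stop("distance matrix must carry labels")
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  ord <- order(rownames(d))
  ape::nj(as.dist(d[ord, ord]))
}

# tips below each node, as a list indexed by node number
.tips_below <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  below <- vector("list", n_node)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  edge <- stats::reorder(tree, "postorder")$edge  # children before parents
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

# canonical key of one bipartition: the smaller side (lexicographically
# smaller side on ties), sorted labels joined by "|"
.split_key <- function(side, all_tips) {
  other <- setdiff(all_tips, side)
  a <- paste(sort(side), collapse = "|")
  b <- paste(sort(other), collapse = "|")
  if (length(side) < length(other)) a
  else if (length(other) < length(side)) b
  else min(a, b)
}

#' Nontrivial bipartitions of a tree
#'
#' One split per internal edge of the unrooted topology; trivial splits
#' (single leaf vs rest) are omitted, and multifurcations contribute one
#' split per edge only. Each split is represented canonically by its
#' smaller side.
#'
#' @param tree an \pkg{ape} `phylo` tree.
#' @return character vector of canonical split keys (class `split_set`,
#'   with attribute `tips`).
#' @export
splits <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  n_tip <- length(tree$tip.label)
  if (n_tip >= 3L && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  out <- character(0)
  if (n_tip >= 4L) {
    below <- .tips_below(tree)
    root <- n_tip + 1L
    internal_children <- tree$edge[tree$edge[, 2L] > n_tip, 2L]
    for (nd in internal_children) {
      side <- below[[nd]]
      if (length(side) >= 2L && length(side) <= n_tip - 2L)
        out <- c(out, .split_key(side, tree$tip.label))
    }
    out <- unique(out)
  }
  structure(sort(out), class = "split_set", tips = sort(tree$tip.label))
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the two trees' nontrivial
#' split sets, computed on unrooted topologies.
#'
#' @param t1,t2 \pkg{ape} `phylo` trees on the same leaf set.
#' @return integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  s1 <- splits(t1); s2 <- splits(t2)
  tips1 <- attr(s1, "tips"); tips2 <- attr(s2, "tips")
  if (!identical(tips1, tips2)) {
    d1 <- setdiff(tips1, tips2); d2 <- setdiff(tips2, tips1)
    stop("leaf sets differ: only in first = {",
         paste(d1, collapse = ","), "}; only in second = {",
         paste(d2, collapse = ","), "}")
  }
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Normalized Robinson-Foulds distance
#'
#' `RF / (|S1| + |S2|)`, in \[0, 1\]; defined as 0 when both trees have
#' empty split sets (e.g. star trees).
#'
#' @inheritParams robinson_foulds
#' @return numeric in \[0, 1\].
#' @export
normalized_rf <- function(t1, t2) {
  rf <- robinson_foulds(t1, t2)
  denom <- length(splits(t1)) + length(splits(t2))
  if (denom == 0L) return(0)
  rf / denom
}

#' Clade association counts against a reference family
#'
#' A leaf of family F is "associated" with the reference family when its
#' sibling subtree (the clade attached at its parent edge) contains at
#' least one reference-family leaf. This operationalizes the notion of a
#' family "sharing nodes" with, e.g., vertebrate GnRH. Computed on the
#' tree as rooted/stored.
#'
#' @param tree an \pkg{ape} `phylo` tree.
#' @param family_labels named character vector mapping every leaf label to
#'   a family name.
#' @param reference_family family name of the reference leaves.
#' @return data.frame with `family`, `associated`, `total` for each
#'   non-reference family.
#' @export
clade_association_counts <- function(tree, family_labels, reference_family) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(family_labels))
  if (length(missing))
    stop("unlabeled leaf/leaves: ", paste(missing, collapse = ", "))
  fam <- family_labels[tips]
  below <- .tips_below(tree)
  ref_tips <- tips[fam == reference_family]

  assoc <- logical(length(tips))
  for (i in seq_along(tips)) {
    if (fam[i] == reference_family) next
    e <- which(tree$edge[, 2L] == i)
    if (!length(e)) next
    parent <- tree$edge[e[1L], 1L]
    sib <- setdiff(below[[parent]], tips[i])
    assoc[i] <- any(sib %in% ref_tips)
  }
  fams <- sort(unique(fam[fam != reference_family]))
  data.frame(
    family = fams,
    associated = vapply(fams, function(f) sum(assoc[fam == f]), integer(1)),
    total = vapply(fams, function(f) sum(fam == f), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise p-distances from a multiple alignment
#'
#' Fraction of differing residues over columns where both rows are
#' ungapped; 1 when two rows share no ungapped column.
#'
#' @param aln named character vector of equal-length gapped rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(aln) {
  ids <- names(aln)
  chars <- lapply(aln, .chars)
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a != "-" & b != "-"
    d[i, j] <- d[j, i] <- if (!any(ok)) 1 else mean(a[ok] != b[ok])
  }
  d
}

#' Read / write newick trees
#'
#' Thin wrappers over \pkg{ape}'s newick I/O so the pipeline's tree format
#' is explicit.
#' @param path newick file path.
#' @return [read_newick()]: a `phylo`; [write_newick()]: `path`, invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree a `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
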