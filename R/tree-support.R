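# Concatenation ("supermatrix") trees versus single-gene trees: build trees by
# neighbor joining on Poisson-corrected distances and measure, for every
# internal node (bipartition) of the concatenated tree, how often the same
# bipartition occurs among the single-gene trees.

#' Concatenate per-gene alignments row-wise
#'
#' All gene alignments must cover the identical taxon set (the universal-gene
#' assumption); a mismatch is an error listing the symmetric difference rather
#' than silent gap padding.
#'
#' @param alignments A list of alignments, each a named character vector of
#'   equal-length aligned amino-acid rows (gap character `-`). List names are
#'   used as gene ids.
#' @return A single alignment (named character vector) with attribute
#'   `gene_ranges`: a data frame of per-gene column ranges.
#' @export
concatenate_alignments <- function(alignments) {
  if (!is.list(alignments) || !length(alignments))
    fail("'alignments' must be a non-empty list of alignments")
  gene_ids <- names(alignments) %||% sprintf("gene_%02d", seq_along(alignments))
  for (g in seq_along(alignments)) validate_alignment(alignments[[g]], gene_ids[g])
  taxa <- names(alignments[[1L]])
  for (g in seq_along(alignments)) {
    other <- names(alignments[[g]])
    if (!setequal(taxa, other)) {
      diff <- c(setdiff(taxa, other), setdiff(other, taxa))
      fail("gene '%s' does not cover the shared taxon set; differing taxa: %s",
           gene_ids[g], paste(sort(diff), collapse = ", "))
    }
  }
  lens <- vapply(alignments, function(a) nchar(a[[1L]]), numeric(1))
  ends <- cumsum(lens)
  rows <- vapply(taxa, function(tx) {
    paste(vapply(alignments, function(a) unname(a[tx]), ""), collapse = "")
  }, "")
  out <- stats::setNames(rows, taxa)
  attr(out, "gene_ranges") <- data.frame(
    gene_id = gene_ids, start = ends - lens + 1, end = ends,
    stringsAsFactors = FALSE)
  out
}

validate_alignment <- function(alignment, label = "alignment") {
  if (!is.character(alignment) || is.null(names(alignment)) ||
      any(!nzchar(names(alignment))))
    fail("%s must be a named character vector of aligned rows", label)
  if (anyDuplicated(names(alignment)))
    fail("%s has duplicated taxon ids", label)
  if (length(unique(nchar(alignment))) > 1L)
    fail("%s rows differ in length", label)
  invisible(alignment)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' For each pair of rows, `p` is the proportion of differing sites among sites
#' where neither row has a gap (pairwise deletion), and the distance is the
#' multiple-hit correction `-ln(1 - p)`, capped at `d_max` as `p` approaches 1.
#'
#' @param alignment Named character vector of equal-length aligned rows.
#' @param d_max Cap applied when `p >= 1 - 1e-9` (default 10).
#' @return Symmetric numeric matrix with zero diagonal, taxon ids as dimnames.
#' @export
poisson_distance <- function(alignment, d_max = 10) {
  validate_alignment(alignment)
  if (length(alignment) < 2L) fail("alignment must contain at least 2 taxa")
  taxa <- names(alignment)
  m <- do.call(rbind, strsplit(unname(alignment), "", fixed = TRUE))
  ok <- m != "-"
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        fail("no comparable (ungapped) sites between '%s' and '%s'",
             taxa[i], taxa[j])
      p <- sum(m[i, comp] != m[j, comp]) / nc
      d <- if (p >= 1 - 1e-9) d_max else min(-log(1 - p), d_max)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree reconstruction
#'
#' Standard neighbor joining on the Q-criterion. Ties in the Q minimum are
#' broken by the smallest (row, column) index pair in the current agglomeration
#' order (merged nodes are appended after the remaining ones), negative
#' estimated branch lengths are clamped to zero, and the returned tree is
#' unrooted. On additive input the generating topology and all path distances
#' are recovered exactly.
#'
#' @param D Symmetric, non-negative, zero-diagonal distance matrix with taxon
#'   ids as dimnames; at least 3 taxa (3 taxa return the unique star
#'   resolution).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    fail("'D' must be a square numeric matrix")
  labels <- rownames(D) %||% colnames(D)
  if (is.null(labels)) fail("'D' must have taxon ids as dimnames")
  if (anyDuplicated(labels)) fail("'D' has duplicated taxon ids")
  if (any(!is.finite(D))) fail("'D' contains non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) fail("'D' must be symmetric")
  if (any(D < 0)) fail("'D' must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) fail("'D' must have a zero diagonal")
  n <- nrow(D)
  if (n < 3L) fail("neighbor joining needs at least 3 taxa")

  frags <- labels
  d <- unname(D)
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    merged <- sprintf("(%s:%.12g,%s:%.12g)", frags[i], li, frags[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    dk <- dk[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, dk), c(dk, 0))
    frags <- c(frags[-c(i, j)], merged)
  }
  la <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  lb <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  lc <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frags[1], la, frags[2], lb, frags[3], lc)
  ape::read.tree(text = nwk)
}

## Table of internal nodes and their canonical bipartitions for an (un)rooted
## binary tree. The returned `tree` element is the unrooted tree the node ids
## refer to.
node_split_table <- function(tree) {
  if (!inherits(tree, "phylo")) fail("'tree' must be a phylo object")
  if (anyDuplicated(tree$tip.label))
    fail("tree has duplicated leaf labels: %s",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) fail("tree must have at least 4 leaves")
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tr$Nnode)
  sets[seq_len(ntip)] <- as.list(tr$tip.label)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  root <- ntip + 1L
  internal <- setdiff(ntip + seq_len(tr$Nnode), root)
  splits <- vapply(internal, function(v) canonical_split(sets[[v]], tr$tip.label), "")
  list(tree = tree,
       table = data.frame(node = internal, split = splits,
                          stringsAsFactors = FALSE))
}

#' Canonical bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves in two; the split
#' is represented canonically as the sorted, comma-joined leaf set on the side
#' *not* containing the lexicographically smallest leaf, so that the two
#' orientations of a split compare equal. Trivial (single-leaf) splits are
#' excluded; a binary tree on `n` leaves yields `n - 3` bipartitions.
#'
#' @param tree A `phylo` tree over at least 4 uniquely labelled leaves (rooted
#'   trees are unrooted first).
#' @return Character vector of canonical bipartition strings.
#' @export
bipartitions <- function(tree) {
  unique(node_split_table(tree)$table$split)
}

#' Node frequencies of a reference tree among gene trees
#'
#' For every bipartition of the reference (e.g. concatenated) tree, counts in
#' how many gene trees the identical bipartition occurs, and reports the count
#' and the frequency `count / n_gene_trees`. All trees must share the same
#' leaf set; matching is exact bipartition identity.
#'
#' @param ref_tree Reference `phylo` tree.
#' @param gene_trees List of `phylo` trees over the identical leaf set.
#' @return A data frame of class `"support_annotation"` with columns
#'   `bipartition`, `count`, `frequency`, and attribute `n_gene_trees`.
#' @export
node_frequencies <- function(ref_tree, gene_trees) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (!length(gene_trees)) fail("'gene_trees' must contain at least one tree")
  ref_leaves <- sort(ref_tree$tip.label)
  gene_splits <- lapply(seq_along(gene_trees), function(g) {
    gt <- gene_trees[[g]]
    if (!setequal(ref_leaves, gt$tip.label)) {
      diff <- c(setdiff(ref_leaves, gt$tip.label),
                setdiff(gt$tip.label, ref_leaves))
      fail("gene tree %d does not match the reference leaf set; differing leaves: %s",
           g, paste(sort(diff), collapse = ", "))
    }
    bipartitions(gt)
  })
  ref_bip <- node_split_table(ref_tree)$table$split
  counts <- vapply(ref_bip, function(b) {
    sum(vapply(gene_splits, function(s) b %in% s, logical(1)))
  }, numeric(1))
  out <- data.frame(bipartition = ref_bip, count = as.integer(counts),
                    frequency = counts / length(gene_trees),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_gene_trees") <- length(gene_trees)
  class(out) <- c("support_annotation", class(out))
  out
}

#' Export a support-annotated Newick string
#'
#' Writes the tree with each internal node labelled by its gene-tree frequency
#' (4 decimal places), so any viewer can render branch support (e.g. as
#' transparency). The string round-trips through [read_newick()].
#'
#' @param tree The reference `phylo` tree (rooted input is unrooted first).
#' @param support A [node_frequencies()] result covering every internal edge
#'   of `tree`; a missing entry is an error.
#' @return A Newick string.
#' @export
annotate_newick <- function(tree, support) {
  nst <- node_split_table(tree)
  tree <- nst$tree
  tab <- nst$table
  idx <- match(tab$split, support$bipartition)
  if (anyNA(idx))
    fail("support annotation is missing bipartition(s): %s",
         paste(tab$split[is.na(idx)], collapse = "; "))
  ntip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  labels[tab$node - ntip] <- sprintf("%.4f", support$frequency[idx])
  tree$node.label <- labels
  ape::write.tree(tree)
}

#' Read Newick trees, unrooting on input
#'
#' The package works with unrooted trees throughout; any rooted tree read from
#' Newick is unrooted.
#'
#' @param path Path to a Newick file (one or more trees), or `NULL` when
#'   `text` is given.
#' @param text Optional Newick string.
#' @return A `phylo` object, or a list of them when the file holds several.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  fix <- function(t) if (ape::is.rooted(t)) ape::unroot(t) else t
  if (inherits(tr, "multiPhylo")) lapply(tr, fix) else fix(tr)
}
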