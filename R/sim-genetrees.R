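# Gene trees with seeded discordance, and protein alignments evolved along
# them. Discordance model: with probability p a gene tree receives exactly one
# nearest-neighbour interchange (NNI) at a uniformly chosen internal edge; the
# inter-domain edge is excluded by default so that every gene recovers the
# deep split between the domains while shallower nodes can be discordant. An
# NNI at an edge replaces only that edge's bipartition, which makes the
# expected gene-tree frequency of each eligible node analytic:
# 1 - p / (number of eligible edges).

#' Simulate gene trees and alignments with controlled discordance
#'
#' @param config A [simulation_config()] object (`n_universal_genes`,
#'   `sites_per_gene`, `discordance_prob`, `exclude_interdomain`,
#'   `background_c_freq` are used).
#' @param species_tree Binary unrooted `phylo` over the full genome set (at
#'   least 4 leaves).
#' @param excluded_splits Canonical bipartition strings of internal edges that
#'   must never be perturbed. Defaults, when `config$exclude_interdomain` is
#'   set, to the inter-domain split derived from the `A*`/`E*` genome naming
#'   of [simulate_taxonomy()].
#' @return A list: `trees` (named list of `phylo`), `alignments` (named list of
#'   named character vectors), `truth` (data frame `gene_id`, `perturbed`,
#'   `destroyed_split`).
#' @export
simulate_gene_trees <- function(config, species_tree, excluded_splits = NULL) {
  if (!inherits(config, "sim_config"))
    fail("invalid simulation configuration: 'config' must be a sim_config object")
  if (!inherits(species_tree, "phylo") || length(species_tree$tip.label) < 4L)
    fail("species tree must be a phylo object with at least 4 leaves (no internal edge to perturb)")

  nst <- node_split_table(species_tree)
  tree <- ape::reorder.phylo(nst$tree, "cladewise")
  nst <- node_split_table(tree)          # node ids valid for `tree`
  if (is.null(excluded_splits) && config$exclude_interdomain) {
    arch <- grep("^A", tree$tip.label, value = TRUE)
    if (length(arch) == 0L || length(arch) == length(tree$tip.label))
      fail("cannot derive the inter-domain split from tip labels; pass 'excluded_splits'")
    excluded_splits <- canonical_split(arch, tree$tip.label)
  }

  ## internal (non-terminal) edges, as rows of tree$edge, keyed by their split
  ntip <- length(tree$tip.label)
  edge_rows <- which(tree$edge[, 2L] > ntip)
  edge_split <- nst$table$split[match(tree$edge[edge_rows, 2L], nst$table$node)]
  eligible <- edge_rows[!(edge_split %in% (excluded_splits %||% character(0)))]
  eligible_split <- edge_split[!(edge_split %in% (excluded_splits %||% character(0)))]

  G <- config$n_universal_genes
  gene_ids <- sprintf("gene_%02d", seq_len(G))
  trees <- vector("list", G)
  alignments <- vector("list", G)
  perturbed <- logical(G)
  destroyed <- rep(NA_character_, G)

  with_seed(config$seed + 202L, {
    for (g in seq_len(G)) {
      gt <- tree
      if (stats::runif(1) < config$discordance_prob) {
        if (!length(eligible))
          fail("no internal edge is eligible for perturbation")
        k <- sample.int(length(eligible), 1L)
        gt <- nni_at_edge(tree, eligible[k])
        perturbed[g] <- TRUE
        destroyed[g] <- eligible_split[k]
      }
      trees[[g]] <- gt
      alignments[[g]] <- evolve_alignment(gt, config$sites_per_gene,
                                          config$background_c_freq)
    }
  })

  names(trees) <- gene_ids
  names(alignments) <- gene_ids
  list(trees = trees, alignments = alignments,
       truth = data.frame(gene_id = gene_ids, perturbed = perturbed,
                          destroyed_split = destroyed,
                          stringsAsFactors = FALSE))
}

## One nearest-neighbour interchange at internal edge `edge_row` (a row index
## of tree$edge whose child is an internal node). A random child subtree of
## the edge's child node is exchanged with a random other-side neighbour
## subtree; only the chosen edge's bipartition changes.
nni_at_edge <- function(tree, edge_row) {
  edge <- tree$edge
  u <- edge[edge_row, 1L]
  v <- edge[edge_row, 2L]
  ntip <- length(tree$tip.label)
  if (v <= ntip) fail("cannot perturb a terminal edge")
  ch_v <- edge[edge[, 1L] == v, 2L]
  ch_u <- setdiff(edge[edge[, 1L] == u, 2L], v)
  c1 <- ch_v[sample.int(length(ch_v), 1L)]
  w <- ch_u[sample.int(length(ch_u), 1L)]
  i_c <- which(edge[, 1L] == v & edge[, 2L] == c1)
  i_w <- which(edge[, 1L] == u & edge[, 2L] == w)
  edge[i_c, 1L] <- u
  edge[i_w, 1L] <- v
  tree$edge <- edge
  attr(tree, "order") <- NULL   # force a real reorder after edge surgery
  ape::reorder.phylo(tree, "cladewise")
}

## Evolve site-independent protein sequence along a tree: root residues drawn
## from the background composition (C at `c_freq`, the rest uniform), each
## branch substitutes a site with probability 1 - exp(-t), replacements
## uniform over the other 19 residues.
evolve_alignment <- function(tree, n_sites, c_freq) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  seqs <- matrix(0L, ntip + tr$Nnode, n_sites)
  p0 <- rep((1 - c_freq) / 19, 20L)
  p0[match("C", AA20)] <- c_freq
  seqs[ntip + 1L, ] <- sample.int(20L, n_sites, replace = TRUE, prob = p0)
  for (k in seq_len(nrow(tr$edge))) {
    s <- seqs[tr$edge[k, 1L], ]
    psub <- 1 - exp(-tr$edge.length[k])
    hit <- stats::runif(n_sites) < psub
    nh <- sum(hit)
    if (nh)
      s[hit] <- ((s[hit] - 1L + sample.int(19L, nh, replace = TRUE)) %% 20L) + 1L
    seqs[tr$edge[k, 2L], ] <- s
  }
  rows <- vapply(seq_len(ntip),
                 function(i) paste(AA20[seqs[i, ]], collapse = ""), "")
  stats::setNames(rows, tr$tip.label)
}
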