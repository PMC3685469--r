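# Independent oracles used to cross-check the package implementations.

## Naive motif scanner: explicit position-by-position check of the four fixed
## cysteines (no regex machinery).
naive_scan <- function(sequence, spacers = c(2L, 2L, 3L)) {
  ch <- strsplit(sequence, "")[[1L]]
  len <- 4L + sum(spacers)
  L <- length(ch)
  if (L < len) return(integer(0))
  p2 <- 1L + spacers[1L] + 1L
  p3 <- p2 + spacers[2L] + 1L
  p4 <- p3 + spacers[3L] + 1L
  hits <- integer(0)
  for (s in seq_len(L - len + 1L)) {
    if (ch[s] == "C" && ch[s + p2 - 1L] == "C" &&
        ch[s + p3 - 1L] == "C" && ch[s + p4 - 1L] == "C")
      hits <- c(hits, s)
  }
  hits
}

## Random amino-acid sequence with a chosen cysteine frequency.
random_protein <- function(len, c_freq = 0.15) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  p <- rep((1 - c_freq) / 19, 20)
  p[aa == "C"] <- c_freq
  paste(sample(aa, len, replace = TRUE, prob = p), collapse = "")
}

## Random unrooted binary tree and its (exactly additive) path-distance matrix.
random_additive_case <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  list(tree = tr, D = as.matrix(ape::cophenetic.phylo(tr)))
}

## Canonical bipartitions via ape::prop.part - an independent route from the
## package's own postorder traversal.
splits_oracle <- function(tree) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  labs <- tree$tip.label
  ref <- min(labs)
  pp <- ape::prop.part(tree)
  out <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (length(side) == length(labs)) return(NA_character_)
    if (ref %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = ",")
  }, "")
  unique(out[!is.na(out) & vapply(strsplit(out, ","), length, 1L) > 1L])
}

## Brute-force (edge x tree) membership count of reference bipartitions.
brute_node_freq <- function(ref_tree, gene_trees) {
  ref <- splits_oracle(ref_tree)
  gsplits <- lapply(gene_trees, splits_oracle)
  counts <- sapply(ref, function(b) {
    n <- 0L
    for (s in gsplits) if (b %in% s) n <- n + 1L
    n
  })
  data.frame(bipartition = ref, count = as.integer(counts),
             frequency = counts / length(gene_trees),
             stringsAsFactors = FALSE, row.names = NULL)
}

## Double-loop recount of the stringency grid.
brute_grid <- function(presence, arch_thresholds, eub_thresholds) {
  counts <- matrix(0L, length(arch_thresholds), length(eub_thresholds))
  for (i in seq_along(arch_thresholds)) {
    for (j in seq_along(eub_thresholds)) {
      n <- 0L
      for (f in seq_len(nrow(presence))) {
        if (presence$n_arch_groups[f] >= arch_thresholds[i] &&
            presence$n_eub_groups[f] >= eub_thresholds[j]) n <- n + 1L
      }
      counts[i, j] <- n
    }
  }
  counts
}

## One passing hit-table row (convenience for constructed cases).
make_hit <- function(qseqid, genome, pident = 80, evalue = 1e-30,
                     protein = "p1") {
  data.frame(qseqid = qseqid, sseqid = sprintf("%s|%s", genome, protein),
             pident = pident, length = 100L, mismatch = 20L, gapopen = 1L,
             qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
             evalue = evalue, bitscore = 200, stringsAsFactors = FALSE)
}

## Small group map for constructed tests.
tiny_group_map <- function() {
  data.frame(
    genome_id = c("a1", "a2", "b1", "b2", "b3", "b4"),
    domain = c("archaebacteria", "archaebacteria", rep("eubacteria", 4)),
    group = c("A01", "A01", "E01", "E01", "E02", "E02"),
    stringsAsFactors = FALSE)
}
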