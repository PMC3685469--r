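aln <- function(...) {
  x <- c(...)
  setNames(as.character(x), names(x))
}

test_that("concatenation is row-wise, additive and order-checked", {
  g1 <- aln(A = "ACDEF", B = "ACDEF", C = "MMMMM")
  g2 <- aln(C = "WWWWWWW", A = "ACDEFGH", B = "ACDEFGH")
  cc <- concatenate_alignments(list(x = g1, y = g2))
  expect_equal(unname(nchar(cc)), rep(12, 3))
  expect_equal(unname(cc["C"]), "MMMMMWWWWWWW")
  rng <- attr(cc, "gene_ranges")
  expect_equal(rng$start, c(1, 6))
  expect_equal(rng$end, c(5, 12))
  # single gene: identity
  one <- concatenate_alignments(list(g = g1))
  expect_equal(unname(one[names(g1)]), unname(g1))
  # taxon mismatch lists the symmetric difference
  g3 <- aln(A = "AA", D = "AA")
  expect_error(concatenate_alignments(list(g1, g3)), "B.*C.*D|D")
})

test_that("gene order does not change the concatenated distance matrix", {
  set.seed(41)
  taxa <- c("A", "B", "C", "D")
  genes <- lapply(1:4, function(i)
    setNames(vapply(taxa, function(t) random_protein(30), ""), taxa))
  D1 <- poisson_distance(concatenate_alignments(genes))
  D2 <- poisson_distance(concatenate_alignments(genes[c(3, 1, 4, 2)]))
  expect_equal(D1, D2)
})

test_that("poisson distances follow -ln(1 - p) with pairwise deletion", {
  a <- aln(x = "AAAAAAAAAA", y = "AAAAAAAAAA")
  expect_equal(poisson_distance(a)["x", "y"], 0)
  # exactly half the sites differ: d = ln 2
  b <- aln(x = "AAAAAAAAAA", y = "AAAAAWWWWW")
  expect_equal(poisson_distance(b)["x", "y"], log(2))
  # gapped sites are skipped in both p's numerator and denominator
  g <- aln(x = "AA--AAAAAA", y = "AAWWAAAAWW")  # 8 comparable, 2 differ
  expect_equal(poisson_distance(g)["x", "y"], -log(1 - 2 / 8))
  # saturated pairs are capped
  s <- aln(x = "AAAA", y = "WWWW")
  expect_equal(poisson_distance(s, d_max = 10)["x", "y"], 10)
  # no comparable sites is an error naming the pair
  n <- aln(x = "--AA", y = "WW--")
  expect_error(poisson_distance(n), "x.*y")
})

test_that("neighbor joining resolves the additive quartet exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_identical(bipartitions(tr), "C,D")   # the AB|CD split
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), colnames(D)],
               D, tolerance = 1e-10)
  # branch lengths recovered: tips at 1, 2, 3, 4 and internal edge 1
  lens <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(lens[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
})

test_that("neighbor joining recovers random additive trees (vs ape oracle)", {
  set.seed(43)
  for (i in 1:25) {
    case <- random_additive_case(sample(4:12, 1))
    tr <- neighbor_joining(case$D)
    expect_setequal(bipartitions(tr), splits_oracle(case$tree))
    # independent implementation route agrees on topology
    expect_setequal(bipartitions(tr), splits_oracle(ape::nj(case$D)))
    # path distances reproduced within 1e-9
    got <- as.matrix(ape::cophenetic.phylo(tr))[rownames(case$D), colnames(case$D)]
    expect_lt(max(abs(got - case$D)), 1e-9)
  }
})

test_that("neighbor joining validates its input and clamps branch lengths", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(D), "at least 3")
  M <- matrix(runif(16), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(neighbor_joining(M), "symmetric")
  S <- (M + t(M)) / 2; diag(S) <- 0; S[1, 2] <- S[2, 1] <- -0.1
  expect_error(neighbor_joining(S), "non-negative")
  # near-degenerate matrices still give non-negative branch lengths
  set.seed(47)
  for (i in 1:10) {
    n <- 6
    R <- matrix(runif(n * n, 0, 0.05), n, n,
                dimnames = list(letters[1:n], letters[1:n]))
    R <- (R + t(R)) / 2; diag(R) <- 0
    tr <- neighbor_joining(R)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("bipartitions are canonical and match the independent oracle", {
  q <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_identical(bipartitions(q), "C,D")
  # same split written from the other side hashes identically
  q2 <- read_newick(text = "((C:1,D:1):1,(A:1,B:1):1);")
  expect_identical(bipartitions(q), bipartitions(q2))
  cat6 <- read_newick(text = "(A:1,(B:1,(C:1,(D:1,(E:1,F:1):1):1):1):1);")
  expect_length(bipartitions(cat6), 3)
  set.seed(53)
  for (i in 1:10) {
    tr <- ape::rtree(sample(5:12, 1), rooted = FALSE)
    expect_setequal(bipartitions(tr), splits_oracle(tr))
  }
  dup <- ape::rtree(5, rooted = FALSE)
  dup$tip.label[2] <- dup$tip.label[1]
  expect_error(bipartitions(dup), "duplicated")
})

test_that("node frequencies count exact bipartition matches", {
  ref <- read_newick(text = "((A,B),(C,D));")
  g1 <- read_newick(text = "((A,B),(C,D));")
  g2 <- read_newick(text = "((A,C),(B,D));")
  nf <- node_frequencies(ref, list(g1, g2, g1))
  expect_equal(nf$frequency, 2 / 3)
  expect_equal(nf$count, 2L)
  expect_equal(attr(nf, "n_gene_trees"), 3)
  # all gene trees identical: every frequency 1
  nf1 <- node_frequencies(ref, list(g1, g1))
  expect_true(all(nf1$frequency == 1))
  bad <- read_newick(text = "((A,B),(C,E));")
  expect_error(node_frequencies(ref, list(bad)), "D.*E|E.*D")
})

test_that("node frequencies equal brute-force membership counts", {
  set.seed(59)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    labs <- paste0("t", seq_len(n))
    ref <- ape::rtree(n, rooted = FALSE, tip.label = labs)
    genes <- lapply(seq_len(sample(5:20, 1)), function(k)
      ape::rtree(n, rooted = FALSE, tip.label = labs))
    nf <- node_frequencies(ref, genes)
    oracle <- brute_node_freq(ref, genes)
    m <- merge(nf, oracle, by = "bipartition")
    expect_equal(nrow(m), nrow(nf))
    expect_equal(m$count.x, m$count.y)
    expect_equal(m$frequency.x, m$frequency.y)
    expect_true(all(nf$frequency >= 0 & nf$frequency <= 1))
    expect_length(nf$bipartition, n - 3)
  }
})

test_that("annotated Newick carries supports and round-trips", {
  ref <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  genes <- list(read_newick(text = "((A,B),(C,D));"),
                read_newick(text = "((A,C),(B,D));"),
                read_newick(text = "((A,B),(C,D));"))
  nf <- node_frequencies(ref, genes)
  nwk <- annotate_newick(ref, nf)
  expect_match(nwk, "0.6667", fixed = TRUE)
  back <- read_newick(text = nwk)
  expect_setequal(bipartitions(back), bipartitions(ref))
  expect_equal(sort(back$edge.length), sort(ref$edge.length), tolerance = 1e-8)
  expect_true("0.6667" %in% back$node.label)
  # a support table missing an edge is an error
  expect_error(annotate_newick(ref, nf[0, ]), "missing bipartition")
})
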