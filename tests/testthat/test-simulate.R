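small_cfg <- function(...) {
  simulation_config(n_arch_groups = 2, n_eub_groups = 2, genomes_per_group = 2,
                    n_universal_genes = 4, sites_per_gene = 120,
                    n_families = 8, proteins_per_genome = 10,
                    protein_length = 40, ...)
}

test_that("configuration validation names the offending field", {
  expect_error(simulation_config(seed = 1.5), "seed")
  expect_error(simulation_config(n_arch_groups = 0), "n_arch_groups")
  expect_error(simulation_config(discordance_prob = 1.2), "discordance_prob")
  expect_error(simulation_config(interdomain_branch = 0), "interdomain_branch")
  expect_error(simulation_config(motif_rate = -0.1), "motif_rate")
})

test_that("taxonomy yields the expected genomes, groups and tree shape", {
  tax <- simulate_taxonomy(small_cfg(seed = 2))
  expect_equal(nrow(tax$group_map), 8)
  expect_setequal(unique(tax$group_map$group), c("A01", "A02", "E01", "E02"))
  tr <- tax$species_tree
  ntip <- length(tr$tip.label)
  expect_equal(ntip, 8)
  expect_equal(sum(tr$edge[, 2] > ntip), ntip - 3)   # 5 internal edges
  expect_true(tax$interdomain_split %in% bipartitions(tr))
  # same seed twice: byte-identical outputs
  tax2 <- simulate_taxonomy(small_cfg(seed = 2))
  expect_identical(ape::write.tree(tax$species_tree),
                   ape::write.tree(tax2$species_tree))
  expect_identical(tax$group_map, tax2$group_map)
})

test_that("inter-domain leaf-to-leaf paths include the inter-domain edge", {
  tax <- simulate_taxonomy(small_cfg(seed = 3, interdomain_branch = 5))
  paths <- as.matrix(ape::cophenetic.phylo(tax$species_tree))
  gm <- tax$group_map
  arch <- gm$genome_id[gm$domain == "archaebacteria"]
  eub <- gm$genome_id[gm$domain == "eubacteria"]
  expect_true(all(paths[arch, eub] >= 5))
})

test_that("discordance bookkeeping matches the perturbation probability", {
  cfg0 <- small_cfg(seed = 4, discordance_prob = 0)
  tax <- simulate_taxonomy(cfg0)
  g0 <- simulate_gene_trees(cfg0, tax$species_tree)
  # p = 0: every gene tree has the species tree's bipartition set
  for (gt in g0$trees)
    expect_setequal(bipartitions(gt), bipartitions(tax$species_tree))
  expect_true(all(!g0$truth$perturbed))
  # p = 1: one destroyed-bipartition record per gene, never the domain split
  cfg1 <- small_cfg(seed = 4, discordance_prob = 1)
  g1 <- simulate_gene_trees(cfg1, tax$species_tree)
  expect_equal(sum(g1$truth$perturbed), cfg1$n_universal_genes)
  expect_true(all(!is.na(g1$truth$destroyed_split)))
  expect_true(all(g1$truth$destroyed_split != tax$interdomain_split))
  sp_splits <- bipartitions(tax$species_tree)
  for (i in seq_len(nrow(g1$truth))) {
    expect_true(g1$truth$destroyed_split[i] %in% sp_splits)
    expect_false(g1$truth$destroyed_split[i] %in%
                   bipartitions(g1$trees[[g1$truth$gene_id[i]]]))
  }
  # the protected domain split is present in every perturbed gene tree
  for (gt in g1$trees)
    expect_true(tax$interdomain_split %in% bipartitions(gt))
})

test_that("zero branch lengths propagate the root sequence unchanged", {
  cfg <- small_cfg(seed = 6, within_group_branch = 0, between_group_branch = 0,
                   interdomain_branch = 1e-12)
  tax <- simulate_taxonomy(cfg)
  g <- simulate_gene_trees(cfg, tax$species_tree)
  a <- g$alignments[[1]]
  expect_equal(length(unique(unname(a))), 1L)
})

test_that("gene-tree simulation needs at least four leaves", {
  cfg <- small_cfg(seed = 7)
  tiny <- read_newick(text = "(A:1,B:1,C:1);")
  expect_error(simulate_gene_trees(cfg, tiny), "at least 4 leaves")
})

test_that("planted motif fraction matches its binomial expectation", {
  gm <- data.frame(genome_id = sprintf("A01.g%02d", 1:20),
                   domain = "archaebacteria", group = "A01")
  cfg <- simulation_config(seed = 8, motif_rate = 0.3,
                           proteins_per_genome = 500, protein_length = 30)
  pr <- simulate_proteomes(cfg, gm)
  n <- 20 * 500
  frac <- nrow(pr$plantings) / n
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), 3 * se)
  # planted proteins are a subset of scanner detections
  some <- pr$plantings[sample(nrow(pr$plantings), 50), ]
  for (i in seq_len(nrow(some))) {
    s <- pr$proteomes[[some$genome_id[i]]][[some$protein_id[i]]]
    expect_true(some$position[i] %in% scan_protein(s))
  }
})

test_that("motif planting rejects proteins shorter than the motif", {
  gm <- tiny_group_map()
  cfg <- simulation_config(seed = 9, protein_length = 8, motif_rate = 0.5)
  expect_error(simulate_proteomes(cfg, gm), "shorter than the motif")
})

test_that("the full pipeline is byte-identical under one seed", {
  cfg <- small_cfg(seed = 10, discordance_prob = 0.5, motif_rate = 0.2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_simulation(cfg, d1)
  run_simulation(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
  # and a different seed actually changes the data
  d3 <- withr::local_tempdir()
  run_simulation(small_cfg(seed = 11, discordance_prob = 0.5, motif_rate = 0.2), d3)
  h3 <- unname(tools::md5sum(file.path(d3, sort(list.files(d3, recursive = TRUE)))))
  expect_false(all(h1 == h3))
})

test_that("written artefacts read back into equivalent objects", {
  cfg <- small_cfg(seed = 12)
  dir <- withr::local_tempdir()
  run <- run_simulation(cfg, dir)
  gm <- read_group_map(file.path(dir, "group_map.tsv"))
  expect_equal(gm, run$taxonomy$group_map)
  fam <- read_family_table(file.path(dir, "families.tsv"))
  expect_equal(fam, run$families$families)
  hits <- read_hit_table(file.path(dir, "hits.tsv"))
  expect_equal(hits$qseqid, run$hit_table$hits$qseqid)
  expect_equal(hits$evalue, run$hit_table$hits$evalue)
  tr <- read_newick(file.path(dir, "species_tree.nwk"))
  expect_setequal(bipartitions(tr), bipartitions(run$taxonomy$species_tree))
  a1 <- read_fasta(file.path(dir, "alignments", "gene_01.fasta"))
  expect_equal(a1[sort(names(a1))],
               run$genes$alignments[[1]][sort(names(run$genes$alignments[[1]]))])
})
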