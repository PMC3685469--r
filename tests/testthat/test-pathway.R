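test_that("hit filtering applies inclusive E-value and identity bounds", {
  hits <- rbind(make_hit("g1", "a1", pident = 30, evalue = 1e-12),
                make_hit("g2", "a1", pident = 90, evalue = 1e-9),
                make_hit("g3", "a1", pident = 25.0, evalue = 1e-20),
                make_hit("g4", "a1", pident = 24.9, evalue = 1e-20),
                make_hit("g5", "a1", pident = 80, evalue = 1e-10))
  kept <- filter_hits(hits)
  expect_setequal(kept$qseqid, c("g1", "g3", "g5"))  # boundaries inclusive
  expect_identical(filter_hits(kept), kept)          # idempotent
})

test_that("completeness counts satisfied slots, not raw hits", {
  pw <- default_pathways()
  mk <- pw$menaquinone_alternative
  hits <- rbind(make_hit("MqnA", "a1"), make_hit("MqnB", "a1"),
                make_hit("MqnD", "a1"), make_hit("MqnD", "a1", protein = "p2"))
  expect_equal(pathway_completeness(hits, mk), 0.75)  # duplicate slot once
  # slash-gene rule: HemN alone satisfies the {HemF, HemN} slot
  expect_equal(pathway_completeness(make_hit("HemN", "a1"), pw$haem_classical),
               0.25)
  expect_equal(pathway_completeness(hits[0, ], mk), 0)
  expect_error(pathway_completeness(hits, list()), "zero gene slots")
})

test_that("completeness is monotone in the filter thresholds", {
  set.seed(31)
  hits <- do.call(rbind, lapply(1:40, function(i) {
    make_hit(sample(c("MqnA", "MqnB", "MqnC", "MqnD"), 1), "a1",
             pident = runif(1, 10, 60), evalue = 10^-runif(1, 5, 40))
  }))
  pw <- default_pathways()$menaquinone_alternative
  comp <- function(e, id) pathway_completeness(filter_hits(hits, e, id), pw)
  for (i in 1:10) {
    e1 <- 10^-runif(1, 8, 20); e2 <- e1 * 100      # e2 more permissive
    id1 <- runif(1, 20, 50); id2 <- id1 - 10
    expect_gte(comp(e2, id1), comp(e1, id1))
    expect_gte(comp(e1, id2), comp(e1, id1))
  }
})

test_that("pathway calls honour the 70% threshold and the haem-d1 rule", {
  pw <- default_pathways()
  hits <- rbind(
    # genome g1: 3 of 4 alternative-MK slots -> present at 0.75
    make_hit("MqnA", "g1"), make_hit("MqnB", "g1"), make_hit("MqnC", "g1"),
    # genome g2: 2 of 4 -> absent
    make_hit("MqnA", "g2"), make_hit("MqnB", "g2"),
    # genome g3: complete haem alternative plus cd1 nitrite reductase
    make_hit("AhbA", "g3"), make_hit("AhbB", "g3"), make_hit("AhbC", "g3"),
    make_hit("AhbD", "g3"), make_hit("NirS", "g3"),
    # genome g4: complete haem alternative, no cd1
    make_hit("AhbA", "g4"), make_hit("AhbB", "g4"), make_hit("AhbC", "g4"),
    make_hit("AhbD", "g4"))
  calls <- call_pathways(hits, pw)
  pick <- function(g, p) calls[calls$genome_id == g & calls$pathway == p, ]
  expect_true(pick("g1", "menaquinone_alternative")$present)
  expect_equal(pick("g1", "menaquinone_alternative")$completeness, 0.75)
  expect_false(pick("g2", "menaquinone_alternative")$present)
  r3 <- pick("g3", "haem_alternative")
  expect_equal(r3$completeness, 1.0)
  expect_false(r3$present)
  expect_true(r3$d1_reassigned)
  r4 <- pick("g4", "haem_alternative")
  expect_true(r4$present)
  expect_false(r4$d1_reassigned)
  # exactly-at-threshold completeness (7 of 10 slots) is called present
  ten <- lapply(paste0("q", 1:10), identity)
  h7 <- do.call(rbind, lapply(paste0("q", 1:7), make_hit, genome = "gx"))
  c7 <- call_pathways(h7, list(ten_slot = ten), haem_alternative = NA)
  expect_equal(c7$completeness, 0.7)
  expect_true(c7$present)
  expect_error(call_pathways(hits, pw, haem_alternative = "nope"),
               "unknown pathway")
})

test_that("taxon aggregation divides present calls by genomes per taxon", {
  gm <- tiny_group_map()
  pw <- list(mk = list("MqnA"))
  hits <- rbind(make_hit("MqnA", "b1"), make_hit("MqnA", "b2"))
  calls <- call_pathways(hits, pw, genomes = gm$genome_id,
                         haem_alternative = NA)
  agg <- aggregate_by_taxon(calls, gm)
  expect_equal(agg$proportion[agg$taxon == "E01"], 1)
  expect_equal(agg$proportion[agg$taxon == "E02"], 0)
  expect_equal(agg$proportion[agg$taxon == "A01"], 0)
  calls$genome_id[1] <- "zz9"
  expect_error(aggregate_by_taxon(calls, gm), "zz9")
})

test_that("simulated hit tables round-trip to the configured truth", {
  gm <- tiny_group_map()
  cfg <- simulation_config(seed = 21, n_arch_groups = 1, n_eub_groups = 2,
                           genomes_per_group = 2)
  sim <- simulate_hit_table(cfg, gm, default_pathways())
  kept <- filter_hits(sim$hits)
  calls <- call_pathways(kept, default_pathways(), genomes = gm$genome_id)
  m <- merge(calls, sim$truth, by = c("genome_id", "pathway"))
  expect_true(nrow(m) == nrow(sim$truth))
  expect_equal(m$completeness.x, m$completeness.y)
  # decoys are present in the raw table but all removed by the filter
  expect_gt(nrow(sim$hits), nrow(kept))
  decoys <- sim$hits[grepl("decoy", sim$hits$sseqid), ]
  expect_true(all(decoys$evalue > 1e-10 | decoys$pident < 25))
  # an explicit truth matrix is honoured exactly (0.75 on 4 slots -> 3 hits)
  pw <- default_pathways()["menaquinone_alternative"]
  truth <- matrix(0.75, nrow(gm), 1,
                  dimnames = list(gm$genome_id, names(pw)))
  cfg2 <- simulation_config(seed = 22, pathway_truth = truth,
                            cd1_truth = setNames(rep(FALSE, nrow(gm)),
                                                 gm$genome_id))
  sim2 <- simulate_hit_table(cfg2, gm, pw)
  passing <- filter_hits(sim2$hits)
  per_genome <- table(hit_genomes(passing))
  expect_true(all(per_genome == 3))
  expect_error(simulate_hit_table(cfg2, gm, list(empty = list())),
               "zero gene slots")
  # fractions that are not multiples of 1/n_slots are rejected
  bad <- matrix(0.6, nrow(gm), 1, dimnames = list(gm$genome_id, names(pw)))
  cfg3 <- simulation_config(seed = 23, pathway_truth = bad)
  expect_error(simulate_hit_table(cfg3, gm, pw), "multiples")
})

test_that("the hit-table reader reports malformed lines by number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("q", "g|p", "80", "100", "20", "1", "1", "100", "1",
                       "100", "1e-30", "200"), collapse = "\t"),
               "too\tfew\tcolumns"), f)
  expect_error(read_hit_table(f), "line 2")
  writeLines(c(paste(c("q", "g|p", "80", "100", "20", "1", "1", "100", "1",
                       "100", "not_a_number", "200"), collapse = "\t")), f)
  expect_error(read_hit_table(f), "line 1")
  # round trip of a valid table
  hits <- rbind(make_hit("MqnA", "g1"), make_hit("NirS", "g2", pident = 25))
  write_hit_table(hits, f)
  back <- read_hit_table(f)
  expect_equal(back$qseqid, hits$qseqid)
  expect_equal(back$pident, hits$pident)
  expect_equal(back$evalue, hits$evalue)
})
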