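# Synthetic similarity-search hit tables in the 12-column tabular layout.
# For every genome x pathway, passing hits (E-value and identity both inside
# the downstream filters) are emitted for exactly the fraction of gene slots
# dictated by the configured pathway truth, plus decoy hits that each fail
# exactly one filter and must be removed downstream.

#' Simulate a similarity hit table with known pathway completeness
#'
#' @param config A [simulation_config()] object; its `pathway_truth`
#'   (genomes x pathways matrix of completeness fractions, each a multiple of
#'   `1/n_slots`) and `cd1_truth` are honoured when set, otherwise drawn from
#'   the seeded generator.
#' @param group_map Genome-to-group map.
#' @param pathways Pathway definitions as from [default_pathways()]; a pathway
#'   with zero gene slots is an error.
#' @param e_max,min_identity The downstream filter thresholds the generated
#'   hits are calibrated against.
#' @param cd1_gene Query name used for cd1 nitrite reductase hits.
#' @return A list: `hits` (12-column data frame; subject ids are
#'   `"<genome>|<protein>"`), `truth` (data frame `genome_id`, `pathway`,
#'   `completeness`) and `cd1` (data frame `genome_id`, `present`).
#' @export
simulate_hit_table <- function(config, group_map, pathways = default_pathways(),
                               e_max = 1e-10, min_identity = 25,
                               cd1_gene = "NirS") {
  if (!inherits(config, "sim_config"))
    fail("invalid simulation configuration: 'config' must be a sim_config object")
  validate_group_map(group_map)
  validate_pathways(pathways)
  genomes <- group_map$genome_id
  pnames <- names(pathways)
  n_slots <- vapply(pathways, length, integer(1))

  truth <- config$pathway_truth
  if (!is.null(truth)) {
    if (!is.matrix(truth) || !setequal(rownames(truth), genomes) ||
        !setequal(colnames(truth), pnames))
      fail("pathway_truth must be a genomes x pathways matrix matching the group map and pathway names")
    truth <- truth[genomes, pnames, drop = FALSE]
    k_mat <- truth * rep(n_slots, each = length(genomes))
    if (max(abs(k_mat - round(k_mat))) > 1e-8)
      fail("pathway_truth fractions must be multiples of 1/n_slots for each pathway")
    k_mat <- round(k_mat)
  }

  with_seed(config$seed + 505L, {
    if (is.null(truth)) {
      k_mat <- matrix(0L, length(genomes), length(pnames),
                      dimnames = list(genomes, pnames))
      for (j in seq_along(pnames))
        k_mat[, j] <- sample.int(n_slots[j] + 1L, length(genomes),
                                 replace = TRUE) - 1L
    }
    cd1 <- config$cd1_truth
    if (is.null(cd1)) {
      cd1 <- stats::setNames(stats::runif(length(genomes)) < config$cd1_prob,
                             genomes)
    } else {
      if (!setequal(names(cd1), genomes))
        fail("cd1_truth must name every genome in the group map")
      cd1 <- cd1[genomes]
    }

    passing_row <- function(genome, gene, tag) {
      data.frame(qseqid = gene,
                 sseqid = sprintf("%s|%s", genome, tag),
                 pident = round(stats::runif(1, min_identity + 15, 95), 1),
                 length = 200L, mismatch = 40L, gapopen = 2L,
                 qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
                 evalue = signif(10^-stats::runif(1, 15, 60), 3),
                 bitscore = round(stats::runif(1, 100, 500), 1),
                 stringsAsFactors = FALSE)
    }

    rows <- list()
    for (gi in seq_along(genomes)) {
      genome <- genomes[gi]
      for (j in seq_along(pnames)) {
        k <- k_mat[gi, j]
        if (k > 0) {
          slots <- sample.int(n_slots[j], k)
          for (s in slots) {
            members <- pathways[[j]][[s]]
            gene <- members[sample.int(length(members), 1L)]
            rows[[length(rows) + 1L]] <-
              passing_row(genome, gene, sprintf("%s.s%d", pnames[j], s))
          }
        }
      }
      if (cd1[[genome]])
        rows[[length(rows) + 1L]] <- passing_row(genome, cd1_gene, "cd1")
      ## decoys: alternate between a failing E-value (identity fine) and a
      ## failing identity (E-value fine)
      all_genes <- unlist(pathways)
      for (dk in seq_len(config$decoys_per_genome)) {
        r <- passing_row(genome, all_genes[sample.int(length(all_genes), 1L)],
                         sprintf("decoy%d", dk))
        if (dk %% 2L == 1L) r$evalue <- e_max * 1e5 else r$pident <- min_identity / 2
        rows[[length(rows) + 1L]] <- r
      }
    }
    hits <- do.call(rbind, rows)
    rownames(hits) <- NULL
    truth_df <- data.frame(
      genome_id = rep(genomes, times = length(pnames)),
      pathway = rep(pnames, each = length(genomes)),
      completeness = as.vector(k_mat) / rep(n_slots, each = length(genomes)),
      stringsAsFactors = FALSE)
    list(hits = hits, truth = truth_df,
         cd1 = data.frame(genome_id = genomes, present = unname(cd1),
                          stringsAsFactors = FALSE))
  })
}
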