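# Pathway presence calling from similarity hit tables: filter hits on E-value
# and percent identity, score per-genome pathway completeness as the fraction
# of gene slots with at least one retained hit, call a pathway present at >=
# 70% completeness, reassign haem-alternative calls to haem d1 biosynthesis
# when cd1 nitrite reductase co-occurs, and aggregate presence per taxon.

#' Filter a hit table on E-value and percent identity
#'
#' Retains hits with `evalue <= e_max` **and** `pident >= min_identity`
#' (both bounds inclusive), preserving input order. Filtering is idempotent.
#'
#' @param hits 12-column hit-table data frame.
#' @param e_max Maximum E-value (default `1e-10`).
#' @param min_identity Minimum percent identity (default 25).
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, e_max = 1e-10, min_identity = 25) {
  validate_hits(hits)
  if (length(e_max) != 1L || !is.numeric(e_max) || e_max <= 0)
    fail("'e_max' must be a single positive number")
  if (length(min_identity) != 1L || !is.numeric(min_identity) || min_identity <= 0)
    fail("'min_identity' must be a single positive number")
  out <- hits[hits$evalue <= e_max & hits$pident >= min_identity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway completeness for one genome
#'
#' The fraction of the pathway's gene slots with at least one hit to any of
#' the slot's interchangeable gene names. Multiple hits to one slot count
#' once; a genome with no hits scores 0.
#'
#' @param genome_hits Hit rows of a single genome, already filtered.
#' @param pathway One pathway definition: a list of character-vector slots.
#' @return Fraction in `[0, 1]`.
#' @export
pathway_completeness <- function(genome_hits, pathway) {
  if (!length(pathway)) fail("pathway has zero gene slots")
  qs <- unique(genome_hits$qseqid)
  satisfied <- vapply(pathway, function(slot) any(slot %in% qs), logical(1))
  sum(satisfied) / length(pathway)
}

#' Call pathway presence per genome
#'
#' A pathway is called present when its completeness reaches `threshold`
#' (inclusive: completeness exactly at threshold is present). Exception: a
#' haem-alternative call passing the threshold in a genome that also has a
#' retained hit to cd1 nitrite reductase is set to `present = FALSE` with
#' `d1_reassigned = TRUE`, since those genes are then attributed to haem d1
#' biosynthesis.
#'
#' @param hits Filtered hit table (see [filter_hits()]); cd1 presence is
#'   derived from the same table.
#' @param pathways Named list of pathway definitions.
#' @param genomes Genomes to score; defaults to every subject genome occurring
#'   in `hits`. Supply the full genome list to score hitless genomes as 0.
#' @param threshold Completeness threshold (default 0.70).
#' @param cd1_gene Query name of cd1 nitrite reductase (default `"NirS"`).
#' @param haem_alternative Name of the haem-alternative pathway within
#'   `pathways`; must exist there (or be `NA` to disable reassignment).
#' @return Data frame `genome_id`, `pathway`, `completeness`, `present`,
#'   `d1_reassigned`.
#' @export
call_pathways <- function(hits, pathways, genomes = NULL, threshold = 0.70,
                          cd1_gene = "NirS",
                          haem_alternative = "haem_alternative") {
  validate_hits(hits)
  validate_pathways(pathways)
  if (!is.na(haem_alternative) && !haem_alternative %in% names(pathways))
    fail("unknown pathway name '%s'", haem_alternative)
  hg <- hit_genomes(hits)
  genomes <- genomes %||% sort(unique(hg))
  rows <- vector("list", length(genomes) * length(pathways))
  k <- 0L
  for (gn in genomes) {
    gh <- hits[hg == gn, , drop = FALSE]
    cd1 <- any(gh$qseqid == cd1_gene)
    for (pn in names(pathways)) {
      comp <- pathway_completeness(gh, pathways[[pn]])
      present <- comp >= threshold
      reassigned <- FALSE
      if (present && !is.na(haem_alternative) && pn == haem_alternative && cd1) {
        present <- FALSE
        reassigned <- TRUE
      }
      k <- k + 1L
      rows[[k]] <- data.frame(genome_id = gn, pathway = pn,
                              completeness = comp, present = present,
                              d1_reassigned = reassigned,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate pathway calls per taxon
#'
#' For each taxon (group) and pathway, the proportion of the taxon's genomes
#' called present. Genomes in the calls that are absent from the group map are
#' an error; taxa whose genomes carry no calls are excluded with a warning.
#'
#' @param calls Output of [call_pathways()].
#' @param group_map Genome-to-group map.
#' @return Data frame `taxon`, `domain`, `pathway`, `n_genomes`, `n_present`,
#'   `proportion`.
#' @export
aggregate_by_taxon <- function(calls, group_map) {
  validate_group_map(group_map)
  unmapped <- setdiff(unique(calls$genome_id), group_map$genome_id)
  if (length(unmapped))
    fail("calls contain genome(s) absent from the group map: %s",
         paste(sort(unmapped), collapse = ", "))
  taxa <- unique(group_map$group)
  pathways <- unique(calls$pathway)
  rows <- list()
  for (tx in taxa) {
    gset <- intersect(group_map$genome_id[group_map$group == tx],
                      unique(calls$genome_id))
    if (!length(gset)) {
      warning(sprintf("taxon '%s' has no scored genomes; excluded", tx),
              call. = FALSE)
      next
    }
    dom <- group_map$domain[group_map$group == tx][1L]
    for (pn in pathways) {
      sub <- calls[calls$genome_id %in% gset & calls$pathway == pn, ,
                   drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, domain = dom, pathway = pn,
        n_genomes = length(gset), n_present = sum(sub$present),
        proportion = sum(sub$present) / length(gset),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
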