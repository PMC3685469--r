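# Full synthetic pipeline run: generate every artefact (taxonomy, species and
# gene trees, alignments, proteomes, families, hit tables) and write them as
# plain-text files with deterministic formatting, so two runs under the same
# seed are byte-identical. Stage order (and hence the order of random draws):
# taxonomy, gene trees + alignments, proteomes, families, hit table; each
# stage draws from its own seed derived from the configured one.

#' Run the full synthetic-data pipeline and write its outputs
#'
#' @param config A [simulation_config()] object.
#' @param out_dir Output directory (created if needed). Files written:
#'   `config.yaml`, `group_map.tsv`, `species_tree.nwk`, `gene_trees.nwk`,
#'   `alignments/<gene>.fasta`, `proteomes/<genome>.fasta`, `families.tsv`,
#'   `family_sequences.fasta`, `hits.tsv` and a `ground_truth/` directory
#'   (gene-tree perturbations, motif plantings, family truth, pathway truth).
#' @param pathways Pathway definitions used for the hit table.
#' @return (Invisibly) a list with all in-memory stage outputs: `taxonomy`,
#'   `genes`, `proteomes`, `families`, `hit_table`, and `files` (the paths
#'   written).
#' @export
run_simulation <- function(config, out_dir, pathways = default_pathways()) {
  if (!inherits(config, "sim_config"))
    fail("invalid simulation configuration: 'config' must be a sim_config object")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "proteomes"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "ground_truth"), showWarnings = FALSE)

  taxonomy <- simulate_taxonomy(config)
  genes <- simulate_gene_trees(config, taxonomy$species_tree,
                               excluded_splits =
                                 if (config$exclude_interdomain)
                                   taxonomy$interdomain_split else NULL)
  proteomes <- simulate_proteomes(config, taxonomy$group_map)
  families <- simulate_families(config, taxonomy$group_map)
  hit_table <- simulate_hit_table(config, taxonomy$group_map, pathways)

  files <- character(0)
  put <- function(p) { files <<- c(files, p); p }

  cfg <- config
  cfg$pathway_truth <- NULL   # matrices are regenerated from the seed
  cfg$cd1_truth <- NULL
  yaml::write_yaml(unclass(cfg), put(file.path(out_dir, "config.yaml")))
  write_group_map(taxonomy$group_map, put(file.path(out_dir, "group_map.tsv")))
  ape::write.tree(taxonomy$species_tree,
                  put(file.path(out_dir, "species_tree.nwk")))
  ape::write.tree(do.call(c, unname(genes$trees)),
                  put(file.path(out_dir, "gene_trees.nwk")))
  for (g in names(genes$alignments))
    write_fasta(genes$alignments[[g]],
                put(file.path(out_dir, "alignments", paste0(g, ".fasta"))))
  for (gn in names(proteomes$proteomes))
    write_fasta(proteomes$proteomes[[gn]],
                put(file.path(out_dir, "proteomes", paste0(gn, ".fasta"))))
  write_family_table(families$families, put(file.path(out_dir, "families.tsv")))
  write_fasta(families$sequences,
              put(file.path(out_dir, "family_sequences.fasta")))
  write_hit_table(hit_table$hits, put(file.path(out_dir, "hits.tsv")))

  tsv <- function(df, name) {
    utils::write.table(df, put(file.path(out_dir, "ground_truth", name)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(genes$truth, "gene_tree_truth.tsv")
  tsv(proteomes$plantings, "motif_plantings.tsv")
  tsv(families$truth$conserved, "family_truth.tsv")
  tsv(families$truth$presence, "family_presence.tsv")
  tsv(hit_table$truth, "pathway_truth.tsv")
  tsv(hit_table$cd1, "cd1_truth.tsv")

  invisible(list(taxonomy = taxonomy, genes = genes, proteomes = proteomes,
                 families = families, hit_table = hit_table, files = files))
}
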