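# Synthetic taxonomy: genome->group map and a binary unrooted species tree in
# which a single internal edge of length `interdomain_branch` separates the
# archaebacterial from the eubacterial genomes.

#' Simulate a two-domain taxonomy and species tree
#'
#' Genomes are named `<group>.g<k>`, groups `A01..` (archaebacterial) and
#' `E01..` (eubacterial). Group subtrees use `within_group_branch` edges and
#' are joined by random binary backbones with `between_group_branch` edges;
#' the two domain subtrees are connected by the inter-domain edge. Topologies
#' are drawn from the seeded generator, so equal seeds give identical trees.
#'
#' @param config A [simulation_config()] object.
#' @return A list with `group_map` (data frame: `genome_id`, `domain`,
#'   `group`), `species_tree` (unrooted binary `phylo`), and
#'   `interdomain_split` (canonical string form of the domain bipartition).
#' @export
simulate_taxonomy <- function(config) {
  if (!inherits(config, "sim_config"))
    fail("invalid simulation configuration: 'config' must be a sim_config object")
  arch_groups <- sprintf("A%02d", seq_len(config$n_arch_groups))
  eub_groups <- sprintf("E%02d", seq_len(config$n_eub_groups))
  gm <- do.call(rbind, lapply(c(arch_groups, eub_groups), function(g) {
    data.frame(genome_id = sprintf("%s.g%02d", g, seq_len(config$genomes_per_group)),
               domain = if (startsWith(g, "A")) "archaebacteria" else "eubacteria",
               group = g, stringsAsFactors = FALSE)
  }))
  if (nrow(gm) < 4L)
    fail("invalid simulation configuration: 'genomes_per_group' and group counts must yield at least 4 genomes")

  tree <- with_seed(config$seed + 101L, {
    domain_token <- function(groups) {
      subtrees <- vapply(groups, function(g) {
        leaves <- gm$genome_id[gm$group == g]
        join_random(leaves, config$within_group_branch)
      }, character(1))
      join_random(subtrees, config$between_group_branch)
    }
    half <- config$interdomain_branch / 2
    nwk <- sprintf("(%s:%.10g,%s:%.10g);",
                   domain_token(arch_groups), half,
                   domain_token(eub_groups), half)
    ape::unroot(ape::read.tree(text = nwk))
  })

  arch_tips <- gm$genome_id[gm$domain == "archaebacteria"]
  list(group_map = gm,
       species_tree = tree,
       interdomain_split = canonical_split(arch_tips, gm$genome_id))
}

## Randomly agglomerate newick fragments into one binary subtree; every edge
## created here gets length `len`.
join_random <- function(tokens, len) {
  while (length(tokens) > 1L) {
    i <- sample.int(length(tokens), 2L)
    merged <- sprintf("(%s:%.10g,%s:%.10g)", tokens[i[1L]], len,
                      tokens[i[2L]], len)
    tokens <- c(tokens[-i], merged)
  }
  tokens
}
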