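# Simulation configuration: the study conditions under which synthetic
# genomes, families, proteomes, hit tables and gene trees are generated.

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic-data generator. The
#' defaults encode the study conditions of the analyses the package
#' re-implements: 11 archaebacterial and 30 eubacterial taxonomic groups and
#' 48 universal genes. Quantities those analyses do not pin down (branch
#' length scales, proteome sizes, family divergence levels) default to
#' realistic protein-evolution values documented in the methods vignette.
#'
#' @param seed Integer seed; every generator stage derives its randomness from
#'   it, so equal seeds give byte-identical outputs.
#' @param n_arch_groups,n_eub_groups Number of archaebacterial / eubacterial
#'   taxonomic groups.
#' @param genomes_per_group Genomes simulated per group.
#' @param n_families Number of ortholog families.
#' @param family_presence_probs Per-family probability that a family is present
#'   in a given group: a scalar, or a `n_families x n_groups` matrix (groups
#'   ordered archaebacterial then eubacterial).
#' @param family_conserved_prob Probability that a family is "conserved"
#'   (members ~85% identical, intended to survive the 30% identity filter)
#'   rather than "diverged" (~10% identical, intended to fail it).
#' @param n_universal_genes Number of universal single-copy genes used for the
#'   gene-tree / concatenation analysis.
#' @param sites_per_gene Alignment columns simulated per gene.
#' @param within_group_branch,between_group_branch Branch lengths (expected
#'   substitutions/site) used inside a group subtree and along the
#'   within-domain backbone, respectively.
#' @param interdomain_branch Length of the single edge separating the two
#'   domains in the species tree; must be positive.
#' @param discordance_prob Probability `p` that a gene tree receives exactly
#'   one nearest-neighbour-interchange perturbation.
#' @param exclude_interdomain If `TRUE` (default) the inter-domain edge is
#'   never perturbed, so every gene recovers the deep domain split.
#' @param motif_rate Per-protein probability `m` of one planted 4Fe-4S motif.
#' @param background_c_freq Background frequency of cysteine in simulated
#'   protein sequence (default 0.014, close to the observed proteome-wide C
#'   frequency); the other 19 residues share the remainder uniformly.
#' @param proteins_per_genome,protein_length Size of each simulated proteome.
#' @param pathway_truth Optional genomes x pathways matrix of intended pathway
#'   completeness fractions (each must be a multiple of 1/n_slots for its
#'   pathway); `NULL` draws them uniformly over the achievable fractions.
#' @param cd1_truth Optional named logical vector: per-genome presence of cd1
#'   nitrite reductase; `NULL` draws it with probability `cd1_prob`.
#' @param cd1_prob Probability of cd1 nitrite reductase presence when
#'   `cd1_truth` is `NULL`.
#' @param decoys_per_genome Number of decoy hits per genome in simulated hit
#'   tables; each decoy fails exactly one of the two downstream filters.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_arch_groups = 11L,
                              n_eub_groups = 30L,
                              genomes_per_group = 2L,
                              n_families = 100L,
                              family_presence_probs = 0.5,
                              family_conserved_prob = 0.7,
                              n_universal_genes = 48L,
                              sites_per_gene = 2000L,
                              within_group_branch = 0.1,
                              between_group_branch = 0.2,
                              interdomain_branch = 1.0,
                              discordance_prob = 0,
                              exclude_interdomain = TRUE,
                              motif_rate = 0.05,
                              background_c_freq = 0.014,
                              proteins_per_genome = 50L,
                              protein_length = 300L,
                              pathway_truth = NULL,
                              cd1_truth = NULL,
                              cd1_prob = 0.3,
                              decoys_per_genome = 2L) {
  cfg_fail <- function(field, what)
    fail("invalid simulation configuration: '%s' %s", field, what)

  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) ||
      seed != as.integer(seed))
    cfg_fail("seed", "must be a single integer")
  counts <- c(n_arch_groups = n_arch_groups, n_eub_groups = n_eub_groups,
              genomes_per_group = genomes_per_group, n_families = n_families,
              n_universal_genes = n_universal_genes,
              sites_per_gene = sites_per_gene,
              proteins_per_genome = proteins_per_genome,
              protein_length = protein_length)
  for (nm in names(counts))
    if (!is_count(counts[[nm]])) cfg_fail(nm, "must be an integer >= 1")
  if (!is_count(decoys_per_genome + 1))  # allows 0
    cfg_fail("decoys_per_genome", "must be a non-negative integer")
  for (nm in c("family_conserved_prob", "discordance_prob", "motif_rate",
               "background_c_freq", "cd1_prob")) {
    v <- get(nm)
    if (length(v) != 1L || !is_prob(v)) cfg_fail(nm, "must be a probability in [0, 1]")
  }
  if (!is_prob(family_presence_probs))
    cfg_fail("family_presence_probs", "must be probabilities in [0, 1]")
  if (is.matrix(family_presence_probs) &&
      !all(dim(family_presence_probs) ==
           c(n_families, n_arch_groups + n_eub_groups)))
    cfg_fail("family_presence_probs",
             "matrix must be n_families x (n_arch_groups + n_eub_groups)")
  for (nm in c("within_group_branch", "between_group_branch")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v < 0)
      cfg_fail(nm, "must be a non-negative number")
  }
  if (length(interdomain_branch) != 1L || !is.numeric(interdomain_branch) ||
      !is.finite(interdomain_branch) || interdomain_branch <= 0)
    cfg_fail("interdomain_branch", "must be > 0")
  if (!is.null(cd1_truth) && (!is.logical(cd1_truth) || is.null(names(cd1_truth))))
    cfg_fail("cd1_truth", "must be a named logical vector or NULL")

  structure(list(
    seed = as.integer(seed),
    n_arch_groups = as.integer(n_arch_groups),
    n_eub_groups = as.integer(n_eub_groups),
    genomes_per_group = as.integer(genomes_per_group),
    n_families = as.integer(n_families),
    family_presence_probs = family_presence_probs,
    family_conserved_prob = family_conserved_prob,
    n_universal_genes = as.integer(n_universal_genes),
    sites_per_gene = as.integer(sites_per_gene),
    within_group_branch = within_group_branch,
    between_group_branch = between_group_branch,
    interdomain_branch = interdomain_branch,
    discordance_prob = discordance_prob,
    exclude_interdomain = isTRUE(exclude_interdomain),
    motif_rate = motif_rate,
    background_c_freq = background_c_freq,
    proteins_per_genome = as.integer(proteins_per_genome),
    protein_length = as.integer(protein_length),
    pathway_truth = pathway_truth,
    cd1_truth = cd1_truth,
    cd1_prob = cd1_prob,
    decoys_per_genome = as.integer(decoys_per_genome)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  seed %d; %d arch groups + %d eub groups x %d genomes/group\n",
              x$seed, x$n_arch_groups, x$n_eub_groups, x$genomes_per_group))
  cat(sprintf("  %d universal genes x %d sites; discordance p = %g%s\n",
              x$n_universal_genes, x$sites_per_gene, x$discordance_prob,
              if (x$exclude_interdomain) " (inter-domain edge protected)" else ""))
  cat(sprintf("  %d families; %d proteins/genome x %d aa; motif rate %g; C freq %g\n",
              x$n_families, x$proteins_per_genome, x$protein_length,
              x$motif_rate, x$background_c_freq))
  invisible(x)
}
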