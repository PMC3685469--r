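# Synthetic ortholog families with controlled group-level presence/absence and
# controlled pairwise identity. Each family is present in a group with its
# configured probability; member sequences are derived from one ancestral
# sequence either at low divergence ("conserved", ~85% pairwise identity,
# intended to survive a 30% identity filter) or at high divergence
# ("diverged", ~10%, intended to fail it). The family model is a stand-in for
# real ortholog clustering, which is outside the generator's scope.

FAMILY_ANCESTOR_LENGTH <- 120L
FAMILY_MUTATION_CONSERVED <- 0.08
FAMILY_MUTATION_DIVERGED <- 0.75
FAMILY_MEMBER_PROB <- 0.6   # per-genome inclusion within a present group

#' Simulate ortholog families with known presence and divergence truth
#'
#' @param config A [simulation_config()] object (`n_families`,
#'   `family_presence_probs`, `family_conserved_prob` are used).
#' @param group_map Genome-to-group map.
#' @return A list: `families` (data frame `family_id`, `genome_id`,
#'   `protein_id`, `annotation`), `sequences` (named character vector keyed by
#'   `protein_id`), and `truth` with `conserved` (data frame `family_id`,
#'   `conserved`, `retained`; `retained` marks families intended to survive an
#'   all-pairs 30% identity filter, i.e. conserved or single-member) and
#'   `presence` (data frame `family_id`, `group`, `present`: the true
#'   group-presence vectors).
#' @export
simulate_families <- function(config, group_map) {
  if (!inherits(config, "sim_config"))
    fail("invalid simulation configuration: 'config' must be a sim_config object")
  validate_group_map(group_map)
  groups <- unique(group_map$group[order(group_map$domain == "eubacteria",
                                         group_map$group)])
  nf <- config$n_families
  pp <- config$family_presence_probs
  pmat <- if (is.matrix(pp)) pp else matrix(pp, nf, length(groups))
  if (ncol(pmat) != length(groups))
    fail("family_presence_probs has %d columns but the group map defines %d groups",
         ncol(pmat), length(groups))

  with_seed(config$seed + 404L, {
    fam_ids <- sprintf("F%04d", seq_len(nf))
    conserved <- stats::runif(nf) < config$family_conserved_prob
    rows <- vector("list", nf)
    seq_list <- vector("list", nf)
    pres_list <- vector("list", nf)
    for (f in seq_len(nf)) {
      present <- stats::runif(length(groups)) < pmat[f, ]
      if (!any(present)) present[sample.int(length(groups), 1L)] <- TRUE
      pres_list[[f]] <- data.frame(family_id = fam_ids[f], group = groups,
                                   present = present, stringsAsFactors = FALSE)
      members <- character(0)
      for (g in groups[present]) {
        in_group <- group_map$genome_id[group_map$group == g]
        take <- stats::runif(length(in_group)) < FAMILY_MEMBER_PROB
        if (!any(take)) take[sample.int(length(in_group), 1L)] <- TRUE
        members <- c(members, in_group[take])
      }
      anc <- sample(AA20, FAMILY_ANCESTOR_LENGTH, replace = TRUE)
      q <- if (conserved[f]) FAMILY_MUTATION_CONSERVED else FAMILY_MUTATION_DIVERGED
      seqs <- vapply(members, function(gn) {
        s <- anc
        hit <- stats::runif(length(s)) < q
        nh <- sum(hit)
        if (nh) {
          cur <- match(s[hit], AA20)
          s[hit] <- AA20[((cur - 1L + sample.int(19L, nh, replace = TRUE)) %% 20L) + 1L]
        }
        paste(s, collapse = "")
      }, "")
      prot_ids <- sprintf("%s.%s", fam_ids[f], members)
      rows[[f]] <- data.frame(
        family_id = fam_ids[f], genome_id = members, protein_id = prot_ids,
        annotation = sprintf("COG%04d (S) simulated family %s product",
                             f, fam_ids[f]),
        stringsAsFactors = FALSE)
      seq_list[[f]] <- stats::setNames(unname(seqs), prot_ids)
    }
    families <- do.call(rbind, rows)
    rownames(families) <- NULL
    n_members <- table(families$family_id)
    truth_cons <- data.frame(
      family_id = fam_ids, conserved = conserved,
      retained = conserved | as.integer(n_members[fam_ids]) < 2L,
      stringsAsFactors = FALSE)
    list(families = families,
         sequences = unlist(seq_list),
         truth = list(conserved = truth_cons,
                      presence = do.call(rbind, pres_list)))
  })
}
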