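# Taxonomic stringency grid: apply an all-pairs percent-identity filter to
# ortholog families, count in how many archaebacterial and eubacterial groups
# each family has at least one member, and tabulate the number of families
# jointly meeting varying group-presence thresholds in both domains.

#' Global pairwise percent identity of two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62 scoring, affine gaps: open 11,
#' extend 1, via Biostrings), then identity = 100 x identical aligned pairs /
#' alignment columns. With the default denominator, columns where either row
#' has a terminal gap are trimmed first; `denominator = "shorter"` divides by
#' the shorter sequence length instead. The measure is symmetric.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @param denominator `"columns"` (alignment columns after terminal-gap
#'   trimming; default) or `"shorter"`.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, gap_opening = 11, gap_extension = 1,
                              denominator = c("columns", "shorter")) {
  denominator <- match.arg(denominator)
  if (length(a) != 1L || length(b) != 1L || !nzchar(a) || !nzchar(b))
    fail("'a' and 'b' must be single non-empty sequences")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  gap <- pa == "-" | sa == "-"
  keep <- seq_along(pa)
  while (length(keep) && gap[keep[1L]]) keep <- keep[-1L]
  while (length(keep) && gap[keep[length(keep)]]) keep <- keep[-length(keep)]
  matches <- sum(pa == sa & !gap)
  denom <- switch(denominator,
                  columns = length(keep),
                  shorter = min(nchar(a), nchar(b)))
  if (denom == 0L) return(0)
  100 * matches / denom
}

#' Filter families by all-pairs identity
#'
#' A family is retained iff **all** pairwise member identities are at least
#' `min_identity` percent; single-member families pass trivially. The
#' all-pairs cost is quadratic in family size, so families larger than
#' `max_family_size` are an error rather than silently subsampled.
#'
#' @param families Family table (`family_id`, `genome_id`, `protein_id`, ...).
#' @param sequences Named character vector resolving every `protein_id`; an
#'   unresolvable reference is an error naming family and member.
#' @param min_identity Inclusive percent-identity cutoff (default 30).
#' @param max_family_size Guard on the O(n^2) alignment cost (default 60).
#' @param ... Passed to [pairwise_identity()].
#' @return The retained rows of `families`, with attribute
#'   `retained_families` (character vector of retained family ids).
#' @export
filter_families_by_identity <- function(families, sequences, min_identity = 30,
                                        max_family_size = 60, ...) {
  fam_ids <- unique(families$family_id)
  keep <- vapply(fam_ids, function(f) {
    sub <- families[families$family_id == f, , drop = FALSE]
    if (nrow(sub) > max_family_size)
      fail("family '%s' has %d members, above max_family_size = %d",
           f, nrow(sub), max_family_size)
    seqs <- sequences[sub$protein_id]
    if (anyNA(seqs)) {
      miss <- sub$protein_id[is.na(seqs)][1L]
      fail("cannot resolve sequence for member '%s' of family '%s'", miss, f)
    }
    if (nrow(sub) < 2L) return(TRUE)
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in seq.int(i + 1L, nrow(sub))) {
        if (pairwise_identity(seqs[[i]], seqs[[j]], ...) < min_identity)
          return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  out <- families[families$family_id %in% fam_ids[keep], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_families") <- fam_ids[keep]
  out
}

#' Group presence of each family
#'
#' Counts, per family, the number of distinct archaebacterial and eubacterial
#' taxonomic groups with at least one member genome (duplicates within a group
#' count once).
#'
#' @param families Family table.
#' @param group_map Genome-to-group map; a member genome missing from the map
#'   is an error.
#' @return Data frame `family_id`, `n_arch_groups`, `n_eub_groups`, with
#'   attributes `n_arch_groups` / `n_eub_groups` giving the total group counts
#'   defined by the map.
#' @export
group_presence <- function(families, group_map) {
  validate_group_map(group_map)
  missing <- setdiff(unique(families$genome_id), group_map$genome_id)
  if (length(missing))
    fail("family member genome(s) absent from the group map: %s",
         paste(sort(missing), collapse = ", "))
  idx <- match(families$genome_id, group_map$genome_id)
  dom <- group_map$domain[idx]
  grp <- group_map$group[idx]
  fam_ids <- unique(families$family_id)
  n_arch <- vapply(fam_ids, function(f) {
    sel <- families$family_id == f
    length(unique(grp[sel & dom == "archaebacteria"]))
  }, integer(1))
  n_eub <- vapply(fam_ids, function(f) {
    sel <- families$family_id == f
    length(unique(grp[sel & dom == "eubacteria"]))
  }, integer(1))
  out <- data.frame(family_id = fam_ids, n_arch_groups = n_arch,
                    n_eub_groups = n_eub, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "n_arch_groups") <- length(unique(
    group_map$group[group_map$domain == "archaebacteria"]))
  attr(out, "n_eub_groups") <- length(unique(
    group_map$group[group_map$domain == "eubacteria"]))
  out
}

#' Taxonomic stringency grid
#'
#' Cell `(a, b)` counts the families present in at least `a` archaebacterial
#' groups **and** at least `b` eubacterial groups. Counts are, by
#' construction, monotone non-decreasing as either threshold relaxes; this is
#' asserted on every run. Per-cell family id lists are kept for annotation
#' reports.
#'
#' @param presence Output of [group_presence()].
#' @param arch_thresholds,eub_thresholds Decreasing threshold vectors; each
#'   threshold must lie in `(0, group count]`.
#' @param n_arch_groups,n_eub_groups Total group counts per domain; default
#'   taken from the `presence` attributes.
#' @return An object of class `"stringency_grid"`: `counts` (matrix,
#'   archaebacterial thresholds as rows), `families` (per-cell id lists),
#'   and the threshold vectors.
#' @export
stringency_grid <- function(presence,
                            arch_thresholds = c(11, 10, 9, 8),
                            eub_thresholds = c(30, 25, 20, 15, 10, 5, 2),
                            n_arch_groups = attr(presence, "n_arch_groups"),
                            n_eub_groups = attr(presence, "n_eub_groups")) {
  if (is.null(n_arch_groups) || is.null(n_eub_groups))
    fail("total group counts unavailable; pass n_arch_groups and n_eub_groups")
  if (any(arch_thresholds <= 0) || any(arch_thresholds > n_arch_groups))
    fail("arch_thresholds must lie in (0, %d]", n_arch_groups)
  if (any(eub_thresholds <= 0) || any(eub_thresholds > n_eub_groups))
    fail("eub_thresholds must lie in (0, %d]", n_eub_groups)
  rn <- ifelse(arch_thresholds == n_arch_groups,
               sprintf("all %d", n_arch_groups), sprintf(">=%d", arch_thresholds))
  cn <- ifelse(eub_thresholds == n_eub_groups,
               sprintf("all %d", n_eub_groups), sprintf(">=%d", eub_thresholds))
  counts <- matrix(0L, length(arch_thresholds), length(eub_thresholds),
                   dimnames = list(archaebacterial = rn, eubacterial = cn))
  fams <- vector("list", length(counts))
  dim(fams) <- dim(counts)
  dimnames(fams) <- dimnames(counts)
  for (i in seq_along(arch_thresholds)) {
    for (j in seq_along(eub_thresholds)) {
      sel <- presence$n_arch_groups >= arch_thresholds[i] &
        presence$n_eub_groups >= eub_thresholds[j]
      counts[i, j] <- sum(sel)
      fams[[i, j]] <- presence$family_id[sel]
    }
  }
  ## monotonicity along both axes is structural; assert it anyway
  o_a <- order(arch_thresholds, decreasing = TRUE)
  o_e <- order(eub_thresholds, decreasing = TRUE)
  sorted <- counts[o_a, o_e, drop = FALSE]
  if (any(apply(sorted, 1L, diff) < 0) || any(apply(sorted, 2L, diff) < 0))
    fail("internal error: stringency grid is not monotone")
  structure(list(counts = counts, families = fams,
                 arch_thresholds = arch_thresholds,
                 eub_thresholds = eub_thresholds,
                 n_arch_groups = n_arch_groups, n_eub_groups = n_eub_groups),
            class = "stringency_grid")
}

#' @export
print.stringency_grid <- function(x, ...) {
  cat(sprintf(
    "Family counts at joint group-presence thresholds (%d arch / %d eub groups)\n",
    x$n_arch_groups, x$n_eub_groups))
  print(x$counts)
  invisible(x)
}

#' Per-cell family annotation report
#'
#' Lists the families in one grid cell with their annotations (COG-style id /
#' category / product text is passed through from the family table).
#'
#' @param grid A [stringency_grid()] result.
#' @param families The family table the grid was derived from.
#' @param arch_threshold,eub_threshold The cell to report.
#' @return Data frame `family_id`, `annotation` (one row per family).
#' @export
grid_cell_report <- function(grid, families, arch_threshold, eub_threshold) {
  i <- match(arch_threshold, grid$arch_thresholds)
  j <- match(eub_threshold, grid$eub_thresholds)
  if (is.na(i) || is.na(j))
    fail("cell (%s, %s) is not in the grid", arch_threshold, eub_threshold)
  ids <- grid$families[[i, j]]
  ann <- families$annotation[match(ids, families$family_id)]
  data.frame(family_id = ids, annotation = ann, stringsAsFactors = FALSE)
}
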