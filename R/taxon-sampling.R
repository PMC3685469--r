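# Balanced taxon sampling: all-vs-all identity of a single marker protein
# (ribosomal protein L3 in the original survey), hierarchical clustering
# within each domain, and one deterministic medoid representative per cluster,
# yielding an equal number of genomes per domain.

#' Marker-protein distance matrix
#'
#' All-vs-all [pairwise_identity()] converted to distances
#' `1 - identity / 100`.
#'
#' @param markers Named character vector: one marker sequence per genome
#'   (names are genome ids); at least 2.
#' @param ... Passed to [pairwise_identity()].
#' @return Symmetric distance matrix in `[0, 1]` with zero diagonal.
#' @export
marker_distance_matrix <- function(markers, ...) {
  if (length(markers) < 2L) fail("need marker sequences for at least 2 genomes")
  if (is.null(names(markers)) || any(!nzchar(names(markers))) ||
      anyDuplicated(names(markers)))
    fail("'markers' must be named by unique genome ids")
  n <- length(markers)
  D <- matrix(0, n, n, dimnames = list(names(markers), names(markers)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- 1 - pairwise_identity(markers[[i]], markers[[j]], ...) / 100
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Cluster genomes per domain and pick medoid representatives
#'
#' Within each domain independently, agglomerative hierarchical clustering
#' (average linkage by default) is cut to `k_per_domain` clusters and each
#' cluster contributes its medoid: the member minimising the summed distance
#' to the other members, ties broken by the lexicographically smallest genome
#' id. The selection is therefore independent of input order.
#'
#' @param D Symmetric distance matrix (zero diagonal, entries in `[0, 1]`)
#'   covering every genome in `group_map`; genomes missing from `D` are an
#'   error.
#' @param group_map Genome-to-group map (only the domain is used).
#' @param k_per_domain Number of representatives per domain; must not exceed
#'   either domain's genome count.
#' @param linkage One of `"average"`, `"single"`, `"complete"`.
#' @return A list: `selected` (character vector of `2 * k_per_domain` genome
#'   ids, archaebacteria first, sorted within domain), `clusters` (named
#'   integer vector of cluster assignments per domain member) and
#'   `dendrograms` (per-domain `phylo` trees of the clustering, for export).
#' @export
cluster_and_sample <- function(D, group_map, k_per_domain,
                               linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  validate_group_map(group_map)
  if (!is.matrix(D) || is.null(rownames(D)))
    fail("'D' must be a matrix with genome ids as dimnames")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    fail("'D' must be symmetric with a zero diagonal")
  if (any(D < 0 | D > 1)) fail("'D' entries must lie in [0, 1]")
  missing <- setdiff(group_map$genome_id, rownames(D))
  if (length(missing))
    fail("distance matrix is missing genome(s): %s",
         paste(sort(missing), collapse = ", "))
  if (!is_count(k_per_domain)) fail("'k_per_domain' must be an integer >= 1")

  per_domain <- function(domain) {
    ids <- sort(group_map$genome_id[group_map$domain == domain])
    if (k_per_domain > length(ids))
      fail("k_per_domain = %d exceeds the %d genomes of %s",
           k_per_domain, length(ids), domain)
    sub <- D[ids, ids, drop = FALSE]
    if (k_per_domain == length(ids)) {
      cl <- stats::setNames(seq_along(ids), ids)
      hc <- if (length(ids) > 1L)
        stats::hclust(stats::as.dist(sub), method = linkage) else NULL
    } else {
      hc <- stats::hclust(stats::as.dist(sub), method = linkage)
      cl <- stats::cutree(hc, k = k_per_domain)
    }
    reps <- vapply(sort(unique(cl)), function(k) {
      members <- sort(names(cl)[cl == k])
      if (length(members) == 1L) return(members)
      tot <- rowSums(sub[members, members, drop = FALSE])
      members[which.min(tot)]   # members sorted, so ties -> smallest id
    }, "")
    list(reps = sort(reps), clusters = cl,
         dendrogram = if (!is.null(hc)) ape::as.phylo(hc) else NULL)
  }

  arch <- per_domain("archaebacteria")
  eub <- per_domain("eubacteria")
  list(selected = c(arch$reps, eub$reps),
       clusters = list(archaebacteria = arch$clusters,
                       eubacteria = eub$clusters),
       dendrograms = list(archaebacteria = arch$dendrogram,
                          eubacteria = eub$dendrogram))
}
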