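# Census of 4Fe-4S cluster-forming cysteine motifs across proteomes. The
# general motif is CX2CX2CX3C: four cysteines whose thiols can ligate a cubane
# iron-sulfur cluster, separated by spacer runs of (2, 2, 3) arbitrary
# residues. Variant motifs differ only in their spacer triple.

#' Define a cysteine-spacing motif pattern
#'
#' @param spacers Ordered triple of non-negative integers: the number of
#'   arbitrary residues between consecutive fixed cysteines. The default
#'   `c(2, 2, 3)` is the general 4Fe-4S motif CX2CX2CX3C.
#' @return An object of class `"motif_pattern"` with the spacer triple, total
#'   length (`4 + sum(spacers)`), the 0-based offsets of the four cysteines
#'   and a compiled lookahead regex matching overlapping occurrences.
#' @export
motif_pattern <- function(spacers = c(2L, 2L, 3L)) {
  if (length(spacers) != 3L || !is.numeric(spacers) || any(spacers < 0) ||
      any(spacers != as.integer(spacers)))
    fail("'spacers' must be three non-negative integers")
  spacers <- as.integer(spacers)
  offsets <- cumsum(c(0L, spacers + 1L))
  structure(list(
    spacers = spacers,
    length = 4L + sum(spacers),
    c_offsets = offsets,
    regex = sprintf("(?=C.{%d}C.{%d}C.{%d}C)", spacers[1], spacers[2], spacers[3]),
    label = paste(spacers, collapse = "_")
  ), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("Motif pattern CX%dCX%dCX%dC (length %d)\n",
              x$spacers[1], x$spacers[2], x$spacers[3], x$length))
  invisible(x)
}

#' Default variant spacer triples
#'
#' Four additional spacer triples scanned alongside the general motif. The
#' exact variant spacings in use vary between surveys; these defaults are
#' placeholders and fully configurable.
#'
#' @return A list of [motif_pattern()] objects.
#' @export
default_variant_patterns <- function() {
  lapply(list(c(2L, 2L, 2L), c(2L, 3L, 3L), c(3L, 2L, 3L), c(2L, 2L, 4L)),
         motif_pattern)
}

#' Scan one protein for a motif
#'
#' Reports every (1-based) start position, including overlapping occurrences,
#' at which the four fixed positions hold cysteine. `X` (and the other
#' extended IUPAC letters) are tolerated in the input: they match at spacer
#' positions and never match a fixed cysteine position. Characters outside
#' the IUPAC amino-acid alphabet are an error naming the offending record.
#'
#' @param sequence A single amino-acid string.
#' @param pattern A [motif_pattern()].
#' @param id Optional record id used in error messages.
#' @return Integer vector of 1-based start positions (possibly empty).
#' @export
scan_protein <- function(sequence, pattern = motif_pattern(), id = NULL) {
  if (length(sequence) != 1L || !is.character(sequence))
    fail("'sequence' must be a single string")
  sequence <- toupper(sequence)
  bad <- gsub(paste0("[", paste(AA_EXTENDED, collapse = ""), "]"), "", sequence)
  if (nzchar(bad))
    fail("record '%s' contains non-IUPAC amino-acid character(s): %s",
         id %||% substr(sequence, 1, 20),
         paste(unique(strsplit(bad, "")[[1L]]), collapse = ", "))
  if (nchar(sequence) < pattern$length) return(integer(0))
  m <- gregexpr(pattern$regex, sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Motif census of one genome
#'
#' Counts, for the general pattern and each variant, the number of proteins
#' containing at least one occurrence (a protein with several occurrences of
#' a pattern counts once for that pattern), and the proportion of matching
#' proteins over all proteins in the genome.
#'
#' @param proteome Named character vector of protein sequences (names are
#'   protein ids; duplicates are an error). Must be non-empty.
#' @param genome_id Genome identifier for the output row.
#' @param general The general [motif_pattern()].
#' @param variants List of variant [motif_pattern()]s; each contributes an
#'   absolute-count column named `n_<i>_<j>_<k>`.
#' @return A one-row data frame: `genome_id`, `n_proteins`,
#'   `n_matching_general`, `proportion_general`, then one count per variant.
#' @export
census_genome <- function(proteome, genome_id,
                          general = motif_pattern(),
                          variants = default_variant_patterns()) {
  if (!length(proteome))
    fail("genome '%s' has an empty proteome; proportion undefined", genome_id)
  if (is.null(names(proteome)) || any(!nzchar(names(proteome))))
    fail("proteome of '%s' must be a named character vector", genome_id)
  if (anyDuplicated(names(proteome)))
    fail("genome '%s' has duplicated protein ids: %s", genome_id,
         paste(unique(names(proteome)[duplicated(names(proteome))]),
               collapse = ", "))
  hits <- function(pat) {
    sum(vapply(seq_along(proteome), function(i) {
      length(scan_protein(proteome[[i]], pat, id = names(proteome)[i])) > 0L
    }, logical(1)))
  }
  n_gen <- hits(general)
  row <- data.frame(genome_id = genome_id,
                    n_proteins = length(proteome),
                    n_matching_general = n_gen,
                    proportion_general = n_gen / length(proteome),
                    stringsAsFactors = FALSE)
  for (v in variants) row[[paste0("n_", v$label)]] <- hits(v)
  row
}

#' Motif census across genomes
#'
#' @param proteomes Named list of proteomes (as in [simulate_proteomes()]
#'   output), or a directory of per-genome FASTA files (file name without
#'   extension = genome id).
#' @inheritParams census_genome
#' @return Data frame with one [census_genome()] row per genome.
#' @export
motif_census <- function(proteomes, general = motif_pattern(),
                         variants = default_variant_patterns()) {
  if (is.character(proteomes) && length(proteomes) == 1L && dir.exists(proteomes)) {
    files <- sort(list.files(proteomes, pattern = "\\.(fa|fasta|faa)$",
                             full.names = TRUE))
    proteomes <- stats::setNames(lapply(files, read_fasta),
                                 sub("\\.[^.]+$", "", basename(files)))
  }
  if (!length(proteomes)) fail("no proteomes to scan")
  out <- do.call(rbind, lapply(names(proteomes), function(g) {
    census_genome(proteomes[[g]], g, general, variants)
  }))
  rownames(out) <- NULL
  out
}

#' Flag taxa carrying electron-bifurcation marker complexes
#'
#' Flags each taxon (group) in which marker subunits of the heterodisulfide
#' reductase (HdrABC) or quinone-interacting oxidoreductase (QmoABC) complexes
#' are found. Under the default lenient reading, a hit to *any single subunit*
#' of either complex flags the taxon; with `strict = TRUE` some genome in the
#' taxon must carry *all* subunits of at least one complex.
#'
#' @param hits 12-column hit table (raw; filtered internally).
#' @param group_map Genome-to-group map; a hit to a genome absent from the map
#'   is an error listing the unmapped genomes.
#' @param marker_sets Named list of subunit name vectors, one per complex.
#' @param e_max,min_identity Hit filters (see [filter_hits()]).
#' @param strict Require a complete complex in one genome instead of any
#'   single subunit.
#' @return Data frame `taxon`, `flagged` covering every group in `group_map`.
#' @export
flag_markers <- function(hits, group_map,
                         marker_sets = list(HdrABC = c("HdrA", "HdrB", "HdrC"),
                                            QmoABC = c("QmoA", "QmoB", "QmoC")),
                         e_max = 1e-10, min_identity = 25, strict = FALSE) {
  validate_group_map(group_map)
  if (!length(marker_sets) || any(!lengths(marker_sets)))
    fail("'marker_sets' must be a non-empty list of non-empty subunit sets")
  kept <- filter_hits(hits, e_max = e_max, min_identity = min_identity)
  kept <- kept[kept$qseqid %in% unlist(marker_sets), , drop = FALSE]
  genomes <- hit_genomes(kept)
  unmapped <- setdiff(unique(genomes), group_map$genome_id)
  if (length(unmapped))
    fail("hit table contains genome(s) absent from the group map: %s",
         paste(sort(unmapped), collapse = ", "))
  taxa <- unique(group_map$group)
  flagged <- vapply(taxa, function(tx) {
    gset <- group_map$genome_id[group_map$group == tx]
    th <- kept[genomes %in% gset, , drop = FALSE]
    if (!nrow(th)) return(FALSE)
    if (!strict) return(TRUE)
    tg <- hit_genomes(th)
    any(vapply(unique(tg), function(gn) {
      qs <- th$qseqid[tg == gn]
      any(vapply(marker_sets, function(su) all(su %in% qs), logical(1)))
    }, logical(1)))
  }, logical(1))
  data.frame(taxon = taxa, flagged = unname(flagged), stringsAsFactors = FALSE)
}
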