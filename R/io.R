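# Readers and writers for the plain-text formats the pipeline exchanges:
# genome->group maps, ortholog family tables, 12-column similarity hit tables,
# FASTA sequence sets and pathway definitions.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")
HIT_NUMERIC <- c("pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a genome-to-group map
#'
#' A group map assigns every genome to one of the two prokaryotic domains
#' (`"archaebacteria"` or `"eubacteria"`) and to a taxonomic group within that
#' domain (the "taxa" of the figures; roughly phylum level).
#'
#' @param path Path to a TSV file with columns `genome_id`, `domain`, `group`.
#' @return A data frame with columns `genome_id`, `domain`, `group`.
#' @export
read_group_map <- function(path) {
  gm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  validate_group_map(gm)
  gm
}

#' @rdname read_group_map
#' @param group_map A group-map data frame.
#' @export
write_group_map <- function(group_map, path) {
  validate_group_map(group_map)
  utils::write.table(group_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_group_map <- function(group_map) {
  need <- c("genome_id", "domain", "group")
  if (!is.data.frame(group_map) || !all(need %in% names(group_map)))
    fail("group map must be a data frame with columns %s",
         paste(need, collapse = ", "))
  if (anyDuplicated(group_map$genome_id))
    fail("group map contains duplicated genome ids: %s",
         paste(unique(group_map$genome_id[duplicated(group_map$genome_id)]),
               collapse = ", "))
  bad <- setdiff(unique(group_map$domain), c("archaebacteria", "eubacteria"))
  if (length(bad))
    fail("group map 'domain' must be 'archaebacteria' or 'eubacteria'; found: %s",
         paste(bad, collapse = ", "))
  invisible(group_map)
}

#' Read an ortholog family table
#'
#' @param path TSV file with columns `family_id`, `genome_id`, `protein_id`,
#'   `annotation` (functional annotation is passthrough text, e.g. a COG id,
#'   category letter and product description).
#' @return A data frame with those four columns.
#' @export
read_family_table <- function(path) {
  fam <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("family_id", "genome_id", "protein_id", "annotation")
  if (!all(need %in% names(fam)))
    fail("family table must have columns %s", paste(need, collapse = ", "))
  fam
}

#' @rdname read_family_table
#' @param families A family-table data frame.
#' @export
write_family_table <- function(families, path) {
  utils::write.table(families, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular similarity hit file
#'
#' Parses the classic 12-column blast-tabular layout (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`), with no
#' header line. Malformed rows (wrong column count, non-numeric fields) raise
#' an error naming the offending line.
#'
#' By convention the subject genome id is the `sseqid` prefix before the first
#' `"|"` (the whole `sseqid` when no `"|"` is present); see [hit_genomes()].
#'
#' @param path Path to the tab-separated hit file.
#' @return A data frame with the 12 standard columns.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12L), HIT_COLUMNS))
    for (cc in HIT_NUMERIC) out[[cc]] <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    fail("malformed hit table '%s': line %d has %d columns, expected 12",
         path, which(nf != 12L)[1L], nf[nf != 12L][1L])
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  hits <- as.data.frame(m, stringsAsFactors = FALSE)
  names(hits) <- HIT_COLUMNS
  for (cc in HIT_NUMERIC) {
    v <- suppressWarnings(as.numeric(hits[[cc]]))
    if (anyNA(v))
      fail("malformed hit table '%s': line %d has non-numeric '%s' value '%s'",
           path, which(is.na(v))[1L], cc, hits[[cc]][which(is.na(v))[1L]])
    hits[[cc]] <- v
  }
  validate_hits(hits)
  hits
}

#' @rdname read_hit_table
#' @param hits A hit-table data frame (12 standard columns).
#' @export
write_hit_table <- function(hits, path) {
  validate_hits(hits)
  utils::write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_hits <- function(hits) {
  if (!is.data.frame(hits) || !all(HIT_COLUMNS %in% names(hits)))
    fail("hit table must be a data frame with columns: %s",
         paste(HIT_COLUMNS, collapse = " "))
  if (any(hits$pident < 0 | hits$pident > 100))
    fail("hit table contains percent identities outside [0, 100]")
  if (any(hits$evalue < 0))
    fail("hit table contains negative E-values")
  invisible(hits)
}

#' Subject genome ids of a hit table
#'
#' @param hits A hit-table data frame.
#' @return Character vector: the `sseqid` prefix before the first `"|"`.
#' @export
hit_genomes <- function(hits) sub("\\|.*$", "", hits$sseqid)

#' Read and write FASTA amino-acid sequence sets
#'
#' Thin wrappers over Biostrings keeping the pipeline's working representation
#' (a named character vector of sequences).
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector of amino-acid sequences.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    fail("sequences must be a named character vector")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Pathway definitions
#'
#' A pathway definition is an ordered list of gene *slots*; each slot is a set
#' of interchangeable gene names (so the slash pairs of the published gene
#' lists, e.g. `ubiD/ubiX` or `HemF/HemN`, form one slot satisfiable by either
#' member and are not double counted). `default_pathways()` returns the five
#' shipped quinone/haem biosynthesis pathway definitions: ubiquinone,
#' the menaquinone alternative (futalosine) pathway, the classical
#' menaquinone/phylloquinone pathway, classical haem and alternative haem.
#'
#' @param path Path to a YAML file of the form
#'   `pathways: {name: [[geneA], [geneB, geneC], ...]}`.
#' @return A named list; each element is a list of character vectors (slots).
#' @export
read_pathways <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$pathways) || !length(y$pathways))
    fail("pathway file '%s' has no 'pathways' entry", path)
  pw <- lapply(y$pathways, function(slots) lapply(slots, as.character))
  validate_pathways(pw)
  pw
}

#' @rdname read_pathways
#' @export
default_pathways <- function() {
  read_pathways(system.file("extdata", "pathways.yaml", package = "prokphylo",
                            mustWork = TRUE))
}

validate_pathways <- function(pathways) {
  if (is.null(names(pathways)) || any(!nzchar(names(pathways))))
    fail("pathways must be a named list")
  for (nm in names(pathways)) {
    slots <- pathways[[nm]]
    if (!length(slots))
      fail("pathway '%s' has zero gene slots", nm)
    genes <- unlist(slots)
    if (anyDuplicated(genes))
      fail("pathway '%s' repeats gene name(s): %s", nm,
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  invisible(pathways)
}
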