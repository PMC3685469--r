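# Synthetic proteomes with planted 4Fe-4S motifs. Background residues are
# drawn with a controllable cysteine frequency; with per-protein probability
# `motif_rate` one instance of the general motif (CX2CX2CX3C) is written over
# a random in-bounds window (protein length unchanged), its spacer residues
# drawn from the 19 non-cysteine letters so a planting never creates a nested
# second match by itself.

#' Simulate proteomes with known motif plantings
#'
#' @param config A [simulation_config()] object (`proteins_per_genome`,
#'   `protein_length`, `motif_rate`, `background_c_freq` are used).
#' @param group_map Genome-to-group map (only `genome_id` is used; order
#'   determines generation order).
#' @param pattern The motif planted, a [motif_pattern()]; default the general
#'   form with spacers (2, 2, 3).
#' @return A list: `proteomes` (named list, one named character vector of
#'   proteins per genome) and `plantings` (data frame `genome_id`,
#'   `protein_id`, `position` of every planted motif; ground truth).
#' @export
simulate_proteomes <- function(config, group_map, pattern = motif_pattern()) {
  if (!inherits(config, "sim_config"))
    fail("invalid simulation configuration: 'config' must be a sim_config object")
  validate_group_map(group_map)
  if (!nrow(group_map)) fail("group map is empty")
  plen <- config$protein_length
  mlen <- pattern$length
  if (config$motif_rate > 0 && plen < mlen)
    fail("protein_length (%d) is shorter than the motif (%d); cannot plant motifs",
         plen, mlen)

  p_bg <- rep((1 - config$background_c_freq) / 19, 20L)
  p_bg[match("C", AA20)] <- config$background_c_freq
  non_c <- setdiff(AA20, "C")
  offsets <- pattern$c_offsets   # 0-based offsets of the four fixed cysteines

  out <- with_seed(config$seed + 303L, {
    proteomes <- vector("list", nrow(group_map))
    plant_list <- vector("list", nrow(group_map))
    for (gi in seq_len(nrow(group_map))) {
      genome <- group_map$genome_id[gi]
      np <- config$proteins_per_genome
      chars <- matrix(sample(AA20, np * plen, replace = TRUE, prob = p_bg),
                      nrow = np)
      planted <- stats::runif(np) < config$motif_rate
      pos <- integer(0)
      if (any(planted)) {
        idx <- which(planted)
        pos <- if (plen == mlen) rep(1L, length(idx))
               else sample.int(plen - mlen + 1L, length(idx), replace = TRUE)
        for (t in seq_along(idx)) {
          window <- sample(non_c, mlen, replace = TRUE)
          window[offsets + 1L] <- "C"
          chars[idx[t], pos[t]:(pos[t] + mlen - 1L)] <- window
        }
      }
      prot_ids <- sprintf("%s.p%04d", genome, seq_len(np))
      proteomes[[gi]] <- stats::setNames(
        vapply(seq_len(np), function(i) paste(chars[i, ], collapse = ""), ""),
        prot_ids)
      plant_list[[gi]] <- data.frame(
        genome_id = rep(genome, sum(planted)),
        protein_id = prot_ids[planted],
        position = pos, stringsAsFactors = FALSE)
    }
    names(proteomes) <- group_map$genome_id
    list(proteomes = proteomes, plantings = do.call(rbind, plant_list))
  })
  rownames(out$plantings) <- NULL
  out
}
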