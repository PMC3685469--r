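# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## The 20 standard amino acids, alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Extended IUPAC letters tolerated on input (never emitted by the generator).
AA_EXTENDED <- c(AA20, "X", "B", "Z", "J", "U", "O")

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Canonical string form of the bipartition separating `side` from the rest of
## `all_tips`: the side NOT containing the lexicographically smallest tip.
canonical_split <- function(side, all_tips) {
  ref <- min(all_tips)
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = ",")
}

## stop() without the call, with sprintf-style formatting.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == as.integer(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)
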