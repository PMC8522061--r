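# Internal helpers: sequence construction, mutation, local RNG scoping.

BASES <- c("A", "C", "G", "T")

#' Random nucleotide sequence with a target G+C fraction
#'
#' Bases are i.i.d. with per-base G+C probability `gc`. This is the base
#' composition model used throughout the generator: density banding and
#' identity-based matching depend on composition, not on higher-order
#' sequence structure.
#'
#' @param n sequence length in bp.
#' @param gc target G+C fraction in `[0, 1]`.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Realized G+C fraction of a sequence
#' @param x character vector of sequences.
#' @return numeric vector of G+C fractions.
#' @export
gc_content <- function(x) {
  s <- Biostrings::DNAStringSet(x)
  as.numeric(Biostrings::letterFrequency(s, "GC", as.prob = TRUE))
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute `n_sub` uniformly chosen positions with a different base.
#' @noRd
mutate_sequence <- function(x, n_sub) {
  if (n_sub == 0L) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sequence from a text tag (Lehmer generator); used for the
# fixed marker gene catalog so marker sequences are identical across
# sessions without touching R's RNG.
#' @noRd
det_seq <- function(tag, len) {
  state <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 2147483646 + 1
  out <- character(len)
  for (i in seq_len(len)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- BASES[(state %% 4) + 1]
  }
  paste(out, collapse = "")
}

#' @noRd
insert_segment <- function(sequence, segment, locus) {
  # locus is 0-based: segment occupies [locus, locus + nchar(segment))
  paste0(substr(sequence, 1L, locus), segment,
         substr(sequence, locus + 1L, nchar(sequence)))
}

# Shift recorded 0-based half-open intervals after an insertion at `locus`.
#' @noRd
shift_intervals <- function(df, locus, by) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  move <- df$start >= locus
  df$start[move] <- df$start[move] + by
  df$end[move] <- df$end[move] + by
  df
}
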