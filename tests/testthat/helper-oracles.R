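# Independent brute-force oracles for the seed-and-extend engines. Each
# oracle enumerates exhaustively (every diagonal / every window / every
# placement) in plain R, sharing only the gate definitions with the
# implementation under test.

# All ungapped matched blocks between a and b, by scanning every diagonal
# and anchoring each block at the outermost exact k-mer matches on that
# diagonal (the same block definition as the engine, found without
# seeding or hashing).
oracle_ani_blocks <- function(a, b, k = 15L) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  out <- list()
  for (d in (-(m - k)):(n - k)) {
    i0 <- max(0L, d); i1 <- min(n, m + d)   # a-positions [i0, i1)
    if (i1 - i0 < k) next
    idx <- (i0 + 1L):i1
    eq <- av[idx] == bv[idx - d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seed_runs <- which(r$values & r$lengths >= k)
    if (length(seed_runs) == 0L) next
    span0 <- starts[min(seed_runs)]
    span1 <- ends[max(seed_runs)]
    out[[length(out) + 1L]] <- data.frame(
      astart = i0 + span0 - 1L, aend = i0 + span1,
      bstart = i0 + span0 - 1L - d, bend = i0 + span1 - d,
      matches = sum(eq[span0:span1]))
  }
  if (length(out) == 0L) {
    return(data.frame(astart = integer(), aend = integer(),
                      bstart = integer(), bend = integer(),
                      matches = integer()))
  }
  do.call(rbind, out)
}

# ANI + aligned fraction of the shorter sequence from the exhaustive
# block table (same summary as pairwise_ani).
oracle_ani <- function(a, b, k = 15L) {
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b > a)) {
    tmp <- a; a <- b; b <- tmp
  }
  blocks <- oracle_ani_blocks(a, b, k)
  if (nrow(blocks) == 0L) return(c(ani = 0, aligned_fraction = 0))
  len <- blocks$aend - blocks$astart
  ir <- IRanges::reduce(IRanges::IRanges(blocks$bstart + 1L, blocks$bend))
  c(ani = 100 * sum(blocks$matches) / sum(len),
    aligned_fraction = sum(IRanges::width(ir)) / nchar(b))
}

# Greedy clustering with the oracle ANI (same rule, exhaustive engine).
oracle_cluster <- function(candidates, min_ani = 95, min_af = 0.85,
                           k = 15L) {
  ord <- order(-candidates$length, candidates$contig_id)
  candidates <- candidates[ord, , drop = FALSE]
  rep_idx <- integer(0)
  assignment <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    placed <- 0L
    for (ci in seq_along(rep_idx)) {
      ani <- oracle_ani(candidates$sequence[rep_idx[ci]],
                        candidates$sequence[i], k)
      if (ani["ani"] >= min_ani && ani["aligned_fraction"] >= min_af) {
        placed <- ci; break
      }
    }
    if (placed == 0L) {
      rep_idx <- c(rep_idx, i); placed <- length(rep_idx)
    }
    assignment[i] <- placed
  }
  setNames(assignment, candidates$contig_id)
}

# Full-length spacer occurrences with <= max_mm substitutions via
# Biostrings sliding-window matching on both strands.
oracle_spacer_hits <- function(spacers, refs, max_mm = 1L) {
  out <- list()
  for (si in seq_along(spacers)) {
    for (ri in seq_along(refs)) {
      for (strand in c("+", "-")) {
        probe <- if (strand == "+") spacers[[si]] else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(spacers[[si]])))
        mt <- Biostrings::matchPattern(probe, refs[[ri]],
                                       max.mismatch = max_mm,
                                       with.indels = FALSE)
        if (length(mt)) {
          out[[length(out) + 1L]] <- data.frame(
            spacer = si, ref = ri,
            start = Biostrings::start(mt) - 1L, strand = strand)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(spacer = integer(), ref = integer(),
                      start = integer(), strand = character()))
  }
  do.call(rbind, out)
}

# Exhaustive read-subtraction oracle: every reference placement, ungapped
# plus all single-indel splits; identity counted over read positions
# (matches / read length), identical to the gate definition.
oracle_subtracted <- function(reads, refs, min_ident = 0.97,
                              max_indel = 1L) {
  refv <- lapply(refs, function(r) strsplit(r, "", fixed = TRUE)[[1]])
  vapply(reads, function(read) {
    rv <- strsplit(read, "", fixed = TRUE)[[1]]
    L <- length(rv)
    need <- ceiling(min_ident * L)
    for (ref in refv) {
      R <- length(ref)
      for (d in (-L):(R - 1L)) {
        match_at <- function(dd) {
          i <- seq_len(L)
          rp <- dd + i
          ok <- rp >= 1L & rp <= R
          m <- logical(L)
          m[ok] <- rv[ok] == ref[rp[ok]]
          m
        }
        m0 <- match_at(d)
        best <- sum(m0)
        if (max_indel >= 1L) {
          mp <- match_at(d + 1L)
          mm <- match_at(d - 1L)
          # deletion in read: prefix on d, suffix on d+1
          pre0 <- c(0L, cumsum(m0))
          sufp <- rev(c(0L, cumsum(rev(mp))))
          best <- max(best, max(pre0 + sufp))
          # insertion in read: base s unaligned, suffix on d-1
          sufm <- rev(c(0L, cumsum(rev(mm))))
          s <- seq_len(L)
          best <- max(best, max(pre0[s] + sufm[s + 1L]))
        }
        if (best >= need) return(TRUE)
      }
    }
    FALSE
  }, TRUE, USE.NAMES = FALSE)
}

# Content-linkage oracle: exhaustive blocks + the same gates.
oracle_content_link <- function(votu_seq, mag_seq, min_identity = 70,
                                min_block = 500L, k = 15L) {
  blocks <- oracle_ani_blocks(mag_seq, votu_seq, k)
  if (nrow(blocks) == 0L) return(NULL)
  len <- blocks$aend - blocks$astart
  ident <- 100 * blocks$matches / len
  keep <- ident >= min_identity
  if (!any(keep)) return(NULL)
  blocks <- blocks[keep, , drop = FALSE]
  ir <- IRanges::reduce(IRanges::IRanges(blocks$bstart + 1L, blocks$bend))
  total <- sum(IRanges::width(ir))
  if (total < min_block) return(NULL)
  list(total_aligned = total,
       votu_aligned_fraction = total / nchar(votu_seq))
}

# Small mutated-copy helper for fixtures.
mutated_copy <- function(seq, rate, seed = NULL) {
  f <- function() frostphage:::mutate_sequence(
    seq, round(rate * nchar(seq)))
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}
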