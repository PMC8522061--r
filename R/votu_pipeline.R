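# Viral population (vOTU) construction and coverage: contig pool, mock
# viral detection, pairwise ANI, greedy 95/85 clustering, read mapping with
# the 90%-identity / 75%-breadth gates, and per-Gbp abundance
# normalization.

#' Build a contig pool from a synthetic community
#'
#' Stands in for metagenome assembly (an external tool outside this
#' package's scope): viral genomes become full-length contigs, a fraction
#' additionally yields a shorter, lightly mutated duplicate (so clustering
#' has redundancy to collapse), and each host contributes genome fragments
#' that the viral detection step must reject.
#'
#' @param truth a `sip_community`.
#' @param dup_fraction fraction of viruses with a duplicate contig.
#' @param dup_length duplicate length as a fraction of the genome.
#' @param dup_mut substitution rate applied to duplicates.
#' @param host_fragments fragments per host genome.
#' @param fragment_len host fragment length, bp.
#' @param seed optional local seed.
#' @return data.frame with columns `contig_id`, `sequence`, `length`,
#'   `source_entity`, `truth_viral`.
#' @export
community_contigs <- function(truth, dup_fraction = 0.5, dup_length = 0.9,
                              dup_mut = 0.01, host_fragments = 2L,
                              fragment_len = 15000L, seed = NULL) {
  with_local_seed(seed, {
    rows <- list()
    for (v in truth$viruses) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = paste0("ctg_", v$id, "_full"), sequence = v$sequence,
        length = v$length, source_entity = v$id, truth_viral = TRUE,
        stringsAsFactors = FALSE)
      if (runif(1) < dup_fraction) {
        dlen <- round(dup_length * v$length)
        s0 <- sample.int(v$length - dlen + 1L, 1L)
        dup <- substr(v$sequence, s0, s0 + dlen - 1L)
        dup <- mutate_sequence(dup, rbinom(1L, dlen, dup_mut))
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = paste0("ctg_", v$id, "_dup"), sequence = dup,
          length = dlen, source_entity = v$id, truth_viral = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    for (h in truth$hosts) {
      for (f in seq_len(host_fragments)) {
        s0 <- sample.int(h$length - fragment_len + 1L, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = sprintf("ctg_%s_f%d", h$id, f),
          sequence = substr(h$sequence, s0, s0 + fragment_len - 1L),
          length = fragment_len, source_entity = h$id,
          truth_viral = FALSE, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Tag contigs as viral candidates
#'
#' Stands in for external machine-learning viral detectors, which are not
#' reimplemented here. `"truth"` mode reads the generator's ground truth;
#' `"marker"` mode flags contigs carrying a viral hallmark marker gene
#' (see [marker_catalog()]).
#'
#' @param contigs contig data.frame from [community_contigs()] or
#'   equivalent (needs `contig_id`, `sequence`; truth mode needs
#'   `truth_viral`).
#' @param mode `"truth"` or `"marker"`.
#' @return the contig data.frame with a `detection` column
#'   (`"viral_candidate"` / `"non_viral"`).
#' @export
mock_detect_viral <- function(contigs, mode = c("truth", "marker")) {
  mode <- match.arg(mode)
  if (mode == "truth") {
    if (is.null(contigs$truth_viral)) {
      stop("truth mode requires a truth_viral column")
    }
    viral <- contigs$truth_viral
  } else {
    seqs <- setNames(contigs$sequence, contigs$contig_id)
    hits <- find_markers(seqs, roles = "hallmark")
    viral <- contigs$contig_id %in% hits$entity
    if (!any(viral)) {
      warning("no hallmark markers found; empty viral candidate set")
    }
  }
  contigs$detection <- ifelse(viral, "viral_candidate", "non_viral")
  contigs
}

#' Select clustering candidates from a tagged contig pool
#'
#' Keeps viral-candidate contigs of at least `min_len` bp (the length
#' floor applied before population clustering).
#'
#' @param contigs contig data.frame with a `detection` column (see
#'   [mock_detect_viral()]).
#' @param min_len length floor, bp.
#' @return the filtered contig data.frame.
#' @export
filter_candidates <- function(contigs, min_len = 10000L) {
  contigs[contigs$detection == "viral_candidate" &
            contigs$length >= min_len, , drop = FALSE]
}

#' Pairwise average nucleotide identity
#'
#' ANI over ungapped aligned blocks found by exact k-mer seeding on shared
#' diagonals; the aligned fraction is measured on the shorter sequence
#' (union of its aligned intervals). Symmetric by construction: arguments
#' are ordered canonically before alignment.
#'
#' @param a,b nucleotide sequences.
#' @param k seed length.
#' @return named numeric: `ani` (percent identity over aligned blocks,
#'   0 when nothing aligns) and `aligned_fraction` (of the shorter
#'   sequence).
#' @export
pairwise_ani <- function(a, b, k = 15L) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  # canonical order: longer first, ties by sequence content
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b > a)) {
    tmp <- a; a <- b; b <- tmp
  }
  blocks <- .cpp_ani_blocks(a, b, as.integer(k), 512L)
  if (nrow(blocks) == 0L) {
    return(c(ani = 0, aligned_fraction = 0))
  }
  len <- blocks$aend - blocks$astart
  ani <- 100 * sum(blocks$matches) / sum(len)
  # b is the shorter sequence; union of its aligned intervals
  ir <- IRanges::reduce(IRanges::IRanges(blocks$bstart + 1L, blocks$bend))
  af <- sum(IRanges::width(ir)) / nchar(b)
  c(ani = ani, aligned_fraction = af)
}

#' Greedy vOTU clustering at 95% ANI over 85% of the shorter contig
#'
#' Contigs are sorted by length (descending, ties by id) and each joins
#' the first existing cluster whose representative it matches at
#' `>= min_ani` percent identity over `>= min_af` of the shorter
#' sequence; otherwise it founds a new cluster. The representative of a
#' cluster is its longest member (the founder). Deterministic and
#' invariant to input order.
#'
#' @param candidates contig data.frame (`contig_id`, `sequence`,
#'   `length`); all candidates must be >= `min_len` bp.
#' @param min_ani percent-identity threshold.
#' @param min_af aligned-fraction threshold on the shorter sequence.
#' @param min_len contig length filter, bp.
#' @param k seed length for the ANI engine.
#' @return list with `votus` (data.frame `votu_id`,
#'   `representative`, `length`, `n_members`), `members` (data.frame
#'   `votu_id`, `contig_id`) and `rep_seqs` (named character vector).
#' @export
cluster_votus <- function(candidates, min_ani = 95, min_af = 0.85,
                          min_len = 10000L, k = 15L) {
  if (nrow(candidates) == 0L) {
    return(list(votus = data.frame(votu_id = character(),
                                   representative = character(),
                                   length = integer(),
                                   n_members = integer(),
                                   stringsAsFactors = FALSE),
                members = data.frame(votu_id = character(),
                                     contig_id = character(),
                                     stringsAsFactors = FALSE),
                rep_seqs = character()))
  }
  if (any(candidates$length < min_len)) {
    stop("all clustering candidates must be >= ", min_len, " bp")
  }
  ord <- order(-candidates$length, candidates$contig_id)
  candidates <- candidates[ord, , drop = FALSE]
  rep_idx <- integer(0)
  assignment <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    placed <- 0L
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      ani <- pairwise_ani(candidates$sequence[r], candidates$sequence[i],
                          k = k)
      if (ani["ani"] >= min_ani && ani["aligned_fraction"] >= min_af) {
        placed <- ci
        break
      }
    }
    if (placed == 0L) {
      rep_idx <- c(rep_idx, i)
      placed <- length(rep_idx)
    }
    assignment[i] <- placed
  }
  votu_id <- sprintf("vOTU_%03d", seq_along(rep_idx))
  votus <- data.frame(
    votu_id = votu_id,
    representative = candidates$contig_id[rep_idx],
    length = candidates$length[rep_idx],
    n_members = as.integer(table(factor(assignment,
                                        levels = seq_along(rep_idx)))),
    stringsAsFactors = FALSE)
  members <- data.frame(votu_id = votu_id[assignment],
                        contig_id = candidates$contig_id,
                        stringsAsFactors = FALSE)
  members <- members[order(members$votu_id, members$contig_id), ]
  rownames(members) <- NULL
  list(votus = votus, members = members,
       rep_seqs = setNames(candidates$sequence[rep_idx], votu_id))
}

#' Normalize mean depth per gigabase-pair of metagenome
#'
#' Mean depth is already a per-position quantity (normalized by reference
#' length); dividing by the metagenome size in Gbp makes values comparable
#' across samples of different sequencing effort.
#'
#' @param mean_depth mean fold coverage.
#' @param sample_total_bp total base pairs in the sample's metagenome.
#' @param ref_length reference length, bp (validated; the length
#'   normalization is inherent in mean depth).
#' @return normalized abundance (depth per Gbp of metagenome).
#' @export
normalize_abundance <- function(mean_depth, sample_total_bp, ref_length) {
  if (any(sample_total_bp <= 0)) stop("sample_total_bp must be > 0")
  if (any(ref_length <= 0)) stop("ref_length must be > 0")
  mean_depth / (sample_total_bp / 1e9)
}

#' Map a fraction sample's reads to references
#'
#' A read is assigned to the reference of its best hit when that hit has
#' identity `>= min_ident` over `>= min_read_cov` of the read (ungapped,
#' k-mer seeded). Per-reference mean depth (aligned bp / reference
#' length), breadth (fraction of positions covered) and per-Gbp
#' normalized abundance are computed from the assigned reads; a reference
#' is `present` when breadth `>= min_breadth` and depth > 0. Ties between
#' equally good hits go to the longest reference, then lexicographic id.
#'
#' @param sample a `fraction_sample` (or data.frame of reads with a
#'   `sequence` column plus a `total_bp` attribute).
#' @param references named character vector of reference sequences.
#' @param min_ident read-level identity gate.
#' @param min_read_cov aligned fraction of the read required.
#' @param min_breadth presence gate on reference breadth.
#' @param k seed length.
#' @param step read-side seed sampling stride (a shared exact run of
#'   `k + step - 1` bases is always found; near-identical reads have
#'   error-free runs far longer than that).
#' @return data.frame of coverage records: `entity`, `sample`, `n_reads`,
#'   `mean_depth`, `breadth`, `normalized_abundance`, `present`.
#' @export
map_reads <- function(sample, references, min_ident = 0.90,
                      min_read_cov = 0.90, min_breadth = 0.75, k = 15L,
                      step = 4L) {
  stopifnot(!is.null(names(references)))
  reads <- sample$reads$sequence
  # reference priority: longest first, then id (ties in best-hit choice)
  ord <- order(-nchar(references), names(references))
  refs <- references[ord]
  hits <- if (length(reads)) {
    .cpp_map_reads(reads, unname(refs), as.integer(k), min_ident,
                   min_read_cov, 256L, as.integer(step))
  } else {
    data.frame(read = integer(), ref = integer(), start = integer(),
               matches = integer(), aligned = integer())
  }
  records_from_hits(hits, reads, refs, sample$total_bp,
                    sample$sample_id, min_breadth)
}

#' Coverage table over all samples
#'
#' Maps every sample against one reference set and binds the coverage
#' records. Reads of all samples are aligned in a single pass (one
#' reference index build), which matters at experiment scale.
#'
#' @param samples list of `fraction_sample` objects.
#' @param references named character vector.
#' @param min_ident,min_read_cov,min_breadth,k,step see [map_reads()].
#' @return data.frame of coverage records.
#' @export
coverage_table <- function(samples, references, min_ident = 0.90,
                           min_read_cov = 0.90, min_breadth = 0.75,
                           k = 15L, step = 4L) {
  stopifnot(!is.null(names(references)))
  ord <- order(-nchar(references), names(references))
  refs <- references[ord]
  n_reads <- vapply(samples, function(s) nrow(s$reads), 0L)
  all_reads <- unlist(lapply(samples, function(s) s$reads$sequence),
                      use.names = FALSE)
  hits <- if (length(all_reads)) {
    .cpp_map_reads(all_reads, unname(refs), as.integer(k), min_ident,
                   min_read_cov, 256L, as.integer(step))
  } else {
    data.frame(read = integer(), ref = integer(), start = integer(),
               matches = integer(), aligned = integer())
  }
  offset <- c(0L, cumsum(n_reads))
  sample_of_hit <- findInterval(hits$read - 1L, offset[-length(offset)],
                                rightmost.closed = FALSE)
  out <- lapply(seq_along(samples), function(si) {
    s <- samples[[si]]
    h <- hits[sample_of_hit == si, , drop = FALSE]
    h$read <- h$read - offset[si]
    records_from_hits(h, s$reads$sequence, refs, s$total_bp,
                      s$sample_id, min_breadth)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Per-reference coverage records from read-to-reference hits.
#' @noRd
records_from_hits <- function(hits, reads, refs, total_bp, sample_id,
                              min_breadth) {
  rl <- nchar(refs)
  rec <- data.frame(entity = names(refs), sample = sample_id,
                    n_reads = 0L, mean_depth = 0, breadth = 0,
                    normalized_abundance = 0, present = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(hits)) {
    for (ri in unique(hits$ref)) {
      hr <- hits[hits$ref == ri, , drop = FALSE]
      starts <- pmax(hr$start, 0L) + 1L
      ends <- pmin(hr$start + nchar(reads[hr$read]), rl[ri])
      ir <- IRanges::reduce(IRanges::IRanges(starts, ends))
      rec$n_reads[ri] <- nrow(hr)
      rec$mean_depth[ri] <- sum(hr$aligned) / rl[ri]
      rec$breadth[ri] <- sum(IRanges::width(ir)) / rl[ri]
    }
    rec$normalized_abundance <- ifelse(
      rec$mean_depth > 0,
      normalize_abundance(rec$mean_depth, total_bp, rl), 0)
    rec$present <- rec$breadth >= min_breadth & rec$mean_depth > 0
  }
  rownames(rec) <- NULL
  rec
}

#' Pool fraction samples per biological replicate
#'
#' Concatenates the reads of the sequenced density bins of every
#' (treatment, timepoint, replicate), yielding one pooled pseudo-sample
#' per replicate. Presence for the activity rule is evaluated on these
#' pooled replicates: a population whose band straddles the MH/H
#' boundary is split between the two bins but is still one labeled
#' population.
#'
#' @param samples list of `fraction_sample` objects.
#' @param sheet sample sheet.
#' @return list with pooled `samples` and `sheet`.
#' @export
pool_replicates <- function(samples, sheet) {
  key <- sprintf("%s_t%d_r%d", sheet$treatment, sheet$timepoint,
                 sheet$replicate)
  pooled <- list()
  rows <- list()
  for (kk in unique(key)) {
    ids <- sheet$sample_id[key == kk]
    reads <- do.call(rbind, lapply(samples[ids], function(s) s$reads))
    first <- sheet[key == kk, ][1, ]
    pooled[[kk]] <- structure(list(
      sample_id = kk, treatment = first$treatment,
      timepoint = first$timepoint, replicate = first$replicate,
      bin = "pooled", reads = reads,
      total_bp = sum(sheet$total_bp[key == kk])),
      class = "fraction_sample")
    rows[[kk]] <- data.frame(
      sample_id = kk, treatment = first$treatment,
      timepoint = first$timepoint, replicate = first$replicate,
      bin = "pooled", total_bp = pooled[[kk]]$total_bp,
      stringsAsFactors = FALSE)
  }
  list(samples = pooled,
       sheet = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
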