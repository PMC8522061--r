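# Virus-host linkage: CRISPR array detection in MAGs, spacer-protospacer
# matching against vOTUs (<= 1 mismatch, word-7 seeded), shared-content
# linkage (>= 70% identity, alignment-length floor), provirus and
# temperate classification, and the activity-by-linkage cross-tabulation.

#' Detect CRISPR arrays in a genome
#'
#' Finds tandem arrays of a repeated word (repeat length 19-47 bp, spacer
#' length 17-50 bp, at least `min_copies` repeat copies identical up to
#' `max_mismatch` substitutions) by exact-word seeding and array
#' extension. Reports the consensus repeat (per-column majority over
#' copies) and the spacers with their intervals (0-based half-open).
#'
#' @param genome nucleotide sequence.
#' @param min_repeat,max_repeat repeat length bounds, bp.
#' @param min_spacer,max_spacer spacer length bounds, bp.
#' @param min_copies minimum repeat copies.
#' @param max_mismatch substitutions tolerated between repeat copies.
#' @return list of arrays; each has `start`, `end`, `repeat_consensus`,
#'   `spacers` (data.frame `sequence`, `start`, `end`).
#' @export
detect_crispr_arrays <- function(genome, min_repeat = 19L,
                                 max_repeat = 47L, min_spacer = 17L,
                                 max_spacer = 50L, min_copies = 2L,
                                 max_mismatch = 1L) {
  stopifnot(nchar(genome) > 0)
  raw <- .cpp_detect_crispr(genome, as.integer(min_repeat),
                            as.integer(max_repeat), as.integer(min_spacer),
                            as.integer(max_spacer), as.integer(min_copies),
                            as.integer(max_mismatch), 13L)
  lapply(raw, function(a) {
    rs <- a$repeat_starts
    rl <- a$repeat_len
    copies <- substring(genome, rs + 1L, rs + rl)
    cons <- apply(do.call(rbind, strsplit(copies, "", fixed = TRUE)), 2,
                  function(col) names(sort(table(col),
                                           decreasing = TRUE))[1])
    sp_start <- rs[-length(rs)] + rl
    sp_end <- rs[-1L]
    list(start = a$start, end = a$end,
         repeat_consensus = paste(cons, collapse = ""),
         spacers = data.frame(
           sequence = substring(genome, sp_start + 1L, sp_end),
           start = sp_start, end = sp_end, stringsAsFactors = FALSE))
  })
}

#' Extract all CRISPR spacers from a MAG set
#'
#' @param mags named character vector of MAG sequences.
#' @param ... passed to [detect_crispr_arrays()].
#' @return data.frame: `mag`, `array`, `spacer_id`, `sequence`, `start`,
#'   `end`.
#' @export
crispr_spacers <- function(mags, ...) {
  out <- list()
  for (m in names(mags)) {
    arrays <- detect_crispr_arrays(mags[[m]], ...)
    for (ai in seq_along(arrays)) {
      sp <- arrays[[ai]]$spacers
      if (nrow(sp) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        mag = m, array = ai,
        spacer_id = sprintf("%s_a%d_s%d", m, ai, seq_len(nrow(sp))),
        sequence = sp$sequence, start = sp$start, end = sp$end,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(mag = character(), array = integer(),
                      spacer_id = character(), sequence = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Match CRISPR spacers to vOTU genomes
#'
#' A spacer links its MAG to a vOTU when either strand of the vOTU
#' representative contains the full spacer with at most `max_mismatch`
#' substitutions. The search is seeded by exact 7-bp words, which is
#' lossless for `max_mismatch <= 1` and spacers of at least 15 bp.
#'
#' @param spacers data.frame from [crispr_spacers()] (or a named
#'   character vector of spacer sequences).
#' @param votus named character vector of vOTU representative sequences.
#' @param max_mismatch substitutions allowed over the full spacer length.
#' @param word seed word size.
#' @return data.frame of raw CRISPR links: `spacer_id`, `mag`, `votu`,
#'   `start`, `strand`, `mismatches`.
#' @export
match_spacers <- function(spacers, votus, max_mismatch = 1L, word = 7L) {
  if (is.character(spacers)) {
    spacers <- data.frame(spacer_id = names(spacers), mag = NA_character_,
                          sequence = unname(spacers),
                          stringsAsFactors = FALSE)
  }
  if (any(nchar(spacers$sequence) < 17L)) {
    stop("spacers must be >= 17 bp")
  }
  empty <- data.frame(spacer_id = character(), mag = character(),
                      votu = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      spacer_len = integer(), stringsAsFactors = FALSE)
  if (nrow(spacers) == 0L || length(votus) == 0L) return(empty)
  out <- list()
  for (strand in c("+", "-")) {
    probe <- if (strand == "+") spacers$sequence else
      revcomp(spacers$sequence)
    hits <- .cpp_spacer_hits(probe, unname(votus),
                             as.integer(max_mismatch), as.integer(word))
    if (nrow(hits)) {
      out[[strand]] <- data.frame(
        spacer_id = spacers$spacer_id[hits$spacer],
        mag = spacers$mag[hits$spacer],
        votu = names(votus)[hits$ref], start = hits$start,
        strand = strand, mismatches = hits$mismatches,
        spacer_len = nchar(spacers$sequence[hits$spacer]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Shared-content linkage between a vOTU and a MAG
#'
#' Local ungapped similarity blocks (k-mer seeded) at or above
#' `min_identity` percent identity; a link is emitted when the union of
#' aligned vOTU intervals reaches `min_block` bp. The fraction of the
#' vOTU covered by the alignment is recorded so provirus containment can
#' be re-evaluated under any threshold.
#'
#' @param votu_seq,mag_seq sequences.
#' @param min_identity block identity gate, percent.
#' @param min_block minimum total aligned length, bp.
#' @param k seed length.
#' @return `NULL` when no link; otherwise a list with `n_blocks`,
#'   `total_aligned`, `best_identity`, `votu_aligned_fraction`.
#' @export
content_linkage <- function(votu_seq, mag_seq, min_identity = 70,
                            min_block = 500L, k = 15L) {
  stopifnot(nchar(votu_seq) > 0, nchar(mag_seq) > 0)
  blocks <- .cpp_ani_blocks(mag_seq, votu_seq, as.integer(k), 512L)
  summarize_content_blocks(blocks, nchar(votu_seq), min_identity,
                           min_block)
}

# Apply the identity and total-length gates to a block table (b side =
# vOTU); returns NULL when no link.
#' @noRd
summarize_content_blocks <- function(blocks, votu_len, min_identity,
                                     min_block) {
  if (nrow(blocks) == 0L) return(NULL)
  len <- blocks$aend - blocks$astart
  ident <- 100 * blocks$matches / len
  keep <- ident >= min_identity
  if (!any(keep)) return(NULL)
  blocks <- blocks[keep, , drop = FALSE]
  ident <- ident[keep]
  # union of aligned vOTU intervals (b side of the block table)
  ir <- IRanges::reduce(IRanges::IRanges(blocks$bstart + 1L, blocks$bend))
  total <- sum(IRanges::width(ir))
  if (total < min_block) return(NULL)
  list(n_blocks = nrow(blocks), total_aligned = total,
       best_identity = max(ident),
       votu_aligned_fraction = total / votu_len)
}

#' Classify a linked temperate virus as a provirus
#'
#' A temperate vOTU is a provirus of a linked MAG when the content
#' alignment contains at least `provirus_containment` of the vOTU contig.
#'
#' @param votu_aligned_fraction fraction of the vOTU covered by the MAG
#'   alignment.
#' @param temperate logical; lysogeny-capable.
#' @param provirus_containment containment threshold.
#' @return logical vector.
#' @export
call_provirus <- function(votu_aligned_fraction, temperate,
                          provirus_containment = 0.90) {
  temperate & votu_aligned_fraction >= provirus_containment
}

#' Classify vOTUs as temperate
#'
#' A vOTU is temperate when it carries a lysogeny marker gene (integrase
#' or parA analogue) or when content-linkage containment in a MAG reaches
#' the provirus threshold. External classifier calls can be supplied as
#' an optional evidence column but are never computed here.
#'
#' @param votu_seqs named character vector of representatives.
#' @param containment named numeric of maximal `votu_aligned_fraction`
#'   per vOTU (optional).
#' @param external named logical of external temperate evidence
#'   (optional).
#' @param provirus_containment containment threshold.
#' @return data.frame: `votu`, `has_lysogeny_marker`, `max_containment`,
#'   `temperate`.
#' @export
classify_temperate <- function(votu_seqs, containment = NULL,
                               external = NULL,
                               provirus_containment = 0.90) {
  hits <- find_markers(votu_seqs, roles = "lysogeny")
  has_marker <- names(votu_seqs) %in% hits$entity
  cont <- rep(0, length(votu_seqs))
  if (!is.null(containment)) {
    idx <- match(names(votu_seqs), names(containment))
    cont <- ifelse(is.na(idx), 0, containment[idx])
  }
  ext <- rep(FALSE, length(votu_seqs))
  if (!is.null(external)) {
    idx <- match(names(votu_seqs), names(external))
    ext <- ifelse(is.na(idx), FALSE, external[idx])
  }
  data.frame(votu = names(votu_seqs), has_lysogeny_marker = has_marker,
             max_containment = unname(cont),
             temperate = has_marker | cont >= provirus_containment | ext,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Link vOTUs to MAGs by CRISPR spacers and shared content
#'
#' Runs CRISPR detection on the MAGs, matches spacers to the vOTUs, runs
#' content linkage for every pair, classifies temperate vOTUs and
#' proviruses, and aggregates per-pair link records.
#'
#' @param votus named character vector of vOTU representatives.
#' @param mags named character vector of MAG sequences.
#' @param max_mismatch spacer mismatch allowance.
#' @param min_identity,min_block content-linkage gates.
#' @param provirus_containment containment threshold.
#' @return list: `crispr_hits`, `content_links`, `links` (per-pair
#'   records with `evidence` in crispr/content/both, `n_matches`,
#'   `best_identity`, `votu_aligned_fraction`, `provirus`), `temperate`.
#' @export
link_virus_host <- function(votus, mags, max_mismatch = 1L,
                            min_identity = 70, min_block = 500L,
                            provirus_containment = 0.90) {
  spacers <- crispr_spacers(mags)
  crispr_hits <- match_spacers(spacers, votus, max_mismatch = max_mismatch)
  # one multi-reference pass: vOTUs indexed once, each MAG scanned once
  blocks <- .cpp_content_blocks(unname(mags), unname(votus), 15L, 512L)
  content <- list()
  if (nrow(blocks)) {
    for (grp in split(blocks, list(blocks$query, blocks$ref),
                      drop = TRUE)) {
      v <- names(votus)[grp$ref[1]]
      m <- names(mags)[grp$query[1]]
      cl <- summarize_content_blocks(grp, nchar(votus[[v]]),
                                     min_identity, min_block)
      if (!is.null(cl)) {
        content[[length(content) + 1L]] <- data.frame(
          votu = v, mag = m, n_blocks = cl$n_blocks,
          total_aligned = cl$total_aligned,
          best_identity = cl$best_identity,
          votu_aligned_fraction = cl$votu_aligned_fraction,
          stringsAsFactors = FALSE)
      }
    }
  }
  content_links <- do.call(rbind, content)
  if (is.null(content_links)) {
    content_links <- data.frame(votu = character(), mag = character(),
                                n_blocks = integer(),
                                total_aligned = integer(),
                                best_identity = numeric(),
                                votu_aligned_fraction = numeric(),
                                stringsAsFactors = FALSE)
  }
  cont_by_votu <- if (nrow(content_links)) {
    tapply(content_links$votu_aligned_fraction, content_links$votu, max)
  } else {
    NULL
  }
  temperate <- classify_temperate(
    votus, containment = cont_by_votu,
    provirus_containment = provirus_containment)

  pairs <- unique(rbind(
    if (nrow(crispr_hits)) crispr_hits[c("votu", "mag")],
    if (nrow(content_links)) content_links[c("votu", "mag")]))
  links <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    links <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      v <- pairs$votu[i]; m <- pairs$mag[i]
      ch <- crispr_hits[crispr_hits$votu == v & crispr_hits$mag == m, ,
                        drop = FALSE]
      cl <- content_links[content_links$votu == v &
                            content_links$mag == m, , drop = FALSE]
      has_content <- nrow(cl) > 0L
      af <- if (has_content) max(cl$votu_aligned_fraction) else 0
      temp <- temperate$temperate[temperate$votu == v]
      crispr_ident <- if (nrow(ch)) {
        100 * max(1 - ch$mismatches / ch$spacer_len)
      }
      data.frame(
        votu = v, mag = m,
        evidence = if (nrow(ch) && has_content) "both"
                   else if (nrow(ch)) "crispr" else "content",
        n_matches = nrow(ch) + nrow(cl),
        best_identity = max(c(if (has_content) cl$best_identity,
                              crispr_ident)),
        votu_aligned_fraction = af,
        provirus = call_provirus(af, temp, provirus_containment),
        stringsAsFactors = FALSE)
    }))
    links <- links[order(links$votu, links$mag), ]
    rownames(links) <- NULL
  } else {
    links <- data.frame(votu = character(), mag = character(),
                        evidence = character(), n_matches = integer(),
                        best_identity = numeric(),
                        votu_aligned_fraction = numeric(),
                        provirus = logical(), stringsAsFactors = FALSE)
  }
  list(crispr_hits = crispr_hits, content_links = content_links,
       links = links, temperate = temperate)
}

#' Activity-by-linkage cross-tabulation
#'
#' Assigns every raw virus-host match to exactly one of four groups by
#' the partners' activity (1: active vOTU-active MAG, 2: active
#' vOTU-unlabeled MAG, 3: unlabeled vOTU-active MAG, 4: unlabeled
#' vOTU-unlabeled MAG) and tallies matches, unique vOTU-MAG pairs, and
#' distinct vOTUs and MAGs per group, with a totals row of column sums.
#' Distinct-overall counts (which can be smaller than the per-group
#' column sums when an entity appears in several groups) are attached as
#' the `distinct_overall` attribute.
#'
#' @param links data.frame of raw matches; one row per match with `votu`,
#'   `mag` and optionally `n_matches` (default 1 per row).
#' @param votu_active named logical: activity per vOTU.
#' @param mag_active named logical: activity per MAG.
#' @return data.frame of class `sip_crosstab` with rows group 1-4 and
#'   `Total`.
#' @export
build_crosstab <- function(links, votu_active, mag_active) {
  if (nrow(links)) {
    miss_v <- setdiff(links$votu, names(votu_active))
    miss_m <- setdiff(links$mag, names(mag_active))
    if (length(miss_v) || length(miss_m)) {
      stop("linked entities lack an activity call: ",
           paste(c(miss_v, miss_m), collapse = ", "))
    }
  }
  n_matches <- if (is.null(links$n_matches)) rep(1L, nrow(links)) else
    links$n_matches
  va <- votu_active[links$votu]
  ma <- mag_active[links$mag]
  group <- ifelse(va & ma, 1L, ifelse(va & !ma, 2L,
                                      ifelse(!va & ma, 3L, 4L)))
  tally <- function(g) {
    idx <- which(group == g)
    c(n_matches = sum(n_matches[idx]),
      n_unique_pairs = nrow(unique(links[idx, c("votu", "mag")])),
      n_votus = length(unique(links$votu[idx])),
      n_mags = length(unique(links$mag[idx])))
  }
  rows <- t(vapply(1:4, tally, numeric(4)))
  crosstab_from_group_counts(
    rows[, "n_matches"], rows[, "n_unique_pairs"], rows[, "n_votus"],
    rows[, "n_mags"],
    distinct_overall = c(
      pairs = nrow(unique(links[c("votu", "mag")])),
      votus = length(unique(links$votu)),
      mags = length(unique(links$mag))))
}

#' Cross-tabulation from per-group tallies
#'
#' Builds the activity-by-linkage table (including the totals row, which
#' is the column sum over groups) from already-tallied per-group rows.
#'
#' @param n_matches,n_unique_pairs,n_votus,n_mags numeric vectors of
#'   length 4 (groups 1-4).
#' @param distinct_overall optional named vector attached as an
#'   attribute.
#' @return data.frame of class `sip_crosstab`.
#' @export
crosstab_from_group_counts <- function(n_matches, n_unique_pairs,
                                       n_votus = rep(NA_real_, 4),
                                       n_mags = rep(NA_real_, 4),
                                       distinct_overall = NULL) {
  stopifnot(length(n_matches) == 4, length(n_unique_pairs) == 4)
  if (any(n_unique_pairs > n_matches, na.rm = TRUE)) {
    stop("n_unique_pairs cannot exceed n_matches")
  }
  tab <- data.frame(
    group = c("1", "2", "3", "4", "Total"),
    description = c("active vOTU-active MAG", "active vOTU-unlabeled MAG",
                    "unlabeled vOTU-active MAG",
                    "unlabeled vOTU-unlabeled MAG", ""),
    n_matches = c(n_matches, sum(n_matches)),
    n_unique_pairs = c(n_unique_pairs, sum(n_unique_pairs)),
    n_votus = c(n_votus, sum(n_votus)),
    n_mags = c(n_mags, sum(n_mags)),
    stringsAsFactors = FALSE)
  if (!is.null(distinct_overall)) {
    attr(tab, "distinct_overall") <- distinct_overall
  }
  class(tab) <- c("sip_crosstab", "data.frame")
  tab
}
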