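# Fixed marker gene catalog. Real pipelines recognise viral hallmark genes
# (capsid, terminase), lysogeny genes (integrase, parA) and auxiliary
# metabolic genes by annotation; here each marker is a fixed synthetic
# nucleotide sequence that the generator plants verbatim and the
# classifiers search for. The catalog is deterministic across sessions.

#' Marker gene catalog
#'
#' Returns the fixed set of synthetic marker sequences used by the
#' community generator and the classifiers. Roles:
#' \describe{
#'   \item{hallmark}{viral hallmark genes; `mock_detect_viral(mode =
#'     "marker")` flags contigs carrying one.}
#'   \item{lysogeny}{integrase / parA analogues; presence classifies a
#'     vOTU as temperate.}
#'   \item{amg}{auxiliary metabolic gene analogue carried by a subset of
#'     viral genomes.}
#' }
#'
#' @return data.frame with columns `name`, `role`, `length`, `sequence`.
#' @export
marker_catalog <- function() {
  defs <- list(
    c("major_capsid", "hallmark", 810),
    c("terminase",    "hallmark", 750),
    c("integrase",    "lysogeny", 900),
    c("parA",         "lysogeny", 660),
    c("amg_glycoside_hydrolase", "amg", 720)
  )
  data.frame(
    name = vapply(defs, `[`, "", 1L),
    role = vapply(defs, `[`, "", 2L),
    length = as.integer(vapply(defs, `[`, "", 3L)),
    sequence = vapply(defs, function(d)
      det_seq(d[[1]], as.integer(d[[3]])), ""),
    stringsAsFactors = FALSE
  )
}

# Overwrite a stretch of `sequence` with a marker, recording coordinates.
#' @noRd
plant_marker <- function(sequence, marker_seq, locus) {
  len <- nchar(marker_seq)
  stopifnot(locus >= 0, locus + len <= nchar(sequence))
  list(
    sequence = paste0(substr(sequence, 1L, locus), marker_seq,
                      substr(sequence, locus + len + 1L, nchar(sequence))),
    start = locus, end = locus + len
  )
}

#' Locate marker genes in sequences
#'
#' Searches each sequence (both strands) for catalog markers with a
#' seed-and-extend scan. Planted marker copies diverge from the catalog
#' sequence like members of a gene family (see
#' [generate_viral_genome()]), so the gate tolerates substantial
#' divergence: at least 70% identity over at least 80% of the marker.
#'
#' @param seqs named character vector of sequences.
#' @param roles marker roles to search for (subset of the catalog roles).
#' @param min_identity minimum identity fraction of the marker alignment.
#' @param min_cov minimum aligned fraction of the marker.
#' @return data.frame with columns `entity`, `marker`, `role`, `strand`.
#' @export
find_markers <- function(seqs, roles = c("hallmark", "lysogeny", "amg"),
                         min_identity = 0.70, min_cov = 0.75) {
  cat_df <- marker_catalog()
  cat_df <- cat_df[cat_df$role %in% roles, , drop = FALSE]
  out <- list()
  for (i in seq_along(seqs)) {
    for (strand in c("+", "-")) {
      probes <- if (strand == "+") cat_df$sequence else
        revcomp(cat_df$sequence)
      hits <- .cpp_map_reads(probes, seqs[[i]], 11L, min_identity, min_cov,
                             512L, 1L)
      if (nrow(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          entity = names(seqs)[i],
          marker = cat_df$name[hits$read],
          role = cat_df$role[hits$read],
          strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(entity = character(), marker = character(),
                      role = character(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  unique(res[c("entity", "marker", "role")])
}
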