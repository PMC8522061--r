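# Writers/readers for the package's on-disk interfaces: community FASTA,
# truth JSON, GFF3 of planted features, per-sample FASTQ, sample sheet and
# tabular outputs. Standard formats go through Biostrings / rtracklayer /
# jsonlite.

#' Write community genomes as FASTA
#' @param truth a `sip_community`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_community_fasta <- function(truth, file) {
  seqs <- Biostrings::DNAStringSet(community_sequences(truth))
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' Write ground truth as JSON
#'
#' Abundances, labeling fractions, activity flags, lifestyle and planted
#' linkage facts (sequences live in the FASTA). Byte-identical for
#' identical `(config, seed)`.
#'
#' @param truth a `sip_community`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, file) {
  hosts <- lapply(truth$hosts, function(h) {
    list(id = h$id, length = h$length, gc = round(h$gc, 6),
         phylum = h$phylum, active = as.list(h$active),
         growth_factor = as.list(round(h$growth_factor, 6)),
         crispr_arrays = h$crispr_arrays[
           c("array_id", "virus", "start", "end", "n_spacers")],
         provirus_loci = h$provirus_loci)
  })
  viruses <- lapply(truth$viruses, function(v) {
    list(id = v$id, length = v$length, gc = round(v$gc, 6),
         lifestyle = v$lifestyle, integrated_in = v$integrated_in,
         active = as.list(v$active), pattern = v$pattern,
         growth_factor = as.list(round(v$growth_factor, 6)),
         true_hosts = v$true_hosts, marker_genes = v$marker_genes)
  })
  payload <- list(
    seed = truth$seed,
    timepoints = truth$config$timepoints,
    hosts = hosts, viruses = viruses,
    abundance = truth$abundance, frac_new = truth$frac_new,
    linkage = truth$linkage)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 12,
                           pretty = TRUE, na = "null")
  writeLines(json, file)
  invisible(file)
}

# GRanges of planted features (1-based closed intervals for GFF3).
#' @noRd
features_granges <- function(truth) {
  rows <- list()
  for (h in truth$hosts) {
    ca <- h$crispr_arrays
    for (i in seq_len(nrow(ca))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = h$id, start = ca$start[i] + 1L, end = ca$end[i],
        type = "repeat_region", id = ca$array_id[i],
        target = ca$virus[i], stringsAsFactors = FALSE)
    }
    pv <- h$provirus_loci
    for (i in seq_len(nrow(pv))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = h$id, start = pv$start[i] + 1L, end = pv$end[i],
        type = "mobile_genetic_element",
        id = sprintf("%s_provirus_%s", h$id, pv$virus[i]),
        target = pv$virus[i], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end), strand = "+")
  gr$type <- df$type
  gr$ID <- df$id
  gr$Target <- df$target
  gr
}

#' Write planted CRISPR arrays and provirus loci as GFF3
#'
#' Internal 0-based half-open intervals are converted to GFF3's 1-based
#' closed convention; [read_features_gff3()] inverts the conversion so
#' coordinates round-trip unchanged.
#'
#' @param truth a `sip_community`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_features_gff3 <- function(truth, file) {
  rtracklayer::export(features_granges(truth), file, format = "gff3")
  invisible(file)
}

#' Read planted features back from GFF3
#' @param file GFF3 path.
#' @return data.frame with 0-based half-open `start`/`end`, `seqnames`,
#'   `type`, `id`, `target`.
#' @export
read_features_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  data.frame(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    type = as.character(gr$type), id = gr$ID, target = gr$Target,
    stringsAsFactors = FALSE)
}

#' Write a fraction sample as FASTQ
#'
#' Fixed-length single-end reads with constant quality (the read model
#' has substitution errors only).
#'
#' @param sample a `fraction_sample`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_fraction_fastq <- function(sample, file) {
  reads <- Biostrings::DNAStringSet(sample$reads$sequence)
  names(reads) <- sample$reads$read_id
  qual <- Biostrings::BStringSet(
    vapply(Biostrings::width(reads),
           function(w) paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(reads, file, format = "fastq",
                              qualities = qual)
  invisible(file)
}

#' Read a FASTQ file into a read table
#' @param file FASTQ path.
#' @return data.frame `read_id`, `sequence`.
#' @export
read_fastq_reads <- function(file) {
  s <- Biostrings::readDNAStringSet(file, format = "fastq")
  data.frame(read_id = names(s), sequence = as.character(s),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write/read tab-separated tables
#'
#' Plain TSV with a header, the interchange format of all tabular
#' outputs (sample sheet, coverage, activity, links, cross-tabulation).
#'
#' @param x data.frame.
#' @param file path.
#' @return the path (write) or a data.frame (read).
#' @export
write_tsv_table <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' Write all simulation outputs of an experiment
#'
#' FASTQ per fraction sample, the sample sheet, and the truth-side read
#' provenance table.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sim$samples) {
    write_fraction_fastq(s, file.path(dir, paste0(s$sample_id, ".fastq")))
  }
  write_tsv_table(sim$sheet, file.path(dir, "samples.tsv"))
  write_tsv_table(sim$provenance, file.path(dir, "read_provenance.tsv"))
  invisible(dir)
}
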