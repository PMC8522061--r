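# Activity calling. vOTUs: the 18O-presence / 16O-absence rule. MAGs: (1)
# read subtraction against an unlabeled (16O) reference followed by
# attribution of the surviving "active" reads, and (2) a zero-inflated
# log-normal fold-change test (18O vs 16O within timepoint and fraction)
# at 5% FDR.

#' Call vOTU activity by the presence rule
#'
#' A vOTU is active at a timepoint when it is present (per the coverage
#' records' breadth gate) in at least one H2-18O fraction sample and in
#' none of the paired natural-abundance (16O) samples at that timepoint.
#' Presence within a replicate is evaluated on the union of its sequenced
#' density-fraction records (present in either bin counts as present).
#' vOTUs present in both treatments are "unlabeled"; vOTUs present
#' nowhere are "undetected".
#'
#' @param coverage coverage records (see [map_reads()]).
#' @param sheet sample sheet with `sample_id`, `treatment`, `timepoint`,
#'   `replicate`, `bin`.
#' @param timepoint timepoint to evaluate.
#' @return data.frame of activity calls: `entity`, `kind`, `timepoint`,
#'   `method`, `status`, `active`, `n_reps_18O`, `n_reps_16O`.
#' @export
call_votu_activity <- function(coverage, sheet, timepoint) {
  sh <- sheet[sheet$timepoint == timepoint, , drop = FALSE]
  for (arm in c("18O", "16O")) {
    if (!any(sh$treatment == arm)) {
      stop("missing treatment arm ", arm, " at timepoint ", timepoint)
    }
  }
  cov <- merge(coverage, sh[c("sample_id", "treatment", "replicate")],
               by.x = "sample", by.y = "sample_id")
  # presence per (entity, treatment, replicate): union over bins
  agg <- stats::aggregate(present ~ entity + treatment + replicate,
                          data = cov, FUN = any)
  entities <- sort(unique(coverage$entity))
  n_arm <- function(ent, arm) {
    sum(agg$present[agg$entity == ent & agg$treatment == arm])
  }
  n18 <- vapply(entities, n_arm, 0, arm = "18O")
  n16 <- vapply(entities, n_arm, 0, arm = "16O")
  status <- ifelse(n18 >= 1 & n16 == 0, "active",
                   ifelse(n18 + n16 >= 1, "unlabeled", "undetected"))
  data.frame(entity = entities, kind = "vOTU", timepoint = timepoint,
             method = "presence_rule", status = status,
             active = status == "active", n_reps_18O = n18,
             n_reps_16O = n16, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mock-assemble the unlabeled (16O) reference
#'
#' Stands in for assembling contigs from the natural-abundance samples:
#' reads of all 16O fraction samples are pooled and mapped to the known
#' genome set; every genome reaching `min_breadth` pooled breadth
#' contributes its sequence to the unlabeled reference. (A real assembly
#' would recover roughly the covered portion of such genomes.)
#'
#' @param samples list of `fraction_sample` objects.
#' @param sheet sample sheet.
#' @param references named character vector of genome sequences.
#' @param min_breadth pooled-breadth threshold for inclusion.
#' @return named character vector: the unlabeled reference contigs.
#' @export
build_unlabeled_reference <- function(samples, sheet, references,
                                      min_breadth = 0.25) {
  ids16 <- sheet$sample_id[sheet$treatment == "16O"]
  reads <- unlist(lapply(samples[ids16], function(s) s$reads$sequence),
                  use.names = FALSE)
  pooled <- list(sample_id = "pooled_16O",
                 reads = data.frame(sequence = reads,
                                    stringsAsFactors = FALSE),
                 total_bp = sum(nchar(reads)))
  if (length(reads) == 0L) return(references[0])
  cov <- map_reads(pooled, references)
  keep <- cov$entity[cov$breadth >= min_breadth]
  references[names(references) %in% keep]
}

#' Subtract reads matching an unlabeled reference
#'
#' A labeled-treatment read is subtracted when it matches any unlabeled
#' reference sequence at `>= min_identity` (counted over read positions)
#' with at most `max_indel` indels; the survivors are the "active" reads.
#' Enlarging the reference can only shrink the survivor set.
#'
#' @param reads character vector of read sequences (or a `fraction_sample`).
#' @param unlabeled_reference named character vector of 16O-derived
#'   contigs (non-empty).
#' @param min_identity identity gate.
#' @param max_indel maximum indels per alignment (0 or 1).
#' @param k seed length.
#' @return the surviving reads (same type as input), with attribute
#'   `subtracted` giving the indices removed.
#' @export
subtract_reads <- function(reads, unlabeled_reference, min_identity = 0.97,
                           max_indel = 1L, k = 15L) {
  if (length(unlabeled_reference) == 0L) {
    stop("unlabeled_reference must be non-empty")
  }
  seqs <- if (inherits(reads, "fraction_sample")) reads$reads$sequence
          else reads
  hit <- .cpp_subtract_hits(seqs, unname(unlabeled_reference),
                            as.integer(k), min_identity,
                            as.integer(max_indel), 256L, 2L)
  out <- if (inherits(reads, "fraction_sample")) {
    r <- reads
    r$reads <- r$reads[!hit, , drop = FALSE]
    r
  } else {
    reads[!hit]
  }
  attr(out, "subtracted") <- which(hit)
  out
}

#' Call MAG activity from attributed active reads
#'
#' Active (subtraction-surviving) reads are assigned to MAGs with the
#' standard mapping gates; a MAG is active when its active-read mean
#' depth and breadth reach the configured floors. This replaces the
#' re-assembly and re-binning of active reads with direct attribution to
#' the known genome set, preserving the inference (which genomes the
#' distinct 18O reads support).
#'
#' @param active_reads character vector of surviving read sequences.
#' @param mags named character vector of MAG sequences.
#' @param min_active_depth mean-depth floor (x-fold).
#' @param min_active_breadth breadth floor.
#' @param timepoint recorded on the calls.
#' @param ... passed to [map_reads()].
#' @return data.frame of activity calls with evidence columns
#'   `active_reads`, `active_depth`, `active_breadth`.
#' @export
call_mag_activity_subtraction <- function(active_reads, mags,
                                          min_active_depth = 0.5,
                                          min_active_breadth = 0.10,
                                          timepoint = NA, ...) {
  pooled <- list(sample_id = "active_reads",
                 reads = data.frame(sequence = active_reads,
                                    stringsAsFactors = FALSE),
                 total_bp = max(1, sum(nchar(active_reads))))
  cov <- map_reads(pooled, mags, ...)
  data.frame(entity = cov$entity, kind = "MAG", timepoint = timepoint,
             method = "read_subtraction",
             active = cov$mean_depth >= min_active_depth &
               cov$breadth >= min_active_breadth,
             active_reads = cov$n_reads, active_depth = cov$mean_depth,
             active_breadth = cov$breadth, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Run the read-subtraction activity method for one timepoint
#'
#' Pools the 18O fraction samples of a timepoint, subtracts reads
#' matching the unlabeled reference, and attributes the survivors to
#' MAGs.
#'
#' @param samples,sheet simulated experiment pieces.
#' @param mags named character vector of MAG sequences.
#' @param unlabeled_reference see [build_unlabeled_reference()].
#' @param timepoint timepoint to evaluate.
#' @param ... passed to [call_mag_activity_subtraction()].
#' @return data.frame of activity calls.
#' @export
subtraction_activity <- function(samples, sheet, mags,
                                 unlabeled_reference, timepoint, ...) {
  ids <- sheet$sample_id[sheet$treatment == "18O" &
                           sheet$timepoint == timepoint]
  reads <- unlist(lapply(samples[ids], function(s) s$reads$sequence),
                  use.names = FALSE)
  survivors <- if (length(unlabeled_reference) == 0L) reads
               else subtract_reads(reads, unlabeled_reference)
  call_mag_activity_subtraction(survivors, mags, timepoint = timepoint,
                                ...)
}

#' Median-of-ratios normalization factors
#'
#' Size factors computed on the entities that are non-zero in every
#' sample (the compositional reference set); when no such entity exists
#' the factors fall back to relative library sizes. Factors are scaled to
#' geometric mean 1.
#'
#' @param counts matrix, entities x samples.
#' @return numeric vector of per-sample size factors.
#' @export
mor_norm_factors <- function(counts) {
  counts <- as.matrix(counts)
  full <- rowSums(counts > 0) == ncol(counts)
  if (any(full)) {
    ref <- exp(rowMeans(log(counts[full, , drop = FALSE])))
    sf <- apply(counts[full, , drop = FALSE], 2,
                function(cn) median(cn / ref))
  } else {
    ls <- colSums(counts)
    if (all(ls == 0)) return(rep(1, ncol(counts)))
    sf <- ls / mean(ls[ls > 0])
    sf[sf == 0] <- min(sf[sf > 0])
  }
  sf / exp(mean(log(sf)))
}

#' Zero-inflated log-normal fold change between treatment arms
#'
#' Model: a count is zero with probability `pi` (shared across arms,
#' estimated from the pooled zero fraction) or log-normal with an
#' arm-specific mean. The log2 fold change is the difference of arm means
#' of `log2(normalized count + pseudocount)` over non-zero observations,
#' weighted by `1 - pi`; the p-value comes from a pooled-variance
#' two-sample t statistic on those log2 values, each arm represented by
#' its non-zero observations when it has any (an all-zero arm enters at
#' the pseudocount, i.e. with mean log2(pseudocount) and zero variance);
#' q-values are Benjamini-Hochberg across entities.
#' Entities with all-zero counts in both arms are untestable and receive
#' no call.
#'
#' @param counts_18O,counts_16O matrices (entities x replicates) or
#'   vectors (single entity) of raw counts; >= 2 replicates per arm.
#' @param norm_18O,norm_16O per-replicate size factors (default 1).
#' @param pseudocount added to normalized counts before log2.
#' @param alpha FDR level for the `active` call.
#' @return data.frame: `entity`, `log2_fold_change`, `p_value`,
#'   `q_value`, `zero_inflation`, `testable`, `active`.
#' @export
ziln_fold_change <- function(counts_18O, counts_16O, norm_18O = NULL,
                             norm_16O = NULL, pseudocount = 0.5,
                             alpha = 0.05) {
  a <- if (is.matrix(counts_18O)) counts_18O else
    matrix(counts_18O, nrow = 1)
  b <- if (is.matrix(counts_16O)) counts_16O else
    matrix(counts_16O, nrow = 1)
  stopifnot(nrow(a) == nrow(b), ncol(a) >= 2, ncol(b) >= 2)
  if (is.null(norm_18O)) norm_18O <- rep(1, ncol(a))
  if (is.null(norm_16O)) norm_16O <- rep(1, ncol(b))
  na <- sweep(a, 2, norm_18O, "/")
  nb <- sweep(b, 2, norm_16O, "/")
  ya <- log2(na + pseudocount)
  yb <- log2(nb + pseudocount)
  n1 <- ncol(a); n2 <- ncol(b)
  # pooled-variance two-sample t on the log-normal (non-zero) component;
  # when an arm has fewer than two non-zero observations the test falls
  # back to the pseudocounted values of all replicates
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    ss <- function(v) if (length(v) > 1) (length(v) - 1) * stats::var(v)
          else 0
    sp2 <- (ss(x) + ss(y)) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    d <- mean(x) - mean(y)
    if (se2 > 0) {
      tt <- d / sqrt(se2)
      2 * pt(-abs(tt), nx + ny - 2)
    } else if (d == 0) 1 else 0
  }
  p <- vapply(seq_len(nrow(a)), function(i) {
    nz1 <- a[i, ] > 0
    nz2 <- b[i, ] > 0
    x <- if (any(nz1)) ya[i, nz1] else ya[i, ]
    y <- if (any(nz2)) yb[i, nz2] else yb[i, ]
    if (length(x) + length(y) >= 3) pooled_t(x, y)
    else pooled_t(ya[i, ], yb[i, ])
  }, 0)
  pi_hat <- (rowSums(a == 0) + rowSums(b == 0)) / (n1 + n2)
  mean_nz <- function(y, cnt) {
    vapply(seq_len(nrow(y)), function(i) {
      nz <- cnt[i, ] > 0
      if (any(nz)) mean(y[i, nz]) else log2(pseudocount)
    }, 0)
  }
  lfc <- (1 - pi_hat) * (mean_nz(ya, a) - mean_nz(yb, b))
  testable <- rowSums(a) + rowSums(b) > 0
  p[!testable] <- NA
  lfc[!testable] <- NA
  q <- rep(NA_real_, length(p))
  q[testable] <- p.adjust(p[testable], method = "BH")
  entity <- rownames(a)
  if (is.null(entity)) entity <- sprintf("entity_%d", seq_len(nrow(a)))
  data.frame(entity = entity, log2_fold_change = lfc, p_value = p,
             q_value = q, zero_inflation = pi_hat, testable = testable,
             active = !is.na(q) & q < alpha & lfc > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' MAG read-count matrix from coverage records
#'
#' @param coverage coverage records with `n_reads`.
#' @return matrix entities x samples of assigned read counts.
#' @export
count_matrix <- function(coverage) {
  ents <- sort(unique(coverage$entity))
  samps <- unique(coverage$sample)
  m <- matrix(0L, length(ents), length(samps),
              dimnames = list(ents, samps))
  m[cbind(match(coverage$entity, ents),
          match(coverage$sample, samps))] <- coverage$n_reads
  m
}

#' Fold-change activity calls per timepoint and fraction
#'
#' Within every (timepoint, density bin) stratum, 18O and 16O replicate
#' counts are normalized by median-of-ratios factors and tested with
#' [ziln_fold_change()]; a MAG is active at a timepoint when it is
#' significant (q < `alpha`) with positive log2 fold change in at least
#' one sequenced bin.
#'
#' @param counts matrix entities x samples (see [count_matrix()]).
#' @param sheet sample sheet.
#' @param alpha FDR level.
#' @return list: `results` (per entity x timepoint x bin
#'   fold-change table), `calls` (per entity x timepoint activity calls).
#' @export
foldchange_activity <- function(counts, sheet, alpha = 0.05) {
  results <- list()
  for (tpt in sort(unique(sheet$timepoint))) {
    for (bn in unique(sheet$bin)) {
      ids18 <- sheet$sample_id[sheet$treatment == "18O" &
                                 sheet$timepoint == tpt & sheet$bin == bn]
      ids16 <- sheet$sample_id[sheet$treatment == "16O" &
                                 sheet$timepoint == tpt & sheet$bin == bn]
      if (length(ids18) < 2 || length(ids16) < 2) next
      sub <- counts[, c(ids18, ids16), drop = FALSE]
      sf <- mor_norm_factors(sub)
      res <- ziln_fold_change(
        counts[, ids18, drop = FALSE], counts[, ids16, drop = FALSE],
        norm_18O = sf[seq_along(ids18)],
        norm_16O = sf[length(ids18) + seq_along(ids16)],
        alpha = alpha)
      res$timepoint <- tpt
      res$bin <- bn
      results[[paste(tpt, bn)]] <- res
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  calls <- stats::aggregate(active ~ entity + timepoint,
                            data = results, FUN = any, na.rm = TRUE)
  calls$kind <- "MAG"
  calls$method <- "fold_change"
  list(results = results,
       calls = calls[c("entity", "kind", "timepoint", "method", "active")])
}
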