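# End-to-end driver: community -> gradient/read simulation -> vOTUs ->
# coverage -> activity calls -> linkage -> cross-tabulation, plus scoring
# of every stage against the generator's ground truth.

#' Run the full SIP inference pipeline on a synthetic community
#'
#' Generates a community, simulates the sequencing experiment, builds
#' vOTUs from the mock contig pool, computes coverage against vOTUs and
#' MAGs, calls activity by all three methods, links viruses to hosts and
#' builds the activity-by-linkage cross-tabulation.
#'
#' @param config a [community_config()].
#' @param seed master seed; internal stages use fixed offsets of it.
#' @param depth reads per fraction sample.
#' @param read_len read length, bp.
#' @param error_rate per-base substitution rate.
#' @param atom_excess 18O atom fraction excess of the labeled arm (set 0
#'   for a no-label null experiment).
#' @param scheme,model gradient model.
#' @param detect_mode viral detection mode, see [mock_detect_viral()].
#' @return list with all intermediate products (`truth`, `sim`, `votus`,
#'   `votu_coverage`, `mag_coverage`, `votu_activity`, `mag_subtraction`,
#'   `mag_foldchange`, `linkage`, `crosstab`, ...).
#' @export
run_sip_pipeline <- function(config = community_config(), seed = 1L,
                             depth = 2000L, read_len = 300L,
                             error_rate = 0.005, atom_excess = 0.97,
                             scheme = fraction_scheme(),
                             model = density_model(),
                             detect_mode = "truth") {
  truth <- assemble_community(config, seed)
  sim <- simulate_experiment(truth, scheme, model, depth = depth,
                             read_len = read_len, error_rate = error_rate,
                             atom_excess = atom_excess, seed = seed + 1L)
  contigs <- community_contigs(truth, seed = seed + 2L)
  contigs <- mock_detect_viral(contigs, mode = detect_mode)
  votus <- cluster_votus(filter_candidates(contigs))
  mags <- community_sequences(truth, "hosts")

  votu_cov <- coverage_table(sim$samples, votus$rep_seqs)
  mag_cov <- coverage_table(sim$samples, mags)

  # presence for the activity rule is evaluated on replicate-pooled reads
  pooled <- pool_replicates(sim$samples, sim$sheet)
  votu_cov_pooled <- coverage_table(pooled$samples, votus$rep_seqs)

  tp <- truth$config$timepoints
  votu_act <- do.call(rbind, lapply(tp, function(t) {
    call_votu_activity(votu_cov_pooled, pooled$sheet, t)
  }))

  unlabeled_ref <- build_unlabeled_reference(sim$samples, sim$sheet, mags)
  mag_sub <- do.call(rbind, lapply(tp, function(t) {
    subtraction_activity(sim$samples, sim$sheet, mags, unlabeled_ref, t)
  }))
  mag_fc <- foldchange_activity(count_matrix(mag_cov), sim$sheet)

  linkage <- link_virus_host(votus$rep_seqs, mags)

  votu_active <- tapply(votu_act$active, votu_act$entity, any)
  sub_active <- tapply(mag_sub$active, mag_sub$entity, any)
  fc_active <- tapply(mag_fc$calls$active, mag_fc$calls$entity, any)
  mag_active <- setNames(
    as.logical(sub_active[names(mags)]) |
      as.logical(fc_active[names(mags)]),
    names(mags))
  mag_active[is.na(mag_active)] <- FALSE
  crosstab <- build_crosstab(linkage$links,
                             setNames(as.logical(votu_active),
                                      names(votu_active)),
                             mag_active)

  list(truth = truth, sim = sim, contigs = contigs, votus = votus,
       votu_coverage = votu_cov, votu_coverage_pooled = votu_cov_pooled,
       mag_coverage = mag_cov,
       votu_activity = votu_act, unlabeled_reference = unlabeled_ref,
       mag_subtraction = mag_sub, mag_foldchange = mag_fc,
       linkage = linkage, crosstab = crosstab,
       votu_active = votu_active, mag_active = mag_active)
}

#' Map vOTUs to their source viruses
#'
#' Synthetic contig ids encode the source genome
#' (`ctg_<entity>_<piece>`), so each vOTU's representative traces back to
#' a single ground-truth virus.
#'
#' @param votus the result of [cluster_votus()] (or its `votus` table).
#' @return named character: vOTU id -> virus id.
#' @export
votu_truth_map <- function(votus) {
  if (is.null(votus$representative) && !is.null(votus$votus)) {
    votus <- votus$votus
  }
  setNames(sub("^ctg_(.*)_(full|dup|f\\d+)$", "\\1",
               votus$representative), votus$votu_id)
}

#' Score pipeline calls against ground truth
#'
#' Computes precision/recall of active-vOTU calls (against cumulative
#' labeling truth, with a detectability floor on the recall denominator),
#' recall of active-MAG calls by both methods, precision/recall of
#' planted virus-host pairs, and temperate-classification recall.
#' Counts (TP/FP/FN) are returned so results can be pooled over seeds.
#'
#' @param res result of [run_sip_pipeline()].
#' @param min_frac labeled-fraction threshold for truth-side labeling.
#' @param min_abundance detectability floor for recall denominators.
#' @return named list of counts and derived rates.
#' @export
score_recovery <- function(res, min_frac = 0.25, min_abundance = 0.005) {
  truth <- res$truth
  tp_days <- truth$config$timepoints
  v2virus <- votu_truth_map(res$votus)
  host_ids <- names(truth$hosts)
  virus_ids <- names(truth$viruses)

  votu_tp <- votu_fp <- votu_fn <- 0L
  for (t in tp_days) {
    labeled <- intersect(truth_labeled(truth, t, min_frac), virus_ids)
    detectable <- intersect(
      truth_labeled(truth, t, min_frac, min_abundance, detectable = TRUE),
      virus_ids)
    act <- res$votu_activity
    called <- unique(v2virus[act$entity[act$timepoint == t & act$active]])
    votu_tp <- votu_tp + length(intersect(called, labeled))
    votu_fp <- votu_fp + length(setdiff(called, labeled))
    votu_fn <- votu_fn + length(setdiff(detectable, called))
  }

  active_hosts <- host_ids[vapply(truth$hosts,
                                  function(h) any(h$active), TRUE)]
  sub_tp <- sub_fn <- fc_tp <- fc_fn <- 0L
  for (t in tp_days) {
    truly <- host_ids[vapply(truth$hosts, function(h) {
      h$active[paste0("t", t)]
    }, TRUE)]
    ms <- res$mag_subtraction
    called_sub <- ms$entity[ms$timepoint == t & ms$active]
    sub_tp <- sub_tp + length(intersect(truly, called_sub))
    sub_fn <- sub_fn + length(setdiff(truly, called_sub))
    mf <- res$mag_foldchange$calls
    called_fc <- mf$entity[mf$timepoint == t & mf$active]
    fc_tp <- fc_tp + length(intersect(truly, called_fc))
    fc_fn <- fc_fn + length(setdiff(truly, called_fc))
  }

  links <- res$linkage$links
  pred_pairs <- unique(data.frame(
    virus = unname(v2virus[links$votu]), host = links$mag,
    stringsAsFactors = FALSE))
  truth_pairs <- unique(truth$linkage[c("virus", "host")])
  key <- function(df) paste(df$virus, df$host)
  pair_tp <- length(intersect(key(pred_pairs), key(truth_pairs)))
  pair_fp <- nrow(pred_pairs) - pair_tp
  pair_fn <- nrow(truth_pairs) - pair_tp

  temp_truth <- virus_ids[vapply(truth$viruses, function(v) {
    v$lifestyle == "temperate"
  }, TRUE)]
  temp_called <- unique(v2virus[
    res$linkage$temperate$votu[res$linkage$temperate$temperate]])
  temp_tp <- length(intersect(temp_called, temp_truth))
  temp_fn <- length(setdiff(temp_truth, temp_called))
  temp_fp <- length(setdiff(temp_called, temp_truth))

  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    votu_tp = votu_tp, votu_fp = votu_fp, votu_fn = votu_fn,
    votu_precision = rate(votu_tp, votu_tp + votu_fp),
    votu_recall = rate(votu_tp, votu_tp + votu_fn),
    sub_tp = sub_tp, sub_fn = sub_fn,
    mag_recall_subtraction = rate(sub_tp, sub_tp + sub_fn),
    fc_tp = fc_tp, fc_fn = fc_fn,
    mag_recall_foldchange = rate(fc_tp, fc_tp + fc_fn),
    pair_tp = pair_tp, pair_fp = pair_fp, pair_fn = pair_fn,
    pair_precision = rate(pair_tp, pair_tp + pair_fp),
    pair_recall = rate(pair_tp, pair_tp + pair_fn),
    temp_tp = temp_tp, temp_fp = temp_fp, temp_fn = temp_fn,
    temperate_recall = rate(temp_tp, temp_tp + temp_fn),
    n_active_hosts = length(active_hosts))
}

#' Pool recovery scores over several seeds
#'
#' Runs [run_sip_pipeline()] + [score_recovery()] per seed and pools the
#' TP/FP/FN counts before computing rates.
#'
#' @param seeds integer vector of master seeds.
#' @param config,... passed to [run_sip_pipeline()].
#' @return named list of pooled rates and counts.
#' @export
pooled_recovery <- function(seeds, config = community_config(), ...) {
  scores <- lapply(seeds, function(s) {
    score_recovery(run_sip_pipeline(config, seed = s, ...))
  })
  pool <- function(f) sum(vapply(scores, `[[`, 0, f))
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    votu_precision = rate(pool("votu_tp"),
                          pool("votu_tp") + pool("votu_fp")),
    votu_recall = rate(pool("votu_tp"), pool("votu_tp") + pool("votu_fn")),
    mag_recall_subtraction = rate(pool("sub_tp"),
                                  pool("sub_tp") + pool("sub_fn")),
    mag_recall_foldchange = rate(pool("fc_tp"),
                                 pool("fc_tp") + pool("fc_fn")),
    pair_precision = rate(pool("pair_tp"),
                          pool("pair_tp") + pool("pair_fp")),
    pair_recall = rate(pool("pair_tp"), pool("pair_tp") + pool("pair_fn")),
    temperate_recall = rate(pool("temp_tp"),
                            pool("temp_tp") + pool("temp_fn")),
    n_seeds = length(seeds))
  out$per_seed <- scores
  out
}

#' Mean normalized vOTU abundance in the labeled arm
#'
#' @param coverage vOTU coverage records.
#' @param sheet sample sheet.
#' @param timepoint timepoint.
#' @return named numeric per vOTU (mean over 18O fraction samples).
#' @export
votu_abundance_18O <- function(coverage, sheet, timepoint) {
  ids <- sheet$sample_id[sheet$treatment == "18O" &
                           sheet$timepoint == timepoint]
  cv <- coverage[coverage$sample %in% ids, , drop = FALSE]
  tapply(cv$normalized_abundance, cv$entity, mean)
}

#' Per-phylum virus:host abundance points
#'
#' One point per (phylum, timepoint, treatment): the summed normalized
#' abundance of the linked MAGs of that phylum over the timepoint's
#' fraction samples, paired with the summed abundance of the vOTUs linked
#' to them. Only linked entities enter (the regression assumes the virus
#' abundance relies on the host, so it is evaluated on virus-host pairs
#' the linkage evidence supports). Summing over the density fractions of
#' a timepoint removes the banding artifact that a genome and its virions
#' sit at different densities within any single fraction.
#'
#' @param res result of [run_sip_pipeline()].
#' @return data.frame: `phylum`, `timepoint`, `treatment`,
#'   `host_abundance`, `virus_abundance`.
#' @export
virus_host_points <- function(res) {
  links <- res$linkage$links
  empty <- data.frame(phylum = character(), timepoint = integer(),
                      treatment = character(),
                      host_abundance = numeric(),
                      virus_abundance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(links) == 0L) return(empty)
  phylum <- vapply(res$truth$hosts, `[[`, "", "phylum")
  linked_mags <- unique(links$mag)
  sheet <- res$sim$sheet
  out <- list()
  for (tpt in sort(unique(sheet$timepoint))) {
    for (trt in unique(sheet$treatment)) {
      ids <- sheet$sample_id[sheet$timepoint == tpt &
                               sheet$treatment == trt]
      mc <- res$mag_coverage[res$mag_coverage$sample %in% ids, ,
                             drop = FALSE]
      vc <- res$votu_coverage[res$votu_coverage$sample %in% ids, ,
                              drop = FALSE]
      for (ph in unique(phylum[linked_mags])) {
        mags_ph <- intersect(linked_mags, names(phylum)[phylum == ph])
        votus_ph <- unique(links$votu[links$mag %in% mags_ph])
        out[[length(out) + 1L]] <- data.frame(
          phylum = ph, timepoint = tpt, treatment = trt,
          host_abundance = sum(mc$normalized_abundance[
            mc$entity %in% mags_ph]),
          virus_abundance = sum(vc$normalized_abundance[
            vc$entity %in% votus_ph]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
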