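# Ground-truth community generator: host genomes with CRISPR arrays and
# integrated proviruses, free viral genomes with lifestyle and marker genes,
# and per-timepoint abundance / growth / labeling truth. Coordinates are
# 0-based half-open on the (+) strand throughout.

#' Default phylum profiles for the host community
#'
#' Stylized phylum-level G+C means and activity weights for a sub-freezing
#' anoxic peat community: the fermentative, psychrotolerant lineages that
#' dominate activity under winter conditions (Firmicutes, Bacteroidota,
#' Acidobacteriota) are low-GC, while the detected-but-dormant background
#' (Chloroflexota, Myxococcota, Actinomycetota) is high-GC. The
#' `active_weight` column is the relative probability that an active host
#' is drawn from that phylum.
#'
#' @return data.frame with columns `phylum`, `gc_mean`, `gc_sd`,
#'   `active_weight`, `weight`.
#' @export
default_phyla <- function() {
  data.frame(
    phylum = c("Firmicutes", "Bacteroidota", "Acidobacteriota",
               "Verrucomicrobiota", "Chloroflexota", "Actinomycetota"),
    gc_mean = c(0.38, 0.41, 0.48, 0.55, 0.58, 0.64),
    gc_sd = 0.02,
    active_weight = c(0.4, 0.35, 0.25, 0, 0, 0),
    weight = c(0.15, 0.15, 0.2, 0.15, 0.2, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Community generator configuration
#'
#' Collects the study-design parameters of the synthetic community: counts,
#' genome sizes, activity structure, growth, abundance and linkage plan.
#' Defaults are the package's desk-scale rendering of the study design
#' (two treatments, 184/370 d timepoints, three replicates); see the
#' methods vignette for the reasoning behind each default.
#'
#' @param n_hosts,n_viruses community sizes.
#' @param host_length,virus_length genome length ranges in bp.
#' @param virus_gc viral G+C range (uniform draw).
#' @param host_active_fraction fraction of hosts growing throughout the
#'   incubation.
#' @param virus_pattern probabilities of the four viral activity patterns
#'   across the two timepoints (`both`, `t2_only`, `t1_only`, `none`).
#' @param growth_active multiplicative abundance change over the first
#'   active interval (uniform range, > 1).
#' @param growth_saturated second-interval multiplier for entities active
#'   in both intervals (growth saturates as resources are drawn down; a
#'   population cannot compound its initial expansion for a full year).
#' @param growth_inactive per-interval multiplier for inactive entities
#'   (uniform range, <= 1; persistence as relic/environmental DNA).
#' @param lost_decay second-interval multiplier for viruses active only in
#'   the first interval (virion pools degrade once production stops).
#' @param viral_dna_fraction fraction of baseline community DNA held by
#'   viruses collectively.
#' @param marker_divergence per-copy divergence of planted marker genes,
#'   see [generate_viral_genome()].
#' @param abundance_sdlog lognormal spread of per-entity baseline abundance.
#' @param temperate_fraction fraction of viruses capable of lysogeny.
#' @param n_proviruses number of temperate viruses with an integrated copy;
#'   default 80% of the temperate viruses.
#' @param amg_fraction fraction of viruses carrying the auxiliary metabolic
#'   gene marker.
#' @param hosts_per_virus range of true hosts per virus.
#' @param active_host_preference probability that an active virus's host is
#'   drawn from the active hosts (kill-the-winner coupling).
#' @param spacers_per_pair,spacer_len,repeat_len,spacer_mismatches CRISPR
#'   array plan: every true virus-host pair is recorded in the host's
#'   CRISPR memory with this many spacers.
#' @param timepoints sampling days.
#' @param phyla phylum profile table, see [default_phyla()].
#' @return A list of class `community_config`.
#' @export
community_config <- function(n_hosts = 20L, n_viruses = 40L,
                             host_length = c(5e4, 1e5),
                             virus_length = c(1e4, 1.3e4),
                             virus_gc = c(0.35, 0.50),
                             host_active_fraction = 0.3,
                             virus_pattern = c(both = 0.25, t2_only = 0.2,
                                               t1_only = 0.1, none = 0.45),
                             growth_active = c(3, 6),
                             growth_saturated = c(1.2, 2),
                             growth_inactive = c(0.85, 1),
                             lost_decay = 0.1,
                             viral_dna_fraction = 0.7,
                             marker_divergence = 0.2,
                             abundance_sdlog = 0.25,
                             temperate_fraction = 0.43,
                             n_proviruses = NULL,
                             amg_fraction = 0.2,
                             hosts_per_virus = c(1L, 2L),
                             active_host_preference = 0.8,
                             spacers_per_pair = 3L,
                             spacer_len = 32L,
                             repeat_len = 28L,
                             spacer_mismatches = 0L,
                             timepoints = c(184L, 370L),
                             phyla = default_phyla()) {
  cfg <- as.list(environment())
  stopifnot(n_hosts >= 1, n_viruses >= 1,
            all(virus_pattern >= 0), length(timepoints) == 2L)
  cfg$virus_pattern <- virus_pattern / sum(virus_pattern)
  n_temperate <- round(temperate_fraction * n_viruses)
  if (is.null(n_proviruses)) n_proviruses <- round(0.8 * n_temperate)
  if (n_proviruses > n_temperate) {
    stop("infeasible linkage plan: more proviruses (", n_proviruses,
         ") than temperate viruses (", n_temperate, ")")
  }
  cfg$n_temperate <- n_temperate
  cfg$n_proviruses <- n_proviruses
  class(cfg) <- "community_config"
  cfg
}

#' Generate a host genome
#'
#' Bases are i.i.d. with per-base G+C probability `gc_target`; the realized
#' G+C fraction is recorded on the object.
#'
#' @param length genome length in bp (20 kb to 5 Mb).
#' @param gc_target target G+C fraction in `[0.2, 0.8]`.
#' @param id genome identifier.
#' @param phylum phylum label.
#' @param seed optional seed applied locally (caller RNG is restored).
#' @return A `host_genome` list: `id`, `sequence`, `length`, `gc`,
#'   `phylum`, `active`, `growth_factor`, `crispr_arrays`, `provirus_loci`.
#' @export
generate_host_genome <- function(length, gc_target, id = "host_1",
                                 phylum = NA_character_, seed = NULL) {
  if (length < 2e4 || length > 5e6) {
    stop("host genome length must be in [20,000, 5,000,000] bp")
  }
  if (gc_target < 0.2 || gc_target > 0.8) {
    stop("gc_target must be in [0.2, 0.8]")
  }
  with_local_seed(seed, {
    seq <- random_dna(length, gc_target)
    structure(list(
      id = id, sequence = seq, length = length,
      gc = gc_content(seq), phylum = phylum,
      active = c(FALSE, FALSE), growth_factor = c(1, 1),
      crispr_arrays = empty_array_df(), provirus_loci = empty_provirus_df()
    ), class = "host_genome")
  })
}

#' @noRd
empty_array_df <- function() {
  data.frame(array_id = character(), virus = character(),
             start = integer(), end = integer(),
             repeat_len = integer(), n_spacers = integer(),
             stringsAsFactors = FALSE)
}

#' @noRd
empty_provirus_df <- function() {
  data.frame(virus = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Generate a viral genome
#'
#' @param length genome length in bp (>= 10 kb by default so the genome
#'   survives the vOTU length filter).
#' @param gc_target target G+C fraction.
#' @param id identifier.
#' @param lifestyle `"virulent"` or `"temperate"`; temperate genomes carry
#'   a lysogeny marker (integrase or parA analogue).
#' @param amg whether to plant the auxiliary metabolic gene marker.
#' @param marker_divergence substitution fraction applied to each planted
#'   marker copy, so marker instances behave like members of a gene
#'   family rather than identical repeats (identical copies across
#'   genomes would read as shared genomic content between unrelated
#'   virus-host pairs).
#' @param seed optional local seed.
#' @return A `viral_genome` list with marker coordinates and truth fields.
#' @export
generate_viral_genome <- function(length, gc_target, id = "virus_1",
                                  lifestyle = c("virulent", "temperate"),
                                  amg = FALSE, marker_divergence = 0.2,
                                  seed = NULL) {
  lifestyle <- match.arg(lifestyle)
  stopifnot(length >= 1000, gc_target >= 0.2, gc_target <= 0.8)
  with_local_seed(seed, {
    seq <- random_dna(length, gc_target)
    cat_df <- marker_catalog()
    markers <- data.frame(marker = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
    plan <- c(sample(cat_df$name[cat_df$role == "hallmark"], 1L),
              if (lifestyle == "temperate")
                sample(cat_df$name[cat_df$role == "lysogeny"], 1L),
              if (amg) cat_df$name[cat_df$role == "amg"])
    # markers occupy disjoint windows spaced across the genome
    slot <- floor(length / (length(plan) + 1))
    for (i in seq_along(plan)) {
      mseq <- cat_df$sequence[cat_df$name == plan[i]]
      mseq <- mutate_sequence(mseq,
                              round(marker_divergence * nchar(mseq)))
      locus <- (i - 1L) * slot +
        sample.int(max(1L, slot - nchar(mseq) - 1L), 1L)
      pl <- plant_marker(seq, mseq, locus)
      seq <- pl$sequence
      markers <- rbind(markers, data.frame(
        marker = plan[i], start = pl$start, end = pl$end,
        stringsAsFactors = FALSE))
    }
    structure(list(
      id = id, sequence = seq, length = length,
      gc = gc_content(seq), lifestyle = lifestyle,
      integrated_in = NA_character_, marker_genes = markers,
      true_hosts = character(), active = c(FALSE, FALSE)
    ), class = "viral_genome")
  })
}

# Insert a segment into a host genome at a 0-based locus, shifting all
# recorded feature coordinates downstream of the insertion point.
#' @noRd
host_insert <- function(host, segment, locus) {
  n <- nchar(segment)
  host$sequence <- insert_segment(host$sequence, segment, locus)
  host$length <- nchar(host$sequence)
  host$crispr_arrays <- shift_intervals(host$crispr_arrays, locus, n)
  host$provirus_loci <- shift_intervals(host$provirus_loci, locus, n)
  host
}

# A random insertion locus in the host avoiding recorded features.
#' @noRd
free_locus <- function(host, margin = 1000L) {
  occupied <- rbind(
    host$crispr_arrays[c("start", "end")],
    host$provirus_loci[c("start", "end")]
  )
  for (i in 1:50) {
    locus <- sample.int(host$length - 2L * margin, 1L) + margin
    if (nrow(occupied) == 0L ||
        !any(locus > occupied$start - margin &
             locus < occupied$end + margin)) {
      return(locus)
    }
  }
  stop("could not place a feature in host ", host$id)
}

#' Plant a CRISPR array in a host genome
#'
#' Writes a `repeat-spacer-...-repeat` array whose spacers are substrings
#' of the virus genome (optionally mutated by a stated number of
#' substitutions), records provenance in the host truth, and shifts
#' existing feature coordinates. An array of `n_spacers` spacers has
#' `n_spacers + 1` repeat copies.
#'
#' @param host a `host_genome`.
#' @param virus a `viral_genome` providing the protospacers.
#' @param n_spacers number of spacers (>= 2).
#' @param repeat_len repeat length (19-47 bp, the detector-supported range).
#' @param spacer_len spacer length (17-50 bp).
#' @param mismatches substitutions applied to each planted spacer.
#' @param locus 0-based insertion point; random free locus by default.
#' @return The updated `host_genome`; the planted array row carries a
#'   `spacers` provenance table (virus coordinates and mismatch count).
#' @export
plant_crispr_array <- function(host, virus, n_spacers = 3L, repeat_len = 28L,
                               spacer_len = 32L, mismatches = 0L,
                               locus = NULL) {
  if (n_spacers < 2L) stop("n_spacers must be >= 2")
  if (repeat_len < 19L || repeat_len > 47L) {
    stop("repeat_len outside detector-supported range [19, 47]")
  }
  if (spacer_len < 17L || spacer_len > 50L) {
    stop("spacer_len outside detector-supported range [17, 50]")
  }
  if (virus$length < spacer_len) stop("virus shorter than spacer_len")
  if (is.null(locus)) locus <- free_locus(host)
  rep_seq <- random_dna(repeat_len, 0.5)
  src_start <- sample.int(virus$length - spacer_len + 1L, n_spacers) - 1L
  spacers <- substring(virus$sequence, src_start + 1L,
                       src_start + spacer_len)
  spacers <- vapply(spacers, mutate_sequence, "", n_sub = mismatches,
                    USE.NAMES = FALSE)
  array_seq <- paste0(rep_seq,
                      paste0(spacers, rep_seq, collapse = ""))
  host <- host_insert(host, array_seq, locus)
  array_id <- sprintf("%s_array%d", host$id,
                      nrow(host$crispr_arrays) + 1L)
  row <- data.frame(array_id = array_id, virus = virus$id,
                    start = locus, end = locus + nchar(array_seq),
                    repeat_len = repeat_len, n_spacers = n_spacers,
                    stringsAsFactors = FALSE)
  row$spacers <- list(data.frame(
    sequence = spacers, virus_start = src_start,
    virus_end = src_start + spacer_len, mismatches = mismatches,
    stringsAsFactors = FALSE))
  host$crispr_arrays <- if (nrow(host$crispr_arrays)) {
    rbind(host$crispr_arrays, row)
  } else {
    row
  }
  host
}

#' Integrate a provirus into a host genome
#'
#' Inserts the full viral sequence at `locus` and records the interval in
#' the host truth. The caller is responsible for marking the virus
#' temperate / integrated (see [assemble_community()], which keeps both
#' sides of the truth in sync).
#'
#' @param host a `host_genome`.
#' @param virus a `viral_genome` not already integrated in this host.
#' @param locus 0-based insertion point; random free locus by default.
#' @return The updated `host_genome`.
#' @export
integrate_provirus <- function(host, virus, locus = NULL) {
  if (virus$id %in% host$provirus_loci$virus) {
    stop("virus ", virus$id, " is already integrated in host ", host$id)
  }
  if (is.null(locus)) locus <- free_locus(host)
  if (locus < 0 || locus > host$length) stop("locus out of bounds")
  host <- host_insert(host, virus$sequence, locus)
  host$provirus_loci <- rbind(host$provirus_loci, data.frame(
    virus = virus$id, start = locus, end = locus + virus$length,
    stringsAsFactors = FALSE))
  host
}

#' Assemble the full synthetic community
#'
#' Draws host and viral genomes, assigns activity patterns and growth,
#' executes the linkage plan (CRISPR memory for every true virus-host
#' pair, provirus integration for the planned temperate viruses), and
#' computes per-timepoint relative abundances and cumulative labeled-DNA
#' fractions. Reproducible bit-for-bit from `(config, seed)`.
#'
#' Labeling truth is cumulative: heavy water is present for the entire
#' incubation, so the labeled fraction of an entity's DNA at a timepoint is
#' `1 - 1/g` where `g` is its cumulative growth since the start.
#'
#' @param config a [community_config()].
#' @param seed integer seed.
#' @return A `sip_community` list: `hosts`, `viruses`, `abundance`
#'   (entity x timepoint), `frac_new`, `linkage` (planted virus-host
#'   facts), `config`, `seed`.
#' @export
assemble_community <- function(config = community_config(), seed = 1L) {
  stopifnot(inherits(config, "community_config"))
  set.seed(seed)
  tp <- config$timepoints
  ph <- config$phyla

  ## hosts: phylum, activity, gc, genome -------------------------------
  n_active <- round(config$host_active_fraction * config$n_hosts)
  host_ids <- sprintf("MAG_%03d", seq_len(config$n_hosts))
  active_host <- rep(FALSE, config$n_hosts)
  active_host[seq_len(n_active)] <- TRUE
  phylum <- character(config$n_hosts)
  phylum[active_host] <- sample(ph$phylum, n_active, replace = TRUE,
                                prob = ph$active_weight)
  phylum[!active_host] <- sample(ph$phylum, config$n_hosts - n_active,
                                 replace = TRUE, prob = ph$weight)
  hosts <- vector("list", config$n_hosts)
  for (i in seq_len(config$n_hosts)) {
    gc <- min(0.8, max(0.2, rnorm(1, ph$gc_mean[ph$phylum == phylum[i]],
                                  ph$gc_sd[1])))
    len <- round(runif(1, config$host_length[1], config$host_length[2]))
    h <- generate_host_genome(len, gc, id = host_ids[i],
                              phylum = phylum[i])
    h$active <- setNames(rep(active_host[i], 2L), paste0("t", tp))
    g <- if (active_host[i]) {
      c(runif(1, config$growth_active[1], config$growth_active[2]),
        runif(1, config$growth_saturated[1], config$growth_saturated[2]))
    } else {
      runif(2, config$growth_inactive[1], config$growth_inactive[2])
    }
    h$growth_factor <- setNames(g, paste0("t", tp))
    hosts[[i]] <- h
  }
  names(hosts) <- host_ids

  ## viruses: pattern, lifestyle, genome --------------------------------
  virus_ids <- sprintf("vir_%03d", seq_len(config$n_viruses))
  # pattern cohort sizes are part of the study design (fixed counts, like
  # the host active fraction); only the assignment is randomized
  n_pat <- round(config$virus_pattern * config$n_viruses)
  n_pat[which.max(n_pat)] <- n_pat[which.max(n_pat)] +
    config$n_viruses - sum(n_pat)
  patterns <- sample(rep(names(n_pat), n_pat))
  temperate <- rep(FALSE, config$n_viruses)
  temperate[sample.int(config$n_viruses, config$n_temperate)] <- TRUE
  amg <- runif(config$n_viruses) < config$amg_fraction
  viruses <- vector("list", config$n_viruses)
  for (i in seq_len(config$n_viruses)) {
    len <- round(runif(1, config$virus_length[1], config$virus_length[2]))
    gc <- runif(1, config$virus_gc[1], config$virus_gc[2])
    v <- generate_viral_genome(
      len, gc, id = virus_ids[i],
      lifestyle = if (temperate[i]) "temperate" else "virulent",
      amg = amg[i], marker_divergence = config$marker_divergence)
    v$active <- setNames(c(patterns[i] %in% c("both", "t1_only"),
                           patterns[i] %in% c("both", "t2_only")),
                         paste0("t", tp))
    v$pattern <- patterns[i]
    viruses[[i]] <- v
  }
  names(viruses) <- virus_ids

  ## linkage plan -------------------------------------------------------
  linkage <- list()
  for (i in seq_len(config$n_viruses)) {
    v <- viruses[[i]]
    k <- sample(seq(config$hosts_per_virus[1], config$hosts_per_virus[2]),
                1L)
    pool_active <- host_ids[active_host]
    pool_inactive <- host_ids[!active_host]
    chosen <- character(0)
    for (j in seq_len(k)) {
      use_active <- v$pattern != "none" &&
        runif(1) < config$active_host_preference &&
        length(setdiff(pool_active, chosen)) > 0
      pool <- if (use_active) setdiff(pool_active, chosen) else
        setdiff(pool_inactive, chosen)
      if (length(pool) == 0) pool <- setdiff(host_ids, chosen)
      chosen <- c(chosen, sample(pool, 1L))
    }
    viruses[[i]]$true_hosts <- chosen
    linkage[[i]] <- data.frame(virus = v$id, host = chosen,
                               crispr = TRUE, provirus = FALSE,
                               stringsAsFactors = FALSE)
  }
  linkage <- do.call(rbind, linkage)

  ## provirus integration (activity-matched: prophages replicate with the
  ## host chromosome, so integration targets a host whose activity matches
  ## the viral population's pattern) -------------------------------------
  temperate_ids <- virus_ids[temperate]
  prov_ids <- sample(temperate_ids, config$n_proviruses)
  for (vid in prov_ids) {
    v <- viruses[[vid]]
    want_active <- v$pattern == "both"
    candidates <- v$true_hosts[active_host[match(v$true_hosts, host_ids)] ==
                                 want_active]
    if (length(candidates) == 0) {
      pool <- host_ids[active_host == want_active]
      if (length(pool) == 0) pool <- host_ids
      candidates <- sample(pool, 1L)
      viruses[[vid]]$true_hosts <- c(v$true_hosts, candidates)
      linkage <- rbind(linkage, data.frame(
        virus = vid, host = candidates, crispr = TRUE, provirus = FALSE,
        stringsAsFactors = FALSE))
    }
    hid <- candidates[1L]
    hosts[[hid]] <- integrate_provirus(hosts[[hid]], viruses[[vid]])
    viruses[[vid]]$integrated_in <- hid
    viruses[[vid]]$lifestyle <- "temperate"
    linkage$provirus[linkage$virus == vid & linkage$host == hid] <- TRUE
  }

  ## CRISPR memory for every true pair ----------------------------------
  for (r in seq_len(nrow(linkage))) {
    hid <- linkage$host[r]
    hosts[[hid]] <- plant_crispr_array(
      hosts[[hid]], viruses[[linkage$virus[r]]],
      n_spacers = config$spacers_per_pair,
      repeat_len = config$repeat_len, spacer_len = config$spacer_len,
      mismatches = config$spacer_mismatches)
  }
  # refresh realized gc after insertions
  for (hid in host_ids) hosts[[hid]]$gc <- gc_content(hosts[[hid]]$sequence)

  ## abundances and labeling truth --------------------------------------
  host_len <- vapply(hosts, `[[`, 0, "length")
  base_host <- host_len * rlnorm(config$n_hosts, 0, config$abundance_sdlog)
  base_host <- base_host / sum(base_host) * (1 - config$viral_dna_fraction)
  base_virus <- rlnorm(config$n_viruses, 0, config$abundance_sdlog)
  base_virus <- base_virus / sum(base_virus) * config$viral_dna_fraction

  # viral growth factors by activity pattern: an active interval draws
  # from growth_active (saturated if growth already happened); a formerly
  # active virus decays (virion pool degradation); otherwise relic decay
  for (i in seq_len(config$n_viruses)) {
    ga <- function() runif(1, config$growth_active[1],
                           config$growth_active[2])
    gs <- function() runif(1, config$growth_saturated[1],
                           config$growth_saturated[2])
    gi <- function() runif(1, config$growth_inactive[1],
                           config$growth_inactive[2])
    g <- switch(viruses[[i]]$pattern,
                both = c(ga(), gs()),
                t2_only = c(gi(), ga()),
                t1_only = c(ga(), config$lost_decay),
                none = c(gi(), gi()))
    viruses[[i]]$growth_factor <- setNames(g, paste0("t", tp))
  }
  m1 <- c(vapply(hosts, function(h) unname(h$growth_factor[1]), 0),
          vapply(viruses, function(v) unname(v$growth_factor[1]), 0))
  m2 <- c(vapply(hosts, function(h) unname(h$growth_factor[2]), 0),
          vapply(viruses, function(v) unname(v$growth_factor[2]), 0))
  base <- c(base_host, base_virus)
  ids <- c(host_ids, virus_ids)
  w1 <- base * m1
  w2 <- base * m1 * m2
  abundance <- rbind(
    data.frame(entity = ids, timepoint = tp[1], abundance = w1 / sum(w1),
               stringsAsFactors = FALSE),
    data.frame(entity = ids, timepoint = tp[2], abundance = w2 / sum(w2),
               stringsAsFactors = FALSE))
  # labeled-DNA fraction: growth adds fully labeled new mass; decay
  # removes labeled and unlabeled DNA proportionally (fraction persists)
  f1 <- ifelse(m1 > 1, 1 - 1 / m1, 0)
  f2 <- ifelse(m2 > 1, (f1 + (m2 - 1)) / m2, f1)
  frac_new <- rbind(
    data.frame(entity = ids, timepoint = tp[1], frac_new = f1,
               stringsAsFactors = FALSE),
    data.frame(entity = ids, timepoint = tp[2], frac_new = f2,
               stringsAsFactors = FALSE))
  rownames(abundance) <- rownames(frac_new) <- NULL

  structure(list(
    hosts = hosts, viruses = viruses, abundance = abundance,
    frac_new = frac_new, linkage = linkage,
    config = config, seed = seed
  ), class = "sip_community")
}

#' @export
print.sip_community <- function(x, ...) {
  cat("Synthetic SIP community (seed ", x$seed, ")\n", sep = "")
  cat("  hosts:   ", length(x$hosts), " (",
      sum(vapply(x$hosts, function(h) h$active[1], TRUE)), " active)\n",
      sep = "")
  n_temp <- sum(vapply(x$viruses, function(v) v$lifestyle == "temperate",
                       TRUE))
  cat("  viruses: ", length(x$viruses), " (", n_temp, " temperate, ",
      sum(x$linkage$provirus), " integrated)\n", sep = "")
  cat("  planted virus-host pairs: ", nrow(x$linkage), "\n", sep = "")
  invisible(x)
}

#' Entity sequences of a community
#' @param truth a `sip_community`.
#' @param what `"hosts"`, `"viruses"` or `"all"`.
#' @return named character vector of genome sequences.
#' @export
community_sequences <- function(truth, what = c("all", "hosts", "viruses")) {
  what <- match.arg(what)
  h <- vapply(truth$hosts, `[[`, "", "sequence")
  v <- vapply(truth$viruses, `[[`, "", "sequence")
  switch(what, hosts = h, viruses = v, all = c(h, v))
}

#' Truth-side labeled entities at a timepoint
#'
#' An entity is labeled when its cumulative new-DNA fraction reaches
#' `min_frac`; `detectable` additionally requires relative abundance at
#' the timepoint of at least `min_abundance` (entities below the floor
#' cannot contribute reads at desk-scale depth and are excluded from
#' recall denominators; see the vignette).
#'
#' @param truth a `sip_community`.
#' @param timepoint one of the configured timepoints.
#' @param min_frac labeled-fraction threshold.
#' @param min_abundance detectability floor (only with
#'   `detectable = TRUE`).
#' @param detectable apply the abundance floor.
#' @return character vector of entity ids.
#' @export
truth_labeled <- function(truth, timepoint, min_frac = 0.25,
                          min_abundance = 0.005, detectable = FALSE) {
  fn <- truth$frac_new[truth$frac_new$timepoint == timepoint, ]
  ids <- fn$entity[fn$frac_new >= min_frac]
  if (detectable) {
    ab <- truth$abundance[truth$abundance$timepoint == timepoint, ]
    ok <- ab$entity[ab$abundance >= min_abundance]
    ids <- intersect(ids, ok)
  }
  ids
}
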