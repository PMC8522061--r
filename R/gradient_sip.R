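# Isotope labeling and CsCl density-gradient model: buoyant density as a
# linear function of G+C, an 18O shift proportional to atom excess and the
# newly synthesized DNA fraction, Gaussian band spreading, binning into the
# five gradient fractions, and per-fraction short-read sampling.

#' Buoyant-density model
#'
#' Linear G+C to density relation plus a maximal fully-labeled 18O shift
#' and a Gaussian band-spreading width. Defaults follow the classical
#' CsCl GC-density relation and quantitative-SIP practice: an unlabeled
#' genome bands at `rho0 + rho_slope * gc`; full 18O labeling at 100 atom%
#' adds `max_shift_18O`.
#'
#' @param rho0 density at GC = 0, g/ml.
#' @param rho_slope density increase per unit GC fraction, g/ml.
#' @param max_shift_18O density shift of fully labeled DNA at 100 atom%,
#'   g/ml.
#' @param band_sigma Gaussian band spread, g/ml.
#' @return list of class `density_model`.
#' @export
density_model <- function(rho0 = 1.660, rho_slope = 0.098,
                          max_shift_18O = 0.036, band_sigma = 0.003) {
  stopifnot(rho0 > 0, rho_slope > 0, max_shift_18O > 0, band_sigma > 0)
  if (rho0 < 1.6 || rho0 + rho_slope > 1.8) {
    stop("unlabeled density for gc in [0,1] must lie within [1.6, 1.8] g/ml")
  }
  structure(list(rho0 = rho0, rho_slope = rho_slope,
                 max_shift_18O = max_shift_18O, band_sigma = band_sigma),
            class = "density_model")
}

#' Density-fraction binning scheme
#'
#' Five density bins; only the two heaviest are sequenced: medium-heavy
#' (MH, 1.717-1.725 g/ml) and heavy (H, 1.725-1.750 g/ml). The three light
#' bins are modelled but discarded, mirroring a SIP design in which only
#' the dense fractions are sequenced.
#'
#' @param edges strictly increasing bin edges (6 values for 5 bins), g/ml.
#' @param labels bin labels.
#' @param sequenced labels of the sequenced bins.
#' @return list of class `fraction_scheme`.
#' @export
fraction_scheme <- function(edges = c(1.660, 1.690, 1.705, 1.717, 1.725,
                                      1.750),
                            labels = c("L1", "L2", "L3", "MH", "H"),
                            sequenced = c("MH", "H")) {
  stopifnot(length(edges) == length(labels) + 1L, all(diff(edges) > 0),
            all(sequenced %in% labels))
  structure(list(edges = edges, labels = labels, sequenced = sequenced),
            class = "fraction_scheme")
}

#' Unlabeled buoyant density of DNA
#' @param gc G+C fraction(s) in `[0, 1]`.
#' @param model a [density_model()].
#' @return density in g/ml.
#' @export
buoyant_density <- function(gc, model = density_model()) {
  if (any(gc < 0 | gc > 1)) stop("gc must be in [0, 1]")
  model$rho0 + model$rho_slope * gc
}

#' Buoyant density of partially 18O-labeled DNA
#'
#' Linear mixing of old and new DNA: the band mean shifts by
#' `max_shift_18O * atom_excess * frac_new_dna`.
#'
#' @param gc G+C fraction(s).
#' @param atom_excess 18O atom fraction excess of the incubation water
#'   (0.97 for 97 atom% heavy water; 0 for natural abundance).
#' @param frac_new_dna fraction of the entity's DNA synthesized during the
#'   labeled incubation.
#' @param model a [density_model()].
#' @return density in g/ml.
#' @export
labeled_density <- function(gc, atom_excess, frac_new_dna,
                            model = density_model()) {
  if (any(atom_excess < 0 | atom_excess > 1) ||
      any(frac_new_dna < 0 | frac_new_dna > 1)) {
    stop("atom_excess and frac_new_dna must be in [0, 1]")
  }
  buoyant_density(gc, model) +
    model$max_shift_18O * atom_excess * frac_new_dna
}

#' Distribute DNA mass over density bins
#'
#' Each entity's DNA is a Gaussian band centred on its (possibly labeled)
#' density with sd `band_sigma`; the mass in each bin is the Gaussian
#' integral over the bin. Mass outside the gradient's modelled range is
#' reported as the `tail` attribute; row sums plus tail equal the input
#' abundances.
#'
#' @param density per-entity band mean, g/ml (named vector).
#' @param abundance per-entity DNA mass (same order).
#' @param scheme a [fraction_scheme()].
#' @param model a [density_model()].
#' @return matrix entities x bins with attribute `tail`.
#' @export
fractionate <- function(density, abundance, scheme = fraction_scheme(),
                        model = density_model()) {
  stopifnot(length(density) == length(abundance), all(abundance >= 0))
  edges <- scheme$edges
  p <- vapply(seq_along(scheme$labels), function(j) {
    pnorm(edges[j + 1], density, model$band_sigma) -
      pnorm(edges[j], density, model$band_sigma)
  }, numeric(length(density)))
  if (length(density) == 1L) p <- matrix(p, nrow = 1L)
  mass <- p * abundance
  dimnames(mass) <- list(names(density), scheme$labels)
  attr(mass, "tail") <- unname(abundance - rowSums(mass))
  mass
}

# Per-entity band means for a treatment arm at a timepoint.
#' @noRd
entity_densities <- function(truth, timepoint, atom_excess,
                             model = density_model()) {
  ids <- c(names(truth$hosts), names(truth$viruses))
  gc <- c(vapply(truth$hosts, `[[`, 0, "gc"),
          vapply(truth$viruses, `[[`, 0, "gc"))
  fn <- truth$frac_new
  fr <- fn$frac_new[fn$timepoint == timepoint][
    match(ids, fn$entity[fn$timepoint == timepoint])]
  setNames(labeled_density(gc, atom_excess, fr, model), ids)
}

#' Simulate one sequenced fraction sample
#'
#' Draws `depth` fixed-length single-end reads from the entities in one
#' density bin of one (treatment, timepoint, replicate), proportionally to
#' each entity's DNA mass in that bin, with uniform start positions and
#' i.i.d. substitution errors. Read provenance is kept in the truth-side
#' `provenance` table, never in the read identifiers the pipeline sees.
#'
#' @param truth a `sip_community`.
#' @param treatment `"18O"` or `"16O"`.
#' @param timepoint,replicate sample coordinates.
#' @param bin sequenced bin label (`"MH"` or `"H"` under the default
#'   scheme).
#' @param scheme,model gradient model.
#' @param depth number of reads.
#' @param read_len read length, bp (>= 50).
#' @param error_rate per-base substitution probability.
#' @param atom_excess 18O atom fraction excess applied to the `"18O"`
#'   treatment (the `"16O"` arm always uses 0).
#' @return list of class `fraction_sample`: `sample_id`, `treatment`,
#'   `timepoint`, `replicate`, `bin`, `reads` (data.frame `read_id`,
#'   `sequence`), `total_bp`, `provenance`.
#' @export
simulate_fraction_sample <- function(truth, treatment, timepoint, replicate,
                                     bin, scheme = fraction_scheme(),
                                     model = density_model(), depth = 2000L,
                                     read_len = 300L, error_rate = 0.005,
                                     atom_excess = 0.97) {
  stopifnot(depth >= 1L, read_len >= 50L, treatment %in% c("18O", "16O"),
            bin %in% scheme$labels)
  excess <- if (treatment == "18O") atom_excess else 0
  dens <- entity_densities(truth, timepoint, excess, model)
  ab <- truth$abundance
  ab_t <- ab$abundance[ab$timepoint == timepoint][
    match(names(dens), ab$entity[ab$timepoint == timepoint])]
  mass <- fractionate(dens, ab_t, scheme, model)[, bin]
  sample_id <- sprintf("%s_t%d_r%d_%s", treatment, timepoint, replicate,
                       bin)
  empty <- data.frame(read_id = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (sum(mass) < 1e-12) {
    warning("bin ", bin, " is empty for sample ", sample_id)
    return(structure(list(sample_id = sample_id, treatment = treatment,
                          timepoint = timepoint, replicate = replicate,
                          bin = bin, reads = empty, total_bp = 0L,
                          provenance = empty),
                     class = "fraction_sample"))
  }
  seqs <- community_sequences(truth)
  lens <- nchar(seqs)
  src <- sample(names(mass), depth, replace = TRUE, prob = mass)
  start <- floor(runif(depth) * (lens[src] - read_len)) + 1L
  reads <- substring(seqs[src], start, start + read_len - 1L)
  n_err <- rbinom(depth, read_len, error_rate)
  for (i in which(n_err > 0L)) {
    reads[i] <- mutate_sequence(reads[i], n_err[i])
  }
  read_id <- sprintf("%s_r%05d", sample_id, seq_len(depth))
  structure(list(
    sample_id = sample_id, treatment = treatment, timepoint = timepoint,
    replicate = replicate, bin = bin,
    reads = data.frame(read_id = read_id, sequence = unname(reads),
                       stringsAsFactors = FALSE),
    total_bp = depth * read_len,
    provenance = data.frame(read_id = read_id, entity = unname(src),
                            start = unname(start) - 1L,
                            stringsAsFactors = FALSE)
  ), class = "fraction_sample")
}

#' Simulate the full SIP sequencing experiment
#'
#' All sequenced fraction samples of the study design: 2 treatments x 2
#' timepoints x `n_replicates` x the scheme's sequenced bins, in a fixed
#' order under a single seeded RNG stream.
#'
#' @inheritParams simulate_fraction_sample
#' @param n_replicates biological replicates per arm.
#' @param seed integer seed.
#' @return list with `samples` (list of `fraction_sample`), `sheet`
#'   (sample metadata data.frame) and `provenance` (truth-side read origin
#'   table).
#' @export
simulate_experiment <- function(truth, scheme = fraction_scheme(),
                                model = density_model(), depth = 2000L,
                                read_len = 300L, error_rate = 0.005,
                                atom_excess = 0.97, n_replicates = 3L,
                                seed = 1L) {
  set.seed(seed)
  tp <- truth$config$timepoints
  samples <- list()
  for (treatment in c("18O", "16O")) {
    for (timepoint in tp) {
      for (replicate in seq_len(n_replicates)) {
        for (bin in scheme$sequenced) {
          s <- simulate_fraction_sample(
            truth, treatment, timepoint, replicate, bin, scheme, model,
            depth, read_len, error_rate, atom_excess)
          samples[[s$sample_id]] <- s
        }
      }
    }
  }
  sheet <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, treatment = s$treatment,
               timepoint = s$timepoint, replicate = s$replicate,
               bin = s$bin, total_bp = s$total_bp,
               stringsAsFactors = FALSE)
  }))
  rownames(sheet) <- NULL
  prov <- do.call(rbind, lapply(samples, function(s) {
    if (nrow(s$provenance) == 0L) return(NULL)
    cbind(sample_id = s$sample_id, s$provenance,
          stringsAsFactors = FALSE)
  }))
  rownames(prov) <- NULL
  list(samples = samples, sheet = sheet, provenance = prov)
}
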