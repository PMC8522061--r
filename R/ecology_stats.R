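# Community statistics: Shannon diversity of the active viral community,
# the 2.2 x IQR outlier rule, Welch t comparison of timepoints, activity
# trajectories between timepoints, and the virus:host abundance
# regression.

#' Shannon diversity of an abundance vector
#'
#' Proportions are taken over the positive entries; `H = -sum(p log p)`
#' in nats, richness is the count of positives, and Pielou evenness is
#' `H / ln(richness)` (defined as 1 for a single taxon).
#'
#' @param abundances non-negative vector with at least one positive
#'   entry.
#' @return named numeric: `richness`, `shannon_h`, `evenness`.
#' @export
shannon_diversity <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  pos <- abundances[abundances > 0]
  if (length(pos) == 0L) stop("all-zero abundance vector")
  p <- pos / sum(pos)
  h <- -sum(p * log(p))
  s <- length(pos)
  c(richness = s, shannon_h = h,
    evenness = if (s == 1L) 1 else h / log(s))
}

#' Per-sample diversity of the active viral community
#'
#' @param coverage coverage records.
#' @param active_votus ids of active vOTUs to restrict to.
#' @return data.frame: `sample`, `richness`, `shannon_h`, `evenness`.
#' @export
diversity_summary <- function(coverage, active_votus = NULL) {
  if (!is.null(active_votus)) {
    coverage <- coverage[coverage$entity %in% active_votus, ,
                         drop = FALSE]
  }
  out <- lapply(split(coverage, coverage$sample), function(cv) {
    ab <- cv$normalized_abundance
    ab[!cv$present] <- 0
    if (all(ab == 0)) {
      return(data.frame(sample = cv$sample[1], richness = 0,
                        shannon_h = NA_real_, evenness = NA_real_,
                        stringsAsFactors = FALSE))
    }
    d <- shannon_diversity(ab)
    data.frame(sample = cv$sample[1], richness = d["richness"],
               shannon_h = d["shannon_h"], evenness = d["evenness"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Outlier filter by the 2.2 x IQR rule
#'
#' Keeps values within `[Q1 - m * IQR, Q3 + m * IQR]` with
#' linear-interpolation (type 7) quartiles and multiplier `m = 2.2`.
#' Idempotent on already-filtered data; vectors shorter than 4 are
#' returned unchanged with a warning.
#'
#' @param values numeric vector.
#' @param multiplier fence multiplier.
#' @return the kept values, with attribute `removed` (count).
#' @export
outlier_filter <- function(values, multiplier = 2.2) {
  if (length(values) < 4L) {
    warning("fewer than 4 values; no outlier filtering applied")
    attr(values, "removed") <- 0L
    return(values)
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - multiplier * iqr &
    values <= q[2] + multiplier * iqr
  out <- values[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Compare a metric between two timepoints
#'
#' Welch two-sample t test on outlier-filtered per-sample values.
#'
#' @param group_a,group_b numeric vectors (per-sample metric values).
#' @param filter_outliers apply [outlier_filter()] first.
#' @return list: `statistic`, `p_value`, `n_a`, `n_b`,
#'   `outliers_removed`.
#' @export
compare_timepoints <- function(group_a, group_b, filter_outliers = TRUE) {
  removed <- 0L
  if (filter_outliers) {
    group_a <- outlier_filter(group_a)
    group_b <- outlier_filter(group_b)
    removed <- attr(group_a, "removed") + attr(group_b, "removed")
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least 2 values per group after filtering")
  }
  tt <- stats::t.test(group_a, group_b)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       n_a = length(group_a), n_b = length(group_b),
       outliers_removed = removed)
}

#' Activity trajectories between the two timepoints
#'
#' Per vOTU: `newly_active` = active only at the later timepoint;
#' `lost` = active only at the earlier; `more_abundant` = active at both
#' with strictly higher normalized abundance at the later timepoint.
#'
#' @param calls_early,calls_late presence-rule activity calls (see
#'   [call_votu_activity()]).
#' @param abundance_early,abundance_late named numeric of per-vOTU
#'   normalized abundance at each timepoint (e.g. mean over 18O
#'   samples).
#' @return list: `counts` (named numeric) and `classes` (per-vOTU
#'   data.frame).
#' @export
activity_trajectories <- function(calls_early, calls_late,
                                  abundance_early, abundance_late) {
  ids <- sort(union(calls_early$entity, calls_late$entity))
  a1 <- setNames(calls_early$active[match(ids, calls_early$entity)], ids)
  a2 <- setNames(calls_late$active[match(ids, calls_late$entity)], ids)
  a1[is.na(a1)] <- FALSE
  a2[is.na(a2)] <- FALSE
  ab1 <- ifelse(is.na(abundance_early[ids]), 0, abundance_early[ids])
  ab2 <- ifelse(is.na(abundance_late[ids]), 0, abundance_late[ids])
  cls <- ifelse(!a1 & a2, "newly_active",
                ifelse(a1 & !a2, "lost",
                       ifelse(a1 & a2 & ab2 > ab1, "more_abundant",
                              "none")))
  list(
    counts = c(more_abundant = sum(cls == "more_abundant"),
               newly_active = sum(cls == "newly_active"),
               lost = sum(cls == "lost")),
    classes = data.frame(entity = ids, active_early = a1,
                         active_late = a2, abundance_early = ab1,
                         abundance_late = ab2, class = cls,
                         stringsAsFactors = FALSE, row.names = NULL))
}

#' Virus:host abundance regression
#'
#' Ordinary least squares of summed linked-virus abundance on summed
#' host abundance (points are typically per phylum per sample), after
#' removing points outside the 2.2 x IQR fences on either axis. The
#' virus abundance is modelled as depending on the host.
#'
#' @param host_abundance,virus_abundance paired numeric vectors.
#' @param filter_outliers apply the fence filter per axis.
#' @return list of class `sip_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n_points`, `outliers_removed`; the fit is
#'   `NULL` with `n_points < 3` after filtering.
#' @export
virus_host_regression <- function(host_abundance, virus_abundance,
                                  filter_outliers = TRUE) {
  stopifnot(length(host_abundance) == length(virus_abundance))
  keep <- rep(TRUE, length(host_abundance))
  if (filter_outliers && length(host_abundance) >= 4L) {
    fence <- function(v) {
      q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      v >= q[1] - 2.2 * iqr & v <= q[2] + 2.2 * iqr
    }
    keep <- fence(host_abundance) & fence(virus_abundance)
  }
  x <- host_abundance[keep]
  y <- virus_abundance[keep]
  removed <- sum(!keep)
  if (length(x) < 3L) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_,
                          n_points = length(x),
                          outliers_removed = removed),
                     class = "sip_regression"))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n_points = length(x), outliers_removed = removed
  ), class = "sip_regression")
}

#' Percentage of active entities
#'
#' @param n_active,n_total counts with `0 <= n_active <= n_total`,
#'   `n_total > 0`.
#' @return percentage rounded to the nearest integer.
#' @export
percent_active <- function(n_active, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  if (any(n_active < 0 | n_active > n_total)) {
    stop("n_active must be in [0, n_total]")
  }
  floor(100 * n_active / n_total + 0.5)
}
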