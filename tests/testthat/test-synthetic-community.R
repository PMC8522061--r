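# Ground-truth generator: composition, determinism, planted features.

test_that("host genome generation respects composition and determinism", {
  h <- generate_host_genome(50000, 0.5, seed = 1)
  # binomial tail bound at n = 50,000: realized gc within 0.02 of target
  expect_gte(h$gc, 0.48)
  expect_lte(h$gc, 0.52)
  expect_equal(nchar(h$sequence), 50000)
  h2 <- generate_host_genome(50000, 0.5, seed = 1)
  expect_identical(h$sequence, h2$sequence)
  h3 <- generate_host_genome(50000, 0.5, seed = 2)
  expect_false(identical(h$sequence, h3$sequence))
})

test_that("generator preconditions are enforced", {
  expect_error(generate_host_genome(50000, 0.0), "gc_target")
  expect_error(generate_host_genome(50000, 0.9), "gc_target")
  expect_error(generate_host_genome(1000, 0.5), "length")
  expect_error(generate_host_genome(1e7, 0.5), "length")
})

test_that("realized gc tracks the target across the supported range", {
  withr::with_seed(7, {
    for (gc in c(0.25, 0.4, 0.6, 0.75)) {
      h <- generate_host_genome(30000, gc, id = "h")
      expect_lt(abs(h$gc - gc), 0.02)
    }
  })
})

test_that("planted CRISPR arrays store verbatim spacers and provenance", {
  withr::with_seed(11, {
    host <- generate_host_genome(40000, 0.45, id = "h1")
    virus <- generate_viral_genome(12000, 0.42, id = "v1")
    host <- plant_crispr_array(host, virus, n_spacers = 3)
    expect_equal(nrow(host$crispr_arrays), 1L)
    arr <- host$crispr_arrays
    sp <- arr$spacers[[1]]
    expect_equal(nrow(sp), 3L)
    # spacers are exact substrings of the virus
    for (i in 1:3) {
      expect_identical(
        sp$sequence[i],
        substr(virus$sequence, sp$virus_start[i] + 1L, sp$virus_end[i]))
      expect_true(grepl(sp$sequence[i], virus$sequence, fixed = TRUE))
    }
    # the array interval contains the planted spacers verbatim
    written <- substr(host$sequence, arr$start + 1L, arr$end)
    for (s in sp$sequence) expect_true(grepl(s, written, fixed = TRUE))
  })
})

test_that("CRISPR planting rejects unsupported parameters", {
  withr::with_seed(2, {
    host <- generate_host_genome(30000, 0.5, id = "h1")
    virus <- generate_viral_genome(11000, 0.45, id = "v1")
    expect_error(plant_crispr_array(host, virus, n_spacers = 1), ">= 2")
    expect_error(plant_crispr_array(host, virus, repeat_len = 10),
                 "repeat_len")
    expect_error(plant_crispr_array(host, virus, spacer_len = 100),
                 "spacer_len")
  })
})

test_that("mutated spacers are recoverable by exhaustive substring search", {
  withr::with_seed(13, {
    host <- generate_host_genome(30000, 0.5, id = "h1")
    virus <- generate_viral_genome(12000, 0.45, id = "v1")
    host <- plant_crispr_array(host, virus, n_spacers = 3, mismatches = 1)
    sp <- host$crispr_arrays$spacers[[1]]
    for (i in seq_len(nrow(sp))) {
      m <- Biostrings::matchPattern(sp$sequence[i], virus$sequence,
                                    max.mismatch = 1)
      expect_true(sp$virus_start[i] %in% (Biostrings::start(m) - 1L))
    }
  })
})

test_that("provirus integration inserts the full viral sequence", {
  withr::with_seed(3, {
    host <- generate_host_genome(100000, 0.5, id = "h1")
    virus <- generate_viral_genome(12000, 0.42, id = "v1")
    host2 <- integrate_provirus(host, virus, locus = 50000L)
    expect_equal(host2$length, 112000L)
    pv <- host2$provirus_loci
    expect_identical(
      substr(host2$sequence, pv$start + 1L, pv$end), virus$sequence)
    expect_error(integrate_provirus(host2, virus), "already integrated")
    expect_error(integrate_provirus(host, virus, locus = 2e5),
                 "out of bounds")
  })
})

test_that("feature coordinates shift consistently under later insertions", {
  withr::with_seed(4, {
    host <- generate_host_genome(80000, 0.5, id = "h1")
    v1 <- generate_viral_genome(11000, 0.40, id = "v1")
    v2 <- generate_viral_genome(11000, 0.45, id = "v2")
    host <- integrate_provirus(host, v1, locus = 60000L)
    host <- integrate_provirus(host, v2, locus = 10000L)  # upstream
    pv <- host$provirus_loci
    for (i in seq_len(nrow(pv))) {
      vid <- pv$virus[i]
      vseq <- if (vid == "v1") v1$sequence else v2$sequence
      expect_identical(substr(host$sequence, pv$start[i] + 1L, pv$end[i]),
                       vseq)
    }
  })
})

test_that("assemble_community satisfies its bookkeeping invariants", {
  cfg <- community_config(n_hosts = 8L, n_viruses = 12L,
                          host_length = c(5e4, 6e4),
                          virus_length = c(1e4, 1.2e4))
  truth <- assemble_community(cfg, seed = 5)
  expect_length(truth$hosts, 8L)
  expect_length(truth$viruses, 12L)
  # abundances sum to 1 at each timepoint
  for (t in cfg$timepoints) {
    s <- sum(truth$abundance$abundance[truth$abundance$timepoint == t])
    expect_equal(s, 1, tolerance = 1e-9)
  }
  # every true host exists
  for (v in truth$viruses) {
    expect_true(all(v$true_hosts %in% names(truth$hosts)))
  }
  # integrated viruses are temperate and recorded on both sides
  for (v in truth$viruses) {
    if (!is.na(v$integrated_in)) {
      expect_identical(v$lifestyle, "temperate")
      expect_true(v$id %in%
                    truth$hosts[[v$integrated_in]]$provirus_loci$virus)
    }
  }
  # inactive hosts never grow
  for (h in truth$hosts) {
    if (!any(h$active)) expect_true(all(h$growth_factor <= 1))
  }
})

test_that("community assembly is reproducible bit-for-bit", {
  cfg <- community_config(n_hosts = 6L, n_viruses = 8L,
                          host_length = c(5e4, 6e4))
  t1 <- assemble_community(cfg, seed = 9)
  t2 <- assemble_community(cfg, seed = 9)
  expect_identical(community_sequences(t1), community_sequences(t2))
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_truth_json(t1, f1)
  write_truth_json(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an infeasible provirus plan is rejected at configuration", {
  expect_error(
    community_config(n_viruses = 10L, temperate_fraction = 0.2,
                     n_proviruses = 5L),
    "infeasible linkage plan")
})

test_that("labeling truth is cumulative and decays with relic DNA", {
  cfg <- community_config()
  truth <- assemble_community(cfg, seed = 21)
  tp <- cfg$timepoints
  for (v in truth$viruses) {
    fn <- truth$frac_new
    f1 <- fn$frac_new[fn$entity == v$id & fn$timepoint == tp[1]]
    f2 <- fn$frac_new[fn$entity == v$id & fn$timepoint == tp[2]]
    if (v$pattern == "t1_only") {
      expect_gt(f1, 0.5)   # labeled by first-interval growth
      expect_gt(f2, 0)     # label persists even as the pool decays
    }
    if (v$pattern == "none") expect_equal(f1 + f2, 0)
  }
})
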