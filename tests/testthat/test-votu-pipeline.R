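# vOTU construction: ANI, clustering, mapping and normalization.

test_that("pairwise ANI recognises identity and unrelatedness", {
  withr::with_seed(1, {
    a <- random_dna(12000, 0.45)
    expect_equal(unname(pairwise_ani(a, a)), c(100, 1), tolerance = 1e-12)
    b <- random_dna(20000, 0.45)
    c2 <- random_dna(20000, 0.45)
    # unrelated i.i.d. sequences: spurious seeding is negligible
    expect_lt(pairwise_ani(b, c2)["aligned_fraction"], 0.05)
  })
})

test_that("ANI of a 3% mutated copy agrees with a global alignment oracle", {
  withr::with_seed(2, {
    a <- random_dna(20000, 0.45)
    b <- mutated_copy(a, 0.03)
    ani <- pairwise_ani(a, b)
    expect_gte(ani["ani"], 96)
    expect_lte(ani["ani"], 98)
    expect_gt(ani["aligned_fraction"], 0.95)
    # independent oracle: full global alignment percent identity
    pa <- Biostrings::pairwiseAlignment(a, b, type = "global")
    expect_equal(unname(ani["ani"]), Biostrings::pid(pa), tolerance = 0.5)
  })
})

test_that("ANI is symmetric", {
  withr::with_seed(3, {
    a <- random_dna(8000, 0.4)
    b <- paste0(substr(a, 2001, 8000), random_dna(1500, 0.4))
    expect_equal(pairwise_ani(a, b), pairwise_ani(b, a), tolerance = 1e-9)
  })
})

test_that("greedy clustering applies the 95/85 rule", {
  withr::with_seed(4, {
    a <- random_dna(15000, 0.45)
    pool <- data.frame(
      contig_id = c("c1", "c2", "c3"),
      sequence = c(a, a, random_dna(15000, 0.45)),
      length = c(15000L, 15000L, 15000L), stringsAsFactors = FALSE)
    cl <- cluster_votus(pool)
    expect_equal(nrow(cl$votus), 2L)
    expect_equal(sort(cl$votus$n_members), c(1L, 2L))
    # identical contigs share a cluster
    mem <- cl$members
    expect_equal(mem$votu_id[mem$contig_id == "c1"],
                 mem$votu_id[mem$contig_id == "c2"])
    # heavily diverged sequences (below threshold) do not cluster
    d <- mutated_copy(a, 0.20)
    pool2 <- data.frame(contig_id = c("c1", "c4"), sequence = c(a, d),
                        length = c(15000L, 15000L),
                        stringsAsFactors = FALSE)
    expect_equal(nrow(cluster_votus(pool2)$votus), 2L)
  })
})

test_that("clustering is order-invariant and length-filtered", {
  withr::with_seed(5, {
    base <- replicate(4, random_dna(12000, 0.45))
    pool <- data.frame(
      contig_id = sprintf("c%d", 1:6),
      sequence = c(base, mutated_copy(base[1], 0.01),
                   mutated_copy(base[2], 0.01)),
      length = 12000L, stringsAsFactors = FALSE)
    cl1 <- cluster_votus(pool)
    cl2 <- cluster_votus(pool[sample(nrow(pool)), ])
    expect_identical(cl1$votus, cl2$votus)
    expect_identical(cl1$members, cl2$members)
    # representatives are the longest members; every member satisfies
    # the 95/85 rule against its representative, re-checked post hoc
    for (i in seq_len(nrow(cl1$members))) {
      v <- cl1$members$votu_id[i]
      rep_seq <- cl1$rep_seqs[[v]]
      mem_seq <- pool$sequence[pool$contig_id == cl1$members$contig_id[i]]
      ani <- pairwise_ani(rep_seq, mem_seq)
      expect_gte(ani["ani"], 95)
      expect_gte(ani["aligned_fraction"], 0.85)
    }
    short <- data.frame(contig_id = "s", sequence = random_dna(9999, 0.4),
                        length = 9999L, stringsAsFactors = FALSE)
    expect_error(cluster_votus(short), ">= 10000")
  })
})

test_that("the contig length filter excludes sub-10kb viral candidates", {
  contigs <- data.frame(
    contig_id = c("a", "b", "c"),
    length = c(9999L, 10000L, 25000L),
    detection = c("viral_candidate", "viral_candidate", "non_viral"),
    stringsAsFactors = FALSE)
  kept <- filter_candidates(contigs)
  expect_identical(kept$contig_id, "b")
})

test_that("mock viral detection tags by truth and by hallmark markers", {
  cfg <- community_config(n_hosts = 4L, n_viruses = 6L,
                          host_length = c(5e4, 6e4))
  truth <- assemble_community(cfg, seed = 6)
  contigs <- community_contigs(truth, seed = 8)
  tr <- mock_detect_viral(contigs, "truth")
  expect_identical(tr$detection == "viral_candidate", tr$truth_viral)
  mk <- mock_detect_viral(contigs, "marker")
  # every full viral genome carries a hallmark marker
  full <- grepl("_full$", contigs$contig_id)
  expect_true(all(mk$detection[full] == "viral_candidate"))
  # pure host fragments with no provirus content are never tagged
  host_frag <- grepl("_f\\d+$", contigs$contig_id)
  prov_hosts <- unique(unlist(lapply(truth$viruses, `[[`,
                                     "integrated_in")))
  clean <- host_frag & !(contigs$source_entity %in% prov_hosts)
  expect_true(all(mk$detection[clean] == "non_viral"))
})

test_that("read mapping applies the identity gate and presence boundary", {
  withr::with_seed(9, {
    ref <- c(refA = random_dna(12000, 0.45))
    # error-free reads tile the reference: breadth grows to presence
    starts <- seq(1, 11900, by = 60)
    reads <- substring(ref[[1]], starts, starts + 99)
    smp <- list(sample_id = "s1",
                reads = data.frame(sequence = reads,
                                   stringsAsFactors = FALSE),
                total_bp = length(reads) * 100)
    cov <- map_reads(smp, ref)
    expect_gte(cov$breadth, 0.99)
    expect_true(cov$present)
    expect_equal(cov$n_reads, length(reads))
    # reads mutated at 15% fall below the 90% identity gate
    bad <- vapply(reads[1:30], function(r) {
      frostphage:::mutate_sequence(r, 15L)
    }, "", USE.NAMES = FALSE)
    smp_bad <- list(sample_id = "s2",
                    reads = data.frame(sequence = bad,
                                       stringsAsFactors = FALSE),
                    total_bp = 3000)
    cov_bad <- map_reads(smp_bad, ref)
    expect_equal(cov_bad$n_reads, 0L)
    expect_false(cov_bad$present)
  })
})

test_that("presence is monotone in added reads", {
  withr::with_seed(10, {
    ref <- c(r = random_dna(10000, 0.45))
    starts <- sample(1:9900, 300, replace = TRUE)
    reads <- substring(ref[[1]], starts, starts + 99)
    present <- vapply(c(50, 100, 200, 300), function(n) {
      smp <- list(sample_id = "s",
                  reads = data.frame(sequence = reads[seq_len(n)],
                                     stringsAsFactors = FALSE),
                  total_bp = n * 100)
      map_reads(smp, ref)$present
    }, TRUE)
    expect_true(all(diff(as.integer(present)) >= 0))
  })
})

test_that("abundance normalization is per gigabase and inverse in size", {
  expect_equal(normalize_abundance(10, 2e9, 20000), 5)
  expect_equal(normalize_abundance(4, 1e9, 5000),
               2 * normalize_abundance(4, 2e9, 5000))
  expect_equal(normalize_abundance(0, 5e8, 1000), 0)
  expect_error(normalize_abundance(1, 0, 1000), "total_bp")
  expect_error(normalize_abundance(1, 1e9, 0), "ref_length")
})

test_that("coverage_table equals per-sample map_reads", {
  withr::with_seed(11, {
    refs <- c(a = random_dna(11000, 0.4), b = random_dna(12000, 0.5))
    mk_sample <- function(id, ref, n) {
      starts <- sample(1:(nchar(ref) - 100), n)
      list(sample_id = id,
           reads = data.frame(sequence = substring(ref, starts,
                                                   starts + 99),
                              stringsAsFactors = FALSE),
           total_bp = n * 100)
    }
    samples <- list(s1 = mk_sample("s1", refs[["a"]], 120),
                    s2 = mk_sample("s2", refs[["b"]], 80))
    combined <- coverage_table(samples, refs)
    single <- do.call(rbind, lapply(samples, map_reads,
                                    references = refs))
    rownames(single) <- NULL
    expect_equal(combined, single)
  })
})
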