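# CRISPR detection, spacer matching, content linkage, provirus and
# temperate classification, cross-tabulation.

plant_array_seq <- function(genome, repeat_seq, spacers, locus) {
  arr <- paste0(repeat_seq, paste0(spacers, repeat_seq, collapse = ""))
  frostphage:::insert_segment(genome, arr, locus)
}

test_that("a planted array is recovered with byte-identical spacers", {
  withr::with_seed(31, {
    g <- random_dna(60000, 0.5)
    rep_seq <- random_dna(28, 0.5)
    spacers <- replicate(3, random_dna(32, 0.45))
    g2 <- plant_array_seq(g, rep_seq, spacers, 30000L)
    arrays <- detect_crispr_arrays(g2)
    expect_length(arrays, 1L)
    a <- arrays[[1]]
    expect_identical(a$repeat_consensus, rep_seq)
    expect_identical(a$spacers$sequence, spacers)
    expect_equal(a$start, 30000)
    # coordinates address the genome: extract and compare
    for (i in 1:3) {
      expect_identical(substr(g2, a$spacers$start[i] + 1L,
                              a$spacers$end[i]), spacers[i])
    }
  })
})

test_that("a minimal two-repeat array is detected", {
  withr::with_seed(32, {
    g <- random_dna(30000, 0.5)
    rep_seq <- random_dna(24, 0.5)
    g2 <- plant_array_seq(g, rep_seq, random_dna(30, 0.45), 12000L)
    arrays <- detect_crispr_arrays(g2, min_copies = 2)
    expect_length(arrays, 1L)
    expect_equal(nrow(arrays[[1]]$spacers), 1L)
  })
})

test_that("repeat copies with one mismatch are still walked", {
  withr::with_seed(33, {
    g <- random_dna(40000, 0.5)
    rep_seq <- random_dna(30, 0.5)
    rep_mut <- frostphage:::mutate_sequence(rep_seq, 1L)
    arr <- paste0(rep_seq, random_dna(35, 0.45), rep_seq,
                  random_dna(33, 0.45), rep_mut)
    g2 <- frostphage:::insert_segment(g, arr, 20000L)
    arrays <- detect_crispr_arrays(g2)
    expect_length(arrays, 1L)
    expect_equal(length(arrays[[1]]$spacers$sequence), 2L)
  })
})

test_that("random genomes yield no arrays at default stringency", {
  for (s in 1:5) {
    withr::with_seed(s, {
      g <- random_dna(100000, 0.5)
      expect_length(detect_crispr_arrays(g), 0L)
    })
  }
})

test_that("spacer matching honours the one-mismatch boundary", {
  withr::with_seed(34, {
    votu <- c(v1 = random_dna(12000, 0.45))
    sp0 <- substr(votu[[1]], 5001, 5032)
    sp1 <- frostphage:::mutate_sequence(sp0, 1L)
    sp2 <- frostphage:::mutate_sequence(sp0, 2L)
    spacers <- setNames(c(sp0, sp1, sp2), c("s0", "s1", "s2"))
    hits <- match_spacers(spacers, votu)
    expect_setequal(hits$spacer_id, c("s0", "s1"))
    expect_equal(hits$mismatches[hits$spacer_id == "s0"], 0L)
    expect_equal(hits$mismatches[hits$spacer_id == "s1"], 1L)
    # reverse-strand protospacers are found
    rc <- frostphage:::revcomp(sp0)
    hits_rc <- match_spacers(setNames(rc, "r0"), votu)
    expect_identical(hits_rc$strand, "-")
    expect_error(match_spacers(setNames("ACGT", "short"), votu), "17")
  })
})

test_that("spacer matching equals the sliding-window oracle", {
  withr::with_seed(35, {
    votus <- setNames(replicate(6, random_dna(6000, 0.45)),
                      sprintf("v%d", 1:6))
    spacers <- character(0)
    for (i in 1:15) {
      src <- sample(6, 1)
      s0 <- sample(5000, 1)
      sp <- substr(votus[[src]], s0, s0 + 31)
      sp <- frostphage:::mutate_sequence(sp, sample(0:2, 1))
      if (runif(1) < 0.3) sp <- frostphage:::revcomp(sp)
      spacers <- c(spacers, sp)
    }
    spacers <- c(spacers, replicate(5, random_dna(32, 0.45)))
    names(spacers) <- sprintf("s%02d", seq_along(spacers))
    hits <- match_spacers(spacers, votus)
    oracle <- oracle_spacer_hits(unname(spacers), unname(votus))
    got <- sort(paste(hits$spacer_id, hits$votu, hits$start, hits$strand))
    want <- sort(paste(names(spacers)[oracle$spacer],
                       names(votus)[oracle$ref], oracle$start,
                       oracle$strand))
    expect_identical(got, want)
  })
})

test_that("content linkage requires 70% identity and 500 aligned bases", {
  withr::with_seed(36, {
    votu <- random_dna(11000, 0.45)
    host <- random_dna(50000, 0.5)
    # full containment: aligned fraction ~ 1
    host_in <- frostphage:::insert_segment(host, votu, 25000L)
    cl <- content_linkage(votu, host_in)
    expect_gte(cl$votu_aligned_fraction, 0.99)
    expect_gte(cl$best_identity, 99)
    # a 2 kb shared module: linked, small fraction
    host_mod <- frostphage:::insert_segment(host, substr(votu, 1, 2000),
                                            25000L)
    cl_mod <- content_linkage(votu, host_mod)
    expect_lt(cl_mod$votu_aligned_fraction, 0.25)
    # the same module at ~35% divergence (65% identity): no link
    far <- frostphage:::mutate_sequence(substr(votu, 1, 2000), 700L)
    host_far <- frostphage:::insert_segment(host, far, 25000L)
    expect_null(content_linkage(votu, host_far))
    # a 400 bp exact module: below the length floor
    host_small <- frostphage:::insert_segment(host, substr(votu, 1, 400),
                                              25000L)
    expect_null(content_linkage(votu, host_small))
  })
})

test_that("content linkage equals the exhaustive-diagonal oracle", {
  withr::with_seed(37, {
    votus <- setNames(replicate(4, random_dna(3000, 0.45)),
                      sprintf("v%d", 1:4))
    mags <- list()
    for (i in 1:4) {
      g <- random_dna(6000, 0.5)
      if (i <= 2) {
        piece <- substr(votus[[i]], 1, sample(800:2500, 1))
        piece <- frostphage:::mutate_sequence(
          piece, round(0.05 * nchar(piece)))
        g <- frostphage:::insert_segment(g, piece, 3000L)
      }
      mags[[sprintf("m%d", i)]] <- g
    }
    for (v in names(votus)) {
      for (m in names(mags)) {
        got <- content_linkage(votus[[v]], mags[[m]])
        want <- oracle_content_link(votus[[v]], mags[[m]])
        expect_identical(is.null(got), is.null(want))
        if (!is.null(got)) {
          expect_equal(got$total_aligned, want$total_aligned)
          expect_equal(got$votu_aligned_fraction,
                       want$votu_aligned_fraction)
        }
      }
    }
  })
})

test_that("provirus and temperate classification follow their gates", {
  expect_true(call_provirus(0.95, temperate = TRUE))
  expect_false(call_provirus(0.10, temperate = TRUE))
  expect_false(call_provirus(0.95, temperate = FALSE))
  withr::with_seed(38, {
    temp <- generate_viral_genome(11000, 0.45, id = "vt",
                                  lifestyle = "temperate")
    vir <- generate_viral_genome(11000, 0.45, id = "vv",
                                 lifestyle = "virulent")
    seqs <- c(vOTU_A = temp$sequence, vOTU_B = vir$sequence)
    cls <- classify_temperate(seqs)
    expect_true(cls$temperate[cls$votu == "vOTU_A"])
    expect_true(cls$has_lysogeny_marker[cls$votu == "vOTU_A"])
    expect_false(cls$temperate[cls$votu == "vOTU_B"])
    # containment evidence alone also classifies temperate
    cls2 <- classify_temperate(seqs, containment = c(vOTU_B = 0.95))
    expect_true(cls2$temperate[cls2$votu == "vOTU_B"])
  })
})

test_that("the cross-tabulation assigns each match to exactly one group", {
  links <- data.frame(
    votu = c("v1", "v1", "v2", "v3", "v3", "v3"),
    mag = c("m1", "m2", "m1", "m3", "m3", "m4"),
    stringsAsFactors = FALSE)
  va <- c(v1 = TRUE, v2 = FALSE, v3 = FALSE)
  ma <- c(m1 = TRUE, m2 = FALSE, m3 = FALSE, m4 = TRUE)
  tab <- build_crosstab(links, va, ma)
  # groups: (v1,m1)->1; (v1,m2)->2; (v2,m1),(v3,m4)->3; (v3,m3) twice->4
  expect_equal(tab$n_matches, c(1, 1, 2, 2, 6))
  expect_equal(tab$n_unique_pairs, c(1, 1, 2, 1, 5))
  expect_equal(sum(tab$n_matches[1:4]), tab$n_matches[5])
  # permutation invariance
  tab2 <- build_crosstab(links[sample(nrow(links)), ], va, ma)
  expect_equal(tab2$n_matches, tab$n_matches)
  # single active-active link
  tab3 <- build_crosstab(links[1, ], va, ma)
  expect_equal(tab3$n_matches[1:4], c(1, 0, 0, 0))
  expect_equal(tab3$n_votus[1:4], c(1, 0, 0, 0))
  # a linked entity without an activity call is an error naming it
  expect_error(build_crosstab(links, va[-1], ma), "v1")
})

test_that("broad-host-range viruses link hosts spanning their phyla", {
  withr::with_seed(39, {
    virus <- generate_viral_genome(11000, 0.45, id = "v1")
    phyla <- c("Firmicutes", "Bacteroidota", "Acidobacteriota")
    mags <- list()
    for (i in 1:3) {
      h <- generate_host_genome(40000, 0.45, id = sprintf("m%d", i),
                                phylum = phyla[i])
      h <- plant_crispr_array(h, virus, n_spacers = 3)
      mags[[h$id]] <- h
    }
    seqs <- vapply(mags, `[[`, "", "sequence")
    res <- link_virus_host(c(vOTU_1 = virus$sequence), seqs)
    linked_phyla <- vapply(mags[unique(res$links$mag)], `[[`, "",
                           "phylum")
    expect_setequal(unname(linked_phyla), phyla)
    expect_true(all(res$links$evidence %in% c("crispr", "both")))
  })
})

test_that("an integrated provirus links with both evidence and the flag", {
  withr::with_seed(40, {
    host <- generate_host_genome(60000, 0.5, id = "m1")
    virus <- generate_viral_genome(11000, 0.45, id = "v1",
                                   lifestyle = "temperate")
    host <- plant_crispr_array(host, virus, n_spacers = 3)
    host <- integrate_provirus(host, virus)
    res <- link_virus_host(c(vOTU_1 = virus$sequence),
                           c(m1 = host$sequence))
    expect_equal(nrow(res$links), 1L)
    expect_identical(res$links$evidence, "both")
    expect_true(res$links$provirus)
    expect_gte(res$links$votu_aligned_fraction, 0.9)
    expect_true(res$temperate$temperate[1])
  })
})
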