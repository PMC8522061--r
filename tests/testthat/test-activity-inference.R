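# Activity calling: presence rule, read subtraction, ZILN fold change.

make_cov <- function(entity, sample, present) {
  data.frame(entity = entity, sample = sample, n_reads = 10L,
             mean_depth = ifelse(present, 1, 0),
             breadth = ifelse(present, 0.9, 0.1),
             normalized_abundance = ifelse(present, 1, 0),
             present = present, stringsAsFactors = FALSE)
}

make_sheet <- function() {
  expand.grid(treatment = c("18O", "16O"), replicate = 1:3,
              stringsAsFactors = FALSE) |>
    transform(timepoint = 184L, bin = "pooled") |>
    transform(sample_id = sprintf("%s_t184_r%d", treatment, replicate))
}

test_that("the presence rule distinguishes active/unlabeled/undetected", {
  sheet <- make_sheet()
  grid <- expand.grid(entity = c("v1", "v2", "v3"),
                      sample_id = sheet$sample_id,
                      stringsAsFactors = FALSE)
  # v1: two 18O replicates, no 16O -> active
  # v2: 18O and one 16O replicate -> unlabeled
  # v3: absent everywhere -> undetected
  pres <- with(grid,
    (entity == "v1" & sample_id %in% c("18O_t184_r1", "18O_t184_r2")) |
    (entity == "v2" & sample_id %in% c("18O_t184_r1", "16O_t184_r2")))
  cov <- make_cov(grid$entity, grid$sample_id, pres)
  calls <- call_votu_activity(cov, sheet, 184L)
  expect_identical(calls$status[calls$entity == "v1"], "active")
  expect_identical(calls$status[calls$entity == "v2"], "unlabeled")
  expect_identical(calls$status[calls$entity == "v3"], "undetected")
  expect_identical(calls$active, calls$status == "active")
})

test_that("a missing treatment arm is reported by name", {
  sheet <- make_sheet()
  sheet16 <- sheet[sheet$treatment == "16O", ]
  cov <- make_cov("v1", sheet16$sample_id, TRUE)
  expect_error(call_votu_activity(cov, sheet16, 184L), "18O")
})

test_that("read subtraction removes matching reads and keeps foreign ones", {
  withr::with_seed(21, {
    ref <- c(u1 = random_dna(5000, 0.45))
    other <- random_dna(5000, 0.45)
    starts <- sample(1:4900, 30)
    copied <- substring(ref[[1]], starts, starts + 99)
    foreign <- substring(other, starts, starts + 99)
    out <- subtract_reads(c(copied, foreign), ref)
    expect_identical(as.character(out), foreign)
    expect_equal(attr(out, "subtracted"), seq_along(copied))
    expect_error(subtract_reads(copied, character(0)), "non-empty")
  })
})

test_that("subtraction tolerates one indel but applies the identity gate", {
  withr::with_seed(22, {
    ref <- c(u1 = random_dna(4000, 0.45))
    read <- substr(ref[[1]], 501, 650)
    # one inserted base: still subtracted under maxindel = 1
    ins <- paste0(substr(read, 1, 70), "A", substr(read, 71, 149))
    # heavy divergence: retained
    far <- frostphage:::mutate_sequence(read, 15L)
    out <- subtract_reads(c(read, ins, far), ref)
    expect_identical(as.character(out), far)
  })
})

test_that("enlarging the unlabeled reference never grows the survivors", {
  withr::with_seed(23, {
    refs <- vapply(1:3, function(i) random_dna(3000, 0.45), "")
    names(refs) <- paste0("u", 1:3)
    reads <- unlist(lapply(refs, function(r) {
      starts <- sample(1:2900, 10)
      substring(r, starts, starts + 99)
    }), use.names = FALSE)
    reads <- c(reads, replicate(10, random_dna(100, 0.45)))
    prev <- Inf
    for (n in 1:3) {
      surv <- length(subtract_reads(reads, refs[seq_len(n)]))
      expect_lte(surv, prev)
      prev <- surv
    }
  })
})

test_that("MAG subtraction calls respect the depth and breadth floors", {
  withr::with_seed(24, {
    mags <- c(m1 = random_dna(20000, 0.45), m2 = random_dna(20000, 0.5))
    starts <- sample(1:19900, 120)
    reads <- substring(mags[["m1"]], starts, starts + 99)
    calls <- call_mag_activity_subtraction(reads, mags)
    expect_true(calls$active[calls$entity == "m1"])
    expect_false(calls$active[calls$entity == "m2"])
    expect_equal(calls$active_reads[calls$entity == "m2"], 0L)
    # most permissive limit: any active read suffices
    calls0 <- call_mag_activity_subtraction(reads[1], mags,
                                            min_active_depth = 0,
                                            min_active_breadth = 0)
    expect_true(calls0$active[calls0$entity == "m1"])
  })
})

test_that("median-of-ratios factors recover sample scaling", {
  withr::with_seed(25, {
    base <- rlnorm(50, 5, 1)
    counts <- cbind(s1 = base, s2 = 2 * base, s3 = base)
    sf <- mor_norm_factors(round(counts))
    expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 0.05)
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
  })
})

test_that("identical arms give zero fold change and p near 1", {
  x <- matrix(c(5, 9, 7), 1, 3)
  res <- ziln_fold_change(x, x)
  expect_equal(res$log2_fold_change, 0)
  expect_gt(res$p_value, 0.99)
  expect_false(res$active)
})

test_that("all-zero entities are untestable, strong signals are called", {
  a <- rbind(e1 = c(0, 0, 0), e2 = c(800, 900, 850))
  b <- rbind(e1 = c(0, 0, 0), e2 = c(0, 0, 0))
  res <- ziln_fold_change(a, b)
  expect_false(res$testable[1])
  expect_true(is.na(res$q_value[1]))
  expect_true(res$testable[2])
  expect_gt(res$log2_fold_change[2], 0)
  expect_true(res$active[2])
  # q >= p for every testable entity
  ok <- res$testable
  expect_true(all(res$q_value[ok] >= res$p_value[ok]))
})

test_that("the null type-I rate of the ZILN test is near nominal", {
  withr::with_seed(26, {
    n <- 1500
    a <- matrix(rlnorm(n * 3, 5, 1), n, 3)
    b <- matrix(rlnorm(n * 3, 5, 1), n, 3)
    res <- ziln_fold_change(a, b)
    rate <- mean(res$p_value < 0.05)
    expect_gt(rate, 0.035)
    expect_lt(rate, 0.065)
    expect_lte(mean(res$active), 0.05)
  })
})

test_that("the ZILN test has power against an 8-fold shift", {
  withr::with_seed(27, {
    n <- 400
    pi0 <- 0.2
    a <- matrix(rlnorm(n * 3, 5 + log(8), 0.35), n, 3)
    b <- matrix(rlnorm(n * 3, 5, 0.35), n, 3)
    zero <- matrix(runif(n * 6) < pi0, n, 6)
    a[zero[, 1:3]] <- 0
    b[zero[, 4:6]] <- 0
    res <- ziln_fold_change(a, b)
    testable <- res$testable
    expect_gt(mean(res$active[testable]), 0.8)
    expect_true(all(abs(res$zero_inflation - pi0) < 0.5))
  })
})
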