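test_that("simulate_pool yields distinct haplotypes tracing back to their parents", {
  pool <- simulate_pool(K = 5, L = 300, mu = 1, seed = 11)
  expect_equal(length(unique(pool$sequences)), 5)
  expect_true(is.na(pool$genealogy[1]))
  # each child differs from its recorded parent by >= 1 site (Hamming scan)
  for (k in 2:5) {
    p <- pool$genealogy[k]
    d <- sum(pool$seq_matrix[k, ] != pool$seq_matrix[p, ])
    expect_gte(d, 1)
  }
})

test_that("pool generation is seed-reproducible and seed-sensitive", {
  a <- simulate_pool(K = 6, L = 40, mu = 2, seed = 42)
  b <- simulate_pool(K = 6, L = 40, mu = 2, seed = 42)
  c <- simulate_pool(K = 6, L = 40, mu = 2, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$sequences, c$sequences))
})

test_that("a single-haplotype pool produces monomorphic cohorts", {
  pool <- simulate_pool(K = 1, L = 50, seed = 2)
  coh <- sample_cohorts(pool, n_ancient = 5, n_modern = 10, miss_rate = 0,
                        deam_rate = 0, seed = 3)
  expect_equal(call_haplotypes(coh)$S, 0)
  expect_equal(length(call_haplotypes(coh)$keys), 1)
})

test_that("cohort sizes and strata match the two-period study design", {
  pool <- simulate_pool(K = 10, L = 60, seed = 5)
  coh <- sample_cohorts(pool, n_ancient = 41, n_modern = 808, seed = 6)
  expect_equal(sum(coh$meta$stratum == "ancient"), 41)
  expect_equal(sum(coh$meta$stratum == "modern"), 808)
  expect_equal(coh$L, 60)
})

test_that("lineage loss caps the modern cohort's haplotype richness", {
  # K=4 equal frequencies, loss=0.5 -> at most 2 distinct modern haplotypes
  pool <- simulate_pool(K = 4, L = 80, mu = 3, seed = 7)
  pool$freqs <- rep(0.25, 4)
  for (s in 1:10) {
    coh <- sample_cohorts(pool, n_ancient = 5, n_modern = 100, loss = 0.5,
                          miss_rate = 0, deam_rate = 0, seed = 100 + s)
    mod <- subset(coh, stratum = "modern")
    expect_lte(length(unique(apply(mod$seqs, 1, paste, collapse = ""))), 2)
  }
  expect_error(sample_cohorts(pool, loss = 1), "no modern lineage survives")
})

test_that("expected modern haplotype richness is non-increasing in loss", {
  pool <- simulate_pool(K = 12, L = 60, mu = 2, seed = 20)
  mean_rich <- sapply(c(0, 0.35, 0.7), function(lam) {
    mean(sapply(1:15, function(s) {
      coh <- sample_cohorts(pool, n_ancient = 2, n_modern = 60, loss = lam,
                            miss_rate = 0, deam_rate = 0, seed = 500 + s)
      mod <- subset(coh, stratum = "modern")
      length(unique(apply(mod$seqs, 1, paste, collapse = "")))
    }))
  })
  expect_true(all(diff(mean_rich) <= 0))
})

test_that("segregating sites increase with the pool mutation rate", {
  S_at <- sapply(c(0.5, 4), function(mu) {
    mean(sapply(1:10, function(s) {
      pool <- simulate_pool(K = 10, L = 200, mu = mu, seed = 900 + s)
      coh <- sample_cohorts(pool, n_ancient = 5, n_modern = 50, miss_rate = 0,
                            deam_rate = 0, seed = 950 + s)
      call_haplotypes(coh)$S
    }))
  })
  expect_gt(S_at[2], S_at[1])
})

test_that("degrade is the identity at zero rates and deterministic under seed", {
  rows <- do.call(rbind, strsplit(rand_seqs(20, 40), ""))
  expect_identical(degrade(rows, 0, 1, 0), rows)
  a <- degrade(rows, 0.1, 3, 0.05, seed = 1)
  b <- degrade(rows, 0.1, 3, 0.05, seed = 1)
  expect_identical(a, b)
})

test_that("full deamination converts the 5' half of an all-C row to T", {
  rows <- matrix("C", 2, 10)
  out <- degrade(rows, miss_rate = 0, end_bias = 1, deam_rate = 0.999999,
                 seed = 1)
  expect_true(all(out[, 1:5] == "T"))
  expect_true(all(out[, 6:10] == "C"))
  # and G -> A only in the 3' half
  rows_g <- matrix("G", 2, 10)
  out_g <- degrade(rows_g, 0, 1, 0.999999, seed = 1)
  expect_true(all(out_g[, 1:5] == "G"))
  expect_true(all(out_g[, 6:10] == "A"))
})

test_that("flat missingness hits the binomial expectation", {
  set.seed(99)
  rows <- do.call(rbind, strsplit(rand_seqs(100, 300), ""))
  out <- degrade(rows, miss_rate = 0.1, end_bias = 1, deam_rate = 0, seed = 13)
  n_N <- sum(out == "N")
  expected <- 100 * 300 * 0.1
  sd3 <- 3 * sqrt(100 * 300 * 0.1 * 0.9)
  expect_lt(abs(n_N - expected), sd3)
})

test_that("end bias concentrates missingness at the alignment termini", {
  rows <- do.call(rbind, strsplit(rand_seqs(200, 100), ""))
  out <- degrade(rows, miss_rate = 0.05, end_bias = 8, deam_rate = 0, seed = 17)
  ends <- mean(out[, c(1:10, 91:100)] == "N")
  centre <- mean(out[, 41:60] == "N")
  expect_gt(ends, centre)
})

test_that("morphometric simulation records truth and respects group sizes", {
  md <- simulate_morphometrics(n_big = 7, n_small = 4, seed = 21)
  expect_equal(sum(md$truth == "big"), 7)
  expect_equal(nrow(md$data), 11)
  expect_equal(md$element, "astragalus")
  expect_true(all(md$data$product == md$data$x * md$data$y))
  single <- simulate_morphometrics(n_big = 0, n_small = 6, seed = 22)
  expect_equal(unique(single$truth), "small")
  expect_error(simulate_morphometrics(rho = 1.2, seed = 1), "covariance")
  a <- simulate_morphometrics(seed = 30); b <- simulate_morphometrics(seed = 30)
  expect_identical(a, b)
})
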