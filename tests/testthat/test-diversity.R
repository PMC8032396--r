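test_that("haplotype calling collapses identical rows and counts segregating sites", {
  expect_equal(length(call_haplotypes(make_aset(rep("ACGTACGT", 3)))$keys), 1)
  expect_equal(call_haplotypes(make_aset(rep("ACGTACGT", 3)))$S, 0)

  ht <- call_haplotypes(make_aset(c("ACGT", "ACGA", "ACGA", "TCGA")))
  expect_equal(length(ht$keys), 3)
  expect_equal(ht$keys[1], "ACGA")              # most frequent first
  expect_equal(ht$counts$total, c(2, 1, 1))
  expect_equal(ht$keys[2:3], c("ACGT", "TCGA")) # tie broken by first appearance
  expect_equal(ht$S, 2)                         # columns 1 and 4
  expect_equal(ht$retained_sites, 1:4)
  # member sets partition the ids
  expect_setequal(unlist(ht$members), paste0("s", 1:4))
  expect_equal(sum(ht$counts$total), ht$n)
})

test_that("deletion policies treat gaps as mask vs literal state", {
  aset <- make_aset(c("AC-T", "ACGT"))
  cd <- call_haplotypes(aset, "complete_deletion")
  expect_equal(cd$keys, "ACT")
  expect_equal(cd$retained_sites, c(1, 2, 4))
  st <- call_haplotypes(aset, "strict")
  expect_equal(length(st$keys), 2)
  expect_equal(st$S, 1)
  # complete deletion with nothing left is an error naming the policy
  expect_error(call_haplotypes(make_aset(c("-N", "N-")), "complete_deletion"),
               "complete_deletion")
})

test_that("Hd matches hand values and errors below n = 2", {
  expect_equal(haplotype_diversity(c(5)), 0)
  expect_equal(haplotype_diversity(c(1, 1, 1)), 1)   # all distinct -> 1.00
  expect_equal(haplotype_diversity(c(2, 2, 1)), 0.8)
  expect_error(haplotype_diversity(c(1)), "n >= 2")
})

test_that("Hd equals the pair-counting oracle on random configurations", {
  set.seed(31)
  for (rep in 1:100) {
    k <- sample(1:6, 1)
    counts <- rmultinom(1, sample(2:12, 1), rep(1, k))[, 1]
    counts <- counts[counts > 0]
    if (sum(counts) < 2) next
    expect_equal(haplotype_diversity(counts), oracle_hd_paircount(counts),
                 tolerance = 1e-12)
  }
})

test_that("pi matches hand-computed pairwise-deletion values", {
  expect_equal(as.numeric(nucleotide_diversity(make_aset(rep("ACGTT", 4)))), 0)
  expect_equal(as.numeric(nucleotide_diversity(make_aset(c("ACGT", "ACGA", "ACNA")))),
               7 / 36, tolerance = 1e-12)
  expect_equal(as.numeric(nucleotide_diversity(make_aset(c("ACGT", "TGAC")))), 1)
  expect_error(nucleotide_diversity(make_aset(c("NNNN", "NNNN"))),
               "no pair")
  # a pair with zero comparable sites is dropped with a message
  expect_message(nucleotide_diversity(make_aset(c("ANN", "NNA", "AAA"))),
                 "1 pair")
})

test_that("pi equals the triple-loop brute force on random degraded cohorts", {
  set.seed(32)
  for (rep in 1:40) {
    n <- sample(3:8, 1); L <- sample(5:12, 1)
    seqs <- rand_seqs(n, L, p_missing = 0.15)
    aset <- make_aset(seqs)
    impl <- try(suppressMessages(nucleotide_diversity(aset)), silent = TRUE)
    if (inherits(impl, "try-error")) next
    expect_equal(as.numeric(impl), oracle_pi_bruteforce(seqs), tolerance = 1e-12)
  }
})

test_that("pi on gap-free data agrees with the classic mean pairwise difference (ape)", {
  skip_if_not_installed("ape")
  set.seed(33)
  seqs <- rand_seqs(10, 40)
  aset <- make_aset(seqs)
  dnabin <- ape::as.DNAbin(aset$seqs)
  d <- ape::dist.dna(dnabin, model = "raw", pairwise.deletion = TRUE)
  expect_equal(as.numeric(nucleotide_diversity(aset)), mean(d),
               tolerance = 1e-10)
})

test_that("diversity statistics are invariant to row order and duplicate rows keep S", {
  set.seed(34)
  seqs <- rand_seqs(8, 20, p_missing = 0.1)
  aset <- make_aset(seqs)
  perm <- sample(8)
  aset_p <- make_aset(seqs[perm], ids = paste0("s", perm))
  s1 <- suppressMessages(diversity_summary(aset))
  s2 <- suppressMessages(diversity_summary(aset_p))
  expect_equal(s1$Hd, s2$Hd)
  expect_equal(s1$S, s2$S)
  expect_equal(s1$pi, s2$pi, tolerance = 1e-12)
  # adding a duplicate row leaves complete-deletion S unchanged
  dup <- make_aset(c(seqs, seqs[1]), ids = paste0("s", 1:9))
  expect_equal(call_haplotypes(dup)$S, call_haplotypes(aset)$S)
})

test_that("diversity_summary bundles consistent statistics", {
  aset <- make_aset(c("ACGT", "ACGA", "ACGA", "TCGA"))
  ds <- diversity_summary(aset)
  expect_equal(ds$n, 4)
  expect_equal(ds$h, 3)
  expect_equal(ds$Hd, 5 / 6, tolerance = 1e-12)   # (4/3)(1 - 6/16); pair count 10/12
  expect_equal(ds$Hd, oracle_hd_paircount(c(2, 1, 1)), tolerance = 1e-12)
  expect_equal(ds$S, 2)
  # monomorphic cohort from a K=1 pool
  pool <- simulate_pool(K = 1, L = 30, seed = 1)
  coh <- sample_cohorts(pool, n_ancient = 3, n_modern = 5, miss_rate = 0,
                        deam_rate = 0, seed = 2)
  ds0 <- diversity_summary(coh)
  expect_equal(c(ds0$h, ds0$Hd, ds0$S, ds0$pi), c(1, 0, 0, 0))
})
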