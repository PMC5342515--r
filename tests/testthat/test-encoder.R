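test_that("kmer frequencies match the worked examples and sum to 1", {
  f1 <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(f1["AA"]), 1)
  expect_equal(sum(f1), 1)

  expect_equal(unname(kmer_frequencies("ACGT", 1)), rep(0.25, 4))

  f2 <- kmer_frequencies("ACGT", 2)
  expect_equal(unname(f2[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(sum(f2), 1)
  expect_identical(names(f2), kmer_names(2))

  expect_error(kmer_frequencies("ACGN", 2), "position 4")
  expect_error(kmer_frequencies("AC", 3), "shorter than k")
  expect_message(kmer_frequencies("acgt", 1), "uppercase")
})

test_that("tier theta handles degenerate sequences and matches the brute-force oracle", {
  tab <- toy_table(2)
  expect_equal(tier_theta("AAAAAA", 1, tab), 0)

  # period-2 sequence: identical dinucleotides align at even lags
  s <- paste(rep("AC", 10), collapse = "")
  expect_equal(tier_theta(s, 2, tab), 0)
  expect_equal(tier_theta(s, 1, tab), theta_correlation("AC", "CA", tab))

  set.seed(7)
  for (rep_i in 1:5) {
    x <- random_dna(20)
    j <- sample(1:5, 1)
    expect_equal(tier_theta(x, j, tab), naive_tier_theta(x, j, tab),
                 tolerance = 1e-12)
  }
  expect_error(tier_theta("ACGT", 3, tab), "out of range")
})

test_that("pseknc reduces correctly in its limiting cases", {
  tab <- toy_table(2)
  # homopolymer: all correlation tiers vanish, k-mer block is one-hot
  v <- pseknc(strrep("A", 300), k = 2, lambda = 5, w = 0.5, table = tab)
  expect_equal(unname(v[paste0("theta_", 1:5)]), rep(0, 5))
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)

  # w -> 0: pseudo block vanishes, k-mer block tends to the raw frequencies
  set.seed(1)
  s <- random_dna(80)
  v0 <- pseknc(s, k = 2, lambda = 3, w = 1e-12, table = tab)
  expect_lt(max(abs(v0[paste0("theta_", 1:3)])), 1e-10)
  expect_equal(unname(v0[kmer_names(2)]), unname(kmer_frequencies(s, 2)),
               tolerance = 1e-9)
})

test_that("pseknc agrees with the naive transcription on random triples", {
  set.seed(123)
  for (rep_i in 1:25) {
    tab <- toy_table(sample(1:4, 1))
    k <- sample(1:3, 1)
    lambda <- sample(1:6, 1)
    w <- sample((1:10) / 10, 1)
    s <- random_dna(sample(30:70, 1))
    got <- pseknc(s, k, lambda, w, table = tab)
    want <- naive_encode(s, k, lambda, w, tab)
    expect_equal(as.vector(got), unname(want), tolerance = 1e-10)
  }
})

test_that("feature vectors are normalized with the lawful dimension for all configs", {
  tab <- toy_table(3)
  set.seed(5)
  for (rep_i in 1:20) {
    k <- sample(1:4, 1)
    lambda <- sample(1:8, 1)
    w <- sample((1:10) / 10, 1)
    s <- random_dna(sample(40:120, 1))
    v <- pseknc(s, k, lambda, w, table = tab)
    expect_length(v, 4^k + lambda)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
  # the benchmark configuration's dimension
  v <- pseknc(random_dna(300), k = 4, lambda = 7, w = 0.9, table = tab)
  expect_length(v, 263)
})

test_that("pseknc rejects infeasible configurations and batch reports the bad record", {
  tab <- toy_table(2)
  expect_error(pseknc("ACGT", k = 2, lambda = 3, w = 0.5, table = tab),
               "lambda")
  expect_warning(pseknc(random_dna(40), k = 5, lambda = 1, w = 0.5, table = tab),
                 "outside the usual range")
  expect_warning(pseknc(random_dna(40), k = 2, lambda = 1, w = 1.5, table = tab),
                 "outside the usual range")

  seqs <- c(random_dna(50), "ACGTNACGTACGTACGTACG", random_dna(50))
  expect_error(pseknc_matrix(seqs, k = 2, lambda = 3, w = 0.5, table = tab),
               "record 2")
  X <- pseknc_matrix(c(a = random_dna(50), b = random_dna(50)),
                     k = 2, lambda = 3, w = 0.5, table = tab)
  expect_identical(dim(X), c(2L, 19L))
  expect_identical(rownames(X), c("a", "b"))
  expect_equal(unname(rowSums(X)), c(1, 1), tolerance = 1e-9)
})

test_that("theta tiers ignore property-table columns of absent dinucleotides", {
  tab <- toy_table(2)
  s <- paste(rep("ACG", 20), collapse = "")           # uses AC, CG, GA only
  present <- c("AC", "CG", "GA")
  vals <- unclass(tab)[, dinucleotides()]
  perturbed <- vals
  absent <- setdiff(dinucleotides(), present)
  perturbed[, absent] <- vals[, sample(absent)]        # permute unused columns
  tab2 <- property_table(perturbed, standardized = TRUE)
  for (j in 1:3)
    expect_equal(tier_theta(s, j, tab), tier_theta(s, j, tab2))
})
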