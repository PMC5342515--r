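test_that("FASTA round-trip preserves order and content; malformed files error", {
  fa <- tempfile(fileext = ".fa")
  seqs <- c(rec1 = "ACGTACGT", rec2 = "GGGGCCCC", rec3 = "ATATATAT")
  write_fasta(seqs, fa)
  got <- read_fasta(fa)
  expect_identical(names(got), names(seqs))
  expect_identical(unname(got), unname(seqs))

  writeLines(c("ACGT", "GGGG"), fa)
  expect_error(read_fasta(fa), "no '>' header")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("upstream negatives come from exactly [-600, -300) of the ORI start", {
  ctx <- random_dna(900)
  neg <- extract_negative(ctx, 600)
  expect_identical(neg, substr(ctx, 1, 300))
  expect_error(extract_negative(ctx, 599), "insufficient upstream")

  # marked-prefix fixture: a recognizable 300-bp block planted at [-600, -300)
  marker <- strrep("ACGT", 75)
  ctx2 <- paste0(random_dna(100), marker, random_dna(300), random_dna(200))
  ori_start <- 100 + 300 + 300                # marker ends 300 bp before this
  expect_identical(extract_negative(ctx2, ori_start), marker)

  # never overlaps the origin: the segment ends 300 bases before ori_start
  set.seed(3)
  for (rep_i in 1:10) {
    start <- sample(600:880, 1)
    ctx3 <- random_dna(start + 20)
    seg <- extract_negative(ctx3, start)
    expect_identical(nchar(seg), 300L)
    expect_identical(seg, substr(ctx3, start - 599, start - 300))
  }
})

test_that("benchmark loading labels from headers and validates lengths", {
  fa <- tempfile(fileext = ".fa")
  seqs <- setNames(replicate(6, random_dna(300)),
                   c(paste0("ORI_", 1:3), paste0("nonORI_", 1:3)))
  write_fasta(seqs, fa)
  ds <- suppressWarnings(load_benchmark(fa))
  expect_identical(as.vector(table(ds$label)), c(3L, 3L))
  expect_warning(load_benchmark(fa), "reference: 283")
  expect_silent(ds2 <- load_benchmark(fa, expected_counts = NULL))
  expect_identical(ds2$sequence, unname(seqs))

  seqs_bad <- c(seqs, ORI_short = random_dna(120))
  write_fasta(seqs_bad, fa)
  expect_error(suppressWarnings(load_benchmark(fa)), "300 bp")
})

test_that("the synthetic generator is seed-deterministic with the stated endpoints", {
  a <- synthesize_dataset(10, 60, epsilon = 0.5, seed = 99)
  b <- synthesize_dataset(10, 60, epsilon = 0.5, seed = 99)
  expect_identical(a, b)
  d <- synthesize_dataset(10, 60, epsilon = 0.5, seed = 100)
  expect_false(identical(a$sequence, d$sequence))

  expect_error(synthesize_dataset(10, 60, epsilon = 1.2, seed = 1), "epsilon")
  expect_error(synthesize_dataset(0, 60, epsilon = 0, seed = 1), "n_per_class")
  expect_error(synthesize_dataset(10, 5, epsilon = 0, seed = 1), "length")

  # epsilon = 0: both classes use the identical uniform chain, so swapping
  # the class labels of a regenerated dataset gives the same distribution;
  # check the per-class base composition is statistically indistinguishable
  null_ds <- synthesize_dataset(50, 300, epsilon = 0, seed = 7)
  at_freq <- function(seqs) {
    d <- unlist(lapply(seqs, function(s) {
      cod <- oriforest:::dinuc_codes(s)
      mean(cod %in% c(4L, 13L))                 # AT = 4, TA = 13
    }))
    mean(d)
  }
  f_ori <- at_freq(null_ds$sequence[null_ds$label == "ORI"])
  f_non <- at_freq(null_ds$sequence[null_ds$label == "nonORI"])
  expect_lt(abs(f_ori - f_non), 0.02)

  # epsilon = 0.8: AT/TA dinucleotides visibly enriched in the ORI class
  sep_ds <- synthesize_dataset(100, 300, epsilon = 0.8, seed = 7)
  expect_gt(at_freq(sep_ds$sequence[sep_ds$label == "ORI"]),
            at_freq(sep_ds$sequence[sep_ds$label == "nonORI"]) + 0.05)
})

test_that("the dataset manifest records ids, labels, lengths and provenance", {
  ds <- synthesize_dataset(3, 50, epsilon = 0, seed = 1)
  tsv <- tempfile(fileext = ".tsv")
  write_manifest(ds, tsv)
  man <- read.delim(tsv)
  expect_identical(nrow(man), 6L)
  expect_true(all(man$length == 50))
  expect_true(all(grepl("synthesize_dataset", man$source)))
})
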