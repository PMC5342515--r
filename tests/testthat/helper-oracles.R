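# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the R/ sources: plain loops and
# direct transcriptions of the defining formulas.

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")

# Deterministic toy property table with phi rows (distinct columns).
toy_table <- function(phi = 2, standardized = TRUE) {
  set.seed(42 + phi)
  vals <- matrix(round(stats::rnorm(phi * 16), 3), nrow = phi,
                 dimnames = list(paste0("p", seq_len(phi)), dinucleotides()))
  tab <- property_table(vals)
  if (standardized) standardize_table(tab) else tab
}

# Row-wise (x - mean) / population-SD with its own mean/SD arithmetic.
naive_standardize <- function(vals) {
  out <- vals
  for (r in seq_len(nrow(vals))) {
    x <- vals[r, ]
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / length(x))
    out[r, ] <- (x - m) / s
  }
  out
}

# Squared-difference correlation, looped over properties.
naive_theta <- function(d1, d2, tab) {
  acc <- 0
  for (r in seq_len(nrow(tab))) acc <- acc + (tab[r, d1] - tab[r, d2])^2
  acc / nrow(tab)
}

# Tier-j correlation factor: double loop over positions and properties.
naive_tier_theta <- function(seq, j, tab) {
  L <- nchar(seq)
  total <- 0
  for (i in seq_len(L - j - 1)) {
    d1 <- substr(seq, i, i + 1)
    d2 <- substr(seq, i + j, i + j + 1)
    total <- total + naive_theta(d1, d2, tab)
  }
  total / (L - j - 1)
}

# k-mer frequencies by explicit window walk (no Biostrings).
naive_kmer_freq <- function(seq, k) {
  km <- kmer_names(k)
  counts <- setNames(numeric(length(km)), km)
  L <- nchar(seq)
  for (i in seq_len(L - k + 1)) {
    word <- substr(seq, i, i + k - 1)
    counts[word] <- counts[word] + 1
  }
  counts / (L - k + 1)
}

# Direct transcription of the type-1 PseKNC definition.
naive_encode <- function(seq, k, lambda, w, tab) {
  f <- naive_kmer_freq(seq, k)
  theta <- vapply(seq_len(lambda), function(j) naive_tier_theta(seq, j, tab),
                  numeric(1))
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

# Conventional confusion-matrix metrics from TP/TN/FP/FN.
conventional_metrics <- function(P, N, fn, fp) {
  tp <- P - fn; tn <- N - fp
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(Sn = tp / P, Sp = tn / N, Acc = (tp + tn) / (P + N),
       MCC = if (den == 0) NA_real_ else (tp * tn - fp * fn) / den)
}
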