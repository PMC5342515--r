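#' @importFrom Biostrings DNAString oligonucleotideFrequency readDNAStringSet
#'   reverseComplement DNAStringSet
NULL

# Validate a DNA sequence string: upcase lowercase (with a notice), reject
# anything outside A/C/G/T reporting the first offending position.
validate_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  if (grepl("[acgt]", seq)) {
    message("note: lowercase bases in ", what, " converted to uppercase")
    seq <- toupper(seq)
  }
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d of %s: only A, C, G, T are allowed",
                 substr(seq, bad, bad), bad, what))
  if (nchar(seq) == 0L) stop(what, " is empty")
  seq
}

# Map a validated sequence to the integer codes 1..16 of its successive
# dinucleotides, in lexicographic dinucleotide order.
dinuc_codes <- function(seq) {
  base <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  n <- length(base)
  4L * (base[-n] - 1L) + base[-1L]
}

#' All k-mers over \{A, C, G, T\} in lexicographic order
#'
#' @param k Word length (positive integer).
#' @return Character vector of length `4^k`.
#' @export
kmer_names <- function(k) {
  stopifnot(k >= 1L)
  b <- c("A", "C", "G", "T")
  out <- b
  if (k > 1L) for (i in 2:k) out <- as.vector(t(outer(out, b, paste0)))
  out
}

#' Normalized k-mer frequencies of a DNA sequence
#'
#' Counts the overlapping k-mers at all `L - k + 1` positions of the
#' sequence and divides by that window count, so the frequencies sum to 1.
#' Output is in lexicographic k-mer order.
#'
#' @param seq DNA sequence string (A/C/G/T; lowercase is upcased with a
#'   notice, any other character is an error reporting its position).
#' @param k Word length; the sequence must be at least `k` long.
#' @return Named numeric vector of length `4^k`.
#' @export
#' @examples
#' kmer_frequencies("ACGT", 1)
#' kmer_frequencies("ACGT", 2)
kmer_frequencies <- function(seq, k) {
  seq <- validate_dna(seq)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  L <- nchar(seq)
  if (L < k)
    stop(sprintf("sequence length %d is shorter than k = %d", L, k))
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  counts / (L - k + 1)
}

#' Tier-j structural correlation factor of a sequence
#'
#' Averages the dinucleotide correlation function over all pairs of
#' dinucleotides separated by lag `j`: positions `(i, i+1)` versus
#' `(i+j, i+j+1)`, for `i = 1, ..., L - j - 1`. Tier `j` therefore
#' requires `L >= j + 2`.
#'
#' @param seq DNA sequence string.
#' @param j Correlation tier (lag), `1 <= j <= L - 2`.
#' @param table A standardized [property_table()].
#' @return A non-negative scalar.
#' @export
tier_theta <- function(seq, j, table) {
  seq <- validate_dna(seq)
  j <- as.integer(j)
  L <- nchar(seq)
  if (j < 1L || j > L - 2L)
    stop(sprintf("correlation tier j = %d out of range for length-%d sequence (need 1 <= j <= L - 2)",
                 j, L))
  tm <- theta_matrix(table)
  d <- dinuc_codes(seq)
  m <- length(d)                       # L - 1 dinucleotides
  mean(tm[cbind(d[seq_len(m - j)], d[(1L + j):m])])
}

# Shared core: kmer frequencies + theta tiers -> PseKNC vector.
pseknc_core <- function(seq, k, lambda, w, tm) {
  L <- nchar(seq)
  f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                            width = k) / (L - k + 1)
  d <- dinuc_codes(seq)
  m <- length(d)
  theta <- vapply(seq_len(lambda), function(j)
    mean(tm[cbind(d[seq_len(m - j)], d[(1L + j):m])]), numeric(1))
  denom <- 1 + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  names(out) <- c(names(f), paste0("theta_", seq_len(lambda)))
  out
}

check_config <- function(k, lambda, w) {
  k <- as.integer(k); lambda <- as.integer(lambda); w <- as.numeric(w)
  if (k < 1L) stop("k must be >= 1")
  if (lambda < 1L) stop("lambda must be >= 1")
  if (w <= 0) stop("w must be > 0")
  if (k > 4L) warning("k = ", k, " is outside the usual range 1..4")
  if (w > 1) warning("w = ", w, " is outside the usual range (0, 1]")
  list(k = k, lambda = lambda, w = w)
}

#' Encode a DNA sequence as a type-1 PseKNC feature vector
#'
#' The pseudo k-tuple nucleotide composition combines the local k-mer
#' frequencies of a sequence with `lambda` tiers of long-range structural
#' autocorrelation computed from dinucleotide physicochemical properties.
#' The resulting vector has dimension `Z = 4^k + lambda`: the first `4^k`
#' components are the k-mer frequencies `f_u / (1 + w * sum(theta))`, the
#' last `lambda` are the weighted correlation factors
#' `w * theta_j / (1 + w * sum(theta))`. All components are non-negative
#' and sum to exactly 1.
#'
#' @param seq DNA sequence string; must satisfy `L >= k` and
#'   `lambda <= L - 2`.
#' @param k K-mer tier of the local composition (usually 1..4).
#' @param lambda Number of correlation tiers (>= 1).
#' @param w Weight balancing the k-mer block against the correlation
#'   block (usually in (0, 1]).
#' @param table A standardized [property_table()]; defaults to the bundled
#'   six-property table.
#' @return Named numeric vector of length `4^k + lambda`, with the
#'   encoding recorded in the `"config"` attribute.
#' @seealso [pseknc_matrix()] for encoding many sequences,
#'   [ori_rf()] which encodes and classifies in one step.
#' @export
#' @examples
#' v <- pseknc(paste(rep("ACGT", 25), collapse = ""), k = 2, lambda = 3, w = 0.5)
#' sum(v)          # exactly 1
#' length(v)       # 4^2 + 3 = 19
pseknc <- function(seq, k = 4, lambda = 7, w = 0.9,
                   table = default_property_table()) {
  cfg <- check_config(k, lambda, w)
  seq <- validate_dna(seq)
  L <- nchar(seq)
  if (L < cfg$k)
    stop(sprintf("sequence length %d is shorter than k = %d", L, cfg$k))
  if (cfg$lambda > L - 2L)
    stop(sprintf("lambda = %d exceeds L - 2 = %d for this sequence",
                 cfg$lambda, L - 2L))
  out <- pseknc_core(seq, cfg$k, cfg$lambda, cfg$w, theta_matrix(table))
  attr(out, "config") <- cfg
  out
}

#' Encode a set of DNA sequences as a PseKNC feature matrix
#'
#' @param seqs Character vector of DNA sequences (names, if any, become
#'   row names).
#' @inheritParams pseknc
#' @return Numeric matrix with one row per sequence and `4^k + lambda`
#'   columns named by k-mer and correlation tier.
#' @export
pseknc_matrix <- function(seqs, k = 4, lambda = 7, w = 0.9,
                          table = default_property_table()) {
  cfg <- check_config(k, lambda, w)
  if (length(seqs) == 0L) stop("no sequences supplied")
  tm <- theta_matrix(table)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- tryCatch(validate_dna(seqs[[i]]), error = function(e)
      stop(sprintf("record %d: %s", i, conditionMessage(e)), call. = FALSE))
    L <- nchar(s)
    if (L < cfg$k || cfg$lambda > L - 2L)
      stop(sprintf("record %d: length %d incompatible with k = %d, lambda = %d",
                   i, L, cfg$k, cfg$lambda))
    rows[[i]] <- pseknc_core(s, cfg$k, cfg$lambda, cfg$w, tm)
  }
  X <- do.call(rbind, rows)
  rownames(X) <- names(seqs)
  attr(X, "config") <- cfg
  X
}

#' Write a PseKNC feature matrix as TSV
#'
#' @param x Matrix from [pseknc_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(x, path) {
  df <- data.frame(id = if (is.null(rownames(x))) seq_len(nrow(x)) else rownames(x),
                   x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
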