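#' Read a multi-FASTA file of DNA sequences
#'
#' Record order is preserved. The file must start with a `>` header and
#' every record must carry a non-empty sequence.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the full header
#'   lines (without `>`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first, ">"))
    stop("not a FASTA file (no '>' header on the first line): ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  if (any(Biostrings::width(ss) == 0L))
    stop("FASTA record with empty sequence: ",
         names(ss)[which(Biostrings::width(ss) == 0L)[1L]])
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ss <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(ss))) names(ss) <- paste0("seq", seq_along(ss))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Extract the upstream non-ORI segment matched to an annotated ORI
#'
#' Given the genomic context of an annotated replication origin, returns
#' the 300-bp segment lying in the window 600 to 300 bases upstream of the
#' ORI start — i.e. `context[ori_start - 600, ori_start - 300)` in 0-based
#' half-open coordinates. The extracted negative therefore never overlaps
#' the origin and ends exactly 300 bases before it.
#'
#' @param context DNA sequence containing the ORI and its upstream flank.
#' @param ori_start 0-based position of the first ORI base within
#'   `context`; must be at least 600.
#' @return A 300-character DNA string.
#' @export
extract_negative <- function(context, ori_start) {
  context <- validate_dna(context, "context")
  ori_start <- as.integer(ori_start)
  if (ori_start < 600L)
    stop(sprintf("insufficient upstream context: ori_start = %d < 600", ori_start))
  if (ori_start > nchar(context))
    stop("ori_start lies beyond the end of the context sequence")
  substr(context, ori_start - 600L + 1L, ori_start - 300L)
}

#' Load a labelled ORI / non-ORI benchmark from FASTA
#'
#' Labels are taken from the record headers: a header containing
#' `non-ORI`/`nonORI`/`non_ORI` (case-insensitive) is negative, any other
#' header containing `ORI` is positive. Alternatively pass the positive
#' and negative sets as two files. All sequences are checked to be 300 bp
#' (the benchmark window length); a warning is issued if the class counts
#' differ from the reference benchmark's 283 ORI + 282 non-ORI.
#'
#' @param path FASTA with labels in headers, or the positive-set FASTA
#'   when `negative_path` is given.
#' @param negative_path Optional FASTA holding the negative set.
#' @param expected_counts Reference class sizes used for the count
#'   warning; `c(ORI = 283, nonORI = 282)` by default.
#' @return A labelled dataset: `data.frame` with columns `id`, `sequence`
#'   and `label` (factor with levels `nonORI`, `ORI`).
#' @export
load_benchmark <- function(path, negative_path = NULL,
                           expected_counts = c(ORI = 283L, nonORI = 282L)) {
  if (is.null(negative_path)) {
    seqs <- read_fasta(path)
    is_neg <- grepl("non[-_ ]?ori", names(seqs), ignore.case = TRUE)
    is_pos <- !is_neg & grepl("ori", names(seqs), ignore.case = TRUE)
    if (any(!is_neg & !is_pos))
      stop("cannot label record(s) from header: ",
           names(seqs)[which(!is_neg & !is_pos)[1L]])
    label <- factor(ifelse(is_neg, "nonORI", "ORI"),
                    levels = c("nonORI", "ORI"))
  } else {
    pos <- read_fasta(path)
    neg <- read_fasta(negative_path)
    seqs <- c(pos, neg)
    label <- factor(rep(c("ORI", "nonORI"), c(length(pos), length(neg))),
                    levels = c("nonORI", "ORI"))
  }
  ids <- make.unique(sub("\\s.*$", "", names(seqs)))
  len <- nchar(seqs)
  if (any(len != 300L))
    stop("benchmark sequences must be 300 bp; offending record: ",
         ids[which(len != 300L)[1L]], " (", len[which(len != 300L)[1L]], " bp)")
  counts <- table(label)
  if (!is.null(expected_counts) &&
      (counts[["ORI"]] != expected_counts[["ORI"]] ||
       counts[["nonORI"]] != expected_counts[["nonORI"]]))
    warning(sprintf("benchmark has %d ORI + %d non-ORI records (reference: %d + %d)",
                    counts[["ORI"]], counts[["nonORI"]],
                    expected_counts[["ORI"]], expected_counts[["nonORI"]]))
  ds <- data.frame(id = ids, sequence = unname(seqs), label = label,
                   stringsAsFactors = FALSE)
  attr(ds, "provenance") <- paste0("load_benchmark(", path, ")")
  ds
}

# Fixed AT/TA-skewed transition matrix used as the epsilon = 1 endpoint of
# the synthetic ORI class. Rows: from-base A, C, G, T; columns: to-base.
# Doubly stochastic, so the stationary single-base composition stays
# uniform and the class signal lives at the dinucleotide level.
skewed_transitions <- function() {
  m <- rbind(A = c(0.10, 0.10, 0.10, 0.70),
             C = c(0.10, 0.40, 0.40, 0.10),
             G = c(0.10, 0.40, 0.40, 0.10),
             T = c(0.70, 0.10, 0.10, 0.10))
  colnames(m) <- c("A", "C", "G", "T")
  m
}

# Sample n sequences of the given length from a first-order Markov chain
# with transition matrix P (uniform initial distribution), vectorized over
# sequences.
sample_markov <- function(n, length, P) {
  bases <- c("A", "C", "G", "T")
  cum <- t(apply(P, 1L, cumsum))
  out <- matrix(0L, nrow = n, ncol = length)
  out[, 1L] <- sample.int(4L, n, replace = TRUE)
  for (pos in 2:length) {
    u <- stats::runif(n)
    prev <- out[, pos - 1L]
    out[, pos] <- 1L + (u > cum[prev, 1L]) + (u > cum[prev, 2L]) +
      (u > cum[prev, 3L])
  }
  apply(out, 1L, function(row) paste(bases[row], collapse = ""))
}

#' Generate a synthetic labelled ORI / non-ORI dataset
#'
#' Emulates the two-class structure of the benchmark with first-order
#' Markov sequences. The non-ORI class is drawn from the uniform chain
#' (all transition probabilities 1/4). The ORI class is drawn from the
#' uniform chain interpolated by `epsilon` toward a fixed AT/TA-enriched
#' transition matrix, so `epsilon = 0` makes the classes statistically
#' identical and `epsilon = 1` makes them strongly separable through
#' dinucleotide composition. The same seed always reproduces the same
#' dataset.
#'
#' @param n_per_class Number of sequences per class (>= 1).
#' @param length Sequence length in bp (>= 10); 300 matches the benchmark
#'   window.
#' @param epsilon Class-separation parameter in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A labelled dataset `data.frame` (columns `id`, `sequence`,
#'   `label`) with a provenance attribute.
#' @export
#' @examples
#' ds <- synthesize_dataset(5, 50, epsilon = 1, seed = 1)
#' table(ds$label)
synthesize_dataset <- function(n_per_class, length = 300L, epsilon, seed) {
  n_per_class <- as.integer(n_per_class)
  length <- as.integer(length)
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (length < 10L) stop("length must be >= 10")
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon > 1)
    stop("epsilon must lie in [0, 1]")
  uniform <- matrix(0.25, 4L, 4L, dimnames = list(c("A", "C", "G", "T"),
                                                  c("A", "C", "G", "T")))
  ori_P <- (1 - epsilon) * uniform + epsilon * skewed_transitions()
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  neg <- sample_markov(n_per_class, length, uniform)
  pos <- sample_markov(n_per_class, length, ori_P)
  ds <- data.frame(
    id = c(sprintf("nonORI_%03d", seq_len(n_per_class)),
           sprintf("ORI_%03d", seq_len(n_per_class))),
    sequence = c(neg, pos),
    label = factor(rep(c("nonORI", "ORI"), each = n_per_class),
                   levels = c("nonORI", "ORI")),
    stringsAsFactors = FALSE)
  attr(ds, "provenance") <- sprintf(
    "synthesize_dataset(n_per_class=%d, length=%d, epsilon=%g, seed=%d)",
    n_per_class, length, epsilon, as.integer(seed))
  ds
}

#' Write a dataset manifest TSV
#'
#' @param data Labelled dataset (`id`, `sequence`, `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(data, path) {
  man <- data.frame(id = data$id, label = as.character(data$label),
                    length = nchar(data$sequence),
                    source = attr(data, "provenance") %||% "unknown")
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
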