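#' Scan a long query with a sliding 300-bp window
#'
#' Applies a fitted classifier to every window of the query: window i
#' (1-based) covers residues i .. i + window - 1, i.e. the 0-based
#' half-open interval [i - 1, i - 1 + window). A query of length L yields
#' `L - window + 1` windows at step 1 (a 514-bp query gives 215), and a
#' query exactly one window long yields a single call. All windows are
#' encoded with the model's own configuration and scored in one batch.
#'
#' @param seq Query DNA sequence, at least `window` bp long.
#' @param model An [ori_rf()] fit.
#' @param window Window width in bp (default 300, the width the
#'   classifier was designed for).
#' @param step Step between successive window starts (default 1).
#' @param threshold Vote-fraction threshold for the per-window call.
#' @param id Query identifier carried into the result.
#' @param both_strands If `TRUE`, also scan the reverse complement and
#'   report a `strand` column.
#' @return An object of class `ori_scan`: `data.frame` with columns
#'   `window` (1-based index), `start0`, `end0` (0-based half-open),
#'   `label`, `score` (and `strand` when both strands are scanned), with
#'   the query id and parameters in attributes.
#' @seealso [merge_calls()], [write_scan_tsv()], [write_bed()]
#' @export
scan_sequence <- function(seq, model, window = 300L, step = 1L,
                          threshold = 0.5, id = "query",
                          both_strands = FALSE) {
  stopifnot(inherits(model, "ori_rf"))
  seq <- validate_dna(seq, paste0("query '", id, "'"))
  window <- as.integer(window); step <- as.integer(step)
  L <- nchar(seq)
  if (L < window)
    stop(sprintf("query '%s' is %d bp; input sequences must be %d bp or longer",
                 id, L, window))
  scan_one <- function(s, strand) {
    starts <- seq.int(1L, nchar(s) - window + 1L, by = step)
    subs <- substring(s, starts, starts + window - 1L)
    score <- predict(model, subs, type = "score")
    out <- data.frame(window = seq_along(starts), start0 = starts - 1L,
                      end0 = starts - 1L + window,
                      label = classify_score(score, threshold),
                      score = score)
    if (both_strands) out$strand <- strand
    out
  }
  res <- scan_one(seq, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    res <- rbind(res, scan_one(rc, "-"))
  }
  structure(res, id = id, window = window, step = step,
            threshold = threshold, class = c("ori_scan", "data.frame"))
}

#' Merge consecutive identical window calls into intervals
#'
#' Collapses the per-window calls of a scan into maximal runs of the same
#' label. The merge is lossless: expanding each interval back into its
#' window indices reproduces the per-window label sequence exactly.
#'
#' @param result An `ori_scan` from [scan_sequence()] (single strand).
#' @return `data.frame` with one row per run: `label`, `from_window`,
#'   `to_window` (1-based, inclusive), `start0`, `end0` (0-based
#'   half-open span of the covered windows' union) and `mean_score`.
#' @export
merge_calls <- function(result) {
  stopifnot(inherits(result, "ori_scan"))
  if (!is.null(result$strand) && length(unique(result$strand)) > 1L)
    stop("merge_calls expects a single-strand scan; split by strand first")
  r <- rle(as.character(result$label))
  to <- cumsum(r$lengths)
  from <- to - r$lengths + 1L
  data.frame(label = factor(r$values, levels = c("nonORI", "ORI")),
             from_window = result$window[from],
             to_window = result$window[to],
             start0 = result$start0[from],
             end0 = result$end0[to],
             mean_score = vapply(seq_along(from), function(i)
               mean(result$score[from[i]:to[i]]), numeric(1)))
}

#' Write per-window scan calls as TSV
#'
#' @param result An `ori_scan`.
#' @param path Output path; columns `query`, `window_index`, `start0`,
#'   `end0`, `label`, `score` (and `strand` if present).
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(result, path) {
  df <- data.frame(query = attr(result, "id"),
                   window_index = result$window,
                   start0 = result$start0, end0 = result$end0,
                   label = as.character(result$label),
                   score = result$score)
  if (!is.null(result$strand)) df$strand <- result$strand
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write merged ORI intervals as BED6
#'
#' Emits one BED line per merged ORI run: chrom = query id, 0-based
#' half-open coordinates, name = query id, score = mean window vote
#' fraction scaled by 1000 and truncated, strand `+`.
#'
#' @param result An `ori_scan` from [scan_sequence()].
#' @param path Output path.
#' @param strand Strand character for the BED records (default `"+"`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(result, path, strand = "+") {
  merged <- merge_calls(result)
  ori <- merged[merged$label == "ORI", , drop = FALSE]
  n <- nrow(ori)
  bed <- data.frame(chrom = rep(attr(result, "id"), n),
                    start = ori$start0, end = ori$end0,
                    name = rep(attr(result, "id"), n),
                    score = trunc(ori$mean_score * 1000),
                    strand = rep(strand, n))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
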