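#' The sixteen dinucleotides in lexicographic order
#'
#' @return Character vector of the 16 two-letter dinucleotides over
#'   \{A, C, G, T\}, ordered lexicographically (`"AA"`, `"AC"`, ..., `"TT"`).
#'   This ordering is fixed throughout the package: property-table columns,
#'   k-mer feature names and the correlation matrix all follow it.
#' @export
#' @examples
#' dinucleotides()
dinucleotides <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(b, b, paste0)))
}

#' Construct a dinucleotide physicochemical property table
#'
#' A property table holds one numeric value per (property, dinucleotide)
#' pair: the helical step parameters that enter the structural correlation
#' function [theta_correlation()]. The canonical configuration carries six
#' properties (twist, tilt, roll, shift, slide, rise), i.e. 6 x 16 = 96
#' values, but any number of properties is accepted; the property count is
#' inferred from the table.
#'
#' @param values Numeric matrix, one row per property, 16 columns named by
#'   the dinucleotides in lexicographic order (see [dinucleotides()]).
#'   Row names are the property names.
#' @param standardized Logical; whether `values` have already been
#'   standardized to mean 0, SD 1 per row (see [standardize_table()]).
#' @return An object of class `property_table`: the validated matrix with a
#'   `standardized` attribute.
#' @seealso [load_property_table()], [default_property_table()]
#' @export
property_table <- function(values, standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (properties x 16 dinucleotides)")
  dn <- dinucleotides()
  if (is.null(colnames(values)))
    stop("'values' must have dinucleotide column names")
  missing_dn <- setdiff(dn, colnames(values))
  if (length(missing_dn))
    stop("property table is missing dinucleotide column(s): ",
         paste(missing_dn, collapse = ", "))
  extra <- setdiff(colnames(values), dn)
  if (length(extra))
    stop("property table has unknown column(s): ", paste(extra, collapse = ", "))
  values <- values[, dn, drop = FALSE]
  if (is.null(rownames(values)))
    rownames(values) <- paste0("property", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate property name(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyNA(values))
    stop("property table contains missing (non-numeric or blank) cells")
  structure(values, standardized = isTRUE(standardized),
            class = c("property_table", class(values)))
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("Dinucleotide property table: %d propert%s x 16 dinucleotides (%s)\n",
              nrow(x), if (nrow(x) == 1L) "y" else "ies",
              if (is_standardized(x)) "standardized" else "raw"))
  print(unclass_table(x), ...)
  invisible(x)
}

unclass_table <- function(x) {
  attr(x, "standardized") <- NULL
  class(x) <- "matrix"
  x
}

#' Is a property table standardized?
#'
#' @param table A [property_table()].
#' @return Logical flag.
#' @export
is_standardized <- function(table) isTRUE(attr(table, "standardized"))

#' Read a dinucleotide property table from a delimited text file
#'
#' Expects a header row naming the 16 dinucleotides in lexicographic order
#' and one data row per property, with the property name in the first
#' column. Tab- and comma-separated files are both accepted (the delimiter
#' is sniffed from the header line). The returned table is raw
#' (unstandardized); pass it through [standardize_table()] before computing
#' correlations.
#'
#' @param path Path to the TSV/CSV file.
#' @return A raw [property_table()].
#' @export
load_property_table <- function(path) {
  if (!file.exists(path)) stop("property table file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L) stop("property table must have a name column and dinucleotide columns")
  prop <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals) || any(vals == "" | is.na(vals)))
    stop("property table contains missing cells or non-numeric values")
  rownames(vals) <- prop
  property_table(vals, standardized = FALSE)
}

#' The bundled default six-property table
#'
#' Returns the package's default table of six dinucleotide helical step
#' parameters: the angular parameters twist, tilt and roll (degrees) and
#' the translational parameters shift, slide and rise (angstroms), one
#' value per dinucleotide step (96 values in total). The bundled values
#' are a synthetic stand-in: physically plausible magnitudes obeying
#' complementary-strand symmetry, not measurements from any specific
#' crystallographic survey (the file is named accordingly). Only
#' standardized differences between dinucleotides enter the encoder, and
#' any user table of the same shape can be supplied wherever a
#' `property_table` is accepted.
#'
#' @param standardized Logical; if `TRUE` (default) the table is returned
#'   standardized to per-property mean 0, SD 1.
#' @return A [property_table()] with 6 rows.
#' @export
#' @examples
#' default_property_table()
default_property_table <- function(standardized = TRUE) {
  path <- system.file("extdata", "dinucleotide_properties_synthetic.tsv",
                      package = "oriforest", mustWork = TRUE)
  tab <- load_property_table(path)
  if (standardized) standardize_table(tab) else tab
}

#' Standardize a property table to per-row mean 0, SD 1
#'
#' Each property row is transformed to `(value - mean) / SD`, where mean
#' and SD are taken over the row's 16 dinucleotide entries. The SD uses
#' the population convention (denominator 16), so the operation is
#' idempotent: a standardized row has mean exactly 0 and population SD
#' exactly 1, and re-standardizing changes nothing (to within machine
#' rounding).
#'
#' @param table A [property_table()].
#' @return The standardized [property_table()].
#' @export
standardize_table <- function(table) {
  stopifnot(inherits(table, "property_table"))
  vals <- unclass_table(table)
  mu <- rowMeans(vals)
  sd_pop <- sqrt(rowMeans((vals - mu)^2))
  if (any(sd_pop == 0))
    stop("degenerate property row(s) with zero variance: ",
         paste(rownames(vals)[sd_pop == 0], collapse = ", "))
  property_table((vals - mu) / sd_pop, standardized = TRUE)
}

#' Structural correlation between two dinucleotides
#'
#' The squared-difference correlation function: the mean, over the
#' properties of a standardized table, of the squared difference between
#' the two dinucleotides' property values. It is non-negative, symmetric
#' in its arguments, and zero for identical dinucleotides.
#'
#' @param d1,d2 Dinucleotide symbols, e.g. `"AC"`.
#' @param table A standardized [property_table()].
#' @return A non-negative scalar.
#' @export
#' @examples
#' tab <- default_property_table()
#' theta_correlation("AC", "GT", tab)
theta_correlation <- function(d1, d2, table) {
  stopifnot(inherits(table, "property_table"))
  if (!is_standardized(table))
    stop("property table must be standardized; see standardize_table()")
  for (d in c(d1, d2))
    if (!(d %in% colnames(table)))
      stop("unknown dinucleotide: ", d)
  mean((table[, d1] - table[, d2])^2)
}

# Precomputed 16 x 16 matrix of theta_correlation over all dinucleotide
# pairs; rows/cols in lexicographic dinucleotide order.
theta_matrix <- function(table) {
  stopifnot(inherits(table, "property_table"))
  if (!is_standardized(table))
    stop("property table must be standardized; see standardize_table()")
  v <- unclass_table(table)            # phi x 16
  g <- crossprod(v)                    # 16 x 16 inner products
  sq <- diag(g)
  (outer(sq, sq, "+") - 2 * g) / nrow(v)
}

# Stable content fingerprint of a property table (used to guard model
# persistence against scoring with a different table).
table_fingerprint <- function(table) {
  txt <- paste(c(rownames(table),
                 format(unclass_table(table), digits = 15, trim = TRUE)),
               collapse = "|")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}
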