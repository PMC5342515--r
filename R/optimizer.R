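#' The default (k, lambda, w) search grid
#'
#' Enumerates the canonical grid: `k` in 1..4 (step 1), `lambda` in 1..10
#' (step 1) and `w` in 0.1..1.0 (step 0.1), i.e. 4 x 10 x 10 = 400
#' configurations. `w` is built as exact decimals (`1:10 / 10`) so a
#' configuration's identity never drifts with floating-point formatting.
#'
#' @param k_range,lambda_range Integer vectors of values to enumerate.
#' @param w_range Numeric vector of weight values.
#' @return `data.frame` with columns `k`, `lambda`, `w`, one row per
#'   configuration.
#' @export
#' @examples
#' nrow(grid_default())  # 400
grid_default <- function(k_range = 1:4, lambda_range = 1:10,
                         w_range = (1:10) / 10) {
  g <- expand.grid(w = w_range, lambda = lambda_range, k = k_range,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("k", "lambda", "w")]
}

#' Grid search over the PseKNC encoding parameters
#'
#' Evaluates every (k, lambda, w) configuration of the grid by stratified
#' K-fold cross-validation with one shared, seeded fold assignment (so
#' configurations are compared on identical splits), and selects the
#' configuration with the highest accuracy; ties are broken by higher
#' MCC, then by smaller feature dimension `4^k + lambda`.
#'
#' @param data Labelled dataset (`sequence`, `label`).
#' @param grid Configurations to evaluate, as from [grid_default()].
#' @param table Property table.
#' @param engine Classifier engine; see [rf_engine()].
#' @param K Folds for the inner cross-validation (default 10).
#' @param seed Seed for the shared fold assignment.
#' @return An object of class `ori_grid`: list with `best` (the winning
#'   row as a list), `results` (`data.frame` with `k`, `lambda`, `w`,
#'   `Sn`, `Sp`, `Acc`, `MCC`, `AUC`) and the `K`/`seed` used.
#' @export
grid_search <- function(data, grid = grid_default(),
                        table = default_property_table(),
                        engine = rf_engine(), K = 10L, seed = 1L) {
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop("empty parameter grid")
  stopifnot(all(c("k", "lambda", "w") %in% names(grid)))
  if (!is_standardized(table)) table <- standardize_table(table)
  y <- check_labels(data$label)
  folds <- stratified_folds(y, as.integer(K), seed)
  res <- grid
  res$Sn <- res$Sp <- res$Acc <- res$MCC <- res$AUC <- NA_real_
  for (i in seq_len(nrow(grid))) {
    rep <- kfold(data, K = K, k = grid$k[i], lambda = grid$lambda[i],
                 w = grid$w[i], table = table, engine = engine, folds = folds)
    res$Sn[i] <- rep$Sn; res$Sp[i] <- rep$Sp; res$Acc[i] <- rep$Acc
    res$MCC[i] <- rep$MCC; res$AUC[i] <- rep$auc
  }
  Z <- 4L^res$k + res$lambda
  best_i <- order(-res$Acc, -res$MCC, Z)[1L]
  structure(list(best = as.list(res[best_i, c("k", "lambda", "w")]),
                 best_index = best_i, results = res,
                 K = as.integer(K), seed = as.integer(seed)),
            class = "ori_grid")
}

#' @export
print.ori_grid <- function(x, ...) {
  b <- x$results[x$best_index, ]
  cat(sprintf("Grid search: %d configurations, %d-fold CV (seed %d)\n",
              nrow(x$results), x$K, x$seed))
  cat(sprintf("  best: k = %d, lambda = %d, w = %g  (Acc = %.3f, MCC = %.3f, AUC = %.3f)\n",
              b$k, b$lambda, b$w, b$Acc, b$MCC, b$AUC))
  invisible(x)
}

#' Write a grid-search results table as TSV
#'
#' @param x An `ori_grid` object.
#' @param path Output path; columns `k`, `lambda`, `w`, `Sn`, `Sp`,
#'   `Acc`, `MCC`, `AUC`.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(x, path) {
  utils::write.table(x$results[, c("k", "lambda", "w", "Sn", "Sp", "Acc",
                                   "MCC", "AUC")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
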