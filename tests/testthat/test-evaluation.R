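test_that("the intuitive metrics reproduce the canonical corner cases", {
  # perfect prediction
  m <- intuitive_metrics(confusion_counts(10, 12, fn = 0, fp = 0))
  expect_equal(c(m$Sn, m$Sp, m$Acc, m$MCC), c(1, 1, 1, 1))
  # total inversion
  m <- intuitive_metrics(confusion_counts(10, 12, fn = 10, fp = 12))
  expect_equal(c(m$Sn, m$Sp, m$Acc, m$MCC), c(0, 0, 0, -1))
  # coin-flip performance
  m <- intuitive_metrics(confusion_counts(10, 12, fn = 5, fp = 6))
  expect_equal(c(m$Acc, m$MCC), c(0.5, 0))
  # all samples predicted ORI: conventional MCC denominator is zero
  m <- intuitive_metrics(confusion_counts(8, 8, fn = 0, fp = 8))
  expect_true(m$mcc_undefined)
  expect_identical(m$MCC, 0)
  expect_error(intuitive_metrics(confusion_counts(0, 5, fn = 0, fp = 0)),
               "both classes")
})

test_that("intuitive forms equal the conventional confusion-matrix formulas", {
  set.seed(11)
  for (rep_i in 1:500) {
    P <- sample(1:40, 1); N <- sample(1:40, 1)
    fn <- sample(0:P, 1); fp <- sample(0:N, 1)
    m <- intuitive_metrics(confusion_counts(P, N, fn = fn, fp = fp))
    conv <- conventional_metrics(P, N, fn, fp)
    expect_equal(m$Sn, conv$Sn, tolerance = 1e-10)
    expect_equal(m$Sp, conv$Sp, tolerance = 1e-10)
    expect_equal(m$Acc, conv$Acc, tolerance = 1e-10)
    if (is.na(conv$MCC)) {
      expect_true(m$mcc_undefined)
    } else {
      expect_equal(m$MCC, conv$MCC, tolerance = 1e-10)
    }
    expect_true(m$Sn >= 0 && m$Sn <= 1)
    expect_true(m$Sp >= 0 && m$Sp <= 1)
    expect_true(m$Acc >= 0 && m$Acc <= 1)
    expect_true(m$MCC >= -1 && m$MCC <= 1)
  }
})

test_that("ROC/AUC: separability, chance level, and the Mann-Whitney identity", {
  lab <- factor(rep(c("nonORI", "ORI"), each = 20), levels = c("nonORI", "ORI"))
  perfect <- roc_auc(c(runif(20, 0, 0.4), runif(20, 0.6, 1)), lab)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$curve$fpr[nrow(perfect$curve)], 1)
  expect_equal(perfect$curve$tpr[nrow(perfect$curve)], 1)

  set.seed(4)
  lab200 <- factor(rep(c("nonORI", "ORI"), each = 100),
                   levels = c("nonORI", "ORI"))
  chance <- roc_auc(runif(200), lab200)
  expect_gt(chance$auc, 0.4)
  expect_lt(chance$auc, 0.6)

  # trapezoid AUC equals U / (n+ * n-), including under heavy ties
  for (rep_i in 1:100) {
    P <- sample(3:30, 1); N <- sample(3:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), P + N, replace = TRUE)
    labs <- factor(c(rep("ORI", P), rep("nonORI", N)),
                   levels = c("nonORI", "ORI"))
    r <- rank(scores)
    u <- sum(r[labs == "ORI"]) - P * (P + 1) / 2
    expect_equal(roc_auc(scores, labs)$auc, u / (P * N), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), factor(rep("ORI", 5),
                                        levels = c("nonORI", "ORI"))),
               "both classes")
})

test_that("jackknife is perfect on separable data and honest on contradictions", {
  tab <- toy_table(2)
  # four trivially separable samples: homopolymer classes
  ds <- data.frame(id = letters[1:4],
                   sequence = c(strrep("A", 60), strrep("A", 60),
                                strrep("CG", 30), strrep("CG", 30)),
                   label = factor(c("ORI", "ORI", "nonORI", "nonORI"),
                                  levels = c("nonORI", "ORI")))
  rep <- jackknife(ds, k = 1, lambda = 2, w = 0.5, table = tab)
  expect_equal(rep$Acc, 1)

  # duplicated, oppositely labelled records can never be classified perfectly
  ds2 <- synthesize_dataset(5, 80, epsilon = 1, seed = 13)
  dup <- ds2[c(1, 1, 6, 6), ]
  dup$label <- factor(c("ORI", "nonORI", "ORI", "nonORI"),
                      levels = c("nonORI", "ORI"))
  dup$id <- paste0("r", 1:4)
  rep2 <- jackknife(dup, k = 1, lambda = 2, w = 0.5, table = tab)
  expect_lt(rep2$Acc, 1)
  expect_error(jackknife(ds[1:3, ], k = 1, lambda = 2, w = 0.5, table = tab),
               "2 samples per class")
  expect_error(jackknife(ds[1:2, ], k = 1, lambda = 2, w = 0.5, table = tab),
               "single class")
})

test_that("stratified kfold balances classes across folds and aggregates like the jackknife", {
  ds <- synthesize_dataset(20, 100, epsilon = 1, seed = 23)
  y <- ds$label
  folds <- oriforest:::stratified_folds(factor(y, levels = c("nonORI", "ORI")),
                                        K = 5, seed = 9)
  expect_identical(sort(unique(folds)), 1:5)
  per_fold <- table(folds, y)
  expect_true(all(per_fold == 4))            # 20 per class / 5 folds

  rep <- kfold(ds, K = 5, k = 2, lambda = 3, w = 0.5, table = toy_table(2),
               seed = 9)
  expect_length(rep$scores, 40)
  expect_gt(rep$auc, 0.9)                    # strongly separable classes
  rep_b <- kfold(ds, K = 5, k = 2, lambda = 3, w = 0.5, table = toy_table(2),
                 seed = 9)
  expect_identical(rep_b$scores, rep$scores) # seeded folds + seeded engine
})

test_that("metrics reports serialize to JSON", {
  m <- intuitive_metrics(confusion_counts(10, 10, fn = 2, fp = 3), auc = 0.9)
  path <- tempfile(fileext = ".json")
  write_metrics_json(m, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$Acc, m$Acc)
  expect_equal(back$AUC, 0.9)
})
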