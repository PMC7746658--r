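test_that("confusion matrix counts items once and validates labels", {
  # perfect predictions give a diagonal matrix
  m <- confusion_matrix(c(0, 1, 2, 1), c(0, 1, 2, 1), 3)
  expect_equal(unclass(unname(m)), diag(c(1L, 2L, 1L)), ignore_attr = TRUE)
  # hand count
  m2 <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(matrix(as.integer(m2), 2), matrix(c(1L, 0L, 1L, 1L), 2))
  # totals preserved on random input
  set.seed(1)
  tl <- sample(0:4, 1000, replace = TRUE)
  pl <- sample(0:4, 1000, replace = TRUE)
  expect_equal(sum(confusion_matrix(tl, pl, 5)), 1000)
  expect_error(confusion_matrix(c(0, 5), c(0, 0), 5), "out of range")
})

test_that("overall accuracy is trace over total", {
  expect_equal(overall_accuracy(diag(c(3, 2, 5))), 1)
  expect_equal(overall_accuracy(matrix(c(2, 0, 1, 3), 2)), 5 / 6)
  expect_equal(overall_accuracy(matrix(1, 4, 4)), 1 / 4)
  expect_error(overall_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("per-class metrics match printed report-card triples", {
  # R=0.89, P=0.94 -> F1 0.91 ; R=0.91, P=1.00 -> F1 0.95 (2 dp)
  expect_equal(leafgan:::round_half_up(f1_score(0.89, 0.94), 2), 0.91)
  expect_equal(leafgan:::round_half_up(f1_score(0.91, 1.00), 2), 0.95)
  # harmonic-mean identity R = P = r -> F1 = r
  r <- runif(10)
  expect_equal(f1_score(r, r), r)
  # formula check on a concrete matrix
  m <- confusion_matrix(c(0, 0, 0, 1, 1, 2), c(0, 0, 1, 1, 1, 1), 3)
  pm <- per_class_metrics(m)
  expect_equal(pm$recall, c(2 / 3, 1, 0))
  expect_equal(pm$precision, c(1, 2 / 4, 0))
  expect_equal(pm$support, c(3L, 2L, 1L))
  # degenerate: class 2 never predicted and never correct -> flagged zero
  expect_false(pm$f1_defined[3])
  expect_equal(pm$f1[3], 0)
})

test_that("metrics agree with an independent reference implementation", {
  set.seed(42)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    n <- 60
    tl <- c(0:(K - 1), sample(0:(K - 1), n - K, replace = TRUE))
    pl <- c(0:(K - 1), sample(0:(K - 1), n - K, replace = TRUE))
    m <- confusion_matrix(tl, pl, K)
    pm <- per_class_metrics(m)
    ref <- caret::confusionMatrix(
      factor(pl, levels = 0:(K - 1)), factor(tl, levels = 0:(K - 1)))
    # caret reports the positive class only when K = 2
    recall_ref <- if (K == 2)
      c(ref$byClass[["Sensitivity"]], ref$byClass[["Specificity"]])
    else unname(ref$byClass[, "Sensitivity"])
    prec_ref <- if (K == 2)
      c(ref$byClass[["Pos Pred Value"]], ref$byClass[["Neg Pred Value"]])
    else unname(ref$byClass[, "Pos Pred Value"])
    prec_ref[is.na(prec_ref)] <- 0
    expect_equal(pm$recall, recall_ref, tolerance = 1e-9)
    expect_equal(pm$precision, prec_ref, tolerance = 1e-9)
    expect_equal(overall_accuracy(m), unname(ref$overall["Accuracy"]),
                 tolerance = 1e-9)
  }
})

test_that("structural identities of the confusion matrix hold", {
  set.seed(3)
  tl <- sample(0:3, 400, replace = TRUE)
  pl <- sample(0:3, 400, replace = TRUE)
  m <- confusion_matrix(tl, pl, 4)
  pm <- per_class_metrics(m)
  expect_equal(unname(rowSums(m)), as.numeric(pm$support))
  expect_equal(unname(colSums(m)), as.numeric(table(factor(pl, 0:3))))
  # accuracy equals support-weighted recall
  expect_equal(overall_accuracy(m),
               sum(pm$recall * pm$support) / sum(m), tolerance = 1e-12)
})

test_that("printed F1 cells and macro averages are reproduced from the report card", {
  tb <- benchmark_tables()
  rd <- reproduce_f1_cells(tb$diseased)
  rh <- reproduce_f1_cells(tb$healthy)
  expect_gte(rd$match_rate, 0.95)
  expect_gte(rh$match_rate, 0.95)
  expect_equal(nrow(rd$mismatches) + nrow(rh$mismatches),
               rd$n_cells + rh$n_cells - rd$n_consistent - rh$n_consistent)
  # printed macro averages: diseased II/III and healthy III/IV
  expect_equal(round(macro_average_f1(tb$diseased$exp2_f1, "table"), 2), 0.71)
  expect_equal(round(macro_average_f1(tb$diseased$exp3_f1, "table"), 2), 0.75)
  expect_equal(round(macro_average_f1(tb$healthy$exp3_f1, "table"), 2), 0.78)
  expect_equal(round(macro_average_f1(tb$healthy$exp4_f1, "table"), 2), 0.81)
  # all-equal shortcut
  expect_equal(macro_average_f1(rep(0.6, 5)), 0.6)
})

test_that("grouped report splits classes and recombines consistently", {
  set.seed(8)
  K <- 6
  tl <- sample(0:(K - 1), 300, replace = TRUE)
  pl <- sample(0:(K - 1), 300, replace = TRUE)
  m <- confusion_matrix(tl, pl, K)
  rep_ <- metrics_report(m, split_map = list(diseased = 0:3, healthy = 4:5))
  expect_equal(nrow(rep_$tables$diseased), 4)
  expect_equal(nrow(rep_$tables$healthy), 2)
  # group macro averages recombine (size-weighted) to the overall macro F1
  expect_equal((4 * rep_$group_macro_f1[["diseased"]] +
                  2 * rep_$group_macro_f1[["healthy"]]) / 6,
               rep_$macro_f1, tolerance = 1e-12)
  # single group reduces to per_class_metrics
  one <- metrics_report(m, split_map = list(all = 0:5))
  expect_equal(one$tables$all$f1, per_class_metrics(m)$f1)
  expect_error(metrics_report(m, split_map = list(a = 0:2, b = 2:5)),
               "partition")
})

test_that("prediction CSV round-trips through evaluate_predictions", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(item_id = 1:6, true_label = c(0, 0, 1, 1, 2, 2),
                       predicted_label = c(0, 1, 1, 1, 2, 0)), f,
            row.names = FALSE)
  ev <- evaluate_predictions(f, 3)
  expect_equal(ev$accuracy, 4 / 6)
  expect_equal(sum(ev$confusion), 6)
})
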