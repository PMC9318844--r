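# Confusion-matrix metrics and per-class aggregation.

test_that("metrics reproduce hand arithmetic including the printed rounding", {
  perfect <- cm_metrics(confusion_matrix(10, 0, 0, 10))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$recall, 100)
  expect_equal(perfect$specificity, 100)

  # 51/1/1/54: 105/107, 51/52, 54/55
  m <- cm_metrics(confusion_matrix(51, 1, 1, 54))
  expect_equal(m$accuracy, 98.13)
  expect_equal(m$recall, 98.08)
  expect_equal(m$specificity, 98.18)
  expect_equal(m$accuracy_exact, 100 * 105 / 107)

  expect_error(cm_metrics(confusion_matrix(0, 0, 1, 1)), "recall undefined")
  expect_error(cm_metrics(confusion_matrix(1, 1, 0, 0)),
               "specificity undefined")
  expect_error(confusion_matrix(-1, 0, 0, 2), "non-negative")
  expect_error(confusion_matrix(0, 0, 0, 0), "at least one")
})

test_that("display rounding is half-up to two decimals", {
  expect_equal(round_half_up(95.015), 95.02)
  expect_equal(round_half_up(95.0249), 95.02)
  expect_equal(round_half_up(2.675), 2.68)
})

test_that("average-per-class aggregation reproduces the published averages", {
  tl <- reference_classification_scores("GLNB-TL")
  avg <- aggregate_metrics(tl)
  expect_equal(avg$accuracy, 95.33)
  expect_equal(avg$recall, 95.02)
  expect_equal(avg$specificity, 95.52)

  base <- aggregate_metrics(reference_classification_scores("GLNB"))
  expect_equal(base$accuracy, 91.59)
  expect_equal(base$recall, 92.32)
  expect_equal(base$specificity, 91.07)

  same <- aggregate_metrics(tl[c(1, 1), ])
  expect_equal(same$accuracy, tl$accuracy[1])
  expect_error(aggregate_metrics(list()), "empty")
  expect_error(aggregate_metrics(data.frame(accuracy = NA_real_,
                                            recall = 1, specificity = 1)),
               "undefined")
})

test_that("confusion counts follow the stressed-positive mapping", {
  all_pos <- confusion_from_predictions(rep("experimental", 4),
                                        rep("experimental", 4))
  expect_equal(unlist(all_pos[c("tp", "fn", "fp", "tn")]),
               c(tp = 4, fn = 0, fp = 0, tn = 0))
  miss <- confusion_from_predictions(rep("experimental", 3),
                                     rep("control", 3))
  expect_equal(miss$tp, 0); expect_equal(miss$fn, 3)

  labels <- c("experimental", "experimental", "experimental", "experimental",
              "control", "control")
  preds <- c("experimental", "experimental", "experimental", "control",
             "experimental", "control")
  cm <- confusion_from_predictions(labels, preds)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 3, fn = 1, fp = 1, tn = 1))
  expect_error(confusion_from_predictions(labels, preds[-1]), "equal length")
})

test_that("accuracy decomposes into recall and specificity (identity)", {
  set.seed(91)
  for (i in 1:25) {
    cm <- confusion_matrix(sample(1:30, 1), sample(1:30, 1),
                           sample(1:30, 1), sample(1:30, 1))
    m <- cm_metrics(cm)
    n <- cm$tp + cm$fn + cm$fp + cm$tn
    lhs <- m$accuracy_exact
    rhs <- (m$recall_exact * (cm$tp + cm$fn) +
              m$specificity_exact * (cm$tn + cm$fp)) / n
    expect_equal(lhs, rhs)
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 100))
  }
})

test_that("per-species evaluation partitions the test set", {
  model <- localizer_model()
  ds <- generate_dataset(3, species = "grass", shape = c(96, 96), seed = 901,
                         radius_range = c(15, 35))
  ev <- evaluate_by_species(model, ds)
  expect_equal(ev$per_species$species, "grass")
  expect_equal(ev$per_species$n, 6)
  expect_true(ev$average$accuracy >= 0 && ev$average$accuracy <= 100)
  rep <- format_metrics_report(ev$per_species, ev$average)
  expect_length(rep, 3)
  expect_match(rep[3], "Average per-class")
})
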