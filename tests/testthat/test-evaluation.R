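test_that("confusion counts match a per-pixel loop and swap symmetry", {
  set.seed(26)
  pred <- matrix(runif(256) < 0.4, 16, 16)
  truth <- matrix(runif(256) < 0.3, 16, 16)
  fov <- matrix(runif(256) < 0.8, 16, 16)
  cc <- confusion_counts(pred, truth, fov)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:256) {
    if (!fov[i]) next
    if (pred[i] && truth[i]) tp <- tp + 1L
    if (!pred[i] && !truth[i]) tn <- tn + 1L
    if (pred[i] && !truth[i]) fp <- fp + 1L
    if (!pred[i] && truth[i]) fn <- fn + 1L
  }
  expect_identical(unclass(cc)[c("tp", "tn", "fp", "fn")],
                   list(tp = tp, tn = tn, fp = fp, fn = fn))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, sum(fov))
  # perfect and inverted predictions
  same <- confusion_counts(truth, truth)
  expect_identical(c(same$fp, same$fn), c(0L, 0L))
  inv <- confusion_counts(!truth, truth)
  expect_identical(c(inv$tp, inv$tn), c(0L, 0L))
  # swapping prediction and truth exchanges FP and FN, fixing TP and TN
  sw <- confusion_counts(truth, pred, fov)
  expect_identical(c(sw$tp, sw$tn, sw$fp, sw$fn),
                   c(cc$tp, cc$tn, cc$fn, cc$fp))
  expect_error(confusion_counts(pred, truth[1:8, ]), "dim|identical")
})

test_that("the metric triple follows its definitions with in-band undefined", {
  truth <- matrix(c(TRUE, FALSE), 4, 4)
  perfect <- metric_triple(confusion_counts(truth, truth))
  expect_equal(c(perfect$sensitivity, perfect$accuracy, perfect$specificity),
               c(1, 1, 1))
  hand <- structure(list(tp = 70L, tn = 880L, fp = 20L, fn = 30L),
                    class = "confusion_counts")
  m <- metric_triple(hand)
  expect_equal(m$sensitivity, 0.70)
  expect_equal(m$accuracy, 950 / 1000)
  expect_equal(m$specificity, 880 / 900)
  # no vessels anywhere and none predicted: sensitivity undefined
  none <- matrix(FALSE, 4, 4)
  m0 <- metric_triple(confusion_counts(none, none))
  expect_true(is.na(m0$sensitivity))
  expect_equal(c(m0$accuracy, m0$specificity), c(1, 1))
})

test_that("regime taxonomy separates under-, over- and accurate segmentation", {
  mk <- function(sen, sp) {
    structure(list(sensitivity = sen, accuracy = 0.9, specificity = sp),
              class = "metric_triple")
  }
  expect_identical(classify_regime(mk(0.95, 0.96), 0.9, 0.5), "accurate")
  expect_identical(classify_regime(mk(0.2, 0.99), 0.9, 0.5), "under_segmented")
  expect_identical(classify_regime(mk(0.99, 0.3), 0.9, 0.5), "over_segmented")
  expect_identical(classify_regime(mk(0.7, 0.7), 0.9, 0.5), "indeterminate")
  expect_error(classify_regime(mk(NA_real_, 0.9)), "defined")
})

test_that("result tables end in an average row consistent with their rows", {
  set.seed(27)
  mk_pair <- function() {
    list(pred = matrix(runif(64) < 0.4, 8, 8),
         truth = matrix(runif(64) < 0.4, 8, 8))
  }
  single <- evaluate_set(list(mk_pair()), labels = "only")
  expect_equal(nrow(single), 2)
  expect_equal(unlist(single[2, -1]), unlist(single[1, -1]),
               ignore_attr = TRUE)
  pairs <- list(mk_pair(), mk_pair(), mk_pair())
  tab <- evaluate_set(pairs)
  body <- tab[tab$image != "Average", ]
  avg <- tab[tab$image == "Average", ]
  expect_equal(avg$sensitivity, mean(body$sensitivity))
  expect_equal(avg$accuracy, mean(body$accuracy))
  expect_equal(avg$specificity, mean(body$specificity))
  expect_error(evaluate_set(list()), "empty")
})

test_that("metrics are invariant under a shared pixel shuffle", {
  set.seed(28)
  pred <- matrix(runif(100) < 0.5, 10, 10)
  truth <- matrix(runif(100) < 0.5, 10, 10)
  perm <- sample(100)
  m1 <- metric_triple(confusion_counts(pred, truth))
  m2 <- metric_triple(confusion_counts(matrix(pred[perm], 10, 10),
                                       matrix(truth[perm], 10, 10)))
  expect_equal(m1, m2)
})
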