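test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2,
                                   dimnames = dimnames(cm)))
  expect_equal(sum(cm), 4)
  # perfect predictions give a diagonal with class counts
  truth <- c(rep(0, 7), rep(1, 3))
  cmd <- confusion(truth, truth)
  expect_equal(diag(unclass(cmd)), c(`0` = 7L, `1` = 3L))
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
  expect_error(confusion(c(0, 5), c(0, 1), K = 2), "range")
  expect_error(confusion(c(0, 1), c(0)), "equal length")
})

test_that("per-class metrics agree with hand arithmetic", {
  cm <- confusion(rep(c(0, 1), times = c(50, 50)),
                  c(rep(0, 45), rep(1, 5), rep(0, 10), rep(1, 40)))
  m0 <- class_metrics(cm, 0)
  expect_equal(m0$sensitivity, 90)
  expect_equal(m0$precision, 45 / 55 * 100, tolerance = 1e-9)
  expect_equal(m0$specificity, 80)
  expect_equal(round_half_up(m0$f_score, 2), 85.71)
  expect_equal(m0$accuracy, m0$sensitivity)   # table convention
  expect_equal(m0$ovr_accuracy, 85)
  # diagonal matrix: all metrics at 100
  cmd <- confusion(c(0, 0, 1), c(0, 0, 1))
  for (c in 0:1) {
    mc <- class_metrics(cmd, c)
    expect_equal(unlist(mc[c("accuracy", "precision", "sensitivity",
                             "specificity", "f_score")]),
                 c(accuracy = 100, precision = 100, sensitivity = 100,
                   specificity = 100, f_score = 100))
  }
  # degenerate all-one-class predictions flag undefined ratios as zero
  mz <- class_metrics(confusion(c(0, 1), c(0, 0)), 1)
  expect_equal(mz$precision, 0)
  expect_true(mz$undefined)
})

test_that("F-scores and macro averages reproduce the reference table cells", {
  expect_equal(round_half_up(f_score_from(100, 93.97), 2), 96.89)
  expect_equal(round_half_up(f_score_from(100, 99.10), 2), 99.55)
  expect_equal(round_half_up(f_score_from(100, 98.04), 2), 99.01)
  expect_equal(f_score_from(73.4, 73.4), 73.4, tolerance = 1e-12)
  expect_equal(round_half_up(mean(c(98.04, 100.00)), 2), 99.02)
  expect_equal(round_half_up(mean(c(96.89, 97.10)), 2), 97.00)
  z <- f_score_from(0, 0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "undefined"))
  # macro average of identical rows is the row itself
  pc <- rbind(class_metrics(confusion(c(0, 1), c(0, 1)), 0),
              class_metrics(confusion(c(0, 1), c(0, 1)), 1))
  expect_equal(macro_average(pc)$f_score, 100)
})

test_that("evaluation reports keep both raw and displayed values", {
  set.seed(6)
  truth <- rep(0:1, each = 50)
  pred <- truth
  flip <- sample(100, 7)
  pred[flip] <- 1 - pred[flip]
  rep_ <- evaluate_split(truth, pred)
  # two-path oracle: metrics from the matrix equal direct label comparison
  expect_equal(rep_$overall_accuracy, 100 * mean(truth == pred))
  sens1_direct <- 100 * mean(pred[truth == 1] == 1)
  expect_equal(rep_$per_class$sensitivity[2], sens1_direct)
  # balanced two-class data: macro sensitivity equals overall accuracy
  expect_equal(rep_$macro$sensitivity, rep_$overall_accuracy, tolerance = 1e-9)
  # K = 2 mirror: class 0 sensitivity is class 1 specificity and vice versa
  expect_equal(rep_$per_class$sensitivity[1], rep_$per_class$specificity[2])
  expect_equal(rep_$per_class$sensitivity[2], rep_$per_class$specificity[1])
  # F between min and max of precision and sensitivity
  for (i in 1:2) {
    p <- rep_$per_class$precision[i]; s <- rep_$per_class$sensitivity[i]
    expect_gte(rep_$per_class$f_score[i], min(p, s))
    expect_lte(rep_$per_class$f_score[i], max(p, s))
  }
  # all-one-class predictions on balanced data score 50
  rep50 <- evaluate_split(truth, rep(0L, 100))
  expect_equal(rep50$overall_accuracy, 50)
  # display is rounded half-up to 2 decimals, raw retained
  expect_equal(rep_$display$sensitivity[1],
               round_half_up(rep_$per_class$sensitivity[1], 2))
})

test_that("K = 2 sensitivity/specificity mirror holds on random matrices", {
  set.seed(17)
  for (rep_i in 1:20) {
    truth <- sample(0:1, 40, TRUE)
    pred <- sample(0:1, 40, TRUE)
    if (length(unique(truth)) < 2) next
    r <- evaluate_split(truth, pred, K = 2)
    expect_equal(r$per_class$sensitivity[1], r$per_class$specificity[2])
  }
})

test_that("reports round-trip through disk without losing raw values", {
  truth <- rep(0:1, each = 20)
  pred <- c(rep(0, 18), rep(1, 2), rep(1, 19), 0)
  rep_ <- evaluate_split(truth, pred)
  d <- withr::local_tempdir()
  paths <- write_metrics_report(rep_, d, phase = "testing")
  expect_true(all(file.exists(paths)))
  back <- read_metrics_report(paths[["yaml"]])
  expect_equal(back$overall_accuracy, rep_$overall_accuracy, tolerance = 1e-12)
  expect_equal(back$per_class$f_score, rep_$per_class$f_score, tolerance = 1e-12)
  expect_equal(back$macro$sensitivity, rep_$macro$sensitivity, tolerance = 1e-12)
  csv <- read.csv(paths[["csv"]])
  expect_equal(names(csv)[1:2], c("phase", "class"))
})

test_that("tidy and glance expose the report as tibbles", {
  r <- evaluate_split(c(0, 0, 1, 1), c(0, 1, 1, 1))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$class), c("0", "1", "macro"))
  g <- glance(r)
  expect_equal(g$n, 4)
  expect_equal(g$overall_accuracy, 75)
})
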