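test_that("confusion counts follow the score >= t rule including boundaries", {
  expect_equal(confusion_at_threshold(c(0.6, 0.4), c(1, 0), 0.5),
               c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  s <- c(0.1, 0.5, 0.9, 0.3)
  y <- c(0, 1, 1, 0)
  expect_equal(confusion_at_threshold(s, y, 0),
               c(TP = 2L, FP = 2L, TN = 0L, FN = 0L))
  expect_equal(confusion_at_threshold(s, y, 0.91),
               c(TP = 0L, FP = 0L, TN = 2L, FN = 2L))
  # ties at the threshold count as positive
  expect_equal(confusion_at_threshold(s, y, 0.5)[["TP"]], 2L)
  expect_error(confusion_at_threshold(c(0.1), c(1, 0)), "length")
})

test_that("ROC AUC equals exhaustive pair counting with ties at one half", {
  with_seed_test(42, {
    for (rep in 1:200) {
      n <- sample(4:50, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
      s <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # force some ties
      expect_equal(roc_auc(s, y), pair_count_auc(s, y), tolerance = 1e-12)
    }
  })
})

test_that("rank-based ROC AUC agrees with an independent library implementation", {
  with_seed_test(31, {
    for (rep in 1:20) {
      n <- sample(10:60, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
      s <- round(stats::runif(n), sample(c(1, 3), 1))
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
    }
  })
})

test_that("summary metrics match the worked examples and invariances", {
  r <- summary_metrics(c(0.9, 0.8, 0.3), c(1, 0, 1))
  expect_equal(r$roc_auc, 0.5)

  # perfectly separated scores
  r2 <- summary_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), t = 0.5)
  expect_equal(r2$roc_auc, 1)
  expect_equal(r2$pr_auc, 1)
  expect_equal(r2$PPA, 1)
  expect_equal(r2$NPA, 1)
  expect_equal(r2$F1, 1)

  # AUC invariant under strictly increasing transforms
  with_seed_test(7, {
    s <- stats::runif(40)
    y <- stats::rbinom(40, 1, 0.3)
    expect_equal(roc_auc(s, y), roc_auc(stats::qlogis(s * 0.98 + 0.01), y),
                 tolerance = 1e-12)
    expect_equal(pr_auc(s, y), pr_auc(s^3, y), tolerance = 1e-12)
  })

  # identity PPA = TP/(TP+FN), PPV = TP/(TP+FP), F1 harmonic mean
  cm <- r2$confusion
  expect_equal(r2$PPA, cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]))
  expect_equal(r2$accuracy, (cm[["TP"]] + cm[["TN"]]) / r2$n)

  single <- summary_metrics(c(0.2, 0.6), c(1, 1))
  expect_true(single$auc_undefined)
  expect_true(is.na(single$roc_auc))
})

test_that("trade-off curve endpoints and monotonicity hold", {
  with_seed_test(11, {
    s <- stats::runif(60)
    y <- stats::rbinom(60, 1, 0.2)
    y[1:2] <- c(0, 1)
    tc <- tradeoff_curve(s, y)
    prev <- mean(y)
    first <- tc[1, ]   # threshold 0: everything positive
    expect_equal(first$ppa, 1)
    expect_equal(first$tn_rate, 0)
    expect_equal(first$fn_rate, 0)
    last <- tc[nrow(tc), ]  # above the max score: everything negative
    expect_equal(last$fn_rate, prev)
    expect_equal(last$tn_rate, 1 - prev)
    expect_equal(last$ppa, 0)
    expect_true(all(diff(tc$fn_rate) >= 0))
    expect_true(all(diff(tc$tn_rate) >= 0))
    # FN/n = prevalence * (1 - PPA) at every threshold
    expect_equal(tc$fn_rate, prev * (1 - tc$ppa), tolerance = 1e-12)
  })
})

test_that("probability histograms are normalized per class on [0, 1]", {
  s <- c(0.05, 0.1, 0.2, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 1)
  h <- probability_histogram(s, y, bins = 10)
  expect_equal(sum(h$positive), 1, tolerance = 1e-9)
  expect_equal(sum(h$negative), 1, tolerance = 1e-9)
  expect_equal(range(h$breaks), c(0, 1))
  expect_length(h$breaks, 11)

  one_bin <- probability_histogram(rep(0.55, 4), rep(1, 4), bins = 5)
  expect_equal(max(one_bin$positive), 1)
  expect_length(one_bin$negative, 0)
})

test_that("fold aggregation reports means and sample standard deviations", {
  r1 <- summary_metrics(c(0.9, 0.1), c(1, 0))
  r2 <- r1; r2$roc_auc <- 0.8
  r1$roc_auc <- 0.9
  agg <- aggregate_folds(list(r1, r2))
  expect_equal(agg$mean[agg$metric == "roc_auc"], 0.85)
  expect_equal(agg$sd[agg$metric == "roc_auc"], stats::sd(c(0.9, 0.8)))

  same <- aggregate_folds(list(r1, r1))
  expect_equal(same$sd[same$metric == "roc_auc"], 0)

  solo <- aggregate_folds(list(r1))
  expect_true(attr(solo, "sd_undefined"))
  expect_equal(solo$sd, rep(0, nrow(solo)))
})

test_that("stratified reports partition the cohort", {
  with_seed_test(5, {
    s <- stats::runif(100)
    y <- stats::rbinom(100, 1, 0.3)
    y[1:4] <- c(0, 1, 0, 1)
    strata <- rep(c("biopsy", "resection"), 50)
    rep_all <- stratified_report(s, y, strata)
    expect_named(rep_all, c("ALL", "biopsy", "resection"))
    expect_equal(rep_all$biopsy$n + rep_all$resection$n, rep_all$ALL$n)
    # with identical score distributions, stratum AUCs agree within noise
    expect_lt(abs(rep_all$biopsy$roc_auc - rep_all$resection$roc_auc), 0.25)
    # single stratum reduces to ALL
    one <- stratified_report(s, y, rep("biopsy", 100))
    expect_equal(one$biopsy, one$ALL)
  })
})

test_that("evaluation plots render to a device without error", {
  with_seed_test(9, {
    s <- stats::runif(50)
    y <- stats::rbinom(50, 1, 0.3)
    y[1:2] <- c(0, 1)
    png_path <- withr::local_tempfile(fileext = ".png")
    grDevices::png(png_path)
    on.exit(grDevices::dev.off(), add = TRUE)
    expect_no_error(plot_evaluation(s, y, "roc"))
    expect_no_error(plot_evaluation(s, y, "pr"))
    expect_no_error(plot_evaluation(s, y, "histogram"))
    expect_no_error(plot_evaluation(s, y, "tradeoff"))
  })
})
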