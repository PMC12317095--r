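test_that("AUROC equals pairwise concordance", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")

  # brute-force oracle over random tie-prone sets up to n = 20
  set.seed(71)
  for (i in 1:200) {
    s <- random_prediction_set(sample(4:20, 1))
    expect_equal(auroc(s$p, s$y), auroc_brute(s$p, s$y))
  }

  # independent cross-check against pROC on a larger untied set
  skip_if_not_installed("pROC")
  set.seed(72)
  p <- runif(100); y <- rbinom(100, 1, 0.4)
  expect_equal(auroc(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                              direction = "<"))))
})

test_that("fold aggregation uses a t interval", {
  same <- mean_auroc_ci(rep(0.9, 4))
  expect_equal(same$mean, 0.9)
  expect_equal(diff(same$ci), 0)

  ci <- mean_auroc_ci(c(0.9, 0.9, 0.9, 0.9, 1.0))
  expect_equal(ci$mean, 0.92)
  half <- qt(0.975, 4) * sd(c(0.9, 0.9, 0.9, 0.9, 1.0)) / sqrt(5)
  expect_equal(ci$ci, c(0.92 - half, 0.92 + half))

  # symmetric perturbation leaves the mean unchanged
  expect_equal(mean_auroc_ci(c(0.9 - 0.03, 0.9 + 0.03, 0.9))$mean, 0.9)
  expect_error(mean_auroc_ci(0.9), "two folds")
})

test_that("stratified AUROC reports undefined strata instead of dropping them", {
  rec <- data.frame(probability = c(0.9, 0.2, 0.8, 0.3, 0.7, 0.6),
                    label = c(1, 0, 1, 0, 1, 1),
                    scanner = c("a", "a", "a", "a", "b", "b"),
                    site = "primary", mode = "DUET")
  tab <- stratified_auroc(rec, "scanner")
  expect_true(tab$defined[tab$group == "a"])
  expect_false(tab$defined[tab$group == "b"])
  expect_true(is.na(tab$auroc[tab$group == "b"]))

  single <- stratified_auroc(transform(rec, scanner = "only"), "scanner")
  expect_equal(single$auroc, auroc(rec$probability, rec$label))
  expect_error(stratified_auroc(rec, "color"))
})

test_that("site-dependent noise degrades the noisy stratum's separability", {
  cfg <- tiny_synth_config(n_cases = 400, seed = 41,
                           tiles_per_slide_range = c(3L, 6L))
  cfg$site_noise_sd <- 3
  cohort <- generate_cohort(cfg)
  # linear readout along the planted H&E signal direction
  score <- vapply(cohort$cases, function(cs) mean(cs$he$embeddings[, 1:2]),
                  numeric(1))
  rec <- data.frame(probability = plogis(score),
                    label = vapply(cohort$cases, `[[`, numeric(1), "status"),
                    scanner = vapply(cohort$cases, `[[`, character(1), "scanner"),
                    site = vapply(cohort$cases, `[[`, character(1), "site"),
                    mode = "HE_ONLY")
  tab <- stratified_auroc(rec, "site")
  expect_gt(tab$auroc[tab$group == "primary"],
            tab$auroc[tab$group == "metastatic"])
})

test_that("trade-off sweep enumerates operating points with monotone errors", {
  rec <- data.frame(probability = c(0.9, 0.8, 0.6, 0.4, 0.2),
                    label = c(1, 1, 0, 1, 0))
  curve <- tradeoff_curve(rec)
  # threshold at/below the minimum probability: everything positive
  first <- curve[1, ]
  expect_equal(first$sensitivity, 1)
  expect_equal(first$fn_pct, 0)
  # the 0.6 threshold row: FN = {0.4}, TN = {0.2}
  row <- curve[curve$threshold == 0.6, ]
  expect_equal(row$fn_pct, 20)
  expect_equal(row$tn_pct, 20)
  expect_equal(row$sensitivity, 2 / 3)
  # above the maximum: nothing positive
  last <- curve[is.infinite(curve$threshold), ]
  expect_equal(last$sensitivity, 0)
  expect_equal(last$tn_pct, 40)  # 2 negatives of 5 cases
  expect_equal(last$fn_pct, 60)

  expect_error(tradeoff_curve(data.frame(probability = 0.5, label = 1)),
               "both classes")

  # monotonicity over random prediction sets
  set.seed(43)
  for (i in 1:200) {
    s <- random_prediction_set(sample(5:40, 1))
    cv <- tradeoff_curve(data.frame(probability = s$p, label = s$y))
    expect_true(all(diff(cv$fn_pct) >= 0))
    expect_true(all(diff(cv$sensitivity) <= 0))
  }
})

test_that("AUROC equals the trapezoidal area under the swept ROC", {
  set.seed(47)
  for (i in 1:100) {
    s <- random_prediction_set(sample(5:50, 1))
    rec <- data.frame(probability = s$p, label = s$y)
    cv <- tradeoff_curve(rec)
    n <- length(s$y); n_neg <- sum(s$y == 0)
    tpr <- cv$sensitivity
    fpr <- (n_neg - cv$tn_pct * n / 100) / n_neg
    o <- order(fpr, tpr)
    area <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
    expect_equal(auroc(rec), area, tolerance = 1e-12)
  }
})

test_that("operating-point selection maximises rule-outs under the FN bound", {
  rec <- data.frame(probability = c(0.9, 0.8, 0.6, 0.4, 0.2),
                    label = c(1, 1, 0, 1, 0))
  curve <- tradeoff_curve(rec)
  # enumeration oracle: best TN% among points with FN% <= 20 is 40 (t = 0.8)
  op <- pick_operating_point(curve, 20)
  expect_equal(op$tn_pct, 40)
  expect_equal(op$threshold, 0.8)
  expect_lte(op$fn_pct, 20)
  # a permissive bound returns the global maximum TN%
  op_all <- pick_operating_point(curve, 100)
  expect_equal(op_all$tn_pct, max(curve$tn_pct))
  # a perfectly separable curve admits FN = 0 with full sensitivity
  sep <- tradeoff_curve(data.frame(probability = c(0.9, 0.8, 0.2, 0.1),
                                   label = c(1, 1, 0, 0)))
  op0 <- pick_operating_point(sep, 0)
  expect_equal(op0$sensitivity, 1)
  expect_equal(op0$tn_pct, 50)
  expect_error(pick_operating_point(curve, -1), "no operating point")

  # the bound is never violated on random curves
  set.seed(53)
  for (i in 1:100) {
    s <- random_prediction_set(20)
    cv <- tradeoff_curve(data.frame(probability = s$p, label = s$y))
    tgt <- runif(1, 0, 100)
    op <- tryCatch(pick_operating_point(cv, tgt), error = function(e) NULL)
    if (!is.null(op)) expect_lte(op$fn_pct, tgt)
  }
})

test_that("probability histograms respect the bin edge convention", {
  rec <- data.frame(probability = rep(0.5, 8), label = rep(c(0, 1), 4))
  h <- probability_histogram(rec, n_bins = 2)
  expect_equal(unname(h$counts[, 2]), c(4, 4))
  expect_equal(unname(h$counts[, 1]), c(0, 0))

  set.seed(59)
  rec2 <- data.frame(probability = runif(200), label = rbinom(200, 1, 0.3))
  h2 <- probability_histogram(rec2, n_bins = 10)
  expect_equal(sum(h2$counts["negative", ]), sum(rec2$label == 0))
  expect_equal(sum(h2$counts["positive", ]), sum(rec2$label == 1))
  # probability exactly 1 lands in the closed last bin
  h3 <- probability_histogram(data.frame(probability = c(1, 0), label = c(1, 0)),
                              n_bins = 4)
  expect_equal(unname(h3$counts["positive", 4]), 1)
  expect_equal(unname(h3$counts["negative", 1]), 1)
  expect_error(probability_histogram(rec, n_bins = 1), ">= 2")
})
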