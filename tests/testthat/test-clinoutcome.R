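outcome_row <- function(first = 0, last_admin = first, last_claim = last_admin,
                        refresh = 1000, death = NA) {
  data.frame(first_admin_day = first, last_admin_day = last_admin,
             last_claim_day = last_claim, refresh_day = refresh,
             death_day = death)
}

test_that("time-on-treatment is the first-to-last administration interval", {
  expect_equal(derive_tot(outcome_row(0, 90, 100)), 90)
  expect_equal(derive_tot(outcome_row(10, 10, 50)), 0)
  expect_equal(derive_tot(outcome_row(5, 5, 5)), 0)
  expect_error(derive_tot(outcome_row(10, 5, 20)), "violate")
})

test_that("overall survival applies the 100-day presumed-death rule", {
  # gap of 120 days: presumed dead at the last claim
  os <- derive_os(outcome_row(0, 50, 200, refresh = 320))
  expect_equal(os$event, 1L)
  expect_equal(os$time, 200)
  # contact within 100 days of the refresh: alive, censored
  os2 <- derive_os(outcome_row(0, 50, 300, refresh = 320))
  expect_equal(os2$event, 0L)
  expect_equal(os2$time, 300)
  # an exact 100-day gap is NOT presumed death (strictly more than 100)
  os3 <- derive_os(outcome_row(0, 50, 220, refresh = 320))
  expect_equal(os3$event, 0L)
  # a recorded death date overrides claims inference
  os4 <- derive_os(outcome_row(0, 50, 300, refresh = 320, death = 180))
  expect_equal(os4$event, 1L)
  expect_equal(os4$time, 180)
})

test_that("the presumed-death indicator is monotone in the claims gap", {
  events <- vapply(0:300, function(gap) {
    derive_os(outcome_row(0, 10, 1000 - gap, refresh = 1000))$event
  }, integer(1))
  expect_true(all(diff(events) >= 0))
  expect_true(all(events[(0:300) <= 100] == 0))
  expect_true(all(events[(0:300) > 100] == 1))
})

test_that("short time-on-treatment records are excluded at 21 days", {
  rec <- data.frame(id = 1:4, tot = c(20, 21, 0, 40))
  expect_message(out <- filter_min_tot(rec), "2 case")
  expect_equal(out$id, c(2, 4))
  expect_silent(filter_min_tot(rec[rec$tot >= 21, ]))
  expect_equal(nrow(filter_min_tot(rec[0, ])), 0)
})

test_that("Kaplan-Meier estimates match the hand product-limit computation", {
  r1 <- survival_records(c(1, 2, 3), c(1, 1, 1), factor(rep("negative", 3)))
  km1 <- km_curve(r1)
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0))

  r2 <- survival_records(c(1, 2, 3), c(1, 0, 1), factor(rep("negative", 3)))
  km2 <- km_curve(r2)
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  r3 <- survival_records(c(1, 2, 3), c(0, 0, 0), factor(rep("negative", 3)))
  expect_true(all(km_curve(r3)$surv == 1))

  # without censoring the curve equals one minus the empirical CDF
  set.seed(73)
  tt <- sample(1:50, 30, replace = TRUE)
  km <- km_curve(survival_records(tt, rep(1, 30), factor(rep("negative", 30))))
  expect_equal(km$surv, 1 - ecdf(tt)(km$time))
})

test_that("log-rank agrees with the per-event-time O-E oracle", {
  # identical groups: no signal
  base <- data.frame(time = c(2, 4, 6), event = 1)
  lr0 <- logrank(transform(base, group = "a"), transform(base, group = "b"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # six-patient fixture: hand O-E/V computation
  tm <- c(1, 3, 4, 6, 8, 9)
  ev <- c(1, 1, 0, 1, 1, 1)
  gr <- c("a", "b", "a", "a", "b", "b")
  oracle <- function(tm, ev, gr) {
    o_minus_e <- 0; v <- 0
    for (t in sort(unique(tm[ev == 1]))) {
      at_risk <- tm >= t
      n <- sum(at_risk); n_a <- sum(at_risk & gr == "a")
      d <- sum(tm == t & ev == 1)
      d_a <- sum(tm == t & ev == 1 & gr == "a")
      o_minus_e <- o_minus_e + d_a - d * n_a / n
      if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
    o_minus_e^2 / v
  }
  rec <- data.frame(time = tm, event = ev, group = gr)
  lr <- logrank(rec)
  expect_equal(lr$statistic, oracle(tm, ev, gr), tolerance = 1e-10)

  # relabelling the groups leaves the statistic unchanged
  rec_fl <- transform(rec, group = ifelse(group == "a", "b", "a"))
  expect_equal(logrank(rec_fl)$statistic, lr$statistic)

  expect_error(logrank(data.frame(time = 1:3, event = 0, group = "a"),
                       data.frame(time = 1:3, event = 0, group = "b")),
               "at least one event")
})

test_that("log-rank equals the Cox score test at the null", {
  set.seed(79)
  rec <- data.frame(time = sample(seq(1, 400, by = 1), 60),
                    event = rbinom(60, 1, 0.8),
                    group = rep(c("a", "b"), 30))
  lr <- logrank(rec)
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = rec,
                         ties = "breslow")
  expect_lt(abs(lr$statistic - fit$score), 1e-6)
})

test_that("Cox hazard ratios behave under relabelling and the null", {
  set.seed(83)
  n <- 400
  g <- rep(c("negative", "positive"), each = n / 2)
  tt <- rexp(n, 1 / 300)
  rec <- survival_records(pmin(tt, 1000), as.integer(tt < 1000),
                          factor(g, levels = c("negative", "positive")))
  cx <- cox_hr(rec)
  expect_gt(cx$hr, 0.8); expect_lt(cx$hr, 1.25)
  expect_equal(cx$n_events, sum(rec$event))

  flipped <- rec
  flipped$group <- factor(ifelse(rec$group == "positive", "negative", "positive"),
                          levels = c("negative", "positive"))
  expect_equal(cox_hr(flipped)$hr, 1 / cx$hr, tolerance = 1e-8)

  # monotone likelihood is an explicit error
  sep <- survival_records(c(1, 2, 3, 10, 11, 12), rep(1, 6),
                          factor(rep(c("negative", "positive"), each = 3),
                                 levels = c("negative", "positive")))
  expect_error(cox_hr(sep), "converge")
})

test_that("survival stratification by predicted status recovers a protective effect", {
  fx <- trained_study_fixture()
  preds <- predict_cases(fx$fit, fx$cohort, names(fx$cohort$cases),
                         mode = "DUET")
  res <- suppressMessages(survival_by_status(fx$cohort, predictions = preds))
  expect_lt(res$cox$hr, 1)
  expect_lt(res$logrank$p, 0.05)
  actual <- suppressMessages(survival_by_status(fx$cohort))
  expect_lt(actual$cox$hr, 1)
  expect_named(res$km, c("negative", "positive"))
})
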