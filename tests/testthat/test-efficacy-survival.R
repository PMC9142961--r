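# Tumor volume, doubling time, humane endpoints, Kaplan-Meier, log-rank.

test_that("ellipsoid volume follows V = 4/3 pi a b c", {
  expect_equal(ellipsoid_volume(1, 1, 1), 4 * pi / 3)
  expect_equal(ellipsoid_volume(3, 4, 5), 4 * pi / 3 * 60)
  expect_equal(ellipsoid_volume(2, 1, 1), 2 * ellipsoid_volume(1, 1, 1))
  expect_error(ellipsoid_volume(0, 1, 1), "positive")
  expect_error(ellipsoid_volume(1, -2, 1), "positive")
})

test_that("doubling-time fits are exact on noiseless exponentials and apply the exclusion rule", {
  days <- c(0, 3, 7, 10, 14, 17, 21)
  v <- 50 * 2^(days / 30)
  f <- fit_doubling_time(days, v)
  expect_equal(f$doubling_time, 30, tolerance = 1e-12)
  expect_equal(f$V0, 50, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_true(f$included)

  shr <- fit_doubling_time(days, 100 * 2^(-days / 20))
  expect_false(shr$included)
  expect_true(is.na(shr$doubling_time))
  expect_match(shr$reason, "decreased")

  expect_error(fit_doubling_time(c(1, 2), c(10, 20)), "3 measurements")
  expect_error(fit_doubling_time(days, c(0, v[-1])), "positive")
})

test_that("cohort doubling-time recovery stays within 10% at realistic caliper noise", {
  g <- efficacy_group("control", n = 10, doubling_time = 31.9, td_sdlog = 0)
  sim <- simulate_efficacy_cohort(g, seed = 19, caliper_cv = 0.05)
  fits <- fit_growth_cohort(sim$tumors)
  expect_true(all(fits$included))
  expect_lt(abs(mean(fits$doubling_time) - 31.9) / 31.9, 0.10)
})

test_that("humane endpoints pick the earliest crossing with the documented causes", {
  vols <- data.frame(day = c(95, 99, 103), volume = c(1500, 2100, 2500))
  rec <- apply_humane_endpoints(vols)
  expect_equal(rec$time, 99)
  expect_true(rec$event)
  expect_equal(rec$cause, "volume")

  # no crossing by day 150: censored there
  rec2 <- apply_humane_endpoints(data.frame(day = c(10, 50, 140),
                                            volume = c(100, 200, 400)))
  expect_false(rec2$event)
  expect_equal(rec2$time, 150)
  expect_equal(rec2$cause, "study-end-censor")

  # chronic weight loss beats a small tumor
  w <- data.frame(day = c(0, 20, 40), weight_g = c(20, 19, 15.5))
  rec3 <- apply_humane_endpoints(data.frame(day = c(0, 20, 40),
                                            volume = c(50, 60, 70)), w)
  expect_equal(rec3$cause, "weight-loss-chronic")
  expect_equal(rec3$time, 40)

  # acute rule: >15% within two days on the interpolated grid
  w4 <- data.frame(day = c(0, 7, 9), weight_g = c(20, 20, 16.5))
  rec4 <- apply_humane_endpoints(data.frame(day = c(0, 7, 9),
                                            volume = c(50, 60, 70)), w4)
  expect_equal(rec4$cause, "weight-loss-acute")

  # input flags become events with their own cause
  rec5 <- apply_humane_endpoints(
    data.frame(day = c(5, 10), volume = c(100, 120)),
    flags = data.frame(day = 10, cause = "ulceration"))
  expect_equal(rec5$cause, "ulceration")
  expect_error(apply_humane_endpoints(data.frame(day = numeric(0),
                                                 volume = numeric(0))),
               "empty")
})

test_that("truncating a series never yields an earlier event", {
  set.seed(77)
  days <- seq(21, 150, by = 7)
  vols <- data.frame(day = days, volume = 80 * 2^((days - 21) / 25) *
                       rlnorm(length(days), 0, 0.05))
  full <- apply_humane_endpoints(vols)
  for (cut in c(5, 10, 15)) {
    part <- apply_humane_endpoints(vols[seq_len(cut), ])
    expect_gte(part$time, min(full$time, max(vols$day[seq_len(cut)])) - 1e-9)
  }
})

test_that("the product-limit curve matches hand computation and the empirical survivor function", {
  rec <- data.frame(time = c(2, 4, 6), event = TRUE)
  k <- km_curve(rec)
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(k$median, 4)
  expect_true(k$median_reached)

  # without censoring the KM curve equals the empirical survivor function
  set.seed(5)
  tt <- sample(1:40, 25, replace = TRUE)
  k2 <- km_curve(data.frame(time = tt, event = TRUE))
  expect_equal(k2$surv, km_hand_nocensor(tt))

  allc <- km_curve(data.frame(time = c(150, 150, 150), event = FALSE))
  expect_true(all(allc$surv == 1))
  expect_false(allc$median_reached)
  expect_error(km_curve(data.frame(time = -1, event = TRUE)), "positive")
})

test_that("median survival is reported as not reached when most animals are censored", {
  rec <- data.frame(time = c(99, 120, rep(150, 8)),
                    event = c(TRUE, TRUE, rep(FALSE, 8)))
  k <- km_curve(rec)
  expect_false(k$median_reached)
  expect_true(is.na(k$median))
})

test_that("the log-rank test matches a manual statistic and behaves at the identity", {
  a <- data.frame(time = c(10, 20, 30, 45, 60), event = c(T, T, F, T, F))
  b <- data.frame(time = c(5, 15, 25, 35, 50), event = c(T, T, T, T, F))
  lr <- logrank_test(a, b)
  man <- logrank_manual(c(a$time, b$time), c(a$event, b$event),
                        rep(c("A", "B"), each = 5))
  expect_equal(lr$statistic, man, tolerance = 1e-9)

  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(logrank_test(a[0, ], b), "non-empty")
  noev <- data.frame(time = c(10, 20), event = FALSE)
  expect_error(logrank_test(noev, noev), "no events")
})

test_that("pairwise log-rank compares each treated group with the control", {
  g <- c(efficacy_group("control", n = 8, doubling_time = 20, td_sdlog = 0.2),
         efficacy_group("hi", n = 8, shrink_rate = -0.03))
  sim <- simulate_efficacy_cohort(g, seed = 23)
  surv <- build_survival(sim$tumors, sim$weights)
  pw <- pairwise_logrank(surv, control = "control")
  expect_equal(pw$group, "hi")
  expect_lt(pw$p, 0.05)
  expect_error(pairwise_logrank(surv, control = "nope"), "not found")
})
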