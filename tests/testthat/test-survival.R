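test_that("Kaplan-Meier matches the hand product-limit and survfit", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: flat at 1
  expect_true(all(kaplan_meier(c(2, 5), c(0, 0))$survival == 1))
  # single event drops to zero
  expect_equal(kaplan_meier(5, 1)$survival, 0)
  expect_error(kaplan_meier(-1, 1), "negative")
  # estimate is non-increasing and matches survfit on censored random data
  set.seed(13)
  for (i in 1:10) {
    s <- random_surv(25)
    km <- kaplan_meier(s$time, s$event)
    expect_true(all(diff(km$survival) <= 1e-12))
    fit <- survival::survfit(survival::Surv(s$time, s$event) ~ 1)
    expect_equal(km$survival, fit$surv)
  }
})

test_that("log-rank reproduces the hand hypergeometric example and symmetries", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, (7 / 6)^2 / (0.25 + 2 / 9), tolerance = 1e-12)
  expect_equal(sum(lr$observed), 4)
  expect_equal(sum(lr$observed - lr$expected), 0, tolerance = 1e-12)
  # identical groups: statistic exactly zero
  tm <- c(1, 3, 5, 1, 3, 5); ev <- c(1, 0, 1, 1, 0, 1)
  same <- logrank_test(tm, ev, rep(c("x", "y"), each = 3))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  # invariant to relabelling the groups
  s <- random_surv(30, seed = 99)
  g <- rep(c("a", "b"), 15)
  expect_equal(logrank_test(s$time, s$event, g)$chisq,
               logrank_test(s$time, s$event, ifelse(g == "a", "b", "a"))$chisq)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")),
               class = "modscreen_no_events")
})

test_that("log-rank agrees with survdiff on random censored data", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    s <- random_surv(n, event_p = 0.7)
    g <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    mine <- logrank_test(s$time, s$event, g)
    ref <- survival::survdiff(survival::Surv(s$time, s$event) ~ g)
    expect_equal(mine$chisq, unname(ref$chisq), tolerance = 1e-9)
    expect_equal(unname(mine$observed), unname(ref$obs), tolerance = 1e-12)
    expect_equal(unname(mine$expected), unname(ref$exp), tolerance = 1e-9)
  }
})

test_that("log-rank p is consistent with a label-permutation oracle", {
  set.seed(15)
  for (i in 1:4) {
    n <- 30
    s <- random_surv(n, event_p = 0.85)
    g <- rep(c("A", "B"), each = 15)
    obs <- logrank_test(s$time, s$event, g)
    perm <- vapply(1:2000, function(k) {
      logrank_test(s$time, s$event, sample(g))$chisq
    }, numeric(1))
    p_perm <- mean(perm >= obs$chisq - 1e-12)
    expect_lt(abs(p_perm - obs$p), 0.07)
  }
})

test_that("maxstat cut-point equals an exhaustive survdiff scan", {
  set.seed(16)
  for (i in 1:12) {
    n <- sample(15:30, 1)
    s <- random_surv(n, event_p = 0.8)
    v <- rnorm(n)
    mine <- maxstat_cutpoint(v, s$time, s$event, minprop = 0.1)
    sv <- sort(unique(v))
    mids <- (sv[-length(sv)] + sv[-1]) / 2
    k_min <- ceiling(0.1 * n)
    n_low <- vapply(mids, function(ct) sum(v <= ct), integer(1))
    mids <- mids[n_low >= k_min & (n - n_low) >= k_min]
    zs <- vapply(mids, function(ct) {
      sqrt(survival::survdiff(
        survival::Surv(s$time, s$event) ~ (v <= ct))$chisq)
    }, numeric(1))
    expect_equal(mine$cutpoint, mids[which.max(zs)])
    expect_equal(mine$abs_statistic, max(zs), tolerance = 1e-9)
    # minprop bounds respected on every output
    expect_gte(mine$n_low, k_min)
    expect_gte(mine$n_high, k_min)
  }
  expect_error(maxstat_cutpoint(rep(1, 20), rexp(20), rep(1, 20)),
               class = "modscreen_constant_marker")
})

test_that("maxstat finds a planted bimodal boundary", {
  found <- vapply(1:100, function(i) {
    set.seed(400 + i)
    n <- 100
    hi <- rep(c(FALSE, TRUE), each = n / 2)
    v <- ifelse(hi, rnorm(n, 2, 0.5), rnorm(n, -2, 0.5))
    tm <- rexp(n, ifelse(hi, 0.8, 0.2))
    cp <- maxstat_cutpoint(v, tm, rep(1L, n))$cutpoint
    cp > -2 && cp < 2
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("dichotomized log-rank reports the naive selected-split p and direction", {
  set.seed(17)
  s <- random_surv(60, event_p = 0.8)
  v <- rnorm(60)
  dl <- dichotomized_logrank(v, s$time, s$event)
  cp <- maxstat_cutpoint(v, s$time, s$event)
  lr <- logrank_test(s$time, s$event, ifelse(v <= dl$cutpoint, "low", "high"))
  expect_equal(dl$cutpoint, cp$cutpoint)
  expect_equal(dl$chisq, lr$chisq, tolerance = 1e-9)
  expect_equal(dl$p, lr$p, tolerance = 1e-9)
  # planted effect: high expression hazardous, direction reported as such
  sim <- simulate_expression_survival(
    1, 120, planted = data.frame(gene = 1, hazard_ratio = 4,
                                 cutpoint_quantile = 0.5),
    censoring_rate = 0.2, seed = 18)
  dh <- dichotomized_logrank(sim$expression[1, ],
                             sim$clinical$endpoint_time,
                             sim$clinical$endpoint_event)
  expect_equal(dh$direction, "high_worse")
  expect_lt(dh$p, 0.05)
})

test_that("the selected-split p-value is anti-conservative under the null", {
  # selection bias is documented, not corrected: null rejection far above 5%
  rej <- vapply(1:100, function(i) {
    set.seed(500 + i)
    s <- random_surv(60, event_p = 0.7)
    dichotomized_logrank(rnorm(60), s$time, s$event)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.15)
})

test_that("KM curves export to TSV and read back", {
  km <- kaplan_meier(c(1, 2, 2, 4), c(1, 0, 1, 1), unit = "years")
  path <- tempfile(fileext = ".tsv")
  write_km_tsv(km, path)
  back <- read.delim(path)
  expect_equal(back$survival, km$survival)
  expect_equal(back$n_risk, km$n_risk)
})
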