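test_that("the C-index matches hand counts and enumeration", {
  rec <- list(time = c(1, 2, 3), event = c(1, 1, 1))
  expect_equal(harrell_cindex(c(3, 2, 1), rec, n_boot = 0)$c, 1)
  expect_equal(harrell_cindex(c(2, 2, 2), rec, n_boot = 0)$c, 0.5)
  expect_equal(harrell_cindex(c(3, 1, 2), rec, n_boot = 0)$c, 2 / 3)

  # antisymmetry on tie-free data
  set.seed(30)
  r <- rnorm(20); time <- rexp(20); event <- rbinom(20, 1, 0.8)
  c1 <- harrell_cindex(r, list(time = time, event = event), n_boot = 0)$c
  c2 <- harrell_cindex(-r, list(time = time, event = event), n_boot = 0)$c
  expect_equal(c1 + c2, 1, tolerance = 1e-12)

  # cross-check against the survival package on tie-free data
  cc <- survival::concordance(survival::Surv(time, event) ~ r, reverse = TRUE)
  expect_equal(c1, unname(cc$concordance), tolerance = 1e-12)

  expect_error(harrell_cindex(1:3, list(time = 1:3, event = c(0, 0, 0)),
                              n_boot = 0),
               "comparable")
  ci <- harrell_cindex(r, list(time = time, event = event), n_boot = 100,
                       seed = 2)
  expect_true(ci$ci[1] <= c1 && c1 <= ci$ci[2])
})

test_that("Kaplan-Meier estimates follow the product-limit rule", {
  km <- km_estimate(list(time = c(1, 2), event = c(1, 1)))
  expect_equal(km_surv_at(km, 1), 0.5)
  expect_equal(km_surv_at(km, 2), 0)

  kmc <- km_estimate(list(time = 1:4, event = rep(0, 4)))
  expect_equal(km_surv_at(kmc, 4), 1)

  km3 <- km_estimate(list(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km_surv_at(km3, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(km_surv_at(km3, 3), 0)
  expect_equal(km_surv_at(km3, 0.99), 1)   # left of the first event
})

test_that("the log-rank test matches explicit hypergeometric sums", {
  time <- c(1, 2, 3, 4, 5, 6); event <- c(1, 1, 0, 1, 1, 1)
  grp <- c(0, 0, 0, 1, 1, 1)
  lr <- logrank_test(list(time = time, event = event), grp)
  # hand-computed O/E/V sums over the event times
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    n <- sum(at); n1 <- sum(at & grp == 1)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$statistic, (O - E)^2 / V, tolerance = 1e-10)

  # identical groups: statistic 0, p 1
  t2 <- rep(c(1, 2, 3, 4), 2); e2 <- rep(c(1, 0, 1, 1), 2)
  g2 <- rep(c(0, 1), each = 4)
  lr2 <- logrank_test(list(time = t2, event = e2), g2)
  expect_equal(lr2$statistic, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1)

  # extreme separation at n = 20 + 20
  lr3 <- logrank_test(list(time = c(1:20, 101:120), event = rep(1, 40)),
                      rep(c("early", "late"), each = 20))
  expect_lt(lr3$p, 0.05)
  expect_error(logrank_test(list(time = 1:4, event = rep(1, 4)),
                            rep("a", 4)), "2 groups")
})

test_that("Cox regression recovers nulls and matches a brute-force optimum", {
  set.seed(31)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05)            # independent of x
  rec <- list(time = time, event = rep(1, n))
  fit <- cox_regression(data.frame(x = x), rec, mode = "multi")
  expect_lt(abs(fit$table$beta), 0.15)

  # 5-patient fit equals the brute-force partial-likelihood maximum
  d5 <- data.frame(x = c(0, 1, 1, 0, 1))
  r5 <- list(time = c(2, 1, 4, 3, 5), event = c(1, 1, 0, 1, 1))
  fit5 <- cox_regression(d5, r5, mode = "multi")
  nll5 <- function(b) cox_nll_brute(b * d5$x, r5$time, r5$event)
  bstar <- optimize(nll5, c(-5, 5), tol = 1e-9)$minimum
  expect_equal(fit5$table$beta, bstar, tolerance = 1e-4)

  expect_error(cox_regression(data.frame(x = rep(1, 5)), r5), "constant")

  # uni mode: one row per covariate, each fitted alone
  d2 <- data.frame(a = rnorm(50), b = rnorm(50))
  r2 <- list(time = rexp(50), event = rbinom(50, 1, 0.8))
  uni <- cox_regression(d2, r2, mode = "uni")
  expect_equal(nrow(uni$table), 2L)
  expect_true(all(uni$table$hr > 0))
})

test_that("time-dependent AUC reduces to the binary AUC without censoring", {
  set.seed(32)
  n <- 60
  r <- rnorm(n); time <- rexp(n, rate = exp(r) / 20)
  rec <- list(time = time, event = rep(1, n))
  h <- median(time)
  expect_equal(td_roc(r, rec, h),
               auc_binary(r, as.integer(time <= h)), tolerance = 1e-12)

  # perfect ordering gives 1; constant risks give 1/2
  tord <- sort(rexp(20), decreasing = TRUE)
  rec2 <- list(time = tord, event = rep(1, 20))
  expect_equal(td_roc(seq_len(20), rec2, median(tord)), 1)
  expect_equal(td_roc(rep(0, 20), rec2, median(tord)), 0.5)

  expect_error(td_roc(r, rec, max(time) + 1), "survivors")
})

test_that("the Youden cutoff maximizes J over score midpoints", {
  rc <- roc_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(rc$threshold, 0.5)
  expect_equal(rc$j, 1)

  # exhaustive-threshold oracle on random label assignments
  set.seed(33)
  for (k in 1:20) {
    s <- sort(runif(8))
    lab <- sample(c(0, 0, 0, 1, 1, 1, sample(0:1, 2, replace = TRUE)))
    if (length(unique(lab)) < 2) next
    ours <- roc_cutoff(s, lab)
    u <- sort(unique(s)); thr <- (u[-1] + u[-length(u)]) / 2
    jall <- sapply(thr, function(th)
      mean(s[lab == 1] > th) + mean(s[lab == 0] <= th) - 1)
    expect_equal(ours$j, max(jall), tolerance = 1e-12)
    # flipping labels yields the same optimal J with reversed direction
    flip <- roc_cutoff(-s, 1 - lab)
    expect_equal(flip$j, ours$j, tolerance = 1e-12)
  }
  expect_error(roc_cutoff(1:4, rep(1, 4)), "both classes")
})

test_that("calibration bins cover the cohort and sit near the diagonal", {
  set.seed(34)
  n <- 600
  lp <- rnorm(n)
  time <- rexp(n, rate = 0.03 * exp(lp))
  cens <- runif(n, 0, 80)
  rec <- list(time = pmin(time, cens), event = as.integer(time <= cens))
  h <- 24
  pred <- exp(-0.03 * h * exp(lp))
  cal <- calibration_curve(pred, rec, horizon = h, bins = 3)
  expect_equal(sum(cal$n), n)
  expect_lt(mean(abs(cal$pred_mean - cal$obs_surv)), 0.1)
  expect_error(calibration_curve(pred * 2, rec, h), "\\[0, 1\\]")
})

test_that("net benefit reproduces closed forms and honours the bounds", {
  # prevalence 0.3, no censoring
  rec <- list(time = c(rep(5, 30), rep(50, 70)), event = c(rep(1, 30), rep(0, 100)[1:70]))
  pred_all <- rep(1, 100)
  dc <- decision_curve(pred_all, rec, horizon = 10, thresholds = 0.2)
  expect_equal(dc$nb_all, 0.3 - 0.7 * 0.25, tolerance = 1e-12)
  expect_equal(dc$nb_model, dc$nb_all)      # treat-all predictor
  expect_equal(dc$nb_none, 0)

  # perfect predictor attains the prevalence below pt = 1
  perfect <- c(rep(1, 30), rep(0, 70))
  dcp <- decision_curve(perfect, rec, horizon = 10,
                        thresholds = c(0.1, 0.3, 0.5))
  expect_true(all(abs(dcp$nb_model - 0.3) < 1e-12))

  # any predictor is dominated by the perfect one
  set.seed(35)
  noisy <- pmin(pmax(perfect + rnorm(100, sd = 0.4), 0), 1)
  dcn <- decision_curve(noisy, rec, horizon = 10,
                        thresholds = c(0.1, 0.3, 0.5))
  expect_true(all(dcn$nb_model <= dcp$nb_model + 1e-12))
})

test_that("nomogram points span 0-100 and round-trip the linear predictor", {
  set.seed(36)
  n <- 120
  df <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5))
  time <- rexp(n, 0.05 * exp(0.8 * df$a - 0.5 * df$b))
  rec <- list(time = time, event = rep(1, n))
  fit <- cox_regression(df, rec, mode = "multi")
  nm <- nomogram_points(fit)
  expect_equal(max(nm$points$points_range), 100, tolerance = 1e-9)

  pts <- nomogram_total_points(nm, df)
  lp <- nomogram_lp(nm, pts)
  lp_direct <- as.vector(as.matrix(df) %*% fit$table$beta)
  expect_equal(lp, lp_direct, tolerance = 1e-6)

  # doubling all betas leaves point assignments unchanged
  fit2 <- fit
  fit2$table$beta <- 2 * fit$table$beta
  nm2 <- nomogram_points(fit2)
  expect_equal(nomogram_total_points(nm2, df), pts, tolerance = 1e-9)

  # single covariate: its range maps to exactly 0-100
  fit1 <- cox_regression(df["a"], rec, mode = "multi")
  nm1 <- nomogram_points(fit1)
  expect_equal(nm1$points$points_range, 100)
})

test_that("risk stratification partitions the cohort and flags separation", {
  set.seed(37)
  n <- 120
  r <- rnorm(n)
  time <- rexp(n, 0.05 * exp(1.5 * r))
  rec <- list(time = time, event = rep(1, n))
  st <- stratify_by_cutoff(r, median(r), rec)
  expect_equal(sum(st$sizes), n)
  expect_lt(st$logrank$p, 0.05)
  expect_error(stratify_by_cutoff(r, min(r) - 1, rec), "empty")
})

test_that("Breslow baselines convert risks into valid survival curves", {
  set.seed(38)
  n <- 150
  r <- rnorm(n)
  time <- rexp(n, 0.05 * exp(r))
  rec <- list(time = time, event = rbinom(n, 1, 0.9))
  bl <- breslow_baseline(r, rec)
  expect_true(all(diff(bl$cumhaz) >= 0))
  s <- survival_probability(bl, r, median(time))
  expect_true(all(s >= 0 & s <= 1))
  # higher risk, lower survival
  expect_true(all(diff(s[order(r)]) <= 1e-12))
})
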