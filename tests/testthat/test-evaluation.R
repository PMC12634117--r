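# Evaluation battery vs brute-force oracles and the survival/pROC packages.

test_that("auroc matches pairwise enumeration on random instances", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(60)
  for (r in 1:40) {
    n <- sample(5:60, 1)
    sc <- round(rnorm(n), 1)  # coarse scores force ties
    la <- rbinom(n, 1, 0.4)
    if (length(unique(la)) < 2) next
    expect_equal(auroc(sc, la), auroc_oracle(sc, la), tolerance = 1e-12)
  }
})

test_that("DeLong machinery agrees with pROC and is null for self-comparison", {
  set.seed(61)
  sc <- rnorm(80); la <- rbinom(80, 1, 0.5)
  self <- delong_test(sc, sc, la)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  sc2 <- sc + rnorm(80, 0, 0.7)
  dt <- delong_test(sc, sc2, la)
  r1 <- suppressMessages(pROC::roc(la, sc, direction = "<"))
  r2 <- suppressMessages(pROC::roc(la, sc2, direction = "<"))
  pt <- suppressMessages(pROC::roc.test(r1, r2, method = "delong", paired = TRUE))
  expect_equal(dt$p, pt$p.value, tolerance = 1e-9)
  expect_equal(delong_variance(sc, la)$var, as.numeric(pROC::var(r1)),
               tolerance = 1e-10)
})

test_that("harrell_c matches the O(n^2) oracle and survival::concordance", {
  expect_equal(harrell_c(c(1, 3, 5), c(1, 1, 1), c(0.2, 0.9, 0.5)), 1 / 3)
  expect_equal(harrell_c(1:4, rep(1, 4), rep(2, 4)), 0.5)  # all score ties
  expect_equal(harrell_c(1:5, rep(1, 5), 5:1), 1)          # anti-ordered
  expect_error(harrell_c(c(1, 2), c(0, 1), c(1, 2)), "no usable pairs")
  set.seed(62)
  for (r in 1:40) {
    n <- sample(10:200, 1)
    tt <- round(rexp(n), 2)
    ev <- rbinom(n, 1, 0.6)
    sc <- round(rnorm(n), 1)
    if (sum(ev) == 0) next
    ours <- tryCatch(harrell_c(tt, ev, sc), error = function(e) NA)
    orc <- cindex_oracle(tt, ev, sc)
    if (is.na(orc)) next
    expect_equal(ours, orc, tolerance = 1e-12)
  }
  # distinct times, no ties: equals survival::concordance
  for (r in 1:10) {
    n <- 100
    tt <- rexp(n); ev <- rbinom(n, 1, 0.5); sc <- rnorm(n)
    if (sum(ev) == 0) next
    expect_equal(harrell_c(tt, ev, sc),
                 survival::concordance(survival::Surv(tt, ev) ~ sc,
                                       reverse = TRUE)$concordance,
                 tolerance = 1e-12)
  }
})

test_that("with no censoring harrell_c reduces to an AUROC-type rank statistic", {
  set.seed(63)
  for (r in 1:20) {
    n <- sample(10:200, 1)
    tt <- rexp(n)           # continuous: no time ties
    sc <- rnorm(n)
    expect_equal(harrell_c(tt, rep(1, n), sc),
                 cindex_oracle(tt, rep(1, n), sc), tolerance = 1e-12)
  }
})

test_that("km_curve is the product-limit estimator", {
  km <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))
  expect_equal(km_at(km, c(0.5, 1, 2.5, 10)), c(1, 2 / 3, 2 / 3, 0))
  expect_true(all(km_curve(c(1, 2), c(0, 0))$surv == 1))     # no events
  expect_equal(km_curve(rep(1, 4), rep(1, 4))$surv, 0)       # all events at 1
  set.seed(64)
  for (r in 1:30) {
    n <- sample(5:80, 1)
    tt <- round(rexp(n), 1)
    ev <- rbinom(n, 1, 0.5)
    km <- km_curve(tt, ev)
    at <- sort(unique(tt))
    expect_equal(km_at(km, at), vapply(at, function(a) km_oracle(tt, ev, a), 0),
                 tolerance = 1e-12)
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    expect_equal(km_at(km, sf$time), sf$surv, tolerance = 1e-12)
  }
})

test_that("brier score at the horizon follows its closed form", {
  expect_equal(brier_at_horizon(c(1, 8), c(1, 0), c(1, 0), 5), 0)   # perfect
  expect_equal(brier_at_horizon(c(2, 9, 3), c(1, 0, 1), rep(0.5, 3), 5), 0.25)
  expect_equal(brier_at_horizon(c(6, 2), c(0, 1), c(0.2, 0.8), 5),
               ((0.2 - 0)^2 + (0.8 - 1)^2) / 2)
  # censored before horizon excluded
  expect_equal(brier_at_horizon(c(2, 6), c(0, 0), c(0.9, 0.1), 5), 0.01)
  expect_error(brier_at_horizon(2, 0, 0.5, 5), "determinate")
})

test_that("continuous NRI counts reclassification directions", {
  expect_equal(continuous_nri(c(0.1, 0.2), c(0.1, 0.2), c(1, 9), c(1, 0)), 0)
  # events moved +0.1/-0.1, one non-event moved down
  old <- c(0.5, 0.5, 0.5); new <- c(0.6, 0.4, 0.2)
  expect_equal(continuous_nri(old, new, c(1, 2, 9), c(1, 1, 0)), 1)
  # everyone moved up, half events: +1 - 1 = 0
  expect_equal(continuous_nri(c(0.2, 0.2), c(0.4, 0.4), c(1, 9), c(1, 0)), 0)
  expect_error(continuous_nri(c(0.1, 0.2), c(0.2, 0.3), c(1, 2), c(1, 1)),
               "non-events")
})

test_that("quartile cutpoints freeze on the tuning set and recover hazards", {
  cuts <- quantile(1:100, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_equal(cuts, c(25.75, 50.5, 75.25))
  set.seed(65)
  n <- 1200
  z <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(z))
  cens <- rexp(n, 0.05)
  test <- data.frame(score = z, time = pmin(tt, cens),
                     event = as.numeric(tt <= cens),
                     age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5))
  qs <- suppressWarnings(
    quartile_stratify(1:100, within(test, score <- 50 + 10 * z)))
  expect_equal(as.character(qs$group[within(test, s <- 50 + 10 * z)$s > 80][1]), "high")
  expect_equal(length(qs$km), 4)
  # planted hazard contrast between top and bottom quartile recovered
  expect_gt(qs$hr["hr"], 1)
  lo <- qnorm(0.125); hi <- qnorm(0.875)  # quartile-centre log-hazard gap
  expect_true(qs$hr["lower"] < exp(hi - lo) && qs$hr["upper"] > 1)
  # null: identical hazards across groups
  test0 <- test; test0$score <- rnorm(n); test0$time <- rexp(n, 0.1)
  test0$event <- 1
  qs0 <- suppressWarnings(quartile_stratify(rnorm(500), test0))
  expect_true(qs0$hr["lower"] < 1 && qs0$hr["upper"] > 1)
})

test_that("cox_model_comparison honours nesting and detects added signal", {
  set.seed(66)
  n <- 500
  age <- rnorm(n, 60, 10); sexn <- rbinom(n, 1, 0.5); z <- rnorm(n)
  tt <- rexp(n, 0.08 * exp(0.02 * (age - 60) + 0.8 * z))
  cens <- rexp(n, 0.05)
  d <- data.frame(time = pmin(tt, cens), event = as.numeric(tt <= cens),
                  age = age, sex = sexn, ai = z + rnorm(n, 0, 0.3))
  r <- cox_model_comparison(d, c("age", "sex"), "ai")
  expect_gt(r$cindex["both"], r$cindex["baseline"])
  expect_lt(r$lrt["p"], 0.001)
  expect_equal(unname(r$lrt["df"]), 1)
  # nesting identity: adding a constant column changes nothing
  d$const_ai <- 1
  suppressWarnings(r0 <- cox_model_comparison(d, c("age", "sex"), "const_ai"))
  expect_equal(unname(r0$lrt["chisq"]), 0, tolerance = 1e-6)
})

test_that("threshold metrics come from the 2x2 table; AUPRC is stepwise", {
  m <- classification_threshold_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0), 0.5)
  expect_equal(unname(m[c("sensitivity", "specificity", "ppv", "npv")]),
               c(0.5, 0.5, 0.5, 0.5))
  perfect <- classification_threshold_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0), 0.5)
  expect_equal(unname(perfect), c(1, 1, 1, 1, 1))
  all_pos <- classification_threshold_metrics(c(0.9, 0.1), c(1, 0), 0)
  expect_equal(unname(all_pos["sensitivity"]), 1)
  expect_equal(unname(all_pos["specificity"]), 0)
  expect_true(is.na(all_pos["npv"]))  # empty denominator reported as NA
  # AUPRC for a perfectly inverted classifier is below prevalence-based AP
  bad <- classification_threshold_metrics(c(0.1, 0.9), c(1, 0), 0.5)
  expect_lt(bad["auprc"], 0.75)
})

test_that("serial trajectories aggregate scores into 90-day bins", {
  d <- data.frame(score = c(0.1, 0.2, 0.5, 0.6),
                  ecg = as.Date("2020-01-01") + c(-300, -200, -100, -10),
                  evt = as.Date("2020-01-01"))
  tr <- serial_trajectory(d$score, d$ecg, d$evt)
  expect_equal(sum(tr$n), 4)
  expect_true(all(diff(tr$bin) > 0))
  # rising morphology -> rising mean toward bin 0
  expect_gt(cor(tr$bin, tr$mean, method = "spearman"), 0)
  one <- serial_trajectory(0.4, as.Date("2020-01-01"), as.Date("2020-06-01"))
  expect_equal(nrow(one), 1)
  flat <- serial_trajectory(rep(0.3, 6), as.Date("2020-01-01") + (0:5) * 100,
                            rep(as.Date("2021-01-01"), 6))
  expect_true(all(abs(flat$mean - 0.3) < 1e-12))
})

test_that("imaging associations are adjusted and standardized", {
  set.seed(67)
  n <- 400
  age <- rnorm(n, 60, 10); sex <- sample(c("male", "female"), n, TRUE)
  pred <- rnorm(n)
  meas <- data.frame(
    la_volume = 50 + 5 * pred + 0.3 * age + rnorm(n, 0, 4),
    noise = rnorm(n),
    constant = rep(1, n))
  expect_message(
    out <- imaging_association(pred, meas, age, sex), "skipping 'constant'")
  expect_equal(nrow(out), 2)
  expect_gt(out$beta[out$measurement == "la_volume"], 0)
  expect_lt(out$p[out$measurement == "la_volume"], 1e-6)
  expect_true(out$lower[out$measurement == "noise"] < 0 &&
                out$upper[out$measurement == "noise"] > 0)
  # prediction regressed on itself: standardized coefficient 1
  self <- suppressWarnings(
    imaging_association(pred, data.frame(self = pred), age, sex))
  expect_equal(self$beta, 1, tolerance = 1e-8)
})

test_that("metrics are invariant to subject permutation", {
  set.seed(68)
  n <- 120
  tt <- rexp(n); ev <- rbinom(n, 1, 0.5); sc <- rnorm(n)
  la <- rbinom(n, 1, 0.4)
  perm <- sample(n)
  expect_equal(auroc(sc, la), auroc(sc[perm], la[perm]))
  expect_equal(harrell_c(tt, ev, sc), harrell_c(tt[perm], ev[perm], sc[perm]))
  expect_equal(brier_at_horizon(tt, ev, plogis(sc), 1),
               brier_at_horizon(tt[perm], ev[perm], plogis(sc[perm]), 1))
  expect_equal(km_curve(tt, ev), km_curve(tt[perm], ev[perm]))
})

test_that("bootstrap CIs bracket the point estimate deterministically", {
  set.seed(69)
  sc <- rnorm(300); la <- rbinom(300, 1, plogis(sc))
  ci <- bootstrap_ci(function(i) auroc(sc[i], la[i]), 300, B = 200, seed = 3)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  ci2 <- bootstrap_ci(function(i) auroc(sc[i], la[i]), 300, B = 200, seed = 3)
  expect_identical(ci$replicates, ci2$replicates)
})
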