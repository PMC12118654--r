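# Log-rank, median split, inner loop, majority vote, Cox, KM evaluation.

test_that("log-rank agrees with survival::survdiff on randomized fixtures", {
  set.seed(71)
  for (k in 1:20) {
    n <- sample(8:60, 1)
    t <- round(rexp(n, 0.2), 2)           # rounding forces ties
    e <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(e) == 0) next
    ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    lr <- logrank_test(t[g == 0], e[g == 0], t[g == 1], e[g == 1])
    expect_equal(lr$chi2, ref$chisq, tolerance = 1e-10)
    expect_equal(lr$p, stats::pchisq(ref$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    ## symmetry in group order
    lr2 <- logrank_test(t[g == 1], e[g == 1], t[g == 0], e[g == 0])
    expect_equal(lr$chi2, lr2$chi2)
  }
})

test_that("log-rank degenerate inputs give statistic 0, p 1", {
  t <- c(1, 2, 3); e <- c(1L, 0L, 1L)
  same <- logrank_test(t, e, t, e)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  none <- logrank_test(c(1, 2), c(0L, 0L), c(3, 4), c(0L, 0L))
  expect_true(none$degenerate)
  expect_equal(none$p, 1)
})

test_that("median split halves by (value, id) with stable ties", {
  sp <- median_split(c(5, 1, 4, 2, 6, 3))
  expect_equal(sort(sp$low), which(c(5, 1, 4, 2, 6, 3) <= 3))
  expect_length(sp$low, 3); expect_length(sp$high, 3)
  sp2 <- median_split(c(1, 1, 2, 2))
  expect_equal(sort(sp2$low), c(1, 2))
  ## ties straddling the median are resolved by id order, deterministically
  sp3 <- median_split(c(2, 2, 2, 1), ids = c("a", "b", "c", "d"))
  expect_equal(sort(sp3$low), c(1, 4))     # value 1, then tie "a" before "b"
  expect_error(median_split(c(3, 3, 3)), "tied")
  expect_error(median_split(c(1, NA)), "defined")
  expect_error(median_split(2), ">= 2")
})

test_that("inner loop: determinism, shorter/longer attribution, exclusions", {
  co <- generate_cohort(n_patients = 40,
                        planted = c("density of CD8 in Tumor in center" = 3),
                        seed = 72)
  X <- co$parameters
  a <- inner_loop(X, co$survival$time, co$survival$event, reps = 300,
                  seed = 9)
  b <- inner_loop(X, co$survival$time, co$survival$event, reps = 300,
                  seed = 9)
  expect_identical(a, b)
  pl <- a[a$parameter == "density of CD8 in Tumor in center", ]
  expect_equal(nrow(pl), 1L)
  ## high density is hazardous: shorter-survival group has the larger mean
  expect_gt(pl$mean_short, pl$mean_long)
  ## the planted parameter tops the significance counts
  expect_equal(which.max(a$n_significant_reps),
               which(a$parameter == "density of CD8 in Tumor in center"))
  ## a constant parameter can never be split
  X2 <- X
  X2[["area of Stroma in center"]] <- 1
  c_ <- inner_loop(X2, co$survival$time, co$survival$event, reps = 50,
                   seed = 9)
  expect_false("area of Stroma in center" %in% c_$parameter)
  expect_equal(unname(attr(c_, "skipped")["area of Stroma in center"]), 50L)
})

test_that("majority vote follows the closer-to-mean rule with stated ties", {
  model <- structure(
    data.frame(parameter = c("p1", "p2", "p3"),
               n_significant_reps = c(5L, 5L, 5L),
               mean_short = c(10, 10, 10), mean_long = c(0, 0, 0)),
    class = c("classifier_model", "data.frame"))
  X <- rbind(c(p1 = 1, p2 = 1, p3 = 1),      # 3 long votes -> good
             c(p1 = 9, p2 = 9, p3 = 1),      # 2 short -> bad
             c(p1 = 5, p2 = 9, p3 = 1),      # equidistant votes long -> good
             c(p1 = NA, p2 = NA, p3 = 1))    # abstentions; 1 long of 1 -> good
  expect_equal(classify_patients(X, model), c("good", "bad", "good", "good"))
  ## even-sized model, 1-1 tie -> bad (conservative)
  model2 <- structure(model[1:2, ], class = c("classifier_model", "data.frame"))
  expect_equal(classify_patients(rbind(c(p1 = 1, p2 = 9, p3 = 0)), model2),
               "bad")
  ## all parameters missing -> unclassifiable
  expect_true(is.na(classify_patients(rbind(c(p1 = NA, p2 = NA, p3 = 0)),
                                      model2)))
})

test_that("Kaplan-Meier evaluation equals the hand-computed product limit", {
  fx <- km_fixture()
  model <- structure(
    data.frame(parameter = "p", n_significant_reps = 1L,
               mean_short = 1, mean_long = 0),
    class = c("classifier_model", "data.frame"))
  ## 6 fixture subjects classified "bad", 3 immortal subjects "good"
  X <- cbind(p = c(rep(1, 6), rep(0, 3)))
  time <- c(fx$time, c(12, 13, 14))
  event <- c(fx$event, c(0L, 0L, 0L))
  ev <- evaluate_classifier(model, X, time, event)
  expect_equal(ev$status, "ok")
  expect_equal(unname(ev$groups["bad"]), 6L)
  ## product-limit at t = 5: survivors of events at 1, 3, 4
  expect_equal(ev$os$os5[ev$os$group == "bad"], fx$surv[5])
  expect_equal(ev$os$os10[ev$os$group == "bad"], fx$surv[6])
  ## no events before year 5 in the good group -> 5-year OS 100%
  expect_equal(ev$os$os5[ev$os$group == "good"], 1)
  ## direct survfit cross-check of the whole fixture curve
  fit <- survival::survfit(survival::Surv(fx$time, fx$event) ~ 1)
  expect_equal(summary(fit, times = fx$time)$surv, fx$surv)
  ## single-group classification aborts cleanly
  ev2 <- evaluate_classifier(model, cbind(p = rep(1, 6)), fx$time, fx$event)
  expect_equal(ev2$status, "degenerate")
})

test_that("Cox (Breslow) matches a hand-coded partial likelihood", {
  ## tiny fixture with a tie, Breslow partial log-likelihood maximized
  ## numerically in the test (independent of survival::coxph internals)
  t <- c(2, 2, 4, 5, 7, 9)
  e <- c(1L, 1L, 1L, 0L, 1L, 0L)
  x <- c(1, 0, 1, 1, 0, 0)
  breslow_ll <- function(b) {
    ll <- 0
    for (tt in unique(t[e == 1])) {
      d <- which(t == tt & e == 1)
      risk <- which(t >= tt)
      ll <- ll + b * sum(x[d]) - length(d) * log(sum(exp(b * x[risk])))
    }
    ll
  }
  b_hat <- stats::optimize(breslow_ll, c(-5, 5), maximum = TRUE)$maximum
  fit <- cox_regression(x, t, e)
  expect_equal(log(fit$hr), b_hat, tolerance = 1e-4)
  ## null covariate at large n: HR near 1
  set.seed(73)
  n <- 1500
  tt <- rexp(n, 0.1); ee <- rbinom(n, 1, 0.8); xx <- rbinom(n, 1, 0.5)
  f2 <- cox_regression(xx, tt, ee)
  expect_lt(abs(f2$hr - 1), 0.1)
  expect_error(cox_regression(xx, tt, rep(0L, n)), "at least one event")
})

test_that("planted median-split hazard ratios are covered by the Cox CI", {
  ## HR 0.3 between median-split groups, n = 63: the 95% CI covers the truth
  ## in about 95% of draws (checked loosely over 20 seeds)
  cover <- 0L
  for (s in 1:20) {
    set.seed(800 + s)
    grp <- rep(c(0, 1), length.out = 63)
    tt <- rexp(63, 0.12 * 0.3^grp)
    cc <- runif(63, 10, 15)
    time <- pmin(tt, cc); event <- as.integer(tt <= cc)
    f <- cox_regression(grp, time, event)
    if (f$ci_low <= 0.3 && 0.3 <= f$ci_high) cover <- cover + 1L
  }
  expect_gte(cover, 17L)
})

test_that("ranking and final classifier recover a planted parameter", {
  pl <- c("density of CD8 in Tumor in center" = 2.5,
          "area of Tumor in center" = 0.4)
  co <- generate_cohort(planted = pl, seed = 74)
  rk <- rank_parameters(co$parameters, co$survival$time, co$survival$event,
                        outer_reps = 40, inner_reps = 150, seed = 75)
  expect_s3_class(rk, "ranking_result")
  expect_equal(nrow(rk$log), 40L)
  expect_true(all(rk$hits <= sum(rk$log$hit)))
  top <- names(sort(rk$hits, decreasing = TRUE))[1:10]
  expect_true("density of CD8 in Tumor in center" %in% top)
  ## determinism of the full nested loop
  rk2 <- rank_parameters(co$parameters, co$survival$time, co$survival$event,
                         outer_reps = 5, inner_reps = 50, seed = 76)
  rk3 <- rank_parameters(co$parameters, co$survival$time, co$survival$event,
                         outer_reps = 5, inner_reps = 50, seed = 76)
  expect_identical(rk2$hits, rk3$hits)
  expect_identical(rk2$log, rk3$log)
  ## final classifier: planted means on the correct sides, JSON round trip
  m <- build_final_classifier(co$parameters, co$survival$time,
                              co$survival$event,
                              names(pl), reps = 300, seed = 77)
  expect_s3_class(m, "classifier_model")
  d <- m[m$parameter == "density of CD8 in Tumor in center", ]
  expect_gt(d$mean_short, d$mean_long)
  a <- m[m$parameter == "area of Tumor in center", ]
  expect_lt(a$mean_short, a$mean_long)     # protective: short survivors low
  pth <- tempfile(fileext = ".json")
  save_classifier(m, pth)
  m2 <- load_classifier(pth)
  expect_equal(as.data.frame(m), as.data.frame(m2))
  ## single-parameter model classifies by the closer-to-mean rule
  m1 <- structure(m[1, ], class = c("classifier_model", "data.frame"))
  grp <- classify_patients(co$parameters, m1)
  v <- co$parameters[[m1$parameter]]
  expect_equal(grp == "good",
               abs(v - m1$mean_long) <= abs(v - m1$mean_short))
})

test_that("sensitivity/specificity stratify extreme survivors correctly", {
  model <- structure(
    data.frame(parameter = "p", n_significant_reps = 1L,
               mean_short = 1, mean_long = 0),
    class = c("classifier_model", "data.frame"))
  ## short survivors carry p = 1 ("bad"), long survivors p = 0 ("good")
  X <- cbind(p = c(1, 1, 0, 0, 1))
  time <- c(2, 3, 11, 12, 11)
  event <- c(1L, 1L, 0L, 0L, 0L)
  ss <- sensitivity_specificity(model, X, time, event)
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$n_short, 2L)
  expect_equal(ss$n_long, 3L)
  expect_equal(ss$specificity, 2 / 3)      # one long survivor voted bad
  ## inverted model scores zero on both
  inv <- structure(
    data.frame(parameter = "p", n_significant_reps = 1L,
               mean_short = 0, mean_long = 1),
    class = c("classifier_model", "data.frame"))
  ss2 <- sensitivity_specificity(inv, X, time, event)
  expect_equal(ss2$sensitivity, 0)
  expect_lt(ss2$specificity, 0.5)
})

test_that("Spearman correlations match cor.test and handle edge cases", {
  set.seed(78)
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"], d = -X[, "a"], e = rep(1, 20))
  ct <- correlate_parameters(X)
  expect_equal(ct$rho["a", "c"], 1)
  expect_equal(ct$rho["a", "d"], -1)
  expect_true(is.na(ct$rho["a", "e"]))     # constant column undefined
  ref <- stats::cor.test(X[, "a"], X[, "b"], method = "spearman",
                         exact = FALSE)
  expect_equal(ct$rho["a", "b"], unname(ref$estimate))
  expect_equal(ct$p["a", "b"], ref$p.value)
  expect_error(correlate_parameters(X[1:2, ]), ">= 3")
})
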