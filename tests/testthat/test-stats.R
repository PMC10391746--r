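test_that("ROC matches exhaustive pair counting and handles edge cases", {
  # perfectly separated
  expect_equal(ht_roc(c(0, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  # interleaved: 3 of 4 discordant-free pairs
  expect_equal(ht_roc(c(0, 1, 2, 3), c(FALSE, TRUE, FALSE, TRUE))$auc, 0.75)
  # complete ties
  expect_equal(ht_roc(rep(2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc,
               0.5)
  expect_error(ht_roc(1:4, rep(TRUE, 4)), "both outcome classes")

  # pair-counting oracle on random data with ties
  set.seed(3)
  for (rep in 1:20) {
    sc <- sample(0:7, 30, replace = TRUE)
    y <- runif(30) < 0.4
    if (!any(y) || all(y)) next
    pos <- sc[y]; neg <- sc[!y]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(ht_roc(sc, y)$auc, mean(pairs))
  }
})

test_that("ROC AUC agrees with an independent implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(11)
  sc <- sample(0:7, 80, replace = TRUE)
  y <- runif(80) < plogis(sc - 3)
  if (any(y) && !all(y)) {
    ref <- suppressMessages(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                                direction = "<")))
    expect_equal(ht_roc(sc, y)$auc, as.numeric(ref))
    # invariance under a strictly monotone transform
    expect_equal(ht_roc(exp(sc), y)$auc, ht_roc(sc, y)$auc)
  }
})

test_that("Youden operating point maximizes sensitivity + specificity", {
  sc <- c(0, 0, 1, 2, 2, 3, 4, 5)
  y <- c(F, F, F, F, T, T, T, T)
  r <- ht_roc(sc, y)
  j <- r$thresholds$sensitivity + r$thresholds$specificity - 1
  expect_equal(r$youden$sensitivity + r$youden$specificity - 1, max(j))
})

test_that("spearman correlation and slope behave on canonical inputs", {
  x <- 1:10
  expect_equal(spearman_slope(x, 2 * x)$r, 1)
  # exhaustive rank-permutation value for a 3-point example:
  # ranks of y against x = (3,1,2) -> rho = 1 - 6*sum(d^2)/(n(n^2-1)) = -0.5
  expect_equal(spearman_slope(c(1, 2, 3), c(3, 1, 2))$r, -0.5)
  # noise-free line recovers its slope
  s <- spearman_slope(0:7, 2.48 * (0:7) + 1)
  expect_equal(s$slope, 2.48, tolerance = 1e-12)
  expect_error(spearman_slope(rep(1, 5), 1:5), "constant")
})

test_that("Kaplan-Meier hand examples and median conventions hold", {
  # no events: flat at 1, median not reached
  km0 <- km_curve(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km0$curve$surv == 1))
  expect_true(is.na(km0$median))

  # all events at distinct times: S(2) = 0.5, median midpoint 2.5
  km <- km_curve(1:4, rep(1, 4))
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2.5)

  # censoring reduces the risk set: classic product-limit hand example
  km2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$curve$surv[km2$curve$time == 3], (2/3) * (1/1) * 0)

  # no censoring: equals the empirical survival function
  set.seed(5)
  t <- sample(1:50, 20, replace = TRUE)
  km3 <- km_curve(t, rep(1, 20))
  for (i in seq_len(nrow(km3$curve)))
    expect_equal(km3$curve$surv[i], mean(t > km3$curve$time[i]))
})

test_that("log-rank matches the hand statistic and the permutation oracle", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(6:10, 1)
    time <- sample(1:15, n, replace = TRUE)
    event <- rbinom(n, 1, 0.8)
    group <- c(rep("a", 3), rep("b", n - 3))
    if (sum(event) == 0) next
    got <- logrank_test(time, event, group)
    expect_equal(got$chisq, logrank_stat_oracle(time, event, group),
                 tolerance = 1e-8)
    # exact permutation p against a from-scratch enumeration
    ex <- logrank_test(time, event, group, exact = TRUE)
    sets <- utils::combn(n, 3, simplify = FALSE)
    stats_all <- vapply(sets, function(ix) {
      g <- rep("b", n); g[ix] <- "a"
      logrank_stat_oracle(time, event, g)
    }, numeric(1))
    expect_equal(ex$p, mean(stats_all >= got$chisq - 1e-9))
  }
})

test_that("identical groups give log-rank p = 1", {
  time <- c(1, 2, 3, 1, 2, 3)
  event <- c(1, 1, 0, 1, 1, 0)
  group <- rep(c("a", "b"), each = 3)
  expect_equal(logrank_test(time, event, group)$p, 1)
})

test_that("Aalen-Johansen matches the hand computation and its identity", {
  # 4 patients: NRM at 2, progression death at 4, censored at 12, 12
  aj <- aj_cuminc(c(2, 4, 12, 12),
                  c("nrm", "progression_death", "censor", "censor"))
  expect_equal(aj$curve$nrm[aj$curve$time == 2], 0.25)
  expect_equal(aj$curve$progression_death[aj$curve$time == 4], 0.25)
  # identity: event-free + sum of incidences = 1 at every time
  tot <- aj$curve$event_free + aj$curve$nrm + aj$curve$progression_death
  expect_equal(tot, rep(1, nrow(aj$curve)))

  # no competing events: reduces to 1 - KM
  t <- c(1, 3, 5, 7); s <- c("nrm", "nrm", "censor", "nrm")
  aj2 <- aj_cuminc(t, s)
  km <- km_curve(t, s == "nrm")
  expect_equal(aj2$curve$nrm, 1 - km$curve$surv)

  # all causes progression: NRM never appears
  aj3 <- aj_cuminc(c(1, 2), c("progression_death", "progression_death"))
  expect_false("nrm" %in% aj3$causes)
})

test_that("Aalen-Johansen agrees with an independent competing-risks fit", {
  skip_if_not_installed("cmprsk")
  set.seed(9)
  n <- 120
  t <- round(rexp(n, 0.1), 2)
  cause <- sample(c("censor", "nrm", "progression_death"), n, replace = TRUE,
                  prob = c(0.4, 0.25, 0.35))
  aj <- aj_cuminc(t, cause)
  ref <- cmprsk::cuminc(t, factor(cause, c("censor", "nrm",
                                           "progression_death")),
                        cencode = "censor")
  # compare at the last NRM event time
  tt <- max(t[cause == "nrm"])
  ref_est <- cmprsk::timepoints(ref, tt)$est
  got <- aj$curve$nrm[max(which(aj$curve$time <= tt))]
  expect_equal(got, unname(ref_est["1 nrm", 1]), tolerance = 1e-6)
})

test_that("NRM analysis validates causes and reports group incidences", {
  p <- rbind(
    patient_row("A", os_time = 2, os_event = 1, pfs_time = 2, pfs_event = 1,
                death_cause = "infection"),
    patient_row("B", os_time = 4, os_event = 1, pfs_time = 3, pfs_event = 1,
                death_cause = "progression"),
    patient_row("C"), patient_row("D"))
  co <- ht_cohort(p)
  nr <- nrm_analysis(co)
  expect_equal(unname(nr$nrm_at_horizon["overall"]), 0.25)

  bad <- patient_row("A", os_time = 2, os_event = 1, pfs_time = 2,
                     pfs_event = 1, death_cause = "progression")
  bad$death_cause <- "none"  # inconsistent on purpose
  expect_error(ht_cohort(bad), "death_cause")
})

test_that("Cox recovers a known hazard ratio and rejects degenerate input", {
  set.seed(21)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(log(3.5) * x))
  cens <- rexp(n, 0.02)
  time <- pmin(t, cens); event <- as.integer(t <= cens)
  fit <- cox_model(time, event, data.frame(x = x))
  expect_gt(fit$ci_upper[1], 3.5)
  expect_lt(fit$ci_lower[1], 3.5)
  expect_error(cox_model(time, event, data.frame(x = rep(1, n))),
               "constant")
  expect_error(cox_model(time, event, data.frame(x = x, y = 2 * x)),
               "collinear|converge")
})

test_that("a null covariate gives HR near 1 with uniform p-values", {
  set.seed(31)
  ps <- replicate(60, {
    n <- 150
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1)
    fit <- cox_model(t, rep(1, n), data.frame(x = x))
    fit$p[1]
  })
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.2)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("logistic regression recovers a known odds ratio and flags separation", {
  set.seed(41)
  n <- 3000
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + log(4.9) * x))
  fit <- logistic_model(y, data.frame(x = x))
  expect_gt(fit$ci_upper[1], 4.9)
  expect_lt(fit$ci_lower[1], 4.9)

  # balanced outcome independent of covariates: OR near 1
  y0 <- rbinom(n, 1, 0.5)
  fit0 <- logistic_model(y0, data.frame(x = x))
  expect_lt(abs(fit0$estimate[1]), 0.2)

  # perfect separation errors
  xs <- c(rep(0, 20), rep(1, 20))
  ys <- xs
  expect_error(logistic_model(ys, data.frame(x = xs)), "converge|separation")
})

test_that("Fisher exact and Mann-Whitney follow the documented conventions", {
  # hand-enumerated hypergeometric two-sided p for [[3,1],[1,3]]
  ft <- group_compare(matrix(c(3, 1, 1, 3), 2))
  expect_equal(ft$p, 34 / 70, tolerance = 1e-12)

  # identical multisets: p = 1 under the normal approximation with ties
  x <- c(1, 2, 3, 1, 2, 3, 4, 4)
  g <- rep(c("a", "b"), 4)[order(rep(1:4, 2))]
  mw <- group_compare(c(1, 2, 3, 4, 1, 2, 3, 4),
                      rep(c("a", "b"), each = 4))
  expect_equal(mw$p, 1)

  expect_error(group_compare(1:3, rep("a", 3)), "two non-empty")
})

test_that("exact Mann-Whitney matches the full permutation oracle", {
  set.seed(51)
  for (rep in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:6, 1)
    vals <- sample(1:100, n1 + n2)   # no ties
    g <- c(rep("a", n1), rep("b", n2))
    got <- group_compare(vals, g)
    expect_equal(got$method, "mann_whitney_exact")
    # enumerate all assignments of values to group a
    sets <- utils::combn(n1 + n2, n1, simplify = FALSE)
    u_all <- vapply(sets, function(ix) {
      a <- vals[ix]; b <- vals[-ix]
      sum(outer(a, b, ">"))
    }, numeric(1))
    u_obs <- sum(outer(vals[g == "a"], vals[g == "b"], ">"))
    p_oracle <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    expect_equal(got$p, p_oracle)
  }
})
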