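test_that("enrichment chi-square matches the Pearson definition", {
  # identical row proportions -> independence, X^2 = 0, p = 1
  ind <- chi_square_enrichment(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))
  expect_equal(ind$statistic, 0, tolerance = 1e-12)
  expect_equal(ind$p_value, 1)

  tab <- matrix(c(50, 10, 30, 200), 2, byrow = TRUE)
  res <- chi_square_enrichment(tab)
  expect_equal(res$statistic, oracle_pearson(tab), tolerance = 1e-9)
  expect_equal(res$df, 1)

  # simultaneous row and column swap leaves the statistic unchanged
  swapped <- tab[2:1, 2:1]
  expect_equal(chi_square_enrichment(swapped)$statistic, res$statistic,
               tolerance = 1e-12)

  expect_error(chi_square_enrichment(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("chi-square agrees with brute force on 500 random tables", {
  set.seed(404)
  for (i in 1:500) {
    tab <- matrix(rpois(4, lambda = sample(c(3, 20, 80), 1)) + 1L, 2)
    res <- chi_square_enrichment(tab)
    expect_equal(res$statistic, oracle_pearson(tab), tolerance = 1e-9)
  }
})

test_that("log-rank matches a hand-tabulated O/E/V computation", {
  # six patients, mixed censoring, tabulated per event time in the oracle
  time <- c(5, 8, 12, 14, 20, 25)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  group <- c("a", "b", "a", "a", "b", "b")
  res <- km_logrank(time, event, group)
  expect_equal(res$statistic, oracle_logrank(time, event, group),
               tolerance = 1e-9)
  expect_equal(res$p_value,
               pchisq(res$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups -> statistic 0, p 1
  t2 <- rep(c(3, 7, 11, 15), 2)
  e2 <- rep(c(TRUE, TRUE, FALSE, TRUE), 2)
  g2 <- rep(c("a", "b"), each = 4)
  same <- km_logrank(t2, e2, g2)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  expect_error(km_logrank(c(1, 2), c(FALSE, FALSE), c("a", "b")),
               "no events")
})

test_that("log-rank is invariant to patient ordering and ties out with ties", {
  set.seed(55)
  n <- 40
  time <- sample(1:30, n, replace = TRUE)  # heavy ties
  event <- runif(n) < 0.7
  group <- sample(c("x", "y"), n, replace = TRUE)
  res <- km_logrank(time, event, group)
  expect_equal(res$statistic, oracle_logrank(time, event, group),
               tolerance = 1e-9)
  perm <- sample(n)
  res_p <- km_logrank(time[perm], event[perm], group[perm])
  expect_equal(res_p$statistic, res$statistic, tolerance = 1e-12)
})

test_that("KM curves are proper step functions; no censoring gives the ECDF", {
  time <- c(2, 4, 4, 7, 9)
  event <- rep(TRUE, 5)
  res <- km_logrank(c(time, 100), c(event, FALSE),
                    c(rep("a", 5), "b"))
  a <- res$curves[res$curves$group == "a", ]
  # product-limit with no censoring = empirical survival function
  expect_equal(a$surv[a$time == 4], 1 - 3 / 5, tolerance = 1e-12)
  expect_equal(a$surv[a$time == 9], 0, tolerance = 1e-12)
  expect_true(all(diff(a$surv) <= 1e-12))
  expect_true(all(a$surv <= 1))
})

test_that("Cox fit maximizes the Efron partial likelihood (grid oracle)", {
  # eight patients, two covariates, ties included
  d <- data.frame(
    time = c(4, 6, 6, 10, 12, 15, 20, 24),
    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    x1 = c(1, 0, 1, 0, 1, 0, 1, 0),
    x2 = c(0.2, 1.1, -0.3, 0.8, 1.5, -0.7, 0.4, -1.2)
  )
  fit <- cox_fit(d, c("x1", "x2"), mode = "multivariate")
  grid <- oracle_grid_cox(d$time, d$event, d[, c("x1", "x2")])
  expect_equal(fit$coef, grid, tolerance = 1e-4)
  # the fitted likelihood is no worse than at zero
  X <- as.matrix(d[, c("x1", "x2")])
  expect_gte(oracle_efron_lpl(fit$coef, d$time, d$event, X),
             oracle_efron_lpl(c(0, 0), d$time, d$event, X))
})

test_that("null covariates give HR 1 and rescaling rescales coefficients", {
  # two identical survival groups differing only in the group label
  base <- data.frame(time = c(5, 8, 12, 20), event = c(1, 1, 0, 1))
  d <- rbind(transform(base, x = 0), transform(base, x = 1))
  d$event <- as.logical(d$event)
  fit <- cox_fit(d, "x", mode = "univariate")
  expect_equal(fit$hr, 1, tolerance = 1e-6)

  set.seed(66)
  d2 <- data.frame(time = rexp(40, 0.1), event = runif(40) < 0.8,
                   z = rnorm(40))
  f1 <- cox_fit(d2, "z")
  d2$z <- d2$z * 10
  f10 <- cox_fit(d2, "z")
  expect_equal(f10$coef, f1$coef / 10, tolerance = 1e-6)
})

test_that("univariate mode fits one covariate at a time", {
  set.seed(8)
  d <- data.frame(time = rexp(60, 0.05), event = runif(60) < 0.7,
                  a = rnorm(60), b = rbinom(60, 1, 0.5))
  uni <- cox_fit(d, c("a", "b"), mode = "univariate")
  expect_equal(nrow(uni), 2)
  solo <- cox_fit(d, "a", mode = "multivariate")
  expect_equal(uni$coef[uni$term == "a"], solo$coef, tolerance = 1e-12)
})

test_that("fixed-horizon AUC follows the rank formulation", {
  # perfectly separating marker
  time <- c(rep(50, 5), rep(400, 5))
  event <- c(rep(TRUE, 5), rep(FALSE, 5))
  perfect <- fixed_horizon_roc(c(rep(1, 5), rep(0, 5)), time, event, 183)
  expect_equal(perfect$estimate, 1)

  # binary marker: AUC = (sens + spec) / 2 exactly (75% / 85% table)
  marker <- c(rep(1, 75), rep(0, 25), rep(1, 15), rep(0, 85))
  time2 <- c(rep(100, 100), rep(300, 100))
  event2 <- c(rep(TRUE, 100), rep(FALSE, 100))
  bin <- fixed_horizon_roc(marker, time2, event2, 183)
  expect_equal(bin$estimate, 0.8, tolerance = 1e-12)

  # matches the exhaustive pairwise oracle with ties
  set.seed(90)
  m <- sample(1:5, 60, replace = TRUE)
  st <- rbinom(60, 1, 0.4)
  t3 <- ifelse(st == 1, 100, 400)
  res <- fixed_horizon_roc(m, t3, st == 1, 183)
  expect_equal(res$estimate, oracle_auc_pairs(m, st), tolerance = 1e-12)

  # null marker on a large sample sits near 0.5
  set.seed(91)
  null_m <- rnorm(4000)
  null_status <- rbinom(4000, 1, 0.3)
  t4 <- ifelse(null_status == 1, 50, 400)
  null_res <- fixed_horizon_roc(null_m, t4, null_status == 1, 183)
  expect_lt(abs(null_res$estimate - 0.5), 0.03)

  expect_error(fixed_horizon_roc(rep(1, 4), rep(400, 4), rep(FALSE, 4),
                                 183), "classes")
})

test_that("censored-before-horizon patients are excluded from the AUC", {
  marker <- c(5, 4, 3, 2, 1)
  time <- c(50, 100, 250, 300, 90)
  event <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  # patient 2 is censored before the horizon: unknown status, dropped
  res <- fixed_horizon_roc(marker, time, event, 183)
  expect_equal(res$n_cases + res$n_controls, 4)
  expect_equal(res$estimate, oracle_auc_pairs(c(5, 3, 2, 1), c(1, 0, 0, 1)),
               tolerance = 1e-12)
})

test_that("time-dependent AUC reduces to the fixed-horizon AUC without censoring", {
  set.seed(14)
  n <- 120
  marker <- rnorm(n)
  time <- rexp(n, 0.004 * exp(0.8 * marker))
  event <- rep(TRUE, n)  # fully observed
  for (t0 in c(183, 365)) {
    td <- time_dependent_roc(marker, time, event, t0)
    fh <- fixed_horizon_roc(marker, time, event, t0)
    expect_equal(td$auc, fh$estimate, tolerance = 1e-12)
  }
  # a perfect marker scores 1 at every valid horizon
  ptime <- c(rep(60, 10), rep(1000, 10))
  pmarker <- c(rep(1, 10), rep(0, 10))
  td_p <- time_dependent_roc(pmarker, ptime, rep(TRUE, 20), c(183, 365))
  expect_true(all(td_p$auc == 1))
  # no events before t -> NA at that horizon
  td_na <- time_dependent_roc(pmarker, ptime, c(rep(FALSE, 10),
                                                rep(TRUE, 10)), 183)
  expect_true(is.na(td_na$auc))
})

test_that("the rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(27)
  marker <- rnorm(80)
  status <- rbinom(80, 1, 0.4)
  time <- ifelse(status == 1, 100, 400)
  ours <- fixed_horizon_roc(marker, time, status == 1, 183)
  ref <- pROC::auc(pROC::roc(status, marker, quiet = TRUE,
                             direction = "<"))
  expect_equal(ours$estimate, as.numeric(ref), tolerance = 1e-12)
})
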