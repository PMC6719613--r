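test_that("rank-statistic AUC matches closed cases and oracles", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)
  r <- roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$orientation, "high")

  # orientation flip: low values predict the event
  rl <- roc_auc(c(4, 3, 2, 1), c(0, 1, 0, 1))
  expect_equal(rl$auc, 0.75)
  expect_equal(rl$orientation, "low")

  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    x <- round(rnorm(n), 1)  # induce ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    got <- roc_auc(x, y)
    want <- oracle_trapz_auc(x, y)
    expect_equal(max(want, 1 - want), got$auc, tolerance = 1e-12)
    # independent package cross-check
    pr <- suppressMessages(pROC::auc(y, x, quiet = TRUE))
    expect_equal(got$auc, max(as.numeric(pr), 1 - as.numeric(pr)),
                 tolerance = 1e-12)
  }
})

test_that("Youden cutoff maximizes J with sensitivity-favoring ties", {
  yc <- youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1), "high")
  expect_equal(yc$cutoff, 2.5)
  expect_equal(yc$sensitivity, 100)
  expect_equal(yc$specificity, 100)
  expect_equal(yc$j, 1)

  # all values equal: no discrimination possible
  yc0 <- youden_cutoff(rep(2, 6), rep(c(0, 1), 3), "high")
  expect_equal(yc0$j, 0)

  # dichotomizing at the chosen cutoff reproduces the scanned maximum
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(30); y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    ori <- roc_auc(x, y)$orientation
    yc <- youden_cutoff(x, y, ori)
    pred <- bcradiomics:::classify_marker(x, yc$cutoff, ori)
    se <- 100 * sum(pred & y) / sum(y)
    sp <- 100 * sum(!pred & !y) / sum(!y)
    expect_equal((se + sp) / 100 - 1, yc$j, tolerance = 1e-12)
  }
})

test_that("univariate report is consistent with its per-variable parts", {
  set.seed(14)
  tab <- cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  y <- rbinom(40, 1, 0.3)
  rep_ <- univariate_report(tab, y)
  expect_equal(rep_$variable, c("a", "b", "c"))
  for (i in 1:3) {
    rr <- roc_auc(tab[, i], y)
    expect_equal(rep_$auc[i], rr$auc)
    expect_equal(rep_$p_value[i], rr$p_value)
  }
  # larger |AUC - 0.5| pairs with smaller p at fixed n
  ord <- order(abs(rep_$auc - 0.5))
  expect_equal(order(rep_$p_value, decreasing = TRUE), ord)
})

test_that("Cox fit recovers hand-computed and null effects", {
  # identical event experience in both groups -> HR ~ 1
  times <- rep(c(3, 6, 9, 12), 2)
  events <- rep(c(1, 1, 0, 1), 2)
  g <- rep(c(0, 1), each = 4)
  fit <- cox_fit(matrix(g, ncol = 1, dimnames = list(NULL, "g")),
                 times, events)
  expect_equal(fit$hr[1], 1, tolerance = 1e-6)

  # 10-row fixture with distinct event times: matches the Newton oracle
  set.seed(15)
  x <- c(0, 1, 0, 1, 1, 0, 1, 0, 1, 0)
  tt <- c(2.1, 1.3, 5.6, 3.2, 0.9, 7.4, 2.8, 6.1, 1.7, 8.8)
  ee <- c(1, 1, 1, 1, 1, 0, 1, 0, 1, 0)
  fit <- cox_fit(matrix(x, ncol = 1, dimnames = list(NULL, "x")), tt, ee)
  beta_oracle <- oracle_cox_beta(x, tt, ee)
  expect_equal(log(fit$hr[1]), beta_oracle, tolerance = 1e-4)

  # complete separation falls back to a penalized fit, flagged
  xs <- rep(c(1, 0), c(5, 5))
  ts <- c(1:5, 51:55)
  es <- rep(c(1, 0), c(5, 5))
  fit_s <- cox_fit(matrix(xs, ncol = 1, dimnames = list(NULL, "x")), ts, es)
  expect_true(attr(fit_s, "penalized"))
  expect_true(is.finite(fit_s$hr[1]))
})

test_that("KM/log-rank match hand computation and the empirical survivor", {
  # identical groups: no difference
  km0 <- km_logrank(rep(c("A", "B"), each = 4),
                    rep(c(1, 2, 3, 4), 2), rep(c(1, 1, 0, 1), 2))
  expect_equal(km0$chisq, 0, tolerance = 1e-12)
  expect_equal(km0$p_value, 1, tolerance = 1e-12)

  # 4-subject fixture vs hypergeometric oracle
  g <- c("A", "A", "B", "B")
  tt <- c(1, 2, 3, 4); ee <- c(1, 1, 1, 0)
  km <- km_logrank(g, tt, ee)
  expect_equal(km$chisq, oracle_logrank_chisq(g, tt, ee), tolerance = 1e-9)
  expect_equal(km$p_value, pchisq(km$chisq, 1, lower.tail = FALSE))

  # KM with no censoring equals the empirical survival function
  set.seed(16)
  tt <- sort(sample(1:50, 12))
  km1 <- km_logrank(rep("A", 12), tt, rep(1, 12))
  expect_equal(km1$curves$survival, 1 - seq_len(12) / 12, tolerance = 1e-12)
})

test_that("log-rank p-values are uniform under permuted group labels", {
  set.seed(17)
  n <- 40
  tt <- rexp(n, 0.05) + 0.5
  ee <- rbinom(n, 1, 0.7)
  ps <- replicate(500, {
    g <- sample(rep(c("A", "B"), each = n / 2))
    km_logrank(g, tt, ee)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DeLong paired test behaves at its boundaries", {
  set.seed(19)
  y <- rep(c(0, 1), each = 25)
  x <- rnorm(50) + y
  # a marker against itself: no difference, p = 1
  dl <- delong_test(x, x, y)
  expect_equal(dl$auc_a, dl$auc_b)
  expect_equal(dl$p_value, 1)
  # the AUCs reported equal the rank-statistic AUCs
  expect_equal(dl$auc_a, roc_auc(x, y)$auc, tolerance = 1e-12)
  # an informative marker beats pure noise decisively at n = 200
  y2 <- rep(c(0, 1), each = 100)
  good <- rnorm(200) + 1.5 * y2
  noise <- rnorm(200)
  dl2 <- delong_test(good, noise, y2)
  expect_gt(dl2$auc_a, dl2$auc_b)
  expect_lt(dl2$p_value, 0.01)
  # under exchangeable markers the test is calibrated (no rejection at 0.001)
  dl3 <- delong_test(rnorm(200) + y2, rnorm(200) + y2, y2)
  expect_gt(dl3$p_value, 0.001)
})

test_that("model building freezes train-side cutoffs and favors parsimony", {
  set.seed(18)
  n_tr <- 60; n_te <- 30
  y_tr <- rbinom(n_tr, 1, 0.3); y_te <- rbinom(n_te, 1, 0.3)
  x_tr <- cbind(s = 1.8 * y_tr + rnorm(n_tr),
                n1 = rnorm(n_tr), n2 = rnorm(n_tr))
  x_te <- cbind(s = 1.8 * y_te + rnorm(n_te),
                n1 = rnorm(n_te), n2 = rnorm(n_te))
  colnames(x_tr) <- colnames(x_te) <- c("ADC|ORIG|FBN16|GLSZM_SZE",
                                        "T2|LLL|FBN16|FO_mean",
                                        "ADC|HHH|FBN32|GLRLM_HGRE")
  cl_tr <- cbind(age = rnorm(n_tr, 65, 6), psa = rexp(n_tr, 1 / 9))
  cl_te <- cbind(age = rnorm(n_te, 65, 6), psa = rexp(n_te, 1 / 9))
  t_tr <- rexp(n_tr, 0.02 * exp(y_tr)) + 1
  t_te <- rexp(n_te, 0.02 * exp(y_te)) + 1
  mc <- evaluate_models(x_tr, x_te, cl_tr, cl_te, y_tr, y_te, t_tr, t_te)

  expect_setequal(names(mc$models), c("clinical", "radiomics", "combined"))
  # the informative feature anchors the radiomics model
  expect_true("ADC|ORIG|FBN16|GLSZM_SZE" %in% mc$factors$radiomics)
  # combined pools both factor sets
  expect_setequal(mc$factors$combined,
                  c(mc$factors$clinical, mc$factors$radiomics))
  # audit records one frozen cutoff per dichotomized variable
  expect_true(all(c("age", "psa") %in% names(mc$audit$variables)))
  for (a in mc$audit$variables)
    expect_true(is.finite(a$cutoff) && a$orientation %in% c("high", "low"))
  # additive score of k binary factors lives on 0..k
  k <- length(mc$factors$combined)
  expect_lte(max(vapply(mc$audit$score_cutoffs, identity, numeric(1))), k)
})
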