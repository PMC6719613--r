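# Craft a stability_evidence by hand (only the fields prune_correlated and
# select_best_variant consume).
fake_evidence <- function(keys, mean_abs, n_above = rep(100L, length(keys)),
                          pass = rep(TRUE, length(keys))) {
  structure(list(abs_pc = matrix(rep(mean_abs, each = 100), 100,
                                 dimnames = list(NULL, keys)),
                 n_above = setNames(n_above, keys),
                 pass = setNames(pass, keys),
                 mean_abs_pc = setNames(mean_abs, keys)),
            class = "stability_evidence")
}

test_that("stratified subsamples preserve class balance and the seed", {
  y <- rep(c(0, 1), each = 15)
  cfg <- selection_config(n_subsamples = 100, seed = 5)
  ss <- make_subsamples(y, cfg)
  expect_length(ss, 100)
  for (s in ss[1:10]) {
    expect_length(s, 20)
    expect_equal(sum(y[s] == 1), 10)
  }
  ss2 <- make_subsamples(y, selection_config(seed = 5))
  expect_identical(ss, ss2)
  expect_gt(length(unique(vapply(ss, paste, character(1), collapse = ","))),
            90)  # draws differ
})

test_that("point-biserial correlation matches hand computations", {
  y <- c(0, 0, 1, 1)
  expect_equal(pearson_with_outcome(as.numeric(y), y), 1)
  expect_equal(pearson_with_outcome(1 - y, y), -1)
  expect_equal(pearson_with_outcome(c(1, 2, 3, 4), y), 2 / sqrt(5))
  expect_equal(pearson_with_outcome(rep(1, 4), y), 0)  # zero variance
})

test_that("the 95-of-100 counting rule is exact at the boundary", {
  # rows 1..20: feature == label (perfect correlation); rows 21..30:
  # constant feature (correlation 0); subsamples built to hit the boundary
  y <- c(rep(c(0, 1), 10), rep(c(0, 1), 5))
  x <- c(y[1:20], rep(0.5, 10))
  tab <- matrix(x, ncol = 1, dimnames = list(NULL, "ADC|LLL|FBN16|GLSZM_SZE"))
  good <- 1:20
  bad <- 21:30
  cfg <- selection_config(seed = 1)
  ev95 <- stability_check(tab, y, cfg,
                          subsamples = c(rep(list(good), 95),
                                         rep(list(bad), 5)))
  expect_equal(unname(ev95$n_above), 95)
  expect_true(ev95$pass[1])
  ev94 <- stability_check(tab, y, cfg,
                          subsamples = c(rep(list(good), 94),
                                         rep(list(bad), 6)))
  expect_false(ev94$pass[1])

  # perfectly informative variant passes outright
  evp <- stability_check(matrix(y, ncol = 1,
                                dimnames = list(NULL, "ADC|LLL|FBN16|X")),
                         y, cfg)
  expect_true(evp$pass[1])
  expect_equal(unname(evp$mean_abs_pc), 1)
})

test_that("best-variant choice maximizes mean |PC| with lexicographic ties", {
  ev <- fake_evidence(c("ADC|LLL|FBN16|GLSZM_SZE", "ADC|HLL|FBN32|GLSZM_SZE",
                        "T2|LLL|FBN16|GLRLM_HGRE"),
                      mean_abs = c(0.42, 0.55, 0.61))
  expect_setequal(select_best_variant(ev),
                  c("ADC|HLL|FBN32|GLSZM_SZE", "T2|LLL|FBN16|GLRLM_HGRE"))

  # exact tie -> lexicographically smallest key
  ev2 <- fake_evidence(c("ADC|LLL|FBN16|GLSZM_SZE", "ADC|HLL|FBN32|GLSZM_SZE"),
                       mean_abs = c(0.5, 0.5))
  expect_equal(select_best_variant(ev2), "ADC|HLL|FBN32|GLSZM_SZE")

  # single stable variant -> itself; failed variants never selected
  ev3 <- fake_evidence(c("ADC|LLL|FBN16|A", "ADC|LLL|FBN16|B"),
                       mean_abs = c(0.6, 0.7), pass = c(TRUE, FALSE))
  expect_equal(select_best_variant(ev3), "ADC|LLL|FBN16|A")
})

test_that("greedy redundancy pruning follows the correlation chain rule", {
  # A~B and B~C high, A~C low, with mean |PC| A > C > B -> keep A and C
  set.seed(21)
  n <- 2000
  b <- rnorm(n); e1 <- rnorm(n)
  a <- 0.75 * b + 0.66 * e1
  cvec <- 0.75 * b - 0.66 * e1
  tab <- cbind(A = a, B = b, C = cvec)
  expect_gt(abs(cor(a, b)), 0.7)
  expect_gt(abs(cor(b, cvec)), 0.7)
  expect_lt(abs(cor(a, cvec)), 0.3)
  ev <- fake_evidence(c("A", "B", "C"), mean_abs = c(0.9, 0.5, 0.7))
  res <- prune_correlated(tab, c("A", "B", "C"), ev, rho = 0.7)
  expect_equal(res$selected, c("A", "C"))
  expect_equal(res$pruned, c(B = "A"))

  # duplicated features: the higher-|PC| one survives
  tab2 <- cbind(X = a, Y = a)
  ev2 <- fake_evidence(c("X", "Y"), mean_abs = c(0.6, 0.8))
  res2 <- prune_correlated(tab2, c("X", "Y"), ev2, rho = 0.7)
  expect_equal(res2$selected, "Y")

  # orthogonal features all survive
  tab3 <- cbind(P = rnorm(n), Q = rnorm(n), R = rnorm(n))
  ev3 <- fake_evidence(c("P", "Q", "R"), mean_abs = c(0.5, 0.4, 0.3))
  res3 <- prune_correlated(tab3, c("P", "Q", "R"), ev3, rho = 0.7)
  expect_setequal(res3$selected, c("P", "Q", "R"))
})

test_that("run_selection recovers a planted feature and is deterministic", {
  set.seed(30)
  n <- 70
  y <- rep(0L, n); y[sample.int(n, 11)] <- 1L
  mk_tab <- function(planted) {
    tab <- matrix(rnorm(n * 11), n, 11)
    colnames(tab) <- sprintf("ADC|LLL|FBN16|N%02d", 1:11)
    if (planted) {
      tab[, 1] <- 1.6 * y + rnorm(n, sd = 0.8)
      colnames(tab)[1] <- "ADC|ORIG|FBN16|GLSZM_SZE"
    }
    tab
  }
  tab <- mk_tab(TRUE)
  res <- run_selection(tab, y, selection_config(seed = 2))
  expect_true("ADC|ORIG|FBN16|GLSZM_SZE" %in% res$selected)
  res2 <- run_selection(tab, y, selection_config(seed = 2))
  expect_identical(res$selected, res2$selected)
  expect_identical(res$evidence$abs_pc, res2$evidence$abs_pc)
})

test_that("thresholds act monotonically on the selected sets", {
  set.seed(31)
  n <- 60
  y <- rep(c(0L, 1L), c(45, 15))
  tab <- matrix(rnorm(n * 8), n, 8)
  tab[, 1:3] <- tab[, 1:3] + 1.2 * y
  colnames(tab) <- sprintf("ADC|LLL|FBN16|F%d", 1:8)

  ev_lo <- stability_check(tab, y, selection_config(pc_min = 0.2, seed = 7))
  ev_hi <- stability_check(tab, y, selection_config(pc_min = 0.4, seed = 7))
  expect_true(all(names(which(ev_hi$pass)) %in% names(which(ev_lo$pass))))

  cand <- colnames(tab)[1:3]
  ev <- fake_evidence(cand, mean_abs = c(0.6, 0.5, 0.4))
  kept_tight <- prune_correlated(tab, cand, ev, rho = 0.3)$selected
  kept_loose <- prune_correlated(tab, cand, ev, rho = 0.9)$selected
  expect_true(all(kept_tight %in% kept_loose))
})
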