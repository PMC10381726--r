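test_that("compute_metrics matches hand-worked examples", {
  # perfect separation
  m <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(m$auc, 1); expect_equal(m$accuracy, 1)
  # flipped scores give AUC 0
  m2 <- compute_metrics(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m2$auc, 0)
  # one discordant pair out of four -> AUC 0.75 (brute-force over pairs)
  lab <- c(0, 0, 1, 1); sc <- c(0.1, 0.6, 0.4, 0.8)
  pairs <- expand.grid(i = which(lab == 1), j = which(lab == 0))
  brute <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                       ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
  expect_equal(brute, 0.75)
  expect_equal(compute_metrics(lab, sc)$auc, brute)
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("compute_metrics agrees with a confusion-matrix oracle on random inputs", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    sc <- round(runif(n), 2)                             # force some ties
    m <- compute_metrics(lab, sc)
    pred <- as.integer(sc >= 0.5)
    tp <- sum(pred & lab); tn <- sum(!pred & !lab)
    fp <- sum(pred & !lab); fn <- sum(!pred & lab)
    expect_equal(m$accuracy, (tp + tn) / n)
    expect_equal(m$recall_1, tp / sum(lab))
    expect_equal(m$recall_0, tn / sum(!lab))
    if (tp + fp > 0) expect_equal(m$precision_1, tp / (tp + fp))
    else expect_true(is.na(m$precision_1) && "precision_1" %in% m$undefined)
    if (tn + fn > 0) expect_equal(m$precision_0, tn / (tn + fn))
    else expect_true(is.na(m$precision_0) && "precision_0" %in% m$undefined)
    expect_equal(m$balanced_accuracy, (m$recall_0 + m$recall_1) / 2,
                 tolerance = 1e-12)
    # pairwise AUC oracle
    pairs <- expand.grid(i = which(lab == 1), j = which(lab == 0))
    brute <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                         ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
    expect_equal(m$auc, brute, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  lab <- sample(0:1, 40, replace = TRUE); lab[1:2] <- 0:1
  sc <- runif(40)
  base <- compute_metrics(lab, sc)$auc
  for (f in list(function(x) x^3, function(x) 1 - exp(-3 * x),
                 function(x) x / 2 + 0.25)) {
    expect_equal(compute_metrics(lab, f(sc))$auc, base, tolerance = 1e-12)
  }
  # cross-check against an established ROC implementation
  expect_equal(base,
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("paired t-test handles regular and degenerate inputs", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  r <- paired_t_test(v, rep(0, 10))
  # closed form: t = 5.5 / (sd/sqrt(10))
  expect_equal(r$statistic, mean(v) / (sd(v) / sqrt(10)), tolerance = 1e-12)
  expect_equal(r$statistic, 5.745, tolerance = 1e-3)
  expect_equal(r$p_value, 2 * pt(-r$statistic, 9), tolerance = 1e-12)
  expect_equal(r$p_value, 2.8e-4, tolerance = 0.05)
  expect_equal(r$df, 9)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)

  deg <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
})

test_that("2x2 chi-square is Pearson without continuity correction", {
  r <- chi_square_2x2(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20, tolerance = 1e-12)  # 4 cells of (o-e)^2/e = 5
  flat <- chi_square_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0); expect_equal(flat$p_value, 1)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "marginal")
  # p-values match the df = 1 survival function via numeric integration
  set.seed(3)
  for (rep in 1:50) {
    tab <- matrix(sample(20:80, 4, replace = TRUE), 2, 2)
    r <- chi_square_2x2(tab)
    p_int <- stats::integrate(function(x) stats::dchisq(x, 1),
                              lower = r$statistic, upper = Inf,
                              rel.tol = 1e-10)$value
    expect_equal(r$p_value, p_int, tolerance = 1e-7)
  }
})

test_that("Welch t from summaries matches closed form and sample-based t.test", {
  same <- welch_t_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)
  r <- welch_t_from_summary(0, 1, 100, 1, 1, 100)
  expect_equal(r$statistic, -1 / sqrt(2 / 100), tolerance = 1e-12)
  expect_equal(r$statistic, -7.071, tolerance = 1e-3)
  # agreement with stats::t.test on actual samples
  set.seed(12)
  x <- rnorm(30, 1, 2); y <- rnorm(45, 0.5, 1.5)
  ht <- t.test(x, y)
  rs <- welch_t_from_summary(mean(x), sd(x), 30, mean(y), sd(y), 45)
  expect_equal(rs$statistic, unname(ht$statistic), tolerance = 1e-10)
  expect_equal(rs$df, unname(ht$parameter), tolerance = 1e-10)
  expect_equal(rs$p_value, ht$p.value, tolerance = 1e-10)
})

test_that("fold summaries give t-based CIs containing the mean", {
  fake_report <- function(v) {
    structure(as.list(setNames(rep(v, 7), qcxr:::.metric_names)),
              class = "metrics_report")
  }
  s <- summarize_folds(list(fake_report(0.8), fake_report(0.9)))
  row <- s[s$metric == "auc", ]
  expect_equal(row$mean, 0.85)
  # half-width = t_{0.975,1} * sd/sqrt(2) = 12.706 * 0.0707/1.414
  expect_equal(row$ci_high - row$mean, qt(0.975, 1) * sd(c(0.8, 0.9)) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(row$ci_high - row$mean, 0.635, tolerance = 1e-3)
  # constant metric -> zero-width interval; CI always brackets the mean
  s2 <- summarize_folds(lapply(1:5, function(i) fake_report(0.7)))
  expect_true(all(s2$ci_low == s2$mean & s2$ci_high == s2$mean))
  set.seed(4)
  s3 <- summarize_folds(lapply(1:6, function(i) fake_report(runif(1))))
  expect_true(all(s3$ci_low <= s3$mean & s3$mean <= s3$ci_high))
  expect_error(summarize_folds(list(fake_report(1))), ">= 2")
})
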