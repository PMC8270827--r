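test_that("cross-tabulation reproduces the published kNN cross-tab", {
  ref <- c(rep("UA", 37), rep("non-UA", 106))
  pred <- c(rep("UA", 37), rep("UA", 3), rep("non-UA", 103))
  cm <- cross_tabulate(pred, ref)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(37L, 0L, 3L, 103L))
})

test_that("identical prediction and reference vectors give zero errors", {
  labs <- rep(c("UA", "non-UA"), c(5, 9))
  cm <- cross_tabulate(labs, labs)
  expect_equal(cm$fp, 0L)
  expect_equal(cm$fn, 0L)
})

test_that("mixed references are excluded and counted, and counting matches the loop oracle", {
  set.seed(11)
  for (rep in 1:5) {
    ref <- sample(c("UA", "non-UA", "mixed"), 60, replace = TRUE,
                  prob = c(0.3, 0.6, 0.1))
    pred <- sample(c("UA", "non-UA"), 60, replace = TRUE)
    cm <- cross_tabulate(pred, ref)
    want <- oracle_counts(pred, ref)
    expect_equal(c(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn), want)
    expect_equal(cm$n_excluded, sum(ref == "mixed"))
  }
  expect_error(cross_tabulate(c("UA", "mixed"), c("UA", "UA")), "mixed")
  expect_error(cross_tabulate("stone", "UA"), "unknown")
})

test_that("diagnostic metrics reproduce the published point estimates", {
  r1 <- diagnostic_metrics(confusion_matrix(tp = 37, fn = 0, fp = 3, tn = 103))
  expect_equal(peakstone:::round_percent(r1$sensitivity$estimate), 100)
  expect_equal(peakstone:::round_percent(r1$specificity$estimate), 97)
  expect_equal(peakstone:::round_percent(r1$accuracy$estimate), 98)
  r2 <- diagnostic_metrics(confusion_matrix(tp = 35, fn = 2, fp = 2, tn = 104))
  expect_equal(peakstone:::round_percent(r2$sensitivity$estimate), 95)
  expect_equal(peakstone:::round_percent(r2$specificity$estimate), 98)
  expect_equal(peakstone:::round_percent(r2$accuracy$estimate), 97)
  r3 <- diagnostic_metrics(confusion_matrix(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(peakstone:::round_percent(r3$accuracy$estimate), 100)
})

test_that("zero denominators are flagged undefined, not dropped", {
  r <- diagnostic_metrics(confusion_matrix(tp = 0, fn = 0, fp = 2, tn = 8))
  expect_true(r$sensitivity$undefined)
  expect_match(format_metric(r$sensitivity), "undefined")
  expect_false(r$specificity$undefined)
})

test_that("Clopper-Pearson interval matches binom.test and hits exact endpoints", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(1:200, 1)
    x <- sample(0:n, 1)
    got <- exact_binomial_ci(x, n)
    want <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-9)
  }
  expect_equal(exact_binomial_ci(0, 17)[["lower"]], 0)
  expect_equal(exact_binomial_ci(17, 17)[["upper"]], 1)
})

test_that("the interval widens monotonically with the confidence level", {
  ci90 <- exact_binomial_ci(35, 37, conf = 0.90)
  ci95 <- exact_binomial_ci(35, 37, conf = 0.95)
  ci99 <- exact_binomial_ci(35, 37, conf = 0.99)
  expect_lt(ci95[["lower"]], ci90[["lower"]])
  expect_gt(ci95[["upper"]], ci90[["upper"]])
  expect_lt(ci99[["lower"]], ci95[["lower"]])
  expect_gt(ci99[["upper"]], ci95[["upper"]])
})

test_that("exact interval coverage is at least nominal", {
  # conservative by construction; check by simulation at a few true p
  set.seed(13)
  for (p in c(0.5, 0.9, 0.97)) {
    n <- 100
    x <- stats::rbinom(2000, n, p)
    covered <- vapply(x, function(xi) {
      ci <- exact_binomial_ci(xi, n)
      ci[["lower"]] <= p && p <= ci[["upper"]]
    }, logical(1))
    expect_gte(mean(covered), 0.95)
  }
})

test_that("exact McNemar p-values match the binomial pmf summation oracle", {
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(1, 0), 1)
  expect_equal(mcnemar_exact(9, 3), 598 / 4096, tolerance = 1e-12)
  for (b in 0:8) for (c in 0:8) {
    expect_equal(mcnemar_exact(b, c), oracle_mcnemar(b, c), tolerance = 1e-12)
    expect_equal(mcnemar_exact(b, c), mcnemar_exact(c, b))
  }
})

test_that("McNemar variants behave sensibly", {
  expect_lt(mcnemar_exact(9, 3, method = "midp"), mcnemar_exact(9, 3))
  expect_equal(mcnemar_exact(5, 5, method = "chisq"), 1)
  got <- mcnemar_exact(9, 3, method = "chisq")
  want <- stats::mcnemar.test(matrix(c(0, 9, 3, 0), 2, 2))$p.value
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("AUC handles perfect separation, constant scores and matches the all-pairs oracle", {
  ref <- rep(c("UA", "non-UA"), c(10, 15))
  expect_equal(roc_auc(c(rep(1, 10), rep(0, 15)), ref), 1)
  expect_equal(roc_auc(rep(0.3, 25), ref), 0.5)
  set.seed(14)
  for (rep in 1:5) {
    scores <- round(stats::runif(30), 1)  # coarse grid forces ties
    refs <- sample(c("UA", "non-UA"), 30, replace = TRUE)
    if (length(unique(refs)) < 2) refs[1:2] <- c("UA", "non-UA")
    expect_equal(roc_auc(scores, refs), oracle_auc(scores, refs == "UA"),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(15)
  scores <- stats::rnorm(40)
  refs <- rep(c("UA", "non-UA"), 20)
  base <- roc_auc(scores, refs)
  expect_equal(roc_auc(exp(scores), refs), base)
  expect_equal(roc_auc(scores^3 + 5 * scores, refs), base)
  expect_equal(roc_auc(-scores, refs, direction = "lower"), base)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  scores <- stats::rnorm(50)
  refs <- sample(c("UA", "non-UA"), 50, replace = TRUE)
  refs[1:2] <- c("UA", "non-UA")
  want <- as.numeric(pROC::auc(pROC::roc(
    response = refs, predictor = scores, levels = c("non-UA", "UA"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, refs), want, tolerance = 1e-12)
})

test_that("single-class AUC input is flagged undefined", {
  expect_warning(a <- roc_auc(1:5, rep("UA", 5)), "one class")
  expect_true(is.na(a))
})
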