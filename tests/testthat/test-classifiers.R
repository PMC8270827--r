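test_that("published worked examples classify correctly under default cutoffs", {
  # UA stone: 693 HU peak, 98 HU Laplacian; non-UA stone: 1398 HU, 182 HU
  expect_equal(classify_cutoff(c(max_hu = 693, pp_lapl = 98)), "UA")
  expect_equal(classify_cutoff(c(max_hu = 1398, pp_lapl = 182)), "non-UA")
  expect_equal(classify_maxhu(c(max_hu = 693, pp_lapl = 98)), "UA")
  expect_equal(classify_maxhu(c(max_hu = 1398, pp_lapl = 182)), "non-UA")
})

test_that("cutoff boundaries are non-UA (>= convention) and maxHU-only is strict <", {
  expect_equal(classify_cutoff(c(max_hu = 999, pp_lapl = 195)), "non-UA")
  expect_equal(classify_cutoff(c(max_hu = 1000, pp_lapl = 0)), "non-UA")
  expect_equal(classify_cutoff(c(max_hu = 999.9, pp_lapl = 194.9)), "UA")
  expect_equal(classify_maxhu(c(max_hu = 745, pp_lapl = 0)), "non-UA")
  expect_equal(classify_maxhu(c(max_hu = 744.9, pp_lapl = 500)), "UA")
})

test_that("classify_cutoff is monotone: raising either feature never flips to UA", {
  set.seed(77)
  pts <- data.frame(max_hu = stats::runif(200, 0, 2000),
                    pp_lapl = stats::runif(200, 0, 600))
  base <- classify_cutoff(pts)
  for (d in list(c(50, 0), c(0, 30), c(100, 100))) {
    up <- classify_cutoff(data.frame(max_hu = pts$max_hu + d[1],
                                     pp_lapl = pts$pp_lapl + d[2]))
    expect_false(any(base == "non-UA" & up == "UA"))
  }
})

test_that("maxHU-UA calls with sub-cutoff ppLapl are also cutoff-UA calls", {
  set.seed(78)
  pts <- data.frame(max_hu = stats::runif(300, 0, 2000),
                    pp_lapl = stats::runif(300, 0, 600))
  mh <- classify_maxhu(pts)
  co <- classify_cutoff(pts)
  sel <- mh == "UA" & pts$pp_lapl < 195
  expect_true(all(co[sel] == "UA"))
})

test_that("kNN vote is unanimous on a single-class neighbourhood", {
  train <- training_set(max_hu = c(rep(500, 9), 1500),
                        pp_lapl = c(rep(100, 9), 400),
                        label = c(rep("UA", 9), "non-UA"))
  got <- classify_knn(c(max_hu = 520, pp_lapl = 110), train, knn_config(k = 9))
  expect_equal(got, "UA")
})

test_that("kNN with k = 1 returns the label of an identical training point", {
  train <- training_set(max_hu = c(400, 1300), pp_lapl = c(90, 350),
                        label = c("UA", "non-UA"))
  cfg <- knn_config(k = 1)
  expect_equal(classify_knn(c(max_hu = 400, pp_lapl = 90), train, cfg), "UA")
  expect_equal(classify_knn(c(max_hu = 1300, pp_lapl = 350), train, cfg), "non-UA")
})

test_that("kNN agrees with the full-sort majority-vote oracle", {
  set.seed(101)
  train <- training_set(max_hu = stats::runif(20, 100, 1900),
                        pp_lapl = stats::runif(20, 20, 550),
                        label = sample(c("UA", "non-UA"), 20, replace = TRUE,
                                       prob = c(0.4, 0.6)))
  q <- data.frame(max_hu = stats::runif(50, 0, 2000),
                  pp_lapl = stats::runif(50, 0, 600))
  got <- classify_knn(q, train, knn_config(k = 9))
  want <- vapply(seq_len(nrow(q)), function(i) {
    oracle_knn(q$max_hu[i], q$pp_lapl[i], train$max_hu, train$pp_lapl,
               train$label, 9)
  }, character(1))
  expect_equal(got, want)
})

test_that("kNN vote fractions are consistent with hard labels", {
  set.seed(102)
  train <- training_set(max_hu = stats::runif(30, 100, 1900),
                        pp_lapl = stats::runif(30, 20, 550),
                        label = rep(c("UA", "non-UA"), 15))
  q <- data.frame(max_hu = stats::runif(25, 0, 2000),
                  pp_lapl = stats::runif(25, 0, 600))
  frac <- classify_knn(q, train, knn_config(k = 9), vote = TRUE)
  lab <- classify_knn(q, train, knn_config(k = 9))
  expect_true(all(frac >= 0 & frac <= 1))
  expect_equal(lab, ifelse(frac > 0.5, "UA", "non-UA"))
})

test_that("configuration invariants are enforced", {
  expect_error(knn_config(k = 8), "odd")
  expect_error(knn_config(k = 0), "positive")
  expect_error(cutoff_config(ppLapl_cut = -5), "positive")
  expect_error(training_set(1, 1, "UA"), "both")
  expect_error(training_set(c(1, 2), c(1, 2), c("UA", "mixed")), "mixed")
  train <- training_set(c(1, 2), c(1, 2), c("UA", "non-UA"))
  expect_error(classify_knn(c(max_hu = 1, pp_lapl = 1), train, knn_config(k = 9)),
               "k = 9")
})

test_that("the cutoff decision map is exactly the UA rectangle", {
  dm <- decision_map(classify_cutoff,
                     max_hu = seq(0, 2000, by = 100),
                     pp_lapl = seq(0, 600, by = 50))
  inside <- dm$max_hu < 1000 & dm$pp_lapl < 195
  expect_equal(dm$label == "UA", inside)
})

test_that("kNN map on a cutoff-labeled surrogate recovers the rectangle away from the lines", {
  set.seed(103)
  pts <- data.frame(max_hu = stats::runif(400, 0, 2000),
                    pp_lapl = stats::runif(400, 0, 600))
  train <- training_set(pts$max_hu, pts$pp_lapl, classify_cutoff(pts),
                        provenance = "surrogate")
  knn_fun <- function(df) classify_knn(df, train, knn_config(k = 9))
  dm <- decision_map(knn_fun,
                     max_hu = seq(0, 2000, by = 80),
                     pp_lapl = seq(0, 600, by = 40))
  ref <- classify_cutoff(dm)
  far <- abs(dm$max_hu - 1000) >= 50 & abs(dm$pp_lapl - 195) >= 50
  expect_gte(mean(dm$label[far] == ref[far]), 0.95)
})

test_that("a single-point grid equals direct classification", {
  dm <- decision_map(classify_cutoff, max_hu = 400, pp_lapl = 80)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$label, classify_cutoff(c(max_hu = 400, pp_lapl = 80)))
  expect_error(decision_map(classify_cutoff, numeric(0), 1), "non-empty")
})

test_that("a deep-interior query against a cutoff-labeled surrogate set votes UA", {
  set.seed(104)
  pts <- data.frame(max_hu = stats::runif(200, 0, 2000),
                    pp_lapl = stats::runif(200, 0, 600))
  train <- training_set(pts$max_hu, pts$pp_lapl, classify_cutoff(pts),
                        provenance = "surrogate")
  expect_equal(classify_knn(c(max_hu = 400, pp_lapl = 80), train), "UA")
})
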