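# cohort whose outcome copies one binary item exactly, plus noise items
separator_cohort <- function(n = 2000, seed = 1) {
  withr::with_seed(seed, {
    d <- data.frame(S = as.character(rbinom(n, 1, 0.5)),
                    N1 = as.character(rbinom(n, 1, 0.3)),
                    N2 = rnorm(n))
    d$rehab6m <- as.integer(d$S == "1")
    cohort(d, item_dictionary(c("S", "N1", "N2"),
                              c("categorical", "categorical", "continuous"),
                              list(c("0", "1"), c("0", "1"), NULL)))
  })
}

test_that("a perfectly separating item drives OOB accuracy above 0.95", {
  fm <- fit_forest(separator_cohort(), n_trees = 100, seed = 2)
  expect_gt(oob_accuracy(fm), 0.95)
  vim <- permutation_vim(fm, seed = 3)
  expect_equal(unname(vim$ranks[["S"]]), 1)
})

test_that("under a null outcome OOB accuracy sits at the majority rate", {
  co <- withr::with_seed(4, {
    d <- data.frame(A = as.character(rbinom(1500, 1, 0.5)), B = rnorm(1500),
                    rehab6m = rbinom(1500, 1, 0.3))
    cohort(d, item_dictionary(c("A", "B"), c("categorical", "continuous"),
                              list(c("0", "1"), NULL)))
  })
  fm <- fit_forest(co, n_trees = 150, seed = 5)
  maj <- max(mean(outcomes(co)), 1 - mean(outcomes(co)))
  expect_lt(abs(oob_accuracy(fm) - maj), 3 * sqrt(maj * (1 - maj) / 1500))
})

test_that("forests and importance are reproducible under a fixed seed", {
  co <- separator_cohort(n = 600, seed = 6)
  f1 <- fit_forest(co, n_trees = 60, seed = 7)
  f2 <- fit_forest(co, n_trees = 60, seed = 7)
  v1 <- permutation_vim(f1, repeats = 2, seed = 8)
  v2 <- permutation_vim(f2, repeats = 2, seed = 8)
  expect_identical(v1$importance, v2$importance)
  expect_identical(v1$ranks, v2$ranks)
})

test_that("the identity permutation produces exactly zero accuracy drop", {
  co <- separator_cohort(n = 400, seed = 9)
  fm <- fit_forest(co, n_trees = 50, seed = 10)
  y <- as.integer(fm$frame$.y) - 1L
  base <- rehabrank:::per_tree_oob_accuracy(
    rehabrank:::tree_predictions(fm, fm$frame), fm$oob, y)
  again <- rehabrank:::per_tree_oob_accuracy(
    rehabrank:::tree_predictions(fm, fm$frame), fm$oob, y)
  expect_identical(mean(base - again), 0)
})

test_that("an item constant across records has importance exactly zero", {
  co <- withr::with_seed(11, {
    d <- data.frame(S = as.character(rbinom(500, 1, 0.5)),
                    CONST = rep("0", 500))
    d$rehab6m <- as.integer(d$S == "1")
    cohort(d, item_dictionary(c("S", "CONST"), rep("categorical", 2),
                              list(c("0", "1"), c("0", "1"))))
  })
  vim <- permutation_vim(fit_forest(co, n_trees = 50, seed = 12), seed = 13)
  expect_identical(unname(vim$importance[["CONST"]]), 0)
})

test_that("planted effect sizes order the permutation importances", {
  agree <- 0L
  for (s in 1:20) {
    spec <- generator_spec(
      1200, extra_items = small_battery(6),
      planted_effects = list(X01 = 2.0, X02 = 1.0), seed = 600 + s)
    co <- generate_cohort(spec)
    vim <- permutation_vim(fit_forest(co, n_trees = 150, seed = s),
                           seed = 700 + s)
    ok <- vim$importance[["X01"]] > vim$importance[["X02"]] &&
      vim$importance[["X02"]] > vim$importance[["X03"]]
    agree <- agree + ok
  }
  expect_gte(agree, 18L)
})

test_that("strengthening a planted effect does not reduce its importance", {
  for (s in 1:3) {
    imp <- sapply(c(0.5, 2.0), function(b) {
      spec <- generator_spec(1500, extra_items = small_battery(5),
                             planted_effects = list(X04 = b),
                             seed = 800 + s)   # common random numbers via seed
      co <- generate_cohort(spec)
      vim <- permutation_vim(fit_forest(co, n_trees = 150, seed = s),
                             seed = 900 + s)
      vim$importance[["X04"]]
    })
    expect_gte(imp[2], imp[1])
  }
})

test_that("degenerate inputs are rejected", {
  co <- separator_cohort(n = 200, seed = 14)
  co$data$rehab6m <- 0L
  all0 <- cohort(co$data, co$dictionary)
  expect_error(fit_forest(all0, n_trees = 20, seed = 1), "single class")
  fm <- fit_forest(separator_cohort(n = 200, seed = 15), n_trees = 20, seed = 1)
  expect_error(permutation_vim(fm, repeats = 0), "repeats")
})
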