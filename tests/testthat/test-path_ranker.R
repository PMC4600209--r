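# staggered-effect instance on independent continuous predictors: entry
# order along the path should follow effect size
staggered_cohort <- function(n = 1500, betas = c(2.0, 1.0, 0.5), seed = 1) {
  withr::with_seed(seed, {
    k <- length(betas)
    x <- matrix(rnorm(n * k), n, k)
    eta <- drop(x %*% betas)
    d <- as.data.frame(x)
    names(d) <- sprintf("C%d", seq_len(k))
    d$rehab6m <- rbinom(n, 1, plogis(eta))
    cohort(d, item_dictionary(names(d)[seq_len(k)],
                              rep("continuous", k)))
  })
}

test_that("lambda_max is the exact all-zero boundary", {
  co <- random_path_instance(5, n = 400)
  dm <- build_design(co)
  lmax <- compute_lambda_max(dm)
  above <- fit_path(dm, lambda = lmax * 1.0001)
  expect_true(all(above$beta == 0))
  below <- fit_path(dm, lambda = lmax * c(1.0001, 0.99))
  expect_gt(sum(abs(below$beta[, 2])), 0)
  expect_error(
    compute_lambda_max(build_design(
      cohort(transform(co$data, rehab6m = 0:0), co$dictionary))),
    "single class")
})

test_that("a column orthogonal to the centered outcome has ~zero gradient norm", {
  withr::with_seed(8, {
    n <- 200
    y <- rep(0:1, each = n / 2)
    z <- rnorm(n)
    z <- residuals(lm(z ~ y))          # orthogonal to centered outcome
    d <- data.frame(A = rnorm(n), B = z, rehab6m = y)
    dm <- build_design(cohort(d, item_dictionary(c("A", "B"),
                                                 rep("continuous", 2))))
    g <- crossprod(dm$x, y - mean(y)) / n
    expect_lt(abs(g[2]), 1e-10)
  })
})

test_that("a single-point grid at lambda_max gives the all-zero solution", {
  co <- random_path_instance(6, n = 300)
  dm <- build_design(co)
  pth <- fit_path(dm, lambda = compute_lambda_max(dm))
  expect_true(all(pth$beta == 0))
  expect_equal(unname(pth$intercept[1]), qlogis(mean(dm$y)), tolerance = 1e-6)
})

test_that("KKT conditions hold at every grid point under independent audit", {
  for (seed in c(11, 12)) {
    co <- random_path_instance(seed, n = 300)
    pth <- fit_path(build_design(co), G = 40)
    expect_lt(audit_kkt(pth), 1e-6)
  }
})

test_that("the path end at tiny lambda matches the unpenalized MLE", {
  co <- staggered_cohort(n = 800, betas = c(1.2, -0.8), seed = 2)
  dm <- build_design(co)
  pth <- fit_path(dm, lambda = compute_lambda_max(dm) * c(1, 1e-6))
  mle <- glm(dm$y ~ dm$x, family = binomial())
  expect_lt(max(abs(pth$beta[, 2] - coef(mle)[-1]) /
                  pmax(abs(coef(mle)[-1]), 1e-8)), 1e-3)
})

test_that("entry order follows staggered effect sizes and a dense-grid oracle", {
  co <- staggered_cohort(n = 2000, betas = c(2.0, 1.0, 0.5), seed = 3)
  dm <- build_design(co)
  rv <- entry_order(fit_path(dm, G = 100))
  expect_equal(unname(rv$ranks[c("C1", "C2", "C3")]), c(1, 2, 3))
  dense <- entry_order(fit_path(dm, G = 2000), refine = FALSE)
  expect_equal(order(rv$ranks), order(dense$ranks))
})

test_that("when no group ever enters all ranks tie-average to (d+1)/2", {
  co <- random_path_instance(13, n = 300)
  dm <- build_design(co)
  # a grid stopping just below lambda_max: nothing has entered yet
  pth <- fit_path(dm, lambda = compute_lambda_max(dm) * c(1.1, 1.05, 1.0001))
  rv <- entry_order(pth)
  d <- length(rv$ranks)
  expect_true(all(rv$ranks == (d + 1) / 2))
})

test_that("rescaling a raw column before restandardization leaves ranks unchanged", {
  co <- staggered_cohort(n = 1000, betas = c(1.5, 0.8, 0.4), seed = 4)
  rv1 <- rank_by_path(co)
  co2 <- co
  co2$data$C2 <- co2$data$C2 * 37.5
  rv2 <- rank_by_path(cohort(co2$data, co2$dictionary))
  expect_equal(rv1$ranks, rv2$ranks, tolerance = 1e-12)
})

test_that("a strongly planted predictor ranks first in nearly all replicates", {
  battery <- lapply(seq_len(30), function(i) {
    list(code = sprintf("X%02d", i), kind = "categorical",
         levels = c("0", "1"), probs = c(0.6, 0.4))
  })
  hits <- 0L
  for (r in 1:100) {
    spec <- generator_spec(2000, extra_items = battery,
                           planted_effects = list(X07 = 2.0),
                           seed = 5000 + r)
    co <- generate_cohort(spec)
    rv <- rank_by_path(co)
    hits <- hits + (rv$ranks[["X07"]] == 1)
  }
  expect_gte(hits, 95L)
})

test_that("singleton-group entry order agrees with an independent lasso path", {
  skip_if_not_installed("glmnet")
  co <- staggered_cohort(n = 2000, betas = c(2.0, 1.2, 0.7, 0.3), seed = 9)
  dm <- build_design(co)
  rv <- entry_order(fit_path(dm, G = 200))
  gfit <- glmnet::glmnet(dm$x, dm$y, family = "binomial",
                         standardize = FALSE, nlambda = 200,
                         lambda.min.ratio = 1e-3)
  first_nz <- apply(abs(gfit$beta) > 0, 1, function(a) which(a)[1])
  expect_equal(order(rv$ranks), order(first_nz))
})

test_that("non-convergence is reported with grid point and residual", {
  co <- random_path_instance(14, n = 300)
  dm <- build_design(co)
  expect_error(fit_path(dm, G = 10, maxit = 2L), "KKT residual")
})
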