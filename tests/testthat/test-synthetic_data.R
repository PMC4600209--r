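test_that("generator spec validates marginals and planted codes", {
  bad <- small_battery(2)
  bad[[1]]$probs <- c(0.5, 0.4)
  expect_error(generator_spec(10, extra_items = bad), "sum to 1")
  spec <- generator_spec(100, extra_items = small_battery(2),
                         planted_effects = list(NOPE = 1), seed = 1)
  expect_error(generate_cohort(spec), "unknown item NOPE")
})

test_that("the generator is fully determined by its seed", {
  spec <- generator_spec(400, extra_items = small_battery(4),
                         planted_effects = list(X01 = 1), seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$data, c2$data)
  b1 <- sample_matching_block(500, default_stratum_table(), seed = 9)
  b2 <- sample_matching_block(500, default_stratum_table(), seed = 9)
  expect_identical(b1, b2)
  expect_false(identical(
    b1, sample_matching_block(500, default_stratum_table(), seed = 10)))
})

test_that("matching block reproduces the target joint distribution", {
  tab <- default_stratum_table()
  block <- sample_matching_block(100000, tab, seed = 5)
  dict <- item_dictionary(
    c("AGE", "GENDER", paste0("H2", LETTERS[1:10]), "B2A", "K5"),
    c("continuous", "categorical", rep("ordinal", 10), "ordinal", "continuous"),
    c(list(NULL), list(c("0", "1")), rep(list(as.character(0:6)), 10),
      list(as.character(0:4)), list(NULL)))
  block$rehab6m <- 0L
  block$rehab6m[1] <- 1L   # outcome irrelevant here, just satisfies validation
  keys <- stratum_keys(cohort(block, dict))
  obs <- table(factor(keys, levels = tab$key))
  gof <- suppressWarnings(
    chisq.test(as.vector(obs), p = tab$pct / sum(tab$pct)))
  expect_gt(gof$p.value, 0.01)
})

test_that("a point-mass stratum table puts every row in that cell", {
  one <- stratum_table(data.frame(age_bin = "65-74", gender = 1, adl = 0,
                                  cognition = 1, falls = 0, pct = 100))
  block <- sample_matching_block(200, one, seed = 2)
  expect_true(all(block$AGE >= 65 & block$AGE <= 74))
  expect_true(all(block$GENDER == "1"))
  expect_true(all(block$B2A != "0"))
  expect_true(all(block$K5 == 0))
})

test_that("derived flags are consistent with the raw items they summarize", {
  block <- sample_matching_block(5000, default_stratum_table(), seed = 7,
                                 method = "exact")
  h2 <- sapply(paste0("H2", LETTERS[1:10]),
               function(cc) as.numeric(block[[cc]]))
  counts <- allocate_counts(default_stratum_table(), 5000)
  adl_flag <- rowSums(h2 >= 1) > 0
  # exact allocation fixes the number of ADL-impaired rows
  tab <- default_stratum_table()
  expect_equal(sum(adl_flag), sum(counts[tab$key[tab$adl == 1]]))
  expect_equal(sum(as.numeric(block$B2A) >= 1),
               sum(counts[tab$key[tab$cognition == 1]]))
  expect_equal(sum(block$K5 >= 1), sum(counts[tab$key[tab$falls == 1]]))
})

test_that("null model gives ~50% prevalence at zero intercept", {
  spec <- generator_spec(50000, extra_items = small_battery(3),
                         intercept = 0, seed = 21)
  co <- generate_cohort(spec)
  p <- mean(outcomes(co))
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 50000))
})

test_that("a planted binary log odds ratio is recovered by the 2x2 table", {
  spec <- generator_spec(50000, extra_items = small_battery(3, prev = 0.5),
                         planted_effects = list(X02 = 1.5), seed = 22)
  co <- generate_cohort(spec)
  t22 <- table(item_values(co, "X02"), outcomes(co))
  lor <- log(t22["1", "1"] * t22["0", "0"] / (t22["1", "0"] * t22["0", "1"]))
  se <- sqrt(sum(1 / t22))
  expect_lt(abs(lor - 1.5), 1.96 * se)
})

test_that("interaction-only effects match the exact 2x2x2 cell probabilities", {
  p3 <- 0.4; p4 <- 0.4; b0 <- -1; cc <- 2.0
  spec <- generator_spec(
    50000, extra_items = small_battery(4, prev = p3),
    planted_interactions = list(list(items = c("X03", "X04"), beta = cc)),
    intercept = b0, seed = 23)
  co <- generate_cohort(spec)
  # exact oracle: P(y=1 | x3) marginalizing over x4
  py <- function(x3, x4) plogis(b0 + cc * x3 * x4)
  p_y_x3 <- function(x3) (1 - p4) * py(x3, 0) + p4 * py(x3, 1)
  lor_marg <- qlogis(p_y_x3(1)) - qlogis(p_y_x3(0))
  lor_joint <- qlogis(py(1, 1)) - qlogis(py(0, 1))   # = cc exactly
  expect_equal(lor_joint, cc)
  expect_gt(lor_marg, 0)
  expect_lt(lor_marg, lor_joint)     # marginal present but weaker than joint
  x3 <- as.numeric(item_values(co, "X03"))
  y <- outcomes(co)
  t22 <- table(x3, y)
  emp <- log(t22["1", "1"] * t22["0", "0"] / (t22["1", "0"] * t22["0", "1"]))
  expect_lt(abs(emp - lor_marg), 3 * sqrt(sum(1 / t22)))
})

test_that("an unpenalized fit recovers planted coefficients within 2 SE", {
  spec <- generator_spec(
    30000, extra_items = small_battery(6),
    planted_effects = list(X01 = 2.0, X02 = -1.5), seed = 24)
  co <- generate_cohort(spec)
  df <- data.frame(sapply(sprintf("X%02d", 1:6),
                          function(cc) as.numeric(item_values(co, cc))))
  df$y <- outcomes(co)
  fit <- glm(y ~ ., data = df, family = binomial())
  est <- coef(summary(fit))
  expect_lt(abs(est["X01", 1] - 2.0), 2 * est["X01", 2])
  expect_lt(abs(est["X02", 1] + 1.5), 2 * est["X02", 2])
  expect_lt(abs(est["(Intercept)", 1] + 1.4), 2 * est["(Intercept)", 2])
})
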