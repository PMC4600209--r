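test_that("stratum keys follow the matching-variable threshold definitions", {
  rec <- c(list(GENDER = 1),
           setNames(as.list(rep(0, 10)), paste0("H2", LETTERS[1:10])),
           list(B2A = 0, K5 = 0))
  rec$H2C <- 2
  expect_equal(stratum_key(rec, age = 45), "<50|1|1|0|0")

  rec2 <- c(list(GENDER = 0),
            setNames(as.list(rep(0, 10)), paste0("H2", LETTERS[1:10])),
            list(B2A = 0, K5 = 0))
  expect_equal(stratum_key(rec2, age = 90), ">84|0|0|0|0")
  expect_error(stratum_key(rec2, age = -1), "age")
  rec3 <- rec2; rec3$B2A <- NULL
  expect_error(stratum_key(rec3, age = 70), "B2A")
})

test_that("stratum keys agree with an independently coded predicate", {
  ages <- c(0, 49, 50, 64, 65, 74, 75, 84, 85, 99)
  grid <- expand.grid(gender = 0:1, h2a = 0:1, h2j = 0:1, b2a = 0:1,
                      k5 = 0:1, age = ages)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rec <- c(list(GENDER = g$gender),
             setNames(as.list(rep(0, 10)), paste0("H2", LETTERS[1:10])),
             list(B2A = g$b2a, K5 = g$k5))
    rec$H2A <- g$h2a; rec$H2J <- g$h2j
    h2 <- rep(0, 10); h2[1] <- g$h2a; h2[10] <- g$h2j
    expect_equal(stratum_key(rec, age = g$age),
                 oracle_stratum_key(g$age, g$gender, h2, g$b2a, g$k5))
  }
})

test_that("largest-remainder allocation is integer-exact and total-preserving", {
  tab <- default_stratum_table()
  counts <- allocate_counts(tab, 10000)
  expect_equal(sum(counts), 10000L)
  expect_equal(counts[["<50|1|1|1|1"]], 6L)   # 10,000 x 0.06 %

  zero <- tab; zero$pct[zero$key == ">84|1|0|1|1"] <- 0
  zero$pct[1] <- zero$pct[1] + tab$pct[tab$key == ">84|1|0|1|1"]
  zero <- stratum_table(as.data.frame(zero)[1:6])
  expect_equal(allocate_counts(zero, 12345)[[">84|1|0|1|1"]], 0L)

  # property: random tables, counts sum to n and sit within 1 of exact quota
  for (seed in 1:6) {
    pct <- withr::with_seed(seed, {
      w <- rgamma(80, 0.5); 100 * w / sum(w)
    })
    rt <- stratum_table(data.frame(tab[1:5], pct = pct))
    for (n in c(97L, 10000L)) {
      cnt <- allocate_counts(rt, n)
      expect_equal(sum(cnt), n)
      expect_true(all(abs(cnt - n * rt$pct / sum(rt$pct)) < 1))
    }
    # scale consistency: doubling n never decreases, at most doubles
    c1 <- allocate_counts(rt, 500); c2 <- allocate_counts(rt, 1000)
    expect_true(all(c2 >= c1))
    expect_true(all(c2 <= 2 * c1 + 1))
  }
})

test_that("matched samples hit the allocated counts exactly", {
  tab <- default_stratum_table()
  spec <- generator_spec(20000, extra_items = small_battery(2), seed = 31)
  src <- generate_cohort(spec, matching_method = "exact")
  samp <- draw_matched_sample(src, tab, 2000, seed = 4)
  expect_equal(n_clients(samp), 2000L)
  got <- table(factor(stratum_keys(samp), levels = tab$key))
  expect_equal(as.vector(got), as.vector(allocate_counts(tab, 2000)))

  samp2 <- draw_matched_sample(src, tab, 2000, seed = 4)
  expect_identical(samp$data, samp2$data)
  samp3 <- draw_matched_sample(src, tab, 2000, seed = 5)
  expect_false(identical(samp$data, samp3$data))
})

test_that("self-matching returns a permutation of the source", {
  spec <- generator_spec(1000, extra_items = small_battery(2), seed = 32)
  src <- generate_cohort(spec)
  keys <- stratum_keys(src)
  emp <- as.data.frame(table(keys), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(emp$keys, "|", fixed = TRUE))
  self_tab <- stratum_table(data.frame(
    age_bin = parts[, 1], gender = parts[, 2], adl = parts[, 3],
    cognition = parts[, 4], falls = parts[, 5],
    pct = 100 * emp$Freq / 1000))
  samp <- draw_matched_sample(src, self_tab, 1000, seed = 1)
  expect_setequal(samp$data$client_id, src$data$client_id)
})

test_that("stratum shortfall errors name the stratum, or warns with replacement", {
  tab <- default_stratum_table()
  spec <- generator_spec(20000, extra_items = small_battery(2), seed = 33)
  src <- generate_cohort(spec, matching_method = "exact")
  # remove one required stratum entirely
  keys <- stratum_keys(src)
  victim <- "<50|1|1|1|1"   # needs 6 at n = 10,000
  src2 <- subset_cohort(src, which(keys != victim))
  err <- expect_error(draw_matched_sample(src2, tab, 10000, seed = 1))
  expect_match(conditionMessage(err), victim, fixed = TRUE)
  # asking for more than the source holds: fillable only with replacement
  w <- capture_warnings(
    samp <- draw_matched_sample(src, tab, 30000, seed = 1,
                                allow_replacement = TRUE))
  expect_true(any(grepl("replacement", w)))
  expect_equal(n_clients(samp), 30000L)
})
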