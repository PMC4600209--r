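# Shared in-code fixtures: no data files, everything generated at test time.

# small three-item dictionary: one count, one ordinal scale, one binary
toy_dictionary <- function() {
  item_dictionary(
    code    = c("K5", "B2A", "X1"),
    kind    = c("continuous", "ordinal", "categorical"),
    levels  = list(NULL, as.character(0:4), c("0", "1")),
    include = c(TRUE, TRUE, TRUE)
  )
}

toy_cohort <- function(n = 50, seed = 1) {
  withr::with_seed(seed, {
    d <- data.frame(
      K5  = rpois(n, 1),
      B2A = as.character(sample(0:4, n, TRUE)),
      X1  = as.character(rbinom(n, 1, 0.4)),
      rehab6m = rbinom(n, 1, 0.3)
    )
    cohort(d, toy_dictionary())
  })
}

# random small instance for path-oracle checks: <= 8 mixed-kind groups
random_path_instance <- function(seed, n = 300) {
  withr::with_seed(seed, {
    G <- sample(3:8, 1)
    codes <- sprintf("V%02d", 1:G)
    kinds <- character(G); levels <- vector("list", G); dat <- list()
    for (g in 1:G) {
      if (runif(1) < 0.5) {
        L <- sample(2:4, 1)
        kinds[g] <- "categorical"
        levels[[g]] <- as.character(0:(L - 1))
        dat[[codes[g]]] <- as.character(sample(0:(L - 1), n, TRUE))
      } else {
        kinds[g] <- "continuous"
        levels[g] <- list(NULL)
        dat[[codes[g]]] <- rnorm(n)
      }
    }
    d <- as.data.frame(dat)
    eta <- rnorm(1, 0, 0.3)
    for (g in 1:G) {
      eta <- eta + rnorm(1) * as.numeric(as.character(d[[codes[g]]]))
    }
    d$rehab6m <- rbinom(n, 1, plogis(drop(scale(eta))))
    cohort(d, item_dictionary(codes, kinds, levels))
  })
}

# compact battery for forest tests: 10 binary items
small_battery <- function(k = 10, prev = 0.4) {
  lapply(seq_len(k), function(i) {
    list(code = sprintf("X%02d", i), kind = "categorical",
         levels = c("0", "1"), probs = c(1 - prev, prev))
  })
}

# independent KKT audit of a fitted path, coded apart from the fitter:
# returns the worst violation over all grid points and groups
audit_kkt <- function(path, lambda_tol = 1e-6) {
  n <- nrow(path$x)
  worst <- 0
  for (l in seq_along(path$lambda)) {
    beta <- path$beta[, l]
    eta <- path$intercept[l] + drop(path$x %*% beta)
    grad <- crossprod(path$x, plogis(eta) - path$y) / n
    for (g in seq_along(path$group_items)) {
      idx <- path$group == g
      gg <- grad[idx]; bg <- beta[idx]
      nb <- sqrt(sum(bg^2))
      v <- if (nb > 0) {
        sqrt(sum((gg + path$lambda[l] * path$weights[g] * bg / nb)^2))
      } else {
        max(0, sqrt(sum(gg^2)) - path$lambda[l] * path$weights[g])
      }
      worst <- max(worst, v)
    }
  }
  worst
}

# independently coded matching predicate used as brute-force oracle
oracle_stratum_key <- function(age, gender, h2, b2a, k5) {
  bin <- if (age < 50) "<50" else if (age < 65) "50-64" else
    if (age < 75) "65-74" else if (age < 85) "75-84" else ">84"
  paste(bin, as.integer(gender == 1), as.integer(any(h2 >= 1)),
        as.integer(b2a >= 1), as.integer(k5 >= 1), sep = "|")
}
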