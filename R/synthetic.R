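#' Specification for a synthetic client cohort
#'
#' A generator spec fully determines a synthetic cohort: sample size, the
#' extra item battery (beyond the raw matching items) with per-item marginal
#' probabilities, planted main effects and pairwise interactions on the
#' log-odds scale, the intercept, and the seed. The outcome is drawn
#' Bernoulli(p) with `logit p = intercept + sum(planted main effects)
#' + sum(planted interactions)` — the generative direction of the logistic
#' model the rankers are later asked to recover.
#'
#' @param n number of clients.
#' @param extra_items list of item definitions, each a list with `code`,
#'   `kind` (`"categorical"`/`"ordinal"`/`"continuous"`), `levels` and
#'   `probs` (marginal probabilities, summing to 1) for non-continuous
#'   items; [default_battery()] supplies the standard desk-scale battery.
#' @param planted_effects named list: item code -> coefficient on the
#'   log-odds scale. For a categorical item with L levels, either a single
#'   coefficient (applied to the numeric value) or a vector of L-1
#'   per-level coefficients for the non-reference levels.
#' @param planted_interactions list of `list(items = c(code1, code2),
#'   beta = coefficient)` pairwise product terms.
#' @param intercept log-odds intercept. The default -1.4 gives roughly 20 %
#'   outcome prevalence under a null signal, a free design choice standing
#'   in for the unpublished prevalence of rehabilitation use.
#' @param seed integer; the seed fully determines the generated cohort.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n, extra_items = default_battery(),
                           planted_effects = list(),
                           planted_interactions = list(),
                           intercept = -1.4, seed = 1L) {
  stopifnot(is.numeric(n), n >= 1)
  for (it in extra_items) {
    stopifnot(!is.null(it$code), !is.null(it$kind))
    if (it$kind != "continuous") {
      if (length(it$levels) < 2 || length(it$probs) != length(it$levels)) {
        stop("item ", it$code, ": levels and probs must align")
      }
      if (abs(sum(it$probs) - 1) > 1e-9) {
        stop("item ", it$code, ": marginal probabilities must sum to 1")
      }
    }
  }
  structure(
    list(n = as.integer(n), extra_items = extra_items,
         planted_effects = planted_effects,
         planted_interactions = planted_interactions,
         intercept = intercept, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' Default desk-scale item battery
#'
#' 30 binary items (`X01`-`X30`, prevalences cycling over 0.1-0.5),
#' 10 three-level ordinal items (`T01`-`T10`, marginals 0.6/0.3/0.1) and
#' 2 standard-normal continuous items (`Z1`, `Z2`) — a ~40-item stand-in
#' for the full several-hundred-item assessment battery.
#'
#' @return list of item definitions for [generator_spec()].
#' @export
default_battery <- function() {
  items <- list()
  prev <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 6)
  for (i in 1:30) {
    items[[length(items) + 1L]] <- list(
      code = sprintf("X%02d", i), kind = "categorical",
      levels = c("0", "1"), probs = c(1 - prev[i], prev[i]))
  }
  for (i in 1:10) {
    items[[length(items) + 1L]] <- list(
      code = sprintf("T%02d", i), kind = "ordinal",
      levels = c("0", "1", "2"), probs = c(0.6, 0.3, 0.1))
  }
  items[[length(items) + 1L]] <- list(code = "Z1", kind = "continuous")
  items[[length(items) + 1L]] <- list(code = "Z2", kind = "continuous")
  items
}

# raw matching-item level sets used by the generator and its dictionary
MATCH_ITEM_LEVELS <- list(
  GENDER = c("0", "1"),
  H2 = as.character(0:6),   # ADL performance items H2A..H2J
  B2A = as.character(0:4)   # cognitive skills for daily decision making
)

#' Draw the five-matching-variable block from a target distribution
#'
#' Assigns each of `n` synthetic clients to one of the 80 strata of a
#' [stratum_table()] — multinomially with the table's cell probabilities, or
#' by exact largest-remainder quota (`method = "exact"`, which guarantees
#' every positive-probability cell is covered at large `n`) — and populates
#' raw items consistent with the cell: an integer age uniform within the age
#' band, gender, ten ADL performance items (`H2A`-`H2J`), cognitive skills
#' (`B2A`) and falls count (`K5`). When a derived flag is 1 the number of
#' elevated raw ADL items is drawn uniformly from 1..10; when 0 all are 0.
#'
#' @param n number of rows.
#' @param table a [stratum_table()].
#' @param seed integer seed (fully determines the block).
#' @param method `"multinomial"` (default) or `"exact"` quota assignment.
#' @return data.frame with columns `AGE`, `GENDER`, `H2A`..`H2J`, `B2A`, `K5`.
#' @export
sample_matching_block <- function(n, table, seed,
                                  method = c("multinomial", "exact")) {
  stopifnot(inherits(table, "stratum_table"))
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be positive")
  method <- match.arg(method)
  withr::with_seed(as.integer(seed), {
    if (method == "multinomial") {
      cell <- sample.int(nrow(table), n, replace = TRUE,
                         prob = table$pct / sum(table$pct))
    } else {
      counts <- allocate_counts(table, n)
      cell <- sample(rep.int(seq_len(nrow(table)), counts[table$key]))
    }
    lo <- c("<50" = 18, "50-64" = 50, "65-74" = 65, "75-84" = 75, ">84" = 85)
    hi <- c("<50" = 49, "50-64" = 64, "65-74" = 74, "75-84" = 84, ">84" = 99)
    ab <- table$age_bin[cell]
    out <- data.frame(
      AGE = lo[ab] + floor(runif(n) * (hi[ab] - lo[ab] + 1)),
      GENDER = as.character(table$gender[cell]),
      stringsAsFactors = FALSE
    )
    h2 <- matrix(0L, n, 10, dimnames = list(NULL, paste0("H2", LETTERS[1:10])))
    adl1 <- which(table$adl[cell] == 1L)
    for (i in adl1) {
      k <- sample.int(10, 1)
      sel <- sample.int(10, k)
      h2[i, sel] <- sample.int(6, k, replace = TRUE)
    }
    for (cc in colnames(h2)) out[[cc]] <- as.character(h2[, cc])
    cog <- integer(n)
    cog[table$cognition[cell] == 1L] <-
      sample.int(4, sum(table$cognition[cell] == 1L), replace = TRUE)
    out$B2A <- as.character(cog)
    falls <- integer(n)
    falls[table$falls[cell] == 1L] <-
      sample.int(5, sum(table$falls[cell] == 1L), replace = TRUE)
    out$K5 <- falls
    rownames(out) <- NULL
    out
  })
}

# numeric value of an item column for the linear predictor
item_numeric <- function(v) as.numeric(as.character(v))

#' Generate a synthetic cohort with planted logistic effects
#'
#' Draws the matching block from the target stratum distribution, the extra
#' item battery from its marginals, and the outcome from the planted
#' logistic model. A planted effect on a categorical item enters through
#' the item's numeric value (single coefficient) or per-level indicators
#' (coefficient vector); an interaction enters as the product of the two
#' items' numeric values.
#'
#' The seed in the spec expands into per-stage substreams at fixed offsets
#' (matching block, battery, outcome), so each stage is individually
#' reproducible.
#'
#' @param spec a [generator_spec()].
#' @param table a [stratum_table()]; defaults to the packaged population
#'   fixture.
#' @param include_matching also flag the raw matching items (`AGE`,
#'   `GENDER`, ADL, cognition, falls) as ranked predictors (default
#'   `FALSE`: only the extra battery is ranked, keeping the ranked set at
#'   desk scale).
#' @param matching_method passed to [sample_matching_block()].
#' @return a [cohort()] with outcome column `rehab6m`.
#' @export
generate_cohort <- function(spec, table = default_stratum_table(),
                            include_matching = FALSE,
                            matching_method = "multinomial") {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n
  block <- sample_matching_block(n, table, seed = spec$seed + 1000L,
                                 method = matching_method)
  battery <- withr::with_seed(spec$seed + 2000L, {
    out <- list()
    for (it in spec$extra_items) {
      if (it$kind == "continuous") {
        out[[it$code]] <- rnorm(n)
      } else {
        out[[it$code]] <- sample(as.character(it$levels), n, replace = TRUE,
                                 prob = it$probs)
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  })
  d <- cbind(block, battery)
  all_codes <- names(d)
  eta <- rep(spec$intercept, n)
  for (code in names(spec$planted_effects)) {
    if (!code %in% all_codes) stop("planted effect on unknown item ", code)
    beta <- spec$planted_effects[[code]]
    v <- d[[code]]
    if (length(beta) == 1L) {
      eta <- eta + beta * item_numeric(v)
    } else {
      lv <- item_levels_of(spec, code)
      if (length(beta) != length(lv) - 1L) {
        stop("item ", code, ": per-level coefficients must have length L-1")
      }
      for (j in seq_along(beta)) eta <- eta + beta[j] * (v == lv[j + 1L])
    }
  }
  for (ia in spec$planted_interactions) {
    miss <- setdiff(ia$items, all_codes)
    if (length(miss)) stop("planted interaction on unknown item ", miss[1])
    eta <- eta + ia$beta * item_numeric(d[[ia$items[1]]]) *
      item_numeric(d[[ia$items[2]]])
  }
  d$rehab6m <- withr::with_seed(spec$seed + 3000L, {
    rbinom(n, 1L, 1 / (1 + exp(-eta)))
  })
  d <- cbind(client_id = sprintf("s%07d", seq_len(n)), d,
             stringsAsFactors = FALSE)
  cohort(d, generator_dictionary(spec, include_matching))
}

item_levels_of <- function(spec, code) {
  for (it in spec$extra_items) if (it$code == code) return(as.character(it$levels))
  stop("item ", code, " has no declared level set")
}

#' Item dictionary implied by a generator spec
#' @inheritParams generate_cohort
#' @return an [item_dictionary()] covering the raw matching items and the
#'   extra battery.
#' @export
generator_dictionary <- function(spec, include_matching = FALSE) {
  codes <- c("AGE", "GENDER", paste0("H2", LETTERS[1:10]), "B2A", "K5")
  kinds <- c("continuous", "categorical", rep("ordinal", 10), "ordinal",
             "continuous")
  levels <- c(list(NULL), list(MATCH_ITEM_LEVELS$GENDER),
              rep(list(MATCH_ITEM_LEVELS$H2), 10),
              list(MATCH_ITEM_LEVELS$B2A), list(NULL))
  include <- rep(include_matching, length(codes))
  for (it in spec$extra_items) {
    codes <- c(codes, it$code)
    kinds <- c(kinds, it$kind)
    levels <- c(levels, if (it$kind == "continuous") list(NULL)
                else list(as.character(it$levels)))
    include <- c(include, TRUE)
  }
  item_dictionary(codes, kinds, levels, include)
}
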