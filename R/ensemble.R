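#' Aggregate a rank matrix into mean ranks and their dispersion
#'
#' Given `r(j, k)`, the rank of item j in resample k, computes each item's
#' average rank over the K resamples, `rbar(j) = (1/K) sum_k r(j, k)`, and
#' its dispersion. The dispersion reported as `se` is the standard error of
#' the mean rank, `sd({r(j, k)}) / sqrt(K)`; the raw across-sample standard
#' deviation is also emitted as `sd`. For K = 1 both are defined as 0.
#'
#' @param rank_matrix d x K numeric matrix, rows named by item; every
#'   column must be a complete (possibly tie-averaged) ranking of the d
#'   items.
#' @return An object of class `rank_summary`: data.frame with columns
#'   `item`, `mean_rank`, `se`, `sd`, plus attributes `K` and `d`.
#' @export
rank_summary <- function(rank_matrix) {
  stopifnot(is.matrix(rank_matrix), !is.null(rownames(rank_matrix)))
  d <- nrow(rank_matrix); K <- ncol(rank_matrix)
  colsum <- colSums(rank_matrix)
  if (any(abs(colsum - d * (d + 1) / 2) > 1e-6)) {
    stop("every column must be a complete ranking of the d items")
  }
  mean_rank <- rowMeans(rank_matrix)
  if (K > 1L) {
    sds <- apply(rank_matrix, 1, stats::sd)
  } else {
    sds <- rep(0, d)
  }
  out <- data.frame(item = rownames(rank_matrix),
                    mean_rank = unname(mean_rank),
                    se = unname(sds / sqrt(K)),
                    sd = unname(sds),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_rank), ]
  rownames(out) <- NULL
  structure(out, class = c("rank_summary", "data.frame"), K = K, d = d)
}

#' Ensemble ranking over repeated frequency-matched samples
#'
#' The stability device at the heart of the pipeline: instead of ranking
#' all items once on the full source, K frequency-matched samples of size n
#' are drawn from the source (sample k seeded with `master_seed + k`, so a
#' client may appear in several samples), the chosen ranker is applied to
#' each, and the per-sample ranks are aggregated by [rank_summary()].
#'
#' @param source a [cohort()] carrying the raw matching items.
#' @param table a [stratum_table()] target distribution.
#' @param ranker `"path"` (group-lasso entry order) or `"forest"`
#'   (permutation importance).
#' @param K number of matched samples (full-scale profile 100; desk-scale
#'   tests use 10).
#' @param n size of each matched sample (full-scale 10,000; desk-scale
#'   2,000).
#' @param master_seed integer; sample k uses seed `master_seed + k`.
#' @param ranker_args list of extra arguments for [rank_by_path()] or
#'   [rank_by_forest()].
#' @param allow_replacement passed to [draw_matched_sample()].
#' @param progress print per-sample progress lines.
#' @return list with `rank_matrix` (d x K, rows named by item,
#'   `sample_seeds` attribute) and `summary` (a [rank_summary()]).
#' @export
ensemble_ranks <- function(source, table, ranker = c("path", "forest"),
                           K = 10L, n = 2000L, master_seed = 1L,
                           ranker_args = list(), allow_replacement = FALSE,
                           progress = FALSE) {
  ranker <- match.arg(ranker)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1")
  keys <- stratum_keys(source)
  items <- included_items(source$dictionary)
  rm <- matrix(NA_real_, length(items), K,
               dimnames = list(items, paste0("S", seq_len(K))))
  seeds <- as.integer(master_seed) + seq_len(K)
  for (k in seq_len(K)) {
    samp <- tryCatch(
      draw_matched_sample(source, table, n, seed = seeds[k],
                          allow_replacement = allow_replacement, keys = keys),
      error = function(e) {
        stop("ensemble sample ", k, ": ", conditionMessage(e))
      })
    rv <- if (ranker == "path") {
      do.call(rank_by_path, c(list(samp), ranker_args))
    } else {
      do.call(rank_by_forest, c(list(samp), list(seed = seeds[k]),
                                ranker_args))
    }
    rm[, k] <- rv$ranks[items]
    if (progress) {
      message(sprintf("[%s] sample %d/%d done", ranker, k, K))
    }
  }
  attr(rm, "sample_seeds") <- seeds
  list(rank_matrix = rm, summary = rank_summary(rm))
}

#' Compare two ensemble rankings
#'
#' Reports the Spearman correlation between two rankers' mean-rank vectors,
#' the items both rank at or better than a cutoff (the "lower-left region"
#' of a mean-rank-vs-mean-rank scatter: small mean rank = important), the
#' items top-ranked by only one ranker (the off-diagonal regions — under a
#' main-effects-only path ranker versus an interaction-sensitive forest,
#' genuinely interacting items drift into the forest-only region), and the
#' paired mean ranks for plotting.
#'
#' @param a,b [rank_summary()] objects over the same item universe.
#' @param top_threshold mean-rank cutoff defining "top-ranked"
#'   (default 20; smaller mean rank is better).
#' @return An object of class `rank_comparison`: list with `spearman`,
#'   `both_top`, `only_a`, `only_b`, `paired` (data.frame `item`,
#'   `mean_rank_a`, `mean_rank_b`), `top_threshold`.
#' @export
compare_rankings <- function(a, b, top_threshold = 20) {
  stopifnot(inherits(a, "rank_summary"), inherits(b, "rank_summary"))
  if (!setequal(a$item, b$item)) {
    stop("rank summaries cover different item sets")
  }
  bb <- b[match(a$item, b$item), ]
  paired <- data.frame(item = a$item,
                       mean_rank_a = a$mean_rank,
                       mean_rank_b = bb$mean_rank,
                       stringsAsFactors = FALSE)
  top_a <- paired$item[paired$mean_rank_a <= top_threshold]
  top_b <- paired$item[paired$mean_rank_b <= top_threshold]
  structure(
    list(spearman = stats::cor(paired$mean_rank_a, paired$mean_rank_b,
                               method = "spearman"),
         both_top = intersect(top_a, top_b),
         only_a = setdiff(top_a, top_b),
         only_b = setdiff(top_b, top_a),
         paired = paired,
         top_threshold = top_threshold),
    class = "rank_comparison"
  )
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat("Rank comparison: Spearman", round(x$spearman, 3), "\n",
      length(x$both_top), "item(s) top-ranked by both (cutoff",
      x$top_threshold, "):", paste(x$both_top, collapse = ", "), "\n")
  invisible(x)
}

#' Scatter plot of paired mean ranks
#'
#' Mean rank under ranker a against mean rank under ranker b, with the
#' both-top (lower-left) region delimited; important items sit near the
#' origin.
#'
#' @param comparison a [compare_rankings()] result.
#' @param labels label items in the both-top region.
#' @param ... passed to [plot()].
#' @return invisibly, the paired data.
#' @export
plot_rank_comparison <- function(comparison, labels = TRUE, ...) {
  stopifnot(inherits(comparison, "rank_comparison"))
  p <- comparison$paired
  plot(p$mean_rank_a, p$mean_rank_b,
       xlab = "mean rank (ranker a)", ylab = "mean rank (ranker b)",
       pch = 19, col = "grey30", ...)
  abline(0, 1, lty = 2, col = "grey60")
  abline(v = comparison$top_threshold, h = comparison$top_threshold,
         lty = 3, col = "steelblue")
  if (labels && length(comparison$both_top)) {
    sel <- p$item %in% comparison$both_top
    text(p$mean_rank_a[sel], p$mean_rank_b[sel], p$item[sel],
         pos = 4, cex = 0.7)
  }
  invisible(p)
}

#' Direction of association for top-ranked items
#'
#' Fits an unpenalized logistic regression of the outcome on the named
#' items jointly and reports, per item, whether it predicts increased (`+`)
#' or decreased (`-`) rehabilitation use: the sign of the coefficient, or
#' for a multi-level item the sign of its largest-magnitude level
#' coefficient. Items whose largest coefficient is within 2 standard errors
#' of zero are flagged unstable. Under complete separation the fit is
#' replaced by a lightly penalized refit (small-lambda point of the
#' group-lasso path) and flagged.
#'
#' @param source a [cohort()].
#' @param items character vector of item codes to fit jointly.
#' @return data.frame with columns `item`, `direction` (`"+"`/`"-"`),
#'   `coef`, `se`, `stable` (logical), plus attribute `penalized` if a
#'   separation fallback was used.
#' @export
effect_direction <- function(source, items) {
  stopifnot(inherits(source, "cohort"))
  miss <- setdiff(items, source$dictionary$code)
  if (length(miss)) stop("item(s) not in cohort: ", paste(miss, collapse = ", "))
  dict <- source$dictionary
  sub_dict <- item_dictionary(dict$code, dict$kind, dict$levels,
                              dict$code %in% items)
  sub <- cohort(source$data, sub_dict, source$outcome_col)
  dm <- build_design(sub, standardize = FALSE)
  df <- as.data.frame(dm$x)
  names(df) <- make.names(colnames(dm$x))
  df$.y <- outcomes(sub)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = binomial()))
  penalized <- FALSE
  cf <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  if (!fit$converged || any(abs(cf) > 15, na.rm = TRUE)) {
    # separation: fall back to a lightly penalized fit
    penalized <- TRUE
    dms <- build_design(sub, standardize = TRUE)
    pr <- fit_path(dms, G = 2L, eps = 1e-4)
    cf <- pr$beta[, ncol(pr$beta)] / dms$scale   # back to raw scale
    names(cf) <- make.names(colnames(dms$x))
    se <- rep(NA_real_, length(cf))
    names(se) <- names(cf)
  }
  out <- do.call(rbind, lapply(items, function(code) {
    cols <- make.names(colnames(dm$x)[dm$group == match(code, dm$group_items)])
    cc <- cf[cols]; ss <- se[cols]
    cc[is.na(cc)] <- 0
    top <- which.max(abs(cc))
    data.frame(item = code,
               direction = if (cc[top] >= 0) "+" else "-",
               coef = unname(cc[top]),
               se = unname(ss[top]),
               stable = if (is.na(ss[top])) NA else abs(cc[top]) >= 2 * ss[top],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "penalized") <- penalized
  out
}
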