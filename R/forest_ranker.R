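#' Fit a classification forest on a cohort
#'
#' Fits a random forest of classification trees on the included items, with
#' categorical/ordinal items handled natively as factors (so each
#' assessment item is a single variable in the forest, matching the
#' group-level granularity of the path ranker). Bootstrap in-bag counts are
#' kept so each tree's out-of-bag records are known; a warning is issued in
#' the unusual event that some record is in-bag for every tree.
#'
#' @param cohort a [cohort()]; the outcome must have both classes.
#' @param n_trees number of trees (default 500, the classic forest default).
#' @param mtry candidate items per split (default `floor(sqrt(d))`).
#' @param min_node minimum node size (default 5).
#' @param seed integer seed; the fitted forest is fully reproducible
#'   (single-threaded).
#' @return An object of class `forest_model`: list with the `ranger` fit
#'   (`fit`), the model frame (`frame`), `oob` (n x n_trees logical matrix
#'   of out-of-bag membership), `items`, and `fit_params`.
#' @export
fit_forest <- function(cohort, n_trees = 500L, mtry = NULL, min_node = 5L,
                       seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  y <- outcomes(cohort)
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  items <- included_items(cohort$dictionary)
  frame <- forest_frame(cohort, items)
  frame$.y <- factor(y, levels = c(0, 1))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(items))))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = frame,
    num.trees = as.integer(n_trees), mtry = as.integer(mtry),
    min.node.size = as.integer(min_node), splitrule = "gini",
    respect.unordered.factors = "partition",
    keep.inbag = TRUE, num.threads = 1L, seed = as.integer(seed),
    verbose = FALSE
  )
  inbag <- do.call(cbind, fit$inbag.counts)
  oob <- inbag == 0L
  if (any(rowSums(oob) == 0L)) {
    warning("some records are in-bag for every tree; ",
            "their OOB contribution is undefined - increase n_trees")
  }
  structure(
    list(fit = fit, frame = frame, oob = oob, items = items,
         fit_params = list(n_trees = as.integer(n_trees),
                           mtry = as.integer(mtry),
                           min_node = as.integer(min_node),
                           seed = as.integer(seed))),
    class = "forest_model"
  )
}

# model frame with factors for categorical items, numeric for continuous
forest_frame <- function(cohort, items) {
  dict <- cohort$dictionary
  out <- list()
  for (code in items) {
    e <- dict_entry(dict, code)
    v <- cohort$data[[code]]
    out[[code]] <- if (e$kind == "continuous") as.numeric(v)
                   else factor(v, levels = e$levels)
  }
  as.data.frame(out, optional = TRUE)
}

#' @export
print.forest_model <- function(x, ...) {
  cat("Forest model:", x$fit_params$n_trees, "trees over",
      length(x$items), "items; OOB accuracy",
      round(oob_accuracy(x), 3), "\n")
  invisible(x)
}

# per-tree class predictions for a frame (n x n_trees matrix of 0/1)
tree_predictions <- function(model, frame) {
  pr <- stats::predict(model$fit, data = frame, predict.all = TRUE,
                       num.threads = 1L, verbose = FALSE)$predictions
  pr - 1L   # ranger returns factor-level indices 1/2
}

#' Out-of-bag accuracy of a fitted forest
#' @param model a [fit_forest()] result.
#' @return scalar OOB accuracy (each record voted on by the trees for which
#'   it is out-of-bag).
#' @export
oob_accuracy <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  preds <- tree_predictions(model, model$frame)
  y <- as.integer(model$frame$.y) - 1L
  votes1 <- rowSums(preds * model$oob)
  nv <- rowSums(model$oob)
  use <- nv > 0
  mean((votes1[use] * 2 > nv[use]) == (y[use] == 1L))
}

# mean over trees of per-tree OOB accuracy given a prediction matrix
per_tree_oob_accuracy <- function(preds, oob, y) {
  hits <- colSums((preds == y) * oob)
  hits / pmax(colSums(oob), 1L)
}

#' Permutation variable importance at the item level
#'
#' For each included item, the drop in out-of-bag accuracy when the item's
#' values are permuted: per permutation repeat, one random permutation of
#' the item's column is drawn, every tree re-predicts, and each tree's
#' accuracy over its own out-of-bag records is compared with its unpermuted
#' baseline. Importance is the drop averaged over trees and repeats;
#' permuting an item the model never uses (or whose values are constant)
#' yields exactly zero. Ranks are the descending order of importance with
#' ties averaged.
#'
#' For multi-level items the whole factor column is permuted jointly, so
#' importance is aggregated at the original-item level, comparable with the
#' path ranker's group-level entry ranks.
#'
#' @param model a [fit_forest()] result.
#' @param repeats number of independent permutations per item (default 1).
#' @param seed integer seed for the permutations.
#' @return An object of class `vim_vector`: list with `importance` (named
#'   mean OOB accuracy drop), `ranks` (named, 1 = most important) and
#'   `repeats`.
#' @export
permutation_vim <- function(model, repeats = 1L, seed = 1L) {
  stopifnot(inherits(model, "forest_model"))
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1L) stop("repeats must be >= 1")
  y <- as.integer(model$frame$.y) - 1L
  base_preds <- tree_predictions(model, model$frame)
  base_acc <- per_tree_oob_accuracy(base_preds, model$oob, y)
  n <- nrow(model$frame)
  imp <- stats::setNames(numeric(length(model$items)), model$items)
  withr::with_seed(as.integer(seed), {
    for (code in model$items) {
      if (length(unique(model$frame[[code]])) < 2L) next  # constant: drop 0
      drops <- numeric(repeats)
      for (r in seq_len(repeats)) {
        perm_frame <- model$frame
        perm_frame[[code]] <- perm_frame[[code]][sample.int(n)]
        acc <- per_tree_oob_accuracy(tree_predictions(model, perm_frame),
                                     model$oob, y)
        drops[r] <- mean(base_acc - acc)
      }
      imp[code] <- mean(drops)
    }
  })
  ranks <- rank(-imp, ties.method = "average")
  structure(list(importance = imp, ranks = ranks, repeats = repeats),
            class = "vim_vector")
}

#' @export
print.vim_vector <- function(x, ...) {
  top <- names(sort(x$ranks))[seq_len(min(5, length(x$ranks)))]
  cat("Permutation VIM over", length(x$ranks), "items; top:",
      paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Export a VIM vector as a table
#' @param vim a [permutation_vim()] result.
#' @param file optional CSV path.
#' @return data.frame with columns `item`, `importance`, `rank`.
#' @export
export_vim <- function(vim, file = NULL) {
  stopifnot(inherits(vim, "vim_vector"))
  out <- data.frame(item = names(vim$importance),
                    importance = unname(vim$importance),
                    rank = unname(vim$ranks))
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Rank a cohort's items by forest permutation importance
#'
#' Convenience wrapper: fit the forest, compute the item-level permutation
#' importance, return the ranking as a `rank_vector` comparable with
#' [rank_by_path()].
#'
#' @param cohort a [cohort()].
#' @param n_trees,mtry,min_node,seed passed to [fit_forest()].
#' @param repeats passed to [permutation_vim()].
#' @return a `rank_vector` over the included items.
#' @export
rank_by_forest <- function(cohort, n_trees = 500L, mtry = NULL,
                           min_node = 5L, repeats = 1L, seed = 1L) {
  model <- fit_forest(cohort, n_trees = n_trees, mtry = mtry,
                      min_node = min_node, seed = seed)
  vim <- permutation_vim(model, repeats = repeats, seed = seed + 1L)
  structure(list(ranks = vim$ranks, importance = vim$importance,
                 tie_policy = "descending importance, ties averaged"),
            class = "rank_vector")
}
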