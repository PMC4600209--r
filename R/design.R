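#' Build a dummy-coded design matrix from a cohort
#'
#' Expands the included items of a cohort into a numeric design matrix with
#' reference-cell (drop-first-level) dummy coding: a categorical or ordinal
#' item with L declared levels contributes L-1 indicator columns, all in one
#' coefficient group; a continuous item contributes a single column in its
#' own group. Grouping is what lets the grouped penalty force an item's
#' dummy columns to enter or leave the model together.
#'
#' With `standardize = TRUE` (the default) every column is centered and
#' scaled to unit sample standard deviation, so the penalty treats columns
#' on different raw scales evenhandedly. Columns constant in the data
#' (zero variance) are left unscaled and flagged; with an intercept in the
#' model their penalized coefficients can never become nonzero along a path.
#'
#' @param cohort a [cohort()].
#' @param standardize center/scale columns (default `TRUE`).
#' @return An object of class `design_matrix`: list with
#'   `x` (n x p numeric matrix), `group` (integer group id per column),
#'   `group_items` (item code per group id), `labels` (column labels),
#'   `constant` (logical flag per column), `y` (outcome vector),
#'   `center`, `scale` (per-column transforms applied).
#' @examples
#' dict <- item_dictionary(c("A", "Z"), c("categorical", "continuous"),
#'                         list(c("0", "1", "2"), NULL))
#' dat <- data.frame(A = c("0", "1", "2", "1"), Z = c(0.3, 1, 2, 5),
#'                   rehab6m = c(0, 1, 0, 1))
#' dm <- build_design(cohort(dat, dict))
#' ncol(dm$x)      # 3 columns
#' dm$group        # 1 1 2
#' @export
build_design <- function(cohort, standardize = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  dict <- cohort$dictionary
  keep <- which(dict$include)
  if (!length(keep)) stop("no included items in dictionary")
  cols <- list(); grp <- integer(); labels <- character()
  group_items <- character()
  g <- 0L
  for (i in keep) {
    code <- dict$code[i]
    v <- cohort$data[[code]]
    g <- g + 1L
    group_items[g] <- code
    if (dict$kind[i] == "continuous") {
      cols[[length(cols) + 1L]] <- as.numeric(v)
      grp <- c(grp, g)
      labels <- c(labels, code)
    } else {
      lv <- dict$levels[[i]]
      for (l in lv[-1]) {
        cols[[length(cols) + 1L]] <- as.numeric(v == l)
        grp <- c(grp, g)
        labels <- c(labels, paste0(code, "=", l))
      }
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- labels
  p <- ncol(x)
  ctr <- rep(0, p); scl <- rep(1, p)
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0
  if (standardize) {
    idx <- which(!constant)
    ctr[idx] <- colMeans(x[, idx, drop = FALSE])
    scl[idx] <- sds[idx]
    x[, idx] <- sweep(sweep(x[, idx, drop = FALSE], 2, ctr[idx]), 2,
                      scl[idx], "/")
  }
  structure(
    list(x = x, group = grp, group_items = group_items, labels = labels,
         constant = constant, y = outcomes(cohort),
         center = ctr, scale = scl, standardized = standardize),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix:", nrow(x$x), "x", ncol(x$x), "(",
      length(x$group_items), "groups )")
  if (any(x$constant)) cat(";", sum(x$constant), "constant column(s) flagged")
  cat("\n")
  invisible(x)
}

#' Number of coefficient groups in a design
#' @param design a [build_design()] result.
#' @return integer.
#' @export
n_groups <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  length(design$group_items)
}
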