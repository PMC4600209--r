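#' Smallest penalty at which the all-zero solution is optimal
#'
#' For the group-penalized logistic objective, the zero coefficient vector
#' (with the intercept at its null maximizer, `logit(mean(y))`) is optimal
#' exactly when, for every group g, the Euclidean norm of the group's
#' log-likelihood gradient at the null does not exceed `lambda * w_g`.
#' Hence `lambda_max = max_g ||X_g'(y - ybar)||_2 / (n w_g)` on the
#' mean-log-likelihood scale used throughout the fitter. Any penalty at or
#' above this value returns the all-zero penalized solution.
#'
#' @param design a [build_design()] result.
#' @param y binary outcome vector (defaults to the design's own).
#' @param group_weights positive weight per group; default
#'   `sqrt(group size)`, the standard grouped-penalty normalization so
#'   multi-level items are not favored over single-column ones.
#' @return `lambda_max`, a positive scalar.
#' @export
compute_lambda_max <- function(design, y = design$y, group_weights = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; penalized fit undefined")
  }
  w <- default_group_weights(design, group_weights)
  n <- nrow(design$x)
  g0 <- crossprod(design$x, y - mean(y)) / n
  norms <- vapply(seq_along(design$group_items), function(g) {
    sqrt(sum(g0[design$group == g]^2))
  }, 0)
  max(norms / w)
}

default_group_weights <- function(design, group_weights) {
  G <- length(design$group_items)
  if (is.null(group_weights)) {
    group_weights <- sqrt(tabulate(design$group, nbins = G))
  }
  stopifnot(length(group_weights) == G, all(group_weights > 0))
  group_weights
}

#' Fit the group-lasso logistic solution path
#'
#' Maximizes the penalized log-likelihood `l(beta)/n - lambda * Omega(beta)`
#' with `Omega(beta) = sum_g w_g ||beta_g||_2` over a decreasing log-spaced
#' penalty grid from `lambda_max` down to `eps * lambda_max`, warm-starting
#' each grid point from the previous solution. The intercept is never
#' penalized. Convergence at every grid point is certified by the KKT
#' residual of the penalized stationarity conditions (default tolerance
#' 1e-6 on the standardized scale); a point that fails to converge raises
#' an error reporting the grid index and residual.
#'
#' @param design a [build_design()] result (standardized recommended).
#' @param y binary outcome (defaults to the design's own).
#' @param G number of grid points (default 100).
#' @param eps grid floor as a fraction of `lambda_max` (default 1e-3).
#' @param lambda optional explicit decreasing penalty vector overriding
#'   `G`/`eps`.
#' @param group_weights per-group penalty weights; default
#'   `sqrt(group size)`.
#' @param tol KKT residual tolerance (default 1e-6).
#' @param maxit maximum proximal-gradient iterations per grid point.
#' @return An object of class `path_result`: list with `lambda` (decreasing
#'   grid), `beta` (p x G coefficient matrix, standardized scale),
#'   `intercept`, `kkt` (per grid point), `active` (G_groups x G logical),
#'   `entry_lambda` (largest grid lambda at which each group is nonzero, NA
#'   if never), plus the design bookkeeping needed for refinement.
#' @export
fit_path <- function(design, y = design$y, G = 100L, eps = 1e-3,
                     lambda = NULL, group_weights = NULL,
                     tol = 1e-6, maxit = 50000L) {
  stopifnot(inherits(design, "design_matrix"))
  w <- default_group_weights(design, group_weights)
  lmax <- compute_lambda_max(design, y, w)
  if (is.null(lambda)) {
    stopifnot(G >= 2L, eps > 0, eps < 1)
    lambda <- exp(seq(log(lmax), log(eps * lmax), length.out = G))
  } else {
    lambda <- as.numeric(lambda)
    if (is.unsorted(rev(lambda))) stop("lambda must be decreasing")
  }
  p <- ncol(design$x)
  fit <- grplasso_path_cpp(design$x, as.numeric(y),
                           as.integer(design$group) - 1L, w, lambda,
                           numeric(p), stats::qlogis(mean(y)),
                           tol, as.integer(maxit))
  bad <- which(fit$kkt >= tol)
  if (length(bad)) {
    stop(sprintf(
      "path fit failed to converge at grid point %d (lambda = %.4g, KKT residual %.3g)",
      bad[1], lambda[bad[1]], fit$kkt[bad[1]]))
  }
  Gg <- length(design$group_items)
  # clamp numerically-dead groups (norm below activity tolerance) to exact
  # zero, so the all-zero solution at lambda >= lambda_max is exact
  for (g in seq_len(Gg)) {
    idx <- design$group == g
    nz <- sqrt(colSums(fit$beta[idx, , drop = FALSE]^2)) > ACTIVE_TOL
    fit$beta[idx, !nz] <- 0
  }
  active <- matrix(FALSE, Gg, length(lambda),
                   dimnames = list(design$group_items, NULL))
  for (g in seq_len(Gg)) {
    active[g, ] <- colSums(abs(fit$beta[design$group == g, , drop = FALSE])) > 0
  }
  entry <- apply(active, 1, function(a) {
    i <- which(a)[1]
    if (is.na(i)) NA_real_ else lambda[i]
  })
  structure(
    list(lambda = lambda, beta = fit$beta, intercept = fit$intercept,
         kkt = fit$kkt, iters = fit$iters, active = active,
         entry_lambda = entry, lambda_max = lmax,
         group = design$group, group_items = design$group_items,
         weights = w, x = design$x, y = as.numeric(y),
         tol = tol, maxit = as.integer(maxit)),
    class = "path_result"
  )
}

#' @export
print.path_result <- function(x, ...) {
  cat("Group-lasso logistic path:", length(x$lambda), "grid points,",
      length(x$group_items), "groups;",
      sum(!is.na(x$entry_lambda)), "groups enter; max KKT residual",
      format(max(x$kkt), digits = 3), "\n")
  invisible(x)
}

# refit at arbitrary lambda values, warm-started from a given solution
refit_at <- function(path, lambda, init_col) {
  grplasso_path_cpp(path$x, path$y, as.integer(path$group) - 1L,
                    path$weights, lambda,
                    path$beta[, init_col], path$intercept[init_col],
                    path$tol, path$maxit)
}

# activity tolerance: a group whose coefficient norm sits below this is
# treated as not yet entered (guards against floating-point ties at entry)
ACTIVE_TOL <- 1e-10

active_groups_of <- function(path, beta_col) {
  Gg <- length(path$group_items)
  vapply(seq_len(Gg), function(g) {
    sqrt(sum(beta_col[path$group == g]^2)) > ACTIVE_TOL
  }, TRUE)
}

# ||grad_g||/w_g per group at a given solution (used for floor tie-breaks)
group_grad_score <- function(path, beta_col, b0) {
  n <- nrow(path$x)
  pr <- 1 / (1 + exp(-(b0 + drop(path$x %*% beta_col))))
  gr <- crossprod(path$x, pr - path$y) / n
  vapply(seq_along(path$group_items), function(g) {
    sqrt(sum(gr[path$group == g]^2))
  }, 0) / path$weights
}

#' Rank items by order of entry along the solution path
#'
#' Items are ranked by decreasing entry penalty: the group whose
#' coefficients first become nonzero at the largest penalty ranks 1. When
#' several groups first appear between the same two adjacent grid points,
#' the interval is bisected (refitting at midpoints, warm-started) until
#' their entries separate or the interval width falls below
#' `floor_frac * lambda_max`; groups still tied at the floor are ordered by
#' their gradient-norm-to-weight ratio `||grad_g||/w_g` at the tie point
#' (the quantity whose threshold crossing defines entry), and any residual
#' ties receive averaged ranks. Groups that never enter share the averaged
#' worst ranks, so every ranking is complete over all d items.
#'
#' @param path a [fit_path()] result.
#' @param refine bisect ambiguous shared-interval entries (default `TRUE`).
#' @param floor_frac bisection floor as a fraction of `lambda_max`
#'   (default 1e-4).
#' @return An object of class `rank_vector`: list with `ranks` (named,
#'   1 = most important, ties averaged), `entry_lambda` (named, refined),
#'   `tie_policy`.
#' @export
entry_order <- function(path, refine = TRUE, floor_frac = 1e-4) {
  stopifnot(inherits(path, "path_result"))
  items <- path$group_items
  Gg <- length(items)
  entry <- path$entry_lambda
  score <- rep(0, Gg)   # secondary key for floor ties
  names(entry) <- names(score) <- items
  tie_policy <- "grid entries distinct"

  first_idx <- apply(path$active, 1, function(a) which(a)[1])
  if (refine) {
    # groups sharing a first-entry grid point need refinement
    shared <- split(seq_len(Gg), first_idx)
    shared <- shared[vapply(shared, length, 0L) > 1L]
    floor_w <- floor_frac * path$lambda_max
    for (s in shared) {
      i <- first_idx[s[1]]
      if (is.na(i) || i == 1L) next   # active at lambda_max itself: leave tied
      lo <- path$lambda[i]; hi <- path$lambda[i - 1L]
      res <- bisect_entries(path, s, lo, hi, i - 1L, floor_w)
      entry[s] <- res$entry[as.character(s)]
      score[s] <- res$score[as.character(s)]
      if (res$refined) tie_policy <- "shared intervals bisected"
      if (res$floored) {
        tie_policy <- paste("bisection floor reached; ties ordered by",
                            "gradient-norm/weight at the tie point")
      }
    }
  }
  ranks <- rank_by_entry(entry, score)
  names(ranks) <- items
  structure(list(ranks = ranks, entry_lambda = entry,
                 tie_policy = tie_policy),
            class = "rank_vector")
}

# Recursive interval bisection for a set of groups all first seen active at
# the lower end `lo` of the grid interval (lo, hi]. Each group's entry value
# is refined upward to the highest midpoint at which it was observed active.
bisect_entries <- function(path, groups, lo, hi, init_col, floor_w) {
  entry <- stats::setNames(rep(lo, length(groups)), as.character(groups))
  score <- stats::setNames(rep(0, length(groups)), as.character(groups))
  refined <- FALSE; floored <- FALSE
  recurse <- function(gs, lo, hi, init_beta, init_b0) {
    if (length(gs) <= 1L) return(invisible())
    if (hi - lo < floor_w) {
      floored <<- TRUE
      sc <- group_grad_score(path, init_beta, init_b0)
      score[as.character(gs)] <<- sc[gs]
      return(invisible())
    }
    refined <<- TRUE
    mid <- sqrt(lo * hi)
    fit <- grplasso_path_cpp(path$x, path$y, as.integer(path$group) - 1L,
                             path$weights, mid, init_beta, init_b0,
                             path$tol, path$maxit)
    act <- active_groups_of(path, fit$beta[, 1])
    above <- gs[act[gs]]    # active at mid: entry in [mid, hi)
    below <- gs[!act[gs]]   # not yet active: entry in (lo, mid)
    if (length(above)) {
      entry[as.character(above)] <<- mid
      recurse(above, mid, hi, init_beta, init_b0)
    }
    recurse(below, lo, mid, fit$beta[, 1], fit$intercept[1])
    invisible()
  }
  recurse(groups, lo, hi, path$beta[, init_col], path$intercept[init_col])
  list(entry = entry, score = score, refined = refined, floored = floored)
}

# complete ranking: primary key entry lambda (desc), secondary tie score
# (desc); never-entered groups all tie at the worst averaged ranks
rank_by_entry <- function(entry, score) {
  key1 <- ifelse(is.na(entry), -Inf, entry)
  key2 <- ifelse(is.na(entry), 0, score)
  ord <- order(-key1, -key2)
  r <- numeric(length(entry))
  pos <- 1L
  i <- 1L
  while (i <= length(ord)) {
    j <- i
    while (j < length(ord) &&
           key1[ord[j + 1L]] == key1[ord[i]] &&
           key2[ord[j + 1L]] == key2[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(pos:(pos + (j - i)))
    pos <- pos + (j - i) + 1L
    i <- j + 1L
  }
  r
}

#' @export
print.rank_vector <- function(x, ...) {
  top <- names(sort(x$ranks))[seq_len(min(5, length(x$ranks)))]
  cat("Rank vector over", length(x$ranks), "items; top:",
      paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Rank a cohort's items by path entry order
#'
#' Convenience wrapper: build the standardized design, fit the path, return
#' the entry-order ranking. Interactions are never included: the path
#' ranker considers main effects only, by construction.
#'
#' @param cohort a [cohort()].
#' @param ... passed to [fit_path()].
#' @param refine,floor_frac passed to [entry_order()].
#' @return a `rank_vector` over the included items.
#' @export
rank_by_path <- function(cohort, ..., refine = TRUE, floor_frac = 1e-4) {
  d <- build_design(cohort, standardize = TRUE)
  entry_order(fit_path(d, ...), refine = refine, floor_frac = floor_frac)
}

#' Export a solution path as a long table
#'
#' One row per (lambda, group): the penalty value and the Euclidean norm of
#' the group's coefficients, suitable for plotting coefficient-trajectory
#' figures.
#'
#' @param path a [fit_path()] result.
#' @param file optional CSV path to write.
#' @return data.frame with columns `lambda`, `item`, `coef_norm`.
#' @export
export_path <- function(path, file = NULL) {
  stopifnot(inherits(path, "path_result"))
  Gg <- length(path$group_items)
  norms <- t(vapply(seq_len(Gg), function(g) {
    sqrt(colSums(path$beta[path$group == g, , drop = FALSE]^2))
  }, numeric(length(path$lambda))))
  out <- data.frame(
    lambda = rep(path$lambda, each = Gg),
    item = rep(path$group_items, times = length(path$lambda)),
    coef_norm = as.vector(norms)
  )
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
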