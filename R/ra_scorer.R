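#' Self-Reliance indicator
#'
#' A client is classified as "impaired" on the Self-Reliance indicator if
#' any of the following is present: modified independence or any impairment
#' in cognitive skills for daily decision making (`C1 = 1`), or supervision
#' or any physical help received in any of the assessed ADLs — bathing
#' (`C2A = 1`), personal hygiene (`C2B = 1`), dressing lower body
#' (`C2C = 1`), locomotion (`C2D = 1`). Otherwise "intact". The rule is
#' monotone: switching any input from 0 to 1 can only move a client toward
#' "impaired".
#'
#' @param record one-row data.frame or named list with binary fields `C1`,
#'   `C2A`, `C2B`, `C2C`, `C2D`; a multi-row data.frame is vectorized.
#' @return character vector, `"impaired"` or `"intact"`.
#' @export
self_reliance <- function(record) {
  fields <- c("C1", "C2A", "C2B", "C2C", "C2D")
  rec <- as.list(record)
  miss <- fields[vapply(fields, function(f) is.null(rec[[f]]) ||
                          anyNA(rec[[f]]), TRUE)]
  if (length(miss)) {
    stop("self_reliance requires field(s): ", paste(miss, collapse = ", "))
  }
  n <- length(rec[[fields[1]]])
  vals <- vapply(fields, function(f) as.numeric(as.character(rec[[f]])),
                 numeric(n))
  vals <- matrix(vals, nrow = n)
  if (!all(vals %in% c(0, 1))) stop("self_reliance fields must be 0/1")
  ifelse(rowSums(vals) > 0, "impaired", "intact")
}

#' Read a decision-tree configuration
#'
#' The tree is a nested YAML structure of binary decision nodes. Each node
#' is either a leaf (`score: k`, k in 1..5) or an internal node with a
#' `test` — either `{item, op, value}` with `op` one of `eq`, `ge`, `le`,
#' `in`, or `{predicate: self_reliance}` (true when impaired) — and `yes` /
#' `no` child nodes. Validation checks finiteness, leaf score range, and
#' test well-formedness.
#'
#' The packaged fixture `ra_tree_synthetic.yaml` is a best-effort synthetic
#' stand-in assembled from the published ingredients of the Contact
#' Assessment rehabilitation algorithm (ADL decline at the root, stair
#' climbing, IADL difficulty, the Self-Reliance indicator); it is NOT the
#' licensed algorithm, whose exact split sequence is only available in the
#' instrument manual.
#'
#' @param path YAML file; `default_ra_tree()` loads the packaged synthetic
#'   fixture.
#' @return An object of class `tree_config`.
#' @export
read_tree_config <- function(path) {
  tree <- yaml::read_yaml(path)
  validate_tree_node(tree, "root")
  structure(tree, class = "tree_config")
}

#' @rdname read_tree_config
#' @export
default_ra_tree <- function() {
  read_tree_config(system.file("extdata", "ra_tree_synthetic.yaml",
                               package = "rehabrank", mustWork = TRUE))
}

validate_tree_node <- function(node, where, depth = 0L) {
  if (depth > 64L) stop("tree too deep at ", where, "; is it acyclic?")
  if (!is.null(node$score)) {
    if (!node$score %in% 1:5) {
      stop("leaf at ", where, ": score must be in 1..5, got ", node$score)
    }
    return(invisible(TRUE))
  }
  t <- node$test
  if (is.null(t)) stop("node at ", where, " has neither score nor test")
  if (is.null(t$predicate)) {
    if (is.null(t$item) || is.null(t$op) || is.null(t$value)) {
      stop("test at ", where, " needs item, op and value")
    }
    if (!t$op %in% c("eq", "ge", "le", "in")) {
      stop("test at ", where, ": unknown op '", t$op, "'")
    }
  } else if (t$predicate != "self_reliance") {
    stop("test at ", where, ": unknown predicate '", t$predicate, "'")
  }
  if (is.null(node$yes) || is.null(node$no)) {
    stop("node at ", where, " must have yes and no children")
  }
  validate_tree_node(node$yes, paste0(where, "/yes"), depth + 1L)
  validate_tree_node(node$no, paste0(where, "/no"), depth + 1L)
  invisible(TRUE)
}

eval_test <- function(test, record, where) {
  if (!is.null(test$predicate)) {
    return(self_reliance(record) == "impaired")
  }
  v <- record[[test$item]]
  if (is.null(v) || anyNA(v)) {
    stop("record missing item '", test$item, "' referenced at ", where)
  }
  v <- as.numeric(as.character(v))
  switch(test$op,
         eq = v == as.numeric(test$value),
         ge = v >= as.numeric(test$value),
         le = v <= as.numeric(test$value),
         `in` = as.character(v) %in% as.character(test$value))
}

#' Score a client on the rehabilitation algorithm tree
#'
#' Deterministically traverses the decision tree for each record and
#' returns the leaf score: an integer from 1 to 5, higher scores marking
#' clients more likely to need rehabilitation services. Derived predicates
#' (the Self-Reliance indicator) are evaluated on demand. A record lacking
#' an item the tree references is an error naming the node — screening
#' scores are never fabricated from incomplete data.
#'
#' @param record one-row data.frame or named list of CA items; a multi-row
#'   data.frame is scored row by row.
#' @param tree a [read_tree_config()] object (default: the packaged
#'   synthetic tree).
#' @return integer vector of scores in 1..5.
#' @export
ra_score <- function(record, tree = default_ra_tree()) {
  stopifnot(inherits(tree, "tree_config"))
  record <- as.data.frame(record, optional = TRUE)
  vapply(seq_len(nrow(record)), function(i) {
    node <- tree
    where <- "root"
    while (is.null(node$score)) {
      yes <- eval_test(node$test, record[i, , drop = FALSE], where)
      node <- if (yes) node$yes else node$no
      where <- paste0(where, if (yes) "/yes" else "/no")
    }
    as.integer(node$score)
  }, integer(1))
}

#' Items referenced by a tree configuration
#' @param tree a [read_tree_config()] object.
#' @return character vector of CA item codes the tree (including the
#'   Self-Reliance predicate) reads.
#' @export
tree_items <- function(tree) {
  stopifnot(inherits(tree, "tree_config"))
  walk <- function(node) {
    if (!is.null(node$score)) return(character())
    own <- if (!is.null(node$test$predicate)) {
      c("C1", "C2A", "C2B", "C2C", "C2D")
    } else {
      node$test$item
    }
    c(own, walk(node$yes), walk(node$no))
  }
  unique(walk(tree))
}

#' Read an item crosswalk between the two instruments
#'
#' The crosswalk maps full-assessment (HC) item codes to their screening
#' (CA) equivalents where equivalents exist, with a human-readable concept
#' label per pair. The packaged fixture transcribes the published pairs:
#' ADL decline (HC `H3` / CA `D5`) and stair climbing (HC `H5` / CA `D4D`).
#'
#' @param path CSV with columns `hc_item`, `ca_item`, `concept`;
#'   `default_crosswalk()` loads the packaged fixture.
#' @return data.frame crosswalk.
#' @export
read_crosswalk <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("hc_item", "ca_item", "concept") %in% names(d)))
  d
}

#' @rdname read_crosswalk
#' @export
default_crosswalk <- function() {
  read_crosswalk(system.file("extdata", "hc_ca_crosswalk.csv",
                             package = "rehabrank", mustWork = TRUE))
}

#' Overlap between top-ranked HC items and the CA algorithm's items
#'
#' Compares the data-driven top-ranked full-assessment items with the
#' expert-chosen items of the screening algorithm, through a crosswalk of
#' item equivalences. Items with no crosswalk entry cannot overlap and are
#' reported on their own side.
#'
#' @param top_ranked character vector of top-ranked HC item codes, or a
#'   [rank_summary()] (combined with `top_threshold`).
#' @param ra_items character vector of CA item codes used by the
#'   rehabilitation algorithm (default: items of the packaged tree).
#' @param crosswalk a [read_crosswalk()] data.frame.
#' @param top_threshold mean-rank cutoff when `top_ranked` is a summary.
#' @return list with `overlap` (data.frame `hc_item`, `ca_item`,
#'   `concept`), `hc_only`, `ca_only`.
#' @export
items_overlap <- function(top_ranked, ra_items = tree_items(default_ra_tree()),
                          crosswalk = default_crosswalk(),
                          top_threshold = 20) {
  if (inherits(top_ranked, "rank_summary")) {
    top_ranked <- top_ranked$item[top_ranked$mean_rank <= top_threshold]
  }
  top_ranked <- as.character(top_ranked)
  hit <- crosswalk[crosswalk$hc_item %in% top_ranked &
                     crosswalk$ca_item %in% ra_items, , drop = FALSE]
  rownames(hit) <- NULL
  list(overlap = hit,
       hc_only = setdiff(top_ranked, hit$hc_item),
       ca_only = setdiff(ra_items, hit$ca_item))
}
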