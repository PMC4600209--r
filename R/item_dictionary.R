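#' Assessment item dictionary
#'
#' An item dictionary records, for each assessment item, its code, how it is
#' typed for modelling (categorical, ordinal treated as categorical, or
#' continuous), its admissible level set when not continuous, and whether it
#' is included as a ranked predictor. The set of included items defines
#' `d`, the number of predictors that every ranker must place in a complete
#' ranking.
#'
#' @param code character vector of unique item codes (e.g. `"K5"`, `"B2A"`).
#' @param kind character vector, one of `"categorical"`, `"ordinal"`
#'   (ordinal-as-categorical) or `"continuous"` per item.
#' @param levels list of level vectors, one per item; ignored (may be `NULL`)
#'   for continuous items. Order matters: the first level is the reference
#'   level under dummy coding.
#' @param include logical vector; `TRUE` marks the item as a ranked predictor.
#'
#' @return An object of class `item_dictionary`.
#' @examples
#' dict <- item_dictionary(
#'   code    = c("K5", "B2A"),
#'   kind    = c("continuous", "ordinal"),
#'   levels  = list(NULL, 0:5),
#'   include = c(TRUE, TRUE)
#' )
#' n_included(dict)
#' @export
item_dictionary <- function(code, kind, levels = NULL, include = TRUE) {
  code <- as.character(code)
  kind <- normalize_kind(kind, length(code))
  if (is.null(levels)) levels <- vector("list", length(code))
  include <- rep_len(as.logical(include), length(code))
  if (anyDuplicated(code)) {
    stop("duplicate item codes: ",
         paste(unique(code[duplicated(code)]), collapse = ", "))
  }
  stopifnot(length(kind) == length(code), length(levels) == length(code))
  for (i in seq_along(code)) {
    if (kind[i] != "continuous") {
      lv <- levels[[i]]
      if (is.null(lv) || length(lv) < 2L) {
        stop("item ", code[i], ": non-continuous items need >= 2 levels")
      }
      levels[[i]] <- as.character(lv)
    } else {
      levels[i] <- list(NULL)
    }
  }
  structure(
    list(code = code, kind = kind, levels = levels, include = include),
    class = "item_dictionary"
  )
}

normalize_kind <- function(kind, n) {
  kind <- rep_len(as.character(kind), n)
  kind[kind %in% c("ordinal-as-categorical", "ordinal")] <- "ordinal"
  bad <- setdiff(unique(kind), c("categorical", "ordinal", "continuous"))
  if (length(bad)) stop("unknown item kind(s): ", paste(bad, collapse = ", "))
  kind
}

#' @export
print.item_dictionary <- function(x, ...) {
  cat("Item dictionary:", length(x$code), "items (",
      sum(x$include), "included as predictors )\n")
  k <- table(x$kind)
  cat(" ", paste(names(k), k, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Number of included (ranked) predictors
#' @param dictionary an [item_dictionary()].
#' @return integer, the number of items with `include = TRUE`.
#' @export
n_included <- function(dictionary) {
  stopifnot(inherits(dictionary, "item_dictionary"))
  sum(dictionary$include)
}

#' Codes of included predictors
#' @inheritParams n_included
#' @return character vector of item codes with `include = TRUE`.
#' @export
included_items <- function(dictionary) {
  stopifnot(inherits(dictionary, "item_dictionary"))
  dictionary$code[dictionary$include]
}

dict_entry <- function(dictionary, code) {
  i <- match(code, dictionary$code)
  if (is.na(i)) stop("item ", code, " not in dictionary")
  list(code = code, kind = dictionary$kind[i],
       levels = dictionary$levels[[i]], include = dictionary$include[i])
}

#' Read / write an item dictionary as YAML
#'
#' The on-disk format is a YAML list of entries with fields `code`, `kind`,
#' `levels` (absent for continuous items) and `include`.
#'
#' @param path file path.
#' @return `read_dictionary()` returns an [item_dictionary()];
#'   `write_dictionary()` returns `path` invisibly.
#' @export
read_dictionary <- function(path) {
  raw <- yaml::read_yaml(path)
  item_dictionary(
    code    = vapply(raw, function(e) as.character(e$code), ""),
    kind    = vapply(raw, function(e) as.character(e$kind), ""),
    levels  = lapply(raw, function(e) e$levels),
    include = vapply(raw, function(e) isTRUE(e$include) || is.null(e$include), TRUE)
  )
}

#' @rdname read_dictionary
#' @param dictionary an [item_dictionary()].
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "item_dictionary"))
  entries <- lapply(seq_along(dictionary$code), function(i) {
    e <- list(code = dictionary$code[i], kind = dictionary$kind[i])
    if (dictionary$kind[i] != "continuous") e$levels <- dictionary$levels[[i]]
    e$include <- dictionary$include[i]
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
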