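#' Client cohort
#'
#' A cohort is a validated client-by-item table together with its item
#' dictionary and the binary outcome (1 = rehabilitation received within 6
#' months of assessment). Validation enforces that every non-continuous
#' value belongs to the item's declared level set, that the outcome is
#' strictly 0/1, that client ids are unique and that no cell is missing
#' (missingness is an input error, never silently imputed).
#'
#' @param data data.frame with one row per client, a `client_id` column, one
#'   column per dictionary item, and the outcome column.
#' @param dictionary an [item_dictionary()].
#' @param outcome_col name of the binary outcome column (default `"rehab6m"`).
#' @return An object of class `cohort` with elements `data`, `dictionary`,
#'   `outcome_col`.
#' @export
cohort <- function(data, dictionary, outcome_col = "rehab6m") {
  stopifnot(is.data.frame(data), inherits(dictionary, "item_dictionary"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop("cohort must contain at least one record")
  if (!outcome_col %in% names(data)) {
    stop("missing outcome column '", outcome_col, "'")
  }
  if (!"client_id" %in% names(data)) {
    data$client_id <- sprintf("c%06d", seq_len(nrow(data)))
  }
  data$client_id <- as.character(data$client_id)
  if (anyDuplicated(data$client_id)) {
    stop("duplicate client_id: ",
         paste(head(unique(data$client_id[duplicated(data$client_id)]), 3),
               collapse = ", "))
  }
  y <- data[[outcome_col]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome column '", outcome_col, "' must be 0/1 with no missing values")
  }
  data[[outcome_col]] <- as.integer(y)
  missing_items <- setdiff(dictionary$code, names(data))
  if (length(missing_items)) {
    stop("cohort table lacks dictionary item(s): ",
         paste(head(missing_items, 5), collapse = ", "))
  }
  for (i in seq_along(dictionary$code)) {
    code <- dictionary$code[i]
    v <- data[[code]]
    if (anyNA(v)) {
      stop("item ", code, ": missing value at row ", which(is.na(v))[1])
    }
    if (dictionary$kind[i] == "continuous") {
      if (!is.numeric(v)) {
        vv <- suppressWarnings(as.numeric(v))
        if (anyNA(vv)) stop("item ", code, ": non-numeric value for continuous item")
        data[[code]] <- vv
      }
    } else {
      lv <- dictionary$levels[[i]]
      chr <- as.character(v)
      bad <- which(!chr %in% lv)
      if (length(bad)) {
        stop("item ", code, ": value '", chr[bad[1]], "' at row ", bad[1],
             " outside declared levels {", paste(lv, collapse = ","), "}")
      }
      data[[code]] <- chr
    }
  }
  structure(
    list(data = data, dictionary = dictionary, outcome_col = outcome_col),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$data), "clients,",
      length(x$dictionary$code), "items (",
      n_included(x$dictionary), "ranked );",
      "outcome prevalence", round(mean(outcomes(x)), 3), "\n")
  invisible(x)
}

#' Cohort accessors
#' @param x a [cohort()].
#' @return `n_clients()`: integer; `outcomes()`: integer 0/1 vector;
#'   `item_values()`: the named item column.
#' @export
n_clients <- function(x) {
  stopifnot(inherits(x, "cohort"))
  nrow(x$data)
}

#' @rdname n_clients
#' @export
outcomes <- function(x) {
  stopifnot(inherits(x, "cohort"))
  x$data[[x$outcome_col]]
}

#' @rdname n_clients
#' @param code item code.
#' @export
item_values <- function(x, code) {
  stopifnot(inherits(x, "cohort"))
  if (!code %in% names(x$data)) stop("item ", code, " not in cohort")
  x$data[[code]]
}

#' Subset a cohort by row index
#' @param x a [cohort()].
#' @param idx integer row indices.
#' @param dedup_ids relabel `client_id` when indices repeat (sampling with
#'   replacement), so the result still validates.
#' @return a [cohort()].
#' @export
subset_cohort <- function(x, idx, dedup_ids = TRUE) {
  stopifnot(inherits(x, "cohort"))
  d <- x$data[idx, , drop = FALSE]
  if (dedup_ids && anyDuplicated(d$client_id)) {
    d$client_id <- make.unique(d$client_id, sep = "#")
  }
  rownames(d) <- NULL
  cohort(d, x$dictionary, x$outcome_col)
}

#' Read / write a cohort as CSV
#'
#' The CSV dialect is UTF-8 with a header row of `client_id`, the item
#' codes, and the outcome column; one client per line. Reading validates
#' against the dictionary and preserves row order; writing then re-reading
#' reproduces the cohort exactly.
#'
#' @param path CSV file path.
#' @param dictionary an [item_dictionary()].
#' @param outcome_col outcome column name (default `"rehab6m"`).
#' @return `read_cohort()`: a [cohort()]; `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path, dictionary, outcome_col = "rehab6m") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       colClasses = "character")
  if (!outcome_col %in% names(d)) {
    stop("missing outcome column '", outcome_col, "' in ", path)
  }
  d[[outcome_col]] <- as.integer(d[[outcome_col]])
  for (i in seq_along(dictionary$code)) {
    if (dictionary$kind[i] == "continuous") {
      code <- dictionary$code[i]
      if (code %in% names(d)) d[[code]] <- as.numeric(d[[code]])
    }
  }
  cohort(d, dictionary, outcome_col)
}

#' @rdname read_cohort
#' @param x a [cohort()].
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
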