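AGE_BINS <- c("<50", "50-64", "65-74", "75-84", ">84")

#' Target joint distribution over the five matching variables
#'
#' A stratum table gives, for each of the 80 cells formed by five age bands
#' crossed with four binary flags (gender, ADL impairment, cognitive
#' impairment, falls), the percentage of the target screening population in
#' that cell. The packaged fixture `ca_stratum_table.csv` transcribes the
#' published distribution of the Contact Assessment population.
#'
#' @param cells data.frame with columns `age_bin`, `gender`, `adl`,
#'   `cognition`, `falls`, `pct`.
#' @param tol allowed deviation of the percentage total from 100
#'   (default 0.05, accommodating two-decimal rounding of printed cells).
#' @return An object of class `stratum_table`: the validated data.frame with
#'   a `key` column added.
#' @export
stratum_table <- function(cells, tol = 0.05) {
  req <- c("age_bin", "gender", "adl", "cognition", "falls", "pct")
  stopifnot(is.data.frame(cells), all(req %in% names(cells)))
  cells <- as.data.frame(cells)[req]
  cells$age_bin <- as.character(cells$age_bin)
  bad <- setdiff(unique(cells$age_bin), AGE_BINS)
  if (length(bad)) stop("unknown age bin(s): ", paste(bad, collapse = ", "))
  for (v in c("gender", "adl", "cognition", "falls")) {
    cells[[v]] <- as.integer(cells[[v]])
    if (!all(cells[[v]] %in% 0:1)) stop("column ", v, " must be 0/1")
  }
  cells$pct <- as.numeric(cells$pct)
  if (any(cells$pct < 0)) stop("negative cell percentage")
  cells$key <- make_stratum_key(cells$age_bin, cells$gender, cells$adl,
                                cells$cognition, cells$falls)
  if (anyDuplicated(cells$key)) stop("duplicate stratum cells")
  total <- sum(cells$pct)
  if (abs(total - 100) > tol) {
    stop(sprintf("stratum percentages sum to %.4f, outside 100 +/- %.2f",
                 total, tol))
  }
  rownames(cells) <- NULL
  structure(cells, class = c("stratum_table", "data.frame"))
}

#' @rdname stratum_table
#' @param path CSV file path; `default_stratum_table()` loads the packaged
#'   population fixture.
#' @export
read_stratum_table <- function(path, tol = 0.05) {
  stratum_table(utils::read.csv(path, stringsAsFactors = FALSE), tol = tol)
}

#' @rdname stratum_table
#' @export
default_stratum_table <- function() {
  read_stratum_table(system.file("extdata", "ca_stratum_table.csv",
                                 package = "rehabrank", mustWork = TRUE))
}

make_stratum_key <- function(age_bin, gender, adl, cognition, falls) {
  paste(age_bin, gender, adl, cognition, falls, sep = "|")
}

#' Bin an age in years into the five matching age bands
#'
#' Bands are closed on the left: `[0,50)`, `[50,65)`, `[65,75)`, `[75,85)`,
#' `[85, Inf)`, labelled `<50`, `50-64`, `65-74`, `75-84`, `>84`.
#'
#' @param age numeric vector of ages in years.
#' @return character vector of bin labels.
#' @export
age_bin <- function(age) {
  age <- as.numeric(age)
  if (anyNA(age) || any(age < 0)) stop("age must be non-negative and non-missing")
  AGE_BINS[findInterval(age, c(0, 50, 65, 75, 85))]
}

#' Derive stratum keys for cohort records
#'
#' Applies the matching-variable definitions: gender = 1 if male;
#' ADL = 1 if any of the ten ADL performance items (H2A-H2J analogues) is
#' >= 1; cognition = 1 if cognitive skills for daily decision making (B2A
#' analogue) is >= 1; falls = 1 if falls frequency (K5 analogue) is >= 1;
#' age binned by [age_bin()].
#'
#' @param cohort a [cohort()] whose table carries the raw matching items.
#' @param age_item,gender_item,adl_items,cognition_item,falls_item column
#'   names of the raw matching items (defaults follow the instrument codes).
#' @return character vector of stratum keys, one per record.
#' @export
stratum_keys <- function(cohort,
                         age_item = "AGE", gender_item = "GENDER",
                         adl_items = paste0("H2", LETTERS[1:10]),
                         cognition_item = "B2A", falls_item = "K5") {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  need <- c(age_item, gender_item, adl_items, cognition_item, falls_item)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("cohort lacks raw matching item(s): ", paste(miss, collapse = ", "))
  }
  num <- function(v) as.numeric(as.character(v))
  adl_mat <- vapply(adl_items, function(cc) num(d[[cc]]) >= 1,
                    logical(nrow(d)))
  make_stratum_key(
    age_bin(num(d[[age_item]])),
    as.integer(num(d[[gender_item]]) == 1),
    as.integer(rowSums(adl_mat) > 0),
    as.integer(num(d[[cognition_item]]) >= 1),
    as.integer(num(d[[falls_item]]) >= 1)
  )
}

#' Stratum key for a single record
#' @param record one-row data.frame or named list with the raw matching items.
#' @param age age in years.
#' @inheritParams stratum_keys
#' @return a single stratum key string `"agebin|g|a|c|f"`.
#' @export
stratum_key <- function(record, age,
                        gender_item = "GENDER",
                        adl_items = paste0("H2", LETTERS[1:10]),
                        cognition_item = "B2A", falls_item = "K5") {
  record <- as.list(record)
  num <- function(cc) {
    if (is.null(record[[cc]])) stop("record lacks matching item ", cc)
    as.numeric(as.character(record[[cc]]))
  }
  make_stratum_key(
    age_bin(age),
    as.integer(num(gender_item) == 1),
    as.integer(any(vapply(adl_items, num, 0) >= 1)),
    as.integer(num(cognition_item) >= 1),
    as.integer(num(falls_item) >= 1)
  )
}

#' Exact per-stratum counts for a target sample size
#'
#' Converts the percentage cells of a stratum table into non-negative
#' integer counts summing exactly to `n`, by largest-remainder (Hamilton)
#' apportionment: every cell gets the floor of its exact quota
#' `n * pct / 100`, and the remaining units are assigned one each to the
#' cells with the largest fractional remainders. Integer-exact quotas are
#' reproduced exactly (a 0.06 % cell at n = 10,000 yields 6).
#'
#' @param table a [stratum_table()].
#' @param n target sample size (positive integer).
#' @return named integer vector of counts, one per stratum key, summing to `n`.
#' @export
allocate_counts <- function(table, n) {
  stopifnot(inherits(table, "stratum_table"))
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer")
  quota <- n * table$pct / sum(table$pct)
  base <- floor(quota + 1e-9)          # guard: integer-exact quotas stay exact
  short <- n - sum(base)
  counts <- base
  if (short > 0) {
    rem <- quota - base
    extra <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  stats::setNames(as.integer(counts), table$key)
}

#' Draw a frequency-matched sample from a source cohort
#'
#' Draws, for each stratum, exactly `allocate_counts(table, n)` records
#' uniformly without replacement from the source records falling in that
#' stratum, so that the joint distribution of the five matching variables in
#' the sample equals the target table's distribution. If a stratum holds
#' fewer source records than required, the draw errors naming the stratum
#' and deficit, unless `allow_replacement = TRUE`, in which case the
#' shortfall is filled by resampling with replacement and a warning is
#' issued.
#'
#' @param source a [cohort()] carrying the raw matching items.
#' @param table a [stratum_table()].
#' @param n target sample size.
#' @param seed integer seed; fixed seed gives a bit-identical sample.
#' @param allow_replacement allow within-stratum resampling on shortfall.
#' @param keys optional precomputed `stratum_keys(source)` (saves recompute
#'   across repeated draws).
#' @return a [cohort()] of exactly `n` records.
#' @export
draw_matched_sample <- function(source, table, n, seed,
                                allow_replacement = FALSE, keys = NULL) {
  stopifnot(inherits(source, "cohort"), inherits(table, "stratum_table"))
  if (is.null(keys)) keys <- stratum_keys(source)
  counts <- allocate_counts(table, n)
  counts <- counts[counts > 0L]
  idx_by_key <- split(seq_len(n_clients(source)), keys)
  picked <- withr::with_seed(as.integer(seed), {
    unlist(lapply(names(counts), function(k) {
      pool <- idx_by_key[[k]]
      need <- counts[[k]]
      avail <- length(pool)
      if (avail >= need) {
        pool[sample.int(avail, need)]
      } else if (allow_replacement) {
        warning(sprintf(
          "stratum %s short by %d record(s); sampling with replacement",
          k, need - avail))
        if (avail == 0L) stop("stratum ", k, " empty in source; cannot fill")
        c(pool, pool[sample.int(avail, need - avail, replace = TRUE)])
      } else {
        stop(sprintf("stratum %s requires %d record(s) but source has %d",
                     k, need, avail))
      }
    }), use.names = FALSE)
  })
  subset_cohort(source, picked)
}
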