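#' Number of two-way interaction terms among d main effects
#'
#' `choose(d, 2)` — the combinatorial count that makes exhaustive
#' interaction screening along a solution path impractical for a
#' several-hundred-item battery (239 main effects already imply 28,441
#' pairwise terms), and motivates using an interaction-sensitive forest as
#' the complementary ranker.
#'
#' @param d number of main effects.
#' @return integer count of unordered pairs.
#' @export
n_pairwise_interactions <- function(d) {
  d <- as.integer(d)
  stopifnot(d >= 0)
  choose(d, 2)
}

#' Run configuration for the full pipeline
#'
#' A run config fully determines a pipeline run: either a generator spec
#' (synthetic source) or a cohort CSV + dictionary to load, the target
#' stratum table, ensemble settings, the master seed and the output
#' directory. A run is reproducible from its config alone; every emitted
#' artifact records the config hash.
#'
#' @param out_dir output directory (created if absent).
#' @param K ensemble samples per ranker.
#' @param n matched-sample size.
#' @param master_seed integer master seed.
#' @param generator a [generator_spec()], or `NULL` when loading a cohort.
#' @param cohort_csv,dictionary_yaml paths to a cohort and its dictionary,
#'   used when `generator` is `NULL`.
#' @param stratum_csv path to a stratum table CSV (`NULL` = packaged
#'   population fixture).
#' @param rankers character subset of `c("path", "forest")`.
#' @param top_threshold mean-rank cutoff for the comparison report.
#' @param path_args,forest_args extra ranker arguments.
#' @param write_plot also write a mean-rank scatter (PDF).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, K = 10L, n = 2000L, master_seed = 1L,
                       generator = NULL, cohort_csv = NULL,
                       dictionary_yaml = NULL, stratum_csv = NULL,
                       rankers = c("path", "forest"), top_threshold = 20,
                       path_args = list(), forest_args = list(),
                       write_plot = FALSE) {
  K <- as.integer(K); n <- as.integer(n)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  rankers <- match.arg(rankers, c("path", "forest"), several.ok = TRUE)
  if (is.null(generator) && (is.null(cohort_csv) || is.null(dictionary_yaml))) {
    stop("provide either a generator spec or cohort_csv + dictionary_yaml")
  }
  structure(
    list(out_dir = out_dir, K = K, n = n,
         master_seed = as.integer(master_seed),
         generator = generator, cohort_csv = cohort_csv,
         dictionary_yaml = dictionary_yaml, stratum_csv = stratum_csv,
         rankers = rankers, top_threshold = top_threshold,
         path_args = path_args, forest_args = forest_args,
         write_plot = isTRUE(write_plot)),
    class = "run_config"
  )
}

config_hash <- function(config) {
  ser <- config
  ser$out_dir <- NULL   # hash the analysis, not where it lands
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full ranking pipeline
#'
#' Executes the two-step analysis end to end: generate (or load) the source
#' cohort; draw K frequency-matched samples and rank items with each
#' configured ranker; aggregate into mean ranks; compare the rankers; fit
#' effect directions for the items top-ranked by all rankers; report the
#' overlap with the screening algorithm's expert-chosen items. All outputs
#' are written to the config's output directory as delimited tables plus a
#' provenance record (config hash, seeds, package version); nothing is
#' written if a stage fails.
#'
#' @param config a [run_config()].
#' @param progress print stage/sample progress.
#' @return invisibly, a list with the in-memory results: `summaries` (per
#'   ranker), `comparison` (when both rankers ran), `directions`,
#'   `overlap`, `provenance`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  table <- stage("stratum-table", {
    if (is.null(config$stratum_csv)) default_stratum_table()
    else read_stratum_table(config$stratum_csv)
  })
  source <- stage("source-cohort", {
    if (!is.null(config$generator)) {
      generate_cohort(config$generator, table)
    } else {
      read_cohort(config$cohort_csv, read_dictionary(config$dictionary_yaml))
    }
  })
  ens <- list()
  for (rk in config$rankers) {
    if (progress) message("ranking with ", rk, " ...")
    ens[[rk]] <- stage(paste0("ensemble-", rk), {
      ensemble_ranks(source, table, ranker = rk, K = config$K, n = config$n,
                     master_seed = config$master_seed,
                     ranker_args = if (rk == "path") config$path_args
                                   else config$forest_args,
                     progress = progress)
    })
  }
  comparison <- NULL
  if (length(ens) == 2L) {
    comparison <- stage("compare", {
      compare_rankings(ens$path$summary, ens$forest$summary,
                       top_threshold = config$top_threshold)
    })
  }
  top_items <- if (!is.null(comparison)) comparison$both_top
               else head(ens[[1]]$summary$item, config$top_threshold)
  directions <- if (length(top_items)) {
    stage("effect-direction", effect_direction(source, top_items))
  } else NULL
  overlap <- stage("ra-overlap", items_overlap(top_items))
  provenance <- list(
    config_hash = hash,
    master_seed = config$master_seed,
    K = config$K, n = config$n,
    sample_seeds = lapply(ens, function(e) attr(e$rank_matrix, "sample_seeds")),
    package_version = as.character(utils::packageVersion("rehabrank")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )

  # all computation succeeded; only now touch the output directory
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tag <- function(f) file.path(out, f)
  for (rk in names(ens)) {
    rs <- ens[[rk]]$summary
    rs$config_hash <- hash
    utils::write.csv(rs, tag(sprintf("rank_summary_%s.csv", rk)),
                     row.names = FALSE)
    rm <- data.frame(item = rownames(ens[[rk]]$rank_matrix),
                     ens[[rk]]$rank_matrix, check.names = FALSE)
    utils::write.csv(rm, tag(sprintf("rank_matrix_%s.csv", rk)),
                     row.names = FALSE)
  }
  if (!is.null(comparison)) {
    pc <- comparison$paired
    pc$config_hash <- hash
    utils::write.csv(pc, tag("rank_comparison_paired.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(list(
      config_hash = hash, spearman = comparison$spearman,
      top_threshold = comparison$top_threshold,
      both_top = comparison$both_top, only_path = comparison$only_a,
      only_forest = comparison$only_b), auto_unbox = TRUE, pretty = TRUE,
      digits = NA), tag("rank_comparison.json"))
    if (config$write_plot) {
      grDevices::pdf(tag("rank_comparison.pdf"), width = 6, height = 6)
      plot_rank_comparison(comparison,
                           main = paste0("config ", substr(hash, 1, 8)))
      grDevices::dev.off()
    }
  }
  if (!is.null(directions)) {
    directions$config_hash <- hash
    utils::write.csv(directions, tag("effect_directions.csv"),
                     row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(c(list(overlap = overlap), provenance),
                              auto_unbox = TRUE, pretty = TRUE, digits = NA,
                              force = TRUE),
             tag("provenance.json"))
  invisible(list(summaries = lapply(ens, `[[`, "summary"),
                 comparison = comparison, directions = directions,
                 overlap = overlap, provenance = provenance))
}
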