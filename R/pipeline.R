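#' Pipeline run configuration
#'
#' Collects the paths, thresholds and seed for a full pipeline run. When
#' `corpus` is `NULL` the synthetic generator supplies the corpus and
#' attribute table (the `synth` config defaults to [synth_config()] with
#' the run seed). Taxonomy, lexicon and pattern files default to the
#' bundled demonstration resources.
#'
#' @param out_dir Output directory for the report bundle (created if
#'   needed).
#' @param corpus Optional JSONL corpus path; `NULL` enables the synth
#'   stage.
#' @param attributes Optional attribute TSV path (required with `corpus`
#'   if age/gender analyses are wanted).
#' @param taxonomy Taxonomy CSV path; default bundled demo taxonomy.
#' @param lexicon Lexicon path (`.yaml` native format or `.dic` dialect);
#'   default bundled open lexicon.
#' @param patterns Diagnosis-pattern YAML path; default
#'   [default_patterns()].
#' @param min_wc Word-count reliability filter (default 25).
#' @param rq2_min Per-context post threshold for the paired comparison
#'   (default 4).
#' @param rq3_min Non-MH post threshold for the outcome-0 group (default
#'   8).
#' @param bonferroni_m Number of corrected comparisons (default 5).
#' @param seed Run seed; drives the synth stage and the gender-balanced
#'   subsample.
#' @param synth Optional `synth_config` for the synth stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("synth", "mine", "classify", "score", "aggregate", "analyze",
#'   "report")`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       corpus = NULL,
                       attributes = NULL,
                       taxonomy = NULL,
                       lexicon = NULL,
                       patterns = NULL,
                       min_wc = 25L,
                       rq2_min = 4L,
                       rq3_min = 8L,
                       bonferroni_m = 5L,
                       seed = 1L,
                       synth = NULL,
                       stages = c("synth", "mine", "classify", "score",
                                  "aggregate", "analyze", "report")) {
  if (any(c(min_wc, rq2_min, rq3_min, bonferroni_m) <= 0)) {
    stop("thresholds must be positive")
  }
  structure(list(out_dir = out_dir, corpus = corpus, attributes = attributes,
                 taxonomy = taxonomy, lexicon = lexicon, patterns = patterns,
                 min_wc = as.integer(min_wc), rq2_min = as.integer(rq2_min),
                 rq3_min = as.integer(rq3_min),
                 bonferroni_m = as.integer(bonferroni_m),
                 seed = as.integer(seed), synth = synth,
                 stages = stages),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

.log_stage <- function(...) message("[peerforum] ", ...)

.write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates synth (or corpus loading), cohort mining, context
#' classification, scoring, aggregation and the three analyses, then writes
#' a report bundle: `rq1_partition.json`/`.tsv`, `rq2_table.tsv`,
#' `rq3_coefficients.tsv`, `rq3_modelfit.json`, `user_records.tsv`, and a
#' `manifest.json` listing every output file with its MD5 hash alongside
#' the config hash and seed. Reruns with an identical config and seed
#' reproduce the bundle byte for byte. Per-stage record counts are logged
#' via `message()`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results: `posts`,
#'   `records`, `rq1`, `rq2`, `rq3` (fits + LRT), `rq3_balanced`,
#'   `cohort`, `manifest`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  sim <- NULL
  if (is.null(config$corpus) && "synth" %in% stages) {
    sim <- .stage("synth", {
      scfg <- if (is.null(config$synth)) synth_config(seed = config$seed) else config$synth
      s <- synth_generate(scfg)
      plant_contamination(s)
    })
    posts <- sim$posts
    attrs <- sim$attributes
    if ("report" %in% stages) {
      files <- c(files,
                 write_posts(posts, file.path(config$out_dir, "corpus.jsonl")),
                 write_attributes(attrs, file.path(config$out_dir, "attributes.tsv")))
    }
    .log_stage("synth: ", nrow(posts), " posts, ",
               length(unique(posts$author)), " users")
  } else {
    posts <- .stage("read", read_posts(config$corpus))
    attrs <- if (!is.null(config$attributes)) {
      .stage("read", read_attributes(config$attributes))
    } else NULL
    .log_stage("read: ", nrow(posts), " posts")
  }

  patterns <- .stage("mine", {
    if (is.null(config$patterns)) default_patterns() else read_patterns_yaml(config$patterns)
  })
  cohort <- .stage("mine", build_cohort(posts, patterns))
  .log_stage("mine: ", cohort$summary$n_included, " of ",
             cohort$summary$n_users, " users included")

  tax <- .stage("classify", {
    load_taxonomy(if (is.null(config$taxonomy)) example_taxonomy_path() else config$taxonomy)
  })
  posts$context <- .stage("classify", classify_context(posts$subreddit, tax))
  .log_stage("classify: ", sum(posts$context == "MH"), " MH posts, ",
             sum(posts$context == "nonMH"), " non-MH posts")

  lex <- .stage("score", {
    if (is.null(config$lexicon)) {
      default_lexicon()
    } else if (grepl("\\.dic$", config$lexicon)) {
      read_dic(config$lexicon)
    } else {
      read_lexicon_yaml(config$lexicon)
    }
  })
  scored <- .stage("score", score_posts(posts, lex))
  .log_stage("score: ", sum(scored$wc >= config$min_wc), " of ", nrow(scored),
             " posts pass the ", config$min_wc, "-word filter")

  records <- .stage("aggregate",
                    build_user_records(cohort$authors, scored, attrs,
                                       min_wc = config$min_wc))
  .log_stage("aggregate: ", nrow(records), " user records")
  if ("report" %in% stages) {
    files <- c(files, .write_tsv(records, file.path(config$out_dir, "user_records.tsv")))
  }

  result <- list(posts = posts, sim = sim, cohort = cohort, records = records,
                 config = config, files = files)
  if (!"analyze" %in% stages) return(invisible(result))

  rq1 <- .stage("analyze", partition_rq1(records, active_min = config$rq2_min,
                                         only_min = config$rq3_min))
  rq2_sample <- .stage("analyze", select_rq2(records, min_posts = config$rq2_min))
  rq2 <- .stage("analyze", rq2_table(rq2_sample, m = config$bonferroni_m))
  rq3_sample <- .stage("analyze", select_rq3(records, rq2_min = config$rq2_min,
                                             rq3_min = config$rq3_min))
  rq3 <- .stage("analyze", rq3_regression(rq3_sample))
  rq3_bal <- .stage("analyze", gender_balanced_rerun(rq3_sample,
                                                     seed = config$seed + 2L))
  .log_stage("analyze: paired sample n = ", nrow(rq2_sample),
             ", regression sample n = ", nrow(rq3_sample),
             ", balanced n = ", rq3_bal$n)

  result <- c(result, list(rq1 = rq1, rq2 = rq2, rq2_sample = rq2_sample,
                           rq3_sample = rq3_sample, rq3 = rq3,
                           rq3_balanced = rq3_bal))

  if ("report" %in% stages) {
    out <- config$out_dir
    files <- c(files,
      .write_json(list(n_users = rq1$n_users,
                       proportions = as.list(rq1$proportions),
                       strata = as.list(rq1$strata),
                       low_activity = as.list(rq1$low_activity)),
                  file.path(out, "rq1_partition.json")),
      .write_tsv(rq1$table, file.path(out, "rq1_partition.tsv")),
      .write_tsv(rq2, file.path(out, "rq2_table.tsv")),
      .write_tsv(rq3$full_fit$coefficients,
                 file.path(out, "rq3_coefficients.tsv")),
      .write_json(list(
        controls = rq3$controls_fit$fit[c("ll", "k", "n", "aic", "bic", "df_resid")],
        full = rq3$full_fit$fit[c("ll", "k", "n", "aic", "bic", "df_resid")],
        pseudo_r2 = rq3$full_fit$fit$pseudo_r2,
        lrt = rq3$lrt,
        gender_balanced_n = rq3_bal$n),
        file.path(out, "rq3_modelfit.json")))
    manifest <- list(
      package = "peerforum",
      seed = config$seed,
      config_hash = .config_hash(config),
      files = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f)))
    )
    manifest_path <- .write_json(manifest, file.path(out, "manifest.json"))
    result$manifest <- manifest
    result$files <- c(files, manifest_path)
  }
  invisible(result)
}

.config_hash <- function(config) {
  flat <- config
  flat$out_dir <- NULL # hash the scientific config, not the output location
  flat$synth <- if (is.null(config$synth)) NULL else unclass(config$synth)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(flat), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
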