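#' Filter calls by behavioural context
#'
#' Removes calls whose context is on the exclusion list (by default `"fed"`,
#' because food passing the esophagus can distort call acoustics) and
#' records per-context counts before and after in a `filter_log` attribute.
#'
#' @param calls Data frame with a `context` column.
#' @param exclude_contexts Character vector of context labels to drop; every
#'   label must exist among the known context labels or in the data.
#' @return Filtered data frame with attribute `filter_log` (data frame:
#'   `context`, `n_before`, `n_after`).
#' @export
apply_filters <- function(calls, exclude_contexts = "fed") {
  stopifnot("context" %in% names(calls))
  known <- union(context_labels(), unique(calls$context))
  bad <- setdiff(exclude_contexts, known)
  if (length(bad) > 0)
    stop("unknown context label(s) in exclusion list: ",
         paste(bad, collapse = ", "))
  keep <- !(calls$context %in% exclude_contexts)
  out <- calls[keep, , drop = FALSE]
  ctxs <- sort(unique(calls$context))
  log <- data.frame(
    context = ctxs,
    n_before = as.integer(table(factor(calls$context, ctxs))),
    n_after = as.integer(table(factor(out$context, ctxs))),
    stringsAsFactors = FALSE)
  message(sprintf("filtered %d of %d calls (excluded: %s)",
                  sum(!keep), nrow(calls),
                  paste(exclude_contexts, collapse = ", ")))
  attr(out, "filter_log") <- log
  out
}

#' Check that per-stratum call counts sum to the pooled total
#'
#' Conservation audit used by the pipeline: the per-age-class (or any
#' partition's) call counts must add up to the pooled count.
#'
#' @param counts Numeric vector of per-stratum counts.
#' @param total Pooled count.
#' @return `TRUE` invisibly; stops if the partition leaks calls.
#' @export
check_count_conservation <- function(counts, total) {
  if (sum(counts) != total)
    stop(sprintf("partition counts sum to %d, expected %d",
                 sum(counts), total))
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' @param input_mode `"synthetic"` (generate data), `"features"` (read a
#'   feature CSV) or `"audio"` (WAV directory + annotations).
#' @param features_path CSV path for `input_mode = "features"`.
#' @param wav_dir,annotations_path Inputs for `input_mode = "audio"`.
#' @param exclude_contexts Contexts removed before analysis (default
#'   `"fed"`).
#' @param generator A [generator_config()] (synthetic mode).
#' @param pdfa A [pdfa_config()].
#' @param pic_contexts Contexts given separate PIC tables.
#' @param dissim_standardize,dissim_score Passed to
#'   [dyadic_dissimilarity()].
#' @param out_dir Output directory.
#' @param seed Master seed; sub-stage seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "features", "audio"),
                            features_path = NULL,
                            wav_dir = NULL, annotations_path = NULL,
                            exclude_contexts = "fed",
                            generator = NULL,
                            pdfa = NULL,
                            pic_contexts = c("beg", "rest",
                                             "touch-affiliative",
                                             "touch-aversive"),
                            dissim_standardize = FALSE,
                            dissim_score = "euclidean",
                            out_dir = "vocalid_out",
                            seed = 1L) {
  input_mode <- match.arg(input_mode)
  seed <- as.integer(seed)
  if (is.null(generator)) generator <- generator_config(seed = seed)
  else generator$seed <- seed
  if (is.null(pdfa)) pdfa <- pdfa_config(seed = seed + 1L)
  else pdfa$seed <- seed + 1L
  structure(list(input_mode = input_mode,
                 features_path = features_path,
                 wav_dir = wav_dir, annotations_path = annotations_path,
                 exclude_contexts = exclude_contexts,
                 generator = generator, pdfa = pdfa,
                 pic_contexts = pic_contexts,
                 dissim_standardize = dissim_standardize,
                 dissim_score = dissim_score,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full vocal-identity analysis pipeline
#'
#' Generates or ingests a call table, applies the context filter, then runs
#' the three analysis stages: pDFA per age class and pooled, PIC per
#' parameter x age class (pooled and per context) with age trends, and
#' dyadic dissimilarity with age trends (pooled-context profiles plus
#' per-context profiles). Writes `calls.csv`, `pdfa.csv`, `pic.csv`,
#' `dissimilarity.csv`, `dissimilarity_trends.csv`,
#' `context_composition.csv` and `manifest.json` to `config$out_dir`;
#' partial outputs are removed on failure. Deterministic given
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(config$out_dir,
                       c("calls.csv", "pdfa.csv", "pic.csv",
                         "dissimilarity.csv", "dissimilarity_trends.csv",
                         "context_composition.csv", "manifest.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)

  calls <- switch(config$input_mode,
    synthetic = generate_dataset(config$generator),
    features = read_call_table(config$features_path),
    audio = {
      ann <- utils::read.csv(config$annotations_path,
                             stringsAsFactors = FALSE)
      extract_features_table(config$wav_dir, ann)
    })
  n_raw <- nrow(calls)
  calls <- apply_filters(calls, config$exclude_contexts)
  filter_log <- attr(calls, "filter_log")
  calls$age_class <- as.character(assign_age_class(calls$age_days))

  # conservation audit: age-class partition must cover every retained call
  class_counts <- table(calls$age_class)
  check_count_conservation(as.integer(class_counts), nrow(calls))

  pdfa_tab <- run_pdfa_by_age_class(calls, config$pdfa)
  pic_tab <- pic_by_age_class(calls, contexts = config$pic_contexts)
  m_pic <- length(acoustic_parameter_names())
  pic_thr <- bonferroni_threshold(0.05, m_pic)
  pic_tab$bonferroni_m <- pic_thr$m
  pic_tab$bonferroni_threshold <- pic_thr$raw

  prof_pooled <- daily_median_profiles(calls, by_context = FALSE)
  prof_ctx <- daily_median_profiles(calls, by_context = TRUE)
  rec <- rbind(
    dyadic_dissimilarity(prof_pooled,
                         standardize = config$dissim_standardize,
                         score = config$dissim_score),
    dyadic_dissimilarity(prof_ctx,
                         standardize = config$dissim_standardize,
                         score = config$dissim_score))
  trend_ctxs <- c("pooled", sort(setdiff(unique(rec$context), "pooled")))
  m_dis <- length(trend_ctxs)
  trends <- do.call(rbind, lapply(trend_ctxs, function(cx) {
    tr <- dissimilarity_trend(rec, cx, bonferroni_m = m_dis)
    data.frame(context = cx, slope = tr$slope, p = tr$p, n = tr$n,
               status = tr$status, bonferroni_m = m_dis,
               bonferroni_threshold = tr$threshold,
               significant = tr$significant, stringsAsFactors = FALSE)
  }))

  comp <- as.data.frame(table(individual = calls$individual,
                              age_class = calls$age_class,
                              context = calls$context),
                        stringsAsFactors = FALSE)
  names(comp)[4] <- "n_calls"

  manifest <- list(
    package_version = as.character(utils::packageVersion("vocalid")),
    r_version = R.version.string,
    seed = config$seed,
    input_mode = config$input_mode,
    n_calls_raw = n_raw,
    n_calls_retained = nrow(calls),
    excluded_contexts = config$exclude_contexts,
    filter_log = filter_log,
    calls_per_age_class = as.list(class_counts),
    pdfa = list(n_permutations = config$pdfa$n_permutations,
                n_selections = config$pdfa$n_selections,
                alpha = config$pdfa$alpha),
    bonferroni = list(pic = pic_thr,
                      dissimilarity = bonferroni_threshold(0.05, m_dis)),
    config = config_to_list(config))

  utils::write.csv(calls, outputs[1], row.names = FALSE)
  utils::write.csv(pdfa_tab, outputs[2], row.names = FALSE)
  utils::write.csv(pic_tab, outputs[3], row.names = FALSE)
  utils::write.csv(rec, outputs[4], row.names = FALSE)
  utils::write.csv(trends, outputs[5], row.names = FALSE)
  utils::write.csv(comp, outputs[6], row.names = FALSE)
  jsonlite::write_json(manifest, outputs[7], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  ok <- TRUE
  invisible(list(calls = calls, pdfa = pdfa_tab, pic = pic_tab,
                 dissimilarity = rec, trends = trends,
                 context_composition = comp, manifest = manifest))
}

# Serialize a config (dropping functions/matrices to plain lists) for the
# manifest and for round-tripping through JSON config files.
config_to_list <- function(config) {
  strip <- function(x) {
    if (is.matrix(x)) {
      as.data.frame(x)
    } else if (inherits(x, c("generator_config", "pdfa_config",
                             "pipeline_config")) || is.list(x)) {
      lapply(unclass(x), strip)
    } else x
  }
  strip(config)
}

#' Read a pipeline configuration from a JSON file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `generator`
#' and `pdfa` sub-objects mirror [generator_config()] and [pdfa_config()].
#' Unknown keys are rejected.
#'
#' @param path JSON file path.
#' @param seed Optional seed override.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(args, fn) {
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  if (!is.null(raw$generator)) {
    g <- raw$generator
    if (!is.null(g$contexts)) g$contexts <- as.data.frame(g$contexts)
    if (!is.null(g$context_effects))
      g$context_effects <- as.matrix(as.data.frame(g$context_effects))
    for (v in c("baseline", "within_sd", "offset_sd", "drift_sd"))
      if (!is.null(g[[v]])) g[[v]] <- unlist(g[[v]])
    raw$generator <- build(g, generator_config)
  }
  if (!is.null(raw$pdfa)) raw$pdfa <- build(raw$pdfa, pdfa_config)
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  build(raw, pipeline_config)
}
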