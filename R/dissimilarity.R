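#' Seven-day age classes
#'
#' Bins ages in days into the five closed seven-day classes 11-17, 18-24,
#' 25-31, 32-38 and 39-45 (days after estimated hatching).
#'
#' @param age_days Integer vector of ages in days, each within \[11, 45\].
#' @return Factor with levels `"11-17"`, `"18-24"`, `"25-31"`, `"32-38"`,
#'   `"39-45"`.
#' @export
assign_age_class <- function(age_days) {
  if (any(is.na(age_days)) || any(age_days < 11 | age_days > 45))
    stop("age_days must lie within [11, 45]")
  labs <- age_class_labels()
  cut(age_days, breaks = seq(11, 46, by = 7) - 0.5, labels = labs,
      right = TRUE)
}

#' @rdname assign_age_class
#' @export
age_class_labels <- function() {
  c("11-17", "18-24", "25-31", "32-38", "39-45")
}

#' @rdname assign_age_class
#' @return `age_class_midpoints()`: named vector of bin midpoint days
#'   (14, 21, 28, 35, 42), used as the age predictor in PIC trend models.
#' @export
age_class_midpoints <- function() {
  stats::setNames(c(14, 21, 28, 35, 42), age_class_labels())
}

#' Daily median acoustic profiles
#'
#' One profile per individual and day (and per context when `by_context`):
#' the per-parameter sample median over that individual's calls, with the
#' call count recorded. Empty strata are simply absent.
#'
#' @param calls Data frame with `individual`, `age_days`, optionally
#'   `context`, and the feature columns.
#' @param by_context Compute profiles per behavioural context instead of
#'   pooling contexts within the day.
#' @param parameters Feature column names.
#' @return Data frame with `individual`, `age_days`, `context` (`"pooled"`
#'   when not split), `n_calls`, and the 8 median feature columns.
#' @export
daily_median_profiles <- function(calls, by_context = FALSE,
                                  parameters = acoustic_parameter_names()) {
  stopifnot(all(c("individual", "age_days", parameters) %in% names(calls)))
  key <- if (by_context) {
    interaction(calls$individual, calls$age_days, calls$context,
                drop = TRUE, sep = "\r")
  } else {
    interaction(calls$individual, calls$age_days, drop = TRUE, sep = "\r")
  }
  idx <- split(seq_len(nrow(calls)), key)
  rows <- lapply(idx, function(i) {
    med <- vapply(parameters, function(p) stats::median(calls[[p]][i]),
                  numeric(1))
    data.frame(individual = calls$individual[i[1]],
               age_days = calls$age_days[i[1]],
               context = if (by_context) calls$context[i[1]] else "pooled",
               n_calls = length(i),
               as.list(med),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$age_days, out$context, out$individual), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dyadic acoustic dissimilarity scores
#'
#' For every day (and context stratum), computes the Euclidean distance
#' between the median profiles of every unordered pair of individuals.
#' A score of 0 means identical profiles; larger values mean greater
#' dissimilarity. Optionally each parameter is z-scaled globally (across all
#' profiles supplied) before distances, so Hz-scaled parameters do not
#' dominate the metric; this is off by default and logged when applied.
#' `score = "max-minus-distance"` instead reports each stratum's maximum
#' distance minus the pair's distance (so 0 marks the most dissimilar pair).
#'
#' @param profiles Data frame from [daily_median_profiles()].
#' @param standardize Z-scale parameters globally before distances.
#' @param score `"euclidean"` (default) or `"max-minus-distance"`.
#' @param parameters Feature column names.
#' @return Data frame with `ind1`, `ind2` (sorted within pair), `dyad`,
#'   `age_days`, `context`, `score`; zero rows when no stratum has 2+
#'   profiles.
#' @export
dyadic_dissimilarity <- function(profiles, standardize = FALSE,
                                 score = c("euclidean", "max-minus-distance"),
                                 parameters = acoustic_parameter_names()) {
  score <- match.arg(score)
  stopifnot(all(c("individual", "age_days", "context", parameters)
                %in% names(profiles)))
  M <- as.matrix(profiles[, parameters, drop = FALSE])
  if (!all(is.finite(M))) stop("non-finite values in profiles")
  if (standardize) {
    message("standardizing parameters (global z-scale) before distances")
    M <- scale(M)
    M[, attr(M, "scaled:scale") == 0] <- 0
  }
  strata <- split(seq_len(nrow(profiles)),
                  interaction(profiles$age_days, profiles$context,
                              drop = TRUE, sep = "\r"))
  rows <- lapply(strata, function(i) {
    if (length(i) < 2L) return(NULL)
    ids <- profiles$individual[i]
    if (anyDuplicated(ids))
      stop("duplicate individual within a day/context stratum")
    D <- as.matrix(stats::dist(M[i, , drop = FALSE]))
    pr <- utils::combn(seq_along(i), 2)
    sc <- D[t(pr)]
    if (score == "max-minus-distance") sc <- max(D) - sc
    a <- ids[pr[1, ]]; b <- ids[pr[2, ]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    data.frame(ind1 = lo, ind2 = hi, dyad = paste(lo, hi, sep = "|"),
               age_days = profiles$age_days[i[1]],
               context = profiles$context[i[1]],
               score = sc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(ind1 = character(0), ind2 = character(0),
                      dyad = character(0), age_days = integer(0),
                      context = character(0), score = numeric(0)))
  out <- out[order(out$age_days, out$context, out$dyad), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Age trend of dyadic dissimilarity
#'
#' OLS of the dissimilarity score on age in days, for one behavioural
#' context or for all records (`context = "pooled"` when the records were
#' built from pooled-context profiles, or any context label present).
#' Strata without at least 3 records spanning 2 distinct ages are flagged
#' `"insufficient"` instead of fitted.
#'
#' @param records Data frame from [dyadic_dissimilarity()].
#' @param context Context label to restrict to (default `"pooled"`).
#' @param bonferroni_m Family size for the significance flag; `NULL` for no
#'   adjustment (threshold `alpha`).
#' @param alpha Family-wise level (default 0.05).
#' @return List with `context`, `slope`, `p`, `n`, `status`
#'   (`"ok"`/`"insufficient"`), `threshold`, `significant`.
#' @export
dissimilarity_trend <- function(records, context = "pooled",
                                bonferroni_m = NULL, alpha = 0.05) {
  sub <- records[records$context == context, , drop = FALSE]
  thr <- if (is.null(bonferroni_m)) list(raw = alpha, rounded = round(alpha, 3))
         else bonferroni_threshold(alpha, bonferroni_m)
  if (nrow(sub) < 3 || length(unique(sub$age_days)) < 2) {
    return(list(context = context, slope = NA_real_, p = NA_real_,
                n = nrow(sub), status = "insufficient",
                threshold = thr$raw, significant = NA))
  }
  tr <- ols_trend(sub$score, sub$age_days)
  list(context = context, slope = tr$slope, p = tr$p, n = nrow(sub),
       status = "ok", threshold = thr$raw,
       significant = tr$p < thr$raw)
}
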