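#' Small-sample corrected coefficient of variation
#'
#' `CV_corr = (SD / |mean|) * (1 + 1/(4n))`, the standard small-sample
#' correction. The absolute mean is used so that negative-valued parameters
#' (spectral slope, in dB/kHz) keep a positive CV; a message is emitted when
#' this applies.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return Corrected CV (non-negative scalar).
#' @export
corrected_cv <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  if (m < 0) message("negative mean; using |mean| in CV denominator")
  (stats::sd(values) / abs(m)) * (1 + 1 / (4 * n))
}

#' Potential of identity coding (PIC) for one parameter
#'
#' Ratio of the corrected CV of all values pooled across individuals to the
#' mean within-individual corrected CV. Values above 1 indicate that the
#' parameter varies more between than within individuals, i.e. it carries
#' identity information.
#'
#' @param values Numeric vector of one acoustic parameter across calls.
#' @param individual Vector of individual identities, same length.
#' @return PIC value; `Inf` (with a warning) when every within-individual CV
#'   is zero.
#' @export
calc_pic <- function(values, individual) {
  if (length(values) != length(individual))
    stop("values and individual must have equal length")
  groups <- split(as.numeric(values), individual)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 individuals")
  if (any(lengths(groups) < 2)) stop("each individual needs at least 2 calls")
  within <- vapply(groups, corrected_cv, numeric(1))
  pooled <- corrected_cv(unlist(groups, use.names = FALSE))
  mw <- mean(within)
  if (mw == 0) {
    warning("all within-individual CVs are zero; PIC is infinite")
    return(Inf)
  }
  pooled / mw
}

#' PIC per parameter and age class, with age trends
#'
#' Computes PIC for every acoustic parameter in every seven-day age class,
#' for all behavioural contexts pooled and for each context in `contexts`
#' separately, then regresses PIC on the age-class midpoint day (14, 21, 28,
#' 35, 42 for the default bins) per parameter and context. Strata failing
#' the PIC preconditions (fewer than 2 individuals with 2 calls each) yield
#' `NA` with a logged message.
#'
#' @param calls Data frame with `individual`, `context`, `age_days` and the
#'   feature columns.
#' @param parameters Feature column names (default the 8 descriptors).
#' @param contexts Contexts analysed separately in addition to `"pooled"`.
#' @return Data frame with columns `context`, `parameter`, `age_class`,
#'   `pic`, `trend_slope`, `trend_p` (trend values repeated across the
#'   parameter's age classes).
#' @export
pic_by_age_class <- function(calls,
                             parameters = acoustic_parameter_names(),
                             contexts = c("beg", "rest", "touch-affiliative",
                                          "touch-aversive")) {
  calls$age_class <- assign_age_class(calls$age_days)
  classes <- levels(calls$age_class)
  mids <- age_class_midpoints()[classes]
  strata <- c("pooled", contexts)
  out <- list()
  for (ctx in strata) {
    sub <- if (ctx == "pooled") calls else
      calls[calls$context == ctx, , drop = FALSE]
    for (par in parameters) {
      pics <- vapply(classes, function(cl) {
        rows <- sub[sub$age_class == cl, , drop = FALSE]
        # need >=2 individuals with >=2 calls each
        tab <- table(rows$individual)
        keep <- names(tab)[tab >= 2]
        if (length(keep) < 2) {
          message(sprintf(
            "PIC undefined for %s / %s / %s: fewer than 2 individuals with 2+ calls",
            ctx, par, cl))
          return(NA_real_)
        }
        rows <- rows[rows$individual %in% keep, , drop = FALSE]
        tryCatch(calc_pic(rows[[par]], rows$individual),
                 error = function(e) {
                   message(sprintf("PIC undefined for %s / %s / %s: %s",
                                   ctx, par, cl, conditionMessage(e)))
                   NA_real_
                 })
      }, numeric(1))
      ok <- is.finite(pics)
      tr <- if (sum(ok) >= 3 && length(unique(mids[ok])) >= 2) {
        ols_trend(pics[ok], mids[ok])
      } else {
        list(slope = NA_real_, p = NA_real_)
      }
      out[[length(out) + 1L]] <- data.frame(
        context = ctx, parameter = par, age_class = classes,
        pic = unname(pics), trend_slope = tr$slope, trend_p = tr$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ordinary least-squares trend
#'
#' Simple linear regression of `y` on `x` with a two-sided t-test on the
#' slope. A numerically exact fit (residual standard error at machine zero)
#' is flagged and its p-value reported at the double floor rather than as 0.
#'
#' @param y,x Numeric vectors, at least 3 points, `x` not constant.
#' @return List with `slope`, `intercept`, `p`, `exact_fit`.
#' @export
ols_trend <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 3) stop("need at least 3 points")
  if (length(unique(x)) < 2) stop("x is constant")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  sigma <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  if (sigma <= .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    return(list(slope = slope, intercept = intercept,
                p = .Machine$double.xmin, exact_fit = TRUE))
  }
  list(slope = slope, intercept = intercept,
       p = unname(summary(fit)$coefficients[2, 4]), exact_fit = FALSE)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy (overall)
#'
#' `KMO = sum(r_ij^2) / (sum(r_ij^2) + sum(q_ij^2))` over all off-diagonal
#' pairs, where `r` are Pearson correlations and `q` are anti-image partial
#' correlations obtained from the inverse correlation matrix:
#' `q_ij = -inv_ij / sqrt(inv_ii * inv_jj)`. Values near 1 indicate the data
#' suit factor analysis; around 0.6-0.7 is conventionally "mediocre".
#'
#' @param x Numeric matrix or data frame of observations x variables.
#' @return Overall KMO statistic in \[0, 1\].
#' @export
kmo_overall <- function(x) {
  X <- as.matrix(x)
  if (nrow(X) < 3) stop("need at least 3 rows")
  if (ncol(X) < 2) stop("need at least 2 variables")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) stop("zero-variance column(s): ",
                        paste(colnames(X)[v == 0], collapse = ", "))
  R <- stats::cor(X)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular"))
  Q <- -Rinv / sqrt(outer(diag(Rinv), diag(Rinv)))
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m` for a family of `m` tests. The raw threshold is used for
#' comparisons; the value rounded to 3 decimals matches conventional
#' reporting (e.g. 0.05/8 -> 0.006, 0.05/7 -> 0.007).
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return List with `raw` and `rounded` thresholds and `m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  raw <- alpha / m
  list(raw = raw, rounded = round(raw, 3), m = as.integer(m))
}
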