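#' Configuration for permuted discriminant function analysis
#'
#' @param test_factor Column holding the grouping to classify (default
#'   `"individual"`).
#' @param restriction_factor Blocking column within which labels are permuted
#'   under the null (default `"context"`), so the null preserves each block's
#'   label composition.
#' @param n_permutations Number of label permutations (default 1000).
#' @param n_selections Number of random balanced train/test splits averaged
#'   for the observed statistic (default 100).
#' @param n_train_per_cell Training calls taken from each test-factor x
#'   restriction-factor cell; `NULL` (default) uses the smallest retained
#'   cell size minus one.
#' @param alpha Nominal significance level (default 0.05).
#' @param seed Integer seed.
#' @return Object of class `pdfa_config`.
#' @export
pdfa_config <- function(test_factor = "individual",
                        restriction_factor = "context",
                        n_permutations = 1000L,
                        n_selections = 100L,
                        n_train_per_cell = NULL,
                        alpha = 0.05,
                        seed = 1L) {
  stopifnot(n_permutations >= 1, n_selections >= 1,
            is.null(n_train_per_cell) || n_train_per_cell >= 1)
  structure(list(test_factor = test_factor,
                 restriction_factor = restriction_factor,
                 n_permutations = as.integer(n_permutations),
                 n_selections = as.integer(n_selections),
                 n_train_per_cell = n_train_per_cell,
                 alpha = alpha,
                 seed = as.integer(seed)),
            class = "pdfa_config")
}

#' Balanced train/test split over factor cells
#'
#' Cells are the combinations of test factor and restriction factor. Cells
#' with fewer than `n_train_per_cell + 1` calls are dropped (with a warning);
#' from each retained cell exactly `n_train_per_cell` calls are sampled
#' without replacement into the training set and the remainder form the test
#' set.
#'
#' @param calls Data frame of calls.
#' @param test_factor,restriction_factor Column names.
#' @param n_train_per_cell Training calls per retained cell.
#' @return List with integer row indices `train` and `test`, and `dropped`
#'   (labels of dropped cells). Uses the current RNG stream.
#' @export
balanced_split <- function(calls, test_factor = "individual",
                           restriction_factor = "context",
                           n_train_per_cell) {
  cell <- interaction(calls[[test_factor]], calls[[restriction_factor]],
                      drop = TRUE, sep = ":")
  sizes <- table(cell)
  keep <- names(sizes)[sizes >= n_train_per_cell + 1]
  dropped <- setdiff(names(sizes), keep)
  if (length(keep) == 0L)
    stop("no cell has at least n_train_per_cell + 1 calls")
  if (length(dropped) > 0L)
    warning(sprintf("dropped %d cell(s) below minimum size: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  train <- integer(0)
  for (k in keep) {
    idx <- which(cell == k)
    train <- c(train, idx[sample.int(length(idx), n_train_per_cell)])
  }
  test <- setdiff(which(cell %in% keep), train)
  if (length(test) == 0L) stop("empty test set after balanced split")
  list(train = sort(train), test = sort(test), dropped = dropped)
}

#' Permute labels within blocks
#'
#' Within each block the labels are replaced by a uniformly random
#' permutation of that block's label multiset; nothing moves across blocks.
#' This is the restricted permutation scheme underlying the pDFA null.
#'
#' @param labels Vector of labels.
#' @param blocks Vector of block identifiers, same length as `labels`.
#' @return Permuted label vector. Uses the current RNG stream.
#' @export
permute_within_blocks <- function(labels, blocks) {
  if (length(labels) != length(blocks))
    stop("labels and blocks must have equal length")
  out <- labels
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    if (length(idx) > 1L) out[idx] <- labels[idx[sample.int(length(idx))]]
  }
  out
}

# Fast LDA on integer-coded labels over a numeric matrix; returns the
# percentage correct on train and test index sets. Shared by the public
# fit_and_classify and the permutation engine.
lda_accuracy <- function(X, y, tr, te, ridge = 1e-6) {
  ytr <- y[tr]
  classes <- sort(unique(ytr))
  k <- length(classes)
  yi <- match(ytr, classes)
  nk <- tabulate(yi, k)
  M <- rowsum(X[tr, , drop = FALSE], yi) / nk
  Xc <- X[tr, , drop = FALSE] - M[yi, , drop = FALSE]
  S <- crossprod(Xc) / (length(tr) - k)
  W <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(W))
    W <- tryCatch(solve(S + diag(ridge * mean(diag(S)) + 1e-12, ncol(X))),
                  error = function(e) stop("covariance singular after ridge"))
  A <- tcrossprod(W, M)                 # p x k
  const <- -0.5 * colSums(t(M) * A) + log(nk / sum(nk))
  pred <- function(idx) {
    sc <- X[idx, , drop = FALSE] %*% A +
      matrix(const, length(idx), k, byrow = TRUE)
    classes[max.col(sc, ties.method = "first")]
  }
  c(100 * mean(pred(tr) == ytr), 100 * mean(pred(te) == y[te]))
}

# One pDFA statistic for one labeling: mean train/test accuracy over K
# random balanced splits. Cells below n_train + 1 calls are dropped; splits
# leaving fewer than 2 training classes are redrawn (bounded retries).
pdfa_statistic <- function(X, y, blocks, n_train, K) {
  cells <- split(seq_along(y), paste(y, blocks))
  cells <- cells[lengths(cells) >= n_train + 1]
  if (length(cells) == 0L)
    stop("no cell has at least n_train_per_cell + 1 calls")
  pool <- unlist(cells, use.names = FALSE)
  acc <- matrix(NA_real_, 2, K)
  for (s in seq_len(K)) {
    for (attempt in 1:50) {
      tr <- unlist(lapply(cells, function(ix)
        ix[sample.int(length(ix), n_train)]), use.names = FALSE)
      te <- setdiff(pool, tr)
      if (length(unique(y[tr])) >= 2L && length(te) > 0L) break
      if (attempt == 50) stop("could not draw a split with 2+ classes")
    }
    acc[, s] <- lda_accuracy(X, y, tr, te)
  }
  rowMeans(acc)
}

# Linear discriminant classifier core: pooled within-class covariance,
# proportional priors, features standardized by training moments. Ridge
# fallback (lambda = 1e-6 * mean diagonal) when the covariance is
# numerically singular. Returns predicted labels for newdata.
lda_fit_predict <- function(X, y, newdata, ridge = 1e-6) {
  classes <- unique(y)
  k <- length(classes)
  p <- ncol(X)
  mu0 <- colMeans(X)
  s0 <- apply(X, 2, stats::sd)
  s0[s0 == 0 | !is.finite(s0)] <- 1
  Xs <- sweep(sweep(X, 2, mu0), 2, s0, "/")
  Ns <- sweep(sweep(newdata, 2, mu0), 2, s0, "/")

  M <- matrix(0, k, p)
  S <- matrix(0, p, p)
  nk <- integer(k)
  for (i in seq_len(k)) {
    rows <- Xs[y == classes[i], , drop = FALSE]
    nk[i] <- nrow(rows)
    M[i, ] <- colMeans(rows)
    C <- sweep(rows, 2, M[i, ])
    S <- S + crossprod(C)
  }
  S <- S / (nrow(Xs) - k)
  W <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(W)) {
    message("within-class covariance singular; applying ridge")
    W <- tryCatch(solve(S + diag(ridge * mean(diag(S)) + 1e-12, p)),
                  error = function(e) stop("covariance singular after ridge"))
  }
  A <- M %*% W                       # k x p
  const <- -0.5 * rowSums(A * M) + log(nk / sum(nk))
  scores <- Ns %*% t(A) + matrix(const, nrow(Ns), k, byrow = TRUE)
  classes[max.col(scores, ties.method = "first")]
}

#' Fit linear discriminant functions and classify
#'
#' Fits a linear discriminant classifier on the training calls (features
#' standardized internally, pooled within-class covariance, proportional
#' priors) and reports the percentage of training calls correctly
#' re-classified by the fitted functions and the percentage of held-out test
#' calls correctly cross-classified.
#'
#' @param train,test Data frames of calls.
#' @param feature_columns Character vector of feature column names.
#' @param test_factor Column holding the class labels.
#' @return Named numeric vector `c(pct_correct_train, pct_correct_test)`.
#' @export
fit_and_classify <- function(train, test,
                             feature_columns = acoustic_parameter_names(),
                             test_factor = "individual") {
  if (nrow(test) == 0L) stop("test set is empty")
  y <- as.character(train[[test_factor]])
  if (length(unique(y)) < 2L) stop("need at least 2 classes in training set")
  Xtr <- as.matrix(train[, feature_columns, drop = FALSE])
  Xte <- as.matrix(test[, feature_columns, drop = FALSE])
  if (!all(is.finite(Xtr)) || !all(is.finite(Xte)))
    stop("non-finite feature values")
  if (nrow(Xtr) <= length(feature_columns))
    warning("fewer training rows than features + 1; fit may be unstable")
  pred_tr <- lda_fit_predict(Xtr, y, Xtr)
  pred_te <- lda_fit_predict(Xtr, y, Xte)
  c(pct_correct_train = 100 * mean(pred_tr == y),
    pct_correct_test = 100 * mean(pred_te == as.character(test[[test_factor]])))
}

#' Run a permuted discriminant function analysis
#'
#' The test statistic for one labeling is the classification rate averaged
#' over `n_selections` random balanced splits. Observed rates apply this to
#' the real labels; the null distribution applies the identical procedure to
#' each of `n_permutations` labelings permuted within restriction-factor
#' blocks, so observed and null values are exchangeable under the null and
#' the test is exactly calibrated for any `n_selections`. Chance levels are
#' the means of the null distributions, and p-values use the add-one
#' convention `(#{null >= observed} + 1) / (n_permutations + 1)`, whose
#' smallest attainable value with 1000 permutations is 1/1001 (reported as
#' 0.001).
#'
#' @param calls Data frame with feature columns and the factor columns.
#' @param config A [pdfa_config()].
#' @param feature_columns Feature column names.
#' @return Object of class `pdfa_result`: a list with
#'   `n_context_categories`, `n_calls`, `pct_correct`, `chance_correct`,
#'   `p_correct`, `pct_cross`, `chance_cross`, `relative_cross`, `p_cross`,
#'   and `n_train_per_cell`. Deterministic given `config$seed`.
#' @export
run_pdfa <- function(calls, config = pdfa_config(),
                     feature_columns = acoustic_parameter_names()) {
  stopifnot(inherits(config, "pdfa_config"))
  set.seed(config$seed)
  tf <- config$test_factor; rf <- config$restriction_factor
  stopifnot(all(c(tf, rf, feature_columns) %in% names(calls)))

  n_train <- config$n_train_per_cell
  if (is.null(n_train)) {
    sizes <- table(interaction(calls[[tf]], calls[[rf]], drop = TRUE))
    usable <- sizes[sizes >= 2]
    if (length(usable) == 0L) stop("no usable cells (all have < 2 calls)")
    n_train <- max(1L, min(usable) - 1L)
  }

  # features scaled once for numerical stability (LDA predictions are
  # invariant to affine per-feature rescaling)
  X <- as.matrix(calls[, feature_columns, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite feature values")
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  X <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  y0 <- as.character(calls[[tf]])
  blocks <- as.character(calls[[rf]])
  K <- config$n_selections

  obs <- pdfa_statistic(X, y0, blocks, n_train, K)
  null_mat <- vapply(seq_len(config$n_permutations), function(b) {
    pdfa_statistic(X, permute_within_blocks(y0, blocks), blocks, n_train, K)
  }, numeric(2))

  p_corr <- (sum(null_mat[1, ] >= obs[1]) + 1) / (config$n_permutations + 1)
  p_cross <- (sum(null_mat[2, ] >= obs[2]) + 1) / (config$n_permutations + 1)
  chance <- rowMeans(null_mat)
  structure(list(
    n_context_categories = length(unique(calls[[rf]])),
    n_calls = nrow(calls),
    n_train_per_cell = n_train,
    pct_correct = unname(obs[1]),
    chance_correct = unname(chance[1]),
    p_correct = p_corr,
    pct_cross = unname(obs[2]),
    chance_cross = unname(chance[2]),
    relative_cross = unname(obs[2] / chance[2]),
    p_cross = p_cross
  ), class = "pdfa_result")
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat("Permuted DFA result\n")
  cat(sprintf("  calls: %d, context categories: %d\n",
              x$n_calls, x$n_context_categories))
  cat(sprintf("  correctly classified: %.2f%% (chance %.2f%%, p = %.4g)\n",
              x$pct_correct, x$chance_correct, x$p_correct))
  cat(sprintf("  correctly cross-classified: %.2f%% (chance %.2f%%, p = %.4g)\n",
              x$pct_cross, x$chance_cross, x$p_cross))
  cat(sprintf("  relative cross-classification level: %.2f\n",
              x$relative_cross))
  invisible(x)
}

#' Relative cross-classification level
#'
#' Held-out classification accuracy divided by its permutation chance level;
#' values above 1 indicate above-chance identity information. Reported
#' rounded to 2 decimals.
#'
#' @param pct_cross Cross-classified percentage.
#' @param chance_cross Chance level percentage (> 0).
#' @return Ratio rounded to 2 decimals.
#' @export
relative_cross_classification <- function(pct_cross, chance_cross) {
  if (any(chance_cross <= 0)) stop("chance_cross must be positive")
  round(pct_cross / chance_cross, 2)
}

#' Run the pDFA per age class and pooled
#'
#' Runs one pDFA per seven-day age class plus one on all classes pooled
#' (six models for the default 11-45 day span), each with its own derived
#' seed from `config$seed`.
#'
#' @param calls Data frame of calls with an `age_days` column.
#' @param config A [pdfa_config()].
#' @param feature_columns Feature column names.
#' @return Data frame with one row per model (age classes in order, then
#'   `"pooled"`) and the `pdfa_result` fields as columns.
#' @export
run_pdfa_by_age_class <- function(calls, config = pdfa_config(),
                                  feature_columns = acoustic_parameter_names()) {
  calls$age_class <- assign_age_class(calls$age_days)
  models <- c(levels(calls$age_class), "pooled")
  rows <- lapply(seq_along(models), function(i) {
    sub <- if (models[i] == "pooled") calls else
      calls[calls$age_class == models[i], , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    res <- run_pdfa(sub, cfg, feature_columns)
    data.frame(model = models[i],
               n_context_categories = res$n_context_categories,
               n_calls = res$n_calls,
               pct_correct = res$pct_correct,
               chance_correct = res$chance_correct,
               p_correct = res$p_correct,
               pct_cross = res$pct_cross,
               chance_cross = res$chance_cross,
               relative_cross = relative_cross_classification(
                 res$pct_cross, res$chance_cross),
               p_cross = res$p_cross,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
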