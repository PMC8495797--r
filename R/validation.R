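#' Area under the ROC curve (rank-based)
#'
#' Probability that a randomly chosen positive tow receives a higher
#' score than a randomly chosen negative tow, with ties counted as one
#' half (the Mann-Whitney formulation). 0.5 marks a model with no
#' predictive value; 1 a perfect ranking.
#'
#' @param scores numeric predictions.
#' @param labels logical (or 0/1) outcomes; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(is.na(scores)) || any(is.na(labels))) stop("missing values")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

new_cv_result <- function(scheme, auc, n_train, n_test, blocks = NULL,
                          n_resampled = 0L) {
  structure(list(scheme = scheme, auc = auc,
                 n_train = n_train, n_test = n_test,
                 blocks = blocks, n_resampled = n_resampled),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  ok <- x$auc[!is.na(x$auc)]
  cat(sprintf("cv_result (%s): %d iteration(s), AUC mean %.3f, range %.3f-%.3f\n",
              x$scheme, length(x$auc), mean(ok), min(ok), max(ok)))
  invisible(x)
}

#' Random Monte-Carlo cross-validation of a presence model
#'
#' Repeatedly splits the tows at random into 75% training / 25% testing,
#' refits the presence curve on the training part and scores the test
#' part by AUC. Iterations whose test split lacks one of the classes are
#' redrawn (up to 50 attempts, counted in `n_resampled`).
#'
#' @param temps,presence tow temperatures and presence flags.
#' @param n_iter number of iterations (default 100).
#' @param train_frac training fraction (default 0.75).
#' @param seed master seed; per-iteration seeds are derived from it by a
#'   fixed increment, so results are reproducible and auditable.
#' @param k spline basis dimension passed to [fit_presence_curve()].
#' @return A `cv_result` with scheme `"random_mc"`.
#' @export
monte_carlo_cv <- function(temps, presence, n_iter = 100, train_frac = 0.75,
                           seed = 1, k = 10) {
  presence <- as.logical(presence)
  n <- length(temps)
  n_train <- round(train_frac * n)
  auc <- numeric(n_iter)
  n_resampled <- 0L
  for (it in seq_len(n_iter)) {
    for (attempt in 1:50) {
      idx <- with_seed(derive_seed(seed, (it - 1L) * 50L + attempt),
                       sample.int(n, n_train))
      te <- presence[-idx]
      if (any(te) && any(!te)) break
      n_resampled <- n_resampled + 1L
      if (attempt == 50) stop("could not draw a two-class test split in 50 attempts")
    }
    curve <- fit_presence_curve(temps[idx], presence[idx], k = k)
    auc[it] <- compute_auc(curve_response(curve, temps[-idx]), presence[-idx])
  }
  if (n_resampled > 0)
    message(sprintf("monte_carlo_cv: %d single-class test split(s) redrawn", n_resampled))
  new_cv_result("random_mc", auc, n_train, n - n_train, n_resampled = n_resampled)
}

#' Rolling year-block cross-validation
#'
#' One iteration per rolling window of `block_years` consecutive
#' calendar years (window start advancing by one year across the span of
#' the data): tows inside the window are withheld for testing, the rest
#' train the model. Respects temporal autocorrelation better than a
#' random split and measures skill at predicting years never seen in
#' training. Windows whose test tows are single-class get a missing AUC.
#'
#' @param temps,presence,years tow temperatures, presence flags and
#'   calendar years.
#' @param block_years window length in years (default 7, about 25% of a
#'   31-year record).
#' @param k spline basis dimension.
#' @return A `cv_result` with scheme `"year_block"` and a `blocks`
#'   data.frame (start, end, n_train, n_test, auc).
#' @export
year_block_cv <- function(temps, presence, years, block_years = 7, k = 10) {
  presence <- as.logical(presence)
  yr <- range(as.integer(years))
  if (diff(yr) + 1 < block_years + 1)
    stop("need more distinct years than the block length")
  starts <- yr[1]:(yr[2] - as.integer(block_years) + 1L)
  blocks <- data.frame(start = starts, end = starts + as.integer(block_years) - 1L,
                       n_train = NA_integer_, n_test = NA_integer_,
                       auc = NA_real_)
  for (b in seq_along(starts)) {
    test <- years >= blocks$start[b] & years <= blocks$end[b]
    blocks$n_train[b] <- sum(!test); blocks$n_test[b] <- sum(test)
    if (!any(test) || !any(presence[test]) || all(presence[test])) next
    curve <- fit_presence_curve(temps[!test], presence[!test], k = k)
    blocks$auc[b] <- compute_auc(curve_response(curve, temps[test]),
                                 presence[test])
  }
  new_cv_result("year_block", blocks$auc, blocks$n_train, blocks$n_test,
                blocks = blocks)
}

#' Cross-survey AUC matrix
#'
#' Entry (i, j) scores curve i's predicted presence probabilities on
#' dataset j's tows: how well a model trained on one survey design
#' predicts presence recorded by another. Single-class datasets yield a
#' missing column.
#'
#' @param curves named list of [thermal_curve()]s.
#' @param datasets named list of data.frames with columns `temp`,
#'   `presence`.
#' @return Matrix of AUCs, rows = curves, columns = datasets.
#' @export
cross_survey_auc <- function(curves, datasets) {
  out <- matrix(NA_real_, length(curves), length(datasets),
                dimnames = list(names(curves), names(datasets)))
  for (j in seq_along(datasets)) {
    d <- datasets[[j]]
    pres <- as.logical(d$presence)
    if (!any(pres) || all(pres)) next
    for (i in seq_along(curves))
      out[i, j] <- compute_auc(curve_response(curves[[i]], d$temp), pres)
  }
  out
}

#' Habitat quality rank from a scaled response
#'
#' Decile binning of a response scaled to `[0, 1]`: values in 0.0-0.1 get
#' rank 1, 0.1-0.2 rank 2, ..., 0.9-1.0 rank 10. Bins are left-closed
#' with the top bin closed (`floor(10 x) + 1`, capped at 10).
#'
#' @param scaled values in `[0, 1]`.
#' @return Integer ranks 1-10.
#' @export
rank_bin <- function(scaled) {
  if (any(!is.finite(scaled)) || any(scaled < 0 | scaled > 1))
    stop("scaled values must lie in [0, 1]")
  pmin(as.integer(floor(scaled * 10)) + 1L, 10L)
}

#' Habitat-quality-ranking cross-validation
#'
#' Bridges survey and laboratory models onto a common footing: for each
#' of `n_iter` iterations, the training data are resampled (a 75% draw
#' for survey sources; exactly `n_lab_per_temp` fish per test temperature
#' for the laboratory source), the model is refitted, its response is
#' scaled to `[0, 1]` over 0-30 C, every test tow's temperature receives
#' a scaled value and hence a decile quality rank, and presence is
#' tallied per rank. Tallies are pooled across iterations. A good model
#' shows the proportion of positive tows rising with rank.
#'
#' When `test` is `NULL`, the held-out 25% of the training survey itself
#' is scored (same-source validation); otherwise the full `test` dataset
#' is scored in every iteration (cross-source validation).
#'
#' @param train either a data.frame with columns `temp`, `presence`
#'   (survey source) or one with columns `temp_c`, `scope` (laboratory
#'   source).
#' @param test data.frame with columns `temp`, `presence`, or `NULL`.
#' @param n_iter iterations (default 100).
#' @param seed master seed.
#' @param train_frac survey training fraction (default 0.75).
#' @param n_lab_per_temp fish resampled per temperature for the
#'   laboratory source (default 9).
#' @param k spline basis dimension (survey: 10; laboratory: 3).
#' @return data.frame of class `quality_ranking` with one row per rank
#'   1-10: `n` tested tows, `n_present`, `proportion` (`NA` where a rank
#'   received no tows).
#' @export
quality_ranking_cv <- function(train, test = NULL, n_iter = 100, seed = 1,
                               train_frac = 0.75, n_lab_per_temp = 9,
                               k = NULL) {
  is_lab <- all(c("temp_c", "scope") %in% names(train))
  if (!is_lab && !all(c("temp", "presence") %in% names(train)))
    stop("train must have columns temp/presence or temp_c/scope")
  if (is_lab && is.null(test))
    stop("laboratory training requires an explicit presence-absence test set")
  if (is.null(k)) k <- if (is_lab) 3 else 10
  tally_n <- integer(10); tally_pos <- integer(10)
  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, it)
    if (is_lab) {
      sub <- with_seed(it_seed, {
        idx <- unlist(lapply(split(seq_len(nrow(train)), train$temp_c),
                             function(ix) sample(ix, min(n_lab_per_temp, length(ix)))))
        train[idx, ]
      })
      curve <- fit_scope_curve(sub, k = k)
      te <- test
    } else {
      n <- nrow(train)
      idx <- with_seed(it_seed, sample.int(n, round(train_frac * n)))
      curve <- fit_presence_curve(train$temp[idx], train$presence[idx], k = k)
      te <- if (is.null(test)) train[-idx, ] else test
    }
    sf <- scale_response(curve)
    ranks <- rank_bin(pmin(pmax(sf(te$temp), 0), 1))
    tally_n <- tally_n + tabulate(ranks, nbins = 10)
    tally_pos <- tally_pos + tabulate(ranks[as.logical(te$presence)], nbins = 10)
  }
  out <- data.frame(rank = 1:10, n = tally_n, n_present = tally_pos,
                    proportion = ifelse(tally_n > 0, tally_pos / tally_n, NA_real_))
  class(out) <- c("quality_ranking", "data.frame")
  attr(out, "n_iter") <- n_iter
  out
}
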