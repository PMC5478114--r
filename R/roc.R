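#' Encode survival outcomes into four aggressiveness categories
#'
#' Categories at a fixed horizon (default 36 months): 1 = disease-free
#' after the horizon (least aggressive); 2 = disease-free but censored
#' within the horizon; 3 = progressed after the horizon; 4 = progressed
#' within the horizon (most aggressive). "Within" is inclusive
#' (time <= horizon).
#'
#' @param time follow-up times in months (non-negative).
#' @param event 0/1 progression/death indicator.
#' @param horizon horizon in months.
#' @return integer vector of categories in 1..4.
#' @export
encode_outcome <- function(time, event, horizon = 36) {
  if (any(time < 0)) stop("negative follow-up time")
  stopifnot(all(event %in% c(0, 1)))
  ifelse(event == 0,
         ifelse(time > horizon, 1L, 2L),
         ifelse(time > horizon, 3L, 4L))
}

#' Rank-based ROC curve and AUC
#'
#' AUC via the Mann-Whitney rank statistic with the usual mid-rank tie
#' correction (a tied positive/negative pair counts one half); the
#' curve is the empirical threshold sweep over the observed ratings.
#'
#' @param ratings numeric scores (higher = more positive).
#' @param truth logical (or 0/1) class labels; both classes must be
#'   present.
#' @return list of class `roc_result` with `auc` and `curve`
#'   (data.frame of `fpr`, `tpr`, from (0,0) to (1,1)).
#' @export
auc_rank <- function(ratings, truth) {
  truth <- as.logical(truth)
  stopifnot(length(ratings) == length(truth), !anyNA(ratings), !anyNA(truth))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("both truth classes must be present")
  r <- rank(ratings)                       # mid-ranks handle ties
  auc <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # threshold sweep (descending unique ratings)
  thr <- sort(unique(ratings), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(ratings[truth] >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(ratings[!truth] >= t) / n_neg, 0)
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC of a signature score against outcome
#'
#' Convenience wrapper: encodes outcomes into the 4 aggressiveness
#' categories, binarizes them as progressed (3,4) vs disease-free
#' (1,2), and computes the rank AUC of the supplied ratings (SSM
#' scores, or an ordinal amplicon count).
#'
#' @inheritParams encode_outcome
#' @param ratings per-sample scores.
#' @return list with `roc` (a `roc_result`) and `category` (the 4-level
#'   encoding).
#' @export
outcome_roc <- function(ratings, time, event, horizon = 36) {
  cat4 <- encode_outcome(time, event, horizon)
  list(roc = auc_rank(ratings, cat4 >= 3L), category = cat4)
}
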