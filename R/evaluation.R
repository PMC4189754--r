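#' Clopper-Pearson exact binomial confidence interval
#'
#' Endpoints via the inverse regularized incomplete beta function:
#' `low = qbeta(a/2; k, n-k+1)` (0 when `k = 0`) and
#' `high = qbeta(1-a/2; k+1, n-k)` (1 when `k = n`), returned in percent.
#'
#' @param k number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return numeric `c(low, high)` in percent.
#' @examples
#' clopper_pearson(116, 120)  # c(91.69, 99.08) to 2 d.p.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integers 0 <= k <= n with n >= 1")
  a <- 1 - conf
  low <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  c(low = 100 * low, high = 100 * high)
}

# Fit a threshold on training samples and predict held-out samples.
# Degenerate training folds (one class) fall back to the majority-class
# prediction, i.e. all-positive or all-negative.
predict_heldout <- function(train_w, train_pos, test_w, beta) {
  if (all(train_pos) || !any(train_pos)) {
    return(rep(all(train_pos), length(test_w)))
  }
  gamma <- optimize_threshold(train_w, train_pos, beta)$gamma
  test_w >= gamma
}

#' Leave-one-out evaluation of a module classifier
#'
#' Successively leaves out each labeled sample, re-optimizes the weight
#' threshold on the remaining labeled samples, and predicts the held-out
#' sample by `weight >= gamma`.  Exactly one prediction per labeled sample is
#' aggregated into confusion counts.
#'
#' @param weights numeric weights (percent) of the labeled samples.
#' @param positive logical phenotype indicator, same length.
#' @param beta F-measure parameter.
#' @return list with `recall`, `precision`, `f`, `confusion` and
#'   `predictions` (logical, one per sample).
#' @export
loo_evaluate <- function(weights, positive, beta = 0.5) {
  n <- length(weights)
  stopifnot(length(positive) == n, is.logical(positive))
  if (sum(positive) < 2L || sum(!positive) < 2L)
    stop("need at least 2 labeled samples per class")
  pred <- vapply(seq_len(n), function(i)
    predict_heldout(weights[-i], positive[-i], weights[i], beta),
    logical(1L))
  cm <- list(tp = sum(pred & positive), fp = sum(pred & !positive),
             fn = sum(!pred & positive), tn = sum(!pred & !positive))
  list(recall = if (sum(positive)) cm$tp / (cm$tp + cm$fn) else 0,
       precision = if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else 0,
       f = f_measure(cm, beta), confusion = cm, predictions = pred)
}

#' Repeated k-fold cross-validation of a module classifier
#'
#' Per repeat, the labeled samples are randomly partitioned into `folds`
#' folds (plain random split by default; `stratified = TRUE` partitions each
#' class separately); per fold the threshold is fitted on the remaining
#' samples and the held-out fold is predicted, giving exactly one prediction
#' per sample per repeat.  Reported are the mean per-repeat accuracy, the
#' macro-accuracy `(TPR + TNR)/2` from the pooled predictions of all
#' repeats, and a Clopper-Pearson 95% interval computed from
#' `round(accuracy_mean * n)` successes of `n` labeled samples.
#'
#' @param weights,positive,beta as in [loo_evaluate()].
#' @param folds number of folds (default 10).
#' @param repeats number of repetitions (default 10).
#' @param seed integer; per-repeat seeds are derived from it.
#' @param conf confidence level for the interval.
#' @param stratified stratify folds by class (default FALSE, plain random).
#' @return list with `accuracy_mean` (percent), `macro_accuracy` (percent),
#'   `ci` (percent low/high), `per_repeat_accuracy`, `n_labeled`.
#' @export
cv_evaluate <- function(weights, positive, beta = 0.5, folds = 10L,
                        repeats = 10L, seed = 1L, conf = 0.95,
                        stratified = FALSE) {
  n <- length(weights)
  stopifnot(length(positive) == n, is.logical(positive), folds >= 2)
  acc <- numeric(repeats)
  pool_tp <- pool_fp <- pool_fn <- pool_tn <- 0L
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    fold_of <- if (stratified) {
      f <- integer(n)
      for (cls in c(TRUE, FALSE)) {
        idx <- which(positive == cls)
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      f
    } else {
      sample(rep_len(seq_len(folds), n))
    }
    pred <- logical(n)
    for (k in seq_len(folds)) {
      test <- which(fold_of == k)
      if (!length(test)) next
      train <- which(fold_of != k)
      pred[test] <- predict_heldout(weights[train], positive[train],
                                    weights[test], beta)
    }
    acc[r] <- mean(pred == positive)
    pool_tp <- pool_tp + sum(pred & positive)
    pool_fp <- pool_fp + sum(pred & !positive)
    pool_fn <- pool_fn + sum(!pred & positive)
    pool_tn <- pool_tn + sum(!pred & !positive)
  }
  tpr <- if (pool_tp + pool_fn > 0) pool_tp / (pool_tp + pool_fn) else 0
  tnr <- if (pool_tn + pool_fp > 0) pool_tn / (pool_tn + pool_fp) else 0
  accuracy_mean <- 100 * mean(acc)
  list(accuracy_mean = accuracy_mean,
       macro_accuracy = 100 * (tpr + tnr) / 2,
       ci = clopper_pearson(round(mean(acc) * n), n, conf),
       per_repeat_accuracy = 100 * acc,
       n_labeled = n)
}

#' Full evaluation report for a set of consensus modules
#'
#' Runs [loo_evaluate()] and [cv_evaluate()] for each consensus module
#' against the labeled samples and assembles a per-module report table
#' (LOO F/recall/precision, CV accuracy and interval, CV macro-accuracy),
#' mirroring a per-module performance summary.
#'
#' @param consensus list of consensus modules from [consensus_modules()]
#'   (each carrying per-sample `weights`).
#' @param labels phenotype label vector (named).
#' @param beta F-measure parameter.
#' @param folds,repeats,seed,stratified passed to [cv_evaluate()].
#' @return data.frame, one row per consensus module.
#' @export
evaluate_consensus <- function(consensus, labels, beta = 0.5, folds = 10L,
                               repeats = 10L, seed = 1L,
                               stratified = FALSE) {
  rows <- lapply(seq_along(consensus), function(i) {
    cm <- consensus[[i]]
    labs <- labels[labels %in% c("positive", "negative")]
    keep <- intersect(names(cm$weights), names(labs))
    w <- cm$weights[keep]
    pos <- unname(labs[keep] == "positive")
    loo <- loo_evaluate(w, pos, beta)
    cv <- cv_evaluate(w, pos, beta, folds = folds, repeats = repeats,
                      seed = seed, stratified = stratified)
    data.frame(consensus_id = paste0("M", i),
               size = length(cm$families), gamma = cm$gamma,
               loo_f = 100 * loo$f, loo_recall = 100 * loo$recall,
               loo_precision = 100 * loo$precision,
               cv_accuracy = cv$accuracy_mean,
               cv_ci_low = cv$ci[["low"]], cv_ci_high = cv$ci[["high"]],
               cv_mac = cv$macro_accuracy, n_labeled = cv$n_labeled)
  })
  do.call(rbind, rows)
}
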