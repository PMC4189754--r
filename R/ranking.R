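#' Completeness-score weight matrix
#'
#' The weight of module `M_t` in document `d` is the percentage of the
#' module's families annotated in the document:
#' `weight_t(d) = |M_t intersect d| / |M_t| * 100`.  Membership uses presence
#' (count >= 1); counts beyond presence do not change the weight.  Columns
#' for empty modules are all zero (reported once via a message).
#'
#' @param modules a `module_set` (or list of character family vectors).
#' @param corpus the `annotation_corpus` the modules were derived from.
#' @return N x T numeric matrix of weights in percent; rownames are sample
#'   ids, colnames `t<k>` by topic index.
#' @examples
#' ann <- data.frame(sample_id = "g1", protein_id = c("p1", "p2", "p3"),
#'                   family_id = c("A", "C", "X"))
#' corp <- build_corpus(ann)
#' completeness_weights(list(c("A", "B", "C", "D")), corp)  # 50
#' @export
completeness_weights <- function(modules, corpus) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  fams <- if (inherits(modules, "module_set")) module_families(modules)
          else lapply(modules, as.character)
  docs <- doc_family_sets(corpus)
  sizes <- lengths(fams)
  if (any(sizes == 0L))
    message(sum(sizes == 0L), " empty module(s); their weights are 0")
  W <- matrix(0, nrow = length(docs), ncol = length(fams),
              dimnames = list(corpus$samples,
                              paste0("t", seq_along(fams))))
  for (t in seq_along(fams)) {
    if (sizes[t] == 0L) next
    W[, t] <- vapply(docs, function(d)
      sum(fams[[t]] %in% d), 1L) / sizes[t] * 100
  }
  W
}

#' F-measure from a confusion matrix
#'
#' `F_beta = (1 + beta^2) P R / (beta^2 P + R)` with precision
#' `P = TP/(TP+FP)` and recall `R = TP/(TP+FN)`.  Degenerate ratios (zero
#' denominators) and `TP = 0` are defined as 0.  The default `beta = 0.5`
#' weights recall half as strongly as precision.
#'
#' @param confusion list or vector with elements `tp`, `fp`, `fn` (and
#'   optionally `tn`, unused).
#' @param beta positive trade-off parameter.
#' @return F score in `[0, 1]`.
#' @export
f_measure <- function(confusion, beta = 0.5) {
  stopifnot(beta > 0)
  tp <- confusion[["tp"]]; fp <- confusion[["fp"]]; fn <- confusion[["fn"]]
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f_from_pr(p, r, beta)
}

#' F-measure from precision and recall
#' @param precision,recall values in `[0, 1]` (vectorized).
#' @param beta positive trade-off parameter.
#' @return F score(s) in `[0, 1]`; 0 where both inputs are 0.
#' @export
f_from_pr <- function(precision, recall, beta = 0.5) {
  stopifnot(beta > 0)
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  ifelse(den > 0, num / den, 0)
}

confusion_at <- function(weights, positive, gamma) {
  pred <- weights >= gamma
  list(tp = sum(pred & positive), fp = sum(pred & !positive),
       fn = sum(!pred & positive), tn = sum(!pred & !positive))
}

#' Optimize a module's classification threshold
#'
#' Exhaustively searches the candidate thresholds -- the distinct weight
#' values observed among labeled samples, plus a sentinel above the maximum
#' (the all-negative classifier) -- for the value gamma maximizing the
#' F_beta score of the rule `weight >= gamma -> positive`.  Ties are broken
#' toward the largest gamma (the most stringent, highest-precision choice).
#'
#' @param weights numeric weights (percent) for the labeled samples.
#' @param positive logical vector, `TRUE` for phenotype-positive samples.
#' @param beta F-measure parameter.
#' @return list with `gamma`, `f`, and `confusion` (tp/fp/fn/tn).
#' @export
optimize_threshold <- function(weights, positive, beta = 0.5) {
  stopifnot(length(weights) == length(positive), is.logical(positive))
  if (!any(positive) || all(positive))
    stop("need at least one positive and one negative labeled sample")
  candidates <- sort(unique(weights))
  candidates <- c(candidates, max(candidates) + 1)  # all-negative sentinel
  best <- NULL
  for (g in candidates) {
    cm <- confusion_at(weights, positive, g)
    f <- f_measure(cm, beta)
    if (is.null(best) || f > best$f ||
        (f == best$f && g > best$gamma))
      best <- list(gamma = g, f = f, confusion = cm)
  }
  best
}

#' Rank candidate modules by phenotype association
#'
#' Applies [optimize_threshold()] to every column of the weight matrix over
#' the labeled samples and sorts modules by decreasing F score (ties broken
#' by topic index, giving a deterministic ranking).
#'
#' @param weights N x T matrix from [completeness_weights()] with sample-id
#'   rownames.
#' @param labels named character vector over
#'   `{"positive","negative","unknown"}`; only labeled samples present in
#'   `weights` enter the optimization.
#' @param beta F-measure parameter.
#' @return data.frame with columns `rank`, `topic_index`, `f_score`, `gamma`,
#'   `tp`, `fp`, `fn`, `tn`, ordered by rank.
#' @export
rank_modules <- function(weights, labels, beta = 0.5) {
  lab <- labeled_subset(weights, labels)
  res <- lapply(seq_len(ncol(weights)), function(t) {
    opt <- optimize_threshold(lab$weights[, t], lab$positive, beta)
    data.frame(topic_index = t, f_score = opt$f, gamma = opt$gamma,
               tp = opt$confusion$tp, fp = opt$confusion$fp,
               fn = opt$confusion$fn, tn = opt$confusion$tn)
  })
  res <- do.call(rbind, res)
  ord <- order(-res$f_score, res$topic_index)
  res <- res[ord, , drop = FALSE]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

# restrict a weight matrix to labeled samples; returns weights + positive flag
labeled_subset <- function(weights, labels) {
  labels <- labels[labels %in% c("positive", "negative")]
  keep <- intersect(rownames(weights), names(labels))
  if (!length(keep)) stop("no labeled samples found in the weight matrix")
  positive <- unname(labels[keep] == "positive")
  if (!any(positive) || all(positive))
    stop("ranking needs both phenotype classes among labeled samples")
  list(weights = weights[keep, , drop = FALSE], positive = positive,
       samples = keep)
}

#' Write a ranking table to TSV
#' @param ranking data.frame from [rank_modules()].
#' @param path file path.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
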