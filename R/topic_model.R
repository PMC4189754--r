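#' LDA configuration
#'
#' Bundles the hyperparameters and sampler settings for [fit_lda()].  The
#' production defaults are 400 topics, symmetric Dirichlet priors
#' `alpha = 50/T` on the document-topic distributions and `beta = 0.01` on
#' the topic-word distributions, a burn-in of 2000 sweeps and 50 collected
#' Gibbs samples.  `alpha` is recomputed from `n_topics` unless given
#' explicitly.
#'
#' @param n_topics number of topics T (>= 2).
#' @param alpha document-topic Dirichlet parameter (default `50/n_topics`).
#' @param beta topic-word Dirichlet parameter.
#' @param burn_in number of burn-in sweeps.
#' @param n_samples number of Gibbs samples collected after burn-in.
#' @param sample_lag sweeps between collected samples.
#' @param seed integer seed making the fit deterministic.
#' @return an `lda_config` list.
#' @export
lda_config <- function(n_topics = 400L, alpha = 50 / n_topics, beta = 0.01,
                       burn_in = 2000L, n_samples = 50L, sample_lag = 10L,
                       seed = 1L) {
  stopifnot(n_topics >= 2, alpha > 0, beta > 0, burn_in >= 0,
            n_samples >= 1, sample_lag >= 1)
  structure(list(n_topics = as.integer(n_topics), alpha = alpha, beta = beta,
                 burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples),
                 sample_lag = as.integer(sample_lag),
                 seed = as.integer(seed)),
            class = "lda_config")
}

#' Scaled-down sampler settings for tests and examples
#'
#' Same model, smaller chain: `n_topics = 20`, `burn_in = 600`,
#' `n_samples = 10`, and `alpha = 0.5` instead of the production `50/T`
#' rule -- at small T that rule yields an overly diffuse document prior
#' (2.5 per topic at T = 20 versus 0.125 at the production T = 400) which
#' makes chains merge distinct topics.  Production-scale defaults remain
#' those of [lda_config()].
#'
#' @param ... overrides passed to [lda_config()].
#' @return an `lda_config`.
#' @export
lda_config_small <- function(...) {
  defaults <- list(n_topics = 20L, burn_in = 600L, n_samples = 10L,
                   alpha = 0.5)
  args <- utils::modifyList(defaults, list(...))
  do.call(lda_config, args)
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Each family count c in a document contributes c word tokens.  Token-topic
#' assignments are resampled from the collapsed full conditional
#' `(n_wt + beta)/(n_t + V beta) * (n_dt + alpha)`; after `burn_in` sweeps,
#' `n_samples` states are collected every `sample_lag` sweeps and the
#' posterior-mean estimates of the topic-word distributions `phi` (T x V) and
#' document-topic distributions `theta` (N x T) are averaged across samples.
#' The fit is deterministic given `config$seed`.
#'
#' @param corpus an `annotation_corpus` with nonempty vocabulary.
#' @param config an [lda_config()].
#' @return a `topic_model`: list with `phi`, `theta`, `config`,
#'   `corpus_hash`, `samples`, `vocabulary` and the final sampler count state
#'   (`ndt`, `nwt`, `nt`).
#' @examples
#' sim <- generate_corpus(synthetic_spec(n_pos = 5, n_neg = 5, n_unlabeled = 0,
#'                                       vocab_size = 30, seed = 1))
#' fit <- fit_lda(sim$corpus, lda_config_small(n_topics = 4, burn_in = 20,
#'                                             n_samples = 2, seed = 1))
#' rowSums(fit$phi)[1:2]
#' @export
fit_lda <- function(corpus, config = lda_config()) {
  stopifnot(inherits(corpus, "annotation_corpus"),
            inherits(config, "lda_config"))
  if (length(corpus$vocabulary) < 1L) stop("empty vocabulary")
  if (config$n_topics < 2L) stop("n_topics must be >= 2")
  tokens <- corpus_tokens(corpus)
  if (length(tokens$doc) == 0L) stop("corpus has no tokens")

  set.seed(config$seed)
  fit <- gibbs_lda_cpp(tokens$doc - 1L, tokens$word - 1L,
                       n_docs = length(corpus$samples),
                       n_vocab = length(corpus$vocabulary),
                       n_topics = config$n_topics,
                       alpha = config$alpha, beta = config$beta,
                       burn_in = config$burn_in,
                       n_samples = config$n_samples,
                       sample_lag = config$sample_lag)
  dimnames(fit$phi) <- list(NULL, corpus$vocabulary)
  dimnames(fit$theta) <- list(corpus$samples, NULL)
  structure(list(phi = fit$phi, theta = fit$theta, config = config,
                 corpus_hash = corpus_hash(corpus),
                 samples = corpus$samples, vocabulary = corpus$vocabulary,
                 ndt = fit$ndt, nwt = fit$nwt, nt = fit$nt),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("topic_model: %d topics, %d documents, %d families\n",
              nrow(x$phi), nrow(x$theta), ncol(x$phi)))
  invisible(x)
}

# expand capped counts into parallel doc/word token index vectors
corpus_tokens <- function(corpus) {
  list(doc = rep(corpus$counts$doc, corpus$counts$count),
       word = rep(corpus$counts$word, corpus$counts$count))
}

corpus_hash <- function(corpus) {
  rlang::hash(list(corpus$samples, corpus$vocabulary, corpus$counts))
}

#' Convert topic distributions into discrete candidate modules
#'
#' Module `M_t = {w in V : phi_t(w) >= cutoff}`.  With the default cutoff
#' `C = 0.01` a uniform topic over a vocabulary larger than 100 families
#' yields an empty module; concentrated topics yield small, interpretable
#' family sets.  Family sets shrink (or stay equal) as the cutoff grows.
#'
#' @param model a `topic_model`.
#' @param cutoff probability threshold C in (0, 1).
#' @return a `module_set`: list of modules, each a list with `topic_index`
#'   (1-based), `families` (character) and `cutoff`.
#' @export
extract_modules <- function(model, cutoff = 0.01) {
  stopifnot(inherits(model, "topic_model"), cutoff > 0, cutoff < 1)
  vocab <- colnames(model$phi)
  mods <- lapply(seq_len(nrow(model$phi)), function(t) {
    list(topic_index = t,
         families = vocab[model$phi[t, ] >= cutoff],
         cutoff = cutoff)
  })
  structure(mods, class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x, function(m) length(m$families), 1L)
  cat(sprintf("module_set: %d modules, sizes %d-%d (median %.0f)\n",
              length(x), min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' Family sets of a module_set
#' @param modules a `module_set`.
#' @return list of character vectors, one per topic.
#' @export
module_families <- function(modules) lapply(modules, `[[`, "families")

#' Serialize / deserialize a fitted topic model (JSON)
#'
#' @param model a `topic_model`.
#' @param path file path.
#' @return `read_topic_model` returns the model; matrices are restored with
#'   dimnames, numeric values round-trip at full double precision.
#' @export
write_topic_model <- function(model, path) {
  stopifnot(inherits(model, "topic_model"))
  payload <- list(phi = model$phi, theta = model$theta,
                  config = unclass(model$config),
                  corpus_hash = model$corpus_hash,
                  samples = model$samples, vocabulary = model$vocabulary)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_topic_model
#' @export
read_topic_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  phi <- as.matrix(p$phi); colnames(phi) <- p$vocabulary
  theta <- as.matrix(p$theta); rownames(theta) <- p$samples
  cfg <- do.call(lda_config, as.list(p$config)[c("n_topics", "alpha", "beta",
                                                 "burn_in", "n_samples",
                                                 "sample_lag", "seed")])
  structure(list(phi = phi, theta = theta, config = cfg,
                 corpus_hash = p$corpus_hash, samples = p$samples,
                 vocabulary = p$vocabulary),
            class = "topic_model")
}
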