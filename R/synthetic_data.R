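#' Specification of a synthetic annotation corpus
#'
#' Describes a corpus generated by the topic-model generative process run
#' forward, with planted phenotype-enriched modules as ground truth.  The
#' defaults mirror the shape of a real learning set: 38 phenotype-positive
#' and 82 phenotype-negative samples plus 80 unlabeled ones, a vocabulary of
#' 300 families, 12 true topics of which 3 (sizes 18, 23 and 13 families)
#' are phenotype modules.  Module carriage is modeled per document and per
#' module: a positive document carries each phenotype module independently
#' with probability `pos_module_prob` (real degraders do not all carry every
#' module), a negative one with the small probability `neg_module_prob`
#' (module-like gene sets occur occasionally outside the phenotype, which is
#' why observed precisions sit below 100%).  A carried module contributes
#' Dirichlet mass `alpha_phenotype * enrichment` to the document's topic
#' prior; an uncarried module contributes none, so carriage fully determines
#' module presence.  The defaults emulate strongly phenotype-defining
#' modules (per-module recall near 0.95, about one module-carrying
#' non-degrader per hundred).  The independent carriage patterns also give
#' the topic model the document-level variation it needs to keep the
#' planted modules apart.
#'
#' @param n_pos,n_neg,n_unlabeled sample counts per label class.
#' @param vocab_size vocabulary size V.
#' @param n_topics_true number of true topics (phenotype + background).
#' @param module_sizes sizes of the planted phenotype modules.
#' @param doc_length Poisson mean of the token count per document.
#' @param alpha_background Dirichlet mass of each background topic.
#' @param alpha_phenotype base unit of phenotype-topic mass; a carried
#'   module's Dirichlet mass is `alpha_phenotype * enrichment`.
#' @param enrichment multiplier for a carried module's topic mass (>= 1).
#' @param pos_module_prob per-module carriage probability in positive
#'   documents.
#' @param neg_module_prob per-module carriage probability in negative
#'   documents.
#' @param concentration within-topic Dirichlet concentration of the
#'   topic-word distributions over the topic's support.
#' @param smoothing small probability mass spread uniformly over the whole
#'   vocabulary (keeps distributions strictly positive).
#' @param unlabeled_pos_frac fraction of unlabeled documents generated from
#'   the positive-document prior (hidden truth, recorded).
#' @param cap per-family count cap applied when converting tokens to counts.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 38L, n_neg = 82L, n_unlabeled = 80L,
                           vocab_size = 300L, n_topics_true = 12L,
                           module_sizes = c(18L, 23L, 13L),
                           doc_length = 150, alpha_background = 0.5,
                           alpha_phenotype = 0.04, enrichment = 100,
                           pos_module_prob = 0.95, neg_module_prob = 0.01,
                           concentration = 5, smoothing = 0.005,
                           unlabeled_pos_frac = 0.25, cap = 10L,
                           seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_unlabeled >= 0,
            vocab_size >= sum(module_sizes),
            n_topics_true > length(module_sizes),
            enrichment >= 1, doc_length > 0, cap >= 1,
            pos_module_prob >= 0, pos_module_prob <= 1,
            neg_module_prob >= 0, neg_module_prob <= 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_unlabeled = as.integer(n_unlabeled),
                 vocab_size = as.integer(vocab_size),
                 n_topics_true = as.integer(n_topics_true),
                 module_sizes = as.integer(module_sizes),
                 doc_length = doc_length,
                 alpha_background = alpha_background,
                 alpha_phenotype = alpha_phenotype,
                 enrichment = enrichment,
                 pos_module_prob = pos_module_prob,
                 neg_module_prob = neg_module_prob,
                 concentration = concentration,
                 smoothing = smoothing,
                 unlabeled_pos_frac = unlabeled_pos_frac,
                 cap = as.integer(cap), seed = as.integer(seed)),
            class = "synthetic_spec")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a synthetic corpus with planted phenotype modules
#'
#' Runs the generative process forward: topic-word distributions are built
#' on disjoint family supports (phenotype modules first, the remaining
#' vocabulary split across background topics) with a within-support
#' Dirichlet draw plus uniform smoothing; per document a topic distribution
#' theta is drawn from the label-dependent Dirichlet prior, tokens are drawn
#' topic-then-word, and token counts are truncated at `spec$cap`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `corpus` (an `annotation_corpus`), `phenotypes` (named
#'   labels incl. `"unknown"`), and `truth` (planted module family sets,
#'   true phi/theta, hidden labels of unlabeled samples, the spec).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  V <- spec$vocab_size
  Tt <- spec$n_topics_true
  k <- length(spec$module_sizes)
  vocab <- sprintf("F%04d", seq_len(V))

  # disjoint topic supports: phenotype modules first, then background split
  perm <- sample(V)
  offsets <- cumsum(c(0L, spec$module_sizes))
  planted <- lapply(seq_len(k), function(i)
    sort(vocab[perm[(offsets[i] + 1L):offsets[i + 1L]]]))
  rest <- perm[(offsets[k + 1L] + 1L):V]
  bg_assign <- rep_len(seq_len(Tt - k), length(rest))
  supports <- c(lapply(planted, function(f) match(f, vocab)),
                split(rest, bg_assign))

  phi_true <- matrix(spec$smoothing / V, nrow = Tt, ncol = V,
                     dimnames = list(NULL, vocab))
  for (t in seq_len(Tt)) {
    s <- supports[[t]]
    w <- rdirichlet1(rep(spec$concentration, length(s)))
    phi_true[t, s] <- phi_true[t, s] + (1 - spec$smoothing) * w
  }

  n_docs <- spec$n_pos + spec$n_neg + spec$n_unlabeled
  labels <- c(rep("positive", spec$n_pos), rep("negative", spec$n_neg),
              rep("unknown", spec$n_unlabeled))
  hidden <- labels
  if (spec$n_unlabeled > 0L) {
    is_pos <- runif(spec$n_unlabeled) < spec$unlabeled_pos_frac
    hidden[labels == "unknown"] <- ifelse(is_pos, "positive", "negative")
  }
  samples <- sprintf("s%03d", seq_len(n_docs))

  alpha_base <- c(rep(spec$alpha_phenotype, k),
                  rep(spec$alpha_background, Tt - k))
  theta_true <- matrix(0, n_docs, Tt, dimnames = list(samples, NULL))
  carriage <- matrix(FALSE, n_docs, k, dimnames = list(samples, NULL))
  rows <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    alpha <- alpha_base
    p_carry <- if (hidden[d] == "positive") spec$pos_module_prob
               else spec$neg_module_prob
    carried <- runif(k) < p_carry
    carriage[d, ] <- carried
    alpha[seq_len(k)] <- ifelse(carried,
                                spec$alpha_phenotype * spec$enrichment, 0)
    theta <- rdirichlet1(alpha)
    theta_true[d, ] <- theta
    n_tok <- rpois(1L, spec$doc_length)
    if (n_tok == 0L) next
    z <- sample.int(Tt, n_tok, replace = TRUE, prob = theta)
    w <- vapply(z, function(t)
      sample.int(V, 1L, prob = phi_true[t, ]), 1L)
    tab <- table(w)
    rows[[d]] <- data.frame(doc = d, word = as.integer(names(tab)),
                            count = pmin(as.integer(tab), spec$cap))
  }
  counts <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(counts))
    counts <- data.frame(doc = integer(), word = integer(),
                         count = integer())
  ord <- order(counts$doc, counts$word)
  corpus <- structure(list(samples = samples,
                           source_kind = rep("genome", n_docs),
                           vocabulary = vocab,
                           counts = counts[ord, , drop = FALSE],
                           cap = spec$cap),
                      class = "annotation_corpus")
  rownames(corpus$counts) <- NULL
  list(corpus = corpus,
       phenotypes = setNames(labels, samples),
       truth = list(planted_modules = planted, phi_true = phi_true,
                    theta_true = theta_true, carriage = carriage,
                    hidden_labels = setNames(hidden, samples),
                    spec = spec))
}

#' Generate a gene table with planted clusters and decoys
#'
#' Plants `n_planted` gene clusters that satisfy the detection criteria
#' (>= `min_genes` genes annotated with module families, every intergenic
#' gap <= `max_gap`, >= 2 distinct families) and `n_decoys` decoy layouts
#' that each violate exactly one criterion (an oversized gap, too few genes,
#' or a single distinct family, cycling).  Each layout sits on its own
#' replicon, so planted spans never merge.
#'
#' @param pdm_families character vector of module family ids (>= 2).
#' @param n_planted,n_decoys number of planted clusters / decoys.
#' @param max_gap,min_genes detection parameters the plants must satisfy.
#' @param sample_id sample id for all records.
#' @param seed integer seed.
#' @return list with `genes` (data.frame for [detect_clusters()]) and
#'   `truth` (data.frame: replicon, kind = planted/decoy, violated
#'   criterion).
#' @export
generate_gene_table <- function(pdm_families, n_planted = 5L, n_decoys = 5L,
                                max_gap = 2000L, min_genes = 4L,
                                sample_id = "g1", seed = 1L) {
  stopifnot(length(pdm_families) >= 2L)
  set.seed(seed)
  genes <- list(); truth <- list()
  make_chain <- function(replicon, n, gaps, fams) {
    start <- sample(1000:5000, 1L)
    lens <- sample(600:1800, n, replace = TRUE)
    starts <- ends <- integer(n)
    for (i in seq_len(n)) {
      starts[i] <- if (i == 1L) start else ends[i - 1L] + gaps[i - 1L] + 1L
      ends[i] <- starts[i] + lens[i] - 1L
    }
    data.frame(sample_id = sample_id, replicon_id = replicon,
               gene_id = paste0(replicon, "_g", seq_len(n)),
               start = starts, end = ends,
               strand = sample(c("+", "-"), n, replace = TRUE),
               families = fams)
  }
  pick_fams <- function(n, distinct = 2L) {
    base <- sample(pdm_families, min(distinct, length(pdm_families)))
    c(base, sample(pdm_families, n - length(base), replace = TRUE))
  }
  for (i in seq_len(n_planted)) {
    rep_id <- sprintf("plant%02d", i)
    n <- sample(min_genes:(min_genes + 4L), 1L)
    genes[[length(genes) + 1L]] <-
      make_chain(rep_id, n, sample(0:max_gap, n - 1L, replace = TRUE),
                 pick_fams(n))
    truth[[length(truth) + 1L]] <-
      data.frame(replicon_id = rep_id, kind = "planted", violates = "none")
  }
  violations <- rep_len(c("gap", "size", "families"), n_decoys)
  for (i in seq_len(n_decoys)) {
    rep_id <- sprintf("decoy%02d", i)
    v <- violations[i]
    if (v == "gap") {
      n <- min_genes
      gaps <- sample(0:max_gap, n - 1L, replace = TRUE)
      gaps[sample(n - 1L, 1L)] <- max_gap + sample(500:2000, 1L)
      g <- make_chain(rep_id, n, gaps, pick_fams(n))
    } else if (v == "size") {
      n <- min_genes - 1L
      g <- make_chain(rep_id, n,
                      sample(0:max_gap, n - 1L, replace = TRUE),
                      pick_fams(n))
    } else {
      n <- min_genes
      g <- make_chain(rep_id, n,
                      sample(0:max_gap, n - 1L, replace = TRUE),
                      rep(sample(pdm_families, 1L), n))
    }
    genes[[length(genes) + 1L]] <- g
    truth[[length(truth) + 1L]] <-
      data.frame(replicon_id = rep_id, kind = "decoy", violates = v)
  }
  list(genes = do.call(rbind, genes), truth = do.call(rbind, truth))
}
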