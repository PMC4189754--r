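#' Jaccard distance between two family sets
#'
#' `1 - |A ∩ B| / |A ∪ B|`; the distance between two empty sets is 0.
#'
#' @param a,b character vectors (treated as sets).
#' @return value in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  1 - length(intersect(a, b)) / u
}

#' Symmetrized Kullback-Leibler distance between two topic distributions
#'
#' `0.5 KL(p||q) + 0.5 KL(q||p)` with natural logarithms.  Both inputs must
#' be strictly positive everywhere (the beta-smoothed phi estimates from
#' [fit_lda()] always are); a zero entry is an error rather than silently
#' producing an infinite divergence.
#'
#' @param p,q probability vectors over the same vocabulary.
#' @return non-negative real.
#' @export
sym_kl_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p <= 0) || any(q <= 0))
    stop("sym_kl_distance requires strictly positive distributions")
  0.5 * sum(p * log(p / q)) + 0.5 * sum(q * log(q / p))
}

#' Minimum-cost perfect matching (Hungarian algorithm)
#'
#' Finds the bijection between the rows and columns of a square distance
#' matrix that minimizes the total distance, via the O(n^3)
#' shortest-augmenting-path formulation with potentials.
#'
#' @param D square matrix of finite non-negative distances.
#' @return list with `assignment` (integer vector; row i is matched to
#'   column `assignment[i]`) and `cost` (total distance of the matching).
#' @examples
#' hungarian_mapping(rbind(c(1, 2), c(2, 1)))$assignment  # 1 2
#' @export
hungarian_mapping <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(!is.finite(D)) || any(D < 0))
    stop("distances must be finite and non-negative")
  assignment <- hungarian_cpp(D)
  list(assignment = assignment,
       cost = sum(D[cbind(seq_len(nrow(D)), assignment)]))
}

#' Fit repeated LDA runs on one corpus
#'
#' Runs [fit_lda()] `n_runs` times with per-run seeds derived from
#' `config$seed` (seed + run index - 1), extracts modules at `cutoff` and
#' ranks them against the labels.  Runs execute sequentially; each run is
#' independently reproducible from its derived seed.
#'
#' @param corpus an `annotation_corpus`.
#' @param labels phenotype label vector (see [rank_modules()]).
#' @param config an [lda_config()]; its seed is the master seed.
#' @param n_runs number of repeated runs R (paper-scale default 18).
#' @param cutoff module extraction cutoff C.
#' @param beta_f F-measure parameter used for ranking.
#' @return a `run_collection`: list of runs, each with `model`, `modules`,
#'   `ranking`; attributes `corpus_hash` and `n_runs`.
#' @export
lda_runs <- function(corpus, labels, config = lda_config(), n_runs = 18L,
                     cutoff = 0.01, beta_f = 0.5) {
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    model <- fit_lda(corpus, cfg)
    modules <- extract_modules(model, cutoff)
    W <- completeness_weights(modules, corpus)
    list(model = model, modules = modules,
         ranking = rank_modules(W, labels, beta_f), weights = W)
  })
  structure(runs, class = "run_collection",
            corpus_hash = corpus_hash(corpus), n_runs = n_runs)
}

#' Build the inter-run module graph
#'
#' Nodes are each run's top-`top_k` ranked modules; edges join similar
#' modules of different runs.  Under the default `edge_rule = "threshold"`,
#' every inter-run node pair with distance at most `d_max` becomes an edge;
#' this tolerates chains that split a module into near-duplicate topics,
#' since all duplicates stay adjacent to the module's representatives in
#' other runs and the clique search later picks one per run.  Under
#' `edge_rule = "hungarian"`, each run pair's full T x T distance matrix is
#' first reduced to a bijection with [hungarian_mapping()] and only matched
#' pairs within `d_max` become edges (one-to-one tracking; brittle when
#' topics are duplicated, see the methods vignette).  With
#' `filter_before_matching = TRUE` the Hungarian variant matches only the
#' top-k modules (padded to a square with distance 1).
#'
#' @param runs a `run_collection` (>= 2 runs).
#' @param distance `"jaccard"` (on discrete family sets, default) or
#'   `"sym_kl"` (on smoothed phi rows).
#' @param d_max maximum distance for an edge.
#' @param top_k per-run ranking depth (default 15).
#' @param edge_rule `"threshold"` or `"hungarian"` (see above).
#' @param filter_before_matching apply the top-k filter before Hungarian
#'   matching rather than to its output edges.
#' @return a `module_graph`: list with `nodes` (data.frame run, topic) and
#'   `edges` (data.frame run1, topic1, run2, topic2, dist).
#' @export
build_module_graph <- function(runs, distance = c("jaccard", "sym_kl"),
                               d_max = 0.7, top_k = 15L,
                               edge_rule = c("threshold", "hungarian"),
                               filter_before_matching = FALSE) {
  edge_rule <- match.arg(edge_rule)
  distance <- match.arg(distance)
  if (length(runs) < 2L) stop("need at least 2 runs")
  stopifnot(d_max > 0)
  R <- length(runs)
  n_topics <- length(runs[[1L]]$modules)
  top <- lapply(runs, function(r)
    r$ranking$topic_index[seq_len(min(top_k, nrow(r$ranking)))])
  fams <- lapply(runs, function(r) module_families(r$modules))

  pair_dist <- function(r1, r2, idx1, idx2) {
    if (distance == "jaccard") {
      D <- matrix(1, length(idx1), length(idx2))
      for (i in seq_along(idx1))
        for (j in seq_along(idx2))
          D[i, j] <- jaccard_distance(fams[[r1]][[idx1[i]]],
                                      fams[[r2]][[idx2[j]]])
    } else {
      D <- matrix(0, length(idx1), length(idx2))
      for (i in seq_along(idx1))
        for (j in seq_along(idx2))
          D[i, j] <- sym_kl_distance(runs[[r1]]$model$phi[idx1[i], ],
                                     runs[[r2]]$model$phi[idx2[j], ])
    }
    D
  }

  edges <- list()
  for (r1 in seq_len(R - 1L)) {
    for (r2 in seq(r1 + 1L, R)) {
      if (edge_rule == "threshold") {
        idx1 <- top[[r1]]; idx2 <- top[[r2]]
        D <- pair_dist(r1, r2, idx1, idx2)
        hit <- which(D <= d_max, arr.ind = TRUE)
        for (h in seq_len(nrow(hit)))
          edges[[length(edges) + 1L]] <-
            data.frame(run1 = r1, topic1 = idx1[hit[h, 1L]],
                       run2 = r2, topic2 = idx2[hit[h, 2L]],
                       dist = D[hit[h, 1L], hit[h, 2L]])
      } else if (filter_before_matching) {
        idx1 <- top[[r1]]; idx2 <- top[[r2]]
        n <- max(length(idx1), length(idx2))
        D <- matrix(max(1, d_max + 1), n, n)  # padding: never an edge
        D[seq_along(idx1), seq_along(idx2)] <- pair_dist(r1, r2, idx1, idx2)
        map <- hungarian_mapping(D)$assignment
        for (i in seq_along(idx1)) {
          j <- map[i]
          if (j > length(idx2)) next
          d <- D[i, j]
          if (d <= d_max)
            edges[[length(edges) + 1L]] <-
              data.frame(run1 = r1, topic1 = idx1[i],
                         run2 = r2, topic2 = idx2[j], dist = d)
        }
      } else {
        D <- pair_dist(r1, r2, seq_len(n_topics), seq_len(n_topics))
        map <- hungarian_mapping(D)$assignment
        for (i in seq_len(n_topics)) {
          j <- map[i]
          if (i %in% top[[r1]] && j %in% top[[r2]] && D[i, j] <= d_max)
            edges[[length(edges) + 1L]] <-
              data.frame(run1 = r1, topic1 = i, run2 = r2, topic2 = j,
                         dist = D[i, j])
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(run1 = integer(), topic1 = integer(),
                           run2 = integer(), topic2 = integer(),
                           dist = numeric())
  nodes <- unique(do.call(rbind, lapply(seq_len(R), function(r)
    data.frame(run = r, topic = top[[r]]))))
  structure(list(nodes = nodes, edges = edges, n_runs = R),
            class = "module_graph")
}

node_id <- function(run, topic) paste0(run, ":", topic)

#' Find stable cross-run module cliques
#'
#' Enumerates maximal cliques of the module graph (Bron-Kerbosch with
#' pivoting, via igraph) and keeps those spanning at least `min_runs`
#' distinct runs.  Since the graph has no intra-run edges, every clique has
#' at most one module per run, so the clique size equals the number of runs
#' spanned.  Overlapping retained cliques are resolved greedily: larger
#' cliques win, ties go to the clique with the smaller mean internal
#' distance.
#'
#' @param graph a `module_graph`.
#' @param min_runs minimum number of runs a clique must span (default
#'   `ceiling(0.75 * n_runs)`).
#' @return list of cliques, each a data.frame with columns `run`, `topic`.
#' @export
find_stable_cliques <- function(graph,
                                min_runs = ceiling(0.75 * graph$n_runs)) {
  if (nrow(graph$edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = node_id(graph$edges$run1, graph$edges$topic1),
               to = node_id(graph$edges$run2, graph$edges$topic2)),
    directed = FALSE,
    vertices = data.frame(name = node_id(graph$nodes$run,
                                         graph$nodes$topic)))
  cliques <- igraph::max_cliques(g, min = min_runs)
  if (!length(cliques)) return(list())

  dist_lookup <- graph$edges
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  dist_map <- setNames(dist_lookup$dist,
                       key(node_id(dist_lookup$run1, dist_lookup$topic1),
                           node_id(dist_lookup$run2, dist_lookup$topic2)))
  mean_internal <- function(ids) {
    pairs <- utils::combn(sort(ids), 2L)
    mean(dist_map[key(pairs[1L, ], pairs[2L, ])], na.rm = TRUE)
  }
  ids_list <- lapply(cliques, function(cl) igraph::V(g)$name[cl])
  ord <- order(-lengths(ids_list),
               vapply(ids_list, mean_internal, 1.0))
  kept <- list()
  used <- character()
  for (i in ord) {
    ids <- ids_list[[i]]
    if (any(ids %in% used)) next
    used <- c(used, ids)
    parts <- strsplit(ids, ":", fixed = TRUE)
    kept[[length(kept) + 1L]] <-
      data.frame(run = as.integer(vapply(parts, `[[`, "", 1L)),
                 topic = as.integer(vapply(parts, `[[`, "", 2L)))
  }
  kept
}

#' Build a consensus module from a clique of matched modules
#'
#' The consensus family set contains every family occurring in at least
#' `quorum` of the clique's member modules; families below the quorum are
#' reported separately as `sub_quorum`.
#'
#' @param clique_families list of character family sets (one per clique
#'   member module).
#' @param quorum minimum number of member modules a family must occur in
#'   (default 9).
#' @return a `consensus_module`: list with `families`, `sub_quorum`,
#'   `family_counts` (named integer), `n_members`, `quorum`.
#' @export
build_consensus <- function(clique_families, quorum = 9L) {
  n <- length(clique_families)
  if (quorum > n)
    stop("quorum (", quorum, ") exceeds clique size (", n, ")")
  if (quorum < 1L) stop("quorum must be >= 1")
  counts <- table(unlist(lapply(clique_families, unique)))
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(families = sort(names(counts)[counts >= quorum]),
                 sub_quorum = sort(names(counts)[counts < quorum]),
                 family_counts = counts, n_members = n,
                 quorum = as.integer(quorum)),
            class = "consensus_module")
}

#' @export
print.consensus_module <- function(x, ...) {
  cat(sprintf("consensus_module: %d families (quorum %d of %d members), %d sub-quorum\n",
              length(x$families), x$quorum, x$n_members,
              length(x$sub_quorum)))
  invisible(x)
}

#' Derive consensus modules from a run collection
#'
#' Chains [build_module_graph()], [find_stable_cliques()] and
#' [build_consensus()], then optimizes each consensus module's
#' classification threshold on the full learning set.  Consensus modules are
#' ordered by decreasing F score.
#'
#' @param runs a `run_collection` (with the corpus used below).
#' @param corpus the shared `annotation_corpus`.
#' @param labels phenotype labels (see [rank_modules()]).
#' @param distance,d_max,top_k,edge_rule passed to [build_module_graph()].
#' @param min_runs_frac fraction of runs a stable clique must span (0.75).
#' @param quorum family quorum within a clique; default
#'   `ceiling(0.5 * n_runs)`, i.e. 9 at the paper-scale 18 runs, so the rule
#'   generalizes to smaller run collections.
#' @param beta_f F-measure parameter.
#' @return list of consensus modules, each additionally carrying `gamma`,
#'   `f_score`, `confusion`, `clique` and `weights` (per-sample completeness
#'   of the consensus family set).
#' @export
consensus_modules <- function(runs, corpus, labels,
                              distance = "jaccard", d_max = 0.7,
                              top_k = 15L, edge_rule = "threshold",
                              min_runs_frac = 0.75,
                              quorum = NULL, beta_f = 0.5) {
  if (is.null(quorum)) quorum <- ceiling(0.5 * length(runs))
  graph <- build_module_graph(runs, distance = distance, d_max = d_max,
                              top_k = top_k, edge_rule = edge_rule)
  min_runs <- ceiling(min_runs_frac * length(runs))
  cliques <- find_stable_cliques(graph, min_runs = min_runs)
  if (!length(cliques)) return(list())
  fams <- lapply(runs, function(r) module_families(r$modules))
  out <- lapply(cliques, function(cl) {
    member_fams <- lapply(seq_len(nrow(cl)), function(i)
      fams[[cl$run[i]]][[cl$topic[i]]])
    cons <- build_consensus(member_fams, quorum = min(quorum, nrow(cl)))
    W <- completeness_weights(list(cons$families), corpus)
    lab <- labeled_subset(W, labels)
    opt <- optimize_threshold(lab$weights[, 1L], lab$positive, beta_f)
    cons$gamma <- opt$gamma
    cons$f_score <- opt$f
    cons$confusion <- opt$confusion
    cons$clique <- cl
    cons$weights <- W[, 1L]
    cons
  })
  out[order(-vapply(out, `[[`, 1.0, "f_score"))]
}

#' Export consensus modules to TSV
#'
#' One row per (consensus module, family) with the member-module occurrence
#' count and whether the family met the quorum.
#'
#' @param consensus list of `consensus_module`s.
#' @param path file path.
#' @export
write_consensus <- function(consensus, path) {
  rows <- lapply(seq_along(consensus), function(i) {
    cm <- consensus[[i]]
    fams <- names(cm$family_counts)
    data.frame(consensus_id = paste0("M", i), family_id = fams,
               n_member_modules = unname(cm$family_counts),
               in_consensus = fams %in% cm$families)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
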