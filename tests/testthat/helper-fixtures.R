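# Shared fixtures, built in code.

# tiny deterministic corpus: 4 documents over 6 families
tiny_corpus <- function() {
  ann <- data.frame(
    sample_id = c("g1", "g1", "g1", "g2", "g2", "g3", "g3", "g3", "g4"),
    protein_id = paste0("p", 1:9),
    family_id = c("GH5", "GH9", "PF00041", "GH5", "GH9",
                  "PL1", "PL9", "GH28", "PL1"))
  build_corpus(ann)
}

# two disjoint word blocks; block A words co-occur only with A, B with B
block_corpus <- function(n_docs_per_block = 12L, tokens_per_doc = 30L,
                         seed = 42L) {
  set.seed(seed)
  blockA <- paste0("A", 1:5)
  blockB <- paste0("B", 1:5)
  ann <- do.call(rbind, lapply(seq_len(2L * n_docs_per_block), function(d) {
    block <- if (d <= n_docs_per_block) blockA else blockB
    fams <- sample(block, tokens_per_doc, replace = TRUE)
    data.frame(sample_id = sprintf("d%02d", d),
               protein_id = sprintf("d%02d_p%02d", d,
                                    seq_len(tokens_per_doc)),
               family_id = fams)
  }))
  build_corpus(ann)
}

# small labeled weight fixture with a known best threshold
make_labels <- function(pos, neg) {
  setNames(c(rep("positive", length(pos)), rep("negative", length(neg))),
           c(pos, neg))
}

# brute-force F-optimal threshold search, independent of optimize_threshold
brute_force_threshold <- function(weights, positive, beta = 0.5) {
  candidates <- c(sort(unique(weights)), max(weights) + 1)
  best <- NULL
  for (g in candidates) {
    pred <- weights >= g
    tp <- sum(pred & positive); fp <- sum(pred & !positive)
    fn <- sum(!pred & positive)
    f <- if (tp == 0) 0 else {
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      (1 + beta^2) * p * r / (beta^2 * p + r)
    }
    if (is.null(best) || f > best$f || (f == best$f && g > best$gamma))
      best <- list(gamma = g, f = f)
  }
  best
}

# brute-force minimal-cost assignment over all permutations (n <= 7)
brute_force_assignment <- function(D) {
  n <- nrow(D)
  perms <- permutations_of(n)
  costs <- vapply(perms, function(p)
    sum(D[cbind(seq_len(n), p)]), 1.0)
  list(cost = min(costs), assignment = perms[[which.min(costs)]])
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in permutations_of(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(sub, n, pos)
  out
}

# brute-force maximal clique enumeration by subset testing (n <= 12)
brute_force_max_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(members) < 1L) next
    ok <- TRUE
    if (length(members) > 1L) {
      pairs <- utils::combn(members, 2L)
      ok <- all(adj[t(pairs)] == 1L)
    }
    if (ok) cliques[[length(cliques) + 1L]] <- members
  }
  # keep maximal ones
  is_max <- vapply(cliques, function(a)
    !any(vapply(cliques, function(b)
      length(b) > length(a) && all(a %in% b), TRUE)), TRUE)
  cliques[is_max]
}

# brute-force cluster finder: test every window of PDM-annotated genes
brute_force_clusters <- function(genes, pdm, max_gap = 2000L,
                                 min_genes = 4L, min_fam = 2L) {
  out <- list()
  keys <- paste(genes$sample_id, genes$replicon_id, sep = "\r")
  for (key in unique(keys)) {
    sel <- genes[keys == key, ]
    sel <- sel[order(sel$start, sel$end), ]
    fam <- lapply(strsplit(ifelse(is.na(sel$families), "", sel$families),
                           ";", fixed = TRUE),
                  intersect, pdm)
    ann <- which(lengths(fam) > 0L)
    if (length(ann) < min_genes) next
    # all maximal windows over annotated genes with every gap <= max_gap
    gaps <- if (length(ann) > 1L)
      pmax(0, sel$start[ann[-1L]] - sel$end[ann[-length(ann)]] - 1)
    else numeric(0)
    brk <- c(TRUE, gaps > max_gap)
    grp <- cumsum(brk)
    for (gidx in unique(grp)) {
      m <- ann[grp == gidx]
      if (length(m) < min_genes) next
      fams <- unique(unlist(fam[m]))
      if (length(fams) < min_fam) next
      out[[length(out) + 1L]] <-
        list(genes = sel$gene_id[m], start = min(sel$start[m]),
             end = max(sel$end[m]))
    }
  }
  out
}

# scaled-down end-to-end pipeline wrapper used in several tests
small_pipeline <- function(seed) {
  sim <- generate_corpus(synthetic_spec(seed = seed))
  res <- run_pipeline(sim$corpus, sim$phenotypes,
                      pipeline_config(scale = "test", seed = seed))
  list(sim = sim, res = res)
}
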