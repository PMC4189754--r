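#' Predict module occurrences in samples
#'
#' Applies the rule `predict(d, M_t, gamma_t) = 1 iff weight_t(d) >= gamma_t`
#' to every (sample, module) pair.  Thresholds come from optimizing each
#' module on the full learning set; prediction is typically applied to the
#' unlabeled samples.
#'
#' @param weights N x T completeness-weight matrix (percent) with sample-id
#'   rownames and module-id colnames.
#' @param gammas named numeric vector of thresholds (percent); names must
#'   match columns of `weights`.
#' @param samples optional character vector restricting the output rows.
#' @return data.frame with columns `sample_id`, `module_id`, `weight`,
#'   `gamma`, `predicted` (0/1).
#' @export
predict_occurrences <- function(weights, gammas, samples = NULL) {
  if (is.null(names(gammas)) || !all(names(gammas) %in% colnames(weights)))
    stop("unknown module id(s) in gammas: ",
         paste(setdiff(names(gammas), colnames(weights)), collapse = ", "))
  if (is.null(samples)) samples <- rownames(weights)
  missing <- setdiff(samples, rownames(weights))
  if (length(missing))
    stop("unknown sample(s): ", paste(head(missing, 5L), collapse = ", "))
  out <- expand.grid(sample_id = samples, module_id = names(gammas),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$weight <- weights[cbind(out$sample_id, out$module_id)]
  out$gamma <- gammas[out$module_id]
  out$predicted <- as.integer(out$weight >= out$gamma)
  rownames(out) <- NULL
  out
}

#' Co-assignment summary of module predictions
#'
#' Fraction of the samples predicted positive for module A that are also
#' predicted positive for module B, for every ordered module pair.
#'
#' @param predictions data.frame from [predict_occurrences()].
#' @return square matrix; entry (A, B) = P(B positive | A positive), NA when
#'   A has no positive samples.
#' @export
co_assignment_matrix <- function(predictions) {
  mods <- unique(predictions$module_id)
  pos <- lapply(mods, function(m)
    predictions$sample_id[predictions$module_id == m &
                            predictions$predicted == 1L])
  names(pos) <- mods
  out <- matrix(NA_real_, length(mods), length(mods),
                dimnames = list(mods, mods))
  for (a in mods)
    for (b in mods)
      if (length(pos[[a]]))
        out[a, b] <- mean(pos[[a]] %in% pos[[b]])
  out
}

#' The saprophyte family-count rule
#'
#' Fixed CAZy family lists for cellulases and for hemicellulases/pectinases,
#' with the minimum distinct-family counts a genome must reach to be called
#' a cellulase- and hemicellulase-containing saprophyte (at least one
#' cellulase family and three or more hemicellulase/pectinase families).
#'
#' @return list with `cellulase_families`, `hemi_pectinase_families`,
#'   `min_cellulases`, `min_hemi`.
#' @export
saprophyte_rule <- function() {
  list(cellulase_families = c("GH5", "GH6", "GH8", "GH9", "GH12", "GH44",
                              "GH45", "GH48", "GH74", "GH124"),
       hemi_pectinase_families = c("GH10", "GH11", "GH26", "GH28", "GH30",
                                   "GH43", "GH53", "GH67", "GH78", "PL1",
                                   "PL2", "PL9", "PL10", "PL11", "PL22"),
       min_cellulases = 1L, min_hemi = 3L)
}

#' Classify samples as saprophytes from their family content
#'
#' A sample qualifies iff it carries at least `min_cellulases` distinct
#' cellulase families and at least `min_hemi` distinct
#' hemicellulase/pectinase families (distinct families, not protein counts).
#'
#' @param corpus an `annotation_corpus`, or a list of character family sets.
#' @param rule a rule list as from [saprophyte_rule()].
#' @return named logical vector, one element per sample.
#' @examples
#' classify_saprophytes(list(g1 = c("GH5", "GH10", "GH28", "PL1")))  # TRUE
#' @export
classify_saprophytes <- function(corpus, rule = saprophyte_rule()) {
  sets <- if (inherits(corpus, "annotation_corpus")) doc_family_sets(corpus)
          else lapply(corpus, as.character)
  vapply(sets, function(fams) {
    sum(rule$cellulase_families %in% fams) >= rule$min_cellulases &&
      sum(rule$hemi_pectinase_families %in% fams) >= rule$min_hemi
  }, logical(1L))
}
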