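#' Detect gene clusters of module-annotated genes
#'
#' Scans each replicon for maximal chains of genes carrying at least one
#' family of the given consensus module (PDM), where consecutive considered
#' genes are separated by an intergenic distance of at most `max_gap`
#' (default 2 kb).  The intergenic distance between genes with 1-based
#' inclusive coordinates is `max(0, next_start - prev_end - 1)`; overlapping
#' genes count as distance 0.  Chains with at least `min_genes` genes and at
#' least `min_distinct_families` distinct module families are reported.
#' Unannotated genes inside a gap do not break a chain unless
#' `strict = TRUE`, in which case chains must also be consecutive in the
#' full per-replicon gene order.
#'
#' @param genes data.frame with columns `sample_id`, `replicon_id`,
#'   `gene_id`, `start`, `end`, optional `strand` (stored, unused), and
#'   `families` (character, `;`-separated family ids, possibly empty).
#' @param pdm_families character vector of the module's family ids (or a
#'   `consensus_module`).
#' @param max_gap maximum intergenic distance in bp (default 2000).
#' @param min_genes minimum chain length (default 4).
#' @param min_distinct_families minimum distinct module families (default 2).
#' @param strict require chains to be consecutive over all genes, annotated
#'   or not.
#' @return data.frame of clusters with columns `sample_id`, `replicon_id`,
#'   `genes` (`;`-separated ids), `n_genes`, `start`, `end`, `gaps`
#'   (`;`-separated), `mean_gap`, `families` (`;`-separated distinct module
#'   families), `n_families`.
#' @export
detect_clusters <- function(genes, pdm_families, max_gap = 2000L,
                            min_genes = 4L, min_distinct_families = 2L,
                            strict = FALSE) {
  if (inherits(pdm_families, "consensus_module"))
    pdm_families <- pdm_families$families
  genes <- as.data.frame(genes)
  required <- c("sample_id", "replicon_id", "gene_id", "start", "end",
                "families")
  missing <- setdiff(required, names(genes))
  if (length(missing))
    stop("genes is missing column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(genes$start)) || any(!is.finite(genes$end)) ||
      any(genes$start < 1) || any(genes$start > genes$end))
    stop("malformed gene coordinates (need 1 <= start <= end)")

  fam_list <- strsplit(ifelse(is.na(genes$families), "", genes$families), ";",
                       fixed = TRUE)
  fam_list <- lapply(fam_list, function(f) intersect(f, pdm_families))
  genes$n_pdm <- lengths(fam_list)

  out <- list()
  for (key in unique(paste(genes$sample_id, genes$replicon_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    idx <- which(genes$sample_id == parts[1L] &
                   genes$replicon_id == parts[2L])
    idx <- idx[order(genes$start[idx], genes$end[idx])]
    ann <- idx[genes$n_pdm[idx] > 0L]
    if (length(ann) < min_genes) next
    pos_in_all <- match(ann, idx)
    gaps <- numeric(0)
    chain_break <- logical(length(ann))
    if (length(ann) > 1L) {
      gaps <- pmax(0, genes$start[ann[-1L]] -
                     genes$end[ann[-length(ann)]] - 1)
      chain_break[-1L] <- gaps > max_gap
      if (strict)
        chain_break[-1L] <- chain_break[-1L] | diff(pos_in_all) != 1L
    }
    chain_id <- cumsum(chain_break)
    for (cid in unique(chain_id)) {
      members <- ann[chain_id == cid]
      if (length(members) < min_genes) next
      fams <- sort(unique(unlist(fam_list[members])))
      if (length(fams) < min_distinct_families) next
      g <- pmax(0, genes$start[members[-1L]] -
                  genes$end[members[-length(members)]] - 1)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = parts[1L], replicon_id = parts[2L],
        genes = paste(genes$gene_id[members], collapse = ";"),
        n_genes = length(members),
        start = min(genes$start[members]), end = max(genes$end[members]),
        gaps = paste(g, collapse = ";"), mean_gap = mean(g),
        families = paste(fams, collapse = ";"), n_families = length(fams))
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), replicon_id = character(),
                      genes = character(), n_genes = integer(),
                      start = integer(), end = integer(), gaps = character(),
                      mean_gap = numeric(), families = character(),
                      n_families = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge clusters from different modules into distinct clusters
#'
#' Clusters whose genomic spans overlap on the same replicon are unioned
#' (transitively), producing pairwise non-overlapping distinct clusters --
#' the number of distinct clusters underlying per-module cluster calls.
#'
#' @param clusters data.frame as from [detect_clusters()] (rows may come
#'   from several modules).
#' @return data.frame with `sample_id`, `replicon_id`, `start`, `end`,
#'   `n_merged` (how many input clusters were unioned).
#' @export
merge_distinct <- function(clusters) {
  if (!nrow(clusters))
    return(data.frame(sample_id = character(), replicon_id = character(),
                      start = integer(), end = integer(),
                      n_merged = integer()))
  out <- list()
  for (key in unique(paste(clusters$sample_id, clusters$replicon_id,
                           sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sel <- clusters[clusters$sample_id == parts[1L] &
                      clusters$replicon_id == parts[2L], , drop = FALSE]
    sel <- sel[order(sel$start, sel$end), , drop = FALSE]
    cur_start <- sel$start[1L]; cur_end <- sel$end[1L]; n <- 1L
    flush <- function(s, e, n)
      data.frame(sample_id = parts[1L], replicon_id = parts[2L],
                 start = s, end = e, n_merged = n)
    for (i in seq_len(nrow(sel))[-1L]) {
      if (sel$start[i] <= cur_end) {  # overlap (1-based inclusive)
        cur_end <- max(cur_end, sel$end[i]); n <- n + 1L
      } else {
        out[[length(out) + 1L]] <- flush(cur_start, cur_end, n)
        cur_start <- sel$start[i]; cur_end <- sel$end[i]; n <- 1L
      }
    }
    out[[length(out) + 1L]] <- flush(cur_start, cur_end, n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster statistics for a module
#'
#' Mean intergenic distance over all gaps of all clusters, and the
#' percentage of the module's families covered by at least one cluster.
#'
#' @param clusters data.frame from [detect_clusters()].
#' @param pdm_families the module's family ids (or a `consensus_module`).
#' @return list with `mean_intergenic_distance` and `family_coverage_pct`;
#'   both `NA` when there are no clusters.
#' @export
cluster_stats <- function(clusters, pdm_families) {
  if (inherits(pdm_families, "consensus_module"))
    pdm_families <- pdm_families$families
  if (!nrow(clusters))
    return(list(mean_intergenic_distance = NA_real_,
                family_coverage_pct = NA_real_))
  gaps <- as.numeric(unlist(strsplit(clusters$gaps[clusters$n_genes > 1L],
                                     ";", fixed = TRUE)))
  covered <- unique(unlist(strsplit(clusters$families, ";", fixed = TRUE)))
  list(mean_intergenic_distance = mean(gaps),
       family_coverage_pct =
         100 * length(intersect(covered, pdm_families)) /
           length(pdm_families))
}

#' Read gene records from GFF3
#'
#' Imports gene (or CDS) features with `rtracklayer` and attaches
#' protein-family annotations either from a GFF3 attribute
#' (`family_attr`, `;`- or `,`-separated ids) or from a join table mapping
#' `gene_id` to `family_id`.
#'
#' @param path GFF3 file path.
#' @param sample_id sample the records belong to.
#' @param feature_type feature types to keep (default `c("gene", "CDS")`).
#' @param family_attr GFF3 attribute carrying family ids (default
#'   `"families"`).
#' @param join optional data.frame (`gene_id`, `family_id`) overriding the
#'   attribute.
#' @return data.frame in the layout expected by [detect_clusters()].
#' @export
read_gene_gff3 <- function(path, sample_id, feature_type = c("gene", "CDS"),
                           family_attr = "families", join = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_gff3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID)
         else paste0("gene", seq_along(gr))
  fams <- if (!is.null(join)) {
    vapply(ids, function(id)
      paste(unique(join$family_id[join$gene_id == id]), collapse = ";"), "")
  } else if (family_attr %in% names(S4Vectors::mcols(gr))) {
    raw <- S4Vectors::mcols(gr)[[family_attr]]
    vapply(raw, function(x)
      paste(unlist(strsplit(paste(unlist(x), collapse = ","), "[;,]")),
            collapse = ";"), "")
  } else {
    rep("", length(gr))
  }
  data.frame(sample_id = sample_id,
             replicon_id = as.character(GenomicRanges::seqnames(gr)),
             gene_id = ids,
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             families = unname(fams))
}

#' Export clusters as BED
#'
#' Converts the 1-based inclusive cluster spans to BED's 0-based half-open
#' convention (`chromStart = start - 1`, `chromEnd = end`).
#'
#' @param clusters data.frame from [detect_clusters()] or [merge_distinct()].
#' @param path output file.
#' @export
write_clusters_bed <- function(clusters, path) {
  name <- if (!is.null(clusters$genes)) clusters$genes
          else paste0("cluster", seq_len(nrow(clusters)))
  bed <- data.frame(chrom = clusters$replicon_id,
                    chromStart = clusters$start - 1L,
                    chromEnd = clusters$end,
                    name = name)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
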