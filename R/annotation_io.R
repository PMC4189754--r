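#' Filter HMMER protein-family hits
#'
#' Applies the annotation-quality filter used to build the corpus: a hit is
#' kept iff its bit score reaches `min_bitscore`, its e-value is at or below
#' the applicable e-value threshold, and -- for Pfam hits with a known
#' gathering threshold -- the bit score also reaches that family-specific
#' threshold when it is stricter than the default.  The applicable e-value
#' threshold is `large_family_evalue` for dbCAN hits whose profile is longer
#' than `large_family_len` amino acids, and `default_evalue` otherwise.
#' Multiple hits per protein (different families) are all retained.
#'
#' @param hits data.frame with columns `protein_id`, `family_id`, `evalue`,
#'   `bitscore`, `family_db` (`"pfam"` or `"dbcan"`); optional columns
#'   `model_length` (profile length, amino acids) and `gathering_threshold`
#'   (NA when unavailable, as for dbCAN).
#' @param default_evalue default e-value threshold (1e-2).
#' @param min_bitscore minimum bit score (25).
#' @param large_family_evalue stricter e-value for long dbCAN profiles (1e-4).
#' @param large_family_len profile-length cutoff in amino acids (100).
#' @return the kept rows of `hits`, in input order.
#' @examples
#' hits <- data.frame(protein_id = "p1", family_id = "GH5",
#'                    evalue = 5e-3, bitscore = 30, family_db = "pfam")
#' filter_hmmer_hits(hits)
#' @export
filter_hmmer_hits <- function(hits, default_evalue = 1e-2, min_bitscore = 25,
                              large_family_evalue = 1e-4,
                              large_family_len = 100L) {
  hits <- as.data.frame(hits)
  required <- c("protein_id", "family_id", "evalue", "bitscore", "family_db")
  missing <- setdiff(required, names(hits))
  if (length(missing))
    stop("hits is missing column(s): ", paste(missing, collapse = ", "))
  if (is.null(hits$model_length)) hits$model_length <- NA_integer_
  if (is.null(hits$gathering_threshold)) hits$gathering_threshold <- NA_real_
  if (nrow(hits) == 0L) return(hits)

  bad <- which(!is.finite(hits$evalue) | hits$evalue <= 0)
  if (length(bad))
    stop("non-positive e-value in hits row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  empty <- which(is.na(hits$family_id) | hits$family_id == "")
  if (length(empty))
    stop("empty family_id in hits row(s): ",
         paste(head(empty, 5L), collapse = ", "))

  ethr <- ifelse(hits$family_db == "dbcan" &
                   !is.na(hits$model_length) &
                   hits$model_length > large_family_len,
                 large_family_evalue, default_evalue)
  keep <- hits$bitscore >= min_bitscore & hits$evalue <= ethr
  ga_applies <- hits$family_db == "pfam" & !is.na(hits$gathering_threshold)
  keep[ga_applies] <- keep[ga_applies] &
    hits$bitscore[ga_applies] >= pmax(min_bitscore,
                                      hits$gathering_threshold[ga_applies])
  hits[keep, , drop = FALSE]
}

#' Read a HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-separated 22+-column domtblout layout and returns one
#' row per line with the full-sequence e-value and bit score.  For
#' `program = "hmmsearch"` the target is the protein and the query is the
#' profile; `"hmmscan"` swaps the two.
#'
#' @param path file path.
#' @param family_db `"pfam"` or `"dbcan"`; stored in the `family_db` column.
#' @param program which HMMER program produced the file.
#' @return data.frame with columns `protein_id`, `family_id`, `evalue`,
#'   `bitscore`, `family_db`, `model_length`, `gathering_threshold` (NA).
#' @export
read_domtblout <- function(path, family_db = c("pfam", "dbcan"),
                           program = c("hmmsearch", "hmmscan")) {
  family_db <- match.arg(family_db)
  program <- match.arg(program)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(protein_id = character(), family_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      family_db = character(), model_length = integer(),
                      gathering_threshold = numeric()))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  short <- which(vapply(fields, length, 1L) < 22L)
  if (length(short))
    stop("malformed domtblout line(s) (fewer than 22 columns): ",
         paste(head(short, 5L), collapse = ", "))
  col <- function(i) vapply(fields, `[[`, "", i)
  if (program == "hmmsearch") {
    protein <- col(1L); family <- col(4L); mlen <- col(6L)
  } else {
    protein <- col(4L); family <- col(1L); mlen <- col(3L)
  }
  evalue <- as.numeric(col(7L))
  if (anyNA(evalue) || any(evalue <= 0))
    stop("non-positive or unparseable e-value in domtblout line(s): ",
         paste(head(which(is.na(evalue) | evalue <= 0), 5L), collapse = ", "))
  data.frame(protein_id = protein, family_id = family, evalue = evalue,
             bitscore = as.numeric(col(8L)), family_db = family_db,
             model_length = as.integer(mlen),
             gathering_threshold = NA_real_)
}

#' Build a bag-of-families corpus from per-sample annotations
#'
#' Counts, for every sample, the number of distinct proteins annotated with
#' each protein family, truncates each count at `cap`, and assembles the
#' document collection consumed by [fit_lda()].  Document order follows the
#' order of first appearance in the input; the vocabulary is the
#' lexicographically sorted union of retained families.  Counting distinct
#' proteins (rather than domain matches) avoids inflation from repeated
#' domains within one protein; set `count_unit = "annotation"` to count every
#' (protein, family) annotation row instead.
#'
#' @param annotations data.frame with columns `sample_id`, `protein_id`,
#'   `family_id`; rows are individual protein-family annotations.
#' @param cap per-sample count cap for a single family (default 10).
#' @param samples optional character vector fixing the full sample set and
#'   document order; samples without annotations become empty documents (a
#'   warning is issued, as for sparsely annotated metagenome bins).
#' @param source_kind `"genome"` or `"metagenome_bin"`, recycled across
#'   samples.
#' @param count_unit `"protein"` (distinct proteins per family; default) or
#'   `"annotation"` (raw annotation rows).
#' @return an `annotation_corpus`: list with `samples`, `source_kind`,
#'   `vocabulary`, and `counts` (data.frame `doc`, `word`, `count` with
#'   1-based indices into `samples` and `vocabulary`).
#' @examples
#' ann <- data.frame(sample_id = c("g1", "g1", "g2"),
#'                   protein_id = c("p1", "p2", "p3"),
#'                   family_id = c("GH5", "PF00041", "GH5"))
#' corp <- build_corpus(ann)
#' corp$vocabulary
#' @export
build_corpus <- function(annotations, cap = 10L, samples = NULL,
                         source_kind = "genome",
                         count_unit = c("protein", "annotation")) {
  count_unit <- match.arg(count_unit)
  annotations <- as.data.frame(annotations)
  required <- c("sample_id", "protein_id", "family_id")
  missing <- setdiff(required, names(annotations))
  if (length(missing))
    stop("annotations is missing column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(cap) || cap < 1) stop("cap must be >= 1")
  cap <- as.integer(cap)

  if (count_unit == "protein")
    annotations <- unique(annotations[, required])

  if (is.null(samples)) {
    samples <- unique(annotations$sample_id)
  } else {
    extra <- setdiff(unique(annotations$sample_id), samples)
    if (length(extra))
      stop("annotations contain sample(s) not in `samples`: ",
           paste(head(extra, 5L), collapse = ", "))
  }
  vocabulary <- sort(unique(annotations$family_id))

  if (nrow(annotations)) {
    key <- paste(annotations$sample_id, annotations$family_id, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    doc <- match(vapply(parts, `[[`, "", 1L), samples)
    word <- match(vapply(parts, `[[`, "", 2L), vocabulary)
    count <- pmin(as.integer(tab), cap)
    ord <- order(doc, word)
    counts <- data.frame(doc = doc[ord], word = word[ord],
                         count = count[ord])
  } else {
    counts <- data.frame(doc = integer(), word = integer(), count = integer())
  }

  empty <- setdiff(seq_along(samples), unique(counts$doc))
  if (length(empty))
    warning(length(empty), " sample(s) have no annotations and become ",
            "empty documents: ", paste(head(samples[empty], 5L), collapse = ", "))

  structure(list(samples = as.character(samples),
                 source_kind = rep_len(source_kind, length(samples)),
                 vocabulary = vocabulary,
                 counts = counts,
                 cap = cap),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation_corpus: %d documents, %d families, %d tokens\n",
              length(x$samples), length(x$vocabulary), sum(x$counts$count)))
  invisible(x)
}

#' Number of documents / vocabulary size of a corpus
#' @param corpus an `annotation_corpus`.
#' @return integer.
#' @export
n_docs <- function(corpus) length(corpus$samples)

#' @rdname n_docs
#' @export
n_vocab <- function(corpus) length(corpus$vocabulary)

#' Families present in each document
#'
#' @param corpus an `annotation_corpus`.
#' @return list (one per document) of character vectors of family ids with
#'   count >= 1.
#' @export
doc_family_sets <- function(corpus) {
  sets <- rep(list(character()), length(corpus$samples))
  if (nrow(corpus$counts)) {
    byd <- split(corpus$vocabulary[corpus$counts$word], corpus$counts$doc)
    sets[as.integer(names(byd))] <- byd
  }
  names(sets) <- corpus$samples
  sets
}

#' Write / read a corpus (TSV counts + JSON header)
#'
#' The TSV holds one `(sample_id, family_id, count)` triple per row; the JSON
#' sidecar (`<path>.json`) records the sample order, source kinds, vocabulary
#' and count cap, so that `read_corpus(write_corpus(x))` reproduces `x`
#' exactly, including empty documents and document/vocabulary order.
#'
#' @param corpus an `annotation_corpus`.
#' @param path TSV file path; the sidecar is written next to it.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns the
#'   corpus.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  df <- data.frame(sample_id = corpus$samples[corpus$counts$doc],
                   family_id = corpus$vocabulary[corpus$counts$word],
                   count = corpus$counts$count)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  header <- list(samples = corpus$samples, source_kind = corpus$source_kind,
                 vocabulary = corpus$vocabulary, cap = corpus$cap)
  jsonlite::write_json(header, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "integer"))
  doc <- match(df$sample_id, header$samples)
  word <- match(df$family_id, header$vocabulary)
  if (anyNA(doc) || anyNA(word))
    stop("corpus TSV refers to samples/families absent from the JSON header")
  ord <- order(doc, word)
  structure(list(samples = as.character(header$samples),
                 source_kind = as.character(header$source_kind),
                 vocabulary = as.character(header$vocabulary),
                 counts = data.frame(doc = doc[ord], word = word[ord],
                                     count = df$count[ord]),
                 cap = as.integer(header$cap)),
            class = "annotation_corpus")
}

#' Read a phenotype label table
#'
#' Two-column TSV with header (`sample_id`, `label`).  Labels are
#' case-insensitive; `+`/`pos`/`1`/`yes` map to positive, `-`/`neg`/`0`/`no`
#' to negative, `?`/`na`/`unlabeled` to unknown.
#'
#' @param path TSV file path.
#' @return named character vector over `{"positive","negative","unknown"}`,
#'   names are sample ids.
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                   comment.char = "")
  if (ncol(df) < 2L) stop("phenotype table needs sample_id and label columns")
  dup <- duplicated(df[[1L]])
  if (any(dup))
    stop("duplicate sample_id in phenotype table: ",
         paste(head(unique(df[[1L]][dup]), 5L), collapse = ", "))
  labels <- normalize_labels(df[[2L]])
  bad <- which(is.na(labels))
  if (length(bad))
    stop("unknown phenotype label in row(s) ",
         paste(head(bad, 5L), collapse = ", "), ": ",
         paste(head(df[[2L]][bad], 5L), collapse = ", "))
  setNames(labels, df[[1L]])
}

normalize_labels <- function(x) {
  key <- tolower(trimws(x))
  map <- c(positive = "positive", pos = "positive", "+" = "positive",
           "1" = "positive", yes = "positive", "true" = "positive",
           negative = "negative", neg = "negative", "-" = "negative",
           "−" = "negative", "0" = "negative", no = "negative",
           "false" = "negative",
           unknown = "unknown", "?" = "unknown", na = "unknown",
           unlabeled = "unknown", unlabelled = "unknown")
  unname(map[key])
}

#' Read a per-annotation TSV
#'
#' Columns: `sample_id`, `protein_id`, `family_id`, and optionally `evalue`,
#' `bitscore`, `db`, `model_len`, `ga` for pre-filter tables.
#'
#' @param path TSV file path (with header).
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "",
                   stringsAsFactors = FALSE)
  required <- c("sample_id", "protein_id", "family_id")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  rename <- c(db = "family_db", model_len = "model_length",
              ga = "gathering_threshold")
  for (i in seq_along(rename))
    names(df)[names(df) == names(rename)[i]] <- rename[i]
  df
}
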