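gene_row <- function(replicon, id, start, end, fams, sample = "g1") {
  data.frame(sample_id = sample, replicon_id = replicon, gene_id = id,
             start = start, end = end, strand = "+", families = fams)
}

test_that("detect_clusters applies the gap, size and family criteria", {
  pdm <- c("GH5", "GH9", "GH43")
  # 4 genes, gaps 100/200/1500, two distinct families -> one cluster
  g <- rbind(gene_row("c1", "a", 1000, 2000, "GH5"),
             gene_row("c1", "b", 2101, 3000, "GH9"),
             gene_row("c1", "c", 3201, 4000, "GH5"),
             gene_row("c1", "d", 5501, 6400, "GH9"))
  cl <- detect_clusters(g, pdm)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_genes, 4)
  expect_equal(cl$gaps, "100;200;1500")
  expect_equal(cl$mean_gap, 600)
  expect_equal(cl$start, 1000)
  expect_equal(cl$end, 6400)

  # one oversized gap splits the chain into two sub-minimum chains
  g2 <- g
  g2$start[3] <- 5501; g2$end[3] <- 6300
  g2$start[4] <- 8801; g2$end[4] <- 9700   # gap 2500 after gene c
  cl2 <- detect_clusters(g2, pdm)
  expect_equal(nrow(cl2), 0)

  # a chain of one family only fails min_distinct_families
  g3 <- g; g3$families <- "GH5"
  expect_equal(nrow(detect_clusters(g3, pdm)), 0)
  expect_equal(nrow(detect_clusters(g3, pdm, min_distinct_families = 1)), 1)
})

test_that("unannotated genes inside gaps break chains only in strict mode", {
  pdm <- c("GH5", "GH9")
  g <- rbind(gene_row("c1", "a", 1000, 2000, "GH5"),
             gene_row("c1", "b", 2101, 3000, "GH9"),
             gene_row("c1", "x", 3101, 3500, ""),        # unannotated
             gene_row("c1", "c", 3601, 4500, "GH5"),
             gene_row("c1", "d", 4601, 5500, "GH9"))
  cl <- detect_clusters(g, pdm)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_genes, 4)
  strict <- detect_clusters(g, pdm, strict = TRUE)
  expect_equal(nrow(strict), 0)
})

test_that("overlapping genes count as distance zero; bad coords error", {
  pdm <- c("GH5", "GH9")
  g <- rbind(gene_row("c1", "a", 1000, 2000, "GH5"),
             gene_row("c1", "b", 1500, 2500, "GH9"),   # overlaps a
             gene_row("c1", "c", 2601, 3500, "GH5"),
             gene_row("c1", "d", 3601, 4500, "GH9"))
  cl <- detect_clusters(g, pdm)
  expect_equal(cl$gaps, "0;100;100")

  bad <- gene_row("c1", "z", 500, 100, "GH5")
  expect_error(detect_clusters(rbind(g, bad), pdm), "coordinates")
})

test_that("detect_clusters equals the brute-force window enumerator", {
  pdm <- sprintf("F%02d", 1:5)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:14, 1)
    starts <- sort(sample(1:40000, n)) ; len <- sample(300:1500, n, TRUE)
    fams <- vapply(seq_len(n), function(j) {
      if (runif(1) < 0.25) ""
      else paste(sample(pdm, sample(1:2, 1)), collapse = ";")
    }, "")
    g <- data.frame(sample_id = "g1", replicon_id = "c1",
                    gene_id = paste0("g", seq_len(n)),
                    start = starts, end = starts + len, strand = "+",
                    families = fams)
    got <- detect_clusters(g, pdm)
    want <- brute_force_clusters(g, pdm)
    expect_equal(nrow(got), length(want))
    if (nrow(got)) {
      got_sets <- sort(got$genes)
      want_sets <- sort(vapply(want, function(x)
        paste(x$genes, collapse = ";"), ""))
      expect_equal(got_sets, want_sets)
    }
  }
})

test_that("shrinking max_gap never adds clusters", {
  pdm <- sprintf("F%02d", 1:4)
  set.seed(33)
  for (i in 1:20) {
    n <- 10
    starts <- sort(sample(1:30000, n)); len <- sample(300:1200, n, TRUE)
    g <- data.frame(sample_id = "g1", replicon_id = "c1",
                    gene_id = paste0("g", seq_len(n)),
                    start = starts, end = starts + len, strand = "+",
                    families = sample(pdm, n, TRUE))
    wide <- detect_clusters(g, pdm, max_gap = 2500)
    narrow <- detect_clusters(g, pdm, max_gap = 1200)
    expect_lte(nrow(narrow), nrow(wide))
    expect_lte(sum(narrow$n_genes), sum(wide$n_genes))
    if (nrow(narrow)) {
      gaps <- as.numeric(unlist(strsplit(narrow$gaps, ";")))
      expect_true(all(gaps <= 1200))
      expect_true(all(narrow$n_genes >= 4))
    }
  }
})

test_that("merge_distinct unions overlapping spans across modules", {
  cl <- data.frame(sample_id = "g1", replicon_id = c("c1", "c1", "c1", "c2"),
                   start = c(100, 100, 900, 50),
                   end = c(1000, 1000, 2000, 500))
  merged <- merge_distinct(cl)
  # identical spans and the chained overlap collapse to one; c2 separate
  expect_equal(nrow(merged), 2)
  c1 <- merged[merged$replicon_id == "c1", ]
  expect_equal(c(c1$start, c1$end, c1$n_merged), c(100, 2000, 3))

  disjoint <- data.frame(sample_id = "g1", replicon_id = "c1",
                         start = c(1, 100), end = c(50, 200))
  expect_equal(nrow(merge_distinct(disjoint)), 2)

  # chain of pairwise-overlapping spans -> single union span
  chain <- data.frame(sample_id = "g1", replicon_id = "c1",
                      start = c(1, 40, 80, 120), end = c(50, 90, 130, 170))
  m <- merge_distinct(chain)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1, 170))
})

test_that("cluster_stats reports mean gap and family coverage", {
  pdm <- sprintf("F%02d", 1:10)
  cl <- data.frame(sample_id = "g1", replicon_id = "c1",
                   genes = c("a;b;c;d", "e;f;g;h"), n_genes = 4,
                   start = c(1, 10000), end = c(5000, 15000),
                   gaps = c("100;200;300", "50;150;250"),
                   mean_gap = c(200, 150),
                   families = c("F01;F02;F03;F04", "F04;F05;F06;F07"),
                   n_families = 4)
  st <- cluster_stats(cl, pdm)
  expect_equal(st$mean_intergenic_distance, mean(c(100, 200, 300, 50, 150,
                                                   250)))
  expect_equal(st$family_coverage_pct, 70)  # 7 of 10 families covered

  empty <- cl[0, ]
  st0 <- cluster_stats(empty, pdm)
  expect_true(is.na(st0$mean_intergenic_distance))
})

test_that("generated gene tables are solved exactly by the detector", {
  for (seed in 1:20) {
    gt <- generate_gene_table(sprintf("F%02d", 1:6), n_planted = 4,
                              n_decoys = 6, seed = seed)
    cl <- detect_clusters(gt$genes, sprintf("F%02d", 1:6))
    planted <- gt$truth$replicon_id[gt$truth$kind == "planted"]
    expect_setequal(cl$replicon_id, planted)
  }
})

test_that("GFF3 round-trip via rtracklayer preserves gene records", {
  skip_if_not_installed("rtracklayer")
  gff <- c("##gff-version 3",
           paste("chr1", "test", "gene", "1000", "2000", ".", "+", ".",
                 "ID=gene1;families=GH5,GH9", sep = "\t"),
           paste("chr1", "test", "gene", "2500", "3500", ".", "-", ".",
                 "ID=gene2;families=GH43", sep = "\t"),
           paste("chr1", "test", "gene", "4000", "5000", ".", "+", ".",
                 "ID=gene3", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  genes <- read_gene_gff3(path, sample_id = "g1")
  expect_equal(genes$gene_id, c("gene1", "gene2", "gene3"))
  expect_equal(genes$start, c(1000, 2500, 4000))
  expect_equal(genes$families, c("GH5;GH9", "GH43", ""))
})

test_that("BED export converts to 0-based half-open coordinates", {
  cl <- data.frame(sample_id = "g1", replicon_id = "c1", genes = "a;b;c;d",
                   n_genes = 4, start = 1000, end = 6400,
                   gaps = "1;2;3", mean_gap = 2,
                   families = "F1;F2", n_families = 2)
  path <- withr::local_tempfile(fileext = ".bed")
  write_clusters_bed(cl, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 999)
  expect_equal(bed$V3, 6400)
})
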