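test_that("gene_annotation resolves the TSS by strand", {
  g <- gene_annotation(c("g1", "g2"), c("chr1", "chr1"),
                       start = c(100, 100), end = c(500, 500),
                       strand = c("+", "-"))
  expect_equal(g$tss, c(100, 500))
  expect_error(gene_annotation("g1", "chr1", 0, 10, "."), "strand")
  expect_error(gene_annotation(c("g1", "g1"), "chr1", c(0, 0), c(10, 10),
                               c("+", "+")), "unique")
})

test_that("nearest-TSS assignment matches the exhaustive oracle", {
  set.seed(70)
  for (rep in 1:20) {
    peaks <- random_atlas(60, span = 50000, max_len = 400)
    ng <- 25
    s <- sample.int(50000, ng, replace = TRUE) - 1
    genes <- gene_annotation(
      sprintf("g%03d", sample(ng)), # shuffled ids exercise the tie-break
      sample(c("chr1", "chr2"), ng, replace = TRUE),
      start = s,
      end = s + 1000,
      strand = sample(c("+", "-"), ng, replace = TRUE)
    )
    w <- sample(c(2000, 10000, 60000), 1)
    got <- suppressWarnings(nearest_tss_assignment(peaks, genes, window = w))
    want <- oracle_nearest(peaks, genes, window = w)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(as.data.frame(got[, c("peak", "gene_id", "distance")]),
                   want)
    }
  }
})

test_that("window boundary is inclusive and ties break lexicographically", {
  peaks <- peak_atlas("chr1", 10000, 10100, name = "pk") # midpoint 10050
  genes <- gene_annotation(c("gB", "gA"), c("chr1", "chr1"),
                           start = c(10000, 10100), end = c(10500, 10600),
                           strand = c("+", "+")) # both TSS 50 bp away
  expect_warning(out <- nearest_tss_assignment(peaks, genes, window = 50),
                 "tie")
  expect_equal(out$gene_id, "gA")
  expect_equal(out$distance, 50)
  # one bp beyond the window: unassigned
  out2 <- suppressWarnings(nearest_tss_assignment(peaks, genes, window = 49))
  expect_equal(nrow(out2), 0)
})

test_that("promoter-distal filter removes peaks near any TSS", {
  peaks <- peak_atlas(rep("chr1", 3), c(0, 10000, 30000),
                      c(1000, 11000, 31000))
  genes <- gene_annotation("g1", "chr1", start = 10700, end = 11700,
                           strand = "+")
  out <- filter_promoter_distal(peaks, genes, tss_pad = 2000)
  expect_equal(out$start, c(0, 30000)) # midpoint 10500 is 200 bp from TSS
})

test_that("DE gene-set filter equals the strict enumeration oracle", {
  set.seed(71)
  n <- 400
  de <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:n),
    baseMean = sample(c(999, 1000, 1001, 5000), n, replace = TRUE),
    log2fc = sample(c(-2, -1.5, -1, 0, 1.5, 1.501, 2), n, replace = TRUE),
    padj = sample(c(0.01, 0.05, 0.2, NA), n, replace = TRUE)
  )
  up <- filter_de_genes(de, direction = "up")
  down <- filter_de_genes(de, direction = "down")
  oracle_up <- de$gene_id[!is.na(de$padj) & de$baseMean > 1000 &
                            de$log2fc > 1.5 & de$padj < 0.05]
  oracle_down <- de$gene_id[!is.na(de$padj) & de$baseMean > 1000 &
                              de$log2fc < -1.5 & de$padj < 0.05]
  expect_identical(up, oracle_up)
  expect_identical(down, oracle_down)
  # boundary values are excluded by the strict comparisons
  expect_false(any(de$baseMean[match(up, de$gene_id)] == 1000))
  expect_false(any(de$log2fc[match(up, de$gene_id)] == 1.5))
  expect_false(any(de$padj[match(up, de$gene_id)] == 0.05))
})

test_that("read_de_table accepts DESeq2-style headers", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = "g1", baseMean = 2000,
                                  log2FoldChange = 2.5, padj = 0.001), path)
  de <- read_de_table(path)
  expect_equal(de$gene_id, "g1")
  expect_equal(de$log2fc, 2.5)
  readr::write_tsv(tibble::tibble(gene = "g1", lfc = 1), path)
  expect_error(read_de_table(path), "columns")
})

test_that("expression-pattern clustering is deterministic with a flat class", {
  set.seed(72)
  expr <- matrix(rnorm(50 * 4), 50,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  expr[1, ] <- 3 # constant profile
  out <- cluster_expression_patterns(expr, k = 5)
  expect_equal(out$cluster[1], "flat")
  expect_setequal(unique(out$cluster), c("flat", as.character(1:5)))
  expect_identical(out, cluster_expression_patterns(expr, k = 5))
  expect_error(cluster_expression_patterns(expr[1:3, ], k = 5), "at least k")
})
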