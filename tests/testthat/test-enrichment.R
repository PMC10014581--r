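test_that("the 2x2 chi-squared matches stats::chisq.test without correction", {
  set.seed(80)
  for (rep in 1:20) {
    tab <- matrix(sample(5:80, 4), 2)
    got <- atacdyn:::chisq_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$pvalue, ref$p.value, tolerance = 1e-12)
  }
})

test_that("gene-set enrichment computes observed/expected per class", {
  links <- tibble::tibble(
    peak = sprintf("p%02d", 1:40),
    gene_id = sprintf("g%02d", 1:40),
    distance = 1000, window = 25000
  )
  labels <- stats::setNames(rep(c("A", "B"), each = 20), links$peak)
  gene_set <- links$gene_id[c(1:10, 21:25)] # 10 of A, 5 of B
  res <- class_geneset_enrichment(links, labels, gene_set)
  expect_equal(res$observed, c(10, 5))
  expect_equal(res$expected, c(20 * 15 / 40, 20 * 15 / 40))
  expect_equal(res$score, log2(c(10, 5) / 7.5))
  # saturation: the set covers every linked gene -> score exactly 0
  sat <- class_geneset_enrichment(links, labels, links$gene_id)
  expect_equal(sat$score, c(0, 0))
  # empty observed yields the -Inf sentinel with the censored flag
  none <- class_geneset_enrichment(links, labels, links$gene_id[21:30],
                                   set_name = "s")
  expect_equal(none$score[none$class_name == "A"], -Inf)
  expect_true(none$censored[none$class_name == "A"])
  # links from unlabeled peaks are excluded from the universe entirely,
  # even when their gene belongs to the set
  extra <- dplyr::bind_rows(
    links, tibble::tibble(peak = "unlabeled1", gene_id = "g01",
                          distance = 1, window = 25000))
  expect_identical(class_geneset_enrichment(extra, labels, gene_set), res)
})

test_that("permutation p-value is small for a planted association", {
  set.seed(81)
  links <- tibble::tibble(peak = sprintf("p%03d", 1:200),
                          gene_id = sprintf("g%03d", 1:200),
                          distance = 1, window = 25000)
  labels <- stats::setNames(rep(c("A", "B"), each = 100), links$peak)
  gene_set <- links$gene_id[1:60] # all in class A
  res <- class_geneset_enrichment(links, labels, gene_set, n_perm = 200)
  expect_lt(res$p_perm[res$class_name == "A"], 0.05)
  expect_identical(
    res$p_perm,
    class_geneset_enrichment(links, labels, gene_set, n_perm = 200)$p_perm)
})

test_that("empty expected produces an all-NA row, not an error", {
  links <- tibble::tibble(peak = "p1", gene_id = "g1", distance = 1,
                          window = 25000)
  labels <- stats::setNames("A", "zzz") # no labelled peak in the links
  res <- class_geneset_enrichment(links, labels, "g1")
  expect_true(is.na(res$score))
  expect_true(is.na(res$pvalue))
})

test_that("tissue sets: replicate filter, uniqueness and lineage pooling", {
  mk <- function(starts, w = 100) {
    peak_atlas(rep("chr1", length(starts)), starts, starts + w)
  }
  reps <- list(
    t1 = list(mk(c(0, 5000, 9000)), mk(c(10, 5010, 20000))),
    t2 = list(mk(c(5000, 12000)), mk(c(5005, 12010))),
    t3 = list(mk(30000))
  )
  lineage <- c(t1 = "endoderm", t2 = "endoderm", t3 = "ectoderm")
  expect_warning(ts <- build_tissue_sets(reps, lineage), "single replicate")
  # t1: the 9000 region has no replicate partner -> dropped
  expect_equal(sort(ts$tissue$t1$start), c(0, 5000))
  # tissue-unique: t1's 5000 region is shared with t2 -> only 0 remains
  expect_equal(ts$tissue_unique$t1$start, 0)
  expect_equal(ts$tissue_unique$t2$start, 12000)
  expect_equal(ts$tissue_unique$t3$start, 30000)
  # lineage-unique endoderm pools t1+t2 and keeps everything off-ectoderm
  expect_setequal(ts$lineage_unique$endoderm$start, c(0, 5000, 12000))
  expect_error(build_tissue_sets(reps, lineage[1:2]), "lineage_map")
})

test_that("region enrichment counts overlaps against the universe", {
  universe <- peak_atlas(rep("chr1", 10), (0:9) * 1000, (0:9) * 1000 + 200)
  class_atlases <- list(
    X = peak_atlas(rep("chr1", 4), (0:3) * 1000, (0:3) * 1000 + 200,
                   name = universe$name[1:4]),
    Y = peak_atlas(rep("chr1", 4), (6:9) * 1000, (6:9) * 1000 + 200,
                   name = universe$name[7:10])
  )
  regions <- list(R = peak_atlas(rep("chr1", 3), c(50, 1050, 6050),
                                 c(150, 1150, 6150)))
  res <- class_region_enrichment(class_atlases, regions, universe)
  expect_equal(res$observed, c(2, 1))
  expect_equal(res$expected, c(4 * 3 / 10, 4 * 3 / 10))
  expect_equal(res$score, log2(c(2, 1) / 1.2))
})
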