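# cat_fixture() lives in helper-fixtures.R (shared with test-tidiers.R)

test_that("cell_matrix recomputes totals and mitochondrial fractions", {
  umis <- matrix(c(10, 0, 5, 5, 0, 20), 2, 3, byrow = TRUE,
                 dimnames = list(c("c1", "c2"), c("MT-1", "gA", "gB")))
  m <- cell_matrix(umis, tibble::tibble(cell = c("c1", "c2"),
                                        cluster = c("x", "x")))
  expect_equal(m$meta$total_umis, c(15, 25))
  expect_equal(m$meta$n_genes, c(2, 2))
  expect_equal(m$meta$mito_fraction, c(10 / 15, 5 / 25))
  expect_error(cell_matrix(umis, tibble::tibble(cell = c("c1", "cX"),
                                                cluster = c("x", "x"))),
               "rownames")
})

test_that("QC filter survivors equal the enumeration oracle at the boundaries", {
  # cells planted exactly on each threshold
  spec <- tibble::tibble(
    umis = c(2000, 2001, 34999, 35000, 10000, 10000, 10000, 10000, 10000),
    genes = c(800, 800, 800, 800, 550, 551, 4949, 4950, 800),
    mito = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.2)
  )
  n_genes_total <- 6000
  umis <- matrix(0, nrow(spec), n_genes_total,
                 dimnames = list(sprintf("c%d", seq_len(nrow(spec))),
                                 c("MT-1", sprintf("g%04d", 1:(n_genes_total - 1)))))
  for (i in seq_len(nrow(spec))) {
    mito_umis <- round(spec$umis[i] * spec$mito[i])
    rest <- spec$umis[i] - mito_umis
    k <- spec$genes[i] - 1
    base <- rep(floor(rest / k), k)
    base[seq_len(rest - sum(base))] <- base[seq_len(rest - sum(base))] + 1
    umis[i, 1] <- mito_umis
    umis[i, 1 + seq_len(k)] <- base
  }
  m <- cell_matrix(umis, tibble::tibble(cell = rownames(umis),
                                        cluster = "k"))
  stopifnot(identical(m$meta$total_umis, spec$umis),
            identical(m$meta$n_genes, spec$genes))
  out <- qc_filter_cells(m)
  oracle <- spec$umis > 2000 & spec$umis < 35000 &
    spec$genes > 550 & spec$genes < 4950 & spec$mito <= 0.20
  expect_identical(out$meta$cell, rownames(umis)[oracle])
  expect_equal(unname(attr(out, "removed")["total"]), sum(!oracle))
  expect_error(qc_filter_cells(m, umi_bounds = c(1, 2)), "no cell passes")
})

test_that("lognormalize implements ln(1 + scale * count / total)", {
  m <- cat_fixture(91, n_per = 5)
  x <- lognormalize(m)
  i <- 3; j <- 17
  expect_equal(x[i, j],
               log1p(1e4 * as.numeric(m$umis[i, j]) / m$meta$total_umis[i]))
})

test_that("gene panel is the union of top HVGs restricted to shared genes", {
  a <- cat_fixture(92, n_per = 10)
  b <- cat_fixture(93, n_per = 10)
  panel <- select_gene_panel(a, b, n_top = 40)
  expect_true(all(panel %in% intersect(colnames(a$umis), colnames(b$umis))))
  expect_true(length(panel) >= 40 && length(panel) <= 80)
  # the 30 signature genes dominate the variance in both datasets
  expect_true(all(sprintf("g%03d", 1:30) %in% panel))
})

test_that("bootstrap profiles are deterministic and order-invariant", {
  m <- cat_fixture(94)
  z <- zscore_genes(lognormalize(m))
  panel <- colnames(z)[4:40]
  p1 <- bootstrap_cluster_profiles(z, m$meta$cluster, panel, n_boot = 50,
                                   seed = 3)
  p2 <- bootstrap_cluster_profiles(z, m$meta$cluster, panel, n_boot = 50,
                                   seed = 3)
  expect_identical(p1$profiles, p2$profiles)
  # per-cluster RNG streams: a cluster's profile does not depend on which
  # other clusters are present
  k1 <- m$meta$cluster == "k1"
  p3 <- bootstrap_cluster_profiles(z[k1, ], m$meta$cluster[k1], panel,
                                   n_boot = 50, seed = 3)
  expect_identical(p1$profiles$k1, p3$profiles$k1)
  expect_warning(
    bootstrap_cluster_profiles(z[1:41, ], c(rep("k1", 40), "tiny"),
                               panel, n_boot = 5, seed = 1),
    "tiny")
})

test_that("self-alignment recovers the identity pairing", {
  m <- cat_fixture(95)
  z <- zscore_genes(lognormalize(m))
  p <- bootstrap_cluster_profiles(z, m$meta$cluster, colnames(z),
                                  n_boot = 100, seed = 2)
  al <- align_clusters(p, p)
  top <- al$pairs[al$pairs$rank == 1, ]
  expect_equal(top$cluster_b, top$cluster_a)
  expect_true(all(top$is_significant))
  expect_true(all(top$mutual_nearest))
  expect_equal(top$profile_cor, rep(1, 3)) # a centroid correlates 1 with itself
})

test_that("indistinguishable targets yield no significant alignment", {
  set.seed(96)
  panel <- sprintf("g%02d", 1:20)
  boots <- function() matrix(rnorm(100 * 20, sd = 0.05), 100,
                             dimnames = list(NULL, panel))
  a <- structure(list(profiles = list(q = boots()), gene_panel = panel,
                      n_boot = 100, seed = 1), class = "bootstrap_profiles")
  # two targets at identical distance from q
  b <- structure(list(profiles = list(t1 = boots() + 5, t2 = boots() - 5),
                      gene_panel = panel, n_boot = 100, seed = 1),
                 class = "bootstrap_profiles")
  al <- align_clusters(a, b)
  expect_false(any(al$pairs$is_significant))
  expect_error(align_clusters(a, structure(list(profiles = list(),
                                                gene_panel = panel[1:2]),
                                           class = "bootstrap_profiles")),
               "identical gene panel")
})
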