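test_that("generators are deterministic under a fixed master seed", {
  cfg <- sim_config(seed = 123, n_peaks_per_group = 20, n_static_peaks = 50,
                    n_noise_genes = 30, n_private_regions = 20,
                    sc_cells_per_cluster = 20)
  s1 <- simulate_atac_timecourse(cfg)
  s2 <- simulate_atac_timecourse(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(atlas_strip(s1$atlas), atlas_strip(s2$atlas))
  expect_identical(s1$truth, s2$truth)
  g1 <- simulate_gene_links(cfg, s1)
  g2 <- simulate_gene_links(cfg, s1)
  expect_identical(g1, g2)
  expect_identical(simulate_de_table(cfg, g1$truth),
                   simulate_de_table(cfg, g1$truth))
  expect_identical(simulate_scrna(cfg)$a$umis, simulate_scrna(cfg)$a$umis)
})

test_that("generator streams are isolated and restore the global RNG", {
  cfg <- sim_config(seed = 7, n_peaks_per_group = 10, n_static_peaks = 20,
                    sc_cells_per_cluster = 10)
  set.seed(999)
  before <- .Random.seed
  sim <- simulate_atac_timecourse(cfg)
  expect_identical(.Random.seed, before)
  # consuming another stream first does not perturb this one
  links_cold <- simulate_gene_links(cfg, sim)
  invisible(simulate_scrna(cfg))
  links_warm <- simulate_gene_links(cfg, sim)
  expect_identical(links_cold, links_warm)
})

test_that("planted counts follow the archetype shapes", {
  cfg <- sim_config(seed = 21)
  sim <- simulate_atac_timecourse(cfg)
  traj <- standardize_trajectories(sim$m)
  arch <- enhancer_archetypes(cfg$stages)
  for (g in rownames(arch)) {
    peaks <- sim$truth$peak[sim$truth$group == g]
    centroid <- colMeans(traj[peaks, ])
    expect_gt(stats::cor(centroid, arch[g, ]), 0.95)
  }
})

test_that("planted_rate solves the observed/expected target exactly", {
  n_total <- 5000; n_class <- 500; bg <- 0.1; o <- 4
  r <- atacdyn:::planted_rate(o, bg, n_class, n_total)
  # expected obs/exp under rates (r inside the class, bg outside)
  obs <- r * n_class
  k <- obs + bg * (n_total - n_class)
  expect_equal(obs / (n_class * k / n_total), o, tolerance = 1e-12)
  expect_error(atacdyn:::planted_rate(11, 0.1, 500, 5000), "too large")
})

test_that("the DE generator hits its over-representation target in expectation", {
  cfg <- sim_config(seed = 22, de_up_classes = "PE^PRIMED",
                    de_down_classes = character(), de_overrep = 3)
  sim <- simulate_atac_timecourse(cfg)
  gl <- simulate_gene_links(cfg, sim)
  de <- simulate_de_table(cfg, gl$truth)
  t_up <- gl$truth[de$truth$direction == "up", ]
  linked <- gl$truth[!is.na(gl$truth$group), ]
  obs <- sum(t_up$group == "PE^PRIMED", na.rm = TRUE)
  n_class <- sum(linked$group == "PE^PRIMED")
  expected <- n_class * nrow(t_up) / nrow(linked)
  expect_equal(obs / expected, 3, tolerance = 0.35)
  # noise genes are never differentially expressed
  expect_true(all(de$truth$direction[is.na(gl$truth$group)] == "null"))
})

test_that("link-universe DE calibration reduces to the truth formula", {
  cfg <- sim_config(seed = 24, de_up_classes = "PE^PRIMED",
                    de_down_classes = character(), de_overrep = 3)
  sim <- simulate_atac_timecourse(cfg)
  gl <- simulate_gene_links(cfg, sim)
  tl <- gl$truth[!is.na(gl$truth$peak), ]
  truth_links <- tibble::tibble(peak = tl$peak, gene_id = tl$gene_id,
                                distance = 1, window = 25000)
  labels <- stats::setNames(sim$truth$group, sim$truth$peak)
  expect_identical(simulate_de_table(cfg, gl$truth),
                   simulate_de_table(cfg, gl$truth, links = truth_links,
                                     class_labels = labels))
})

test_that("tissue replicates jitter but stay reproducible at 50% reciprocal", {
  cfg <- sim_config(seed = 23)
  sim <- simulate_atac_timecourse(cfg)
  tis <- simulate_tissue_h3k27ac(cfg, sim)
  expect_setequal(names(tis$replicates), c("pancreas", "liver", "brain", "heart"))
  r <- tis$replicates$pancreas
  kept <- reproducible_peaks(r[[1]], r[[2]])
  expect_gt(nrow(kept) / nrow(r[[1]]), 0.9)
})

test_that("scRNA truth marks exactly the shared signature pairs", {
  cfg <- sim_config(seed = 24, sc_cells_per_cluster = 20)
  sc <- simulate_scrna(cfg)
  expect_equal(sum(sc$truth$shared), cfg$sc_shared)
  expect_equal(nrow(sc$truth), cfg$sc_clusters)
  expect_equal(sort(unique(sc$a$meta$cluster)), paste0("A", 1:5))
  # mitochondrial load close to the configured fraction
  expect_equal(mean(sc$a$meta$mito_fraction), cfg$sc_mito_fraction,
               tolerance = 0.02)
})
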