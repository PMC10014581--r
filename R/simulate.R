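# Synthetic-data generators with planted ground truth. Every input the
# pipeline consumes can be produced here, so all stages are testable
# without external downloads. Each generator draws from its own RNG stream
# (derived from the master seed and a stream label), so adding one
# generator never perturbs another.

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, label))
  force(expr)
}

#' Simulation configuration with study-scale defaults
#'
#' Defaults emulate the study conditions: five stages x two replicates,
#' negative-binomial counts with dispersion 0.1, an 8-fold opening/closing
#' range for dynamic peaks, six planted temporal archetypes, and a synthetic
#' genome of two 10 Mb chromosomes. Over-representation parameters (gene
#' sets, tissue overlaps) are expressed as the target observed/expected
#' ratio, the same estimand the enrichment score measures.
#'
#' @param seed Master seed; all generator streams derive from it.
#' @param ... Overrides for any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    stages = c("ESC", "ADE", "VFGp3", "VFGp6", "PE"),
    replicates_per_stage = 2,
    n_peaks_per_group = 500,
    n_static_peaks = 2000,
    nb_dispersion = 0.1,
    base_mean_range = c(10, 50),      # closed-state mean count
    fold_change = 8,                  # open/closed accessibility ratio
    genome = c(chr1 = 10e6, chr2 = 10e6),
    peak_width_range = c(200, 1000),
    nominal_library_size = 2e7,
    library_size_cv = 0.1,
    # gene linking / DE
    link_rate = 0.3,
    link_distance_range = c(3000, 20000),
    n_noise_genes = 500,
    de_effect = 2,
    de_up_classes = c("PE^PRIMED", "PE^ON"),
    de_down_classes = c("PE^OFF", "VFG^TR"),
    de_overrep = 2.5,                 # target obs/exp of enriched classes
                                      # (feasibility bound is 3 when the
                                      # enriched classes hold 1/3 of links)
    de_rate = 0.8,                    # DE rate within enriched classes
    de_base_mean_range = c(1500, 50000),
    # tissue H3K27ac
    tissues = list(
      pancreas = list(lineage = "endoderm", overrep = c("PE^ON" = 4)),
      liver = list(lineage = "endoderm", overrep = c("VFG^TR" = 2)),
      brain = list(lineage = "ectoderm", overrep = c("ADE^OFF" = 2)),
      heart = list(lineage = "mesoderm", overrep = numeric())
    ),
    tissue_background_rate = 0.1,
    tissue_region_width = c(500, 1500),
    tissue_jitter = 0.2,
    n_private_regions = 200,
    # scRNA
    sc_clusters = 5,
    sc_shared = 3,
    sc_cells_per_cluster = 100,
    sc_genes = 700,
    sc_mito_genes = 10,
    sc_signature_size = 20,
    sc_signature_fold = 6,
    sc_dispersion = 0.3,
    sc_base_mean = 4,
    sc_mito_fraction = 0.05
  )
  cfg[names(list(...))] <- list(...)
  structure(cfg, class = "sim_config")
}

# observed/expected-calibrated per-class hit rate: choosing this rate makes
# the class's expected obs/exp equal `overrep` given the background rate
# and the class share of the universe
planted_rate <- function(overrep, bg_rate, n_class, n_total) {
  if (overrep * n_class >= n_total) {
    stop("over-representation too large for the class share", call. = FALSE)
  }
  r <- overrep * bg_rate * (n_total - n_class) / (n_total - overrep * n_class)
  if (r > 1) stop("implied overlap rate exceeds 1", call. = FALSE)
  r
}

#' Simulate an ATAC-seq time course with planted temporal groups
#'
#' Places non-overlapping peaks uniformly on the synthetic genome, plants
#' six temporal archetype groups plus static peaks, and draws
#' negative-binomial counts whose stage means follow each group's raw
#' accessibility shape scaled between the closed-state mean and
#' `fold_change` times it (and by peak length and library-size factor).
#'
#' @param cfg A [sim_config()].
#' @return A list with `atlas` ([peak_atlas()]), `counts` (matrix),
#'   `samples` (tibble), `m` (the assembled [accessibility_matrix()]) and
#'   `truth` (tibble `peak`, `group`; `"static"` for flat peaks).
#' @export
simulate_atac_timecourse <- function(cfg = sim_config()) {
  shapes <- archetype_shapes(cfg$stages)
  groups <- rownames(shapes)
  n_dyn <- cfg$n_peaks_per_group * length(groups)
  n_total <- n_dyn + cfg$n_static_peaks

  atlas <- with_stream(cfg$seed, "peaks", {
    per_chrom <- table(factor(
      sample(names(cfg$genome), n_total, replace = TRUE), names(cfg$genome)))
    rows <- lapply(names(cfg$genome), function(ch) {
      n <- per_chrom[[ch]]
      if (n == 0) return(NULL)
      slot <- floor(cfg$genome[[ch]] / n)
      if (slot <= max(cfg$peak_width_range) + 1) {
        stop("genome too small to place peaks without overlap", call. = FALSE)
      }
      w <- round(stats::runif(n, cfg$peak_width_range[1], cfg$peak_width_range[2]))
      off <- floor(stats::runif(n, 0, slot - w))
      tibble::tibble(chrom = ch, start = (seq_len(n) - 1) * slot + off,
                     end = (seq_len(n) - 1) * slot + off + w)
    })
    pooled <- dplyr::bind_rows(rows)
    peak_atlas(pooled$chrom, pooled$start, pooled$end,
               genome_label = "synthetic")
  })

  truth <- with_stream(cfg$seed, "groups", {
    lab <- sample(c(rep(groups, each = cfg$n_peaks_per_group),
                    rep("static", cfg$n_static_peaks)))
    tibble::tibble(peak = atlas$name, group = lab)
  })

  samples <- tibble::tibble(
    sample = paste0(rep(cfg$stages, each = cfg$replicates_per_stage), "_r",
                    rep(seq_len(cfg$replicates_per_stage), length(cfg$stages))),
    stage = rep(cfg$stages, each = cfg$replicates_per_stage),
    replicate = rep(seq_len(cfg$replicates_per_stage), length(cfg$stages))
  )

  counts <- with_stream(cfg$seed, "counts", {
    libfac <- exp(stats::rnorm(nrow(samples), 0, cfg$library_size_cv))
    samples$library_size <- round(cfg$nominal_library_size * libfac)
    base <- exp(stats::runif(n_total, log(cfg$base_mean_range[1]),
                             log(cfg$base_mean_range[2])))
    shape <- matrix(0, n_total, length(cfg$stages))
    dyn <- truth$group != "static"
    shape[dyn, ] <- shapes[truth$group[dyn], , drop = FALSE]
    len_fac <- (atlas$end - atlas$start) / 500
    mu_stage <- base * len_fac * cfg$fold_change^shape
    ct <- matrix(0L, n_total, nrow(samples),
                 dimnames = list(atlas$name, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- mu_stage[, match(samples$stage[j], cfg$stages)] * libfac[j]
      ct[, j] <- stats::rnbinom(n_total, mu = mu, size = 1 / cfg$nb_dispersion)
    }
    ct
  })

  m <- accessibility_matrix(counts, samples, atlas, stage_order = cfg$stages)
  list(atlas = atlas, counts = counts, samples = samples, m = m, truth = truth)
}

#' Simulate a gene annotation with planted enhancer-gene links
#'
#' Each dynamic peak gets, with probability `link_rate`, a gene whose TSS
#' lies a random 3-20 kb from the peak midpoint; noise genes are placed
#' uniformly. Linked genes inherit their peak's temporal group in the truth
#' table.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [simulate_atac_timecourse()].
#' @return A list with `genes` (a [gene_annotation()] tibble) and `truth`
#'   (tibble `gene_id`, `peak`, `group`; noise genes have `NA` peak).
#' @export
simulate_gene_links <- function(cfg, sim) {
  with_stream(cfg$seed, "genes", {
    dyn <- sim$truth[sim$truth$group != "static", ]
    linked <- dyn[stats::runif(nrow(dyn)) < cfg$link_rate, ]
    idx <- match(linked$peak, sim$atlas$name)
    mid <- floor((sim$atlas$start[idx] + sim$atlas$end[idx]) / 2)
    d <- round(stats::runif(nrow(linked), cfg$link_distance_range[1],
                            cfg$link_distance_range[2]))
    sign <- sample(c(-1, 1), nrow(linked), replace = TRUE)
    tss <- pmax(mid + sign * d, 0)
    chrom <- sim$atlas$chrom[idx]
    n_noise <- cfg$n_noise_genes
    noise_chrom <- sample(names(cfg$genome), n_noise, replace = TRUE)
    noise_tss <- floor(stats::runif(n_noise, 0, cfg$genome[noise_chrom]))
    gene_id <- sprintf("gene%05d", seq_len(nrow(linked) + n_noise))
    strand <- sample(c("+", "-"), length(gene_id), replace = TRUE)
    all_chrom <- c(chrom, noise_chrom)
    all_tss <- c(tss, noise_tss)
    genes <- gene_annotation(
      gene_id, all_chrom,
      start = ifelse(strand == "+", all_tss, pmax(all_tss - 1000, 0)),
      end = ifelse(strand == "+", all_tss + 1000, all_tss),
      strand = strand
    )
    truth <- tibble::tibble(
      gene_id = gene_id,
      peak = c(linked$peak, rep(NA_character_, n_noise)),
      group = c(linked$group, rep(NA_character_, n_noise))
    )
    list(genes = genes, truth = truth)
  })
}

#' Simulate a differential-expression table consistent with planted links
#'
#' Genes linked to the configured up-classes are drawn as upregulated
#' (log2FC above `de_effect`, small adjusted p, high base mean) at rate
#' `de_rate`; the background rate of the remaining linked genes is derived
#' so the enriched classes' expected observed/expected ratio equals
#' `de_overrep` exactly. Down-classes are analogous with negative effect;
#' noise genes are null.
#'
#' The calibration universe must match the universe the enrichment is later
#' computed over. By default that is the planted one-gene-per-peak truth
#' universe. When the analysis' own link table and class labels are
#' supplied, the planted target genes are instead the genes whose
#' class-labeled links all come from the enriched classes (drawn at
#' `de_rate`), and the background rate of the remaining universe genes is
#' solved so the expected observed/expected ratio over exactly that link
#' universe equals `de_overrep`. With one link per gene from its own
#' planted peak this reduces to the default formula.
#'
#' @param cfg A [sim_config()].
#' @param link_truth The `truth` element of [simulate_gene_links()].
#' @param links Optional peak-gene link table (e.g. from
#'   [nearest_tss_assignment()]) defining the enrichment universe.
#' @param class_labels Optional named vector (peak -> class) used with
#'   `links`; links from unlabeled peaks are excluded, mirroring
#'   [class_geneset_enrichment()].
#' @return A list with `de` (tibble `gene_id`, `baseMean`, `log2fc`,
#'   `padj`) and `truth` (tibble `gene_id`, `direction`).
#' @export
simulate_de_table <- function(cfg, link_truth, links = NULL,
                              class_labels = NULL) {
  with_stream(cfg$seed, "de", {
    n <- nrow(link_truth)
    grp <- link_truth$group
    if (is.null(links)) {
      # truth universe: one link per linked gene, from its own peak
      n_linked <- sum(!is.na(grp))
      n_up_class <- sum(!is.na(grp) & grp %in% cfg$de_up_classes)
      n_down_class <- sum(!is.na(grp) & grp %in% cfg$de_down_classes)
      bg_rate <- function(q, o, n_c) {
        if (n_c == 0) return(0) # no enriched class: nothing to calibrate
        if (o * n_c > n_linked) {
          stop("over-representation too large for the class share",
               call. = FALSE)
        }
        max(q * (n_linked - o * n_c) / (o * (n_linked - n_c)), 0)
      }
      p_up <- ifelse(!is.na(grp) & grp %in% cfg$de_up_classes, cfg$de_rate,
                     bg_rate(cfg$de_rate, cfg$de_overrep, n_up_class))
      p_down <- ifelse(!is.na(grp) & grp %in% cfg$de_down_classes, cfg$de_rate,
                       bg_rate(cfg$de_rate, cfg$de_overrep, n_down_class))
      p_up[is.na(grp)] <- 0
      p_down[is.na(grp)] <- 0
    } else {
      stopifnot(!is.null(class_labels))
      p_up <- universe_rates(cfg$de_rate, cfg$de_overrep, cfg$de_up_classes,
                             link_truth$gene_id, links, class_labels)
      p_down <- universe_rates(cfg$de_rate, cfg$de_overrep,
                               cfg$de_down_classes,
                               link_truth$gene_id, links, class_labels)
    }
    p_down <- pmin(p_down, 1 - p_up)
    u <- stats::runif(n)
    direction <- ifelse(u < p_up, "up",
                        ifelse(u < p_up + p_down, "down", "null"))
    lfc <- stats::rnorm(n, 0, 0.4)
    lfc[direction == "up"] <- cfg$de_effect + stats::rexp(sum(direction == "up"), 2)
    lfc[direction == "down"] <- -cfg$de_effect - stats::rexp(sum(direction == "down"), 2)
    padj <- stats::runif(n)
    padj[direction != "null"] <- stats::runif(sum(direction != "null"), 0, 0.01)
    bm_lo <- log(cfg$de_base_mean_range[1]); bm_hi <- log(cfg$de_base_mean_range[2])
    base_mean <- exp(stats::runif(n, log(10), bm_hi))
    base_mean[direction != "null"] <- exp(stats::runif(sum(direction != "null"),
                                                       bm_lo, bm_hi))
    list(de = tibble::tibble(gene_id = link_truth$gene_id,
                             baseMean = base_mean, log2fc = lfc, padj = padj),
         truth = tibble::tibble(gene_id = link_truth$gene_id,
                                direction = direction))
  })
}

# Per-gene DE rates calibrated over an arbitrary link universe: genes whose
# class-labeled links all come from the enriched classes ("pure" targets)
# get rate q; every other gene in the universe gets the background rate b
# that solves E[observed] = o * expected over that universe. With one link
# per gene, from its own peak, this reduces to the truth-universe formula.
universe_rates <- function(q, o, enriched, gene_ids, links, class_labels) {
  cls <- unname(class_labels[links$peak])
  keep <- !is.na(cls)
  lk <- links$gene_id[keep]
  in_c <- cls[keep] %in% enriched
  l <- tapply(rep(1, length(lk)), lk, sum)
  l_c <- tapply(as.numeric(in_c), lk, sum)
  n_c <- sum(l_c)
  if (n_c == 0) return(rep(0, length(gene_ids)))
  total <- sum(l)
  pure <- l_c == l
  a <- sum(l[pure]) # enriched-class links owned by pure target genes
  k <- o * n_c / total
  b <- q * a * (k - 1) / ((n_c - a) - k * (total - a))
  if (!is.finite(b) || b < 0 || b > 1) {
    stop("over-representation too large for the class share", call. = FALSE)
  }
  p <- ifelse(pure[gene_ids], q, b)
  p[is.na(p)] <- 0 # genes absent from the labeled universe stay null
  as.vector(p)
}

#' Simulate tissue H3K27ac replicate peak sets with planted class overlaps
#'
#' For each configured tissue, every atlas peak spawns an overlapping
#' H3K27ac region with class-specific probability (over-representation
#' calibrated as in [simulate_de_table()]); private background regions are
#' added in the inter-peak space. Two replicates are produced by jittering
#' each region edge by at most `tissue_jitter` of its length, so the 50%
#' reciprocal replicate filter retains nearly all regions.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [simulate_atac_timecourse()].
#' @return A list with `replicates` (tissue -> list of two [peak_atlas()]),
#'   `lineage_map` (tissue -> germ layer) and `truth` (tibble `tissue`,
#'   `peak` of overlapped peaks).
#' @export
simulate_tissue_h3k27ac <- function(cfg, sim) {
  with_stream(cfg$seed, "tissues", {
    atlas <- sim$atlas
    n <- nrow(atlas)
    grp <- sim$truth$group[match(atlas$name, sim$truth$peak)]
    truth <- list()
    replicates <- list()
    for (tn in names(cfg$tissues)) {
      tis <- cfg$tissues[[tn]]
      p <- rep(cfg$tissue_background_rate, n)
      for (cl in names(tis$overrep)) {
        rate <- planted_rate(tis$overrep[[cl]], cfg$tissue_background_rate,
                             sum(grp == cl), n)
        p[grp == cl] <- rate
      }
      hit <- stats::runif(n) < p
      mid <- floor((atlas$start[hit] + atlas$end[hit]) / 2)
      w <- round(stats::runif(sum(hit), cfg$tissue_region_width[1],
                              cfg$tissue_region_width[2]))
      base <- tibble::tibble(chrom = atlas$chrom[hit],
                             start = pmax(mid - floor(w / 2), 0),
                             end = mid + ceiling(w / 2))
      # tissue-private background regions, rejected if they touch the atlas
      priv <- private_regions(cfg, atlas)
      base <- dplyr::bind_rows(base, priv)
      jit <- function() {
        len <- base$end - base$start
        s <- base$start + round(stats::runif(nrow(base), -cfg$tissue_jitter,
                                             cfg$tissue_jitter) * len)
        e <- base$end + round(stats::runif(nrow(base), -cfg$tissue_jitter,
                                           cfg$tissue_jitter) * len)
        s <- pmax(s, 0)
        e <- pmax(e, s + 1)
        peak_atlas(base$chrom, s, e)
      }
      replicates[[tn]] <- list(jit(), jit())
      truth[[tn]] <- tibble::tibble(tissue = tn, peak = atlas$name[hit])
    }
    lineage_map <- vapply(cfg$tissues, `[[`, "", "lineage")
    list(replicates = replicates, lineage_map = lineage_map,
         truth = dplyr::bind_rows(truth))
  })
}

private_regions <- function(cfg, atlas) {
  n <- cfg$n_private_regions
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  ch <- sample(names(cfg$genome), n * 3, replace = TRUE)
  w <- round(stats::runif(n * 3, cfg$tissue_region_width[1],
                          cfg$tissue_region_width[2]))
  s <- floor(stats::runif(n * 3, 0, cfg$genome[ch] - w))
  cand <- peak_atlas(ch, s, s + w)
  free <- intersect_atlas(cand, atlas, mode = "unique_a")
  out <- atlas_tbl(free)[seq_len(min(n, nrow(free))), c("chrom", "start", "end")]
  out
}

#' Simulate two clustered scRNA-seq UMI datasets with shared signatures
#'
#' Negative-binomial counts with cluster-specific signature genes; the first
#' `sc_shared` clusters of each dataset share their signatures (planted
#' alignable pairs), the rest are dataset-unique. Mitochondrial genes
#' (`MT-*`) are scaled to the configured mito fraction.
#'
#' @param cfg A [sim_config()].
#' @return A list with `a`, `b` ([cell_matrix()] objects with cluster
#'   labels in the metadata) and `truth` (tibble `cluster_a`, `cluster_b`,
#'   `shared`).
#' @export
simulate_scrna <- function(cfg = sim_config()) {
  with_stream(cfg$seed, "scrna", {
    n_sig <- cfg$sc_clusters * 2 - cfg$sc_shared
    genes <- c(sprintf("MT-%d", seq_len(cfg$sc_mito_genes)),
               sprintf("g%04d", seq_len(cfg$sc_genes - cfg$sc_mito_genes)))
    non_mito <- genes[-seq_len(cfg$sc_mito_genes)]
    if (n_sig * cfg$sc_signature_size > length(non_mito)) {
      stop("not enough genes for the requested signatures", call. = FALSE)
    }
    sig_pool <- sample(non_mito, n_sig * cfg$sc_signature_size)
    signatures <- split(sig_pool, rep(seq_len(n_sig),
                                      each = cfg$sc_signature_size))
    base_mu <- exp(stats::rnorm(length(genes), log(cfg$sc_base_mean), 0.4))
    names(base_mu) <- genes

    make_dataset <- function(prefix, sig_idx) {
      cl_names <- paste0(prefix, seq_len(cfg$sc_clusters))
      cells <- paste0(prefix, "_cell",
                      seq_len(cfg$sc_clusters * cfg$sc_cells_per_cluster))
      lab <- rep(cl_names, each = cfg$sc_cells_per_cluster)
      mu <- matrix(rep(base_mu, each = length(cells)), length(cells),
                   dimnames = list(cells, genes))
      for (k in seq_len(cfg$sc_clusters)) {
        sel <- lab == cl_names[k]
        mu[sel, signatures[[sig_idx[k]]]] <-
          mu[sel, signatures[[sig_idx[k]]]] * cfg$sc_signature_fold
        # mito genes pinned to the target mitochondrial share of each
        # cluster's post-signature expression
        nm_tot <- sum(base_mu[non_mito]) +
          (cfg$sc_signature_fold - 1) * sum(base_mu[signatures[[sig_idx[k]]]])
        mu[sel, seq_len(cfg$sc_mito_genes)] <-
          cfg$sc_mito_fraction * nm_tot /
          ((1 - cfg$sc_mito_fraction) * cfg$sc_mito_genes)
      }
      umis <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$sc_dispersion),
                     nrow(mu), dimnames = dimnames(mu))
      cell_matrix(umis, tibble::tibble(cell = cells, cluster = lab))
    }
    sig_a <- seq_len(cfg$sc_clusters)
    sig_b <- c(seq_len(cfg$sc_shared),
               cfg$sc_clusters + seq_len(cfg$sc_clusters - cfg$sc_shared))
    a <- make_dataset("A", sig_a)
    b <- make_dataset("B", sig_b)
    truth <- tibble::tibble(
      cluster_a = paste0("A", seq_len(cfg$sc_clusters)),
      cluster_b = paste0("B", seq_len(cfg$sc_clusters)),
      shared = seq_len(cfg$sc_clusters) <= cfg$sc_shared
    )
    list(a = a, b = b, truth = truth)
  })
}
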