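# Bootstrap cluster alignment between two clustered single-cell datasets,
# plus the scRNA QC filters applied upstream.

#' Bundle a cell-by-gene UMI matrix with per-cell metadata
#'
#' @param umis Non-negative integer matrix or sparse Matrix, cells in rows
#'   (rownames = barcodes), genes in columns (colnames = gene ids).
#' @param meta Tibble with one row per cell: `cell`, `cluster`, and
#'   optionally `mito_fraction` (computed from `mito_genes` when absent).
#'   `total_umis` and `n_genes` are always recomputed from the matrix.
#' @param mito_genes Gene ids counted as mitochondrial (default: names
#'   starting `MT-`).
#' @return A `cell_matrix` object.
#' @export
cell_matrix <- function(umis, meta, mito_genes = grep("^MT-", colnames(umis), value = TRUE)) {
  if (is.null(rownames(umis)) || is.null(colnames(umis))) {
    stop("umis needs cell rownames and gene colnames", call. = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("cell", "cluster") %in% names(meta)))
  if (!identical(sort(meta$cell), sort(rownames(umis)))) {
    stop("meta$cell must match the matrix rownames", call. = FALSE)
  }
  meta <- meta[match(rownames(umis), meta$cell), , drop = FALSE]
  tot <- Matrix::rowSums(umis)
  meta$total_umis <- as.numeric(tot)
  meta$n_genes <- as.numeric(Matrix::rowSums(umis > 0))
  if (!"mito_fraction" %in% names(meta)) {
    mito <- if (length(mito_genes)) {
      Matrix::rowSums(umis[, colnames(umis) %in% mito_genes, drop = FALSE])
    } else 0
    meta$mito_fraction <- as.vector(
      ifelse(tot > 0, as.numeric(mito) / as.numeric(tot), 0))
  }
  structure(list(umis = umis, meta = meta), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d genes, %d cluster(s)\n",
              nrow(x$umis), ncol(x$umis), dplyr::n_distinct(x$meta$cluster)))
  invisible(x)
}

#' Quality-filter cells
#'
#' Keeps cells with total UMIs and detected genes strictly inside their
#' bounds and mitochondrial fraction at most `mito_max`; per-criterion
#' removal counts are attached as attribute `removed`.
#'
#' @param m A [cell_matrix()].
#' @param umi_bounds Length-2 numeric `(lower, upper)`, default
#'   `c(2000, 35000)`.
#' @param gene_bounds Length-2 numeric, default `c(550, 4950)`.
#' @param mito_max Maximum mitochondrial content (default 0.20).
#' @return The filtered [cell_matrix()].
#' @export
qc_filter_cells <- function(m, umi_bounds = c(2000, 35000),
                            gene_bounds = c(550, 4950), mito_max = 0.20) {
  stopifnot(umi_bounds[1] < umi_bounds[2], gene_bounds[1] < gene_bounds[2])
  meta <- m$meta
  ok_umi <- meta$total_umis > umi_bounds[1] & meta$total_umis < umi_bounds[2]
  ok_gene <- meta$n_genes > gene_bounds[1] & meta$n_genes < gene_bounds[2]
  ok_mito <- meta$mito_fraction <= mito_max
  keep <- ok_umi & ok_gene & ok_mito
  if (!any(keep)) {
    stop("no cell passes QC; review the thresholds", call. = FALSE)
  }
  out <- structure(list(umis = m$umis[keep, , drop = FALSE],
                        meta = meta[keep, , drop = FALSE]),
                   class = "cell_matrix")
  attr(out, "removed") <- c(umi = sum(!ok_umi), genes = sum(!ok_gene),
                            mito = sum(!ok_mito), total = sum(!keep))
  out
}

#' Library-size log-normalization
#'
#' `ln(1 + scale * count / cell_total)`, the standard per-cell
#' normalization.
#'
#' @param m A [cell_matrix()] with no zero-total cells.
#' @param scale Size factor target (default 1e4).
#' @return A dense cell-by-gene numeric matrix.
#' @export
lognormalize <- function(m, scale = 1e4) {
  tot <- m$meta$total_umis
  if (any(tot == 0)) stop("zero-total cell; filter before normalizing", call. = FALSE)
  x <- as.matrix(m$umis)
  log1p(scale * x / tot)
}

#' Shared highly-variable gene panel for cluster alignment
#'
#' Union of the top `n_top` most variable genes (variance of log-normalized
#' expression) of each dataset, intersected with the genes present in both.
#'
#' @param a,b [cell_matrix()] objects.
#' @param n_top Number of highly variable genes per dataset (default 2000).
#' @return Character vector of gene ids (sorted).
#' @export
select_gene_panel <- function(a, b, n_top = 2000) {
  shared <- intersect(colnames(a$umis), colnames(b$umis))
  hvg <- function(m) {
    v <- apply(lognormalize(m), 2, stats::var)
    names(sort(v, decreasing = TRUE))[seq_len(min(n_top, length(v)))]
  }
  sort(intersect(union(hvg(a), hvg(b)), shared))
}

stream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_along(utf8ToInt(label)) %% 31 + 1))
  (as.numeric(seed) * 7919 + h) %% .Machine$integer.max
}

#' Bootstrap per-cluster mean expression profiles
#'
#' For each cluster, draws `n_boot` resamples of its cells with replacement
#' and records the mean panel expression of each resample. Each cluster has
#' its own RNG stream derived from `seed` and the cluster label, so profiles
#' are reproducible and independent of cluster order.
#'
#' @param normalized Cell-by-gene matrix from [lognormalize()] (optionally
#'   z-scored).
#' @param labels Cluster label per cell (same order as rows).
#' @param gene_panel Genes to profile (subset of columns).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param min_cells Clusters below this size are excluded with a warning.
#' @return A `bootstrap_profiles` object: named list of n_boot-by-panel
#'   matrices plus metadata.
#' @export
bootstrap_cluster_profiles <- function(normalized, labels, gene_panel,
                                       n_boot = 1000, seed = 1,
                                       min_cells = 2) {
  stopifnot(length(labels) == nrow(normalized))
  if (!all(gene_panel %in% colnames(normalized))) {
    stop("gene_panel contains genes absent from the matrix", call. = FALSE)
  }
  x <- normalized[, gene_panel, drop = FALSE]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  profiles <- list()
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(labels == cl)
    if (length(idx) < min_cells) {
      warning("cluster '", cl, "' has fewer than ", min_cells,
              " cells; excluded", call. = FALSE)
      next
    }
    set.seed(stream_seed(seed, paste0("boot:", cl)))
    boots <- matrix(0, n_boot, ncol(x),
                    dimnames = list(NULL, colnames(x)))
    for (b in seq_len(n_boot)) {
      take <- idx[sample.int(length(idx), length(idx), replace = TRUE)]
      boots[b, ] <- colMeans(x[take, , drop = FALSE])
    }
    profiles[[cl]] <- boots
  }
  structure(list(profiles = profiles, gene_panel = gene_panel,
                 n_boot = n_boot, seed = seed),
            class = "bootstrap_profiles")
}

#' Align clusters between two datasets by bootstrap distance
#'
#' For each query cluster, the Euclidean distance from each of its bootstrap
#' mean-expression replicates to every target cluster's bootstrap centroid
#' yields a per-target distance distribution. Targets are ranked by mean
#' distance; a significant alignment to the top r targets is declared at
#' the smallest rank r (up to `rank_depth`) whose rank-r distances are smaller than
#' `(1 - effect_margin)` times the rank-`r+1` distances (one-sided Welch
#' test at level `alpha`). The relative margin makes "nearest but no closer
#' than the rest" clusters non-significant regardless of bootstrap depth.
#'
#' Relative separation alone cannot rule out a cluster with no true partner
#' that merely sits closer to one subset of targets than to another, so a
#' significant pair must in addition be absolutely similar: the Pearson
#' correlation between the query and target centroid profiles across the
#' gene panel must reach `min_cor`. A genuine match shares its standardized
#' expression structure (strongly positive correlation) while an unrelated
#' pair is near zero or negative, so the two conditions together declare
#' "closer than the alternatives, and similar in its own right".
#' A cluster failing either condition has no significant alignment.
#' Alignment is directional (a -> b); mutual nearest pairs are flagged.
#'
#' @param a,b `bootstrap_profiles` over an identical gene panel.
#' @param alpha Test level (default 0.01).
#' @param effect_margin Required relative separation between consecutive
#'   ranks, as a fraction of the farther distance (default 0.1).
#' @param rank_depth Maximum number of targets a cluster may align to
#'   (default 2).
#' @param min_cor Minimum Pearson correlation between query and target
#'   centroid profiles for a pair to be significant (default 0.5: an
#'   aligned pair must share the majority of its profile structure).
#' @return A `cat_alignment` object whose `pairs` tibble has columns
#'   `cluster_a`, `cluster_b`, `rank`, `mean_distance`, `distance_sd`,
#'   `profile_cor`, `p_gap`, `is_significant`, `mutual_nearest`.
#' @export
align_clusters <- function(a, b, alpha = 0.01, effect_margin = 0.1,
                           rank_depth = 2, min_cor = 0.5) {
  stopifnot(effect_margin >= 0, effect_margin < 1, min_cor >= -1, min_cor <= 1)
  if (!identical(a$gene_panel, b$gene_panel)) {
    stop("profiles must share an identical gene panel", call. = FALSE)
  }
  cent_b <- t(vapply(b$profiles, colMeans, numeric(length(b$gene_panel))))
  cent_a <- t(vapply(a$profiles, colMeans, numeric(length(a$gene_panel))))
  dist_rows <- function(boots, cent) {
    sqrt(pmax(outer(rowSums(boots^2), rowSums(cent^2), "+") -
                2 * tcrossprod(boots, cent), 0))
  }
  nearest_of <- function(profiles, cent) {
    vapply(profiles, function(p) {
      rownames(cent)[which.min(colMeans(dist_rows(p, cent)))]
    }, character(1))
  }
  nearest_ab <- nearest_of(a$profiles, cent_b)
  nearest_ba <- if (length(b$profiles) > 0) nearest_of(b$profiles, cent_a) else character()

  out <- lapply(names(a$profiles), function(ca) {
    d <- dist_rows(a$profiles[[ca]], cent_b) # n_boot x n_targets
    mu <- colMeans(d)
    ord <- order(mu)
    n_t <- length(mu)
    cors <- apply(cent_b, 1, function(cb) {
      suppressWarnings(stats::cor(cent_a[ca, ], cb)) # NA for constant profiles
    })
    rows <- tibble::tibble(
      cluster_a = ca,
      cluster_b = rownames(cent_b)[ord],
      rank = seq_len(n_t),
      mean_distance = mu[ord],
      distance_sd = apply(d, 2, stats::sd)[ord],
      profile_cor = as.vector(cors[ord]),
      p_gap = NA_real_,
      is_significant = FALSE
    )
    if (n_t >= 2) {
      aligned_to <- 0L
      for (r in seq_len(min(rank_depth, n_t - 1))) {
        p <- welch_less(d[, ord[r]], d[, ord[r + 1]], margin = effect_margin)
        rows$p_gap[r] <- p
        if (!is.na(p) && p < alpha) {
          aligned_to <- r
          break
        }
      }
      if (aligned_to > 0) {
        sig <- seq_len(aligned_to)
        rows$is_significant[sig] <- !is.na(rows$profile_cor[sig]) &
          rows$profile_cor[sig] >= min_cor
      }
    }
    rows
  })
  pairs <- dplyr::bind_rows(out) |>
    dplyr::mutate(mutual_nearest = .data$rank == 1 &
                    !is.na(nearest_ba[.data$cluster_b]) &
                    nearest_ba[.data$cluster_b] == .data$cluster_a)
  structure(list(pairs = pairs,
                 criterion = list(alpha = alpha, effect_margin = effect_margin,
                                  rank_depth = rank_depth, min_cor = min_cor,
                                  n_boot = a$n_boot,
                                  panel_size = length(a$gene_panel))),
            class = "cat_alignment")
}

# one-sided Welch test that mean(x) < (1 - margin) * mean(y); robust to
# zero-variance inputs
welch_less <- function(x, y, margin = 0) {
  y <- (1 - margin) * y
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (mean(x) < mean(y)) 0 else 1)
  }
  stats::t.test(x, y, alternative = "less")$p.value
}

#' @export
print.cat_alignment <- function(x, ...) {
  sig <- x$pairs[x$pairs$is_significant, ]
  cat(sprintf("cat_alignment: %d query cluster(s), %d significant pair(s)\n",
              dplyr::n_distinct(x$pairs$cluster_a), nrow(sig)))
  if (nrow(sig)) print(sig[, c("cluster_a", "cluster_b", "mean_distance")])
  invisible(x)
}

#' Z-score genes across cells
#'
#' Removes per-gene platform scale before computing cross-dataset distances;
#' constant genes become zero columns.
#'
#' @param normalized Cell-by-gene matrix from [lognormalize()].
#' @return Matrix of the same shape.
#' @export
zscore_genes <- function(normalized) {
  mu <- colMeans(normalized)
  sd <- apply(normalized, 2, stats::sd)
  z <- sweep(sweep(normalized, 2, mu), 2, ifelse(sd > 0, sd, 1), "/")
  z[, sd == 0] <- 0
  z
}

#' Read a Matrix Market UMI matrix with row/column annotation files
#'
#' @param mtx_path Matrix Market file (genes x cells or cells x genes,
#'   see `cells_in_rows`).
#' @param genes_path,barcodes_path One-column TSVs (no header).
#' @param cells_in_rows Set `TRUE` when the matrix is cells x genes.
#' @return A sparse cell-by-gene matrix.
#' @export
read_umi_mtx <- function(mtx_path, genes_path, barcodes_path,
                         cells_in_rows = FALSE) {
  m <- Matrix::readMM(mtx_path)
  genes <- readr::read_lines(genes_path)
  cells <- readr::read_lines(barcodes_path)
  if (!cells_in_rows) m <- Matrix::t(m)
  rownames(m) <- cells
  colnames(m) <- genes
  m
}
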