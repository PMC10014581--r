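#' Read a gene annotation table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' The TSS is strand-resolved: span start for `+`, span end for `-`.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  gene_annotation(g$gene_id, g$chrom, g$start, g$end, g$strand)
}

#' Build a gene annotation from spans
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open gene span.
#' @param strand `"+"` or `"-"`; resolves which span edge is the TSS.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id)) stop("gene_id must be unique", call. = FALSE)
  if (!all(strand %in% c("+", "-"))) stop("strand must be + or -", call. = FALSE)
  tss <- ifelse(strand == "+", start, end)
  if (any(tss < 0)) stop("TSS must be >= 0", call. = FALSE)
  tibble::tibble(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 tss = as.numeric(tss), strand = strand)
}

#' Assign each peak to its single nearest gene within a window
#'
#' Distance is measured from the peak midpoint (`floor((start+end)/2)`) to
#' the TSS, unstranded. Peaks whose nearest TSS lies beyond `window` bp are
#' left unassigned (dropped from the table). Equidistant ties resolve to the
#' lexicographically smaller `gene_id`, with a warning.
#'
#' @param peaks A [peak_atlas()].
#' @param genes A [gene_annotation()] tibble.
#' @param window Maximum midpoint-to-TSS distance in bp (e.g. 25000 or
#'   200000).
#' @return A tibble with columns `peak`, `gene_id`, `distance`, `window`;
#'   at most one row per peak.
#' @export
nearest_tss_assignment <- function(peaks, genes, window) {
  stopifnot(window > 0)
  if (nrow(genes) == 0 || nrow(peaks) == 0) {
    return(tibble::tibble(peak = character(), gene_id = character(),
                          distance = numeric(), window = numeric()))
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  tied <- 0L
  res <- lapply(split(seq_len(nrow(peaks)), peaks$chrom), function(idx) {
    ch <- peaks$chrom[idx[1]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    # sort TSS; ties on distance resolved by lexicographic gene_id
    g <- g[order(g$tss, g$gene_id, method = "radix"), , drop = FALSE]
    pos <- findInterval(mid[idx], g$tss)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, nrow(g))
    d_lo <- abs(mid[idx] - g$tss[lo])
    d_hi <- abs(mid[idx] - g$tss[hi])
    # candidate set may contain duplicated tss values; expand around the
    # minimum to honour the lexicographic tie-break exactly
    best <- pmin(d_lo, d_hi)
    pick <- character(length(idx))
    for (q in seq_along(idx)) {
      cand <- which(abs(g$tss - mid[idx][q]) == best[q])
      if (length(cand) > 1) tied <<- tied + 1L
      pick[q] <- g$gene_id[cand[order(g$gene_id[cand])[1]]]
    }
    tibble::tibble(peak = peaks$name[idx], gene_id = pick, distance = best)
  })
  if (tied > 0) {
    warning(tied, " equidistant TSS tie(s) broken by gene_id order",
            call. = FALSE)
  }
  dplyr::bind_rows(res) |>
    dplyr::filter(.data$distance <= window) |>
    dplyr::mutate(window = window) |>
    dplyr::arrange(match(.data$peak, peaks$name))
}

#' Drop promoter-proximal peaks
#'
#' Putative-enhancer selection: peaks whose midpoint lies within `tss_pad`
#' bp of any TSS are removed before temporal clustering.
#'
#' @param peaks A [peak_atlas()].
#' @param genes A [gene_annotation()] tibble.
#' @param tss_pad Promoter half-width in bp (default 2000).
#' @return The promoter-distal subset of `peaks`.
#' @export
filter_promoter_distal <- function(peaks, genes, tss_pad = 2000) {
  if (nrow(genes) == 0) return(peaks)
  prox <- nearest_tss_assignment(peaks, genes, window = tss_pad)
  keep <- !(peaks$name %in% prox$peak)
  out <- atlas_tbl(peaks)[keep, , drop = FALSE]
  as_peak_atlas(out, genome_label = attr(peaks, "genome_label"))
}

#' Threshold a differential-expression table into a gene set
#'
#' Keeps genes with `baseMean > base_mean_min`, adjusted p below `padj_max`
#' and `log2fc > lfc_min` (direction `"up"`) or `log2fc < -lfc_min`
#' (direction `"down"`). Genes with missing adjusted p are excluded.
#'
#' @param de Tibble with columns `gene_id`, `baseMean`, `log2fc`, `padj`.
#' @param base_mean_min Minimum mean normalized expression (default 1000).
#' @param lfc_min Minimum absolute log2 fold change (default 1.5).
#' @param padj_max Maximum adjusted p (default 0.05).
#' @param direction `"up"` or `"down"`.
#' @return A character vector of gene ids.
#' @export
filter_de_genes <- function(de, base_mean_min = 1000, lfc_min = 1.5,
                            padj_max = 0.05, direction = c("up", "down")) {
  direction <- match.arg(direction)
  keep <- !is.na(de$padj) & de$baseMean > base_mean_min & de$padj < padj_max
  keep <- keep & if (direction == "up") de$log2fc > lfc_min else de$log2fc < -lfc_min
  de$gene_id[keep]
}

#' Read a differential-expression result table
#'
#' TSV with header columns `gene`, `baseMean`, `log2FoldChange`, `padj`
#' (DESeq2-style naming accepted).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `baseMean`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(d)
  gene_col <- intersect(c("gene", "gene_id"), nm)[1]
  lfc_col <- intersect(c("log2FoldChange", "log2fc"), nm)[1]
  if (is.na(gene_col) || is.na(lfc_col) || !all(c("baseMean", "padj") %in% nm)) {
    stop("DE table needs gene, baseMean, log2FoldChange and padj columns",
         call. = FALSE)
  }
  tibble::tibble(gene_id = as.character(d[[gene_col]]),
                 baseMean = d$baseMean, log2fc = d[[lfc_col]], padj = d$padj)
}

#' Cluster gene-expression patterns
#'
#' Z-scores each gene's condition-mean profile and cuts an agglomerative
#' tree (average linkage, Euclidean distance) at `k` clusters. Constant
#' profiles go to a dedicated `"flat"` cluster. Deterministic.
#'
#' @param expr Gene-by-condition numeric matrix of normalized means
#'   (rownames = gene ids).
#' @param k Number of clusters (default 10).
#' @return A tibble with columns `gene_id`, `cluster` (character; `"flat"`
#'   or `"1" .. "k"`).
#' @export
cluster_expression_patterns <- function(expr, k = 10) {
  expr <- as.matrix(expr)
  flat <- apply(expr, 1, stats::sd) == 0
  z <- zscore_rows(expr[!flat, , drop = FALSE])
  if (nrow(z) < k) stop("need at least k non-constant genes", call. = FALSE)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "average")
  lab <- stats::cutree(hc, k = k)
  tibble::tibble(
    gene_id = c(rownames(z), rownames(expr)[flat]),
    cluster = c(as.character(lab), rep("flat", sum(flat)))
  ) |>
    dplyr::arrange(match(.data$gene_id, rownames(expr)))
}
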