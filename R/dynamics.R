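#' Bundle a peak-by-sample count matrix with its metadata
#'
#' @param counts Non-negative integer matrix, peaks in rows (rownames = peak
#'   names present in `atlas`), samples in columns.
#' @param samples Tibble with columns `sample`, `stage`, `replicate`,
#'   `library_size` (total mapped insertions, > 0), one row per column of
#'   `counts`.
#' @param atlas The [peak_atlas()] the rows belong to.
#' @param stage_order Ordered stage labels; defaults to order of first
#'   appearance in `samples`.
#' @return An `accessibility_matrix` object.
#' @export
accessibility_matrix <- function(counts, samples, atlas,
                                 stage_order = unique(samples$stage)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts needs peak rownames", call. = FALSE)
  if (!all(rownames(counts) %in% atlas$name)) {
    stop("every counted peak must exist in the atlas", call. = FALSE)
  }
  if (nrow(samples) != ncol(counts)) {
    stop("one sample-sheet row per counts column required", call. = FALSE)
  }
  if (!all(samples$stage %in% stage_order)) {
    stop("samples contain stages missing from stage_order", call. = FALSE)
  }
  if (dplyr::n_distinct(samples$stage) < 2) stop(">= 2 stages required", call. = FALSE)
  if (any(samples$library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  colnames(counts) <- samples$sample
  structure(
    list(counts = counts,
         samples = tibble::as_tibble(samples),
         atlas = atlas,
         stage_order = stage_order),
    class = "accessibility_matrix"
  )
}

#' @export
print.accessibility_matrix <- function(x, ...) {
  cat(sprintf("accessibility_matrix: %d peaks x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$stage_order, collapse = " > ")))
  invisible(x)
}

#' RPKM-normalize an accessibility matrix
#'
#' Reads per kilobase of peak per million library insertions:
#' `count / (length_kb * library_size_millions)`.
#'
#' @param m An [accessibility_matrix()].
#' @return A numeric peak-by-sample matrix.
#' @export
rpkm_normalize <- function(m) {
  len <- peak_lengths(m)
  if (any(len <= 0)) stop("zero-length peak", call. = FALSE)
  sweep(m$counts / (len / 1000), 2, m$samples$library_size / 1e6, "/")
}

peak_lengths <- function(m) {
  idx <- match(rownames(m$counts), m$atlas$name)
  m$atlas$end[idx] - m$atlas$start[idx]
}

nb_dispersions <- function(m, design, dispersion = c("eb", "mom")) {
  dispersion <- match.arg(dispersion)
  if (dispersion == "mom") return(estimate_dispersions(m))
  y <- edgeR::DGEList(m$counts, lib.size = m$samples$library_size)
  y <- edgeR::estimateDisp(y, design)
  y$tagwise.dispersion
}

# Method-of-moments NB dispersion per peak on library-size-scaled counts,
# floored at `floor` then shrunk 50% toward the global median.
estimate_dispersions <- function(m, floor = 0.01, shrink = 0.5) {
  sf <- m$samples$library_size / mean(m$samples$library_size)
  q <- sweep(m$counts, 2, sf, "/")
  stages <- split(seq_len(ncol(q)), m$samples$stage)
  per_stage <- lapply(stages, function(cols) {
    if (length(cols) < 2) return(rep(NA_real_, nrow(q)))
    mu <- rowMeans(q[, cols, drop = FALSE])
    v <- apply(q[, cols, drop = FALSE], 1, stats::var)
    ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  })
  alpha <- rowMeans(do.call(cbind, per_stage), na.rm = TRUE)
  alpha[!is.finite(alpha)] <- floor
  alpha <- pmax(alpha, floor)
  med <- stats::median(alpha)
  (1 - shrink) * alpha + shrink * med
}

#' Detect dynamic peaks across the time course
#'
#' Fits, per peak, a log-link generalized linear model of counts on the
#' stage factor with a log library-size offset under a negative-binomial
#' error (per-peak method-of-moments dispersion, floored and shrunk toward
#' the global median), and tests the stage factor against the
#' intercept-only model by likelihood ratio. A peak is called dynamic when
#' its largest absolute stage-versus-reference log2 fold change exceeds
#' `lfc_threshold` *and* its Benjamini-Hochberg adjusted p-value is below
#' `padj_threshold` (both strict).
#'
#' @param m An [accessibility_matrix()]; at least two replicates per stage.
#' @param lfc_threshold Minimum `|log2FC|` (default 2).
#' @param padj_threshold Maximum BH-adjusted p (default 0.005).
#' @param method `"nb"` (negative binomial, default) or `"gaussian"`
#'   (ordinary F-test on `log2(RPKM + 1)`).
#' @param dispersion `"eb"` (default) shares dispersion information across
#'   peaks by empirical Bayes (calibrated at small replicate numbers);
#'   `"mom"` uses the raw per-peak method-of-moments estimate floored at
#'   0.01 and shrunk 50% toward the global median (anti-conservative with
#'   two replicates; retained for comparison).
#' @return A tibble with columns `peak`, `log2fc_max`, `pvalue`, `padj`,
#'   `is_dynamic`.
#' @export
detect_dynamic_peaks <- function(m, lfc_threshold = 2, padj_threshold = 0.005,
                                 method = c("nb", "gaussian"),
                                 dispersion = c("eb", "mom")) {
  method <- match.arg(method)
  dispersion <- match.arg(dispersion)
  stage <- factor(m$samples$stage, levels = m$stage_order)
  design <- stats::model.matrix(~stage)
  zero <- rowSums(m$counts) == 0
  if (method == "nb") {
    disp <- nb_dispersions(m, design, dispersion)
    fit <- edgeR::glmFit(m$counts, design = design, dispersion = disp,
                         offset = log(m$samples$library_size),
                         prior.count = 0.125)
    lrt <- edgeR::glmLRT(fit, coef = seq_len(nlevels(stage))[-1])
    lfc_cols <- grep("^logFC", colnames(lrt$table), value = TRUE)
    lfc <- as.matrix(lrt$table[, lfc_cols, drop = FALSE])
    log2fc_max <- apply(abs(lfc), 1, max)
    pvalue <- lrt$table$PValue
  } else {
    y <- log2(rpkm_normalize(m) + 1)
    res <- anova_rows(y, stage)
    log2fc_max <- res$log2fc_max
    pvalue <- res$pvalue
  }
  log2fc_max[zero] <- 0
  pvalue[zero] <- 1
  padj <- stats::p.adjust(pvalue, method = "BH")
  tibble::tibble(
    peak = rownames(m$counts),
    log2fc_max = unname(log2fc_max),
    pvalue = unname(pvalue),
    padj = unname(padj),
    is_dynamic = abs(log2fc_max) > lfc_threshold & padj < padj_threshold
  )
}

# Vectorized one-way ANOVA across matrix rows; lfc = stage mean minus
# reference stage mean (already log2 scale).
anova_rows <- function(y, stage) {
  n <- ncol(y)
  k <- nlevels(stage)
  grp <- lapply(levels(stage), function(s) which(stage == s))
  means <- vapply(grp, function(cols) rowMeans(y[, cols, drop = FALSE]),
                  numeric(nrow(y)))
  fitted <- means[, as.integer(stage), drop = FALSE]
  rss1 <- rowSums((y - fitted)^2)
  rss0 <- rowSums((y - rowMeans(y))^2)
  fstat <- ((rss0 - rss1) / (k - 1)) / (rss1 / (n - k))
  p <- stats::pf(fstat, k - 1, n - k, lower.tail = FALSE)
  p[rss1 == 0 & rss0 == 0] <- 1
  lfc <- abs(means[, -1, drop = FALSE] - means[, 1])
  list(log2fc_max = apply(lfc, 1, max), pvalue = ifelse(is.na(p), 1, p))
}

#' Stage-mean z-scored trajectories
#'
#' Replicate-averages `log2(RPKM + 1)` per stage and z-scores each peak's
#' trajectory across stages (constant trajectories become all-zero rows).
#'
#' @param m An [accessibility_matrix()].
#' @param peaks Optional character vector restricting rows (e.g. dynamic
#'   peak names).
#' @return A peak-by-stage matrix of z-scores with stages in time order.
#' @export
standardize_trajectories <- function(m, peaks = NULL) {
  y <- log2(rpkm_normalize(m) + 1)
  if (!is.null(peaks)) y <- y[peaks, , drop = FALSE]
  stage <- factor(m$samples$stage, levels = m$stage_order)
  means <- vapply(levels(stage), function(s) {
    rowMeans(y[, stage == s, drop = FALSE])
  }, numeric(nrow(y)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(rownames(y), levels(stage)))
  }
  zscore_rows(means)
}

zscore_rows <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Read a counts TSV (first column peak names) and its sample sheet
#'
#' @param counts_path TSV with header: `peak` then one column per sample.
#' @param samples_path TSV with header: `sample`, `stage`, `replicate`,
#'   `library_size`.
#' @param atlas The [peak_atlas()] the counts refer to.
#' @param stage_order Optional explicit stage order.
#' @return An [accessibility_matrix()].
#' @export
read_accessibility <- function(counts_path, samples_path, atlas,
                               stage_order = NULL) {
  ct <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  sm <- readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  counts <- as.matrix(ct[, -1])
  rownames(counts) <- ct[[1]]
  counts <- counts[, sm$sample, drop = FALSE]
  accessibility_matrix(counts, sm, atlas,
                       stage_order = stage_order %||% unique(sm$stage))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
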