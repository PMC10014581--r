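# Pairwise stage-transition classes and cross-protocol class construction.

# Two-stage NB GLM likelihood-ratio test; lfc is the log2 fold change of
# stage_b over stage_a.
pair_test <- function(m, stage_a, stage_b, method = c("nb", "gaussian")) {
  method <- match.arg(method)
  keep <- m$samples$stage %in% c(stage_a, stage_b)
  sub <- accessibility_matrix(m$counts[, keep, drop = FALSE],
                              m$samples[keep, ], m$atlas,
                              stage_order = c(stage_a, stage_b))
  stage <- factor(sub$samples$stage, levels = c(stage_a, stage_b))
  if (method == "nb") {
    design <- stats::model.matrix(~stage)
    disp <- nb_dispersions(sub, design, "eb")
    fit <- edgeR::glmFit(sub$counts, design = design,
                         dispersion = disp,
                         offset = log(sub$samples$library_size),
                         prior.count = 0.125)

    lrt <- edgeR::glmLRT(fit, coef = 2)
    lfc <- lrt$table$logFC
    pvalue <- lrt$table$PValue
  } else {
    y <- log2(rpkm_normalize(sub) + 1)
    mu_a <- rowMeans(y[, stage == stage_a, drop = FALSE])
    mu_b <- rowMeans(y[, stage == stage_b, drop = FALSE])
    lfc <- mu_b - mu_a
    pvalue <- anova_rows(y, stage)$pvalue
  }
  zero <- rowSums(sub$counts) == 0
  lfc[zero] <- 0
  pvalue[zero] <- 1
  tibble::tibble(peak = rownames(sub$counts), lfc = lfc, pvalue = pvalue,
                 padj = stats::p.adjust(pvalue, method = "BH"))
}

#' Classify peaks by the stage at which they first open or close
#'
#' Over the transitions into the two expansion stages (stage positions 3 and
#' 4 of the declared order, e.g. ADE->VFGp3 and VFGp3->VFGp6), peaks are
#' classified as `<stage>^OPEN` when they gain accessibility significantly
#' at that transition and were not already open at any earlier stage, and as
#' `<stage>^CLOSE` when they were open at the preceding stage and lose
#' accessibility significantly. Each peak enters the earliest class whose
#' definition it satisfies ("first time" logic), so classes are disjoint.
#' A peak counts as open at a stage when its replicate-averaged
#' `log2(RPKM+1)` there exceeds the midpoint of its own range across stages.
#'
#' @param m An [accessibility_matrix()] with >= 4 ordered stages.
#' @param lfc_threshold,padj_threshold Significance thresholds for the
#'   per-transition GLM test (defaults 2 and 0.005).
#' @param method GLM flavour, as in [detect_dynamic_peaks()].
#' @return A tibble with columns `peak`, `class` (one of the four
#'   `OPEN`/`CLOSE` labels or `"none"`).
#' @export
pairwise_open_close <- function(m, lfc_threshold = 2, padj_threshold = 0.005,
                                method = c("nb", "gaussian")) {
  method <- match.arg(method)
  so <- m$stage_order
  if (length(so) < 4) stop("need >= 4 ordered stages", call. = FALSE)
  traj <- stage_log_means(m)
  mid <- (apply(traj, 1, min) + apply(traj, 1, max)) / 2
  open <- traj > mid # strict: flat trajectories are never "open"

  t3 <- pair_test(m, so[2], so[3], method = method)
  t4 <- pair_test(m, so[3], so[4], method = method)
  sig <- function(t, sign) {
    if (sign > 0) t$lfc > lfc_threshold & t$padj < padj_threshold
    else t$lfc < -lfc_threshold & t$padj < padj_threshold
  }
  cls <- rep("none", nrow(traj))
  take <- function(cls, cond, label) ifelse(cls == "none" & cond, label, cls)
  cls <- take(cls, sig(t3, +1) & !open[, so[1]] & !open[, so[2]],
              paste0(so[3], "^OPEN"))
  cls <- take(cls, sig(t3, -1) & open[, so[2]], paste0(so[3], "^CLOSE"))
  cls <- take(cls, sig(t4, +1) & !open[, so[1]] & !open[, so[2]] & !open[, so[3]],
              paste0(so[4], "^OPEN"))
  cls <- take(cls, sig(t4, -1) & open[, so[3]], paste0(so[4], "^CLOSE"))
  tibble::tibble(peak = rownames(traj), class = cls)
}

stage_log_means <- function(m) {
  y <- log2(rpkm_normalize(m) + 1)
  stage <- factor(m$samples$stage, levels = m$stage_order)
  means <- vapply(levels(stage), function(s) {
    rowMeans(y[, stage == s, drop = FALSE])
  }, numeric(nrow(y)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(rownames(y), levels(stage)))
  }
  means
}

#' Compare temporal classes against an external differentiation protocol
#'
#' Splits the pancreas-directed classes by their accessibility in an
#' external directed-differentiation peak set (stages such as DE, FG, PP1):
#' elements accessible in both protocols (`PE-PP1-common`), elements not
#' induced in the external protocol (`PE-not-PP1`), decommissioned elements
#' that are accessible there (`VFG^OFF-in-DE-PP1`), and transient elements
#' accessible at the external pancreatic-progenitor stage (`VFG^TR-in-PP1`).
#' Overlap is any-overlap (>= 1 bp); the "not" class uses the unique
#' (`-v`) semantics.
#'
#' @param class_atlases Named list of [peak_atlas()] per temporal group;
#'   must contain `PE^PRIMED`, `PE^ON`, `VFG^OFF`, `VFG^TR`.
#' @param external Named list of [peak_atlas()] for the external protocol
#'   stages; must contain `PP1`, and `DE` when available.
#' @return Named list of [peak_atlas()] per cross-protocol class.
#' @export
cross_protocol_classes <- function(class_atlases, external) {
  need <- c("PE^PRIMED", "PE^ON", "VFG^OFF", "VFG^TR")
  if (!all(need %in% names(class_atlases))) {
    stop("class_atlases must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"PP1" %in% names(external)) stop("external needs a PP1 atlas", call. = FALSE)
  pe_set <- bind_atlases(class_atlases[c("PE^PRIMED", "PE^ON")])
  pp1 <- external$PP1
  de_pp1 <- if ("DE" %in% names(external)) {
    consensus_atlas(list(external$DE, pp1))
  } else pp1
  list(
    "PE-PP1-common" = intersect_atlas(pe_set, pp1, mode = "report_a"),
    "PE-not-PP1" = intersect_atlas(pe_set, pp1, mode = "unique_a"),
    "VFG^OFF-in-DE-PP1" = intersect_atlas(class_atlases$`VFG^OFF`, de_pp1,
                                          mode = "report_a"),
    "VFG^TR-in-PP1" = intersect_atlas(class_atlases$`VFG^TR`, pp1,
                                      mode = "report_a")
  )
}

# concatenate atlases drawn from one universe, keeping names
bind_atlases <- function(atlases) {
  pooled <- dplyr::bind_rows(lapply(atlases, atlas_tbl))
  pooled <- dplyr::distinct(pooled, .data$name, .keep_all = TRUE)
  peak_atlas(pooled$chrom, pooled$start, pooled$end, name = pooled$name)
}

#' Split a peak atlas into per-group atlases
#'
#' @param atlas The universe [peak_atlas()].
#' @param labels Named character vector (names = peak names, values = group).
#' @return Named list of [peak_atlas()], one per group.
#' @export
split_atlas_by_group <- function(atlas, labels) {
  x <- atlas_tbl(atlas)
  x$group <- unname(labels[x$name])
  x <- x[!is.na(x$group), , drop = FALSE]
  lapply(split(x, x$group), function(g) {
    peak_atlas(g$chrom, g$start, g$end, name = g$name)
  })
}
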