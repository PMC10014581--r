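# Observed/expected enrichment of enhancer classes against gene sets and
# tissue H3K27ac region sets, with chi-squared significance.

# 2x2 chi-squared (class vs rest) x (in-set vs not), 1 df, no continuity
# correction, computed from the contingency expectation directly.
chisq_2x2 <- function(obs_in, obs_out, rest_in, rest_out) {
  tab <- c(obs_in, obs_out, rest_in, rest_out)
  n <- sum(tab)
  row1 <- obs_in + obs_out
  col1 <- obs_in + rest_in
  exp_tab <- c(row1 * col1, row1 * (n - col1),
               (n - row1) * col1, (n - row1) * (n - col1)) / n
  if (any(exp_tab == 0)) return(list(chi2 = NA_real_, pvalue = NA_real_))
  chi2 <- sum((tab - exp_tab)^2 / exp_tab)
  list(chi2 = chi2, pvalue = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

enrichment_row <- function(class_name, set_name, observed, n_class,
                           in_set_total, total) {
  expected <- n_class * in_set_total / total
  if (!is.finite(expected) || expected == 0) { # NaN when the universe is empty
    return(tibble::tibble(class_name = class_name, set_name = set_name,
                          observed = observed, expected = expected,
                          score = NA_real_, chi2 = NA_real_,
                          pvalue = NA_real_, censored = NA))
  }
  score <- log2(observed / expected) # -Inf sentinel when observed == 0
  cs <- chisq_2x2(observed, n_class - observed,
                  in_set_total - observed,
                  (total - n_class) - (in_set_total - observed))
  tibble::tibble(class_name = class_name, set_name = set_name,
                 observed = observed, expected = expected, score = score,
                 chi2 = cs$chi2, pvalue = cs$pvalue,
                 censored = observed == 0)
}

#' Enrichment of enhancer classes in a differential-expression gene set
#'
#' For each class, counts the linked peaks whose gene belongs to the set
#' (observed) against the two-way contingency expectation
#' `n_class * in_set_linked / linked_total`, reports the
#' `log2(observed/expected)` score and a 1-df chi-squared test on the
#' implied 2x2 table (class vs rest) x (in-set vs not), without continuity
#' correction. Optionally adds a permutation p-value from shuffling peak
#' class labels.
#'
#' The universe of the test is the links whose peak carries a class label:
#' the 2x2 table contrasts one class against the other classes, so links
#' from unclassified peaks (e.g. static peaks in a link table computed over
#' the whole atlas) are excluded before any total is formed. Including them
#' would dilute the expected in-set rate with peaks that were never
#' candidates for any class.
#'
#' @param links A peak-gene link table from [nearest_tss_assignment()].
#' @param class_labels Named character vector: peak name -> class. Links
#'   from peaks without a label are dropped from the universe.
#' @param gene_set Character vector of gene ids.
#' @param set_name Label recorded in the `set_name` column.
#' @param n_perm Number of label permutations for the optional Monte-Carlo
#'   p-value (0 = off).
#' @param seed Seed for the permutations.
#' @return An `enrichment_result` tibble: `class_name`, `set_name`,
#'   `observed`, `expected`, `score`, `chi2`, `pvalue`, `censored`
#'   (and `p_perm` when `n_perm > 0`).
#' @export
class_geneset_enrichment <- function(links, class_labels, gene_set,
                                     set_name = "gene_set", n_perm = 0,
                                     seed = 1) {
  cls <- unname(class_labels[links$peak])
  links <- links[!is.na(cls), , drop = FALSE]
  cls <- cls[!is.na(cls)]
  in_set <- links$gene_id %in% gene_set
  classes <- sort(unique(stats::na.omit(unname(class_labels))))
  total <- nrow(links)
  in_set_total <- sum(in_set)
  res <- dplyr::bind_rows(lapply(classes, function(cl) {
    sel <- !is.na(cls) & cls == cl
    enrichment_row(cl, set_name, observed = sum(sel & in_set),
                   n_class = sum(sel), in_set_total = in_set_total,
                   total = total)
  }))
  if (n_perm > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    obs_dev <- abs(res$observed - res$expected)
    exceed <- matrix(0, nrow(res), 1)
    for (p in seq_len(n_perm)) {
      perm <- sample(cls)
      dev <- vapply(classes, function(cl) {
        sel <- !is.na(perm) & perm == cl
        abs(sum(sel & in_set) - sum(sel) * in_set_total / total)
      }, numeric(1))
      exceed <- exceed + (dev >= obs_dev)
    }
    res$p_perm <- (exceed[, 1] + 1) / (n_perm + 1)
  }
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Replicate-consistent, tissue-unique and lineage-unique H3K27ac sets
#'
#' Per tissue, keeps the peaks present in both replicates (50% reciprocal
#' overlap); tissues with a single replicate pass through unfiltered with a
#' warning. Tissue-unique regions are those with no overlap in any other
#' tissue (then sorted and merged); lineage-unique sets are built the same
#' way on the concatenated member-tissue sets per germ layer.
#'
#' @param replicate_peaks Named list: tissue -> list of 1 or 2
#'   [peak_atlas()] replicates.
#' @param lineage_map Named character vector: tissue -> germ layer.
#' @param min_frac Reciprocal replicate-overlap fraction (default 0.5).
#' @return A `tissue_region_sets` list with elements `tissue` (named list of
#'   replicate-consistent atlases), `tissue_unique` and `lineage_unique`.
#' @export
build_tissue_sets <- function(replicate_peaks, lineage_map, min_frac = 0.5) {
  stopifnot(length(replicate_peaks) >= 1)
  missing <- setdiff(names(replicate_peaks), names(lineage_map))
  if (length(missing)) {
    stop("tissue(s) missing from lineage_map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  consistent <- lapply(names(replicate_peaks), function(t) {
    reps <- replicate_peaks[[t]]
    if (length(reps) == 1) {
      warning("tissue '", t, "' has a single replicate; passed unfiltered",
              call. = FALSE)
      reps[[1]]
    } else {
      reproducible_peaks(reps[[1]], reps[[2]], min_frac = min_frac,
                         reciprocal = TRUE)
    }
  })
  names(consistent) <- names(replicate_peaks)

  uniq_against <- function(own, others) {
    if (length(others) == 0) return(merge_intervals(own))
    pooled <- consensus_atlas(others)
    merge_intervals(intersect_atlas(own, pooled, mode = "unique_a"))
  }
  tissue_unique <- lapply(names(consistent), function(t) {
    uniq_against(consistent[[t]], consistent[names(consistent) != t])
  })
  names(tissue_unique) <- names(consistent)

  layers <- unique(unname(lineage_map[names(consistent)]))
  lineage_sets <- lapply(layers, function(l) {
    consensus_atlas(consistent[names(consistent)[lineage_map[names(consistent)] == l]])
  })
  names(lineage_sets) <- layers
  lineage_unique <- lapply(layers, function(l) {
    uniq_against(lineage_sets[[l]], lineage_sets[names(lineage_sets) != l])
  })
  names(lineage_unique) <- layers

  structure(list(tissue = consistent, tissue_unique = tissue_unique,
                 lineage_unique = lineage_unique),
            class = "tissue_region_sets")
}

#' Enrichment of enhancer classes in tissue/lineage region sets
#'
#' Observed = number of class peaks overlapping (any overlap, >= 1 bp) the
#' region set; expected = `|class| * K / N` where `K` is the number of
#' universe peaks overlapping the set and `N` the universe size. Score and
#' chi-squared as in [class_geneset_enrichment()]. Empty region sets yield
#' a missing (all-NA) result row.
#'
#' @param class_atlases Named list of class [peak_atlas()] objects, each a
#'   subset of `universe`.
#' @param region_sets Named list of region [peak_atlas()] objects (e.g. the
#'   `tissue_unique` or `lineage_unique` element of [build_tissue_sets()]).
#' @param universe The consensus [peak_atlas()].
#' @return An `enrichment_result` tibble, one row per (class x set).
#' @export
class_region_enrichment <- function(class_atlases, region_sets, universe) {
  res <- dplyr::bind_rows(lapply(names(region_sets), function(sn) {
    set <- region_sets[[sn]]
    hit_universe <- intersect_atlas(universe, set, mode = "report_a")
    k <- nrow(hit_universe)
    dplyr::bind_rows(lapply(names(class_atlases), function(cn) {
      cl <- class_atlases[[cn]]
      observed <- sum(cl$name %in% hit_universe$name)
      enrichment_row(cn, sn, observed = observed, n_class = nrow(cl),
                     in_set_total = k, total = nrow(universe))
    }))
  }))
  class(res) <- c("enrichment_result", class(res))
  res
}
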