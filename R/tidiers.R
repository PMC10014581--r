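#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enhancer classification
#'
#' @param x An `enhancer_classification`.
#' @param ... Unused.
#' @return A tibble with one row per peak: `peak`, `cluster`,
#'   `membership_score`, `group` (NA before [assign_groups()]).
#' @export
tidy.enhancer_classification <- function(x, ...) {
  tibble::tibble(
    peak = rownames(x$membership),
    cluster = x$hard_cluster,
    membership_score = unname(x$membership_score),
    group = if (is.null(x$group)) NA_character_ else unname(x$group)
  )
}

#' One-row summary of an enhancer classification
#'
#' @param x An `enhancer_classification`.
#' @param ... Unused.
#' @return A tibble with `n_peaks`, `k`, `fuzzifier_m`, `n_groups`,
#'   `iterations`, `converged`, `objective`.
#' @export
glance.enhancer_classification <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x$membership),
    k = x$k,
    fuzzifier_m = x$fuzzifier_m,
    n_groups = if (is.null(x$group)) NA_integer_ else
      length(unique(x$group)),
    iterations = length(x$objective),
    converged = x$converged,
    objective = x$objective[length(x$objective)]
  )
}

#' Tidy a cluster alignment
#'
#' @param x A `cat_alignment`.
#' @param ... Unused.
#' @return The pairs tibble (`cluster_a`, `cluster_b`, `rank`,
#'   `mean_distance`, `distance_sd`, `profile_cor`, `p_gap`,
#'   `is_significant`, `mutual_nearest`).
#' @export
tidy.cat_alignment <- function(x, ...) x$pairs

#' One-row summary of a cluster alignment
#'
#' @param x A `cat_alignment`.
#' @param ... Unused.
#' @return A tibble with the criterion metadata and pair counts.
#' @export
glance.cat_alignment <- function(x, ...) {
  tibble::tibble(
    n_clusters_a = dplyr::n_distinct(x$pairs$cluster_a),
    n_significant = sum(x$pairs$is_significant),
    alpha = x$criterion$alpha,
    effect_margin = x$criterion$effect_margin,
    rank_depth = x$criterion$rank_depth,
    min_cor = x$criterion$min_cor,
    n_boot = x$criterion$n_boot,
    panel_size = x$criterion$panel_size
  )
}

#' Plot cluster centroids against stage order
#'
#' One line per c-means centroid, faceted by named group when groups have
#' been assigned.
#'
#' @param object An `enhancer_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enhancer_classification <- function(object, ...) {
  cent <- tibble::as_tibble(object$centers, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "stage", values_to = "z")
  cent$stage <- factor(cent$stage, levels = object$stages)
  if (!is.null(object$cluster_groups)) {
    cent$group <- object$cluster_groups$group[
      match(cent$cluster, object$cluster_groups$cluster)]
  }
  p <- ggplot2::ggplot(cent, ggplot2::aes(x = .data$stage, y = .data$z,
                                          group = .data$cluster,
                                          colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "accessibility (z-score)",
                  colour = "cluster")
  if (!is.null(object$cluster_groups)) {
    p <- p + ggplot2::facet_wrap(~group)
  }
  p
}

#' Bar plot of enrichment scores
#'
#' @param object An `enrichment_result` tibble.
#' @param ... Unused.
#' @return A ggplot object (censored and missing rows dropped).
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- object[is.finite(object$score), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class_name, y = .data$score,
                                  fill = .data$class_name)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~set_name) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "log2(observed / expected)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot significant cluster alignments as an edge diagram
#'
#' @param object A `cat_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cat_alignment <- function(object, ...) {
  sig <- object$pairs[object$pairs$is_significant, , drop = FALSE]
  a_lev <- sort(unique(object$pairs$cluster_a))
  b_lev <- sort(unique(object$pairs$cluster_b))
  sig$ya <- match(sig$cluster_a, a_lev)
  sig$yb <- match(sig$cluster_b, b_lev)
  nodes <- dplyr::bind_rows(
    tibble::tibble(x = 0, y = seq_along(a_lev), label = a_lev),
    tibble::tibble(x = 1, y = seq_along(b_lev), label = b_lev)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = sig,
                          ggplot2::aes(x = 0, xend = 1, y = .data$ya,
                                       yend = .data$yb,
                                       linewidth = -log10(.data$p_gap + 1e-300)),
                          colour = "grey40", show.legend = FALSE) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$label)) +
    ggplot2::theme_void()
}
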