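#' Shift read 5' ends to Tn5 insertion sites
#'
#' ATAC-seq transposition leaves a 9 bp duplication, so read starts are
#' offset to the insertion centre: +4 bp on the Watson (`+`) strand and
#' -5 bp on the Crick (`-`) strand. Positions that would become negative
#' are clipped to 0 and counted.
#'
#' @param events A data frame with columns `chrom`, `position` (0-based bp
#'   of the raw read 5' end) and `strand` (`"+"` or `"-"`).
#' @return A tibble of insertion events (`chrom`, `position`), with the
#'   number of clipped positions in attribute `n_clipped` (a warning is
#'   emitted when it is non-zero).
#' @export
tn5_shift <- function(events) {
  stopifnot(all(c("chrom", "position", "strand") %in% names(events)))
  if (any(events$position < 0)) stop("raw positions must be >= 0", call. = FALSE)
  bad <- !events$strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand symbol: ", events$strand[which(bad)[1]], call. = FALSE)
  }
  pos <- events$position + ifelse(events$strand == "+", 4, -5)
  n_clip <- sum(pos < 0)
  if (n_clip > 0) {
    warning(sprintf("%d shifted position(s) clipped to 0", n_clip),
            call. = FALSE)
  }
  out <- tibble::tibble(chrom = as.character(events$chrom),
                        position = pmax(pos, 0))
  attr(out, "n_clipped") <- n_clip
  out
}

#' Read insertion events from TSV
#'
#' Three tab-separated columns, no header: chrom, 0-based position, strand.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return A tibble with columns `chrom`, `position`, `strand`.
#' @export
read_insertions <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "position", "strand"),
                  col_types = "cdc", progress = FALSE)
}

#' Per-base coverage of insertion-centred fragments
#'
#' Each insertion contributes a fragment of `width` bp centred on the
#' insertion site (positions `[position - width/2, position + width/2)`,
#' clipped at 0). The result is run-length encoded coverage, sorted and
#' non-overlapping, with zero-depth runs omitted — ready to write as
#' bedGraph.
#'
#' @param events A tibble of insertion events (`chrom`, `position`).
#' @param width Even fragment width in bp (default 30).
#' @return A tibble with columns `chrom`, `start`, `end`, `depth`.
#' @export
insertion_coverage <- function(events, width = 30) {
  if (width <= 0 || width %% 2 != 0) {
    stop("width must be even and > 0", call. = FALSE)
  }
  half <- width / 2
  starts <- pmax(events$position - half, 0)
  ends <- events$position + half
  out <- lapply(split(seq_len(nrow(events)), events$chrom), function(idx) {
    # breakpoint sweep: +1 at each fragment start, -1 at each end
    bp <- sort(unique(c(starts[idx], ends[idx])))
    delta <- rep(0, length(bp))
    tab_s <- table(match(starts[idx], bp))
    tab_e <- table(match(ends[idx], bp))
    delta[as.integer(names(tab_s))] <- delta[as.integer(names(tab_s))] + as.numeric(tab_s)
    delta[as.integer(names(tab_e))] <- delta[as.integer(names(tab_e))] - as.numeric(tab_e)
    depth <- cumsum(delta)
    runs <- tibble::tibble(
      chrom = events$chrom[idx[1]],
      start = bp[-length(bp)],
      end = bp[-1],
      depth = depth[-length(depth)]
    )
    # coalesce adjacent runs of equal depth into canonical run-length form
    runs$.grp <- cumsum(c(TRUE, runs$depth[-1] != runs$depth[-nrow(runs)]))
    out <- dplyr::summarise(runs, chrom = .data$chrom[1],
                            start = min(.data$start), end = max(.data$end),
                            depth = .data$depth[1], .by = ".grp")
    out[, c("chrom", "start", "end", "depth")]
  })
  dplyr::bind_rows(out) |>
    dplyr::filter(.data$depth > 0) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Write run-length coverage as bedGraph
#'
#' @param coverage A tibble from [insertion_coverage()].
#' @param path Output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  out <- coverage[, c("chrom", "start", "end", "depth")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
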