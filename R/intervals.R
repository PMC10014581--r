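# Interval algebra on peak atlases (BED semantics: 0-based, half-open).
#
# Fraction tests are done in scaled-integer arithmetic (parts-per-million)
# so that boundary cases like a 50 bp overlap of a 100 bp interval at
# min_frac = 0.5 never depend on floating-point ties.

FRAC_DEN <- 1e6

frac_ok <- function(overlap_bp, len_bp, min_frac) {
  overlap_bp * FRAC_DEN >= round(min_frac * FRAC_DEN) * len_bp
}

# All overlapping (i, j) index pairs between two interval tables, with the
# overlap width in bp. Blocked outer comparison per chromosome: exact, and
# fast enough for atlas sizes in the tens of thousands.
overlap_pairs <- function(a, b, block = 512L) {
  out_i <- list(); out_j <- list(); k <- 0L
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    jb <- which(b$chrom == ch)
    bs <- b$start[jb]; be <- b$end[jb]
    for (off in seq(1L, length(ia), by = block)) {
      blk <- ia[off:min(off + block - 1L, length(ia))]
      hit <- outer(a$start[blk], be, "<") & outer(a$end[blk], bs, ">")
      w <- which(hit, arr.ind = TRUE)
      if (nrow(w)) {
        k <- k + 1L
        out_i[[k]] <- blk[w[, 1L]]
        out_j[[k]] <- jb[w[, 2L]]
      }
    }
  }
  i <- if (k) unlist(out_i) else integer()
  j <- if (k) unlist(out_j) else integer()
  tibble::tibble(
    i = i, j = j,
    overlap = pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j])
  )
}

#' Merge overlapping or book-ended intervals
#'
#' Collapses an atlas so that the result is sorted and pairwise
#' non-overlapping while covering exactly the same bases; intervals whose
#' gap is at most `max_gap` bp are also joined. Fresh sequential names are
#' assigned.
#'
#' @param atlas A [peak_atlas()].
#' @param max_gap Maximum gap (bp) across which adjacent intervals are still
#'   merged; 0 merges only overlapping or touching intervals.
#' @return A merged [peak_atlas()].
#' @export
merge_intervals <- function(atlas, max_gap = 0) {
  if (nrow(atlas) == 0) return(as_peak_atlas(atlas_tbl(atlas)))
  x <- atlas_tbl(atlas)
  new_chrom <- x$chrom != dplyr::lag(x$chrom, default = "")
  prev_max_end <- dplyr::lag(cummax_by(x$end, new_chrom), default = -Inf)
  grp <- cumsum(new_chrom | x$start > prev_max_end + max_gap)
  out <- x |>
    dplyr::mutate(.grp = grp) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                     end = max(.data$end), .by = ".grp")
  peak_atlas(out$chrom, out$start, out$end,
             genome_label = attr(atlas, "genome_label"))
}

# cumulative max of x restarting wherever reset is TRUE
cummax_by <- function(x, reset) {
  grp <- cumsum(reset)
  unlist(lapply(split(x, grp), cummax), use.names = FALSE)
}

#' Intersect two atlases with bedtools-like semantics
#'
#' `mode = "report_a"` returns each interval of `a` at most once when at
#' least one interval of `b` overlaps it by at least `min_frac` of the
#' `a`-interval's length (and, when `reciprocal`, also at least `min_frac`
#' of the `b`-interval's length). `min_frac = NULL` means any overlap of
#' at least 1 bp. `mode = "unique_a"` returns the `a`-intervals with no
#' overlapping `b`-interval of any extent (the `-v` semantics).
#'
#' @param a,b [peak_atlas()] objects.
#' @param min_frac Minimum overlap as a fraction of the `a`-interval length,
#'   in (0, 1], or `NULL` for any overlap. Ignored in `unique_a` mode.
#' @param reciprocal Require the fraction on both intervals.
#' @param mode `"report_a"` or `"unique_a"`.
#' @return A [peak_atlas()] subset of `a` (names preserved).
#' @export
intersect_atlas <- function(a, b, min_frac = NULL, reciprocal = FALSE,
                            mode = c("report_a", "unique_a")) {
  mode <- match.arg(mode)
  if (!is.null(min_frac) && (min_frac <= 0 || min_frac > 1)) {
    stop("min_frac must be in (0, 1]", call. = FALSE)
  }
  prs <- overlap_pairs(a, b)
  if (mode == "unique_a") {
    keep <- setdiff(seq_len(nrow(a)), unique(prs$i))
  } else {
    if (!is.null(min_frac)) {
      ok <- frac_ok(prs$overlap, a$end[prs$i] - a$start[prs$i], min_frac)
      if (reciprocal) {
        ok <- ok & frac_ok(prs$overlap, b$end[prs$j] - b$start[prs$j], min_frac)
      }
      prs <- prs[ok, , drop = FALSE]
    }
    keep <- sort(unique(prs$i))
  }
  out <- atlas_tbl(a)[keep, , drop = FALSE]
  as_peak_atlas(out, genome_label = attr(a, "genome_label"))
}

#' Replicate-reproducible peaks
#'
#' Keeps the peaks of `rep1` that pass a reciprocal-fraction overlap test
#' against `rep2` (default 50% reciprocal, the classic
#' `intersect -f 0.50 -r -u` filter). This is a deliberate simplification of
#' the full irreproducible-discovery-rate procedure.
#'
#' @param rep1,rep2 Replicate [peak_atlas()] objects.
#' @param min_frac Minimum reciprocal overlap fraction.
#' @param reciprocal Require the fraction of both peaks.
#' @return The reproducible subset of `rep1`.
#' @export
reproducible_peaks <- function(rep1, rep2, min_frac = 0.5, reciprocal = TRUE) {
  intersect_atlas(rep1, rep2, min_frac = min_frac, reciprocal = reciprocal,
                  mode = "report_a")
}

#' Build a consensus atlas across stages
#'
#' Concatenates per-stage reproducible peak sets, sorts, merges overlapping
#' regions and assigns fresh sequential peak names — the universe for all
#' downstream classification.
#'
#' @param atlases A list of [peak_atlas()] objects (one per stage).
#' @param max_gap Passed to [merge_intervals()].
#' @return A merged, renamed [peak_atlas()].
#' @export
consensus_atlas <- function(atlases, max_gap = 0) {
  stopifnot(length(atlases) >= 1)
  pooled <- dplyr::bind_rows(lapply(atlases, function(x) {
    atlas_tbl(x)[, c("chrom", "start", "end")]
  }))
  merge_intervals(
    peak_atlas(pooled$chrom, pooled$start, pooled$end,
               genome_label = attr(atlases[[1]], "genome_label")),
    max_gap = max_gap
  )
}
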