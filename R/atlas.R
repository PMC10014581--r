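#' Construct a peak atlas
#'
#' A peak atlas is the ordered universe of genomic intervals (BED convention:
#' 0-based, half-open) that all downstream classification operates on. Rows
#' are sorted by (chrom, start, end) and carry unique stable names.
#'
#' @param chrom Character vector of chromosome names (exact string identity;
#'   no alias table, so `"chr1"` and `"1"` are different sequences).
#' @param start,end Integer-like 0-based half-open coordinates; `end > start`.
#' @param name Optional unique interval identifiers. When `NULL`, sequential
#'   `peak%06d` names are assigned *after* sorting.
#' @param score Optional numeric signal column.
#' @param genome_label Informational assembly tag stored as an attribute.
#' @return A tibble of class `peak_atlas` with columns `chrom`, `start`,
#'   `end`, `name` and (if supplied) `score`.
#' @export
peak_atlas <- function(chrom, start, end, name = NULL, score = NULL,
                       genome_label = NA_character_) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n) {
    stop("chrom, start and end must have equal length", call. = FALSE)
  }
  if (n > 0 && any(start < 0)) stop("interval start must be >= 0", call. = FALSE)
  if (n > 0 && any(end <= start)) {
    bad <- which(end <= start)[1]
    stop(sprintf("interval %d has end <= start (%s:%s-%s)",
                 bad, chrom[bad], start[bad], end[bad]), call. = FALSE)
  }
  x <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (!is.null(score)) x$score <- as.numeric(score)
  ord <- order(x$chrom, x$start, x$end, method = "radix")
  x <- x[ord, , drop = FALSE]
  if (is.null(name)) {
    x$name <- sprintf("peak%06d", seq_len(n))
  } else {
    name <- as.character(name)
    if (anyDuplicated(name)) stop("interval names must be unique", call. = FALSE)
    x$name <- name[ord]
  }
  x <- dplyr::relocate(x, "chrom", "start", "end", "name")
  attr(x, "genome_label") <- genome_label
  class(x) <- c("peak_atlas", class(x))
  x
}

#' @export
print.peak_atlas <- function(x, ...) {
  cat(sprintf("# A peak_atlas: %d intervals on %d sequence(s)\n",
              nrow(x), dplyr::n_distinct(x$chrom)))
  NextMethod()
}

# Strip the class so dplyr verbs inside the package do not have to fight
# attribute propagation; re-wrap with as_peak_atlas() on the way out.
atlas_tbl <- function(x) {
  class(x) <- setdiff(class(x), "peak_atlas")
  x
}

as_peak_atlas <- function(x, name = NULL, genome_label = NA_character_) {
  peak_atlas(x$chrom, x$start, x$end,
             name = if (is.null(name)) x$name else name,
             score = x[["score"]], genome_label = genome_label)
}

#' Read a BED file into a peak atlas
#'
#' Accepts BED3/BED4/BED6 (tab-separated, no header); gzip is handled
#' transparently. Intervals are sorted and, when no name column is present,
#' given sequential `peak%06d` names in sorted order.
#'
#' @param path Path to a BED file (optionally `.gz`).
#' @param genome_label Informational assembly tag.
#' @return A [peak_atlas()].
#' @export
read_bed <- function(path, genome_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(peak_atlas(character(), numeric(), numeric(),
                      genome_label = genome_label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 which(nf < 3)[1]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates",
                 which(is.na(start) | is.na(end))[1]), call. = FALSE)
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: end <= start", bad[1]), call. = FALSE)
  }
  name <- if (all(nf >= 4)) vapply(fields, `[[`, "", 4L) else NULL
  score <- if (all(nf >= 5)) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  } else NULL
  peak_atlas(chrom, start, end, name = name, score = score,
             genome_label = genome_label)
}

#' Write a peak atlas as BED
#'
#' @param atlas A [peak_atlas()].
#' @param path Output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_bed <- function(atlas, path) {
  cols <- c("chrom", "start", "end", "name")
  if ("score" %in% names(atlas)) cols <- c(cols, "score")
  out <- atlas_tbl(atlas)[, cols]
  # readr::write_tsv writes integers in full; coordinates may exceed int range
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
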