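# Brute-force reference implementations ("oracles") used to validate the
# optimized interval, coverage and linking code on random instances. These
# are deliberately written in the most literal way possible: explicit loops
# over all pairs or all bases, no shared helpers with the package.

random_atlas <- function(n, chroms = c("chr1", "chr2"), span = 5000,
                         max_len = 80) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  peak_atlas(chrom, start, start + len)
}

# fraction passed as c(numerator, denominator) so the oracle decides the
# boundary in exact integer arithmetic, independently of the package
oracle_intersect_names <- function(a, b, frac = NULL, reciprocal = FALSE,
                                   mode = "report_a") {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    any_hit <- FALSE
    frac_hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov <= 0) next
      any_hit <- TRUE
      ok <- TRUE
      if (!is.null(frac)) {
        ok <- ov * frac[2] >= frac[1] * (a$end[i] - a$start[i])
        if (reciprocal) {
          ok <- ok && ov * frac[2] >= frac[1] * (b$end[j] - b$start[j])
        }
      }
      if (ok) frac_hit <- TRUE
    }
    keep[i] <- if (mode == "unique_a") !any_hit else frac_hit
  }
  a$name[keep]
}

oracle_merge <- function(a, max_gap = 0) {
  x <- data.frame(chrom = a$chrom, start = a$start, end = a$end)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rows <- list()
  cur <- NULL
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (is.null(cur) || r$chrom != cur$chrom || r$start > cur$end + max_gap) {
      rows[[length(rows) + 1]] <- cur
      cur <- r
    } else {
      cur$end <- max(cur$end, r$end)
    }
  }
  rows[[length(rows) + 1]] <- cur
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end")]
  rownames(out) <- NULL
  out
}

oracle_coverage <- function(events, width) {
  half <- width / 2
  out <- list()
  for (ch in sort(unique(events$chrom))) {
    pos <- events$position[events$chrom == ch]
    s <- pmax(pos - half, 0)
    e <- pos + half
    depth <- numeric(max(e))
    for (k in seq_along(s)) {
      if (e[k] > s[k]) {
        idx <- (s[k] + 1):e[k] # base b occupies vector slot b + 1
        depth[idx] <- depth[idx] + 1
      }
    }
    r <- rle(depth)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            end = ends[keep], depth = r$values[keep])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

oracle_nearest <- function(peaks, genes, window) {
  mid <- floor((peaks$start + peaks$end) / 2)
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- abs(g$tss - mid[i])
    dm <- min(d)
    if (dm > window) next
    rows[[length(rows) + 1]] <- data.frame(
      peak = peaks$name[i],
      gene_id = sort(g$gene_id[d == dm])[1],
      distance = dm
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# compare atlases by value, ignoring class/attributes
atlas_strip <- function(x) {
  out <- tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                        name = x$name)
  if ("score" %in% names(x)) out$score <- x$score
  out
}

# shared small accessibility fixture builder
toy_matrix <- function(counts, stages, lib = NULL, width = 500) {
  n <- nrow(counts)
  atlas <- peak_atlas(rep("chr1", n), (seq_len(n) - 1) * 10000,
                      (seq_len(n) - 1) * 10000 + width)
  rownames(counts) <- atlas$name
  samples <- tibble::tibble(
    sample = paste0("s", seq_along(stages)),
    stage = stages,
    replicate = stats::ave(seq_along(stages), stages, FUN = seq_along),
    library_size = if (is.null(lib)) rep(2e7, length(stages)) else lib
  )
  accessibility_matrix(counts, samples, atlas, stage_order = unique(stages))
}
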