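test_that("peak_atlas validates, sorts and names intervals", {
  a <- peak_atlas(c("chr2", "chr1"), c(10, 5), c(20, 9))
  expect_s3_class(a, "peak_atlas")
  expect_equal(a$chrom, c("chr1", "chr2"))
  expect_equal(a$name, c("peak000001", "peak000002"))
  expect_error(peak_atlas("chr1", 10, 10), "end <= start")
  expect_error(peak_atlas("chr1", -1, 10), ">= 0")
  expect_error(peak_atlas(c("chr1", "chr1"), c(0, 5), c(4, 9),
                          name = c("x", "x")),
               "unique")
})

test_that("read_bed/write_bed round-trip and reject malformed input", {
  a <- peak_atlas(c("chr1", "chr1", "chr2"), c(0, 100, 5), c(50, 200, 25),
                  score = c(1.5, 2, 3))
  path <- tempfile(fileext = ".bed")
  write_bed(a, path)
  b <- read_bed(path)
  expect_equal(atlas_strip(b), atlas_strip(a))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t5"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines(c("chr1\t0\t10", "chr1\tx\t20"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines(c("chr1\t20\t10"), bad)
  expect_error(read_bed(bad), "end <= start")
})

test_that("merge_intervals joins overlapping, touching and gapped intervals", {
  a <- peak_atlas(rep("chr1", 4), c(0, 5, 10, 30), c(6, 8, 20, 40))
  m <- merge_intervals(a)
  # (0,6)+(5,8) overlap; (10,20) is 2 bp away and stays separate at gap 0
  expect_equal(m$start, c(0, 10, 30))
  expect_equal(m$end, c(8, 20, 40))
  m5 <- merge_intervals(a, max_gap = 10)
  expect_equal(m5$start, 0)
  expect_equal(m5$end, 40)
  # book-ended intervals (gap 0) merge
  b <- peak_atlas(rep("chr1", 2), c(0, 10), c(10, 20))
  expect_equal(nrow(merge_intervals(b)), 1)
})

test_that("intersect_atlas boundary fractions are exact", {
  # 50 bp overlap of a 100 bp interval at min_frac = 0.5: passes exactly
  a <- peak_atlas("chr1", 0, 100)
  b50 <- peak_atlas("chr1", 50, 200)
  b49 <- peak_atlas("chr1", 51, 200)
  expect_equal(nrow(intersect_atlas(a, b50, min_frac = 0.5)), 1)
  expect_equal(nrow(intersect_atlas(a, b49, min_frac = 0.5)), 0)
  # reciprocal: overlap must also cover half of the 300 bp b-interval
  b_big <- peak_atlas("chr1", 50, 350)
  expect_equal(nrow(intersect_atlas(a, b_big, min_frac = 0.5)), 1)
  expect_equal(nrow(intersect_atlas(a, b_big, min_frac = 0.5,
                                    reciprocal = TRUE)), 0)
  # unique_a drops any-overlap hits regardless of fraction
  expect_equal(nrow(intersect_atlas(a, b49, mode = "unique_a")), 0)
  c_far <- peak_atlas("chr1", 500, 600)
  expect_equal(intersect_atlas(a, c_far, mode = "unique_a")$name, a$name)
})

test_that("each a-interval is reported at most once", {
  a <- peak_atlas("chr1", 0, 100)
  b <- peak_atlas(rep("chr1", 3), c(0, 20, 40), c(60, 80, 100))
  expect_equal(nrow(intersect_atlas(a, b)), 1)
})

test_that("interval operations match brute-force oracles on random instances", {
  set.seed(401)
  fracs <- list(c(1, 2), c(1, 4), c(3, 4), c(1, 1))
  for (rep in 1:25) {
    a <- random_atlas(sample(20:120, 1))
    b <- random_atlas(sample(20:120, 1))
    fr <- fracs[[sample(4, 1)]]
    mf <- fr[1] / fr[2]
    expect_equal(intersect_atlas(a, b, min_frac = mf)$name,
                 oracle_intersect_names(a, b, frac = fr))
    expect_equal(intersect_atlas(a, b, min_frac = mf, reciprocal = TRUE)$name,
                 oracle_intersect_names(a, b, frac = fr, reciprocal = TRUE))
    expect_equal(intersect_atlas(a, b, mode = "unique_a")$name,
                 oracle_intersect_names(a, b, mode = "unique_a"))
    gap <- sample(c(0, 3, 10), 1)
    m <- merge_intervals(a, max_gap = gap)
    expect_equal(as.data.frame(atlas_strip(m)[, 1:3]),
                 oracle_merge(a, max_gap = gap))
  }
})

test_that("consensus_atlas yields a sorted non-overlapping universe", {
  set.seed(402)
  atlases <- replicate(3, random_atlas(60), simplify = FALSE)
  u <- consensus_atlas(atlases)
  same_chrom <- u$chrom[-1] == u$chrom[-nrow(u)]
  expect_true(all(u$start[-1][same_chrom] > u$end[-nrow(u)][same_chrom]))
  # idempotent: merging the consensus changes nothing
  expect_equal(atlas_strip(merge_intervals(u))[, c("chrom", "start", "end")],
               atlas_strip(u)[, c("chrom", "start", "end")])
})

test_that("reproducible_peaks applies the 50% reciprocal filter", {
  rep1 <- peak_atlas(rep("chr1", 2), c(0, 1000), c(100, 1100))
  # first peak matched well; second shifted so reciprocal fails
  rep2 <- peak_atlas(rep("chr1", 2), c(10, 1090), c(110, 1500))
  out <- reproducible_peaks(rep1, rep2)
  expect_equal(out$start, 0)
})
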