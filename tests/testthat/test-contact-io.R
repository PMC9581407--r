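test_that("triplet text parsing follows the upper-triangle convention", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1 4", "1 2 2", "0 2 1"), f)
  cm <- read_contact_map(f, resolution = 10000)
  expect_equal(nrow(cm$entries), 3)
  expect_equal(cm$n_bins, 3)
  expect_equal(cm$entries$value[cm$entries$i == 0 & cm$entries$j == 1], 4)

  # lower-triangle input is mirrored
  writeLines("5 3 2.0", f)
  cm <- read_contact_map(f, resolution = 10000)
  expect_equal(cm$entries$i, 3L)
  expect_equal(cm$entries$j, 5L)

  # duplicate mirrored entries are summed
  writeLines(c("1 2 3", "2 1 2"), f)
  cm <- read_contact_map(f, resolution = 10000)
  expect_equal(nrow(cm$entries), 1)
  expect_equal(cm$entries$value, 5)

  writeLines("0 1 -2", f)
  expect_error(read_contact_map(f), "negative")
})

test_that("multi-chromosome triplet files select by chromosome", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chrA 0 1 4", "chrB 0 2 7"), f)
  cm <- read_contact_map(f, chrom = "chrB", n_bins = 5)
  expect_equal(cm$entries$value, 7)
  expect_equal(cm$chrom, "chrB")
  expect_error(read_contact_map(f, chrom = "chrZ"), "chrZ")
})

test_that("cool container round-trips the simulated study", {
  p <- small_sim_params(seed = 9)
  sim <- simulate_contact_map(p, 1)
  f <- withr::local_tempfile(fileext = ".cool")
  write_cool(list(sim$map), f)
  back <- read_contact_map(f, chrom = sim$map$chrom, resolution = p$resolution)
  expect_equal(back$n_bins, sim$map$n_bins)
  expect_equal(as.data.frame(back$entries), as.data.frame(sim$map$entries))
  expect_error(read_contact_map(f, chrom = sim$map$chrom, resolution = 5000),
               "resolution mismatch")
  expect_error(read_contact_map(f, chrom = "chrNope"), "not present")
})

test_that("cool balancing weights are applied and undefined weights dropped", {
  cm <- contact_map("chr1", 10000, 4,
                    data.frame(i = c(0, 1, 2), j = c(1, 2, 3), value = c(10, 20, 30)))
  f <- withr::local_tempfile(fileext = ".cool")
  write_cool(list(cm), f, weights = list(c(0.5, 2, 1, NaN)))
  bal <- read_contact_map(f, chrom = "chr1", use_balanced = TRUE)
  expect_true(bal$balanced)
  expect_equal(nrow(bal$entries), 2)  # pixel touching the NaN-weight bin dropped
  expect_equal(bal$entries$value[bal$entries$i == 0], 10 * 0.5 * 2)
  expect_equal(bal$entries$value[bal$entries$i == 1], 20 * 2 * 1)
})

test_that("bedGraph signal is averaged per bin with uncovered bases as zero", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  # one full 10-kb bin at 5, then half a bin at 8
  writeLines(c("chrT\t0\t10000\t5", "chrT\t10000\t15000\t8"), f)
  tr <- read_accessibility(f, "chrT", resolution = 10000, n_bins = 3)
  expect_equal(tr$values, c(5, 4, 0))

  writeLines("chrT\t0\t1000\t-3", f)
  expect_error(read_accessibility(f, "chrT", n_bins = 2), "negative")

  writeLines("chrT\t0\t25000\t2", f)
  expect_warning(read_accessibility(f, "chrT", n_bins = 2), "truncated")
})

test_that("binned accessibility equals a per-base oracle", {
  set.seed(42)
  n_bins <- 12; res <- 1000
  start <- sort(sample(0:(n_bins * res - 200), 25))
  width <- sample(50:3000, 25, replace = TRUE)
  end <- pmin(start + width, n_bins * res)
  score <- round(runif(25, 0, 10), 3)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(sprintf("chrT\t%d\t%d\t%g", start, end, score), f)
  tr <- read_accessibility(f, "chrT", resolution = res, n_bins = n_bins)

  base <- numeric(n_bins * res)
  for (k in seq_along(start)) {
    idx <- (start[k] + 1):end[k]
    base[idx] <- base[idx] + score[k]
  }
  oracle <- colMeans(matrix(base, nrow = res))
  expect_equal(tr$values, oracle, tolerance = 1e-9)
})

test_that("bigWig input gives the same binned values as bedGraph", {
  gr <- GenomicRanges::GRanges("chrT",
                               IRanges::IRanges(c(1, 5001, 12001),
                                                end = c(4000, 11000, 20000)),
                               score = c(2.5, 1, 4))
  GenomeInfoDb::seqlengths(gr) <- c(chrT = 30000)
  fbw <- withr::local_tempfile(fileext = ".bw")
  rtracklayer::export.bw(gr, fbw)
  fbg <- withr::local_tempfile(fileext = ".bedGraph")
  df <- as.data.frame(gr)
  writeLines(sprintf("chrT\t%d\t%d\t%g", df$start - 1, df$end, df$score), fbg)
  t1 <- read_accessibility(fbw, "chrT", resolution = 10000, n_bins = 3)
  t2 <- read_accessibility(fbg, "chrT", resolution = 10000, n_bins = 3)
  expect_equal(t1$values, t2$values, tolerance = 1e-9)
})

test_that("BEDPE anchors are binned by midpoint and ordered", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t100000\t110000\tchr1\t500000\t510000",
               "chr1\t500000\t510000\tchr1\t100000\t110000",   # reversed order
               "chr1\t100000\t110000\tchr2\t500000\t510000",   # inter-chromosomal
               "chr1\t200000\t210000\tchr1\t201000\t209000"),  # same bin
             f)
  suppressMessages(ints <- read_interactions(f, resolution = 10000))
  expect_equal(nrow(ints), 2)
  expect_equal(ints$bin1, c(10L, 10L))
  expect_equal(ints$bin2, c(50L, 50L))
  expect_equal(attr(ints, "n_interchrom"), 1L)
  expect_equal(attr(ints, "n_samebin"), 1L)

  # a midpoint exactly on a bin boundary goes to the left bin
  writeLines("chr1\t95000\t105000\tchr1\t300000\t310000", f)
  ints <- read_interactions(f, resolution = 10000)
  expect_equal(ints$bin1, 9L)

  writeLines("chr1\t100\tnot_a_number\tchr1\t1\t2", f)
  expect_error(read_interactions(f), "line 1")
  writeLines(c("chr1\t1\t2\tchr1\t3\t4\t0.5\textra", "chr1\t1\t2"), f)
  expect_error(read_interactions(f), "line 2")
})

test_that("loop BEDPE output round-trips and carries probabilities", {
  loops <- tibble::tibble(chrom = c("chr2", "chr1"), bin1 = c(7L, 10L),
                          bin2 = c(30L, 50L), probability = c(0.75, 0.9))
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_loops(loops, 10000, f)
  lines <- readLines(f)
  expect_equal(length(lines), 2)
  expect_equal(lines[1], "chr1\t100000\t110000\tchr1\t500000\t510000\t0.9")
  back <- read_interactions(f, resolution = 10000)
  expect_equal(back$bin1, c(10L, 7L))
  expect_equal(back$bin2, c(50L, 30L))
  expect_equal(back$probability, c(0.9, 0.75))

  write_loops(loops[0, ], 10000, f)
  expect_equal(length(readLines(f)), 0)
})
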