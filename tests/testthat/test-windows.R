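test_that("contact windows are dense, mirrored and bounds-checked", {
  cm <- contact_map("chrT", 10000, 120,
                    data.frame(i = 50, j = 80, value = 7))
  m <- extract_window(cm, 50, 80, w = 23)
  expect_equal(dim(m), c(23, 23))
  expect_equal(m[12, 12], 7)
  expect_equal(sum(m), 7)

  expect_error(extract_window(cm, 3, 8, w = 23), "bounds")

  # a window centred close to the diagonal picks up mirrored entries
  cm2 <- contact_map("chrT", 10000, 60, data.frame(i = 20, j = 24, value = 9))
  m2 <- extract_window(cm2, 22, 26, w = 11)
  expect_equal(m2[6 + (24 - 26), 6 + (20 - 22)], 9)  # (j, i) orientation
})

test_that("windows at (i, j) and (j, i) are transposes under symmetry", {
  cm <- rand_map(n_bins = 100, n_entries = 300, seed = 8)
  for (ctr in list(c(30, 40), c(48, 52), c(60, 88))) {
    wij <- extract_window(cm, ctr[1], ctr[2], w = 15)
    wji <- extract_window(cm, ctr[2], ctr[1], w = 15)
    expect_equal(wij, t(wji))
  }
})

test_that("accessibility matrix is the outer product of anchor windows", {
  tr <- accessibility_track("chrT", 10000, rep(1, 60))
  expect_equal(accessibility_matrix(tr, 20, 40, w = 5), matrix(1, 5, 5))

  vals <- seq(0.1, 6, length.out = 60)
  tr2 <- accessibility_track("chrT", 10000, vals)
  a <- accessibility_matrix(tr2, 20, 40, w = 5)
  x <- vals[(18:22) + 1]; y <- vals[(38:42) + 1]
  expect_equal(a, outer(x, y))

  vals[21] <- 0  # row through a zero bin is all zero
  tr3 <- accessibility_track("chrT", 10000, vals)
  a3 <- accessibility_matrix(tr3, 20, 40, w = 5)
  expect_true(all(a3[3, ] == 0))
  expect_error(accessibility_matrix(tr3, 1, 40, w = 5), "bounds")
})

test_that("window normalization is the log/max-scale transform", {
  expect_equal(normalize_window(matrix(0, 23, 23)), matrix(0, 23, 23))

  m <- matrix(0, 23, 23); m[12, 12] <- 9
  expect_equal(normalize_window(m)[12, 12], 0.5)   # log10(10) / (1 + 1)

  set.seed(4)
  r <- matrix(rexp(121, 0.2), 11, 11)
  nr <- normalize_window(r)
  expect_equal(order(r), order(nr))                # rank preserving
  M <- max(log10(1 + r))
  expect_equal(max(nr), M / (1 + M))
  expect_true(all(nr >= 0 & nr < 1))

  # not idempotent away from zero (guards against double application)
  expect_false(isTRUE(all.equal(normalize_window(nr), nr)))
  expect_error(normalize_window(matrix(-1, 2, 2)), "non-negative")
})

test_that("the empirical distance distribution is a normalized histogram", {
  pos <- tibble::tibble(bin1 = c(0L, 10L, 20L), bin2 = c(5L, 15L, 30L))
  pdf <- distance_pdf(pos)
  expect_equal(pdf$distance, c(5L, 10L))
  expect_equal(pdf$prob, c(2 / 3, 1 / 3))

  one <- distance_pdf(tibble::tibble(bin1 = 0L, bin2 = 7L))
  expect_equal(one$prob, 1)
  expect_error(distance_pdf(pos[0, ]), "non-empty")

  # sampling from the pdf reproduces the frequencies
  set.seed(9)
  draws <- sample(pdf$distance, 1e5, replace = TRUE, prob = pdf$prob)
  expect_lt(max(abs(table(draws) / 1e5 - pdf$prob)), 0.01)
})

test_that("negative sampling respects count, halo, eligibility and seeds", {
  cm <- rand_map(n_bins = 200, n_entries = 6000, seed = 12)
  pos <- tibble::tibble(chrom = "chrT",
                        bin1 = c(30L, 60L, 90L, 120L),
                        bin2 = c(45L, 80L, 105L, 140L))
  expect_equal(nrow(sample_negatives(cm, pos[0, ], seed = 1)), 0)

  for (ff in c(0, 0.25, 0.5, 1)) {
    neg <- sample_negatives(cm, pos, far_fraction = ff, w = 23, seed = 5,
                            max_dist = 150)
    expect_equal(nrow(neg), nrow(pos))
    d <- neg$bin2 - neg$bin1
    expect_equal(sum(d > max(pos$bin2 - pos$bin1)), round(ff * nrow(pos)))
    # all negatives are stored non-zero pixels with in-bounds windows
    key <- paste(neg$bin1, neg$bin2)
    expect_true(all(key %in% paste(cm$entries$i, cm$entries$j)))
    expect_false(any(duplicated(key)))
    # Chebyshev-1 halo around positives is excluded
    for (k in seq_len(nrow(pos))) {
      expect_true(all(pmax(abs(neg$bin1 - pos$bin1[k]),
                           abs(neg$bin2 - pos$bin2[k])) > 1))
    }
  }

  n1 <- sample_negatives(cm, pos, seed = 77)
  n2 <- sample_negatives(cm, pos, seed = 77)
  expect_identical(n1, n2)
  expect_false(identical(n1, sample_negatives(cm, pos, seed = 78)))
})

test_that("datasets pair each usable positive with a negative window", {
  p <- small_sim_params(seed = 21)
  sim <- simulate_contact_map(p, 1)
  tr <- simulate_accessibility(p, sim$truth, 1)

  suppressMessages(ds <- build_dataset(sim$map, tr, sim$truth, seed = 3,
                                       max_dist = p$max_sim_dist))
  expect_s3_class(ds, "loop_dataset")
  expect_equal(sum(ds$label == 1), nrow(sim$truth))
  expect_equal(sum(ds$label == 0), sum(ds$label == 1))
  expect_true(all(ds$x >= 0 & ds$x < 1))

  # out-of-bounds positives are dropped and counted
  pos2 <- dplyr::bind_rows(sim$truth,
                           tibble::tibble(chrom = sim$map$chrom,
                                          bin1 = 2L, bin2 = 12L))
  suppressMessages(ds2 <- build_dataset(sim$map, tr, pos2, seed = 3,
                                        max_dist = p$max_sim_dist))
  expect_equal(ds2$manifest$n_dropped, 1)
  expect_equal(sum(ds2$label == 1), nrow(sim$truth))

  suppressMessages(ds3 <- build_dataset(sim$map, tr, sim$truth, seed = 3,
                                        max_dist = p$max_sim_dist))
  expect_identical(ds$x, ds3$x)
})

test_that("window construction matches the reference channel operations", {
  p <- small_sim_params(seed = 22)
  sim <- simulate_contact_map(p, 1)
  tr <- simulate_accessibility(p, sim$truth, 1)
  suppressMessages(ds <- build_dataset(sim$map, tr, sim$truth, seed = 4,
                                       max_dist = p$max_sim_dist))
  for (k in c(1, 3, length(ds$label))) {
    hic_ref <- normalize_window(extract_window(sim$map, ds$i[k], ds$j[k], 23))
    acc_ref <- normalize_window(accessibility_matrix(tr, ds$i[k], ds$j[k], 23))
    expect_equal(ds$x[, , 1, k], hic_ref, tolerance = 1e-12)
    expect_equal(ds$x[, , 2, k], acc_ref, tolerance = 1e-12)
  }
})

test_that("datasets round-trip through the HDF5 container", {
  ds <- tiny_dataset(n = 8)
  f <- withr::local_tempfile(fileext = ".h5")
  write_dataset(ds, f)
  back <- read_dataset(f)
  expect_equal(back$x, ds$x)
  expect_equal(back$label, ds$label)
  expect_equal(back$i, ds$i)

  both <- bind_datasets(list(ds, ds))
  expect_equal(length(both$label), 16)
  expect_equal(both$x[, , , 9:16], ds$x)
})
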