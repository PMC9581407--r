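test_that("the frequency filter keeps strictly above-mean candidates", {
  cands <- tibble::tibble(chrom = "chrT", i = 1:4, j = 11:14,
                          distance = 10L, raw_value = c(1, 2, 3, 4),
                          probability = 0.9)
  kept <- filter_by_frequency(cands)
  expect_equal(kept$raw_value, c(3, 4))

  equal <- dplyr::mutate(cands, raw_value = 2)
  expect_equal(nrow(filter_by_frequency(equal)), 0)
  expect_equal(nrow(filter_by_frequency(cands[0, ])), 0)

  # per-chromosome means, against a brute-force filter
  set.seed(6)
  two <- dplyr::bind_rows(
    dplyr::mutate(rand_candidates(40, seed = 1), chrom = "chrA"),
    dplyr::mutate(rand_candidates(40, seed = 2), chrom = "chrB"))
  got <- filter_by_frequency(two)
  want <- do.call(rbind, lapply(split(two, two$chrom), function(df) {
    df[df$raw_value > mean(df$raw_value), ]
  }))
  expect_setequal(paste(got$chrom, got$i, got$j),
                  paste(want$chrom, want$i, want$j))
})

test_that("the probability filter thresholds inclusively", {
  cands <- rand_candidates(50, seed = 3)
  expect_equal(nrow(filter_by_probability(cands, 0)), nrow(cands))
  expect_equal(nrow(filter_by_probability(cands, 1)), sum(cands$probability >= 1))
  expect_equal(filter_by_probability(cands, 0.5)$probability,
               cands$probability[cands$probability >= 0.5])
})

test_that("pooling matches a brute-force connected-components oracle", {
  one <- rand_candidates(1, seed = 4)
  expect_equal(pool_candidates(one, 2), one)

  two <- tibble::tibble(chrom = "chrT", i = c(10L, 13L), j = c(40L, 40L),
                        distance = c(30L, 27L), raw_value = c(5, 6),
                        probability = c(0.9, 0.8))
  expect_equal(nrow(pool_candidates(two, radius = 2)), 2)  # distance 3 > 2

  for (s in 1:25) {
    cands <- rand_candidates(n = 40, seed = s, span = 25)
    got <- pool_candidates(cands, radius = 2)
    want <- brute_pool(cands, radius = 2)
    expect_equal(as.data.frame(got), as.data.frame(want))
    # idempotence
    expect_equal(as.data.frame(pool_candidates(got, radius = 2)),
                 as.data.frame(got))
  }
})

test_that("binomial downsampling preserves structure and moments", {
  cm <- rand_map(n_bins = 150, n_entries = 3000, seed = 5)

  full <- downsample_map(cm, 1, seed = 1)
  expect_equal(as.data.frame(full$entries), as.data.frame(cm$entries))
  empty <- downsample_map(cm, 0, seed = 1)
  expect_equal(nrow(empty$entries), 0)

  N <- sum(cm$entries$value)
  half <- downsample_map(cm, 0.5, seed = 2)
  expect_lt(abs(sum(half$entries$value) - N / 2), 4 * sqrt(N * 0.25))
  expect_identical(downsample_map(cm, 0.5, seed = 2)$entries, half$entries)

  # expected totals scale linearly with the fraction (20 seeds)
  for (fr in c(0.25, 0.75)) {
    tot <- vapply(1:20, function(s) sum(downsample_map(cm, fr, seed = s)$entries$value), 0)
    expect_lt(abs(mean(tot) - fr * N), 4 * sqrt(N * fr * (1 - fr) / 20))
  }

  bal <- contact_map("chrT", 10000, 5, data.frame(i = 0, j = 2, value = 1.5))
  expect_error(downsample_map(bal, 0.5, seed = 1), "integer counts")
})

test_that("chromosome scoring enumerates exactly the eligible pixels", {
  p <- small_sim_params(seed = 13)
  sim <- simulate_contact_map(p, 1)
  tr <- simulate_accessibility(p, sim$truth, 1)
  m <- init_model(model_config(seed = 2, filters = c(2, 3, 2), fc_width = 4))

  cands <- score_chromosome(m, sim$map, tr, min_dist = 5, max_dist = 30)
  e <- sim$map$entries
  d <- e$j - e$i
  want <- e[d >= 5 & d <= 30 & e$i >= 11 & e$j < sim$map$n_bins - 11, ]
  expect_equal(nrow(cands), nrow(want))
  expect_setequal(paste(cands$i, cands$j), paste(want$i, want$j))
  expect_true(all(cands$probability > 0 & cands$probability < 1))

  none <- score_chromosome(m, sim$map, tr, min_dist = 200, max_dist = 300)
  expect_equal(nrow(none), 0)
})

test_that("the calling pipeline is monotone and a subset of the candidates", {
  p <- small_sim_params(seed = 13)
  sim <- simulate_contact_map(p, 1)
  tr <- simulate_accessibility(p, sim$truth, 1)
  m <- init_model(model_config(seed = 2, filters = c(2, 3, 2), fc_width = 4))

  calls <- call_loops(m, sim$map, tr, max_dist = p$max_sim_dist, quiet = TRUE)
  counts <- attr(calls, "stage_counts")
  expect_equal(counts$stage,
               c("candidates", "after_frequency", "after_probability", "pooled"))
  expect_true(all(diff(counts$n) <= 0))
  cands <- score_chromosome(m, sim$map, tr, max_dist = p$max_sim_dist)
  expect_true(all(paste(calls$i, calls$j) %in% paste(cands$i, cands$j)))

  # an empty map yields no calls
  empty_map <- contact_map("chr1", 10000, 500,
                           data.frame(i = integer(), j = integer(),
                                      value = numeric()))
  flat <- accessibility_track("chr1", 10000, rep(1, 500))
  expect_equal(nrow(call_loops(m, empty_map, flat, quiet = TRUE)), 0)
})

test_that("threshold calibration returns the F1-maximizing cutoff", {
  pipe <- fixture_pipeline()
  cal <- pipe$calibration
  expect_s3_class(cal$curve, "tbl_df")
  expect_equal(cal$threshold, cal$curve$threshold[which.max(cal$curve$f1)])
  expect_true(all(diff(cal$curve$calls) <= 0))  # higher cutoff, fewer calls
})
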