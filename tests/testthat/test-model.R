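test_that("initialization is seed-deterministic and forward output is a probability", {
  cfg <- tiny_model_config(seed = 5)
  m1 <- init_model(cfg)
  m2 <- init_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- init_model(tiny_model_config(seed = 6))
  expect_false(identical(m1$params, m3$params))

  x0 <- array(0, dim = c(9, 9, 2, 1))
  pr <- predict(m1, x0)
  expect_true(pr > 0 && pr < 1)
})

test_that("parameter count matches the closed-form architecture count", {
  cfg <- model_config(window_size = 23, filters = c(4, 8, 16), fc_width = 64)
  m <- init_model(cfg)
  chans <- c(2, 4, 8, 16)
  conv_n <- sum(chans[2:4] * chans[1:3] * 9 + 3 * chans[2:4])  # W + b/gamma/beta
  flat <- 16 * (23 %/% 8)^2
  fc_n <- (64 * flat + 3 * 64) + (64 * 64 + 3 * 64)
  out_n <- 64 + 1
  expect_equal(n_params(m), conv_n + fc_n + out_n)
})

test_that("binary cross-entropy matches its closed forms", {
  expect_lt(bce_loss(1, 1 - 1e-9), 1e-6)
  expect_equal(bce_loss(0, 0.5), log(2))
  expect_equal(bce_loss(c(1, 0), c(0.8, 0.3)),
               mean(c(-log(0.8), -log(0.7))))

  set.seed(3)
  y <- rbinom(50, 1, 0.5); p <- runif(50, 0.01, 0.99)
  expect_equal(bce_loss(y, p), mean(-y * log(p) - (1 - y) * log(1 - p)))
  expect_error(bce_loss(c(1, 0), 0.5), "equal length")
})

test_that("leave-one-chromosome-out split partitions deterministically", {
  chroms <- paste0("chr", 1:23)
  sp <- loco_split(chroms, "chr1", val_fraction = 0.2, seed = 3)
  expect_length(sp$train, 18)
  expect_length(sp$validation, 4)
  expect_equal(sp$test, "chr1")
  expect_setequal(c(sp$train, sp$validation, sp$test), chroms)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_identical(sp, loco_split(chroms, "chr1", val_fraction = 0.2, seed = 3))
  expect_error(loco_split(chroms, "chrX", seed = 1), "chrX")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_model_config(seed = 5)
  m <- init_model(cfg)
  set.seed(31)
  n <- 6
  x <- array(runif(9 * 9 * 2 * n), dim = c(9, 9, 2, n))
  y <- c(1, 0, 1, 1, 0, 0)
  hs <- 9 %/% c(1, 2, 4)
  du <- lapply(1:3, function(l) runif(cfg$filters[l] * hs[l]^2 * n))
  base <- loopcallr:::cpp_cnn_train_batch(m$params, x, y, du, cfg$dropout)
  eps <- 1e-6
  paths <- list(list("conv", 1, "W"), list("conv", 2, "gamma"),
                list("conv", 3, "W"), list("fc", 1, "W"),
                list("fc", 2, "beta"), list("out", "W"))
  for (path in paths) {
    v <- purrr::pluck(m$params, !!!path)
    g <- purrr::pluck(base$grads, !!!path)
    for (ii in sample(length(v), min(3, length(v)))) {
      vv <- v; vv[ii] <- vv[ii] + eps
      pert <- purrr::assign_in(m$params, path, vv)
      num <- (loopcallr:::cpp_cnn_train_batch(pert, x, y, du, cfg$dropout)$loss - base$loss) / eps
      expect_equal(g[ii], num, tolerance = 1e-3)
    }
  }
})

test_that("one Adam step on a mislabeled example reduces its loss", {
  cfg <- tiny_model_config(seed = 5)
  m <- init_model(cfg)
  set.seed(8)
  x <- array(runif(9 * 9 * 2), dim = c(9, 9, 2, 1))
  ds <- structure(list(x = x, label = 1L, chrom = "chrT", i = 1L, j = 9L,
                       manifest = list()), class = "loop_dataset")
  hs <- 9 %/% c(1, 2, 4)
  du <- lapply(1:3, function(l) rep(1, cfg$filters[l] * hs[l]^2))
  before <- loopcallr:::cpp_cnn_train_batch(m$params, x, 1, du, 0)
  st <- loopcallr:::adam_step(m$params, before$grads, loopcallr:::adam_init(m$params), lr = 0.001)
  after <- loopcallr:::cpp_cnn_train_batch(st$params, x, 1, du, 0)
  expect_lt(after$loss, before$loss)
})

test_that("training is reproducible, tracks history and keeps the best epoch", {
  tr <- tiny_dataset(n = 24, seed = 2)
  va <- tiny_dataset(n = 12, seed = 3)
  tc <- train_config(batch_size = 8, max_epochs = 12, patience = 12, seed = 9)
  m1 <- train_model(init_model(tiny_model_config()), tr, va, tc)
  m2 <- train_model(init_model(tiny_model_config()), tr, va, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 12)
  expect_equal(max(m1$history$val_prauc),
               m1$history$val_prauc[m1$best_epoch])

  bad <- tiny_dataset(n = 8)
  bad$label <- rep(1L, 8)
  expect_error(train_model(init_model(tiny_model_config()), bad, va, tc),
               "both classes")
})

test_that("prediction is deterministic and batching-invariant", {
  tr <- tiny_dataset(n = 24, seed = 2)
  va <- tiny_dataset(n = 12, seed = 3)
  m <- train_model(init_model(tiny_model_config()), tr, va,
                   train_config(batch_size = 8, max_epochs = 5, patience = 5,
                                seed = 9))
  # duplicate window -> identical probability
  x2 <- va$x[, , , c(1, 1), drop = FALSE]
  pr <- predict(m, x2)
  expect_identical(pr[1], pr[2])
  # one-by-one vs one batch
  whole <- predict(m, va)
  single <- vapply(seq_len(12), function(k) {
    predict(m, va$x[, , , k, drop = FALSE])
  }, 0)
  expect_equal(whole, single, tolerance = 1e-6)
  expect_error(predict(m, array(0, c(7, 7, 2, 1))), "shape|window")
})

test_that("tidy and glance summarize a trained model", {
  tr <- tiny_dataset(n = 16, seed = 2)
  va <- tiny_dataset(n = 8, seed = 3)
  m <- train_model(init_model(tiny_model_config()), tr, va,
                   train_config(batch_size = 8, max_epochs = 4, patience = 4,
                                seed = 9))
  td <- tidy(m)
  expect_equal(names(td), c("epoch", "train_loss", "val_loss", "val_prauc"))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$epochs, nrow(td))
  expect_equal(gl$n_params, n_params(m))

  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_identical(load_model(f)$params, m$params)
})
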