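# small deterministic fixtures shared across test files

# a sparse random symmetric map on n_bins bins
rand_map <- function(n_bins = 80, n_entries = 200, seed = 1, chrom = "chrT",
                     resolution = 10000) {
  set.seed(seed)
  i <- sample(0:(n_bins - 1), n_entries, replace = TRUE)
  j <- sample(0:(n_bins - 1), n_entries, replace = TRUE)
  v <- rpois(n_entries, 4) + 1
  contact_map(chrom, resolution, n_bins,
              data.frame(i = i, j = j, value = v))
}

rand_track <- function(n_bins = 80, seed = 1, chrom = "chrT",
                       resolution = 10000) {
  set.seed(seed)
  accessibility_track(chrom, resolution, runif(n_bins, 0, 4))
}

# small simulation, cheap enough for unit tests
small_sim_params <- function(seed = 3, ...) {
  sim_params(n_chroms = 1, n_bins = 500, n_loops = 5, seed = seed, ...)
}

# tiny model configuration for fast training tests
tiny_model_config <- function(seed = 5) {
  model_config(window_size = 9, filters = c(2, 3, 2), fc_width = 5,
               seed = seed)
}

# a tiny separable labeled dataset built directly (no simulator)
tiny_dataset <- function(n = 16, w = 9, seed = 2) {
  set.seed(seed)
  x <- array(runif(w * w * 2 * n, 0, 0.2), dim = c(w, w, 2, n))
  label <- rep(0:1, length.out = n)
  ctr <- (w + 1) / 2
  for (k in which(label == 1)) {
    x[ctr + (-1:1), ctr + (-1:1), 1, k] <- x[ctr + (-1:1), ctr + (-1:1), 1, k] + 0.6
    x[ctr, ctr, 2, k] <- x[ctr, ctr, 2, k] + 0.7
  }
  structure(list(x = x, label = label, chrom = rep("chrT", n),
                 i = seq_len(n), j = seq_len(n) + 10,
                 manifest = list()), class = "loop_dataset")
}

# brute-force single-linkage pooling oracle (Chebyshev <= radius)
brute_pool <- function(df, radius) {
  n <- nrow(df)
  if (n == 0) return(df)
  out <- lapply(split(seq_len(n), df$chrom), function(ix) {
    sub <- df[ix, , drop = FALSE]
    m <- nrow(sub)
    adj <- as.matrix(stats::dist(sub[, c("i", "j")], method = "maximum")) <= radius
    comp <- rep(NA_integer_, m); cid <- 0L
    for (s in seq_len(m)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      frontier <- s; comp[s] <- cid
      while (length(frontier) > 0) {
        nb <- which(adj[frontier[1], ] & is.na(comp))
        comp[nb] <- cid
        frontier <- c(frontier[-1], nb)
      }
    }
    reps <- vapply(split(seq_len(m), comp), function(q) {
      q[order(-sub$probability[q], -sub$raw_value[q], sub$i[q], sub$j[q])][1]
    }, 0L)
    sub[sort(reps), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  res[order(res$chrom, res$i, res$j), , drop = FALSE]
}

rand_candidates <- function(n = 30, seed = 1, span = 40, chrom = "chrT") {
  set.seed(seed)
  unique_ij <- unique(data.frame(i = sample(0:span, n, replace = TRUE),
                                 j = sample(50:(50 + span), n, replace = TRUE)))
  tibble::tibble(chrom = chrom, i = unique_ij$i, j = unique_ij$j,
                 distance = unique_ij$j - unique_ij$i,
                 raw_value = rpois(nrow(unique_ij), 6) + 1,
                 probability = runif(nrow(unique_ij)))
}
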