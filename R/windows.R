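#' Extract a contact window around a bin pair
#'
#' Returns the dense `w x w` sub-matrix of contact values centred on the
#' pixel `(i, j)`, with absent entries as 0. Cells below the matrix diagonal
#' take the mirrored upper-triangle value, so windows straddling the
#' diagonal are consistent with a symmetric contact matrix.
#'
#' @param map A [contact_map()].
#' @param i,j 0-based bin indices, `i < j`.
#' @param w Window size in bins (odd; default 23).
#' @return A `w x w` numeric matrix of raw contact values.
#' @export
extract_window <- function(map, i, j, w = 23) {
  hw <- half_width(w)
  if (!window_in_bounds(i, j, w, map$n_bins)) {
    stop(sprintf("window (%d, %d, w = %d) overruns chromosome bounds [0, %d)",
                 i, j, w, map$n_bins), call. = FALSE)
  }
  rows <- (i - hw):(i + hw)
  cols <- (j - hw):(j + hw)
  m <- matrix(0, w, w)
  e <- map$entries
  sel <- e$i >= min(rows, cols) & e$j <= max(rows, cols)
  e <- e[sel, , drop = FALSE]
  # direct orientation: entry (a, b) lands at (row a, col b)
  d1 <- e$i >= rows[1] & e$i <= rows[w] & e$j >= cols[1] & e$j <= cols[w]
  if (any(d1)) m[cbind(e$i[d1] - rows[1] + 1L, e$j[d1] - cols[1] + 1L)] <- e$value[d1]
  # mirrored orientation: entry (a, b) also represents (b, a)
  d2 <- e$j >= rows[1] & e$j <= rows[w] & e$i >= cols[1] & e$i <= cols[w]
  if (any(d2)) m[cbind(e$j[d2] - rows[1] + 1L, e$i[d2] - cols[1] + 1L)] <- e$value[d2]
  m
}

#' Build the accessibility matrix for a window
#'
#' Lifts the 1D accessibility signal into a 2D channel as the outer product
#' of the row-anchor and column-anchor bin values: with `x` the track over
#' the window's rows and `y` over its columns, `A[r, c] = x[r] * y[c]`.
#'
#' @param track An [accessibility_track()].
#' @param i,j 0-based bin indices of the window centre.
#' @param w Window size in bins (odd; default 23).
#' @return A `w x w` numeric matrix.
#' @export
accessibility_matrix <- function(track, i, j, w = 23) {
  hw <- half_width(w)
  n <- length(track$values)
  if (!window_in_bounds(i, j, w, n)) {
    stop(sprintf("window (%d, %d, w = %d) overruns chromosome bounds [0, %d)",
                 i, j, w, n), call. = FALSE)
  }
  x <- track$values[(i - hw):(i + hw) + 1L]
  y <- track$values[(j - hw):(j + hw) + 1L]
  outer(x, y)
}

#' Normalize a window channel
#'
#' Applies `m <- log10(1 + m)` elementwise, then scales by
#' `1 / (1 + max(m))` with the maximum taken over this window after the log
#' step, mapping any non-negative window into `[0, 1)`. An all-zero window
#' stays all-zero.
#'
#' @param m Non-negative numeric matrix.
#' @return A matrix of the same shape with values in `[0, 1)`.
#' @export
#' @examples
#' m <- matrix(0, 23, 23); m[12, 12] <- 9
#' normalize_window(m)[12, 12]  # log10(10) / (1 + 1) = 0.5
normalize_window <- function(m) {
  if (any(m < 0)) stop("window entries must be non-negative", call. = FALSE)
  lm <- log10(1 + m)
  lm / (1 + max(lm))
}

#' Empirical distance distribution of positive interactions
#'
#' @param positives Tibble with `bin1`, `bin2` columns.
#' @return A tibble with `distance` (bins) and `prob`, summing to 1.
#' @export
distance_pdf <- function(positives) {
  if (is.null(positives) || nrow(positives) == 0) {
    stop("`positives` must be non-empty", call. = FALSE)
  }
  d <- positives$bin2 - positives$bin1
  tab <- table(d)
  tibble::tibble(distance = as.integer(names(tab)),
                 prob = as.numeric(tab) / sum(tab))
}

#' Sample distance-matched and long-range negative interactions
#'
#' Draws exactly `nrow(positives)` negative bin pairs from the non-zero
#' pixels of the contact map: a `1 - far_fraction` share with distances
#' drawn from the empirical positive distance distribution, and a
#' `far_fraction` share with distances strictly greater than the maximum
#' positive distance (capped at `max_dist`). Negatives never fall within
#' Chebyshev distance 1 of a positive centre, always have in-bounds windows,
#' and are sampled without replacement.
#'
#' @param map A [contact_map()].
#' @param positives Tibble with `bin1`, `bin2` for one chromosome.
#' @param far_fraction Share of long-range negatives in `[0, 1]` (default 0.2).
#' @param w Window size in bins used for the bounds check (default 23).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param max_dist Cap (bins) on negative distances (default 300).
#' @return A tibble with `chrom`, `bin1`, `bin2`, `label = 0`.
#' @export
sample_negatives <- function(map, positives, far_fraction = 0.2, w = 23,
                             seed = 1, max_dist = 300) {
  assert_scalar_number(far_fraction, "far_fraction", 0, 1)
  n <- nrow(positives)
  empty <- tibble::tibble(chrom = character(), bin1 = integer(),
                          bin2 = integer(), label = integer())
  if (n == 0) return(empty)

  e <- map$entries
  d <- e$j - e$i
  ok <- d >= 1L & window_in_bounds(e$i, e$j, w, map$n_bins)
  # exclude a Chebyshev-1 halo around every positive centre
  halo <- expand.grid(di = -1:1, dj = -1:1)
  pos_keys <- unlist(lapply(seq_len(nrow(halo)), function(k) {
    (positives$bin1 + halo$di[k]) * as.double(map$n_bins) +
      (positives$bin2 + halo$dj[k])
  }))
  key <- e$i * as.double(map$n_bins) + e$j
  ok <- ok & !(key %in% pos_keys)

  elig <- which(ok)
  if (length(elig) < n) {
    stop("not enough eligible non-zero pixels to sample negatives", call. = FALSE)
  }
  n_far <- round(far_fraction * n)
  n_near <- n - n_far
  pdf <- distance_pdf(positives)
  max_pos <- max(positives$bin2 - positives$bin1)

  with_seed(seed, {
    taken <- logical(length(ok))
    by_dist <- split(elig, d[elig])
    avail_d <- as.integer(names(by_dist))
    # shuffle each distance bucket once; pop from the front
    by_dist <- lapply(by_dist, function(v) if (length(v) > 1) sample(v) else v)
    ptr <- stats::setNames(rep(1L, length(by_dist)), names(by_dist))

    pick_at <- function(target) {
      # nearest distance bucket with availability
      cand <- avail_d[vapply(as.character(avail_d),
                             function(k) ptr[[k]] <= length(by_dist[[k]]), TRUE)]
      if (length(cand) == 0) return(NA_integer_)
      dd <- cand[which.min(abs(cand - target))]
      if (dd != target) {
        message("negative sampling: distance ", target,
                " exhausted, using nearest available ", dd)
      }
      k <- as.character(dd)
      idx <- by_dist[[k]][ptr[[k]]]
      ptr[[k]] <<- ptr[[k]] + 1L
      idx
    }

    near_idx <- integer(0)
    if (n_near > 0) {
      targets <- if (nrow(pdf) == 1) rep(pdf$distance, n_near) else
        sample(pdf$distance, n_near, replace = TRUE, prob = pdf$prob)
      near_idx <- vapply(targets, pick_at, 0L)
      if (anyNA(near_idx)) {
        stop("not enough eligible pixels for distance-matched negatives",
             call. = FALSE)
      }
    }
    far_pool <- setdiff(elig[d[elig] > max_pos & d[elig] <= max_dist], near_idx)
    if (length(far_pool) < n_far) {
      stop("not enough eligible pixels beyond the maximum positive distance",
           call. = FALSE)
    }
    far_idx <- if (n_far > 0) {
      if (length(far_pool) == 1) far_pool else sample(far_pool, n_far)
    } else integer(0)
    idx <- c(near_idx, far_idx)
    tibble::tibble(chrom = map$chrom, bin1 = e$i[idx], bin2 = e$j[idx],
                   label = 0L)
  })
}

#' Build a labeled two-channel training dataset
#'
#' Creates one sample per usable positive interaction (label 1) and per
#' sampled negative (label 0). Each sample is a two-channel `w x w` window:
#' the contact sub-matrix and the accessibility outer-product matrix, each
#' normalized independently with [normalize_window()]. Positives whose
#' window overruns the chromosome are dropped and counted in the manifest.
#'
#' @inheritParams sample_negatives
#' @param track An [accessibility_track()] for the same chromosome.
#' @return An object of class `loop_dataset`: list with `x` (array
#'   `w x w x 2 x n`), `label`, `chrom`, `i`, `j` and `manifest`.
#' @export
build_dataset <- function(map, track, positives, w = 23, far_fraction = 0.2,
                          seed = 1, max_dist = 300) {
  stopifnot(inherits(map, "contact_map"), inherits(track, "accessibility_track"))
  if (length(track$values) != map$n_bins) {
    stop("track length must equal the contact map bin count", call. = FALSE)
  }
  inb <- window_in_bounds(positives$bin1, positives$bin2, w, map$n_bins)
  n_dropped <- sum(!inb)
  if (n_dropped > 0) {
    message(n_dropped, " positive(s) dropped: window out of bounds")
  }
  pos <- positives[inb, , drop = FALSE]
  neg <- sample_negatives(map, pos, far_fraction = far_fraction, w = w,
                          seed = seed, max_dist = max_dist)
  centers_i <- c(pos$bin1, neg$bin1)
  centers_j <- c(pos$bin2, neg$bin2)
  label <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  M <- dense_matrix(map)
  x <- cpp_build_windows(M, track$values, as.integer(centers_i),
                         as.integer(centers_j), as.integer(w))
  manifest <- list(chrom = map$chrom, n_pos = nrow(pos), n_neg = nrow(neg),
                   n_dropped = n_dropped, seed = seed, w = w,
                   far_fraction = far_fraction,
                   max_pos_dist = if (nrow(pos)) max(pos$bin2 - pos$bin1) else NA_integer_)
  structure(list(x = x, label = label,
                 chrom = rep(map$chrom, length(label)),
                 i = as.integer(centers_i), j = as.integer(centers_j),
                 manifest = manifest),
            class = "loop_dataset")
}

#' @export
print.loop_dataset <- function(x, ...) {
  cat(sprintf("<loop_dataset> %d samples (%d positive / %d negative), %dx%d windows\n",
              length(x$label), sum(x$label == 1), sum(x$label == 0),
              dim(x$x)[1], dim(x$x)[2]))
  invisible(x)
}

#' Concatenate datasets from several chromosomes
#'
#' @param datasets List of `loop_dataset` objects with identical window size.
#' @return A single `loop_dataset`; `manifest` becomes a list of the
#'   per-chromosome manifests.
#' @export
bind_datasets <- function(datasets) {
  datasets <- datasets[vapply(datasets, function(d) length(d$label) > 0, TRUE)]
  stopifnot(length(datasets) > 0)
  w <- dim(datasets[[1]]$x)[1]
  n <- sum(vapply(datasets, function(d) length(d$label), 0L))
  x <- array(0, dim = c(w, w, 2, n))
  at <- 0L
  for (d in datasets) {
    k <- length(d$label)
    if (k > 0) x[, , , at + seq_len(k)] <- d$x
    at <- at + k
  }
  structure(list(x = x,
                 label = unlist(lapply(datasets, `[[`, "label")),
                 chrom = unlist(lapply(datasets, `[[`, "chrom")),
                 i = unlist(lapply(datasets, `[[`, "i")),
                 j = unlist(lapply(datasets, `[[`, "j")),
                 manifest = lapply(datasets, `[[`, "manifest")),
            class = "loop_dataset")
}

# subset a dataset by sample index
dataset_subset <- function(ds, idx) {
  structure(list(x = ds$x[, , , idx, drop = FALSE],
                 label = ds$label[idx], chrom = ds$chrom[idx],
                 i = ds$i[idx], j = ds$j[idx], manifest = ds$manifest),
            class = "loop_dataset")
}

#' Save / load a dataset as an HDF5 container
#'
#' @param ds A `loop_dataset`.
#' @param path Output `.h5` path.
#' @return `write_dataset` returns the path invisibly; `read_dataset`
#'   returns the `loop_dataset`.
#' @export
write_dataset <- function(ds, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(ds$x, path, "windows")
  rhdf5::h5write(as.integer(ds$label), path, "label")
  rhdf5::h5write(ds$chrom, path, "chrom")
  rhdf5::h5write(as.integer(ds$i), path, "bin1")
  rhdf5::h5write(as.integer(ds$j), path, "bin2")
  rhdf5::h5write(as.character(jsonlite::toJSON(ds$manifest, auto_unbox = TRUE)), path, "manifest")
  invisible(path)
}

#' @rdname write_dataset
#' @param path Path to a dataset written by `write_dataset`.
#' @export
read_dataset <- function(path) {
  x <- rhdf5::h5read(path, "windows")
  structure(list(x = x,
                 label = as.integer(rhdf5::h5read(path, "label")),
                 chrom = as.character(rhdf5::h5read(path, "chrom")),
                 i = as.integer(rhdf5::h5read(path, "bin1")),
                 j = as.integer(rhdf5::h5read(path, "bin2")),
                 manifest = jsonlite::fromJSON(as.character(rhdf5::h5read(path, "manifest")))),
            class = "loop_dataset")
}
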