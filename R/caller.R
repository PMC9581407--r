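#' Score all candidate pixels on a chromosome
#'
#' Every stored (non-zero) pixel with `min_dist <= j - i <= max_dist` and an
#' in-bounds `w`-window becomes a candidate; its probability comes from the
#' trained classifier applied to the same two-channel normalized window
#' construction used for training.
#'
#' @param model A trained `loop_cnn`.
#' @param map A [contact_map()].
#' @param track The matching [accessibility_track()].
#' @param min_dist,max_dist Scoring distance range in bins (defaults 3 and
#'   300, i.e. 30 kb to 3 Mb at 10 kb resolution).
#' @param w Window size in bins (default from the model configuration).
#' @param chunk Scoring batch size.
#' @return A tibble of candidates: `chrom`, `i`, `j`, `distance`,
#'   `raw_value`, `probability`.
#' @export
score_chromosome <- function(model, map, track, min_dist = 3, max_dist = 300,
                             w = NULL, chunk = 128L) {
  stopifnot(inherits(model, "loop_cnn"), inherits(map, "contact_map"),
            inherits(track, "accessibility_track"))
  w <- w %||% model$config$window_size
  if (length(track$values) != map$n_bins) {
    stop("track length must equal the contact map bin count", call. = FALSE)
  }
  e <- map$entries
  d <- e$j - e$i
  keep <- d >= min_dist & d <= max_dist & window_in_bounds(e$i, e$j, w, map$n_bins)
  cand <- e[keep, , drop = FALSE]
  out <- tibble::tibble(chrom = rep(map$chrom, nrow(cand)),
                        i = cand$i, j = cand$j,
                        distance = cand$j - cand$i,
                        raw_value = cand$value,
                        probability = numeric(nrow(cand)))
  if (nrow(cand) == 0) return(out)
  M <- dense_matrix(map)
  probs <- numeric(nrow(cand))
  for (start in seq(1, nrow(cand), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(cand))
    x <- cpp_build_windows(M, track$values, as.integer(cand$i[idx]),
                           as.integer(cand$j[idx]), as.integer(w))
    probs[idx] <- cpp_cnn_infer(model$params, x)
  }
  out$probability <- probs
  out
}

#' Keep candidates above the mean contact frequency
#'
#' Retains candidates whose raw contact value strictly exceeds the
#' arithmetic mean over all input candidates, computed per chromosome.
#'
#' @param cands Candidate tibble from [score_chromosome()].
#' @return The filtered tibble.
#' @export
filter_by_frequency <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  dplyr::filter(cands, .data$raw_value > mean(.data$raw_value),
                .by = "chrom")
}

#' Keep candidates at or above a probability threshold
#'
#' @param cands Candidate tibble.
#' @param threshold Probability cutoff in `[0, 1]` (default 0.5); in
#'   practice the cutoff is tuned per dataset to control the call count
#'   (see [calibrate_threshold()]).
#' @return The filtered tibble.
#' @export
filter_by_probability <- function(cands, threshold = 0.5) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  dplyr::filter(cands, .data$probability >= threshold)
}

#' Pool candidate pixels into representative loop calls
#'
#' Candidates are grouped per chromosome into single-linkage clusters under
#' Chebyshev distance `<= radius` on `(i, j)`; each cluster contributes the
#' candidate with the highest probability (ties broken by higher raw value,
#' then smaller `(i, j)`).
#'
#' @param cands Candidate tibble.
#' @param radius Linking radius in bins (default 2, i.e. 20 kb at 10 kb).
#' @return A tibble of representatives, one per cluster.
#' @export
pool_candidates <- function(cands, radius = 2) {
  assert_scalar_number(radius, "radius", lower = 1)
  if (nrow(cands) == 0) return(cands)
  pooled <- lapply(split(cands, cands$chrom), pool_one_chrom, radius = radius)
  dplyr::bind_rows(pooled) |>
    dplyr::arrange(.data$chrom, .data$i, .data$j)
}

pool_one_chrom <- function(df, radius) {
  n <- nrow(df)
  if (n == 1) return(df)
  # spatial hash: Chebyshev-<=radius neighbours lie in adjacent cells
  ci <- df$i %/% radius
  cj <- df$j %/% radius
  span <- max(cj) - min(cj) + 3L
  cell <- (ci - min(ci)) * as.double(span) + (cj - min(cj))
  members <- split(seq_len(n), cell)
  cell_ids <- as.numeric(names(members))
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  offsets <- as.vector(outer(-1:1 * span, -1:1, `+`))
  idx_of <- function(ids) match(ids, cell_ids)
  for (k in seq_along(members)) {
    base <- cell_ids[k]
    neigh <- idx_of(base + offsets)
    neigh <- neigh[!is.na(neigh) & neigh >= k]
    pts_a <- members[[k]]
    for (nk in neigh) {
      pts_b <- members[[nk]]
      same_cell <- nk == k
      for (a in pts_a) for (b in pts_b) {
        if ((!same_cell || a < b) && a != b &&
            abs(df$i[a] - df$i[b]) <= radius &&
            abs(df$j[a] - df$j[b]) <= radius) union_(a, b)
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  reps <- vapply(split(seq_len(n), root), function(idx) {
    o <- order(-df$probability[idx], -df$raw_value[idx], df$i[idx], df$j[idx])
    idx[o[1]]
  }, 0L)
  df[sort(reps), , drop = FALSE]
}

#' Calibrate the call probability threshold on reference interactions
#'
#' The probability cutoff controls the call count and is tuned per dataset
#' (different sequencing depths and training sets put the classifier's
#' operating point at different scores). This helper scores the given
#' chromosomes, applies the full filter/pool pipeline at each candidate
#' threshold, and returns the threshold maximizing F1 against a reference
#' loop set under tolerant matching — typically the training chromosomes
#' against their own training interactions, so no held-out data is used.
#'
#' @param model A trained `loop_cnn`.
#' @param maps Named list of [contact_map()]s (calibration chromosomes).
#' @param tracks Named list of matching [accessibility_track()]s.
#' @param reference Tibble of reference loops (`chrom`, `bin1`, `bin2`).
#' @param thresholds Candidate cutoffs (default a coarse grid up to
#'   1 - 1e-5).
#' @param radius Pooling radius in bins.
#' @param tol Matching tolerance in bp (default one bin).
#' @param min_dist,max_dist Scoring distance range in bins.
#' @return A list: `threshold` (the F1-maximizing cutoff; ties go to the
#'   smaller threshold) and `curve` (a tibble of threshold, calls,
#'   precision, recall, f1).
#' @export
calibrate_threshold <- function(model, maps, tracks, reference,
                                thresholds = c(0.5, 0.9, 0.99, 0.999,
                                               0.9999, 0.99999),
                                radius = 2, tol = NULL,
                                min_dist = 3, max_dist = 300) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  if (inherits(tracks, "accessibility_track")) tracks <- list(tracks)
  tol <- tol %||% maps[[1]]$resolution
  freq <- lapply(seq_along(maps), function(k) {
    filter_by_frequency(score_chromosome(model, maps[[k]], tracks[[k]],
                                         min_dist = min_dist,
                                         max_dist = max_dist))
  })
  curve <- purrr::map_dfr(thresholds, function(thr) {
    calls <- dplyr::bind_rows(lapply(freq, function(f) {
      pool_candidates(filter_by_probability(f, thr), radius)
    }))
    calls <- dplyr::rename(calls, bin1 = "i", bin2 = "j")
    mm <- match_loops(calls, reference, mode = "tolerant", tol = tol,
                      resolution = maps[[1]]$resolution)
    prec <- if (nrow(calls) > 0) mm$n_matched_a / nrow(calls) else 0
    rec <- mm$n_matched_b / nrow(reference)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(threshold = thr, calls = nrow(calls),
                   precision = prec, recall = rec, f1 = f1)
  })
  list(threshold = curve$threshold[which.max(curve$f1)], curve = curve)
}

#' Binomially downsample a raw-count contact map
#'
#' Replaces each entry value by a `Binomial(value, fraction)` draw,
#' emulating a shallower sequencing depth without re-mapping; zero draws
#' are removed. Defined on raw integer counts only.
#'
#' @param map A [contact_map()] holding integer counts.
#' @param fraction Retention probability in `[0, 1]`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A new [contact_map()].
#' @export
downsample_map <- function(map, fraction, seed = 1) {
  assert_scalar_number(fraction, "fraction", 0, 1)
  v <- map$entries$value
  if (any(v != round(v))) {
    stop("downsampling is defined on raw integer counts only", call. = FALSE)
  }
  new_v <- with_seed(seed, stats::rbinom(length(v), size = as.integer(round(v)),
                                         prob = fraction))
  e <- map$entries
  e$value <- as.numeric(new_v)
  e <- e[e$value > 0, , drop = FALSE]
  contact_map(map$chrom, map$resolution, map$n_bins, e, balanced = FALSE)
}

#' Call chromatin loops on a chromosome
#'
#' Two-stage genome-wide identification: score all candidate pixels with
#' the trained classifier, keep those above the mean contact frequency and
#' the probability threshold, then pool neighbouring survivors into
#' representative calls. Stage counts are attached as the
#' `"stage_counts"` attribute and logged via `message()`.
#'
#' @inheritParams score_chromosome
#' @param threshold Probability cutoff (default 0.5).
#' @param radius Pooling radius in bins (default 2).
#' @param quiet Suppress stage-count messages.
#' @return A tibble of loop calls (`chrom`, `i`, `j`, `distance`,
#'   `raw_value`, `probability`).
#' @export
call_loops <- function(model, map, track, min_dist = 3, max_dist = 300,
                       threshold = 0.5, radius = 2, w = NULL, quiet = FALSE) {
  cands <- score_chromosome(model, map, track, min_dist = min_dist,
                            max_dist = max_dist, w = w)
  freq <- filter_by_frequency(cands)
  prob <- filter_by_probability(freq, threshold)
  pooled <- pool_candidates(prob, radius)
  counts <- tibble::tibble(
    stage = c("candidates", "after_frequency", "after_probability", "pooled"),
    n = c(nrow(cands), nrow(freq), nrow(prob), nrow(pooled)))
  if (!quiet) {
    message(sprintf("%s: %d candidates -> %d after frequency -> %d after probability -> %d loops",
                    map$chrom, nrow(cands), nrow(freq), nrow(prob), nrow(pooled)))
  }
  attr(pooled, "stage_counts") <- counts
  pooled
}
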