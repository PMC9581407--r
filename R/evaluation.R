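#' Area under the precision-recall curve
#'
#' Step integration over all distinct thresholds (no interpolation): with
#' candidates ranked by decreasing probability, the area is
#' `sum_k (R_k - R_(k-1)) * P_k` evaluated at every distinct probability.
#'
#' @param labels 0/1 vector.
#' @param probabilities Scores in `[0, 1]`.
#' @return Scalar PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(labels, probabilities) {
  if (length(labels) != length(probabilities) || length(labels) == 0) {
    stop("labels and probabilities must be non-empty and equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("PR-AUC undefined without positive labels", call. = FALSE)
  o <- order(probabilities, decreasing = TRUE)
  y <- labels[o]
  p <- probabilities[o]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # evaluate only at the last index of each distinct threshold
  last <- c(p[-1] != p[-length(p)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics at a probability threshold
#'
#' Precision, recall and F1 at the given threshold (predictions are
#' positive when `probability >= threshold`), plus the threshold-free
#' PR-AUC. Undefined ratios are reported as 0.
#'
#' @param labels 0/1 vector.
#' @param probabilities Scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble: `precision`, `recall`, `f1`, `prauc`,
#'   `threshold`, `tp`, `fp`, `fn`.
#' @export
classification_metrics <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) == 0) stop("empty input", call. = FALSE)
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  pred <- probabilities >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 prauc = pr_auc(labels, probabilities),
                 threshold = threshold, tp = tp, fp = fp, fn = fn)
}

#' Aggregate peak analysis (APA)
#'
#' Averages the `(2 * flank + 1)`-square raw contact windows centred on a
#' loop set, then scores enrichment as the centre value divided by the mean
#' of the `corner x corner` block nearest the matrix diagonal (the
#' short-distance, "lower-left" corner). Loops with out-of-bounds windows
#' or distance `< 2 * flank + 1` bins are excluded and counted.
#'
#' @param map A [contact_map()].
#' @param loops Tibble with `bin1`, `bin2`.
#' @param flank Half-width of the aggregate in bins (default 10, a 21x21
#'   aggregate at 10 kb resolution).
#' @param corner Corner block edge in bins (default 6).
#' @return An object of class `apa_result` with fields `aggregate`,
#'   `apa_score`, `n_used`, `n_excluded`, `flank`, `corner`.
#' @export
apa <- function(map, loops, flank = 10, corner = 6) {
  stopifnot(inherits(map, "contact_map"))
  if (flank < corner || corner < 1) {
    stop("need flank >= corner >= 1", call. = FALSE)
  }
  size <- 2 * flank + 1
  d <- loops$bin2 - loops$bin1
  usable <- d >= size &
    window_in_bounds(loops$bin1, loops$bin2, size, map$n_bins)
  n_used <- sum(usable)
  if (n_used == 0) stop("no usable loops for APA", call. = FALSE)
  M <- dense_matrix(map)
  agg <- matrix(0, size, size)
  for (k in which(usable)) {
    rows <- (loops$bin1[k] - flank):(loops$bin1[k] + flank) + 1L
    cols <- (loops$bin2[k] - flank):(loops$bin2[k] + flank) + 1L
    agg <- agg + M[rows, cols]
  }
  agg <- agg / n_used
  corner_block <- agg[(size - corner + 1):size, 1:corner]
  score <- agg[flank + 1, flank + 1] / mean(corner_block)
  structure(list(aggregate = agg, apa_score = score, n_used = n_used,
                 n_excluded = sum(!usable), flank = flank, corner = corner),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("<apa_result> %dx%d aggregate over %d loops (%d excluded), APA score %.3f\n",
              nrow(x$aggregate), ncol(x$aggregate), x$n_used, x$n_excluded,
              x$apa_score))
  invisible(x)
}

#' Plot an APA aggregate as a heatmap
#'
#' @param object An `apa_result`.
#' @param ... Unused.
#' @return A ggplot heatmap of the aggregate matrix; the centre pixel is
#'   the loop anchor pair, the lower-left corner is the short-distance
#'   background.
#' @export
autoplot.apa_result <- function(object, ...) {
  size <- nrow(object$aggregate)
  f <- object$flank
  df <- expand.grid(row = seq_len(size) - f - 1, col = seq_len(size) - f - 1)
  df$value <- as.vector(object$aggregate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean contacts") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "offset from anchor 2 (bins)",
                  y = "offset from anchor 1 (bins)",
                  title = sprintf("APA score %.2f (n = %d)",
                                  object$apa_score, object$n_used)) +
    ggplot2::theme_minimal()
}

#' Match two loop sets
#'
#' Exact mode: two loops match when both anchor bins are equal. Tolerant
#' mode: they match when, per anchor, the `±tol` windows around the anchor
#' centres overlap, i.e. the centre distance is `<= 2 * tol`. One element
#' may match several on the other side; the reported counts are of matched
#' elements per side, not of pairs.
#'
#' @param a,b Loop tibbles with `chrom`, `bin1`, `bin2`.
#' @param mode `"exact"` or `"tolerant"`.
#' @param tol Tolerance in bp per anchor (default 10000).
#' @param resolution Bin size in bp (default 10000).
#' @return A list: `n_matched_a`, `n_matched_b`, `pairs` (tibble of index
#'   pairs `idx_a`, `idx_b`).
#' @export
match_loops <- function(a, b, mode = c("exact", "tolerant"), tol = 10000,
                        resolution = 10000) {
  mode <- match.arg(mode)
  a2 <- dplyr::mutate(tibble::as_tibble(a), idx_a = dplyr::row_number())
  b2 <- dplyr::mutate(tibble::as_tibble(b), idx_b = dplyr::row_number())
  if (nrow(a2) == 0 || nrow(b2) == 0) {
    return(list(n_matched_a = 0L, n_matched_b = 0L,
                pairs = tibble::tibble(idx_a = integer(), idx_b = integer())))
  }
  if (mode == "exact") {
    pairs <- dplyr::inner_join(a2, b2,
                               by = c("chrom", "bin1", "bin2"),
                               relationship = "many-to-many")
  } else {
    ctr <- function(bin) (bin + 0.5) * resolution
    pairs <- dplyr::inner_join(a2, b2, by = "chrom",
                               relationship = "many-to-many",
                               suffix = c("_a", "_b")) |>
      dplyr::filter(abs(ctr(.data$bin1_a) - ctr(.data$bin1_b)) <= 2 * tol,
                    abs(ctr(.data$bin2_a) - ctr(.data$bin2_b)) <= 2 * tol)
  }
  pairs <- dplyr::select(pairs, "idx_a", "idx_b")
  list(n_matched_a = dplyr::n_distinct(pairs$idx_a),
       n_matched_b = dplyr::n_distinct(pairs$idx_b),
       pairs = pairs)
}

#' Distance distribution of a loop set
#'
#' @param loops Tibble with `bin1`, `bin2`.
#' @param resolution Bin size in bp.
#' @param breakpoints Strictly increasing band edges in bp (use `Inf` for
#'   an open last band). Bands are half-open `[b_k, b_(k+1))`.
#' @return A tibble with `lower`, `upper`, `proportion`; proportions sum
#'   to 1.
#' @export
distance_profile <- function(loops, resolution, breakpoints) {
  if (nrow(loops) == 0) stop("empty loop set", call. = FALSE)
  if (any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  d_bp <- (loops$bin2 - loops$bin1) * resolution
  band <- cut(d_bp, breaks = breakpoints, right = FALSE)
  tab <- table(band)
  tibble::tibble(lower = breakpoints[-length(breakpoints)],
                 upper = breakpoints[-1],
                 proportion = as.numeric(tab) / nrow(loops))
}
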