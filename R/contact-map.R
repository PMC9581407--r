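#' Construct a sparse intra-chromosomal contact map
#'
#' A contact map stores the upper triangle of a symmetric Hi-C matrix for one
#' chromosome at a fixed bin resolution. Only strictly positive values are
#' kept; absent entries are implicit zeros. Bins are 0-based.
#'
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp (default 10000).
#' @param n_bins Number of bins on the chromosome.
#' @param entries A data frame with integer columns `i`, `j` (0-based,
#'   `i <= j`) and a positive numeric column `value`. Lower-triangle input is
#'   mirrored; duplicate keys are summed.
#' @param balanced Logical; `TRUE` when `value` holds matrix-balanced signal
#'   rather than raw counts.
#'
#' @return An object of class `contact_map`: a list with fields `chrom`,
#'   `resolution`, `n_bins`, `entries` (a tibble) and `balanced`.
#' @export
#' @examples
#' cm <- contact_map("chr1", 10000, 5,
#'                   data.frame(i = c(0, 1), j = c(1, 2), value = c(4, 2)))
#' cm$entries
contact_map <- function(chrom, resolution, n_bins, entries, balanced = FALSE) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  assert_scalar_number(resolution, "resolution", lower = 1)
  assert_scalar_number(n_bins, "n_bins", lower = 1)
  entries <- tibble::as_tibble(entries)
  if (!all(c("i", "j", "value") %in% names(entries))) {
    stop("`entries` needs columns i, j, value", call. = FALSE)
  }
  if (nrow(entries) > 0) {
    if (any(entries$value < 0)) stop("contact values must be non-negative", call. = FALSE)
    ii <- pmin(entries$i, entries$j)
    jj <- pmax(entries$i, entries$j)
    entries <- tibble::tibble(i = as.integer(ii), j = as.integer(jj),
                              value = as.numeric(entries$value)) |>
      dplyr::filter(.data$value > 0) |>
      dplyr::summarise(value = sum(.data$value), .by = c("i", "j")) |>
      dplyr::arrange(.data$i, .data$j)
    if (nrow(entries) > 0 && (min(entries$i) < 0 || max(entries$j) >= n_bins)) {
      stop("entry indices must satisfy 0 <= i <= j < n_bins", call. = FALSE)
    }
  } else {
    entries <- tibble::tibble(i = integer(), j = integer(), value = numeric())
  }
  structure(
    list(chrom = chrom, resolution = as.integer(resolution),
         n_bins = as.integer(n_bins), entries = entries,
         balanced = isTRUE(balanced)),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s: %d bins @ %d bp, %d non-zero pixels (%s)\n",
              x$chrom, x$n_bins, x$resolution, nrow(x$entries),
              if (x$balanced) "balanced" else "raw counts"))
  invisible(x)
}

# Dense symmetric matrix view (used for window building, APA).
dense_matrix <- function(map) {
  m <- matrix(0, map$n_bins, map$n_bins)
  if (nrow(map$entries) > 0) {
    idx1 <- cbind(map$entries$i + 1L, map$entries$j + 1L)
    m[idx1] <- map$entries$value
    m[idx1[, c(2L, 1L), drop = FALSE]] <- map$entries$value
  }
  m
}

#' Construct a per-bin accessibility track
#'
#' Holds the mean accessible-chromatin signal (e.g. ATAC-seq or DNase-seq)
#' per fixed-width genomic bin for one chromosome.
#'
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @param values Non-negative numeric vector, one mean signal value per bin;
#'   bins without data are exactly 0.
#'
#' @return An object of class `accessibility_track`.
#' @export
accessibility_track <- function(chrom, resolution, values) {
  stopifnot(is.character(chrom), length(chrom) == 1L, is.numeric(values))
  assert_scalar_number(resolution, "resolution", lower = 1)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("accessibility values must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(chrom = chrom, resolution = as.integer(resolution),
         values = as.numeric(values)),
    class = "accessibility_track"
  )
}

#' @export
print.accessibility_track <- function(x, ...) {
  cat(sprintf("<accessibility_track> %s: %d bins @ %d bp, mean signal %.3g\n",
              x$chrom, length(x$values), x$resolution, mean(x$values)))
  invisible(x)
}
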