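#' Read an intra-chromosomal contact matrix
#'
#' Reads either a cool-dialect HDF5 container (`.cool`, `.h5`) or a
#' plain-text sparse-triplet file (whitespace-separated `i j value`, or
#' `chrom i j value` for multi-chromosome files). Lower-triangle entries are
#' mirrored to `(min, max)` order and duplicate mirrored keys are summed.
#'
#' @param path Path to the file.
#' @param chrom Chromosome to extract. Ignored for 3-column triplet files.
#' @param resolution Expected bin size in bp; for cool input a mismatch with
#'   the stored bin size is an error.
#' @param n_bins Number of bins; inferred (`max(j) + 1` for triplet input,
#'   chromosome length for cool input) when `NULL`.
#' @param use_balanced When `TRUE`, values are multiplied by per-bin
#'   balancing weights (the `weight` column of a cool container, or the
#'   `weights` argument for triplet input); pixels with undefined weights are
#'   dropped.
#' @param weights Optional numeric vector of per-bin balancing weights for
#'   triplet input.
#'
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, chrom = NULL, resolution = 10000,
                             n_bins = NULL, use_balanced = FALSE,
                             weights = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(cool|h5|hdf5)$", path, ignore.case = TRUE)) {
    read_cool(path, chrom = chrom, resolution = resolution,
              use_balanced = use_balanced)
  } else {
    read_triplet(path, chrom = chrom, resolution = resolution,
                 n_bins = n_bins, use_balanced = use_balanced,
                 weights = weights)
  }
}

read_triplet <- function(path, chrom, resolution, n_bins, use_balanced,
                         weights) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 4L) {
    names(df) <- c("chrom", "i", "j", "value")
    if (is.null(chrom)) stop("multi-chromosome triplet file: `chrom` is required",
                             call. = FALSE)
    if (!chrom %in% df$chrom) {
      stop(sprintf("chromosome '%s' not present in %s", chrom, path), call. = FALSE)
    }
    df <- df[df$chrom == chrom, c("i", "j", "value")]
  } else if (ncol(df) == 3L) {
    names(df) <- c("i", "j", "value")
  } else {
    stop("triplet file must have 3 (i j value) or 4 (chrom i j value) columns",
         call. = FALSE)
  }
  if (any(df$value < 0)) stop("negative contact values in ", path, call. = FALSE)
  n_bins <- n_bins %||% (max(df$j, df$i) + 1L)
  if (use_balanced) {
    if (is.null(weights)) {
      stop("use_balanced = TRUE requires per-bin `weights` for triplet input",
           call. = FALSE)
    }
    w1 <- weights[pmin(df$i, df$j) + 1L]
    w2 <- weights[pmax(df$i, df$j) + 1L]
    df$value <- df$value * w1 * w2
    df <- df[is.finite(df$value), , drop = FALSE]
  }
  contact_map(chrom %||% "chr?", resolution, n_bins, df,
              balanced = use_balanced)
}

read_cool <- function(path, chrom, resolution, use_balanced) {
  if (is.null(chrom)) stop("`chrom` is required for cool input", call. = FALSE)
  root <- rhdf5::h5ls(path, recursive = 1)$name
  attrs <- rhdf5::h5readAttributes(path, "/")
  stored_res <- as.numeric(attrs[["bin-size"]] %||% NA)
  chrom_names <- as.character(rhdf5::h5read(path, "chroms/name"))
  chrom_len <- as.numeric(rhdf5::h5read(path, "chroms/length"))
  if (!chrom %in% chrom_names) {
    stop(sprintf("chromosome '%s' not present in %s", chrom, path), call. = FALSE)
  }
  bins_chrom <- as.integer(rhdf5::h5read(path, "bins/chrom"))
  bins_start <- as.numeric(rhdf5::h5read(path, "bins/start"))
  if (is.na(stored_res)) stored_res <- stats::median(diff(bins_start[bins_chrom == bins_chrom[1]]))
  if (!isTRUE(all.equal(stored_res, resolution))) {
    stop(sprintf("resolution mismatch: requested %d, container stores %g",
                 as.integer(resolution), stored_res), call. = FALSE)
  }
  ci <- match(chrom, chrom_names) - 1L  # bins/chrom holds 0-based chrom codes
  sel <- which(bins_chrom == ci)
  offset <- sel[1] - 1L                 # 0-based global index of first bin
  nb <- length(sel)
  b1 <- as.numeric(rhdf5::h5read(path, "pixels/bin1_id"))
  b2 <- as.numeric(rhdf5::h5read(path, "pixels/bin2_id"))
  cnt <- as.numeric(rhdf5::h5read(path, "pixels/count"))
  keep <- b1 >= offset & b1 < offset + nb & b2 >= offset & b2 < offset + nb
  df <- data.frame(i = b1[keep] - offset, j = b2[keep] - offset,
                   value = cnt[keep])
  if (use_balanced) {
    if (!"weight" %in% rhdf5::h5ls(path)$name) {
      stop("use_balanced = TRUE but the container has no bins/weight table",
           call. = FALSE)
    }
    w <- as.numeric(rhdf5::h5read(path, "bins/weight"))[sel]
    df$value <- df$value * w[df$i + 1L] * w[df$j + 1L]
    df <- df[is.finite(df$value), , drop = FALSE]
  }
  contact_map(chrom, resolution, nb, df, balanced = use_balanced)
}

#' Write contact maps to a cool-dialect HDF5 container
#'
#' Writes a minimal single-resolution cooler layout (`chroms`, `bins`,
#' `pixels` tables plus a `bin-size` root attribute) readable by
#' [read_contact_map()].
#'
#' @param maps A single [contact_map()] or a list of them (one per
#'   chromosome, raw counts).
#' @param path Output path (`.cool`).
#' @param weights Optional list (parallel to `maps`) of per-bin balancing
#'   weight vectors stored as `bins/weight`.
#' @return The path, invisibly.
#' @export
write_cool <- function(maps, path, weights = NULL) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  res <- maps[[1]]$resolution
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "chroms")
  rhdf5::h5createGroup(path, "bins")
  rhdf5::h5createGroup(path, "pixels")
  rhdf5::h5write(vapply(maps, function(m) m$chrom, ""), path, "chroms/name")
  rhdf5::h5write(vapply(maps, function(m) m$n_bins * res, 0), path, "chroms/length")
  bins_chrom <- integer(0); bins_start <- numeric(0); bins_end <- numeric(0)
  b1 <- numeric(0); b2 <- numeric(0); cnt <- numeric(0)
  offset <- 0L
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    stopifnot(m$resolution == res)
    bins_chrom <- c(bins_chrom, rep.int(k - 1L, m$n_bins))
    s <- (seq_len(m$n_bins) - 1) * res
    bins_start <- c(bins_start, s)
    bins_end <- c(bins_end, pmin(s + res, m$n_bins * res))
    b1 <- c(b1, m$entries$i + offset)
    b2 <- c(b2, m$entries$j + offset)
    cnt <- c(cnt, m$entries$value)
    offset <- offset + m$n_bins
  }
  rhdf5::h5write(as.integer(bins_chrom), path, "bins/chrom")
  rhdf5::h5write(bins_start, path, "bins/start")
  rhdf5::h5write(bins_end, path, "bins/end")
  if (!is.null(weights)) {
    rhdf5::h5write(unlist(weights), path, "bins/weight")
  }
  ord <- order(b1, b2)
  rhdf5::h5write(b1[ord], path, "pixels/bin1_id")
  rhdf5::h5write(b2[ord], path, "pixels/bin2_id")
  rhdf5::h5write(cnt[ord], path, "pixels/count")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("HDF5::Cooler", fid, "format")
  rhdf5::h5writeAttribute(as.integer(res), fid, "bin-size")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Write a contact map as sparse-triplet text
#'
#' @param map A [contact_map()].
#' @param path Output path; one `i j value` line per non-zero pixel.
#' @return The path, invisibly.
#' @export
write_contact_map <- function(map, path) {
  e <- map$entries
  val <- if (all(e$value == round(e$value))) format(e$value, scientific = FALSE, trim = TRUE)
         else sprintf("%.10g", e$value)
  writeLines(paste(e$i, e$j, val), path)
  invisible(path)
}

#' Read a binned accessibility track from bedGraph or bigWig
#'
#' Interval signal is averaged into fixed-width bins: each bin value is the
#' coverage-weighted mean of the signal over `[b * resolution,
#' (b + 1) * resolution)`, with uncovered base pairs contributing 0 (the mean
#' is taken over the full bin width). Intervals extending beyond
#' `n_bins * resolution` are truncated with a warning.
#'
#' @param path bedGraph (`.bedGraph`, `.bg`) or bigWig (`.bw`, `.bigWig`) file.
#' @param chrom Chromosome to extract.
#' @param resolution Bin size in bp.
#' @param n_bins Number of bins (must match the companion contact map).
#' @return An [accessibility_track()] of length `n_bins`.
#' @export
read_accessibility <- function(path, chrom, resolution = 10000, n_bins) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) "bedGraph" else NULL
  gr <- if (is.null(fmt)) rtracklayer::import(path) else rtracklayer::import(path, format = fmt)
  gr <- gr[GenomicRanges::seqnames(gr) == chrom]
  if (length(gr) > 0 && any(S4Vectors::mcols(gr)$score < 0)) {
    stop("negative signal values in ", path, call. = FALSE)
  }
  total_bp <- n_bins * resolution
  if (length(gr) > 0 && any(GenomicRanges::end(gr) > total_bp)) {
    n_tr <- sum(GenomicRanges::end(gr) > total_bp)
    warning(sprintf("%d interval(s) extend beyond %d bp and were truncated",
                    n_tr, total_bp), call. = FALSE)
    gr <- gr[GenomicRanges::start(gr) <= total_bp]
    GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), total_bp)
  }
  vals <- numeric(n_bins)
  if (length(gr) > 0) {
    cov <- GenomicRanges::coverage(gr, weight = "score")[[chrom]]
    if (length(cov) < total_bp) {
      cov <- c(cov, S4Vectors::Rle(0, total_bp - length(cov)))
    }
    v <- IRanges::Views(cov, start = seq(1, total_bp, by = resolution),
                        width = resolution)
    vals <- as.numeric(IRanges::viewSums(v)) / resolution
  }
  accessibility_track(chrom, resolution, vals)
}

#' Read interactions from a BEDPE file
#'
#' Keeps intra-chromosomal rows, maps each anchor to the bin containing its
#' interval midpoint (a midpoint exactly on a bin boundary goes to the left
#' bin), and orders anchors so `bin1 < bin2`. Rows whose anchors fall in the
#' same bin are dropped with a message.
#'
#' @param path Six(+)-column BEDPE file; column 7, when numeric, is read as a
#'   probability.
#' @param resolution Bin size in bp.
#' @return A tibble with columns `chrom`, `bin1`, `bin2` and optionally
#'   `probability`, plus attributes `n_interchrom` and `n_samebin` with the
#'   dropped-row counts.
#' @export
read_interactions <- function(path, resolution = 10000) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 0L) < 6L)
  if (length(bad) > 0) {
    stop(sprintf("malformed BEDPE row at line %d (fewer than 6 columns)",
                 line_no[bad[1]]), call. = FALSE)
  }
  f <- function(k) vapply(parts, `[[`, "", k)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(f(k)))
    if (anyNA(v)) {
      stop(sprintf("malformed BEDPE row at line %d (non-numeric coordinate)",
                   line_no[which(is.na(v))[1]]), call. = FALSE)
    }
    v
  }
  df <- tibble::tibble(chrom1 = f(1), s1 = num(2), e1 = num(3),
                       chrom2 = f(4), s2 = num(5), e2 = num(6))
  prob <- if (all(vapply(parts, length, 0L) >= 7L)) {
    suppressWarnings(as.numeric(f(7)))
  } else NULL
  inter <- df$chrom1 != df$chrom2
  n_inter <- sum(inter)
  df <- df[!inter, ]
  if (!is.null(prob)) prob <- prob[!inter]
  bin_of <- function(s, e) {
    mid <- (s + e) / 2
    b <- floor(mid / resolution)
    ifelse(mid %% resolution == 0 & mid > 0, b - 1, b)
  }
  b1 <- bin_of(df$s1, df$e1)
  b2 <- bin_of(df$s2, df$e2)
  same <- b1 == b2
  n_same <- sum(same)
  if (n_same > 0) message(n_same, " interaction(s) dropped: anchors share a bin")
  out <- tibble::tibble(chrom = df$chrom1,
                        bin1 = as.integer(pmin(b1, b2)),
                        bin2 = as.integer(pmax(b1, b2)))
  if (!is.null(prob) && !anyNA(prob)) out$probability <- prob
  out <- out[!same, , drop = FALSE]
  attr(out, "n_interchrom") <- n_inter
  attr(out, "n_samebin") <- n_same
  out
}

#' Write loop calls as BEDPE
#'
#' Anchor intervals are 0-based half-open, `[bin * resolution,
#' (bin + 1) * resolution)`; a seventh column carries the call probability.
#' Rows are sorted by `(chrom, bin1, bin2)`.
#'
#' @param loops Tibble with `chrom`, `bin1`, `bin2` and `probability`.
#' @param resolution Bin size in bp.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_loops <- function(loops, resolution, path) {
  loops <- dplyr::arrange(loops, .data$chrom, .data$bin1, .data$bin2)
  if (nrow(loops) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  prob <- loops[["probability"]] %||% rep(NA_real_, nrow(loops))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                   loops$chrom,
                   loops$bin1 * resolution, (loops$bin1 + 1) * resolution,
                   loops$chrom,
                   loops$bin2 * resolution, (loops$bin2 + 1) * resolution,
                   sprintf("%.6g", prob))
  writeLines(lines, path)
  invisible(path)
}
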