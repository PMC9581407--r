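#' Parameters for the synthetic Hi-C study generator
#'
#' The generator emulates the structure of a real 10 kb-resolution study:
#' a contact background whose mean decays with genomic distance as a power
#' law, `mu(d) = c * (d + 1)^(-alpha)`, with Poisson counting noise; planted
#' loops that multiply the background by up to `loop_strength` under a
#' Gaussian spatial kernel; an accessibility track with Gaussian peaks at
#' the loop anchors over a noisy baseline; and a BEDPE truth set.
#'
#' @param n_chroms Number of chromosomes (default 3).
#' @param n_bins Bins per chromosome (default 2000).
#' @param resolution Bin size in bp (default 10000).
#' @param decay_amplitude `c` in `mu(d)` (default 300, emulating a deeply
#'   sequenced map, hundreds of counts per near-diagonal pixel at 10 kb).
#' @param decay_exponent `alpha > 0` (default 0.75, the shallow decay
#'   typical of sub-megabase, intra-domain contacts).
#' @param max_sim_dist Largest simulated diagonal in bins (default 40, so
#'   every scorable pixel lies within the distance range spanned by the
#'   planted loops and their distance-matched negatives).
#' @param n_loops Planted loops per chromosome (default 30).
#' @param loop_strength Peak background multiplier `s >= 1` (default 5).
#' @param loop_sigma Gaussian kernel width in bins (default 1).
#' @param loop_min_dist,loop_max_dist Loop anchor separation range in bins
#'   (defaults 3 and 35, i.e. 30-350 kb; separations are drawn with
#'   probability proportional to `1/d`, so most planted loops are
#'   short-range as in experimentally supported loop sets, and the planted
#'   distances span the caller's candidate space so the negative sampler
#'   can cover it).
#' @param loop_min_sep Minimum pairwise Chebyshev separation between loop
#'   centres in bins (default 6; the array layout always exceeds it).
#' @param acc_baseline,acc_peak,acc_width,acc_noise Accessibility baseline
#'   level, anchor peak height, peak width in bins, and half-normal noise
#'   scale (defaults 1, 5, 1, 0.5).
#' @param acc_decoy_every Mean spacing (bins) of non-anchor "decoy"
#'   accessibility peaks (default 6; 0 disables). Real accessible-chromatin
#'   tracks carry peaks at many sites besides loop anchors, so accessibility
#'   alone must not identify a loop.
#' @param seed Master seed; per-chromosome streams are derived from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_chroms = 3, n_bins = 2000, resolution = 10000,
                       decay_amplitude = 300, decay_exponent = 0.75,
                       max_sim_dist = 40, n_loops = 30, loop_strength = 5,
                       loop_sigma = 1, loop_min_dist = 3, loop_max_dist = 35,
                       loop_min_sep = 6, acc_baseline = 1, acc_peak = 5,
                       acc_width = 1, acc_noise = 0.5, acc_decoy_every = 0,
                       seed = 1) {
  assert_scalar_number(decay_amplitude, "decay_amplitude", lower = 1e-12)
  assert_scalar_number(decay_exponent, "decay_exponent", lower = 1e-12)
  assert_scalar_number(loop_strength, "loop_strength", lower = 1)
  assert_scalar_number(loop_sigma, "loop_sigma", lower = 1e-12)
  if (loop_min_dist > loop_max_dist) stop("loop_min_dist > loop_max_dist", call. = FALSE)
  structure(as.list(environment()), class = "sim_params")
}

sim_chrom_name <- function(idx) paste0("chr", idx)

# derived per-chromosome seed, kept within 32-bit integer range
sub_seed <- function(seed, idx, salt = 0L) {
  (as.double(seed) * 1009 + idx * 7919 + salt * 104729) %% 2147483647
}

#' Simulate one chromosome's contact map and truth loops
#'
#' Entry values at distance `d <= max_sim_dist` are Poisson draws with mean
#' `mu(d) * (1 + (s - 1) * G)`, where `G` is a unit-peak Gaussian kernel
#' around the nearest planted loop centre; zero draws are not stored. Loop
#' centres are placed with windows in bounds and pairwise Chebyshev
#' separation of at least `loop_min_sep` bins.
#'
#' @param p A [sim_params()].
#' @param chrom_idx Chromosome index in `1:n_chroms`.
#' @return A list: `map` (a [contact_map()] of raw counts) and `truth`
#'   (tibble `chrom`, `bin1`, `bin2`).
#' @export
simulate_contact_map <- function(p, chrom_idx = 1) {
  stopifnot(inherits(p, "sim_params"))
  chrom <- sim_chrom_name(chrom_idx)
  n <- p$n_bins
  margin <- 15L  # room for 23-bin windows and APA flanks
  with_seed(sub_seed(p$seed, chrom_idx), {
    # Loop placement: an ordered array of non-overlapping loops. Anchor
    # separations are short-range-heavy (p(d) ~ 1/d), matching the distance
    # profiles of experimentally supported loop sets, and consecutive loops
    # are separated by more than the maximum simulated contact distance so
    # that anchors of different loops never form a contacting (candidate)
    # pixel pair — in real data such pairs are themselves loop candidates,
    # which a 30-loop truth set cannot represent.
    if (p$n_loops > 0) {
      drange <- p$loop_min_dist:p$loop_max_dist
      d <- if (length(drange) == 1) rep(drange, p$n_loops) else
        sample(drange, p$n_loops, replace = TRUE, prob = 1 / drange)
      gap_min <- p$max_sim_dist + 1L
      need <- sum(d) + (p$n_loops - 1L) * gap_min + 2L * margin
      if (need > n) {
        stop("loop placement infeasible: chromosome too short for ",
             p$n_loops, " loops with the required separation", call. = FALSE)
      }
      # distribute the remaining slack as random extra gaps
      extra <- tabulate(sample.int(p$n_loops, n - need, replace = TRUE),
                        nbins = p$n_loops)
      a <- integer(p$n_loops)
      at <- margin
      for (k in seq_len(p$n_loops)) {
        at <- at + extra[k]
        a[k] <- at
        at <- a[k] + d[k] + gap_min
      }
    } else {
      a <- integer(0)
      d <- integer(0)
    }
    truth <- tibble::tibble(chrom = rep(chrom, length(a)), bin1 = a,
                            bin2 = as.integer(a + d)) |>
      dplyr::arrange(.data$bin1, .data$bin2)

    # enhancement factors near loop centres (max over loops of the kernel)
    reach <- ceiling(4 * p$loop_sigma)
    enh <- matrix(1, n, p$max_sim_dist + 1L)
    for (k in seq_len(nrow(truth))) {
      ci <- truth$bin1[k]; cj <- truth$bin2[k]
      for (di in -reach:reach) {
        r <- ci + di
        if (r < 0 || r >= n) next
        for (dj in -reach:reach) {
          cc <- cj + dj
          d <- cc - r
          if (d < 0 || d > p$max_sim_dist || cc >= n) next
          g <- exp(-(di^2 + dj^2) / (2 * p$loop_sigma^2))
          val <- 1 + (p$loop_strength - 1) * g
          if (val > enh[r + 1L, d + 1L]) enh[r + 1L, d + 1L] <- val
        }
      }
    }

    entries <- vector("list", p$max_sim_dist + 1L)
    for (d in 0:p$max_sim_dist) {
      m <- n - d
      if (m <= 0) break
      lam <- p$decay_amplitude * (d + 1)^(-p$decay_exponent) * enh[seq_len(m), d + 1L]
      v <- stats::rpois(m, lam)
      nz <- which(v > 0)
      if (length(nz) > 0) {
        entries[[d + 1L]] <- tibble::tibble(i = nz - 1L, j = nz - 1L + d,
                                            value = as.numeric(v[nz]))
      }
    }
    map <- contact_map(chrom, p$resolution, n, dplyr::bind_rows(entries))
    list(map = map, truth = truth)
  })
}

#' Simulate an accessibility track peaked at loop anchors
#'
#' `values = baseline + peak * Gaussian bumps at every anchor bin and at
#' uniformly placed non-anchor decoy bins + half-normal noise`; all values
#' are non-negative and the draw is deterministic given the master seed and
#' chromosome index. Decoy peaks emulate the many accessible sites of real
#' ATAC/DNase tracks that are not loop anchors, so that accessibility alone
#' cannot identify a loop.
#'
#' @param p A [sim_params()].
#' @param truth Truth tibble from [simulate_contact_map()].
#' @param chrom_idx Chromosome index.
#' @return An [accessibility_track()].
#' @export
simulate_accessibility <- function(p, truth, chrom_idx = 1) {
  stopifnot(inherits(p, "sim_params"))
  n <- p$n_bins
  with_seed(sub_seed(p$seed, chrom_idx, salt = 1L), {
    vals <- rep(p$acc_baseline, n)
    anchors <- unique(c(truth$bin1, truth$bin2))
    decoys <- integer(0)
    if (p$acc_decoy_every > 0) {
      n_decoy <- round(n / p$acc_decoy_every)
      decoys <- sample(setdiff(0:(n - 1), anchors), n_decoy)
    }
    reach <- ceiling(4 * p$acc_width)
    sites <- c(anchors, decoys)
    # peak heights vary several-fold, as in real ATAC/DNase tracks
    heights <- p$acc_peak * stats::runif(length(sites), 0.5, 1.5)
    for (k in seq_along(sites)) {
      a <- sites[k]
      idx <- max(0, a - reach):min(n - 1, a + reach)
      vals[idx + 1] <- vals[idx + 1] +
        heights[k] * exp(-(idx - a)^2 / (2 * p$acc_width^2))
    }
    vals <- vals + abs(stats::rnorm(n, 0, p$acc_noise))
    accessibility_track(sim_chrom_name(chrom_idx), p$resolution, vals)
  })
}

#' Simulate a full study bundle
#'
#' Generates every chromosome's contact map, accessibility track and truth
#' loops; when `out_dir` is given, writes sparse-triplet text and a
#' cool-dialect container for the maps, a bedGraph per chromosome, the
#' combined truth BEDPE and a JSON manifest of all parameters.
#'
#' @param p A [sim_params()].
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @return A list: `maps`, `tracks`, `truth` (per-chromosome lists /
#'   combined tibble) and `paths` (named file paths, when written).
#' @export
simulate_study <- function(p, out_dir = NULL) {
  stopifnot(inherits(p, "sim_params"))
  sims <- lapply(seq_len(p$n_chroms), function(k) simulate_contact_map(p, k))
  maps <- lapply(sims, `[[`, "map")
  truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  tracks <- lapply(seq_len(p$n_chroms), function(k) {
    simulate_accessibility(p, sims[[k]]$truth, k)
  })
  names(maps) <- names(tracks) <- vapply(maps, `[[`, "", "chrom")
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (nm in names(maps)) {
      f <- file.path(out_dir, paste0(nm, ".triplet.txt"))
      write_contact_map(maps[[nm]], f)
      paths[[paste0("triplet_", nm)]] <- f
      bg <- file.path(out_dir, paste0(nm, ".bedGraph"))
      tr <- tracks[[nm]]
      starts <- (seq_along(tr$values) - 1) * tr$resolution
      writeLines(sprintf("%s\t%d\t%d\t%.10g", nm, starts,
                         starts + tr$resolution, tr$values), bg)
      paths[[paste0("bedgraph_", nm)]] <- bg
    }
    cool <- file.path(out_dir, "study.cool")
    write_cool(maps, cool)
    paths$cool <- cool
    bedpe <- file.path(out_dir, "truth.bedpe")
    write_loops(truth, p$resolution, bedpe)
    paths$truth <- bedpe
    manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(unclass(p), manifest, auto_unbox = TRUE, digits = NA)
    paths$manifest <- manifest
  }
  list(maps = maps, tracks = tracks, truth = truth, paths = paths)
}
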