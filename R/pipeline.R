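#' Run the full simulated-study pipeline
#'
#' One call reproduces the package's end-to-end experiment on a synthetic
#' study: simulate contact maps, accessibility tracks and truth loops;
#' build labeled two-channel datasets; train the classifier under a
#' leave-one-chromosome-out protocol (the held-out test chromosome is
#' never seen in training; with fewer than two remaining chromosomes the
#' validation set is a held-out 20% window split, since a chromosome-level
#' validation set requires at least two non-test chromosomes); calibrate
#' the probability threshold on the training chromosomes against their own
#' training interactions; and call loops genome-wide.
#'
#' @param p A [sim_params()].
#' @param test_chrom Held-out chromosome (default the last).
#' @param mc A [model_config()]; the default fixture-scale configuration
#'   uses 4/8/16 conv filters.
#' @param tc A [train_config()]; the default fixture-scale configuration
#'   uses batch size 8 and an 800-epoch budget with patience 150, giving
#'   the small fixture datasets an optimizer-step count comparable to
#'   full-scale training at batch 128.
#' @param data_seed Seed base for negative sampling (per-chromosome seeds
#'   are `data_seed + chromosome index`).
#' @param split_seed Seed for the window-level validation split.
#' @param calibrate Logical; when `FALSE`, calls use `threshold = 0.5`.
#' @param quiet Suppress stage messages.
#' @return A list with `study`, `datasets`, `split`, `model`,
#'   `val_metrics`, `test_metrics`, `threshold`, `calibration`, `calls`
#'   (all chromosomes, bin pairs as `bin1`/`bin2`) and `call_metrics`
#'   (precision/recall/F1 of the calls against the full truth set under
#'   tolerant matching at one bin resolution).
#' @export
run_study_pipeline <- function(p = sim_params(),
                               test_chrom = NULL,
                               mc = model_config(filters = c(4, 8, 16), seed = 7),
                               tc = train_config(batch_size = 8,
                                                max_epochs = 800,
                                                patience = 150, seed = 13),
                               data_seed = 100, split_seed = 41,
                               calibrate = TRUE, quiet = FALSE) {
  study <- simulate_study(p)
  chroms <- names(study$maps)
  test_chrom <- test_chrom %||% chroms[length(chroms)]
  datasets <- lapply(seq_along(chroms), function(k) {
    ch <- chroms[k]
    pos <- dplyr::filter(study$truth, .data$chrom == ch)
    build_dataset(study$maps[[ch]], study$tracks[[ch]], pos,
                  far_fraction = 0.2, seed = data_seed + k,
                  max_dist = p$max_sim_dist)
  })
  names(datasets) <- chroms

  rest <- setdiff(chroms, test_chrom)
  if (length(rest) >= 5) {
    sp <- loco_split(chroms, test_chrom, val_fraction = tc$val_fraction,
                     seed = split_seed)
    train_ds <- bind_datasets(datasets[sp$train])
    val_ds <- bind_datasets(datasets[sp$validation])
    split <- sp
  } else {
    pooled <- bind_datasets(datasets[rest])
    n <- length(pooled$label)
    idx <- with_seed(split_seed, sample(n))
    n_val <- max(1L, round(tc$val_fraction * n))
    val_ds <- dataset_subset(pooled, idx[seq_len(n_val)])
    train_ds <- dataset_subset(pooled, idx[-seq_len(n_val)])
    split <- list(train = rest, validation = paste0("windows:", n_val),
                  test = test_chrom)
  }

  model <- train_model(init_model(mc), train_ds, val_ds, tc)
  val_metrics <- classification_metrics(val_ds$label, predict(model, val_ds))
  test_ds <- datasets[[test_chrom]]
  test_metrics <- classification_metrics(test_ds$label, predict(model, test_ds))

  calibration <- NULL
  threshold <- 0.5
  if (calibrate) {
    ref <- dplyr::filter(study$truth, .data$chrom %in% rest)
    calibration <- calibrate_threshold(model, study$maps[rest],
                                       study$tracks[rest], ref,
                                       max_dist = p$max_sim_dist)
    threshold <- calibration$threshold
  }
  if (!quiet) message("calling threshold: ", threshold)

  calls <- dplyr::bind_rows(lapply(chroms, function(ch) {
    call_loops(model, study$maps[[ch]], study$tracks[[ch]],
               max_dist = p$max_sim_dist, threshold = threshold,
               quiet = quiet)
  }))
  calls <- dplyr::rename(calls, bin1 = "i", bin2 = "j")
  mm <- match_loops(calls, study$truth, mode = "tolerant",
                    tol = p$resolution, resolution = p$resolution)
  precision <- if (nrow(calls) > 0) mm$n_matched_a / nrow(calls) else 0
  recall <- mm$n_matched_b / nrow(study$truth)
  call_metrics <- tibble::tibble(
    n_calls = nrow(calls), n_truth = nrow(study$truth),
    precision = precision, recall = recall,
    f1 = if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0)

  list(study = study, datasets = datasets, split = split, model = model,
       val_metrics = val_metrics, test_metrics = test_metrics,
       threshold = threshold, calibration = calibration,
       calls = calls, call_metrics = call_metrics)
}

#' Downsampling-robustness experiment
#'
#' Binomially downsamples every raw contact map of a completed pipeline
#' run, re-scores it with the same trained model and calling threshold,
#' and reports the concordance: the fraction of downsampled-map calls that
#' tolerantly match a full-map call.
#'
#' @param pipe Result of [run_study_pipeline()].
#' @param p The [sim_params()] used for the run.
#' @param fraction Binomial retention probability (default 0.5).
#' @param seed Seed for the binomial draws.
#' @param quiet Suppress stage messages.
#' @return A list: `calls` (downsampled-map calls), `concordance`,
#'   `n_full`, `n_down`.
#' @export
downsampling_concordance <- function(pipe, p, fraction = 0.5, seed = 7,
                                     quiet = TRUE) {
  chroms <- names(pipe$study$maps)
  down_calls <- dplyr::bind_rows(lapply(seq_along(chroms), function(k) {
    ch <- chroms[k]
    dmap <- downsample_map(pipe$study$maps[[ch]], fraction, seed = seed + k)
    call_loops(pipe$model, dmap, pipe$study$tracks[[ch]],
               max_dist = p$max_sim_dist, threshold = pipe$threshold,
               quiet = quiet)
  }))
  down_calls <- dplyr::rename(down_calls, bin1 = "i", bin2 = "j")
  mm <- match_loops(down_calls, pipe$calls, mode = "tolerant",
                    tol = p$resolution, resolution = p$resolution)
  list(calls = down_calls,
       concordance = if (nrow(down_calls) > 0) mm$n_matched_a / nrow(down_calls) else 0,
       n_full = nrow(pipe$calls), n_down = nrow(down_calls))
}
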