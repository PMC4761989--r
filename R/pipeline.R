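# End-to-end orchestration: denoise -> layers -> features -> classify ->
# seeds -> brightness transform -> graph cut -> morphology -> evaluation.

#' Default pipeline configuration
#'
#' @param output_dir directory for per-volume outputs (`NULL` = keep in
#'   memory only).
#' @param denoise [diffusion_params] (K on the 0..255 grey scale).
#' @param layers [layer_params].
#' @param weights [energy_weights].
#' @param c_fg,c_bg,c_recon,c_close adaptive structuring-element
#'   coefficients for seeds and refinement.
#' @param brightness_targets anchors of [brightness_transform].
#' @param seed global RNG seed recorded in the run manifest.
#' @export
pipeline_config <- function(output_dir = NULL,
                            denoise = diffusion_params(K = 25, iterations = 5),
                            layers = layer_params(),
                            weights = energy_weights(),
                            c_fg = 0.143, c_bg = 1.143,
                            c_recon = 0.200, c_close = 0.700,
                            brightness_targets = c(bg = 30, rpe = 200),
                            seed = 1L) {
  list(output_dir = output_dir, denoise = denoise, layers = layers,
       weights = weights, c_fg = c_fg, c_bg = c_bg,
       c_recon = c_recon, c_close = c_close,
       brightness_targets = brightness_targets, seed = as.integer(seed))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[pedseg %s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full segmentation pipeline on one volume
#'
#' @param volume [oct_volume] (raw intensities, 0..255).
#' @param clf trained `strong_classifier` ([ada_train]); `NULL` skips the
#'   false-positive filter (the initial mask is used as the refined mask).
#' @param config [pipeline_config].
#' @param truth optional truth list (as from [generate_phantom]) with
#'   `ped_mask` and `retina_mask`; adds metrics to the result.
#' @param volume_id identifier used in outputs.
#' @param verbose log stage progress to stderr.
#' @return list with `surfaces` (ILM, EZ_ROOF, RPE_FLOOR, BM),
#'   `initial_mask`, `refined_mask`, `final_mask`, `features`, and — with
#'   truth — `metrics` ([compute_metrics]).
#' @export
run_pipeline <- function(volume, clf = NULL, config = pipeline_config(),
                         truth = NULL, volume_id = "vol", verbose = FALSE) {
  stopifnot(inherits(volume, "oct_volume"))
  nz <- dim(volume$intensities)[3]
  log_stage(verbose, "%s: denoise", volume_id)
  den <- mcde_filter(volume, config$denoise)
  log_stage(verbose, "%s: layer segmentation", volume_id)
  surfaces <- segment_layers(den, config$layers)
  surfaces$BM <- estimate_bm(surfaces$RPE_FLOOR)
  initial <- initial_ped_mask(surfaces$RPE_FLOOR, surfaces$BM, nz)
  log_stage(verbose, "%s: features (%d candidate voxels)", volume_id, sum(initial))
  feats <- build_feature_table(den, initial, surfaces,
                               truth = if (!is.null(truth)) truth$ped_mask,
                               volume_id = volume_id)
  if (!is.null(clf) && nrow(feats) > 0) {
    refined <- filter_regions(initial, attr(feats, "regions"), feats, clf)
  } else refined <- initial
  log_stage(verbose, "%s: graph cut (%d refined voxels)", volume_id, sum(refined))
  if (any(refined)) {
    bt <- brightness_transform(den, surfaces, config$brightness_targets)
    seeds <- make_seeds(refined, config$c_fg, config$c_bg)
    prior <- build_shape_prior(refined)
    cut <- graph_cut(bt, seeds, prior, config$weights)
    final <- postprocess_mask(cut, config$c_recon, config$c_close)
  } else {
    cut <- refined
    final <- refined
  }
  out <- list(volume_id = volume_id, surfaces = surfaces,
              initial_mask = initial, refined_mask = refined,
              cut_mask = cut, final_mask = final, features = feats)
  if (!is.null(truth)) {
    out$metrics <- compute_metrics(final, truth$ped_mask, truth$retina_mask)
    out$initial_metrics <- compute_metrics(initial, truth$ped_mask, truth$retina_mask)
  }
  if (!is.null(config$output_dir)) persist_outputs(out, volume, config)
  out
}

persist_outputs <- function(res, volume, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  pfx <- file.path(config$output_dir, res$volume_id)
  write_surfaces(res$surfaces, paste0(pfx, "_surfaces.csv"))
  write_mask(res$initial_mask, paste0(pfx, "_initial.tif"))
  write_mask(res$refined_mask, paste0(pfx, "_refined.tif"))
  write_mask(res$final_mask, paste0(pfx, "_final.tif"))
  if (nrow(res$features) > 0)
    write.csv(res$features, paste0(pfx, "_features.csv"), row.names = FALSE)
  manifest <- list(volume_id = res$volume_id, seed = config$seed,
                   package_version = as.character(utils::packageVersion("pedseg")),
                   parameters = list(denoise = config$denoise,
                                     layers = config$layers[setdiff(names(config$layers), "")],
                                     weights = config$weights,
                                     se_coefficients = c(fg = config$c_fg, bg = config$c_bg,
                                                         recon = config$c_recon, close = config$c_close)))
  write_config(manifest, paste0(pfx, "_manifest.json"))
  invisible(NULL)
}

#' Train the false-positive classifier on volumes with truth masks
#'
#' Runs denoising, layer segmentation and feature extraction on each
#' training volume, labels candidate regions against the truth PED masks
#' ([make_labels]) and trains AdaBoost.
#'
#' @param volumes list of [oct_volume].
#' @param truths list of truth lists (with `ped_mask`), aligned with
#'   `volumes`.
#' @param config [pipeline_config].
#' @param rounds boosting rounds.
#' @param verbose log progress.
#' @return `strong_classifier` with attribute `"training_table"`.
#' @export
train_pipeline <- function(volumes, truths, config = pipeline_config(),
                           rounds = 50L, verbose = FALSE) {
  stopifnot(length(volumes) == length(truths))
  tabs <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    log_stage(verbose, "training volume %d/%d", i, length(volumes))
    den <- mcde_filter(volumes[[i]], config$denoise)
    surfaces <- segment_layers(den, config$layers)
    surfaces$BM <- estimate_bm(surfaces$RPE_FLOOR)
    nz <- dim(volumes[[i]]$intensities)[3]
    initial <- initial_ped_mask(surfaces$RPE_FLOOR, surfaces$BM, nz)
    tabs[[i]] <- build_feature_table(den, initial, surfaces,
                                     truth = truths[[i]]$ped_mask,
                                     volume_id = paste0("train", i))
  }
  tab <- do.call(rbind, tabs[vapply(tabs, nrow, integer(1)) > 0])
  clf <- ada_train(tab, rounds = rounds)
  attr(clf, "training_table") <- tab
  clf
}

#' Run a phantom batch experiment
#'
#' Generates seeded phantoms, trains the classifier on a disjoint training
#' batch and segments the test batch, returning per-volume metrics and the
#' aggregate.
#'
#' @param n_train,n_test phantom counts.
#' @param seed experiment seed (training phantoms use `seed + 1000 + i`).
#' @param config [pipeline_config].
#' @param confounder include a confounding fluid pocket in each phantom.
#' @param speckle_scale multiplicative noise level.
#' @param rounds boosting rounds.
#' @param verbose log progress.
#' @return list `classifier`, `results` (per test volume), `metrics`
#'   (data.frame, one row per volume plus the aggregate mean row).
#' @export
phantom_experiment <- function(n_train = 20L, n_test = 10L, seed = 1L,
                               config = pipeline_config(),
                               confounder = TRUE, speckle_scale = 0.25,
                               rounds = 50L, verbose = FALSE) {
  mk <- function(params) {
    ph <- generate_phantom(params)
    vol <- add_speckle(ph$volume, params$speckle$scale, seed = params$seed)
    list(volume = vol, truth = ph$truth)
  }
  tr_par <- sample_phantom_params(n_train, seed = seed + 1000L,
                                  confounder = confounder,
                                  speckle_scale = speckle_scale)
  te_par <- sample_phantom_params(n_test, seed = seed,
                                  confounder = confounder,
                                  speckle_scale = speckle_scale)
  train <- lapply(tr_par, mk)
  clf <- train_pipeline(lapply(train, `[[`, "volume"),
                        lapply(train, `[[`, "truth"),
                        config, rounds = rounds, verbose = verbose)
  results <- vector("list", n_test)
  rows <- vector("list", n_test)
  for (i in seq_len(n_test)) {
    cs <- mk(te_par[[i]])
    res <- run_pipeline(cs$volume, clf, config, truth = cs$truth,
                        volume_id = paste0("phantom", i), verbose = verbose)
    conf_vox <- which(cs$truth$confounder_mask)
    res$confounder_removed <-
      length(conf_vox) == 0 ||
      sum(res$refined_mask[conf_vox]) / length(conf_vox) < 0.2
    results[[i]] <- res
    m <- res$metrics
    rows[[i]] <- data.frame(volume = res$volume_id, tpvf = m$tpvf, fpvf = m$fpvf,
                            dsc = m$dsc, ppv = m$ppv,
                            auto_voxels = sum(res$final_mask),
                            truth_voxels = sum(cs$truth$ped_mask),
                            confounder_removed = res$confounder_removed)
  }
  metrics <- do.call(rbind, rows)
  agg <- data.frame(volume = "mean", tpvf = mean(metrics$tpvf),
                    fpvf = mean(metrics$fpvf), dsc = mean(metrics$dsc),
                    ppv = mean(metrics$ppv),
                    auto_voxels = mean(metrics$auto_voxels),
                    truth_voxels = mean(metrics$truth_voxels),
                    confounder_removed = mean(metrics$confounder_removed))
  list(classifier = clf, results = results, metrics = rbind(metrics, agg))
}
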