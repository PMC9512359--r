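#' Desk-scale cascade architecture
#'
#' Tiny network specifications (base 4 filters) for the three cascade
#' stages, sized for the default 128 x 128 x 64 phantom grid: a depth-2
#' 3-D U-Net for the bladder (the 94-voxel coarse grid admits one
#' in-plane pooling), a depth-3 2-D attention U-Net for span detection and
#' a depth-3 3-D U-Net with dropout 0.2 for block segmentation (the extra
#' level widens the in-plane receptive field enough to tell the anterior
#' bladder margin from the CTV inside the 128 mm window).
#'
#' @return Named list of [network_spec()] objects: `bladder`, `span`,
#'   `block`.
#' @export
cascade_specs_desk <- function() {
  list(bladder = network_spec(dims = 3, depth = 2, base_filters = 4, dropout = 0),
       span = network_spec(dims = 2, depth = 3, base_filters = 4,
                           attention = TRUE, dropout = 0),
       block = network_spec(dims = 3, depth = 3, base_filters = 4, dropout = 0.2))
}

#' Train the full cascade on a phantom dataset
#'
#' Trains the three stage networks separately on their stage-specific
#' samples (see [make_training_samples()]) with the soft-Dice objective,
#' AdaDelta, a seeded 10% validation split and best-vs-final model
#' selection.
#'
#' @param phantoms manifest data.frame or list of phantoms.
#' @param specs stage specifications, as [cascade_specs_desk()].
#' @param epochs named integer vector of epochs per stage.
#' @param span_pos,span_neg CTV-positive / CTV-free slices per phantom for
#'   span training (NULL keeps all slices with augmented positives).
#' @param block_stride SI stride for block sample extraction.
#' @param offset_mm posterior offset for ground-truth ROI centres.
#' @param seed master seed.
#' @param verbose print per-epoch progress.
#' @return List of trained stage models (`bladder`, `span`, `block`) with
#'   attached training histories in `histories`.
#' @export
train_cascade <- function(phantoms, specs = cascade_specs_desk(),
                          epochs = c(bladder = 6L, span = 5L, block = 3L),
                          span_pos = 12L, span_neg = 8L, block_stride = 2L,
                          offset_mm = 39, seed = 1L, verbose = FALSE) {
  models <- list(); histories <- list()
  stages <- c("bladder", "span", "block")
  if (is.data.frame(phantoms)) phantoms <- load_manifest_phantoms(phantoms)
  # preprocess once; the stage samplers detect the marker and skip it
  phantoms <- lapply(phantoms, function(ph) {
    if (is.null(attr(ph$image, "ctv_preprocessed"))) {
      ph$image <- preprocess_volume(ph$image)
      attr(ph$image, "ctv_preprocessed") <- TRUE
    }
    ph
  })
  init_steps <- c(bladder = 0.01, span = 0.01, block = 0.02)
  for (st in stages) {
    samp <- make_training_samples(
      phantoms, stage = st, offset_mm = offset_mm,
      pos_per_phantom = if (st == "span") span_pos else NULL,
      neg_per_phantom = if (st == "span") span_neg else NULL,
      block_stride = block_stride, seed = seed + match(st, stages))
    model <- build_model(specs[[st]], seed = seed + 10L + match(st, stages))
    cfg <- train_config(epochs = epochs[[st]], batch_size = 1L,
                        seed = seed + 20L + match(st, stages),
                        init_step = init_steps[[st]], rho = 0.9,
                        max_step = 0.05)
    fit <- train_model(model, samp, cfg, verbose = verbose)
    models[[st]] <- fit$model
    histories[[st]] <- fit$history
  }
  models$histories <- histories
  models
}

#' Pipeline configuration
#'
#' @param bladder,span,block stage models (`ctv_model`) or checkpoint
#'   paths.
#' @param offset_mm posterior offset of the CTV centre from the bladder
#'   centroid (default 39 mm).
#' @param threshold probability threshold for all stages (default 0.5).
#' @param min_area_px span-detection cleaning threshold (default 50 px).
#' @param block_depth,block_stride block geometry (default 15 / 1).
#' @param fusion `"union"` (default) or `"majority"`.
#' @param margin_slices ROI margin beyond the detected span (default 2).
#' @param mc_samples Monte-Carlo dropout samples when uncertainty is
#'   requested (default 100).
#' @param seed seed for the Monte-Carlo draws.
#' @return A `ctv_pipeline_config` list.
#' @export
pipeline_config <- function(bladder, span, block, offset_mm = 39,
                            threshold = 0.5, min_area_px = 50L,
                            block_depth = 15L, block_stride = 1L,
                            fusion = c("union", "majority"),
                            margin_slices = 2L, mc_samples = 100L, seed = 1L) {
  fusion <- match.arg(fusion)
  as_model <- function(m) if (inherits(m, "ctv_model")) m else load_model(m)
  structure(list(bladder = as_model(bladder), span = as_model(span),
                 block = as_model(block), offset_mm = offset_mm,
                 threshold = threshold, min_area_px = as.integer(min_area_px),
                 block_depth = as.integer(block_depth),
                 block_stride = as.integer(block_stride), fusion = fusion,
                 margin_slices = as.integer(margin_slices),
                 mc_samples = as.integer(mc_samples), seed = as.integer(seed)),
            class = "ctv_pipeline_config")
}

#' Segment the CTV from a volume (in memory)
#'
#' Executes the full cascade: preprocessing, bladder segmentation, CTV
#' centre estimation, SI span detection, ROI construction, block
#' extraction, per-block prediction, fusion and resampling to the native
#' grid.  Optionally adds Monte-Carlo-dropout uncertainty maps.
#'
#' @param volume a `ctv_volume` (native grid).
#' @param config a [pipeline_config()].
#' @param uncertainty also compute MC-dropout uncertainty maps.
#' @return A `ctv_segmentation` list: `mask` (native-grid CTV label map),
#'   `bladder`, `ctv_center`, `span`, `roi`, `roi_mask`, optional
#'   `uncertainty` (ROI grid), and per-stage `timings` (seconds).
#' @export
segment_ctv <- function(volume, config, uncertainty = FALSE) {
  timings <- c()
  tic <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    r
  }
  pre <- tic("preprocess", preprocess_volume(volume))
  bladder <- tic("bladder", segment_bladder(pre, config$bladder, config$threshold))
  ctr <- estimate_ctv_center(centroid(bladder), config$offset_mm)
  span <- tic("span", detect_ctv_span(pre, ctr, config$span, config$threshold,
                                      config$min_area_px))
  roi <- build_roi(volume, ctr, span$span, config$margin_slices)
  roi_img <- resample(pre, roi)
  blocks <- extract_blocks(roi_img, config$block_depth, config$block_stride)
  preds <- tic("blocks", predict_blocks(config$block, blocks, config$threshold))
  fused <- if (config$fusion == "union") fuse_union(blocks, preds)
           else fuse_majority(blocks, preds)
  mask <- to_native(fused, volume)
  unc <- NULL
  if (uncertainty)
    unc <- tic("uncertainty",
               mc_predict(config$block, blocks, config$mc_samples, config$seed))
  structure(list(mask = mask, bladder = bladder, ctv_center = ctr,
                 span = span$span, positive = span$positive, roi = roi,
                 roi_mask = fused, uncertainty = unc,
                 timings = unlist(timings)),
            class = "ctv_segmentation")
}

#' Run the pipeline on a volume file
#'
#' Reads the volume, runs [segment_ctv()] and writes the native-grid CTV
#' mask, a JSON provenance sidecar (stage geometries, parameters, seeds,
#' per-stage timings) and, when requested, the uncertainty maps.  On a
#' localization failure, partial outputs are removed and the error names
#' the failing stage.
#'
#' @param volume_path input image (NIfTI or MetaImage).
#' @param config a [pipeline_config()].
#' @param out_prefix output path prefix; writes `<prefix>_ctv.nii.gz`,
#'   `<prefix>_provenance.json` and optionally `<prefix>_mc_mean.nii.gz`
#'   and `<prefix>_mc_sd.nii.gz`.
#' @param uncertainty also write MC-dropout uncertainty maps.
#' @return Invisibly, the `ctv_segmentation` result.
#' @export
run_pipeline <- function(volume_path, config, out_prefix,
                         uncertainty = FALSE) {
  volume <- read_volume(volume_path)
  paths <- paste0(out_prefix, c("_ctv.nii.gz", "_provenance.json",
                                "_mc_mean.nii.gz", "_mc_sd.nii.gz"))
  res <- tryCatch(segment_ctv(volume, config, uncertainty = uncertainty),
                  ctv_error = function(e) {
                    unlink(paths[file.exists(paths)])
                    stop(e)
                  })
  write_volume(res$mask, paths[1])
  prov <- list(input = volume_path,
               grid = list(size = dim(volume$data), spacing = volume$spacing,
                           origin = volume$origin),
               parameters = config[c("offset_mm", "threshold", "min_area_px",
                                     "block_depth", "block_stride", "fusion",
                                     "margin_slices", "mc_samples", "seed")],
               ctv_center = res$ctv_center, span = res$span,
               roi = unclass(res$roi), timings = as.list(res$timings),
               uncertainty = uncertainty)
  jsonlite::write_json(prov, paths[2], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (uncertainty && !is.null(res$uncertainty)) {
    write_volume(as_volume(res$uncertainty$mean_prob$data,
                           res$uncertainty$mean_prob$spacing,
                           res$uncertainty$mean_prob$origin), paths[3])
    write_volume(res$uncertainty$sample_sd, paths[4])
  }
  invisible(res)
}
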