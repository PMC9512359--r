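#' Soft-Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1`,
#' the direct differentiable complement of the Dice similarity
#' coefficient used to train every network in the cascade.
#'
#' @param pred probability map (`ctv_probmap`, array or matrix).
#' @param target binary mask of the same shape.
#' @param eps smoothing constant (default 1).
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(pred, target, eps = 1) {
  p <- if (inherits(pred, "ctv_volume")) pred$data else pred
  t <- if (inherits(target, "ctv_volume")) target$data else target
  if (!identical(dim(p), dim(t)) && !identical(length(p), length(t)))
    ctv_stop("ctv_error_shape", "prediction and target shapes differ")
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

dice_loss_grad <- function(p, t, eps = 1) {
  num <- 2 * sum(p * t) + eps
  den <- sum(p) + sum(t) + eps
  -((2 * t * den - num) / den^2)
}

# ---- AdaDelta ---------------------------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(out))
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    out
  } else {
    do.call(f, trees)
  }
}

adadelta_init <- function(params, init_step = 0) {
  zeros <- tree_map(function(p) p * 0, params)
  list(Eg2 = zeros, Edx2 = tree_map(function(p) p * 0 + init_step^2, params))
}

adadelta_step <- function(params, grads, state, rho = 0.95, eps = 1e-6,
                          max_step = Inf) {
  Eg2 <- tree_map(function(s, g) rho * s + (1 - rho) * g^2, state$Eg2, grads)
  dx <- tree_map(function(s2, s1, g)
    -pmin(sqrt(s2 + eps), max_step) / sqrt(s1 + eps) * g,
    state$Edx2, Eg2, grads)
  Edx2 <- tree_map(function(s, d) rho * s + (1 - rho) * d^2, state$Edx2, dx)
  params <- tree_map(`+`, params, dx)
  list(params = params, state = list(Eg2 = Eg2, Edx2 = Edx2))
}

# ---- augmentation -----------------------------------------------------------

shift2d_int <- function(m, dx, dy) {
  out <- m * 0
  nx <- nrow(m); ny <- ncol(m)
  sx <- max(1, 1 + dx):min(nx, nx + dx)
  sy <- max(1, 1 + dy):min(ny, ny + dy)
  out[sx, sy] <- m[sx - dx, sy - dy]
  out
}

#' Augment a training sample
#'
#' `shift_2d`: uniform integer in-plane translation up to `shift_max_px`.
#' `translate_rotate_3d`: uniform integer translation up to
#' `translate_max_vox` per axis plus an in-plane rotation up to
#' `rotate_max_deg` about the volume centre.  Image and mask receive the
#' identical transform; the mask is resampled nearest-neighbour.
#'
#' @param sample list with elements `x` (image array/matrix) and `y`
#'   (binary mask of the same shape).
#' @param kind `"none"`, `"shift_2d"` or `"translate_rotate_3d"`.
#' @param shift_max_px maximum in-plane shift for `shift_2d` (pixels).
#' @param translate_max_vox maximum per-axis translation for 3-D (voxels).
#' @param rotate_max_deg maximum in-plane rotation (degrees).
#' @param seed optional seed; by default draws from the current RNG stream.
#' @return The augmented sample (same structure).
#' @export
augment <- function(sample, kind = c("none", "shift_2d", "translate_rotate_3d"),
                    shift_max_px = 10, translate_max_vox = 5,
                    rotate_max_deg = 10, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) return(with_seed(seed, augment(sample, kind, shift_max_px,
                                                     translate_max_vox, rotate_max_deg)))
  if (kind == "none") return(sample)
  if (kind == "shift_2d") {
    d <- round(runif(2, -shift_max_px, shift_max_px))
    sample$x <- shift2d_int(sample$x, d[1], d[2])
    sample$y <- shift2d_int(sample$y, d[1], d[2])
  } else {
    sh <- round(runif(3, -translate_max_vox, translate_max_vox))
    ang <- runif(1, -rotate_max_deg, rotate_max_deg)
    d <- dim(sample$x)
    x <- affine_inplane(as.numeric(sample$x), d, ang, sh, FALSE)
    y <- affine_inplane(as.numeric(sample$y), d, ang, sh, TRUE)
    dim(x) <- d; dim(y) <- d
    sample$x <- x
    sample$y <- array(as.integer(y), d)
  }
  sample
}

# ---- stage-specific sample sets --------------------------------------------

bladder_roi_for <- function(volume) {
  roi_spec(volume_center(volume), c(94L, 94L, 50L), c(3, 3, 3.2))
}

load_manifest_phantoms <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(image = read_volume(manifest$image_path[i]),
         bladder = read_labelmap(manifest$bladder_path[i]),
         ctv = read_labelmap(manifest$ctv_path[i]))
  })
}

#' Build stage-specific training samples
#'
#' Converts a phantom dataset (a manifest data.frame from
#' [generate_dataset()] or a list of in-memory phantoms) into the sample
#' set each stage of the cascade trains on:
#'
#' * `bladder`: (94 x 94 x 50 volume at 3 x 3 x 3.2 mm, bladder mask)
#'   pairs cropped about the volume centre;
#' * `span`: (128 x 128 axial slice at 1 x 1 mm, CTV slice mask) pairs
#'   centred at the CTV centre estimated from the ground-truth bladder
#'   centroid; CTV-bearing slices are oversampled with random in-plane
#'   shifts of the crop centre to counter class imbalance;
#' * `block`: (128 x 128 x depth_b block, CTV block mask) pairs extracted
#'   with stride `block_stride` from the ground-truth-centred ROI.
#'
#' @param phantoms manifest data.frame or list of `ctv_phantom` /
#'   image-bladder-ctv lists.
#' @param stage `"bladder"`, `"span"` or `"block"`.
#' @param offset_mm posterior offset used for ground-truth ROI centres.
#' @param pos_per_phantom,neg_per_phantom for `span`: number of
#'   CTV-positive and CTV-free slices kept per phantom (`NULL` keeps all
#'   slices and adds one shifted copy of every positive slice).
#' @param shift_max_px maximum random shift of the span crop centre.
#' @param block_depth,block_stride block geometry for `block`.
#' @param seed seed controlling slice selection and shifts.
#' @return A `ctv_samples` object; use `length()` and `get_sample()`.
#' @export
make_training_samples <- function(phantoms, stage = c("bladder", "span", "block"),
                                  offset_mm = 39, pos_per_phantom = NULL,
                                  neg_per_phantom = NULL, shift_max_px = 10,
                                  block_depth = 15L, block_stride = 1L,
                                  seed = 1L) {
  stage <- match.arg(stage)
  if (is.data.frame(phantoms)) {
    if (nrow(phantoms) == 0) ctv_stop("ctv_error_parameter", "empty manifest")
    phantoms <- load_manifest_phantoms(phantoms)
  }
  if (length(phantoms) == 0) ctv_stop("ctv_error_parameter", "no phantoms supplied")
  items <- list()
  rois <- list()
  with_seed(seed, {
    for (ph in phantoms) {
      img <- if (is.null(attr(ph$image, "ctv_preprocessed")))
        preprocess_volume(ph$image) else ph$image
      if (stage == "bladder") {
        roi <- bladder_roi_for(img)
        items[[length(items) + 1L]] <-
          list(x = resample(img, roi)$data,
               y = resample(ph$bladder, roi, "nearest")$data)
      } else if (stage == "span") {
        ctr <- estimate_ctv_center(centroid(ph$bladder), offset_mm)
        nz <- dim(img$data)[3]
        pos <- which(apply(ph$ctv$data, 3, sum) > 0)
        neg <- setdiff(seq_len(nz), pos)
        crop_slice <- function(k, shift = c(0, 0)) {
          zk <- img$origin[3] + (k - 1) * img$spacing[3]
          roi <- roi_spec(c(ctr[1] + shift[1], ctr[2] + shift[2], zk),
                          c(128L, 128L, 1L), c(1, 1, img$spacing[3]))
          list(x = resample(img, roi)$data[, , 1],
               y = resample(ph$ctv, roi, "nearest")$data[, , 1])
        }
        if (is.null(pos_per_phantom)) {
          for (k in seq_len(nz)) items[[length(items) + 1L]] <- crop_slice(k)
          for (k in pos)
            items[[length(items) + 1L]] <-
              crop_slice(k, round(runif(2, -shift_max_px, shift_max_px)))
        } else {
          kp <- if (length(pos)) sample(pos, min(pos_per_phantom, length(pos))) else integer()
          kn <- if (length(neg)) sample(neg, min(neg_per_phantom %||% pos_per_phantom,
                                                 length(neg))) else integer()
          for (k in kp)
            items[[length(items) + 1L]] <-
              crop_slice(k, round(runif(2, -shift_max_px, shift_max_px)))
          for (k in kn) items[[length(items) + 1L]] <- crop_slice(k)
        }
      } else { # block
        ctr <- estimate_ctv_center(centroid(ph$bladder), offset_mm)
        pos <- which(apply(ph$ctv$data, 3, sum) > 0)
        if (length(pos) == 0) next
        roi <- build_roi(img, ctr, c(min(pos), max(pos)))
        ri <- resample(img, roi)$data
        rm_ <- resample(ph$ctv, roi, "nearest")$data
        rois[[length(rois) + 1L]] <- list(x = ri, y = rm_)
        D <- dim(ri)[3]
        starts <- seq(1L, max(1L, D - block_depth + 1L), by = block_stride)
        for (s in starts)
          items[[length(items) + 1L]] <- list(roi = length(rois), start = s)
      }
    }
  })
  structure(list(stage = stage, items = items, rois = rois,
                 block_depth = as.integer(block_depth)),
            class = "ctv_samples")
}

#' @export
length.ctv_samples <- function(x) length(x$items)

#' Fetch one training sample
#' @param samples a `ctv_samples` set.
#' @param i sample index.
#' @return list with image `x` and mask `y` arrays.
#' @export
get_sample <- function(samples, i) {
  it <- samples$items[[i]]
  if (samples$stage != "block") return(it)
  r <- samples$rois[[it$roi]]
  zz <- it$start:(it$start + samples$block_depth - 1L)
  list(x = r$x[, , zz, drop = FALSE], y = r$y[, , zz, drop = FALSE])
}

# ---- training loop ----------------------------------------------------------

#' Training configuration
#'
#' @param epochs training epochs (default 100).
#' @param val_fraction fraction of samples held out for validation,
#'   default 0.10.
#' @param batch_size gradient-accumulation batch; default 16 for 2-D
#'   models and 4 for 3-D.
#' @param seed seed for the split, shuffling, dropout and augmentation.
#' @param augmentation `"none"`, `"shift_2d"` or `"translate_rotate_3d"`.
#' @param shift_max_px,translate_max_vox,rotate_max_deg augmentation
#'   magnitudes (see [augment()]).
#' @param rho,eps AdaDelta accumulator decay and stabilizer.
#' @param init_step initial RMS update scale seeding the squared-update
#'   accumulator; 0 reproduces the classical cold start, the default 0.05
#'   lets short desk-scale runs take useful steps from the first epoch.
#' @param max_step cap on the accumulated RMS update scale; `Inf` is the
#'   classical unbounded behaviour.
#' @return A `ctv_train_config` list.
#' @export
train_config <- function(epochs = 100L, val_fraction = 0.10, batch_size = NULL,
                         seed = 1L, augmentation = "none", shift_max_px = 10,
                         translate_max_vox = 5, rotate_max_deg = 10,
                         rho = 0.95, eps = 1e-6, init_step = 0.05,
                         max_step = Inf) {
  if (val_fraction <= 0 || val_fraction >= 1)
    ctv_stop("ctv_error_parameter", "val_fraction must lie in (0, 1)")
  if (epochs < 1) ctv_stop("ctv_error_parameter", "epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), val_fraction = val_fraction,
                 batch_size = batch_size, seed = as.integer(seed),
                 augmentation = augmentation, shift_max_px = shift_max_px,
                 translate_max_vox = translate_max_vox,
                 rotate_max_deg = rotate_max_deg, rho = rho, eps = eps,
                 init_step = init_step, max_step = max_step),
            class = "ctv_train_config")
}

#' Number of validation samples for a split
#' @param n total sample count.
#' @param val_fraction validation fraction.
#' @return Integer count (at least 1).
#' @export
validation_count <- function(n, val_fraction) max(1L, round(n * val_fraction))

hard_dice_counts <- function(p, y, t = 0.5) {
  a <- as.vector(p) > t
  yv <- as.vector(y) > 0
  c(inter = sum(a & yv), a = sum(a), m = sum(yv))
}

#' Train a model
#'
#' Splits off `val_fraction` of the samples (seeded, deterministic),
#' optimizes the soft-Dice loss with AdaDelta, checkpoints the weights
#' whenever the validation DSC improves, and finally returns whichever of
#' the best checkpoint and the final-epoch model has the higher validation
#' DSC.  Per-epoch train/validation loss and DSC are returned as history.
#'
#' @param model a `ctv_model` from [build_model()].
#' @param samples a `ctv_samples` set from [make_training_samples()].
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return List with `model` (selected weights), `history` (data.frame),
#'   `best_epoch` and `selected` (`"best"` or `"final"`).
#' @export
train_model <- function(model, samples, config = train_config(), verbose = FALSE) {
  n <- length(samples)
  if (n < 2) ctv_stop("ctv_error_parameter", "need at least 2 samples to split")
  bs <- config$batch_size %||% if (model$spec$dims == 2L) 16L else 4L
  with_seed(config$seed, {
    perm <- sample.int(n)
    nval <- validation_count(n, config$val_fraction)
    val_idx <- perm[seq_len(nval)]
    tr_idx <- perm[-seq_len(nval)]
    state <- adadelta_init(model$params, config$init_step)
    hist <- vector("list", config$epochs)
    best <- list(dsc = -Inf, params = NULL, epoch = 0L)
    val_dsc_of <- function() {
      cnt <- c(inter = 0, a = 0, m = 0); loss <- 0
      for (i in val_idx) {
        s <- get_sample(samples, i)
        p <- model_forward(model, as_net_input(s$x))$p
        loss <- loss + dice_loss(as.vector(p), as.vector(s$y))
        cnt <- cnt + hard_dice_counts(p, s$y)
      }
      list(dsc = as.numeric(2 * cnt["inter"] / max(1, cnt["a"] + cnt["m"])),
           loss = loss / length(val_idx))
    }
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; cnt <- c(inter = 0, a = 0, m = 0)
      for (b0 in seq(1, length(ord), by = bs)) {
        bidx <- ord[b0:min(length(ord), b0 + bs - 1)]
        gacc <- NULL
        for (i in bidx) {
          s <- get_sample(samples, i)
          if (config$augmentation != "none")
            s <- augment(s, config$augmentation, config$shift_max_px,
                         config$translate_max_vox, config$rotate_max_deg)
          x <- as_net_input(s$x)
          fw <- model_forward(model, x, dropout_active = TRUE, need_cache = TRUE)
          y <- as.vector(s$y)
          l <- dice_loss(as.vector(fw$p), y)
          if (!is.finite(l))
            ctv_stop("ctv_error_training",
                     sprintf("non-finite loss at epoch %d", ep), epoch = ep)
          ep_loss <- ep_loss + l
          cnt <- cnt + hard_dice_counts(fw$p, s$y)
          tgt <- array(as.numeric(s$y), dim(x))
          dp <- dice_loss_grad(fw$p, tgt)
          g <- model_backward(model, fw$cache, dp)
          gacc <- if (is.null(gacc)) g else tree_map(`+`, gacc, g)
        }
        gacc <- tree_map(function(g) g / length(bidx), gacc)
        st <- adadelta_step(model$params, gacc, state, config$rho, config$eps,
                            config$max_step)
        model$params <- st$params
        state <- st$state
      }
      v <- val_dsc_of()
      hist[[ep]] <- data.frame(epoch = ep,
                               train_loss = ep_loss / length(tr_idx),
                               train_dsc = as.numeric(2 * cnt["inter"] / max(1, cnt["a"] + cnt["m"])),
                               val_loss = v$loss, val_dsc = v$dsc)
      if (v$dsc > best$dsc) best <- list(dsc = v$dsc, params = model$params, epoch = ep)
      if (verbose)
        message(sprintf("epoch %3d  train loss %.4f  train DSC %.4f  val DSC %.4f",
                        ep, hist[[ep]]$train_loss, hist[[ep]]$train_dsc, v$dsc))
    }
    history <- do.call(rbind, hist)
    final_dsc <- history$val_dsc[config$epochs]
    selected <- if (final_dsc >= best$dsc) "final" else "best"
    if (selected == "best") model$params <- best$params
    list(model = model, history = history, best_epoch = best$epoch,
         selected = selected)
  })
}
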