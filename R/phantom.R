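#' Phantom generator configuration
#'
#' Defines the synthetic pelvic-phantom population: a bright, smooth
#' ellipsoidal bladder in the anterior half of the volume and a darker,
#' irregular CTV blob whose centre is drawn `offset_mean_mm` +/-
#' `offset_sd_mm` (normal) posterior to the bladder centre, laterally
#' aligned up to a small jitter.  The default grid is a desk-scale
#' 128 x 128 x 64 voxel volume at 1 x 1 x 1.6 mm.  CTV volumes are drawn
#' log-uniformly inside `ctv_volume_range_cm3`; the default range keeps the
#' clinical lower end (3.93 cm3) and scales the upper end to what the desk
#' grid can hold.
#'
#' @param grid_size integer(3) voxel counts.
#' @param spacing_mm numeric(3) voxel size in mm.
#' @param bladder_volume_range_cm3 numeric(2) low/high bladder volume; the
#'   default keeps the bladder (a comfortably full RT-planning bladder,
#'   desk-scaled) larger than the CTV, as in the clinic.
#' @param ctv_volume_range_cm3 numeric(2) low/high CTV volume (draws are
#'   log-uniform and truncated to this range).
#' @param offset_mean_mm mean posterior offset of the CTV centre from the
#'   bladder centre, in mm.
#' @param offset_sd_mm standard deviation of the posterior offset, mm.
#' @param lateral_jitter_sd_mm SD of the left-right offset component, mm.
#' @param si_jitter_sd_mm SD of the superior-inferior offset component, mm.
#' @param noise_sd additive Gaussian noise SD as a fraction of the \[0,1\]
#'   dynamic range.
#' @param bias_field_amplitude amplitude of the smooth multiplicative
#'   intensity inhomogeneity field.
#' @param irregularity amplitude of the smooth radial perturbation applied
#'   to the CTV ellipsoid (0 gives a plain ellipsoid).
#' @param intensities named numeric: `background`, `ctv`, `bladder` mean
#'   intensities on the \[0,1\] scale before bias and noise.
#' @return A `ctv_phantom_config` list.
#' @export
phantom_config <- function(grid_size = c(128L, 128L, 64L),
                           spacing_mm = c(1, 1, 1.6),
                           bladder_volume_range_cm3 = c(40, 100),
                           ctv_volume_range_cm3 = c(3.93, 45),
                           offset_mean_mm = 39,
                           offset_sd_mm = 10,
                           lateral_jitter_sd_mm = 2,
                           si_jitter_sd_mm = 5,
                           noise_sd = 0.03,
                           bias_field_amplitude = 0.1,
                           irregularity = 0.12,
                           intensities = c(background = 0.2, ctv = 0.45,
                                           bladder = 0.9)) {
  stopifnot(length(grid_size) == 3L, length(spacing_mm) == 3L,
            bladder_volume_range_cm3[1] <= bladder_volume_range_cm3[2],
            ctv_volume_range_cm3[1] <= ctv_volume_range_cm3[2],
            offset_sd_mm >= 0, noise_sd >= 0, irregularity >= 0)
  structure(list(grid_size = as.integer(grid_size),
                 spacing_mm = as.numeric(spacing_mm),
                 bladder_volume_range_cm3 = bladder_volume_range_cm3,
                 ctv_volume_range_cm3 = ctv_volume_range_cm3,
                 offset_mean_mm = offset_mean_mm, offset_sd_mm = offset_sd_mm,
                 lateral_jitter_sd_mm = lateral_jitter_sd_mm,
                 si_jitter_sd_mm = si_jitter_sd_mm,
                 noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 irregularity = irregularity, intensities = intensities),
            class = "ctv_phantom_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Snap a world point to the nearest voxel centre so that blobs are
# point-symmetric on the grid and their mask centroid equals their centre.
snap_to_grid <- function(p, spacing) round(p / spacing) * spacing

# Rasterize an ellipsoid centred at `center` (mm) with semi-axes `ax` (mm),
# perturbed radially by the even function g(e) built from two random
# symmetric quadratic forms.  Point symmetry of g keeps the centroid at
# `center` exactly (up to grid clipping).
rasterize_blob <- function(grid_size, spacing, center, ax, irregularity) {
  A1 <- matrix(rnorm(9), 3); A1 <- (A1 + t(A1)) / 2; diag(A1) <- diag(A1) - sum(diag(A1)) / 3
  A2 <- matrix(rnorm(9), 3); A2 <- (A2 + t(A2)) / 2; diag(A2) <- diag(A2) - sum(diag(A2)) / 3
  margin <- 1 + 3 * irregularity
  lo <- pmax(1L, floor((center - ax * margin) / spacing) + 1L)
  hi <- pmin(grid_size, ceiling((center + ax * margin) / spacing) + 1L)
  mask <- array(0L, grid_size)
  if (any(lo > hi)) return(mask)
  xs <- ((lo[1]:hi[1]) - 1) * spacing[1]
  ys <- ((lo[2]:hi[2]) - 1) * spacing[2]
  zs <- ((lo[3]:hi[3]) - 1) * spacing[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  wx <- (xs - center[1]) / ax[1]
  wy <- (ys - center[2]) / ax[2]
  wz <- (zs - center[3]) / ax[3]
  W1 <- array(rep(wx, times = ny * nz), c(nx, ny, nz))
  W2 <- array(rep(rep(wy, each = nx), times = nz), c(nx, ny, nz))
  W3 <- array(rep(wz, each = nx * ny), c(nx, ny, nz))
  u <- sqrt(W1^2 + W2^2 + W3^2)
  u[u == 0] <- 1e-9
  e1 <- W1 / u; e2 <- W2 / u; e3 <- W3 / u
  q <- function(A) A[1,1]*e1*e1 + A[2,2]*e2*e2 + A[3,3]*e3*e3 +
    2 * (A[1,2]*e1*e2 + A[1,3]*e1*e3 + A[2,3]*e2*e3)
  g <- irregularity * (q(A1) + 0.5 * (q(A2)^2 - 0.5))
  g <- pmin(pmax(g, -0.35), 0.35)
  inside <- u <= 1 + g
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- as.integer(inside)
  mask
}

# Semi-axes (mm) for a blob of volume V cm3 with per-axis shape ratios
# jittered log-normally.
draw_axes <- function(volume_cm3, base_ratio, jitter_sd = 0.08) {
  r <- base_ratio * exp(rnorm(3, 0, jitter_sd))
  s <- (volume_cm3 * 1000 / (4 / 3 * pi * prod(r)))^(1 / 3)
  r * s
}

smooth_field <- function(grid_size, spacing, coarse = c(5L, 5L, 5L)) {
  extent <- (grid_size - 1) * spacing
  vals <- rnorm(prod(coarse))
  out <- resample_grid(vals, coarse, extent / (coarse - 1), c(0, 0, 0),
                       grid_size, spacing, c(0, 0, 0), FALSE)
  array(out, grid_size)
}

#' Generate one synthetic pelvic phantom
#'
#' Draws bladder and CTV geometry from the configured population, builds
#' the two ground-truth masks and synthesizes the image as structure
#' intensities modulated by a smooth multiplicative bias field plus
#' additive Gaussian noise.  The CTV never overlaps the bladder (the
#' bladder wins where the draws collide).  The same `config` and `seed`
#' give a bit-identical sample.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed controlling every random draw.
#' @return A `ctv_phantom` list: `image` (volume), `bladder`, `ctv` (label
#'   maps) and `params` (all realized draws, centres in world mm).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  with_seed(seed, {
    gs <- config$grid_size; sp <- config$spacing_mm
    extent <- (gs - 1) * sp
    b_center <- snap_to_grid(c(extent[1] / 2 + rnorm(1, 0, 2),
                               30 + rnorm(1, 0, 2),
                               extent[3] / 2 + rnorm(1, 0, 3)), sp)
    b_vol <- exp(runif(1, log(config$bladder_volume_range_cm3[1]),
                       log(config$bladder_volume_range_cm3[2])))
    b_ax <- draw_axes(b_vol, c(1.15, 0.55, 1), jitter_sd = 0.05)
    if (any(b_center - b_ax * 1.05 < 0) || any(b_center + b_ax * 1.05 > extent))
      ctv_stop("ctv_error_generation",
               "bladder does not fit the phantom grid; use a larger grid")
    offset <- c(rnorm(1, 0, config$lateral_jitter_sd_mm),
                rnorm(1, config$offset_mean_mm, config$offset_sd_mm),
                rnorm(1, 0, config$si_jitter_sd_mm))
    c_center <- snap_to_grid(b_center + offset, sp)
    if (any(c_center < 0) || any(c_center > extent))
      ctv_stop("ctv_error_generation",
               "CTV centre falls outside the phantom grid; use a larger grid")
    c_vol <- exp(runif(1, log(config$ctv_volume_range_cm3[1]),
                       log(config$ctv_volume_range_cm3[2])))
    c_ax <- draw_axes(c_vol, c(1, 0.8, 1.1))
    bladder <- rasterize_blob(gs, sp, b_center, b_ax, 0)
    ctv <- rasterize_blob(gs, sp, c_center, c_ax, config$irregularity)
    ctv[bladder == 1L] <- 0L
    if (sum(bladder) == 0 || sum(ctv) == 0)
      ctv_stop("ctv_error_generation",
               "degenerate phantom: empty structure; use a larger grid")
    ints <- config$intensities
    base <- array(ints[["background"]], gs)
    base[ctv == 1L] <- ints[["ctv"]]
    base[bladder == 1L] <- ints[["bladder"]]
    bias <- 1 + config$bias_field_amplitude * smooth_field(gs, sp)
    img <- base * bias
    if (config$noise_sd > 0) img <- img + rnorm(length(img), 0, config$noise_sd)
    image <- as_volume(img, sp, c(0, 0, 0))
    bl <- as_labelmap(bladder, sp, c(0, 0, 0))
    cv <- as_labelmap(ctv, sp, c(0, 0, 0))
    params <- list(seed = seed,
                   bladder_center = b_center, ctv_center = c_center,
                   offset_mm = c_center - b_center,
                   bladder_volume_cm3 = b_vol, ctv_volume_cm3 = c_vol,
                   bladder_axes_mm = b_ax, ctv_axes_mm = c_ax,
                   bladder_centroid = centroid(bl), ctv_centroid = centroid(cv))
    structure(list(image = image, bladder = bl, ctv = cv, params = params),
              class = "ctv_phantom")
  })
}

#' Generate and write a phantom dataset
#'
#' Writes `n` phantoms (image plus bladder and CTV masks, NIfTI) under
#' `out_dir` together with a `manifest.csv` listing paths and realized
#' generation parameters.  Per-sample seeds are derived deterministically
#' from the master seed, so regeneration reproduces the dataset.
#'
#' @param n number of phantoms (>= 1).
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @return The manifest as a data.frame (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(n, config = phantom_config(), out_dir, seed = 1L) {
  if (n < 1) ctv_stop("ctv_error_parameter", "n must be >= 1")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) ctv_stop("ctv_error_io", sprintf("cannot create output directory '%s'", out_dir))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(config, seeds[i])
    id <- sprintf("phantom_%03d", i)
    paths <- file.path(out_dir, paste0(id, c("_image.nii.gz", "_bladder.nii.gz",
                                             "_ctv.nii.gz")))
    write_volume(ph$image, paths[1])
    write_volume(ph$bladder, paths[2])
    write_volume(ph$ctv, paths[3])
    p <- ph$params
    rows[[i]] <- data.frame(id = id, image_path = paths[1],
                            bladder_path = paths[2], ctv_path = paths[3],
                            bladder_cx = p$bladder_centroid[1],
                            bladder_cy = p$bladder_centroid[2],
                            bladder_cz = p$bladder_centroid[3],
                            ctv_cx = p$ctv_centroid[1],
                            ctv_cy = p$ctv_centroid[2],
                            ctv_cz = p$ctv_centroid[3],
                            offset_mm = p$offset_mm[2],
                            ctv_volume_cm3 = p$ctv_volume_cm3,
                            seed = seeds[i], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
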