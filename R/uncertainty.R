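#' Monte-Carlo-dropout prediction over a block set
#'
#' Draws `n_samples` Monte-Carlo realizations of the fused probability
#' map: in each realization every block is predicted with dropout active
#' and the per-voxel probabilities are averaged over the covering blocks.
#' The returned `mean_prob` and `sample_sd` are the per-voxel mean and
#' standard deviation across realizations, so `sample_sd` measures the
#' dropout-induced dispersion of the fused prediction.  With dropout rate
#' 0 all realizations coincide and the SD map is identically zero.  A
#' fixed seed reproduces the maps exactly.
#'
#' @param model a 3-D `ctv_model` with dropout layers.
#' @param blocks a `ctv_blockset`.
#' @param n_samples Monte-Carlo samples per block (default 100, >= 2).
#' @param seed seed for the dropout draws.
#' @return A `ctv_uncertainty` list: `mean_prob` (probability map on the
#'   ROI grid), `sample_sd` (volume of per-voxel sample SDs) and
#'   `n_samples`.
#' @export
mc_predict <- function(model, blocks, n_samples = 100L, seed = 1L) {
  if (n_samples < 2) ctv_stop("ctv_error_parameter", "n_samples must be >= 2")
  shape <- blocks$roi_shape
  s1 <- array(0, shape); s2 <- array(0, shape)
  cover <- array(0, shape)
  for (i in seq_along(blocks$blocks)) {
    zz <- blocks$si_starts[i]:(blocks$si_starts[i] + blocks$depth_b - 1L)
    cover[, , zz] <- cover[, , zz] + 1
  }
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      ps <- array(0, shape)
      for (i in seq_along(blocks$blocks)) {
        zz <- blocks$si_starts[i]:(blocks$si_starts[i] + blocks$depth_b - 1L)
        p <- predict_map(model, blocks$blocks[[i]], dropout_active = TRUE)
        ps[, , zz] <- ps[, , zz] + p
      }
      ps <- ps / pmax(cover, 1)
      s1 <- s1 + ps
      s2 <- s2 + ps^2
    }
  })
  m <- s1 / n_samples
  v <- s2 / n_samples - m^2
  # clamp accumulation round-off so identical realizations give exactly 0 SD
  v[v < 1e-12] <- 0
  keep <- seq_along(blocks$valid_z)[blocks$valid_z]
  m <- m[, , keep, drop = FALSE]
  v <- v[, , keep, drop = FALSE]
  structure(list(
    mean_prob = structure(list(data = m, spacing = blocks$spacing,
                               origin = blocks$origin),
                          class = c("ctv_probmap", "ctv_volume")),
    sample_sd = as_volume(sqrt(v), blocks$spacing, blocks$origin),
    n_samples = as.integer(n_samples)),
    class = "ctv_uncertainty")
}

blue_red <- grDevices::colorRamp(c("#0000b0", "#00b0ff", "#ffe000", "#ff2000"))

#' Render an uncertainty overlay
#'
#' Writes a PNG montage of axial slices: the grayscale image blended with
#' a blue (low) to red (high) heatmap of the per-voxel uncertainty, with
#' the segmentation boundary drawn in white when a mask is supplied.  The
#' colour scale spans \[0, max uncertainty\] and is recorded in the PNG
#' text metadata.
#'
#' @param map a `ctv_uncertainty` from [mc_predict()].
#' @param image the `ctv_volume` the map was computed on (same grid).
#' @param path output PNG path.
#' @param mask optional segmentation label map to contour.
#' @param n_slices number of axial slices in the montage (default 6).
#' @param alpha heatmap opacity in \[0, 1\].
#' @return Invisibly, `path`.
#' @export
render_uncertainty <- function(map, image, path, mask = NULL, n_slices = 6L,
                               alpha = 0.45) {
  u <- map$sample_sd
  if (!same_grid(u, image))
    ctv_stop("ctv_error_shape", "uncertainty map and image grids differ")
  d <- dim(image$data)
  ks <- unique(round(seq(1, d[3], length.out = min(n_slices, d[3]))))
  umax <- max(u$data)
  rng <- range(image$data)
  gscale <- if (diff(rng) > 0) (image$data - rng[1]) / diff(rng) else image$data * 0
  panels <- lapply(ks, function(k) {
    g <- t(gscale[, , k])[rev(seq_len(d[2])), , drop = FALSE]
    uv <- t(u$data[, , k])[rev(seq_len(d[2])), , drop = FALSE]
    un <- if (umax > 0) uv / umax else uv * 0
    cols <- blue_red(pmin(pmax(as.vector(un), 0), 1)) / 255
    rgb <- array(0, c(dim(g), 3))
    for (ch in 1:3)
      rgb[, , ch] <- (1 - alpha) * g + alpha * cols[, ch]
    if (!is.null(mask)) {
      sl <- mask$data[, , k]
      edge <- sl & !(shift2d_int(sl, 1, 0) & shift2d_int(sl, -1, 0) &
                     shift2d_int(sl, 0, 1) & shift2d_int(sl, 0, -1))
      e <- t(edge)[rev(seq_len(d[2])), , drop = FALSE]
      for (ch in 1:3) { p <- rgb[, , ch]; p[e > 0] <- 1; rgb[, , ch] <- p }
    }
    rgb
  })
  h <- dim(panels[[1]])[1]
  montage <- array(0, c(h, sum(vapply(panels, function(p) dim(p)[2], 0L)), 3))
  off <- 0L
  for (p in panels) {
    w <- dim(p)[2]
    montage[, off + seq_len(w), ] <- p
    off <- off + w
  }
  png::writePNG(pmin(pmax(montage, 0), 1), path,
                text = c(uncertainty_range = sprintf("0,%g", umax),
                         n_samples = as.character(map$n_samples)))
  invisible(path)
}
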