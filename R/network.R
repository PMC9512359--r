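#' Network architecture specification
#'
#' Describes an encoder-decoder segmentation network: `depth` resolution
#' levels whose filter counts start at `base_filters` and double per level,
#' two (convolution -> spatial normalization -> ReLU) blocks per level with
#' 3-per-axis kernels, factor-2 max pooling between encoder levels, nearest
#' -neighbour upsampling followed by a 1x1 channel-halving convolution in
#' the decoder, optional additive attention gates on the skip connections,
#' dropout (bottleneck and decoder levels, switchable at inference) and a
#' final 1x1 convolution with sigmoid output.
#'
#' In-plane input sizes must be divisible by `2^(depth-1)`.  Along the
#' superior-inferior axis of a 3-D input, pooling is applied only at levels
#' where the current size is even, so shallow blocks (e.g. 15 slices) pass
#' through without SI pooling.
#'
#' @param dims spatial dimensionality, 2 or 3.
#' @param depth number of encoder levels (>= 2).
#' @param base_filters filters in the first level (>= 1).
#' @param attention add additive attention gates on skip connections.
#' @param dropout dropout rate in \[0, 1), default 0.5.
#' @return A `ctv_netspec` object.
#' @export
network_spec <- function(dims = 3L, depth = 4L, base_filters = 16L,
                         attention = FALSE, dropout = 0.5) {
  if (!dims %in% c(2L, 3L)) ctv_stop("ctv_error_parameter", "dims must be 2 or 3")
  if (depth < 2L) ctv_stop("ctv_error_parameter", "depth must be >= 2")
  if (base_filters < 1L) ctv_stop("ctv_error_parameter", "base_filters must be >= 1")
  if (dropout < 0 || dropout >= 1) ctv_stop("ctv_error_parameter", "dropout must be in [0, 1)")
  structure(list(dims = as.integer(dims), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 attention = isTRUE(attention), dropout = dropout),
            class = "ctv_netspec")
}

#' Per-level encoder channel counts
#' @param spec a [network_spec()].
#' @return Integer vector of filter counts, one per level.
#' @export
spec_channels <- function(spec) spec$base_filters * 2L^(seq_len(spec$depth) - 1L)

he_init <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)

#' Build a trainable model from a specification
#'
#' Initializes all weights (He initialization, seeded) for the encoder,
#' decoder, optional attention gates and the final sigmoid head.  The
#' weight shapes are independent of the input size, so one model serves
#' any compatible input grid.
#'
#' @param spec a [network_spec()].
#' @param in_channels input channels (1 for a grayscale volume).
#' @param seed seed for weight initialization.
#' @return A `ctv_model` list with elements `spec` and `params`.
#' @export
build_model <- function(spec, in_channels = 1L, seed = 1L) {
  ch <- spec_channels(spec)
  K <- 3L^spec$dims
  with_seed(seed, {
    enc <- vector("list", spec$depth)
    cin <- in_channels
    for (l in seq_len(spec$depth)) {
      enc[[l]] <- list(
        conv1 = list(W = he_init(cin * K, ch[l]), b = numeric(ch[l])),
        n1 = list(gamma = rep(1, ch[l]), beta = numeric(ch[l])),
        conv2 = list(W = he_init(ch[l] * K, ch[l]), b = numeric(ch[l])),
        n2 = list(gamma = rep(1, ch[l]), beta = numeric(ch[l])))
      cin <- ch[l]
    }
    dec <- vector("list", spec$depth - 1L)
    for (l in seq_len(spec$depth - 1L)) {
      d <- list(
        up = list(W = he_init(ch[l + 1], ch[l]), b = numeric(ch[l])),
        conv1 = list(W = he_init(2L * ch[l] * K, ch[l]), b = numeric(ch[l])),
        n1 = list(gamma = rep(1, ch[l]), beta = numeric(ch[l])),
        conv2 = list(W = he_init(ch[l] * K, ch[l]), b = numeric(ch[l])),
        n2 = list(gamma = rep(1, ch[l]), beta = numeric(ch[l])))
      if (spec$attention)
        d$att <- list(Wg = he_init(ch[l + 1], ch[l]), bg = numeric(ch[l]),
                      Wx = he_init(ch[l], ch[l]), bx = numeric(ch[l]),
                      Wpsi = he_init(ch[l], 1L), bpsi = numeric(1L))
      dec[[l]] <- d
    }
    # prior-probability initialization: start the sigmoid output low, as
    # foreground voxels are a small fraction of any segmentation target
    final <- list(W = he_init(ch[1], 1L), b = -3)
    structure(list(spec = spec, params = list(enc = enc, dec = dec, final = final),
                   in_channels = as.integer(in_channels)),
              class = "ctv_model")
  })
}

#' @export
print.ctv_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<ctv model> %d-D U-Net, depth %d, filters %s%s, dropout %.2f\n",
              s$dims, s$depth, paste(spec_channels(s), collapse = "-"),
              if (s$attention) ", attention gates" else "", s$dropout))
  invisible(x)
}

# ---- internal layer helpers (channel-last arrays, dim = c(nx, ny, nz, C)) --

net_kernel <- function(spec) if (spec$dims == 3L) c(3L, 3L, 3L) else c(3L, 3L, 1L)

# Convolutions run in float32 unless exact double arithmetic is requested
# (used by the finite-difference gradient checks).
conv_double <- function() isTRUE(getOption("ctvseg.double_precision", FALSE))

convk_fw <- function(W, b, x, ks) {
  d <- dim(x)
  y <- nn_conv_fw(x, d, W, b, ks, conv_double())
  dim(y) <- c(d[1:3], ncol(W))
  y
}

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

conv1x1_fw <- function(W, b, x) {
  d <- dim(x)
  y <- nn_mix_fw(x, d, W, b)
  dim(y) <- c(d[1:3], ncol(W))
  y
}

conv1x1_bw <- function(W, x, dy) {
  d <- dim(x)
  r <- nn_mix_bw(x, d, W, dy)
  dim(r$dx) <- d
  r
}

norm_eps <- 1e-5

norm_fw <- function(p, x) {
  d <- dim(x)
  r <- nn_norm_fw(x, d, p$gamma, p$beta, norm_eps)
  dim(r$y) <- d
  list(y = r$y, xhat = r$xhat, istd = r$istd, d = d)
}

norm_bw <- function(p, cache, dy) {
  r <- nn_norm_bw(cache$xhat, cache$d, p$gamma, cache$istd, dy)
  dim(r$dx) <- cache$d
  list(dgamma = r$dgamma, dbeta = r$dbeta, dx = r$dx)
}

block_fw <- function(pb, x, ks) {
  c1 <- convk_fw(pb$conv1$W, pb$conv1$b, x, ks)
  n1 <- norm_fw(pb$n1, c1)
  r1 <- nn_relu(n1$y); dim(r1) <- dim(c1)
  c2 <- convk_fw(pb$conv2$W, pb$conv2$b, r1, ks)
  n2 <- norm_fw(pb$n2, c2)
  y <- nn_relu(n2$y); dim(y) <- dim(c2)
  list(y = y, x = x, n1 = n1, r1 = r1, n2 = n2)
}

block_bw <- function(pb, cache, dy, ks) {
  dn2 <- nn_relu_bw(dy, cache$n2$y)
  b2 <- norm_bw(pb$n2, cache$n2, dn2)
  g2 <- nn_conv_bw(cache$r1, dim(cache$r1), pb$conv2$W, ks, b2$dx, conv_double())
  dr1 <- g2$dx
  dn1 <- nn_relu_bw(dr1, cache$n1$y)
  b1 <- norm_bw(pb$n1, cache$n1, dn1)
  g1 <- nn_conv_bw(cache$x, dim(cache$x), pb$conv1$W, ks, b1$dx, conv_double())
  dx <- g1$dx; dim(dx) <- dim(cache$x)
  list(dx = dx,
       grads = list(conv1 = list(W = g1$dW, b = g1$db),
                    n1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                    conv2 = list(W = g2$dW, b = g2$db),
                    n2 = list(gamma = b2$dgamma, beta = b2$dbeta)))
}

dropout_fw <- function(x, rate, active) {
  if (!active || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  y <- x * mask; dim(y) <- dim(x)
  list(y = y, mask = mask)
}

# Pooling factors per level given the input spatial size.  In-plane axes
# must be divisible by 2^(depth-1); the SI axis halves only while even.
pool_plan <- function(spec, sdim) {
  need <- 2L^(spec$depth - 1L)
  ax <- c("x", "y")
  for (a in 1:2) if (sdim[a] %% need != 0L)
    ctv_stop("ctv_error_shape",
             sprintf("input %s size %d is not divisible by %d (depth %d)",
                     ax[a], sdim[a], need, spec$depth))
  plan <- vector("list", spec$depth - 1L)
  cur <- sdim
  for (l in seq_len(spec$depth - 1L)) {
    f <- c(2L, 2L, if (spec$dims == 3L && cur[3] %% 2L == 0L && cur[3] > 1L) 2L else 1L)
    plan[[l]] <- f
    cur <- cur %/% f
  }
  plan
}

model_forward <- function(model, x, dropout_active = FALSE, need_cache = FALSE) {
  spec <- model$spec; pp <- model$params
  ks <- net_kernel(spec)
  sdim <- dim(x)[1:3]
  plan <- pool_plan(spec, sdim)
  enc_caches <- vector("list", spec$depth)
  pool_caches <- vector("list", spec$depth - 1L)
  cur <- x
  for (l in seq_len(spec$depth)) {
    bc <- block_fw(pp$enc[[l]], cur, ks)
    enc_caches[[l]] <- bc
    cur <- bc$y
    if (l < spec$depth) {
      pl <- nn_pool_fw(cur, dim(cur), plan[[l]])
      pool_caches[[l]] <- list(idx = pl$idx, xdim = dim(cur))
      cur <- pl$y
      dim(cur) <- c(dim(bc$y)[1:3] %/% plan[[l]], dim(bc$y)[4])
    }
  }
  dob <- dropout_fw(cur, spec$dropout, dropout_active)
  cur <- dob$y
  dec_caches <- vector("list", spec$depth - 1L)
  for (l in rev(seq_len(spec$depth - 1L))) {
    dp <- pp$dec[[l]]
    f <- plan[[l]]
    g <- cur
    gU <- nn_upsample_fw(g, dim(g), f)
    dim(gU) <- c(dim(g)[1:3] * f, dim(g)[4])
    u <- conv1x1_fw(dp$up$W, dp$up$b, gU)
    skip <- enc_caches[[l]]$y
    att_cache <- NULL
    if (spec$attention) {
      a1 <- conv1x1_fw(dp$att$Wg, dp$att$bg, gU) + conv1x1_fw(dp$att$Wx, dp$att$bx, skip)
      r <- pmax(a1, 0); dim(r) <- dim(a1)
      s <- conv1x1_fw(dp$att$Wpsi, dp$att$bpsi, r)
      alpha <- 1 / (1 + exp(-s))
      C <- dim(skip)[4]
      am <- array(rep(as.vector(alpha), times = C), dim(skip))
      skip_g <- skip * am
      att_cache <- list(a1 = a1, r = r, alpha = alpha, skip = skip, am = am)
      skip <- skip_g
    }
    xin <- cat_channels(u, skip)
    bc <- block_fw(dp, xin, ks)
    do <- dropout_fw(bc$y, if (l > 1L) spec$dropout else 0, dropout_active)
    dec_caches[[l]] <- list(g = g, gU = gU, block = bc, att = att_cache,
                            f = f, drop_mask = do$mask)
    cur <- do$y
  }
  z <- conv1x1_fw(pp$final$W, pp$final$b, cur)
  p <- 1 / (1 + exp(-z))
  cache <- if (need_cache)
    list(plan = plan, enc = enc_caches, pools = pool_caches, dec = dec_caches,
         bottleneck_drop = dob$mask, head_in = cur, p = p)
  else NULL
  list(p = p, cache = cache)
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

model_backward <- function(model, cache, dp) {
  spec <- model$spec; pp <- model$params
  ks <- net_kernel(spec)
  dz <- dp * cache$p * (1 - cache$p)
  fb <- conv1x1_bw(pp$final$W, cache$head_in, dz)
  grads <- list(enc = vector("list", spec$depth),
                dec = vector("list", spec$depth - 1L),
                final = list(W = fb$dW, b = fb$db))
  dskip <- vector("list", spec$depth)
  dcur <- fb$dx
  for (l in seq_len(spec$depth - 1L)) {
    dc <- cache$dec[[l]]
    dp_ <- pp$dec[[l]]
    if (!is.null(dc$drop_mask)) { dcur <- dcur * dc$drop_mask; dim(dcur) <- dim(dc$block$y) }
    bb <- block_bw(dp_, dc$block, dcur, ks)
    C <- ncol(dp_$up$W)
    din <- bb$dx
    du <- din[, , , seq_len(C), drop = FALSE]
    dskip_g <- din[, , , C + seq_len(C), drop = FALSE]
    ub <- conv1x1_bw(dp_$up$W, dc$gU, du)
    g_dec <- c(list(up = list(W = ub$dW, b = ub$db)), bb$grads)
    dgU <- ub$dx
    if (spec$attention) {
      at <- dc$att; ap <- dp_$att
      dskip_l <- dskip_g * at$am; dim(dskip_l) <- dim(dskip_g)
      dalpha <- rowSums(matrix(dskip_g * at$skip, ncol = C))
      ds <- dalpha * as.vector(at$alpha) * (1 - as.vector(at$alpha))
      ds <- array(ds, dim(at$alpha))
      pb <- conv1x1_bw(ap$Wpsi, at$r, ds)
      da1 <- pb$dx * (at$a1 > 0); dim(da1) <- dim(at$a1)
      gb <- conv1x1_bw(ap$Wg, dc$gU, da1)
      xb <- conv1x1_bw(ap$Wx, at$skip, da1)
      g_dec$att <- list(Wg = gb$dW, bg = gb$db, Wx = xb$dW, bx = xb$db,
                        Wpsi = pb$dW, bpsi = pb$db)
      dgU <- dgU + gb$dx
      dskip[[l]] <- dskip_l + xb$dx
    } else {
      dskip[[l]] <- dskip_g
    }
    grads$dec[[l]] <- g_dec
    dg <- nn_upsample_bw(dgU, dim(dc$g), dc$f)
    dim(dg) <- dim(dc$g)
    dcur <- dg
  }
  if (!is.null(cache$bottleneck_drop)) {
    dcur <- dcur * cache$bottleneck_drop
    dim(dcur) <- dim(cache$enc[[spec$depth]]$y)
  }
  dfeat <- dcur
  for (l in rev(seq_len(spec$depth))) {
    if (l < spec$depth) {
      dfeat <- dfeat + dskip[[l]]
      dim(dfeat) <- dim(cache$enc[[l]]$y)
    }
    bb <- block_bw(pp$enc[[l]], cache$enc[[l]], dfeat, ks)
    grads$enc[[l]] <- bb$grads
    if (l > 1L) {
      pl <- cache$pools[[l - 1L]]
      dfeat <- nn_pool_bw(pl$idx, bb$dx, pl$xdim)
      dfeat <- nn_pool_bw_reshape(dfeat, pl$xdim)
    }
  }
  grads
}

nn_pool_bw_reshape <- function(dx, xdim) { dim(dx) <- xdim; dx }

as_net_input <- function(input) {
  if (inherits(input, "ctv_volume")) {
    d <- dim(input$data)
    array(as.numeric(input$data), c(d, 1L))
  } else if (is.matrix(input)) {
    array(as.numeric(input), c(dim(input), 1L, 1L))
  } else if (is.array(input) && length(dim(input)) == 3L) {
    array(as.numeric(input), c(dim(input), 1L))
  } else {
    ctv_stop("ctv_error_shape", "input must be a ctv_volume, 3-D array or 2-D matrix")
  }
}

#' Predict a probability map
#'
#' Runs the network on a volume (3-D models) or a 2-D image (2-D models)
#' and returns per-voxel sigmoid probabilities on the input grid.  With
#' `dropout_active = FALSE` the output is deterministic for fixed weights;
#' with `dropout_active = TRUE` the configured dropout layers stay on, as
#' used for Monte-Carlo uncertainty sampling.
#'
#' @param model a `ctv_model`.
#' @param input a `ctv_volume`, 3-D array or 2-D matrix.
#' @param dropout_active keep dropout on at inference.
#' @return A probability map: a `ctv_probmap` on the input grid for volume
#'   input, otherwise an array/matrix of probabilities.
#' @export
predict_map <- function(model, input, dropout_active = FALSE) {
  x <- as_net_input(input)
  if (model$spec$dims == 2L && dim(x)[3] != 1L)
    ctv_stop("ctv_error_shape", "2-D model requires a single-slice input")
  out <- model_forward(model, x, dropout_active = dropout_active)$p
  if (inherits(input, "ctv_volume")) {
    p <- array(out, dim(input$data))
    structure(list(data = p, spacing = input$spacing, origin = input$origin),
              class = c("ctv_probmap", "ctv_volume"))
  } else if (is.matrix(input)) {
    matrix(out, dim(input)[1], dim(input)[2])
  } else {
    array(out, dim(input))
  }
}

#' @export
predict.ctv_model <- function(object, input, dropout_active = FALSE, ...) {
  predict_map(object, input, dropout_active = dropout_active)
}

#' Threshold a probability map
#'
#' A voxel is labelled foreground iff its probability is strictly greater
#' than `t` (so a probability exactly equal to `t` maps to background).
#'
#' @param prob a `ctv_probmap`, array or matrix of probabilities.
#' @param t threshold in (0, 1); default 0.5.
#' @return A label map (for `ctv_probmap` input) or 0/1 array.
#' @export
threshold_map <- function(prob, t = 0.5) {
  if (t <= 0 || t >= 1)
    ctv_stop("ctv_error_parameter", "threshold t must lie strictly inside (0, 1)")
  if (inherits(prob, "ctv_probmap")) {
    as_labelmap(array(as.integer(prob$data > t), dim(prob$data)),
                prob$spacing, prob$origin)
  } else {
    out <- prob
    out[] <- as.integer(prob > t)
    out
  }
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the architecture specification and all weights.
#' @param model a `ctv_model`.
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  if (!dir.exists(dirname(path)))
    ctv_stop("ctv_error_io", sprintf("cannot write '%s': directory does not exist", path))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    ctv_stop("ctv_error_io", sprintf("checkpoint '%s' does not exist", path))
  m <- readRDS(path)
  if (!inherits(m, "ctv_model"))
    ctv_stop("ctv_error_format", sprintf("'%s' is not a model checkpoint", path))
  m
}
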