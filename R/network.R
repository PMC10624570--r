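#' 3D U-Net architecture specification
#'
#' An encoder-decoder with `n_levels` resolution levels (so `n_levels - 1`
#' down- and up-sampling operations). Every level applies two 3x3x3
#' convolutions, each followed by instance normalization and PReLU
#' activation; downsampling is a stride-2 convolution and upsampling a
#' transposed (up-)convolution, with skip connections by channel
#' concatenation. The head is either a 1-channel sigmoid segmentation head
#' or a 3-channel linear displacement head whose output feeds the spatial
#' transformer.
#'
#' @param n_levels resolution levels (>= 2; clinical-scale default 5).
#' @param base_channels channels at the first level (doubled per level).
#' @param head "segmentation" or "displacement".
#' @param in_channels input channels (1 for segmentation, 2 for the
#'   planning/fraction concatenation of the displacement network). Defaults
#'   to match the head.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_levels = 5, base_channels = 4,
                         head = c("segmentation", "displacement"),
                         in_channels = NULL) {
  head <- match.arg(head)
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (base_channels < 1) stop("base_channels must be >= 1")
  in_channels <- in_channels %||% if (head == "segmentation") 1L else 2L
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 head = head, in_channels = as.integer(in_channels),
                 out_channels = if (head == "segmentation") 1L else 3L),
            class = "network_spec")
}

spec_channels <- function(spec) spec$base_channels * 2^(0:(spec$n_levels - 1))

check_divisible <- function(d, spec) {
  f <- 2^(spec$n_levels - 1)
  if (any(d %% f != 0)) {
    stop(sprintf("input shape %s is not divisible by 2^(n_levels-1) = %d",
                 paste(d, collapse = "x"), f))
  }
}

init_conv_unit <- function(ci, co, k = 3) {
  list(w = array(rnorm(k^3 * ci * co, 0, sqrt(2 / (k^3 * ci))), c(k, k, k, ci, co)),
       b = numeric(co), gamma = rep(1, co), beta = numeric(co),
       alpha = rep(0.25, co))
}

#' Build a 3D U-Net model
#'
#' Deterministic initialization under the seed; the parameter count is a pure
#' function of the spec (He-scaled convolution weights, unit instance-norm
#' gain, PReLU slope 0.25, near-zero head).
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed for initialization.
#' @return An object of class `unet3d`.
#' @export
build_network <- function(spec, seed = 1) {
  ch <- spec_channels(spec)
  L <- spec$n_levels
  params <- with_seed(seed, {
    enc <- lapply(seq_len(L), function(i) {
      cin <- if (i == 1) spec$in_channels else ch[i]
      list(conv1 = init_conv_unit(cin, ch[i]), conv2 = init_conv_unit(ch[i], ch[i]),
           down = if (i < L) init_conv_unit(ch[i], ch[i + 1]) else NULL)
    })
    dec <- if (L >= 2) lapply(seq_len(L - 1), function(i) {
      list(up = list(w = array(rnorm(8 * ch[i + 1] * ch[i], 0, sqrt(2 / (8 * ch[i + 1]))),
                               c(2, 2, 2, ch[i + 1], ch[i])),
                     b = numeric(ch[i])),
           conv1 = init_conv_unit(2 * ch[i], ch[i]),
           conv2 = init_conv_unit(ch[i], ch[i]))
    }) else list()
    head_sd <- if (spec$head == "displacement") 1e-3 else sqrt(1 / ch[1])
    list(enc = enc, dec = dec,
         head = list(w = matrix(rnorm(ch[1] * spec$out_channels, 0, head_sd),
                                ch[1], spec$out_channels),
                     b = numeric(spec$out_channels)))
  })
  structure(list(spec = spec, params = params, seed = seed, history = NULL),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  cat(sprintf("<unet3d> %s head, %d levels, base %d channels, %d parameters\n",
              x$spec$head, x$spec$n_levels, x$spec$base_channels, n_params(x)))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, final loss %.4f\n", nrow(x$history),
                x$history$total[nrow(x$history)]))
  }
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `unet3d` model.
#' @return Integer parameter count.
#' @export
n_params <- function(model) length(unlist(model$params))

# ---- layer primitives (instance norm / PReLU in R, convs in C++) -----------

in_fw <- function(x, gamma, beta) {
  d <- dim(x); C <- d[4]; nsp <- prod(d[1:3])
  m <- matrix(x, ncol = C)
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  istd <- 1 / sqrt(v + 1e-5)
  xhat <- sweep(sweep(m, 2, mu), 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(y, d), xhat = xhat, istd = istd)
}

in_bw <- function(gy, cache, gamma) {
  d <- dim(gy); C <- d[4]; nsp <- prod(d[1:3])
  gm <- matrix(gy, ncol = C)
  dgamma <- colSums(gm * cache$xhat)
  dbeta <- colSums(gm)
  dxhat <- sweep(gm, 2, gamma, `*`)
  s1 <- colSums(dxhat); s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat * nsp - matrix(s1, nsp, C, byrow = TRUE) -
                sweep(cache$xhat, 2, s2, `*`),
              2, cache$istd / nsp, `*`)
  list(gx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

prelu_fw <- function(x, alpha) {
  d <- dim(x); C <- d[4]
  a <- array(rep(alpha, each = prod(d[1:3])), d)
  list(y = ifelse(x > 0, x, a * x), x = x)
}

prelu_bw <- function(gy, cache, alpha) {
  d <- dim(gy); C <- d[4]; nsp <- prod(d[1:3])
  a <- array(rep(alpha, each = nsp), d)
  neg <- cache$x <= 0
  gx <- ifelse(neg, a * gy, gy)
  dalpha <- colSums(matrix(gy * cache$x * neg, ncol = C))
  list(gx = gx, dalpha = dalpha)
}

conv_unit_fw <- function(x, pr, stride) {
  y <- cp_conv3d_fw(as.numeric(x), dim(x), as.numeric(pr$w), pr$b, stride)
  inr <- in_fw(y, pr$gamma, pr$beta)
  ar <- prelu_fw(inr$y, pr$alpha)
  list(y = ar$y, cache = list(x = x, stride = stride,
                              inc = list(xhat = inr$xhat, istd = inr$istd),
                              prc = list(x = ar$x)))
}

conv_unit_bw <- function(gy, cache, pr) {
  pb <- prelu_bw(gy, cache$prc, pr$alpha)
  ib <- in_bw(pb$gx, cache$inc, pr$gamma)
  cb <- cp_conv3d_bw(as.numeric(cache$x), dim(cache$x), as.numeric(pr$w),
                     as.numeric(ib$gx), cache$stride)
  list(gx = cb$gx,
       g = list(w = array(cb$gw, dim(pr$w)), b = cb$gb,
                gamma = ib$dgamma, beta = ib$dbeta, alpha = pb$dalpha))
}

# Full forward pass; returns head output (pre-sigmoid for segmentation) and,
# if requested, the cache needed for the backward pass.
unet_forward <- function(model, x, want_cache = FALSE) {
  spec <- model$spec; P <- model$params; L <- spec$n_levels
  d <- dim(x)[1:3]
  check_divisible(d, spec)
  cache <- list(enc = vector("list", L), down = vector("list", L - 1),
                dec = vector("list", max(L - 1, 0)))
  skips <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    c1 <- conv_unit_fw(cur, P$enc[[i]]$conv1, 1L)
    c2 <- conv_unit_fw(c1$y, P$enc[[i]]$conv2, 1L)
    skips[[i]] <- c2$y
    if (want_cache) cache$enc[[i]] <- list(c1 = c1$cache, c2 = c2$cache)
    cur <- c2$y
    if (i < L) {
      dn <- conv_unit_fw(cur, P$enc[[i]]$down, 2L)
      if (want_cache) cache$down[[i]] <- dn$cache
      cur <- dn$y
    }
  }
  for (i in rev(seq_len(L - 1))) {
    up <- cp_convt3d_fw(as.numeric(cur), dim(cur),
                        as.numeric(P$dec[[i]]$up$w), P$dec[[i]]$up$b)
    cat4 <- array(c(up, skips[[i]]), c(dim(up)[1:3], dim(up)[4] + dim(skips[[i]])[4]))
    c1 <- conv_unit_fw(cat4, P$dec[[i]]$conv1, 1L)
    c2 <- conv_unit_fw(c1$y, P$dec[[i]]$conv2, 1L)
    if (want_cache) {
      cache$dec[[i]] <- list(xin = cur, up_ch = dim(up)[4],
                             c1 = c1$cache, c2 = c2$cache)
    }
    cur <- c2$y
  }
  nsp <- prod(dim(cur)[1:3])
  hm <- matrix(cur, ncol = dim(cur)[4])
  out <- sweep(hm %*% P$head$w, 2, P$head$b, `+`)
  out <- array(out, c(dim(cur)[1:3], spec$out_channels))
  if (want_cache) {
    cache$head_in <- cur
    list(out = out, cache = cache)
  } else {
    list(out = out)
  }
}

# Backward pass from the gradient of the loss wrt the head output.
unet_backward <- function(model, cache, gout) {
  spec <- model$spec; P <- model$params; L <- spec$n_levels
  G <- list(enc = vector("list", L), dec = vector("list", max(L - 1, 0)))
  hin <- cache$head_in
  ch1 <- dim(hin)[4]
  gm <- matrix(gout, ncol = spec$out_channels)
  hm <- matrix(hin, ncol = ch1)
  G$head <- list(w = t(hm) %*% gm, b = colSums(gm))
  gcur <- array(gm %*% t(P$head$w), dim(hin))
  gskip <- vector("list", L)
  for (i in seq_len(L - 1)) {
    dc <- cache$dec[[i]]
    b2 <- conv_unit_bw(gcur, dc$c2, P$dec[[i]]$conv2)
    b1 <- conv_unit_bw(b2$gx, dc$c1, P$dec[[i]]$conv1)
    up_ch <- dc$up_ch
    gcat <- b1$gx
    gup <- gcat[, , , seq_len(up_ch), drop = FALSE]
    gskip[[i]] <- gcat[, , , up_ch + seq_len(dim(gcat)[4] - up_ch), drop = FALSE]
    ub <- cp_convt3d_bw(as.numeric(dc$xin), dim(dc$xin),
                        as.numeric(P$dec[[i]]$up$w), as.numeric(gup))
    G$dec[[i]] <- list(up = list(w = array(ub$gw, dim(P$dec[[i]]$up$w)), b = ub$gb),
                       conv1 = b1$g, conv2 = b2$g)
    gcur <- ub$gx
  }
  for (i in rev(seq_len(L))) {
    if (i < L) {
      db <- conv_unit_bw(gcur, cache$down[[i]], P$enc[[i]]$down)
      gsk <- db$gx + (gskip[[i]] %||% 0)
      gdown <- db$g
    } else {
      gsk <- gcur
      gdown <- NULL
    }
    b2 <- conv_unit_bw(gsk, cache$enc[[i]]$c2, P$enc[[i]]$conv2)
    b1 <- conv_unit_bw(b2$gx, cache$enc[[i]]$c1, P$enc[[i]]$conv1)
    # order must mirror the parameter tree (conv1, conv2, down)
    G$enc[[i]] <- list(conv1 = b1$g, conv2 = b2$g, down = gdown)
    gcur <- b1$gx
  }
  G
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Predict a foreground-probability volume
#'
#' Runs the segmentation network on a (z-scored) image and returns per-voxel
#' foreground probabilities in [0, 1]; binarize at 0.5 for evaluation.
#'
#' @param model a `unet3d` with segmentation head.
#' @param image a [volume_image()] with shape divisible per the spec.
#' @return A [volume_image()] of probabilities.
#' @export
predict_segmentation <- function(model, image) {
  if (model$spec$head != "segmentation") stop("model does not have a segmentation head")
  x <- array(normalize_volume(image$data), c(dim(image$data), 1))
  out <- unet_forward(model, x)$out
  volume_image(array(sigmoid(out[, , , 1]), dim(image$data)),
               image$spacing, image$origin)
}

#' Predict a dense displacement field between planning and fraction image
#'
#' The two (z-scored) images are concatenated as a 2-channel input; the
#' 3-channel head output (voxel-unit offsets) is converted to millimetres in
#' the backward-warping convention on the fraction grid.
#'
#' @param model a `unet3d` with displacement head.
#' @param planning,fraction [volume_image()] objects on one grid.
#' @return A [displacement_field()].
#' @export
predict_ddf <- function(model, planning, fraction) {
  if (model$spec$head != "displacement") stop("model does not have a displacement head")
  stopifnot_same_grid(dim(planning$data), dim(fraction$data),
                      "planning and fraction images")
  x <- array(c(normalize_volume(planning$data), normalize_volume(fraction$data)),
             c(dim(planning$data), 2))
  out <- unet_forward(model, x)$out
  for (k in 1:3) out[, , , k] <- out[, , , k] * fraction$spacing[k]
  displacement_field(out, fraction$spacing, fraction$origin)
}

#' Differentiable spatial transformer (grid interpolator)
#'
#' Warps a volume (image or mask-probability) by a displacement field with
#' trilinear interpolation and border clamping. Numerically identical to
#' [warp_image()] with linear interpolation, but implemented so its gradient
#' with respect to the field is available to the training loop (it has no
#' learnable parameters itself).
#'
#' @param moving a [volume_image()] or plain 3D array.
#' @param ddf a [displacement_field()] on the output grid.
#' @param mode "linear" or "nearest".
#' @return Same type as `moving`, warped.
#' @export
spatial_transform <- function(moving, ddf, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  arr <- if (inherits(moving, "volume_image")) moving$data else moving
  stopifnot_same_grid(dim(arr), dim(ddf$vectors)[1:3], "moving volume and ddf")
  out <- cp_warp_fw(as.numeric(arr), dim(arr), as.numeric(ddf_to_voxel_units(ddf)),
                    if (mode == "nearest") 1L else 0L)
  out <- array(out, dim(arr))
  if (inherits(moving, "volume_image")) {
    volume_image(out, ddf$spacing, ddf$origin)
  } else out
}

# Gradient of sum(gout * spatial_transform(moving, ddf)) wrt the mm-unit ddf.
spatial_transform_grad_ddf <- function(moving, ddf, gout) {
  arr <- if (inherits(moving, "volume_image")) moving$data else moving
  g <- cp_warp_bw_ddf(as.numeric(arr), dim(arr),
                      as.numeric(ddf_to_voxel_units(ddf)), as.numeric(gout))
  g <- array(g, c(dim(arr), 3))
  for (k in 1:3) g[, , , k] <- g[, , , k] / ddf$spacing[k]   # voxel -> mm chain
  g
}
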