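# Orientation-specialized 2D encoder-decoder network.
#
# Feature tensors are (C, H, W, N) arrays (channels first, batch last).
# 3x3 convolutions are evaluated as im2col + GEMM; all convolutions are
# same-padded and bias-free; every double-convolution block carries a
# parallel 1x1 convolution from the block input added to the block output
# (a residual path that also adapts the channel count); batch
# normalization follows every convolution in a block. Downsampling is 2x2
# max pooling, upsampling a 2x2 stride-2 transposed convolution, and
# encoder features are concatenated to the matching decoder level.

#' Network configuration
#'
#' @param in_channels number of input channels; 3 for extended-2D patches
#'   (previous / target / next slice).
#' @param base_width filters in the first encoder block; doubled at each of
#'   the `depth` downsamplings.
#' @param depth number of 2x downsamplings; input sides must be divisible
#'   by `2^depth`.
#' @param output_mode `"sigmoid_1ch"` (single foreground probability) or
#'   `"softmax_2ch"` (background/foreground channels summing to 1).
#' @param encoder_init `NULL` for seeded random (He) initialization, or a
#'   function `params -> params` used as a pretrained-weights hook for the
#'   encoder.
#' @param seed seed for weight initialization.
#' @export
network_config <- function(in_channels = 3L, base_width = 16L, depth = 4L,
                           output_mode = c("sigmoid_1ch", "softmax_2ch"),
                           encoder_init = NULL, seed = 1L) {
  output_mode <- match.arg(output_mode)
  if (in_channels != 3L)
    e2d_stop("extended-2D networks take exactly 3 input channels",
             "e2d_config_error")
  if (depth < 1L) e2d_stop("depth must be >= 1", "e2d_config_error")
  if (!is.null(encoder_init) && !is.function(encoder_init))
    e2d_stop("encoder_init must be NULL or a function", "e2d_config_error")
  structure(list(in_channels = 3L, base_width = as.integer(base_width),
                 depth = as.integer(depth), output_mode = output_mode,
                 encoder_init = encoder_init, seed = as.integer(seed),
                 bn_eps = 1e-5, bn_momentum = 0.1),
            class = "network_config")
}

network_arch <- function(cfg) {
  D <- cfg$depth
  w <- cfg$base_width * 2L^(seq_len(D) - 1L)
  blocks <- list()
  for (l in seq_len(D))
    blocks[[paste0("enc", l)]] <- c(if (l == 1L) cfg$in_channels else w[l - 1L], w[l])
  blocks[["bott"]] <- c(w[D], cfg$base_width * 2L^D)
  for (l in seq_len(D))
    blocks[[paste0("dec", l)]] <- c(2L * w[l], w[l])
  ups <- list()
  for (l in seq_len(D))
    ups[[paste0("dec", l, ".up")]] <- c(if (l == D) cfg$base_width * 2L^D else w[l + 1L], w[l])
  out_ch <- if (cfg$output_mode == "sigmoid_1ch") 1L else 2L
  list(depth = D, widths = w, blocks = blocks, ups = ups, out_ch = out_ch)
}

he_mat <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / ncol)), nrow, ncol)
}

#' Build a network from its configuration
#'
#' Weights are initialized with seeded He-normal draws (batch-norm scale 1,
#' shift 0), so two builds from the same configuration are identical. If
#' `cfg$encoder_init` is a function it is applied to the parameter list
#' after random initialization (pretrained-encoder hook).
#'
#' @param cfg a [network_config()].
#' @return An object of class `e2d_network`.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  arch <- network_arch(cfg)
  with_seed(cfg$seed, {
    P <- list()
    bn <- list()
    for (b in names(arch$blocks)) {
      io <- arch$blocks[[b]]
      P[[paste0(b, ".conv1")]] <- he_mat(io[2], 9L * io[1])
      P[[paste0(b, ".conv2")]] <- he_mat(io[2], 9L * io[2])
      P[[paste0(b, ".res")]] <- he_mat(io[2], io[1])
      for (k in 1:2) {
        P[[paste0(b, ".bn", k, ".gamma")]] <- rep(1, io[2])
        P[[paste0(b, ".bn", k, ".beta")]] <- rep(0, io[2])
        bn[[paste0(b, ".bn", k)]] <- list(mean = rep(0, io[2]), var = rep(1, io[2]))
      }
    }
    for (u in names(arch$ups)) {
      io <- arch$ups[[u]]
      P[[u]] <- he_mat(4L * io[2], io[1])
    }
    # damped head initialization: keeps initial probabilities near 0.5 so
    # region losses (Dice/GDL) cannot saturate pixels irrecoverably through
    # the sigmoid/softmax before the features have formed
    P[["final"]] <- he_mat(arch$out_ch, arch$widths[1]) * 0.1
    if (is.function(cfg$encoder_init)) P <- cfg$encoder_init(P)
    structure(list(cfg = cfg, arch = arch, params = P, bn = bn),
              class = "e2d_network")
  })
}

#' Number of trainable parameters
#' @param model an `e2d_network`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# ---- layer primitives -------------------------------------------------

conv3_fw <- function(x, W, keep_col = TRUE) {
  d <- dim(x)
  col <- cpp_im2col(x, d[1], d[2], d[3], d[4])
  y <- W %*% col
  dim(y) <- c(nrow(W), d[2], d[3], d[4])
  list(y = y, col = if (keep_col) col, d = d)
}

conv3_bw <- function(dy, W, cache) {
  d <- cache$d
  dim(dy) <- c(nrow(W), prod(d[2:4]))
  dW <- tcrossprod(dy, cache$col)
  dcol <- crossprod(W, dy)
  dx <- cpp_col2im(dcol, d[1], d[2], d[3], d[4])
  list(dx = dx, dW = dW)
}

conv1_fw <- function(x, W) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1], prod(d[2:4]))
  y <- W %*% xm
  dim(y) <- c(nrow(W), d[2], d[3], d[4])
  list(y = y, xm = xm, d = d)
}

conv1_bw <- function(dy, W, cache) {
  d <- cache$d
  dim(dy) <- c(nrow(W), prod(d[2:4]))
  dW <- tcrossprod(dy, cache$xm)
  dx <- crossprod(W, dy)
  dim(dx) <- d
  list(dx = dx, dW = dW)
}

bn_fw <- function(x, gamma, beta, state, train, eps, momentum) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1], prod(d[2:4]))
  if (!train) {
    # fused evaluation path: y = x * scale + shift per channel
    scale <- gamma / sqrt(state$var + eps)
    y <- xm * scale + (beta - state$mean * scale)
    dim(y) <- d
    return(list(y = y, cache = NULL, state = state))
  }
  mu <- rowMeans(xm)
  v <- rowMeans(xm * xm) - mu * mu
  state$mean <- (1 - momentum) * state$mean + momentum * mu
  state$var <- (1 - momentum) * state$var + momentum * v
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * invstd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d),
       state = state)
}

bn_bw <- function(dy, cache) {
  d <- cache$d
  dim(dy) <- c(d[1], prod(d[2:4]))
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$invstd * (dxhat - m1 - cache$xhat * m2)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x, keep_mask = TRUE) {
  if (!keep_mask) {
    x[x < 0] <- 0
    return(list(y = x, mask = NULL))
  }
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, mask = mask)
}

tconv_fw <- function(x, W4) {
  d <- dim(x)
  Cout <- nrow(W4) %/% 4L
  xm <- x
  dim(xm) <- c(d[1], prod(d[2:4]))
  y4 <- W4 %*% xm
  dim(y4) <- c(Cout, 2L, 2L, d[2], d[3], d[4])
  y <- aperm(y4, c(1, 2, 4, 3, 5, 6))
  dim(y) <- c(Cout, 2L * d[2], 2L * d[3], d[4])
  list(y = y, xm = xm, d = d, Cout = Cout)
}

tconv_bw <- function(dy, W4, cache) {
  d <- cache$d
  dim(dy) <- c(cache$Cout, 2L, d[2], 2L, d[3], d[4])
  dy4 <- aperm(dy, c(1, 2, 4, 3, 5, 6))
  dim(dy4) <- c(4L * cache$Cout, prod(d[2:4]))
  dW4 <- tcrossprod(dy4, cache$xm)
  dx <- crossprod(W4, dy4)
  dim(dx) <- d
  list(dx = dx, dW = dW4)
}

concat_ch <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

# ---- double-convolution block with residual 1x1 path ------------------

block_fw <- function(x, b, P, bn, train, eps, momentum) {
  c1 <- conv3_fw(x, P[[paste0(b, ".conv1")]], keep_col = train)
  b1 <- bn_fw(c1$y, P[[paste0(b, ".bn1.gamma")]], P[[paste0(b, ".bn1.beta")]],
              bn[[paste0(b, ".bn1")]], train, eps, momentum)
  r1 <- relu_fw(b1$y, keep_mask = train)
  c2 <- conv3_fw(r1$y, P[[paste0(b, ".conv2")]], keep_col = train)
  b2 <- bn_fw(c2$y, P[[paste0(b, ".bn2.gamma")]], P[[paste0(b, ".bn2.beta")]],
              bn[[paste0(b, ".bn2")]], train, eps, momentum)
  r2 <- relu_fw(b2$y, keep_mask = train)
  rs <- conv1_fw(x, P[[paste0(b, ".res")]])
  out <- r2$y + rs$y
  cache <- if (train)
    list(c1 = c1["col"], d1 = c1$d, bn1 = b1$cache, m1 = r1$mask,
         c2 = c2["col"], d2 = c2$d, bn2 = b2$cache, m2 = r2$mask,
         rs = rs[c("xm", "d")])
  list(out = out, cache = cache, bn1 = b1$state, bn2 = b2$state)
}

block_bw <- function(dout, b, P, cache, grads) {
  # residual path
  rb <- conv1_bw(dout, P[[paste0(b, ".res")]],
                 list(xm = cache$rs$xm, d = cache$rs$d))
  grads[[paste0(b, ".res")]] <- rb$dW
  # main path
  dr2 <- dout
  dr2[!cache$m2] <- 0
  b2 <- bn_bw(dr2, cache$bn2)
  grads[[paste0(b, ".bn2.gamma")]] <- b2$dgamma
  grads[[paste0(b, ".bn2.beta")]] <- b2$dbeta
  c2 <- conv3_bw(b2$dx, P[[paste0(b, ".conv2")]],
                 list(col = cache$c2$col, d = cache$d2))
  grads[[paste0(b, ".conv2")]] <- c2$dW
  dr1 <- c2$dx
  dr1[!cache$m1] <- 0
  b1 <- bn_bw(dr1, cache$bn1)
  grads[[paste0(b, ".bn1.gamma")]] <- b1$dgamma
  grads[[paste0(b, ".bn1.beta")]] <- b1$dbeta
  c1 <- conv3_bw(b1$dx, P[[paste0(b, ".conv1")]],
                 list(col = cache$c1$col, d = cache$d1))
  grads[[paste0(b, ".conv1")]] <- c1$dW
  list(dx = c1$dx + rb$dx, grads = grads)
}

# ---- full network -----------------------------------------------------

check_divisible <- function(x, depth) {
  d <- dim(x)
  if (d[2] %% 2L^depth != 0L || d[3] %% 2L^depth != 0L)
    e2d_stop(sprintf("spatial size %dx%d is not divisible by 2^%d",
                     d[2], d[3], depth), "e2d_shape_error")
}

net_forward_full <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  check_divisible(x, model$cfg$depth)
  P <- model$params
  eps <- model$cfg$bn_eps
  mom <- model$cfg$bn_momentum
  D <- model$arch$depth
  bn <- model$bn
  cache <- list()
  skips <- list()
  h <- x
  for (l in seq_len(D)) {
    b <- paste0("enc", l)
    r <- block_fw(h, b, P, bn, train, eps, mom)
    bn[[paste0(b, ".bn1")]] <- r$bn1
    bn[[paste0(b, ".bn2")]] <- r$bn2
    cache[[b]] <- r$cache
    skips[[l]] <- r$out
    pl <- cpp_maxpool(r$out, dim(r$out)[1], dim(r$out)[2], dim(r$out)[3],
                      dim(r$out)[4])
    cache[[paste0("pool", l)]] <- list(idx = pl$idx, d = dim(r$out))
    h <- pl$y
  }
  r <- block_fw(h, "bott", P, bn, train, eps, mom)
  bn[["bott.bn1"]] <- r$bn1
  bn[["bott.bn2"]] <- r$bn2
  cache[["bott"]] <- r$cache
  h <- r$out
  for (l in rev(seq_len(D))) {
    up <- tconv_fw(h, P[[paste0("dec", l, ".up")]])
    cache[[paste0("up", l)]] <- up[c("xm", "d", "Cout")]
    h <- concat_ch(up$y, skips[[l]])
    cache[[paste0("cat", l)]] <- c(up$Cout, dim(skips[[l]])[1])
    b <- paste0("dec", l)
    r <- block_fw(h, b, P, bn, train, eps, mom)
    bn[[paste0(b, ".bn1")]] <- r$bn1
    bn[[paste0(b, ".bn2")]] <- r$bn2
    cache[[b]] <- r$cache
    h <- r$out
  }
  fin <- conv1_fw(h, P[["final"]])
  cache[["final"]] <- fin[c("xm", "d")]
  z <- fin$y
  if (model$cfg$output_mode == "sigmoid_1ch") {
    p <- 1 / (1 + exp(-z))
  } else {
    zm <- pmax(z[1, , , , drop = FALSE], z[2, , , , drop = FALSE])
    e1 <- exp(z[1, , , , drop = FALSE] - zm)
    e2 <- exp(z[2, , , , drop = FALSE] - zm)
    s <- e1 + e2
    p <- z
    p[1, , , ] <- e1 / s
    p[2, , , ] <- e2 / s
  }
  list(p = p, cache = cache, bn = bn)
}

net_backward_full <- function(model, dz, cache) {
  P <- model$params
  D <- model$arch$depth
  grads <- list()
  fb <- conv1_bw(dz, P[["final"]],
                 list(xm = cache$final$xm, d = cache$final$d))
  grads[["final"]] <- fb$dW
  dh <- fb$dx
  dskips <- vector("list", D)
  for (l in seq_len(D)) {
    b <- paste0("dec", l)
    r <- block_bw(dh, b, P, cache[[b]], grads)
    grads <- r$grads
    nch <- cache[[paste0("cat", l)]]
    dup <- r$dx[seq_len(nch[1]), , , , drop = FALSE]
    dskips[[l]] <- r$dx[nch[1] + seq_len(nch[2]), , , , drop = FALSE]
    ub <- tconv_bw(dup, P[[paste0("dec", l, ".up")]], cache[[paste0("up", l)]])
    grads[[paste0("dec", l, ".up")]] <- ub$dW
    dh <- ub$dx
  }
  r <- block_bw(dh, "bott", P, cache[["bott"]], grads)
  grads <- r$grads
  dh <- r$dx
  for (l in rev(seq_len(D))) {
    pc <- cache[[paste0("pool", l)]]
    dpool <- cpp_maxpool_bw(dh, pc$idx, pc$d[1], pc$d[2], pc$d[3], pc$d[4])
    dblock <- dpool + dskips[[l]]
    b <- paste0("enc", l)
    r <- block_bw(dblock, b, P, cache[[b]], grads)
    grads <- r$grads
    dh <- r$dx
  }
  grads
}

#' Forward pass through a network
#'
#' In evaluation mode (the default) batch-norm uses its running statistics
#' and the pass is a deterministic pure function of the inputs.
#'
#' @param model an `e2d_network` from [build_network()].
#' @param x input array `(3, H, W)` or `(3, H, W, N)`; `H` and `W` must be
#'   divisible by `2^depth`.
#' @return Probability array `(out_channels, H, W, N)`; sigmoid output lies
#'   in (0, 1), softmax channels sum to 1 at every pixel.
#' @export
network_forward <- function(model, x) {
  stopifnot(inherits(model, "e2d_network"))
  net_forward_full(model, x, train = FALSE)$p
}

# Foreground probability maps (H, W, N) for a batch of extended slices,
# dispatching on the model class so that stub models can stand in for a
# trained network in pipeline tests.
predict_probs <- function(model, x) UseMethod("predict_probs")

#' @export
predict_probs.e2d_network <- function(model, x) {
  p <- network_forward(model, x)
  d <- dim(p)
  if (model$cfg$output_mode == "sigmoid_1ch")
    array(p[1, , , ], d[2:4])
  else
    array(p[2, , , ], d[2:4])
}

#' Stub models for pipeline testing
#'
#' `stub_identity_model` returns the center input channel unchanged;
#' `stub_constant_model` returns a constant probability everywhere. Both
#' honour the crop-divisibility contract through their `depth`.
#'
#' @param depth downsampling depth the stub pretends to have.
#' @param value constant probability for `stub_constant_model`.
#' @export
stub_identity_model <- function(depth = 4L) {
  structure(list(cfg = list(depth = as.integer(depth))),
            class = c("stub_identity", "e2d_stub"))
}

#' @rdname stub_identity_model
#' @export
stub_constant_model <- function(value = 0.5, depth = 4L) {
  structure(list(cfg = list(depth = as.integer(depth)), value = value),
            class = c("stub_constant", "e2d_stub"))
}

#' @export
predict_probs.stub_identity <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  array(x[2, , , ], dim(x)[2:4])
}

#' @export
predict_probs.stub_constant <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  array(model$value, dim(x)[2:4])
}

#' Save / load a trained network
#'
#' @param model an `e2d_network`.
#' @param path file path (`.rds`).
#' @export
save_network <- function(model, path) {
  obj <- unclass(model)
  obj$cfg <- unclass(obj$cfg)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  obj$cfg <- structure(obj$cfg, class = "network_config")
  structure(obj, class = "e2d_network")
}

#' @export
print.e2d_network <- function(x, ...) {
  cat(sprintf("<e2d_network> width %d, depth %d, %s output, %d parameters\n",
              x$cfg$base_width, x$cfg$depth, x$cfg$output_mode,
              n_parameters(x)))
  invisible(x)
}
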