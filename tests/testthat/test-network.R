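test_that("network output honours shape and range contracts", {
  m <- build_network(network_config(base_width = 4, depth = 2, seed = 1))
  x <- array(stats::runif(3 * 16 * 16 * 2), c(3, 16, 16, 2))
  p <- network_forward(m, x)
  expect_identical(dim(p), c(1L, 16L, 16L, 2L))
  expect_true(all(p > 0 & p < 1))
  # all-zero input: finite outputs in (0,1)
  p0 <- network_forward(m, array(0, c(3, 16, 16, 1)))
  expect_true(all(is.finite(p0)) && all(p0 > 0 & p0 < 1))
  # softmax head: channels sum to 1 everywhere
  ms <- build_network(network_config(base_width = 4, depth = 2,
                                     output_mode = "softmax_2ch", seed = 1))
  ps <- network_forward(ms, x)
  expect_equal(array(ps[1, , , ] + ps[2, , , ], dim(ps)[2:4]),
               array(1, dim(ps)[2:4]), tolerance = 1e-12)
  # non-divisible side is rejected before compute
  expect_error(network_forward(m, array(0, c(3, 15, 16, 1))),
               class = "e2d_shape_error")
})

test_that("builds are seed-deterministic and eval-mode forward is pure", {
  cfg <- network_config(base_width = 4, depth = 2, seed = 7)
  m1 <- build_network(cfg)
  m2 <- build_network(cfg)
  expect_identical(m1$params, m2$params)
  x <- array(stats::runif(3 * 16 * 16 * 2), c(3, 16, 16, 2))
  expect_identical(network_forward(m1, x), network_forward(m1, x))
  # a batch of two identical patches yields identical outputs
  x2 <- array(x[, , , c(1, 1)], c(3, 16, 16, 2))
  p <- network_forward(m1, x2)
  expect_equal(p[, , , 1], p[, , , 2], tolerance = 1e-12)
})

test_that("parameter count is a deterministic function of the configuration", {
  count_for <- function(base_width, depth, out_ch) {
    w <- base_width * 2^(seq_len(depth) - 1)
    widths_in <- c(3, w[-depth])
    n <- 0
    blocks <- rbind(cbind(widths_in, w),                       # encoders
                    c(w[depth], base_width * 2^depth),         # bottleneck
                    cbind(2 * w, w))                           # decoders
    for (r in seq_len(nrow(blocks))) {
      ci <- blocks[r, 1]; co <- blocks[r, 2]
      n <- n + co * 9 * ci + co * 9 * co + co * ci + 4 * co    # convs+res+bn
    }
    prev <- c(w[-1], base_width * 2^depth)
    n <- n + sum(4 * w * prev)                                 # up-convs
    unname(n + out_ch * base_width)                            # final 1x1
  }
  for (bw in c(4, 8)) {
    for (d in 2:3) {
      m <- build_network(network_config(base_width = bw, depth = d, seed = 1))
      expect_identical(n_parameters(m), count_for(bw, d, 1))
    }
  }
  ms <- build_network(network_config(base_width = 4, depth = 2,
                                     output_mode = "softmax_2ch", seed = 1))
  expect_identical(n_parameters(ms), count_for(4, 2, 2))
})

test_that("backpropagation matches central finite differences through the whole net", {
  m <- build_network(network_config(base_width = 2, depth = 2, seed = 3))
  x <- array(stats::runif(3 * 8 * 8 * 2), c(3, 8, 8, 2))
  y <- array(as.integer(stats::runif(8 * 8 * 2) > 0.7), c(8, 8, 2))
  loss_of <- function(model) {
    fw <- e2dseg:::net_forward_full(model, x, train = TRUE)
    dice_loss(array(fw$p[1, , , ], dim(fw$p)[2:4]), y)
  }
  fw <- e2dseg:::net_forward_full(m, x, train = TRUE)
  pf <- array(fw$p[1, , , ], dim(fw$p)[2:4])
  dz <- dice_loss_grad(pf, y) * pf * (1 - pf)
  dim(dz) <- dim(fw$p)
  grads <- e2dseg:::net_backward_full(m, dz, fw$cache)
  set.seed(1)
  for (nm in sample(names(m$params), 12)) {
    i <- sample.int(length(m$params[[nm]]), 1)
    eps <- 1e-5
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    numg <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
    expect_lt(abs(numg - grads[[nm]][i]) / max(abs(numg), abs(grads[[nm]][i]), 1e-6),
              1e-4)
  }
})

test_that("a width-8 depth-3 net can overfit one phantom slice quickly", {
  s <- tiny_subject(4)
  idx <- 32L
  es <- extract_extended_slice(s$image, "coronal", idx, depth = 3)
  x <- array(es$channels, c(3, dim(es$channels)[2], dim(es$channels)[3], 1))
  y <- array(e2dseg:::slice_2d(s$label$data, 2L, idx), c(64, 64, 1))
  m <- build_network(network_config(base_width = 8, depth = 3, seed = 2))
  opt <- e2dseg:::adam_init(m$params)
  loss <- NA
  for (step in 1:200) {
    fw <- e2dseg:::net_forward_full(m, x, train = TRUE)
    m$bn <- fw$bn
    pf <- array(fw$p[1, , , ], dim(fw$p)[2:4])
    loss <- dice_loss(pf, y)
    if (loss < 0.04) break
    dz <- dice_loss_grad(pf, y) * pf * (1 - pf)
    dim(dz) <- dim(fw$p)
    grads <- e2dseg:::net_backward_full(m, dz, fw$cache)
    upd <- e2dseg:::adam_step(m$params, grads, opt, 1e-3)
    m$params <- upd$params
    opt <- upd$state
  }
  expect_lt(loss, 0.05)
})

test_that("networks round-trip through checkpoints with config embedded", {
  m <- build_network(network_config(base_width = 4, depth = 2, seed = 5))
  f <- withr::local_tempfile(fileext = ".rds")
  save_network(m, f)
  m2 <- load_network(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$cfg$base_width, m$cfg$base_width)
  x <- array(stats::runif(3 * 16 * 16), c(3, 16, 16))
  expect_identical(network_forward(m2, x), network_forward(m, x))
})
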