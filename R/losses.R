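# Training objectives: soft Dice (squared-denominator form), generalized
# Dice over a background/foreground softmax pair, and the boundary loss
# B = alpha * GDL + (1 - alpha) * S, where S integrates predicted
# foreground probability against the target's signed boundary-distance map
# and alpha anneals linearly from 1 (first epoch) to 0 (last epoch).
# Analytic gradients are provided for every loss and are verified against
# central finite differences in the test suite.

#' Loss configuration
#'
#' @param kind `"dice"`, `"gdl"` or `"boundary"`.
#' @param epsilon numerical stabilizer used in ratios and GDL weights.
#' @param total_epochs schedule horizon for the boundary loss; the mixing
#'   weight alpha anneals from 1 at epoch 1 to 0 at `total_epochs`.
#' @export
loss_config <- function(kind = c("dice", "gdl", "boundary"),
                        epsilon = 1e-6, total_epochs = 15L) {
  kind <- match.arg(kind)
  if (epsilon <= 0) e2d_stop("epsilon must be > 0", "e2d_config_error")
  if (kind == "boundary" && total_epochs < 2L)
    e2d_stop("boundary loss needs total_epochs >= 2", "e2d_config_error")
  structure(list(kind = kind, epsilon = epsilon,
                 total_epochs = as.integer(total_epochs)),
            class = "loss_config")
}

check_same_shape <- function(p, g) {
  if (!identical(dim(p) %||% length(p), dim(g) %||% length(g)))
    e2d_stop("probability and target shapes differ", "e2d_shape_error")
}

#' Soft Dice coefficient and Dice loss
#'
#' Squared-denominator form `2 * sum(p*g) / (sum(p^2) + sum(g^2) + eps)`,
#' summing over all voxels of the (possibly batched) arrays. On binary
#' inputs this equals the classical overlap Dice `2|P&G| / (|P|+|G|)`.
#'
#' @param p probability map in \[0, 1\].
#' @param g binary target of the same shape.
#' @param epsilon numerical stabilizer.
#' @export
soft_dice <- function(p, g, epsilon = 1e-6) {
  check_same_shape(p, g)
  2 * sum(p * g) / (sum(p * p) + sum(g * g) + epsilon)
}

#' @rdname soft_dice
#' @export
dice_loss <- function(p, g, epsilon = 1e-6) 1 - soft_dice(p, g, epsilon)

#' @rdname soft_dice
#' @export
dice_loss_grad <- function(p, g, epsilon = 1e-6) {
  check_same_shape(p, g)
  num <- 2 * sum(p * g)
  den <- sum(p * p) + sum(g * g) + epsilon
  -(2 * g * den - num * 2 * p) / den^2
}

one_hot2 <- function(g) {
  d <- dim(g) %||% length(g)
  out <- array(0, c(2L, d))
  n <- length(out)
  out[seq.int(1L, n, by = 2L)] <- 1 - g
  out[seq.int(2L, n, by = 2L)] <- g
  out
}

gdl_weights <- function(g2, epsilon) {
  m <- g2
  dim(m) <- c(2L, length(g2) / 2L)
  1 / (rowSums(m) + epsilon)^2
}

gdl_parts <- function(p2, g2, epsilon) {
  w <- gdl_weights(g2, epsilon)
  pm <- p2
  gm <- g2
  dim(pm) <- c(2L, length(p2) / 2L)
  dim(gm) <- dim(pm)
  num <- sum(w * rowSums(pm * gm))
  den <- sum(w * rowSums(pm + gm))
  list(w = w, num = num, den = den)
}

#' Generalized Dice loss over a background/foreground channel pair
#'
#' `1 - 2 * sum_l w_l sum_i p_li g_li / sum_l w_l sum_i (p_li + g_li)` with
#' per-label weights `w_l = 1 / (sum_i g_li + eps)^2`, which rebalances the
#' foreground against the much larger background.
#'
#' @param p2 probability array whose first dimension has length 2
#'   (background, foreground), channels summing to 1 per pixel.
#' @param g2 one-hot target of the same shape (see [one_hot_target()]).
#' @param epsilon stabilizer in the label weights.
#' @export
generalized_dice_loss <- function(p2, g2, epsilon = 1e-6) {
  check_same_shape(p2, g2)
  if ((dim(p2) %||% length(p2))[1] != 2L)
    e2d_stop("GDL expects 2 channels in the first dimension", "e2d_shape_error")
  gp <- gdl_parts(p2, g2, epsilon)
  1 - 2 * gp$num / gp$den
}

#' @rdname generalized_dice_loss
#' @export
generalized_dice_loss_grad <- function(p2, g2, epsilon = 1e-6) {
  check_same_shape(p2, g2)
  gp <- gdl_parts(p2, g2, epsilon)
  wfull <- array(gp$w, dim(p2))  # w recycles along the first (label) dim
  -2 * (wfull * g2 * gp$den - gp$num * wfull) / gp$den^2
}

#' One-hot background/foreground encoding of a binary target
#' @param g binary array.
#' @return Array with a leading length-2 dimension (background, foreground).
#' @export
one_hot_target <- function(g) one_hot2(g)

#' Signed Euclidean distance map of a binary region
#'
#' Positive outside the region, negative strictly inside, and exactly zero
#' on the inner boundary (foreground pixels with a background neighbour).
#' Distances are Euclidean in pixel units.
#'
#' @param g binary 2D matrix, neither empty nor full.
#' @return Matrix of signed distances.
#' @export
signed_distance <- function(g) {
  if (is.null(dim(g)) || length(dim(g)) != 2L)
    e2d_stop("signed_distance expects a 2D matrix", "e2d_shape_error")
  s <- sum(g)
  if (s == 0 || s == length(g))
    e2d_stop("signed distance is undefined for an empty or full mask",
             "e2d_degenerate_error")
  outside <- as.matrix(EBImage::distmap(1 - g, metric = "euclidean"))
  inside <- as.matrix(EBImage::distmap(g, metric = "euclidean"))
  outside * (1 - g) - (inside - 1) * g
}

#' Surface (boundary-distance) loss term
#'
#' Mean over pixels of the elementwise product of the predicted foreground
#' probability with the target's signed distance map: probability mass
#' outside the target is penalized in proportion to its distance from the
#' boundary, mass inside is rewarded.
#'
#' @param p foreground probability map.
#' @param dmap signed distance map from [signed_distance()].
#' @export
surface_loss <- function(p, dmap) {
  check_same_shape(p, dmap)
  mean(dmap * p)
}

#' @rdname surface_loss
#' @export
surface_loss_grad <- function(p, dmap) {
  check_same_shape(p, dmap)
  dmap / length(p)
}

#' Linear annealing schedule for the boundary-loss mixing weight
#'
#' `alpha = (total_epochs - epoch) / (total_epochs - 1)`: exactly 1 at the
#' first epoch, exactly 0 at the last, monotone non-increasing between.
#'
#' @param epoch current epoch in `[1, total_epochs]`.
#' @param total_epochs schedule horizon (>= 2).
#' @export
alpha_schedule <- function(epoch, total_epochs) {
  if (total_epochs < 2) e2d_stop("total_epochs must be >= 2", "e2d_config_error")
  if (epoch < 1 || epoch > total_epochs)
    e2d_stop(sprintf("epoch %s outside [1, %d]", epoch, total_epochs),
             "e2d_schedule_error")
  (total_epochs - epoch) / (total_epochs - 1)
}

#' Boundary loss: annealed mix of generalized Dice and surface terms
#'
#' `B(p, g) = alpha * GDL(p, g) + (1 - alpha) * S(p, g)` with alpha from
#' [alpha_schedule()]. `p2` carries the two softmax channels; the surface
#' term operates on the foreground channel only.
#'
#' @param p2 2-channel probability array.
#' @param g binary target (without the channel dimension).
#' @param epoch,cfg current epoch and a [loss_config()] of kind
#'   `"boundary"` supplying the schedule horizon.
#' @param dmap optional precomputed [signed_distance()] of `g`.
#' @export
boundary_loss <- function(p2, g, epoch, cfg, dmap = NULL) {
  stopifnot(inherits(cfg, "loss_config"))
  a <- alpha_schedule(epoch, cfg$total_epochs)
  g2 <- one_hot2(g)
  gdl <- generalized_dice_loss(p2, g2, cfg$epsilon)
  if (a == 1) return(gdl)
  if (is.null(dmap)) dmap <- signed_distance(g)
  pf <- array(p2, dim(p2))[2, , ]
  s <- surface_loss(pf, dmap)
  a * gdl + (1 - a) * s
}

#' @rdname boundary_loss
#' @export
boundary_loss_grad <- function(p2, g, epoch, cfg, dmap = NULL) {
  stopifnot(inherits(cfg, "loss_config"))
  a <- alpha_schedule(epoch, cfg$total_epochs)
  g2 <- one_hot2(g)
  grad <- a * generalized_dice_loss_grad(p2, g2, cfg$epsilon)
  if (a < 1) {
    if (is.null(dmap)) dmap <- signed_distance(g)
    gs <- surface_loss_grad(array(p2, dim(p2))[2, , ], dmap)
    grad[2, , ] <- grad[2, , ] + (1 - a) * gs
  }
  grad
}
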