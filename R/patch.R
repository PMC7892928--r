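ORIENTATIONS <- c("sagittal", "coronal", "axial")

orientation_axis <- function(orientation) {
  match.arg(orientation, ORIENTATIONS)
  match(orientation, ORIENTATIONS)
}

#' Augmentation configuration
#'
#' Runtime augmentation draws one value per transform per patch: an
#' additive intensity shift, a rotation (degrees) and a scale change
#' (percent) applied jointly as one bilinear warp to all channels and the
#' target, and pixelwise Gaussian noise on the channels only. Targets are
#' re-binarized at 0.5 after interpolation; channel intensities are clipped
#' to \[0, 1\].
#'
#' @param intensity_shift_range,rotation_range_deg,scale_range_pct ranges
#'   from which the per-patch shift/rotation/scale are drawn uniformly.
#' @param noise_mean,noise_variance moments of the additive Gaussian noise.
#' @param enabled logical master switch.
#' @export
augment_config <- function(intensity_shift_range = c(-0.05, 0.05),
                           rotation_range_deg = c(-10, 10),
                           scale_range_pct = c(-10, 10),
                           noise_mean = 0,
                           noise_variance = 2e-4,
                           enabled = TRUE) {
  stopifnot(length(intensity_shift_range) == 2, length(rotation_range_deg) == 2,
            length(scale_range_pct) == 2, noise_variance >= 0)
  structure(list(intensity_shift_range = sort(intensity_shift_range),
                 rotation_range_deg = sort(rotation_range_deg),
                 scale_range_pct = sort(scale_range_pct),
                 noise_mean = noise_mean, noise_variance = noise_variance,
                 enabled = isTRUE(enabled)),
            class = "augment_config")
}

#' Patch sampler configuration
#'
#' @param patch_size side length of the square training patch; must be
#'   divisible by `2^depth` so it survives the network's downsampling path.
#' @param positive_fraction share of sampled patches centered on a
#'   structure-border voxel (the rest are centered anywhere in the head).
#' @param augment an [augment_config()].
#' @param depth downsampling depth of the network the patches feed.
#' @param head_threshold normalized intensity above which a voxel counts as
#'   head/brain support for negative patch centers.
#' @export
sampler_config <- function(patch_size = 64L, positive_fraction = 0.8,
                           augment = augment_config(), depth = 4L,
                           head_threshold = 0.05) {
  patch_size <- as.integer(patch_size)
  if (positive_fraction < 0 || positive_fraction > 1)
    e2d_stop("positive_fraction must be in [0, 1]", "e2d_config_error")
  if (patch_size %% 2L^depth != 0L)
    e2d_stop(sprintf("patch_size %d is not divisible by 2^%d", patch_size, depth),
             "e2d_config_error")
  structure(list(patch_size = patch_size, positive_fraction = positive_fraction,
                 augment = augment, depth = as.integer(depth),
                 head_threshold = head_threshold),
            class = "sampler_config")
}

#' Inner-border voxels of a binary mask
#'
#' A voxel is a border voxel if it is foreground and at least one of its
#' six face neighbours (or the outside of the grid) is background.
#'
#' @param m a [label_volume()] or 3D binary array.
#' @return Integer matrix with one row per border voxel (columns i, j, k);
#'   zero rows for an empty mask.
#' @export
border_voxels <- function(m) {
  d <- if (inherits(m, "label_volume")) m$data else m
  dm <- dim(d)
  has_bg <- array(FALSE, dm)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      shifted <- shift_fill(d, axis, dir, fill = 0L)
      has_bg <- has_bg | shifted == 0L
    }
  }
  which(d == 1L & has_bg, arr.ind = TRUE)
}

# Shift an array by one voxel along `axis` (dir = +1 brings in the value
# from index-1), filling the vacated face with `fill` (outside the grid).
shift_fill <- function(d, axis, dir, fill = 0L) {
  dm <- dim(d)
  n <- dm[axis]
  idx_src <- if (dir == 1L) c(1L, seq_len(n - 1L)) else c(seq.int(2L, n), n)
  args <- rep(list(quote(expr = )), 3)
  args[[axis]] <- idx_src
  out <- do.call(`[`, c(list(d), args, list(drop = FALSE)))
  face <- rep(list(quote(expr = )), 3)
  face[[axis]] <- if (dir == 1L) 1L else n
  out <- do.call(`[<-`, c(list(out), face, list(value = fill)))
  out
}

slice_2d <- function(d, axis, index) {
  args <- rep(list(quote(expr = )), 3)
  args[[axis]] <- index
  matrix(do.call(`[`, c(list(d), args, list(drop = FALSE))),
         dim(d)[-axis][1], dim(d)[-axis][2])
}

# Three neighbouring slices (index-1, index, index+1; edges replicated),
# each cropped to rows `r1` and cols `r2` of the slice plane, stacked as a
# (3, length(r1), length(r2)) channels-first array.
extended_channels <- function(d, axis, index, r1, r2) {
  n <- dim(d)[axis]
  ks <- pmin(pmax(index + (-1):1, 1L), n)
  out <- array(0, c(3L, length(r1), length(r2)))
  for (c in 1:3) out[c, , ] <- slice_2d(d, axis, ks[c])[r1, r2]
  out
}

#' Pre-computed per-subject sampling support
#'
#' Caches the structure-border coordinate list and the head-voxel indices
#' of one subject so repeated [sample_patch()] calls during training do not
#' recompute them.
#'
#' @param v normalized canonical [image_volume()].
#' @param m matching [label_volume()].
#' @param cfg a [sampler_config()].
#' @export
sampler_cache <- function(v, m, cfg = sampler_config()) {
  list(border = border_voxels(m),
       head = which(v$data > cfg$head_threshold))
}

#' Sample one extended-2D training patch
#'
#' Positive patches are centered on a uniformly drawn structure-border
#' voxel; negative patches on a uniformly drawn head voxel. The patch
#' window is clamped to lie fully inside the volume (so centers near a face
#' still yield full-size patches), and the three channels are the slices
#' below, at, and above the center along the chosen orientation axis, with
#' edge replication. The target window comes from the center slice only.
#'
#' @param v normalized canonical [image_volume()].
#' @param m matching [label_volume()].
#' @param positive logical; sample a border-centered (foreground) patch?
#' @param cfg a [sampler_config()].
#' @param orientation `"sagittal"`, `"coronal"`, `"axial"`, or `NULL` to
#'   draw one uniformly.
#' @param cache optional [sampler_cache()].
#' @return An `extended_patch`: list with `channels` (3 x p x p array),
#'   `target` (p x p binary matrix), `orientation`, `center`.
#' @export
sample_patch <- function(v, m, positive, cfg = sampler_config(),
                         orientation = NULL, cache = NULL) {
  stopifnot(inherits(v, "image_volume"), inherits(m, "label_volume"))
  if (!v$normalized)
    e2d_stop("sample_patch expects a minmax-normalized volume", "e2d_value_error")
  if (is.null(orientation)) orientation <- sample(ORIENTATIONS, 1L)
  axis <- orientation_axis(orientation)
  dm <- dim(v$data)
  if (positive) {
    border <- if (is.null(cache)) border_voxels(m) else cache$border
    if (nrow(border) == 0L)
      e2d_stop("positive patch requested on an empty mask", "e2d_sampling_error")
    center <- border[sample.int(nrow(border), 1L), ]
  } else {
    head <- if (is.null(cache)) which(v$data > cfg$head_threshold) else cache$head
    if (length(head) == 0L)
      e2d_stop("volume has no head support for negative patches",
               "e2d_sampling_error")
    center <- arrayInd(head[sample.int(length(head), 1L)], dm)[1, ]
  }
  p <- cfg$patch_size
  plane <- setdiff(1:3, axis)
  if (any(dm[plane] < p))
    e2d_stop("patch does not fit inside the slice plane", "e2d_bounds_error")
  starts <- vapply(seq_along(plane), function(i) {
    n <- dm[plane[i]]
    min(max(center[plane[i]] - (p - 1L) %/% 2L, 1L), n - p + 1L)
  }, integer(1))
  r1 <- seq.int(starts[1], length.out = p)
  r2 <- seq.int(starts[2], length.out = p)
  structure(
    list(channels = extended_channels(v$data, axis, center[axis], r1, r2),
         target = slice_2d(m$data, axis, center[axis])[r1, r2],
         orientation = orientation,
         center = unname(center)),
    class = "extended_patch")
}

#' Extract a full extended-2D slice for prediction
#'
#' At prediction time whole slices are used: the slice at `index` and its
#' two neighbours (edges replicated) are center-cropped to the largest size
#' not exceeding `crop` that is divisible by `2^depth`, and the crop
#' offsets are recorded so the network activation can be padded back to the
#' full slice exactly.
#'
#' @param v normalized canonical [image_volume()].
#' @param orientation slicing plane.
#' @param index slice index along the orientation axis (1-based).
#' @param crop maximum in-plane size (scalar or length 2); default
#'   unbounded.
#' @param depth downsampling depth the crop must accommodate.
#' @return List with `channels` (3 x t1 x t2), `offsets` (voxels cropped
#'   before the window on each in-plane axis), `slice_dim`, `index`,
#'   `orientation`.
#' @export
extract_extended_slice <- function(v, orientation, index, crop = Inf,
                                   depth = 4L) {
  stopifnot(inherits(v, "image_volume"))
  axis <- orientation_axis(orientation)
  dm <- dim(v$data)
  if (index < 1L || index > dm[axis])
    e2d_stop(sprintf("slice index %d outside [1, %d]", index, dm[axis]),
             "e2d_bounds_error")
  plane <- setdiff(1:3, axis)
  crop <- rep(crop, length.out = 2)
  step <- 2L^depth
  tgt <- vapply(1:2, function(i) {
    t_i <- step * (min(crop[i], dm[plane[i]]) %/% step)
    if (t_i < step)
      e2d_stop(sprintf("slice extent %d too small for depth %d",
                       dm[plane[i]], depth), "e2d_shape_error")
    as.integer(t_i)
  }, integer(1))
  offsets <- (dm[plane] - tgt) %/% 2L
  r1 <- seq.int(offsets[1] + 1L, length.out = tgt[1])
  r2 <- seq.int(offsets[2] + 1L, length.out = tgt[2])
  list(channels = extended_channels(v$data, axis, as.integer(index), r1, r2),
       offsets = offsets, slice_dim = dm[plane], index = as.integer(index),
       orientation = orientation)
}

# Bilinear warp of a 2D image by rotation `theta_deg` and scale factor
# `scale` about the patch center, sampling with edge clamping. Written so
# that theta = 0, scale = 1 is exactly the identity (the warp is skipped).
warp_2d <- function(img, theta_deg, scale) {
  P <- dim(img)
  th <- theta_deg * pi / 180
  ci <- (P[1] + 1) / 2
  cj <- (P[2] + 1) / 2
  i <- matrix(seq_len(P[1]), P[1], P[2])
  j <- matrix(rep(seq_len(P[2]), each = P[1]), P[1], P[2])
  u <- i - ci
  v <- j - cj
  si <- (cos(th) * u - sin(th) * v) / scale + ci
  sj <- (sin(th) * u + cos(th) * v) / scale + cj
  si <- pmin(pmax(si, 1), P[1])
  sj <- pmin(pmax(sj, 1), P[2])
  i0 <- pmin(floor(si), P[1] - 1)
  j0 <- pmin(floor(sj), P[2] - 1)
  fi <- si - i0
  fj <- sj - j0
  g <- function(ii, jj) img[cbind(as.vector(ii), as.vector(jj))]
  out <- (1 - fi) * (1 - fj) * g(i0, j0) + fi * (1 - fj) * g(i0 + 1, j0) +
    (1 - fi) * fj * g(i0, j0 + 1) + fi * fj * g(i0 + 1, j0 + 1)
  matrix(out, P[1], P[2])
}

#' Randomly augment an extended patch
#'
#' Draws one intensity shift, rotation and scale within the configured
#' ranges and applies the spatial transform identically to all three
#' channels and the target (re-binarized at 0.5), then adds the intensity
#' shift and Gaussian noise to the channels only, clipping to \[0, 1\].
#' With all ranges zero (or `enabled = FALSE`) the patch is returned
#' unchanged. The drawn values are attached as attribute `"draws"`.
#'
#' @param p an `extended_patch` from [sample_patch()].
#' @param cfg an [augment_config()].
#' @return The augmented `extended_patch`.
#' @export
augment_patch <- function(p, cfg = augment_config()) {
  stopifnot(inherits(p, "extended_patch"))
  if (!cfg$enabled) return(p)
  draw <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
  delta <- draw(cfg$intensity_shift_range)
  theta <- draw(cfg$rotation_range_deg)
  scale_pct <- draw(cfg$scale_range_pct)
  scale <- 1 + scale_pct / 100
  ch <- p$channels
  tgt <- p$target
  if (theta != 0 || scale != 1) {
    for (c in 1:3) ch[c, , ] <- warp_2d(matrix(ch[c, , ], dim(ch)[2]), theta, scale)
    tgt <- (warp_2d(tgt, theta, scale) > 0.5) + 0L
  }
  if (delta != 0) ch <- ch + delta
  if (cfg$noise_variance > 0)
    ch <- ch + stats::rnorm(length(ch), cfg$noise_mean, sqrt(cfg$noise_variance))
  ch <- pmin(pmax(ch, 0), 1)  # first argument keeps the dim attribute
  out <- p
  out$channels <- ch
  out$target <- tgt
  attr(out, "draws") <- c(intensity = delta, rotation = theta, scale = scale_pct)
  out
}
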