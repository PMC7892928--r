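#' Consensus configuration
#'
#' @param threshold binarization cut in (0, 1); voxels with averaged
#'   activation strictly greater than the threshold become foreground
#'   (voxels exactly at the threshold are background).
#' @param max_components connected components retained after binarization.
#' @export
consensus_config <- function(threshold = 0.5, max_components = 2L) {
  if (threshold <= 0 || threshold >= 1)
    e2d_stop("threshold must be in (0, 1)", "e2d_config_error")
  structure(list(threshold = threshold,
                 max_components = as.integer(max_components)),
            class = "consensus_config")
}

activation_volume <- function(data, orientation) {
  structure(list(data = data, orientation = orientation),
            class = "activation_volume")
}

#' Slice-wise prediction of one orientation's activation volume
#'
#' For every slice along the orientation axis, the extended slice (center
#' crop recorded by [extract_extended_slice()]) is pushed through the
#' model and the resulting foreground probabilities are written back at
#' the recorded crop offsets; voxels outside the crop window stay exactly
#' 0, so the activation volume has the input volume's shape.
#'
#' @param model an `e2d_network` or stub model.
#' @param v normalized canonical [image_volume()].
#' @param orientation slicing plane the model is specialized for.
#' @param batch_size slices forwarded per batch.
#' @return An `activation_volume` with values in \[0, 1\].
#' @export
predict_orientation <- function(model, v, orientation, batch_size = 16L) {
  stopifnot(inherits(v, "image_volume"))
  axis <- orientation_axis(orientation)
  dm <- dim(v$data)
  act <- array(0, dm)
  n_slices <- dm[axis]
  first <- extract_extended_slice(v, orientation, 1L, depth = model$cfg$depth)
  tdim <- dim(first$channels)[2:3]
  off <- first$offsets
  for (start in seq(1L, n_slices, by = batch_size)) {
    idxs <- start:min(start + batch_size - 1L, n_slices)
    x <- array(0, c(3L, tdim[1], tdim[2], length(idxs)))
    for (j in seq_along(idxs)) {
      x[, , , j] <- if (idxs[j] == 1L) first$channels else
        extract_extended_slice(v, orientation, idxs[j],
                               depth = model$cfg$depth)$channels
    }
    probs <- predict_probs(model, x)
    for (j in seq_along(idxs)) {
      args <- rep(list(quote(expr = )), 3)
      args[[axis]] <- idxs[j]
      plane <- setdiff(1:3, axis)
      args[[plane[1]]] <- seq.int(off[1] + 1L, length.out = tdim[1])
      args[[plane[2]]] <- seq.int(off[2] + 1L, length.out = tdim[2])
      act <- do.call(`[<-`, c(list(act), args, list(value = probs[, , j])))
    }
  }
  activation_volume(act, orientation)
}

#' Average the three orientation activations into a consensus
#'
#' @param a_sag,a_cor,a_ax `activation_volume`s (or bare arrays) of equal
#'   shape.
#' @return An `activation_volume` holding the voxelwise arithmetic mean.
#' @export
consensus <- function(a_sag, a_cor, a_ax) {
  arrs <- lapply(list(a_sag, a_cor, a_ax), function(a)
    if (inherits(a, "activation_volume")) a$data else a)
  if (!identical(dim(arrs[[1]]), dim(arrs[[2]])) ||
      !identical(dim(arrs[[1]]), dim(arrs[[3]])))
    e2d_stop("activation volumes must have equal shapes", "e2d_shape_error")
  # formulated so that three identical inputs reproduce the input exactly
  avg <- arrs[[1]] + (arrs[[2]] - arrs[[1]]) / 3 + (arrs[[3]] - arrs[[1]]) / 3
  activation_volume(avg, "consensus")
}

#' Binarize a consensus activation volume
#'
#' @param c an `activation_volume` (or array).
#' @param cfg a [consensus_config()].
#' @param affine affine for the resulting mask.
#' @return A [label_volume()]; voxel = 1 iff activation > threshold.
#' @export
binarize <- function(c, cfg = consensus_config(), affine = diag(4)) {
  data <- if (inherits(c, "activation_volume")) c$data else c
  label_volume((data > cfg$threshold) + 0L, affine)
}

#' Keep only the largest connected components of a 3D mask
#'
#' Components are labeled under 26-connectivity and ranked by voxel count;
#' up to `max_components` largest are retained (one, if a second is not
#' present; none, if the mask is empty). Ties at the size cut are broken
#' in favour of the component whose first voxel appears earlier in
#' column-major scan order, which makes the result deterministic.
#'
#' @param m a [label_volume()] (or binary array).
#' @param max_components number of components to keep.
#' @return A [label_volume()] of the same shape.
#' @export
keep_largest_components <- function(m, max_components = 2L) {
  data <- if (inherits(m, "label_volume")) m$data else m
  affine <- if (inherits(m, "label_volume")) m$affine else diag(4)
  dm <- dim(data)
  lab <- cpp_label3d(as.integer(data), dm[1], dm[2], dm[3])
  sizes <- tabulate(lab)
  if (length(sizes) > max_components) {
    # order by size descending, ties by smaller label id (scan order)
    keep <- order(-sizes, seq_along(sizes))[seq_len(max_components)]
    data <- array(as.integer(lab %in% keep), dm)
  }
  label_volume(data, affine)
}

#' Segment a volume with a trained three-orientation ensemble
#'
#' Full prediction chain: canonicalize, minmax-normalize, predict the
#' three orientation activation volumes slice by slice, average them,
#' threshold, keep the largest components, and reorient the mask back to
#' the input volume's native space (the output affine equals the input
#' affine).
#'
#' @param v an [image_volume()] in native space.
#' @param ensemble an `e2d_ensemble` (or named list with models `sagittal`,
#'   `coronal`, `axial`).
#' @param cfg a [consensus_config()].
#' @param return_activation also return the consensus activation (native
#'   space not applied; canonical grid) for debugging.
#' @return A [label_volume()] in native space; with `return_activation`,
#'   a list `(mask, activation)`.
#' @export
segment <- function(v, ensemble, cfg = consensus_config(),
                    return_activation = FALSE) {
  models <- if (inherits(ensemble, "e2d_ensemble")) ensemble$models else ensemble
  missing <- setdiff(ORIENTATIONS, names(models))
  if (length(missing))
    e2d_stop(sprintf("ensemble is missing orientation model(s): %s",
                     paste(missing, collapse = ", ")), "e2d_ensemble_error")
  can <- to_canonical(v)
  vn <- minmax_normalize(can$volume)
  acts <- lapply(ORIENTATIONS, function(o)
    predict_orientation(models[[o]], vn, o))
  cons <- consensus(acts[[1]], acts[[2]], acts[[3]])
  mask <- keep_largest_components(
    binarize(cons, cfg, can$volume$affine), cfg$max_components)
  native <- label_volume(invert_frame(mask$data, can$frame), v$affine)
  if (return_activation) list(mask = native, activation = cons) else native
}
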