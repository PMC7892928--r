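#' Core volumetric containers and NIfTI input/output
#'
#' An `image_volume` holds a 3D scalar grid together with its 4x4
#' grid-to-world affine, the voxel spacing derived from it, and a flag
#' recording whether the intensities have been minmax-normalized to
#' \[0, 1\]. A `label_volume` is a binary mask on the same grid.
#'
#' @param data 3D numeric array; must be finite everywhere.
#' @param affine 4x4 grid-to-world matrix (NIfTI convention, 1-based voxel
#'   indices are mapped via `affine %*% c(i - 1, j - 1, k - 1, 1)`).
#' @param normalized logical; `TRUE` only when the data are known to lie in
#'   \[0, 1\] after [minmax_normalize()].
#' @return An object of class `image_volume` with fields `data`, `affine`,
#'   `spacing` (mm per axis) and `normalized`.
#' @export
image_volume <- function(data, affine = diag(4), normalized = FALSE) {
  data <- drop_singletons(data)
  if (length(dim(data)) != 3L)
    e2d_stop("image data must be a 3D array", "e2d_dim_error")
  if (!all(is.finite(data)))
    e2d_stop("image data contains non-finite values", "e2d_value_error")
  affine <- validate_affine(affine)
  if (isTRUE(normalized) && (min(data) < 0 || max(data) > 1))
    e2d_stop("normalized volume must lie in [0, 1]", "e2d_value_error")
  structure(
    list(data = data, affine = affine,
         spacing = sqrt(colSums(affine[1:3, 1:3]^2)),
         normalized = isTRUE(normalized)),
    class = "image_volume")
}

#' @param data for `label_volume`, a 3D array with values exactly 0 or 1
#'   (logical arrays are accepted).
#' @rdname image_volume
#' @export
label_volume <- function(data, affine = diag(4)) {
  if (is.logical(data)) {
    dm <- dim(data)
    data <- array(as.integer(data), dm)
  }
  if (length(dim(data)) != 3L)
    e2d_stop("label data must be a 3D array", "e2d_dim_error")
  if (!all(data == 0 | data == 1))
    e2d_stop("label values must be exactly 0 or 1", "e2d_value_error")
  affine <- validate_affine(affine)
  structure(
    list(data = array(as.integer(data), dim(data)), affine = affine,
         spacing = sqrt(colSums(affine[1:3, 1:3]^2))),
    class = "label_volume")
}

validate_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine)))
    e2d_stop("affine must be a finite 4x4 matrix", "e2d_geometry_error")
  affine
}

drop_singletons <- function(data) {
  dm <- dim(data)
  if (is.null(dm)) e2d_stop("data must be an array", "e2d_dim_error")
  if (length(dm) > 3L) {
    if (!all(dm[-(1:3)] == 1L))
      e2d_stop(sprintf("cannot squeeze %s to 3D", paste(dm, collapse = "x")),
               "e2d_dim_error")
    data <- array(data, dm[1:3])
  }
  data
}

#' Read a 3D volume or binary mask from a NIfTI file
#'
#' Reads a NIfTI-1/2 file, squeezing trailing singleton dimensions, and
#' returns the raw intensities with the file's affine; no normalization is
#' applied. `read_label` additionally checks that the values are binary.
#'
#' @param path path to a readable NIfTI file.
#' @return An [image_volume()] (or [label_volume()]).
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) e2d_stop(
                    sprintf("cannot read NIfTI file '%s': %s",
                            path, conditionMessage(e)), "e2d_io_error"))
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  data <- array(as.numeric(img), dim(img))
  image_volume(drop_singletons(data), affine)
}

#' @rdname read_volume
#' @export
read_label <- function(path) {
  v <- read_volume(path)
  label_volume(round(v$data), v$affine)
}

#' Write an image volume to a NIfTI file
#'
#' Images are stored as float64 so that write-read round trips are exact;
#' masks (see [write_mask()]) are stored as unsigned 8-bit.
#'
#' @param v an [image_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(v, path) {
  write_nifti_array(v$data, v$affine, path, datatype = "double")
  invisible(path)
}

write_nifti_array <- function(arr, affine, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
}

#' Minmax intensity normalization to \[0, 1\]
#'
#' Rescales a volume's intensities linearly so that the minimum maps to 0
#' and the maximum to 1. Normalization is per volume over all voxels. A
#' constant volume has no intensity range and raises a degenerate-input
#' error rather than being silently zeroed.
#'
#' @param v an [image_volume()].
#' @return The normalized [image_volume()] with `normalized = TRUE`.
#' @export
minmax_normalize <- function(v) {
  stopifnot(inherits(v, "image_volume"))
  r <- range(v$data)
  if (r[2] <= r[1])
    e2d_stop("cannot minmax-normalize a constant volume", "e2d_degenerate_error")
  image_volume((v$data - r[1]) / (r[2] - r[1]), v$affine, normalized = TRUE)
}

#' Reorient a volume to the canonical anatomical axis order
#'
#' Permutes and flips the voxel axes (never resampling) so that array axis
#' 1 runs left-to-right (sagittal slicing axis), axis 2 posterior-to-anterior
#' (coronal) and axis 3 inferior-to-superior (axial) — i.e. RAS+. The
#' returned `orientation_frame` records the permutation and flips together
#' with the native affine so the transformation can be inverted exactly.
#'
#' @param v an [image_volume()] whose affine has a well-defined dominant
#'   world axis per voxel axis.
#' @return A list with elements `volume` (canonical [image_volume()]) and
#'   `frame` (an `orientation_frame`).
#' @export
to_canonical <- function(v) {
  stopifnot(inherits(v, "image_volume"))
  frame <- orientation_frame(v$affine, dim(v$data))
  vol <- image_volume(apply_frame(v$data, frame), frame$affine_canonical,
                      normalized = v$normalized)
  list(volume = vol, frame = frame)
}

orientation_frame <- function(affine, shape) {
  M <- affine[1:3, 1:3]
  if (abs(det(M)) < 1e-8)
    e2d_stop("affine is singular; orientation is undefined", "e2d_geometry_error")
  dominant <- apply(abs(M), 2, which.max)
  if (length(unique(dominant)) != 3L)
    e2d_stop("affine is too oblique: voxel axes do not map to distinct world axes",
             "e2d_geometry_error")
  # perm[r] = native axis whose dominant world axis is r
  perm <- order(dominant)
  flips <- vapply(1:3, function(r) M[r, perm[r]] < 0, logical(1))
  shape_can <- shape[perm]
  # canonical affine: permute columns, then negate flipped columns and move
  # the origin to the (former) far corner along each flipped axis
  origin <- affine[1:3, 4]
  cols <- M[, perm, drop = FALSE]
  for (r in which(flips)) {
    origin <- origin + cols[, r] * (shape_can[r] - 1)
    cols[, r] <- -cols[, r]
  }
  A <- diag(4)
  A[1:3, 1:3] <- cols
  A[1:3, 4] <- origin
  structure(list(perm = perm, flips = flips,
                 shape_native = shape, shape_canonical = shape_can,
                 affine_native = affine, affine_canonical = A),
            class = "orientation_frame")
}

flip_axis <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- seq.int(dim(arr)[axis], 1L)
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Transport an array through (or back through) an orientation frame
#'
#' `apply_frame` maps a native-space array to the canonical axis order;
#' `invert_frame` is its exact inverse. Voxel values are only permuted and
#' flipped, never interpolated.
#'
#' @param arr 3D array in native (`apply_frame`) or canonical
#'   (`invert_frame`) axis order.
#' @param frame an `orientation_frame` from [to_canonical()].
#' @export
apply_frame <- function(arr, frame) {
  if (!identical(dim(arr), as.integer(frame$shape_native)))
    e2d_stop("array shape does not match the frame's native shape",
             "e2d_geometry_error")
  out <- aperm(arr, frame$perm)
  for (r in which(frame$flips)) out <- flip_axis(out, r)
  out
}

#' @rdname apply_frame
#' @export
invert_frame <- function(arr, frame) {
  if (!identical(dim(arr), as.integer(frame$shape_canonical)))
    e2d_stop("array shape does not match the frame's canonical shape",
             "e2d_geometry_error")
  for (r in which(frame$flips)) arr <- flip_axis(arr, r)
  aperm(arr, order(frame$perm))
}

#' Write a canonical-space mask back to the native space of its subject
#'
#' Applies the inverse orientation frame so the written mask is on the
#' original input grid with the original affine, stored as unsigned 8-bit
#' with values \{0, 1\}.
#'
#' @param m a [label_volume()] on the canonical grid.
#' @param frame the `orientation_frame` produced when canonicalizing the
#'   subject's image.
#' @param path output NIfTI path.
#' @export
write_mask <- function(m, frame, path) {
  stopifnot(inherits(m, "label_volume"), inherits(frame, "orientation_frame"))
  native <- invert_frame(m$data, frame)
  write_nifti_array(native, frame$affine_native, path, datatype = "uint8")
  invisible(path)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}
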