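#' Specification of a synthetic bilateral-structure head phantom
#'
#' The phantom emulates the contrast situation of a T1 brain volume with a
#' small bright bilateral structure: a smooth ellipsoidal "brain" envelope
#' at `brain_intensity`, two mirror-placed curved (bent prolate) ellipsoids
#' at `target_intensity`, additive Gaussian noise, and optionally a
#' unilateral "resection": the structure on one side is removed and
#' replaced by a dark cavity whose rim keeps a faint structure-like
#' texture — deliberately reproducing the false-positive trap that
#' resection cavities present to models trained on intact anatomy.
#'
#' @param shape integer grid size per axis (canonical RAS order).
#' @param brain_intensity mean background (brain) level in (0, 1).
#' @param target_intensity mean structure level; must exceed
#'   `brain_intensity` and be at most 1.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param structure_semiaxes ellipsoid semi-axes of each structure, in
#'   voxels, along (sagittal, coronal, axial).
#' @param bend lateral displacement (in voxels, at the coronal extremes)
#'   that curves the prolate ellipsoid into a banana shape.
#' @param resect_side one of `"none"`, `"left"`, `"right"`.
#' @param seed RNG seed; the same spec yields bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         brain_intensity = 0.3,
                         target_intensity = 0.6,
                         noise_sd = 0.03,
                         structure_semiaxes = c(5, 9, 5),
                         bend = 3,
                         resect_side = c("none", "left", "right"),
                         seed = 1L) {
  resect_side <- match.arg(resect_side)
  shape <- as.integer(rep(shape, length.out = 3))
  if (any(shape < 16L))
    e2d_stop("phantom grid must be at least 16 voxels per axis", "e2d_spec_error")
  if (!(brain_intensity > 0 && brain_intensity < target_intensity &&
        target_intensity <= 1))
    e2d_stop("need 0 < brain_intensity < target_intensity <= 1", "e2d_spec_error")
  if (noise_sd < 0) e2d_stop("noise_sd must be >= 0", "e2d_spec_error")
  spec <- structure(
    list(shape = shape, brain_intensity = brain_intensity,
         target_intensity = target_intensity, noise_sd = noise_sd,
         structure_semiaxes = structure_semiaxes, bend = bend,
         resect_side = resect_side, seed = as.integer(seed)),
    class = "phantom_spec")
  check_structures_fit(spec)
  spec
}

structure_centers <- function(spec) {
  ctr <- (spec$shape + 1) / 2
  dx <- 0.16 * spec$shape[1]
  list(left = c(ctr[1] - dx, ctr[2], ctr[3]),
       right = c(ctr[1] + dx, ctr[2], ctr[3]))
}

check_structures_fit <- function(spec) {
  cs <- structure_centers(spec)
  ax <- spec$structure_semiaxes
  for (side in names(cs)) {
    lo <- cs[[side]] - ax - c(spec$bend, 0, 0)
    hi <- cs[[side]] + ax + c(spec$bend, 0, 0)
    if (any(lo < 1.5) || any(hi > spec$shape - 0.5))
      e2d_stop("structure overlaps the grid boundary", "e2d_spec_error")
  }
  invisible(spec)
}

# Squared normalized ellipsoid radius of the curved structure on one side.
# The structure is a prolate ellipsoid elongated along the coronal axis,
# bent laterally (outward) by `bend * t^2` where t is the normalized
# coronal offset, so its boundary is anisotropic and curved.
structure_radius2 <- function(coords, center, semiaxes, bend, sign_bend) {
  t2 <- ((coords$y - center[2]) / semiaxes[2])^2
  xs <- coords$x - (center[1] + sign_bend * bend * t2)
  (xs / semiaxes[1])^2 + t2 + ((coords$z - center[3]) / semiaxes[3])^2
}

#' Generate one phantom subject
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` (an [image_volume()]) and `label`
#'   (a [label_volume()] marking only the structures actually present).
#' @export
generate_subject <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_structures_fit(spec)
  with_seed(spec$seed, {
    sh <- spec$shape
    coords <- list(
      x = array(rep(seq_len(sh[1]), times = sh[2] * sh[3]), sh),
      y = array(rep(seq_len(sh[2]), each = sh[1], times = sh[3]), sh),
      z = array(rep(seq_len(sh[3]), each = sh[1] * sh[2]), sh))
    ctr <- (sh + 1) / 2
    env_ax <- c(0.42, 0.45, 0.40) * sh
    r2_brain <- ((coords$x - ctr[1]) / env_ax[1])^2 +
      ((coords$y - ctr[2]) / env_ax[2])^2 +
      ((coords$z - ctr[3]) / env_ax[3])^2
    # smooth envelope: 1 well inside, linear ramp to 0 across the rim
    envelope <- pmin(1, pmax(0, (1.1 - r2_brain) / 0.2))
    vol <- spec$brain_intensity * envelope

    cs <- structure_centers(spec)
    label <- array(0L, sh)
    for (side in c("left", "right")) {
      r2 <- structure_radius2(coords, cs[[side]], spec$structure_semiaxes,
                              spec$bend, if (side == "left") -1 else 1)
      inside <- r2 <= 1
      if (identical(side, spec$resect_side)) {
        # resection cavity: dark interior and a textured rim carrying small
        # nodular remnants at structure intensity — the trap that makes
        # models trained on intact anatomy hallucinate the structure here
        core <- r2 <= 0.75
        rim <- inside & !core
        vol[core] <- 0.12
        n_rim <- sum(rim)
        vol[rim] <- spec$brain_intensity +
          0.35 * (spec$target_intensity - spec$brain_intensity) +
          stats::rnorm(n_rim, 0, 0.08)
        rim_idx <- which(rim)
        n_nod <- 3L
        centers <- arrayInd(sample(rim_idx, n_nod), sh)
        for (k in seq_len(n_nod)) {
          nod <- (coords$x - centers[k, 1])^2 + (coords$y - centers[k, 2])^2 +
            (coords$z - centers[k, 3])^2 <= 1.8^2
          vol[nod] <- spec$target_intensity
        }
      } else {
        vol[inside] <- spec$target_intensity
        label[inside] <- 1L
      }
    }
    if (spec$noise_sd > 0)
      vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sd)
    vol <- pmin(1, pmax(0, vol))
    affine <- diag(4)
    affine[1:3, 4] <- -(sh - 1) / 2
    list(image = image_volume(array(vol, sh), affine),
         label = label_volume(label, affine))
  })
}

#' Generate a reproducible cohort of phantom subjects
#'
#' Controls keep both structures; patients have one side resected (the side
#' is sampled uniformly). Each subject's structure size, position and bend
#' are jittered around `base_spec`, and each subject gets its own seed
#' derived from `seed`, so the whole cohort is reproducible.
#'
#' @param n_controls,n_patients subject counts (>= 0).
#' @param base_spec a [phantom_spec()] providing the nominal geometry.
#' @param seed master seed for the cohort.
#' @return A list of subjects, each a list with `id`, `image`, `label`,
#'   `cohort` (`"control"` or `"patient"`) and `resect_side`.
#' @export
generate_cohort <- function(n_controls, n_patients,
                            base_spec = phantom_spec(), seed = 1L) {
  if (n_controls < 0 || n_patients < 0)
    e2d_stop("subject counts must be >= 0", "e2d_spec_error")
  roles <- c(rep("control", n_controls), rep("patient", n_patients))
  ids <- c(sprintf("ctrl%03d", seq_len(n_controls)),
           sprintf("pat%03d", seq_len(n_patients)))
  lapply(seq_along(roles), function(i) {
    sseed <- derive_seed(seed, "subject", ids[i])
    with_seed(sseed, {
      side <- if (roles[i] == "patient") sample(c("left", "right"), 1) else "none"
      jit_ax <- base_spec$structure_semiaxes * stats::runif(3, 0.9, 1.1)
      jit_bend <- base_spec$bend * stats::runif(1, 0.8, 1.2)
      spec <- phantom_spec(
        shape = base_spec$shape,
        brain_intensity = base_spec$brain_intensity,
        target_intensity = base_spec$target_intensity,
        noise_sd = base_spec$noise_sd,
        structure_semiaxes = jit_ax,
        bend = jit_bend,
        resect_side = side,
        seed = derive_seed(sseed, "voxels"))
      subj <- generate_subject(spec)
      list(id = ids[i], image = subj$image, label = subj$label,
           cohort = roles[i], resect_side = side, spec = spec)
    })
  })
}

#' Write a cohort to disk as NIfTI files plus a manifest
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame (also written as
#'   `manifest.csv` in `dir`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    img <- file.path(dir, paste0(s$id, "_img.nii.gz"))
    lab <- file.path(dir, paste0(s$id, "_lab.nii.gz"))
    write_volume(s$image, img)
    write_nifti_array(s$label$data, s$label$affine, lab, datatype = "uint8")
    data.frame(id = s$id, image = basename(img), label = basename(lab),
               cohort = s$cohort, resect_side = s$resect_side,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the NIfTI files.
#' @return A list of subjects in the same layout as [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    e2d_stop(sprintf("no manifest.csv in '%s'", dir), "e2d_io_error")
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    list(id = manifest$id[i],
         image = read_volume(file.path(dir, manifest$image[i])),
         label = read_label(file.path(dir, manifest$label[i])),
         cohort = manifest$cohort[i],
         resect_side = manifest$resect_side[i])
  })
}
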