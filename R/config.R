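#' Default run configuration
#'
#' A run configuration is a plain nested list, fully serializable to YAML,
#' that determines every tunable of a run: phantom geometry, sampler and
#' augmentation, network, loss, training schedule and consensus
#' post-processing. A run directory always contains the exact
#' configuration that produced it.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    phantom = list(shape = 64L, brain_intensity = 0.3, target_intensity = 0.6,
                   noise_sd = 0.03),
    sampler = list(patch_size = 64L, positive_fraction = 0.8,
                   head_threshold = 0.05),
    augment = list(enabled = TRUE, intensity_shift = 0.05, rotation_deg = 10,
                   scale_pct = 10, noise_variance = 2e-4),
    network = list(base_width = 16L, depth = 4L,
                   output_mode = "sigmoid_1ch"),
    loss = list(kind = "dice", epsilon = 1e-6),
    train = list(epochs = 15L, patches_per_epoch = 512L, batch_size = 16L,
                 learning_rate = 1e-3, val_patches = 64L,
                 fractions = c(0.8, 0.1, 0.1)),
    consensus = list(threshold = 0.5, max_components = 2L))
}

merge_config <- function(base, override, path = character()) {
  for (nm in names(override)) {
    here <- c(path, nm)
    if (!nm %in% names(base))
      e2d_stop(sprintf("unknown configuration key '%s'",
                       paste(here, collapse = ".")), "e2d_config_error")
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' `read_run_config` merges the file over [default_run_config()] and
#' rejects unknown keys (naming the offending key).
#'
#' @param path YAML file path.
#' @param config nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    e2d_stop(sprintf("config file '%s' not found", path), "e2d_io_error")
  merge_config(default_run_config(), yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Materialize the module-level configuration objects from a run config.
build_train_config <- function(rc) {
  aug <- augment_config(
    intensity_shift_range = c(-1, 1) * rc$augment$intensity_shift,
    rotation_range_deg = c(-1, 1) * rc$augment$rotation_deg,
    scale_range_pct = c(-1, 1) * rc$augment$scale_pct,
    noise_variance = rc$augment$noise_variance,
    enabled = rc$augment$enabled)
  train_config(
    epochs = rc$train$epochs,
    patches_per_epoch = rc$train$patches_per_epoch,
    batch_size = rc$train$batch_size,
    learning_rate = rc$train$learning_rate,
    loss = loss_config(rc$loss$kind, rc$loss$epsilon,
                       total_epochs = rc$train$epochs),
    sampler = sampler_config(rc$sampler$patch_size,
                             rc$sampler$positive_fraction, aug,
                             depth = rc$network$depth,
                             head_threshold = rc$sampler$head_threshold),
    network = network_config(base_width = rc$network$base_width,
                             depth = rc$network$depth,
                             output_mode = rc$network$output_mode),
    val_patches = rc$train$val_patches,
    seed = rc$seed)
}
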