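#' Seeded end-to-end phantom study
#'
#' The package's reference experiment, used by the acceptance tests and
#' the acceptance script: generate a control cohort and a resected-patient
#' cohort of 64-cubed phantoms, train the three-orientation ensemble on
#' controls only (width-8, depth-3 networks, Dice loss, 15 epochs of 512
#' runtime-sampled 32x32 patches), segment the held-out control test
#' subjects and the resected patients, and evaluate both groups. Training
#' on intact anatomy only deliberately reproduces the domain-shift
#' situation in which resection cavities attract false positives.
#'
#' @param seed master seed for the whole study.
#' @param n_train,n_val,n_test control subjects per role.
#' @param n_patients resected subjects (evaluation only).
#' @param epochs,patches_per_epoch training schedule.
#' @param base_width,depth network size.
#' @param patch_size training patch side (divisible by `2^depth`).
#' @param loss_kind `"dice"`, `"gdl"` or `"boundary"`.
#' @return List with the trained `ensemble`, per-subject `records`,
#'   grouped `summary`, the control/patient evaluation inputs, and
#'   `elapsed` seconds.
#' @export
run_phantom_demo <- function(seed = 1L, n_train = 20L, n_val = 4L,
                             n_test = 8L, n_patients = 8L, epochs = 15L,
                             patches_per_epoch = 512L, base_width = 8L,
                             depth = 3L, patch_size = 32L,
                             loss_kind = "dice") {
  t0 <- proc.time()[["elapsed"]]
  n_controls <- n_train + n_val + n_test
  cohort <- generate_cohort(n_controls, n_patients,
                            base_spec = phantom_spec(),
                            seed = derive_seed(seed, "cohort"))
  is_control <- vapply(cohort, `[[`, "", "cohort") == "control"
  controls <- cohort[is_control]
  patients <- cohort[!is_control]
  plan <- make_holdout(vapply(controls, `[[`, "", "id"),
                       fractions = c(n_train, n_val, n_test) / n_controls,
                       seed = derive_seed(seed, "split"))
  cfg <- train_config(
    epochs = epochs, patches_per_epoch = patches_per_epoch,
    loss = loss_config(loss_kind, total_epochs = epochs),
    sampler = sampler_config(patch_size = patch_size, depth = depth),
    network = network_config(
      base_width = base_width, depth = depth,
      output_mode = if (loss_kind == "dice") "sigmoid_1ch" else "softmax_2ch"),
    seed = derive_seed(seed, "train"))
  ensemble <- train_ensemble(controls, plan, cfg)

  eval_subjects <- c(controls[vapply(controls, `[[`, "", "id") %in% plan$test],
                     patients)
  preds <- list()
  gts <- list()
  tags <- character()
  for (s in eval_subjects) {
    preds[[s$id]] <- segment(s$image, ensemble)
    gts[[s$id]] <- s$label
    tags[s$id] <- s$cohort
  }
  ev <- evaluate_cohort(preds, gts, tags)
  # per-patient resected-side Dice and false-positive presence
  resect <- do.call(rbind, lapply(patients, function(s) {
    rec <- ev$records[ev$records$id == s$id, ]
    side_dice <- if (s$resect_side == "left") rec$dice_left else rec$dice_right
    halves <- split_left_right(preds[[s$id]])
    fp_voxels <- sum(halves[[s$resect_side]]$data)
    data.frame(id = s$id, resect_side = s$resect_side,
               resected_side_dice = side_dice, fp_voxels = fp_voxels,
               stringsAsFactors = FALSE)
  }))
  list(ensemble = ensemble, records = ev$records, summary = ev$summary,
       resect = resect, predictions = preds, ground_truths = gts,
       plan = plan, cfg = cfg,
       elapsed = proc.time()[["elapsed"]] - t0)
}
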