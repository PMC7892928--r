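test_that("stratified hold-out honours fractions, disjointness and determinism", {
  ids <- sprintf("s%02d", 1:10)
  plan <- make_holdout(ids, c(0.8, 0.1, 0.1), seed = 3)
  expect_length(plan$train, 8)
  expect_length(plan$validation, 1)
  expect_length(plan$test, 1)
  expect_setequal(c(plan$train, plan$validation, plan$test), ids)
  expect_identical(make_holdout(ids, c(0.8, 0.1, 0.1), seed = 3), plan)

  # 20 subjects, 10 controls / 10 patients at (0.7, 0.1, 0.2): each role
  # balanced 50/50 where divisible
  ids20 <- sprintf("s%02d", 1:20)
  strata <- rep(c("control", "patient"), each = 10)
  plan2 <- make_holdout(ids20, c(0.7, 0.1, 0.2), strata = strata, seed = 5)
  stratum_of <- function(x) strata[match(x, ids20)]
  expect_identical(sum(stratum_of(plan2$train) == "control"), 7L)
  expect_identical(sum(stratum_of(plan2$validation) == "control"), 1L)
  expect_identical(sum(stratum_of(plan2$test) == "control"), 2L)

  expect_error(make_holdout(ids, c(0.5, 0.5, 0.1)), class = "e2d_split_error")
  expect_error(make_holdout(c("a", "b"), c(0.4, 0.3, 0.3)),
               class = "e2d_split_error")
})

test_that("k-fold test sets partition the cohort", {
  ids <- sprintf("s%02d", 1:10)
  plans <- make_kfold(ids, 5, seed = 2)
  tests <- unlist(lapply(plans, `[[`, "test"))
  expect_length(tests, 10)
  expect_false(anyDuplicated(tests) > 0)
  expect_setequal(tests, ids)
  for (p in plans) {
    expect_length(p$test, 2)
    expect_setequal(c(p$train, p$test), ids)
    expect_length(intersect(p$train, p$test), 0)
  }
  expect_error(make_kfold(ids, 1, seed = 1), class = "e2d_split_error")
  expect_error(make_kfold(ids, 11, seed = 1), class = "e2d_split_error")
})

test_that("training logs per-epoch records, saves the best model, and is seeded", {
  cohort <- generate_cohort(3, 0, seed = 31)
  plan <- make_holdout(cohort, c(2 / 3, 1 / 3, 0), seed = 1)
  cfg <- train_config(epochs = 2, patches_per_epoch = 32, batch_size = 8,
                      sampler = sampler_config(patch_size = 16, depth = 2,
                                               augment = augment_config(enabled = FALSE)),
                      network = network_config(base_width = 4, depth = 2),
                      loss = loss_config("dice", total_epochs = 2), seed = 9)
  fit <- train_orientation(cohort, plan, "sagittal", cfg)
  expect_identical(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_dice)))
  fit2 <- train_orientation(cohort, plan, "sagittal", cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$params, fit2$model$params)
  # no validation/test subject id enters the training subject set
  expect_length(intersect(plan$train, c(plan$validation, plan$test)), 0)
  expect_error(
    train_orientation(cohort, structure(list(train = character(),
                                             validation = "x", test = "y"),
                                        class = "split_plan"),
                      "sagittal", cfg),
    class = "e2d_config_error")
})

test_that("patch streams differ between epochs under the same master seed", {
  s <- tiny_subject(3)
  subjects <- list(list(id = "a", image = s$image, label = s$label))
  cfg <- train_config(sampler = sampler_config(patch_size = 16, depth = 2,
                                               augment = augment_config(enabled = FALSE)),
                      network = network_config(base_width = 4, depth = 2),
                      seed = 5)
  caches <- list(sampler_cache(s$image, s$label, cfg$sampler))
  draw_epoch <- function(epoch) {
    e2dseg:::with_seed(e2dseg:::derive_seed(cfg$seed, "sample", "axial", epoch),
                       e2dseg:::sample_batch(subjects, caches, cfg, "axial", 8L))
  }
  e1 <- draw_epoch(1)
  e1b <- draw_epoch(1)
  e2 <- draw_epoch(2)
  expect_identical(e1$x, e1b$x)          # same epoch, same stream
  expect_false(identical(e1$x, e2$x))    # different epoch, fresh draws
})

test_that("the ensemble trains one tagged model per orientation", {
  cohort <- generate_cohort(3, 0, seed = 77)
  plan <- make_holdout(cohort, c(2 / 3, 1 / 3, 0), seed = 1)
  cfg <- train_config(epochs = 1, patches_per_epoch = 16, batch_size = 8,
                      sampler = sampler_config(patch_size = 16, depth = 2,
                                               augment = augment_config(enabled = FALSE)),
                      network = network_config(base_width = 2, depth = 2),
                      loss = loss_config("dice", total_epochs = 2), seed = 4)
  ens <- train_ensemble(cohort, plan, cfg)
  expect_setequal(names(ens$models), c("sagittal", "coronal", "axial"))
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  expect_true(all(file.exists(file.path(dir, c("sagittal.rds", "coronal.rds",
                                               "axial.rds")))))
  # a missing orientation checkpoint is an ensemble error naming it
  file.remove(file.path(dir, "axial.rds"))
  expect_error(load_ensemble(dir), "axial", class = "e2d_ensemble_error")
})
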