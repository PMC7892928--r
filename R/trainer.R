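#' Stratified hold-out split
#'
#' Allocates subjects to train/validation/test roles within each stratum
#' (largest-remainder rounding), then pools strata, so role proportions are
#' honoured per stratum as closely as rounding allows. Deterministic for a
#' given seed.
#'
#' @param ids character vector of subject ids (or a cohort list from
#'   [generate_cohort()], whose `cohort` tags are then used as strata when
#'   `strata` is `NULL`).
#' @param fractions length-3 numeric `(train, validation, test)` summing
#'   to 1.
#' @param strata optional stratification labels, one per id.
#' @param seed RNG seed.
#' @return A `split_plan`: list with character id vectors `train`,
#'   `validation`, `test`.
#' @export
make_holdout <- function(ids, fractions = c(0.8, 0.1, 0.1), strata = NULL,
                         seed = 1L) {
  if (is.list(ids) && !is.null(ids[[1]]$id)) {
    if (is.null(strata)) strata <- vapply(ids, `[[`, "", "cohort")
    ids <- vapply(ids, `[[`, "", "id")
  }
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    e2d_stop("fractions must be length 3 and sum to 1", "e2d_split_error")
  if (is.null(strata)) strata <- rep("all", length(ids))
  if (length(strata) != length(ids))
    e2d_stop("strata must match ids in length", "e2d_split_error")
  roles <- c("train", "validation", "test")
  out <- stats::setNames(vector("list", 3), roles)
  with_seed(seed, {
    for (s in unique(strata)) {
      sid <- sample(ids[strata == s])
      n <- length(sid)
      base <- floor(fractions * n)
      rem <- fractions * n - base
      extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
      counts <- base
      counts[extra] <- counts[extra] + 1L
      if (any(counts == 0L & fractions > 0))
        e2d_stop(sprintf("stratum '%s' (n=%d) too small for all roles", s, n),
                 "e2d_split_error")
      cut <- cumsum(counts)
      out$train <- c(out$train, sid[seq_len(counts[1])])
      out$validation <- c(out$validation,
                          if (counts[2] > 0) sid[(cut[1] + 1):cut[2]])
      out$test <- c(out$test, if (counts[3] > 0) sid[(cut[2] + 1):cut[3]])
    }
  })
  structure(list(train = out$train, validation = out$validation %||% character(),
                 test = out$test %||% character(), seed = seed),
            class = "split_plan")
}

#' k-fold cross-validation plans
#'
#' Returns `k` split plans whose test sets are pairwise disjoint and
#' together partition the cohort; the remaining subjects form each fold's
#' training role.
#'
#' @param ids subject ids (or a cohort list).
#' @param k number of folds (>= 2, <= number of subjects).
#' @param seed RNG seed.
#' @export
make_kfold <- function(ids, k, seed = 1L) {
  if (is.list(ids) && !is.null(ids[[1]]$id))
    ids <- vapply(ids, `[[`, "", "id")
  n <- length(ids)
  if (k < 2L || k > n)
    e2d_stop(sprintf("k must be in [2, %d]", n), "e2d_split_error")
  with_seed(seed, {
    shuffled <- sample(ids)
    fold <- sort(rep_len(seq_len(k), n))
    lapply(seq_len(k), function(f) {
      structure(list(train = shuffled[fold != f], validation = character(),
                     test = shuffled[fold == f], seed = seed),
                class = "split_plan")
    })
  })
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param patches_per_epoch patches freshly sampled (never pre-materialized)
#'   in each epoch.
#' @param batch_size patches per optimizer step.
#' @param optimizer optimizer name; `"adam"`.
#' @param learning_rate step size.
#' @param loss a [loss_config()]; its `total_epochs` is aligned with
#'   `epochs` for the boundary schedule.
#' @param sampler a [sampler_config()].
#' @param network a [network_config()].
#' @param val_patches patches drawn (with an epoch-fixed seed) from the
#'   validation subjects to compute the per-epoch validation soft Dice.
#' @param seed master seed; fans out to sampling, augmentation and
#'   initialization substreams.
#' @export
train_config <- function(epochs = 15L, patches_per_epoch = 512L,
                         batch_size = 16L, optimizer = "adam",
                         learning_rate = 1e-3,
                         loss = loss_config("dice", total_epochs = epochs),
                         sampler = sampler_config(),
                         network = network_config(),
                         val_patches = 64L, seed = 1L) {
  if (epochs < 1L || patches_per_epoch < 1L || batch_size < 1L)
    e2d_stop("epochs, patches_per_epoch and batch_size must be positive",
             "e2d_config_error")
  if (!identical(optimizer, "adam"))
    e2d_stop("only the adam optimizer is provided", "e2d_config_error")
  if (loss$kind != "dice" && network$output_mode != "softmax_2ch")
    e2d_stop("gdl/boundary losses need the softmax_2ch output head",
             "e2d_config_error")
  if (sampler$depth != network$depth)
    e2d_stop("sampler depth must match network depth", "e2d_config_error")
  structure(list(epochs = as.integer(epochs),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate, loss = loss, sampler = sampler,
                 network = network, val_patches = as.integer(val_patches),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- loss glue: dL/dp -> dL/dz through the output nonlinearity --------

# Returns list(loss, dz) for a batch: p is the network output
# (out_ch, H, W, N), y the binary targets (H, W, N). Batch losses sum
# voxel sums over the whole batch before the ratio (batch-Dice), which
# stabilizes patches with little foreground. For the boundary loss the
# surface term is averaged over the non-degenerate samples only (patches
# with an empty or full target legitimately occur among negatives and
# contribute through the regional term alone).
batch_loss <- function(p, y, cfg, epoch, dmaps = NULL) {
  if (cfg$loss$kind == "dice") {
    pf <- array(p[1, , , ], dim(p)[2:4])
    loss <- dice_loss(pf, y, cfg$loss$epsilon)
    dldp <- dice_loss_grad(pf, y, cfg$loss$epsilon)
    dz <- dldp * pf * (1 - pf)
    dim(dz) <- dim(p)
    return(list(loss = loss, dz = dz))
  }
  g2 <- one_hot2(y)
  a <- if (cfg$loss$kind == "boundary")
    alpha_schedule(epoch, cfg$loss$total_epochs) else 1
  loss <- a * generalized_dice_loss(p, g2, cfg$loss$epsilon)
  dldp <- a * generalized_dice_loss_grad(p, g2, cfg$loss$epsilon)
  if (cfg$loss$kind == "boundary" && a < 1) {
    N <- dim(p)[4]
    valid <- 0L
    sacc <- 0
    gacc <- array(0, dim(p)[2:4])
    for (n in seq_len(N)) {
      gn <- y[, , n]
      s <- sum(gn)
      if (s == 0 || s == length(gn)) next
      valid <- valid + 1L
      dmap <- if (is.null(dmaps)) signed_distance(gn) else dmaps[[n]]
      sacc <- sacc + surface_loss(array(p[2, , , n], dim(gn)), dmap)
      gacc[, , n] <- surface_loss_grad(array(p[2, , , n], dim(gn)), dmap)
    }
    if (valid > 0L) {
      loss <- loss + (1 - a) * sacc / valid
      dldp[2, , , ] <- dldp[2, , , ] + (1 - a) * gacc / valid
    }
  }
  # softmax jacobian: dz_c = p_c * (dldp_c - sum_k dldp_k p_k)
  inner <- p[1, , , ] * dldp[1, , , ] + p[2, , , ] * dldp[2, , , ]
  dz <- p * 0
  dz[1, , , ] <- p[1, , , ] * (dldp[1, , , ] - inner)
  dz[2, , , ] <- p[2, , , ] * (dldp[2, , , ] - inner)
  list(loss = loss, dz = dz)
}

sample_batch <- function(subjects, caches, cfg, orientation, n) {
  sc <- cfg$sampler
  p <- sc$patch_size
  x <- array(0, c(3L, p, p, n))
  y <- array(0L, c(p, p, n))
  positives <- logical(n)
  for (i in seq_len(n)) {
    si <- sample.int(length(subjects), 1L)
    s <- subjects[[si]]
    pos <- stats::runif(1) < sc$positive_fraction
    if (pos && nrow(caches[[si]]$border) == 0L) pos <- FALSE
    positives[i] <- pos
    patch <- sample_patch(s$image, s$label, pos, sc, orientation, caches[[si]])
    patch <- augment_patch(patch, sc$augment)
    x[, , , i] <- patch$channels
    y[, , i] <- patch$target
  }
  list(x = x, y = y, positives = positives)
}

prepare_subjects <- function(cohort, ids) {
  subjects <- cohort[vapply(cohort, `[[`, "", "id") %in% ids]
  if (length(subjects) != length(ids))
    e2d_stop("split plan references unknown subject ids", "e2d_split_error")
  lapply(subjects, function(s) {
    can <- to_canonical(s$image)
    img <- minmax_normalize(can$volume)
    lab <- label_volume(apply_frame(s$label$data, can$frame),
                        can$volume$affine)
    list(id = s$id, image = img, label = lab, frame = can$frame)
  })
}

#' Train one orientation-specialized network
#'
#' Patches are drawn fresh from the training subjects at every step (never
#' pre-materialized), augmented, and optimized with batch-Dice style
#' losses; after each epoch the soft Dice on patches drawn from the
#' validation subjects with an epoch-fixed seed is logged, and the
#' best-validation parameters are retained. All randomness derives from
#' `cfg$seed` and the orientation name, so reruns are identical.
#'
#' @param cohort list of subjects ([generate_cohort()] / [read_cohort()]).
#' @param plan a `split_plan` from [make_holdout()].
#' @param orientation `"sagittal"`, `"coronal"` or `"axial"`.
#' @param cfg a [train_config()].
#' @return List with `model` (best-validation `e2d_network`), `history`
#'   (per-epoch data frame) and `orientation`.
#' @export
train_orientation <- function(cohort, plan, orientation, cfg = train_config()) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  if (length(plan$train) == 0L)
    e2d_stop("split plan has an empty training role", "e2d_config_error")
  train_subj <- prepare_subjects(cohort, plan$train)
  val_subj <- if (length(plan$validation))
    prepare_subjects(cohort, plan$validation) else list()
  train_caches <- lapply(train_subj, function(s)
    sampler_cache(s$image, s$label, cfg$sampler))
  val_caches <- lapply(val_subj, function(s)
    sampler_cache(s$image, s$label, cfg$sampler))

  net_cfg <- cfg$network
  net_cfg$seed <- derive_seed(cfg$seed, "init", orientation)
  model <- build_network(net_cfg)
  opt <- adam_init(model$params)
  steps <- max(1L, cfg$patches_per_epoch %/% cfg$batch_size)
  best <- list(metric = -Inf, params = model$params, bn = model$bn)
  history <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    alpha <- if (cfg$loss$kind == "boundary")
      alpha_schedule(epoch, cfg$loss$total_epochs) else NA_real_
    epoch_loss <- 0
    with_seed(derive_seed(cfg$seed, "sample", orientation, epoch), {
      for (step in seq_len(steps)) {
        batch <- sample_batch(train_subj, train_caches, cfg, orientation,
                              cfg$batch_size)
        fw <- net_forward_full(model, batch$x, train = TRUE)
        model$bn <- fw$bn
        bl <- batch_loss(fw$p, batch$y, cfg, epoch)
        if (!is.finite(bl$loss))
          e2d_stop("non-finite training loss", "e2d_numeric_error")
        grads <- net_backward_full(model, bl$dz, fw$cache)
        upd <- adam_step(model$params, grads, opt, cfg$learning_rate)
        model$params <- upd$params
        opt <- upd$state
        epoch_loss <- epoch_loss + bl$loss
      }
    })
    val_dice <- NA_real_
    if (length(val_subj)) {
      with_seed(derive_seed(cfg$seed, "val", orientation, epoch), {
        vb <- sample_batch(val_subj, val_caches, cfg, orientation,
                           min(cfg$val_patches, 256L))
        pf <- predict_probs(model, vb$x)
        val_dice <- soft_dice(pf, vb$y, cfg$loss$epsilon)
      })
      metric <- val_dice
    } else {
      metric <- -epoch_loss / steps
    }
    if (metric >= best$metric)
      best <- list(metric = metric, params = model$params, bn = model$bn)
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = epoch_loss / steps,
      val_dice = val_dice, alpha = alpha)
  }
  model$params <- best$params
  model$bn <- best$bn
  list(model = model, history = do.call(rbind, history),
       orientation = orientation)
}

#' Train the three-orientation ensemble
#'
#' Runs [train_orientation()] for the sagittal, coronal and axial planes
#' over the same split plan and returns the ensemble used by [segment()].
#'
#' @inheritParams train_orientation
#' @return An `e2d_ensemble`: named list of models plus histories.
#' @export
train_ensemble <- function(cohort, plan, cfg = train_config()) {
  fits <- lapply(ORIENTATIONS, function(o)
    train_orientation(cohort, plan, o, cfg))
  names(fits) <- ORIENTATIONS
  structure(list(models = lapply(fits, `[[`, "model"),
                 histories = lapply(fits, `[[`, "history"),
                 plan = plan, cfg = cfg),
            class = "e2d_ensemble")
}

#' Save / load a trained ensemble as one checkpoint per orientation
#'
#' @param ensemble an `e2d_ensemble`.
#' @param dir checkpoint directory.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (o in ORIENTATIONS)
    save_network(ensemble$models[[o]], file.path(dir, paste0(o, ".rds")))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  paths <- file.path(dir, paste0(ORIENTATIONS, ".rds"))
  missing <- !file.exists(paths)
  if (any(missing))
    e2d_stop(sprintf("missing orientation checkpoint(s): %s",
                     paste(ORIENTATIONS[missing], collapse = ", ")),
             "e2d_ensemble_error")
  models <- lapply(paths, load_network)
  names(models) <- ORIENTATIONS
  structure(list(models = models), class = "e2d_ensemble")
}
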