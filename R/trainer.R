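# Training, tuning and selection of the compound-scaled patch classifier.
#
# The family is indexed by phi: depth, width and input resolution of the
# base model are multiplied by alpha^phi, beta^phi and gamma^phi and
# rounded, the joint-scaling recipe used by the EfficientNet family. The
# base here is deliberately small (two conv blocks, 8 channels, 32 px) so
# a family member trains on one CPU in minutes; the scaling law, the
# learning-rate screening protocol and the selection rule are what is
# exercised, not large-scale capacity.

#' Compound-scaling specification
#'
#' @param phi nonnegative integer family index (0 = base model).
#' @param alpha,beta,gamma depth / width / resolution scaling coefficients
#'   (all >= 1; defaults 1.2 / 1.1 / 1.15, the canonical compound-scaling
#'   coefficients).
#' @param base_depth conv blocks of the base model.
#' @param base_width channels of the base model.
#' @param base_resolution input side (px) of the base model.
#' @return object of class `scaling_spec` with derived `depth`, `width`
#'   and `resolution`.
#' @export
scaling_spec <- function(phi = 0L, alpha = 1.2, beta = 1.1, gamma = 1.15,
                         base_depth = 2L, base_width = 8L,
                         base_resolution = 32L) {
  stopifnot(phi >= 0, alpha >= 1, beta >= 1, gamma >= 1)
  s <- list(phi = as.integer(phi), alpha = alpha, beta = beta, gamma = gamma,
            base_depth = as.integer(base_depth),
            base_width = as.integer(base_width),
            base_resolution = as.integer(base_resolution))
  s$depth <- as.integer(round_half_away(base_depth * alpha^phi))
  s$width <- as.integer(round_half_away(base_width * beta^phi))
  s$resolution <- as.integer(round_half_away(base_resolution * gamma^phi))
  structure(s, class = "scaling_spec")
}

#' Build a classifier from a scaling specification
#'
#' @param scaling a [scaling_spec()].
#' @param n_classes number of output classes.
#' @param seed initialization seed.
#' @return a `cnn_classifier` (see [cnn_init()]).
#' @export
build_model <- function(scaling, n_classes, seed = 1L) {
  stopifnot(inherits(scaling, "scaling_spec"))
  if (scaling$resolution < 32) {
    stop("derived resolution ", scaling$resolution, " is below the 32 px minimum")
  }
  m <- cnn_init(scaling$depth, scaling$width, scaling$resolution,
                n_classes, seed = seed)
  m$scaling <- scaling
  m
}

#' Training configuration
#'
#' @param scaling a [scaling_spec()].
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size minibatch size; must be a power of two.
#' @param epochs training epochs.
#' @param patience early-stopping patience in epochs without a new best
#'   validation accuracy (Inf disables early stopping).
#' @param seed integer seed (initialization and shuffling).
#' @param class_list ordered training classes.
#' @return object of class `train_config`.
#' @export
train_config <- function(scaling = scaling_spec(), learning_rate = 1e-3,
                         batch_size = 32L, epochs = 30L, patience = 10L,
                         seed = 1L, class_list = TRAINING_CLASSES) {
  stopifnot(inherits(scaling, "scaling_spec"), learning_rate > 0, epochs >= 0)
  b <- as.integer(batch_size)
  if (b < 1L || bitwAnd(b, b - 1L) != 0L) {
    stop("batch_size must be a power of two (got ", batch_size, ")")
  }
  structure(list(scaling = scaling, learning_rate = learning_rate,
                 batch_size = b, epochs = as.integer(epochs),
                 patience = patience, seed = as.integer(seed),
                 class_list = class_list),
            class = "train_config")
}

#' Assemble patch records into a model-ready dataset
#'
#' Tiles are bilinearly resized to the model resolution and scaled to
#' `[0, 1]`.
#'
#' @param records list of patch records (from [extract_patches()] or
#'   [render_patch()]-built fixtures): each needs `tile`, `case_id`,
#'   `true_class`, `patch_id`.
#' @param class_list ordered class vocabulary.
#' @param resolution model input side (px).
#' @return list: `x` (res x res x 3 x N array), `y` (integer class
#'   indices), `index` (data.frame `patch_id`, `case_id`, `true_class`).
#' @export
build_patch_dataset <- function(records, class_list, resolution) {
  stopifnot(length(records) > 0)
  n <- length(records)
  x <- array(NA_real_, c(resolution, resolution, 3L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- resize_bilinear(records[[i]]$tile / 255, resolution)
  }
  idx <- data.frame(
    patch_id = vapply(records, `[[`, "", "patch_id"),
    case_id = vapply(records, `[[`, "", "case_id"),
    true_class = vapply(records, `[[`, "", "true_class"))
  y <- match(idx$true_class, class_list)
  if (anyNA(y)) stop("records contain classes outside class_list")
  list(x = clamp(x, 0, 1), y = y, index = idx)
}

dataset_accuracy <- function(model, dataset, batch_size = 128L) {
  p <- cnn_probs(model, dataset$x, batch_size)
  mean(max.col(p, ties.method = "first") == dataset$y)
}

#' Train the patch classifier
#'
#' Minibatch Adam on the cross-entropy, deterministic for a fixed seed
#' (single-threaded base-R arithmetic). Records per-epoch training and
#' validation accuracy, keeps a checkpoint of the weights at the epoch
#' with the highest validation accuracy, and stops early when validation
#' accuracy has not improved for `patience` epochs. Training refuses to
#' run if any case appears in both sets (leak guard).
#'
#' @param train_set,val_set datasets from [build_patch_dataset()].
#' @param config a [train_config()].
#' @return object of class `fitted_classifier`: `model` (best-checkpoint
#'   weights), `final_model`, `curves` (epoch, train_acc, val_acc,
#'   overfit_gap), `best_epoch`, `best_val_acc`, `config`.
#' @export
train <- function(train_set, val_set, config) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_set$y) == 0L) stop("training set is empty")
  if (length(val_set$y) == 0L) stop("validation set is empty")
  leaked <- intersect(unique(train_set$index$case_id),
                      unique(val_set$index$case_id))
  if (length(leaked)) {
    stop("case leak between training and validation sets: ",
         paste(leaked, collapse = ", "))
  }

  n_classes <- length(config$class_list)
  model <- build_model(config$scaling, n_classes, seed = config$seed)
  n <- length(train_set$y)
  state <- NULL
  curves <- data.frame(epoch = integer(0), train_acc = numeric(0),
                       val_acc = numeric(0), overfit_gap = numeric(0))
  best <- list(epoch = 0L, val_acc = -Inf,
               params = param_list(model))

  if (config$epochs > 0L) withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      correct <- 0L
      for (s in seq(1L, n, by = config$batch_size)) {
        ids <- ord[s:min(n, s + config$batch_size - 1L)]
        xb <- train_set$x[, , , ids, drop = FALSE]
        yb <- train_set$y[ids]
        fwd <- cnn_forward(model, xb, keep_cache = TRUE)
        correct <- correct +
          sum(max.col(fwd$probs, ties.method = "first") == yb)
        Y <- matrix(0, length(ids), n_classes)
        Y[cbind(seq_along(ids), yb)] <- 1
        g <- cnn_backward(model, fwd, (fwd$probs - Y) / length(ids))
        upd <- adam_step(param_list(model), grad_list(model, g), state,
                         config$learning_rate)
        model <- set_params(model, upd$params)
        state <- upd$state
      }
      train_acc <- correct / n
      val_acc <- dataset_accuracy(model, val_set)
      curves <- rbind(curves, data.frame(
        epoch = epoch, train_acc = train_acc, val_acc = val_acc,
        overfit_gap = train_acc - val_acc))
      if (val_acc > best$val_acc) {
        best <- list(epoch = epoch, val_acc = val_acc,
                     params = param_list(model))
      }
      if (is.finite(config$patience) &&
          epoch - best$epoch >= config$patience) break
    }
  })
  structure(list(model = set_params(model, best$params),
                 final_model = model, curves = curves,
                 best_epoch = best$epoch,
                 best_val_acc = if (is.finite(best$val_acc)) best$val_acc
                                else NA_real_,
                 config = config),
            class = "fitted_classifier")
}

#' Learning-rate screening sweep
#'
#' Trains every candidate learning rate for `screen_epochs` epochs from
#' the same seed (hence the same initialization) and picks the rate whose
#' best validation accuracy is highest; exact ties go to the smaller rate.
#'
#' @param train_set,val_set datasets from [build_patch_dataset()].
#' @param scaling a [scaling_spec()].
#' @param candidate_lrs numeric vector of at least 2 learning rates.
#' @param screen_epochs screening epochs per candidate (default 50).
#' @param seed shared seed.
#' @param batch_size minibatch size (power of two).
#' @param class_list ordered training classes.
#' @return list: `chosen_lr`, `results` (per-lr best val accuracy),
#'   `curves` (long data.frame), `fits` (per-lr `fitted_classifier`).
#' @export
lr_sweep <- function(train_set, val_set, scaling, candidate_lrs,
                     screen_epochs = 50L, seed = 1L, batch_size = 32L,
                     class_list = TRAINING_CLASSES) {
  if (length(candidate_lrs) < 2L) {
    stop("need at least two candidate learning rates")
  }
  if (length(train_set$y) == 0L) stop("training set is empty")
  fits <- lapply(candidate_lrs, function(lr) {
    train(train_set, val_set,
          train_config(scaling, learning_rate = lr, batch_size = batch_size,
                       epochs = screen_epochs, patience = Inf, seed = seed,
                       class_list = class_list))
  })
  best_acc <- vapply(fits, function(f) max(f$curves$val_acc), 0)
  ord <- order(-best_acc, candidate_lrs)  # ties -> smaller lr
  curves <- do.call(rbind, lapply(seq_along(fits), function(i) {
    cbind(lr = candidate_lrs[i], fits[[i]]$curves)
  }))
  list(chosen_lr = candidate_lrs[ord[1L]],
       results = data.frame(lr = candidate_lrs, best_val_acc = best_acc),
       curves = curves, fits = fits)
}

#' Select the best family member
#'
#' Primary key: best validation accuracy. Candidates within `tie_tol` of
#' the top are tie-broken by validation balanced accuracy (higher wins),
#' remaining ties by smaller phi.
#'
#' @param candidates list; each element has `scaling` (a [scaling_spec()]),
#'   `curves` (with a `val_acc` column), `fitted`, and optionally
#'   `val_bacc` (computed from `val_set` when absent and needed).
#' @param val_set validation dataset, used to compute a missing `val_bacc`.
#' @param map class map for the BACC tie-break ([default_class_map()]).
#' @param tie_tol accuracy window treated as a tie (default 0.0025,
#'   i.e. 0.25 percentage points).
#' @return the chosen candidate (list element), with `val_bacc` filled in
#'   when it was computed.
#' @export
select_model <- function(candidates, val_set = NULL,
                         map = default_class_map(), tie_tol = 0.0025) {
  stopifnot(length(candidates) >= 1L)
  acc <- vapply(candidates, function(cd) max(cd$curves$val_acc), 0)
  phi <- vapply(candidates, function(cd) cd$scaling$phi, 0L)
  contenders <- which(acc >= max(acc) - tie_tol)
  if (length(contenders) > 1L) {
    bacc <- vapply(contenders, function(i) {
      cd <- candidates[[i]]
      if (!is.null(cd$val_bacc)) return(cd$val_bacc)
      if (is.null(val_set)) return(NA_real_)
      preds <- predict_patches(cd$fitted, val_set)
      agg <- aggregate_probs(preds, map)
      classes <- attr(agg, "classes")
      confusion_and_bacc(agg$true_class, patch_argmax(agg, classes),
                         classes)$bacc
    }, 0)
    if (all(is.na(bacc))) bacc <- rep(0, length(contenders))
    ord <- order(-bacc, phi[contenders], -acc[contenders])
    pick <- contenders[ord[1L]]
    if (is.null(candidates[[pick]]$val_bacc)) {
      candidates[[pick]]$val_bacc <- bacc[ord[1L]]
    }
  } else {
    pick <- contenders
  }
  candidates[[pick]]
}

#' Per-patch class probabilities as a prediction table
#'
#' @param fitted a `fitted_classifier` (its best checkpoint is used) or a
#'   bare `cnn_classifier`.
#' @param dataset dataset from [build_patch_dataset()] at the model's
#'   resolution.
#' @param batch_size forward batch size (outputs are batching-invariant).
#' @return prediction table: `patch_id`, `case_id`, `true_class`,
#'   `p_<class>` per training class.
#' @export
predict_patches <- function(fitted, dataset, batch_size = 64L) {
  model <- if (inherits(fitted, "fitted_classifier")) fitted$model else fitted
  class_list <- if (inherits(fitted, "fitted_classifier")) {
    fitted$config$class_list
  } else {
    TRAINING_CLASSES[seq_len(model$n_classes)]
  }
  p <- cnn_probs(model, dataset$x, batch_size)
  colnames(p) <- paste0("p_", class_list)
  out <- cbind(dataset$index, as.data.frame(p))
  rownames(out) <- NULL
  out
}
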