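# Training and evaluation loops: soft Dice loss minimised with AdamW under a
# single-cycle cosine-annealed learning rate, deterministic under one seed.

#' Training configuration
#'
#' @param epochs Total epochs `E_max` (0 is allowed and returns the model
#'   unchanged).
#' @param lr_max Initial (maximum) learning rate; the published recipe uses
#'   5e-5 for full-scale training. Desk-scale phantom runs need a larger
#'   value (see [tiny_train_config()]).
#' @param lr_min Final learning rate of the cosine cycle.
#' @param weight_decay Decoupled AdamW weight decay, applied to weight
#'   matrices/tensors (parameter names ending in `.W`), not to biases, norm
#'   affines or relative-position tables.
#' @param beta1,beta2,adam_eps AdamW moment parameters.
#' @param batch_size Cases per optimiser step (gradient averaging).
#' @param seed Seed covering the entire run; identical seed + cohort gives a
#'   bitwise-identical loss history.
#' @param eval_every Validation cadence in epochs.
#' @param stop_dsc Optional early-stop target: stop once the validation mean
#'   DSC reaches this value.
#' @param threshold Binarisation threshold for validation DSC.
#' @param preprocess Apply [preprocess_case()] (z-score + crop/pad to the
#'   model's input shape) to every case before use.
#' @param checkpoint_path Optional path; the best-validation-DSC state is
#'   saved there whenever it improves.
#' @export
train_config <- function(epochs = 100L, lr_max = 5e-5, lr_min = 0,
                         weight_decay = 0.01, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, batch_size = 1L, seed = 42L,
                         eval_every = 1L, stop_dsc = NULL, threshold = 0.5,
                         preprocess = TRUE, checkpoint_path = NULL) {
  stopifnot(epochs >= 0L, lr_min <= lr_max, batch_size >= 1L, eval_every >= 1L)
  structure(list(epochs = as.integer(epochs), lr_max = lr_max, lr_min = lr_min,
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 stop_dsc = stop_dsc, threshold = threshold,
                 preprocess = isTRUE(preprocess),
                 checkpoint_path = checkpoint_path),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' Defaults sized for overfitting a handful of 16^3 phantoms on one CPU:
#' AdamW needs a far larger step size than the full-scale recipe at this
#' model size, so `lr_max = 1e-2` (cosine-annealed to 0 as usual).
#'
#' @param ... Overrides forwarded to [train_config()].
#' @export
tiny_train_config <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 200L, lr_max = 1e-2, eval_every = 5L)
  do.call(train_config, utils::modifyList(defaults, args))
}

#' Cosine-annealed learning rate
#'
#' `lr_t = lr_min + (lr_max - lr_min) * (1 + cos(pi * E_curr / E_max)) / 2`:
#' the single-cycle cosine schedule, giving `lr_max` at `E_curr = 0`,
#' `lr_min` at `E_curr = E_max`, and their midpoint halfway.
#'
#' @param e_curr Epochs since the start (or last restart), `0..E_max`.
#' @param config A [train_config()] (or any list with `lr_max`, `lr_min`).
#' @param e_max Total epochs; defaults to `config$epochs`.
#' @return The learning rate at `e_curr`.
#' @export
cosine_lr <- function(e_curr, config = train_config(), e_max = config$epochs) {
  if (any(e_curr < 0) || any(e_curr > e_max)) {
    stop("e_curr must lie in [0, E_max] = [0, ", e_max, "], got ", e_curr)
  }
  config$lr_min + 0.5 * (config$lr_max - config$lr_min) *
    (1 + cos(pi * e_curr / e_max))
}

# Parameters are optimised as one flat vector (one vectorised update per
# step); a skeleton of names/dims converts back to the model's list form.
param_skeleton <- function(params) {
  lens <- vapply(params, length, integer(1))
  ends <- cumsum(lens)
  list(names = names(params), dims = lapply(params, dim),
       starts = ends - lens + 1L, ends = ends,
       decay = rep(grepl("\\.W$", names(params)), lens))
}

flatten_params <- function(params) unlist(params, use.names = FALSE)

relist_params <- function(vec, skel) {
  out <- vector("list", length(skel$names))
  names(out) <- skel$names
  for (i in seq_along(out)) {
    p <- vec[skel$starts[i]:skel$ends[i]]
    if (!is.null(skel$dims[[i]])) dim(p) <- skel$dims[[i]]
    out[[i]] <- p
  }
  out
}

adamw_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(pvec, gvec, state, lr, cfg, decay) {
  state$t <- state$t + 1L
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * gvec
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * gvec * gvec
  step <- lr * (state$m / (1 - cfg$beta1^state$t)) /
    (sqrt(state$v / (1 - cfg$beta2^state$t)) + cfg$adam_eps)
  step[decay] <- step[decay] + lr * cfg$weight_decay * pvec[decay]
  list(params = pvec - step, state = state)
}

case_to_matrices <- function(case) {
  list(x = fm_to_mat(case$volume$intensities),
       t = if (is.null(case$mask)) NULL else fm_to_mat(case$mask$channels),
       sp = dim(case$volume$intensities)[2:4])
}

#' Train a segmentation model
#'
#' Minimises the soft Dice loss over the cohort with AdamW; the learning rate
#' follows [cosine_lr()] stepped once per epoch. Per-epoch loss and
#' validation mean DSC are logged; the best-validation state is retained
#' (and optionally checkpointed). The run is fully deterministic for a fixed
#' seed, cohort and configuration.
#'
#' @param model A [catseg_model()].
#' @param cohort List of [case_record()]s with masks.
#' @param config A [train_config()].
#' @param val_cohort Validation cases; defaults to the training cohort.
#' @return A `catseg_train`: list with the trained `model`, the best state
#'   (`best_model`, `best_dsc`, `best_epoch`), a `history` tibble
#'   (epoch, lr, loss, val_dsc) and the `config`.
#' @export
train_model <- function(model, cohort, config = train_config(),
                        val_cohort = NULL) {
  stopifnot(inherits(model, "catseg_model"), length(cohort) >= 1L)
  if (any(vapply(cohort, function(cs) is.null(cs$mask), logical(1)))) {
    stop("every training case needs a mask")
  }
  cfg <- model$config
  if (config$preprocess) {
    cohort <- lapply(cohort, preprocess_case, target_shape = cfg$input_shape)
    if (!is.null(val_cohort)) {
      val_cohort <- lapply(val_cohort, preprocess_case,
                           target_shape = cfg$input_shape)
    }
  }
  if (is.null(val_cohort)) val_cohort <- cohort
  data <- lapply(cohort, case_to_matrices)
  skel <- param_skeleton(model$params)
  pvec <- flatten_params(model$params)
  params <- model$params
  buffers <- model$buffers
  opt <- adamw_init(length(pvec))
  history <- vector("list", config$epochs)
  best <- list(dsc = -Inf, epoch = 0L, params = params,
               buffers = buffers_to_list(buffers))
  epochs_run <- 0L
  with_local_seed(config$seed, {
    for (e in seq_len(config$epochs)) {
      lr <- cosine_lr(e - 1L, config, config$epochs)
      losses <- numeric(length(data))
      bidx <- split(seq_along(data),
                    ceiling(seq_along(data) / config$batch_size))
      for (b in bidx) {
        acc <- NULL
        for (ci in b) {
          leaves <- ag_wrap_params(params)
          ag_tape_start()
          out <- model_fwd(leaves, buffers, cfg, data[[ci]]$x, data[[ci]]$sp,
                           training = TRUE)
          loss <- nn_dice_loss(out$prob, data[[ci]]$t)
          losses[ci] <- vof(loss)
          if (!is.finite(losses[ci])) {
            ag_tape_stop()
            stop(sprintf("non-finite loss at epoch %d, case %s, lr %.3g",
                         e, cohort[[ci]]$case_id, lr))
          }
          ag_backward(loss)
          ag_tape_stop()
          g <- flatten_params(ag_collect_grads(leaves))
          acc <- if (is.null(acc)) g else acc + g
        }
        if (length(b) > 1L) acc <- acc / length(b)
        upd <- adamw_step(pvec, acc, opt, lr, config, skel$decay)
        pvec <- upd$params
        opt <- upd$state
        params <- relist_params(pvec, skel)
      }
      val_dsc <- NA_real_
      if (e %% config$eval_every == 0L || e == config$epochs) {
        val_dsc <- mean_val_dsc(params, buffers, cfg, val_cohort,
                                config$threshold)
        if (val_dsc > best$dsc) {
          best <- list(dsc = val_dsc, epoch = e, params = params,
                       buffers = buffers_to_list(buffers))
          if (!is.null(config$checkpoint_path)) {
            save_checkpoint(make_train_state(model, params, buffers, opt,
                                             history, best, config),
                            config$checkpoint_path)
          }
        }
      }
      history[[e]] <- tibble::tibble(epoch = e, lr = lr,
                                     loss = mean(losses), val_dsc = val_dsc)
      epochs_run <- e
      if (!is.null(config$stop_dsc) && is.finite(val_dsc) &&
          val_dsc >= config$stop_dsc) break
    }
  })
  model$params <- params
  out <- make_train_state(model, params, buffers, opt,
                          history[seq_len(epochs_run)], best, config)
  if (!is.null(config$checkpoint_path) && best$epoch == 0L) {
    save_checkpoint(out, config$checkpoint_path)
  }
  out
}

make_train_state <- function(model, params, buffers, opt, history, best, config) {
  m <- model
  m$params <- params
  m$buffers <- buffers
  bm <- model
  bm$params <- best$params
  bm$buffers <- list_to_buffers(best$buffers)
  structure(list(model = m, best_model = bm, best_dsc = best$dsc,
                 best_epoch = best$epoch,
                 history = dplyr::bind_rows(history), config = config,
                 optimizer = opt),
            class = "catseg_train")
}

#' @export
print.catseg_train <- function(x, ...) {
  cat("catseg training run:", nrow(x$history), "epoch(s)\n")
  if (nrow(x$history) > 0) {
    cat("  final loss:", signif(utils::tail(x$history$loss, 1), 4), "\n")
  }
  if (is.finite(x$best_dsc)) {
    cat("  best validation mean DSC:", signif(x$best_dsc, 4),
        "at epoch", x$best_epoch, "\n")
  }
  invisible(x)
}

#' @export
tidy.catseg_train <- function(x, ...) x$history

#' @export
glance.catseg_train <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 final_loss = if (nrow(x$history)) utils::tail(x$history$loss, 1) else NA_real_,
                 best_dsc = x$best_dsc, best_epoch = x$best_epoch)
}

mean_val_dsc <- function(params, buffers, cfg, cohort, threshold) {
  vals <- vapply(cohort, function(cs) {
    d <- case_to_matrices(cs)
    if (is.null(d$t)) return(NA_real_)
    out <- model_fwd(params, buffers, cfg, d$x, d$sp, training = FALSE)
    mean(vapply(1:3, function(r) {
      dsc(d$t[, r] >= 0.5, out$prob[, r] >= threshold)
    }, numeric(1)))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Evaluate a model over a cohort
#'
#' Forward pass per case, binarisation with [predict_mask()], all three
#' metrics per region, aggregated with [aggregate_metrics()]. Cases without
#' a mask are skipped with a warning and counted in the report footer.
#'
#' @param model A `catseg_model`, or a function `volume_array -> probability
#'   array` (e.g. an oracle segmenter) for cross-checking.
#' @param cohort List of [case_record()]s.
#' @param threshold Binarisation threshold.
#' @param hd_mode,hd_percentile Hausdorff variant.
#' @param preprocess Apply [preprocess_case()] first (models only; the target
#'   shape is the model's configured input shape).
#' @return A `metric_report`.
#' @export
evaluate_model <- function(model, cohort, threshold = 0.5,
                           hd_mode = "symmetric", hd_percentile = 100,
                           preprocess = inherits(model, "catseg_model")) {
  stopifnot(length(cohort) >= 1L)
  has_mask <- vapply(cohort, function(cs) !is.null(cs$mask), logical(1))
  if (!any(has_mask)) stop("no case in the cohort has a mask")
  if (any(!has_mask)) {
    warning(sum(!has_mask), " case(s) without mask skipped", call. = FALSE)
  }
  if (preprocess && inherits(model, "catseg_model")) {
    cohort <- lapply(cohort, preprocess_case,
                     target_shape = model$config$input_shape)
  }
  rows <- lapply(cohort[has_mask], function(cs) {
    prob <- if (inherits(model, "catseg_model")) {
      suppressWarnings(predict(model, cs))
    } else {
      model(cs$volume$intensities)
    }
    evaluate_case(cs$mask, predict_mask(prob, threshold),
                  case_id = cs$case_id, spacing = cs$volume$spacing,
                  hd_mode = hd_mode, hd_percentile = hd_percentile)
  })
  rep <- aggregate_metrics(dplyr::bind_rows(rows))
  attr(rep, "n_skipped") <- sum(!has_mask)
  rep
}

## ---- checkpointing ----------------------------------------------------------

buffers_to_list <- function(buffers) {
  nms <- ls(buffers)
  out <- lapply(nms, function(nm) list(mean = buffers[[nm]]$mean,
                                       var = buffers[[nm]]$var))
  names(out) <- nms
  out
}

list_to_buffers <- function(lst) {
  env <- new.env(parent = emptyenv())
  for (nm in names(lst)) {
    st <- new.env(parent = emptyenv())
    st$mean <- lst[[nm]]$mean
    st$var <- lst[[nm]]$var
    env[[nm]] <- st
  }
  env
}

#' Save / load a training checkpoint
#'
#' Checkpoints carry the full model configuration, parameters, batch-norm
#' running statistics, optimiser state and history, so evaluation after a
#' load round-trip is bitwise identical.
#'
#' @param state A `catseg_train` (or a bare `catseg_model`).
#' @param path Destination file.
#' @export
save_checkpoint <- function(state, path) {
  if (inherits(state, "catseg_model")) {
    state <- list(model = state)
    class(state) <- "catseg_train"
  }
  ser <- list(config = state$model$config,
              params = state$model$params,
              buffers = buffers_to_list(state$model$buffers),
              best = if (!is.null(state$best_model)) {
                list(params = state$best_model$params,
                     buffers = buffers_to_list(state$best_model$buffers),
                     dsc = state$best_dsc, epoch = state$best_epoch)
              },
              history = state$history,
              optimizer = state$optimizer,
              train_config = state$config)
  saveRDS(ser, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ser <- readRDS(path)
  model <- structure(list(config = ser$config, params = ser$params,
                          buffers = list_to_buffers(ser$buffers)),
                     class = "catseg_model")
  best_model <- model
  best_dsc <- -Inf
  best_epoch <- 0L
  if (!is.null(ser$best)) {
    best_model$params <- ser$best$params
    best_model$buffers <- list_to_buffers(ser$best$buffers)
    best_dsc <- ser$best$dsc
    best_epoch <- ser$best$epoch
  }
  structure(list(model = model, best_model = best_model, best_dsc = best_dsc,
                 best_epoch = best_epoch, history = ser$history,
                 config = ser$train_config, optimizer = ser$optimizer),
            class = "catseg_train")
}
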