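#' Convolutional architecture specification
#'
#' The default is the six-block architecture used throughout: kernels
#' 16@1x3, 32@1x3, 64@1x5, 96@1x7, 128@5x5, 256@3x3 (valid padding,
#' stride 1, no bias — batch normalization follows every convolution),
#' max pools 1x2, 1x2, 1x5, 1x2, 2x2, 2x2, dropout 0.2 after every pool
#' except the last block's 0.5, then dense layers of 128 and 32 ReLU units
#' and a single sigmoid output. Kernel height spans channels and width spans
#' time, so 1xk kernels are purely temporal and the late square kernels mix
#' across channels.
#'
#' @param conv_blocks list of blocks, each a list with `maps`, `kh`, `kw`,
#'   `ph`, `pw`, `dropout`.
#' @param dense_units integer vector of hidden dense layer sizes.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(conv_blocks = NULL, dense_units = c(128L, 32L)) {
  if (is.null(conv_blocks)) {
    maps <- c(16L, 32L, 64L, 96L, 128L, 256L)
    kh <- c(1L, 1L, 1L, 1L, 5L, 3L); kw <- c(3L, 3L, 5L, 7L, 5L, 3L)
    ph <- c(1L, 1L, 1L, 1L, 2L, 2L); pw <- c(2L, 2L, 5L, 2L, 2L, 2L)
    dr <- c(0.2, 0.2, 0.2, 0.2, 0.2, 0.5)
    conv_blocks <- lapply(seq_along(maps), function(i)
      list(maps = maps[i], kh = kh[i], kw = kw[i], ph = ph[i], pw = pw[i],
           dropout = dr[i]))
  }
  for (b in conv_blocks)
    stopifnot(b$maps >= 1, b$kh >= 1, b$kw >= 1, b$ph >= 1, b$pw >= 1,
              b$dropout >= 0, b$dropout < 1)
  structure(list(conv_blocks = conv_blocks,
                 dense_units = as.integer(dense_units)),
            class = "cnn_spec")
}

#' Training configuration
#'
#' Learning rate and batch size default to 2e-4 and 64 (values from the
#' searched grids). Early stopping monitors a label-stratified validation
#' split of the training windows; fine-tuning runs at a reduced rate with a
#' small fixed epoch budget and no holdout, since calibration sets are tiny.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; `0` disables early stopping (all epochs run).
#' @param validation_fraction fraction of training windows held out for
#'   early stopping, in (0, 0.5).
#' @param fine_tune_learning_rate learning rate for calibration fine-tuning
#'   (default a tenth of the training rate).
#' @param fine_tune_max_epochs epoch budget for fine-tuning.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, batch_size = 64L,
                         max_epochs = 100L, early_stop_patience = 5L,
                         validation_fraction = 0.1,
                         fine_tune_learning_rate = learning_rate / 10,
                         fine_tune_max_epochs = 20L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 2, max_epochs >= 1,
            validation_fraction > 0, validation_fraction < 0.5)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 fine_tune_learning_rate = fine_tune_learning_rate,
                 fine_tune_max_epochs = as.integer(fine_tune_max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

.blocks_for_cpp <- function(spec) spec$conv_blocks

#' Trace the conv/pool stack's output shape
#'
#' Per block the spatial extent shrinks by `kernel - 1` (valid convolution,
#' stride 1) and is then floor-divided by the pool size; the flatten
#' dimension is the final map count times the remaining spatial extent. The
#' default stack maps both a 22 x 640 and a 20 x 640 input to 768 nodes.
#'
#' @param n_channels,n_samples input window shape.
#' @param spec a `cnn_spec`.
#' @return Named integer vector `channel_extent`, `time_extent`,
#'   `flatten_dim`. Errors, naming the offending block, if any intermediate
#'   extent is smaller than its kernel or pool.
#' @export
conv_stack_output_shape <- function(n_channels, n_samples, spec = cnn_spec()) {
  .cnn_shape_trace(as.integer(n_channels), as.integer(n_samples),
                   .blocks_for_cpp(spec))
}

#' Build an untrained model
#'
#' He-normal seeded initialization; batch-norm scale/shift start at 1/0.
#'
#' @param n_channels,n_samples input window shape.
#' @param spec a `cnn_spec`.
#' @param seed integer seed; equal seeds give identical initial parameters.
#' @return An object of class `seiz_cnn` (untrained).
#' @export
build_model <- function(n_channels, n_samples, spec = cnn_spec(), seed = 1L) {
  params <- .cnn_init(as.integer(n_channels), as.integer(n_samples),
                      .blocks_for_cpp(spec), spec$dense_units,
                      as.integer(seed))
  structure(list(params = params, spec = spec, seed = as.integer(seed),
                 trained = FALSE, history = NULL),
            class = "seiz_cnn")
}

#' @export
print.seiz_cnn <- function(x, ...) {
  cat(sprintf("<seiz_cnn> %d x %d input, %d conv blocks, %s; %s\n",
              x$params$n_channels, x$params$n_samples,
              length(x$spec$conv_blocks),
              paste0(format(count_parameters(x), big.mark = ","), " parameters"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Total trainable parameter count
#'
#' Convolution weights (no bias), batch-norm scale and shift, dense weights
#' and biases. A pure function of the input channel count and the spec.
#'
#' @param model a `seiz_cnn`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  p <- model$params
  n <- 0
  for (b in p$conv)
    n <- n + length(b$W) + length(b$gamma) + length(b$beta)
  for (d in p$dense)
    n <- n + length(d$W) + length(d$b)
  as.integer(n)
}

# stratified tail reordering: move a label-balanced validation split to the
# end of the array, as the C++ trainer expects
.val_split_order <- function(labels, fraction, seed) {
  n <- length(labels)
  n_val <- max(2L, as.integer(round(n * fraction)))
  idx_val <- withr::with_seed(seed, {
    pos <- which(labels == 1); neg <- which(labels == 0)
    nv_pos <- max(1L, round(n_val * length(pos) / n))
    nv_neg <- max(1L, n_val - nv_pos)
    c(sample(pos, min(nv_pos, length(pos))),
      sample(neg, min(nv_neg, length(neg))))
  })
  list(order = c(setdiff(seq_len(n), idx_val), idx_val),
       n_val = length(idx_val))
}

.windows_to_cube <- function(ws) {
  # n x ch x samp -> ch x samp x n
  aperm(ws$windows, c(2, 3, 1))
}

#' Train the model
#'
#' Adam on binary cross-entropy over standardized windows, with early
#' stopping on a stratified validation holdout; returns the
#' best-validation checkpoint and the per-epoch loss history.
#'
#' @param model an untrained (or starting-point) `seiz_cnn`.
#' @param train_windows a standardized `window_set` containing both classes.
#' @param config a `train_config`.
#' @return A trained `seiz_cnn` with a `history` data.frame.
#' @export
train_model <- function(model, train_windows, config = train_config()) {
  stopifnot(inherits(model, "seiz_cnn"), inherits(train_windows, "window_set"))
  y <- train_windows$labels
  if (length(unique(y)) < 2)
    stop("training windows contain a single class")
  use_val <- config$early_stop_patience > 0
  if (use_val) {
    sp <- .val_split_order(y, config$validation_fraction, config$seed)
    ws <- subset_windows(train_windows, sp$order)
    n_val <- sp$n_val
  } else {
    ws <- train_windows
    n_val <- 0L
  }
  fit <- .cnn_train(model$params, .windows_to_cube(ws),
                    as.numeric(ws$labels), as.integer(n_val),
                    config$learning_rate, config$batch_size,
                    config$max_epochs,
                    max(config$early_stop_patience, 1L), config$seed)
  model$params <- fit$params
  model$trained <- TRUE
  model$history <- data.frame(
    epoch = seq_along(fit$train_loss),
    train_loss = fit$train_loss,
    val_loss = if (length(fit$val_loss)) fit$val_loss else NA_real_)
  model
}

#' Fine-tune a trained model on calibration windows
#'
#' Continues optimization from the patient-independent checkpoint — no
#' re-initialization — at the reduced fine-tuning rate for a bounded number
#' of epochs, on the calibration seizures' windows only. With an epoch
#' budget of 0 the model is returned unchanged. The input checkpoint object
#' is never mutated.
#'
#' @param model a trained `seiz_cnn`.
#' @param cal_windows `window_set` from the target patient, standardized
#'   with the calibration statistics.
#' @param config a `train_config`.
#' @return The calibrated `seiz_cnn`.
#' @export
fine_tune <- function(model, cal_windows, config = train_config()) {
  stopifnot(inherits(model, "seiz_cnn"))
  if (!model$trained) stop("fine_tune requires a trained model")
  if (!inherits(cal_windows, "window_set") || dim(cal_windows$windows)[1] == 0)
    stop("empty calibration window set")
  if (config$fine_tune_max_epochs == 0L) return(model)
  fit <- .cnn_train(model$params, .windows_to_cube(cal_windows),
                    as.numeric(cal_windows$labels), 0L,
                    config$fine_tune_learning_rate, config$batch_size,
                    config$fine_tune_max_epochs, 1L, config$seed + 1L)
  model$params <- fit$params
  model$history <- rbind(model$history,
                         data.frame(epoch = seq_along(fit$train_loss),
                                    train_loss = fit$train_loss,
                                    val_loss = NA_real_))
  model
}

#' Predict preictal probabilities
#'
#' Deterministic inference: dropout off, batch normalization in running-
#' statistics mode; order-preserving over the input windows.
#'
#' @param model a trained `seiz_cnn`.
#' @param windows a `window_set` with matching channel/sample shape.
#' @return Numeric vector of probabilities in (0, 1), one per window.
#' @export
predict_proba <- function(model, windows) {
  stopifnot(inherits(model, "seiz_cnn"), inherits(windows, "window_set"))
  .cnn_predict(model$params, .windows_to_cube(windows))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain JSON (parameters, spec, seed), portable and
#' diffable; loading reconstructs an identical predictor.
#'
#' @param model a `seiz_cnn`.
#' @param path file path ending in .json.
#' @return `path` (save) or the restored `seiz_cnn` (load).
#' @export
save_checkpoint <- function(model, path) {
  jsonlite::write_json(
    list(params = model$params, dense_units = model$spec$dense_units,
         conv_blocks = model$spec$conv_blocks, seed = model$seed,
         trained = model$trained),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  # reconstruct explicitly rather than relying on jsonlite simplification,
  # which would collapse the homogeneous per-block lists into data frames
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num_vec <- function(v) vapply(v, as.numeric, 0)
  num_mat <- function(w) do.call(rbind, lapply(w, num_vec))
  block_geom <- function(b)
    list(maps = as.integer(b$maps), kh = as.integer(b$kh),
         kw = as.integer(b$kw), ph = as.integer(b$ph),
         pw = as.integer(b$pw), dropout = as.numeric(b$dropout))
  params <- list(
    n_channels = as.integer(j$params$n_channels),
    n_samples = as.integer(j$params$n_samples),
    conv = lapply(j$params$conv, function(b)
      c(block_geom(b),
        list(W = num_mat(b$W), gamma = num_vec(b$gamma),
             beta = num_vec(b$beta), run_mean = num_vec(b$run_mean),
             run_var = num_vec(b$run_var)))),
    dense = lapply(j$params$dense, function(d)
      list(W = num_mat(d$W), b = num_vec(d$b))))
  blocks <- lapply(j$conv_blocks, block_geom)
  structure(list(params = params,
                 spec = cnn_spec(blocks, as.integer(j$dense_units)),
                 seed = j$seed, trained = isTRUE(j$trained), history = NULL),
            class = "seiz_cnn")
}
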