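#' Hyperparameter specification for the classifiers
#'
#' Defaults follow the compact architecture used throughout the package:
#' 4 filters of 3x3 per convolutional layer, two fully connected layers of 32
#' units, dropout 0.5 before the output, batch size 32, Adam with binary
#' cross-entropy. `epochs` caps training; the checkpoint with the best
#' validation loss is always the one returned, so the cap is a budget, not a
#' stopping rule.
#'
#' @param kind `"CNN"` (voronoi-image input) or `"NN"` (deviation vector plus
#'   MD and sLV).
#' @param conv_filters,kernel,fc_units,dropout,batch_size architecture and
#'   training hyperparameters.
#' @param lr Adam step size.
#' @param epochs maximum training epochs.
#' @param seed controls weight initialization (and, via [train_model()],
#'   shuffling and dropout noise).
#' @return An object of class `"vf_model_spec"`.
#' @export
model_spec <- function(kind = c("CNN", "NN"), conv_filters = 4, kernel = 3,
                       fc_units = 32, dropout = 0.5, batch_size = 32,
                       lr = 1e-3, epochs = 100, seed = 1) {
  kind <- match.arg(kind)
  for (v in c(conv_filters, kernel, fc_units, batch_size, epochs))
    if (!is_count(v)) stop_fmt("model_spec: hyperparameters must be positive integers")
  if (kernel != 3) stop_fmt("only 3x3 kernels are supported")
  if (dropout < 0 || dropout >= 1) stop_fmt("dropout must be in [0, 1)")
  if (lr <= 0) stop_fmt("lr must be positive")
  structure(list(kind = kind, conv_filters = conv_filters, kernel = kernel,
                 fc_units = fc_units, dropout = dropout,
                 batch_size = batch_size, optimizer = "adam",
                 loss = "binary_crossentropy", lr = lr, epochs = epochs,
                 seed = as.integer(seed)),
            class = "vf_model_spec")
}

#' Build the untrained convolutional classifier
#'
#' The network takes one 61x61 voronoi image and returns the probability of
#' the early-glaucoma class. Architecture: two conv(4, 3x3)-BN-ReLU blocks,
#' max-pool /2, two more conv-BN-ReLU blocks, max-pool /2, a fifth
#' conv-BN-ReLU block, global average pooling, FC-32-ReLU-BN,
#' FC-32-ReLU-dropout(0.5), FC-1 with sigmoid. "Same" padding keeps spatial
#' maps at 61 -> 31 -> 16 across the two pools.
#'
#' @param spec a [model_spec()] with `kind = "CNN"`.
#' @return An untrained `"vf_network"`; initialization is a pure function of
#'   `spec$seed`.
#' @export
build_cnn <- function(spec = model_spec("CNN")) {
  stopifnot(inherits(spec, "vf_model_spec"))
  if (spec$kind != "CNN") stop_fmt("build_cnn needs spec kind 'CNN'")
  f <- spec$conv_filters
  u <- spec$fc_units
  with_seed(spec$seed, {
    layers <- list(
      layer_conv(1, f, 61), layer_bn(f), layer_relu(),
      layer_conv(f, f, 61), layer_bn(f), layer_relu(),
      layer_pool(61),
      layer_conv(f, f, 31), layer_bn(f), layer_relu(),
      layer_conv(f, f, 31), layer_bn(f), layer_relu(),
      layer_pool(31),
      layer_conv(f, f, 16), layer_bn(f), layer_relu(),
      layer_gap(16),
      layer_dense(f, u), layer_relu(), layer_bn(u),
      layer_dense(u, u), layer_relu(), layer_dropout(spec$dropout),
      layer_dense(u, 1, head = TRUE)
    )
    net <- new_network(layers, input = list(type = "image", side = 61L),
                       head = "sigmoid", kind = "cnn")
    net$spec <- spec
    net
  })
}

#' Build the untrained flat neural-network baseline
#'
#' Input is the concatenation of the deviation vector with MD and sLV
#' (`L + 2` features); two FC-32 ReLU hidden layers, dropout 0.5 after the
#' second, sigmoid output — the dense head of the CNN without the
#' convolutional trunk.
#'
#' @param spec a [model_spec()] with `kind = "NN"`.
#' @param input_len number of input features (pattern `L` plus 2).
#' @return An untrained `"vf_network"`.
#' @export
build_nn <- function(spec = model_spec("NN"), input_len) {
  stopifnot(inherits(spec, "vf_model_spec"))
  if (spec$kind != "NN") stop_fmt("build_nn needs spec kind 'NN'")
  if (!is_count(input_len)) stop_fmt("input_len must be a positive integer")
  u <- spec$fc_units
  with_seed(spec$seed, {
    layers <- list(
      layer_dense(input_len, u), layer_relu(),
      layer_dense(u, u), layer_relu(), layer_dropout(spec$dropout),
      layer_dense(u, 1, head = TRUE)
    )
    net <- new_network(layers, input = list(type = "vector", d = as.integer(input_len)),
                       head = "sigmoid", kind = "nn")
    net$spec <- spec
    net
  })
}

# Model-ready inputs for the flat NN: deviations plus MD and sLV.
nn_features <- function(records, pattern) {
  cbind(vf_deviations(records, pattern),
        md = global_indices(records, pattern)$md,
        slv = global_indices(records, pattern)$slv)
}

#' Train a classifier with validation-loss checkpointing
#'
#' Minimizes binary cross-entropy with Adam on mini-batches and returns the
#' parameters of the epoch with the lowest validation loss. Training and
#' validation sets must be subject-disjoint; the training set must contain
#' both classes.
#'
#' @param network an untrained `"vf_network"` from [build_cnn()] or
#'   [build_nn()].
#' @param train,val lists with elements `x` (3721 x n image matrix for the
#'   CNN, n x (L+2) feature matrix for the NN), `y` (0/1 labels, 1 = EG) and
#'   optionally `subjects` (enables the leakage check).
#' @param epochs,batch_size,lr override the spec's training settings.
#' @param seed controls shuffling and dropout noise.
#' @param verbose print per-epoch losses.
#' @return An object of class `"vf_model"`: `network` (weights at the
#'   selected checkpoint), `spec`, `history` (per-epoch train/validation
#'   loss) and `selected_epoch`.
#' @export
train_model <- function(network, train, val, epochs = NULL, batch_size = NULL,
                        lr = NULL, seed = 1, verbose = FALSE) {
  stopifnot(inherits(network, "vf_network"))
  spec <- network$spec %||% model_spec(toupper(network$kind))
  epochs <- epochs %||% spec$epochs
  batch_size <- batch_size %||% spec$batch_size
  lr <- lr %||% spec$lr
  n_tr <- if (network$input$type == "image") ncol(train$x) else nrow(train$x)
  n_va <- if (network$input$type == "image") ncol(val$x) else nrow(val$x)
  if (n_tr == 0 || n_va == 0) stop_fmt("train and validation sets must be non-empty")
  if (!is.null(train$subjects) && !is.null(val$subjects)) {
    leak <- intersect(unique(train$subjects), unique(val$subjects))
    if (length(leak))
      stop_fmt("subject(s) %s appear in both training and validation sets",
               paste(utils::head(leak, 3), collapse = ", "))
  }
  if (length(unique(train$y)) < 2)
    stop_fmt("training set must contain both classes")
  res <- train_network(network, train$x, train$y, val$x, val$y,
                       epochs = epochs, batch_size = batch_size, lr = lr,
                       seed = seed, verbose = verbose)
  structure(list(network = res$network, spec = spec, history = res$history,
                 selected_epoch = res$selected_epoch),
            class = "vf_model")
}

#' Predict early-glaucoma probabilities
#'
#' Inference is deterministic: dropout is disabled and batch normalization
#' uses its running statistics, so batching never changes per-record scores.
#'
#' @param object a `"vf_model"` (or the higher-level `"vf_cnn"` / `"vf_nn"`
#'   fits).
#' @param newdata model-ready inputs (image matrix / feature matrix), or for
#'   `"vf_cnn"` / `"vf_nn"` a `"vf_table"` of records.
#' @param ... unused.
#' @return numeric vector of scores in (0, 1).
#' @export
predict.vf_model <- function(object, newdata, ...) {
  net <- object$network
  if (net$input$type == "image") {
    if (inherits(newdata, "voronoi_image")) newdata <- matrix(newdata$values, ncol = 1)
    if (!is.matrix(newdata) || nrow(newdata) != 3721)
      stop_fmt("CNN input must be a 3721 x n image matrix")
  } else {
    if (!is.matrix(newdata) || ncol(newdata) != net$input$d)
      stop_fmt("NN input must have %d features", net$input$d)
  }
  predict_network(net, newdata)
}

#' @export
print.vf_model <- function(x, ...) {
  cat(sprintf("Trained %s: %d parameters, selected epoch %d/%d (val loss %.4f)\n",
              toupper(x$network$kind), n_params(x$network), x$selected_epoch,
              nrow(x$history), x$history$val_loss[x$selected_epoch]))
  invisible(x)
}

#' @export
summary.vf_model <- function(object, ...) {
  print(object)
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.vf_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$selected_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

# Subject-grouped, label-stratified internal validation split.
validation_subjects <- function(records, fraction = 0.1, seed = 1) {
  with_seed(seed, {
    picks <- character(0)
    for (g in unique(records$group)) {
      subj <- unique(records$subject_id[records$group == g])
      n_val <- max(1L, round(fraction * length(subj)))
      if (n_val >= length(subj)) n_val <- length(subj) - 1L
      if (n_val > 0) picks <- c(picks, sample(subj, n_val))
    }
    picks
  })
}

#' Fit the voronoi-image CNN on a labelled VF table
#'
#' High-level fitting interface: rasterizes the records (mirroring OS eyes),
#' holds out a subject-grouped, label-stratified validation split, trains with
#' [train_model()] and returns a classed fit whose `predict` method accepts VF
#' tables directly.
#'
#' @param records labelled `"vf_table"`.
#' @param pattern the associated [test_pattern()].
#' @param val_fraction fraction of subjects (per group) held out for
#'   validation-loss checkpointing.
#' @param spec a [model_spec()]; `kind` is forced to the fitted model type.
#' @param seed one seed driving initialization, the validation split,
#'   shuffling and dropout.
#' @param ... passed to [train_model()] (e.g. `epochs`, `verbose`).
#' @return An object of classes `"vf_cnn"`, `"vf_model"`.
#' @export
vf_cnn <- function(records, pattern, val_fraction = 0.1,
                   spec = model_spec("CNN"), seed = 1, ...) {
  spec$kind <- "CNN"
  spec$seed <- derive_seed(seed, 1)
  rmres <- region_assignment(pattern)
  fit_highlevel(records, pattern, spec, val_fraction, seed,
                to_x = function(rec) voronoi_image_matrix(rec, rmres, pattern),
                builder = function(s) build_cnn(s),
                subclass = "vf_cnn", region_map = rmres, ...)
}

#' Fit the flat NN baseline on a labelled VF table
#'
#' @inheritParams vf_cnn
#' @return An object of classes `"vf_nn"`, `"vf_model"`.
#' @export
vf_nn <- function(records, pattern, val_fraction = 0.1,
                  spec = model_spec("NN"), seed = 1, ...) {
  spec$kind <- "NN"
  spec$seed <- derive_seed(seed, 1)
  fit_highlevel(records, pattern, spec, val_fraction, seed,
                to_x = function(rec) t(nn_features(rec, pattern)),
                builder = function(s) build_nn(s, pattern$L + 2L),
                subclass = "vf_nn", transpose_x = TRUE, ...)
}

fit_highlevel <- function(records, pattern, spec, val_fraction, seed, to_x,
                          builder, subclass, region_map = NULL,
                          transpose_x = FALSE, ...) {
  if (anyNA(records$group)) stop_fmt("all records must be labelled for fitting")
  val_subj <- validation_subjects(records, val_fraction, derive_seed(seed, 2))
  is_val <- records$subject_id %in% val_subj
  xs <- to_x(records)
  if (transpose_x) xs <- t(xs)  # back to n x D for vector nets
  y <- as.numeric(records$group == "EG")
  pick <- function(keep) {
    x <- if (transpose_x) xs[keep, , drop = FALSE] else xs[, keep, drop = FALSE]
    list(x = x, y = y[keep], subjects = records$subject_id[keep])
  }
  net <- builder(spec)
  fit <- train_model(net, pick(!is_val), pick(is_val),
                     seed = derive_seed(seed, 3), ...)
  fit$pattern <- pattern
  fit$region_map <- region_map
  fit$val_subjects <- val_subj
  class(fit) <- c(subclass, class(fit))
  fit
}

#' @export
predict.vf_cnn <- function(object, newdata, ...) {
  if (inherits(newdata, "data.frame"))
    newdata <- voronoi_image_matrix(newdata, object$region_map, object$pattern)
  NextMethod()
}

#' @export
predict.vf_nn <- function(object, newdata, ...) {
  if (inherits(newdata, "data.frame"))
    newdata <- nn_features(newdata, object$pattern)
  NextMethod()
}

#' Save / load a trained model
#'
#' The weight container is written in R's native serialized form next to a
#' JSON sidecar recording the spec, seed and selected epoch.
#'
#' @param model a `"vf_model"`.
#' @param path output `.rds` path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(list(spec = unclass(model$spec),
                            selected_epoch = model$selected_epoch,
                            n_params = n_params(model$network)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
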