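#' Training hyperparameters
#'
#' The optimization regime for [train_cnn()]: mean squared error loss
#' minimized by Adam over mini-batches, with validation-based early stopping.
#' Defaults: 250 epochs, batch size 64, learning rate 1e-3 (Adam's customary
#' step size; with only a few thousand updates in a run, much smaller rates
#' bound the total per-weight movement below what feature learning requires),
#' a 10% validation split, and patience of 25 epochs with the best-validation
#' weights restored.
#'
#' @param epochs Maximum number of epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param validation_fraction Fraction of the training set held out for early
#'   stopping, in (0, 1); set to 0 to disable early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param warm_start_output Initialize the output weights to zero and the
#'   output bias to the mean training label, so optimization starts from the
#'   best constant predictor.  With a rectified-linear output head this also
#'   guarantees a live gradient at the first step; a head whose
#'   pre-activations start negative on every sample would never learn.
#' @param seed Optional integer seed; fixes the validation split, weight
#'   initialization noise consumed here, mini-batch order and dropout masks.
#'
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 250, learning_rate = 1e-3, batch_size = 64,
                            validation_fraction = 0.1, patience = 25,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                            warm_start_output = TRUE, seed = NULL) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            validation_fraction >= 0, validation_fraction < 1, patience >= 1)
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         validation_fraction = validation_fraction,
         patience = as.integer(patience),
         beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         warm_start_output = isTRUE(warm_start_output), seed = seed),
    class = "training_config"
  )
}

#' Build an untrained strain-regression network
#'
#' Instantiates the layer stack of a [cnn_spec()] for a given input shape and
#' initializes the weights (Glorot uniform; the output layer is left at zero
#' and is warm-started by [train_cnn()]).
#'
#' @param spec A [cnn_spec()].
#' @param seed Optional integer seed for the weight initialization.
#' @param input_height,input_width Input dimensions (3 x 201 by default).
#'
#' @return An object of class `strain_cnn` (untrained).
#' @export
#' @examples
#' model <- build_cnn(cnn_spec(), seed = 1)
#' glance(model)$n_parameters  # 98465
build_cnn <- function(spec = cnn_spec(), seed = NULL,
                      input_height = 3, input_width = 201) {
  stopifnot(inherits(spec, "cnn_spec"))
  shapes <- cnn_shapes(spec, input_height, input_width)
  if (!is.null(seed)) withr::local_seed(seed)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  weights <- list()
  rows <- input_height
  for (l in seq_along(spec$conv_filters)) {
    f <- spec$conv_filters[l]
    patch <- rows * spec$conv_kernel[l]
    weights[[length(weights) + 1]] <- glorot(f, patch)
    weights[[length(weights) + 1]] <- matrix(0, f, 1)
    rows <- f
  }
  prev <- shapes$flatten
  n_fc <- length(spec$fc_sizes)
  for (i in seq_len(n_fc)) {
    h <- spec$fc_sizes[i]
    W <- if (i == n_fc) matrix(0, h, prev) else glorot(h, prev)
    weights[[length(weights) + 1]] <- W
    weights[[length(weights) + 1]] <- matrix(0, h, 1)
    prev <- h
  }
  structure(
    list(spec = spec, weights = weights,
         input_height = input_height, input_width = input_width,
         trained = FALSE, history = NULL, best_epoch = NA_integer_,
         measure = NULL, config = NULL),
    class = "strain_cnn"
  )
}

# accepts a strain_input, an N x 3 x 201 array, or a D x N matrix, and
# returns the flattened column-major (channel-fastest) D x N input matrix
as_input_matrix <- function(data, input_height = 3, input_width = 201) {
  if (inherits(data, "strain_input")) data <- data$inputs
  D <- input_height * input_width
  if (is.matrix(data)) {
    if (nrow(data) != D) abort(paste0("input matrix must have ", D, " rows"))
    return(data)
  }
  if (is.array(data) && length(dim(data)) == 3) {
    d <- dim(data)
    if (d[2] != input_height || d[3] != input_width) {
      abort(paste0("inputs must be N x ", input_height, " x ", input_width,
                   "; got N x ", d[2], " x ", d[3]))
    }
    X <- matrix(0, D, d[1])
    for (i in seq_len(d[1])) X[, i] <- as.vector(data[i, , ])
    return(X)
  }
  abort("inputs must be a strain_input, an N x 3 x 201 array, or a matrix")
}

#' Train a strain-regression network
#'
#' Minimizes the mean squared error between predicted and reference strains
#' with the Adam optimizer.  A validation split is carved from the training
#' data for early stopping; the weights achieving the best validation loss
#' are restored.  Training aborts with diagnostics if the loss becomes
#' non-finite.
#'
#' @param model An untrained (or previously trained) [build_cnn()] model.
#' @param data A `strain_input`, an N x 3 x 201 array, or a D x N matrix of
#'   flattened inputs.
#' @param labels Numeric vector of non-negative strain labels, or `NULL` to
#'   pull the column named by `measure` from `data$labels`.
#' @param config A [training_config()].
#' @param measure Which strain measure this model targets (one of
#'   [strain_measures()]); informational unless used to pull labels.
#'
#' @return The fitted `strain_cnn`: weights at the best validation epoch,
#'   with `history` (per-epoch train/validation loss), `best_epoch`, and the
#'   training configuration recorded.
#' @export
train_cnn <- function(model, data, labels = NULL, config = training_config(),
                      measure = NULL) {
  stopifnot(inherits(model, "strain_cnn"), inherits(config, "training_config"))
  X <- as_input_matrix(data, model$input_height, model$input_width)
  if (is.null(labels)) {
    if (is.null(measure) || !inherits(data, "strain_input") || is.null(data$labels)) {
      abort("labels are required (or pass a labelled strain_input plus measure)")
    }
    labels <- data$labels[[measure]]
  }
  N <- ncol(X)
  if (length(labels) != N) abort("length(labels) must match the number of inputs")
  if (any(!is.finite(labels)) || any(labels < 0)) {
    abort("labels must be finite and non-negative strains")
  }
  if (N < config$batch_size) {
    abort(paste0("need at least batch_size = ", config$batch_size, " samples"))
  }
  if (!is.null(config$seed)) withr::local_seed(config$seed)

  n_val <- floor(config$validation_fraction * N)
  val_idx <- if (n_val > 0) sample.int(N, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(N), val_idx)

  weights <- model$weights
  if (config$warm_start_output) {
    nw <- length(weights)
    weights[[nw - 1]][] <- 0
    weights[[nw]][] <- mean(labels[tr_idx])
  }
  geom <- cnn_geometry(model$spec, model$input_height, model$input_width)
  cpp_seed <- sample.int(.Machine$integer.max, 1)
  fit <- cnn_train_cpp(
    weights, X[, tr_idx, drop = FALSE], labels[tr_idx],
    X[, val_idx, drop = FALSE], labels[val_idx],
    geom$idx, length(model$spec$conv_filters),
    config$epochs, config$learning_rate, config$batch_size,
    model$spec$dropout_rate, config$patience, cpp_seed,
    config$beta1, config$beta2, config$epsilon
  )
  model$weights <- fit$weights
  model$history <- tibble::tibble(
    epoch = seq_along(fit$train_loss),
    train_loss = as.numeric(fit$train_loss),
    val_loss = if (n_val > 0) as.numeric(fit$val_loss) else NA_real_
  )
  model$best_epoch <- as.integer(fit$best_epoch)
  model$trained <- TRUE
  model$config <- config
  model$measure <- measure
  model
}

#' Predict strains with a trained network
#'
#' Inference is deterministic (dropout disabled) and the rectified-linear
#' output head guarantees non-negative strain estimates.
#'
#' @param object A trained `strain_cnn`.
#' @param newdata A `strain_input`, N x 3 x 201 array, or D x N matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted strains (one per input sample).
#' @export
predict.strain_cnn <- function(object, newdata, ...) {
  if (!object$trained) warn("predicting with an untrained model")
  X <- as_input_matrix(newdata, object$input_height, object$input_width)
  geom <- cnn_geometry(object$spec, object$input_height, object$input_width)
  as.numeric(cnn_predict_cpp(object$weights, X, geom$idx,
                             length(object$spec$conv_filters)))
}

#' @export
print.strain_cnn <- function(x, ...) {
  sh <- cnn_shapes(x$spec, x$input_height, x$input_width)
  cat("<strain_cnn> ", if (x$trained) "trained" else "untrained",
      if (!is.null(x$measure)) paste0(" [", x$measure, "]") else "", "\n",
      sep = "")
  cat("  conv widths: ", paste(sh$conv_widths, collapse = " -> "),
      "; flatten ", sh$flatten, "; fc ",
      paste(x$spec$fc_sizes, collapse = " -> "), "\n", sep = "")
  cat("  parameters:", sh$n_parameters, "\n")
  if (!is.null(x$history)) {
    cat("  best epoch ", x$best_epoch, " of ", nrow(x$history),
        " (val loss ", signif(min(x$history$val_loss, na.rm = TRUE), 4), ")\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy the training history of a fitted network
#'
#' @param x A `strain_cnn`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.strain_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0)))
  }
  x$history
}

#' One-row model summary
#'
#' @param x A `strain_cnn`.
#' @param ... Unused.
#' @return Tibble with `n_parameters`, `trained`, `measure`, `epochs_run`,
#'   `best_epoch`, `best_val_loss`.
#' @export
glance.strain_cnn <- function(x, ...) {
  sh <- cnn_shapes(x$spec, x$input_height, x$input_width)
  tibble::tibble(
    n_parameters = sh$n_parameters,
    trained = x$trained,
    measure = x$measure %||% NA_character_,
    epochs_run = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = if (is.null(x$history)) NA_real_ else
      suppressWarnings(min(x$history$val_loss, na.rm = TRUE))
  )
}

#' Plot training and validation loss curves
#'
#' @param object A fitted `strain_cnn`.
#' @param ... Unused.
#' @return A ggplot object (log-scale MSE loss by epoch).
#' @export
autoplot.strain_cnn <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a trained network as plain text
#'
#' The model directory holds `manifest.json` (architecture, training
#' configuration, history, best epoch) and `weights.csv` (layer, index,
#' value), both diffable text.
#'
#' @param model A `strain_cnn`.
#' @param dir Directory to create/overwrite.
#' @return `save_cnn`: `model` invisibly; `load_cnn`: a `strain_cnn`.
#' @export
save_cnn <- function(model, dir) {
  stopifnot(inherits(model, "strain_cnn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    spec = unclass(model$spec),
    input_height = model$input_height, input_width = model$input_width,
    trained = model$trained, best_epoch = model$best_epoch,
    measure = model$measure,
    config = if (!is.null(model$config)) unclass(model$config),
    history = if (!is.null(model$history)) as.list(model$history),
    weight_dims = lapply(model$weights, dim)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  w <- dplyr::bind_rows(purrr::imap(model$weights, function(m, i) {
    tibble::tibble(layer = i, index = seq_along(m), value = as.vector(m))
  }))
  readr::write_csv(w, file.path(dir, "weights.csv"))
  invisible(model)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  spec <- cnn_spec(conv_filters = man$spec$conv_filters,
                   conv_kernel = man$spec$conv_kernel,
                   conv_stride = man$spec$conv_stride,
                   dropout_rate = man$spec$dropout_rate,
                   fc_sizes = man$spec$fc_sizes)
  w <- readr::read_csv(file.path(dir, "weights.csv"),
                       col_types = readr::cols(
                         layer = readr::col_integer(),
                         index = readr::col_integer(),
                         value = readr::col_double()))
  wd <- man$weight_dims  # jsonlite may simplify the dim list to a matrix
  n_layers <- if (is.matrix(wd)) nrow(wd) else length(wd)
  weights <- lapply(seq_len(n_layers), function(i) {
    d <- if (is.matrix(wd)) wd[i, ] else unlist(wd[[i]])
    vals <- w$value[w$layer == i][order(w$index[w$layer == i])]
    matrix(vals, d[1], d[2])
  })
  model <- build_cnn(spec, input_height = man$input_height,
                     input_width = man$input_width)
  model$weights <- weights
  model$trained <- isTRUE(man$trained)
  model$best_epoch <- man$best_epoch
  model$measure <- if (is.null(man$measure)) NULL else man$measure
  if (!is.null(man$history) && length(man$history) > 0) {
    model$history <- tibble::as_tibble(man$history)
  }
  model
}
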