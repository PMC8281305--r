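net_tasks <- function() c("segment17", "segment68", "epiendo", "uvc_regression", "phi_classification")

#' Specify one of the four localization networks
#'
#' All tasks share the same small convolutional topology (two conv+pool
#' blocks, one fully connected layer, linear head): classification heads
#' are trained with softmax cross-entropy, the ventricular-coordinate
#' regressor with mean absolute error. Defaults: batch 23, learning rate
#' 0.001, 10 epochs (15 for the regression), conv filters 16 and 32
#' (3 x 3), fully connected width 128, plain stochastic gradient descent.
#'
#' @param task One of `"segment17"`, `"segment68"`, `"epiendo"`,
#'   `"uvc_regression"`, `"phi_classification"`.
#' @param conv1,conv2 Numbers of 3x3 filters in the two conv blocks.
#' @param fc Fully connected layer width.
#' @param lr Learning rate.
#' @param batch Mini-batch size.
#' @param epochs Training epochs (`NULL` = task default: 15 for
#'   regression, 10 otherwise).
#' @return A `vt_netspec`.
#' @export
build_network <- function(task, conv1 = 16, conv2 = 32, fc = 128,
                          lr = 0.001, batch = 23, epochs = NULL) {
  if (!task %in% net_tasks()) abort(sprintf("unknown task `%s`", task))
  n_out <- switch(task, segment17 = 17L, segment68 = 68L, epiendo = 2L,
                  uvc_regression = 2L, phi_classification = 68L)
  loss <- if (task == "uvc_regression") "mae" else "cross-entropy"
  epochs <- epochs %||% if (task == "uvc_regression") 15L else 10L
  structure(list(task = task, n_out = n_out, loss = loss,
                 conv1 = as.integer(conv1), conv2 = as.integer(conv2),
                 fc = as.integer(fc), lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs)),
            class = "vt_netspec")
}

#' @export
print.vt_netspec <- function(x, ...) {
  cat(sprintf("<vt_netspec> %s: conv %d/%d (3x3), fc %d, %d outputs, %s loss, batch %d, lr %g, %d epochs\n",
              x$task, x$conv1, x$conv2, x$fc, x$n_out, x$loss, x$batch, x$lr, x$epochs))
  invisible(x)
}

#' Train a network on one modality of a dataset
#'
#' Trains on the (augmented) train split only. With `cv_folds`, a k-fold
#' cross-validation report is added: folds group augmented copies by their
#' parent beat so no beat leaks across folds.
#'
#' @param spec A `vt_netspec`.
#' @param dataset A `vt_dataset` (use [epiendo_training_view()] for the
#'   endo/epi task).
#' @param modality `"ecg"` or `"egm"`.
#' @param seed Integer seed (weights init and shuffling).
#' @param cv_folds Optional fold count for a cross-validation report.
#' @return A `vt_model`: spec, weights, per-epoch `history`, optional
#'   `cv` tibble.
#' @export
train_network <- function(spec, dataset, modality, seed = 1L, cv_folds = NULL) {
  stopifnot(inherits(spec, "vt_netspec"))
  modality <- match.arg(modality, c("ecg", "egm"))
  tens <- dataset_tensors(dataset, modality, spec$task, split = "train")
  if (nrow(tens$x) == 0L) abort("train split is empty")
  classify <- spec$loss == "cross-entropy"
  ymat <- if (classify) matrix(as.numeric(tens$y), ncol = 1L) else unname(as.matrix(tens$y))

  cv <- NULL
  if (!is.null(cv_folds)) {
    parents <- dataset$parent[dataset$split == "train"]
    cv <- cross_validate(spec, tens$x, ymat, parents, classify, cv_folds, seed)
  }

  w0 <- cnn_init(spec$conv1, spec$conv2, spec$fc, spec$n_out, as.integer(seed))
  fit <- cnn_fit(w0, tens$x, ymat, classify, spec$lr, spec$batch, spec$epochs,
                 as.integer(seed))
  structure(list(spec = spec, weights = fit$weights,
                 history = tibble(epoch = seq_along(as.numeric(fit$loss)),
                                  loss = as.numeric(fit$loss)),
                 cv = cv, modality = modality, task = spec$task,
                 classes = tens$classes, seed = as.integer(seed)),
            class = "vt_model")
}

cross_validate <- function(spec, x, ymat, parents, classify, folds, seed) {
  up <- unique(parents)
  fold_of <- with_seed(seed, setNames(sample(rep(seq_len(folds), length.out = length(up))), up))
  rows <- lapply(seq_len(folds), function(f) {
    hold <- fold_of[as.character(parents)] == f
    w0 <- cnn_init(spec$conv1, spec$conv2, spec$fc, spec$n_out, as.integer(seed) + f)
    fit <- cnn_fit(w0, x[!hold, , drop = FALSE], ymat[!hold, , drop = FALSE],
                   classify, spec$lr, spec$batch, spec$epochs, as.integer(seed) + f)
    pred <- cnn_forward(fit$weights, x[hold, , drop = FALSE], classify)
    metric <- if (classify) {
      mean(max.col(pred) == ymat[hold, 1L]) * 100
    } else {
      mean(abs(pred - ymat[hold, , drop = FALSE]))
    }
    tibble(fold = f, n_holdout = sum(hold),
           metric = metric,
           metric_name = if (classify) "accuracy_pct" else "mae")
  })
  dplyr::bind_rows(rows)
}

#' @export
print.vt_model <- function(x, ...) {
  cat(sprintf("<vt_model> %s on %s: final training loss %.4f after %d epochs\n",
              x$task, toupper(x$modality), utils::tail(x$history$loss, 1L),
              nrow(x$history)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vt_model <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.vt_model <- function(x, ...) {
  w <- x$weights
  n_par <- sum(vapply(w, length, numeric(1)))
  tibble(task = x$task, modality = x$modality,
         epochs = nrow(x$history), final_loss = utils::tail(x$history$loss, 1L),
         n_parameters = n_par, seed = x$seed)
}

model_input <- function(x) {
  if (inherits(x, "vt_signal_matrix")) matrix(as.vector(x$values), nrow = 1L)
  else if (is.matrix(x) && ncol(x) == 256L) x
  else if (is.matrix(x) && all(dim(x) == c(16L, 16L))) matrix(as.vector(x), nrow = 1L)
  else abort("input must be a vt_signal_matrix, a 16x16 matrix, or an n x 256 matrix")
}

#' Class-probability predictions of a classification network
#'
#' @param model A classification `vt_model`.
#' @param x A `vt_signal_matrix`, a 16 x 16 matrix, or an n x 256 batch.
#' @return Probability matrix (rows sum to 1); a single input gives one row.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "vt_model"))
  if (model$spec$loss != "cross-entropy") abort("predict_proba() needs a classification model")
  cnn_forward(model$weights, model_input(x), TRUE)
}

#' Raw head outputs of a regression network
#' @param model A regression `vt_model`.
#' @param x Input as in [predict_proba()].
#' @return Numeric matrix of head outputs.
#' @export
predict_raw <- function(model, x) {
  stopifnot(inherits(model, "vt_model"))
  cnn_forward(model$weights, model_input(x), FALSE)
}

#' Combine the UVC regressor and the phi-wedge classifier into coordinates
#'
#' z and rho predictions are clipped to `[0, 1]`; phi is the midpoint of
#' the highest-probability wedge.
#'
#' @param regressor `vt_model` trained on `uvc_regression`.
#' @param classifier `vt_model` trained on `phi_classification`.
#' @param x Input batch (same modality as both models).
#' @return Tibble with columns `z`, `rho`, `phi`.
#' @export
predict_uvc <- function(regressor, classifier, x) {
  if (regressor$task != "uvc_regression" || classifier$task != "phi_classification") {
    abort("need a uvc_regression model and a phi_classification model")
  }
  if (!identical(regressor$modality, classifier$modality)) {
    abort("regressor and classifier were trained on different modalities")
  }
  if (inherits(x, "vt_signal_matrix") && !identical(x$modality, regressor$modality)) {
    abort("input modality does not match the models")
  }
  zr <- predict_raw(regressor, x)
  zr <- pmin(pmax(zr, 0), 1)
  p <- predict_proba(classifier, x)
  wedge <- max.col(p, ties.method = "first")
  tibble(z = zr[, 1L], rho = zr[, 2L], phi = wedge_to_phi(wedge), wedge = wedge)
}
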