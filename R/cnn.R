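#' CNN hyperparameter set
#'
#' The compact architecture has a single convolution layer (filters of
#' height 20 spanning the full one-hot alphabet and width `kernel_width`),
#' ReLU rectification, 1x2 max-pooling, one hidden dense layer, dropout,
#' and a 2-node softmax output. The architecture-defining fields
#' (`input_length`, `kernel_width`, `filters`, `hidden_dims`, `epochs`)
#' follow the published optimum per residue type (see [cnn_preset()]);
#' optimizer settings (Adam, learning rate 1e-3, batch 64, dropout 0.5)
#' are package defaults and fully configurable.
#'
#' @param input_length Window length L (`2 * flank_n + 1`).
#' @param kernel_width Convolution filter width k (<= L).
#' @param filters Number of convolution filters F.
#' @param hidden_dims Hidden dense layer width H.
#' @param epochs Training epochs E.
#' @param dropout_rate Dropout probability after the hidden layer.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed for weight init and batch shuffling.
#' @return An object of class `cnn_hyperparams`.
#' @export
cnn_hyperparams <- function(input_length, kernel_width = 9L, filters = 50L,
                            hidden_dims = 200L, epochs = 100L,
                            dropout_rate = 0.5, batch_size = 64L,
                            learning_rate = 1e-3, seed = 1L) {
  L <- as.integer(input_length); k <- as.integer(kernel_width)
  if (k > L) abort(paste0("kernel_width (", k, ") exceeds input_length (", L, ")"))
  if (filters < 1L || hidden_dims < 1L || epochs < 0L) {
    abort("filters and hidden_dims must be >= 1; epochs >= 0")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) abort("learning_rate must be positive")
  structure(list(
    input_length = L, kernel_width = k, filters = as.integer(filters),
    hidden_dims = as.integer(hidden_dims), epochs = as.integer(epochs),
    dropout_rate = dropout_rate, batch_size = as.integer(batch_size),
    learning_rate = learning_rate, seed = as.integer(seed)
  ), class = "cnn_hyperparams")
}

#' Published per-residue hyperparameter presets
#'
#' The optimal settings found by 10-fold cross-validation for each
#' residue type: Ser (L=141, k=9, 50 filters, 200 hidden, 100 epochs),
#' Tyr (L=121, k=9, 100 filters, 50 hidden, 80 epochs), Thr (L=41, k=7,
#' 200 filters, 100 hidden, 40 epochs).
#'
#' @param residue "Ser", "Tyr" or "Thr" (also accepts "S"/"T"/"Y").
#' @param ... Overrides passed to [cnn_hyperparams()] (e.g. `seed`).
#' @return A `cnn_hyperparams` object.
#' @export
cnn_preset <- function(residue = c("Ser", "Tyr", "Thr", "S", "Y", "T"), ...) {
  residue <- match.arg(residue)
  alias <- c(S = "Ser", Y = "Tyr", T = "Thr")
  if (residue %in% names(alias)) residue <- alias[[residue]]
  preset <- switch(residue,
    Ser = list(input_length = 141L, kernel_width = 9L, filters = 50L,
               hidden_dims = 200L, epochs = 100L),
    Tyr = list(input_length = 121L, kernel_width = 9L, filters = 100L,
               hidden_dims = 50L, epochs = 80L),
    Thr = list(input_length = 41L, kernel_width = 7L, filters = 200L,
               hidden_dims = 100L, epochs = 40L)
  )
  do.call(cnn_hyperparams, modifyList(preset, list(...)))
}

# Symbolic layer geometry; pooled length uses floor division (133 -> 66).
compute_shape <- function(hp) {
  conv <- hp$input_length - hp$kernel_width + 1L
  pooled <- conv %/% 2L
  flat <- hp$filters * pooled
  n_par <- hp$filters * (20L * hp$kernel_width) + hp$filters +
    hp$hidden_dims * flat + hp$hidden_dims +
    2L * hp$hidden_dims + 2L
  list(conv_map_length = conv, pooled_map_length = pooled,
       flattened_dim = flat, parameter_count = n_par)
}

#' Build an untrained CNN
#'
#' Instantiates the layer stack and computes the shape report
#' symbolically: `conv_map_length = L - k + 1`,
#' `pooled_map_length = floor(conv_map_length / 2)`,
#' `flattened_dim = filters * pooled_map_length`. For the Ser preset this
#' gives 50 feature maps of length 133 after convolution and 66 after
#' pooling. Weights use fan-in-scaled normal initialisation under the
#' hyperparameter seed.
#'
#' @param hp A [cnn_hyperparams()] object or preset name.
#' @return An object of class `phoscnn_model` with elements `hp`,
#'   `params`, `shape`, `history`, `trained`.
#' @export
#' @examples
#' m <- build_cnn(cnn_preset("Ser"))
#' m$shape$conv_map_length # 133
#' m$shape$pooled_map_length # 66
build_cnn <- function(hp) {
  if (is.character(hp)) hp <- cnn_preset(hp)
  stopifnot(inherits(hp, "cnn_hyperparams"))
  shape <- compute_shape(hp)
  if (shape$pooled_map_length < 1L) {
    abort(paste0("un-poolable geometry: conv map length ",
                 shape$conv_map_length, " gives pooled length ",
                 shape$pooled_map_length))
  }
  params <- cnn_init_params(hp, shape)
  structure(list(hp = hp, params = params, shape = shape,
                 history = tibble::tibble(epoch = integer(),
                                          loss = numeric(),
                                          accuracy = numeric()),
                 trained = FALSE, provenance = NULL),
            class = "phoscnn_model")
}

cnn_init_params <- function(hp, shape) {
  set.seed(hp$seed)
  fan_c <- 20L * hp$kernel_width
  flat <- shape$flattened_dim
  list(
    Wc = matrix(rnorm(fan_c * hp$filters, 0, sqrt(2 / fan_c)),
                nrow = fan_c, ncol = hp$filters),
    bc = numeric(hp$filters),
    W1 = matrix(rnorm(flat * hp$hidden_dims, 0, sqrt(2 / flat)),
                nrow = flat, ncol = hp$hidden_dims),
    b1 = numeric(hp$hidden_dims),
    W2 = matrix(rnorm(hp$hidden_dims * 2L, 0, sqrt(2 / hp$hidden_dims)),
                nrow = hp$hidden_dims, ncol = 2L),
    b2 = numeric(2L)
  )
}

# Sparse patch matrix for the convolution-as-matmul trick: row (i-1)*m+j
# holds the one-hot of window i's k-mer starting at position j; columns
# are (offset-1)*20 + residue code. 'X' contributes no entry.
build_patch_matrix <- function(ord, k) {
  n <- nrow(ord); L <- ncol(ord); m <- L - k + 1L
  row_vec <- rep((seq_len(n) - 1L) * m, each = m) + rep(seq_len(m), n)
  is <- integer(0); js <- integer(0)
  for (t in seq_len(k)) {
    v <- as.vector(t(ord[, t:(t + m - 1L), drop = FALSE]))
    hit <- v > 0L
    is <- c(is, row_vec[hit])
    js <- c(js, (t - 1L) * 20L + v[hit])
  }
  Matrix::sparseMatrix(i = is, j = js, x = 1,
                       dims = c(n * m, 20L * k))
}

# Forward pass on a block of samples. P_rows: sparse patch rows for the
# block (b*m rows). Returns intermediates needed for backprop.
cnn_forward <- function(params, P_rows, b, m, p, dropout_mask = NULL) {
  F_ <- ncol(params$Wc)
  Z1 <- as.matrix(P_rows %*% params$Wc) +
    matrix(params$bc, nrow = b * m, ncol = F_, byrow = TRUE)
  A1 <- pmax(Z1, 0)
  base <- rep((seq_len(b) - 1L) * m, each = p)
  oi <- base + rep(seq(1L, 2L * p, by = 2L), b)
  ei <- oi + 1L
  odd_wins <- A1[oi, , drop = FALSE] >= A1[ei, , drop = FALSE]
  Ap <- ifelse(odd_wins, A1[oi, , drop = FALSE], A1[ei, , drop = FALSE])
  X2 <- t(matrix(aperm(array(Ap, c(p, b, F_)), c(1, 3, 2)), nrow = p * F_))
  H1 <- X2 %*% params$W1 +
    matrix(params$b1, nrow = b, ncol = length(params$b1), byrow = TRUE)
  A2 <- pmax(H1, 0)
  A2d <- if (is.null(dropout_mask)) A2 else A2 * dropout_mask
  Z3 <- A2d %*% params$W2 +
    matrix(params$b2, nrow = b, ncol = 2L, byrow = TRUE)
  Z3s <- Z3 - apply(Z3, 1, max)
  expZ <- exp(Z3s)
  probs <- expZ / rowSums(expZ)
  list(Z1 = Z1, A1 = A1, oi = oi, ei = ei, odd_wins = odd_wins,
       Ap = Ap, X2 = X2, H1 = H1, A2d = A2d, probs = probs)
}

cnn_backward <- function(params, fw, P_rows, y01, b, m, p, dropout_mask) {
  F_ <- ncol(params$Wc)
  Y <- cbind(1 - y01, y01)
  dZ3 <- (fw$probs - Y) / b
  dW2 <- crossprod(fw$A2d, dZ3)
  db2 <- colSums(dZ3)
  dA2d <- dZ3 %*% t(params$W2)
  if (!is.null(dropout_mask)) dA2d <- dA2d * dropout_mask
  dH1 <- dA2d * (fw$H1 > 0)
  dW1 <- crossprod(fw$X2, dH1)
  db1 <- colSums(dH1)
  dX2 <- dH1 %*% t(params$W1)
  # reshape b x (p*F) -> (b*p) x F, inverse of the flatten above
  dAp <- matrix(aperm(array(t(dX2), c(p, F_, b)), c(1, 3, 2)), nrow = b * p)
  dA1 <- matrix(0, nrow = b * m, ncol = F_)
  dA1[fw$oi, ] <- dAp * fw$odd_wins
  dA1[fw$ei, ] <- dA1[fw$ei, , drop = FALSE] + dAp * (!fw$odd_wins)
  dZ1 <- dA1 * (fw$Z1 > 0)
  dWc <- as.matrix(Matrix::crossprod(P_rows, dZ1))
  dbc <- colSums(dZ1)
  list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_step <- function(state, params, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# Normalise labels to 0/1 with 1 = positive.
label01 <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  if (is.logical(labels)) return(as.integer(labels))
  as.integer(as.character(labels) == "positive")
}

#' Train the CNN
#'
#' Trains by minibatch backpropagation with cross-entropy loss on the
#' 2-node softmax output and Adam updates, for `hp$epochs` epochs.
#' Inverted dropout is applied after the hidden layer during training
#' only, so predictions are deterministic given the weights. Training is
#' reproducible from the hyperparameter seed.
#'
#' @param model A `phoscnn_model` from [build_cnn()], or a
#'   `cnn_hyperparams` object / preset name.
#' @param dataset A window tibble with `sequence` and `label` columns;
#'   window length must equal `hp$input_length` and both classes must be
#'   present.
#' @param epochs Optional override of `hp$epochs`.
#' @return The trained `phoscnn_model`, with per-epoch `history`
#'   (mean minibatch loss and training accuracy).
#' @export
train_cnn <- function(model, dataset, epochs = NULL) {
  if (!inherits(model, "phoscnn_model")) model <- build_cnn(model)
  hp <- model$hp
  E <- if (is.null(epochs)) hp$epochs else as.integer(epochs)
  seqs <- if (is.data.frame(dataset)) dataset$sequence else dataset
  y <- label01(dataset$label)
  if (length(unique(y)) < 2L) {
    abort("training data must contain both classes")
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L || L != hp$input_length) {
    abort(paste0("window length ", paste(L, collapse = "/"),
                 " does not match model input_length ", hp$input_length))
  }
  ord <- ordinal_matrix(seqs)
  P <- build_patch_matrix(ord, hp$kernel_width)
  n <- nrow(ord)
  m <- model$shape$conv_map_length
  p <- model$shape$pooled_map_length
  params <- model$params
  state <- list(m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  set.seed(hp$seed + 1L)
  hist <- vector("list", E)
  step <- 0L
  for (e in seq_len(E)) {
    idx <- sample.int(n)
    losses <- c(); correct <- 0L
    for (start in seq(1L, n, by = hp$batch_size)) {
      batch <- idx[start:min(start + hp$batch_size - 1L, n)]
      b <- length(batch)
      prows <- rep((batch - 1L) * m, each = m) + rep(seq_len(m), b)
      P_rows <- P[prows, , drop = FALSE]
      mask <- if (hp$dropout_rate > 0) {
        matrix(rbinom(b * hp$hidden_dims, 1L, 1 - hp$dropout_rate),
               nrow = b) / (1 - hp$dropout_rate)
      } else NULL
      fw <- cnn_forward(params, P_rows, b, m, p, mask)
      yb <- y[batch]
      eps <- 1e-12
      loss <- -mean(log(fw$probs[cbind(seq_len(b), yb + 1L)] + eps))
      if (!is.finite(loss)) {
        abort(paste0("non-finite loss at epoch ", e,
                     "; try a smaller learning_rate"))
      }
      losses <- c(losses, loss)
      correct <- correct + sum((fw$probs[, 2] > 0.5) == (yb == 1L))
      grads <- cnn_backward(params, fw, P_rows, yb, b, m, p, mask)
      step <- step + 1L
      upd <- adam_step(state, params, grads, hp$learning_rate, step)
      state <- upd$state; params <- upd$params
    }
    hist[[e]] <- tibble::tibble(epoch = e, loss = mean(losses),
                                accuracy = correct / n)
  }
  model$params <- params
  model$history <- dplyr::bind_rows(model$history, dplyr::bind_rows(hist))
  model$trained <- TRUE
  model
}

#' Predict phosphosite probabilities
#'
#' Positive-class probability for each window from the softmax output;
#' dropout is disabled, so prediction is deterministic and independent of
#' batch composition.
#'
#' @param object A trained `phoscnn_model`.
#' @param newdata Window tibble or character vector; window length must
#'   equal the model's `input_length`.
#' @param type `"prob"` (default) for positive-class probability,
#'   `"class"` for "positive"/"negative" labels at `threshold`.
#' @param threshold Classification threshold (default 0.5).
#' @param ... Unused.
#' @return Numeric probabilities or a character label vector.
#' @export
predict.phoscnn_model <- function(object, newdata,
                                  type = c("prob", "class"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  seqs <- if (is.data.frame(newdata)) newdata$sequence else newdata
  L <- unique(nchar(seqs))
  if (length(L) != 1L || L != object$hp$input_length) {
    abort(paste0("window length ", paste(L, collapse = "/"),
                 " does not match model input_length ",
                 object$hp$input_length))
  }
  ord <- ordinal_matrix(seqs)
  n <- nrow(ord)
  m <- object$shape$conv_map_length
  p <- object$shape$pooled_map_length
  probs <- numeric(n)
  chunk <- 1024L
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    P <- build_patch_matrix(ord[sel, , drop = FALSE], object$hp$kernel_width)
    fw <- cnn_forward(object$params, P, length(sel), m, p, NULL)
    probs[sel] <- fw$probs[, 2]
  }
  if (type == "prob") probs
  else ifelse(probs > threshold, "positive", "negative")
}

#' Convolution-layer activations
#'
#' Rectified activations of every filter at every window position, used
#' for motif extraction from filter activations.
#'
#' @param model Trained `phoscnn_model`.
#' @param windows Window tibble or character vector of model length.
#' @return A list: `act`, an `(n * m) x F` matrix of ReLU activations in
#'   sample-major order, and `m`, the conv map length.
#' @export
cnn_activations <- function(model, windows) {
  seqs <- if (is.data.frame(windows)) windows$sequence else windows
  L <- unique(nchar(seqs))
  if (length(L) != 1L || L != model$hp$input_length) {
    abort("window length does not match model input_length")
  }
  ord <- ordinal_matrix(seqs)
  P <- build_patch_matrix(ord, model$hp$kernel_width)
  F_ <- ncol(model$params$Wc)
  Z1 <- as.matrix(P %*% model$params$Wc) +
    matrix(model$params$bc, nrow = nrow(P), ncol = F_, byrow = TRUE)
  list(act = pmax(Z1, 0), m = model$shape$conv_map_length)
}

#' Transfer a pre-trained model to a small dataset
#'
#' Shared-parameter transfer learning: the new model inherits both the
#' hyperparameters and (by default) the weights of the pre-model, and
#' every layer — including the convolution layer — is then retrained on
#' the small dataset (warm-start fine-tuning, not layer freezing).
#' `init = "random"` shares hyperparameters only and re-initialises the
#' weights, for comparison with scratch training.
#'
#' @param pre_model A trained `phoscnn_model`.
#' @param small_dataset Window tibble whose window length equals the
#'   pre-model's `input_length` (re-extract windows at the pre-model's
#'   flank if needed).
#' @param epochs Optional retraining epochs (default: pre-model's).
#'   `epochs = 0` returns the warm-started model unchanged.
#' @param init `"pretrained"` (warm start, default) or `"random"`.
#' @param seed Optional new seed for retraining.
#' @return A trained `phoscnn_model` with `provenance` recording the
#'   transfer.
#' @export
transfer_cnn <- function(pre_model, small_dataset, epochs = NULL,
                         init = c("pretrained", "random"), seed = NULL) {
  stopifnot(inherits(pre_model, "phoscnn_model"))
  init <- match.arg(init)
  hp <- pre_model$hp
  if (!is.null(seed)) hp$seed <- as.integer(seed)
  new_model <- build_cnn(hp)
  if (init == "pretrained") new_model$params <- pre_model$params
  new_model$provenance <- list(
    transfer_from = "pre_model",
    init = init,
    pre_model_trained = pre_model$trained
  )
  E <- if (is.null(epochs)) hp$epochs else as.integer(epochs)
  if (E == 0L) {
    new_model$trained <- pre_model$trained && init == "pretrained"
    return(new_model)
  }
  train_cnn(new_model, small_dataset, epochs = E)
}

#' @export
print.phoscnn_model <- function(x, ...) {
  cat("<phoscnn_model> ", if (x$trained) "trained" else "untrained", "\n",
      "  L=", x$hp$input_length, " k=", x$hp$kernel_width,
      " filters=", x$hp$filters, " hidden=", x$hp$hidden_dims,
      " epochs=", x$hp$epochs, "\n",
      "  conv map 1x", x$shape$conv_map_length,
      ", pooled 1x", x$shape$pooled_map_length,
      ", flattened ", x$shape$flattened_dim,
      ", parameters ", x$shape$parameter_count, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phoscnn_model <- function(x, ...) {
  x$history
}

#' @exportS3Method generics::glance
glance.phoscnn_model <- function(x, ...) {
  tibble::tibble(
    input_length = x$hp$input_length,
    kernel_width = x$hp$kernel_width,
    filters = x$hp$filters,
    hidden_dims = x$hp$hidden_dims,
    epochs_run = nrow(x$history),
    conv_map_length = x$shape$conv_map_length,
    pooled_map_length = x$shape$pooled_map_length,
    flattened_dim = x$shape$flattened_dim,
    parameter_count = x$shape$parameter_count,
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_,
    final_accuracy = if (nrow(x$history)) x$history$accuracy[nrow(x$history)] else NA_real_
  )
}

#' Save / load a trained model
#'
#' Serializes weights, hyperparameters and the shape report to a single
#' JSON file (text, portable).
#'
#' @param model A `phoscnn_model`.
#' @param path Output path.
#' @return `path` invisibly; `read_cnn()` returns the model.
#' @export
write_cnn <- function(model, path) {
  payload <- list(
    hp = unclass(model$hp),
    shape = model$shape,
    params = lapply(model$params, function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
      else list(dim = NULL, data = as.vector(x))
    }),
    history = as.list(model$history),
    trained = model$trained
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cnn
#' @export
read_cnn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  hp <- do.call(cnn_hyperparams, payload$hp[c("input_length", "kernel_width",
                                              "filters", "hidden_dims",
                                              "epochs", "dropout_rate",
                                              "batch_size", "learning_rate",
                                              "seed")])
  model <- build_cnn(hp)
  model$params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2L) {
      matrix(p$data, nrow = p$dim[[1]], ncol = p$dim[[2]])
    } else {
      as.numeric(p$data)
    }
  })
  model$history <- tibble::as_tibble(payload$history)
  model$trained <- isTRUE(payload$trained)
  model
}
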