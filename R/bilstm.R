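#' @title From-scratch bidirectional LSTM classifier
#' @description Implements the standard LSTM cell (input/forget/output
#'   gates and candidate state), a bidirectional pair of cells whose
#'   final hidden states are concatenated into an output head, full
#'   backpropagation through time, and Adam training. Two head modes are
#'   supported: `"onehot"` (softmax + categorical cross-entropy) and
#'   `"walsh"` (per-bit logistic + summed binary cross-entropy against
#'   Walsh codeword targets).
#' @name bilstm
NULL

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Gate rows in the stacked weight matrix: i, f, o, g blocks of h rows each.
.gate_rows <- function(h) {
  list(i = 1:h, f = (h + 1):(2 * h), o = (2 * h + 1):(3 * h),
       g = (3 * h + 1):(4 * h))
}

.init_matrix <- function(nrow, ncol, fan_in) {
  matrix(stats::runif(nrow * ncol, -1, 1) / sqrt(fan_in), nrow, ncol)
}

#' Create an untrained Bi-LSTM model
#'
#' Weights are drawn uniform in `[-1/sqrt(fan_in), 1/sqrt(fan_in)]` from
#' the current R random stream (seed externally). The stacked gate
#' matrices act on the concatenation `[y_prev, x_t]`.
#'
#' @param input_dim Dimension of each sequence element (1 when the ten
#'   features are presented as a length-10 sequence of scalars).
#' @param hidden Hidden units per direction.
#' @param out_dim Output dimension: number of classes (one-hot mode) or
#'   codeword length (Walsh mode).
#' @param head_mode `"onehot"` or `"walsh"`.
#' @return A `bilstm_model` with forward/backward gate weights `Wg_f`,
#'   `bg_f`, `Wg_b`, `bg_b` and head `W_head`, `b_head`.
#' @export
new_bilstm <- function(input_dim, hidden, out_dim,
                       head_mode = c("onehot", "walsh")) {
  head_mode <- match.arg(head_mode)
  stopifnot(input_dim >= 1L, hidden >= 1L, out_dim >= 1L)
  zin <- hidden + input_dim
  structure(
    list(
      Wg_f = .init_matrix(4L * hidden, zin, zin),
      bg_f = numeric(4L * hidden),
      Wg_b = .init_matrix(4L * hidden, zin, zin),
      bg_b = numeric(4L * hidden),
      W_head = .init_matrix(out_dim, 2L * hidden, 2L * hidden),
      b_head = numeric(out_dim),
      input_dim = as.integer(input_dim),
      hidden = as.integer(hidden),
      out_dim = as.integer(out_dim),
      head_mode = head_mode
    ),
    class = "bilstm_model"
  )
}

#' One LSTM cell step
#'
#' Evaluates the gate equations on a batch: `i,f,o = sigmoid(W [y;x]+b)`
#' blocks, `g = tanh(...)`, `s_t = f*s_prev + i*g`, `y_t = o*tanh(s_t)`.
#'
#' @param Wg Stacked gate weight matrix, `4h x (h + d)` (row blocks
#'   i, f, o, g).
#' @param bg Stacked gate bias, length `4h`.
#' @param x_t Input at this step, `d x B` matrix.
#' @param y_prev,s_prev Previous output and cell state, `h x B`.
#' @return List `y`, `s`, and `cache` of gate activations for BPTT.
#' @export
lstm_step <- function(Wg, bg, x_t, y_prev, s_prev) {
  h <- nrow(y_prev)
  if (nrow(Wg) != 4L * h || length(bg) != 4L * h ||
      ncol(Wg) != h + nrow(x_t) || ncol(x_t) != ncol(y_prev)) {
    stop("inconsistent shapes in lstm_step")
  }
  z <- rbind(y_prev, x_t)
  a <- Wg %*% z + bg
  rows <- .gate_rows(h)
  i <- .sigmoid(a[rows$i, , drop = FALSE])
  f <- .sigmoid(a[rows$f, , drop = FALSE])
  o <- .sigmoid(a[rows$o, , drop = FALSE])
  g <- tanh(a[rows$g, , drop = FALSE])
  s <- f * s_prev + i * g
  tanh_s <- tanh(s)
  y <- o * tanh_s
  list(y = y, s = s,
       cache = list(z = z, i = i, f = f, o = o, g = g,
                    s_prev = s_prev, tanh_s = tanh_s))
}

# Run one direction over a T x B matrix of scalar inputs (or d x T x B
# array slices); X is a list of d x B matrices, one per step.
.cell_forward <- function(Wg, bg, X, hidden) {
  B <- ncol(X[[1L]])
  y <- matrix(0, hidden, B)
  s <- matrix(0, hidden, B)
  caches <- vector("list", length(X))
  for (t in seq_along(X)) {
    st <- lstm_step(Wg, bg, X[[t]], y, s)
    y <- st$y
    s <- st$s
    caches[[t]] <- st$cache
  }
  list(y_final = y, caches = caches)
}

# inputs X: matrix seq_len x B of scalars, or list of d x B matrices
.as_step_list <- function(X, input_dim) {
  if (is.list(X)) return(X)
  X <- as.matrix(X)
  if (input_dim != 1L) stop("matrix input only supported for input_dim = 1")
  lapply(seq_len(nrow(X)), function(t) matrix(X[t, ], 1L))
}

#' Bi-LSTM forward pass
#'
#' Runs the forward cell over the sequence and the backward cell over
#' the reversed sequence, concatenates the two final hidden outputs, and
#' applies the output head: column-wise softmax in one-hot mode,
#' element-wise logistic in Walsh mode.
#'
#' @param model A `bilstm_model`.
#' @param X Sequence batch: a `T x B` numeric matrix of scalar inputs
#'   (each column one sample) or a list of `d x B` matrices.
#' @return List `outputs` (`out_dim x B`), `kf` (concatenated final
#'   states) and the per-direction caches.
#' @export
bilstm_forward <- function(model, X) {
  stopifnot(inherits(model, "bilstm_model"))
  steps <- .as_step_list(X, model$input_dim)
  if (length(steps) < 1L) stop("empty input sequence")
  fwd <- .cell_forward(model$Wg_f, model$bg_f, steps, model$hidden)
  bwd <- .cell_forward(model$Wg_b, model$bg_b, rev(steps), model$hidden)
  kf <- rbind(fwd$y_final, bwd$y_final)
  logits <- model$W_head %*% kf + model$b_head
  outputs <- if (model$head_mode == "onehot") {
    e <- exp(sweep(logits, 2L, apply(logits, 2L, max), "-"))
    sweep(e, 2L, colSums(e), "/")
  } else {
    .sigmoid(logits)
  }
  list(outputs = outputs, kf = kf,
       caches = list(fwd = fwd$caches, bwd = bwd$caches))
}

#' Classification loss with L2 penalty
#'
#' One-hot mode: categorical cross-entropy (natural log). Walsh mode:
#' summed per-bit binary cross-entropy. Both add
#' `lambda/(2*n_train) * sum(W_head^2)`. Outputs are clipped at 1e-12
#' for log stability. The data term is averaged over the batch.
#'
#' @param outputs `out_dim x B` head outputs.
#' @param targets `out_dim x B` one-hot columns or codeword columns.
#' @param model The `bilstm_model` (for the L2 term).
#' @param lambda L2 regularization coefficient.
#' @param n_train Training-set size N in the `lambda/(2N)` term.
#' @return Scalar loss.
#' @export
bilstm_loss <- function(outputs, targets, model, lambda = 0, n_train = 1L) {
  stopifnot(all(dim(outputs) == dim(targets)))
  eps <- 1e-12
  s <- pmin(pmax(outputs, eps), 1 - eps)
  data_loss <- if (model$head_mode == "onehot") {
    -colSums(targets * log(s))
  } else {
    -colSums(targets * log(s) + (1 - targets) * log(1 - s))
  }
  mean(data_loss) + lambda / (2 * n_train) * sum(model$W_head^2)
}

# BPTT through one direction. d_y_final: gradient wrt the final hidden
# output (h x B). Returns gradients for Wg, bg.
.cell_backward <- function(Wg, caches, d_y_final, hidden) {
  Tn <- length(caches)
  B <- ncol(d_y_final)
  rows <- .gate_rows(hidden)
  dW <- matrix(0, nrow(Wg), ncol(Wg))
  db <- numeric(nrow(Wg))
  dy_rec <- matrix(0, hidden, B)
  ds_carry <- matrix(0, hidden, B)
  for (t in Tn:1) {
    cc <- caches[[t]]
    dy <- dy_rec + (if (t == Tn) d_y_final else 0)
    ds <- ds_carry + dy * cc$o * (1 - cc$tanh_s^2)
    da_o <- (dy * cc$tanh_s) * cc$o * (1 - cc$o)
    da_i <- (ds * cc$g) * cc$i * (1 - cc$i)
    da_f <- (ds * cc$s_prev) * cc$f * (1 - cc$f)
    da_g <- (ds * cc$i) * (1 - cc$g^2)
    dA <- matrix(0, 4L * hidden, B)
    dA[rows$i, ] <- da_i
    dA[rows$f, ] <- da_f
    dA[rows$o, ] <- da_o
    dA[rows$g, ] <- da_g
    dW <- dW + dA %*% t(cc$z)
    db <- db + rowSums(dA)
    dz <- crossprod(Wg, dA)
    dy_rec <- dz[1:hidden, , drop = FALSE]
    ds_carry <- ds * cc$f
  }
  list(dW = dW, db = db)
}

#' Gradients of the loss by backpropagation through time
#'
#' Full analytic gradient of [bilstm_loss()] with respect to every
#' weight and bias, for a forward pass cached by [bilstm_forward()].
#' Both head modes reduce to `d logits = outputs - targets`, which is
#' then propagated through the head and both LSTM directions.
#'
#' @param model A `bilstm_model`.
#' @param forward The list returned by [bilstm_forward()] on the same
#'   model and batch.
#' @param targets `out_dim x B` target columns.
#' @inheritParams bilstm_loss
#' @return List of gradients `Wg_f`, `bg_f`, `Wg_b`, `bg_b`, `W_head`,
#'   `b_head`.
#' @export
bilstm_backward <- function(model, forward, targets, lambda = 0,
                            n_train = 1L) {
  stopifnot(inherits(model, "bilstm_model"))
  B <- ncol(targets)
  if (ncol(forward$outputs) != B || nrow(forward$outputs) != nrow(targets)) {
    stop("forward cache does not match targets")
  }
  dlogits <- (forward$outputs - targets) / B
  dW_head <- dlogits %*% t(forward$kf) +
    (lambda / n_train) * model$W_head
  db_head <- rowSums(dlogits)
  dkf <- crossprod(model$W_head, dlogits)
  h <- model$hidden
  gf <- .cell_backward(model$Wg_f, forward$caches$fwd,
                       dkf[1:h, , drop = FALSE], h)
  gb <- .cell_backward(model$Wg_b, forward$caches$bwd,
                       dkf[(h + 1L):(2L * h), , drop = FALSE], h)
  list(Wg_f = gf$dW, bg_f = gf$db, Wg_b = gb$dW, bg_b = gb$db,
       W_head = dW_head, b_head = db_head)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 8, 100 epochs,
#' learning rate 5e-4, 128 hidden units, Adam with moments (0.9, 0.999,
#' 1e-8), L2 coefficient 1e-3, and additive Gaussian feature noise of
#' sd 0.1 applied to the (z-scored) inputs at every presentation.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param hidden Hidden units per direction.
#' @param l2_lambda L2 regularization coefficient.
#' @param feature_noise_sd Sd of the Gaussian noise added to inputs each
#'   presentation; 0 disables it.
#' @param seed Integer seed controlling initialization, shuffling and
#'   noise.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, epochs = 100L,
                         learning_rate = 5e-4, hidden = 128L,
                         l2_lambda = 1e-3, feature_noise_sd = 0.1,
                         seed = 1L) {
  stopifnot(batch_size >= 1L, epochs >= 1L, learning_rate > 0,
            hidden >= 1L, l2_lambda >= 0, feature_noise_sd >= 0)
  structure(
    list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         learning_rate = learning_rate, hidden = as.integer(hidden),
         l2_lambda = l2_lambda, feature_noise_sd = feature_noise_sd,
         seed = as.integer(seed),
         adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8),
    class = "train_config"
  )
}

.targets_for <- function(labels, model, codebook) {
  if (model$head_mode == "onehot") {
    Y <- matrix(0, model$out_dim, length(labels))
    Y[cbind(labels + 1L, seq_along(labels))] <- 1
    Y
  } else {
    t(codebook$codewords[labels + 1L, , drop = FALSE])
  }
}

#' Train a Bi-LSTM on a feature matrix
#'
#' Presents each 10-component feature vector as a length-10 sequence of
#' scalars, shuffles mini-batches each epoch from the seeded stream,
#' optionally adds Gaussian noise to the inputs at every presentation,
#' and updates all weights with Adam. With a codebook the head is
#' per-bit logistic against Walsh codewords; without, softmax one-hot.
#' Weight initialization uses `config$seed`; the epoch loop (shuffling
#' and noise) is reseeded with `config$seed + 1`, so two head modes
#' trained with the same seed see identical data order and noise.
#'
#' @param X Numeric feature matrix, rows = samples, columns = the 10
#'   features (already normalized).
#' @param labels Integer vector of 0-based class indices.
#' @param config A [train_config()].
#' @param codebook Optional [walsh_codebook()]; selects the Walsh head.
#' @return List `model` (trained `bilstm_model` with the codebook
#'   attached in Walsh mode) and `history` (per-epoch `loss` and
#'   `accuracy`).
#' @export
train_bilstm <- function(X, labels, config = train_config(),
                         codebook = NULL) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  n <- nrow(X)
  stopifnot(n == length(labels), n >= 2L)
  n_classes <- length(unique(labels))
  if (n_classes < 2L) stop("need at least two classes to train")
  if (!is.null(codebook) && n_classes > codebook$num_classes) {
    stop("more classes than codewords in the codebook")
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))

  out_dim <- if (is.null(codebook)) max(labels) + 1L else codebook$order
  head_mode <- if (is.null(codebook)) "onehot" else "walsh"
  set.seed(config$seed)
  model <- new_bilstm(1L, config$hidden, out_dim, head_mode)
  Yall <- .targets_for(labels, model, codebook)

  # Adam state per parameter
  pn <- c("Wg_f", "bg_f", "Wg_b", "bg_b", "W_head", "b_head")
  mstate <- lapply(pn, function(p) model[[p]] * 0)
  vstate <- lapply(pn, function(p) model[[p]] * 0)
  names(mstate) <- names(vstate) <- pn
  step <- 0L

  loss_hist <- numeric(config$epochs)
  acc_hist <- numeric(config$epochs)
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0L
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      Xb <- t(X[idx, , drop = FALSE])  # T x B
      if (config$feature_noise_sd > 0) {
        Xb <- Xb + stats::rnorm(length(Xb), 0, config$feature_noise_sd)
      }
      Yb <- Yall[, idx, drop = FALSE]
      fw <- bilstm_forward(model, Xb)
      ep_loss <- ep_loss +
        bilstm_loss(fw$outputs, Yb, model, config$l2_lambda, n)
      pred <- .decode_outputs(fw$outputs, head_mode, codebook)
      ep_correct <- ep_correct + sum(pred == labels[idx])
      nb <- nb + 1L
      gr <- bilstm_backward(model, fw, Yb, config$l2_lambda, n)
      step <- step + 1L
      b1 <- config$adam_beta1; b2 <- config$adam_beta2
      for (p in pn) {
        mstate[[p]] <- b1 * mstate[[p]] + (1 - b1) * gr[[p]]
        vstate[[p]] <- b2 * vstate[[p]] + (1 - b2) * gr[[p]]^2
        mhat <- mstate[[p]] / (1 - b1^step)
        vhat <- vstate[[p]] / (1 - b2^step)
        model[[p]] <- model[[p]] -
          config$learning_rate * mhat / (sqrt(vhat) + config$adam_eps)
      }
    }
    loss_hist[ep] <- ep_loss / nb
    acc_hist[ep] <- ep_correct / n
  }
  model$codebook <- codebook
  list(model = model,
       history = data.frame(epoch = seq_len(config$epochs),
                            loss = loss_hist, accuracy = acc_hist))
}

.decode_outputs <- function(outputs, head_mode, codebook) {
  if (head_mode == "onehot") {
    apply(outputs, 2L, which.max) - 1L  # which.max: first max, lowest index
  } else {
    vapply(seq_len(ncol(outputs)), function(j) {
      walsh_decode(outputs[, j], codebook)$class_index
    }, integer(1L))
  }
}

#' Predict class indices for a feature matrix
#'
#' One-hot mode: argmax of the softmax outputs (ties to the lowest
#' index). Walsh mode: nearest-codeword decoding of the per-bit
#' logistic outputs.
#'
#' @param model A trained `bilstm_model` (with its codebook attached in
#'   Walsh mode).
#' @param X Numeric feature matrix, rows = samples.
#' @return Integer vector of 0-based class indices.
#' @export
predict_bilstm <- function(model, X) {
  stopifnot(inherits(model, "bilstm_model"))
  X <- as.matrix(X)
  fw <- bilstm_forward(model, t(X))
  .decode_outputs(fw$outputs, model$head_mode, model$codebook)
}
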