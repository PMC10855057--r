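#' Configuration of the breath-phase sequence classifier
#'
#' A compact 1-D convolutional + LSTM network that maps a window of the 30 Hz
#' respiratory signal to a per-timestep two-class (exhalation/inhalation)
#' probability sequence at the pooled rate. Defaults mirror the tuned
#' operating point: window of 210 samples (7 s at 30 Hz), one conv stage,
#' filter length 1, pool size 2, batch size 20, plain SGD.
#'
#' @param window_samples Input window length in samples (canonically one of
#'   120, 150, 180, 210, 240, i.e. 4-8 s at 30 Hz).
#' @param conv_layers Number of conv+pool+ReLU stages (1-3).
#' @param conv_filters Convolution channels per stage.
#' @param filter_length Convolution kernel length (1-5).
#' @param pool_size Max-pool factor per stage (2-5). The pooled sequence
#'   length per stage is `floor(T / pool_size)`; a remainder tail is dropped.
#' @param lstm_units LSTM hidden size.
#' @param batch_size SGD minibatch size (default 20).
#' @param epochs Maximum training epochs (default 100).
#' @param learning_rate Plain-SGD learning rate (default 0.01).
#' @param split_ratio Train:test ratio, one of `"20:80"`, `"50:50"`,
#'   `"80:20"`.
#' @param val_fraction Fraction of the train portion held out for validation
#'   (default 0.2).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 10).
#' @param input_rate Sampling rate of the input respiratory signal, Hz
#'   (default 30).
#' @param seed Integer seed controlling initialisation and batch order.
#' @return A validated list of class `model_config`.
#' @export
model_config <- function(window_samples = 210, conv_layers = 1,
                         conv_filters = 8, filter_length = 1, pool_size = 2,
                         lstm_units = 64, batch_size = 20, epochs = 100,
                         learning_rate = 0.01, split_ratio = "50:50",
                         val_fraction = 0.2, patience = 10, input_rate = 30,
                         seed = 1L) {
  check_number(window_samples, "window_samples", min = 4)
  check_number(conv_layers, "conv_layers", min = 1, max = 3)
  check_number(conv_filters, "conv_filters", min = 1)
  check_number(filter_length, "filter_length", min = 1, max = 5)
  check_number(pool_size, "pool_size", min = 2, max = 5)
  check_number(lstm_units, "lstm_units", min = 1)
  check_number(batch_size, "batch_size", min = 1)
  check_number(epochs, "epochs", min = 1)
  check_number(learning_rate, "learning_rate", min = .Machine$double.eps)
  check_number(val_fraction, "val_fraction", min = 0, max = 0.9)
  check_number(patience, "patience", min = 1)
  check_number(input_rate, "input_rate", min = 1)
  if (!split_ratio %in% c("20:80", "50:50", "80:20")) {
    stop_respyre('`split_ratio` must be one of "20:80", "50:50", "80:20".',
                 "respyre_config_error")
  }
  t_out <- window_samples
  for (s in seq_len(conv_layers)) t_out <- t_out %/% pool_size
  if (t_out < 1) {
    stop_respyre("window_samples too small for the pooling cascade.",
                 "respyre_config_error")
  }
  structure(
    list(window_samples = as.integer(window_samples),
         conv_layers = as.integer(conv_layers),
         conv_filters = as.integer(conv_filters),
         filter_length = as.integer(filter_length),
         pool_size = as.integer(pool_size),
         lstm_units = as.integer(lstm_units),
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         learning_rate = learning_rate,
         split_ratio = split_ratio,
         val_fraction = val_fraction,
         patience = as.integer(patience),
         input_rate = input_rate,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Label a respiratory signal as inhalation/exhalation
#'
#' Cuts the (z-scored, zero-mean) respiratory signal at zero: samples above
#' zero are inhalation (1), samples at or below zero are exhalation (0).
#'
#' @param resp A `resp_wave`, data frame, or numeric vector.
#' @return An integer vector of 0/1 labels, one per sample.
#' @export
label_breath_phase <- function(resp) {
  x <- if (is.numeric(resp)) resp else as_wave(resp)$amplitude
  as.integer(x > 0)
}

# max-pool labels down to the network's output resolution
pool_labels <- function(y, config) {
  ymat <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  p <- config$pool_size
  for (s in seq_len(config$conv_layers)) {
    tp <- ncol(ymat) %/% p
    yt <- ymat[, seq_len(tp * p), drop = FALSE]
    dim(yt) <- c(nrow(ymat), p, tp)
    out <- yt[, 1, , drop = TRUE]
    out <- matrix(out, nrow = nrow(ymat))
    for (q in seq_len(p)[-1]) {
      out <- pmax(out, matrix(yt[, q, ], nrow = nrow(ymat)))
    }
    ymat <- out
  }
  if (is.matrix(y)) ymat else as.integer(ymat[1, ])
}

#' Split labelled windows into train, validation and test sets
#'
#' The test split is taken at `split_ratio` — by default at subject level, so
#' no subject contributes windows to both sides. Within the train portion,
#' `1 - val_fraction` of the windows train and the remainder validate
#' (floor arithmetic). Deterministic under `seed`.
#'
#' @param windows A tibble of windows; a `subject` column is required for the
#'   subject-level split.
#' @param split_ratio Train:test ratio, one of `"20:80"`, `"50:50"`,
#'   `"80:20"`.
#' @param val_fraction Validation fraction within the train portion.
#' @param seed Integer seed.
#' @param by_subject Split test subjects disjointly (default `TRUE`); with
#'   `FALSE` the split is at window level and hits the ratio exactly.
#' @return The input tibble with a `split` factor column
#'   (`train`/`validation`/`test`).
#' @export
split_dataset <- function(windows, split_ratio = "50:50", val_fraction = 0.2,
                          seed = 1L, by_subject = TRUE) {
  if (!split_ratio %in% c("20:80", "50:50", "80:20")) {
    stop_respyre('`split_ratio` must be one of "20:80", "50:50", "80:20".',
                 "respyre_config_error")
  }
  n <- nrow(windows)
  if (n < 10) {
    stop_respyre("At least 10 windows are required to split.", "respyre_data_error")
  }
  parts <- as.numeric(strsplit(split_ratio, ":")[[1]])
  test_frac <- parts[2] / sum(parts)
  n_test <- round(n * test_frac)
  split <- rep("train", n)
  with_seed_(derive_seed(seed, 17L), {
    if (by_subject) {
      if (!"subject" %in% names(windows)) {
        stop_respyre("Subject-level split needs a `subject` column.",
                     "respyre_data_error")
      }
      subjects <- sample(unique(windows$subject))
      counts <- vapply(subjects, function(s) sum(windows$subject == s), numeric(1))
      cum <- cumsum(counts)
      m <- which.min(abs(cum - n_test))
      test_idx <- which(windows$subject %in% subjects[seq_len(m)])
    } else {
      test_idx <- sample(n, n_test)
    }
    split[test_idx] <- "test"
    train_pool <- which(split == "train")
    n_tr <- floor(length(train_pool) * (1 - val_fraction))
    perm <- sample(train_pool)
    split[perm[seq_len(length(perm) - n_tr) + n_tr]] <- "train"
    if (length(perm) > n_tr) split[perm[(n_tr + 1):length(perm)]] <- "validation"
  })
  dplyr::mutate(windows,
                split = factor(split, levels = c("train", "validation", "test")))
}

# ---- network internals ------------------------------------------------------

glorot <- function(n_in, n_out, nrow_, ncol_) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(runif(nrow_ * ncol_, -r, r), nrow_, ncol_)
}

#' Build an (untrained) breath-phase network
#'
#' Architecture per stage: 1-D convolution (same padding), max pooling,
#' ReLU; then an LSTM (tanh cell) over the pooled sequence, a
#' time-distributed dense layer and a softmax over the two classes
#' (exhalation, inhalation). Initialisation is deterministic under the
#' config seed.
#'
#' @param config A [model_config()].
#' @return A list of class `breath_net` with elements `config`, `params`,
#'   `pooled_len` (output sequence length) and `label_rate` (Hz of the
#'   output labels).
#' @export
build_model <- function(config) {
  if (!inherits(config, "model_config")) {
    stop_respyre("`config` must be created with model_config().", "respyre_config_error")
  }
  L <- config$filter_length; F_ <- config$conv_filters; H <- config$lstm_units
  params <- with_seed_(config$seed, {
    conv <- list()
    c_in <- 1L
    for (s in seq_len(config$conv_layers)) {
      W <- array(runif(L * c_in * F_, -1, 1) * sqrt(6 / (L * c_in + F_)),
                 dim = c(L, c_in, F_))
      conv[[s]] <- list(W = W, b = numeric(F_))
      c_in <- F_
    }
    lstm <- list(
      Wx = glorot(F_, 4 * H, F_, 4 * H),
      Wh = glorot(H, 4 * H, H, 4 * H),
      b = c(numeric(H), rep(1, H), numeric(2 * H))  # forget bias 1
    )
    out <- list(W = glorot(H, 2, H, 2), b = numeric(2))
    list(conv = conv, lstm = lstm, out = out)
  })
  t_out <- config$window_samples
  for (s in seq_len(config$conv_layers)) t_out <- t_out %/% config$pool_size
  structure(
    list(config = config, params = params, pooled_len = as.integer(t_out),
         label_rate = config$input_rate / config$pool_size^config$conv_layers),
    class = "breath_net"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass. X: B x T matrix. y (optional): B x pooled_len 0/1 matrix.
# Returns probs (B x T_out x 2), loss, and caches for backprop.
net_forward <- function(model, X, y = NULL, keep_cache = FALSE) {
  cfg <- model$config; pr <- model$params
  B <- nrow(X)
  A <- array(X, dim = c(B, ncol(X), 1L))
  stage_cache <- list()
  for (s in seq_len(cfg$conv_layers)) {
    W <- pr$conv[[s]]$W; b <- pr$conv[[s]]$b
    L <- dim(W)[1]; C <- dim(W)[2]; F_ <- dim(W)[3]
    Tt <- dim(A)[2]
    pad <- (L - 1L) %/% 2L
    Amat <- matrix(A, B * Tt, C)
    Z <- matrix(0, B * Tt, F_)
    for (l in seq_len(L)) {
      off <- l - 1L - pad
      # source timestep t + off
      src <- seq_len(Tt) + off
      ok <- src >= 1L & src <= Tt
      if (!any(ok)) next
      rows_dst <- as.vector(outer(seq_len(B), (which(ok) - 1L) * B, `+`))
      rows_src <- as.vector(outer(seq_len(B), (src[ok] - 1L) * B, `+`))
      Z[rows_dst, ] <- Z[rows_dst, ] +
        matrix(Amat[rows_src, , drop = FALSE], ncol = C) %*%
        matrix(W[l, , ], C, F_)
    }
    Z <- sweep(Z, 2, b, `+`)
    dim(Z) <- c(B, Tt, F_)
    # max pool over non-overlapping blocks of pool_size
    p <- cfg$pool_size
    Tp <- Tt %/% p
    Zt <- Z[, seq_len(Tp * p), , drop = FALSE]
    dim(Zt) <- c(B, p, Tp, F_)
    mx <- Zt[, 1, , , drop = FALSE]; dim(mx) <- c(B, Tp, F_)
    arg <- array(1L, dim = c(B, Tp, F_))
    for (q in seq_len(p)[-1]) {
      cand <- Zt[, q, , , drop = FALSE]; dim(cand) <- c(B, Tp, F_)
      better <- cand > mx
      mx[better] <- cand[better]
      arg[better] <- q
    }
    relu_mask <- mx > 0
    Aout <- mx * relu_mask
    if (keep_cache) {
      stage_cache[[s]] <- list(Amat = Amat, Tt = Tt, arg = arg,
                               relu_mask = relu_mask, Tp = Tp)
    }
    A <- Aout
  }

  # LSTM over pooled timesteps
  H <- cfg$lstm_units; F_ <- dim(A)[3]; T_out <- dim(A)[2]
  Wx <- pr$lstm$Wx; Wh <- pr$lstm$Wh; bl <- pr$lstm$b
  Wo <- pr$out$W; bo <- pr$out$b
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  probs <- array(0, dim = c(B, T_out, 2))
  lstm_cache <- if (keep_cache) vector("list", T_out) else NULL
  loss <- 0
  for (t in seq_len(T_out)) {
    Xt <- matrix(A[, t, ], B, F_)
    z <- Xt %*% Wx + h %*% Wh
    z <- sweep(z, 2, bl, `+`)
    i_g <- sigmoid(z[, seq_len(H), drop = FALSE])
    f_g <- sigmoid(z[, H + seq_len(H), drop = FALSE])
    g_g <- tanh(z[, 2 * H + seq_len(H), drop = FALSE])
    o_g <- sigmoid(z[, 3 * H + seq_len(H), drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h_prev <- h
    h <- o_g * tc
    logits <- sweep(h %*% Wo, 2, bo, `+`)
    m <- pmax(logits[, 1], logits[, 2])
    ez <- exp(logits - m)
    denom <- ez[, 1] + ez[, 2]
    pt <- ez / denom
    probs[, t, ] <- pt
    if (!is.null(y)) {
      yt <- y[, t]
      pcorr <- ifelse(yt == 1L, pt[, 2], pt[, 1])
      loss <- loss - sum(log(pmax(pcorr, 1e-12)))
    }
    if (keep_cache) {
      lstm_cache[[t]] <- list(Xt = Xt, i = i_g, f = f_g, g = g_g, o = o_g,
                              c = cc, c_prev = c_prev, tc = tc,
                              h_prev = h_prev, h = h)
    }
  }
  if (!is.null(y)) loss <- loss / (B * T_out)
  list(probs = probs, loss = if (is.null(y)) NA_real_ else loss,
       stage_cache = stage_cache, lstm_cache = lstm_cache,
       T_out = T_out, B = B, F_in = F_)
}

# backward pass; returns gradients with the same structure as params
net_backward <- function(model, fw, y) {
  cfg <- model$config; pr <- model$params
  B <- fw$B; T_out <- fw$T_out; H <- cfg$lstm_units; F_ <- fw$F_in
  Wx <- pr$lstm$Wx; Wh <- pr$lstm$Wh
  Wo <- pr$out$W
  scale <- 1 / (B * T_out)

  dWo <- matrix(0, H, 2); dbo <- numeric(2)
  dWx <- matrix(0, F_, 4 * H); dWh <- matrix(0, H, 4 * H); dbl <- numeric(4 * H)
  dA <- array(0, dim = c(B, T_out, F_))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)

  for (t in rev(seq_len(T_out))) {
    cache <- fw$lstm_cache[[t]]
    pt <- matrix(fw$probs[, t, ], B, 2)
    yt <- y[, t]
    dlogits <- pt
    dlogits[cbind(seq_len(B), yt + 1L)] <- dlogits[cbind(seq_len(B), yt + 1L)] - 1
    dlogits <- dlogits * scale
    dWo <- dWo + t(cache$h) %*% dlogits
    dbo <- dbo + colSums(dlogits)
    dh <- dlogits %*% t(Wo) + dh_next

    do_ <- dh * cache$tc
    dtc <- dh * cache$o
    dc <- dtc * (1 - cache$tc^2) + dc_next
    di <- dc * cache$g
    dg <- dc * cache$i
    df <- dc * cache$c_prev
    dc_next <- dc * cache$f
    dz <- cbind(di * cache$i * (1 - cache$i),
                df * cache$f * (1 - cache$f),
                dg * (1 - cache$g^2),
                do_ * cache$o * (1 - cache$o))
    dWx <- dWx + t(cache$Xt) %*% dz
    dWh <- dWh + t(cache$h_prev) %*% dz
    dbl <- dbl + colSums(dz)
    dh_next <- dz %*% t(Wh)
    dA[, t, ] <- dA[, t, ] + dz %*% t(Wx)
  }

  # conv stages in reverse
  dconv <- vector("list", cfg$conv_layers)
  dcur <- dA
  for (s in rev(seq_len(cfg$conv_layers))) {
    cache <- fw$stage_cache[[s]]
    W <- pr$conv[[s]]$W
    L <- dim(W)[1]; C <- dim(W)[2]; Fs <- dim(W)[3]
    p <- cfg$pool_size; Tp <- cache$Tp; Tt <- cache$Tt
    dpool <- dcur * cache$relu_mask
    # un-pool to full resolution at the argmax positions
    dZ <- array(0, dim = c(B, Tt, Fs))
    bi <- slice.index(dpool, 1)
    ti <- slice.index(dpool, 2)
    fi <- slice.index(dpool, 3)
    full_t <- (as.vector(ti) - 1L) * p + as.vector(cache$arg)
    idx <- cbind(as.vector(bi), full_t, as.vector(fi))
    dZ[idx] <- as.vector(dpool)
    dZmat <- matrix(dZ, B * Tt, Fs)
    pad <- (L - 1L) %/% 2L
    Amat <- cache$Amat
    dW <- array(0, dim = dim(W)); db <- colSums(dZmat)
    dAprev_mat <- matrix(0, B * Tt, C)
    for (l in seq_len(L)) {
      off <- l - 1L - pad
      src <- seq_len(Tt) + off
      ok <- src >= 1L & src <= Tt
      if (!any(ok)) next
      rows_dst <- as.vector(outer(seq_len(B), (which(ok) - 1L) * B, `+`))
      rows_src <- as.vector(outer(seq_len(B), (src[ok] - 1L) * B, `+`))
      Asub <- matrix(Amat[rows_src, , drop = FALSE], ncol = C)
      Dsub <- matrix(dZmat[rows_dst, , drop = FALSE], ncol = Fs)
      dW[l, , ] <- dW[l, , ] + t(Asub) %*% Dsub
      dAprev_mat[rows_src, ] <- dAprev_mat[rows_src, ] +
        Dsub %*% t(matrix(W[l, , ], C, Fs))
    }
    dconv[[s]] <- list(W = dW, b = db)
    dcur <- array(dAprev_mat, dim = c(B, Tt, C))
  }

  list(conv = dconv,
       lstm = list(Wx = dWx, Wh = dWh, b = dbl),
       out = list(W = dWo, b = dbo))
}

sgd_update <- function(params, grads, lr) {
  for (s in seq_along(params$conv)) {
    params$conv[[s]]$W <- params$conv[[s]]$W - lr * grads$conv[[s]]$W
    params$conv[[s]]$b <- params$conv[[s]]$b - lr * grads$conv[[s]]$b
  }
  params$lstm$Wx <- params$lstm$Wx - lr * grads$lstm$Wx
  params$lstm$Wh <- params$lstm$Wh - lr * grads$lstm$Wh
  params$lstm$b <- params$lstm$b - lr * grads$lstm$b
  params$out$W <- params$out$W - lr * grads$out$W
  params$out$b <- params$out$b - lr * grads$out$b
  params
}

# flatten/unflatten parameters (used by the finite-difference check)
flatten_params <- function(params) {
  unlist(list(
    conv = lapply(params$conv, function(p) c(as.vector(p$W), p$b)),
    lstm = c(as.vector(params$lstm$Wx), as.vector(params$lstm$Wh), params$lstm$b),
    out = c(as.vector(params$out$W), params$out$b)
  ), use.names = FALSE)
}

unflatten_params <- function(theta, template) {
  pos <- 0L
  take <- function(k) {
    v <- theta[pos + seq_len(k)]
    pos <<- pos + k
    v
  }
  out <- template
  for (s in seq_along(template$conv)) {
    W <- template$conv[[s]]$W
    out$conv[[s]]$W <- array(take(length(W)), dim = dim(W))
    out$conv[[s]]$b <- take(length(template$conv[[s]]$b))
  }
  out$lstm$Wx <- matrix(take(length(template$lstm$Wx)), nrow = nrow(template$lstm$Wx))
  out$lstm$Wh <- matrix(take(length(template$lstm$Wh)), nrow = nrow(template$lstm$Wh))
  out$lstm$b <- take(length(template$lstm$b))
  out$out$W <- matrix(take(length(template$out$W)), nrow = nrow(template$out$W))
  out$out$b <- take(length(template$out$b))
  out
}

as_xy <- function(data, model) {
  if (is.list(data) && !is.data.frame(data) && all(c("x", "y") %in% names(data))) {
    return(list(x = data$x, y = data$y))
  }
  if (is.data.frame(data) && all(c("samples", "labels") %in% names(data))) {
    x <- do.call(rbind, data$samples)
    y <- do.call(rbind, purrr::map(data$labels, ~ pool_labels(.x, model$config)))
    return(list(x = x, y = y))
  }
  stop_respyre("Training data must be list(x, y) or a tibble with samples/labels.",
               "respyre_data_error")
}

batched_loss <- function(model, x, y, chunk = 256L) {
  n <- nrow(x)
  tot <- 0
  for (s0 in seq(1L, n, by = chunk)) {
    idx <- s0:min(n, s0 + chunk - 1L)
    fw <- net_forward(model, x[idx, , drop = FALSE], y[idx, , drop = FALSE])
    tot <- tot + fw$loss * length(idx)
  }
  tot / n
}

#' Train the breath-phase network
#'
#' Minimises per-timestep cross-entropy with plain SGD. Reference labels are
#' max-pooled to the network's output resolution (a pooled step counts as
#' inhalation if any of its source samples does). Validation loss is recorded
#' per epoch; the parameter state at the epoch with the minimum validation
#' loss is kept, and training stops early after `patience` epochs without
#' improvement. Deterministic under the config seed.
#'
#' @param model An untrained [build_model()] network.
#' @param train,validation Either `list(x = , y = )` with `x` a
#'   windows-by-samples matrix and `y` the matching pooled 0/1 label matrix,
#'   or a tibble with `samples` and `labels` list-columns (labels at input
#'   resolution; pooled internally).
#' @param epochs,patience,learning_rate,batch_size Optional overrides of the
#'   config values.
#' @return A list of class `breath_net_fit`: the best `model`, `history`
#'   (tibble of epoch, train and validation loss), `best_epoch`,
#'   `best_val_loss`, `epochs_run`.
#' @export
train_model <- function(model, train, validation,
                        epochs = NULL, patience = NULL,
                        learning_rate = NULL, batch_size = NULL) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  patience <- patience %||% cfg$patience
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size
  tr <- as_xy(train, model)
  va <- as_xy(validation, model)
  if (!nrow(tr$x) || !nrow(va$x)) {
    stop_respyre("Train and validation partitions must be non-empty.",
                 "respyre_data_error")
  }

  n <- nrow(tr$x)
  history <- tibble(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best <- list(params = model$params, val = Inf, epoch = 0L)
  stall <- 0L
  with_seed_(derive_seed(cfg$seed, 23L), {
    for (ep in seq_len(epochs)) {
      idx <- sample(n)
      ep_loss <- 0
      for (s0 in seq(1L, n, by = bs)) {
        bi <- idx[s0:min(n, s0 + bs - 1L)]
        fw <- net_forward(model, tr$x[bi, , drop = FALSE],
                          tr$y[bi, , drop = FALSE], keep_cache = TRUE)
        if (!is.finite(fw$loss)) {
          stop_respyre(sprintf("Training diverged (non-finite loss) at epoch %d.", ep),
                       "respyre_training_error")
        }
        gr <- net_backward(model, fw, tr$y[bi, , drop = FALSE])
        model$params <- sgd_update(model$params, gr, lr)
        ep_loss <- ep_loss + fw$loss * length(bi)
      }
      val_loss <- batched_loss(model, va$x, va$y)
      history <- dplyr::bind_rows(history, tibble(
        epoch = ep, train_loss = ep_loss / n, val_loss = val_loss))
      if (val_loss < best$val - 1e-9) {
        best <- list(params = model$params, val = val_loss, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  })
  model$params <- best$params
  structure(
    list(model = model, config = cfg, history = history,
         best_epoch = best$epoch, best_val_loss = best$val,
         epochs_run = nrow(history)),
    class = "breath_net_fit"
  )
}

#' Predict inhalation/exhalation labels for signal windows
#'
#' Runs the trained network and takes the per-timestep argmax over the two
#' classes; ties label as exhalation (0). Labels are at the pooled rate
#' (`input_rate / pool_size^conv_layers` Hz).
#'
#' @param fit A `breath_net_fit` (or an untrained `breath_net`).
#' @param windows A numeric vector of `window_samples` values, or a matrix
#'   with one window per row.
#' @return An integer 0/1 matrix (or vector for vector input) of pooled
#'   labels, with attribute `"rate"`.
#' @export
predict_labels <- function(fit, windows) {
  model <- if (inherits(fit, "breath_net_fit")) fit$model else fit
  single <- is.null(dim(windows))
  X <- if (single) matrix(windows, nrow = 1) else as.matrix(windows)
  if (ncol(X) != model$config$window_samples) {
    stop_respyre(sprintf("Windows must have %d samples, got %d.",
                         model$config$window_samples, ncol(X)),
                 "respyre_data_error")
  }
  fw <- net_forward(model, X)
  lab <- (fw$probs[, , 2, drop = FALSE] > fw$probs[, , 1, drop = FALSE]) * 1L
  lab <- matrix(as.integer(lab), nrow(X), fw$T_out)
  out <- if (single) lab[1, ] else lab
  attr(out, "rate") <- model$label_rate
  out
}

#' Respiratory rate from a breath-phase label sequence
#'
#' Breaths are inhalation onsets: 0-to-1 transitions in the label sequence
#' (a leading 1 counts as an onset). RR is 60 times the onset count over the
#' covered duration.
#'
#' @param labels Integer 0/1 vector.
#' @param duration_s Duration covered by the labels, seconds (> 0).
#' @return A one-row tibble: `method`, `breaths`, `rr`, `valid` (RR within
#'   4-60 breaths/min).
#' @export
#' @examples
#' rr_from_labels(rep(c(1, 1, 0, 0), 15), duration_s = 60)  # 15 breaths/min
rr_from_labels <- function(labels, duration_s) {
  check_number(duration_s, "duration_s", min = .Machine$double.eps)
  if (!length(labels)) {
    stop_respyre("`labels` must be non-empty.", "respyre_data_error")
  }
  breaths <- sum(diff(c(0L, as.integer(labels))) == 1L)
  rr <- 60 * breaths / duration_s
  tibble(method = "cnn_lstm", breaths = breaths, rr = rr,
         valid = rr >= 4 && rr <= 60)
}

#' @export
print.breath_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<breath_net> window %d -> %d pooled steps | %d conv stage(s) x %d filters (len %d), pool %d, LSTM %d\n",
    cfg$window_samples, x$pooled_len, cfg$conv_layers, cfg$conv_filters,
    cfg$filter_length, cfg$pool_size, cfg$lstm_units))
  invisible(x)
}

#' @export
print.breath_net_fit <- function(x, ...) {
  cat(sprintf("<breath_net_fit> %d epoch(s); best val loss %.4f at epoch %d\n",
              x$epochs_run, x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @rdname train_model
#' @param x A `breath_net_fit`.
#' @param ... Unused.
#' @export
tidy.breath_net_fit <- function(x, ...) x$history

#' @rdname train_model
#' @export
glance.breath_net_fit <- function(x, ...) {
  tibble(epochs_run = x$epochs_run, best_epoch = x$best_epoch,
         best_val_loss = x$best_val_loss,
         n_parameters = length(flatten_params(x$model$params)))
}

#' @rdname train_model
#' @param object A `breath_net_fit`.
#' @export
autoplot.breath_net_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "loss")
  ggplot(d, aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    geom_line() +
    labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    theme_minimal()
}
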