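#' Victim model architecture specification
#'
#' Describes one of the eight victim models: a per-slice convolutional
#' feature extractor shared across the T time slices (the stack depends only
#' on whether the model consumes BEAMs or raw EEG), followed by one of four
#' aggregation heads over the per-slice feature vectors.
#'
#' The BEAM-related stack is four 3x3x32 convolutions (ReLU, same padding)
#' and one 2x2 max pool on 4-channel 22x22 slices; the EEG-related stack
#' continues with two 3x3x64 convolutions + pool and one 3x3x128 convolution
#' + pool on 1-channel 22x256 slices. Heads: `maxpool` (element-wise max over
#' slices), `temporal_conv` (width-3 1-D convolution across slices), `lstm`
#' (recurrent layer over slice features), `mixed_lstm` (concatenated lstm and
#' temporal-convolution paths); each ends in a fully connected layer and a
#' 2-class softmax.
#'
#' @param name Head name: `"maxpool"`, `"temporal_conv"`, `"lstm"` or
#'   `"mixed_lstm"`.
#' @param input_kind `"beam"` or `"eeg"`.
#' @param t_slices Number of time slices per sample.
#' @param input_shape `c(H, W, channels)` of one slice; defaults to
#'   22 x 22 x 4 for beam input and 22 x 256 x 1 for eeg input.
#' @param fc_width Fully connected layer width.
#' @param lstm_hidden LSTM hidden size.
#' @param tconv_filters Filters of the temporal-convolution head.
#' @return Object of class `victim_spec`.
#' @export
architecture_spec <- function(name = c("maxpool", "temporal_conv", "lstm",
                                       "mixed_lstm"),
                              input_kind = c("beam", "eeg"),
                              t_slices = 5L,
                              input_shape = NULL,
                              fc_width = 512L, lstm_hidden = 128L,
                              tconv_filters = 32L) {
  name <- match.arg(name)
  input_kind <- match.arg(input_kind)
  if (is.null(input_shape)) {
    input_shape <- if (input_kind == "beam") c(22L, 22L, 4L) else c(22L, 256L, 1L)
  }
  structure(
    list(name = name, input_kind = input_kind, t_slices = as.integer(t_slices),
         input_shape = as.integer(input_shape), fc_width = as.integer(fc_width),
         lstm_hidden = as.integer(lstm_hidden),
         tconv_filters = as.integer(tconv_filters)),
    class = "victim_spec"
  )
}

# conv stack layout: list of ops + resulting feature dimension
stack_layout <- function(spec) {
  ch_in <- spec$input_shape[3]
  if (spec$input_kind == "beam") {
    chans <- c(ch_in, 32L, 32L, 32L, 32L)
    ops <- c(lapply(1:4, function(i) list(type = "conv", i = i)),
             list(list(type = "pool")))
    H <- spec$input_shape[1] %/% 2L; W <- spec$input_shape[2] %/% 2L
    D <- H * W * 32L
  } else {
    chans <- c(ch_in, 32L, 32L, 32L, 32L, 64L, 64L, 128L)
    ops <- c(lapply(1:4, function(i) list(type = "conv", i = i)),
             list(list(type = "pool")),
             lapply(5:6, function(i) list(type = "conv", i = i)),
             list(list(type = "pool")),
             list(list(type = "conv", i = 7L)),
             list(list(type = "pool")))
    H <- spec$input_shape[1]; W <- spec$input_shape[2]
    H <- H %/% 2L; W <- W %/% 2L          # after first pool
    H <- H %/% 2L; W <- W %/% 2L          # after second pool
    H <- H %/% 2L; W <- W %/% 2L          # after third pool
    D <- H * W * 128L
  }
  list(ops = ops, chans = chans, D = as.integer(D))
}

head_input_dim <- function(spec, D) {
  switch(spec$name,
    maxpool = D,
    temporal_conv = spec$tconv_filters * spec$t_slices,
    lstm = spec$lstm_hidden,
    mixed_lstm = spec$lstm_hidden + spec$tconv_filters * spec$t_slices
  )
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Build an untrained victim model
#'
#' Instantiates the parameter tensors for an architecture with seeded He
#' initialization; the final classification layer starts down-scaled so the
#' initial logits are near zero (large first cross-entropy steps through the
#' wide feature heads otherwise destabilize early training).
#'
#' @param spec A `victim_spec` from [architecture_spec()].
#' @param seed Initialization seed.
#' @param classes Length-2 character vector naming the output classes.
#' @return Object of class `victim_model`.
#' @export
build_victim <- function(spec, seed = 1L, classes = c("background", "seizure")) {
  stopifnot(inherits(spec, "victim_spec"), length(classes) == 2L)
  lay <- stack_layout(spec)
  params <- with_local_seed(seed, {
    p <- list()
    for (op in lay$ops) {
      if (op$type != "conv") next
      i <- op$i
      p[[paste0("cw", i)]] <- he_mat(9L * lay$chans[i], lay$chans[i + 1L])
      p[[paste0("cb", i)]] <- numeric(lay$chans[i + 1L])
    }
    D <- lay$D
    if (spec$name %in% c("temporal_conv", "mixed_lstm")) {
      p$tw <- he_mat(3L * D, spec$tconv_filters)
      p$tb <- numeric(spec$tconv_filters)
    }
    if (spec$name %in% c("lstm", "mixed_lstm")) {
      Hd <- spec$lstm_hidden
      p$lwx <- he_mat(D, 4L * Hd) * 0.5
      p$lwh <- he_mat(Hd, 4L * Hd) * 0.5
      p$lb <- numeric(4L * Hd)
      p$lb[Hd + seq_len(Hd)] <- 1      # forget-gate bias
    }
    hin <- head_input_dim(spec, D)
    p$fw1 <- he_mat(hin, spec$fc_width)
    p$fb1 <- numeric(spec$fc_width)
    # down-scaled final layer: near-uniform initial probabilities (tames the
    # first cross-entropy steps through the wide feature head) while keeping
    # nonzero gradients flowing to every layer from step one
    p$fw2 <- he_mat(spec$fc_width, 2L) * 0.05
    p$fb2 <- numeric(2L)
    p
  })
  structure(
    list(spec = spec, params = params, classes = classes, trained = FALSE,
         metrics = NULL, layout = lay),
    class = "victim_model"
  )
}

#' @export
print.victim_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat("<victim_model> ", x$spec$input_kind, "-input, ", x$spec$name,
      " head, ", format(np, big.mark = ","), " parameters",
      if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  invisible(x)
}

# ---- batch plumbing ---------------------------------------------------------

# turn a sample / batch into the (H, W, chan, T*N) slice stack
to_slice_stack <- function(model, x) {
  spec <- model$spec
  sh <- spec$input_shape; Tn <- spec$t_slices
  d <- dim(x)
  if (spec$input_kind == "beam") {
    if (length(d) == 4L) { x <- array(x, c(1L, d)); d <- dim(x) }
    if (length(d) != 5L || !all(d[2:5] == c(Tn, sh[3], sh[1], sh[2]))) {
      stop("shape mismatch: expected samples of shape ", Tn, " x ", sh[3],
           " x ", sh[1], " x ", sh[2])
    }
    N <- d[1]
    # (N,T,B,H,W) -> (H,W,B,T,N)
    xs <- aperm(x, c(4, 5, 3, 2, 1))
    dim(xs) <- c(sh[1], sh[2], sh[3], Tn * N)
  } else {
    if (length(d) == 3L) { x <- array(x, c(1L, d)); d <- dim(x) }
    if (length(d) != 4L || !all(d[2:4] == c(Tn, sh[1], sh[2]))) {
      stop("shape mismatch: expected samples of shape ", Tn, " x ", sh[1],
           " x ", sh[2])
    }
    N <- d[1]
    # (N,T,C,S) -> (C,S,T,N), 1-channel images
    xs <- aperm(x, c(3, 4, 2, 1))
    dim(xs) <- c(sh[1], sh[2], 1L, Tn * N)
  }
  list(xs = xs, N = N)
}

conv_stack_fwd <- function(params, X, ops) {
  caches <- vector("list", length(ops))
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    if (op$type == "conv") {
      Xin <- X
      A <- conv3x3_fwd(X, params[[paste0("cw", op$i)]],
                       params[[paste0("cb", op$i)]], relu = TRUE)
      caches[[k]] <- list(type = "conv", i = op$i, Xin = Xin, A = A)
      X <- A
    } else {
      r <- maxpool2_fwd(X)
      caches[[k]] <- list(type = "pool", idx = r$idx, xdim = dim(X))
      X <- r$y
    }
  }
  list(out = X, caches = caches)
}

# 180-degree rotation + transpose of a (9*Cin x Cout) conv weight, giving the
# (9*Cout x Cin) kernel whose forward convolution computes the input gradient
rotate_conv_weight <- function(w, cin, cout) {
  w4 <- array(w, c(9L, cin, cout))
  w4 <- w4[9:1, , , drop = FALSE]        # offset (di,dj) -> (-di,-dj)
  matrix(aperm(w4, c(1, 3, 2)), 9L * cout, cin)
}

conv_stack_bwd <- function(params, caches, dOut, need_dinput) {
  grads <- list()
  dX <- dOut
  for (k in rev(seq_along(caches))) {
    cs <- caches[[k]]
    if (cs$type == "pool") {
      dX <- maxpool2_bwd(dX, cs$idx, cs$xdim)
    } else {
      first <- k == 1L
      w <- params[[paste0("cw", cs$i)]]
      dY <- relu_mask(dX, cs$A)
      r <- conv3x3_grad(cs$Xin, w, dY)
      grads[[paste0("cw", cs$i)]] <- r$dw
      grads[[paste0("cb", cs$i)]] <- r$db
      if (!first || need_dinput) {
        cin <- nrow(w) %/% 9L
        wr <- rotate_conv_weight(w, cin, ncol(w))
        dX <- conv3x3_fwd(dY, wr, numeric(cin), relu = FALSE)
      } else {
        dX <- NULL
      }
    }
  }
  list(grads = grads, dX = dX)
}

forward_victim <- function(model, x, train = FALSE, dropout_p = 0) {
  spec <- model$spec
  bs <- to_slice_stack(model, x)
  st <- conv_stack_fwd(model$params, bs$xs, model$layout$ops)
  D <- model$layout$D
  Tn <- spec$t_slices; N <- bs$N
  F3 <- array(matrix(st$out, D, Tn * N), c(D, Tn, N))
  p <- model$params
  head_cache <- list()
  feat <- switch(spec$name,
    maxpool = {
      m <- matrix(F3[, 1, ], D, N); arg <- matrix(1L, D, N)
      for (t in seq_len(Tn)[-1]) {
        xt <- matrix(F3[, t, ], D, N)
        sel <- xt > m
        m[sel] <- xt[sel]; arg[sel] <- t
      }
      head_cache$arg <- arg
      m
    },
    temporal_conv = {
      tc <- tconv_fwd(p$tw, p$tb, F3)
      head_cache$tc <- tc
      matrix(tc$Y, spec$tconv_filters * Tn, N)
    },
    lstm = {
      ls <- lstm_fwd(p$lwx, p$lwh, p$lb, F3)
      head_cache$ls <- ls
      ls$h
    },
    mixed_lstm = {
      ls <- lstm_fwd(p$lwx, p$lwh, p$lb, F3)
      tc <- tconv_fwd(p$tw, p$tb, F3)
      head_cache$ls <- ls; head_cache$tc <- tc
      rbind(ls$h, matrix(tc$Y, spec$tconv_filters * Tn, N))
    }
  )
  H1 <- relu_fwd(dense_fwd(p$fw1, p$fb1, feat))
  if (train && dropout_p > 0) {
    mask <- (matrix(stats::runif(length(H1)), nrow(H1)) > dropout_p) /
      (1 - dropout_p)
    H1 <- H1 * mask
    head_cache$drop_mask <- mask
  }
  logits <- dense_fwd(p$fw2, p$fb2, H1)
  list(logits = logits,
       cache = list(bs = bs, st = st, F3 = F3, feat = feat, H1 = H1,
                    head = head_cache, N = N))
}

backward_victim <- function(model, fw, dZ, need_dinput = FALSE) {
  spec <- model$spec; p <- model$params
  cache <- fw$cache
  D <- model$layout$D; Tn <- spec$t_slices; N <- cache$N
  grads <- list()
  r2 <- dense_bwd(p$fw2, cache$H1, dZ)
  grads$fw2 <- r2$dW; grads$fb2 <- r2$db
  dH1 <- r2$dX
  if (!is.null(cache$head$drop_mask)) dH1 <- dH1 * cache$head$drop_mask
  dH1[cache$H1 <= 0] <- 0
  r1 <- dense_bwd(p$fw1, cache$feat, dH1)
  grads$fw1 <- r1$dW; grads$fb1 <- r1$db
  dfeat <- r1$dX
  dF3 <- switch(spec$name,
    maxpool = {
      arg <- cache$head$arg
      dF3 <- array(0, c(D, Tn, N))
      idx <- cbind(rep(seq_len(D), N), as.vector(arg), rep(seq_len(N), each = D))
      dF3[idx] <- as.vector(dfeat)
      dF3
    },
    temporal_conv = {
      r <- tconv_bwd(p$tw, cache$head$tc,
                     array(dfeat, c(spec$tconv_filters, Tn, N)))
      grads[["tw"]] <- r$dWt; grads[["tb"]] <- r$dbt
      r$dF3
    },
    lstm = {
      r <- lstm_bwd(p$lwx, p$lwh, cache$head$ls, dfeat)
      grads[["lwx"]] <- r$dWx; grads[["lwh"]] <- r$dWh; grads[["lb"]] <- r$db
      r$dF3
    },
    mixed_lstm = {
      Hd <- spec$lstm_hidden
      rl <- lstm_bwd(p$lwx, p$lwh, cache$head$ls,
                     dfeat[seq_len(Hd), , drop = FALSE])
      rt <- tconv_bwd(p$tw, cache$head$tc,
                      array(dfeat[-seq_len(Hd), , drop = FALSE],
                            c(spec$tconv_filters, Tn, N)))
      grads[["lwx"]] <- rl$dWx; grads[["lwh"]] <- rl$dWh; grads[["lb"]] <- rl$db
      grads[["tw"]] <- rt$dWt; grads[["tb"]] <- rt$dbt
      rl$dF3 + rt$dF3
    }
  )
  dOut <- matrix(dF3, D, Tn * N)
  dim(dOut) <- dim(cache$st$out)
  sb <- conv_stack_bwd(p, cache$st$caches, dOut, need_dinput)
  grads <- c(grads, sb$grads)
  dinput <- NULL
  if (need_dinput) {
    sh <- spec$input_shape
    if (spec$input_kind == "beam") {
      dx <- array(sb$dX, c(sh[1], sh[2], sh[3], Tn, N))
      dinput <- aperm(dx, c(5, 4, 3, 1, 2))       # (N,T,B,H,W)
    } else {
      dx <- array(sb$dX, c(sh[1], sh[2], Tn, N))
      dinput <- aperm(dx, c(4, 3, 1, 2))          # (N,T,C,S)
    }
  }
  list(grads = grads, dinput = dinput)
}

# ---- public services --------------------------------------------------------

#' Class probabilities from a victim model
#'
#' @param model A `victim_model`.
#' @param x One sample (T x B x H x W for beam input, T x C x S for eeg
#'   input) or a batch with samples along the first axis.
#' @param batch_size Internal evaluation chunk size; defaults to 64 for
#'   beam input and 8 for the (much larger) eeg activations.
#' @return N x 2 matrix of probabilities (columns named by class).
#' @export
predict_proba <- function(model, x, batch_size = NULL) {
  batch_size <- batch_size %||%
    (if (model$spec$input_kind == "beam") 64L else 8L)
  d <- dim(x)
  if ((model$spec$input_kind == "beam" && length(d) == 4L) ||
      (model$spec$input_kind == "eeg" && length(d) == 3L)) {
    x <- array(x, c(1L, d))
    d <- dim(x)
  }
  want <- if (model$spec$input_kind == "beam") 5L else 4L
  if (length(d) != want) {
    stop("shape mismatch: expected a batch with ", want - 1L,
         "-dimensional samples on the first axis")
  }
  N <- d[1]
  out <- matrix(0, N, 2L, dimnames = list(NULL, model$classes))
  i <- 1L
  while (i <= N) {
    j <- min(i + batch_size - 1L, N)
    idx <- i:j
    xb <- if (model$spec$input_kind == "beam") {
      x[idx, , , , , drop = FALSE]
    } else x[idx, , , , drop = FALSE]
    fw <- forward_victim(model, xb)
    out[idx, ] <- t(softmax_rows(fw$logits))
    i <- j + 1L
  }
  out
}

#' Predicted class labels
#'
#' @inheritParams predict_proba
#' @return Integer vector of class indices (1 or 2).
#' @export
predict_label <- function(model, x, batch_size = NULL) {
  max.col(predict_proba(model, x, batch_size), ties.method = "first")
}

#' Gradient of the cross-entropy loss with respect to the input
#'
#' The input-gradient service used by the gradient-sign attacks: returns
#' d J(theta, x, y_true) / d x, shaped like `x`.
#'
#' @param model A `victim_model`.
#' @param x One sample or a batch (first axis = samples).
#' @param y_true Integer class index (1 or 2), recycled over the batch.
#' @return Numeric array shaped like `x`.
#' @export
loss_gradient <- function(model, x, y_true) {
  d <- dim(x)
  single <- (model$spec$input_kind == "beam" && length(d) == 4L) ||
    (model$spec$input_kind == "eeg" && length(d) == 3L)
  fw <- forward_victim(model, x)
  N <- fw$cache$N
  y <- as.integer(rep_len(y_true, N))
  ls <- xent_loss(fw$logits, y)
  bw <- backward_victim(model, fw, ls$dZ * N, need_dinput = TRUE)  # per-sample grad
  g <- bw$dinput
  if (single) {
    dim(g) <- d
  }
  g
}

#' Training configuration
#'
#' Adam with the reference training hyper-parameters: learning rate 1e-3,
#' moment decay (0.9, 0.999), cross-entropy loss. Dropout (p = 0.5) and L2
#' regularization are by default enabled only for the eeg-input mixed_lstm
#' model, the one combination that overfits.
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param adam_betas First/second moment decay rates.
#' @param seed Seed controlling shuffling, dropout and the validation split.
#' @param dropout_p Dropout probability on the FC layer; `NULL` = automatic
#'   rule above.
#' @param l2 L2 penalty weight; `NULL` = automatic rule above.
#' @param val_frac Fraction of the training set held out for early stopping.
#' @param patience Early-stopping patience in epochs (0 disables).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, learning_rate = 1e-3,
                         adam_betas = c(0.9, 0.999), seed = 1L,
                         dropout_p = NULL, l2 = NULL, val_frac = 0.15,
                         patience = 5L) {
  stopifnot(learning_rate > 0, epochs >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, adam_betas = adam_betas,
                 seed = as.integer(seed), dropout_p = dropout_p, l2 = l2,
                 val_frac = val_frac, patience = as.integer(patience)),
            class = "train_config")
}

subset_samples <- function(x, idx, input_kind) {
  if (input_kind == "beam") x[idx, , , , , drop = FALSE]
  else x[idx, , , , drop = FALSE]
}

#' Train a victim model
#'
#' Minibatch Adam on the cross-entropy loss, deterministic given
#' `config$seed`. A fraction of the training set is held out and used for
#' early stopping on validation loss; loss/accuracy curves are recorded on
#' the returned model.
#'
#' @param model An (untrained or trained) `victim_model`.
#' @param dataset List with `x` (batch array, samples on the first axis) and
#'   `y` (integer class indices 1/2, or a factor).
#' @param config A [train_config()].
#' @return The trained `victim_model`, with `$metrics` (a tibble of per-epoch
#'   curves).
#' @export
train_victim <- function(model, dataset, config = train_config()) {
  spec <- model$spec
  y <- dataset$y
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  stopifnot(all(y %in% c(1L, 2L)))
  x <- dataset$x
  N <- dim(x)[1]
  dropout_p <- config$dropout_p
  if (is.null(dropout_p)) {
    dropout_p <- if (spec$input_kind == "eeg" && spec$name == "mixed_lstm") 0.5 else 0
  }
  l2 <- config$l2
  if (is.null(l2)) {
    l2 <- if (spec$input_kind == "eeg" && spec$name == "mixed_lstm") 1e-4 else 0
  }
  with_local_seed(config$seed, {
    n_val <- if (config$patience > 0) max(2L, round(config$val_frac * N)) else 0L
    perm <- sample.int(N)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    state <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params, epoch = 0L)
    bad <- 0L
    curves <- list()
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + config$batch_size - 1L, length(ord))
        bidx <- ord[i:j]
        xb <- subset_samples(x, bidx, spec$input_kind)
        fw <- forward_victim(model, xb, train = TRUE, dropout_p = dropout_p)
        ls <- xent_loss(fw$logits, y[bidx])
        if (!is.finite(ls$loss)) stop("training-failure: loss diverged (NaN)")
        bw <- backward_victim(model, fw, ls$dZ)
        upd <- adam_step(model$params, bw$grads, state, config$learning_rate,
                         config$adam_betas, l2 = l2)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + ls$loss * length(bidx)
        ep_correct <- ep_correct + sum(max.col(t(ls$P), ties.method = "first") == y[bidx])
        ep_n <- ep_n + length(bidx)
        i <- j + 1L
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (n_val > 0) {
        xv <- subset_samples(x, val_idx, spec$input_kind)
        fwv <- forward_victim(model, xv)
        lsv <- xent_loss(fwv$logits, y[val_idx])
        val_loss <- lsv$loss
        val_acc <- mean(max.col(t(lsv$P), ties.method = "first") == y[val_idx])
        if (val_loss < best$loss - 1e-6) {
          best <- list(loss = val_loss, params = model$params, epoch = ep)
          bad <- 0L
        } else {
          bad <- bad + 1L
        }
      }
      curves[[ep]] <- tibble::tibble(
        epoch = ep, train_loss = ep_loss / ep_n, train_acc = ep_correct / ep_n,
        val_loss = val_loss, val_acc = val_acc)
      if (n_val > 0 && config$patience > 0 && bad >= config$patience) break
    }
    if (n_val > 0) model$params <- best$params
    model$trained <- TRUE
    model$metrics <- dplyr::bind_rows(curves)
    model$train_config <- config
  })
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.victim_model <- function(x, ...) {
  if (is.null(x$metrics)) return(tibble::tibble())
  x$metrics
}

#' @export
glance.victim_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  m <- x$metrics
  tibble::tibble(
    input_kind = x$spec$input_kind, head = x$spec$name, n_parameters = np,
    trained = x$trained,
    epochs_run = if (is.null(m)) 0L else nrow(m),
    final_train_loss = if (is.null(m)) NA_real_ else m$train_loss[nrow(m)],
    final_val_loss = if (is.null(m)) NA_real_ else m$val_loss[nrow(m)],
    final_val_acc = if (is.null(m)) NA_real_ else m$val_acc[nrow(m)]
  )
}

#' Save / load victim model weights as JSON
#'
#' Plain-text checkpoint: architecture spec, classes, and all parameter
#' tensors.
#'
#' @param model A `victim_model`.
#' @param path File path.
#' @export
save_victim <- function(model, path) {
  obj <- list(
    spec = unclass(model$spec), classes = model$classes,
    trained = model$trained,
    params = lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.numeric(p))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_victim
#' @export
load_victim <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(architecture_spec, obj$spec[c("name", "input_kind")])
  spec$t_slices <- as.integer(obj$spec$t_slices)
  spec$input_shape <- as.integer(obj$spec$input_shape)
  spec$fc_width <- as.integer(obj$spec$fc_width)
  spec$lstm_hidden <- as.integer(obj$spec$lstm_hidden)
  spec$tconv_filters <- as.integer(obj$spec$tconv_filters)
  model <- build_victim(spec, seed = 1L, classes = obj$classes)
  for (k in names(model$params)) {
    p <- obj$params[[k]]
    v <- as.numeric(p$data)
    if (length(p$dim) > 1) dim(v) <- p$dim
    model$params[[k]] <- v
  }
  model$trained <- isTRUE(obj$trained)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
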