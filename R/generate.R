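# Dual-branch recurrent sequence model over (code type, inter-peak
# interval) events: encoding, training (multi-task loss: categorical
# cross-entropy on the next code type + MSE on the next interval),
# statistically controlled generation, fidelity validation, and rendering
# of generated sequences into stimulus waveforms.
#
# The LSTM (selectable GRU cell) is implemented in-package with full
# backpropagation through time and Adam; gradients are validated against
# finite differences in the test suite.

#' Encode event sequences for the sequence model
#'
#' Each event becomes a one-hot code-type vector plus its inter-peak
#' interval as a continuous feature (normalized by the corpus mean
#' interval). Decoding inverts encoding exactly.
#'
#' @param sequences list of `event_sequence` data.frames
#'   (`code_id`, `interval_ms`).
#' @param code_ids the code alphabet; defaults to the sorted set of codes
#'   present.
#' @param interval_scale_ms normalization constant; defaults to the corpus
#'   mean interval.
#' @return list of class `encoded_events`: `code_ids`, `interval_scale_ms`,
#'   `sequences` (each a list with `type` integer vector and `interval`
#'   normalized numeric vector).
#' @export
encode_events <- function(sequences, code_ids = NULL,
                          interval_scale_ms = NULL) {
  if (!length(sequences)) stop("encode_events: empty corpus")
  all_codes <- unlist(lapply(sequences, function(s) s$code_id))
  if (is.null(code_ids)) code_ids <- sort(unique(all_codes))
  unknown <- setdiff(all_codes, code_ids)
  if (length(unknown))
    stop("encode_events: unknown code(s): ", paste(unique(unknown), collapse = ", "))
  if (is.null(interval_scale_ms))
    interval_scale_ms <- mean(unlist(lapply(sequences, function(s) s$interval_ms)))
  enc <- lapply(sequences, function(s)
    list(type = match(s$code_id, code_ids),
         interval = s$interval_ms / interval_scale_ms))
  structure(list(code_ids = code_ids, interval_scale_ms = interval_scale_ms,
                 sequences = enc),
            class = "encoded_events")
}

#' @rdname encode_events
#' @param encoded an `encoded_events` object.
#' @export
decode_events <- function(encoded) {
  lapply(encoded$sequences, function(s) {
    df <- data.frame(code_id = encoded$code_ids[s$type],
                     interval_ms = s$interval * encoded$interval_scale_ms,
                     stringsAsFactors = FALSE)
    class(df) <- c("event_sequence", "data.frame")
    df
  })
}

#' Sequence-model configuration
#'
#' Defaults follow the reference architecture: two recurrent layers of 128
#' hidden units, dropout 0.3 between layers, Adam at learning rate 0.001,
#' up to 50 epochs with early stopping (patience 5 on a 10% held-out
#' split), equal type/interval loss weights. `cell` selects LSTM (default)
#' or GRU. `window`/`stride` control the truncated-BPTT windowing of the
#' corpus; `hidden_units` may be scaled down for small corpora.
#'
#' @param hidden_units recurrent units per layer.
#' @param n_layers number of recurrent layers.
#' @param dropout dropout rate between layers, in \[0, 1).
#' @param learning_rate Adam step size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param loss_weight_interval weight of the interval MSE term relative to
#'   the type cross-entropy.
#' @param window,stride BPTT window length and stride (events).
#' @param batch_size minibatch size (windows).
#' @param val_fraction held-out fraction for early stopping.
#' @param cell `"lstm"` or `"gru"`.
#' @param grad_clip global gradient-norm clip.
#' @param seed seed for initialization, shuffling and dropout.
#' @return a `seq_model_config` list.
#' @export
seq_model_config <- function(hidden_units = 128, n_layers = 2, dropout = 0.3,
                             learning_rate = 1e-3, max_epochs = 50,
                             patience = 5, loss_weight_interval = 1,
                             window = 16, stride = 8, batch_size = 64,
                             val_fraction = 0.1, cell = c("lstm", "gru"),
                             grad_clip = 5, seed = 1) {
  cell <- match.arg(cell)
  cfg <- as.list(environment())
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("seq_model_config: dropout must be in [0, 1)")
  if (any(c(cfg$hidden_units, cfg$n_layers, cfg$learning_rate,
            cfg$max_epochs, cfg$window, cfg$batch_size) <= 0))
    stop("seq_model_config: config error: non-positive parameter")
  class(cfg) <- "seq_model_config"
  cfg
}

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# parameter initialization -------------------------------------------------

init_params <- function(input_dim, hidden, n_layers, n_types, cell, seed) {
  set.seed(seed)
  gmul <- if (cell == "lstm") 4L else 3L
  glorot <- function(r, c) matrix(stats::rnorm(r * c, 0, sqrt(2 / (r + c))), r, c)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1) input_dim else hidden
    b <- numeric(gmul * hidden)
    if (cell == "lstm") b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
    layers[[l]] <- list(W = glorot(gmul * hidden, d_in),
                        U = glorot(gmul * hidden, hidden),
                        b = b)
  }
  list(layers = layers,
       Wy = glorot(n_types, hidden), by = numeric(n_types),
       Wr = glorot(1, hidden), br = numeric(1))
}

flatten_params <- function(p) {
  unlist(c(lapply(p$layers, function(l) list(l$W, l$U, l$b)),
           list(p$Wy, p$by, p$Wr, p$br)), use.names = FALSE)
}

relist_params <- function(v, skel) {
  pos <- 0
  take <- function(template) {
    n <- length(template)
    out <- v[(pos + 1):(pos + n)]
    pos <<- pos + n
    if (is.matrix(template)) dim(out) <- dim(template)
    out
  }
  layers <- lapply(skel$layers, function(l)
    list(W = take(l$W), U = take(l$U), b = take(l$b)))
  list(layers = layers, Wy = take(skel$Wy), by = take(skel$by),
       Wr = take(skel$Wr), br = take(skel$br))
}

# recurrent cells (batched: states are hidden x batch matrices) ------------

cell_forward <- function(layer, x, h_prev, c_prev, hidden, cell) {
  if (cell == "lstm") {
    z <- layer$W %*% x + layer$U %*% h_prev + layer$b
    i <- sigmoid(z[1:hidden, , drop = FALSE])
    f <- sigmoid(z[(hidden + 1):(2 * hidden), , drop = FALSE])
    g <- tanh(z[(2 * hidden + 1):(3 * hidden), , drop = FALSE])
    o <- sigmoid(z[(3 * hidden + 1):(4 * hidden), , drop = FALSE])
    c_new <- f * c_prev + i * g
    h_new <- o * tanh(c_new)
    list(h = h_new, c = c_new, cache = list(x = x, h_prev = h_prev,
                                            c_prev = c_prev, i = i, f = f,
                                            g = g, o = o, c_new = c_new))
  } else {  # GRU
    zu <- layer$W[1:(2 * hidden), , drop = FALSE] %*% x +
      layer$U[1:(2 * hidden), , drop = FALSE] %*% h_prev +
      layer$b[1:(2 * hidden)]
    zg <- sigmoid(zu[1:hidden, , drop = FALSE])          # update gate
    rg <- sigmoid(zu[(hidden + 1):(2 * hidden), , drop = FALSE])  # reset
    hh <- tanh(layer$W[(2 * hidden + 1):(3 * hidden), , drop = FALSE] %*% x +
                 layer$U[(2 * hidden + 1):(3 * hidden), , drop = FALSE] %*%
                 (rg * h_prev) + layer$b[(2 * hidden + 1):(3 * hidden)])
    h_new <- zg * h_prev + (1 - zg) * hh
    list(h = h_new, c = c_prev,
         cache = list(x = x, h_prev = h_prev, zg = zg, rg = rg, hh = hh))
  }
}

cell_backward <- function(layer, cache, dh, dc, hidden, cell) {
  if (cell == "lstm") {
    tc <- tanh(cache$c_new)
    do <- dh * tc
    dc_tot <- dc + dh * cache$o * (1 - tc^2)
    di <- dc_tot * cache$g
    dg <- dc_tot * cache$i
    df <- dc_tot * cache$c_prev
    dc_prev <- dc_tot * cache$f
    dz <- rbind(di * cache$i * (1 - cache$i),
                df * cache$f * (1 - cache$f),
                dg * (1 - cache$g^2),
                do * cache$o * (1 - cache$o))
    list(dW = dz %*% t(cache$x), dU = dz %*% t(cache$h_prev),
         db = rowSums(dz), dx = t(layer$W) %*% dz,
         dh_prev = t(layer$U) %*% dz, dc_prev = dc_prev)
  } else {  # GRU
    dzg <- dh * (cache$h_prev - cache$hh)
    dhh <- dh * (1 - cache$zg)
    dh_prev <- dh * cache$zg
    da_h <- dhh * (1 - cache$hh^2)               # pre-activation of hh
    Uh <- layer$U[(2 * hidden + 1):(3 * hidden), , drop = FALSE]
    drh <- t(Uh) %*% da_h                        # d wrt (rg * h_prev)
    drg <- drh * cache$h_prev
    dh_prev <- dh_prev + drh * cache$rg
    da_z <- dzg * cache$zg * (1 - cache$zg)
    da_r <- drg * cache$rg * (1 - cache$rg)
    dz_all <- rbind(da_z, da_r, da_h)
    dW <- dz_all %*% t(cache$x)
    dU <- rbind(da_z %*% t(cache$h_prev),
                da_r %*% t(cache$h_prev),
                da_h %*% t(cache$rg * cache$h_prev))
    dh_prev <- dh_prev +
      t(layer$U[1:(2 * hidden), , drop = FALSE]) %*% rbind(da_z, da_r)
    list(dW = dW, dU = dU, db = rowSums(dz_all),
         dx = t(layer$W) %*% dz_all, dh_prev = dh_prev,
         dc_prev = dc * 0)
  }
}

# forward + loss + gradients over a batch of windows ------------------------
# xt: list over time of input matrices (D x B); ty/iv: targets (type index
# matrix T x B, interval matrix T x B). Returns loss and gradient list.
seq_net_loss <- function(params, xt, ty, iv, hidden, n_layers, cell,
                         w_int, dropout_masks = NULL, want_grads = TRUE) {
  T_ <- length(xt); B <- ncol(xt[[1]])
  h <- lapply(seq_len(n_layers), function(l) matrix(0, hidden, B))
  cst <- h
  caches <- vector("list", T_)
  hs_top <- vector("list", T_)
  layer_in <- vector("list", T_)
  for (t in seq_len(T_)) {
    inp <- xt[[t]]
    caches[[t]] <- vector("list", n_layers)
    layer_in[[t]] <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      layer_in[[t]][[l]] <- inp
      st <- cell_forward(params$layers[[l]], inp, h[[l]], cst[[l]], hidden, cell)
      h[[l]] <- st$h; cst[[l]] <- st$c
      caches[[t]][[l]] <- st$cache
      inp <- st$h
      if (!is.null(dropout_masks) && l < n_layers)
        inp <- inp * dropout_masks[[l]]
    }
    hs_top[[t]] <- inp
  }
  # heads at every timestep
  loss_type <- 0; loss_int <- 0
  dh_top <- vector("list", T_)
  gWy <- params$Wy * 0; gby <- params$by * 0
  gWr <- params$Wr * 0; gbr <- params$br * 0
  nobs <- T_ * B
  for (t in seq_len(T_)) {
    ht <- hs_top[[t]]
    logits <- params$Wy %*% ht + params$by
    logits <- sweep(logits, 2, apply(logits, 2, max), "-")
    p <- exp(logits)
    p <- sweep(p, 2, colSums(p), "/")
    idx <- cbind(ty[t, ], seq_len(B))
    loss_type <- loss_type - sum(log(pmax(p[idx], 1e-12)))
    u <- as.numeric(params$Wr %*% ht + params$br)
    r <- softplus(u)
    loss_int <- loss_int + sum((r - iv[t, ])^2)
    if (want_grads) {
      dlog <- p
      dlog[idx] <- dlog[idx] - 1
      dlog <- dlog / nobs
      du <- 2 * w_int * (r - iv[t, ]) * sigmoid(u) / nobs
      gWy <- gWy + dlog %*% t(ht); gby <- gby + rowSums(dlog)
      gWr <- gWr + matrix(du, 1) %*% t(ht); gbr <- gbr + sum(du)
      dh_top[[t]] <- t(params$Wy) %*% dlog + t(params$Wr) %*% matrix(du, 1)
    }
  }
  loss <- loss_type / nobs + w_int * loss_int / nobs
  if (!want_grads)
    return(list(loss = loss, loss_type = loss_type / nobs,
                loss_int = loss_int / nobs))
  gl <- lapply(params$layers, function(l)
    list(dW = l$W * 0, dU = l$U * 0, db = l$b * 0))
  dh_next <- lapply(seq_len(n_layers), function(l) matrix(0, hidden, B))
  dc_next <- dh_next
  for (t in rev(seq_len(T_))) {
    dfrom_above <- dh_top[[t]]
    for (l in rev(seq_len(n_layers))) {
      if (!is.null(dropout_masks) && l < n_layers)
        dfrom_above <- dfrom_above * dropout_masks[[l]]
      dh <- dfrom_above + dh_next[[l]]
      bk <- cell_backward(params$layers[[l]], caches[[t]][[l]], dh,
                          dc_next[[l]], hidden, cell)
      gl[[l]]$dW <- gl[[l]]$dW + bk$dW
      gl[[l]]$dU <- gl[[l]]$dU + bk$dU
      gl[[l]]$db <- gl[[l]]$db + bk$db
      dh_next[[l]] <- bk$dh_prev
      dc_next[[l]] <- bk$dc_prev
      dfrom_above <- bk$dx
    }
  }
  list(loss = loss, loss_type = loss_type / nobs, loss_int = loss_int / nobs,
       grads = list(layers = gl, Wy = gWy, by = gby, Wr = gWr, br = gbr))
}

one_hot_batch <- function(types, K) {
  B <- length(types)
  m <- matrix(0, K, B)
  m[cbind(types, seq_len(B))] <- 1
  m
}

# build (input, target) windows from encoded sequences
make_windows <- function(encoded, window, stride) {
  wins <- list()
  for (s in encoded$sequences) {
    n <- length(s$type)
    if (n < 2) next
    W <- min(window, n - 1)
    starts <- unique(c(seq(1, n - W, by = max(1, stride)), n - W))
    for (st in starts)
      wins[[length(wins) + 1L]] <-
        list(type_in = s$type[st:(st + W - 1)],
             iv_in = s$interval[st:(st + W - 1)],
             type_out = s$type[(st + 1):(st + W)],
             iv_out = s$interval[(st + 1):(st + W)])
  }
  wins
}

batch_tensors <- function(wins, K) {
  T_ <- length(wins[[1]]$type_in); B <- length(wins)
  ty_in <- vapply(wins, `[[`, integer(T_), "type_in")
  iv_in <- vapply(wins, `[[`, numeric(T_), "iv_in")
  ty_out <- vapply(wins, `[[`, integer(T_), "type_out")
  iv_out <- vapply(wins, `[[`, numeric(T_), "iv_out")
  dim(ty_in) <- c(T_, B); dim(iv_in) <- c(T_, B)
  dim(ty_out) <- c(T_, B); dim(iv_out) <- c(T_, B)
  xt <- lapply(seq_len(T_), function(t)
    rbind(one_hot_batch(ty_in[t, ], K), iv_in[t, ]))
  list(xt = xt, ty = ty_out, iv = iv_out)
}

adam_update <- function(v, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(value = v - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Train the dual-branch sequence model
#'
#' Truncated BPTT over fixed-length windows with Adam, a combined loss
#' (categorical cross-entropy on the next code type + weighted MSE on the
#' next normalized interval, both predicted at every step), seeded
#' shuffling and dropout, and early stopping on a held-out window split.
#' Training is deterministic given the config seed (single-threaded BLAS
#' assumed).
#'
#' @param sequences list of `event_sequence` data.frames, or an
#'   `encoded_events` object.
#' @param config a [seq_model_config()].
#' @return object of class `seq_model`: parameters, the encoding metadata
#'   (`code_ids`, `interval_scale_ms`), training frequencies, and a
#'   per-epoch `log` data.frame with separate type/interval losses.
#' @export
train_seq_model <- function(sequences, config = seq_model_config()) {
  enc <- if (inherits(sequences, "encoded_events")) sequences
         else encode_events(sequences)
  if (!length(enc$sequences) ||
      all(vapply(enc$sequences, function(s) length(s$type), 0L) < 2))
    stop("train_seq_model: corpus must contain a sequence with >= 2 events")
  K <- length(enc$code_ids)
  types_all <- unlist(lapply(enc$sequences, `[[`, "type"))
  iv_all <- unlist(lapply(enc$sequences, `[[`, "interval"))
  degenerate <- length(unique(types_all)) == 1 &&
    stats::sd(iv_all) < 1e-12
  if (degenerate)
    warning("train_seq_model: degenerate corpus (single type, constant interval)")
  hidden <- config$hidden_units
  cell <- config$cell
  params <- init_params(K + 1, hidden, config$n_layers, K, cell, config$seed)
  wins <- make_windows(enc, config$window, config$stride)
  set.seed(config$seed + 1)
  n_val <- max(1L, floor(config$val_fraction * length(wins)))
  if (length(wins) < 2) n_val <- 0L
  perm <- sample(length(wins))
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer()
  tr_idx <- setdiff(perm, val_idx)
  val_batch <- if (n_val > 0) {
    vb <- wins[val_idx]
    # group by window length
    lens <- vapply(vb, function(w) length(w$type_in), 0L)
    lapply(split(vb, lens), batch_tensors, K = K)
  } else NULL

  # Adam state
  zero_like <- function(p) list(m = p * 0, v = p * 0)
  ast <- list(layers = lapply(params$layers, function(l)
    list(W = zero_like(l$W), U = zero_like(l$U), b = zero_like(l$b))),
    Wy = zero_like(params$Wy), by = zero_like(params$by),
    Wr = zero_like(params$Wr), br = zero_like(params$br))

  log_rows <- list()
  best_val <- Inf; best_params <- params; bad <- 0L; step <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    set.seed(config$seed + 100 + epoch)
    order_tr <- sample(tr_idx)
    ep_type <- 0; ep_int <- 0; nb <- 0L
    lens <- vapply(wins[order_tr], function(w) length(w$type_in), 0L)
    for (grp in split(order_tr, lens)) {
      bstarts <- seq(1, length(grp), by = config$batch_size)
      for (bs in bstarts) {
        ids <- grp[bs:min(bs + config$batch_size - 1, length(grp))]
        bt <- batch_tensors(wins[ids], K)
        masks <- if (config$dropout > 0 && config$n_layers > 1)
          lapply(seq_len(config$n_layers - 1), function(l)
            matrix(stats::rbinom(hidden * length(ids), 1, 1 - config$dropout),
                   hidden) / (1 - config$dropout))
        else NULL
        res <- seq_net_loss(params, bt$xt, bt$ty, bt$iv, hidden,
                            config$n_layers, cell,
                            config$loss_weight_interval, masks)
        # global gradient clipping
        gv <- flatten_params(list(layers = lapply(res$grads$layers, function(l)
          list(W = l$dW, U = l$dU, b = l$db)),
          Wy = res$grads$Wy, by = res$grads$by,
          Wr = res$grads$Wr, br = res$grads$br))
        gn <- sqrt(sum(gv^2))
        if (gn > config$grad_clip) gv <- gv * config$grad_clip / gn
        gr <- relist_params(gv, params)
        step <- step + 1L
        for (l in seq_len(config$n_layers)) {
          for (nm in c("W", "U", "b")) {
            up <- adam_update(params$layers[[l]][[nm]], gr$layers[[l]][[nm]],
                              ast$layers[[l]][[nm]], config$learning_rate, step)
            params$layers[[l]][[nm]] <- up$value
            ast$layers[[l]][[nm]] <- up$state
          }
        }
        for (nm in c("Wy", "by", "Wr", "br")) {
          up <- adam_update(params[[nm]], gr[[nm]], ast[[nm]],
                            config$learning_rate, step)
          params[[nm]] <- up$value
          ast[[nm]] <- up$state
        }
        ep_type <- ep_type + res$loss_type; ep_int <- ep_int + res$loss_int
        nb <- nb + 1L
      }
    }
    val_loss <- if (!is.null(val_batch)) {
      mean(vapply(val_batch, function(vb)
        seq_net_loss(params, vb$xt, vb$ty, vb$iv, hidden, config$n_layers,
                     cell, config$loss_weight_interval,
                     want_grads = FALSE)$loss, 0))
    } else ep_type / nb + ep_int / nb
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    train_type_loss = ep_type / nb,
                                    train_interval_loss = ep_int / nb,
                                    val_loss = val_loss)
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_params <- params; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  freq <- as.numeric(table(factor(types_all, levels = seq_len(K))))
  structure(list(params = best_params, config = config,
                 code_ids = enc$code_ids,
                 interval_scale_ms = enc$interval_scale_ms,
                 train_freq = stats::setNames(freq / sum(freq), enc$code_ids),
                 degenerate = degenerate,
                 log = do.call(rbind, log_rows)),
            class = "seq_model")
}

#' @export
print.seq_model <- function(x, ...) {
  cat(sprintf("<seq_model> %s, %d layer(s) x %d units, %d code types, %d epoch(s) trained\n",
              toupper(x$config$cell), x$config$n_layers,
              x$config$hidden_units, length(x$code_ids), nrow(x$log)))
  invisible(x)
}

# single-step stateful forward; state is list(h = list, c = list)
seq_model_step <- function(model, x, state) {
  hidden <- model$config$hidden_units
  nl <- model$config$n_layers
  cell <- model$config$cell
  inp <- matrix(x, ncol = 1)
  for (l in seq_len(nl)) {
    st <- cell_forward(model$params$layers[[l]], inp, state$h[[l]],
                       state$c[[l]], hidden, cell)
    state$h[[l]] <- st$h; state$c[[l]] <- st$c
    inp <- st$h
  }
  logits <- as.numeric(model$params$Wy %*% inp + model$params$by)
  u <- as.numeric(model$params$Wr %*% inp + model$params$br)
  list(logits = logits, interval_norm = softplus(u), state = state)
}

seq_model_state0 <- function(model) {
  hidden <- model$config$hidden_units
  nl <- model$config$n_layers
  list(h = lapply(seq_len(nl), function(l) matrix(0, hidden, 1)),
       c = lapply(seq_len(nl), function(l) matrix(0, hidden, 1)))
}

#' Generation control parameters
#'
#' The statistical control mechanism multiplies the model's predicted type
#' probabilities by `(target_freq / running_freq)^beta` (with add-half
#' smoothing of the running counts) and renormalizes, pulling the empirical
#' code frequencies of the generated sequence toward the target
#' distribution. Generation stops once every common code type (the top
#' `common_k` codes by training frequency) has occurred at least
#' `min_common_occurrences` times, or at `max_length` (flagged).
#'
#' @param target_distribution named probabilities; `NULL` uses the training
#'   frequencies.
#' @param min_common_occurrences required occurrences per common code
#'   (default 70).
#' @param common_k number of top codes forming the common set (`NULL` =
#'   all codes with positive target frequency).
#' @param max_length hard cap on generated events.
#' @param temperature softmax temperature (`-> 0` approaches argmax).
#' @param beta reweighting exponent of the statistical control.
#' @param min_interval_ms floor on generated intervals (one sample period
#'   at 30 kHz by default).
#' @return a `gen_control` list.
#' @export
gen_control <- function(target_distribution = NULL,
                        min_common_occurrences = 70, common_k = NULL,
                        max_length = 20000, temperature = 1, beta = 1,
                        min_interval_ms = 1000 / 30000) {
  if (min_common_occurrences < 1)
    stop("gen_control: min_common_occurrences must be >= 1")
  if (!is.null(target_distribution) &&
      abs(sum(target_distribution) - 1) > 1e-6)
    stop("gen_control: target distribution must sum to 1")
  structure(as.list(environment()), class = "gen_control")
}

#' Generate an event sequence from a trained model
#'
#' Warm-starts the recurrent state on `seed_events` (a sequence drawn from
#' the corpus), then alternates type sampling (temperature softmax,
#' reweighted by the statistical control) and interval prediction. All
#' intervals are strictly positive (softplus head plus a floor of one
#' sample period). Deterministic for a given `seed`.
#'
#' @param model a `seq_model`.
#' @param seed_events an `event_sequence` data.frame to prime the state.
#' @param control a [gen_control()].
#' @param seed RNG seed for type sampling.
#' @return an `event_sequence` (`code_id`, `interval_ms`) with attributes
#'   `source = "generated"`, `capped` (TRUE if `max_length` was hit before
#'   the occurrence quota) and `common_codes`.
#' @export
generate_sequence <- function(model, seed_events, control = gen_control(),
                              seed = 1) {
  set.seed(seed)
  K <- length(model$code_ids)
  target <- if (is.null(control$target_distribution)) model$train_freq
            else control$target_distribution[model$code_ids]
  target[is.na(target)] <- 0
  common <- if (is.null(control$common_k)) names(target)[target > 0]
            else names(sort(target, decreasing = TRUE))[
              seq_len(min(control$common_k, K))]
  state <- seq_model_state0(model)
  res <- NULL
  emit_x <- function(type_idx, iv_norm)
    c(as.numeric(seq_len(K) == type_idx), iv_norm)
  for (r in seq_len(nrow(seed_events))) {
    ti <- match(seed_events$code_id[r], model$code_ids)
    if (is.na(ti)) stop("generate_sequence: seed event code not in model alphabet")
    res <- seq_model_step(model, emit_x(ti, seed_events$interval_ms[r] /
                                          model$interval_scale_ms), state)
    state <- res$state
  }
  counts <- stats::setNames(numeric(K), model$code_ids)
  out_type <- integer(); out_iv <- numeric()
  capped <- FALSE
  repeat {
    if (length(out_type) >= control$max_length) { capped <- TRUE; break }
    logits <- res$logits / max(control$temperature, 1e-6)
    logits <- logits - max(logits)
    p <- exp(logits); p <- p / sum(p)
    # statistical control: pull empirical frequencies toward the target
    run <- (counts + 0.5) / sum(counts + 0.5)
    wgt <- (target / run)^control$beta
    wgt[!is.finite(wgt)] <- 0
    p <- p * wgt
    if (sum(p) <= 0) p <- rep(1 / K, K) else p <- p / sum(p)
    ti <- if (control$temperature <= 1e-6) which.max(p)
          else sample.int(K, 1, prob = p)
    iv <- max(res$interval_norm * model$interval_scale_ms,
              control$min_interval_ms)
    out_type <- c(out_type, ti); out_iv <- c(out_iv, iv)
    counts[ti] <- counts[ti] + 1
    if (all(counts[common] >= control$min_common_occurrences)) break
    res <- seq_model_step(model, emit_x(ti, iv / model$interval_scale_ms),
                          state)
    state <- res$state
  }
  df <- data.frame(code_id = model$code_ids[out_type], interval_ms = out_iv,
                   stringsAsFactors = FALSE)
  attr(df, "source") <- "generated"
  attr(df, "capped") <- capped
  attr(df, "common_codes") <- common
  class(df) <- c("event_sequence", "data.frame")
  df
}

#' Validate a generated sequence against its training corpus
#'
#' Chi-square homogeneity test on code-type counts (union alphabet; absent
#' codes count 0, with a warning on alphabet mismatch) and a two-sample
#' Kolmogorov-Smirnov test on the interval distributions, with a combined
#' pass/fail verdict at `alpha`.
#'
#' @param generated an `event_sequence` (or data.frame with `code_id`,
#'   `interval_ms`).
#' @param training list of `event_sequence` data.frames or a single one.
#' @param alpha significance level for the verdict.
#' @return list of class `fidelity_report`: `chi_sq`, `chi_df`, `chi_p`,
#'   `ks_stat`, `ks_p`, `freq_table`, `pass`.
#' @export
validate_generated <- function(generated, training, alpha = 0.05) {
  if (is.data.frame(training)) training <- list(training)
  tr_codes <- unlist(lapply(training, `[[`, "code_id"))
  tr_iv <- unlist(lapply(training, `[[`, "interval_ms"))
  if (!nrow(generated) || !length(tr_codes))
    stop("validate_generated: empty input")
  if (length(setdiff(generated$code_id, tr_codes)) ||
      length(setdiff(tr_codes, generated$code_id)))
    warning("validate_generated: alphabet mismatch; using union with zero counts")
  codes <- sort(union(generated$code_id, tr_codes))
  cg <- table(factor(generated$code_id, levels = codes))
  ct <- table(factor(tr_codes, levels = codes))
  ft <- data.frame(code_id = codes,
                   generated_freq = as.numeric(cg) / sum(cg),
                   training_freq = as.numeric(ct) / sum(ct))
  same_iv <- length(generated$interval_ms) == length(tr_iv) &&
    all(sort(generated$interval_ms) == sort(tr_iv))
  if (all(as.numeric(cg) * sum(ct) == as.numeric(ct) * sum(cg))) {
    chi <- 0; df <- length(codes) - 1; chip <- 1
  } else {
    keep <- as.numeric(cg) + as.numeric(ct) > 0
    tst <- suppressWarnings(stats::chisq.test(rbind(as.numeric(cg)[keep],
                                                    as.numeric(ct)[keep])))
    chi <- unname(tst$statistic); df <- unname(tst$parameter)
    chip <- unname(tst$p.value)
  }
  if (same_iv) {
    ks <- 0; ksp <- 1
  } else {
    kt <- suppressWarnings(stats::ks.test(generated$interval_ms, tr_iv))
    ks <- unname(kt$statistic); ksp <- unname(kt$p.value)
  }
  structure(list(chi_sq = chi, chi_df = df, chi_p = chip,
                 ks_stat = ks, ks_p = ksp, freq_table = ft,
                 alpha = alpha, pass = chip > alpha && ksp > alpha),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> chi-sq %.3f (df %d, p %.4f); K-S %.4f (p %.4f) -> %s at alpha %.2g\n",
              x$chi_sq, x$chi_df, x$chi_p, x$ks_stat, x$ks_p,
              if (x$pass) "PASS" else "FAIL", x$alpha))
  invisible(x)
}

#' Render an event sequence into a stimulus waveform
#'
#' Places each event's code template (peak-aligned) on a zero baseline at
#' the cumulative inter-peak times; overlapping templates are summed with a
#' warning. At zero noise, re-running detection and classification on the
#' rendered trace recovers the (code, interval) sequence exactly.
#'
#' @param events an `event_sequence` (`code_id`, `interval_ms`). The first
#'   event's interval positions the second peak, and so on; the last
#'   interval pads the tail.
#' @param library a `code_library` containing every referenced code.
#' @param rate sampling rate (Hz).
#' @param uv_per_count quantization of the output recording.
#' @return a single-channel `mea_recording`.
#' @export
render_stimulus <- function(events, library, rate, uv_per_count = 0.01) {
  if (!nrow(events)) {
    return(recording(matrix(integer(), nrow = 1, ncol = 0), rate,
                     uv_per_count))
  }
  ids <- vapply(library$codes, `[[`, "", "code_id")
  miss <- setdiff(events$code_id, ids)
  if (length(miss))
    stop("render_stimulus: code(s) not in library: ", paste(miss, collapse = ", "))
  peaks_s <- c(0, cumsum(events$interval_ms[-nrow(events)])) / 1000
  tpl_len <- length(library$codes[[1]]$template_uv)
  offset <- tpl_len                      # headroom so no template is clipped
  n <- round(peaks_s[length(peaks_s)] * rate) + 2L * tpl_len + 1L
  x <- numeric(n)
  spans <- vapply(library$codes, function(cd) {
    nz <- which(cd$template_uv != 0)
    if (length(nz)) diff(range(nz)) + 1L else 0L
  }, 0L)
  min_iv <- min(events$interval_ms)
  if (min_iv / 1000 * rate < max(spans))
    warning("render_stimulus: interval shorter than template span; overlap-added")
  for (r in seq_len(nrow(events))) {
    cd <- library$codes[[match(events$code_id[r], ids)]]
    s0 <- round(peaks_s[r] * rate) + offset
    a <- s0 - cd$alignment_index + 1L
    idx <- seq_along(cd$template_uv) + a - 1L
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + cd$template_uv[ok]
  }
  counts <- round(x / uv_per_count)
  counts[counts > 32767] <- 32767; counts[counts < -32768] <- -32768
  recording(matrix(as.integer(counts), nrow = 1), rate, uv_per_count)
}
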