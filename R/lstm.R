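# Character-level LSTM language model, implemented directly on BLAS-batched
# matrix operations.  One-hot inputs to layer 1 (vocabularies are a few dozen
# tokens), stacked LSTM layers, a softmax output head, Adam optimisation and
# truncated-at-sequence-end BPTT.  All randomness flows through the caller's
# set.seed().

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(vocab_size, hidden = 256L, layers = 2L, scale = 0.08) {
  lay <- vector("list", layers)
  for (l in seq_len(layers)) {
    din <- if (l == 1) vocab_size else hidden
    W <- matrix(stats::runif(4 * hidden * (din + hidden), -scale, scale),
                4 * hidden, din + hidden)
    b <- numeric(4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias: remember by default
    lay[[l]] <- list(W = W, b = b)
  }
  list(layers = lay,
       Wy = matrix(stats::runif(vocab_size * hidden, -scale, scale),
                   vocab_size, hidden),
       by = numeric(vocab_size),
       vocab_size = as.integer(vocab_size), hidden = as.integer(hidden),
       n_layers = as.integer(layers))
}

one_hot <- function(ids, V) {
  x <- matrix(0, V, length(ids))
  x[cbind(ids, seq_along(ids))] <- 1
  x
}

# Pad a list of id sequences into input/target matrices (Tmax x B).
lstm_batchify <- function(seqs, pad) {
  lens <- lengths(seqs) - 1L  # number of (input, target) steps
  Tmax <- max(lens)
  B <- length(seqs)
  IN <- matrix(pad, Tmax, B)
  TG <- matrix(pad, Tmax, B)
  for (j in seq_len(B)) {
    s <- seqs[[j]]
    IN[seq_len(lens[j]), j] <- s[-length(s)]
    TG[seq_len(lens[j]), j] <- s[-1]
  }
  list(IN = IN, TG = TG, mask = TG != pad)
}

# Forward (and optionally backward) pass over one padded batch.
# Returns mean-per-token negative log-likelihood; with grad=TRUE also the
# gradients in the same shapes as the parameters.
lstm_batch_pass <- function(params, batch, grad = TRUE) {
  V <- params$vocab_size; H <- params$hidden; L <- params$n_layers
  IN <- batch$IN; TG <- batch$TG; mask <- batch$mask
  Tmax <- nrow(IN); B <- ncol(IN)
  n_tok <- sum(mask)
  h <- lapply(seq_len(L), function(l) matrix(0, H, B))
  cc <- lapply(seq_len(L), function(l) matrix(0, H, B))
  cache <- if (grad) vector("list", Tmax)
  dlogits_all <- if (grad) vector("list", Tmax)
  loss <- 0
  gi <- 1:H; gf <- (H + 1):(2 * H); go <- (2 * H + 1):(3 * H); gg <- (3 * H + 1):(4 * H)
  for (t in seq_len(Tmax)) {
    x <- one_hot(IN[t, ], V)
    step <- if (grad) vector("list", L)
    for (l in seq_len(L)) {
      inp <- if (l == 1) x else h[[l - 1]]
      z <- params$layers[[l]]$W %*% rbind(inp, h[[l]]) + params$layers[[l]]$b
      i_g <- sigmoid(z[gi, , drop = FALSE])
      f_g <- sigmoid(z[gf, , drop = FALSE])
      o_g <- sigmoid(z[go, , drop = FALSE])
      g_g <- tanh(z[gg, , drop = FALSE])
      c_new <- f_g * cc[[l]] + i_g * g_g
      tc <- tanh(c_new)
      h_new <- o_g * tc
      if (grad) {
        step[[l]] <- list(inp = inp, h_prev = h[[l]], c_prev = cc[[l]],
                          i = i_g, f = f_g, o = o_g, g = g_g, tc = tc)
      }
      cc[[l]] <- c_new
      h[[l]] <- h_new
    }
    logits <- params$Wy %*% h[[L]] + params$by
    logits <- sweep(logits, 2, apply(logits, 2, max))
    e <- exp(logits)
    p <- sweep(e, 2, colSums(e), "/")
    sel <- cbind(TG[t, ], seq_len(B))
    lp <- log(p[sel])
    loss <- loss - sum(lp[mask[t, ]])
    if (grad) {
      d <- p
      d[sel] <- d[sel] - 1
      d[, !mask[t, ]] <- 0
      dlogits_all[[t]] <- d / n_tok
      step$h_top <- h[[L]]
      cache[[t]] <- step
    }
  }
  loss <- loss / n_tok
  if (!grad) return(list(loss = loss))

  gW <- lapply(params$layers, function(pl) matrix(0, nrow(pl$W), ncol(pl$W)))
  gb <- lapply(params$layers, function(pl) numeric(length(pl$b)))
  gWy <- matrix(0, V, H); gby <- numeric(V)
  dh_time <- lapply(seq_len(L), function(l) matrix(0, H, B))
  dc_time <- lapply(seq_len(L), function(l) matrix(0, H, B))
  for (t in rev(seq_len(Tmax))) {
    st <- cache[[t]]
    dlog <- dlogits_all[[t]]
    gWy <- gWy + dlog %*% t(st$h_top)
    gby <- gby + rowSums(dlog)
    dx_above <- crossprod(params$Wy, dlog)
    for (l in rev(seq_len(L))) {
      s <- st[[l]]
      dh <- dh_time[[l]] + dx_above
      dc <- dh * s$o * (1 - s$tc^2) + dc_time[[l]]
      d_i <- dc * s$g * s$i * (1 - s$i)
      d_f <- dc * s$c_prev * s$f * (1 - s$f)
      d_o <- dh * s$tc * s$o * (1 - s$o)
      d_g <- dc * s$i * (1 - s$g^2)
      dz <- rbind(d_i, d_f, d_o, d_g)
      gW[[l]] <- gW[[l]] + dz %*% t(rbind(s$inp, s$h_prev))
      gb[[l]] <- gb[[l]] + rowSums(dz)
      dinp <- crossprod(params$layers[[l]]$W, dz)
      din <- nrow(s$inp)
      dx_above <- dinp[seq_len(din), , drop = FALSE]
      dh_time[[l]] <- dinp[(din + 1):(din + H), , drop = FALSE]
      dc_time[[l]] <- dc * s$f
    }
  }
  list(loss = loss,
       grads = list(layers = Map(function(W, b) list(W = W, b = b), gW, gb),
                    Wy = gWy, by = gby))
}

# Flatten/unflatten parameter lists so the optimiser is shape-agnostic.
param_leaves <- function(p) {
  c(unlist(lapply(p$layers, function(l) list(l$W, l$b)), recursive = FALSE),
    list(p$Wy, p$by))
}

set_leaves <- function(p, leaves) {
  k <- 1
  for (l in seq_along(p$layers)) {
    p$layers[[l]]$W <- leaves[[k]]; k <- k + 1
    p$layers[[l]]$b <- leaves[[k]]; k <- k + 1
  }
  p$Wy <- leaves[[k]]; p$by <- leaves[[k + 1]]
  p
}

adam_init <- function(params) {
  leaves <- param_leaves(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gl <- param_leaves(grads)
  gnorm <- sqrt(sum(vapply(gl, function(g) sum(g^2), numeric(1))))
  if (!is.finite(gnorm)) stop("non-finite gradient norm", call. = FALSE)
  if (gnorm > clip) gl <- lapply(gl, function(g) g * (clip / gnorm))
  pl <- param_leaves(params)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(pl)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gl[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gl[[k]]^2
    pl[[k]] <- pl[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = set_leaves(params, pl), state = state)
}

# Mean per-token NLL of a set of sequences under the model (no gradients).
lstm_nll <- function(params, seqs, pad, batch_size = 256L) {
  tot <- 0; n <- 0
  for (idx in split(seq_along(seqs), ceiling(seq_along(seqs) / batch_size))) {
    b <- lstm_batchify(seqs[idx], pad)
    tot <- tot + lstm_batch_pass(params, b, grad = FALSE)$loss * sum(b$mask)
    n <- n + sum(b$mask)
  }
  tot / n
}

# One training epoch over shuffled minibatches; returns updated params/state
# and the epoch's mean training loss.
lstm_epoch <- function(params, state, seqs, pad, batch_size, lr) {
  ord <- sample(length(seqs))
  losses <- numeric(0)
  wts <- numeric(0)
  for (idx in split(ord, ceiling(seq_along(ord) / batch_size))) {
    b <- lstm_batchify(seqs[idx], pad)
    res <- lstm_batch_pass(params, b, grad = TRUE)
    if (!is.finite(res$loss)) {
      stop("non-finite training loss; try a lower learning rate", call. = FALSE)
    }
    up <- adam_step(params, res$grads, state, lr)
    params <- up$params; state <- up$state
    losses <- c(losses, res$loss); wts <- c(wts, sum(b$mask))
  }
  list(params = params, state = state,
       loss = sum(losses * wts) / sum(wts))
}

# Batched ancestral sampling with temperature; returns an integer matrix of
# sampled ids (max_length x n), END-terminated columns padded with PAD.
lstm_sample_ids <- function(params, n, temperature, max_length, begin, end, pad) {
  V <- params$vocab_size; H <- params$hidden; L <- params$n_layers
  h <- lapply(seq_len(L), function(l) matrix(0, H, n))
  cc <- lapply(seq_len(L), function(l) matrix(0, H, n))
  prev <- rep(begin, n)
  done <- rep(FALSE, n)
  out <- matrix(pad, max_length, n)
  gi <- 1:H; gf <- (H + 1):(2 * H); go <- (2 * H + 1):(3 * H); gg <- (3 * H + 1):(4 * H)
  for (t in seq_len(max_length)) {
    x <- one_hot(prev, V)
    for (l in seq_len(L)) {
      inp <- if (l == 1) x else h[[l - 1]]
      z <- params$layers[[l]]$W %*% rbind(inp, h[[l]]) + params$layers[[l]]$b
      i_g <- sigmoid(z[gi, , drop = FALSE]); f_g <- sigmoid(z[gf, , drop = FALSE])
      o_g <- sigmoid(z[go, , drop = FALSE]); g_g <- tanh(z[gg, , drop = FALSE])
      cc[[l]] <- f_g * cc[[l]] + i_g * g_g
      h[[l]] <- o_g * tanh(cc[[l]])
    }
    logits <- (params$Wy %*% h[[L]] + params$by) / temperature
    logits <- sweep(logits, 2, apply(logits, 2, max))
    # never emit PAD or BEGIN
    logits[c(pad, begin), ] <- -Inf
    e <- exp(logits)
    p <- sweep(e, 2, colSums(e), "/")
    u <- stats::runif(n)
    cs <- apply(p, 2, cumsum)
    pick <- colSums(cs < rep(u, each = V)) + 1L
    pick[pick > V] <- V
    pick[done] <- pad
    out[t, ] <- pick
    done <- done | pick == end
    prev <- pick
    prev[done] <- end  # keep feeding END to finished sequences
    if (all(done)) break
  }
  out
}
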