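# Recurrent and dense building blocks on top of the tape engine.
#
# Sequences are represented as lists of per-timestep matrices (N x F), padded
# to the batch maximum; a 0/1 mask matrix (N x T) marks real positions.  The
# GRU runs as a single fused tape op: the whole forward loop in one node,
# with the backward-through-time recursion written out by hand.

# ---- sequence-list ops -----------------------------------------------------

# token matrix (N x T, 0-based indices) -> list of T embedding matrices
tp_embed_seq <- function(tape, emb, tokens) {
  tt <- ncol(tokens)
  val <- lapply(seq_len(tt), function(t) emb$value[tokens[, t] + 1L, , drop = FALSE])
  tp_node(tape, val, list(emb), function(nd) {
    g <- matrix(0, nrow(emb$value), ncol(emb$value))
    for (t in seq_len(tt)) {
      rs <- rowsum(nd$grad[[t]], group = tokens[, t] + 1L)
      rows <- as.integer(rownames(rs))
      g[rows, ] <- g[rows, ] + rs
    }
    acc_grad(emb, g)
  })
}

# reverse each row's prefix of length len[i]; an involution, so backward
# applies the same permutation to the gradient
seq_reverse_perm <- function(lengths, tt) {
  lapply(seq_len(tt), function(t) ifelse(t <= lengths, lengths - t + 1L, t))
}

tp_seq_reverse <- function(tape, x, lengths) {
  tt <- length(x$value)
  n <- nrow(x$value[[1L]])
  perm <- seq_reverse_perm(lengths, tt)
  pick <- function(src, t) {
    out <- src[[t]]
    for (i in seq_len(n)) {
      pt <- perm[[t]][i]
      if (pt != t) out[i, ] <- src[[pt]][i, ]
    }
    out
  }
  val <- lapply(seq_len(tt), function(t) pick(x$value, t))
  tp_node(tape, val, list(x), function(nd) {
    acc_grad(x, lapply(seq_len(tt), function(t) pick(nd$grad, t)))
  })
}

tp_seq_concat <- function(tape, a, b) {
  na <- ncol(a$value[[1L]])
  val <- Map(cbind, a$value, b$value)
  tp_node(tape, val, list(a, b), function(nd) {
    acc_grad(a, lapply(nd$grad, function(g) g[, seq_len(na), drop = FALSE]))
    acc_grad(b, lapply(nd$grad, function(g) g[, -seq_len(na), drop = FALSE]))
  })
}

tp_seq_last <- function(tape, x) {
  tt <- length(x$value)
  tp_node(tape, x$value[[tt]], list(x), function(nd) {
    g <- lapply(x$value, function(v) matrix(0, nrow(v), ncol(v)))
    g[[tt]] <- nd$grad
    acc_grad(x, g)
  })
}

tp_seq_dropout <- function(tape, x, masks) {
  val <- Map(`*`, x$value, masks)
  tp_node(tape, val, list(x), function(nd) {
    acc_grad(x, Map(`*`, nd$grad, masks))
  })
}

# ---- fused GRU -------------------------------------------------------------

# One direction, one layer.  Gate conventions:
#   z = sigmoid(x Wz + h Uz + bz); r = sigmoid(x Wr + h Ur + br)
#   n = tanh(x Wn + r * (h Un) + bn);  h' = (1 - z) * n + z * h
# Masked steps carry the previous state through unchanged, which makes the
# final timestep equal to the state at each row's true length.
tp_gru <- function(tape, x, p, mask) {
  tt <- length(x$value)
  n <- nrow(x$value[[1L]])
  hdim <- ncol(p$Uz$value)
  Wz <- p$Wz$value; Wr <- p$Wr$value; Wn <- p$Wn$value
  Uz <- p$Uz$value; Ur <- p$Ur$value; Un <- p$Un$value
  bz <- as.numeric(p$bz$value); br <- as.numeric(p$br$value); bn <- as.numeric(p$bn$value)

  h <- matrix(0, n, hdim)
  cache <- vector("list", tt)
  out <- vector("list", tt)
  for (t in seq_len(tt)) {
    xt <- x$value[[t]]
    m <- mask[, t]
    z <- 1 / (1 + exp(-(sweep(xt %*% Wz + h %*% Uz, 2L, bz, `+`))))
    r <- 1 / (1 + exp(-(sweep(xt %*% Wr + h %*% Ur, 2L, br, `+`))))
    a <- h %*% Un
    nt <- tanh(sweep(xt %*% Wn + r * a, 2L, bn, `+`))
    hnew <- (1 - z) * nt + z * h
    hout <- m * hnew + (1 - m) * h
    cache[[t]] <- list(z = z, r = r, nt = nt, a = a, hp = h, m = m)
    h <- hout
    out[[t]] <- hout
  }

  parents <- list(x, p$Wz, p$Wr, p$Wn, p$Uz, p$Ur, p$Un, p$bz, p$br, p$bn)
  tp_node(tape, out, parents, function(nd) {
    gW <- list(z = 0 * Wz, r = 0 * Wr, n = 0 * Wn)
    gU <- list(z = 0 * Uz, r = 0 * Ur, n = 0 * Un)
    gb <- list(z = 0 * bz, r = 0 * br, n = 0 * bn)
    gx <- vector("list", tt)
    gh <- matrix(0, n, hdim)
    for (t in rev(seq_len(tt))) {
      cc <- cache[[t]]
      gh <- gh + nd$grad[[t]]
      gi <- gh * cc$m
      carry <- gh * (1 - cc$m)
      gz <- gi * (cc$hp - cc$nt)
      gn <- gi * (1 - cc$z)
      ghp <- gi * cc$z + carry
      dn <- gn * (1 - cc$nt * cc$nt)
      gr <- dn * cc$a
      ga <- dn * cc$r
      dz <- gz * cc$z * (1 - cc$z)
      dr <- gr * cc$r * (1 - cc$r)
      xt <- x$value[[t]]
      gW$z <- gW$z + crossprod(xt, dz)
      gW$r <- gW$r + crossprod(xt, dr)
      gW$n <- gW$n + crossprod(xt, dn)
      gU$z <- gU$z + crossprod(cc$hp, dz)
      gU$r <- gU$r + crossprod(cc$hp, dr)
      gU$n <- gU$n + crossprod(cc$hp, ga)
      gb$z <- gb$z + colSums(dz)
      gb$r <- gb$r + colSums(dr)
      gb$n <- gb$n + colSums(dn)
      gx[[t]] <- tcrossprod(dz, Wz) + tcrossprod(dr, Wr) + tcrossprod(dn, Wn)
      gh <- ghp + tcrossprod(dz, Uz) + tcrossprod(dr, Ur) + tcrossprod(ga, Un)
    }
    acc_grad(x, gx)
    acc_grad(p$Wz, gW$z); acc_grad(p$Wr, gW$r); acc_grad(p$Wn, gW$n)
    acc_grad(p$Uz, gU$z); acc_grad(p$Ur, gU$r); acc_grad(p$Un, gU$n)
    acc_grad(p$bz, gb$z); acc_grad(p$br, gb$r); acc_grad(p$bn, gb$n)
  })
}

# ---- parameter containers --------------------------------------------------

nn_init_dense <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  list(W = matrix(stats::runif(nin * nout, -s, s), nin, nout),
       b = numeric(nout))
}

nn_init_gru <- function(nin, nh) {
  s <- 1 / sqrt(nh)
  mk <- function(a, b) matrix(stats::runif(a * b, -s, s), a, b)
  list(Wz = mk(nin, nh), Wr = mk(nin, nh), Wn = mk(nin, nh),
       Uz = mk(nh, nh), Ur = mk(nh, nh), Un = mk(nh, nh),
       bz = numeric(nh), br = numeric(nh), bn = numeric(nh))
}

nn_init_embedding <- function(nvocab, dim) {
  matrix(stats::rnorm(nvocab * dim, sd = 0.1), nvocab, dim)
}

# flatten a nested list of numeric arrays into named leaves
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(x[[nm]])) {
      out <- c(out, flatten_params(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

unflatten_assign <- function(params, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1L]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), path, quote(params))
  eval(call("<-", expr, quote(value)))
  params
}

# wrap every leaf of a parameter list as a tape node
params_to_nodes <- function(tape, params) {
  rapply(params, function(v) tp_node(tape, v), how = "replace")
}

# collect leaf gradients from a node tree (zeros where untouched)
collect_grads <- function(nodes) {
  rapply(nodes, function(nd) nd$grad %||% (0 * nd$value), how = "replace",
         classes = "environment")
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  flat <- flatten_params(params)
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$wd <- weight_decay; st$t <- 0L
  st$m <- lapply(flat, function(v) 0 * v)
  st$v <- lapply(flat, function(v) 0 * v)
  st
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (k in names(fp)) {
    g <- fg[[k]]
    if (st$wd > 0) g <- g + st$wd * fp[[k]]
    st$m[[k]] <- st$beta1 * st$m[[k]] + (1 - st$beta1) * g
    st$v[[k]] <- st$beta2 * st$v[[k]] + (1 - st$beta2) * g * g
    step <- st$lr * (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + st$eps)
    params <- unflatten_assign(params, k, fp[[k]] - step)
    fp[[k]] <- fp[[k]] - step
  }
  params
}

# dense layer helper on the tape
tp_dense <- function(tape, x, p) {
  tp_add_bias(tape, tp_matmul(tape, x, p$W), p$b)
}
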