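# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Node values are numeric matrices, scalars, or (for recurrent inputs) lists
# of per-timestep matrices.  Each operation records a closure that propagates
# the node's accumulated gradient to its parents.  Gradients are checked
# against central finite differences in the test suite.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

#' @noRd
tp_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

tp_const <- function(tape, value) tp_node(tape, value)

# gradient accumulation; list-valued grads are summed elementwise
acc_grad <- function(nd, g) {
  if (is.null(nd$grad)) {
    nd$grad <- g
  } else if (is.list(g)) {
    nd$grad <- Map(`+`, nd$grad, g)
  } else {
    nd$grad <- nd$grad + g
  }
  invisible(NULL)
}

tape_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- elementwise / linear algebra ops --------------------------------------

tp_add <- function(tape, a, b) {
  tp_node(tape, a$value + b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad)
    acc_grad(b, nd$grad)
  })
}

tp_sub <- function(tape, a, b) {
  tp_node(tape, a$value - b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad)
    acc_grad(b, -nd$grad)
  })
}

tp_mul <- function(tape, a, b) {
  tp_node(tape, a$value * b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad * b$value)
    acc_grad(b, nd$grad * a$value)
  })
}

tp_scale <- function(tape, a, s) {
  tp_node(tape, a$value * s, list(a), function(nd) acc_grad(a, nd$grad * s))
}

tp_matmul <- function(tape, a, b) {
  tp_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad %*% t(b$value))
    acc_grad(b, crossprod(a$value, nd$grad))
  })
}

# add a length-ncol bias vector to every row
tp_add_bias <- function(tape, a, b) {
  bv <- as.numeric(b$value)
  tp_node(tape, sweep(a$value, 2L, bv, `+`), list(a, b), function(nd) {
    acc_grad(a, nd$grad)
    acc_grad(b, colSums(nd$grad))
  })
}

# multiply row i by scalar w[i] (w constant)
tp_scale_rows <- function(tape, a, w) {
  tp_node(tape, a$value * w, list(a), function(nd) acc_grad(a, nd$grad * w))
}

tp_tanh <- function(tape, a) {
  v <- tanh(a$value)
  tp_node(tape, v, list(a), function(nd) acc_grad(a, nd$grad * (1 - v * v)))
}

tp_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  tp_node(tape, v, list(a), function(nd) acc_grad(a, nd$grad * v * (1 - v)))
}

tp_relu <- function(tape, a) {
  v <- pmax(a$value, 0)
  tp_node(tape, v, list(a), function(nd) acc_grad(a, nd$grad * (a$value > 0)))
}

# shifted softplus ln(0.5 e^x + 0.5): smooth, ssp(0) = 0
tp_ssp <- function(tape, a) {
  x <- a$value
  v <- ifelse(x > 30, x, log1p(exp(-abs(x))) + pmax(x, 0)) - log(2)
  tp_node(tape, v, list(a), function(nd) {
    acc_grad(a, nd$grad / (1 + exp(-x)))
  })
}

tp_mean <- function(tape, a) {
  n <- length(a$value)
  tp_node(tape, mean(a$value), list(a), function(nd) {
    g <- array(nd$grad / n, dim = dim(a$value) %||% length(a$value))
    acc_grad(a, g)
  })
}

tp_sum <- function(tape, a) {
  tp_node(tape, sum(a$value), list(a), function(nd) {
    g <- array(nd$grad, dim = dim(a$value) %||% length(a$value))
    acc_grad(a, g)
  })
}

# ---- gather / scatter ------------------------------------------------------

# rows of a indexed by integer vector idx (value: length(idx) x ncol)
tp_gather_rows <- function(tape, a, idx) {
  tp_node(tape, a$value[idx, , drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    rs <- rowsum(nd$grad, group = idx)
    rows <- as.integer(rownames(rs))
    g[rows, ] <- rs
    acc_grad(a, g)
  })
}

# sum rows of a into nout groups given by idx (scatter-add)
tp_aggregate_rows <- function(tape, a, idx, nout) {
  val <- matrix(0, nout, ncol(a$value))
  rs <- rowsum(a$value, group = idx)
  val[as.integer(rownames(rs)), ] <- rs
  tp_node(tape, val, list(a), function(nd) {
    acc_grad(a, nd$grad[idx, , drop = FALSE])
  })
}

tp_concat_cols <- function(tape, a, b) {
  na <- ncol(a$value)
  tp_node(tape, cbind(a$value, b$value), list(a, b), function(nd) {
    acc_grad(a, nd$grad[, seq_len(na), drop = FALSE])
    acc_grad(b, nd$grad[, -seq_len(na), drop = FALSE])
  })
}

# append one zero row (padding target for gathers)
tp_pad_row <- function(tape, a) {
  tp_node(tape, rbind(a$value, 0), list(a), function(nd) {
    acc_grad(a, nd$grad[-nrow(nd$grad), , drop = FALSE])
  })
}

# inverted dropout; mask is sampled by the caller so seeding stays explicit
tp_dropout <- function(tape, a, mask) {
  tp_node(tape, a$value * mask, list(a), function(nd) acc_grad(a, nd$grad * mask))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
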