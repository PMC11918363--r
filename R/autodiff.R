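# Reverse-mode automatic differentiation on a linear tape.
#
# All trainable components in this package (the graph attention network and the
# tiny transformer encoder) run their forward passes through these primitives,
# so a single generic backward sweep provides exact gradients for any model
# variant, including the adaptive-weight fusion models where gradients flow
# from the NER loss through the wordpiece alignment into the GAT parameters.
# Node values are base-R numeric matrices; the tape is an environment holding
# nodes in creation order, which is already a topological order of the DAG.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_new <- function(tp, value, parents = integer(0), backward = NULL) {
  # Force all arguments before allocating this node's id: lazily evaluated
  # argument expressions may themselves create tape nodes, and reading tp$n
  # first would hand out the same slot twice.
  force(value); force(parents); force(backward)
  i <- tp$n + 1L
  if (i > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[i]] <- list(value = value, parents = parents, backward = backward)
  tp$n <- i
  structure(list(tape = tp, id = i), class = "adnode")
}

#' @noRd
ad_value <- function(x) x$tape$nodes[[x$id]]$value

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

# Leaf node; requires_grad only matters for whether the caller reads the grad.
ad_leaf <- function(tp, value) ad_new(tp, as_mat(value))

ad_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  A <- ad_value(a); B <- ad_value(b)
  V <- if (!ta && !tb) A %*% B
  else if (ta && !tb) crossprod(A, B)
  else if (!ta && tb) tcrossprod(A, B)
  else t(B %*% A)
  ad_new(a$tape, V, c(a$id, b$id), function(G) {
    if (!ta && !tb) list(tcrossprod(G, B), crossprod(A, G))
    else if (ta && !tb) list(tcrossprod(B, G), A %*% G)
    else if (!ta && tb) list(G %*% B, crossprod(G, A))
    else list(t(tcrossprod(G, B)), t(crossprod(G, A)))
  })
}

ad_add <- function(a, b) {
  ad_new(a$tape, ad_value(a) + ad_value(b), c(a$id, b$id),
         function(G) list(G, G))
}

# Add a 1 x d bias row to every row of a.
ad_add_bias <- function(a, bias) {
  bv <- ad_value(bias)
  ad_new(a$tape, sweep(ad_value(a), 2L, as.vector(bv), "+"),
         c(a$id, bias$id),
         function(G) list(G, matrix(colSums(G), nrow = 1L)))
}

ad_scale <- function(a, s) {
  ad_new(a$tape, ad_value(a) * s, a$id, function(G) list(G * s))
}

ad_mul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_new(a$tape, A * B, c(a$id, b$id), function(G) list(G * B, G * A))
}

# Multiply row i of a (n x d) by s[i] (n x 1 node).
ad_colscale <- function(a, s) {
  A <- ad_value(a); sv <- as.vector(ad_value(s))
  ad_new(a$tape, A * sv, c(a$id, s$id), function(G) {
    list(G * sv, matrix(rowSums(G * A), ncol = 1L))
  })
}

ad_relu <- function(a) {
  A <- ad_value(a)
  ad_new(a$tape, pmax(A, 0), a$id, function(G) list(G * (A > 0)))
}

ad_leaky_relu <- function(a, slope = 0.2) {
  A <- ad_value(a)
  ad_new(a$tape, ifelse(A > 0, A, slope * A), a$id,
         function(G) list(G * ifelse(A > 0, 1, slope)))
}

ad_elu <- function(a) {
  A <- ad_value(a)
  V <- ifelse(A > 0, A, exp(pmin(A, 0)) - 1)
  ad_new(a$tape, V, a$id, function(G) list(G * ifelse(A > 0, 1, V + 1)))
}

ad_tanh <- function(a) {
  V <- tanh(ad_value(a))
  ad_new(a$tape, V, a$id, function(G) list(G * (1 - V^2)))
}

# Gather rows; backward scatter-adds into the source.
ad_rows <- function(a, idx) {
  A <- ad_value(a)
  n <- nrow(A)
  ad_new(a$tape, A[idx, , drop = FALSE], a$id, function(G) {
    agg <- rowsum(G, group = idx)
    dA <- matrix(0, n, ncol(A))
    dA[as.integer(rownames(agg)), ] <- agg
    list(dA)
  })
}

# Place rows of a (length(idx) x d) at rows idx of an n x d zero matrix.
ad_scatter_rows <- function(a, idx, n) {
  A <- ad_value(a)
  V <- matrix(0, n, ncol(A))
  V[idx, ] <- A
  ad_new(a$tape, V, a$id, function(G) list(G[idx, , drop = FALSE]))
}

# Sum rows of a sharing a segment id into an nseg-row matrix.
ad_rowsum_segments <- function(a, seg, nseg) {
  A <- ad_value(a)
  agg <- rowsum(A, group = seg)
  V <- matrix(0, nseg, ncol(A))
  V[as.integer(rownames(agg)), ] <- agg
  ad_new(a$tape, V, a$id, function(G) list(G[seg, , drop = FALSE]))
}

# Column-wise softmax within segments of rows (per attention neighborhood).
ad_segment_softmax <- function(a, seg, nseg) {
  A <- ad_value(a)
  P <- A
  for (j in seq_len(ncol(A))) {
    x <- A[, j]
    mx <- vapply(split(x, seg), max, numeric(1))
    e <- exp(x - mx[as.character(seg)])
    z <- vapply(split(e, seg), sum, numeric(1))
    P[, j] <- e / z[as.character(seg)]
  }
  ad_new(a$tape, P, a$id, function(G) {
    D <- G
    for (j in seq_len(ncol(G))) {
      gp <- G[, j] * P[, j]
      s <- vapply(split(gp, seg), sum, numeric(1))
      D[, j] <- P[, j] * (G[, j] - s[as.character(seg)])
    }
    list(D)
  })
}

# Row-wise softmax with optional additive mask (constant matrix of 0 / -Inf).
ad_softmax_rows <- function(a, mask = NULL) {
  A <- ad_value(a)
  if (!is.null(mask)) A <- A + mask
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  P <- E / rowSums(E)
  ad_new(a$tape, P, a$id, function(G) {
    list(P * (G - rowSums(G * P)))
  })
}

ad_cbind <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ka <- ncol(A)
  ad_new(a$tape, cbind(A, B), c(a$id, b$id), function(G) {
    list(G[, seq_len(ka), drop = FALSE],
         G[, -seq_len(ka), drop = FALSE])
  })
}

ad_mean_rows <- function(a) {
  A <- ad_value(a)
  n <- nrow(A)
  ad_new(a$tape, matrix(colMeans(A), nrow = 1L), a$id, function(G) {
    list(matrix(rep(G / n, each = n), nrow = n))
  })
}

ad_max_rows <- function(a) {
  A <- ad_value(a)
  am <- apply(A, 2L, which.max)
  ad_new(a$tape, matrix(apply(A, 2L, max), nrow = 1L), a$id, function(G) {
    D <- matrix(0, nrow(A), ncol(A))
    D[cbind(am, seq_len(ncol(A)))] <- G
    list(D)
  })
}

# Layer normalization over rows with learned gain/bias (1 x d nodes).
ad_layernorm <- function(a, gain, bias, eps = 1e-5) {
  A <- ad_value(a)
  g <- as.vector(ad_value(gain)); b <- as.vector(ad_value(bias))
  d <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  s <- sqrt(rowMeans(xc^2) + eps)
  xh <- xc / s
  V <- sweep(xh %*% diag(g, d), 2L, b, "+")
  ad_new(a$tape, V, c(a$id, gain$id, bias$id), function(G) {
    dxh <- G %*% diag(g, d)
    dA <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) / s
    list(dA,
         matrix(colSums(G * xh), nrow = 1L),
         matrix(colSums(G), nrow = 1L))
  })
}

# Inverted dropout; draws from the session RNG so seeded runs reproduce.
ad_dropout <- function(a, p) {
  if (p <= 0) return(a)
  A <- ad_value(a)
  m <- (matrix(stats::runif(length(A)), nrow(A)) >= p) / (1 - p)
  ad_new(a$tape, A * m, a$id, function(G) list(G * m))
}

# Mean softmax cross-entropy over rows; target is an integer vector in
# 1..ncol(logits) with NA marking positions excluded from the loss.
ad_softmax_xent <- function(logits, target) {
  A <- ad_value(logits)
  keep <- which(!is.na(target))
  m <- length(keep)
  stopifnot(m > 0L)
  Z <- A - apply(A, 1L, max)
  P <- exp(Z) / rowSums(exp(Z))
  ll <- log(P[cbind(keep, target[keep])] + 1e-12)
  ad_new(logits$tape, matrix(-mean(ll), 1L, 1L), logits$id, function(G) {
    D <- matrix(0, nrow(A), ncol(A))
    D[keep, ] <- P[keep, , drop = FALSE]
    D[cbind(keep, target[keep])] <- D[cbind(keep, target[keep])] - 1
    list(D * (as.numeric(G) / m))
  })
}

# Mean binary cross-entropy with logits; labels in {0,1}, scores n x 1.
ad_bce_logits <- function(scores, labels) {
  A <- as.vector(ad_value(scores))
  n <- length(A)
  # log(1 + exp(x)) computed stably
  sp <- ifelse(A > 0, A + log1p(exp(-A)), log1p(exp(A)))
  loss <- mean(sp - labels * A)
  p <- 1 / (1 + exp(-A))
  ad_new(scores$tape, matrix(loss, 1L, 1L), scores$id, function(G) {
    list(matrix((p - labels) * (as.numeric(G) / n), ncol = 1L))
  })
}

# Backward sweep; afterwards ad_grad(node) returns the accumulated gradient.
ad_backward <- function(loss) {
  tp <- loss$tape
  grads <- vector("list", tp$n)
  grads[[loss$id]] <- matrix(1, 1L, 1L)
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    if (is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  tp$grads <- grads
  invisible(loss)
}

ad_grad <- function(x) {
  g <- x$tape$grads[[x$id]]
  if (is.null(g)) matrix(0, nrow(ad_value(x)), ncol(ad_value(x))) else g
}

# ---- AdamW ------------------------------------------------------------------

#' @noRd
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Decoupled weight decay as in the AdamW formulation: decay is applied to the
# weights directly, not folded into the gradient moments.
adamw_step <- function(params, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       no_decay = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    wd <- if (nm %in% no_decay) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           wd * params[[nm]])
  }
  list(params = params, state = state)
}

# Gaussian init helper used by all model constructors.
rmat <- function(n, d, sd = 0.05) matrix(stats::rnorm(n * d, sd = sd), n, d)
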