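## A minimal reverse-mode automatic-differentiation tape.
##
## Every forward operation appends a node holding its value, its parent
## nodes and a closure mapping the output gradient to parent gradients.
## backward() walks the tape in reverse creation order, so any DAG built
## by the forward pass is differentiated correctly.  Gradients are checked
## against central finite differences in the test-suite.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

t_node <- function(tp, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd
}

t_const <- function(tp, value) t_node(tp, value)

#' @noRd
tape_backward <- function(tp, loss) {
  loss$grad <- if (is.null(dim(loss$value))) rep(1, length(loss$value)) else array(1, dim(loss$value))
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn) || !length(nd$parents)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- nd$parents[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

## ---- primitive ops -------------------------------------------------------

op_conv <- function(tp, x, w, b, stride = 1L, pad = 1L) {
  y <- cpp_conv2d_fwd(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  t_node(tp, y, list(x, w, b), function(g) {
    dim(g) <- dim(y)
    bw <- cpp_conv2d_bwd(x$value, w$value, g, as.integer(stride), as.integer(pad))
    list(bw$gx, bw$gk, bw$gb)
  })
}

op_dense <- function(tp, x, w, b) {
  y <- x$value %*% w$value
  y <- sweep(y, 2L, b$value, "+")
  t_node(tp, y, list(x, w, b), function(g) {
    list(g %*% t(w$value), crossprod(x$value, g), colSums(g))
  })
}

op_lrelu <- function(tp, x, alpha = 0.2) {
  v <- x$value
  m <- alpha + (1 - alpha) * (v > 0)   # elementwise slope mask
  t_node(tp, v * m, list(x), function(g) list(g * m))
}

op_sigmoid <- function(tp, x) {
  y <- 1 / (1 + exp(-x$value))
  t_node(tp, y, list(x), function(g) list(g * y * (1 - y)))
}

op_tanh <- function(tp, x) {
  y <- tanh(x$value)
  t_node(tp, y, list(x), function(g) list(g * (1 - y^2)))
}

op_add <- function(tp, a, b) {
  t_node(tp, a$value + b$value, list(a, b), function(g) list(g, g))
}

op_scale <- function(tp, x, s) {
  t_node(tp, x$value * s, list(x), function(g) list(g * s))
}

op_upsample2 <- function(tp, x) {
  y <- cpp_upsample2_fwd(x$value)
  t_node(tp, y, list(x), function(g) {
    dim(g) <- dim(y)
    list(cpp_upsample2_bwd(g))
  })
}

# concatenate two batches along the channel axis
op_concat_c <- function(tp, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  t_node(tp, y, list(a, b), function(g) {
    dim(g) <- dim(y)
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# c(H, W, C, N) batch -> N x (H*W*C) matrix (row per sample)
op_flatten <- function(tp, x) {
  d <- dim(x$value)
  y <- t(matrix(x$value, prod(d[1:3]), d[4]))
  t_node(tp, y, list(x), function(g) {
    gx <- t(g)
    dim(gx) <- d
    list(gx)
  })
}

# N x (H*W*C) matrix -> c(H, W, C, N) batch
op_unflatten <- function(tp, x, H, W, C) {
  y <- array(t(x$value), c(H, W, C, nrow(x$value)))
  t_node(tp, y, list(x), function(g) {
    dim(g) <- c(H * W * C, nrow(x$value))
    list(t(g))
  })
}

op_cols <- function(tp, x, cols) {
  t_node(tp, x$value[, cols, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(x$value), ncol(x$value))
    gx[, cols] <- g
    list(gx)
  })
}

op_mean <- function(tp, x) {
  n <- length(x$value)
  t_node(tp, mean(x$value), list(x), function(g) {
    gx <- array(as.numeric(g) / n, if (is.null(dim(x$value))) length(x$value) else dim(x$value))
    if (is.null(dim(x$value))) gx <- as.numeric(gx)
    list(gx)
  })
}

# weighted sum of scalar nodes
op_wsum <- function(tp, nodes, weights) {
  v <- sum(vapply(seq_along(nodes), function(i) weights[i] * as.numeric(nodes[[i]]$value), 0))
  t_node(tp, v, nodes, function(g) lapply(weights, function(w) as.numeric(g) * w))
}

## ---- loss heads ----------------------------------------------------------

EPS_LOG <- 1e-12

# mean over all entries of log(x), with a probability floor
op_meanlog <- function(tp, x) {
  v <- pmax(x$value, EPS_LOG)
  n <- length(v)
  t_node(tp, mean(log(v)), list(x), function(g) {
    gx <- as.numeric(g) / (n * v)
    if (!is.null(dim(x$value))) dim(gx) <- dim(x$value)
    list(gx)
  })
}

# mean over all entries of log(1 - x)
op_meanlog1m <- function(tp, x) {
  v <- pmax(1 - x$value, EPS_LOG)
  n <- length(v)
  t_node(tp, mean(log(v)), list(x), function(g) {
    gx <- -as.numeric(g) / (n * v)
    if (!is.null(dim(x$value))) dim(gx) <- dim(x$value)
    list(gx)
  })
}

# softmax cross-entropy from logits (N x C), integer labels in 0..C-1
op_softmax_ce <- function(tp, logits, labels) {
  z <- logits$value
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(z)
  ii <- cbind(seq_len(n), labels + 1L)
  t_node(tp, -mean(log(pmax(p[ii], EPS_LOG))), list(logits), function(g) {
    gx <- p
    gx[ii] <- gx[ii] - 1
    list(gx * as.numeric(g) / n)
  })
}

# row-wise unit normalization, y_i = x_i / max(||x_i||, eps)
op_rownorm <- function(tp, x, eps = 1e-12) {
  v <- x$value
  nr <- sqrt(rowSums(v^2))
  nr <- pmax(nr, eps)
  y <- v / nr
  t_node(tp, y, list(x), function(g) {
    dot <- rowSums(y * g)
    list((g - y * dot) / nr)
  })
}

# InfoNCE from row-normalized view matrices E1 (anchors), E2 (positives):
# sims are cosine because rows are unit vectors; negatives for anchor i are
# the other anchors' first-view embeddings (in-batch negatives).
op_infonce <- function(tp, e1, e2, tau) {
  A <- e1$value; P <- e2$value
  n <- nrow(A)
  S <- tcrossprod(A)                # anchor-anchor sims
  pos <- rowSums(A * P)             # anchor-positive sims
  L <- 0
  probs <- matrix(0, n, n)          # softmax over [pos_i, S_i,-i]; col i self slot unused
  ppos <- numeric(n)
  for (i in seq_len(n)) {
    l <- c(pos[i], S[i, -i]) / tau
    m <- max(l)
    e <- exp(l - m)
    p <- e / sum(e)
    ppos[i] <- p[1]
    probs[i, -i] <- p[-1]
    L <- L - log(pmax(p[1], EPS_LOG))
  }
  L <- L / n
  t_node(tp, L, list(e1, e2), function(g) {
    g <- as.numeric(g)
    gpos <- (ppos - 1) / (tau * n) * g
    gS <- probs / (tau * n) * g
    diag(gS) <- 0
    gA <- (gS + t(gS)) %*% A + gpos * P
    gP <- gpos * A
    list(gA, gP)
  })
}

# mean |a - b| (L1 reconstruction)
op_mean_abs_diff <- function(tp, a, b) {
  d <- a$value - b$value
  n <- length(d)
  sg <- sign(d)
  t_node(tp, mean(abs(d)), list(a, b), function(g) {
    gg <- as.numeric(g) * sg / n
    list(gg, -gg)
  })
}

## ---- Fourier op ----------------------------------------------------------

# DC-centering index permutation for even side length
fft_shift_idx <- function(n) c((n / 2 + 1):n, 1:(n / 2))

# log(1 + |F|) of the 2-D DFT of each image in the batch, DC-centered.
# Backward uses the adjoint of the (linear, unnormalized) DFT:
# dL/dx = Re(sum_k g_k e^{+2*pi*i*k*n/N}) = Re(fft(g, inverse)).
op_spectrum <- function(tp, x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; N <- d[4]
  si <- fft_shift_idx(H); sj <- fft_shift_idx(W)
  Fs <- vector("list", N)
  y <- array(0, d)
  for (n in seq_len(N)) {
    Fm <- fft(matrix(x$value[, , 1L, n], H, W))
    Fs[[n]] <- Fm
    y[, , 1L, n] <- log1p(Mod(Fm))[si, sj]
  }
  t_node(tp, y, list(x), function(g) {
    dim(g) <- d
    gx <- array(0, d)
    inv_i <- order(si); inv_j <- order(sj)
    for (n in seq_len(N)) {
      gm <- matrix(g[, , 1L, n], H, W)[inv_i, inv_j]   # undo the shift
      Fm <- Fs[[n]]
      mag <- pmax(Mod(Fm), 1e-12)
      gF <- gm / (1 + mag) * (Fm / mag)
      gx[, , 1L, n] <- Re(fft(gF, inverse = TRUE))
    }
    list(gx)
  })
}
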