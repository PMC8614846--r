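# Minimal computational-graph engine for the segmentation network.
#
# A feature map batch is a "tensor": a (N*H*W) x C matrix whose row index
# is (n*W + w)*H + h (h fastest), so each column reshapes to an H x W x N
# array without permutation. Convolutions are im2col + BLAS gemm; the
# graph is a fixed DAG built once by the architecture constructor, and
# forward/backward walk it in (reverse) topological order.

kj_tensor <- function(x, N, H, W) list(x = x, N = N, H = H, W = W)

images_to_tensor <- function(images) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- matrix(unlist(lapply(images, as.vector), use.names = FALSE), ncol = 1L)
  kj_tensor(x, length(images), H, W)
}

masks_to_onehot <- function(masks, n_classes = 4L) {
  v <- unlist(lapply(masks, function(m) as.vector(unclass(m))),
              use.names = FALSE)
  out <- matrix(0, length(v), n_classes)
  for (cl in seq_len(n_classes)) out[v == cl - 1L, cl] <- 1
  out
}

graph_builder <- function() {
  nodes <- list()
  add <- function(op, inputs = integer(0), ...) {
    inputs <- as.integer(inputs)  # force: inputs may be nested add() calls
    id <- length(nodes) + 1L
    nodes[[id]] <<- c(list(id = id, op = op, inputs = inputs), list(...))
    id
  }
  list(add = add, get_nodes = function() nodes)
}

.kj_cache <- new.env(parent = emptyenv())

up2_index <- function(N, H, W) {
  key <- paste(N, H, W, sep = "x")
  idx <- .kj_cache[[key]]
  if (!is.null(idx)) return(idx)
  ho <- rep.int(seq_len(2 * H), 2 * W * N)
  wo <- rep.int(rep(seq_len(2 * W), each = 2 * H), N)
  n <- rep(seq_len(N), each = 4L * H * W)
  hi <- ceiling(ho / 2); wi <- ceiling(wo / 2)
  idx <- as.integer(((n - 1) * W + (wi - 1)) * H + hi)
  .kj_cache[[key]] <- idx
  idx
}

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

conv_out_dim <- function(d, k, stride, pad) (d + 2L * pad - k) %/% stride + 1L

# rows of the input tensor seen by a 1x1 stride-2 convolution
k1s2_index <- function(N, H, W) {
  key <- paste("k1s2", N, H, W, sep = "x")
  idx <- .kj_cache[[key]]
  if (!is.null(idx)) return(idx)
  Ho <- (H - 1L) %/% 2L + 1L; Wo <- (W - 1L) %/% 2L + 1L
  ho <- rep.int(seq_len(Ho), Wo * N)
  wo <- rep.int(rep(seq_len(Wo), each = Ho), N)
  n <- rep(seq_len(N), each = Ho * Wo)
  idx <- as.integer(((n - 1) * W + 2L * (wo - 1L)) * H + 2L * (ho - 1L) + 1L)
  .kj_cache[[key]] <- idx
  idx
}

# im2col with fast paths for 1x1 kernels (no patch expansion needed)
conv_xcol <- function(inp, node) {
  if (node$k == 1L && node$pad == 0L) {
    if (node$stride == 1L) return(inp$x)
    if (node$stride == 2L)
      return(inp$x[k1s2_index(inp$N, inp$H, inp$W), , drop = FALSE])
  }
  nn_im2col(inp$x, inp$N, inp$H, inp$W, node$k, node$stride, node$pad)
}

conv_dx <- function(dxcol, inp, node) {
  if (node$k == 1L && node$pad == 0L) {
    if (node$stride == 1L) return(dxcol)
    if (node$stride == 2L) {
      dx <- matrix(0, nrow(inp$x), ncol(dxcol))
      dx[k1s2_index(inp$N, inp$H, inp$W), ] <- dxcol
      return(dx)
    }
  }
  nn_col2im(dxcol, inp$N, inp$H, inp$W, node$k, node$stride, node$pad)
}

nn_forward <- function(model, xt, train = TRUE) {
  nodes <- model$graph
  P <- model$params; B <- model$buffers
  vals <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  for (node in nodes) {
    id <- node$id
    switch(node$op,
      input = {
        if (xt$H %% 32L != 0L || xt$W %% 32L != 0L)
          stop("input side must be divisible by 32 (got ",
               xt$H, "x", xt$W, ")")
        vals[[id]] <- xt
      },
      conv = {
        inp <- vals[[node$inputs]]
        xcol <- conv_xcol(inp, node)
        if (train && node$k > 1L) caches[[id]] <- xcol
        y <- xcol %*% P[[paste0(node$pname, ".W")]]
        if (isTRUE(node$bias))
          y <- y + rep_row(P[[paste0(node$pname, ".b")]], nrow(y))
        vals[[id]] <- kj_tensor(y, inp$N,
                                conv_out_dim(inp$H, node$k, node$stride, node$pad),
                                conv_out_dim(inp$W, node$k, node$stride, node$pad))
      },
      bn = {
        inp <- vals[[node$inputs]]
        x <- inp$x; n <- nrow(x)
        gam <- P[[paste0(node$pname, ".gamma")]]
        bet <- P[[paste0(node$pname, ".beta")]]
        if (train) {
          mu <- colMeans(x)
          xc <- x - rep_row(mu, n)
          va <- colMeans(xc * xc)
          inv <- 1 / sqrt(va + 1e-5)
          xhat <- xc * rep_row(inv, n)
          B[[paste0(node$pname, ".mean")]] <-
            0.9 * B[[paste0(node$pname, ".mean")]] + 0.1 * mu
          B[[paste0(node$pname, ".var")]] <-
            0.9 * B[[paste0(node$pname, ".var")]] + 0.1 * va
          caches[[id]] <- list(xhat = xhat, inv = inv)
        } else {
          inv <- 1 / sqrt(B[[paste0(node$pname, ".var")]] + 1e-5)
          xhat <- (x - rep_row(B[[paste0(node$pname, ".mean")]], n)) *
            rep_row(inv, n)
        }
        vals[[id]] <- kj_tensor(xhat * rep_row(gam, n) + rep_row(bet, n),
                                inp$N, inp$H, inp$W)
      },
      relu = {
        inp <- vals[[node$inputs]]
        y <- inp$x; y[y < 0] <- 0
        vals[[id]] <- kj_tensor(y, inp$N, inp$H, inp$W)
      },
      add = {
        a <- vals[[node$inputs[1]]]; b <- vals[[node$inputs[2]]]
        vals[[id]] <- kj_tensor(a$x + b$x, a$N, a$H, a$W)
      },
      maxpool = {
        inp <- vals[[node$inputs]]
        r <- nn_maxpool_fwd(inp$x, inp$N, inp$H, inp$W,
                            node$k, node$stride, node$pad)
        caches[[id]] <- list(idx = r$idx, n_in = nrow(inp$x))
        vals[[id]] <- kj_tensor(r$y, inp$N,
                                conv_out_dim(inp$H, node$k, node$stride, node$pad),
                                conv_out_dim(inp$W, node$k, node$stride, node$pad))
      },
      up2 = {
        inp <- vals[[node$inputs]]
        idx <- up2_index(inp$N, inp$H, inp$W)
        vals[[id]] <- kj_tensor(inp$x[idx, , drop = FALSE],
                                inp$N, 2L * inp$H, 2L * inp$W)
      },
      concat = {
        a <- vals[[node$inputs[1]]]; b <- vals[[node$inputs[2]]]
        if (a$H != b$H || a$W != b$W)
          stop("concat shape mismatch: ", a$H, "x", a$W, " vs ", b$H, "x", b$W)
        caches[[id]] <- ncol(a$x)
        vals[[id]] <- kj_tensor(cbind(a$x, b$x), a$N, a$H, a$W)
      },
      stop("unknown op ", node$op))
  }
  # buffers are returned (not assigned in place) so the caller decides
  # whether a training-mode forward updates the running BN statistics
  list(vals = vals, caches = caches, buffers = B)
}

nn_backward <- function(model, fw, dout) {
  nodes <- model$graph
  P <- model$params
  vals <- fw$vals; caches <- fw$caches
  dvals <- vector("list", length(nodes))
  grads <- list()
  dvals[[length(nodes)]] <- dout
  bump <- function(id, g) {
    dvals[[id]] <<- if (is.null(dvals[[id]])) g else dvals[[id]] + g
  }
  for (node in rev(nodes)) {
    id <- node$id
    dy <- dvals[[id]]
    if (is.null(dy)) next
    switch(node$op,
      input = {},
      conv = {
        inp <- vals[[node$inputs]]
        xcol <- if (!is.null(caches[[id]])) caches[[id]]
                else conv_xcol(inp, node)
        Wn <- paste0(node$pname, ".W")
        grads[[Wn]] <- crossprod(xcol, dy)
        if (isTRUE(node$bias))
          grads[[paste0(node$pname, ".b")]] <- colSums(dy)
        dxcol <- tcrossprod(dy, P[[Wn]])
        bump(node$inputs, conv_dx(dxcol, inp, node))
      },
      bn = {
        cc <- caches[[id]]
        if (is.null(cc)) stop("bn backward requires a training-mode forward")
        n <- nrow(dy)
        gam <- P[[paste0(node$pname, ".gamma")]]
        dgamma <- colSums(dy * cc$xhat)
        dbeta <- colSums(dy)
        grads[[paste0(node$pname, ".gamma")]] <- dgamma
        grads[[paste0(node$pname, ".beta")]] <- dbeta
        coef <- gam * cc$inv
        dx <- (dy - rep_row(dbeta / n, n) -
                 cc$xhat * rep_row(dgamma / n, n)) * rep_row(coef, n)
        bump(node$inputs, dx)
      },
      relu = {
        y <- vals[[id]]$x
        bump(node$inputs, dy * (y > 0))
      },
      add = {
        bump(node$inputs[1], dy)
        bump(node$inputs[2], dy)
      },
      maxpool = {
        cc <- caches[[id]]
        bump(node$inputs, nn_maxpool_bwd(dy, cc$idx, cc$n_in))
      },
      up2 = {
        inp <- vals[[node$inputs]]
        idx <- up2_index(inp$N, inp$H, inp$W)
        dx <- rowsum(dy, idx, reorder = TRUE)
        dimnames(dx) <- NULL
        bump(node$inputs, dx)
      },
      concat = {
        ca <- caches[[id]]
        bump(node$inputs[1], dy[, seq_len(ca), drop = FALSE])
        bump(node$inputs[2], dy[, -seq_len(ca), drop = FALSE])
      })
  }
  grads
}

# Numerically stable mean BCE over independent sigmoid channels, on
# logits; returns the loss and its gradient wrt the logits.
bce_with_logits <- function(z, y) {
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  loss <- mean(sp - y * z)
  dz <- (plogis(z) - y) / length(z)
  list(loss = loss, dz = dz)
}
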