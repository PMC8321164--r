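# Minimal CNN engine: vectorised im2col convolutions on BLAS, batch norm,
# max pooling, depthwise-separable convolutions, SGD with milestone schedule.
#
# Data layout between layers: a numeric matrix of shape (C*H*W) x N, column
# major with channel fastest, then image row y, then image column x; i.e.
# row index = c + C*((y-1) + H*(x-1)). An H x W x C image maps to a column
# via as.vector(aperm(img, c(3, 1, 2))). All spatial geometry (padding,
# gather/scatter indices) is precomputed at build time, so the forward and
# backward passes are pure index-gather + gemm operations.

im2col_geometry <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  ys <- rep(seq_len(H), times = W)
  xs <- rep(seq_len(W), each = H)
  # interior rows of the zero-padded (C, Hp*Wp) matrix
  q0 <- (ys + 1L) + Hp * xs
  pad_idx <- as.vector(outer(seq_len(C), (q0 - 1L) * C, "+"))
  offs <- expand.grid(dy = -1:1, dx = -1:1)  # dy fastest: fixed kernel order
  gather <- array(0L, dim = c(C, 9L, H * W))
  for (k in seq_len(9L)) {
    q <- (ys + offs$dy[k] + 1L) + Hp * (xs + offs$dx[k])
    gather[, k, ] <- outer(seq_len(C), (q - 1L) * C, "+")
  }
  gidx <- as.vector(gather)
  # map each gather position to a source row of the unpadded input
  # (0 = zero padding), for the compiled row-gather kernel
  src_of_padded <- integer(C * Hp * Wp)
  src_of_padded[pad_idx] <- seq_along(pad_idx)
  list(pad_idx = pad_idx, gather_idx = gidx,
       gather_src = src_of_padded[gidx], Hp = Hp, Wp = Wp)
}

nn_conv <- function(Cin, Cout, H, W) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"; ly$Cin <- Cin; ly$Cout <- Cout; ly$H <- H; ly$W <- W
  ly$geom <- im2col_geometry(H, W, Cin)
  ly$geom_out <- im2col_geometry(H, W, Cout)  # for the gradient pass
  ly$Wt <- matrix(stats::rnorm(Cout * 9L * Cin, sd = sqrt(2 / (9 * Cin))),
                  Cout, 9L * Cin)
  ly$b <- numeric(Cout)
  ly
}

# weight rearrangement for the conv-transpose-as-convolution identity:
# dx[ci, p] = sum_{co, k} W[co, (ci, k)] * dy[co, shift(p, flip(k))]
flip_weights <- function(Wt, Cout, Cin) {
  Wa <- array(Wt, c(Cout, Cin, 9L))
  Wb <- aperm(Wa[, , 9:1, drop = FALSE], c(2, 1, 3))
  dim(Wb) <- c(Cin, 9L * Cout)
  Wb
}

nn_dwsep <- function(Cin, Cout, H, W) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "dwsep"; ly$Cin <- Cin; ly$Cout <- Cout; ly$H <- H; ly$W <- W
  ly$geom <- im2col_geometry(H, W, Cin)
  ly$geom_out <- ly$geom  # depthwise gradient stays in Cin channels
  ly$Wd <- matrix(stats::rnorm(Cin * 9L, sd = sqrt(2 / 9)), Cin, 9L)
  ly$Wp <- matrix(stats::rnorm(Cout * Cin, sd = sqrt(2 / Cin)), Cout, Cin)
  ly$b <- numeric(Cout)
  ly
}

nn_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bn"; ly$C <- C; ly$momentum <- momentum; ly$eps <- eps
  ly$gamma <- rep(1, C); ly$beta <- numeric(C)
  ly$run_mean <- numeric(C); ly$run_var <- rep(1, C)
  ly
}

nn_relu <- function() {
  ly <- new.env(parent = emptyenv()); ly$type <- "relu"; ly
}

nn_maxpool <- function(C, H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  ly <- new.env(parent = emptyenv())
  ly$type <- "maxpool"; ly$C <- C; ly$H <- H; ly$W <- W
  Ho <- H %/% 2L; Wo <- W %/% 2L
  yo <- rep(seq_len(Ho), times = Wo)
  xo <- rep(seq_len(Wo), each = Ho)
  corners <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  ly$rows <- lapply(corners, function(d) {
    q <- (2L * yo - 1L + d[1]) + H * (2L * xo - 2L + d[2])
    as.vector(outer(seq_len(C), (q - 1L) * C, "+"))
  })
  ly
}

nn_gap <- function(C, P) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "gap"; ly$C <- C; ly$P <- P
  ly
}

nn_linear <- function(Fin, Fout) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "linear"; ly$Fin <- Fin; ly$Fout <- Fout
  ly$Wt <- matrix(stats::rnorm(Fout * Fin, sd = sqrt(2 / Fin)), Fout, Fin)
  ly$b <- numeric(Fout)
  ly
}

layer_forward <- function(ly, x, train) {
  N <- ncol(x)
  switch(ly$type,
    conv = {
      g <- ly$geom
      col <- gather_rows(x, g$gather_src)
      dim(col) <- c(9L * ly$Cin, ly$H * ly$W * N)
      Y <- ly$Wt %*% col + ly$b
      dim(Y) <- c(ly$Cout * ly$H * ly$W, N)
      list(out = Y, cache = list(col = col))
    },
    dwsep = {
      g <- ly$geom
      C <- ly$Cin; P <- ly$H * ly$W
      col <- gather_rows(x, g$gather_src)
      dim(col) <- c(C, 9L, P * N)
      Z <- matrix(0, C, P * N)
      for (k in seq_len(9L)) Z <- Z + ly$Wd[, k] * col[, k, ]
      Y <- ly$Wp %*% Z + ly$b
      dim(Y) <- c(ly$Cout * P, N)
      list(out = Y, cache = list(col = col, Z = Z))
    },
    bn = {
      C <- ly$C; m <- length(x) / C
      xm <- x; dim(xm) <- c(C, m)
      if (train) {
        mu <- rowMeans(xm)
        xc <- xm - mu
        v <- rowMeans(xc * xc)
        ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
        ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * v
      } else {
        mu <- ly$run_mean; v <- ly$run_var
        xc <- xm - mu
      }
      istd <- 1 / sqrt(v + ly$eps)
      xhat <- xc * istd
      y <- ly$gamma * xhat + ly$beta
      dim(y) <- dim(x)
      list(out = y, cache = list(xhat = xhat, istd = istd))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    maxpool = {
      r <- maxpool_fwd(x, ly$rows[[1]], ly$rows[[2]], ly$rows[[3]],
                       ly$rows[[4]])
      list(out = r$out, cache = list(which = r$which, nin = nrow(x)))
    },
    gap = {
      xa <- x; dim(xa) <- c(ly$C, ly$P, N)
      out <- xa[, 1, ]
      if (ly$P > 1) for (p in 2:ly$P) out <- out + xa[, p, ]
      if (is.null(dim(out))) out <- matrix(out, ly$C, N)
      list(out = out / ly$P, cache = NULL)
    },
    linear = {
      list(out = ly$Wt %*% x + ly$b, cache = list(x = x))
    },
    stop("unknown layer type: ", ly$type))
}

layer_backward <- function(ly, dy, cache, need_dx = TRUE) {
  N <- ncol(dy)
  switch(ly$type,
    conv = {
      P <- ly$H * ly$W
      dym <- dy; dim(dym) <- c(ly$Cout, P * N)
      ly$dWt <- tcrossprod(dym, cache$col)
      ly$db <- rowSums(dym)
      if (!need_dx) return(NULL)
      go <- ly$geom_out
      col2 <- gather_rows(dy, go$gather_src)
      dim(col2) <- c(9L * ly$Cout, P * N)
      dx <- flip_weights(ly$Wt, ly$Cout, ly$Cin) %*% col2
      dim(dx) <- c(ly$Cin * P, N)
      dx
    },
    dwsep = {
      g <- ly$geom; C <- ly$Cin; P <- ly$H * ly$W
      dym <- dy; dim(dym) <- c(ly$Cout, P * N)
      ly$dWp <- tcrossprod(dym, cache$Z)
      ly$db <- rowSums(dym)
      dZ <- crossprod(ly$Wp, dym)
      dWd <- matrix(0, C, 9L)
      for (k in seq_len(9L)) dWd[, k] <- rowSums(dZ * cache$col[, k, ])
      ly$dWd <- dWd
      if (!need_dx) return(NULL)
      dim(dZ) <- c(C * P, N)
      colZ <- gather_rows(dZ, g$gather_src)
      dim(colZ) <- c(C, 9L, P * N)
      dx <- matrix(0, C, P * N)
      for (k in seq_len(9L)) dx <- dx + ly$Wd[, 10L - k] * colZ[, k, ]
      dim(dx) <- c(C * P, N)
      dx
    },
    bn = {
      C <- ly$C; m <- length(dy) / C
      dym <- dy; dim(dym) <- c(C, m)
      xhat <- cache$xhat
      ly$dgamma <- rowSums(dym * xhat)
      ly$dbeta <- rowSums(dym)
      dxhat <- ly$gamma * dym
      dx <- (cache$istd / m) *
        (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
      dim(dx) <- dim(dy)
      dx
    },
    relu = dy * cache$mask,
    gap = {
      d <- dy / ly$P
      dxa <- array(0, c(ly$C, ly$P, N))
      for (p in seq_len(ly$P)) dxa[, p, ] <- d
      dim(dxa) <- c(ly$C * ly$P, N)
      dxa
    },
    maxpool = {
      maxpool_bwd(dy, cache$which, ly$rows[[1]], ly$rows[[2]],
                  ly$rows[[3]], ly$rows[[4]], cache$nin)
    },
    linear = {
      ly$dWt <- tcrossprod(dy, cache$x)
      ly$db <- rowSums(dy)
      if (!need_dx) return(NULL)
      crossprod(ly$Wt, dy)
    },
    stop("unknown layer type: ", ly$type))
}

seq_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, dy, need_dx = TRUE) {
  for (i in rev(seq_along(layers))) {
    dy <- layer_backward(layers[[i]], dy, caches[[i]],
                         need_dx = need_dx || i > 1L)
  }
  dy
}

#' @noRd
net_forward <- function(net, x, train = FALSE) {
  if (net$type == "seq") {
    seq_forward(net$layers, x, train)
  } else { # dual stream: x is list(rgb = , mhi = )
    r1 <- seq_forward(net$rgb_tower, x$rgb, train)
    r2 <- seq_forward(net$mhi_tower, x$mhi, train)
    h <- seq_forward(net$head, rbind(r1$out, r2$out), train)
    list(out = h$out, caches = list(r1 = r1$caches, r2 = r2$caches,
                                    h = h$caches, n1 = nrow(r1$out)))
  }
}

net_backward <- function(net, caches, dy, need_dx = FALSE) {
  if (net$type == "seq") {
    seq_backward(net$layers, caches, dy, need_dx = need_dx)
  } else {
    dh <- seq_backward(net$head, caches$h, dy, need_dx = TRUE)
    n1 <- caches$n1
    d1 <- seq_backward(net$rgb_tower, caches$r1,
                       dh[seq_len(n1), , drop = FALSE], need_dx = need_dx)
    d2 <- seq_backward(net$mhi_tower, caches$r2,
                       dh[(n1 + 1L):nrow(dh), , drop = FALSE],
                       need_dx = need_dx)
    list(rgb = d1, mhi = d2)
  }
}

net_layers <- function(net) {
  if (net$type == "seq") net$layers
  else c(net$rgb_tower, net$mhi_tower, net$head)
}

#' @noRd
net_param_count <- function(net) {
  sum(vapply(net_layers(net), function(ly) {
    switch(ly$type,
      conv = length(ly$Wt) + length(ly$b),
      dwsep = length(ly$Wd) + length(ly$Wp) + length(ly$b),
      bn = length(ly$gamma) + length(ly$beta),
      linear = length(ly$Wt) + length(ly$b),
      0)
  }, numeric(1)))
}

sgd_step <- function(net, lr) {
  for (ly in net_layers(net)) {
    switch(ly$type,
      conv = , linear = {
        ly$Wt <- ly$Wt - lr * ly$dWt
        ly$b <- ly$b - lr * ly$db
      },
      dwsep = {
        ly$Wd <- ly$Wd - lr * ly$dWd
        ly$Wp <- ly$Wp - lr * ly$dWp
        ly$b <- ly$b - lr * ly$db
      },
      bn = {
        ly$gamma <- ly$gamma - lr * ly$dgamma
        ly$beta <- ly$beta - lr * ly$dbeta
      })
  }
  invisible(net)
}

softmax_cols <- function(z) {
  zmax <- apply(z, 2, max)
  e <- exp(sweep(z, 2, zmax))
  sweep(e, 2, colSums(e), "/")
}

# cross-entropy loss + gradient; y: integer class indices 1..K
softmax_ce <- function(z, y) {
  p <- softmax_cols(z)
  n <- ncol(z); k <- nrow(z)
  picked <- p[y + k * (seq_len(n) - 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dz <- p
  dz[y + k * (seq_len(n) - 1L)] <- dz[y + k * (seq_len(n) - 1L)] - 1
  list(loss = loss, dz = dz / n)
}

# binary cross-entropy on a single sigmoid logit; y in {0,1}
sigmoid_bce <- function(z, y) {
  p <- 1 / (1 + exp(-z))
  loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, dz = (p - y) / length(y), p = p)
}

# serialise parameters/buffers to a plain list (for checkpoints)
net_state <- function(net) {
  lapply(net_layers(net), function(ly) {
    switch(ly$type,
      conv = , linear = list(Wt = ly$Wt, b = ly$b),
      dwsep = list(Wd = ly$Wd, Wp = ly$Wp, b = ly$b),
      bn = list(gamma = ly$gamma, beta = ly$beta,
                run_mean = ly$run_mean, run_var = ly$run_var),
      list())
  })
}

net_load_state <- function(net, state) {
  lys <- net_layers(net)
  stopifnot(length(lys) == length(state))
  for (i in seq_along(lys)) {
    for (nm in names(state[[i]])) assign(nm, state[[i]][[nm]], envir = lys[[i]])
  }
  invisible(net)
}
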