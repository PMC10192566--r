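# Minimal batch-major neural-network engine.
#
# Shapes: dense (n x d); conv1d (n, C, L); conv2d (n, C, H, W);
# bilstm in (n, T, C) -> out (n, 2H, T).  Each layer is an environment with
# $forward(x, train), $backward(g) (returns grad w.r.t. input, stores
# parameter grads as g_<name>), and $pnames naming its parameter fields.
# All randomness comes from the caller's RNG state, so building a network
# under set.seed() is fully deterministic.

new_layer <- function(type) {
  L <- new.env(parent = emptyenv())
  L$type <- type
  L$pnames <- character(0)
  L
}

#' @keywords internal
layer_dense <- function(n_in, n_out) {
  L <- new_layer("dense")
  L$W <- matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  L$b <- numeric(n_out)
  L$pnames <- c("W", "b")
  L$forward <- function(x, train = FALSE) {
    if (!is.matrix(x)) x <- as.matrix(x)
    if (ncol(x) != nrow(L$W)) {
      stop(sprintf("dense layer: expected %d input features, got %d",
                   nrow(L$W), ncol(x)))
    }
    L$x <- x
    sweep(x %*% L$W, 2L, L$b, `+`)
  }
  L$backward <- function(g) {
    L$g_W <- crossprod(L$x, g)
    L$g_b <- colSums(g)
    g %*% t(L$W)
  }
  L
}

#' @keywords internal
layer_relu <- function() {
  L <- new_layer("relu")
  L$forward <- function(x, train = FALSE) {
    L$mask <- x > 0
    x * L$mask
  }
  L$backward <- function(g) g * L$mask
  L
}

#' @keywords internal
layer_dropout <- function(rate = 0.2) {
  L <- new_layer("dropout")
  L$rate <- rate
  L$forward <- function(x, train = FALSE) {
    if (!train || L$rate <= 0) {
      L$mask <- NULL
      return(x)
    }
    keep <- 1 - L$rate
    L$mask <- array(stats::rbinom(length(x), 1L, keep), dim = dim2(x)) / keep
    x * L$mask
  }
  L$backward <- function(g) {
    if (is.null(L$mask)) g else g * L$mask
  }
  L
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' @keywords internal
layer_flatten <- function() {
  L <- new_layer("flatten")
  L$forward <- function(x, train = FALSE) {
    L$in_dim <- dim(x)
    n <- L$in_dim[1L]
    dim(x) <- c(n, prod(L$in_dim[-1L]))
    x
  }
  L$backward <- function(g) {
    dim(g) <- L$in_dim
    g
  }
  L
}

# Softmax over rows; backward propagates dL/dp -> dL/dlogits.
#' @keywords internal
layer_softmax <- function() {
  L <- new_layer("softmax")
  L$forward <- function(x, train = FALSE) {
    z <- x - apply(x, 1L, max)
    e <- exp(z)
    L$p <- e / rowSums(e)
    L$p
  }
  L$backward <- function(g) {
    L$p * (g - rowSums(g * L$p))
  }
  L
}

# Gradient reversal: identity forward, times -lambda backward.
#' @keywords internal
layer_grl <- function(lambda = 1) {
  L <- new_layer("grl")
  L$lambda <- lambda
  L$forward <- function(x, train = FALSE) x
  L$backward <- function(g) -L$lambda * g
  L
}

## --- 1-D convolution (same padding, kernel k odd) -----------------------

#' @keywords internal
layer_conv1d <- function(in_ch, out_ch, kernel = 3L) {
  stopifnot(kernel %% 2L == 1L)
  L <- new_layer("conv1d")
  L$in_ch <- in_ch; L$out_ch <- out_ch; L$k <- kernel
  fan_in <- in_ch * kernel
  L$W <- matrix(stats::rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                fan_in, out_ch)
  L$b <- numeric(out_ch)
  L$pnames <- c("W", "b")
  L$forward <- function(x, train = FALSE) {
    d <- dim(x)
    if (length(d) != 3L || d[2L] != L$in_ch) {
      stop(sprintf("conv1d: expected input (n, %d, L), got (%s)",
                   L$in_ch, paste(d, collapse = ", ")))
    }
    n <- d[1L]; C <- d[2L]; len <- d[3L]
    pad <- (L$k - 1L) %/% 2L
    xp <- array(0, c(n, C, len + 2L * pad))
    xp[, , pad + seq_len(len)] <- x
    col <- matrix(0, n * len, L$k * C)
    for (k in seq_len(L$k)) {
      sub <- xp[, , k:(k + len - 1L), drop = FALSE]     # (n, C, len)
      sub <- aperm(sub, c(1L, 3L, 2L))                  # (n, len, C)
      dim(sub) <- c(n * len, C)
      col[, ((k - 1L) * C + 1L):(k * C)] <- sub
    }
    L$col <- col; L$n <- n; L$len <- len; L$pad <- pad
    out <- sweep(col %*% L$W, 2L, L$b, `+`)             # (n*len, F)
    dim(out) <- c(n, len, L$out_ch)
    aperm(out, c(1L, 3L, 2L))                           # (n, F, len)
  }
  L$backward <- function(g) {
    n <- L$n; len <- L$len; C <- L$in_ch; pad <- L$pad
    gm <- aperm(g, c(1L, 3L, 2L))                       # (n, len, F)
    dim(gm) <- c(n * len, L$out_ch)
    L$g_W <- crossprod(L$col, gm)
    L$g_b <- colSums(gm)
    dcol <- gm %*% t(L$W)                               # (n*len, k*C)
    dxp <- array(0, c(n, C, len + 2L * pad))
    for (k in seq_len(L$k)) {
      blk <- dcol[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
      dim(blk) <- c(n, len, C)
      blk <- aperm(blk, c(1L, 3L, 2L))                  # (n, C, len)
      dxp[, , k:(k + len - 1L)] <- dxp[, , k:(k + len - 1L), drop = FALSE] + blk
    }
    dxp[, , pad + seq_len(len), drop = FALSE]
  }
  L
}

# Max-pool by 2 along the last axis; odd trailing element dropped.
#' @keywords internal
layer_maxpool1d <- function() {
  L <- new_layer("maxpool1d")
  L$forward <- function(x, train = FALSE) {
    d <- dim(x)
    L$in_len <- d[3L]
    l2 <- d[3L] %/% 2L
    if (l2 < 1L) stop("maxpool1d: input length < 2")
    a <- x[, , seq(1L, 2L * l2, by = 2L), drop = FALSE]
    b <- x[, , seq(2L, 2L * l2, by = 2L), drop = FALSE]
    L$amax <- a >= b           # ties -> first element
    L$d <- d; L$l2 <- l2
    pmax(a, b)
  }
  L$backward <- function(g) {
    dx <- array(0, L$d)
    dx[, , seq(1L, 2L * L$l2, by = 2L)] <- g * L$amax
    dx[, , seq(2L, 2L * L$l2, by = 2L)] <- g * !L$amax
    dx
  }
  L
}

## --- 2-D convolution (same padding, square odd kernel) ------------------

#' @keywords internal
layer_conv2d <- function(in_ch, out_ch, kernel = 3L) {
  stopifnot(kernel %% 2L == 1L)
  L <- new_layer("conv2d")
  L$in_ch <- in_ch; L$out_ch <- out_ch; L$k <- kernel
  fan_in <- in_ch * kernel^2
  L$W <- matrix(stats::rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                fan_in, out_ch)
  L$b <- numeric(out_ch)
  L$pnames <- c("W", "b")
  L$forward <- function(x, train = FALSE) {
    d <- dim(x)
    if (length(d) != 4L || d[2L] != L$in_ch) {
      stop(sprintf("conv2d: expected input (n, %d, H, W), got (%s)",
                   L$in_ch, paste(d, collapse = ", ")))
    }
    n <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
    pad <- (L$k - 1L) %/% 2L
    xp <- array(0, c(n, C, H + 2L * pad, W + 2L * pad))
    xp[, , pad + seq_len(H), pad + seq_len(W)] <- x
    col <- matrix(0, n * H * W, L$k^2 * C)
    idx <- 0L
    for (ki in seq_len(L$k)) for (kj in seq_len(L$k)) {
      sub <- xp[, , ki:(ki + H - 1L), kj:(kj + W - 1L), drop = FALSE]
      sub <- aperm(sub, c(1L, 3L, 4L, 2L))              # (n, H, W, C)
      dim(sub) <- c(n * H * W, C)
      col[, idx + seq_len(C)] <- sub
      idx <- idx + C
    }
    L$col <- col; L$n <- n; L$H <- H; L$Wd <- W; L$pad <- pad
    out <- sweep(col %*% L$W, 2L, L$b, `+`)
    dim(out) <- c(n, H, W, L$out_ch)
    aperm(out, c(1L, 4L, 2L, 3L))                       # (n, F, H, W)
  }
  L$backward <- function(g) {
    n <- L$n; H <- L$H; W <- L$Wd; C <- L$in_ch; pad <- L$pad
    gm <- aperm(g, c(1L, 3L, 4L, 2L))
    dim(gm) <- c(n * H * W, L$out_ch)
    L$g_W <- crossprod(L$col, gm)
    L$g_b <- colSums(gm)
    dcol <- gm %*% t(L$W)
    dxp <- array(0, c(n, C, H + 2L * pad, W + 2L * pad))
    idx <- 0L
    for (ki in seq_len(L$k)) for (kj in seq_len(L$k)) {
      blk <- dcol[, idx + seq_len(C), drop = FALSE]
      dim(blk) <- c(n, H, W, C)
      blk <- aperm(blk, c(1L, 4L, 2L, 3L))
      dxp[, , ki:(ki + H - 1L), kj:(kj + W - 1L)] <-
        dxp[, , ki:(ki + H - 1L), kj:(kj + W - 1L), drop = FALSE] + blk
      idx <- idx + C
    }
    dxp[, , pad + seq_len(H), pad + seq_len(W), drop = FALSE]
  }
  L
}

# Pool-by-2 independently along H (axis 3) and W (axis 4); an axis of
# size 1 is left untouched so deep stacks degrade gracefully.
#' @keywords internal
layer_maxpool2d <- function() {
  L <- new_layer("maxpool2d")
  pool_axis <- function(x, axis) {
    d <- dim(x)
    if (d[axis] < 2L) return(list(out = x, mask = NULL, d = d))
    l2 <- d[axis] %/% 2L
    ia <- seq(1L, 2L * l2, by = 2L); ib <- ia + 1L
    if (axis == 3L) {
      a <- x[, , ia, , drop = FALSE]; b <- x[, , ib, , drop = FALSE]
    } else {
      a <- x[, , , ia, drop = FALSE]; b <- x[, , , ib, drop = FALSE]
    }
    list(out = pmax(a, b), mask = a >= b, d = d, l2 = l2)
  }
  unpool_axis <- function(g, info, axis) {
    if (is.null(info$mask)) return(g)
    dx <- array(0, info$d)
    ia <- seq(1L, 2L * info$l2, by = 2L); ib <- ia + 1L
    if (axis == 3L) {
      dx[, , ia, ] <- g * info$mask
      dx[, , ib, ] <- g * !info$mask
    } else {
      dx[, , , ia] <- g * info$mask
      dx[, , , ib] <- g * !info$mask
    }
    dx
  }
  L$forward <- function(x, train = FALSE) {
    h <- pool_axis(x, 3L)
    w <- pool_axis(h$out, 4L)
    L$h <- h; L$w <- w
    w$out
  }
  L$backward <- function(g) {
    g <- unpool_axis(g, L$w, 4L)
    unpool_axis(g, L$h, 3L)
  }
  L
}

## --- Bidirectional LSTM --------------------------------------------------
# Input (n, T, C); output (n, 2H, T) with rows 1..H the forward pass and
# H+1..2H the time-reversed pass, both aligned to input time.  Gate order
# in the packed weight matrix: input, forget, cell, output.  Forget-gate
# bias initialized to 1.

#' @keywords internal
layer_bilstm <- function(n_in, hidden) {
  L <- new_layer("bilstm")
  L$n_in <- n_in; L$H <- hidden
  mk_w <- function() {
    W <- matrix(stats::rnorm((n_in + hidden) * 4L * hidden,
                             sd = 1 / sqrt(n_in + hidden)),
                n_in + hidden, 4L * hidden)
    b <- numeric(4L * hidden)
    b[hidden + seq_len(hidden)] <- 1     # forget bias
    list(W = W, b = b)
  }
  wf <- mk_w(); wb <- mk_w()
  L$Wf <- wf$W; L$bf <- wf$b; L$Wb <- wb$W; L$bb <- wb$b
  L$pnames <- c("Wf", "bf", "Wb", "bb")

  sigm <- function(z) 1 / (1 + exp(-z))

  run_dir <- function(x, W, b) {
    d <- dim(x); n <- d[1L]; Tt <- d[2L]; H <- L$H
    gi <- array(0, c(n, H, Tt)); gf <- gi; gg <- gi; go <- gi
    cs <- gi; tc <- gi; hs <- gi
    h <- matrix(0, n, H); cc <- matrix(0, n, H)
    xh <- array(0, c(n, L$n_in + H, Tt))
    for (t in seq_len(Tt)) {
      xt <- x[, t, , drop = FALSE]; dim(xt) <- c(n, L$n_in)
      z <- cbind(xt, h)
      xh[, , t] <- z
      a <- sweep(z %*% W, 2L, b, `+`)
      i <- sigm(a[, seq_len(H), drop = FALSE])
      f <- sigm(a[, H + seq_len(H), drop = FALSE])
      g <- tanh(a[, 2L * H + seq_len(H), drop = FALSE])
      o <- sigm(a[, 3L * H + seq_len(H), drop = FALSE])
      cc <- f * cc + i * g
      tcc <- tanh(cc)
      h <- o * tcc
      gi[, , t] <- i; gf[, , t] <- f; gg[, , t] <- g; go[, , t] <- o
      cs[, , t] <- cc; tc[, , t] <- tcc; hs[, , t] <- h
    }
    list(gi = gi, gf = gf, gg = gg, go = go, cs = cs, tc = tc, hs = hs,
         xh = xh, n = n, Tt = Tt)
  }

  bptt_dir <- function(cache, gh_seq, W) {
    # gh_seq: (n, H, T) gradient on the hidden output of this direction
    n <- cache$n; Tt <- cache$Tt; H <- L$H
    dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(ncol(W))
    dh <- matrix(0, n, H); dc <- matrix(0, n, H)
    dx <- array(0, c(n, Tt, L$n_in))
    for (t in rev(seq_len(Tt))) {
      dh <- dh + matrix(gh_seq[, , t], n, H)
      i <- matrix(cache$gi[, , t], n, H); f <- matrix(cache$gf[, , t], n, H)
      g <- matrix(cache$gg[, , t], n, H); o <- matrix(cache$go[, , t], n, H)
      tcc <- matrix(cache$tc[, , t], n, H)
      c_prev <- if (t > 1L) matrix(cache$cs[, , t - 1L], n, H) else matrix(0, n, H)
      do_ <- dh * tcc
      dct <- dh * o * (1 - tcc^2) + dc
      di <- dct * g
      df <- dct * c_prev
      dg <- dct * i
      dc <- dct * f
      da <- cbind(di * i * (1 - i), df * f * (1 - f),
                  dg * (1 - g^2), do_ * o * (1 - o))
      z <- matrix(cache$xh[, , t], n, L$n_in + H)
      dW <- dW + crossprod(z, da)
      db <- db + colSums(da)
      dz <- da %*% t(W)
      dx[, t, ] <- dz[, seq_len(L$n_in), drop = FALSE]
      dh <- dz[, L$n_in + seq_len(H), drop = FALSE]
    }
    list(dW = dW, db = db, dx = dx)
  }

  L$forward <- function(x, train = FALSE) {
    d <- dim(x)
    if (length(d) != 3L || d[3L] != L$n_in) {
      stop(sprintf("bilstm: expected input (n, T, %d), got (%s)",
                   L$n_in, paste(d, collapse = ", ")))
    }
    n <- d[1L]; Tt <- d[2L]; H <- L$H
    L$cf <- run_dir(x, L$Wf, L$bf)
    xr <- x[, rev(seq_len(Tt)), , drop = FALSE]
    L$cb <- run_dir(xr, L$Wb, L$bb)
    out <- array(0, c(n, 2L * H, Tt))
    out[, seq_len(H), ] <- aperm(L$cf$hs, c(1L, 2L, 3L))
    # backward-direction h at reversed step t corresponds to input time T+1-t
    out[, H + seq_len(H), ] <- L$cb$hs[, , rev(seq_len(Tt)), drop = FALSE]
    L$Tt <- Tt
    out
  }
  L$backward <- function(g) {
    H <- L$H; Tt <- L$Tt
    gf_seq <- g[, seq_len(H), , drop = FALSE]
    gb_seq <- g[, H + seq_len(H), rev(seq_len(Tt)), drop = FALSE]
    rf <- bptt_dir(L$cf, gf_seq, L$Wf)
    rb <- bptt_dir(L$cb, gb_seq, L$Wb)
    L$g_Wf <- rf$dW; L$g_bf <- rf$db
    L$g_Wb <- rb$dW; L$g_bb <- rb$db
    rf$dx + rb$dx[, rev(seq_len(Tt)), , drop = FALSE]
  }
  L
}

# Reshape (n, H, W) -> (n, 1, H, W) so scalograms enter conv2d as 1-channel
# images.
#' @keywords internal
layer_expand_image <- function() {
  L <- new_layer("expand_image")
  L$forward <- function(x, train = FALSE) {
    d <- dim(x)
    if (length(d) == 4L) return(x)
    dim(x) <- c(d[1L], 1L, d[2L], d[3L])
    L$was3 <- length(d) == 3L
    x
  }
  L$backward <- function(g) {
    d <- dim(g)
    dim(g) <- c(d[1L], d[3L], d[4L])
    g
  }
  L
}

# Batch normalization over feature columns; running statistics are used in
# eval mode. Keeps the feature scale bounded, which in adversarial training
# blocks the degenerate "inflate the features to blow up the discriminator
# loss" direction.
#' @keywords internal
layer_batchnorm <- function(dim, momentum = 0.9, eps = 1e-5) {
  L <- new_layer("batchnorm")
  L$gamma <- rep(1, dim); L$beta <- rep(0, dim)
  L$run_mean <- rep(0, dim); L$run_var <- rep(1, dim)
  L$momentum <- momentum; L$eps <- eps
  L$pnames <- c("gamma", "beta")
  L$forward <- function(x, train = FALSE) {
    if (train && nrow(x) > 1L) {
      mu <- colMeans(x)
      xc <- sweep(x, 2L, mu)
      v <- colMeans(xc^2)
      L$run_mean <- L$momentum * L$run_mean + (1 - L$momentum) * mu
      L$run_var <- L$momentum * L$run_var + (1 - L$momentum) * v
      L$istd <- 1 / sqrt(v + L$eps)
      L$xhat <- sweep(xc, 2L, L$istd, `*`)
      sweep(sweep(L$xhat, 2L, L$gamma, `*`), 2L, L$beta, `+`)
    } else {
      L$xhat <- NULL
      xc <- sweep(x, 2L, L$run_mean)
      xn <- sweep(xc, 2L, 1 / sqrt(L$run_var + L$eps), `*`)
      sweep(sweep(xn, 2L, L$gamma, `*`), 2L, L$beta, `+`)
    }
  }
  L$backward <- function(g) {
    if (is.null(L$xhat)) {
      L$g_gamma <- rep(0, length(L$gamma)); L$g_beta <- rep(0, length(L$beta))
      return(sweep(g, 2L, L$gamma / sqrt(L$run_var + L$eps), `*`))
    }
    n <- nrow(g)
    L$g_gamma <- colSums(g * L$xhat)
    L$g_beta <- colSums(g)
    gx <- sweep(g, 2L, L$gamma, `*`)
    sweep(gx - matrix(colMeans(gx), n, ncol(g), byrow = TRUE) -
            L$xhat * matrix(colMeans(gx * L$xhat), n, ncol(g), byrow = TRUE),
          2L, L$istd, `*`)
  }
  L
}

## --- network-level helpers ----------------------------------------------

#' @keywords internal
net_forward <- function(layers, x, train = FALSE) {
  for (L in layers) x <- L$forward(x, train)
  x
}

#' @keywords internal
net_backward <- function(layers, g) {
  for (L in rev(layers)) g <- L$backward(g)
  g
}

#' @keywords internal
net_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    for (p in L$pnames) out[[length(out) + 1L]] <- list(layer = L, name = p)
  }
  out
}

#' @keywords internal
net_n_params <- function(layers) {
  sum(vapply(net_params(layers),
             function(e) length(e$layer[[e$name]]), numeric(1)))
}

# Snapshot / restore parameter values (used for determinism and leakage
# tests, and to keep best-epoch models).
#' @keywords internal
net_get_params <- function(layers) {
  lapply(net_params(layers), function(e) e$layer[[e$name]])
}

# Full state snapshot: parameters plus batch-norm running statistics.
#' @keywords internal
net_get_state <- function(layers) {
  list(params = net_get_params(layers),
       bn = lapply(layers, function(L) {
         if (identical(L$type, "batchnorm")) {
           list(run_mean = L$run_mean, run_var = L$run_var)
         } else NULL
       }))
}

#' @keywords internal
net_set_state <- function(layers, state) {
  net_set_params(layers, state$params)
  for (i in seq_along(layers)) {
    if (!is.null(state$bn[[i]])) {
      layers[[i]]$run_mean <- state$bn[[i]]$run_mean
      layers[[i]]$run_var <- state$bn[[i]]$run_var
    }
  }
  invisible(layers)
}

#' @keywords internal
net_set_params <- function(layers, values) {
  ps <- net_params(layers)
  stopifnot(length(ps) == length(values))
  for (i in seq_along(ps)) ps[[i]]$layer[[ps[[i]]$name]] <- values[[i]]
  invisible(layers)
}

## --- optimizers -----------------------------------------------------------

#' @keywords internal
optim_adam <- function(layer_groups, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  O <- new.env(parent = emptyenv())
  O$entries <- net_params(unlist(layer_groups, recursive = FALSE))
  O$lr <- lr; O$b1 <- beta1; O$b2 <- beta2; O$eps <- eps
  O$t <- 0L
  O$m <- lapply(O$entries, function(e) 0 * e$layer[[e$name]])
  O$v <- O$m
  O$step <- function() {
    O$t <- O$t + 1L
    for (i in seq_along(O$entries)) {
      e <- O$entries[[i]]
      g <- e$layer[[paste0("g_", e$name)]]
      if (is.null(g)) next
      O$m[[i]] <- O$b1 * O$m[[i]] + (1 - O$b1) * g
      O$v[[i]] <- O$b2 * O$v[[i]] + (1 - O$b2) * g * g
      mh <- O$m[[i]] / (1 - O$b1^O$t)
      vh <- O$v[[i]] / (1 - O$b2^O$t)
      e$layer[[e$name]] <- e$layer[[e$name]] - O$lr * mh / (sqrt(vh) + O$eps)
    }
    invisible(NULL)
  }
  O
}

## --- cross-entropy on probability rows ------------------------------------

# Numerically guarded -log p; labels are 0-based class indices.
#' @keywords internal
ce_from_probs <- function(p, labels, floor = 1e-12) {
  n <- nrow(p)
  idx <- cbind(seq_len(n), labels + 1L)
  -mean(log(pmax(p[idx], floor)))
}

# Gradient of ce_from_probs w.r.t. the probability matrix.
#' @keywords internal
ce_grad_probs <- function(p, labels, floor = 1e-12) {
  n <- nrow(p)
  g <- matrix(0, n, ncol(p))
  idx <- cbind(seq_len(n), labels + 1L)
  g[idx] <- -1 / (n * pmax(p[idx], floor))
  g
}
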