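# Minimal neural-network primitives with explicit forward/backward passes.
#
# Every layer is an environment with:
#   $name    identifier used in summaries and freeze policies
#   $params  named list of numeric arrays (absent for parameter-free layers)
#   $grads   matching gradient accumulators
#   $frozen  logical: excluded from optimizer updates and trainable counts
#   $fw(x, train)   forward pass; caches what backward needs
#   $bw(dout)       backward pass; accumulates $grads, returns input grad
#
# Array convention: features x time x batch (batch last), so a reshape to
# (features, time * batch) exposes each (time, batch) column to plain
# matrix algebra. All randomness (init, dropout) draws from the session
# RNG, which callers seed via with_seed().

new_layer <- function(name) {
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$frozen <- FALSE
  e$params <- list()
  e$grads <- list()
  e
}

zero_grads <- function(layer) {
  for (p in names(layer$params)) {
    layer$grads[[p]] <- array(0, dim = dim_or_len(layer$params[[p]]))
  }
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

uniform_init <- function(dims, fan_in) {
  s <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -s, s), dim = dims)
}

## ---- temporal convolution (channels-as-features, "same" padding) -------

layer_conv1d <- function(name, c_in, c_out, k) {
  e <- new_layer(name)
  e$k <- as.integer(k); e$c_in <- c_in; e$c_out <- c_out
  e$pad_l <- (k - 1L) %/% 2L
  e$pad_r <- k - 1L - e$pad_l
  e$params$W <- uniform_init(c(c_out, c_in, k), fan_in = c_in * k)
  e$params$b <- as.numeric(uniform_init(c_out, fan_in = c_in * k))
  zero_grads(e)
  e$fw <- function(x, train = TRUE) {
    d <- dim(x); TT <- d[2]; B <- d[3]
    xp <- array(0, dim = c(e$c_in, TT + e$k - 1L, B))
    xp[, e$pad_l + seq_len(TT), ] <- x
    y <- matrix(0, e$c_out, TT * B)
    for (j in seq_len(e$k)) {
      xs <- xp[, j:(j + TT - 1L), , drop = FALSE]
      dim(xs) <- c(e$c_in, TT * B)
      y <- y + matrix(e$params$W[, , j], e$c_out, e$c_in) %*% xs
    }
    y <- y + e$params$b
    e$cache <- list(xp = xp, TT = TT, B = B)
    dim(y) <- c(e$c_out, TT, B)
    e$out_shape <- dim(y)
    y
  }
  e$bw <- function(dy) {
    TT <- e$cache$TT; B <- e$cache$B
    dym <- dy; dim(dym) <- c(e$c_out, TT * B)
    dxp <- array(0, dim = dim(e$cache$xp))
    for (j in seq_len(e$k)) {
      xs <- e$cache$xp[, j:(j + TT - 1L), , drop = FALSE]
      dim(xs) <- c(e$c_in, TT * B)
      e$grads$W[, , j] <- e$grads$W[, , j] + dym %*% t(xs)
      dxs <- t(matrix(e$params$W[, , j], e$c_out, e$c_in)) %*% dym
      dim(dxs) <- c(e$c_in, TT, B)
      dxp[, j:(j + TT - 1L), ] <- dxp[, j:(j + TT - 1L), ] + dxs
    }
    e$grads$b <- e$grads$b + rowSums(dym)
    dxp[, e$pad_l + seq_len(TT), , drop = FALSE]
  }
  e
}

## ---- batch normalization (per feature over time x batch) ---------------

layer_batchnorm <- function(name, f, eps = 1e-5, momentum = 0.1) {
  e <- new_layer(name)
  e$f <- f; e$eps <- eps; e$momentum <- momentum
  e$params$gamma <- rep(1, f)
  e$params$beta <- rep(0, f)
  e$running_mean <- rep(0, f)
  e$running_var <- rep(1, f)
  zero_grads(e)
  e$fw <- function(x, train = TRUE) {
    d <- dim(x); xm <- x; dim(xm) <- c(d[1], d[2] * d[3])
    if (train) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc^2)
      e$running_mean <- (1 - e$momentum) * e$running_mean + e$momentum * mu
      e$running_var <- (1 - e$momentum) * e$running_var + e$momentum * v
    } else {
      mu <- e$running_mean
      v <- e$running_var
      xc <- xm - mu
    }
    istd <- 1 / sqrt(v + e$eps)
    xhat <- xc * istd
    y <- xhat * e$params$gamma + e$params$beta
    e$cache <- list(xhat = xhat, istd = istd, d = d, train = train)
    dim(y) <- d
    e$out_shape <- d
    y
  }
  e$bw <- function(dy) {
    d <- e$cache$d
    dym <- dy; dim(dym) <- c(d[1], d[2] * d[3])
    xhat <- e$cache$xhat
    e$grads$gamma <- e$grads$gamma + rowSums(dym * xhat)
    e$grads$beta <- e$grads$beta + rowSums(dym)
    n <- ncol(dym)
    dxhat <- dym * e$params$gamma
    if (e$cache$train) {
      dx <- e$cache$istd * (dxhat - rowMeans(dxhat) -
                              xhat * rowMeans(dxhat * xhat))
    } else {
      dx <- dxhat * e$cache$istd
    }
    dim(dx) <- d
    dx
  }
  e
}

## ---- activations --------------------------------------------------------

layer_activation <- function(name, type = c("ELU", "ReLU", "Tanh", "GELU")) {
  type <- match.arg(type)
  e <- new_layer(name)
  e$type <- type
  e$fw <- function(x, train = TRUE) {
    y <- switch(type,
      ELU = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
      ReLU = pmax(x, 0),
      Tanh = tanh(x),
      GELU = x * stats::pnorm(x))
    dim(y) <- dim_or_null(x)
    e$cache <- list(x = x, y = y)
    y
  }
  e$bw <- function(dy) {
    x <- e$cache$x; y <- e$cache$y
    g <- switch(type,
      ELU = ifelse(x > 0, 1, y + 1),
      ReLU = (x > 0) * 1,
      Tanh = 1 - y^2,
      GELU = stats::pnorm(x) + x * stats::dnorm(x))
    d <- dy * g
    dim(d) <- dim_or_null(dy)
    d
  }
  e
}

dim_or_null <- function(x) if (is.null(dim(x))) NULL else dim(x)

## ---- temporal pooling ---------------------------------------------------

layer_pool <- function(name, k, type = c("max", "avg")) {
  type <- match.arg(type)
  e <- new_layer(name)
  e$k <- as.integer(k); e$type <- type
  e$fw <- function(x, train = TRUE) {
    d <- dim(x); TT <- d[2]
    t_out <- TT %/% e$k
    xr <- x[, seq_len(t_out * e$k), , drop = FALSE]
    dim(xr) <- c(d[1], e$k, t_out, d[3])
    if (type == "avg") {
      y <- xr[, 1, , , drop = FALSE]
      for (j in seq_len(e$k)[-1]) y <- y + xr[, j, , , drop = FALSE]
      y <- y / e$k
      dim(y) <- c(d[1], t_out, d[3])
      e$cache <- list(d = d, t_out = t_out)
    } else {
      y <- xr[, 1, , ]
      dim(y) <- c(d[1], t_out, d[3])
      amax <- array(1L, dim = c(d[1], t_out, d[3]))
      for (j in seq_len(e$k)[-1]) {
        xj <- xr[, j, , ]
        dim(xj) <- c(d[1], t_out, d[3])
        upd <- xj > y
        y[upd] <- xj[upd]
        amax[upd] <- j
      }
      e$cache <- list(d = d, t_out = t_out, amax = amax)
    }
    y
  }
  e$bw <- function(dy) {
    d <- e$cache$d; t_out <- e$cache$t_out
    dxr <- array(0, dim = c(d[1], e$k, t_out, d[3]))
    if (type == "avg") {
      for (j in seq_len(e$k)) dxr[, j, , ] <- dy / e$k
    } else {
      for (j in seq_len(e$k)) {
        m <- (e$cache$amax == j)
        g <- array(0, dim = c(d[1], t_out, d[3]))
        g[m] <- dy[m]
        dxr[, j, , ] <- g
      }
    }
    dim(dxr) <- c(d[1], e$k * t_out, d[3])
    dx <- array(0, dim = d)
    dx[, seq_len(e$k * t_out), ] <- dxr
    dx
  }
  e
}

## ---- dropout (inverted) -------------------------------------------------

layer_dropout <- function(name, p) {
  e <- new_layer(name)
  e$p <- p
  e$fw <- function(x, train = TRUE) {
    if (!train || e$p <= 0) {
      e$cache <- list(mask = NULL)
      return(x)
    }
    mask <- (stats::runif(length(x)) >= e$p) / (1 - e$p)
    dim(mask) <- dim_or_null(x)
    e$cache <- list(mask = mask)
    x * mask
  }
  e$bw <- function(dy) {
    if (is.null(e$cache$mask)) dy else dy * e$cache$mask
  }
  e
}

## ---- dense --------------------------------------------------------------

layer_dense <- function(name, n_in, n_out) {
  e <- new_layer(name)
  e$n_in <- n_in; e$n_out <- n_out
  e$params$W <- uniform_init(c(n_out, n_in), fan_in = n_in)
  e$params$b <- as.numeric(uniform_init(n_out, fan_in = n_in))
  zero_grads(e)
  e$fw <- function(x, train = TRUE) {
    # x: (n_in, N) matrix or (n_in, T, B) array
    d <- dim(x)
    xm <- x; if (length(d) == 3) dim(xm) <- c(d[1], d[2] * d[3])
    y <- e$params$W %*% xm + e$params$b
    e$cache <- list(xm = xm, d = d)
    if (length(d) == 3) dim(y) <- c(e$n_out, d[2], d[3])
    e$out_shape <- dim_or_len(y)
    y
  }
  e$bw <- function(dy) {
    d <- e$cache$d
    dym <- dy; if (length(d) == 3) dim(dym) <- c(e$n_out, d[2] * d[3])
    e$grads$W <- e$grads$W + dym %*% t(e$cache$xm)
    e$grads$b <- e$grads$b + rowSums(dym)
    dx <- t(e$params$W) %*% dym
    if (length(d) == 3) dim(dx) <- d
    dx
  }
  e
}

## ---- layer normalization (per column of (d, N)) -------------------------

layer_layernorm <- function(name, d_model, eps = 1e-5) {
  e <- new_layer(name)
  e$d_model <- d_model; e$eps <- eps
  e$params$gamma <- rep(1, d_model)
  e$params$beta <- rep(0, d_model)
  zero_grads(e)
  e$fw <- function(x, train = TRUE) {
    d <- dim(x); xm <- x; dim(xm) <- c(d[1], prod(d[-1]))
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    istd <- 1 / sqrt(v + e$eps)
    xhat <- sweep(xc, 2, istd, `*`)
    y <- xhat * e$params$gamma + e$params$beta
    e$cache <- list(xhat = xhat, istd = istd, d = d)
    dim(y) <- d
    e$out_shape <- d
    y
  }
  e$bw <- function(dy) {
    d <- e$cache$d
    dym <- dy; dim(dym) <- c(d[1], prod(d[-1]))
    xhat <- e$cache$xhat
    e$grads$gamma <- e$grads$gamma + rowSums(dym * xhat)
    e$grads$beta <- e$grads$beta + rowSums(dym)
    dxhat <- dym * e$params$gamma
    m <- colMeans(dxhat)
    mh <- colMeans(dxhat * xhat)
    dx <- sweep(sweep(dxhat, 2, m) - sweep(xhat, 2, mh, `*`),
                2, e$cache$istd, `*`)
    dim(dx) <- d
    dx
  }
  e
}

## ---- multi-head self-attention ------------------------------------------

layer_mha <- function(name, d_model, n_heads) {
  stopifnot(d_model %% n_heads == 0)
  e <- new_layer(name)
  e$d_model <- d_model; e$h <- n_heads; e$dh <- d_model %/% n_heads
  for (p in c("Wq", "Wk", "Wv", "Wo")) {
    e$params[[p]] <- uniform_init(c(d_model, d_model), fan_in = d_model)
  }
  for (p in c("bq", "bk", "bv", "bo")) {
    e$params[[p]] <- as.numeric(uniform_init(d_model, fan_in = d_model))
  }
  zero_grads(e)
  e$fw <- function(x, train = TRUE) {
    d <- dim(x); TT <- d[2]; B <- d[3]
    xm <- x; dim(xm) <- c(e$d_model, TT * B)
    Q <- e$params$Wq %*% xm + e$params$bq
    K <- e$params$Wk %*% xm + e$params$bk
    V <- e$params$Wv %*% xm + e$params$bv
    dim(Q) <- dim(K) <- dim(V) <- c(e$dh, e$h, TT, B)
    O <- array(0, dim = c(e$dh, e$h, TT, B))
    A <- vector("list", B * e$h)
    sc <- 1 / sqrt(e$dh)
    for (b in seq_len(B)) {
      for (hh in seq_len(e$h)) {
        Qh <- matrix(Q[, hh, , b], e$dh, TT)
        Kh <- matrix(K[, hh, , b], e$dh, TT)
        Vh <- matrix(V[, hh, , b], e$dh, TT)
        S <- crossprod(Qh, Kh) * sc                 # (T_query, T_key)
        S <- S - apply(S, 1, max)
        Aw <- exp(S)
        Aw <- Aw / rowSums(Aw)
        O[, hh, , b] <- Vh %*% t(Aw)
        A[[(b - 1) * e$h + hh]] <- Aw
      }
    }
    Om <- O; dim(Om) <- c(e$d_model, TT * B)
    y <- e$params$Wo %*% Om + e$params$bo
    e$cache <- list(xm = xm, Q = Q, K = K, V = V, A = A, Om = Om,
                    TT = TT, B = B)
    dim(y) <- d
    e$out_shape <- d
    y
  }
  e$bw <- function(dy) {
    TT <- e$cache$TT; B <- e$cache$B
    dym <- dy; dim(dym) <- c(e$d_model, TT * B)
    e$grads$Wo <- e$grads$Wo + dym %*% t(e$cache$Om)
    e$grads$bo <- e$grads$bo + rowSums(dym)
    dOm <- t(e$params$Wo) %*% dym
    dO <- dOm; dim(dO) <- c(e$dh, e$h, TT, B)
    dQ <- array(0, dim = dim(e$cache$Q))
    dK <- array(0, dim = dim(e$cache$K))
    dV <- array(0, dim = dim(e$cache$V))
    sc <- 1 / sqrt(e$dh)
    for (b in seq_len(B)) {
      for (hh in seq_len(e$h)) {
        Aw <- e$cache$A[[(b - 1) * e$h + hh]]
        Qh <- matrix(e$cache$Q[, hh, , b], e$dh, TT)
        Kh <- matrix(e$cache$K[, hh, , b], e$dh, TT)
        Vh <- matrix(e$cache$V[, hh, , b], e$dh, TT)
        dOh <- matrix(dO[, hh, , b], e$dh, TT)
        # O = V %*% t(A): dV = dO %*% A; dA[i, j] = sum_d dO[d, i] V[d, j]
        dV[, hh, , b] <- dOh %*% Aw
        dAw <- crossprod(dOh, Vh)                   # (T_query, T_key)
        rs <- rowSums(dAw * Aw)
        dS <- Aw * (dAw - rs)
        dQ[, hh, , b] <- Kh %*% t(dS) * sc
        dK[, hh, , b] <- Qh %*% dS * sc
      }
    }
    dQm <- dQ; dim(dQm) <- c(e$d_model, TT * B)
    dKm <- dK; dim(dKm) <- c(e$d_model, TT * B)
    dVm <- dV; dim(dVm) <- c(e$d_model, TT * B)
    xm <- e$cache$xm
    e$grads$Wq <- e$grads$Wq + dQm %*% t(xm)
    e$grads$Wk <- e$grads$Wk + dKm %*% t(xm)
    e$grads$Wv <- e$grads$Wv + dVm %*% t(xm)
    e$grads$bq <- e$grads$bq + rowSums(dQm)
    e$grads$bk <- e$grads$bk + rowSums(dKm)
    e$grads$bv <- e$grads$bv + rowSums(dVm)
    dx <- t(e$params$Wq) %*% dQm + t(e$params$Wk) %*% dKm +
      t(e$params$Wv) %*% dVm
    dim(dx) <- c(e$d_model, TT, B)
    dx
  }
  e
}

## ---- LSTM (one direction) ----------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

layer_lstm_dir <- function(name, n_in, hidden, reverse = FALSE) {
  e <- new_layer(name)
  e$n_in <- n_in; e$hidden <- hidden; e$reverse <- reverse
  e$params$W <- uniform_init(c(4 * hidden, n_in), fan_in = hidden)
  e$params$U <- uniform_init(c(4 * hidden, hidden), fan_in = hidden)
  e$params$b <- as.numeric(uniform_init(4 * hidden, fan_in = hidden))
  zero_grads(e)
  e$fw <- function(x, train = TRUE) {
    d <- dim(x); TT <- d[2]; B <- d[3]
    ord <- if (e$reverse) rev(seq_len(TT)) else seq_len(TT)
    H <- array(0, dim = c(e$hidden, TT, B))
    h <- matrix(0, e$hidden, B); cc <- matrix(0, e$hidden, B)
    gates <- vector("list", TT); cs <- vector("list", TT)
    hs <- vector("list", TT)
    hid <- e$hidden
    for (step in seq_len(TT)) {
      t_ <- ord[step]
      xt <- matrix(x[, t_, ], d[1], B)
      a <- e$params$W %*% xt + e$params$U %*% h + e$params$b
      i_ <- sigmoid(a[seq_len(hid), , drop = FALSE])
      f_ <- sigmoid(a[hid + seq_len(hid), , drop = FALSE])
      g_ <- tanh(a[2 * hid + seq_len(hid), , drop = FALSE])
      o_ <- sigmoid(a[3 * hid + seq_len(hid), , drop = FALSE])
      c_prev <- cc
      cc <- f_ * c_prev + i_ * g_
      tc <- tanh(cc)
      h_prev <- h
      h <- o_ * tc
      H[, t_, ] <- h
      gates[[step]] <- list(i = i_, f = f_, g = g_, o = o_, tc = tc,
                            c_prev = c_prev, h_prev = h_prev, xt = xt)
    }
    e$cache <- list(gates = gates, ord = ord, TT = TT, B = B, d = d)
    e$out_shape <- dim(H)
    H
  }
  e$bw <- function(dH) {
    TT <- e$cache$TT; B <- e$cache$B; hid <- e$hidden
    ord <- e$cache$ord
    dx <- array(0, dim = e$cache$d)
    dh_next <- matrix(0, hid, B)
    dc_next <- matrix(0, hid, B)
    for (step in rev(seq_len(TT))) {
      t_ <- ord[step]
      g <- e$cache$gates[[step]]
      dh <- matrix(dH[, t_, ], hid, B) + dh_next
      do_ <- dh * g$tc
      dtc <- dh * g$o
      dc <- dtc * (1 - g$tc^2) + dc_next
      di <- dc * g$g
      dg <- dc * g$i
      df <- dc * g$c_prev
      dc_next <- dc * g$f
      da <- rbind(di * g$i * (1 - g$i),
                  df * g$f * (1 - g$f),
                  dg * (1 - g$g^2),
                  do_ * g$o * (1 - g$o))
      e$grads$W <- e$grads$W + da %*% t(g$xt)
      e$grads$U <- e$grads$U + da %*% t(g$h_prev)
      e$grads$b <- e$grads$b + rowSums(da)
      dh_next <- t(e$params$U) %*% da
      dx[, t_, ] <- dx[, t_, ] + t(e$params$W) %*% da
    }
    dx
  }
  e
}
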