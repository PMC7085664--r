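## Minimal neural-network engine: "same"-padded 5x5 convolutions via
## im2col + BLAS matrix products, 2x2 max pooling, dense layers, ReLU,
## softmax cross-entropy and Adam. Arrays are laid out (H, W, C, B) so a
## per-sample column-major flatten is contiguous.

conv_prep <- function(H, W, C, k = 5L) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  base <- (i - 1L) + (j - 1L) * Hp
  di <- rep(seq_len(k), times = k * C)
  dj <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  off <- di + (dj - 1L) * Hp + (cc - 1L) * Hp * Wp
  list(H = H, W = W, C = C, k = k, p = p, Hp = Hp, Wp = Wp,
       P = H * W, kkC = k * k * C,
       idx = outer(base, off, "+"),
       cache = new.env(parent = emptyenv()))
}

# batch-expanded im2col index matrix, cached per batch size
conv_bigidx <- function(prep, B) {
  key <- as.character(B)
  hit <- prep$cache[[key]]
  if (!is.null(hit)) return(hit)
  offs <- (seq_len(B) - 1L) * (prep$Hp * prep$Wp * prep$C)
  tmp <- outer(as.vector(prep$idx), offs, "+")
  dim(tmp) <- c(prep$P, prep$kkC, B)
  tmp <- aperm(tmp, c(1L, 3L, 2L))
  dim(tmp) <- c(prep$P * B, prep$kkC)
  prep$cache[[key]] <- tmp
  tmp
}

conv_forward <- function(x, Wf, b, prep) {
  B <- dim(x)[4]
  xp <- array(0, c(prep$Hp, prep$Wp, prep$C, B))
  xp[prep$p + seq_len(prep$H), prep$p + seq_len(prep$W), , ] <- x
  bigidx <- conv_bigidx(prep, B)
  colmat <- as.vector(xp)[bigidx]
  dim(colmat) <- dim(bigidx)
  out <- colmat %*% Wf
  out <- sweep(out, 2L, b, "+")
  nf <- length(b)
  y <- array(out, c(prep$P, B, nf))
  y <- aperm(y, c(1L, 3L, 2L))
  dim(y) <- c(prep$H, prep$W, nf, B)
  list(y = y, colmat = colmat, bigidx = bigidx, B = B)
}

conv_backward <- function(dy, Wf, cache, prep, need_dx = TRUE) {
  nf <- ncol(Wf)
  B <- cache$B
  dim(dy) <- c(prep$P, nf, B)
  dym <- aperm(dy, c(1L, 3L, 2L))
  dim(dym) <- c(prep$P * B, nf)
  out <- list(dW = crossprod(cache$colmat, dym), db = colSums(dym), dx = NULL)
  if (need_dx) {
    dcol <- tcrossprod(dym, Wf)
    dxp <- numeric(prep$Hp * prep$Wp * prep$C * B)
    for (q in seq_len(prep$kkC)) {
      ind <- cache$bigidx[, q]
      dxp[ind] <- dxp[ind] + dcol[, q]
    }
    dim(dxp) <- c(prep$Hp, prep$Wp, prep$C, B)
    out$dx <- dxp[prep$p + seq_len(prep$H), prep$p + seq_len(prep$W), , ,
                  drop = FALSE]
  }
  out
}

pool_forward <- function(x) {
  d <- dim(x)
  Ho <- d[1] %/% 2L
  Wo <- d[2] %/% 2L
  ro <- seq(1L, 2L * Ho, 2L)
  co <- seq(1L, 2L * Wo, 2L)
  a <- x[ro, co, , , drop = FALSE]
  b <- x[ro + 1L, co, , , drop = FALSE]
  cc <- x[ro, co + 1L, , , drop = FALSE]
  dd <- x[ro + 1L, co + 1L, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  ma <- a == y
  mb <- (b == y) & !ma
  mc <- (cc == y) & !(ma | mb)
  md <- !(ma | mb | mc)
  list(y = y, masks = list(ma, mb, mc, md), dims = d, Ho = Ho, Wo = Wo)
}

pool_backward <- function(dy, cache) {
  dx <- array(0, cache$dims)
  ro <- seq(1L, 2L * cache$Ho, 2L)
  co <- seq(1L, 2L * cache$Wo, 2L)
  dx[ro, co, , ] <- dy * cache$masks[[1]]
  dx[ro + 1L, co, , ] <- dy * cache$masks[[2]]
  dx[ro, co + 1L, , ] <- dy * cache$masks[[3]]
  dx[ro + 1L, co + 1L, , ] <- dy * cache$masks[[4]]
  dx
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

dense_forward <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

softmax_rows <- function(logits) {
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  ex / rowSums(ex)
}

softmax_ce <- function(logits, y_int) {
  B <- nrow(logits)
  p <- softmax_rows(logits)
  hot <- cbind(seq_len(B), y_int)
  loss <- -mean(log(pmax(p[hot], 1e-12)))
  d <- p
  d[hot] <- d[hot] - 1
  list(loss = loss, dlogits = d / B)
}

zero_like <- function(params) {
  lapply(params, function(layer) lapply(layer, function(v) {
    z <- v
    z[] <- 0
    z
  }))
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (ln in names(params)) {
    for (pn in names(params[[ln]])) {
      g <- grads[[ln]][[pn]]
      state$m[[ln]][[pn]] <- beta1 * state$m[[ln]][[pn]] + (1 - beta1) * g
      state$v[[ln]][[pn]] <- beta2 * state$v[[ln]][[pn]] + (1 - beta2) * g^2
      mh <- state$m[[ln]][[pn]] / bc1
      vh <- state$v[[ln]][[pn]] / bc2
      params[[ln]][[pn]] <- params[[ln]][[pn]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, state = state)
}

n_params <- function(params) {
  sum(vapply(params, function(l) sum(vapply(l, length, integer(1))),
             integer(1)))
}
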