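# Neural-network primitives for the dual adversarial autoencoder: dense and
# GRU layers with analytic backprop, Adam updates, and a two-hidden-layer
# feed-forward critic. Everything is plain base-R matrix code; batches are
# rows.

sigm <- function(x) 1 / (1 + exp(-x))

init_mat <- function(nr, nc, scale = 0.08) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

gru_params <- function(d_in, h) {
  list(Wz = init_mat(d_in, h), Uz = init_mat(h, h), bz = numeric(h),
       Wr = init_mat(d_in, h), Ur = init_mat(h, h), br = numeric(h),
       Wh = init_mat(d_in, h), Uh = init_mat(h, h), bh = numeric(h))
}

# forward one GRU over a list of input matrices xs (each n x d_in) with a
# mask matrix (n x L); masked steps carry the previous hidden state
gru_forward <- function(p, xs, mask, h0 = NULL) {
  n <- nrow(xs[[1]]); H <- ncol(p$Uz); L <- length(xs)
  h_prev <- if (is.null(h0)) matrix(0, n, H) else h0
  cache <- vector("list", L)
  hs <- vector("list", L)
  for (t in seq_len(L)) {
    x <- xs[[t]]
    z <- sigm(x %*% p$Wz + h_prev %*% p$Uz + rep(p$bz, each = n))
    r <- sigm(x %*% p$Wr + h_prev %*% p$Ur + rep(p$br, each = n))
    hc <- tanh(x %*% p$Wh + (r * h_prev) %*% p$Uh + rep(p$bh, each = n))
    h <- (1 - z) * h_prev + z * hc
    m <- mask[, t]
    h <- m * h + (1 - m) * h_prev
    cache[[t]] <- list(x = x, h_prev = h_prev, z = z, r = r, hc = hc, m = m)
    hs[[t]] <- h
    h_prev <- h
  }
  list(hs = hs, h_last = h_prev, cache = cache)
}

# backward through the GRU. dhs: list of per-step upstream grads (or NULL),
# dh_last: grad wrt the final hidden state. Returns param grads, per-step
# input grads, and grad wrt h0.
gru_backward <- function(p, fw, dhs = NULL, dh_last = NULL) {
  L <- length(fw$cache)
  n <- nrow(fw$cache[[1]]$x)
  H <- ncol(p$Uz)
  g <- lapply(p, function(m) m * 0)
  dxs <- vector("list", L)
  dh <- if (is.null(dh_last)) matrix(0, n, H) else dh_last
  for (t in rev(seq_len(L))) {
    if (!is.null(dhs) && !is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    cc <- fw$cache[[t]]
    m <- cc$m
    dh_step <- dh * m                     # grads only where the step was live
    dh_skip <- dh * (1 - m)               # carried straight to h_{t-1}
    dz <- dh_step * (cc$hc - cc$h_prev) * cc$z * (1 - cc$z)
    dhc_pre <- dh_step * cc$z * (1 - cc$hc^2)
    drh <- dhc_pre %*% t(p$Uh)
    dr <- drh * cc$h_prev * cc$r * (1 - cc$r)
    dh_prev <- dh_step * (1 - cc$z) + dz %*% t(p$Uz) + dr %*% t(p$Ur) +
      drh * cc$r + dh_skip
    g$Wz <- g$Wz + crossprod(cc$x, dz); g$Uz <- g$Uz + crossprod(cc$h_prev, dz)
    g$bz <- g$bz + colSums(dz)
    g$Wr <- g$Wr + crossprod(cc$x, dr); g$Ur <- g$Ur + crossprod(cc$h_prev, dr)
    g$br <- g$br + colSums(dr)
    g$Wh <- g$Wh + crossprod(cc$x, dhc_pre)
    g$Uh <- g$Uh + crossprod(cc$r * cc$h_prev, dhc_pre)
    g$bh <- g$bh + colSums(dhc_pre)
    dxs[[t]] <- (dz %*% t(p$Wz) + dr %*% t(p$Wr) + dhc_pre %*% t(p$Wh)) * m
    dh <- dh_prev
  }
  list(grads = g, dxs = dxs, dh0 = dh)
}

mlp_params <- function(d_in, h) {
  list(W1 = init_mat(d_in, h), b1 = numeric(h),
       W2 = init_mat(h, h), b2 = numeric(h),
       W3 = init_mat(h, 1), b3 = numeric(1))
}

# two-hidden-layer feed-forward critic, ReLU activations, sigmoid output
mlp_forward <- function(p, x) {
  n <- nrow(x)
  a1 <- pmax(x %*% p$W1 + rep(p$b1, each = n), 0)
  a2 <- pmax(a1 %*% p$W2 + rep(p$b2, each = n), 0)
  out <- sigm(a2 %*% p$W3 + rep(p$b3, each = n))
  list(out = out, a1 = a1, a2 = a2, x = x)
}

# backward from d(pre-sigmoid logit); returns param grads and input grad
mlp_backward <- function(p, fw, dlogit) {
  g <- list()
  g$W3 <- crossprod(fw$a2, dlogit); g$b3 <- colSums(dlogit)
  da2 <- (dlogit %*% t(p$W3)) * (fw$a2 > 0)
  g$W2 <- crossprod(fw$a1, da2); g$b2 <- colSums(da2)
  da1 <- (da2 %*% t(p$W2)) * (fw$a1 > 0)
  g$W1 <- crossprod(fw$x, da1); g$b1 <- colSums(da1)
  dx <- da1 %*% t(p$W1)
  list(grads = g, dx = dx)
}

adam_state <- function(params) {
  lapply(params, function(grp) lapply(grp, function(m)
    list(m = m * 0, v = m * 0)))
}

# one Adam update of a parameter group; returns list(params, state)
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * grads[[nm]]
    st$v <- beta2 * st$v + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

global_norm <- function(grads_nested) {
  sqrt(sum(vapply(grads_nested, function(grp)
    sum(vapply(grp, function(m) sum(m^2), 0.0)), 0.0)))
}

scale_grads <- function(grads_nested, s) {
  lapply(grads_nested, function(grp) lapply(grp, function(m) m * s))
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (gn in names(b)) for (nm in names(b[[gn]]))
    a[[gn]][[nm]] <- a[[gn]][[nm]] + b[[gn]][[nm]]
  a
}
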