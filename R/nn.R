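# Minimal neural-network engine for the flexibility models: 1D convolutions
# (kernel 3, padding 1, stride 1), ReLU, additive attention pooling, gated
# recurrent units, dense heads, hand-written backpropagation and Adam.
# Activations for a batch of B length-L single/multi-channel signals are
# stored as (B*L) x C matrices with row index r = (b-1)*L + l.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_rand <- function(n, sd) stats::rnorm(n, sd = sd)

# uniform init on (-1/sqrt(fan_in), 1/sqrt(fan_in)), robust to inputs whose
# components carry large fixed offsets
nn_unif <- function(n, fan_in) stats::runif(n, -1, 1) / sqrt(fan_in)

# --- conv1d ----------------------------------------------------------------

conv1d_init <- function(c_in, c_out) {
  list(W = matrix(nn_unif(3 * c_in * c_out, 3 * c_in), 3 * c_in, c_out),
       b = nn_unif(c_out, 3 * c_in))
}

# index maps for kernel-3 shifts within each length-L block (rows of a
# zero-padded matrix rbind(0, H): entry 1 is the zero row, entry k+1 is row k)
conv1d_maps <- function(B, L) {
  l <- rep(seq_len(L), B)
  r <- seq_len(B * L)
  list(prev = ifelse(l == 1L, 1L, r),          # H[r-1] lives at Xz[r]
       nxt  = ifelse(l == L, 1L, r + 2L),
       l = l)
}

conv1d_forward <- function(layer, H, maps) {
  Hz <- rbind(0, H)
  col <- cbind(Hz[maps$prev, , drop = FALSE], H, Hz[maps$nxt, , drop = FALSE])
  out <- col %*% layer$W
  out <- sweep(out, 2, layer$b, `+`)
  list(out = out, col = col)
}

conv1d_backward <- function(layer, cache, dOut, maps) {
  dW <- crossprod(cache$col, dOut)
  db <- colSums(dOut)
  dcol <- dOut %*% t(layer$W)
  C <- ncol(dcol) / 3
  dprev <- dcol[, seq_len(C), drop = FALSE]
  dmid <- dcol[, C + seq_len(C), drop = FALSE]
  dnxt <- dcol[, 2 * C + seq_len(C), drop = FALSE]
  dH <- dmid
  up <- maps$l > 1L            # dprev[r] feeds H[r-1]
  dH[which(up) - 1L, ] <- dH[which(up) - 1L, , drop = FALSE] + dprev[up, , drop = FALSE]
  L <- max(maps$l)
  dn <- maps$l < L             # dnxt[r] feeds H[r+1]
  dH[which(dn) + 1L, ] <- dH[which(dn) + 1L, , drop = FALSE] + dnxt[dn, , drop = FALSE]
  list(dW = dW, db = db, dH = dH)
}

# --- attention / pooling ---------------------------------------------------

attention_init <- function(c_feat, attn_dim) {
  list(Wa = matrix(nn_unif(c_feat * attn_dim, c_feat), c_feat, attn_dim),
       ba = numeric(attn_dim),
       va = nn_unif(attn_dim, attn_dim))
}

attention_forward <- function(layer, H, B, L) {
  pre <- tanh(sweep(H %*% layer$Wa, 2, layer$ba, `+`))   # (B*L) x A
  sc <- as.vector(pre %*% layer$va)
  S <- matrix(sc, L, B)
  S <- sweep(S, 2, apply(S, 2, max))
  E <- exp(S)
  alpha <- sweep(E, 2, colSums(E), `/`)                  # L x B
  av <- as.vector(alpha)
  groups <- rep(seq_len(B), each = L)
  context <- rowsum(H * av, groups, reorder = TRUE)      # B x C
  list(context = context, alpha = alpha, pre = pre, H = H)
}

attention_backward <- function(layer, cache, dcontext, B, L) {
  av <- as.vector(cache$alpha)
  dctx_big <- dcontext[rep(seq_len(B), each = L), , drop = FALSE]
  dH <- dctx_big * av
  dalpha <- matrix(rowSums(cache$H * dctx_big), L, B)
  # softmax backward per column
  dS <- cache$alpha * sweep(dalpha, 2, colSums(cache$alpha * dalpha))
  dsc <- as.vector(dS)
  dva <- as.vector(crossprod(cache$pre, dsc))
  dpre <- outer(dsc, layer$va) * (1 - cache$pre^2)
  dWa <- crossprod(cache$H, dpre)
  dba <- colSums(dpre)
  dH <- dH + dpre %*% t(layer$Wa)
  list(dWa = dWa, dba = dba, dva = dva, dH = dH)
}

meanpool_forward <- function(H, B, L) {
  groups <- rep(seq_len(B), each = L)
  rowsum(H, groups, reorder = TRUE) / L
}

# --- GRU -------------------------------------------------------------------

gru_init <- function(hidden) {
  list(wz = nn_unif(hidden, hidden), wr = nn_unif(hidden, hidden),
       wh = nn_unif(hidden, hidden),
       Uz = matrix(nn_unif(hidden^2, hidden), hidden, hidden),
       Ur = matrix(nn_unif(hidden^2, hidden), hidden, hidden),
       Uh = matrix(nn_unif(hidden^2, hidden), hidden, hidden),
       bz = nn_unif(hidden, hidden), br = nn_unif(hidden, hidden),
       bh = nn_unif(hidden, hidden))
}

gru_forward <- function(layer, X) {          # X: B x L (scalar sequence)
  B <- nrow(X); L <- ncol(X); Hd <- length(layer$bz)
  h <- matrix(0, B, Hd)
  steps <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- X[, t]
    z <- sigmoid(outer(xt, layer$wz) + h %*% layer$Uz +
                   matrix(layer$bz, B, Hd, byrow = TRUE))
    r <- sigmoid(outer(xt, layer$wr) + h %*% layer$Ur +
                   matrix(layer$br, B, Hd, byrow = TRUE))
    hh <- tanh(outer(xt, layer$wh) + (r * h) %*% layer$Uh +
                 matrix(layer$bh, B, Hd, byrow = TRUE))
    hn <- (1 - z) * h + z * hh
    steps[[t]] <- list(x = xt, hprev = h, z = z, r = r, hh = hh)
    h <- hn
  }
  list(h = h, steps = steps)
}

gru_backward <- function(layer, cache, dh_last, X) {
  B <- nrow(X); L <- ncol(X)
  g <- lapply(layer, function(p) p * 0)
  dh <- dh_last
  dX <- matrix(0, B, L)
  for (t in rev(seq_len(L))) {
    st <- cache$steps[[t]]
    z <- st$z; r <- st$r; hh <- st$hh; hprev <- st$hprev
    dz <- dh * (hh - hprev) * z * (1 - z)
    dhh <- dh * z * (1 - hh^2)
    dhprev <- dh * (1 - z)
    # hh = tanh(x wh + (r*hprev) Uh + bh)
    g$wh <- g$wh + as.vector(crossprod(dhh, st$x))
    g$Uh <- g$Uh + crossprod(r * hprev, dhh)
    g$bh <- g$bh + colSums(dhh)
    drh <- dhh %*% t(layer$Uh)
    dr <- drh * hprev * r * (1 - r)
    dhprev <- dhprev + drh * r
    g$wz <- g$wz + as.vector(crossprod(dz, st$x))
    g$Uz <- g$Uz + crossprod(hprev, dz)
    g$bz <- g$bz + colSums(dz)
    dhprev <- dhprev + dz %*% t(layer$Uz)
    g$wr <- g$wr + as.vector(crossprod(dr, st$x))
    g$Ur <- g$Ur + crossprod(hprev, dr)
    g$br <- g$br + colSums(dr)
    dhprev <- dhprev + dr %*% t(layer$Ur)
    dX[, t] <- as.vector(dz %*% layer$wz) + as.vector(dr %*% layer$wr) +
      as.vector(dhh %*% layer$wh)
    dh <- dhprev
  }
  list(grads = g, dX = dX)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  flat <- rapply(params, function(p) p * 0, how = "replace")
  list(m = flat, v = flat, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    g <- g + weight_decay * p                     # L2 coupled into the gradient
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(rec, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else walk(p, g, m, v)
  }
  out <- rec(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
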