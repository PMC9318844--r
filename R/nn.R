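# Minimal CNN engine: batched conv / pool / bilinear-pool layers with exact
# reverse-mode gradients and an Adam optimizer.
#
# Activations are 4-D arrays dim (H, W, C, N). Convolutions are computed as
# im2col + BLAS matrix products; kernels are stored as K x Cout matrices with
# K = kh*kw*Cin flattened column-major (kernel row fastest), matching the
# patch extraction order below.

# ---- im2col ----------------------------------------------------------------

# Linear patch indices into a padded (Hp, Wp, C) volume.
# Returns a (P x K) matrix, P = OH*OW output positions (column-major),
# K = kh*kw*C patch entries (kernel row fastest, then kernel col, then channel).
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(Hp, Wp, C, kh, kw, sh, sw) {
  key <- paste(Hp, Wp, C, kh, kw, sh, sw, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  OH <- (Hp - kh) %/% sh + 1
  OW <- (Wp - kw) %/% sw + 1
  pos_r <- rep((0:(OH - 1)) * sh, times = OW)
  pos_c <- rep((0:(OW - 1)) * sw, each = OH)
  off_a <- rep(1:kh, times = kw * C)
  off_b <- rep(rep(1:kw, each = kh), times = C)
  off_ch <- rep(1:C, each = kh * kw)
  M <- outer(pos_c * Hp + pos_r,
             (off_ch - 1) * Hp * Wp + (off_b - 1) * Hp + off_a, "+")
  storage.mode(M) <- "integer"
  res <- list(M = M, OH = OH, OW = OW)
  .im2col_cache[[key]] <- res
  res
}

pad_batch <- function(x, ph, pw, value = 0) {
  d <- dim(x)
  if (ph == 0 && pw == 0) return(x)
  out <- array(value, c(d[1] + 2 * ph, d[2] + 2 * pw, d[3], d[4]))
  out[ph + seq_len(d[1]), pw + seq_len(d[2]), , ] <- x
  out
}

# Patch matrix for the whole batch: ((P*N) x K), rows ordered position-fastest
# within each image. Also returns the batched index array used for scatter.
im2col <- function(xp, kh, kw, sh, sw) {
  d <- dim(xp)
  ix <- im2col_index(d[1], d[2], d[3], kh, kw, sh, sw)
  P <- nrow(ix$M); K <- ncol(ix$M); N <- d[4]
  akey <- paste(d[1], d[2], d[3], kh, kw, sh, sw, N, sep = "_")
  arr <- .im2col_cache[[akey]]
  if (is.null(arr)) {
    offs <- as.integer((seq_len(N) - 1) * prod(d[1:3]))
    arr <- array(outer(as.vector(ix$M), offs, "+"), c(P, K, N))
    .im2col_cache[[akey]] <- arr
  }
  vals <- array(xp[arr], c(P, K, N))
  Xc <- matrix(aperm(vals, c(1, 3, 2)), P * N, K)
  list(Xc = Xc, arr = arr, OH = ix$OH, OW = ix$OW, P = P, K = K, N = N,
       pdim = d)
}

# Scatter-add patch gradients back to the padded input volume.
# dXc: ((P*N) x K) with the same row ordering as im2col()$Xc.
col2im <- function(dXc, info) {
  dxp <- numeric(prod(info$pdim))
  PN <- info$P * info$N
  for (k in seq_len(info$K)) {
    idx <- info$arr[, k, ]                 # P x N, unique within a column
    dxp[idx] <- dxp[idx] + dXc[, k]
  }
  array(dxp, info$pdim)
}

# ---- layers ----------------------------------------------------------------

layer_conv <- function(cin, cout, k, stride = 1, pad = (k - 1) %/% 2,
                       init_sd = NULL) {
  K <- k * k * cin
  sd <- init_sd %||% sqrt(2 / K)
  list(type = "conv", k = k, stride = stride, pad = pad, cin = cin, cout = cout,
       params = list(W = matrix(stats::rnorm(K * cout, sd = sd), K, cout),
                     b = numeric(cout)))
}

conv_forward <- function(layer, x) {
  xp <- pad_batch(x, layer$pad, layer$pad)
  info <- im2col(xp, layer$k, layer$k, layer$stride, layer$stride)
  y <- info$Xc %*% layer$params$W
  y <- sweep(y, 2, layer$params$b, "+")
  out <- aperm(array(y, c(info$OH, info$OW, info$N, layer$cout)), c(1, 2, 4, 3))
  list(out = out, cache = info)
}

conv_backward <- function(layer, dy, cache) {
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), cache$P * cache$N, layer$cout)
  dW <- crossprod(cache$Xc, dym)
  db <- colSums(dym)
  dXc <- dym %*% t(layer$params$W)
  dxp <- col2im(dXc, cache)
  p <- layer$pad
  dx <- if (p > 0) {
    d <- dim(dxp)
    dxp[p + seq_len(d[1] - 2 * p), p + seq_len(d[2] - 2 * p), , , drop = FALSE]
  } else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

layer_relu <- function() list(type = "relu", params = list())

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

layer_maxpool <- function(k = 3, stride = 2, pad = 1)
  list(type = "maxpool", k = k, stride = stride, pad = pad, params = list())

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  xr <- array(x, c(d[1], d[2], 1, d[3] * d[4]))
  xp <- pad_batch(xr, layer$pad, layer$pad, value = -Inf)
  info <- im2col(xp, layer$k, layer$k, layer$stride, layer$stride)
  vals <- info$Xc
  sel <- max.col(vals, ties.method = "first")
  mx <- vals[cbind(seq_along(sel), sel)]
  out <- array(matrix(mx, info$P, info$N), c(info$OH, info$OW, d[3], d[4]))
  list(out = out, cache = list(info = info, sel = sel, din = d))
}

maxpool_backward <- function(layer, dy, cache) {
  info <- cache$info
  dxp <- numeric(prod(info$pdim))
  selm <- matrix(cache$sel, info$P, info$N)
  dyv <- matrix(as.vector(dy), info$P, info$N)
  for (k in seq_len(info$K)) {
    # within one patch offset, source positions are unique across (p, image)
    hit <- selm == k
    if (!any(hit)) next
    idx <- info$arr[, k, ][hit]
    dxp[idx] <- dxp[idx] + dyv[hit]
  }
  dxp <- array(dxp, info$pdim)
  p <- layer$pad
  d <- cache$din
  core <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), 1, , drop = FALSE]
  array(core, d)
}

# Inception module: four parallel branches concatenated channel-wise.
#   b1: 1x1 conv;  b2: 1x1 reduce then 3x3;  b3: 1x1 reduce then 5x5;
#   b4: 3x3 maxpool (stride 1) then 1x1 projection. ReLU after every conv.
layer_inception <- function(cin, spec) {
  list(type = "inception", cin = cin,
       cout = spec$b1 + spec$b2 + spec$b3 + spec$b4,
       spec = spec,
       params = list(
         b1  = layer_conv(cin, spec$b1, 1)$params,
         b2r = layer_conv(cin, spec$b2_reduce, 1)$params,
         b2  = layer_conv(spec$b2_reduce, spec$b2, 3)$params,
         b3r = layer_conv(cin, spec$b3_reduce, 1)$params,
         b3  = layer_conv(spec$b3_reduce, spec$b3, 5)$params,
         b4  = layer_conv(cin, spec$b4, 1)$params))
}

# wrap a params list as a conv layer view for reuse of conv_forward/backward
.conv_view <- function(params, cin, cout, k)
  list(type = "conv", k = k, stride = 1, pad = (k - 1) %/% 2,
       cin = cin, cout = cout, params = params)

inception_forward <- function(layer, x) {
  s <- layer$spec; cin <- layer$cin
  f1 <- conv_forward(.conv_view(layer$params$b1, cin, s$b1, 1), x)
  r1 <- relu_forward(f1$out)
  f2r <- conv_forward(.conv_view(layer$params$b2r, cin, s$b2_reduce, 1), x)
  r2r <- relu_forward(f2r$out)
  f2 <- conv_forward(.conv_view(layer$params$b2, s$b2_reduce, s$b2, 3), r2r$out)
  r2 <- relu_forward(f2$out)
  f3r <- conv_forward(.conv_view(layer$params$b3r, cin, s$b3_reduce, 1), x)
  r3r <- relu_forward(f3r$out)
  f3 <- conv_forward(.conv_view(layer$params$b3, s$b3_reduce, s$b3, 5), r3r$out)
  r3 <- relu_forward(f3$out)
  pl <- layer_maxpool(3, 1, 1)
  f4p <- maxpool_forward(pl, x)
  f4 <- conv_forward(.conv_view(layer$params$b4, cin, s$b4, 1), f4p$out)
  r4 <- relu_forward(f4$out)
  d <- dim(x)
  out <- array(0, c(dim(r1$out)[1], dim(r1$out)[2], layer$cout, d[4]))
  ch <- cumsum(c(0, s$b1, s$b2, s$b3, s$b4))
  out[, , (ch[1] + 1):ch[2], ] <- r1$out
  out[, , (ch[2] + 1):ch[3], ] <- r2$out
  out[, , (ch[3] + 1):ch[4], ] <- r3$out
  out[, , (ch[4] + 1):ch[5], ] <- r4$out
  list(out = out,
       cache = list(f1 = f1, r1 = r1, f2r = f2r, r2r = r2r, f2 = f2, r2 = r2,
                    f3r = f3r, r3r = r3r, f3 = f3, r3 = r3, f4p = f4p,
                    f4 = f4, r4 = r4, ch = ch, pl = pl))
}

inception_backward <- function(layer, dy, cache) {
  s <- layer$spec; cin <- layer$cin; ch <- cache$ch
  d1 <- dy[, , (ch[1] + 1):ch[2], , drop = FALSE]
  d2 <- dy[, , (ch[2] + 1):ch[3], , drop = FALSE]
  d3 <- dy[, , (ch[3] + 1):ch[4], , drop = FALSE]
  d4 <- dy[, , (ch[4] + 1):ch[5], , drop = FALSE]
  g <- list()
  bb <- conv_backward(.conv_view(layer$params$b1, cin, s$b1, 1),
                      relu_backward(d1, cache$r1$cache), cache$f1$cache)
  dx <- bb$dx; g$b1 <- bb$grads
  bb <- conv_backward(.conv_view(layer$params$b2, s$b2_reduce, s$b2, 3),
                      relu_backward(d2, cache$r2$cache), cache$f2$cache)
  g$b2 <- bb$grads
  bb2 <- conv_backward(.conv_view(layer$params$b2r, cin, s$b2_reduce, 1),
                       relu_backward(bb$dx, cache$r2r$cache), cache$f2r$cache)
  dx <- dx + bb2$dx; g$b2r <- bb2$grads
  bb <- conv_backward(.conv_view(layer$params$b3, s$b3_reduce, s$b3, 5),
                      relu_backward(d3, cache$r3$cache), cache$f3$cache)
  g$b3 <- bb$grads
  bb2 <- conv_backward(.conv_view(layer$params$b3r, cin, s$b3_reduce, 1),
                       relu_backward(bb$dx, cache$r3r$cache), cache$f3r$cache)
  dx <- dx + bb2$dx; g$b3r <- bb2$grads
  bb <- conv_backward(.conv_view(layer$params$b4, cin, s$b4, 1),
                      relu_backward(d4, cache$r4$cache), cache$f4$cache)
  g$b4 <- bb$grads
  dx <- dx + maxpool_backward(cache$pl, bb$dx, cache$f4p$cache)
  list(dx = dx, grads = g)
}

layer_bilinear <- function(signed_sqrt = TRUE, l2 = TRUE)
  list(type = "bilinear", signed_sqrt = signed_sqrt, l2 = l2, params = list())

#' Bilinear pooling of a convolutional feature map
#'
#' Pools second-order channel statistics: the outer product of the channel
#' feature vector with itself, averaged over all spatial locations, flattened
#' to length `C^2`. Optional signed square root (`x -> sign(x) sqrt(|x|)`)
#' and L2 normalization stabilize the features. The result is invariant to
#' any permutation of the spatial locations.
#'
#' @param fmap feature map: an `H x W x C` array, or a `S x C` matrix of `S`
#'   locations.
#' @param signed_sqrt apply the signed square root.
#' @param l2 scale to unit Euclidean norm (zero vectors stay zero).
#' @return numeric vector of length `C^2` (column-major flattening of the
#'   `C x C` pooled matrix).
#' @export
bilinear_pool <- function(fmap, signed_sqrt = TRUE, l2 = TRUE) {
  Fm <- if (length(dim(fmap)) == 3)
    matrix(fmap, prod(dim(fmap)[1:2]), dim(fmap)[3])
  else as.matrix(fmap)
  if (nrow(Fm) < 1 || ncol(Fm) < 1) stop("empty feature map")
  B <- crossprod(Fm) / nrow(Fm)
  v <- as.vector(B)
  if (signed_sqrt) v <- sign(v) * sqrt(abs(v))
  if (l2) {
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  v
}

bilinear_forward <- function(layer, x) {
  d <- dim(x)
  S <- d[1] * d[2]; C <- d[3]; N <- d[4]
  Fs <- array(x, c(S, C, N))
  out <- matrix(0, C * C, N)
  cache <- list(Fs = Fs, S = S, C = C, v = matrix(0, C * C, N),
                s = matrix(0, C * C, N), nrm = numeric(N), din = d)
  for (n in seq_len(N)) {
    B <- crossprod(Fs[, , n]) / S
    v <- as.vector(B)
    s <- if (layer$signed_sqrt) sign(v) * sqrt(abs(v)) else v
    nrm <- sqrt(sum(s^2))
    u <- if (layer$l2 && nrm > 0) s / nrm else s
    out[, n] <- u
    cache$v[, n] <- v; cache$s[, n] <- s; cache$nrm[n] <- nrm
  }
  list(out = out, cache = cache)
}

bilinear_backward <- function(layer, dy, cache) {
  C <- cache$C; S <- cache$S; d <- cache$din
  dx <- array(0, d)
  dxm <- array(dx, c(S, C, d[4]))
  for (n in seq_len(d[4])) {
    du <- dy[, n]
    s <- cache$s[, n]; nrm <- cache$nrm[n]
    ds <- if (layer$l2 && nrm > 0) {
      u <- s / nrm
      (du - u * sum(u * du)) / nrm
    } else du
    dv <- if (layer$signed_sqrt) {
      ds * 0.5 / pmax(sqrt(abs(cache$v[, n])), 1e-8)
    } else ds
    dB <- matrix(dv, C, C)
    dF <- cache$Fs[, , n] %*% (dB + t(dB)) / S
    dxm[, , n] <- dF
  }
  array(dxm, d)
}

layer_linear <- function(din, dout, init_sd = NULL) {
  sd <- init_sd %||% sqrt(2 / din)
  list(type = "linear", din = din, dout = dout,
       params = list(W = matrix(stats::rnorm(din * dout, sd = sd), din, dout),
                     b = numeric(dout)))
}

linear_forward <- function(layer, x) {
  # x: din x N
  y <- crossprod(layer$params$W, x) + layer$params$b
  list(out = y, cache = x)
}

linear_backward <- function(layer, dy, cache) {
  list(dx = layer$params$W %*% dy,
       grads = list(W = cache %*% t(dy), b = rowSums(dy)))
}

softmax <- function(scores) {
  z <- sweep(scores, 2, apply(scores, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# cross-entropy loss and gradient wrt scores; y: integer class labels 1..nc
softmax_xent <- function(scores, y) {
  p <- softmax(scores)
  N <- ncol(p)
  idx <- cbind(y, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dscores <- p
  dscores[idx] <- dscores[idx] - 1
  list(loss = loss, dscores = dscores / N, probs = p)
}

# ---- parameter tree walking ------------------------------------------------

# Apply f(param, path) to every numeric leaf of a params tree.
walk_params <- function(params, f, path = character(0)) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p)) params[[nm]] <- walk_params(p, f, c(path, nm))
    else params[[nm]] <- f(p, c(path, nm))
  }
  params
}

# Elementwise combine two congruent params trees.
map2_params <- function(a, b, f) {
  for (nm in names(a)) {
    if (is.list(a[[nm]])) a[[nm]] <- map2_params(a[[nm]], b[[nm]], f)
    else a[[nm]] <- f(a[[nm]], b[[nm]])
  }
  a
}

zero_like <- function(params) walk_params(params, function(p, path) p * 0)

count_params <- function(params) {
  n <- 0
  walk_params(params, function(p, path) { n <<- n + length(p); p })
  n
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params)
  list(m = zero_like(params), v = zero_like(params), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
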