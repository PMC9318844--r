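# Internal numeric and RNG helpers shared across the package.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (the convention used by the
#' field tables this package reproduces), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a over raw bytes; small stable hash for config identity and seed mixing.
fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in int range
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h)
}

#' Derive a stage seed from a global seed and a tag
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from one global seed plus a stage label, so that re-running any stage in
#' isolation reproduces the run.
#'
#' @param seed integer global seed.
#' @param tag character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  h <- fnv1a32(utf8ToInt(as.character(tag)))
  as.integer((abs(as.numeric(seed)) * 69069 + h) %% 2147483645 + 1)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Bilinear sampling of matrix `m` at fractional (row, col) coordinates.
# Coordinates are clamped to the matrix extent.
bilinear_sample <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- clamp(r, 1, H); c <- clamp(c, 1, W)
  r0 <- pmin(floor(r), H - 1L); r0[H == 1] <- 1
  c0 <- pmin(floor(c), W - 1L); c0[W == 1] <- 1
  if (H == 1) r0 <- rep(1, length(r))
  if (W == 1) c0 <- rep(1, length(c))
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc +
    m[cbind(r1, c1)] * fr * fc
}

# Corner-aligned bilinear resize: output corners sample input corners exactly.
resize_bilinear <- function(m, out_h, out_w) {
  H <- nrow(m); W <- ncol(m)
  rows <- if (out_h == 1) rep((1 + H) / 2, 1) else seq(1, H, length.out = out_h)
  cols <- if (out_w == 1) rep((1 + W) / 2, 1) else seq(1, W, length.out = out_w)
  rr <- rep(rows, times = out_w)
  cc <- rep(cols, each = out_h)
  matrix(bilinear_sample(m, rr, cc), out_h, out_w)
}

# Reflection-padded index sequence for an axis of length n (no edge repeat).
reflect_index <- function(n, pad) {
  pos <- seq(1 - pad, n + pad)
  while (any(pos < 1 | pos > n)) {
    pos <- ifelse(pos < 1, 2 - pos, pos)
    pos <- ifelse(pos > n, 2 * n - pos, pos)
  }
  pos
}

`%||%` <- function(a, b) if (is.null(a)) b else a
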