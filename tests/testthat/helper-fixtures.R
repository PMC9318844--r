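# Shared fixtures. Heavy trained models are built once per test run and
# memoized here; every builder is fully seeded.

.fixtures <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a tiny untrained model for shape/determinism checks (fast to build)
tiny_glnb <- function() memo("tiny", function() {
  build_glnb(glnb_config(input_size = c(32, 32), n_modules = 2,
                         width_factor = 0.05, pool_after = 1), seed = 7)
})

# small seeded mixed dataset (4 species x 2 x 2 = 16 scenes, 96x96)
small_dataset <- function() memo("small_ds", function() {
  generate_dataset(2, shape = c(96, 96), seed = 401,
                   radius_range = c(20, 30))
})

# trained desk-scale localizer shared by localization tests and acceptance
localizer_model <- function() memo("localizer", function() {
  train_localizer(seed = 1)$model
})

# a rasterized disk mask
disk_mask <- function(shape, center, radius) {
  rr <- outer(seq_len(shape[1]) - center[1], rep(1, shape[2]))
  cc <- outer(rep(1, shape[1]), seq_len(shape[2]) - center[2])
  sqrt(rr^2 + cc^2) <= radius
}

# brute-force local-median despike oracle (replicated-edge padding)
brute_despike <- function(x, window, k) {
  H <- nrow(x); W <- ncol(x); p <- (window - 1) / 2
  out <- x
  for (i in seq_len(H)) for (j in seq_len(W)) {
    nb <- x[pmin(pmax(seq(i - p, i + p), 1), H),
            pmin(pmax(seq(j - p, j + p), 1), W)]
    med <- median(nb)
    mad_ <- 1.4826 * median(abs(nb - med))
    if (abs(x[i, j] - med) > max(k * mad_, 1e-9)) out[i, j] <- med
  }
  out
}

# brute-force bilinear pooling: explicit double loop over channel pairs
brute_bilinear <- function(fmap, signed_sqrt = TRUE, l2 = TRUE) {
  S <- prod(dim(fmap)[1:2]); C <- dim(fmap)[3]
  Fm <- matrix(fmap, S, C)
  B <- matrix(0, C, C)
  for (a in seq_len(C)) for (b in seq_len(C))
    B[a, b] <- mean(Fm[, a] * Fm[, b])
  v <- as.vector(B)
  if (signed_sqrt) v <- sign(v) * sqrt(abs(v))
  if (l2 && sqrt(sum(v^2)) > 0) v <- v / sqrt(sum(v^2))
  v
}
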