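# Grad-CAM: neuron weights, map arithmetic, gradient oracles, upsampling.

test_that("neuron weights are the spatial mean of the gradients", {
  g0 <- array(0, c(3, 3, 2))
  expect_equal(neuron_weights(g0), c(0, 0))
  gc_ <- array(1.7, c(4, 5, 3))
  expect_equal(neuron_weights(gc_), rep(1.7, 3))
  g <- array(c(1, 3, 2, 4), c(2, 2, 1))  # [[1,2],[3,4]] row-major
  expect_equal(neuron_weights(g), 2.5)
  expect_error(neuron_weights(array(0, c(0, 2, 1))), "non-empty")
})

test_that("the raw map is the ReLU of the alpha-weighted channel sum", {
  # single channel, alpha = 1: map [[1,-1],[2,0]] -> [[1,0],[2,0]]
  A <- matrix(c(1, 2, -1, 0), 2, 2)
  expect_equal(pmax(1 * A, 0), matrix(c(1, 2, 0, 0), 2, 2))
})

test_that("computed CAM matches finite differences and the head closed form", {
  m <- build_glnb(glnb_config(input_size = c(24, 24), n_modules = 1,
                              width_factor = 0.05, pool_after = integer(0),
                              signed_sqrt = FALSE, l2 = FALSE), seed = 71)
  set.seed(72)
  x <- array(runif(24 * 24 * 3), c(24, 24, 3))
  for (cls in 1:2) {
    cam <- compute_cam(m, x, class = cls)
    A <- cam$activations
    d <- dim(A); S <- d[1] * d[2]; C <- d[3]

    # independent head: score_c(A) recomputed from raw parameters
    W <- m$layers[[length(m$layers)]]$l$params$W
    b <- m$layers[[length(m$layers)]]$l$params$b
    score <- function(Aarr) {
      Fm <- matrix(Aarr, S, C)
      feat <- as.vector(crossprod(Fm) / S)
      (crossprod(W, feat) + b)[cls]
    }
    expect_equal(score(A), cam$score, tolerance = 1e-8)

    # finite-difference gradients on a pixel sample
    set.seed(73 + cls)
    idx <- sample(length(A), 30)
    eps <- 1e-4
    for (i in idx) {
      Ap <- A; Ap[i] <- Ap[i] + eps
      Am <- A; Am[i] <- Am[i] - eps
      fd <- (score(Ap) - score(Am)) / (2 * eps)
      expect_lt(abs(cam$grads[i] - fd), 1e-3 * max(abs(fd), 1e-6))
    }

    # closed form of the bilinear head: dy/dA_k(s) = (1/S) (Wc+Wc^T) A(s)
    Wc <- matrix(W[, cls], C, C)
    Fm <- matrix(A, S, C)
    G <- Fm %*% (Wc + t(Wc)) / S
    expect_equal(as.vector(cam$grads), as.vector(G), tolerance = 1e-8)
    alpha <- colMeans(G)
    expect_equal(cam$alpha, alpha, tolerance = 1e-8)
    raw <- matrix(pmax(Fm %*% alpha, 0), d[1], d[2])
    expect_equal(cam$raw, raw, tolerance = 1e-8)
    # Eq-1 bookkeeping: Z * alpha_k equals the gradient sum
    expect_equal(cam$Z * cam$alpha, apply(cam$grads, 3, sum))
    expect_true(all(cam$raw >= 0))
  }
  expect_error(compute_cam(m, x, class = 5), "out of range")
})

test_that("pre-softmax CAM scales linearly with the logits", {
  m <- build_glnb(glnb_config(input_size = c(24, 24), n_modules = 1,
                              width_factor = 0.05, pool_after = integer(0),
                              signed_sqrt = FALSE, l2 = FALSE), seed = 74)
  set.seed(75)
  x <- array(runif(24 * 24 * 3), c(24, 24, 3))
  cam1 <- compute_cam(m, x, class = 1)
  lam <- 3.7
  m2 <- m
  nl <- length(m2$layers)
  m2$layers[[nl]]$l$params$W <- m2$layers[[nl]]$l$params$W * lam
  m2$layers[[nl]]$l$params$b <- m2$layers[[nl]]$l$params$b * lam
  cam2 <- compute_cam(m2, x, class = 1)
  expect_equal(cam2$raw, lam * cam1$raw, tolerance = 1e-8)
  # post-softmax mode differs from pre-softmax but keeps non-negativity
  cam3 <- compute_cam(m, x, class = 1, score_kind = "post_softmax")
  expect_true(all(cam3$raw >= 0))
})

test_that("upsampling is corner-anchored bilinear with max normalization", {
  raw <- matrix(c(0, 0, 0, 1), 2, 2)
  up <- upsample_cam(raw, c(4, 4))
  expect_equal(up[4, 4], 1)
  expect_equal(up[1, 1], 0)
  expect_true(all(up[2:3, 2:3] > 0 & up[2:3, 2:3] < 1))

  # same-shape target: normalization only
  expect_equal(upsample_cam(matrix(c(1, 2, 3, 4), 2, 2), c(2, 2)),
               matrix(c(1, 2, 3, 4), 2, 2) / 4)
  # constant positive map -> constant 1; zero map stays zero
  expect_true(all(upsample_cam(matrix(0.3, 3, 3), c(6, 6)) == 1))
  expect_true(all(upsample_cam(matrix(0, 3, 3), c(6, 6)) == 0))
  expect_error(upsample_cam(matrix(1, 4, 4), c(2, 2)), "smaller")
})

test_that("heatmaps write as csv matrices", {
  h <- matrix(runif(24), 4, 6)
  p <- withr::local_tempfile(fileext = ".csv")
  write_heatmap(h, p)
  back <- as.matrix(read.csv(p, header = FALSE))
  expect_equal(unname(back), h, tolerance = 1e-6)
})
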