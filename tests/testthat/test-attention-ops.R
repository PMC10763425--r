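test_that("scaled dot-product attention normalizes and mixes values correctly", {
  # single key: every query copies the single value row
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(c(0.3, -0.2), 1, 2)
  V <- matrix(c(2, 5), 1, 2)
  out <- scaled_dot_product_attention(Q, K, V)
  expect_equal(unname(out), matrix(rep(c(2, 5), each = 3), 3, 2),
               ignore_attr = TRUE)

  # zero queries: uniform weights, output is the column-wise mean of V
  Qz <- matrix(0, 2, 3)
  Kr <- matrix(rnorm(12), 4, 3)
  Vr <- matrix(rnorm(8), 4, 2)
  outz <- scaled_dot_product_attention(Qz, Kr, Vr)
  expect_equal(unname(outz[1, ]), colMeans(Vr))
  expect_equal(unname(outz[2, ]), colMeans(Vr))

  # worked example: weights softmax(1/sqrt(2), 0)
  out2 <- scaled_dot_product_attention(matrix(c(1, 0), 1, 2),
                                       diag(2), diag(2), d_k = 2)
  w <- exp(c(1 / sqrt(2), 0)); w <- w / sum(w)
  expect_equal(unname(drop(out2)), w, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(round(unname(drop(out2)), 4), c(0.6698, 0.3302),
               ignore_attr = TRUE)

  # weights are a probability distribution per query row
  set.seed(1)
  for (i in 1:5) {
    o <- scaled_dot_product_attention(matrix(rnorm(8), 2), matrix(rnorm(12), 3),
                                      matrix(rnorm(6), 3))
    ww <- attr(o, "weights")
    expect_true(all(ww >= 0))
    expect_equal(rowSums(ww), c(1, 1))
  }

  expect_error(scaled_dot_product_attention(matrix(0, 1, 2), matrix(0, 2, 3),
                                            matrix(0, 2, 1)),
               class = "pneumonet_contract_error")
})

test_that("channel attention gates lie in (0,1) and act per channel", {
  set.seed(2)
  F <- array(rnorm(4 * 4 * 3), c(4, 4, 3))

  # zero weights: every gate is exactly sigmoid(0) = 0.5
  w0 <- channel_attention_weights(3, init = "zero")
  half <- channel_attention(F, w0)
  expect_equal(unname(attr(half, "gates")), rep(0.5, 3))
  expect_equal(as.numeric(half), as.numeric(F / 2))

  # saturated gates approximate the identity
  wbig <- w0; wbig$b2 <- rep(20, 3)
  idish <- channel_attention(F, wbig)
  expect_equal(as.numeric(idish), as.numeric(F), tolerance = 1e-6)

  # a silent channel has a zero descriptor: its gate stays at the bias value
  # regardless of the content of other channels (pooling locality)
  Fz <- F; Fz[, , 2] <- 0
  wdiag <- list(W1 = diag(3) * 5, b1 = numeric(3), W2 = diag(3) * 5,
                b2 = numeric(3))
  g1 <- attr(channel_attention(Fz, wdiag), "gates")
  Fz2 <- Fz; Fz2[, , 1] <- abs(Fz2[, , 1]) + 1
  g2 <- attr(channel_attention(Fz2, wdiag), "gates")
  expect_equal(g1[2], 0.5)
  expect_equal(g2[2], 0.5)
  expect_false(isTRUE(all.equal(g1[1], g2[1])))

  # gates strictly inside (0,1) shrink channel norms
  set.seed(3)
  wr <- channel_attention_weights(3, init = "he")
  y <- channel_attention(F, wr)
  g <- attr(y, "gates")
  expect_true(all(g > 0 & g < 1))
  for (c in 1:3)
    expect_lte(sqrt(sum(y[, , c]^2)), sqrt(sum(F[, , c]^2)))
})

test_that("side-branch block obeys identity, hand-computed and shape contracts", {
  # zero kernels, additive fusion, residual skip: exact identity
  set.seed(4)
  F <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  wz <- side_branch_weights(2, reduction = 2, stride = 2, init = "zero")
  expect_identical(side_branch_block(F, wz, skip = TRUE), F)

  # identity main path with zero branches is also the identity without skip
  wid <- side_branch_weights(2, reduction = 2, stride = 2, init = "identity")
  expect_equal(side_branch_block(F, wid, skip = FALSE), F, tolerance = 1e-12)

  # hand example: 4x4 ones, all-1x1 unit kernels, stride 1 -> 3 * ones
  ones <- array(1, c(4, 4, 1))
  w1 <- list(main = list(W = array(1, c(1, 1, 1, 1)), b = 0, stride = 1L,
                         pad = 0L),
             branches = list(
               list(reduce = list(W = array(1, c(1, 1, 1, 1)), b = 0,
                                  stride = 1L, pad = 0L),
                    up = list(W = array(1, c(1, 1, 1, 1)), b = 0,
                              stride = 1L, pad = 0L)),
               list(reduce = list(W = array(1, c(1, 1, 1, 1)), b = 0,
                                  stride = 1L, pad = 0L),
                    up = list(W = array(1, c(1, 1, 1, 1)), b = 0,
                              stride = 1L, pad = 0L))))
  expect_equal(side_branch_block(ones, w1), array(3, c(4, 4, 1)))

  # shape preservation fuzz across strides, sizes and channel counts
  set.seed(5)
  for (i in 1:10) {
    s <- sample(c(1L, 2L), 1)
    H <- s * sample(2:5, 1)
    C <- sample(1:4, 1)
    Fx <- array(rnorm(H * H * C), c(H, H, C))
    wts <- side_branch_weights(C, reduction = sample(c(1L, 2L, 4L), 1),
                               stride = s, init = "he")
    for (fus in c("additive", "gated")) {
      y <- side_branch_block(Fx, wts, fusion = fus, skip = TRUE)
      expect_identical(dim(y), dim(Fx))
      expect_true(all(is.finite(y)))
    }
  }

  expect_error(side_branch_block(array(0, c(5, 5, 2)),
                                 side_branch_weights(2, stride = 2)),
               class = "pneumonet_contract_error")
})

test_that("block output matches a loop-based convolution oracle on small inputs", {
  set.seed(6)
  for (i in 1:12) {
    s <- sample(c(1L, 2L), 1)
    H <- s * sample(seq_len(6 %/% s), 1)
    H <- max(H, s)
    C <- sample(1:3, 1)
    Fx <- array(rnorm(H * H * C), c(H, H, C))
    wts <- side_branch_weights(C, reduction = sample(c(1L, 2L), 1),
                               stride = s, init = "he")
    fus <- sample(c("additive", "gated"), 1)
    skip <- sample(c(TRUE, FALSE), 1)
    got <- side_branch_block(Fx, wts, fusion = fus, skip = skip)
    want <- side_branch_ref(Fx, wts, fusion = fus, skip = skip)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-10)
  }
})

test_that("convolution kernels agree with loop references including gradients", {
  set.seed(7)
  for (i in 1:6) {
    H <- sample(3:6, 1); W <- sample(3:6, 1)
    Cin <- sample(1:3, 1); Cout <- sample(1:3, 1)
    k <- sample(1:3, 1); stride <- sample(1:2, 1); pad <- sample(0:1, 1)
    if ((H + 2 * pad - k) < 0 || (W + 2 * pad - k) < 0) next
    x <- array(rnorm(H * W * Cin), c(H, W, Cin, 1))
    w <- array(rnorm(k * k * Cin * Cout), c(k, k, Cin, Cout))
    b <- rnorm(Cout)
    got <- pneumonet:::conv2d_fwd_cpp(x, w, b, stride, pad)
    want <- conv2d_ref(x[, , , 1, drop = TRUE] |>
                         array(c(H, W, Cin)), w, b, stride, pad)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)

    wt <- array(rnorm(k * k * Cout * Cin), c(k, k, Cout, Cin))
    gotT <- pneumonet:::convt2d_fwd_cpp(x, wt, b, stride, pad)
    wantT <- convt2d_ref(array(x, c(H, W, Cin)), wt, b, stride, pad)
    expect_equal(as.numeric(gotT), as.numeric(wantT), tolerance = 1e-12)
  }
})
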