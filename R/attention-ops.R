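#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`: each query row attends over the
#' keys and the output row is the corresponding convex combination of the
#' rows of `V`. The attention weights are non-negative and sum to one per
#' query row; they are attached to the result as attribute `"weights"`.
#'
#' @param Q `n_q x d_k` query matrix.
#' @param K `n_k x d_k` key matrix.
#' @param V `n_k x d_v` value matrix.
#' @param d_k key dimension used in the scaling; defaults to `ncol(Q)`.
#' @return `n_q x d_v` matrix with attribute `weights` (`n_q x n_k`).
#' @export
scaled_dot_product_attention <- function(Q, K, V, d_k = ncol(Q)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K))
    pn_stop("Q and K must share the key dimension d_k",
            "pneumonet_contract_error")
  if (nrow(K) != nrow(V))
    pn_stop("K and V must have the same number of rows",
            "pneumonet_contract_error")
  scores <- Q %*% t(K) / sqrt(d_k)
  # row-wise softmax, shifted for numerical stability
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  w <- e / rowSums(e)
  structure(w %*% V, weights = w)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Channel-attention weights for channel-attention gating
#'
#' @param channels number of feature-map channels `C`.
#' @param reduction bottleneck reduction ratio (at least 1).
#' @param init `"zero"` for all-zero weights (every gate is exactly 0.5) or
#'   `"he"` for seeded random initialization.
#' @return list with `W1` (`C x ceil(C/r)`), `b1`, `W2`, `b2`.
#' @export
channel_attention_weights <- function(channels, reduction = 4L,
                                      init = c("zero", "he")) {
  init <- match.arg(init)
  cr <- max(1L, as.integer(ceiling(channels / reduction)))
  rnd <- function(n, fan) if (init == "zero") numeric(n)
                          else rnorm(n, 0, sqrt(2 / fan))
  list(W1 = matrix(rnd(channels * cr, channels), channels, cr),
       b1 = numeric(cr),
       W2 = matrix(rnd(cr * channels, cr), cr, channels),
       b2 = numeric(channels))
}

#' Channel attention
#'
#' Squeezes each feature-map channel to a scalar descriptor by global
#' average pooling, maps the `C`-vector through a two-layer bottleneck
#' (ReLU inside), applies a sigmoid to obtain per-channel gates in
#' `(0,1)`, and rescales the feature map channel-wise by the gates.
#'
#' @param F an `H x W x C` feature map (or `H x W x C x N` batch).
#' @param weights a list as from [channel_attention_weights()].
#' @return the gated feature map, with the gates attached as attribute
#'   `"gates"`.
#' @export
channel_attention <- function(F, weights) {
  x <- F
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  z <- t(matrix(colSums(matrix(x, nrow = d[1L] * d[2L])), d[3L], d[4L])) /
    (d[1L] * d[2L])                     # N x C channel descriptors
  h <- pmax(z %*% weights$W1 + rep(weights$b1, each = nrow(z)), 0)
  g <- sigmoid(h %*% weights$W2 + rep(weights$b2, each = nrow(z)))
  gx <- aperm(array(t(g), dim = c(d[3L], d[4L], d[1L], d[2L])), c(3L, 4L, 1L, 2L))
  y <- x * gx
  if (squeeze) { dim(y) <- d[1:3]; g <- g[1L, ] }
  structure(y, gates = g)
}

# default transposed-convolution geometry restoring an s-fold reduction:
# stride 1 -> 3x3 pad 1; even stride s -> kernel 2s, pad s/2
upsample_geom <- function(stride) {
  if (stride == 1L) list(k = 3L, pad = 1L)
  else if (stride %% 2L == 0L) list(k = 2L * stride, pad = stride %/% 2L)
  else pn_stop("branch_stride must be 1 or even", "pneumonet_config_error")
}

#' Weights for a side-branch attention block
#'
#' The default geometry: main path 3x3 convolution (`C -> C`), two side
#' branches each made of a 3x3 stride-`s` reducing convolution
#' (`C -> ceil(C/r)`) and a `2s x 2s` stride-`s` transposed convolution
#' restoring `H x W x C`.
#'
#' @param channels feature-map channels `C`.
#' @param reduction branch channel reduction `r`.
#' @param stride branch spatial stride `s` (1 or even).
#' @param init `"zero"`, `"identity"` (zero branches, identity main path),
#'   or `"he"` (seeded random).
#' @return nested list of main/branch convolution weights.
#' @export
side_branch_weights <- function(channels, reduction = 4L, stride = 2L,
                                init = c("he", "zero", "identity")) {
  init <- match.arg(init)
  cb <- max(1L, as.integer(ceiling(channels / reduction)))
  ug <- upsample_geom(stride)
  mk <- function(k, cin, cout, identity = FALSE) {
    W <- array(0, dim = c(k, k, cin, cout))
    if (identity) {
      ctr <- (k + 1L) %/% 2L
      for (c in seq_len(min(cin, cout))) W[ctr, ctr, c, c] <- 1
    } else if (init == "he") {
      W[] <- rnorm(length(W), 0, sqrt(2 / (k * k * cin)))
    }
    list(W = W, b = numeric(cout))
  }
  mkT <- function(k, cin, cout) {
    W <- array(0, dim = c(k, k, cout, cin))
    if (init == "he") W[] <- rnorm(length(W), 0, sqrt(2 / (k * k * cin)))
    list(W = W, b = numeric(cout))
  }
  branch <- function() list(
    reduce = c(mk(3L, channels, cb), list(stride = stride, pad = 1L)),
    up = c(mkT(ug$k, cb, channels), list(stride = stride, pad = ug$pad)))
  list(main = c(mk(3L, channels, channels, identity = init == "identity"),
                list(stride = 1L, pad = 1L)),
       branches = list(branch(), branch()))
}

#' Side-branch attention block (functional form)
#'
#' The block at the heart of the attention-enhanced backbone. Two side
#' branches reduce the feature map by strided convolution (lower spatial
#' and channel dimensionality), restore the original `H x W x C` shape by
#' transposed convolution, and are fused with the main-path convolution of
#' the original feature map — element-wise addition in `"additive"` mode,
#' or sigmoid gating (`main * sigmoid(branch sum)`) in `"gated"` mode.
#' Optionally the fused map passes through batch normalization and ReLU,
#' and the whole transform is wrapped in a residual skip
#' (`output = F + transform(F)`).
#'
#' @param F `H x W x C` feature map (or `H x W x C x N` batch); `H` and `W`
#'   must be divisible by the branch stride.
#' @param weights list as from [side_branch_weights()]; kernel sizes,
#'   strides and paddings are taken from it, so arbitrary geometries
#'   (e.g. 1x1 kernels) can be supplied directly.
#' @param fusion `"additive"` or `"gated"`.
#' @param skip wrap in a residual skip connection.
#' @param norm `"none"` or `"batch"`.
#' @param activation `"none"` or `"relu"`.
#' @return feature map of identical shape.
#' @export
side_branch_block <- function(F, weights, fusion = c("additive", "gated"),
                              skip = FALSE, norm = c("none", "batch"),
                              activation = c("none", "relu")) {
  fusion <- match.arg(fusion)
  norm <- match.arg(norm)
  activation <- match.arg(activation)
  x <- F
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  st <- weights$branches[[1L]]$reduce$stride
  if (d[1L] %% st != 0L || d[2L] %% st != 0L)
    pn_stop(sprintf("spatial dims (%d x %d) not divisible by branch stride %d",
                    d[1L], d[2L], st), "pneumonet_contract_error")
  m <- conv2d_fwd_cpp(x, weights$main$W, weights$main$b,
                      weights$main$stride, weights$main$pad)
  ssum <- 0
  for (br in weights$branches) {
    r <- conv2d_fwd_cpp(x, br$reduce$W, br$reduce$b, br$reduce$stride,
                        br$reduce$pad)
    u <- convt2d_fwd_cpp(r, br$up$W, br$up$b, br$up$stride, br$up$pad)
    ssum <- ssum + u
  }
  fused <- if (fusion == "additive") m + ssum else m * sigmoid(ssum)
  if (norm == "batch") {
    mu <- apply(fused, 3L, mean)
    v <- apply(fused, 3L, function(ch) mean((ch - mean(ch))^2))
    for (c in seq_len(d[3L]))
      fused[, , c, ] <- (fused[, , c, ] - mu[c]) / sqrt(v[c] + 1e-5)
  }
  if (activation == "relu") fused <- pmax(fused, 0)
  y <- if (skip) x + fused else fused
  if (squeeze) dim(y) <- d[1:3]
  y
}
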