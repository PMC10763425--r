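# Independent reference implementations used as oracles. These are written
# as plain loops, independent of the package's im2col/BLAS kernels.

conv2d_ref <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]
  k <- dim(w)[1]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
    acc <- b[co]
    for (ci in seq_len(Cin)) for (kw in seq_len(k)) for (kh in seq_len(k)) {
      hi <- (ho - 1) * stride + kh - pad
      wi <- (wo - 1) * stride + kw - pad
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, ci] * w[kh, kw, ci, co]
    }
    y[ho, wo, co] <- acc
  }
  y
}

convt2d_ref <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(w)[1]; Cout <- dim(w)[3]
  Ho <- (H - 1) * stride - 2 * pad + k
  Wo <- (W - 1) * stride - 2 * pad + k
  y <- array(0, c(Ho, Wo, Cout))
  for (ci in seq_len(Cin)) for (j in seq_len(W)) for (i in seq_len(H))
    for (co in seq_len(Cout)) for (kw in seq_len(k)) for (kh in seq_len(k)) {
      oh <- (i - 1) * stride + kh - pad
      ow <- (j - 1) * stride + kw - pad
      if (oh >= 1 && oh <= Ho && ow >= 1 && ow <= Wo)
        y[oh, ow, co] <- y[oh, ow, co] + x[i, j, ci] * w[kh, kw, co, ci]
    }
  for (co in seq_len(Cout)) y[, , co] <- y[, , co] + b[co]
  y
}

# loop-based reference of the whole side-branch block (norm-free form)
side_branch_ref <- function(x, wts, fusion = "additive", skip = FALSE) {
  m <- conv2d_ref(x, wts$main$W, wts$main$b, wts$main$stride, wts$main$pad)
  s <- 0
  for (br in wts$branches) {
    r <- conv2d_ref(x, br$reduce$W, br$reduce$b, br$reduce$stride,
                    br$reduce$pad)
    s <- s + convt2d_ref(r, br$up$W, br$up$b, br$up$stride, br$up$pad)
  }
  fused <- if (fusion == "additive") m + s else m / (1 + exp(-s)) # m * sigmoid(s)
  if (skip) x + fused else fused
}

# scalar-loop, formula-level evaluation of the losses
focal_ref <- function(y, p, alpha_t, gamma, eps = 1e-7) {
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    pt <- if (y[i] == 1) pi else 1 - pi
    a <- if (length(alpha_t) == 1) alpha_t else alpha_t[i]
    out[i] <- -a * (1 - pt)^gamma * log(pt)
  }
  out
}

modified_focal_ref <- function(y, p, alpha, gamma, n_normal, n_pneumonia,
                               count_mapping = "as_printed", eps = 1e-7) {
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    if (y[i] == 1) {
      nn <- if (count_mapping == "as_printed") n_normal else n_pneumonia
      out[i] <- -(1 / sqrt(nn)) * alpha * (1 - pi)^gamma * log(pi)
    } else {
      nn <- if (count_mapping == "as_printed") n_pneumonia else n_normal
      out[i] <- -(1 / sqrt(nn)) * (1 - alpha) * pi^gamma * log(1 - pi)
    }
  }
  out
}

# first-principles metric formulas, written out one ratio at a time
metrics_ref <- function(tp, fp, tn, fn) {
  tot <- tp + fp + tn + fn
  acc <- if (tot > 0) (tp + tn) / tot else NA_real_
  pre <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(pre) && !is.na(rec) && pre + rec > 0)
    2 * pre * rec / (pre + rec) else NA_real_
  list(accuracy = acc, precision = pre, recall = rec, specificity = spe,
       f1 = f1)
}

# tiny dataset + configs shared by the training tests
tiny_setup <- function(seed = 1) {
  spec <- phantom_spec(image_size = 32L, n_pneumonia = 30L, n_normal = 15L,
                       noise_sd = 0, seed = seed)
  ds <- generate_dataset(spec)
  sp <- split_dataset(ds, c(pneumonia = 22, normal = 11),
                      c(pneumonia = 8, normal = 4), seed = seed)
  list(train = as_batch_array(sp$train), val = as_batch_array(sp$validation),
       net = network_config(input_size = c(32L, 32L, 1L), stem_channels = 8L,
                            n_blocks = 1L, stem_stride = 2L, stem_pool = TRUE,
                            seed = seed))
}
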