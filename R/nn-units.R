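# Trainable network units.
#
# A unit is a plain list: list(type, hyper, params, children, buffers).
# forward_unit() returns list(y, cache, unit) (the unit comes back so batch
# normalization can update its running statistics); backward_unit() returns
# list(gx, grads) with grads mirroring the params/children structure.
# Composite units (seq, residual, resblock, sideb, chattn) recurse. All
# gradients are exact: every backward pass is the hand-derived adjoint of
# its forward pass, which the finite-difference tests verify.

unit_conv <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv",
       hyper = list(k = k, stride = as.integer(stride), pad = as.integer(pad)),
       params = list(
         W = array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                   dim = c(k, k, cin, cout)),
         b = numeric(cout)),
       children = list(), buffers = list())
}

unit_convt <- function(k, cin, cout, stride, pad) {
  list(type = "convt",
       hyper = list(k = k, stride = as.integer(stride), pad = as.integer(pad)),
       params = list(
         W = array(rnorm(k * k * cout * cin, 0, sqrt(2 / (k * k * cin))),
                   dim = c(k, k, cout, cin)),
         b = numeric(cout)),
       children = list(), buffers = list())
}

unit_bn <- function(channels, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", hyper = list(eps = eps, momentum = momentum),
       params = list(gamma = rep(1, channels), beta = numeric(channels)),
       children = list(),
       buffers = list(rmean = numeric(channels), rvar = rep(1, channels)))
}

unit_relu <- function()
  list(type = "relu", hyper = list(), params = list(), children = list(),
       buffers = list())

unit_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(type = "maxpool",
       hyper = list(k = as.integer(k), stride = as.integer(stride),
                    pad = as.integer(pad)),
       params = list(), children = list(), buffers = list())

unit_gap <- function()
  list(type = "gap", hyper = list(), params = list(), children = list(),
       buffers = list())

unit_linear <- function(cin, cout) {
  list(type = "linear", hyper = list(),
       params = list(W = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
                     b = numeric(cout)),
       children = list(), buffers = list())
}

unit_seq <- function(units) {
  names(units) <- sprintf("u%02d", seq_along(units))
  list(type = "seq", hyper = list(), params = list(), children = units,
       buffers = list())
}

# basic residual block: conv-bn-relu-conv-bn (+ 1x1 projection when shape
# changes), residual add, final relu
unit_resblock <- function(cin, cout, stride = 1L) {
  ch <- list(conv1 = unit_conv(3L, cin, cout, stride = stride),
             bn1 = unit_bn(cout),
             conv2 = unit_conv(3L, cout, cout),
             bn2 = unit_bn(cout))
  if (stride != 1L || cin != cout)
    ch$proj <- unit_conv(1L, cin, cout, stride = stride, pad = 0L)
  list(type = "resblock", hyper = list(), params = list(), children = ch,
       buffers = list())
}

# side-branch attention block as a trainable unit (residual skip by default)
unit_sideb <- function(channels, reduction = 4L, stride = 2L,
                       fusion = "additive", skip = TRUE, norm = "batch") {
  cb <- max(1L, as.integer(ceiling(channels / reduction)))
  ug <- upsample_geom(stride)
  ch <- list(main = unit_conv(3L, channels, channels),
             r1 = unit_conv(3L, channels, cb, stride = stride),
             up1 = unit_convt(ug$k, cb, channels, stride, ug$pad),
             r2 = unit_conv(3L, channels, cb, stride = stride),
             up2 = unit_convt(ug$k, cb, channels, stride, ug$pad))
  if (norm == "batch") ch$bn <- unit_bn(channels)
  list(type = "sideb",
       hyper = list(fusion = fusion, skip = skip, norm = norm,
                    stride = as.integer(stride)),
       params = list(), children = ch, buffers = list())
}

unit_chattn <- function(channels, reduction = 4L) {
  cr <- max(1L, as.integer(ceiling(channels / reduction)))
  list(type = "chattn", hyper = list(),
       params = list(
         W1 = matrix(rnorm(channels * cr, 0, sqrt(2 / channels)), channels, cr),
         b1 = numeric(cr),
         W2 = matrix(rnorm(cr * channels, 0, sqrt(2 / cr)), cr, channels),
         b2 = numeric(channels)),
       children = list(), buffers = list())
}

# ---- forward ---------------------------------------------------------------

forward_unit <- function(u, x, training = FALSE) {
  switch(u$type,
    conv = {
      y <- conv2d_fwd_cpp(x, u$params$W, u$params$b, u$hyper$stride,
                          u$hyper$pad)
      list(y = y, cache = list(x = x), unit = u)
    },
    convt = {
      y <- convt2d_fwd_cpp(x, u$params$W, u$params$b, u$hyper$stride,
                           u$hyper$pad)
      list(y = y, cache = list(x = x), unit = u)
    },
    bn = {
      d <- dim(x)
      C <- d[3L]
      m <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = C)
      if (training) {
        mu <- colMeans(m)
        v <- colMeans(m * m) - mu^2
        v[v < 0] <- 0
        mom <- u$hyper$momentum
        u$buffers$rmean <- (1 - mom) * u$buffers$rmean + mom * mu
        u$buffers$rvar <- (1 - mom) * u$buffers$rvar + mom * v
      } else {
        mu <- u$buffers$rmean
        v <- u$buffers$rvar
      }
      invstd <- 1 / sqrt(v + u$hyper$eps)
      xhat <- sweep(sweep(m, 2L, mu), 2L, invstd, "*")
      ym <- sweep(sweep(xhat, 2L, u$params$gamma, "*"), 2L, u$params$beta, "+")
      y <- aperm(array(ym, dim = c(d[1L], d[2L], d[4L], C)), c(1L, 2L, 4L, 3L))
      list(y = y,
           cache = list(xhat = xhat, invstd = invstd, d = d,
                        training = training),
           unit = u)
    },
    relu = list(y = pmax(x, 0), cache = list(mask = x > 0), unit = u),
    maxpool = {
      r <- maxpool_fwd_cpp(x, u$hyper$k, u$hyper$stride, u$hyper$pad)
      list(y = r$y, cache = list(idx = r$idx, d = dim(x)), unit = u)
    },
    gap = {
      d <- dim(x)
      y <- t(matrix(colSums(matrix(x, nrow = d[1L] * d[2L])), d[3L], d[4L])) /
        (d[1L] * d[2L])
      list(y = y, cache = list(d = d), unit = u)
    },
    linear = {
      y <- x %*% u$params$W + rep(u$params$b, each = nrow(x))
      list(y = y, cache = list(x = x), unit = u)
    },
    seq = {
      caches <- vector("list", length(u$children))
      h <- x
      for (i in seq_along(u$children)) {
        r <- forward_unit(u$children[[i]], h, training)
        h <- r$y
        caches[[i]] <- r$cache
        u$children[[i]] <- r$unit
      }
      list(y = h, cache = caches, unit = u)
    },
    resblock = {
      ch <- u$children
      r1 <- forward_unit(ch$conv1, x, training); ch$conv1 <- r1$unit
      r2 <- forward_unit(ch$bn1, r1$y, training); ch$bn1 <- r2$unit
      a1 <- pmax(r2$y, 0)
      r3 <- forward_unit(ch$conv2, a1, training); ch$conv2 <- r3$unit
      r4 <- forward_unit(ch$bn2, r3$y, training); ch$bn2 <- r4$unit
      if (!is.null(ch$proj)) {
        rp <- forward_unit(ch$proj, x, training); ch$proj <- rp$unit
        idp <- rp$y
        cp <- rp$cache
      } else { idp <- x; cp <- NULL }
      pre <- r4$y + idp
      u$children <- ch
      list(y = pmax(pre, 0),
           cache = list(c1 = r1$cache, cb1 = r2$cache, m1 = r2$y > 0,
                        c2 = r3$cache, cb2 = r4$cache, cp = cp,
                        mout = pre > 0),
           unit = u)
    },
    sideb = {
      ch <- u$children
      rm <- forward_unit(ch$main, x, training); ch$main <- rm$unit
      rr1 <- forward_unit(ch$r1, x, training); ch$r1 <- rr1$unit
      ru1 <- forward_unit(ch$up1, rr1$y, training); ch$up1 <- ru1$unit
      rr2 <- forward_unit(ch$r2, x, training); ch$r2 <- rr2$unit
      ru2 <- forward_unit(ch$up2, rr2$y, training); ch$up2 <- ru2$unit
      s <- ru1$y + ru2$y
      if (u$hyper$fusion == "additive") {
        fused <- rm$y + s
        sg <- NULL
      } else {
        sg <- sigmoid(s)
        fused <- rm$y * sg
      }
      cbn <- NULL
      if (!is.null(ch$bn)) {
        rb <- forward_unit(ch$bn, fused, training); ch$bn <- rb$unit
        cbn <- rb$cache
        fused <- rb$y
      }
      mask <- fused > 0
      h <- pmax(fused, 0)
      y <- if (u$hyper$skip) x + h else h
      u$children <- ch
      list(y = y,
           cache = list(cm = rm$cache, cr1 = rr1$cache, cu1 = ru1$cache,
                        cr2 = rr2$cache, cu2 = ru2$cache, cbn = cbn,
                        mask = mask, m = rm$y, sg = sg),
           unit = u)
    },
    chattn = {
      d <- dim(x)
      z <- t(matrix(colSums(matrix(x, nrow = d[1L] * d[2L])), d[3L], d[4L])) /
        (d[1L] * d[2L])
      a1 <- z %*% u$params$W1 + rep(u$params$b1, each = nrow(z))
      h <- pmax(a1, 0)
      g <- sigmoid(h %*% u$params$W2 + rep(u$params$b2, each = nrow(z)))
      gx <- aperm(array(t(g), dim = c(d[3L], d[4L], d[1L], d[2L])),
                  c(3L, 4L, 1L, 2L))
      list(y = x * gx,
           cache = list(x = x, z = z, a1 = a1, h = h, g = g, gxp = gx, d = d),
           unit = u)
    },
    stop("unknown unit type: ", u$type))
}

# ---- backward --------------------------------------------------------------

empty_grads <- function() list(params = list(), children = list())

backward_unit <- function(u, cache, gy) {
  switch(u$type,
    conv = {
      r <- conv2d_bwd_cpp(cache$x, u$params$W, gy, u$hyper$stride, u$hyper$pad)
      list(gx = r$gx, grads = list(params = list(W = r$gW, b = r$gb),
                                   children = list()))
    },
    convt = {
      r <- convt2d_bwd_cpp(cache$x, u$params$W, gy, u$hyper$stride, u$hyper$pad)
      list(gx = r$gx, grads = list(params = list(W = r$gW, b = r$gb),
                                   children = list()))
    },
    bn = {
      d <- cache$d
      C <- d[3L]
      gm <- matrix(aperm(gy, c(1L, 2L, 4L, 3L)), ncol = C)
      ggamma <- colSums(gm * cache$xhat)
      gbeta <- colSums(gm)
      gxhat <- sweep(gm, 2L, u$params$gamma, "*")
      if (cache$training) {
        mg <- colMeans(gxhat)
        mgx <- colMeans(gxhat * cache$xhat)
        gxm <- sweep(gxhat, 2L, mg) - sweep(cache$xhat, 2L, mgx, "*")
        gxm <- sweep(gxm, 2L, cache$invstd, "*")
      } else {
        gxm <- sweep(gxhat, 2L, cache$invstd, "*")
      }
      gx <- aperm(array(gxm, dim = c(d[1L], d[2L], d[4L], C)),
                  c(1L, 2L, 4L, 3L))
      list(gx = gx,
           grads = list(params = list(gamma = ggamma, beta = gbeta),
                        children = list()))
    },
    relu = list(gx = gy * cache$mask, grads = empty_grads()),
    maxpool = {
      d <- cache$d
      gx <- maxpool_bwd_cpp(gy, cache$idx, d[1L], d[2L], d[3L], d[4L])
      list(gx = gx, grads = empty_grads())
    },
    gap = {
      d <- cache$d
      gx <- aperm(array(t(gy) / (d[1L] * d[2L]),
                        dim = c(d[3L], d[4L], d[1L], d[2L])), c(3L, 4L, 1L, 2L))
      list(gx = gx, grads = empty_grads())
    },
    linear = {
      list(gx = gy %*% t(u$params$W),
           grads = list(params = list(W = t(cache$x) %*% gy,
                                      b = colSums(gy)),
                        children = list()))
    },
    seq = {
      g <- gy
      gch <- vector("list", length(u$children))
      for (i in rev(seq_along(u$children))) {
        r <- backward_unit(u$children[[i]], cache[[i]], g)
        g <- r$gx
        gch[[i]] <- r$grads
      }
      names(gch) <- names(u$children)
      list(gx = g, grads = list(params = list(), children = gch))
    },
    resblock = {
      ch <- u$children
      gpre <- gy * cache$mout
      rb2 <- backward_unit(ch$bn2, cache$cb2, gpre)
      rc2 <- backward_unit(ch$conv2, cache$c2, rb2$gx)
      ga1 <- rc2$gx * cache$m1
      rb1 <- backward_unit(ch$bn1, cache$cb1, ga1)
      rc1 <- backward_unit(ch$conv1, cache$c1, rb1$gx)
      gch <- list(conv1 = rc1$grads, bn1 = rb1$grads, conv2 = rc2$grads,
                  bn2 = rb2$grads)
      if (!is.null(ch$proj)) {
        rp <- backward_unit(ch$proj, cache$cp, gpre)
        gch$proj <- rp$grads
        gx <- rc1$gx + rp$gx
      } else {
        gx <- rc1$gx + gpre
      }
      list(gx = gx, grads = list(params = list(), children = gch))
    },
    sideb = {
      ch <- u$children
      gh <- gy # gradient on the transform output
      gfused <- gh * cache$mask
      gch <- list()
      if (!is.null(ch$bn)) {
        rb <- backward_unit(ch$bn, cache$cbn, gfused)
        gch$bn <- rb$grads
        gfused <- rb$gx
      }
      if (u$hyper$fusion == "additive") {
        gm <- gfused
        gs <- gfused
      } else {
        gm <- gfused * cache$sg
        gs <- gfused * cache$m * cache$sg * (1 - cache$sg)
      }
      ru1 <- backward_unit(ch$up1, cache$cu1, gs)
      rr1 <- backward_unit(ch$r1, cache$cr1, ru1$gx)
      ru2 <- backward_unit(ch$up2, cache$cu2, gs)
      rr2 <- backward_unit(ch$r2, cache$cr2, ru2$gx)
      rm <- backward_unit(ch$main, cache$cm, gm)
      gx <- rm$gx + rr1$gx + rr2$gx
      if (u$hyper$skip) gx <- gx + gy
      gch <- c(gch, list(main = rm$grads, r1 = rr1$grads, up1 = ru1$grads,
                         r2 = rr2$grads, up2 = ru2$grads))
      list(gx = gx, grads = list(params = list(), children = gch))
    },
    chattn = {
      d <- cache$d
      HW <- d[1L] * d[2L]
      # gradient on the gates: gg[n,c] = sum_hw gy * x
      gg <- t(matrix(colSums(matrix(gy * cache$x, nrow = HW)), d[3L], d[4L]))
      dgpre <- gg * cache$g * (1 - cache$g)
      gW2 <- t(cache$h) %*% dgpre
      gb2 <- colSums(dgpre)
      dh <- dgpre %*% t(u$params$W2)
      da1 <- dh * (cache$a1 > 0)
      gW1 <- t(cache$z) %*% da1
      gb1 <- colSums(da1)
      dz <- da1 %*% t(u$params$W1)
      gx2 <- aperm(array(t(dz) / HW, dim = c(d[3L], d[4L], d[1L], d[2L])),
                   c(3L, 4L, 1L, 2L))
      list(gx = gy * cache$gxp + gx2,
           grads = list(params = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                        children = list()))
    },
    stop("unknown unit type: ", u$type))
}

# ---- optimizer -------------------------------------------------------------

# One AdamW step over a unit tree. Decoupled weight decay is applied to
# weight matrices but not to biases or normalization parameters.
adamw_init <- function(u) {
  st <- list(params = lapply(u$params, function(p) list(m = p * 0, v = p * 0)),
             children = lapply(u$children, adamw_init))
  st
}

adamw_step_unit <- function(u, g, st, lr, wd, beta1, beta2, eps, bc1, bc2) {
  decay_ok <- c("W", "W1", "W2")
  for (nm in names(u$params)) {
    gp <- g$params[[nm]]
    s <- st$params[[nm]]
    s$m <- beta1 * s$m + (1 - beta1) * gp
    s$v <- beta2 * s$v + (1 - beta2) * gp * gp
    step <- (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    if (nm %in% decay_ok) step <- step + wd * u$params[[nm]]
    u$params[[nm]] <- u$params[[nm]] - lr * step
    st$params[[nm]] <- s
  }
  for (nm in names(u$children)) {
    r <- adamw_step_unit(u$children[[nm]], g$children[[nm]], st$children[[nm]],
                         lr, wd, beta1, beta2, eps, bc1, bc2)
    u$children[[nm]] <- r$unit
    st$children[[nm]] <- r$state
  }
  list(unit = u, state = st)
}
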