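test_that("focal loss matches direct formula evaluation at worked examples", {
  # p_t = 0.9, alpha_t = 0.25, gamma = 2
  expect_equal(focal_loss(1, 0.9, alpha_t = 0.25, gamma = 2),
               0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_equal(focal_loss(1, 0.9, alpha_t = 0.25, gamma = 2), 2.6340e-4,
               tolerance = 1e-4)
  # gamma = 0, alpha = 1 collapses to cross-entropy
  expect_equal(focal_loss(1, 0.5, alpha_t = 1, gamma = 0), -log(0.5))
  # perfectly classified samples lose (almost) nothing
  expect_lt(focal_loss(1, 1 - 1e-9, alpha_t = 0.25, gamma = 2), 1e-12)
  expect_error(focal_loss(1, 0.5, gamma = -1), class = "pneumonet_config_error")
})

test_that("modified focal loss reproduces the printed piecewise formula", {
  lc <- loss_config(alpha = 0.25, gamma = 2, n_normal = 16, n_pneumonia = 100,
                    count_mapping = "as_printed", reduction = "none")
  expect_equal(modified_focal_loss(1, 0.9, lc),
               (1 / 4) * 0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_equal(modified_focal_loss(1, 0.9, lc), 6.5850e-5, tolerance = 1e-4)
  expect_equal(modified_focal_loss(0, 0.1, lc),
               (1 / 10) * 0.75 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_equal(modified_focal_loss(0, 0.1, lc), 7.9020e-5, tolerance = 1e-4)
  expect_lt(modified_focal_loss(1, 1 - 1e-9, lc), 1e-12)
  expect_error(loss_config(n_normal = 0), class = "pneumonet_config_error")
})

test_that("inverse-square-root class weights are exact", {
  expect_identical(class_weight(1), 1)
  expect_identical(class_weight(16), 0.25)
  expect_equal(class_weight(4273), 0.015299, tolerance = 1e-4)
  expect_equal(class_weight(4273), 1 / sqrt(4273), tolerance = 1e-15)
  expect_error(class_weight(0), class = "pneumonet_config_error")
})

test_that("losses agree with scalar-loop oracles on many random batches", {
  set.seed(11)
  max_f <- 0; max_m <- 0; max_ce <- 0
  for (i in 1:1000) {
    n <- sample(1:16, 1)
    y <- sample(0:1, n, replace = TRUE)
    p <- runif(n, 1e-6, 1 - 1e-6)
    a <- runif(1, 0.05, 0.95)
    g <- sample(c(0, 0.5, 1, 2, 5), 1)
    nn <- sample(1:5000, 2)
    mapping <- sample(c("as_printed", "per_class"), 1)
    max_f <- max(max_f, abs(
      focal_loss(y, p, alpha_t = a, gamma = g, reduction = "none") -
        focal_ref(y, p, a, g)))
    lc <- loss_config(alpha = a, gamma = g, n_normal = nn[1],
                      n_pneumonia = nn[2], count_mapping = mapping,
                      reduction = "none")
    max_m <- max(max_m, abs(
      modified_focal_loss(y, p, lc) -
        modified_focal_ref(y, p, a, g, nn[1], nn[2], mapping)))
    max_ce <- max(max_ce, abs(
      cross_entropy(y, p, reduction = "none") -
        focal_loss(y, p, alpha_t = 1, gamma = 0, reduction = "none")))
  }
  expect_lt(max_f, 1e-12)
  expect_lt(max_m, 1e-12)
  expect_lt(max_ce, 1e-12)
})

test_that("cross-entropy is symmetric and reductions behave", {
  expect_equal(cross_entropy(1, 0.5), -log(0.5))
  expect_equal(cross_entropy(0, 0.5), -log(0.5))
  y <- c(1, 0, 1); p <- c(0.8, 0.3, 0.6)
  expect_equal(cross_entropy(y, p, "sum"),
               sum(cross_entropy(y, p, "none")))
  expect_equal(cross_entropy(y, p, "mean"),
               mean(cross_entropy(y, p, "none")))
})

test_that("losses are non-negative and strictly decreasing in p_t", {
  p <- seq(0.02, 0.98, by = 0.02)
  for (g in c(0, 0.5, 1, 2, 5)) {
    l1 <- focal_loss(rep(1, length(p)), p, alpha_t = 0.25, gamma = g,
                     reduction = "none")
    expect_true(all(l1 >= 0))
    expect_true(all(diff(l1) < 0))
    lc <- loss_config(gamma = g, n_normal = 70, n_pneumonia = 230,
                      reduction = "none")
    lm <- modified_focal_loss(rep(1, length(p)), p, lc)
    expect_true(all(lm >= 0))
    expect_true(all(diff(lm) < 0))
  }
  lce <- cross_entropy(rep(0, length(p)), p, reduction = "none")
  expect_true(all(diff(lce) > 0)) # p_t = 1 - p for the negative class
})

test_that("higher gamma focuses the loss on hard samples", {
  gammas <- c(0, 0.5, 1, 2, 5)
  ratio <- vapply(gammas, function(g)
    focal_loss(1, 0.9, alpha_t = 0.25, gamma = g) /
      focal_loss(1, 0.5, alpha_t = 0.25, gamma = g), 0)
  expect_true(all(diff(ratio) < 0))
})

test_that("class-count weighting scales the rarer class by the closed form", {
  a <- 0.25; g <- 2; q <- 0.8
  n_major <- 230; n_minor <- 70 # majority = pneumonia (label 1)

  # printed mapping: class-1 loss / class-0 loss at symmetric predictions
  lc_ap <- loss_config(alpha = a, gamma = g, n_normal = n_minor,
                       n_pneumonia = n_major, count_mapping = "as_printed",
                       reduction = "none")
  r_ap <- modified_focal_loss(1, q, lc_ap) / modified_focal_loss(0, 1 - q, lc_ap)
  expect_equal(r_ap, sqrt(n_major / n_minor) * a / (1 - a), tolerance = 1e-10)

  # per-class mapping: the rarer class (normal) is upweighted
  lc_pc <- loss_config(alpha = a, gamma = g, n_normal = n_minor,
                       n_pneumonia = n_major, count_mapping = "per_class",
                       reduction = "none")
  r_pc <- modified_focal_loss(0, 1 - q, lc_pc) / modified_focal_loss(1, q, lc_pc)
  expect_equal(r_pc, sqrt(n_major / n_minor) * (1 - a) / a, tolerance = 1e-10)
  expect_gt(r_pc, 1)
})

test_that("analytic loss derivatives match central finite differences", {
  h <- 1e-7
  grid <- seq(0.05, 0.95, by = 0.05)
  for (y in c(0, 1)) {
    for (g in c(0, 1, 2)) {
      num <- (focal_loss(rep(y, length(grid)), grid + h, alpha_t = 0.3,
                         gamma = g, reduction = "none") -
              focal_loss(rep(y, length(grid)), grid - h, alpha_t = 0.3,
                         gamma = g, reduction = "none")) / (2 * h)
      ana <- focal_loss_grad(rep(y, length(grid)), grid, alpha_t = 0.3,
                             gamma = g)
      expect_equal(ana, num, tolerance = 1e-6)
    }
    numce <- (cross_entropy(rep(y, length(grid)), grid + h, "none") -
              cross_entropy(rep(y, length(grid)), grid - h, "none")) / (2 * h)
    expect_equal(cross_entropy_grad(rep(y, length(grid)), grid), numce,
                 tolerance = 1e-6)
    lc <- loss_config(alpha = 0.25, gamma = 2, n_normal = 70,
                      n_pneumonia = 230, reduction = "none")
    nummf <- (modified_focal_loss(rep(y, length(grid)), grid + h, lc) -
              modified_focal_loss(rep(y, length(grid)), grid - h, lc)) / (2 * h)
    expect_equal(modified_focal_loss_grad(rep(y, length(grid)), grid, lc),
                 nummf, tolerance = 1e-6)
  }
})
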