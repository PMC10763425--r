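test_that("phantom generation is deterministic and respects the size contract", {
  spec <- phantom_spec(image_size = 64L, noise_sd = 0, seed = 3L)
  a <- generate_lung_phantom(spec, seed = 11)
  b <- generate_lung_phantom(spec, seed = 11)
  expect_identical(a$pixels, b$pixels)

  tiny <- generate_lung_phantom(phantom_spec(image_size = 16L, noise_sd = 0.05),
                                seed = 1)
  expect_equal(dim(tiny$pixels), c(16L, 16L, 1L))
  expect_true(all(tiny$pixels >= 0 & tiny$pixels <= 1))

  expect_error(phantom_spec(image_size = 8L), class = "pneumonet_spec_error")
})

test_that("lung fields are darker than their surroundings", {
  sm <- generate_lung_phantom(phantom_spec(noise_sd = 0), seed = 5)
  img <- sm$pixels[, , 1]
  expect_lt(mean(img[sm$lung_mask]), mean(img[!sm$lung_mask]))
})

test_that("grayscale content is replicated across RGB planes", {
  sm <- generate_lung_phantom(phantom_spec(channels = 3L, noise_sd = 0.02),
                              seed = 2)
  expect_equal(dim(sm$pixels)[3], 3L)
  expect_identical(sm$pixels[, , 1], sm$pixels[, , 2])
  expect_identical(sm$pixels[, , 1], sm$pixels[, , 3])
})

test_that("lesion overlay is a no-op at zero parameters and only brightens lungs", {
  sm <- generate_lung_phantom(phantom_spec(noise_sd = 0), seed = 7)
  lp0 <- lesion_params(0L, 0L, 0, 0, 0)
  out0 <- add_pneumonia_features(sm, lp0, seed = 1)
  expect_identical(out0$pixels, sm$pixels)
  expect_identical(out0$added_brightness, 0)

  out <- add_pneumonia_features(sm, lesion_params(2L, 2L, 1, 0.5, 1), seed = 1)
  img0 <- sm$pixels[, , 1]
  img1 <- out$pixels[, , 1]
  expect_true(all(img1 - img0 >= 0))                        # only additive
  expect_identical(img1[!sm$lung_mask], img0[!sm$lung_mask]) # lungs only
  expect_gte(mean(img1[sm$lung_mask]), mean(img0[sm$lung_mask]))
  expect_true(all(img1 >= 0 & img1 <= 1))
})

test_that("lesion overlay requires lung-mask metadata", {
  fake <- structure(list(pixels = array(0.5, c(16, 16, 1)), label = 0L,
                         sample_id = "x", lung_mask = NULL),
                    class = "xray_sample")
  expect_error(add_pneumonia_features(fake, lesion_params()),
               class = "pneumonet_contract_error")
})

test_that("isolated nodules form exactly that many bright components", {
  sm <- generate_lung_phantom(phantom_spec(noise_sd = 0), seed = 9)
  out <- add_pneumonia_features(sm, lesion_params(0L, 3L, 0, 0, 0), seed = 4)
  diffimg <- out$pixels[, , 1] - sm$pixels[, , 1]
  lab <- EBImage::bwlabel(diffimg > 1e-12)
  expect_equal(max(lab), 3)
})

test_that("dataset generation reproduces counts, labels and seeded shuffling", {
  spec <- phantom_spec(image_size = 16L, n_pneumonia = 12L, n_normal = 5L,
                       seed = 21L)
  ds <- generate_dataset(spec)
  expect_equal(length(ds), 17L)
  expect_equal(sum(ds$manifest$label == 1), 12L)
  expect_equal(sum(ds$manifest$label == 0), 5L)

  ds2 <- generate_dataset(spec)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$samples[[3]]$pixels, ds2$samples[[3]]$pixels)

  spec3 <- spec; spec3$seed <- 22L
  ds3 <- generate_dataset(spec3)
  expect_identical(table(ds$manifest$label), table(ds3$manifest$label))
  expect_false(identical(ds$samples[[1]]$pixels, ds3$samples[[1]]$pixels))

  only_norm <- generate_dataset(phantom_spec(image_size = 16L,
                                             n_pneumonia = 0L, n_normal = 5L))
  expect_true(all(only_norm$manifest$label == 0))
  expect_error(generate_dataset(phantom_spec(image_size = 16L,
                                             n_pneumonia = 0L, n_normal = 0L)),
               class = "pneumonet_spec_error")
})

test_that("noise-free lesion brightness separates the classes by threshold", {
  ds <- generate_dataset(phantom_spec(image_size = 32L, n_pneumonia = 25L,
                                      n_normal = 15L, noise_sd = 0, seed = 5L))
  added <- ds$manifest$added_brightness
  lab <- ds$manifest$label
  expect_gt(min(added[lab == 1]), 0)
  expect_identical(unique(added[lab == 0]), 0)
  thr <- min(added[lab == 1]) / 2
  expect_identical(as.integer(added > thr), lab)
})

test_that("splits are exact, disjoint, and fail loudly when infeasible", {
  ds <- generate_dataset(phantom_spec(image_size = 16L, seed = 2L))
  sp <- split_dataset(ds, c(pneumonia = 230, normal = 70),
                      c(pneumonia = 40, normal = 30), seed = 3)
  expect_equal(length(sp$train), 300L)
  expect_equal(length(sp$validation), 70L)
  expect_equal(sum(sp$train$manifest$label == 1), 230L)
  expect_equal(sum(sp$validation$manifest$label == 0), 30L)
  expect_length(intersect(sp$train$manifest$sample_id,
                          sp$validation$manifest$sample_id), 0L)

  small <- generate_dataset(phantom_spec(image_size = 16L, n_pneumonia = 5L,
                                         n_normal = 5L))
  expect_error(split_dataset(small, c(pneumonia = 0, normal = 0),
                             c(pneumonia = 6, normal = 0)),
               regexp = "pneumonia", class = "pneumonet_split_error")
})
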