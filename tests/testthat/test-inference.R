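test_that("activation assembly with stub models is exact inside the crop window", {
  s <- tiny_subject(5)
  stub <- stub_identity_model(depth = 4)
  for (o in c("sagittal", "coronal", "axial")) {
    act <- predict_orientation(stub, s$image, o)
    expect_identical(act$data, s$image$data)   # 64^3: no crop at depth 4
  }
  const <- stub_constant_model(0.7, depth = 3)
  act <- predict_orientation(const, s$image, "axial")
  expect_true(all(act$data == 0.7))
  # deterministic
  expect_identical(predict_orientation(stub, s$image, "coronal")$data,
                   predict_orientation(stub, s$image, "coronal")$data)
})

test_that("odd-sized volumes pad back exactly with zero margins", {
  set.seed(8)
  v <- minmax_normalize(image_volume(array(stats::runif(70 * 65 * 63),
                                           c(70, 65, 63))))
  stub <- stub_identity_model(depth = 4)
  act <- predict_orientation(stub, v, "sagittal")  # plane (65, 63) -> (64, 48)
  expect_identical(act$data[, 1:64, 8:55], v$data[, 1:64, 8:55])
  expect_true(all(act$data[, 65, ] == 0))
  expect_true(all(act$data[, , c(1:7, 56:63)] == 0))
  act2 <- predict_orientation(stub, v, "axial")    # plane (70, 65) -> (64, 64)
  expect_identical(act2$data[4:67, 1:64, ], v$data[4:67, 1:64, ])
  expect_true(all(act2$data[c(1:3, 68:70), , ] == 0))
})

test_that("consensus is the exact mean, commutative, and identity on equal inputs", {
  a <- array(stats::runif(4^3), c(4, 4, 4))
  b <- array(stats::runif(4^3), c(4, 4, 4))
  c3 <- array(stats::runif(4^3), c(4, 4, 4))
  expect_identical(consensus(a, a, a)$data, a)
  expect_equal(consensus(a, b, c3)$data, (a + b + c3) / 3, tolerance = 1e-12)
  expect_equal(consensus(b, c3, a)$data, consensus(a, b, c3)$data,
               tolerance = 1e-12)
  expect_equal(consensus(array(0, c(1, 1, 1)), array(0.5, c(1, 1, 1)),
                         array(1, c(1, 1, 1)))$data[1], 0.5)
  expect_error(consensus(a, b, array(0, c(2, 2, 2))), class = "e2d_shape_error")
})

test_that("binarization is strict and monotone in the threshold", {
  act <- array(c(0.4, 0.5, 0.6), c(3, 1, 1))
  expect_identical(as.vector(binarize(act, consensus_config(0.5))$data),
                   c(0L, 0L, 1L))
  expect_identical(sum(binarize(array(0, c(3, 3, 3)))$data), 0L)
  set.seed(2)
  a <- array(stats::runif(6^3), c(6, 6, 6))
  hi <- binarize(a, consensus_config(0.9))$data
  lo <- binarize(a, consensus_config(0.1))$data
  expect_true(all(hi <= lo))   # nested masks as the threshold decreases
})

test_that("largest-component filtering keeps the documented components", {
  m <- array(0L, c(20, 20, 20))
  m[1:5, 1:5, 1:5] <- 1L        # 125 voxels
  m[10:12, 1:4, 1:4] <- 1L      # 48 voxels
  m[18:19, 18:19, 18:19] <- 1L  # 8 voxels
  kept <- keep_largest_components(label_volume(m), 2)
  expect_identical(sum(kept$data), 125L + 48L)
  expect_identical(sum(kept$data[18:19, 18:19, 18:19]), 0L)
  # single component: unchanged
  single <- array(0L, c(6, 6, 6))
  single[2:4, 2:4, 2:4] <- 1L
  expect_identical(keep_largest_components(label_volume(single), 2)$data, single)
  # empty input, empty output
  expect_identical(sum(keep_largest_components(label_volume(array(0L, c(4, 4, 4))))$data), 0L)
  # two equal-size components plus a smaller third: both equals kept
  eq <- array(0L, c(12, 12, 12))
  eq[1:2, 1:2, 1:2] <- 1L
  eq[6:7, 6:7, 6:7] <- 1L
  eq[11, 11, 11] <- 1L
  kept2 <- keep_largest_components(label_volume(eq), 2)
  expect_identical(sum(kept2$data), 16L)
  expect_identical(kept2$data[11, 11, 11], 0L)
  # tie at the cut resolved toward the earlier scan-order component
  tie <- array(0L, c(10, 10, 10))
  tie[1:2, 1:2, 1:2] <- 1L   # 8, first in scan order
  tie[5:6, 5:6, 5:6] <- 1L   # 8
  tie[9:10, 9:10, 9:10] <- 1L # 8
  kept3 <- keep_largest_components(label_volume(tie), 2)
  expect_identical(sum(kept3$data[1:2, 1:2, 1:2]), 8L)
  expect_identical(sum(kept3$data[5:6, 5:6, 5:6]), 8L)
  expect_identical(sum(kept3$data[9:10, 9:10, 9:10]), 0L)
})

test_that("segment runs the full chain and returns native-space masks", {
  s <- tiny_subject(13)
  stubs <- list(sagittal = stub_identity_model(3), coronal = stub_identity_model(3),
                axial = stub_identity_model(3))
  raw <- generate_subject(phantom_spec(seed = 13))
  mask <- segment(raw$image, stubs, consensus_config(threshold = 0.55))
  expect_s3_class(mask, "label_volume")
  expect_identical(dim(mask$data), dim(raw$image$data))
  expect_equal(mask$affine, raw$image$affine)
  expect_lte(n_components_26(mask$data), 2)
  # all-zero stubs produce an empty mask without crashing
  zeros <- list(sagittal = stub_constant_model(0, 3),
                coronal = stub_constant_model(0, 3),
                axial = stub_constant_model(0, 3))
  expect_identical(sum(segment(raw$image, zeros)$data), 0L)
  # a missing orientation model is an ensemble error
  expect_error(segment(raw$image, stubs[c("sagittal", "coronal")]),
               class = "e2d_ensemble_error")
})
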