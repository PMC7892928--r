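test_that("soft Dice matches voxel-counting on binary masks and is bounded", {
  p <- numeric(16); g <- numeric(16)
  p[1:4] <- 1
  g[c(2, 3, 4, 7, 8, 9)] <- 1     # |P| = 4, |G| = 6, overlap 3
  expect_equal(soft_dice(p, g), 0.6, tolerance = 1e-6)
  expect_equal(dice_loss(p, g), 0.4, tolerance = 1e-6)
  expect_lt(dice_loss(g, g), 1e-5)
  expect_equal(soft_dice(g, g), 1, tolerance = 1e-6)  # perfect overlap
  expect_equal(soft_dice(c(1, 0), c(0, 1)), 0)        # disjoint
  # symmetry and bounds on random binary pairs
  set.seed(1)
  for (k in 1:20) {
    a <- as.numeric(stats::runif(32) > 0.5)
    b <- as.numeric(stats::runif(32) > 0.5)
    expect_equal(soft_dice(a, b), soft_dice(b, a))
    expect_gte(soft_dice(a, b), 0)
    expect_lte(soft_dice(a, b), 1)
  }
  expect_error(soft_dice(numeric(4), numeric(5)), class = "e2d_shape_error")
})

test_that("generalized Dice loss matches direct arithmetic and is label-symmetric", {
  gm <- array(c(1, 0, 0, 0), c(2, 2))
  g2 <- one_hot_target(gm)
  p2 <- array(0.5, c(2, 2, 2))
  eps <- 1e-6
  w <- c(1 / (3 + eps)^2, 1 / (1 + eps)^2)
  num <- w[1] * sum(0.5 * (1 - gm)) + w[2] * sum(0.5 * gm)
  den <- w[1] * sum(0.5 + 1 - gm) + w[2] * sum(0.5 + gm)
  expect_equal(generalized_dice_loss(p2, g2), 1 - 2 * num / den,
               tolerance = 1e-12)
  expect_equal(generalized_dice_loss(g2, g2), 0, tolerance = 1e-5)
  # swapping which channel is "foreground" leaves the value unchanged
  set.seed(2)
  pr <- array(stats::runif(2 * 3 * 3), c(2, 3, 3))
  gr <- one_hot_target(matrix(as.integer(stats::runif(9) > 0.6), 3, 3))
  expect_equal(generalized_dice_loss(pr, gr),
               generalized_dice_loss(pr[2:1, , ], gr[2:1, , ]))
  # correcting a wrong foreground pixel decreases the loss
  for (k in 1:10) {
    g <- matrix(as.integer(stats::runif(16) > 0.6), 4, 4)
    if (sum(g) == 0) next
    p <- array(stats::runif(32), c(2, 4, 4))
    s <- p[1, , ] + p[2, , ]
    p[1, , ] <- p[1, , ] / s
    p[2, , ] <- p[2, , ] / s
    i <- which(g == 1 & p[2, , ] < 0.5)[1]
    if (is.na(i)) next
    before <- generalized_dice_loss(p, one_hot_target(g))
    p[2, , ][i] <- 0.95
    p[1, , ][i] <- 0.05
    expect_lt(generalized_dice_loss(p, one_hot_target(g)), before)
  }
})

test_that("signed distance maps are Euclidean, signed, and zero on the inner boundary", {
  g <- matrix(0, 5, 5)
  g[3, 3] <- 1
  bf <- outer(1:5, 1:5, function(i, j) sqrt((i - 3)^2 + (j - 3)^2))
  expect_equal(signed_distance(g), bf, tolerance = 1e-12)
  g2 <- matrix(0, 6, 6)
  g2[2:5, 2:5] <- 1
  sd2 <- signed_distance(g2)
  expect_true(all(sd2[3:4, 3:4] < 0))              # strictly inside
  expect_true(all(sd2[2, 2:5] == 0))               # inner boundary
  expect_true(all(sd2[1, ] > 0))                   # outside
  expect_error(signed_distance(matrix(0, 4, 4)), class = "e2d_degenerate_error")
  expect_error(signed_distance(matrix(1, 4, 4)), class = "e2d_degenerate_error")
})

test_that("surface loss is the mean distance-weighted probability", {
  g <- matrix(0, 5, 5)
  g[2:4, 2:4] <- 1
  dmap <- signed_distance(g)
  expect_equal(surface_loss(matrix(0, 5, 5), dmap), 0)
  inside <- matrix(0, 5, 5)
  inside[3, 3] <- 1
  expect_lt(surface_loss(inside, dmap), 0)        # mass strictly inside
  # 3x3 worked example by direct arithmetic
  p3 <- matrix(seq(0.1, 0.9, by = 0.1), 3, 3)
  g3 <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  d3 <- signed_distance(g3)
  expect_equal(surface_loss(p3, d3), sum(p3 * d3) / 9, tolerance = 1e-12)
})

test_that("alpha schedule hits its endpoints and the boundary loss interpolates", {
  expect_identical(alpha_schedule(1, 7), 1)
  expect_identical(alpha_schedule(7, 7), 0)
  expect_equal(alpha_schedule(6, 11), 0.5)
  expect_true(all(diff(sapply(1:9, alpha_schedule, total_epochs = 9)) < 0))
  expect_error(alpha_schedule(0, 5), class = "e2d_schedule_error")
  expect_error(alpha_schedule(6, 5), class = "e2d_schedule_error")
  expect_error(loss_config("boundary", total_epochs = 1), class = "e2d_config_error")

  set.seed(3)
  gm <- matrix(0, 8, 8)
  gm[3:5, 3:6] <- 1
  p2 <- array(stats::runif(128), c(2, 8, 8))
  s <- p2[1, , ] + p2[2, , ]
  p2[1, , ] <- p2[1, , ] / s
  p2[2, , ] <- p2[2, , ] / s
  cfg <- loss_config("boundary", total_epochs = 9)
  gdl <- generalized_dice_loss(p2, one_hot_target(gm))
  surf <- surface_loss(p2[2, , ], signed_distance(gm))
  for (ep in 1:9) {
    a <- alpha_schedule(ep, 9)
    expect_equal(boundary_loss(p2, gm, ep, cfg), a * gdl + (1 - a) * surf,
                 tolerance = 1e-12)
  }
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(4)
  pr <- array(stats::runif(64), c(8, 8))
  gr <- matrix(as.integer(stats::runif(64) > 0.7), 8, 8)
  ga <- dice_loss_grad(pr, gr)
  gn <- num_grad(function(q) dice_loss(q, gr), pr)
  expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-8)), 1e-4)

  p2 <- array(stats::runif(128), c(2, 8, 8))
  g2 <- one_hot_target(gr)
  ga <- generalized_dice_loss_grad(p2, g2)
  gn <- num_grad(function(q) generalized_dice_loss(q, g2), p2)
  expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-8)), 1e-4)

  cfg <- loss_config("boundary", total_epochs = 5)
  ga <- boundary_loss_grad(p2, gr, 3, cfg)
  gn <- num_grad(function(q) boundary_loss(q, gr, 3, cfg), p2)
  expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-8)), 1e-4)
})
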