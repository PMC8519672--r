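test_that("dice_loss matches set counting and handles edge cases", {
  m <- matrix(0, 4, 4); m[2:3, 2:3] <- 1
  expect_equal(dice_loss(m, m), 0)
  disj <- matrix(0, 4, 4); disj[1, ] <- 1
  expect_equal(dice_loss(disj, m), 1)
  # |A| = 4, |B| = 4, |A n B| = 2 on a 4x4 grid
  a <- matrix(0, 4, 4); a[2, ] <- 1
  b <- matrix(0, 4, 4); b[2, 1:2] <- 1; b[3, 1:2] <- 1
  expect_equal(dice_loss(a, b), 0.5)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(1, 3, 3)), "shapes differ")
  z <- matrix(0, 3, 3)
  expect_equal(dice_loss(z, z), 0)  # both empty: smoothed to perfect
})

test_that("soft dice uses the continuous relaxation", {
  t <- matrix(c(1, 0, 0, 1), 2, 2)
  p <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2)
  expect_equal(dice_loss(p, t), 1 - 2 * (0.8 + 0.6) / (2 + 2))
})

test_that("signed_distance_map reproduces the worked 1D examples", {
  expect_equal(signed_distance_map(c(0, 0, 1, 0, 0)), c(2, 1, 0, 1, 2))
  expect_equal(signed_distance_map(c(0, 1, 1, 0)), c(1, 0, 0, 1))
  expect_error(signed_distance_map(c(0, 0, 0)), "all-background")
  expect_error(signed_distance_map(matrix(1, 2, 2)), "all-foreground")
})

test_that("signed_distance_map agrees with exhaustive nearest-boundary search", {
  set.seed(42)
  for (rep in 1:40) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    m <- random_mask(nr, nc)
    expect_equal(signed_distance_map(m), sdm_oracle(m), tolerance = 1e-9)
  }
  # interior pixels are strictly negative, background strictly positive
  m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
  phi <- signed_distance_map(m)
  expect_equal(phi[3, 3], -1)
  expect_true(all(phi[m == 0] > 0))
})

test_that("boundary_loss follows the worked examples and vanishes at the truth", {
  phi <- c(2, 1, 0, 1, 2)
  expect_equal(boundary_loss(rep(0, 5), phi), 0)
  expect_equal(boundary_loss(rep(1, 5), phi), 1.2)       # (2+1+0+1+2)/5
  expect_equal(boundary_loss(rep(1, 5), phi, "sum"), 6)
  expect_equal(boundary_loss(c(0, 0, 1, 0, 0), phi), 0)  # prediction equals G
  expect_error(boundary_loss(rep(1, 4), phi), "shapes differ")
})

test_that("boundary_loss is minimized by the ground-truth region", {
  set.seed(9)
  m <- matrix(0, 6, 6); m[2:5, 2:4] <- 1
  phi <- signed_distance_map(m)
  best <- (phi < 0) * 1 + (phi == 0) * 1   # indicator of G (phi <= 0)
  lb_best <- boundary_loss(best, phi)
  for (i in 1:100) {
    s <- matrix(runif(36), 6, 6)
    expect_gte(boundary_loss(s, phi), lb_best)
  }
})

test_that("composite_loss is the affine combination with weights summing to 1", {
  set.seed(4)
  m <- matrix(0, 6, 6); m[2:4, 3:5] <- 1
  p <- matrix(runif(36), 6, 6)
  phi <- signed_distance_map(m)
  ld <- dice_loss(p, m)
  lb <- boundary_loss(p, phi)
  expect_equal(composite_loss(p, m, loss_config(alpha = 1)), ld)
  expect_equal(composite_loss(p, m, loss_config(alpha = 0)), lb)
  for (a in c(0.1, 0.3, 0.7)) {
    expect_equal(composite_loss(p, m, loss_config(alpha = a)),
                 a * ld + (1 - a) * lb)
  }
  expect_error(loss_config(alpha = 1.5), "alpha")
})

test_that("Wasserstein losses follow their closed forms", {
  expect_equal(critic_loss(c(1, 1), c(0, 0)), -1)
  expect_equal(critic_loss(c(0), c(1)), 1)
  expect_equal(critic_loss(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_error(critic_loss(numeric(0), 1), "non-empty")
  set.seed(5)
  r <- rnorm(4); f <- rnorm(4)
  expect_equal(critic_loss(r, f), -critic_loss(f, r))
  expect_equal(generator_adv_loss(0.5), -0.5)
  expect_equal(generator_adv_loss(c(0, 0)), 0)
  expect_lt(generator_adv_loss(c(0.2, 0.9)), generator_adv_loss(c(0.2, 0.3)))
  expect_error(generator_adv_loss(numeric(0)), "non-empty")
})

test_that("ablation baselines follow their closed forms", {
  t <- matrix(c(1, 0, 0, 1), 2, 2)
  p <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2)
  inter <- 0.8 + 0.6
  expect_equal(iou_loss(p, t), 1 - inter / (sum(p) + 2 - inter))
  expect_equal(iou_loss(t, t), 0)
  expect_equal(iou_loss(1 - t, t), 1)
  expect_equal(bce_loss(t, t), 0, tolerance = 1e-5)
  expect_equal(bce_loss(p, t),
               -mean(t * log(p) + (1 - t) * log(1 - p)))
  expect_gt(bce_loss(1 - t, t), 10)
  # gradients match finite differences
  h <- 1e-6
  gi <- liverseg:::iou_loss_grad(p, t)
  gb <- liverseg:::bce_loss_grad(p, t)
  for (i in 1:4) {
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    expect_equal((iou_loss(pp, t) - iou_loss(pm, t)) / (2 * h), gi[i],
                 tolerance = 1e-5)
    expect_equal((bce_loss(pp, t) - bce_loss(pm, t)) / (2 * h), gb[i],
                 tolerance = 1e-4)
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(6)
  m <- matrix(0, 5, 5); m[2:4, 2:3] <- 1
  p <- matrix(runif(25, 0.05, 0.95), 5, 5)
  gd <- liverseg:::dice_loss_grad(p, m)
  phi <- signed_distance_map(m)
  gb <- liverseg:::boundary_loss_grad(phi, "mean")
  h <- 1e-6
  for (i in sample(25, 6)) {
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    expect_equal((dice_loss(pp, m) - dice_loss(pm, m)) / (2 * h), gd[i],
                 tolerance = 1e-5)
    expect_equal((boundary_loss(pp, phi) - boundary_loss(pm, phi)) / (2 * h),
                 gb[i], tolerance = 1e-5)
  }
})
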