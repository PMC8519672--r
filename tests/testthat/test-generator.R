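test_that("layer parameter counts follow the biased closed forms", {
  # Cin * K * Cout + Cout for convolutions, Fin * Fout + Fout for FC
  expect_equal(count_parameters(liverseg:::conv3d(3, 32, kernel = c(1, 3, 3))), 896)
  expect_equal(count_parameters(liverseg:::linear_layer(32, 1)), 33)
  expect_equal(count_parameters(liverseg:::nn_sequential(list())), 0)
  set.seed(1)
  for (i in 1:5) {
    cin <- sample(1:16, 1); cout <- sample(1:16, 1)
    k <- sample(c(1, 3), 3, replace = TRUE)
    expect_equal(count_parameters(liverseg:::conv3d(cin, cout, kernel = k)),
                 cin * prod(k) * cout + cout)
  }
})

test_that("series and full3d convolution blocks have the published counts", {
  expect_equal(count_parameters(series_conv_block(32, 32, "series")),
               32 * 9 * 32 + 32 + 32 * 3 * 32 + 32)  # 12352
  expect_equal(count_parameters(series_conv_block(32, 32, "series")), 12352)
  expect_equal(count_parameters(series_conv_block(128, 128, "full3d")), 442496)
  expect_equal(count_parameters(upsample_block(256, 512, "full3d")), 3539456)
  expect_error(series_conv_block(8, 8, "bogus"))
})

test_that("convolution blocks preserve spatial shape in both modes", {
  x <- array(rnorm(4 * 16 * 16 * 3 * 2), c(4, 16, 16, 3, 2))
  for (mode in c("series", "full3d")) {
    blk <- series_conv_block(4, 6, mode)
    expect_equal(dim(nn_forward(blk, x)), c(6, 16, 16, 3, 2))
  }
})

test_that("downsampling halves and upsampling doubles the in-plane size", {
  x <- array(rnorm(2 * 64 * 64 * 3), c(2, 64, 64, 3, 1))
  down <- downsample_block(2, 5)
  y <- nn_forward(down, x)
  expect_equal(dim(y), c(5, 32, 32, 3, 1))
  up <- upsample_block(5, 2)
  z <- nn_forward(up, y)
  expect_equal(dim(z), c(2, 64, 64, 3, 1))
  # four downsamplings: 128 -> 8
  x128 <- array(rnorm(2 * 128 * 128 * 1), c(2, 128, 128, 1, 1))
  for (i in 1:4) x128 <- nn_forward(downsample_block(2, 2), x128)
  expect_equal(dim(x128)[2:3], c(8, 8))
})

test_that("CRP blocks preserve shape, reduce to identity with zero weights, and are deterministic in eval", {
  x <- array(rnorm(32 * 16 * 16 * 1), c(32, 16, 16, 1, 1))
  cb <- crp_block(32, dropout_rate = 0.5)
  y <- nn_forward(cb, x)
  expect_equal(dim(y), dim(x))
  for (ly in liverseg:::nn_collect(cb)) {
    if (inherits(ly, "conv3d")) { ly$params$W[] <- 0; ly$params$b[] <- 0 }
  }
  expect_equal(nn_forward(cb, x), x, tolerance = 1e-12)
  cb2 <- crp_block(8, dropout_rate = 0.5)
  x2 <- array(rnorm(8 * 16 * 16 * 3 * 2), c(8, 16, 16, 3, 2))
  expect_identical(nn_forward(cb2, x2, training = FALSE),
                   nn_forward(cb2, x2, training = FALSE))
})

test_that("the built generator maps triplets to centre-slice probabilities", {
  set.seed(11)
  g <- build_generator(tiny_arch())
  x <- array(runif(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  p <- generator_forward(g, x)
  expect_equal(dim(p), c(2, 1, 64, 64))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(generator_forward(g, x), p)  # eval determinism
})

test_that("non-multiple-of-16 inputs are padded with a note and cropped back", {
  set.seed(12)
  g <- build_generator(tiny_arch())
  x <- array(runif(1 * 3 * 24 * 24), c(1, 3, 24, 24))
  expect_message(p <- generator_forward(g, x), "zero-padding")
  expect_equal(dim(p), c(1, 1, 24, 24))
})

test_that("encoder stage widths are readable from the built model", {
  g <- build_generator(tiny_arch())
  expect_equal(encoder_channels(g), c(2L, 2L, 4L, 4L, 4L))
})

test_that("every parameter receives a finite gradient and matches finite differences", {
  set.seed(13)
  spec <- arch_spec(stage_channels = c(2, 2, 2, 2, 2), dropout_rate = 0,
                    crp_kernel = c(1, 1, 1))  # no pooling kinks
  g <- build_generator(spec)
  x <- array(runif(1 * 3 * 16 * 16), c(1, 3, 16, 16))
  m <- matrix(0, 16, 16); m[5:10, 6:12] <- 1
  phi <- signed_distance_map(m)
  loss_fn <- function() {
    p <- generator_forward(g, x, training = TRUE)[1, 1, , ]
    0.1 * dice_loss(p, m) + 0.9 * boundary_loss(p, phi)
  }
  loss_fn()
  p <- generator_forward(g, x, training = TRUE)[1, 1, , ]
  grad <- 0.1 * liverseg:::dice_loss_grad(p, m) + 0.9 * liverseg:::boundary_loss_grad(phi)
  generator_backward(g, array(grad, c(1, 1, 16, 16)))
  refs <- liverseg:::nn_param_refs(g)
  for (r in refs) {
    expect_true(all(is.finite(r$env$grads[[r$name]])))
  }
  set.seed(14)
  for (ri in sample(length(refs), 8)) {
    r <- refs[[ri]]
    i <- sample(length(r$env$params[[r$name]]), 1)
    ng <- liverseg:::nn_numeric_grad(loss_fn, r$env, r$name, i, h = 1e-5)
    expect_equal(r$env$grads[[r$name]][i], ng, tolerance = 1e-4)
  }
})

test_that("zeroing a skip feature changes the decoder output", {
  set.seed(15)
  g <- build_generator(tiny_arch())
  x <- array(runif(1 * 3 * 32 * 32), c(1, 3, 32, 32))
  base <- generator_forward(g, x)
  for (s in 1:4) {
    expect_gt(max(abs(generator_forward(g, x, zero_skips = s) - base)), 0)
  }
})

test_that("two-channel softmax head yields probabilities summing to one", {
  set.seed(16)
  g <- build_generator(tiny_arch(out_channels = 2L))
  x <- array(runif(1 * 3 * 16 * 16), c(1, 3, 16, 16))
  p <- generator_forward(g, x)
  expect_equal(dim(p), c(1, 2, 16, 16))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[1, 1, , ] + p[1, 2, , ], matrix(1, 16, 16), tolerance = 1e-12)
})
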