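test_that("segment_series cuts equal frames and drops the remainder", {
  f <- segment_series(1:12, 3)
  expect_equal(f, matrix(1:12, 3, 4, byrow = TRUE))
  f2 <- segment_series(1:10, 3)
  expect_equal(ncol(f2), 3L)
  expect_equal(as.vector(t(f2)), 1:9)  # last sample dropped, order kept
  f3 <- segment_series(rnorm(7), 1)
  expect_equal(nrow(f3), 1L)
  expect_equal(ncol(f3), 7L)
  expect_error(segment_series(1:5, 6), "cannot cut 5")
})

test_that("lstm_step matches hand-evaluated zero and scalar cases", {
  zero_cell <- list(Wx = matrix(0, 2, 8), Wh = matrix(0, 2, 8), b = rep(0, 8))
  out <- lstm_step(c(1, -1), c(0, 0), c(0, 0), zero_cell)
  expect_equal(out$c, c(0, 0))
  expect_equal(out$h, c(0, 0))
  one_cell <- list(Wx = matrix(1, 1, 4), Wh = matrix(1, 1, 4), b = 0 * 1:4)
  out <- lstm_step(0, 0, 1, one_cell)
  expect_equal(out$c, 0.5, tolerance = 1e-12)
  expect_equal(out$h, 0.5 * tanh(0.5), tolerance = 1e-12)
  expect_error(lstm_step(c(1, 2, 3), c(0, 0), c(0, 0), zero_cell),
               "shape mismatch")
})

test_that("lstm_step equals the straight-line five-equation oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:5, 1); u <- sample(1:4, 1)
    cell <- list(Wx = matrix(rnorm(n * 4 * u), n, 4 * u),
                 Wh = matrix(rnorm(u * 4 * u), u, 4 * u),
                 b = rnorm(4 * u))
    x <- rnorm(n); h <- rnorm(u); cc <- rnorm(u)
    got <- lstm_step(x, h, cc, cell)
    ref <- lstm_step_ref(x, h, cc, cell)
    expect_lt(max(abs(got$h - ref$h)), 1e-6)
    expect_lt(max(abs(got$c - ref$c)), 1e-6)
  }
})

test_that("encode at T=1 reduces to a single lstm_step per direction", {
  enc <- encoder_params(input_size = 5, hidden_size = 3, num_layers = 1,
                        bidirectional = TRUE, seed = 3)
  x <- matrix(rnorm(5), 1, 5)
  H <- encode(x, enc)$H
  f <- lstm_step(drop(x), rep(0, 3), rep(0, 3), enc$layers[[1]]$fwd)
  b <- lstm_step(drop(x), rep(0, 3), rep(0, 3), enc$layers[[1]]$bwd)
  expect_equal(drop(H), c(f$h, b$h), tolerance = 1e-12)
})

test_that("input reversal changes a unidirectional encoding and time-reverses a symmetric bidirectional one", {
  enc1 <- encoder_params(4, hidden_size = 3, num_layers = 1,
                         bidirectional = FALSE, seed = 5)
  fr <- matrix(rnorm(12), 3, 4)
  expect_false(isTRUE(all.equal(encode(fr, enc1)$H,
                                encode(fr[3:1, ], enc1)$H)))
  # bidirectional encoder with tied direction weights: reversing the input
  # swaps the two direction blocks, time-reversed
  enc2 <- encoder_params(4, hidden_size = 3, num_layers = 1,
                         bidirectional = TRUE, seed = 5)
  enc2$layers[[1]]$bwd <- enc2$layers[[1]]$fwd
  H <- encode(fr, enc2)$H
  Hr <- encode(fr[3:1, ], enc2)$H
  swapped <- cbind(H[3:1, 4:6], H[3:1, 1:3])
  expect_equal(Hr, swapped, tolerance = 1e-12)
})

test_that("default encoder matches the reference shape: 3 bidirectional layers of 16 units", {
  m <- proto_model()
  expect_equal(m$encoder$num_layers, 3L)
  expect_equal(m$encoder$hidden_size, 16L)
  expect_true(m$encoder$bidirectional)
  expect_equal(m$config$u, 32L)
})

test_that("hidden states stay strictly inside (-1, 1) and encode is reproducible", {
  enc <- encoder_params(6, hidden_size = 4, num_layers = 2, seed = 1)
  set.seed(7)
  for (rep in 1:10) {
    fr <- matrix(rnorm(5 * 6, sd = 10^runif(1, -1, 2)), 5, 6)
    H <- encode(fr, enc)$H
    expect_true(all(abs(H) < 1))
    expect_identical(H, encode(fr, enc)$H)
  }
})

test_that("attend reproduces hand-evaluated softmax pooling", {
  att <- attention_params(u = 2, d_alpha = 2, seed = 1)
  att$W <- diag(2); att$b <- c(0, 0); att$V <- c(1, 0)
  H <- rbind(c(0, 0), c(log(3), 0))
  out <- attend(H, att)
  expect_equal(out$alpha, c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(out$e, c(0.75 * log(3), 0), tolerance = 1e-12)
  # singleton softmax
  out1 <- attend(H[1, , drop = FALSE], att)
  expect_equal(out1$alpha, 1)
  expect_equal(out1$e, H[1, ])
  # identical states: uniform weights
  Hc <- rbind(c(1, 2), c(1, 2), c(1, 2))
  outc <- attend(Hc, att)
  expect_equal(outc$alpha, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(outc$e, c(1, 2), tolerance = 1e-12)
  expect_error(attend(H[0, , drop = FALSE], att), "no time steps")
})

test_that("attention weights are a probability vector over 1000 random draws", {
  set.seed(99)
  for (rep in 1:1000) {
    u <- sample(2:4, 1); T_ <- sample(1:6, 1)
    att <- attention_params(u, d_alpha = 3, seed = rep)
    H <- matrix(rnorm(T_ * u, sd = 3), T_, u)
    out <- attend(H, att)
    expect_lt(abs(sum(out$alpha) - 1), 1e-6)
    expect_gte(min(out$alpha), 0)
  }
})
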