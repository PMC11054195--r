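test_that("generator is deterministic and balanced under a fixed seed", {
  cfg <- synthetic_config(n_per_class = 20L, seed = 9L)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$data$x, g2$data$x)
  expect_identical(g1$data$y, g2$data$y)
  expect_equal(n_beats(g1$data), 60L)
  expect_equal(as.integer(table(g1$data$y)), c(20L, 20L, 20L))
  expect_equal(g1$data$classes, c("N", "A", "O"))
  g3 <- generate_dataset(synthetic_config(n_per_class = 20L, seed = 10L))
  expect_false(identical(g1$data$x, g3$data$x))
})

test_that("class morphology follows the recipes: P waves in N, fibrillation in A", {
  gen <- generate_dataset(synthetic_config(n_per_class = 50L, seed = 3L))
  kinds <- function(r) vapply(r$components, `[[`, character(1L), "kind")
  for (r in gen$recipes) {
    if (r$class == "N") {
      expect_true("P" %in% kinds(r))
      expect_false("fibrillatory" %in% kinds(r))
    }
    if (r$class == "A") {
      expect_false("P" %in% kinds(r))
      expect_true("fibrillatory" %in% kinds(r))
    }
  }
})

test_that("recipe parameters stay inside the configured ranges", {
  gen <- generate_dataset(synthetic_config(n_per_class = 400L, seed = 5L))
  for (r in gen$recipes) {
    rg <- protobeat:::beat_ranges(r$class)
    for (cmp in r$components) {
      p <- rg[[cmp$kind]]
      if (cmp$kind == "fibrillatory") {
        expect_gte(cmp$freq, p$freq[1]); expect_lte(cmp$freq, p$freq[2])
        expect_gte(cmp$amplitude, p$amplitude[1])
        expect_lte(cmp$amplitude, p$amplitude[2])
      } else {
        expect_gte(cmp$center, p$center[1]); expect_lte(cmp$center, p$center[2])
        expect_gte(cmp$width, p$width[1]); expect_lte(cmp$width, p$width[2])
        expect_gte(cmp$amplitude, p$amplitude[1])
        expect_lte(cmp$amplitude, p$amplitude[2])
      }
    }
  }
})

test_that("identical recipe renders an identical waveform and noise-free peaks sit in the QRS window", {
  cfg <- synthetic_config(noise_sd = 0, n_per_class = 5L, seed = 2L)
  gen <- generate_dataset(cfg)
  r <- gen$recipes[[1L]]
  expect_identical(synth_beat(r, cfg), synth_beat(r, cfg))
  # class-N beat with dominant QRS: maximum inside the QRS support window
  rN <- gen$recipes[[which(sapply(gen$recipes, `[[`, "class") == "N")[1L]]]
  w <- synth_beat(rN, cfg)
  qrs <- rN$components[[which(sapply(rN$components, `[[`, "kind") == "QRS")]]
  peak_t <- (which.max(abs(w)) - 1L) / cfg$sample_rate
  expect_lt(abs(peak_t - qrs$center), 4 * qrs$width)
})

test_that("signal amplitude is bounded by component amplitudes plus noise", {
  cfg <- synthetic_config(n_per_class = 100L, seed = 8L)
  gen <- generate_dataset(cfg)
  n_bad <- 0L
  for (i in seq_along(gen$recipes)) {
    amp_sum <- sum(vapply(gen$recipes[[i]]$components, function(c)
      abs(c$amplitude) * 1.5, numeric(1L)))  # 1.5 covers the fib modulation
    bound <- amp_sum + 6 * cfg$noise_sd
    n_bad <- n_bad + sum(abs(gen$data$x[i, ]) > bound)
  }
  expect_lt(n_bad / length(gen$data$x), 0.001)
})

test_that("a nearest-centroid classifier separates the default classes", {
  gen <- generate_dataset(synthetic_config(seed = 17L))
  sp <- split_dataset(gen$data, training_config(seed = 17L))
  cent <- sapply(sort(unique(sp$train$y)), function(c)
    colMeans(sp$train$x[sp$train$y == c, , drop = FALSE]))
  pred <- apply(sp$test$x, 1L, function(r) which.min(colSums((cent - r)^2)) - 1L)
  expect_gt(mean(pred == sp$test$y), 0.80)
})

test_that("tiny fixture is deterministic and threshold-separable on the P window", {
  f1 <- fixture_tiny()
  f2 <- fixture_tiny()
  expect_identical(f1$data$x, f2$data$x)
  expect_equal(n_beats(f1$data), 60L)
  expect_equal(f1$data$classes, c("N", "A"))
  # P-window peak (0.05-0.15 s at 300 Hz): N beats high, A beats low
  pwin <- 16:45
  feat <- apply(f1$data$x[, pwin], 1L, max)
  expect_gt(min(feat[f1$data$y == 0L]), max(feat[f1$data$y == 1L]))
})
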