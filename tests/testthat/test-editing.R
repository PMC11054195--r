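# a small trained-ish model plus data shared across editing tests
editing_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_tiny()
      m <- proto_model(n_prototypes = 4, classes = fx$data$classes, seed = 5)
      res <- fit(m, fx$data, fx$data,
                 training_config(batch_size = 16, epochs = 12, seed = 5))
      cache <<- list(model = res$model, data = fx$data)
    }
    cache
  }
})

test_that("projection matches the exhaustive nearest-neighbor scan", {
  ef <- editing_fixture()
  pr <- project_prototypes(ef$model, ef$data)
  E <- embed_dataset(ef$model, ef$data)
  ref <- project_ref(ef$model$prototypes, E)
  expect_equal(pr$map$exemplar_index, ref$index)
  expect_equal(pr$map$distance, ref$distance, tolerance = 1e-9)
  # a prototype placed exactly on an embedding projects to it at distance 0
  m2 <- ef$model
  m2$prototypes[1, ] <- E[7, ]
  pr2 <- project_prototypes(m2, ef$data)
  expect_equal(pr2$map$exemplar_index[1], 7L)
  expect_equal(pr2$map$distance[1], 0)
})

test_that("snap projection makes every prototype an observable waveform's image", {
  ef <- editing_fixture()
  pr <- project_prototypes(ef$model, ef$data, snap = TRUE)
  E <- embed_dataset(pr$model, ef$data)
  expect_equal(pr$model$prototypes,
               E[pr$map$exemplar_index, , drop = FALSE], tolerance = 1e-12)
  # querying an exemplar's own waveform ranks its prototype first with s = 1
  k <- 1L
  q <- ef$data$x[pr$map$exemplar_index[k], ]
  rep <- explain(pr$model, q, top_m = 4)
  expect_equal(rep$all_rows$id[1], pr$map$id[k])
  expect_gt(rep$all_rows$similarity[1], 0.999)
})

test_that("explanations decompose the predicted logit exactly", {
  ef <- editing_fixture()
  for (i in c(1, 25, 60)) {
    rep <- explain(ef$model, ef$data$x[i, ], top_m = 2)
    expect_lt(abs(rep$contribution_total - rep$z[rep$label + 1]), 1e-9)
    expect_equal(nrow(rep$rows), 2L)
    expect_true(all(diff(rep$all_rows$similarity) <= 0))
  }
  m1 <- toy_model(seed = 4, C = 2, K = 1)
  x <- toy_batch(1, B = 1)$X[1, ]
  rep1 <- explain(m1, x, top_m = 1)
  expect_lt(abs(rep1$rows$contribution[1] - rep1$z[rep1$label + 1]), 1e-9)
  expect_warning(explain(m1, x, top_m = 5), "clamped")
})

test_that("candidate filtering equals the brute-force rule, boundary inclusive", {
  ef <- editing_fixture()
  E <- embed_dataset(ef$model, ef$data)
  for (dmin in c(0.5, 2.0, 5.0)) {
    got <- filter_candidates(ef$data, ef$model, dmin)
    expect_equal(as.integer(got), filter_ref(E, ef$model$prototypes, dmin))
  }
  # a signal whose embedding equals a prototype is excluded (distance 0)
  m2 <- ef$model
  m2$prototypes[1, ] <- E[3, ]
  expect_false(3L %in% filter_candidates(ef$data, m2, dmin = 0.1))
  # boundary: distance exactly dmin is retained
  mind <- attr(filter_candidates(ef$data, ef$model, 0), "min_distance")
  got <- filter_candidates(ef$data, ef$model, dmin = mind[5])
  expect_true(5L %in% got)
  # empty prototype set retains everything
  m0 <- ef$model
  m0$prototypes <- m0$prototypes[0, , drop = FALSE]
  expect_equal(as.integer(filter_candidates(ef$data, m0, 2)), 1:60)
})

test_that("adding a prototype is non-destructive until fine-tuning", {
  ef <- editing_fixture()
  queries <- ef$data$x[seq(1, 60, by = 3), ]
  z_before <- t(apply(queries, 1, function(q) forward(ef$model, q)$z))
  m2 <- add_prototype(ef$model, ef$data$x[2, ], class_hint = "N",
                      note = "expert add")
  expect_equal(m2$config$K, ef$model$config$K + 1L)
  expect_equal(ncol(m2$W), ncol(ef$model$W) + 1L)
  expect_true(all(m2$W[, ncol(m2$W)] == 0))
  expect_equal(m2$proto_meta$provenance[m2$config$K], "expert")
  z_after <- t(apply(queries, 1, function(q) forward(m2, q)$z))
  expect_lt(max(abs(z_after - z_before)), 1e-6)
  # duplicating the just-added prototype is rejected
  expect_error(add_prototype(m2, ef$data$x[2, ]), "duplicate")
  entry <- m2$edit_log[[length(m2$edit_log)]]
  expect_equal(entry$operation, "add")
  expect_equal(entry$post_K, entry$pre_K + 1L)
})

test_that("removal subtracts exactly the missing similarity term and guards apply", {
  ef <- editing_fixture()
  q <- ef$data$x[10, ]
  pred <- forward(ef$model, q)
  k <- 2L
  m2 <- remove_prototype(ef$model, k)
  pred2 <- forward(m2, q)
  expect_equal(pred2$z, pred$z - ef$model$W[, k] * pred$s[k],
               tolerance = 1e-12)
  expect_equal(m2$config$K, ef$model$config$K - 1L)
  # re-adding an equivalent vector restores K
  m3 <- add_prototype(m2, ef$data$x[50, ])
  expect_equal(m3$config$K, ef$model$config$K)
  # guards
  m1 <- toy_model(seed = 2, K = 1)
  expect_error(remove_prototype(m1, 1), "last prototype")
  mv <- validate_prototype(ef$model, 1)
  expect_error(remove_prototype(mv, 1), "validated")
  expect_equal(remove_prototype(mv, 1, force = TRUE)$config$K,
               ef$model$config$K - 1L)
})

test_that("validated prototypes freeze through fine-tuning; unfrozen ones move", {
  ef <- editing_fixture()
  mv <- validate_prototype(ef$model, 3)
  expect_true(mv$proto_meta$validated[3])
  mft <- fine_tune(mv, ef$data, epochs = 1,
                   config = training_config(batch_size = 16, seed = 11))
  expect_identical(mft$prototypes[3, ], mv$prototypes[3, ])
  expect_false(isTRUE(all.equal(mft$prototypes[1, ], mv$prototypes[1, ])))
  expect_identical(fine_tune(mv, ef$data, epochs = 0), mv)
})

test_that("pruning removes a zero-scoring duplicate but keeps essential and validated prototypes", {
  ef <- editing_fixture()
  acc0 <- evaluate(ef$model, ef$data)$accuracy
  # inject a redundant prototype: copy of p1's vector with a zero head
  # column, so its leave-one-out score is exactly 0
  m2 <- ef$model
  m2$prototypes <- rbind(m2$prototypes, m2$prototypes[1, ] + 1e-6)
  m2$W <- cbind(m2$W, 0)
  meta <- protobeat:::new_proto_meta(1L, provenance = "expert")
  meta$id <- "p99"
  m2$proto_meta <- rbind(m2$proto_meta, meta)
  m2$config$K <- m2$config$K + 1L
  mp <- prune_prototypes(m2, ef$data, editing_config())
  expect_false("p99" %in% mp$proto_meta$id)
  expect_gte(evaluate(mp, ef$data)$accuracy, acc0)  # greedy rule never hurts
  expect_gte(mp$config$K, mp$config$C)
  # validated prototypes survive pruning regardless of score
  m3 <- m2
  m3 <- validate_prototype(m3, which(m3$proto_meta$id == "p99"))
  mp3 <- prune_prototypes(m3, ef$data, editing_config())
  expect_true("p99" %in% mp3$proto_meta$id)
})

test_that("edit-log replay on the same base model reproduces metadata and predictions", {
  ef <- editing_fixture()
  base <- ef$model
  m2 <- add_prototype(base, ef$data$x[4, ], class_hint = "N", note = "a1")
  m2 <- validate_prototype(m2, 1, note = "ok")
  m2 <- remove_prototype(m2, 2, note = "drop")
  path <- file.path(tempdir(), "edits.jsonl")
  write_edit_log(m2, path)
  entries <- read_edit_log(path)
  expect_length(entries, 3L)
  m3 <- replay_edit_log(base, entries)
  expect_equal(m3$config$K, m2$config$K)
  expect_equal(m3$proto_meta, m2$proto_meta)
  q <- ef$data$x[30, ]
  expect_equal(forward(m3, q)$z, forward(m2, q)$z, tolerance = 1e-12)
})
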