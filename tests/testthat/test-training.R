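make_random_dataset <- function(N, C, L = 30, seed = 1) {
  set.seed(seed)
  beat_dataset(matrix(rnorm(N * L), N, L), rep(0:(C - 1), length.out = N),
               classes = c("N", "A", "O")[1:C])
}

test_that("stratified split honors the 70/10/20 fractions and is seeded", {
  data <- make_random_dataset(1000, 2)
  tc <- training_config(seed = 5)
  sp <- split_dataset(data, tc)
  expect_equal(n_beats(sp$train), 700L)
  expect_equal(n_beats(sp$val), 100L)
  expect_equal(n_beats(sp$test), 200L)
  # disjoint and exhaustive
  all_ids <- sort(c(sp$train$ids, sp$val$ids, sp$test$ids))
  expect_equal(all_ids, sort(data$ids))
  expect_equal(anyDuplicated(all_ids), 0L)
  sp2 <- split_dataset(data, tc)
  expect_identical(sp$train$ids, sp2$train$ids)
  sp3 <- split_dataset(data, training_config(seed = 6))
  expect_false(identical(sp$train$ids, sp3$train$ids))
})

test_that("every class reaches every subset and tiny classes warn", {
  data <- make_random_dataset(300, 3)
  sp <- split_dataset(data, training_config(seed = 2))
  for (part in sp) expect_equal(sort(unique(part$y)), 0:2)
  few <- subset_beats(data, c(which(data$y == 0), which(data$y == 1)[1:2]))
  expect_warning(split_dataset(few, training_config(seed = 2)), "best-effort")
})

test_that("zero epochs is a no-op with empty history", {
  m <- toy_model(seed = 3)
  data <- make_random_dataset(20, 2)
  res <- fit(m, data, data, training_config(epochs = 0))
  expect_identical(protobeat:::param_list(res$model),
                   protobeat:::param_list(m))
  expect_equal(nrow(res$history), 0L)
})

test_that("training on the fixture reduces the loss and is bit-reproducible", {
  fx <- fixture_tiny()
  tc <- training_config(batch_size = 16, epochs = 10, seed = 7)
  m <- proto_model(n_prototypes = 4, classes = fx$data$classes, seed = 7)
  res <- fit(m, fx$data, fx$data, tc)
  expect_lt(res$history$total[10], res$history$total[1])
  res2 <- fit(m, fx$data, fx$data, tc)
  expect_identical(res$history, res2$history)
  expect_identical(protobeat:::param_list(res$model),
                   protobeat:::param_list(res2$model))
  # returned model carries the best validation accuracy seen
  final_acc <- res$history$val_accuracy[10]
  best_acc <- evaluate(res$model, fx$data)$accuracy
  expect_gte(best_acc, final_acc)
})

test_that("frozen prototypes stay fixed through fit while free ones move", {
  fx <- fixture_tiny()
  m <- proto_model(n_prototypes = 3, classes = fx$data$classes, seed = 9)
  m <- validate_prototype(m, 2)
  res <- fit(m, fx$data, NULL, training_config(batch_size = 16, epochs = 2,
                                               seed = 9),
             init_prototypes = FALSE)
  expect_identical(res$final_model$prototypes[2, ], m$prototypes[2, ])
  expect_false(isTRUE(all.equal(res$final_model$prototypes[1, ],
                                m$prototypes[1, ])))
})

test_that("metrics match hand confusion-matrix arithmetic", {
  conf <- rbind(c(2, 0, 0), c(1, 1, 0), c(0, 0, 2))
  met <- protobeat:::metrics_from_confusion(conf)
  expect_equal(met$accuracy, 5 / 6)
  expect_equal(met$per_class_precision, c(2 / 3, 1, 1))
  expect_equal(met$per_class_recall, c(1, 1 / 2, 1))
  expect_equal(met$macro_precision, mean(c(2 / 3, 1, 1)))
  expect_equal(met$macro_recall, mean(c(1, 0.5, 1)))
  # class receiving no predictions contributes precision 0
  conf2 <- rbind(c(2, 0), c(1, 0))
  met2 <- protobeat:::metrics_from_confusion(conf2)
  expect_equal(met2$per_class_precision, c(2 / 3, 0))
})

test_that("rank-statistic ROC-AUC matches separation and an independent implementation", {
  expect_equal(protobeat:::auc_rank(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_true(is.na(protobeat:::auc_rank(c(0.9, 0.8), c(1, 1))))
  set.seed(15)
  scores <- runif(60)
  y <- rbinom(60, 1, 0.4)
  got <- protobeat:::auc_rank(scores, y)
  # brute-force pair counting oracle
  pos <- scores[y == 1]; neg <- scores[y == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(got, mean(pairs), tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE)))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("evaluate reports perfect metrics for a perfectly fitted fixture model", {
  fx <- fixture_tiny()
  tc <- training_config(batch_size = 16, epochs = 25, seed = 3)
  m <- proto_model(n_prototypes = 4, classes = fx$data$classes, seed = 3)
  res <- fit(m, fx$data, fx$data, tc)
  met <- evaluate(res$model, fx$data)
  expect_equal(met$accuracy, 1.0)
  expect_equal(met$macro_f1, 1.0)
  expect_equal(met$roc_auc, 1.0)
  expect_equal(diag(met$confusion), c(N = 30L, A = 30L))
})
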