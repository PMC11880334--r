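test_that("split sizes follow the floor / round-half-up / remainder rule", {
  labs90 <- rep(1:3, each = 30)
  sp <- stratified_split(labs90, seed = 1)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 63L, val = 14L, test = 13L))
  labs20 <- rep(1:2, each = 10)
  sp20 <- stratified_split(labs20, seed = 1)
  expect_equal(lengths(sp20[c("train", "val", "test")]),
               c(train = 14L, val = 3L, test = 3L))
  # degenerate all-train fractions
  spall <- stratified_split(labs20, fractions = c(1, 0, 0), seed = 1)
  expect_equal(length(spall$train), 20)
  # the size rule holds for every n in [10, 500] (2-class balanced-ish data)
  for (n in seq(10, 500, by = 7)) {
    labs <- rep_len(1:2, n)
    s <- stratified_split(labs, seed = 2)
    expect_equal(length(s$train), floor(0.70 * n + 1e-9))
    expect_equal(length(s$val), floor(0.15 * n + 0.5 + 1e-9))
    expect_equal(length(s$train) + length(s$val) + length(s$test), n)
  }
})

test_that("splits are disjoint, exhaustive and stratified within one item", {
  set.seed(30)
  labs <- sample(1:3, 120, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  sp <- stratified_split(labs, seed = 3)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_equal(sort(all_idx), seq_along(labs))
  expect_equal(anyDuplicated(all_idx), 0L)
  for (part in c("train", "val", "test")) {
    got <- table(factor(labs[sp[[part]]], levels = 1:3))
    want <- length(sp[[part]]) * table(factor(labs, levels = 1:3)) / length(labs)
    expect_lte(max(abs(got - want)), 1)
  }
  expect_error(stratified_split(c(1, 1, 1, 2), seed = 1), "3 items")
})

test_that("kfold partitions are disjoint, exhaustive and seeded", {
  labs <- rep(1:3, each = 30)
  folds <- kfold_split(labs, k = 5, seed = 4)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:90)
  expect_true(all(lengths(tests) == 18))
  for (f in folds) expect_equal(sort(c(f$train, f$test)), 1:90)
  expect_identical(kfold_split(labs, 5, seed = 4), folds)
  expect_error(kfold_split(1:3, k = 5), "exceeds")
})

test_that("augmentation preserves shape; neutral draws are the identity", {
  img <- random_rgb(20, 20, seed = 31)
  out <- augment(img, seed = 5)
  expect_equal(dim(out), dim(img))
  expect_s3_class(out, "rgb_image")
  # neutral parameters reproduce the input exactly
  neutral <- list(angle = 0, flip_h = FALSE, flip_v = FALSE,
                  brightness = 1, zoom = 1)
  x <- array(as.numeric(img), dim(img))
  expect_equal(burnscope:::.apply_augment(x, neutral), x)
  # brightness acts multiplicatively before clipping
  bright <- list(angle = 0, flip_h = FALSE, flip_v = FALSE,
                 brightness = 1.2, zoom = 1)
  mid <- array(100, c(4, 4, 3))
  expect_true(all(burnscope:::.apply_augment(mid, bright) == 120))
})

test_that("cross-entropy matches its closed forms and is monotone", {
  y <- diag(3)
  expect_equal(categorical_crossentropy(y, y), 0, tolerance = 1e-10)
  p_unif <- matrix(1 / 3, 3, 3)
  expect_equal(categorical_crossentropy(y, p_unif), log(3))
  # moving mass toward the truth lowers the loss
  p1 <- matrix(c(0.5, 0.25, 0.25), 1)
  p2 <- matrix(c(0.7, 0.15, 0.15), 1)
  y1 <- matrix(c(1, 0, 0), 1)
  expect_lt(categorical_crossentropy(y1, p2), categorical_crossentropy(y1, p1))
  expect_error(categorical_crossentropy(y, p1), "shapes")
})

test_that("freshly built models emit normalized class probabilities", {
  cnn <- build_model("cnn", input_size = 16, seed = 1)
  zero <- array(0, c(16, 16, 3))
  probs <- burnscope:::.softmax(
    matrix(burnscope:::.cnn_forward1(cnn$params, zero)$logits, 1))
  expect_equal(sum(probs), 1)
  expect_true(all(probs > 0))
  # rnn with zero weights keeps a zero hidden state at every step
  rnn <- build_model("rnn", input_size = 8, seed = 1)
  rnn$params$Wxh[] <- 0; rnn$params$Whh[] <- 0; rnn$params$bh[] <- 0
  fw <- burnscope:::.rnn_forward1(rnn$params, matrix(1, 8, 8))
  expect_true(all(fw$H == 0))
  # single dense neuron: w.x + b evaluates exactly
  expect_equal(as.vector(c(3, 4) %*% matrix(c(1, 2), 2, 1)) + 1, 12)
  expect_error(build_model("cnn", input_size = 20), "divisible")
})

test_that("evaluation metrics match hand computation on a fixed confusion", {
  truth <- rep(1:3, times = c(10, 10, 10))
  pred <- c(rep(1, 10), c(1, rep(2, 8), 3), rep(3, 10))
  ev <- evaluate_predictions(truth, pred, n_classes = 3)
  expect_equal(ev$confusion,
               matrix(c(10L, 1L, 0L, 0L, 8L, 0L, 0L, 1L, 10L), 3, 3))
  expect_equal(ev$accuracy, 28 / 30)
  expect_equal(ev$per_class$recall[2], 0.8)
  expect_equal(ev$per_class$precision[2], 1.0)
  # macro-F1 is the mean of per-class F1 (oracle recomputation)
  expect_equal(ev$macro[["f1"]], mean(ev$per_class$f1))
  # perfect predictions
  evp <- evaluate_predictions(truth, truth, 3)
  expect_equal(evp$accuracy, 1)
  expect_true(all(evp$per_class$f1 == 1))
  # order invariance
  perm <- sample(30)
  evo <- evaluate_predictions(truth[perm], pred[perm], 3)
  expect_equal(evo$confusion, ev$confusion)
  # absent class flagged with zero metrics
  eva <- evaluate_predictions(c(1, 1), c(1, 1), n_classes = 2)
  expect_equal(eva$absent_classes, 2L)
  expect_equal(eva$per_class$f1[2], 0)
})

test_that("macro-F1 equals its oracle on random prediction sets", {
  set.seed(33)
  for (rep in 1:10) {
    truth <- sample(1:3, 60, replace = TRUE)
    pred <- sample(1:3, 60, replace = TRUE)
    ev <- evaluate_predictions(truth, pred, 3)
    f1s <- vapply(1:3, function(cl) {
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }, numeric(1))
    expect_equal(ev$macro[["f1"]], mean(f1s))
  }
})

test_that("binary severity collapse groups superficial with dermal", {
  expect_equal(collapse_severity(c(1, 2, 3, 3, 1)), c(1L, 1L, 2L, 2L, 1L))
  expect_error(collapse_severity(c(0, 1)), "1..3")
  # collapsed metrics agree with direct binary evaluation
  truth <- c(1, 2, 3, 3, 2, 1); pred <- c(1, 3, 3, 2, 2, 1)
  ev <- evaluate_predictions(collapse_severity(truth),
                             collapse_severity(pred), 2)
  expect_equal(ev$accuracy, 4 / 6)
})

test_that("a tiny fnn training run is finite, seeded and learns", {
  set.seed(34)
  X <- rbind(matrix(rnorm(60, 0), 6), matrix(rnorm(60, 3), 6),
             matrix(rnorm(60, -3), 6))
  labs <- rep(1:3, each = 6)
  sp <- stratified_split(labs, c(0.7, 0.15, 0.15), seed = 6)
  cfg <- train_config(epochs = 30, seed = 7, augment = FALSE)
  m1 <- train_model(build_model("fnn", seed = 8), X, labs, sp, cfg)
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_lte(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_model(build_model("fnn", seed = 8), X, labs, sp, cfg)
  expect_identical(m1$params, m2$params) # bitwise reproducible
  probs <- predict_model(m1, X)
  expect_equal(rowSums(probs), rep(1, nrow(X)), tolerance = 1e-9)
})
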