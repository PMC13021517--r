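# small hand-built model for closed-form prediction checks
manual_linear <- function(W, b) {
  structure(list(params = list(list(W = W, b = b)),
                 spec = classifier_spec("linear", nrow(W), ncol(W)),
                 config = train_config(), history = NULL),
            class = "hce_classifier")
}

separable_data <- function(n_per = 40, seed = 5) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2, mean = 3), n_per, 2),
             matrix(rnorm(n_per * 2, mean = -3), n_per, 2))
  list(X = X, y = rep(1:2, each = n_per))
}

test_that("a linear model separates linearly separable classes", {
  d <- separable_data()
  spec <- classifier_spec("linear", 2, 2)
  fit <- train_classifier(spec, d$X, d$y,
                          config = train_config("ce", epochs = 200,
                                                batch_size = 16,
                                                learning_rate = 0.05,
                                                seed = 1))
  expect_equal(mean(predict_label(fit, d$X) == d$y), 1.0)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("training is deterministic given the seed", {
  d <- separable_data()
  spec <- classifier_spec("mlp", 2, 2, hidden_dims = 8)
  cfg <- train_config("ce", epochs = 10, seed = 42, learning_rate = 0.05)
  f1 <- train_classifier(spec, d$X, d$y, config = cfg)
  f2 <- train_classifier(spec, d$X, d$y, config = cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("HCE training on an edge-free ontology reproduces the CE run", {
  d <- separable_data()
  R_free <- reachability(ontology_dag(c("a", "b")))
  spec <- classifier_spec("linear", 2, 2)
  ce <- train_classifier(spec, d$X, d$y,
                         config = train_config("ce", epochs = 15, seed = 9,
                                               learning_rate = 0.05))
  hce <- train_classifier(spec, d$X, d$y, R = R_free,
                          config = train_config("hce", epochs = 15, seed = 9,
                                                learning_rate = 0.05))
  expect_equal(ce$params, hce$params, tolerance = 1e-12)
  expect_equal(ce$history$train_loss, hce$history$train_loss,
               tolerance = 1e-12)
})

test_that("predicted probabilities are valid distributions in input order", {
  d <- separable_data()
  spec <- classifier_spec("mlp", 2, 2, hidden_dims = 4)
  fit <- train_classifier(spec, d$X, d$y,
                          config = train_config("ce", epochs = 5, seed = 2,
                                                learning_rate = 0.05))
  P <- predict_proba(fit, d$X)
  expect_equal(nrow(P), nrow(d$X))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  expect_true(all(P >= 0))
  # order preserved: permuting inputs permutes outputs
  idx <- sample(nrow(d$X))
  expect_equal(predict_proba(fit, d$X[idx, ]), P[idx, ])
  expect_error(predict_proba(fit, matrix(0, 2, 5)), "dimension")
})

test_that("zero input to a linear model yields the softmax of its bias", {
  m <- manual_linear(matrix(0.3, 2, 3), b = c(1, -1, 0.5))
  expect_equal(predict_proba(m, matrix(0, 1, 2))[1, ],
               softmax(c(1, -1, 0.5)))
})

test_that("label prediction argmaxes with ties to the lowest index", {
  # weights chosen so logits are (0, 0) -> tie -> class 1
  m <- manual_linear(matrix(0, 1, 2), b = c(0, 0))
  expect_equal(predict_label(m, matrix(1, 1, 1)), 1L)
  m2 <- manual_linear(matrix(c(0, 1), 1, 2), b = c(0, 0))
  expect_equal(predict_label(m2, matrix(1, 1, 1)), 2L)
})

test_that("invalid specs and label ranges are rejected", {
  expect_error(classifier_spec("linear", 5, 3, hidden_dims = 4), "hidden")
  expect_error(classifier_spec("mlp", 5, 3, hidden_dims = integer(0)),
               "hidden")
  d <- separable_data(10)
  spec <- classifier_spec("linear", 2, 2)
  expect_error(train_classifier(spec, d$X, rep(3, 20)), "labels")
  expect_error(train_classifier(spec, d$X, d$y,
                                config = train_config("hce")),
               "reachability")
})
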