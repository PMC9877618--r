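## shared small training fixture: separable Gaussian features, d = 3
trainFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generateFeatureTable(generatorSpec(nPerClass = 100L, seed = 31L))
      sp <- stratifiedSplit(gen$y, seed = 31)
      sc <- fitScaler(gen$X[sp$train, ])
      Z <- function(i) transformFeatures(gen$X[i, , drop = FALSE], sc)
      cache <<- list(gen = gen, sp = sp,
                     Ztrain = Z(sp$train), Zcore = Z(sp$trainCore),
                     Zval = Z(sp$validation), Ztest = Z(sp$test))
    }
    cache
  }
})

test_that("the network has the closed-form parameter count and seeded init", {
  dense <- buildNetwork(modelConfig(inputMode = "dense"))
  expect_equal(parameterCount(dense),
               46 * 150 + 150 + 150 * 50 + 50 + 50 * 1 + 1)  # 14,651
  ## one-step recurrent input layer triples the input-layer parameters
  rec <- buildNetwork(modelConfig(inputMode = "recurrent-length-1"))
  expect_equal(parameterCount(rec),
               3 * (46 * 150 + 150) + 150 * 50 + 50 + 50 * 1 + 1)
  m1 <- buildNetwork(modelConfig(seed = 7L))
  m2 <- buildNetwork(modelConfig(seed = 7L))
  expect_identical(m1@weights, m2@weights)
  ## He-normal input layer: empirical variance about 2 / fan-in
  v <- mean(vapply(1:5, function(s)
    var(as.numeric(buildNetwork(modelConfig(inputMode = "dense",
                                            seed = s))@weights$W1)),
    numeric(1)))
  expect_lt(abs(v - 2 / 46) / (2 / 46), 0.1)
  expect_error(modelConfig(activation = "swish"), "unknown activation")
})

test_that("training separable data reaches high accuracy in both input modes", {
  fx <- trainFixture()
  for (mode in c("dense", "recurrent-length-1")) {
    cfg <- modelConfig(epochs = 60L, seed = 31L, inputMode = mode)
    m <- trainNetwork(buildNetwork(cfg), fx$Zcore, fx$gen$y[fx$sp$trainCore],
                      fx$Zval, fx$gen$y[fx$sp$validation])
    h <- trainingHistory(m)
    expect_identical(nrow(h), 60L)     # one row per epoch, no early stopping
    expect_identical(names(h), c("epoch", "train_acc", "val_acc", "loss"))
    expect_gte(tail(h$train_acc, 1), 0.95)
    ## independent oracle: logistic regression clears the same bar
    glmFit <- suppressWarnings(
      glm(y ~ ., data = data.frame(y = fx$gen$y[fx$sp$trainCore], fx$Zcore),
          family = binomial))
    expect_gte(mean((predict(glmFit, type = "response") >= 0.5) ==
                      fx$gen$y[fx$sp$trainCore]), 0.95)
    acc <- mean(predictLabel(m, fx$Ztest) == fx$gen$y[fx$sp$test])
    expect_gte(acc, fx$gen$bayesRate - 0.05)  # Bayes rate minus 5 points
  }
})

test_that("shuffled labels yield chance-level validation accuracy", {
  fx <- trainFixture()
  set.seed(32)
  yNull <- sample(fx$gen$y[fx$sp$trainCore])
  cfg <- modelConfig(epochs = 40L, seed = 32L, inputMode = "dense")
  m <- trainNetwork(buildNetwork(cfg), fx$Zcore, yNull,
                    fx$Zval, sample(fx$gen$y[fx$sp$validation]))
  expect_lt(abs(tail(trainingHistory(m)$val_acc, 1) - 0.5), 0.2)
})

test_that("analytic gradients match finite differences in both modes", {
  for (mode in c("dense", "recurrent-length-1")) {
    cfg <- modelConfig(nFeatures = 5L, inputUnits = 4L, hiddenUnits = 3L,
                       dropoutRate = 0, inputMode = mode, seed = 33L)
    m <- buildNetwork(cfg)
    set.seed(33)
    X <- matrix(rnorm(6 * 5), 6, 5)
    y <- c(1, 0, 1, 1, 0, 0)
    w <- m@weights
    cache <- ProtStress:::.forward(w, cfg, X)
    grads <- ProtStress:::.backward(w, cfg, cache, y)
    lossAt <- function(w) ProtStress:::.lossValue(
      cfg, ProtStress:::.forward(w, cfg, X)$P, y)
    h <- 1e-6
    for (nm in names(w)) {
      for (k in sample(length(w[[nm]]), min(4, length(w[[nm]])))) {
        wp <- w; wp[[nm]][k] <- wp[[nm]][k] + h
        wm <- w; wm[[nm]][k] <- wm[[nm]][k] - h
        fd <- (lossAt(wp) - lossAt(wm)) / (2 * h)
        expect_equal(grads[[nm]][k], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("SIELU and GELU networks follow identical training trajectories", {
  fx <- trainFixture()
  run <- function(act, mode) {
    cfg <- modelConfig(epochs = 25L, seed = 34L, activation = act,
                       inputMode = mode)
    trainNetwork(buildNetwork(cfg), fx$Zcore, fx$gen$y[fx$sp$trainCore],
                 fx$Zval, fx$gen$y[fx$sp$validation])
  }
  for (mode in c("dense", "recurrent-length-1")) {
    a <- run("sielu", mode); b <- run("gelu", mode)
    expect_lt(max(abs(trainingHistory(a)$loss - trainingHistory(b)$loss)), 1e-6)
    expect_lt(max(abs(predictProba(a, fx$Ztest) - predictProba(b, fx$Ztest))),
              1e-6)
  }
})

test_that("prediction, thresholding and serialization are exact", {
  fx <- trainFixture()
  cfg <- modelConfig(epochs = 20L, seed = 35L, inputMode = "dense")
  m <- trainNetwork(buildNetwork(cfg), fx$Zcore, fx$gen$y[fx$sp$trainCore],
                    fx$Zval, fx$gen$y[fx$sp$validation])
  p <- predictProba(m, fx$Ztest)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(predictLabel(m, fx$Ztest, threshold = 0) == 1L))
  f <- tempfile(fileext = ".json")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(predictProba(m2, fx$Ztest), p)  # bit-identical round trip
  expect_identical(trainingHistory(m2)$loss, trainingHistory(m)$loss)
})

test_that("prediction rejects features from a different schema", {
  fx <- trainFixture()
  Z <- fx$Zcore
  attr(Z, "schemaHash") <- "hash-A"
  cfg <- modelConfig(epochs = 2L, seed = 36L, inputMode = "dense")
  m <- trainNetwork(buildNetwork(cfg), Z, fx$gen$y[fx$sp$trainCore],
                    fx$Zval, fx$gen$y[fx$sp$validation])
  bad <- fx$Ztest
  attr(bad, "schemaHash") <- "hash-B"
  expect_error(predictProba(m, bad), "hash-A")
  expect_error(
    predictProba(m, fx$Ztest[, 1:10]), "features")
})

test_that("baselines learn the sequence fixture and respect their seeds", {
  fx <- seqFixture()
  sp <- stratifiedSplit(fx$y, seed = 37)
  sc <- fitScaler(fx$X[sp$train, ])
  Ztr <- transformFeatures(fx$X[sp$train, ], sc)
  Zte <- transformFeatures(fx$X[sp$test, ], sc)
  svmFit <- trainSvmBaseline(Ztr, fx$y[sp$train])
  rfFit <- trainRfBaseline(Ztr, fx$y[sp$train])
  expect_gte(mean(predictLabel(svmFit, Zte) == fx$y[sp$test]), 0.9)
  expect_gte(mean(predictLabel(rfFit, Zte) == fx$y[sp$test]), 0.9)
  ## same seed, same predictions
  rf2 <- trainRfBaseline(Ztr, fx$y[sp$train])
  expect_identical(predictLabel(rf2, Zte), predictLabel(rfFit, Zte))
  ## probabilities are valid scores
  expect_true(all(predictProba(svmFit, Zte) >= 0 & predictProba(svmFit, Zte) <= 1))
  ## shuffled labels: chance level
  set.seed(38)
  yN <- sample(fx$y[sp$train])
  svmN <- trainSvmBaseline(Ztr, yN)
  expect_lt(abs(mean(predictLabel(svmN, Zte) == fx$y[sp$test]) - 0.5), 0.2)
  expect_error(trainSvmBaseline(Ztr, rep(1, nrow(Ztr))), "both classes")
  expect_error(trainRfBaseline(Ztr, rep(0, nrow(Ztr))), "both classes")
})

test_that("cross-validation aggregates five per-fold metric reports", {
  fx <- seqFixture()
  sc <- fitScaler(fx$X)
  Z <- transformFeatures(fx$X, sc)
  cv <- crossValidate(function(X, y) trainSvmBaseline(X, y), Z, fx$y,
                      nFolds = 5, seed = 39)
  expect_identical(nrow(cv$folds), 5L)
  expect_true(all(c("accuracy", "mcc") %in% names(cv$folds)))
  expect_gte(cv$mean[["accuracy"]], min(cv$folds$accuracy))
  expect_lte(cv$mean[["accuracy"]], max(cv$folds$accuracy))
  cv2 <- crossValidate(function(X, y) trainSvmBaseline(X, y), Z, fx$y,
                       nFolds = 5, seed = 39)
  expect_identical(cv$folds, cv2$folds)  # deterministic given seed
})
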