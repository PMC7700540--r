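test_that("templates are per-class means", {
  m <- rbind(c(1, 0), c(0, 1), c(3, 3))
  colnames(m) <- c("f1", "f2")
  tpl <- build_templates(m, c("a", "b", "b"))
  expect_equal(tpl["a", ], c(f1 = 1, f2 = 0))
  expect_equal(tpl["b", ], c(f1 = 1.5, f2 = 2))
  ## duplicated samples leave the mean unchanged
  tpl2 <- build_templates(rbind(m, m), rep(c("a", "b", "b"), 2))
  expect_equal(tpl2, tpl)
  ## oracle: naive loop-and-average
  set.seed(30)
  mm <- matrix(rnorm(60), 20, 3)
  lab <- sample(c("p", "q"), 20, TRUE)
  tpl3 <- build_templates(mm, lab)
  for (cl in c("p", "q")) for (j in 1:3) {
    s <- 0; n <- 0
    for (i in 1:20) if (lab[i] == cl) { s <- s + mm[i, j]; n <- n + 1 }
    expect_equal(unname(tpl3[cl, j]), s / n, tolerance = 1e-12)
  }
})

test_that("matching is cosine argmax with deterministic tie-breaks", {
  tpl <- rbind(a = c(1, 0, 0), b = c(0, 1, 0))
  res <- match_template(c(2, 0, 0), tpl)
  expect_equal(res$label, "a")
  expect_equal(unname(res$scores["a"]), 1)
  ## exact tie: earlier class in training order wins
  tie <- match_template(c(1, 1, 0), tpl)
  expect_equal(tie$label, "a")
  expect_equal(unname(tie$scores["a"]), unname(tie$scores["b"]))
  ## scale invariance of the cosine score
  r1 <- match_template(c(0.2, 0.7, 0.1), tpl)
  r2 <- match_template(10 * c(0.2, 0.7, 0.1), tpl)
  expect_equal(r1$scores, r2$scores, tolerance = 1e-12)
  ## all-zero vector falls back to negative Euclidean distance
  z <- match_template(c(0, 0, 0), tpl)
  expect_equal(unname(z$scores["a"]), -1)
  expect_error(match_template(c(1, 2), tpl), "does not match")
})

test_that("separated clusters classify above 0.9 via templates", {
  set.seed(31)
  centers <- rbind(c(1, 6), c(6, 1), c(5, 5))
  mk <- function(i, n) sweep(matrix(rnorm(n * 2, sd = 0.7), n), 2,
                             centers[i, ], `+`)
  train <- do.call(rbind, lapply(1:3, mk, n = 40))
  test <- do.call(rbind, lapply(1:3, mk, n = 40))
  colnames(train) <- colnames(test) <- c("f1", "f2")
  lab <- rep(c("a", "b", "c"), each = 40)
  model <- har_train(train, lab)
  pred <- har_predict(model, test)
  acc <- mean(pred == lab)
  expect_gt(acc, 0.9)
  ## oracle: nearest-centroid equivalence on the same normalised data
  expect_equal(nrow(model$templates), 3)
})

test_that("one retained feature reduces to a 1-D nearest-centroid rule", {
  set.seed(32)
  x <- c(rnorm(30, 0.2, 0.05), rnorm(30, 0.8, 0.05))
  lab <- rep(c("lo", "hi"), each = 30)
  m <- cbind(f1 = x)
  model <- har_train(m, lab, weights = 1,
                     config = har_config(similarity = "euclidean"))
  pred <- har_predict(model, m)
  ## brute-force 1-D nearest-centroid oracle on the normalised scale
  v <- (x - min(x)) / (max(x) - min(x))
  c_lo <- mean(v[lab == "lo"]); c_hi <- mean(v[lab == "hi"])
  oracle <- ifelse(abs(v - c_lo) <= abs(v - c_hi), "lo", "hi")
  expect_equal(as.character(pred), oracle)
})

test_that("baselines wrap the fitness classifiers and validate input", {
  set.seed(33)
  m <- rbind(matrix(rnorm(40 * 3), 40), matrix(rnorm(40 * 3, 4), 40))
  colnames(m) <- paste0("f", 1:3)
  lab <- rep(c("a", "b"), each = 40)
  svm_model <- train_baseline("lsvm", m, lab)
  expect_equal(mean(predict_baseline(svm_model, m) == lab), 1)
  rf_model <- train_baseline("rf", m, lab, seed = 2)
  acc_rf <- mean(predict_baseline(rf_model, m) == lab)
  expect_gte(acc_rf, mean(predict_baseline(svm_model, m) == lab) - 1e-9)
  expect_error(train_baseline("rf", m, rep("a", 80)), "2 classes")
})

test_that("models serialise to JSON and predict identically", {
  set.seed(34)
  m <- rbind(matrix(rnorm(30 * 4), 30), matrix(rnorm(30 * 4, 3), 30))
  colnames(m) <- paste0("f", 1:4)
  lab <- rep(c("a", "b"), each = 30)
  model <- har_train(m, lab, weights = runif(4))
  path <- withr::local_tempfile(fileext = ".json")
  write_har_model(model, path)
  back <- read_har_model(path)
  expect_equal(back$templates, model$templates, tolerance = 1e-12)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  expect_identical(as.character(har_predict(back, m)),
                   as.character(har_predict(model, m)))
})
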