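test_that("population initialisation is seeded, bounded and validated", {
  a <- init_population(30, 71, seed = 4)
  b <- init_population(30, 71, seed = 4)
  expect_identical(a, b)
  expect_length(a, 30)
  expect_true(all(vapply(a, function(w)
    all(w >= 0 & w <= 1) && length(w) == 71, TRUE)))
  expect_error(init_population(1, 10), "at least 2")
  expect_error(init_population(5, 0), "at least 1")
})

test_that("single-point crossover conserves the gene multiset", {
  p1 <- rep(0, 10); p2 <- rep(1, 10)
  off <- crossover(p1, p2, seed = 1)
  ## structure forced: a 0-block then 1-block, and its mirror
  expect_true(all(diff(off[[1]]) >= 0))
  expect_true(all(diff(off[[2]]) <= 0))
  expect_equal(off[[1]] + off[[2]], rep(1, 10))
  same <- crossover(p1, p1, seed = 2)
  expect_equal(same[[1]], p1)
  expect_equal(same[[2]], p1)
  set.seed(8)
  a <- runif(12); b <- runif(12)
  off2 <- crossover(a, b, seed = 3)
  ## positionwise union of offspring genes equals union of parent genes
  for (j in 1:12)
    expect_setequal(c(off2[[1]][j], off2[[2]][j]), c(a[j], b[j]))
  expect_error(crossover(a, b[1:5]), "equal gene counts")
})

test_that("mutation resamples genes at the configured rate", {
  w <- runif(20)
  expect_identical(mutate(w, 0, seed = 1), w)
  expect_error(mutate(w, 1.5), "rate")
  ## rate 1: every gene comes from the seeded uniform stream
  got <- mutate(w, 1, seed = 42)
  expected <- withr::with_seed(42L, {
    hit <- runif(20) < 1
    runif(20)
  })
  expect_equal(got, expected)
  ## binomial bound on the mutated-gene count at rate 0.05
  big <- runif(10000)
  mut <- mutate(big, 0.05, seed = 7)
  n_changed <- sum(mut != big)
  expect_lt(abs(n_changed - 500), 3 * sqrt(10000 * 0.05 * 0.95))
})

test_that("reweighting multiplies columns by genes", {
  set.seed(10)
  tab <- matrix(rnorm(40), 8, 5)
  expect_equal(reweight(tab, rep(1, 5)), tab)
  w <- c(1, 0, 0, 0, 0)
  out <- reweight(tab, w)
  expect_equal(out[, 1], tab[, 1])
  expect_true(all(out[, 2:5] == 0))
  w2 <- runif(5)
  out2 <- reweight(tab, w2)
  for (i in 1:8) for (j in 1:5)
    expect_equal(out2[i, j], tab[i, j] * w2[j], tolerance = 1e-12)
  expect_error(reweight(tab, 1:3), "does not match")
})

test_that("fitness averages the two classifier accuracies", {
  ## two well-separated Gaussian classes: near-perfect accuracy
  set.seed(20)
  m <- rbind(matrix(rnorm(50 * 4), 50), matrix(rnorm(50 * 4, 5), 50))
  lab <- rep(c("a", "b"), each = 50)
  fit <- ga_fitness(rep(1, 4), m, lab, seed = 1)
  expect_gt(fit$combined, 0.95)
  expect_equal(fit$combined, (fit$acc_lsvm + fit$acc_rf) / 2)
  ## permuted labels give chance-level fitness
  set.seed(21)
  m2 <- matrix(rnorm(200 * 6), 200)
  lab2 <- sample(rep(c("a", "b"), each = 100))
  fit2 <- ga_fitness(rep(1, 6), m2, lab2, seed = 2)
  expect_lt(abs(fit2$combined - 0.5), 0.15)
  expect_error(ga_fitness(rep(1, 4), m, rep("a", 100)), "2 classes")
})

test_that("evolution is elitist-monotone, deterministic and bounded", {
  dat <- make_weighted_table(1, n_per_class = 30, k_info = 3, k_noise = 5,
                             shift = 1)
  cfg <- har_config(ga = list(population = 8, generations = 5,
                              patience = 5))
  ev1 <- evolve(dat$features, dat$labels, cfg, seed = 5)
  ev2 <- evolve(dat$features, dat$labels, cfg, seed = 5)
  expect_identical(ev1$best, ev2$best)
  expect_true(all(diff(ev1$history) >= 0))
  expect_lte(ev1$generations_run, 5)
  cfg1 <- har_config(ga = list(population = 6, generations = 1))
  ev3 <- evolve(dat$features, dat$labels, cfg1, seed = 6)
  expect_equal(ev3$generations_run, 1)
  expect_length(ev3$history, 1)
})

test_that("threshold selection retains features at or above the mean weight", {
  expect_equal(select_features(c(0.8, 0.2, 0.6, 0.4), paste0("f", 1:4)),
               c("f1", "f3"))
  expect_equal(select_features(rep(0.5, 6), paste0("f", 1:6)),
               paste0("f", 1:6))
  expect_equal(select_features(c(0.9, 0, 0, 0), paste0("f", 1:4)), "f1")
  expect_error(select_features(1:3, "a"), "equal length")
})

test_that("weight report mirrors the chromosome through the registry", {
  reg <- har_feature_registry()
  ev <- list(best = rep(0.5, nrow(reg)),
             best_fitness = list(combined = 1), history = 1,
             generations_run = 1)
  class(ev) <- "har_evolution"
  rep13 <- weight_report(ev, grouped = TRUE)
  expect_equal(dim(rep13), c(13, 2))
  expect_true(all(rep13$trial_1 == 0.5))
  full <- weight_report(list(ev, ev), grouped = FALSE)
  expect_equal(dim(full), c(nrow(reg), 3))
  expect_identical(full$feature, reg$name)
  ## grouped cells are exactly the per-kind means of the genes
  ev$best <- seq(0, 1, length.out = nrow(reg))
  g <- weight_report(ev, grouped = TRUE)
  names(ev$best) <- reg$name
  expect_equal(g$trial_1[g$feature == "Zero Crossing Rate"],
               mean(ev$best[reg$kind == "zcr"]))
})
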