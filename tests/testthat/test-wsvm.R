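toy_x <- matrix(c(-2, -1, 1, 2), ncol = 1)
toy_y <- c(-1, -1, 1, 1)

test_that("gaussian kernel matches its closed form and is symmetric", {
  x <- c(1, 2, 3)
  expect_equal(gaussian_kernel(x, x, 0.7), 1)
  # squared distance 2*sigma^2 gives exp(-1)
  expect_equal(gaussian_kernel(0, sqrt(2) * 0.5, 0.5), exp(-1))
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(gaussian_kernel(a, b, 1.3), gaussian_kernel(b, a, 1.3))
    expect_lte(gaussian_kernel(a, b, 1.3), 1)
    expect_gt(gaussian_kernel(a, b, 1.3), 0)
  }
  expect_error(gaussian_kernel(a, b, 0), "positive")
  expect_error(gaussian_kernel(1:2, 1:3, 1), "equal length")
})

test_that("gaussian kernel matrices are positive semidefinite", {
  for (seed in 1:4) {
    set.seed(seed)
    x <- matrix(rnorm(30 * 3), 30)
    K <- actiseq:::kernel_matrix(x, x, runif(1, 0.3, 2))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("per-class costs follow the majority-ratio rule", {
  expect_equal(class_costs(c(50, 50, 50), 7)$costs, c(7L, 7L, 7L))
  expect_equal(class_costs(c(300, 100), 10)$costs, c(10L, 30L))
  # ratio 2.5: half away from zero rounds up (round-half-even would give 2)
  expect_equal(class_costs(c(100, 40), 1)$costs, c(1L, 3L))
  expect_equal(class_costs(c(10, 10), 0.2)$costs, c(1L, 1L))  # floored at 1
  expect_equal(class_costs(c(8, 2, 4), 2)$majority, 8L)
  expect_error(class_costs(c(5, 0), 1), ">= 1")
  expect_error(class_costs(c(5, 5), -1), "positive")
})

test_that("the binary solver separates a 1-D toy problem", {
  m <- train_binary_wsvm(toy_x, toy_y, 100, 100, 1)
  f <- decision_value(m, toy_x)
  expect_true(all(sign(f) == toy_y))
  expect_lt(decision_value(m, matrix(-2)), 0)
  expect_gt(decision_value(m, matrix(2)), 0)
  expect_gte(nrow(m$sv), 1)
  # decision value is continuous in x
  expect_lt(abs(decision_value(m, matrix(0.5)) - decision_value(m, matrix(0.5 + 1e-7))),
            1e-5)
  expect_error(train_binary_wsvm(toy_x, rep(1, 4), 1, 1, 1), "both classes")
  expect_error(decision_value(m, matrix(1, 1, 2)), "mismatch")
})

test_that("dual feasibility holds after every fit", {
  set.seed(21)
  for (i in 1:6) {
    n <- 40
    x <- matrix(rnorm(n * 2), n)
    y <- sign(x[, 1] + 0.5 * rnorm(n)); y[y == 0] <- 1
    if (length(unique(y)) < 2) next
    cp <- sample(c(1, 5, 20), 1); cn <- sample(c(1, 5, 20), 1)
    m <- train_binary_wsvm(x, y, cp, cn, runif(1, 0.5, 2))
    expect_true(all(m$alpha >= 0))
    expect_true(all(m$alpha <= m$upper + 1e-9))
    expect_lte(abs(m$sum_alpha_y), 1e-6 * max(1, sum(m$alpha)))
  }
})

test_that("duplicating a separable training set leaves the decision function unchanged", {
  m1 <- train_binary_wsvm(toy_x, toy_y, 100, 100, 1)
  m2 <- train_binary_wsvm(rbind(toy_x, toy_x), c(toy_y, toy_y), 100, 100, 1)
  grid <- matrix(seq(-3, 3, by = 0.25), ncol = 1)
  expect_equal(decision_value(m1, grid), decision_value(m2, grid), tolerance = 1e-6)
})

test_that("equal costs reproduce an unweighted reference SVM", {
  skip_if_not_installed("e1071")
  set.seed(22)
  blobs <- make_blobs(100, rbind(c(0, 0), c(1.5, 1.5)), seed = 22)
  xt <- make_blobs(75, rbind(c(0, 0), c(1.5, 1.5)), seed = 23)$x
  m <- train_binary_wsvm(blobs$x, ifelse(blobs$labels == 1, 1, -1), 10, 10, 1)
  ref <- e1071::svm(blobs$x, factor(blobs$labels), scale = FALSE,
                    kernel = "radial", gamma = 1 / 2, cost = 10)
  dv <- drop(attr(predict(ref, xt, decision.values = TRUE), "decision.values"))
  ours <- decision_value(m, xt)
  expect_true(all(sign(ours) == sign(dv)))
  expect_lt(max(abs(ours - dv)), 0.02)  # both solvers stop at KKT tol 1e-3
})

test_that("one-vs-one training builds a machine per class pair and predicts blobs", {
  blobs <- make_blobs(20, 4 * diag(6), seed = 24)
  m <- train_wsvm(blobs$x, blobs$labels, C = 10, sigma = 2)
  expect_length(m$machines, 15L)  # 6 activities -> 15 pairwise machines
  expect_equal(predict(m, blobs$x), blobs$labels)

  b3 <- make_blobs(30, 4 * diag(3), seed = 25)
  m3 <- train_wsvm(b3$x, b3$labels, C = 10, sigma = 2)
  expect_length(m3$machines, 3L)
  expect_equal(predict(m3, b3$x), b3$labels)
  expect_error(train_wsvm(b3$x, pmin(b3$labels, 2), n_classes = 3),
               "no training samples")
})

test_that("two-class prediction equals the sign of the decision value", {
  blobs <- make_blobs(25, rbind(c(0, 0), c(3, 3)), seed = 26)
  m <- train_wsvm(blobs$x, blobs$labels, C = 5, sigma = 1)
  f <- decision_value(m$machines[[1]], blobs$x)
  expect_equal(predict(m, blobs$x), ifelse(f >= 0, 1L, 2L))
})

test_that("a full voting tie goes to the smallest class index", {
  fake <- function(b) structure(
    list(sv = matrix(0, 1, 1), coef = 0, alpha = 0, y = 1, upper = 1,
         b = b, sigma = 1), class = "binary_wsvm")
  # machine (1,2) votes 1, (1,3) votes 3, (2,3) votes 2: one vote each
  m <- structure(list(n_classes = 3L, sigma = 1,
                      scheme = class_costs(c(1, 1, 1), 1),
                      pairs = utils::combn(3, 2),
                      machines = list(fake(1), fake(-1), fake(1)),
                      weighted = TRUE), class = "wsvm")
  expect_equal(predict(m, matrix(0)), 1L)
})

test_that("grid search is deterministic and returns the accuracy table", {
  blobs <- make_blobs(25, rbind(c(0, 0), c(2, 2), c(-2, 2)), seed = 27)
  single <- wsvm_grid_search(blobs$x, blobs$labels, sigma_grid = 0.5,
                             c_grid = 10, folds = 3, seed = 1)
  expect_equal(single$sigma, 0.5)
  expect_equal(single$C, 10)

  res1 <- wsvm_grid_search(blobs$x, blobs$labels, sigma_grid = c(0.5, 1),
                           c_grid = c(1, 10), folds = 3, seed = 4)
  res2 <- wsvm_grid_search(blobs$x, blobs$labels, sigma_grid = c(0.5, 1),
                           c_grid = c(1, 10), folds = 3, seed = 4)
  expect_identical(res1, res2)
  expect_equal(nrow(res1$table), 4L)
  expect_true(all(res1$table$cv_accuracy >= 0 & res1$table$cv_accuracy <= 1))
})

test_that("out-of-fold estimates cover every row exactly once", {
  blobs <- make_blobs(30, 4 * diag(3), seed = 28)
  est <- cv_wsvm_labels(blobs$x, blobs$labels, sigma = 2, C = 10,
                        folds = 5, seed = 2)
  expect_length(est, 90L)
  expect_true(all(est %in% 1:3))
  expect_equal(est, blobs$labels)  # well-separated blobs

  # leave-one-out on a small separable set
  small <- make_blobs(4, rbind(c(0, 0), c(5, 5)), sd = 0.3, seed = 29)
  loo <- cv_wsvm_labels(small$x, small$labels, sigma = 2, C = 10,
                        folds = 8, seed = 3)
  expect_equal(loo, small$labels)
})

test_that("minority recall improves under majority-ratio costs", {
  wins <- 0L; strict <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    x <- rbind(matrix(rnorm(190 * 2), ncol = 2),
               matrix(rnorm(10 * 2, mean = 2), ncol = 2))
    y <- rep(1:2, c(190, 10))
    xt <- rbind(matrix(rnorm(200 * 2), ncol = 2),
                matrix(rnorm(200 * 2, mean = 2), ncol = 2))
    yt <- rep(1:2, each = 200)
    rw <- mean(predict(train_wsvm(x, y, C = 1, sigma = 1), xt)[yt == 2] == 2)
    ru <- mean(predict(train_wsvm(x, y, C = 1, sigma = 1, weighted = FALSE),
                       xt)[yt == 2] == 2)
    wins <- wins + (rw >= ru)
    strict <- strict + (rw > ru)
  }
  expect_gte(wins, 8L)
})
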