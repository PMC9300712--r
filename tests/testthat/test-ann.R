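test_that("forward pass matches hand arithmetic", {
  rng_in <- list(min = c(0, 0, 0, 0), max = c(2, 2, 2, 2))
  rng_out <- c(0, 100)

  # zero weights: output is the unscaled output bias
  zero <- mlp_network(matrix(0, 3, 4), rep(0, 3), rep(0, 3), 0,
                      input_scaling = rng_in, output_scaling = rng_out)
  expect_equal(predict(zero, c(0.5, 1.7, 0.2, 2)), 50)  # bias 0 -> midpoint

  # single hidden node, hand-set weights
  w <- c(0.3, -0.2, 0.1, 0.4); theta <- 0.05; wo <- 0.7; bo <- -0.1
  net <- mlp_network(matrix(w, 1, 4), theta, wo, bo,
                     input_scaling = rng_in, output_scaling = rng_out)
  x <- c(1.2, 0.4, 1.9, 0.3)
  xs <- 2 * x / 2 - 1
  ys <- tanh(sum(xs * w) + theta) * wo + bo
  expect_equal(predict(net, x), (ys + 1) / 2 * 100)

  # linearity of the output layer: doubling output weights doubles
  # (scaled output - output bias)
  net2 <- net; net2$output_weights <- 2 * net$output_weights
  s1 <- 2 * predict(net, x) / 100 - 1
  s2 <- 2 * predict(net2, x) / 100 - 1
  expect_equal(s2 - bo, 2 * (s1 - bo), tolerance = 1e-12)
})

test_that("backprop gradients match central finite differences", {
  set.seed(11)
  for (H in c(1, 3, 5)) {
    net <- toy_network(H, seed = H)
    Xs <- matrix(runif(20, -1, 1), 5, 4)
    ts <- runif(5, -0.8, 0.8)
    g <- biosorb:::mlp_gradients(net, Xs, ts)
    packed <- c(as.vector(g$W1), g$b1, g$w2, g$b2)
    numeric <- numeric_gradient(function(th)
      biosorb:::mlp_mse(mlp_unpack(th, net), Xs, ts), mlp_pack(net))
    expect_equal(packed, numeric, tolerance = 1e-6)
  }
})

test_that("training is deterministic under a fixed seed", {
  d <- table2_ccd()
  r1 <- train_mlp(d, hidden = 4, max_epochs = 300, seed = 5)
  r2 <- train_mlp(d, hidden = 4, max_epochs = 300, seed = 5)
  expect_identical(r1, r2)
})

test_that("an easy linear target is learned to tight training MSE", {
  d <- table2_ccd()
  runs <- d$runs
  runs$removal_obs <- 70 + 10 * code_factor(runs$dose, d$factors$dose)
  lin <- ccd_dataset(runs, d$factors)
  res <- train_mlp(lin, hidden = 2, max_epochs = 4000, mse_goal = 1e-5,
                   weight_selection = "final", seed = 2)
  expect_lt(res$mse_train, 1e-4)
})

test_that("a small teacher network is recovered from noiseless samples", {
  teacher <- toy_network(H = 2, seed = 42)
  set.seed(9)
  n <- 200
  X <- cbind(runif(n, 0.1, 1.3), runif(n, 2, 10),
             runif(n, 25, 45), runif(n, 0.1, 1.3))
  y <- predict(teacher, X)
  runs <- data.frame(dose = X[, 1], ph = X[, 2], temp = X[, 3],
                     conc = X[, 4], removal_obs = y,
                     split = rep(c("train", "test"), length.out = n))
  d <- ccd_dataset(runs)
  res <- train_mlp(d, hidden = 4, max_epochs = 6000, mse_goal = 1e-7,
                   weight_selection = "final", seed = 3)
  # held-out grid in the interior of the factor box
  grid <- as.matrix(expand.grid(seq(0.2, 1.2, length.out = 4),
                                seq(3, 9, length.out = 4),
                                seq(27, 43, length.out = 4),
                                seq(0.2, 1.2, length.out = 4)))
  scale_y <- function(v) 2 * (v - 40) / (95 - 40) - 1
  mse_grid <- mean((scale_y(predict(res$network, grid)) -
                      scale_y(predict(teacher, grid)))^2)
  expect_lt(mse_grid, 1e-3)
})

test_that("the descent fits the design and snapshot selection generalises", {
  d <- table2_ccd()
  obs <- d$runs$removal_obs
  X <- as.matrix(d$runs[, c("dose", "ph", "temp", "conc")])
  tr <- d$runs$split == "train"
  for (s in 1:2) {
    final <- train_mlp(d, hidden = 10, weight_selection = "final", seed = s)
    expect_lte(final$epochs_run, 10000)
    # the optimiser can drive the training split to near-interpolation
    pred <- predict(final$network, X)
    r2_train <- 1 - sum((obs[tr] - pred[tr])^2) /
      sum((obs[tr] - mean(obs[tr]))^2)
    expect_gt(r2_train, 0.99)
    # the default snapshot never generalises worse than the final weights
    snap <- train_mlp(d, hidden = 10, seed = s)
    expect_lte(snap$mse_test, final$mse_test)
  }
})

test_that("evaluation statistics behave at the extremes", {
  d <- table2_ccd()
  obs <- d$runs$removal_obs
  r2 <- function(pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  expect_equal(r2(obs), 1)
  expect_equal(r2(rep(mean(obs), length(obs))), 0)

  # the study's own predicted column is a fixed property of the fixture
  expect_equal(r2(d$runs$removal_ann), 0.9962491, tolerance = 1e-6)
})

test_that("hidden-size sweep returns the best-generalising candidate", {
  d <- table2_ccd()
  sw <- sweep_hidden_sizes(d, hidden = c(2, 4), seeds = 1,
                           max_epochs = 500)
  expect_identical(nrow(sw$summary), 2L)
  expect_equal(sw$best$mse_test, min(sw$summary$mse_test))
})

test_that("restart selection keeps the least-test-MSE network", {
  d <- table2_ccd()
  sel <- select_mlp(d, restarts = 3, seed = 1, hidden = 4,
                    max_epochs = 500)
  expect_length(sel$mse_test, 3)
  expect_equal(sel$best$mse_test, min(sel$mse_test))
  # restart i reproduces a plain training run with seed + i - 1
  direct <- train_mlp(d, hidden = 4, max_epochs = 500, seed = 2)
  expect_equal(sel$mse_test[2], direct$mse_test)
})
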