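test_that("surface evaluation matches hand arithmetic on printed coefficients", {
  s <- printed_surface()
  expect_equal(predict(s, c(0, 0, 0, 0)), 94.00)
  expect_equal(predict(s, c(1, 0, 0, 0)), 94.00 + 9.87 - 8.68)
  flat <- quadratic_surface(42, rep(0, 4), rep(0, 4), rep(0, 6))
  expect_equal(predict(flat, c(-2, 1, 0.3, 2)), 42)
  # matrix input vectorises
  expect_equal(predict(s, rbind(c(0, 0, 0, 0), c(1, 0, 0, 0))),
               c(94.00, 95.19))
})

test_that("least-squares fit agrees with the normal-equations oracle", {
  d <- table2_ccd()
  set.seed(7)
  idx <- sample(31, 20)
  sub <- ccd_dataset(d$runs[idx, ], d$factors)
  fit <- fit_quadratic(sub)
  X <- biosorb:::quadratic_model_matrix(coded_matrix(sub))
  oracle <- drop(normal_equations_fit(X, sub$runs$removal_obs))
  ours <- c(fit$surface$beta0, fit$surface$linear,
            fit$surface$quadratic, fit$surface$interaction)
  expect_equal(ours, unname(oracle), tolerance = 1e-10)
})

test_that("fit recovers a noiseless quadratic exactly and reports honest R2", {
  truth <- printed_surface()
  sim <- simulate_ccd(truth, noise_sd = 0)
  fit <- fit_quadratic(sim)
  expect_equal(c(fit$surface$beta0, fit$surface$linear,
                 fit$surface$quadratic, fit$surface$interaction),
               c(truth$beta0, truth$linear, truth$quadratic,
                 truth$interaction),
               tolerance = 1e-8)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-10)

  # R2 on the real fixture vs independent accumulation
  d <- table2_ccd()
  fitd <- fit_quadratic(d)
  pred <- predict(fitd$surface, coded_matrix(d))
  y <- d$runs$removal_obs
  expect_equal(fitd$stats$r2, 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_lte(fitd$stats$adj_r2, fitd$stats$r2)
})

test_that("ANOVA partitions degrees of freedom and sums of squares", {
  fit <- fit_quadratic(table2_ccd())
  a <- fit$stats$anova
  df <- setNames(a$df, a$source)
  ss <- setNames(a$ss, a$source)
  expect_identical(unname(df["regression"] + df["residual"]), 30L)
  expect_identical(unname(df["lack_of_fit"] + df["pure_error"]),
                   unname(df["residual"]))
  expect_equal(unname(ss["regression"] + ss["residual"]),
               unname(ss["total"]))
  expect_equal(unname(ss["lack_of_fit"] + ss["pure_error"]),
               unname(ss["residual"]))
  expect_gt(a$f[1], 1)
  expect_lt(a$p[1], 1e-6)
})

test_that("rank-deficient designs fail loudly", {
  d <- table2_ccd()
  centre_only <- ccd_dataset(
    d$runs[rep(which(d$runs$dose == 0.7 & d$runs$ph == 6 &
                       d$runs$temp == 35 & d$runs$conc == 0.7), 3), ],
    d$factors)
  expect_error(fit_quadratic(centre_only), "rank")
})

test_that("surface maximisation handles trivial and printed cases", {
  bowl <- quadratic_surface(0, rep(0, 4), rep(-1, 4), rep(0, 6))
  m <- maximize_surface(bowl, n_random = 0)
  expect_equal(m$x, rep(0, 4), tolerance = 1e-6)
  expect_equal(m$value, 0, tolerance = 1e-10)

  ramp <- quadratic_surface(0, c(1, 0, 0, 0), rep(0, 4), rep(0, 6))
  expect_equal(maximize_surface(ramp, n_random = 0)$x[1], 2,
               tolerance = 1e-6)

  s <- printed_surface()
  ours <- maximize_surface(s, seed = 1)
  oracle <- grid_max_oracle(s, n = 21)
  # grid resolution is 0.2 coded units
  expect_lt(abs(ours$value - oracle$value), 0.5)
  expect_gte(ours$value + 1e-8, oracle$value)
  expect_true(all(abs(ours$x - oracle$x) < 0.2 + 1e-8))
})

test_that("maximisation is invariant to factor reordering", {
  s <- quadratic_surface(80, c(2, -1, 0.5, 1.5), c(-3, -2, -4, -1),
                         c(0.5, -0.3, 0.2, 0.1, -0.4, 0.6))
  perm <- c(2, 4, 1, 3)  # new order of factors
  inv <- order(perm)
  pair_index <- function(i, j) {
    p <- sort(c(i, j))
    which(apply(biosorb:::interaction_pairs, 1,
                function(q) all(q == p)))
  }
  new_inter <- numeric(6)
  for (k in 1:6) {
    ij <- biosorb:::interaction_pairs[k, ]
    new_inter[pair_index(inv[ij[1]], inv[ij[2]])] <- s$interaction[k]
  }
  s2 <- quadratic_surface(s$beta0, s$linear[perm], s$quadratic[perm],
                          new_inter)
  m1 <- maximize_surface(s, seed = 3)
  m2 <- maximize_surface(s2, seed = 3)
  expect_equal(m2$value, m1$value, tolerance = 1e-6)
  expect_equal(m2$x, m1$x[perm], tolerance = 1e-4)
})
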