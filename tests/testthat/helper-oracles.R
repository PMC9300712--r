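# Independent oracles used across test files. These deliberately avoid the
# package's own fitting/integration code paths.

# normal-equations least squares: solve (X'X) b = X'y directly
normal_equations_fit <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# dense grid search for the maximum of a quadratic surface over a coded box
grid_max_oracle <- function(surface, lower = -2, upper = 2, n = 21) {
  grid <- as.matrix(expand.grid(rep(list(seq(lower, upper,
                                             length.out = n)), 4)))
  vals <- predict(surface, grid)
  i <- which.max(vals)
  list(x = grid[i, ], value = vals[i])
}

# central finite-difference gradient of f at x (flattened parameter vector)
numeric_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# flatten / unflatten an mlp_network's weights for the gradient check
mlp_pack <- function(net) {
  c(as.vector(net$hidden_weights), net$hidden_bias,
    net$output_weights, net$output_bias)
}
mlp_unpack <- function(theta, net) {
  H <- nrow(net$hidden_weights)
  net$hidden_weights <- matrix(theta[1:(H * 4)], H, 4)
  net$hidden_bias <- theta[H * 4 + 1:H]
  net$output_weights <- theta[H * 5 + 1:H]
  net$output_bias <- theta[H * 6 + 1]
  net
}

# a small, well-behaved teacher network on the usual factor ranges
toy_network <- function(H = 2, seed = 42) {
  set.seed(seed)
  mlp_network(matrix(runif(H * 4, -1, 1), H, 4), runif(H, -0.5, 0.5),
              runif(H, -1, 1), 0.2, activation = "tansig",
              input_scaling = list(min = c(0.1, 2, 25, 0.1),
                                   max = c(1.3, 10, 45, 1.3)),
              output_scaling = c(40, 95))
}

# quadratic surface with the study's printed model coefficients
printed_surface <- function() {
  quadratic_surface(94.00, c(9.87, 0.017, 3.57, -5.98),
                    c(-8.68, -22.35, -4.3, -7.23),
                    c(-1.85, 5.75, -2.22, -0.53, 0.33, -1.3))
}
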