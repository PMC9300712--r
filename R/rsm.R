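interaction_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4),
                           c(2, 3), c(2, 4), c(3, 4))

# 31 x 15 model matrix (intercept, 4 linear, 4 square, 6 interaction)
# from a coded n x 4 matrix.
quadratic_model_matrix <- function(X) {
  stopifnot(is.matrix(X), ncol(X) == 4)
  sq <- X^2
  colnames(sq) <- paste0(colnames(X), "^2")
  inter <- apply(interaction_pairs, 1, function(p) X[, p[1]] * X[, p[2]])
  inter <- matrix(inter, nrow = nrow(X))
  colnames(inter) <- apply(interaction_pairs, 1, function(p)
    paste0("x", p[1], ":x", p[2]))
  cbind(`(Intercept)` = 1, X, sq, inter)
}

#' Construct a quadratic response surface
#'
#' The second-order polynomial response model in coded factor units:
#' \deqn{Y = \beta_0 + \sum_i \beta_i X_i + \sum_i \beta_{ii} X_i^2 +
#'   \sum_{i<j} \beta_{ij} X_i X_j}
#' Interactions are ordered (1,2), (1,3), (1,4), (2,3), (2,4), (3,4).
#'
#' @param beta0 intercept.
#' @param linear 4 linear coefficients.
#' @param quadratic 4 pure-quadratic coefficients.
#' @param interaction 6 interaction coefficients in the pair order above.
#' @param factor_specs factor specifications used to translate between coded
#'   and actual units when reporting.
#' @return object of class \code{quadratic_surface}.
#' @export
quadratic_surface <- function(beta0, linear, quadratic, interaction,
                              factor_specs = ccd_factors()) {
  stopifnot(length(beta0) == 1L, length(linear) == 4L,
            length(quadratic) == 4L, length(interaction) == 6L)
  structure(
    list(beta0 = as.numeric(beta0), linear = as.numeric(linear),
         quadratic = as.numeric(quadratic),
         interaction = as.numeric(interaction),
         factor_specs = factor_specs),
    class = "quadratic_surface")
}

#' @export
print.quadratic_surface <- function(x, ...) {
  cat("<quadratic_surface> (coded units)\n")
  cat(sprintf("  beta0       %8.3f\n", x$beta0))
  cat("  linear     ", sprintf("%8.3f", x$linear), "\n")
  cat("  quadratic  ", sprintf("%8.3f", x$quadratic), "\n")
  cat("  interaction", sprintf("%8.3f", x$interaction), "\n")
  invisible(x)
}

surface_coef_vector <- function(surface) {
  c(surface$beta0, surface$linear, surface$quadratic, surface$interaction)
}

#' Evaluate a quadratic surface at coded points
#'
#' @param object a \code{\link{quadratic_surface}}.
#' @param x coded factor values: a length-4 vector or an n x 4 matrix.
#' @param ... unused.
#' @return predicted response (percent removal), one value per row of
#'   \code{x}.
#' @export
predict.quadratic_surface <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 4, byrow = TRUE)
  x <- as.matrix(x)
  colnames(x) <- paste0("x", 1:4)
  drop(quadratic_model_matrix(x) %*% surface_coef_vector(object))
}

#' Fit the full quadratic response surface to a CCD dataset
#'
#' Ordinary least squares of observed percentage removal on the 15-term
#' second-order model in coded units, with fit statistics and an ANOVA table.
#' The residual is partitioned into lack of fit and pure error using the
#' centre-replicate (and any other replicated) factor settings, so the
#' adequacy of the quadratic can be tested against replication noise.
#'
#' @param dataset a \code{\link{ccd_dataset}} with at least 15 runs and a
#'   full-rank design.
#' @return list with components \code{surface}
#'   (\code{\link{quadratic_surface}}) and \code{stats}, the latter holding
#'   \code{r2}, \code{adj_r2}, \code{mean_pct_error} (mean absolute
#'   percentage error over all runs) and \code{anova} (data frame with
#'   regression, residual, lack-of-fit, pure-error and total rows).
#' @examples
#' fit <- fit_quadratic(table2_ccd())
#' fit$stats$r2
#' @export
fit_quadratic <- function(dataset) {
  stopifnot(inherits(dataset, "ccd_dataset"))
  X <- coded_matrix(dataset)
  y <- dataset$runs$removal_obs
  n <- length(y)
  M <- quadratic_model_matrix(X)
  p <- ncol(M) - 1L                     # non-intercept terms
  if (n < ncol(M))
    stop("need at least ", ncol(M), " runs to fit the 15-term model",
         call. = FALSE)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dropped <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrM, y)
  fitted <- drop(M %*% beta)
  res <- y - fitted

  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(res^2)
  ss_reg <- ss_tot - ss_res
  df_reg <- p
  df_res <- n - p - 1L
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res

  # pure error from replicated factor settings
  key <- apply(X, 1, paste, collapse = "|")
  ss_pe <- sum(tapply(y, key, function(v) sum((v - mean(v))^2)))
  df_pe <- n - length(unique(key))
  ss_lof <- ss_res - ss_pe
  df_lof <- df_res - df_pe

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  anova_tab <- data.frame(
    source = c("regression", "residual", "lack_of_fit", "pure_error",
               "total"),
    df = c(df_reg, df_res, df_lof, df_pe, n - 1L),
    ss = c(ss_reg, ss_res, ss_lof, ss_pe, ss_tot),
    stringsAsFactors = FALSE)
  anova_tab$ms <- ifelse(anova_tab$df > 0, anova_tab$ss / anova_tab$df,
                         NA_real_)
  anova_tab$f <- NA_real_
  anova_tab$p <- NA_real_
  if (df_res > 0) {
    anova_tab$f[1] <- ms(ss_reg, df_reg) / ms(ss_res, df_res)
    anova_tab$p[1] <- pf(anova_tab$f[1], df_reg, df_res, lower.tail = FALSE)
  }
  if (df_pe > 0 && df_lof > 0) {
    anova_tab$f[3] <- ms(ss_lof, df_lof) / ms(ss_pe, df_pe)
    anova_tab$p[3] <- pf(anova_tab$f[3], df_lof, df_pe, lower.tail = FALSE)
  }

  surface <- quadratic_surface(beta[1], beta[2:5], beta[6:9], beta[10:15],
                               factor_specs = dataset$factors)
  list(surface = surface,
       stats = list(r2 = r2, adj_r2 = adj_r2,
                    mean_pct_error = mean(abs(res) / y * 100),
                    anova = anova_tab))
}

#' Maximise a quadratic surface over a coded box
#'
#' Multi-start bounded local optimisation: one start at every corner of the
#' box, one at the centre, and optional extra random starts. With several
#' equally good optima the one with the smallest coded L2 norm is reported.
#'
#' @param surface a \code{\link{quadratic_surface}}.
#' @param lower,upper coded bounds, scalars or length-4 vectors
#'   (default \code{[-2, 2]^4}).
#' @param n_random extra uniform random starts (default 8; seeded runs
#'   reproduce via \code{seed}).
#' @param seed optional integer seed for the random starts.
#' @return list with \code{x} (coded maximiser), \code{x_actual} (actual
#'   units) and \code{value} (predicted response at the maximum).
#' @export
maximize_surface <- function(surface, lower = -2, upper = 2,
                             n_random = 8, seed = NULL) {
  stopifnot(inherits(surface, "quadratic_surface"))
  lower <- rep_len(lower, 4); upper <- rep_len(upper, 4)
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(lower <= upper))
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), 4)))
  starts <- sweep(sweep(corners, 2, upper - lower, `*`), 2, lower, `+`)
  starts <- rbind(starts, (lower + upper) / 2)
  if (n_random > 0) {
    extra <- with_seed(seed, function()
      matrix(runif(4 * n_random, lower, upper), ncol = 4, byrow = TRUE))
    starts <- rbind(starts, extra)
  }
  obj <- function(z) -predict(surface, z)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- optim(starts[i, ], obj, method = "L-BFGS-B",
                 lower = lower, upper = upper)
    cand <- list(x = pmin(pmax(res$par, lower), upper), value = -res$value)
    if (is.null(best) || cand$value > best$value + 1e-9 ||
        (abs(cand$value - best$value) <= 1e-9 &&
         sum(cand$x^2) < sum(best$x^2)))
      best <- cand
  }
  x_actual <- mapply(decode_factor, best$x, surface$factor_specs)
  list(x = unname(best$x), x_actual = unname(x_actual), value = best$value)
}
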