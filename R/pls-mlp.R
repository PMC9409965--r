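# One-component PLS regression on a 0/1 response, thresholded for
# discriminant analysis. The single latent direction maximizes the
# covariance between the data matrix and the response; with one component
# the regression coefficient vector is the (normalized) weight vector scaled
# by the score regression coefficient.
pls1_fit <- function(x, y, threshold = 0.5) {
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2L, x_mean, "-")
  yc <- y - y_mean
  w <- drop(crossprod(xc, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("PLS-DA weight vector is zero (no covariance with labels)",
                    call. = FALSE)
  w <- w / nw
  t_score <- drop(xc %*% w)
  q <- sum(t_score * yc) / sum(t_score^2)
  list(beta = w * q, x_mean = x_mean, y_mean = y_mean, threshold = threshold)
}

# Continuous PLS output thresholded; scores exactly at the threshold go to
# class 1.
pls1_predict <- function(model, x) {
  yhat <- model$y_mean + drop(sweep(x, 2L, model$x_mean, "-") %*% model$beta)
  as.integer(yhat >= model$threshold)
}

# Minimal fully-connected two-hidden-layer perceptron (ReLU hidden units,
# logistic output) trained full-batch with Adam on the cross-entropy loss.
# Sized for small tabular panels, where a handful of matrix products per
# iteration is cheap.
mlp_fit <- function(x, y, hidden = c(32L, 16L), maxit = 1000L,
                    learn_rate = 0.01, tol = 1e-8) {
  stopifnot(length(hidden) == 2L)
  n <- nrow(x)
  sizes <- c(ncol(x), hidden, 1L)
  he_init <- function(fan_in, fan_out) {
    matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
           fan_in, fan_out)
  }
  w <- list(he_init(sizes[1], sizes[2]), he_init(sizes[2], sizes[3]),
            he_init(sizes[3], sizes[4]))
  b <- list(numeric(sizes[2]), numeric(sizes[3]), numeric(sizes[4]))
  mw <- lapply(w, function(z) z * 0); vw <- mw
  mb <- lapply(b, function(z) z * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  sigmoid <- function(z) 1 / (1 + exp(-z))
  prev_loss <- Inf
  for (it in seq_len(maxit)) {
    z1 <- sweep(x %*% w[[1]], 2L, b[[1]], "+"); h1 <- pmax(z1, 0)
    z2 <- sweep(h1 %*% w[[2]], 2L, b[[2]], "+"); h2 <- pmax(z2, 0)
    p <- sigmoid(drop(sweep(h2 %*% w[[3]], 2L, b[[3]], "+")))
    p_cl <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p_cl) + (1 - y) * log(1 - p_cl))
    if (abs(prev_loss - loss) < tol) break
    prev_loss <- loss
    d3 <- matrix((p - y) / n, ncol = 1L)
    gw3 <- crossprod(h2, d3); gb3 <- colSums(d3)
    d2 <- (d3 %*% t(w[[3]])) * (z2 > 0)
    gw2 <- crossprod(h1, d2); gb2 <- colSums(d2)
    d1 <- (d2 %*% t(w[[2]])) * (z1 > 0)
    gw1 <- crossprod(x, d1); gb1 <- colSums(d1)
    gws <- list(gw1, gw2, gw3); gbs <- list(gb1, gb2, gb3)
    for (l in 1:3) {
      mw[[l]] <- beta1 * mw[[l]] + (1 - beta1) * gws[[l]]
      vw[[l]] <- beta2 * vw[[l]] + (1 - beta2) * gws[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gbs[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gbs[[l]]^2
      mw_hat <- mw[[l]] / (1 - beta1^it); vw_hat <- vw[[l]] / (1 - beta2^it)
      mb_hat <- mb[[l]] / (1 - beta1^it); vb_hat <- vb[[l]] / (1 - beta2^it)
      w[[l]] <- w[[l]] - learn_rate * mw_hat / (sqrt(vw_hat) + eps)
      b[[l]] <- b[[l]] - learn_rate * mb_hat / (sqrt(vb_hat) + eps)
    }
  }
  list(w = w, b = b, iterations = it, loss = loss)
}

mlp_predict <- function(model, x) {
  w <- model$w; b <- model$b
  h1 <- pmax(sweep(x %*% w[[1]], 2L, b[[1]], "+"), 0)
  h2 <- pmax(sweep(h1 %*% w[[2]], 2L, b[[2]], "+"), 0)
  p <- 1 / (1 + exp(-drop(sweep(h2 %*% w[[3]], 2L, b[[3]], "+"))))
  as.integer(p >= 0.5)
}
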