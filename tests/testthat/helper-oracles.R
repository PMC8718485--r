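# Independent reference implementations used only as test oracles.

# FISTA proximal-gradient solver for the summed weighted logistic
# objective with L1 (soft-threshold prox) or L2 (smooth) penalty and an
# unpenalized intercept. Deliberately shares no code with the package.
proxgrad_logistic <- function(X, y, w = NULL, lambda, penalty = "l1",
                              max_iter = 20000, tol = 1e-12) {
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, length(y))
  p <- ncol(X)
  th <- rep(0, p + 1)             # (intercept, theta)
  zk <- th
  tk <- 1
  A <- cbind(1, X)
  loss <- function(par) {
    eta <- drop(A %*% par)
    sum(w * (-y * eta + ifelse(eta > 30, eta, log1p(exp(eta)))))
  }
  grad <- function(par) {
    eta <- drop(A %*% par)
    drop(crossprod(A, w * (plogis(eta) - y)))
  }
  smooth_pen <- function(par)
    if (penalty == "l2") lambda * sum(par[-1]^2) else 0
  grad_pen <- function(par)
    if (penalty == "l2") c(0, 2 * lambda * par[-1]) else 0
  obj <- function(par)
    loss(par) + smooth_pen(par) +
      if (penalty == "l1") lambda * sum(abs(par[-1])) else 0
  L <- 0.25 * norm(sqrt(w) * A, "2")^2 + if (penalty == "l2") 2 * lambda else 0
  step <- 1 / L
  prev_obj <- obj(th)
  for (it in seq_len(max_iter)) {
    g <- grad(zk) + grad_pen(zk)
    par <- zk - step * g
    if (penalty == "l1") {
      s <- lambda * step
      par[-1] <- sign(par[-1]) * pmax(abs(par[-1]) - s, 0)
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zk <- par + ((tk - 1) / t_next) * (par - th)
    tk <- t_next
    th <- par
    if (it %% 50 == 0) {
      cur <- obj(th)
      if (abs(prev_obj - cur) < tol * (abs(cur) + 1)) break
      prev_obj <- cur
    }
  }
  list(intercept = th[1], theta = th[-1], objective = obj(th))
}

# plain Newton-Raphson weighted logistic MLE (no penalty)
newton_logistic <- function(X, y, w = NULL, max_iter = 100, tol = 1e-12) {
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, length(y))
  A <- cbind(1, X)
  par <- rep(0, ncol(A))
  for (it in seq_len(max_iter)) {
    eta <- drop(A %*% par)
    mu <- plogis(eta)
    g <- crossprod(A, w * (mu - y))
    H <- crossprod(A * (w * mu * (1 - mu)), A)
    delta <- solve(H, g)
    par <- par - delta
    if (max(abs(delta)) < tol) break
  }
  list(intercept = par[1], theta = par[-1])
}

# O(n^2) pair-enumeration weighted AUC
brute_auc <- function(scores, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  pos <- which(y == 1); neg <- which(y == 0)
  num <- 0; den <- 0
  for (i in pos) for (j in neg) {
    ww <- w[i] * w[j]
    num <- num + ww * ((scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j]))
    den <- den + ww
  }
  num / den
}

# exhaustive threshold search minimizing weighted BER (predict positive
# when score strictly exceeds the threshold; ties -> lowest threshold)
brute_threshold <- function(scores, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  cand <- sort(unique(scores))
  best <- cand[1]; best_ber <- Inf
  for (t in cand) {
    yhat <- as.integer(scores > t)
    tp <- sum(w[yhat == 1 & y == 1]); fn <- sum(w[yhat == 0 & y == 1])
    tn <- sum(w[yhat == 0 & y == 0]); fp <- sum(w[yhat == 1 & y == 0])
    ber <- 1 - (tp / (tp + fn) + tn / (tn + fp)) / 2
    if (ber < best_ber - 1e-15) { best_ber <- ber; best <- t }
  }
  best
}

# discrete-curvature knee oracle: central second differences on the
# smoothed (range-normalized) curve values
discrete_knee_oracle <- function(values) {
  p <- length(values)
  r <- seq_len(p)
  yn <- (values - min(values)) / (max(values) - min(values))
  sp <- smooth.spline(r, yn)
  cap <- min(6, p - 1)
  if (sp$df > cap) sp <- smooth.spline(r, yn, df = cap)
  f <- predict(sp, r)$y
  d2 <- abs(f[3:p] - 2 * f[2:(p - 1)] + f[1:(p - 2)])
  d1 <- (f[3:p] - f[1:(p - 2)]) / 2
  kappa <- d2 / (1 + d1^2)^1.5
  (2:(p - 1))[which.max(kappa)]
}

# random convex decreasing curve (noise-free up to a small jitter floor)
random_convex_curve <- function(p, rate = runif(1, 0.5, 3)) {
  d <- sort(rexp(p - 1, rate = rate), decreasing = TRUE)
  v <- rev(cumsum(c(0, d)))
  v - min(v) + runif(1, 0, 0.1)
}
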