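# Independent textbook NIPALS PLS1 oracle, written with explicit scalar-ish
# loops and kept deliberately naive. Used to cross-check the package's PLS
# core on small instances.

oracle_nipals_pls1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- X - matrix(x_mean, n, p, byrow = TRUE)
  f <- y - y_mean
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  tt <- numeric(ncomp)
  for (a in 1:ncomp) {
    w <- numeric(p)
    for (j in 1:p) w[j] <- sum(E[, j] * f)
    w <- w / sqrt(sum(w^2))
    t <- numeric(n)
    for (i in 1:n) t[i] <- sum(E[i, ] * w)
    t2 <- sum(t^2)
    pl <- numeric(p)
    for (j in 1:p) pl[j] <- sum(E[, j] * t) / t2
    qa <- sum(t * f) / t2
    E <- E - t %*% t(pl)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pl; q[a] <- qa; tt[a] <- t2
  }
  # regression coefficients for the ncomp-rank model
  B <- W %*% solve(t(P) %*% W) %*% q
  list(W = W, P = P, q = q, tt = tt, coefficients = drop(B),
       x_mean = x_mean, y_mean = y_mean)
}

oracle_nipals_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  drop(fit$y_mean + (Xnew - matrix(fit$x_mean, nrow(Xnew), ncol(Xnew),
                                   byrow = TRUE)) %*% fit$coefficients)
}
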